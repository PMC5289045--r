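# plastome data model and format round-trips

test_that("plastome constructor normalizes and validates", {
  p <- plastome("x", "acgt")
  expect_equal(p$sequence, "ACGT")
  expect_equal(p$length, 4L)
  expect_equal(plastome("x", "acgu")$sequence, "ACGT")  # U -> T
  expect_error(plastome("x", "ACGZ"), "non-IUPAC")
  expect_error(plastome("x", ""), "empty")
})

test_that("FASTA read/write round-trips byte-stably with 60-column wrap", {
  tmp <- withr::local_tempfile(fileext = ".fasta")
  set.seed(1)
  for (len in c(10L, 60L, 61L, 1234L)) {
    p <- plastome("g1", random_seq(len))
    write_plastome(p, tmp)
    lines <- readLines(tmp)
    expect_true(all(nchar(lines[-1]) <= 60L))
    p2 <- read_plastome(tmp)
    expect_identical(p2$sequence, p$sequence)
    expect_identical(p2$id, p$id)
    # byte-stable: writing the re-read object reproduces the file
    tmp2 <- withr::local_tempfile(fileext = ".fasta")
    write_plastome(p2, tmp2)
    expect_identical(readLines(tmp2), lines)
  }
})

test_that("a 151,338-base record round-trips at full plastome scale", {
  tmp <- withr::local_tempfile(fileext = ".fasta")
  p <- plastome("chr", random_seq(151338L, seed = 2))
  write_plastome(p, tmp)
  p2 <- read_plastome(tmp)
  expect_equal(p2$length, 151338L)
  expect_identical(p2$sequence, p$sequence)
})

test_that("GFF3 features read back with kinds, strands and exon structure", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  gff <- withr::local_tempfile(fileext = ".gff3")
  p <- plastome("g1", random_seq(300, seed = 3),
                features = gene_features(
                  name = c("geneA", "trnX-AAA", "geneB", "geneB"),
                  kind = c("CDS", "tRNA", "CDS", "CDS"),
                  strand = c("+", "-", "+", "+"),
                  start = c(2L, 50L, 100L, 160L),
                  end = c(7L, 124L, 150L, 201L),
                  feature_id = c("geneA", "trnX", "geneB", "geneB"),
                  exon = c(1L, 1L, 1L, 2L)))
  write_plastome(p, fa, gff_path = gff)
  p2 <- read_plastome(fa, annotation_path = gff)
  expect_equal(nrow(p2$features), 4L)
  ga <- p2$features[p2$features$name == "geneA", ]
  expect_equal(ga$kind, "CDS")
  expect_equal(c(ga$start, ga$end), c(2L, 7L))
  gb <- p2$features[p2$features$name == "geneB", ]
  expect_equal(nrow(gb), 2L)
  expect_equal(sort(gb$exon), c(1L, 2L))
  expect_equal(p2$features$strand[p2$features$name == "trnX-AAA"], "-")
})

test_that("GFF3 seqid mismatch is rejected", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  gff <- withr::local_tempfile(fileext = ".gff3")
  p <- plastome("right", random_seq(100, seed = 4),
                features = gene_features("g", "CDS", "+", 10L, 30L))
  write_plastome(p, fa, gff_path = gff)
  p$id <- "wrong"
  fa2 <- withr::local_tempfile(fileext = ".fasta")
  write_plastome(p, fa2)
  expect_error(read_plastome(fa2, annotation_path = gff), "seqid")
})

test_that("minimal GenBank flat records parse", {
  gb <- withr::local_tempfile(fileext = ".gb")
  writeLines(c(
    "LOCUS       TESTREC 120 bp DNA circular",
    "FEATURES             Location/Qualifiers",
    "     CDS             join(10..30,51..70)",
    '                     /gene="geneX"',
    "                     /codon_start=1",
    "     tRNA            complement(80..110)",
    '                     /gene="trnQ"',
    "ORIGIN",
    paste0("        1 ", paste(rep("acgtacgtac", 6), collapse = " ")),
    paste0("       61 ", paste(rep("acgtacgtac", 6), collapse = " ")),
    "//"), gb)
  p <- read_plastome(gb, format = "genbank")
  expect_equal(p$id, "TESTREC")
  expect_equal(p$length, 120L)
  cds <- p$features[p$features$kind == "CDS", ]
  expect_equal(nrow(cds), 2L)          # two exons
  expect_equal(cds$start, c(10L, 51L))
  trna <- p$features[p$features$kind == "tRNA", ]
  expect_equal(trna$strand, "-")
  expect_equal(trna$name, "trnQ")
})

test_that("default enzyme catalog covers the CAPS enzymes and validates", {
  cat0 <- read_enzyme_catalog()
  need <- c("TaqI", "NcoI", "KpnI", "HinfI", "MspI", "AluI", "DpnII", "RsaI",
            "BanI", "MluI", "HaeIII", "ScrFI", "BstEII", "XbaI")
  expect_true(all(need %in% cat0$name))
  expect_equal(cat0$recognition[cat0$name == "NcoI"], "CCATGG")
  # palindromy flag agrees with an independent reverse-complement check
  expect_equal(cat0$palindromic, cat0$recognition == revcomp(cat0$recognition))
  expect_true(all(nchar(cat0$recognition) >= 4))
  expect_true(all(cat0$cut_offset >= 0 & cat0$cut_offset <= nchar(cat0$recognition)))
})

test_that("enzyme catalog rejects bad input, warns on empty", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("name\trecognition\tcut_offset", "BadI\tACQT\t1"), tmp)
  expect_error(read_enzyme_catalog(tmp), "non-IUPAC")
  file.create(tmp2 <- withr::local_tempfile(fileext = ".tsv"))
  expect_warning(cat2 <- read_enzyme_catalog(tmp2), "empty")
  expect_equal(nrow(cat2), 0L)
})

test_that("VCF writer emits a valid v4.2 subset and round-trips", {
  ref <- flat_genome(500, seed = 5, id = "ref1")
  refv <- strsplit(ref$sequence, "")[[1]]
  pos <- c(40L, 100L, 333L)
  alt <- ifelse(refv[pos] == "A", "G", "A")
  rec <- data.frame(pos = pos, ref = refv[pos], allele_a = refv[pos],
                    allele_b = alt,
                    class = c("fixed_interspecific", "intraspecific_polymorphic",
                              "fixed_interspecific"),
                    depth_a = 100L, depth_b = 120L, pos_b = pos,
                    mirror_pos = NA_integer_)
  tmp <- withr::local_tempfile(fileext = ".vcf")
  write_variants_vcf(rec, ref, tmp)
  lines <- readLines(tmp)
  expect_equal(lines[1], "##fileformat=VCFv4.2")
  body <- lines[!startsWith(lines, "#")]
  expect_equal(length(body), 3L)
  fields <- strsplit(body, "\t")
  expect_true(all(lengths(fields) == 8L))
  expect_match(body[1], "CLASS=fixed_interspecific")
  # positions sorted
  expect_false(is.unsorted(as.integer(vapply(fields, `[`, "", 2))))
  # round-trip through an independent VCF reader
  skip_if_not_installed("VariantAnnotation")
  v <- VariantAnnotation::readVcf(tmp)
  expect_equal(BiocGenerics::start(SummarizedExperiment::rowRanges(v)), pos)
  expect_equal(as.character(VariantAnnotation::ref(v)), refv[pos])
})

test_that("VCF writer refuses alleles inconsistent with the reference", {
  ref <- flat_genome(100, seed = 6)
  rec <- data.frame(pos = 10L, ref = "N", allele_a = "N", allele_b = "A",
                    class = "fixed_interspecific", depth_a = 10L, depth_b = 10L)
  expect_error(write_variants_vcf(rec, ref, withr::local_tempfile()),
               "disagrees")
})

test_that("a 16-record variant set writes 16 data lines", {
  ref <- flat_genome(2000, seed = 7)
  refv <- strsplit(ref$sequence, "")[[1]]
  pos <- as.integer(seq(50, 1950, length.out = 16))
  rec <- data.frame(pos = pos, ref = refv[pos], allele_a = refv[pos],
                    allele_b = ifelse(refv[pos] == "C", "T", "C"),
                    class = "fixed_interspecific", depth_a = 50L, depth_b = 60L)
  tmp <- withr::local_tempfile(fileext = ".vcf")
  write_variants_vcf(rec, ref, tmp)
  expect_equal(sum(!startsWith(readLines(tmp), "#")), 16L)
})

test_that("SAM subset round-trips through write_sam/read_sam", {
  ref <- flat_genome(400, seed = 8)
  aln <- data.frame(qname = c("r1", "r2"), pos = c(5L, 100L),
                    strand = c("+", "-"),
                    seq = c(substr(ref$sequence, 5, 54),
                            substr(ref$sequence, 100, 149)),
                    nm = c(0L, 1L), tie = FALSE, cigar = "50M",
                    stringsAsFactors = FALSE)
  tmp <- withr::local_tempfile(fileext = ".sam")
  write_sam(aln, ref, tmp)
  back <- read_sam(tmp)
  expect_equal(back$pos, aln$pos)
  expect_equal(back$strand, aln$strand)
  expect_equal(back$seq, aln$seq)
})

test_that("read_sam rejects unsupported dialects and honors soft clips", {
  tmp <- withr::local_tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6",
               "r1\t1\tref\t10\t60\t50M\t*\t0\t0\tACGT\t*"), tmp)
  expect_error(read_sam(tmp), "paired")
  writeLines(c("r1\t0\tref\t10\t60\t10M100N10M\t*\t0\t0\tACGT\t*"), tmp)
  expect_error(read_sam(tmp), "CIGAR")
  writeLines(c(sprintf("r1\t0\tref\t10\t60\t3S6M\t*\t0\t0\t%s\t*", "TTTACGTAC")),
             tmp)
  ok <- read_sam(tmp)
  expect_equal(ok$seq, "ACGTAC")
  expect_equal(ok$cigar, "6M")
})
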