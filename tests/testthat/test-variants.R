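# Read mapping, pileup, site classification, IR mirroring, EST selection.

test_that("error-free reads place exactly, including across the origin", {
  g <- flat_genome(5000, seed = 41)
  r1 <- substr(g$sequence, 1000, 1149)
  # read spanning the circular origin
  r2 <- paste0(substr(g$sequence, 4951, 5000), substr(g$sequence, 1, 99))
  aln <- map_reads_exactish(c(r1, r2), g)
  expect_equal(aln$pos[aln$seq == r1], 1000L)
  expect_equal(aln$nm, c(0L, 0L))
  expect_equal(sort(aln$pos), c(1000L, 4951L))
})

test_that("simulated reads map within one base of truth (mirror-aware)", {
  w <- small_world()
  A <- w$species$A
  pan <- derive_genotype_panel(A, 4L, 20L, seed = 42L)
  cfg <- synth_config(length = A$length, coverage = 80, error_rate = 0.002)
  rp <- simulate_pooled_reads(pan$genotypes, cfg, seed = 43L)
  rp$reads <- rp$reads[seq_len(10000L), ]
  aln <- map_reads_exactish(rp$reads, A)
  expect_gte(nrow(aln) / 10000, 0.97)
  tp <- rp$reads$truth_pos[match(aln$qname, rp$reads$id)]
  part <- w$part_a
  mir <- plastmarker:::mirror_position(
    part, plastmarker:::wrap_pos(tp + cfg$read_length - 1L, A$length))
  ok <- abs(aln$pos - tp) <= 1L | (!is.na(mir) & abs(aln$pos - mir) <= 1L)
  expect_gte(mean(ok), 0.99)
})

test_that("pileup tallies depths and disagreements per position", {
  g <- plastome("tiny", "ACGTACGTACGTACGTACGT")
  aln <- data.frame(qname = c("r1", "r2", "r3"), pos = c(1L, 3L, 3L),
                    strand = "+", seq = c("ACGTA", "GTACG", "GAACG"),
                    nm = c(0L, 0L, 1L), tie = FALSE, cigar = "5M",
                    stringsAsFactors = FALSE)
  pc <- pileup(aln, g)
  expect_equal(pc$depth[1:8], c(1L, 1L, 3L, 3L, 3L, 2L, 2L, 0L))
  # r2 and r3 disagree at position 4 (T vs A)
  expect_equal(unname(pc$counts[4, c("T", "A")]), c(2L, 1L))
  expect_equal(pc$summary$min, 1L)
  expect_equal(pc$summary$max, 3L)
  expect_error(pileup(transform(aln, pos = 100L), g), "beyond")
})

test_that("pileup handles I/D CIGARs and records gap positions", {
  g <- plastome("tiny", strrep("ACGT", 10))
  aln <- data.frame(qname = "r1", pos = 1L, strand = "+",
                    seq = "ACGTCGT",      # 4M2D3M relative to ACGTACGTACG
                    nm = 2L, tie = FALSE, cigar = "4M2D3M",
                    stringsAsFactors = FALSE)
  pc <- pileup(aln, g)
  expect_equal(unname(pc$counts[5, "del"]), 1L)
  expect_equal(unname(pc$counts[6, "del"]), 1L)
  expect_equal(pc$depth[7], 1L)
  expect_true(all(c(5L, 6L) %in% pc$gap_positions))
})

test_that("mean pileup depth tracks target coverage on a unique genome", {
  g <- flat_genome(10000, seed = 44)
  cfg <- synth_config(length = 10000L, coverage = 300, error_rate = 0.002)
  rp <- simulate_pooled_reads(list(g), cfg, seed = 45L)
  expect_equal(rp$coverage_summary$mean, 300, tolerance = 0.01)
  pc <- pileup(map_reads_exactish(rp$reads, g), g)
  expect_gte(pc$summary$mean, 285)
  expect_lte(pc$summary$mean, 315)
})

test_that("classification thresholds behave as documented", {
  ref <- flat_genome(200, seed = 46)
  cfg <- run_config()
  cls_of <- function(a_spec, b_spec) {
    ca <- counts_at(ref, a_spec, "A")
    cb <- counts_at(ref, b_spec, "B")
    rec <- classify_sites(ca, cb, ref, cfg, all_sites = TRUE)
    rec$class[50]
  }
  expect_equal(cls_of(list(`50` = c(T = 100)), list(`50` = c(C = 100))),
               "fixed_interspecific")
  expect_equal(cls_of(list(`50` = c(T = 60, C = 40)), list(`50` = c(C = 100))),
               "intraspecific_polymorphic")
  # 1% minor allele treated as sequencing error: still fixed
  expect_equal(cls_of(list(`50` = c(T = 99, C = 1)), list(`50` = c(C = 100))),
               "fixed_interspecific")
  expect_equal(cls_of(list(`50` = c(T = 100)), list(`50` = c(T = 100))),
               "monomorphic_shared")
  expect_equal(cls_of(list(`50` = c(T = 10)), list(`50` = c(C = 100))),
               "low_coverage")
  # minor at 3% but fewer than 5 reads -> not polymorphic
  expect_equal(cls_of(list(`50` = c(T = 96, C = 4)), list(`50` = c(T = 130))),
               "ambiguous")
})

test_that("classification is symmetric up to label swap", {
  ref <- flat_genome(300, seed = 47)
  cfg <- run_config()
  set.seed(48)
  spec_a <- list(); spec_b <- list()
  for (p in seq(20, 280, by = 20)) {
    spec_a[[as.character(p)]] <- c(T = sample(0:100, 1), C = sample(0:100, 1))
    spec_b[[as.character(p)]] <- c(T = sample(0:100, 1), G = sample(0:100, 1))
  }
  ca <- counts_at(ref, spec_a, "A"); cb <- counts_at(ref, spec_b, "B")
  r1 <- classify_sites(ca, cb, ref, cfg, all_sites = TRUE)
  r2 <- classify_sites(cb, ca, ref, cfg, all_sites = TRUE)
  expect_equal(r1$class, r2$class)
  expect_equal(r1$allele_a, r2$allele_b)
  expect_equal(r1$allele_b, r2$allele_a)
})

test_that("raising fixed_freq never grows the fixed set", {
  ref <- flat_genome(300, seed = 49)
  set.seed(50)
  spec_a <- list(); spec_b <- list()
  for (p in seq(10, 290, by = 10)) {
    spec_a[[as.character(p)]] <- c(T = sample(50:100, 1), C = sample(0:10, 1))
    spec_b[[as.character(p)]] <- c(C = sample(50:100, 1), T = sample(0:10, 1))
  }
  ca <- counts_at(ref, spec_a, "A"); cb <- counts_at(ref, spec_b, "B")
  prev <- NULL
  for (ff in c(0.9, 0.95, 0.98, 0.995)) {
    cfg <- run_config(fixed_freq = ff)
    rec <- classify_sites(ca, cb, ref, cfg, all_sites = TRUE)
    fixed <- rec$pos[rec$class == "fixed_interspecific"]
    if (!is.null(prev)) expect_true(all(fixed %in% prev))
    prev <- fixed
  }
})

test_that("IR mirroring collapses concordant sites and flags discordance", {
  w <- small_world()
  ref <- w$species$A
  part <- w$part_a
  ira_pos <- part$ira[1] + 10L
  irb_pos <- plastmarker:::mirror_position(part, ira_pos)
  lsc_pos <- 100L
  refb <- function(p) substring(ref$sequence, p, p)
  other <- function(b) if (b == "T") "C" else "T"
  comp <- function(b) chartr("ACGT", "TGCA", b)
  mkrec <- function(rows) {
    rec <- do.call(rbind, rows)
    rec$pos_b <- NA_integer_; rec$mirror_pos <- NA_integer_
    class(rec) <- c("variant_records", "data.frame")
    rec
  }
  row_at <- function(p, cls, aa, ab) {
    data.frame(pos = p, ref = refb(p), allele_a = aa, allele_b = ab,
               class = cls, depth_a = 100L, depth_b = 100L,
               maf_a = 1, maf_b = 1, stringsAsFactors = FALSE)
  }
  # concordant IR pair + LSC singleton
  aa <- refb(ira_pos); ab <- other(aa)
  rec <- mkrec(list(
    row_at(ira_pos, "fixed_interspecific", aa, ab),
    row_at(irb_pos, "fixed_interspecific", comp(aa), comp(ab)),
    row_at(lsc_pos, "fixed_interspecific", refb(lsc_pos), other(refb(lsc_pos)))))
  out <- mirror_ir_sites(rec, part)
  expect_equal(nrow(out), 2L)
  ir_row <- out[out$pos == ira_pos, ]
  expect_equal(ir_row$mirror_pos, irb_pos)
  expect_equal(ir_row$mirror_status, "concordant")
  expect_equal(ir_row$class, "fixed_interspecific")
  expect_true(is.na(out$mirror_pos[out$pos == lsc_pos]))
  # discordant pair -> ambiguous
  rec2 <- mkrec(list(
    row_at(ira_pos, "fixed_interspecific", aa, ab),
    row_at(irb_pos, "intraspecific_polymorphic", comp(aa), comp(aa))))
  out2 <- mirror_ir_sites(rec2, part)
  expect_equal(nrow(out2), 1L)
  expect_equal(out2$class, "ambiguous")
  expect_equal(out2$mirror_status, "discordant")
  # lone IRb record re-coordinated to IRa with complemented alleles
  rec3 <- mkrec(list(row_at(irb_pos, "fixed_interspecific", comp(aa), comp(ab))))
  out3 <- mirror_ir_sites(rec3, part)
  expect_equal(out3$pos, ira_pos)
  expect_equal(out3$allele_a, aa)
  expect_equal(out3$mirror_status, "mirror_absent")
})

test_that("EST column selection follows the perfect-partition + redundancy rule", {
  contigs <- list(
    list(name = "c1",
         seqs = c("ATGGA", "ATGGA", "ATCGA", "ATCGA"),
         species = c("sp1", "sp1", "sp2", "sp2")),
    list(name = "c2",   # redundancy failure: sp1 allele observed once
         seqs = c("AAAA", "GCAA", "GCAA"),
         species = c("sp1", "sp2", "sp2")),
    list(name = "c3",   # single species -> skipped
         seqs = c("ATAT", "ATAT"), species = c("sp1", "sp1")),
    list(name = "c4",   # gap column skipped
         seqs = c("A-G", "A-G", "A-C", "A-C"),
         species = c("sp1", "sp1", "sp2", "sp2")))
  expect_message(out <- select_est_interspecific(contigs), "single-species")
  expect_equal(out$contig, c("c1", "c4"))
  expect_equal(out$column, c(3L, 3L))
  expect_equal(out$allele_sp1, c("G", "G"))
  expect_equal(out$allele_sp2, c("C", "C"))
})

test_that("EST selection equals a brute-force column scan on random inputs", {
  set.seed(51)
  brute <- function(cg, min_red = 2L) {
    if (length(unique(cg$species)) < 2L) return(integer(0))
    m <- do.call(rbind, strsplit(cg$seqs, ""))
    keep <- integer(0)
    for (j in seq_len(ncol(m))) {
      col <- m[, j]
      if (any(col == "-")) next
      sp <- split(col, cg$species)
      if (any(lengths(sp) < min_red)) next
      if (any(vapply(sp, function(x) length(unique(x)) != 1L, logical(1)))) next
      if (anyDuplicated(vapply(sp, `[`, "", 1L))) next
      keep <- c(keep, j)
    }
    keep
  }
  for (rep in 1:25) {
    n <- sample(4:8, 1)
    w <- sample(10:30, 1)
    cg <- list(name = "r",
               seqs = vapply(seq_len(n), function(i) {
                 paste(sample(c("A", "C", "G", "T", "-"), w, replace = TRUE,
                              prob = c(0.3, 0.25, 0.2, 0.2, 0.05)),
                       collapse = "")
               }, character(1)),
               species = sample(c("x", "y"), n, replace = TRUE))
    got <- suppressMessages(select_est_interspecific(list(cg)))
    expect_setequal(got$column, brute(cg))
  }
})
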