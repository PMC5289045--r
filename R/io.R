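# Readers and writers for every external format the pipeline touches:
# FASTA (60-column), GFF3 (via rtracklayer), a minimal GenBank flat-file
# feature parser, a minimal VCF v4.2 writer, and the TSV enzyme catalog.

#' Read a plastome from FASTA or GenBank flat file
#'
#' @param path path to the sequence file.
#' @param format `"fasta"` (default) or `"genbank"` (minimal flat-file
#'   dialect: LOCUS/FEATURES/ORIGIN with CDS, tRNA and rRNA keys,
#'   `join()`/`complement()` locations and `/gene`, `/codon_start`,
#'   `/pseudo` qualifiers).
#' @param annotation_path optional GFF3 file; its seqid must match the
#'   record id.
#' @return a [plastome()].
#' @export
read_plastome <- function(path, format = c("fasta", "genbank"),
                          annotation_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "fasta") {
    set <- tryCatch(Biostrings::readDNAStringSet(path),
                    error = function(e) stop(sprintf("malformed FASTA '%s': %s",
                                                     path, conditionMessage(e)),
                                             call. = FALSE))
    if (length(set) == 0L) stop("no records in ", path, call. = FALSE)
    id <- strsplit(names(set)[1], "[ \t]")[[1]][1]
    p <- plastome(id, as.character(set[[1]]))
  } else {
    p <- read_genbank_flat(path)
  }
  if (!is.null(annotation_path)) {
    feats <- read_gff3_features(annotation_path, expected_seqid = p$id,
                                genome_length = p$length)
    p$features <- feats
  }
  p
}

#' Write a plastome
#'
#' FASTA output is 60-column wrapped and round-trips byte-stably through
#' [read_plastome()]. If the plastome carries features and `gff_path` is
#' given, a GFF3 companion file is written.
#'
#' @param p a [plastome()].
#' @param path output FASTA path.
#' @param gff_path optional output GFF3 path for the feature table.
#' @return `path`, invisibly.
#' @export
write_plastome <- function(p, path, gff_path = NULL) {
  stopifnot(inherits(p, "plastome"))
  set <- Biostrings::DNAStringSet(p$sequence)
  names(set) <- p$id
  Biostrings::writeXStringSet(set, path, width = 60L)
  if (!is.null(gff_path)) write_gff3_features(p, gff_path)
  invisible(path)
}

GFF_KIND_MAP <- c(CDS = "CDS", tRNA = "tRNA", rRNA = "rRNA",
                  pseudogene = "pseudo_or_ORF", ORF = "pseudo_or_ORF",
                  pseudogenic_region = "pseudo_or_ORF")

read_gff3_features <- function(path, expected_seqid = NULL, genome_length = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) stop(sprintf("malformed GFF3 '%s': %s", path,
                                                  conditionMessage(e)), call. = FALSE))
  df <- as.data.frame(gr)
  keep <- df$type %in% names(GFF_KIND_MAP)
  df <- df[keep, , drop = FALSE]
  if (!is.null(expected_seqid) && nrow(df) > 0 &&
      !all(as.character(df$seqnames) == expected_seqid)) {
    stop(sprintf("GFF3 seqid(s) %s do not match record id '%s'",
                 paste(unique(setdiff(as.character(df$seqnames), expected_seqid)),
                       collapse = ","), expected_seqid), call. = FALSE)
  }
  if (nrow(df) == 0) return(empty_features())
  getcol <- function(nm, default) {
    if (nm %in% names(df)) {
      v <- as.character(df[[nm]])
      ifelse(is.na(v), default, v)
    } else rep(default, nrow(df))
  }
  id <- getcol("ID", NA_character_)
  parent <- if ("Parent" %in% names(df)) {
    vapply(df$Parent, function(x) if (length(x) > 0) as.character(x)[1] else NA_character_,
           character(1))
  } else rep(NA_character_, nrow(df))
  fid <- ifelse(!is.na(parent), parent, ifelse(!is.na(id), id, getcol("Name", "feat")))
  name <- getcol("Name", NA_character_)
  gene <- getcol("gene", NA_character_)
  name <- ifelse(!is.na(name), name, ifelse(!is.na(gene), gene, fid))
  phase <- if ("phase" %in% names(df)) suppressWarnings(as.integer(as.character(df$phase))) else rep(NA_integer_, nrow(df))
  feats <- data.frame(feature_id = fid, name = name,
                      kind = unname(GFF_KIND_MAP[as.character(df$type)]),
                      strand = ifelse(as.character(df$strand) == "-", "-", "+"),
                      start = df$start, end = df$end,
                      exon = 1L,
                      codon_start = ifelse(is.na(phase), 1L, phase + 1L),
                      partial = FALSE, stringsAsFactors = FALSE)
  # exon numbering within multi-interval features, in transcription order
  feats <- feats[order(feats$feature_id, feats$start), , drop = FALSE]
  sp <- split(seq_len(nrow(feats)), feats$feature_id)
  for (idx in sp) {
    if (length(idx) > 1L) {
      ord <- if (feats$strand[idx[1]] == "-") rev(seq_along(idx)) else seq_along(idx)
      feats$exon[idx] <- ord
      # only the first exon carries the reading-frame offset
      first <- idx[which(feats$exon[idx] == 1L)]
      feats$codon_start[idx] <- feats$codon_start[first]
    }
  }
  if (is.null(genome_length)) genome_length <- max(feats$end)
  as_gene_features(feats, genome_length)
}

write_gff3_features <- function(p, path) {
  feats <- p$features
  if (nrow(feats) == 0) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  if (any(feats$end < feats$start)) {
    stop("origin-wrapping features cannot be written to GFF3; split them first",
         call. = FALSE)
  }
  type <- vapply(feats$kind, function(k) {
    switch(k, CDS = "CDS", tRNA = "tRNA", rRNA = "rRNA", "pseudogene")
  }, character(1))
  gr <- GenomicRanges::GRanges(
    seqnames = p$id,
    ranges = IRanges::IRanges(feats$start, feats$end),
    strand = feats$strand)
  S4Vectors::mcols(gr)$source <- "plastmarker"
  S4Vectors::mcols(gr)$type <- type
  S4Vectors::mcols(gr)$ID <- feats$feature_id
  S4Vectors::mcols(gr)$Name <- feats$name
  S4Vectors::mcols(gr)$phase <- ifelse(feats$kind == "CDS" & feats$exon == 1L,
                                       feats$codon_start - 1L,
                                       ifelse(feats$kind == "CDS", 0L, NA_integer_))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

# --- minimal GenBank flat-file reader -------------------------------------

read_genbank_flat <- function(path) {
  lines <- readLines(path, warn = FALSE)
  loc <- grep("^LOCUS", lines)
  if (length(loc) == 0) stop("GenBank record lacks LOCUS line: ", path, call. = FALSE)
  id <- strsplit(sub("^LOCUS\\s+", "", lines[loc[1]]), "\\s+")[[1]][1]
  ostart <- grep("^ORIGIN", lines)
  if (length(ostart) == 0) stop("GenBank record lacks ORIGIN section: ", path, call. = FALSE)
  oend <- grep("^//", lines)
  oend <- if (length(oend) > 0) oend[oend > ostart[1]][1] else length(lines) + 1L
  seqlines <- lines[(ostart[1] + 1L):(oend - 1L)]
  sequence <- gsub("[ 0-9/]", "", paste(seqlines, collapse = ""))

  fstart <- grep("^FEATURES", lines)
  feats <- empty_features()
  if (length(fstart) > 0) {
    fl <- lines[(fstart[1] + 1L):(ostart[1] - 1L)]
    # a new feature starts at column 6 with a key; continuation lines start at 22
    is_key <- grepl("^ {5}\\S", fl)
    grp <- cumsum(is_key)
    recs <- split(fl, grp)
    rows <- list()
    for (rec in recs) {
      key <- sub("^ {5}(\\S+).*$", "\\1", rec[1])
      if (!key %in% c("CDS", "tRNA", "rRNA", "misc_feature", "gene")) next
      if (key == "gene") next
      body <- paste(sub("^ +", "", rec), collapse = " ")
      locstr <- sub(sprintf("^%s +", key), "", sub("^ +", "", rec[1]))
      # location may continue onto following lines until the first qualifier
      qual_at <- regexpr("/", body, fixed = TRUE)
      full <- if (qual_at > 0) substr(body, 1, qual_at - 1L) else body
      full <- sub(sprintf("^%s +", key), "", full)
      locstr <- gsub("[ \t]", "", full)
      pl <- parse_genbank_location(locstr)
      quals <- body
      gene <- genbank_qualifier(quals, "gene")
      if (is.na(gene)) gene <- genbank_qualifier(quals, "locus_tag")
      if (is.na(gene)) gene <- key
      cs <- suppressWarnings(as.integer(genbank_qualifier(quals, "codon_start")))
      pseudo <- grepl("/pseudo\\b", quals)
      kind <- if (pseudo) "pseudo_or_ORF" else switch(key, CDS = "CDS",
                                                      tRNA = "tRNA", rRNA = "rRNA",
                                                      "pseudo_or_ORF")
      n <- nrow(pl)
      rows[[length(rows) + 1L]] <- data.frame(
        feature_id = paste0(gene, "@", pl$start[1]),
        name = gene, kind = kind,
        strand = if (pl$complement[1]) "-" else "+",
        start = pl$start, end = pl$end,
        exon = if (pl$complement[1]) rev(seq_len(n)) else seq_len(n),
        codon_start = if (is.na(cs) || length(cs) == 0) 1L else cs,
        partial = pl$partial,
        stringsAsFactors = FALSE)
    }
    if (length(rows) > 0) {
      feats <- as_gene_features(do.call(rbind, rows), nchar(sequence))
    }
  }
  plastome(id, sequence, features = feats)
}

genbank_qualifier <- function(body, name) {
  m <- regmatches(body, regexpr(sprintf('/%s=("[^"]*"|[^ /]+)', name), body))
  if (length(m) == 0) return(NA_character_)
  gsub('"', "", sub(sprintf("/%s=", name), "", m))
}

parse_genbank_location <- function(loc) {
  complement <- grepl("^complement\\(", loc)
  inner <- gsub("^complement\\(|^join\\(|\\)$", "", gsub("complement\\(", "", loc))
  inner <- gsub("join\\(|\\)", "", inner)
  parts <- strsplit(inner, ",")[[1]]
  partial <- grepl("[<>]", parts)
  parts <- gsub("[<>]", "", parts)
  se <- do.call(rbind, lapply(strsplit(parts, "\\.\\."), function(x) {
    x <- as.integer(x)
    if (length(x) == 1L) c(x, x) else x
  }))
  data.frame(start = se[, 1], end = se[, 2], complement = complement,
             partial = partial)
}

# --- enzyme catalog -------------------------------------------------------

#' Read a restriction-enzyme catalog
#'
#' Tab-separated with columns `name`, `recognition` (IUPAC pattern) and
#' `cut_offset` (0-based top-strand cut position within the site; 0 cuts
#' before the first base, site-length cuts after the last). With no `path`
#' the catalog bundled with the package is returned; it covers the common
#' 4-6-cutters used for CAPS genotyping (TaqI, NcoI, KpnI, HinfI, MspI,
#' AluI, DpnII, RsaI, BanI, MluI, HaeIII, ScrFI, BstEII, XbaI and others).
#'
#' @param path optional catalog path; `NULL` loads the bundled default.
#' @return data frame of class `enzyme_catalog` with columns `name`,
#'   `recognition`, `cut_offset`, `palindromic`.
#' @export
read_enzyme_catalog <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "enzymes.tsv", package = "plastmarker",
                        mustWork = TRUE)
  }
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (file.size(path) == 0L) {
    warning("empty enzyme catalog: ", path)
    cat0 <- data.frame(name = character(), recognition = character(),
                       cut_offset = integer(), palindromic = logical())
    class(cat0) <- c("enzyme_catalog", "data.frame")
    return(cat0)
  }
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          comment.char = "#")
  if (ncol(df) < 3) stop("enzyme catalog needs >= 3 tab-separated columns", call. = FALSE)
  names(df)[1:3] <- c("name", "recognition", "cut_offset")
  df$recognition <- toupper(df$recognition)
  bad <- grepl(sprintf("[^%s]", paste(IUPAC_DNA, collapse = "")), df$recognition)
  if (any(bad)) {
    stop("non-IUPAC recognition pattern(s): ",
         paste(df$name[bad], collapse = ", "), call. = FALSE)
  }
  if (any(nchar(df$recognition) < 4)) {
    stop("recognition sites shorter than 4 bases are not supported", call. = FALSE)
  }
  df$cut_offset <- as.integer(df$cut_offset)
  if (any(df$cut_offset < 0L | df$cut_offset > nchar(df$recognition))) {
    stop("cut_offset outside the recognition site is not supported", call. = FALSE)
  }
  df$palindromic <- df$recognition == revcomp(df$recognition)
  df <- df[, c("name", "recognition", "cut_offset", "palindromic")]
  class(df) <- c("enzyme_catalog", "data.frame")
  df
}

# One catalog row as a plain list (EnzymeSpec).
enzyme_spec <- function(catalog, name) {
  i <- match(name, catalog$name)
  if (is.na(i)) stop("enzyme not in catalog: ", name, call. = FALSE)
  as.list(catalog[i, , drop = FALSE])
}

# --- VCF writer -----------------------------------------------------------

#' Write classified variant records as minimal VCF v4.2
#'
#' Emits the 8 fixed columns with INFO keys `CLASS` (site class), `POSB`
#' (position in the second species' own coordinates), `DPA`/`DPB` (pool
#' depths), `MIRROR` (mirrored IR coordinate) and, when present, `ANN`
#' (location annotation) and `EFF` (substitution/coding effect).
#'
#' @param records variant record data frame from [classify_sites()].
#' @param reference the reference [plastome()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_variants_vcf <- function(records, reference, path) {
  stopifnot(inherits(reference, "plastome"))
  rec <- as.data.frame(records)
  if (nrow(rec) > 0) {
    refbase <- substring(reference$sequence, rec$pos, rec$pos)
    bad <- rec$ref != refbase
    if (any(bad)) {
      stop(sprintf("REF allele disagrees with reference base at position(s) %s",
                   paste(utils::head(rec$pos[bad], 5), collapse = ",")),
           call. = FALSE)
    }
    rec <- rec[order(rec$pos), , drop = FALSE]
  }
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", reference$id, reference$length),
           "##INFO=<ID=CLASS,Number=1,Type=String,Description=\"Site class\">",
           "##INFO=<ID=POSB,Number=1,Type=Integer,Description=\"Position in pool-B genome coordinates\">",
           "##INFO=<ID=DPA,Number=1,Type=Integer,Description=\"Pool A depth\">",
           "##INFO=<ID=DPB,Number=1,Type=Integer,Description=\"Pool B depth\">",
           "##INFO=<ID=MIRROR,Number=1,Type=Integer,Description=\"Mirrored IR coordinate\">",
           "##INFO=<ID=ANN,Number=1,Type=String,Description=\"Location annotation\">",
           "##INFO=<ID=EFF,Number=1,Type=String,Description=\"Substitution class and coding effect\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
                 sep = "\t"))
  lines <- hdr
  if (nrow(rec) > 0) {
    alt <- ifelse(rec$allele_a == rec$ref, rec$allele_b, rec$allele_a)
    alt[alt == rec$ref | is.na(alt)] <- "."
    info <- sprintf("CLASS=%s;DPA=%d;DPB=%d", rec$class, rec$depth_a, rec$depth_b)
    if ("pos_b" %in% names(rec)) {
      info <- ifelse(is.na(rec$pos_b), info, sprintf("%s;POSB=%d", info, rec$pos_b))
    }
    if ("mirror_pos" %in% names(rec)) {
      info <- ifelse(is.na(rec$mirror_pos), info,
                     sprintf("%s;MIRROR=%d", info, rec$mirror_pos))
    }
    if ("annotation" %in% names(rec)) {
      ann <- gsub("[ ;=]", "_", rec$annotation)
      info <- ifelse(is.na(ann), info, sprintf("%s;ANN=%s", info, ann))
    }
    if ("substitution" %in% names(rec)) {
      eff <- ifelse(is.na(rec$coding_effect) | rec$coding_effect == "not_applicable",
                    rec$substitution,
                    paste0(rec$substitution, "_", rec$coding_effect))
      info <- ifelse(is.na(eff), info, sprintf("%s;EFF=%s", info, eff))
    }
    lines <- c(lines, paste(reference$id, rec$pos, ".", rec$ref, alt, ".", "PASS",
                            info, sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}
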