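#' Plastome: a circular annotated chloroplast genome
#'
#' The central data container of the package. A plastome couples a circular
#' DNA sequence with gene annotations and (optionally) the canonical
#' quadripartite partition into LSC, IRa, SSC and IRb. Coordinates are
#' 1-based inclusive; intervals that wrap the circular origin are written
#' with `end < start`.
#'
#' @param id record identifier (used as FASTA header / GFF3 seqid).
#' @param sequence DNA string; lowercase and RNA `U` are normalized, any
#'   IUPAC ambiguity code is accepted.
#' @param features `NULL` or a data frame of gene features, see
#'   [gene_features()].
#' @param partition `NULL` or a quadripartite partition, see
#'   [region_partition()].
#' @return an object of class `plastome` with elements `id`, `sequence`,
#'   `length`, `features`, `partition`.
#' @examples
#' p <- plastome("x", "acgt")
#' p$sequence  # "ACGT"
#' @export
plastome <- function(id, sequence, features = NULL, partition = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- normalize_dna(sequence, sprintf("sequence of '%s'", id))
  len <- nchar(sequence)
  if (len == 0L) stop("empty sequence", call. = FALSE)
  features <- if (is.null(features)) empty_features() else as_gene_features(features, len)
  p <- structure(list(id = id, sequence = sequence, length = len,
                      features = features, partition = NULL),
                 class = "plastome")
  if (!is.null(partition)) p$partition <- validate_partition(partition, p)
  p
}

#' @export
print.plastome <- function(x, ...) {
  cat(sprintf("<plastome> %s: %s bp, %d feature intervals%s\n", x$id,
              format(x$length, big.mark = ","), nrow(x$features),
              if (is.null(x$partition)) "" else ", quadripartite partition set"))
  invisible(x)
}

empty_features <- function() {
  data.frame(feature_id = character(), name = character(), kind = character(),
              strand = character(), start = integer(), end = integer(),
              exon = integer(), codon_start = integer(), partial = logical(),
              stringsAsFactors = FALSE)
}

FEATURE_KINDS <- c("CDS", "tRNA", "rRNA", "pseudo_or_ORF")

#' Build a gene-feature table
#'
#' Features are stored as a flat data frame with one row per interval;
#' multi-exon features share a `feature_id` and are ordered by `exon`.
#'
#' @param name gene name (e.g. `"accD"`, `"trnF-GAA"`).
#' @param kind one of `"CDS"`, `"tRNA"`, `"rRNA"`, `"pseudo_or_ORF"`.
#' @param strand `"+"` or `"-"`.
#' @param start,end 1-based inclusive interval bounds (`end < start` wraps
#'   the origin).
#' @param feature_id unique id per feature (default derived from name).
#' @param exon exon index within the feature (1 for single-interval).
#' @param codon_start 1, 2 or 3 (CDS reading-frame offset).
#' @param partial flag for features truncated e.g. at an IR boundary.
#' @return data frame of class `gene_features`.
#' @export
gene_features <- function(name, kind, strand, start, end,
                          feature_id = NULL, exon = 1L,
                          codon_start = 1L, partial = FALSE) {
  n <- length(name)
  if (is.null(feature_id)) feature_id <- make.unique(name, sep = "#")
  df <- data.frame(feature_id = as.character(feature_id),
                   name = as.character(name), kind = as.character(kind),
                   strand = as.character(strand),
                   start = as.integer(start), end = as.integer(end),
                   exon = rep_len(as.integer(exon), n),
                   codon_start = rep_len(as.integer(codon_start), n),
                   partial = rep_len(as.logical(partial), n),
                   stringsAsFactors = FALSE)
  class(df) <- c("gene_features", "data.frame")
  df
}

as_gene_features <- function(df, genome_length) {
  req <- c("name", "kind", "strand", "start", "end")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0) {
    stop("feature table lacks columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!"feature_id" %in% names(df)) df$feature_id <- make.unique(df$name, sep = "#")
  if (!"exon" %in% names(df)) df$exon <- 1L
  if (!"codon_start" %in% names(df)) df$codon_start <- 1L
  if (!"partial" %in% names(df)) df$partial <- FALSE
  df <- df[, c("feature_id", "name", "kind", "strand", "start", "end",
               "exon", "codon_start", "partial")]
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  bad <- !(df$kind %in% FEATURE_KINDS)
  if (any(bad)) {
    stop("unknown feature kind(s): ", paste(unique(df$kind[bad]), collapse = ", "),
         call. = FALSE)
  }
  if (any(df$start < 1L | df$start > genome_length |
          df$end < 1L | df$end > genome_length)) {
    stop("feature interval outside [1, genome length]", call. = FALSE)
  }
  if (!all(df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'", call. = FALSE)
  rownames(df) <- NULL
  class(df) <- c("gene_features", "data.frame")
  df
}

#' Quadripartite region partition (LSC / IRa / SSC / IRb)
#'
#' The four circular intervals must tile the circle with no overlap or gap,
#' the two inverted-repeat copies must have equal length, and
#' `LSC + SSC + 2*IR` must equal the genome length.
#'
#' @param lsc,ira,ssc,irb circular intervals `c(start, end)`.
#' @param genome_length circle size in bases.
#' @return object of class `region_partition` with the four intervals and
#'   their lengths.
#' @export
region_partition <- function(lsc, ira, ssc, irb, genome_length) {
  part <- structure(list(lsc = as.integer(lsc), ira = as.integer(ira),
                         ssc = as.integer(ssc), irb = as.integer(irb),
                         genome_length = as.integer(genome_length)),
                    class = "region_partition")
  lens <- vapply(part[c("lsc", "ira", "ssc", "irb")], circ_len,
                 integer(1), len = genome_length)
  names(lens) <- c("lsc", "ira", "ssc", "irb")
  if (lens[["ira"]] != lens[["irb"]]) {
    stop("IR copies have unequal lengths", call. = FALSE)
  }
  if (sum(lens) != genome_length) {
    stop(sprintf("partition lengths sum to %d, genome length is %d",
                 sum(lens), genome_length), call. = FALSE)
  }
  cov <- integer(genome_length)
  for (r in c("lsc", "ira", "ssc", "irb")) {
    idx <- circ_positions(part[[r]], genome_length)
    cov[idx] <- cov[idx] + 1L
  }
  if (any(cov != 1L)) stop("partition intervals overlap or leave gaps", call. = FALSE)
  part$lengths <- lens
  part
}

# Check partition against the sequence it claims to partition: IRb must be
# the exact reverse complement of IRa.
validate_partition <- function(part, p) {
  stopifnot(inherits(part, "region_partition"))
  if (part$genome_length != p$length) {
    stop("partition genome length disagrees with sequence length", call. = FALSE)
  }
  ira <- circ_extract(p$sequence, part$ira, p$length)
  irb <- circ_extract(p$sequence, part$irb, p$length)
  if (!identical(revcomp(ira), irb)) {
    stop("IRb is not the reverse complement of IRa", call. = FALSE)
  }
  part
}

#' @export
print.region_partition <- function(x, ...) {
  cat(sprintf("<region_partition> LSC %d bp [%d..%d], IRa %d bp [%d..%d], SSC %d bp [%d..%d], IRb %d bp [%d..%d]\n",
              x$lengths[["lsc"]], x$lsc[1], x$lsc[2],
              x$lengths[["ira"]], x$ira[1], x$ira[2],
              x$lengths[["ssc"]], x$ssc[1], x$ssc[2],
              x$lengths[["irb"]], x$irb[1], x$irb[2]))
  invisible(x)
}

# Which region does a position fall in? Returns "lsc"/"ira"/"ssc"/"irb".
partition_region_of <- function(part, pos) {
  out <- character(length(pos))
  for (r in c("lsc", "ira", "ssc", "irb")) {
    out[circ_contains(part[[r]], pos, part$genome_length)] <- r
  }
  out
}

# Mirror an IR position onto the opposite IR copy (reverse-complement
# coordinates): the i-th base of IRa pairs with the (len - i + 1)-th of IRb.
mirror_position <- function(part, pos) {
  L <- part$genome_length
  reg <- partition_region_of(part, pos)
  out <- rep(NA_integer_, length(pos))
  for (i in seq_along(pos)) {
    if (reg[i] == "ira") {
      off <- (pos[i] - part$ira[1]) %% L          # 0-based offset into IRa
      out[i] <- wrap_pos(part$irb[2] - off, L)
    } else if (reg[i] == "irb") {
      off <- (part$irb[2] - pos[i]) %% L
      out[i] <- wrap_pos(part$ira[1] + off, L)
    }
  }
  out
}
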