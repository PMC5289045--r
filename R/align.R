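# Pairwise divergence machinery: affine-gap global alignment (direct
# dynamic programming for short sequences, unique-anchor chaining with
# stitched sub-alignments for genome-scale inputs), percent identity,
# per-coding-region divergence ranking, sliding identity profiles, and the
# cross-genome position lift-over.

DEFAULT_SCORES <- c(match = 1, mismatch = -1, gap_open = -5, gap_ext = -1)

#' Affine-gap global alignment
#'
#' For inputs up to `direct_limit` bases the optimal alignment is computed
#' directly (Needleman-Wunsch with affine gaps, via
#' [Biostrings::pairwiseAlignment()]). Longer inputs are aligned by
#' chaining unique shared 31-mers (longest colinear chain) and aligning the
#' short inter-anchor segments, which is exact in practice for the highly
#' similar (>99%) sequences this package compares and scales linearly.
#'
#' @param a,b DNA strings (or [plastome()]s).
#' @param scores named vector `match`, `mismatch`, `gap_open`, `gap_ext`
#'   (gap of length k costs `gap_open + k*gap_ext`).
#' @param direct_limit maximum length for the direct DP (default 4000).
#' @return object of class `pairwise_alignment`: `a`, `b` (aligned strings
#'   with `-`), `score`.
#' @export
global_align <- function(a, b, scores = DEFAULT_SCORES, direct_limit = 4000L) {
  a <- if (inherits(a, "plastome")) a$sequence else normalize_dna(a)
  b <- if (inherits(b, "plastome")) b$sequence else normalize_dna(b)
  if (nchar(a) == 0 || nchar(b) == 0) stop("empty sequence", call. = FALSE)
  if (max(nchar(a), nchar(b)) <= direct_limit) {
    aln <- align_direct(a, b, scores)
  } else {
    aln <- align_anchored(a, b, scores, direct_limit)
  }
  aln$score <- score_alignment(aln, scores)
  class(aln) <- "pairwise_alignment"
  aln
}

align_direct <- function(a, b, scores) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = scores[["match"]],
                                                  mismatch = scores[["mismatch"]],
                                                  baseOnly = FALSE)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    type = "global", substitutionMatrix = mat,
    gapOpening = -scores[["gap_open"]], gapExtension = -scores[["gap_ext"]])
  list(a = as.character(Biostrings::alignedPattern(pa)),
       b = as.character(Biostrings::alignedSubject(pa)))
}

# unique k-mers of a string (those occurring exactly once)
unique_kmers <- function(x, k) {
  n <- nchar(x) - k + 1L
  if (n < 1L) return(data.table::data.table(kmer = character(), pos = integer()))
  dt <- data.table::data.table(kmer = substring(x, 1:n, 1:n + k - 1L), pos = 1:n)
  dt[, if (.N == 1L) .SD, by = kmer]
}

align_anchored <- function(a, b, scores, direct_limit, k = 31L) {
  ka <- unique_kmers(a, k); kb <- unique_kmers(b, k)
  anchors <- merge(ka, kb, by = "kmer", suffixes = c("_a", "_b"))
  data.table::setorder(anchors, pos_a)
  if (nrow(anchors) == 0) {
    if (max(nchar(a), nchar(b)) > 20000L) {
      stop("no shared unique anchors between sequences of this size; ",
           "cannot align", call. = FALSE)
    }
    return(align_direct(a, b, scores))
  }
  # longest chain increasing in both coordinates (patience-style O(n log n))
  pb <- anchors$pos_b
  n <- length(pb)
  tails <- integer(0); tails_idx <- integer(0); prev <- integer(n)
  for (i in seq_len(n)) {
    j <- findInterval(pb[i] - 1L, tails) + 1L
    tails[j] <- pb[i]; tails_idx[j] <- i
    prev[i] <- if (j > 1L) tails_idx[j - 1L] else 0L
  }
  chain <- integer(0); cur <- tails_idx[length(tails_idx)]
  while (cur != 0L) { chain <- c(cur, chain); cur <- prev[cur] }
  anc <- anchors[chain]
  # merge colinear overlapping/adjacent anchors into runs
  runs <- list()
  cur <- c(anc$pos_a[1], anc$pos_b[1], k)  # start_a, start_b, len
  if (nrow(anc) > 1) {
    for (i in 2:nrow(anc)) {
      da <- anc$pos_a[i] - cur[1]; db <- anc$pos_b[i] - cur[2]
      if (da == db && da <= cur[3]) {
        cur[3] <- da + k
      } else if (anc$pos_a[i] >= cur[1] + cur[3] && anc$pos_b[i] >= cur[2] + cur[3]) {
        runs[[length(runs) + 1L]] <- cur
        cur <- c(anc$pos_a[i], anc$pos_b[i], k)
      }
      # anchors violating both conditions (overlapping but off-diagonal) skipped
    }
  }
  runs[[length(runs) + 1L]] <- cur
  runs <- do.call(rbind, runs)

  seg_a <- character(0); seg_b <- character(0)
  pa_prev <- 1L; pb_prev <- 1L
  glue <- function(sa, sb) {
    if (nchar(sa) == 0 && nchar(sb) == 0) return(c("", ""))
    if (nchar(sa) == 0) return(c(strrep("-", nchar(sb)), sb))
    if (nchar(sb) == 0) return(c(sa, strrep("-", nchar(sa))))
    sub <- align_direct_safe(sa, sb, scores, direct_limit)
    c(sub$a, sub$b)
  }
  for (r in seq_len(nrow(runs))) {
    ga <- substr(a, pa_prev, runs[r, 1] - 1L)
    gb <- substr(b, pb_prev, runs[r, 2] - 1L)
    gl <- glue(ga, gb)
    seg_a <- c(seg_a, gl[1], substr(a, runs[r, 1], runs[r, 1] + runs[r, 3] - 1L))
    seg_b <- c(seg_b, gl[2], substr(b, runs[r, 2], runs[r, 2] + runs[r, 3] - 1L))
    pa_prev <- runs[r, 1] + runs[r, 3]
    pb_prev <- runs[r, 2] + runs[r, 3]
  }
  gl <- glue(substr(a, pa_prev, nchar(a)), substr(b, pb_prev, nchar(b)))
  seg_a <- c(seg_a, gl[1]); seg_b <- c(seg_b, gl[2])
  list(a = paste(seg_a, collapse = ""), b = paste(seg_b, collapse = ""))
}

align_direct_safe <- function(a, b, scores, direct_limit) {
  if (max(nchar(a), nchar(b)) <= max(direct_limit, 4000L)) {
    align_direct(a, b, scores)
  } else {
    # recurse with shorter anchors for large unanchored gaps
    align_anchored(a, b, scores, direct_limit, k = 15L)
  }
}

score_alignment <- function(aln, scores) {
  ca <- strsplit(aln$a, "")[[1]]; cb <- strsplit(aln$b, "")[[1]]
  gap_a <- ca == "-"; gap_b <- cb == "-"
  matches <- sum(!gap_a & !gap_b & ca == cb)
  mism <- sum(!gap_a & !gap_b & ca != cb)
  gaps <- gap_a | gap_b
  n_gap_bases <- sum(gaps)
  n_gap_opens <- sum(diff(c(FALSE, gap_a)) == 1L) + sum(diff(c(FALSE, gap_b)) == 1L)
  matches * scores[["match"]] + mism * scores[["mismatch"]] +
    n_gap_opens * scores[["gap_open"]] + n_gap_bases * scores[["gap_ext"]]
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("<pairwise_alignment> %d columns, score %.0f, identity %.2f%%\n",
              nchar(x$a), x$score, percent_identity(x)))
  invisible(x)
}

#' Percent identity of an alignment
#'
#' `100 * matched columns / total alignment columns`; gap columns count in
#' the denominator. Rounded half-up to `digits` decimals.
#'
#' @param aln a `pairwise_alignment`.
#' @param digits decimals (default 2).
#' @return percentage in `[0, 100]`; 100 iff the sequences are identical.
#' @export
percent_identity <- function(aln, digits = 2L) {
  ca <- strsplit(aln$a, "")[[1]]; cb <- strsplit(aln$b, "")[[1]]
  ncol <- length(ca)
  if (ncol == 0) stop("empty alignment", call. = FALSE)
  matches <- sum(ca == cb & ca != "-")
  floor(100 * matches / ncol * 10^digits + 0.5) / 10^digits
}

#' Rank shared coding regions by pairwise identity
#'
#' Extracts every shared coding feature (CDS, tRNA, rRNA), exon by exon
#' for multi-exon genes (named `gene exonN`), aligns the two species'
#' copies and ranks by ascending percent identity. IR-duplicated genes are
#' represented once (copies are identical within a genome). Genes present
#' in only one genome are skipped with a message.
#'
#' @param genome_a,genome_b annotated [plastome()]s.
#' @param k how many lowest-identity regions to return (default 15).
#' @param kinds feature kinds considered coding regions.
#' @return data frame of class `identity_records`: `region`, `length_a`,
#'   `length_b`, `identity`, ascending by identity (ties by region name).
#' @export
rank_coding_divergence <- function(genome_a, genome_b, k = 15L,
                                   kinds = c("CDS", "tRNA", "rRNA")) {
  fa <- genome_a$features; fb <- genome_b$features
  fa <- fa[fa$kind %in% kinds, , drop = FALSE]
  fb <- fb[fb$kind %in% kinds, , drop = FALSE]
  regions_of <- function(f, p) {
    # first feature instance per gene name; one row per exon
    first_ids <- f$feature_id[!duplicated(f$name)]
    f <- f[f$feature_id %in% first_ids, , drop = FALSE]
    multi_ids <- unique(f$feature_id[duplicated(f$feature_id)])
    f$region <- ifelse(f$feature_id %in% multi_ids,
                       sprintf("%s exon%d", f$name, f$exon), f$name)
    f$seq <- vapply(seq_len(nrow(f)), function(i) {
      s <- circ_extract(p$sequence, c(f$start[i], f$end[i]), p$length)
      if (f$strand[i] == "-") revcomp(s) else s
    }, character(1))
    f[, c("region", "seq")]
  }
  ra <- regions_of(fa, genome_a); rb <- regions_of(fb, genome_b)
  shared <- intersect(ra$region, rb$region)
  only <- c(setdiff(ra$region, rb$region), setdiff(rb$region, ra$region))
  if (length(only) > 0) {
    message("skipping regions present in one genome only: ",
            paste(utils::head(only, 5), collapse = ", "))
  }
  out <- lapply(shared, function(rg) {
    sa <- ra$seq[match(rg, ra$region)]
    sb <- rb$seq[match(rg, rb$region)]
    aln <- global_align(sa, sb)
    data.frame(region = rg, length_a = nchar(sa), length_b = nchar(sb),
               identity = percent_identity(aln), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(region = character(), length_a = integer(),
                      length_b = integer(), identity = numeric())
  }
  res <- res[order(res$identity, res$region), , drop = FALSE]
  res <- utils::head(res, k)
  rownames(res) <- NULL
  class(res) <- c("identity_records", "data.frame")
  res
}

#' Sliding-window identity profile
#'
#' Per-window percent identity over alignment columns (the windowed view
#' of a whole-genome comparison: conserved IRs plateau near 100, divergent
#' intergenic regions dip).
#'
#' @param aln a `pairwise_alignment`.
#' @param window window size in alignment columns (default 100).
#' @param step step in columns (default 25).
#' @return data frame: `start`, `end` (columns), `identity`.
#' @export
sliding_identity <- function(aln, window = 100L, step = 25L) {
  ca <- strsplit(aln$a, "")[[1]]; cb <- strsplit(aln$b, "")[[1]]
  ncol <- length(ca)
  if (window > ncol) stop("window exceeds alignment length", call. = FALSE)
  match_ind <- as.integer(ca == cb & ca != "-")
  cs <- c(0L, cumsum(match_ind))
  starts <- seq.int(1L, ncol - window + 1L, by = step)
  ident <- 100 * (cs[starts + window] - cs[starts]) / window
  data.frame(start = starts, end = starts + window - 1L,
             identity = floor(ident * 100 + 0.5) / 100)
}

#' Build a cross-genome position map from a global alignment
#'
#' Matched columns (both sequences have a base, matching or not) define a
#' strictly increasing, invertible coordinate mapping.
#'
#' @param aln a `pairwise_alignment`.
#' @return object of class `position_map` with matched-column coordinate
#'   vectors `a_pos`, `b_pos`.
#' @export
build_position_map <- function(aln) {
  ca <- strsplit(aln$a, "")[[1]]; cb <- strsplit(aln$b, "")[[1]]
  both <- ca != "-" & cb != "-"
  structure(list(a_pos = cumsum(ca != "-")[both],
                 b_pos = cumsum(cb != "-")[both]),
            class = "position_map")
}

#' Map a coordinate through a position map
#'
#' Positions inside a gap return the nearest left-anchored partner with
#' `exact = FALSE`.
#'
#' @param pm a `position_map`.
#' @param pos positions to map.
#' @param from `"a"` (default) or `"b"`: the coordinate system of `pos`.
#' @return data frame: `pos`, `mapped`, `exact`.
#' @export
map_position <- function(pm, pos, from = c("a", "b")) {
  from <- match.arg(from)
  src <- if (from == "a") pm$a_pos else pm$b_pos
  dst <- if (from == "a") pm$b_pos else pm$a_pos
  i <- match(pos, src)
  exact <- !is.na(i)
  mapped <- dst[i]
  if (any(!exact)) {
    j <- findInterval(pos[!exact], src)
    mapped[!exact] <- ifelse(j >= 1L, dst[pmax(j, 1L)], NA_integer_)
  }
  data.frame(pos = pos, mapped = mapped, exact = exact)
}
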