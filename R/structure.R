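# Structural characterization of circular plastomes: inverted-repeat
# detection, quadripartite LSC/IRa/SSC/IRb partition, GC content, gene copy
# counts, and gene-order inversion blocks.

#' Find the canonical inverted repeat of a circular genome
#'
#' Searches the circular sequence for the longest pair of disjoint intervals
#' whose sequences are exact reverse complements of each other. Detection is
#' seeded with 31-mers shared between the sequence and its reverse
#' complement and extended maximally; the two IR copies of a single plastid
#' molecule are identical, so exact matching is appropriate.
#'
#' @param p a [plastome()].
#' @param min_len minimum repeat length to report (default 10000, the scale
#'   of the canonical plastome IR).
#' @param k seed length (default 31).
#' @return `NULL` if no repeat of at least `min_len` is found, else a list
#'   with circular intervals `ira` and `irb` (`ira` is the copy with the
#'   smaller start coordinate) and `length` (bases, one copy).
#' @export
find_inverted_repeat <- function(p, min_len = 10000L, k = 31L) {
  stopifnot(inherits(p, "plastome"))
  n <- p$length
  if (n < 2L * k) return(NULL)
  S2 <- paste0(p$sequence, substr(p$sequence, 1L, k))
  km <- substring(S2, 1:n, 1:n + (k - 1L))
  rc <- revcomp(p$sequence)
  rc2 <- paste0(rc, substr(rc, 1L, k))
  krc <- substring(rc2, 1:n, 1:n + (k - 1L))
  # krc[q] is the reverse complement of the k-mer starting at j = n - q - k + 2
  dt1 <- data.table::data.table(kmer = km, i = 1:n)
  dt2 <- data.table::data.table(kmer = krc, q = 1:n)
  m <- merge(dt1, dt2, by = "kmer", allow.cartesian = TRUE)
  if (nrow(m) == 0L) return(NULL)
  m[, j := wrap_pos(n - q - k + 2L, n)]
  # self pair (a k-mer overlapping its own reverse complement) gives i approx j;
  # keep all, disjointness is checked on the final intervals.
  # Matches with constant (i + j) mod n form anti-diagonal runs.
  m[, d := (i + j) %% n]
  best <- NULL
  for (dd in unique(m$d)) {
    ii <- sort(m$i[m$d == dd])
    runs <- split(ii, cumsum(c(1L, diff(ii) != 1L)))
    # merge a run ending at n with a run starting at 1 (circular wrap)
    if (length(runs) > 1L) {
      first <- runs[[1]]; last <- runs[[length(runs)]]
      if (first[1] == 1L && last[length(last)] == n && length(runs) > 1L) {
        runs[[1]] <- c(last, first)
        runs[[length(runs)]] <- NULL
      }
    }
    for (r in runs) {
      a <- r[1]; b <- r[length(r)]
      len <- length(r) + k - 1L
      ivA <- c(a, wrap_pos(b + k - 1L, n))
      # partner segment of seed i sits at j = d - i; the run's partner
      # interval is [d - b, d - a + k - 1]
      ivB <- c(wrap_pos(dd - b, n), wrap_pos(dd - a + k - 1L, n))
      if (len > n %/% 2L) next                    # cannot be disjoint
      if (!intervals_disjoint(ivA, ivB, n)) next
      if (is.null(best) || len > best$length) {
        best <- list(ivA = ivA, ivB = ivB, length = len)
      }
    }
  }
  if (is.null(best) || best$length < min_len) return(NULL)
  # orient deterministically: ira is the copy with the smaller start
  if (best$ivA[1] <= best$ivB[1]) {
    out <- list(ira = best$ivA, irb = best$ivB, length = best$length)
  } else {
    out <- list(ira = best$ivB, irb = best$ivA, length = best$length)
  }
  sa <- circ_extract(p$sequence, out$ira, n)
  sb <- circ_extract(p$sequence, out$irb, n)
  if (!identical(revcomp(sa), sb)) {
    stop("internal error: detected IR pair fails reverse-complement check")
  }
  out
}

intervals_disjoint <- function(iv1, iv2, n) {
  p1 <- circ_positions(iv1, n)
  !any(circ_contains(iv2, p1, n))
}

#' Partition a plastome into LSC / IRa / SSC / IRb
#'
#' Given the inverted-repeat pair, the two single-copy gaps between the IR
#' copies are labelled LSC (the longer) and SSC (the shorter). When the two
#' gaps tie exactly, the gap following the IR copy with the smaller start
#' coordinate is declared the LSC (a documented, arbitrary convention).
#'
#' @param p a [plastome()].
#' @param ir result of [find_inverted_repeat()]; computed if `NULL`.
#' @param min_len passed to [find_inverted_repeat()] when `ir` is `NULL`;
#'   defaults to 5% of the genome (capped at the canonical 10 kb) so small
#'   test genomes partition too.
#' @return a [region_partition()] (also attached to `p` when assigned back).
#' @export
partition_quadripartite <- function(p, ir = NULL,
                                    min_len = min(10000L,
                                                  max(1000L, p$length %/% 20L))) {
  stopifnot(inherits(p, "plastome"))
  if (is.null(ir)) ir <- find_inverted_repeat(p, min_len = min_len)
  if (is.null(ir)) stop("no inverted repeat found; cannot partition", call. = FALSE)
  n <- p$length
  if (!intervals_disjoint(ir$ira, ir$irb, n)) {
    stop("IR copies overlap; malformed structure", call. = FALSE)
  }
  gap1 <- c(wrap_pos(ir$ira[2] + 1L, n), wrap_pos(ir$irb[1] - 1L, n))  # after ira
  gap2 <- c(wrap_pos(ir$irb[2] + 1L, n), wrap_pos(ir$ira[1] - 1L, n))  # after irb
  l1 <- circ_len(gap1, n); l2 <- circ_len(gap2, n)
  if (l1 + l2 + 2L * ir$length != n) {
    stop("IR pair does not leave two clean single-copy gaps", call. = FALSE)
  }
  if (l1 > l2 || (l1 == l2 && TRUE)) {
    # gap following ira (smaller start) is LSC on tie
    lsc <- gap1; ssc <- gap2; ira <- ir$irb; irb <- ir$ira
    # orientation convention LSC -> IRa -> SSC -> IRb: the IR after the LSC
    # is IRa. gap1 follows ir$ira, so the IR after gap1 is ir$irb.
  }
  if (l2 > l1) {
    lsc <- gap2; ssc <- gap1; ira <- ir$ira; irb <- ir$irb
  }
  part <- region_partition(lsc = lsc, ira = ira, ssc = ssc, irb = irb,
                           genome_length = n)
  validate_partition(part, p)
}

#' GC content of a plastome
#'
#' `100 * (G + C) / (A + C + G + T)`; IUPAC ambiguity codes are excluded
#' from numerator and denominator. Reported rounded half-up to one decimal.
#'
#' @param p a [plastome()] or a DNA string.
#' @param digits decimals to report (default 1).
#' @return percentage.
#' @export
gc_content <- function(p, digits = 1L) {
  seqs <- if (inherits(p, "plastome")) p$sequence else normalize_dna(p)
  fr <- Biostrings::letterFrequency(Biostrings::DNAString(seqs),
                                    letters = c("A", "C", "G", "T"))
  tot <- sum(fr)
  if (tot == 0L) stop("sequence has no unambiguous bases", call. = FALSE)
  pct <- 100 * (fr[["C"]] + fr[["G"]]) / tot
  floor(pct * 10^digits + 0.5) / 10^digits    # round half-up
}

#' Count annotated copies of a gene
#'
#' Counts features whose name matches exactly (case-sensitive) after
#' normalizing unicode hyphen variants to `-`. Multi-exon features count
#' once.
#'
#' @param p a [plastome()] with features loaded.
#' @param gene_name gene name, e.g. `"trnF-GAA"`.
#' @return integer copy count.
#' @export
count_gene_copies <- function(p, gene_name) {
  stopifnot(inherits(p, "plastome"))
  feats <- p$features
  if (nrow(feats) == 0) return(0L)
  norm <- function(x) gsub("[‐‑‒–—−]", "-", x)
  length(unique(feats$feature_id[norm(feats$name) == norm(gene_name)]))
}

# --- gene-order inversion detection ---------------------------------------

# Parse a signed gene list ("-psbA" marks reversed orientation).
signed_order <- function(x) {
  sign <- ifelse(startsWith(x, "-"), -1L, 1L)
  list(name = sub("^-", "", x), sign = sign)
}

n_breakpoints <- function(perm) {
  ext <- c(0L, perm, length(perm) + 1L)
  sum(diff(ext) != 1L)
}

#' Detect inversion blocks between two gene orders
#'
#' Operates on signed gene orders (orientation marked by a leading `-`),
#' as plastome inversions are conventionally described by their flanking
#' genes rather than by nucleotide coordinates. Finds a set of reversals
#' transforming the reference order into the query order, greedily choosing
#' at each step the reversal that removes the most signed-permutation
#' breakpoints (ties broken by block length, then leftmost). Nested blocks
#' (e.g. a short inversion sharing an endpoint with a long one) are
#' reported with their nesting depth.
#'
#' @param query_order,ref_order character vectors of signed gene names;
#'   must contain the same gene set (single-copy genes only).
#' @return data frame with columns `start`, `end` (query gene-order
#'   indices), `genes` (comma-joined reference gene names inside the
#'   block), `flank_left`, `flank_right` (query-order neighbours, `NA` at
#'   the ends), `depth` (nesting depth, 1 = outermost).
#' @export
detect_inversions <- function(query_order, ref_order) {
  q <- signed_order(query_order); r <- signed_order(ref_order)
  if (!setequal(q$name, r$name) || anyDuplicated(q$name) || anyDuplicated(r$name)) {
    stop("query and reference must contain the same single-copy gene set",
         call. = FALSE)
  }
  n <- length(q$name)
  idx <- match(q$name, r$name)
  perm <- idx * q$sign * r$sign[idx]
  blocks <- list()
  guard <- 0L
  while (n_breakpoints(perm) > 0L) {
    guard <- guard + 1L
    if (guard > n + 1L) stop("inversion search failed to converge", call. = FALSE)
    base_bp <- n_breakpoints(perm)
    best <- NULL
    for (i in seq_len(n)) {
      for (j in i:n) {
        cand <- perm
        cand[i:j] <- -rev(cand[i:j])
        red <- base_bp - n_breakpoints(cand)
        if (red <= 0L) next
        if (is.null(best) || red > best$red ||
            (red == best$red && (j - i) > (best$j - best$i))) {
          best <- list(i = i, j = j, red = red)
        }
      }
    }
    if (is.null(best)) stop("gene orders differ by more than reversals", call. = FALSE)
    blocks[[length(blocks) + 1L]] <- c(best$i, best$j)
    perm[best$i:best$j] <- -rev(perm[best$i:best$j])
  }
  if (length(blocks) == 0L) {
    return(data.frame(start = integer(), end = integer(), genes = character(),
                      flank_left = character(), flank_right = character(),
                      depth = integer(), stringsAsFactors = FALSE))
  }
  st <- vapply(blocks, `[`, integer(1), 1L)
  en <- vapply(blocks, `[`, integer(1), 2L)
  depth <- vapply(seq_along(blocks), function(b) {
    1L + sum(st <= st[b] & en >= en[b]) - 1L
  }, integer(1))
  data.frame(
    start = st, end = en,
    genes = vapply(seq_along(blocks), function(b)
      paste(q$name[st[b]:en[b]], collapse = ","), character(1)),
    flank_left = ifelse(st > 1L, q$name[pmax(st - 1L, 1L)], NA_character_),
    flank_right = ifelse(en < n, q$name[pmin(en + 1L, n)], NA_character_),
    depth = depth, stringsAsFactors = FALSE)
}
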