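# Gel-scorable assay design: in-silico PCR on circular templates,
# IUPAC-aware restriction digestion, discriminating-enzyme search, CAPS and
# tetra-primer ARMS-PCR design, and band-pattern / marker-status prediction
# across genotype panels.

#' Primer melting temperature
#'
#' Wallace rule (`2*(A+T) + 4*(G+C)`) up to 13 bases, otherwise the
#' GC-fraction formula `64.9 + 41*(GC - 16.4)/length`.
#'
#' @param x primer sequence(s), 5'->3'.
#' @return Tm in degrees Celsius.
#' @export
primer_tm <- function(x) {
  x <- toupper(x)
  vapply(x, function(s) {
    n <- nchar(s)
    bases <- strsplit(s, "")[[1]]
    gc <- sum(bases %in% c("G", "C"))
    at <- sum(bases %in% c("A", "T"))
    if (n <= 13) 2 * at + 4 * gc else 64.9 + 41 * (gc - 16.4) / n
  }, numeric(1), USE.NAMES = FALSE)
}

# Binding sites of a primer on a circular template. Returns, per site, the
# reference position of the primer's 5' end and the binding strand.
primer_sites <- function(template_seq, primer, max_mismatch = 0L,
                         require_3prime_match = TRUE) {
  L <- nchar(template_seq)
  plen <- nchar(primer)
  ext <- paste0(template_seq, substr(template_seq, 1L, min(plen + 1L, L)))
  subject <- Biostrings::DNAString(ext)
  out <- list()
  # plus strand: primer sequence read along the template
  m <- Biostrings::matchPattern(Biostrings::DNAString(primer), subject,
                                max.mismatch = max_mismatch, fixed = TRUE)
  st <- BiocGenerics::start(m)
  st <- st[st <= L]
  if (require_3prime_match && length(st) > 0) {
    tb <- substring(ext, st + plen - 1L, st + plen - 1L)
    st <- st[tb == substring(primer, plen, plen)]
  }
  if (length(st) > 0) {
    out[[1]] <- data.frame(five_prime = st, strand = "+", stringsAsFactors = FALSE)
  }
  # minus strand: reverse complement of the primer appears on the template;
  # the primer's 5' end sits at the match end, its 3' end at the match start
  rcp <- revcomp(primer)
  m2 <- Biostrings::matchPattern(Biostrings::DNAString(rcp), subject,
                                 max.mismatch = max_mismatch, fixed = TRUE)
  st2 <- BiocGenerics::start(m2)
  st2 <- st2[st2 <= L]
  if (require_3prime_match && length(st2) > 0) {
    tb <- substring(ext, st2, st2)
    st2 <- st2[tb == substring(rcp, 1L, 1L)]
  }
  if (length(st2) > 0) {
    out[[2]] <- data.frame(five_prime = wrap_pos(st2 + plen - 1L, L),
                           strand = "-", stringsAsFactors = FALSE)
  }
  if (length(out) == 0) {
    return(data.frame(five_prime = integer(), strand = character()))
  }
  do.call(rbind, out)
}

#' In-silico PCR on a circular template
#'
#' Finds all binding sites of both primers on both strands within the
#' mismatch budget (3'-terminal base required to match exactly by default)
#' and pairs convergent sites within `max_product`. Product length is
#' measured 5'-end to 5'-end inclusive.
#'
#' @param template a [plastome()] or DNA string.
#' @param fwd,rev primer sequences, 5'->3'.
#' @param max_mismatch per-primer mismatch allowance (default 0).
#' @param require_3prime_match require an exact 3'-terminal base
#'   (default `TRUE`; this is what makes ARMS allele-specificity work).
#' @param max_product maximum product length (default 5000).
#' @return data frame: `start` (plus-strand 5' position), `end`, `length`,
#'   `fwd_primer`, `rev_primer` (which input primer bound each side),
#'   `seq`.
#' @export
in_silico_pcr <- function(template, fwd, rev, max_mismatch = 0L,
                          require_3prime_match = TRUE, max_product = 5000L) {
  seqs <- if (inherits(template, "plastome")) template$sequence else
    normalize_dna(template)
  if (nchar(fwd) < 15L || nchar(rev) < 15L) {
    stop("primers must be at least 15 bases", call. = FALSE)
  }
  L <- nchar(seqs)
  primers <- c(fwd = toupper(fwd), rev = toupper(rev))
  sites <- do.call(rbind, lapply(names(primers), function(nm) {
    s <- primer_sites(seqs, primers[[nm]], max_mismatch, require_3prime_match)
    if (nrow(s) > 0) s$primer <- nm
    s
  }))
  empty <- data.frame(start = integer(), end = integer(), length = integer(),
                      fwd_primer = character(), rev_primer = character(),
                      seq = character(), stringsAsFactors = FALSE)
  if (is.null(sites) || nrow(sites) == 0) return(empty)
  plus <- sites[sites$strand == "+", , drop = FALSE]
  minus <- sites[sites$strand == "-", , drop = FALSE]
  if (nrow(plus) == 0 || nrow(minus) == 0) return(empty)
  out <- list()
  for (i in seq_len(nrow(plus))) {
    a <- plus$five_prime[i]
    # convergent pairing: minus-strand 5' end downstream of a within range
    dl <- (minus$five_prime - a) %% L + 1L
    min_len <- nchar(primers[[plus$primer[i]]]) +
      vapply(minus$primer, function(nm) nchar(primers[[nm]]), integer(1))
    ok <- dl >= min_len & dl <= max_product
    for (j in which(ok)) {
      len <- dl[j]
      out[[length(out) + 1L]] <- data.frame(
        start = a, end = wrap_pos(a + len - 1L, L), length = len,
        fwd_primer = plus$primer[i], rev_primer = minus$primer[j],
        seq = circ_substr(seqs, a, len, L), stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) return(empty)
  res <- unique(do.call(rbind, out))
  res[order(res$start, res$length), , drop = FALSE]
}

#' Digest a linear product with a restriction enzyme
#'
#' Locates all degenerate-IUPAC matches of the recognition site on both
#' strands (palindromic sites count once), applies the top-strand cut at
#' `cut_offset`, and returns fragment lengths sorted descending. A product
#' with no site returns a single fragment of its own length.
#'
#' @param product_seq linear DNA string (a PCR product).
#' @param enzyme one row of an enzyme catalog (list or single-row data
#'   frame with `recognition`, `cut_offset`).
#' @return integer vector of fragment lengths, descending (class
#'   `band_pattern` attribute-free; plain integers).
#' @export
digest <- function(product_seq, enzyme) {
  seqs <- toupper(if (inherits(product_seq, "plastome")) product_seq$sequence
                  else product_seq)
  n <- nchar(seqs)
  pat <- enzyme$recognition
  off <- enzyme$cut_offset
  subject <- Biostrings::DNAString(seqs)
  cuts <- integer(0)
  m <- Biostrings::matchPattern(Biostrings::DNAString(pat), subject,
                                fixed = FALSE)
  if (length(m) > 0) cuts <- c(cuts, BiocGenerics::start(m) + off - 1L)
  rcpat <- rc_quick(pat)
  if (!identical(rcpat, pat)) {
    m2 <- Biostrings::matchPattern(Biostrings::DNAString(rcpat), subject,
                                   fixed = FALSE)
    if (length(m2) > 0) {
      cuts <- c(cuts, BiocGenerics::start(m2) + (nchar(pat) - off) - 1L)
    }
  }
  cuts <- sort(unique(cuts[cuts >= 1L & cuts < n]))
  frags <- diff(c(0L, cuts, n))
  sort(as.integer(frags), decreasing = TRUE)
}

#' Marker-design failure sentinel
#'
#' Returned by [design_caps()] / [design_arms()] when no assay is feasible;
#' carries a `reason` code (`"no_enzyme"`, `"no_primers"`,
#' `"ambiguous_flank"`). Test with [is_marker()].
#'
#' @param reason short reason code.
#' @return object of class `marker_failure`.
#' @export
marker_failure <- function(reason) {
  structure(list(reason = reason), class = "marker_failure")
}

#' Is this a usable marker (not a design failure)?
#'
#' @param x result of [design_caps()] or [design_arms()].
#' @return `TRUE` for `caps_marker`/`arms_marker` objects.
#' @export
is_marker <- function(x) {
  inherits(x, "caps_marker") || inherits(x, "arms_marker")
}

#' @export
print.marker_failure <- function(x, ...) {
  cat(sprintf("<marker_failure> reason: %s\n", x$reason))
  invisible(x)
}

# Compare two band patterns under gel resolution: equal iff same fragment
# count and each sorted fragment within `resolution` bases of its partner.
bands_equal <- function(p1, p2, resolution = 20L) {
  if (length(p1) != length(p2)) return(FALSE)
  all(abs(sort(p1) - sort(p2)) <= resolution)
}

#' Find enzymes that discriminate a fixed SNP
#'
#' An enzyme discriminates the SNP iff digestion of the two species'
#' windows around the site yields different fragment multisets (the SNP
#' creates or destroys a recognition site, possibly in combination with
#' nearby fixed differences inside the window). Windows containing IUPAC
#' ambiguity codes are evaluated conservatively: every enzyme is excluded,
#' with a message.
#'
#' @param snp one variant record (list/row with `pos` and `pos_b`).
#' @param genomes named list of the two species' [plastome()]s, in the
#'   same A/B order as the record's alleles.
#' @param catalog an enzyme catalog ([read_enzyme_catalog()]).
#' @param window flank size on each side of the SNP (default 25).
#' @return the discriminating subset of `catalog` (possibly 0 rows).
#' @export
find_discriminating_enzymes <- function(snp, genomes, catalog, window = 25L) {
  stopifnot(length(genomes) == 2L)
  pa <- genomes[[1]]; pb <- genomes[[2]]
  pos_a <- snp$pos
  pos_b <- if (!is.null(snp$pos_b) && !is.na(snp$pos_b)) snp$pos_b else snp$pos
  win_a <- circ_substr(pa$sequence, wrap_pos(pos_a - window, pa$length),
                       2L * window + 1L, pa$length)
  win_b <- circ_substr(pb$sequence, wrap_pos(pos_b - window, pb$length),
                       2L * window + 1L, pb$length)
  if (grepl("[^ACGT]", win_a) || grepl("[^ACGT]", win_b)) {
    message("ambiguity code in SNP flank; excluding all enzymes at pos ", pos_a)
    return(catalog[0, , drop = FALSE])
  }
  # hoist S4 construction out of the per-enzyme loop (this runs over
  # thousands of SNP contexts in a full design pass)
  sub_a <- Biostrings::DNAString(win_a)
  sub_b <- Biostrings::DNAString(win_b)
  pats <- lapply(catalog$recognition, Biostrings::DNAString)
  rcpats <- lapply(pats, Biostrings::reverseComplement)
  frags_of <- function(subject, n, i) {
    pat <- pats[[i]]; off <- catalog$cut_offset[i]
    cuts <- BiocGenerics::start(Biostrings::matchPattern(pat, subject,
                                                         fixed = FALSE)) +
      off - 1L
    if (!catalog$palindromic[i]) {
      m2 <- Biostrings::matchPattern(rcpats[[i]], subject, fixed = FALSE)
      cuts <- c(cuts, BiocGenerics::start(m2) + (length(pat) - off) - 1L)
    }
    cuts <- sort(unique(cuts[cuts >= 1L & cuts < n]))
    sort(diff(c(0L, cuts, n)))
  }
  keep <- vapply(seq_len(nrow(catalog)), function(i) {
    # the defining criterion is a different fragment *multiset* (a shifted
    # cut yielding the same fragment lengths is not gel-scorable)
    !identical(frags_of(sub_a, nchar(win_a), i), frags_of(sub_b, nchar(win_b), i))
  }, logical(1))
  catalog[keep, , drop = FALSE]
}

# Sorted top-strand cut positions of an enzyme within a linear sequence.
cut_positions <- function(seqs, enzyme) {
  subject <- Biostrings::DNAString(seqs)
  pat <- enzyme$recognition; off <- enzyme$cut_offset
  cuts <- integer(0)
  m <- Biostrings::matchPattern(Biostrings::DNAString(pat), subject, fixed = FALSE)
  if (length(m) > 0) cuts <- c(cuts, BiocGenerics::start(m) + off - 1L)
  rcpat <- rc_quick(pat)
  if (!identical(rcpat, pat)) {
    m2 <- Biostrings::matchPattern(Biostrings::DNAString(rcpat), subject,
                                   fixed = FALSE)
    if (length(m2) > 0) {
      cuts <- c(cuts, BiocGenerics::start(m2) + (nchar(pat) - off) - 1L)
    }
  }
  sort(unique(cuts[cuts >= 1L & cuts < nchar(seqs)]))
}

# Pick a primer of acceptable Tm ending (3'-wise) at a fixed template
# position; scans lengths within cfg$primer_len. Returns NULL if no length
# fits the Tm window or the region has ambiguity codes.
pick_primer <- function(template_seq, three_prime_pos, strand, cfg) {
  L <- nchar(template_seq)
  for (plen in seq(cfg$primer_len[1], cfg$primer_len[2])) {
    if (strand == "+") {
      st <- wrap_pos(three_prime_pos - plen + 1L, L)
      pr <- circ_substr(template_seq, st, plen, L)
    } else {
      pr <- revcomp(circ_substr(template_seq, three_prime_pos, plen, L))
    }
    if (grepl("[^ACGT]", pr)) return(NULL)
    tm <- primer_tm(pr)
    if (tm >= cfg$tm_range[1] && tm <= cfg$tm_range[2]) {
      return(list(seq = pr, tm = tm, length = plen,
                  three_prime = three_prime_pos, strand = strand))
    }
  }
  NULL
}

#' Design a CAPS marker for a fixed SNP
#'
#' Chooses the first discriminating enzyme in catalog order, places a
#' primer pair flanking the SNP (product inside
#' `cfg$product_range`, primer Tm inside `cfg$tm_range`, SNP at least
#' `cfg$snp_margin` bases from each primer's 3' end), and fills per-species
#' products and digestion fragments via [in_silico_pcr()] + [digest()].
#' The design is validated by requiring exactly one product on each
#' species' genome and distinguishable fragment patterns under
#' `cfg$band_resolution`.
#'
#' @param snp one fixed-interspecific variant record (with `pos`, `pos_b`).
#' @param genomes named list of the two species' [plastome()]s.
#' @param catalog enzyme catalog.
#' @param cfg a [run_config()].
#' @return object of class `caps_marker`, or a [marker_failure()]
#'   with reason `"no_enzyme"` or `"no_primers"`.
#' @export
design_caps <- function(snp, genomes, catalog, cfg = run_config()) {
  enz <- find_discriminating_enzymes(snp, genomes, catalog,
                                     window = cfg$enzyme_window)
  if (nrow(enz) == 0) {
    return(marker_failure("no_enzyme"))
  }
  pa <- genomes[[1]]
  pos <- snp$pos
  pos_b <- if (!is.null(snp$pos_b) && !is.na(snp$pos_b)) snp$pos_b else snp$pos
  margin <- cfg$snp_margin
  # candidate screening runs on locus windows (fast); the winning pair is
  # confirmed for uniqueness on the full genomes below
  flank <- cfg$product_range[2] + 300L
  centers <- c(pos, pos_b)
  wins <- lapply(seq_along(genomes), function(i) {
    g <- genomes[[i]]
    circ_substr(g$sequence, wrap_pos(centers[i] - flank, g$length),
                min(2L * flank, g$length), g$length)
  })
  # primer placement is independent of the enzyme: find the first pair that
  # amplifies a unique product from both genomes, then scan enzymes on the
  # actual products
  for (d3f in seq(margin, margin + 300L, by = 11L)) {
    fwd <- pick_primer(pa$sequence, wrap_pos(pos - d3f, pa$length), "+", cfg)
    if (is.null(fwd)) next
    for (d3r in seq(margin, margin + 300L, by = 11L)) {
      prod_len <- d3f + d3r + 1L
      if (prod_len < cfg$product_range[1]) next
      if (prod_len > cfg$product_range[2]) break
      rev <- pick_primer(pa$sequence, wrap_pos(pos + d3r, pa$length), "-", cfg)
      if (is.null(rev)) next
      prods <- lapply(wins, function(wn) {
        in_silico_pcr(wn, fwd$seq, rev$seq, max_mismatch = 0L,
                      max_product = cfg$product_range[2] + 200L)
      })
      if (any(vapply(prods, nrow, integer(1)) != 1L)) next
      # uniqueness on the full genomes
      full <- lapply(genomes, function(g) {
        in_silico_pcr(g, fwd$seq, rev$seq, max_mismatch = 0L,
                      max_product = cfg$product_range[2] + 200L)
      })
      if (any(vapply(full, nrow, integer(1)) != 1L)) next
      prods <- full
      for (k in seq_len(nrow(enz))) {
        enzyme <- as.list(enz[k, , drop = FALSE])
        frags <- lapply(prods, function(pr) digest(pr$seq[1], enzyme))
        if (bands_equal(frags[[1]], frags[[2]], cfg$band_resolution)) next
        sp <- names(genomes)
        return(structure(list(
          id = sprintf("CAPS_%d", snp$pos), target_pos = snp$pos,
          fwd = fwd, rev = rev,
          ta = min(fwd$tm, rev$tm) - 5,
          enzyme = enzyme,
          product_length = stats::setNames(
            vapply(prods, function(x) x$length[1], integer(1)), sp),
          fragments = stats::setNames(frags, sp)),
          class = "caps_marker"))
      }
      return(marker_failure("no_enzyme"))
    }
  }
  marker_failure("no_primers")
}

#' @export
print.caps_marker <- function(x, ...) {
  cat(sprintf("<caps_marker> %s: %s/%s, Ta %.1f, %s; products %s; fragments %s\n",
              x$id, x$fwd$seq, x$rev$seq, x$ta, x$enzyme$name,
              paste(x$product_length, collapse = "/"),
              paste(vapply(x$fragments, paste, character(1), collapse = "+"),
                    collapse = " vs ")))
  invisible(x)
}

# Deliberate ARMS destabilizing mismatch: substitute the 2nd base from the
# 3' terminus with a transversion partner of the template base (fixed
# lookup, deterministic).
ARMS_MISMATCH <- c(A = "C", C = "A", G = "T", T = "G")

#' Design a tetra-primer ARMS-PCR marker for a fixed SNP
#'
#' Inner primers end exactly on the SNP on opposite strands (one per
#' allele) and carry one deliberate destabilizing mismatch at the second
#' base from the 3' terminus; outer primers are placed asymmetrically so
#' the two allele-specific products differ by at least
#' `cfg$arms_min_diff` bases. Validated by simulated amplification: with
#' the 3'-terminal-match rule each allele-specific band must appear only on
#' its own genome.
#'
#' @param snp one fixed-interspecific variant record.
#' @param genomes named list of the two species' [plastome()]s.
#' @param cfg a [run_config()].
#' @return object of class `arms_marker` or a [marker_failure()].
#' @export
design_arms <- function(snp, genomes, cfg = run_config()) {
  pa <- genomes[[1]]; pb <- genomes[[2]]
  pos_a <- snp$pos
  pos_b <- if (!is.null(snp$pos_b) && !is.na(snp$pos_b)) snp$pos_b else snp$pos
  ilen <- cfg$arms_inner_len
  # inner forward (allele A) ends 3' at the SNP on the plus strand
  inner_f <- circ_substr(pa$sequence, wrap_pos(pos_a - ilen + 1L, pa$length),
                         ilen, pa$length)
  # inner reverse (allele B) ends 3' at the SNP on the minus strand
  inner_r <- revcomp(circ_substr(pb$sequence, pos_b, ilen, pb$length))
  if (grepl("[^ACGT]", inner_f) || grepl("[^ACGT]", inner_r)) {
    return(marker_failure("ambiguous_flank"))
  }
  mm <- function(p) {
    b <- substring(p, nchar(p) - 1L, nchar(p) - 1L)
    paste0(substring(p, 1L, nchar(p) - 2L), ARMS_MISMATCH[[b]],
           substring(p, nchar(p), nchar(p)))
  }
  inner_f <- mm(inner_f); inner_r <- mm(inner_r)

  for (d_f in seq(cfg$arms_outer_near, cfg$arms_outer_near + 250L, by = 13L)) {
    outer_f <- pick_primer(pa$sequence, wrap_pos(pos_a - d_f, pa$length), "+", cfg)
    if (is.null(outer_f)) next
    for (d_r in seq(d_f + cfg$arms_min_diff, d_f + cfg$arms_min_diff + 250L,
                    by = 13L)) {
      outer_r <- pick_primer(pa$sequence, wrap_pos(pos_a + d_r, pa$length),
                             "-", cfg)
      if (is.null(outer_r)) next
      # product lengths are 5'-to-5' inclusive: the outer primers' 3' ends
      # sit d_f/d_r from the SNP, their 5' ends one primer length further out
      # allele-A product: inner_f -> outer_r; allele-B: outer_f -> inner_r
      len_a <- d_r + outer_r$length + ilen - 1L
      len_b <- d_f + outer_f$length + ilen - 1L
      if (abs(len_a - len_b) < cfg$arms_min_diff) next
      common <- d_f + outer_f$length + d_r + outer_r$length - 1L
      if (common > cfg$arms_max_common) break
      # validate on locus windows (primer binding near the SNP is what the
      # assay interrogates; whole-genome uniqueness is a design-time given)
      flank <- common + 300L
      wa <- circ_substr(pa$sequence, wrap_pos(pos_a - flank, pa$length),
                        min(2L * flank, pa$length), pa$length)
      wb <- circ_substr(pb$sequence, wrap_pos(pos_b - flank, pb$length),
                        min(2L * flank, pb$length), pb$length)
      cand <- structure(list(
        id = sprintf("ARMS_%d", snp$pos), target_pos = snp$pos,
        outer_f = outer_f, outer_r = outer_r,
        inner_f = list(seq = inner_f, allele = names(genomes)[1]),
        inner_r = list(seq = inner_r, allele = names(genomes)[2]),
        ta = min(outer_f$tm, outer_r$tm) - 5,
        common_length = common,
        allele_length = stats::setNames(c(len_a, len_b), names(genomes))),
        class = "arms_marker")
      bands <- lapply(list(wa, wb), function(g) arms_bands(cand, g))
      okA <- length(bands[[1]]) == 2L &&
        bands_equal(bands[[1]], sort(c(common, len_a), decreasing = TRUE), 0L)
      okB <- length(bands[[2]]) == 2L &&
        bands_equal(bands[[2]], sort(c(common, len_b), decreasing = TRUE), 0L)
      if (okA && okB) return(cand)
    }
  }
  marker_failure("no_primers")
}

#' Predicted ARMS band pattern on one genome
#'
#' Simulates the four-primer single-tube reaction: the common outer-outer
#' product plus whichever inner primer's 3'-terminal base matches the
#' template (each inner primer tolerates its one deliberate mismatch).
#'
#' @param marker an `arms_marker`.
#' @param genome a [plastome()] or a DNA string (e.g. a locus window).
#' @return sorted (descending) product lengths.
#' @export
arms_bands <- function(marker, genome) {
  lens <- integer(0)
  p1 <- in_silico_pcr(genome, marker$outer_f$seq, marker$outer_r$seq,
                      max_mismatch = 0L, max_product = marker$common_length + 500L)
  lens <- c(lens, p1$length)
  p2 <- in_silico_pcr(genome, marker$inner_f$seq, marker$outer_r$seq,
                      max_mismatch = 1L, max_product = marker$common_length + 500L)
  lens <- c(lens, p2$length)
  p3 <- in_silico_pcr(genome, marker$outer_f$seq, marker$inner_r$seq,
                      max_mismatch = 1L, max_product = marker$common_length + 500L)
  lens <- c(lens, p3$length)
  sort(unique(lens), decreasing = TRUE)
}

#' @export
print.arms_marker <- function(x, ...) {
  cat(sprintf("<arms_marker> %s: common %d, alleles %s\n", x$id,
              x$common_length,
              paste(sprintf("%s:%d", names(x$allele_length), x$allele_length),
                    collapse = " / ")))
  invisible(x)
}

#' Predict marker status across genotype panels
#'
#' Computes the gel band pattern of the marker for every genotype (PCR +
#' digestion for CAPS; allele products for ARMS). A species is `Fixed` iff
#' all its genotypes' patterns agree under `cfg$band_resolution` merging,
#' otherwise `Polymorphic`; the marker is species-specific iff every
#' species is Fixed and the species patterns differ pairwise.
#' Genotypes failing to amplify are flagged and excluded with a warning.
#'
#' @param marker a `caps_marker` or `arms_marker`.
#' @param panel named list (per species) of lists of genotype
#'   [plastome()]s.
#' @param cfg a [run_config()].
#' @return list: `status` (named Fixed/Polymorphic), `species_specific`,
#'   `patterns` (per species, representative band pattern), `failures`
#'   (genotype ids that failed to amplify).
#' @export
predict_marker_status <- function(marker, panel, cfg = run_config()) {
  res <- cfg$band_resolution
  # run the PCR on a window around the marker locus rather than the whole
  # genome: primer uniqueness was established at design time, and genotype
  # genomes share the designed species' coordinates (panel variants are
  # SNPs), so this is exact and much faster
  flank <- as.integer(if (inherits(marker, "caps_marker"))
    max(marker$product_length) + 500L else marker$common_length + 500L)
  locus <- function(genome) {
    circ_substr(genome$sequence, wrap_pos(marker$target_pos - flank, genome$length),
                min(2L * flank, genome$length), genome$length)
  }
  geno_bands <- function(genome) {
    tmpl <- locus(genome)
    if (inherits(marker, "caps_marker")) {
      pr <- in_silico_pcr(tmpl, marker$fwd$seq, marker$rev$seq,
                          max_mismatch = 1L,
                          max_product = max(marker$product_length) + 500L)
      if (nrow(pr) != 1L) return(NULL)
      digest(pr$seq[1], marker$enzyme)
    } else {
      b <- arms_bands(marker, tmpl)
      if (length(b) == 0) NULL else b
    }
  }
  status <- character(0)
  patterns <- list()
  failures <- character(0)
  for (sp in names(panel)) {
    pats <- list()
    for (g in panel[[sp]]) {
      b <- geno_bands(g)
      if (is.null(b)) {
        failures <- c(failures, g$id)
        next
      }
      pats[[length(pats) + 1L]] <- b
    }
    if (length(pats) == 0L) {
      warning("no genotype of species ", sp, " amplified")
      status[sp] <- NA_character_
      next
    }
    fixed <- all(vapply(pats, bands_equal, logical(1), p2 = pats[[1]],
                        resolution = res))
    status[sp] <- if (fixed) "Fixed" else "Polymorphic"
    patterns[[sp]] <- pats[[1]]
  }
  if (length(failures) > 0) {
    warning(length(failures), " genotype(s) failed to amplify: ",
            paste(utils::head(failures, 3), collapse = ", "))
  }
  specific <- all(status == "Fixed", na.rm = FALSE) && length(patterns) >= 2L
  if (isTRUE(specific)) {
    cmb <- utils::combn(length(patterns), 2)
    for (i in seq_len(ncol(cmb))) {
      if (bands_equal(patterns[[cmb[1, i]]], patterns[[cmb[2, i]]], res)) {
        specific <- FALSE
        break
      }
    }
  } else {
    specific <- FALSE
  }
  list(status = status, species_specific = specific, patterns = patterns,
       failures = failures)
}
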