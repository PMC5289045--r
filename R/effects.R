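# Functional labelling of SNPs: transition/transversion class, genomic
# location (coding / intron / intergenic with flanking genes), and
# synonymous vs non-synonymous calls under the bacterial/plastid genetic
# code (translation table 11).

PURINES <- c("A", "G")

#' Transition or transversion?
#'
#' @param a,b two different bases in `A`, `C`, `G`, `T` (vectorized).
#' @return `"transition"` (both purines or both pyrimidines) or
#'   `"transversion"`.
#' @export
classify_substitution <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  if (any(!(a %in% BASES) | !(b %in% BASES))) {
    stop("alleles must be unambiguous bases", call. = FALSE)
  }
  if (any(a == b)) stop("alleles must differ", call. = FALSE)
  ifelse((a %in% PURINES) == (b %in% PURINES), "transition", "transversion")
}

#' Locate a position relative to the annotation
#'
#' Returns the functional context of a genome position: inside a
#' CDS/tRNA/rRNA/pseudogene interval (`coding`, with the gene name and a
#' pseudo flag), between two exons of one feature (`intron`), or
#' `intergenic` with the nearest flanking gene on either side in circular
#' genome order (regardless of strand). Overlap ties prefer
#' CDS > tRNA/rRNA > pseudo.
#'
#' @param pos 1-based position.
#' @param p a [plastome()] with features.
#' @return list with `kind` (`"coding"`, `"intron"`, `"intergenic"`),
#'   `gene` (coding/intron) or `left`/`right` (intergenic), `feature_kind`
#'   and `pseudo` flag for coding hits, and `label` (human-readable,
#'   e.g. `"Inter space between trnH-GUG and psbA"`).
#' @export
locate_position <- function(pos, p) {
  stopifnot(inherits(p, "plastome"))
  if (pos < 1L || pos > p$length) stop("position out of range", call. = FALSE)
  feats <- p$features
  if (nrow(feats) == 0) {
    return(list(kind = "intergenic", left = NA_character_,
                right = NA_character_, label = "unannotated"))
  }
  L <- p$length
  inside <- vapply(seq_len(nrow(feats)), function(i) {
    circ_contains(c(feats$start[i], feats$end[i]), pos, L)
  }, logical(1))
  if (any(inside)) {
    hit <- feats[inside, , drop = FALSE]
    pri <- match(hit$kind, c("CDS", "tRNA", "rRNA", "pseudo_or_ORF"))
    hit <- hit[order(pri), , drop = FALSE][1L, ]
    return(list(kind = "coding", gene = hit$name, feature_id = hit$feature_id,
                feature_kind = hit$kind, pseudo = hit$kind == "pseudo_or_ORF",
                label = hit$name))
  }
  # intron: between two intervals of the same multi-exon feature, with no
  # other feature interval in between (checked via the gap bounds)
  multi <- feats$feature_id[duplicated(feats$feature_id)]
  for (fid in unique(multi)) {
    iv <- feats[feats$feature_id == fid, , drop = FALSE]
    iv <- iv[order(iv$start), , drop = FALSE]
    for (j in seq_len(nrow(iv) - 1L)) {
      if (pos > iv$end[j] && pos < iv$start[j + 1L]) {
        return(list(kind = "intron", gene = iv$name[1L],
                    feature_id = fid,
                    label = sprintf("intron of %s", iv$name[1L])))
      }
    }
  }
  # intergenic: nearest feature end upstream / feature start downstream on
  # the circle
  dist_up <- (pos - feats$end) %% L
  dist_dn <- (feats$start - pos) %% L
  left <- feats$name[which.min(dist_up)]
  right <- feats$name[which.min(dist_dn)]
  list(kind = "intergenic", left = left, right = right,
       label = sprintf("Inter space between %s and %s", left, right))
}

#' Synonymous or non-synonymous?
#'
#' Translates the codon affected by a SNP with each allele under NCBI
#' translation table 11 (bacterial/plastid), honoring strand, reading-frame
#' offset (`codon_start`) and multi-exon (including origin-wrapping)
#' features.
#'
#' @param pos reference position of the SNP.
#' @param ref_allele,alt_allele plus-strand alleles; `ref_allele` must
#'   match the genome base at `pos`.
#' @param feature_id the CDS feature to evaluate.
#' @param p the [plastome()].
#' @return `"synonymous"` or `"non-synonymous"`.
#' @export
coding_effect <- function(pos, ref_allele, alt_allele, feature_id, p) {
  stopifnot(inherits(p, "plastome"))
  feats <- p$features[p$features$feature_id == feature_id, , drop = FALSE]
  if (nrow(feats) == 0) stop("unknown feature: ", feature_id, call. = FALSE)
  if (substring(p$sequence, pos, pos) != toupper(ref_allele)) {
    stop(sprintf("ref allele %s disagrees with genome base %s at %d",
                 ref_allele, substring(p$sequence, pos, pos), pos),
         call. = FALSE)
  }
  strand <- feats$strand[1L]
  feats <- feats[order(feats$exon), , drop = FALSE]
  # genomic positions in transcription order
  gpos <- unlist(lapply(seq_len(nrow(feats)), function(i) {
    ps <- circ_positions(c(feats$start[i], feats$end[i]), p$length)
    if (strand == "-") rev(ps) else ps
  }))
  idx <- match(pos, gpos)
  if (is.na(idx)) stop("position not inside feature ", feature_id, call. = FALSE)
  cs <- feats$codon_start[1L]
  idx0 <- idx - cs                       # 0-based within reading frame
  if (idx0 < 0L) return("synonymous")    # upstream of the declared frame
  codon_i <- idx0 %/% 3L
  cpos <- gpos[(codon_i * 3L + cs):(codon_i * 3L + cs + 2L)]
  if (anyNA(cpos)) return("synonymous")  # incomplete terminal codon
  getb <- function(allele) {
    bs <- substring(p$sequence, cpos, cpos)
    bs[cpos == pos] <- toupper(allele)
    if (strand == "-") bs <- chartr("ACGT", "TGCA", bs)
    paste(bs, collapse = "")
  }
  code <- Biostrings::getGeneticCode("11")
  aa_ref <- code[[getb(ref_allele)]]
  aa_alt <- code[[getb(alt_allele)]]
  if (identical(aa_ref, aa_alt)) "synonymous" else "non-synonymous"
}

#' Annotate variant records with location and effect labels
#'
#' Adds `annotation` (location label), `substitution`
#' (transition/transversion), `coding_effect` (synonymous /
#' non-synonymous / not_applicable) and `pseudo` columns. Pseudogene and
#' RNA-gene hits are coding-context but carry `not_applicable` effects.
#'
#' @param records `variant_records`.
#' @param p the reference [plastome()] with features.
#' @return augmented `variant_records`.
#' @export
annotate_effects <- function(records, p) {
  rec <- as.data.frame(records)
  n <- nrow(rec)
  rec$annotation <- NA_character_
  rec$substitution <- NA_character_
  rec$coding_effect <- NA_character_
  rec$pseudo <- FALSE
  for (i in seq_len(n)) {
    loc <- locate_position(rec$pos[i], p)
    rec$annotation[i] <- loc$label
    aa <- rec$allele_a[i]; ab <- rec$allele_b[i]
    if (aa %in% BASES && ab %in% BASES && aa != ab) {
      rec$substitution[i] <- classify_substitution(aa, ab)
    }
    rec$coding_effect[i] <- "not_applicable"
    if (loc$kind == "coding" && identical(loc$feature_kind, "CDS")) {
      ref <- rec$ref[i]
      alt <- if (aa == ref) ab else aa
      if (ref %in% BASES && alt %in% BASES && alt != ref) {
        rec$coding_effect[i] <- coding_effect(rec$pos[i], ref, alt,
                                              loc$feature_id, p)
      }
    }
    if (loc$kind == "coding") rec$pseudo[i] <- isTRUE(loc$pseudo)
  }
  for (a in c("n_monomorphic", "n_low_coverage", "species")) {
    attr(rec, a) <- attr(records, a)
  }
  class(rec) <- c("variant_records", "data.frame")
  rec
}
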