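# Pooled-variant discovery: a built-in exact-ish short-read mapper (31-mer
# seeding + Hamming extension on the circular reference), per-site allele
# tallies, and the fixed-interspecific / intraspecific-polymorphic site
# classifier. External single-end SAM is accepted as an alternative to the
# built-in mapper; the classification contract is identical.

#' Map short reads to a circular reference
#'
#' Seeds each read (both orientations) with 31-mers at three offsets,
#' extends by Hamming comparison on the circular reference, and keeps the
#' unique best placement. Ties (e.g. reads wholly inside an inverted-repeat
#' copy) are assigned to the lexicographically smallest position and
#' flagged `tie`. Reads exceeding the mismatch budget are dropped; the
#' count is recorded in attribute `n_unmapped`.
#'
#' @param reads a character vector of read sequences, a data frame with a
#'   `seq` column (ids taken from an `id` column when present), or a path
#'   to a FASTQ file.
#' @param reference a [plastome()].
#' @param max_mismatches mismatch budget per read (default 5, scaled
#'   nothing — a flat cap, appropriate for 150 b reads).
#' @param k seed length (default 31; reference must be longer).
#' @return data frame of class `read_alignments`: `qname`, `pos` (1-based
#'   leftmost reference position; reads may wrap the origin), `strand`,
#'   `seq` (reference-oriented), `nm`, `tie`, `cigar`.
#' @export
map_reads_exactish <- function(reads, reference, max_mismatches = 5L, k = 31L) {
  stopifnot(inherits(reference, "plastome"))
  L <- reference$length
  if (L < k) stop("reference shorter than seed length", call. = FALSE)
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    set <- Biostrings::readDNAStringSet(reads, format = "fastq")
    reads <- data.frame(id = names(set), seq = as.character(set),
                        stringsAsFactors = FALSE)
  }
  if (is.character(reads)) {
    reads <- data.frame(id = sprintf("read_%07d", seq_along(reads)), seq = reads,
                        stringsAsFactors = FALSE)
  }
  if (!"id" %in% names(reads)) reads$id <- sprintf("read_%07d", seq_len(nrow(reads)))

  ref2 <- paste0(reference$sequence, substr(reference$sequence, 1L, 200L + k))
  refint <- as.integer(charToRaw(ref2))
  idx <- data.table::data.table(kmer = substring(ref2, 1:L, 1:L + (k - 1L)),
                                rpos = 1:L)
  data.table::setkey(idx, kmer)

  widths <- nchar(reads$seq)
  out <- vector("list", 0L)
  n_unmapped <- 0L
  for (w in sort(unique(widths))) {
    rows <- which(widths == w)
    if (w < k) { n_unmapped <- n_unmapped + length(rows); next }
    fwd <- reads$seq[rows]
    readint_f <- matrix(as.integer(charToRaw(paste(fwd, collapse = ""))),
                        ncol = w, byrow = TRUE)
    # complement lookup over ASCII codes; reverse columns for the rc matrix
    comp_lut <- integer(128)
    comp_lut[as.integer(charToRaw("ACGTNRYSWKMBDHV")) + 1L] <-
      as.integer(charToRaw(chartr("ACGTNRYSWKMBDHV", "TGCANYRSWMKVHDB",
                                  "ACGTNRYSWKMBDHV")))
    readint_r <- matrix(comp_lut[readint_f[, w:1, drop = FALSE] + 1L], ncol = w)

    candidates <- function(active, offsets) {
      cand <- list()
      for (ori in c("+", "-")) {
        for (o in offsets) {
          seed <- if (ori == "+") substring(fwd[active], o + 1L, o + k) else
            revcomp(substring(fwd[active], w - o - k + 1L, w - o))
          dt <- data.table::data.table(read = active, kmer = seed)
          hit <- idx[dt, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
          if (nrow(hit) > 0) {
            hit[, pos := wrap_pos(rpos - o, L)]
            cand[[length(cand) + 1L]] <- hit[, list(read, pos, ori = ori)]
          }
        }
      }
      if (length(cand) == 0L) return(NULL)
      cand <- unique(data.table::rbindlist(cand))
      # Hamming distance at every candidate placement, as integer matrices
      posm <- outer(cand$pos - 1L, 0:(w - 1L), `+`) %% L + 1L
      refm <- matrix(refint[posm], nrow = nrow(cand))
      readm <- matrix(0L, nrow = nrow(cand), ncol = w)
      fsel <- cand$ori == "+"
      readm[fsel, ] <- readint_f[cand$read[fsel], , drop = FALSE]
      readm[!fsel, ] <- readint_r[cand$read[!fsel], , drop = FALSE]
      cand[, nm := rowSums(readm != refm)]
      cand[nm <= max_mismatches]
    }
    # stage 1: leading seed only (finds both IR copies of a tied read, as
    # their sequences are identical); stage 2 rescues reads whose leading
    # seed carries an error, with seeds at three offsets
    cand1 <- candidates(seq_along(rows), 0L)
    resolved <- if (is.null(cand1)) integer(0) else unique(cand1$read)
    rest <- setdiff(seq_along(rows), resolved)
    cand2 <- if (length(rest) > 0) {
      candidates(rest, unique(c(0L, (w - k) %/% 2L, w - k)))
    } else NULL
    cand <- data.table::rbindlist(list(cand1, cand2))
    if (nrow(cand) == 0L) { n_unmapped <- n_unmapped + length(rows); next }
    data.table::setorder(cand, read, nm, pos, ori)
    best <- cand[, list(pos = pos[1], strand = ori[1], nm = nm[1],
                        tie = .N > 1L && nm[2] == nm[1]), by = read]
    n_unmapped <- n_unmapped + (length(rows) - nrow(best))
    oseq <- fwd[best$read]
    neg <- best$strand == "-"
    if (any(neg)) oseq[neg] <- revcomp(oseq[neg])
    out[[length(out) + 1L]] <- data.frame(
      qname = reads$id[rows][best$read],
      pos = best$pos, strand = best$strand, seq = oseq,
      nm = best$nm, tie = best$tie, cigar = paste0(w, "M"),
      stringsAsFactors = FALSE)
  }
  aln <- if (length(out) > 0) do.call(rbind, out) else
    data.frame(qname = character(), pos = integer(), strand = character(),
               seq = character(), nm = integer(), tie = logical(),
               cigar = character(), stringsAsFactors = FALSE)
  aln <- aln[order(aln$pos), , drop = FALSE]
  rownames(aln) <- NULL
  attr(aln, "n_unmapped") <- n_unmapped
  attr(aln, "reference_id") <- reference$id
  class(aln) <- c("read_alignments", "data.frame")
  aln
}

#' Write alignments as minimal single-end SAM
#'
#' @param aln a `read_alignments` data frame.
#' @param reference the [plastome()] they were mapped to.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(aln, reference, path) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", reference$id, reference$length))
  flag <- ifelse(aln$strand == "-", 16L, 0L)
  lines <- c(hdr,
             paste(aln$qname, flag, reference$id, aln$pos, 60L, aln$cigar,
                   "*", 0L, 0L, aln$seq, "*", paste0("NM:i:", aln$nm),
                   sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a minimal single-end SAM file
#'
#' Accepts the dialect this package writes plus externally produced
#' single-end alignments with `M`, `S` (honored), `I`, `D` CIGAR
#' operations. Spliced (`N`), hard-clipped, paired or secondary records
#' are rejected loudly.
#'
#' @param path SAM path.
#' @return `read_alignments` data frame (`seq` has soft clips removed).
#' @export
read_sam <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0L) {
    return(structure(data.frame(qname = character(), pos = integer(),
                                strand = character(), seq = character(),
                                nm = integer(), tie = logical(),
                                cigar = character()),
                     class = c("read_alignments", "data.frame")))
  }
  f <- data.table::tstrsplit(lines, "\t", fixed = TRUE, keep = 1:10)
  qname <- f[[1]]; flag <- as.integer(f[[2]]); pos <- as.integer(f[[4]])
  cigar <- f[[6]]; seqs <- f[[10]]
  if (any(bitwAnd(flag, 1L) != 0L)) stop("paired-end SAM rejected", call. = FALSE)
  if (any(bitwAnd(flag, 256L) != 0L | bitwAnd(flag, 2048L) != 0L)) {
    stop("secondary/supplementary SAM records rejected", call. = FALSE)
  }
  if (any(grepl("[NHP=X]", cigar))) {
    stop("unsupported CIGAR operations (only M, S, I, D accepted)", call. = FALSE)
  }
  keep <- !bitwAnd(flag, 4L)
  # strip soft clips from seq (pos already points at the first aligned base)
  lead <- rep(0L, length(cigar))
  has_lead <- grepl("^[0-9]+S", cigar)
  lead[has_lead] <- as.integer(sub("^([0-9]+)S.*$", "\\1", cigar[has_lead]))
  tail_ <- rep(0L, length(cigar))
  has_tail <- grepl("[0-9]+S$", cigar)
  tail_[has_tail] <- as.integer(sub("^.*?([0-9]+)S$", "\\1", cigar[has_tail]))
  seqs <- substr(seqs, lead + 1L, nchar(seqs) - tail_)
  cigar2 <- gsub("^[0-9]+S|[0-9]+S$", "", cigar)
  out <- data.frame(qname = qname[keep], pos = pos[keep],
                    strand = ifelse(bitwAnd(flag[keep], 16L) != 0L, "-", "+"),
                    seq = toupper(seqs[keep]), nm = NA_integer_, tie = FALSE,
                    cigar = cigar2[keep], stringsAsFactors = FALSE)
  class(out) <- c("read_alignments", "data.frame")
  out
}

#' Per-position allele tallies for one pooled library
#'
#' @param aln `read_alignments` (from [map_reads_exactish()] or
#'   [read_sam()]).
#' @param reference the [plastome()] mapped against.
#' @param species label carried into downstream records.
#' @return object of class `pool_counts`: `species`, `counts` (length x 6
#'   matrix, columns A/C/G/T/del/ins), `depth`, `gap_positions` (reference
#'   positions adjacent to alignment I/D gaps), `summary` (mean/min/max
#'   depth over covered positions).
#' @export
pileup <- function(aln, reference, species = "pool") {
  stopifnot(inherits(reference, "plastome"))
  L <- reference$length
  counts <- matrix(0L, nrow = L, ncol = 6L,
                   dimnames = list(NULL, c("A", "C", "G", "T", "del", "ins")))
  gap_pos <- integer(0)
  if (nrow(aln) > 0 && any(aln$pos > L)) {
    stop("alignment position beyond reference bounds", call. = FALSE)
  }
  simple <- grepl("^[0-9]+M$", aln$cigar)
  # fast path: ungapped constant-width alignments
  if (any(simple)) {
    sa <- aln[simple, , drop = FALSE]
    for (w in unique(nchar(sa$seq))) {
      rows <- which(nchar(sa$seq) == w)
      readm <- matrix(as.integer(charToRaw(paste(sa$seq[rows], collapse = ""))),
                      ncol = w, byrow = TRUE)
      posm <- outer(sa$pos[rows] - 1L, 0:(w - 1L), `+`) %% L + 1L
      for (b in c("A", "C", "G", "T")) {
        hits <- posm[readm == utf8ToInt(b)]
        if (length(hits) > 0) {
          counts[, b] <- counts[, b] + tabulate(hits, nbins = L)
        }
      }
    }
  }
  # slow path: alignments with I/D operations
  for (i in which(!simple)) {
    ops <- regmatches(aln$cigar[i], gregexpr("[0-9]+[MID]", aln$cigar[i]))[[1]]
    n_op <- as.integer(sub("[MID]", "", ops))
    t_op <- sub("[0-9]+", "", ops)
    rp <- aln$pos[i]; qp <- 1L
    sq <- aln$seq[i]
    for (j in seq_along(ops)) {
      if (t_op[j] == "M") {
        for (u in seq_len(n_op[j])) {
          b <- substring(sq, qp + u - 1L, qp + u - 1L)
          if (b %in% c("A", "C", "G", "T")) {
            p <- wrap_pos(rp + u - 1L, L)
            counts[p, b] <- counts[p, b] + 1L
          }
        }
        rp <- rp + n_op[j]; qp <- qp + n_op[j]
      } else if (t_op[j] == "D") {
        pp <- wrap_pos(rp + seq_len(n_op[j]) - 1L, L)
        counts[pp, "del"] <- counts[pp, "del"] + 1L
        gap_pos <- c(gap_pos, wrap_pos(rp - 1L, L), pp,
                     wrap_pos(rp + n_op[j], L))
        rp <- rp + n_op[j]
      } else if (t_op[j] == "I") {
        p <- wrap_pos(rp - 1L, L)
        counts[p, "ins"] <- counts[p, "ins"] + 1L
        gap_pos <- c(gap_pos, p, wrap_pos(rp, L))
        qp <- qp + n_op[j]
      }
    }
  }
  depth <- as.integer(rowSums(counts[, c("A", "C", "G", "T", "del"), drop = FALSE]))
  covered <- depth[depth > 0L]
  structure(list(species = species, counts = counts, depth = depth,
                 gap_positions = sort(unique(gap_pos)),
                 reference_id = reference$id,
                 summary = list(mean = if (length(covered)) mean(covered) else 0,
                                min = if (length(covered)) min(covered) else 0L,
                                max = if (length(covered)) max(covered) else 0L)),
            class = "pool_counts")
}

#' @export
print.pool_counts <- function(x, ...) {
  cat(sprintf("<pool_counts> %s vs %s: mean depth %.1f (range %d-%d)\n",
              x$species, x$reference_id, x$summary$mean, x$summary$min,
              x$summary$max))
  invisible(x)
}

#' Fold inverted-repeat tallies onto the canonical copy
#'
#' Reads wholly inside the IR cannot distinguish the two copies, and reads
#' whose sequencing errors break the tie land arbitrarily on either copy,
#' splitting the evidence. Folding adds each IRb position's tallies
#' (complement-transformed) into its mirrored IRa position and zeroes the
#' IRb rows, so the IR is analyzed once at full depth; IRb sites then drop
#' out as `low_coverage` and [mirror_ir_sites()] records the mirror
#' coordinate of the canonical calls.
#'
#' @param counts a [pileup()] result.
#' @param partition the reference's [region_partition()].
#' @return the folded `pool_counts`.
#' @export
fold_ir_counts <- function(counts, partition) {
  stopifnot(inherits(counts, "pool_counts"))
  L <- partition$genome_length
  idx_b <- circ_positions(partition$irb, L)
  off <- (partition$irb[2] - idx_b) %% L
  idx_a <- wrap_pos(partition$ira[1] + off, L)
  comp_cols <- c("T", "G", "C", "A", "del", "ins")   # complement of A C G T
  counts$counts[idx_a, ] <- counts$counts[idx_a, ] +
    counts$counts[idx_b, comp_cols]
  counts$counts[idx_b, ] <- 0L
  counts$depth <- as.integer(rowSums(counts$counts[, c("A", "C", "G", "T",
                                                       "del"), drop = FALSE]))
  covered <- counts$depth[counts$depth > 0L]
  counts$summary <- list(mean = if (length(covered)) mean(covered) else 0,
                         min = if (length(covered)) min(covered) else 0L,
                         max = if (length(covered)) max(covered) else 0L)
  counts$folded_ir <- TRUE
  counts
}

SITE_CLASSES <- c("fixed_interspecific", "intraspecific_polymorphic",
                  "monomorphic_shared", "low_coverage", "ambiguous")

#' Classify sites from two pooled libraries against one reference
#'
#' Per site, in order: `low_coverage` when depth is below `min_depth` in
#' either pool; `fixed_interspecific` when the major allele frequency is at
#' least `fixed_freq` in *both* pools and the major alleles differ;
#' `intraspecific_polymorphic` when a minor allele reaches `poly_freq` with
#' at least `poly_count` supporting reads in either pool;
#' `monomorphic_shared` when both pools are fixed for the same allele;
#' `ambiguous` otherwise. Sites within `indel_mask` bases of an alignment
#' gap are reclassified `ambiguous` (alignment-ambiguity guard).
#'
#' @param counts_a,counts_b [pileup()] results for the two species pools.
#' @param reference the shared reference [plastome()].
#' @param cfg a [run_config()] supplying the thresholds.
#' @param all_sites return every site (default `FALSE`: monomorphic and
#'   low-coverage sites are summarized in attributes `n_monomorphic` /
#'   `n_low_coverage` instead of returned).
#' @return data frame of class `variant_records` with columns `pos`, `ref`,
#'   `allele_a`, `allele_b`, `class`, `depth_a`, `depth_b`, `maf_a`,
#'   `maf_b`, `pos_b` (NA until lifted), `mirror_pos` (NA until mirrored).
#' @export
classify_sites <- function(counts_a, counts_b, reference, cfg = run_config(),
                           all_sites = FALSE) {
  stopifnot(inherits(counts_a, "pool_counts"), inherits(counts_b, "pool_counts"))
  if (nrow(counts_a$counts) != nrow(counts_b$counts)) {
    stop("pools were tallied against references of different lengths", call. = FALSE)
  }
  L <- nrow(counts_a$counts)
  base_a <- counts_a$counts[, c("A", "C", "G", "T"), drop = FALSE]
  base_b <- counts_b$counts[, c("A", "C", "G", "T"), drop = FALSE]
  da <- rowSums(base_a); db <- rowSums(base_b)
  maj_ia <- max.col(base_a, ties.method = "first")
  maj_ib <- max.col(base_b, ties.method = "first")
  maj_ca <- base_a[cbind(seq_len(L), maj_ia)]
  maj_cb <- base_b[cbind(seq_len(L), maj_ib)]
  maf_a <- ifelse(da > 0, maj_ca / da, 0)
  maf_b <- ifelse(db > 0, maj_cb / db, 0)
  minor_ca <- da - maj_ca
  minor_cb <- db - maj_cb
  # largest single minor allele (not the residual sum) drives polymorphism
  sec_a <- apply_second_max(base_a, maj_ia)
  sec_b <- apply_second_max(base_b, maj_ib)

  depth_a <- counts_a$depth; depth_b <- counts_b$depth
  low <- depth_a < cfg$min_depth | depth_b < cfg$min_depth
  fixed_a <- maf_a >= cfg$fixed_freq
  fixed_b <- maf_b >= cfg$fixed_freq
  poly_a <- da > 0 & (sec_a / pmax(da, 1L)) >= cfg$poly_freq & sec_a >= cfg$poly_count
  poly_b <- db > 0 & (sec_b / pmax(db, 1L)) >= cfg$poly_freq & sec_b >= cfg$poly_count

  cls <- rep("ambiguous", L)
  cls[fixed_a & fixed_b & maj_ia == maj_ib] <- "monomorphic_shared"
  cls[poly_a | poly_b] <- "intraspecific_polymorphic"
  cls[fixed_a & fixed_b & maj_ia != maj_ib] <- "fixed_interspecific"
  cls[low] <- "low_coverage"

  gaps <- sort(unique(c(counts_a$gap_positions, counts_b$gap_positions)))
  if (length(gaps) > 0 && cfg$indel_mask > 0) {
    masked <- unique(as.vector(outer(gaps, -cfg$indel_mask:cfg$indel_mask, `+`)))
    masked <- masked[masked >= 1L & masked <= L]
    cls[masked][cls[masked] != "low_coverage"] <- "ambiguous"
  }

  refbase <- substring(reference$sequence, 1L, L)
  refv <- strsplit(refbase, "")[[1]]
  rec <- data.frame(pos = seq_len(L), ref = refv,
                    allele_a = c("A", "C", "G", "T")[maj_ia],
                    allele_b = c("A", "C", "G", "T")[maj_ib],
                    class = cls, depth_a = as.integer(depth_a),
                    depth_b = as.integer(depth_b),
                    maf_a = round(maf_a, 4), maf_b = round(maf_b, 4),
                    pos_b = NA_integer_, mirror_pos = NA_integer_,
                    stringsAsFactors = FALSE)
  n_mono <- sum(cls == "monomorphic_shared")
  n_low <- sum(cls == "low_coverage")
  if (!all_sites) {
    rec <- rec[!(rec$class %in% c("monomorphic_shared", "low_coverage")), ,
               drop = FALSE]
    # ambiguous sites with no allele signal (zero depth everywhere) excluded
    rownames(rec) <- NULL
  }
  attr(rec, "n_monomorphic") <- n_mono
  attr(rec, "n_low_coverage") <- n_low
  attr(rec, "species") <- c(counts_a$species, counts_b$species)
  class(rec) <- c("variant_records", "data.frame")
  rec
}

# second-largest count per row given the argmax column
apply_second_max <- function(m, maj_i) {
  m2 <- m
  m2[cbind(seq_len(nrow(m)), maj_i)] <- -1L
  m2[cbind(seq_len(nrow(m)), max.col(m2, ties.method = "first"))]
}

#' Collapse mirrored inverted-repeat sites
#'
#' Each IR-resident record is paired with its mirrored coordinate.
#' Concordant pairs (same class, reverse-complementary alleles) collapse to
#' one canonical record at the IRa coordinate; discordant pairs are
#' reclassified `ambiguous`; a record whose mirror is absent from the set
#' (e.g. the mirror copy received no uniquely assigned reads) is
#' re-coordinated to IRa and kept, with `mirror_status = "mirror_absent"`.
#'
#' @param records `variant_records` from [classify_sites()].
#' @param partition the reference's [region_partition()].
#' @return `variant_records` with `mirror_pos` and `mirror_status` filled
#'   and IR duplicates collapsed.
#' @export
mirror_ir_sites <- function(records, partition) {
  rec <- as.data.frame(records)
  if (nrow(rec) == 0) {
    records$mirror_status <- character(0)
    return(records)
  }
  reg <- partition_region_of(partition, rec$pos)
  rec$mirror_status <- ifelse(reg %in% c("ira", "irb"), "pending", NA_character_)
  mp <- mirror_position(partition, rec$pos)
  comp <- function(x) chartr("ACGT", "TGCA", x)
  canon <- ifelse(reg == "irb", mp, rec$pos)
  keep <- rep(TRUE, nrow(rec))
  for (cp in unique(canon[reg %in% c("ira", "irb")])) {
    grp <- which(canon == cp)
    ia <- grp[reg[grp] == "ira"]
    ib <- grp[reg[grp] == "irb"]
    if (length(ia) == 1L && length(ib) == 1L) {
      concord <- rec$class[ia] == rec$class[ib] &&
        rec$allele_a[ib] == comp(rec$allele_a[ia]) &&
        rec$allele_b[ib] == comp(rec$allele_b[ia])
      rec$mirror_pos[ia] <- rec$pos[ib]
      rec$mirror_status[ia] <- if (concord) "concordant" else "discordant"
      if (!concord) rec$class[ia] <- "ambiguous"
      keep[ib] <- FALSE
    } else if (length(ib) == 1L && length(ia) == 0L) {
      # re-coordinate lone IRb record to the canonical IRa position
      rec$mirror_pos[ib] <- rec$pos[ib]
      rec$pos[ib] <- cp
      rec$ref[ib] <- comp(rec$ref[ib])
      rec$allele_a[ib] <- comp(rec$allele_a[ib])
      rec$allele_b[ib] <- comp(rec$allele_b[ib])
      rec$mirror_status[ib] <- "mirror_absent"
    } else if (length(ia) == 1L) {
      rec$mirror_pos[ia] <- mp[ia]
      rec$mirror_status[ia] <- "mirror_absent"
    }
  }
  rec <- rec[keep, , drop = FALSE]
  rec <- rec[order(rec$pos), , drop = FALSE]
  rownames(rec) <- NULL
  for (a in c("n_monomorphic", "n_low_coverage", "species")) {
    attr(rec, a) <- attr(records, a)
  }
  class(rec) <- c("variant_records", "data.frame")
  rec
}

#' Select interspecific candidate columns from tagged contig alignments
#'
#' For EST-derived contig multiple alignments in which every sequence
#' carries a species tag, a column is an interspecific candidate iff its
#' alleles partition perfectly by species (monomorphic within each species,
#' different between species) and each species' allele is observed at least
#' `min_redundancy` times. Columns containing a gap are skipped;
#' single-species contigs are skipped with a message.
#'
#' @param contigs list; each element a list with `seqs` (equal-width
#'   aligned sequences, gaps as `-`) and `species` (parallel tags). A
#'   `name` element is used in the output when present.
#' @param min_redundancy minimum observations of each species' allele
#'   (default 2: singleton support is treated as possible sequencing
#'   error).
#' @return data frame: `contig`, `column`, one `allele_<species>` column
#'   per species observed.
#' @export
select_est_interspecific <- function(contigs, min_redundancy = 2L) {
  out <- list()
  for (ci in seq_along(contigs)) {
    cg <- contigs[[ci]]
    nm <- if (!is.null(cg$name)) cg$name else sprintf("contig_%d", ci)
    sp <- cg$species
    if (length(unique(sp)) < 2L) {
      message("skipping single-species contig: ", nm)
      next
    }
    w <- unique(nchar(cg$seqs))
    if (length(w) != 1L) stop("unaligned contig (unequal widths): ", nm, call. = FALSE)
    m <- matrix(utf8ToInt(paste(toupper(cg$seqs), collapse = "")),
                ncol = w, byrow = TRUE)
    gapcode <- utf8ToInt("-")
    has_gap <- colSums(m == gapcode) > 0L
    species_list <- sort(unique(sp))
    # per-species columnwise uniformity and the uniform value
    uniform <- matrix(TRUE, nrow = length(species_list), ncol = w)
    value <- matrix(0L, nrow = length(species_list), ncol = w)
    count <- integer(length(species_list))
    for (si in seq_along(species_list)) {
      rows <- sp == species_list[si]
      count[si] <- sum(rows)
      sm <- m[rows, , drop = FALSE]
      value[si, ] <- sm[1L, ]
      uniform[si, ] <- colSums(sm != rep(sm[1L, ], each = nrow(sm))) == 0L
    }
    ok <- !has_gap & colSums(!uniform) == 0L &
      apply(value, 2, function(v) length(unique(v)) == length(species_list)) &
      all(count >= min_redundancy)
    cols <- which(ok)
    if (length(cols) > 0) {
      df <- data.frame(contig = nm, column = cols, stringsAsFactors = FALSE)
      for (si in seq_along(species_list)) {
        df[[paste0("allele_", species_list[si])]] <-
          intToUtf8(value[si, cols], multiple = TRUE)
      }
      out[[length(out) + 1L]] <- df
    }
  }
  if (length(out) == 0L) {
    return(data.frame(contig = character(), column = integer()))
  }
  data.table::rbindlist(out, fill = TRUE) |> as.data.frame()
}
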