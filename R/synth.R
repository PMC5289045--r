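# Synthetic plastome world with known truth: an ancestral quadripartite
# genome, three descendant species on the tree ((A,B),C), per-species
# genotype panels with contrasting diversity, and pooled short reads.
# Species A and B play the outcrossing / distant roles in tests; defaults
# emulate pooled sequencing of one outcrossing species (24 genotypes, ~218
# segregating variants) and two clonal apomicts (24 and 12 genotypes, ~31
# variants).

#' Configuration for the synthetic plastome generator
#'
#' Defaults describe the emulated study system: a ~151 kb circular genome
#' with LSC/SSC/IR fractions 0.555/0.122/0.1615, three species at ~99.6%
#' pairwise identity (substitution rate 0.002/site per terminal lineage
#' pair-path half, transition:transversion ratio 1), pools of 24/24/12
#' genotypes with 218/31/31 intraspecific variants, 150 b reads at 300x
#' mean pool coverage with 0.2% base error.
#'
#' @param length ancestor genome length in bases.
#' @param frac_lsc,frac_ssc,frac_ir region fractions of the circle;
#'   `frac_lsc + frac_ssc + 2*frac_ir` must equal 1 (tolerance 1e-9).
#' @param branch_terminal expected substitutions/site on each terminal
#'   branch of ((A,B),C).
#' @param branch_internal expected substitutions/site on the internal
#'   branch leading to the (A,B) pair.
#' @param ts_tv transition:transversion ratio for planted substitutions.
#' @param indel_rate interspecific indel events per site per branch
#'   (geometric lengths, mean `indel_mean`); indels are never planted
#'   inside the IR.
#' @param indel_mean mean indel length.
#' @param genotypes integer vector, pool sizes for species A, B, C.
#' @param intra_variants integer vector, segregating intraspecific variant
#'   counts for species A, B, C (outcrosser high, apomicts low).
#' @param read_length,coverage,error_rate pooled-read simulation settings.
#' @param seed master RNG seed; all sub-generators derive from it.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(length = 151000L,
                         frac_lsc = 0.555, frac_ssc = 0.122, frac_ir = 0.1615,
                         branch_terminal = 0.00175, branch_internal = 0.0005,
                         ts_tv = 1.0,
                         indel_rate = 0.0002, indel_mean = 3,
                         genotypes = c(A = 24L, B = 24L, C = 12L),
                         intra_variants = c(A = 218L, B = 31L, C = 31L),
                         read_length = 150L, coverage = 300, error_rate = 0.002,
                         seed = 1L) {
  stopifnot(abs(frac_lsc + frac_ssc + 2 * frac_ir - 1) < 1e-9)
  rates <- c(branch_terminal, branch_internal, indel_rate, error_rate)
  stopifnot(all(rates >= 0 & rates < 1))
  structure(list(length = as.integer(length), frac_lsc = frac_lsc,
                 frac_ssc = frac_ssc, frac_ir = frac_ir,
                 branch_terminal = branch_terminal,
                 branch_internal = branch_internal,
                 ts_tv = ts_tv, indel_rate = indel_rate,
                 indel_mean = indel_mean,
                 genotypes = genotypes, intra_variants = intra_variants,
                 read_length = as.integer(read_length), coverage = coverage,
                 error_rate = error_rate, seed = as.integer(seed)),
            class = "synth_config")
}

BASES <- c("A", "C", "G", "T")
TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")

random_dna <- function(n, gc = 0.37) {
  paste(sample(BASES, n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Generate the ancestral plastome
#'
#' Builds a circular genome laid out LSC - IRa - SSC - IRb starting at LSC
#' base 1, with IRb the exact reverse complement of IRa, and places
#' non-overlapping gene features in all four regions (IR features are
#' mirrored into both copies). A three-copy tRNA gene (`trnF-GAA`) is
#' planted in the LSC to emulate tandem copy-number structure.
#'
#' @param cfg a [synth_config()].
#' @return a [plastome()] with `partition` set.
#' @export
generate_ancestor <- function(cfg) {
  set.seed(derive_seed(cfg$seed, 1L))
  L <- cfg$length
  ir_len <- as.integer(round(cfg$frac_ir * L))
  lsc_len <- as.integer(round(cfg$frac_lsc * L))
  ssc_len <- L - lsc_len - 2L * ir_len
  if (ssc_len < 100L) stop("region fractions infeasible at this length", call. = FALSE)

  lsc_iv <- c(1L, lsc_len)
  ira_iv <- c(lsc_len + 1L, lsc_len + ir_len)
  ssc_iv <- c(lsc_len + ir_len + 1L, lsc_len + ir_len + ssc_len)
  irb_iv <- c(lsc_len + ir_len + ssc_len + 1L, L)

  lsc_seq <- random_dna(lsc_len)
  ira_seq <- random_dna(ir_len)
  ssc_seq <- random_dna(ssc_len)
  sequence <- paste0(lsc_seq, ira_seq, ssc_seq, revcomp(ira_seq))

  # gene load per region scales with the genome so small test genomes work
  scale <- max(0.02, min(1, L / 151000))
  n_cds_lsc <- max(2L, as.integer(round(50 * scale)))
  n_trna_lsc <- max(1L, as.integer(round(18 * scale)))
  n_pseudo_lsc <- max(1L, as.integer(round(4 * scale)))
  n_cds_ssc <- max(1L, as.integer(round(11 * scale)))
  n_cds_ir <- max(1L, as.integer(round(2 * scale)))
  n_rrna_ir <- max(1L, as.integer(round(4 * scale)))
  n_trna_ir <- max(1L, as.integer(round(3 * scale)))

  place_region <- function(iv, specs, prefix) {
    # specs: data.frame(kind, len); sequential placement with random gaps
    avail <- circ_len(iv, L)
    # shrink over-long genes deterministically so scaled-down genomes fit
    guard <- 0L
    while (sum(specs$len) > 0.7 * avail && guard < 50L) {
      i <- which.max(specs$len)
      specs$len[i] <- max(60L, as.integer(specs$len[i] * 0.6) %/% 3L * 3L)
      guard <- guard + 1L
    }
    need <- sum(specs$len)
    if (need > 0.8 * avail) stop("region too crowded for requested gene load", call. = FALSE)
    slack <- avail - need
    gaps <- as.vector(stats::rmultinom(1, slack, rep(1, nrow(specs) + 1L)))
    cur <- iv[1]
    out <- vector("list", nrow(specs))
    for (i in seq_len(nrow(specs))) {
      cur <- cur + gaps[i]
      out[[i]] <- data.frame(
        feature_id = sprintf("%s%02d", prefix, i),
        name = sprintf("%s%02d", prefix, i),
        kind = specs$kind[i],
        strand = sample(c("+", "-"), 1),
        start = cur, end = cur + specs$len[i] - 1L,
        exon = 1L, codon_start = 1L, partial = FALSE,
        stringsAsFactors = FALSE)
      cur <- cur + specs$len[i]
    }
    do.call(rbind, out)
  }
  cds_len <- function(n) 3L * sample(80:400, n, replace = TRUE)
  lsc_specs <- data.frame(
    kind = c(rep("CDS", n_cds_lsc), rep("tRNA", n_trna_lsc),
             rep("pseudo_or_ORF", n_pseudo_lsc)),
    len = c(cds_len(n_cds_lsc), rep(75L, n_trna_lsc),
            3L * sample(40:120, n_pseudo_lsc, replace = TRUE)))
  lsc_specs <- lsc_specs[sample(nrow(lsc_specs)), , drop = FALSE]
  ssc_specs <- data.frame(kind = c(rep("CDS", n_cds_ssc), "tRNA"),
                          len = c(cds_len(n_cds_ssc), 75L))
  ir_specs <- data.frame(
    kind = c(rep("rRNA", n_rrna_ir), rep("CDS", n_cds_ir), rep("tRNA", n_trna_ir)),
    len = c(sample(c(1500L, 2900L, 120L, 280L), n_rrna_ir, replace = TRUE),
            cds_len(n_cds_ir), rep(75L, n_trna_ir)))

  flsc <- place_region(lsc_iv, lsc_specs, "lg")
  fssc <- place_region(ssc_iv, ssc_specs, "sg")
  fira <- place_region(ira_iv, ir_specs, "rg")
  # mirror IR features into IRb with flipped strand
  firb <- fira
  firb$start <- wrap_pos(irb_iv[2] - (fira$end - ira_iv[1]), L)
  firb$end <- wrap_pos(irb_iv[2] - (fira$start - ira_iv[1]), L)
  firb$strand <- ifelse(fira$strand == "+", "-", "+")
  firb$feature_id <- paste0(fira$feature_id, "_irb")

  # three tandem copies of trnF-GAA: overwrite three LSC tRNA-sized slots by
  # relabeling the first LSC tRNA and appending two planted copies in a gap
  trna_rows <- which(flsc$kind == "tRNA")
  flsc$name[trna_rows[1]] <- "trnF-GAA"
  gap_start <- flsc$end[nrow(flsc)] + 10L
  extra <- data.frame(feature_id = c("trnF2", "trnF3"),
                      name = "trnF-GAA", kind = "tRNA", strand = "+",
                      start = c(gap_start, gap_start + 90L),
                      end = c(gap_start + 74L, gap_start + 164L),
                      exon = 1L, codon_start = 1L, partial = FALSE,
                      stringsAsFactors = FALSE)
  if (extra$end[2] >= lsc_iv[2]) extra <- extra[0, , drop = FALSE]

  feats <- rbind(flsc, extra, fira, fssc, firb)

  # give CDS features a clean reading frame: ATG ... stop-free body ... TAA
  seqchars <- strsplit(sequence, "")[[1]]
  for (i in which(feats$kind == "CDS" & feats$exon == 1L)) {
    st <- feats$start[i]; en <- feats$end[i]
    if (grepl("_irb$", feats$feature_id[i])) next  # written via mirror below
    body <- make_orf(en - st + 1L)
    if (feats$strand[i] == "-") body <- revcomp(body)
    seqchars[st:en] <- strsplit(body, "")[[1]]
  }
  sequence <- paste(seqchars, collapse = "")
  # re-mirror IRb after CDS rewrites inside IRa
  ira_seq <- substr(sequence, ira_iv[1], ira_iv[2])
  sequence <- paste0(substr(sequence, 1, ira_iv[2]),
                     substr(sequence, ssc_iv[1], ssc_iv[2]),
                     revcomp(ira_seq))
  # boundary sentinels: make the planted IR the *maximal* exact inverted
  # repeat by breaking chance complementarity just outside each IR edge
  # (outer edge pairs LSC end with position 1; inner edge pairs SSC start
  # with SSC end)
  sequence <- break_palindrome_extension(sequence, lsc_iv[2], 1L)
  sequence <- break_palindrome_extension(sequence, ssc_iv[1], ssc_iv[2])

  part <- region_partition(lsc = lsc_iv, ira = ira_iv, ssc = ssc_iv,
                           irb = irb_iv, genome_length = L)
  plastome("ancestor", sequence, features = feats, partition = part)
}

# If sequence[i] complements sequence[j], substitute sequence[i] so the IR
# cannot extend across its planted boundary by chance.
break_palindrome_extension <- function(sequence, i, j) {
  bi <- substring(sequence, i, i)
  bj <- substring(sequence, j, j)
  if (bi == chartr("ACGT", "TGCA", bj)) {
    repl <- setdiff(BASES, c(bi, chartr("ACGT", "TGCA", bj)))[1]
    substring(sequence, i, i) <- repl
  }
  sequence
}

# A stop-free open reading frame of the given length (multiple of 3).
make_orf <- function(len) {
  stopifnot(len %% 3 == 0, len >= 6)
  n_codon <- len / 3L - 2L
  codons <- c("GCT", "GCA", "TGT", "GAT", "GAA", "TTT", "GGA", "CAT", "ATT",
              "AAA", "TTA", "ATG", "AAT", "CCT", "CAA", "CGT", "TCT", "ACT",
              "GTA", "TGG", "TAC", "GGG", "CTC", "AGA")
  paste0("ATG", paste(sample(codons, n_codon, replace = TRUE), collapse = ""), "TAA")
}

# --- species derivation ----------------------------------------------------

# Draw substitution targets: transitions w.p. ts_tv/(ts_tv+1), else one of
# the two transversions.
draw_subs <- function(ref_bases, ts_tv) {
  n <- length(ref_bases)
  is_ts <- stats::runif(n) < ts_tv / (ts_tv + 1)
  out <- character(n)
  out[is_ts] <- TRANSITION[ref_bases[is_ts]]
  tv <- !is_ts
  if (any(tv)) {
    # the two transversion partners of each base
    tv_map <- list(A = c("C", "T"), G = c("C", "T"),
                   C = c("A", "G"), T = c("A", "G"))
    pick <- stats::runif(sum(tv)) < 0.5
    out[tv] <- mapply(function(b, p) tv_map[[b]][1 + p],
                      ref_bases[tv], pick, USE.NAMES = FALSE)
  }
  out
}

# Plant `n_sub` substitutions and `n_indel` indels on a genome with a
# quadripartite partition; IR substitutions are mirrored (complemented) into
# the other copy, indels avoid the IR entirely. Returns the edit set in the
# *input* genome's coordinates.
plant_edits <- function(p, n_sub, n_indel, ts_tv, indel_mean) {
  L <- p$length
  part <- p$partition
  subs <- data.frame(pos = integer(), ref = character(), alt = character())
  if (n_sub > 0L) {
    # n_sub is a changed-base budget: an IR hit is mirrored into the other
    # copy and therefore costs two bases
    pos <- sample.int(L, min(L, 2L * n_sub + 10L))
    canon <- pos
    cost <- rep(1L, length(pos))
    if (!is.null(part)) {
      reg <- partition_region_of(part, pos)
      irb <- reg == "irb"
      canon[irb] <- mirror_position(part, pos[irb])
      cost[reg %in% c("ira", "irb")] <- 2L
    }
    keep <- !duplicated(canon)
    canon <- canon[keep]; cost <- cost[keep]
    keep <- cumsum(cost) <= n_sub
    canon <- canon[keep]
    refb <- substring(p$sequence, canon, canon)
    ok <- refb %in% BASES
    canon <- canon[ok]; refb <- refb[ok]
    altb <- draw_subs(refb, ts_tv)
    subs <- data.frame(pos = canon, ref = refb, alt = altb)
  }

  indels <- data.frame(pos = integer(), len = integer(), ins = character())
  if (n_indel > 0 && !is.null(part)) {
    sc_pos <- c(circ_positions(part$lsc, L), circ_positions(part$ssc, L))
    # keep indels clear of the IR boundary so mirrored bookkeeping stays exact
    ip <- sample(sc_pos, n_indel)
    ilen <- stats::rgeom(n_indel, 1 / indel_mean) + 1L
    is_ins <- stats::runif(n_indel) < 0.5
    ins <- ifelse(is_ins,
                  vapply(ilen, function(k) paste(sample(BASES, k, replace = TRUE),
                                                 collapse = ""), character(1)),
                  NA_character_)
    indels <- data.frame(pos = ip, len = ifelse(is_ins, ilen, -ilen), ins = ins,
                         stringsAsFactors = FALSE)
    indels <- indels[order(indels$pos), , drop = FALSE]
    # drop overlapping deletions (rare)
    if (nrow(indels) > 1) {
      delend <- indels$pos + pmax(0L, -indels$len)
      keep <- c(TRUE, indels$pos[-1] > cummax(delend[-nrow(indels)]))
      indels <- indels[keep, , drop = FALSE]
    }
  }
  list(subs = subs, indels = indels)
}

# Apply an edit set. Substitutions (given in input coordinates, already
# IR-canonicalized) are mirrored into the IR partner; indels are applied
# from the end so earlier coordinates stay valid.
apply_edits <- function(p, edits) {
  chars <- strsplit(p$sequence, "")[[1]]
  subs <- edits$subs
  if (nrow(subs) > 0) {
    chars[subs$pos] <- subs$alt
    if (!is.null(p$partition)) {
      mp <- mirror_position(p$partition, subs$pos)
      inir <- !is.na(mp)
      if (any(inir)) {
        chars[mp[inir]] <- chartr("ACGT", "TGCA", subs$alt[inir])
      }
    }
  }
  seqs <- paste(chars, collapse = "")
  indels <- edits$indels
  if (nrow(indels) > 0) {
    for (i in rev(seq_len(nrow(indels)))) {
      pos <- indels$pos[i]; len <- indels$len[i]
      if (len > 0) {
        seqs <- paste0(substr(seqs, 1, pos), indels$ins[i],
                       substr(seqs, pos + 1, nchar(seqs)))
      } else {
        seqs <- paste0(substr(seqs, 1, pos - 1),
                       substr(seqs, pos - len, nchar(seqs)))
      }
    }
  }
  seqs
}

# Map positions from the pre-edit to the post-edit coordinate system.
lift_over_indels <- function(pos, indels) {
  if (nrow(indels) == 0 || length(pos) == 0) return(pos)
  out <- pos
  for (i in seq_len(nrow(indels))) {
    ip <- indels$pos[i]; len <- indels$len[i]
    if (len > 0) {
      out <- out + ifelse(pos > ip, len, 0L)
    } else {
      # deletion removes bases ip+1 .. ip-len
      del_from <- ip + 1L; del_to <- ip - len
      out <- out + ifelse(pos > del_to, len, 0L)
      out[pos >= del_from & pos <= del_to] <- NA_integer_
    }
  }
  out
}

# Lift a feature table across indels; features losing a boundary are dropped.
lift_features <- function(feats, indels) {
  if (nrow(feats) == 0 || nrow(indels) == 0) return(feats)
  st <- lift_over_indels(feats$start, indels)
  en <- lift_over_indels(feats$end, indels)
  keep <- !is.na(st) & !is.na(en)
  feats <- feats[keep, , drop = FALSE]
  feats$start <- st[keep]; feats$end <- en[keep]
  feats
}

#' Derive three related species from an ancestor
#'
#' Mutations are placed on the species tree `((A,B),C)`: the internal
#' branch contributes shared derived alleles to A and B, terminal branches
#' are independent. IR substitutions are planted symmetrically
#' (complemented) in both copies; indels avoid the IR. The returned truth
#' table records, per ancestor-coordinate site, each species' allele and
#' each species' own coordinate of that site.
#'
#' @param ancestor a partitioned [plastome()] from [generate_ancestor()].
#' @param cfg a [synth_config()].
#' @return list with `species` (named list of three plastomes A, B, C),
#'   `truth` (data frame: `pos_anc`, `allele_A/B/C`, `pos_A/B/C`,
#'   `mirror_anc`), `indels` (per-species indel tables, ancestor
#'   coordinates), and `tree` (newick).
#' @export
derive_species <- function(ancestor, cfg) {
  stopifnot(inherits(ancestor, "plastome"), !is.null(ancestor$partition))
  set.seed(derive_seed(cfg$seed, 2L))
  L <- ancestor$length
  n_term <- round(cfg$branch_terminal * L)
  n_int <- round(cfg$branch_internal * L)
  n_indel <- round(cfg$indel_rate * L)

  e_int <- plant_edits(ancestor, n_int, 0L, cfg$ts_tv, cfg$indel_mean)
  e_A <- plant_edits(ancestor, n_term, n_indel, cfg$ts_tv, cfg$indel_mean)
  e_B <- plant_edits(ancestor, n_term, n_indel, cfg$ts_tv, cfg$indel_mean)
  e_C <- plant_edits(ancestor, n_term, n_indel, cfg$ts_tv, cfg$indel_mean)

  # resolve collisions: a site mutated on >1 contributing branch keeps the
  # most terminal edit; abort if collisions are widespread
  combine <- function(term, internal) {
    if (nrow(internal$subs) == 0) return(term)
    dup <- internal$subs$pos %in% term$subs$pos
    term$subs <- rbind(term$subs, internal$subs[!dup, , drop = FALSE])
    term
  }
  all_planted <- c(e_int$subs$pos, e_A$subs$pos, e_B$subs$pos, e_C$subs$pos)
  n_coll <- sum(duplicated(all_planted))
  if (n_coll > 0.05 * length(all_planted)) {
    stop(sprintf("planted-site collisions too frequent (%d of %d); lower divergence",
                 n_coll, length(all_planted)), call. = FALSE)
  }
  ed_A <- combine(e_A, e_int)
  ed_B <- combine(e_B, e_int)
  ed_C <- e_C

  mk <- function(id, ed) {
    seqs <- apply_edits(ancestor, ed)
    feats <- lift_features(ancestor$features, ed$indels)
    plastome(id, seqs, features = feats)
  }
  spA <- mk("A", ed_A); spB <- mk("B", ed_B); spC <- mk("C", ed_C)

  pos_all <- sort(unique(c(ed_A$subs$pos, ed_B$subs$pos, ed_C$subs$pos)))
  anc_base <- if (length(pos_all) > 0) {
    substring(ancestor$sequence, pos_all, pos_all)
  } else character(0)
  allele_of <- function(ed) {
    i <- match(pos_all, ed$subs$pos)
    ifelse(is.na(i), anc_base, ed$subs$alt[i])
  }
  truth <- data.frame(pos_anc = pos_all,
                      allele_anc = anc_base,
                      allele_A = allele_of(ed_A),
                      allele_B = allele_of(ed_B),
                      allele_C = allele_of(ed_C),
                      pos_A = lift_over_indels(pos_all, ed_A$indels),
                      pos_B = lift_over_indels(pos_all, ed_B$indels),
                      pos_C = lift_over_indels(pos_all, ed_C$indels),
                      mirror_anc = mirror_position(ancestor$partition, pos_all),
                      stringsAsFactors = FALSE)
  list(species = list(A = spA, B = spB, C = spC), truth = truth,
       indels = list(A = ed_A$indels, B = ed_B$indels, C = ed_C$indels),
       tree = "((A,B),C);")
}

#' Truth-based pairwise identity of two derived species
#'
#' Percent identity computed by direct comparison in ancestor coordinates
#' (indels replayed, i.e. excluded from the column count): `100 * (1 -
#' changed_bases / genome_length)`, where an IR-resident difference counts
#' both mirrored copies.
#'
#' @param derived result of [derive_species()].
#' @param ancestor the ancestor [plastome()] (for length and partition).
#' @param x,y species labels among `"A"`, `"B"`, `"C"`.
#' @return percentage.
#' @export
truth_identity <- function(derived, ancestor, x, y) {
  tr <- derived$truth
  ax <- tr[[paste0("allele_", x)]]
  ay <- tr[[paste0("allele_", y)]]
  diffs <- ax != ay
  cost <- ifelse(!is.na(tr$mirror_anc), 2L, 1L)
  100 * (1 - sum(cost[diffs]) / ancestor$length)
}

#' Derive a genotype panel within one species
#'
#' Plants `n_variants` segregating SNPs, each carried by a random nonempty
#' proper subset of the `n_genotypes` genotypes. Variants falling in the IR
#' (if the species genome has a detectable partition passed via `partition`)
#' are mirrored within each carrier genotype.
#'
#' @param species a [plastome()].
#' @param n_genotypes panel size (>= 1).
#' @param n_variants segregating variant count (must be < length/100).
#' @param seed RNG seed.
#' @param partition optional [region_partition()] for IR mirroring.
#' @return list with `genotypes` (list of plastomes) and `truth`
#'   (data frame: `pos`, `ref`, `alt`, `carriers` comma-joined genotype
#'   indices, `n_carriers`).
#' @export
derive_genotype_panel <- function(species, n_genotypes, n_variants,
                                  seed = 1L, partition = NULL) {
  stopifnot(inherits(species, "plastome"), n_genotypes >= 1L)
  if (n_variants >= species$length / 100) {
    stop("requested variant count too high for genome length", call. = FALSE)
  }
  set.seed(seed)
  L <- species$length
  if (n_genotypes == 1L || n_variants == 0L) {
    return(list(genotypes = replicate(n_genotypes, species, simplify = FALSE),
                truth = data.frame(pos = integer(), ref = character(),
                                   alt = character(), carriers = character(),
                                   n_carriers = integer())))
  }
  pos <- sort(sample.int(L, n_variants))
  if (!is.null(partition)) {
    reg <- partition_region_of(partition, pos)
    irb <- reg == "irb"
    pos[irb] <- mirror_position(partition, pos[irb])
    pos <- sort(unique(pos))
  }
  refb <- substring(species$sequence, pos, pos)
  ok <- refb %in% BASES
  pos <- pos[ok]; refb <- refb[ok]
  altb <- draw_subs(refb, 1.0)
  # nonempty proper subsets of genotypes
  sizes <- sample.int(n_genotypes - 1L, length(pos), replace = TRUE)
  carriers <- lapply(sizes, function(k) sort(sample.int(n_genotypes, k)))
  mirror <- if (is.null(partition)) rep(NA_integer_, length(pos)) else
    mirror_position(partition, pos)
  genomes <- vector("list", n_genotypes)
  for (g in seq_len(n_genotypes)) {
    has <- vapply(carriers, function(cs) g %in% cs, logical(1))
    if (!any(has)) {
      genomes[[g]] <- species
      next
    }
    seqs <- species$sequence
    for (i in which(has)) {
      substring(seqs, pos[i], pos[i]) <- altb[i]
      if (!is.na(mirror[i])) {
        substring(seqs, mirror[i], mirror[i]) <- chartr("ACGT", "TGCA", altb[i])
      }
    }
    g2 <- species
    g2$id <- sprintf("%s_g%02d", species$id, g)
    g2$sequence <- seqs
    genomes[[g]] <- g2
  }
  truth <- data.frame(pos = pos, ref = refb, alt = altb,
                      carriers = vapply(carriers, paste, character(1),
                                        collapse = ","),
                      n_carriers = lengths(carriers),
                      stringsAsFactors = FALSE)
  list(genotypes = genomes, truth = truth)
}

#' Simulate pooled short reads from a genotype panel
#'
#' Reads are drawn uniformly across genotypes, circular start positions and
#' strands; per-base errors are i.i.d. substitutions at `error_rate`;
#' quality is a constant `I` (the pipeline never consumes base qualities).
#'
#' @param panel list of genotype [plastome()]s (equal lengths assumed; the
#'   panel generator plants SNPs only).
#' @param cfg a [synth_config()] (uses `read_length`, `coverage`,
#'   `error_rate`).
#' @param path optional FASTQ output path (plain text).
#' @param seed RNG seed.
#' @return list with `reads` (data frame: `id`, `seq`, `truth_pos`,
#'   `truth_strand`, `genotype`) and `coverage_summary` (`mean` realized
#'   mean depth, `n_reads`).
#' @export
simulate_pooled_reads <- function(panel, cfg, path = NULL, seed = 1L) {
  stopifnot(length(panel) >= 1L)
  set.seed(seed)
  w <- cfg$read_length
  L <- panel[[1]]$length
  if (w > L) stop("read length exceeds genome length", call. = FALSE)
  n_reads <- as.integer(round(cfg$coverage * L / w))
  gt <- sample.int(length(panel), n_reads, replace = TRUE)
  start <- sample.int(L, n_reads, replace = TRUE)
  minus <- stats::runif(n_reads) < 0.5

  seqs <- character(n_reads)
  for (g in unique(gt)) {
    rows <- which(gt == g)
    doubled <- paste0(panel[[g]]$sequence, substr(panel[[g]]$sequence, 1L, w))
    seqs[rows] <- substring(doubled, start[rows], start[rows] + w - 1L)
  }
  # i.i.d. substitution errors
  if (cfg$error_rate > 0) {
    err <- which(stats::runif(n_reads * w) < cfg$error_rate)
    if (length(err) > 0) {
      ridx <- ((err - 1L) %/% w) + 1L
      cidx <- ((err - 1L) %% w) + 1L
      old <- substring(seqs[ridx], cidx, cidx)
      shift <- sample.int(3L, length(err), replace = TRUE)
      new <- BASES[((match(old, BASES) - 1L + shift) %% 4L) + 1L]
      for (i in seq_along(err)) {
        substring(seqs[ridx[i]], cidx[i], cidx[i]) <- new[i]
      }
    }
  }
  if (any(minus)) seqs[minus] <- revcomp(seqs[minus])
  ids <- sprintf("read_%07d", seq_len(n_reads))
  reads <- data.frame(id = ids, seq = seqs, truth_pos = start,
                      truth_strand = ifelse(minus, "-", "+"), genotype = gt,
                      stringsAsFactors = FALSE)
  if (!is.null(path)) {
    qual <- strrep("I", w)
    writeLines(as.vector(rbind(paste0("@", ids), seqs, "+", qual)), path)
  }
  list(reads = reads,
       coverage_summary = list(mean = n_reads * w / L, n_reads = n_reads))
}
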