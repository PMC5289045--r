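# Shared fixtures, built in code and memoized across test files.
# Genome sizes are scaled down from the ~151 kb defaults to keep the suite
# inside its time budget; structure (quadripartite layout, IR mirroring,
# pool sizes, variant counts where feasible) is preserved.

.world_cache <- new.env(parent = emptyenv())

# A small three-species world with pools, used by several files.
small_world <- function() {
  if (is.null(.world_cache$w)) {
    cfg <- synth_config(length = 20000L, coverage = 200, seed = 42L,
                        intra_variants = c(A = 120L, B = 25L, C = 25L))
    anc <- generate_ancestor(cfg)
    sp <- derive_species(anc, cfg)
    part_a <- partition_quadripartite(sp$species$A)
    .world_cache$w <- list(cfg = cfg, ancestor = anc, species = sp$species,
                           truth = sp$truth, indels = sp$indels,
                           part_a = part_a)
  }
  .world_cache$w
}

# Full-size ancestor (the stated default world), built once.
default_ancestor <- function() {
  if (is.null(.world_cache$anc_full)) {
    .world_cache$anc_full <- generate_ancestor(synth_config(seed = 1L))
  }
  .world_cache$anc_full
}

# A plain plastome with no repeat structure (for coverage statistics that
# assume unique mappability).
flat_genome <- function(len = 10000L, seed = 7L, id = "flat") {
  set.seed(seed)
  plastome(id, paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
                            prob = c(0.315, 0.185, 0.185, 0.315)),
                     collapse = ""))
}

# Construct pool_counts directly from a named base-count specification,
# e.g. counts_at(ref, list(`50` = c(T = 100)), species = "A")
counts_at <- function(reference, spec, species = "pool") {
  L <- reference$length
  m <- matrix(0L, nrow = L, ncol = 6,
              dimnames = list(NULL, c("A", "C", "G", "T", "del", "ins")))
  # background: high clean coverage matching the reference base
  refv <- strsplit(reference$sequence, "")[[1]]
  for (b in c("A", "C", "G", "T")) m[refv == b, b] <- 100L
  for (p in names(spec)) {
    i <- as.integer(p)
    m[i, ] <- 0L
    m[i, names(spec[[p]])] <- as.integer(spec[[p]])
  }
  depth <- as.integer(rowSums(m[, 1:5]))
  structure(list(species = species, counts = m, depth = depth,
                 gap_positions = integer(0), reference_id = reference$id,
                 summary = list(mean = mean(depth), min = min(depth),
                                max = max(depth))),
            class = "pool_counts")
}

# Independent affine-gap global alignment score by exhaustive dynamic
# programming (Gotoh), used as the oracle for global_align on short inputs.
oracle_align_score <- function(a, b, scores = c(match = 1, mismatch = -1,
                                                gap_open = -5, gap_ext = -1)) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  go <- scores[["gap_open"]]; ge <- scores[["gap_ext"]]
  M <- matrix(NEG, n + 1, m + 1); X <- M; Y <- M
  M[1, 1] <- 0
  for (j in seq_len(m)) Y[1, j + 1] <- go + ge * j
  for (i in seq_len(n)) X[i + 1, 1] <- go + ge * i
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (A[i] == B[j]) scores[["match"]] else scores[["mismatch"]]
      best_prev <- max(M[i, j], X[i, j], Y[i, j])
      M[i + 1, j + 1] <- best_prev + s
      X[i + 1, j + 1] <- max(M[i, j + 1] + go + ge, X[i, j + 1] + ge)
      Y[i + 1, j + 1] <- max(M[i + 1, j] + go + ge, Y[i + 1, j] + ge)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Independent digestion oracle: find recognition sites by regex over the
# expanded IUPAC pattern (overlapping matches via lookahead), both strands,
# and cut fragments.
IUPAC_CLASS <- c(A = "A", C = "C", G = "G", T = "T", R = "[AG]", Y = "[CT]",
                 S = "[CG]", W = "[AT]", K = "[GT]", M = "[AC]",
                 B = "[CGT]", D = "[AGT]", H = "[ACT]", V = "[ACG]",
                 N = "[ACGT]")

iupac_regex <- function(pat) {
  paste(IUPAC_CLASS[strsplit(pat, "")[[1]]], collapse = "")
}

# plain-character reverse complement (keeps the oracle independent of the
# package's Biostrings-backed revcomp, and fast for short patterns)
rc_chr <- function(x) {
  paste(rev(strsplit(chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", x), "")[[1]]),
        collapse = "")
}

oracle_digest <- function(seqs, enzyme) {
  n <- nchar(seqs)
  find <- function(pat) {
    rx <- sprintf("(?=%s)", iupac_regex(pat))
    m <- gregexpr(rx, seqs, perl = TRUE)[[1]]
    if (m[1] == -1) integer(0) else as.integer(m)
  }
  cuts <- find(enzyme$recognition) + enzyme$cut_offset - 1L
  rcpat <- rc_chr(enzyme$recognition)
  if (!identical(rcpat, enzyme$recognition)) {
    cuts <- c(cuts,
              find(rcpat) + (nchar(enzyme$recognition) - enzyme$cut_offset) - 1L)
  }
  cuts <- sort(unique(cuts[cuts >= 1L & cuts < n]))
  sort(as.integer(diff(c(0L, cuts, n))), decreasing = TRUE)
}

random_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Path to the bundled fixed-SNP table fixture (positions/alleles/labels of
# the published 16-SNP chloroplast panel).
table3_fixture <- function() {
  system.file("extdata", "fixed_snps_tk_to.tsv", package = "plastmarker",
              mustWork = TRUE)
}
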