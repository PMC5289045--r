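# In-silico PCR, digestion, discriminating enzymes, CAPS/ARMS design,
# band patterns and marker status.

test_that("primer Tm follows the documented formulas and GC monotonicity", {
  expect_equal(primer_tm("AATT"), 8)            # Wallace: 2*(A+T)
  expect_equal(primer_tm("GGCC"), 16)           # 4*(G+C)
  expect_equal(primer_tm("AATTGGCCAATTG"), 2 * 8 + 4 * 5)  # 13-mer boundary
  tm20 <- primer_tm(strrep("AT", 10))
  expect_equal(tm20, 64.9 + 41 * (0 - 16.4) / 20)
  # adding a G/C base never lowers Tm (long-primer formula)
  set.seed(71)
  for (i in 1:20) {
    p <- random_seq(sample(18:28, 1))
    expect_gte(primer_tm(paste0(p, "G")), primer_tm(p) - 1e-9)
  }
})

test_that("in_silico_pcr finds the designed product and nothing spurious", {
  set.seed(72)
  left <- random_seq(400)
  fwd <- random_seq(20)
  mid <- random_seq(247)
  rev_site <- random_seq(20)
  right <- random_seq(300)
  template <- paste0(left, fwd, mid, rev_site, right)
  rev_primer <- revcomp(rev_site)
  prods <- in_silico_pcr(template, fwd, rev_primer)
  expect_equal(nrow(prods), 1L)
  expect_equal(prods$length, 20L + 247L + 20L)
  expect_equal(prods$start, 401L)
  expect_equal(substr(prods$seq, 1, 20), fwd)
  # absent primer -> empty
  expect_equal(nrow(in_silico_pcr(template, random_seq(20), rev_primer)), 0L)
})

test_that("products spanning the origin survive template rotation", {
  set.seed(73)
  fwd <- random_seq(20); mid <- random_seq(200); rev_site <- random_seq(20)
  template <- paste0(random_seq(500), fwd, mid, rev_site, random_seq(500))
  rev_primer <- revcomp(rev_site)
  base <- in_silico_pcr(template, fwd, rev_primer)
  # rotate so the amplicon straddles position 1
  cut <- 500L + 20L + 100L
  rot <- paste0(substr(template, cut + 1, nchar(template)),
                substr(template, 1, cut))
  rotated <- in_silico_pcr(rot, fwd, rev_primer)
  expect_equal(rotated$length, base$length)
  expect_identical(rotated$seq, base$seq)
})

test_that("3'-terminal mismatch blocks priming when required", {
  set.seed(74)
  fwd <- random_seq(20); mid <- random_seq(200); rev_site <- random_seq(20)
  template <- paste0(random_seq(100), fwd, mid, rev_site, random_seq(100))
  bad_fwd <- paste0(substr(fwd, 1, 19),
                    setdiff(c("A", "C", "G", "T"), substr(fwd, 20, 20))[1])
  expect_equal(nrow(in_silico_pcr(template, bad_fwd, revcomp(rev_site),
                                  max_mismatch = 1L)), 0L)
  expect_equal(nrow(in_silico_pcr(template, bad_fwd, revcomp(rev_site),
                                  max_mismatch = 1L,
                                  require_3prime_match = FALSE)), 1L)
})

test_that("digest cuts where expected", {
  cat0 <- read_enzyme_catalog()
  taq <- as.list(cat0[cat0$name == "TaqI", ])
  expect_equal(digest("AATCGATT", taq), c(5L, 3L))
  expect_equal(digest("AAAAAAAA", taq), 8L)
  # two sites
  expect_equal(digest("TCGAAATCGA", taq), c(6L, 3L, 1L))
  # non-palindromic orientation handling exercised through the oracle below
})

test_that("digestion equals the regex-expansion oracle and conserves length", {
  cat0 <- read_enzyme_catalog()
  set.seed(75)
  bad <- character(0)
  for (i in 1:40) {
    n <- sample(200:500, 1)
    s <- random_seq(n)
    for (k in seq_len(nrow(cat0))) {
      e <- as.list(cat0[k, ])
      got <- digest(s, e)
      if (sum(got) != n || !identical(got, oracle_digest(s, e))) {
        bad <- c(bad, paste(e$name, "rep", i))
      }
    }
  }
  expect_identical(bad, character(0))
})

test_that("find_discriminating_enzymes matches brute-force digest comparison", {
  cat0 <- read_enzyme_catalog()
  w <- small_world()
  A <- w$species$A; B <- w$species$B
  tr <- w$truth
  fx <- tr[tr$allele_A != tr$allele_B & !is.na(tr$pos_A) & !is.na(tr$pos_B), ]
  genomes <- list(A = A, B = B)
  bad <- integer(0)
  for (i in seq_len(min(40L, nrow(fx)))) {
    snp <- list(pos = fx$pos_A[i], pos_b = fx$pos_B[i])
    got <- find_discriminating_enzymes(snp, genomes, cat0)$name
    win_a <- plastmarker:::circ_substr(A$sequence,
                                       plastmarker:::wrap_pos(snp$pos - 25L, A$length),
                                       51L, A$length)
    win_b <- plastmarker:::circ_substr(B$sequence,
                                       plastmarker:::wrap_pos(snp$pos_b - 25L, B$length),
                                       51L, B$length)
    brute <- cat0$name[vapply(seq_len(nrow(cat0)), function(k) {
      e <- as.list(cat0[k, ])
      !identical(oracle_digest(win_a, e), oracle_digest(win_b, e))
    }, logical(1))]
    if (!setequal(got, brute)) bad <- c(bad, i)
  }
  expect_identical(bad, integer(0))
})

test_that("SNP with no site change yields an empty enzyme list", {
  cat0 <- read_enzyme_catalog()
  # poly-A flanks: no catalog site with either allele
  ga <- plastome("a", paste0(strrep("A", 60), "T", strrep("A", 60)))
  gb <- plastome("b", paste0(strrep("A", 60), "C", strrep("A", 60)))
  enz <- find_discriminating_enzymes(list(pos = 61L, pos_b = 61L),
                                     list(a = ga, b = gb), cat0)
  expect_equal(nrow(enz), 0L)
})

test_that("ambiguous flanks are excluded conservatively", {
  cat0 <- read_enzyme_catalog()
  ga <- plastome("a", paste0(strrep("A", 45), "N", strrep("A", 14), "T",
                             strrep("A", 60)))
  gb <- plastome("b", paste0(strrep("A", 60), "C", strrep("A", 60)))
  expect_message(
    enz <- find_discriminating_enzymes(list(pos = 61L, pos_b = 61L),
                                       list(a = ga, b = gb), cat0),
    "ambiguity")
  expect_equal(nrow(enz), 0L)
})

test_that("designed CAPS markers satisfy their invariants on synthetic SNPs", {
  w <- small_world()
  A <- w$species$A; B <- w$species$B
  genomes <- list(A = A, B = B)
  cat0 <- read_enzyme_catalog()
  cfg <- run_config()
  tr <- w$truth
  fx <- tr[tr$allele_A != tr$allele_B & !is.na(tr$pos_A) & !is.na(tr$pos_B), ]
  n_ok <- 0L
  for (i in seq_len(min(15L, nrow(fx)))) {
    snp <- list(pos = fx$pos_A[i], pos_b = fx$pos_B[i])
    mk <- design_caps(snp, genomes, cat0, cfg)
    if (!is_marker(mk)) {
      expect_true(mk$reason %in% c("no_enzyme", "no_primers"))
      next
    }
    n_ok <- n_ok + 1L
    # fragments sum to product length per species
    expect_equal(sum(mk$fragments$A), unname(mk$product_length[["A"]]))
    expect_equal(sum(mk$fragments$B), unname(mk$product_length[["B"]]))
    # the two species' patterns are distinguishable at gel resolution
    expect_false(plastmarker:::bands_equal(mk$fragments$A, mk$fragments$B,
                                           cfg$band_resolution))
    # SNP is at least snp_margin from each primer 3' end, product in range
    expect_gte(mk$product_length[["A"]], cfg$product_range[1])
    expect_lte(mk$product_length[["A"]], cfg$product_range[2])
    # primer Tm inside the window
    expect_gte(mk$fwd$tm, cfg$tm_range[1])
    expect_lte(mk$rev$tm, cfg$tm_range[2])
  }
  expect_gte(n_ok, 4L)
})

test_that("SNP with no discriminating enzyme fails with reason no_enzyme", {
  cat0 <- read_enzyme_catalog()
  ga <- plastome("a", paste0(strrep("A", 500), "T", strrep("A", 500)))
  gb <- plastome("b", paste0(strrep("A", 500), "C", strrep("A", 500)))
  mk <- design_caps(list(pos = 501L, pos_b = 501L), list(a = ga, b = gb), cat0,
                    run_config())
  expect_false(is_marker(mk))
  expect_equal(mk$reason, "no_enzyme")
})

test_that("ARMS designs produce allele-specific bands only on the matching genome", {
  w <- small_world()
  A <- w$species$A; B <- w$species$B
  genomes <- list(A = A, B = B)
  cfg <- run_config()
  tr <- w$truth
  fx <- tr[tr$allele_A != tr$allele_B & !is.na(tr$pos_A) & !is.na(tr$pos_B), ]
  n_ok <- 0L
  for (i in seq_len(min(12L, nrow(fx)))) {
    snp <- list(pos = fx$pos_A[i], pos_b = fx$pos_B[i])
    mk <- design_arms(snp, genomes, cfg)
    if (!is_marker(mk)) next
    n_ok <- n_ok + 1L
    expect_gte(abs(mk$allele_length[["A"]] - mk$allele_length[["B"]]),
               cfg$arms_min_diff)
    expect_gt(mk$common_length, max(mk$allele_length))
    # deliberate mismatch at the 2nd base from the 3' terminus
    tail_a <- substring(mk$inner_f$seq, nchar(mk$inner_f$seq) - 1L,
                        nchar(mk$inner_f$seq) - 1L)
    tmpl_a <- substring(A$sequence, snp$pos - 1L, snp$pos - 1L)
    expect_false(tail_a == tmpl_a)
    # full-genome simulated amplification: each allele band only on its genome
    ba <- arms_bands(mk, A)
    bb <- arms_bands(mk, B)
    expect_true(mk$allele_length[["A"]] %in% ba)
    expect_false(mk$allele_length[["A"]] %in% bb)
    expect_true(mk$allele_length[["B"]] %in% bb)
    expect_false(mk$allele_length[["B"]] %in% ba)
    expect_true(mk$common_length %in% ba && mk$common_length %in% bb)
  }
  expect_gte(n_ok, 5L)
})

test_that("marker status across panels: fixed, polymorphic, species-specific", {
  set.seed(76)
  # build a locus where species A carries a TaqI site and B does not
  cat0 <- read_enzyme_catalog()
  taq <- as.list(cat0[cat0$name == "TaqI", ])
  left <- random_seq(150)
  right <- random_seq(150)
  core_a <- paste0(random_seq(60), "TCGA", random_seq(60))
  core_b <- paste0(substr(core_a, 1, 60), "TGGA", substr(core_a, 65, 124))
  ga <- plastome("A", paste0(left, core_a, right))
  gb <- plastome("B", paste0(left, core_b, right))
  fwd <- substr(left, 101, 120)
  rev_p <- revcomp(substr(right, 31, 50))
  prod_a <- in_silico_pcr(ga, fwd, rev_p)
  expect_equal(nrow(prod_a), 1L)
  mk <- structure(list(
    id = "CAPS_demo", target_pos = 150L + 63L,
    fwd = list(seq = fwd, tm = primer_tm(fwd), length = 20L),
    rev = list(seq = rev_p, tm = primer_tm(rev_p), length = 20L),
    ta = 50, enzyme = taq,
    product_length = c(A = prod_a$length, B = prod_a$length),
    fragments = list(A = digest(prod_a$seq, taq),
                     B = prod_a$length)), class = "caps_marker")
  panel_fixed <- list(A = replicate(5, ga, simplify = FALSE),
                      B = replicate(5, gb, simplify = FALSE))
  st <- predict_marker_status(mk, panel_fixed, run_config())
  expect_equal(unname(st$status), c("Fixed", "Fixed"))
  expect_true(st$species_specific)
  # 2 of 10 B genotypes carry the cut allele -> B polymorphic
  panel_poly <- list(A = replicate(5, ga, simplify = FALSE),
                     B = c(replicate(8, gb, simplify = FALSE),
                           replicate(2, ga, simplify = FALSE)))
  st2 <- predict_marker_status(mk, panel_poly, run_config())
  expect_equal(unname(st2$status), c("Fixed", "Polymorphic"))
  expect_false(st2$species_specific)
})

test_that("planted intraspecific variant inside the enzyme site flips status", {
  # scaled to a handful of seeds; the pattern is deterministic given truth
  w <- small_world()
  A <- w$species$A; B <- w$species$B
  cat0 <- read_enzyme_catalog()
  cfg <- run_config()
  tr <- w$truth
  fx <- tr[tr$allele_A != tr$allele_B & !is.na(tr$pos_A) & !is.na(tr$pos_B), ]
  mk <- NULL
  for (i in seq_len(nrow(fx))) {
    m2 <- design_caps(list(pos = fx$pos_A[i], pos_b = fx$pos_B[i]),
                      list(A = A, B = B), cat0, cfg)
    if (is_marker(m2)) { mk <- m2; snp_row <- i; break }
  }
  expect_false(is.null(mk))
  # give 3 of 8 A genotypes the whole B amplicon at the marker locus; their
  # band pattern then equals B's, which the marker by construction
  # distinguishes from A's
  pr_a <- in_silico_pcr(A, mk$fwd$seq, mk$rev$seq)
  pr_b <- in_silico_pcr(B, mk$fwd$seq, mk$rev$seq)
  expect_true(pr_a$start < pr_a$end)   # no origin wrap at this locus
  mutant <- A
  mutant$sequence <- paste0(substr(A$sequence, 1, pr_a$start - 1), pr_b$seq,
                            substr(A$sequence, pr_a$end + 1, A$length))
  mutant$length <- nchar(mutant$sequence)
  panel <- list(A = c(replicate(5, A, simplify = FALSE),
                      replicate(3, mutant, simplify = FALSE)),
                B = replicate(5, B, simplify = FALSE))
  st <- predict_marker_status(mk, panel, cfg)
  expect_equal(unname(st$status[["A"]]), "Polymorphic")
  expect_false(st$species_specific)
})
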