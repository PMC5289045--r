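# Orchestration: run configuration, the end-to-end synthetic or file-based
# workflow (simulate -> structure -> call -> effects -> design -> status ->
# diverge), TSV outputs shaped like the standard summary tables, a JSON run
# manifest, and a human-readable report.

#' Pipeline run configuration
#'
#' All tunable thresholds of the variant classifier and marker designer.
#'
#' @param min_depth minimum pool depth per site (default 20); below it a
#'   site is `low_coverage`.
#' @param fixed_freq within-pool major-allele frequency required to call a
#'   pool fixed (default 0.98, leaving ~2% room for sequencing error).
#' @param poly_freq minor-allele frequency that flags intraspecific
#'   polymorphism (default 0.03: one divergent genotype in a 24-genotype
#'   pool, ~4.2%, clears it; error at 0.2% does not).
#' @param poly_count minimum minor-allele read count (default 5).
#' @param indel_mask mask sites within this many bases of an alignment gap
#'   (default 5).
#' @param max_mismatches read-mapping mismatch budget (default 5 per read).
#' @param primer_len allowed primer lengths (default 18-30).
#' @param tm_range allowed primer Tm window in Celsius (default 50-65).
#' @param product_range CAPS product size range (default 200-800).
#' @param snp_margin minimum distance from the SNP to each CAPS primer's
#'   3' end (default 50).
#' @param band_resolution fragments within this many bases are
#'   indistinguishable on a gel (default 20).
#' @param enzyme_window flank on each side of a SNP scanned for
#'   site creation/destruction (default 25).
#' @param arms_inner_len ARMS inner-primer length (default 26).
#' @param arms_outer_near distance from SNP to the nearer ARMS outer
#'   primer's 3' end (default 120).
#' @param arms_min_diff minimum difference between the two allele-specific
#'   ARMS products (default 30).
#' @param arms_max_common maximum ARMS outer-outer product (default 800).
#' @param identity_window,identity_step sliding identity profile
#'   parameters, alignment columns (defaults 100/25).
#' @param seed RNG seed recorded in every output manifest.
#' @return list of class `run_config`.
#' @export
run_config <- function(min_depth = 20L, fixed_freq = 0.98, poly_freq = 0.03,
                       poly_count = 5L, indel_mask = 5L, max_mismatches = 5L,
                       primer_len = c(18L, 30L), tm_range = c(50, 65),
                       product_range = c(200L, 800L), snp_margin = 50L,
                       band_resolution = 20L, enzyme_window = 25L,
                       arms_inner_len = 26L, arms_outer_near = 120L,
                       arms_min_diff = 30L, arms_max_common = 800L,
                       identity_window = 100L, identity_step = 25L,
                       seed = 1L) {
  stopifnot(min_depth >= 1L, fixed_freq > 0.5, fixed_freq <= 1,
            poly_freq > 0, poly_freq < 0.5, poly_count >= 1L,
            primer_len[1] >= 15L, primer_len[2] >= primer_len[1],
            product_range[1] > 0L, product_range[2] > product_range[1],
            band_resolution >= 0L)
  structure(as.list(environment()), class = "run_config")
}

#' Read a run configuration from JSON
#'
#' Keys mirror the arguments of [run_config()] (unknown keys rejected);
#' a nested `synth` object, when present, overrides [synth_config()]
#' arguments and is carried in attribute `synth`.
#'
#' @param path JSON file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  synth <- raw$synth
  raw$synth <- NULL
  known <- names(formals(run_config))
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  cfg <- do.call(run_config, raw)
  if (!is.null(synth)) {
    bad <- setdiff(names(synth), names(formals(synth_config)))
    if (length(bad) > 0) {
      stop("unknown synth key(s): ", paste(bad, collapse = ", "), call. = FALSE)
    }
    attr(cfg, "synth") <- do.call(synth_config, synth)
  }
  cfg
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the end-to-end marker-discovery workflow on synthetic data
#'
#' Generates the three-species world, characterizes each genome's
#' structure, simulates pooled reads for the two focal species (A and B),
#' maps, tallies and classifies sites, annotates effects, designs CAPS and
#' ARMS markers for fixed SNPs, predicts marker status on the truth
#' genotype panels, ranks coding-region divergence, and writes the table
#' outputs plus a JSON manifest. Deterministic given the seed.
#'
#' @param cfg a [run_config()].
#' @param outdir output directory (created).
#' @param synth a [synth_config()]; defaults to attribute `synth` of `cfg`
#'   or the package defaults with `cfg$seed`.
#' @param max_markers design at most this many CAPS markers (default 5,
#'   matching the scale at which gel assays are practical).
#' @param verbose print stage progress.
#' @return invisible list: `manifest`, `records`, `markers`, `statuses`,
#'   `divergence`, `structure`, plus the synthetic `world`.
#' @export
run_pipeline <- function(cfg = run_config(), outdir, synth = NULL,
                         max_markers = 5L, verbose = TRUE) {
  t0 <- Sys.time()
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(synth)) synth <- attr(cfg, "synth")
  if (is.null(synth)) synth <- synth_config(seed = cfg$seed)
  timings <- c()
  stage <- function(name, expr) {
    st <- Sys.time()
    vmessage(verbose, "[%s] ...", name)
    r <- tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s (check inputs/config and rerun)",
                   name, conditionMessage(e)), call. = FALSE)
    })
    timings[name] <<- round(as.numeric(difftime(Sys.time(), st, units = "secs")), 2)
    r
  }

  world <- stage("simulate", {
    anc <- generate_ancestor(synth)
    sp <- derive_species(anc, synth)
    panels <- list()
    for (i in seq_along(sp$species)) {
      nm <- names(sp$species)[i]
      panels[[nm]] <- derive_genotype_panel(
        sp$species[[nm]], synth$genotypes[[i]], synth$intra_variants[[i]],
        seed = derive_seed(synth$seed, 10L + i),
        partition = if (nm == "A") anc$partition else NULL)
    }
    list(ancestor = anc, species = sp$species, truth = sp$truth,
         indels = sp$indels, panels = panels)
  })
  ref <- world$species$A
  ref$partition <- tryCatch(partition_quadripartite(ref), error = function(e) NULL)

  structure_tab <- stage("structure", {
    rows <- lapply(world$species, function(g) {
      part <- tryCatch(partition_quadripartite(g), error = function(e) NULL)
      data.frame(species = g$id, size = g$length,
                 ssc = if (is.null(part)) NA else part$lengths[["ssc"]],
                 ir = if (is.null(part)) NA else part$lengths[["ira"]],
                 lsc = if (is.null(part)) NA else part$lengths[["lsc"]],
                 gc = gc_content(g))
    })
    do.call(rbind, rows)
  })

  pools <- stage("pool_reads", {
    lapply(c(A = "A", B = "B"), function(nm) {
      simulate_pooled_reads(world$panels[[nm]]$genotypes, synth,
                            seed = derive_seed(synth$seed, 20L + match(nm, c("A", "B"))))
    })
  })

  counts <- stage("map_and_pileup", {
    lapply(c(A = "A", B = "B"), function(nm) {
      aln <- map_reads_exactish(pools[[nm]]$reads, ref,
                                max_mismatches = cfg$max_mismatches)
      vmessage(verbose, "  pool %s: %d reads mapped, %d dropped", nm, nrow(aln),
               attr(aln, "n_unmapped"))
      pc <- pileup(aln, ref, species = nm)
      if (!is.null(ref$partition)) pc <- fold_ir_counts(pc, ref$partition)
      pc
    })
  })

  pm <- stage("lift_over", {
    aln_ab <- global_align(world$species$A, world$species$B)
    build_position_map(aln_ab)
  })

  records <- stage("call", {
    rec <- classify_sites(counts$A, counts$B, ref, cfg)
    if (!is.null(ref$partition)) rec <- mirror_ir_sites(rec, ref$partition)
    mp <- map_position(pm, rec$pos)
    rec$pos_b <- mp$mapped
    vmessage(verbose, "  %d fixed_interspecific, %d intraspecific_polymorphic, %d ambiguous",
             sum(rec$class == "fixed_interspecific"),
             sum(rec$class == "intraspecific_polymorphic"),
             sum(rec$class == "ambiguous"))
    rec
  })

  records <- stage("effects", annotate_effects(records, ref))

  catalog <- read_enzyme_catalog()
  design <- stage("design", {
    fixed <- records[records$class == "fixed_interspecific", , drop = FALSE]
    markers <- list()
    for (i in seq_len(nrow(fixed))) {
      if (length(markers) >= max_markers) break
      mk <- design_caps(as.list(fixed[i, ]), world$species[c("A", "B")],
                        catalog, cfg)
      if (is_marker(mk)) markers[[mk$id]] <- mk
    }
    arms <- NULL
    for (i in seq_len(nrow(fixed))) {
      mk <- design_arms(as.list(fixed[i, ]), world$species[c("A", "B")], cfg)
      if (is_marker(mk)) { arms <- mk; break }
    }
    if (is_marker(arms)) markers[[arms$id]] <- arms
    markers
  })

  statuses <- stage("status", {
    panel <- list(A = world$panels$A$genotypes, B = world$panels$B$genotypes)
    lapply(design, function(mk) predict_marker_status(mk, panel, cfg))
  })

  divergence <- stage("diverge", {
    rank_coding_divergence(world$species$A, world$species$B, k = 15L)
  })

  # ---- outputs -----------------------------------------------------------
  files <- c(
    structure = write_tsv(structure_tab, file.path(outdir, "structure.tsv")),
    variants_tsv = write_tsv(
      as.data.frame(records)[, c("pos", "pos_b", "ref", "allele_a", "allele_b",
                                 "class", "depth_a", "depth_b", "annotation",
                                 "substitution", "coding_effect")],
      file.path(outdir, "variants.tsv")),
    variants_vcf = write_variants_vcf(records, ref,
                                      file.path(outdir, "variants.vcf")),
    markers = write_tsv(markers_table(design, statuses),
                        file.path(outdir, "markers.tsv")),
    divergence = write_tsv(as.data.frame(divergence),
                           file.path(outdir, "divergence.tsv")),
    truth = write_tsv(world$truth, file.path(outdir, "truth_sites.tsv"))
  )
  manifest <- list(
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), "")],
    synth = unclass(synth),
    timings = as.list(timings),
    outputs = lapply(stats::setNames(as.list(files), names(files)), function(f) {
      list(path = basename(f), md5 = unname(tools::md5sum(f)))
    }),
    pool_summaries = lapply(counts, function(x) x$summary),
    n_reads = lapply(pools, function(x) x$coverage_summary$n_reads),
    elapsed_s = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 2))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(manifest = manifest, records = records, markers = design,
                 statuses = statuses, divergence = divergence,
                 structure = structure_tab, world = world, outdir = outdir))
}

markers_table <- function(markers, statuses) {
  if (length(markers) == 0) {
    return(data.frame(id = character(), type = character(), target = integer(),
                      fwd = character(), rev = character(), length = character(),
                      ta = numeric(), enzyme = character(),
                      status_A = character(), status_B = character(),
                      species_specific = logical()))
  }
  rows <- lapply(names(markers), function(id) {
    mk <- markers[[id]]
    st <- statuses[[id]]
    if (inherits(mk, "caps_marker")) {
      data.frame(id = id, type = "CAPS", target = mk$target_pos,
                 fwd = mk$fwd$seq, rev = mk$rev$seq,
                 length = paste(mk$product_length, collapse = "/"),
                 ta = round(mk$ta, 1), enzyme = mk$enzyme$name,
                 status_A = if (is.null(st)) NA else st$status[["A"]],
                 status_B = if (is.null(st)) NA else st$status[["B"]],
                 species_specific = if (is.null(st)) NA else st$species_specific)
    } else {
      data.frame(id = id, type = "ARMS", target = mk$target_pos,
                 fwd = paste(mk$outer_f$seq, mk$inner_f$seq, sep = ";"),
                 rev = paste(mk$outer_r$seq, mk$inner_r$seq, sep = ";"),
                 length = paste0(paste(mk$allele_length, collapse = "/"), ";",
                                 mk$common_length),
                 ta = round(mk$ta, 1), enzyme = "",
                 status_A = if (is.null(st)) NA else st$status[["A"]],
                 status_B = if (is.null(st)) NA else st$status[["B"]],
                 species_specific = if (is.null(st)) NA else st$species_specific)
    }
  })
  do.call(rbind, rows)
}

#' Summarize a pipeline output directory
#'
#' Recounts everything from the raw TSV outputs (no cached numbers) and
#' renders a plain-text summary.
#'
#' @param outdir a directory written by [run_pipeline()].
#' @return character vector of report lines (also printed).
#' @export
pipeline_report <- function(outdir) {
  need <- file.path(outdir, c("structure.tsv", "variants.tsv", "markers.tsv",
                              "divergence.tsv", "manifest.json"))
  miss <- need[!file.exists(need)]
  if (length(miss) > 0) {
    stop("missing pipeline outputs: ", paste(basename(miss), collapse = ", "),
         call. = FALSE)
  }
  man <- jsonlite::read_json(file.path(outdir, "manifest.json"))
  st <- utils::read.delim(need[1])
  va <- utils::read.delim(need[2])
  mk <- utils::read.delim(need[3])
  dv <- utils::read.delim(need[4])
  lines <- c(
    sprintf("# plastmarker run (seed %s)", man$seed),
    "",
    "## Genome structure",
    sprintf("  %s: %s bp (LSC %s, SSC %s, IR %s), GC %.1f%%",
            st$species, format(st$size, big.mark = ","), st$lsc, st$ssc, st$ir,
            st$gc),
    "",
    "## Variant classes",
    if (nrow(va) == 0) "  no variant sites detected" else
      sprintf("  %s: %d", names(table(va$class)), as.integer(table(va$class))),
    "",
    "## Markers",
    if (nrow(mk) == 0) "  no markers designed" else
      sprintf("  %s (%s) at %d: products %s, status A=%s B=%s, species-specific=%s",
              mk$id, mk$type, mk$target, mk$length, mk$status_A, mk$status_B,
              mk$species_specific),
    "",
    "## Lowest-identity coding regions",
    if (nrow(dv) == 0) "  none computed" else
      sprintf("  %-16s %5d bp  %6.2f%%", utils::head(dv$region, 5),
              utils::head(dv$length_a, 5), utils::head(dv$identity, 5)))
  writeLines(lines, file.path(outdir, "report.txt"))
  cat(lines, sep = "\n")
  invisible(lines)
}
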