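# plastmarker

Species-diagnostic SNP discovery and gel-based marker design for
chloroplast genomes.

## The problem

Closely related plant species — e.g. a crop being domesticated alongside
weedy congeners it may hybridize with — often cannot be told apart
morphologically. The chloroplast genome (plastome) is a compact
(~150 kb), maternally inherited, slowly evolving molecule, which makes it
an ideal source of diagnostic markers: a **fixed interspecific SNP** is a
site where each species' whole population carries a different allele, and
such a SNP can be scored on an agarose gel either as a **CAPS** assay
(the SNP creates or destroys a restriction site inside a PCR product) or
as a **tetra-primer ARMS-PCR** assay (allele-specific inner primers yield
different-sized bands in one tube).

`plastmarker` is for researchers who have (or simulate) pooled
multi-genotype short-read sequencing of two or three related species and
want to go from reads to validated, gel-scorable species-specific
markers. It implements:

* plastome structure: inverted-repeat detection, quadripartite
  LSC/IRa/SSC/IRb partition, GC%, gene copy counts, gene-order inversion
  blocks (`find_inverted_repeat`, `partition_quadripartite`,
  `gc_content`, `count_gene_copies`, `detect_inversions`);
* pooled variant discovery: a built-in exact-ish read mapper (31-mer
  seeding + Hamming extension on the circular reference), per-site allele
  tallies, and classification of sites into fixed-interspecific /
  intraspecific-polymorphic / monomorphic / low-coverage / ambiguous,
  with inverted-repeat mirror collapsing (`map_reads_exactish`, `pileup`,
  `classify_sites`, `mirror_ir_sites`);
* effect annotation: transition/transversion, coding/intron/intergenic
  context, synonymous vs non-synonymous under translation table 11
  (`classify_substitution`, `locate_position`, `coding_effect`);
* marker design: in-silico PCR on circular templates, IUPAC-aware
  restriction digestion, discriminating-enzyme search, CAPS and
  tetra-primer ARMS design, and band-pattern prediction across genotype
  panels (`in_silico_pcr`, `digest`, `find_discriminating_enzymes`,
  `design_caps`, `design_arms`, `predict_marker_status`);
* divergence scanning: affine-gap global alignment (exact for short
  inputs, unique-anchor chaining at genome scale), per-coding-region
  identity ranking, sliding identity profiles, and cross-genome position
  lift-over (`global_align`, `rank_coding_divergence`,
  `sliding_identity`, `build_position_map`);
* a synthetic three-species world with known truth — quadripartite
  ancestor, species on the tree ((A,B),C) at ~99.6% pairwise identity,
  genotype panels of contrasting diversity (outcrosser ~218 segregating
  variants in 24 genotypes; apomicts ~31), pooled reads at configurable
  coverage and error (`synth_config`, `generate_ancestor`,
  `derive_species`, `derive_genotype_panel`, `simulate_pooled_reads`);
* an orchestrated end-to-end pipeline with TSV/VCF outputs, a JSON
  manifest and a plain-text report (`run_pipeline`, `pipeline_report`),
  plus a CLI (`inst/cli/plastmarker.R`).

## The classifier at its core

For two pools against one reference, with per-site depth `d` and major
allele frequency `p̂`:

* depth `d < 20` in either pool → `low_coverage`;
* `p̂ ≥ 0.98` in both pools with different major alleles →
  `fixed_interspecific` (the candidate species marker class);
* a minor allele at frequency `≥ 0.03` with `≥ 5` reads in either pool →
  `intraspecific_polymorphic` (one divergent genotype out of 24 is
  1/24 ≈ 4.2% and registers; 0.2% sequencing error does not);
* both pools fixed for the same allele → `monomorphic_shared`;
* otherwise `ambiguous`.

All thresholds are arguments of `run_config()`. See the methods vignette
(`vignettes/plastmarker-methods.Rmd`) for rationale, numerical
conventions, and the limits of what the synthetic world establishes.

## Worked example

```r
library(plastmarker)

# a scaled synthetic world (22 kb genome; pool sizes, variant counts,
# coverage and error at their defaults) and the full pipeline
synth <- synth_config(length = 22000, coverage = 300, seed = 1)
res <- run_pipeline(run_config(seed = 1), outdir = "demo_run",
                    synth = synth, verbose = FALSE)
res$structure
#>   species  size  ssc   ir   lsc   gc
#> A       A 22001 2684 3553 12211 37.5
#> B       B 22005 2692 3553 12207 37.5
#> C       C 21993 2678 3553 12209 37.5
table(res$records$class)
#>
#>                 ambiguous       fixed_interspecific
#>                        31                        55
#> intraspecific_polymorphic
#>                       312
res$markers[[1]]
#> <caps_marker> CAPS_84: TATTAGTTATCGTCAAATATGGGC/AAATTGTTGCCCTTATGACAAACA,
#>   Ta 45.6, MseI; products 257/257; fragments 80+74+65+38 vs 139+80+38
res$statuses[[1]]$species_specific
#> [1] TRUE
head(res$divergence, 3)
#>   region length_a length_b identity
#> 1   lg11       75       75    98.67
#> 2   rg03       75       75    98.67
#> 3   lg05     1111     1113    99.37
```

The structure table is the quadripartite summary (sizes in bases; LSC +
SSC + 2·IR = genome size; GC in percent). `records` are the classified
sites: the 55 `fixed_interspecific` sites are the marker candidates (the
world planted exactly those between A and B; see `res$world$truth`). Each
designed marker reports its primers, annealing temperature, enzyme and
per-species digestion fragments — here the SNP destroys one MseI site in
species B, so A's 257-base product cuts into 80+74+65+38 while B's keeps
a fused 139-base fragment, a pattern scorable on any agarose gel, and the
marker is Fixed within both truth panels (`species_specific TRUE`). The
divergence table ranks shared coding regions by pairwise identity,
ascending (the synthetic analogue of finding the fastest-evolving
chloroplast genes).

(Numbers above are what this exact call prints; your platform's RNG
stream is the same given the seed.)

## CLI

```sh
Rscript inst/cli/plastmarker.R simulate --outdir world --seed 7
Rscript inst/cli/plastmarker.R structure --genome world/A.fasta
Rscript inst/cli/plastmarker.R call --ref world/A.fasta \
    --sam-a a.sam --sam-b b.sam --out variants.vcf
Rscript inst/cli/plastmarker.R diverge --genome-a world/A.fasta \
    --gff-a world/A.gff3 --genome-b world/B.fasta --gff-b world/B.gff3
Rscript inst/cli/plastmarker.R run --outdir full_run --seed 7
Rscript inst/cli/plastmarker.R report --outdir full_run
```

Every subcommand exits non-zero with a one-line diagnostic on malformed
input.
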