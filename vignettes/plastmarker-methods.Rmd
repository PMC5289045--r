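---
title: "plastmarker: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{plastmarker: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem this package addresses

Closely related plant species — for example a crop and the weedy congeners
it can hybridize with — are often indistinguishable in the field and in
germplasm collections. Their chloroplast genomes (plastomes), being
maternally inherited, slowly evolving and present in high copy number, are
a natural source of diagnostic markers: a SNP at which each species' entire
population carries a different allele ("fixed interspecific") can be scored
cheaply on a gel, either as a CAPS assay (PCR product cut or not cut by a
restriction enzyme whose site the SNP creates or destroys) or as a
tetra-primer ARMS-PCR assay (allele-specific inner primers producing
different-sized bands).

`plastmarker` implements the complete desk-side workflow:

1. **Structural characterization** of a circular plastome: inverted-repeat
   (IR) detection, the quadripartite LSC/IRa/SSC/IRb partition, GC content,
   gene copy counts, and gene-order inversion blocks between species.
2. **Pooled variant discovery**: species pools (many genotypes, one
   library) are mapped to a reference plastome; per-site allele tallies are
   classified as fixed-interspecific, intraspecific-polymorphic,
   monomorphic, low-coverage or ambiguous.
3. **Effect annotation**: transition/transversion, genomic context
   (coding / intron / intergenic with flanking genes), and
   synonymous/non-synonymous calls under translation table 11.
4. **Marker design**: in-silico PCR, IUPAC-aware restriction digestion,
   discriminating-enzyme search, CAPS and tetra-primer ARMS-PCR design,
   and band-pattern prediction across genotype panels to assign Fixed /
   Polymorphic / species-specific status.
5. **Divergence scanning**: per-coding-region identity ranking and
   sliding-window identity profiles between plastomes, plus the position
   lift-over used to express a SNP in each genome's own coordinates.
6. A **synthetic-data generator** that produces a three-species world with
   known truth, so that every stage is testable without any downloads.

## The classification model

Pooled sequencing replaces per-genotype genotypes with a per-site allele
frequency sample. For pools A and B against one reference, each site is
assigned exactly one class, in this order:

* `low_coverage` — depth < `min_depth` (default 20) in either pool. Below
  this, frequency estimates are too noisy to call anything.
* `fixed_interspecific` — the major allele reaches `fixed_freq` (default
  0.98) in *both* pools and the majors differ. The 2% slack absorbs
  sequencing error (at the 0.2–1% per-base rates typical of short reads)
  without admitting real polymorphism.
* `intraspecific_polymorphic` — a minor allele reaches `poly_freq`
  (default 0.03) with at least `poly_count` (default 5) supporting reads
  in either pool. The defaults are chosen so that a single divergent
  genotype in a 24-genotype pool (frequency 1/24 ≈ 4.2%) registers, while
  base-call error (≈0.2%) does not.
* `monomorphic_shared` — both pools fixed for the same allele.
* `ambiguous` — everything else, plus any site within `indel_mask`
  (default 5) bases of an alignment gap (alignment ambiguity guard).

These thresholds are configurable (`run_config()`); the defaults are the
package's documented operating point and all tests run at it.

### Inverted-repeat handling

The two IR copies of a plastid molecule are identical, so reads from the
IR map equally well to both copies. The built-in mapper assigns such ties
to the lexicographically smaller coordinate and flags them; reads whose
sequencing errors happen to break the tie land on either copy. After
classification, `mirror_ir_sites()` pairs every IR-resident site with its
mirror coordinate: concordant pairs collapse into one canonical record at
the IRa coordinate, discordant pairs are demoted to `ambiguous`, and a
record whose mirror carries no information (e.g. the other copy got no
uniquely assigned reads) is re-coordinated to IRa and kept, labelled
`mirror_absent`.

## Marker design choices

* **Discriminating enzymes** are defined by digest-and-compare semantics:
  an enzyme discriminates a SNP iff digestion of the two species' windows
  (default ±25 bases) yields different fragment *multisets*. A shifted cut
  that yields the same fragment lengths is not gel-scorable and is
  correctly excluded. This definition is verified against an independent
  regex-expansion digestion oracle in the test suite.
* **CAPS layout**: primers are placed so the SNP is at least `snp_margin`
  (default 50) bases from each primer's 3′ end, product in 200–800 bases,
  primer Tm inside 50–65 °C. The first enzyme in catalog (alphabetical)
  order that distinguishes the actual products at gel resolution is
  chosen; all candidates can be recovered via
  `find_discriminating_enzymes()`.
* **Tm formula**: Wallace rule `2(A+T) + 4(G+C)` for ≤13-mers, else
  `64.9 + 41(GC − 16.4)/length`. The annealing temperature metadata
  defaults to `min(Tm) − 5`.
* **ARMS**: inner primers end exactly on the SNP on opposite strands, with
  one deliberate destabilizing mismatch at the second base from the 3′
  terminus; the substituted base is the fixed transversion partner of the
  template base (A↔C, G↔T), a deterministic choice within the latitude the
  method leaves open. Outer primers are placed asymmetrically so the two
  allele-specific products differ by ≥30 bases. Product lengths are
  measured 5′-end to 5′-end inclusive.
* **Band patterns** are compared under a gel-resolution merge: fragments
  within `band_resolution` (default 20) bases are indistinguishable. A
  species is *Fixed* for a marker iff all its genotypes' patterns agree
  under this merge; a marker is *species-specific* iff every species is
  Fixed and the patterns differ pairwise between species.

## The synthetic world

The generator emulates the statistical structure of pooled plastome
sequencing of one outcrossing species and two clonal apomicts:

* A ~151 kb circular ancestor laid out LSC–IRa–SSC–IRb (fractions
  0.555/0.122/0.1615 of the genome), IRb the exact reverse complement of
  IRa, genes placed in all four regions, and a three-copy tRNA gene
  (`trnF-GAA`) planted as a copy-number feature.
* Three species derived on the tree ((A,B),C). Terminal branches carry
  0.00175 substitutions/site and the internal branch 0.0005, so that
  every pairwise comparison sits at ≈99.6% identity while the (A,B) pair
  is slightly closer — the constraint the emulated system states. (A
  naive "equal branch lengths" choice of 0.002 per branch would push the
  cross-pairs to 99.4%, outside the stated band, so it was not used.)
  The transition:transversion ratio defaults to 1:1, matching the
  observed 8:8 split of the published 16-SNP panel. IR substitutions are
  planted symmetrically in both copies (and the substitution budget counts
  them twice); indels (rate 0.0002/site, geometric lengths of mean 3) are
  excluded from the IR so mirror bookkeeping stays exact.
* Genotype panels: 24/24/12 genotypes with 218/31/31 segregating SNPs
  (outcrosser high, apomicts low), each variant carried by a random
  nonempty proper subset of genotypes.
* Pooled reads: 150-base single-end reads uniform over genotypes, circular
  positions and strands; i.i.d. substitution errors at 0.002/base;
  constant quality `I` (base qualities are never consumed — read QC is
  upstream of this pipeline's scope).

What a green synthetic test does **not** establish: the generator has no
quality-dependent or indel-type sequencing errors, no GC-coverage bias,
no paired-end structure, and no amplicon-boundary coverage artifacts of
long-range-PCR libraries; divergence is uniform rather than locally
clustered (real plastomes concentrate variation in intergenic hotspots).
Conclusions about threshold behavior transfer to real data only to the
extent these simplifications are immaterial at ~10²–10³× pool coverage.

## Numerical choices

* **Coordinates** are 1-based inclusive everywhere; a circular interval
  that wraps the origin has `end < start`.
* **Percent identity** counts gap columns in the denominator
  (`100·matches/columns`), rounded half-up to 2 decimals; GC% is rounded
  half-up to 1 decimal. Identity is 100 iff the sequences are identical.
* **Global alignment** scores +1/−1 with affine gaps (open −5, extend −1).
  Inputs ≤4 kb are solved by exact dynamic programming; longer inputs are
  aligned by chaining unique shared 31-mers (longest colinear chain) and
  solving the short inter-anchor segments exactly. At the ≥99% identities
  this package compares, anchors occur every few hundred bases and the
  stitched alignment is in practice optimal; the test suite checks score
  equality against an exhaustive Gotoh oracle on short inputs and
  consistency of the two routes at genome scale.
* **IR detection** is exact-match (the two copies of one molecule are
  identical): 31-mer seeds shared between the sequence and its reverse
  complement are extended along anti-diagonals; the longest disjoint pair
  wins. The LSC/SSC labels go to the longer/shorter inter-IR gap; an
  exact tie is broken by declaring the gap that follows the
  smaller-start IR copy the LSC (arbitrary, documented, deterministic).
* **Genetic code**: translation table 11 (bacterial/plastid). Pseudogene
  and RNA-gene hits are reported as coding-context with effect
  `not_applicable` and a `pseudo` flag, rather than guessing at their
  translatability.
* **Config format**: JSON (`read_run_config()`), because the R ecosystem
  ships `jsonlite` everywhere this package runs; the schema mirrors
  `run_config()` exactly and rejects unknown keys.
* **Random seeds**: one master seed; every sub-generator derives its own
  seed through a fixed integer map, so any stage can be reproduced in
  isolation.

## Known limitations

* The accession-based checks (deposited genome records of the emulated
  study system) require those ~151 kb records to be supplied locally
  (`PLASTMARKER_ACCESSION_DIR`); they cannot be bundled and are reported
  as failing, not skipped, when absent.
* The built-in mapper is Hamming-only (no gapped alignment): reads
  spanning an interspecific indel are dropped, which depresses coverage
  within ~a read length of indels. Sites near indels are excluded from
  the parameter-recovery guarantees for the same reason. Real-data users
  can supply SAM from any external aligner; the classification contract
  is identical.
* `detect_inversions()` reports a minimal greedy decomposition into
  reversal blocks; when two decompositions are equally parsimonious
  (mirror-image nestings), the one it returns is deterministic but not
  necessarily the one history took.
* Whole-genome alignment assumes collinearity; regions rearranged by
  large inversions should be oriented by gene anchors before alignment.
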