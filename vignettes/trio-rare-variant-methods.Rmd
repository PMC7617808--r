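---
title: "Methods: trio exome analysis of rare and de novo variants in childhood-onset lupus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trio exome analysis of rare and de novo variants in childhood-onset lupus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The analysis problem

Childhood-onset systemic lupus erythematosus (cSLE) is more severe and
more heritable than adult disease, and sporadic severe cases are often
explained by rare coding variants of large effect. A trio design —
sequencing the proband with both parents — makes the mode of
inheritance observable per variant: paternal, maternal, biallelic, or
de novo. `lupustrio` implements the downstream analysis such a study
runs after variant calling: relatedness checks, inheritance
classification with mosaicism flagging, rare-variant filtering against
population allele frequencies, gene-panel burden statistics against
control cohorts, and candidate-gene prioritization by pathway
enrichment and B-cell expression. Everything upstream of a called,
annotated VCF (alignment, variant calling, consequence/score
annotation) is out of scope and consumed as input.

# Relatedness verification

De novo calls are only as believable as the pedigree. Before
classification, every declared parent–offspring pair is checked with
the within-pair KING-robust estimator over common biallelic sites:

$$\hat\varphi = \frac{N_{\text{het,het}} - 2N_{AA,aa}}{N_{\text{het}}^{(1)} + N_{\text{het}}^{(2)}}$$

where $N_{\text{het,het}}$ counts sites heterozygous in both samples,
$N_{AA,aa}$ opposite homozygotes (IBS0), and $N_{\text{het}}^{(i)}$
heterozygous sites per sample. The estimator does not require allele
frequencies, which makes it robust to reference-panel
misspecification. Expected values: parent–offspring ≈ 0.25 with IBS0
≈ 0 (an opposite homozygote in a true parent–offspring pair requires a
genotyping error), duplicates/MZ twins 0.5, unrelated ≈ 0. A family
passes when both pairs fall inside `kinship_range` (default
[0.15, 0.40]) with IBS0 ≤ 0.02; failing families are excluded with a
log entry. At least 200 informative sites are required; fewer is an
error instructing the user to add sites.

# Inheritance classification

Per (variant, proband), with genotypes `GT`, allele depths `AD`, depth
`DP`, genotype quality `GQ`:

* proband het, exactly one parent carries the allele → `paternal` /
  `maternal`;
* both parents carry it → `biparental_ambiguous` (phase is unknowable
  without read-backed phasing, which is out of scope);
* proband hom-alt with both parents carrying → `homozygous_recessive`;
* both parents hom-ref → candidate Mendelian violation, gated below;
* missing genotypes or failed gates → `unresolved`. Degraded evidence
  only ever downgrades: a missing parent never produces a de novo call.

**De novo gates.** Proband `DP ≥ 10`, `GQ ≥ 20`, `AD_alt ≥ 5`; each
parent `DP ≥ 10` with `AD_alt ≤ 1`. The `AD_alt ≥ 5` gate is the
read-support reading of a minimum minor-allele-count filter; the
alternative cohort-allele-count reading is available in the filter
cascade as `mac_mode = "cohort"` (under that reading a cohort-private
variant can never reach count 5, which empties rare-variant sets — one
reason the read-support reading is the default). The parental
tolerance of one alternate read accommodates stray sequencing error
without treating a low-level carrier parent as hom-ref; it is
configurable through `default_gates()`.

**VAF banding.** A germline heterozygote draws half its reads from the
alternate allele, so VAF concentrates near 0.5; a post-zygotic
(somatic or early-embryonic mosaic) variant is present in only a
fraction of cells and shows systematically lower VAF. Calls passing
the gates are banded on observed VAF: ≥ 0.30 → `de_novo_germline`;
[0.10, 0.30) → `de_novo_mosaic_suspect`; below 0.10 the call is not
believed (`unresolved`). The band is a deliberately round, configurable
boundary containing the descriptive 10–26% range reported for
somatic-mosaicism cases; pushing the germline boundary to exactly 0.26
would split hairs the read-sampling noise cannot support.

**Hemizygous male X.** A male proband has one X, inherited from his
mother; calls on X in males are compared against the mother alone and
flagged `hemizygous` in the notes. The father's X genotype never
enters the logic.

**Outlier probands.** A proband whose de novo count exceeds
Q3 + 3·IQR of the cohort distribution (quartiles type 7; ties broken
toward *not* flagging, i.e. strict inequality) is flagged as a
candidate somatic-mosaicism case; the per-proband fraction of de novo
calls with VAF < 0.30 is reported alongside. Cohorts under 5 probands
skip flagging with a warning. Flagged probands are excluded from the
enrichment query and trigger a sensitivity re-run of the de novo rate
comparison.

**Compound heterozygotes** are enumerated per gene as pairs of one
paternal and one maternal rare variant; `biparental_ambiguous`
variants are excluded from pairing.

# The filter cascade

Stage order (configurable, default as listed), applied to one row per
(proband, alternate allele):

1. `decompose` — multi-allelic sites are split upstream by the VCF
   reader into one biallelic record per alternate allele (genotype
   indices remapped, per-allele AD extracted); the stage asserts this.
2. `consequence` — keep missense, nonsense, frameshift/inframe coding
   indels, and canonical splice variants (±1/±2 at donor and acceptor
   sites; a donor +3 variant is `other` and excluded). Synonymous and
   unknown annotations are excluded; unknown strings warn.
3. `maf` — exclude when allele frequency is **strictly greater than**
   0.005 in *either* the global or the East-Asian reference panel
   (frequency exactly 0.005 passes: a literal reading of
   "greater than ... excluded"). An absent frequency is a distinct
   state that passes — a variant never seen by the reference panels is
   by definition rare, and coercing absent to 0 would be wrong in the
   other direction for the common decoys.
4. `qc` — read-support gates on the carrier genotype (as above).
5. `panel` — tag (not filter) membership in the monogenic / GWAS /
   eQTL panels; tags are not exclusive.

Per-stage in/out counts are logged. The stages are row-filters, so the
cascade is idempotent and the `consequence`/`maf` stages commute;
these are enforced as property tests.

**Damage consensus.** PolyPhen-2 (`probably_damaging` or
`possibly_damaging`), SIFT (`deleterious`) and CADD (phred ≥ 20, the
standard convention for the top ~1% of substitutions) each cast one
vote. `likely_damaging` requires ≥ 2 votes among available tools and
≥ 2 tools available; fewer than two tools is `indeterminate`. The
2-of-available-3 rule is one defensible reading of a three-tool joint
criterion and is exposed in the function arguments
(`min_votes`, `cadd_cutoff`); reproduction of any particular damaging
fraction is sensitive to this rule.

# Burden statistics

Counts are distinct qualifying variants per proband per panel; medians
use the midpoint-of-central-pair convention (so half-integer medians
like 4.5 are representable). The case–control comparison bins
per-individual counts at 0,1,2,3,4,≥5 and applies Pearson's chi-square
without continuity correction over the groups×bins table; empty bins
are dropped, a single-bin table is an error, and any expected cell
below 5 warns. The binned construction is one defensible reading of a
count-distribution comparison; a carrier/non-carrier 2×2 mode is the
config-exposed alternative (`mode = "carrier"`), and both are
implemented because the original figure legend does not disambiguate.

Per-gene carrier comparison: a carrier has ≥ 1 qualifying variant in
the gene; genes with case carrier prevalence ≥ 2× the control
prevalence are selected, with an infinite ratio (case carriers,
control zero) explicitly retained and 0/0 excluded as undefined. The
de novo rate comparison reports means, their ratio, and a two-sided
Mann–Whitney test on per-sample counts, then repeats itself without
the flagged outlier probands. The qPCR utility computes
$2^{-\Delta\Delta C_t}$ with the reference gene normalizing input.

# Prioritization

Over-representation of a query gene list against a GMT collection uses
the hypergeometric upper tail $p = P(X \ge k)$,
$X \sim \mathrm{Hypergeom}(N, K, n)$, BH-corrected across sets; sets
with fewer than 3 background members are skipped, and the query is
restricted to the background (the test is conditional on the
universe). Top pathways are the 20 most significant among those with
$-\log_{10} p > 4$, ties broken lexicographically by term id. The
similarity-based term clustering of web enrichment tools is **not**
reproduced — each term is independent — so "clusters" here are simply
the selected sets, and a gene's cluster-membership count is the number
of selected sets containing it.

The expression criterion flags genes whose expression singles out
age-associated B cells or plasma cells. "Highly expressed" is not a
defined quantity in the field, so two modes are offered: `argmax`
(default; the gene's maximum across cell types is achieved in a target
cell type, strictly — ties and constant rows fail) and `zscore`
(across-cell-type z ≥ 1.5 in a target column; constant rows have no
z-score and fail). Candidates are de novo genes satisfying both the
top-pathway and the expression criterion, ranked by cluster-membership
count; Venn counts (pathway-only / expression-only / both) are
reported.

The enrichment background defaults to all genes in the annotation
table but should be the annotation source's full universe when known
(`ora_background`): a background restricted to variant-carrying genes
makes the query a dense fraction of the universe and dilutes
enrichment — visible at simulation scale, where the cohort's ~600
variant-carrying genes must be padded toward exome size for any set to
clear the selection floor.

# The synthetic cohort generator

`simulate_cohort()` emulates the study conditions the analysis assumes;
its defaults are fixed once and shared by the tests and the acceptance
script:

* **50 trios**, proband sex drawn at the cohort's reported 78.4%
  female fraction.
* A **backbone of 1500 common biallelic sites** with allele
  frequencies ~ U(0.05, 0.5); parents Hardy–Weinberg, children by
  Mendelian gene-dropping. These sites power the kinship checks and
  exercise the MAF filter's rejection path.
* **Inherited rare implants**: Poisson(1.0) per proband in the
  monogenic panel and Poisson(5.0) in the GWAS panel — total Poisson(6),
  per-proband median 6, split roughly as the published 45:224 variant
  totals — plus a compound-heterozygous monogenic pair in 5% of
  probands. Qualifying implants carry protein-altering consequences
  (92% missense, matching the "over 90%" reported split) and
  frequencies below the MAF threshold, 15% of them novel (absent
  frequency) to exercise the absent-AF path.
* **De novo implants**: Poisson(1.2) per proband (count median 1 with
  a realistic upper tail), 10% drawn as mosaics with true VAF ~
  U(0.10, 0.26); genes drawn mostly from a dedicated pool, 4% from the
  SLE panels. The **last two families** carry an extra Poisson(30)
  somatic-like mosaic load, mirroring the two reported outlier
  probands (67 extra calls between them).
* **Decoys** that must fall out of the cascade: Poisson(2) common
  inherited variants (AF 0.02–0.2) and Poisson(1) rare synonymous
  variants per proband.
* **Reads**: depth ~ NegBin(mean 40, size 20) per (site, sample);
  alternate reads Binomial(DP, VAF) in the default `binomial` model or
  `round(DP · VAF)` in the `expected` (noiseless) model; error rate 0
  by default. GQ is 99 at DP ≥ 15, else 3·DP.
* **Controls without case enrichment**: 105 individuals with rare
  counts ~ Poisson(3) (the 1KGP-like comparison cohort) and 2049 with
  de novo counts ~ Poisson(0.79) (a population WES database yields
  1619 calls in 2049 individuals, hence the mean).
* **Reproducibility**: one RNG stream per family derived from
  (seed, family index), so enlarging the cohort leaves existing
  families bit-identical; all outputs are deterministic given the seed.

Every implant is recorded in a truth table (class, parental side,
mosaic flag, true VAF, panel). `write_cohort()` emits one VCF 4.2 per
trio plus PED, annotation TSV, panel TSVs and the truth table;
`read_cohort_dir()` reassembles the cohort through the same loaders
real data would use.

**What the generator does not emulate** — and hence what passing tests
do not show about real data: linkage disequilibrium and population
structure; genotyping error and parental low-level mosaicism (parents
are exactly their generated genotypes; `error_rate` exists but
defaults to 0); sequencing-platform batch effects between cases and
controls; annotation error (gene assignment and consequence are
correct by construction); and allele-frequency estimation error in the
reference panels. Specificity and sensitivity measured here are
upper bounds for real cohorts.

**Recovery definitions.** Germline sensitivity is the fraction of
implanted germline (true VAF 0.5) de novo variants called
`de_novo_germline`; at mean depth 40 the read-support gates are nearly
always satisfied, so sensitivity sits at 1 in the noiseless limit.
False calls are classifier de novo calls absent from the truth table;
with exact parental genotypes there are none. The mosaic check is
conditioned on implants whose *observed* reads pass the gates with an
observed VAF at or above the band floor: a mosaic with true VAF 0.10
has expected alternate depth 4 at DP 40 and so cannot systematically
clear the `AD_alt ≥ 5` gate, and integer read counts can place an
observed VAF just below the floor — classification is necessarily a
function of observed allele fractions. Under that conditioning the
band construction makes assignment exact: a gate-passing observed VAF
cannot exceed `v·(1 + 1/9) < 0.30` for in-band `v`, so every such
implant is labelled `de_novo_mosaic_suspect`.

**Gene panels.** The three screening panels ship as synthetic
stand-ins (`inst/extdata/panel_*_synthetic.tsv`) at the published
sizes (49 / 213 / 64): anchor symbols named in the cohort's report
(ACP5, C3, C4A, C4B, DNASE1, IFIH1, NRAS, RNASEH2B, RNASEH2C, SAMHD1,
TYK2, BLK, …) padded with clearly artificial `SLEGnnn` placeholders,
because the original supplementary lists are not redistributed.

# Problem sizes and runtime choices

The test suite runs the full pipeline at two scales: an 8-trio /
400-site cohort for unit-level checks and the 50-trio / 1500-site
study cohort (noiseless mode) for the recovery and burden checks;
count-level replicates (medians, type-I error, Monte-Carlo oracles)
use 200–1000 repetitions. These sizes were chosen so the whole suite
completes in well under a minute of simulation time while keeping
binomial standard errors comfortably inside the asserted bands; the
acceptance script re-simulates the 50-trio cohort, writes it to disk
and reads it back, which dominates its runtime.

# Known limitations

* No read-backed phasing: cis/trans resolution relies entirely on
  parental origin, so two variants inherited from the same parent are
  conservatively not paired even if trans on that parent's haplotypes.
* Parental gonadal mosaicism is not modelled beyond the descriptive
  VAF flag; a gonadal-mosaic parent would produce an apparent de novo
  call with germline-like VAF.
* Gene symbols match exactly after normalization; alias resolution is
  an annotation-time concern.
* The chi-square burden comparison inherits the usual asymptotic
  caveats at sparse bins (warned, not corrected).
* Enrichment treats gene sets as independent terms; redundancy between
  overlapping sets inflates the number of "pathways" a gene appears
  in, which is why cluster counts are reported, not tested.
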