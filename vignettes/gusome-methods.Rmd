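---
title: "Methods: structure-guided GUSome profiling and rate association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structure-guided GUSome profiling and rate association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Gut bacterial beta-glucuronidases (GUS enzymes) cleave glucuronide
conjugates and can thereby re-activate drugs that the liver has
inactivated. For mycophenolate (MMF), the hepatic metabolite MPAG is
hydrolyzed back to the active immunosuppressant MPA in the intestine, and
individual differences in the gut "GUSome" — the complement of GUS genes
and proteins an individual carries — may drive individual differences in
drug exposure and toxicity.

`gusome` implements the desk half of that study design as a tested
pipeline: identify GUS genes in a metagenomic protein catalog by a
structure-guided screen, quantify them with length-bias-corrected read
abundances, quantify expressed GUS proteins from activity-based-probe
metaproteomic peptide tables, fit MPAG-disappearance rates from lysate
time courses, and test which structural class of GUS tracks the rate.

# The discovery screen

Every catalog protein is aligned pairwise to a set of representative GUS
enzymes (Smith–Waterman, BLOSUM62, affine gaps 11/1 — the conventions of
protein–protein BLAST). A candidate is accepted iff

1. its identity to at least one representative strictly exceeds 25%, and
2. all seven conserved catalytic residues are present — i.e. each
   annotated catalytic position of the best-identity representative
   aligns, gap-free, to the identical letter in the candidate.

Identity is `identical columns / aligned columns` by default; a
`query`-length denominator is available because the convention is not
universal. Two deliberate strictness choices: the 25% threshold is a
strict inequality, and the residue match is exact (a chemically
conservative Glu→Asp substitution does not count).

**Coverage floor.** Local alignment of two *unrelated* ~400-residue
proteins typically still yields a short spurious alignment of 15–80
columns whose column identity is 0.2–0.5. A raw identity threshold would
therefore be meaningless for non-homologs — a database search simply
reports no hit in that situation. The screen reproduces that behaviour
explicitly: an alignment only counts as a hit when it covers at least
`min_coverage` (default 0.30) of the shorter sequence; otherwise the
screening identity is 0 and the candidate is rejected as `below_identity`.
The floor is far below the coverage of genuine homologs (even 35%-identity
homologs align at >90% coverage) and far above that of spurious hits
(≤ ~0.25 in simulation).

**Residue-check reference.** By default the heptad is checked against the
best-identity representative; `residue_mode = "any"` accepts the heptad
via any above-threshold representative instead. The best-hit rule is the
default because it is the most reproducible reading; the any mode exists
because near the identity floor the best hit can belong to a different
subfamily whose alignment misregisters the catalytic positions.

**Deterministic alignment.** Ties are broken identically on every run:
the traceback starts at the highest-scoring cell with the smallest
(query index, target index), and prefers diagonal over up (gap in target)
over left (gap in query). This matters because screening decisions near
the threshold can depend on which co-optimal alignment is reported.

# Redundancy clustering

Accepted sequences are collapsed at 90% identity by a greedy incremental
scheme in the style of CD-HIT: sort by length descending (ties by id),
seed clusters in order, join the first cluster whose representative is
matched at ≥ 90%. Representatives are therefore the longest members, the
partition is invariant to input order, and raising the threshold can only
increase the cluster count. The in-package implementation (rather than an
external binary) keeps the partition reproducible and testable.

# Structural class assignment

Classes (Loop 1, mini-Loop 1, Loop 2, mini-Loop 2, mini-Loop 1,2,
No Loop, FMN-binding, No Coverage) are assigned from active-site-adjacent
loop architecture:

1. **FMN test.** If the identity over an FMN representative's annotated
   C-terminal segment (unaligned window positions counting as
   mismatches) reaches `fmn_identity` (default 0.50), the class is FMN.
   The FMN-binding domain is an accessory domain whose presence, not
   fine conservation, defines the class.
2. **Loop projection.** Otherwise the sequence is projected onto the
   highest-identity representative's two loop windows. The measured loop
   length is the number of query residues strictly between the nearest
   aligned positions flanking the window — anchoring on the conserved
   flanks makes the measure robust to alignments that gap through a
   divergent loop interior. If a representative's windows are not
   measurable the next representative by identity is tried; if none is,
   the nearest representative's own class is used, flagged `by_nearest`.
3. **Thresholds.** Loop length ≥ 12 → full loop; in [5, 12) → mini-loop;
   both loops ≥ mini → mL1_2; both below → NL. The cut-offs are
   package defaults chosen so that the bundled representatives (loop
   segments of 16–18, 8, and ≤2 residues) are unambiguous, and they are
   config-exposed because published loop-class parameterizations are
   reported in residue-count terms of the same order.

Taxonomy is the label of the highest-identity reference, reported with
that identity, or `unassigned` below a 0.40 floor.

# The bundled representative set is synthetic

The screen needs a representative set with annotated catalytic heptads,
loop windows and FMN segments. The package ships a **synthetic** set of
17 such records (`inst/extdata/synthetic_representatives.*`): a common
core scaffold diversified to 38–50% mutual identity, class-specific loop
segment lengths, an invariant N/K/Y/E/E/N/H heptad, and a conserved
C-terminal FMN domain on the FMN members. It has the same annotation
structure as a curated crystal-structure reference set and is intended
for simulation and validation; screening a real catalog requires
supplying a real reference set in the same two-file format.

# Abundance normalization

Two formulas, applied exactly as printed in the field:

$$\mathrm{RelativeCount} = \log_{10}\!\left[
  \frac{\mathrm{GeneReadCount}}{\mathrm{TotalAssignedReadsInSample}}
  \times \frac{\mathrm{TotalAssignedReadsAcrossAllSamples}}
              {\mathrm{NumberOfSamples}} + 1\right]$$

$$\mathrm{NormalizedGeneAbundance} = \mathrm{RelativeCount} +
  \mathrm{Slope} \times (\mathrm{AverageGeneLength} - \mathrm{GeneLength})$$

The slope is the OLS slope of relative count on gene length, pooled over
all (gene, sample) pairs — one cohort slope, matching the singular
"slope" in the second formula (a per-sample mode exists). When the
correction uses the fitted slope and the mean length, regressing the
normalized abundances back on length returns slope 0 to machine
precision; this algebraic identity is asserted at 1e-10 in the tests.
Gene length is in residues here; the unit is recorded in the output
header and is configurable since counts tables may carry nucleotide
lengths. Class-level gene abundance is the per-sample sum of member
genes' normalized abundances.

# Diversity statistics

Shannon index (log base 2 by default, the convention of the common
amplicon toolkits; the base is a parameter), Bray–Curtis dissimilarity
(`sum|x−y| / sum(x+y)`), classical PCoA (double-centered Gram matrix
eigendecomposition; negative eigenvalues reported but never used for
coordinates; each axis's first non-zero loading made positive so runs are
sign-stable), and a one-factor PERMANOVA. A distance-based ordination
with no constraints reduces to exactly this PCoA, which is why the
unconstrained analysis is implemented directly. The PERMANOVA p-value
uses the add-one convention `p = (1 + #{F* ≥ F}) / (1 + n_perm)` with a
seeded permutation stream, so p is never 0 and never smaller than
`1/(n_perm+1)`; note that permutations reproducing the observed grouping
tie with the observed F and are counted, so even perfectly separated
groups need not attain the floor.

# Proteomics quantification

Peptide rows (sample, peptide, intensity) are assumed already
FDR-filtered by the upstream search engine. Mapping is exact substring
matching under I/L equivalence (isobaric residues; disablable). A peptide
is *unique* iff it matches exactly one cluster — uniqueness at the
cluster level mirrors quantification against a non-redundant database.
Protein (cluster) intensity is the per-sample sum of unique-peptide
intensities, log2-transformed after summation; classes likewise sum raw
member intensities then log2 (never a mean of logs). An undetected
protein is an absent row, not a zero: group tests run on detected values
with absent classes missing, and a sensitivity mode substitutes a floor.
Sequence coverage is the union of matched peptide intervals (all
occurrences) over the protein length, verified against a per-residue
bitmap oracle.

Group comparisons: Welch's t-test (via the standard library routine, with
explicit degenerate contracts — two zero-variance groups give p = 1 when
means agree and p = 0, flagged, when they differ) and the Wilcoxon
matched-pairs signed-rank test. The signed-rank p is exact by full
enumeration of the 2^n sign assignments of the observed ranks for n ≤ 15
(valid under ties), with the tie-corrected normal approximation beyond.

# Rate fitting and association

The lysate assay tracks MPAG disappearance: per replicate, concentration
is regressed on time and the reactivation rate is the magnitude of the
negative slope; a rising-MPAG fit is flagged and reported as rate 0
rather than silently negated. Replicate rates are averaged (SEM =
sd/sqrt(k)) and log2-transformed. The default design mirrors the assay:
five endpoints including t = 0, three biological replicates, 400 µM
(400,000 nM) starting MPAG.

Purified-enzyme specific activity uses an initial-rate rule for the
under-specified "custom linear regression": among contiguous windows of
at least max(3, 25% of points), the highest-r² window wins (earliest on
ties, biasing to the early linear phase), and its slope magnitude is
divided by enzyme concentration to give 1/s. A window r² floor (default
0.8) turns saturating or erratic curves into a "no linear phase" error.

Associations are Wald slope tests: OLS slope over its standard error,
two-sided p from the standard normal by default (the literal reading of
"Wald test") with a t(n−2) mode. At cohort-scale n (≈9) the normal
reference is anticonservative — its true type-I rate at the nominal 0.05
level is about 0.09 — so the t mode is used wherever calibration
matters; results record which reference ran. One test per predictor
(total GUS intensity, each class intensity, metagenomic class
abundances, optional taxa), no multiplicity adjustment by default
(Benjamini–Hochberg by flag), predictors with fewer than 3 shared
samples skipped with a warning.

# The synthetic cohort

All validation runs on a generated, fully labelled cohort (default: five
MMF recipients T1–T5, four healthy donors H1–H4):

* **Catalog.** True GUS genes are representative scaffolds mutated to a
  target identity drawn from [0.35, 0.95] — clean margins around the
  0.25 screen — by substitutions only (flat over the 19 alternatives; an
  option adds short indels). Catalytic positions are preserved with ±2
  anchor flanks (±5 at identity ≥ 0.6, which also plants shared tryptic
  peptides across genes of the same representative); FMN-class genes
  keep every other residue of the FMN segment. Identity is measured with
  the discovery aligner itself and landed within ±0.02 of target by a
  bisection on the nested mutation count. A GUS-like entry is re-drawn
  until its source representative is its best screening hit, which is
  what "clean margins" requires operationally. Decoys: residue-ablated
  (GUS-like identity, 1–3 catalytic residues substituted), low-identity
  (random-composition sequences verified to screen below 0.20 against
  every representative), and composition-shuffled non-homologs.
* **Counts.** Per-gene log10 abundances follow a linear trend in gene
  length with the planted bias slope plus N(0, 0.4) gene noise; library
  factors span ≥2-fold; counts are Poisson. Calibration checks fit one
  sample at a time, because the gene-level noise is shared across a
  cohort's samples by design.
* **Proteome.** A cohort-level expressed subset of the true GUS genes;
  per (sample, protein) log2 intensity is a baseline plus a
  class-by-group shift (default FMN +2 in the MMF group) plus N(0, 0.8);
  tryptic peptides (cleave after K/R, not before P, 7–30 residues)
  receive lognormal intensities summing to the protein intensity in
  expectation. Intensities are lognormal as peak areas usually are; no
  spectrum-level simulation is attempted.
* **Time courses.** True rate r = a + b·FMN + ε with the FMN predictor
  being the *centered* per-sample log2 FMN intensity (so `a` is the rate
  of a cohort-average sample and default rates span ~0–20 nM/s),
  defaults a = 10 nM/s, b = 5 nM/s per log2 unit, ε ~ N(0, 1), plus
  N(0, 500 nM) measurement noise per point, truncated at zero
  concentration.

Every generator is a pure function of (arguments, seed), with per-stage
seed streams so stages re-run independently.

**What passing tests do and do not show.** The cohort emulates the
*statistical structure* the analysis assumes — identity margins, planted
length bias, class-specific expression shifts, a linear rate model — not
real data. Real catalogs contain fragments, indel-rich homologs and
sequencing artefacts; real peptide tables contain missed cleavages,
modifications and intensity-dependent missingness; real rate curves
saturate. Passing here demonstrates that the implementation computes the
stated quantities correctly and recovers effects it was told exist, not
that the biological conclusions transfer to any particular cohort.

# Numerical and degenerate-input choices

* Alignment scores are exact integers in doubles; equality tests in the
  traceback are exact.
* An all-mismatch pair with no positive-scoring cell is an empty
  alignment with identity 0 (not an error).
* `relative_count` errors if a count exceeds its sample total or if the
  total is 0 with a positive count; an all-zero sample is legal and maps
  to all-zero relative counts.
* The bias fit requires ≥3 points and non-constant lengths.
* An exact linear fit in the Wald test reports p = 0 with an
  `exact_fit` flag (residual sum below 1e-12 of the response's total sum
  of squares).
* Zero differences are dropped before the signed-rank test; fewer than
  3 non-zero pairs is an error.
* Configuration files are YAML, one section per stage, merged over the
  package defaults; CLI flags override both. All coordinates are 1-based
  with closed intervals, stated in every output header; TSV outputs use
  `.` for missing, no quoting.

# Validation problem sizes

The shipped test suite validates at sizes chosen to exercise every code
path quickly: 200-candidate screening oracle comparisons against a
plain-R dynamic-programming aligner, 20-seed recall/specificity sweeps,
planted-group clustering, 200×199-permutation PERMANOVA and 1000-dataset
Wald calibrations, 100-seed end-to-end FMN-effect recovery on a 46-entry
catalog with 9 samples, and 100-simulation joint confidence-region
coverage of the planted rate model at n = 30. `scripts/acceptance.R`
re-runs the full simulate→discover→quantify→associate chain on the same
cohort design from a single seed.

# Known limitations

* The screen is alignment-based; profile/HMM search and E-value
  statistics are out of scope, so sensitivity below ~30% identity is not
  claimed.
* Class assignment degrades gracefully (flagged `by_nearest`) when loop
  windows cannot be projected; on heavily fragmented proteins the class
  may be driven by the nearest representative.
* The bundled representative set is synthetic; biological conclusions
  require a curated reference set.
* PERMANOVA is one-factor; no strata/covariate support.
* The normal-reference Wald p is anticonservative at small n (documented
  above); the t mode is provided and used in calibration tests.
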