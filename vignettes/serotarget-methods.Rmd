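---
title: "Methods: seromics-guided tumor antigen discovery with serotarget"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seromics-guided tumor antigen discovery with serotarget}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(serotarget)
```

# Overview

`serotarget` integrates four orthogonal lines of evidence about tumor
antigens — plasma auto-antibody reactivity on high-density protein arrays,
expressed somatic mutations, tumor and thymic expression, and eluted
MHC-associated peptides (MAPs) — into a single prioritization pipeline. This
vignette documents the statistical model of each stage, the parameters that
matter and why their defaults are what they are, what the synthetic cohort
generator does and does not emulate, and the design decisions taken where
the methodology was genuinely open.

# Auto-antibody hit calling

Each array feature carries replicate spots of one protein; an array also
carries negative-control features, pooled per patient into one control set.
The hit statistic is the Z-Factor,

$$Z = 1 - \frac{3\sigma_s + 3\sigma_{c-}}{\lvert \mu_s - \mu_{c-} \rvert},$$

a screening-window statistic: it is 1 only when both the feature and control
replicates are noiseless, shrinks as three standard deviations of either side
eat into the separation of the means, and goes negative when the
signal-to-noise window closes. A feature is a significant hit when its mean
replicate signal exceeds `signal_threshold` (default 1000 fluorescence
units) **and** its Z-Factor exceeds `z_threshold` (default 0.4); both
comparisons are strict, so a feature exactly at a threshold is not a hit.

Numerical conventions:

* Replicates are summarized by their arithmetic mean; σ is the sample
  (n − 1) standard deviation. At least two replicates are required, since σ
  is undefined otherwise.
* Signals are used raw. The hit rule is stated in signal units, so no
  background subtraction or normalization is applied at this stage; the
  differential stage (below) normalizes explicitly.
* If a feature's mean equals the control mean the Z-Factor denominator is
  zero; such features are excluded from the repertoire with a warning rather
  than failing the patient, because a feature indistinguishable from the
  controls carries no evidence either way.
* Z is invariant under a common positive rescaling of all signals (gain
  changes on the scanner), which the test suite checks as a property.

# Repertoire set algebra

The cross-patient *shared* repertoire is the set of genes hit in at least
`min_patients` case repertoires (default 4, mirroring a shared-in-4-of-9
design); it is monotone non-increasing in `min_patients`, with 1 giving the
union and n the intersection.

The *differential* repertoire is computed by a per-gene two-sided Welch
t-test on per-array median-normalized log(signal + 1), with
Benjamini–Hochberg adjustment across genes; genes with q ≤ `alpha` (default
0.05) and a higher case-group mean are "enriched". Two points deserve
emphasis:

* **Choice of test.** Count-based differential frameworks designed for
  sequencing data are a poor model for continuous fluorescence intensities.
  The package therefore uses a defined, appropriate test — Welch on
  median-normalized log signals — rather than imitating a count model, and
  exposes `alpha` so alternative multiplicity controls can be applied to the
  returned p-values.
* **Normalization.** "Normalized array signals" is underdetermined; the
  package's convention is per-array median scaling to the cohort grand
  median on the log scale, which removes array-level brightness differences
  without touching gene-level structure.

The *combined* repertoire is the plain union of shared and enriched sets;
inclusion–exclusion (|A ∪ B| = |A| + |B| − |A ∩ B|) is asserted on random
fixtures. Overlap between repertoires is reported as an exact intersection
count and as a percentage of the first set, rounded to one decimal place
with round-half-even.

# Expressed somatic SNVs

A variant is an *expressed somatic SNV* when it satisfies all three printed
rules at once:

1. called in **both** tumor WES and tumor RNA-seq (keyed by chromosome,
   position, reference and alternate allele);
2. not a suspected germline SNP: population allele frequency **strictly
   greater** than `af_threshold` (default 0.005) removes a variant, so a
   variant exactly at 0.005 is retained;
3. variant allele frequency **at least** `min_vaf` (default 0.10,
   inclusive).

The two post-intersection filters commute and the cascade is idempotent,
both verified as properties. Variants with no population-frequency record
are retained with a warning — absence from the population database is weak
evidence the allele is rare, and silently dropping such variants would
bias against novel mutations. Only SNVs producing a single amino-acid
substitution are carried to peptide tiling; other rows remain in counts but
are flagged non-tileable.

VCF ingestion maps VAF from the `AF` INFO field when present, otherwise from
allelic depths (`AD`), with `AF` taking precedence; the TSV dialect is the
test-native format and the generator emits both, with a test asserting they
parse identically.

# Neo-epitope candidate generation

For a substitution at protein position p, the tiler emits every 8-, 9- and
10-mer window that contains p and lies fully within the protein; an interior
mutation with at least nine flanking residues on both sides yields
8 + 9 + 10 = 27 mutant/wildtype pairs. The closed-form window count
$\sum_k \bigl(\min(p, L-k+1) - \max(1, p-k+1) + 1\bigr)$ is checked against
exhaustive enumeration on 1000 random fixtures. The tiler refuses
annotation/sequence disagreements (wildtype residue not found at the stated
position) rather than guessing, since a mismatch means the variant
annotation and the proteome are out of sync.

Scoring runs through a *predictor contract*: any object providing
`affinity(peptide, allele)` in nM and `processing_score(peptide, allele)` in
[0, 1]. The packaged toy predictor derives both from fixed per-position
residue weight matrices (a closed-form trigonometric hash of residue,
position, length and allele, with affinity an exponential transform of the
summed weights into a plausible 1 nM–50 µM range). It is deterministic,
covers lengths 8–10, and exists so that filtering, ranking and panel logic
are testable end-to-end with byte-identical results; it has no predictive
validity for real MHC binding. Real predictions enter through
`tabular_predictor()`, an adapter over precomputed score tables.

The filter cascade keeps candidates with mutant IC50 < `max_affinity_nM`
(default 500 nM), combined score > `min_combined_score`, and — by default —
mutant affinity stronger (numerically lower IC50) than the wildtype window,
the standard interpretation of "greater affinity than wildtype" given the
inverse relation between IC50 and affinity. The combined-score default is
0.6: where two stated values conflicted (a 0.8 appears in one context and
0.6 in the quantitative record tied to reported epitope counts), the value
anchored to the quantitative record was taken as default, and the threshold
is exposed as configuration.

Panel selection mimics choosing 2–9 peptides for synthesis: candidates whose
Kyte–Doolittle GRAVY exceeds `hydropathy_limit` (default 2.0; `NULL`
disables) are removed first — "acceptable hydrophobic residue content" is
otherwise undefined, and GRAVY is the standard documented hydropathy scale —
then one candidate per (gene, mutation, length) is kept and the rest ranked
by mutant affinity ascending, ties broken by higher combined score then
lexicographic peptide, so the ordering is total and reruns are
byte-identical. Whether overlapping windows of different lengths should be
collapsed further is not determined by the source material; the
per-(gene, mutation, length) rule is this package's convention and is stated
in the function documentation.

# MAP matching and panels

Eluted ligands (8–11-mers) are assigned to every proteome entry containing
them as an exact substring (Biostrings pattern matching; the test oracle is
an independent naive scan). Isoleucine/leucine are distinct by default:
although MS cannot distinguish the isobaric pair, collapsing them changes
gene assignments and is therefore opt-in (`il_equivalent = TRUE`).
Annotation flags (geneset membership, auto-antibody-target status, known
epitope identity by exact sequence) are monotone in their inputs. The
screening panel takes up to `max_known` known-epitope MAPs plus
`max_autoab` auto-antibody-target MAPs (defaults 10 and 2, the composition
of the published 12-peptide pool), deduplicated by sequence, ordered known
first and within category by gene then sequence, making the panel
deterministic under input reordering.

# The synthetic cohort generator

The generator is the package's test bed and defines its study conditions:

* **Design**: 9 case (HGSC) + 9 comparison patients; 800 array features and
  30 pooled negative controls per array; duplicate spots (2 replicates).
* **Signal model**: log-normal background (meanlog log 300, sdlog 0.4 in
  fluorescence units) for unspiked features and controls; multiplicative
  log-normal replicate noise at 5% CV, a typical duplicate-spot
  reproducibility for fluorescence arrays; spiked responders sit at
  fold-change 8 over the control mean, comfortably above the 1000-unit rule
  so that recovery measures the statistic rather than the spike placement.
  10% of features are spiked per patient: 20 group-enriched genes present in
  every case patient (driving the differential stage) plus per-patient draws
  from a 150-gene shared pool so that targets recur across patients and the
  shared-repertoire rule has structure to find.
* **Variants**: 30 true expressed SNVs per patient (within the reported
  10–67 per-patient range), each satisfying all three filter rules, plus
  decoy classes violating exactly one rule each (WES-only, RNA-only,
  population AF > 0.005, VAF < 0.10), so cascade recall and precision are
  exactly measurable.
* **Proteome and MAPs**: a shared 120-protein reference (lengths 80–300,
  uniform random residues) that includes the enriched genes; variant
  wildtype residues are taken from it, so tiling never hits a residue
  mismatch on generated data. MAP lists are exact 8–11-mer substrings plus
  10% scrambled decoys verified absent from the proteome. The known-epitope
  list is drawn from the reference patient's true MAPs, preferring genes
  outside the enriched repertoire so the known-epitope and
  auto-antibody-target panel categories remain distinct, as they are in the
  study design it emulates.
* **Ledger**: every spiked responder, true variant and MAP source is written
  to `ground_truth.json`, so pipeline outputs are classifiable as TP/FP/FN
  with no ambiguity.

What the generator does **not** emulate: spatial array artifacts and
scanner saturation; linkage between expression level and immunogenicity;
realistic mutational signatures, transcript structure or splice isoforms;
biased amino-acid composition, HLA-binding motifs in MAPs, or MS
identification error. Passing tests therefore demonstrate the correctness of
the statistics, filters and set operations under a controlled noise model —
not the biological performance of the thresholds on real cohorts.

Test and acceptance runs use a scaled cohort (6 + 4 patients, 200 features,
40 proteins) chosen as the smallest design in which every rule keeps its
structure — the shared rule is still "4 of n" rather than an intersection,
and every decoy class is populated — with the full 9 + 9 / 800-feature
default exercised by the acceptance script.

# Determinism and reproducibility

All randomness flows from a single integer seed: the generator seeds once
and writes byte-identical bundles per seed; the toy predictor is seedless
and closed-form; ranking keys are total orders. The pipeline writes a
manifest (package and R versions, seed, config hash) and a summary whose
every number is recomputable from the stage outputs alone; reruns with the
same config and seed produce identical stage outputs, verified by checksum
in the tests.

# Known limitations

* The toy predictor is a determinism fixture, not a binding model; real
  prioritization requires external predictions via the adapter.
* Gene identity is exact-symbol matching plus an explicit alias map; no
  fuzzy cross-dataset reconciliation is attempted.
* The differential stage assumes approximately log-normal signals after
  median scaling; heavy-tailed contamination (e.g. saturated spots) is not
  modeled.
* Expression "high/low" quadrant cutoffs are caller-supplied parameters;
  no data-driven threshold selection is provided.
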