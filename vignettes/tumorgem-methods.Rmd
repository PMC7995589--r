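---
title: "Allele-frequency-pattern filtering of multi-biopsy tumor variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allele-frequency-pattern filtering of multi-biopsy tumor variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tumorgem)
```

## The problem

Tumors sequenced repeatedly — across treatment time points or across
regions and metastases — carry millions of called variants, of which a
handful follow allele-frequency patterns that matter: mutations sweeping to
higher frequency under treatment pressure, clonal (truncal) mutations
present in every tumor sample, loss-of-heterozygosity events, and mutations
private to particular biopsies. `tumorgem` imports a jointly called,
annotated multi-sample VCF into a relational database keyed by a sample
manifest that records, per sample, the patient it came from, its sampling
time (0 = normal/germline tissue, larger values = tumor biopsies in
temporal order), and optionally the tumor purity of the biopsy. Filtering
tools then evaluate per-variant predicates over the per-sample variant
allele frequencies (VAFs), composable with SQL filters over the annotation
columns imported from the VCF INFO field.

## The allele-frequency model

For each sample and variant the VAF is estimated as

$$\hat f = \frac{\mathrm{AD}_{alt}}{\mathrm{DP}},$$

falling back to the sum of allelic depths when `DP` is absent, to the
genotype dosage (0, 0.5, 1 for hom-ref, het, hom-alt) when allelic depths
are absent entirely but a genotype was called, and to the sentinel value
−1 when nothing is computable (no call, zero depth). An alternate depth
exceeding the total is clamped to 1 with a counted warning. Sentinels
propagate deliberately: a variant with an uncomputable VAF in any
considered sample is excluded from every tool's evaluation rather than
guessed at, and the exclusion is logged. Half-missing genotypes such as
`./1` are coded UNKNOWN for the same reason — the depth gate and the
sentinel rule decide their fate, not an imputation.

When purity correction is requested, each VAF is divided by the biopsy's
tumor cell fraction and clamped to 1,
$\hat f_{corr} = \min(\hat f / p, 1)$, the standard cellularity correction
for somatic VAFs diluted by admixed normal cells. The correction applies to
every sample that has a manifest purity value; samples without one are
treated as purity 1.0 with a warning naming them, so an omitted purity
column never silently changes results. Purity is an input — the package
does not estimate it.

## Tool predicates and their parameters

All thresholds are fractions of VAF unless noted. Boundary semantics are
deliberately strict where presence is asserted and inclusive where absence
is tolerated:

* **bottleneck** — over the considered *tumor* samples of a patient, the
  ordinary least-squares slope of VAF on manifest time,
  $\hat\beta = \sum_i (t_i-\bar t)(f_i-\bar f) / \sum_i (t_i-\bar t)^2$,
  must strictly exceed `minSlope` (default 0.05). Normal samples never
  enter the regression; when considered they act only as a germline gate
  (every normal VAF ≤ `maxNorm`, default 0). Times are used verbatim —
  they need not be consecutive integers — and replicate samples at one
  time each contribute a point (no averaging). A patient needs at least
  two distinct tumor time points; otherwise its variants are skipped with
  a one-time warning. The germline gate is what hides inherited variants
  that rise in frequency; raising `maxNorm` (or dropping the normal via
  `samples`) recovers them.
* **loh** — every considered normal VAF within the heterozygosity band
  [`hetLo`, `hetHi`] and every considered tumor VAF within
  `lohTumorDelta` of 0 or of 1. The defaults 0.3/0.7 and 0.05 are the
  conventional het and homozygous calling bands for germline sites; no
  numeric definition is canonical, so all three are exposed as parameters.
* **truncal** — every considered normal VAF ≤ `maxNorm` and every
  considered tumor VAF strictly greater than `maxNorm` (default 0).
  `maxNorm` therefore plays a dual role: normal ceiling and tumor presence
  floor. One consequence worth knowing: lowering `maxNorm` tightens the
  germline side but *loosens* the presence side, so the returned set is
  only guaranteed to shrink when no tumor VAF lies between the old and new
  values — at sequencing noise level, a near-zero tumor VAF can drift
  across a strict `> 0` floor.
* **unique** — every sample in `specific` has VAF strictly above `minAF`
  (default 0) and every other considered sample is at or below `maxOthers`
  (default 0). Small positive ceilings (e.g. 0.05) absorb sequencing noise
  in the "absent" samples.
* **set_somatic** — flags variants where all samples reach `minDP`, every
  normal VAF is ≤ `normAF`, and at least one tumor VAF is ≥ `tumorAF`
  (purity-corrected when requested); the flag persists in the database and
  the `somatic_only` option of every tool then restricts evaluation to
  flagged variants. Requesting `somatic_only` on a database that was never
  flagged (and whose VCF carried no somatic INFO flag) is a hard error
  pointing at `set_somatic`. LOH variants are germline-heterozygous by
  definition and will generally *not* be flagged somatic; combining `loh`
  with `somatic_only` is allowed but usually not what you want.

A depth gate shared by all tools (`minDP`, default 0 = disabled) requires
every considered sample to reach the minimum depth; a missing depth fails
the gate. Databases holding several patients are evaluated patient by
patient and the union returned, tagged with `patient_id`; for `set_somatic`
a variant is flagged when its rule holds within at least one patient. This
generalizes the one-database-per-patient workflow without changing
single-patient behavior.

Output rows are ordered by contig (numeric-aware, so chr2 precedes chr10),
then start, then insertion order, and carry the per-sample VAFs that the
decision used plus, for bottleneck, the fitted slope.

## Database construction choices

VCF parsing is delegated to `VariantAnnotation::readVcf()`; INFO fields
become typed columns per their header declarations (Flag → 0/1, multi-value
fields stored as their first element with a counted warning — records are
single-ALT after the skip rule below). Column names are lowercased with
non-alphanumerics replaced by underscores; collisions with core columns get
an `_info` suffix. An INFO field named `gene` populates the core `gene`
column; pre-flattened annotation keys are expected, and raw SnpEff/VEP CSQ
strings are deliberately not parsed. Coordinates are stored 0-based
half-open (`start = POS − 1`, `end = start + nchar(ref)`).

Multiallelic records are skipped with a counted warning rather than split:
splitting allelic-depth fields correctly is error-prone and upstream
normalizers (`bcftools norm -m-`, vt decompose) already do it well. The
loaded + skipped counts always add up to the VCF body line count.

Genotype class, depth and VAF vectors are stored per variant as compressed
binary blobs in the variants table rather than a long-format join table:
the tools always read whole per-variant vectors, and a 3-column blob read
is an order of magnitude cheaper than a million-row join. The samples table
is reordered to VCF column order at load so stored vectors and manifest
metadata share one ordering; explicit `samples` selections are likewise
reordered so time vectors stay sorted regardless of how the user typed the
list.

The query engine executes read-only SQL only (single statement, write
keywords rejected); filter fragments are validated against existing columns
before execution, and the emptiness idiom `col != ''` is rewritten to
`(col IS NOT NULL AND col != '')` so that un-annotated (NULL) rows are
excluded, which is what "has a CGI gene entry" means. Annotation filtering
commutes with the VAF predicates by construction — the filter restricts the
candidate rows, the predicate never looks at annotations — and the test
suite checks the intersection law on every fixture.

## The synthetic cohort generator

The generator emulates the measurement process the tools consume: per
patient, one normal (time 0) and `tumors_per_patient` tumor biopsies at
times 1..T; per variant, a planted class with its archetypal VAF pattern
(constants drawn once per variant and patient):

| class | normal | tumors |
|-------|--------|--------|
| truncal | 0 | one VAF from [0.2, 0.6], constant across tumors |
| bottleneck | 0 | $s\,(t-1)$ with slope $s \sim U[0.1, 0.3]$ |
| loh | 0.5 | 1.0 |
| unique | 0 | VAF from [0.2, 0.6] in the first tumor only |
| germline_flat | 0.5 | 0.5 |
| noise | sub-threshold in one middle tumor, or one value uniform everywhere |

VAFs are realized through integer read counts: depth is Poisson around
`depth_mean`, the planted VAF is jittered by `rnorm(0, af_noise_sd)`, and
the alternate-read count is `round(VAF × DP)` with the reference count
making up the difference. Rounding rather than binomial sampling is a
deliberate design choice: at `af_noise_sd = 0` the emitted files recover
each planted class *exactly* at default thresholds (precision and recall
1.0 on a 1,000-variant cohort — the recovery check in the test suite and
acceptance script), whereas binomial read sampling would give a
constant-VAF truncal variant a noisy slope that crosses the 0.05 bottleneck
threshold for a few percent of variants. Jitter is reintroduced explicitly
through `af_noise_sd` (default 0.01) when noisy conditions are wanted, and
the planted slope remains recoverable from the emitted reads within
`2/depth_mean + 3·af_noise_sd`.

Two placements keep the planted classes mutually exclusive at default
thresholds, which exact-recovery checks require: bottleneck variants start
at VAF 0 in the first tumor (so they are not also truncal), and unique
variants target the *first* tumor time point (a later-time target would be
a genuine VAF riser that the bottleneck tool must also return). Noise
variants put their sub-threshold VAF in a middle tumor so they stay out of
the unique target, and their "uniform" variant fails the loh band by
construction (a normal VAF inside 0.3–0.7 implies tumor VAFs at least 0.3
away from both 0 and 1).

Annotations (`impact_severity`, `cgi_gene`, `civic_gene_max_level`,
`civic_gene_max_rating`) are assigned so that a configurable fraction
(default 0.5) of variants passes the canonical cancer filter; the rest fail
at least one randomly chosen component, so each filter clause is
individually selective. Output is byte-identical for a fixed seed, and the
caller's RNG stream is left untouched.

What the generator does **not** emulate — and hence what passing tests do
not certify about real data: mapping and alignment artifacts, strand bias,
copy-number-driven VAF shifts (real LOH often passes through intermediate
VAFs under aneuploidy), multiallelic sites, indel representation issues,
sample contamination, or realistic mutational signatures. Recovery results
on clean synthetic cohorts are a correctness statement about the
predicates, not a sensitivity claim about noisy sequencing.

## Numerical and degenerate-input conventions

* Slope uses the centered one-pass formula; it agrees with a
  normal-equations solve to < 1e−9 across random instances with
  manifest-like (small, distinct) time values.
* All-equal tumor times make the slope undefined: the patient is skipped
  with a warning, never divided by zero.
* Ties in manifest time are allowed (multi-region designs give all
  post-mortem samples one time); ordering among ties follows file order
  and each tied sample contributes its own regression point.
* Empty results are ordinary: every tool and the CLI return an empty table
  with exit code 0.
* `depth_gate(·, 0)` is constantly true; any positive `minDP` fails
  missing (−1) depths.
* Manifest purity must lie in (0, 1]; absent purity is `NA`, not 1.0, so
  the correction step can tell "no estimate" from "pure tumor".

## Problem sizes used in the checks

The bundled checks run on cohorts of 200–1,000 variants (plus one
5,000-variant database for the somatic-flag equivalence check) with 4
samples at depth 100 — sizes chosen so that brute-force per-variant oracles
(full scans, per-variant `lm()` fits) remain practical to run alongside the
vectorized implementation. The implementation itself is linear in variants
× samples and comfortably handles the millions-of-variants scale of
whole-genome studies inside SQLite.

## Known limitations

* No structural-variant or CNV support; `loh` is purely VAF-based and
  blind to copy-number context (no B-allele frequency segmentation).
* No subclonal reconstruction or phylogenetics — the tools are filters,
  not models of clonal structure.
* Multiallelic records are skipped, not split; normalize upstream.
* The SQL filter surface is a trusted local interface: validation rejects
  write statements and unknown columns, but the package is not a
  multi-tenant query sandbox.
* Genotype-level query syntax inside SQL (per-sample columns in `WHERE`)
  is not provided; sample-resolved logic lives in the tools' parameters.
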