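# tumorgem

Exploration and prioritization of tumor variants across multiple biopsies.
`tumorgem` builds a searchable single-file SQL database from an annotated
multi-sample VCF plus a pedigree-style sample manifest extended with
`patient_id`, sampling `time` and optional tumor `purity`, and provides a
suite of allele-frequency-pattern filters for longitudinal and multi-region
tumor studies:

| tool | pattern |
|------|---------|
| `bottleneck` | variant allele frequency (VAF) rising across tumor time points: the ordinary least-squares slope of VAF on time, computed over tumor samples only, must exceed `minSlope` (default 0.05); normals act as a germline gate (`maxNorm`, default 0) |
| `loh` | loss of heterozygosity: heterozygous in every normal (VAF in 0.3–0.7) and collapsed to within 0.05 of 0 or 1 in every tumor |
| `truncal` | clonal mutations: every normal VAF ≤ `maxNorm` (default 0) and every tumor VAF strictly greater |
| `unique` | private to a listed sample group: VAF > `minAF` (default 0) in all listed samples, ≤ `maxOthers` (default 0) in all others |
| `set_somatic` | persists an `is_somatic` flag per variant (all depths ≥ `minDP`, all normal VAFs ≤ `normAF`, ≥ 1 tumor VAF ≥ `tumorAF`), unlocking `--somatic-only` on every tool |

Per-sample VAF is estimated as alt depth / total depth (FORMAT `AD`/`DP`),
with a genotype-dosage fallback when allelic depths are absent and a `-1`
sentinel when uncomputable. With the `purity` flag, VAFs are divided by the
biopsy's tumor cell fraction (clamped to 1) before any predicate is
evaluated. Every tool composes with SQL annotation filters over the INFO
columns imported from the VCF (e.g. `impact_severity != 'LOW' and
cgi_gene != ''`) and with explicit sample selection (`samples`).

A synthetic-cohort generator with planted variant classes (truncal,
bottleneck, loh, unique, germline-flat, noise) plus a truth table makes the
whole pipeline testable end to end without external data.

## Worked example

Simulate a one-patient cohort (1 normal + 3 tumor biopsies at times 1–3,
500 variants, 10 planted per class, mean depth 100), load it, flag somatic
variants, and ask for somatic truncal mutations with a cancer-annotation
filter:

```r
library(tumorgem)

cfg <- sim_config(n_patients = 1, tumors_per_patient = 3, n_variants = 500,
                  class_counts = c(truncal = 10, bottleneck = 10, loh = 10,
                                   unique = 10, germline_flat = 10),
                  depth_mean = 100, af_noise_sd = 0, seed = 42)
sim <- simulate_cohort(cfg, "readme")
load_db(sim$vcf, sim$manifest, "readme.db")
#> loaded 500 variant(s), skipped 0 multiallelic record(s) into readme.db

set_somatic("readme.db", minDP = 10, normAF = 0.05, tumorAF = 0.2)
#> set_somatic: flagged 30 of 500 variant(s)

truncal("readme.db", tool_params(minDP = 10, somatic_only = TRUE),
        filter = "impact_severity != 'LOW' and cgi_gene != ''")
#> truncal: 19 candidate variant(s), 6 returned
#>   variant_id patient_id chrom start  end ref alt    gene af_p1_N af_p1_T1 af_p1_T2 af_p1_T3
#> 1         28         p1  chr1  4835 4836   G   C  GENE28       0    0.560    0.561    0.558
#> 2         49         p1  chr1  7712 7713   T   A  GENE49       0    0.476    0.485    0.481
#> 3        118         p1  chr2  3465 3466   A   T GENE118       0    0.398    0.395    0.396
#> ...
```

Each returned row is a variant absent from the normal (`af_p1_N` = 0) but
present in every tumor biopsy, restricted to medium/high functional impact
within the CGI gene catalog. The annotation filter reduced 500 variants to
19 candidates; the truncal AF predicate left 6. The bottleneck tool instead
reports the fitted VAF-versus-time slope:

```r
bottleneck("readme.db", tool_params(minDP = 10))
#> bottleneck: 500 candidate variant(s), 10 returned
#>   chrom start ref alt    gene slope
#> 1  chr1  3465   C   G  GENE18 0.267
#> 2  chr1 12096   T   G  GENE81 0.165
#> ...
```

## Command line

The same operations are available as subcommands through the bundled
wrapper (results on stdout as TSV, logs on stderr; exit code 0 on success
including empty results, 1 on usage errors, 2 on data errors):

```sh
TG=$(Rscript -e 'cat(system.file("cli/tumorgem.R", package = "tumorgem"))')
Rscript $TG load cohort.vcf cohort.manifest -o cohort.db
Rscript $TG set_somatic --minDP 10 --normAF 0.05 --tumorAF 0.2 --purity cohort.db
Rscript $TG truncal --minDP 10 --columns "chrom,start,end,ref,alt,gene" \
    --filter "impact_severity != 'LOW' and cgi_gene != ''" cohort.db
Rscript $TG unique --minDP 10 --specific A1,A2,A4 cohort.db
Rscript $TG query -q "select chrom, start, end, ref, alt, gene from variants where civic_evi_level = 'A'" cohort.db
Rscript $TG simulate --config sim.yaml --out cohort
```

## Database schema

One SQLite file with three tables:

- `variants` — one row per decomposed (single-ALT) record: `variant_id`,
  `chrom`, `start` (0-based), `end` (half-open), `ref`, `alt`, `gene`,
  `is_somatic`, one typed column per VCF INFO field (Integer→INTEGER,
  Float→REAL, Flag→0/1, String→TEXT; names lowercased, non-alphanumerics →
  `_`, core-name collisions suffixed `_info`), and three compressed BLOB
  columns with the per-sample genotype class / depth / VAF vectors.
- `samples` — the manifest, reordered to VCF sample order (the order of all
  genotype vectors).
- `meta` — schema version, load/skip counts, somatic-flag state.

Multiallelic records are skipped with a counted warning: decompose and
normalize the VCF upstream (e.g. `bcftools norm -m-`) to keep them.

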