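# hladq

HLA-DQ genotype interpretation for coeliac-disease (CD) genetic testing,
and a simulator/scorer for the external proficiency testing (EPT)
schemes that keep that testing honest.

A hard genetic prerequisite for CD is an HLA-DQ molecule able to present
deamidated gluten peptides: the heterodimers **DQ2.5**
(`DQB1*02 + DQA1*05`), **DQ2.2** (`DQB1*02 + DQA1*02`, without
`DQA1*05`) and **DQ8** (`DQB1*03:02 + DQA1*03`). Nearly all patients
carry at least one, but so does roughly 43% of the general population —
so the HLA test *excludes* CD (high negative predictive value) rather
than confirming it. `hladq` is for clinical immunogenetics laboratories,
EPT organisers and methodologists who need this logic as tested,
reproducible code rather than as a wall-chart.

## What it does

* **Nomenclature** — parse, normalize and format WHO-style DQA1/DQB1
  allele names; prefix-based allele-group matching
  (`parse_allele()`, `matches_group()`).
* **Interpretation** — phase-agnostic heterodimer detection in unphased
  genotypes and three-category classification (`ASSOCIATED`,
  `NOT_EXCLUDED`, `EXCLUDED`) under five versioned rule sets (Czech
  2015/2020/2022/2023 and UK NEQAS/BSHI), plus assembly of the
  three-element clinical report (`interpret_genotypes()`,
  `build_report()`).
* **Population arithmetic** — haplotype-frequency bookkeeping,
  Hardy–Weinberg carrier proportion `1 - (1 - f)^2`, and Bayesian
  NPV/PPV (`carrier_frequency_hwe()`, `predictive_values()`); the Czech
  haplotype-frequency table ships with the package
  (`czech_frequencies()`).
* **EPT simulation** — seeded reference panels drawn under random
  mating, realistic laboratory error models (the recurrent
  `DQB1*03:03` → `DQB1*03:02` miscall, allele dropouts), scoring at the
  required resolution (DQA1\*02/\*03/\*05, DQB1\*02, DQB1\*03:02), and
  method-stratified lab error rates (`generate_panel()`,
  `apply_error_model()`, `score_submission()`, `aggregate_cohort()`,
  `simulate_ept()`).

Everything takes a data frame first and returns a tibble, so calls
chain with the pipe; `tidy()`/`glance()` methods and `autoplot()` are
provided for the result objects.

## Worked example

```r
library(hladq)

g <- read_genotypes(system.file("extdata", "example_genotypes.csv", package = "hladq"))
res <- interpret_genotypes(g, ruleset = "CZ2023")
res[, c("sample_id", "dq25", "dq22", "dq8", "category")]
#> # A tibble: 3 × 5
#>   sample_id dq25  dq22  dq8   category
#>   <chr>     <lgl> <lgl> <lgl> <ord>
#> 1 EX01      TRUE  FALSE TRUE  ASSOCIATED
#> 2 EX02      FALSE FALSE FALSE NOT_EXCLUDED
#> 3 EX03      FALSE FALSE FALSE EXCLUDED

cat(format_report_text(build_report(res))[1])
#> Sample: EX01
#> Predisposing alleles/allele groups: DQA1*05:01, DQA1*03:01, DQB1*02:01, DQB1*03:02
#> Serological equivalents: DQ2.5 present, DQ2.2 absent, DQ8 present
#> Interpretation (CZ2023): Detected HLA genotype is associated with the risk of CD.
#> This result cannot be separately interpreted as a confirmation of CD due to low specificity.
```

EX01 carries both DQ2.5 and DQ8 and is associated with CD risk. EX02
carries `DQA1*05` but completes no heterodimer: under the 2023 Czech
rules the diagnosis cannot be excluded (under `ruleset = "UK_BSHI"` the
same genotype is EXCLUDED — that is the two guidelines' one point of
divergence). EX03 carries nothing predisposing and CD is excluded with
high probability.

Population headline numbers:

```r
f <- total_predisposing_frequency(czech_frequencies())  # 0.244
carrier_frequency_hwe(f)                                # 0.428464 ~ 43%
glance(predictive_values(0.01, 0.99, carrier_frequency_hwe(f)))[, c("npv", "ppv")]
#> npv 0.99982..., ppv 0.0231...
```

## Command line

A thin CLI over the same functions ships at `inst/cli/hladq.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","hladq.R",package="hladq"))')" \
  interpret --input genotypes.csv --output reports.json --ruleset CZ2023
# other commands: popfreq, ept simulate, ept score, ept summarize
```

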