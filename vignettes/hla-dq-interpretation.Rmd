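---
title: "HLA-DQ genotype interpretation for coeliac disease: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{HLA-DQ genotype interpretation for coeliac disease: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hladq)
library(dplyr)
```

## The problem

Coeliac disease (CD) is an autoimmune enteropathy triggered by dietary
gluten. A hard genetic prerequisite is the ability to present deamidated
gluten peptides on specific HLA-DQ molecules: the heterodimers **DQ2.5**,
**DQ2.2** and **DQ8**, each an α/β chain pair encoded by particular allele
combinations at the *HLA-DQA1* and *HLA-DQB1* loci:

| heterodimer | DQB1 requirement | DQA1 requirement |
|---|---|---|
| DQ2.5 | `DQB1*02` | `DQA1*05` |
| DQ2.2 | `DQB1*02` | `DQA1*02` (without any `DQA1*05`) |
| DQ8   | `DQB1*03:02` | `DQA1*03` |

Because nearly all patients carry at least one of these, while they are
also common in the healthy population, the HLA test is an *exclusion*
test: a high negative predictive value and a low positive one. `hladq`
implements the full desk side of this testing workflow: allele
nomenclature handling, heterodimer detection, versioned clinical
interpretation, the population arithmetic behind the predictive values,
and a simulator/scorer for external proficiency testing (EPT) schemes.

## Nomenclature choices

Alleles are handled in WHO nomenclature (`LOCUS*FF:FF`), restricted to
DQA1 and DQB1. Parsing accepts an optional `HLA-` prefix and unpadded
fields (`DQB1*3:2`), and normalizes to a canonical zero-padded form;
formatting and parsing are mutually inverse on canonical names. Up to
four fields are carried, but all interpretation logic uses only the five
group-level prefixes that clinical detection requires: `DQA1*02`, `*03`,
`*05`, `DQB1*02` and `DQB1*03:02`. Expression/null suffixes (N, L, Q, …)
are rejected outright rather than stripped: a silently dropped null
suffix could flip an interpretation, and such alleles are outside the
scope of CD kit-based testing. G/P groups and GL-string ambiguity are
likewise out of scope.

One genuinely open design point is input typed only as `DQB1*03`. The
rules need the second field there (to separate predisposing `*03:02`
from neutral `*03:03`), so such input is accepted but flagged
*insufficient resolution*; the DQ8 call becomes `NA`, and the final
category is `NA` unless it is already decided by other alleles. With
`insufficient = "error"` the same situation aborts instead. We prefer
the flag-and-propagate default because a partial genotype can still be
conclusive (e.g. a DQ2.5-positive sample).

## The interpretation rule sets

Detection is deliberately **unphased**: the recommendation defines
heterodimers by allele co-presence in the genotype, so trans-encoded
dimers count. DQ2.2 carries a "without DQA1*05" qualifier; when DQA1*05,
DQA1*02 and DQB1*02 co-occur, DQ2.5 is reported present and DQ2.2 absent
(the category is unaffected).

Five named rule sets map the heterodimer evidence to one of three
categories, `ASSOCIATED` > `NOT_EXCLUDED` > `EXCLUDED`:

```{r}
rule_sets()
```

* **CZ2015**: DQ2.5 or DQ8 → ASSOCIATED, else EXCLUDED.
* **CZ2020**: additionally DQ2.2 alone → NOT_EXCLUDED (rare risk).
* **CZ2022**: all three heterodimers → ASSOCIATED, else EXCLUDED.
* **CZ2023** (default): all three heterodimers → ASSOCIATED; DQA1*05
  without a complete heterodimer → NOT_EXCLUDED; else EXCLUDED.
* **UK_BSHI**: as CZ2022; DQA1*05-only genotypes are explicitly
  EXCLUDED. This is the single point of divergence from CZ2023.

The interpretation sentence attached to each category is the canonical
output string of the rule set. The three CZ2023 sentences are verbatim
from the 2023 recommendation; sentences for the earlier Czech versions
and for UK_BSHI are only partially documented and have been
reconstructed around the published fragments — `rule_sets()` flags these
with `reconstructed_text = TRUE`.

### The DQA1*05 "solely" question

The CZ2023 second category is worded for genotypes carrying DQA1*05
*solely without any of the other predisposing alleles*. It is ambiguous
whether a genotype with DQA1*05 plus a different lone predisposing
allele that completes nothing (say `DQB1*03:02` without `DQA1*03`)
belongs there. Both readings are implemented:

* default (`strict_dqa105 = FALSE`): NOT_EXCLUDED whenever DQA1*05 is
  present and no heterodimer is complete — the rare confirmed cases were
  defined by DQA1*05 positivity, and this reading never downgrades a
  DQA1*05 carrier;
* `strict_dqa105 = TRUE`: NOT_EXCLUDED only when DQA1*05 is the sole
  predisposing allele.

Whenever the two readings disagree on a sample, a warning is recorded so
the report writer can see the sample sits in contested territory.

## Population arithmetic

The packaged Czech haplotype table carries the three published
predisposing frequencies — DQA1\*05~DQB1\*02 9.2%, DQA1\*02~DQB1\*02 8.3%,
DQA1\*03~DQB1\*03:02 6.9%, together 24.4%. The carrier proportion uses
Hardy–Weinberg random mating: for class frequency $f$,

$$ P(\text{carrier}) = 1 - (1 - f)^2, $$

giving $1 - 0.756^2 = 0.4285 \approx 43\%$. Whether the published 43%
was derived this way or from typed-population data is not stated; the
HWE formula reproduces it and is adopted as a documented assumption.
The non-predisposing remainder of the packaged table (75.6%) is a
*synthetic* decomposition across common neutral haplotypes — including
DQA1\*03~DQB1\*03:03 (the recurring miscall target) and
DQA1\*05~DQB1\*03:01 (a DQA1\*05 carrier outside the risk set) — chosen so
every interpretation category is reachable in simulation; only the three
predisposing rows are published values.

Predictive values use standard 2×2 Bayes arithmetic
(`predictive_values()`). The test sensitivity — the fraction of patients
carrying a predisposing genotype — has no exact published value ("very
small" numbers of non-carrier patients), so it is a required parameter
with a documented default of 0.99 rather than an invented constant
presented as fact:

```{r}
predictive_values(
  prevalence = 0.01, sensitivity = 0.99,
  carrier_freq_population = carrier_frequency_hwe(0.244)
) |> glance()
```

Display rounding is half-up, one decimal for percentages; the 43%
headline uses whole-percent rounding, matching its "approximately".

## The EPT simulator

`generate_panel()` draws each reference sample as two haplotypes sampled
independently from the frequency table (HWE random mating), expands
group labels to two-field reference alleles (`DQA1*05` → `DQA1*05:01`,
as an organiser's high-resolution typing would report), and records the
reference category under a stated rule set. `rare_enrichment` forces a
fraction of samples to carry a haplotype from the low-frequency stratum
(< 5% by default), mirroring organisers' deliberate inclusion of rare
haplotypes — the samples laboratories most often get wrong.

`error_model()` captures the two error modes that dominate real schemes:
**miscalls** (an allele in one group reported as another, the canonical
example being neutral `DQB1*03:03` reported as predisposing
`DQB1*03:02`) and **dropouts** (an allele missed entirely; the sample is
then reported homozygous for the remaining allele). Each rule fires
independently per sample per matching allele slot with its stated
probability. Crucially, the submitted interpretation is *recomputed from
the corrupted genotype*, so a genotyping miscall propagates into an
interpretation error — in a DQA1*03 carrier the false `*03:02` call
fabricates DQ8 and flips the clinical category to ASSOCIATED.

`score_submission()` judges genotype correctness **only at the required
resolution**: agreement on presence/absence of the five required groups.
Extra subtype detail is never penalized (`DQA1*05:05` for `DQA1*05:01`
is correct), a missing sample scores false on both axes, and
interpretation correctness is a category match. The per-sample binary
scheme (genotype yes/no, interpretation yes/no) is this package's own
scoring definition; real schemes' point systems are not publicly
documented. `aggregate_cohort()` counts a laboratory as erroneous if any
of its samples fails either axis, stratifies by typing method (a lab
appears once per method used), and reports percentages to one decimal,
half-up — alongside separate genotype-only and interpretation-only
sub-rates, which the single published error flag does not distinguish.

```{r}
labs <- tibble::tibble(
  lab_id = sprintf("L%02d", 1:6),
  method = rep(c("PCR-SSP", "RT-PCR", "SSO"), each = 2)
)
run <- simulate_ept(
  czech_frequencies(), n_samples = 5, labs = labs,
  model = error_model(
    miscalls = data.frame(from = "DQB1*03:03", to = "DQB1*03:02", prob = 0.3)
  ),
  seed = 2023
)
run$summary
```

All randomness flows through one integer seed; per-laboratory seeds are
derived from it, and the whole simulate → corrupt → score → summarize
pipeline is byte-reproducible for a fixed seed.

## What the simulations do and do not show

The generator emulates random-mating genotypes from a fixed haplotype
table with independent, memoryless laboratory errors. It does **not**
model typing chemistry (primer panels, probe cross-reactivity), kit- or
lot-specific failure correlations, linkage-disequilibrium structure
beyond the listed haplotypes, allele ambiguity strings, or real
participant behaviour. Passing statistical checks therefore validates
the package's arithmetic and bookkeeping under its stated model — not
the error profile of any real laboratory or kit.

Problem sizes used by the test suite and the acceptance script: 100,000
genotypes for the HWE carrier check (3-standard-error band ≈ ±0.47
percentage points) and 10,000 replicates for the miscall-probability
recovery (± 0.9 points); both chosen so the bands are tight enough to
catch an off-by-one-haplotype bug while running in seconds. Exhaustive
rule-set checks enumerate all 210 two-allele-per-locus genotypes over a
ten-allele universe and compare against an independently written
brute-force classifier.

## Known limitations

* Gene-dose effects (homozygosity, DQ2.5 trans vs cis) are deliberately
  not graded — the implemented recommendations do not use them.
* Interpretation sentences for pre-2022 rule sets are reconstructions
  (flagged as such), not archival wordings.
* The packaged neutral haplotype frequencies are synthetic; analyses
  that depend on the neutral spectrum (not just its total mass) should
  substitute a population-specific table via `read_frequency_table()`.
* Serology integration, paediatric no-biopsy pathway logic and
  laboratory-information-system connectivity are out of scope.
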