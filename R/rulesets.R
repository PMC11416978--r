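#' @keywords internal
"_PACKAGE"

# Risk categories, ordered from lowest to highest evidence of predisposition.
RISK_LEVELS <- c("EXCLUDED", "NOT_EXCLUDED", "ASSOCIATED")

# The five allele groups whose correct detection the EPT scheme requires.
REQUIRED_GROUPS <- c("DQA1*02", "DQA1*03", "DQA1*05", "DQB1*02", "DQB1*03:02")

risk_factor <- function(x) {
  factor(x, levels = RISK_LEVELS, ordered = TRUE)
}

# Canonical interpretation sentences. The three CZ2023 texts are the
# verbatim wording of the 2023 national recommendation; earlier rule-set
# texts are only partially documented and are reconstructed around the
# published fragments (flagged `reconstructed` in rule_sets()).
INTERPRETATION_TEXTS <- list(
  CZ2023 = c(
    ASSOCIATED = paste(
      "Detected HLA genotype is associated with the risk of CD.",
      "This result cannot be separately interpreted as a confirmation of CD due to low specificity."
    ),
    NOT_EXCLUDED = paste(
      "Detected HLA genotype is associated with the occurrence of coeliac disease in rare cases.",
      "The diagnosis of CD cannot be excluded."
    ),
    EXCLUDED = paste(
      "Detected HLA genotype is not associated with the risk of CD.",
      "The result excludes this diagnosis with high probability."
    )
  ),
  CZ2022 = c(
    ASSOCIATED = paste(
      "Detected HLA genotype (DQ2.5, DQ2.2 and/or DQ8) is associated with the predisposition to CD.",
      "This result cannot be separately interpreted as a confirmation of CD due to low specificity."
    ),
    NOT_EXCLUDED = NA_character_, # category unreachable under CZ2022
    EXCLUDED = paste(
      "Detected HLA genotype is not associated with the risk of CD.",
      "The result excludes this diagnosis with high probability."
    )
  ),
  CZ2020 = c(
    ASSOCIATED = paste(
      "Detected HLA genotype (DQ2.5 and/or DQ8) is associated with the predisposition to CD.",
      "This result cannot be separately interpreted as a confirmation of CD due to low specificity."
    ),
    NOT_EXCLUDED = paste(
      "Detected HLA genotype (DQ2.2) is associated with a rare risk of CD,",
      "the diagnosis could not be excluded."
    ),
    EXCLUDED = paste(
      "Detected HLA genotype is not associated with the risk of CD.",
      "The result excludes this diagnosis with high probability."
    )
  ),
  CZ2015 = c(
    ASSOCIATED = paste(
      "Detected HLA genotype (DQ2.5 and/or DQ8) is associated with the predisposition to CD."
    ),
    NOT_EXCLUDED = NA_character_,
    EXCLUDED = paste(
      "Detected HLA genotype is not associated with the predisposition to CD."
    )
  ),
  UK_BSHI = c(
    ASSOCIATED = paste(
      "Detected HLA genotype encodes the DQ2.5, DQ2.2 and/or DQ8 heterodimer",
      "and is consistent with a predisposition to CD."
    ),
    NOT_EXCLUDED = NA_character_,
    EXCLUDED = paste(
      "Detected HLA genotype does not encode the DQ2.5, DQ2.2 or DQ8 heterodimer;",
      "the individual should be excluded from a diagnosis of CD."
    )
  )
)

#' Available interpretation rule sets
#'
#' Five versioned rule sets are implemented. The Czech national
#' recommendation evolved in four steps:
#'
#' * `CZ2015` - DQ2.5 and DQ8 are predisposing; everything else excludes CD.
#' * `CZ2020` - as 2015, plus DQ2.2 alone classed as a rare risk for which
#'   the diagnosis cannot be excluded.
#' * `CZ2022` - DQ2.5, DQ2.2 and DQ8 all predisposing (the strength of the
#'   association is deliberately not graded); everything else excludes CD.
#' * `CZ2023` - the current three-category scheme: any of the three
#'   heterodimers is ASSOCIATED; DQA1*05 without a complete heterodimer is
#'   NOT_EXCLUDED (rare confirmed cases carry only DQA1*05); everything
#'   else is EXCLUDED.
#'
#' `UK_BSHI` implements the UK NEQAS/BSHI position, which differs from
#' CZ2023 only in excluding CD for DQA1*05-only genotypes.
#'
#' @return A tibble with columns `ruleset`, `year`, `origin`,
#'   `categories` (number of reachable categories) and `reconstructed_text`
#'   (TRUE where the exact interpretation wording is not documented verbatim
#'   and has been reconstructed around published fragments).
#' @export
rule_sets <- function() {
  tibble::tibble(
    ruleset = c("CZ2015", "CZ2020", "CZ2022", "CZ2023", "UK_BSHI"),
    year = c(2015L, 2020L, 2022L, 2023L, 2023L),
    origin = c(
      "Czech national recommendation",
      "Czech national recommendation",
      "Czech national recommendation",
      "Czech national recommendation",
      "UK NEQAS / BSHI guideline"
    ),
    categories = c(2L, 3L, 2L, 3L, 2L),
    reconstructed_text = c(TRUE, TRUE, TRUE, FALSE, TRUE)
  )
}

assert_ruleset <- function(ruleset) {
  if (!is.character(ruleset) || length(ruleset) != 1 ||
      !ruleset %in% rule_sets()$ruleset) {
    stop(
      "unknown rule set; expected one of: ",
      paste(rule_sets()$ruleset, collapse = ", "),
      call. = FALSE
    )
  }
  invisible(ruleset)
}
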