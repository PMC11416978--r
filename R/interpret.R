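#' Detect CD-predisposing DQ heterodimers in unphased genotypes
#'
#' Works sample-wise on a genotype table with one row per individual and
#' two allele columns per locus. Detection is deliberately phase-agnostic:
#' the recommendation defines the heterodimers by allele co-presence in the
#' genotype, so cis and trans encoded dimers count equally.
#'
#' * DQ2.5: some DQA1 allele in group `DQA1*05` and some DQB1 allele in
#'   group `DQB1*02`.
#' * DQ2.2: `DQB1*02` plus `DQA1*02`, *without* any `DQA1*05` (the DQA1*05
#'   qualifier makes DQ2.5 take precedence).
#' * DQ8: `DQB1*03:02` plus `DQA1*03`.
#'
#' A DQB1 allele typed only as `DQB1*03` cannot be distinguished between
#' the predisposing `*03:02` and the non-predisposing `*03:03`; such rows
#' get an "insufficient resolution" warning and `NA` wherever the call
#' cannot be made (or an error, with `insufficient = "error"`).
#'
#' @param genotypes A data frame with columns `sample_id`, `dqa1_1`,
#'   `dqa1_2`, `dqb1_1`, `dqb1_2`. A blank/`NA` second allele at a locus is
#'   treated as homozygous for the first.
#' @param insufficient How to handle DQB1*03 typed without a second field:
#'   `"warn"` (default; flag and propagate `NA`) or `"error"`.
#' @return The input tibble with normalized allele columns plus logical
#'   columns `has_dqa1_02`, `has_dqa1_03`, `has_dqa1_05`, `has_dqb1_02`,
#'   `has_dqb1_0302`, the heterodimer indicators `dq25`, `dq22`, `dq8`, and
#'   a `warnings` list column.
#' @examples
#' g <- tibble::tibble(
#'   sample_id = "S1",
#'   dqa1_1 = "DQA1*05:01", dqa1_2 = "DQA1*03:01",
#'   dqb1_1 = "DQB1*02:01", dqb1_2 = "DQB1*03:02"
#' )
#' detect_heterodimers(g)[, c("dq25", "dq22", "dq8")]
#' @export
detect_heterodimers <- function(genotypes, insufficient = c("warn", "error")) {
  insufficient <- match.arg(insufficient)
  g <- validate_genotypes(genotypes)

  ambiguous_b <- function(b) b == "DQB1*03"
  amb1 <- ambiguous_b(g$dqb1_1)
  amb2 <- ambiguous_b(g$dqb1_2)
  if (any(amb1 | amb2)) {
    msg <- paste0(
      "insufficient resolution: DQB1*03 without a second field cannot be ",
      "distinguished between *03:02 and *03:03 (samples: ",
      paste(g$sample_id[amb1 | amb2], collapse = ", "), ")"
    )
    if (insufficient == "error") stop(msg, call. = FALSE)
  }

  has2 <- function(a1, a2, group) {
    matches_group(a1, group) | matches_group(a2, group)
  }
  # A bare DQB1*03 contributes NA (not FALSE) to the *03:02 group call.
  m0302_1 <- ifelse(amb1, NA, matches_group(g$dqb1_1, "DQB1*03:02"))
  m0302_2 <- ifelse(amb2, NA, matches_group(g$dqb1_2, "DQB1*03:02"))

  out <- g |>
    dplyr::mutate(
      has_dqa1_02 = has2(.data$dqa1_1, .data$dqa1_2, "DQA1*02"),
      has_dqa1_03 = has2(.data$dqa1_1, .data$dqa1_2, "DQA1*03"),
      has_dqa1_05 = has2(.data$dqa1_1, .data$dqa1_2, "DQA1*05"),
      has_dqb1_02 = has2(.data$dqb1_1, .data$dqb1_2, "DQB1*02"),
      has_dqb1_0302 = m0302_1 | m0302_2,
      dq25 = .data$has_dqa1_05 & .data$has_dqb1_02,
      dq22 = .data$has_dqa1_02 & .data$has_dqb1_02 & !.data$has_dqa1_05,
      dq8 = .data$has_dqa1_03 & .data$has_dqb1_0302
    )
  out$warnings <- purrr::map(amb1 | amb2, function(a) {
    if (a) "insufficient resolution: DQB1*03 lacks a second field" else character()
  })
  out
}

#' Classify heterodimer evidence under a named rule set
#'
#' Maps the heterodimer indicators produced by [detect_heterodimers()] to
#' one of three risk categories (`ASSOCIATED` > `NOT_EXCLUDED` >
#' `EXCLUDED`) and attaches the rule set's canonical interpretation
#' sentence. See [rule_sets()] for the five rule sets.
#'
#' `strict_dqa105` controls the reading of the CZ2023 DQA1*05-only
#' category. The default (`FALSE`) assigns `NOT_EXCLUDED` whenever DQA1*05
#' is present and no complete heterodimer is formed, even if another lone
#' predisposing allele (e.g. DQB1*03:02 without DQA1*03) coexists; the
#' rare confirmed cases motivating the category were defined by positivity
#' for DQA1*05. With `strict_dqa105 = TRUE` the category is only assigned
#' when DQA1*05 is the *sole* predisposing allele present. When the two
#' readings disagree on a sample, a warning is recorded either way.
#'
#' @param heterodimers A data frame as returned by [detect_heterodimers()].
#' @param ruleset One of `"CZ2015"`, `"CZ2020"`, `"CZ2022"`, `"CZ2023"`,
#'   `"UK_BSHI"`.
#' @param strict_dqa105 Logical; strict "solely DQA1*05" reading of the
#'   CZ2023 second category (see Details).
#' @return The input with added columns `category` (ordered factor),
#'   `interpretation` (the rule set's sentence for that category) and
#'   `ruleset`; `warnings` is extended in place.
#' @export
classify_heterodimers <- function(heterodimers, ruleset = "CZ2023",
                                  strict_dqa105 = FALSE) {
  assert_ruleset(ruleset)
  h <- heterodimers
  need <- c("dq25", "dq22", "dq8", "has_dqa1_05")
  if (!all(need %in% names(h))) {
    stop(
      "input lacks heterodimer columns; run detect_heterodimers() first",
      call. = FALSE
    )
  }

  any_het <- h$dq25 | h$dq22 | h$dq8
  other_lone <- (h$has_dqa1_02 %||% FALSE) | (h$has_dqa1_03 %||% FALSE) |
    (h$has_dqb1_02 %||% FALSE) | (h$has_dqb1_0302 %||% FALSE)

  category <- switch(ruleset,
    CZ2015 = ifelse(h$dq25 | h$dq8, "ASSOCIATED", "EXCLUDED"),
    CZ2020 = dplyr::case_when(
      h$dq25 | h$dq8 ~ "ASSOCIATED",
      h$dq22 ~ "NOT_EXCLUDED",
      !(h$dq25 | h$dq8 | h$dq22) ~ "EXCLUDED",
      .default = NA_character_
    ),
    CZ2022 = ifelse(any_het, "ASSOCIATED", "EXCLUDED"),
    UK_BSHI = ifelse(any_het, "ASSOCIATED", "EXCLUDED"),
    CZ2023 = {
      dqa105_only <- if (strict_dqa105) {
        h$has_dqa1_05 & !other_lone
      } else {
        h$has_dqa1_05
      }
      dplyr::case_when(
        any_het ~ "ASSOCIATED",
        !any_het & dqa105_only ~ "NOT_EXCLUDED",
        !any_het ~ "EXCLUDED",
        .default = NA_character_
      )
    }
  )

  h$category <- risk_factor(category)
  texts <- INTERPRETATION_TEXTS[[ruleset]]
  h$interpretation <- unname(texts[category])
  h$ruleset <- ruleset

  if (ruleset == "CZ2023") {
    # Flag samples where the strict and permissive DQA1*05 readings diverge.
    divergent <- !is.na(any_het) & !any_het & h$has_dqa1_05 & other_lone
    if (any(divergent) && !is.null(h$warnings)) {
      note <- if (strict_dqa105) {
        "strict DQA1*05 reading applied: another lone predisposing allele coexists; permissive reading would give NOT_EXCLUDED"
      } else {
        "DQA1*05 coexists with another lone predisposing allele; strict 'solely DQA1*05' reading would give EXCLUDED"
      }
      h$warnings[divergent] <- purrr::map(h$warnings[divergent], c, note)
    }
  }
  na_cat <- is.na(h$category)
  if (any(na_cat) && !is.null(h$warnings)) {
    h$warnings[na_cat] <- purrr::map(
      h$warnings[na_cat], c,
      "category indeterminate at this typing resolution"
    )
  }
  h
}

#' Interpret HLA-DQ genotypes for coeliac-disease predisposition
#'
#' Composes [detect_heterodimers()] and [classify_heterodimers()]: the
#' one-call entry point from a genotype table to risk categories and
#' clinical interpretation sentences.
#'
#' @inheritParams detect_heterodimers
#' @inheritParams classify_heterodimers
#' @return A tibble: the normalized genotypes plus heterodimer indicators,
#'   `category`, `interpretation`, `ruleset` and `warnings`.
#' @examples
#' g <- tibble::tibble(
#'   sample_id = c("A", "B"),
#'   dqa1_1 = c("DQA1*05:01", "DQA1*01:01"),
#'   dqa1_2 = c("DQA1*03:01", "DQA1*01:02"),
#'   dqb1_1 = c("DQB1*02:01", "DQB1*05:01"),
#'   dqb1_2 = c("DQB1*03:02", "DQB1*06:02")
#' )
#' interpret_genotypes(g)[, c("sample_id", "category")]
#' @export
interpret_genotypes <- function(genotypes, ruleset = "CZ2023",
                                strict_dqa105 = FALSE,
                                insufficient = c("warn", "error")) {
  genotypes |>
    detect_heterodimers(insufficient = insufficient) |>
    classify_heterodimers(ruleset = ruleset, strict_dqa105 = strict_dqa105)
}

# Normalize and validate a genotype table; expands homozygotes given as a
# blank second allele.
validate_genotypes <- function(genotypes) {
  need <- c("sample_id", "dqa1_1", "dqa1_2", "dqb1_1", "dqb1_2")
  if (!is.data.frame(genotypes)) {
    stop("genotypes must be a data frame", call. = FALSE)
  }
  missing_cols <- setdiff(need, names(genotypes))
  if (length(missing_cols) > 0) {
    stop(
      "genotype table lacks column(s): ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  g <- tibble::as_tibble(genotypes)
  blank <- function(x) is.na(x) | stringr::str_trim(as.character(x)) == ""
  g$dqa1_2 <- ifelse(blank(g$dqa1_2), g$dqa1_1, g$dqa1_2)
  g$dqb1_2 <- ifelse(blank(g$dqb1_2), g$dqb1_1, g$dqb1_2)

  for (col in c("dqa1_1", "dqa1_2", "dqb1_1", "dqb1_2")) {
    locus <- toupper(substr(col, 1, 4))
    ux <- unique(as.character(g[[col]]))
    parsed <- parse_allele(ux)
    wrong <- parsed$locus != locus
    if (any(wrong)) {
      stop(
        "allele \"", parsed$raw[wrong][1], "\" in column ", col,
        " belongs to locus ", parsed$locus[wrong][1], ", expected ", locus,
        call. = FALSE
      )
    }
    g[[col]] <- parsed$allele[match(as.character(g[[col]]), ux)]
  }
  g
}
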