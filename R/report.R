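#' Assemble clinical reports from interpretation results
#'
#' A complete clinical report for an HLA-DQ coeliac-disease test carries
#' three elements, each always present (as an explicit negative where
#' nothing was found):
#'
#' 1. the detected DQA1/DQB1 alleles or allele groups that predispose to CD
#'    (only alleles matching the required detection set DQA1*02, *03, *05,
#'    DQB1*02, DQB1*03:02 are listed);
#' 2. presence or absence of the serological equivalents DQ2.5, DQ2.2 and
#'    DQ8 (when DQA1*05 co-occurs with DQA1*02 and DQB1*02, DQ2.5 is
#'    reported present and DQ2.2 absent, per the "without DQA1*05"
#'    qualifier);
#' 3. the clinical interpretation sentence of the active rule set.
#'
#' @param results A tibble from [interpret_genotypes()] (allele columns
#'   must still be present).
#' @return A tibble with columns `sample_id`, `predisposing_alleles` (list
#'   column; character(0) when none), `dq2_5`, `dq2_2`, `dq8` (each
#'   `"present"`/`"absent"`, or `"indeterminate"` when typing resolution
#'   was insufficient), `category`, `interpretation`, `ruleset` and
#'   `warnings`.
#' @export
build_report <- function(results) {
  need <- c(
    "sample_id", "dqa1_1", "dqa1_2", "dqb1_1", "dqb1_2",
    "dq25", "dq22", "dq8", "category", "interpretation", "ruleset"
  )
  missing_cols <- setdiff(need, names(results))
  if (length(missing_cols) > 0) {
    stop(
      "results lack column(s): ", paste(missing_cols, collapse = ", "),
      "; run interpret_genotypes() first",
      call. = FALSE
    )
  }

  predisposing <- purrr::pmap(
    results[c("dqa1_1", "dqa1_2", "dqb1_1", "dqb1_2")],
    function(dqa1_1, dqa1_2, dqb1_1, dqb1_2) {
      alleles <- unique(c(dqa1_1, dqa1_2, dqb1_1, dqb1_2))
      hit <- purrr::map_lgl(alleles, function(a) {
        isTRUE(any(matches_group(a, REQUIRED_GROUPS)))
      })
      alleles[hit]
    }
  )

  presence <- function(x) {
    dplyr::case_when(is.na(x) ~ "indeterminate", x ~ "present", !x ~ "absent")
  }

  tibble::tibble(
    sample_id = results$sample_id,
    predisposing_alleles = predisposing,
    dq2_5 = presence(results$dq25),
    dq2_2 = presence(results$dq22),
    dq8 = presence(results$dq8),
    category = results$category,
    interpretation = results$interpretation,
    ruleset = results$ruleset,
    warnings = results$warnings %||% purrr::map(results$sample_id, ~character())
  )
}

#' Write clinical reports as JSON
#'
#' One JSON object per sample, in an array. The rendering is pipe-safe:
#' nothing but the JSON goes to the connection.
#'
#' @param reports A tibble from [build_report()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_reports_json <- function(reports, path) {
  objs <- purrr::pmap(reports, function(sample_id, predisposing_alleles,
                                        dq2_5, dq2_2, dq8, category,
                                        interpretation, ruleset, warnings) {
    list(
      sample_id = sample_id,
      predisposing_alleles = as.list(predisposing_alleles),
      serological_equivalents = list(
        dq2_5 = dq2_5, dq2_2 = dq2_2, dq8 = dq8
      ),
      category = as.character(category),
      interpretation = interpretation,
      ruleset = ruleset,
      warnings = as.list(warnings)
    )
  })
  jsonlite::write_json(objs, path, auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(path)
}

#' Render clinical reports as plain text
#'
#' @param reports A tibble from [build_report()].
#' @return A character vector, one multi-line block per sample.
#' @export
format_report_text <- function(reports) {
  purrr::pmap_chr(reports, function(sample_id, predisposing_alleles,
                                    dq2_5, dq2_2, dq8, category,
                                    interpretation, ruleset, warnings) {
    alleles <- if (length(predisposing_alleles) == 0) {
      "none detected"
    } else {
      paste(predisposing_alleles, collapse = ", ")
    }
    paste0(
      "Sample: ", sample_id, "\n",
      "Predisposing alleles/allele groups: ", alleles, "\n",
      "Serological equivalents: DQ2.5 ", dq2_5, ", DQ2.2 ", dq2_2,
      ", DQ8 ", dq8, "\n",
      "Interpretation (", ruleset, "): ",
      ifelse(is.na(interpretation), "indeterminate", interpretation),
      if (length(warnings) > 0) {
        paste0("\nWarnings: ", paste(warnings, collapse = "; "))
      } else {
        ""
      }
    )
  })
}
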