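#' Simulate an EPT reference panel from haplotype frequencies
#'
#' Draws unphased DQA1/DQB1 genotypes by sampling two haplotypes per
#' individual independently from the frequency table (random mating /
#' Hardy-Weinberg), the sampling scheme an external proficiency testing
#' (EPT) organiser would use to assemble a reference panel representative
#' of the population. Group-level haplotype labels are expanded to
#' two-field reference alleles (e.g. `DQA1*05` becomes `DQA1*05:01`),
#' mirroring reference genotypes obtained by high-resolution typing.
#'
#' Panels containing rare haplotypes are the ones laboratories most often
#' get wrong, so `rare_enrichment` lets a fraction of samples be forced to
#' carry at least one haplotype from the low-frequency stratum
#' (`frequency < rare_threshold`), as organisers deliberately include such
#' samples.
#'
#' @param table A haplotype-frequency tibble ([read_frequency_table()]).
#'   Frequencies are renormalized to sum to 1.
#' @param n_samples Number of reference samples (>= 1).
#' @param rare_enrichment Fraction of samples (in \[0, 1\]) forced to carry
#'   a rare haplotype.
#' @param seed Integer seed; the same seed always yields the same panel.
#' @param ruleset Rule set under which the reference category is computed.
#' @param rare_threshold Haplotype frequency below which a haplotype counts
#'   as rare (default 0.05).
#' @return A tibble with one row per sample: the genotype columns, the two
#'   drawn haplotype labels (`hap1`, `hap2`), `carrier` (carries at least
#'   one predisposing haplotype), `rare_haplotype`, `true_category` and
#'   `ruleset`.
#' @examples
#' generate_panel(czech_frequencies(), n_samples = 5, seed = 1)
#' @export
generate_panel <- function(table, n_samples, rare_enrichment = 0,
                           seed = NULL, ruleset = "CZ2023",
                           rare_threshold = 0.05) {
  validate_frequency_table(table)
  assert_ruleset(ruleset)
  if (!is.numeric(n_samples) || n_samples < 1) {
    stop("n_samples must be at least 1", call. = FALSE)
  }
  n_samples <- as.integer(n_samples)
  if (!is.numeric(rare_enrichment) || rare_enrichment < 0 || rare_enrichment > 1) {
    stop("rare_enrichment must be a proportion in [0, 1]", call. = FALSE)
  }
  if (!is.null(seed)) withr::local_seed(seed)

  p <- table$frequency / sum(table$frequency)
  k <- nrow(table)
  h1 <- sample.int(k, n_samples, replace = TRUE, prob = p)
  h2 <- sample.int(k, n_samples, replace = TRUE, prob = p)

  rare_idx <- which(p < rare_threshold)
  n_rare <- floor(rare_enrichment * n_samples)
  if (n_rare > 0) {
    if (length(rare_idx) == 0) {
      stop("rare_enrichment requested but no haplotype is below the rare threshold",
        call. = FALSE
      )
    }
    enriched <- sample.int(n_samples, n_rare)
    h1[enriched] <- rare_idx[
      sample.int(length(rare_idx), n_rare,
        replace = TRUE,
        prob = p[rare_idx] / sum(p[rare_idx])
      )
    ]
  }

  dqa1 <- expand_reference_allele(table$dqa1)
  dqb1 <- expand_reference_allele(table$dqb1)
  hap <- paste0(table$dqa1, "~", table$dqb1)

  panel <- tibble::tibble(
    sample_id = sprintf("S%05d", seq_len(n_samples)),
    dqa1_1 = dqa1[h1], dqa1_2 = dqa1[h2],
    dqb1_1 = dqb1[h1], dqb1_2 = dqb1[h2],
    hap1 = hap[h1], hap2 = hap[h2],
    carrier = table$predisposing[h1] | table$predisposing[h2],
    rare_haplotype = p[h1] < rare_threshold | p[h2] < rare_threshold
  )
  res <- interpret_genotypes(panel[1:5], ruleset = ruleset)
  panel$true_category <- as.character(res$category)
  panel$ruleset <- ruleset
  panel
}

# Expand a group-level haplotype allele to a representative two-field
# reference allele (first subtype: ":01").
expand_reference_allele <- function(x) {
  parsed <- parse_allele(x)
  ifelse(n_fields(parsed$allele) >= 2, parsed$allele,
    paste0(parsed$allele, ":01")
  )
}

#' Define a laboratory error model
#'
#' Two error modes observed in proficiency testing are modelled:
#'
#' * **miscalls** — a carried allele in `from` is reported as `to` with
#'   probability `prob`, applied independently per matching allele slot.
#'   The recurring real-world example is reporting DQB1*03:02 (predisposing)
#'   in carriers of DQB1*03:03 (not associated with disease).
#' * **dropouts** — a carried allele in `group` is missed with probability
#'   `prob`; the sample is then reported homozygous for the other allele at
#'   that locus.
#'
#' @param miscalls A data frame with columns `from`, `to` (allele groups at
#'   the same locus) and `prob`, or `NULL`.
#' @param dropouts A data frame with columns `group` and `prob`, or `NULL`.
#' @return An object of class `hladq_error_model`.
#' @examples
#' error_model(miscalls = data.frame(
#'   from = "DQB1*03:03", to = "DQB1*03:02", prob = 0.1
#' ))
#' @export
error_model <- function(miscalls = NULL, dropouts = NULL) {
  norm_rules <- function(df, cols) {
    if (is.null(df)) {
      return(tibble::as_tibble(stats::setNames(
        c(rep(list(character()), length(cols) - 1), list(numeric())), cols
      )))
    }
    df <- tibble::as_tibble(df)
    stopifnot(all(cols %in% names(df)))
    for (cc in setdiff(cols, "prob")) df[[cc]] <- normalize_allele(df[[cc]])
    if (any(is.na(df$prob) | df$prob < 0 | df$prob > 1)) {
      stop("error-model probabilities must lie in [0, 1]", call. = FALSE)
    }
    df[cols]
  }
  miscalls <- norm_rules(miscalls, c("from", "to", "prob"))
  if (nrow(miscalls) > 0) {
    same_locus <- parse_allele(miscalls$from)$locus == parse_allele(miscalls$to)$locus
    if (!all(same_locus)) {
      stop("miscall rules must stay within one locus", call. = FALSE)
    }
  }
  structure(
    list(
      miscalls = miscalls,
      dropouts = norm_rules(dropouts, c("group", "prob"))
    ),
    class = "hladq_error_model"
  )
}

#' Simulate one laboratory's EPT submission
#'
#' Applies an error model to the reference panel: each rule fires
#' independently per sample per matching allele slot with its stated
#' probability. The reported clinical interpretation is then recomputed
#' from the (possibly corrupted) genotype, so a genotyping miscall
#' propagates into an interpretation error — exactly the failure mode seen
#' in practice, where a false DQB1*03:02 call flips the clinical category.
#'
#' @param panel A reference panel from [generate_panel()].
#' @param model An [error_model()].
#' @param lab_id Identifier of the simulated laboratory.
#' @param method Typing method label, one of `"PCR-SSP"`, `"RT-PCR"`,
#'   `"SSO"`, `"SANGER"`, `"NGS"`.
#' @param seed Optional integer seed for the corruption draws.
#' @param ruleset Rule set used for the reported interpretation (defaults
#'   to the panel's).
#' @return A submission tibble: `lab_id`, `method`, `sample_id`, reported
#'   genotype columns, `reported_category` and `reported_interpretation`.
#' @export
apply_error_model <- function(panel, model, lab_id = "LAB1",
                              method = c("PCR-SSP", "RT-PCR", "SSO", "SANGER", "NGS"),
                              seed = NULL, ruleset = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(model, "hladq_error_model"))
  ruleset <- ruleset %||% panel$ruleset[1] %||% "CZ2023"
  if (!is.null(seed)) withr::local_seed(seed)

  rep_g <- panel[c("sample_id", "dqa1_1", "dqa1_2", "dqb1_1", "dqb1_2")]
  n <- nrow(rep_g)
  slot_cols <- list(
    DQA1 = c("dqa1_1", "dqa1_2"),
    DQB1 = c("dqb1_1", "dqb1_2")
  )

  for (r in seq_len(nrow(model$miscalls))) {
    from <- model$miscalls$from[r]
    to <- model$miscalls$to[r]
    prob <- model$miscalls$prob[r]
    locus <- parse_allele(from)$locus
    for (col in slot_cols[[locus]]) {
      hit <- matches_group(rep_g[[col]], from) & stats::runif(n) < prob
      if (any(hit)) {
        rep_g[[col]][hit] <- substitute_group(rep_g[[col]][hit], to)
      }
    }
  }
  for (r in seq_len(nrow(model$dropouts))) {
    grp <- model$dropouts$group[r]
    prob <- model$dropouts$prob[r]
    locus <- parse_allele(grp)$locus
    cols <- slot_cols[[locus]]
    for (ci in 1:2) {
      col <- cols[ci]
      other <- cols[3 - ci]
      hit <- matches_group(rep_g[[col]], grp) & stats::runif(n) < prob
      if (any(hit)) rep_g[[col]][hit] <- rep_g[[other]][hit]
    }
  }

  res <- interpret_genotypes(rep_g, ruleset = ruleset)
  tibble::tibble(
    lab_id = lab_id,
    method = method,
    sample_id = rep_g$sample_id,
    dqa1_1 = rep_g$dqa1_1, dqa1_2 = rep_g$dqa1_2,
    dqb1_1 = rep_g$dqb1_1, dqb1_2 = rep_g$dqb1_2,
    reported_category = as.character(res$category),
    reported_interpretation = res$interpretation
  )
}

# Replace the leading fields of alleles by those of a (same-locus) group:
# substitute_group("DQB1*03:03", "DQB1*03:02") -> "DQB1*03:02".
substitute_group <- function(allele, group) {
  a <- parse_allele(allele)
  g <- parse_allele(rep_len(group, nrow(a)))
  purrr::pmap_chr(
    list(a$locus, a$fields, g$fields),
    function(locus, af, gf) {
      k <- length(gf)
      rest <- if (length(af) > k) af[(k + 1):length(af)] else character()
      format_allele(locus, c(gf, rest))
    }
  )
}

#' Score one laboratory's submission against the reference panel
#'
#' Genotype correctness is judged at the scheme's required resolution
#' only: a submission is genotype-correct for a sample iff it agrees with
#' the reference on the presence/absence of each of the five required
#' allele groups (DQA1*02, *03, *05; DQB1*02; DQB1*03:02). Extra or
#' differing detail beyond those groups (e.g. DQA1*05:05 vs DQA1*05:01) is
#' never penalized. Interpretation correctness is a category match under
#' the stated rule set. A panel sample missing from the submission scores
#' false on both. The per-sample binary scheme (genotype, interpretation)
#' is this package's own scoring definition.
#'
#' @param panel A reference panel from [generate_panel()].
#' @param submission A submission tibble ([apply_error_model()] or read
#'   from file).
#' @param ruleset Rule set for interpretation scoring (defaults to the
#'   panel's).
#' @return A tibble with one row per panel sample: `lab_id`, `method`,
#'   `sample_id`, `genotype_correct`, `interpretation_correct` and a
#'   `discrepancies` list column of tibbles (`group`, `expected`,
#'   `reported`).
#' @export
score_submission <- function(panel, submission, ruleset = NULL) {
  ruleset <- ruleset %||% panel$ruleset[1] %||% "CZ2023"
  assert_ruleset(ruleset)
  extra <- setdiff(submission$sample_id, panel$sample_id)
  if (length(extra) > 0) {
    stop(
      "submission contains sample id(s) not on the panel: ",
      paste(extra, collapse = ", "),
      call. = FALSE
    )
  }
  if (anyDuplicated(submission$sample_id) > 0) {
    stop("submission reports a sample more than once", call. = FALSE)
  }

  true_cat <- as.character(
    interpret_genotypes(
      panel[c("sample_id", "dqa1_1", "dqa1_2", "dqb1_1", "dqb1_2")],
      ruleset = ruleset
    )$category
  )
  true_pres <- required_group_presence(panel)

  idx <- match(panel$sample_id, submission$sample_id)
  answered <- !is.na(idx)
  sub_row <- submission[idx[answered], , drop = FALSE]
  rep_pres <- required_group_presence(sub_row)

  rep_cat <- if ("reported_category" %in% names(submission)) {
    submission$reported_category[idx]
  } else {
    # No category column: derive the lab's interpretation from its genotype.
    out <- rep(NA_character_, nrow(panel))
    out[answered] <- as.character(
      interpret_genotypes(sub_row, ruleset = ruleset)$category
    )
    out
  }

  n <- nrow(panel)
  genotype_correct <- logical(n)
  interpretation_correct <- logical(n)
  discrepancies <- vector("list", n)
  ai <- 0L
  for (i in seq_len(n)) {
    if (!answered[i]) {
      genotype_correct[i] <- FALSE
      interpretation_correct[i] <- FALSE
      discrepancies[[i]] <- tibble::tibble(
        group = REQUIRED_GROUPS,
        expected = true_pres[i, ],
        reported = NA
      )
      next
    }
    ai <- ai + 1L
    diff <- which(true_pres[i, ] != rep_pres[ai, ])
    genotype_correct[i] <- length(diff) == 0
    interpretation_correct[i] <- !is.na(rep_cat[i]) &&
      !is.na(true_cat[i]) && rep_cat[i] == true_cat[i]
    discrepancies[[i]] <- tibble::tibble(
      group = REQUIRED_GROUPS[diff],
      expected = true_pres[i, diff],
      reported = rep_pres[ai, diff]
    )
  }

  tibble::tibble(
    lab_id = submission$lab_id[1] %||% NA_character_,
    method = submission$method[1] %||% NA_character_,
    sample_id = panel$sample_id,
    genotype_correct = genotype_correct,
    interpretation_correct = interpretation_correct,
    discrepancies = discrepancies
  )
}

# Presence matrix (samples x required groups) for a genotype table.
required_group_presence <- function(g) {
  out <- matrix(FALSE, nrow(g), length(REQUIRED_GROUPS),
    dimnames = list(NULL, REQUIRED_GROUPS)
  )
  for (j in seq_along(REQUIRED_GROUPS)) {
    grp <- REQUIRED_GROUPS[j]
    cols <- if (startsWith(grp, "DQA1")) c("dqa1_1", "dqa1_2") else c("dqb1_1", "dqb1_2")
    out[, j] <- matches_group(g[[cols[1]]], grp) | matches_group(g[[cols[2]]], grp)
  }
  out
}

#' Aggregate per-sample scores into a method-stratified cohort summary
#'
#' A laboratory counts as erroneous if at least one of its samples is
#' wrong on genotype or on interpretation (proficiency schemes typically
#' report a single error flag per lab). A lab that used several methods
#' appears once per method. Sub-rates for genotype-only and
#' interpretation-only errors are also reported.
#'
#' @param scores Row-bound per-sample scores from [score_submission()]
#'   (columns `lab_id`, `method`, `genotype_correct`,
#'   `interpretation_correct`).
#' @return A tibble of class `hladq_ept_summary` with one row per method:
#'   `labs_n`, `labs_with_error_n`, `error_rate` (percent, one decimal,
#'   half-up), plus `genotype_error_rate` and `interpretation_error_rate`.
#' @examples
#' # 19 labs, the first 3 each with one wrong sample: 15.8% error rate
#' scores <- tibble::tibble(
#'   lab_id = rep(sprintf("L%02d", 1:19), each = 5),
#'   method = "PCR-SSP",
#'   sample_id = rep(sprintf("S%d", 1:5), 19),
#'   genotype_correct = !(rep(1:19, each = 5) <= 3 & rep(1:5, 19) == 1),
#'   interpretation_correct = TRUE
#' )
#' aggregate_cohort(scores)
#' @export
aggregate_cohort <- function(scores) {
  if (nrow(scores) == 0) stop("no scores to aggregate", call. = FALSE)
  per_lab <- scores |>
    dplyr::group_by(.data$method, .data$lab_id) |>
    dplyr::summarise(
      any_genotype_error = any(!.data$genotype_correct),
      any_interpretation_error = any(!.data$interpretation_correct),
      any_error = any(!.data$genotype_correct | !.data$interpretation_correct),
      .groups = "drop"
    )
  out <- per_lab |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(
      labs_n = dplyr::n(),
      labs_with_error_n = sum(.data$any_error),
      error_rate = round_half_up(100 * sum(.data$any_error) / dplyr::n(), 1),
      genotype_error_rate = round_half_up(
        100 * sum(.data$any_genotype_error) / dplyr::n(), 1
      ),
      interpretation_error_rate = round_half_up(
        100 * sum(.data$any_interpretation_error) / dplyr::n(), 1
      ),
      .groups = "drop"
    )
  class(out) <- c("hladq_ept_summary", class(out))
  out
}

#' Run a full seeded EPT round: simulate, corrupt, score, summarize
#'
#' Convenience pipeline reproducing one proficiency-testing round
#' end-to-end. Each laboratory receives the same reference panel; its
#' submission is corrupted under its own error model (or a shared one) with
#' a per-lab seed derived from the master seed, then scored and aggregated
#' by method. The whole run is reproducible bit-for-bit for a fixed seed.
#'
#' @param table Haplotype-frequency tibble.
#' @param n_samples Panel size (proficiency rounds typically use 5).
#' @param labs A tibble with columns `lab_id`, `method`, and optionally a
#'   `model` list column of per-lab [error_model()]s.
#' @param model Shared [error_model()] for labs without their own.
#' @param seed Master integer seed.
#' @param ruleset Interpretation rule set.
#' @param rare_enrichment Passed to [generate_panel()].
#' @return A list with elements `panel`, `submissions`, `scores`,
#'   `summary`.
#' @export
simulate_ept <- function(table, n_samples, labs, model = error_model(),
                         seed = 1L, ruleset = "CZ2023",
                         rare_enrichment = 0) {
  stopifnot(all(c("lab_id", "method") %in% names(labs)))
  panel <- generate_panel(table, n_samples,
    rare_enrichment = rare_enrichment,
    seed = seed, ruleset = ruleset
  )
  submissions <- purrr::map(seq_len(nrow(labs)), function(i) {
    lab_model <- if ("model" %in% names(labs)) {
      labs$model[[i]] %||% model
    } else {
      model
    }
    apply_error_model(
      panel, lab_model,
      lab_id = labs$lab_id[i], method = labs$method[i],
      seed = derive_seed(seed, i), ruleset = ruleset
    )
  })
  scores <- purrr::map(submissions, function(s) {
    score_submission(panel, s, ruleset = ruleset)
  }) |>
    dplyr::bind_rows()
  list(
    panel = panel,
    submissions = dplyr::bind_rows(submissions),
    scores = scores,
    summary = aggregate_cohort(scores)
  )
}
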