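#' Read a DQA1~DQB1 haplotype-frequency table
#'
#' Delimited text with header `dqa1,dqb1,frequency,predisposing`:
#' group-level allele names, population frequency as a proportion, and a
#' logical flag marking the CD-predisposing haplotypes. Frequencies must be
#' non-negative and sum to at most 1 (the table may be partial).
#'
#' @param path Path to a delimited text file.
#' @return A tibble with normalized group names and an added `haplotype`
#'   label column (`"DQA1*05~DQB1*02"` style).
#' @seealso [czech_frequencies()] for the packaged Czech table.
#' @export
read_frequency_table <- function(path) {
  if (!file.exists(path)) stop("cannot read frequency table: ", path, call. = FALSE)
  raw <- read_delim_auto(path)
  need <- c("dqa1", "dqb1", "frequency", "predisposing")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    stop(
      "frequency table lacks column(s): ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  tbl <- tibble::tibble(
    dqa1 = normalize_allele(raw$dqa1),
    dqb1 = normalize_allele(raw$dqb1),
    frequency = as.numeric(raw$frequency),
    predisposing = as.logical(raw$predisposing)
  )
  validate_frequency_table(tbl)
  tbl$haplotype <- paste0(tbl$dqa1, "~", tbl$dqb1)
  tbl
}

#' Write a haplotype-frequency table to delimited text
#'
#' Lossless counterpart of [read_frequency_table()].
#'
#' @param table A frequency tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_frequency_table <- function(table, path) {
  validate_frequency_table(table)
  write_delim_auto(
    table[, c("dqa1", "dqb1", "frequency", "predisposing")], path
  )
}

validate_frequency_table <- function(tbl) {
  if (nrow(tbl) == 0) stop("frequency table is empty", call. = FALSE)
  if (anyNA(tbl$frequency) || any(tbl$frequency < 0)) {
    stop("haplotype frequencies must be non-negative numbers", call. = FALSE)
  }
  if (sum(tbl$frequency) > 1 + 1e-9) {
    stop(
      "haplotype frequencies sum to ", format(sum(tbl$frequency)),
      "; must not exceed 1",
      call. = FALSE
    )
  }
  if (anyNA(tbl$predisposing)) {
    stop("'predisposing' must be TRUE/FALSE for every row", call. = FALSE)
  }
  wrong_a <- parse_allele(tbl$dqa1)$locus != "DQA1"
  wrong_b <- parse_allele(tbl$dqb1)$locus != "DQB1"
  if (any(wrong_a) || any(wrong_b)) {
    stop("haplotype columns must contain DQA1 and DQB1 groups respectively",
      call. = FALSE
    )
  }
  invisible(tbl)
}

#' The packaged Czech haplotype-frequency table
#'
#' Loads the frequency table shipped with the package. The three
#' CD-predisposing haplotypes carry the published Czech population
#' frequencies (DQA1*05~DQB1*02 9.2%, DQA1*02~DQB1*02 8.3%,
#' DQA1*03~DQB1*03:02 6.9%, together 24.4%). The non-predisposing
#' remainder is a synthetic decomposition of the residual 75.6% across
#' common neutral haplotypes — including DQA1*03~DQB1*03:03 (the recurring
#' miscall target) and DQA1*05~DQB1*03:01 (a DQA1*05 carrier outside the
#' risk set) — chosen to exercise every interpretation category; only the
#' predisposing rows are published values.
#'
#' @return A frequency tibble (see [read_frequency_table()]).
#' @examples
#' sum(czech_frequencies()$frequency)
#' @export
czech_frequencies <- function() {
  read_frequency_table(
    system.file("extdata", "czech_haplotype_frequencies.csv",
      package = "hladq", mustWork = TRUE
    )
  )
}

#' Total frequency of CD-predisposing haplotypes
#'
#' @param table A frequency tibble.
#' @return The sum of `frequency` over rows flagged `predisposing`, as a
#'   proportion.
#' @examples
#' total_predisposing_frequency(czech_frequencies()) # 0.244
#' @export
total_predisposing_frequency <- function(table) {
  validate_frequency_table(table)
  sum(table$frequency[table$predisposing])
}

#' Carrier proportion under Hardy-Weinberg equilibrium
#'
#' For a haplotype class of total frequency `f`, the proportion of
#' individuals carrying at least one such haplotype under random mating is
#' `1 - (1 - f)^2`. With the Czech predisposing total of 24.4% this gives
#' 0.4285, i.e. approximately 43% of the population carries at least one
#' predisposing haplotype.
#'
#' @param f Haplotype-class frequency (proportion in \[0, 1\]); vectorized.
#' @return Carrier proportion(s) in \[0, 1\].
#' @examples
#' carrier_frequency_hwe(0.244)
#' @export
carrier_frequency_hwe <- function(f) {
  if (!is.numeric(f) || anyNA(f) || any(f < 0 | f > 1)) {
    stop("haplotype frequency must be within [0, 1]", call. = FALSE)
  }
  1 - (1 - f)^2
}

#' Predictive values of the HLA test
#'
#' Standard Bayesian 2x2 arithmetic for a carrier-based test. Given the
#' disease prevalence, the test sensitivity (the proportion of patients
#' carrying a predisposing genotype) and the overall population carrier
#' frequency, the carrier frequency among unaffected controls is
#' `(carrier - prevalence * sensitivity) / (1 - prevalence)`, and
#'
#' \deqn{NPV = \frac{(1-p)(1-c)}{(1-p)(1-c) + p(1-se)}, \quad
#'       PPV = \frac{p \cdot se}{p \cdot se + (1-p) c}}
#'
#' with `p` prevalence, `se` sensitivity and `c` the control carrier
#' frequency. The HLA test owes its clinical value to the high NPV:
#' absence of the predisposing variants virtually excludes coeliac
#' disease, while the PPV is low because carriers are common.
#'
#' @param prevalence Disease prevalence (proportion; ~0.01 for coeliac
#'   disease in Western countries).
#' @param sensitivity Proportion of patients who carry a predisposing
#'   genotype. Default 0.99: the number of confirmed patients without the
#'   predisposing variants is very small, but no exact published figure
#'   exists, so this is an explicit, documented assumption.
#' @param carrier_freq_population Overall carrier proportion in the
#'   population (~0.43 for the Czech predisposing set).
#' @return A one-row tibble of class `hladq_pv` with columns `prevalence`,
#'   `sensitivity`, `carrier_freq_population`, `carrier_freq_controls`,
#'   `npv` and `ppv`.
#' @examples
#' predictive_values(0.01, 0.99, 0.43)
#' @export
predictive_values <- function(prevalence, sensitivity = 0.99,
                              carrier_freq_population) {
  for (v in list(prevalence, sensitivity, carrier_freq_population)) {
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1) {
      stop("all inputs must be single proportions in [0, 1]", call. = FALSE)
    }
  }
  if (prevalence * sensitivity > carrier_freq_population + 1e-12) {
    stop(
      "inconsistent inputs: prevalence * sensitivity exceeds the population ",
      "carrier frequency",
      call. = FALSE
    )
  }
  carrier_controls <- if (prevalence < 1) {
    (carrier_freq_population - prevalence * sensitivity) / (1 - prevalence)
  } else {
    0
  }
  neg_healthy <- (1 - prevalence) * (1 - carrier_controls)
  neg_diseased <- prevalence * (1 - sensitivity)
  npv <- if (neg_healthy + neg_diseased > 0) {
    neg_healthy / (neg_healthy + neg_diseased)
  } else {
    1
  }
  pos_diseased <- prevalence * sensitivity
  pos_healthy <- (1 - prevalence) * carrier_controls
  ppv <- if (pos_diseased + pos_healthy > 0) {
    pos_diseased / (pos_diseased + pos_healthy)
  } else {
    0
  }
  out <- tibble::tibble(
    prevalence = prevalence,
    sensitivity = sensitivity,
    carrier_freq_population = carrier_freq_population,
    carrier_freq_controls = carrier_controls,
    npv = npv,
    ppv = ppv
  )
  class(out) <- c("hladq_pv", class(out))
  out
}
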