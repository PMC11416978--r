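# Shared test helpers: a brute-force reference classifier written
# independently of the package's vectorized implementation, and an
# enumerator of the two-allele-per-locus genotype universe.

# Allele universe used for exhaustive rule checks: every DQA1 first-field
# group relevant to the rules plus a neutral one, and the DQB1 groups that
# the rules and the known miscall confusions involve.
UNIVERSE_DQA1 <- c("DQA1*01", "DQA1*02", "DQA1*03", "DQA1*05")
UNIVERSE_DQB1 <- c(
  "DQB1*02", "DQB1*03:01", "DQB1*03:02", "DQB1*03:03",
  "DQB1*05", "DQB1*06"
)

# All unordered pairs (with repetition) from a vector.
unordered_pairs <- function(x) {
  idx <- which(upper.tri(matrix(TRUE, length(x), length(x)), diag = TRUE),
    arr.ind = TRUE
  )
  data.frame(a = x[idx[, 1]], b = x[idx[, 2]], stringsAsFactors = FALSE)
}

# Every two-allele-per-locus genotype over the universe (210 genotypes).
enumerate_genotypes <- function() {
  qa <- unordered_pairs(UNIVERSE_DQA1)
  qb <- unordered_pairs(UNIVERSE_DQB1)
  grid <- expand.grid(ia = seq_len(nrow(qa)), ib = seq_len(nrow(qb)))
  tibble::tibble(
    sample_id = sprintf("G%03d", seq_len(nrow(grid))),
    dqa1_1 = qa$a[grid$ia], dqa1_2 = qa$b[grid$ia],
    dqb1_1 = qb$a[grid$ib], dqb1_2 = qb$b[grid$ib]
  )
}

# Scalar reference classifier: plain, loop-free re-statement of each rule
# set from first principles, sharing no code with the package.
oracle_classify <- function(a1, a2, b1, b2, ruleset, strict = FALSE) {
  first_field <- function(x) sub("^DQ[AB]1\\*([0-9]+).*$", "\\1", x)
  a_first <- c(first_field(a1), first_field(a2))
  b_first <- c(first_field(b1), first_field(b2))
  bs <- c(b1, b2)

  has_a02 <- "02" %in% a_first
  has_a03 <- "03" %in% a_first
  has_a05 <- "05" %in% a_first
  has_b02 <- "02" %in% b_first
  has_b0302 <- any(bs == "DQB1*03:02" | startsWith(bs, "DQB1*03:02:"))

  dq25 <- has_a05 && has_b02
  dq22 <- has_a02 && has_b02 && !has_a05
  dq8 <- has_a03 && has_b0302
  any_het <- dq25 || dq22 || dq8

  if (ruleset == "CZ2015") {
    if (dq25 || dq8) "ASSOCIATED" else "EXCLUDED"
  } else if (ruleset == "CZ2020") {
    if (dq25 || dq8) "ASSOCIATED" else if (dq22) "NOT_EXCLUDED" else "EXCLUDED"
  } else if (ruleset == "CZ2022" || ruleset == "UK_BSHI") {
    if (any_het) "ASSOCIATED" else "EXCLUDED"
  } else if (ruleset == "CZ2023") {
    if (any_het) {
      "ASSOCIATED"
    } else if (has_a05 &&
      (!strict || !(has_a02 || has_a03 || has_b02 || has_b0302))) {
      "NOT_EXCLUDED"
    } else {
      "EXCLUDED"
    }
  } else {
    stop("oracle: unknown rule set ", ruleset)
  }
}

oracle_classify_all <- function(genotypes, ruleset, strict = FALSE) {
  vapply(
    seq_len(nrow(genotypes)),
    function(i) {
      oracle_classify(
        genotypes$dqa1_1[i], genotypes$dqa1_2[i],
        genotypes$dqb1_1[i], genotypes$dqb1_2[i],
        ruleset, strict
      )
    },
    character(1)
  )
}

# One-row genotype tibble from four allele strings.
gt <- function(a1, a2, b1, b2, id = "S1") {
  tibble::tibble(
    sample_id = id, dqa1_1 = a1, dqa1_2 = a2, dqb1_1 = b1, dqb1_2 = b2
  )
}
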