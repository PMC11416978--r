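test_that("heterodimer detection follows the allele co-presence definitions", {
  h <- detect_heterodimers(gt("DQA1*05:01", "DQA1*03:01", "DQB1*02:01", "DQB1*03:02"))
  expect_true(h$dq25)
  expect_true(h$dq8)
  expect_false(h$dq22)

  # DQ2.2 requires absence of DQA1*05: DQ2.5 takes precedence
  h <- detect_heterodimers(gt("DQA1*05:05", "DQA1*02:01", "DQB1*02:02", "DQB1*02:02"))
  expect_true(h$dq25)
  expect_false(h$dq22)

  h <- detect_heterodimers(gt("DQA1*02:01", "DQA1*01:01", "DQB1*02:02", "DQB1*05:01"))
  expect_true(h$dq22)
  expect_false(h$dq25)

  h <- detect_heterodimers(gt("DQA1*01:01", "DQA1*01:02", "DQB1*05:01", "DQB1*06:02"))
  expect_false(any(h$dq25, h$dq22, h$dq8))
  expect_false(h$has_dqa1_05)
})

test_that("detection is phase-agnostic and order-invariant", {
  # trans configuration counts: DQA1*05 and DQB1*02 on opposite rows of input
  combos <- list(
    c("DQA1*05:01", "DQA1*03:01", "DQB1*03:02", "DQB1*02:01"),
    c("DQA1*03:01", "DQA1*05:01", "DQB1*02:01", "DQB1*03:02"),
    c("DQA1*03:01", "DQA1*05:01", "DQB1*03:02", "DQB1*02:01")
  )
  base <- interpret_genotypes(gt("DQA1*05:01", "DQA1*03:01", "DQB1*02:01", "DQB1*03:02"))
  for (cc in combos) {
    r <- interpret_genotypes(gt(cc[1], cc[2], cc[3], cc[4]))
    expect_equal(r$category, base$category)
    expect_equal(r[c("dq25", "dq22", "dq8")], base[c("dq25", "dq22", "dq8")])
  }
})

test_that("blank second allele is treated as homozygous", {
  g <- tibble::tibble(
    sample_id = "H1", dqa1_1 = "DQA1*05:01", dqa1_2 = NA,
    dqb1_1 = "DQB1*02:01", dqb1_2 = ""
  )
  h <- detect_heterodimers(g)
  expect_equal(h$dqa1_2, "DQA1*05:01")
  expect_equal(h$dqb1_2, "DQB1*02:01")
  expect_true(h$dq25)
})

test_that("bare DQB1*03 yields an insufficient-resolution warning or error", {
  g <- gt("DQA1*03:01", "DQA1*01:01", "DQB1*03", "DQB1*05:01")
  h <- detect_heterodimers(g)
  expect_true(is.na(h$dq8))
  expect_match(h$warnings[[1]], "insufficient resolution")
  r <- classify_heterodimers(h)
  expect_true(is.na(r$category))
  expect_error(
    detect_heterodimers(g, insufficient = "error"),
    "insufficient resolution"
  )
  # but resolution does not matter when the category is decided without DQ8
  g2 <- gt("DQA1*05:01", "DQA1*03:01", "DQB1*02:01", "DQB1*03")
  r2 <- interpret_genotypes(g2)
  expect_equal(as.character(r2$category), "ASSOCIATED")
})

test_that("spec'd genotype classifications hold under CZ2023", {
  # DQA1*05 without any complete heterodimer -> rare-risk category
  r <- interpret_genotypes(gt("DQA1*05:05", "DQA1*01:01", "DQB1*03:01", "DQB1*05:01"))
  expect_equal(as.character(r$category), "NOT_EXCLUDED")
  expect_match(r$interpretation, "cannot be excluded")
  # DQB1*03:03 is not associated: excluded despite DQA1*03
  r <- interpret_genotypes(gt("DQA1*03:01", "DQA1*01:01", "DQB1*03:03", "DQB1*05:01"))
  expect_equal(as.character(r$category), "EXCLUDED")
  expect_match(r$interpretation, "excludes this diagnosis")
})

test_that("DQA1*05-only genotypes split the rule sets as documented", {
  g <- gt("DQA1*05:05", "DQA1*01:01", "DQB1*03:01", "DQB1*05:01")
  expect_equal(
    as.character(interpret_genotypes(g, ruleset = "CZ2023")$category),
    "NOT_EXCLUDED"
  )
  expect_equal(
    as.character(interpret_genotypes(g, ruleset = "UK_BSHI")$category),
    "EXCLUDED"
  )
  expect_equal(
    as.character(interpret_genotypes(g, ruleset = "CZ2022")$category),
    "EXCLUDED"
  )
})

test_that("strict and permissive DQA1*05 readings differ only on mixed lone-allele cases", {
  # DQA1*05 + lone DQB1*03:02 (no DQA1*03): readings diverge, with a warning
  g <- gt("DQA1*05:01", "DQA1*01:01", "DQB1*03:02", "DQB1*05:01")
  permissive <- interpret_genotypes(g, ruleset = "CZ2023")
  strict <- interpret_genotypes(g, ruleset = "CZ2023", strict_dqa105 = TRUE)
  expect_equal(as.character(permissive$category), "NOT_EXCLUDED")
  expect_equal(as.character(strict$category), "EXCLUDED")
  expect_true(any(grepl("strict", c(permissive$warnings[[1]], strict$warnings[[1]]))))
  # truly solo DQA1*05: readings agree
  g2 <- gt("DQA1*05:05", "DQA1*01:01", "DQB1*03:01", "DQB1*05:01")
  expect_equal(
    interpret_genotypes(g2, ruleset = "CZ2023")$category,
    interpret_genotypes(g2, ruleset = "CZ2023", strict_dqa105 = TRUE)$category
  )
})

test_that("classification matches the brute-force oracle over the whole universe", {
  genotypes <- enumerate_genotypes()
  for (rs in rule_sets()$ruleset) {
    got <- as.character(interpret_genotypes(genotypes, ruleset = rs)$category)
    want <- oracle_classify_all(genotypes, rs)
    expect_equal(got, want, info = rs)
    expect_false(anyNA(got), info = rs) # rules are total on this universe
  }
  # strict mode, too
  got <- as.character(
    interpret_genotypes(genotypes, ruleset = "CZ2023", strict_dqa105 = TRUE)$category
  )
  expect_equal(got, oracle_classify_all(genotypes, "CZ2023", strict = TRUE))
})

test_that("adding a predisposing allele never lowers the CZ2023 category", {
  req_groups <- c("DQA1*02", "DQA1*03", "DQA1*05", "DQB1*02", "DQB1*03:02")
  genotypes <- enumerate_genotypes()
  base <- interpret_genotypes(genotypes, ruleset = "CZ2023")
  # overwrite a *neutral* slot with a predisposing allele (a genuine
  # addition: nothing predisposing is removed in the process), batched
  variants <- list()
  base_idx <- integer()
  for (sub in list(
    c("dqa1_2", "DQA1*05"), c("dqa1_2", "DQA1*02"), c("dqa1_2", "DQA1*03"),
    c("dqb1_2", "DQB1*02"), c("dqb1_2", "DQB1*03:02")
  )) {
    slot_neutral <- !purrr::map_lgl(
      genotypes[[sub[1]]], ~ any(matches_group(.x, req_groups))
    )
    g2 <- genotypes[slot_neutral, ]
    g2[[sub[1]]] <- sub[2]
    variants[[length(variants) + 1]] <- g2
    base_idx <- c(base_idx, which(slot_neutral))
  }
  added <- dplyr::bind_rows(variants)
  cat2 <- interpret_genotypes(added, ruleset = "CZ2023")$category
  expect_true(all(as.integer(cat2) >= as.integer(base$category[base_idx])))
})

test_that("rule-set pairs diverge exactly on the documented genotype classes", {
  genotypes <- enumerate_genotypes()
  h <- detect_heterodimers(genotypes)
  cats <- sapply(rule_sets()$ruleset, function(rs) {
    as.character(classify_heterodimers(h, ruleset = rs)$category)
  })
  any_het <- h$dq25 | h$dq22 | h$dq8
  dqa105_only <- !any_het & h$has_dqa1_05
  dq22_alone <- h$dq22 & !(h$dq25 | h$dq8)

  expect_equal(cats[, "CZ2023"] != cats[, "UK_BSHI"], unname(dqa105_only))
  expect_equal(cats[, "CZ2023"] != cats[, "CZ2022"], unname(dqa105_only))
  expect_equal(cats[, "CZ2015"] != cats[, "CZ2020"], unname(dq22_alone))
})

test_that("unknown rule sets are refused", {
  g <- gt("DQA1*05:01", "DQA1*01:01", "DQB1*02:01", "DQB1*05:01")
  expect_error(interpret_genotypes(g, ruleset = "CZ1999"), "unknown rule set")
})

test_that("clinical reports always carry the three required elements", {
  g <- dplyr::bind_rows(
    gt("DQA1*05:01", "DQA1*03:01", "DQB1*02:01", "DQB1*03:02", id = "POS"),
    gt("DQA1*01:01", "DQA1*01:02", "DQB1*05:01", "DQB1*06:02", id = "NEG")
  )
  rep <- build_report(interpret_genotypes(g))
  expect_equal(nrow(rep), 2)
  expect_true(all(c("predisposing_alleles", "dq2_5", "dq2_2", "dq8", "interpretation") %in% names(rep)))
  # positive sample: equivalents present, predisposing alleles listed
  expect_equal(rep$dq2_5[1], "present")
  expect_equal(rep$dq8[1], "present")
  expect_setequal(
    rep$predisposing_alleles[[1]],
    c("DQA1*05:01", "DQA1*03:01", "DQB1*02:01", "DQB1*03:02")
  )
  expect_match(rep$interpretation[1], "low specificity")
  # negative sample: explicit negatives, empty allele list
  expect_equal(rep$predisposing_alleles[[2]], character(0))
  expect_equal(unlist(rep[2, c("dq2_5", "dq2_2", "dq8")], use.names = FALSE),
    rep("absent", 3))
})

test_that("JSON report rendering carries one object per sample", {
  g <- dplyr::bind_rows(
    gt("DQA1*05:01", "DQA1*03:01", "DQB1*02:01", "DQB1*03:02", id = "A"),
    gt("DQA1*05:05", "DQA1*01:01", "DQB1*03:01", "DQB1*05:01", id = "B")
  )
  rep <- build_report(interpret_genotypes(g))
  path <- withr::local_tempfile(fileext = ".json")
  write_reports_json(rep, path)
  parsed <- jsonlite::read_json(path)
  expect_length(parsed, 2)
  expect_equal(parsed[[1]]$sample_id, "A")
  expect_equal(parsed[[1]]$category, "ASSOCIATED")
  expect_equal(parsed[[2]]$category, "NOT_EXCLUDED")
  expect_equal(parsed[[1]]$serological_equivalents$dq2_5, "present")
})
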