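#' Read a genotype table from delimited text
#'
#' Expects columns `sample_id`, `dqa1_1`, `dqa1_2`, `dqb1_1`, `dqb1_2`
#' (CSV by default; TSV when the file ends in `.tsv` or `.txt`). A blank
#' second allele at a locus means the sample is homozygous there. Allele
#' strings may use any accepted input form ("HLA-" prefix, unpadded
#' fields); they are normalized on read.
#'
#' @param path Path to a delimited text file.
#' @return A normalized genotype tibble (see [detect_heterodimers()] for
#'   the schema).
#' @export
read_genotypes <- function(path) {
  if (!file.exists(path)) stop("cannot read genotype file: ", path, call. = FALSE)
  raw <- read_delim_auto(path)
  if (nrow(raw) == 0) {
    stop("genotype file is empty: ", path, call. = FALSE)
  }
  out <- try(validate_genotypes(raw), silent = TRUE)
  if (inherits(out, "try-error")) {
    # Re-locate the failure to a row number for actionable CLI errors.
    for (i in seq_len(nrow(raw))) {
      row_ok <- try(validate_genotypes(raw[i, , drop = FALSE]), silent = TRUE)
      if (inherits(row_ok, "try-error")) {
        stop(
          "row ", i, " of ", basename(path), ": ",
          conditionMessage(attr(row_ok, "condition")),
          call. = FALSE
        )
      }
    }
    stop(conditionMessage(attr(out, "condition")), call. = FALSE)
  }
  out
}

#' Write a genotype table to delimited text
#'
#' @param genotypes A genotype tibble.
#' @param path Output path (CSV, or TSV for `.tsv`/`.txt`).
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(genotypes, path) {
  write_delim_auto(genotypes, path)
}

#' Read any package-produced delimited file
#'
#' Thin reader used by the command-line front end for panels, submissions
#' and score tables: CSV (or TSV for `.tsv`/`.txt`), all columns as
#' character, blank cells as `NA`.
#'
#' @param path Path to a delimited text file.
#' @return A tibble of character columns.
#' @export
read_delim_file <- function(path) {
  if (!file.exists(path)) stop("cannot read file: ", path, call. = FALSE)
  read_delim_auto(path)
}

read_delim_auto <- function(path) {
  delim <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  readr::read_delim(
    path,
    delim = delim, col_types = readr::cols(.default = readr::col_character()),
    na = c("", "NA"), trim_ws = TRUE, progress = FALSE,
    show_col_types = FALSE
  )
}

write_delim_auto <- function(x, path) {
  x <- dplyr::select(x, dplyr::where(~ !is.list(.x)))
  delim <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  readr::write_delim(x, path, delim = delim, na = "", progress = FALSE)
  invisible(path)
}
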