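#' Parse HLA-DQA1/DQB1 allele names
#'
#' Parses allele names written in standard WHO HLA nomenclature
#' (`"LOCUS*FF:FF"`, e.g. `"DQB1*03:02"`) for the two loci relevant to
#' coeliac-disease testing, DQA1 and DQB1. An optional `"HLA-"` prefix and
#' surrounding whitespace are tolerated on input; one-digit values in the
#' first two fields are left-padded to two digits (`"DQB1*3:2"` becomes
#' `"DQB1*03:02"`). Group-level names with a single field (e.g. `"DQA1*05"`)
#' are valid.
#'
#' Expression/null suffixes (N, L, S, C, A, Q) are rejected rather than
#' silently dropped: losing a null suffix could flip a clinical
#' interpretation.
#'
#' @param x Character vector of allele names.
#' @return A tibble with one row per input: `raw` (the input string),
#'   `locus` (`"DQA1"` or `"DQB1"`), `fields` (list column of character
#'   vectors, 1-4 numeric field strings with leading zeros preserved) and
#'   `allele` (the canonical formatted name, never with an `"HLA-"` prefix).
#' @seealso [format_allele()], [normalize_allele()], [matches_group()]
#' @examples
#' parse_allele(c("DQB1*03:02", "HLA-DQA1*05", "DQB1*3:2"))
#' @export
parse_allele <- function(x) {
  if (!is.character(x)) {
    stop("allele names must be supplied as a character vector", call. = FALSE)
  }
  raw <- x
  s <- stringr::str_trim(x)
  blank <- is.na(s) | s == ""
  if (any(blank)) {
    stop("blank allele name at position ", which(blank)[1], call. = FALSE)
  }
  s <- stringr::str_remove(s, "^HLA-")

  no_star <- !stringr::str_detect(s, stringr::fixed("*"))
  if (any(no_star)) {
    stop(
      "malformed allele name (missing '*'): \"", raw[no_star][1], "\"",
      call. = FALSE
    )
  }
  locus <- stringr::str_extract(s, "^[^*]*")
  body <- stringr::str_remove(s, "^[^*]*\\*")

  bad_locus <- !locus %in% c("DQA1", "DQB1")
  if (any(bad_locus)) {
    stop(
      "unsupported locus \"", locus[bad_locus][1], "\" in \"",
      raw[bad_locus][1], "\" (only DQA1 and DQB1 are handled)",
      call. = FALSE
    )
  }

  suffixed <- stringr::str_detect(body, "[NLSCAQnlscaq]$")
  if (any(suffixed)) {
    stop(
      "expression/null suffix not supported: \"", raw[suffixed][1], "\"",
      call. = FALSE
    )
  }

  fields <- stringr::str_split(body, stringr::fixed(":"))
  ok <- purrr::map_lgl(fields, function(f) {
    length(f) >= 1 && length(f) <= 4 && all(stringr::str_detect(f, "^[0-9]+$"))
  })
  if (any(!ok)) {
    stop(
      "malformed allele fields in \"", raw[!ok][1],
      "\" (expected 1-4 ':'-separated numeric fields)",
      call. = FALSE
    )
  }
  # Left-pad the first two fields to two digits; deeper fields kept verbatim.
  fields <- purrr::map(fields, function(f) {
    k <- seq_len(min(2L, length(f)))
    f[k] <- stringr::str_pad(f[k], 2L, pad = "0")
    f
  })

  tibble::tibble(
    raw = raw,
    locus = locus,
    fields = fields,
    allele = paste0(locus, "*", purrr::map_chr(fields, paste, collapse = ":"))
  )
}

#' Format a parsed allele back to its canonical name
#'
#' @param locus Character vector, `"DQA1"` or `"DQB1"`.
#' @param fields List of character vectors of numeric field strings (as
#'   produced by [parse_allele()]), or a single character vector for one
#'   allele.
#' @return Character vector of canonical names, e.g. `"DQB1*03:02"`.
#' @examples
#' format_allele("DQB1", c("03", "02"))
#' @export
format_allele <- function(locus, fields) {
  if (!is.list(fields)) fields <- list(fields)
  stopifnot(all(locus %in% c("DQA1", "DQB1")))
  paste0(locus, "*", purrr::map_chr(fields, paste, collapse = ":"))
}

#' Normalize allele names to canonical form
#'
#' Convenience wrapper around [parse_allele()] returning just the canonical
#' string (prefix stripped, fields zero-padded).
#'
#' @inheritParams parse_allele
#' @return Character vector of canonical allele names.
#' @export
normalize_allele <- function(x) {
  # parse unique values only: genotype tables repeat a handful of alleles
  # thousands of times
  ux <- unique(x)
  parse_allele(ux)$allele[match(x, ux)]
}

#' Test whether alleles fall within an allele group
#'
#' An allele group is a first-field (or two-field) prefix of an allele name:
#' the group `DQA1*05` covers `DQA1*05:01` and `DQA1*05:05`; the group
#' `DQB1*03:02` covers `DQB1*03:02` and any of its higher-field subtypes but
#' *not* `DQB1*03:03`. A group with k fields matches an allele iff the loci
#' agree and the allele's first k fields equal the group's fields.
#'
#' @param allele Character vector of allele names (any accepted input form).
#' @param group Character vector of group names; recycled against `allele`.
#' @return Logical vector.
#' @examples
#' matches_group("DQA1*05:05", "DQA1*05")   # TRUE
#' matches_group("DQB1*03:03", "DQB1*03:02") # FALSE
#' @export
matches_group <- function(allele, group) {
  a <- normalize_allele(allele)
  g <- normalize_allele(group)
  n <- max(length(a), length(g))
  a <- rep_len(a, n)
  g <- rep_len(g, n)
  hit <- startsWith(a, g)
  # Field boundary: the character after the matched prefix must be a field
  # separator or the end of the name, so "DQB1*03" never matches "DQB1*030...".
  nxt <- substr(a, nchar(g) + 1L, nchar(g) + 1L)
  hit & (nxt == "" | nxt == ":")
}

# Number of fields in an already-canonical allele name (internal, no
# re-validation).
n_fields <- function(allele) {
  stringr::str_count(allele, stringr::fixed(":")) + 1L
}
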