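#' The six CNS-active medication classes
#'
#' The polypharmacy definition covers six classes of centrally acting agents:
#' antidepressants (SSRIs, SNRIs and tricyclics under the strict definition),
#' anti-epileptics, antipsychotics, benzodiazepines, Z-drugs and opioids.
#'
#' @return character vector of the six canonical class names.
#' @export
drug_classes <- function() {
  c("antidepressant", "anti_epileptic", "antipsychotic",
    "benzodiazepine", "z_drug", "opioid")
}

VALID_CLASS <- function() c(drug_classes(), "excluded")

# ATC fragments are 1, 3, 4, 5 or 7 characters: A, A10, A10B, A10BA, A10BA02
ATC_FRAG_RE <- "^[A-Z]([0-9]{2}([A-Z]([A-Z]([0-9]{2})?)?)?)?$"
ATC_FULL_RE <- "^[A-Z][0-9]{2}[A-Z]{2}[0-9]{2}$"

#' Build an ATC-to-class classification
#'
#' A classification is an ordered prefix rule table plus optional full-code
#' overrides. Lookup is deterministic: the longest matching prefix wins, a
#' 7-character override beats any prefix, and the pseudo-class `"excluded"`
#' removes a code from CNS-active status (used e.g. for lithium within N05A).
#'
#' @param rules data frame with columns `atc_prefix`, `class`; `class` is one of
#'   [drug_classes()] or `"excluded"`.
#' @param overrides optional data frame with columns `atc_code` (full
#'   7-character code), `class` (a class name or `"excluded"`).
#' @return an object of class `atc_classification`.
#' @export
atc_classification <- function(rules, overrides = NULL) {
  rules <- tibble::as_tibble(rules)
  stopifnot(all(c("atc_prefix", "class") %in% names(rules)))
  rules$atc_prefix <- toupper(trimws(rules$atc_prefix))
  bad <- !grepl(ATC_FRAG_RE, rules$atc_prefix) |
    !nchar(rules$atc_prefix) %in% c(1L, 3L, 4L, 5L, 7L)
  if (any(bad)) abort_bad_rows("invalid ATC prefix in classification rules", which(bad))
  if (!all(rules$class %in% VALID_CLASS())) {
    stop("rule classes must be one of: ", paste(VALID_CLASS(), collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(overrides)) {
    overrides <- tibble::as_tibble(overrides)
    stopifnot(all(c("atc_code", "class") %in% names(overrides)))
    overrides$atc_code <- toupper(trimws(overrides$atc_code))
    bad <- !grepl(ATC_FULL_RE, overrides$atc_code)
    if (any(bad)) abort_bad_rows("overrides must be full 7-character ATC codes", which(bad))
    if (!all(overrides$class %in% VALID_CLASS())) {
      stop("override classes must be one of: ", paste(VALID_CLASS(), collapse = ", "),
           call. = FALSE)
    }
  } else {
    overrides <- tibble::tibble(atc_code = character(), class = character())
  }
  # partition property: a prefix may appear once only
  if (anyDuplicated(rules$atc_prefix)) {
    stop("duplicate ATC prefixes in classification rules", call. = FALSE)
  }
  if (anyDuplicated(overrides$atc_code)) {
    stop("duplicate ATC codes in overrides", call. = FALSE)
  }
  structure(list(rules = rules, overrides = overrides),
            class = "atc_classification")
}

#' Default CNS-active classification
#'
#' The shipped prefix convention: `N06AA` (tricyclics), `N06AB` (SSRIs) and the
#' listed SNRIs (`N06AX16` venlafaxine, `N06AX21` duloxetine, `N06AX23`
#' desvenlafaxine) map to antidepressant; `N03A` to anti-epileptic; `N05A` to
#' antipsychotic with `N05AN` (lithium) excluded; `N05BA` and `N05CD` to
#' benzodiazepine; `N05CF` to Z-drug; `N02A` to opioid. Under
#' `antidepressants = "permissive"` all of `N06A` counts as antidepressant
#' (which additionally captures e.g. bupropion, mirtazapine, trazodone).
#'
#' @param antidepressants `"strict"` (SSRI/SNRI/TCA only, the default) or
#'   `"permissive"` (all N06A).
#' @return an `atc_classification`.
#' @export
default_classification <- function(antidepressants = c("strict", "permissive")) {
  antidepressants <- match.arg(antidepressants)
  rules <- tibble::tribble(
    ~atc_prefix, ~class,
    "N06AA",   "antidepressant",
    "N06AB",   "antidepressant",
    "N06AX16", "antidepressant",
    "N06AX21", "antidepressant",
    "N06AX23", "antidepressant",
    "N03A",    "anti_epileptic",
    "N05A",    "antipsychotic",
    "N05AN",   "excluded",
    "N05BA",   "benzodiazepine",
    "N05CD",   "benzodiazepine",
    "N05CF",   "z_drug",
    "N02A",    "opioid"
  )
  if (antidepressants == "permissive") {
    rules <- dplyr::bind_rows(rules,
      tibble::tibble(atc_prefix = "N06A", class = "antidepressant"))
  }
  atc_classification(rules)
}

#' Classify ATC codes into CNS-active classes
#'
#' Vectorised, case-normalising and deterministic: overrides beat prefixes, the
#' longest matching prefix wins, `"excluded"` yields `NA` like a non-match.
#'
#' @param code character vector of full 7-character ATC codes.
#' @param classification an [atc_classification()]; defaults to
#'   [default_classification()].
#' @return character vector: the class name, or `NA` for codes that are not
#'   CNS-active.
#' @export
classify_atc <- function(code, classification = default_classification()) {
  stopifnot(inherits(classification, "atc_classification"))
  code <- toupper(trimws(as.character(code)))
  bad <- !grepl(ATC_FULL_RE, code) & !is.na(code)
  if (any(bad)) {
    abort_bad_rows(
      sprintf("malformed ATC code(s): %s",
              paste(unique(code[bad]), collapse = ", ")),
      which(bad))
  }
  out <- rep(NA_character_, length(code))
  rules <- classification$rules[order(nchar(classification$rules$atc_prefix)), ]
  for (i in seq_len(nrow(rules))) {  # increasing length: longest prefix wins
    hit <- startsWith(code, rules$atc_prefix[i])
    out[hit] <- rules$class[i]
  }
  ov <- classification$overrides
  if (nrow(ov)) {
    m <- match(code, ov$atc_code)
    out[!is.na(m)] <- ov$class[m[!is.na(m)]]
  }
  out[!is.na(out) & out == "excluded"] <- NA_character_
  out
}

#' Read / write a classification as CSV
#'
#' `rules_path` holds `atc_prefix,class`; `overrides_path` (optional) holds
#' `atc_code,class`. Round-trips preserve all lookups.
#'
#' @param rules_path path to the prefix-rule CSV.
#' @param overrides_path optional path to the overrides CSV.
#' @return an `atc_classification`.
#' @export
read_classification <- function(rules_path, overrides_path = NULL) {
  rules <- readr::read_csv(rules_path, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  overrides <- if (!is.null(overrides_path)) {
    readr::read_csv(overrides_path, col_types = readr::cols(.default = "c"),
                    progress = FALSE)
  }
  atc_classification(rules, overrides)
}

#' @rdname read_classification
#' @param classification an `atc_classification` to serialise.
#' @export
write_classification <- function(classification, rules_path,
                                 overrides_path = NULL) {
  stopifnot(inherits(classification, "atc_classification"))
  readr::write_csv(classification$rules, rules_path, progress = FALSE)
  if (!is.null(overrides_path)) {
    readr::write_csv(classification$overrides, overrides_path, progress = FALSE)
  }
  invisible(rules_path)
}

#' @export
print.atc_classification <- function(x, ...) {
  cat("<atc_classification>", nrow(x$rules), "prefix rules,",
      nrow(x$overrides), "overrides\n")
  invisible(x)
}
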