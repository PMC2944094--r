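#' Health-event code filter
#'
#' Describes the set of diagnosis codes defining an outcome, as individual
#' codes and/or closed ranges within one coding system. ICD-9 codes are
#' numeric three-digit rubrics (e.g. \code{"200"}); ICD-10 codes are a
#' chapter letter plus two digits (e.g. \code{"C82"}). Ranges are written
#' with a hyphen and are inclusive at both ends; an ICD-10 range must stay
#' within one chapter letter. User-defined systems take literal codes only.
#'
#' A compact string form is accepted: \code{"icd10:C82-C85,C91"}.
#'
#' @param include Character vector of codes and ranges, or a single
#'   \code{"system:codes"} string when \code{system} is missing.
#' @param system One of \code{"ICD9"}, \code{"ICD10"}, \code{"user"}
#'   (case-insensitive).
#' @return An object of class \code{code_filter}.
#' @examples
#' codeFilter("C82-C85", "ICD10")
#' codeFilter("icd9:200,202")
#' @export
codeFilter <- function(include, system = NULL) {
  if (is.null(system)) {
    if (length(include) != 1L || !grepl(":", include, fixed = TRUE))
      stop("supply `system`, or a single 'system:codes' string",
           call. = FALSE)
    parts <- strsplit(include, ":", fixed = TRUE)[[1]]
    system <- parts[1]
    include <- strsplit(parts[2], ",", fixed = TRUE)[[1]]
  }
  system <- toupper(gsub("[^A-Za-z0-9]", "", system))
  if (!system %in% c("ICD9", "ICD10", "USER"))
    stop("unknown code system: ", system, call. = FALSE)
  include <- trimws(include)
  # normalise unicode en-dash (common in copied code lists) to hyphen
  include <- gsub("–", "-", include)
  if (!length(include)) stop("empty code filter", call. = FALSE)
  structure(list(system = if (system == "USER") "user" else system,
                 include = include),
            class = "code_filter")
}

#' @export
print.code_filter <- function(x, ...) {
  cat(sprintf("<code_filter> %s: %s\n", x$system,
              paste(x$include, collapse = ", ")))
  invisible(x)
}

.expand_icd9 <- function(term) {
  if (grepl("-", term, fixed = TRUE)) {
    ends <- strsplit(term, "-", fixed = TRUE)[[1]]
    if (length(ends) != 2L || !all(grepl("^[0-9]{3}$", ends)))
      stop("malformed ICD-9 range: ", term, call. = FALSE)
    a <- as.integer(ends[1]); b <- as.integer(ends[2])
    if (b < a) stop("reversed range (end before start): ", term,
                    call. = FALSE)
    sprintf("%03d", a:b)
  } else {
    if (!grepl("^[0-9]{3}$", term))
      stop("malformed ICD-9 code: ", term, call. = FALSE)
    term
  }
}

.expand_icd10 <- function(term) {
  if (grepl("-", term, fixed = TRUE)) {
    ends <- strsplit(term, "-", fixed = TRUE)[[1]]
    if (length(ends) != 2L || !all(grepl("^[A-Z][0-9]{2}$", ends)))
      stop("malformed ICD-10 range: ", term, call. = FALSE)
    la <- substr(ends[1], 1, 1); lb <- substr(ends[2], 1, 1)
    if (la != lb)
      stop("ICD-10 range spans chapter letters: ", term, call. = FALSE)
    a <- as.integer(substr(ends[1], 2, 3))
    b <- as.integer(substr(ends[2], 2, 3))
    if (b < a) stop("reversed range (end before start): ", term,
                    call. = FALSE)
    paste0(la, sprintf("%02d", a:b))
  } else {
    if (!grepl("^[A-Z][0-9]{2}$", term))
      stop("malformed ICD-10 code: ", term, call. = FALSE)
    term
  }
}

#' Expand a code filter to concrete codes
#'
#' Expands every range in the filter and returns the sorted, de-duplicated
#' list of concrete codes. Expansion is deterministic and independent of the
#' order of the filter's terms, and idempotent (expanding an already-expanded
#' list is a no-op).
#'
#' @param filter A \code{\link{codeFilter}}.
#' @return Character vector of concrete codes, sorted.
#' @examples
#' expandCodeFilter(codeFilter("C91-C95", "ICD10"))
#' @export
expandCodeFilter <- function(filter) {
  stopifnot(inherits(filter, "code_filter"))
  expand1 <- switch(filter$system,
                    ICD9 = .expand_icd9,
                    ICD10 = .expand_icd10,
                    user = function(term) {
                      if (grepl("-", term, fixed = TRUE))
                        stop("ranges are not defined for user code systems: ",
                             term, call. = FALSE)
                      term
                    })
  out <- unlist(lapply(filter$include, expand1), use.names = FALSE)
  sort(unique(out))
}
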