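#' CWIS label vocabularies
#'
#' The Chest Wall Injury Society (CWIS) taxonomy classifies every rib
#' fracture along three categories: fracture *type* (simple, wedge,
#' complex), *displacement* (undisplaced, offset, displaced) and
#' *location* along the rib (anterior, lateral, posterior). Fused
#' detections may additionally carry the value `"unknown"` in a category
#' when the detector for that category did not contribute.
#'
#' @format A named list with one character vector per category.
#' @export
cwis_vocab <- list(
  type         = c("simple", "wedge", "complex"),
  displacement = c("undisplaced", "offset", "displaced"),
  location     = c("anterior", "lateral", "posterior")
)

#' @rdname cwis_vocab
#' @export
cwis_categories <- names(cwis_vocab)

#' Normalize a CWIS label
#'
#' Labels are matched case-insensitively against the category vocabulary
#' and returned in canonical lower-case form.
#'
#' @param x character vector of labels.
#' @param category one of `"type"`, `"displacement"`, `"location"`.
#' @param allow_unknown accept the value `"unknown"` (used for fused
#'   detections where one detector was absent)?
#' @param context prefix used in error messages (e.g. a file/line tag).
#' @return canonical labels, same length as `x`.
#' @export
normalize_label <- function(x, category, allow_unknown = FALSE,
                            context = "label") {
  category <- match.arg(category, cwis_categories)
  vocab <- cwis_vocab[[category]]
  if (allow_unknown) vocab <- c(vocab, "unknown")
  out <- vocab[match(tolower(trimws(x)), vocab)]
  if (anyNA(out)) {
    bad <- unique(x[is.na(out)])
    stop(sprintf("%s: unknown %s label(s): %s (expected one of %s)",
                 context, category, paste(sQuote(bad), collapse = ", "),
                 paste(vocab, collapse = ", ")), call. = FALSE)
  }
  out
}

# Run an expression under a fixed RNG state without disturbing the caller's
# stream; seed = NULL leaves the ambient RNG in charge.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
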