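#' Label schemes for ONH segmentation masks
#'
#' A label scheme maps tissue-class names to the integer codes used in a
#' segmentation volume. The required classes are `background`, `rnfl`
#' (retinal nerve fiber layer), `vessel`, `rpe_bm` (the RPE--Bruch's membrane
#' complex, annotated jointly because BM is thinner than the axial pixel
#' size) and `prelaminar` (neural tissue inside the disc, past the BMO).
#' Optional classes: `lamina_cribrosa` and the three peripapillary-atrophy
#' zones `ppa_alpha`, `ppa_beta`, `ppa_gamma`.
#'
#' @param codes named integer vector mapping class names to codes.
#' @return an object of class `label_scheme` (named integer vector).
#' @examples
#' sc <- default_scheme()
#' validate_scheme(sc)
#' @export
label_scheme <- function(codes) {
  if (is.null(names(codes)) || any(!nzchar(names(codes))))
    stop("label_scheme: 'codes' must be a fully named vector", call. = FALSE)
  codes <- stats::setNames(as.integer(codes), names(codes))
  structure(codes, class = "label_scheme")
}

.required_labels <- c("background", "rnfl", "vessel", "rpe_bm", "prelaminar")
.optional_labels <- c("lamina_cribrosa", "ppa_alpha", "ppa_beta", "ppa_gamma")

#' @rdname label_scheme
#' @export
default_scheme <- function() {
  label_scheme(c(
    background = 0L, rnfl = 1L, vessel = 2L, rpe_bm = 3L, prelaminar = 4L,
    lamina_cribrosa = 5L, ppa_alpha = 6L, ppa_beta = 7L, ppa_gamma = 8L
  ))
}

#' Validate a label scheme
#'
#' Checks the scheme invariants: all required classes present, codes distinct
#' non-negative integers, no unknown class names.
#'
#' @param scheme a [label_scheme()].
#' @return character vector of violations; `character(0)` if the scheme is
#'   valid.
#' @export
validate_scheme <- function(scheme) {
  v <- character(0)
  nm <- names(scheme)
  missing <- setdiff(.required_labels, nm)
  if (length(missing))
    v <- c(v, paste0("missing required label(s): ", paste(missing, collapse = ", ")))
  unknown <- setdiff(nm, c(.required_labels, .optional_labels))
  if (length(unknown))
    v <- c(v, paste0("unknown label name(s): ", paste(unknown, collapse = ", ")))
  if (anyNA(scheme))
    v <- c(v, "NA code(s)")
  else {
    if (any(scheme < 0L))
      v <- c(v, "negative code(s)")
    if (anyDuplicated(scheme)) {
      dup <- scheme[duplicated(scheme)]
      v <- c(v, paste0("duplicate code(s): ", paste(unique(dup), collapse = ", ")))
    }
  }
  v
}

.assert_scheme <- function(scheme) {
  if (!inherits(scheme, "label_scheme"))
    scheme <- label_scheme(scheme)
  v <- validate_scheme(scheme)
  if (length(v))
    stop("invalid label scheme: ", paste(v, collapse = "; "), call. = FALSE)
  scheme
}

# codes for a set of class names, erroring on names absent from the scheme
.scheme_codes <- function(scheme, label_set, allow_missing = FALSE) {
  if (allow_missing) label_set <- intersect(label_set, names(scheme))
  bad <- setdiff(label_set, names(scheme))
  if (length(bad))
    stop("label(s) not in scheme: ", paste(bad, collapse = ", "), call. = FALSE)
  unname(scheme[label_set])
}

#' @export
print.label_scheme <- function(x, ...) {
  cat("<label_scheme>\n")
  for (nm in names(x)) cat(sprintf("  %-16s %d\n", nm, x[[nm]]))
  invisible(x)
}
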