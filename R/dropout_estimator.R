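# Drop-out probability prediction from average peak height via a
# user-parameterized logistic regression. Coefficients are configuration,
# never hard-coded: laboratories should estimate them from their own
# validation data for their own typing system; fixture coefficients in the
# test suite are synthetic.

#' Construct a logistic drop-out model
#'
#' @param intercept,slope Logistic regression coefficients on the logit
#'   scale: `logit(P(D_O)) = intercept + slope * T(h)`.
#' @param covariate_transform Transform `T` applied to the average peak
#'   height before the linear predictor: `"identity"` or `"log10"`. Must be
#'   stated explicitly; no default is applied silently.
#' @param note Optional free-text provenance note (instrument, kit, study).
#' @return Object of class `logistic_model`.
#' @export
logistic_model <- function(intercept, slope,
                           covariate_transform = c("identity", "log10"),
                           note = NULL) {
  if (!is.numeric(intercept) || !is.numeric(slope))
    stop("intercept and slope must be numeric")
  covariate_transform <- match.arg(covariate_transform)
  structure(list(intercept = intercept, slope = slope,
                 covariate_transform = covariate_transform,
                 note = note),
            class = "logistic_model")
}

#' Average height of detected peaks
#'
#' @param evidence Named list (marker -> [locus_evidence()]).
#' @param subset Optional character vector of markers to restrict to.
#' @return Arithmetic mean peak height (RFU) over detected alleles carrying a
#'   height in the chosen markers; an error if no heights are present
#'   (supply P(D_O) directly in that case).
#' @export
average_peak_height <- function(evidence, subset = NULL) {
  markers <- names(evidence)
  if (!is.null(subset)) markers <- intersect(markers, subset)
  h <- unlist(lapply(evidence[markers], function(e) e$heights))
  if (length(h) == 0)
    stop("no peak heights in the evidence profile; supply P(D_O) directly")
  mean(h)
}

#' Predict P(D_O) from average peak height
#'
#' @param model A [logistic_model()].
#' @param h Average peak height in RFU (> 0).
#' @return `1 / (1 + exp(-(intercept + slope * T(h))))`, clipped to
#'   `[1e-6, 1 - 1e-6]` so degenerate 0/1 drop-out probabilities never enter
#'   the likelihood engine.
#' @export
predict_dropout <- function(model, h) {
  if (!inherits(model, "logistic_model")) stop("model must be a logistic_model()")
  if (!is.numeric(h) || any(h <= 0)) stop("average peak height must be positive")
  x <- switch(model$covariate_transform, identity = h, log10 = log10(h))
  p <- 1 / (1 + exp(-(model$intercept + model$slope * x)))
  pmin(pmax(p, 1e-6), 1 - 1e-6)
}

#' Read a logistic drop-out model from JSON
#'
#' The file must contain `intercept`, `slope` and `covariate_transform`
#' fields; `note` is optional.
#'
#' @param path Path to the JSON file.
#' @return A [logistic_model()].
#' @export
read_logistic_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("intercept", "slope", "covariate_transform"))
    if (is.null(x[[f]])) stop("drop-out model file missing field '", f, "'")
  logistic_model(x$intercept, x$slope, x$covariate_transform, x$note)
}

#' Write a logistic drop-out model to JSON
#'
#' @param model A [logistic_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_logistic_model <- function(model, path) {
  jsonlite::write_json(
    list(intercept = model$intercept, slope = model$slope,
         covariate_transform = model$covariate_transform,
         note = model$note %||% "unspecified"),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
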