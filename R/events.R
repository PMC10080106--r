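#' Event matrix container
#'
#' Holds one sample's per-event channel intensities (scatter, viability dye
#' and markers), optional per-event ground-truth population labels (from the
#' synthetic generator) and sample metadata.
#'
#' @param exprs Numeric matrix, events x channels, with column names.
#' @param truth Optional character vector of per-event population labels
#'   (`debris`, `doublet`, `dead` or a population name).
#' @param meta Named list of sample metadata (donor, group, condition, ...).
#' @return An `event_matrix`.
#' @export
event_matrix <- function(exprs, truth = NULL, meta = list()) {
  if (!is.matrix(exprs) || !is.numeric(exprs)) {
    cs_abort("`exprs` must be a numeric matrix", "input")
  }
  if (is.null(colnames(exprs))) {
    cs_abort("`exprs` must have channel (column) names", "input")
  }
  if (any(!is.finite(exprs))) {
    cs_abort("event intensities must be finite", "input")
  }
  if (!is.null(truth) && length(truth) != nrow(exprs)) {
    cs_abort("`truth` length must equal the event count", "input")
  }
  structure(list(exprs = exprs, truth = truth, meta = meta),
            class = "event_matrix")
}

#' Extract the intensity matrix from events
#' @param x An `event_matrix` or a bare numeric matrix.
#' @return Numeric matrix, events x channels.
#' @export
event_exprs <- function(x) {
  if (inherits(x, "event_matrix")) x$exprs
  else if (is.matrix(x) && is.numeric(x)) x
  else cs_abort("expected an event_matrix or numeric matrix", "input")
}

#' @export
print.event_matrix <- function(x, ...) {
  cat("<event_matrix>", nrow(x$exprs), "events x", ncol(x$exprs),
      "channels\n")
  cat(" channels:", paste(utils::head(colnames(x$exprs), 10), collapse = ", "),
      if (ncol(x$exprs) > 10) "..." else "", "\n")
  if (!is.null(x$truth)) {
    tb <- sort(table(x$truth), decreasing = TRUE)
    cat(" truth labels:", paste(utils::head(names(tb), 6), collapse = ", "),
        if (length(tb) > 6) "..." else "", "\n")
  }
  invisible(x)
}

#' @export
dim.event_matrix <- function(x) dim(x$exprs)

#' Inverse hyperbolic sine display transform
#'
#' Applies `x -> asinh(x / cofactor)` to the fluorescence channels (scatter
#' channels, identified by an `FSC`/`SSC` prefix, are left untouched). The
#' transform is monotone and invertible, so population medians commute with
#' it; gating runs on the transformed scale while MFIs are always reported
#' raw.
#'
#' @param events `event_matrix` or numeric matrix.
#' @param cofactor Positive scale cofactor (default 150).
#' @param channels Channels to transform; defaults to all non-scatter
#'   channels.
#' @param inverse Apply the inverse transform `x -> cofactor * sinh(x)`.
#' @return Same container type as the input, transformed.
#' @export
transform_asinh <- function(events, cofactor = 150, channels = NULL,
                            inverse = FALSE) {
  if (!is.numeric(cofactor) || length(cofactor) != 1 || cofactor <= 0) {
    cs_abort("`cofactor` must be a positive scalar", "input")
  }
  X <- event_exprs(events)
  if (is.null(channels)) {
    channels <- colnames(X)[!is_scatter_channel(colnames(X))]
  }
  miss <- setdiff(channels, colnames(X))
  if (length(miss)) {
    cs_abort(paste("unknown channels:", paste(miss, collapse = ", ")),
             "configuration")
  }
  X[, channels] <- if (inverse) cofactor * sinh(X[, channels])
  else asinh(X[, channels] / cofactor)
  if (inherits(events, "event_matrix")) {
    out <- events
    out$exprs <- X
    out
  } else X
}
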