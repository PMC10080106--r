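# Antibody titration: stain indices across a 2-fold serial-dilution ladder
# and a concentration-selection rule.

#' Robust standard deviation
#'
#' `1.4826 * MAD` about the median — the consistent estimator of a normal
#' standard deviation. Used as the robust SD of the negative population in
#' the stain index.
#'
#' @param values Numeric vector, at least 2 values.
#' @return Non-negative scalar.
#' @export
robust_sd <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 2) cs_abort("need at least 2 values", "input")
  stats::mad(values)  # default constant 1.4826
}

#' Stain index
#'
#' `SI = (median(positive) - median(negative)) / (2 * rSD(negative))`:
#' the separation between stained and unstained populations in units of
#' twice the negative population's robust spread. Scale-invariant under a
#' common positive rescaling of all intensities.
#'
#' @param positive_values,negative_values Raw intensities of the two
#'   populations (non-empty; the negative population must have positive
#'   robust SD).
#' @return The stain index.
#' @export
stain_index <- function(positive_values, negative_values) {
  if (!length(positive_values) || !length(negative_values)) {
    cs_abort("both populations must be non-empty", "input")
  }
  rsd <- robust_sd(negative_values)
  if (rsd == 0) {
    cs_abort("negative population has zero robust SD; stain index undefined",
             "degenerate")
  }
  (stats::median(positive_values) - stats::median(negative_values)) / (2 * rsd)
}

#' Stain-index curve over a titration series and concentration selection
#'
#' Computes MFI of the positive and negative populations, the negative
#' robust SD and the stain index at every concentration, then selects the
#' lowest concentration whose SI reaches at least `keep_fraction` of the
#' series maximum — a formalization of picking the dilution that still
#' shows high separation.
#'
#' @param series A `titration_series` (see [generate_titration_series()]),
#'   or a list with `entries` of `(concentration, positive, negative)`.
#' @param keep_fraction Fraction of the maximum SI a selected concentration
#'   must retain (default 0.9).
#' @return A `stain_index_result`: data frame with one row per
#'   concentration (`concentration`, `mfi_pos`, `mfi_neg`, `rsd_neg`,
#'   `stain_index`) plus attribute `selected_concentration`.
#' @export
titration_curve <- function(series, keep_fraction = 0.9) {
  entries <- series$entries %||% series
  rows <- lapply(entries, function(e) {
    data.frame(concentration = e$concentration,
               mfi_pos = stats::median(e$positive),
               mfi_neg = stats::median(e$negative),
               rsd_neg = robust_sd(e$negative),
               stain_index = stain_index(e$positive, e$negative))
  })
  out <- do.call(rbind, rows)
  if (all(out$stain_index <= 0)) {
    cs_abort("no concentration separates positive from negative (all SI <= 0)",
             "no_separation")
  }
  ok <- out$stain_index >= keep_fraction * max(out$stain_index)
  sel <- min(out$concentration[ok])
  structure(out, selected_concentration = sel,
            class = c("stain_index_result", "data.frame"))
}

#' @export
print.stain_index_result <- function(x, ...) {
  cat("<stain_index_result> selected concentration:",
      attr(x, "selected_concentration"), "uL/test\n")
  print(as.data.frame(x))
  invisible(x)
}
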