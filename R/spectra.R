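#' Spectral signature of a fluorophore
#'
#' A spectral signature is the relative emission of one fluorophore across all
#' detectors of the instrument configuration (38 for the packaged 3-laser
#' layout). Intensities are clipped at zero and stored with unit Euclidean
#' norm, which makes the cosine similarity index well defined.
#'
#' @param fluorophore Fluorophore name.
#' @param intensities Numeric vector of per-detector relative emission values.
#' @return An object of class `spectral_signature` with elements
#'   `fluorophore` and `intensities` (unit-norm, non-negative).
#' @export
#' @examples
#' s <- spectral_signature("FITC", c(0, 1, 2, 1, 0))
#' sum(s$intensities^2)  # 1
spectral_signature <- function(fluorophore, intensities) {
  if (!is.numeric(intensities) || length(intensities) == 0 ||
      anyNA(intensities)) {
    cs_abort("`intensities` must be a non-empty numeric vector without NAs",
             "input")
  }
  v <- pmax(as.numeric(intensities), 0)
  nrm <- sqrt(sum(v^2))
  if (nrm == 0) {
    cs_abort(sprintf("signature for '%s' is all zero after clipping",
                     fluorophore), "degenerate")
  }
  structure(list(fluorophore = as.character(fluorophore),
                 intensities = v / nrm),
            class = "spectral_signature")
}

#' @export
print.spectral_signature <- function(x, ...) {
  cat("<spectral_signature>", x$fluorophore, "-", length(x$intensities),
      "detectors, peak at detector", which.max(x$intensities), "\n")
  invisible(x)
}

sig_vec <- function(x) {
  if (inherits(x, "spectral_signature")) x$intensities
  else if (is.numeric(x)) as.numeric(x)
  else cs_abort("expected a spectral_signature or numeric vector", "input")
}

#' Similarity index between two spectral signatures
#'
#' The cosine of the angle between the two unit-normalized, non-negative
#' emission vectors. 0 means the spectra occupy disjoint detectors, 1 means
#' identical spectral shapes. This is a documented surrogate for the
#' vendor-proprietary similarity measure, whose formula is unpublished.
#'
#' @param sig_a,sig_b `spectral_signature` objects or numeric vectors of the
#'   same length.
#' @return A value in \[0, 1\].
#' @export
#' @examples
#' similarity_index(c(1, 1, 0), c(1, 0, 0))  # 0.7071
similarity_index <- function(sig_a, sig_b) {
  a <- pmax(sig_vec(sig_a), 0)
  b <- pmax(sig_vec(sig_b), 0)
  if (length(a) != length(b)) {
    cs_abort(sprintf("signature lengths differ (%d vs %d)",
                     length(a), length(b)), "dimension")
  }
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) cs_abort("all-zero signature vector", "degenerate")
  min(1, max(0, sum(a * b) / (na * nb)))
}

#' Pairwise similarity matrix of a panel
#'
#' @param panel A `panel_definition`, or a list of `spectral_signature`
#'   objects (>= 2).
#' @return A symmetric numeric matrix with unit diagonal, entries in
#'   \[0, 1\], dimnames set to the fluorophore names.
#' @export
similarity_matrix <- function(panel) {
  sigs <- panel_signature_list(panel)
  k <- length(sigs)
  if (k < 2) cs_abort("need at least 2 signatures", "input")
  labs <- vapply(sigs, function(s) s$fluorophore, character(1))
  m <- diag(1, k)
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      m[i, j] <- m[j, i] <- similarity_index(sigs[[i]], sigs[[j]])
    }
  }
  dimnames(m) <- list(labs, labs)
  m
}

#' Panel complexity score
#'
#' Sum of all strictly-upper-triangle pairwise similarity indices. 0 for a
#' fully orthogonal panel; strictly increases when any pairwise overlap
#' increases. A surrogate for the vendor's unpublished panel-complexity
#' metric, so the vendor's printed values are not comparable.
#'
#' @param sim A square similarity matrix (e.g. from [similarity_matrix()]),
#'   or anything [similarity_matrix()] accepts.
#' @return Non-negative scalar.
#' @export
complexity_score <- function(sim) {
  if (!is.matrix(sim)) sim <- similarity_matrix(sim)
  if (nrow(sim) != ncol(sim)) cs_abort("similarity matrix must be square",
                                       "dimension")
  sum(sim[upper.tri(sim)])
}

#' Estimate a reference signature from single-stain controls
#'
#' Mirrors the reference-control workflow: the per-detector median of the
#' positive (stained) events minus the per-detector median of negative
#' (unstained) events, clipped at zero and unit-normalized. Median
#' subtraction makes the estimate invariant to a constant background added
#' to both tubes.
#'
#' @param single_stain_events Detector-space matrix or `event_matrix` of the
#'   single-stain control (positive fraction present).
#' @param negative_events Detector-space matrix or `event_matrix` of
#'   unstained events, same detector count.
#' @param fluorophore Name to attach to the estimate.
#' @return A `spectral_signature`.
#' @export
estimate_signature <- function(single_stain_events, negative_events,
                               fluorophore = "estimated") {
  pos <- event_exprs(single_stain_events)
  neg <- event_exprs(negative_events)
  if (ncol(pos) != ncol(neg)) {
    cs_abort("detector counts differ between control tubes", "dimension")
  }
  d <- apply(pos, 2, stats::median) - apply(neg, 2, stats::median)
  d <- pmax(d, 0)
  if (sum(d) == 0 || sqrt(sum(d^2)) == 0) {
    cs_abort("no positive signal above the negative control; cannot estimate",
             "estimation_failure")
  }
  spectral_signature(fluorophore, d)
}

signature_matrix <- function(signatures) {
  sigs <- panel_signature_list(signatures)
  S <- do.call(rbind, lapply(sigs, sig_vec))
  rownames(S) <- vapply(sigs, function(s) s$fluorophore, character(1))
  S
}

#' Least-squares spectral unmixing
#'
#' Per-event ordinary least squares: detector-space events `raw` are
#' decomposed as `raw ~ abundances %*% S` where the rows of `S` are the
#' unit-norm reference signatures (optionally plus one autofluorescence
#' row). No non-negativity constraint is applied, matching standard
#' spectral-unmixing practice.
#'
#' @param raw Detector-space events (`event_matrix` or numeric matrix,
#'   events x detectors).
#' @param signatures `panel_definition` or list of `spectral_signature`s.
#' @param include_autofluorescence Add an autofluorescence signature row?
#'   Off by default (cells with low autofluorescence do not need the tag).
#' @param autofluorescence The autofluorescence `spectral_signature`
#'   (required when `include_autofluorescence = TRUE`).
#' @return An `unmix_result`: list with `abundances` (events x
#'   fluorophores), `residual_rms` (per-event root-mean-square detector
#'   residual) and `residuals` (events x detectors).
#' @export
unmix <- function(raw, signatures, include_autofluorescence = FALSE,
                  autofluorescence = NULL) {
  X <- event_exprs(raw)
  S <- signature_matrix(signatures)
  if (include_autofluorescence) {
    if (is.null(autofluorescence)) {
      cs_abort("autofluorescence signature required when flag is on", "input")
    }
    S <- rbind(S, AF = sig_vec(autofluorescence))
    rownames(S)[nrow(S)] <- "AF"
  }
  if (nrow(S) > ncol(S)) {
    cs_abort(sprintf("more signatures (%d) than detectors (%d)",
                     nrow(S), ncol(S)), "dimension")
  }
  if (ncol(X) != ncol(S)) {
    cs_abort(sprintf("event detector count (%d) does not match signatures (%d)",
                     ncol(X), ncol(S)), "dimension")
  }
  G <- S %*% t(S)
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0 || max(ev) / min(ev) > 1e8) {
    sm <- abs(G / sqrt(diag(G) %o% diag(G))); diag(sm) <- 0
    worst <- which(sm == max(sm), arr.ind = TRUE)[1, ]
    cs_abort(sprintf(
      "signature matrix is (near) rank deficient; most collinear pair: %s / %s (similarity %.4f)",
      rownames(S)[worst[1]], rownames(S)[worst[2]], max(sm)), "collinearity")
  }
  A <- X %*% t(S) %*% solve(G)
  colnames(A) <- rownames(S)
  R <- X - A %*% S
  structure(list(abundances = A,
                 residual_rms = sqrt(rowMeans(R^2)),
                 residuals = R),
            class = "unmix_result")
}

#' @export
print.unmix_result <- function(x, ...) {
  cat("<unmix_result>", nrow(x$abundances), "events x",
      ncol(x$abundances), "fluorophores; median residual RMS",
      signif(stats::median(x$residual_rms), 4), "\n")
  invisible(x)
}

#' Numeric unmixing-quality report
#'
#' Summarizes per-detector absolute residuals of an [unmix()] fit (mean,
#' RMS and upper percentiles). A numeric stand-in for the visual NxN-plot
#' inspection used to audit unmixing quality.
#'
#' @param result An `unmix_result`.
#' @return A data frame with one row per detector: `detector`, `mean_abs`,
#'   `rms`, `p50`, `p95`, `p99`. Zero rows if the result holds no events.
#' @export
unmix_residual_report <- function(result) {
  if (!inherits(result, "unmix_result")) {
    cs_abort("expected an unmix_result", "input")
  }
  R <- abs(result$residuals)
  if (nrow(R) == 0) {
    return(data.frame(detector = character(0), mean_abs = numeric(0),
                      rms = numeric(0), p50 = numeric(0), p95 = numeric(0),
                      p99 = numeric(0)))
  }
  det <- colnames(R) %||% paste0("D", seq_len(ncol(R)))
  qs <- apply(R, 2, stats::quantile, probs = c(0.5, 0.95, 0.99), names = FALSE)
  data.frame(detector = det,
             mean_abs = colMeans(R),
             rms = sqrt(colMeans(R^2)),
             p50 = qs[1, ], p95 = qs[2, ], p99 = qs[3, ],
             row.names = NULL)
}
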