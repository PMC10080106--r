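# Drug-screen and cohort-comparison statistics: fractional differences vs
# vehicle, outlier masking, column clustering, t tests with star
# annotation, min-max normalization, variance filtering, PCA and a
# silhouette separation score.

#' Fractional difference of a treatment MFI against its control
#'
#' `FD = mfi_treat / mfi_control - 1`: the drug-effect statistic. The
#' vehicle control maps to exactly 0; FD is rendered in percent on
#' heatmaps (x 100). Vectorized; missing treatment MFIs propagate as `NA`.
#'
#' @param mfi_treat,mfi_control Median fluorescence intensities
#'   (`mfi_control` must be positive).
#' @return FD on the fractional scale, in (-1, Inf) for positive MFIs.
#' @export
fractional_difference <- function(mfi_treat, mfi_control) {
  if (any(!is.na(mfi_control) & mfi_control <= 0)) {
    cs_abort("control MFI must be positive", "degenerate")
  }
  mfi_treat / mfi_control - 1
}

#' Star annotation for p values
#'
#' `***` p < 0.001, `**` p < 0.01, `*` p < 0.05, otherwise `ns`.
#'
#' @param p Numeric vector of p values.
#' @return Character vector.
#' @export
p_stars <- function(p) {
  ifelse(is.na(p), NA_character_,
         ifelse(p < 0.001, "***",
                ifelse(p < 0.01, "**",
                       ifelse(p < 0.05, "*", "ns"))))
}

#' One-sample t test with screening annotation
#'
#' Tests whether the per-donor replicate values differ from `mu`
#' (two-sided); `t = mean / (sd / sqrt(n))` for `mu = 0`, `df = n - 1`.
#' Zero-variance input is reported as not testable rather than as p = 0.
#'
#' @param values Per-donor values (n >= 2).
#' @param mu Null value (default 0, the vehicle control).
#' @return List: `t`, `df`, `p`, `stars`, `mean`.
#' @export
one_sample_t <- function(values, mu = 0) {
  values <- values[!is.na(values)]
  if (length(values) < 2) cs_abort("need at least 2 replicates", "input")
  if (stats::sd(values) == 0) {
    cs_abort("zero variance across replicates; t test undefined",
             "undefined_test")
  }
  ht <- stats::t.test(values, mu = mu)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, stars = p_stars(ht$p.value), mean = mean(values))
}

#' Two-sample t test with screening annotation
#'
#' Pooled-variance Student's t by default (as in patient-vs-control bar
#' charts); set `welch = TRUE` for the unequal-variance form.
#'
#' @param group_a,group_b Replicate values (each n >= 2).
#' @param welch Use Welch's correction.
#' @return List: `t`, `df`, `p`, `stars`, `mean_a`, `mean_b`.
#' @export
two_sample_t <- function(group_a, group_b, welch = FALSE) {
  group_a <- group_a[!is.na(group_a)]
  group_b <- group_b[!is.na(group_b)]
  if (length(group_a) < 2 || length(group_b) < 2) {
    cs_abort("need at least 2 replicates per group", "input")
  }
  if (stats::sd(group_a) == 0 && stats::sd(group_b) == 0) {
    if (mean(group_a) == mean(group_b)) {
      cs_abort("both groups constant and equal; t test undefined",
               "undefined_test")
    }
  }
  ht <- stats::t.test(group_a, group_b, var.equal = !welch)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, stars = p_stars(ht$p.value),
       mean_a = mean(group_a), mean_b = mean(group_b))
}

#' Build an FD matrix from a long MFI table
#'
#' Takes per-sample subset MFIs in long form and computes, per donor, the
#' fractional difference of every (subset, marker) feature under every
#' treatment against the same donor's control condition.
#'
#' @param mfi_long Data frame with columns `donor`, `condition`, `subset`,
#'   `marker`, `mfi`.
#' @param control Control condition label (default `"DMSO"`).
#' @return An `fd_matrix`: list with `fd` (3-d array feature x treatment x
#'   donor), `mean_fd` (feature x treatment, donor mean), `mask` (logical,
#'   same shape as `mean_fd`, all `FALSE` initially) and `features`
#'   (subset/marker lookup).
#' @export
build_fd_matrix <- function(mfi_long, control = "DMSO") {
  need <- c("donor", "condition", "subset", "marker", "mfi")
  if (!all(need %in% names(mfi_long))) {
    cs_abort(paste("mfi table needs columns:", paste(need, collapse = ", ")),
             "input")
  }
  if (!control %in% mfi_long$condition) {
    cs_abort(sprintf("control condition '%s' absent from the table", control),
             "degenerate")
  }
  feats <- unique(mfi_long[, c("subset", "marker")])
  fid <- paste(feats$subset, feats$marker, sep = ":")
  treatments <- setdiff(unique(mfi_long$condition), control)
  donors <- unique(mfi_long$donor)
  key <- function(d, cond, s, m) paste(d, cond, s, m, sep = "\r")
  lut <- stats::setNames(mfi_long$mfi,
                         key(mfi_long$donor, mfi_long$condition,
                             mfi_long$subset, mfi_long$marker))
  fd <- array(NA_real_, c(length(fid), length(treatments), length(donors)),
              dimnames = list(fid, treatments, donors))
  for (di in seq_along(donors)) {
    ctrl <- lut[key(donors[di], control, feats$subset, feats$marker)]
    for (ti in seq_along(treatments)) {
      trt <- lut[key(donors[di], treatments[ti], feats$subset, feats$marker)]
      ok <- !is.na(ctrl) & ctrl > 0
      fd[ok, ti, di] <- trt[ok] / ctrl[ok] - 1
    }
  }
  mean_fd <- apply(fd, c(1, 2), function(v) {
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  })
  structure(list(fd = fd, mean_fd = mean_fd,
                 mask = array(FALSE, dim(mean_fd), dimnames(mean_fd)),
                 features = cbind(feature = fid, feats)),
            class = "fd_matrix")
}

#' Mask extreme FD values
#'
#' Flags cells whose pooled FD exceeds `bound` in magnitude with *strict*
#' inequalities (`FD < -bound` or `FD > bound`), matching the published
#' heatmap rule "outliers (x < -150%, x > 150%) removed": exactly +/-150%
#' is retained. Masked cells are flagged, never zeroed; unmasked values are
#' untouched and masking is idempotent.
#'
#' @param fdm An `fd_matrix`, or a numeric matrix/vector of FD values.
#' @param bound Mask bound on the fractional scale (default 1.5 = 150%).
#' @return Same type as the input; for an `fd_matrix` the `mask` entry is
#'   updated and `mean_fd_masked` (masked cells `NA`) added. For a bare
#'   matrix/vector, the values with masked entries set to `NA`.
#' @export
mask_outliers <- function(fdm, bound = 1.5) {
  if (!is.numeric(bound) || bound <= 0) cs_abort("bound must be > 0", "input")
  if (inherits(fdm, "fd_matrix")) {
    fdm$mask <- !is.na(fdm$mean_fd) &
      (fdm$mean_fd < -bound | fdm$mean_fd > bound)
    m <- fdm$mean_fd
    m[fdm$mask] <- NA_real_
    fdm$mean_fd_masked <- m
    return(fdm)
  }
  out <- fdm
  out[!is.na(out) & (out < -bound | out > bound)] <- NA_real_
  out
}

#' Hierarchically cluster treatment columns
#'
#' Agglomerative clustering of the treatment columns of a (masked) FD
#' matrix with Euclidean distance on pairwise-complete rows — scaled by
#' `sqrt(total/observed)`, which is `stats::dist`'s handling of missing
#' values — and complete linkage. Deterministic for a given column order;
#' distance ties are resolved by column index (hclust's convention).
#'
#' @param fdm An `fd_matrix` (uses the masked means when present) or a
#'   numeric feature x treatment matrix.
#' @param method Linkage (default `"complete"`).
#' @return List: `order` (column labels in dendrogram order), `merge`,
#'   `height`, and the `hclust` object.
#' @export
cluster_columns <- function(fdm, method = "complete") {
  m <- if (inherits(fdm, "fd_matrix")) {
    fdm$mean_fd_masked %||% fdm$mean_fd
  } else fdm
  if (ncol(m) < 2) cs_abort("need at least 2 columns to cluster", "input")
  d <- stats::dist(t(m))  # pairwise-complete, sqrt(total/observed)-scaled
  if (any(is.na(d))) {
    bad <- which(is.na(as.matrix(d)), arr.ind = TRUE)[1, ]
    cs_abort(sprintf(
      "columns '%s' and '%s' share no unmasked rows; cannot cluster",
      colnames(m)[bad[1]], colnames(m)[bad[2]]), "connectivity")
  }
  hc <- stats::hclust(d, method = method)
  list(order = colnames(m)[hc$order], merge = hc$merge, height = hc$height,
       hclust = hc)
}

#' Per-feature screening summary
#'
#' One-sample t test of every (feature, treatment) donor FD vector against
#' 0 (the vehicle), with star annotation. Features whose donor FDs cannot
#' be tested (missing or zero variance) are reported `NA`/not testable. No
#' multiple-testing correction by default, matching raw-p star annotation;
#' `adjust = "BH"` applies Benjamini-Hochberg across features within each
#' treatment.
#'
#' @param fdm An `fd_matrix`.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return A `screen_result` data frame: `feature`, `subset`, `marker`,
#'   `treatment`, `mean_fd`, `t`, `df`, `p`, `stars`, `masked`.
#' @export
screen_summary <- function(fdm, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(inherits(fdm, "fd_matrix"))
  dn <- dimnames(fdm$fd)
  rows <- list()
  for (ti in seq_along(dn[[2]])) {
    for (fi in seq_along(dn[[1]])) {
      v <- fdm$fd[fi, ti, ]
      tt <- tryCatch(one_sample_t(v), cytoscreen_error = function(e) NULL)
      rows[[length(rows) + 1]] <- data.frame(
        feature = dn[[1]][fi],
        subset = fdm$features$subset[fi],
        marker = fdm$features$marker[fi],
        treatment = dn[[2]][ti],
        mean_fd = fdm$mean_fd[fi, ti],
        t = tt$t %||% NA_real_, df = tt$df %||% NA_real_,
        p = tt$p %||% NA_real_,
        stars = tt$stars %||% NA_character_,
        masked = fdm$mask[fi, ti])
    }
  }
  out <- do.call(rbind, rows)
  if (adjust == "BH") {
    out$p_adj <- stats::ave(out$p, out$treatment,
                            FUN = function(p) stats::p.adjust(p, "BH"))
    out$stars <- p_stars(out$p_adj)
  }
  rownames(out) <- NULL
  class(out) <- c("screen_result", "data.frame")
  out
}

#' Min-max normalize a feature across donors
#'
#' `(x - min) / (max - min)`; a constant feature maps to all zeros (the
#' formula is 0/0 there, so the convention is declared and fixed).
#'
#' @param values Numeric vector (length >= 1).
#' @return Values in \[0, 1\].
#' @export
minmax_normalize <- function(values) {
  if (!length(values)) cs_abort("empty input", "input")
  rng <- range(values, na.rm = TRUE)
  if (rng[1] == rng[2]) return(rep(0, length(values)))
  (values - rng[1]) / (rng[2] - rng[1])
}

#' Drop the lowest-variance features
#'
#' Removes the `floor(fraction * F)` features (columns) with the smallest
#' variance; ties are broken by original column order. With the default
#' `fraction = 0.10` this is the "lower 10% of variables removed based on
#' variance" rule.
#'
#' @param mat Donors x features numeric matrix.
#' @param fraction Fraction of features to drop, in \[0, 1).
#' @return List: `matrix` (retained columns), `retained`, `removed`.
#' @export
variance_filter <- function(mat, fraction = 0.10) {
  if (fraction < 0 || fraction >= 1) cs_abort("fraction must be in [0, 1)", "input")
  v <- apply(mat, 2, stats::var)
  n_drop <- floor(fraction * ncol(mat))
  ord <- order(v, seq_along(v))  # stable: ties by original order
  removed <- sort(ord[seq_len(n_drop)])
  retained <- setdiff(seq_len(ncol(mat)), removed)
  list(matrix = mat[, retained, drop = FALSE],
       retained = colnames(mat)[retained] %||% retained,
       removed = colnames(mat)[removed] %||% removed)
}

#' Principal-component embedding of a normalized feature matrix
#'
#' Column-centered PCA (no rescaling beyond the min-max normalization the
#' caller applied), components ordered by decreasing explained variance.
#' Sign convention: each component is flipped so its largest-magnitude
#' loading is positive, making scores reproducible across platforms.
#'
#' @param mat Donors x features matrix (donors >= n_components + 1).
#' @param n_components Number of components (default 3).
#' @param groups Optional group labels stored in the embedding.
#' @return A `cohort_embedding`: list with `scores` (donors x components),
#'   `loadings`, `explained` (variance fractions), `groups`.
#' @export
pca_embed <- function(mat, n_components = 3, groups = NULL) {
  if (nrow(mat) < n_components + 1) {
    cs_abort(sprintf("need at least %d donors for %d components",
                     n_components + 1, n_components), "dimension")
  }
  pc <- stats::prcomp(mat, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  loadings <- pc$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    if (loadings[which.max(abs(loadings[, j])), j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  structure(list(scores = scores, loadings = loadings,
                 explained = pc$sdev^2 / sum(pc$sdev^2),
                 groups = groups),
            class = "cohort_embedding")
}

#' Silhouette separation score of a group-labeled embedding
#'
#' Mean silhouette coefficient of the group labels in component space: 1
#' for perfectly separated tight groups, about 0 for arbitrary labels,
#' negative when groups are inverted/mixed. Quantifies the "clear
#' separation" a cohort PCA plot is read for.
#'
#' @param embedding A `cohort_embedding` with `groups`, or a score matrix.
#' @param groups Group labels (>= 2 groups, >= 2 members each) if not in
#'   the embedding.
#' @return Mean silhouette width in \[-1, 1\].
#' @export
separation_score <- function(embedding, groups = NULL) {
  scores <- if (inherits(embedding, "cohort_embedding")) embedding$scores
  else as.matrix(embedding)
  groups <- groups %||%
    (if (inherits(embedding, "cohort_embedding")) embedding$groups)
  if (is.null(groups)) cs_abort("group labels required", "input")
  tab <- table(groups)
  if (length(tab) < 2 || any(tab < 2)) {
    cs_abort("need >= 2 groups with >= 2 donors each", "input")
  }
  sil <- cluster::silhouette(as.integer(factor(groups)),
                             stats::dist(scores))
  mean(sil[, "sil_width"])
}

#' Cohort feature matrix from stacked MFI tables
#'
#' Pivots a long per-sample MFI table into a donors x (subset:marker)
#' feature matrix, optionally restricted to given subsets/markers, for the
#' min-max + variance-filter + PCA cohort comparison.
#'
#' @param mfi_long Data frame with `donor`, `subset`, `marker`, `mfi`.
#' @param subsets,markers Optional filters.
#' @return Numeric matrix, donors x features.
#' @export
cohort_feature_matrix <- function(mfi_long, subsets = NULL, markers = NULL) {
  d <- mfi_long
  if (!is.null(subsets)) d <- d[d$subset %in% subsets, ]
  if (!is.null(markers)) d <- d[d$marker %in% markers, ]
  feat <- paste(d$subset, d$marker, sep = ":")
  donors <- unique(d$donor)
  feats <- unique(feat)
  m <- matrix(NA_real_, length(donors), length(feats),
              dimnames = list(donors, feats))
  m[cbind(match(d$donor, donors), match(feat, feats))] <- d$mfi
  m
}

#' Two-group cohort comparison
#'
#' The published patient-vs-control workflow: min-max normalize every
#' feature across donors, drop the lowest-variance decile, embed with
#' 3-component PCA and score the group separation; per-feature two-sample
#' t tests are reported alongside.
#'
#' @param feature_matrix Donors x features matrix (e.g. from
#'   [cohort_feature_matrix()]).
#' @param groups Group label per donor (row).
#' @param var_fraction Variance-filter fraction (default 0.10).
#' @param n_components PCA components (default 3).
#' @param welch Use Welch t tests.
#' @return List: `embedding`, `separation`, `tests` (per-feature data
#'   frame), `normalized` matrix, `retained`/`removed` features.
#' @export
compare_cohorts <- function(feature_matrix, groups, var_fraction = 0.10,
                            n_components = 3, welch = FALSE) {
  if (nrow(feature_matrix) != length(groups)) {
    cs_abort("one group label per donor row required", "input")
  }
  ok <- colSums(is.na(feature_matrix)) == 0
  fm <- feature_matrix[, ok, drop = FALSE]
  norm <- apply(fm, 2, minmax_normalize)
  rownames(norm) <- rownames(fm)
  vf <- variance_filter(norm, var_fraction)
  emb <- pca_embed(vf$matrix, n_components, groups = groups)
  gl <- unique(groups)
  tests <- do.call(rbind, lapply(colnames(fm), function(f) {
    tt <- tryCatch(
      two_sample_t(fm[groups == gl[1], f], fm[groups == gl[2], f],
                   welch = welch),
      cytoscreen_error = function(e) NULL)
    data.frame(feature = f, t = tt$t %||% NA_real_, p = tt$p %||% NA_real_,
               stars = tt$stars %||% NA_character_)
  }))
  list(embedding = emb, separation = separation_score(emb),
       tests = tests, normalized = norm,
       retained = vf$retained, removed = vf$removed)
}

#' Pivot a wide MFI table to long form
#'
#' Turns the wide output of [subset_mfi()]/[gate_cohort()] (one column per
#' marker) into the long `subset`/`marker`/`mfi` form that
#' [build_fd_matrix()] and [cohort_feature_matrix()] consume, carrying any
#' id columns (e.g. `sample_id`, `donor`, `condition`) along.
#'
#' @param mfi_wide Data frame from [subset_mfi()] (optionally with extra id
#'   columns prepended).
#' @return Long data frame with one row per (id columns, subset, marker).
#' @export
mfi_to_long <- function(mfi_wide) {
  idc <- intersect(c("sample_id", "donor", "group", "condition", "panel",
                     "subset", "n_events"), names(mfi_wide))
  mk <- setdiff(names(mfi_wide), idc)
  out <- do.call(rbind, lapply(mk, function(m) {
    cbind(mfi_wide[idc], marker = m, mfi = mfi_wide[[m]])
  }))
  rownames(out) <- NULL
  out
}

#' Gate a synthetic cohort and assemble its activation feature table
#'
#' Runs the packaged gating tree matching each sample's panel, extracts the
#' activation/inhibitory-marker MFIs of the headline subsets and returns a
#' long per-donor table ready for [cohort_feature_matrix()] /
#' [compare_cohorts()].
#'
#' @param cohort Output of [generate_cohort()].
#' @param subsets Named list with `pbmc` / `tcell` character vectors of
#'   gate ids to keep (defaults to the headline subsets).
#' @return Long data frame: `donor`, `group`, `subset` (prefixed by
#'   panel), `marker`, `mfi`.
#' @export
cohort_activation_mfi <- function(cohort,
                                  subsets = list(
                                    pbmc = c("t_cells", "b_cells", "nk_cells",
                                             "mono_classical", "dc"),
                                    tcell = c("cd4_t", "cd8_t", "treg",
                                              "tfh", "tph"))) {
  meta <- cohort$metadata
  out <- list()
  for (p in unique(meta$panel)) {
    tree <- if (p == "pbmc") pbmc_gating_tree() else tcell_gating_tree()
    panel <- if (p == "pbmc") pbmc_panel() else tcell_panel()
    mk <- panel$channels$marker[panel$channels$category %in%
                                  c("activation", "inhibitory")]
    ids <- meta$sample_id[meta$panel == p]
    gc <- gate_cohort(cohort$samples[ids], tree, markers = mk)
    m <- gc$mfi[gc$mfi$subset %in% subsets[[p]], ]
    long <- mfi_to_long(m)
    long$donor <- meta$donor[match(long$sample_id, meta$sample_id)]
    long$group <- meta$group[match(long$sample_id, meta$sample_id)]
    long$subset <- paste(p, long$subset, sep = ".")
    out[[p]] <- long[, c("donor", "group", "subset", "marker", "mfi")]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
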