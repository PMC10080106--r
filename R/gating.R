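# Declarative hierarchical gating with automatic 1-D threshold placement.
# Thresholds are placed on asinh-transformed fluorescence values; scatter
# gates operate on the raw scale. Tie-break convention, stated once and
# tested: value >= threshold is the positive side.

#' Automatic 1-D threshold placement
#'
#' `kde_valley` takes the deepest density minimum between the two highest
#' modes of a Gaussian kernel density estimate (Silverman's bandwidth);
#' `gmm2` fits a two-component Gaussian mixture and returns the
#' equal-posterior boundary between the component means; `quantile` returns
#' the empirical quantile `q`.
#'
#' @param values Numeric vector (already on the display/transform scale);
#'   at least 50 values for `kde_valley`/`gmm2`.
#' @param method One of `"kde_valley"`, `"gmm2"`, `"quantile"`.
#' @param q Quantile for `method = "quantile"`.
#' @return Threshold value.
#' @export
auto_threshold <- function(values, method = c("kde_valley", "gmm2", "quantile"),
                           q = 0.5) {
  method <- match.arg(method)
  values <- values[is.finite(values)]
  if (method == "quantile") {
    if (!length(values)) cs_abort("no finite values", "input")
    return(unname(stats::quantile(values, q)))
  }
  if (length(values) < 50) {
    cs_abort("need >= 50 values for density-based thresholding", "input")
  }
  if (method == "kde_valley") {
    d <- stats::density(values, bw = "nrd0", n = 512)
    y <- d$y
    is_max <- which(diff(sign(diff(y))) == -2) + 1
    if (length(is_max) < 2) {
      cs_abort("density is unimodal; no valley to place a threshold in",
               "no_valley")
    }
    top2 <- is_max[order(y[is_max], decreasing = TRUE)[1:2]]
    lo <- min(top2); hi <- max(top2)
    valley <- lo + which.min(y[lo:hi]) - 1
    return(d$x[valley])
  }
  # gmm2: deterministic model-based clustering fit (mclustBIC aliased into
  # scope because Mclust resolves it in the calling frame)
  mclustBIC <- mclust::mclustBIC
  fit <- mclust::Mclust(values, G = 2, modelNames = "V",
                        verbose = FALSE)
  if (is.null(fit)) cs_abort("2-component mixture fit failed", "no_valley")
  mu <- fit$parameters$mean
  grid <- seq(min(mu), max(mu), length.out = 512)
  pr <- do.call(cbind, lapply(1:2, function(k) {
    fit$parameters$pro[k] * stats::dnorm(grid, mu[k],
                                         sqrt(fit$parameters$variance$sigmasq[k]))
  }))
  grid[which.min(abs(pr[, 1] - pr[, 2]))]
}

# ---- gate constructors ----------------------------------------------------

#' Gate specifications
#'
#' Constructors for the gate types a [gating_tree()] node can carry:
#' `gate_all()` (root), `gate_range()` (1-D window, raw scale by default,
#' used for scatter), `gate_ratio()` (window on a channel ratio, e.g. the
#' FSC-H/FSC-A singlet gate), `gate_threshold()` (1-D split with an
#' automatic or fixed threshold), `gate_quadrant()` (one quadrant of a
#' shared 2-D threshold pair) and `gate_and()` (conjunction of several
#' threshold conditions).
#'
#' For automatic thresholds, `method` is tried first and `fallback_q` is the
#' quantile used if no valley is found; quantile thresholds pass
#' `method = "quantile"`. Thresholds are always computed from the parent
#' gate's events and cached per (parent, channel).
#'
#' @param channel,channel_x,channel_y Channel names.
#' @param min,max Window bounds.
#' @param numerator,denominator Ratio channels.
#' @param side `"+"` keeps values >= threshold, `"-"` keeps values below.
#' @param quadrant Two characters from `+`/`-`: sign on `channel_x` then
#'   `channel_y` (e.g. `"+-"` is x-positive, y-negative).
#' @param method,fallback_q Threshold method and fallback quantile.
#' @param value Fixed threshold (transform scale); disables auto placement.
#' @param gates List of `gate_threshold()` specs for `gate_and()`.
#' @return A gate specification (plain list).
#' @name gates
NULL

#' @rdname gates
#' @export
gate_all <- function() list(type = "all")

#' @rdname gates
#' @export
gate_range <- function(channel, min = -Inf, max = Inf) {
  list(type = "range", channel = channel, min = min, max = max)
}

#' @rdname gates
#' @export
gate_ratio <- function(numerator, denominator, min = -Inf, max = Inf) {
  list(type = "ratio", numerator = numerator, denominator = denominator,
       min = min, max = max)
}

#' @rdname gates
#' @export
gate_threshold <- function(channel, side = c("+", "-"),
                           method = "kde_valley", fallback_q = 0.5,
                           value = NULL) {
  side <- match.arg(side)
  list(type = "threshold", channel = channel, side = side, method = method,
       fallback_q = fallback_q, value = value)
}

#' @rdname gates
#' @export
gate_quadrant <- function(channel_x, channel_y, quadrant,
                          method = "kde_valley", fallback_q = 0.5) {
  if (!grepl("^[+-][+-]$", quadrant)) {
    cs_abort("quadrant must be two characters from '+'/'-'", "input")
  }
  list(type = "quadrant", channel_x = channel_x, channel_y = channel_y,
       quadrant = quadrant, method = method, fallback_q = fallback_q)
}

#' @rdname gates
#' @export
gate_and <- function(gates) list(type = "and", gates = gates)

#' Declare a gating-tree node
#'
#' @param id Unique node id.
#' @param parent Parent node id (`NULL` for the root).
#' @param gate A gate specification (see [gates]).
#' @param lineage Optional major-subset tag used for label accuracy
#'   summaries.
#' @return A `gate_node` (plain list).
#' @export
gate_node <- function(id, parent = NULL, gate = gate_all(), lineage = NULL) {
  structure(list(id = id, parent = parent, gate = gate, lineage = lineage),
            class = "gate_node")
}

#' Assemble a gating tree
#'
#' Nodes must form a single-rooted acyclic hierarchy; they are reordered
#' topologically. Node order among siblings defines label priority when
#' leaf gates overlap (first declared wins).
#'
#' @param nodes List of [gate_node()]s.
#' @param name Tree name.
#' @param cofactor asinh cofactor used for fluorescence channels.
#' @return A `gating_tree`.
#' @export
gating_tree <- function(nodes, name = "custom", cofactor = 150) {
  ids <- vapply(nodes, `[[`, character(1), "id")
  if (anyDuplicated(ids)) cs_abort("duplicate gate node ids", "configuration")
  names(nodes) <- ids
  roots <- ids[vapply(nodes, function(n) is.null(n$parent), logical(1))]
  if (length(roots) != 1) cs_abort("tree must have exactly one root", "configuration")
  for (n in nodes) {
    if (!is.null(n$parent) && !n$parent %in% ids) {
      cs_abort(sprintf("unknown parent '%s' of node '%s'", n$parent, n$id),
               "configuration")
    }
  }
  # topological order preserving declaration order among siblings
  ordered <- roots
  repeat {
    nxt <- ids[!ids %in% ordered &
                 vapply(nodes, function(n) (n$parent %||% "") %in% ordered,
                        logical(1))]
    if (!length(nxt)) break
    ordered <- c(ordered, nxt)
  }
  if (length(ordered) != length(ids)) cs_abort("gating tree contains a cycle",
                                               "configuration")
  structure(list(name = name, nodes = nodes[ordered], cofactor = cofactor),
            class = "gating_tree")
}

#' @export
print.gating_tree <- function(x, ...) {
  cat("<gating_tree>", x$name, "-", length(x$nodes), "nodes\n")
  depth <- function(id) {
    d <- 0
    while (!is.null(x$nodes[[id]]$parent)) { id <- x$nodes[[id]]$parent; d <- d + 1 }
    d
  }
  for (n in x$nodes) {
    cat(strrep("  ", depth(n$id)), n$id, " [", n$gate$type, "]",
        if (!is.null(n$lineage)) paste0(" <", n$lineage, ">") else "", "\n",
        sep = "")
  }
  invisible(x)
}

.tree_channels <- function(tree) {
  unique(unlist(lapply(tree$nodes, function(n) {
    g <- n$gate
    switch(g$type,
           range = g$channel,
           ratio = c(g$numerator, g$denominator),
           threshold = g$channel,
           quadrant = c(g$channel_x, g$channel_y),
           and = vapply(g$gates, `[[`, character(1), "channel"),
           NULL)
  })))
}

# threshold for one channel on the parent gate's events, with caching and
# the kde_valley -> gmm2 -> quantile fallback chain
.place_threshold <- function(vals, method, fallback_q) {
  if (method == "quantile") {
    return(list(value = auto_threshold(vals, "quantile", q = fallback_q),
                method = sprintf("quantile(%.2f)", fallback_q)))
  }
  th <- tryCatch(auto_threshold(vals, "kde_valley"), cytoscreen_no_valley = function(e) NULL,
                 cytoscreen_input = function(e) NULL)
  if (!is.null(th)) return(list(value = th, method = "kde_valley"))
  th <- tryCatch(auto_threshold(vals, "gmm2"), error = function(e) NULL)
  if (!is.null(th)) return(list(value = th, method = "gmm2"))
  list(value = auto_threshold(vals, "quantile", q = fallback_q),
       method = sprintf("quantile(%.2f) fallback", fallback_q))
}

#' Apply a gating tree to events
#'
#' Deterministically assigns events to the hierarchy: thresholds are placed
#' per node on its parent's events (cached per parent x channel so quadrant
#' families and sibling gates share them), membership uses the half-open
#' convention (value >= threshold is positive), and every event receives
#' the label of the first (declaration order) leaf gate containing it, or
#' `"other"`.
#'
#' @param events An `event_matrix` (raw scale).
#' @param tree A `gating_tree`.
#' @return A `gating_result`: per-node index sets (`indices`), per-event
#'   leaf `labels` and major-subset `lineages`, the placed `thresholds`
#'   (transform and raw scale) and bookkeeping.
#' @export
apply_gating <- function(events, tree) {
  stopifnot(inherits(tree, "gating_tree"))
  X <- event_exprs(events)
  chans <- .tree_channels(tree)
  miss <- setdiff(chans, colnames(X))
  if (length(miss)) {
    cs_abort(paste("events are missing gating channels:",
                   paste(miss, collapse = ", ")), "configuration")
  }
  Xt <- X
  fl <- colnames(X)[!is_scatter_channel(colnames(X))]
  Xt[, fl] <- asinh(X[, fl] / tree$cofactor)
  n <- nrow(X)
  indices <- list()
  cache <- new.env(parent = emptyenv())
  thresholds <- list()
  get_threshold <- function(parent_id, parent_idx, channel, method, fallback_q) {
    key <- paste(parent_id, channel, sep = "\r")
    if (!is.null(cache[[key]])) return(cache[[key]])
    vals <- Xt[parent_idx, channel]
    th <- .place_threshold(vals, method, fallback_q)
    th$raw <- if (channel %in% fl) tree$cofactor * sinh(th$value) else th$value
    cache[[key]] <- th
    thresholds[[length(thresholds) + 1]] <<-
      data.frame(node = parent_id, channel = channel, threshold = th$value,
                 threshold_raw = th$raw, method = th$method)
    th
  }
  side_keep <- function(vals, th, side) {
    if (side == "+") vals >= th else vals < th
  }
  for (node in tree$nodes) {
    g <- node$gate
    if (is.null(node$parent)) {
      indices[[node$id]] <- seq_len(n)
      next
    }
    pidx <- indices[[node$parent]]
    if (!length(pidx)) {
      indices[[node$id]] <- integer(0)
      next
    }
    keep <- switch(
      g$type,
      all = rep(TRUE, length(pidx)),
      range = {
        v <- X[pidx, g$channel]
        v >= g$min & v <= g$max
      },
      ratio = {
        r <- X[pidx, g$numerator] / X[pidx, g$denominator]
        r >= g$min & r <= g$max
      },
      threshold = {
        th <- if (!is.null(g$value)) list(value = g$value)
        else get_threshold(node$parent, pidx, g$channel, g$method, g$fallback_q)
        side_keep(Xt[pidx, g$channel], th$value, g$side)
      },
      quadrant = {
        thx <- get_threshold(node$parent, pidx, g$channel_x, g$method, g$fallback_q)
        thy <- get_threshold(node$parent, pidx, g$channel_y, g$method, g$fallback_q)
        sx <- substr(g$quadrant, 1, 1)
        sy <- substr(g$quadrant, 2, 2)
        side_keep(Xt[pidx, g$channel_x], thx$value, sx) &
          side_keep(Xt[pidx, g$channel_y], thy$value, sy)
      },
      and = {
        k <- rep(TRUE, length(pidx))
        for (sub in g$gates) {
          th <- if (!is.null(sub$value)) list(value = sub$value)
          else get_threshold(node$parent, pidx, sub$channel, sub$method,
                             sub$fallback_q)
          k <- k & side_keep(Xt[pidx, sub$channel], th$value, sub$side)
        }
        k
      },
      cs_abort(paste("unknown gate type", g$type), "configuration"))
    indices[[node$id]] <- pidx[keep]
  }
  # per-event labels: first leaf (declaration order) containing the event
  is_parent <- unique(unlist(lapply(tree$nodes, `[[`, "parent")))
  leaf_ids <- setdiff(names(tree$nodes), is_parent)
  labels <- rep("other", n)
  unassigned <- rep(TRUE, n)
  for (id in leaf_ids) {
    idx <- indices[[id]]
    take <- idx[unassigned[idx]]
    labels[take] <- id
    unassigned[take] <- FALSE
  }
  # per-event lineage: deepest tagged node containing the event
  lineages <- rep(NA_character_, n)
  for (node in tree$nodes) {      # topological order => deepest wins
    if (!is.null(node$lineage)) lineages[indices[[node$id]]] <- node$lineage
  }
  structure(list(tree = tree, n_events = n, indices = indices,
                 labels = labels, lineages = lineages,
                 thresholds = if (length(thresholds))
                   do.call(rbind, thresholds)
                 else data.frame()),
            class = "gating_result")
}

#' @export
print.gating_result <- function(x, ...) {
  cat("<gating_result>", x$n_events, "events,", length(x$indices), "gates\n")
  print(utils::head(subset_frequencies(x), 12))
  invisible(x)
}

#' Subset frequencies from a gating result
#'
#' @param result A `gating_result`.
#' @param viable_node Node id used as the denominator for `pct_of_viable`
#'   (default `"viable"` when present).
#' @return Data frame per node: `subset`, `parent`, `n_events`,
#'   `pct_of_parent` (0-100, `NA` when the parent is empty) and
#'   `pct_of_viable`.
#' @export
subset_frequencies <- function(result, viable_node = "viable") {
  stopifnot(inherits(result, "gating_result"))
  nodes <- result$tree$nodes
  nv <- if (viable_node %in% names(result$indices))
    length(result$indices[[viable_node]]) else NA_integer_
  rows <- lapply(nodes, function(nd) {
    n <- length(result$indices[[nd$id]])
    np <- if (is.null(nd$parent)) result$n_events
    else length(result$indices[[nd$parent]])
    data.frame(subset = nd$id, parent = nd$parent %||% NA_character_,
               n_events = n,
               pct_of_parent = if (np > 0) 100 * n / np else NA_real_,
               pct_of_viable = if (!is.na(nv) && nv > 0) 100 * n / nv
               else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-subset median fluorescence intensities
#'
#' Medians are computed on the raw intensity scale (the asinh transform is
#' monotone, so gating scale and MFI scale commute). Subsets with fewer
#' than `min_events` events are reported as missing rather than as an
#' unstable median.
#'
#' @param result A `gating_result`.
#' @param events The `event_matrix` that was gated.
#' @param markers Markers to summarize (default: all fluorescence channels).
#' @param min_events Minimum events for a reported median.
#' @return Data frame: `subset`, `n_events`, one column per marker.
#' @export
subset_mfi <- function(result, events, markers = NULL, min_events = 20) {
  stopifnot(inherits(result, "gating_result"))
  X <- event_exprs(events)
  if (is.null(markers)) {
    markers <- colnames(X)[!is_scatter_channel(colnames(X))]
  }
  miss <- setdiff(markers, colnames(X))
  if (length(miss)) {
    cs_abort(paste("unknown markers:", paste(miss, collapse = ", ")),
             "configuration")
  }
  rows <- lapply(names(result$indices), function(id) {
    idx <- result$indices[[id]]
    med <- if (length(idx) >= min_events) {
      apply(X[idx, markers, drop = FALSE], 2, stats::median)
    } else stats::setNames(rep(NA_real_, length(markers)), markers)
    cbind(data.frame(subset = id, n_events = length(idx)),
          as.data.frame(as.list(med), check.names = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Major-subset label accuracy against generator ground truth
#'
#' Compares the gated lineage of each event to the lineage of its
#' ground-truth population, restricted to events whose truth lineage is in
#' `lineages`.
#'
#' @param result A `gating_result`.
#' @param events The gated `event_matrix` (must carry truth labels).
#' @param tree The `population_tree` the events were generated from.
#' @param lineages Major subsets to score.
#' @return Accuracy in \[0, 1\].
#' @export
label_accuracy <- function(result, events, tree,
                           lineages = c("T", "B", "NK", "Mono", "DC")) {
  if (is.null(events$truth)) cs_abort("events carry no truth labels", "input")
  tl <- truth_lineages(tree)[events$truth]
  sel <- which(tl %in% lineages)
  hit <- result$lineages[sel] == tl[sel]
  mean(ifelse(is.na(hit), FALSE, hit))  # unassigned lineage counts as a miss
}

#' Gate several samples and stack frequency/MFI tables
#'
#' @param samples Named list of `event_matrix` objects.
#' @param tree A `gating_tree`.
#' @param markers Markers for the MFI table.
#' @return List with `frequencies` and `mfi` data frames (leading
#'   `sample_id` column) and the per-sample `results`.
#' @export
gate_cohort <- function(samples, tree, markers = NULL) {
  stopifnot(length(samples) >= 1)
  if (is.null(names(samples))) names(samples) <- paste0("S", seq_along(samples))
  res <- lapply(samples, apply_gating, tree = tree)
  freq <- do.call(rbind, Map(function(r, id) {
    cbind(sample_id = id, subset_frequencies(r))
  }, res, names(samples)))
  mfi <- do.call(rbind, Map(function(r, ev, id) {
    cbind(sample_id = id, subset_mfi(r, ev, markers = markers))
  }, res, samples, names(samples)))
  rownames(freq) <- rownames(mfi) <- NULL
  list(frequencies = freq, mfi = mfi, results = res)
}

#' Across-donor summary of subset frequencies
#'
#' @param frequencies The `frequencies` table from [gate_cohort()].
#' @param stat Column to summarize.
#' @return Data frame per subset: mean and interquartile range across
#'   samples.
#' @export
summarize_frequencies <- function(frequencies, stat = "pct_of_viable") {
  sp <- split(frequencies[[stat]], frequencies$subset)
  out <- data.frame(subset = names(sp),
                    mean = vapply(sp, function(v) mean(v, na.rm = TRUE), numeric(1)),
                    iqr = vapply(sp, function(v) stats::IQR(v, na.rm = TRUE), numeric(1)),
                    n = vapply(sp, function(v) sum(!is.na(v)), numeric(1)))
  rownames(out) <- NULL
  out
}

# ---- packaged gating hierarchies ------------------------------------------

.pregate_nodes <- function() {
  list(
    gate_node("all", gate = gate_all()),
    gate_node("cells", "all", gate_range("FSC-A", min = 45000)),
    gate_node("singlets", "cells", gate_ratio("FSC-H", "FSC-A", 0.75, 1.25)),
    gate_node("viable", "singlets",
              gate_threshold("LiveDead", "-", fallback_q = 0.90))
  )
}

#' Packaged PBMC gating hierarchy
#'
#' Scatter/debris removal, FSC-H/FSC-A singlet gate, viability-dye gate,
#' then CD3/CD19 quadrants (T and B cells), IgD/CD27 B-cell subsets with
#' CD38/CD27 plasmablasts within IgD- B cells, the CD3-CD19- HLA-DR split,
#' CD56+ NK cells with a CD16 early/mature split, CD14/CD16 monocyte
#' quadrants and CD11b/CD11c dendritic-cell subsets.
#'
#' @return A `gating_tree`.
#' @export
pbmc_gating_tree <- function() {
  nodes <- c(.pregate_nodes(), list(
    gate_node("t_cells", "viable", gate_quadrant("CD3", "CD19", "+-"),
              lineage = "T"),
    gate_node("b_cells", "viable", gate_quadrant("CD3", "CD19", "-+"),
              lineage = "B"),
    gate_node("t_b_dp", "viable", gate_quadrant("CD3", "CD19", "++")),
    gate_node("non_tb", "viable", gate_quadrant("CD3", "CD19", "--")),
    gate_node("b_naive", "b_cells", gate_quadrant("IgD", "CD27", "+-")),
    gate_node("b_um", "b_cells", gate_quadrant("IgD", "CD27", "++")),
    gate_node("b_swme", "b_cells", gate_quadrant("IgD", "CD27", "-+")),
    gate_node("b_dn", "b_cells", gate_quadrant("IgD", "CD27", "--")),
    gate_node("b_igdneg", "b_cells", gate_threshold("IgD", "-")),
    gate_node("b_pbpc", "b_igdneg",
              gate_quadrant("CD38", "CD27", "++", fallback_q = 0.95)),
    gate_node("hladr_neg", "non_tb", gate_threshold("HLA-DR", "-")),
    gate_node("hladr_pos", "non_tb", gate_threshold("HLA-DR", "+")),
    gate_node("nk_cells", "hladr_neg", gate_threshold("CD56", "+"),
              lineage = "NK"),
    gate_node("nk_mature", "nk_cells", gate_threshold("CD16", "+")),
    gate_node("nk_early", "nk_cells", gate_threshold("CD16", "-")),
    gate_node("mono_classical", "hladr_pos",
              gate_quadrant("CD14", "CD16", "+-"), lineage = "Mono"),
    gate_node("mono_intermediate", "hladr_pos",
              gate_quadrant("CD14", "CD16", "++"), lineage = "Mono"),
    gate_node("mono_nonclassical", "hladr_pos",
              gate_quadrant("CD14", "CD16", "-+"), lineage = "Mono"),
    gate_node("dc", "hladr_pos", gate_quadrant("CD14", "CD16", "--"),
              lineage = "DC"),
    gate_node("dc_mdc", "dc", gate_quadrant("CD11c", "CD11b", "++")),
    gate_node("dc_pdc", "dc", gate_quadrant("CD11c", "CD11b", "--"))
  ))
  gating_tree(nodes, name = "pbmc")
}

#' Packaged T-cell gating hierarchy
#'
#' After the shared pre-gates: TCR-gamma-delta cells first, then CD3+
#' alpha-beta T cells, CD4/CD8 quadrants, CCR7/CD45RA effector-memory
#' quadrants per lineage and the T-helper gates on CD4+ cells (Th1
#' CCR4-CXCR3+, Th2 CCR4+CXCR3-, Th17 CCR4-CXCR3-CXCR5-CCR6+, Treg
#' CD25+CD127low, Tfh CD45RA-CXCR5+, Tph CXCR5-PD-1high). Fallback
#' quantiles for rare-positive channels reflect the expected positive
#' fractions.
#'
#' @return A `gating_tree`.
#' @export
tcell_gating_tree <- function() {
  mem_quads <- function(parent, prefix) list(
    gate_node(paste0(prefix, "_tn"), parent,
              gate_quadrant("CD45RA", "CCR7", "++")),
    gate_node(paste0(prefix, "_tcm"), parent,
              gate_quadrant("CD45RA", "CCR7", "-+")),
    gate_node(paste0(prefix, "_tem"), parent,
              gate_quadrant("CD45RA", "CCR7", "--")),
    gate_node(paste0(prefix, "_temra"), parent,
              gate_quadrant("CD45RA", "CCR7", "+-"))
  )
  nodes <- c(.pregate_nodes(), list(
    gate_node("gd_t", "viable",
              gate_threshold("TCRgd", "+", fallback_q = 0.97),
              lineage = "gdT"),
    gate_node("ab_t", "viable",
              gate_and(list(gate_threshold("TCRgd", "-", fallback_q = 0.97),
                            gate_threshold("CD3", "+"))),
              lineage = "T"),
    gate_node("cd4_t", "ab_t", gate_quadrant("CD4", "CD8", "+-"),
              lineage = "CD4"),
    gate_node("cd8_t", "ab_t", gate_quadrant("CD4", "CD8", "-+"),
              lineage = "CD8"),
    gate_node("dp_t", "ab_t", gate_quadrant("CD4", "CD8", "++"),
              lineage = "DPT"),
    gate_node("dn_t", "ab_t", gate_quadrant("CD4", "CD8", "--"),
              lineage = "DNT"),
    gate_node("th1", "cd4_t",
              gate_and(list(gate_threshold("CCR4", "-", fallback_q = 0.97),
                            gate_threshold("CXCR3", "+", fallback_q = 0.60)))),
    gate_node("th2", "cd4_t",
              gate_and(list(gate_threshold("CCR4", "+", fallback_q = 0.97),
                            gate_threshold("CXCR3", "-", fallback_q = 0.60)))),
    gate_node("th17", "cd4_t",
              gate_and(list(gate_threshold("CCR4", "-", fallback_q = 0.97),
                            gate_threshold("CXCR3", "-", fallback_q = 0.60),
                            gate_threshold("CXCR5", "-", fallback_q = 0.88),
                            gate_threshold("CCR6", "+", fallback_q = 0.92)))),
    gate_node("treg", "cd4_t",
              gate_and(list(gate_threshold("CD25", "+", fallback_q = 0.90),
                            gate_threshold("CD127", "-", fallback_q = 0.25)))),
    gate_node("tfh", "cd4_t",
              gate_and(list(gate_threshold("CD45RA", "-", fallback_q = 0.50),
                            gate_threshold("CXCR5", "+", fallback_q = 0.88)))),
    gate_node("tph", "cd4_t",
              gate_and(list(gate_threshold("CXCR5", "-", fallback_q = 0.88),
                            gate_threshold("CD45RA", "-", fallback_q = 0.50),
                            gate_threshold("PD-1", "+", fallback_q = 0.90))))),
    mem_quads("cd4_t", "cd4"),
    mem_quads("cd8_t", "cd8")
  )
  gating_tree(nodes, name = "tcell")
}
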