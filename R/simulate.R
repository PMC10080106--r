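# Seeded synthetic cytometry generator. Marker expression is log-normal per
# population (the standard model for cytometry intensities); positive vs
# negative status is encoded purely through the log-location so subset
# identities stay crisp for the gating tests. Every generator output is a
# pure function of (spec, seed).

# canonical log-normal expression levels on the raw intensity scale:
# median = exp(mu). "neg" ~ unstained background, "lo" dim, "pos" clearly
# positive, "hi" bright (used for PD-1^high, CD38^high plasmablasts, dead dye)
.expr_levels <- list(
  neg = c(mu = log(60),    sd = 0.55),
  lo  = c(mu = log(400),   sd = 0.50),
  mid = c(mu = log(300),   sd = 0.60),
  pos = c(mu = log(5000),  sd = 0.45),
  hi  = c(mu = log(20000), sd = 0.40)
)

#' Declare one node of a population taxonomy
#'
#' @param name Node name (unique within a tree).
#' @param parent Parent node name, or `NULL` for a root-level population.
#' @param fraction Fraction of the parent population in \[0, 1\].
#' @param lineage Major-subset tag (e.g. `"T"`, `"B"`, `"NK"`, `"Mono"`,
#'   `"DC"`); inherited by children unless overridden.
#' @param pos,hi,lo,mid,neg Markers expressed at the corresponding canonical
#'   level (positive, bright, dim, intermediate, negative); unspecified
#'   markers default to negative. Children inherit the parent's profile and
#'   override per marker (`neg` resets an inherited positive marker).
#' @param scatter `"lymphocyte"` or `"monocyte"` scatter class.
#' @return A `population_node` description (plain list).
#' @export
population_node <- function(name, parent = NULL, fraction = 1,
                            lineage = NULL, pos = character(0),
                            hi = character(0), lo = character(0),
                            mid = character(0), neg = character(0),
                            scatter = NULL) {
  if (fraction < 0 || fraction > 1) {
    cs_abort(sprintf("fraction of '%s' outside [0, 1]", name), "composition")
  }
  structure(list(name = name, parent = parent, fraction = fraction,
                 lineage = lineage, pos = pos, hi = hi, lo = lo, mid = mid,
                 neg = neg, scatter = scatter),
            class = "population_node")
}

#' Assemble a population tree
#'
#' Validates the hierarchy (children's fractions must not exceed 1 within a
#' parent), resolves inherited expression profiles and flattens the leaves
#' into an absolute composition over the viable-cell compartment.
#'
#' @param nodes List of [population_node()] descriptions.
#' @param markers Character vector of marker channels every population
#'   expresses (at some level).
#' @param name Tree name.
#' @return A `population_tree` with a `leaves` data frame (name, lineage,
#'   absolute fraction, scatter class) and per-leaf log-normal expression
#'   parameters.
#' @export
population_tree <- function(nodes, markers, name = "custom") {
  names(nodes) <- vapply(nodes, `[[`, character(1), "name")
  if (anyDuplicated(names(nodes))) cs_abort("duplicate population names", "composition")
  for (nd in nodes) {
    if (!is.null(nd$parent) && !nd$parent %in% names(nodes)) {
      cs_abort(sprintf("unknown parent '%s' of '%s'", nd$parent, nd$name),
               "composition")
    }
  }
  kids <- split(names(nodes),
                vapply(nodes, function(n) n$parent %||% ".root", character(1)))
  for (p in names(kids)) {
    fr <- sum(vapply(nodes[kids[[p]]], `[[`, numeric(1), "fraction"))
    if (fr > 1 + 1e-8) {
      cs_abort(sprintf("children of '%s' have fractions summing to %.4f > 1",
                       p, fr), "composition")
    }
  }
  # resolve each node's absolute fraction, lineage, scatter and profile
  resolve <- function(nm) {
    nd <- nodes[[nm]]
    if (is.null(nd$parent)) {
      anc <- list(fraction = 1, lineage = NULL, scatter = "lymphocyte",
                  profile = stats::setNames(rep("neg", length(markers)), markers))
    } else anc <- resolve(nd$parent)
    prof <- anc$profile
    for (lvl in c("neg", "pos", "hi", "lo", "mid")) {
      mk <- nd[[lvl]]
      bad <- setdiff(mk, markers)
      if (length(bad)) {
        cs_abort(paste("unknown markers in profile:", paste(bad, collapse = ", ")),
                 "reference")
      }
      prof[mk] <- lvl
    }
    list(fraction = anc$fraction * nd$fraction,
         lineage = nd$lineage %||% anc$lineage,
         scatter = nd$scatter %||% anc$scatter,
         profile = prof)
  }
  res <- lapply(names(nodes), resolve)
  names(res) <- names(nodes)
  is_leaf <- !names(nodes) %in% unlist(lapply(nodes, `[[`, "parent"))
  leaves <- data.frame(
    name = names(nodes)[is_leaf],
    lineage = vapply(res[is_leaf], function(r) r$lineage %||% "other", character(1)),
    fraction = vapply(res[is_leaf], `[[`, numeric(1), "fraction"),
    scatter = vapply(res[is_leaf], `[[`, character(1), "scatter"),
    row.names = NULL)
  if (sum(leaves$fraction) > 1 + 1e-8) {
    cs_abort("leaf fractions sum above 1", "composition")
  }
  structure(list(name = name, markers = markers, nodes = nodes,
                 leaves = leaves,
                 profiles = lapply(res[is_leaf], `[[`, "profile"),
                 expr_levels = .expr_levels),
            class = "population_tree")
}

#' @export
print.population_tree <- function(x, ...) {
  cat("<population_tree>", x$name, "-", nrow(x$leaves), "leaf populations,",
      length(x$markers), "markers\n")
  print(x$leaves)
  invisible(x)
}

#' Default healthy-donor PBMC composition
#'
#' Leaf fractions encode the reported healthy-donor means: 70.6% T cells,
#' 7.5% B cells (59.4/14.6/18.5/7.5 naive/unswitched/switched/double-negative,
#' plasmablasts 4.1% of IgD- B), 7.1% NK, 4.1% monocytes, 2.1% DC of viable
#' PBMCs; the remainder is unlabeled. Monocyte (43.5/5.4/2.1) and DC
#' (28.6/45.3) sub-fractions are renormalized proportionally so that they
#' partition their parent gate.
#'
#' @return A `population_tree`.
#' @export
pbmc_population_tree <- function() {
  m <- c("CD126", "HLA-DR", "IgD", "CD16", "IgG", "CD4", "CD56", "CD95",
         "CD11b", "PD-1", "CD11c", "CD69", "CD27", "CD70", "CD14", "CD3",
         "CD25", "CD169", "CD86", "CD19", "CD38")
  # plasmablasts/plasma cells: 4.1% of IgD- B (= 26% of B) -> 1.066% of B,
  # carved out of the switched-memory (IgD- CD27+) compartment
  pbpc <- 0.041 * (0.185 + 0.075)
  nodes <- list(
    population_node("t_cells", fraction = 0.706, lineage = "T",
                    pos = c("CD3", "CD27"), lo = c("CD4", "CD95")),
    population_node("b_cells", fraction = 0.075, lineage = "B",
                    pos = c("CD19", "HLA-DR")),
    population_node("b_naive", "b_cells", 0.594, pos = "IgD"),
    population_node("b_um", "b_cells", 0.146, pos = c("IgD", "CD27")),
    population_node("b_swme", "b_cells", 0.185 - pbpc, pos = c("CD27", "IgG")),
    population_node("b_dn", "b_cells", 0.075),
    population_node("b_pbpc", "b_cells", pbpc, pos = "CD27", hi = "CD38"),
    population_node("nk_cells", fraction = 0.071, lineage = "NK",
                    pos = "CD56"),
    population_node("nk_mature", "nk_cells", 0.90, pos = "CD16"),
    population_node("nk_early", "nk_cells", 0.10, hi = "CD56"),
    population_node("monocytes", fraction = 0.041, lineage = "Mono",
                    scatter = "monocyte",
                    pos = c("HLA-DR", "CD86"),
                    lo = c("CD69", "CD95", "CD169", "CD126", "CD11b")),
    population_node("mono_classical", "monocytes", 43.5 / 51.0, pos = "CD14"),
    population_node("mono_intermediate", "monocytes", 5.4 / 51.0,
                    pos = c("CD14", "CD16")),
    population_node("mono_nonclassical", "monocytes", 2.1 / 51.0, pos = "CD16"),
    population_node("dc", fraction = 0.021, lineage = "DC",
                    scatter = "monocyte", pos = "HLA-DR", lo = "CD86"),
    population_node("dc_pdc", "dc", 28.6 / 73.9, lo = "CD70"),
    population_node("dc_mdc", "dc", 45.3 / 73.9, pos = "CD11b", hi = "CD11c"),
    population_node("other_lymphocytes", fraction = 0.086, lineage = "other")
  )
  population_tree(nodes, m, name = "pbmc_healthy")
}

#' Default healthy-donor T-cell panel composition
#'
#' 70.6% of viable events are T cells; 3.2% of those are TCR-gamma-delta.
#' Within the alpha-beta compartment the reported CD4 (54.5%), CD8 (32.6%)
#' and double-positive (1.3%) fractions are kept as printed, the
#' double-negative gate absorbing the remainder. CD4 T-helper leaves use the
#' reported means (Th1 32.9, Th2 2.0, Th17 7.0, Treg 7.0, Tfh 10.1, Tph 3.4,
#' rest naive) and CD8 memory leaves the reported CCR7/CD45RA quadrant
#' means.
#'
#' @return A `population_tree`.
#' @export
tcell_population_tree <- function() {
  m <- c("CCR7", "CD45RO", "TCRgd", "CD8", "CD134", "CD28", "CCR6", "CXCR5",
         "PD-1", "CD69", "CTLA-4", "CXCR3", "CD45RA", "CD71", "CCR4", "CD4",
         "CD25", "ICOS", "CD127", "CD3", "CD38")
  nodes <- list(
    population_node("t_cells", fraction = 0.706, lineage = "T",
                    pos = c("CD3", "CD28")),
    population_node("gd_t", "t_cells", 0.032, lineage = "gdT", pos = "TCRgd"),
    population_node("ab_t", "t_cells", 0.968),
    population_node("cd4_t", "ab_t", 0.545, lineage = "CD4",
                    pos = c("CD4", "CD127")),
    population_node("cd4_naive", "cd4_t", 0.376,
                    pos = c("CCR7", "CD45RA")),
    population_node("th1", "cd4_t", 0.329, pos = c("CXCR3", "CD45RO")),
    population_node("th2", "cd4_t", 0.020, pos = c("CCR4", "CD45RO")),
    population_node("th17", "cd4_t", 0.070, pos = c("CCR6", "CD45RO")),
    population_node("treg", "cd4_t", 0.070, pos = c("CD25", "CD45RO"),
                    lo = "CTLA-4", neg = "CD127"),
    population_node("tfh", "cd4_t", 0.101,
                    pos = c("CXCR5", "CD45RO", "CCR7"), lo = "PD-1"),
    population_node("tph", "cd4_t", 0.034, pos = "CD45RO", hi = "PD-1",
                    lo = "ICOS"),
    population_node("cd8_t", "ab_t", 0.326, lineage = "CD8",
                    pos = c("CD8", "CD127")),
    population_node("cd8_tn", "cd8_t", 0.465, pos = c("CCR7", "CD45RA")),
    population_node("cd8_tcm", "cd8_t", 0.167, pos = c("CCR7", "CD45RO")),
    population_node("cd8_tem", "cd8_t", 0.207, pos = "CD45RO"),
    population_node("cd8_temra", "cd8_t", 0.161, pos = "CD45RA"),
    population_node("dp_t", "ab_t", 0.013, lineage = "DPT",
                    pos = c("CD4", "CD8")),
    population_node("dn_t", "ab_t", 0.116, lineage = "DNT"),
    population_node("non_t", fraction = 0.294, lineage = "other")
  )
  population_tree(nodes, m, name = "tcell_healthy")
}

#' Donor specification for the synthetic generator
#'
#' @param donor_id Donor identifier.
#' @param composition_jitter Scale of the logit-normal perturbation applied
#'   to leaf fractions (biological donor-to-donor variability). 0 disables
#'   it.
#' @param group Cohort label, `"HC"` or `"RA"`.
#' @param condition Condition label (e.g. `"unstim"`, `"PHA"`, `"DMSO"`,
#'   `"drug_1"`).
#' @param seed Seed recorded with (and used by) every draw for this donor.
#' @return A `donor_spec`.
#' @export
donor_spec <- function(donor_id, composition_jitter = 0.15, group = "HC",
                       condition = "unstim", seed = 1) {
  structure(list(donor_id = donor_id,
                 composition_jitter = composition_jitter,
                 group = group, condition = condition, seed = seed),
            class = "donor_spec")
}

.scatter_params <- list(
  lymphocyte = c(fsc = 100000, fsc_sd = 12000, ssc = 30000, ssc_sd = 8000),
  monocyte   = c(fsc = 150000, fsc_sd = 15000, ssc = 80000, ssc_sd = 15000)
)

.draw_population_block <- function(n, profile, scatter_class, levels) {
  mk <- names(profile)
  X <- matrix(0, n, length(mk) + 4,
              dimnames = list(NULL, c("FSC-A", "FSC-H", "SSC-A", "LiveDead", mk)))
  sp <- .scatter_params[[scatter_class]]
  fsc <- stats::rnorm(n, sp["fsc"], sp["fsc_sd"])
  X[, "FSC-A"] <- fsc
  X[, "FSC-H"] <- fsc / 1.02 * (1 + stats::rnorm(n, 0, 0.03))
  X[, "SSC-A"] <- pmax(stats::rnorm(n, sp["ssc"], sp["ssc_sd"]), 0)
  X[, "LiveDead"] <- stats::rlnorm(n, levels$neg["mu"], levels$neg["sd"])
  for (j in seq_along(mk)) {
    lv <- levels[[profile[j]]]
    X[, mk[j]] <- stats::rlnorm(n, lv["mu"], lv["sd"])
  }
  X
}

#' Generate one donor's synthetic events
#'
#' Event labels are drawn multinomially from the donor-perturbed leaf
#' composition; marker intensities are log-normal per population. Debris
#' (low forward scatter), doublets (FSC-A about twice FSC-H) and dead cells
#' (bright viability-dye signal) are added at configurable rates; with the
#' defaults about 83% of events are viable cells, matching the roughly 80%
#' viability reported for PHA cultures. Output is a pure function of
#' (tree, donor, n_events, rates, seed).
#'
#' @param tree A `population_tree`.
#' @param donor A [donor_spec()].
#' @param n_events Total events to draw (>= 1).
#' @param debris_frac,doublet_frac,dead_frac Contaminant rates.
#' @param seed Overrides `donor$seed` when given.
#' @return An `event_matrix` with `truth` labels (leaf names or
#'   `debris`/`doublet`/`dead`) and donor metadata.
#' @export
generate_donor_events <- function(tree, donor = donor_spec("D1"),
                                  n_events = 10000,
                                  debris_frac = 0.02, doublet_frac = 0.05,
                                  dead_frac = 0.10, seed = NULL) {
  stopifnot(inherits(tree, "population_tree"), n_events >= 1)
  seed <- seed %||% donor$seed
  frac_junk <- debris_frac + doublet_frac + dead_frac
  if (frac_junk >= 1) cs_abort("contaminant fractions sum to >= 1", "composition")
  withr::with_seed(seed, {
    f <- tree$leaves$fraction
    f <- f / sum(f)
    if (donor$composition_jitter > 0) {
      l <- stats::qlogis(pmin(pmax(f, 1e-12), 1 - 1e-12))
      f <- stats::plogis(l + stats::rnorm(length(l), 0, donor$composition_jitter))
      f <- f / sum(f)
    }
    probs <- c(debris_frac, doublet_frac, dead_frac, (1 - frac_junk) * f)
    labs <- c("debris", "doublet", "dead", tree$leaves$name)
    counts <- as.vector(stats::rmultinom(1, n_events, probs))
    blocks <- vector("list", length(labs))
    for (i in seq_along(labs)) {
      n <- counts[i]
      if (n == 0) next
      lab <- labs[i]
      if (lab == "debris") {
        X <- .draw_population_block(n, stats::setNames(rep("neg", length(tree$markers)),
                                                       tree$markers),
                                    "lymphocyte", tree$expr_levels)
        X[, "FSC-A"] <- abs(stats::rnorm(n, 20000, 8000))
        X[, "FSC-H"] <- X[, "FSC-A"] * stats::runif(n, 0.9, 1.1)
        X[, "SSC-A"] <- abs(stats::rnorm(n, 10000, 5000))
      } else if (lab == "doublet") {
        X <- .draw_population_block(n, stats::setNames(rep("mid", length(tree$markers)),
                                                       tree$markers),
                                    "lymphocyte", tree$expr_levels)
        h <- stats::rnorm(n, 100000, 12000)
        X[, "FSC-H"] <- h
        X[, "FSC-A"] <- 2 * h * (1 + stats::rnorm(n, 0, 0.05))
      } else if (lab == "dead") {
        X <- .draw_population_block(n, stats::setNames(rep("mid", length(tree$markers)),
                                                       tree$markers),
                                    "lymphocyte", tree$expr_levels)
        X[, "LiveDead"] <- stats::rlnorm(n, tree$expr_levels$hi["mu"],
                                         tree$expr_levels$hi["sd"])
      } else {
        k <- match(lab, tree$leaves$name)
        X <- .draw_population_block(n, tree$profiles[[k]],
                                    tree$leaves$scatter[k], tree$expr_levels)
      }
      blocks[[i]] <- X
    }
    keep <- counts > 0
    X <- do.call(rbind, blocks[keep])
    truth <- rep(labs[keep], counts[keep])
    ord <- sample.int(nrow(X))
    event_matrix(X[ord, , drop = FALSE], truth = truth[ord],
                 meta = list(donor = donor$donor_id, group = donor$group,
                             condition = donor$condition, seed = seed,
                             tree = tree$name))
  })
}

#' Major-subset lineage of each ground-truth label
#' @param tree A `population_tree`.
#' @return Named character vector mapping leaf names (plus
#'   debris/doublet/dead) to lineage tags.
#' @export
truth_lineages <- function(tree) {
  c(stats::setNames(tree$leaves$lineage, tree$leaves$name),
    debris = "junk", doublet = "junk", dead = "junk")
}

#' Define a multiplicative condition effect
#'
#' Maps (population, marker) pairs to multiplicative factors k > 0 applied
#' to the population's raw-scale median (the log-location shifts by log k).
#' The implied ground-truth fractional difference of the affected MFI is
#' k - 1. Population names may be leaf names, internal node names (the
#' effect then covers all descendant leaves) or lineage tags.
#'
#' @param population,marker,factor Equal-length vectors.
#' @return A `condition_effect` data frame.
#' @export
condition_effect <- function(population, marker, factor) {
  if (any(factor <= 0)) cs_abort("effect factors must be > 0", "input")
  structure(data.frame(population = population, marker = marker,
                       factor = factor),
            class = c("condition_effect", "data.frame"))
}

.match_leaves <- function(tree, population) {
  if (population %in% tree$leaves$name) return(population)
  if (population %in% names(tree$nodes)) {
    # all descendant leaves of an internal node
    desc <- population
    repeat {
      more <- names(tree$nodes)[vapply(tree$nodes, function(n)
        !is.null(n$parent) && n$parent %in% desc, logical(1))]
      new <- setdiff(more, desc)
      if (!length(new)) break
      desc <- c(desc, new)
    }
    return(intersect(tree$leaves$name, desc))
  }
  if (population %in% tree$leaves$lineage) {
    return(tree$leaves$name[tree$leaves$lineage == population])
  }
  cs_abort(sprintf("unknown population '%s'", population), "reference")
}

#' Apply a condition effect to a population tree
#'
#' Shifts the log-location of each targeted (population, marker) pair by
#' log(k); the composition is left unchanged (mitogen stimulation does not
#' alter subset distributions).
#'
#' @param tree A `population_tree`.
#' @param effect A [condition_effect()].
#' @return The modified tree.
#' @export
apply_condition <- function(tree, effect) {
  stopifnot(inherits(tree, "population_tree"))
  for (i in seq_len(nrow(effect))) {
    mk <- effect$marker[i]
    if (!mk %in% tree$markers) {
      cs_abort(sprintf("unknown marker '%s' in condition effect", mk),
               "reference")
    }
    leaves <- .match_leaves(tree, effect$population[i])
    for (lf in leaves) {
      prof <- tree$profiles[[lf]]
      lvl <- tree$expr_levels[[prof[mk]]]
      # promote the marker to a leaf-specific numeric level
      key <- paste0(".", lf, ".", mk)
      tree$expr_levels[[key]] <- c(mu = unname(lvl["mu"]) + log(effect$factor[i]),
                                   sd = unname(lvl["sd"]))
      tree$profiles[[lf]][mk] <- key
    }
  }
  tree
}

#' Rescale the composition of selected populations
#'
#' Multiplies the `fraction` of the named nodes by the given factors, then
#' renormalizes their sibling family so the family total is preserved.
#' Used by the packaged patient-cohort effect (e.g. fewer Th2, more
#' Tfh/Tph/Treg).
#'
#' @param tree A `population_tree`.
#' @param population,factor Equal-length vectors; populations must be node
#'   names.
#' @return The modified tree (rebuilt, so leaf fractions are recomputed).
#' @export
scale_composition <- function(tree, population, factor) {
  stopifnot(inherits(tree, "population_tree"))
  nodes <- tree$nodes
  for (i in seq_along(population)) {
    nm <- population[i]
    if (!nm %in% names(nodes)) {
      cs_abort(sprintf("unknown population '%s'", nm), "reference")
    }
    nodes[[nm]]$fraction <- nodes[[nm]]$fraction * factor[i]
  }
  # renormalize each touched sibling family back to its original total
  fam <- vapply(nodes, function(n) n$parent %||% ".root", character(1))
  for (p in unique(fam[population])) {
    sibs <- names(nodes)[fam == p]
    old <- sum(vapply(tree$nodes[sibs], `[[`, numeric(1), "fraction"))
    new <- sum(vapply(nodes[sibs], `[[`, numeric(1), "fraction"))
    for (s in sibs) nodes[[s]]$fraction <- nodes[[s]]$fraction * old / new
  }
  out <- population_tree(unname(nodes), tree$markers, name = tree$name)
  out$expr_levels <- tree$expr_levels
  out$profiles <- out$profiles[names(out$profiles)]
  for (lf in names(tree$profiles)) {
    if (lf %in% names(out$profiles)) out$profiles[[lf]] <- tree$profiles[[lf]]
  }
  out
}

#' Packaged PHA stimulation effect
#'
#' Strong induction of CD69 across all subsets plus CD38/CD25/HLA-DR (or
#' panel equivalents) increases in the populations the stimulation
#' narrative describes. Magnitudes are nominal synthetic choices, not
#' reported values.
#'
#' @param panel `"pbmc"` or `"tcell"`.
#' @return A [condition_effect()].
#' @export
pha_condition_effect <- function(panel = c("pbmc", "tcell")) {
  panel <- match.arg(panel)
  if (panel == "pbmc") {
    condition_effect(
      population = c("t_cells", "b_cells", "nk_cells", "monocytes", "dc",
                     "t_cells", "monocytes", "monocytes", "t_cells"),
      marker = c("CD69", "CD69", "CD69", "CD69", "CD69",
                 "CD38", "CD38", "HLA-DR", "CD25"),
      factor = c(5, 5, 5, 5, 5, 2, 2, 1.5, 2))
  } else {
    condition_effect(
      population = c("t_cells", "t_cells", "cd4_t", "tph", "tph", "treg",
                     "th2", "t_cells"),
      marker = c("CD69", "CD38", "CD25", "CD134", "PD-1", "CD25",
                 "ICOS", "CCR7"),
      factor = c(5, 2, 2, 3, 2, 1.5, 3, 1.5))
  }
}

#' Packaged rheumatoid-arthritis cohort effect
#'
#' Raises activation markers (CD69, CD95, ICOS) and lowers CD45RA in the
#' relevant subsets, and shifts the T-helper composition (Th2 down; Tfh,
#' Tph, Treg up) as described for the patient cohort. Magnitudes are
#' nominal synthetic choices.
#'
#' @return List with `pbmc` / `tcell` [condition_effect()]s and a
#'   `tcell_composition` data frame of composition factors.
#' @export
ra_cohort_effect <- function() {
  list(
    pbmc = condition_effect(
      population = c("b_cells", "monocytes", "nk_cells", "dc", "t_cells",
                     "b_cells", "monocytes", "nk_cells", "dc"),
      marker = c(rep("CD69", 5), rep("CD95", 4)),
      factor = c(3, 3, 3, 3, 3, 2, 2, 2, 2)),
    tcell = condition_effect(
      population = c("cd4_t", "cd8_t", "cd4_t", "cd8_t", "t_cells"),
      marker = c("ICOS", "ICOS", "CD45RA", "CD45RA", "CD69"),
      factor = c(2.5, 2.5, 0.6, 0.6, 3)),
    tcell_composition = data.frame(
      population = c("th2", "tfh", "tph", "treg"),
      factor = c(0.5, 1.5, 1.8, 1.4))
  )
}

#' Synthesize raw multi-detector spectra from channel-space events
#'
#' Detector intensities are the abundance-weighted sum of the panel's
#' spectral signatures, optionally plus a per-event autofluorescence
#' contribution and additive Gaussian detector noise. Scatter channels are
#' carried through unchanged.
#'
#' @param events Channel-space `event_matrix`; marker columns must map to
#'   panel markers.
#' @param panel A `panel_definition`.
#' @param autofluorescence Optional autofluorescence `spectral_signature`.
#' @param af_scale Median autofluorescence abundance (log-normal per event).
#' @param noise_sd Additive Gaussian detector noise SD (intensity units).
#' @param seed Seed for noise and autofluorescence draws.
#' @return Detector-space `event_matrix` (detector columns named as in
#'   [instrument_detectors()]), truth labels preserved.
#' @export
synthesize_spectral_raw <- function(events, panel, autofluorescence = NULL,
                                    af_scale = 100, noise_sd = 0, seed = 1) {
  stopifnot(inherits(panel, "panel_definition"))
  X <- event_exprs(events)
  scatter <- colnames(X)[is_scatter_channel(colnames(X))]
  mk <- setdiff(colnames(X), scatter)
  map <- match(mk, panel$channels$marker)
  if (anyNA(map)) {
    cs_abort(paste("markers missing from panel:",
                   paste(mk[is.na(map)], collapse = ", ")), "mapping")
  }
  S <- signature_matrix(panel)[map, , drop = FALSE]
  withr::with_seed(seed, {
    D <- X[, mk, drop = FALSE] %*% S
    if (!is.null(autofluorescence)) {
      af <- stats::rlnorm(nrow(D), log(af_scale), 0.5)
      D <- D + af %o% sig_vec(autofluorescence)
    }
    if (noise_sd > 0) {
      D <- D + matrix(stats::rnorm(length(D), 0, noise_sd), nrow(D))
    }
    colnames(D) <- panel$detectors$detector
    out <- cbind(X[, scatter, drop = FALSE], D)
    ev <- event_matrix(out,
                       truth = if (inherits(events, "event_matrix")) events$truth,
                       meta = c(if (inherits(events, "event_matrix")) events$meta,
                                list(space = "detector", panel = panel$name)))
    ev
  })
}

#' Generate a 2-fold antibody titration series
#'
#' Emulates a serial-dilution titration: the positive-population median
#' follows a saturating binding curve `mfi_max * c / (c + K)` on top of a
#' background that rises linearly with concentration (a synthetic stand-in
#' for over-titration spread), so the stain index is unimodal across the
#' ladder.
#'
#' @param reagent Reagent name.
#' @param concentrations Strictly decreasing 2-fold ladder (uL/test),
#'   default 20 down to 0.3125.
#' @param n_events Events per concentration.
#' @param pos_frac Positive-population fraction.
#' @param mfi_max Saturating median of the positive population.
#' @param K Half-saturation concentration (uL/test).
#' @param bg0,bg_slope Background median intercept and slope per uL.
#' @param sdlog_pos,sdlog_neg Log-scale spreads.
#' @param seed Seed.
#' @return A `titration_series`: list with `reagent` and `entries`, each
#'   entry holding `concentration`, `positive` and `negative` raw
#'   intensities.
#' @export
generate_titration_series <- function(reagent = "CD28-BV650",
                                      concentrations = 20 / 2^(0:6),
                                      n_events = 5000, pos_frac = 0.3,
                                      mfi_max = 30000, K = 1,
                                      bg0 = 50, bg_slope = 15,
                                      sdlog_pos = 0.45, sdlog_neg = 0.5,
                                      seed = 1) {
  if (any(concentrations <= 0)) cs_abort("concentrations must be positive", "input")
  if (is.unsorted(rev(concentrations), strictly = TRUE)) {
    cs_abort("concentrations must be strictly decreasing", "input")
  }
  withr::with_seed(seed, {
    entries <- lapply(concentrations, function(cc) {
      n_pos <- max(round(n_events * pos_frac), 50)
      n_neg <- max(n_events - n_pos, 50)
      bg <- bg0 + bg_slope * cc
      list(concentration = cc,
           positive = stats::rlnorm(n_pos, log(mfi_max * cc / (cc + K) + bg),
                                    sdlog_pos),
           negative = stats::rlnorm(n_neg, log(bg), sdlog_neg))
    })
    structure(list(reagent = reagent, entries = entries),
              class = "titration_series")
  })
}

#' Generate a synthetic two-group cohort
#'
#' Healthy-control donors draw from the default composition fixtures;
#' patient (RA) donors additionally receive the packaged activation and
#' composition effect ([ra_cohort_effect()]). One sample is produced per
#' donor x condition x panel; everything is seeded.
#'
#' @param donors_per_group Donors per group (>= 1).
#' @param groups Group labels (first is the reference/control group).
#' @param conditions Condition labels applied to every donor.
#' @param panels Which panels to synthesize: `"pbmc"`, `"tcell"` or both.
#' @param n_events Events per sample.
#' @param composition_jitter Donor-level composition variability.
#' @param seed Global seed; per-sample seeds are derived from it.
#' @return List with `samples` (named list of `event_matrix`) and
#'   `metadata` (data frame: sample_id, donor, group, condition, panel).
#' @export
generate_cohort <- function(donors_per_group = 5, groups = c("HC", "RA"),
                            conditions = "unstim",
                            panels = c("pbmc", "tcell"),
                            n_events = 10000, composition_jitter = 0.15,
                            seed = 1) {
  stopifnot(donors_per_group >= 1)
  panels <- match.arg(panels, several.ok = TRUE)
  eff <- ra_cohort_effect()
  base <- list(pbmc = pbmc_population_tree(), tcell = tcell_population_tree())
  trees <- list(HC = base, RA = list(
    pbmc = apply_condition(base$pbmc, eff$pbmc),
    tcell = scale_composition(apply_condition(base$tcell, eff$tcell),
                              eff$tcell_composition$population,
                              eff$tcell_composition$factor)))
  samples <- list()
  meta <- list()
  idx <- 0
  for (g in groups) {
    gt <- trees[[g]] %||% base
    for (d in seq_len(donors_per_group)) {
      donor_id <- paste0(g, d)
      for (cond in conditions) {
        for (p in panels) {
          idx <- idx + 1
          sid <- paste(donor_id, cond, p, sep = "_")
          ds <- donor_spec(donor_id, composition_jitter, group = g,
                           condition = cond,
                           seed = derive_seed(seed, idx))
          samples[[sid]] <- generate_donor_events(gt[[p]], ds, n_events)
          meta[[idx]] <- data.frame(sample_id = sid, donor = donor_id,
                                    group = g, condition = cond, panel = p)
        }
      }
    }
  }
  list(samples = samples, metadata = do.call(rbind, meta))
}
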