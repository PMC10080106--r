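test_that("asinh transform is invertible, monotone and leaves scatter alone", {
  X <- cbind(`FSC-A` = c(1e5, 2e5), `SSC-A` = c(3e4, 4e4),
             M1 = c(0, 1500), M2 = c(10, 700))
  ev <- event_matrix(X)
  tf <- transform_asinh(ev, 150)
  expect_equal(tf$exprs[, "FSC-A"], X[, "FSC-A"])
  expect_equal(unname(tf$exprs[1, "M1"]), 0)
  back <- transform_asinh(tf, 150, inverse = TRUE)
  expect_equal(back$exprs, X, tolerance = 1e-12)
  v <- sort(stats::rlnorm(100, 5, 1))
  expect_false(is.unsorted(asinh(v / 150)))
  expect_error(transform_asinh(ev, cofactor = 0), class = "cytoscreen_input")
})

test_that("auto thresholds split bimodal data and refuse unimodal data", {
  withr::with_seed(21, {
    x <- c(stats::rnorm(10000), stats::rnorm(10000, 10))
    th <- auto_threshold(x, "kde_valley")
    expect_gt(th, 3); expect_lt(th, 7)
    # fine-grid KDE oracle: valley of a dense manual density evaluation
    d <- stats::density(x, bw = "nrd0", n = 4096)
    mid <- d$x > 2 & d$x < 8
    oracle <- d$x[mid][which.min(d$y[mid])]
    expect_equal(th, oracle, tolerance = 0.3)
    th2 <- auto_threshold(x, "gmm2")
    expect_gt(th2, 3); expect_lt(th2, 7)
    # perfectly separated values: threshold strictly between the clumps
    y <- c(rep(0, 500), rep(100, 500)) + stats::rnorm(1000, 0, 0.1)
    ts <- auto_threshold(y, "kde_valley")
    expect_gt(ts, 1); expect_lt(ts, 99)
    expect_error(auto_threshold(stats::rnorm(5000), "kde_valley"),
                 class = "cytoscreen_no_valley")
    expect_equal(auto_threshold(0:100, "quantile", q = 0.25), 25)
  })
})

test_that("quadrant gating places one corner event per quadrant with >= positive", {
  X <- cbind(`FSC-A` = rep(1e5, 4), `FSC-H` = rep(1e5, 4),
             A = c(10, 10, 5000, 5000), B = c(10, 5000, 10, 5000))
  ev <- event_matrix(X)
  tree <- gating_tree(list(
    gate_node("all"),
    gate_node("pp", "all", gate_quadrant("A", "B", "++", method = "quantile",
                                         fallback_q = 0.5)),
    gate_node("pm", "all", gate_quadrant("A", "B", "+-", method = "quantile",
                                         fallback_q = 0.5)),
    gate_node("mp", "all", gate_quadrant("A", "B", "-+", method = "quantile",
                                         fallback_q = 0.5)),
    gate_node("mm", "all", gate_quadrant("A", "B", "--", method = "quantile",
                                         fallback_q = 0.5))))
  gr <- apply_gating(ev, tree)
  expect_equal(lengths(gr$indices[c("pp", "pm", "mp", "mm")]),
               c(pp = 1, pm = 1, mp = 1, mm = 1))
  # half-open convention: a value exactly at the threshold is positive
  th <- gr$thresholds$threshold[gr$thresholds$channel == "A"][1]
  X2 <- X; X2[, "A"] <- 150 * sinh(th)   # land exactly on the threshold
  gr2 <- apply_gating(event_matrix(X2), tree)
  expect_equal(length(gr2$indices$mm), 0)
  expect_equal(length(gr2$indices$pp) + length(gr2$indices$pm), 4)
})

test_that("gating results are contained, partitioned and idempotent", {
  tr <- pbmc_population_tree()
  ev <- generate_donor_events(tr, donor_spec("D1", 0), 50000, seed = 13)
  tree <- pbmc_gating_tree()
  gr <- apply_gating(ev, tree)
  # containment along every path
  for (nd in tree$nodes) {
    if (!is.null(nd$parent)) {
      expect_true(all(gr$indices[[nd$id]] %in% gr$indices[[nd$parent]]))
    }
  }
  # quadrant families partition their parent exactly
  quad <- c("t_cells", "b_cells", "t_b_dp", "non_tb")
  expect_equal(sum(lengths(gr$indices[quad])), length(gr$indices$viable))
  expect_equal(sort(unlist(gr$indices[quad], use.names = FALSE)),
               sort(gr$indices$viable))
  f <- subset_frequencies(gr)
  expect_equal(sum(f$pct_of_parent[f$subset %in% quad]), 100, tolerance = 1e-9)
  # idempotence: re-applying the tree reproduces identical labels
  gr2 <- apply_gating(ev, tree)
  expect_identical(gr$labels, gr2$labels)
  # missing channel is a configuration error naming the channel
  ev2 <- ev; colnames(ev2$exprs)[colnames(ev2$exprs) == "CD3"] <- "XX3"
  err <- tryCatch(apply_gating(ev2, tree), error = function(e) e)
  expect_s3_class(err, "cytoscreen_configuration")
  expect_match(conditionMessage(err), "CD3")
})

test_that("empty parents propagate empty children and missing percentages", {
  X <- cbind(`FSC-A` = rep(1000, 60), `FSC-H` = rep(1000, 60),
             M = stats::rlnorm(60, 4, 0.5))
  tree <- gating_tree(list(
    gate_node("all"),
    gate_node("cells", "all", gate_range("FSC-A", min = 45000)),
    gate_node("mpos", "cells", gate_threshold("M", "+", method = "quantile"))))
  gr <- apply_gating(event_matrix(X), tree)
  expect_equal(length(gr$indices$cells), 0)
  expect_equal(length(gr$indices$mpos), 0)
  f <- subset_frequencies(gr)
  expect_true(is.na(f$pct_of_parent[f$subset == "mpos"]))
})

test_that("subset MFIs are raw-scale medians with a minimum-event rule", {
  tr <- toy_tree()
  ev <- generate_donor_events(tr, donor_spec("D", 0), 10000, debris_frac = 0,
                              doublet_frac = 0, dead_frac = 0, seed = 41)
  tree <- gating_tree(list(
    gate_node("all"),
    gate_node("a", "all", gate_threshold("M1", "+")),
    gate_node("b", "all", gate_threshold("M1", "-"))))
  gr <- apply_gating(ev, tree)
  m <- subset_mfi(gr, ev, markers = c("M1", "M2"))
  # log-normal median oracle: exp(mu) for the positive population
  expect_equal(m$M1[m$subset == "a"], 5000, tolerance = 0.03 * 5000)
  # median commutes with the asinh transform
  tfev <- transform_asinh(ev)
  mt <- subset_mfi(gr, tfev, markers = "M1")
  expect_equal(150 * sinh(mt$M1[mt$subset == "a"]), m$M1[m$subset == "a"],
               tolerance = 1e-9)
  # constant channel -> MFI equals the constant; small subsets -> NA
  ev$exprs[, "M2"] <- 42
  m2 <- subset_mfi(gr, ev, markers = "M2")
  expect_true(all(m2$M2[m2$n_events >= 20] == 42))
  m3 <- subset_mfi(gr, ev, markers = "M2", min_events = 1e9)
  expect_true(all(is.na(m3$M2)))
})

test_that("gating recovers the synthetic composition and labels accurately", {
  tr <- pbmc_population_tree()
  ev <- generate_donor_events(tr, donor_spec("D1", 0), 100000, seed = 55)
  gr <- apply_gating(ev, pbmc_gating_tree())
  f <- subset_frequencies(gr)
  pct <- function(id) f$pct_of_viable[f$subset == id]
  expect_equal(pct("t_cells"), 70.6, tolerance = 2 / 70.6)
  expect_equal(pct("b_cells"), 7.5, tolerance = 2 / 7.5)
  expect_equal(pct("nk_cells"), 7.1, tolerance = 2 / 7.1)
  expect_gte(label_accuracy(gr, ev, tr), 0.95)
})

test_that("the T-cell tree recovers helper subsets from ground truth", {
  tr <- tcell_population_tree()
  ev <- generate_donor_events(tr, donor_spec("D1", 0), 100000, seed = 56)
  gr <- apply_gating(ev, tcell_gating_tree())
  f <- subset_frequencies(gr)
  pp <- function(id) f$pct_of_parent[f$subset == id]
  expect_equal(pp("cd4_t"), 54.5, tolerance = 3 / 54.5)
  expect_equal(pp("cd8_t"), 32.6, tolerance = 3 / 32.6)
  expect_equal(pp("th1"), 32.9, tolerance = 3 / 32.9)
  expect_equal(pp("treg"), 7.0, tolerance = 2 / 7.0)
  expect_equal(pp("tph"), 3.4, tolerance = 1.5 / 3.4)
  expect_gte(label_accuracy(gr, ev, tr, lineages = c("T", "CD4", "CD8", "gdT")),
             0.95)
})
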