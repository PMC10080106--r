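test_that("generation is a pure function of spec and seed", {
  tr <- toy_tree()
  a <- generate_donor_events(tr, donor_spec("D1"), 2000, seed = 31)
  b <- generate_donor_events(tr, donor_spec("D1"), 2000, seed = 31)
  expect_identical(a$exprs, b$exprs)
  expect_identical(a$truth, b$truth)
  c <- generate_donor_events(tr, donor_spec("D1"), 2000, seed = 32)
  expect_false(identical(a$exprs, c$exprs))
})

test_that("empirical composition converges to the spec (multinomial law)", {
  tr <- pbmc_population_tree()
  n <- 200000
  ev <- generate_donor_events(tr, donor_spec("D1", composition_jitter = 0),
                              n, debris_frac = 0, doublet_frac = 0,
                              dead_frac = 0, seed = 77)
  tab <- table(ev$truth) / n
  for (i in seq_len(nrow(tr$leaves))) {
    p <- tr$leaves$fraction[i]
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(tab[[tr$leaves$name[i]]] - p), 3 * se + 1e-12)
  }
})

test_that("contaminants honor their configured rates including zero", {
  tr <- toy_tree()
  ev <- generate_donor_events(tr, donor_spec("D1"), 5000, debris_frac = 0,
                              doublet_frac = 0, dead_frac = 0, seed = 4)
  expect_false(any(ev$truth %in% c("debris", "doublet", "dead")))
  ev2 <- generate_donor_events(tr, donor_spec("D1"), 50000, seed = 4)
  expect_lt(abs(mean(ev2$truth == "dead") - 0.10), 0.01)
  expect_lt(abs(mean(ev2$truth == "doublet") - 0.05), 0.01)
  # doublets have FSC-A about twice FSC-H
  db <- ev2$exprs[ev2$truth == "doublet", , drop = FALSE]
  expect_equal(median(db[, "FSC-A"] / db[, "FSC-H"]), 2, tolerance = 0.05)
  expect_error(generate_donor_events(tr, donor_spec("D1"), 100,
                                     dead_frac = 0.7, doublet_frac = 0.35),
               class = "cytoscreen_composition")
})

test_that("condition effects shift exactly the targeted medians", {
  tr <- pbmc_population_tree()
  same <- apply_condition(tr, condition_effect("monocytes", "CD69", 1))
  e1 <- generate_donor_events(tr, donor_spec("D", 0), 20000, seed = 9)
  e2 <- generate_donor_events(same, donor_spec("D", 0), 20000, seed = 9)
  expect_identical(e1$exprs, e2$exprs)  # k = 1 everywhere is the identity

  # same seed, doubled effect: identical draws except the targeted cells'
  # CD69 values, which scale by exactly k (log-normal location shift)
  doubled <- apply_condition(tr, condition_effect("monocytes", "CD69", 2))
  e3 <- generate_donor_events(doubled, donor_spec("D", 0), 20000, seed = 9)
  expect_identical(e3$truth, e1$truth)
  mono <- startsWith(e3$truth, "mono")
  expect_equal(e3$exprs[mono, "CD69"], 2 * e1$exprs[mono, "CD69"],
               tolerance = 1e-12)
  untouched <- setdiff(colnames(e3$exprs), "CD69")
  expect_identical(e3$exprs[, untouched], e1$exprs[, untouched])
  expect_identical(e3$exprs[!mono, "CD69"], e1$exprs[!mono, "CD69"])
  expect_error(apply_condition(tr, condition_effect("no_such_pop", "CD69", 2)),
               class = "cytoscreen_reference")
  expect_error(apply_condition(tr, condition_effect("monocytes", "CD999", 2)),
               class = "cytoscreen_reference")
})

test_that("composition rescaling preserves the family total", {
  tr <- tcell_population_tree()
  tr2 <- scale_composition(tr, c("th2", "tfh"), c(0.5, 1.5))
  fam <- function(t) sum(vapply(t$nodes[c("cd4_naive", "th1", "th2", "th17",
                                          "treg", "tfh", "tph")],
                                `[[`, numeric(1), "fraction"))
  expect_equal(fam(tr2), fam(tr), tolerance = 1e-12)
  expect_lt(tr2$nodes$th2$fraction, tr$nodes$th2$fraction)
  expect_gt(tr2$nodes$tfh$fraction, tr$nodes$tfh$fraction)
  expect_equal(sum(tr2$leaves$fraction), sum(tr$leaves$fraction),
               tolerance = 1e-9)
})

test_that("spectral synthesis round-trips through unmixing", {
  tr <- pbmc_population_tree()
  p <- pbmc_panel()
  ev <- generate_donor_events(tr, donor_spec("D1"), 500, seed = 3)
  raw <- synthesize_spectral_raw(ev, p, noise_sd = 0, seed = 4)
  expect_true(all(p$detectors$detector %in% colnames(raw$exprs)))
  um <- unmix(raw$exprs[, p$detectors$detector], p$signatures)
  truth <- ev$exprs[, p$channels$marker]
  rec <- um$abundances[, p$channels$fluorophore]
  expect_lt(max(abs(rec - truth)) / max(truth), 1e-8)
  # unmixed-channel RMSE grows monotonically with detector noise
  rmse <- vapply(c(1, 2, 4), function(f) {
    r <- synthesize_spectral_raw(ev, p, noise_sd = 5 * f, seed = 4)
    u <- unmix(r$exprs[, p$detectors$detector], p$signatures)
    sqrt(mean((u$abundances[, p$channels$fluorophore] - truth)^2))
  }, numeric(1))
  expect_true(all(diff(rmse) > 0))
  # markers missing from the panel are a mapping error
  bad <- ev
  colnames(bad$exprs)[5] <- "NotInPanel"
  expect_error(synthesize_spectral_raw(bad, p, seed = 1),
               class = "cytoscreen_mapping")
})

test_that("titration series follows the saturating binding model", {
  # c = 1e6 * K: positive median within 1% of mfi_max
  hi <- generate_titration_series(concentrations = c(1e6, 5e5), K = 1,
                                  mfi_max = 30000, bg_slope = 0,
                                  sdlog_pos = 1e-4, sdlog_neg = 1e-4,
                                  seed = 8)
  expect_equal(median(hi$entries[[1]]$positive), 30000 + 50,
               tolerance = 0.01 * 30000)
  # c = K: positive median = mfi_max/2 + background
  half <- generate_titration_series(concentrations = c(2, 1), K = 1,
                                    mfi_max = 30000, bg0 = 50, bg_slope = 15,
                                    sdlog_pos = 1e-4, sdlog_neg = 1e-4,
                                    seed = 8)
  expect_equal(median(half$entries[[2]]$positive), 15000 + 50 + 15,
               tolerance = 20)
  expect_error(generate_titration_series(concentrations = c(2, -1)),
               class = "cytoscreen_input")
  expect_error(generate_titration_series(concentrations = c(1, 2)),
               class = "cytoscreen_input")
})

test_that("cohort generation is seeded and produces donors x conditions x panels", {
  co <- generate_cohort(donors_per_group = 2, n_events = 500, seed = 5)
  expect_equal(nrow(co$metadata), 2 * 2 * 2)  # groups x donors x panels
  expect_setequal(co$metadata$sample_id, names(co$samples))
  co2 <- generate_cohort(donors_per_group = 2, n_events = 500, seed = 5)
  expect_identical(co$samples[[1]]$exprs, co2$samples[[1]]$exprs)
  # identical group specs (no RA effect): only sampling noise separates
  base <- pbmc_population_tree()
  a <- generate_donor_events(base, donor_spec("x", 0), 50000, seed = 1)
  b <- generate_donor_events(base, donor_spec("y", 0), 50000, seed = 2)
  fa <- mean(a$truth == "t_cells"); fb <- mean(b$truth == "t_cells")
  expect_lt(abs(fa - fb), 0.01)
})
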