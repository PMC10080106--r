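# shared in-code fixtures; everything is generated, nothing is stored

random_signatures <- function(k, d, seed = 1) {
  withr::with_seed(seed, {
    lapply(seq_len(k), function(i) {
      spectral_signature(paste0("F", i), stats::runif(d))
    })
  })
}

orthogonal_signatures <- function(k, d = k) {
  lapply(seq_len(k), function(i) {
    v <- rep(0, d); v[i] <- 1
    spectral_signature(paste0("E", i), v)
  })
}

# tiny two-population tree for focused gating tests
toy_tree <- function() {
  population_tree(list(
    population_node("pop_a", fraction = 0.7, lineage = "A", pos = "M1"),
    population_node("pop_b", fraction = 0.3, lineage = "B", pos = "M2")
  ), markers = c("M1", "M2"), name = "toy")
}

# donor loop used by the drug-screen recovery checks: returns a long MFI
# table for control + one treated condition over `n_donors` donors
screen_mfi_table <- function(effect_tree, base_tree, n_donors = 6,
                             n_events = 30000, seed = 1,
                             subsets = c("t_cells", "b_cells", "nk_cells",
                                         "mono_classical", "dc")) {
  gt <- pbmc_gating_tree()
  rows <- list()
  for (d in seq_len(n_donors)) {
    for (cond in c("DMSO", "drug")) {
      tr <- if (cond == "DMSO") base_tree else effect_tree
      ev <- generate_donor_events(
        tr, donor_spec(paste0("D", d), 0.15, condition = cond,
                       seed = derive_seed(seed, 2 * d + (cond == "drug"))),
        n_events)
      gr <- apply_gating(ev, gt)
      m <- subset_mfi(gr, ev)
      long <- mfi_to_long(m[m$subset %in% subsets, ])
      long$donor <- paste0("D", d)
      long$condition <- cond
      rows[[length(rows) + 1]] <- long[, c("donor", "condition", "subset",
                                           "marker", "mfi")]
    }
  }
  do.call(rbind, rows)
}

derive_seed <- cytoscreen:::derive_seed
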