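test_that("fractional difference matches its formula and edge cases", {
  expect_identical(fractional_difference(500, 500), 0)
  expect_equal(fractional_difference(1000, 500), 1)
  expect_equal(fractional_difference(125, 500), -0.75)
  expect_true(is.na(fractional_difference(NA, 500)))
  expect_error(fractional_difference(10, 0), class = "cytoscreen_degenerate")
  # FD > -1 for any positive MFIs
  withr::with_seed(1, {
    fd <- fractional_difference(stats::rlnorm(1000, 5, 2),
                                stats::rlnorm(1000, 5, 2))
    expect_true(all(fd > -1))
  })
})

test_that("outlier masking uses strict bounds and never alters kept values", {
  v <- c(-1.7, -1.2, 0, 1.2, 1.7)
  out <- mask_outliers(v)
  expect_equal(out, c(NA, -1.2, 0, 1.2, NA))
  # exactly +/-150% is retained (strict inequalities)
  expect_equal(mask_outliers(c(-1.5, 1.5)), c(-1.5, 1.5))
  expect_equal(mask_outliers(matrix(0, 3, 3)), matrix(0, 3, 3))
  # idempotent
  expect_equal(mask_outliers(out), out)
})

test_that("column clustering matches a naive O(n^3) agglomeration oracle", {
  withr::with_seed(81, {
    m <- matrix(stats::rnorm(40), 8, 5, dimnames = list(NULL, paste0("d", 1:5)))
  })
  cl <- cluster_columns(m)
  # brute-force complete linkage on the same distances
  naive_heights <- local({
    D <- as.matrix(stats::dist(t(m)))
    groups <- as.list(seq_len(ncol(m)))
    hts <- numeric(0)
    while (length(groups) > 1) {
      best <- c(Inf, 0, 0)
      for (i in seq_along(groups)) {
        for (j in seq_len(i - 1)) {
          h <- max(D[groups[[i]], groups[[j]]])
          if (h < best[1]) best <- c(h, j, i)
        }
      }
      hts <- c(hts, best[1])
      groups[[best[2]]] <- c(groups[[best[2]]], groups[[best[3]]])
      groups[[best[3]]] <- NULL
    }
    hts
  })
  expect_equal(cl$height, naive_heights, tolerance = 1e-12)
  # duplicated column pairs merge first, at height 0
  m2 <- cbind(A = m[, 1], A2 = m[, 1], B = m[, 1] + 100, B2 = m[, 1] + 100)
  cl2 <- cluster_columns(m2)
  expect_equal(cl2$height[1:2], c(0, 0))
  expect_setequal(cl2$order[1:2],
                  if ("A" %in% cl2$order[1:2]) c("A", "A2") else c("B", "B2"))
  # single pair: one merge at the Euclidean distance
  m3 <- m[, 1:2]
  cl3 <- cluster_columns(m3)
  expect_equal(cl3$height, sqrt(sum((m3[, 1] - m3[, 2])^2)))
})

test_that("one-sample t reproduces the textbook computation and stars", {
  r <- one_sample_t(1:6)
  expect_equal(r$t, 4.58258, tolerance = 1e-4)
  expect_equal(r$df, 5)
  expect_equal(r$p, 0.005934, tolerance = 1e-3)
  expect_identical(r$stars, "**")
  sym <- one_sample_t(c(-1, 1))
  expect_equal(sym$t, 0)
  expect_equal(sym$p, 1)
  expect_identical(sym$stars, "ns")
  expect_error(one_sample_t(rep(3, 6)), class = "cytoscreen_undefined_test")
  expect_error(one_sample_t(2), class = "cytoscreen_input")
})

test_that("two-sample t matches a hand pooled-variance computation", {
  a <- c(4.1, 5.0, 4.4, 4.9, 4.6)
  b <- c(3.2, 3.9, 3.4, 3.8, 3.3)
  sp2 <- (4 * stats::var(a) + 4 * stats::var(b)) / 8
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 5 + 1 / 5))
  r <- two_sample_t(a, b)
  expect_equal(r$t, t_hand, tolerance = 1e-12)
  expect_equal(r$df, 8)
  expect_identical(two_sample_t(a, a)$stars, "ns")
  expect_equal(two_sample_t(a, a)$t, 0)
  withr::with_seed(5, {
    lo <- stats::rnorm(5, 0, 1e-6); hi <- 1 + stats::rnorm(5, 0, 1e-6)
    expect_lt(two_sample_t(lo, hi)$p, 0.001)
  })
  expect_error(two_sample_t(rep(1, 4), rep(1, 4)),
               class = "cytoscreen_undefined_test")
})

test_that("null FDs reject near the nominal rate", {
  withr::with_seed(91, {
    p <- replicate(2000, one_sample_t(stats::rnorm(6, 0, 0.2))$p)
  })
  expect_gt(mean(p < 0.05), 0.035)
  expect_lt(mean(p < 0.05), 0.065)
})

test_that("min-max normalization and variance filter behave as declared", {
  expect_equal(minmax_normalize(c(2, 4, 6)), c(0, 0.5, 1))
  expect_equal(minmax_normalize(c(3, 3, 3)), c(0, 0, 0))
  withr::with_seed(3, {
    v <- stats::rnorm(50)
    expect_true(all(minmax_normalize(v) >= 0 & minmax_normalize(v) <= 1))
    m <- matrix(stats::rnorm(120), 6, 20, dimnames = list(NULL, paste0("f", 1:20)))
  })
  vf <- variance_filter(m, 0.10)
  # brute-force sort-by-variance oracle
  expect_equal(sort(vf$removed),
               sort(paste0("f", order(apply(m, 2, var))[1:2])))
  expect_equal(ncol(vf$matrix), 18)
  expect_equal(ncol(variance_filter(m, 0)$matrix), 20)
  m2 <- cbind(m[, 1:9], const = 0)
  expect_identical(variance_filter(m2, 0.10)$removed, "const")
  # row permutations commute with normalize + filter
  perm <- sample(6)
  n1 <- apply(m, 2, minmax_normalize)[perm, ]
  n2 <- apply(m[perm, ], 2, minmax_normalize)
  expect_equal(n1, n2)
})

test_that("PCA embedding matches an eigen-decomposition oracle", {
  withr::with_seed(17, {
    m <- matrix(stats::rnorm(48), 6, 8)
  })
  emb <- pca_embed(m, 3)
  ctr <- scale(m, center = TRUE, scale = FALSE)
  eig <- eigen(stats::cov(ctr))
  oracle <- ctr %*% eig$vectors[, 1:3]
  expect_equal(abs(unname(emb$scores)), abs(oracle), tolerance = 1e-9)
  expect_equal(emb$explained[1:3],
               eig$values[1:3] / sum(eig$values), tolerance = 1e-9)
  # sign convention: largest-magnitude loading positive
  for (j in 1:3) {
    expect_gt(emb$loadings[which.max(abs(emb$loadings[, j])), j], 0)
  }
  # rank-1 data: first component explains (essentially) everything
  line <- outer(1:6, stats::runif(8))
  expect_gt(pca_embed(line, 3)$explained[1], 0.999)
  expect_error(pca_embed(m[1:3, ], 3), class = "cytoscreen_dimension")
})

test_that("separation score distinguishes split from shuffled labels", {
  withr::with_seed(23, {
    a <- matrix(stats::rnorm(15, 0), 5, 3)
    b <- matrix(stats::rnorm(15, 10), 5, 3)
    sc <- separation_score(rbind(a, b), rep(c("HC", "RA"), each = 5))
    expect_gt(sc, 0.5)
    shuffled <- replicate(25, separation_score(
      rbind(a, b) + stats::rnorm(30), sample(rep(c("HC", "RA"), 5))))
    expect_lt(abs(median(shuffled)), 0.3)
  })
  # vanishing within-group spread approaches a perfect score
  tight <- rbind(matrix(rep(c(0, 0, 0), 3), 3, byrow = TRUE),
                 matrix(rep(c(10, 10, 10), 3), 3, byrow = TRUE)) +
    stats::rnorm(18, 0, 1e-6)
  expect_gt(separation_score(tight, rep(c("a", "b"), each = 3)), 0.999)
  expect_error(separation_score(tight, rep("a", 6)), class = "cytoscreen_input")
})

test_that("FD matrices assemble, mask and summarize donor-level screens", {
  # two donors, control + two drugs, two features with known effects
  tab <- expand.grid(donor = c("D1", "D2"),
                     condition = c("DMSO", "drugA", "drugB"),
                     subset = c("s1", "s2"), marker = "CD69",
                     stringsAsFactors = FALSE)
  base <- 1000
  tab$mfi <- base
  tab$mfi[tab$condition == "drugA" & tab$subset == "s1"] <- 2 * base   # FD +1
  tab$mfi[tab$condition == "drugB"] <- 5 * base                       # FD +4
  fdm <- build_fd_matrix(tab, control = "DMSO")
  expect_equal(unname(fdm$mean_fd["s1:CD69", "drugA"]), 1)
  expect_equal(unname(fdm$mean_fd["s2:CD69", "drugA"]), 0)
  expect_equal(unname(fdm$mean_fd["s1:CD69", "drugB"]), 4)
  fdm <- mask_outliers(fdm)
  expect_true(all(fdm$mask[, "drugB"]))
  expect_false(any(fdm$mask[, "drugA"]))
  expect_true(all(is.na(fdm$mean_fd_masked[, "drugB"])))
  # self-comparison: FD identically zero for every feature
  self <- tab[tab$condition == "DMSO", ]
  self2 <- self; self2$condition <- "copy"
  fd0 <- build_fd_matrix(rbind(self, self2), control = "DMSO")
  expect_true(all(fd0$mean_fd == 0))
  expect_error(build_fd_matrix(tab, control = "nope"),
               class = "cytoscreen_degenerate")
  # screen summary flags untestable (zero-variance) features as NA
  sr <- screen_summary(fdm)
  expect_s3_class(sr, "screen_result")
  expect_true(all(is.na(sr$p)))  # n = 2 with identical FDs -> zero variance
})

test_that("star annotation respects the published thresholds", {
  expect_identical(p_stars(c(0.0005, 0.005, 0.03, 0.2, NA)),
                   c("***", "**", "*", "ns", NA))
})
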