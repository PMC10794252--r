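test_that("per-image medians summarize cells robustly", {
  cells <- data.frame(image_id = c("i1", "i2", "i2", "i2"),
                      cell_id = 1:4,
                      f1 = c(7, 1, 2, 100), f2 = c(0.5, 1, 1, 1))
  prof <- summarize_per_image(cells)
  expect_equal(nrow(prof), 2)
  expect_equal(prof$f1[prof$image_id == "i1"], 7)   # single cell = itself
  expect_equal(prof$f1[prof$image_id == "i2"], 2)   # outlier-robust median
  expect_error(summarize_per_image(cells[0, ]), "empty")
  # medians approach the population mean for symmetric noise
  set.seed(5)
  big <- data.frame(image_id = rep(sprintf("im%d", 1:20), each = 50),
                    f = rnorm(1000, 10, 2))
  p <- summarize_per_image(big)
  expect_lt(max(abs(p$f - 10)), 4 * 2 / sqrt(50))
})

test_that("clean_and_scale drops degenerate data, standardizes, and is
           idempotent", {
  set.seed(6)
  m <- cbind(a = rnorm(30), b = rnorm(30), const = rep(2, 30))
  m[4, "b"] <- NA
  cs <- clean_and_scale(m)
  expect_equal(cs$dropped_columns, "const")
  expect_equal(cs$dropped_rows, 4)
  expect_true(all(abs(colMeans(cs$matrix)) < 1e-9))
  expect_true(all(abs(apply(cs$matrix, 2, sd) - 1) < 1e-9))
  twice <- clean_and_scale(cs$matrix)
  expect_equal(unname(twice$matrix), unname(cs$matrix), tolerance = 1e-12)
  expect_length(twice$dropped_columns, 0)
  expect_error(clean_and_scale(matrix(1, 5, 2)), "zero variance")
})

test_that("pairwise-complete correlation matrix is symmetric with unit
           diagonal", {
  set.seed(7)
  x <- cbind(a = rnorm(50), b = rnorm(50))
  x <- cbind(x, c = -x[, "a"])
  x[3, "b"] <- NA
  r <- correlation_matrix(x)
  expect_equal(diag(r), c(a = 1, b = 1, c = 1))
  expect_equal(r, t(r))
  expect_equal(r["a", "c"], -1)
  # independent noise columns stay near zero at n = 1000
  big <- matrix(rnorm(2000), 1000, 2)
  expect_lt(abs(correlation_matrix(big)[1, 2]), 0.1)
})

test_that("PCA variance ratios are a non-increasing partition of unity with
           a deterministic sign convention", {
  set.seed(8)
  z <- rnorm(200)
  # two perfectly correlated features: PC1 carries everything
  perf <- clean_and_scale(cbind(f1 = z, f2 = 2 * z + 1))
  p1 <- run_pca(perf)
  expect_equal(p1$variance_ratio[1], 1, tolerance = 1e-9)
  # isotropic 2D Gaussian: ratios about [0.5, 0.5]
  iso <- clean_and_scale(matrix(rnorm(20000), 10000, 2))
  expect_equal(run_pca(iso)$variance_ratio, c(0.5, 0.5), tolerance = 0.02)
  # general case: sum 1, non-increasing, largest |loading| positive
  m <- clean_and_scale(matrix(rnorm(600), 60, 10))
  p <- run_pca(m)
  expect_equal(sum(p$variance_ratio), 1)
  expect_true(all(diff(p$variance_ratio) <= 1e-12))
  for (j in seq_len(ncol(p$loadings))) {
    expect_gt(p$loadings[which.max(abs(p$loadings[, j])), j], 0)
  }
})

test_that("PC1 correlation selection recovers exactly the planted
           high-correlation features and is monotone in the cutoff", {
  set.seed(9)
  n <- 300
  g <- rnorm(n)
  strong <- sapply(1:5, function(i) 0.9 * g + sqrt(1 - 0.81) * rnorm(n))
  weak <- sapply(1:5, function(i) 0.5 * g + sqrt(1 - 0.25) * rnorm(n))
  colnames(strong) <- paste0("s", 1:5); colnames(weak) <- paste0("w", 1:5)
  cs <- clean_and_scale(cbind(strong, weak))
  pca <- run_pca(cs)
  sel <- pc1_feature_correlations(pca, cs)
  expect_equal(sel$cutoff, 0.75)
  expect_setequal(sel$selected, paste0("s", 1:5))
  # raising the cutoff never adds features
  for (cut in c(0.5, 0.8, 0.95)) {
    lo <- pc1_feature_correlations(pca, cs, cutoff = cut)$selected
    hi <- pc1_feature_correlations(pca, cs, cutoff = cut + 0.04)$selected
    expect_true(all(hi %in% lo))
  }
  # single feature correlates +-1 with PC1
  one <- clean_and_scale(cbind(solo = rnorm(40)))
  p1 <- run_pca(one)
  expect_equal(abs(unname(pc1_feature_correlations(p1, one)$r)), 1)
})

test_that("planted two-factor profiles put the dominant factor on PC1 and a
           dose-dependent shift appears only on the targeted features", {
  set.seed(10)
  n_img <- 120
  dose <- rep(c(0, 1, 2.5, 5, 10, 20), each = 20)
  cargo_factor <- rnorm(n_img, sd = 3)           # dominant factor
  tgn_factor <- 0.4 * log1p(dose) + rnorm(n_img, sd = 0.3)
  cargo_feats <- sapply(1:6, function(i) cargo_factor + rnorm(n_img, 0, 0.5))
  tgn_feats <- sapply(1:4, function(i) tgn_factor + rnorm(n_img, 0, 0.3))
  other <- matrix(rnorm(n_img * 5), n_img)
  colnames(cargo_feats) <- paste0("cargo_", 1:6)
  colnames(tgn_feats) <- paste0("tgn_", 1:4)
  colnames(other) <- paste0("x_", 1:5)
  cs <- clean_and_scale(cbind(cargo_feats, tgn_feats, other))
  pca <- run_pca(cs)
  expect_gt(abs(cor(pca$scores[, 1], cargo_factor)), 0.9)

  summ <- profile_summary(cs, colnames(cs$matrix),
                          condition = rep("cmpd", n_img), dose = dose)
  trend <- function(f) {
    s <- summ[summ$feature == f, ]
    cor(s$mean[order(s$dose)], sort(unique(dose)), method = "spearman")
  }
  for (f in paste0("tgn_", 1:4)) expect_gt(trend(f), 0.9)
  for (f in paste0("x_", 1:5)) expect_lt(abs(trend(f)), 0.9)

  # control-like groups differing only in cargo features separate only there
  grp <- rep(c("neg", "pos"), each = 60)
  mat2 <- cbind(cargo_feats, other)
  mat2[grp == "pos", 1:6] <- mat2[grp == "pos", 1:6] - 5
  cs2 <- clean_and_scale(mat2)
  s2 <- profile_summary(cs2, colnames(cs2$matrix), condition = grp)
  dd <- sapply(colnames(cs2$matrix), function(f) {
    v <- s2[s2$feature == f, ]
    abs(diff(v$mean))
  })
  expect_true(all(dd[paste0("cargo_", 1:6)] > 1))
  expect_true(all(dd[paste0("x_", 1:5)] < 0.8))
})
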