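test_that("robust Z'-factor matches hand computation and its edge cases", {
  # zero spread, distinct medians -> exactly 1
  expect_equal(zprime_robust(rep(1.3, 4), rep(1.1, 4)), 1)
  # coincident medians -> -Inf sentinel
  expect_identical(zprime_robust(c(1, 1.2, 0.8), c(1, 1.1, 0.9)), -Inf)
  # hand computation with the MAD x 1.4826 convention:
  # neg: median 1.34, MADn = 1.4826 * 0.02; pos: median 1.10, MADp = 1.4826 * 0.01
  neg <- c(1.30, 1.34, 1.38, 1.34); pos <- c(1.08, 1.10, 1.12, 1.10)
  byhand <- 1 - 3 * (1.4826 * 0.02 + 1.4826 * 0.01) / 0.24
  expect_equal(zprime_robust(neg, pos), byhand)
  expect_error(zprime_robust(1.3, pos), "2 wells")
})

test_that("SSMD: sign, scaling, the printed-control value, and sentinels", {
  expect_equal(ssmd(c(1, 2, 3), c(1, 2, 3)), 0)
  # the screen's control parameters give ~0.24/sqrt(0.0029) = 4.46
  set.seed(1)
  neg <- rnorm(4000, 1.34, 0.05); pos <- rnorm(4000, 1.10, 0.02)
  expect_equal(ssmd(neg, pos), 0.24 / sqrt(0.05^2 + 0.02^2), tolerance = 0.05)
  # doubling both SDs halves SSMD
  a <- c(1.2, 1.3, 1.4, 1.5); b <- c(0.9, 1.0, 1.1, 1.0)
  am <- mean(a); bm <- mean(b)
  expect_equal(ssmd((a - am) * 2 + am, (b - bm) * 2 + bm), ssmd(a, b) / 2)
  expect_identical(ssmd(rep(2, 3), rep(1, 3)), Inf)
  # robust form uses medians/MADs
  expect_equal(ssmd(neg, pos, robust = TRUE),
               (median(neg) - median(pos)) /
                 sqrt(mad(neg)^2 + mad(pos)^2))
})

test_that("Z'-robust and SSMD are invariant under common affine transforms", {
  set.seed(2)
  neg <- rnorm(16, 1.34, 0.05); pos <- rnorm(16, 1.10, 0.02)
  for (ab in list(c(2, 0), c(0.5, 3), c(10, -1))) {
    expect_equal(zprime_robust(ab[1] * neg + ab[2], ab[1] * pos + ab[2]),
                 zprime_robust(neg, pos))
    expect_equal(ssmd(ab[1] * neg + ab[2], ab[1] * pos + ab[2]),
                 ssmd(neg, pos))
  }
})

test_that("plate CV matches hand arithmetic and is not shift-invariant", {
  expect_equal(plate_cv(rep(1.2, 5)), 0)
  v <- c(1.0, 1.1, 0.9)
  expect_equal(plate_cv(v), 100 * sd(v) / mean(v))
  expect_false(isTRUE(all.equal(plate_cv(v + 1), plate_cv(v))))
  expect_error(plate_cv(c(-1, 1)), "positive mean")
})

test_that("qc_evaluate applies inclusive conjunctive thresholds", {
  # constructed plate: Z' = 1, CV = 0, SSMD = Inf -> pass
  wells <- data.frame(role = rep(c("negative_control", "positive_control"),
                                 each = 4),
                      ratio = rep(c(1.34, 1.10), each = 4))
  expect_true(qc_evaluate(wells)$pass)
  # identical distributions -> fail
  bad <- wells; bad$ratio <- rep(1.2, 8)
  expect_false(qc_evaluate(bad)$pass)
  # SSMD exactly 3.0 passes the inclusive gate, anything below does not
  w3 <- data.frame(role = rep(c("negative_control", "positive_control"),
                              each = 2),
                   ratio = c(1.6, 1.8, 1.0, 1.2))  # ssmd = 0.6/0.2 = 3
  q3 <- qc_evaluate(w3, zprime_min = -Inf, cv_max = Inf)
  expect_equal(q3$ssmd, 3)
  expect_true(q3$pass)
  expect_false(qc_evaluate(w3, zprime_min = -Inf, ssmd_min = 3 + 1e-9,
                           cv_max = Inf)$pass)
  # missing control group errors
  expect_error(qc_evaluate(wells[wells$role == "negative_control", ]),
               "control group")
})

test_that("z-score normalization centres negative controls and is invariant
           to per-plate shifts; planted effects are recovered", {
  spec <- screen_spec(n_plates = 4, plate_shift_sd = 0.05,
                      active_effect_sd_units = 5, seed = 6)
  scr <- generate_screen(spec)
  nz <- normalize_wells(scr$wells)
  for (p in unique(nz$plate)) {
    negz <- nz$ratio_z[nz$plate == p & nz$role == "negative_control"]
    expect_equal(mean(negz), 0, tolerance = 1e-12)
    expect_equal(sd(negz), 1, tolerance = 1e-12)
  }
  # adding a constant plate shift leaves every z unchanged
  shifted <- scr$wells
  for (p in unique(shifted$plate)) {
    shifted$ratio[shifted$plate == p] <-
      shifted$ratio[shifted$plate == p] + runif(1, -1, 1)
  }
  nz2 <- normalize_wells(shifted)
  expect_equal(nz2$ratio_z, nz$ratio_z, tolerance = 1e-9)
  # planted -5 SD actives sit near z = -5
  act <- nz$compound_id %in% scr$truth$compound_id[scr$truth$active]
  expect_equal(mean(nz$ratio_z[act & nz$role == "compound"]), -5,
               tolerance = 0.6)
})

test_that("replicate-sampling correlation: identical plates give r = 1,
           pure noise gives r near 0, 100 samplings by default", {
  pos_effect <- rnorm(384)
  ident <- matrix(rep(pos_effect, 4), ncol = 4)
  rc <- replicate_correlation(ident, seed = 1)
  expect_equal(rc$mean_r, 1)
  expect_equal(rc$sd_r, 0)
  expect_length(rc$r, 100)
  set.seed(3)
  noise <- matrix(rnorm(384 * 8), 384, 8)
  rc0 <- replicate_correlation(noise, seed = 2)
  expect_lt(abs(rc0$mean_r), 0.1)
  expect_error(replicate_correlation(matrix(1:10, ncol = 1)))
})

test_that("control separability AUC: separation, null, and rank invariance", {
  set.seed(9)
  x <- c(rnorm(500, 5), rnorm(500, 0)); y <- rep(c(TRUE, FALSE), each = 500)
  expect_equal(control_separability_auc(x, y, seed = 1)$auc, 1,
               tolerance = 0.005)
  xn <- rnorm(30000); yn <- rep(c(TRUE, FALSE), 15000)
  expect_lt(abs(control_separability_auc(xn, yn, seed = 2)$auc - 0.5), 0.02)
  # AUC is a rank statistic: any strictly increasing transform preserves it
  s <- rnorm(200); cls <- s + rnorm(200) > 0
  expect_equal(rank_auc(exp(3 * s), cls), rank_auc(s, cls))
  expect_error(control_separability_auc(x, rep(TRUE, 1000)), "classes")
})
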