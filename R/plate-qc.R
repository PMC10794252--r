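## Plate-level quality control, control-based normalization, replicate
## correlation, and control separability.

#' Robust Z'-factor
#'
#' Median/MAD analogue of the Z'-factor:
#' `1 - 3 * (1.4826*MAD_neg + 1.4826*MAD_pos) / |median_neg - median_pos|`.
#' Returns `-Inf` when the medians coincide (no separation). Invariant under
#' a common affine transform of both groups.
#'
#' @param neg,pos numeric vectors of control-well values (>= 2 each).
#' @return unitless scalar, at most 1.
#' @export
zprime_robust <- function(neg, pos) {
  check_groups(neg, pos)
  sep <- abs(stats::median(neg) - stats::median(pos))
  if (sep == 0) return(-Inf)
  1 - 3 * (stats::mad(neg) + stats::mad(pos)) / sep
}

#' Strictly standardized mean difference
#'
#' `(mean_neg - mean_pos) / sqrt(sd_neg^2 + sd_pos^2)`; positive when the
#' negative control exceeds the positive control. `robust = TRUE` uses
#' medians and scaled MADs instead.
#'
#' @param neg,pos numeric vectors of control-well values (>= 2 each).
#' @param robust use median/MAD form.
#' @return unitless scalar; `Inf` (with sign of the difference) when both
#'   spreads are zero.
#' @export
ssmd <- function(neg, pos, robust = FALSE) {
  check_groups(neg, pos)
  if (robust) {
    d <- stats::median(neg) - stats::median(pos)
    s <- sqrt(stats::mad(neg)^2 + stats::mad(pos)^2)
  } else {
    d <- mean(neg) - mean(pos)
    s <- sqrt(stats::var(neg) + stats::var(pos))
  }
  if (s == 0) return(sign(d) * Inf)
  d / s
}

#' Coefficient of variation of negative-control wells
#'
#' `100 * sd/mean`, in percent. Also usable across plates on per-plate
#' control means for an inter-assay CV.
#'
#' @param neg numeric vector with positive mean.
#' @return percent.
#' @export
plate_cv <- function(neg) {
  m <- mean(neg)
  if (m <= 0) stop("plate_cv requires a positive mean")
  100 * stats::sd(neg) / m
}

#' Evaluate plate quality control
#'
#' Computes robust Z'-factor, SSMD and negative-control CV for one plate and
#' the conjunctive pass flag at the screen's thresholds (all inclusive):
#' Z'-robust >= 0.3, SSMD >= 3 and CV <= 10 percent.
#'
#' @param wells data frame with columns `role` and `ratio` (one plate).
#' @param zprime_min,ssmd_min,cv_max thresholds.
#' @return one-row data frame: plate metrics, group sizes, `pass`.
#' @export
qc_evaluate <- function(wells, zprime_min = 0.3, ssmd_min = 3, cv_max = 10) {
  neg <- wells$ratio[wells$role == "negative_control"]
  pos <- wells$ratio[wells$role == "positive_control"]
  if (length(neg) < 2 || length(pos) < 2) {
    stop("plate must carry at least 2 wells of each control group")
  }
  zp <- zprime_robust(neg, pos)
  ss <- ssmd(neg, pos)
  cv <- plate_cv(neg)
  data.frame(zprime_robust = zp, ssmd = ss, cv_percent = cv,
             n_neg = length(neg), n_pos = length(pos),
             pass = (zp >= zprime_min) && (ss >= ssmd_min) && (cv <= cv_max))
}

#' Per-plate z-score normalization against negative controls
#'
#' `ratio_z = (well - mean(neg ratios on the same plate)) / sd(neg ratios)`;
#' `cellcount_z` likewise from negative-control cell counts. Using same-plate
#' controls makes the z-scores invariant under any per-plate additive shift.
#'
#' @param wells data frame with columns `plate`, `role`, `ratio` and
#'   optionally `cell_count`.
#' @param require_pass when `TRUE`, plates failing [qc_evaluate()] are
#'   dropped with a warning.
#' @return `wells` with added columns `ratio_z` (and `cellcount_z` when cell
#'   counts are present), control wells included.
#' @export
normalize_wells <- function(wells, require_pass = FALSE) {
  out <- vector("list", length(unique(wells$plate)))
  for (i in seq_along(out)) {
    p <- unique(wells$plate)[i]
    w <- wells[wells$plate == p, , drop = FALSE]
    if (require_pass && !qc_evaluate(w)$pass) {
      warning("plate ", p, " failed QC and was dropped")
      next
    }
    neg <- w$ratio[w$role == "negative_control"]
    if (length(neg) < 2 || stats::sd(neg) == 0) {
      stop("plate ", p, ": cannot normalize (negative-control sd is 0)")
    }
    w$ratio_z <- (w$ratio - mean(neg)) / stats::sd(neg)
    if ("cell_count" %in% names(w)) {
      nc <- w$cell_count[w$role == "negative_control"]
      if (stats::sd(nc) == 0) stop("plate ", p, ": cell-count sd is 0")
      w$cellcount_z <- (w$cell_count - mean(nc)) / stats::sd(nc)
    }
    out[[i]] <- w
  }
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

#' Replicate-sampling correlation across plates
#'
#' Repeatedly splits the plates at random into two disjoint halves, averages
#' each well position within each half, and computes the Pearson correlation
#' of the two position profiles; reports mean and SD over `n_samplings`
#' splits (100 by default, matching the assay-validation convention). For an
#' odd number of plates the halves have sizes floor(N/2) and ceiling(N/2).
#'
#' @param plate_values numeric matrix, positions x plates (identical layouts).
#' @param n_samplings number of random splits.
#' @param seed integer seed.
#' @return list: `mean_r`, `sd_r`, `r` (per-sampling values).
#' @export
replicate_correlation <- function(plate_values, n_samplings = 100, seed = 1L) {
  stopifnot(is.matrix(plate_values), ncol(plate_values) >= 2)
  set.seed(seed)
  N <- ncol(plate_values)
  r <- vapply(seq_len(n_samplings), function(i) {
    half <- sample(N, N %/% 2)
    a <- rowMeans(plate_values[, half, drop = FALSE], na.rm = TRUE)
    b <- rowMeans(plate_values[, -half, drop = FALSE], na.rm = TRUE)
    stats::cor(a, b, use = "pairwise.complete.obs")
  }, numeric(1))
  list(mean_r = mean(r), sd_r = stats::sd(r), r = r)
}

#' Control separability via a logistic model and held-out AUC
#'
#' Fits a logistic (binomial GLM) model of class on the predictor(s) on a
#' random training fraction and evaluates the area under the ROC curve on
#' the held-out split using the rank-sum (Mann-Whitney) estimator, which
#' makes the AUC invariant under any strictly increasing transform of the
#' score.
#'
#' @param values numeric vector or matrix/data.frame of predictors (cells x
#'   features).
#' @param class logical or two-level factor; `TRUE`/second level = positive
#'   class.
#' @param train_fraction fraction used for fitting (default 0.7).
#' @param seed integer seed for the split.
#' @return list: `auc`, `n_train`, `n_test`, `model`.
#' @export
control_separability_auc <- function(values, class, train_fraction = 0.7,
                                     seed = 1L) {
  x <- as.data.frame(values)
  y <- if (is.logical(class)) class else as.integer(as.factor(class)) == 2L
  if (length(unique(y)) < 2) stop("both classes must be present")
  stopifnot(nrow(x) == length(y))
  set.seed(seed)
  idx <- sample(nrow(x), round(train_fraction * nrow(x)))
  fit <- suppressWarnings(
    stats::glm(y ~ ., data = cbind(y = y[idx], x[idx, , drop = FALSE]),
               family = stats::binomial()))
  score <- suppressWarnings(
    stats::predict(fit, newdata = x[-idx, , drop = FALSE]))
  yt <- y[-idx]
  auc <- rank_auc(score, yt)
  list(auc = auc, n_train = length(idx), n_test = length(yt), model = fit)
}

#' Rank-sum (Mann-Whitney) AUC estimator
#'
#' @param score numeric scores.
#' @param positive logical, `TRUE` for the positive class.
#' @return AUC in `[0, 1]`.
#' @export
rank_auc <- function(score, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(score)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

check_groups <- function(neg, pos) {
  if (length(neg) < 2 || length(pos) < 2) {
    stop("need at least 2 wells per control group")
  }
  invisible(TRUE)
}
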