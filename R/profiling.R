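## Multiparametric morphological profiling: per-image medians, cleaning and
## standardization, PCA, PC1-feature correlations, profile selection and
## condition-level summaries.

#' Summarize single-cell features to per-image medians
#'
#' @param cells data frame of single-cell features with an `image_id` column
#'   (and optional annotation columns listed in `annotations`, carried
#'   through unchanged; they must be constant within an image).
#' @param annotations character vector of annotation column names.
#' @return data frame, one row per image: annotations + per-feature medians.
#'   Images with zero cells simply do not appear.
#' @export
summarize_per_image <- function(cells, annotations = character()) {
  if (!nrow(cells)) stop("empty cell table")
  stopifnot("image_id" %in% names(cells))
  feat <- setdiff(names(cells), c("image_id", "cell_id", annotations))
  ids <- unique(cells$image_id)
  rows <- lapply(ids, function(im) {
    w <- cells[cells$image_id == im, , drop = FALSE]
    med <- vapply(feat, function(f)
      stats::median(w[[f]], na.rm = TRUE), numeric(1))
    ann <- w[1, annotations, drop = FALSE]
    cbind(data.frame(image_id = im), ann,
          as.data.frame(as.list(med), check.names = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Clean and standardize a profile matrix
#'
#' Drops zero-variance feature columns, then rows (observations) with any
#' missing value, then z-scales every remaining column to mean 0, sd 1.
#' Idempotent: applying it to its own output changes nothing. The drop log
#' records what was removed and why.
#'
#' @param x numeric matrix or all-numeric data frame (rows = images).
#' @return list of class `profile_matrix`: `matrix` (standardized),
#'   `dropped_columns`, `dropped_rows`, `center`, `scale`.
#' @export
clean_and_scale <- function(x) {
  m <- as.matrix(x)
  stopifnot(is.numeric(m))
  v <- apply(m, 2, function(col) stats::var(col[is.finite(col)]))
  zero_var <- which(!is.finite(v) | v == 0)
  dropped_columns <- colnames(m)[zero_var]
  if (length(zero_var)) m <- m[, -zero_var, drop = FALSE]
  if (!ncol(m)) stop("all columns have zero variance")
  bad_rows <- which(rowSums(!is.finite(m)) > 0)
  dropped_rows <- if (is.null(rownames(m))) bad_rows else rownames(m)[bad_rows]
  if (length(bad_rows)) m <- m[-bad_rows, , drop = FALSE]
  ## a column can lose its variance once rows are dropped
  v2 <- apply(m, 2, stats::var)
  if (any(v2 == 0)) {
    dropped_columns <- c(dropped_columns, colnames(m)[v2 == 0])
    m <- m[, v2 > 0, drop = FALSE]
  }
  ctr <- colMeans(m)
  scl <- apply(m, 2, stats::sd)
  m <- scale(m, center = ctr, scale = scl)
  attr(m, "scaled:center") <- NULL
  attr(m, "scaled:scale") <- NULL
  structure(list(matrix = m, dropped_columns = dropped_columns,
                 dropped_rows = dropped_rows, center = ctr, scale = scl),
            class = "profile_matrix")
}

#' Pairwise-complete Pearson correlation matrix of features
#'
#' @param x numeric matrix (rows = observations).
#' @return symmetric correlation matrix with unit diagonal; entries with
#'   fewer than 2 complete pairs are `NA`.
#' @export
correlation_matrix <- function(x) {
  m <- as.matrix(x)
  if (nrow(m) < 2) stop("need at least 2 observations")
  r <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))
  diag(r) <- 1
  r
}

#' Principal component analysis of a standardized profile matrix
#'
#' PCA of the column-standardized data (i.e. on the correlation structure)
#' with a deterministic sign convention: each component is flipped so that
#' its largest-magnitude loading is positive, making reports reproducible
#' across platforms.
#'
#' @param x a `profile_matrix` from [clean_and_scale()] or an already
#'   standardized numeric matrix.
#' @return list of class `profile_pca`: `variance_ratio` (non-increasing,
#'   summing to 1), `scores` (images x components), `loadings`
#'   (features x components).
#' @export
run_pca <- function(x) {
  m <- if (inherits(x, "profile_matrix")) x$matrix else as.matrix(x)
  if (nrow(m) < 2) stop("need at least 2 rows")
  pc <- stats::prcomp(m, center = FALSE, scale. = FALSE)
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  pc$rotation <- sweep(pc$rotation, 2, flip, `*`)
  pc$x <- sweep(pc$x, 2, flip, `*`)
  structure(list(variance_ratio = pc$sdev^2 / sum(pc$sdev^2),
                 scores = pc$x, loadings = pc$rotation),
            class = "profile_pca")
}

#' PC1-feature correlations and profile-feature selection
#'
#' Pearson correlation of the first principal component's scores with every
#' feature column; features with `|r|` above the cutoff (default 0.75)
#' define the morphological profile.
#'
#' @param pca `profile_pca` from [run_pca()].
#' @param x the matrix the PCA was run on.
#' @param cutoff absolute-correlation cutoff.
#' @return list of class `profile_selection`: `r` (named vector),
#'   `selected` (feature names), `cutoff`.
#' @export
pc1_feature_correlations <- function(pca, x, cutoff = 0.75) {
  m <- if (inherits(x, "profile_matrix")) x$matrix else as.matrix(x)
  pc1 <- pca$scores[, 1]
  r <- apply(m, 2, function(col) stats::cor(pc1, col))
  structure(list(r = r, selected = names(r)[abs(r) > cutoff],
                 cutoff = cutoff),
            class = "profile_selection")
}

#' Condition-level profile summary (heatmap-ready)
#'
#' Per-group mean and SD of each selected feature on the standardized scale,
#' ordered by dose within condition.
#'
#' @param x standardized matrix or `profile_matrix`.
#' @param selected character vector of feature names (e.g. from
#'   [pc1_feature_correlations()]).
#' @param condition,dose grouping vectors along the rows of `x` (dose may be
#'   `NULL`).
#' @return data frame: condition, dose, feature, mean, sd, n.
#' @export
profile_summary <- function(x, selected, condition, dose = NULL) {
  m <- if (inherits(x, "profile_matrix")) x$matrix else as.matrix(x)
  stopifnot(length(condition) == nrow(m),
            all(selected %in% colnames(m)))
  if (is.null(dose)) dose <- rep(NA_real_, nrow(m))
  key <- paste(condition, ifelse(is.na(dose), "", dose), sep = "\r")
  groups <- unique(key)
  rows <- lapply(groups, function(g) {
    idx <- key == g
    data.frame(condition = condition[idx][1], dose = dose[idx][1],
               feature = selected,
               mean = colMeans(m[idx, selected, drop = FALSE]),
               sd = apply(m[idx, selected, drop = FALSE], 2, stats::sd),
               n = sum(idx))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$condition, out$dose, out$feature), ]
  rownames(out) <- NULL
  out
}
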