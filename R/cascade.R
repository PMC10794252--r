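## Primary-screen triage, 4PL dose-response confirmation, counter-screen
## activity calls, and the funnel summary.

#' Prefilter well records before triage
#'
#' Removes wells with no quantifiable signal (`NA` ratio), a cell count below
#' an absolute floor, or an artifact flag (e.g. autofluorescence spotted at
#' image review), recording the exclusion reason for each.
#'
#' @param wells data frame with columns `compound_id`, `ratio`, `cell_count`
#'   and optionally logical `artifact`.
#' @param min_cells absolute cell-count floor (default 10).
#' @return list: `retained` (data frame), `excluded` (data frame with
#'   `reason`).
#' @export
prefilter <- function(wells, min_cells = 10) {
  reason <- rep(NA_character_, nrow(wells))
  if ("artifact" %in% names(wells)) {
    reason[which(wells$artifact)] <- "imaging_artifact"
  }
  reason[is.na(reason) & !is.finite(wells$ratio)] <- "no_quantifiable_signal"
  reason[is.na(reason) & wells$cell_count < min_cells] <- "low_cell_count"
  keep <- is.na(reason)
  list(retained = wells[keep, , drop = FALSE],
       excluded = cbind(wells[!keep, , drop = FALSE],
                        reason = reason[!keep]))
}

#' Primary-screen hit triage
#'
#' Classifies each compound well from its per-plate z-scores into one of four
#' mutually exclusive, exhaustive categories using inclusive SD thresholds:
#' active means `ratio_z <= -activity_sd` (default 3, i.e. a reduction of the
#' translocation ratio by at least 3 negative-control SDs), toxic means
#' `cellcount_z <= -toxicity_sd` (default 2).
#'
#' @param wells normalized well table with columns `compound_id`, `ratio_z`,
#'   `cellcount_z` (compound wells only; control rows are ignored).
#' @param activity_sd,toxicity_sd positive threshold magnitudes.
#' @return data frame `compound_id`, `ratio_z`, `cellcount_z`, `category`
#'   (factor: inactive, toxic, active_toxic, active_nontoxic).
#' @export
triage_primary <- function(wells, activity_sd = 3, toxicity_sd = 2) {
  w <- if ("role" %in% names(wells)) {
    wells[is.na(wells$role) | wells$role == "compound", , drop = FALSE]
  } else wells
  if (!all(c("ratio_z", "cellcount_z") %in% names(w))) {
    stop("triage requires ratio_z and cellcount_z (run normalize_wells)")
  }
  act <- w$ratio_z <= -activity_sd
  tox <- w$cellcount_z <= -toxicity_sd
  category <- ifelse(act & tox, "active_toxic",
                     ifelse(act, "active_nontoxic",
                            ifelse(tox, "toxic", "inactive")))
  data.frame(compound_id = w$compound_id, ratio_z = w$ratio_z,
             cellcount_z = w$cellcount_z,
             category = factor(category,
                               levels = c("inactive", "toxic",
                                          "active_toxic", "active_nontoxic")))
}

#' Fit a four-parameter logistic dose-response model
#'
#' Least-squares fit of
#' `y = bottom + (top - bottom) / (1 + (x/ec50)^hill)`
#' parameterized in log10(ec50), via bounded Levenberg-Marquardt with a
#' multi-start over hill/EC50 initializations (shallow curves otherwise trap
#' the optimizer in boundary optima). EC50 is constrained to
#' `[min(dose)/10, max(dose)*10]`; a fit whose EC50 sits on that boundary or
#' whose dynamic range collapses is flagged rather than thrown.
#'
#' @param doses concentrations (micromolar, > 0); >= 4 distinct values.
#' @param responses numeric responses (replicates allowed: same length as
#'   `doses` after recycling the dose grid, or supply long-format vectors).
#' @return object of class `pl4_fit`: list with `bottom`, `top`, `ec50`,
#'   `hill`, `converged`, `ec50_in_range`, `degenerate`, `residual_sse`,
#'   `data`.
#' @export
fit_4pl <- function(doses, responses) {
  if (length(responses) %% length(doses) == 0 &&
      length(responses) > length(doses)) {
    doses <- rep(doses, length(responses) / length(doses))
  }
  stopifnot(length(doses) == length(responses))
  ok <- is.finite(doses) & is.finite(responses)
  doses <- doses[ok]; responses <- responses[ok]
  if (length(unique(doses)) < 4) stop("need at least 4 distinct doses")
  if (any(doses <= 0)) stop("doses must be positive")

  lx <- log10(doses)
  rng <- diff(range(responses))
  if (rng == 0) rng <- max(abs(responses[1]), 1)
  ## parameter vector: (bottom, top, lec50 = log10 EC50, hill)
  lo <- c(min(responses) - rng, min(responses) - 0.05 * rng,
          min(lx) - 1, 0.1)
  hi <- c(max(responses) + 0.05 * rng, max(responses) + rng,
          max(lx) + 1, 10)
  residfn <- function(p) {
    responses - (p[1] + (p[2] - p[1]) / (1 + 10^((lx - p[3]) * p[4])))
  }

  starts <- expand.grid(
    lec50 = stats::quantile(lx, c(0.25, 0.5, 0.75), names = FALSE),
    hill = c(0.5, 1, 2))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    st <- c(min(responses), max(responses), starts$lec50[i], starts$hill[i])
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, fn = residfn, lower = lo, upper = hi,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit) && fit$info %in% 1:4) {
      sse <- sum(fit$fvec^2)
      if (is.null(best) || sse < best$sse) best <- list(fit = fit, sse = sse)
    }
  }

  if (is.null(best)) {
    out <- list(bottom = NA_real_, top = NA_real_, ec50 = NA_real_,
                hill = NA_real_, converged = FALSE, ec50_in_range = FALSE,
                degenerate = TRUE, residual_sse = NA_real_,
                data = data.frame(dose_uM = doses, response = responses))
    return(structure(out, class = "pl4_fit"))
  }
  p <- stats::setNames(best$fit$par, c("bottom", "top", "lec50", "hill"))
  ec50 <- 10^p[["lec50"]]
  rng_lo <- min(doses) / 10; rng_hi <- max(doses) * 10
  span <- abs(p[["top"]] - p[["bottom"]])
  degenerate <- span < 1e-6 ||
    span < 0.05 * max(stats::sd(responses), 1e-12)
  out <- list(bottom = p[["bottom"]], top = p[["top"]], ec50 = ec50,
              hill = p[["hill"]], converged = TRUE,
              ec50_in_range = !degenerate && ec50 > rng_lo * 1.0001 &&
                ec50 < rng_hi * 0.9999,
              degenerate = degenerate, residual_sse = best$sse,
              data = data.frame(dose_uM = doses, response = responses))
  structure(out, class = "pl4_fit")
}

#' @export
print.pl4_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<pl4_fit> did not converge\n")
  } else {
    cat(sprintf(
      "<pl4_fit> bottom %.3g, top %.3g, EC50 %.3g uM%s, hill %.3g (SSE %.3g)%s\n",
      x$bottom, x$top, x$ec50,
      if (x$ec50_in_range) "" else " [out of range]",
      x$hill, x$residual_sse,
      if (x$degenerate) " [degenerate: flat response]" else ""))
  }
  invisible(x)
}

#' @export
coef.pl4_fit <- function(object, ...) {
  c(bottom = object$bottom, top = object$top, ec50 = object$ec50,
    hill = object$hill)
}

#' @export
predict.pl4_fit <- function(object, newdata = NULL, ...) {
  dose <- if (is.null(newdata)) object$data$dose_uM else {
    if (is.data.frame(newdata)) newdata$dose_uM else newdata
  }
  pl4(dose, object$bottom, object$top, object$ec50, object$hill)
}

#' @export
residuals.pl4_fit <- function(object, ...) {
  object$data$response - predict(object)
}

#' @export
plot.pl4_fit <- function(x, ...) {
  d <- x$data
  graphics::plot(d$dose_uM, d$response, log = "x",
                 xlab = "dose (uM)", ylab = "response", ...)
  if (x$converged) {
    xs <- 10^seq(log10(min(d$dose_uM)), log10(max(d$dose_uM)), length.out = 200)
    graphics::lines(xs, pl4(xs, x$bottom, x$top, x$ec50, x$hill))
    graphics::abline(v = x$ec50, lty = 2)
  }
  invisible(x)
}

#' Counter-screen activity call for one compound
#'
#' A compound is called active when its translocation-ratio z-score is at or
#' below the activity threshold in both replicates at two or more
#' concentrations, counting only concentrations that are not toxic
#' (cell-count z at or below the toxicity threshold in any replicate marks a
#' concentration toxic, and toxic concentrations contribute no activity
#' evidence). The call is invariant to the order of concentrations.
#'
#' @param titration data frame with columns `dose_uM`, `replicate`,
#'   `ratio_z` and optionally `cellcount_z`.
#' @param activity_sd,toxicity_sd positive threshold magnitudes (defaults 3
#'   and 2).
#' @param min_concentrations concentrations with activity in both replicates
#'   required for an active call (default 2).
#' @return list of class `counter_screen_call`: `active`,
#'   `n_active_concentrations`, `active_in_both_replicates`,
#'   `toxic_concentrations`.
#' @export
counter_screen_call <- function(titration, activity_sd = 3, toxicity_sd = 2,
                                min_concentrations = 2L) {
  stopifnot(all(c("dose_uM", "replicate", "ratio_z") %in% names(titration)))
  reps <- sort(unique(titration$replicate))
  if (length(reps) != 2) {
    stop("counter-screen expects exactly 2 replicates per concentration")
  }
  doses <- sort(unique(titration$dose_uM))
  toxic <- vapply(doses, function(d) {
    rows <- titration[titration$dose_uM == d, , drop = FALSE]
    "cellcount_z" %in% names(rows) &&
      any(rows$cellcount_z <= -toxicity_sd, na.rm = TRUE)
  }, logical(1))
  active_both <- vapply(doses, function(d) {
    rows <- titration[titration$dose_uM == d, , drop = FALSE]
    all(vapply(reps, function(r) {
      any(rows$ratio_z[rows$replicate == r] <= -activity_sd, na.rm = TRUE)
    }, logical(1)))
  }, logical(1))
  n_active <- sum(active_both & !toxic)
  structure(list(active = n_active >= min_concentrations,
                 n_active_concentrations = n_active,
                 active_in_both_replicates = any(active_both & !toxic),
                 toxic_concentrations = doses[toxic]),
            class = "counter_screen_call")
}

#' Format a share as a screen-convention percentage
#'
#' One decimal place, e.g. `51/503` prints as `"10.1%"`.
#'
#' @param k numerator. @param n denominator.
#' @return character.
#' @export
format_percent <- function(k, n) {
  sprintf("%.1f%%", 100 * k / n)
}

#' Funnel summary of the screening cascade
#'
#' Aggregates per-stage counts and percentages: prefilter exclusions,
#' primary-triage categories over retained compounds, counter-screen
#' confirmations (optionally reduced by artifact review) and the EC50
#' distribution (median, IQR) over confirmed compounds.
#'
#' @param triage data frame from [triage_primary()].
#' @param n_input total compounds entering the screen (defaults to triage
#'   rows, i.e. no prefilter exclusions).
#' @param counter_calls optional list of [counter_screen_call()] results for
#'   the compounds taken into the counter-screen.
#' @param artifact_flags optional logical vector along `counter_calls`
#'   marking compounds excluded at image review.
#' @param fits optional list of [fit_4pl()] objects for confirmed compounds.
#' @return list of class `cascade_summary` with `counts`, `percentages`
#'   (formatted strings) and `ec50_summary`.
#' @export
cascade_summary <- function(triage, n_input = nrow(triage),
                            counter_calls = NULL, artifact_flags = NULL,
                            fits = NULL) {
  tab <- table(triage$category)
  retained <- nrow(triage)
  n_active <- sum(tab[c("active_toxic", "active_nontoxic")])
  counts <- list(
    input = n_input,
    excluded_prefilter = n_input - retained,
    retained = retained,
    inactive = unname(tab[["inactive"]]),
    toxic = unname(tab[["toxic"]]),
    active_toxic = unname(tab[["active_toxic"]]),
    active_nontoxic = unname(tab[["active_nontoxic"]]),
    active_total = unname(n_active),
    ## screen-report convention: "excluded due to toxicity" counts every
    ## compound at or past the cell-count gate, active or not
    toxic_excluded = unname(tab[["toxic"]] + tab[["active_toxic"]]))
  percentages <- list(
    inactive = format_percent(counts$inactive, retained),
    toxic = format_percent(counts$toxic_excluded, retained),
    active_total = format_percent(counts$active_total, retained),
    active_nontoxic = format_percent(counts$active_nontoxic, retained))
  if (!is.null(counter_calls)) {
    act <- vapply(counter_calls, function(cc) isTRUE(cc$active), logical(1))
    counts$counter_screen_tested <- length(counter_calls)
    counts$counter_screen_active <- sum(act)
    percentages$counter_screen_active <-
      format_percent(sum(act), length(counter_calls))
    if (!is.null(artifact_flags)) {
      stopifnot(length(artifact_flags) == length(counter_calls))
      counts$counter_screen_artifact <- sum(act & artifact_flags)
      counts$confirmed <- sum(act & !artifact_flags)
    }
  }
  ec50_summary <- NULL
  if (!is.null(fits)) {
    ec <- vapply(fits, function(f) {
      if (isTRUE(f$converged) && isTRUE(f$ec50_in_range)) f$ec50 else NA_real_
    }, numeric(1))
    ec <- ec[is.finite(ec)]
    if (length(ec)) {
      ec50_summary <- list(n = length(ec), median = stats::median(ec),
                           iqr = stats::IQR(ec))
    }
  }
  structure(list(counts = counts, percentages = percentages,
                 ec50_summary = ec50_summary),
            class = "cascade_summary")
}

#' @export
print.cascade_summary <- function(x, ...) {
  c0 <- x$counts
  cat(sprintf("<cascade_summary> %d in, %d excluded, %d retained\n",
              c0$input, c0$excluded_prefilter, c0$retained))
  cat(sprintf("  inactive %d (%s), toxic %d (%s), active %d (%s; %d non-toxic, %d toxic)\n",
              c0$inactive, x$percentages$inactive, c0$toxic,
              x$percentages$toxic, c0$active_total,
              x$percentages$active_total, c0$active_nontoxic, c0$active_toxic))
  if (!is.null(c0$counter_screen_tested)) {
    cat(sprintf("  counter-screen: %d tested, %d active (%s)",
                c0$counter_screen_tested, c0$counter_screen_active,
                x$percentages$counter_screen_active))
    if (!is.null(c0$confirmed)) {
      cat(sprintf(", %d artifact-excluded, %d confirmed",
                  c0$counter_screen_artifact, c0$confirmed))
    }
    cat("\n")
  }
  if (!is.null(x$ec50_summary)) {
    cat(sprintf("  EC50 over %d confirmed fits: median %.3g uM (IQR %.3g)\n",
                x$ec50_summary$n, x$ec50_summary$median, x$ec50_summary$iqr))
  }
  invisible(x)
}
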