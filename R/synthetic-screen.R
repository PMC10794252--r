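## Well-level screen and titration simulators.
##
## Screen-scale tests work directly on per-well summary values (the image
## renderer is reserved for the image-quantification tests): wells are drawn
## from Normal models whose defaults are the control-well statistics of the
## assay (negative controls, i.e. the disease phenotype, mean ratio 1.34 sd
## 0.05; positive controls 1.10 sd 0.02), with planted active and toxic
## compounds at configurable rates and effect sizes.

#' Specification of a simulated screen
#'
#' @param n_plates number of assay plates.
#' @param wells_per_plate total wells per plate (default 384).
#' @param n_neg_ctrl,n_pos_ctrl control wells per plate (default 16 each,
#'   i.e. 1312 control wells per condition across an 82-plate screen).
#' @param neg_ratio_mean,neg_ratio_sd negative-control (disease phenotype)
#'   well-mean ratio distribution; defaults 1.34 and 0.05.
#' @param pos_ratio_mean,pos_ratio_sd positive-control (rescued phenotype)
#'   distribution; defaults 1.10 and 0.02.
#' @param cellcount_mean,cellcount_sd per-well cell-count distribution.
#' @param active_fraction fraction of compounds planted as active (default
#'   0.017, the primary-screen hit rate).
#' @param toxic_fraction fraction planted as toxic (default 0.05).
#' @param active_effect_sd_units downward shift of active-compound ratios in
#'   units of the negative-control SD (default 5).
#' @param toxic_effect_sd_units downward shift of toxic-compound cell counts
#'   in units of the cell-count SD (default 3).
#' @param plate_shift_sd SD of the per-plate additive shift applied to every
#'   ratio on a plate (inter-plate variability).
#' @param replicates compound replicates (wells per compound; default 1 as
#'   in a single-well primary screen).
#' @param seed integer seed.
#' @return object of class `screen_spec`.
#' @export
screen_spec <- function(n_plates = 6L, wells_per_plate = 384L,
                        n_neg_ctrl = 16L, n_pos_ctrl = 16L,
                        neg_ratio_mean = 1.34, neg_ratio_sd = 0.05,
                        pos_ratio_mean = 1.10, pos_ratio_sd = 0.02,
                        cellcount_mean = 150, cellcount_sd = 15,
                        active_fraction = 0.017, toxic_fraction = 0.05,
                        active_effect_sd_units = 5,
                        toxic_effect_sd_units = 3,
                        plate_shift_sd = 0.01, replicates = 1L, seed = 1L) {
  stopifnot(n_plates >= 1, wells_per_plate >= 1,
            n_neg_ctrl >= 0, n_pos_ctrl >= 0,
            neg_ratio_sd > 0, pos_ratio_sd > 0, cellcount_sd > 0,
            active_fraction >= 0, active_fraction <= 1,
            toxic_fraction >= 0, toxic_fraction <= 1,
            plate_shift_sd >= 0, replicates >= 1)
  if (wells_per_plate < n_neg_ctrl + n_pos_ctrl) {
    stop("controls exceed plate capacity")
  }
  structure(as.list(environment()), class = "screen_spec")
}

#' Simulate a whole screen at well level
#'
#' Generates a well table with plate/well coordinates, roles, compound ids,
#' per-well mean translocation ratio and cell count, drawing from the Normal
#' models of the [screen_spec()]. A single per-plate shift (Normal(0,
#' `plate_shift_sd`)) is added to all ratios of that plate; active compounds
#' are shifted down by `active_effect_sd_units * neg_ratio_sd`, toxic
#' compounds' cell counts by `toxic_effect_sd_units * cellcount_sd`. The
#' planted truth is returned separately.
#'
#' @param spec a [screen_spec()].
#' @return list of class `screen_table`: `wells` (data frame with columns
#'   plate, well, role, compound_id, concentration_uM, ratio, cell_count)
#'   and `truth` (data frame compound_id, active, toxic).
#' @export
generate_screen <- function(spec) {
  stopifnot(inherits(spec, "screen_spec"))
  set.seed(spec$seed)
  n_cmpd_wells <- spec$wells_per_plate - spec$n_neg_ctrl - spec$n_pos_ctrl
  n_compounds <- (spec$n_plates * n_cmpd_wells) %/% spec$replicates
  cmpd_ids <- sprintf("C%05d", seq_len(n_compounds))
  active <- stats::runif(n_compounds) < spec$active_fraction
  toxic <- stats::runif(n_compounds) < spec$toxic_fraction
  truth <- data.frame(compound_id = cmpd_ids, active = active, toxic = toxic)

  well_names <- plate_well_ids(spec$wells_per_plate)
  cmpd_queue <- rep(cmpd_ids, each = spec$replicates)
  rows <- vector("list", spec$n_plates)
  qpos <- 0L
  for (p in seq_len(spec$n_plates)) {
    shift <- stats::rnorm(1, 0, spec$plate_shift_sd)
    role <- c(rep("negative_control", spec$n_neg_ctrl),
              rep("positive_control", spec$n_pos_ctrl),
              rep("compound", n_cmpd_wells))
    cid <- c(rep(NA_character_, spec$n_neg_ctrl + spec$n_pos_ctrl),
             cmpd_queue[qpos + seq_len(n_cmpd_wells)])
    qpos <- qpos + n_cmpd_wells
    ratio <- numeric(spec$wells_per_plate)
    cc <- stats::rnorm(spec$wells_per_plate, spec$cellcount_mean,
                       spec$cellcount_sd)
    i_neg <- role == "negative_control"
    i_pos <- role == "positive_control"
    i_cmp <- role == "compound"
    ratio[i_neg] <- stats::rnorm(sum(i_neg), spec$neg_ratio_mean,
                                 spec$neg_ratio_sd)
    ratio[i_pos] <- stats::rnorm(sum(i_pos), spec$pos_ratio_mean,
                                 spec$pos_ratio_sd)
    ## untreated compound wells sit on the negative-control distribution
    ratio[i_cmp] <- stats::rnorm(sum(i_cmp), spec$neg_ratio_mean,
                                 spec$neg_ratio_sd)
    is_active <- i_cmp & cid %in% cmpd_ids[active]
    ratio[is_active] <- ratio[is_active] -
      spec$active_effect_sd_units * spec$neg_ratio_sd
    is_toxic <- i_cmp & cid %in% cmpd_ids[toxic]
    cc[is_toxic] <- cc[is_toxic] -
      spec$toxic_effect_sd_units * spec$cellcount_sd
    rows[[p]] <- data.frame(
      plate = sprintf("P%03d", p), well = well_names[seq_along(role)],
      role = role, compound_id = cid,
      concentration_uM = ifelse(role == "compound", 10, NA_real_),
      ratio = ratio + shift, cell_count = pmax(0, round(cc)))
  }
  wells <- do.call(rbind, rows)
  ## drop surplus compound wells that got no compound assigned
  wells <- wells[!(wells$role == "compound" & is.na(wells$compound_id)), ]
  structure(list(wells = wells, truth = truth, spec = spec),
            class = "screen_table")
}

#' @export
print.screen_table <- function(x, ...) {
  cat(sprintf(
    "<screen_table> %d plates, %d wells (%d compound), %d compounds (%d active, %d toxic planted)\n",
    length(unique(x$wells$plate)), nrow(x$wells),
    sum(x$wells$role == "compound"), nrow(x$truth),
    sum(x$truth$active), sum(x$truth$toxic)))
  invisible(x)
}

#' Row-letter + column-number well ids for a plate
#'
#' @param wells_per_plate 96 or 384 (8x12 / 16x24); other sizes get the
#'   smallest standard-shaped grid that holds them.
#' @return character vector like "A01", "A02", ...
#' @export
plate_well_ids <- function(wells_per_plate) {
  dims <- if (wells_per_plate <= 96) c(8L, 12L) else c(16L, 24L)
  if (wells_per_plate > prod(dims)) {
    dims <- c(ceiling(sqrt(wells_per_plate / 1.5)), 0L)
    dims[2] <- ceiling(wells_per_plate / dims[1])
  }
  ids <- as.vector(t(outer(LETTERS[seq_len(dims[1])],
                           sprintf("%02d", seq_len(dims[2])), paste0)))
  ids[seq_len(wells_per_plate)]
}

#' Eleven-point counter-screen dose grid
#'
#' The default titration used for confirmation: eleven concentrations from
#' 0.04 to 40 micromolar in two-fold steps.
#'
#' @return numeric vector of concentrations in micromolar.
#' @export
default_dose_grid <- function() {
  c(0.04, 0.08, 0.16, 0.31, 0.63, 1.25, 2.5, 5, 10, 20, 40)
}

#' Four-parameter logistic response
#'
#' @param dose concentrations (> 0).
#' @param bottom,top asymptotes (response units).
#' @param ec50 inflection concentration (same units as `dose`).
#' @param hill Hill slope (> 0 for a response that falls from `top` to
#'   `bottom` with increasing dose).
#' @return responses: `bottom + (top - bottom) / (1 + (dose/ec50)^hill)`.
#' @export
pl4 <- function(dose, bottom, top, ec50, hill) {
  bottom + (top - bottom) / (1 + (dose / ec50)^hill)
}

#' Simulate a titration experiment
#'
#' Responses are the 4PL curve plus Normal(0, `noise_sd`) per replicate;
#' deterministic given `seed`.
#'
#' @param bottom,top,ec50,hill generating 4PL parameters.
#' @param doses concentration grid (strictly positive); defaults to
#'   [default_dose_grid()].
#' @param noise_sd response noise SD (>= 0).
#' @param replicates replicates per dose.
#' @param seed integer seed.
#' @return data frame: dose_uM, replicate, response.
#' @export
generate_titration <- function(bottom, top, ec50, hill,
                               doses = default_dose_grid(),
                               noise_sd = 0, replicates = 2L, seed = 1L) {
  if (!length(doses)) stop("empty dose list")
  if (any(doses <= 0)) stop("doses must be strictly positive")
  if (noise_sd < 0) stop("negative noise_sd")
  set.seed(seed)
  out <- expand.grid(dose_uM = doses, replicate = seq_len(replicates))
  mu <- pl4(out$dose_uM, bottom, top, ec50, hill)
  out$response <- mu + if (noise_sd > 0) {
    stats::rnorm(nrow(out), 0, noise_sd)
  } else 0
  out[order(out$replicate, out$dose_uM), ]
}
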