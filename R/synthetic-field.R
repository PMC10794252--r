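## Synthetic 4-channel fluorescence fields with ground truth.
##
## The simulator emulates the geometry of the translocation assay: adherent
## cells with a stained nucleus, a cell-body stain, a compact perinuclear TGN
## blob, and a cargo channel whose total per-cell intensity is split between
## the TGN and the rest of the cell body with a controllable fraction. It is
## deliberately cartoon-like: its purpose is ground truth for the estimators,
## not photorealism.

#' Specification of a synthetic imaging field
#'
#' @param image_size integer vector (height, width) in pixels.
#' @param pixel_size physical pixel size in micrometres per pixel.
#' @param n_cells number of cells to place (>= 0).
#' @param cell_radius_range range (min, max) of the cell semi-major radius in
#'   pixels; each cell is a filled ellipse with mild random ellipticity.
#' @param nucleus_radius_fraction nucleus radius as a fraction of the cell
#'   minor radius, in (0, 1).
#' @param tgn_area_fraction designed TGN area as a fraction of cell area,
#'   in (0, 1).
#' @param cargo_tgn_fraction fraction of each cell's total cargo intensity
#'   budget deposited inside the TGN mask, in (0, 1). Ignored for a cell when
#'   `target_ratio` is given.
#' @param target_ratio optional designed translocation ratio (mean cargo
#'   intensity inside the TGN over mean intensity in the rest of the cell);
#'   when non-NULL the cargo split of every cell is solved from the realized
#'   compartment areas so the designed per-cell ratio equals this value.
#' @param puncta_count_mean mean number of cytoplasmic cargo puncta per cell
#'   (Poisson).
#' @param background_level constant background intensity added to every
#'   channel.
#' @param noise_sd standard deviation of additive Gaussian noise (intensity
#'   units); images are clipped at 0.
#' @param seed integer seed making the field reproducible.
#' @return object of class `field_spec`.
#' @export
field_spec <- function(image_size = c(256L, 256L), pixel_size = 0.65,
                       n_cells = 25L, cell_radius_range = c(16, 24),
                       nucleus_radius_fraction = 0.45,
                       tgn_area_fraction = 0.08, cargo_tgn_fraction = 0.6,
                       target_ratio = NULL, puncta_count_mean = 12,
                       background_level = 0.02, noise_sd = 0, seed = 1L) {
  stopifnot(length(image_size) == 2L, all(image_size >= 1),
            pixel_size > 0, n_cells >= 0,
            length(cell_radius_range) == 2L,
            cell_radius_range[1] > 0,
            cell_radius_range[2] >= cell_radius_range[1],
            noise_sd >= 0, puncta_count_mean >= 0, background_level >= 0)
  for (f in c(nucleus_radius_fraction, tgn_area_fraction)) {
    if (!(f > 0 && f < 1)) stop("fractions must lie strictly in (0, 1)")
  }
  if (is.null(target_ratio)) {
    if (!(cargo_tgn_fraction > 0 && cargo_tgn_fraction < 1)) {
      stop("cargo_tgn_fraction must lie strictly in (0, 1)")
    }
  } else stopifnot(target_ratio > 0)
  structure(list(image_size = as.integer(image_size), pixel_size = pixel_size,
                 n_cells = as.integer(n_cells),
                 cell_radius_range = cell_radius_range,
                 nucleus_radius_fraction = nucleus_radius_fraction,
                 tgn_area_fraction = tgn_area_fraction,
                 cargo_tgn_fraction = cargo_tgn_fraction,
                 target_ratio = target_ratio,
                 puncta_count_mean = puncta_count_mean,
                 background_level = background_level,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "field_spec")
}

#' Render a synthetic field with ground truth
#'
#' Places `n_cells` non-overlapping elliptical cell bodies (rejection sampling
#' of centres) fully inside the field, each containing a nuclear disk and a
#' compact perinuclear TGN blob, then deposits per-cell cargo intensity:
#' `cargo_tgn_fraction` of the cell's cargo budget spread uniformly over its
#' TGN mask, the remainder split between diffuse cytoplasmic signal and
#' discrete puncta. Additive Gaussian noise of sd `noise_sd` is applied to
#' every channel and the result clipped at zero. Deterministic given
#' `spec$seed`.
#'
#' @param spec a [field_spec()].
#' @return list of class `field_image` with elements
#'   \describe{
#'     \item{channels}{named list of H x W intensity matrices:
#'       `nucleus`, `body`, `tgn`, `cargo`.}
#'     \item{pixel_size}{micrometres per pixel.}
#'     \item{truth}{ground truth: labelled masks `nucleus_labels`,
#'       `cell_labels`, `tgn_labels` and a per-cell data frame `cells` with
#'       designed cargo split and designed ratio, plus a `clipped` flag.}
#'   }
#' @export
generate_field <- function(spec) {
  stopifnot(inherits(spec, "field_spec"))
  set.seed(spec$seed)
  H <- spec$image_size[1]; W <- spec$image_size[2]
  dimhw <- c(H, W)
  zero <- matrix(0, H, W)
  lab0 <- matrix(0L, H, W)
  ch <- list(nucleus = zero, body = zero, tgn = zero, cargo = zero)
  nuc_lab <- lab0; cell_lab <- lab0; tgn_lab <- lab0

  cells <- data.frame(cell_id = integer(), row = numeric(), col = numeric(),
                      radius = numeric(), cell_area = numeric(),
                      nucleus_area = numeric(), tgn_area = numeric(),
                      cargo_budget = numeric(), cargo_tgn_fraction = numeric(),
                      designed_ratio = numeric(), clipped = logical())

  if (spec$n_cells > 0L) {
    ## rejection-sample non-overlapping centres with an interior margin
    centers <- matrix(numeric(0), 0, 2); radii <- numeric(0)
    tries <- 0L
    while (nrow(centers) < spec$n_cells && tries < 20000L) {
      tries <- tries + 1L
      r <- stats::runif(1, spec$cell_radius_range[1], spec$cell_radius_range[2])
      m <- r + 2
      if (H - 2 * m < 1 || W - 2 * m < 1) break
      p <- c(stats::runif(1, 1 + m, H - m), stats::runif(1, 1 + m, W - m))
      if (nrow(centers) == 0L ||
          all(sqrt(rowSums(sweep(centers, 2, p)^2)) > radii + r + 2)) {
        centers <- rbind(centers, p); radii <- c(radii, r)
      }
    }
    if (nrow(centers) < spec$n_cells) {
      warning("field too crowded: placed ", nrow(centers), " of ",
              spec$n_cells, " cells")
    }

    for (i in seq_len(nrow(centers))) {
      cen <- centers[i, ]; a <- radii[i]
      b <- a * stats::runif(1, 0.75, 1)   # mild ellipticity, convex body
      theta <- stats::runif(1, 0, pi)
      cell <- raster_ellipse(dimhw, cen, a, b, theta)
      nr <- spec$nucleus_radius_fraction * b
      nuc <- raster_disk(dimhw, cen, nr) & cell
      ## perinuclear TGN: disk tangent to the nucleus, clipped to the
      ## cytoplasm (cell minus nucleus)
      tr <- sqrt(spec$tgn_area_fraction * sum(cell) / pi)
      phi <- stats::runif(1, 0, 2 * pi)
      tcen <- cen + (nr + tr * 0.7) * c(cos(phi), sin(phi))
      tgn <- raster_disk(dimhw, tcen, tr) & cell & !nuc
      if (sum(tgn) < 4) {  # pathological clip: re-anchor next to nucleus centre
        tgn <- raster_disk(dimhw, cen + c(0, nr), tr) & cell & !nuc
      }

      a_cell <- sum(cell); a_nuc <- sum(nuc); a_tgn <- sum(tgn)
      a_out <- a_cell - a_tgn
      if (a_tgn == 0 || a_out == 0) next

      budget <- 100 * a_cell / 1000   # arbitrary intensity units per cell
      if (!is.null(spec$target_ratio)) {
        ## solve f/(1-f) = ratio * a_tgn / a_out for the budget split
        k <- spec$target_ratio * a_tgn / a_out
        f <- k / (1 + k)
      } else f <- spec$cargo_tgn_fraction
      designed_ratio <- (f / a_tgn) / ((1 - f) / a_out)

      id <- nrow(cells) + 1L
      nuc_lab[nuc] <- id; cell_lab[cell] <- id; tgn_lab[tgn] <- id

      ch$nucleus[nuc] <- ch$nucleus[nuc] + 0.8
      ch$body[cell] <- ch$body[cell] + 0.5
      ch$tgn[tgn] <- ch$tgn[tgn] + 0.9

      ## cargo: uniform over TGN; outside budget = diffuse + puncta, both
      ## confined to the cell-minus-TGN compartment so compartment means are
      ## exactly the designed ones
      ch$cargo[tgn] <- ch$cargo[tgn] + f * budget / a_tgn
      out_mask <- cell & !tgn
      out_budget <- (1 - f) * budget
      n_puncta <- stats::rpois(1, spec$puncta_count_mean)
      puncta_budget <- if (n_puncta > 0) 0.3 * out_budget else 0
      ch$cargo[out_mask] <- ch$cargo[out_mask] +
        (out_budget - puncta_budget) / a_out
      if (n_puncta > 0) {
        out_idx <- which(out_mask)
        pk <- sample(out_idx, min(n_puncta, length(out_idx)))
        ## each punctum: a 3x3 stamp clipped to the compartment
        per_punctum <- puncta_budget / length(pk)
        for (p in pk) {
          rr <- ((p - 1L) %% H) + 1L; cc <- ((p - 1L) %/% H) + 1L
          rs <- max(1, rr - 1):min(H, rr + 1)
          cs <- max(1, cc - 1):min(W, cc + 1)
          sub <- out_mask[rs, cs, drop = FALSE]
          if (any(sub)) {
            add <- matrix(0, length(rs), length(cs))
            add[sub] <- per_punctum / sum(sub)
            ch$cargo[rs, cs] <- ch$cargo[rs, cs] + add
          }
        }
      }

      cells <- rbind(cells, data.frame(
        cell_id = id, row = cen[1], col = cen[2], radius = a,
        cell_area = a_cell, nucleus_area = a_nuc, tgn_area = a_tgn,
        cargo_budget = budget, cargo_tgn_fraction = f,
        designed_ratio = designed_ratio, clipped = FALSE))
    }
  }

  for (nm in names(ch)) {
    x <- ch[[nm]] + spec$background_level
    if (spec$noise_sd > 0) {
      x <- x + matrix(stats::rnorm(H * W, 0, spec$noise_sd), H, W)
    }
    ch[[nm]] <- pmax(x, 0)
  }

  structure(list(channels = ch, pixel_size = spec$pixel_size,
                 spec = spec,
                 truth = list(nucleus_labels = nuc_lab,
                              cell_labels = cell_lab,
                              tgn_labels = tgn_lab,
                              cells = cells)),
            class = "field_image")
}

#' @export
print.field_image <- function(x, ...) {
  cat(sprintf("<field_image> %d x %d px (%.2f um/px), %d cells, channels: %s\n",
              nrow(x$channels[[1]]), ncol(x$channels[[1]]), x$pixel_size,
              nrow(x$truth$cells), paste(names(x$channels), collapse = ", ")))
  invisible(x)
}
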