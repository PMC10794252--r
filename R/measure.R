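## Per-cell quantification: compartment intensities, the translocation
## ratio, TGN morphology, and the multiparametric feature vector.

#' Quantify every retained cell of a segmented field
#'
#' For each cell the cargo channel is summarized over the two compartments
#' (TGN mask, and cell-minus-TGN) as the arithmetic mean of
#' background-subtracted pixel intensities, and the translocation ratio is
#' their quotient:
#' \deqn{ratio = mean(cargo | TGN) / mean(cargo | cell \ TGN)}
#' TGN morphology (elongation, compactness, roughness) is computed on the
#' cell's TGN mask. Cells with an empty TGN mask or with zero mean intensity
#' outside the TGN are excluded with reason codes rather than producing
#' undefined numbers.
#'
#' @param field `field_image` or named list of channel matrices (must contain
#'   `cargo`).
#' @param seg `segmentation_result` from [segment_field()].
#' @param background constant background estimate subtracted from the cargo
#'   channel before averaging; `NULL` (default) estimates it as the median
#'   cargo intensity outside all cell masks.
#' @param pixel_size micrometres per pixel (taken from `field` when it is a
#'   `field_image`).
#' @return data frame with one row per retained cell: `cell_id`,
#'   `nucleus_area`, `cell_area`, `tgn_area` (um^2), `cargo_in_tgn`,
#'   `cargo_out_tgn` (mean intensity), `translocation_ratio`,
#'   `tgn_elongation`, `tgn_compactness`, `tgn_roughness`, plus attribute
#'   `"excluded"` carrying the exclusion table (cell_id, reason).
#' @export
measure_cells <- function(field, seg, background = NULL, pixel_size = NULL) {
  ch <- if (inherits(field, "field_image")) field$channels else field
  if (is.null(pixel_size)) {
    pixel_size <- if (inherits(field, "field_image")) field$pixel_size else 1
  }
  stopifnot(inherits(seg, "segmentation_result"), "cargo" %in% names(ch))
  cargo <- ch$cargo
  if (is.null(background)) {
    out_all <- cargo[seg$cell_labels == 0L]
    background <- if (length(out_all)) stats::median(out_all) else 0
  }
  cargo <- cargo - background

  ids <- setdiff(sort(unique(as.vector(seg$cell_labels))), 0L)
  excluded <- seg$excluded
  rows <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    id <- ids[k]
    cell <- seg$cell_labels == id
    tgn <- seg$tgn_labels == id
    if (!any(tgn)) {
      excluded <- rbind(excluded, data.frame(cell_id = id, reason = "no_tgn"))
      next
    }
    outm <- cell & !tgn
    mean_in <- mean(cargo[tgn])
    mean_out <- mean(cargo[outm])
    if (!is.finite(mean_out) || mean_out <= 0) {
      excluded <- rbind(excluded,
                        data.frame(cell_id = id, reason = "undefined_ratio"))
      next
    }
    morph <- tgn_morphology(tgn, pixel_size)
    rows[[k]] <- data.frame(
      cell_id = id,
      nucleus_area = sum(seg$nucleus_labels == id) * pixel_size^2,
      cell_area = sum(cell) * pixel_size^2,
      tgn_area = sum(tgn) * pixel_size^2,
      cargo_in_tgn = mean_in,
      cargo_out_tgn = mean_out,
      translocation_ratio = mean_in / mean_out,
      tgn_elongation = morph$elongation,
      tgn_compactness = morph$compactness,
      tgn_roughness = morph$roughness)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(cell_id = integer(), nucleus_area = numeric(),
                      cell_area = numeric(), tgn_area = numeric(),
                      cargo_in_tgn = numeric(), cargo_out_tgn = numeric(),
                      translocation_ratio = numeric(),
                      tgn_elongation = numeric(), tgn_compactness = numeric(),
                      tgn_roughness = numeric())
  }
  attr(out, "excluded") <- excluded
  attr(out, "background") <- background
  out
}

#' Multiparametric feature vector per cell
#'
#' A fixed-order, named set of 90 descriptors per cell: for each of the three
#' regions (nucleus, whole cell, TGN) eight shape descriptors (area,
#' perimeter, major and minor axis, eccentricity, solidity, compactness,
#' roughness) and, for each of the four channels, five intensity statistics
#' (mean, sd, median, mad, total) over nucleus/cell/TGN in a documented
#' rotation (60 intensity features); plus cargo-positive-region descriptors
#' (area, puncta count, mean punctum size, mean intensity), the translocation
#' ratio and the in-TGN cargo fraction. Descriptors of an empty sub-mask are
#' `NA`.
#'
#' @param field `field_image` or named channel list (`nucleus`, `body`,
#'   `tgn`, `cargo`).
#' @param seg `segmentation_result`.
#' @param pixel_size micrometres per pixel.
#' @return data frame, one row per retained cell, 1 + 90 columns
#'   (`cell_id` + features); column order is stable across runs.
#' @export
extract_features <- function(field, seg, pixel_size = NULL) {
  ch <- if (inherits(field, "field_image")) field$channels else field
  if (is.null(pixel_size)) {
    pixel_size <- if (inherits(field, "field_image")) field$pixel_size else 1
  }
  stopifnot(inherits(seg, "segmentation_result"),
            all(c("nucleus", "body", "tgn", "cargo") %in% names(ch)))
  ids <- setdiff(sort(unique(as.vector(seg$cell_labels))), 0L)
  cargo_th <- threshold_image(ch$cargo)

  shape_names <- c("area", "perimeter", "major_axis", "minor_axis",
                   "eccentricity", "solidity", "compactness", "roughness")
  int_names <- c("mean", "sd", "median", "mad", "total")
  regions <- c("nucleus", "cell", "tgn")
  channels <- c("nucleus", "body", "tgn", "cargo")
  feat_names <- c(
    as.vector(outer(shape_names, regions, function(s, r) paste(r, s, sep = "_"))),
    as.vector(vapply(channels, function(cn)
      as.vector(outer(int_names, regions, function(s, r)
        paste(cn, r, s, sep = "_"))), character(15))),
    paste0("cargo_pos_", c("area", "puncta_count", "puncta_mean_size",
                           "mean_intensity")),
    "translocation_ratio", "cargo_fraction_in_tgn")

  shape_block <- function(mask) {
    if (!any(mask)) return(rep(NA_real_, 8))
    m <- tgn_morphology(mask, pixel_size)
    c(m$area, m$perimeter, m$major, m$minor, m$eccentricity, m$solidity,
      m$compactness, m$roughness)
  }
  int_block <- function(img, mask) {
    if (!any(mask)) return(rep(NA_real_, 5))
    v <- img[mask]
    c(mean(v), stats::sd(v), stats::median(v), stats::mad(v), sum(v))
  }

  rows <- matrix(NA_real_, length(ids), length(feat_names),
                 dimnames = list(NULL, feat_names))
  for (k in seq_along(ids)) {
    id <- ids[k]
    cell <- seg$cell_labels == id
    nuc <- seg$nucleus_labels == id
    tgn <- seg$tgn_labels == id
    masks <- list(nucleus = nuc, cell = cell, tgn = tgn)
    f <- unlist(lapply(masks, shape_block), use.names = FALSE)
    for (cn in channels) {
      f <- c(f, unlist(lapply(masks, function(m) int_block(ch[[cn]], m)),
                       use.names = FALSE))
    }
    ## cargo-positive region inside the cell body, outside the TGN (puncta)
    pos <- (ch$cargo > cargo_th) & cell & !tgn
    if (any(pos)) {
      plab <- EBImage::bwlabel(EBImage::Image(pos * 1))
      np <- max(as_label_matrix(plab))
      f <- c(f, sum(pos) * pixel_size^2, np,
             sum(pos) / np * pixel_size^2, mean(ch$cargo[pos]))
    } else {
      f <- c(f, 0, 0, NA_real_, 0)
    }
    outm <- cell & !tgn
    if (any(tgn) && any(outm) && mean(ch$cargo[outm]) > 0) {
      ratio <- mean(ch$cargo[tgn]) / mean(ch$cargo[outm])
      frac <- sum(ch$cargo[tgn]) / sum(ch$cargo[cell])
    } else {
      ratio <- NA_real_; frac <- NA_real_
    }
    rows[k, ] <- c(f, ratio, frac)
  }
  out <- data.frame(cell_id = ids, rows, check.names = FALSE)
  out
}

#' Cargo puncta density along a neurite
#'
#' Detects puncta as local intensity maxima above a threshold inside the
#' neurite mask, skeletonizes the mask (Zhang-Suen thinning) and reports
#' puncta per micrometre of skeleton length.
#'
#' @param cargo cargo channel, numeric matrix.
#' @param neurite_mask logical matrix.
#' @param pixel_size micrometres per pixel.
#' @param threshold intensity threshold for a punctum; `NULL` uses Otsu over
#'   the masked pixels.
#' @return list: `density` (puncta / um), `n_puncta`, `skeleton_length_um`.
#' @export
puncta_density <- function(cargo, neurite_mask, pixel_size = 1,
                           threshold = NULL) {
  stopifnot(all(dim(cargo) == dim(neurite_mask)))
  skel <- skeletonize(neurite_mask > 0)
  len <- skeleton_length(skel) * pixel_size
  if (len <= 0) stop("zero-length skeleton")
  if (is.null(threshold)) threshold <- threshold_image(cargo)
  ## local maxima: pixel equal to its 3x3 neighbourhood maximum
  dil <- EBImage::imageData(
    EBImage::dilate(EBImage::Image(cargo), EBImage::makeBrush(3, "box")))
  peaks <- (cargo >= dil) & (cargo > threshold) & (neurite_mask > 0)
  n <- if (any(peaks)) {
    max(as_label_matrix(EBImage::bwlabel(EBImage::Image(peaks * 1))))
  } else 0L
  list(density = n / len, n_puncta = n, skeleton_length_um = len)
}

#' Zhang-Suen skeletonization of a binary mask
#'
#' @param mask logical matrix.
#' @return logical matrix, the one-pixel-wide skeleton.
#' @export
skeletonize <- function(mask) {
  m <- pad_mask(mask)
  repeat {
    changed <- FALSE
    for (phase in 1:2) {
      nb <- neighbours8(m)
      p <- m
      B <- nb$n2 + nb$n3 + nb$n4 + nb$n5 + nb$n6 + nb$n7 + nb$n8 + nb$n9
      ## A = number of 0->1 transitions in the ordered ring P2..P9,P2
      ring <- list(nb$n2, nb$n3, nb$n4, nb$n5, nb$n6, nb$n7, nb$n8, nb$n9,
                   nb$n2)
      A <- matrix(0L, nrow(m), ncol(m))
      for (i in 1:8) A <- A + (!ring[[i]] & ring[[i + 1]])
      if (phase == 1) {
        c1 <- !(nb$n2 & nb$n4 & nb$n6)
        c2 <- !(nb$n4 & nb$n6 & nb$n8)
      } else {
        c1 <- !(nb$n2 & nb$n4 & nb$n8)
        c2 <- !(nb$n2 & nb$n6 & nb$n8)
      }
      del <- p & B >= 2 & B <= 6 & A == 1 & c1 & c2
      if (any(del)) { m[del] <- FALSE; changed <- TRUE }
    }
    if (!changed) break
  }
  m[2:(nrow(m) - 1), 2:(ncol(m) - 1)]
}

neighbours8 <- function(m) {
  H <- nrow(m); W <- ncol(m)
  sh <- function(dr, dc) {  # value of the neighbour at offset (dr, dc)
    out <- matrix(FALSE, H, W)
    rs <- max(1, 1 - dr):min(H, H - dr)
    cs <- max(1, 1 - dc):min(W, W - dc)
    out[rs, cs] <- m[rs + dr, cs + dc]
    out
  }
  ## P2 = north, then clockwise (P4 = east, P6 = south, P8 = west)
  list(n2 = sh(-1, 0), n3 = sh(-1, 1), n4 = sh(0, 1), n5 = sh(1, 1),
       n6 = sh(1, 0), n7 = sh(1, -1), n8 = sh(0, -1), n9 = sh(-1, -1))
}

## sum of inter-pixel steps along the skeleton graph: orthogonal neighbours
## contribute 1, diagonal neighbours sqrt(2); each adjacency counted once
skeleton_length <- function(skel) {
  if (!any(skel)) return(0)
  m <- pad_mask(skel)
  H <- nrow(m); W <- ncol(m)
  east <- m[, -W] & m[, -1]
  south <- m[-H, ] & m[-1, ]
  se <- m[-H, -W] & m[-1, -1]
  sw <- m[-H, -1] & m[-1, -W]
  ## don't double-count diagonals that shortcut an orthogonal pair
  sum(east) + sum(south) + sqrt(2) * (sum(se) + sum(sw))
}
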