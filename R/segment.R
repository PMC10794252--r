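## Segmentation of nuclei, cell bodies and the TGN compartment.
## EBImage provides the primitives (global Otsu threshold, connected
## components, hole filling, Voronoi-style seeded region growing).

#' Global threshold of a single-channel image
#'
#' @param img numeric matrix.
#' @param method "otsu" (default) or "fixed".
#' @param fixed threshold value for `method = "fixed"`.
#' @param offset additive offset applied to the computed threshold.
#' @return scalar threshold; `Inf` for a constant image (nothing above
#'   threshold).
#' @export
threshold_image <- function(img, method = c("otsu", "fixed"), fixed = NULL,
                            offset = 0) {
  method <- match.arg(method)
  if (method == "fixed") {
    if (is.null(fixed)) stop("method = 'fixed' requires `fixed`")
    return(fixed + offset)
  }
  rng <- range(img)
  if (diff(rng) <= 0) return(Inf)
  x <- (img - rng[1]) / diff(rng)
  th <- EBImage::otsu(EBImage::Image(x), range = c(0, 1))
  th * diff(rng) + rng[1] + offset
}

#' Segment nuclei from the nuclear-stain channel
#'
#' Global threshold, hole filling, connected-component labelling, and removal
#' of objects below `min_area`. An all-background image yields an empty
#' labelling, not an error.
#'
#' @param img nuclear channel, numeric matrix.
#' @param min_area minimum object area in pixels.
#' @param method,fixed,offset passed to [threshold_image()].
#' @return integer label matrix (0 = background).
#' @export
segment_nuclei <- function(img, min_area = 30, method = "otsu",
                           fixed = NULL, offset = 0) {
  stopifnot(is.matrix(img))
  th <- threshold_image(img, method, fixed, offset)
  bw <- img > th
  if (!any(bw)) return(matrix(0L, nrow(img), ncol(img)))
  bw <- EBImage::fillHull(EBImage::Image(bw * 1))
  lab <- EBImage::bwlabel(bw)
  lab <- drop_small_objects(lab, min_area)
  relabel(as_label_matrix(lab))
}

#' Segment cell bodies seeded by nuclei
#'
#' Thresholds the cell-body channel and grows one region per nucleus inside
#' the body mask (Voronoi propagation on image intensity), so a body blob
#' containing two nuclei is split along the seeded boundary. Nuclei with no
#' surrounding body signal produce no cell; body signal with no nucleus is
#' discarded.
#'
#' @param img cell-body channel, numeric matrix.
#' @param nuclei integer label matrix from [segment_nuclei()].
#' @param method,fixed,offset passed to [threshold_image()].
#' @return integer label matrix; labels correspond to nucleus labels.
#' @export
segment_cell_bodies <- function(img, nuclei, method = "otsu",
                                fixed = NULL, offset = 0) {
  if (!all(dim(img) == dim(nuclei))) stop("channel/nuclei shape mismatch")
  th <- threshold_image(img, method, fixed, offset)
  bw <- (img > th) | nuclei > 0   # a nucleus is always part of its cell
  seeds <- EBImage::Image(nuclei)
  cells <- EBImage::propagate(EBImage::Image(img), seeds = seeds,
                              mask = EBImage::Image(bw * 1))
  lab <- as_label_matrix(cells)
  ## a "cell" that is no bigger than its nucleus has no body signal: drop it
  keep <- integer(0)
  for (id in setdiff(unique(as.vector(lab)), 0L)) {
    if (sum(lab == id) > 1.05 * sum(nuclei == id)) keep <- c(keep, id)
  }
  lab[!(lab %in% keep)] <- 0L
  lab
}

#' Segment the TGN compartment within each cell
#'
#' Thresholds the TGN-marker channel and intersects the mask with each cell,
#' so a blob straddling two cells is split by the cell boundary. The
#' cytoplasm compartment is implicitly cell-minus-TGN.
#'
#' @param img TGN channel, numeric matrix.
#' @param cell_labels integer label matrix from [segment_cell_bodies()].
#' @param method,fixed,offset passed to [threshold_image()].
#' @return integer label matrix sharing label ids with `cell_labels`; cells
#'   whose TGN mask is empty simply have no pixels here (flagged downstream).
#' @export
segment_tgn <- function(img, cell_labels, method = "otsu",
                        fixed = NULL, offset = 0) {
  if (!all(dim(img) == dim(cell_labels))) stop("channel/cell shape mismatch")
  th <- threshold_image(img, method, fixed, offset)
  lab <- cell_labels
  lab[!(img > th)] <- 0L
  lab
}

#' Segment a whole field
#'
#' Runs nucleus, cell-body and TGN segmentation on a 4-channel field and
#' assembles a consistent labelling: border-touching cells are excluded, and
#' every retained TGN belongs to a retained cell. Exclusions are recorded
#' with reason codes.
#'
#' @param field a `field_image` (see [generate_field()]) or a named list of
#'   channel matrices `nucleus`, `body`, `tgn`, `cargo`.
#' @param min_nucleus_area minimum nucleus area in pixels.
#' @param method threshold method for all channels.
#' @return list of class `segmentation_result`: `nucleus_labels`,
#'   `cell_labels`, `tgn_labels`, and data frame `excluded`
#'   (cell_id, reason).
#' @export
segment_field <- function(field, min_nucleus_area = 30, method = "otsu") {
  ch <- if (inherits(field, "field_image")) field$channels else field
  stopifnot(all(c("nucleus", "body", "tgn") %in% names(ch)))
  nuc <- segment_nuclei(ch$nucleus, min_area = min_nucleus_area,
                        method = method)
  cells <- segment_cell_bodies(ch$body, nuc, method = method)
  excluded <- data.frame(cell_id = integer(), reason = character())

  ## nuclei that did not yield a cell
  lost <- setdiff(setdiff(unique(as.vector(nuc)), 0L),
                  unique(as.vector(cells)))
  if (length(lost)) {
    excluded <- rbind(excluded,
                      data.frame(cell_id = lost, reason = "no_cell_body"))
  }
  ## border-touching cells
  border_ids <- setdiff(unique(c(cells[1, ], cells[nrow(cells), ],
                                 cells[, 1], cells[, ncol(cells)])), 0L)
  if (length(border_ids)) {
    cells[cells %in% border_ids] <- 0L
    excluded <- rbind(excluded,
                      data.frame(cell_id = border_ids,
                                 reason = "touching_border"))
  }
  nuc[!(nuc %in% unique(as.vector(cells)))] <- 0L
  tgn <- segment_tgn(ch$tgn, cells, method = method)
  structure(list(nucleus_labels = nuc, cell_labels = cells,
                 tgn_labels = tgn, excluded = excluded),
            class = "segmentation_result")
}

## ---- internals -----------------------------------------------------------

as_label_matrix <- function(x) {
  m <- EBImage::imageData(x)
  storage.mode(m) <- "integer"
  m
}

drop_small_objects <- function(lab, min_area) {
  m <- as_label_matrix(lab)
  tab <- tabulate(m[m > 0])
  small <- which(tab < min_area)
  if (length(small)) m[m %in% small] <- 0L
  m
}

relabel <- function(m) {
  ids <- setdiff(sort(unique(as.vector(m))), 0L)
  if (!length(ids)) return(m)
  map <- integer(max(ids)); map[ids] <- seq_along(ids)
  out <- m
  out[m > 0] <- map[m[m > 0]]
  out
}
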