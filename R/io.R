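## File formats: CSV plate maps and well tables, multi-page TIFF fields with
## a JSON ground-truth sidecar, YAML run configuration, JSON run manifests.

WELL_ROLES <- c("negative_control", "positive_control", "compound", "empty")

#' Read and validate a plate map
#'
#' A plate map is a CSV with columns `plate`, `well` (row letter + 2-digit
#' column, e.g. "A01"), `role` (one of negative_control, positive_control,
#' compound, empty) and optionally `compound_id`, `concentration_uM`,
#' `replicate`. Violations are reported with the offending rows.
#'
#' @param path CSV file.
#' @return data frame of class `plate_map`.
#' @export
read_plate_map <- function(path) {
  pm <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_plate_map(pm)
}

#' Validate a plate-map data frame
#'
#' @param pm data frame with plate-map columns.
#' @return the validated data frame (class `plate_map`).
#' @export
validate_plate_map <- function(pm) {
  need <- c("plate", "well", "role")
  miss <- setdiff(need, names(pm))
  if (length(miss)) stop("plate map missing columns: ",
                         paste(miss, collapse = ", "))
  bad <- which(!grepl("^[A-P](0[1-9]|1[0-9]|2[0-4])$", pm$well))
  if (length(bad)) {
    stop("malformed well id(s) at row(s) ", paste(utils::head(bad, 5),
         collapse = ", "), ": ", paste(utils::head(pm$well[bad], 5),
         collapse = ", "))
  }
  badrole <- which(!pm$role %in% WELL_ROLES)
  if (length(badrole)) {
    stop("unknown role(s) at row(s) ", paste(utils::head(badrole, 5),
         collapse = ", "), ": ", paste(unique(pm$role[badrole]),
         collapse = ", "))
  }
  dup <- duplicated(pm[, c("plate", "well")])
  if (any(dup)) stop("duplicate wells within a plate: ",
                     paste(utils::head(paste(pm$plate[dup], pm$well[dup]), 5),
                           collapse = ", "))
  if ("concentration_uM" %in% names(pm)) {
    badc <- which(pm$role == "compound" &
                    !is.na(pm$concentration_uM) & pm$concentration_uM <= 0)
    if (length(badc)) stop("non-positive concentration at row(s) ",
                           paste(utils::head(badc, 5), collapse = ", "))
  }
  class(pm) <- c("plate_map", class(pm))
  pm
}

#' Write a well/screen table as CSV
#'
#' @param tab data frame (e.g. `screen_table$wells`).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_screen_csv <- function(tab, path) {
  if (inherits(tab, "screen_table")) tab <- tab$wells
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a well/screen table from CSV
#'
#' @param path CSV path.
#' @return data frame.
#' @export
read_screen_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write a field as a multi-page TIFF plus a JSON ground-truth sidecar
#'
#' One 32-bit float page per channel, in the order nucleus, body, tgn,
#' cargo; intensities are stored as-is (not rescaled). When the field
#' carries ground truth a `<path>.truth.json` sidecar holds the designed
#' per-cell table and run-length-encoded label masks.
#'
#' @param field `field_image`.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_field_tiff <- function(field, path) {
  stopifnot(inherits(field, "field_image"))
  mx <- max(unlist(lapply(field$channels, max)), 1e-12)
  pages <- lapply(field$channels, function(ch) ch / mx)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta <- list(channels = names(field$channels),
               pixel_size = field$pixel_size, intensity_scale = mx)
  if (!is.null(field$truth)) {
    meta$cells <- field$truth$cells
    meta$labels <- lapply(
      field$truth[c("nucleus_labels", "cell_labels", "tgn_labels")],
      function(m) {
        r <- rle(as.integer(m))
        list(dim = dim(m), lengths = r$lengths, values = r$values)
      })
  }
  jsonlite::write_json(meta, paste0(path, ".truth.json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}

#' Read a field written by [write_field_tiff()]
#'
#' @param path TIFF path (sidecar `<path>.truth.json` read when present).
#' @return `field_image`.
#' @export
read_field_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  sidecar <- paste0(path, ".truth.json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else NULL
  nm <- if (!is.null(meta)) unlist(meta$channels) else
    c("nucleus", "body", "tgn", "cargo")[seq_along(pages)]
  scale <- if (!is.null(meta)) meta$intensity_scale else 1
  ch <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]
    p * scale
  })
  names(ch) <- nm
  truth <- NULL
  if (!is.null(meta$labels)) {
    labs <- lapply(meta$labels, function(l) {
      m <- inverse.rle(list(lengths = unlist(l$lengths),
                            values = as.integer(unlist(l$values))))
      matrix(m, unlist(l$dim)[1], unlist(l$dim)[2])
    })
    cells <- as.data.frame(lapply(as.data.frame(
      do.call(rbind, lapply(meta$cells, as.data.frame))), unlist))
    truth <- c(labs, list(cells = cells))
  }
  px <- if (!is.null(meta)) meta$pixel_size else 1
  structure(list(channels = ch, pixel_size = px, truth = truth),
            class = "field_image")
}

#' Read a YAML run configuration
#'
#' Fills defaults for missing entries: channel role order, segmentation
#' parameters, QC thresholds (0.3 / 3 / 10), triage thresholds (3 / 2),
#' dose grid, profile-selection cutoff (0.75) and seed.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return named list of class `run_config`.
#' @export
read_run_config <- function(path = NULL) {
  defaults <- list(
    channels = c("nucleus", "body", "tgn", "cargo"),
    min_nucleus_area = 30, threshold_method = "otsu",
    zprime_min = 0.3, ssmd_min = 3, cv_max = 10,
    activity_sd = 3, toxicity_sd = 2,
    dose_grid = default_dose_grid(), pc1_cutoff = 0.75, seed = 1L)
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  out <- utils::modifyList(defaults, cfg)
  stopifnot(out$zprime_min <= 1, out$ssmd_min >= 0, out$cv_max > 0,
            out$activity_sd > 0, out$toxicity_sd > 0,
            out$pc1_cutoff > 0, out$pc1_cutoff <= 1)
  structure(out, class = c("run_config", "list"))
}

#' Write a JSON run manifest next to an output
#'
#' Records package version, seed, parameters and an md5 digest of the
#' serialized configuration, so a rerun with the same manifest reproduces
#' identical tables.
#'
#' @param config `run_config` (or any list of parameters).
#' @param path manifest path (JSON).
#' @param outputs optional character vector of produced files.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(config, path, outputs = character()) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(unclass(config)[order(names(config))], tmp)
  manifest <- list(
    package = "cargoscreen",
    version = as.character(utils::packageVersion("cargoscreen")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    config = unclass(config),
    config_md5 = unname(tools::md5sum(tmp)),
    outputs = outputs)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
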