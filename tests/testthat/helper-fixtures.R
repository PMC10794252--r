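# fixtures are generated in code and memoised for the session

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# a clean noiseless field reused across segmentation/measurement tests
default_field <- function() {
  cached("default_field", generate_field(field_spec(n_cells = 20, noise_sd = 0,
                                                    seed = 3)))
}

default_seg <- function() {
  cached("default_seg", segment_field(default_field()))
}

# simple two-cell scene built by hand: two disk bodies with nuclei, one TGN
# blob straddling the boundary between them
two_cell_scene <- function() {
  cached("two_cell_scene", {
    dimhw <- c(120, 120)
    body <- raster_disk_fix(dimhw, c(60, 40), 25) |
      raster_disk_fix(dimhw, c(60, 80), 25)
    nuc <- raster_disk_fix(dimhw, c(60, 40), 8) |
      raster_disk_fix(dimhw, c(60, 80), 8)
    tgn <- raster_disk_fix(dimhw, c(60, 60), 8)  # straddles both cells
    ch <- list(nucleus = nuc * 1, body = body * 0.6, tgn = tgn * 0.9,
               cargo = body * 0.2 + tgn * 0.4)
    ch
  })
}

raster_disk_fix <- function(dimhw, center, radius) {
  r <- matrix(seq_len(dimhw[1]), dimhw[1], dimhw[2])
  c <- matrix(seq_len(dimhw[2]), dimhw[1], dimhw[2], byrow = TRUE)
  (r - center[1])^2 + (c - center[2])^2 <= radius^2
}
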