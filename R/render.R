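## Rendering 2D multichannel images from thin in-silico slices.

#' Noise model parameters for slice rendering
#'
#' Per-cell brightness is drawn from a log-normal distribution
#' (`brightness_sdlog` on the log scale, median 1) to emulate cell-to-cell
#' staining variability; per-pixel additive Gaussian read noise has standard
#' deviation `gaussian_sd_frac` times the painted voxel intensity, and
#' images are clipped at 0. Set both to 0 for noise-free rendering.
#'
#' @param brightness_sdlog Log-sd of the per-cell brightness factor.
#' @param gaussian_sd_frac Additive pixel noise sd as a fraction of the
#'   painted intensity.
#' @return Named list of noise parameters.
#' @export
render_noise <- function(brightness_sdlog = 0.3, gaussian_sd_frac = 0.05) {
  list(brightness_sdlog = brightness_sdlog,
       gaussian_sd_frac = gaussian_sd_frac)
}

#' Render a multichannel image from an 8-voxel-thick slice
#'
#' Takes the 8 consecutive voxel planes starting at `z_start` (a 4 um
#' tissue slice at 0.5 um voxels). For each marker channel, intensity is
#' painted on the membrane voxels (membrane-localized markers) or nucleus
#' voxels (nuclear markers) of expressing cells inside the slab, multiplied
#' by a per-cell brightness factor, and summed along z; DAPI is painted on
#' all nuclei. There is no spillover between channels and no steric
#' hindrance. The exact ground truth (segmentation mask and cell centroids)
#' is taken from the middle plane of the slab.
#'
#' @param state A relaxed `potts_state`.
#' @param z_start First plane of the slab (1-based); `z_start + 7` must not
#'   exceed the lattice z extent.
#' @param noise See [render_noise()].
#' @param rng_seed Optional seed for brightness/noise draws; at zero noise
#'   the image is a deterministic function of `(state, z_start)`.
#' @param paint_intensity Intensity painted per expressing voxel.
#' @return A `sim_slice` object: list with `image` (H x W x 7 array,
#'   channels as in [panel_channels()], `image[y + 1, x + 1, ]` indexing),
#'   `truth_mask` (H x W integer cell-id label image from the mid-plane),
#'   `truth_centers` (data.frame `cell_id, x_px, y_px, phenotype`; 0-based
#'   pixel coordinates), `z_range`, and `pixel_size_um`.
#' @export
render_slice <- function(state, z_start = 1L, noise = render_noise(),
                         rng_seed = NULL, paint_intensity = 1) {
  stopifnot(inherits(state, "potts_state"))
  dims <- dim(state$lattice)
  z_start <- as.integer(z_start)
  if (z_start < 1L || z_start + 7L > dims[3])
    stop("slab [", z_start, ", ", z_start + 7L, "] exceeds lattice z extent ",
         dims[3])
  if (!is.null(rng_seed)) set.seed(rng_seed)

  zz <- z_start:(z_start + 7L)
  slab <- state$lattice[, , zz, drop = FALSE]
  cells <- cell_map(state)[, , zz, drop = FALSE]
  memb <- membrane_mask(state)[, , zz, drop = FALSE]
  nucl <- array(FALSE, dim = dim(slab))
  nz <- slab > 0L
  nucl[nz] <- state$spin_comp[slab[nz]] == 1L

  ct <- state$cell_table
  n_cells <- max(ct$cell_id)
  bright <- if (noise$brightness_sdlog > 0)
    rlnorm(n_cells, 0, noise$brightness_sdlog) else rep(1, n_cells)

  profiles <- phenotype_profiles()
  chans <- panel_channels()
  h <- dims[2]; w <- dims[1] # image rows = y, cols = x
  img <- array(0, dim = c(h, w, length(chans)),
               dimnames = list(NULL, NULL, chans))

  cellw <- array(0, dim = dim(slab))
  cellw[nz] <- bright[cells[nz]] * paint_intensity
  expressing <- function(marker, loc) {
    ids <- ct$cell_id[ct$alive & vapply(ct$phenotype, function(ph) {
      pr <- profiles[[ph]]
      marker %in% names(pr) && unname(pr[marker]) == loc
    }, logical(1))]
    ids
  }
  for (ci in seq_along(chans)) {
    ch <- chans[ci]
    if (ch == "DAPI") {
      wgt <- cellw * nucl
    } else {
      ids_m <- expressing(ch, "membrane")
      ids_n <- expressing(ch, "nuclear")
      sel <- (memb & array(cells %in% ids_m, dim = dim(cells))) |
             (nucl & array(cells %in% ids_n, dim = dim(cells)))
      wgt <- cellw * sel
    }
    plane <- rowSums(wgt, dims = 2) # integrate along z; dim (x, y)
    img[, , ci] <- t(plane)
  }
  if (noise$gaussian_sd_frac > 0) {
    img <- img + array(rnorm(length(img), 0,
                             noise$gaussian_sd_frac * paint_intensity),
                       dim = dim(img))
    img[img < 0] <- 0
  }

  mid <- t(cells[, , 5L]) # mid-plane of the 8-voxel slab
  labs <- sort(unique(mid[mid > 0L]))
  if (length(labs) > 0) {
    co <- which(mid > 0L, arr.ind = TRUE)
    ids <- mid[mid > 0L]
    cx <- tapply(co[, 2] - 1, ids, mean) # x = col, 0-based
    cy <- tapply(co[, 1] - 1, ids, mean)
    centers <- data.frame(
      cell_id = as.integer(names(cx)),
      x_px = as.numeric(cx), y_px = as.numeric(cy),
      phenotype = ct$phenotype[match(as.integer(names(cx)), ct$cell_id)],
      stringsAsFactors = FALSE)
  } else {
    centers <- data.frame(cell_id = integer(), x_px = numeric(),
                          y_px = numeric(), phenotype = character(),
                          stringsAsFactors = FALSE)
  }

  structure(list(image = img, truth_mask = mid, truth_centers = centers,
                 z_range = c(z_start, z_start + 7L),
                 pixel_size_um = PIXEL_SIZE_UM),
            class = "sim_slice")
}

#' Extract several slices from one volume
#'
#' Slices are spaced 8 um apart (a z-start stride of 16 planes), mirroring
#' serial sectioning of a block.
#'
#' @inheritParams render_slice
#' @param n_slices Maximum number of slices to cut (limited by the lattice).
#' @return List of `sim_slice` objects.
#' @export
render_slices <- function(state, n_slices = 2L, noise = render_noise(),
                          rng_seed = NULL, paint_intensity = 1) {
  nz <- dim(state$lattice)[3]
  starts <- seq(1L, nz - 7L, by = 16L)
  starts <- utils::head(starts, n_slices)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  lapply(starts, function(z0)
    render_slice(state, z0, noise = noise, rng_seed = NULL,
                 paint_intensity = paint_intensity))
}

#' Density sweep: simulate and render at several densities
#'
#' Runs one full simulate-render cycle per (fraction, repetition) and
#' reports the mid-plane cell density of each rendered slice, measured as
#' the number of distinct labels in the ground-truth mask divided by the
#' slice area in mm^2. At 100% density this calibrates to roughly
#' 30,000 cells/mm^2 and at 10% to roughly 3000 cells/mm^2.
#'
#' @param fractions Density fractions in (0, 1].
#' @param reps Repetitions (independent seeds) per fraction.
#' @param side_um Simulation volume side in um (64 is sufficient for
#'   density estimates and much faster than 128).
#' @param rng_seed Base seed; seed for (fraction i, rep j) is derived
#'   deterministically.
#' @param phenotype_freqs Passed to [seed_cells()].
#' @param noise Passed to [render_slice()].
#' @param keep_slices Return the rendered slices as well (memory permitting).
#' @return List with `table` (data.frame `fraction, rep, n_cells,
#'   density_cells_mm2`) and, if `keep_slices`, `slices` (list parallel to
#'   the table rows).
#' @export
density_sweep <- function(fractions, reps = 1L, side_um = 64,
                          rng_seed = 1L,
                          phenotype_freqs = default_phenotype_freqs(),
                          noise = render_noise(), keep_slices = TRUE) {
  if (any(fractions <= 0 | fractions > 1))
    stop("`fractions` must lie in (0, 1]")
  rows <- list(); slices <- list(); k <- 0L
  for (i in seq_along(fractions)) {
    for (j in seq_len(reps)) {
      k <- k + 1L
      seed <- (rng_seed + 7919L * (i - 1L) + 104729L * (j - 1L)) %% .Machine$integer.max
      st <- simulate_tissue(side_um, fractions[i], phenotype_freqs,
                            rng_seed = seed)
      zmid <- max(1L, dim(st$lattice)[3] %/% 2L - 4L)
      sl <- render_slice(st, zmid, noise = noise, rng_seed = seed + 1L)
      area_mm2 <- prod(dim(sl$truth_mask)) * (PIXEL_SIZE_UM / 1000)^2
      ncell <- length(unique(sl$truth_mask[sl$truth_mask > 0L]))
      rows[[k]] <- data.frame(fraction = fractions[i], rep = j,
                              n_cells = ncell,
                              density_cells_mm2 = ncell / area_mm2)
      if (keep_slices) slices[[k]] <- sl
    }
  }
  out <- list(table = do.call(rbind, rows))
  if (keep_slices) out$slices <- slices
  out
}

#' Perfect-segmentation phenotyping baseline
#'
#' Per-cell mean intensity of each channel over that cell's ground-truth
#' mask pixels. This plays the role of a segmentation-based phenotyper with
#' a *perfect* segmentation: its failure at high densities is due purely to
#' overlapping cells spilling signal into each other's footprints.
#'
#' @param slice A `sim_slice`.
#' @return data.frame with `cell_id`, `phenotype`, and one `mean_<channel>`
#'   column per panel channel. Empty mask gives an empty table.
#' @export
perfect_segmentation_phenotyping <- function(slice) {
  stopifnot(inherits(slice, "sim_slice"))
  mask <- slice$truth_mask
  sel <- mask > 0L
  chans <- panel_channels()
  if (!any(sel)) {
    out <- data.frame(cell_id = integer(), phenotype = character())
    for (ch in chans) out[[paste0("mean_", ch)]] <- numeric()
    return(out)
  }
  ids <- mask[sel]
  means <- vapply(seq_along(chans), function(ci) {
    v <- slice$image[, , ci][sel]
    as.numeric(tapply(v, ids, mean))
  }, numeric(length(unique(ids))))
  if (is.null(dim(means))) means <- matrix(means, nrow = 1)
  uid <- as.integer(names(tapply(ids, ids, length)))
  out <- data.frame(cell_id = uid,
                    phenotype = slice$truth_centers$phenotype[
                      match(uid, slice$truth_centers$cell_id)],
                    stringsAsFactors = FALSE)
  colnames(means) <- paste0("mean_", chans)
  cbind(out, as.data.frame(means))
}

#' Population separability of the perfect-mask expression table
#'
#' Fraction of ground-truth lymphocytes (B, T subsets, and memory T) that
#' are unambiguously single-positive in the CD3/CD20 mean-intensity plane:
#' exactly one of the two channels exceeds its fixed threshold. High values
#' mean the flow-cytometry-like scatterplot still shows separated
#' populations; the statistic degrades as overlapping cells mix signals at
#' high densities.
#'
#' @param expr_table Output of [perfect_segmentation_phenotyping()].
#' @param thresholds Named vector with fixed `CD3` and `CD20` thresholds on
#'   mean intensity.
#' @return Fraction in \[0, 1\] (NA if the table has no lymphocytes).
#' @export
population_separability <- function(expr_table,
                                    thresholds = c(CD3 = 0.5, CD20 = 0.5)) {
  lymph <- expr_table$phenotype %in% c(lymphocyte_phenotypes(), "Tmem")
  if (!any(lymph)) return(NA_real_)
  cd3 <- expr_table$mean_CD3[lymph] >= thresholds[["CD3"]]
  cd20 <- expr_table$mean_CD20[lymph] >= thresholds[["CD20"]]
  mean(xor(cd3, cd20))
}
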