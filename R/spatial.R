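## Spatial tumor-microenvironment analysis: tissue masks, invasive-margin
## densities, neighbor-preference matrices, compartment stratification.

#' Adaptive-threshold parameters for tissue segmentation
#'
#' A pixel is foreground when it exceeds its Gaussian-weighted local mean
#' (window of `block` px) by more than `offset`. Masks are then closed with
#' a disk of radius `close_radius` px and connected components smaller than
#' `min_area` px are removed. Tissue-specific values are expected to be
#' tuned per staining; these defaults suit the simulator's intensity scale.
#'
#' @param block Local-mean window size in px (odd).
#' @param offset Threshold offset above the local mean.
#' @param close_radius Morphological closing radius in px.
#' @param min_area Minimum connected-component area in px.
#' @return Named list of parameters.
#' @export
threshold_params <- function(block = 255, offset = 0.02, close_radius = 5,
                             min_area = 1e4) {
  list(block = block, offset = offset, close_radius = close_radius,
       min_area = min_area)
}

## Gaussian-weighted local mean with window ~ block px.
local_mean <- function(img, block) {
  EBImage::gblur(img, sigma = block / 6)
}

adaptive_mask <- function(img, p) {
  m <- img > local_mean(img, p$block) + p$offset
  m <- EBImage::closing(m, EBImage::makeBrush(2 * p$close_radius + 1, "disc"))
  ## large uniform regions threshold as rims; fill their interiors
  m <- EBImage::fillHull(m)
  lab <- EBImage::bwlabel(m)
  if (max(lab) > 0) {
    areas <- tabulate(lab[lab > 0])
    drop <- which(areas < p$min_area)
    m[lab %in% drop] <- FALSE
  }
  m > 0
}

#' Segment tumor and stroma tissue by adaptive thresholding
#'
#' The tumor mask is a locally adaptive threshold of the tumor-marker
#' channel; the general tissue mask is an adaptive threshold of the sum of
#' all stainings; stroma is tissue minus tumor. A signed Euclidean distance
#' map to the tumor boundary is returned (negative inside the tumor, 0 on
#' the boundary pixels).
#'
#' @param image `H x W x 7` array (normalized, see [normalize_tile()]).
#' @param tumor_channel Name or index of the tumor channel (default
#'   `"tumor"`).
#' @param tumor_params,tissue_params [threshold_params()] for the two
#'   thresholding passes.
#' @return A `tissue_masks` object: list with `tumor`, `stroma` (logical
#'   matrices), and `distance_to_border` (signed distance in um; NA
#'   everywhere if there is no tumor, with a warning).
#' @export
segment_tissue <- function(image, tumor_channel = "tumor",
                           tumor_params = threshold_params(),
                           tissue_params = threshold_params()) {
  chans <- dimnames(image)[[3]] %||% as.character(seq_len(dim(image)[3]))
  ti <- if (is.character(tumor_channel)) match(tumor_channel, chans)
        else tumor_channel
  if (is.na(ti)) stop("tumor channel not found")
  tumor <- adaptive_mask(image[, , ti], tumor_params)
  tissue <- adaptive_mask(rowSums(image, dims = 2), tissue_params)
  stroma <- tissue & !tumor

  if (!any(tumor)) {
    warning("no tumor pixels found; returning stroma-only masks")
    dist <- matrix(NA_real_, nrow(tumor), ncol(tumor))
  } else {
    dist <- signed_distance_to_border(tumor)
  }
  structure(list(tumor = tumor, stroma = stroma,
                 distance_to_border = dist), class = "tissue_masks")
}

#' Signed Euclidean distance to the tumor boundary
#'
#' The boundary is the set of tumor pixels with a 4-connected non-tumor
#' neighbor; the distance map is exactly 0 there, positive outside the
#' tumor and negative inside, in um.
#'
#' @param tumor_mask Logical matrix.
#' @return Numeric matrix of signed distances (um).
#' @export
signed_distance_to_border <- function(tumor_mask) {
  tm <- tumor_mask
  shift <- function(m, dr, dc) {
    out <- matrix(FALSE, nrow(m), ncol(m))
    r <- seq_len(nrow(m)); c <- seq_len(ncol(m))
    ok_r <- r + dr >= 1 & r + dr <= nrow(m)
    ok_c <- c + dc >= 1 & c + dc <= ncol(m)
    out[r[ok_r], c[ok_c]] <- m[r[ok_r] + dr, c[ok_c] + dc]
    out
  }
  border <- tm & (shift(!tm, 1, 0) | shift(!tm, -1, 0) |
                  shift(!tm, 0, 1) | shift(!tm, 0, -1))
  if (!any(border)) border <- tm # tumor fills the tile
  d <- EBImage::distmap(1 - border) # distance to nearest border pixel
  dist <- as.matrix(d) * PIXEL_SIZE_UM
  dist[tumor_mask] <- -dist[tumor_mask]
  dist
}

## Map detections to matrix indices; drops out-of-bounds points.
det_indices <- function(detections, shape) {
  p <- as_points(detections)
  r <- round(p$y) + 1L; c <- round(p$x) + 1L
  ok <- r >= 1 & r <= shape[1] & c >= 1 & c <= shape[2]
  list(idx = cbind(r[ok], c[ok]), phenotype = p$phenotype[ok])
}

#' Lymphocyte densities inside the tumor and in the invasive margin
#'
#' Counts detections per phenotype group (T = Th + CTL + Treg; B) inside
#' the tumor mask and in the invasive margin, defined as the stromal band
#' within `margin_um` of the tumor-stroma boundary, and divides by the
#' compartment areas.
#'
#' @param detections Detection table (`x_px`, `y_px`, `phenotype`).
#' @param masks A `tissue_masks` object.
#' @param margin_um Invasive-margin width on the stroma side (default
#'   100 um).
#' @return data.frame `group, compartment, n, area_mm2, density_mm2`;
#'   densities are NA (flagged by `defined = FALSE`) for zero-area
#'   compartments.
#' @export
compartment_densities <- function(detections, masks, margin_um = 100) {
  stopifnot(inherits(masks, "tissue_masks"))
  shape <- dim(masks$tumor)
  di <- det_indices(detections, shape)
  grp <- ifelse(di$phenotype %in% c("Th", "CTL", "Treg"), "T",
                ifelse(di$phenotype == "B", "B", NA))
  margin <- masks$stroma & !is.na(masks$distance_to_border) &
    masks$distance_to_border > 0 & masks$distance_to_border <= margin_um
  px_mm2 <- (PIXEL_SIZE_UM / 1000)^2
  comps <- list(tumor = masks$tumor, margin = margin)
  out <- do.call(rbind, lapply(c("T", "B"), function(g) {
    do.call(rbind, lapply(names(comps), function(cn) {
      sel <- !is.na(grp) & grp == g & comps[[cn]][di$idx]
      area <- sum(comps[[cn]]) * px_mm2
      data.frame(group = g, compartment = cn, n = sum(sel),
                 area_mm2 = area,
                 density_mm2 = if (area > 0) sum(sel) / area else NA_real_,
                 defined = area > 0)
    }))
  }))
  rownames(out) <- NULL
  out
}

## Neighbor counts: for each reference cell, number of neighbors of each
## type within radius (self excluded).
neighbor_count_matrix <- function(pts, radius_um) {
  n <- nrow(pts)
  d <- as.matrix(stats::dist(cbind(pts$x, pts$y))) * PIXEL_SIZE_UM
  within <- d <= radius_um & upper.tri(d, diag = FALSE)
  within <- within | t(within)
  types <- sort(unique(pts$phenotype))
  cnt <- sapply(types, function(tt)
    as.numeric(within %*% (pts$phenotype == tt)))
  if (is.null(dim(cnt))) cnt <- matrix(cnt, nrow = n)
  colnames(cnt) <- types
  cnt
}

#' Neighbor-preference matrix of lymphocyte phenotypes
#'
#' Neighbors are pairs of lymphocytes whose centers lie within `radius_um`
#' (self excluded). The preference of reference type A for neighbor type B
#' is the mean count of type-B neighbors per type-A cell divided by the
#' mean count of type-B neighbors per lymphocyte of any type; 1 means no
#' preference, >1 co-localization, <1 avoidance. Detections with
#' non-lymphocyte phenotypes (`other`, `invalid`) are excluded.
#'
#' @param detections Detection table (`x_px`, `y_px`, `phenotype`).
#' @param radius_um Neighborhood radius between cell centers (default
#'   14 um).
#' @return Square numeric matrix (reference type in rows, neighbor type in
#'   columns). Entries are NA where undefined (no reference cells of that
#'   type, or no neighbors of that type anywhere).
#' @export
neighbor_preference <- function(detections, radius_um = 14) {
  p <- as_points(detections)
  p <- p[p$phenotype %in% lymphocyte_phenotypes(), , drop = FALSE]
  if (nrow(p) < 2) stop("need at least 2 lymphocytes")
  cnt <- neighbor_count_matrix(p, radius_um)
  types <- colnames(cnt)
  overall <- colMeans(cnt) # mean type-B neighbors per lymphocyte
  pref <- matrix(NA_real_, length(types), length(types),
                 dimnames = list(reference = types, neighbor = types))
  for (a in types) {
    sel <- p$phenotype == a
    if (!any(sel)) next
    pref[a, ] <- ifelse(overall > 0, colMeans(cnt[sel, , drop = FALSE]) /
                          overall, NA_real_)
  }
  pref
}

#' Stratify a spatial metric by tissue compartment across slides
#'
#' Computes a per-slide metric separately for intratumoral and stromal
#' (peritumoral) reference cells and compares compartments with a Welch
#' two-sample t-test across slides. Also returns the frequency profile of
#' a phenotype against signed distance to the tumor border.
#'
#' @param slides List of slides; each a list with `detections` (table) and
#'   `masks` (`tissue_masks`).
#' @param metric Function `(detections, compartment_mask_value) -> scalar`;
#'   receives the slide's detections restricted to one compartment.
#'   Default: Treg fraction among lymphocytes.
#' @param profile_phenotype Phenotype for the distance profile (default
#'   `"Treg"`).
#' @param breaks_um Signed-distance bin edges for the profile (um;
#'   negative = inside tumor).
#' @return List with `per_slide` (data.frame slide, compartment, value),
#'   `p_value` (Welch t-test; NA with `test_skipped = TRUE` if fewer than
#'   2 slides per compartment or degenerate values), and `profile`
#'   (data.frame bin_lo, bin_hi, n_phenotype, n_lymphocytes, frequency).
#' @export
stratify_by_compartment <- function(slides, metric = NULL,
                                    profile_phenotype = "Treg",
                                    breaks_um = seq(-100, 100, by = 25)) {
  if (is.null(metric))
    metric <- function(det) {
      lym <- det$phenotype %in% lymphocyte_phenotypes()
      if (!any(lym)) return(NA_real_)
      mean(det$phenotype[lym] == profile_phenotype)
    }
  rows <- list(); k <- 0
  prof_n <- numeric(length(breaks_um) - 1)
  prof_tot <- numeric(length(breaks_um) - 1)
  for (si in seq_along(slides)) {
    sl <- slides[[si]]
    di <- det_indices(sl$detections, dim(sl$masks$tumor))
    dd <- sl$masks$distance_to_border[di$idx]
    in_tumor <- sl$masks$tumor[di$idx]
    for (comp in c("tumor", "stroma")) {
      sel <- if (comp == "tumor") in_tumor else !in_tumor
      det <- data.frame(phenotype = di$phenotype[sel])
      k <- k + 1
      rows[[k]] <- data.frame(slide = si, compartment = comp,
                              value = metric(det))
    }
    lym <- di$phenotype %in% lymphocyte_phenotypes() & !is.na(dd)
    b <- findInterval(dd[lym], breaks_um, rightmost.closed = TRUE)
    ok <- b >= 1 & b <= length(prof_n)
    prof_tot <- prof_tot + tabulate(b[ok], nbins = length(prof_n))
    isph <- di$phenotype[lym] == profile_phenotype
    prof_n <- prof_n + tabulate(b[ok & isph], nbins = length(prof_n))
  }
  per_slide <- do.call(rbind, rows)
  vt <- per_slide$value[per_slide$compartment == "tumor"]
  vs <- per_slide$value[per_slide$compartment == "stroma"]
  vt <- vt[!is.na(vt)]; vs <- vs[!is.na(vs)]
  skipped <- length(vt) < 2 || length(vs) < 2 ||
    (sd(vt) == 0 && sd(vs) == 0)
  p <- if (skipped) NA_real_ else t.test(vt, vs)$p.value
  profile <- data.frame(bin_lo = breaks_um[-length(breaks_um)],
                        bin_hi = breaks_um[-1],
                        n_phenotype = prof_n, n_lymphocytes = prof_tot,
                        frequency = ifelse(prof_tot > 0,
                                           prof_n / prof_tot, NA))
  list(per_slide = per_slide, p_value = p, test_skipped = skipped,
       profile = profile)
}
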