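## Predicted maps -> cell table: LoG blob detection, pseudomarker readout,
## phenotype calling, FCS export.

## Analytic Laplacian-of-Gaussian kernel, truncated at 4 sigma.
log_kernel <- function(sigma) {
  r <- ceiling(4 * sigma)
  xs <- -r:r
  d2 <- outer(xs^2, xs^2, "+")
  k <- (d2 - 2 * sigma^2) / (2 * pi * sigma^6) * exp(-d2 / (2 * sigma^2))
  k - mean(k) # zero-sum so constant regions give zero response
}

## Scale-normalized LoG response stack: response[, , i] = -s_i^2 * (LoG_s_i * map),
## positive at bright blobs.
log_response_stack <- function(map, sigmas) {
  stack <- array(0, dim = c(dim(map), length(sigmas)))
  for (i in seq_along(sigmas)) {
    k <- log_kernel(sigmas[i])
    stack[, , i] <- -sigmas[i]^2 *
      EBImage::filter2(map, k, boundary = "replicate")
  }
  stack
}

## Strict local maxima of a 3D stack over the 26-neighborhood.
local_maxima_3d <- function(stack, threshold) {
  d <- dim(stack)
  pad <- array(-Inf, d + 2L)
  pad[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- stack
  ge <- array(TRUE, d)
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    nb <- pad[(2 + dx):(d[1] + 1L + dx), (2 + dy):(d[2] + 1L + dy),
              (2 + dz):(d[3] + 1L + dz)]
    ge <- ge & (stack >= nb)
  }
  which(ge & stack > threshold, arr.ind = TRUE)
}

## Fraction of the smaller disk covered by the lens of two overlapping disks.
disk_overlap_frac <- function(d, r1, r2) {
  if (d >= r1 + r2) return(0)
  if (d <= abs(r1 - r2)) return(1)
  a1 <- r1^2 * acos((d^2 + r1^2 - r2^2) / (2 * d * r1))
  a2 <- r2^2 * acos((d^2 + r2^2 - r1^2) / (2 * d * r2))
  a3 <- 0.5 * sqrt((-d + r1 + r2) * (d + r1 - r2) * (d - r1 + r2) *
                   (d + r1 + r2))
  (a1 + a2 - a3) / (pi * min(r1, r2)^2)
}

#' Detect cell centers on a predicted proximity map
#'
#' Multiscale Laplacian-of-Gaussian (LoG) blob detection. Negative map
#' values (the -1/-2 sentinel codes are training conventions, not physical
#' proximities) are clipped to 0, the scale-normalized LoG response is
#' computed at `n_sigma` scales between `min_sigma` and `max_sigma`, and
#' blobs are the strict local maxima of the response over the 3D
#' (x, y, scale) neighborhood that exceed `threshold`. Overlapping blobs
#' (disk radius `sigma * sqrt(2)`, overlap fraction above `overlap`) are
#' pruned keeping the stronger response.
#'
#' @param proximity Numeric matrix (predicted proximity map).
#' @param min_sigma,max_sigma,threshold LoG parameters (defaults 3, 5,
#'   0.07).
#' @param n_sigma Number of scales (default 10).
#' @param overlap Maximum allowed overlap fraction before pruning.
#' @return data.frame with one row per detection: `x`, `y` (0-based pixel
#'   coordinates), `sigma`, `response`. Zero rows if nothing exceeds the
#'   threshold.
#' @export
detect_cells <- function(proximity, min_sigma = 3, max_sigma = 5,
                         threshold = 0.07, n_sigma = 10, overlap = 0.5) {
  stopifnot(is.matrix(proximity), all(is.finite(proximity)))
  map <- pmax(proximity, 0)
  sigmas <- seq(min_sigma, max_sigma, length.out = n_sigma)
  stack <- log_response_stack(map, sigmas)
  pk <- local_maxima_3d(stack, threshold)
  if (nrow(pk) == 0)
    return(data.frame(x = numeric(), y = numeric(), sigma = numeric(),
                      response = numeric()))
  blobs <- data.frame(x = pk[, 2] - 1, y = pk[, 1] - 1,
                      sigma = sigmas[pk[, 3]],
                      response = stack[pk])
  blobs <- blobs[order(-blobs$response), , drop = FALSE]
  keep <- rep(TRUE, nrow(blobs))
  r <- blobs$sigma * sqrt(2)
  for (i in seq_len(nrow(blobs))) {
    if (!keep[i]) next
    j <- which(keep & seq_len(nrow(blobs)) > i)
    if (!length(j)) next
    d <- sqrt((blobs$x[j] - blobs$x[i])^2 + (blobs$y[j] - blobs$y[i])^2)
    ov <- vapply(seq_along(j), function(k)
      disk_overlap_frac(d[k], r[i], r[j[k]]), numeric(1))
    keep[j[ov > overlap]] <- FALSE
  }
  blobs <- blobs[keep, , drop = FALSE]
  rownames(blobs) <- NULL
  blobs
}

## 13-pixel disk of radius 2 around the origin.
PSEUDOMARKER_DISK <- {
  g <- expand.grid(dx = -2:2, dy = -2:2)
  g[g$dx^2 + g$dy^2 <= 4, ]
}

#' Read out pseudomarker values around a detected center
#'
#' Per phenotype channel, the mean value within a radius of 2 px around
#' the center (a 13-pixel disk), clipped to \[0, 1\]. Near image borders
#' the disk is clipped to the map.
#'
#' @param pheno_maps Named list of phenotype-map matrices (or an
#'   `H x W x 5` array with channel dimnames), as predicted by the network.
#' @param x,y Center coordinates in px (0-based; rounded to the nearest
#'   pixel).
#' @return Named numeric vector `psi_<marker>` of length 5.
#' @export
extract_pseudomarkers <- function(pheno_maps, x, y) {
  if (is.array(pheno_maps) && length(dim(pheno_maps)) == 3) {
    nm <- dimnames(pheno_maps)[[3]] %||% phenotyping_markers()
    pheno_maps <- setNames(
      lapply(seq_len(dim(pheno_maps)[3]), function(i) pheno_maps[, , i]), nm)
  }
  h <- nrow(pheno_maps[[1]]); w <- ncol(pheno_maps[[1]])
  cx <- round(x); cy <- round(y)
  if (cx < 0 || cx > w - 1 || cy < 0 || cy > h - 1)
    stop("center (", x, ", ", y, ") out of map bounds")
  px <- PSEUDOMARKER_DISK$dx + cx
  py <- PSEUDOMARKER_DISK$dy + cy
  ok <- px >= 0 & px <= w - 1 & py >= 0 & py <= h - 1
  ii <- cbind(py[ok] + 1L, px[ok] + 1L)
  psi <- vapply(pheno_maps, function(m) mean(m[ii]), numeric(1))
  psi <- pmin(pmax(psi, 0), 1)
  names(psi) <- paste0("psi_", names(pheno_maps))
  psi
}

#' Call a phenotype from pseudomarker values
#'
#' Binarizes `psi_CD3`, `psi_CD8`, `psi_FOXP3` and `psi_CD20` at `cutoff`
#' (values exactly at the cutoff count as positive) and applies the marker
#' logic: B = CD20+CD3-CD8-FOXP3-, Th = CD3+CD8-FOXP3-CD20-,
#' CTL = CD3+CD8+FOXP3-CD20-, Treg = CD3+FOXP3+CD8-CD20-, other = all four
#' negative; any remaining combination is an invalid prediction. CD45RO is
#' never binarized: memory phenotype is evaluated on a continuum via
#' `psi_CD45RO`.
#'
#' @param psi Named numeric vector (`psi_CD3`, `psi_FOXP3`, `psi_CD20`,
#'   `psi_CD45RO`, `psi_CD8`) or a matrix/data.frame with those columns.
#' @param cutoff Positivity cutoff (default 0.4).
#' @return Character vector of phenotype calls.
#' @export
call_phenotype <- function(psi, cutoff = 0.4) {
  if (is.null(dim(psi))) psi <- t(as.matrix(psi))
  psi <- as.data.frame(psi)
  cd3 <- psi$psi_CD3 >= cutoff
  cd8 <- psi$psi_CD8 >= cutoff
  foxp3 <- psi$psi_FOXP3 >= cutoff
  cd20 <- psi$psi_CD20 >= cutoff
  out <- rep("invalid", nrow(psi))
  out[cd20 & !cd3 & !cd8 & !foxp3] <- "B"
  out[cd3 & !cd8 & !foxp3 & !cd20] <- "Th"
  out[cd3 & cd8 & !foxp3 & !cd20] <- "CTL"
  out[cd3 & foxp3 & !cd8 & !cd20] <- "Treg"
  out[!cd3 & !cd8 & !foxp3 & !cd20] <- "other"
  out
}

#' Full detection step: proximity map + phenotype maps -> cell table
#'
#' Runs [detect_cells()] on the proximity map, reads pseudomarkers at each
#' center, and calls phenotypes.
#'
#' @param maps Prediction maps as returned by [predict_tile()]: list with
#'   `proximity` (matrix) and `phenotype` (named list of matrices).
#' @param cutoff Positivity cutoff for [call_phenotype()].
#' @param ... Passed to [detect_cells()].
#' @return data.frame `x_px, y_px, x_um, y_um, psi_CD3, psi_FOXP3,
#'   psi_CD20, psi_CD45RO, psi_CD8, phenotype`.
#' @export
detect_and_phenotype <- function(maps, cutoff = 0.4, ...) {
  blobs <- detect_cells(maps$proximity, ...)
  psi <- t(vapply(seq_len(nrow(blobs)), function(i)
    extract_pseudomarkers(maps$phenotype, blobs$x[i], blobs$y[i]),
    numeric(length(maps$phenotype))))
  if (nrow(blobs) == 0)
    psi <- matrix(numeric(), 0, length(maps$phenotype),
                  dimnames = list(NULL, paste0("psi_", names(maps$phenotype))))
  out <- data.frame(x_px = blobs$x, y_px = blobs$y,
                    x_um = blobs$x * PIXEL_SIZE_UM,
                    y_um = blobs$y * PIXEL_SIZE_UM)
  out <- cbind(out, as.data.frame(psi))
  out$phenotype <- if (nrow(out)) call_phenotype(out, cutoff) else character(0)
  out
}

## ---- FCS 3.1 export -------------------------------------------------------

#' Export a detection table to an FCS file
#'
#' Writes a minimal FCS 3.1 file (list mode, 32-bit floats, little-endian)
#' with parameters `x`, `y` (in um) and the five pseudomarkers, so
#' detections can be explored in standard flow cytometry software.
#'
#' @param detections Nonempty data.frame from [detect_and_phenotype()] (or
#'   any table with `x_um`, `y_um` and `psi_*` columns).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_fcs()]
#' @export
export_fcs <- function(detections, path) {
  if (nrow(detections) == 0) stop("cannot export an empty detection table")
  cols <- c("x_um", "y_um", paste0("psi_", phenotyping_markers()))
  stopifnot(all(cols %in% colnames(detections)))
  dat <- as.matrix(detections[, cols])
  pnames <- c("x", "y", paste0("psi_", phenotyping_markers()))
  n_par <- ncol(dat); n_tot <- nrow(dat)

  kw <- c("$BEGINANALYSIS", "0", "$ENDANALYSIS", "0",
          "$BEGINSTEXT", "0", "$ENDSTEXT", "0",
          "$BEGINDATA", "%08d", "$ENDDATA", "%08d",
          "$BYTEORD", "1,2,3,4", "$DATATYPE", "F", "$MODE", "L",
          "$NEXTDATA", "0", "$PAR", as.character(n_par),
          "$TOT", as.character(n_tot))
  for (i in seq_len(n_par)) {
    rng <- max(1, ceiling(max(abs(dat[, i]), 1)))
    kw <- c(kw, sprintf("$P%dB", i), "32", sprintf("$P%dE", i), "0,0",
            sprintf("$P%dN", i), pnames[i], sprintf("$P%dR", i),
            as.character(rng))
  }
  ## fixed-width (8-digit) data offsets keep the TEXT segment length
  ## independent of the values substituted in
  text_tpl <- paste0("/", paste(kw, collapse = "/"), "/")
  text_begin <- 58L
  text_end <- text_begin + nchar(sprintf(text_tpl, 0L, 0L)) - 1L
  data_begin <- text_end + 1L
  data_end <- data_begin + 4L * n_par * n_tot - 1L
  text <- sprintf(text_tpl, data_begin, data_end)

  header <- sprintf("FCS3.1    %8d%8d%8d%8d%8d%8d", text_begin, text_end,
                    data_begin, data_end, 0L, 0L)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeChar(text, con, eos = NULL)
  writeBin(as.numeric(t(dat)), con, size = 4, endian = "little")
  invisible(path)
}

#' Read back an FCS file written by [export_fcs()]
#'
#' A small FCS 3.x reader sufficient to round-trip list-mode float data:
#' parses the TEXT segment and the float32 DATA segment.
#'
#' @param path FCS file path.
#' @return List with `data` (events x parameters matrix, parameter names
#'   as colnames) and `keywords` (named character vector).
#' @export
read_fcs <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readChar(con, 58, useBytes = TRUE)
  if (substr(header, 1, 3) != "FCS") stop("not an FCS file")
  offs <- as.integer(substring(header, 11 + 8 * (0:3), 18 + 8 * (0:3)))
  seek(con, offs[1])
  text <- readChar(con, offs[2] - offs[1] + 1, useBytes = TRUE)
  delim <- substr(text, 1, 1)
  parts <- strsplit(substring(text, 2), delim, fixed = TRUE)[[1]]
  keys <- parts[seq(1, length(parts), 2)]
  vals <- parts[seq(2, length(parts), 2)]
  kw <- setNames(vals, keys)
  n_par <- as.integer(kw[["$PAR"]])
  n_tot <- as.integer(kw[["$TOT"]])
  seek(con, as.integer(kw[["$BEGINDATA"]]))
  raw <- readBin(con, "numeric", n = n_par * n_tot, size = 4,
                 endian = "little")
  dat <- matrix(raw, nrow = n_tot, ncol = n_par, byrow = TRUE)
  colnames(dat) <- vapply(seq_len(n_par), function(i)
    kw[[sprintf("$P%dN", i)]], character(1))
  list(data = dat, keywords = kw)
}
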