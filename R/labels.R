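## Sparse click annotations -> dense training targets (proximity and
## phenotype maps) and patch sampling.

ANNOTATION_DISK_PX <- 5 # disk radius around an annotation (2.5 um)

#' Construct an annotation set
#'
#' An annotation is a single click on a cell center (`kind = "cell"`) or on
#' a site that contains no lymphocyte (`kind = "background"`: tumor cells,
#' stromal cells, look-alike structures, or no cell at all). Cell
#' annotations carry a "decoration": a 1-5 Likert score per phenotyping
#' marker encoding the annotator's certainty that the marker is expressed
#' (1 = certainly negative, 3 = undecided, 5 = certainly positive).
#'
#' @param x,y 0-based pixel coordinates (x = column, y = row).
#' @param kind Character vector, `"cell"` or `"background"`.
#' @param likert Data frame (or matrix) with one column per marker in
#'   [phenotyping_markers()] and one row per annotation; values 1-5.
#'   Ignored (may be NA) for background annotations.
#' @return A data.frame of class `annotation_set` with columns `x`, `y`,
#'   `kind`, and `likert_<marker>`.
#' @export
annotation_set <- function(x, y, kind, likert = NULL) {
  n <- length(x)
  stopifnot(length(y) == n, length(kind) == n,
            all(kind %in% c("cell", "background")))
  out <- data.frame(x = as.numeric(x), y = as.numeric(y), kind = kind,
                    stringsAsFactors = FALSE)
  mk <- phenotyping_markers()
  if (is.null(likert)) {
    for (m in mk) out[[paste0("likert_", m)]] <- NA_real_
  } else {
    likert <- as.data.frame(likert)
    if (!all(mk %in% colnames(likert)))
      stop("`likert` must have columns ", paste(mk, collapse = ", "))
    for (m in mk) out[[paste0("likert_", m)]] <- as.numeric(likert[[m]])
  }
  bad <- out$kind == "cell" &
    apply(is.na(out[paste0("likert_", mk)]), 1, any)
  if (any(bad))
    stop("cell annotations must carry Likert scores for all markers (rows ",
         paste(which(bad), collapse = ", "), ")")
  rng <- as.matrix(out[out$kind == "cell", paste0("likert_", mk)])
  if (length(rng) && (any(rng < 1) || any(rng > 5)))
    stop("Likert scores must lie in 1..5")
  class(out) <- c("annotation_set", "data.frame")
  out
}

check_bounds <- function(annotations, shape) {
  h <- shape[1]; w <- shape[2]
  bad <- which(annotations$x < 0 | annotations$x > w - 1 |
               annotations$y < 0 | annotations$y > h - 1)
  if (length(bad))
    stop("annotation(s) out of tile bounds: rows ",
         paste(bad, collapse = ", "))
}

## Squared distance of every pixel in a bounding box to (ax, ay); returns
## list(rows, cols, d) restricted to d <= r. Coordinates 0-based.
disk_pixels <- function(ax, ay, r, shape) {
  h <- shape[1]; w <- shape[2]
  x0 <- max(0, ceiling(ax - r)); x1 <- min(w - 1, floor(ax + r))
  y0 <- max(0, ceiling(ay - r)); y1 <- min(h - 1, floor(ay + r))
  if (x0 > x1 || y0 > y1)
    return(list(rows = integer(), cols = integer(), d = numeric()))
  xs <- x0:x1; ys <- y0:y1
  dx <- matrix(xs - ax, nrow = length(ys), ncol = length(xs), byrow = TRUE)
  dy <- matrix(ys - ay, nrow = length(ys), ncol = length(xs))
  d <- sqrt(dx^2 + dy^2)
  keep <- d <= r
  list(rows = (matrix(ys, length(ys), length(xs)))[keep] + 1L,
       cols = (matrix(xs, length(ys), length(xs), byrow = TRUE))[keep] + 1L,
       d = d[keep])
}

#' Build the proximity training map from point annotations
#'
#' The proximity map encodes closeness to the nearest annotated cell center
#' within a disk of radius 5 px (2.5 um) around each annotation: its value
#' is 5 at the annotation's coordinates and falls off linearly to 0 at the
#' disk boundary (`5 - d`, with `d` the distance in px to the nearest
#' annotated center). Background-annotation disks are coded -2, and all
#' pixels not covered by any disk (unknown status) are coded -1. Where a
#' cell disk and a background disk overlap, the cell disk wins.
#'
#' @param annotations An [annotation_set()].
#' @param shape Tile dims `c(height, width)` in px.
#' @return `height x width` numeric matrix with values in
#'   `{-2} U {-1} U [0, 5]`.
#' @export
build_proximity_map <- function(annotations, shape) {
  check_bounds(annotations, shape)
  prox <- matrix(-1, nrow = shape[1], ncol = shape[2])
  cells <- annotations[annotations$kind == "cell", , drop = FALSE]
  bg <- annotations[annotations$kind == "background", , drop = FALSE]
  for (i in seq_len(nrow(cells))) {
    px <- disk_pixels(cells$x[i], cells$y[i], ANNOTATION_DISK_PX, shape)
    ii <- cbind(px$rows, px$cols)
    prox[ii] <- pmax(prox[ii], 5 - px$d)
  }
  for (i in seq_len(nrow(bg))) {
    px <- disk_pixels(bg$x[i], bg$y[i], ANNOTATION_DISK_PX, shape)
    ii <- cbind(px$rows, px$cols)
    keep <- prox[ii] == -1 # cell disks take precedence
    prox[ii[keep, , drop = FALSE]] <- -2
  }
  prox
}

#' Build per-marker phenotype training maps
#'
#' Each phenotype map is initialized with 0 and, inside the disk around a
#' cell annotation, set to that annotation's Likert score mapped affinely
#' onto \[0, 1\] (`(likert - 1) / 4`, so 1 -> 0, 3 -> 0.5, 5 -> 1). Where
#' disks overlap, the nearest annotation wins. Background-annotation disks
#' stay 0.
#'
#' @inheritParams build_proximity_map
#' @param markers Markers to build maps for (default all five).
#' @return Named list of `height x width` matrices with values in \[0, 1\].
#' @export
build_phenotype_maps <- function(annotations, shape,
                                 markers = phenotyping_markers()) {
  check_bounds(annotations, shape)
  cells <- annotations[annotations$kind == "cell", , drop = FALSE]
  maps <- lapply(markers, function(m) matrix(0, shape[1], shape[2]))
  names(maps) <- markers
  best <- matrix(Inf, shape[1], shape[2]) # nearest-annotation distance
  for (i in seq_len(nrow(cells))) {
    px <- disk_pixels(cells$x[i], cells$y[i], ANNOTATION_DISK_PX, shape)
    ii <- cbind(px$rows, px$cols)
    win <- px$d < best[ii]
    iw <- ii[win, , drop = FALSE]
    best[iw] <- px$d[win]
    for (m in markers)
      maps[[m]][iw] <- (cells[[paste0("likert_", m)]][i] - 1) / 4
  }
  maps
}

#' Build all training label maps for a tile
#'
#' @inheritParams build_proximity_map
#' @return A `label_maps` object: list with `proximity` (matrix),
#'   `phenotype` (named list of matrices), and `known_mask` (logical
#'   matrix, TRUE where the proximity map is not -1).
#' @export
build_label_maps <- function(annotations, shape) {
  prox <- build_proximity_map(annotations, shape)
  structure(list(proximity = prox,
                 phenotype = build_phenotype_maps(annotations, shape),
                 known_mask = prox != -1),
            class = "label_maps")
}

## Reflect-pad a matrix by `p` pixels on every side (edge pixels are not
## duplicated, matching mirror boundary handling of the network input).
reflect_pad <- function(m, p) {
  n <- nrow(m); k <- ncol(m)
  ri <- c(rev(seq_len(p) + 1L), seq_len(n), n - seq_len(p))
  ci <- c(rev(seq_len(p) + 1L), seq_len(k), k - seq_len(p))
  m[ri, ci, drop = FALSE]
}

reflect_pad_stack <- function(a, p) {
  out <- array(0, dim = dim(a) + c(2 * p, 2 * p, 0))
  for (c in seq_len(dim(a)[3])) out[, , c] <- reflect_pad(a[, , c], p)
  dimnames(out)[[3]] <- dimnames(a)[[3]]
  out
}

#' Sample training patches from a labeled tile
#'
#' Candidate centers are the pixels of the proximity map with known status
#' (value not equal to -1); one-eighth of them are sampled uniformly
#' without replacement, with an upper bound of 1000 patches per tile. Each
#' patch pairs a 63 x 63 x 7 input window with the 3 x 3 x 6 label window
#' (proximity plus the five phenotype maps) around its center; windows near
#' tile borders are completed by mirror reflection. Since the annotation
#' disk has radius 5 px, one annotation is covered by many patches.
#'
#' @param image `H x W x 7` numeric array (normalized tile, see
#'   [normalize_tile()]).
#' @param maps A `label_maps` object matching the image dims.
#' @param rng_seed Integer seed; the same seed reproduces the same patches.
#' @param patch Input window size (odd; default 63).
#' @param label_patch Label window size (odd; default 3).
#' @param max_patches Upper bound per tile (default 1000).
#' @return List with `input` (`63 x 63 x 7 x n` array), `label`
#'   (`3 x 3 x 6 x n` array; channel 1 = proximity, channels 2-6 = the
#'   phenotype maps in panel order), and `centers` (data.frame `x`, `y`,
#'   0-based). `n = min(floor(K / 8), 1000)` for `K` candidates; `n = 0`
#'   with a warning if the tile has no known-status pixel.
#' @export
sample_patches <- function(image, maps, rng_seed = 1L, patch = 63L,
                           label_patch = 3L, max_patches = 1000L) {
  stopifnot(inherits(maps, "label_maps"),
            all(dim(image)[1:2] == dim(maps$proximity)))
  cand <- which(maps$known_mask)
  k <- length(cand)
  n <- min(k %/% 8L, max_patches)
  if (n == 0L) {
    warning("no known-status locations to sample from")
    return(list(input = array(0, c(patch, patch, dim(image)[3], 0)),
                label = array(0, c(label_patch, label_patch,
                                   1 + length(maps$phenotype), 0)),
                centers = data.frame(x = integer(), y = integer())))
  }
  set.seed(rng_seed)
  sel <- sample(cand, n)
  rc <- arrayInd(sel, dim(maps$proximity))

  hp <- (patch - 1L) %/% 2L
  hl <- (label_patch - 1L) %/% 2L
  pad_img <- reflect_pad_stack(image, hp)
  lab_stack <- array(0, dim = c(dim(maps$proximity), 1 + length(maps$phenotype)))
  lab_stack[, , 1] <- maps$proximity
  for (i in seq_along(maps$phenotype))
    lab_stack[, , 1 + i] <- maps$phenotype[[i]]
  pad_lab <- reflect_pad_stack(lab_stack, hl)

  input <- array(0, dim = c(patch, patch, dim(image)[3], n))
  label <- array(0, dim = c(label_patch, label_patch, dim(lab_stack)[3], n))
  for (i in seq_len(n)) {
    r <- rc[i, 1]; c <- rc[i, 2]
    input[, , , i] <- pad_img[r:(r + patch - 1L), c:(c + patch - 1L), ]
    label[, , , i] <- pad_lab[r:(r + label_patch - 1L),
                              c:(c + label_patch - 1L), ]
  }
  list(input = input, label = label,
       centers = data.frame(x = rc[, 2] - 1L, y = rc[, 1] - 1L))
}

#' Binarize Likert decorations for training-data curation
#'
#' For the markers where positivity is a clear-cut call (CD3, CD8, FOXP3,
#' CD20), Likert 1-2 maps to negative, 4-5 to positive, and the undecided
#' middle level 3 is discarded (returned as NA). CD45RO is deliberately
#' left on its ordinal scale elsewhere in the pipeline.
#'
#' @param likert Numeric vector of Likert scores 1..5.
#' @return Logical vector (TRUE = positive, NA = undecided).
#' @export
binarize_likert <- function(likert) {
  stopifnot(all(likert >= 1 & likert <= 5, na.rm = TRUE))
  out <- likert >= 4
  out[likert == 3] <- NA
  out
}
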