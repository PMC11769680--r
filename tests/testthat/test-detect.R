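## Ideal proximity cone: value max(0, 5 - d) around a center.
cone_map <- function(shape, centers) {
  m <- matrix(0, shape[1], shape[2])
  for (r in seq_len(shape[1])) for (c in seq_len(shape[2])) {
    d <- sqrt((c - 1 - centers[, 1])^2 + (r - 1 - centers[, 2])^2)
    m[r, c] <- max(0, 5 - min(d))
  }
  m
}

test_that("LoG calling finds ideal cones and nothing on a flat map", {
  expect_equal(nrow(detect_cells(matrix(0, 60, 60))), 0)

  m1 <- cone_map(c(80, 80), cbind(40, 25))
  d1 <- detect_cells(m1)
  expect_equal(nrow(d1), 1)
  expect_lt(sqrt((d1$x - 40)^2 + (d1$y - 25)^2), 1)

  m2 <- cone_map(c(80, 80), cbind(c(25, 45), c(40, 40)))
  d2 <- detect_cells(m2)
  expect_equal(nrow(d2), 2)
})

test_that("LoG maxima agree with an independent response scan", {
  centers <- cbind(c(20, 55, 70), c(30, 60, 20))
  m <- cone_map(c(90, 90), centers)
  det <- detect_cells(m)
  expect_equal(nrow(det), 3)
  for (i in seq_len(nrow(centers)))
    expect_lt(min(sqrt((det$x - centers[i, 1])^2 +
                       (det$y - centers[i, 2])^2)), 1)
  ## oracle: recompute the response stack by explicit kernel shifting and
  ## scan for maxima exhaustively
  sigmas <- seq(3, 5, length.out = 10)
  stack <- array(0, c(90, 90, 10))
  for (s in seq_along(sigmas))
    stack[, , s] <- oracle_log_response(m, sigmas[s])
  hits <- oracle_scan_maxima(stack, 0.07)
  ## cluster oracle hits to unique blob locations
  expect_gte(nrow(hits), 3)
  for (i in seq_len(nrow(centers))) {
    dd <- sqrt((hits[, "x"] - centers[i, 1])^2 +
               (hits[, "y"] - centers[i, 2])^2)
    expect_lt(min(dd), 1)
  }
  ## every oracle hit is near one of the detected blobs (no extra blobs
  ## beyond overlap pruning)
  for (k in seq_len(nrow(hits))) {
    dd <- sqrt((det$x - hits[k, "x"])^2 + (det$y - hits[k, "y"])^2)
    expect_lt(min(dd), 3)
  }
})

test_that("detections rotate with the map and stay in bounds", {
  m <- cone_map(c(70, 90), cbind(c(20, 60), c(30, 50)))
  d0 <- detect_cells(m)
  ## rotate the map 90 degrees counterclockwise: (x, y) -> (y, W - 1 - x)
  mr <- t(m)[ncol(m):1, ]
  dr <- detect_cells(mr)
  expect_equal(nrow(dr), nrow(d0))
  mapped <- data.frame(x = d0$y, y = ncol(m) - 1 - d0$x)
  for (i in seq_len(nrow(mapped)))
    expect_lt(min(sqrt((dr$x - mapped$x[i])^2 + (dr$y - mapped$y[i])^2)),
              1.01)
  expect_true(all(d0$x >= 0 & d0$x < ncol(m) & d0$y >= 0 & d0$y < nrow(m)))

  ## sentinel codes below zero do not create blobs
  m2 <- m; m2[m2 == 0] <- -1
  expect_equal(nrow(detect_cells(m2)), nrow(d0))
})

test_that("pseudomarker readout averages the 13-pixel disk", {
  mk <- function(v) matrix(v, 50, 50)
  maps <- setNames(lapply(c(0.3, 0, 1, 0.25, 0.8), mk),
                   phenotyping_markers())
  psi <- extract_pseudomarkers(maps, 25, 25)
  expect_equal(unname(psi), c(0.3, 0, 1, 0.25, 0.8))

  ## disk of ones with radius 5 fully covers the readout disk
  disk <- matrix(0, 50, 50)
  for (r in 1:50) for (c in 1:50)
    if ((r - 26)^2 + (c - 26)^2 <= 25) disk[r, c] <- 1
  maps$CD3 <- disk
  expect_equal(unname(extract_pseudomarkers(maps, 25, 25)["psi_CD3"]), 1)

  ## half-plane: expected value from explicit enumeration of the disk
  half <- matrix(0, 50, 50); half[, 1:26] <- 1 # x <= 25
  maps$CD3 <- half
  offs <- expand.grid(dx = -2:2, dy = -2:2)
  offs <- offs[offs$dx^2 + offs$dy^2 <= 4, ]
  expect_equal(nrow(offs), 13)
  expected <- mean(25 + offs$dx <= 25)
  expect_equal(unname(extract_pseudomarkers(maps, 25, 25)["psi_CD3"]),
               expected)
  expect_error(extract_pseudomarkers(maps, 60, 10), "out of map bounds")
})

test_that("phenotype calling follows the marker logic with cutoff 0.4", {
  psi <- function(cd3, foxp3, cd20, cd45ro, cd8)
    c(psi_CD3 = cd3, psi_FOXP3 = foxp3, psi_CD20 = cd20,
      psi_CD45RO = cd45ro, psi_CD8 = cd8)
  expect_equal(call_phenotype(psi(.9, .1, .05, .7, .8)), "CTL")
  expect_equal(call_phenotype(psi(0, 0, 0, 0, 0)), "other")
  expect_equal(call_phenotype(psi(.1, .1, .9, .3, .9)), "invalid")
  expect_equal(call_phenotype(psi(.9, .1, .1, .2, .1)), "Th")
  expect_equal(call_phenotype(psi(.9, .8, .1, .2, .1)), "Treg")
  expect_equal(call_phenotype(psi(.1, .1, .9, .2, .1)), "B")
  ## a tie at exactly the cutoff counts as positive
  expect_equal(call_phenotype(psi(.4, 0, 0, 0, 0)), "Th")
  ## vectorized over rows
  m <- rbind(psi(.9, 0, 0, 0, 0), psi(0, 0, .9, 0, 0))
  expect_equal(call_phenotype(m), c("Th", "B"))
})

test_that("FCS export round-trips detections through a standard reader", {
  set.seed(1)
  det <- data.frame(x_px = runif(10, 0, 100), y_px = runif(10, 0, 100))
  det$x_um <- det$x_px * 0.5; det$y_um <- det$y_px * 0.5
  for (m in phenotyping_markers()) det[[paste0("psi_", m)]] <- runif(10)
  f <- tempfile(fileext = ".fcs")
  export_fcs(det, f)
  back <- read_fcs(f)
  expect_equal(nrow(back$data), 10)
  expect_equal(unname(back$keywords["$TOT"]), "10")
  expect_equal(colnames(back$data),
               c("x", "y", paste0("psi_", phenotyping_markers())))
  expect_equal(back$data[, "psi_CD3"], det$psi_CD3, tolerance = 1e-4)
  expect_equal(back$data[, "x"], det$x_um, tolerance = 1e-4)
  ## header is well-formed FCS
  con <- file(f, "rb"); hdr <- readChar(con, 6); close(con)
  expect_equal(hdr, "FCS3.1")
  expect_error(export_fcs(det[0, ], tempfile()), "empty")
})
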