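test_that("proximity map carries the sentinel codes and linear ramp", {
  ann <- annotation_set(
    x = c(50, 50.5, 20), y = c(50, 60, 20),
    kind = c("cell", "cell", "background"),
    likert = data.frame(CD3 = c(5, 4, NA), FOXP3 = c(1, 1, NA),
                        CD20 = c(1, 2, NA), CD45RO = c(3, 3, NA),
                        CD8 = c(1, 1, NA)))
  prox <- build_proximity_map(ann, c(100, 100))
  expect_equal(prox[51, 51], 5)                 # value 5 at the click
  expect_equal(prox[51, 56], 0)                 # d = 5: disk boundary
  expect_equal(prox[51, 57], -1)                # d = 6: unknown status
  expect_equal(prox[49, 51], 3)                 # d = 2 on the linear ramp
  expect_equal(prox[61, 54], 2.5)               # d = 2.5 from (50.5, 60)
  expect_equal(prox[21, 21], -2)                # background disk
  expect_true(all(prox %in% -2:-1 | (prox >= 0 & prox <= 5)))
})

test_that("cell disks take precedence over overlapping background disks", {
  ann <- annotation_set(
    x = c(30, 36), y = c(30, 30), kind = c("cell", "background"),
    likert = data.frame(CD3 = c(5, NA), FOXP3 = c(1, NA), CD20 = c(1, NA),
                        CD45RO = c(1, NA), CD8 = c(1, NA)))
  prox <- build_proximity_map(ann, c(60, 60))
  ## pixel (31, 30): d = 1 from the cell, d = 5 from the background center
  expect_equal(prox[31, 32], 4)
  ## pixel inside only the background disk
  expect_equal(prox[31, 40], -2)
})

test_that("phenotype maps encode the affine Likert mapping", {
  lik <- data.frame(CD3 = 5, FOXP3 = 1, CD20 = 3, CD45RO = 2, CD8 = 4)
  ann <- annotation_set(40, 40, "cell", likert = lik)
  maps <- build_phenotype_maps(ann, c(80, 80))
  expect_equal(maps$CD3[41, 41], 1)     # likert 5 -> 1
  expect_equal(maps$FOXP3[41, 41], 0)   # likert 1 -> 0
  expect_equal(maps$CD20[41, 41], 0.5)  # likert 3 -> 0.5
  expect_equal(maps$CD45RO[41, 41], 0.25)
  expect_equal(maps$CD8[41, 41], 0.75)
  expect_equal(maps$CD3[41, 47], 0)     # outside every disk
  ## whole disk carries the annotation value
  expect_equal(maps$CD3[41, 44], 1)
})

test_that("overlapping phenotype disks resolve to the nearest annotation", {
  lik <- data.frame(CD3 = c(5, 1), FOXP3 = c(1, 1), CD20 = c(1, 5),
                    CD45RO = c(1, 1), CD8 = c(1, 1))
  ann <- annotation_set(c(30, 36), c(30, 30), c("cell", "cell"),
                        likert = lik)
  maps <- build_phenotype_maps(ann, c(60, 60))
  expect_equal(maps$CD3[31, 32], 1)  # closer to the CD3+ annotation
  expect_equal(maps$CD3[31, 36], 0)  # closer to the CD3- annotation
  expect_equal(maps$CD20[31, 36], 1)
})

test_that("annotation validation rejects bad input", {
  lik <- data.frame(CD3 = 5, FOXP3 = 1, CD20 = 1, CD45RO = 1, CD8 = 1)
  ann <- annotation_set(200, 10, "cell", likert = lik)
  expect_error(build_proximity_map(ann, c(100, 100)), "out of tile bounds")
  expect_error(
    annotation_set(10, 10, "cell",
                   likert = data.frame(CD3 = 6, FOXP3 = 1, CD20 = 1,
                                       CD45RO = 1, CD8 = 1)),
    "1..5")
  expect_error(annotation_set(10, 10, "cell"), "Likert")
})

test_that("patch sampler draws one eighth of known pixels, capped at 1000", {
  dummy_maps <- function(k, shape) {
    prox <- matrix(-1, shape[1], shape[2])
    prox[seq_len(k)] <- 0
    structure(list(proximity = prox,
                   phenotype = setNames(replicate(5, prox * 0,
                                                  simplify = FALSE),
                                        phenotyping_markers()),
                   known_mask = prox != -1), class = "label_maps")
  }
  img <- array(0, dim = c(200, 200, 7))
  big <- sample_patches(img, dummy_maps(16000, c(200, 200)), rng_seed = 1)
  expect_equal(dim(big$input), c(63, 63, 7, 1000))
  expect_equal(dim(big$label), c(3, 3, 6, 1000))
  small <- sample_patches(img, dummy_maps(80, c(200, 200)), rng_seed = 1)
  expect_equal(dim(small$input)[4], 10)
  expect_warning(
    none <- sample_patches(img, dummy_maps(0, c(200, 200)), rng_seed = 1),
    "no known-status")
  expect_equal(dim(none$input)[4], 0)
})

test_that("patch sampling is deterministic and covers annotations densely", {
  lik <- data.frame(CD3 = 5, FOXP3 = 1, CD20 = 1, CD45RO = 1, CD8 = 1)
  ann <- annotation_set(50, 50, "cell", likert = lik)
  maps <- build_label_maps(ann, c(100, 100))
  img <- array(rnorm(100 * 100 * 7), dim = c(100, 100, 7))
  p1 <- sample_patches(img, maps, rng_seed = 42)
  p2 <- sample_patches(img, maps, rng_seed = 42)
  expect_identical(p1$centers, p2$centers)
  expect_identical(p1$input, p2$input)
  ## every sampled center sits in the disk of the single annotation, so the
  ## label's center value is a known proximity (> 0 strictly inside)
  d <- sqrt((p1$centers$x - 50)^2 + (p1$centers$y - 50)^2)
  expect_true(all(d <= 5))
  inside <- d < 5
  expect_true(all(p1$label[2, 2, 1, inside] > 0))
})

test_that("proximity maxima recover well-separated annotation coordinates", {
  lik <- data.frame(CD3 = c(5, 5, 5), FOXP3 = 1, CD20 = 1, CD45RO = 1,
                    CD8 = 1)
  xs <- c(20, 60, 85); ys <- c(30, 70, 15)
  ann <- annotation_set(xs, ys, rep("cell", 3), likert = lik)
  prox <- build_proximity_map(ann, c(100, 100))
  top <- which(prox == 5, arr.ind = TRUE)
  expect_equal(nrow(top), 3)
  expect_setequal(paste(top[, 2] - 1, top[, 1] - 1),
                  paste(xs, ys))
})

test_that("map construction is order-independent for disjoint annotations", {
  lik <- data.frame(CD3 = c(5, 2), FOXP3 = c(1, 4), CD20 = c(1, 1),
                    CD45RO = c(3, 1), CD8 = c(1, 5))
  a12 <- annotation_set(c(20, 60), c(20, 60), c("cell", "cell"), lik)
  a21 <- annotation_set(c(60, 20), c(60, 20), c("cell", "cell"), lik[2:1, ])
  expect_equal(build_proximity_map(a12, c(80, 80)),
               build_proximity_map(a21, c(80, 80)))
  expect_equal(build_phenotype_maps(a12, c(80, 80)),
               build_phenotype_maps(a21, c(80, 80)))
})

test_that("likert binarization discards the undecided middle", {
  expect_identical(binarize_likert(c(1, 2, 3, 4, 5)),
                   c(FALSE, FALSE, NA, TRUE, TRUE))
})
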