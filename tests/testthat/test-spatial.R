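test_that("adaptive thresholding recovers a bright tumor region", {
  set.seed(1)
  h <- 260; w <- 260
  img <- array(0, c(h, w, 7), dimnames = list(NULL, NULL, panel_channels()))
  ## bright disk in the tumor channel on a dim background
  for (r in 1:h) for (c in 1:w)
    if ((r - 130)^2 + (c - 130)^2 <= 60^2) img[r, c, "tumor"] <- 1
  img[, , "tumor"] <- img[, , "tumor"] + matrix(rnorm(h * w, 0, 0.02), h, w)
  img[, , "DAPI"] <- 0.5 # tissue everywhere
  p <- threshold_params(block = 101, offset = 0.05, min_area = 100)
  masks <- segment_tissue(img, tumor_params = p, tissue_params = p)
  ## core of the disk is tumor
  core <- matrix(FALSE, h, w)
  for (r in 1:h) for (c in 1:w)
    if ((r - 130)^2 + (c - 130)^2 <= 40^2) core[r, c] <- TRUE
  expect_gt(mean(masks$tumor[core]), 0.95)
  expect_equal(sum(masks$tumor & masks$stroma), 0)
  expect_s3_class(masks, "tissue_masks")
})

test_that("signed distance is analytic for a straight tumor edge", {
  tumor <- matrix(FALSE, 100, 200)
  tumor[, 1:100] <- TRUE # tumor fills the left half
  d <- signed_distance_to_border(tumor)
  ## boundary column (last tumor column) is exactly 0
  expect_true(all(d[, 100] == 0))
  ## 20 um (40 px) outside the edge
  expect_equal(d[50, 140], 40 * 0.5, tolerance = 0.5)
  expect_gt(d[50, 140], 0)
  ## inside the tumor the distance is negative
  expect_equal(d[50, 60], -40 * 0.5, tolerance = 0.5)
})

test_that("compartment densities count per group and conserve across the border", {
  tumor <- matrix(FALSE, 200, 400)
  tumor[, 1:200] <- TRUE
  masks <- make_masks(tumor)
  ## margin = stroma within 100 um (200 px): columns 201..400 at 0.5 um/px
  ## here the whole right half is within 100 um of the border
  det <- data.frame(
    x_px = c(rep(250, 10), rep(100, 4), 260),
    y_px = c(seq(10, 190, length.out = 10), c(20, 60, 100, 140), 100),
    phenotype = c(rep("Th", 10), rep("CTL", 4), "B"))
  cd <- compartment_densities(det, masks, margin_um = 100)
  t_marg <- cd[cd$group == "T" & cd$compartment == "margin", ]
  t_tum <- cd[cd$group == "T" & cd$compartment == "tumor", ]
  b_marg <- cd[cd$group == "B" & cd$compartment == "margin", ]
  area_mm2 <- 200 * 200 * (0.5 / 1000)^2 # 0.01 mm^2 per half
  expect_equal(t_marg$n, 10)
  expect_equal(t_marg$density_mm2, 10 / area_mm2)
  expect_equal(t_tum$n, 4)
  expect_equal(b_marg$n, 1)
  ## moving one detection across the border shifts exactly one count
  det2 <- det
  det2$x_px[1] <- 150 # now inside the tumor
  cd2 <- compartment_densities(det2, masks, margin_um = 100)
  expect_equal(cd2[cd2$group == "T" & cd2$compartment == "margin", "n"], 9)
  expect_equal(cd2[cd2$group == "T" & cd2$compartment == "tumor", "n"], 5)
  expect_equal(sum(cd$n), sum(cd2$n))
})

test_that("neighbor preference is 1 for a single cell type and under label permutation", {
  set.seed(3)
  pts <- data.frame(x_px = runif(60, 0, 100), y_px = runif(60, 0, 100),
                    phenotype = "Th")
  pref <- neighbor_preference(pts)
  expect_equal(unname(pref["Th", "Th"]), 1)

  ## permutation null: fixed positions, shuffled labels -> matrix ~ 1
  pts$phenotype <- rep(c("B", "Th", "CTL"), each = 20)
  acc <- matrix(0, 3, 3); nshuf <- 200
  for (i in seq_len(nshuf)) {
    sh <- pts
    sh$phenotype <- sample(sh$phenotype)
    acc <- acc + neighbor_preference(sh)[c("B", "CTL", "Th"),
                                         c("B", "CTL", "Th")]
  }
  expect_lt(max(abs(acc / nshuf - 1)), 0.1)
  expect_error(neighbor_preference(pts[1, ]), "at least 2")
})

test_that("segregated clusters show homotypic preference > 1 and heterotypic < 1", {
  set.seed(5)
  a <- data.frame(x_px = runif(40, 0, 40), y_px = runif(40, 0, 40),
                  phenotype = "B")
  b <- data.frame(x_px = runif(40, 160, 200), y_px = runif(40, 160, 200),
                  phenotype = "Th")
  pref <- neighbor_preference(rbind(a, b))
  expect_gt(pref["B", "B"], 1)
  expect_gt(pref["Th", "Th"], 1)
  expect_lt(pref["B", "Th"], 1)
  expect_lt(pref["Th", "B"], 1)
})

test_that("compartment stratification runs a Welch test across slides", {
  set.seed(7)
  tumor <- matrix(FALSE, 100, 100); tumor[, 1:50] <- TRUE
  masks <- make_masks(tumor)
  mk_slide <- function(frac_tumor, frac_stroma, n = 60) {
    x <- c(runif(n / 2, 0, 49), runif(n / 2, 51, 99))
    inside <- x < 50
    ph <- character(n)
    ph[inside] <- ifelse(runif(sum(inside)) < frac_tumor, "Treg", "Th")
    ph[!inside] <- ifelse(runif(sum(!inside)) < frac_stroma, "Treg", "Th")
    list(detections = data.frame(x_px = x, y_px = runif(n, 0, 99),
                                 phenotype = ph), masks = masks)
  }
  slides <- lapply(1:8, function(i) mk_slide(0.55, 0.10))
  out <- stratify_by_compartment(slides)
  expect_false(out$test_skipped)
  expect_lt(out$p_value, 0.01)
  expect_equal(nrow(out$per_slide), 16)
  ## the distance profile partitions each lymphocyte exactly once
  n_lymph <- sum(vapply(slides, function(s) {
    di <- immunopoint:::det_indices(s$detections, dim(masks$tumor))
    dd <- masks$distance_to_border[di$idx]
    sum(di$phenotype %in% lymphocyte_phenotypes() &
        dd >= -100 & dd <= 100 & !is.na(dd))
  }, numeric(1)))
  expect_equal(sum(out$profile$n_lymphocytes), n_lymph)

  ## identical values in both compartments: test skipped, flagged
  same <- lapply(1:3, function(i) {
    det <- data.frame(x_px = c(25, 75), y_px = c(50, 50),
                      phenotype = c("Treg", "Treg"))
    list(detections = det, masks = masks)
  })
  out2 <- stratify_by_compartment(same)
  expect_true(out2$test_skipped)
  expect_true(is.na(out2$p_value))
})

test_that("densities are invariant to joint translation", {
  tumor <- matrix(FALSE, 200, 200)
  tumor[50:150, 50:150] <- TRUE
  det <- data.frame(x_px = c(60, 100, 180), y_px = c(60, 100, 20),
                    phenotype = c("Th", "B", "CTL"))
  cd1 <- compartment_densities(det, make_masks(tumor))
  shift <- 15
  tumor2 <- matrix(FALSE, 200, 200)
  tumor2[(50 + shift):(150 + shift), (50 + shift):(150 + shift)] <- TRUE
  det2 <- det; det2$x_px <- det2$x_px + shift; det2$y_px <- det2$y_px + shift
  cd2 <- compartment_densities(det2, make_masks(tumor2))
  expect_equal(cd1$n, cd2$n)
})
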