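test_that("nearest-detection distances are Euclidean in um", {
  ann <- data.frame(x = c(4, 0, 10), y = c(0, 0, 10))
  det <- data.frame(x_px = c(0, 10), y_px = c(0, 0))
  d <- nearest_detection_distance(ann, det)
  expect_equal(d[1], 2.0)  # 4 px * 0.5 um/px
  expect_equal(d[2], 0)
  expect_equal(nearest_detection_distance(ann, det[0, ]),
               rep(Inf, 3))
})

test_that("sparse error rates implement the 3.5 um same-phenotype rule", {
  ann <- data.frame(x = c(10, 40, 70), y = c(10, 10, 10),
                    phenotype = c("B", "Th", "other"))
  ## perfect detections: same spots, same phenotypes, nothing near "other"
  det <- data.frame(x_px = c(10, 40), y_px = c(10, 10),
                    phenotype = c("B", "Th"))
  r <- sparse_error_rates(ann, det)
  expect_equal(r$rate[r$category == "B"], 0)
  expect_equal(r$ci_lower[r$category == "B"], 0)
  expect_equal(r$rate[r$category == "background"], 0)
  ## a wrong-phenotype detection 1 um away is an error even if closest
  det2 <- data.frame(x_px = c(12), y_px = c(10), phenotype = "Th")
  r2 <- sparse_error_rates(ann[1, ], det2)
  expect_equal(r2$rate[r2$category == "B"], 1)
  ## a lymphocyte detected near a background annotation is a false positive
  det3 <- data.frame(x_px = 71, y_px = 10, phenotype = "B")
  r3 <- sparse_error_rates(ann[3, ], det3)
  expect_equal(r3$rate[r3$category == "background"], 1)
  ## zero-annotation categories are flagged undefined with CI [0, 1]
  expect_true(all(!r3$defined[r3$category %in% c("Th", "CTL", "Treg")]))
  expect_equal(r3$ci_lower[r3$category == "Th"], 0)
  expect_equal(r3$ci_upper[r3$category == "Th"], 1)
})

test_that("Clopper-Pearson intervals match the beta-quantile oracle", {
  ci <- clopper_pearson(1, 10)
  expect_equal(unname(ci["lower"]), qbeta(0.025, 1, 10))
  expect_equal(unname(ci["upper"]), qbeta(0.975, 2, 9))
  expect_equal(unname(clopper_pearson(0, 20)), c(0, 1 - 0.025^(1 / 20)))
  ## rate 1 error in 10 via sparse_error_rates
  ann <- data.frame(x = seq(0, 180, by = 20), y = rep(0, 10),
                    phenotype = rep("B", 10))
  det <- data.frame(x_px = ann$x[-1], y_px = ann$y[-1],
                    phenotype = rep("B", 9))
  r <- sparse_error_rates(ann, det)
  expect_equal(r$rate[r$category == "B"], 0.1)
  expect_equal(r$ci_lower[r$category == "B"], qbeta(0.025, 1, 10))
  expect_equal(r$ci_upper[r$category == "B"], qbeta(0.975, 2, 9))
})

test_that("ROI matching is one-to-one within the radius and maximal", {
  ann <- data.frame(x = 10, y = 10, phenotype = "B")
  det <- data.frame(x_px = 12, y_px = 10, phenotype = "B") # 1 um away
  m <- match_roi(ann, det)
  expect_equal(nrow(m$pairs), 1)
  expect_equal(m$pairs$dist_um, 1)
  expect_equal(m$counts$TP, 1)
  expect_equal(m$counts$FP, 0)
  expect_equal(m$counts$FN, 0)

  ## two annotations competing for one detection: cardinality 1, FN 1
  ann2 <- data.frame(x = c(10, 14), y = c(10, 10),
                     phenotype = c("B", "B"))
  m2 <- match_roi(ann2, det)
  expect_equal(nrow(m2$pairs), 1)
  expect_equal(m2$counts$FN, 1)

  ## beyond the radius nothing matches
  det3 <- data.frame(x_px = 30, y_px = 10, phenotype = "B")
  m3 <- match_roi(ann, det3)
  expect_equal(nrow(m3$pairs), 0)
  expect_equal(m3$counts$FP, 1)
  expect_equal(m3$counts$FN, 1)

  ## a matched pair with different phenotypes is both FP and FN
  det4 <- data.frame(x_px = 12, y_px = 10, phenotype = "Th")
  m4 <- match_roi(ann, det4)
  expect_equal(nrow(m4$pairs), 1)
  expect_equal(m4$counts$TP, c(0, 0))
  expect_equal(sum(m4$counts$FP), 1)
  expect_equal(sum(m4$counts$FN), 1)
})

test_that("matching cardinality equals brute-force enumeration and is order-invariant", {
  set.seed(42)
  for (i in 1:60) {
    inst <- random_instance(sample(0:8, 1), sample(0:8, 1))
    ann <- data.frame(x = inst$ax, y = inst$ay,
                      phenotype = sample(c("B", "Th"), length(inst$ax),
                                         replace = TRUE))
    det <- data.frame(x_px = inst$dx, y_px = inst$dy,
                      phenotype = sample(c("B", "Th"), length(inst$dx),
                                         replace = TRUE))
    m <- match_roi(ann, det, radius_um = 3.5)
    card <- oracle_max_matching(inst$ax, inst$ay, inst$dx, inst$dy,
                                3.5 / 0.5)
    expect_equal(nrow(m$pairs), card)
    ## per-phenotype count identities
    for (ph in unique(c(ann$phenotype, det$phenotype))) {
      row <- m$counts[m$counts$phenotype == ph, ]
      expect_equal(row$TP + row$FN, sum(ann$phenotype == ph))
      expect_equal(row$TP + row$FP, sum(det$phenotype == ph))
    }
    ## permutation invariance
    if (nrow(ann) > 1 && nrow(det) > 1) {
      mp <- match_roi(ann[sample(nrow(ann)), ], det[sample(nrow(det)), ],
                      radius_um = 3.5)
      expect_equal(mp$counts[order(mp$counts$phenotype), ],
                   m$counts[order(m$counts$phenotype), ],
                   ignore_attr = TRUE)
    }
  }
})

test_that("matching minimizes total distance among maximum matchings", {
  ## two annotations, two detections; the greedy pairing is suboptimal
  ann <- data.frame(x = c(0, 4), y = c(0, 0), phenotype = c("B", "B"))
  det <- data.frame(x_px = c(1, 5), y_px = c(0, 0),
                    phenotype = c("B", "B"))
  m <- match_roi(ann, det)
  expect_equal(nrow(m$pairs), 2)
  expect_equal(sum(m$pairs$dist_um), 1) # 0.5 + 0.5, not 2.5 + 0.5
})

test_that("pooled precision/recall/F and bootstrap behave as expected", {
  mk <- function(tp, fp, fn) {
    structure(list(pairs = NULL, unmatched_annotations = NULL,
                   unmatched_detections = NULL,
                   counts = data.frame(phenotype = "B", TP = tp, FP = fp,
                                       FN = fn)), class = "match_result")
  }
  p <- prf(list(mk(8, 2, 2)), n_boot = 50, rng_seed = 1)
  expect_equal(p$precision, 0.8)
  expect_equal(p$recall, 0.8)
  expect_equal(p$f_score, 0.8)
  ## a perfect detector
  pp <- prf(list(mk(5, 0, 0), mk(3, 0, 0)), n_boot = 50, rng_seed = 1)
  expect_equal(pp$f_score, 1)
  expect_equal(pp$f_score_lower, 1)
  ## undefined precision when nothing is detected
  p0 <- prf(list(mk(0, 0, 4)), n_boot = 10, rng_seed = 1)
  expect_true(is.na(p0$precision))

  ## CI width shrinks with more ROIs
  set.seed(9)
  rois_small <- lapply(1:10, function(i)
    mk(rpois(1, 20), rpois(1, 4), rpois(1, 4)))
  rois_big <- lapply(1:100, function(i)
    mk(rpois(1, 20), rpois(1, 4), rpois(1, 4)))
  ps <- prf(rois_small, n_boot = 200, rng_seed = 2)
  pb <- prf(rois_big, n_boot = 200, rng_seed = 2)
  expect_lt(pb$f_score_upper - pb$f_score_lower,
            ps$f_score_upper - ps$f_score_lower)
})

test_that("ICC and RMSE match ANOVA-based oracles on a toy table", {
  a <- c(12, 30, 44, 18, 7, 25)
  b <- c(14, 28, 40, 20, 9, 26)
  ag <- count_agreement(a, b, n_boot = 100, rng_seed = 1)
  ## one-way random effects, single measurement, via aov mean squares
  dat <- data.frame(y = c(a, b), roi = factor(rep(1:6, 2)))
  ms <- summary(aov(y ~ roi, dat))[[1]]$`Mean Sq`
  icc_oracle <- (ms[1] - ms[2]) / (ms[1] + ms[2])
  expect_equal(ag$icc, icc_oracle, tolerance = 1e-12)
  expect_equal(ag$rmse, sqrt(mean((a - b)^2)))

  ident <- count_agreement(a, a, n_boot = 10, rng_seed = 1)
  expect_equal(ident$icc, 1)
  expect_equal(ident$rmse, 0)
  shifted <- count_agreement(a, a + 3, n_boot = 10, rng_seed = 1)
  expect_equal(shifted$rmse, 3)
  expect_error(count_agreement(1, 2), "at least 2")
})

test_that("polyserial estimation matches a grid-search oracle and recovers rho", {
  set.seed(11)
  n <- 2000
  for (rho in c(0, 0.8)) {
    z1 <- rnorm(n); z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
    ord <- cut(z1, c(-Inf, -1, -0.3, 0.4, 1.2, Inf), labels = FALSE)
    est <- polyserial_cor(ord, z2)
    expect_lt(abs(est - rho), 0.05)
    ## grid oracle with an independently coded likelihood
    grid <- seq(-0.99, 0.99, by = 1e-3)
    ll <- vapply(grid, oracle_polyserial_loglik, numeric(1), ordinal = ord,
                 continuous = z2)
    expect_lt(abs(est - grid[which.max(ll)]), 1e-3 + 1e-9)
  }
  expect_error(polyserial_cor(rep(1, 50), rnorm(50)), "2 levels")
})

test_that("polychoric estimation recovers latent correlations", {
  set.seed(13)
  n <- 5000
  z1 <- rnorm(n); z2 <- 0.5 * z1 + sqrt(0.75) * rnorm(n)
  a <- as.integer(z1 > 0); b <- as.integer(z2 > 0.2)
  est <- polychoric_cor(a, b)
  expect_lt(abs(est - 0.5), 0.05)
  ## grid oracle agreement (coarser grid: pmvnorm is the slow part)
  grid <- seq(est - 0.01, est + 0.01, by = 1e-3)
  ll <- vapply(grid, oracle_polychoric_loglik, numeric(1), a = a, b = b)
  expect_lt(abs(est - grid[which.max(ll)]), 1e-3 + 1e-9)
  ## perfectly concordant binary table sits at the boundary
  expect_warning(hi <- polychoric_cor(c(0, 0, 1, 1), c(0, 0, 1, 1)),
                 "boundary")
  expect_gt(hi, 0.99)
})

test_that("latent-normal correlations approach Pearson with many levels", {
  set.seed(17)
  n <- 4000; rho <- 0.6
  z1 <- rnorm(n); z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
  lev <- cut(z1, qnorm(seq(0, 1, length.out = 51)), labels = FALSE,
             include.lowest = TRUE)
  expect_lt(abs(polyserial_cor(lev, z2) - cor(z1, z2)), 0.02)
})

test_that("density profiles partition the log-density range", {
  dp <- density_profiles(c(10, 100, 1000, 10000), rep(1, 4), n_bins = 4)
  expect_equal(dp$bin, 1:4)
  expect_equal(dp$edges, seq(1, 4, length.out = 5))

  same <- density_profiles(rep(50, 5), rep(1, 5), n_bins = 4)
  expect_true(all(same$bin == 1))

  ## hand-computed edges on a 6-ROI toy set with a zero-density ROI
  n <- c(0, 5, 20, 80, 320, 1280); a <- rep(0.1, 6)
  dp6 <- density_profiles(n, a, n_bins = 4)
  lo <- log10(50); hi <- log10(12800)
  expect_equal(dp6$edges, seq(lo, hi, length.out = 5))
  expect_equal(dp6$bin[1], 1L) # zero density floors into the lowest bin
  expect_equal(dp6$bin[6], 4L)
})

test_that("annotation phenotypes derive from binarized decorations", {
  lik <- data.frame(CD3 = c(5, 1, 5, 3), FOXP3 = c(1, 1, 4, 1),
                    CD20 = c(1, 5, 1, 1), CD45RO = c(3, 3, 3, 3),
                    CD8 = c(1, 1, 1, 1))
  ann <- annotation_set(c(1, 2, 3, 4), c(1, 1, 1, 1),
                        c("cell", "cell", "cell", "cell"), lik)
  ph <- annotation_phenotype(ann)
  expect_equal(ph[1:3], c("Th", "B", "Treg"))
  expect_true(is.na(ph[4])) # undecided CD3
})
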