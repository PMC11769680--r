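## Evaluation machinery: nearest-detection distances, sparse-annotation
## error rates, ROI maximum matching, P/R/F with bootstrap, ICC/RMSE,
## polyserial/polychoric correlation, density profiles.

## Normalize a table of points to 0-based px columns x, y (+ phenotype).
as_points <- function(d) {
  x <- if ("x_px" %in% colnames(d)) d$x_px else d$x
  y <- if ("y_px" %in% colnames(d)) d$y_px else d$y
  data.frame(x = as.numeric(x), y = as.numeric(y),
             phenotype = if ("phenotype" %in% colnames(d))
               as.character(d$phenotype) else rep(NA_character_, length(x)),
             stringsAsFactors = FALSE)
}

#' Distance from an annotation to the nearest detection
#'
#' @param annotations,detections Tables with `x`, `y` (or `x_px`, `y_px`)
#'   pixel coordinates.
#' @return Numeric vector (one per annotation) of Euclidean distances in
#'   um; `Inf` where there is no detection.
#' @export
nearest_detection_distance <- function(annotations, detections) {
  a <- as_points(annotations); d <- as_points(detections)
  if (nrow(d) == 0) return(rep(Inf, nrow(a)))
  vapply(seq_len(nrow(a)), function(i)
    min(sqrt((d$x - a$x[i])^2 + (d$y - a$y[i])^2)) * PIXEL_SIZE_UM,
    numeric(1))
}

#' Clopper-Pearson exact binomial confidence interval
#'
#' @param x Number of successes (errors).
#' @param n Number of trials.
#' @param conf Confidence level (default 0.95).
#' @return Numeric vector `c(lower, upper)`.
#' @export
clopper_pearson <- function(x, n, conf = 0.95) {
  a <- (1 - conf) / 2
  lo <- if (x == 0) 0 else qbeta(a, x, n - x + 1)
  hi <- if (x == n) 1 else qbeta(1 - a, x + 1, n - x)
  c(lower = lo, upper = hi)
}

#' Error rates for sparse annotations
#'
#' Mirrors the sparse validation protocol: an annotated B or T cell counts
#' as an error unless the nearest detected *lymphocyte* lies within
#' `radius_um` and carries the same phenotype; a background/other
#' annotation counts as an error (false positive) if any detected
#' lymphocyte lies within `radius_um`. Rates are reported per annotation
#' category with exact (Clopper-Pearson) binomial confidence intervals.
#'
#' @param annotations Table with `x`, `y` (px) and either `phenotype`
#'   (`"B"`, `"Th"`, `"CTL"`, `"Treg"`, anything else = background/other)
#'   or `kind == "background"`.
#' @param detections Detection table with `x_px`, `y_px`, `phenotype`.
#' @param radius_um Detection radius (default 3.5 um = 7 px).
#' @param conf Confidence level for the intervals.
#' @return data.frame `category, n, errors, rate, ci_lower, ci_upper,
#'   defined`; categories with zero annotations have `rate = NA`, CI
#'   `[0, 1]`, and `defined = FALSE`.
#' @export
sparse_error_rates <- function(annotations, detections, radius_um = 3.5,
                               conf = 0.95) {
  a <- as_points(annotations)
  if ("kind" %in% colnames(annotations))
    a$phenotype[annotations$kind == "background"] <- "background"
  a$category <- ifelse(a$phenotype %in% lymphocyte_phenotypes(),
                       a$phenotype, "background")
  d <- as_points(detections)
  d <- d[d$phenotype %in% lymphocyte_phenotypes(), , drop = FALSE]

  err <- logical(nrow(a))
  for (i in seq_len(nrow(a))) {
    if (nrow(d) == 0) {
      err[i] <- a$category[i] != "background"
      next
    }
    dist <- sqrt((d$x - a$x[i])^2 + (d$y - a$y[i])^2) * PIXEL_SIZE_UM
    within <- dist <= radius_um
    if (a$category[i] == "background") {
      err[i] <- any(within)
    } else {
      err[i] <- !any(within) ||
        d$phenotype[which(within)[which.min(dist[within])]] != a$category[i]
    }
  }
  cats <- c(lymphocyte_phenotypes(), "background")
  out <- do.call(rbind, lapply(cats, function(cc) {
    sel <- a$category == cc
    n <- sum(sel); x <- sum(err[sel])
    if (n == 0)
      return(data.frame(category = cc, n = 0L, errors = 0L, rate = NA_real_,
                        ci_lower = 0, ci_upper = 1, defined = FALSE))
    ci <- clopper_pearson(x, n, conf)
    data.frame(category = cc, n = n, errors = x, rate = x / n,
               ci_lower = ci[["lower"]], ci_upper = ci[["upper"]],
               defined = TRUE)
  }))
  rownames(out) <- NULL
  out
}

## ---- maximum matching -----------------------------------------------------

## Hungarian algorithm (Jacobi/Kuhn-Munkres with potentials, O(n^3)).
## cost: n x m matrix, n <= m. Returns assignment: for each row, the
## assigned column index.
hungarian <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n <= m)
  u <- numeric(n + 1); v <- numeric(m + 1)
  p <- integer(m + 1); way <- integer(m + 1) # 0 = none; offset index +1
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, m); used <- rep(FALSE, m + 1)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      free <- which(!used[-1L]) # candidate columns 1..m
      cur <- cost[i0, free] - u[i0 + 1L] - v[free + 1L]
      upd <- cur < minv[free]
      minv[free[upd]] <- cur[upd]
      way[free[upd] + 1L] <- j0
      j1 <- free[which.min(minv[free])]
      delta <- minv[j1]
      usedj <- which(used) - 1L # columns (incl. 0) in the tree
      u[p[usedj + 1L] + 1L] <- u[p[usedj + 1L] + 1L] + delta
      v[usedj + 1L] <- v[usedj + 1L] - delta
      minv[setdiff(seq_len(m), usedj)] <-
        minv[setdiff(seq_len(m), usedj)] - delta
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assign <- integer(n)
  for (j in seq_len(m)) if (p[j + 1L] > 0L) assign[p[j + 1L]] <- j
  assign
}

#' Match annotations to detections within an ROI
#'
#' Maximum-cardinality bipartite matching between annotations and
#' detections under the distance cutoff, breaking ties among maximum
#' matchings by minimizing the total matched distance (solved as a
#' min-cost assignment with a large penalty for infeasible pairs). A
#' matched pair with equal phenotype is a true positive (TP); a detection
#' that is unmatched or matched to a different phenotype is a false
#' positive (FP); an annotation that is unmatched or matched to a
#' different phenotype is a false negative (FN).
#'
#' @param annotations Table with `x`, `y` (px, 0-based) and `phenotype`.
#' @param detections Table with `x_px`, `y_px` (or `x`, `y`) and
#'   `phenotype`.
#' @param radius_um Distance cutoff (default 3.5 um).
#' @return A `match_result` object: list with `pairs` (data.frame
#'   `annotation, detection, dist_um, a_phenotype, d_phenotype`),
#'   `unmatched_annotations`, `unmatched_detections` (index vectors), and
#'   `counts` (data.frame `phenotype, TP, FP, FN`, one row per phenotype
#'   present).
#' @export
match_roi <- function(annotations, detections, radius_um = 3.5) {
  a <- as_points(annotations); d <- as_points(detections)
  na <- nrow(a); nd <- nrow(d)
  if (na == 0 && nd == 0) {
    pairs <- data.frame(annotation = integer(), detection = integer(),
                        dist_um = numeric(), a_phenotype = character(),
                        d_phenotype = character())
    return(structure(list(pairs = pairs, unmatched_annotations = integer(),
                          unmatched_detections = integer(),
                          counts = match_counts(pairs, a, d)),
                     class = "match_result"))
  }
  BIG <- 1e9
  if (na > 0 && nd > 0) {
    dist <- outer(a$x, d$x, "-")^2 + outer(a$y, d$y, "-")^2
    dist <- sqrt(dist) * PIXEL_SIZE_UM
    cost <- ifelse(dist <= radius_um, dist, BIG)
    n <- max(na, nd)
    sq <- matrix(BIG, n, n) # padding: dummy pairs cost BIG, never preferred
    sq[seq_len(na), seq_len(nd)] <- cost
    assign <- hungarian(sq)
    ai <- seq_len(na)
    di <- assign[seq_len(na)]
    ok <- di <= nd & sq[cbind(ai, di)] < BIG
    pairs <- data.frame(annotation = ai[ok], detection = di[ok],
                        dist_um = dist[cbind(ai[ok], di[ok])],
                        a_phenotype = a$phenotype[ai[ok]],
                        d_phenotype = d$phenotype[di[ok]],
                        stringsAsFactors = FALSE)
  } else {
    pairs <- data.frame(annotation = integer(), detection = integer(),
                        dist_um = numeric(), a_phenotype = character(),
                        d_phenotype = character(), stringsAsFactors = FALSE)
  }
  structure(list(
    pairs = pairs,
    unmatched_annotations = setdiff(seq_len(na), pairs$annotation),
    unmatched_detections = setdiff(seq_len(nd), pairs$detection),
    counts = match_counts(pairs, a, d)), class = "match_result")
}

match_counts <- function(pairs, a, d) {
  phens <- sort(unique(c(a$phenotype, d$phenotype)))
  phens <- phens[!is.na(phens)]
  do.call(rbind, lapply(phens, function(ph) {
    tp <- sum(pairs$a_phenotype == ph & pairs$d_phenotype == ph)
    n_ann <- sum(a$phenotype == ph, na.rm = TRUE)
    n_det <- sum(d$phenotype == ph, na.rm = TRUE)
    data.frame(phenotype = ph, TP = tp, FP = n_det - tp, FN = n_ann - tp,
               stringsAsFactors = FALSE)
  }))
}

#' Precision, recall and F-score over ROIs with bootstrap CIs
#'
#' Point estimates come from TP/FP/FN counts pooled across all ROIs
#' (`P = TP/(TP+FP)`, `R = TP/(TP+FN)`, `F = 2PR/(P+R)`); confidence
#' intervals from a percentile bootstrap that resamples ROIs with
#' replacement.
#'
#' @param matches List of `match_result` objects (one per ROI), see
#'   [match_roi()].
#' @param n_boot Bootstrap replicates (default 1000).
#' @param conf Confidence level.
#' @param rng_seed Seed for the bootstrap.
#' @return data.frame per phenotype: pooled counts, `precision`, `recall`,
#'   `f_score`, and bootstrap CI columns. Undefined ratios (e.g. TP+FP = 0)
#'   are reported as NA.
#' @export
prf <- function(matches, n_boot = 1000L, conf = 0.95, rng_seed = 1L) {
  stopifnot(length(matches) >= 1)
  counts <- lapply(matches, `[[`, "counts")
  pool <- function(idx) {
    all <- do.call(rbind, counts[idx])
    agg <- stats::aggregate(all[c("TP", "FP", "FN")],
                            by = list(phenotype = all$phenotype), sum)
    p <- ifelse(agg$TP + agg$FP > 0, agg$TP / (agg$TP + agg$FP), NA)
    r <- ifelse(agg$TP + agg$FN > 0, agg$TP / (agg$TP + agg$FN), NA)
    f <- ifelse(!is.na(p) & !is.na(r) & p + r > 0, 2 * p * r / (p + r), NA)
    data.frame(agg, precision = p, recall = r, f_score = f)
  }
  pt <- pool(seq_along(matches))
  set.seed(rng_seed)
  boot <- replicate(n_boot, {
    b <- pool(sample(seq_along(matches), replace = TRUE))
    m <- sapply(c("precision", "recall", "f_score"), function(mm)
      b[[mm]][match(pt$phenotype, b$phenotype)])
    if (is.null(dim(m)))
      m <- matrix(m, nrow = 1, dimnames = list(NULL, names(m)))
    m
  }, simplify = "array") # phen x metric x boot
  a <- (1 - conf) / 2
  for (mm in c("precision", "recall", "f_score")) {
    q <- apply(boot[, mm, , drop = FALSE], 1, quantile,
               probs = c(a, 1 - a), na.rm = TRUE)
    pt[[paste0(mm, "_lower")]] <- q[1, ]
    pt[[paste0(mm, "_upper")]] <- q[2, ]
  }
  pt
}

#' Agreement between two per-ROI count series: ICC and RMSE
#'
#' Intraclass correlation coefficient (one-way random effects, single
#' measurement; ranges from -1 for perfect disagreement to 1 for perfect
#' agreement) and root-mean-square error between paired counts, with
#' percentile bootstrap confidence intervals over ROIs.
#'
#' @param counts_a,counts_b Numeric vectors of per-ROI counts (same
#'   length, >= 2 ROIs).
#' @param n_boot Bootstrap replicates.
#' @param conf Confidence level.
#' @param rng_seed Seed for the bootstrap.
#' @return List with `icc`, `icc_ci`, `rmse`, `rmse_ci`.
#' @export
count_agreement <- function(counts_a, counts_b, n_boot = 1000L, conf = 0.95,
                            rng_seed = 1L) {
  stopifnot(length(counts_a) == length(counts_b))
  n <- length(counts_a)
  if (n < 2) stop("need at least 2 ROIs")
  icc1 <- function(a, b) {
    x <- cbind(a, b); k <- 2
    rm <- rowMeans(x); gm <- mean(x)
    msb <- k * sum((rm - gm)^2) / (length(a) - 1)
    msw <- sum((x - rm)^2) / (length(a) * (k - 1))
    (msb - msw) / (msb + (k - 1) * msw)
  }
  rmse <- function(a, b) sqrt(mean((a - b)^2))
  set.seed(rng_seed)
  bi <- replicate(n_boot, {
    s <- sample(n, replace = TRUE)
    c(icc1(counts_a[s], counts_b[s]), rmse(counts_a[s], counts_b[s]))
  })
  a <- (1 - conf) / 2
  list(icc = icc1(counts_a, counts_b),
       icc_ci = unname(quantile(bi[1, ], c(a, 1 - a), na.rm = TRUE)),
       rmse = rmse(counts_a, counts_b),
       rmse_ci = unname(quantile(bi[2, ], c(a, 1 - a), na.rm = TRUE)))
}

## ---- latent-normal correlations ------------------------------------------

ordinal_thresholds <- function(f) {
  ## f: factor/integer vector; returns interior thresholds on the latent
  ## normal scale from the cumulative marginal proportions
  tab <- table(f)
  if (length(tab) < 2) stop("ordinal variable has fewer than 2 levels")
  qnorm(cumsum(tab / sum(tab)))[-length(tab)]
}

#' Polyserial correlation (two-step estimator)
#'
#' Correlation between a latent standard-normal variable underlying an
#' ordinal rating (e.g. a Likert decoration) and an observed continuous
#' variable (e.g. a pseudomarker), assuming latent bivariate normality.
#' Two-step: thresholds are fixed at the normal quantiles of the ordinal
#' margin's cumulative proportions, then the likelihood of the conditional
#' ordinal response given the standardized continuous value is maximized
#' over the correlation.
#'
#' @param ordinal Integer/factor vector (>= 2 observed levels, n >= 10).
#' @param continuous Numeric vector, same length.
#' @return Estimated correlation in (-1, 1).
#' @export
polyserial_cor <- function(ordinal, continuous) {
  stopifnot(length(ordinal) == length(continuous))
  ok <- complete.cases(ordinal, continuous)
  ordinal <- ordinal[ok]; continuous <- continuous[ok]
  if (length(ordinal) < 10) stop("need n >= 10")
  f <- factor(ordinal)
  tau <- ordinal_thresholds(f)
  z <- as.numeric(scale(continuous))
  lev <- as.integer(f)
  lo <- c(-Inf, tau)[lev]
  hi <- c(tau, Inf)[lev]
  nll <- function(rho) {
    s <- sqrt(1 - rho^2)
    p <- pnorm((hi - rho * z) / s) - pnorm((lo - rho * z) / s)
    -sum(log(pmax(p, 1e-300)))
  }
  optimize(nll, c(-0.999, 0.999))$minimum
}

#' Polychoric correlation (two-step estimator)
#'
#' Latent bivariate-normal correlation between two ordinal variables. Both
#' threshold sets are fixed from the marginals; the multinomial likelihood
#' of the contingency table, with cell probabilities given by
#' bivariate-normal rectangle probabilities, is maximized over the
#' correlation. For a 2x2 table this is the tetrachoric correlation.
#'
#' @param ordinal_a,ordinal_b Integer/factor vectors (each >= 2 observed
#'   levels).
#' @return Estimated correlation in (-1, 1); a warning is issued at a
#'   boundary estimate (|rho| > 0.99), which arises when the table has
#'   empty discordant cells.
#' @export
polychoric_cor <- function(ordinal_a, ordinal_b) {
  ok <- complete.cases(ordinal_a, ordinal_b)
  fa <- factor(ordinal_a[ok]); fb <- factor(ordinal_b[ok])
  ta <- ordinal_thresholds(fa); tb <- ordinal_thresholds(fb)
  tab <- table(fa, fb)
  ca <- c(-Inf, ta, Inf); cb <- c(-Inf, tb, Inf)
  nll <- function(rho) {
    S <- matrix(c(1, rho, rho, 1), 2)
    ll <- 0
    for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
      if (tab[i, j] == 0) next
      p <- mvtnorm::pmvnorm(lower = c(ca[i], cb[j]),
                            upper = c(ca[i + 1], cb[j + 1]), corr = S)
      ll <- ll + tab[i, j] * log(max(as.numeric(p), 1e-300))
    }
    -ll
  }
  est <- optimize(nll, c(-0.999, 0.999))$minimum
  if (abs(est) > 0.99)
    warning("polychoric estimate at boundary (", round(est, 3),
            "); table likely has empty discordant cells")
  est
}

#' Bin ROIs into density profiles
#'
#' Computes the annotated lymphocyte density of each ROI (cells/mm^2) and
#' partitions the log10 density range into `n_bins` equal-width bins.
#' Zero-density ROIs are assigned the lowest bin (with a pseudo-density
#' floor of one tenth of the smallest positive density for binning).
#'
#' @param n_lymphocytes Annotated lymphocyte count per ROI.
#' @param area_mm2 ROI area in mm^2.
#' @param n_bins Number of bins (default 4).
#' @return List with `density` (cells/mm^2), `bin` (integer 1..n_bins),
#'   and `edges` (log10-density bin edges, length `n_bins + 1`).
#' @export
density_profiles <- function(n_lymphocytes, area_mm2, n_bins = 4L) {
  stopifnot(length(n_lymphocytes) == length(area_mm2), all(area_mm2 > 0))
  dens <- n_lymphocytes / area_mm2
  pos <- dens[dens > 0]
  if (!length(pos)) stop("all ROIs have zero density")
  floor_d <- min(pos) / 10
  ld <- log10(pmax(dens, floor_d))
  lp <- log10(pos)
  if (diff(range(lp)) == 0) {
    edges <- c(min(lp) - 0.5, max(lp) + 0.5)
    bin <- rep(1L, length(dens))
    return(list(density = dens, bin = bin, edges = edges))
  }
  edges <- seq(min(lp), max(lp), length.out = n_bins + 1)
  bin <- findInterval(ld, edges, rightmost.closed = TRUE, all.inside = TRUE)
  list(density = dens, bin = as.integer(bin), edges = edges)
}

#' Derive the annotated phenotype from Likert decorations
#'
#' Binarizes the CD3/CD8/FOXP3/CD20 decorations ([binarize_likert()]) and
#' applies the same marker logic as [call_phenotype()]. Annotations with
#' any undecided (Likert 3) decisive marker give NA.
#'
#' @param annotations An [annotation_set()].
#' @return Character vector of phenotypes (`B`, `Th`, `CTL`, `Treg`,
#'   `other`, `invalid`, or NA); background annotations give `"background"`.
#' @export
annotation_phenotype <- function(annotations) {
  out <- rep(NA_character_, nrow(annotations))
  out[annotations$kind == "background"] <- "background"
  cells <- which(annotations$kind == "cell")
  if (!length(cells)) return(out)
  b <- lapply(c("CD3", "CD8", "FOXP3", "CD20"), function(m)
    binarize_likert(annotations[[paste0("likert_", m)]][cells]))
  names(b) <- c("CD3", "CD8", "FOXP3", "CD20")
  undec <- Reduce(`|`, lapply(b, is.na))
  psi <- data.frame(psi_CD3 = as.numeric(b$CD3),
                    psi_CD8 = as.numeric(b$CD8),
                    psi_FOXP3 = as.numeric(b$FOXP3),
                    psi_CD20 = as.numeric(b$CD20))
  psi[is.na(psi)] <- 0
  ph <- call_phenotype(psi, cutoff = 0.5)
  ph[undec] <- NA_character_
  out[cells] <- ph
  out
}
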