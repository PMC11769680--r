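## Independent oracles used across tests. These deliberately re-derive
## quantities with different code paths than the package implementation.

## Scale-normalized LoG response by explicit kernel shifting (no package
## filtering code): response(x, y) = -sigma^2 * sum_k K(k) map(x+kx, y+ky),
## replicate boundary.
oracle_log_response <- function(map, sigma) {
  r <- ceiling(4 * sigma)
  xs <- -r:r
  d2 <- outer(xs^2, xs^2, "+")
  K <- (d2 - 2 * sigma^2) / (2 * pi * sigma^6) * exp(-d2 / (2 * sigma^2))
  K <- K - mean(K)
  h <- nrow(map); w <- ncol(map)
  out <- matrix(0, h, w)
  for (i in seq_along(xs)) {
    ri <- pmin(pmax(seq_len(h) + xs[i], 1), h)
    for (j in seq_along(xs)) {
      cj <- pmin(pmax(seq_len(w) + xs[j], 1), w)
      out <- out + K[i, j] * map[ri, cj]
    }
  }
  -sigma^2 * out
}

## Exhaustive scan for local maxima of a 3D response stack above a
## threshold (26-neighborhood, plain loops).
oracle_scan_maxima <- function(stack, threshold) {
  d <- dim(stack)
  hits <- NULL
  for (s in seq_len(d[3])) for (r in seq_len(d[1])) for (c in seq_len(d[2])) {
    v <- stack[r, c, s]
    if (v <= threshold) next
    ok <- TRUE
    for (ds in -1:1) for (dr in -1:1) for (dc in -1:1) {
      if (ds == 0 && dr == 0 && dc == 0) next
      rr <- r + dr; cc <- c + dc; ss <- s + ds
      if (rr < 1 || rr > d[1] || cc < 1 || cc > d[2] ||
          ss < 1 || ss > d[3]) next
      if (stack[rr, cc, ss] > v) ok <- FALSE
    }
    if (ok) hits <- rbind(hits, c(x = c - 1, y = r - 1, s = s))
  }
  hits
}

## Brute-force maximum-cardinality matching under a distance cutoff, by
## recursive enumeration over annotations. Returns the max cardinality.
oracle_max_matching <- function(ax, ay, dx, dy, radius) {
  na <- length(ax); nd <- length(dx)
  if (na == 0 || nd == 0) return(0L)
  feas <- outer(ax, dx, "-")^2 + outer(ay, dy, "-")^2 <= radius^2
  best <- 0L
  rec <- function(i, used) {
    if (i > na) return(0L)
    most <- rec(i + 1L, used) # skip annotation i
    for (j in which(feas[i, ] & !used)) {
      used[j] <- TRUE
      most <- max(most, 1L + rec(i + 1L, used))
      used[j] <- FALSE
    }
    most
  }
  rec(1L, rep(FALSE, nd))
}

## Independent polyserial log-likelihood (full, including the marginal
## density of the continuous variable) for a grid search oracle.
oracle_polyserial_loglik <- function(rho, ordinal, continuous) {
  f <- factor(ordinal)
  tab <- table(f)
  tau <- qnorm(cumsum(as.numeric(tab)) / sum(tab))[-length(tab)]
  z <- (continuous - mean(continuous)) / sd(continuous)
  lev <- as.integer(f)
  lo <- c(-Inf, tau)[lev]; hi <- c(tau, Inf)[lev]
  s <- sqrt(1 - rho^2)
  sum(dnorm(z, log = TRUE)) +
    sum(log(pmax(pnorm((hi - rho * z) / s) - pnorm((lo - rho * z) / s),
                 1e-300)))
}

## Independent polychoric log-likelihood using mvtnorm rectangle
## probabilities computed cell by cell from scratch.
oracle_polychoric_loglik <- function(rho, a, b) {
  fa <- factor(a); fb <- factor(b)
  ta <- qnorm(cumsum(table(fa)) / length(a))
  tb <- qnorm(cumsum(table(fb)) / length(b))
  ca <- c(-Inf, ta[-length(ta)], Inf)
  cb <- c(-Inf, tb[-length(tb)], Inf)
  tab <- table(fa, fb)
  ll <- 0
  S <- matrix(c(1, rho, rho, 1), 2)
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
    if (tab[i, j] == 0) next
    p <- mvtnorm::pmvnorm(lower = c(ca[i], cb[j]),
                          upper = c(ca[i + 1], cb[j + 1]), corr = S)
    ll <- ll + tab[i, j] * log(max(as.numeric(p), 1e-300))
  }
  ll
}

## Build a minimal hand-made tissue_masks object for spatial tests.
make_masks <- function(tumor, stroma = NULL) {
  if (is.null(stroma)) stroma <- !tumor
  structure(list(tumor = tumor, stroma = stroma,
                 distance_to_border = signed_distance_to_border(tumor)),
            class = "tissue_masks")
}

## Random small matching instance generator.
random_instance <- function(n_ann, n_det, extent = 20) {
  list(ax = runif(n_ann, 0, extent), ay = runif(n_ann, 0, extent),
       dx = runif(n_det, 0, extent), dy = runif(n_det, 0, extent))
}
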