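# Independent oracles used to cross-check the package implementations.
# Each is written from the definition, with plain loops, and shares no
# code path with the functions it checks.

## O(n^2) minimum-image pair-distance histogram (counts only)
brute_force_rdf_counts <- function(frame, idx_a, idx_b, bin_width, r_max) {
  n_bins <- floor(r_max / bin_width + 1e-9)
  counts <- numeric(n_bins)
  b <- frame$beads
  for (i in idx_a) {
    for (j in idx_b) {
      if (i == j) next
      d <- 0
      for (k in c("x", "y", "z")) {
        dk <- b[[k]][i] - b[[k]][j]
        L <- frame$box[match(k, c("x", "y", "z"))]
        dk <- dk - L * round(dk / L)
        d <- d + dk^2
      }
      d <- sqrt(d)
      if (d < r_max) {
        bin <- min(n_bins, floor(d / bin_width) + 1)
        counts[bin] <- counts[bin] + 1
      }
    }
  }
  counts
}

## eccentricity from a direct inertia-tensor eigen-decomposition,
## element by element
direct_eccentricity <- function(pos) {
  cm <- colMeans(pos)
  xx <- yy <- zz <- xy <- xz <- yz <- 0
  for (i in seq_len(nrow(pos))) {
    p <- pos[i, ] - cm
    xx <- xx + p[2]^2 + p[3]^2
    yy <- yy + p[1]^2 + p[3]^2
    zz <- zz + p[1]^2 + p[2]^2
    xy <- xy - p[1] * p[2]
    xz <- xz - p[1] * p[3]
    yz <- yz - p[2] * p[3]
  }
  I <- matrix(c(xx, xy, xz, xy, yy, yz, xz, yz, zz), 3, 3)
  ev <- eigen(I, symmetric = TRUE, only.values = TRUE)$values
  1 - min(ev) / mean(ev)
}

## all-pairs distance filter for the elastic network
brute_force_pair_filter <- function(pos, r_min, r_max) {
  hits <- 0
  n <- nrow(pos)
  if (n < 2) return(0)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      d <- sqrt(sum((pos[i, ] - pos[j, ])^2))
      if (d >= r_min && d <= r_max) hits <- hits + 1
    }
  }
  hits
}

## random-walk Metropolis sampler of the biased umbrella density,
## independent of the inverse-CDF generator
metropolis_umbrella <- function(pmf, center, k_bias, n, seed,
                                step = 0.1, burn = 2000) {
  kT <- 0.008314462618 * pmf$temperature
  logp <- function(z) {
    if (z < pmf$z_lo || z > pmf$z_hi) return(-Inf)
    -(pmf$fn(z) * 4.184 + 0.5 * k_bias * (z - center)^2) / kT
  }
  set.seed(seed)
  z <- center
  lp <- logp(z)
  out <- numeric(n)
  for (i in seq_len(n + burn)) {
    zp <- z + rnorm(1, 0, step)
    lpp <- logp(zp)
    if (log(runif(1)) < lpp - lp) {
      z <- zp; lp <- lpp
    }
    if (i > burn) out[i - burn] <- z
  }
  out
}

## binless MBAR estimator: per-sample reweighting with the window
## normalisations obtained by minimising the convex MBAR likelihood
## (BFGS with analytic gradient); the reference reconstruction the
## histogram WHAM is compared against
mbar_profile <- function(windows, bin_width) {
  kT <- 0.008314462618 * windows[[1]]$temperature
  x <- unlist(lapply(windows, `[[`, "samples"))
  N_k <- vapply(windows, function(w) length(w$samples), numeric(1))
  centers <- vapply(windows, `[[`, numeric(1), "center")
  kb <- vapply(windows, `[[`, numeric(1), "k_bias")
  K <- length(windows)
  ## K x N biased Boltzmann factors
  C <- exp(-0.5 * outer(kb, rep(1, length(x))) *
             (outer(rep(1, K), x) - outer(centers, rep(1, length(x))))^2 /
             kT)
  obj <- function(f) {
    d <- as.vector(crossprod(C, N_k * exp(f)))
    sum(log(d)) - sum(N_k * f)
  }
  grad <- function(f) {
    d <- as.vector(crossprod(C, N_k * exp(f)))
    as.vector(C %*% (1 / d)) * N_k * exp(f) - N_k
  }
  fit <- stats::optim(rep(0, K), obj, grad, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-15))
  f <- exp(fit$par)
  w <- 1 / as.vector(crossprod(C, N_k * f))     # unbiased sample weights
  lo <- floor(min(x) / bin_width) * bin_width
  hi <- ceiling(max(x) / bin_width) * bin_width
  edges <- seq(lo, hi, by = bin_width)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  bin <- pmin(length(mids), pmax(1, floor((x - lo) / bin_width) + 1))
  wsum <- vapply(seq_along(mids),
                 function(m) sum(w[bin == m]), numeric(1))
  G <- ifelse(wsum > 0, -kT / 4.184 * log(wsum / bin_width), NA_real_)
  data.frame(z = mids, G = G)
}

## zero a profile on the mean over its largest-z `width` nm of
## occupied bins (mirrors the package's reference convention)
zero_on_reference <- function(z, G, width = 0.5) {
  occ <- !is.na(G)
  ref <- occ & z >= max(z[occ]) - width
  G - mean(G[ref])
}
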