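# Independent brute-force oracles, pure vectorized R. These re-derive the
# pairwise statistics from their definitions, sharing no code with the
# package's C++ kernels.

oracle_neighbor_counts <- function(x, y, radius) {
  d <- as.matrix(dist(cbind(x, y)))
  diag(d) <- Inf
  as.integer(rowSums(d <= radius))
}

# Goreaud-Pelissier isotropic correction weight, independent derivation.
oracle_iso_weight <- function(x, y, r, ox, oy, w, h) {
  d1 <- pmin(x - ox, ox + w - x)
  d2 <- pmin(y - oy, oy + h - y)
  a <- numeric(length(r))
  c1 <- d1 < r; c2 <- d2 < r
  both <- c1 & c2
  corner <- both & (d1^2 + d2^2 < r^2)
  a[c1 & !c2] <- 2 * acos(d1[c1 & !c2] / r[c1 & !c2])
  a[c2 & !c1] <- 2 * acos(d2[c2 & !c1] / r[c2 & !c1])
  a[both & !corner] <- 2 * acos(d1[both & !corner] / r[both & !corner]) +
    2 * acos(d2[both & !corner] / r[both & !corner])
  a[corner] <- pi / 2 + acos(d1[corner] / r[corner]) +
    acos(d2[corner] / r[corner])
  2 * pi / (2 * pi - a)
}

oracle_ripley_sums <- function(x, y, r_grid, ox, oy, w, h,
                               correction = "isotropic") {
  n <- length(x)
  d <- as.matrix(dist(cbind(x, y)))
  i <- rep(seq_len(n), n); j <- rep(seq_len(n), each = n)
  keep <- i != j
  i <- i[keep]; j <- j[keep]; dij <- d[cbind(i, j)]
  wt <- switch(correction,
               none = rep(1, length(dij)),
               isotropic = oracle_iso_weight(x[i], y[i], dij, ox, oy, w, h),
               translation = (w * h) / ((w - abs(x[i] - x[j])) *
                                          (h - abs(y[i] - y[j]))))
  vapply(r_grid, function(r) sum(wt[dij <= r]), numeric(1))
}

oracle_cross_counts <- function(xa, ya, xb, yb, breaks) {
  d <- sqrt(outer(xa, xb, "-")^2 + outer(ya, yb, "-")^2)
  counts <- hist(d[d >= breaks[1] & d < breaks[length(breaks)]],
                 breaks = breaks, plot = FALSE, right = FALSE)$counts
  as.integer(counts)
}

oracle_contacts <- function(a, b, cutoff, box) {
  count <- 0L
  for (i in seq_len(nrow(a))) {
    dv <- sweep(b, 2, a[i, ])
    for (k in 1:3) dv[, k] <- dv[, k] - box[k] * round(dv[, k] / box[k])
    count <- count + sum(rowSums(dv^2) <= cutoff^2)
  }
  count
}

# Analytic argmax of H(r) for the Thomas process (kappa in nm^-2).
thomas_h_argmax <- function(kappa_nm2, sigma_nm, upper = 500) {
  h <- function(r) sqrt(thomas_k_theoretical(r, kappa_nm2, sigma_nm) / pi) - r
  optimize(h, c(1, upper), maximum = TRUE)$maximum
}

# Toroidal cross-correlation oracle by direct pair counting: on a torus the
# expected independent pair count per annulus is exactly na*nb*area/A.
oracle_cross_correlation_torus <- function(xa, ya, xb, yb, breaks, w, h) {
  dx <- abs(outer(xa, xb, "-")); dx <- pmin(dx, w - dx)
  dy <- abs(outer(ya, yb, "-")); dy <- pmin(dy, h - dy)
  d <- sqrt(dx^2 + dy^2)
  obs <- hist(d[d >= breaks[1] & d < breaks[length(breaks)]],
              breaks = breaks, plot = FALSE, right = FALSE)$counts
  expected <- length(xa) * length(xb) *
    pi * diff(breaks^2) / (w * h)
  obs / expected
}
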