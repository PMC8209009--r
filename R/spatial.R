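#' Neighbor-density analysis of localizations
#'
#' For every localization, counts the other localizations within
#' `radius` nm (self excluded), the statistic behind SMLM density maps and
#' the frequency-of-occurrence density plots used to read cluster
#' densification. The conventional radius for this readout is 100 nm.
#'
#' @param points A [localization_table()].
#' @param window An [analysis_window()] containing the points.
#' @param radius Neighbor radius in nm (positive; default 100).
#' @return An object of class `density_result`: list with `neighbor_radius`,
#'   `per_point_counts` and `histogram` (data.frame of count value and
#'   frequency).
#' @export
neighbor_density <- function(points, window, radius = 100) {
  stopifnot(radius > 0)
  if (nrow(points) == 0) {
    warning("empty localization table")
    return(structure(list(neighbor_radius = radius,
                          per_point_counts = integer(0),
                          histogram = data.frame(count = integer(0),
                                                 frequency = integer(0))),
                     class = "density_result"))
  }
  check_in_window(points, window)
  counts <- cpp_neighbor_counts(points$x, points$y, radius)
  tab <- table(counts)
  structure(
    list(neighbor_radius = radius,
         per_point_counts = counts,
         histogram = data.frame(count = as.integer(names(tab)),
                                frequency = as.integer(tab))),
    class = "density_result"
  )
}

check_in_window <- function(points, window) {
  if (nrow(points) && !all(in_window(points$x, points$y, window)))
    stop("localizations fall outside the analysis window")
  invisible(TRUE)
}

#' Ripley's K, L and H functions with edge correction
#'
#' Computes the second-order statistic
#' \deqn{\hat K(r) = \frac{A}{n(n-1)} \sum_i \sum_{j \ne i} w_{ij}
#'       \, 1(d_{ij} \le r)}
#' over a grid of distances, with `A` the window area and `w_ij` the chosen
#' edge-correction weight, plus the derived `L(r) = sqrt(K/pi)` and
#' `H(r) = L(r) - r`. Under complete spatial randomness `K(r) = pi r^2` and
#' `H(r) = 0`; clustering pushes `H` above zero with a maximum near the
#' characteristic cluster scale (see [estimate_rmax()]).
#'
#' Edge corrections for rectangular windows: `"isotropic"` (Ripley's weight,
#' the reciprocal of the fraction of the circle of radius `d_ij` about point
#' i inside the window), `"translation"`, or `"none"`.
#'
#' @param points A [localization_table()] with at least 2 points.
#' @param window An [analysis_window()].
#' @param r_grid Strictly increasing distances in nm; must not exceed half
#'   the shorter window side. Default `seq(5, 500, by = 5)` clipped to the
#'   window bound.
#' @param edge_correction `"isotropic"` (default), `"translation"` or `"none"`.
#' @return An object of class `ripley_result`: data.frame with columns `r`,
#'   `k`, `l`, `h`, plus attributes `r_max` (from [estimate_rmax()]),
#'   `edge_correction`, `n_points`, `window`.
#' @export
ripley_k <- function(points, window, r_grid = NULL,
                     edge_correction = c("isotropic", "translation", "none")) {
  edge_correction <- match.arg(edge_correction)
  n <- nrow(points)
  if (n < 2) stop("ripley_k requires at least 2 points")
  check_in_window(points, window)
  bound <- min(window$width, window$height) / 2
  if (is.null(r_grid)) {
    r_grid <- seq(5, 500, by = 5)
    r_grid <- r_grid[r_grid <= bound]
  }
  stopifnot(length(r_grid) >= 1, all(diff(r_grid) > 0), r_grid[1] >= 0)
  if (max(r_grid) > bound)
    stop("r_grid exceeds half the shorter window side")
  corr_code <- match(edge_correction, c("none", "isotropic", "translation")) - 1L
  sums <- cpp_ripley_pair_sums(points$x, points$y, r_grid,
                               window$origin_x, window$origin_y,
                               window$width, window$height, corr_code)
  A <- window_area(window)
  k <- A * sums / (n * (n - 1))
  l <- sqrt(k / pi)
  h <- l - r_grid
  df <- data.frame(r = r_grid, k = k, l = l, h = h)
  class(df) <- c("ripley_result", "data.frame")
  attr(df, "edge_correction") <- edge_correction
  attr(df, "n_points") <- n
  attr(df, "window") <- window
  rm <- estimate_rmax(df)
  attr(df, "r_max") <- rm$r_max
  attr(df, "r_max_boundary") <- rm$boundary
  df
}

#' Characteristic clustering length r_max
#'
#' `r_max` is the location of the maximum of `H(r) = L(r) - r`, the
#' clustering-scale normalization of Ripley's K; it shifts to larger values
#' when clusters enlarge (e.g. upon CTxB-driven GM1 coalescence). The
#' discrete argmax is refined by parabolic interpolation through the three
#' surrounding grid points; ties break toward smaller r. A maximum at either
#' end of the grid sets the `boundary` flag and returns the endpoint.
#'
#' @param result A [ripley_k()] result (or any data.frame with `r` and `h`),
#'   with H defined on at least 5 grid points.
#' @return List with `r_max` (nm), `h_max`, and logical `boundary`.
#' @export
estimate_rmax <- function(result) {
  r <- result$r; h <- result$h
  if (length(r) < 5) stop("H must be defined on at least 5 grid points")
  i <- which(h >= max(h))[1]           # ties toward smaller r
  if (i == 1L || i == length(r))
    return(list(r_max = r[i], h_max = h[i], boundary = TRUE))
  # parabola through (r[i-1], h[i-1]), (r[i], h[i]), (r[i+1], h[i+1])
  x <- r[(i - 1):(i + 1)]; y <- h[(i - 1):(i + 1)]
  d21 <- (y[2] - y[1]) / (x[2] - x[1])
  d32 <- (y[3] - y[2]) / (x[3] - x[2])
  curv <- (d32 - d21) / (x[3] - x[1])
  if (curv >= 0) return(list(r_max = r[i], h_max = h[i], boundary = FALSE))
  # vertex of p(x) = y1 + d21 (x - x1) + curv (x - x1)(x - x2)
  vert <- (x[1] + x[2]) / 2 - d21 / (2 * curv)
  list(r_max = vert, h_max = h[i], boundary = FALSE)
}

#' Pool Ripley functions across tiles or replicates
#'
#' Averages K(r) over several [ripley_k()] results computed on a common r
#' grid (e.g. the 3 x 3 um tiles of one cell, or cells of one condition),
#' recomputes L and H from the mean K, and re-estimates r_max on the pooled
#' curve. Averaging before locating the H maximum suppresses the
#' large-r noise of individual windows; this mirrors reporting a single
#' clustering length per condition from many regions.
#'
#' @param results List of `ripley_result` objects with identical `r` grids.
#' @return A `ripley_result` for the pooled curve (attribute `n_pooled`).
#' @export
pool_ripley <- function(results) {
  stopifnot(length(results) >= 1)
  r <- results[[1]]$r
  for (res in results)
    if (!isTRUE(all.equal(res$r, r))) stop("r grids differ across results")
  k <- rowMeans(vapply(results, function(res) res$k, numeric(length(r))))
  l <- sqrt(k / pi)
  df <- data.frame(r = r, k = k, l = l, h = l - r)
  class(df) <- c("ripley_result", "data.frame")
  attr(df, "edge_correction") <- attr(results[[1]], "edge_correction")
  attr(df, "n_pooled") <- length(results)
  rm <- estimate_rmax(df)
  attr(df, "r_max") <- rm$r_max
  attr(df, "r_max_boundary") <- rm$boundary
  df
}

#' Theoretical Ripley K of a Thomas cluster process
#'
#' For Poisson parents of intensity `kappa` with isotropically
#' Gaussian-displaced offspring (spread `sigma`),
#' `K(r) = pi r^2 + (1/kappa) (1 - exp(-r^2 / (4 sigma^2)))`.
#'
#' @param r Distances (nm).
#' @param kappa Parent intensity in points per nm^2.
#' @param sigma Offspring displacement SD in nm.
#' @return K(r) in nm^2.
#' @export
thomas_k_theoretical <- function(r, kappa, sigma) {
  pi * r^2 + (1 / kappa) * (1 - exp(-r^2 / (4 * sigma^2)))
}

# Isotropized set covariance of a w x h rectangle at distance r
# (valid for r <= min(w, h)).
rect_set_covariance_integral <- function(r, w, h) {
  # F(r) = int_0^r 2 pi s * gamma(s) ds with
  # gamma(s) = w h - 2 s (w + h)/pi + s^2/pi
  pi * w * h * r^2 - (4 / 3) * (w + h) * r^3 + r^4 / 2
}

#' Two-channel pair cross-correlation C(r)
#'
#' Measures the relative probability of finding channel-A/channel-B
#' localization pairs separated by distance r compared with independent
#' uniform placement at the same intensities: observed A-B pair counts per
#' annulus divided by the expectation under independence, with the edge
#' correction given analytically by the isotropized set covariance of the
#' rectangular window. `C(r) = 1` under independence; co-clustered channels
#' give `C(r) > 1` at short range.
#'
#' @param channel_a,channel_b Nonempty [localization_table()]s in `window`.
#' @param window An [analysis_window()].
#' @param r_bins Ascending annulus edges in nm; default `seq(0, 500, by = 10)`
#'   clipped to the shorter window side.
#' @return An object of class `cross_correlation_result`: data.frame with
#'   `r` (bin centers), `c` (C(r), `NA` where the expected count is zero) and
#'   `n_pairs` per bin; attribute `normalization`.
#' @export
cross_correlation <- function(channel_a, channel_b, window, r_bins = NULL) {
  if (nrow(channel_a) == 0 || nrow(channel_b) == 0)
    stop("both channels must be nonempty")
  check_in_window(channel_a, window)
  check_in_window(channel_b, window)
  if (is.null(r_bins)) {
    r_bins <- seq(0, 500, by = 10)
    r_bins <- r_bins[r_bins <= min(window$width, window$height)]
  }
  stopifnot(length(r_bins) >= 2, all(diff(r_bins) > 0))
  obs <- cpp_cross_pair_counts(channel_a$x, channel_a$y,
                               channel_b$x, channel_b$y, r_bins)
  na <- nrow(channel_a); nb <- nrow(channel_b)
  A <- window_area(window)
  Fr <- rect_set_covariance_integral(r_bins, window$width, window$height)
  expected <- na * nb / A^2 * diff(Fr)
  cvals <- ifelse(expected > 0, obs / expected, NA_real_)
  df <- data.frame(r = (head(r_bins, -1) + r_bins[-1]) / 2,
                   c = cvals, n_pairs = obs)
  class(df) <- c("cross_correlation_result", "data.frame")
  attr(df, "normalization") <- "analytic rectangle set covariance"
  attr(df, "n_a") <- na
  attr(df, "n_b") <- nb
  df
}

#' @export
plot.ripley_result <- function(x, which = c("h", "k", "l"), ...) {
  which <- match.arg(which)
  graphics::plot(x$r, x[[which]], type = "l", xlab = "r (nm)",
                 ylab = toupper(which), ...)
  if (which == "h") graphics::abline(h = 0, lty = 2)
  invisible(x)
}

#' @export
plot.cross_correlation_result <- function(x, ...) {
  graphics::plot(x$r, x$c, type = "b", pch = 16, xlab = "r (nm)",
                 ylab = "C(r)", ...)
  graphics::abline(h = 1, lty = 2)
  invisible(x)
}
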