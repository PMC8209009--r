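#' Point-pattern ground truth
#'
#' Parameter record for the localization-pattern simulator. `"csr"` is a
#' homogeneous Poisson process at `intensity_um2`; `"thomas"` is a
#' Neyman-Scott cluster process: Poisson parents of intensity `kappa_um2`,
#' Poisson(`mu`) offspring per parent displaced isotropically by a Gaussian
#' of SD `sigma_nm`, with toroidal wrapping. Optional blinking re-records
#' each molecule a geometric number of times (mean `mean_localizations`),
#' displacing each localization by the localization precision.
#'
#' @param process `"csr"` or `"thomas"`.
#' @param intensity_um2 CSR intensity (points per um^2).
#' @param kappa_um2 Thomas parent intensity (per um^2).
#' @param mu Mean offspring per parent.
#' @param sigma_nm Offspring displacement SD (nm, positive for thomas).
#' @param linkage For two-channel simulation: `"shared_parents"` (co-clustered)
#'   or `"independent"`.
#' @param blinking `NULL` (off, the default) or
#'   `list(mean_localizations =, precision_nm =)`.
#' @return An object of class `pattern_truth`.
#' @export
pattern_truth <- function(process = c("csr", "thomas"),
                          intensity_um2 = 100,
                          kappa_um2 = 50, mu = 20, sigma_nm = 30,
                          linkage = c("independent", "shared_parents"),
                          blinking = NULL) {
  process <- match.arg(process)
  linkage <- match.arg(linkage)
  stopifnot(intensity_um2 >= 0, kappa_um2 >= 0, mu >= 0)
  if (process == "thomas") stopifnot(sigma_nm > 0)
  structure(list(process = process, intensity_um2 = intensity_um2,
                 kappa_um2 = kappa_um2, mu = mu, sigma_nm = sigma_nm,
                 linkage = linkage, blinking = blinking),
            class = "pattern_truth")
}

wrap_into <- function(v, origin, extent) origin + (v - origin) %% extent

apply_blinking <- function(x, y, blinking) {
  n <- length(x)
  k <- rgeom(n, 1 / blinking$mean_localizations) + 1L
  idx <- rep(seq_len(n), k)
  list(x = x[idx] + rnorm(length(idx), 0, blinking$precision_nm),
       y = y[idx] + rnorm(length(idx), 0, blinking$precision_nm),
       molecule = idx)
}

sim_parents <- function(kappa_nm2, window) {
  np <- rpois(1, kappa_nm2 * window_area(window))
  list(x = runif(np, window$origin_x, window$origin_x + window$width),
       y = runif(np, window$origin_y, window$origin_y + window$height))
}

sim_offspring <- function(parents, mu, sigma, window) {
  counts <- rpois(length(parents$x), mu)
  px <- rep(parents$x, counts); py <- rep(parents$y, counts)
  n <- length(px)
  x <- wrap_into(px + rnorm(n, 0, sigma), window$origin_x, window$width)
  y <- wrap_into(py + rnorm(n, 0, sigma), window$origin_y, window$height)
  list(x = x, y = y)
}

finalize_pattern <- function(x, y, truth, window, channel = NULL, seed = NULL) {
  frame <- seq_along(x)
  if (!is.null(truth$blinking)) {
    bl <- apply_blinking(x, y, truth$blinking)
    x <- wrap_into(bl$x, window$origin_x, window$width)
    y <- wrap_into(bl$y, window$origin_y, window$height)
    # blinking repeats of a molecule land in consecutive frames
    frame <- stats::ave(bl$molecule, bl$molecule, FUN = seq_along) +
      sample.int(10000L, length(unique(bl$molecule)))[bl$molecule]
  }
  locs <- localization_table(x, y, frame = frame,
                             channel = if (is.null(channel)) NULL
                                       else rep(channel, length(x)))
  attr(locs, "truth") <- c(truth, list(seed = seed))
  locs
}

#' Simulate a single-channel localization pattern
#'
#' Draws a CSR or Thomas-process point pattern inside `window` per the truth
#' record, applies optional blinking, and embeds the full truth (including
#' the seed) in the output's `"truth"` attribute.
#'
#' @param truth A [pattern_truth()].
#' @param window An [analysis_window()].
#' @param seed Integer RNG seed (recorded in the truth attribute).
#' @param max_points Guard against runaway inputs: error if the expected
#'   point count exceeds this cap (default 1e6).
#' @return A [localization_table()] with attribute `truth`.
#' @export
simulate_point_pattern <- function(truth, window, seed = NULL,
                                   max_points = 1e6) {
  if (!is.null(seed)) set.seed(seed)
  A_um2 <- window_area(window) / 1e6
  expected <- if (truth$process == "csr") truth$intensity_um2 * A_um2
              else truth$kappa_um2 * truth$mu * A_um2
  if (expected > max_points)
    stop(sprintf("expected %.3g points exceeds cap %g", expected, max_points))
  if (truth$process == "csr") {
    n <- rpois(1, truth$intensity_um2 * A_um2)
    x <- runif(n, window$origin_x, window$origin_x + window$width)
    y <- runif(n, window$origin_y, window$origin_y + window$height)
  } else {
    parents <- sim_parents(truth$kappa_um2 / 1e6, window)
    off <- sim_offspring(parents, truth$mu, truth$sigma_nm, window)
    x <- off$x; y <- off$y
  }
  finalize_pattern(x, y, truth, window, seed = seed)
}

#' Simulate a two-channel localization pattern
#'
#' Generates channel A and channel B Thomas patterns that are either
#' co-clustered (`linkage = "shared_parents"`: both channels' offspring
#' scatter around the same parent set, emulating CTxB-driven co-distribution
#' of GM1 and CD59) or `"independent"` (separate parent sets; the
#' cross-correlation null).
#'
#' @param truth A [pattern_truth()] with `process = "thomas"` and a linkage.
#' @param window An [analysis_window()].
#' @param seed Integer RNG seed.
#' @param channels Two channel labels (default `c("GM1", "CD59")`).
#' @param max_points Expected-count guard per channel.
#' @return A [localization_table()] with both channels and attribute `truth`.
#' @export
simulate_two_channel_pattern <- function(truth, window, seed = NULL,
                                         channels = c("GM1", "CD59"),
                                         max_points = 1e6) {
  if (truth$process != "thomas")
    stop("two-channel simulation is defined for the thomas process")
  if (!is.null(seed)) set.seed(seed)
  expected <- truth$kappa_um2 * truth$mu * window_area(window) / 1e6
  if (expected > max_points)
    stop(sprintf("expected %.3g points exceeds cap %g", expected, max_points))
  parents_a <- sim_parents(truth$kappa_um2 / 1e6, window)
  parents_b <- if (truth$linkage == "shared_parents") parents_a
               else sim_parents(truth$kappa_um2 / 1e6, window)
  off_a <- sim_offspring(parents_a, truth$mu, truth$sigma_nm, window)
  off_b <- sim_offspring(parents_b, truth$mu, truth$sigma_nm, window)
  a <- finalize_pattern(off_a$x, off_a$y, truth, window,
                        channel = channels[1], seed = seed)
  b <- finalize_pattern(off_b$x, off_b$y, truth, window,
                        channel = channels[2], seed = seed)
  locs <- rbind(a, b)
  class(locs) <- c("localization_table", "data.frame")
  attr(locs, "truth") <- c(truth, list(seed = seed, channels = channels))
  locs
}

#' Homo-FRET photophysics parameters
#'
#' Defaults: monomer anisotropy `r_mono = 0.35` (a conventional value for a
#' membrane-bound dye, not a measured constant), post-transfer anisotropy
#' `r_et = 0` (complete depolarization after one transfer step), bound-state
#' anisotropy `r_mono_bound = 0.45` (rotational restriction by the
#' pentameric toxin), and Forster radius `r0_nm = 5`.
#'
#' @param r_mono,r_et,r_mono_bound Anisotropies.
#' @param r0_nm Forster radius in nm.
#' @return A list of class `fret_params`.
#' @export
fret_params <- function(r_mono = 0.35, r_et = 0, r_mono_bound = 0.45,
                        r0_nm = 5) {
  stopifnot(r0_nm > 0, r_et <= r_mono, r_mono <= r_mono_bound)
  structure(list(r_mono = r_mono, r_et = r_et,
                 r_mono_bound = r_mono_bound, r0_nm = r0_nm),
            class = "fret_params")
}

#' Emitter field with homo-FRET depolarization
#'
#' Builds a fluorophore field and assigns each emitter an effective
#' anisotropy under the one-step transfer approximation: the self-emission
#' weight is \eqn{w_i = 1 / (1 + \sum_{j \ne i} (R_0/d_{ij})^6)} and
#' \eqn{r_i = w_i r_{base} + (1 - w_i) r_{et}}, with `r_base` the monomer
#' anisotropy (or the bound-state anisotropy for toxin-bound emitters, whose
#' dipoles are rotationally restricted). Modes:
#' \describe{
#'   \item{`"random"`}{CSR monomers at `density_um2` — the bystander-FRET
#'     regime, depolarization grows with density.}
#'   \item{`"clustered"`}{clusters (Poisson at `cluster_density_um2`) of
#'     `cluster_size` emitters on a ring of radius `cluster_radius_nm` —
#'     fixed-size nanoclusters, density-independent depolarization.}
#'   \item{`"ctxb_bound"`}{same pentamer-like ring geometry (five binding
#'     sites on a 3 nm ring) but emitters carry `r_mono_bound`.}
#' }
#'
#' @param window An [analysis_window()] (the field of view, nm).
#' @param mode `"random"`, `"clustered"` or `"ctxb_bound"`.
#' @param density_um2 Monomer density for `"random"` (per um^2).
#' @param cluster_density_um2 Cluster density for the cluster modes.
#' @param cluster_size Emitters per cluster (default 5).
#' @param cluster_radius_nm Ring radius (default 3 nm).
#' @param fret A [fret_params()].
#' @param seed Integer RNG seed.
#' @return An object of class `emitter_field`: data.frame `emitters`
#'   (x, y, state, w, r) plus the truth record.
#' @export
simulate_emitter_field <- function(window,
                                   mode = c("random", "clustered", "ctxb_bound"),
                                   density_um2 = 50,
                                   cluster_density_um2 = 10,
                                   cluster_size = 5,
                                   cluster_radius_nm = 3,
                                   fret = fret_params(), seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  A_um2 <- window_area(window) / 1e6
  if (mode == "random") {
    n <- rpois(1, density_um2 * A_um2)
    x <- runif(n, window$origin_x, window$origin_x + window$width)
    y <- runif(n, window$origin_y, window$origin_y + window$height)
    state <- rep("free", n)
  } else {
    nc <- rpois(1, cluster_density_um2 * A_um2)
    cx <- runif(nc, window$origin_x, window$origin_x + window$width)
    cy <- runif(nc, window$origin_y, window$origin_y + window$height)
    phase <- runif(nc, 0, 2 * pi)
    ang <- rep(phase, each = cluster_size) +
      rep(2 * pi * seq_len(cluster_size) / cluster_size, nc)
    x <- rep(cx, each = cluster_size) + cluster_radius_nm * cos(ang)
    y <- rep(cy, each = cluster_size) + cluster_radius_nm * sin(ang)
    x <- wrap_into(x, window$origin_x, window$width)
    y <- wrap_into(y, window$origin_y, window$height)
    state <- rep(if (mode == "ctxb_bound") "ctxb_bound" else "clustered",
                 length(x))
  }
  w <- if (length(x)) cpp_fret_weights(x, y, fret$r0_nm) else numeric(0)
  r_base <- ifelse(state == "ctxb_bound", fret$r_mono_bound, fret$r_mono)
  r <- w * r_base + (1 - w) * fret$r_et
  structure(
    list(emitters = data.frame(x = x, y = y, state = state, w = w, r = r),
         window = window, fret = fret,
         truth = list(mode = mode, density_um2 = density_um2,
                      cluster_density_um2 = cluster_density_um2,
                      cluster_size = cluster_size,
                      cluster_radius_nm = cluster_radius_nm,
                      fret = unclass(fret), seed = seed)),
    class = "emitter_field"
  )
}

#' Camera model parameters
#'
#' Two-camera detection model: the perpendicular channel detects with
#' efficiency `1/g` relative to the parallel channel (so an isotropic source
#' yields a per-pixel ratio of g), Poisson shot noise, multiplicative gain,
#' Gaussian read noise and a constant offset, quantized to 16-bit counts.
#'
#' @param pixel_size_nm Pixel size (nm).
#' @param gain Counts per detected photon.
#' @param offset Constant offset (counts).
#' @param read_noise Read-noise SD (counts).
#' @param g Detection-efficiency ratio (the true G-factor).
#' @return A list of class `camera_params`.
#' @export
camera_params <- function(pixel_size_nm = 100, gain = 1, offset = 100,
                          read_noise = 2, g = 1) {
  stopifnot(pixel_size_nm > 0, gain > 0, g > 0)
  structure(list(pixel_size_nm = pixel_size_nm, gain = gain, offset = offset,
                 read_noise = read_noise, g = g),
            class = "camera_params")
}

# Separable Gaussian blur; photons leaving the field of view are lost.
gaussian_blur <- function(img, sigma_px) {
  if (sigma_px <= 0) return(img)
  k <- ceiling(4 * sigma_px)
  kern <- dnorm(-k:k, sd = sigma_px)
  kern <- kern / sum(kern)
  band <- function(n) {
    m <- matrix(0, n, n)
    for (o in -k:k) {
      i <- seq_len(n)
      j <- i + o
      ok <- j >= 1 & j <= n
      m[cbind(i[ok], j[ok])] <- kern[o + k + 1]
    }
    m
  }
  band(nrow(img)) %*% img %*% t(band(ncol(img)))
}

#' Simulate a polarization-resolved image pair
#'
#' Forward model of the two-camera anisotropy microscope. Each emitter emits
#' `B_i ~ Poisson(photons_mean)` photons with effective anisotropy `r_i`
#' (from the emitter field's homo-FRET model), splitting into channel
#' expectations `B_i (1 + 2 r_i) / 3` (parallel) and `B_i (1 - r_i) / (3 g)`
#' (perpendicular). Emitter contributions are deposited on the pixel grid,
#' convolved with a Gaussian PSF, and passed through the camera noise model.
#' Analyzing the output with [compute_anisotropy_maps()] at the same g
#' recovers `r_i` in the sparse limit.
#'
#' @param field An [simulate_emitter_field()] result.
#' @param shape Image shape in pixels `c(ny, nx)`.
#' @param psf_sigma_nm Gaussian PSF SD in nm (default 150).
#' @param photons_mean Mean photon budget per emitter.
#' @param camera A [camera_params()].
#' @param noise Apply shot/read noise and quantization (default TRUE); with
#'   `FALSE` the expected signal is returned (no offset, no rounding).
#' @param seed Integer RNG seed.
#' @return A [polarized_image_pair()] with attribute `truth`.
#' @export
simulate_polarized_image_pair <- function(field, shape = c(64, 64),
                                          psf_sigma_nm = 150,
                                          photons_mean = 1e4,
                                          camera = camera_params(),
                                          noise = TRUE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  em <- field$emitters
  px <- camera$pixel_size_nm
  n <- nrow(em)
  B <- if (noise) rpois(n, photons_mean) else rep(photons_mean, n)
  ix <- pmin(pmax(floor((em$y - field$window$origin_y) / px) + 1, 1), shape[1])
  iy <- pmin(pmax(floor((em$x - field$window$origin_x) / px) + 1, 1), shape[2])
  par_img <- matrix(0, shape[1], shape[2])
  per_img <- matrix(0, shape[1], shape[2])
  amp_par <- B * (1 + 2 * em$r) / 3
  amp_per <- B * (1 - em$r) / (3 * camera$g)
  for (i in seq_len(n)) {
    par_img[ix[i], iy[i]] <- par_img[ix[i], iy[i]] + amp_par[i]
    per_img[ix[i], iy[i]] <- per_img[ix[i], iy[i]] + amp_per[i]
  }
  sig <- psf_sigma_nm / px
  par_img <- gaussian_blur(par_img, sig)
  per_img <- gaussian_blur(per_img, sig)
  if (noise) {
    shoot <- function(lam) {
      counts <- camera$gain * rpois(length(lam), lam) +
        rnorm(length(lam), 0, camera$read_noise) + camera$offset
      matrix(pmin(pmax(round(counts), 0), 65535), nrow(lam))
    }
    par_img <- shoot(par_img)
    per_img <- shoot(per_img)
    bg_pa <- camera$offset; bg_pe <- camera$offset
  } else {
    bg_pa <- 0; bg_pe <- 0
  }
  pair <- polarized_image_pair(par_img, per_img, pixel_size = px,
                               background_parallel = bg_pa,
                               background_perpendicular = bg_pe)
  attr(pair, "truth") <- list(field = field$truth, emitter_r = em$r,
                              photons_mean = photons_mean,
                              psf_sigma_nm = psf_sigma_nm,
                              camera = unclass(camera), noise = noise,
                              seed = seed)
  pair
}

#' Simulate an isotropic-reference image pair for G-factor calibration
#'
#' Emulates the rhodamine-in-buffer reference: a spatially uniform isotropic
#' source (anisotropy 0) imaged by the two cameras with detection ratio `g`,
#' Poisson shot noise, read noise and offset.
#'
#' @param shape Image shape in pixels.
#' @param mean_photons Mean photons per pixel (total intensity scale).
#' @param camera A [camera_params()]; its `g` is the true detection ratio.
#' @param seed Integer RNG seed.
#' @return A [polarized_image_pair()].
#' @export
simulate_reference_pair <- function(shape = c(100, 100), mean_photons = 3000,
                                    camera = camera_params(g = 1.25),
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  npx <- shape[1] * shape[2]
  lam_pa <- mean_photons / 3
  lam_pe <- mean_photons / (3 * camera$g)
  mk <- function(lam) {
    counts <- camera$gain * rpois(npx, lam) +
      rnorm(npx, 0, camera$read_noise) + camera$offset
    matrix(pmin(pmax(round(counts), 0), 65535), shape[1], shape[2])
  }
  polarized_image_pair(mk(lam_pa), mk(lam_pe),
                       pixel_size = camera$pixel_size_nm,
                       background_parallel = camera$offset,
                       background_perpendicular = camera$offset)
}
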