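test_that("neighbor counts handle singletons and threshold crossings", {
  w <- analysis_window(1000)
  one <- localization_table(500, 500)
  expect_identical(neighbor_density(one, w, 100)$per_point_counts, 0L)
  two <- localization_table(c(500, 550), c(500, 500))
  expect_identical(neighbor_density(two, w, 100)$per_point_counts, c(1L, 1L))
  expect_identical(neighbor_density(two, w, 40)$per_point_counts, c(0L, 0L))
  expect_warning(nd <- neighbor_density(localization_table(numeric(0),
                                                           numeric(0)), w),
                 "empty")
  expect_length(nd$per_point_counts, 0)
})

test_that("neighbor counts match the brute-force oracle and CSR expectation", {
  w <- analysis_window(3000)
  set.seed(101)
  lt <- localization_table(runif(1000, 0, 3000), runif(1000, 0, 3000))
  nd <- neighbor_density(lt, w, 100)
  expect_identical(nd$per_point_counts,
                   oracle_neighbor_counts(lt$x, lt$y, 100))
  expect_identical(sum(nd$histogram$frequency), 1000L)
  # interior points: mean count ~ lambda * pi * r^2
  interior <- lt$x > 100 & lt$x < 2900 & lt$y > 100 & lt$y < 2900
  lam <- 1000 / 3000^2
  expect_equal(mean(nd$per_point_counts[interior]), lam * pi * 100^2,
               tolerance = 0.15)
})

test_that("Ripley pair sums match the brute-force oracle for every correction", {
  w <- analysis_window(2000)
  set.seed(7)
  lt <- localization_table(runif(400, 0, 2000), runif(400, 0, 2000))
  rg <- seq(20, 500, by = 20)
  for (corr in c("none", "isotropic", "translation")) {
    got <- ripley_k(lt, w, rg, edge_correction = corr)
    sums <- got$k * 400 * 399 / (2000 * 2000)
    expect_equal(sums, oracle_ripley_sums(lt$x, lt$y, rg, 0, 0, 2000, 2000,
                                          corr),
                 tolerance = 1e-9)
  }
})

test_that("a central two-point pattern gives the hand-computed K step", {
  w <- analysis_window(2000)
  lt <- localization_table(c(950, 1050), c(1000, 1000))   # d = 100, central
  res <- ripley_k(lt, w, r_grid = seq(25, 500, by = 25))
  A <- 2000^2
  expect_equal(res$k[res$r < 100], rep(0, sum(res$r < 100)))
  # both points are > 500 nm from every edge: weights are 1
  expect_equal(res$k[res$r >= 100], rep(A * 2 / (2 * 1), sum(res$r >= 100)))
})

test_that("K is nonnegative, nondecreasing, and r_grid is validated", {
  w <- analysis_window(1000)
  set.seed(8)
  lt <- localization_table(runif(200, 0, 1000), runif(200, 0, 1000))
  res <- ripley_k(lt, w, seq(10, 400, 10))
  expect_true(all(res$k >= 0))
  expect_true(all(diff(res$k) >= 0))
  expect_error(ripley_k(lt, w, seq(10, 600, 10)), "half")
  expect_error(ripley_k(lt, w, seq(10, 400, 10), edge_correction = "fancy"))
})

test_that("CSR calibration: K(100)/pi r^2 near 1 and H near 0", {
  w <- analysis_window(3000)
  ratios <- h100 <- numeric(8)
  for (s in seq_len(8)) {
    lt <- simulate_point_pattern(pattern_truth("csr", intensity_um2 = 2000 / 9),
                                 w, seed = 300 + s)
    res <- ripley_k(lt, w, r_grid = seq(10, 500, 10))
    ratios[s] <- res$k[res$r == 100] / (pi * 100^2)
    h100[s] <- res$h[res$r == 100]
  }
  expect_equal(mean(ratios), 1, tolerance = 0.05)
  expect_lt(abs(mean(h100)), 5)
})

test_that("Thomas-process K follows the closed form", {
  w <- analysis_window(3000)
  tr <- pattern_truth("thomas", kappa_um2 = 50, mu = 20, sigma_nm = 30)
  rg <- seq(30, 300, by = 15)
  ks <- sapply(1:10, function(s) {
    lt <- simulate_point_pattern(tr, w, seed = 500 + s)
    ripley_k(lt, w, rg)$k
  })
  kth <- thomas_k_theoretical(rg, 50e-6, 30)
  expect_lt(max(abs(rowMeans(ks) - kth) / kth), 0.05)
})

test_that("r_max parabolic refinement and tie rule behave as specified", {
  mk <- function(r, h) data.frame(r = r, h = h)
  # symmetric peak refines to the central point
  expect_equal(estimate_rmax(mk(seq(0, 200, 50),
                                c(-1, 0, 1, 0, -1)))$r_max, 100)
  # discrete tie: parabola through the three points around the SMALLER argmax
  res <- estimate_rmax(mk(c(0, 50, 100, 150, 200), c(-1, 0, 1, 1, 0)))
  expect_equal(res$r_max, 125)   # vertex of parabola through (50,0),(100,1),(150,1)
  expect_false(res$boundary)
  # monotone H: boundary flag with endpoint argmax
  res2 <- estimate_rmax(mk(seq(0, 200, 50), 1:5))
  expect_true(res2$boundary)
  expect_equal(res2$r_max, 200)
  expect_error(estimate_rmax(mk(c(0, 50, 100), c(0, 1, 0))), "5 grid")
})

test_that("r_max recovery is monotone in cluster spread and near the analytic argmax", {
  w <- analysis_window(3000)
  rmaxes <- sapply(c(20, 30, 60), function(sig) {
    tr <- pattern_truth("thomas", kappa_um2 = 50, mu = 20, sigma_nm = sig)
    reps <- lapply(1:6, function(s) {
      lt <- simulate_point_pattern(tr, w, seed = 700 + s + sig)
      ripley_k(lt, w, seq(5, 500, 5))
    })
    attr(pool_ripley(reps), "r_max")
  })
  expect_true(all(diff(rmaxes) > 0))
  analytic <- sapply(c(20, 30, 60), function(sig) thomas_h_argmax(50e-6, sig))
  expect_true(all(abs(rmaxes - analytic) / analytic < 0.10))
})

test_that("cross-correlation pair counts match the brute-force oracle", {
  w <- analysis_window(2000)
  set.seed(9)
  a <- localization_table(runif(300, 0, 2000), runif(300, 0, 2000))
  b <- localization_table(runif(400, 0, 2000), runif(400, 0, 2000))
  breaks <- seq(0, 400, 20)
  cc <- cross_correlation(a, b, w, breaks)
  expect_identical(cc$n_pairs, oracle_cross_counts(a$x, a$y, b$x, b$y, breaks))
})

test_that("identical channels give a strongly peaked, decreasing C(r)", {
  w <- analysis_window(3000)
  set.seed(10)
  a <- localization_table(runif(500, 0, 3000), runif(500, 0, 3000))
  cc <- cross_correlation(a, a, w, seq(0, 300, 10))
  expect_gt(cc$c[1], 10)
  expect_gt(cc$c[1], cc$c[2])
})

test_that("independent CSR channels give C(r) ~ 1", {
  w <- analysis_window(3000)
  cs <- sapply(1:6, function(s) {
    set.seed(900 + s)
    a <- localization_table(runif(1500, 0, 3000), runif(1500, 0, 3000))
    b <- localization_table(runif(1500, 0, 3000), runif(1500, 0, 3000))
    cross_correlation(a, b, w, seq(0, 300, 20))$c
  })
  expect_lt(max(abs(rowMeans(cs) - 1)), 0.05)
})

test_that("C(r) is symmetric under channel swap for equal-width bins", {
  w <- analysis_window(2000)
  set.seed(12)
  a <- localization_table(runif(200, 0, 2000), runif(200, 0, 2000))
  b <- localization_table(runif(300, 0, 2000), runif(300, 0, 2000))
  br <- seq(0, 300, 15)
  expect_equal(cross_correlation(a, b, w, br)$c,
               cross_correlation(b, a, w, br)$c)
})

test_that("tiling follows the floor rule and half-open membership", {
  pts <- localization_table(c(1, 3000, 8999), c(1, 0, 8999))
  full <- analysis_window(9000)
  tiles <- tile_windows(pts, full, 3000)
  expect_length(tiles, 9)
  # 10000 nm window: margins discarded
  expect_length(tile_windows(pts, analysis_window(10000), 3000), 9)
  # point at x = 3000 belongs to the second-column tile
  t2 <- tiles[[2]]
  expect_identical(t2$window$origin_x, 3000)
  expect_true(3000 %in% t2$points$x)
  # per-tile point totals preserve all points
  expect_identical(sum(vapply(tiles, function(t) nrow(t$points), integer(1))),
                   3L)
  expect_error(tile_windows(pts, full, 10000), "tile")
})

test_that("duplicated blinking localizations inflate K and merging restores CSR", {
  w <- analysis_window(3000)
  tr_blink <- pattern_truth("csr", intensity_um2 = 60,
                            blinking = list(mean_localizations = 4,
                                            precision_nm = 10))
  k_ratio <- function(locs) {
    res <- ripley_k(locs, w, seq(10, 300, 10))
    res$k[res$r == 100] / (pi * 100^2)
  }
  ratios <- sapply(1:4, function(s) {
    blink <- simulate_point_pattern(tr_blink, w, seed = 40 + s)
    merged <- merge_blinking(blink, radius = 40, max_gap = 2)
    c(blinked = k_ratio(blink), merged = k_ratio(merged))
  })
  expect_gt(mean(ratios["blinked", ]), 1.5)     # blinking fakes clustering
  expect_equal(mean(ratios["merged", ]), 1, tolerance = 0.10)
})
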