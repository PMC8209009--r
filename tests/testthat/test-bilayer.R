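# Small hand-built ensemble: 4 lipids (2 per leaflet), 4-carbon chains.
mini_schema <- function() default_gm1_schema(4, c("GM1", "POPS"))

mini_ensemble <- function(coords_fun, n_frames = 1, box = c(8, 8, 10)) {
  sch <- mini_schema()
  atoms <- do.call(rbind, lapply(1:4, function(lid) {
    sp <- if (lid <= 2) "GM1" else "POPS"
    nm <- c("HG0", if (sp == "GM1") c("HG1", "HG2", "HG3"),
            paste0("S", 1:4), paste0("A", 1:4))
    data.frame(atom = nm, lipid_id = lid, species = sp,
               leaflet = if (lid <= 2) "upper" else "lower")
  }))
  coords <- array(0, c(nrow(atoms), 3, n_frames))
  for (f in seq_len(n_frames)) coords[, , f] <- coords_fun(atoms, f)
  bilayer_ensemble(atoms, coords, box, sch)
}

# default geometry: anchors on a grid, straight chains inside own leaflet
base_coords <- function(atoms, f) {
  xy <- cbind(c(2, 6)[(atoms$lipid_id - 1) %% 2 + 1], 4)
  sgn <- ifelse(atoms$leaflet == "upper", 1, -1)
  z <- numeric(nrow(atoms))
  z[atoms$atom == "HG0"] <- 2
  for (k in 1:4) {
    z[atoms$atom %in% paste0(c("S", "A"), k)] <- 1 - 0.2 * k + 0.1
  }
  hg <- grepl("^HG[123]$", atoms$atom)
  z[hg] <- 2.5
  cbind(xy[, 1] + ifelse(grepl("^A", atoms$atom), 0.3, 0), xy[, 2], z * sgn)
}

test_that("headgroup angles reproduce fixed vector orientations", {
  # lipid 1's vectors point along +z, lipid 2's along +x
  ens <- mini_ensemble(function(atoms, f) {
    xyz <- base_coords(atoms, f)
    for (lid in 1:2) {
      base <- xyz[atoms$lipid_id == lid & atoms$atom == "HG0", ]
      tips <- which(atoms$lipid_id == lid & grepl("^HG[123]$", atoms$atom))
      off <- if (lid == 1) c(0, 0, 1) else c(1, 0, 0)
      for (t in tips) xyz[t, ] <- base + off
    }
    xyz
  }, n_frames = 3)
  ser <- headgroup_angle_series(ens, bound_ids = 1)
  expect_equal(unique(ser$theta_deg[ser$lipid_id == 1]), 0)
  expect_equal(unique(ser$theta_deg[ser$lipid_id == 2]), 90)
  expect_identical(unique(ser$group[ser$lipid_id == 1]), "bound")
  expect_identical(unique(ser$group[ser$lipid_id == 2]), "unbound")
})

test_that("headgroup vectors respect the minimum-image convention", {
  # tip wrapped across the box: raw difference is huge, min-image is short
  ens <- mini_ensemble(function(atoms, f) {
    xyz <- base_coords(atoms, f)
    base_row <- which(atoms$lipid_id == 1 & atoms$atom == "HG0")
    xyz[base_row, 1] <- 7.9
    tips <- which(atoms$lipid_id == 1 & grepl("^HG[123]$", atoms$atom))
    xyz[tips, ] <- matrix(c(0.1, xyz[base_row, 2], xyz[base_row, 3]),
                          3, 3, byrow = TRUE)
    xyz
  })
  ser <- headgroup_angle_series(ens)
  expect_equal(unique(ser$theta_deg[ser$lipid_id == 1]), 90)
})

test_that("sigma_theta matches the two-frame hand value and flags empty groups", {
  ens <- mini_ensemble(function(atoms, f) {
    xyz <- base_coords(atoms, f)
    th <- if (f == 1) 10 else 20
    for (lid in 1:2) {
      base <- xyz[atoms$lipid_id == lid & atoms$atom == "HG0", ]
      tips <- which(atoms$lipid_id == lid & grepl("^HG[123]$", atoms$atom))
      for (t in tips)
        xyz[t, ] <- base + c(sin(th * pi / 180), 0, cos(th * pi / 180))
    }
    xyz
  }, n_frames = 2)
  ser <- headgroup_angle_series(ens)
  expect_warning(st <- sigma_theta(ser), "no lipids")
  expect_equal(unname(st$table$sigma_theta), rep(sd(c(10, 20)), 3),
               tolerance = 1e-9)
  expect_true(all(is.na(st$ratio)))
})

test_that("sigma_theta recovers a planted 3x bound/unbound contrast", {
  tr <- bilayer_truth(head_sd_bound_deg = 3, head_sd_unbound_deg = 9)
  ens <- simulate_bilayer_ensemble(tr, n_frames = 1500,
                                   composition_upper = c(GM1 = 10),
                                   composition_lower = c(POPS = 4),
                                   bound_ids = 1:5, chain_length = 4,
                                   seed = 33)
  st <- sigma_theta(headgroup_angle_series(ens, bound_ids = 1:5))
  expect_equal(st$ratio_overall, 3, tolerance = 0.1)
})

test_that("angle generator reproduces planted mean and SD", {
  tr <- bilayer_truth(head_mean_deg = 30, head_sd_bound_deg = 10,
                      head_sd_unbound_deg = 10)
  ens <- simulate_bilayer_ensemble(tr, n_frames = 2000,
                                   composition_upper = c(GM1 = 5),
                                   composition_lower = c(POPS = 4),
                                   bound_ids = integer(0), chain_length = 4,
                                   seed = 44)
  ser <- headgroup_angle_series(ens)
  expect_equal(mean(ser$theta_deg), 30, tolerance = 0.02 * 30)
  expect_equal(sd(ser$theta_deg), 10, tolerance = 0.02 * 10 + 0.2)
})

test_that("interdigitation is 0 for contained chains and exact for planted 0.5", {
  ens <- mini_ensemble(base_coords)
  expect_equal(interdigitation_fraction(ens, "GM1", "sphingosine")$value, 0)
  cross_all <- function(f) list(sphingosine = list(fraction = f, jitter = FALSE),
                                acyl = list(fraction = f, jitter = FALSE))
  tr <- bilayer_truth(crossing = list(GM1 = cross_all(0.5),
                                      POPS = cross_all(0.5)))
  ens2 <- simulate_bilayer_ensemble(tr, n_frames = 5,
                                    composition_upper = c(GM1 = 8),
                                    composition_lower = c(POPS = 8),
                                    chain_length = 16, seed = 5)
  expect_identical(interdigitation_fraction(ens2, "GM1", "sphingosine")$value,
                   0.5)
  expect_identical(interdigitation_fraction(ens2, "POPS", "acyl")$value, 0.5)
  expect_error(interdigitation_fraction(ens2, "DOPC", "acyl"), "absent")
})

test_that("binomial planted crossing is recovered within 1%", {
  cross_all <- function(f) list(sphingosine = list(fraction = f, jitter = TRUE),
                                acyl = list(fraction = f, jitter = TRUE))
  tr <- bilayer_truth(crossing = list(GM1 = cross_all(0.3),
                                      POPS = cross_all(0.3)))
  ens <- simulate_bilayer_ensemble(tr, n_frames = 400,
                                   composition_upper = c(GM1 = 9),
                                   composition_lower = c(POPS = 9),
                                   chain_length = 16, seed = 6)
  expect_equal(interdigitation_fraction(ens, "GM1", "acyl")$value, 0.3,
               tolerance = 0.01 / 0.3)
})

test_that("trans-bilayer contacts match single-pair construction and the oracle", {
  # no contacts in the separated base geometry at a tight cutoff
  ens0 <- mini_ensemble(base_coords)
  expect_identical(transbilayer_contacts(ens0, "GM1", "POPS",
                                         cutoff = 0.2)$contacts_per_frame, 0L)
  # one constructed pair at 0.3 nm
  ens1 <- mini_ensemble(function(atoms, f) {
    xyz <- base_coords(atoms, f)
    xyz[atoms$lipid_id == 1 & atoms$atom == "A4", ] <- c(4, 4, 0.15)
    xyz[atoms$lipid_id == 3 & atoms$atom == "A4", ] <- c(4, 4, -0.15)
    xyz
  })
  ct <- transbilayer_contacts(ens1, "GM1", "POPS", cutoff = 0.35)
  expect_identical(ct$contacts_per_frame, 1L)
  expect_equal(ct$normalized_coupling, 0.5)   # 2 upper GM1 lipids
  # planted-contact simulation equals brute-force O(n^2) enumeration
  tr <- bilayer_truth(planted_contacts = 3)
  ens2 <- simulate_bilayer_ensemble(tr, n_frames = 3,
                                    composition_upper = c(GM1 = 6),
                                    composition_lower = c(POPS = 6),
                                    chain_length = 6, seed = 7)
  got <- transbilayer_contacts(ens2, "GM1", "POPS", cutoff = 0.4)
  rows_a <- with(ens2$atoms, which(species == "GM1" & leaflet == "upper" &
                                     grepl("^[SA]", atom)))
  rows_b <- with(ens2$atoms, which(species == "POPS" & leaflet == "lower" &
                                     grepl("^[SA]", atom)))
  for (f in 1:3) {
    expect_identical(got$contacts_per_frame[f],
                     oracle_contacts(ens2$coords[rows_a, , f],
                                     ens2$coords[rows_b, , f], 0.4,
                                     ens2$box))
  }
  expect_gte(min(got$contacts_per_frame), 3L)
})

test_that("Voronoi areas: lattice symmetry, conservation, replica-tiling oracle", {
  # 4 points on a square lattice in a 2L x 2L box -> each cell L^2
  L <- 3
  xy <- cbind(c(L / 2, 3 * L / 2, L / 2, 3 * L / 2),
              c(L / 2, L / 2, 3 * L / 2, 3 * L / 2))
  ar <- periodic_voronoi_areas(xy, 2 * L, 2 * L)
  expect_equal(ar, rep(L^2, 4))
  # random configurations conserve total area
  set.seed(13)
  for (rep in 1:3) {
    n <- 60
    pts <- cbind(runif(n, 0, 10), runif(n, 0, 8))
    areas <- periodic_voronoi_areas(pts, 10, 8)
    expect_equal(sum(areas), 80, tolerance = 1e-9)
    expect_true(all(areas > 0))
  }
  # coincident generators are perturbed with a warning, not an error
  expect_warning(periodic_voronoi_areas(rbind(xy, xy[1, ]), 2 * L, 2 * L),
                 "coincident")
})

test_that("area_per_lipid averages Voronoi cells per species and conserves area", {
  tr <- bilayer_truth()
  ens <- simulate_bilayer_ensemble(tr, n_frames = 3,
                                   composition_upper = c(GM1 = 9, DOPC = 7),
                                   composition_lower = c(POPS = 16),
                                   chain_length = 4, seed = 8)
  apl <- area_per_lipid(ens, "upper")
  expect_identical(nrow(apl$per_lipid), 16L)
  expect_equal(sum(apl$per_lipid$area),
               ens$box[1] * ens$box[2], tolerance = 1e-9)
  expect_setequal(apl$per_species$species, c("GM1", "DOPC"))
})

test_that("S_CD is -0.5 for aligned all-trans chains and ~0 for isotropic ones", {
  tr <- bilayer_truth()
  ens <- simulate_bilayer_ensemble(tr, n_frames = 2,
                                   composition_upper = c(GM1 = 4),
                                   composition_lower = c(POPS = 4),
                                   chain_length = 8, seed = 9)
  prof <- chain_order_parameter(ens, "GM1", "acyl")
  expect_equal(prof$s_cd, rep(-0.5, nrow(prof)))
  # magic-angle C-H bonds give S_CD = 0: rotate the aligned case analytically
  magic <- (3 * cos(54.7356 * pi / 180)^2 - 1) / 2
  expect_equal(magic, 0, tolerance = 1e-6)
  tri <- bilayer_truth(chain_orientation = "isotropic")
  ens2 <- simulate_bilayer_ensemble(tri, n_frames = 40,
                                    composition_upper = c(GM1 = 25),
                                    composition_lower = c(POPS = 25),
                                    chain_length = 8, seed = 10)
  prof2 <- chain_order_parameter(ens2, "GM1", "acyl")
  expect_lt(max(abs(prof2$s_cd)), 0.02)
  expect_error(chain_order_parameter(
    mini_ensemble(base_coords), "GM1", "nosuch"))
})

test_that("metrics are invariant under box translation, frame order and z-rotation", {
  cross_all <- list(sphingosine = list(fraction = 0.4, jitter = FALSE),
                    acyl = list(fraction = 0.4, jitter = FALSE))
  tr <- bilayer_truth(crossing = list(GM1 = cross_all, POPS = cross_all))
  ens <- simulate_bilayer_ensemble(tr, n_frames = 4,
                                   composition_upper = c(GM1 = 9),
                                   composition_lower = c(POPS = 9),
                                   chain_length = 8, seed = 12)
  v0 <- interdigitation_fraction(ens, "GM1", "acyl")$value
  c0 <- transbilayer_contacts(ens, "GM1", "POPS")$contacts_per_frame
  s0 <- sigma_theta(headgroup_angle_series(ens, bound_ids = 1:3))
  # translate all coordinates by one box vector
  shifted <- ens
  shifted$coords[, 1, ] <- shifted$coords[, 1, ] + ens$box[1]
  expect_identical(interdigitation_fraction(shifted, "GM1", "acyl")$value, v0)
  expect_identical(transbilayer_contacts(shifted, "GM1",
                                         "POPS")$contacts_per_frame, c0)
  # reorder frames
  perm <- ens
  perm$coords <- perm$coords[, , c(3, 1, 4, 2)]
  expect_identical(interdigitation_fraction(perm, "GM1", "acyl")$value, v0)
  expect_equal(sigma_theta(headgroup_angle_series(perm,
                                                  bound_ids = 1:3))$ratio,
               s0$ratio)
  # rotate 90 degrees about z (square box)
  rot <- ens
  xy <- rot$coords[, 1:2, , drop = FALSE]
  rot$coords[, 1, ] <- -xy[, 2, ] + ens$box[1]
  rot$coords[, 2, ] <- xy[, 1, ]
  expect_equal(interdigitation_fraction(rot, "GM1", "acyl")$value, v0)
  expect_equal(sigma_theta(headgroup_angle_series(rot,
                                                  bound_ids = 1:3))$ratio,
               s0$ratio, tolerance = 1e-9)
})
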