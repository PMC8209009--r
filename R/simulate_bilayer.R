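#' Default species schema for synthetic GM1 bilayers
#'
#' Atom-group schema used by the bilayer simulator and readers. GM1 carries
#' a headgroup base atom `HG0`, three vector tip atoms `HG1`-`HG3` (the three
#' headgroup vectors are `HG0->HG1`, `HG0->HG2`, `HG0->HG3`), a sphingosine
#' chain `S1..S<L>` and an acyl chain `A1..A<L>`, both ordered from the
#' backbone outward. The phospholipids (DOPC, POPC, POPS, POPE) carry two
#' acyl chains `S*` and `A*` and the anchor `HG0`. The vector-defining atoms
#' are a simulator convention (the three sugar-ring anchor pairs of real GM1
#' are not modeled atomistically here).
#'
#' @param chain_length Carbons per chain (default 16).
#' @param species Species to include.
#' @return A named schema list, one entry per species.
#' @export
default_gm1_schema <- function(chain_length = 16,
                               species = c("GM1", "DOPC", "POPS", "POPE")) {
  chains <- list(sphingosine = paste0("S", seq_len(chain_length)),
                 acyl = paste0("A", seq_len(chain_length)))
  out <- lapply(species, function(sp) {
    sch <- list(anchor = "HG0", chains = chains)
    if (sp == "GM1")
      sch$headgroup_vectors <- list(V1 = c("HG0", "HG1"),
                                    V2 = c("HG0", "HG2"),
                                    V3 = c("HG0", "HG3"))
    sch
  })
  names(out) <- species
  out
}

#' Bilayer ground truth
#'
#' Parameter record for [simulate_bilayer_ensemble()]. Headgroup vectors of
#' bound lipids fluctuate with SD `head_sd_bound_deg` about
#' `head_mean_deg`, unbound ones with `head_sd_unbound_deg` (defaults 3 and
#' 9 degrees: the 3x contrast of the toxin-restrained regime). `crossing`
#' plants per-species, per-chain interdigitation: the expected fraction of
#' chain carbons past the midplane, realized either deterministically
#' (`jitter = FALSE`, exact planted value) or as per-frame binomial draws.
#'
#' @param head_mean_deg Mean headgroup vector angle to the normal (degrees).
#' @param head_sd_bound_deg,head_sd_unbound_deg Angular SDs (degrees).
#' @param crossing Named list per species of named list per chain of
#'   `list(fraction =, jitter =)`; species/chains not listed do not cross.
#' @param chain_orientation `"straight"` (all-trans chains along the normal)
#'   or `"isotropic"` (each lipid's chains rigidly and uniformly rotated per
#'   frame; used to probe orientation-sensitive statistics).
#' @param planted_contacts Number of upper-GM1/lower-species terminal-atom
#'   pairs placed 0.3 nm apart each frame (default 0).
#' @param jitter_sd_nm Per-frame in-plane anchor jitter SD (default 0.05).
#' @return A list of class `bilayer_truth`.
#' @export
bilayer_truth <- function(head_mean_deg = 30,
                          head_sd_bound_deg = 3, head_sd_unbound_deg = 9,
                          crossing = list(),
                          chain_orientation = c("straight", "isotropic"),
                          planted_contacts = 0,
                          jitter_sd_nm = 0.05) {
  chain_orientation <- match.arg(chain_orientation)
  stopifnot(head_sd_bound_deg >= 0, head_sd_unbound_deg >= 0)
  for (sp in crossing) for (ch in sp)
    if (ch$fraction < 0 || ch$fraction > 1)
      stop("crossing fraction must lie in [0, 1]")
  structure(list(head_mean_deg = head_mean_deg,
                 head_sd_bound_deg = head_sd_bound_deg,
                 head_sd_unbound_deg = head_sd_unbound_deg,
                 crossing = crossing,
                 chain_orientation = chain_orientation,
                 planted_contacts = planted_contacts,
                 jitter_sd_nm = jitter_sd_nm),
            class = "bilayer_truth")
}

rand_rotation <- function() {
  # uniform random rotation via a random unit quaternion
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Simulate a bilayer coordinate ensemble with planted metric truths
#'
#' Builds an asymmetric two-leaflet coordinate ensemble that stands in for
#' all-atom MD snapshots (synthetic; no dynamics). Anchors sit on a jittered
#' lattice per leaflet (spacing 0.8 nm, a realistic ~64 A^2 area per lipid);
#' each lipid carries two all-trans zig-zag chains directed along the normal
#' with a 0.127 nm rise per carbon; per frame, the number of chain carbons
#' past the midplane is drawn from the planted crossing distribution (the
#' two leaflets are built mirror-symmetrically, so the terminal-carbon
#' midplane sits at z = 0 and deterministic planted fractions are recovered
#' exactly). GM1 headgroup vectors are drawn per frame with the planted
#' per-group angular SDs. All truths and the seed are recorded in the
#' returned ensemble's `truth` attribute.
#'
#' @param truth A [bilayer_truth()].
#' @param n_frames Number of frames.
#' @param composition_upper,composition_lower Named integer vectors of
#'   lipids per species (defaults emulate an 18-GM1 asymmetric patch).
#' @param bound_ids Lipid ids treated as toxin-bound for headgroup
#'   fluctuations (default 1:5, the five binding sites of one pentamer).
#' @param chain_length Carbons per chain (default 16).
#' @param schema Species schema (default [default_gm1_schema()]).
#' @param seed Integer RNG seed.
#' @return A [bilayer_ensemble()] with attribute `truth`.
#' @export
simulate_bilayer_ensemble <- function(truth = bilayer_truth(),
                                      n_frames = 100,
                                      composition_upper = c(GM1 = 18, DOPC = 18),
                                      composition_lower = c(POPS = 18, POPE = 18),
                                      bound_ids = 1:5,
                                      chain_length = 16,
                                      schema = NULL,
                                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(schema))
    schema <- default_gm1_schema(chain_length,
                                 species = unique(c(names(composition_upper),
                                                    names(composition_lower))))
  stopifnot(all(composition_upper > 0) || all(composition_lower > 0),
            n_frames >= 1, chain_length >= 3)
  a_lat <- 0.8                       # lattice spacing, nm
  dz <- 0.127                        # z rise per carbon, nm
  n_up <- sum(composition_upper); n_lo <- sum(composition_lower)
  ngrid <- ceiling(sqrt(max(n_up, n_lo)))
  box <- c(ngrid * a_lat, ngrid * a_lat, 10)

  lat_positions <- function(n) {
    g <- ceiling(sqrt(n))
    i <- (seq_len(n) - 1) %% g
    j <- (seq_len(n) - 1) %/% g
    cbind((i + 0.5) * box[1] / g, (j + 0.5) * box[2] / g)
  }

  # topology
  lipids <- data.frame(
    lipid_id = seq_len(n_up + n_lo),
    species = c(rep(names(composition_upper), composition_upper),
                rep(names(composition_lower), composition_lower)),
    leaflet = c(rep("upper", n_up), rep("lower", n_lo)))
  atoms_list <- lapply(seq_len(nrow(lipids)), function(i) {
    sp <- lipids$species[i]
    nm <- c(schema[[sp]]$anchor,
            if (!is.null(schema[[sp]]$headgroup_vectors))
              unique(unlist(schema[[sp]]$headgroup_vectors)),
            unlist(schema[[sp]]$chains))
    nm <- unique(nm)
    data.frame(atom = nm, lipid_id = lipids$lipid_id[i],
               species = sp, leaflet = lipids$leaflet[i])
  })
  atoms <- do.call(rbind, atoms_list)
  natoms <- nrow(atoms)
  coords <- array(0, dim = c(natoms, 3, n_frames))

  anchors0 <- rbind(lat_positions(n_up), lat_positions(n_lo))
  anchor_z <- ifelse(lipids$leaflet == "upper", 1, -1) * (chain_length * dz + 0.4)
  crossing_spec <- function(sp, ch) {
    cs <- truth$crossing[[sp]][[ch]]
    if (is.null(cs)) list(fraction = 0, jitter = FALSE) else cs
  }

  hg_len <- 0.5
  for (f in seq_len(n_frames)) {
    jit <- matrix(rnorm(2 * nrow(lipids), 0, truth$jitter_sd_nm), ncol = 2)
    axy <- cbind(wrap_into(anchors0[, 1] + jit[, 1], 0, box[1]),
                 wrap_into(anchors0[, 2] + jit[, 2], 0, box[2]))
    for (i in seq_len(nrow(lipids))) {
      lid <- lipids$lipid_id[i]; sp <- lipids$species[i]
      up <- lipids$leaflet[i] == "upper"
      sgn <- if (up) 1 else -1
      rows <- which(atoms$lipid_id == lid)
      anames <- atoms$atom[rows]
      base <- c(axy[i, ], sgn * abs(anchor_z[i]))
      coords[rows[anames == "HG0"], , f] <- base
      if (!is.null(schema[[sp]]$headgroup_vectors)) {
        sd_deg <- if (lid %in% bound_ids) truth$head_sd_bound_deg
                  else truth$head_sd_unbound_deg
        for (vi in 1:3) {
          th <- abs(rnorm(1, truth$head_mean_deg, sd_deg)) * pi / 180
          ph <- runif(1, 0, 2 * pi)
          tip <- base + hg_len * c(sin(th) * cos(ph), sin(th) * sin(ph),
                                   cos(th)) * c(1, 1, sgn)
          coords[rows[anames == paste0("HG", vi)], , f] <- tip
        }
      }
      chs <- names(schema[[sp]]$chains)
      local_chain <- vector("list", length(chs))
      for (ci in seq_along(chs)) {
        cs <- crossing_spec(sp, chs[ci])
        ncross <- if (cs$jitter) rbinom(1, chain_length, cs$fraction)
                  else round(chain_length * cs$fraction)
        k <- seq_len(chain_length)
        z <- sgn * (dz * (chain_length - k) - (ncross - 0.5) * dz)
        x <- (ci - 1.5) * 0.25 + ((-1)^k) * 0.05
        local_chain[[ci]] <- cbind(x, 0, z)
      }
      chain_xyz <- do.call(rbind, local_chain)
      if (truth$chain_orientation == "isotropic") {
        ctr <- colMeans(chain_xyz)
        chain_xyz <- sweep(sweep(chain_xyz, 2, ctr) %*% t(rand_rotation()),
                           2, ctr, `+`)
      }
      chain_xyz[, 1] <- chain_xyz[, 1] + axy[i, 1]
      chain_xyz[, 2] <- chain_xyz[, 2] + axy[i, 2]
      for (ci in seq_along(chs)) {
        cn <- schema[[sp]]$chains[[chs[ci]]]
        ridx <- rows[match(cn, anames)]
        coords[ridx, , f] <-
          chain_xyz[(ci - 1) * chain_length + seq_len(chain_length), ]
      }
    }
    if (truth$planted_contacts > 0) {
      up_gm1 <- lipids$lipid_id[lipids$species == "GM1" &
                                  lipids$leaflet == "upper"]
      lo_ids <- lipids$lipid_id[lipids$leaflet == "lower"]
      np <- min(truth$planted_contacts, length(up_gm1), length(lo_ids))
      for (p in seq_len(np)) {
        ra <- which(atoms$lipid_id == up_gm1[p] &
                      atoms$atom == paste0("A", chain_length))
        rb <- which(atoms$lipid_id == lo_ids[p] &
                      atoms$atom == paste0("A", chain_length))
        pos <- c(runif(1, 0, box[1]), runif(1, 0, box[2]), -0.05)
        coords[ra, , f] <- pos + c(0, 0, 0.15)
        coords[rb, , f] <- pos - c(0, 0, 0.15)
      }
    }
  }
  ens <- bilayer_ensemble(atoms, coords, box, schema)
  attr(ens, "truth") <- c(unclass(truth),
                          list(composition_upper = composition_upper,
                               composition_lower = composition_lower,
                               bound_ids = bound_ids,
                               chain_length = chain_length, seed = seed))
  ens
}
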