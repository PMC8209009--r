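#' Bilayer coordinate ensemble
#'
#' Container for post-hoc analysis of membrane snapshots: a fixed atom
#' topology plus per-frame coordinates in nm, with the bilayer midplane near
#' z = 0 and the bilayer normal along +z. This stands in for all-atom MD
#' trajectory frames; the package analyses coordinates only and runs no
#' dynamics.
#'
#' @param atoms `data.frame` with columns `atom` (name), `lipid_id`,
#'   `species`, `leaflet` (`"upper"`/`"lower"`), one row per atom.
#' @param coords Numeric array `n_atoms x 3 x n_frames` (nm).
#' @param box Length-3 periodic box lengths in nm (positive).
#' @param schema Per-species atom-group schema: a named list whose entries
#'   have fields `anchor` (atom name), `chains` (named list of ordered
#'   carbon-atom name vectors, from backbone outward; names typically
#'   `sphingosine` and `acyl`) and optionally `headgroup_vectors` (named list
#'   of `c(base_atom, tip_atom)` pairs). See [default_gm1_schema()].
#' @return An object of class `bilayer_ensemble`.
#' @export
bilayer_ensemble <- function(atoms, coords, box, schema) {
  stopifnot(is.data.frame(atoms),
            all(c("atom", "lipid_id", "species", "leaflet") %in% names(atoms)),
            length(dim(coords)) == 3, dim(coords)[1] == nrow(atoms),
            dim(coords)[2] == 3, length(box) == 3, all(box > 0))
  if (!all(atoms$leaflet %in% c("upper", "lower")))
    stop("leaflet labels must be 'upper' or 'lower'")
  for (lid in unique(atoms$lipid_id)) {
    sp <- atoms$species[atoms$lipid_id == lid][1]
    sch <- schema[[sp]]
    if (is.null(sch)) stop(sprintf("species '%s' missing from schema", sp))
    chain_atoms <- unlist(sch$chains)
    if (!any(atoms$atom[atoms$lipid_id == lid] %in% chain_atoms))
      stop(sprintf("lipid %s has no chain atoms", lid))
  }
  structure(list(atoms = atoms, coords = coords, box = as.numeric(box),
                 schema = schema),
            class = "bilayer_ensemble")
}

#' @export
print.bilayer_ensemble <- function(x, ...) {
  cat(sprintf("bilayer_ensemble: %d atoms, %d lipids, %d frame(s), box %.2f x %.2f x %.2f nm\n",
              nrow(x$atoms), length(unique(x$atoms$lipid_id)),
              dim(x$coords)[3], x$box[1], x$box[2], x$box[3]))
  sp <- table(x$atoms$species[!duplicated(x$atoms$lipid_id)])
  cat("  species:", paste(sprintf("%s (%d)", names(sp), sp), collapse = ", "),
      "\n")
  invisible(x)
}

n_frames <- function(ensemble) dim(ensemble$coords)[3]

min_image <- function(v, box) v - box * round(v / box)

# Row indices of named atoms for one lipid; errors name lipid and atom.
lipid_atom_rows <- function(ensemble, lipid_id, atom_names) {
  rows <- which(ensemble$atoms$lipid_id == lipid_id)
  idx <- rows[match(atom_names, ensemble$atoms$atom[rows])]
  if (anyNA(idx)) {
    missing <- atom_names[is.na(match(atom_names, ensemble$atoms$atom[rows]))]
    stop(sprintf("schema error: lipid %s lacks atom(s) %s",
                 lipid_id, paste(missing, collapse = ", ")))
  }
  idx
}

lipids_of_species <- function(ensemble, species, leaflet = NULL) {
  a <- ensemble$atoms[!duplicated(ensemble$atoms$lipid_id), ]
  keep <- a$species == species
  if (!is.null(leaflet)) keep <- keep & a$leaflet == leaflet
  a$lipid_id[keep]
}

#' Headgroup vector angle time series
#'
#' For each GM1 (or other species carrying headgroup vectors) lipid and each
#' defined headgroup vector, computes the per-frame angle between the vector
#' and the bilayer normal (+z), using the minimum-image convention for the
#' vector construction across periodic boundaries. Lipids in `bound_ids`
#' (e.g. CTxB-contacting lipids) are labeled `"bound"`, the rest `"unbound"`;
#' the bound/unbound contrast feeds [sigma_theta()].
#'
#' @param ensemble A [bilayer_ensemble()].
#' @param spec Named list of `c(base_atom, tip_atom)` pairs; default: the
#'   `headgroup_vectors` entry of the species schema.
#' @param bound_ids Lipid ids in contact with the toxin (may be empty).
#' @param species Species carrying the vectors (default `"GM1"`).
#' @return `data.frame` with columns `lipid_id`, `vector`, `frame`,
#'   `theta_deg` (in `[0, 180]`), `group`.
#' @export
headgroup_angle_series <- function(ensemble, spec = NULL,
                                   bound_ids = integer(0), species = "GM1") {
  if (is.null(spec)) spec <- ensemble$schema[[species]]$headgroup_vectors
  if (is.null(spec)) stop(sprintf("no headgroup vectors defined for %s", species))
  lids <- lipids_of_species(ensemble, species)
  if (!all(bound_ids %in% lids))
    stop("bound_ids must be a subset of the species' lipid ids")
  nf <- n_frames(ensemble)
  out <- vector("list", length(lids) * length(spec))
  k <- 0
  for (lid in lids) {
    for (vn in names(spec)) {
      idx <- lipid_atom_rows(ensemble, lid, spec[[vn]])
      v <- ensemble$coords[idx[2], , ] - ensemble$coords[idx[1], , ]
      v <- matrix(v, nrow = 3)            # 3 x nf
      for (d in 1:3) v[d, ] <- min_image(v[d, ], ensemble$box[d])
      nrm <- sqrt(colSums(v^2))
      theta <- acos(pmin(pmax(v[3, ] / nrm, -1), 1)) * 180 / pi
      k <- k + 1
      out[[k]] <- data.frame(
        lipid_id = lid, vector = vn, frame = seq_len(nf),
        theta_deg = theta,
        group = if (lid %in% bound_ids) "bound" else "unbound")
    }
  }
  do.call(rbind, out)
}

#' Headgroup angular fluctuation sigma-theta
#'
#' The fluctuation statistic sigma_theta is the sample SD over frames of the
#' angle between each headgroup vector and the bilayer normal, computed per
#' (lipid, vector) and averaged within the bound and unbound groups. Toxin
#' binding restrains the headgroup, so the unbound/bound ratio exceeds 1
#' (reported 2-4x in the reference regime).
#'
#' @param series Output of [headgroup_angle_series()] (>= 2 frames per lipid).
#' @return List with `table` (per vector and group: mean sigma_theta in
#'   degrees, number of lipids), `ratio` (named per-vector unbound/bound
#'   ratio, `NA` when a group is empty) and `ratio_overall`.
#' @export
sigma_theta <- function(series) {
  if (min(table(paste(series$lipid_id, series$vector))) < 2)
    stop("sigma_theta requires at least 2 frames per series")
  per <- aggregate(theta_deg ~ lipid_id + vector + group, data = series,
                   FUN = sd)
  names(per)[names(per) == "theta_deg"] <- "sigma_theta"
  tab <- aggregate(sigma_theta ~ vector + group, data = per, FUN = mean)
  cnt <- aggregate(sigma_theta ~ vector + group, data = per, FUN = length)
  tab$n_lipids <- cnt$sigma_theta
  ratio <- sapply(unique(tab$vector), function(vn) {
    b <- tab$sigma_theta[tab$vector == vn & tab$group == "bound"]
    u <- tab$sigma_theta[tab$vector == vn & tab$group == "unbound"]
    if (length(b) == 0 || length(u) == 0) return(NA_real_)
    u / b
  })
  names(ratio) <- unique(tab$vector)
  if (anyNA(ratio))
    warning("a group has no lipids; ratio undefined for some vectors")
  list(table = tab, ratio = ratio,
       ratio_overall = mean(ratio, na.rm = FALSE))
}

chain_rows_by_lipid <- function(ensemble, species, chain, leaflet = NULL) {
  lids <- lipids_of_species(ensemble, species, leaflet)
  if (length(lids) == 0) stop(sprintf("species '%s' absent", species))
  sch <- ensemble$schema[[species]]
  atoms <- sch$chains[[chain]]
  if (is.null(atoms)) stop(sprintf("chain '%s' not defined for %s", chain, species))
  lapply(stats::setNames(lids, lids),
         function(l) lipid_atom_rows(ensemble, l, atoms))
}

# Per-frame bilayer midplane: z center of mass of all terminal chain carbons.
# Robust to leaflet asymmetry (unlike the fixed box center).
midplane_z <- function(ensemble) {
  term_rows <- integer(0)
  for (lid in unique(ensemble$atoms$lipid_id)) {
    sp <- ensemble$atoms$species[ensemble$atoms$lipid_id == lid][1]
    for (ch in ensemble$schema[[sp]]$chains) {
      term_rows <- c(term_rows,
                     lipid_atom_rows(ensemble, lid, ch[length(ch)]))
    }
  }
  colMeans(matrix(ensemble$coords[term_rows, 3, ], nrow = length(term_rows)))
}

#' Chain interdigitation fraction
#'
#' Quantifies penetration of one leaflet's chains past the bilayer midplane
#' into the opposing leaflet: per frame, the fraction of the chain's carbon
#' atoms lying beyond the midplane (z below it for upper-leaflet lipids,
#' above it for lower-leaflet lipids), averaged over the species' lipids and
#' over frames. The midplane is the per-frame z center of mass of all
#' terminal chain carbons. Bounded in `[0, 1]` and monotone in penetration
#' depth.
#'
#' @param ensemble A [bilayer_ensemble()].
#' @param species Species label (must be present).
#' @param chain `"sphingosine"` or `"acyl"` (any chain named in the schema).
#' @return An object of class `interdigitation_result`: list with `chain`,
#'   `species`, `value` (time-averaged fraction) and `per_frame` series.
#' @export
interdigitation_fraction <- function(ensemble, species,
                                     chain = c("sphingosine", "acyl")) {
  chain <- if (length(chain) > 1) chain[1] else chain
  rows <- chain_rows_by_lipid(ensemble, species, chain)
  lids <- names(rows)
  leaf <- ensemble$atoms$leaflet[match(lids,
                                       as.character(ensemble$atoms$lipid_id))]
  mid <- midplane_z(ensemble)
  nf <- n_frames(ensemble)
  per_lipid <- sapply(seq_along(rows), function(i) {
    z <- matrix(ensemble$coords[rows[[i]], 3, ], nrow = length(rows[[i]]))
    crossed <- if (leaf[i] == "upper") sweep(z, 2, mid, `<`)
               else sweep(z, 2, mid, `>`)
    colMeans(crossed)
  })                                       # nf x n_lipids
  per_frame <- rowMeans(matrix(per_lipid, nrow = nf))
  structure(list(chain = chain, species = species,
                 value = mean(per_frame), per_frame = per_frame),
            class = "interdigitation_result")
}

#' @export
print.interdigitation_result <- function(x, ...) {
  cat(sprintf("interdigitation (%s, %s chain): %.3f over %d frame(s)\n",
              x$species, x$chain, x$value, length(x$per_frame)))
  invisible(x)
}

#' Trans-bilayer chain contacts
#'
#' Counts inter-leaflet heavy-atom contacts between the chain atoms of an
#' upper-leaflet species and those of a lower-leaflet species: pairs within
#' `cutoff` nm under minimum-image distances, per frame, normalized per
#' lipid of the upper species. This is the contact-count reading of
#' trans-bilayer coupling (e.g. GM1-POPS versus GM1-POPE).
#'
#' @param ensemble A [bilayer_ensemble()].
#' @param species_a Upper-leaflet species (e.g. `"GM1"`).
#' @param species_b Lower-leaflet species (e.g. `"POPS"`).
#' @param cutoff Heavy-atom contact cutoff in nm (default 0.4).
#' @return An object of class `coupling_result`: list with `pair_label`,
#'   `contacts_per_frame` and `normalized_coupling` (mean contacts per
#'   `species_a` lipid per frame).
#' @export
transbilayer_contacts <- function(ensemble, species_a, species_b,
                                  cutoff = 0.4) {
  stopifnot(cutoff > 0)
  rows_a <- unlist(lapply(names(ensemble$schema[[species_a]]$chains),
                          function(ch) unlist(chain_rows_by_lipid(
                            ensemble, species_a, ch, leaflet = "upper"))))
  rows_b <- unlist(lapply(names(ensemble$schema[[species_b]]$chains),
                          function(ch) unlist(chain_rows_by_lipid(
                            ensemble, species_b, ch, leaflet = "lower"))))
  n_a_lipids <- length(lipids_of_species(ensemble, species_a, "upper"))
  nf <- n_frames(ensemble)
  counts <- vapply(seq_len(nf), function(f) {
    cpp_min_image_contacts(ensemble$coords[rows_a, , f, drop = FALSE][, , 1],
                           ensemble$coords[rows_b, , f, drop = FALSE][, , 1],
                           cutoff, ensemble$box)
  }, integer(1))
  structure(list(pair_label = paste0(species_a, "-", species_b),
                 contacts_per_frame = counts,
                 normalized_coupling = mean(counts) / n_a_lipids,
                 cutoff = cutoff),
            class = "coupling_result")
}

#' @export
print.coupling_result <- function(x, ...) {
  cat(sprintf("%s trans-bilayer contacts: %.2f per frame (%.3f per lipid), cutoff %.2f nm\n",
              x$pair_label, mean(x$contacts_per_frame),
              x$normalized_coupling, x$cutoff))
  invisible(x)
}

#' Voronoi area per lipid
#'
#' Tessellates the (x, y) anchor-atom positions of one leaflet with a
#' periodic 2-D Voronoi diagram (ghost replicas across the box boundaries)
#' and reports per-lipid cell areas and per-species means, averaged over
#' frames. Cell areas tile the leaflet, so each frame's areas sum to the
#' in-plane box area; this conservation is asserted at every call.
#'
#' @param ensemble A [bilayer_ensemble()] with >= 3 lipids in the leaflet.
#' @param leaflet `"upper"` or `"lower"`.
#' @return An object of class `area_per_lipid_result`: list with `per_lipid`
#'   (`data.frame` of lipid id, species, mean area in nm^2) and `per_species`
#'   (`data.frame` of species, mean area, n lipids).
#' @export
area_per_lipid <- function(ensemble, leaflet = c("upper", "lower")) {
  leaflet <- match.arg(leaflet)
  a <- ensemble$atoms[!duplicated(ensemble$atoms$lipid_id), ]
  a <- a[a$leaflet == leaflet, ]
  if (nrow(a) < 3) stop("need at least 3 lipids in the leaflet")
  anchor_rows <- vapply(seq_len(nrow(a)), function(i) {
    lipid_atom_rows(ensemble, a$lipid_id[i],
                    ensemble$schema[[a$species[i]]]$anchor)
  }, integer(1))
  nf <- n_frames(ensemble)
  box_area <- ensemble$box[1] * ensemble$box[2]
  acc <- matrix(0, nrow(a), nf)
  for (f in seq_len(nf)) {
    xy <- ensemble$coords[anchor_rows, 1:2, f]
    ar <- periodic_voronoi_areas(xy, ensemble$box[1], ensemble$box[2])
    if (abs(sum(ar) - box_area) > 1e-6 * box_area)
      stop("Voronoi areas do not tile the box (conservation violated)")
    acc[, f] <- ar
  }
  per_lipid <- data.frame(lipid_id = a$lipid_id, species = a$species,
                          area = rowMeans(acc))
  per_species <- aggregate(area ~ species, data = per_lipid, FUN = mean)
  per_species$n_lipids <- as.integer(table(per_lipid$species)[per_species$species])
  structure(list(per_lipid = per_lipid, per_species = per_species,
                 leaflet = leaflet),
            class = "area_per_lipid_result")
}

#' @export
print.area_per_lipid_result <- function(x, ...) {
  cat(sprintf("area per lipid (%s leaflet):\n", x$leaflet))
  print(x$per_species, row.names = FALSE)
  invisible(x)
}

# Ideal-geometry C-H unit vectors at carbon k from carbons k-1, k, k+1.
# Returns a 2 x 3 matrix; the two H directions lie in the plane spanned by
# the inverted C-C bisector and the normal to the C-C-C plane, at the
# tetrahedral half-angle.
ch_vectors <- function(cm1, c0, cp1) {
  a <- cm1 - c0; b <- cp1 - c0
  s <- a / sqrt(sum(a^2)) + b / sqrt(sum(b^2))
  ns <- sqrt(sum(s^2))
  tcr <- c(a[2] * b[3] - a[3] * b[2],
           a[3] * b[1] - a[1] * b[3],
           a[1] * b[2] - a[2] * b[1])
  nt <- sqrt(sum(tcr^2))
  if (ns < 1e-10 || nt < 1e-10)
    stop("degenerate (collinear) carbon geometry; cannot place hydrogens")
  s <- s / ns; tcr <- tcr / nt
  half <- 54.7356 * pi / 180
  rbind(-s * cos(half) + tcr * sin(half),
        -s * cos(half) - tcr * sin(half))
}

#' Acyl-chain order parameter profile S_CD
#'
#' The carbon-deuterium (C-H) bond order parameter per chain carbon,
#' \deqn{S_{CD}(k) = \langle (3\cos^2\theta_{CH} - 1)/2 \rangle}
#' averaged over frames, lipids and the two methylene hydrogens, with
#' theta_CH the angle between the C-H bond and the bilayer normal (+z).
#' Hydrogens are reconstructed from heavy-atom geometry (ideal tetrahedral
#' construction from three consecutive chain carbons), so the profile covers
#' carbons 2 .. L-1. S_CD is -0.5 for an all-trans chain aligned with the
#' normal and 0 for isotropic orientations.
#'
#' @param ensemble A [bilayer_ensemble()].
#' @param species Species label.
#' @param chain `"sphingosine"` or `"acyl"`.
#' @return `data.frame` with columns `carbon` (index along the chain) and
#'   `s_cd`.
#' @export
chain_order_parameter <- function(ensemble, species,
                                  chain = c("sphingosine", "acyl")) {
  chain <- if (length(chain) > 1) chain[1] else chain
  rows <- chain_rows_by_lipid(ensemble, species, chain)
  L <- length(rows[[1]])
  if (L < 3) stop("chain must have at least 3 carbons")
  nf <- n_frames(ensemble)
  sums <- numeric(L - 2); nobs <- 0
  for (idx in rows) {
    for (f in seq_len(nf)) {
      xyz <- ensemble$coords[idx, , f]
      for (k in 2:(L - 1)) {
        hv <- ch_vectors(xyz[k - 1, ], xyz[k, ], xyz[k + 1, ])
        cz2 <- hv[, 3]^2      # unit vectors: cos(theta) = z component
        sums[k - 1] <- sums[k - 1] + sum((3 * cz2 - 1) / 2)
      }
    }
    nobs <- nobs + 2 * nf
  }
  data.frame(carbon = 2:(L - 1), s_cd = sums / nobs)
}
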