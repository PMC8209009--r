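#' Read a localization table from CSV
#'
#' Reads SMLM localizations from a headered CSV. The default dialect uses
#' columns `x_nm`, `y_nm` and optional `frame`, `channel`, `precision_nm`;
#' other dialects (e.g. ThunderSTORM's `"x [nm]"`) are handled through
#' `column_map`. Units are normalized to nm via the `unit` directive.
#' Rows with non-finite coordinates are rejected with their line numbers.
#'
#' @param path CSV file path.
#' @param column_map Named list mapping logical fields (`x`, `y`, `frame`,
#'   `channel`, `precision`) to file column names, plus optional
#'   `unit = "nm"` or `"um"` for the coordinate columns.
#' @return A [localization_table()].
#' @export
read_localization_csv <- function(path,
                                  column_map = list(x = "x_nm", y = "y_nm",
                                                    frame = "frame",
                                                    channel = "channel",
                                                    precision = "precision_nm",
                                                    unit = "nm")) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("x", "y")
  for (f in need) {
    if (is.null(column_map[[f]]) || !column_map[[f]] %in% names(df))
      stop(sprintf("schema error: mandatory column '%s' (%s) missing; available: %s",
                   f, column_map[[f]], paste(names(df), collapse = ", ")))
  }
  scale <- switch(column_map$unit %||% "nm", nm = 1, um = 1000,
                  stop("unit must be 'nm' or 'um'"))
  x <- suppressWarnings(as.numeric(df[[column_map$x]])) * scale
  y <- suppressWarnings(as.numeric(df[[column_map$y]])) * scale
  bad <- which(!is.finite(x) | !is.finite(y))
  if (length(bad)) {
    warning(sprintf("rejected %d malformed row(s) at line(s): %s",
                    length(bad), paste(bad + 1, collapse = ", ")))
    keep <- setdiff(seq_along(x), bad)
  } else keep <- seq_along(x)
  getcol <- function(f, scale = 1) {
    nm <- column_map[[f]]
    if (!is.null(nm) && nm %in% names(df)) df[[nm]][keep] else NULL
  }
  prec <- getcol("precision")
  localization_table(x[keep], y[keep],
                     frame = getcol("frame"),
                     channel = getcol("channel"),
                     precision = if (is.null(prec)) NULL
                                 else as.numeric(prec) * scale)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a localization table to CSV
#'
#' Writes the default dialect (`x_nm`, `y_nm`, optional `frame`, `channel`,
#' `precision_nm`), the format [read_localization_csv()] reads back.
#'
#' @param locs A [localization_table()].
#' @param path Output path.
#' @export
write_localization_csv <- function(locs, path) {
  out <- data.frame(x_nm = locs$x, y_nm = locs$y)
  if (!is.null(locs$frame)) out$frame <- locs$frame
  if (!is.null(locs$channel)) out$channel <- locs$channel
  if (!is.null(locs$precision)) out$precision_nm <- locs$precision
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a polarization-resolved TIFF image pair
#'
#' Reads two single-channel 16-bit integer TIFFs (parallel and
#' perpendicular emission), preserving counts exactly.
#'
#' @param parallel_path,perpendicular_path TIFF paths.
#' @param pixel_size Pixel size in nm (from acquisition config).
#' @param background_parallel,background_perpendicular Channel offsets.
#' @return A [polarized_image_pair()].
#' @export
read_image_pair <- function(parallel_path, perpendicular_path,
                            pixel_size = 100,
                            background_parallel = 0,
                            background_perpendicular = 0) {
  rd <- function(p) {
    img <- tiff::readTIFF(p, as.is = TRUE)
    if (length(dim(img)) != 2) stop("expected a single-channel TIFF: ", p)
    img
  }
  pa <- rd(parallel_path); pe <- rd(perpendicular_path)
  if (!identical(dim(pa), dim(pe))) stop("image shapes differ")
  polarized_image_pair(pa, pe, pixel_size = pixel_size,
                       background_parallel = background_parallel,
                       background_perpendicular = background_perpendicular)
}

#' Write a polarization-resolved image pair as 16-bit TIFFs
#'
#' @param pair A [polarized_image_pair()] with integer counts in 0..65535.
#' @param parallel_path,perpendicular_path Output paths.
#' @export
write_image_pair <- function(pair, parallel_path, perpendicular_path) {
  wr <- function(img, p) {
    if (any(img < 0 | img > 65535)) stop("counts outside 16-bit range")
    tiff::writeTIFF(img / 65535, p, bits.per.sample = 16)
  }
  wr(pair$parallel, parallel_path)
  wr(pair$perpendicular, perpendicular_path)
  invisible(c(parallel_path, perpendicular_path))
}

#' Write anisotropy and total-intensity maps as 32-bit float TIFFs
#'
#' TIFF float samples are stored on a [0, 1] scale, so each map is written
#' affinely rescaled with the scale recorded in a JSON sidecar
#' (`<anisotropy_path>.json`); [read_anisotropy_maps()] reverses the
#' transform. Invalid pixels carry anisotropy 0 in the file; validity is
#' recovered from the intensity map (total intensity > 0).
#'
#' @param maps A [compute_anisotropy_maps()] result.
#' @param anisotropy_path,intensity_path Output paths.
#' @export
write_anisotropy_maps <- function(maps, anisotropy_path, intensity_path) {
  scale_of <- function(v) {
    fin <- v[is.finite(v)]
    lo <- min(fin, 0); hi <- max(fin, lo + 1)
    list(lo = lo, hi = hi)
  }
  wr <- function(v, sc, path) {
    v[!is.finite(v)] <- sc$lo
    tiff::writeTIFF((v - sc$lo) / (sc$hi - sc$lo), path, bits.per.sample = 32)
  }
  sr <- scale_of(maps$anisotropy); si <- scale_of(maps$total_intensity)
  wr(maps$anisotropy, sr, anisotropy_path)
  wr(maps$total_intensity, si, intensity_path)
  jsonlite::write_json(list(anisotropy_scale = sr, intensity_scale = si,
                            pixel_size = maps$pixel_size, g = maps$g),
                       paste0(anisotropy_path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(c(anisotropy_path, intensity_path))
}

#' Read anisotropy and total-intensity maps written by [write_anisotropy_maps()]
#'
#' @param anisotropy_path,intensity_path TIFF paths (the JSON sidecar
#'   `<anisotropy_path>.json` must be present).
#' @return An `anisotropy_maps` object.
#' @export
read_anisotropy_maps <- function(anisotropy_path, intensity_path) {
  meta <- jsonlite::read_json(paste0(anisotropy_path, ".json"),
                              simplifyVector = TRUE)
  unscale <- function(path, sc) {
    v <- tiff::readTIFF(path)
    v * (sc$hi - sc$lo) + sc$lo
  }
  itot <- unscale(intensity_path, meta$intensity_scale)
  r <- unscale(anisotropy_path, meta$anisotropy_scale)
  valid <- itot > 0
  r[!valid] <- NA_real_
  structure(list(total_intensity = itot, anisotropy = r, valid_mask = valid,
                 pixel_size = meta$pixel_size, g = meta$g),
            class = "anisotropy_maps")
}

# ---- bilayer coordinate IO ------------------------------------------------

#' Write a bilayer ensemble as GRO frames
#'
#' One fixed-format GRO file per frame (`frame_0001.gro`, ...), coordinates
#' in nm, the box on the final line.
#'
#' @param ensemble A [bilayer_ensemble()].
#' @param dir Output directory (created if needed).
#' @return The written paths, invisibly.
#' @export
write_gro_frames <- function(ensemble, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nf <- dim(ensemble$coords)[3]
  at <- ensemble$atoms
  paths <- character(nf)
  for (f in seq_len(nf)) {
    path <- file.path(dir, sprintf("frame_%04d.gro", f))
    xyz <- ensemble$coords[, , f]
    lines <- c(
      sprintf("synthetic bilayer frame %d", f),
      sprintf("%5d", nrow(at)),
      sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
              at$lipid_id, at$species, at$atom, seq_len(nrow(at)),
              xyz[, 1], xyz[, 2], xyz[, 3]),
      sprintf("%10.5f%10.5f%10.5f", ensemble$box[1], ensemble$box[2],
              ensemble$box[3])
    )
    writeLines(lines, path)
    paths[f] <- path
  }
  invisible(paths)
}

parse_gro <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[2]))
  body <- lines[3:(2 + n)]
  df <- data.frame(
    lipid_id = as.integer(substr(body, 1, 5)),
    species = trimws(substr(body, 6, 10)),
    atom = trimws(substr(body, 11, 15)),
    x = as.numeric(substr(body, 21, 28)),
    y = as.numeric(substr(body, 29, 36)),
    z = as.numeric(substr(body, 37, 44)))
  box <- as.numeric(strsplit(trimws(lines[3 + n]), "\\s+")[[1]])[1:3]
  list(atoms = df, box = box)
}

#' Write a bilayer ensemble as PDB frames
#'
#' One PDB file per frame, coordinates converted from nm to Angstrom.
#'
#' @param ensemble A [bilayer_ensemble()].
#' @param dir Output directory.
#' @return The written paths, invisibly.
#' @export
write_pdb_frames <- function(ensemble, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nf <- dim(ensemble$coords)[3]
  at <- ensemble$atoms
  paths <- character(nf)
  for (f in seq_len(nf)) {
    path <- file.path(dir, sprintf("frame_%04d.pdb", f))
    xyz <- ensemble$coords[, , f] * 10
    lines <- c(
      sprintf("CRYST1%9.3f%9.3f%9.3f  90.00  90.00  90.00 P 1           1",
              ensemble$box[1] * 10, ensemble$box[2] * 10,
              ensemble$box[3] * 10),
      sprintf("ATOM  %5d %-4s %-4s%5d    %8.3f%8.3f%8.3f  1.00  0.00           C",
              seq_len(nrow(at)), substr(at$atom, 1, 4),
              substr(at$species, 1, 4), at$lipid_id,
              xyz[, 1], xyz[, 2], xyz[, 3]),
      "END")
    writeLines(lines, path)
    paths[f] <- path
  }
  invisible(paths)
}

#' Read bilayer coordinate frames into an ensemble
#'
#' Reads one or more GRO or PDB coordinate files (one frame each; PDB via
#' bio3d, coordinates converted to nm) and assembles a [bilayer_ensemble()].
#' Leaflets are assigned per lipid by the sign of the mean chain-atom z in
#' the first frame (midplane convention z = 0). The schema must resolve
#' every declared atom group; unresolved atoms raise an error naming the
#' lipid and atom.
#'
#' @param paths Character vector of frame files, in frame order.
#' @param schema Species schema (see [default_gm1_schema()]), or a YAML path
#'   accepted by [read_species_schema()].
#' @param box For PDB inputs without a CRYST1 record: box lengths in nm.
#' @return A [bilayer_ensemble()].
#' @export
read_bilayer_frames <- function(paths, schema, box = NULL) {
  if (is.character(schema) && length(schema) == 1 && file.exists(schema))
    schema <- read_species_schema(schema)
  is_pdb <- grepl("\\.pdb$", paths[1], ignore.case = TRUE)
  frames <- lapply(paths, function(p) {
    if (is_pdb) {
      pdb <- bio3d::read.pdb(p, verbose = FALSE)
      at <- pdb$atom
      bx <- box
      cr <- grep("^CRYST1", readLines(p, n = 5), value = TRUE)
      if (length(cr))
        bx <- as.numeric(c(substr(cr, 7, 15), substr(cr, 16, 24),
                           substr(cr, 25, 33))) / 10
      if (is.null(bx)) stop("PDB lacks CRYST1; supply box=")
      list(atoms = data.frame(lipid_id = at$resno,
                              species = trimws(at$resid),
                              atom = trimws(at$elety),
                              x = at$x / 10, y = at$y / 10, z = at$z / 10),
           box = bx)
    } else parse_gro(p)
  })
  a0 <- frames[[1]]$atoms
  natoms <- nrow(a0)
  coords <- array(NA_real_, dim = c(natoms, 3, length(frames)))
  for (f in seq_along(frames)) {
    af <- frames[[f]]$atoms
    if (nrow(af) != natoms) stop("frame atom counts differ")
    coords[, , f] <- cbind(af$x, af$y, af$z)
  }
  # leaflet from mean chain z in frame 1
  leaflet <- character(natoms)
  for (lid in unique(a0$lipid_id)) {
    rows <- which(a0$lipid_id == lid)
    sp <- a0$species[rows[1]]
    if (is.null(schema[[sp]]))
      stop(sprintf("schema error: species '%s' not in schema", sp))
    chain_atoms <- unlist(schema[[sp]]$chains)
    crows <- rows[a0$atom[rows] %in% chain_atoms]
    if (!length(crows))
      stop(sprintf("schema error: lipid %s has no resolvable chain atoms", lid))
    leaflet[rows] <- if (mean(a0$z[crows]) >= 0) "upper" else "lower"
  }
  atoms <- data.frame(atom = a0$atom, lipid_id = a0$lipid_id,
                      species = a0$species, leaflet = leaflet)
  bilayer_ensemble(atoms, coords, frames[[1]]$box, schema)
}

#' Read a species definition (atom-group schema) from YAML
#'
#' The YAML maps species names to `anchor`, `chains` (named lists of ordered
#' atom names) and optional `headgroup_vectors` (named lists of two atom
#' names).
#'
#' @param path YAML file path.
#' @return A schema list as used by [bilayer_ensemble()].
#' @export
read_species_schema <- function(path) {
  sch <- yaml::read_yaml(path)
  lapply(sch, function(sp) {
    sp$chains <- lapply(sp$chains, as.character)
    if (!is.null(sp$headgroup_vectors))
      sp$headgroup_vectors <- lapply(sp$headgroup_vectors, as.character)
    sp
  })
}

#' Write a species definition schema to YAML
#'
#' @param schema A schema list.
#' @param path Output path.
#' @export
write_species_schema <- function(schema, path) {
  yaml::write_yaml(schema, path)
  invisible(path)
}
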