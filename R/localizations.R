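#' Rectangular analysis window
#'
#' A half-open rectangle `[origin_x, origin_x + width) x
#' [origin_y, origin_y + height)` in nm, the spatial domain for all
#' point-pattern statistics. SMLM cluster analyses in this package follow the
#' convention of tiling cell membranes into fixed-size regions (typically
#' 3 x 3 um) and pooling statistics across them.
#'
#' @param width,height Extent in nm; must be positive.
#' @param origin_x,origin_y Lower-left corner in nm.
#' @return An object of class `analysis_window`.
#' @export
analysis_window <- function(width, height = width, origin_x = 0, origin_y = 0) {
  stopifnot(is.numeric(width), is.numeric(height), width > 0, height > 0)
  structure(
    list(origin_x = origin_x, origin_y = origin_y,
         width = width, height = height),
    class = "analysis_window"
  )
}

#' @export
print.analysis_window <- function(x, ...) {
  cat(sprintf("analysis_window: [%g, %g) x [%g, %g) nm\n",
              x$origin_x, x$origin_x + x$width,
              x$origin_y, x$origin_y + x$height))
  invisible(x)
}

window_area <- function(window) window$width * window$height

in_window <- function(x, y, window) {
  x >= window$origin_x & x < window$origin_x + window$width &
    y >= window$origin_y & y < window$origin_y + window$height
}

#' Single-molecule localization table
#'
#' Columnar container for SMLM localizations: planar coordinates in nm with
#' optional acquisition frame, channel label and localization precision.
#' This is the raw input of the neighbor-density, Ripley and
#' cross-correlation analyses.
#'
#' @param x,y Coordinates in nm (finite).
#' @param frame Integer acquisition frame index (optional).
#' @param channel Character channel label (optional, e.g. `"GM1"`, `"CD59"`).
#' @param precision Localization uncertainty in nm (optional).
#' @return A `data.frame` with class `localization_table`.
#' @export
localization_table <- function(x, y, frame = NULL, channel = NULL,
                               precision = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y))
    stop("x and y must have equal length")
  if (length(x) && (!all(is.finite(x)) || !all(is.finite(y))))
    stop("localization coordinates must be finite")
  df <- data.frame(x = x, y = y)
  if (!is.null(frame))     df$frame <- as.integer(frame)
  if (!is.null(channel))   df$channel <- as.character(channel)
  if (!is.null(precision)) df$precision <- as.numeric(precision)
  class(df) <- c("localization_table", "data.frame")
  df
}

as_localization_table <- function(df) {
  localization_table(df$x, df$y, frame = df$frame, channel = df$channel,
                     precision = df$precision)
}

#' Extract one channel from a localization table
#'
#' @param locs A [localization_table()] with a `channel` column.
#' @param channel Channel label (case-sensitive).
#' @return A `localization_table` restricted to that channel.
#' @export
subset_channel <- function(locs, channel) {
  if (is.null(locs$channel)) stop("localization table has no channel column")
  out <- locs[locs$channel == channel, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("localization_table", "data.frame")
  out
}

#' Tile a window into fixed-size square analysis regions
#'
#' Splits `full_window` into a non-overlapping grid of `tile` x `tile` nm
#' windows fully contained in `full_window` (partial margins are discarded)
#' and assigns localizations to tiles by the half-open membership convention.
#' Tiles with fewer than `min_points` localizations are dropped.
#'
#' @param points A [localization_table()].
#' @param full_window An [analysis_window()] containing the points.
#' @param tile Tile side length in nm; must not exceed the window extent.
#' @param min_points Minimum localizations for a tile to be kept (default 0).
#' @return A list of `list(window = , points = )` entries, one per kept tile.
#' @export
tile_windows <- function(points, full_window, tile, min_points = 0) {
  stopifnot(tile > 0)
  if (tile > min(full_window$width, full_window$height))
    stop("tile exceeds the window extent")
  nx <- floor(full_window$width / tile)
  ny <- floor(full_window$height / tile)
  out <- list()
  dropped <- 0L
  for (iy in seq_len(ny) - 1L) {
    for (ix in seq_len(nx) - 1L) {
      w <- analysis_window(tile, tile,
                           origin_x = full_window$origin_x + ix * tile,
                           origin_y = full_window$origin_y + iy * tile)
      keep <- in_window(points$x, points$y, w)
      pts <- points[keep, , drop = FALSE]
      rownames(pts) <- NULL
      class(pts) <- c("localization_table", "data.frame")
      if (nrow(pts) >= min_points) {
        out[[length(out) + 1L]] <- list(window = w, points = pts)
      } else {
        dropped <- dropped + 1L
      }
    }
  }
  if (dropped > 0)
    message(sprintf("tile_windows: dropped %d tile(s) below %d points",
                    dropped, min_points))
  out
}

#' Merge blinking-related repeat localizations
#'
#' Fluorophore blinking records one molecule several times across consecutive
#' frames, inflating apparent clustering at short range. This pass greedily
#' links localizations that appear within `radius` nm in frames separated by
#' at most `max_gap`, and collapses each chain to its mean position.
#'
#' @param locs A [localization_table()] with a `frame` column.
#' @param radius Linking radius in nm (typically the localization precision).
#' @param max_gap Maximum frame gap within a chain (default 1).
#' @return A `localization_table` of collapsed localizations.
#' @export
merge_blinking <- function(locs, radius, max_gap = 1L) {
  if (is.null(locs$frame)) stop("merge_blinking requires a frame column")
  n <- nrow(locs)
  if (n == 0) return(locs)
  ord <- order(locs$frame)
  x <- locs$x[ord]; y <- locs$y[ord]; fr <- locs$frame[ord]
  group <- integer(n)
  # active chains: last position and frame per group
  gx <- numeric(0); gy <- numeric(0); gf <- integer(0)
  r2 <- radius^2
  for (i in seq_len(n)) {
    cand <- which(fr[i] - gf >= 1L & fr[i] - gf <= max_gap)
    hit <- 0L
    if (length(cand)) {
      d2 <- (gx[cand] - x[i])^2 + (gy[cand] - y[i])^2
      k <- which.min(d2)
      if (d2[k] <= r2) hit <- cand[k]
    }
    if (hit > 0L) {
      group[i] <- hit
      gx[hit] <- x[i]; gy[hit] <- y[i]; gf[hit] <- fr[i]
    } else {
      gx <- c(gx, x[i]); gy <- c(gy, y[i]); gf <- c(gf, fr[i])
      group[i] <- length(gx)
    }
  }
  mx <- tapply(x, group, mean)
  my <- tapply(y, group, mean)
  mf <- tapply(fr, group, min)
  localization_table(as.numeric(mx), as.numeric(my), frame = as.integer(mf))
}
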