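# Perimetric test-grid geometry: canonical grids, eye transposition,
# location matching and nerve-fibre-bundle sector assignment.
#
# All coordinates are degrees of visual angle in right-eye format:
# positive x = temporal field, positive y = superior field.

#' Construct a canonical perimetric test grid
#'
#' Builds one of the two supported stimulus grids:
#'
#' * `"30-2"`: 76 locations on a 6-degree square lattice (odd multiples of
#'   3 degrees) covering the central 30 degrees; equivalently the lattice
#'   points with \eqn{x^2 + y^2 \le 841}.  Two locations, (+15, +3) and
#'   (+15, -3), fall in the physiological blind spot and are flagged.
#' * `"SPARK66"`: the 66-location grid (30 x 24 degrees) obtained from
#'   30-2 by removing the uppermost and bottommost rows (y = +/-27) and
#'   the two blind-spot locations.
#'
#' @param pattern grid name, `"30-2"` or `"SPARK66"`.
#' @return an object of class `perim_grid`: a list with `name`, `points`
#'   (data frame with columns `x`, `y`, ordered top row first, nasal to
#'   temporal) and `blind_spot` (logical vector flagging blind-spot
#'   locations).
#' @examples
#' nrow(build_grid("30-2")$points)    # 76
#' nrow(build_grid("SPARK66")$points) # 66
#' @export
build_grid <- function(pattern = c("30-2", "SPARK66")) {
  valid <- c("30-2", "SPARK66")
  if (!is.character(pattern) || length(pattern) < 1L || !(pattern[1L] %in% valid))
    stop_perisim("unknown grid pattern ", deparse(pattern[1L]),
                 "; valid patterns are: ", paste(dQuote(valid, FALSE), collapse = ", "))
  pattern <- pattern[1L]
  ax <- seq(-27L, 27L, by = 6L)              # odd multiples of 3 degrees
  pts <- expand.grid(x = ax, y = ax, KEEP.OUT.ATTRS = FALSE)
  pts <- pts[pts$x^2 + pts$y^2 <= 841, ]     # central-30 disc -> 76 points
  pts <- pts[order(-pts$y, pts$x), ]
  rownames(pts) <- NULL
  blind <- pts$x == 15L & abs(pts$y) == 3L
  if (pattern == "SPARK66") {
    keep <- abs(pts$y) != 27L & !blind
    pts <- pts[keep, ]
    rownames(pts) <- NULL
    blind <- rep(FALSE, nrow(pts))
  }
  structure(list(name = pattern, points = pts, blind_spot = blind),
            class = "perim_grid")
}

#' @export
print.perim_grid <- function(x, ...) {
  cat("<perim_grid>", x$name, "-", nrow(x$points), "locations,",
      sum(x$blind_spot), "blind-spot flagged\n")
  invisible(x)
}

grid_size <- function(grid) nrow(grid$points)

grid_ecc <- function(grid) sqrt(grid$points$x^2 + grid$points$y^2)

#' Transpose stimulus locations to right-eye format
#'
#' Left-eye coordinates are mirrored about the vertical midline
#' (x -> -x); right-eye input is returned unchanged.  Applying the
#' transposition twice (treating the output as left-eye again) is the
#' identity.
#'
#' @param points data frame with columns `x`, `y` (degrees).
#' @param eye `"left"` or `"right"`.
#' @return data frame of the same shape in right-eye format.
#' @export
transpose_to_right_eye <- function(points, eye = c("right", "left")) {
  eye <- match.arg(eye)
  stopifnot(is.data.frame(points), all(c("x", "y") %in% names(points)))
  if (eye == "left") points$x <- -points$x
  points
}

#' Match coincident locations between two grids
#'
#' Returns all pairs of indices `(i, j)` such that location `i` of grid
#' `a` and location `j` of grid `b` have identical coordinates.  Both
#' grids must be in right-eye format.  Order follows grid `a`.
#'
#' @param a,b `perim_grid` objects.
#' @return data frame with integer columns `i`, `j` (possibly 0 rows).
#' @export
match_locations <- function(a, b) {
  stopifnot(inherits(a, "perim_grid"), inherits(b, "perim_grid"))
  key <- function(g) paste(g$points$x, g$points$y)
  j <- match(key(a), key(b))
  keep <- !is.na(j)
  data.frame(i = seq_len(grid_size(a))[keep], j = j[keep])
}

# Sector labels used throughout the package.
SECTOR_LEVELS <- c("superior_nasal", "superior_temporal", "temporal",
                   "inferior_temporal", "inferior_nasal", "central")

# Rule-based sector of a single (x, y); vectorised over points.
sector_rule <- function(x, y) {
  ecc <- sqrt(x^2 + y^2)
  out <- character(length(x))
  central <- ecc < 10
  temporal <- !central & x >= 21 & abs(y) <= 9
  out[central] <- "central"
  out[temporal] <- "temporal"
  rest <- !central & !temporal
  out[rest & y > 0 & x < 0] <- "superior_nasal"
  out[rest & y > 0 & x >= 0] <- "superior_temporal"
  out[rest & y < 0 & x < 0] <- "inferior_nasal"
  out[rest & y < 0 & x >= 0] <- "inferior_temporal"
  factor(out, levels = SECTOR_LEVELS)
}

# Default phase-1 seed locations, one per functional region (right-eye
# degrees).  The superior/inferior temporal pair sits above/below the
# blind-spot region at x = +15.
DEFAULT_SEEDS <- data.frame(
  x = c(-15, 15, -15, 15, 27, 3),
  y = c( 15, 15,  -9, -9, -3, 3),
  sector = c("superior_nasal", "superior_temporal",
             "inferior_nasal", "inferior_temporal",
             "temporal", "central"),
  stringsAsFactors = FALSE
)

#' Partition a grid into functional sectors and designate seed points
#'
#' Assigns each stimulus location to one of six angular sectors loosely
#' following ganglion-cell fibre-bundle anatomy (a Garway-Heath-style
#' partition): a central region below 10 degrees eccentricity, a
#' temporal wedge, and superior/inferior nasal and temporal quadrants.
#' The partition respects the horizontal midline in the nasal field.
#' Six seed locations are designated, one per sector: two above/below
#' the blind-spot region, two in the superior/inferior nasal field, one
#' temporal and one central (< 10 degrees eccentricity).
#'
#' @param grid a `perim_grid`, normally the SPARK66 grid.
#' @param n_regions number of sectors; only 6 is supported.
#' @param seeds optional data frame with columns `x`, `y`, `sector`
#'   overriding the default seed locations.
#' @return object of class `sector_map`: list with `sector` (factor, one
#'   level per location), `seeds` (data frame with `x`, `y`, `sector`,
#'   `index` into the grid) and `grid_name`.
#' @export
assign_sectors <- function(grid, n_regions = 6L, seeds = DEFAULT_SEEDS) {
  stopifnot(inherits(grid, "perim_grid"))
  if (!identical(as.integer(n_regions), 6L))
    stop_perisim("only n_regions = 6 is supported (got ", n_regions, ")")
  sec <- sector_rule(grid$points$x, grid$points$y)
  idx <- match(paste(seeds$x, seeds$y), paste(grid$points$x, grid$points$y))
  if (anyNA(idx))
    stop_perisim("seed location(s) not on grid: ",
                 paste(sprintf("(%g, %g)", seeds$x[is.na(idx)],
                               seeds$y[is.na(idx)]), collapse = ", "))
  seeds$index <- idx
  structure(list(sector = sec, seeds = seeds, grid_name = grid$name),
            class = "sector_map")
}

#' Write a grid (with optional sectors) to CSV
#'
#' Columns: `index`, `x_deg`, `y_deg`, `is_blind_spot`, `sector`.
#'
#' @param grid a `perim_grid`.
#' @param path output file path.
#' @param sector_map optional `sector_map` for the `sector` column.
#' @return the path, invisibly.
#' @export
write_grid_csv <- function(grid, path, sector_map = NULL) {
  df <- data.frame(index = seq_len(grid_size(grid)),
                   x_deg = grid$points$x, y_deg = grid$points$y,
                   is_blind_spot = grid$blind_spot,
                   sector = if (is.null(sector_map)) NA_character_
                            else as.character(sector_map$sector))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
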