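# Virtual pheromone raster: disc deposition along marker-on trajectories,
# capped accumulation, periodic exponential evaporation.

#' Create an empty pheromone field
#'
#' The field is a 2D intensity raster emulating a projected trail image:
#' 800 x 600 cells covering a 140 x 105 cm arena (1.75 mm per cell). Trail
#' marks are uniform discs of fixed intensity added cell-wise, accumulation is
#' capped at 255, and the whole raster decays exponentially with characteristic
#' time `tau` on a fixed evaporation schedule.
#'
#' Two storage modes are supported. `"float"` keeps exact real-valued
#' intensities and is used by the analysis pipeline (evaporation is exactly
#' multiplicative). `"8bit"` mimics a projector image buffer: intensities are
#' integer-valued and evaporation rounds to the nearest integer, so faint
#' residues (below 0.5) are flushed to zero.
#'
#' @param nx,ny raster size in cells (x is the 140 cm axis).
#' @param extent arena extent `c(xmin, xmax, ymin, ymax)` in cm.
#' @param mode `"float"` or `"8bit"`.
#' @param disc_diameter deposition disc diameter in cm.
#' @param disc_intensity intensity added per cell per deposit.
#' @param tau evaporation characteristic time in seconds.
#' @param evap_period seconds between evaporation steps.
#' @return an object of class `pheromone_field`.
#' @export
pheromone_field <- function(nx = 800L, ny = 600L,
                            extent = c(0, 140, 0, 105),
                            mode = c("float", "8bit"),
                            disc_diameter = 6,
                            disc_intensity = 7,
                            tau = 1800,
                            evap_period = 5) {
  mode <- match.arg(mode)
  stopifnot(nx >= 2L, ny >= 2L, length(extent) == 4L,
            extent[2] > extent[1], extent[4] > extent[3],
            disc_diameter > 0, disc_intensity > 0, tau > 0, evap_period > 0)
  f <- list(
    grid = matrix(0, nrow = as.integer(ny), ncol = as.integer(nx)),
    extent = as.numeric(extent),
    mode = mode,
    disc_diameter = disc_diameter,
    disc_intensity = disc_intensity,
    tau = tau,
    evap_period = evap_period,
    last_disc = list()   # per-agent center of the last deposited disc
  )
  class(f) <- "pheromone_field"
  f
}

#' @export
print.pheromone_field <- function(x, ...) {
  cat(sprintf("<pheromone_field> %d x %d cells, extent [%g,%g] x [%g,%g] cm (%s mode)\n",
              ncol(x$grid), nrow(x$grid),
              x$extent[1], x$extent[2], x$extent[3], x$extent[4], x$mode))
  cat(sprintf("  disc %g cm @ intensity %g, tau %g s, evaporation every %g s\n",
              x$disc_diameter, x$disc_intensity, x$tau, x$evap_period))
  cat(sprintf("  total intensity %.6g\n", sum(x$grid)))
  invisible(x)
}

# cell size in cm (x and y)
field_cell_size <- function(field) {
  c((field$extent[2] - field$extent[1]) / ncol(field$grid),
    (field$extent[4] - field$extent[3]) / nrow(field$grid))
}

# indices of cells whose centers lie within `radius` of point (x, y);
# returns integer vector of matrix indices, possibly empty
field_disc_cells <- function(field, x, y, radius) {
  cs <- field_cell_size(field)
  nx <- ncol(field$grid); ny <- nrow(field$grid)
  jmin <- max(1L, floor((x - radius - field$extent[1]) / cs[1]) )
  jmax <- min(nx, ceiling((x + radius - field$extent[1]) / cs[1]) + 1L)
  imin <- max(1L, floor((y - radius - field$extent[3]) / cs[2]) )
  imax <- min(ny, ceiling((y + radius - field$extent[3]) / cs[2]) + 1L)
  if (jmin > jmax || imin > imax) return(integer(0))
  jj <- jmin:jmax
  ii <- imin:imax
  cx <- field$extent[1] + (jj - 0.5) * cs[1]
  cy <- field$extent[3] + (ii - 0.5) * cs[2]
  dx2 <- outer(cy * 0, (cx - x)^2, "+")      # |ii| x |jj|
  dy2 <- outer((cy - y)^2, cx * 0, "+")
  sel <- which(dx2 + dy2 <= radius^2)
  if (length(sel) == 0L) return(integer(0))
  ri <- ((sel - 1L) %% length(ii)) + 1L
  ci <- ((sel - 1L) %/% length(ii)) + 1L
  (jj[ci] - 1L) * ny + ii[ri]
}

#' Deposit a pheromone disc
#'
#' Adds a uniform disc of intensity `disc_intensity` centred on `position`,
#' clipped cell-wise at 255. Consecutive discs laid by the same agent must not
#' overlap: the deposit is skipped unless the center is at least one disc
#' diameter away from that agent's previous disc center. Discs from different
#' agents, or non-consecutive discs of one agent, may overlap and sum.
#'
#' @param field a [pheromone_field()].
#' @param agent_id scalar identifying the trajectory the disc belongs to.
#' @param position `c(x, y)` in cm.
#' @return the updated field (with `deposited` attribute: TRUE if a disc was added).
#' @export
deposit <- function(field, agent_id, position) {
  stopifnot(inherits(field, "pheromone_field"), length(position) == 2L)
  x <- position[1]; y <- position[2]
  if (x < field$extent[1] || x > field$extent[2] ||
      y < field$extent[3] || y > field$extent[4]) {
    stop("deposit position outside the raster extent")
  }
  key <- as.character(agent_id)
  prev <- field$last_disc[[key]]
  if (!is.null(prev)) {
    if (sqrt(sum((c(x, y) - prev)^2)) < field$disc_diameter) {
      attr(field, "deposited") <- FALSE
      return(field)
    }
  }
  cells <- field_disc_cells(field, x, y, field$disc_diameter / 2)
  if (length(cells)) {
    v <- field$grid[cells] + field$disc_intensity
    field$grid[cells] <- pmin(v, 255)
  }
  field$last_disc[[key]] <- c(x, y)
  attr(field, "deposited") <- TRUE
  field
}

#' Evaporate the field by one schedule step
#'
#' Multiplies every cell by `exp(-dt / tau)`. In `"8bit"` mode the result is
#' truncated to an integer (so sub-unit residues are flushed to zero),
#' mirroring an 8-bit image buffer; in `"float"` mode the decay is exactly
#' multiplicative.
#'
#' @param field a [pheromone_field()].
#' @param dt elapsed time in seconds (defaults to the field's schedule period).
#' @return the updated field.
#' @export
evaporate <- function(field, dt = field$evap_period) {
  stopifnot(inherits(field, "pheromone_field"), dt >= 0)
  if (dt == 0) return(field)
  f <- exp(-dt / field$tau)
  g <- field$grid * f
  if (field$mode == "8bit") g <- floor(g)
  field$grid <- g
  field
}

#' Sample mean intensity around a point
#'
#' Returns the mean intensity of the cells within `radius` of `point`, scaled
#' to `[0, 1]` by the 255 cap. This is the photoreceptor reading used by the
#' behavioural simulator.
#'
#' @param field a [pheromone_field()].
#' @param point `c(x, y)` in cm.
#' @param radius sampling radius in cm.
#' @return mean scaled intensity in `[0, 1]`.
#' @export
sample_field <- function(field, point, radius = 1) {
  stopifnot(inherits(field, "pheromone_field"), length(point) == 2L)
  if (point[1] < field$extent[1] || point[1] > field$extent[2] ||
      point[2] < field$extent[3] || point[2] > field$extent[4]) {
    stop("sample point outside the arena extent")
  }
  cells <- field_disc_cells(field, point[1], point[2], radius)
  if (!length(cells)) return(0)
  mean(field$grid[cells]) / 255
}

#' Total field intensity
#' @param field a [pheromone_field()].
#' @return sum of all cell intensities.
#' @export
field_total <- function(field) {
  stopifnot(inherits(field, "pheromone_field"))
  sum(field$grid)
}

#' Write a field as a plain-text portable graymap (P2)
#'
#' 16-bit plain PGM; float-mode intensities are scaled by `scale` and rounded.
#' @param field a [pheromone_field()].
#' @param path output file.
#' @param scale multiplier applied before rounding (use 257 to spread 0..255
#'   over the 16-bit range, or 1 to keep raw units).
#' @export
write_field_pgm <- function(field, path, scale = 1) {
  g <- round(field$grid * scale)
  g[g < 0] <- 0
  maxval <- max(1, max(g))
  if (maxval > 65535) stop("scaled intensities exceed 16-bit range")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2",
               sprintf("# extent %g %g %g %g", field$extent[1], field$extent[2],
                       field$extent[3], field$extent[4]),
               sprintf("%d %d", ncol(g), nrow(g)),
               sprintf("%d", maxval)), con)
  # PGM rows run top-to-bottom; our row 1 is the bottom of the arena
  for (i in nrow(g):1) {
    writeLines(paste(g[i, ], collapse = " "), con)
  }
  invisible(path)
}

#' Read a plain-text PGM written by [write_field_pgm()]
#' @param path file path.
#' @param ... passed to [pheromone_field()] (e.g. `mode`).
#' @return a `pheromone_field` with the stored extent if present.
#' @export
read_field_pgm <- function(path, ...) {
  lines <- readLines(path)
  if (lines[1] != "P2") stop("not a plain PGM (P2) file")
  extent <- c(0, 140, 0, 105)
  body <- lines[-1]
  com <- grepl("^#", body)
  ext_line <- body[com][grepl("^# extent", body[com])]
  if (length(ext_line)) {
    extent <- as.numeric(strsplit(sub("^# extent ", "", ext_line[1]), " ")[[1]])
  }
  body <- body[!com]
  dims <- as.integer(strsplit(trimws(body[1]), "\\s+")[[1]])
  vals <- as.numeric(unlist(strsplit(trimws(body[-(1:2)]), "\\s+")))
  if (length(vals) != dims[1] * dims[2]) stop("corrupt PGM payload")
  f <- pheromone_field(nx = dims[1], ny = dims[2], extent = extent, ...)
  g <- matrix(vals, nrow = dims[2], ncol = dims[1], byrow = TRUE)
  f$grid <- g[dims[2]:1, , drop = FALSE]
  f
}
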