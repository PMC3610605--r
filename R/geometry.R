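# Three-loop corridor maze: graph, corridor centerlines, bifurcation angles.
#
# The layout is reconstructed from its published constraints rather than from
# digitized coordinates: 7 start-to-target paths that never reuse a segment,
# segment-count categories {4, 6, 8, 10}, shortest path 86 cm, longest 178 cm,
# 9 cm corridors, 22.5 cm hexagonal start/target areas, the whole network
# inside a 140 x 105 cm arena. In configuration S every bifurcation is
# symmetrical (both branches deviate 60 deg from the incoming direction); in
# configuration A the loops are flattened so each bifurcation has a symmetric
# side (30/30) and an asymmetric side (30/120), with segment lengths identical
# to S.

# --- canonical tables ------------------------------------------------------

.maze_positions <- function() {
  p <- rbind(
    S = c(98, 76), T = c(42, 32),
    A = c(90, 56), R = c(76, 45), E = c(59, 41),
    B = c(78, 70), V = c(62, 56),
    U = c(71, 79), D = c(62, 69),
    C = c(58, 84), P = c(52, 74),
    Q = c(42, 89), F = c(36, 76))
  colnames(p) <- c("x", "y")
  p
}

.maze_segments <- function() {
  data.frame(
    id     = c("sSA","sSB","sTE","sPC","sPD","sPF","sQC","sQFa","sQFb",
               "sRAa","sRAb","sRE","sUB","sUC","sUD","sVB","sVD","sVE"),
    node_a = c("S","S","T","P","P","P","Q","Q","Q","R","R","R","U","U","U","V","V","V"),
    node_b = c("A","B","E","C","D","F","C","F","F","A","A","E","B","C","D","B","D","E"),
    length = c(26, 26, 20, 12, 12, 18, 20, 18, 18, 22, 22, 18, 18, 14, 14, 22, 14, 18),
    stringsAsFactors = FALSE)
}

# configuration A stub roles: at each bifurcation the corridor listed as
# `stem` faces the asymmetric side (30/120 seen from it); `b1` is the
# through-branch (30 deg from both others), `b2` the wide branch.
.maze_roles_A <- function() {
  list(A = c("sSA","sRAa","sRAb"), R = c("sRAa","sRE","sRAb"),
       E = c("sTE","sVE","sRE"),  B = c("sSB","sVB","sUB"),
       V = c("sVB","sVE","sVD"),  U = c("sUB","sUC","sUD"),
       D = c("sUD","sVD","sPD"),  C = c("sUC","sPC","sQC"),
       P = c("sPC","sPD","sPF"),  Q = c("sQC","sQFa","sQFb"),
       F = c("sQFa","sPF","sQFb"))
}

.wrap_angle <- function(a) {
  (a + pi) %% (2 * pi) - pi
}

# --- stub fitting ----------------------------------------------------------

# For each bifurcation, corridors leave along three "stub" directions with the
# configuration's exact template angles (S: 0/+120/-120; A: 180/+30/-120 about
# the stem), rotated to best face the neighbouring nodes.
.fit_stubs <- function(pos, segs, config, roles_A) {
  junctions <- setdiff(rownames(pos), c("S", "T"))
  stubs <- list()
  for (n in junctions) {
    inc <- segs$id[segs$node_a == n | segs$node_b == n]
    bearing <- vapply(inc, function(s) {
      r <- segs[segs$id == s, ]
      o <- if (r$node_a == n) r$node_b else r$node_a
      atan2(pos[o, 2] - pos[n, 2], pos[o, 1] - pos[n, 1])
    }, numeric(1))
    best <- NULL
    if (config == "S") {
      offsets <- c(0, 2 * pi / 3, -2 * pi / 3)
      perms <- list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
      for (pm in perms) {
        off <- offsets[pm]
        d <- .wrap_angle(bearing - off)
        th <- atan2(sum(sin(d)), sum(cos(d)))
        err <- sum(.wrap_angle(bearing - (th + off))^2)
        if (is.null(best) || err < best$err) {
          ang <- .wrap_angle(th + off); names(ang) <- inc
          best <- list(err = err, ang = ang)
        }
      }
    } else {
      rl <- roles_A[[n]]                      # stem, b1, b2
      bearing <- bearing[rl]
      for (chir in c(1, -1)) {
        off <- c(pi, chir * pi / 6, chir * (-2 * pi / 3))
        d <- .wrap_angle(bearing - off)
        th <- atan2(sum(sin(d)), sum(cos(d)))
        err <- sum(.wrap_angle(bearing - (th + off))^2)
        if (is.null(best) || err < best$err) {
          ang <- .wrap_angle(th + off); names(ang) <- rl
          best <- list(err = err, ang = ang)
        }
      }
    }
    stubs[[n]] <- best$ang
  }
  stubs
}

# --- corridor centerline routing ------------------------------------------

.bezier_pts <- function(p0, c0, c1, p1, n = 80) {
  t <- seq(0, 1, length.out = n)
  b <- cbind((1 - t)^3, 3 * (1 - t)^2 * t, 3 * (1 - t) * t^2, t^3)
  b %*% rbind(p0, c0, c1, p1)
}

.poly_len <- function(p) {
  sum(sqrt(rowSums(diff(p)^2)))
}

# route one segment as a cubic bezier leaving/arriving along the exact stub
# directions; the control-point distance is solved so the arc length equals
# the stored segment length.
.route_segment <- function(pos, stubs, seg) {
  pa <- pos[seg$node_a, ]; pb <- pos[seg$node_b, ]
  L <- seg$length
  da <- if (seg$node_a %in% c("S", "T")) (pb - pa) / sqrt(sum((pb - pa)^2))
        else c(cos(stubs[[seg$node_a]][seg$id]), sin(stubs[[seg$node_a]][seg$id]))
  db <- if (seg$node_b %in% c("S", "T")) (pa - pb) / sqrt(sum((pa - pb)^2))
        else c(cos(stubs[[seg$node_b]][seg$id]), sin(stubs[[seg$node_b]][seg$id]))
  build <- function(cc) .bezier_pts(pa, pa + cc * da, pb + cc * db, pb)
  lo <- 0.3; hi <- 1.35 * L
  Llo <- .poly_len(build(lo)); Lhi <- .poly_len(build(hi))
  if (!(min(Llo, Lhi) <= L && L <= max(Llo, Lhi))) {
    stop(sprintf("cannot route segment %s to length %g", seg$id, L))
  }
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if ((.poly_len(build(mid)) < L) == (Llo < L)) lo <- mid else hi <- mid
  }
  p <- build((lo + hi) / 2)
  dimnames(p) <- NULL
  p
}

.arm_separation <- function(p1, p2, pos, shared) {
  keep <- function(p) {
    ok <- rep(TRUE, nrow(p))
    for (n in shared) {
      ok <- ok & sqrt((p[, 1] - pos[n, 1])^2 + (p[, 2] - pos[n, 2])^2) > 8
    }
    ok
  }
  k1 <- keep(p1); k2 <- keep(p2)
  if (!any(k1) || !any(k2)) return(99)
  a <- p1[k1, , drop = FALSE]; b <- p2[k2, , drop = FALSE]
  d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  sqrt(min(d2))
}

# --- public constructor ----------------------------------------------------

#' Build the three-loop corridor network
#'
#' Constructs the maze in configuration `"S"` (all bifurcations symmetrical:
#' both branches deviate 60 degrees from the incoming direction) or `"A"`
#' (flattened loops: each bifurcation has a 30/30 symmetric side and a 30/120
#' asymmetric side). Both configurations share the same topology and the same
#' per-segment lengths, so all seven start-to-target paths have identical
#' lengths in S and A. The construction is deterministic.
#'
#' @param config `"S"` or `"A"`.
#' @param loops number of diamond loops; 3 is the canonical network, 4 an
#'   untested courtesy variant (an extra diamond spliced before the target).
#' @return an object of class `trail_network`: list with `nodes` (data.frame:
#'   id, x, y, kind), `segments` (data.frame: id, node_a, node_b, length_cm,
#'   plus a `polylines` list of centerline matrices), `corridor_width`,
#'   `config_label`, `branch_angles` (data.frame: node, incoming, outgoing,
#'   deviation_deg), `area_radius` (hexagon circumradius), `extent`.
#' @export
build_network <- function(config = c("S", "A"), loops = 3L) {
  config <- match.arg(config)
  if (!loops %in% c(3L, 4L)) {
    stop("unsupported loops count: only the 3-loop network (and the untested ",
         "4-loop courtesy variant) are available")
  }
  pos <- .maze_positions()
  segs <- .maze_segments()
  roles <- .maze_roles_A()
  if (loops == 4L) {
    # splice an extra diamond V--G==H--E in place of segment sVE
    pos <- rbind(pos, G = c(64, 52), H = c(56, 47))
    segs <- segs[segs$id != "sVE", ]
    segs <- rbind(segs, data.frame(
      id = c("sVG", "sGHa", "sGHb", "sHE"),
      node_a = c("V", "G", "G", "H"), node_b = c("G", "H", "H", "E"),
      length = c(8, 12, 12, 8), stringsAsFactors = FALSE))
    roles$V <- c("sVB", "sVG", "sVD")
    roles$E <- c("sHE", "sTE", "sRE")
    roles$G <- c("sVG", "sGHa", "sGHb")
    roles$H <- c("sGHa", "sHE", "sGHb")
  }
  stubs <- .fit_stubs(pos, segs, config, roles)
  # pair parallel arms consistently (avoid crossing corridors)
  arm_pairs <- list(c("sRAa", "sRAb"), c("sQFa", "sQFb"))
  if (loops == 4L) arm_pairs <- c(arm_pairs, list(c("sGHa", "sGHb")))
  route1 <- function(id) .route_segment(pos, stubs, segs[segs$id == id, ])
  for (ap in arm_pairs) {
    sa <- segs[segs$id == ap[1], ]
    shared <- c(sa$node_a, sa$node_b)
    d0 <- .arm_separation(route1(ap[1]), route1(ap[2]), pos, shared)
    j <- shared[1]
    tmp <- stubs[[j]][ap[1]]
    stubs[[j]][ap[1]] <- stubs[[j]][ap[2]]; stubs[[j]][ap[2]] <- tmp
    d1 <- tryCatch(.arm_separation(route1(ap[1]), route1(ap[2]), pos, shared),
                   error = function(e) -1)
    if (d1 < d0) {  # swap back
      tmp <- stubs[[j]][ap[1]]
      stubs[[j]][ap[1]] <- stubs[[j]][ap[2]]; stubs[[j]][ap[2]] <- tmp
    }
  }
  polylines <- lapply(segs$id, route1)
  names(polylines) <- segs$id

  # branch-angle table: deviation of each outgoing corridor from the incoming
  # travel direction, per (bifurcation, incoming segment)
  ba <- list()
  for (n in names(stubs)) {
    inc <- names(stubs[[n]])
    for (si in inc) {
      arrive <- .wrap_angle(stubs[[n]][si] + pi)   # direction of travel into node
      for (so in setdiff(inc, si)) {
        dev <- abs(.wrap_angle(stubs[[n]][so] - arrive)) * 180 / pi
        ba[[length(ba) + 1L]] <- data.frame(
          node = n, incoming = si, outgoing = so,
          deviation_deg = round(dev, 6), stringsAsFactors = FALSE)
      }
    }
  }
  branch_angles <- do.call(rbind, ba)

  nodes <- data.frame(
    id = rownames(pos), x = pos[, 1], y = pos[, 2],
    kind = ifelse(rownames(pos) == "S", "start_area",
                  ifelse(rownames(pos) == "T", "target_area", "bifurcation")),
    stringsAsFactors = FALSE)
  rownames(nodes) <- NULL

  net <- list(
    nodes = nodes,
    segments = data.frame(id = segs$id, node_a = segs$node_a,
                          node_b = segs$node_b, length_cm = segs$length,
                          stringsAsFactors = FALSE),
    polylines = polylines,
    corridor_width = 9,
    config_label = config,
    loops = as.integer(loops),
    branch_angles = branch_angles,
    stub_angles = stubs,
    roles_A = roles,
    area_diameter = 22.5,
    extent = c(0, 140, 0, 105))
  class(net) <- "trail_network"
  net
}

#' @export
print.trail_network <- function(x, ...) {
  cat(sprintf("<trail_network> configuration %s, %d loops: %d nodes, %d segments, total %g cm\n",
              x$config_label, x$loops, nrow(x$nodes), nrow(x$segments),
              sum(x$segments$length_cm)))
  cat(sprintf("  corridor width %g cm, areas %g cm hexagons, arena [%g x %g] cm\n",
              x$corridor_width, x$area_diameter,
              x$extent[2] - x$extent[1], x$extent[4] - x$extent[3]))
  invisible(x)
}

#' @export
plot.trail_network <- function(x, ...) {
  graphics::plot(NA, xlim = x$extent[1:2], ylim = x$extent[3:4], asp = 1,
                 xlab = "x (cm)", ylab = "y (cm)",
                 main = sprintf("configuration %s", x$config_label), ...)
  for (p in x$polylines) {
    graphics::lines(p[, 1], p[, 2], lwd = 6, col = grDevices::adjustcolor("steelblue", 0.4))
    graphics::lines(p[, 1], p[, 2], col = "grey20")
  }
  hx <- function(cn) {
    th <- seq(0, 2 * pi, length.out = 7)
    graphics::lines(cn[1] + x$area_diameter / 2 * cos(th),
                    cn[2] + x$area_diameter / 2 * sin(th), col = "darkgreen")
  }
  ar <- x$nodes[x$nodes$kind != "bifurcation", ]
  for (i in seq_len(nrow(ar))) hx(c(ar$x[i], ar$y[i]))
  graphics::text(x$nodes$x, x$nodes$y, x$nodes$id, cex = 0.7, col = "red")
  invisible(x)
}

# --- path enumeration ------------------------------------------------------

#' Enumerate all start-to-target paths
#'
#' Exhaustive depth-first enumeration of walks from the start area to the
#' target area that never use the same segment twice (revisiting a node is
#' permitted). Paths are returned sorted by total centerline length.
#'
#' @param network a [build_network()] object.
#' @return data.frame of class `path_records`: `path` (id), `n_segments`,
#'   `length_cm`, `category` (= n_segments), and a `segments` list-column of
#'   segment id vectors.
#' @export
enumerate_paths <- function(network) {
  stopifnot(inherits(network, "trail_network"))
  segs <- network$segments
  out <- list()
  used <- logical(nrow(segs))
  acc <- character(0)
  dfs <- function(v) {
    if (v == "T") {
      out[[length(out) + 1L]] <<- acc
      return(invisible())
    }
    idx <- which(!used & (segs$node_a == v | segs$node_b == v))
    for (i in idx) {
      used[i] <<- TRUE
      acc <<- c(acc, segs$id[i])
      dfs(if (segs$node_a[i] == v) segs$node_b[i] else segs$node_a[i])
      acc <<- acc[-length(acc)]
      used[i] <<- FALSE
    }
  }
  dfs("S")
  if (length(out) == 0L) stop("network has no start-to-target path")
  len <- vapply(out, function(p) sum(segs$length_cm[match(p, segs$id)]), numeric(1))
  ord <- order(len, lengths(out))
  res <- data.frame(path = seq_along(out),
                    n_segments = lengths(out)[ord],
                    length_cm = len[ord])
  res$category <- res$n_segments
  res$segments <- out[ord]
  class(res) <- c("path_records", "data.frame")
  res
}

# --- raster masks ----------------------------------------------------------

# session cache for expensive per-network rasterizations
.trailnet_cache <- new.env(parent = emptyenv())

# squared distance from points (matrix n x 2) to a polyline
.dist2_to_polyline <- function(pts, poly) {
  d2 <- rep(Inf, nrow(pts))
  for (i in seq_len(nrow(poly) - 1L)) {
    a <- poly[i, ]; b <- poly[i + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 < 1e-12) next
    t <- ((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2]) / len2
    t <- pmin(pmax(t, 0), 1)
    dx <- a[1] + t * ab[1] - pts[, 1]
    dy <- a[2] + t * ab[2] - pts[, 2]
    d2 <- pmin(d2, dx * dx + dy * dy)
  }
  d2
}

.in_hexagon <- function(pts, center, diameter) {
  # regular hexagon, flat orientation as drawn (circumradius = diameter / 2)
  r <- diameter / 2
  x <- pts[, 1] - center[1]; y <- pts[, 2] - center[2]
  inside <- rep(TRUE, nrow(pts))
  for (k in 0:5) {
    th <- pi / 6 + k * pi / 3   # edge normals of the hexagon with vertices at k*60 deg
    inside <- inside & (x * cos(th) + y * sin(th)) <= r * cos(pi / 6) + 1e-9
  }
  inside
}

#' Assign raster cells to corridor segments
#'
#' Partitions the cells of a raster covering the arena among the network's
#' segments: a cell belongs to the segment whose centerline is nearest,
#' provided it lies within half a corridor width of it; cells inside the
#' start/target hexagons are assigned to no segment.
#'
#' @param network a [build_network()] object.
#' @param raster_shape `c(nx, ny)` cells.
#' @param extent arena extent `c(xmin, xmax, ymin, ymax)`; default the
#'   network's extent.
#' @return list with `assignment` (ny x nx integer matrix; 0 = no segment,
#'   otherwise row index into `network$segments`), and `masks`, a named list
#'   of cell-index vectors per segment id.
#' @export
segment_masks <- function(network, raster_shape = c(800L, 600L),
                          extent = network$extent) {
  stopifnot(inherits(network, "trail_network"), length(raster_shape) == 2L)
  nx <- as.integer(raster_shape[1]); ny <- as.integer(raster_shape[2])
  csx <- (extent[2] - extent[1]) / nx
  csy <- (extent[4] - extent[3]) / ny
  if (max(csx, csy) > network$corridor_width / 4) {
    stop("raster too coarse to separate adjacent corridors")
  }
  key <- paste(network$config_label, network$loops, nx, ny,
               paste(signif(extent, 10), collapse = ","), sep = "|")
  cached <- .trailnet_cache[[key]]
  if (!is.null(cached)) return(cached)
  ar <- network$nodes[network$nodes$kind != "bifurcation", ]
  hexes <- as.matrix(ar[, c("x", "y")])
  assignment <- .segment_assign_cpp(
    network$polylines[network$segments$id], hexes, network$area_diameter,
    network$corridor_width / 2, nx, ny, extent)
  nseg <- nrow(network$segments)
  best_id <- as.vector(assignment)
  masks <- lapply(seq_len(nseg), function(i) which(best_id == i))
  names(masks) <- network$segments$id
  out <- list(assignment = assignment, masks = masks)
  .trailnet_cache[[key]] <- out
  out
}

# --- JSON serialization ----------------------------------------------------

#' Write a network to structured text (JSON)
#' @param network a [build_network()] object.
#' @param path output file.
#' @export
write_network_json <- function(network, path) {
  stopifnot(inherits(network, "trail_network"))
  obj <- list(
    config = network$config_label,
    loops = network$loops,
    corridor_width = network$corridor_width,
    area_diameter = network$area_diameter,
    extent = network$extent,
    nodes = network$nodes,
    segments = network$segments,
    branch_angles = network$branch_angles,
    polylines = lapply(network$polylines, function(p) unname(as.data.frame(p))))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a network written by [write_network_json()]
#' @param path file path.
#' @return a `trail_network`.
#' @export
read_network_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  net <- build_network(obj$config, as.integer(obj$loops))
  # serialized geometry is authoritative for the polylines
  net$polylines <- lapply(obj$polylines, function(p) as.matrix(p))
  names(net$polylines) <- names(obj$polylines)
  net
}
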