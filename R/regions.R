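# Regions of interest: named simple polygons in image pixel coordinates,
# read from GeoJSON, with boundary-inclusive point-in-polygon assignment.

#' Sentinel for reads outside every region polygon
#' @export
REGION_NONE <- "NONE"

#' Construct a region set
#'
#' @param polygons named list of polygons; each polygon is a two-column
#'   numeric matrix (x, y) of vertices, not closed (first vertex not
#'   repeated).
#' @return An object of class `region_set` (the validated named list).
#' @details Polygons must be simple (non-self-intersecting), have unique
#'   names and be pairwise disjoint; overlapping ROIs are rejected because
#'   regional strata must partition reads.
#' @export
region_set <- function(polygons) {
  if (length(polygons) == 0)
    return(structure(list(), class = "region_set"))
  nms <- names(polygons)
  if (is.null(nms) || any(nms == "") || anyDuplicated(nms))
    stop("region polygons must have unique non-empty names")
  polygons <- lapply(polygons, function(p) {
    p <- as.matrix(p)
    if (ncol(p) != 2 || nrow(p) < 3 || !is.numeric(p))
      stop("each polygon must be a numeric matrix with >= 3 (x, y) vertices")
    # drop an explicitly closed final vertex
    if (all(p[1, ] == p[nrow(p), ])) p <- p[-nrow(p), , drop = FALSE]
    colnames(p) <- c("x", "y")
    p
  })
  for (nm in nms)
    if (!.polygon_is_simple(polygons[[nm]]))
      stop("region '", nm, "' is not a simple polygon")
  if (length(polygons) > 1) {
    for (i in seq_len(length(polygons) - 1)) for (j in (i + 1):length(polygons))
      if (.polygons_overlap(polygons[[i]], polygons[[j]]))
        stop("regions '", nms[i], "' and '", nms[j], "' overlap")
  }
  structure(polygons, class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("region_set: %d region(s)\n", length(x)))
  for (nm in names(x))
    cat(sprintf("  %-20s %d vertices, area %.0f px^2\n",
                nm, nrow(x[[nm]]), abs(.polygon_area(x[[nm]]))))
  invisible(x)
}

#' Read regions of interest from GeoJSON
#'
#' Expects a FeatureCollection of Polygon features, each with a `name`
#' property, with coordinates in image pixel units.
#'
#' @param path GeoJSON file
#' @return A [region_set].
#' @export
read_regions <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection: ", path)
  polys <- list()
  for (f in gj$features) {
    if (!identical(f$geometry$type, "Polygon"))
      stop("only Polygon features are supported; got ", f$geometry$type)
    nm <- f$properties$name
    if (is.null(nm)) stop("polygon feature without a 'name' property")
    ring <- f$geometry$coordinates[[1]]  # exterior ring; holes unsupported
    m <- do.call(rbind, lapply(ring, function(v) c(v[[1]], v[[2]])))
    polys[[nm]] <- m
  }
  region_set(polys)
}

#' Write regions of interest to GeoJSON
#'
#' @param regions a [region_set]
#' @param path output file
#' @return `path`, invisibly.
#' @export
write_regions <- function(regions, path) {
  feats <- lapply(names(regions), function(nm) {
    p <- regions[[nm]]
    ring <- lapply(seq_len(nrow(p) + 1), function(i) {
      v <- p[if (i > nrow(p)) 1 else i, ]
      c(v[["x"]], v[["y"]])
    })
    list(type = "Feature",
         properties = list(name = nm),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Rectangular regions spanning an image
#'
#' Convenience constructor used by simulations: splits the image into a grid
#' of named rectangular ROIs (with an optional margin left unassigned).
#'
#' @param image_shape `c(height, width)` in pixels
#' @param names region names, length must equal `nx * ny`
#' @param nx,ny grid dimensions
#' @param margin gap in pixels between adjacent rectangles and to the border
#' @return A [region_set].
#' @export
rect_regions <- function(image_shape, names, nx = 2, ny = 2, margin = 1) {
  stopifnot(length(names) == nx * ny)
  h <- image_shape[1]; w <- image_shape[2]
  polys <- list()
  k <- 0
  for (iy in seq_len(ny)) for (ix in seq_len(nx)) {
    k <- k + 1
    x0 <- (ix - 1) * w / nx + margin; x1 <- ix * w / nx - margin
    y0 <- (iy - 1) * h / ny + margin; y1 <- iy * h / ny - margin
    polys[[names[k]]] <- cbind(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1))
  }
  region_set(polys)
}

#' Boundary-inclusive point-in-polygon test
#'
#' Ray-crossing test; points exactly on a polygon edge or vertex count as
#' inside, so reads on an ROI outline are deterministically assigned.
#'
#' @param x,y point coordinates (vectors of equal length)
#' @param polygon two-column (x, y) vertex matrix
#' @return Logical vector.
#' @export
point_in_polygon <- function(x, y, polygon) {
  p <- as.matrix(polygon)
  n <- nrow(p)
  px <- p[, 1]; py <- p[, 2]
  qx <- px[c(2:n, 1)]; qy <- py[c(2:n, 1)]
  inside <- logical(length(x))
  on_edge <- logical(length(x))
  eps <- 1e-9
  for (i in seq_len(n)) {
    x1 <- px[i]; y1 <- py[i]; x2 <- qx[i]; y2 <- qy[i]
    # collinear and within the segment's bounding box => on the edge
    cross <- (x2 - x1) * (y - y1) - (y2 - y1) * (x - x1)
    on_edge <- on_edge |
      (abs(cross) <= eps * (abs(x2 - x1) + abs(y2 - y1) + 1) &
         x >= pmin(x1, x2) - eps & x <= pmax(x1, x2) + eps &
         y >= pmin(y1, y2) - eps & y <= pmax(y1, y2) + eps)
    crosses <- ((y1 > y) != (y2 > y)) &
      (x < x1 + (y - y1) * (x2 - x1) / (y2 - y1))
    inside <- xor(inside, crosses & !is.na(crosses))
  }
  inside | on_edge
}

#' Assign points to regions
#'
#' @param x,y point coordinates
#' @param regions a [region_set] (or `NULL`)
#' @return Character vector of region names, `"NONE"` for points outside all
#'   polygons. Regions are disjoint so each point matches at most one.
#' @export
assign_regions <- function(x, y, regions) {
  out <- rep(REGION_NONE, length(x))
  if (is.null(regions) || length(regions) == 0) return(out)
  for (nm in names(regions)) {
    hit <- point_in_polygon(x, y, regions[[nm]])
    out[hit & out == REGION_NONE] <- nm
  }
  out
}

# ---- internal polygon helpers -------------------------------------------

.polygon_area <- function(p) {
  n <- nrow(p)
  j <- c(2:n, 1)
  sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2]) / 2
}

.seg_intersect <- function(a1, a2, b1, b2) {
  d <- function(p, q, r) (q[1] - p[1]) * (r[2] - p[2]) - (q[2] - p[2]) * (r[1] - p[1])
  d1 <- d(b1, b2, a1); d2 <- d(b1, b2, a2)
  d3 <- d(a1, a2, b1); d4 <- d(a1, a2, b2)
  (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
     ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
}

.polygon_is_simple <- function(p) {
  n <- nrow(p)
  v <- rbind(p, p[1, ])
  if (n > 3) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      # skip adjacent edges (share a vertex)
      if (j == i || j == i %% n + 1 || i == j %% n + 1) next
      if (.seg_intersect(v[i, ], v[i + 1, ], v[j, ], v[j + 1, ])) return(FALSE)
    }
  }
  TRUE
}

.polygons_overlap <- function(a, b) {
  if (any(point_in_polygon(a[, 1], a[, 2], b)) ||
      any(point_in_polygon(b[, 1], b[, 2], a))) return(TRUE)
  na <- nrow(a); nb <- nrow(b)
  va <- rbind(a, a[1, ]); vb <- rbind(b, b[1, ])
  for (i in 1:na) for (j in 1:nb)
    if (.seg_intersect(va[i, ], va[i + 1, ], vb[j, ], vb[j + 1, ])) return(TRUE)
  FALSE
}
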