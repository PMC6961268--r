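# Nucleus segmentation from DAPI, soma definition by fixed-distance
# expansion with watershed borders between neighbouring cells, and
# assignment of decoded reads to cells and regions of interest.

#' Segment nuclei from a DAPI image
#'
#' Otsu threshold, connected components, watershed split of touching
#' nuclei seeded at distance-transform maxima, and filtering by area (and
#' optionally solidity) as a reproducible proxy for shape-descriptor
#' selection.
#'
#' @param dapi 2D numeric matrix
#' @param min_area,max_area nucleus area bounds in px^2
#' @param min_solidity optional minimum solidity (area / convex hull
#'   area); `NULL` disables the filter
#' @param watershed_tolerance tolerance of the splitting watershed on the
#'   distance transform
#' @return Object of class `cell_label_map`: list with `nuclei` (integer
#'   label matrix, 0 = background), `cells` (`NULL` until
#'   [expand_cells()]), and `table` (per-cell `cell_id`, centroid `x`,
#'   `y`, `area`).
#' @export
segment_nuclei <- function(dapi, min_area = 30, max_area = Inf,
                           min_solidity = NULL, watershed_tolerance = 1) {
  if (min_area >= max_area) stop("min_area must be below max_area")
  h <- nrow(dapi); w <- ncol(dapi)
  empty <- function() structure(
    list(nuclei = matrix(0L, h, w), cells = NULL,
         table = data.frame(cell_id = integer(0), x = numeric(0),
                            y = numeric(0), area = numeric(0))),
    class = "cell_label_map")
  mx <- max(dapi)
  if (mx <= 0) return(empty())
  norm <- dapi / mx
  thr <- EBImage::otsu(EBImage::as.Image(norm), range = c(0, 1))
  mask <- norm > thr
  if (!any(mask)) return(empty())
  dm <- EBImage::distmap(EBImage::as.Image(mask))
  labels <- as.matrix(EBImage::watershed(dm, tolerance = watershed_tolerance, ext = 1))

  # area/solidity filter, then sequential relabel
  keep <- integer(0)
  tab <- tabulate(labels[labels > 0])
  for (lab in seq_along(tab)) {
    a <- tab[lab]
    if (a < min_area || a > max_area) next
    if (!is.null(min_solidity)) {
      ii <- which(labels == lab)
      yy <- (ii - 1) %% h + 1; xx <- (ii - 1) %/% h + 1
      if (.solidity(xx, yy) < min_solidity) next
    }
    keep <- c(keep, lab)
  }
  out <- matrix(0L, h, w)
  cx <- numeric(length(keep)); cy <- numeric(length(keep)); area <- numeric(length(keep))
  for (k in seq_along(keep)) {
    ii <- which(labels == keep[k])
    out[ii] <- k
    yy <- (ii - 1) %% h + 1; xx <- (ii - 1) %/% h + 1
    cx[k] <- mean(xx); cy[k] <- mean(yy); area[k] <- length(ii)
  }
  structure(list(nuclei = out, cells = NULL,
                 table = data.frame(cell_id = seq_along(keep), x = cx, y = cy,
                                    area = area)),
            class = "cell_label_map")
}

# solidity = pixel count / convex hull area (shoelace on the hull of
# pixel centers, padded by half-pixel border via +1 correction terms)
.solidity <- function(xx, yy) {
  if (length(xx) < 4) return(1)
  pts <- unique(cbind(xx, yy))
  hull <- grDevices::chull(pts)
  hp <- pts[hull, , drop = FALSE]
  a <- abs(.polygon_area(hp))
  # hull of pixel centers underestimates pixel-covered area; pad by perimeter/2 + 1
  n <- nrow(hp)
  per <- sum(sqrt(rowSums((hp - hp[c(2:n, 1), , drop = FALSE])^2)))
  hull_area <- a + per / 2 + 1
  min(1, length(xx) / hull_area)
}

#' @export
print.cell_label_map <- function(x, ...) {
  cat(sprintf("cell_label_map: %d nuclei%s, %dx%d px\n",
              nrow(x$table),
              if (is.null(x$cells)) "" else " (expanded to cells)",
              nrow(x$nuclei), ncol(x$nuclei)))
  invisible(x)
}

#' Expand nuclei to cell somata at a fixed distance
#'
#' Each nucleus is grown outward by up to `distance` pixels (Euclidean
#' distance transform); pixels claimed by several nuclei are resolved by a
#' nearest-nucleus geodesic watershed, so neighbouring cells meet at the
#' perpendicular bisector and cells are pairwise disjoint.
#'
#' @param labmap a `cell_label_map` from [segment_nuclei()]
#' @param distance expansion distance in pixels (default 20)
#' @return The `cell_label_map` with the `cells` label matrix filled in.
#' @export
expand_cells <- function(labmap, distance = 20) {
  if (distance < 0) stop("expansion distance must be nonnegative")
  nuc <- labmap$nuclei
  if (max(nuc) == 0) { labmap$cells <- nuc; return(labmap) }
  d <- as.matrix(EBImage::distmap(EBImage::as.Image(nuc == 0)))
  mask <- d <= distance
  cells <- as.matrix(EBImage::propagate(
    EBImage::as.Image(matrix(0, nrow(nuc), ncol(nuc))),
    seeds = EBImage::as.Image(nuc),
    mask = EBImage::as.Image(mask)))
  storage.mode(cells) <- "integer"
  labmap$cells <- cells
  labmap$expansion <- distance
  labmap
}

#' Assign reads to cells and regions
#'
#' Cell assignment looks the read coordinate up in the expanded cell label
#' map (background pixels give `NA`); region assignment is
#' boundary-inclusive point-in-polygon against the ROI set.
#'
#' @param reads read table with `x`, `y` (and `spot_id`)
#' @param labmap an expanded `cell_label_map`, or `NULL` to skip cell
#'   assignment
#' @param regions a [region_set] or `NULL`
#' @return `reads` with `cell_id` (integer or `NA`) and `region`
#'   (name or `"NONE"`) columns.
#' @export
assign_reads <- function(reads, labmap = NULL, regions = NULL) {
  out <- reads
  if (!is.null(labmap)) {
    cells <- labmap$cells
    if (is.null(cells)) stop("label map has no expanded cells; run expand_cells()")
    h <- nrow(cells); w <- ncol(cells)
    xi <- round(reads$x); yi <- round(reads$y)
    bad <- xi < 1 | xi > w | yi < 1 | yi > h
    if (any(bad))
      stop("read coordinates outside image for spot_id: ",
           paste(utils::head(reads$spot_id[bad], 10), collapse = ", "))
    lab <- cells[cbind(yi, xi)]
    out$cell_id <- ifelse(lab == 0, NA_integer_, lab)
  }
  out$region <- assign_regions(reads$x, reads$y, regions)
  out
}
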