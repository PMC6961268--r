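# Synthetic ISS scene generator: nuclei in 2D tissue, named regions with
# region- and cell-class-specific per-site editing probabilities, per-cell
# Poisson read counts, 4-nt barcodes read over 4 cycles with signal,
# background, Gaussian noise and channel crosstalk — plus full ground truth,
# so every downstream stage can be tested for parameter recovery.

#' Scene configuration for the synthetic ISS generator
#'
#' @param image_shape `c(height, width)` in pixels.
#' @param n_cells number of cells (nuclei) to place.
#' @param nucleus_radius nucleus radius in pixels.
#' @param expansion soma expansion distance beyond the nucleus border, in
#'   pixels; reads are placed uniformly in the soma disk of radius
#'   `nucleus_radius + expansion - soma_margin`, matching the downstream
#'   cell definition.
#' @param soma_margin interior margin (px) kept between reads and the
#'   nominal soma border so that rounding a continuous read position to a
#'   pixel cannot push it outside the expanded cell (default 1).
#' @param cell_classes data frame with columns `name` and `proportion`
#'   (proportions must sum to 1). Class names must match the `cell_class`
#'   values of the codebook's marker entries for markers to be expressed.
#' @param regions a [region_set] or `NULL` (whole image unassigned).
#' @param editing_probs data frame with columns `site_id`, `region`,
#'   `cell_class`, `p`; `"*"` acts as a wildcard for region and class. The
#'   most specific matching row wins (exact region+class, then exact
#'   region, then exact class, then full wildcard).
#' @param default_editing_prob probability used for sites with no matching
#'   row at all.
#' @param reads_per_cell_mean Poisson mean of reads per cell.
#' @param target_weights named numeric vector of relative transcript
#'   abundances (site ids, marker names, transcript groups); unnamed
#'   targets get weight 1. Markers are expressed only in cells of their
#'   class (class-exclusive expression).
#' @param signal_intensity fluorescence of the true channel (arbitrary units).
#' @param background_intensity fluorescence of the other three channels.
#' @param noise_sd standard deviation of additive i.i.d. Gaussian noise,
#'   clipped at zero.
#' @param crosstalk 4x4 nonnegative channel mixing matrix (identity = none).
#' @param unmatched_read_rate fraction of reads carrying a random barcode
#'   absent from the codebook (off-panel artifacts).
#' @param unmatched_signal_factor signal attenuation for unmatched reads;
#'   values below 1 make artifact reads lower-quality, which is what a
#'   quality threshold calibrated on the expected-read fraction exploits.
#' @param min_spot_separation minimum distance between any two read
#'   positions in pixels (0 disables the check).
#' @param nucleus_min_separation minimal distance between nucleus centers;
#'   default `2 * nucleus_radius` (non-overlapping nuclei).
#' @param spot_sigma Gaussian spot standard deviation used by
#'   [render_scene()], in pixels.
#' @param seed integer seed; a fixed seed makes the scene fully
#'   reproducible.
#' @return A list of class `scene_config`.
#' @export
scene_config <- function(image_shape = c(512, 512),
                         n_cells = 150,
                         nucleus_radius = 8,
                         expansion = 20,
                         soma_margin = 1,
                         cell_classes = data.frame(
                           name = c("interneuron", "pyramidal",
                                    "oligodendrocyte", "astrocyte"),
                           proportion = c(0.2, 0.4, 0.2, 0.2)),
                         regions = NULL,
                         editing_probs = NULL,
                         default_editing_prob = 0.5,
                         reads_per_cell_mean = 8,
                         target_weights = NULL,
                         signal_intensity = 200,
                         background_intensity = 20,
                         noise_sd = 0,
                         crosstalk = diag(4),
                         unmatched_read_rate = 0,
                         unmatched_signal_factor = 0.3,
                         min_spot_separation = 0,
                         nucleus_min_separation = NULL,
                         spot_sigma = 1.5,
                         seed = 1L) {
  cfg <- as.list(environment())
  cell_classes <- as.data.frame(cell_classes)
  if (abs(sum(cell_classes$proportion) - 1) > 1e-8)
    stop("cell class proportions must sum to 1")
  if (any(cell_classes$proportion < 0)) stop("negative class proportion")
  if (!is.null(editing_probs)) {
    editing_probs <- as.data.frame(editing_probs)
    stopifnot(all(c("site_id", "region", "cell_class", "p") %in% names(editing_probs)))
    if (any(editing_probs$p < 0 | editing_probs$p > 1))
      stop("editing probabilities must lie in [0, 1]")
  }
  if (default_editing_prob < 0 || default_editing_prob > 1)
    stop("default_editing_prob must lie in [0, 1]")
  if (!is.null(regions) && !inherits(regions, "region_set"))
    regions <- region_set(regions)
  stopifnot(length(image_shape) == 2, all(image_shape > 0),
            nucleus_radius > 0, expansion >= 0, reads_per_cell_mean > 0,
            signal_intensity > 0, background_intensity >= 0, noise_sd >= 0,
            all(dim(crosstalk) == c(4, 4)), all(crosstalk >= 0),
            unmatched_read_rate >= 0, unmatched_read_rate <= 1)
  if (is.null(nucleus_min_separation))
    cfg$nucleus_min_separation <- 2 * nucleus_radius
  cfg$cell_classes <- cell_classes
  cfg$editing_probs <- editing_probs
  cfg$regions <- regions
  structure(cfg, class = "scene_config")
}

# editing probability lookup with wildcard precedence
.editing_prob <- function(cfg, site, region, class) {
  ep <- cfg$editing_probs
  if (is.null(ep)) return(cfg$default_editing_prob)
  cand <- ep[ep$site_id == site, , drop = FALSE]
  if (nrow(cand) == 0) return(cfg$default_editing_prob)
  score <- (cand$region == region) * 2 + (cand$cell_class == class) * 1
  score[cand$region != region & cand$region != "*"] <- -1
  score[cand$cell_class != class & cand$cell_class != "*"] <- -1
  if (all(score < 0)) return(cfg$default_editing_prob)
  cand$p[which.max(score)]
}

#' Simulate a synthetic ISS scene
#'
#' Places non-overlapping nuclei by rejection sampling, assigns each cell a
#' class (by configured proportions) and a region (by nucleus-center
#' point-in-polygon), draws a Poisson number of reads per cell, gives each
#' read a target (markers only within their class; edited/unedited variant
#' by the configured editing probability of that cell's region and class)
#' and a position uniform in the cell's soma disk, and synthesizes
#' per-cycle per-channel intensities: signal on the true channel,
#' background elsewhere, then crosstalk mixing, then Gaussian noise clipped
#' at zero. A configured fraction of reads carries a barcode absent from
#' the codebook.
#'
#' @param cfg a [scene_config]
#' @param cb a [codebook]
#' @return Object of class `iss_scene`: list with `spots` (the spot
#'   intensity table: `spot_id`, `x`, `y`, and `c<cycle>_<channel>`
#'   intensity columns), `truth` (list of `cells`, `reads`, and the
#'   expanded per-(site, region, class) `editing` probability table), plus
#'   the `config` and `codebook`.
#' @export
simulate_scene <- function(cfg, cb) {
  stopifnot(inherits(cfg, "scene_config"), inherits(cb, "codebook"))
  L <- attr(cb, "barcode_length")
  with_seed(cfg$seed, .simulate_scene_impl(cfg, cb, L))
}

.simulate_scene_impl <- function(cfg, cb, L) {
  h <- cfg$image_shape[1]; w <- cfg$image_shape[2]
  soma_r <- max(cfg$nucleus_radius + cfg$expansion - cfg$soma_margin, 1)
  margin <- soma_r + 4 * cfg$spot_sigma + 2

  if (w - 2 * margin <= 0 || h - 2 * margin <= 0)
    stop("cannot place nuclei: image too small for soma radius")

  # nucleus placement, rejection sampling on center distance
  cx <- numeric(0); cy <- numeric(0)
  attempts <- 0L; max_attempts <- 5000L * cfg$n_cells
  min_sep2 <- cfg$nucleus_min_separation^2
  while (length(cx) < cfg$n_cells) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) stop("cannot place nuclei")
    x <- stats::runif(1, margin, w - margin)
    y <- stats::runif(1, margin, h - margin)
    if (length(cx) == 0 || all((cx - x)^2 + (cy - y)^2 >= min_sep2)) {
      cx <- c(cx, x); cy <- c(cy, y)
    }
  }

  classes <- sample(cfg$cell_classes$name, cfg$n_cells, replace = TRUE,
                    prob = cfg$cell_classes$proportion)
  region <- assign_regions(cx, cy, cfg$regions)
  cells <- data.frame(cell_id = seq_len(cfg$n_cells), x = cx, y = cy,
                      cell_class = classes, region = region,
                      stringsAsFactors = FALSE)

  # transcript units: one per editing site, per marker, per other target
  pairs <- site_pairs(cb)
  markers <- cb[cb$probe_class == "marker", , drop = FALSE]
  other <- cb[!cb$probe_class %in% c("edited_variant", "unedited_variant", "marker"), , drop = FALSE]
  units <- data.frame(
    unit = c(pairs$site_id, markers$target_name, other$target_name),
    kind = c(rep("site", nrow(pairs)), rep("marker", nrow(markers)),
             rep("other", nrow(other))),
    cell_class = c(rep(NA, nrow(pairs)), markers$cell_class, rep(NA, nrow(other))),
    stringsAsFactors = FALSE)
  if (nrow(units) == 0) stop("codebook has no targets to express")
  wts <- rep(1, nrow(units))
  if (!is.null(cfg$target_weights)) {
    idx <- match(units$unit, names(cfg$target_weights))
    wts[!is.na(idx)] <- cfg$target_weights[idx[!is.na(idx)]]
  }

  ed_bc <- stats::setNames(pairs$edited_barcode, pairs$site_id)
  un_bc <- stats::setNames(pairs$unedited_barcode, pairs$site_id)
  mk_bc <- stats::setNames(markers$barcode, markers$target_name)
  ot_bc <- stats::setNames(other$barcode, other$target_name)

  n_reads <- stats::rpois(cfg$n_cells, cfg$reads_per_cell_mean)
  total <- sum(n_reads)
  reads <- data.frame(read_id = seq_len(total),
                      cell_id = rep(cells$cell_id, n_reads),
                      x = rep(NA_real_, total), y = rep(NA_real_, total),
                      target = rep(NA_character_, total),
                      site_id = rep(NA_character_, total),
                      edited = rep(NA, total),
                      barcode = rep(NA_character_, total),
                      unmatched = rep(FALSE, total), stringsAsFactors = FALSE)

  all_bc <- apply(expand.grid(rep(list(iss_channels()), L)), 1, paste0, collapse = "")
  absent_bc <- setdiff(all_bc, cb$barcode)

  # positions: uniform in the soma disk, optional global minimum spacing
  ccx <- rep(cx, n_reads); ccy <- rep(cy, n_reads)
  if (cfg$min_spot_separation <= 0) {
    r <- soma_r * sqrt(stats::runif(total))
    a <- stats::runif(total, 0, 2 * pi)
    reads$x <- ccx + r * cos(a)
    reads$y <- ccy + r * sin(a)
  } else {
    px <- numeric(total); py <- numeric(total)
    sep2 <- cfg$min_spot_separation^2
    for (i in seq_len(total)) {
      placed <- FALSE
      for (try in 1:2000) {
        r <- soma_r * sqrt(stats::runif(1))
        a <- stats::runif(1, 0, 2 * pi)
        xx <- ccx[i] + r * cos(a); yy <- ccy[i] + r * sin(a)
        if (i == 1 ||
            min((px[seq_len(i - 1)] - xx)^2 + (py[seq_len(i - 1)] - yy)^2) >= sep2) {
          placed <- TRUE; break
        }
      }
      if (!placed) stop("cannot place reads at the requested spot separation")
      px[i] <- xx; py[i] <- yy
    }
    reads$x <- px; reads$y <- py
  }

  # targets and barcodes, vectorized per (region, class) stratum
  cell_class_of <- cells$cell_class[reads$cell_id]
  cell_region_of <- cells$region[reads$cell_id]
  strat_key <- paste(cell_region_of, cell_class_of, sep = "\r")
  for (sk in unique(strat_key)) {
    idx <- which(strat_key == sk)
    reg <- cell_region_of[idx[1]]; cls <- cell_class_of[idx[1]]
    ok <- units$kind != "marker" |
      (!is.na(units$cell_class) & units$cell_class == cls)
    wi <- wts * ok
    u <- sample.int(nrow(units), length(idx), replace = TRUE, prob = wi)
    kind <- units$kind[u]; unit <- units$unit[u]
    is_site <- kind == "site"
    if (any(is_site)) {
      su <- unit[is_site]
      usites <- unique(su)
      pmap <- vapply(usites, function(s) .editing_prob(cfg, s, reg, cls), 0)
      p <- pmap[match(su, usites)]
      ed <- stats::runif(sum(is_site)) < p
      ii <- idx[is_site]
      reads$site_id[ii] <- su
      reads$edited[ii] <- ed
      reads$barcode[ii] <- ifelse(ed, ed_bc[su], un_bc[su])
    }
    if (any(!is_site)) {
      ii <- idx[!is_site]
      uu <- unit[!is_site]
      reads$barcode[ii] <- ifelse(kind[!is_site] == "marker", mk_bc[uu], ot_bc[uu])
      reads$target[ii] <- uu
    }
  }
  site_sel <- !is.na(reads$site_id)
  reads$target[site_sel] <- cb$target_name[match(reads$barcode[site_sel], cb$barcode)]
  if (cfg$unmatched_read_rate > 0 && length(absent_bc) > 0) {
    um <- stats::runif(total) < cfg$unmatched_read_rate
    reads$unmatched <- um
    if (any(um)) {
      reads$barcode[um] <- sample(absent_bc, sum(um), replace = TRUE)
      reads$target[um] <- NA_character_
      reads$site_id[um] <- NA_character_
      reads$edited[um] <- NA
    }
  }

  # intensities
  chans <- iss_channels()
  inten <- matrix(0, nrow = total, ncol = L * 4)
  colnames(inten) <- as.vector(t(outer(seq_len(L), chans,
                                       function(i, c) paste0("c", i, "_", c))))
  if (total > 0) {
    bcm <- do.call(rbind, strsplit(reads$barcode, ""))
    sig <- ifelse(reads$unmatched,
                  cfg$signal_intensity * cfg$unmatched_signal_factor,
                  cfg$signal_intensity)
    for (cyc in seq_len(L)) {
      v <- matrix(cfg$background_intensity, nrow = total, ncol = 4)
      ch_idx <- match(bcm[, cyc], chans)
      v[cbind(seq_len(total), ch_idx)] <- sig
      v <- v %*% t(cfg$crosstalk)
      if (cfg$noise_sd > 0)
        v <- v + matrix(stats::rnorm(total * 4, 0, cfg$noise_sd), ncol = 4)
      v[v < 0] <- 0
      inten[, (cyc - 1) * 4 + 1:4] <- v
    }
  }

  spots <- cbind(data.frame(spot_id = reads$read_id, x = reads$x, y = reads$y),
                 as.data.frame(inten))

  # expanded truth table of editing probabilities actually in force
  strata <- unique(data.frame(region = cells$region, cell_class = cells$cell_class,
                              stringsAsFactors = FALSE))
  editing <- do.call(rbind, lapply(pairs$site_id, function(s) {
    cbind(site_id = s, strata,
          p = vapply(seq_len(nrow(strata)), function(j)
            .editing_prob(cfg, s, strata$region[j], strata$cell_class[j]), 0))
  }))

  structure(list(spots = spots,
                 truth = list(cells = cells, reads = reads, editing = editing),
                 config = cfg, codebook = cb),
            class = "iss_scene")
}

#' @export
print.iss_scene <- function(x, ...) {
  cat(sprintf("iss_scene: %d cells, %d reads, %dx%d px, seed %d\n",
              nrow(x$truth$cells), nrow(x$truth$reads),
              x$config$image_shape[1], x$config$image_shape[2],
              x$config$seed))
  invisible(x)
}

#' Render a simulated scene to images
#'
#' Produces a DAPI image (Gaussian-blurred nucleus disks) and, per
#' sequencing cycle, four channel images in which each read is an isotropic
#' Gaussian spot carrying its per-channel intensities, plus a general-stain
#' image equal to the channel sum. Values are plain fluorescence units; use
#' [write_scene_images()] for 16-bit TIFF output.
#'
#' @param scene an `iss_scene` from [simulate_scene()]
#' @param spot_sigma Gaussian spot sd in pixels (default from the scene
#'   config)
#' @return Object of class `iss_images`: list with `dapi` (matrix),
#'   `cycles` (list per cycle of named channel matrices `A`,`C`,`G`,`T`),
#'   `general` (list per cycle), and `shape`.
#' @export
render_scene <- function(scene, spot_sigma = NULL) {
  stopifnot(inherits(scene, "iss_scene"))
  cfg <- scene$config
  if (is.null(spot_sigma)) spot_sigma <- cfg$spot_sigma
  h <- cfg$image_shape[1]; w <- cfg$image_shape[2]
  spots <- scene$spots
  if (nrow(spots) > 0 &&
      (any(spots$x < 1) || any(spots$x > w) || any(spots$y < 1) || any(spots$y > h)))
    stop("spot outside image bounds")

  dapi <- matrix(0, h, w)
  cells <- scene$truth$cells
  if (nrow(cells) > 0) {
    for (i in seq_len(nrow(cells))) {
      x0 <- cells$x[i]; y0 <- cells$y[i]; r <- cfg$nucleus_radius
      xr <- max(1, floor(x0 - r - 2)):min(w, ceiling(x0 + r + 2))
      yr <- max(1, floor(y0 - r - 2)):min(h, ceiling(y0 + r + 2))
      d2 <- outer((yr - y0)^2, (xr - x0)^2, "+")
      dapi[yr, xr] <- pmax(dapi[yr, xr], (d2 <= r^2) * 0.8)
    }
    dapi <- as.matrix(EBImage::gblur(dapi, sigma = 1.5))
  }

  L <- attr(scene$codebook, "barcode_length")
  chans <- iss_channels()
  cycles <- vector("list", L)
  general <- vector("list", L)
  r <- ceiling(4 * spot_sigma)
  for (cyc in seq_len(L)) {
    imgs <- vector("list", 4)
    names(imgs) <- chans
    for (j in seq_along(chans)) {
      vals <- spots[[paste0("c", cyc, "_", chans[j])]]
      img <- matrix(0, h, w)
      for (i in seq_len(nrow(spots))) {
        x <- spots$x[i]; y <- spots$y[i]
        xs <- max(1, round(x) - r):min(w, round(x) + r)
        ys <- max(1, round(y) - r):min(h, round(y) + r)
        gx <- exp(-(xs - x)^2 / (2 * spot_sigma^2))
        gy <- exp(-(ys - y)^2 / (2 * spot_sigma^2))
        img[ys, xs] <- img[ys, xs] + vals[i] * outer(gy, gx)
      }
      imgs[[j]] <- img
    }
    cycles[[cyc]] <- imgs
    general[[cyc]] <- imgs[[1]] + imgs[[2]] + imgs[[3]] + imgs[[4]]
  }
  structure(list(dapi = dapi, cycles = cycles, general = general,
                 shape = c(h, w)),
            class = "iss_images")
}

#' Write rendered scene images as 16-bit TIFFs with a manifest
#'
#' Writes `dapi.tif`, `cycle<i>_<channel>.tif` and `general<i>.tif` plus a
#' `manifest.json` naming the role of every file and the intensity scale
#' used (images are stored as value/65535).
#'
#' @param images an `iss_images` object
#' @param dir output directory (created if needed)
#' @return Path to the manifest, invisibly.
#' @export
write_scene_images <- function(images, dir) {
  stopifnot(inherits(images, "iss_images"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(m, f) {
    m <- pmin(pmax(m / 65535, 0), 1)
    tiff::writeTIFF(m, file.path(dir, f), bits.per.sample = 16)
    f
  }
  manifest <- list(scale = 65535, dapi = wr(images$dapi, "dapi.tif"),
                   cycles = list())
  for (cyc in seq_along(images$cycles)) {
    entry <- list(general = wr(images$general[[cyc]], sprintf("general%d.tif", cyc)))
    for (ch in names(images$cycles[[cyc]]))
      entry[[ch]] <- wr(images$cycles[[cyc]][[ch]], sprintf("cycle%d_%s.tif", cyc, ch))
    manifest$cycles[[cyc]] <- entry
  }
  mf <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE)
  invisible(mf)
}

#' Read scene images written by [write_scene_images()]
#'
#' @param manifest path to `manifest.json`
#' @return An `iss_images` object.
#' @export
read_scene_images <- function(manifest) {
  mf <- jsonlite::fromJSON(manifest, simplifyVector = FALSE)
  dir <- dirname(manifest)
  rd <- function(f) tiff::readTIFF(file.path(dir, f)) * mf$scale
  dapi <- rd(mf$dapi)
  cycles <- list(); general <- list()
  for (cyc in seq_along(mf$cycles)) {
    e <- mf$cycles[[cyc]]
    general[[cyc]] <- rd(e$general)
    cycles[[cyc]] <- lapply(e[iss_channels()], rd)
  }
  structure(list(dapi = dapi, cycles = cycles, general = general,
                 shape = dim(dapi)), class = "iss_images")
}

#' Extract the per-cycle intensity array from a spot table
#'
#' @param spots data frame with `c<cycle>_<channel>` columns
#' @param cycles number of cycles (default: inferred)
#' @return Numeric array `[spot, cycle, channel]` with channels A,C,G,T.
#' @export
intensity_array <- function(spots, cycles = NULL) {
  chans <- iss_channels()
  cols <- grep("^c[0-9]+_[ACGT]$", names(spots), value = TRUE)
  if (is.null(cycles))
    cycles <- max(as.integer(sub("^c([0-9]+)_.*$", "\\1", cols)))
  arr <- array(NA_real_, c(nrow(spots), cycles, 4),
               dimnames = list(NULL, NULL, chans))
  for (cyc in seq_len(cycles)) for (j in 1:4)
    arr[, cyc, j] <- spots[[paste0("c", cyc, "_", chans[j])]]
  arr
}
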