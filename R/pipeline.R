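# End-to-end orchestration: decode -> segment -> assign -> quantify ->
# celltype -> mixed-cell -> stats, with every intermediate table written
# as CSV and a run log carrying the seed and parameters.

#' Build a run configuration
#'
#' @param codebook a [codebook] object or a path to a codebook file
#' @param samples data frame with one row per tissue section: columns
#'   `stage`, `replicate`, and either `spots` (path to a spot intensity
#'   CSV) + optional `dapi` (TIFF path), or `seed` (simulate the section
#'   with [simulate_scene()] under `scene`)
#' @param scene a [scene_config] used for simulated samples (its `seed`
#'   is overridden per sample)
#' @param regions a [region_set] or GeoJSON path; defaults to the scene's
#'   regions for simulated runs
#' @param threshold decode quality threshold, number or `"auto"`
#' @param expected_fraction expected-read fraction for `"auto"` (default 0.95)
#' @param expansion cell expansion distance in px (default 20)
#' @param min_nucleus_area,max_nucleus_area segmentation area bounds
#' @param whole_min_reads,region_min_reads,marker_min_cells,class_min_cells
#'   the coverage filters (defaults 500 / 100 / 100 / 20)
#' @param out_dir output directory (`NULL`: tables only returned, not
#'   written)
#' @return list of class `run_config`.
#' @export
run_config <- function(codebook, samples, scene = NULL, regions = NULL,
                       threshold = "auto", expected_fraction = 0.95,
                       expansion = 20,
                       min_nucleus_area = 30, max_nucleus_area = Inf,
                       whole_min_reads = 500, region_min_reads = 100,
                       marker_min_cells = 100, class_min_cells = 20,
                       out_dir = NULL) {
  if (is.character(codebook)) codebook <- read_codebook(codebook)
  if (is.character(regions)) regions <- read_regions(regions)
  samples <- as.data.frame(samples)
  if (!all(c("stage", "replicate") %in% names(samples)))
    stop("samples needs stage and replicate columns")
  simulated <- "seed" %in% names(samples)
  if (!simulated && !"spots" %in% names(samples))
    stop("samples needs either a seed or a spots column")
  if (simulated && is.null(scene))
    stop("simulated samples require a scene config")
  if (!simulated) {
    missing <- samples$spots[!file.exists(samples$spots)]
    if (length(missing) > 0)
      stop("spot table(s) not found: ", paste(missing, collapse = ", "))
  }
  if (is.null(regions) && !is.null(scene)) regions <- scene$regions
  for (v in c(expansion, whole_min_reads, region_min_reads,
              marker_min_cells, class_min_cells))
    if (v < 0) stop("filters and distances must be nonnegative")
  structure(list(codebook = codebook, samples = samples, scene = scene,
                 regions = regions, threshold = threshold,
                 expected_fraction = expected_fraction,
                 expansion = expansion,
                 min_nucleus_area = min_nucleus_area,
                 max_nucleus_area = max_nucleus_area,
                 whole_min_reads = whole_min_reads,
                 region_min_reads = region_min_reads,
                 marker_min_cells = marker_min_cells,
                 class_min_cells = class_min_cells,
                 out_dir = out_dir, simulated = simulated),
            class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' The file holds the [run_config()] arguments: `codebook` and `regions`
#' as paths (resolved relative to the config file), a `samples` list of
#' `{stage, replicate, spots[, dapi]}` records, and any of the scalar
#' parameters (`threshold`, `expected_fraction`, `expansion`,
#' `whole_min_reads`, `region_min_reads`, `marker_min_cells`,
#' `class_min_cells`, `out_dir`).
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file
#' @return A validated [run_config].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyVector = TRUE)
  base <- dirname(normalizePath(path))
  resolve <- function(p)
    if (!is.null(p) && !grepl("^(/|[A-Za-z]:)", p)) file.path(base, p) else p
  samples <- as.data.frame(do.call(rbind, lapply(raw$samples, function(s)
    as.data.frame(s, stringsAsFactors = FALSE))))
  if ("spots" %in% names(samples))
    samples$spots <- vapply(samples$spots, resolve, "")
  args <- list(codebook = resolve(raw$codebook), samples = samples,
               regions = resolve(raw$regions))
  for (nm in c("threshold", "expected_fraction", "expansion",
               "min_nucleus_area", "max_nucleus_area", "whole_min_reads",
               "region_min_reads", "marker_min_cells", "class_min_cells",
               "out_dir"))
    if (!is.null(raw[[nm]])) args[[nm]] <- raw[[nm]]
  do.call(run_config, args)
}

#' Run the full analysis pipeline
#'
#' For every sample: obtain the spot intensity table (from file or by
#' simulating and — for cell-level analyses — rendering and segmenting a
#' DAPI image), decode barcodes, assign reads to cells and regions. Then
#' across samples: whole-tissue counts and the 500-read site filter,
#' regional counts/ratios with the 100-read filter, replicate
#' aggregation, non-strict cell classification, marker editing with the
#' 100-cell filter, the three-class temporal table with the 20-cell
#' filter, the mixed-cell observed-vs-expected analysis per stage, and
#' Kruskal-Wallis + Dunn-Sidak comparisons of regional ratios per site.
#'
#' @param cfg a [run_config]
#' @param quiet suppress progress messages
#' @return list of class `edscape_run` with elements `reads`, `whole`,
#'   `site_filter`, `regional`, `ratios`, `aggregated`, `cells`,
#'   `marker_editing`, `class_temporal`, `mixed`, `stats`, `log`. When
#'   `out_dir` is set each table is also written as CSV.
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  cb <- cfg$codebook
  say <- function(...) if (!quiet) message(...)
  all_reads <- NULL
  cell_tables <- list()
  cell_offset <- 0L
  thresholds <- numeric(0)

  for (i in seq_len(nrow(cfg$samples))) {
    s <- cfg$samples[i, ]
    tag <- paste0(s$stage, "/", s$replicate)
    say("[", tag, "] decode")
    if (cfg$simulated) {
      sc <- cfg$scene
      sc$seed <- as.integer(s$seed)
      scene <- simulate_scene(sc, cb)
      spots <- scene$spots
      dapi <- render_dapi(scene)
    } else {
      spots <- utils::read.csv(s$spots)
      dapi <- if ("dapi" %in% names(s) && nzchar(s$dapi) && !is.na(s$dapi))
        tiff::readTIFF(s$dapi) else NULL
    }
    reads <- decode_spots(spots, cb, cfg$threshold, cfg$expected_fraction)
    thresholds[tag] <- attr(reads, "threshold")

    labmap <- NULL
    if (!is.null(dapi)) {
      say("[", tag, "] segment")
      labmap <- segment_nuclei(dapi, cfg$min_nucleus_area, cfg$max_nucleus_area)
      labmap <- expand_cells(labmap, cfg$expansion)
    }
    reads <- assign_reads(reads, labmap, cfg$regions)
    if (!is.null(labmap) && nrow(labmap$table) > 0 && any(!is.na(reads$cell_id)))
      reads$cell_id <- reads$cell_id + cell_offset
    cell_offset <- cell_offset + if (is.null(labmap)) 0L else nrow(labmap$table)
    reads$stage <- as.character(s$stage)
    reads$replicate <- as.character(s$replicate)
    all_reads <- rbind(all_reads, as.data.frame(reads))
  }

  pass <- all_reads[all_reads$pass_qc, , drop = FALSE]
  say("quantify")
  whole <- whole_counts(pass, cb, by = c("replicate", "stage"))
  sf <- whole_brain_site_filter(
    data.frame(site_id = whole$site_id, replicate = whole$replicate,
               stage = whole$stage, n_edited = whole$n_edited,
               n_unedited = whole$n_unedited),
    min_reads = cfg$whole_min_reads)
  retained <- sf$site_id[sf$retained]

  regional <- NULL; ratios <- NULL; aggregated <- NULL
  if (!is.null(cfg$regions) && length(cfg$regions) > 0) {
    regional <- do.call(rbind, lapply(split(pass, pass$stage), function(r) {
      rc <- regional_counts(r, cb, min_reads = cfg$region_min_reads,
                            replicate = "replicate")
      rc$stage <- r$stage[1]
      rc
    }))
    rownames(regional) <- NULL
    regional <- regional[regional$site_id %in% retained, , drop = FALSE]
    ratios <- do.call(rbind, lapply(split(regional, regional$stage), function(rc) {
      rr <- regional_ratios(rc)
      rr$stage <- rc$stage[1]
      rr
    }))
    rownames(ratios) <- NULL
    aggregated <- aggregate_replicates(regional[regional$stratum == "region", ])
  }

  say("cell typing")
  have_cells <- any(!is.na(pass$cell_id))
  cells_df <- NULL; marker_ed <- NULL; class_tmp <- NULL; mixed <- NULL
  if (have_cells) {
    ct <- build_cell_table(pass, cb, replicate = "replicate", stage = "stage")
    ct <- classify_cells(ct)
    cells_df <- merge(ct$cells,
                      stats::aggregate(cell_class ~ cell_id,
                                       data = ct$classes,
                                       FUN = function(v) paste(sort(v), collapse = ";")),
                      by = "cell_id", all.x = TRUE)
    markers <- cb$target_name[cb$probe_class == "marker"]
    for (sid in retained) for (mk in markers) {
      me <- marker_editing(ct, sid, mk, min_cells = cfg$marker_min_cells,
                           replicate = "replicate")
      marker_ed <- rbind(marker_ed, me)
    }
    classes <- unique(cb$cell_class[cb$probe_class == "marker"])
    class_tmp <- do.call(rbind, lapply(retained, function(sid)
      class_temporal_editing(ct, sid, classes = classes,
                             min_cells_per_replicate = cfg$class_min_cells,
                             replicate = "replicate", stage = "stage")))
    mixed <- do.call(rbind, lapply(split(pass, pass$stage), function(r) {
      cts <- build_cell_table(r, cb)
      mt <- mixed_cell_table(cts)
      mt$stage <- r$stage[1]
      mt[mt$site_id %in% retained, , drop = FALSE]
    }))
    rownames(mixed) <- NULL
  }

  say("statistics")
  stat_rows <- NULL
  if (!is.null(ratios)) {
    for (st in unique(ratios$stage)) for (sid in unique(ratios$site_id)) {
      sub <- ratios[ratios$stage == st & ratios$site_id == sid &
                      !is.na(ratios$ratio), ]
      if (length(unique(sub$region)) < 2 || nrow(sub) < 3) next
      gc <- tryCatch(group_comparison(sub$ratio, sub$region),
                     error = function(e) NULL)
      if (is.null(gc)) next
      pw <- gc$pairwise
      stat_rows <- rbind(stat_rows, data.frame(
        stage = st, site_id = sid, H = gc$H, p_omnibus = gc$p_omnibus,
        pw, stringsAsFactors = FALSE))
    }
  }

  run <- structure(list(reads = all_reads, whole = whole, site_filter = sf,
                        regional = regional, ratios = ratios,
                        aggregated = aggregated, cells = cells_df,
                        marker_editing = marker_ed,
                        class_temporal = class_tmp, mixed = mixed,
                        stats = stat_rows,
                        log = list(time = format(Sys.time()),
                                   thresholds = thresholds,
                                   n_samples = nrow(cfg$samples),
                                   n_reads = nrow(all_reads),
                                   n_pass = nrow(pass),
                                   retained_sites = retained,
                                   filters = c(whole = cfg$whole_min_reads,
                                               region = cfg$region_min_reads,
                                               marker_cells = cfg$marker_min_cells,
                                               class_cells = cfg$class_min_cells))),
                   class = "edscape_run")
  if (!is.null(cfg$out_dir)) write_run(run, cfg$out_dir)
  run
}

#' @export
print.edscape_run <- function(x, ...) {
  cat(sprintf("edscape run: %d samples, %d reads (%d passing QC), %d/%d sites retained\n",
              x$log$n_samples, x$log$n_reads, x$log$n_pass,
              length(x$log$retained_sites), nrow(x$site_filter)))
  invisible(x)
}

#' Write all run tables to a directory
#'
#' @param run an `edscape_run`
#' @param dir output directory
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("reads", "whole", "site_filter", "regional", "ratios",
               "aggregated", "cells", "marker_editing", "class_temporal",
               "mixed", "stats")) {
    if (!is.null(run[[nm]]))
      utils::write.csv(run[[nm]], file.path(dir, paste0(nm, ".csv")),
                       row.names = FALSE)
  }
  writeLines(jsonlite::toJSON(run$log, auto_unbox = TRUE, pretty = TRUE),
             file.path(dir, "run_log.json"))
  invisible(dir)
}

#' Render only the DAPI image of a scene
#'
#' Cheaper than [render_scene()] when just the nuclei are needed for
#' segmentation.
#'
#' @param scene an `iss_scene`
#' @return DAPI matrix.
#' @export
render_dapi <- function(scene) {
  cfg <- scene$config
  h <- cfg$image_shape[1]; w <- cfg$image_shape[2]
  dapi <- matrix(0, h, w)
  cells <- scene$truth$cells
  for (i in seq_len(nrow(cells))) {
    x0 <- cells$x[i]; y0 <- cells$y[i]; r <- cfg$nucleus_radius
    xr <- max(1, floor(x0 - r - 2)):min(w, ceiling(x0 + r + 2))
    yr <- max(1, floor(y0 - r - 2)):min(h, ceiling(y0 + r + 2))
    d2 <- outer((yr - y0)^2, (xr - x0)^2, "+")
    dapi[yr, xr] <- pmax(dapi[yr, xr], (d2 <= r^2) * 0.8)
  }
  if (nrow(cells) > 0) dapi <- as.matrix(EBImage::gblur(dapi, sigma = 1.5))
  dapi
}

#' Demo run configuration on a synthetic scene
#'
#' A two-region scene whose codebook has 22 editing sites of which 7 are
#' given low abundance so that exactly 15 survive the 500-read
#' whole-tissue filter at the default scale.
#'
#' @param n_replicates sections to simulate (default 2)
#' @param n_cells,reads_per_cell_mean scene scale
#' @param seed base seed; replicate r uses `seed + r`
#' @param out_dir optional output directory
#' @return A [run_config].
#' @export
demo_run_config <- function(n_replicates = 2, n_cells = 600,
                            reads_per_cell_mean = 50, seed = 1L,
                            out_dir = NULL) {
  cb <- example_codebook(n_sites = 22, seed = seed)
  sites <- site_pairs(cb)$site_id
  rare <- sites[16:22]
  wts <- stats::setNames(rep(1, length(sites)), sites)
  wts[rare] <- 0.05
  shape <- c(600, 600)
  regions <- rect_regions(shape, c("thalamus", "hypothalamus"), nx = 2, ny = 1,
                          margin = 2)
  probs <- rbind(
    data.frame(site_id = sites, region = "thalamus", cell_class = "*", p = 0.65),
    data.frame(site_id = sites, region = "hypothalamus", cell_class = "*", p = 0.40))
  sc <- scene_config(image_shape = shape, n_cells = n_cells,
                     reads_per_cell_mean = reads_per_cell_mean,
                     regions = regions, editing_probs = probs,
                     target_weights = wts, noise_sd = 10, seed = seed)
  samples <- data.frame(stage = "P7", replicate = as.character(seq_len(n_replicates)),
                        seed = seed + seq_len(n_replicates))
  run_config(cb, samples, scene = sc, threshold = 0.4, out_dir = out_dir)
}
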