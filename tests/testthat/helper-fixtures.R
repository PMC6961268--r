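# Shared fixtures: a tiny hand-written codebook and small scene configs.

tiny_codebook <- function() {
  codebook(data.frame(
    target_name = c("Cyfip2_ed", "Cyfip2_un", "Gria2_ed", "Gria2_un",
                    "Sst", "Gfap", "Adar2"),
    barcode = c("AAGC", "AAGT", "CCAG", "CCAA", "GGGG", "TTTT", "ACGT"),
    probe_class = c("edited_variant", "unedited_variant",
                    "edited_variant", "unedited_variant",
                    "marker", "marker", "adar"),
    site_id = c("Cyfip2_KE", "Cyfip2_KE", "Gria2_QR", "Gria2_QR", NA, NA, NA),
    cell_class = c(NA, NA, NA, NA, "interneuron", "astrocyte", NA),
    transcript_group = c(NA, NA, NA, NA, NA, NA, "Adar2"),
    stringsAsFactors = FALSE))
}

# a small clean scene: two regions, two classes, noiseless by default
small_scene_config <- function(seed = 1, ...) {
  args <- list(...)
  defaults <- list(
    image_shape = c(256, 256), n_cells = 40, reads_per_cell_mean = 6,
    cell_classes = data.frame(name = c("interneuron", "astrocyte"),
                              proportion = c(0.5, 0.5)),
    regions = rect_regions(c(256, 256), c("thalamus", "hypothalamus"),
                           nx = 2, ny = 1),
    seed = seed)
  defaults[names(args)] <- args
  do.call(scene_config, defaults)
}

# cell table with prescribed per-cell (edited, unedited) counts of the
# Cyfip2_KE site of the tiny codebook
ct_from_counts <- function(counts) {
  rows <- list()
  for (i in seq_len(nrow(counts))) {
    ne <- counts$ed[i]; nu <- counts$un[i]
    if (ne > 0) rows[[length(rows) + 1]] <-
        data.frame(cell_id = i, target = rep("Cyfip2_ed", ne))
    if (nu > 0) rows[[length(rows) + 1]] <-
        data.frame(cell_id = i, target = rep("Cyfip2_un", nu))
  }
  build_cell_table(do.call(rbind, rows), tiny_codebook())
}
accept_ct_from_counts <- ct_from_counts

# annotate decoded reads with their called site/variant (from the codebook)
# and the generative cell class of the cell each read came from (the class
# is the stratum definition, not a measured quantity; decode_spots preserves
# the spot order, so truth rows align one-to-one)
annotate_region_class <- function(reads, sc) {
  cbk <- sc$codebook
  idx <- match(reads$target, cbk$target_name)
  reads$site <- cbk$site_id[idx]
  reads$edited_call <- cbk$probe_class[idx] == "edited_variant"
  reads$cell_class <- sc$truth$cells$cell_class[sc$truth$reads$cell_id]
  reads
}

# spot rows from explicit per-cycle intensity vectors (list of 4-vectors)
spot_from_cycles <- function(cycles) {
  row <- data.frame(spot_id = 1L, x = 10, y = 10)
  for (i in seq_along(cycles)) {
    v <- cycles[[i]]
    for (j in 1:4) row[[paste0("c", i, "_", iss_channels()[j])]] <- v[j]
  }
  row
}
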