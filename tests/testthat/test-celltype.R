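# helper: cell table straight from simulation ground truth
truth_cell_table <- function(sc, cb) {
  tr <- sc$truth$reads
  tr <- tr[!tr$unmatched, ]
  reads <- data.frame(cell_id = tr$cell_id, target = tr$target,
                      region = sc$truth$cells$region[tr$cell_id],
                      stringsAsFactors = FALSE)
  build_cell_table(reads, cb)
}

test_that("classification is non-strict: multi-marker cells join every class", {
  cb <- tiny_codebook()
  reads <- data.frame(
    cell_id = c(1L, 1L, 2L, 3L, 3L),
    target = c("Sst", "Gfap", "Cyfip2_ed", "Adar2", "Sst"))
  ct <- classify_cells(build_cell_table(reads, cb))
  cl1 <- ct$classes$cell_class[ct$classes$cell_id == 1]
  expect_setequal(cl1, c("interneuron", "astrocyte"))
  expect_equal(sum(ct$classes$cell_id == 2), 0)  # no marker reads
  expect_equal(ct$classes$cell_class[ct$classes$cell_id == 3], "interneuron")
})

test_that("class-exclusive simulated markers classify cells perfectly", {
  cb <- tiny_codebook()
  sc <- simulate_scene(small_scene_config(seed = 41, n_cells = 60,
                                          reads_per_cell_mean = 12), cb)
  ct <- classify_cells(truth_cell_table(sc, cb))
  truth_class <- sc$truth$cells$cell_class
  for (i in seq_len(nrow(ct$classes))) {
    row <- ct$classes[i, ]
    expect_equal(row$cell_class, truth_class[row$cell_id])
  }
  expect_gt(nrow(ct$classes), 0)
})

test_that("marker positive and negative cells partition reads and counts", {
  cb <- tiny_codebook()
  sc <- simulate_scene(small_scene_config(seed = 42, n_cells = 80,
                                          reads_per_cell_mean = 20), cb)
  ct <- classify_cells(truth_cell_table(sc, cb))
  me <- marker_editing(ct, "Cyfip2_KE", "Sst", min_cells = 1)
  w <- sum(ct$counts$n[ct$counts$target == "Cyfip2_ed"])
  expect_equal(sum(me$n_edited), w)
  expect_equal(nrow(me), 2)
  expect_error(marker_editing(ct, "Cyfip2_KE", "NotAMarker"), "unknown marker")
})

test_that("marker-stratified levels recover class-specific editing", {
  cb <- tiny_codebook()
  probs <- data.frame(site_id = "Cyfip2_KE", region = "*",
                      cell_class = c("interneuron", "astrocyte"),
                      p = c(0.8, 0.2))
  cfg <- small_scene_config(seed = 43, image_shape = c(768, 768), n_cells = 250,
                            reads_per_cell_mean = 25, regions = NULL,
                            editing_probs = probs)
  sc <- simulate_scene(cfg, cb)
  ct <- classify_cells(truth_cell_table(sc, cb))
  me <- marker_editing(ct, "Cyfip2_KE", "Sst", min_cells = 10)
  pos <- me[me$stratum == "marker:Sst", ]
  n <- pos$n_edited + pos$n_unedited
  expect_lt(abs(pos$level - 0.8), 3 * sqrt(0.8 * 0.2 / n))
  ratio <- marker_editing_ratio(me$level[1], me$level[2])
  expect_gt(ratio, 1.5)  # 0.8 vs mixed-negative strata well below
})

test_that("the 100-cell marker filter uses the replicate mean, boundary exact", {
  cb <- tiny_codebook()
  mk_ct <- function(n_cells) {
    reads <- do.call(rbind, lapply(seq_len(n_cells), function(i)
      data.frame(cell_id = i, target = c("Sst", "Cyfip2_ed"))))
    classify_cells(build_cell_table(reads, cb))
  }
  expect_equal(marker_editing(mk_ct(99), "Cyfip2_KE", "Sst")$qc[1],
               "below_100_cells")
  expect_equal(marker_editing(mk_ct(100), "Cyfip2_KE", "Sst")$qc[1], "")
  none <- marker_editing(mk_ct(5), "Cyfip2_KE", "Gfap")
  expect_true(is.na(none$level[none$stratum == "marker:Gfap"]))
})

test_that("the temporal class analysis applies the per-replicate 20-cell filter", {
  cb <- tiny_codebook()
  mk_reads <- function(n_cells, rep_id, offset) {
    do.call(rbind, lapply(seq_len(n_cells), function(i)
      data.frame(cell_id = offset + i, target = c("Sst", "Cyfip2_ed", "Cyfip2_un"),
                 rep = rep_id)))
  }
  reads <- rbind(mk_reads(19, "r1", 0), mk_reads(20, "r2", 1000))
  ct <- classify_cells(build_cell_table(reads, cb, replicate = "rep"))
  te <- class_temporal_editing(ct, "Cyfip2_KE", classes = "interneuron",
                               replicate = "rep")
  expect_equal(te$qc[te$replicate == "r1"], "below_20_cells")
  expect_equal(te$qc[te$replicate == "r2"], "")
  expect_equal(te$level[te$replicate == "r2"], 0.5)
})

test_that("class differences in editing are detectable across replicate levels", {
  cb <- tiny_codebook()
  probs <- data.frame(site_id = "Cyfip2_KE", region = "*",
                      cell_class = c("interneuron", "astrocyte"),
                      p = c(0.8, 0.4))
  per_rep <- lapply(1:4, function(r) {
    cfg <- small_scene_config(seed = 50 + r, image_shape = c(512, 512),
                              n_cells = 150, reads_per_cell_mean = 15,
                              regions = NULL, editing_probs = probs)
    sc <- simulate_scene(cfg, cb)
    ct <- classify_cells(truth_cell_table(sc, cb))
    te <- class_temporal_editing(ct, "Cyfip2_KE",
                                 classes = c("interneuron", "astrocyte"),
                                 min_cells_per_replicate = 5)
    te$replicate <- as.character(r)
    te
  })
  te <- do.call(rbind, per_rep)
  gc <- group_comparison(te$level, te$cell_class)
  expect_lt(gc$p_omnibus, 0.05)
})
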