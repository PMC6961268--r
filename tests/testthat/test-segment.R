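test_that("nuclei of a rendered scene are recovered with accurate centroids", {
  cb <- tiny_codebook()
  cfg <- small_scene_config(seed = 21, image_shape = c(768, 768), n_cells = 100,
                            reads_per_cell_mean = 1, regions = NULL,
                            nucleus_min_separation = 40)
  sc <- simulate_scene(cfg, cb)
  lm <- segment_nuclei(render_dapi(sc))
  expect_equal(nrow(lm$table), 100)
  truth <- sc$truth$cells
  d <- sqrt(outer(truth$x, lm$table$x, "-")^2 + outer(truth$y, lm$table$y, "-")^2)
  expect_lt(max(apply(d, 1, min)), 2)
})

test_that("a blank DAPI image yields zero nuclei without error", {
  lm <- segment_nuclei(matrix(0, 64, 64))
  expect_equal(nrow(lm$table), 0)
  expect_error(segment_nuclei(matrix(0, 8, 8), min_area = 10, max_area = 5),
               "min_area")
})

test_that("touching nuclei are split by the watershed", {
  img <- matrix(0, 80, 80)
  for (y in 1:80) for (x in 1:80) {
    if ((x - 30)^2 + (y - 40)^2 <= 100) img[y, x] <- 1
    if ((x - 45)^2 + (y - 40)^2 <= 100) img[y, x] <- 1  # centers 1.5 radii apart
  }
  img <- as.matrix(EBImage::gblur(img, 1))
  lm <- segment_nuclei(img, min_area = 20)
  expect_equal(nrow(lm$table), 2)
})

test_that("expansion grows a nucleus into a soma disk of the right area", {
  nuc <- matrix(0L, 101, 101)
  for (y in 1:101) for (x in 1:101)
    if ((x - 51)^2 + (y - 51)^2 <= 100) nuc[y, x] <- 1L
  lm <- structure(list(nuclei = nuc, cells = NULL,
                       table = data.frame(cell_id = 1L, x = 51, y = 51,
                                          area = sum(nuc))),
                  class = "cell_label_map")
  expect_error(expand_cells(lm, -1), "nonnegative")
  lm20 <- expand_cells(lm, 20)
  expect_lt(abs(sum(lm20$cells == 1) - pi * 30^2) / (pi * 30^2), 0.05)
  # nucleus pixels are inside the cell; monotone growth with distance
  expect_true(all(lm20$cells[lm$nuclei == 1L] == 1L))
  lm10 <- expand_cells(lm, 10)
  expect_lt(sum(lm10$cells == 1), sum(lm20$cells == 1))
})

test_that("distant nuclei stay separated, near nuclei split at the bisector", {
  mk <- function(cx1, cx2) {
    nuc <- matrix(0L, 101, 161)
    for (y in 1:101) for (x in 1:161) {
      if ((x - cx1)^2 + (y - 51)^2 <= 25) nuc[y, x] <- 1L
      if ((x - cx2)^2 + (y - 51)^2 <= 25) nuc[y, x] <- 2L
    }
    structure(list(nuclei = nuc, cells = NULL,
                   table = data.frame(cell_id = 1:2, x = c(cx1, cx2), y = 51,
                                      area = NA)),
              class = "cell_label_map")
  }
  far <- expand_cells(mk(40, 120), 20)  # 80 px apart: gap in between
  mid_col <- far$cells[, 80]
  expect_true(all(mid_col == 0))
  near <- expand_cells(mk(60, 90), 20)  # 30 px apart: frontier at bisector
  left <- which(near$cells == 1, arr.ind = TRUE)
  right <- which(near$cells == 2, arr.ind = TRUE)
  expect_lte(max(left[, "col"]), 76)
  expect_gte(min(right[, "col"]), 75)
  expect_equal(sum(near$cells == 1 & near$cells == 2), 0)
  # every cell pixel is within the expansion distance of its nucleus
  d <- as.matrix(EBImage::distmap(EBImage::as.Image(near$nuclei == 0)))
  expect_true(all(d[near$cells > 0] <= 20 + 1e-6))
})

test_that("reads are assigned to their true cells and to regions inclusively", {
  cb <- tiny_codebook()
  cfg <- small_scene_config(seed = 22, image_shape = c(600, 600), n_cells = 30,
                            reads_per_cell_mean = 8,
                            nucleus_min_separation = 64,
                            regions = rect_regions(c(600, 600),
                                                   c("thalamus", "hypothalamus"),
                                                   nx = 2, ny = 1))
  sc <- simulate_scene(cfg, cb)
  lm <- expand_cells(segment_nuclei(render_dapi(sc)), cfg$expansion)
  reads <- assign_reads(sc$truth$reads, lm, cfg$regions)
  # map each truth cell to the segmented label under its nucleus center
  truth_cells <- sc$truth$cells
  lab_of_truth <- lm$cells[cbind(round(truth_cells$y), round(truth_cells$x))]
  expected <- lab_of_truth[sc$truth$reads$cell_id]
  ok <- !is.na(reads$cell_id) & reads$cell_id == expected
  expect_gte(mean(ok), 0.99)
  # region agreement with the generative region of the cell
  cell_region <- truth_cells$region[sc$truth$reads$cell_id]
  in_regions <- reads$region != REGION_NONE & cell_region != REGION_NONE
  expect_gte(mean(reads$region[in_regions] == cell_region[in_regions]), 0.95)
})

test_that("background pixels, polygon vertices and out-of-bounds reads behave as specified", {
  nuc <- matrix(0L, 50, 50); nuc[20:25, 20:25] <- 1L
  lm <- expand_cells(structure(list(nuclei = nuc, cells = NULL,
                                    table = data.frame(cell_id = 1L, x = 22,
                                                       y = 22, area = 36)),
                               class = "cell_label_map"), 5)
  regions <- region_set(list(roi = cbind(x = c(10, 40, 40, 10),
                                         y = c(10, 10, 40, 40))))
  reads <- data.frame(spot_id = 1:3, x = c(2, 10, 22), y = c(2, 10, 22))
  out <- assign_reads(reads, lm, regions)
  expect_true(is.na(out$cell_id[1]))          # background, far from the cell
  expect_equal(out$region[1], REGION_NONE)
  expect_equal(out$region[2], "roi")          # exactly on a polygon vertex
  expect_equal(out$cell_id[3], 1L)
  expect_error(assign_reads(data.frame(spot_id = 9L, x = 99, y = 2), lm, regions),
               "spot_id: 9")
})
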