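test_that("registration recovers identity and constructed shifts", {
  set.seed(1)
  img <- matrix(rnorm(96 * 96), 96, 96)
  img <- as.matrix(EBImage::gblur(img, 2))
  expect_equal(register_translation(img, img), c(dx = 0L, dy = 0L))
  shifted <- apply_translation(img, 3, -2)
  expect_equal(register_translation(shifted, img), c(dx = -3L, dy = 2L))
  expect_equal(register_translation(img, shifted), c(dx = 3L, dy = -2L))
})

test_that("registration is exact under moderate noise", {
  set.seed(11)
  base <- as.matrix(EBImage::gblur(matrix(runif(96 * 96), 96, 96), 2))
  amp <- diff(range(base))
  for (s in 1:5) {
    noisy <- apply_translation(base, 4, -3) + matrix(rnorm(96 * 96, 0, 0.05 * amp), 96, 96)
    expect_equal(register_translation(noisy, base), c(dx = -4L, dy = 3L))
  }
})

test_that("flat images cannot be registered", {
  flat <- matrix(1, 32, 32)
  expect_error(register_translation(flat, flat), "registration undefined")
})

test_that("spot detection finds rendered spots and nothing in flat fields", {
  expect_equal(nrow(detect_spots(matrix(5, 64, 64))), 0)
  expect_error(detect_spots(matrix(0, 8, 8), tophat_radius = 0), "positive")
  img <- matrix(0, 64, 64)
  add <- function(img, x, y, v) {
    for (dy in -5:5) for (dx in -5:5)
      img[y + dy, x + dx] <- img[y + dy, x + dx] + v * exp(-(dx^2 + dy^2) / (2 * 1.5^2))
    img
  }
  one <- add(img, 30, 20, 100)
  sp <- detect_spots(one, min_intensity = 20)
  expect_equal(nrow(sp), 1)
  expect_equal(c(sp$x, sp$y), c(30, 20))
  two <- add(one, 40, 20, 100)
  sp2 <- detect_spots(two, min_intensity = 20)
  expect_equal(nrow(sp2), 2)
  ord <- order(sp2$x)
  expect_lt(max(abs(sp2$x[ord] - c(30, 40))), 1.5)
  expect_lt(max(abs(sp2$y - 20)), 1.5)
})

test_that("intensity extraction round-trips rendered channel intensities", {
  cb <- tiny_codebook()
  cfg <- small_scene_config(seed = 5, n_cells = 3, reads_per_cell_mean = 4,
                            regions = NULL, image_shape = c(128, 128))
  sc <- simulate_scene(cfg, cb)
  sc$spots <- sc$spots[1, , drop = FALSE]
  sc$spots$x <- 30; sc$spots$y <- 30
  chans <- paste0("c1_", iss_channels())
  sc$spots[chans] <- as.list(c(100, 10, 10, 10))
  imgs <- render_scene(sc)
  got <- extract_intensities(sc$spots[c("spot_id", "x", "y")], imgs)
  expect_equal(unlist(got[chans]), unlist(sc$spots[chans]),
               tolerance = 0.01, ignore_attr = TRUE)
  expect_false(got$edge_flag)
  corner <- sc$spots[c("spot_id", "x", "y")]
  corner$x <- 1; corner$y <- 1
  expect_true(extract_intensities(corner, imgs)$edge_flag)
  none <- extract_intensities(sc$spots[0, c("spot_id", "x", "y")], imgs)
  expect_equal(nrow(none), 0)
})

test_that("base calling follows the max-intensity rule with max/sum quality", {
  sp <- spot_from_cycles(list(c(1, 1, 1, 1), c(10, 0, 0, 0),
                              c(4, 2, 2, 2), c(0, 0, 1, 9)))
  called <- call_bases(sp)
  expect_equal(called$q1, 0.25)
  expect_equal(called$q2, 1.0)
  expect_equal(called$q3, 0.4)
  expect_equal(called$q4, 0.9)
  expect_equal(called$barcode, "AAAT")
  expect_equal(called$quality, 0.25)
  # read quality is the minimum base quality
  sp2 <- spot_from_cycles(list(c(4, 2, 2, 2), c(9, 1, 0, 0),
                               c(0, 8, 1, 1), c(1, 1, 8, 0)))
  expect_equal(call_bases(sp2)$quality, 0.4)
  # ties resolved by fixed channel order A < C < G < T
  tie <- call_bases(spot_from_cycles(list(c(5, 5, 0, 0), c(0, 3, 3, 0),
                                          c(1, 1, 1, 1), c(0, 0, 2, 2))))
  expect_equal(tie$barcode, "ACAG")
})

test_that("an all-zero cycle makes the read uncallable, with reason preserved", {
  sp <- spot_from_cycles(list(c(1, 2, 3, 4), c(0, 0, 0, 0),
                              c(1, 0, 0, 0), c(2, 2, 2, 2)))
  called <- call_bases(sp)
  expect_false(called$callable)
  expect_true(is.na(called$barcode))
  expect_true(is.na(called$quality))
})

test_that("base quality spans exactly [0.25, 1] over random intensities", {
  set.seed(99)
  v <- matrix(rexp(4e4), ncol = 4)
  sp <- data.frame(spot_id = seq_len(nrow(v)), x = 1, y = 1,
                   c1_A = v[, 1], c1_C = v[, 2], c1_G = v[, 3], c1_T = v[, 4])
  q <- call_bases(sp)$q1
  expect_true(all(q >= 0.25 & q <= 1))
  expect_equal(call_bases(spot_from_cycles(list(c(7, 7, 7, 7))))$q1, 0.25)
  expect_equal(call_bases(spot_from_cycles(list(c(0, 0, 3, 0))))$q1, 1)
  expect_true(all(q[apply(v, 1, function(r) sum(r > 0) == 1)] == 1))
})

test_that("matching and filtering respects the threshold boundary and conserves reads", {
  cb <- tiny_codebook()
  sc <- simulate_scene(small_scene_config(seed = 12, noise_sd = 15,
                                          unmatched_read_rate = 0.2), cb)
  called <- call_bases(sc$spots)
  expect_error(match_and_filter(called, cb, threshold = 0.2), "0.25")
  expect_error(match_and_filter(called, cb, threshold = 1.01), "0.25")
  filt <- match_and_filter(called, cb, threshold = 0.35)
  cnt <- attr(filt, "counts")
  expect_equal(cnt[["n_total"]],
               cnt[["n_pass"]] + cnt[["n_fail_quality"]] +
                 cnt[["n_unmatched_only"]] + cnt[["n_uncallable"]])
  # strict >= at the boundary, on a read with a matched barcode
  one <- data.frame(spot_id = 1L, x = 1, y = 1, barcode = "AAGC",
                    quality = 0.34, callable = TRUE)
  expect_false(match_and_filter(one, cb, threshold = 0.35)$pass_qc)
  one$quality <- 0.35
  expect_true(match_and_filter(one, cb, threshold = 0.35)$pass_qc)
  # unmatched reads fail regardless of quality
  um <- called[1, , drop = FALSE]
  um$barcode <- "AAAA"; um$quality <- 0.99
  expect_false(match_and_filter(um, cb, threshold = 0.35)$pass_qc)
  # raising the threshold never increases the passing count
  n_pass <- vapply(seq(0.25, 1, by = 0.05), function(th)
    sum(match_and_filter(called, cb, th)$pass_qc), 0)
  expect_true(all(diff(n_pass) <= 0))
})

test_that("noiseless decode matches truth perfectly at threshold 0.5", {
  cb <- tiny_codebook()
  sc <- simulate_scene(small_scene_config(seed = 13), cb)
  reads <- decode_spots(sc$spots, cb, threshold = 0.5)
  expect_true(all(reads$pass_qc))
  expect_equal(reads$target, sc$truth$reads$target)
})

test_that("threshold calibration attains the expected-read fraction", {
  cb <- tiny_codebook()
  # clean scene: everything matched, lowest grid value suffices
  clean <- simulate_scene(small_scene_config(seed = 14), cb)
  thr <- calibrate_threshold(call_bases(clean$spots), cb)
  expect_equal(as.numeric(thr), 0.25)
  # half the reads off-panel with attenuated signal: calibration separates them
  dirty <- simulate_scene(small_scene_config(
    seed = 15, n_cells = 80, reads_per_cell_mean = 15, noise_sd = 25,
    unmatched_read_rate = 0.5, unmatched_signal_factor = 0), cb)
  called <- call_bases(dirty$spots)
  thr2 <- calibrate_threshold(called, cb, target_fraction = 0.95)
  expect_false(attr(thr2, "warning"))
  refilt <- match_and_filter(called, cb, as.numeric(thr2))
  cnt <- attr(refilt, "counts")
  frac <- cnt[["n_pass"]] / (cnt[["n_pass"]] + cnt[["n_unmatched_only"]])
  expect_gte(frac, 0.95)
  # an unattainable target returns 1.00 with a warning flag
  um <- call_bases(dirty$spots)[1, , drop = FALSE]
  um$barcode <- "AAAA"; um$quality <- 1
  both <- rbind(call_bases(clean$spots), um)
  expect_warning(thr3 <- calibrate_threshold(both, cb, target_fraction = 1.0),
                 "not attainable")
  expect_equal(as.numeric(thr3), 1.0)
  expect_error(calibrate_threshold(both[0, ], cb), "no reads")
})
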