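test_that("editing level is the edited fraction with NA on empty denominators", {
  expect_equal(editing_level(50, 50), 0.5)
  expect_equal(editing_level(90, 10), 0.9)
  expect_true(is.na(editing_level(0, 0)))
  expect_equal(editing_level(c(1, 0), c(1, 0)), c(0.5, NA))
  expect_error(editing_level(-1, 5), "nonnegative")
})

test_that("editing ratio divides stratum by complement with NA guards", {
  expect_equal(editing_ratio(0.5, 0.5), 1.0)
  expect_equal(editing_ratio(0.8, 0.4), 2.0)
  expect_true(is.na(editing_ratio(0.3, 0)))
  expect_true(is.na(editing_ratio(NA, 0.4)))
})

test_that("the whole-tissue filter keeps sites by the stage-best mean minor variant", {
  counts <- rbind(
    data.frame(site_id = "a", replicate = "1", stage = c("E15", "Adult"),
               n_edited = c(20, 500), n_unedited = c(5000, 5000)),
    data.frame(site_id = "b", replicate = "1", stage = c("E15", "Adult"),
               n_edited = c(499, 499), n_unedited = c(5000, 5000)))
  sf <- whole_brain_site_filter(counts)
  expect_true(sf$retained[sf$site_id == "a"])    # >= 500 at one stage suffices
  expect_false(sf$retained[sf$site_id == "b"])   # 499 everywhere
  expect_equal(sf$qc[sf$site_id == "b"], "below_500_whole")
  # replicate averaging: 400 and 600 average to 500 -> retained
  counts2 <- data.frame(site_id = "c", replicate = c("1", "2"), stage = "P0",
                        n_edited = c(400, 600), n_unedited = c(5000, 5000))
  expect_true(whole_brain_site_filter(counts2)$retained)
})

test_that("a panel with 7 under-covered sites retains the other 15", {
  cb <- example_codebook(n_sites = 22, seed = 2)
  sites <- site_pairs(cb)$site_id
  counts <- data.frame(site_id = sites, replicate = "1", stage = "P7",
                       n_edited = c(rep(800, 15), rep(60, 7)),
                       n_unedited = 2000)
  sf <- whole_brain_site_filter(counts)
  expect_equal(sum(sf$retained), 15)
})

test_that("regional counts partition the whole and apply the 100-read filter", {
  cb <- tiny_codebook()
  cfg <- small_scene_config(seed = 31, image_shape = c(512, 512), n_cells = 120,
                            reads_per_cell_mean = 25)
  sc <- simulate_scene(cfg, cb)
  reads <- decode_spots(sc$spots, cb, threshold = 0.5)
  reads <- assign_reads(reads, NULL, cfg$regions)
  reads <- reads[reads$pass_qc, ]
  rc <- regional_counts(reads, cb)
  whole <- whole_counts(reads, cb)
  for (s in unique(rc$site_id)) for (r in unique(rc$region)) {
    inside <- rc[rc$site_id == s & rc$region == r & rc$stratum == "region", ]
    outside <- rc[rc$site_id == s & rc$region == r &
                    rc$stratum == "whole_minus_region", ]
    w <- whole[whole$site_id == s, ]
    expect_equal(inside$n_edited + outside$n_edited, w$n_edited)
    expect_equal(inside$n_unedited + outside$n_unedited, w$n_unedited)
  }
  # homogeneous editing: regional levels near the global level
  for (s in unique(rc$site_id)) {
    w <- whole[whole$site_id == s, ]
    n_tot <- w$n_edited + w$n_unedited
    for (r in unique(rc$region)) {
      inside <- rc[rc$site_id == s & rc$region == r & rc$stratum == "region", ]
      n_in <- inside$n_edited + inside$n_unedited
      if (n_in >= 100)
        expect_lt(abs(inside$level - w$level),
                  3 * sqrt(w$level * (1 - w$level) / n_in))
    }
  }
})

test_that("the 100-read regional boundary is strict and complements can be NA", {
  cb <- tiny_codebook()
  mk_reads <- function(n_in) {
    data.frame(target = rep(c("Cyfip2_ed", "Cyfip2_un"), length.out = n_in),
               region = "thalamus", stringsAsFactors = FALSE)
  }
  rc99 <- regional_counts(mk_reads(99), cb)
  row99 <- rc99[rc99$site_id == "Cyfip2_KE" & rc99$stratum == "region", ]
  expect_equal(row99$qc, "below_100_region")
  rc100 <- regional_counts(mk_reads(100), cb)
  row100 <- rc100[rc100$site_id == "Cyfip2_KE" & rc100$stratum == "region", ]
  expect_equal(row100$qc, "")
  # all reads inside one region: complement has no data
  comp <- rc100[rc100$site_id == "Cyfip2_KE" &
                  rc100$stratum == "whole_minus_region", ]
  expect_true(is.na(comp$level))
  rr <- regional_ratios(rc100)
  expect_true(is.na(rr$ratio[rr$site_id == "Cyfip2_KE"]))
})

test_that("Adar2 reads decompose into isoforms by the auto-editing level", {
  expect_equal(adar2_decompose(0.5, 1000), list(active = 500L, inactive = 500L))
  expect_equal(adar2_decompose(0.0, 400), list(active = 400L, inactive = 0L))
  expect_equal(adar2_decompose(0.37, 100), list(active = 63L, inactive = 37L))
  dec <- adar2_decompose(NA, 100)
  expect_true(is.na(dec$active) && is.na(dec$inactive))
  expect_error(adar2_decompose(1.2, 10), "\\[0, 1\\]")
})

test_that("replicate aggregation averages levels, reports SD, ignores order", {
  est <- data.frame(site_id = "s", stratum = "region", region = "r",
                    replicate = c("1", "2"), n_edited = c(40, 60),
                    n_unedited = c(60, 40), level = c(0.4, 0.6), qc = "")
  agg <- aggregate_replicates(est)
  expect_equal(agg$mean_level, 0.5)
  expect_equal(agg$sd_level, sd(c(0.4, 0.6)))
  expect_equal(agg$n_replicates, 2)
  expect_equal(aggregate_replicates(est[2:1, ])$mean_level, agg$mean_level)
  one <- aggregate_replicates(est[1, ])
  expect_true(is.na(one$sd_level))
  flagged <- est; flagged$qc <- "below_100_region"
  empty <- aggregate_replicates(flagged)
  expect_true(is.na(empty$mean_level))
  expect_equal(empty$qc, "no_contributing_replicates")
  pooled <- aggregate_replicates(est, pool_counts = TRUE)
  expect_equal(pooled$mean_level, editing_level(100, 100))
})

test_that("simulated replicate levels recover the configured truth", {
  cb <- tiny_codebook()
  levels <- vapply(1:5, function(r) {
    cfg <- small_scene_config(seed = 100 + r, image_shape = c(512, 512),
                              n_cells = 80, reads_per_cell_mean = 30,
                              regions = NULL, default_editing_prob = 0.6)
    sc <- simulate_scene(cfg, cb)
    reads <- decode_spots(sc$spots, cb, threshold = 0.5)
    w <- whole_counts(reads[reads$pass_qc, ], cb)
    w$level[w$site_id == "Cyfip2_KE"]
  }, 0)
  se <- sd(levels) / sqrt(5)
  expect_lt(abs(mean(levels) - 0.6), 3 * max(se, 0.01))
})
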