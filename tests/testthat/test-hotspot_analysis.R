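test_that("moving average is NA-aware, end-truncated and range-bounded", {
  expect_equal(moving_average(c(1, 1, 1, 1, 1)), rep(1, 5))
  expect_equal(moving_average(c(0, 0, 5, 0, 0))[3], 1)
  expect_equal(moving_average(c(1, 2, 3), 5), c(2, 2, 2))  # end truncation
  expect_error(moving_average(1:5, 4), "odd")
  expect_equal(moving_average(c(1, NA, 3), 3), c(1, 2, 3))
  set.seed(2)
  x <- rnorm(100)
  s <- moving_average(x, 5)
  for (i in 3:98) {
    w <- x[(i - 2):(i + 2)]
    expect_gte(s[i], min(w)); expect_lte(s[i], max(w))
  }
})

test_that("local rate profile divides by bin separation in kb", {
  ann <- toy_annotation()
  m <- build_linkage_matrix(
    data.frame(query_id = "gA1", array_id = "gA2", sga_gd = 10), ann, "chrA")
  m <- consolidate(m)    # single cell (1,2), G' = 10 both directions
  p <- local_rate_profile(m)
  expect_equal(p$rate[1], 2)      # 10 / (1 * 5 kb)
  expect_equal(p$rate[2], 2)
  expect_true(is.na(p$rate[10]))  # empty window is missing
  # fully masked window is missing
  mm <- apply_masks(m, mask_rules("chrA", 1, 20000, "test"))
  expect_true(all(is.na(local_rate_profile(mm)$rate[1:2])))
})

test_that("profile recovers a planted uniform rate at interior bins", {
  cfg <- uniform_sim_config(seed = 13, n_genes = 120)
  sim <- simulate_screens(cfg)
  d <- estimate_distances(sim$screens$chrA, no_self_norm())
  m <- consolidate(build_linkage_matrix(d, sim$annotation, "chrA"))
  p <- local_rate_profile(m)
  interior <- p$rate[5:55]
  expect_true(all(!is.na(interior)))
  expect_lt(max(abs(interior - cfg$base_rate) / cfg$base_rate), 0.10)
})

test_that("hotspot calling finds interior super-average maxima", {
  prof <- structure(list(chromosome = "chrA", bin_size = 5000,
                         position = (1:5 - 0.5) * 5000,
                         rate = c(1, 2, 5, 2, 1),
                         smoothed = c(1, 2, 5, 2, 1)),
                    class = "recomb_profile")
  calls <- call_hotspots(prof, genome_avg = 2)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$position, 2.5 * 5000)
  expect_true(all(calls$rate > 2))
  # monotone profile has no interior maxima
  prof$smoothed <- 1:5
  expect_equal(nrow(call_hotspots(prof, 0)), 0)
  # plateau yields one call at its (rounded-down) center
  prof$smoothed <- c(1, 4, 4, 4, 1)
  expect_equal(call_hotspots(prof, 0)$position, 2.5 * 5000)
  # unsmoothed profile is rejected
  prof$smoothed <- NULL
  expect_error(call_hotspots(prof, 0), "smoothed")
})

test_that("close calls merge keeping the higher peak", {
  prof <- structure(list(chromosome = "chrA", bin_size = 5000,
                         position = (1:9 - 0.5) * 5000,
                         rate = c(1, 5, 1, 6, 1, 1, 1, 4, 1),
                         smoothed = c(1, 5, 1, 6, 1, 1, 1, 4, 1)),
                    class = "recomb_profile")
  expect_equal(nrow(call_hotspots(prof, 0)), 3)
  merged <- call_hotspots(prof, 0, min_separation = 15000)
  expect_equal(merged$rate, c(6, 4))
})

test_that("hotspot set comparison matches within tolerance per chromosome", {
  calls <- data.frame(chrom = c("chrA", "chrA", "chrB"),
                      position = c(10000, 50000, 20000))
  ref <- site_list(calls$chrom, calls$position)
  cmp <- compare_hotspot_sets(calls, ref)
  expect_equal(cmp$precision, 1)
  expect_equal(cmp$sensitivity, 1)
  # +8 kb shift matches at 10-kb tolerance, +12 kb does not
  ref8 <- site_list(calls$chrom, calls$position + 8000)
  expect_equal(compare_hotspot_sets(calls, ref8, 10000)$sensitivity, 1)
  ref12 <- site_list(calls$chrom, calls$position + 12000)
  expect_equal(compare_hotspot_sets(calls, ref12, 10000)$sensitivity, 0)
  # disjoint chromosome naming errors
  refX <- site_list(c("A", "B"), c(1, 2))
  expect_error(compare_hotspot_sets(calls, refX), "no shared chromosome")
})

test_that("planted hotspots are recovered from simulated screens", {
  genome <- data.frame(name = "chrS", length = 5e5, centromere = 25e4)
  hs <- data.frame(chrom = "chrS",
                   position = c(5e4, 15e4, 30e4, 42e4),
                   fold = 3, width = 4000)
  cfg <- sim_config(seed = 19, genome = genome, n_genes = 300, hotspots = hs,
                    noise_sd = 0.1, replicate_count = 2,
                    rho0_kb = 0, residual_fraction = 1)
  sim <- simulate_screens(cfg)
  d <- estimate_distances(sim$screens$chrS, no_self_norm())
  m <- consolidate(build_linkage_matrix(d, sim$annotation, "chrS"))
  prof <- smooth_profile(local_rate_profile(m))
  gavg <- genome_average_rate(list(prof))
  calls <- call_hotspots(prof, gavg, min_separation = 25000)
  expect_true(all(calls$rate > gavg))
  cmp <- compare_hotspot_sets(calls, site_list(hs$chrom, hs$position), 10000)
  expect_gte(cmp$sensitivity, 0.75)   # 3 of 4 on a single small chromosome
  expect_gte(cmp$precision, 0.75)
})
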