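test_that("rate map composes base rate, hotspots and suppression", {
  cfg <- sim_config(seed = 1,
                    genome = data.frame(name = c("c1", "c2"),
                                        length = c(3e5, 9e5),
                                        centromere = c(1.5e5, 2e5)),
                    rho0_kb = 10, size_coupling = 10, residual_fraction = 0.2,
                    hotspots = data.frame(chrom = "c1", position = 50000,
                                          fold = 3, width = 4000))
  # radii follow rho0 + coupling * L_Mb
  expect_equal(unname(suppression_radii(cfg)), c(13, 19))
  rm_ <- build_rate_map(cfg)
  expect_equal(rate_at(rm_, "c1", 250000), cfg$base_rate)       # background
  expect_equal(rate_at(rm_, "c1", 50000), 3 * cfg$base_rate)    # hotspot
  expect_equal(rate_at(rm_, "c1", 150000), 0.2 * cfg$base_rate) # suppressed
  # no hotspots, no suppression: constant everywhere
  cfg0 <- sim_config(seed = 1, rho0_kb = 0, residual_fraction = 1)
  rm0 <- build_rate_map(cfg0)
  x <- seq(1, 200000, length.out = 50)
  expect_true(all(rate_at(rm0, "chrI", x) == cfg0$base_rate))
  # overlapping hotspots merge by max fold
  cfg2 <- sim_config(seed = 1, genome = cfg$genome, rho0_kb = 0,
                     residual_fraction = 1,
                     hotspots = data.frame(chrom = "c1",
                                           position = c(50000, 51000),
                                           fold = c(3, 5), width = 4000))
  expect_equal(rate_at(build_rate_map(cfg2), "c1", 50500), 5 * cfg$base_rate)
})

test_that("true recombinant fractions follow the Poisson crossover model", {
  cfg <- uniform_sim_config()      # uniform 1.4 SGA-GD/kb
  rm_ <- build_rate_map(cfg)
  expect_equal(pair_true_R(rm_, "chrA", 50000, 50000), 0)
  # 50 cM apart: m = 1, R = (1 - 1/e)/2
  d_bp <- 50 / cfg$base_rate * 1000
  expect_equal(pair_true_R(rm_, "chrA", 50000, 50000 + d_bp),
               (1 - exp(-1)) / 2, tolerance = 1e-12)
  expect_equal(pair_true_R(rm_, "chrA", 50000, 50000 + d_bp), 0.31606,
               tolerance = 1e-4)
  # asymptote: huge separation approaches 0.5 from below
  R_far <- pair_true_R(rm_, "chrB", 1000, 899000)
  expect_lt(R_far, 0.5); expect_gt(R_far, 0.499)
  # cumulative cM at the chromosome end equals the full integral
  expect_equal(cum_cm(rm_, "chrA", 3e5), cfg$base_rate * 300)
})

test_that("noise-free screens invert exactly through the estimator", {
  cfg <- uniform_sim_config(seed = 3, n_genes = 25)
  sim <- simulate_screens(cfg)
  for (ch in names(sim$screens)) {
    j <- joined_truth(sim, ch)
    expect_lt(max(abs(j$R - j$R_true)), 1e-12)
    sub <- j$cm_true < 49.9
    expect_lt(max(abs(j$sga_gd[sub] - j$gd_true[sub])), 1e-9)
    # far-apart pairs (>= 50 cM) report exactly the 50 SGA-GD cap
    expect_true(all(j$sga_gd[j$cm_true >= 50] == 50))
  }
})

test_that("simulation output is a deterministic function of the seed", {
  a <- simulate_screens(uniform_sim_config(seed = 5))
  b <- simulate_screens(uniform_sim_config(seed = 5))
  expect_identical(a$screens, b$screens)
  expect_identical(a$truth, b$truth)
  c_ <- simulate_screens(uniform_sim_config(seed = 6))
  expect_false(identical(a$screens, c_$screens))
  ta <- simulate_tracks(uniform_sim_config(seed = 5))
  tb <- simulate_tracks(uniform_sim_config(seed = 5))
  expect_identical(ta, tb)
})

test_that("simulated tracks reflect the planted truth", {
  cfg <- sim_config(seed = 9,
                    genome = data.frame(name = c("c1", "c2"),
                                        length = c(4e5, 8e5),
                                        centromere = c(2e5, 3e5)),
                    rho0_kb = 20, size_coupling = 0, residual_fraction = 0,
                    rec8_width0_kb = 40, rec8_coupling = 0)
  trk <- simulate_tracks(cfg)
  # zero residual: no Spo11 oligos within the suppressed radius
  sp <- trk$spo11$c1
  inside <- abs(sp$position - 2e5) < 20000
  expect_true(all(sp$value[inside] == 0))
  expect_gt(mean(sp$value[!inside]), 0)
  # planted Rec8 width is recovered within a smoothing window
  gga <- global_genomic_average(trk$rec8, 25)
  pk <- cohesin_peak_width(trk$rec8$c1, 2e5, gga, 25)
  expect_lt(abs(pk$width_kb - 40), 12.5)
  # genetic map cM at the last locus approaches the chromosome-end integral
  rm_ <- build_rate_map(cfg)
  gm1 <- trk$genetic_map[trk$genetic_map$chrom == "c1", ]
  expect_equal(max(gm1$score),
               cum_cm(rm_, "c1", max(gm1$position)), tolerance = 1e-9)
})

test_that("fixture writer emits all dialects readable by the io layer", {
  cfg <- uniform_sim_config(seed = 2, n_genes = 10,
                            hotspots = data.frame(chrom = "chrA",
                                                  position = 5e4, fold = 3,
                                                  width = 4000))
  dir <- withr::local_tempdir()
  write_sim_fixtures(cfg, dir)
  ann <- read_annotation(file.path(dir, "annotation.tsv"), "sgd_tab")
  expect_equal(nrow(ann$chromosomes), 2)
  scr <- read_fitness_screen(file.path(dir, "screens"), "chrA")
  expect_equal(length(scr$array_ids), 10)
  tr <- read_track(file.path(dir, "spo11_chrA.tsv"), "two_column",
                   chromosome = "chrA")
  expect_gt(length(tr$position), 0)
  hs <- read_sites(file.path(dir, "hotspots.bed"), "bed")
  expect_equal(hs$position, 5e4)
  gm <- read_sites(file.path(dir, "genetic_map.tsv"), "map_tab")
  expect_equal(nrow(gm), 20)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(truth$seed, 2)
})
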