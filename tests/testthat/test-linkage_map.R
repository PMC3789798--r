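test_that("bin assignment uses 1-based half-open 5-kb bins", {
  expect_equal(assign_bin(1), 0L)
  expect_equal(assign_bin(5000), 0L)
  expect_equal(assign_bin(5001), 1L)
  expect_equal(assign_bin(12300), 2L)
  expect_error(assign_bin(0), ">= 1")
  expect_error(assign_bin(400, chrom_len = 300), "beyond")
})

test_that("linkage matrix cells average contributing pairs and keep counts", {
  ann <- toy_annotation()
  # gA1 mid 1000 -> bin 0; gA2 mid 10000 -> bin 1; gA3 mid 100000 -> bin 19
  pairs <- data.frame(query_id = c("gA1", "gA1", "gA2", "gA1"),
                      array_id = c("gA3", "gA3", "gA3", "gA2"),
                      sga_gd = c(20, 30, 12, NA))
  m <- build_linkage_matrix(pairs, ann, "chrA")
  expect_equal(m$n, 60L)
  expect_equal(m$G[1, 20], 25)            # mean of 20 and 30
  expect_equal(m$counts[1, 20], 2L)
  expect_equal(m$G[2, 20], 12)
  expect_true(is.na(m$G[1, 2]))           # NA-valued pair contributes nothing
  expect_equal(m$counts[1, 2], 0L)
  expect_true(is.na(m$G[5, 5]))           # empty cell is missing, not 0
  expect_error(build_linkage_matrix(
    data.frame(query_id = "gB1", array_id = "gB2", sga_gd = 1), ann, "chrA"),
    "gB1")
})

test_that("cell averages are invariant to pair ordering", {
  ann <- toy_annotation()
  set.seed(4)
  pairs <- data.frame(
    query_id = sample(c("gA1", "gA2", "gA3", "gA4"), 40, TRUE),
    array_id = sample(c("gA1", "gA2", "gA3", "gA4"), 40, TRUE),
    sga_gd = runif(40, 0, 50))
  m1 <- build_linkage_matrix(pairs, ann, "chrA")
  m2 <- build_linkage_matrix(pairs[sample(40), ], ann, "chrA")
  expect_equal(m1$G, m2$G)
  expect_equal(m1$counts, m2$counts)
})

test_that("consolidation averages available directions, with exclusions", {
  ann <- toy_annotation()
  base <- build_linkage_matrix(
    data.frame(query_id = "gA1", array_id = "gA2", sga_gd = 10), ann, "chrA")
  base$G[1:2, 1:2] <- matrix(c(0, 20, 10, 0), 2, 2)   # G[1,2]=10, G[2,1]=20
  m <- consolidate(base)
  expect_equal(m$G_prime[1, 2], 15)
  expect_equal(m$G_prime[2, 1], 15)
  # single available direction is used as-is
  base$G[2, 1] <- NA
  m <- consolidate(base)
  expect_equal(m$G_prime[1, 2], 10)
  expect_equal(m$G_prime[2, 1], 10)
  # excluded chromosome left untouched
  base$chromosome <- "chrIII"
  m <- consolidate(base, exclude = "chrIII")
  expect_identical(m$G_prime, base$G)
})

test_that("consolidated matrices are exactly symmetric where unmasked", {
  cfg <- uniform_sim_config(seed = 21, n_genes = 25)
  sim <- simulate_screens(cfg)
  d <- estimate_distances(sim$screens$chrA, no_self_norm())
  m <- consolidate(build_linkage_matrix(d, sim$annotation, "chrA"))
  G <- m$G_prime
  G[is.na(G)] <- -1
  expect_identical(max(abs(G - t(G))), 0)
})

test_that("mask rules invalidate whole rows and columns, idempotently", {
  ann <- toy_annotation()
  m <- build_linkage_matrix(
    data.frame(query_id = "gA1", array_id = "gA2", sga_gd = 10), ann, "chrA")
  rules <- mask_rules("chrA", 1, 15000, "marker")      # bins 0-2
  mm <- apply_masks(m, rules)
  expect_false(any(mm$mask[1:3, ]))
  expect_false(any(mm$mask[, 1:3]))
  expect_true(all(mm$mask[4:60, 4:60]))
  # empty rule list leaves mask unchanged; reapplication is a no-op (union)
  expect_identical(apply_masks(m, rules[0, ])$mask, m$mask)
  expect_identical(apply_masks(mm, rules)$mask, mm$mask)
  # masked cells drop out of downstream values
  expect_true(all(is.na(masked_values(mm)[1:3, ])))
})

test_that("mean cell distance grows monotonically with bin separation", {
  cfg <- uniform_sim_config(seed = 33, n_genes = 60)
  sim <- simulate_screens(cfg)
  d <- estimate_distances(sim$screens$chrB, no_self_norm())
  m <- consolidate(build_linkage_matrix(d, sim$annotation, "chrB"))
  G <- masked_values(m)
  sep <- abs(row(G) - col(G))
  ok <- !is.na(G) & sep > 0
  mean_by_sep <- tapply(G[ok], sep[ok], mean)
  seps <- as.integer(names(mean_by_sep))
  # up to the cap-reaching separation (~36 kb / 5 kb at rate 1.4)
  within <- seps <= 7
  rho <- suppressWarnings(
    cor(seps[within], mean_by_sep[within], method = "spearman"))
  expect_gte(rho, 0.95)
})

test_that("total genetic length recovers a planted uniform rate with b ~ 0", {
  cfg <- sim_config(seed = 5,
                    genome = data.frame(name = c("c1", "c2", "c3", "c4"),
                                        length = c(3e5, 5e5, 7e5, 9e5),
                                        centromere = c(1e5, 2e5, 3e5, 4e5)),
                    n_genes = 60, noise_sd = 0, interaction_rate = 0,
                    replicate_count = 1, rho0_kb = 0, residual_fraction = 1)
  sim <- simulate_screens(cfg)
  maps <- lapply(names(sim$screens), function(ch) {
    d <- estimate_distances(sim$screens[[ch]], no_self_norm())
    consolidate(build_linkage_matrix(d, sim$annotation, ch))
  })
  fit <- chromosome_genetic_length(maps, sim$annotation)
  expect_equal(fit$a, cfg$base_rate, tolerance = 0.1)
  expect_lt(abs(fit$b), 0.05 * mean(fit$per_chromosome$total_gd))
  expect_error(chromosome_genetic_length(maps[1:2], sim$annotation), ">= 3")
})

test_that("equal per-chromosome rates give a perfect linear fit", {
  ann <- genome_annotation(
    data.frame(name = c("c1", "c2", "c3"), length = c(2e5, 4e5, 6e5),
               centromere = c(1e5, 2e5, 3e5)),
    data.frame(gene_id = paste0("c", rep(1:3, each = 2), "_g", 1:2),
               chrom = rep(c("c1", "c2", "c3"), each = 2),
               start = rep(c(2500, 12500), 3) - 100,
               end = rep(c(2500, 12500), 3) + 100,
               strand = "+"))
  # genes at bin centers, distances exactly rate * separation
  r <- 2
  maps <- lapply(c("c1", "c2", "c3"), function(ch) {
    g <- paste0(ch, "_g", 1:2)
    consolidate(build_linkage_matrix(
      data.frame(query_id = g[1], array_id = g[2], sga_gd = r * 10),
      ann, ch))
  })
  fit <- chromosome_genetic_length(maps, ann)
  expect_equal(fit$a, r, tolerance = 1e-10)
  expect_equal(fit$b, 0, tolerance = 1e-8)
  expect_equal(unname(residuals(fit$fit)), rep(0, 3), tolerance = 1e-9)
})
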