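make_peri_ann <- function(positions, cen = 150000, len = 300000) {
  genome_annotation(
    data.frame(name = "chrA", length = len, centromere = cen),
    data.frame(gene_id = names(positions), chrom = "chrA",
               start = unname(positions) - 100, end = unname(positions) + 100,
               strand = "+"))
}

test_that("cis/trans classification brackets the centromere midpoint", {
  ann <- make_peri_ann(c(g1 = 100000, g2 = 140000, g3 = 160000, g4 = 140000))
  p <- classify_pairs(data.frame(query_id = c("g1", "g2", "g2"),
                                 array_id = c("g2", "g3", "g4")), ann)
  expect_equal(p$side, c("cis", "trans", "cis"))
  expect_equal(p$physical_distance, c(40, 20, 0))
  # a gene overlapping the centromere midpoint warns and uses its midpoint
  ann2 <- make_peri_ann(c(g1 = 100000, g2 = 150000))
  expect_warning(p2 <- classify_pairs(
    data.frame(query_id = "g1", array_id = "g2"), ann2), "centromere")
  expect_equal(p2$side, "cis")
  expect_error(classify_pairs(data.frame(query_id = "g1", array_id = "nope"),
                              ann), "nope")
})

test_that("binned extent returns the first qualifying bin distance", {
  expect_equal(binned_extent(c(5, 10, 15, 20), c(30, 45, 50, 50)), 15)
  expect_equal(binned_extent(c(5, 10, 15), c(55, 60, 70)), 5)
  expect_true(is.na(binned_extent(c(5, 10, 15), c(10, 20, 30))))
})

test_that("linkage extent bins by physical distance and is order-invariant", {
  ann <- make_peri_ann(setNames(seq(5000, 295000, by = 10000),
                                sprintf("g%02d", 1:30)))
  ids <- sprintf("g%02d", 1:30)
  pairs <- expand.grid(query_id = ids, array_id = ids,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$query_id < pairs$array_id, ]
  cl <- classify_pairs(pairs, ann)
  # plant: distances below 40 kb linked, at/above 40 kb unlinked
  cl$R <- ifelse(cl$physical_distance < 40, 0.1, 0.5)
  cl$sga_gd <- sga_gd(cl$R)
  e1 <- linkage_extent(cl, "cis")
  expect_equal(e1, 37.5)     # d = 40 falls in bin (35,40], center 37.5
  e2 <- linkage_extent(cl[sample(nrow(cl)), ], "cis")
  expect_equal(e2, e1)
  cl$R <- 0.1; cl$sga_gd <- sga_gd(cl$R)
  expect_true(is.na(linkage_extent(cl, "cis")))
  expect_error(linkage_extent(cl[0, ], "cis"), "no cis pairs")
})

test_that("hotspot-based pericentric gap and spacing control", {
  ann <- make_peri_ann(c(g = 1000))
  hs <- site_list("chrA", c(90000, 120000, 180000, 210000))
  g <- hotspot_centromere_gap(hs, ann)
  expect_equal(g$gap_kb, 60)             # 120 <-> 180 flank the centromere
  expect_equal(g$control_kb, mean(c(30, 60, 30)))
  # single hotspot: no gap, no control
  g1 <- hotspot_centromere_gap(site_list("chrA", 90000), ann)
  expect_true(is.na(g1$gap_kb) && is.na(g1$control_kb))
  # evenly spaced hotspots give their spacing as control
  g2 <- hotspot_centromere_gap(site_list("chrA", seq(30000, 270000, 30000)), ann)
  expect_equal(g2$control_kb, 30)
})

test_that("genetic-map pericentric gap and expected-unlinked control", {
  ann <- make_peri_ann(c(g = 1000))
  loci <- site_list("chrA", c(100000, 140000, 200000),
                    score = c(10, 40, 70))
  g <- genetic_map_centromere_gap(loci, ann, c(chrA = 0.4))
  expect_equal(g$control_kb, 125)        # 50 / 0.4
  expect_equal(g$gap_kb, 100)            # only (100k,10cM)-(200k,70cM) >= 50 cM
  # all trans pairs < 50 cM apart -> not available
  loci2 <- site_list("chrA", c(100000, 200000), score = c(10, 40))
  expect_true(is.na(genetic_map_centromere_gap(loci2, ann, c(chrA = 0.4))$gap_kb))
  expect_error(genetic_map_centromere_gap(loci, ann, c(chrA = -1)), "> 0")
})

test_that("size correlation: exact proportionality, degeneracy, recovery", {
  ann <- genome_annotation(
    data.frame(name = paste0("c", 1:16),
               length = default_genome()$length,
               centromere = default_genome()$centromere),
    data.frame(gene_id = character(), chrom = character(), start = numeric(),
               end = numeric(), strand = character()))
  L <- setNames(ann$chromosomes$length, ann$chromosomes$name)
  s <- size_correlation(0.05 * L / 1000, ann)
  expect_equal(s$R, 1)
  expect_lt(s$p, 1e-6)
  expect_error(size_correlation(setNames(rep(5, 16), names(L)), ann),
               "degenerate")
  expect_error(size_correlation(L[1:2] / 1000, ann), ">= 3")
  # planted extents 0.05*L_kb + noise(sd 5 kb): R >= 0.7 across 20 seeds
  set.seed(91)
  Rs <- replicate(20, size_correlation(
    0.05 * L / 1000 + rnorm(16, 0, 5), ann)$R)
  expect_true(all(Rs >= 0.7))
  # exclusion set is honoured and recorded
  s2 <- size_correlation(0.05 * L / 1000, ann, excluded = c("c1", "c3"))
  expect_equal(s2$n, 14)
  expect_equal(s2$excluded, c("c1", "c3"))
})

test_that("exclusion of the four smallest kills a small-chromosome-only signal", {
  ann <- genome_annotation(
    data.frame(name = default_genome()$name, length = default_genome()$length,
               centromere = default_genome()$centromere),
    data.frame(gene_id = character(), chrom = character(), start = numeric(),
               end = numeric(), strand = character()))
  L <- setNames(ann$chromosomes$length, ann$chromosomes$name)
  smallest <- names(sort(L))[1:4]      # chrI, chrVI, chrIII, chrIX
  # signal planted ONLY in the four smallest chromosomes; elsewhere noise
  set.seed(17)
  with_R <- without_R <- without_p <- numeric(25)
  for (i in 1:25) {
    v <- setNames(rnorm(16, 100, 1), names(L))
    v[smallest] <- c(40, 50, 60, 70)
    with_R[i] <- size_correlation(v, ann)$R
    s <- size_correlation(v, ann, excluded = smallest)
    without_R[i] <- s$R; without_p[i] <- s$p
  }
  expect_gt(median(abs(with_R)), 0.6)
  expect_lt(median(abs(without_R)), 0.35)
  expect_gt(median(without_p), 0.05)
})
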