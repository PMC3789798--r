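#' Classify same-chromosome gene pairs as cis or trans to the centromere
#'
#' A pair is `trans` iff the centromere midpoint lies strictly between the
#' two gene midpoints, `cis` otherwise. Genes overlapping the centromere
#' midpoint are resolved by their own midpoint, with a warning.
#'
#' @param pairs data.frame with `query_id`, `array_id` (plus any other
#'   columns, carried through).
#' @param annotation a [genome_annotation()].
#' @return the input with added columns `side` (`"cis"`/`"trans"`) and
#'   `physical_distance` (kb between gene midpoints).
#' @export
classify_pairs <- function(pairs, annotation) {
  g <- annotation$genes
  ia <- match(pairs$query_id, g$gene_id)
  ib <- match(pairs$array_id, g$gene_id)
  if (anyNA(ia) || anyNA(ib))
    .stopf("gene(s) absent from annotation: %s",
           paste(unique(c(pairs$query_id[is.na(ia)],
                          pairs$array_id[is.na(ib)])), collapse = ", "))
  if (any(g$chrom[ia] != g$chrom[ib]))
    .stopf("classify_pairs requires same-chromosome pairs")
  cen <- centromere_position(annotation, g$chrom[ia])
  ma <- (g$start[ia] + g$end[ia]) / 2
  mb <- (g$start[ib] + g$end[ib]) / 2
  spans <- (g$start[ia] <= cen & g$end[ia] >= cen) |
           (g$start[ib] <= cen & g$end[ib] >= cen)
  if (any(spans))
    .warnf("%d pair(s) involve a gene overlapping the centromere midpoint; classified by gene midpoint",
           sum(spans))
  lo <- pmin(ma, mb); hi <- pmax(ma, mb)
  pairs$side <- ifelse(lo < cen & cen < hi, "trans", "cis")
  pairs$physical_distance <- abs(ma - mb) / 1000
  pairs
}

#' Extent of linkage from binned pair distances
#'
#' Pairs are distributed into `bin_kb`-wide bins by physical distance and
#' averaged within each bin; the extent is the distance of the smallest
#' (closest) bin whose mean genetic distance reaches `threshold` (50 SGA-GD
#' = independent segregation). Bin distance is reported as the bin center.
#' By default (`average = "R"`, requires an `R` column) the within-bin
#' average is taken on the bounded recombinant-fraction scale and the bin
#' mean is then mapped to SGA-GD: with the output cap equal to the
#' independence threshold, averaging capped distances would make "mean >=
#' threshold" equivalent to "every pair capped", a knife-edge under noise
#' (the same cap-saturation argument behind replicate averaging on R).
#' `average = "sga_gd"` averages the distances themselves;
#' `binned_extent` operates on an already-binned distance profile.
#'
#' @param classified output of [classify_pairs()] with `sga_gd` (and, for
#'   the default mode, `R`) columns.
#' @param side `"cis"` or `"trans"`.
#' @param bin_kb bin width in kb, default 5.
#' @param threshold SGA-GD threshold, default 50.
#' @param average `"R"` or `"sga_gd"`.
#' @param config [distance_config()] used to map bin-mean R to SGA-GD.
#' @return extent in kb, or `NA` if no bin qualifies.
#' @export
linkage_extent <- function(classified, side = c("trans", "cis"), bin_kb = 5,
                           threshold = 50, average = c("R", "sga_gd"),
                           config = distance_config()) {
  side <- match.arg(side)
  average <- match.arg(average)
  if (average == "R" && is.null(classified$R)) average <- "sga_gd"
  val <- if (average == "R") classified$R else classified$sga_gd
  d <- classified[classified$side == side & !is.na(val), , drop = FALSE]
  if (!nrow(d)) .stopf("no %s pairs with genetic distances", side)
  if (average == "R") {
    k <- pmax(1L, ceiling(d$physical_distance / bin_kb))
    mR <- tapply(d$R, k, mean)
    ks <- as.integer(names(mR))
    binned_extent((ks - 0.5) * bin_kb, sga_gd(as.numeric(mR), config),
                  threshold)
  } else {
    b <- bin_pairs_by_distance(d$physical_distance, d$sga_gd, bin_kb)
    binned_extent(b$bin_center, b$mean_gd, threshold)
  }
}

#' @rdname linkage_extent
#' @param bin_dist bin distances (kb).
#' @param bin_mean mean SGA-GD per bin.
#' @export
binned_extent <- function(bin_dist, bin_mean, threshold = 50) {
  o <- order(bin_dist)
  bin_dist <- bin_dist[o]; bin_mean <- bin_mean[o]
  hit <- which(!is.na(bin_mean) & bin_mean >= threshold)
  if (!length(hit)) return(NA_real_)
  bin_dist[hit[1]]
}

#' Pericentric gap and spacing control from a hotspot set
#'
#' Per chromosome: `gap` is the shortest physical distance between two
#' hotspots on opposite sides of the centromere (the nearest flanking
#' pair); `control` is the mean distance between consecutive hotspots on
#' the chromosome (a centromere-unrelated baseline).
#'
#' @param hotspots a [site_list()] (hotspot positions).
#' @param annotation a [genome_annotation()].
#' @return data.frame `chrom`, `gap_kb` (`NA` when a side has no hotspot),
#'   `control_kb` (`NA` with fewer than 2 hotspots).
#' @export
hotspot_centromere_gap <- function(hotspots, annotation) {
  chroms <- annotation$chromosomes$name
  out <- lapply(chroms, function(ch) {
    p <- sort(hotspots$position[hotspots$chrom == ch])
    cen <- centromere_position(annotation, ch)
    left <- p[p < cen]; right <- p[p > cen]
    gap <- if (length(left) && length(right))
      (min(right) - max(left)) / 1000 else NA_real_
    control <- if (length(p) >= 2) mean(diff(p)) / 1000 else NA_real_
    data.frame(chrom = ch, gap_kb = gap, control_kb = control,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Pericentric gap and expected-unlinked control from a classical genetic map
#'
#' Per chromosome: `gap` is the minimum physical distance over locus pairs
#' on opposite sides of the centromere whose map positions differ by at
#' least `cm_threshold` (genetically independent loci); `control` is the
#' expected physical distance between two unlinked loci,
#' `cm_threshold / rate`, from the chromosome's average cM/kb.
#'
#' @param map_loci a [site_list()] with cM in `score`.
#' @param annotation a [genome_annotation()].
#' @param per_chrom_rate named numeric, cM/kb per chromosome (> 0).
#' @param cm_threshold cM difference marking independence, default 50.
#' @return data.frame `chrom`, `gap_kb`, `control_kb`.
#' @export
genetic_map_centromere_gap <- function(map_loci, annotation, per_chrom_rate,
                                       cm_threshold = 50) {
  if (any(per_chrom_rate <= 0, na.rm = TRUE)) .stopf("rates must be > 0")
  chroms <- annotation$chromosomes$name
  out <- lapply(chroms, function(ch) {
    d <- map_loci[map_loci$chrom == ch & !is.na(map_loci$score), , drop = FALSE]
    cen <- centromere_position(annotation, ch)
    left <- d[d$position < cen, , drop = FALSE]
    right <- d[d$position > cen, , drop = FALSE]
    gap <- NA_real_
    if (nrow(left) && nrow(right)) {
      dd <- outer(right$position, left$position, `-`)
      dc <- abs(outer(right$score, left$score, `-`))
      ok <- dc >= cm_threshold
      if (any(ok)) gap <- min(dd[ok]) / 1000
    }
    rate <- per_chrom_rate[ch]
    control <- if (!is.null(rate) && !is.na(rate)) cm_threshold / rate else NA_real_
    data.frame(chrom = ch, gap_kb = gap, control_kb = unname(control),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Pearson correlation of a per-chromosome quantity with chromosome size
#'
#' Two-sided p-value from the exact t transform with n - 2 degrees of
#' freedom. Chromosomes in `excluded` (e.g. the four smallest yeast
#' chromosomes I, III, VI, IX, whose globally elevated recombination rates
#' confound size comparisons) and chromosomes with `NA` values are dropped.
#'
#' @param values named numeric vector (names = chromosome names).
#' @param annotation a [genome_annotation()].
#' @param excluded character vector of chromosome names to drop.
#' @return object of class `size_correlation`: `R`, `p`, `n`, `excluded`.
#'   Errors with fewer than 3 usable chromosomes or degenerate (constant)
#'   input.
#' @export
size_correlation <- function(values, annotation, excluded = character()) {
  stopifnot(!is.null(names(values)))
  keep <- setdiff(names(values)[!is.na(values)], excluded)
  if (length(keep) < 3)
    .stopf("size_correlation needs >= 3 chromosomes, have %d", length(keep))
  x <- chrom_length(annotation, keep)
  y <- values[keep]
  if (stats::sd(y) == 0 || stats::sd(x) == 0)
    .stopf("degenerate input: values (or lengths) are constant, correlation undefined")
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  structure(list(R = unname(ct$estimate), p = ct$p.value, n = length(keep),
                 excluded = excluded),
            class = "size_correlation")
}

#' @export
print.size_correlation <- function(x, ...) {
  cat(sprintf("size_correlation: R = %.3f, p = %.3g, n = %d%s\n", x$R, x$p,
              x$n, if (length(x$excluded))
                paste0(" (excluded: ", paste(x$excluded, collapse = ", "), ")")
              else ""))
  invisible(x)
}
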