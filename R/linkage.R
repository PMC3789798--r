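#' Bin index for a chromosomal position
#'
#' Chromosomes are split into consecutive nonoverlapping bins of `bin_size`
#' bp (5 kb by default); bin k (0-based) covers
#' `[k*bin_size + 1, (k+1)*bin_size]`.
#'
#' @param position 1-based bp position(s), >= 1.
#' @param bin_size bin width in bp.
#' @param chrom_len optional chromosome length; positions beyond it error.
#' @return integer 0-based bin indices.
#' @export
assign_bin <- function(position, bin_size = 5000, chrom_len = NULL) {
  if (any(position < 1)) .stopf("positions must be >= 1")
  if (!is.null(chrom_len) && any(position > chrom_len))
    .stopf("position beyond chromosome length %g", chrom_len)
  as.integer(floor((position - 1) / bin_size))
}

#' Binned per-chromosome linkage matrix
#'
#' `G[i, j]` is the mean SGA-GD over query-array gene pairs whose query
#' midpoint falls in bin i and array midpoint in bin j. Cells with no pairs
#' are `NA` (missing, never 0: 0 means measured complete linkage). `counts`
#' records contributing pair numbers, `mask` is TRUE where the cell is
#' valid for downstream use.
#'
#' @param pairs data.frame with columns `query_id`, `array_id`, `sga_gd`
#'   (e.g. from [estimate_distances()]).
#' @param annotation a [genome_annotation()].
#' @param chromosome chromosome name; all pair genes must lie on it.
#' @param bin_size bin width bp (default 5000).
#' @return object of class `linkage_matrix` with fields `chromosome`,
#'   `bin_size`, `n`, `G`, `G_prime` (NULL until [consolidate()]), `mask`,
#'   `counts`.
#' @export
build_linkage_matrix <- function(pairs, annotation, chromosome,
                                 bin_size = 5000) {
  L <- chrom_length(annotation, chromosome)
  n <- as.integer(ceiling(L / bin_size))
  ids <- unique(c(pairs$query_id, pairs$array_id))
  mid <- gene_midpoints(annotation, ids)
  gchrom <- annotation$genes$chrom[match(ids, annotation$genes$gene_id)]
  off <- ids[gchrom != chromosome]
  if (length(off))
    .stopf("gene(s) not on %s: %s", chromosome, paste(off, collapse = ", "))
  qb <- assign_bin(mid[pairs$query_id], bin_size, L)
  ab <- assign_bin(mid[pairs$array_id], bin_size, L)
  keep <- !is.na(pairs$sga_gd)
  idx <- qb[keep] * n + ab[keep] + 1L
  sums <- counts <- numeric(n * n)
  t_s <- tapply(pairs$sga_gd[keep], idx, sum)
  t_n <- table(idx)
  at <- as.integer(names(t_s))
  sums[at] <- as.numeric(t_s)
  counts[at] <- as.integer(t_n[names(t_s)])
  G <- matrix(NA_real_, n, n)
  cnt <- matrix(as.integer(counts), n, n, byrow = TRUE)
  Gv <- ifelse(counts > 0, sums / counts, NA_real_)
  G <- matrix(Gv, n, n, byrow = TRUE)
  structure(list(chromosome = chromosome, bin_size = bin_size, n = n,
                 G = G, G_prime = NULL,
                 mask = matrix(TRUE, n, n), counts = cnt),
            class = "linkage_matrix")
}

#' @export
print.linkage_matrix <- function(x, ...) {
  cat(sprintf("linkage_matrix [%s]: %d x %d bins of %g bp, %d cell(s) with data%s\n",
              x$chromosome, x$n, x$n, x$bin_size, sum(!is.na(x$G)),
              if (is.null(x$G_prime)) "" else ", consolidated"))
  invisible(x)
}

#' Consolidate query-array and array-query directions
#'
#' `G'[i, j] = (G[i, j] + G[j, i]) / 2` where both directions are present;
#' where only one direction has data it is used as-is. Chromosomes in
#' `exclude` (chromosome III in the yeast runs, because of its special role
#' in the SGA selection process) keep `G' = G` untouched.
#'
#' @param map a `linkage_matrix`.
#' @param exclude character vector of chromosome names to leave unaveraged.
#' @return the map with `G_prime` filled in.
#' @export
consolidate <- function(map, exclude = character()) {
  stopifnot(inherits(map, "linkage_matrix"))
  if (map$chromosome %in% exclude) {
    map$G_prime <- map$G
    return(map)
  }
  G <- map$G; Gt <- t(G)
  s <- ifelse(is.na(G), 0, G) + ifelse(is.na(Gt), 0, Gt)
  n_dir <- (!is.na(G)) + (!is.na(Gt))
  map$G_prime <- ifelse(n_dir > 0, s / n_dir, NA_real_)
  map
}

#' Mask rules
#'
#' Intervals whose bins must be excluded from every downstream average, e.g.
#' the CAN1 / LYP1 SGA selection-marker regions on the left arms of
#' chromosomes V and XIV where every screen shows linkage.
#'
#' @param chrom chromosome name(s).
#' @param start,end interval bounds, bp (1-based inclusive).
#' @param reason free-text reason(s).
#' @return data.frame of class `mask_rules`.
#' @export
mask_rules <- function(chrom, start, end, reason = "") {
  d <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                  end = as.numeric(end),
                  reason = as.character(reason), stringsAsFactors = FALSE)
  if (any(d$start > d$end)) .stopf("mask rule start > end")
  class(d) <- c("mask_rules", "data.frame")
  d
}

#' Default marker masks for the yeast genome
#'
#' Covers the CAN1 (YEL063C, chrV left arm) and LYP1 (YNL268W, chrXIV left
#' arm) selection-marker neighbourhoods. Synthetic genomes need no masks.
#'
#' @param flank bp masked on each side of the marker gene.
#' @return a [mask_rules()] table.
#' @export
default_yeast_masks <- function(flank = 20000) {
  mask_rules(chrom = c("chrV", "chrXIV"),
             start = pmax(1, c(31694, 131645) - flank),
             end = c(33466, 133448) + flank,
             reason = c("CAN1 (YEL063C) SGA selection marker",
                        "LYP1 (YNL268W) SGA selection marker"))
}

#' Apply mask rules to a linkage matrix
#'
#' Any cell whose row or column bin overlaps a rule interval on this
#' chromosome is flagged invalid. Rules are combined by union, so repeated
#' application is idempotent.
#'
#' @param map a `linkage_matrix`.
#' @param rules a [mask_rules()] table.
#' @return the map with its `mask` updated.
#' @export
apply_masks <- function(map, rules) {
  stopifnot(inherits(map, "linkage_matrix"))
  rules <- rules[rules$chrom == map$chromosome, , drop = FALSE]
  if (!nrow(rules)) return(map)
  bad <- logical(map$n)
  for (r in seq_len(nrow(rules))) {
    k0 <- assign_bin(max(1, rules$start[r]), map$bin_size)
    k1 <- assign_bin(rules$end[r], map$bin_size)
    k1 <- min(k1, map$n - 1L)
    if (k0 <= k1) bad[(k0:k1) + 1L] <- TRUE
  }
  map$mask[bad, ] <- FALSE
  map$mask[, bad] <- FALSE
  map
}

#' Valid consolidated values of a linkage matrix
#'
#' @param map a consolidated `linkage_matrix`.
#' @return the `G_prime` matrix with masked cells set to `NA`.
#' @export
masked_values <- function(map) {
  G <- if (is.null(map$G_prime)) map$G else map$G_prime
  G[!map$mask] <- NA_real_
  G
}

#' Total genetic length per chromosome and its linear fit on physical length
#'
#' Each chromosome's mean recombination rate (SGA-GD/kb) is the average over
#' unmasked, off-diagonal cells within the linear range (cell value below
#' `cap`) of `G'[i, j] / (|i - j| * bin_kb)`. The total genetic length is
#' `rate * L_kb`, and a least-squares line `total_gd = a * L + b` is fitted
#' across chromosomes (the aL + b model: a constant per-kb component plus a
#' size-independent component).
#'
#' @param maps list of consolidated `linkage_matrix` objects.
#' @param annotation a [genome_annotation()].
#' @param cap linear-range cutoff, default 50 SGA-GD.
#' @return object of class `chromosome_fit`: data.frame `per_chromosome`
#'   (`chrom`, `L_kb`, `rate`, `total_gd`) plus coefficients `a`
#'   (SGA-GD/kb) and `b` (SGA-GD).
#' @export
chromosome_genetic_length <- function(maps, annotation, cap = 50) {
  rows <- lapply(maps, function(m) {
    G <- masked_values(m)
    sep <- abs(row(G) - col(G))
    ok <- !is.na(G) & sep > 0 & G < cap
    rate <- if (any(ok)) mean(G[ok] / (sep[ok] * m$bin_size / 1000)) else NA_real_
    L_kb <- chrom_length(annotation, m$chromosome) / 1000
    data.frame(chrom = m$chromosome, L_kb = L_kb, rate = rate,
               total_gd = rate * L_kb, stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  use <- per[!is.na(per$total_gd), , drop = FALSE]
  if (nrow(use) < 3)
    .stopf("linear fit needs >= 3 chromosomes with data, have %d", nrow(use))
  fit <- lm(total_gd ~ L_kb, data = use)
  structure(list(per_chromosome = per,
                 a = unname(coef(fit)[2]), b = unname(coef(fit)[1]),
                 fit = fit),
            class = "chromosome_fit")
}

#' @export
print.chromosome_fit <- function(x, ...) {
  cat(sprintf("chromosome_fit: total_gd = %.4g * L + %.4g over %d chromosomes\n",
              x$a, x$b, nrow(x$per_chromosome)))
  invisible(x)
}
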