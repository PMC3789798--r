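#' Distance-mapping configuration
#'
#' Controls how recombinant fractions become SGA-GD genetic distances.
#'
#' `haldane_capped` (default) applies the Haldane mapping function
#' `M = -ln(1 - 2R)/2` and caps the output at `cap_sga_gd` (50 by default),
#' so that independent segregation (`R = 0.5`, which Haldane maps to
#' infinity) reports exactly 50 SGA-GD. `linear` is the
#' complete-interference mapping `100 * R`, provided for sensitivity
#' analysis. Both map `R = 0` to 0 and `R = 0.5` to 50.
#'
#' @param mapping_mode `"haldane_capped"` or `"linear"`.
#' @param cap_sga_gd cap in SGA-GD units (> 0).
#' @param r_clip length-2 clamping interval for R, within \[0, 0.5\].
#' @param self_normalization `"affine_R"` (anchor each query's self distance
#'   at 0 on the R scale) or `"none"`.
#' @return object of class `distance_config`.
#' @export
distance_config <- function(mapping_mode = c("haldane_capped", "linear"),
                            cap_sga_gd = 50, r_clip = c(0, 0.5),
                            self_normalization = c("affine_R", "none")) {
  mapping_mode <- match.arg(mapping_mode)
  self_normalization <- match.arg(self_normalization)
  if (cap_sga_gd <= 0) .stopf("cap_sga_gd must be > 0")
  if (length(r_clip) != 2 || r_clip[1] > r_clip[2] ||
      r_clip[1] < 0 || r_clip[2] > 0.5)
    .stopf("r_clip must be an interval within [0, 0.5]")
  structure(list(mapping_mode = mapping_mode, cap_sga_gd = cap_sga_gd,
                 r_clip = as.numeric(r_clip),
                 self_normalization = self_normalization),
            class = "distance_config")
}

#' Recombinant fraction from a fitness triple
#'
#' `R = 0.5 * f_ij / (f_i * f_j)`: half the ratio of observed to expected
#' double-mutant colony size, so that independent loci
#' (`f_ij = f_i * f_j`) give `R = 0.5` and complete linkage (`f_ij = 0`)
#' gives `R = 0`. The value is returned unclipped so raw estimates stay
#' inspectable; see [clip_R()].
#'
#' @param f_i,f_j normalized single-mutant colony sizes (> 0).
#' @param f_ij normalized double-mutant colony size (>= 0).
#' @return numeric recombinant fraction (vectorized).
#' @export
recombinant_fraction <- function(f_i, f_j, f_ij) {
  if (any(!is.na(f_i) & f_i <= 0) || any(!is.na(f_j) & f_j <= 0))
    .stopf("single-mutant colony size <= 0: dead or missing single mutant")
  if (any(!is.na(f_ij) & f_ij < 0)) .stopf("negative double-mutant colony size")
  0.5 * f_ij / (f_i * f_j)
}

#' Clamp a recombinant fraction into the mapping domain
#'
#' @param R numeric recombinant fraction(s), finite.
#' @param config a [distance_config()].
#' @return list with `R` (clamped values) and `clamped` (logical).
#' @export
clip_R <- function(R, config = distance_config()) {
  lo <- config$r_clip[1]; hi <- config$r_clip[2]
  clamped <- !is.na(R) & (R < lo | R > hi)
  list(R = pmin(pmax(R, lo), hi), clamped = clamped)
}

#' Haldane mapping function
#'
#' Under a Poisson crossover model the mean number of recombination events
#' per meiosis is `m = -ln(1 - 2R)` and the genetic distance in Morgans is
#' `M = m / 2` (each event yields two recombinant products). For small R,
#' `M -> R`.
#'
#' @param R recombinant fraction(s) in `[0, 0.5)`.
#' @return list with `m` (events per meiosis) and `M` (Morgans).
#' @export
haldane_morgans <- function(R) {
  if (any(!is.na(R) & (R < 0 | R >= 0.5)))
    .stopf("haldane_morgans requires 0 <= R < 0.5; clip or cap first")
  m <- -log(1 - 2 * R)
  list(m = m, M = m / 2)
}

#' Map a recombinant fraction to SGA-GD
#'
#' One SGA-GD is the centimorgan-equivalent of the SGA data; 50 SGA-GD marks
#' independent segregation. In `haldane_capped` mode R is clamped, mapped
#' through [haldane_morgans()] and reported as `min(cap, 100 * M)` (R at the
#' upper clip returns the cap). In `linear` mode the result is
#' `100 * clamped R`. Monotone nondecreasing in R in both modes.
#'
#' @param R recombinant fraction(s), finite.
#' @param config a [distance_config()].
#' @return numeric SGA-GD value(s), in `[0, cap]`.
#' @export
sga_gd <- function(R, config = distance_config()) {
  Rc <- clip_R(R, config)$R
  if (config$mapping_mode == "linear") return(100 * Rc)
  cap <- config$cap_sga_gd
  out <- rep(cap, length(Rc))
  sub <- !is.na(Rc) & Rc < 0.5
  out[sub] <- pmin(cap, 100 * haldane_morgans(Rc[sub])$M)
  out[is.na(Rc)] <- NA_real_
  out
}

#' Self-zero normalization of recombinant fractions
#'
#' Even inviable double mutants form small residual colonies, so the raw
#' distance of a query to itself is not zero. The affine map
#' `R' = 0.5 * (R - self_R) / (0.5 - self_R)` anchors the query-self pair at
#' `R' = 0` while leaving independent pairs (`R = 0.5`) fixed, then clips to
#' `[0, 0.5]`. Applying it again with the transformed self value (0) is the
#' identity.
#'
#' @param R numeric recombinant fraction(s) for one screen.
#' @param self_R raw recombinant fraction of the query against its own array
#'   position; must be `< 0.5` or the screen is uninformative.
#' @return numeric transformed fractions, clipped to `[0, 0.5]`.
#' @export
normalize_self_zero <- function(R, self_R) {
  if (is.na(self_R) || self_R >= 0.5)
    .stopf("self_R = %s: screen rejected as uninformative (self_R must be < 0.5)",
           format(self_R))
  out <- 0.5 * (R - self_R) / (0.5 - self_R)
  pmin(pmax(out, 0), 0.5)
}

#' Pairwise genetic distances from a fitness screen
#'
#' Runs the full estimation path for one per-chromosome screen:
#' recombinant fractions from colony-size triples (see
#' [recombinant_fraction()]), replicate rows averaged on the R scale
#' (averaging on the bounded R scale avoids cap-saturation bias), optional
#' self-zero normalization per query using the query's own array position,
#' clamping, and the SGA-GD mapping.
#'
#' @param screen a [fitness_screen()].
#' @param config a [distance_config()].
#' @return data.frame with columns `query_id`, `array_id`, `R` (after
#'   averaging/normalization/clamping), `m`, `M`, `sga_gd`, `clamped`,
#'   `is_self`, `n_rep`.
#' @export
estimate_distances <- function(screen, config = distance_config()) {
  stopifnot(inherits(screen, "fitness_screen"))
  Rmat <- recombinant_fraction(
    matrix(screen$f_query, length(screen$f_query), length(screen$f_array)),
    matrix(screen$f_array, length(screen$f_query), length(screen$f_array),
           byrow = TRUE),
    screen$f_double)
  uq <- unique(screen$query_ids)
  Ravg <- matrix(NA_real_, length(uq), length(screen$array_ids))
  nrep <- integer(length(uq))
  for (k in seq_along(uq)) {
    rows <- which(screen$query_ids == uq[k])
    nrep[k] <- length(rows)
    Ravg[k, ] <- colMeans(Rmat[rows, , drop = FALSE], na.rm = TRUE)
  }
  Ravg[is.nan(Ravg)] <- NA_real_
  if (config$self_normalization == "affine_R") {
    for (k in seq_along(uq)) {
      a <- match(uq[k], screen$array_ids)
      if (is.na(a) || is.na(Ravg[k, a])) next
      if (Ravg[k, a] >= 0.5) {
        .warnf("query %s: self R = %.3f >= 0.5, screen rejected as uninformative",
               uq[k], Ravg[k, a])
        Ravg[k, ] <- NA_real_
        next
      }
      Ravg[k, ] <- normalize_self_zero(Ravg[k, ], Ravg[k, a])
    }
  }
  cl <- clip_R(as.vector(Ravg), config)
  gd <- sga_gd(cl$R, config)
  hm <- list(m = rep(NA_real_, length(gd)), M = rep(NA_real_, length(gd)))
  sub <- !is.na(cl$R) & cl$R < 0.5
  hm$m[sub] <- haldane_morgans(cl$R[sub])$m
  hm$M <- hm$m / 2
  out <- data.frame(
    query_id = rep(uq, times = length(screen$array_ids)),
    array_id = rep(screen$array_ids, each = length(uq)),
    R = cl$R, m = hm$m, M = hm$M, sga_gd = gd, clamped = cl$clamped,
    n_rep = rep(nrep, times = length(screen$array_ids)),
    stringsAsFactors = FALSE)
  out$is_self <- out$query_id == out$array_id
  out[!is.na(out$R), , drop = FALSE]
}

#' Bin gene pairs by physical distance
#'
#' Pairs are assigned to consecutive `bin_kb`-wide bins by physical distance
#' (bin k covers `((k-1)*bin_kb, k*bin_kb]`; zero distance joins the first
#' bin) and the genetic distances in each bin are averaged. Reported bin
#' distance is the bin center.
#'
#' @param dist_kb physical distances (kb).
#' @param gd genetic distances (SGA-GD).
#' @param bin_kb bin width (kb), default 5.
#' @return data.frame `bin_center` (kb), `mean_gd`, `n`, sorted by distance.
#' @export
bin_pairs_by_distance <- function(dist_kb, gd, bin_kb = 5) {
  keep <- !is.na(dist_kb) & !is.na(gd)
  dist_kb <- dist_kb[keep]; gd <- gd[keep]
  if (!length(dist_kb)) .stopf("no pairs to bin")
  k <- pmax(1L, ceiling(dist_kb / bin_kb))
  agg <- tapply(gd, k, mean)
  ks <- as.integer(names(agg))
  data.frame(bin_center = (ks - 0.5) * bin_kb,
             mean_gd = as.numeric(agg),
             n = as.integer(table(k)[as.character(ks)]))[order(ks), ]
}

#' Physical distance at which loci become unlinked
#'
#' Given a binned profile of mean SGA-GD against physical distance, returns
#' the smallest physical distance at which the mean reaches `threshold`
#' (50 SGA-GD = independent segregation), interpolating linearly between the
#' bracketing bins. In the published analysis this threshold falls at ~35 kb.
#'
#' @param dist_kb bin distances (kb), increasing.
#' @param mean_gd mean SGA-GD per bin.
#' @param threshold SGA-GD threshold, default 50.
#' @return distance in kb, or `NA` with a warning if never reached.
#' @export
unlinked_distance_threshold <- function(dist_kb, mean_gd, threshold = 50) {
  o <- order(dist_kb)
  dist_kb <- dist_kb[o]; mean_gd <- mean_gd[o]
  hit <- which(mean_gd >= threshold)
  if (!length(hit)) {
    .warnf("mean SGA-GD never reaches %g: unlinked threshold not available",
           threshold)
    return(NA_real_)
  }
  i <- hit[1]
  if (i == 1 || mean_gd[i] == threshold) return(dist_kb[i])
  # linear interpolation between the bracketing bins
  d0 <- dist_kb[i - 1]; d1 <- dist_kb[i]
  g0 <- mean_gd[i - 1]; g1 <- mean_gd[i]
  d0 + (threshold - g0) * (d1 - d0) / (g1 - g0)
}
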