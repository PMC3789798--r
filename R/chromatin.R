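#' Pericentric DSB-repressed region from a Spo11-oligo track
#'
#' Walks outward from the centromere on each side, accumulating oligo
#' counts; the repressed extent on a side is the distance to the last
#' position whose cumulative count is still below `threshold` (the first
#' position reaching the threshold bounds the region; if the first flanking
#' position already reaches it the extent is 0 — ties resolve toward the
#' smaller region). If the threshold is never reached the extent runs to
#' the chromosome end.
#'
#' @param track a [genomic_track()] of non-negative oligo counts.
#' @param centromere centromere midpoint, bp; must lie within the track
#'   span.
#' @param threshold oligo count bounding the region, default 3000.
#' @param chrom_length optional chromosome length bp; bounds the extents
#'   when the threshold is never reached (defaults to the track span).
#' @return object of class `repressed_region`: `chromosome`, `left_kb`,
#'   `right_kb`, `total_kb` (= left + right), `threshold`.
#' @export
dsb_repressed_region <- function(track, centromere, threshold = 3000,
                                 chrom_length = NULL) {
  stopifnot(inherits(track, "genomic_track"))
  if (any(track$value < 0)) .stopf("oligo counts must be >= 0")
  if (!length(track$position) || centromere < min(track$position) ||
      centromere > max(track$position))
    .stopf("centromere %g outside track span", centromere)
  lo <- if (is.null(chrom_length)) min(track$position) else 1
  hi <- if (is.null(chrom_length)) max(track$position) else chrom_length
  walk <- function(pos, val, end_dist) {
    if (!length(pos)) return(end_dist)
    cum <- cumsum(val)
    k <- which(cum >= threshold)
    if (!length(k)) return(end_dist)
    k <- k[1]
    if (k == 1) 0 else pos[k - 1]
  }
  left_sel <- track$position < centromere
  right_sel <- track$position > centromere
  ld <- centromere - track$position[left_sel]      # distances, increasing order needed
  lo_d <- order(ld)
  left <- walk(ld[lo_d], track$value[left_sel][lo_d], centromere - lo)
  rd <- track$position[right_sel] - centromere
  ro <- order(rd)
  right <- walk(rd[ro], track$value[right_sel][ro], hi - centromere)
  structure(list(chromosome = track$chromosome,
                 left_kb = left / 1000, right_kb = right / 1000,
                 total_kb = (left + right) / 1000, threshold = threshold),
            class = "repressed_region")
}

#' @export
print.repressed_region <- function(x, ...) {
  cat(sprintf("repressed_region [%s]: left %.1f kb + right %.1f kb = %.1f kb (< %g oligos)\n",
              x$chromosome, x$left_kb, x$right_kb, x$total_kb, x$threshold))
  invisible(x)
}

#' Left-right asymmetry of a pericentric region
#'
#' Signed difference `left_extent - right_extent` in kb. Also applicable to
#' linkage-based extents where the boundaries are the first positions at or
#' beyond 50 SGA-GD from the centromere.
#'
#' @param region a `repressed_region`, or a list with `left_kb` and
#'   `right_kb`.
#' @return numeric, kb (positive = left side wider).
#' @export
asymmetry_score <- function(region) {
  if (is.na(region$left_kb) || is.na(region$right_kb))
    .stopf("both extents must be defined")
  region$left_kb - region$right_kb
}

#' Global genomic average of a binding dataset
#'
#' Mean smoothed binding over all positions of all supplied tracks
#' (smoothing first, with the same moving-average window used for peak
#' measurement, so the cutoff and the profile are on the same scale).
#'
#' @param tracks list of [genomic_track()] objects (the whole dataset).
#' @param window moving-average window (positions), default 25.
#' @return numeric scalar (track units).
#' @export
global_genomic_average <- function(tracks, window = 25) {
  v <- unlist(lapply(tracks, function(t) moving_average(t$value, window)))
  mean(v, na.rm = TRUE)
}

#' Width of the centromere-centered cohesin peak
#'
#' The track is smoothed with a centered moving average over `window`
#' consecutive positions (index space; position spacing is recorded in the
#' output). From the position nearest the centromere the walk extends
#' outward on both sides while the smoothed binding stays strictly above
#' `gga` (the global genomic average, `b > GGA` cutoff); the width is the
#' distance between the two farthest contiguous super-GGA positions
#' flanking the centromere. If smoothed binding at the centromere is not
#' above `gga` the width is 0, with a warning.
#'
#' @param track a [genomic_track()].
#' @param centromere centromere midpoint, bp (within the track span).
#' @param gga global genomic average (see [global_genomic_average()]).
#' @param window smoothing window, default 25 positions.
#' @return object of class `cohesin_peak`: `chromosome`, `width_kb`,
#'   `gga`, `window`, `spacing` (median position spacing, bp).
#' @export
cohesin_peak_width <- function(track, centromere, gga, window = 25) {
  stopifnot(inherits(track, "genomic_track"))
  if (!length(track$position) || centromere < min(track$position) ||
      centromere > max(track$position))
    .stopf("centromere %g outside track span", centromere)
  s <- moving_average(track$value, window)
  ic <- which.min(abs(track$position - centromere))
  width <- 0
  if (is.na(s[ic]) || s[ic] <= gga) {
    .warnf("no centromeric peak on %s: smoothed binding at centromere <= GGA",
           track$chromosome)
  } else {
    l <- ic
    while (l > 1 && !is.na(s[l - 1]) && s[l - 1] > gga) l <- l - 1
    r <- ic
    nmax <- length(s)
    while (r < nmax && !is.na(s[r + 1]) && s[r + 1] > gga) r <- r + 1
    width <- (track$position[r] - track$position[l]) / 1000
  }
  structure(list(chromosome = track$chromosome, width_kb = width, gga = gga,
                 window = window,
                 spacing = stats::median(diff(track$position))),
            class = "cohesin_peak")
}

#' @export
print.cohesin_peak <- function(x, ...) {
  cat(sprintf("cohesin_peak [%s]: width %.1f kb (GGA %.3g, window %d positions)\n",
              x$chromosome, x$width_kb, x$gga, x$window))
  invisible(x)
}
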