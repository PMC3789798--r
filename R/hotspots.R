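#' Missing-aware centered moving average
#'
#' Window truncated at the ends; `NA`s inside a window are ignored; positions
#' whose whole window is `NA` stay `NA`. Never produces a value outside the
#' \[min, max\] of its raw window.
#'
#' @param x numeric vector.
#' @param window odd integer >= 1.
#' @return numeric vector of the same length.
#' @export
moving_average <- function(x, window = 5) {
  if (window %% 2 == 0 || window < 1) .stopf("window must be odd and >= 1")
  h <- (window - 1) / 2
  n <- length(x)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    w <- x[max(1, i - h):min(n, i + h)]
    if (any(!is.na(w))) out[i] <- mean(w, na.rm = TRUE)
  }
  out
}

#' Local recombination-rate profile from a linkage matrix
#'
#' For each bin x, all unmasked off-diagonal cells (i, j) with both indices
#' in `[x - half_window, x + half_window]` (a 25-kb interval for 5-kb bins
#' and `half_window = 2`) contribute a per-cell rate
#' `G'[i, j] / (|i - j| * bin_kb)` in SGA-GD/kb; the profile value is their
#' mean, `NA` where no cells qualify. Diagonal cells are excluded (self
#' pairs are normalized to zero and would bias rates down).
#'
#' @param map a consolidated (and masked, if applicable) `linkage_matrix`.
#' @param half_window bins on each side of x, default 2.
#' @return object of class `recomb_profile`: `chromosome`, `bin_size`,
#'   `position` (bin centers, bp), `rate`, `smoothed` (NULL until
#'   [smooth_profile()]).
#' @export
local_rate_profile <- function(map, half_window = 2) {
  stopifnot(inherits(map, "linkage_matrix"))
  G <- masked_values(map)
  n <- map$n
  kb <- map$bin_size / 1000
  sep <- abs(row(G) - col(G))
  rateM <- G / (sep * kb)
  rateM[sep == 0] <- NA_real_
  rate <- rep(NA_real_, n)
  for (x in seq_len(n)) {
    w <- max(1, x - half_window):min(n, x + half_window)
    v <- rateM[w, w]
    if (any(!is.na(v))) rate[x] <- mean(v, na.rm = TRUE)
  }
  structure(list(chromosome = map$chromosome, bin_size = map$bin_size,
                 position = (seq_len(n) - 0.5) * map$bin_size,
                 rate = rate, smoothed = NULL),
            class = "recomb_profile")
}

#' @export
print.recomb_profile <- function(x, ...) {
  cat(sprintf("recomb_profile [%s]: %d bin(s) of %g bp, mean rate %.3g SGA-GD/kb%s\n",
              x$chromosome, length(x$rate), x$bin_size,
              mean(x$rate, na.rm = TRUE),
              if (is.null(x$smoothed)) "" else ", smoothed"))
  invisible(x)
}

#' Smooth a recombination profile
#'
#' Centered moving-average filter over `window` consecutive positions
#' (default 5), truncated at chromosome ends, ignoring missing values.
#'
#' @param profile a `recomb_profile`.
#' @param window odd integer, default 5.
#' @return the profile with `smoothed` filled in.
#' @export
smooth_profile <- function(profile, window = 5) {
  stopifnot(inherits(profile, "recomb_profile"))
  profile$smoothed <- moving_average(profile$rate, window)
  profile
}

#' Genome-wide average recombination rate
#'
#' Mean of the raw (unsmoothed) profile values over all non-missing,
#' unmasked positions across the supplied profiles. Chromosomes excluded
#' from consolidation should not be passed in.
#'
#' @param profiles list of `recomb_profile` objects.
#' @return numeric scalar.
#' @export
genome_average_rate <- function(profiles) {
  v <- unlist(lapply(profiles, `[[`, "rate"))
  if (!any(!is.na(v))) .stopf("no rate values to average")
  mean(v, na.rm = TRUE)
}

#' Call recombination hotspots
#'
#' Hotspots are local maxima of the smoothed recombination frequency that
#' exceed the genome-wide average rate. A plateau of tied values yields a
#' single call at the plateau center (rounded down). Calls closer than
#' `min_separation` are merged keeping the higher one. Profile ends and
#' positions adjacent to missing stretches are not callable.
#'
#' @param profile a smoothed `recomb_profile`.
#' @param genome_avg genome-wide average rate (see [genome_average_rate()]).
#' @param min_separation bp, default 0 (no merging).
#' @return data.frame of class `hotspot_calls`: `chrom`, `position` (bin
#'   center bp), `rate` (SGA-GD/kb). Every call's rate strictly exceeds
#'   `genome_avg`.
#' @export
call_hotspots <- function(profile, genome_avg, min_separation = 0) {
  stopifnot(inherits(profile, "recomb_profile"))
  v <- profile$smoothed
  if (is.null(v)) .stopf("profile must be smoothed first (smooth_profile)")
  idx <- integer()
  ok <- !is.na(v)
  # examine maximal runs of equal values inside contiguous non-NA segments
  seg_id <- cumsum(!ok)
  for (s in split(which(ok), seg_id[ok])) {
    if (length(s) < 3) next
    y <- v[s]
    r <- rle(y)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in seq_along(r$values)) {
      if (k == 1 || k == length(r$values)) next   # segment ends not callable
      if (r$values[k] > r$values[k - 1] && r$values[k] > r$values[k + 1]) {
        center <- floor((starts[k] + ends[k]) / 2)
        idx <- c(idx, s[center])
      }
    }
  }
  idx <- idx[v[idx] > genome_avg]
  calls <- data.frame(chrom = rep(profile$chromosome, length(idx)),
                      position = profile$position[idx],
                      rate = v[idx], stringsAsFactors = FALSE)
  if (min_separation > 0 && nrow(calls) > 1) {
    o <- order(-calls$rate)
    keep <- logical(nrow(calls))
    for (i in o) {
      if (!any(keep & abs(calls$position - calls$position[i]) < min_separation))
        keep[i] <- TRUE
    }
    calls <- calls[keep, , drop = FALSE]
    calls <- calls[order(calls$position), , drop = FALSE]
  }
  rownames(calls) <- NULL
  class(calls) <- c("hotspot_calls", "data.frame")
  calls
}

#' Compare a hotspot call set against a reference set
#'
#' Sensitivity is the fraction of reference sites with a call within
#' `tolerance` on the same chromosome; precision is the fraction of calls
#' with a reference site within `tolerance`.
#'
#' @param calls data.frame with `chrom`, `position` (e.g. `hotspot_calls`).
#' @param reference a [site_list()] (or any data.frame with `chrom`,
#'   `position`).
#' @param tolerance bp, default 10000.
#' @return list with `precision`, `sensitivity`, `n_calls`, `n_reference`,
#'   and `reference_distance` (per reference site, bp to nearest same-
#'   chromosome call, `Inf` if none). Errors if the two sets share no
#'   chromosome names.
#' @export
compare_hotspot_sets <- function(calls, reference, tolerance = 10000) {
  if (nrow(calls) && nrow(reference)) {
    shared <- intersect(unique(calls$chrom), unique(reference$chrom))
    if (!length(shared))
      .stopf("no shared chromosome names between calls (%s) and reference (%s)",
             paste(unique(calls$chrom), collapse = ","),
             paste(unique(reference$chrom), collapse = ","))
  }
  nearest <- function(from, to) {
    vapply(seq_len(nrow(from)), function(i) {
      p <- to$position[to$chrom == from$chrom[i]]
      if (!length(p)) Inf else min(abs(p - from$position[i]))
    }, 0)
  }
  ref_d <- if (nrow(reference)) nearest(reference, calls) else numeric()
  call_d <- if (nrow(calls)) nearest(calls, reference) else numeric()
  list(precision = if (length(call_d)) mean(call_d <= tolerance) else NA_real_,
       sensitivity = if (length(ref_d)) mean(ref_d <= tolerance) else NA_real_,
       n_calls = nrow(calls), n_reference = nrow(reference),
       reference_distance = ref_d)
}
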