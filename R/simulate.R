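#' Built-in yeast-like genome
#'
#' Sixteen chromosomes with S. cerevisiae S288C lengths and centromere
#' midpoints (SGD coordinates, rounded to the kb below for the lengths'
#' published sizes). Used as the default synthetic genome so simulated
#' data have realistic size structure.
#'
#' @return data.frame `name`, `length` (bp), `centromere` (bp).
#' @export
default_genome <- function() {
  data.frame(
    name = paste0("chr", c("I", "II", "III", "IV", "V", "VI", "VII", "VIII",
                           "IX", "X", "XI", "XII", "XIII", "XIV", "XV", "XVI")),
    length = c(230218, 813184, 316620, 1531933, 576874, 270161, 1090940,
               562643, 439888, 745751, 666816, 1078177, 924431, 784333,
               1091291, 948066),
    centromere = c(151465, 238207, 114385, 449711, 151987, 148510, 496920,
                   105586, 355629, 436307, 440129, 150828, 268031, 628758,
                   326584, 555957),
    stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' The generative model: a per-chromosome crossover-rate map
#' `rate(x) = base_rate * hotspot_fold(x) * suppression(x)` in SGA-GD/kb,
#' where suppression multiplies the rate by `residual_fraction` within
#' radius rho of the centromere, `rho = rho0_kb + size_coupling * L_Mb`
#' (kb). True recombinant fractions follow the Poisson crossover model
#' `R = (1 - exp(-m))/2` with `m = cM/50`. Double-mutant colony sizes obey
#' `f_ij = (f_i * f_j * R/0.5)^gamma`, the minimal model under which the
#' colony-size estimator is exact in the absence of noise (`gamma < 1`
#' optionally emulates colony saturation); observed sizes are multiplied by
#' lognormal noise with sdlog `noise_sd`. Query-self pairs yield the
#' residual colony size of unformed double mutants.
#'
#' Default rates put the unlinked threshold at 50/1.4 ~ 36 kb of physical
#' distance, matching the elevated recombination scale of SGA data (where
#' unlinked loci sit at ~35 kb rather than the ~139 kb of classical maps).
#'
#' @param seed integer; all outputs are deterministic functions of it.
#' @param genome data.frame `name`, `length`, `centromere` (bp).
#' @param n_genes genes per chromosome.
#' @param bin_size bp, default 5000.
#' @param base_rate background rate, SGA-GD/kb.
#' @param hotspots NULL or data.frame `chrom`, `position` (bp), `fold`,
#'   `width` (bp); overlapping hotspots merge by max fold.
#' @param rho0_kb baseline pericentric suppression radius (kb).
#' @param size_coupling slope of rho on chromosome length (kb per Mb).
#' @param rho_kb optional named per-chromosome radius override (kb).
#' @param residual_fraction rate multiplier inside the suppressed region.
#' @param noise_sd sdlog of multiplicative colony-size noise.
#' @param single_sd sdlog of true single-mutant fitness around 1.
#' @param residual_colony baseline normalized size of unformed double
#'   mutants (small residual colonies).
#' @param interaction_rate fraction of pairs with a fitness interaction.
#' @param interaction_sd sdlog of the interaction multiplier.
#' @param replicate_count duplicate query rows per screen.
#' @param gamma compressive saturation exponent in (0, 1].
#' @param track_spacing bp between track positions.
#' @param spo11_per_kb expected Spo11 oligos per kb at the base rate.
#' @param rec8_background,rec8_peak Rec8 binding levels outside/inside the
#'   centromeric cluster.
#' @param rec8_width0_kb,rec8_coupling Rec8 cluster width intercept (kb) and
#'   slope on length (kb per Mb).
#' @param mcd1_width_kb constant mitotic-cohesin cluster width (kb).
#' @param track_noise_sd additive Gaussian noise sd on binding tracks
#'   (default 0: the track model itself is noise-free).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1, genome = default_genome(), n_genes = 40,
                       bin_size = 5000, base_rate = 1.4, hotspots = NULL,
                       rho0_kb = 10, size_coupling = 0, rho_kb = NULL,
                       residual_fraction = 0.1, noise_sd = 0.1,
                       single_sd = 0.05, residual_colony = 0.05,
                       interaction_rate = 0.02, interaction_sd = 0.4,
                       replicate_count = 2, gamma = 1,
                       track_spacing = 500, spo11_per_kb = 200,
                       rec8_background = 1, rec8_peak = 3,
                       rec8_width0_kb = 20, rec8_coupling = 20,
                       mcd1_width_kb = 20, track_noise_sd = 0) {
  stopifnot(base_rate >= 0, residual_fraction >= 0, residual_fraction <= 1,
            noise_sd >= 0, replicate_count >= 1, gamma > 0, gamma <= 1,
            residual_colony >= 0)
  if (!is.null(hotspots))
    stopifnot(all(c("chrom", "position", "fold", "width") %in% names(hotspots)))
  cfg <- list(seed = as.integer(seed), genome = genome, n_genes = n_genes,
              bin_size = bin_size, base_rate = base_rate, hotspots = hotspots,
              rho0_kb = rho0_kb, size_coupling = size_coupling,
              rho_kb = rho_kb, residual_fraction = residual_fraction,
              noise_sd = noise_sd, single_sd = single_sd,
              residual_colony = residual_colony,
              interaction_rate = interaction_rate,
              interaction_sd = interaction_sd,
              replicate_count = as.integer(replicate_count), gamma = gamma,
              track_spacing = track_spacing, spo11_per_kb = spo11_per_kb,
              rec8_background = rec8_background, rec8_peak = rec8_peak,
              rec8_width0_kb = rec8_width0_kb, rec8_coupling = rec8_coupling,
              mcd1_width_kb = mcd1_width_kb, track_noise_sd = track_noise_sd)
  class(cfg) <- "sim_config"
  cfg
}

#' Pericentric suppression radii implied by a configuration
#'
#' `rho = rho0_kb + size_coupling * L_Mb`, unless overridden per
#' chromosome via `rho_kb`.
#'
#' @param config a [sim_config()].
#' @return named numeric vector, kb.
#' @export
suppression_radii <- function(config) {
  g <- config$genome
  rho <- config$rho0_kb + config$size_coupling * g$length / 1e6
  names(rho) <- g$name
  if (!is.null(config$rho_kb)) rho[names(config$rho_kb)] <- config$rho_kb
  rho
}

#' True crossover-rate map
#'
#' Piecewise-constant rate per chromosome:
#' `rate(x) = base_rate * hotspot_fold(x) * suppression(x)`, plus the
#' cumulative genetic position (cM == SGA-GD here) at each breakpoint.
#'
#' @param config a [sim_config()].
#' @return object of class `rate_map`: per chromosome a data.frame
#'   `start`, `end` (bp, half-open on \[start, end)), `rate` (SGA-GD/kb),
#'   `cum0` (cM at `start`).
#' @export
build_rate_map <- function(config) {
  g <- config$genome
  rho <- suppression_radii(config) * 1000
  maps <- lapply(seq_len(nrow(g)), function(i) {
    L <- g$length[i]; cen <- g$centromere[i]; ch <- g$name[i]
    cuts <- c(0, L, max(0, cen - rho[ch]), min(L, cen + rho[ch]))
    hs <- config$hotspots
    if (!is.null(hs)) {
      hs <- hs[hs$chrom == ch, , drop = FALSE]
      cuts <- c(cuts, pmax(0, hs$position - hs$width / 2),
                pmin(L, hs$position + hs$width / 2))
    } else hs <- data.frame(position = numeric(), fold = numeric(),
                            width = numeric())
    cuts <- sort(unique(cuts))
    start <- head(cuts, -1); end <- tail(cuts, -1)
    midp <- (start + end) / 2
    rate <- rep(config$base_rate, length(midp))
    supp <- midp > cen - rho[ch] & midp < cen + rho[ch]
    rate[supp] <- rate[supp] * config$residual_fraction
    if (nrow(hs)) {
      for (k in seq_along(midp)) {
        cover <- abs(hs$position - midp[k]) <= hs$width / 2
        if (any(cover)) rate[k] <- rate[k] * max(hs$fold[cover])
      }
    }
    cum0 <- c(0, cumsum(rate * (end - start) / 1000))
    data.frame(start = start, end = end, rate = rate,
               cum0 = head(cum0, -1))
  })
  names(maps) <- g$name
  structure(list(maps = maps, genome = g), class = "rate_map")
}

#' Evaluate a rate map
#'
#' `rate_at` gives the local rate (SGA-GD/kb); `cum_cm` the cumulative
#' genetic position (cM) from the chromosome start.
#'
#' @param ratemap a [build_rate_map()] result.
#' @param chrom chromosome name.
#' @param x position(s), bp.
#' @return numeric vector.
#' @export
rate_at <- function(ratemap, chrom, x) {
  m <- ratemap$maps[[chrom]]
  if (is.null(m)) .stopf("unknown chromosome %s in rate map", chrom)
  i <- findInterval(x, m$start, rightmost.closed = FALSE)
  i[i < 1] <- 1L; i[i > nrow(m)] <- nrow(m)
  m$rate[i]
}

#' @rdname rate_at
#' @export
cum_cm <- function(ratemap, chrom, x) {
  m <- ratemap$maps[[chrom]]
  if (is.null(m)) .stopf("unknown chromosome %s in rate map", chrom)
  i <- findInterval(x, m$start)
  i[i < 1] <- 1L; i[i > nrow(m)] <- nrow(m)
  m$cum0[i] + m$rate[i] * (pmin(x, m$end[i]) - m$start[i]) / 1000
}

#' True recombinant fraction for a gene pair
#'
#' `m = cM / 50` expected crossovers per meiosis between the midpoints
#' (100 cM = 1 Morgan, each crossover yields two recombinant products),
#' then the Poisson model gives `R = (1 - exp(-m)) / 2`.
#'
#' @param ratemap a [build_rate_map()] result.
#' @param chrom chromosome name.
#' @param a,b midpoint positions, bp.
#' @return numeric recombinant fraction(s) in `[0, 0.5)`.
#' @export
pair_true_R <- function(ratemap, chrom, a, b) {
  cm <- abs(cum_cm(ratemap, chrom, a) - cum_cm(ratemap, chrom, b))
  (1 - exp(-cm / 50)) / 2
}

# deterministic gene placement: jittered grid, independent of downstream draws
.gene_positions <- function(config) {
  set.seed(config$seed)
  g <- config$genome
  out <- lapply(seq_len(nrow(g)), function(i) {
    L <- g$length[i]; n <- config$n_genes
    step <- L / n
    pos <- round(step * (seq_len(n) - 0.5) +
                   runif(n, -step / 4, step / 4))
    pos <- pmin(pmax(pos, 500), L - 500)
    pos <- sort(pos)
    while (anyDuplicated(pos)) pos[duplicated(pos)] <- pos[duplicated(pos)] + 1
    data.frame(gene_id = sprintf("%s_g%03d", g$name[i], seq_len(n)),
               chrom = g$name[i], pos = pos, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Genome annotation of a simulated genome
#'
#' Gene bodies are placed symmetrically (+/- 400 bp) around deterministic,
#' seed-jittered grid midpoints, so gene midpoints equal the simulated
#' positions exactly.
#'
#' @param config a [sim_config()].
#' @return a [genome_annotation()].
#' @export
sim_annotation <- function(config) {
  gp <- .gene_positions(config)
  genome_annotation(config$genome,
                    data.frame(gene_id = gp$gene_id, chrom = gp$chrom,
                               start = gp$pos - 400, end = gp$pos + 400,
                               strand = rep_len(c("+", "-"), nrow(gp)),
                               stringsAsFactors = FALSE))
}

#' Simulate SGA fitness screens with known ground truth
#'
#' One per-chromosome screen whose queries and arrays are the chromosome's
#' genes, with `replicate_count` duplicate query rows carrying independent
#' measurement noise. See [sim_config()] for the generative model.
#'
#' @param config a [sim_config()].
#' @return list with `screens` (named list of [fitness_screen()]),
#'   `truth` (data.frame `chrom`, `query_id`, `array_id`, `R_true`,
#'   `cm_true`, `gd_true` where `gd_true = min(50, cm_true)`),
#'   `annotation`, `rate_map`, and `rho_kb`.
#' @export
simulate_screens <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  ann <- sim_annotation(config)
  rm_ <- build_rate_map(config)
  gp <- .gene_positions(config)
  set.seed(config$seed + 1L)
  screens <- list(); truths <- list()
  for (ch in config$genome$name) {
    gi <- gp[gp$chrom == ch, , drop = FALSE]
    n <- nrow(gi)
    f_true <- exp(rnorm(n, 0, config$single_sd))
    cm <- cum_cm(rm_, ch, gi$pos)
    Rtrue <- (1 - exp(-abs(outer(cm, cm, `-`)) / 50)) / 2
    inter <- matrix(1, n, n)
    if (config$interaction_rate > 0) {
      hit <- matrix(runif(n * n) < config$interaction_rate, n, n)
      inter[hit] <- exp(rnorm(sum(hit), 0, config$interaction_sd))
    }
    reps <- config$replicate_count
    qrow <- rep(seq_len(n), each = reps)
    f_exp <- (outer(f_true, f_true) * 2 * Rtrue)^config$gamma * inter
    fd <- f_exp[qrow, , drop = FALSE]
    diag_cells <- cbind(seq_along(qrow), qrow)
    fd[diag_cells] <- config$residual_colony
    if (config$noise_sd > 0)
      fd <- fd * exp(matrix(rnorm(length(fd), 0, config$noise_sd),
                            nrow(fd), ncol(fd)))
    f_q <- f_true[qrow]
    f_a <- f_true
    if (config$noise_sd > 0) {
      f_q <- f_q * exp(rnorm(length(f_q), 0, config$noise_sd))
      f_a <- f_a * exp(rnorm(length(f_a), 0, config$noise_sd))
    }
    screens[[ch]] <- fitness_screen(ch, gi$gene_id[qrow], gi$gene_id,
                                    f_q, f_a, fd)
    truths[[ch]] <- data.frame(
      chrom = ch,
      query_id = rep(gi$gene_id, times = n),
      array_id = rep(gi$gene_id, each = n),
      R_true = as.vector(Rtrue),
      cm_true = as.vector(abs(outer(cm, cm, `-`))),
      stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truths)
  truth$gd_true <- pmin(50, truth$cm_true)
  rownames(truth) <- NULL
  list(screens = screens, truth = truth, annotation = ann, rate_map = rm_,
       rho_kb = suppression_radii(config))
}

#' Simulate genomic tracks, hotspot lists and a genetic map
#'
#' Spo11-oligo counts are Poisson draws with mean proportional to the true
#' rate map; Rec8 binding is a flat background plus a rectangular
#' centromeric cluster whose width grows with chromosome length
#' (`rec8_width0_kb + rec8_coupling * L_Mb`); Mcd1 has a constant-width
#' cluster. The hotspot site list contains the planted hotspot positions;
#' genetic-map loci sit at the simulated gene positions with cM equal to
#' the cumulative rate-map integral.
#'
#' @param config a [sim_config()].
#' @return list with `spo11`, `rec8`, `mcd1` (named lists of
#'   [genomic_track()]), `hotspot_sites` ([site_list()]), `genetic_map`
#'   (site_list with `locus`, cM in `score`), and `truth` (data.frame
#'   `chrom`, `rec8_width_kb`, `mcd1_width_kb`).
#' @export
simulate_tracks <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  rm_ <- build_rate_map(config)
  gp <- .gene_positions(config)
  set.seed(config$seed + 2L)
  g <- config$genome
  spo11 <- rec8 <- mcd1 <- list()
  widths <- numeric(nrow(g))
  for (i in seq_len(nrow(g))) {
    ch <- g$name[i]; L <- g$length[i]; cen <- g$centromere[i]
    pos <- seq(config$track_spacing / 2, L, by = config$track_spacing)
    lam <- rate_at(rm_, ch, pos) / config$base_rate *
      config$spo11_per_kb * config$track_spacing / 1000
    spo11[[ch]] <- genomic_track(ch, pos, rpois(length(pos), lam))
    w8 <- (config$rec8_width0_kb + config$rec8_coupling * L / 1e6) * 1000
    widths[i] <- w8 / 1000
    mk <- function(width_bp) {
      v <- ifelse(abs(pos - cen) <= width_bp / 2,
                  config$rec8_peak, config$rec8_background)
      if (config$track_noise_sd > 0)
        v <- v + rnorm(length(v), 0, config$track_noise_sd)
      genomic_track(ch, pos, v)
    }
    rec8[[ch]] <- mk(w8)
    mcd1[[ch]] <- mk(config$mcd1_width_kb * 1000)
  }
  hs <- config$hotspots
  hotspot_sites <- if (is.null(hs))
    site_list(character(), numeric(), numeric())
  else site_list(hs$chrom, hs$position, hs$fold)
  gmap <- site_list(gp$chrom, gp$pos,
                    unlist(lapply(split(gp, gp$chrom)[unique(gp$chrom)],
                                  function(d) cum_cm(rm_, d$chrom[1], d$pos))))
  gmap$locus <- gp$gene_id
  list(spo11 = spo11, rec8 = rec8, mcd1 = mcd1,
       hotspot_sites = hotspot_sites, genetic_map = gmap,
       truth = data.frame(chrom = g$name, rec8_width_kb = widths,
                          mcd1_width_kb = config$mcd1_width_kb,
                          stringsAsFactors = FALSE))
}

#' Write all simulated fixtures in the pipeline's on-disk dialects
#'
#' Emits the annotation (`annotation.tsv`, sgd_tab), per-chromosome fitness
#' screens, two-column tracks (`spo11_<chrom>.tsv`, `rec8_<chrom>.tsv`,
#' `mcd1_<chrom>.tsv`), `hotspots.bed`, `genetic_map.tsv` and a
#' `truth.json` sidecar.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_fixtures <- function(config, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sim <- simulate_screens(config)
  trk <- simulate_tracks(config)
  write_annotation(sim$annotation, file.path(dir, "annotation.tsv"))
  scr_dir <- file.path(dir, "screens")
  for (s in sim$screens) write_fitness_screen(s, scr_dir)
  for (ch in names(trk$spo11)) {
    write_track(trk$spo11[[ch]], file.path(dir, sprintf("spo11_%s.tsv", ch)))
    write_track(trk$rec8[[ch]], file.path(dir, sprintf("rec8_%s.tsv", ch)))
    write_track(trk$mcd1[[ch]], file.path(dir, sprintf("mcd1_%s.tsv", ch)))
  }
  if (nrow(trk$hotspot_sites))
    write_sites(trk$hotspot_sites, file.path(dir, "hotspots.bed"), "bed")
  write_sites(trk$genetic_map, file.path(dir, "genetic_map.tsv"), "map_tab")
  jsonlite::write_json(
    list(seed = config$seed,
         rho_kb = as.list(sim$rho_kb),
         rec8_width_kb = setNames(as.list(trk$truth$rec8_width_kb),
                                  trk$truth$chrom),
         n_pairs = nrow(sim$truth)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
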