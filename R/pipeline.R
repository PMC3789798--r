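#' Pipeline configuration
#'
#' Bundles every path and tunable of the end-to-end analysis. Defaults echo
#' the published analysis: 5-kb bins, 25-kb rate window (5 bins), 5-position
#' profile smoothing, 50 SGA-GD independence threshold, 10-kb hotspot match
#' tolerance, 3000-oligo DSB threshold, 25-position cohesin smoothing,
#' chromosome III excluded from consolidation, chromosomes I/III/VI/IX
#' excluded in the size-correlation sensitivity check.
#'
#' @param annotation_path annotation file (see [read_annotation()]).
#' @param annotation_format `"sgd_tab"` or `"gff3"`.
#' @param screens_dir directory of per-chromosome fitness screens (see
#'   [write_fitness_screen()]).
#' @param out_dir output directory.
#' @param tracks_dir optional directory with `spo11_<chrom>.tsv`,
#'   `rec8_<chrom>.tsv`, `mcd1_<chrom>.tsv` two-column tracks.
#' @param reference_hotspots optional BED of reference hotspot sites.
#' @param mask_file optional TSV of mask rules (`chrom start end reason`).
#' @param distance a [distance_config()].
#' @param bin_size bp.
#' @param profile_half_window bins each side for the rate profile.
#' @param smooth_window positions for profile smoothing (odd).
#' @param unlinked_threshold SGA-GD marking independence.
#' @param hotspot_tolerance bp for cross-study hotspot matching.
#' @param hotspot_min_separation bp between retained hotspot calls.
#' @param oligo_threshold Spo11 count bounding DSB-repressed regions.
#' @param cohesin_window positions for cohesin-track smoothing.
#' @param exclude_consolidation chromosomes kept unaveraged.
#' @param exclude_smallest chromosomes dropped in the exclusion-sensitivity
#'   correlation.
#' @param seed integer, used by `simulate` stages only.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(annotation_path, screens_dir, out_dir,
                            annotation_format = "sgd_tab",
                            tracks_dir = NULL, reference_hotspots = NULL,
                            mask_file = NULL,
                            distance = distance_config(),
                            bin_size = 5000, profile_half_window = 2,
                            smooth_window = 5, unlinked_threshold = 50,
                            hotspot_tolerance = 10000,
                            hotspot_min_separation = 0,
                            oligo_threshold = 3000, cohesin_window = 25,
                            exclude_consolidation = "chrIII",
                            exclude_smallest = c("chrI", "chrIII", "chrVI",
                                                 "chrIX"),
                            seed = 1) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

.cfg_echo <- function(config) {
  flat <- config
  flat$distance <- unclass(config$distance)
  unclass(flat)
}

#' Run the full analysis pipeline
#'
#' Stages: read annotation and screens; estimate pairwise distances
#' ([estimate_distances()]); build, consolidate and mask per-chromosome
#' linkage matrices; derive recombination profiles and call hotspots;
#' quantify cis/trans pericentric linkage extents and their correlation
#' with chromosome size; measure DSB-repressed regions and cohesin peak
#' widths when tracks are supplied. Outputs are TSV/BED files plus a JSON
#' echo of every configuration value and a run log; rerunning on the same
#' inputs is byte-identical.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) a list with the in-memory results: `distances`,
#'   `maps`, `profiles`, `hotspots`, `pericentric`, `correlations`,
#'   `chromatin`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!file.exists(config$annotation_path))
    .stopf("config error: annotation path not found: %s", config$annotation_path)
  if (!dir.exists(config$screens_dir))
    .stopf("config error: screens directory not found: %s", config$screens_dir)
  if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)
  logf <- file.path(config$out_dir, "run.log")
  cat("", file = logf)
  log_ <- function(fmt, ...) {
    cat(sprintf(paste0("[%s] ", fmt, "\n"), "linkmap", ...), file = logf,
        append = TRUE)
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[3]
    out <- tryCatch(expr, error = function(e)
      .stopf("stage '%s' failed: %s", name, conditionMessage(e)))
    log_("stage %s done in %.2fs", name, proc.time()[3] - t0)
    out
  }
  jsonlite::write_json(.cfg_echo(config),
                       file.path(config$out_dir, "config_echo.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)

  ann <- stage("annotation",
               read_annotation(config$annotation_path, config$annotation_format))
  chroms <- ann$chromosomes$name
  screens <- stage("screens", {
    found <- chroms[file.exists(file.path(config$screens_dir,
                                          paste0(chroms, "_double.tsv")))]
    if (!length(found)) .stopf("no screens found in %s", config$screens_dir)
    lapply(setNames(found, found),
           function(ch) read_fitness_screen(config$screens_dir, ch))
  })
  dists <- stage("distances",
                 lapply(screens, estimate_distances, config = config$distance))

  rules <- if (!is.null(config$mask_file)) {
    d <- read.table(config$mask_file, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
    mask_rules(d$chrom, d$start, d$end, d$reason)
  } else mask_rules(character(), numeric(), numeric(), character())

  maps <- stage("build", lapply(names(dists), function(ch) {
    m <- build_linkage_matrix(dists[[ch]], ann, ch, config$bin_size)
    m <- consolidate(m, exclude = config$exclude_consolidation)
    apply_masks(m, rules)
  }))
  names(maps) <- names(dists)
  for (ch in names(maps)) {
    G <- masked_values(maps[[ch]])
    tab <- screen_table(ch, sprintf("bin%04d", seq_len(nrow(G))),
                        sprintf("bin%04d", seq_len(ncol(G))), G)
    write_distance_matrix(tab, file.path(config$out_dir,
                                         sprintf("linkage_%s.tsv", ch)))
  }

  prof_chroms <- setdiff(names(maps), config$exclude_consolidation)
  profiles <- stage("profiles", lapply(setNames(prof_chroms, prof_chroms),
    function(ch) smooth_profile(local_rate_profile(maps[[ch]],
                                                   config$profile_half_window),
                                config$smooth_window)))
  gavg <- genome_average_rate(profiles)
  hs <- stage("hotspots", {
    calls <- do.call(rbind, lapply(profiles, call_hotspots, genome_avg = gavg,
                                   min_separation = config$hotspot_min_separation))
    rownames(calls) <- NULL
    calls
  })
  if (nrow(hs)) {
    half <- config$bin_size / 2
    writeLines(sprintf("%s\t%d\t%d\t%s", hs$chrom,
                       as.integer(hs$position - half),
                       as.integer(hs$position + half), .fmt_num(hs$rate)),
               file.path(config$out_dir, "hotspots.bed"))
  }
  hs_cmp <- NULL
  if (!is.null(config$reference_hotspots)) {
    ref <- read_sites(config$reference_hotspots, "bed")
    hs_cmp <- compare_hotspot_sets(hs, ref, config$hotspot_tolerance)
    log_("hotspot comparison: precision %.3f sensitivity %.3f",
         hs_cmp$precision, hs_cmp$sensitivity)
  }

  peri <- stage("pericentric", {
    rows <- lapply(prof_chroms, function(ch) {
      d <- dists[[ch]][!dists[[ch]]$is_self, , drop = FALSE]
      cl <- classify_pairs(d, ann)
      ext <- function(side) tryCatch(
        linkage_extent(cl, side, config$bin_size / 1000,
                       config$unlinked_threshold, config = config$distance),
        error = function(e) NA_real_)
      data.frame(chrom = ch, length_bp = chrom_length(ann, ch),
                 extent_cis = ext("cis"), extent_trans = ext("trans"),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  write.table(peri, file.path(config$out_dir, "pericentric.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cors <- stage("correlations", {
    mk <- function(v, excl) tryCatch({
      s <- size_correlation(setNames(v, peri$chrom), ann, excl)
      data.frame(R = s$R, p = s$p, n = s$n)
    }, error = function(e) data.frame(R = NA_real_, p = NA_real_, n = NA))
    rbind(cbind(variable = "extent_trans", mk(peri$extent_trans, character())),
          cbind(variable = "extent_cis", mk(peri$extent_cis, character())),
          cbind(variable = "extent_trans_excl",
                mk(peri$extent_trans, config$exclude_smallest)),
          cbind(variable = "extent_cis_excl",
                mk(peri$extent_cis, config$exclude_smallest)))
  })
  write.table(cors, file.path(config$out_dir, "size_correlations.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  chromatin <- NULL
  if (!is.null(config$tracks_dir)) {
    chromatin <- stage("chromatin", {
      rd <- function(pre, ch) {
        p <- file.path(config$tracks_dir, sprintf("%s_%s.tsv", pre, ch))
        if (file.exists(p)) read_track(p, "two_column", chromosome = ch) else NULL
      }
      sp <- Filter(Negate(is.null), lapply(setNames(chroms, chroms),
                                           function(ch) rd("spo11", ch)))
      r8 <- Filter(Negate(is.null), lapply(setNames(chroms, chroms),
                                           function(ch) rd("rec8", ch)))
      dsb <- do.call(rbind, lapply(names(sp), function(ch) {
        r <- dsb_repressed_region(sp[[ch]], centromere_position(ann, ch),
                                  config$oligo_threshold,
                                  chrom_length(ann, ch))
        data.frame(chrom = ch, left_kb = r$left_kb, right_kb = r$right_kb,
                   total_kb = r$total_kb, asymmetry_kb = asymmetry_score(r),
                   stringsAsFactors = FALSE)
      }))
      peaks <- NULL
      if (length(r8)) {
        gga <- global_genomic_average(r8, config$cohesin_window)
        peaks <- do.call(rbind, lapply(names(r8), function(ch) {
          p <- cohesin_peak_width(r8[[ch]], centromere_position(ann, ch),
                                  gga, config$cohesin_window)
          data.frame(chrom = ch, width_kb = p$width_kb,
                     stringsAsFactors = FALSE)
        }))
      }
      if (!is.null(dsb))
        write.table(dsb, file.path(config$out_dir, "dsb_repressed.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
      if (!is.null(peaks))
        write.table(peaks, file.path(config$out_dir, "cohesin_peaks.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
      list(dsb = dsb, cohesin = peaks)
    })
  }
  log_("pipeline complete")
  invisible(list(distances = dists, maps = maps, profiles = profiles,
                 hotspots = hs, hotspot_comparison = hs_cmp,
                 pericentric = peri, correlations = cors,
                 chromatin = chromatin, genome_average_rate = gavg))
}
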