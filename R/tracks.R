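#' Genomic track container
#'
#' A per-chromosome position/value track (Spo11-oligo counts, cohesin ChIP
#' signal, ...). Positions are 1-based bp, strictly increasing.
#'
#' @param chromosome chromosome name.
#' @param position numeric, strictly increasing bp coordinates.
#' @param value numeric, one value per position.
#' @return object of class `genomic_track`.
#' @export
genomic_track <- function(chromosome, position, value) {
  if (length(position) != length(value))
    .stopf("position and value lengths differ (%d vs %d)",
           length(position), length(value))
  if (length(position) && any(diff(position) <= 0))
    .stopf("track positions must be strictly increasing")
  if (length(position) && any(position < 0))
    .stopf("negative track positions")
  structure(list(chromosome = chromosome, position = as.numeric(position),
                 value = as.numeric(value)),
            class = "genomic_track")
}

#' @export
print.genomic_track <- function(x, ...) {
  cat(sprintf("genomic_track [%s]: %d position(s)", x$chromosome,
              length(x$position)))
  if (length(x$position))
    cat(sprintf(", span %g-%g bp", min(x$position), max(x$position)))
  cat("\n")
  invisible(x)
}

#' Read a genomic track
#'
#' `bedgraph` rows (`chrom  start  end  value`, 0-based half-open) are
#' converted to midpoint positions `(start + end)/2`; `two_column` rows are
#' `position<TAB>value`, 1-based. Duplicate positions are combined with
#' `dedup` (`"sum"` for count data such as Spo11 oligos, `"mean"` for ratio
#' tracks such as ChIP signal). 0-based conventions never leak past this
#' reader.
#'
#' @param path file path.
#' @param format `"bedgraph"` or `"two_column"`.
#' @param chromosome chromosome name; for bedGraph defaults to the first
#'   column (a single chromosome per track is required), for two_column to
#'   the file name.
#' @param dedup `"sum"` or `"mean"`.
#' @return a [genomic_track()]. Empty files give an empty track.
#' @export
read_track <- function(path, format = c("bedgraph", "two_column"),
                       chromosome = NULL, dedup = c("sum", "mean")) {
  format <- match.arg(format)
  dedup <- match.arg(dedup)
  if (!file.exists(path)) .stopf("track file not found: %s", path)
  if (file.size(path) == 0 || !length(readLines(path, n = 1L, warn = FALSE))) {
    if (is.null(chromosome))
      chromosome <- sub("\\.[^.]*$", "", basename(path))
    return(genomic_track(chromosome, numeric(), numeric()))
  }
  if (format == "bedgraph") {
    d <- read.table(path, sep = "", header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("chrom", "start", "end", "value"),
                    comment.char = "#")
    if (any(d$start < 0)) .stopf("negative positions in %s", path)
    chroms <- unique(d$chrom)
    if (is.null(chromosome)) {
      if (length(chroms) > 1)
        .stopf("track %s spans multiple chromosomes (%s); read per chromosome",
               path, paste(chroms, collapse = ", "))
      chromosome <- chroms[1]
    } else {
      d <- d[d$chrom == chromosome, , drop = FALSE]
    }
    pos <- (d$start + d$end) / 2
    val <- d$value
  } else {
    d <- read.table(path, sep = "", header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("position", "value"), comment.char = "#")
    if (any(d$position < 0)) .stopf("negative positions in %s", path)
    if (is.null(chromosome))
      chromosome <- sub("\\.[^.]*$", "", basename(path))
    pos <- d$position
    val <- d$value
  }
  o <- order(pos)
  pos <- pos[o]; val <- val[o]
  if (anyDuplicated(pos)) {
    f <- factor(pos, levels = unique(pos))
    val <- as.numeric(tapply(val, f, if (dedup == "sum") sum else mean))
    pos <- unique(pos)
  }
  genomic_track(chromosome, pos, val)
}

#' Write a genomic track
#'
#' @param track a [genomic_track()].
#' @param path output path.
#' @param format `"two_column"` (position/value, 1-based) or `"bedgraph"`
#'   (unit-width 0-based intervals whose midpoints reproduce the positions).
#' @return `path`, invisibly.
#' @export
write_track <- function(track, path, format = c("two_column", "bedgraph")) {
  format <- match.arg(format)
  if (format == "two_column") {
    writeLines(sprintf("%s\t%s", .fmt_num(track$position),
                       .fmt_num(track$value)), path)
  } else {
    # interval [p-1, p+1) has midpoint p under the (start+end)/2 rule
    writeLines(sprintf("%s\t%s\t%s\t%s", track$chromosome,
                       .fmt_num(track$position - 1), .fmt_num(track$position + 1),
                       .fmt_num(track$value)), path)
  }
  invisible(path)
}

#' Site lists (hotspots, genetic-map loci)
#'
#' A `site_list` is a data.frame with columns `chrom`, `position` (bp) and
#' optional `score` (cM for genetic-map loci, rate for hotspot calls).
#'
#' @param chrom character vector of chromosome names.
#' @param position numeric positions (bp).
#' @param score optional numeric scores.
#' @param annotation optional [genome_annotation()]; when given, positions are
#'   checked against chromosome bounds.
#' @return data.frame of class `site_list`.
#' @export
site_list <- function(chrom, position, score = NULL, annotation = NULL) {
  d <- data.frame(chrom = as.character(chrom), position = as.numeric(position),
                  stringsAsFactors = FALSE)
  d$score <- if (is.null(score)) NA_real_ else as.numeric(score)
  if (!is.null(annotation)) {
    L <- chrom_length(annotation, d$chrom)
    bad <- d$position < 1 | d$position > L
    if (any(bad))
      .stopf("%d site position(s) outside chromosome bounds", sum(bad))
  }
  class(d) <- c("site_list", "data.frame")
  d
}

#' Read a site list
#'
#' `bed` is BED3+score (`chrom start end [score]`, 0-based half-open; the
#' site position is the interval midpoint `(start+end)/2`). `map_tab` is a
#' classical genetic-map table `locus chrom position_bp cM`.
#'
#' @param path file path.
#' @param format `"bed"` or `"map_tab"`.
#' @param annotation optional [genome_annotation()] for bounds checking.
#' @return a [site_list()]; `map_tab` rows additionally carry a `locus`
#'   column and their cM in `score`.
#' @export
read_sites <- function(path, format = c("bed", "map_tab"), annotation = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) .stopf("site file not found: %s", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (!length(first) || !nzchar(first)) {
    return(site_list(character(), numeric(), numeric()))
  }
  if (format == "bed") {
    d <- read.table(path, sep = "", header = FALSE, stringsAsFactors = FALSE,
                    comment.char = "#", fill = TRUE)
    if (ncol(d) < 3) .stopf("BED file %s needs >= 3 columns", path)
    s <- site_list(d[[1]], (d[[2]] + d[[3]]) / 2,
                   if (ncol(d) >= 4) suppressWarnings(as.numeric(d[[4]])),
                   annotation)
  } else {
    d <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
    need <- c("locus", "chrom", "position", "cM")
    if (!all(need %in% names(d)))
      .stopf("map_tab file %s needs columns: %s", path,
             paste(need, collapse = ", "))
    s <- site_list(d$chrom, d$position, d$cM, annotation)
    s$locus <- d$locus
  }
  s
}

#' Write a site list
#'
#' @param sites a [site_list()].
#' @param path output path.
#' @param format `"bed"` (unit-width intervals whose midpoints reproduce the
#'   positions) or `"map_tab"` (requires a `locus` column; `score` is cM).
#' @return `path`, invisibly.
#' @export
write_sites <- function(sites, path, format = c("bed", "map_tab")) {
  format <- match.arg(format)
  if (format == "bed") {
    writeLines(sprintf("%s\t%s\t%s\t%s", sites$chrom,
                       .fmt_num(sites$position - 1), .fmt_num(sites$position + 1),
                       .fmt_num(sites$score)), path)
  } else {
    locus <- if (!is.null(sites$locus)) sites$locus else
      sprintf("L%04d", seq_len(nrow(sites)))
    writeLines(c("locus\tchrom\tposition\tcM",
                 sprintf("%s\t%s\t%s\t%s", locus, sites$chrom,
                         .fmt_num(sites$position), .fmt_num(sites$score))), path)
  }
  invisible(path)
}
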