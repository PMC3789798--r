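#' Genome annotation container
#'
#' Holds chromosome sizes, centromere midpoints, and gene coordinates.
#' All coordinates are 1-based and inclusive (SGD convention); readers for
#' 0-based formats convert at the boundary.
#'
#' @param chromosomes data.frame with columns `name`, `length` (bp),
#'   `centromere` (midpoint, bp).
#' @param genes data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand` (`"+"`, `"-"` or `"."`).
#' @return An object of class `genome_annotation`.
#' @export
genome_annotation <- function(chromosomes, genes) {
  chromosomes <- as.data.frame(chromosomes, stringsAsFactors = FALSE)
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  need_c <- c("name", "length", "centromere")
  need_g <- c("gene_id", "chrom", "start", "end", "strand")
  if (!all(need_c %in% names(chromosomes)))
    .stopf("chromosomes must have columns: %s", paste(need_c, collapse = ", "))
  if (nrow(genes) == 0) {
    genes <- data.frame(gene_id = character(), chrom = character(),
                        start = numeric(), end = numeric(),
                        strand = character(), stringsAsFactors = FALSE)
  }
  if (!all(need_g %in% names(genes)))
    .stopf("genes must have columns: %s", paste(need_g, collapse = ", "))
  if (anyDuplicated(chromosomes$name))
    .stopf("duplicated chromosome names")
  if (any(chromosomes$length <= 0))
    .stopf("chromosome lengths must be > 0")
  bad_cen <- chromosomes$centromere < 1 | chromosomes$centromere >= chromosomes$length
  if (any(bad_cen))
    .stopf("centromere outside (1, length) for chromosome(s): %s",
           paste(chromosomes$name[bad_cen], collapse = ", "))
  if (any(genes$start > genes$end))
    .stopf("gene start > end for: %s",
           paste(genes$gene_id[genes$start > genes$end], collapse = ", "))
  unknown <- setdiff(unique(genes$chrom), chromosomes$name)
  if (length(unknown))
    .stopf("genes reference unknown chromosome(s): %s",
           paste(unknown, collapse = ", "))
  if (anyDuplicated(genes$gene_id))
    .stopf("duplicated gene_id(s): %s",
           paste(unique(genes$gene_id[duplicated(genes$gene_id)]), collapse = ", "))
  structure(list(chromosomes = chromosomes, genes = genes),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("genome_annotation: %d chromosome(s), %d gene(s)\n",
              nrow(x$chromosomes), nrow(x$genes)))
  invisible(x)
}

#' Chromosome length / centromere lookup
#' @param annotation a [genome_annotation()].
#' @param chrom chromosome name(s).
#' @return numeric vector.
#' @export
chrom_length <- function(annotation, chrom) {
  i <- match(chrom, annotation$chromosomes$name)
  if (anyNA(i)) .stopf("unknown chromosome(s): %s",
                       paste(chrom[is.na(i)], collapse = ", "))
  annotation$chromosomes$length[i]
}

#' @rdname chrom_length
#' @export
centromere_position <- function(annotation, chrom) {
  i <- match(chrom, annotation$chromosomes$name)
  if (anyNA(i)) .stopf("unknown chromosome(s): %s",
                       paste(chrom[is.na(i)], collapse = ", "))
  annotation$chromosomes$centromere[i]
}

#' Gene midpoints
#'
#' Gene position used for binning and distance calculations is the midpoint
#' of (start, end).
#'
#' @param annotation a [genome_annotation()].
#' @param gene_ids character vector; defaults to all genes.
#' @return named numeric vector of midpoints (bp).
#' @export
gene_midpoints <- function(annotation, gene_ids = NULL) {
  g <- annotation$genes
  if (!is.null(gene_ids)) {
    i <- match(gene_ids, g$gene_id)
    if (anyNA(i)) .stopf("gene(s) absent from annotation: %s",
                         paste(gene_ids[is.na(i)], collapse = ", "))
    g <- g[i, , drop = FALSE]
  }
  setNames((g$start + g$end) / 2, g$gene_id)
}

#' Read a genome annotation
#'
#' Two dialects are supported. `sgd_tab` is an SGD-chromosomal-features-style
#' tab-delimited table with columns `name`, `type`, `chrom`, `start`, `end`,
#' `strand` where `type` is one of `chromosome`, `centromere`, `gene`
#' (chromosome rows carry the length in `end`). `gff3` is a GFF3 subset with
#' `##sequence-region` pragmas for chromosome lengths and `gene` /
#' `centromere` feature rows (`ID=` attribute names the gene). Centromere
#' midpoints are `floor((start+end)/2)`.
#'
#' @param path file path.
#' @param format `"sgd_tab"` or `"gff3"`.
#' @return a [genome_annotation()]. Errors if any chromosome lacks a
#'   centromere record.
#' @export
read_annotation <- function(path, format = c("sgd_tab", "gff3")) {
  format <- match.arg(format)
  if (!file.exists(path)) .stopf("annotation file not found: %s", path)
  if (format == "sgd_tab") .read_annotation_sgd(path) else .read_annotation_gff3(path)
}

.read_annotation_sgd <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  chroms <- list(); cens <- list(); genes <- list()
  for (k in seq_along(lines)) {
    f <- strsplit(lines[[k]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 6) .stopf("malformed annotation line %d in %s", k, path)
    start <- suppressWarnings(as.numeric(f[4])); end <- suppressWarnings(as.numeric(f[5]))
    if (is.na(start) || is.na(end)) .stopf("malformed coordinates at line %d in %s", k, path)
    rec <- list(name = f[1], chrom = f[3], start = start, end = end, strand = f[6])
    switch(f[2],
      chromosome = { chroms[[length(chroms) + 1L]] <- rec },
      centromere = { cens[[length(cens) + 1L]] <- rec },
      gene = { genes[[length(genes) + 1L]] <- rec },
      .stopf("unknown feature type '%s' at line %d in %s", f[2], k, path))
  }
  if (!length(chroms)) .stopf("no chromosome records in %s", path)
  cdf <- data.frame(name = vapply(chroms, `[[`, "", "chrom"),
                    length = vapply(chroms, `[[`, 0, "end"),
                    stringsAsFactors = FALSE)
  cen_chrom <- vapply(cens, `[[`, "", "chrom")
  mid <- vapply(cens, function(r) floor((r$start + r$end) / 2), 0)
  miss <- setdiff(cdf$name, cen_chrom)
  if (length(miss))
    .stopf("missing centromere record for chromosome(s): %s",
           paste(miss, collapse = ", "))
  cdf$centromere <- mid[match(cdf$name, cen_chrom)]
  gdf <- data.frame(
    gene_id = vapply(genes, `[[`, "", "name"),
    chrom = vapply(genes, `[[`, "", "chrom"),
    start = vapply(genes, `[[`, 0, "start"),
    end = vapply(genes, `[[`, 0, "end"),
    strand = vapply(genes, `[[`, "", "strand"),
    stringsAsFactors = FALSE)
  genome_annotation(cdf, gdf)
}

.read_annotation_gff3 <- function(path) {
  lines <- readLines(path, warn = FALSE)
  seqreg <- grep("^##sequence-region", lines, value = TRUE)
  cdf <- NULL
  if (length(seqreg)) {
    parts <- strsplit(trimws(seqreg), "[ \t]+")
    cdf <- data.frame(name = vapply(parts, `[`, "", 2),
                      length = as.numeric(vapply(parts, `[`, "", 4)),
                      stringsAsFactors = FALSE)
  }
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  cens <- list(); genes <- list()
  for (k in seq_along(body)) {
    f <- strsplit(body[[k]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 9) .stopf("malformed GFF3 line %d in %s", k, path)
    start <- suppressWarnings(as.numeric(f[4])); end <- suppressWarnings(as.numeric(f[5]))
    if (is.na(start) || is.na(end)) .stopf("malformed coordinates at GFF3 line %d in %s", k, path)
    id <- sub(".*ID=([^;]+).*", "\\1", f[9])
    rec <- list(chrom = f[1], type = f[3], start = start, end = end,
                strand = if (f[7] %in% c("+", "-")) f[7] else ".", id = id)
    if (f[3] == "centromere") cens[[length(cens) + 1L]] <- rec
    if (f[3] == "gene") genes[[length(genes) + 1L]] <- rec
    if (f[3] %in% c("region", "chromosome") && is.null(cdf))
      cdf <- rbind(cdf, data.frame(name = f[1], length = end, stringsAsFactors = FALSE))
  }
  if (is.null(cdf) || !nrow(cdf))
    .stopf("no chromosome lengths (##sequence-region or region features) in %s", path)
  cen_chrom <- vapply(cens, `[[`, "", "chrom")
  miss <- setdiff(cdf$name, cen_chrom)
  if (length(miss))
    .stopf("missing centromere record for chromosome(s): %s",
           paste(miss, collapse = ", "))
  mid <- vapply(cens, function(r) floor((r$start + r$end) / 2), 0)
  cdf$centromere <- mid[match(cdf$name, cen_chrom)]
  gdf <- data.frame(
    gene_id = vapply(genes, `[[`, "", "id"),
    chrom = vapply(genes, `[[`, "", "chrom"),
    start = vapply(genes, `[[`, 0, "start"),
    end = vapply(genes, `[[`, 0, "end"),
    strand = vapply(genes, `[[`, "", "strand"),
    stringsAsFactors = FALSE)
  genome_annotation(cdf, gdf)
}

#' Write a genome annotation in the `sgd_tab` dialect
#'
#' @param annotation a [genome_annotation()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path) {
  ch <- annotation$chromosomes
  g <- annotation$genes
  lines <- c(
    sprintf("%s\tchromosome\t%s\t1\t%s\t.", ch$name, ch$name, .fmt_num(ch$length)),
    sprintf("CEN_%s\tcentromere\t%s\t%s\t%s\t.", ch$name, ch$name,
            .fmt_num(ch$centromere), .fmt_num(ch$centromere)),
    if (nrow(g)) sprintf("%s\tgene\t%s\t%s\t%s\t%s", g$gene_id, g$chrom,
                         .fmt_num(g$start), .fmt_num(g$end), g$strand))
  writeLines(lines, path)
  invisible(path)
}
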