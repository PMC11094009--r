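## Readers and writers for the plain-text formats the pipeline consumes:
## BED3/BED6, ENCODE narrowPeak, TSS tables, featureCounts-style count
## tables, design tables and the simulators' fixture bundles. All tables are
## tab-separated with a header and LF endings; missing values are "NA".
## Coordinates are 0-based half-open in memory; 1-based inputs
## (featureCounts Start) are converted at the reader boundary.

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, na = "NA", eol = "\n")
  invisible(path)
}

#' Read genomic intervals from BED, narrowPeak, or a TSS table
#'
#' BED3/BED6 and ENCODE narrowPeak (10 columns; the summit offset is kept
#' in a `summit` column but otherwise unused). `tss_tsv` expects columns
#' gene_id, chrom, tss, strand. Malformed lines (non-numeric coordinates,
#' `end <= start`) are reported with their line numbers.
#'
#' @param path input file.
#' @param format `"bed"`, `"narrowPeak"`, or `"tss_tsv"`.
#' @return interval data.frame, or for `tss_tsv` a TSS data.frame.
#' @export
read_intervals <- function(path, format = c("bed", "narrowPeak", "tss_tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "tss_tsv") {
    df <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("gene_id", "chrom", "tss")
    if (!all(need %in% names(df))) {
      stop("TSS table needs columns gene_id, chrom, tss", call. = FALSE)
    }
    if (!"strand" %in% names(df)) df$strand <- "."
    return(df[, c("gene_id", "chrom", "tss", "strand")])
  }
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "track") & !startsWith(lines, "#")]
  if (length(lines) == 0) return(empty_intervals())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  min_cols <- if (format == "narrowPeak") 10L else 3L
  bad <- which(lengths(fields) < min_cols)
  if (length(bad) > 0) {
    stop(sprintf("line %d of %s: expected >= %d tab-separated columns",
                 bad[1], path, min_cols), call. = FALSE)
  }
  chrom <- vapply(fields, `[[`, character(1), 1)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0) {
    stop(sprintf("line %d of %s: non-numeric coordinates", bad[1], path),
         call. = FALSE)
  }
  bad <- which(end <= start)
  if (length(bad) > 0) {
    stop(sprintf("line %d of %s: end <= start", bad[1], path), call. = FALSE)
  }
  nm <- if (all(lengths(fields) >= 4)) vapply(fields, `[[`, character(1), 4)
        else NULL
  sc <- if (all(lengths(fields) >= 5)) {
    suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 5)))
  } else NULL
  st <- if (all(lengths(fields) >= 6)) vapply(fields, `[[`, character(1), 6)
        else NULL
  if (!is.null(st)) st[!st %in% c("+", "-", ".")] <- "."
  iv <- genomic_intervals(chrom, start, end, name = nm, score = sc,
                          strand = st)
  if (format == "narrowPeak") {
    summit <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1),
                                                 10)))
    iv$summit <- summit[order(chrom, start, end)]
  }
  iv
}

#' Write intervals as BED6
#'
#' @param intervals interval data.frame.
#' @param path output path.
#' @export
write_bed <- function(intervals, path) {
  df <- data.frame(chrom = intervals$chrom,
                   start = format(intervals$start, scientific = FALSE,
                                  trim = TRUE),
                   end = format(intervals$end, scientific = FALSE,
                                trim = TRUE),
                   name = intervals$name, score = intervals$score,
                   strand = intervals$strand)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE, eol = "\n")
  invisible(path)
}

#' Write / read an allelic count table (triplet layout)
#'
#' One row per feature (feature_id, chrom, start, end) followed by
#' `<sample>_total`, `<sample>_genome1`, `<sample>_genome2` triplets;
#' genome1/genome2 are recovered from Xi/Xa using the recorded Xi allele.
#'
#' @param counts `allelic_counts` object.
#' @param path output path.
#' @export
write_counts_tsv <- function(counts, path) {
  g1 <- if (counts$xi_allele == "genome1") counts$xi else counts$xa
  g2 <- if (counts$xi_allele == "genome1") counts$xa else counts$xi
  samples <- colnames(counts$total)
  cols <- list()
  for (s in seq_along(samples)) {
    cols[[paste0(samples[s], "_total")]] <- counts$total[, s]
    cols[[paste0(samples[s], "_genome1")]] <- g1[, s]
    cols[[paste0(samples[s], "_genome2")]] <- g2[, s]
  }
  df <- cbind(counts$features[, c("feature_id", "chrom", "start", "end")],
              as.data.frame(cols, check.names = FALSE))
  write_tsv(df, path)
}

#' @rdname write_counts_tsv
#' @param xi_allele which genome is Xi when reading back.
#' @export
read_counts_tsv <- function(path, xi_allele = "genome1") {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  features <- df[, c("feature_id", "chrom", "start", "end")]
  rest <- df[, -(1:4), drop = FALSE]
  samples <- unique(sub("_(total|genome1|genome2)$", "", names(rest)))
  grab <- function(suffix) {
    m <- as.matrix(rest[, paste0(samples, "_", suffix), drop = FALSE])
    dimnames(m) <- list(features$feature_id, samples)
    m
  }
  total <- grab("total"); g1 <- grab("genome1"); g2 <- grab("genome2")
  xi <- if (xi_allele == "genome1") g1 else g2
  xa <- if (xi_allele == "genome1") g2 else g1
  allelic_counts(features, total, xi, xa, xi_allele = xi_allele)
}

#' Write featureCounts-style count tables (one per alignment class)
#'
#' Produces `<prefix>_total.tsv`, `<prefix>_genome1.tsv`,
#' `<prefix>_genome2.tsv` in the featureCounts layout (comment line, then
#' Geneid/Chr/Start/End/Strand/Length and one column per sample, Start
#' 1-based inclusive).
#'
#' @param counts `allelic_counts` object.
#' @param prefix output path prefix.
#' @return character vector of the three paths.
#' @export
write_featurecounts <- function(counts, prefix) {
  g1 <- if (counts$xi_allele == "genome1") counts$xi else counts$xa
  g2 <- if (counts$xi_allele == "genome1") counts$xa else counts$xi
  layers <- list(total = counts$total, genome1 = g1, genome2 = g2)
  paths <- character(0)
  for (nm in names(layers)) {
    f <- counts$features
    df <- data.frame(Geneid = f$feature_id, Chr = f$chrom,
                     Start = f$start + 1, End = f$end, Strand = ".",
                     Length = f$end - f$start, check.names = FALSE)
    df <- cbind(df, as.data.frame(layers[[nm]], check.names = FALSE))
    path <- paste0(prefix, "_", nm, ".tsv")
    con <- file(path, "w")
    writeLines("# Program:xcikinetics synthetic featureCounts-style table",
               con)
    close(con)
    suppressWarnings(
      write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                  col.names = TRUE, append = TRUE, eol = "\n"))
    paths <- c(paths, path)
  }
  paths
}

read_featurecounts_one <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.delim(path, comment.char = "#", check.names = FALSE,
                   stringsAsFactors = FALSE)
  need <- c("Geneid", "Chr", "Start", "End")
  if (!all(need %in% names(df))) {
    stop("not a featureCounts-style table: ", path, call. = FALSE)
  }
  meta_cols <- intersect(c("Geneid", "Chr", "Start", "End", "Strand",
                           "Length"), names(df))
  samples <- setdiff(names(df), meta_cols)
  m <- as.matrix(df[, samples, drop = FALSE])
  rownames(m) <- df$Geneid
  list(features = data.frame(feature_id = df$Geneid, chrom = df$Chr,
                             start = df$Start - 1, end = df$End,
                             stringsAsFactors = FALSE),
       counts = m)
}

#' Read a featureCounts triple plus design into an allelic count matrix
#'
#' The three tables must share feature ids and sample columns; the design
#' must cover every sample and determines Xi/Xa orientation through its
#' `xi_allele` column (constant per cell line; e.g. Dom lines carry
#' inducible Xist on genome2 = 129/Sv). Cells where genome1 + genome2
#' exceed the total are rejected.
#'
#' @param total_path,genome1_path,genome2_path featureCounts-style tables.
#' @param design_path design TSV (sample_id, day, replicate, condition,
#'   cell_line, xi_allele).
#' @return list with `counts` ([allelic_counts()]) and `design`.
#' @export
read_count_matrix <- function(total_path, genome1_path, genome2_path,
                              design_path) {
  tot <- read_featurecounts_one(total_path)
  g1 <- read_featurecounts_one(genome1_path)
  g2 <- read_featurecounts_one(genome2_path)
  ids <- list(rownames(tot$counts), rownames(g1$counts), rownames(g2$counts))
  if (!all(vapply(ids, identical, logical(1), ids[[1]]))) {
    sym <- unique(c(setdiff(ids[[1]], ids[[2]]), setdiff(ids[[2]], ids[[1]]),
                    setdiff(ids[[1]], ids[[3]]), setdiff(ids[[3]], ids[[1]])))
    stop("count tables disagree on features: ",
         paste(head(sym, 5), collapse = ", "), call. = FALSE)
  }
  if (!identical(colnames(tot$counts), colnames(g1$counts)) ||
      !identical(colnames(tot$counts), colnames(g2$counts))) {
    stop("count tables disagree on sample columns", call. = FALSE)
  }
  design <- validate_design(read.delim(design_path,
                                       stringsAsFactors = FALSE))
  missing_samples <- setdiff(colnames(tot$counts), design$sample_id)
  if (length(missing_samples) > 0) {
    stop("samples absent from design table: ",
         paste(missing_samples, collapse = ", "), call. = FALSE)
  }
  xi_allele <- unique(design$xi_allele)
  if (length(xi_allele) != 1) {
    stop("mixed xi_allele across design; split by cell line first",
         call. = FALSE)
  }
  xi <- if (xi_allele == "genome1") g1$counts else g2$counts
  xa <- if (xi_allele == "genome1") g2$counts else g1$counts
  counts <- allelic_counts(tot$features, tot$counts, xi, xa,
                           xi_allele = xi_allele)
  list(counts = counts, design = design)
}

#' Write a complete synthetic fixture bundle
#'
#' Emits everything downstream stages consume: per-replicate BED6 peak
#' files, the featureCounts-style count triple, the design table, and the
#' ground-truth ledger.
#'
#' @param truth `sim_truth` table.
#' @param design `sim_design` object.
#' @param dir output directory (created if needed).
#' @param n_replicate_peaks,jitter_sd,dropout_rate peak-call simulation
#'   knobs.
#' @return named list of written paths.
#' @export
write_fixture_bundle <- function(truth, design, dir,
                                 n_replicate_peaks = 3, jitter_sd = 5,
                                 dropout_rate = 0.05) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_timecourse_counts(truth, design)
  peaks <- simulate_replicate_peaks(truth, n_replicates = n_replicate_peaks,
                                    jitter_sd = jitter_sd,
                                    dropout_rate = dropout_rate,
                                    seed = design$seed + 1)
  peak_paths <- vapply(seq_along(peaks), function(r) {
    p <- file.path(dir, sprintf("peaks_rep%d.bed", r))
    write_bed(peaks[[r]], p)
    p
  }, character(1))
  count_paths <- write_featurecounts(sim$counts, file.path(dir, "counts"))
  design_path <- file.path(dir, "design.tsv")
  write_tsv(sim$design, design_path)
  truth_path <- file.path(dir, "truth.tsv")
  write_tsv(as.data.frame(truth), truth_path)
  list(peaks = peak_paths, counts = count_paths, design = design_path,
       truth = truth_path)
}
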