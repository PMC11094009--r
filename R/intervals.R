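## Interval algebra on 0-based half-open (BED-convention) coordinates.
## Intervals travel as plain data.frames with columns chrom/start/end and
## optionally name/score/strand; IRanges does the heavy lifting internally
## (converted to 1-based closed at the call boundary).

#' Construct a genomic interval table
#'
#' Intervals use the BED convention: 0-based start, exclusive end.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors; `start >= 0`, `end > start`.
#' @param name,score,strand optional per-interval annotations; `strand` must
#'   be one of `"+"`, `"-"`, `"."` when given.
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `name`,
#'   `score`, `strand`, sorted by chromosome then start.
#' @export
genomic_intervals <- function(chrom, start, end, name = NULL, score = NULL,
                              strand = NULL) {
  start <- as.numeric(start); end <- as.numeric(end)
  n <- length(start)
  stopifnot(length(end) == n)
  chrom <- rep_len(as.character(chrom), n)
  if (any(start < 0)) stop("interval start must be >= 0", call. = FALSE)
  if (any(end <= start)) stop("interval end must be > start", call. = FALSE)
  if (is.null(name)) name <- sprintf("iv_%d", seq_len(n))
  if (is.null(score)) score <- rep(0, n)
  if (is.null(strand)) strand <- rep(".", n)
  if (!all(strand %in% c("+", "-", "."))) {
    stop("strand must be one of '+', '-', '.'", call. = FALSE)
  }
  df <- data.frame(chrom = as.character(chrom), start = start, end = end,
                   name = as.character(name), score = score,
                   strand = as.character(strand), stringsAsFactors = FALSE)
  sort_intervals(df)
}

sort_intervals <- function(iv) {
  iv[order(iv$chrom, iv$start, iv$end), , drop = FALSE]
}

empty_intervals <- function() {
  data.frame(chrom = character(), start = numeric(), end = numeric(),
             name = character(), score = numeric(), strand = character(),
             stringsAsFactors = FALSE)
}

## 0-based half-open -> IRanges (1-based closed)
as_iranges0 <- function(iv) IRanges::IRanges(start = iv$start + 1, end = iv$end)

#' Consensus regions supported by multiple replicate peak sets
#'
#' Computes maximal regions where the per-base count of covering peak files
#' reaches `min_support` — the standard construction of a consensus
#' regulatory-element set from per-replicate peak calls ("covered by peaks in
#' at least two sample replicates"). An alternative `"merge"` method unions
#' all peaks and keeps merged regions hit by at least `min_support` files.
#'
#' @param replicate_sets list of interval data.frames, one per peak file.
#' @param min_support minimum number of files covering a base (default 2).
#' @param method `"coverage"` (per-base semantics, default) or `"merge"`.
#' @return Interval data.frame of sorted, non-overlapping consensus regions.
#' @export
build_consensus <- function(replicate_sets, min_support = 2L,
                            method = c("coverage", "merge")) {
  method <- match.arg(method)
  if (!is.list(replicate_sets) || length(replicate_sets) == 0) {
    stop("replicate_sets must be a non-empty list of interval tables",
         call. = FALSE)
  }
  if (min_support < 1) stop("min_support must be >= 1", call. = FALSE)
  if (length(replicate_sets) < min_support) {
    stop("need at least min_support replicate sets", call. = FALSE)
  }
  all_iv <- do.call(rbind, lapply(replicate_sets, function(x) {
    x[, c("chrom", "start", "end"), drop = FALSE]
  }))
  if (nrow(all_iv) == 0) return(empty_intervals())
  out <- lapply(split(all_iv, all_iv$chrom), function(ch) {
    ir <- as_iranges0(ch)
    if (method == "coverage") {
      cov <- IRanges::coverage(ir)
      hits <- IRanges::slice(cov, lower = min_support, rangesOnly = TRUE)
    } else {
      merged <- IRanges::reduce(ir)
      n_files <- vapply(seq_along(merged), function(i) {
        sum(vapply(replicate_sets, function(rs) {
          rs <- rs[rs$chrom == ch$chrom[1], , drop = FALSE]
          if (nrow(rs) == 0) return(FALSE)
          any(IRanges::overlapsAny(merged[i], as_iranges0(rs)))
        }, logical(1)))
      }, numeric(1))
      hits <- merged[n_files >= min_support]
    }
    if (length(hits) == 0) return(NULL)
    data.frame(chrom = ch$chrom[1], start = IRanges::start(hits) - 1,
               end = IRanges::end(hits), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out) || nrow(out) == 0) return(empty_intervals())
  rownames(out) <- NULL
  genomic_intervals(out$chrom, out$start, out$end,
                    name = sprintf("consensus_%d", seq_len(nrow(out))))
}

#' Filter intervals by length
#'
#' Retains intervals with `min_len <= width <= max_len` (bounds inclusive);
#' the canonical consensus-set thresholds are 50 bp and 10 kb.
#'
#' @param intervals interval data.frame.
#' @param min_len,max_len inclusive width bounds in bases.
#' @export
filter_by_length <- function(intervals, min_len = 50, max_len = 10000) {
  if (min_len > max_len) stop("min_len must be <= max_len", call. = FALSE)
  w <- intervals$end - intervals$start
  intervals[w >= min_len & w <= max_len, , drop = FALSE]
}

#' Remove intervals overlapping a blacklist
#'
#' Any interval overlapping a blacklist region by at least 1 bp is removed
#' wholesale (not trimmed): blacklisted peaks are treated as mapping
#' artifacts to be discarded.
#'
#' @param intervals,blacklist interval data.frames.
#' @export
subtract_blacklist <- function(intervals, blacklist) {
  if (nrow(intervals) == 0 || is.null(blacklist) || nrow(blacklist) == 0) {
    return(intervals)
  }
  keep <- !overlaps_any(intervals, blacklist)
  intervals[keep, , drop = FALSE]
}

## per-interval TRUE iff >=1 bp overlap with any interval of `other`
overlaps_any <- function(intervals, other) {
  out <- logical(nrow(intervals))
  for (ch in unique(intervals$chrom)) {
    i_idx <- which(intervals$chrom == ch)
    o <- other[other$chrom == ch, , drop = FALSE]
    if (nrow(o) == 0) next
    out[i_idx] <- IRanges::overlapsAny(
      as_iranges0(intervals[i_idx, , drop = FALSE]), as_iranges0(o))
  }
  out
}

## distance from a TSS point (0-based) to an interval [s, e):
## 0 when s <= tss < e, else max(s - tss, tss - e)
point_interval_distance <- function(tss, start, end) {
  inside <- tss >= start & tss < end
  d <- pmax(start - tss, tss - end)
  d[inside] <- 0
  pmax(d, 0)
}

#' Classify intervals as promoter or distal
#'
#' An interval is a promoter iff it lies within `window` bases of some TSS
#' (distance 0 when the TSS falls inside the interval).
#'
#' @param intervals interval data.frame.
#' @param tss_table data.frame with columns `gene_id`, `chrom`, `tss`
#'   (0-based position), optionally `strand`.
#' @param window promoter window in bases (default 500).
#' @return character vector `"promoter"`/`"distal"` per interval.
#' @export
classify_promoter_distal <- function(intervals, tss_table, window = 500) {
  nearest <- assign_nearest_gene(intervals, tss_table)
  ifelse(!is.na(nearest$nearest_distance) & nearest$nearest_distance <= window,
         "promoter", "distal")
}

#' Assign each interval to its nearest gene TSS
#'
#' Nearest by point-to-interval distance on the same chromosome (bedtools
#' closest semantics); ties broken by smaller TSS coordinate, then
#' lexicographic gene id. Intervals on a chromosome with no TSS are reported
#' as `"unassigned"` with distance `NA`.
#'
#' @inheritParams classify_promoter_distal
#' @return data.frame with per-interval `nearest_gene`, `nearest_distance`,
#'   `tss`.
#' @export
assign_nearest_gene <- function(intervals, tss_table) {
  n <- nrow(intervals)
  gene <- rep("unassigned", n); dist <- rep(NA_real_, n); tpos <- rep(NA_real_, n)
  for (ch in unique(intervals$chrom)) {
    idx <- which(intervals$chrom == ch)
    tt <- tss_table[tss_table$chrom == ch, , drop = FALSE]
    if (nrow(tt) == 0) next
    tt <- tt[order(tt$tss, tt$gene_id), , drop = FALSE]
    s <- intervals$start[idx]; e <- intervals$end[idx]
    for (j in seq_along(idx)) {
      d <- point_interval_distance(tt$tss, s[j], e[j])
      best <- which.min(d)  # ties: first = smallest tss, then gene_id
      gene[idx[j]] <- tt$gene_id[best]
      dist[idx[j]] <- d[best]
      tpos[idx[j]] <- tt$tss[best]
    }
  }
  data.frame(name = intervals$name, nearest_gene = gene,
             nearest_distance = dist, tss = tpos, stringsAsFactors = FALSE)
}

#' Flag intervals overlapping a TF peak set
#'
#' @param intervals interval data.frame.
#' @param tf_peaks interval data.frame of ChIP-seq peaks.
#' @param label label used for the returned column name (e.g. "YY1").
#' @return logical vector, TRUE iff >= 1 bp overlap; named `<label>_binding`
#'   via its attribute `label`.
#' @export
flag_overlap <- function(intervals, tf_peaks, label = "TF") {
  flags <- if (is.null(tf_peaks) || nrow(tf_peaks) == 0) {
    rep(FALSE, nrow(intervals))
  } else {
    overlaps_any(intervals, tf_peaks)
  }
  attr(flags, "label") <- paste0(label, "_binding")
  flags
}

#' Genes whose TSS is directly overlapped by a TF peak
#'
#' A gene is a direct target iff its TSS point lies within `[start, end)` of
#' some peak.
#'
#' @param tf_peaks interval data.frame.
#' @param tss_table TSS data.frame (`gene_id`, `chrom`, `tss`).
#' @return character vector of unique direct-target gene ids.
#' @export
direct_target_genes <- function(tf_peaks, tss_table) {
  if (is.null(tf_peaks) || nrow(tf_peaks) == 0) return(character())
  hit <- logical(nrow(tss_table))
  for (ch in unique(tss_table$chrom)) {
    t_idx <- which(tss_table$chrom == ch)
    pk <- tf_peaks[tf_peaks$chrom == ch, , drop = FALSE]
    if (nrow(pk) == 0) next
    pt <- IRanges::IRanges(start = tss_table$tss[t_idx] + 1, width = 1)
    hit[t_idx] <- IRanges::overlapsAny(pt, as_iranges0(pk))
  }
  sort(unique(tss_table$gene_id[hit]))
}
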