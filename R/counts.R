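## AllelicCountMatrix: per-feature x per-sample fragment counts split into
## total / Xi / Xa. Stored as three numeric matrices sharing dimnames, plus a
## feature coordinate table; Xi/Xa orientation is resolved once from the
## design table (xi_allele column), never inferred from data.

#' Construct an allelic count matrix
#'
#' @param features data.frame with columns `feature_id`, `chrom`, `start`,
#'   `end` (0-based half-open).
#' @param total,xi,xa numeric matrices (features x samples) with identical
#'   dimnames; `xi + xa <= total` cellwise.
#' @param xi_allele which genome haplotype carries the inducible Xist allele
#'   (`"genome1"` or `"genome2"`); recorded for writers.
#' @return An object of class `allelic_counts`.
#' @export
allelic_counts <- function(features, total, xi, xa, xi_allele = "genome1") {
  stopifnot(is.matrix(total), is.matrix(xi), is.matrix(xa))
  if (!identical(dim(total), dim(xi)) || !identical(dim(total), dim(xa))) {
    stop("total/xi/xa matrices must share dimensions", call. = FALSE)
  }
  if (nrow(total) != nrow(features)) {
    stop("feature table and count matrices disagree on feature number",
         call. = FALSE)
  }
  if (any(xi < 0) || any(xa < 0) || any(total < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  bad <- which(xi + xa > total, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("xi + xa exceeds total at feature '%s', sample '%s'",
                 features$feature_id[bad[1, 1]], colnames(total)[bad[1, 2]]),
         call. = FALSE)
  }
  rownames(total) <- rownames(xi) <- rownames(xa) <- features$feature_id
  structure(list(features = features, total = total, xi = xi, xa = xa,
                 xi_allele = match.arg(xi_allele, c("genome1", "genome2"))),
            class = "allelic_counts")
}

#' @export
print.allelic_counts <- function(x, ...) {
  cat(sprintf("Allelic count matrix: %d features x %d samples (Xi = %s)\n",
              nrow(x$total), ncol(x$total), x$xi_allele))
  cat("samples:", paste(head(colnames(x$total), 8), collapse = ", "),
      if (ncol(x$total) > 8) "..." else "", "\n")
  invisible(x)
}

#' @export
dim.allelic_counts <- function(x) dim(x$total)

#' Subset an allelic count matrix by feature and/or sample
#'
#' @param x `allelic_counts` object.
#' @param features character vector of feature ids or logical/integer index.
#' @param samples character vector of sample ids or index.
#' @export
subset_counts <- function(x, features = NULL, samples = NULL) {
  fi <- if (is.null(features)) seq_len(nrow(x$total)) else features
  si <- if (is.null(samples)) seq_len(ncol(x$total)) else samples
  if (is.character(fi)) fi <- match(fi, x$features$feature_id)
  allelic_counts(x$features[fi, , drop = FALSE],
                 x$total[fi, si, drop = FALSE],
                 x$xi[fi, si, drop = FALSE],
                 x$xa[fi, si, drop = FALSE],
                 xi_allele = x$xi_allele)
}

#' Validate a time-course design table
#'
#' Requires columns `sample_id`, `day`, `replicate`, `condition`,
#' `cell_line`, `xi_allele`; `xi_allele` must be constant within a cell line
#' and one of `"genome1"`/`"genome2"`.
#'
#' @param design data.frame.
#' @return The design, checked and with `sample_id` as character.
#' @export
validate_design <- function(design) {
  need <- c("sample_id", "day", "replicate", "condition", "cell_line",
            "xi_allele")
  miss <- setdiff(need, names(design))
  if (length(miss) > 0) {
    stop("design table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!all(design$xi_allele %in% c("genome1", "genome2"))) {
    stop("xi_allele must be 'genome1' or 'genome2'", call. = FALSE)
  }
  per_line <- tapply(design$xi_allele, design$cell_line,
                     function(v) length(unique(v)))
  if (any(per_line > 1)) {
    stop("xi_allele must be constant within a cell line", call. = FALSE)
  }
  if (any(design$day < 0)) stop("days must be >= 0", call. = FALSE)
  design$sample_id <- as.character(design$sample_id)
  design
}

check_counts_design <- function(counts, design) {
  design <- validate_design(design)
  missing_samples <- setdiff(colnames(counts$total), design$sample_id)
  if (length(missing_samples) > 0) {
    stop("samples absent from design table: ",
         paste(missing_samples, collapse = ", "), call. = FALSE)
  }
  design[match(colnames(counts$total), design$sample_id), , drop = FALSE]
}
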