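## Position-weight-matrix handling: JASPAR raw count (PFM) reader with
## pseudocount, log2-odds scoring against a background distribution, and a
## both-strand scanner over DNA sequences (FIMO-style known-motif scan, but
## thresholded in bits rather than by a calibrated p-value).

DNA_BASES <- c("A", "C", "G", "T")

#' Construct a position weight matrix
#'
#' @param probs 4 x width numeric matrix of base probabilities, rows in
#'   A, C, G, T order; columns must sum to 1 (1e-9 tolerance).
#' @param motif_id motif identifier (e.g. "YY1_MA0095.2").
#' @param background length-4 background base distribution (default
#'   uniform).
#' @return An object of class `pwm`.
#' @export
pwm <- function(probs, motif_id = "motif", background = rep(0.25, 4)) {
  probs <- as.matrix(probs)
  if (nrow(probs) != 4) stop("PWM needs 4 rows (A, C, G, T)", call. = FALSE)
  if (any(probs < 0) || any(probs > 1)) {
    stop("PWM probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (any(abs(colSums(probs) - 1) > 1e-9)) {
    stop("PWM columns must each sum to 1", call. = FALSE)
  }
  if (length(background) != 4 || abs(sum(background) - 1) > 1e-9) {
    stop("background must be a length-4 distribution", call. = FALSE)
  }
  rownames(probs) <- DNA_BASES
  structure(list(probs = probs, width = ncol(probs), motif_id = motif_id,
                 background = setNames(as.numeric(background), DNA_BASES)),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM '%s', width %d; consensus %s; max score %.2f bits\n",
              x$motif_id, x$width, pwm_consensus(x), pwm_max_score(x)))
  invisible(x)
}

#' Read a JASPAR-format raw count matrix
#'
#' Accepts the JASPAR "raw PFM" layout: an optional `>` header line with
#' the motif id, then four rows of counts in A, C, G, T order, optionally
#' prefixed `A [ ... ]`. Counts are converted to probabilities after adding
#' a total pseudocount of `pseudocount` per column, split according to the
#' background distribution.
#'
#' @param path file path.
#' @param pseudocount total pseudocount per column (default 0.8).
#' @param background background base distribution (default uniform).
#' @return A [pwm()] object.
#' @export
read_jaspar_pfm <- function(path, pseudocount = 0.8,
                            background = rep(0.25, 4)) {
  lines <- readLines(path)
  lines <- trimws(lines[nzchar(trimws(lines))])
  motif_id <- "motif"
  if (startsWith(lines[1], ">")) {
    motif_id <- gsub("^>\\s*", "", lines[1])
    motif_id <- gsub("\\s+", "_", motif_id)
    lines <- lines[-1]
  }
  if (length(lines) < 4) stop("expected 4 count rows", call. = FALSE)
  rows <- lapply(lines[1:4], function(l) {
    l <- gsub("^[ACGTacgt]\\s*\\[", "", l)
    l <- gsub("\\]\\s*$", "", l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  })
  if (length(unique(lengths(rows))) != 1 || anyNA(unlist(rows))) {
    stop("malformed JASPAR count rows", call. = FALSE)
  }
  counts <- do.call(rbind, rows)
  probs <- apply(counts, 2, function(col) {
    (col + pseudocount * background) / (sum(col) + pseudocount)
  })
  pwm(probs, motif_id = motif_id, background = background)
}

pwm_consensus <- function(p) {
  paste(DNA_BASES[apply(p$probs, 2, which.max)], collapse = "")
}

#' Maximum achievable log2-odds score of a PWM
#' @param p `pwm` object.
#' @export
pwm_max_score <- function(p) {
  sum(apply(log2(p$probs / p$background), 2, max))
}

reverse_complement <- function(seq) {
  chartr("ACGTacgtN", "TGCAtgcaN",
         vapply(strsplit(seq, NULL), function(s) paste(rev(s), collapse = ""),
                character(1)))
}

pwm_score_positions <- function(seq_chars, p) {
  w <- p$width
  L <- length(seq_chars)
  if (L < w) return(numeric(0))
  lods <- log2(p$probs / p$background)  # 4 x w
  idx <- match(seq_chars, DNA_BASES)    # NA for N / unknown
  scores <- numeric(L - w + 1)
  for (pos in seq_len(L - w + 1)) {
    ii <- idx[pos:(pos + w - 1)]
    if (anyNA(ii)) { scores[pos] <- NA_real_; next }
    scores[pos] <- sum(lods[cbind(ii, seq_len(w))])
  }
  scores
}

#' Scan a DNA sequence for PWM motif hits on both strands
#'
#' Scores every window with the log2-odds
#' \eqn{\sum_j \log_2(p_{j,b_j} / q_{b_j})} on the forward strand and on
#' the reverse complement; windows containing `N` are skipped. Positions
#' are 0-based offsets of the window start on the forward strand (for a
#' minus-strand hit, the window's forward-strand location).
#'
#' @param sequence DNA string over A/C/G/T/N.
#' @param p `pwm` object.
#' @param score_threshold minimum score in bits; default 80% of the
#'   maximal achievable score.
#' @return data.frame of hits sorted by position: `position`, `strand`,
#'   `score`.
#' @export
pwm_scan <- function(sequence, p, score_threshold = 0.8 * pwm_max_score(p)) {
  if (!is.finite(score_threshold)) {
    stop("score_threshold must be finite", call. = FALSE)
  }
  sequence <- toupper(sequence)
  chars <- strsplit(sequence, NULL)[[1]]
  if (!all(chars %in% c(DNA_BASES, "N"))) {
    stop("sequence must be over A/C/G/T/N", call. = FALSE)
  }
  fwd <- pwm_score_positions(chars, p)
  rc_chars <- strsplit(reverse_complement(sequence), NULL)[[1]]
  rev_scores <- pwm_score_positions(rc_chars, p)
  ## hit at offset i (0-based) on the rc maps to forward position L - w - i
  L <- length(chars); w <- p$width
  hits <- list()
  if (length(fwd) > 0) {
    keep <- !is.na(fwd) & fwd >= score_threshold
    if (any(keep)) {
      hits[[1]] <- data.frame(position = which(keep) - 1, strand = "+",
                              score = fwd[keep], stringsAsFactors = FALSE)
    }
  }
  if (length(rev_scores) > 0) {
    keep <- !is.na(rev_scores) & rev_scores >= score_threshold
    if (any(keep)) {
      hits[[length(hits) + 1]] <-
        data.frame(position = L - w - (which(keep) - 1), strand = "-",
                   score = rev_scores[keep], stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0) {
    return(data.frame(position = integer(), strand = character(),
                      score = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  out[order(out$position, out$strand), , drop = FALSE]
}

#' Read DNA sequences from a FASTA file
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  s <- Biostrings::readDNAStringSet(path)
  setNames(as.character(s), names(s))
}
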