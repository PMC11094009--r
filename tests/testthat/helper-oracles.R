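# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals.

# per-base coverage consensus on small coordinates
oracle_consensus <- function(replicate_sets, min_support, max_pos = 1e4) {
  cov <- integer(max_pos)
  for (rs in replicate_sets) {
    for (i in seq_len(nrow(rs))) {
      s <- rs$start[i] + 1; e <- rs$end[i]
      cov[s:e] <- cov[s:e] + 1L
    }
  }
  hit <- cov >= min_support
  if (!any(hit)) return(data.frame(start = numeric(), end = numeric()))
  r <- rle(hit)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  data.frame(start = starts[keep] - 1, end = ends[keep])
}

# exhaustive nearest-TSS search with the tie rule (smaller tss, then gene id)
oracle_nearest <- function(iv_row, tss_table) {
  tt <- tss_table[tss_table$chrom == iv_row$chrom, , drop = FALSE]
  if (nrow(tt) == 0) return(list(gene = "unassigned", dist = NA_real_))
  best_gene <- NA_character_; best_d <- Inf; best_t <- Inf
  for (i in seq_len(nrow(tt))) {
    tss <- tt$tss[i]
    d <- if (tss >= iv_row$start && tss < iv_row$end) 0
         else max(iv_row$start - tss, tss - iv_row$end)
    better <- d < best_d ||
      (d == best_d && tss < best_t) ||
      (d == best_d && tss == best_t && tt$gene_id[i] < best_gene)
    if (better) { best_gene <- tt$gene_id[i]; best_d <- d; best_t <- tss }
  }
  list(gene = best_gene, dist = best_d)
}

# two-sided exact Wilcoxon p by full enumeration of rank assignments
oracle_wilcoxon_exact <- function(x, y) {
  n <- length(x); m <- length(y)
  ranks <- rank(c(x, y))
  u_obs <- sum(ranks[seq_len(n)]) - n * (n + 1) / 2
  combs <- utils::combn(n + m, n)
  u_all <- apply(combs, 2, function(idx) sum(seq_len(n + m)[idx]) -
                   n * (n + 1) / 2)
  p_le <- mean(u_all <= u_obs); p_ge <- mean(u_all >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# two-sided Fisher p by hypergeometric enumeration (tables no more probable
# than the observed one, with fisher.test's 1e-7 relative slack)
oracle_fisher <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- dhyper(lo:hi, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# naive single-position PWM log2-odds score
oracle_pwm_score <- function(window, probs, background) {
  bases <- c("A", "C", "G", "T")
  s <- 0
  for (j in seq_len(nchar(window))) {
    b <- match(substr(window, j, j), bases)
    if (is.na(b)) return(NA_real_)
    s <- s + unname(log2(probs[b, j] / background[b]))
  }
  s
}

# small allelic_counts builder for filter/ratio tests
make_counts <- function(xi, xa, total = NULL, days = NULL, reps = NULL) {
  xi <- as.matrix(xi); xa <- as.matrix(xa)
  if (is.null(total)) total <- xi + xa
  ns <- ncol(xi)
  if (is.null(days)) days <- rep(0, ns)
  if (is.null(reps)) reps <- seq_len(ns)
  samples <- sprintf("s%d", seq_len(ns))
  dimnames(xi) <- dimnames(xa) <- dimnames(total) <-
    list(sprintf("f%d", seq_len(nrow(xi))), samples)
  feats <- data.frame(feature_id = rownames(xi), chrom = "chrT",
                      start = seq_len(nrow(xi)) * 1000,
                      end = seq_len(nrow(xi)) * 1000 + 500,
                      stringsAsFactors = FALSE)
  counts <- allelic_counts(feats, total, xi, xa)
  design <- data.frame(sample_id = samples, day = days, replicate = reps,
                       condition = "dox", cell_line = "simDom",
                       xi_allele = "genome1", stringsAsFactors = FALSE)
  list(counts = counts, design = design)
}

random_interval_set <- function(n, max_pos = 9000, max_w = 400) {
  s <- sample.int(max_pos - max_w, n)
  w <- sample.int(max_w, n)
  genomic_intervals("chrT", s, s + w)
}
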