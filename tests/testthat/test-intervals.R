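test_that("consensus regions follow per-base replicate support", {
  r1 <- genomic_intervals("chrT", 100, 200)
  r2 <- genomic_intervals("chrT", 150, 250)
  r3 <- genomic_intervals("chrT", 300, 400)
  cs <- build_consensus(list(r1, r2, r3), min_support = 2)
  expect_equal(cs$start, 150)
  expect_equal(cs$end, 200)

  # min_support = 1 with one replicate: merged union
  one <- genomic_intervals("chrT", c(10, 50, 300), c(60, 100, 350))
  cs1 <- build_consensus(list(one), min_support = 1)
  expect_equal(cs1$start, c(10, 300))
  expect_equal(cs1$end, c(100, 350))

  # unanimity over identical replicates returns the common set
  cs3 <- build_consensus(list(r1, r1, r1), min_support = 3)
  expect_equal(cs3$start, 100)
  expect_equal(cs3$end, 200)

  expect_error(build_consensus(list(), 2), "non-empty")
})

test_that("consensus matches the per-base brute-force oracle and ignores order", {
  set.seed(101)
  for (i in 1:30) {
    n_rep <- sample(2:5, 1)
    reps <- lapply(seq_len(n_rep), function(r) {
      random_interval_set(sample(1:8, 1))
    })
    ms <- sample(1:n_rep, 1)
    got <- build_consensus(reps, min_support = ms)
    want <- oracle_consensus(reps, ms)
    expect_equal(got$start, want$start, info = sprintf("instance %d", i))
    expect_equal(got$end, want$end, info = sprintf("instance %d", i))
    # invariant to replicate order
    perm <- build_consensus(reps[sample(n_rep)], min_support = ms)
    expect_equal(perm$start, got$start)
  }
})

test_that("length filter applies inclusive bounds", {
  iv <- genomic_intervals("chrT", c(0, 0, 0), c(50, 10001, 5000))
  kept <- filter_by_length(iv, 50, 10000)
  expect_equal(sort(kept$end), c(50, 5000))   # 50 bp kept, 10001 bp dropped
  expect_equal(nrow(filter_by_length(empty_intervals(), 50, 10000)), 0)
  expect_error(filter_by_length(iv, 100, 50), "min_len")
})

test_that("blacklist subtraction removes whole peaks on >= 1 bp overlap", {
  iv <- genomic_intervals("chrT", 100, 200)
  expect_equal(nrow(subtract_blacklist(iv, genomic_intervals("chrT", 199, 300))), 0)
  # half-open adjacency is not overlap
  expect_equal(nrow(subtract_blacklist(iv, genomic_intervals("chrT", 200, 300))), 1)
  expect_equal(nrow(subtract_blacklist(iv, empty_intervals())), 1)
})

test_that("filter-then-subtract is idempotent", {
  set.seed(7)
  iv <- random_interval_set(40)
  bl <- random_interval_set(5)
  once <- subtract_blacklist(filter_by_length(iv, 50, 300), bl)
  twice <- subtract_blacklist(filter_by_length(once, 50, 300), bl)
  expect_identical(once, twice)
})

test_that("promoter assignment uses point distance to the TSS within 500 bp", {
  iv <- genomic_intervals("chrT", 1000, 1100)
  tss <- function(pos) data.frame(gene_id = "g", chrom = "chrT", tss = pos)
  expect_equal(classify_promoter_distal(iv, tss(1500)), "promoter")  # 400 bp
  expect_equal(classify_promoter_distal(iv, tss(1601)), "distal")    # 501 bp
  expect_equal(classify_promoter_distal(iv, tss(1050)), "promoter")  # inside
})

test_that("nearest-gene assignment matches exhaustive search with tie rules", {
  iv <- genomic_intervals("chrT", 1900, 2100)
  tt <- data.frame(gene_id = c("gA", "gB"), chrom = "chrT",
                   tss = c(1000, 5000))
  got <- assign_nearest_gene(iv, tt)
  expect_equal(got$nearest_gene, "gA")
  expect_equal(got$nearest_distance, 900)

  # TSS inside the interval: distance 0
  tt2 <- data.frame(gene_id = "gC", chrom = "chrT", tss = 2000)
  expect_equal(assign_nearest_gene(iv, tt2)$nearest_distance, 0)

  # equidistant: smaller coordinate wins
  tt3 <- data.frame(gene_id = c("far", "near"), chrom = "chrT",
                    tss = c(3500, 500))
  expect_equal(assign_nearest_gene(iv, tt3)$nearest_gene, "near")

  # random instances against the exhaustive oracle
  set.seed(55)
  for (i in 1:25) {
    ivs <- random_interval_set(6)
    tts <- data.frame(gene_id = sprintf("g%02d", 1:8), chrom = "chrT",
                      tss = sample.int(9500, 8))
    got <- assign_nearest_gene(ivs, tts)
    for (j in seq_len(nrow(ivs))) {
      want <- oracle_nearest(ivs[j, ], tts)
      expect_equal(got$nearest_gene[j], want$gene)
      expect_equal(got$nearest_distance[j], want$dist)
    }
  }

  # chromosome with no TSS
  lonely <- genomic_intervals("chrZ", 10, 20)
  out <- assign_nearest_gene(lonely, tt)
  expect_equal(out$nearest_gene, "unassigned")
  expect_true(is.na(out$nearest_distance))
})

test_that("TF overlap flags and direct targets respect half-open bounds", {
  iv <- genomic_intervals("chrT", 100, 200)
  expect_true(flag_overlap(iv, genomic_intervals("chrT", 150, 160))[1])
  expect_false(flag_overlap(iv, genomic_intervals("chrT", 200, 220))[1])
  expect_false(flag_overlap(iv, empty_intervals())[1])

  tt <- data.frame(gene_id = c("in", "edge"), chrom = "chrT",
                   tss = c(500, 600))
  pk <- genomic_intervals("chrT", 400, 600)
  expect_equal(direct_target_genes(pk, tt), "in")  # tss 600 excluded
  expect_equal(direct_target_genes(empty_intervals(), tt), character())
})
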