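test_that("contig and alignment filters use inclusive thresholds", {
  ctg <- setNames(vapply(c(499, 500, 501), strrep, character(1), x = "A"),
                  c("a", "b", "c"))
  expect_identical(names(filter_contigs(ctg)), c("b", "c"))
  expect_identical(filter_contigs(character(0)), character(0))
  expect_identical(filter_contigs(ctg, 100), ctg)

  rec <- alignment_records(
    contig_id = c("c1", "c1", "c1", "c2"), genome_id = c("g1", "g1", "g2", "g1"),
    contig_start = c(0, 0, 0, 0), contig_end = c(200, 150, 120, 100),
    genome_start = c(0, 300, 0, 0), genome_end = c(200, 450, 120, 100),
    identity = c(0.949, 0.95, 0.99, 0.95),
    contig_length = c(400, 400, 400, 100), genome_length = 1000)
  flt <- filter_alignments(rec)
  ## identity 0.949 dropped; 0.95/100 bp kept (inclusive boundaries)
  expect_false(any(flt$identity < 0.95))
  expect_true(any(flt$identity == 0.95 & flt$aligned_length == 100))
  ## c1 keeps only its best-scoring genome's alignments
  c1 <- flt[flt$contig_id == "c1", ]
  expect_equal(unique(c1$genome_id), "g1")
  expect_equal(nrow(c1), 1)  # the 0.949 and g2's 120 bp lose out

  ## max selection between two alignments to the same genome
  rec2 <- alignment_records(
    contig_id = "cx", genome_id = "gx",
    contig_start = c(0, 0), contig_end = c(80, 60),
    genome_start = c(0, 200), genome_end = c(100, 300),
    identity = c(0.96, 0.97), contig_length = 100, genome_length = 1000,
    score = c(80, 60))
  f2 <- filter_alignments(rec2, min_length = 50)
  expect_equal(nrow(f2), 2)  # same genome: both survive for coverage
  acc <- contig_accuracy(f2, 100)
  expect_equal(acc$accuracy, 100 * 0.96 * 0.8)  # score-80 alignment wins
})

test_that("contig statistics match the cumulative-sum oracle", {
  st <- contig_stats(c(1000, 800, 500, 300))
  expect_equal(st$n50, 800)
  expect_equal(st$sum, 2600)
  st1 <- contig_stats(42)
  expect_equal(st1[c("n50", "max", "mean")], list(n50 = 42, max = 42,
                                                  mean = 42))
  expect_equal(contig_stats(c(2, 2, 2, 2))$n50, 2)
  expect_equal(contig_stats(numeric(0))$count, 0L)
  set.seed(21)
  for (i in 1:20) {
    lens <- sample(100:5000, sample(1:40, 1), replace = TRUE)
    expect_identical(contig_stats(lens)$n50, oracle_n50(lens))
  }
})

test_that("genome coverage: union overall, longest contig for max", {
  rec <- alignment_records(
    contig_id = c("c1", "c2"), genome_id = "g",
    contig_start = c(0, 0), contig_end = c(400, 400),
    genome_start = c(0, 300), genome_end = c(400, 700),
    identity = 1, contig_length = c(400, 400), genome_length = 1000)
  cov <- genome_coverage(1000, rec)
  expect_equal(cov$overall, 70)

  one <- alignment_records("c", "g", 0, 1000, 0, 1000, 1, 1000, 1000)
  expect_equal(genome_coverage(1000, one),
               list(overall = 100, max_contig = 100, longest_contig = "c"))

  ## the longest contig is not the best-covering one
  rec2 <- alignment_records(
    contig_id = c("long", "short"), genome_id = "g",
    contig_start = c(0, 0), contig_end = c(400, 450),
    genome_start = c(0, 500), genome_end = c(400, 950),
    identity = 1, contig_length = c(500, 460), genome_length = 1000)
  cov2 <- genome_coverage(1000, rec2)
  expect_equal(cov2$max_contig, 40)
  expect_equal(cov2$longest_contig, "long")

  expect_equal(genome_coverage(1000, NULL)$overall, 0)
})

test_that("coverage equals the per-base boolean-array oracle on random fixtures", {
  set.seed(22)
  for (i in 1:30) {
    rec <- random_alignment_fixture()
    for (gid in unique(rec$genome_id)) {
      gr <- rec[rec$genome_id == gid, ]
      cov <- genome_coverage(2000, gr)
      expect_identical(cov$overall,
                       100 * oracle_covered_bases(2000, gr$genome_start,
                                                  gr$genome_end) / 2000)
      expect_true(cov$max_contig <= cov$overall + 1e-12)
      expect_true(cov$overall <= 100)
    }
  }
})

test_that("contig accuracy is the identity times aligned fraction", {
  r <- alignment_records("c", "g", 0, 900, 0, 900, 0.98, 1000, 5000)
  expect_equal(contig_accuracy(r, 1000)$accuracy, 88.2)
  r2 <- alignment_records("c", "g", 0, 100, 0, 100, 0.95, 500, 5000)
  expect_equal(contig_accuracy(r2, 500)$accuracy, 19.0)
  r3 <- alignment_records("c", "g", 0, 1000, 0, 1000, 1, 1000, 5000)
  expect_equal(contig_accuracy(r3, 1000)$accuracy, 100)
  ## accuracy ignores genome-side coordinates
  r4 <- alignment_records("c", "g", 0, 900, 3000, 3900, 0.98, 1000, 5000)
  expect_equal(contig_accuracy(r4, 1000)$accuracy, 88.2)
  expect_equal(contig_accuracy(NULL, 1000),
               list(accuracy = 0, aligned = FALSE))
})

test_that("chimericity is the natural-log entropy of read origins", {
  expect_equal(chimericity(c(37)), 0)
  expect_equal(chimericity(c(1, 1)), log(2))
  expect_equal(chimericity(c(3, 1)), -(0.75 * log(0.75) + 0.25 * log(0.25)),
               tolerance = 1e-12)
  expect_equal(chimericity(c(3, 1)), 0.562335, tolerance = 1e-6)
  expect_true(is.na(chimericity(c(0, 0))))
  ## maximal exactly at equal k-way splits; never exceeds ln k
  set.seed(23)
  for (k in 2:5) {
    expect_equal(chimericity(rep(7, k)), log(k), tolerance = 1e-12)
    for (i in 1:10) {
      cnt <- rep(7, k)
      cnt[sample(k, 1)] <- cnt[sample(k, 1)] + sample(1:20, 1)
      expect_lte(chimericity(cnt), log(k) + 1e-12)
    }
    cnt <- sample(1:50, k)
    expect_equal(chimericity(cnt), oracle_entropy(cnt), tolerance = 1e-12)
  }
})

test_that("coverage by others follows the printed arithmetic", {
  expect_equal(coverage_by_others(450, 450, 10000)$ratio, 0)
  cb <- coverage_by_others(500, 450, 10000)
  expect_equal(cb$cbo, 0.005)
  expect_equal(cb$ratio, 50 / 450, tolerance = 1e-12)
  deg <- coverage_by_others(10, 0, 10000)
  expect_true(is.na(deg$ratio))
  expect_false(deg$defined)
})

test_that("PCoA embeds similarity structure (cross-checked against ape)", {
  ## three equidistant points: embedded pairwise distances equal
  sim <- matrix(0.9, 3, 3); diag(sim) <- 1
  dimnames(sim) <- list(letters[1:3], letters[1:3])
  p <- pcoa_similarity(sim)
  d <- dist(p$points)
  expect_equal(max(d) - min(d), 0, tolerance = 1e-9)

  ## identical genomes -> all coordinates at the origin
  sim1 <- matrix(1, 4, 4); dimnames(sim1) <- list(letters[1:4], letters[1:4])
  p1 <- suppressWarnings(pcoa_similarity(sim1))  # degenerate: zero spread
  expect_equal(max(abs(p1$points)), 0, tolerance = 1e-9)

  ## distances from known 2-D coordinates are recovered up to rotation
  set.seed(24)
  xy <- matrix(runif(12, 0, 0.3), ncol = 2,
               dimnames = list(paste0("g", 1:6), NULL))
  dm <- as.matrix(dist(xy))
  sim2 <- 1 - dm
  p2 <- pcoa_similarity(sim2, k = 2)
  expect_equal(as.matrix(dist(p2$points)), dm, tolerance = 1e-8,
               ignore_attr = TRUE)
  ## centroid-nearest member agrees with explicit norms
  expect_equal(p2$medoid,
               rownames(xy)[which.min(rowSums(scale(xy, scale = FALSE)^2))])

  if (requireNamespace("ape", quietly = TRUE)) {
    ap <- ape::pcoa(as.dist(dm))
    expect_equal(abs(cor(ap$vectors[, 1], p2$points[, 1])), 1,
                 tolerance = 1e-6)
  }

  expect_error(pcoa_similarity(matrix(c(1, 0.5, 0.2, 1), 2, 2)), "symmetric")
})

test_that("longest repeat matches the exhaustive substring oracle", {
  expect_equal(longest_repeat("AAAA"), 3)
  set.seed(25)
  g <- random_genome(10000)
  expect_lt(longest_repeat(g), 50)  # far below 400 for random sequence
  planted <- paste0(substr(g, 1, 5000), substr(g, 2001, 2150),
                    substr(g, 5001, 10000))
  ## the planted 150 bp duplication may extend by a flanking chance match
  expect_gte(longest_repeat(planted), 150)
  expect_lte(longest_repeat(planted), 155)
  for (i in 1:10) {
    s <- random_genome(sample(20:60, 1))
    expect_identical(longest_repeat(s), oracle_longest_repeat(s))
  }
})

test_that("paired Wilcoxon wrapper reports no-difference as p = 1", {
  x <- c(10, 20, 30, 40)
  expect_equal(compare_paired(x, x)$p_value, 1)
  res <- compare_paired(c(1, 2, 3, 4, 5, 6), c(2, 3, 4, 5, 6, 7))
  expect_lt(res$p_value, 0.05)
})

test_that("reconstruction report applies the 1700 nt filter and summaries", {
  seqs <- c(big = random_genome(3000), small = random_genome(1699),
             other = random_genome(2500))
  comm <- community_profile(seqs, c(0.5, 0.25, 0.25))
  aln <- alignment_records(
    contig_id = c("c1", "c2"), genome_id = c("big", "other"),
    contig_start = c(0, 0), contig_end = c(3000, 1000),
    genome_start = c(0, 0), genome_end = c(3000, 1000),
    identity = 1, contig_length = c(3000, 1000),
    genome_length = c(3000, 2500))
  rep_ <- reconstruction_report(comm, aln)
  expect_false("small" %in% rep_$per_genome$genome_id)
  big <- rep_$per_genome[rep_$per_genome$genome_id == "big", ]
  expect_equal(big$max_contig_coverage, 100)
  expect_equal(rep_$summary$n_max_ge95, 1)
  expect_equal(rep_$summary$n_max_ge50, 1)
  ## summary equals brute-force recomputation from the per-genome table
  expect_equal(rep_$summary$mean_overall,
               mean(rep_$per_genome$overall_coverage))
  expect_equal(rep_$summary$mean_max_contig,
               mean(rep_$per_genome$max_contig_coverage))
})
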