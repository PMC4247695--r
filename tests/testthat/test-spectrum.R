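test_that("overlap detection honours inclusive length/identity boundaries", {
  set.seed(30)
  g <- random_genome(400)
  a <- substr(g, 1, 100)
  expect_true(detect_overlap(a, a))                      # full-length overlap
  expect_false(detect_overlap(a, substr(g, 67, 166)))    # 34 bp overlap
  expect_true(detect_overlap(a, substr(g, 66, 165)))     # 35 bp overlap
  ## 50 bp overlap with exactly one mismatch: 49/50 = 0.98 passes
  b <- substr(g, 51, 150)
  bc <- seq_chars(b)
  bc[10] <- setdiff(c("A", "C", "G", "T"), bc[10])[1]
  expect_true(detect_overlap(a, paste(bc, collapse = ""),
                             min_overlap = 50, min_identity = 0.98))
  ## two mismatches in 50 drop below 0.98
  bc[20] <- setdiff(c("A", "C", "G", "T"), bc[20])[1]
  expect_false(detect_overlap(a, paste(bc, collapse = ""),
                              min_overlap = 50, min_identity = 0.98))
  ## reverse-complement overlaps count
  expect_true(detect_overlap(a, revcomp(substr(g, 50, 149))))
  expect_false(detect_overlap(a, revcomp(substr(g, 50, 149)),
                              both_strands = FALSE))
})

test_that("spectra from trivial configurations", {
  set.seed(31)
  ## mutually non-overlapping reads -> all singletons
  reads <- vapply(1:8, function(i) random_genome(60), character(1))
  sp <- build_spectrum(reads, method = "exhaustive")
  expect_equal(sp$counts, c(8))
  ## three reads tiling one region chain into one contig
  g <- random_genome(200)
  tile <- c(substr(g, 1, 90), substr(g, 50, 140), substr(g, 100, 190))
  sp3 <- build_spectrum(tile, method = "exhaustive")
  expect_equal(sp3$counts, c(0, 0, 1))
  sp3i <- build_spectrum(tile, method = "index")
  expect_equal(sp3i$counts, c(0, 0, 1))
})

test_that("index clustering matches the brute-force oracle and is order-independent", {
  set.seed(32)
  g <- random_genome(1500)
  comm <- community_profile(c(g1 = g), 1)
  prof <- platform_profile("ft", read_length = 80, paired = FALSE,
                           substitution_rate_start = 0.005,
                           substitution_rate_end = 0.005, indel_rate = 5e-4)
  reads <- simulate_reads(prof, comm, 120, seed = 33)$sequence

  spi <- build_spectrum(reads, method = "index")
  spe <- build_spectrum(reads, method = "exhaustive")
  expect_identical(spi$counts, spe$counts)

  ## oracle: O(n^2) all-pairs single linkage under detect_overlap
  sizes <- oracle_single_linkage_sizes(
    length(reads), function(i, j) detect_overlap(reads[i], reads[j], gapped = TRUE))
  expect_identical(spi$counts, as.numeric(tabulate(sizes)))

  ## order independence
  sh <- build_spectrum(sample(reads), method = "index")
  expect_identical(sh$counts, spi$counts)

  ## read conservation
  expect_equal(sum(seq_along(spi$counts) * spi$counts), length(reads))
})

test_that("subsampled spectra: subsample size, averaging, conservation", {
  set.seed(34)
  g <- random_genome(3000)
  comm <- community_profile(c(g1 = g), 1)
  reads <- simulate_reads(platform_profile("clean", read_length = 90,
                                           paired = FALSE,
                                           substitution_rate_start = 0,
                                           substitution_rate_end = 0,
                                           indel_rate = 0),
                          comm, 400, seed = 35)
  ## n_sub = ceil(fold * AGL / read length)
  sp <- subsampled_spectrum(reads, avg_genome_length = 3000,
                            fold_coverage = 3, repetitions = 4, seed = 36)
  expect_equal(sp$n_reads_used, ceiling(3 * 3000 / 90))
  ## per-repetition and averaged conservation
  per <- sp$per_rep
  for (r in seq_len(ncol(per)))
    expect_equal(sum(seq_len(nrow(per)) * per[, r]), sp$n_reads_used)
  expect_equal(sum(seq_along(sp$counts) * sp$counts), sp$n_reads_used,
               tolerance = 1e-9)

  ## repetitions = 1 with all reads equals build_spectrum on the full set
  sp_all <- subsampled_spectrum(reads, avg_genome_length = 3000,
                                fold_coverage = 1000, repetitions = 1,
                                seed = 37)
  expect_true(isTRUE(attr(sp_all, "insufficient_reads")))
  full <- build_spectrum(reads)
  expect_equal(sp_all$counts, full$counts)

  ## the worked subsample-size example: fold 3, AGL 50 kb, 450 bp reads
  expect_equal(ceiling(3 * 50000 / 450), 334)
})

test_that("spectrum TSV and star-string round-trips", {
  sp <- structure(list(counts = c(10, 3, 0, 1.5), n_reads_used = 22,
                       params = list(min_identity = 0.98, min_overlap = 35,
                                     fold_coverage = 3, repetitions = 2)),
                  class = "contig_spectrum")
  f <- tempfile(fileext = ".tsv")
  write_spectrum(sp, f)
  back <- read_spectrum(f, n_reads_used = 22)
  expect_equal(back$counts, sp$counts)
  expect_equal(as_star_string(sp), "10*3*0*1.5")
})
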