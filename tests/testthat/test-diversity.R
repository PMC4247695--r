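test_that("rank-abundance forms are normalized and ordered", {
  for (form in c("power", "logarithmic", "exponential", "lognormal",
                 "uniform")) {
    m <- rank_abundance(form, 50, 0.8)
    expect_equal(sum(m$abundances), 1, tolerance = 1e-12)
    expect_true(all(m$abundances > 0))
    expect_true(all(diff(m$abundances) <= 1e-15))
  }
  expect_error(rank_abundance("power", 10, -1), "non-negative")
})

test_that("predicted spectra obey read conservation and closed forms", {
  ## conservation sum(q * E[c_q]) = n across forms (large q_max)
  for (form in c("power", "exponential", "lognormal", "uniform")) {
    m <- rank_abundance(form, 40, 1.1)
    e <- predict_spectrum(m, 800, 100, 35, 50000, q_max = 4000)
    expect_equal(sum(seq_along(e) * e), 800, tolerance = 1e-6)
  }
  ## single species: total contigs = n * exp(-c * sigma)
  m1 <- rank_abundance("uniform", 1)
  e1 <- predict_spectrum(m1, 1000, 100, 35, 100000, q_max = 600)
  cc <- 1000 * 100 / 100000
  expect_equal(sum(e1) + attr(e1, "tail"), 1000 * exp(-cc * 0.65),
               tolerance = 1e-9)
  ## coverage -> 0 limit: all singletons
  e0 <- predict_spectrum(rank_abundance("uniform", 5), 50, 100, 35, 1e8,
                         q_max = 10)
  expect_equal(e0[1], 50, tolerance = 1e-3)
  expect_lt(sum(e0[-1]), 0.01)
  expect_error(predict_spectrum(m1, 100, 30, 35, 1000), "read_length")
})

test_that("fitting recovers self-generated spectra within a factor of two", {
  truth <- rank_abundance("power", 100, 1.13)
  obs <- predict_spectrum(truth, 1000, 100, 35, 100000, q_max = 60)
  f <- fit_spectrum(as.numeric(obs), 100, 35, 100000, n_reads = 1000,
                    s_max = 1e4)
  expect_gte(f$richness, 50)
  expect_lte(f$richness, 200)
  expect_equal(f$evenness, shannon_ev <- {
    H <- -sum(truth$abundances * log(truth$abundances))
    H / log(100)
  }, tolerance = 0.1)

  ## single-genome spectrum pins S = 1 (parsimony at equal fit)
  obs1 <- predict_spectrum(rank_abundance("uniform", 1), 400, 100, 35,
                           20000, q_max = 400)
  f1 <- fit_spectrum(as.numeric(obs1), 100, 35, 20000, n_reads = 400,
                     s_max = 1e3)
  expect_lte(f1$richness, 2)
})

test_that("spectrum_fit methods are coherent", {
  truth <- rank_abundance("power", 50, 1.0)
  obs <- predict_spectrum(truth, 500, 100, 35, 50000, q_max = 40)
  f <- fit_spectrum(as.numeric(obs), 100, 35, 50000, n_reads = 500,
                    s_max = 1e3)
  expect_s3_class(f, "spectrum_fit")
  expect_named(coef(f), c("S", "param", "evenness"))
  expect_equal(length(fitted(f)), length(f$observed))
  expect_equal(residuals(f), f$observed - fitted(f))
  expect_output(print(f), "richness")
  expect_output(print(summary(f)), "S = ")
  sims <- simulate(f, nsim = 2, seed = 41)
  expect_length(sims, 2)
  expect_equal(sum(seq_along(sims[[1]]) * sims[[1]]), f$n_reads)
  pdf(NULL); on.exit(dev.off())
  expect_no_error(suppressWarnings(plot(f)))
})

test_that("frequency-count richness embodies one-contig-one-genome", {
  expect_equal(frequency_count_richness(c(5, 2, 3))$richness, 16.25)
  expect_equal(frequency_count_richness(c(0, 4, 2))$richness, 6)
  ## c2 = 0 falls back to the bias-corrected form
  expect_equal(frequency_count_richness(c(5, 0))$richness, 5 + 5 * 4 / 2)
  expect_error(frequency_count_richness(numeric(0)), "empty")
})

test_that("greedy clustering richness: identity, monotonicity, oracle", {
  reads <- rep(strrep("ACGT", 25), 5)
  expect_true(all(clustering_richness(reads) == 1))

  set.seed(42)
  g <- random_genome(800)
  comm <- community_profile(c(g1 = g), 1)
  rr <- simulate_reads(platform_profile("ft", read_length = 70,
                                        paired = FALSE,
                                        substitution_rate_start = 0.01,
                                        substitution_rate_end = 0.01,
                                        indel_rate = 0),
                       comm, 60, seed = 43)$sequence
  cl <- clustering_richness(rr)
  expect_true(all(diff(cl) <= 0))  # relaxing the threshold merges clusters
  cle <- clustering_richness(rr, method = "exhaustive")
  expect_identical(cl, cle)
})

test_that("genome-length correction divides by (AGL - ARL)", {
  gc <- genome_length_correction(5000, 50000, 450)
  expect_equal(gc$corrected, 5000 / 49550)
  expect_equal(genome_length_correction(0, 50000, 450)$corrected, 0)
  ## halving the divisor doubles the corrected value
  a <- genome_length_correction(100, 10450, 450)$corrected
  b <- genome_length_correction(100, 5450, 450)$corrected
  expect_equal(b / a, 2, tolerance = 1e-12)
  expect_error(genome_length_correction(10, 400, 450), "exceed")
})
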