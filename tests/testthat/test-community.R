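test_that("power-law abundances hit the printed anchors and normalize", {
  ## equal-abundance limit
  p <- power_law_abundances(4, 0.25)
  expect_equal(as.numeric(p), rep(0.25, 4))
  expect_equal(attr(p, "b"), 0)

  ## closed form for S = 2: 0.8 * 2^(-b) = 0.2 => b = 2
  p2 <- power_law_abundances(2, 0.8)
  expect_equal(as.numeric(p2), c(0.8, 0.2), tolerance = 1e-9)
  expect_equal(attr(p2, "b"), 2, tolerance = 1e-6)

  ## b for S = 100, top 0.25, frozen from a bisection oracle on the
  ## partial sum sum_{r<=100} 0.25 r^(-b) = 1
  p3 <- power_law_abundances(100, 0.25)
  expect_equal(attr(p3, "b"), 1.137724, tolerance = 1e-4)
  expect_equal(sum(p3), 1, tolerance = 1e-9)
  expect_true(all(diff(as.numeric(p3)) <= 0))

  expect_error(power_law_abundances(50, 0.01), "infeasible")
})

test_that("sibling evolution: identity at alpha 0, monotone ANI, determinism", {
  set.seed(1)
  g <- random_genome(4000)

  sib0 <- evolve_siblings(g, 5, alpha = 0, seed = 7)
  expect_true(all(sib0 == g))
  expect_equal(unname(pairwise_ani(setNames(sib0, paste0("s", 1:5)))[1, 2]), 1)

  ## mean pairwise ANI non-increasing in alpha over a few seeds
  alphas <- c(0, 0.0025, 0.01, 0.05)
  for (seed in 1:3) {
    anis <- vapply(alphas, function(a) {
      s <- evolve_siblings(g, 6, alpha = a, seed = seed)
      mean_pairwise_ani(pairwise_ani(setNames(s, paste0("s", 1:6))))
    }, numeric(1))
    expect_true(all(diff(anis) <= 1e-12))
  }

  ## byte-identical FASTA for identical seeds
  f1 <- tempfile(fileext = ".fasta"); f2 <- tempfile(fileext = ".fasta")
  write_fasta(setNames(evolve_siblings(g, 4, 0.01, seed = 99),
                       paste0("s", 1:4)), f1)
  write_fasta(setNames(evolve_siblings(g, 4, 0.01, seed = 99),
                       paste0("s", 1:4)), f2)
  expect_identical(readLines(f1), readLines(f2))

  expect_error(evolve_siblings(g, 3, alpha = 1.5), "alpha")
  expect_error(evolve_siblings("", 3, alpha = 0.01), "non-empty")
})

test_that("pairwise ANI counts mismatches positionally", {
  m <- pairwise_ani(c(a = "AAAA", b = "AAAT"))
  expect_equal(m["a", "b"], 0.75)
  expect_equal(diag(m), c(a = 1, b = 1))
  ## 10 siblings -> choose(10, 2) unique off-diagonal pairs
  set.seed(2)
  sibs <- setNames(evolve_siblings(random_genome(1000), 10, 0.01),
                   paste0("s", 1:10))
  m10 <- pairwise_ani(sibs)
  expect_equal(sum(upper.tri(m10)), choose(10, 2))
  expect_true(isSymmetric(m10))
})

test_that("the evolved mock design has the printed structure", {
  src <- simulate_source_genomes(length_range = c(3000, 8000), seed = 5)
  comm <- build_evolved_community(src, seed = 6)
  g <- comm$genomes

  expect_equal(nrow(g), 300)
  expect_equal(length(unique(g$family)), 6)
  ## 40 evolved + 10 unmodified per family
  tab <- table(g$family, g$is_evolved)
  expect_true(all(tab[, "TRUE"] == 40))
  expect_true(all(tab[, "FALSE"] == 10))
  ## sibling groups: per family 2 pairs + 2 octets at each rate
  grp <- comm$groups
  expect_equal(nrow(grp), 6 * 8)
  cnt <- table(grp$family, grp$alpha, grp$size)
  expect_true(all(cnt == 2))

  ## families share total abundance equally; profile sums to 1
  fam_ab <- tapply(g$abundance, g$family, sum)
  expect_equal(as.numeric(fam_ab), rep(1 / 6, 6), tolerance = 1e-9)
  expect_equal(sum(g$abundance), 1, tolerance = 1e-9)

  ## within each family, every 5th ranked genome is unmodified
  for (fam in unique(g$family)) {
    fg <- g[g$family == fam, ]
    fg <- fg[order(-fg$abundance), ]
    expect_true(all(!fg$is_evolved[seq(5, 50, by = 5)]))
    expect_true(all(fg$is_evolved[setdiff(1:50, seq(5, 50, by = 5))]))
  }

  expect_error(build_evolved_community(src[1:5]), "6 families")
})

test_that("benchmark communities sample without replacement per structure", {
  set.seed(3)
  pool <- setNames(vapply(rep(2000, 60), random_genome, character(1)),
                   paste0("p", 1:60))
  comms <- build_benchmark_communities(pool, richness_levels = c(10, 50),
                                       top_abundances = c(0.1, 0.25),
                                       replicates = 2, seed = 4)
  expect_length(comms, 8)
  for (cm in comms) {
    S <- attr(cm, "richness")
    expect_equal(nrow(cm$genomes), S)
    expect_equal(anyDuplicated(cm$genomes$genome_id), 0)
    expect_equal(cm$genomes$abundance[1], attr(cm, "top_abundance"),
                 tolerance = 1e-9)
    expect_equal(sum(cm$genomes$abundance), 1, tolerance = 1e-9)
  }
  expect_error(
    build_benchmark_communities(pool[1:5], richness_levels = 10,
                                top_abundances = 0.25, replicates = 1),
    "pool")
})
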