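## Independent brute-force oracles used across the suite. These deliberately
## avoid the package's own code paths (interval unions, k-mer indexes,
## geometric-series formulas) so agreement is informative.

## per-base boolean-array coverage of 0-based half-open spans
oracle_covered_bases <- function(genome_length, start0, end0) {
  covered <- logical(genome_length)
  for (k in seq_along(start0)) {
    if (end0[k] > start0[k])
      covered[(start0[k] + 1L):end0[k]] <- TRUE
  }
  sum(covered)
}

## N50 by explicit cumulative scan
oracle_n50 <- function(lengths) {
  s <- sort(lengths, decreasing = TRUE)
  half <- sum(s) / 2
  tot <- 0
  for (x in s) {
    tot <- tot + x
    if (tot >= half) return(x)
  }
}

## Shannon entropy computed term by term
oracle_entropy <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  acc <- 0
  for (pi in p) acc <- acc - pi * log(pi)
  acc
}

## longest repeated substring by exhaustive enumeration (small inputs only)
oracle_longest_repeat <- function(genome) {
  L <- nchar(genome)
  best <- 0L
  for (len in seq_len(L - 1L)) {
    starts <- seq_len(L - len + 1L)
    subs <- substring(genome, starts, starts + len - 1L)
    if (anyDuplicated(subs)) best <- len
  }
  best
}

## Monte-Carlo read tiling: n reads placed uniformly on one genome, chained
## into islands when consecutive starts are within read_length - min_overlap.
## Returns the island-size spectrum. Written independently of the package's
## simulate() method.
oracle_tiling_spectrum <- function(n, read_length, min_overlap,
                                   genome_length) {
  starts <- sort(runif(n, 0, genome_length - read_length))
  sizes <- integer(0)
  cur <- 1L
  if (n > 1) for (i in 2:n) {
    if (starts[i] - starts[i - 1] > read_length - min_overlap) {
      sizes <- c(sizes, cur); cur <- 1L
    } else cur <- cur + 1L
  }
  sizes <- c(sizes, cur)
  tabulate(sizes)
}

## all-pairs single-linkage clustering sizes under a pair predicate
oracle_single_linkage_sizes <- function(n, link) {
  labels <- seq_len(n)
  if (n > 1) for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (link(i, j) && labels[i] != labels[j]) {
      old <- labels[j]
      labels[labels == old] <- labels[i]
    }
  }
  as.integer(table(labels))
}

## random alignment-record fixture on small genomes, with ground truth
## easily recomputable per-base
random_alignment_fixture <- function(n_genomes = 3, n_contigs = 6,
                                     genome_length = 2000) {
  recs <- NULL
  for (ci in seq_len(n_contigs)) {
    gi <- sample.int(n_genomes, 1)
    clen <- sample(300:900, 1)
    n_aln <- sample(1:3, 1)
    for (a in seq_len(n_aln)) {
      alen <- sample(80:min(clen, 600), 1)
      gstart <- sample.int(genome_length - alen, 1) - 1L
      cstart <- sample.int(clen - alen + 1L, 1) - 1L
      recs <- rbind(recs, alignment_records(
        contig_id = paste0("c", ci), genome_id = paste0("g", gi),
        contig_start = cstart, contig_end = cstart + alen,
        genome_start = gstart, genome_end = gstart + alen,
        identity = round(runif(1, 0.9, 1), 4),
        contig_length = clen, genome_length = genome_length))
    }
  }
  recs
}
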