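## Assembly scoring against reference genomes: filtering rules, contig
## statistics, genome coverage, contig accuracy, chimericity, coverage by
## others, PCoA of sibling similarity, repeat scan.
##
## Coordinate convention: alignment records are 0-based half-open
## internally; nucmer-style coords files are 1-based inclusive and are
## converted exactly on read/write.

#' Filter contigs by length
#'
#' @param contigs Named character vector of contig sequences.
#' @param min_length Minimum length kept (inclusive; default 500 bp).
#' @return The retained contigs.
#' @export
filter_contigs <- function(contigs, min_length = 500) {
  contigs[nchar(contigs) >= min_length]
}

#' Construct alignment records
#'
#' Builds the internal alignment table (0-based half-open spans).
#'
#' @param contig_id,genome_id Identifier vectors.
#' @param contig_start,contig_end 0-based half-open span on the contig.
#' @param genome_start,genome_end 0-based half-open span on the genome.
#' @param identity Alignment identity as a fraction in \[0, 1\].
#' @param contig_length,genome_length Full sequence lengths.
#' @param score Alignment score; defaults to `identity * aligned_length`.
#' @return data.frame of alignment records with an `aligned_length` column
#'   (genome-span length).
#' @export
alignment_records <- function(contig_id, genome_id, contig_start, contig_end,
                              genome_start, genome_end, identity,
                              contig_length, genome_length, score = NULL) {
  stopifnot(all(identity >= 0 & identity <= 1),
            all(genome_end > genome_start), all(contig_end > contig_start),
            all(genome_end <= genome_length), all(contig_end <= contig_length))
  aligned_length <- genome_end - genome_start
  if (is.null(score)) score <- identity * aligned_length
  data.frame(contig_id = contig_id, genome_id = genome_id,
             contig_start = contig_start, contig_end = contig_end,
             genome_start = genome_start, genome_end = genome_end,
             identity = identity, aligned_length = aligned_length,
             score = score, contig_length = contig_length,
             genome_length = genome_length, stringsAsFactors = FALSE)
}

#' Filter alignment records
#'
#' Drops alignments below the identity/length thresholds (both inclusive),
#' then, per contig, retains only its alignments to the best-scoring genome
#' (the genome holding the contig's top-scoring alignment; ties broken by
#' lexicographic genome id). Keeping all alignments to that genome lets
#' coverage use split alignments, while accuracy later uses the single best.
#'
#' @param records Alignment data.frame from [alignment_records()] or
#'   [read_coords()].
#' @param min_identity Minimum identity fraction (default 0.95).
#' @param min_length Minimum alignment length in bp (default 100).
#' @return Filtered alignment data.frame.
#' @export
filter_alignments <- function(records, min_identity = 0.95,
                              min_length = 100) {
  keep <- records$identity >= min_identity &
    records$aligned_length >= min_length
  rec <- records[keep, , drop = FALSE]
  if (!nrow(rec)) return(rec)
  best <- do.call(rbind, lapply(split(rec, rec$contig_id), function(d) {
    ord <- order(-d$score, d$genome_id)
    d[d$genome_id == d$genome_id[ord[1]], , drop = FALSE]
  }))
  rownames(best) <- NULL
  best
}

#' Contig length statistics
#'
#' @param lengths Positive integer vector of contig lengths.
#' @return List with `count`, `sum`, `mean`, `max`, `n50`. For an empty
#'   input, `count` is 0 and the remaining entries are `NA`.
#' @export
contig_stats <- function(lengths) {
  if (!length(lengths))
    return(list(count = 0L, sum = NA_real_, mean = NA_real_,
                max = NA_real_, n50 = NA_real_))
  stopifnot(all(lengths > 0))
  s <- sort(lengths, decreasing = TRUE)
  n50 <- s[which(cumsum(s) >= sum(s) / 2)[1]]
  list(count = length(lengths), sum = sum(lengths), mean = mean(lengths),
       max = max(lengths), n50 = n50)
}

## total bases covered by the union of 0-based half-open spans
span_union <- function(start0, end0) {
  if (!length(start0)) return(0L)
  sum(IRanges::width(IRanges::reduce(
    IRanges::IRanges(start = start0 + 1L, end = end0))))
}

#' Genome coverage by contigs
#'
#' Overall contig coverage is the percentage of the genome covered by the
#' union of all its (filtered) alignments; maximum contig coverage is the
#' percentage covered by the single longest aligning contig (ties broken by
#' greater aligned length, then lexicographic contig id).
#'
#' @param genome_length Genome length in bp.
#' @param records Filtered alignment records for this genome.
#' @return List with `overall` and `max_contig` (percentages), and
#'   `longest_contig` (its id, or `NA` if no alignments).
#' @export
genome_coverage <- function(genome_length, records) {
  stopifnot(genome_length > 0)
  if (is.null(records) || !nrow(records))
    return(list(overall = 0, max_contig = 0, longest_contig = NA_character_))
  overall <- 100 * span_union(records$genome_start, records$genome_end) /
    genome_length
  per <- split(records, records$contig_id)
  clen <- vapply(per, function(d) d$contig_length[1], numeric(1))
  alen <- vapply(per, function(d) sum(d$aligned_length), numeric(1))
  ord <- order(-clen, -alen, names(per))
  top <- per[[ord[1]]]
  maxc <- 100 * span_union(top$genome_start, top$genome_end) / genome_length
  list(overall = overall, max_contig = maxc,
       longest_contig = names(per)[ord[1]])
}

#' Contig accuracy score
#'
#' Identity of the best local alignment multiplied by the fraction of the
#' contig covered by that alignment, as a percentage (capped at 100).
#'
#' @param records Filtered alignment records of one contig (the top-scoring
#'   one is used), or `NULL`/empty for an unaligned contig.
#' @param contig_length Contig length in bp.
#' @return List with `accuracy` (percent) and `aligned` (logical flag;
#'   unaligned contigs score 0).
#' @export
contig_accuracy <- function(records, contig_length) {
  stopifnot(contig_length > 0)
  if (is.null(records) || !nrow(records))
    return(list(accuracy = 0, aligned = FALSE))
  b <- records[order(-records$score, records$genome_id), , drop = FALSE][1, ]
  frac <- (b$contig_end - b$contig_start) / contig_length
  list(accuracy = min(100, 100 * b$identity * frac), aligned = TRUE)
}

#' Chimericity: entropy of read origins within a contig
#'
#' Shannon entropy (natural log) of the proportions of mapped reads arising
#' from each source genome; 0 when a single genome contributed.
#'
#' @param origin_counts Non-negative numeric vector of read counts per
#'   source genome.
#' @return Entropy in nats; `NA` (flagged by a warning-free convention) for
#'   an all-zero count vector.
#' @export
chimericity <- function(origin_counts) {
  stopifnot(all(origin_counts >= 0))
  tot <- sum(origin_counts)
  if (tot == 0) return(NA_real_)
  p <- origin_counts[origin_counts > 0] / tot
  ## adding zero normalizes IEEE negative zero from the single-origin case
  -sum(p * log(p)) + 0
}

#' Coverage by others
#'
#' Foreign reads mapping to a genome, normalized by genome length:
#' `CbO = max(0, mapped - own) / genome_length`. With the genome's own
#' coverage on the same normalization (`C = own / genome_length`), the
#' ratio `CbO / C` equals foreign over own reads and gauges cross-genome
#' assembly interference.
#'
#' @param mapped Total reads mapping to the genome (all above-threshold
#'   hits).
#' @param own Reads truly originating from the genome.
#' @param genome_length Genome length in bp.
#' @return List with `cbo`, `coverage` (both per-bp read counts) and
#'   `ratio` (`NA` when `own` is 0, flagged via `defined = FALSE`).
#' @export
coverage_by_others <- function(mapped, own, genome_length) {
  stopifnot(mapped >= 0, own >= 0, genome_length > 0)
  cbo <- max(0, mapped - own) / genome_length
  cc <- own / genome_length
  if (own == 0)
    return(list(cbo = cbo, coverage = cc, ratio = NA_real_, defined = FALSE))
  list(cbo = cbo, coverage = cc, ratio = cbo / cc, defined = TRUE)
}

#' Principal coordinate analysis of a similarity matrix
#'
#' Classical metric scaling of `d = 1 - similarity`: double-centering and
#' eigendecomposition via [stats::cmdscale()]. Coordinates are ordered by
#' eigenvalue; because classical scaling centres the configuration, the
#' member nearest the centroid is the row with the smallest coordinate norm.
#'
#' @param similarity Square symmetric matrix with unit diagonal (e.g. from
#'   [pairwise_ani()]).
#' @param k Number of coordinates (default `n - 1`).
#' @return List with `points` (n x k matrix), `eig` (eigenvalues) and
#'   `medoid` (id of the centroid-nearest member).
#' @export
pcoa_similarity <- function(similarity, k = nrow(similarity) - 1) {
  if (!is.matrix(similarity) || nrow(similarity) != ncol(similarity) ||
      !isTRUE(all.equal(similarity, t(similarity), tolerance = 1e-12)))
    stop("`similarity` must be a square symmetric matrix")
  if (any(abs(diag(similarity) - 1) > 1e-9))
    stop("`similarity` must have a unit diagonal")
  d <- stats::as.dist(1 - similarity)
  k <- max(1, k)
  fit <- stats::cmdscale(d, k = k, eig = TRUE)
  pts <- fit$points
  ## degenerate configurations (e.g. all-identical members) can come back
  ## with fewer coordinate axes than requested; pad with zeros
  if (ncol(pts) < k) {
    pad <- matrix(0, nrow(similarity), k - ncol(pts))
    pts <- cbind(pts, pad)
  }
  if (is.null(rownames(pts))) rownames(pts) <- rownames(similarity)
  norms <- sqrt(rowSums(pts^2))
  list(points = pts, eig = fit$eig,
       medoid = rownames(similarity)[which.min(norms)])
}

#' Longest exact repeat within a genome
#'
#' Length of the longest substring occurring at two or more distinct start
#' positions (overlapping occurrences allowed). Found by binary search on
#' the span length with a hashed duplicate-substring check; the property
#' "a repeat of length L implies one of length L - 1" makes the predicate
#' monotone, so the result is exact.
#'
#' @param genome Genome sequence (single string).
#' @return Length in bp of the longest repeated span (0 if none).
#' @export
longest_repeat <- function(genome) {
  L <- nchar(genome)
  if (L < 2) return(0L)
  has_repeat <- function(len) {
    starts <- seq_len(L - len + 1L)
    anyDuplicated(substring(genome, starts, starts + len - 1L)) > 0L
  }
  if (!has_repeat(1L)) return(0L)
  lo <- 1L; hi <- L - 1L
  while (lo < hi) {
    mid <- (lo + hi + 1L) %/% 2L
    if (has_repeat(mid)) lo <- mid else hi <- mid - 1L
  }
  lo
}

#' Paired two-sided Wilcoxon signed-rank comparison
#'
#' Used to compare per-genome reconstruction metrics between two
#' platform/assembler/depth combinations. Identical vectors (all zero
#' differences) are reported as p = 1 (no evidence of a difference).
#'
#' @param x,y Paired metric vectors.
#' @return List with `p_value` and `statistic`.
#' @export
compare_paired <- function(x, y) {
  stopifnot(length(x) == length(y))
  d <- x - y
  if (all(d == 0)) return(list(p_value = 1, statistic = 0))
  wt <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                            alternative = "two.sided"))
  list(p_value = wt$p.value, statistic = unname(wt$statistic))
}

#' Per-genome reconstruction report
#'
#' Combines contig-to-genome alignments with read-to-genome mapping counts
#' into the per-genome metric table: overall and maximum contig coverage,
#' fold coverage by own reads, coverage-by-others and its ratio to own
#' coverage, with summary counts of genomes reaching 95% and 50% maximum
#' contig coverage. Genomes shorter than `min_genome_length` are excluded
#' (short circular genomes interact with the alignment thresholds).
#'
#' @param community A [community_profile()].
#' @param alignments Filtered alignment records ([filter_alignments()]).
#' @param read_genome_map Optional data.frame (`read_id`, `genome_id`) of
#'   all above-threshold read-to-genome hits.
#' @param reads Optional read data.frame (for ground-truth own-read counts);
#'   required when `read_genome_map` is given.
#' @param min_genome_length Exclusion threshold in nt (default 1700).
#' @return List of class `reconstruction_report` with `per_genome`
#'   (data.frame), `summary` (counts and means) and `by_group` (mean
#'   maximum contig coverage per sibling group, if the community has
#'   groups).
#' @export
reconstruction_report <- function(community, alignments,
                                  read_genome_map = NULL, reads = NULL,
                                  min_genome_length = 1700) {
  g <- community$genomes
  g <- g[g$length >= min_genome_length, , drop = FALSE]
  aln_by_genome <- if (nrow(alignments))
    split(alignments, alignments$genome_id) else list()
  rows <- lapply(seq_len(nrow(g)), function(i) {
    gid <- g$genome_id[i]
    cov <- genome_coverage(g$length[i], aln_by_genome[[gid]])
    row <- data.frame(genome_id = gid, length = g$length[i],
                      abundance = g$abundance[i],
                      overall_coverage = cov$overall,
                      max_contig_coverage = cov$max_contig,
                      longest_contig = cov$longest_contig,
                      stringsAsFactors = FALSE)
    if (!is.null(read_genome_map)) {
      mapped <- sum(read_genome_map$genome_id == gid)
      own <- sum(reads$true_source == gid)
      cb <- coverage_by_others(mapped, own, g$length[i])
      row$fold_coverage <- fold_coverage(reads, gid, g$length[i])
      row$cbo <- cb$cbo
      row$cbo_ratio <- cb$ratio
    }
    row
  })
  per <- do.call(rbind, rows)
  per$ge95 <- per$max_contig_coverage >= 95
  per$ge50 <- per$max_contig_coverage >= 50
  smry <- list(n_genomes = nrow(per),
               n_max_ge95 = sum(per$ge95), n_max_ge50 = sum(per$ge50),
               mean_overall = mean(per$overall_coverage),
               mean_max_contig = mean(per$max_contig_coverage))
  by_group <- NULL
  if (!is.null(community$groups) && !is.null(g$group_id)) {
    memb <- g$group_id[match(per$genome_id, g$genome_id)]
    keep <- !is.na(memb)
    if (any(keep)) {
      agg <- stats::aggregate(per$max_contig_coverage[keep],
                              by = list(group_id = memb[keep]), FUN = mean)
      names(agg)[2] <- "mean_max_contig_coverage"
      by_group <- merge(community$groups, agg, by = "group_id")
    }
  }
  structure(list(per_genome = per, summary = smry, by_group = by_group),
            class = "reconstruction_report")
}

#' @export
print.reconstruction_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "Reconstruction report: %d genomes; mean overall %.1f%%, mean max %.1f%%\n",
    s$n_genomes, s$mean_overall, s$mean_max_contig))
  cat(sprintf("  max contig coverage >= 95%%: %d genomes; >= 50%%: %d genomes\n",
              s$n_max_ge95, s$n_max_ge50))
  invisible(x)
}
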