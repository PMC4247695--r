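## Contig spectra: greedy single-linkage clustering of reads under an
## ungapped overlap criterion, with coverage-limited subsampling. The q-th
## spectrum entry counts clusters ("contigs") containing exactly q reads.

## Check one ungapped offset: does placing b at offset s relative to a
## (b[1] against a[1+s]) give an overlap >= min_overlap at identity >=
## min_identity? ra/rb are raw vectors.
verify_offset <- function(ra, rb, s, min_overlap, min_identity) {
  na <- length(ra); nb <- length(rb)
  i1 <- max(1L, s + 1L); i2 <- min(na, s + nb)
  len <- i2 - i1 + 1L
  if (len < min_overlap) return(FALSE)
  j1 <- i1 - s
  matches <- sum(ra[i1:i2] == rb[j1:(j1 + len - 1L)])
  matches / len >= min_identity
}

## cached scoring matrix for gapped overlap alignments
.vm_cache <- new.env(parent = emptyenv())
nuc_submat <- function() {
  if (is.null(.vm_cache$submat))
    .vm_cache$submat <- Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -2, baseOnly = TRUE)
  .vm_cache$submat
}

## Gapped overlap acceptance: best ends-free overlap alignment; identity is
## matches over alignment columns (gap columns count as errors). A cheap
## shared 11-mer prescreen rejects clearly unrelated pairs first, keeping
## exhaustive all-pairs scans affordable.
gapped_overlap_ok <- function(a, b, min_overlap, min_identity) {
  if (min(nchar(a), nchar(b)) < min_overlap) return(FALSE)
  ca <- kmer_codes(a, 11L)
  cb <- kmer_codes(b, 11L)
  if (!length(ca) || !length(cb) || !any(cb %in% ca)) return(FALSE)
  pa <- Biostrings::pairwiseAlignment(a, b, type = "overlap",
                                      substitutionMatrix = nuc_submat(),
                                      gapOpening = 3, gapExtension = 2)
  nm <- Biostrings::nmatch(pa)
  nmm <- Biostrings::nmismatch(pa)
  ind <- Biostrings::nindel(pa)
  gapw <- Biostrings::insertion(ind)[1, "WidthSum"] +
    Biostrings::deletion(ind)[1, "WidthSum"]
  len <- nm + nmm + gapw
  len >= min_overlap && nm / len >= min_identity
}

#' Overlap detection between two reads
#'
#' Scans every end-to-end ungapped offset in both orientations and reports
#' whether any yields an overlap of at least `min_overlap` bp with identity
#' at least `min_identity` over the overlap (both thresholds inclusive).
#' With `gapped = TRUE`, pairs failing the ungapped scan are additionally
#' tested with an ends-free overlap alignment that tolerates indels (gap
#' columns count as identity errors), mirroring how overlap assemblers
#' align through indel-type sequencing errors.
#'
#' @param read_a,read_b Read sequences (single strings).
#' @param min_overlap Minimum overlap length in bp (default 35).
#' @param min_identity Minimum identity over the overlap (default 0.98).
#' @param both_strands Also test `read_b`'s reverse complement (default
#'   `TRUE`).
#' @param gapped Allow indel-tolerant overlaps (default `FALSE`).
#' @return Logical.
#' @export
detect_overlap <- function(read_a, read_b, min_overlap = 35,
                           min_identity = 0.98, both_strands = TRUE,
                           gapped = FALSE) {
  stopifnot(nchar(read_a) > 0, nchar(read_b) > 0)
  ra <- charToRaw(read_a)
  orientations <- list(read_b)
  if (both_strands) orientations <- c(orientations, list(revcomp(read_b)))
  for (ob in orientations) {
    rb <- charToRaw(ob)
    na <- length(ra); nb <- length(rb)
    if (min(na, nb) < min_overlap) next
    for (s in seq.int(-(nb - min_overlap), na - min_overlap)) {
      if (verify_offset(ra, rb, s, min_overlap, min_identity)) return(TRUE)
    }
    if (gapped && gapped_overlap_ok(read_a, ob, min_overlap, min_identity))
      return(TRUE)
  }
  FALSE
}

## union-find root lookup (no path compression; cluster counts are small)
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

## Integer k-mer codes (base-4 Horner over a sliding window); k <= 15 keeps
## codes inside the integer range. Much faster to group than string k-mers.
kmer_codes <- function(s, k) {
  b <- match(seq_chars(s), DNA_BASES) - 1L
  L <- length(b)
  if (L < k || anyNA(b)) return(integer(0))
  n <- L - k + 1L
  code <- numeric(n)
  for (j in seq_len(k)) code <- code * 4 + b[j:(j + n - 1L)]
  as.integer(code)
}

## candidate (i, j, rc, offset) tuples from shared k-mers; each read is
## indexed in both orientations, pairs are canonicalized so the first
## member is always taken forward.
overlap_candidates <- function(seqs, rc_seqs, k, bucket_cap = 200L) {
  stopifnot(k <= 15L)
  per <- lapply(seq_along(seqs), function(i) {
    cf <- kmer_codes(seqs[i], k)
    cr <- kmer_codes(rc_seqs[i], k)
    list(code = c(cf, cr),
         read = rep.int(i, length(cf) + length(cr)),
         pos = c(seq_along(cf), seq_along(cr)),
         strand = rep.int(c(0L, 1L), c(length(cf), length(cr))))
  })
  code <- unlist(lapply(per, `[[`, "code"), use.names = FALSE)
  if (!length(code)) return(NULL)
  read <- unlist(lapply(per, `[[`, "read"), use.names = FALSE)
  pos <- unlist(lapply(per, `[[`, "pos"), use.names = FALSE)
  strand <- unlist(lapply(per, `[[`, "strand"), use.names = FALSE)
  ord <- order(code, method = "radix")
  code <- code[ord]; read <- read[ord]; pos <- pos[ord]
  strand <- strand[ord]
  runs <- rle(code)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  multi <- which(runs$lengths > 1L & runs$lengths <= bucket_cap)
  cand <- vector("list", length(multi))
  ci <- 0L
  for (bi in multi) {
    rows <- starts[bi]:ends[bi]
    plus <- rows[strand[rows] == 0L]
    minus <- rows[strand[rows] == 1L]
    np <- length(plus)
    pieces <- NULL
    if (np > 1L) {
      u <- rep.int(plus[-np], (np - 1L):1L)
      v <- plus[sequence((np - 1L):1L, from = 2:np)]
      keep <- read[u] != read[v]
      if (any(keep)) {
        u <- u[keep]; v <- v[keep]
        swap <- read[u] > read[v]
        a <- ifelse(swap, v, u); b <- ifelse(swap, u, v)
        pieces <- cbind(read[a], read[b], 0L, pos[a] - pos[b])
      }
    }
    if (np && length(minus)) {
      u <- rep(plus, each = length(minus))
      v <- rep(minus, times = np)
      keep <- read[u] != read[v]
      if (any(keep))
        pieces <- rbind(pieces, cbind(read[u[keep]], read[v[keep]], 1L,
                                      pos[u[keep]] - pos[v[keep]]))
    }
    if (!is.null(pieces)) { ci <- ci + 1L; cand[[ci]] <- pieces }
  }
  if (ci == 0L) return(NULL)
  m <- unique(do.call(rbind, cand[seq_len(ci)]))
  colnames(m) <- c("i", "j", "rc", "offset")
  m
}

#' Build a contig spectrum from reads
#'
#' Single-linkage clustering: reads joined whenever [detect_overlap()]
#' accepts some pair member; `c_q` counts clusters of exactly q reads.
#' The default method indexes shared k-mers to propose (pair, orientation,
#' offset) candidates and verifies each against the same ungapped criterion,
#' so it agrees with the exhaustive all-offsets scan whenever qualifying
#' overlaps contain a clean shared k-mer; `method = "exhaustive"` scans all
#' pairs and offsets (quadratic, for testing).
#'
#' @param reads Character vector of read sequences, or a data.frame with a
#'   `sequence` column.
#' @param min_overlap Minimum overlap in bp (default 35).
#' @param min_identity Minimum identity over the overlap (default 0.98).
#' @param method `"index"` (default) or `"exhaustive"`.
#' @param kmer k-mer size for candidate pairing (default 14).
#' @param gapped Allow indel-tolerant overlaps (default `TRUE`; see
#'   [detect_overlap()]). Candidate pairs that fail every ungapped offset
#'   are re-tested with the gapped criterion.
#' @return Object of class `contig_spectrum`: list with `counts` (numeric
#'   vector, `counts[q]` = clusters of size q), `n_reads_used`, `params`,
#'   and `membership` (cluster id per read).
#' @export
build_spectrum <- function(reads, min_overlap = 35, min_identity = 0.98,
                           method = c("index", "exhaustive"), kmer = 14,
                           gapped = TRUE) {
  method <- match.arg(method)
  if (is.data.frame(reads)) reads <- reads$sequence
  n <- length(reads)
  stopifnot(n >= 1)
  raws <- lapply(reads, charToRaw)
  rc_seqs <- revcomp(reads)
  rc_raws <- lapply(rc_seqs, charToRaw)
  parent <- seq_len(n)

  if (method == "exhaustive") {
    if (n > 1) for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
      ri <- uf_find(parent, i); rj <- uf_find(parent, j)
      if (ri == rj) next
      if (detect_overlap(reads[i], reads[j], min_overlap, min_identity,
                         gapped = gapped))
        parent[max(ri, rj)] <- min(ri, rj)
    }
  } else {
    cand <- overlap_candidates(reads, rc_seqs, kmer)
    if (!is.null(cand)) for (r in seq_len(nrow(cand))) {
      i <- cand[r, "i"]; j <- cand[r, "j"]
      ri <- uf_find(parent, i); rj <- uf_find(parent, j)
      if (ri == rj) next
      rb <- if (cand[r, "rc"] == 1L) rc_raws[[j]] else raws[[j]]
      if (verify_offset(raws[[i]], rb, cand[r, "offset"],
                        min_overlap, min_identity))
        parent[max(ri, rj)] <- min(ri, rj)
    }
    ## second pass: candidate pairs still unlinked get the gapped test
    if (gapped && !is.null(cand)) {
      key <- cand[, "i"] * (n + 1) * 2 + cand[, "j"] * 2 + cand[, "rc"]
      first <- !duplicated(key)
      for (r in which(first)) {
        i <- cand[r, "i"]; j <- cand[r, "j"]
        ri <- uf_find(parent, i); rj <- uf_find(parent, j)
        if (ri == rj) next
        ob <- if (cand[r, "rc"] == 1L) rc_seqs[j] else reads[j]
        if (gapped_overlap_ok(reads[i], ob, min_overlap, min_identity))
          parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }

  roots <- vapply(seq_len(n), function(i) uf_find(parent, i), integer(1))
  sizes <- tabulate(match(roots, unique(roots)))
  counts <- tabulate(sizes)
  structure(list(counts = as.numeric(counts), n_reads_used = n,
                 params = list(min_identity = min_identity,
                               min_overlap = min_overlap,
                               fold_coverage = NA_real_, repetitions = 1L),
                 membership = match(roots, unique(roots))),
            class = "contig_spectrum")
}

#' Coverage-limited subsampled contig spectrum
#'
#' Each repetition samples `n_sub = ceiling(fold_coverage *
#' avg_genome_length / mean_read_length)` reads without replacement, builds
#' a spectrum, and the repetition spectra are averaged element-wise (so the
#' averaged counts may be fractional; read conservation
#' `sum(q * c_q) = n_sub` holds per repetition and in the mean).
#'
#' @param reads Character vector of read sequences or data.frame with a
#'   `sequence` column.
#' @param avg_genome_length Mean genome length in the community (bp).
#' @param fold_coverage Target fold coverage of the subsample (default 3).
#' @param repetitions Number of subsampling repetitions (default 10).
#' @param min_overlap,min_identity Overlap criterion (35 bp, 0.98).
#' @param seed Integer seed.
#' @param method Clustering method, see [build_spectrum()].
#' @param gapped Allow indel-tolerant overlaps (default `TRUE`).
#' @return `contig_spectrum` whose `counts` is the mean spectrum; the
#'   per-repetition spectra are kept in `$per_rep` (a matrix). If fewer
#'   reads than `n_sub` are available all reads are used in every
#'   repetition and the result carries `insufficient_reads = TRUE`.
#' @export
subsampled_spectrum <- function(reads, avg_genome_length, fold_coverage = 3,
                                repetitions = 10, min_overlap = 35,
                                min_identity = 0.98, seed = NULL,
                                method = "index", gapped = TRUE) {
  if (is.data.frame(reads)) reads <- reads$sequence
  stopifnot(length(reads) >= 1, avg_genome_length > 0, fold_coverage > 0)
  if (!is.null(seed)) set.seed(seed)
  n_sub <- ceiling(fold_coverage * avg_genome_length / mean(nchar(reads)))
  short <- n_sub > length(reads)
  if (short) n_sub <- length(reads)
  reps <- vector("list", repetitions)
  for (r in seq_len(repetitions)) {
    sub <- if (n_sub == length(reads)) reads else sample(reads, n_sub)
    reps[[r]] <- build_spectrum(sub, min_overlap, min_identity,
                                method = method, gapped = gapped)$counts
  }
  qmax <- max(lengths(reps))
  mat <- vapply(reps, function(v) c(v, rep(0, qmax - length(v))),
                numeric(qmax))
  mat <- matrix(mat, nrow = qmax)
  out <- structure(list(counts = rowMeans(mat), n_reads_used = n_sub,
                        params = list(min_identity = min_identity,
                                      min_overlap = min_overlap,
                                      fold_coverage = fold_coverage,
                                      repetitions = repetitions),
                        per_rep = mat),
                   class = "contig_spectrum")
  if (short) attr(out, "insufficient_reads") <- TRUE
  out
}

#' @export
print.contig_spectrum <- function(x, ...) {
  nz <- which(x$counts > 0)
  cat(sprintf("Contig spectrum from %d reads (%d repetition%s):\n",
              x$n_reads_used, x$params$repetitions,
              if (x$params$repetitions == 1) "" else "s"))
  show <- utils::head(nz, 12)
  cat(paste(sprintf("c%d=%.4g", show, x$counts[show]), collapse = "  "))
  if (length(nz) > 12) cat("  ...")
  cat("\n")
  invisible(x)
}

#' @export
plot.contig_spectrum <- function(x, ...) {
  q <- seq_along(x$counts)
  graphics::plot(q, x$counts, type = "h", lwd = 3,
                 xlab = "reads per contig (q)", ylab = expression(c[q]),
                 main = "Contig spectrum", ...)
  invisible(x)
}

#' Write a contig spectrum as TSV
#'
#' Two columns (`q`, `count`), '#'-prefixed header.
#'
#' @param spectrum A `contig_spectrum`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  df <- data.frame(q = seq_along(spectrum$counts), count = spectrum$counts)
  write_hashed_tsv(df, path)
}

#' Read a contig spectrum TSV
#'
#' @param path Path written by [write_spectrum()].
#' @param n_reads_used Reads per repetition behind the spectrum (recovered
#'   from read conservation if omitted).
#' @return A `contig_spectrum`.
#' @export
read_spectrum <- function(path, n_reads_used = NULL) {
  df <- read_hashed_tsv(path, c(q = "integer", count = "numeric"))
  counts <- numeric(max(df$q))
  counts[df$q] <- df$count
  if (is.null(n_reads_used))
    n_reads_used <- round(sum(seq_along(counts) * counts))
  structure(list(counts = counts, n_reads_used = n_reads_used,
                 params = list(min_identity = NA_real_,
                               min_overlap = NA_integer_,
                               fold_coverage = NA_real_,
                               repetitions = NA_integer_)),
            class = "contig_spectrum")
}

#' Historical star-separated contig-spectrum string
#'
#' @param spectrum A `contig_spectrum`.
#' @return Single string `"c1*c2*...*cQ"`.
#' @export
as_star_string <- function(spectrum) {
  paste(trimws(formatC(spectrum$counts, format = "g", digits = 10)),
        collapse = "*")
}
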