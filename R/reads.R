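## Shotgun read simulation with ground-truth provenance. A parametric
## platform model (read length, pairing, linear substitution-rate ramp,
## homopolymer-style indels) stands in for empirically trained error models.

#' Platform sequencing profile
#'
#' Describes read length, pairing and a simple error model: a per-base
#' substitution probability ramping linearly from `substitution_rate_start`
#' at the 5' end to `substitution_rate_end` at the 3' end, plus a uniform
#' per-base indel probability (insertions duplicate the current base,
#' mimicking homopolymer over/under-calls).
#'
#' @param name Profile name. One of the bundled profiles
#'   (`"454-flx+"`, `"454-ti"`, `"gaiix"`, `"hiseq"`, `"miseq"`) or any
#'   string when the remaining arguments are given explicitly.
#' @param read_length Read length in bp (per mate when paired).
#' @param paired Logical; paired-end reads.
#' @param insert_mean,insert_sd Insert size mean/SD in bp (paired only).
#' @param substitution_rate_start,substitution_rate_end Per-base
#'   substitution probabilities at the two read ends.
#' @param indel_rate Per-base indel probability.
#' @return An object of class `platform_profile`.
#' @export
platform_profile <- function(name,
                             read_length = NULL, paired = NULL,
                             insert_mean = 500, insert_sd = 50,
                             substitution_rate_start = NULL,
                             substitution_rate_end = NULL,
                             indel_rate = NULL) {
  bundled <- list(
    "454-flx+" = list(read_length = 700, paired = FALSE,
                      sub_start = 0.001, sub_end = 0.001, indel = 5e-4),
    "454-ti"   = list(read_length = 450, paired = FALSE,
                      sub_start = 0.001, sub_end = 0.001, indel = 5e-4),
    "gaiix"    = list(read_length = 150, paired = TRUE,
                      sub_start = 0.001, sub_end = 0.01, indel = 0),
    "hiseq"    = list(read_length = 100, paired = TRUE,
                      sub_start = 0.001, sub_end = 0.01, indel = 0),
    "miseq"    = list(read_length = 300, paired = TRUE,
                      sub_start = 0.001, sub_end = 0.01, indel = 0))
  key <- tolower(name)
  if (key %in% names(bundled)) {
    d <- bundled[[key]]
    if (is.null(read_length)) read_length <- d$read_length
    if (is.null(paired)) paired <- d$paired
    if (is.null(substitution_rate_start)) substitution_rate_start <- d$sub_start
    if (is.null(substitution_rate_end)) substitution_rate_end <- d$sub_end
    if (is.null(indel_rate)) indel_rate <- d$indel
  } else if (is.null(read_length) || is.null(paired) ||
             is.null(substitution_rate_start) ||
             is.null(substitution_rate_end) || is.null(indel_rate)) {
    stop("unknown profile name; supply all parameters explicitly")
  }
  stopifnot(read_length >= 1,
            substitution_rate_start >= 0, substitution_rate_start <= 1,
            substitution_rate_end >= 0, substitution_rate_end <= 1,
            indel_rate >= 0, indel_rate <= 1)
  if (paired && insert_mean < 2 * read_length)
    stop("paired profiles require insert_mean >= 2 * read_length")
  structure(list(name = name, read_length = as.integer(read_length),
                 paired = paired,
                 insert_mean = insert_mean, insert_sd = insert_sd,
                 substitution_rate_start = substitution_rate_start,
                 substitution_rate_end = substitution_rate_end,
                 indel_rate = indel_rate),
            class = "platform_profile")
}

#' @export
print.platform_profile <- function(x, ...) {
  cat(sprintf("Platform profile '%s': %d bp %s; sub %.4g-%.4g; indel %.4g\n",
              x$name, x$read_length,
              if (x$paired) sprintf("paired (insert %g +/- %g)",
                                    x$insert_mean, x$insert_sd)
              else "single-end",
              x$substitution_rate_start, x$substitution_rate_end,
              x$indel_rate))
  invisible(x)
}

## apply the error model to one read (character vector of bases)
inject_errors <- function(chars, p_sub, indel_rate) {
  L <- length(chars)
  hit <- stats::runif(L) < p_sub[seq_len(L)]
  if (any(hit)) {
    ## substitute with a uniformly random *different* base
    idx <- which(hit)
    off <- sample.int(3L, length(idx), replace = TRUE)
    cur <- match(chars[idx], DNA_BASES)
    chars[idx] <- DNA_BASES[((cur - 1L + off) %% 4L) + 1L]
  }
  if (indel_rate > 0) {
    ind <- which(stats::runif(L) < indel_rate)
    if (length(ind)) {
      del <- stats::runif(length(ind)) < 0.5
      keep <- rep(1L, L)
      keep[ind[del]] <- 0L          # deletion
      keep[ind[!del]] <- 2L         # insertion: duplicate the base
      chars <- rep(chars, keep)
    }
  }
  chars
}

#' Simulate shotgun reads from a community
#'
#' Draws source genomes multinomially by relative abundance, start positions
#' uniformly, strands with probability 1/2, and injects errors per the
#' platform profile. Genomes are treated as linear: reads never wrap the
#' origin. When a genome is shorter than the profile read length the read is
#' clamped to the genome length. Every record keeps its ground-truth
#' provenance (source genome, 0-based start on the forward strand, strand).
#'
#' @param profile A [platform_profile()].
#' @param community A [community_profile()].
#' @param n_reads Total number of reads (pairs count as two; must be even
#'   for paired profiles).
#' @param seed Integer seed.
#' @return A data.frame with columns `read_id`, `sequence`, `mate`
#'   (0 for single-end, 1/2 for pairs), `true_source`, `true_start`
#'   (0-based), `true_strand` (`+`/`-`).
#' @export
simulate_reads <- function(profile, community, n_reads, seed = NULL) {
  stopifnot(inherits(profile, "platform_profile"),
            inherits(community, "community_profile"), n_reads >= 1)
  if (!is.null(seed)) set.seed(seed)
  g <- community$genomes
  seqs <- community$sequences
  glen <- g$length
  L <- profile$read_length
  ramp <- if (L > 1)
    profile$substitution_rate_start +
      (profile$substitution_rate_end - profile$substitution_rate_start) *
      (seq_len(L) - 1) / (L - 1)
  else profile$substitution_rate_start

  emit_one <- function(src_i, start, strand, rid, mate) {
    start <- as.integer(start)
    len <- min(L, glen[src_i])
    frag <- substr(seqs[[src_i]], start + 1L, start + len)
    if (strand == "-") frag <- revcomp(frag)
    chars <- inject_errors(seq_chars(frag), ramp, profile$indel_rate)
    list(read_id = rid, sequence = paste(chars, collapse = ""),
         mate = mate, true_source = g$genome_id[src_i],
         true_start = start, true_strand = strand)
  }

  recs <- vector("list", n_reads)
  if (!profile$paired) {
    src <- sample.int(nrow(g), n_reads, replace = TRUE, prob = g$abundance)
    for (k in seq_len(n_reads)) {
      i <- src[k]
      len <- min(L, glen[i])
      start <- sample.int(glen[i] - len + 1L, 1L) - 1L
      strand <- if (stats::runif(1) < 0.5) "+" else "-"
      recs[[k]] <- emit_one(i, start, strand, sprintf("read%07d", k), 0L)
    }
  } else {
    if (n_reads %% 2L != 0L) stop("paired profiles need an even n_reads")
    n_pairs <- n_reads %/% 2L
    src <- sample.int(nrow(g), n_pairs, replace = TRUE, prob = g$abundance)
    k <- 0L
    for (p in seq_len(n_pairs)) {
      i <- src[p]
      len <- min(L, glen[i])
      ins <- max(2L * len,
                 as.integer(round(stats::rnorm(1, profile$insert_mean,
                                               profile$insert_sd))))
      ins <- min(ins, glen[i])
      fstart <- sample.int(glen[i] - ins + 1L, 1L) - 1L
      rstart <- fstart + ins - len
      flip <- stats::runif(1) < 0.5  # which mate is on the forward strand
      rid <- sprintf("pair%07d", p)
      if (!flip) {
        recs[[k + 1L]] <- emit_one(i, fstart, "+", rid, 1L)
        recs[[k + 2L]] <- emit_one(i, rstart, "-", rid, 2L)
      } else {
        recs[[k + 1L]] <- emit_one(i, rstart, "-", rid, 1L)
        recs[[k + 2L]] <- emit_one(i, fstart, "+", rid, 2L)
      }
      k <- k + 2L
    }
  }
  out <- data.frame(
    read_id = vapply(recs, `[[`, character(1), "read_id"),
    sequence = vapply(recs, `[[`, character(1), "sequence"),
    mate = vapply(recs, `[[`, integer(1), "mate"),
    true_source = vapply(recs, `[[`, character(1), "true_source"),
    true_start = vapply(recs, `[[`, integer(1), "true_start"),
    true_strand = vapply(recs, `[[`, character(1), "true_strand"),
    stringsAsFactors = FALSE)
  if (any(out$mate > 0L))
    out$read_id <- ifelse(out$mate > 0L,
                          paste0(out$read_id, "/", out$mate), out$read_id)
  out
}

#' Fold coverage of a genome by its own reads
#'
#' Total bases of reads whose true source is the genome, divided by genome
#' length (equivalently, read count times mean read length over length).
#'
#' @param reads Read data.frame from [simulate_reads()].
#' @param genome_id Genome identifier.
#' @param genome_length Genome length in bp.
#' @return Single numeric fold coverage.
#' @export
fold_coverage <- function(reads, genome_id, genome_length) {
  stopifnot(genome_length > 0)
  own <- reads$sequence[reads$true_source == genome_id]
  if (!length(own)) return(0)
  sum(nchar(own)) / genome_length
}

#' Write reads and their provenance
#'
#' Writes reads as FASTA or FASTQ plus a sidecar provenance TSV
#' (`read_id`, `genome_id`, `start`, `strand`).
#'
#' @param reads Read data.frame from [simulate_reads()].
#' @param path Output sequence file path.
#' @param format `"fastq"` (default) or `"fasta"`.
#' @param provenance_path Path for the provenance TSV, or `NULL` to skip.
#' @return `path`, invisibly.
#' @export
write_reads <- function(reads, path, format = c("fastq", "fasta"),
                        provenance_path = NULL) {
  format <- match.arg(format)
  seqs <- stats::setNames(reads$sequence, reads$read_id)
  if (format == "fastq") write_fastq(seqs, path) else write_fasta(seqs, path)
  if (!is.null(provenance_path)) {
    con <- file(provenance_path, "w")
    on.exit(close(con))
    writeLines("#read_id\tgenome_id\tstart\tstrand", con)
    writeLines(sprintf("%s\t%s\t%d\t%s", reads$read_id, reads$true_source,
                       reads$true_start, reads$true_strand), con)
  }
  invisible(path)
}

#' Read a provenance TSV
#'
#' @param path Provenance TSV written by [write_reads()].
#' @return data.frame with `read_id`, `genome_id`, `start`, `strand`.
#' @export
read_provenance <- function(path) {
  read_hashed_tsv(path, c(read_id = "character", genome_id = "character",
                          start = "integer", strand = "character"))
}
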