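## File formats: hashed-header TSVs, nucmer-style coords, minimal SAM,
## community tables and flat key-value configs. All text outputs are UTF-8,
## tab-separated, with header lines beginning '#'.

## Read a TSV whose header line is "#col1\tcol2..."; coltypes is a named
## character vector of column classes, in file order.
read_hashed_tsv <- function(path, coltypes) {
  lines <- readLines(path)
  if (!length(lines)) stop(path, ": empty file")
  if (!startsWith(lines[1], "#"))
    stop(path, ": line 1: expected a '#'-prefixed header")
  header <- strsplit(sub("^#", "", lines[1]), "\t", fixed = TRUE)[[1]]
  if (!identical(header, names(coltypes)))
    stop(path, ": line 1: header is '", paste(header, collapse = ","),
         "', expected '", paste(names(coltypes), collapse = ","), "'")
  body <- lines[-1]
  body <- body[!startsWith(body, "#") & nzchar(body)]
  if (!length(body)) {
    out <- lapply(coltypes, function(cl) vector(cl, 0))
    return(as.data.frame(out, stringsAsFactors = FALSE))
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf != length(coltypes))
  if (length(bad))
    stop(path, ": line ", bad[1] + 1L, ": expected ", length(coltypes),
         " fields, found ", nf[bad[1]])
  out <- lapply(seq_along(coltypes), function(j) {
    v <- vapply(parts, `[[`, character(1), j)
    cl <- coltypes[[j]]
    v[v == "NA"] <- NA_character_
    conv <- switch(cl, character = v,
                   integer = suppressWarnings(as.integer(v)),
                   numeric = suppressWarnings(as.numeric(v)),
                   logical = as.logical(v))
    if (cl != "character") {
      bad <- which(is.na(conv) & !is.na(v))[1]
      if (!is.na(bad))
        stop(path, ": line ", bad + 1L, ": cannot parse '", v[bad],
             "' as ", cl)
    }
    conv
  })
  names(out) <- names(coltypes)
  as.data.frame(out, stringsAsFactors = FALSE)
}

write_hashed_tsv <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(df), collapse = "\t")), con)
  if (nrow(df)) {
    cols <- lapply(df, function(v) {
      if (is.double(v)) trimws(formatC(v, format = "g", digits = 10))
      else as.character(v)
    })
    writeLines(do.call(paste, c(cols, sep = "\t")), con)
  }
  invisible(path)
}

#' Write a community profile as TSV
#'
#' Columns: genome_id, family, group_id, alpha, rank, abundance, length.
#'
#' @param community A [community_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_community_tsv <- function(community, path) {
  g <- community$genomes
  df <- data.frame(genome_id = g$genome_id,
                   family = if (!is.null(g$family)) g$family else NA,
                   group_id = if (!is.null(g$group_id)) g$group_id else NA,
                   alpha = if (!is.null(g$alpha)) g$alpha else NA,
                   rank = g$rank,
                   abundance = formatC(g$abundance, format = "g",
                                       digits = 12),
                   length = g$length, stringsAsFactors = FALSE)
  write_hashed_tsv(df, path)
}

#' Read a community TSV
#'
#' @param path Path written by [write_community_tsv()].
#' @return data.frame of the community table (sequences are carried in
#'   FASTA separately).
#' @export
read_community_tsv <- function(path) {
  read_hashed_tsv(path, c(genome_id = "character", family = "character",
                          group_id = "character", alpha = "numeric",
                          rank = "integer", abundance = "numeric",
                          length = "integer"))
}

## ---- nucmer-style coords -------------------------------------------------

#' Write alignment records as a nucmer-style coords TSV
#'
#' Columns `S1 E1 S2 E2 LEN1 LEN2 PIDY LENR LENQ REF QRY` with 1-based
#' inclusive coordinates; the reference is the genome and the query the
#' contig. The conversion from the internal 0-based half-open model is
#' exact and round-trips bit-identically.
#'
#' @param records Alignment data.frame ([alignment_records()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coords <- function(records, path) {
  df <- data.frame(
    S1 = records$genome_start + 1L, E1 = records$genome_end,
    S2 = records$contig_start + 1L, E2 = records$contig_end,
    LEN1 = records$genome_end - records$genome_start,
    LEN2 = records$contig_end - records$contig_start,
    PIDY = formatC(100 * records$identity, format = "g", digits = 12),
    LENR = records$genome_length, LENQ = records$contig_length,
    REF = records$genome_id, QRY = records$contig_id,
    stringsAsFactors = FALSE)
  write_hashed_tsv(df, path)
}

#' Read a nucmer-style coords TSV
#'
#' @param path Coords file written by [write_coords()] (or converted from
#'   `show-coords -T -l` output with the same column order).
#' @return Alignment data.frame in the internal 0-based half-open model.
#' @export
read_coords <- function(path) {
  df <- read_hashed_tsv(path, c(
    S1 = "integer", E1 = "integer", S2 = "integer", E2 = "integer",
    LEN1 = "integer", LEN2 = "integer", PIDY = "numeric",
    LENR = "integer", LENQ = "integer", REF = "character",
    QRY = "character"))
  ## reverse-strand query alignments have S2 > E2
  cs <- pmin(df$S2, df$E2); ce <- pmax(df$S2, df$E2)
  alignment_records(contig_id = df$QRY, genome_id = df$REF,
                    contig_start = cs - 1L, contig_end = ce,
                    genome_start = df$S1 - 1L, genome_end = df$E1,
                    identity = df$PIDY / 100,
                    contig_length = df$LENQ, genome_length = df$LENR)
}

## ---- minimal SAM ---------------------------------------------------------

#' Read read-to-reference mappings from a SAM file
#'
#' Minimal parser for the fixed SAM columns: keeps mapped, primary,
#' non-supplementary records and returns one row per alignment line.
#'
#' @param path SAM file path.
#' @param best_only If `TRUE` (default), keep a single best hit per read
#'   (highest MAPQ, ties by file order).
#' @return data.frame with `read_id`, `ref_id`, `pos` (0-based), `mapq`.
#' @export
read_sam_map <- function(path, best_only = TRUE) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "@")]
  body <- body[nzchar(body)]
  if (!length(body))
    return(data.frame(read_id = character(0), ref_id = character(0),
                      pos = integer(0), mapq = integer(0)))
  parts <- strsplit(body, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 11L)
  if (length(short))
    stop(path, ": alignment line ", short[1],
         ": fewer than 11 mandatory SAM fields")
  flag <- as.integer(vapply(parts, `[[`, character(1), 2L))
  rname <- vapply(parts, `[[`, character(1), 3L)
  keep <- rname != "*" & bitwAnd(flag, 0x4L) == 0L &
    bitwAnd(flag, 0x100L) == 0L & bitwAnd(flag, 0x800L) == 0L
  df <- data.frame(
    read_id = vapply(parts, `[[`, character(1), 1L)[keep],
    ref_id = rname[keep],
    pos = as.integer(vapply(parts, `[[`, character(1), 4L))[keep] - 1L,
    mapq = as.integer(vapply(parts, `[[`, character(1), 5L))[keep],
    stringsAsFactors = FALSE)
  if (best_only && nrow(df)) {
    df <- df[order(df$read_id, -df$mapq), , drop = FALSE]
    df <- df[!duplicated(df$read_id), , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}

#' Write read-to-reference mappings as a minimal SAM file
#'
#' Emits unpaired records with fixed MAPQ and a full-length match CIGAR;
#' sufficient for the "one best hit per read" mapping contract used by the
#' evaluation metrics.
#'
#' @param map data.frame with `read_id`, `ref_id`, `pos` (0-based),
#'   `seq` (read sequence) and optional `strand`.
#' @param ref_lengths Named integer vector of reference lengths (for the
#'   `@SQ` header).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam_map <- function(map, ref_lengths, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(ref_lengths),
                     as.integer(ref_lengths)), con)
  strand <- if (!is.null(map$strand)) map$strand else rep("+", nrow(map))
  flag <- ifelse(strand == "-", 16L, 0L)
  writeLines(sprintf("%s\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t*",
                     map$read_id, flag, map$ref_id, map$pos + 1L,
                     nchar(map$seq), map$seq), con)
  invisible(path)
}

## ---- run configuration ---------------------------------------------------

#' Default run configuration
#'
#' Flat list of pipeline parameters; the defaults are the analysis
#' thresholds used throughout: 500 bp contig filter, 95% identity / 100 bp
#' alignment filter, 1700 nt genome filter, 98% identity / 35 bp overlaps
#' at 3X fold coverage for contig spectra.
#'
#' @param seed Integer seed.
#' @param platform Platform profile name.
#' @param n_reads Metagenome size in reads.
#' @return Named list of class `run_config`.
#' @export
default_config <- function(seed = 1, platform = "454-ti", n_reads = 200000) {
  structure(list(
    seed = as.integer(seed), platform = platform,
    n_reads = as.integer(n_reads),
    min_contig_length = 500L, min_alignment_identity = 0.95,
    min_alignment_length = 100L, min_genome_length = 1700L,
    spectrum_min_identity = 0.98, spectrum_min_overlap = 35L,
    spectrum_fold_coverage = 3, spectrum_repetitions = 10L,
    diversity_search = "exhaustive", diversity_s_max = 1e6),
    class = "run_config")
}

#' Write a run configuration as a flat key-value file
#'
#' @param config A `run_config` list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  vals <- vapply(config, function(v) {
    if (is.numeric(v)) formatC(v, format = "g", digits = 15)
    else as.character(v)
  }, character(1))
  writeLines(paste0(names(config), " = ", vals), path)
  invisible(path)
}

#' Read a run configuration
#'
#' Round-trips [write_config()] output exactly: numeric-looking values are
#' restored to numeric (integers where whole).
#'
#' @param path Key-value file path.
#' @return Named list of class `run_config`.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^\\s*([^=\\s]+)\\s*=\\s*(.*)$",
                                  lines, perl = TRUE))
  bad <- which(lengths(kv) != 3L)
  if (length(bad))
    stop(path, ": line ", bad[1], ": expected 'key = value'")
  out <- lapply(kv, function(m) {
    v <- m[3]
    n <- suppressWarnings(as.numeric(v))
    if (!is.na(n)) {
      if (n == round(n) && abs(n) < .Machine$integer.max) as.integer(n) else n
    } else v
  })
  names(out) <- vapply(kv, `[[`, character(1), 2L)
  class(out) <- "run_config"
  out
}
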