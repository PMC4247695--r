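## Self-contained fixtures and pipeline orchestration. The fixture bundles
## a small community with known structure, reads with provenance, contigs
## constructed from genome substrings (including planted mismatches and one
## deliberate chimera) and exact ground-truth alignments and mappings, with
## closed-form expected metric values recorded in a manifest.

#' Generate a self-contained benchmark fixture
#'
#' Builds a bundle under `dir`: genomes FASTA, community TSV, reads FASTQ
#' with a provenance TSV, contigs FASTA, ground-truth coords TSV, a
#' read-to-contig SAM and a read-to-genome all-hits TSV. Contigs are cut
#' from genome substrings: one perfect contig per focal genome, one contig
#' with planted mismatches, and one deliberate chimera joining two genomes
#' (its support reads split 50/50, so its chimericity is `ln 2`). Every
#' downstream metric has a closed-form expectation recorded in
#' `manifest.json`, computed from the construction arithmetic, not by
#' running the pipeline.
#'
#' @param dir Output directory (created if needed).
#' @param scale `"tiny"` (1 family, 10 genomes) or `"small"` (2 families,
#'   24 genomes).
#' @param seed Integer seed.
#' @return Invisibly, a list with the bundle paths and the manifest.
#' @export
generate_fixture <- function(dir, scale = c("tiny", "small"), seed = 1) {
  scale <- match.arg(scale)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)

  n_fam <- if (scale == "tiny") 1L else 2L
  glen <- 3000L
  seqs <- character(0); meta <- NULL; groups <- NULL
  for (f in seq_len(n_fam)) {
    fam <- paste0("F", f)
    src <- random_genome(glen)
    sibs <- evolve_siblings(src, 8, alpha = 0.0025)
    names(sibs) <- sprintf("%s_oct_s%d", fam, 1:8)
    gid <- paste0(fam, "_oct")
    groups <- rbind(groups, data.frame(
      group_id = gid, family = fam, alpha = 0.0025, size = 8L,
      source_id = paste0(fam, "_u1"), stringsAsFactors = FALSE))
    unmod <- c(src, random_genome(glen))
    names(unmod) <- paste0(fam, "_u", 1:2)
    fam_seqs <- c(sibs, unmod)
    meta <- rbind(meta, data.frame(
      genome_id = names(fam_seqs), family = fam,
      group_id = c(rep(gid, 8), NA, NA),
      alpha = c(rep(0.0025, 8), NA, NA),
      origin_id = c(rep(paste0(fam, "_u1"), 8), names(unmod)),
      is_evolved = c(rep(TRUE, 8), FALSE, FALSE),
      stringsAsFactors = FALSE))
    seqs <- c(seqs, fam_seqs)
  }
  S <- length(seqs)
  ab <- as.numeric(power_law_abundances(S, max(0.25, 1 / S)))
  names(ab) <- names(seqs)
  comm <- community_profile(seqs, ab, meta = meta, groups = groups,
                            b = attr(power_law_abundances(S, 0.25), "b"))

  ## background reads: error-free 100-mers with provenance
  prof <- platform_profile("fixture", read_length = 100, paired = FALSE,
                           substitution_rate_start = 0,
                           substitution_rate_end = 0, indel_rate = 0)
  n_bg <- if (scale == "tiny") 300L else 600L
  reads <- simulate_reads(prof, comm, n_bg)

  ## planted contigs on the first two genomes of family 1
  gA <- comm$genomes$genome_id[1]; gB <- comm$genomes$genome_id[2]
  sA <- comm$sequences[[gA]]; sB <- comm$sequences[[gB]]

  perfect_seq <- substr(sA, 101, 700)                      # 600 bp of gA
  mism_src <- substr(sB, 201, 700)                         # 500 bp of gB
  mm_pos <- seq(25, by = 50, length.out = 10)              # 10 mismatches
  mm_chars <- seq_chars(mism_src)
  mm_chars[mm_pos] <- TRANSITION[mm_chars[mm_pos]]
  mism_seq <- paste(mm_chars, collapse = "")
  chim_seq <- paste0(substr(sA, 1001, 1310), substr(sB, 1001, 1310)) # 620 bp
  contigs <- c(ctg_perfect = perfect_seq, ctg_mismatch = mism_seq,
               ctg_chimera = chim_seq)

  truth <- alignment_records(
    contig_id = c("ctg_perfect", "ctg_mismatch", "ctg_chimera",
                  "ctg_chimera"),
    genome_id = c(gA, gB, gA, gB),
    contig_start = c(0L, 0L, 0L, 310L),
    contig_end = c(600L, 500L, 310L, 620L),
    genome_start = c(100L, 200L, 1000L, 1000L),
    genome_end = c(700L, 700L, 1310L, 1310L),
    identity = c(1, 0.98, 1, 1),
    contig_length = nchar(contigs)[c(1, 2, 3, 3)],
    genome_length = rep(glen, 4))

  ## dedicated support reads: 8 per perfect/mismatch contig (single
  ## origin), 6 + 6 for the chimera (50/50 split -> chimericity ln 2)
  support <- rbind(
    data.frame(contig = "ctg_perfect", origin = gA, gpos = 100 + (0:7) * 60,
               cpos = (0:7) * 60),
    data.frame(contig = "ctg_mismatch", origin = gB, gpos = 200 + (0:7) * 50,
               cpos = (0:7) * 50),
    data.frame(contig = "ctg_chimera", origin = gA, gpos = 1000 + (0:5) * 35,
               cpos = (0:5) * 35),
    data.frame(contig = "ctg_chimera", origin = gB, gpos = 1000 + (0:5) * 35,
               cpos = 310 + (0:5) * 35))
  sup_reads <- data.frame(
    read_id = sprintf("sup%03d", seq_len(nrow(support))),
    sequence = vapply(seq_len(nrow(support)), function(k)
      substr(comm$sequences[[support$origin[k]]], support$gpos[k] + 1L,
             support$gpos[k] + 100L), character(1)),
    mate = 0L, true_source = support$origin,
    true_start = support$gpos, true_strand = "+",
    stringsAsFactors = FALSE)
  reads <- rbind(reads, sup_reads)

  ## read-to-contig SAM (support reads only; one best hit per read)
  read_contig <- data.frame(read_id = sup_reads$read_id,
                            ref_id = support$contig, pos = support$cpos,
                            seq = sup_reads$sequence, strand = "+",
                            stringsAsFactors = FALSE)

  ## read-to-genome all-hits map: every read maps to its own genome; reads
  ## of the first octet sibling also map to the second (planted foreign
  ## hits for the coverage-by-others arithmetic)
  oct_ids <- sprintf("F1_oct_s%d", 1:8)
  oct_counts <- vapply(oct_ids, function(g) sum(reads$true_source == g),
                       integer(1))
  ord <- order(-oct_counts, oct_ids)
  sib1 <- oct_ids[ord[1]]; sib2 <- oct_ids[ord[2]]
  own_map <- data.frame(read_id = reads$read_id, genome_id = reads$true_source,
                        stringsAsFactors = FALSE)
  cross <- reads$read_id[reads$true_source == sib1]
  read_genome <- rbind(own_map,
                       data.frame(read_id = cross, genome_id = sib2,
                                  stringsAsFactors = FALSE))

  ## ---- closed-form manifest ----------------------------------------------
  ## chimera ties its two 310 bp alignments; lexicographically smaller
  ## genome id wins, so only that genome keeps the chimera span.
  chim_keep <- min(gA, gB)
  overall_A <- 100 * (600 + if (chim_keep == gA) 310 else 0) / glen
  overall_B <- 100 * (500 + if (chim_keep == gB) 310 else 0) / glen
  ## longest contig per genome: gA has ctg_chimera (620 bp) if kept, else
  ## ctg_perfect (600); gB has ctg_mismatch (500) or the chimera if kept
  max_A <- if (chim_keep == gA) 100 * 310 / glen else 100 * 600 / glen
  max_B <- if (chim_keep == gB) 100 * 310 / glen else 100 * 500 / glen
  own2 <- sum(reads$true_source == sib2)
  foreign2 <- length(cross)
  manifest <- list(
    scale = scale, seed = seed, n_genomes = S, genome_length = glen,
    contigs = list(
      ctg_perfect = list(accuracy = 100, chimericity = 0),
      ctg_mismatch = list(accuracy = 98, chimericity = 0),
      ctg_chimera = list(accuracy = 100 * 1 * (310 / 620),
                         chimericity = log(2))),
    genomes = stats::setNames(list(
      list(overall_coverage = overall_A, max_contig_coverage = max_A),
      list(overall_coverage = overall_B, max_contig_coverage = max_B)),
      c(gA, gB)),
    cbo = list(genome_id = sib2, own = own2, foreign = foreign2,
               cbo = foreign2 / glen, ratio = foreign2 / own2),
    n_reads = nrow(reads))

  paths <- list(
    genomes = file.path(dir, "genomes.fasta"),
    community = file.path(dir, "community.tsv"),
    reads = file.path(dir, "reads.fastq"),
    provenance = file.path(dir, "provenance.tsv"),
    contigs = file.path(dir, "contigs.fasta"),
    coords = file.path(dir, "truth.coords.tsv"),
    read_contig_sam = file.path(dir, "readmap.sam"),
    read_genome_map = file.path(dir, "genomemap.tsv"),
    manifest = file.path(dir, "manifest.json"))
  write_fasta(comm$sequences, paths$genomes)
  write_community_tsv(comm, paths$community)
  write_reads(reads, paths$reads, "fastq", paths$provenance)
  write_fasta(contigs, paths$contigs)
  write_coords(truth, paths$coords)
  write_sam_map(read_contig, vapply(contigs, nchar, integer(1)),
                paths$read_contig_sam)
  write_hashed_tsv(read_genome, paths$read_genome_map)
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(paths = paths, manifest = manifest, community = comm,
                 reads = reads, contigs = contigs, truth = truth,
                 read_contig = read_contig, read_genome = read_genome))
}

#' Run the evaluation pipeline over a fixture bundle
#'
#' Orchestrates simulate -> evaluate -> diversity on a fixture directory
#' (or one laid out the same way with externally assembled contigs) and
#' writes four report artifacts: contig length statistics
#' (`table1_contig_stats.tsv`), per-contig accuracy and chimericity
#' (`table2_accuracy.tsv`), the per-genome reconstruction table
#' (`fig1_genomes.tsv`) and diversity estimates by method
#' (`fig4_diversity.tsv`), plus `run_config.txt` and `run_log.txt`.
#' Reruns with the same seed are byte-identical.
#'
#' @param dir Fixture directory (see [generate_fixture()]).
#' @param config A [default_config()] list.
#' @param out_dir Output directory (defaults to `dir`).
#' @return Invisibly, a list with the report tables.
#' @export
run_benchmark <- function(dir, config = default_config(), out_dir = dir) {
  need <- c("genomes.fasta", "community.tsv", "reads.fastq",
            "provenance.tsv", "contigs.fasta", "truth.coords.tsv",
            "readmap.sam", "genomemap.tsv")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing))
    stop("missing pipeline inputs in ", dir, ": ",
         paste(missing, collapse = ", "),
         " (run generate_fixture(), or stage external assembly outputs",
         " under these names)")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)

  genomes <- read_fasta(file.path(dir, "genomes.fasta"))
  comm_tab <- read_community_tsv(file.path(dir, "community.tsv"))
  comm <- community_profile(
    genomes[comm_tab$genome_id],
    comm_tab$abundance / sum(comm_tab$abundance),
    meta = comm_tab[, c("genome_id", "family", "group_id", "alpha")])
  read_seqs <- read_fastq(file.path(dir, "reads.fastq"))
  prov <- read_provenance(file.path(dir, "provenance.tsv"))
  reads <- data.frame(read_id = prov$read_id,
                      sequence = unname(read_seqs[prov$read_id]),
                      true_source = prov$genome_id,
                      true_start = prov$start, true_strand = prov$strand,
                      stringsAsFactors = FALSE)
  contigs <- read_fasta(file.path(dir, "contigs.fasta"))
  coords <- read_coords(file.path(dir, "truth.coords.tsv"))
  read_contig <- read_sam_map(file.path(dir, "readmap.sam"))
  read_genome <- read_hashed_tsv(file.path(dir, "genomemap.tsv"),
                                 c(read_id = "character",
                                   genome_id = "character"))

  ## contig filtering + stats
  kept <- filter_contigs(contigs, config$min_contig_length)
  st <- contig_stats(nchar(kept))
  t1 <- data.frame(metric = c("n_contigs", "contig_sum", "contig_mean",
                              "contig_max", "n50"),
                   value = c(st$count, st$sum, st$mean, st$max, st$n50))
  write_hashed_tsv(t1, file.path(out_dir, "table1_contig_stats.tsv"))

  ## accuracy + chimericity per retained contig
  flt <- filter_alignments(coords, config$min_alignment_identity,
                           config$min_alignment_length)
  origin_of <- stats::setNames(reads$true_source, reads$read_id)
  t2 <- do.call(rbind, lapply(names(kept), function(cid) {
    acc <- contig_accuracy(flt[flt$contig_id == cid, , drop = FALSE],
                           nchar(kept[[cid]]))
    rids <- read_contig$read_id[read_contig$ref_id == cid]
    chim <- if (length(rids))
      chimericity(table(origin_of[rids])) else NA_real_
    data.frame(contig_id = cid, length = nchar(kept[[cid]]),
               accuracy = acc$accuracy, aligned = acc$aligned,
               chimericity = chim, stringsAsFactors = FALSE)
  }))
  write_hashed_tsv(t2, file.path(out_dir, "table2_accuracy.tsv"))

  ## per-genome reconstruction
  rep_ <- reconstruction_report(comm, flt, read_genome, reads,
                                min_genome_length = config$min_genome_length)
  write_hashed_tsv(rep_$per_genome, file.path(out_dir, "fig1_genomes.tsv"))

  ## diversity estimates
  agl <- mean(comm$genomes$length)
  spec <- subsampled_spectrum(reads, agl,
                              fold_coverage = config$spectrum_fold_coverage,
                              repetitions = config$spectrum_repetitions,
                              min_overlap = config$spectrum_min_overlap,
                              min_identity = config$spectrum_min_identity,
                              seed = config$seed)
  fit <- fit_spectrum(spec, read_length = round(mean(nchar(reads$sequence))),
                      min_overlap = config$spectrum_min_overlap,
                      avg_genome_length = agl,
                      search = config$diversity_search,
                      s_max = config$diversity_s_max)
  fc <- frequency_count_richness(spec)
  clus <- clustering_richness(reads, identity_thresholds = 0.98)
  corr <- genome_length_correction(unname(clus), agl,
                                   mean(nchar(reads$sequence)))
  t4 <- data.frame(
    method = c("spectrum_fit", "frequency_count", "clustering_098",
               "clustering_098_length_corrected",
               "clustering_098_length_corrected_read_scaled", "true"),
    richness = c(fit$richness, fc$richness, unname(clus), corr$corrected,
                 corr$corrected_read_scaled, nrow(comm$genomes)),
    evenness = c(fit$evenness, NA, NA, NA, NA,
                 summary(comm)$evenness))
  write_hashed_tsv(t4, file.path(out_dir, "fig4_diversity.tsv"))

  write_config(config, file.path(out_dir, "run_config.txt"))
  cfg_file <- file.path(out_dir, "run_config.txt")
  log_lines <- c(
    sprintf("viromock %s", as.character(utils::packageVersion("viromock"))),
    sprintf("seed: %d", config$seed),
    sprintf("config_hash: %s",
            substr(paste(tools::md5sum(cfg_file), collapse = ""), 1, 12)),
    sprintf("reads: %d  contigs kept: %d  genomes: %d",
            nrow(reads), length(kept), nrow(comm$genomes)))
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))

  invisible(list(contig_stats = st, accuracy = t2,
                 report = rep_, diversity = t4, fit = fit))
}
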