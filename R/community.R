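## Community simulation: evolved sibling genomes along random trees,
## power-law rank abundances, the 300-genome evolved mock design and the
## 100-community factorial benchmark set.

## Default branch-length scale, calibrated once with calibrate_tree_scale()
## against the alpha = 0.01 mean-ANI observation (0.85) for 10 siblings
## (seed 20260101, 60 trees). See the methods vignette.
DEFAULT_TREE_SCALE <- 12.149

## ---- random bifurcating trees -------------------------------------------

## Pure-birth (Yule) topology: starting from the root, a uniformly chosen
## active lineage splits until n tips exist. Branch lengths are iid Exp(1),
## then rescaled so the mean root-to-tip depth equals `scale`.
## Returns list(parent = integer vector (0 for root), blen = numeric,
##              tips = integer vector of tip node ids).
sim_tree <- function(n_tips, scale = 1) {
  stopifnot(n_tips >= 1)
  if (n_tips == 1L) {
    ## a single branch root -> tip
    return(list(parent = c(0L, 1L), blen = c(0, scale), tips = 2L))
  }
  parent <- 0L       # node 1 = root
  blen <- 0
  active <- 1L
  nnode <- 1L
  while (length(active) < n_tips) {
    split_at <- if (length(active) == 1L) active else sample(active, 1L)
    kids <- nnode + 1:2
    parent[kids] <- split_at
    blen[kids] <- stats::rexp(2L)
    nnode <- nnode + 2L
    active <- c(setdiff(active, split_at), kids)
  }
  depth <- numeric(nnode)
  for (v in 2:nnode) depth[v] <- depth[parent[v]] + blen[v]
  f <- scale / mean(depth[active])
  list(parent = parent, blen = blen * f, tips = sort(active))
}

## Edge lengths along the path between two tips (via their MRCA).
path_blens <- function(tree, i, j) {
  anc <- function(v) {
    out <- integer(0)
    while (v != 0L) { out <- c(out, v); v <- tree$parent[v] }
    out
  }
  ai <- anc(i); aj <- anc(j)
  common <- intersect(ai, aj)
  mrca <- common[1L]  # anc() lists bottom-up, intersect keeps ai's order
  on_path <- c(ai[seq_len(match(mrca, ai) - 1L)],
               aj[seq_len(match(mrca, aj) - 1L)])
  tree$blen[on_path]
}

## ---- sibling evolution ---------------------------------------------------

#' Evolve sibling genomes along a random tree
#'
#' Produces `n_siblings` genomes from a single source by a substitution-only
#' process along a simulated random bifurcating tree. Each branch of length
#' t substitutes each site independently with probability `min(1, alpha * t)`;
#' substitutions are transitions (A<->G, C<->T) by default, with an optional
#' transversion fraction. Lengths are preserved (no indels), so pairwise
#' identity can be read off positionally.
#'
#' @param source Source genome (single character string, A/C/G/T).
#' @param n_siblings Number of evolved genomes to return.
#' @param alpha Per-site transition rate per unit branch length, in \[0, 1\].
#' @param tree_scale Mean root-to-tip branch length of the simulated tree.
#'   The default was calibrated so that `alpha = 0.01` yields a mean pairwise
#'   ANI of about 0.85 among 10 siblings (see [calibrate_tree_scale()]).
#' @param seed Integer seed; identical seeds give identical output.
#' @param transversion_fraction Fraction of substitutions drawn as
#'   transversions instead of transitions (default 0).
#' @return Character vector of `n_siblings` evolved sequences, each the same
#'   length as `source`.
#' @export
evolve_siblings <- function(source, n_siblings, alpha,
                            tree_scale = DEFAULT_TREE_SCALE, seed = NULL,
                            transversion_fraction = 0) {
  if (!is.character(source) || length(source) != 1L || nchar(source) == 0L)
    stop("`source` must be a single non-empty sequence string")
  if (alpha < 0 || alpha > 1) stop("`alpha` must lie in [0, 1]")
  stopifnot(n_siblings >= 1, tree_scale > 0)
  if (!is.null(seed)) set.seed(seed)

  tree <- sim_tree(n_siblings, scale = tree_scale)
  L <- nchar(source)
  src <- seq_chars(source)
  nnode <- length(tree$parent)
  seqs <- vector("list", nnode)
  seqs[[1L]] <- src
  for (v in seq.int(2L, length.out = max(0L, nnode - 1L))) {
    s <- seqs[[tree$parent[v]]]
    p <- min(1, alpha * tree$blen[v])
    k <- stats::rbinom(1L, L, p)
    if (k > 0L) {
      pos <- sample.int(L, k)
      if (transversion_fraction > 0) {
        tv <- stats::runif(k) < transversion_fraction
        s[pos[!tv]] <- TRANSITION[s[pos[!tv]]]
        for (p2 in pos[tv]) s[p2] <- sample(TRANSVERSIONS[[s[p2]]], 1L)
      } else {
        s[pos] <- TRANSITION[s[pos]]
      }
    }
    seqs[[v]] <- s
  }
  vapply(seqs[tree$tips], paste, character(1), collapse = "")
}

#' Calibrate the tree branch-length scale against a target mean ANI
#'
#' The substitution process has one free scale (the mean root-to-tip branch
#' length). This routine fixes it by root-finding on the expected mean
#' pairwise ANI: for a bank of simulated trees, the probability that a site
#' differs between tips i and j is `(1 - prod(1 - 2 p_e)) / 2` over the
#' branches e on the i-j path with per-branch substitution probability
#' `p_e = min(1, alpha * t_e)` (an even number of transition flips restores
#' the base). The tree bank is fixed by `seed`, so the objective is smooth
#' and deterministic in the scale.
#'
#' @param alpha Transition rate the target refers to (default 0.01).
#' @param target_ani Target mean pairwise ANI (default 0.85).
#' @param n_siblings Tips per tree (default 10).
#' @param n_trees Trees in the bank (default 60).
#' @param seed Seed for the tree bank.
#' @param interval Search interval for the scale.
#' @return The calibrated scale (single numeric).
#' @export
calibrate_tree_scale <- function(alpha = 0.01, target_ani = 0.85,
                                 n_siblings = 10, n_trees = 60,
                                 seed = 20260101, interval = c(0.01, 500)) {
  set.seed(seed)
  banks <- vector("list", n_trees)
  for (b in seq_len(n_trees)) {
    tr <- sim_tree(n_siblings, scale = 1)
    pairs <- utils::combn(tr$tips, 2L)
    banks[[b]] <- lapply(seq_len(ncol(pairs)), function(k)
      path_blens(tr, pairs[1L, k], pairs[2L, k]))
  }
  expected_ani <- function(s) {
    pdiff <- unlist(lapply(banks, function(bk)
      vapply(bk, function(v) (1 - prod(1 - 2 * pmin(1, alpha * s * v))) / 2,
             numeric(1))))
    1 - mean(pdiff)
  }
  stats::uniroot(function(s) expected_ani(s) - target_ani,
                 interval = interval, tol = 1e-8)$root
}

## ---- abundances ----------------------------------------------------------

#' Power-law rank abundances with a fixed top abundance
#'
#' Returns relative abundances `p(r) = a * r^(-b)` for ranks `r = 1..S` with
#' `p(1) = top_abundance` and `sum(p) = 1`; the exponent `b` is found by
#' root-finding to `|sum - 1| < 1e-9`.
#'
#' @param S Richness (number of species).
#' @param top_abundance Relative abundance of the rank-1 species, in (0, 1].
#' @return Numeric vector of length `S`, with attribute `"b"` (the exponent).
#' @export
power_law_abundances <- function(S, top_abundance) {
  stopifnot(S >= 1, top_abundance > 0, top_abundance <= 1)
  if (S == 1L) {
    if (abs(top_abundance - 1) > 1e-9)
      stop("with S = 1 the top abundance must be 1")
    return(structure(1, b = 0))
  }
  r <- seq_len(S)
  total <- function(b) sum(top_abundance * r^(-b))
  if (top_abundance < 1 / S - 1e-12)
    stop("infeasible: top_abundance < 1/S would require a negative exponent")
  if (abs(total(0) - 1) < 1e-12) {
    b <- 0
  } else {
    hi <- 1
    while (total(hi) > 1) hi <- hi * 2
    b <- stats::uniroot(function(b) total(b) - 1, c(0, hi), tol = 1e-13)$root
  }
  p <- top_abundance * r^(-b)
  stopifnot(abs(sum(p) - 1) < 1e-9)
  structure(p, b = b)
}

## ---- community profile class --------------------------------------------

#' Construct a community profile
#'
#' Bundles genome sequences, relative abundances and optional sibling-group
#' metadata into a `community_profile` object. Genomes are stored in rank
#' order (non-increasing abundance).
#'
#' @param sequences Named character vector of genome sequences.
#' @param abundances Numeric vector of relative abundances (same order and
#'   names as `sequences`); must sum to 1 within 1e-9.
#' @param meta Optional data.frame with one row per genome (columns such as
#'   family, group_id, alpha, origin_id, is_evolved), matched by `genome_id`.
#' @param groups Optional data.frame describing sibling groups
#'   (group_id, family, alpha, size, source_id).
#' @param b Power-law exponent used for the abundances, if any.
#' @return An object of class `community_profile` with components
#'   `genomes` (data.frame in rank order, with rank, abundance, length),
#'   `sequences`, `groups`, `b`.
#' @export
community_profile <- function(sequences, abundances, meta = NULL,
                              groups = NULL, b = NA_real_) {
  stopifnot(is.character(sequences), length(sequences) >= 1,
            length(abundances) == length(sequences),
            !is.null(names(sequences)),
            !anyDuplicated(names(sequences)))
  if (abs(sum(abundances) - 1) > 1e-9)
    stop("abundances must sum to 1 (within 1e-9)")
  ord <- order(-abundances, names(sequences))
  df <- data.frame(genome_id = names(sequences)[ord],
                   rank = seq_along(ord),
                   abundance = abundances[ord],
                   length = nchar(sequences)[ord],
                   stringsAsFactors = FALSE)
  rownames(df) <- NULL
  if (!is.null(meta)) {
    stopifnot("genome_id" %in% names(meta))
    df <- merge(df, meta, by = "genome_id", sort = FALSE)
    df <- df[order(df$rank), ]
    rownames(df) <- NULL
  }
  structure(list(genomes = df, sequences = sequences[df$genome_id],
                 groups = groups, b = b),
            class = "community_profile")
}

#' @export
print.community_profile <- function(x, ...) {
  g <- x$genomes
  cat("Community profile:", nrow(g), "genomes")
  if (!is.null(g$family)) cat(",", length(unique(g$family)), "families")
  cat("\n")
  cat("  genome length:", min(g$length), "-", max(g$length), "bp\n")
  cat(sprintf("  top abundance: %.4g  (power-law exponent b = %.4g)\n",
              g$abundance[1], x$b))
  if (!is.null(x$groups))
    cat("  sibling groups:", nrow(x$groups),
        sprintf("(sizes %s)", paste(sort(unique(x$groups$size)),
                                    collapse = "/")), "\n")
  invisible(x)
}

#' @export
summary.community_profile <- function(object, ...) {
  g <- object$genomes
  out <- list(n_genomes = nrow(g),
              total_abundance = sum(g$abundance),
              shannon = -sum(g$abundance * log(g$abundance)),
              b = object$b)
  out$evenness <- if (nrow(g) > 1) out$shannon / log(nrow(g)) else 1
  class(out) <- "summary.community_profile"
  out
}

#' @export
print.summary.community_profile <- function(x, ...) {
  cat(sprintf("%d genomes; Shannon %.3f nats; evenness %.3f; b = %.3g\n",
              x$n_genomes, x$shannon, x$evenness, x$b))
  invisible(x)
}

## ---- evolved mock community ---------------------------------------------

#' Simulate source genomes for an evolved mock community
#'
#' Random genomes grouped into families, with lengths drawn uniformly from
#' `length_range` (log-uniform would also be defensible; viral genome
#' lengths here only need to span a realistic 5-50 kb range).
#'
#' @param n_families Number of families.
#' @param per_family Source genomes per family (the evolved design needs 18:
#'   8 evolution sources plus 10 genomes kept unmodified).
#' @param length_range Genome length range in bp.
#' @param seed Integer seed.
#' @return Named list of character vectors, one per family.
#' @export
simulate_source_genomes <- function(n_families = 6, per_family = 18,
                                    length_range = c(5000, 50000),
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fams <- paste0("F", seq_len(n_families))
  out <- lapply(fams, function(f) {
    lens <- round(stats::runif(per_family, length_range[1], length_range[2]))
    gs <- vapply(lens, random_genome, character(1))
    names(gs) <- sprintf("%s_src%02d", f, seq_len(per_family))
    gs
  })
  names(out) <- fams
  out
}

#' Build the evolved mock community
#'
#' Assembles the 300-genome design: 6 families, each contributing 10
#' unmodified genomes plus 40 evolved genomes produced from 8 sources as
#' duplicates of the four (transition rate x group size) combinations --
#' 2 pairs and 2 octets at each of two rates. Families receive equal total
#' abundance; within each family the rank list follows a power law and one
#' unmodified genome is intercalated after every four evolved genomes.
#'
#' @param source_genomes Named list of families, each a named character
#'   vector of at least 18 source genomes (see [simulate_source_genomes()]).
#' @param alphas Numeric pair of transition rates (default `c(0.01, 0.0025)`).
#' @param tree_scale Branch-length scale passed to [evolve_siblings()].
#' @param b Within-family power-law exponent (default 1).
#' @param seed Integer seed.
#' @return A [community_profile()] with sibling-group metadata.
#' @export
build_evolved_community <- function(source_genomes,
                                    alphas = c(0.01, 0.0025),
                                    tree_scale = DEFAULT_TREE_SCALE,
                                    b = 1.0, seed = NULL) {
  if (length(source_genomes) != 6L)
    stop("the evolved design requires exactly 6 families")
  if (any(vapply(source_genomes, length, integer(1)) < 18L))
    stop("each family needs >= 18 source genomes (8 evolved + 10 unmodified)")
  if (length(alphas) != 2L) stop("`alphas` must be a pair of rates")
  if (!is.null(seed)) set.seed(seed)

  seqs <- character(0)
  meta <- NULL
  groups <- NULL
  for (fam in names(source_genomes)) {
    src <- source_genomes[[fam]]
    ## design: sources 1-2 pairs@a1, 3-4 pairs@a2, 5-6 octets@a1, 7-8 octets@a2
    design <- data.frame(src_idx = 1:8,
                         alpha = rep(c(alphas[1], alphas[2]), each = 2,
                                     times = 2),
                         size = rep(c(2L, 8L), each = 4))
    fam_seqs <- character(0)
    fam_meta <- NULL
    for (g in seq_len(nrow(design))) {
      source_id <- names(src)[design$src_idx[g]]
      gid <- sprintf("%s_g%02d", fam, g)
      sibs <- evolve_siblings(src[[design$src_idx[g]]], design$size[g],
                              alpha = design$alpha[g],
                              tree_scale = tree_scale)
      names(sibs) <- sprintf("%s_s%d", gid, seq_along(sibs))
      fam_seqs <- c(fam_seqs, sibs)
      fam_meta <- rbind(fam_meta, data.frame(
        genome_id = names(sibs), family = fam, group_id = gid,
        alpha = design$alpha[g], origin_id = source_id,
        is_evolved = TRUE, stringsAsFactors = FALSE))
      groups <- rbind(groups, data.frame(
        group_id = gid, family = fam, alpha = design$alpha[g],
        size = design$size[g], source_id = source_id,
        stringsAsFactors = FALSE))
    }
    unmod <- src[9:18]
    fam_seqs <- c(fam_seqs, unmod)
    fam_meta <- rbind(fam_meta, data.frame(
      genome_id = names(unmod), family = fam, group_id = NA_character_,
      alpha = NA_real_, origin_id = names(unmod), is_evolved = FALSE,
      stringsAsFactors = FALSE))

    ## rank pattern within the family: [4 evolved, 1 unmodified] x 10
    ev_ids <- sample(fam_meta$genome_id[fam_meta$is_evolved])   # 40
    un_ids <- sample(fam_meta$genome_id[!fam_meta$is_evolved])  # 10
    ranked <- character(50)
    ranked[seq(5, 50, by = 5)] <- un_ids
    ranked[setdiff(1:50, seq(5, 50, by = 5))] <- ev_ids

    w <- seq_len(50)^(-b)
    ab <- (w / sum(w)) / length(source_genomes)  # family share = 1/6
    names(ab) <- ranked

    seqs <- c(seqs, fam_seqs)
    fm <- fam_meta
    fm$abund <- ab[fm$genome_id]
    meta <- rbind(meta, fm)
  }
  abundances <- meta$abund[match(names(seqs), meta$genome_id)]
  meta$abund <- NULL
  community_profile(seqs, abundances, meta = meta, groups = groups, b = b)
}

## ---- hundred-community benchmark ----------------------------------------

#' Build a factorial set of benchmark communities
#'
#' Crosses richness levels with top (rank-1) abundances and draws
#' `replicates` communities per structure, each sampling distinct genomes
#' from a pool without replacement and assigning power-law abundances.
#'
#' @param genome_pool Named character vector of genome sequences; must hold
#'   at least `max(richness_levels)` genomes.
#' @param richness_levels Integer vector of community richness values.
#' @param top_abundances Rank-1 relative abundances.
#' @param replicates Communities per structure.
#' @param seed Integer seed.
#' @return List of [community_profile()] objects; each carries attributes
#'   `richness` and `top_abundance`.
#' @export
build_benchmark_communities <- function(genome_pool,
                                        richness_levels = c(100, 1000),
                                        top_abundances = c(0.02, 0.25),
                                        replicates = 25, seed = NULL) {
  if (length(genome_pool) < max(richness_levels))
    stop("genome pool smaller than the largest richness level")
  if (!is.null(seed)) set.seed(seed)
  out <- list()
  for (S in richness_levels) for (a in top_abundances) {
    for (rep_i in seq_len(replicates)) {
      ids <- sample(names(genome_pool), S)
      ab <- power_law_abundances(S, a)
      names(ab) <- ids
      cp <- community_profile(genome_pool[ids], as.numeric(ab),
                              b = attr(ab, "b"))
      attr(cp, "richness") <- S
      attr(cp, "top_abundance") <- a
      out[[sprintf("S%d_top%g_rep%d", S, a, rep_i)]] <- cp
    }
  }
  out
}

## ---- pairwise ANI --------------------------------------------------------

#' Pairwise average nucleotide identity
#'
#' For equal-length substitution-only siblings, ANI is the fraction of
#' positions with identical bases. Pairs of unequal length (which would need
#' an alignment) are reported as `NA` with a warning.
#'
#' @param genomes Named character vector of >= 2 sequences.
#' @return Symmetric matrix with unit diagonal.
#' @export
pairwise_ani <- function(genomes) {
  n <- length(genomes)
  if (n < 2) stop("need at least 2 genomes")
  ids <- names(genomes)
  if (is.null(ids)) ids <- paste0("g", seq_len(n))
  raws <- lapply(genomes, charToRaw)
  m <- diag(1, n)
  dimnames(m) <- list(ids, ids)
  unequal <- FALSE
  for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
    if (length(raws[[i]]) != length(raws[[j]])) {
      m[i, j] <- m[j, i] <- NA_real_
      unequal <- TRUE
    } else {
      m[i, j] <- m[j, i] <- mean(raws[[i]] == raws[[j]])
    }
  }
  if (unequal)
    warning("length-mismatched pairs reported as NA (no alignment support)")
  m
}

#' Mean of the off-diagonal pairwise ANI values
#'
#' @param ani_matrix Matrix from [pairwise_ani()].
#' @return Single numeric.
#' @export
mean_pairwise_ani <- function(ani_matrix) {
  mean(ani_matrix[upper.tri(ani_matrix)])
}
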