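## Synthetic-data generator: every input the pipeline consumes (annotated
## genome, strand-specific coverage tracks, planted expression programs,
## species tree, conservation matrix), together with ground-truth tables
## for parameter-recovery tests.

#' Specification of a synthetic annotated genome
#'
#' @param genome_length genome size in nucleotides.
#' @param n_genes number of genes to place.
#' @param gene_length_range integer interval of gene lengths (nt).
#' @param strand_fraction proportion of genes on the plus strand.
#' @param gc_profile function mapping a window index to a GC fraction in
#'   `[0, 1]`.  The default oscillates around 0.67, the GC content typical
#'   of a GC-rich alphaproteobacterial genome.
#' @param duplicate_gene_pairs number of gene pairs flagged as sharing an
#'   identical sequence (reads mapping ambiguously are split between them,
#'   as happens for duplicated tRNAs).
#' @param window_size GC window size in nt.
#'
#' @return An object of class `genome_spec`.
#' @export
genome_spec <- function(genome_length = 50000L,
                        n_genes = 60L,
                        gene_length_range = c(300L, 900L),
                        strand_fraction = 0.5,
                        gc_profile = function(i) 0.67 + 0.12 * sin(i / 3),
                        duplicate_gene_pairs = 0L,
                        window_size = 500L) {
  stopifnot(genome_length >= 1, n_genes >= 0,
            length(gene_length_range) == 2,
            gene_length_range[1] >= 1,
            gene_length_range[2] >= gene_length_range[1],
            is.function(gc_profile), duplicate_gene_pairs >= 0,
            window_size >= 1)
  .check_fraction(strand_fraction, "strand_fraction")
  structure(list(genome_length = as.integer(genome_length),
                 n_genes = as.integer(n_genes),
                 gene_length_range = as.integer(gene_length_range),
                 strand_fraction = strand_fraction,
                 gc_profile = gc_profile,
                 duplicate_gene_pairs = as.integer(duplicate_gene_pairs),
                 window_size = as.integer(window_size)),
            class = "genome_spec")
}

## pack genes without overlap on one strand: sorted random offsets spread
## the slack between consecutive genes
.place_genes <- function(lengths, genome_length) {
  n <- length(lengths)
  if (n == 0) return(integer(0))
  total <- sum(lengths)
  slack <- genome_length - total
  if (slack < 0)
    stop("infeasible packing: total gene length (", total,
         ") exceeds genome length (", genome_length, ")", call. = FALSE)
  off <- sort(floor(runif(n, 0, slack + 1)))
  off <- pmin(off, slack)
  off + c(0L, cumsum(lengths))[seq_len(n)]
}

#' Generate a synthetic gene annotation and GC track
#'
#' Places `n_genes` non-overlapping genes per strand inside the genome and
#' evaluates the GC profile over fixed windows.  Coordinates are 0-based,
#' half-open; the GFF3 writer converts to 1-based closed at the boundary.
#'
#' @param spec a [genome_spec()].
#' @param seed integer RNG seed; identical seeds give identical output.
#'
#' @return A list of class `synthetic_genome` with elements `annotation`
#'   (data frame: gene_id, start, end, strand, length, dup_group), `gc`
#'   (data frame: window, start, end, gc), `genome_length`, `window_size`.
#' @export
generate_genome <- function(spec, seed) {
  stopifnot(inherits(spec, "genome_spec"))
  .local_seed(seed)
  n <- spec$n_genes

  lengths <- if (n > 0)
    sample(seq(spec$gene_length_range[1], spec$gene_length_range[2]), n,
           replace = TRUE) else integer(0)

  dup_group <- rep(NA_integer_, n)
  ndup <- spec$duplicate_gene_pairs
  if (ndup > 0) {
    if (2L * ndup > n)
      stop("duplicate_gene_pairs too large for n_genes", call. = FALSE)
    idx <- sample.int(n, 2L * ndup)
    for (p in seq_len(ndup)) {
      a <- idx[2L * p - 1L]; b <- idx[2L * p]
      lengths[b] <- lengths[a]   # identical sequence implies equal length
      dup_group[c(a, b)] <- p
    }
  }

  n_plus <- round(n * spec$strand_fraction)
  strand <- rep("-", n)
  if (n > 0) strand[sample.int(n, n_plus)] <- "+"

  start <- integer(n)
  for (s in c("+", "-")) {
    on <- which(strand == s)
    if (length(on)) {
      ord <- on[order(runif(length(on)))]  # random packing order
      start[ord] <- .place_genes(lengths[ord], spec$genome_length)
    }
  }

  annotation <- data.frame(
    gene_id = if (n > 0) sprintf("gene%04d", seq_len(n)) else character(0),
    start = start, end = start + lengths,
    strand = strand, length = lengths, dup_group = dup_group,
    stringsAsFactors = FALSE
  )

  n_win <- ceiling(spec$genome_length / spec$window_size)
  wstart <- (seq_len(n_win) - 1L) * spec$window_size
  gc <- data.frame(
    window = seq_len(n_win),
    start = wstart,
    end = pmin(wstart + spec$window_size, spec$genome_length),
    gc = pmin(1, pmax(0, vapply(seq_len(n_win), spec$gc_profile, numeric(1))))
  )

  structure(list(annotation = annotation, gc = gc,
                 genome_length = spec$genome_length,
                 window_size = spec$window_size),
            class = "synthetic_genome")
}

## truncated continuous power-law sampler (inverse CDF)
.rplaw <- function(n, alpha, xmin, xmax = Inf) {
  u <- runif(n)
  a1 <- 1 - alpha
  if (is.finite(xmax)) {
    (xmin^a1 - u * (xmin^a1 - xmax^a1))^(1 / a1)
  } else {
    xmin * (1 - u)^(1 / a1)
  }
}

#' Assign expression programs to genes
#'
#' Draws, for every gene, an expression stratum (low / bulk / high), a base
#' expression level (x-fold coverage) and per-time-point multipliers.
#' Cell-cycle-regulated (CCR) genes receive a planted pattern: a contiguous
#' blocking of the time points with block levels spanning a fold change
#' whose geometric mean across genes is `fold_change_mean`.  Bulk and high
#' peak levels follow a truncated power law (exponent `alpha`), matching
#' the heavy-tailed expression distribution of bacterial transcriptomes.
#'
#' @param n_genes number of genes.
#' @param stratum_fractions named proportions for `low`, `bulk`, `high`;
#'   must sum to 1.  Defaults are the observed 738 / 3136 / 90 split of a
#'   3,964-gene genome.
#' @param ccr_fraction proportion of genes given a cell-cycle pattern
#'   (default 1586/3964).
#' @param fold_change_mean geometric-mean peak-to-trough fold change of
#'   planted CCR patterns (default 8.2).
#' @param n_timepoints number of time points (default 5).
#' @param alpha power-law exponent of peak expression (default 1.74).
#' @param fold_sdlog log-scale spread of per-gene fold changes.
#' @param seed integer RNG seed.
#'
#' @return A data frame of class `expression_programs`: gene index,
#'   stratum, base_level, is_ccr, pattern_id and one `mult_t*` column per
#'   time point (multipliers in `(0, 1]`, all 1 for non-CCR genes).
#' @export
assign_programs <- function(n_genes,
                            stratum_fractions = c(low = 738, bulk = 3136,
                                                  high = 90) / 3964,
                            ccr_fraction = 1586 / 3964,
                            fold_change_mean = 8.2,
                            n_timepoints = 5L,
                            alpha = 1.74,
                            fold_sdlog = 0.4,
                            seed = 1L) {
  .check_fraction(stratum_fractions, "stratum_fractions")
  .check_fraction(ccr_fraction, "ccr_fraction")
  if (abs(sum(stratum_fractions) - 1) > 1e-8)
    stop("stratum_fractions must sum to 1", call. = FALSE)
  stopifnot(fold_change_mean > 1, n_timepoints >= 2)
  .local_seed(seed)

  n_low <- round(n_genes * stratum_fractions[["low"]])
  n_high <- round(n_genes * stratum_fractions[["high"]])
  n_bulk <- n_genes - n_low - n_high
  stratum <- sample(rep(c("low", "bulk", "high"), c(n_low, n_bulk, n_high)))

  peak <- numeric(n_genes)
  peak[stratum == "low"] <- runif(sum(stratum == "low"), 0.3, 4.9)
  peak[stratum == "bulk"] <- .rplaw(sum(stratum == "bulk"), alpha, 5, 1000)
  peak[stratum == "high"] <- pmin(.rplaw(sum(stratum == "high"), alpha, 1000),
                                  5e4)

  is_ccr <- runif(n_genes) < ccr_fraction
  models <- enumerate_models(n_timepoints)
  diffm <- Filter(function(m) m$kind == "differential", models)

  mult <- matrix(1, n_genes, n_timepoints)
  pattern_id <- rep(NA_character_, n_genes)
  for (g in which(is_ccr)) {
    m <- diffm[[sample.int(length(diffm), 1)]]
    f <- rlnorm(1, log(fold_change_mean), fold_sdlog)
    B <- max(m$blocks)
    lev <- f^((sample.int(B) - 1) / (B - 1))  # block levels from 1 to f
    mult[g, ] <- lev[m$blocks] / max(lev[m$blocks])
    pattern_id[g] <- m$pattern_id
  }

  out <- data.frame(gene = seq_len(n_genes), stratum = stratum,
                    base_level = peak, is_ccr = is_ccr,
                    pattern_id = pattern_id, stringsAsFactors = FALSE)
  mcols <- as.data.frame(mult)
  names(mcols) <- paste0("mult_t", seq_len(n_timepoints))
  out <- cbind(out, mcols)
  class(out) <- c("expression_programs", "data.frame")
  out
}

#' Simulate strand-specific replicate coverage tracks
#'
#' Expected per-nucleotide coverage of a gene at a time point is its base
#' level times the time-point multiplier.  Replicate gene-level means are
#' drawn from a gamma mixture (negative binomial at the gene level,
#' dispersion `count_noise$dispersion`), then per-nucleotide values are
#' Poisson around the gene mean.  Within the GC-flagged windows (the
#' `gc_noise$affected_fraction` highest-GC windows) an independent
#' multiplicative log-normal perturbation per (window, replicate, time
#' point) raises the local replicate CV to about `gc_noise$cv_target`,
#' emulating GC-correlated mapping inconsistency.  Coverage of
#' duplicate-gene identity groups is averaged across the copies (ambiguous
#' reads split evenly).
#'
#' @param genome a `synthetic_genome` from [generate_genome()].
#' @param programs an `expression_programs` table from [assign_programs()].
#' @param n_timepoints,n_replicates design dimensions (defaults 5 and 3).
#' @param gc_noise list with `affected_fraction` and `cv_target`.
#' @param count_noise list with `dispersion` (gene-level NB dispersion) and
#'   `nucleotide_poisson` (logical; `FALSE` gives deterministic coverage).
#' @param seed integer RNG seed.
#'
#' @return A `coverage_experiment`: per-(time point, replicate) plus/minus
#'   strand coverage vectors, the annotation, the flagged GC windows, and
#'   a `truth` matrix of planted expected expression (genes x time points).
#' @export
simulate_coverage <- function(genome, programs,
                              n_timepoints = 5L, n_replicates = 3L,
                              gc_noise = list(affected_fraction = 0.1,
                                              cv_target = 1.5),
                              count_noise = list(dispersion = 0.05,
                                                 nucleotide_poisson = TRUE),
                              seed = 1L) {
  stopifnot(inherits(genome, "synthetic_genome"))
  ann <- genome$annotation
  if (nrow(ann) != nrow(programs))
    stop("annotation and programs disagree on gene count", call. = FALSE)
  .check_fraction(gc_noise$affected_fraction %||% 0, "gc_noise$affected_fraction")
  .local_seed(seed)

  L <- genome$genome_length
  T <- as.integer(n_timepoints)
  R <- as.integer(n_replicates)
  phi <- count_noise$dispersion %||% 0
  pois <- isTRUE(count_noise$nucleotide_poisson %||% TRUE)
  multc <- as.matrix(programs[, paste0("mult_t", seq_len(T))])
  mu_truth <- programs$base_level * multc   # genes x timepoints

  tracks <- vector("list", T)
  for (t in seq_len(T)) {
    tracks[[t]] <- vector("list", R)
    for (r in seq_len(R))
      tracks[[t]][[r]] <- list(`+` = numeric(L), `-` = numeric(L))
  }

  for (g in seq_len(nrow(ann))) {
    idx <- (ann$start[g] + 1L):ann$end[g]
    s <- ann$strand[g]
    for (t in seq_len(T)) {
      mu <- mu_truth[g, t]
      for (r in seq_len(R)) {
        lam <- if (mu <= 0) 0
          else if (phi > 0) rgamma(1, shape = 1 / phi, scale = mu * phi)
          else mu
        v <- if (lam <= 0) rep(0, length(idx))
          else if (pois) rpois(length(idx), lam) else rep(lam, length(idx))
        tracks[[t]][[r]][[s]][idx] <- v
      }
    }
  }

  ## ambiguous mapping: identity groups share averaged coverage
  dup_groups <- unique(na.omit(ann$dup_group))
  for (p in dup_groups) {
    gs <- which(ann$dup_group == p)
    for (t in seq_len(T)) for (r in seq_len(R)) {
      regs <- lapply(gs, function(g) {
        tracks[[t]][[r]][[ann$strand[g]]][(ann$start[g] + 1L):ann$end[g]]
      })
      avg <- Reduce(`+`, regs) / length(regs)
      for (g in gs)
        tracks[[t]][[r]][[ann$strand[g]]][(ann$start[g] + 1L):ann$end[g]] <- avg
    }
  }

  ## GC-linked replicate inconsistency in the highest-GC windows: per
  ## (window, time point) one replicate's local coverage is inflated by a
  ## spike factor solved so that the replicate CV equals cv_target (with
  ## n replicates the largest reachable CV is that of a single dominant
  ## replicate); a mild log-normal jitter is added to every replicate.
  ## A mean-one perturbation would average out across replicates, whereas
  ## the emulated phenomenon is a local mapping artifact that biases and
  ## destabilizes the affected windows.
  affected <- integer(0)
  afrac <- gc_noise$affected_fraction %||% 0
  cvt <- gc_noise$cv_target %||% 0
  if (afrac > 0 && cvt > 0) {
    nw <- nrow(genome$gc)
    n_aff <- max(1L, round(afrac * nw))
    affected <- order(genome$gc$gc, decreasing = TRUE)[seq_len(n_aff)]
    spike_cv <- function(b) {
      x <- c(b, rep(1, R - 1))
      sd(x) / mean(x)
    }
    b <- if (spike_cv(1e6) <= cvt) 1e6
      else stats::uniroot(function(b) spike_cv(b) - cvt, c(1 + 1e-6, 1e6))$root
    jitter_sd <- 0.25
    for (w in affected) {
      idx <- (genome$gc$start[w] + 1L):genome$gc$end[w]
      for (t in seq_len(T)) {
        spike <- sample.int(R, 1)
        for (r in seq_len(R)) {
          f <- rlnorm(1, 0, jitter_sd) * if (r == spike) b else 1
          tracks[[t]][[r]][["+"]][idx] <- tracks[[t]][[r]][["+"]][idx] * f
          tracks[[t]][[r]][["-"]][idx] <- tracks[[t]][[r]][["-"]][idx] * f
        }
      }
    }
  }

  rownames(mu_truth) <- ann$gene_id
  colnames(mu_truth) <- paste0("t", seq_len(T))
  structure(list(tracks = tracks, annotation = ann, genome_length = L,
                 n_timepoints = T, n_replicates = R,
                 gc = genome$gc, affected_windows = sort(affected),
                 window_size = genome$window_size,
                 truth = mu_truth, programs = programs),
            class = "coverage_experiment")
}

#' Simulate a replicate expression matrix directly from programs
#'
#' Bypasses the coverage layer: draws gene x sample expression values
#' straight from the negative-binomial replicate model (gene-level
#' dispersion `dispersion`) around the planted program means.  Useful for
#' testing the differential-expression and network stages at scales where
#' per-nucleotide simulation is unnecessary.
#'
#' @param programs an `expression_programs` table.
#' @param n_replicates replicates per time point (default 3).
#' @param dispersion gene-level NB dispersion (default 0.05).
#' @param seed integer RNG seed.
#'
#' @return An `expression_matrix` whose values are NB draws around
#'   `base_level * multiplier`.
#' @export
simulate_expression <- function(programs, n_replicates = 3L,
                                dispersion = 0.05, seed = 1L) {
  .local_seed(seed)
  T <- sum(grepl("^mult_t", names(programs)))
  mu <- programs$base_level *
    as.matrix(programs[, paste0("mult_t", seq_len(T))])
  G <- nrow(mu); R <- as.integer(n_replicates)
  values <- matrix(0, G, T * R,
                   dimnames = list(sprintf("gene%04d", seq_len(G)),
                                   .sample_names(T, R)))
  for (t in seq_len(T)) for (r in seq_len(R)) {
    col <- (t - 1L) * R + r
    values[, col] <- if (dispersion > 0)
      rnbinom(G, size = 1 / dispersion, mu = mu[, t])
    else rpois(G, mu[, t])
  }
  structure(list(values = values, layout = .sample_layout(T, R),
                 retained_fraction = rep(1, G),
                 fallback = matrix(FALSE, G, T),
                 annotation = NULL),
            class = "expression_matrix")
}

#' Simulate a species tree with planted conservation modules
#'
#' Simulates a constant-rate birth-death tree conditioned on the number of
#' tips, then evolves gene presence/absence down the tree.  Each gene
#' originates at an origin node and is lost on each branch of its subtree
#' with probability `loss_probability` (a loss removes the gene from every
#' descendant species).  Broadly conserved genes originate at the root
#' and are additionally subject to distance-graded ortholog
#' detectability: the probability of detecting an ortholog in a species
#' decays as `exp(-d/lambda)` with the patristic distance d from the
#' focal species (`lambda = detection_scale * max distance`), emulating
#' the decline of reciprocal-best-hit detection with sequence divergence.
#' Clade-specific genes originate, independently per gene, at small
#' random clades (`clade_size_range` tips, always at most
#' `clade_max_fraction` of the tips); being recent, they are detected
#' wherever present.
#'
#' @param n_species number of tips (>= 4); the study scale is 236.
#' @param module_truths list of lists with fields `module_id`,
#'   `depth_class` (`"broad"` or `"clade"`) and either `size` or `genes`
#'   (gene ids).
#' @param loss_probability per-branch loss probability in `[0, 1]`.
#' @param clade_max_fraction maximal clade size (fraction of tips) for
#'   clade-specific origins (default 0.15).
#' @param clade_size_range tip-count range of clade-specific origins
#'   (default 2 to 3; clipped by `clade_max_fraction`).
#' @param detection_scale scale of the broad-gene detectability decay as
#'   a fraction of the maximal distance from the focal species; `Inf`
#'   disables the decay (default 0.4).
#' @param focal_species tip index of the focal species, or `"auto"`
#'   (default) to pick the tip with the smallest median patristic
#'   distance to the others: the focal organism of such a study is nested
#'   among close relatives, not an isolated deep lineage.
#' @param birth,death birth-death rates of the species tree.
#' @param seed integer RNG seed.
#'
#' @return A list of class `phylo_truth`: `tree` (ape phylo, ultrametric),
#'   `conservation` (genes x species 0/1 matrix), and `truth` (data frame
#'   gene_id, module_id, depth_class, origin_node).
#' @export
simulate_tree_and_conservation <- function(n_species, module_truths,
                                           loss_probability = 0.1,
                                           clade_max_fraction = 0.15,
                                           clade_size_range = c(2L, 3L),
                                           detection_scale = 0.4,
                                           focal_species = "auto",
                                           birth = 1, death = 0.5,
                                           seed = 1L) {
  stopifnot(n_species >= 4)
  .check_fraction(loss_probability, "loss_probability")
  .local_seed(seed)

  tree <- ape::rphylo(n_species, birth = birth, death = death)
  tree$tip.label <- sprintf("s%03d", seq_len(n_species))

  ## descendant node sets (self + all descendants), built in postorder
  nnode <- n_species + tree$Nnode
  desc <- as.list(seq_len(nnode))
  ord <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(ord$edge))) {
    p <- ord$edge[e, 1]; ch <- ord$edge[e, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  n_tips_below <- vapply(desc, function(d) sum(d <= n_species), integer(1))
  root <- n_species + 1L
  max_clade <- max(2L, floor(clade_max_fraction * n_species))
  lo <- min(max(2L, clade_size_range[1]), max_clade)
  hi <- min(clade_size_range[2], max_clade)
  clade_nodes <- which(seq_len(nnode) > n_species &
                       n_tips_below >= lo & n_tips_below <= max(lo, hi))
  if (!length(clade_nodes))
    clade_nodes <- which(seq_len(nnode) > n_species &
                         n_tips_below <= max_clade)
  if (!length(clade_nodes)) clade_nodes <- root  # degenerate tiny trees

  edge <- tree$edge
  subtree_edges <- function(node) which(edge[, 1] %in% desc[[node]])

  D <- ape::cophenetic.phylo(tree)[tree$tip.label, tree$tip.label]

  ## distance-graded detectability for broad (anciently diverged) genes
  detect_p <- rep(1, n_species)
  if (is.finite(detection_scale)) {
    if (identical(focal_species, "auto"))
      focal_species <- which.min(apply(D, 1, median))
    dfoc <- D[focal_species, ]
    lambda <- detection_scale * max(dfoc)
    detect_p <- exp(-dfoc / lambda)
    detect_p[focal_species] <- 1
  }

  ## clade-specific origins of one module are spread over the tree by
  ## farthest-point sampling among the candidate clades (tip-level
  ## clustering is scattered clumps, not one concentrated region)
  rep_tip <- vapply(clade_nodes, function(nd) {
    d <- desc[[nd]]; d[d <= n_species][1]
  }, integer(1))
  spread_origins <- function(k) {
    chosen <- sample.int(length(clade_nodes), 1)
    while (length(chosen) < k) {
      if (length(chosen) == length(clade_nodes)) {   # recycle when exhausted
        chosen <- c(chosen, sample(chosen, k - length(chosen), replace = TRUE))
        break
      }
      dmin <- apply(D[rep_tip[chosen], rep_tip, drop = FALSE], 2, min)
      dmin[chosen] <- -Inf
      top <- order(dmin, decreasing = TRUE)[seq_len(min(3, sum(is.finite(dmin))))]
      chosen <- c(chosen, top[sample.int(length(top), 1)])
    }
    clade_nodes[chosen]
  }

  rows <- list(); truth <- list()
  for (mt in module_truths) {
    ids <- mt$genes %||% sprintf("%s_g%02d", mt$module_id, seq_len(mt$size))
    origins <- if (identical(mt$depth_class, "broad"))
      rep(root, length(ids))
    else spread_origins(length(ids))
    for (gi in seq_along(ids)) {
      broad <- identical(mt$depth_class, "broad")
      origin <- origins[gi]
      present <- rep(0L, n_species)
      tips <- desc[[origin]]; tips <- tips[tips <= n_species]
      present[tips] <- 1L
      if (loss_probability > 0) {
        se <- subtree_edges(origin)
        lost <- se[runif(length(se)) < loss_probability]
        for (e in lost) {
          dt <- desc[[edge[e, 2]]]
          present[dt[dt <= n_species]] <- 0L
        }
      }
      if (broad && is.finite(detection_scale))
        present <- present * as.integer(runif(n_species) < detect_p)
      rows[[ids[gi]]] <- present
      truth[[length(truth) + 1L]] <- data.frame(
        gene_id = ids[gi], module_id = mt$module_id,
        depth_class = mt$depth_class, origin_node = origin,
        stringsAsFactors = FALSE)
    }
  }

  conservation <- do.call(rbind, rows)
  colnames(conservation) <- tree$tip.label
  structure(list(tree = tree, conservation = conservation,
                 truth = do.call(rbind, truth),
                 loss_probability = loss_probability),
            class = "phylo_truth")
}
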