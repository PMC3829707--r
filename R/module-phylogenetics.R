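## Gene persistence, orthology, per-module species conservation profiles,
## and phylogenetic signal: Blomberg's K with a permutation p-value and
## standardized-effect-size MPD / MNTD against a tip-shuffling null, with
## quadrant classification of modules.

#' Reciprocal-best-hit orthologs
#'
#' `(a, b)` is an ortholog pair iff b is a's best-similarity hit and a is
#' b's, the similarity exceeds `sim_min` in both directions, and the
#' protein length difference `|len(a) - len(b)| / max(len)` is below
#' `len_diff_max`.  Similarity ties are broken by lexicographic subject
#' id.
#'
#' @param hits data frame with columns `query`, `subject`, `similarity`
#'   (percent), `query_length`, `subject_length`, covering both search
#'   directions.
#' @param sim_min minimal similarity percent (default 40).
#' @param len_diff_max maximal relative length difference (default 0.20).
#'
#' @return Data frame of ortholog pairs (`a`, `b`, `similarity_ab`,
#'   `similarity_ba`), with `a < b` lexicographically.
#' @export
bbh_orthologs <- function(hits, sim_min = 40, len_diff_max = 0.20) {
  need <- c("query", "subject", "similarity", "query_length", "subject_length")
  if (!all(need %in% names(hits)))
    stop("hit table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(is.na(hits$query_length)) || any(is.na(hits$subject_length)))
    stop("missing length field in hit table", call. = FALSE)

  ## best hit per query: max similarity, ties to lexicographically
  ## smallest subject
  o <- order(hits$query, -hits$similarity, hits$subject)
  h <- hits[o, ]
  best <- h[!duplicated(h$query), ]
  bmap <- setNames(best$subject, best$query)
  bsim <- setNames(best$similarity, best$query)
  blen_q <- setNames(best$query_length, best$query)
  blen_s <- setNames(best$subject_length, best$query)

  pairs <- list()
  for (q in names(bmap)) {
    s <- bmap[[q]]
    if (q >= s) next                       # visit each unordered pair once
    if (is.na(bmap[s]) || bmap[[s]] != q) next   # not reciprocal
    if (bsim[[q]] <= sim_min || bsim[[s]] <= sim_min) next
    la <- blen_q[[q]]; lb <- blen_s[[q]]
    if (abs(la - lb) / max(la, lb) >= len_diff_max) next
    pairs[[length(pairs) + 1L]] <- data.frame(
      a = q, b = s, similarity_ab = bsim[[q]], similarity_ba = bsim[[s]],
      stringsAsFactors = FALSE)
  }
  if (!length(pairs))
    return(data.frame(a = character(0), b = character(0),
                      similarity_ab = numeric(0), similarity_ba = numeric(0)))
  do.call(rbind, pairs)
}

#' Gene persistence index
#'
#' Number of species in which an ortholog of the gene is found (row sum
#' of the binary conservation matrix), with the conventional bands: less
#' conserved (`PI < 50`), mid, and persistent (`PI > 150`).
#'
#' @param conservation genes x species 0/1 matrix.
#' @param low_cut,high_cut band borders (defaults 50 and 150).
#'
#' @return Data frame: `gene_id`, `pi`, `band`.
#' @export
persistence_index <- function(conservation, low_cut = 50, high_cut = 150) {
  if (!all(conservation %in% c(0, 1)))
    stop("conservation matrix must be binary", call. = FALSE)
  pi <- rowSums(conservation)
  band <- ifelse(pi < low_cut, "low",
                 ifelse(pi > high_cut, "persistent", "mid"))
  data.frame(gene_id = rownames(conservation) %||%
               as.character(seq_along(pi)),
             pi = unname(pi), band = unname(band),
             stringsAsFactors = FALSE)
}

#' Select representative species by clade cutting
#'
#' Cuts the tree at the node depth (distance from the root) whose
#' crossing branches yield the clade count closest to `target_clades`
#' (searching the sorted node depths), then picks one uniformly random
#' tip per clade.
#'
#' @param tree an `ape` phylo object.
#' @param target_clades desired number of clades (about 300 at the study
#'   scale).
#' @param seed integer RNG seed.
#'
#' @return Character vector of representative tip labels (one per clade).
#' @export
select_representatives <- function(tree, target_clades, seed = 1L) {
  .local_seed(seed)
  n <- length(tree$tip.label)
  if (target_clades >= n) return(tree$tip.label)

  depth <- ape::node.depth.edgelength(tree)
  edge <- tree$edge
  clades_at <- function(x)
    which(depth[edge[, 1]] < x & depth[edge[, 2]] >= x)

  cand <- sort(unique(depth[depth > 0]))
  counts <- vapply(cand, function(x) length(clades_at(x)), integer(1))
  x <- cand[which.min(abs(counts - target_clades))]

  ## tips below each crossing branch form one clade
  reps <- vapply(clades_at(x), function(e) {
    node <- edge[e, 2]
    tips <- if (node <= n) node else {
      ex <- ape::extract.clade(tree, node)
      match(ex$tip.label, tree$tip.label)
    }
    tree$tip.label[tips[sample.int(length(tips), 1)]]
  }, character(1))
  unname(reps)
}

#' Per-module species conservation profile
#'
#' Sums the conservation values of the module's member genes in every
#' species: profile(s) = number of member genes with an ortholog in s.
#'
#' @param genes character vector of member gene ids.
#' @param conservation genes x species 0/1 matrix.
#'
#' @return Named integer vector over species.
#' @export
module_species_profile <- function(genes, conservation) {
  if (!length(genes)) stop("module is empty", call. = FALSE)
  missing <- setdiff(genes, rownames(conservation))
  if (length(missing))
    stop("unknown gene id(s): ", paste(head(missing, 5), collapse = ", "),
         call. = FALSE)
  colSums(conservation[genes, , drop = FALSE])
}

#' Blomberg's K with a permutation p-value
#'
#' `K = (MSE0/MSE) / E[MSE0/MSE]` where, with V the Brownian-motion tip
#' covariance implied by the tree, `a = (1'V^-1 y)/(1'V^-1 1)`,
#' `MSE0 = (y-a)'(y-a)/(n-1)`, `MSE = (y-a)'V^-1(y-a)/(n-1)` and
#' `E[MSE0/MSE] = [tr(V) - n/(1'V^-1 1)]/(n-1)`.  K = 1 matches Brownian
#' motion; larger K means stronger phylogenetic signal.  The p-value is
#' the fraction of tip-label permutations whose variance of
#' phylogenetically independent contrasts is at most the observed one
#' (observed included in numerator and denominator).
#'
#' @param tree phylo object with branch lengths.
#' @param trait named numeric vector over the tips.
#' @param n_permutations permutation count for the p-value (default 999).
#' @param seed integer RNG seed.
#'
#' @return List: `K`, `K_p`, `flagged` (TRUE when the trait is constant
#'   and K is undefined).
#' @export
blomberg_k <- function(tree, trait, n_permutations = 999L, seed = 1L) {
  .local_seed(seed)
  n <- length(tree$tip.label)
  y <- trait[tree$tip.label]
  if (any(is.na(y))) stop("trait must be defined on all tips", call. = FALSE)
  if (var(y) == 0)
    return(list(K = NA_real_, K_p = NA_real_, flagged = TRUE))

  V <- ape::vcv(tree)
  Vi <- tryCatch(solve(V), error = function(e)
    stop("singular phylogenetic covariance matrix", call. = FALSE))
  one <- rep(1, n)
  denom1 <- drop(one %*% Vi %*% one)
  a <- drop(one %*% Vi %*% y) / denom1
  r <- y - a
  mse0 <- drop(r %*% r) / (n - 1)
  mse <- drop(r %*% Vi %*% r) / (n - 1)
  expected <- (sum(diag(V)) - n / denom1) / (n - 1)
  K <- (mse0 / mse) / expected

  if (n_permutations < 1)
    return(list(K = K, K_p = NA_real_, flagged = FALSE))
  ptree <- if (ape::is.binary(tree)) tree
    else ape::multi2di(tree, random = FALSE)
  obs <- var(ape::pic(y, ptree))
  perm <- replicate(n_permutations, {
    yp <- setNames(sample(y), ptree$tip.label)
    var(ape::pic(yp, ptree))
  })
  K_p <- (1 + sum(perm <= obs)) / (n_permutations + 1)
  list(K = K, K_p = K_p, flagged = FALSE)
}

#' Standardized-effect-size MPD and MNTD
#'
#' Abundance-weighted mean pairwise distance and mean nearest-taxon
#' distance of the species carrying the module (weights = conservation
#' counts; set `abundance_weighted = FALSE` for presence-only), with a
#' null obtained by shuffling the profile values across tips
#' `n_randomizations` times while the tree (and its distances) stays
#' fixed.  `z = (obs - mean_null) / sd_null`; strongly negative z means
#' the carrying species are phylogenetically clustered.
#'
#' @param profile named per-species counts (a [module_species_profile()]).
#' @param distances patristic species distance matrix (e.g.
#'   `ape::cophenetic.phylo(tree)`); row order defines tip order.
#' @param n_randomizations null draws (default 9999).
#' @param seed integer RNG seed.
#' @param abundance_weighted use counts as weights (default TRUE).
#'
#' @return List: `mpd_obs`, `mpd_z`, `mntd_obs`, `mntd_z`, `flagged`
#'   (TRUE when fewer than two species carry the module).
#' @export
ses_mpd_mntd <- function(profile, distances, n_randomizations = 9999L,
                         seed = 1L, abundance_weighted = TRUE) {
  .local_seed(seed)
  sp <- rownames(distances)
  w <- as.numeric(profile[sp])
  if (any(is.na(w)))
    stop("profile must cover all species in the distance matrix",
         call. = FALSE)
  if (!abundance_weighted) w <- as.numeric(w > 0)
  if (sum(w > 0) < 2)
    return(list(mpd_obs = NA_real_, mpd_z = NA_real_,
                mntd_obs = NA_real_, mntd_z = NA_real_, flagged = TRUE))

  obs <- .mpd_mntd_cpp(distances, w)
  null <- .mpd_mntd_null_cpp(distances, w, as.integer(n_randomizations))
  zs <- function(o, nv) {
    s <- sd(nv)
    if (!is.finite(s) || s == 0) return(0)
    (o - mean(nv)) / s
  }
  list(mpd_obs = unname(obs["mpd"]),
       mpd_z = zs(obs["mpd"], null[, 1]),
       mntd_obs = unname(obs["mntd"]),
       mntd_z = zs(obs["mntd"], null[, 2]),
       flagged = FALSE)
}

#' Quadrant classification of a module
#'
#' At the conventional threshold of -2 on both z-scores (about p = 0.01):
#' quadrant 3 = both MPD and MNTD significantly low (tree-wide
#' clustering, also clustered at the tips); quadrant 2 = MPD low only
#' (tree-wide clustering); quadrant 4 = MNTD low but MPD not (tip-level,
#' clade-specific clustering); quadrant 1 = no significant clustering.
#'
#' @param mpd_z,mntd_z standardized effect sizes.
#' @param threshold significance threshold (default -2, inclusive).
#'
#' @return Integer quadrant in 1..4, or `NA` (flagged) for non-finite
#'   input.
#' @export
classify_quadrant <- function(mpd_z, mntd_z, threshold = -2) {
  if (!is.finite(mpd_z) || !is.finite(mntd_z)) return(NA_integer_)
  if (mpd_z <= threshold) {
    if (mntd_z <= threshold) 3L else 2L
  } else if (mntd_z <= threshold) 4L else 1L
}

#' Compare module contributions of persistent versus other genes
#'
#' Two-sample Kolmogorov-Smirnov test of the gene-contribution
#' distributions, persistent (`PI >= persistent_cut`) versus the rest.
#'
#' @param contributions named per-gene module contributions.
#' @param pi named per-gene persistence index (same gene universe).
#' @param persistent_cut PI cut (default 150).
#'
#' @return List: `ks`, `p`, group sizes, `flagged` when a group is empty
#'   or has a single element.
#' @export
contribution_vs_persistence <- function(contributions, pi,
                                        persistent_cut = 150) {
  genes <- intersect(names(contributions), names(pi))
  cc <- contributions[genes]
  pp <- pi[genes]
  a <- cc[pp >= persistent_cut]
  b <- cc[pp < persistent_cut]
  if (!length(a) || !length(b))
    return(list(ks = NA_real_, p = NA_real_,
                n = c(persistent = length(a), rest = length(b)),
                flagged = TRUE))
  kt <- suppressWarnings(ks.test(a, b))
  list(ks = unname(kt$statistic), p = kt$p.value,
       n = c(persistent = length(a), rest = length(b)),
       flagged = length(a) < 2 || length(b) < 2)
}

#' Phylogenetic signal for every module
#'
#' Runs [module_species_profile()], [blomberg_k()] and [ses_mpd_mntd()]
#' for each module and classifies it into a quadrant.
#'
#' @param modules named list of gene-id vectors (or a `module_set`).
#' @param conservation genes x species 0/1 matrix.
#' @param tree species tree (tips = conservation columns).
#' @param n_randomizations MPD/MNTD null draws (default 9999).
#' @param n_permutations K permutations (default 999).
#' @param threshold quadrant threshold (default -2).
#' @param seed integer RNG seed.
#' @param abundance_weighted weight MPD/MNTD by conservation counts.
#'
#' @return Data frame, one row per module: K, K_p, mpd_z, mntd_z,
#'   quadrant, flags.
#' @export
module_phylo_signal <- function(modules, conservation, tree,
                                n_randomizations = 9999L,
                                n_permutations = 999L,
                                threshold = -2, seed = 1L,
                                abundance_weighted = TRUE) {
  if (inherits(modules, "module_set")) modules <- modules$modules
  dm <- ape::cophenetic.phylo(tree)
  dm <- dm[tree$tip.label, tree$tip.label]
  rows <- lapply(seq_along(modules), function(i) {
    prof <- module_species_profile(modules[[i]], conservation)
    k <- blomberg_k(tree, prof, n_permutations, seed = seed + i)
    s <- ses_mpd_mntd(prof, dm, n_randomizations, seed = seed + i,
                      abundance_weighted = abundance_weighted)
    data.frame(module = names(modules)[i] %||% as.character(i),
               size = length(modules[[i]]),
               K = k$K, K_p = k$K_p,
               mpd_obs = s$mpd_obs, mpd_z = s$mpd_z,
               mntd_obs = s$mntd_obs, mntd_z = s$mntd_z,
               quadrant = if (s$flagged) NA_integer_ else
                 classify_quadrant(s$mpd_z, s$mntd_z, threshold),
               flagged = k$flagged || s$flagged,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
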