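## shared fixtures and small oracles, all built in code

## adjusted Rand index between two labelings
ari <- function(a, b) {
  tab <- table(a, b)
  sn <- sum(choose(tab, 2))
  sa <- sum(choose(rowSums(tab), 2))
  sb <- sum(choose(colSums(tab), 2))
  n <- choose(length(a), 2)
  (sn - sa * sb / n) / ((sa + sb) / 2 - sa * sb / n)
}

## brute-force least-squares segmentation: enumerate every placement of
## k - 1 changepoints and minimize the residual sum of squares
brute_rss <- function(x, k) {
  n <- length(x)
  seg_rss <- function(v) sum((v - mean(v))^2)
  if (k == 1) return(seg_rss(x))
  best <- Inf
  for (cp in utils::combn(n - 1, k - 1, simplify = FALSE)) {
    bounds <- c(0, cp, n)
    rss <- sum(vapply(seq_len(k), function(i)
      seg_rss(x[(bounds[i] + 1):bounds[i + 1]]), numeric(1)))
    if (rss < best) best <- rss
  }
  best
}

## literal triple-loop topological overlap
tom_oracle <- function(a) {
  n <- nrow(a)
  k <- rowSums(a) - 1
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) { out[i, j] <- 1; next }
    s <- 0
    for (u in seq_len(n)) if (u != i && u != j) s <- s + a[i, u] * a[u, j]
    out[i, j] <- (s + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  out
}

## planted-module expression matrix: n_mod modules of mod_size genes with
## unit-variance time-point profiles (pairwise |cor| < 0.7), plus noise
## genes; samples = 5 time points x 3 replicates
planted_module_expr <- function(n_mod = 10, mod_size = 30, n_noise = 50,
                                noise_sd = 0.5, seed = 99) {
  set.seed(seed)
  profs <- matrix(rnorm(5), 1, 5)
  while (nrow(profs) < n_mod) {
    cand <- rnorm(5)
    if (all(abs(cor(cand, t(profs))) < 0.7)) profs <- rbind(profs, cand)
  }
  profs <- t(scale(t(profs)))
  prof15 <- profs[, rep(1:5, each = 3), drop = FALSE]
  truth <- c(rep(seq_len(n_mod), each = mod_size), rep(0, n_noise))
  G <- length(truth)
  expr <- matrix(rnorm(G * 15, 0, noise_sd), G, 15)
  for (i in which(truth > 0)) expr[i, ] <- expr[i, ] + prof15[truth[i], ]
  rownames(expr) <- sprintf("g%03d", seq_len(G))
  colnames(expr) <- sprintf("t%dr%d", rep(1:5, each = 3), rep(1:3, 5))
  list(expr = expr, truth = truth)
}

## tiny coverage experiment built directly (bypassing the generator) so
## unit tests can control every track value
toy_experiment <- function(tracks, annotation, genome_length) {
  T <- length(tracks); R <- length(tracks[[1]])
  structure(list(tracks = tracks, annotation = annotation,
                 genome_length = genome_length,
                 n_timepoints = T, n_replicates = R,
                 gc = NULL, affected_windows = integer(0),
                 window_size = genome_length, truth = NULL),
            class = "coverage_experiment")
}

flat_tracks <- function(T, R, L, value = 0) {
  lapply(seq_len(T), function(t) lapply(seq_len(R), function(r)
    list(`+` = rep(value, L), `-` = rep(value, L))))
}

toy_annotation <- function(starts, ends, strands) {
  data.frame(gene_id = sprintf("g%02d", seq_along(starts)),
             start = starts, end = ends, strand = strands,
             length = ends - starts, dup_group = NA_integer_,
             stringsAsFactors = FALSE)
}
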