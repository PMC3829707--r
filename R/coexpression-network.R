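## Signed weighted co-expression network over CCR genes: soft-thresholded
## signed adjacency, topological overlap, module detection by
## average-linkage clustering of the TOM dissimilarity, module
## eigenvectors with variance explained and gene contributions, and
## module-eigenvector bi-clustering.

#' Signed soft-thresholded adjacency
#'
#' `a_ij = ((1 + cor(x_i, x_j)) / 2)^beta` with Pearson correlation over
#' samples.  The signed transform maps correlation -1 to adjacency 0, so
#' anti-correlated genes are not connected; the large default power
#' (beta = 36) drives all but the strongest positive correlations to
#' effectively zero.
#'
#' @param expr genes x samples matrix.
#' @param beta soft-threshold power (default 36).
#'
#' @return Symmetric genes x genes adjacency matrix with unit diagonal.
#' @export
signed_adjacency <- function(expr, beta = 36) {
  if (ncol(expr) < 2) stop("need at least 2 samples per gene", call. = FALSE)
  v <- apply(expr, 1, var)
  if (any(v == 0))
    stop("zero-variance gene(s): ",
         paste(head(rownames(expr)[v == 0] %||% which(v == 0), 5),
               collapse = ", "), call. = FALSE)
  a <- ((1 + cor(t(expr))) / 2)^beta
  diag(a) <- 1
  a
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' the sum over u distinct from i and j and `k_i` the connectivity of
#' gene i; the diagonal is 1 by convention.  Genes overlap when they share
#' neighbors even if their direct adjacency is modest.
#'
#' @param adjacency symmetric adjacency in `[0, 1]` with unit diagonal.
#'
#' @return Symmetric TOM matrix in `[0, 1]`.
#' @export
topological_overlap <- function(adjacency) {
  a <- adjacency
  n <- nrow(a)
  k <- rowSums(a) - 1
  shared <- a %*% a - 2 * a   # removes u = i and u = j terms (diag = 1)
  kmin <- outer(k, k, pmin)
  tom <- (shared + a) / (kmin + 1 - a)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  tom
}

#' Detect co-expression modules
#'
#' Average-linkage hierarchical clustering of the dissimilarity `1 - TOM`,
#' cut at a fixed fraction of the maximal merge height; clusters smaller
#' than `min_size` are pooled as unassigned (module 0).  Deterministic
#' given the input.
#'
#' @param tom topological overlap matrix.
#' @param min_size minimal module size (default 5).
#' @param cut_height cut as a fraction of the maximal merge height
#'   (default 0.995).
#'
#' @return Object of class `module_set`: integer `labels` (0 =
#'   unassigned), list `modules` of gene-name vectors, and the dendrogram.
#' @export
detect_modules <- function(tom, min_size = 5L, cut_height = 0.995) {
  stopifnot(nrow(tom) >= min_size)
  d <- as.dist(1 - tom)
  h <- hclust(d, method = "average")
  cut <- cut_height * max(h$height)
  raw <- cutree(h, h = cut)
  tab <- table(raw)
  keep <- as.integer(names(tab)[tab >= min_size])
  labels <- integer(length(raw))
  for (i in seq_along(keep)) labels[raw == keep[i]] <- i
  ## stable ids: order modules by size, largest first
  if (length(keep)) {
    sizes <- table(labels[labels > 0])
    ord <- order(-sizes)
    remap <- integer(length(keep)); remap[ord] <- seq_along(keep)
    labels[labels > 0] <- remap[labels[labels > 0]]
  }
  names(labels) <- rownames(tom)
  modules <- split(names(labels)[labels > 0], labels[labels > 0])
  structure(list(labels = labels, modules = modules, tree = h,
                 min_size = min_size, cut_height = cut_height),
            class = "module_set")
}

#' Module eigenvector, variance explained and gene contributions
#'
#' Each member gene's profile is scaled to mean 0, sd 1 over samples; the
#' module eigenvector is the first right singular vector of the scaled
#' matrix, the variance explained is the first squared singular value over
#' the total, and a gene's contribution is the projection of its scaled
#' profile on the eigenvector, normalized so the absolute contributions
#' sum to 1.  The eigenvector sign is oriented so the mean contribution is
#' positive.
#'
#' @param expr samples-column matrix of the module's genes (>= 2 genes).
#'
#' @return List: `eigenvector` (length = samples), `variance_explained`,
#'   `contributions` (named per gene).
#' @export
module_eigenvector <- function(expr) {
  if (nrow(expr) < 2) stop("module must have >= 2 genes", call. = FALSE)
  s <- apply(expr, 1, sd)
  if (any(s == 0))
    stop("constant gene in module: scaling undefined", call. = FALSE)
  x <- t(scale(t(expr)))   # genes x samples, rows standardized
  sv <- svd(x)
  v <- sv$v[, 1]
  ve <- sv$d[1]^2 / sum(sv$d^2)
  contrib <- drop(x %*% v)
  if (mean(contrib) < 0) { v <- -v; contrib <- -contrib }
  contrib <- contrib / sum(abs(contrib))
  names(contrib) <- rownames(expr)
  list(eigenvector = v, variance_explained = ve, contributions = contrib)
}

#' Summarize all modules of a module set
#'
#' @param ms a `module_set`.
#' @param expr genes x samples matrix (superset of module genes).
#'
#' @return The `module_set` with `eigenvectors` (samples x modules),
#'   `variance_explained` and `contributions` filled in.
#' @export
module_eigenvectors <- function(ms, expr) {
  stopifnot(inherits(ms, "module_set"))
  res <- lapply(ms$modules, function(g)
    module_eigenvector(expr[g, , drop = FALSE]))
  ms$eigenvectors <- vapply(res, `[[`, numeric(ncol(expr)), "eigenvector")
  ms$variance_explained <- vapply(res, `[[`, numeric(1), "variance_explained")
  ms$contributions <- unlist(lapply(res, `[[`, "contributions"))
  names(ms$contributions) <- unlist(lapply(res, function(r)
    names(r$contributions)))
  ms
}

#' Bi-cluster module eigenvectors
#'
#' Pairwise Pearson correlations of the module eigenvectors (collapsed to
#' per-time-point means), ordered by average-linkage clustering and
#' grouped at a 3-cluster cut: cell-cycle modules fall into a few large
#' phase groups peaking at different stages.
#'
#' @param ms a `module_set` with eigenvectors.
#' @param layout sample layout (`timepoint` column) used to collapse
#'   replicates; `NULL` keeps raw sample profiles.
#' @param k number of groups for the cut (default 3).
#'
#' @return List: `correlation` (ordered matrix), `order`, `groups`.
#' @export
cluster_module_eigenvectors <- function(ms, layout = NULL, k = 3L) {
  stopifnot(inherits(ms, "module_set"), !is.null(ms$eigenvectors))
  ev <- ms$eigenvectors
  if (ncol(ev) < 2) stop("need at least 2 modules", call. = FALSE)
  if (!is.null(layout)) {
    tps <- sort(unique(layout$timepoint))
    ev <- vapply(tps, function(t)
      colMeans(ev[layout$timepoint == t, , drop = FALSE]),
      numeric(ncol(ev)))
    ev <- t(ev)   # timepoints x modules
  }
  cc <- cor(ev)
  h <- hclust(as.dist(1 - cc), method = "average")
  groups <- cutree(h, k = min(k, ncol(cc)))
  list(correlation = cc[h$order, h$order], order = h$order,
       groups = groups, tree = h)
}

#' Select samples for network construction
#'
#' Drops, within each named time point, the replicate whose expression
#' profile has the largest median distance to its peers (replicate outlier
#' removal before network construction; the time points to prune default
#' to the first three).
#'
#' @param em an `expression_matrix`.
#' @param drop_timepoints time points to prune one replicate from.
#'
#' @return Logical mask over samples (TRUE = keep).
#' @export
select_network_samples <- function(em, drop_timepoints = c(1L, 2L, 3L)) {
  stopifnot(inherits(em, "expression_matrix"))
  keep <- rep(TRUE, ncol(em$values))
  lx <- log1p(em$values)
  for (t in drop_timepoints) {
    cols <- which(em$layout$timepoint == t)
    if (length(cols) < 3) next
    d <- as.matrix(dist(t(lx[, cols, drop = FALSE])))
    med <- apply(d, 1, function(r) median(r[r > 0]))
    keep[cols[which.max(med)]] <- FALSE
  }
  keep
}
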