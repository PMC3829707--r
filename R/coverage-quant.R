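## Replicate coverage tracks -> gene expression: split normalization,
## per-nucleotide CV, exact DP segmentation of the CV signal, CV > 1
## filtering, and mean-coverage quantification over retained nucleotides.

.strands <- c("+", "-")

## per-strand logical footprint of a gene set
.footprint <- function(annotation, genes, L) {
  out <- list(`+` = logical(L), `-` = logical(L))
  for (g in genes) {
    idx <- (annotation$start[g] + 1L):annotation$end[g]
    out[[annotation$strand[g]]][idx] <- TRUE
  }
  out
}

#' Split normalization of replicate coverage
#'
#' Genes are partitioned by their provisional mean depth into a bulk
#' (<= `split_threshold`) and a highly expressed (> `split_threshold`)
#' set, and every (time point, replicate) sample is rescaled so that its
#' summed coverage over each partition's gene footprint equals the mean of
#' those sums across samples.  Highly expressed genes concentrate a large,
#' sample-variable share of the reads, so normalizing both partitions by a
#' single sum would distort the bulk; the two are therefore scaled
#' separately.  Intergenic positions follow the bulk scaling.
#'
#' @param experiment a `coverage_experiment`.
#' @param split_threshold depth (x-fold) separating the partitions
#'   (default 1000).
#'
#' @return The experiment with rescaled tracks; per-sample scale factors
#'   are stored in `$norm_factors`.
#' @export
normalize_split <- function(experiment, split_threshold = 1000) {
  stopifnot(inherits(experiment, "coverage_experiment"))
  ann <- experiment$annotation
  L <- experiment$genome_length
  T <- experiment$n_timepoints; R <- experiment$n_replicates

  ## provisional per-gene mean depth over all samples
  prov <- vapply(seq_len(nrow(ann)), function(g) {
    idx <- (ann$start[g] + 1L):ann$end[g]
    s <- ann$strand[g]
    tot <- 0
    for (t in seq_len(T)) for (r in seq_len(R))
      tot <- tot + mean(experiment$tracks[[t]][[r]][[s]][idx])
    tot / (T * R)
  }, numeric(1))

  high <- which(prov > split_threshold)
  low <- setdiff(seq_len(nrow(ann)), high)
  fp_high <- .footprint(ann, high, L)
  fp_low <- .footprint(ann, low, L)
  ## bulk scaling also covers intergenic positions
  fp_bulk <- list(`+` = !fp_high$`+`, `-` = !fp_high$`-`)

  part_sum <- function(t, r, fp) {
    sum(experiment$tracks[[t]][[r]][["+"]][fp$`+`]) +
      sum(experiment$tracks[[t]][[r]][["-"]][fp$`-`])
  }

  sums_low <- matrix(0, T, R)
  sums_high <- matrix(0, T, R)
  for (t in seq_len(T)) for (r in seq_len(R)) {
    sums_low[t, r] <- part_sum(t, r, fp_low)
    if (length(high)) sums_high[t, r] <- part_sum(t, r, fp_high)
  }
  if (length(low) && any(sums_low == 0)) {
    bad <- which(sums_low == 0, arr.ind = TRUE)[1, ]
    stop(sprintf("replicate t%dr%d has zero coverage over the bulk partition",
                 bad[1], bad[2]), call. = FALSE)
  }
  if (length(high) && any(sums_high == 0)) {
    bad <- which(sums_high == 0, arr.ind = TRUE)[1, ]
    stop(sprintf("replicate t%dr%d has zero coverage over the high partition",
                 bad[1], bad[2]), call. = FALSE)
  }

  f_low <- if (length(low)) mean(sums_low) / sums_low else matrix(1, T, R)
  f_high <- if (length(high)) mean(sums_high) / sums_high else matrix(1, T, R)

  out <- experiment
  for (t in seq_len(T)) for (r in seq_len(R)) for (s in .strands) {
    v <- experiment$tracks[[t]][[r]][[s]]
    v[fp_bulk[[s]]] <- v[fp_bulk[[s]]] * f_low[t, r]
    if (length(high)) v[fp_high[[s]]] <- v[fp_high[[s]]] * f_high[t, r]
    out$tracks[[t]][[r]][[s]] <- v
  }
  out$norm_factors <- list(bulk = f_low, high = f_high,
                           high_genes = ann$gene_id[high],
                           split_threshold = split_threshold)
  out
}

#' Per-nucleotide coefficient of variation across replicates
#'
#' Sample standard deviation over the replicates of one time point divided
#' by their mean, per nucleotide and strand.  Positions where the
#' replicate mean is 0 get CV = 0: replicates that consistently observe
#' nothing are consistent, so silent regions are retained downstream.
#'
#' @param experiment a `coverage_experiment` (normalized or not).
#' @param timepoint time point index.
#'
#' @return A list of class `cv_track` with per-strand CV vectors.
#' @export
compute_cv <- function(experiment, timepoint) {
  stopifnot(inherits(experiment, "coverage_experiment"))
  R <- experiment$n_replicates
  if (R < 2) stop("at least 2 replicates are required to compute a CV",
                  call. = FALSE)
  out <- list()
  for (s in .strands) {
    reps <- lapply(seq_len(R), function(r)
      experiment$tracks[[timepoint]][[r]][[s]])
    m <- Reduce(`+`, reps) / R
    ss <- Reduce(`+`, lapply(reps, function(v) (v - m)^2)) / (R - 1)
    cv <- ifelse(m > 0, sqrt(ss) / m, 0)
    out[[s]] <- cv
  }
  structure(out, class = "cv_track", timepoint = timepoint)
}

#' Exact least-squares segmentation of a signal
#'
#' Dynamic-programming segmentation into piecewise-constant segments: for
#' every segment count k up to `max_segments` the changepoints minimizing
#' the residual sum of squares are found exactly, and k is selected by the
#' Bayesian information criterion `n*ln(RSS/n) + k*ln(n)` (ties broken
#' toward fewer segments).
#'
#' @param values numeric signal (here: a CV track).
#' @param max_segments maximal number of segments (clipped to `length(values)`
#'   with a warning).
#'
#' @return An object of class `segmentation`: data frame `segments` with
#'   0-based half-open bounds and per-segment mean, the chosen `k`, and the
#'   RSS path over k.
#' @export
segment_signal <- function(values, max_segments) {
  n <- length(values)
  if (n == 0) stop("empty signal", call. = FALSE)
  if (max_segments < 1) stop("max_segments must be >= 1", call. = FALSE)
  if (max_segments > n) {
    warning("max_segments exceeds signal length; clipped to ", n)
    max_segments <- n
  }
  dp <- .segment_dp_cpp(as.numeric(values), as.integer(max_segments))
  bic <- n * log(pmax(dp$rss, 1e-12) / n) +
    seq_len(max_segments) * log(n)
  k <- which.min(bic)
  cps <- if (k == 1) integer(0)
    else .segment_backtrack_cpp(dp$arg, n, as.integer(k))
  bounds <- c(0L, cps, n)
  segments <- data.frame(
    start = bounds[-length(bounds)],
    end = bounds[-1]
  )
  segments$mean <- vapply(seq_len(nrow(segments)), function(i)
    mean(values[(segments$start[i] + 1L):segments$end[i]]), numeric(1))
  structure(list(segments = segments, k = k, rss = dp$rss, n = n),
            class = "segmentation")
}

#' Segment a whole-genome CV track in windows
#'
#' The exact DP is quadratic in window length, so the track is processed
#' in fixed windows (default 2 kb) with `max(2, window_length/250)`
#' segments allowed per window; per-window exactness is preserved and the
#' segment lists are concatenated.
#'
#' @param values full-length CV vector.
#' @param window window size in nt (default 2000).
#'
#' @return A `segmentation` whose bounds cover `[0, length(values))`.
#' @export
segment_cv_track <- function(values, window = 2000L) {
  n <- length(values)
  starts <- seq(0L, n - 1L, by = window)
  pieces <- lapply(starts, function(s0) {
    e0 <- min(s0 + window, n)
    len <- e0 - s0
    seg <- segment_signal(values[(s0 + 1L):e0],
                          max_segments = max(2L, floor(len / 250)))
    df <- seg$segments
    df$start <- df$start + s0
    df$end <- df$end + s0
    df
  })
  segments <- do.call(rbind, pieces)
  structure(list(segments = segments, k = nrow(segments), rss = NULL, n = n),
            class = "segmentation")
}

#' Filter segments by mean CV
#'
#' Discards every nucleotide belonging to a segment whose mean CV exceeds
#' the threshold; all other nucleotides (including zero-CV silent regions)
#' are retained.
#'
#' @param segmentation a `segmentation`.
#' @param cv_threshold CV cutoff (default 1.0).
#'
#' @return Logical vector over the analyzed interval: `TRUE` = retained.
#' @export
filter_segments <- function(segmentation, cv_threshold = 1.0) {
  stopifnot(inherits(segmentation, "segmentation"))
  seg <- segmentation$segments
  keep <- logical(segmentation$n)
  for (i in seq_len(nrow(seg)))
    if (seg$mean[i] <= cv_threshold)
      keep[(seg$start[i] + 1L):seg$end[i]] <- TRUE
  keep
}

## retained masks per (timepoint, strand)
.retained_masks <- function(experiment, cv_threshold, window) {
  lapply(seq_len(experiment$n_timepoints), function(t) {
    cv <- compute_cv(experiment, t)
    lapply(setNames(.strands, .strands), function(s)
      filter_segments(segment_cv_track(cv[[s]], window), cv_threshold))
  })
}

#' Quantify gene expression from retained nucleotides
#'
#' Expression of gene g in sample (t, r) is the mean coverage, on g's
#' strand, over the nucleotides of g retained by the CV filter at time
#' point t.  Genes with no retained nucleotide fall back to the unfiltered
#' mean and are flagged.
#'
#' @param experiment a (normalized) `coverage_experiment`.
#' @param retained optional list (per time point) of per-strand logical
#'   retention masks; computed from `cv_threshold` and `window` when
#'   omitted.
#' @param cv_threshold CV cutoff for [filter_segments()] (default 1.0).
#' @param window segmentation window for [segment_cv_track()] (default
#'   2000 nt).
#'
#' @return An object of class `expression_matrix`: `values` (genes x
#'   samples matrix, columns t1r1..tTrR), `layout`, per-gene
#'   `retained_fraction`, `fallback` flags and the annotation.
#' @export
quantify_genes <- function(experiment, retained = NULL, cv_threshold = 1.0,
                           window = 2000L) {
  stopifnot(inherits(experiment, "coverage_experiment"))
  ann <- experiment$annotation
  L <- experiment$genome_length
  if (any(ann$start < 0) || any(ann$end > L))
    stop("gene outside genome bounds", call. = FALSE)
  T <- experiment$n_timepoints; R <- experiment$n_replicates
  if (is.null(retained))
    retained <- .retained_masks(experiment, cv_threshold, window)

  G <- nrow(ann)
  values <- matrix(0, G, T * R,
                   dimnames = list(ann$gene_id, .sample_names(T, R)))
  rfrac <- matrix(0, G, T)
  fallback <- matrix(FALSE, G, T)
  for (g in seq_len(G)) {
    idx <- (ann$start[g] + 1L):ann$end[g]
    s <- ann$strand[g]
    for (t in seq_len(T)) {
      keep <- retained[[t]][[s]][idx]
      rfrac[g, t] <- mean(keep)
      use <- if (any(keep)) idx[keep] else idx
      fallback[g, t] <- !any(keep)
      for (r in seq_len(R))
        values[g, (t - 1L) * R + r] <-
          mean(experiment$tracks[[t]][[r]][[s]][use])
    }
  }

  structure(list(values = values,
                 layout = .sample_layout(T, R),
                 retained_fraction = rowMeans(rfrac),
                 retained_fraction_tp = rfrac,
                 fallback = fallback,
                 annotation = ann),
            class = "expression_matrix")
}

#' Per-time-point mean expression
#'
#' @param em an `expression_matrix`.
#' @return Genes x time points matrix of replicate means.
#' @export
timepoint_means <- function(em) {
  stopifnot(inherits(em, "expression_matrix"))
  .timepoint_means(em$values, em$layout)
}
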