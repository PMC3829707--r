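## Global expression structure: power-law fit of the expression
## distribution, smoothed CV-versus-expression curve, three expression
## groups, and the expression/persistence comparison.

#' Continuous power-law fit by maximum likelihood
#'
#' Fits `p(e) ~ e^-alpha` to the tail `x >= xmin` with the continuous
#' maximum-likelihood estimator `alpha = 1 + n / sum(log(x/xmin))`.  When
#' `xmin` is not given it is chosen, following Clauset et al's procedure,
#' to minimize the Kolmogorov-Smirnov distance between the tail data and
#' the fitted law.
#'
#' @param values positive expression values.
#' @param xmin optional lower cutoff; estimated when `NULL`.
#' @param max_candidates cap on the number of xmin candidates scanned
#'   (evenly spaced quantiles of the unique values).
#'
#' @return Object of class `power_law_fit`: `alpha`, `xmin`, `n_tail`,
#'   `ks_distance`.
#' @export
fit_power_law <- function(values, xmin = NULL, max_candidates = 100L) {
  x <- values[is.finite(values) & values > 0]
  if (length(x) < 10) stop("need at least 10 positive values", call. = FALSE)

  fit_at <- function(xm) {
    tail <- sort(x[x >= xm])
    n <- length(tail)
    if (n < 10) return(NULL)
    ls <- sum(log(tail / xm))
    if (ls <= 0) stop("all tail values equal: exponent undefined",
                      call. = FALSE)
    alpha <- 1 + n / ls
    theo <- 1 - (tail / xm)^(1 - alpha)
    emp_hi <- seq_len(n) / n
    emp_lo <- (seq_len(n) - 1) / n
    ks <- max(pmax(abs(theo - emp_hi), abs(theo - emp_lo)))
    list(alpha = alpha, xmin = xm, n_tail = n, ks_distance = ks)
  }

  if (!is.null(xmin)) {
    fit <- fit_at(xmin)
    if (is.null(fit)) stop("fewer than 10 values above xmin", call. = FALSE)
  } else {
    cand <- sort(unique(x))
    cand <- cand[seq_len(max(1L, length(cand) - 9L))] # keep >= 10 in tail
    if (length(cand) > max_candidates)
      cand <- cand[unique(round(seq(1, length(cand),
                                    length.out = max_candidates)))]
    fits <- Filter(Negate(is.null), lapply(cand, fit_at))
    if (!length(fits)) stop("no admissible xmin candidate", call. = FALSE)
    fit <- fits[[which.min(vapply(fits, `[[`, numeric(1), "ks_distance"))]]
  }
  structure(fit, class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("power-law fit: alpha = %.3f, xmin = %.3g (n_tail = %d, KS = %.4f)\n",
              x$alpha, x$xmin, x$n_tail, x$ks_distance))
  invisible(x)
}

#' Local regression of CV against expression
#'
#' Tricube-weighted local linear regression (LOESS, degree 1) of per-gene
#' CV on log expression, evaluable at arbitrary expression values through
#' monotone interpolation between the fitted points.
#'
#' @param expression per-gene pooled expression values (positive).
#' @param cv per-gene pooled CV values.
#' @param span LOESS span in `(0, 1]` (default 0.3).
#'
#' @return A function of class `cv_smooth` mapping expression to smoothed
#'   CV.
#' @export
smooth_cv_vs_expression <- function(expression, cv, span = 0.3) {
  if (!is.numeric(span) || length(span) != 1 || span <= 0 || span > 1)
    stop("span must be in (0, 1]", call. = FALSE)
  ok <- is.finite(expression) & expression > 0 & is.finite(cv)
  if (sum(ok) < 20) stop("need at least 20 genes", call. = FALSE)
  lx <- log(expression[ok]); y <- cv[ok]
  fit <- loess(y ~ lx, span = span, degree = 1,
               control = loess.control(surface = "direct"))
  xs <- sort(unique(lx))
  ys <- predict(fit, data.frame(lx = xs))
  f <- function(e) approx(xs, ys, xout = log(e), rule = 2)$y
  structure(f, class = c("cv_smooth", "function"),
            span = span, x = exp(xs), fitted = ys)
}

#' Classify genes into low / bulk / high expression groups
#'
#' A gene is `low` when its maximal per-time-point mean expression stays
#' below `low_cut` (default 5x: likely background transcription), `high`
#' when its pooled mean exceeds `high_cut` (default 1000x), and `bulk`
#' otherwise.  Per-gene CV is the mean of the per-time-point replicate
#' CVs; per-group mean CVs are reported.
#'
#' @param em an `expression_matrix`.
#' @param low_cut,high_cut thresholds in x-fold coverage (5 and 1000).
#'
#' @return Object of class `expression_groups`: per-gene `label`, pooled
#'   expression, per-gene CV, group sizes and group mean CVs.
#' @export
classify_groups <- function(em, low_cut = 5, high_cut = 1000) {
  stopifnot(inherits(em, "expression_matrix"))
  tpm <- timepoint_means(em)
  pooled <- rowMeans(em$values)
  gcv <- gene_cv(em)
  label <- ifelse(apply(tpm, 1, max) < low_cut, "low",
                  ifelse(pooled > high_cut, "high", "bulk"))
  group_mean_cv <- vapply(c(low = "low", bulk = "bulk", high = "high"),
                          function(l) mean(gcv[label == l]), numeric(1))
  structure(list(label = label, pooled_expression = pooled,
                 gene_cv = gcv,
                 thresholds = c(low_cut = low_cut, high_cut = high_cut),
                 sizes = table(factor(label, c("low", "bulk", "high"))),
                 group_mean_cv = group_mean_cv),
            class = "expression_groups")
}

#' Per-gene CV pooled over time points
#'
#' Mean over the time points of the replicate CV (sd/mean, 0 where the
#' mean is 0) of each gene.
#'
#' @param em an `expression_matrix`.
#' @return Named numeric vector of per-gene CVs.
#' @export
gene_cv <- function(em) {
  stopifnot(inherits(em, "expression_matrix"))
  tps <- sort(unique(em$layout$timepoint))
  percv <- vapply(tps, function(t) {
    sub <- em$values[, em$layout$timepoint == t, drop = FALSE]
    m <- rowMeans(sub)
    s <- apply(sub, 1, sd)
    ifelse(m > 0, s / m, 0)
  }, numeric(nrow(em$values)))
  rowMeans(percv)
}

#' Compare expression between persistence partitions
#'
#' Splits genes into less conserved (`PI < low_cut`) and persistent
#' (`PI > high_cut`) partitions and reports group medians, a Welch t
#' statistic on expression, and a chi-square statistic on the 2x2 table of
#' partition versus expression above/below the overall median.  Pure
#' reporting; no decision logic.
#'
#' @param expression per-gene pooled expression.
#' @param persistence_index per-gene persistence index (same order).
#' @param low_cut,high_cut PI borders (defaults 50 and 150).
#'
#' @return List with medians, statistics, p-values, partition sizes, and a
#'   `flagged` marker when a partition is empty.
#' @export
compare_expression_by_conservation <- function(expression, persistence_index,
                                               low_cut = 50, high_cut = 150) {
  stopifnot(length(expression) == length(persistence_index))
  less <- expression[persistence_index < low_cut]
  pers <- expression[persistence_index > high_cut]
  flagged <- length(less) == 0 || length(pers) == 0
  if (flagged) {
    return(list(medians = c(persistent = NA_real_, less_conserved = NA_real_),
                t = NA_real_, t_p = NA_real_,
                chisq = NA_real_, chisq_p = NA_real_,
                n = c(persistent = length(pers), less_conserved = length(less)),
                flagged = TRUE))
  }
  tt <- if (sd(pers) == 0 && sd(less) == 0 && median(pers) == median(less))
    list(statistic = c(t = 0), p.value = 1)
  else t.test(pers, less)
  med <- median(expression)
  tab <- rbind(persistent = c(sum(pers > med), sum(pers <= med)),
               less = c(sum(less > med), sum(less <= med)))
  cs <- suppressWarnings(chisq.test(tab))
  list(medians = c(persistent = median(pers), less_conserved = median(less)),
       t = unname(tt$statistic), t_p = tt$p.value,
       chisq = unname(cs$statistic), chisq_p = cs$p.value,
       n = c(persistent = length(pers), less_conserved = length(less)),
       flagged = FALSE)
}
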