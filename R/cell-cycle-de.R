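## Detection of cell-cycle-regulated (CCR) genes: enumerated up/down
## time-course patterns, empirical priors sampled from the data, and
## negative-binomial posterior model selection with iteratively estimated
## model weights.

#' Enumerate time-course model patterns
#'
#' Every assignment of the ordered time points to contiguous equal-mean
#' blocks (one bit per boundary between consecutive time points, hence
#' `2^(T-1)` blockings), plus one distinguished `silent` model for genes
#' expressed near zero throughout.  The blocking with no boundary is the
#' flat (constant expression) model; all others are differential.  For
#' T = 5 this gives 17 models.
#'
#' @param n_timepoints number of ordered time points (>= 2).
#'
#' @return List of models, each a list with `pattern_id` (e.g. `"12|345"`),
#'   `blocks` (block index per time point) and `kind` (`flat`,
#'   `differential` or `silent`).
#' @export
enumerate_models <- function(n_timepoints = 5L) {
  T <- as.integer(n_timepoints)
  stopifnot(T >= 2)
  models <- list()
  for (code in 0:(2^(T - 1) - 1)) {
    bits <- as.integer(intToBits(code))[seq_len(T - 1)]
    blocks <- cumsum(c(1L, bits))
    id <- paste(tapply(seq_len(T), blocks, paste, collapse = ""),
                collapse = "|")
    models[[length(models) + 1L]] <- list(
      pattern_id = id, blocks = blocks,
      kind = if (all(bits == 0)) "flat" else "differential")
  }
  models[[length(models) + 1L]] <- list(
    pattern_id = "silent", blocks = rep(1L, T), kind = "silent")
  models
}

.as_counts <- function(counts) {
  if (inherits(counts, "expression_matrix"))
    list(y = round(counts$values), layout = counts$layout)
  else stop("counts must be an expression_matrix", call. = FALSE)
}

#' Estimate empirical priors for the model set
#'
#' For each model, `Q` genes are sampled from the data; per sampled gene
#' and per block of the model, method-of-moments negative-binomial (mean,
#' dispersion) estimates over the block's observations form the discrete
#' prior support.  The silent model's mean is fixed at the 5th percentile
#' of the nonzero gene means (background level); its dispersions are the
#' sampled genes' pooled estimates.
#'
#' @param em an `expression_matrix` (expression values are rounded to
#'   integer counts; the split normalization preserves scale).
#' @param models model list from [enumerate_models()].
#' @param Q prior sample size per model (default 100; clipped to the
#'   number of genes).
#' @param seed integer RNG seed.
#'
#' @return Object of class `empirical_prior`.
#' @export
estimate_priors <- function(em, models, Q = 100L, seed = 1L) {
  cl <- .as_counts(em)
  y <- cl$y; layout <- cl$layout
  G <- nrow(y)
  if (G < 50) stop("need at least 50 genes to estimate priors", call. = FALSE)
  .local_seed(seed)
  if (Q > G) Q <- G

  gm <- rowMeans(y)
  silent_mu <- unname(quantile(gm[gm > 0], 0.05))

  ## block means per sampled gene; dispersion pooled over the gene's
  ## residuals around its block means (per-block moments on 3 replicates
  ## are too unstable and collapse to Poisson)
  pooled_disp <- function(obs, fit) {
    ok <- fit > 0
    if (!any(ok)) return(0)
    d <- sum(((obs[ok] - fit[ok])^2 - fit[ok]) / fit[ok]^2) / sum(ok)
    min(max(d, 0), 5)
  }

  support <- lapply(models, function(mod) {
    idx <- sample.int(G, Q)
    B <- max(mod$blocks)
    mu <- matrix(0, Q, B); disp <- matrix(0, Q, B)
    for (q in seq_len(Q)) {
      obs <- y[idx[q], ]
      if (mod$kind == "silent") {
        mu[q, 1] <- silent_mu
        disp[q, 1] <- pooled_disp(obs, rep(mean(obs), length(obs)))
      } else {
        bm <- vapply(seq_len(B), function(b)
          mean(obs[layout$timepoint %in% which(mod$blocks == b)]),
          numeric(1))
        mu[q, ] <- bm
        fit <- bm[mod$blocks[layout$timepoint]]
        disp[q, ] <- pooled_disp(obs, fit)
      }
    }
    list(mean = mu, disp = disp, genes = idx)
  })

  structure(list(models = models, support = support, Q = Q,
                 silent_mu = silent_mu, seed = seed),
            class = "empirical_prior")
}

#' Posterior model probabilities per gene
#'
#' The marginal likelihood of a gene under a model is the average, over
#' the model's prior samples, of the product of negative-binomial
#' likelihoods with block-shared means.  By default each prior sample's
#' means are rescaled so its expected total matches the gene's observed
#' total (a library-scaling step that makes the empirical prior scale
#' free; the rescaled level is bounded below by twice the background mean
#' so the silent model keeps ownership of the near-zero regime).  Model
#' weights are estimated by iterating `weight = mean posterior across
#' genes` to convergence, and posteriors are normalized per gene.
#'
#' @param em an `expression_matrix`.
#' @param models model list from [enumerate_models()].
#' @param priors an `empirical_prior` from [estimate_priors()].
#' @param prior_weights optional initial model weights.
#' @param rescale rescale prior means to the gene's level (default TRUE).
#' @param bootstraps rounds of prior re-weighting: after each posterior
#'   pass, each model's prior samples are re-weighted by their own genes'
#'   posterior probability of following that model, so a differential
#'   model's prior concentrates on genuinely differential genes (default
#'   3, at which point the re-weighting has stabilized).
#' @param tol,max_iter weight-iteration convergence controls.
#'
#' @return Object of class `ccr_result`: per-gene posterior matrix,
#'   `ccr_likelihood` (summed posterior over differential models),
#'   `best_pattern`, estimated weights and flags.
#' @export
posterior_likelihoods <- function(em, models, priors, prior_weights = NULL,
                                  rescale = TRUE, bootstraps = 3L,
                                  tol = 1e-6, max_iter = 100L) {
  cl <- .as_counts(em)
  y <- cl$y; layout <- cl$layout
  G <- nrow(y); S <- ncol(y)
  M <- length(models)
  Q <- priors$Q
  total <- rowSums(y)
  mu_floor <- 2 * priors$silent_mu

  ## per-model gene x prior-sample log-likelihoods, computed once
  ll_list <- vector("list", M)
  for (m in seq_len(M)) {
    mod <- models[[m]]
    sup <- priors$support[[m]]
    ll <- matrix(0, G, Q)
    blk <- mod$blocks[layout$timepoint]   # block index per sample column
    for (q in seq_len(Q)) {
      mu_base <- sup$mean[q, blk]
      disp <- pmax(sup$disp[q, blk], 1e-6)
      if (mod$kind == "silent") {
        mu <- matrix(mu_base, G, S, byrow = TRUE)
      } else if (rescale) {
        tb <- sum(mu_base)
        scale <- if (tb > 0) pmax(total, S * mu_floor) / tb else rep(1, G)
        mu <- outer(scale, mu_base)
      } else {
        mu <- matrix(mu_base, G, S, byrow = TRUE)
      }
      mu <- pmax(mu, 1e-8)
      sz <- matrix(1 / disp, G, S, byrow = TRUE)
      ll[, q] <- rowSums(matrix(dnbinom(y, size = sz, mu = mu, log = TRUE),
                                G, S))
    }
    ll_list[[m]] <- ll
  }

  ## marginal likelihood = weighted average over prior samples; sample
  ## weights start uniform and are re-weighted by the sampled genes' own
  ## posteriors in each bootstrap round
  u <- lapply(seq_len(M), function(m) rep(1 / Q, Q))
  w <- prior_weights %||% rep(1 / M, M)
  post <- matrix(NA_real_, G, M)
  flagged <- rep(FALSE, G)

  for (boot in seq_len(bootstraps + 1L)) {
    logml <- matrix(-Inf, G, M)
    for (m in seq_len(M)) {
      lu <- sweep(ll_list[[m]], 2, log(u[[m]]), `+`)
      mx <- apply(lu, 1, max)
      logml[, m] <- mx + log(rowSums(exp(lu - mx)))
      logml[!is.finite(mx), m] <- -Inf
    }
    flagged <- !is.finite(apply(logml, 1, max))
    est <- which(!flagged)

    for (it in seq_len(max_iter)) {
      lw <- sweep(logml, 2, log(w), `+`)
      mx <- apply(lw, 1, max)
      p <- exp(lw - mx)
      p <- p / rowSums(p)
      wn <- colMeans(p[est, , drop = FALSE])
      wn <- wn / sum(wn)
      delta <- max(abs(wn - w))
      w <- wn
      post <- p
      if (delta < tol) break
    }

    if (boot <= bootstraps) {
      for (m in seq_len(M)) {
        pq <- post[priors$support[[m]]$genes, m]
        pq[!is.finite(pq)] <- 0
        un <- pq + 1 / G           # floor keeps every sample reachable
        u[[m]] <- un / sum(un)
      }
    }
  }
  post[flagged, ] <- NA_real_

  ## a gene observed at zero everywhere is unexpressed by definition; its
  ## likelihood ratios between models are artifacts of which prior
  ## samples carry extreme dispersions, so it is assigned to silent
  silent_col <- which(vapply(models, `[[`, character(1), "kind") == "silent")
  zero <- total == 0 & !flagged
  if (length(silent_col) && any(zero)) {
    post[zero, ] <- 0
    post[zero, silent_col] <- 1
  }

  kinds <- vapply(models, `[[`, character(1), "kind")
  ids <- vapply(models, `[[`, character(1), "pattern_id")
  colnames(post) <- ids
  ccr_lik <- rowSums(post[, kinds == "differential", drop = FALSE])
  best <- ids[apply(post, 1, function(r)
    if (all(is.na(r))) NA_integer_ else which.max(r))]

  structure(list(posteriors = post, ccr_likelihood = ccr_lik,
                 best_pattern = best, weights = setNames(w, ids),
                 flagged = flagged, models = models,
                 counts = y, layout = layout,
                 gene_id = rownames(y) %||% as.character(seq_len(G))),
            class = "ccr_result")
}

#' Call cell-cycle-regulated genes
#'
#' A gene is called CCR when its summed posterior over differential models
#' reaches `threshold`.  The output mirrors the role of a CCR gene table:
#' likelihood, best pattern, peak expression and max/min fold change of
#' the time-point means (the trough is floored at 0.1x to keep fold
#' changes finite for silent troughs).
#'
#' @param result a `ccr_result`.
#' @param threshold CCR likelihood cutoff (default 0.5).
#'
#' @return Data frame with one row per called gene, sorted by decreasing
#'   likelihood.
#' @export
call_ccr <- function(result, threshold = 0.5) {
  stopifnot(inherits(result, "ccr_result"))
  tpm <- .timepoint_means(result$counts, result$layout)
  peak <- apply(tpm, 1, max)
  trough <- pmax(apply(tpm, 1, min), 0.1)
  fold <- peak / trough
  lik <- result$ccr_likelihood
  called <- which(!is.na(lik) & lik >= threshold)
  out <- data.frame(gene_id = result$gene_id[called],
                    ccr_likelihood = lik[called],
                    best_pattern = result$best_pattern[called],
                    peak_expression = peak[called],
                    fold_change = fold[called],
                    stringsAsFactors = FALSE)
  out[order(-out$ccr_likelihood), , drop = FALSE]
}

#' Detect CCR genes from an expression matrix
#'
#' Convenience wrapper running [estimate_priors()] and
#' [posterior_likelihoods()] separately on the highly expressed
#' (pooled mean > `split`) genes and the bulk of the genome, mirroring the
#' split normalization, then recombining the per-gene results.  Partitions
#' smaller than 50 genes are folded into the other partition.
#'
#' @param em an `expression_matrix`.
#' @param split expression cut separating the partitions (default 1000).
#' @param Q,seed,threshold,rescale passed to the stage functions.
#'
#' @return List with the combined `ccr_result` fields, the called gene
#'   table (`calls`) and the partition labels.
#' @export
detect_ccr <- function(em, split = 1000, Q = 100L, seed = 1L,
                       threshold = 0.5, rescale = TRUE) {
  stopifnot(inherits(em, "expression_matrix"))
  pooled <- rowMeans(em$values)
  high <- pooled > split
  if (sum(high) < 50 || sum(!high) < 50) high[] <- FALSE  # single partition
  models <- enumerate_models(length(unique(em$layout$timepoint)))

  run_part <- function(sel, part_seed) {
    sub <- em
    sub$values <- em$values[sel, , drop = FALSE]
    pri <- estimate_priors(sub, models, Q = Q, seed = part_seed)
    posterior_likelihoods(sub, models, pri, rescale = rescale)
  }

  parts <- if (any(high))
    list(run_part(!high, seed), run_part(high, seed + 1L))
  else list(run_part(rep(TRUE, nrow(em$values)), seed))

  G <- nrow(em$values)
  lik <- numeric(G); best <- character(G); flagged <- logical(G)
  sel_list <- if (any(high)) list(!high, high) else list(rep(TRUE, G))
  for (i in seq_along(parts)) {
    lik[sel_list[[i]]] <- parts[[i]]$ccr_likelihood
    best[sel_list[[i]]] <- parts[[i]]$best_pattern
    flagged[sel_list[[i]]] <- parts[[i]]$flagged
  }
  combined <- structure(list(
    posteriors = NULL, ccr_likelihood = lik, best_pattern = best,
    weights = lapply(parts, `[[`, "weights"), flagged = flagged,
    models = models, counts = round(em$values), layout = em$layout,
    gene_id = rownames(em$values) %||% as.character(seq_len(G))),
    class = "ccr_result")
  list(result = combined, calls = call_ccr(combined, threshold),
       partition = ifelse(high, "high", "bulk"))
}
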