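## End-to-end orchestration: simulate -> quantify -> classify -> de ->
## network -> phylo -> report, with one config, seed control, uniform
## logging and a provenance manifest.

#' Default pipeline configuration
#'
#' Returns the full default configuration as a nested list; any file- or
#' YAML-supplied configuration is merged over these defaults.  The
#' simulation block encodes the emulated study design: 5 time points x 3
#' replicates, stratum fractions 738/3136/90 of 3964 genes, CCR fraction
#' 1586/3964 with geometric-mean fold change 8.2, power-law exponent
#' 1.74, GC-linked inconsistency on 10% of windows at CV target 1.5, and
#' a 236-species birth-death tree.
#'
#' @return Nested configuration list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    stages = c("simulate", "quantify", "classify", "de", "network",
               "phylo", "report"),
    inputs = list(annotation = NULL, tracks = NULL, tree = NULL,
                  conservation = NULL),
    simulate = list(
      genome_length = 100000L, n_genes = 150L,
      gene_length_range = c(300L, 900L), duplicate_gene_pairs = 1L,
      strand_fraction = 0.5, window_size = 500L,
      stratum_fractions = c(low = 738, bulk = 3136, high = 90) / 3964,
      ccr_fraction = 1586 / 3964, fold_change_mean = 8.2, alpha = 1.74,
      n_timepoints = 5L, n_replicates = 3L,
      gc_noise = list(affected_fraction = 0.1, cv_target = 1.5),
      count_noise = list(dispersion = 0.05, nucleotide_poisson = TRUE),
      n_species = 236L, loss_probability = 0.1),
    quantify = list(cv_threshold = 1.0, split_threshold = 1000,
                    window = 2000L),
    classify = list(span = 0.3, low_cut = 5, high_cut = 1000),
    de = list(threshold = 0.5, Q = 100L),
    network = list(beta = 36, min_size = 5L, cut_height = 0.995,
                   drop_timepoints = c(1L, 2L, 3L)),
    phylo = list(randomizations = 9999L, k_permutations = 999L,
                 threshold = -2, abundance_weighted = TRUE)
  )
}

.merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- .merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Load a pipeline configuration
#'
#' @param path YAML file, a list, or `NULL` for the defaults.
#' @return Full configuration list (defaults merged with overrides).
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  over <- if (is.character(path)) yaml::read_yaml(path) else path
  .merge_config(cfg, over)
}

.log <- function(logfile, stage, ...) {
  msg <- sprintf("[%s] %s", stage, paste0(...))
  message(msg)
  if (!is.null(logfile)) cat(msg, "\n", file = logfile, append = TRUE)
}

#' Run the pipeline
#'
#' Executes the enabled stages in order and writes stage outputs plus a
#' provenance manifest (seeds, parameters, output checksums) into the run
#' directory.  A stage failure stops the run naming the failing stage;
#' outputs of completed stages are retained.
#'
#' @param config configuration (list, YAML path or `NULL` = defaults).
#' @param outdir run directory.
#' @param seed overrides the configured seed when non-`NULL`.
#'
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config = NULL, outdir = "ccrnet_run", seed = NULL) {
  cfg <- load_config(config)
  if (!is.null(seed)) cfg$seed <- .check_seed(seed)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(outdir, "pipeline.log")
  cat("", file = logfile)
  state <- list(config = cfg)

  stage <- function(name, fun) {
    if (!(name %in% cfg$stages)) return()
    .log(logfile, name, "started")
    res <- tryCatch(fun(), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    state <<- res
    .log(logfile, name, "done")
  }

  stage("simulate", function() .stage_simulate(state, outdir))
  stage("quantify", function() .stage_quantify(state, outdir))
  stage("classify", function() .stage_classify(state, outdir))
  stage("de", function() .stage_de(state, outdir))
  stage("network", function() .stage_network(state, outdir))
  stage("phylo", function() .stage_phylo(state, outdir))
  stage("report", function() .stage_report(state, outdir))

  manifest <- list(
    package = "ccrnet",
    version = as.character(utils::packageVersion("ccrnet")),
    seed = cfg$seed,
    stages = cfg$stages,
    parameters = cfg[setdiff(names(cfg), "stages")],
    checksums = as.list(tools::md5sum(
      list.files(outdir, full.names = TRUE, recursive = TRUE,
                 pattern = "\\.(tsv|gff3|bedGraph|nwk|json)$"))))
  names(manifest$checksums) <- basename(names(manifest$checksums))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  state$manifest <- manifest
  invisible(state)
}

.stage_simulate <- function(state, outdir) {
  cfg <- state$config
  p <- cfg$simulate
  spec <- genome_spec(genome_length = p$genome_length, n_genes = p$n_genes,
                      gene_length_range = p$gene_length_range,
                      strand_fraction = p$strand_fraction,
                      duplicate_gene_pairs = p$duplicate_gene_pairs,
                      window_size = p$window_size)
  genome <- generate_genome(spec, seed = cfg$seed)
  programs <- assign_programs(p$n_genes,
                              stratum_fractions = p$stratum_fractions,
                              ccr_fraction = p$ccr_fraction,
                              fold_change_mean = p$fold_change_mean,
                              n_timepoints = p$n_timepoints,
                              alpha = p$alpha, seed = cfg$seed + 1L)
  experiment <- simulate_coverage(genome, programs,
                                  n_timepoints = p$n_timepoints,
                                  n_replicates = p$n_replicates,
                                  gc_noise = p$gc_noise,
                                  count_noise = p$count_noise,
                                  seed = cfg$seed + 2L)

  ## conservation modules aligned with the planted expression patterns:
  ## genes sharing a planted pattern form one module, alternating broad /
  ## clade-specific; everything else is background (broad descent)
  ann <- genome$annotation
  ccr_ids <- ann$gene_id[programs$is_ccr]
  pats <- split(ccr_ids, programs$pattern_id[programs$is_ccr])
  pats <- pats[order(names(pats))]
  module_truths <- list()
  for (i in seq_along(pats)) {
    module_truths[[i]] <- list(
      module_id = sprintf("m%02d", i),
      depth_class = if (i %% 2 == 1) "broad" else "clade",
      genes = pats[[i]])
  }
  module_truths[[length(module_truths) + 1L]] <- list(
    module_id = "bg", depth_class = "broad",
    genes = setdiff(ann$gene_id, ccr_ids))
  phy <- simulate_tree_and_conservation(p$n_species, module_truths,
                                        loss_probability = p$loss_probability,
                                        seed = cfg$seed + 3L)

  write_gff3(ann, file.path(outdir, "annotation.gff3"))
  write_coverage_tracks(experiment, file.path(outdir, "tracks"))
  ape::write.tree(phy$tree, file.path(outdir, "species.nwk"))
  write_conservation_tsv(phy$conservation,
                         file.path(outdir, "conservation.tsv"))
  utils::write.table(programs, file.path(outdir, "truth_programs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(phy$truth, file.path(outdir, "truth_conservation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  c(state, list(genome = genome, programs = programs,
                experiment = experiment, phylo_truth = phy))
}

.stage_quantify <- function(state, outdir) {
  cfg <- state$config
  if (is.null(state$experiment))
    stop("no coverage experiment available (enable 'simulate' or provide inputs)")
  q <- cfg$quantify
  normed <- normalize_split(state$experiment,
                            split_threshold = q$split_threshold)
  em <- quantify_genes(normed, cv_threshold = q$cv_threshold,
                       window = q$window)
  write_expression_tsv(em, file.path(outdir, "expression.tsv"))
  c(state, list(normalized = normed, em = em))
}

.stage_classify <- function(state, outdir) {
  cfg <- state$config
  em <- state$em
  groups <- classify_groups(em, low_cut = cfg$classify$low_cut,
                            high_cut = cfg$classify$high_cut)
  pooled <- groups$pooled_expression
  nonlow <- pooled[groups$label != "low"]
  pl <- tryCatch(fit_power_law(nonlow, xmin = cfg$classify$low_cut),
                 error = function(e) NULL)
  sm <- tryCatch(smooth_cv_vs_expression(pooled, groups$gene_cv,
                                         span = cfg$classify$span),
                 error = function(e) NULL)
  summary <- list(
    alpha = if (is.null(pl)) NA else pl$alpha,
    xmin = if (is.null(pl)) NA else pl$xmin,
    group_sizes = as.list(groups$sizes),
    group_mean_cv = as.list(groups$group_mean_cv))
  jsonlite::write_json(summary, file.path(outdir, "classify.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.table(
    data.frame(gene_id = names(groups$label) %||%
                 rownames(em$values), group = groups$label,
               pooled_expression = pooled, cv = groups$gene_cv),
    file.path(outdir, "groups.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  c(state, list(groups = groups, power_law = pl, cv_smooth = sm))
}

.stage_de <- function(state, outdir) {
  cfg <- state$config
  de <- detect_ccr(state$em, split = cfg$classify$high_cut,
                   Q = cfg$de$Q, seed = state$config$seed + 10L,
                   threshold = cfg$de$threshold)
  utils::write.table(de$calls, file.path(outdir, "ccr_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  c(state, list(de = de))
}

.stage_network <- function(state, outdir) {
  cfg <- state$config
  n <- cfg$network
  ccr <- state$de$calls$gene_id
  if (length(ccr) < n$min_size) {
    .log(NULL, "network", "skipped: no CCR genes")
    return(c(state, list(network = NULL)))
  }
  em <- state$em
  mask <- select_network_samples(em, drop_timepoints = n$drop_timepoints)
  expr <- em$values[ccr, mask, drop = FALSE]
  expr <- expr[apply(expr, 1, var) > 0, , drop = FALSE]
  adj <- signed_adjacency(expr, beta = n$beta)
  tom <- topological_overlap(adj)
  ms <- detect_modules(tom, min_size = n$min_size,
                       cut_height = n$cut_height)
  ms <- module_eigenvectors(ms, expr)
  memb <- data.frame(gene_id = names(ms$labels), module = ms$labels,
                     contribution = ms$contributions[names(ms$labels)],
                     stringsAsFactors = FALSE)
  utils::write.table(memb, file.path(outdir, "modules.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample = colnames(expr), ms$eigenvectors,
               check.names = FALSE),
    file.path(outdir, "eigenvectors.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  ## edge list for external network viewers (weak edges omitted)
  ut <- upper.tri(tom)
  keep_e <- ut & tom > 0.01
  if (any(keep_e)) {
    ij <- which(keep_e, arr.ind = TRUE)
    edges <- data.frame(gene_i = rownames(tom)[ij[, 1]],
                        gene_j = colnames(tom)[ij[, 2]],
                        tom = tom[keep_e], stringsAsFactors = FALSE)
    utils::write.table(edges[order(-edges$tom), ],
                       file.path(outdir, "edges.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  bic <- if (length(ms$modules) >= 2)
    cluster_module_eigenvectors(ms, layout = em$layout[mask, ]) else NULL
  c(state, list(network = list(adjacency = adj, tom = tom, modules = ms,
                               mask = mask, biclust = bic, expr = expr)))
}

.stage_phylo <- function(state, outdir) {
  cfg <- state$config
  if (is.null(state$network) || !length(state$network$modules$modules)) {
    .log(NULL, "phylo", "skipped: no modules")
    return(c(state, list(phylo = NULL)))
  }
  p <- cfg$phylo
  cons <- state$phylo_truth$conservation
  tree <- state$phylo_truth$tree
  sig <- module_phylo_signal(state$network$modules, cons, tree,
                             n_randomizations = p$randomizations,
                             n_permutations = p$k_permutations,
                             threshold = p$threshold,
                             seed = state$config$seed + 20L,
                             abundance_weighted = p$abundance_weighted)
  pit <- persistence_index(cons)
  utils::write.table(sig, file.path(outdir, "module_phylo.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(pit, file.path(outdir, "persistence.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  pi_vec <- setNames(pit$pi, pit$gene_id)
  kv <- contribution_vs_persistence(state$network$modules$contributions,
                                    pi_vec)
  c(state, list(phylo = list(signal = sig, persistence = pit,
                             contribution_ks = kv)))
}

.stage_report <- function(state, outdir) {
  report(state, outdir)
  state
}

#' Summarize a pipeline run
#'
#' Aggregates stage outputs into a machine-readable JSON summary and a
#' small set of diagnostic plots (CV versus expression, expression CCDF
#' with the power-law fit, module-eigenvector correlations, MPD/MNTD
#' quadrants).  No new computation beyond aggregation.
#'
#' @param state pipeline state as returned by [run_pipeline()].
#' @param outdir run directory.
#'
#' @return Invisibly, the summary list.
#' @export
report <- function(state, outdir) {
  s <- list()
  if (!is.null(state$em))
    s$genes_quantified <- nrow(state$em$values)
  if (!is.null(state$groups))
    s$group_sizes <- as.list(state$groups$sizes)
  if (!is.null(state$power_law))
    s$power_law <- list(alpha = state$power_law$alpha,
                        xmin = state$power_law$xmin)
  if (!is.null(state$de))
    s$ccr <- list(n_called = nrow(state$de$calls))
  if (is.null(state$network))
    s$network <- "skipped: no CCR genes"
  else {
    ms <- state$network$modules
    s$network <- list(n_modules = length(ms$modules),
                      n_unassigned = sum(ms$labels == 0),
                      median_variance_explained =
                        unname(median(ms$variance_explained)))
  }
  if (is.null(state$phylo))
    s$phylo <- "skipped: no CCR genes"
  else {
    sig <- state$phylo$signal
    s$phylo <- list(
      quadrant_tally = as.list(table(factor(sig$quadrant, 1:4))),
      mean_K = mean(sig$K, na.rm = TRUE),
      contribution_ks_p = state$phylo$contribution_ks$p)
  }
  jsonlite::write_json(s, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)

  grDevices::pdf(file.path(outdir, "report.pdf"), width = 7, height = 6)
  on.exit(grDevices::dev.off())
  if (!is.null(state$groups)) {
    g <- state$groups
    graphics::plot(g$pooled_expression, g$gene_cv, log = "x", pch = 16,
                   cex = 0.5, col = factor(g$label),
                   xlab = "expression (x-fold)", ylab = "CV",
                   main = "CV vs expression")
    if (!is.null(state$cv_smooth)) {
      xs <- sort(g$pooled_expression[g$pooled_expression > 0])
      graphics::lines(xs, state$cv_smooth(xs), col = "red", lwd = 2)
    }
  }
  if (!is.null(state$power_law)) {
    x <- sort(state$groups$pooled_expression[
      state$groups$pooled_expression > 0])
    cc <- rev(seq_along(x)) / length(x)
    graphics::plot(x, cc, log = "xy", type = "s",
                   xlab = "expression", ylab = "Pr(E > e)",
                   main = sprintf("expression CCDF (alpha = %.2f)",
                                  state$power_law$alpha))
  }
  if (!is.null(state$network) && !is.null(state$network$biclust)) {
    cc <- state$network$biclust$correlation
    graphics::image(cc, main = "module eigenvector correlations",
                    axes = FALSE)
  }
  if (!is.null(state$phylo)) {
    sig <- state$phylo$signal
    graphics::plot(sig$mpd_z, sig$mntd_z, pch = 16, col = "red",
                   xlab = "MPD z", ylab = "MNTD z",
                   main = "module quadrants")
    graphics::abline(h = -2, v = -2, lty = 2)
  }
  invisible(s)
}
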