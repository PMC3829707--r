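test_that("genome generation handles empty, duplicate and infeasible cases", {
  spec0 <- genome_spec(genome_length = 5000, n_genes = 0)
  g0 <- generate_genome(spec0, seed = 1)
  expect_equal(nrow(g0$annotation), 0)
  expect_gt(nrow(g0$gc), 0)          # GC track defined even with no genes

  spec <- genome_spec(genome_length = 30000, n_genes = 20,
                      duplicate_gene_pairs = 1)
  g <- generate_genome(spec, seed = 2)
  dup <- g$annotation[!is.na(g$annotation$dup_group), ]
  expect_equal(nrow(dup), 2)          # exactly two genes share an identity group
  expect_equal(dup$length[1], dup$length[2])
  expect_true(all(g$annotation$start >= 0 & g$annotation$end <= 30000))
  for (s in c("+", "-")) {            # non-overlap within strand
    a <- g$annotation[g$annotation$strand == s, ]
    a <- a[order(a$start), ]
    if (nrow(a) > 1) expect_true(all(a$start[-1] >= a$end[-nrow(a)]))
  }

  tight <- genome_spec(genome_length = 1000, n_genes = 10,
                       gene_length_range = c(300, 400))
  expect_error(generate_genome(tight, seed = 1), "infeasible packing")
})

test_that("genome generation is byte-identical for a fixed seed", {
  spec <- genome_spec(genome_length = 20000, n_genes = 15,
                      duplicate_gene_pairs = 1)
  f1 <- tempfile(fileext = ".gff3"); f2 <- tempfile(fileext = ".gff3")
  write_gff3(generate_genome(spec, seed = 7)$annotation, f1)
  write_gff3(generate_genome(spec, seed = 7)$annotation, f2)
  expect_identical(readLines(f1), readLines(f2))
  f3 <- tempfile(fileext = ".gff3")
  write_gff3(generate_genome(spec, seed = 8)$annotation, f3)
  expect_false(identical(readLines(f1), readLines(f3)))
})

test_that("expression programs respect strata, CCR fraction and fold scale", {
  pr0 <- assign_programs(200, ccr_fraction = 0, seed = 3)
  mult <- as.matrix(pr0[, grep("^mult_t", names(pr0))])
  expect_true(all(mult == 1))         # no CCR: flat multipliers

  pr <- assign_programs(4000, seed = 4)
  expect_equal(mean(pr$stratum == "low"), 738 / 3964, tolerance = 0.01)
  expect_equal(mean(pr$stratum == "high"), 90 / 3964, tolerance = 0.01)
  ## stratum invariants on peak expression
  peak <- pr$base_level
  expect_true(all(peak[pr$stratum == "low"] < 5))
  expect_true(all(peak[pr$stratum == "high"] > 1000))

  ## realized fold changes: sample mean within 20% of 8.2
  big <- assign_programs(2500, ccr_fraction = 0.5, fold_change_mean = 8.2,
                         seed = 5)
  m <- as.matrix(big[big$is_ccr, grep("^mult_t", names(big))])
  folds <- apply(m, 1, max) / apply(m, 1, min)
  expect_gt(length(folds), 1000)
  expect_lt(abs(mean(folds) - 8.2) / 8.2, 0.2)

  expect_error(assign_programs(100, ccr_fraction = 1.5), "must be in")
})

test_that("coverage simulation honors noise switches and duplicate splitting", {
  spec <- genome_spec(genome_length = 10000, n_genes = 8,
                      duplicate_gene_pairs = 1)
  g <- generate_genome(spec, seed = 11)
  pr <- assign_programs(8, stratum_fractions = c(low = 0, bulk = 1, high = 0),
                        ccr_fraction = 0.5, seed = 12)

  ## all noise off: replicates identical, CV = 0 everywhere
  ex0 <- simulate_coverage(g, pr, gc_noise = list(affected_fraction = 0,
                                                  cv_target = 0),
                           count_noise = list(dispersion = 0,
                                              nucleotide_poisson = FALSE),
                           seed = 13)
  cv <- compute_cv(ex0, 1)
  expect_lt(max(cv[["+"]], cv[["-"]]), 1e-10)

  ## duplicate identity group: both copies carry the same (averaged) value
  ann <- ex0$annotation
  dg <- which(!is.na(ann$dup_group))
  v <- vapply(dg, function(i)
    mean(ex0$tracks[[1]][[1]][[ann$strand[i]]][(ann$start[i] + 1):ann$end[i]]),
    numeric(1))
  expect_equal(v[1], v[2])
  ## and it is the even split of the summed signal
  expect_equal(v[1], mean(ex0$truth[dg, 1]))

  ## noiseless coverage equals the planted program exactly (duplicate
  ## copies report the identity group's shared average)
  tpm <- timepoint_means(quantify_genes(ex0, cv_threshold = 1))
  expected <- ex0$truth
  expected[dg, ] <- rep(colMeans(ex0$truth[dg, , drop = FALSE]),
                        each = length(dg))
  expect_equal(unname(tpm), unname(expected), tolerance = 1e-10)
})

test_that("GC-flagged windows carry high replicate CV, elsewhere low", {
  spec <- genome_spec(genome_length = 50000, n_genes = 60)
  g <- generate_genome(spec, seed = 21)
  pr <- assign_programs(60, seed = 22)
  ex <- simulate_coverage(g, pr, gc_noise = list(affected_fraction = 0.1,
                                                 cv_target = 1.5), seed = 23)
  gc <- ex$gc
  affm <- logical(ex$genome_length)
  for (w in ex$affected_windows) affm[(gc$start[w] + 1):gc$end[w]] <- TRUE
  cv <- compute_cv(ex, 1)
  ## per-nucleotide CV on each gene's own strand
  ann <- ex$annotation
  cvg <- unlist(lapply(seq_len(nrow(ann)), function(i)
    cv[[ann$strand[i]]][(ann$start[i] + 1):ann$end[i]]))
  inaff <- unlist(lapply(seq_len(nrow(ann)), function(i)
    affm[(ann$start[i] + 1):ann$end[i]]))
  expect_gt(median(cvg[inaff]), 1)
  expect_lt(median(cvg[!inaff]), 0.5)
})

test_that("tree and conservation respect origin clades and losses", {
  mt <- list(list(module_id = "b1", depth_class = "broad", size = 4),
             list(module_id = "c1", depth_class = "clade", size = 5))
  phy0 <- simulate_tree_and_conservation(40, mt, loss_probability = 0,
                                         detection_scale = Inf, seed = 31)
  b <- phy0$truth$module_id == "b1"
  expect_true(all(phy0$conservation[b, ] == 1))   # no losses, root origin
  pit <- persistence_index(phy0$conservation)
  expect_true(all(pit$pi[b] == 40))

  ## clade genes confined to <= 15% of tips; presence is exactly one clade
  cl <- phy0$truth$module_id == "c1"
  expect_true(all(rowSums(phy0$conservation[cl, , drop = FALSE]) <=
                    ceiling(0.15 * 40)))
  tr <- phy0$tree
  parts <- ape::prop.part(tr)
  part_sets <- lapply(parts, function(p) sort(tr$tip.label[p]))
  for (gid in phy0$truth$gene_id[cl]) {
    pres <- sort(colnames(phy0$conservation)[phy0$conservation[gid, ] == 1])
    expect_true(length(pres) == 1 ||
                  any(vapply(part_sets, identical, logical(1), y = pres)))
  }

  phy236 <- simulate_tree_and_conservation(
    236, list(list(module_id = "m", depth_class = "broad", size = 2)),
    seed = 32)
  expect_equal(ncol(phy236$conservation), 236)
  expect_true(ape::is.ultrametric(phy236$tree, tol = 1e-6))
})

test_that("generated expression is heavy-tailed with the planted exponent", {
  pr <- assign_programs(4000, seed = 41)
  nonlow <- pr$base_level[pr$stratum != "low"]
  fit <- fit_power_law(nonlow, xmin = 5)
  expect_lt(abs(fit$alpha - 1.74), 0.08)
})

test_that("simulated expression matrices are reproducible and NB-dispersed", {
  pr <- assign_programs(300, seed = 51)
  em1 <- simulate_expression(pr, seed = 52)
  em2 <- simulate_expression(pr, seed = 52)
  expect_identical(em1$values, em2$values)
  ## flat genes: replicate CV^2 ~ 1/mu + dispersion
  flat <- which(!pr$is_ccr & pr$base_level > 200)
  cvs <- gene_cv(em1)[flat]
  expect_lt(abs(median(cvs) - sqrt(0.05)), 0.1)
})
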