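test_that("signed adjacency maps correlations through the soft threshold", {
  x <- c(1, 2, 3, 4, 5, 6)
  y <- c(2, 4, 6, 8, 10, 12)         # cor +1
  z <- -x                            # cor -1
  w <- c(1, -1, 1, -1, 1, -1) * sd(x)  # cor 0 with x
  expr <- rbind(a = x, b = y, c = z, d = w)
  adj <- signed_adjacency(expr, beta = 36)
  expect_equal(adj["a", "b"], 1)
  expect_equal(adj["a", "c"], 0)
  expect_equal(adj["a", "d"], 0.5^36)
  expect_true(isSymmetric(adj))
  expect_true(all(diag(adj) == 1))

  bad <- rbind(a = x, const = rep(3, 6))
  expect_error(signed_adjacency(bad), "const")
})

test_that("topological overlap matches the literal triple-loop formula", {
  ## perfect clique
  a1 <- matrix(1, 3, 3)
  expect_true(all(topological_overlap(a1) == 1))
  ## isolated pair
  a0 <- diag(2)
  expect_equal(topological_overlap(a0)[1, 2], 0)

  set.seed(30)
  for (i in 1:50) {
    a <- matrix(runif(64), 8, 8)
    a <- (a + t(a)) / 2
    diag(a) <- 1
    expect_lt(max(abs(topological_overlap(a) - tom_oracle(a))), 1e-10)
  }
})

test_that("TOM entries stay within [0, 1] on random adjacencies", {
  set.seed(31)
  for (i in 1:20) {
    n <- sample(4:15, 1)
    a <- matrix(runif(n * n)^sample(c(1, 4, 36), 1), n, n)
    a <- (a + t(a)) / 2; diag(a) <- 1
    tom <- topological_overlap(a)
    expect_true(all(tom >= -1e-12 & tom <= 1 + 1e-12))
  }
})

test_that("noise-free planted blocks are recovered exactly", {
  set.seed(32)
  p1 <- rnorm(12); p2 <- rnorm(12)
  expr <- rbind(matrix(rep(p1, 6), 6, 12, byrow = TRUE) * runif(6, 0.5, 2),
                matrix(rep(p2, 6), 6, 12, byrow = TRUE) * runif(6, 0.5, 2))
  expr <- expr + matrix(rnorm(144, 0, 1e-4), 12, 12)  # break exact ties
  rownames(expr) <- sprintf("g%02d", 1:12)
  ms <- detect_modules(topological_overlap(signed_adjacency(expr)), min_size = 5)
  expect_length(ms$modules, 2)
  expect_equal(ari(rep(1:2, each = 6), ms$labels), 1)
})

test_that("planted modules are recovered from noisy expression", {
  pm <- planted_module_expr(seed = 99)
  tom <- topological_overlap(signed_adjacency(pm$expr, beta = 36))
  ms <- detect_modules(tom, min_size = 5)
  expect_gte(ari(pm$truth, ms$labels), 0.8)

  ## order invariance: permuting genes permutes labels consistently
  set.seed(33)
  perm <- sample(nrow(pm$expr))
  ms2 <- detect_modules(tom[perm, perm], min_size = 5)
  expect_equal(ari(ms$labels[perm], ms2$labels), 1)
})

test_that("uncorrelated genes form no module", {
  hits <- 0
  for (s in 1:5) {
    set.seed(40 + s)
    e0 <- matrix(rnorm(60 * 15), 60, 15)
    rownames(e0) <- sprintf("n%02d", 1:60)
    ms0 <- detect_modules(topological_overlap(signed_adjacency(e0)),
                          min_size = 5)
    hits <- hits + (length(ms0$modules) == 0)
  }
  expect_gte(hits, 4)   # no spurious module in at least 4 of 5 seeds
})

test_that("module eigenvector, variance explained and contributions", {
  set.seed(34)
  p <- rnorm(12)
  shared <- matrix(rep(p, 5), 5, 12, byrow = TRUE) * runif(5, 0.5, 3)
  ev <- module_eigenvector(shared)
  expect_equal(ev$variance_explained, 1)
  expect_equal(unname(ev$contributions), rep(0.2, 5))
  expect_equal(sum(abs(ev$contributions)), 1)

  ## two orthogonal equal-norm profiles split the variance
  q <- rnorm(12); q <- q - mean(q)
  r <- rnorm(12); r <- r - mean(r)
  r <- r - q * sum(q * r) / sum(q * q)
  two <- rbind(q / sd(q), r / sd(r))
  expect_equal(module_eigenvector(two)$variance_explained, 0.5,
               tolerance = 1e-10)

  expect_error(module_eigenvector(rbind(p, rep(1, 12))), "constant")

  ## eigenvector beats any single member direction
  pm <- planted_module_expr(n_mod = 2, mod_size = 10, n_noise = 0, seed = 35)
  sub <- pm$expr[1:10, ]
  ve <- module_eigenvector(sub)$variance_explained
  x <- t(scale(t(sub)))
  for (g in 1:10) {
    d <- x[g, ] / sqrt(sum(x[g, ]^2))
    expect_gte(ve + 1e-10, sum((x %*% d)^2) / sum(x^2))
  }
})

test_that("module pipeline is invariant to per-gene affine rescaling", {
  pm <- planted_module_expr(n_mod = 3, mod_size = 8, n_noise = 0, seed = 36)
  e1 <- pm$expr
  set.seed(37)
  e2 <- e1 * runif(nrow(e1), 0.5, 4) + rnorm(nrow(e1), 0, 2)
  m1 <- module_eigenvector(e1[1:8, ])
  m2 <- module_eigenvector(e2[1:8, ])
  expect_equal(m1$variance_explained, m2$variance_explained, tolerance = 1e-10)
  expect_equal(m1$contributions, m2$contributions, tolerance = 1e-10)
})

test_that("eigenvector bi-clustering recovers planted phase groups", {
  ## three phase groups peaking at different stages, 3 modules each,
  ## with known module membership
  set.seed(38)
  phases <- rbind(c(3, 1, 0, 0, 1), c(0, 3, 2, 0, 0), c(0, 0, 1, 3, 2))
  expr <- NULL; modules <- list()
  for (p in 1:3) for (m in 1:3) {
    prof <- phases[p, ] + rnorm(5, 0, 0.3)
    block <- matrix(rep(prof[rep(1:5, each = 3)], 6), 6, 15, byrow = TRUE) +
      matrix(rnorm(90, 0, 0.15), 6, 15)
    rownames(block) <- sprintf("p%dm%dg%d", p, m, 1:6)
    expr <- rbind(expr, block)
    modules[[sprintf("p%dm%d", p, m)]] <- rownames(block)
  }
  ms <- structure(list(labels = setNames(rep(seq_along(modules), each = 6),
                                         rownames(expr)),
                       modules = modules, tree = NULL,
                       min_size = 5, cut_height = 0.995),
                  class = "module_set")
  ms <- module_eigenvectors(ms, expr)
  layout <- data.frame(timepoint = rep(1:5, each = 3), replicate = rep(1:3, 5))
  bc <- cluster_module_eigenvectors(ms, layout = layout, k = 3)
  ## modules from the same planted phase must co-cluster
  phase_of <- as.integer(substr(names(modules), 2, 2))
  expect_equal(ari(phase_of, bc$groups), 1)

  ## identical and anti-phase eigenvectors
  ms2 <- ms
  ms2$eigenvectors <- cbind(a = ms$eigenvectors[, 1],
                            b = ms$eigenvectors[, 1],
                            c = -ms$eigenvectors[, 1])
  bc2 <- cluster_module_eigenvectors(ms2, layout = NULL, k = 2)
  cc <- bc2$correlation
  expect_equal(cc["a", "b"], 1)
  expect_equal(cc["a", "c"], -1)
})

test_that("network sample selection drops one outlier replicate", {
  pr <- assign_programs(150, seed = 39)
  em <- simulate_expression(pr, seed = 40)
  ## corrupt replicate 2 of time point 1
  em$values[, 2] <- em$values[, 2] * 10
  keep <- select_network_samples(em, drop_timepoints = 1:3)
  expect_equal(sum(!keep), 3)
  expect_false(keep[2])
})
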