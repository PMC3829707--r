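test_that("reciprocal best hits honor similarity, length and reciprocity", {
  hits <- data.frame(
    query = c("a1", "b1", "a2", "b2", "a3", "b3", "c3"),
    subject = c("b1", "a1", "b2", "a2", "b3", "c3", "b3"),
    similarity = c(60, 60, 35, 35, 55, 50, 50),
    query_length = c(100, 100, 200, 200, 100, 100, 150),
    subject_length = c(100, 100, 200, 200, 100, 150, 100),
    stringsAsFactors = FALSE)
  orth <- bbh_orthologs(hits)
  expect_equal(nrow(orth), 1)             # only the 60% reciprocal pair
  expect_equal(orth$a, "a1"); expect_equal(orth$b, "b1")

  ## a3's best is b3 but b3's best is c3: rejected
  expect_false(any(orth$a == "a3"))

  ## length difference >= 20% is rejected even when reciprocal
  hits2 <- data.frame(query = c("x", "y"), subject = c("y", "x"),
                      similarity = c(80, 80),
                      query_length = c(100, 130),
                      subject_length = c(130, 100))
  expect_equal(nrow(bbh_orthologs(hits2)), 0)
  hits2$query_length <- c(100, 115); hits2$subject_length <- c(115, 100)
  expect_equal(nrow(bbh_orthologs(hits2)), 1)

  hits3 <- hits2; hits3$query_length <- NA
  expect_error(bbh_orthologs(hits3), "length")

  ## similarity ties break toward the lexicographically smaller subject
  hits4 <- data.frame(query = c("q", "q", "bb", "aa"),
                      subject = c("bb", "aa", "q", "q"),
                      similarity = c(70, 70, 70, 70),
                      query_length = 100, subject_length = 100)
  orth4 <- bbh_orthologs(hits4)
  expect_equal(orth4$a, "aa"); expect_equal(orth4$b, "q")
})

test_that("persistence index bands follow the 50/150 borders", {
  m <- rbind(all = rep(1, 236), none = rep(0, 236),
             edge = c(rep(1, 150), rep(0, 86)))
  p <- persistence_index(m)
  expect_equal(p$pi, c(236, 0, 150))
  expect_equal(p$band, c("persistent", "low", "mid"))
  expect_error(persistence_index(matrix(2, 2, 3)), "binary")
})

test_that("representative selection cuts the tree into even clades", {
  star <- ape::stree(9, "star")
  star$edge.length <- rep(1, 9)
  expect_setequal(select_representatives(star, 9, seed = 1), star$tip.label)

  bal <- ape::stree(16, "balanced")
  bal$edge.length <- rep(1, nrow(bal$edge))
  reps <- select_representatives(bal, 4, seed = 2)
  expect_length(reps, 4)
  ## one representative per depth-2 subtree of 4 tips
  grp <- (match(reps, bal$tip.label) - 1) %/% 4
  expect_setequal(grp, 0:3)

  expect_identical(select_representatives(bal, 4, seed = 5),
                   select_representatives(bal, 4, seed = 5))
})

test_that("module species profiles are column sums over member genes", {
  cons <- rbind(g1 = c(1, 1, 0, 0), g2 = c(1, 0, 1, 0), g3 = c(1, 1, 1, 1))
  colnames(cons) <- paste0("s", 1:4)
  expect_equal(module_species_profile(c("g1", "g2", "g3"), cons),
               c(s1 = 3, s2 = 2, s3 = 2, s4 = 1))
  expect_equal(module_species_profile("g2", cons), cons["g2", ])
  expect_error(module_species_profile("nope", cons), "unknown gene")
  expect_error(module_species_profile(character(0), cons), "empty")

  ## disjoint-clade module: support is the union of the clades
  phy <- simulate_tree_and_conservation(
    8, list(list(module_id = "c", depth_class = "clade", size = 2)),
    loss_probability = 0, detection_scale = Inf, seed = 3)
  prof <- module_species_profile(phy$truth$gene_id, phy$conservation)
  per_gene <- lapply(phy$truth$gene_id, function(g)
    names(which(phy$conservation[g, ] == 1)))
  expect_setequal(names(which(prof > 0)), unique(unlist(per_gene)))
})

test_that("Blomberg's K matches its closed form and reference values", {
  set.seed(50)
  star <- ape::stree(8, "star"); star$edge.length <- rep(1, 8)
  tr <- setNames(rnorm(8), star$tip.label)
  k <- blomberg_k(star, tr, n_permutations = 99, seed = 1)
  expect_equal(k$K, 1, tolerance = 1e-10)

  tree <- ape::rphylo(32, 1, 0.3)
  y <- setNames(rnorm(32)^2, tree$tip.label)
  k1 <- blomberg_k(tree, y, n_permutations = 99, seed = 2)
  skip_if_not_installed("picante")
  expect_equal(k1$K, as.numeric(picante::Kcalc(y[tree$tip.label], tree)),
               tolerance = 1e-10)

  ## scale invariance in trait and branch lengths
  k2 <- blomberg_k(tree, 5 * y, n_permutations = 9, seed = 2)
  tree3 <- tree; tree3$edge.length <- tree$edge.length * 3
  k3 <- blomberg_k(tree3, y, n_permutations = 9, seed = 2)
  expect_equal(k1$K, k2$K, tolerance = 1e-12)
  expect_equal(k1$K, k3$K, tolerance = 1e-10)

  expect_true(blomberg_k(tree, setNames(rep(2, 32), tree$tip.label))$flagged)
})

test_that("K detects a clade-structured trait and calibrates on BM", {
  set.seed(51)
  tree <- ape::rphylo(32, 1, 0)
  clade <- ape::extract.clade(tree, 40)$tip.label
  trait <- setNames(as.numeric(tree$tip.label %in% clade), tree$tip.label)
  k <- blomberg_k(tree, trait, n_permutations = 999, seed = 4)
  expect_lte(k$K_p, 0.05)

  tree64 <- ape::rphylo(64, 1, 0.3)
  ks <- replicate(150, {
    x <- ape::rTraitCont(tree64)
    blomberg_k(tree64, x, n_permutations = 0, seed = 1)$K
  })
  expect_gt(mean(ks), 0.85)
  expect_lt(mean(ks), 1.15)
})

test_that("SES MPD/MNTD match direct computation and the exhaustive null", {
  set.seed(52)
  t6 <- ape::rphylo(6, 1, 0)
  D <- ape::cophenetic.phylo(t6)
  ## two present species: both statistics equal their distance
  w2 <- setNames(c(1, 2, 0, 0, 0, 0), t6$tip.label)
  s2 <- ses_mpd_mntd(w2, D, n_randomizations = 99, seed = 1)
  expect_equal(s2$mpd_obs, D[1, 2])
  expect_equal(s2$mntd_obs, D[1, 2])

  ## uniform presence, unweighted: MPD is the grand mean distance, z ~ 0
  wu <- setNames(rep(1, 6), t6$tip.label)
  su <- ses_mpd_mntd(wu, D, n_randomizations = 999, seed = 2,
                     abundance_weighted = FALSE)
  expect_equal(su$mpd_obs, mean(D[upper.tri(D)]))
  expect_lt(abs(su$mpd_z), 0.2)

  ## sampled null against the exhaustive 720-permutation null
  w <- setNames(c(2, 1, 0, 0, 3, 0), t6$tip.label)
  s <- ses_mpd_mntd(w, D, n_randomizations = 9999, seed = 3)
  perms <- as.matrix(expand.grid(rep(list(1:6), 6)))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 6), ]
  null <- t(apply(perms, 1, function(p) ccrnet:::.mpd_mntd_cpp(D, w[p])))
  expect_lt(abs(s$mpd_z - (s$mpd_obs - mean(null[, 1])) / sd(null[, 1])), 0.1)
  expect_lt(abs(s$mntd_z - (s$mntd_obs - mean(null[, 2])) / sd(null[, 2])), 0.1)

  expect_true(ses_mpd_mntd(setNames(c(1, 0, 0, 0, 0, 0), t6$tip.label),
                           D, 99, seed = 1)$flagged)
})

test_that("SES z-scores agree with picante on a presence profile", {
  ## presence-only mode: picante's unweighted MPD/MNTD use the same
  ## pairwise definition as ours (its abundance-weighted MPD includes
  ## self-pairs in the weighted mean, a different convention, so the
  ## weighted mode is checked against the exhaustive oracle instead)
  skip_if_not_installed("picante")
  set.seed(53)
  t8 <- ape::rphylo(8, 1, 0)
  D <- ape::cophenetic.phylo(t8)
  w <- setNames(c(1, 1, 0, 1, 0, 0, 1, 0), t8$tip.label)
  s <- ses_mpd_mntd(w, D, n_randomizations = 20000, seed = 4,
                    abundance_weighted = FALSE)
  comm <- rbind(m = w, dummy = rep(1, 8))
  sp <- picante::ses.mpd(comm, D, null.model = "taxa.labels",
                         abundance.weighted = FALSE, runs = 20000)
  sn <- picante::ses.mntd(comm, D, null.model = "taxa.labels",
                          abundance.weighted = FALSE, runs = 20000)
  expect_equal(s$mpd_obs, sp$mpd.obs[1])
  expect_equal(s$mntd_obs, sn$mntd.obs[1])
  expect_lt(abs(s$mpd_z - sp$mpd.obs.z[1]), 0.15)
  expect_lt(abs(s$mntd_z - sn$mntd.obs.z[1]), 0.15)
})

test_that("quadrant classification follows the -2 thresholds", {
  expect_equal(classify_quadrant(-3, -3), 3L)
  expect_equal(classify_quadrant(-3, 0), 2L)
  expect_equal(classify_quadrant(-1, -3), 4L)
  expect_equal(classify_quadrant(0, 0), 1L)
  ## boundary is inclusive
  expect_equal(classify_quadrant(-2, 0), 2L)
  expect_equal(classify_quadrant(0, -2), 4L)
  expect_true(is.na(classify_quadrant(NaN, 0)))
})

test_that("contribution/persistence comparison flags and detects shifts", {
  cc <- setNames(rep(0.1, 100), paste0("g", 1:100))
  pi <- setNames(rep(c(10, 200), 50), paste0("g", 1:100))
  expect_equal(contribution_vs_persistence(cc, pi)$ks, 0)

  set.seed(54)
  cc2 <- setNames(c(runif(200, 0, 0.5), runif(200, 0.2, 0.7)),
                  paste0("g", 1:400))
  pi2 <- setNames(c(rep(10, 200), rep(200, 200)), paste0("g", 1:400))
  r <- contribution_vs_persistence(cc2, pi2)
  expect_lt(r$p, 1e-5)

  r1 <- contribution_vs_persistence(setNames(c(0.2, 0.4), c("a", "b")),
                                    setNames(c(200, 10), c("a", "b")))
  expect_true(r1$flagged)
  expect_true(r1$ks %in% c(0, 1))
})
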