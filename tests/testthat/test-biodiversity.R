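test_that("Bray-Curtis on presence-absence matches definition and vegan", {
  occ <- rbind(a = c(1, 1, 0), b = c(0, 1, 1), c = c(1, 1, 0))
  d <- as.matrix(bray_curtis(occ))
  expect_equal(d["a", "b"], 0.5)
  expect_equal(d["a", "c"], 0)
  expect_true(all(diag(d) == 0))
  expect_equal(d, t(d))

  disjoint <- rbind(x = c(1, 1, 0, 0), y = c(0, 0, 1, 1))
  expect_equal(as.vector(bray_curtis(disjoint)), 1)

  set.seed(1)
  occ2 <- matrix(rbinom(200, 1, 0.4), 10, 20)
  occ2[rowSums(occ2) == 0, 1] <- 1
  expect_equal(as.matrix(bray_curtis(occ2)),
               as.matrix(vegan::vegdist(occ2, method = "bray")),
               ignore_attr = TRUE, tolerance = 1e-12)

  # permuting species columns leaves D unchanged
  expect_equal(as.matrix(bray_curtis(occ2[, sample(20)])),
               as.matrix(bray_curtis(occ2)), ignore_attr = TRUE)

  expect_error(bray_curtis(rbind(p1 = c(0, 0))), "p1")
})

test_that("NMDS recovers embeddable configurations and orders axes", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  d <- dist(sq)
  fit <- nmds(d, k = 2, n_starts = 10, seed = 1)
  expect_lt(fit$stress, 1e-3)
  expect_equal(colMeans(fit$points), c(NMDS1 = 0, NMDS2 = 0),
               tolerance = 1e-8)
  expect_gte(var(fit$points[, 1]), var(fit$points[, 2]))

  # the same dissimilarities in one dimension strain the fit
  fit1 <- nmds(d, k = 1, n_starts = 10, seed = 1)
  expect_gt(fit1$stress, fit$stress)

  # collinear points embed perfectly in one dimension
  line <- cbind(c(0, 1, 2, 3.5, 5), 0)
  sel <- select_dimension(dist(line), k_max = 3, n_starts = 5, seed = 2)
  expect_equal(sel$k, 1)
  expect_true(sel$passed)
})

test_that("stress is non-increasing in k and matches a naive minimiser", {
  set.seed(3)
  for (rep in 1:3) {
    delta <- as.dist(matrix(runif(64, 0.2, 1), 8, 8))
    stresses <- vapply(1:3, function(k) {
      nmds(delta, k, n_starts = 15, seed = 10 + rep)$stress
    }, numeric(1))
    # nesting across dimensions via the padded-start mechanism
    sel <- suppressWarnings(
      select_dimension(delta, k_max = 3, n_starts = 15,
                       seed = 10 + rep, stress_threshold = 0))
    expect_true(all(diff(sel$stress) < 1e-6))
    # agreement with an independent direct minimisation of stress-1
    oracle <- oracle_nmds_stress(delta, k = 2, n_tries = 6,
                                 seed = 100 + rep)
    expect_lt(abs(stresses[2] - oracle), 0.02)
  }
})

test_that("high-dimensional structure defeats the stress rule up to k_max", {
  set.seed(4)
  # strongly non-embeddable: near-equidistant random dissimilarities
  delta <- as.dist(matrix(runif(900, 0.95, 1), 30, 30))
  expect_warning(
    sel <- select_dimension(delta, k_max = 2, n_starts = 5, seed = 5),
    "k_max")
  expect_equal(sel$k, 2)
  expect_false(sel$passed)
  expect_true(all(sel$stress >= 0.2))
})

test_that("log richness is the natural log of the species count", {
  occ <- rbind(a = c(1, rep(0, 19)), b = rep(1, 20))
  lr <- log_richness(occ)
  expect_equal(unname(lr), c(0, log(20)))
  expect_error(log_richness(rbind(empty = rep(0, 5))), "empty")
})

test_that("MPD and SES-MPD follow their definitions", {
  tr <- simulate_phylogeny(10, seed = 1)
  D <- ape::cophenetic.phylo(tr)
  occ <- matrix(0L, 2, 10, dimnames = list(c("p1", "p2"), tr$tip.label))
  occ["p1", 1:2] <- 1L
  occ["p2", c(1, 4, 7)] <- 1L
  res <- ses_mpd(occ, D, n_null = 99, seed = 1)
  # two-species plot: MPD equals the patristic distance
  expect_equal(res["p1", "mpd"], D[tr$tip.label[1], tr$tip.label[2]])
  sp2 <- tr$tip.label[c(1, 4, 7)]
  expect_equal(res["p2", "mpd"], mean(D[sp2, sp2][lower.tri(diag(3))]))
  expect_equal(res$flag, c("ok", "ok"))

  # observed MPD agrees with the independent picante implementation
  skip_if_not_installed("picante")
  expect_equal(unname(res$mpd), unname(picante::mpd(occ, D)),
               tolerance = 1e-12)

  # star phylogeny: all null assemblages identical -> degenerate
  star <- ape::stree(6, type = "star")
  star$edge.length <- rep(1, nrow(star$edge))
  Ds <- ape::cophenetic.phylo(star)
  occ_s <- matrix(0L, 1, 6, dimnames = list("s", star$tip.label))
  occ_s[1, 1:3] <- 1L
  res_s <- ses_mpd(occ_s, Ds, n_null = 49, seed = 2)
  expect_equal(res_s$flag, "degenerate_null")
  expect_true(is.na(res_s$ses_mpd))

  # single-species plots are flagged, not dropped
  occ1 <- matrix(0L, 1, 10, dimnames = list("solo", tr$tip.label))
  occ1[1, 3] <- 1L
  expect_equal(ses_mpd(occ1, D, n_null = 9, seed = 3)$flag,
               "single_species")
})

test_that("SES-MPD is centred and scaled under its own null", {
  # communities assembled uniformly at random from the pool are the null
  tr <- simulate_phylogeny(40, seed = 6)
  D <- ape::cophenetic.phylo(tr)
  set.seed(7)
  n <- 60
  occ <- t(vapply(seq_len(n), function(i) {
    s <- sample(3:12, 1)
    as.integer(seq_len(40) %in% sample.int(40, s))
  }, integer(40)))
  colnames(occ) <- tr$tip.label
  res <- ses_mpd(occ, D, n_null = 199, seed = 8)
  expect_true(abs(mean(res$ses_mpd)) < 0.2)
  expect_true(sd(res$ses_mpd) > 0.7 && sd(res$ses_mpd) < 1.3)
})

test_that("regional pools restrict the null draws", {
  tr <- simulate_phylogeny(20, seed = 9)
  D <- ape::cophenetic.phylo(tr)
  occ <- matrix(0L, 2, 20, dimnames = list(c("a", "b"), tr$tip.label))
  occ["a", 1:3] <- 1L
  occ["b", 4:6] <- 1L
  pools <- list(r1 = tr$tip.label[1:5], r2 = tr$tip.label[4:20])
  res <- ses_mpd(occ, D, pools = pools, regions = c("r1", "r2"),
                 n_null = 99, seed = 10)
  expect_true(all(is.finite(res$ses_mpd)))
  expect_error(ses_mpd(occ, D, pools = pools, regions = c("r1", "zz"),
                       n_null = 9, seed = 1), "zz")
})

test_that("sample coverage follows the Chao-Jost estimator", {
  # counts {3,2,1,1}: n = 7, f1 = 2, f2 = 1
  ab <- rbind(p = c(3, 2, 1, 1))
  expect_equal(unname(sample_coverage(ab)),
               1 - (2 / 7) * ((6 * 2) / (6 * 2 + 2 * 1)))
  # no singletons: complete coverage
  expect_equal(unname(sample_coverage(rbind(q = c(5, 3, 2)))), 1)
  # all singletons, no doubletons
  expect_equal(unname(sample_coverage(rbind(r = c(1, 1, 1, 1)))), 0)
  expect_error(sample_coverage(rbind(z = c(0, 0))), "zero")

  ab2 <- rbind(lo = c(1, 1, 1), hi = c(9, 5, 4))
  keep <- coverage_subset(ab2, 0.8)
  expect_equal(unname(keep), c(FALSE, TRUE))
})
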