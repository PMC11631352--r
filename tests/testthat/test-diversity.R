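mk_tab <- function(counts, features, samples) {
  validate_feature_table(matrix(as.integer(counts), nrow = length(features),
                                dimnames = list(features, samples)))
}

test_that("rarefy subsamples without replacement to an exact depth", {
  set.seed(51)
  tab <- mk_tab(rpois(10 * 4, 40), paste0("f", 1:10), paste0("s", 1:4))
  r <- rarefy(tab, depth = 100, seed = 1)
  expect_true(all(colSums(r) == 100))
  expect_true(all(r <= tab))                 # never inflates a count

  # sample below depth is dropped
  tab2 <- tab; tab2[, 2] <- 0L; tab2[1, 2] <- 99L
  expect_message(r2 <- rarefy(tab2, depth = 100, seed = 1), "dropping")
  expect_false("s2" %in% colnames(r2))

  # seeded reproducibility
  expect_identical(rarefy(tab, depth = 100, seed = 9),
                   rarefy(tab, depth = 100, seed = 9))

  expect_error(rarefy(tab, depth = 10000, seed = 1), "below")

  # conservation across many seeds
  for (s in 1:25) {
    r <- rarefy(tab, depth = 57, seed = s)
    expect_true(all(colSums(r) == 57) && all(r <= tab))
  }
})

test_that("alpha diversity matches closed forms", {
  tab <- mk_tab(c(25, 25, 25, 25), paste0("f", 1:4), "s1")
  expect_equal(unname(alpha_diversity(tab, "shannon")), 2.0)     # 4 equal: 2 bits
  expect_equal(unname(alpha_diversity(tab, "simpson_e")), 1.0)   # uniform: E = 1
  expect_equal(unname(alpha_diversity(tab, "observed_features")), 4)

  skewed <- mk_tab(c(97, 1, 1, 1), paste0("f", 1:4), "s1")
  expect_lt(unname(alpha_diversity(skewed, "simpson_e")), 1.0)
  p <- c(97, 1, 1, 1) / 100
  expect_equal(unname(alpha_diversity(skewed, "shannon")), -sum(p * log2(p)))
})

test_that("faith_pd is the spanning branch length including the root path", {
  tree <- ape::read.tree(text = "((t1:1,t2:1):1,(t3:1,t4:1):2);")
  tab <- mk_tab(c(5, 0, 0, 0,   3, 3, 0, 0,   1, 1, 1, 1),
                paste0("t", 1:4), c("s1", "s2", "s3"))
  pd <- alpha_diversity(tab, "faith_pd", tree = tree)
  expect_equal(unname(pd["s1"]), 2)          # single tip: path to root
  expect_equal(unname(pd["s2"]), 3)
  expect_equal(unname(pd["s3"]), 7)          # whole tree

  bad <- mk_tab(c(1, 1), c("t1", "missing"), "s1")
  expect_error(alpha_diversity(bad, "faith_pd", tree = tree), "missing")
})

test_that("beta diversity metrics satisfy their closed forms and bounds", {
  tree <- ape::read.tree(text = "((t1:1,t2:1):1,(t3:1,t4:1):1);")
  feats <- paste0("t", 1:4)

  # identical columns -> distance 0 for every metric
  tab <- mk_tab(rep(c(4, 3, 2, 1), 2), feats, c("s1", "s2"))
  for (m in c("jaccard", "bray_curtis", "aitchison",
              "unweighted_unifrac", "weighted_unifrac")) {
    d <- beta_diversity(tab, m, tree = tree)
    expect_equal(unname(as.matrix(d)[1, 2]), 0,
                 tolerance = 1e-12, label = m)
  }

  # disjoint presence sets -> jaccard 1
  tab <- mk_tab(c(5, 3, 0, 0,   0, 0, 2, 9), feats, c("s1", "s2"))
  expect_equal(unname(as.matrix(beta_diversity(tab, "jaccard"))[1, 2]), 1)

  # samples (2,0) and (0,2) -> bray-curtis 1
  tab2 <- mk_tab(c(2, 0, 0, 2), c("a", "b"), c("s1", "s2"))
  expect_equal(unname(as.matrix(beta_diversity(tab2, "bray_curtis"))[1, 2]), 1)

  # aitchison equals the Euclidean distance of the CLR by hand
  tab3 <- mk_tab(c(3, 9, 1, 0, 4, 2), c("a", "b", "c"), c("s1", "s2"))
  x <- t(tab3) + 1
  clr <- log(x) - rowMeans(log(x))
  expect_equal(unname(as.matrix(beta_diversity(tab3, "aitchison"))[1, 2]),
               sqrt(sum((clr[1, ] - clr[2, ])^2)))

  # symmetry, zero diagonal, bounds, on random tables
  set.seed(52)
  tab4 <- mk_tab(rpois(4 * 5, 6), feats, paste0("s", 1:5))
  for (m in c("jaccard", "bray_curtis", "aitchison",
              "unweighted_unifrac", "weighted_unifrac")) {
    d <- as.matrix(beta_diversity(tab4, m, tree = tree))
    expect_equal(d, t(d), tolerance = 1e-12)
    expect_true(all(diag(d) == 0))
    if (m %in% c("jaccard", "bray_curtis"))
      expect_true(all(d >= 0 & d <= 1))
  }

  expect_error(beta_diversity(tab4, "unweighted_unifrac"), "tree")
})

test_that("kruskal_wallis reproduces the rank-sum oracle", {
  # identical value multisets: H = 0
  r <- kruskal_wallis(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(r$statistic, 0)

  # {1,2,3} vs {4,5,6}: H = 12/(6*7) * (6^2/3 + 15^2/3) - 3*7 = 27/7 = 3.857
  r <- kruskal_wallis(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(round(r$statistic, 3), 3.857)
  expect_equal(r$statistic, 27 / 7, tolerance = 1e-12)
  expect_equal(r$n_permutations, 0L)

  # rank invariance under constant shifts
  r2 <- kruskal_wallis(c(1, 2, 3, 4, 5, 6) + 100, rep(c("a", "b"), each = 3))
  expect_equal(r2$statistic, r$statistic)

  expect_error(kruskal_wallis(1:5, rep("a", 5)), "2 groups")
})

test_that("permanova matches the vegan pseudo-F and the permutation bound", {
  set.seed(53)
  x <- matrix(rnorm(18 * 6), 18)
  dm <- stats::dist(x)
  g <- rep(c("a", "b", "c"), each = 6)
  mine <- permanova(dm, g, n_permutations = 499, seed = 3)
  ora <- vegan::adonis2(dm ~ g, permutations = 499)
  expect_equal(mine$statistic, ora$F[1], tolerance = 1e-10)
  expect_gte(mine$p_value, 1 / 500)
  expect_lte(mine$p_value, 1)

  # two far-separated tight clusters at n = 20: every informative permutation
  # breaks the separation, so p attains the 1/(n_permutations + 1) floor
  z <- rbind(matrix(rnorm(10 * 3, 0, 0.1), 10),
             matrix(rnorm(10 * 3, 50, 0.1), 10))
  p20 <- permanova(stats::dist(z), rep(c("a", "b"), each = 10),
                   n_permutations = 999, seed = 1)$p_value
  expect_equal(p20, 1 / 1000)

  # at n = 6 (3 + 3) enumeration of all 20 label assignments shows 2 preserve
  # the partition and tie the observed F, so the exact p is 2/20 = 0.1 — not
  # the floor; the permutation p must approximate that enumeration oracle
  z6 <- rbind(matrix(rnorm(3 * 3, 0, 0.1), 3),
              matrix(rnorm(3 * 3, 50, 0.1), 3))
  d6 <- stats::dist(z6)
  g6 <- rep(c("a", "b"), each = 3)
  f_obs <- permanova(d6, g6, n_permutations = 0, seed = 1)$statistic
  assignments <- utils::combn(6, 3)
  n_ge <- sum(apply(assignments, 2, function(idx) {
    gi <- rep("b", 6); gi[idx] <- "a"
    permanova(d6, gi, n_permutations = 0, seed = 1)$statistic >= f_obs
  }))
  expect_equal(n_ge / ncol(assignments), 0.1)   # enumeration oracle
  p6 <- permanova(d6, g6, n_permutations = 999, seed = 2)$p_value
  expect_lt(abs(p6 - 0.1), 0.04)

  expect_error(permanova(dm, g[1:5]), "cover")
  expect_error(permanova(dm, rep("a", 18)), "2 groups")
})

test_that("compare_conditions pairs results and flags threshold crossings", {
  tr <- function(metric, stat, p) organaudit:::test_result(
    stat, p, 999L, "permanova", metric, "group")
  base <- list(tr("jaccard", 2.0, 0.04), tr("bray_curtis", 1.5, 0.20))
  ext_same <- list(tr("bray_curtis", 1.5, 0.20), tr("jaccard", 2.0, 0.04))

  out <- compare_conditions(base, ext_same)
  expect_equal(out$effect_fold, c(1, 1))
  expect_equal(out$p_shift, c(0, 0))
  expect_false(any(out$crossed))

  ext <- list(tr("jaccard", 1.0, 0.06), tr("bray_curtis", 1.5, 0.03))
  out <- compare_conditions(base, ext)
  j <- out[out$metric == "jaccard", ]
  expect_equal(j$effect_fold, 0.5)           # effect 2.0 -> 1.0
  expect_true(j$crossed)                     # 0.04 -> 0.06 crosses alpha
  expect_equal(j$direction, "significant->not")
  b <- out[out$metric == "bray_curtis", ]
  expect_equal(b$direction, "not->significant")

  expect_error(compare_conditions(base, ext[1]), "unpaired")
})
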