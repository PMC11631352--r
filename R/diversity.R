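#' Rarefy a feature table
#'
#' Per sample, subsamples exactly `depth` reads without replacement (seeded and
#' reproducible); samples with fewer than `depth` total reads are dropped with
#' a message.
#'
#' @param table feature table (integer matrix, features x samples).
#' @param depth rarefaction depth (default 1000, the depth the benchmark
#'   workflow rarefies to).
#' @param seed RNG seed; `NULL` uses the current RNG state.
#' @return rarefied feature table (same features, retained samples).
#' @export
rarefy <- function(table, depth = 1000L, seed = NULL) {
  table <- validate_feature_table(table)
  stopifnot(depth >= 1L)
  totals <- colSums(table)
  keep <- totals >= depth
  if (!any(keep)) stop("all samples are below the rarefaction depth ", depth)
  if (any(!keep))
    message("rarefy: dropping ", sum(!keep), " sample(s) below depth ", depth,
            ": ", paste(head(colnames(table)[!keep], 5), collapse = ", "))
  out <- table[, keep, drop = FALSE]
  with_seed(seed, {
    for (j in seq_len(ncol(out))) {
      counts <- out[, j]
      # draw `depth` reads uniformly without replacement from the multiset
      picks <- sample.int(sum(counts), depth)
      breaks <- cumsum(counts)
      feat <- findInterval(picks - 1L, c(0L, breaks), rightmost.closed = FALSE)
      newc <- tabulate(feat, nbins = nrow(out))
      out[, j] <- newc
    }
    out
  })
}

#' Alpha diversity
#'
#' Metrics: `observed_features` (count of nonzero features), `shannon`
#' (-sum p log2 p, bits), `simpson_e` (Simpson's evenness, inverse Simpson over
#' observed richness: (1/sum p^2)/S_obs), `faith_pd` (total branch length of
#' the minimal subtree spanning the observed tips and the root).
#'
#' @param table feature table.
#' @param metric one of `"observed_features"`, `"shannon"`, `"simpson_e"`,
#'   `"faith_pd"`.
#' @param tree `ape::phylo` tree (required for `faith_pd`; every nonzero
#'   feature must be a tip).
#' @return named numeric vector, one value per sample.
#' @export
alpha_diversity <- function(table, metric = c("observed_features", "shannon",
                                              "simpson_e", "faith_pd"),
                            tree = NULL) {
  table <- validate_feature_table(table)
  metric <- match.arg(metric)
  vals <- switch(metric,
    observed_features = colSums(table > 0),
    shannon = apply(table, 2L, function(x) {
      p <- x[x > 0] / sum(x)
      if (length(p) == 0) return(NA_real_)
      -sum(p * log2(p))
    }),
    simpson_e = apply(table, 2L, function(x) {
      p <- x[x > 0] / sum(x)
      if (length(p) == 0) return(NA_real_)
      (1 / sum(p^2)) / length(p)
    }),
    faith_pd = {
      if (is.null(tree)) stop("faith_pd requires a tree")
      apply(table, 2L, function(x) faith_pd_one(rownames(table)[x > 0], tree))
    })
  setNames(as.numeric(vals), colnames(table))
}

# Faith's PD for one set of observed tips, path to the root included.
faith_pd_one <- function(tips, tree) {
  if (length(tips) == 0) return(0)
  missing <- setdiff(tips, tree$tip.label)
  if (length(missing) > 0)
    stop("features absent from tree: ", paste(head(missing, 5), collapse = ", "))
  ntip <- length(tree$tip.label)
  present <- logical(ntip + tree$Nnode)
  present[match(tips, tree$tip.label)] <- TRUE
  # postorder: propagate tip presence up; an edge counts if its child subtree
  # contains an observed tip (this includes the path to the root).
  edge <- tree$edge[ape::postorder(tree), , drop = FALSE]
  lens <- tree$edge.length[ape::postorder(tree)]
  pd <- 0
  for (e in seq_len(nrow(edge))) {
    child <- edge[e, 2]; parent <- edge[e, 1]
    if (present[child]) {
      pd <- pd + lens[e]
      present[parent] <- TRUE
    }
  }
  pd
}

#' Beta diversity distance matrix
#'
#' Metrics: `jaccard` (presence/absence, 1 - |A&B|/|A|B|), `bray_curtis`,
#' `aitchison` (Euclidean distance of CLR-transformed counts + pseudocount;
#' apply to unrarefied counts), `unweighted_unifrac` and `weighted_unifrac`
#' (standard branch-length definitions; weighted is the unnormalised variant).
#'
#' @param table feature table.
#' @param metric metric name.
#' @param tree `ape::phylo` (required for UniFrac metrics).
#' @param pseudocount added to counts before the CLR (Aitchison only).
#' @return a `dist` object over samples.
#' @export
beta_diversity <- function(table, metric = c("jaccard", "bray_curtis",
                                             "aitchison", "unweighted_unifrac",
                                             "weighted_unifrac"),
                           tree = NULL, pseudocount = 1) {
  table <- validate_feature_table(table)
  metric <- match.arg(metric)
  x <- t(table)  # vegan convention: rows = samples
  switch(metric,
    jaccard = vegan::vegdist(x, method = "jaccard", binary = TRUE),
    bray_curtis = vegan::vegdist(x, method = "bray"),
    aitchison = {
      lx <- log(x + pseudocount)
      clr <- lx - rowMeans(lx)
      stats::dist(clr)
    },
    unweighted_unifrac = unifrac_dist(table, tree, weighted = FALSE),
    weighted_unifrac = unifrac_dist(table, tree, weighted = TRUE))
}

unifrac_dist <- function(table, tree, weighted) {
  if (is.null(tree)) stop("UniFrac metrics require a tree")
  missing <- setdiff(rownames(table)[rowSums(table) > 0], tree$tip.label)
  if (length(missing) > 0)
    stop("features absent from tree: ", paste(head(missing, 5), collapse = ", "))
  ps <- phyloseq::phyloseq(
    phyloseq::otu_table(table, taxa_are_rows = TRUE),
    phyloseq::phy_tree(tree))
  phyloseq::UniFrac(ps, weighted = weighted, normalized = FALSE, fast = TRUE)
}

#' Kruskal-Wallis rank-sum test
#'
#' H statistic with tie correction; p-value from the chi-square approximation
#' with (groups - 1) degrees of freedom. The statistic is reported as the
#' effect size.
#'
#' @param values per-sample numeric values.
#' @param groups per-sample group labels (>= 2 non-empty groups).
#' @param metric,grouping optional names recorded in the result.
#' @return a `test_result`: `statistic`, `p_value`, `n_permutations` (0:
#'   analytic), `method`, `metric`, `grouping`.
#' @export
kruskal_wallis <- function(values, groups, metric = NA_character_,
                           grouping = NA_character_) {
  groups <- as.factor(as.character(groups))
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (any(table(groups) == 0L)) stop("a group has 0 samples")
  kt <- stats::kruskal.test(values, groups)
  test_result(statistic = unname(kt$statistic), p_value = kt$p.value,
              n_permutations = 0L, method = "kruskal-wallis",
              metric = metric, grouping = grouping)
}

test_result <- function(statistic, p_value, n_permutations, method,
                        metric = NA_character_, grouping = NA_character_) {
  structure(list(statistic = statistic, p_value = p_value,
                 n_permutations = n_permutations, method = method,
                 metric = metric, grouping = grouping),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat("<test_result> ", x$method,
      if (!is.na(x$metric)) paste0(" [", x$metric, "]"),
      ": statistic = ", signif(x$statistic, 4),
      ", p = ", signif(x$p_value, 4),
      if (x$n_permutations > 0) paste0(" (", x$n_permutations, " permutations)"),
      "\n", sep = "")
  invisible(x)
}

#' One-way PERMANOVA
#'
#' Pseudo-F from the standard one-way decomposition of squared inter-sample
#' distances (among/within groups); the p-value is
#' (1 + #\{permuted F >= observed F\}) / (1 + n_permutations) under seeded
#' label permutations.
#'
#' @param dm a `dist` object (or symmetric matrix) over samples.
#' @param groups group labels covering the samples of `dm` (>= 2 groups).
#' @param n_permutations number of label permutations (default 999; the
#'   large-scale analyses the package mirrors used 999999, available here but
#'   not a desk-scale default).
#' @param seed RNG seed for the permutations.
#' @param metric,grouping optional names recorded in the result.
#' @return a `test_result` (method `"permanova"`).
#' @export
permanova <- function(dm, groups, n_permutations = 999L, seed = NULL,
                      metric = NA_character_, grouping = NA_character_) {
  d <- as.matrix(dm)
  if (!isSymmetric(unname(d), tol = 1e-12)) stop("distance matrix not symmetric")
  n <- nrow(d)
  groups <- as.factor(as.character(groups))
  if (length(groups) != n) stop("labels do not cover the distance matrix")
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (any(table(groups) < 1L)) stop("a group has < 1 sample")
  d2 <- d^2
  g <- nlevels(groups)
  lev_ids <- seq_len(g)
  gi0 <- as.integer(groups)
  ss_total <- sum(d2) / (2 * n)
  f_stat <- function(gi) {
    ss_within <- 0
    for (lev in lev_ids) {
      idx <- gi == lev
      # sum over the full block double-counts pairs; divide by 2 * group size
      ss_within <- ss_within + sum(d2[idx, idx]) / (2 * sum(idx))
    }
    ss_among <- ss_total - ss_within
    (ss_among / (g - 1)) / (ss_within / (n - g))
  }
  observed <- f_stat(gi0)
  perm_ge <- with_seed(seed, {
    count <- 0L
    for (i in seq_len(n_permutations)) {
      if (f_stat(gi0[sample.int(n)]) >= observed) count <- count + 1L
    }
    count
  })
  test_result(statistic = observed,
              p_value = (1 + perm_ge) / (1 + n_permutations),
              n_permutations = as.integer(n_permutations),
              method = "permanova", metric = metric, grouping = grouping)
}

#' Compare test results between base and extended references
#'
#' Pairs results by (metric, grouping variable) and reports, per pair, the
#' effect-size fold-change (extended / base), the p-value shift (extended -
#' base), and whether the pair crosses alpha = 0.05 in either direction. A
#' Benjamini-Hochberg adjusted p-value column is emitted alongside for
#' convenience; the crossing flag uses raw p-values.
#'
#' @param results_base,results_ext lists of `test_result` objects.
#' @param alpha significance threshold for the crossing flag.
#' @return data frame: `metric`, `grouping`, `method`, `effect_base`,
#'   `effect_ext`, `effect_fold`, `p_base`, `p_ext`, `p_shift`, `crossed`,
#'   `direction`, `p_base_bh`, `p_ext_bh`.
#' @export
compare_conditions <- function(results_base, results_ext, alpha = 0.05) {
  key <- function(r) paste(r$metric, r$grouping, sep = "||")
  kb <- vapply(results_base, key, character(1))
  ke <- vapply(results_ext, key, character(1))
  if (anyDuplicated(kb) || anyDuplicated(ke))
    stop("duplicate (metric, grouping) pairs in results")
  unpaired <- c(setdiff(kb, ke), setdiff(ke, kb))
  if (length(unpaired) > 0)
    stop("unpaired entries: ", paste(gsub("\\|\\|", " / ", unpaired),
                                     collapse = ", "))
  results_ext <- results_ext[match(kb, ke)]
  eb <- vapply(results_base, `[[`, numeric(1), "statistic")
  ee <- vapply(results_ext, `[[`, numeric(1), "statistic")
  pb <- vapply(results_base, `[[`, numeric(1), "p_value")
  pe <- vapply(results_ext, `[[`, numeric(1), "p_value")
  crossed <- (pb <= alpha) != (pe <= alpha)
  direction <- ifelse(!crossed, "none",
                      ifelse(pb <= alpha, "significant->not", "not->significant"))
  data.frame(
    metric = vapply(results_base, `[[`, character(1), "metric"),
    grouping = vapply(results_base, `[[`, character(1), "grouping"),
    method = vapply(results_base, `[[`, character(1), "method"),
    effect_base = eb, effect_ext = ee, effect_fold = ee / eb,
    p_base = pb, p_ext = pe, p_shift = pe - pb,
    crossed = crossed, direction = direction,
    p_base_bh = stats::p.adjust(pb, "BH"),
    p_ext_bh = stats::p.adjust(pe, "BH"),
    stringsAsFactors = FALSE)
}

#' Alpha + beta diversity group-significance analysis
#'
#' The per-study workflow: rarefy, compute each requested alpha metric and test
#' it against the grouping column with Kruskal-Wallis; compute each requested
#' beta metric and test it with PERMANOVA. Aitchison distances are computed on
#' the unrarefied table (CLR of counts + pseudocount), as compositional
#' methods require.
#'
#' @param table feature table (unrarefied).
#' @param metadata data frame with `sample_id` and the grouping column.
#' @param column name of the grouping column.
#' @param alpha_metrics,beta_metrics metric names (see [alpha_diversity()],
#'   [beta_diversity()]); UniFrac/Faith metrics are skipped with a message when
#'   no tree is given.
#' @param tree optional `ape::phylo`.
#' @param depth rarefaction depth.
#' @param n_permutations PERMANOVA permutations.
#' @param seed seed for rarefaction and permutations.
#' @return list of `test_result` objects (one per metric).
#' @export
diversity_analysis <- function(table, metadata, column,
                               alpha_metrics = c("observed_features", "shannon",
                                                 "simpson_e"),
                               beta_metrics = c("jaccard", "bray_curtis",
                                                "aitchison"),
                               tree = NULL, depth = 1000L,
                               n_permutations = 999L, seed = 0L) {
  table <- validate_feature_table(table)
  if (is.null(tree)) {
    drop <- c(alpha_metrics, beta_metrics) %in%
      c("faith_pd", "unweighted_unifrac", "weighted_unifrac")
    if (any(drop))
      message("no tree supplied; skipping phylogenetic metrics")
    alpha_metrics <- setdiff(alpha_metrics, "faith_pd")
    beta_metrics <- setdiff(beta_metrics,
                            c("unweighted_unifrac", "weighted_unifrac"))
  }
  rt <- rarefy(table, depth = depth, seed = seed)
  md <- metadata[match(colnames(rt), metadata$sample_id), ]
  if (anyNA(md$sample_id)) stop("metadata does not cover all samples")
  grp <- md[[column]]
  results <- list()
  for (m in alpha_metrics) {
    vals <- alpha_diversity(rt, m, tree = tree)
    results[[m]] <- kruskal_wallis(vals, grp, metric = m, grouping = column)
  }
  for (m in beta_metrics) {
    dm <- if (m == "aitchison")
      beta_diversity(table[, colnames(rt), drop = FALSE], m)
    else beta_diversity(rt, m, tree = tree)
    results[[m]] <- permanova(dm, grp, n_permutations = n_permutations,
                              seed = seed, metric = m, grouping = column)
  }
  results
}
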