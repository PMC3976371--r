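# Seeded study-condition experiments shared by the acceptance tests.

# The most isolated 2-step tree in the pool: fewest pool trees within RF 2
# (ties broken by largest summed RF). Chosen by topology alone, before any
# data are simulated.
pick_isolated_nni2 <- function(pool) {
  rf <- as.matrix(phangorn::RF.dist(pool$trees))
  idxs <- which(pool$origin == "nni2")
  near <- sapply(idxs, function(i) sum(rf[i, ] <= 2))
  tot <- sapply(idxs, function(i) sum(rf[i, ]))
  idxs[order(near, -tot)][1]
}

# One partitioned-RAD run on synthetic data. Two regimes share the machinery:
#  * no-conflict ("negative result"): shallow backbone signal and heavy,
#    phylogenetically structured missingness — every locus from the species
#    tree; the optimal tree should top the favor counts without exceeding the
#    prediction interval.
#  * hybridization detection: deeper backbone, mild missingness, an
#    ILS-like per-locus topology switch among the 1-step neighbors for the
#    backbone loci, and 30% of loci from one 2-step alternative whose
#    internal edges are half-length (a recent hybrid divergence: coherent but
#    shallow signal). The alternative should be flagged above the interval.
# Per-locus tables use the pool's fixed branch lengths; the total-data
# likelihoods (the regression x-axis) are branch-length optimized.
partition_experiment <- function(seed, mix_frac, depth, retain, drop_rate,
                                 switch_prob, n_loci = 250L, len = 50L,
                                 n_taxa = 10L, n_perm = 30L,
                                 alt_internal_scale = 0.5) {
  tr <- simulate_tree(n_taxa, depth, 777)
  pool <- build_tree_pool(tr, n_perm, 101)
  pool$trees <- lapply(pool$trees, function(t) {
    t$edge.length <- rep(depth / 3, nrow(t$edge)); t })
  class(pool$trees) <- "multiPhylo"
  alt_idx <- pick_isolated_nni2(pool)
  alt_topo <- pool$trees[[alt_idx]]
  internal <- alt_topo$edge[, 2] > length(alt_topo$tip.label)
  alt_topo$edge.length[internal] <- alt_internal_scale * depth / 3
  nni1 <- pool$trees[pool$origin == "nni1"]
  class(nni1) <- "multiPhylo"
  n_alt <- round(mix_frac * n_loci)
  loci <- simulate_loci(tr, sim_config(n_taxa, n_loci - n_alt, len,
                                       tree_depth = depth,
                                       site_dropout_rate = drop_rate,
                                       coverage_retain_prob = retain,
                                       rng_seed = seed),
                        switch_trees = if (switch_prob > 0) nni1,
                        switch_prob = switch_prob)$loci
  if (n_alt > 0) {
    al <- simulate_loci(alt_topo, sim_config(n_taxa, n_alt, len,
                                             tree_depth = depth,
                                             site_dropout_rate = drop_rate,
                                             coverage_retain_prob = retain,
                                             rng_seed = seed + 5000L))$loci
    for (i in seq_along(al)) al[[i]]$locus_id <- sprintf("A%06d", i)
    loci <- c(loci, al)
  }
  fit <- rad_partition(loci, pool = pool,
                       config = partition_config(min_trees = 20L),
                       optimize = FALSE, optimize_total = TRUE)
  tab <- fit$regression$table
  list(top_is_opt = fit$favor$n_favoring[1L] == max(fit$favor$n_favoring),
       opt_outlier = tab$outlier[tab$tree_index == 1L],
       alt_outlier = tab$outlier[tab$tree_index == alt_idx],
       n_used = fit$n_loci_used)
}

no_conflict_run <- function(seed) {
  partition_experiment(seed, mix_frac = 0, depth = 0.04, retain = 0.8,
                       drop_rate = 2, switch_prob = 0)
}

hybridization_run <- function(seed) {
  partition_experiment(seed, mix_frac = 0.3, depth = 0.08, retain = 0.9,
                       drop_rate = 1, switch_prob = 0.4)
}

# EST-vs-non-EST comparison on synthetic loci: "genic" loci evolve at half
# the substitution rate of the background loci on the same topology.
est_rate_half_run <- function(seed, n_est = 25L, n_non = 150L,
                              n_replicates = 50L) {
  n_taxa <- 8L
  tr <- simulate_tree(n_taxa, 0.08, 321)
  half <- tr; half$edge.length <- tr$edge.length * 0.5
  mod <- subst_model(n_categories = 1L)
  est <- simulate_loci(half, sim_config(n_taxa, n_est, 50L, tree_depth = 0.04,
                                        site_dropout_rate = 0,
                                        coverage_retain_prob = 1,
                                        rng_seed = seed))$loci
  non <- simulate_loci(tr, sim_config(n_taxa, n_non, 50L, tree_depth = 0.08,
                                      site_dropout_rate = 0,
                                      coverage_retain_prob = 1,
                                      rng_seed = seed + 4000L))$loci
  for (i in seq_along(non)) non[[i]]$locus_id <- sprintf("N%06d", i)
  cmp <- est_compare(est, non, tr$tip.label,
                     subsample_config(n_replicates = n_replicates,
                                      rng_seed = seed),
                     model = mod, search = "start")
  tst <- cmp$test
  pi_row <- tst[tst$statistic == "n_pi", ]
  tip_row <- tst[tst$statistic == "tip_proportion", ]
  list(pi_sig_low = pi_row$p < 0.05 && pi_row$observed < pi_row$null_mean,
       tip_sig = tip_row$p < 0.05,
       tip_diff = tip_row$observed - tip_row$null_mean)
}

# Technical-replicate experiment: thin one individual's locus set twice at
# the retention rate matching the observed mean replicate overlap (0.552),
# give the replicate identical consensus sequences where present, and
# re-infer the tree.
replicate_sister_run <- function(seed, target = "t1") {
  n_taxa <- 10L
  tr <- simulate_tree(n_taxa, 0.05, 600L + seed)
  st <- simulate_loci(tr, sim_config(n_taxa, 150L, 50L, rng_seed = 600L + seed))
  r <- 2 * 0.552 / 1.552
  rep_name <- paste0(target, "rep")
  loci2 <- list()
  set.seed(900L + seed)
  for (l in st$loci) {
    seqs <- apply(l$seqs, 1L, paste, collapse = "")
    if (target %in% names(seqs)) {
      s <- seqs[[target]]
      if (stats::runif(1) > r) seqs <- seqs[names(seqs) != target]
      if (stats::runif(1) < r) seqs <- c(seqs, stats::setNames(s, rep_name))
    }
    if (length(seqs) >= 4L)
      loci2[[length(loci2) + 1L]] <- rad_locus(l$locus_id, seqs)
  }
  sm <- concatenate_loci(loci2, c(tr$tip.label, rep_name))
  mod <- subst_model(n_categories = 1L)
  fit <- nni_hill_climb(sm$matrix, mod,
                        radpartition:::distance_start_tree(sm$matrix))
  tt <- fit$tree
  tips <- match(c(target, rep_name), tt$tip.label)
  parents <- tt$edge[match(tips, tt$edge[, 2L]), 1L]
  list(sister = parents[1L] == parents[2L],
       branches = tt$edge.length[match(tips, tt$edge[, 2L])])
}
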