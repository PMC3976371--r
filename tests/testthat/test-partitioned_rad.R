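make_pool <- function(ntaxa = 8, n_permuted = 20L, seed = 5L) {
  set.seed(seed)
  build_tree_pool(random_tree(ntaxa, 0.15), n_permuted, seed)
}

test_that("partition filters drop sparse, invariant, and over-pruned loci", {
  pool <- make_pool()
  taxa <- pool$trees[[1]]$tip.label
  cfg <- partition_config(min_trees = 5L)

  sparse <- rad_locus("L1", stats::setNames(rep(strrep("ACGTG", 10), 3),
                                            taxa[1:3]))
  inv <- invariant_locus("L2", taxa)
  set.seed(7)
  good <- rad_locus("L3", random_alignment(8, 50, taxa = taxa))
  res <- filter_partition_loci(list(sparse, inv, good), pool, cfg)
  expect_length(res$loci, 1L)
  expect_equal(res$loci[[1]]$locus_id, "L3")
  expect_setequal(res$dropped$reason, c("min_individuals", "no_PI"))

  # a locus with every pool taxon keeps the whole pool after pruning
  expect_length(res$pruned[[1]]$trees, length(pool$trees))

  # a stringent min_trees drops loci whose pruned pool collapses
  strict <- partition_config(min_trees = length(pool$trees) + 1L)
  res2 <- filter_partition_loci(list(good), pool, strict)
  expect_length(res2$loci, 0L)
  expect_equal(res2$dropped$reason, "min_trees")
})

test_that("per-locus tree tables rank the generating topology first", {
  # all internal edges long, so any NNI rearrangement costs likelihood
  t1 <- ape::read.tree(
    text = "(((a:0.1,b:0.1):0.15,(c:0.1,d:0.1):0.15):0.15,(e:0.1,f:0.1):0.1);")
  t1 <- ape::unroot(t1)
  set.seed(17)
  t2 <- nni_neighbors(t1)[[1]]
  pool <- structure(list(trees = structure(list(t1, t2), class = "multiPhylo"),
                         origin = c("optimal", "nni1"),
                         ids = c(canonical_id(t1), canonical_id(t2))),
                    class = "rad_tree_pool")
  pr <- prune_and_dedup(pool, t1$tip.label)
  mod <- subst_model(n_categories = 1L)
  sim <- toupper(as.character(phangorn::simSeq(t1, l = 600, Q = mod$rates,
                                               bf = mod$base_freqs)))
  loc <- rad_locus("L1", sim)
  tab <- locus_tree_table(loc, pr, mod, min_ll_range = 4)
  expect_gt(tab$loglik[1], tab$loglik[2])
  expect_false(tab$excluded)

  # internal consistency with direct engine calls
  direct <- optimize_branch_lengths(sim, pr$trees[[2]], mod)$loglik
  expect_equal(tab$loglik[2], direct, tolerance = 1e-6)

  # an invariant locus is flat and excluded
  flat <- invariant_locus("L2", t1$tip.label)
  tabf <- locus_tree_table(flat, pr, mod, min_ll_range = 4)
  expect_equal(tabf$ll_range, 0)
  expect_true(tabf$excluded)
})

test_that("favor/disfavor counting applies the log-likelihood window", {
  pool <- list(trees = structure(vector("list", 3), class = "multiPhylo"),
               origin = c("optimal", "nni1", "nni1"),
               ids = c("a", "b", "c"))
  class(pool) <- "rad_tree_pool"
  tb <- fake_table("L1", c(-100, -101.5, -110))
  ft <- favor_disfavor(list(tb), pool, partition_config(min_trees = 1L))
  expect_equal(ft$n_favoring, c(1L, 1L, 0L))
  expect_equal(ft$n_disfavoring, c(0L, 0L, 1L))

  # excluded tables contribute nothing
  flat <- fake_table("L2", c(-100, -100, -100))
  expect_true(flat$excluded)
  ft2 <- favor_disfavor(list(tb, flat), pool, partition_config(min_trees = 1L))
  expect_equal(ft2$n_favoring, ft$n_favoring)
  expect_equal(attr(ft2, "n_loci"), 1L)

  # every locus favors at least its own best tree
  set.seed(23)
  tabs <- lapply(1:10, function(i)
    fake_table(paste0("L", i), -100 - runif(3) * 20))
  tabs <- Filter(function(t) !t$excluded, tabs)
  ft3 <- favor_disfavor(tabs, pool, partition_config(min_trees = 1L))
  expect_gte(sum(ft3$n_favoring), length(tabs))

  # order invariance
  ft4 <- favor_disfavor(rev(tabs), pool, partition_config(min_trees = 1L))
  expect_equal(ft4$n_favoring, ft3$n_favoring)
  expect_equal(ft4$n_disfavoring, ft3$n_disfavoring)
})

test_that("index maps propagate pruned-tree status to all pool trees", {
  pool <- list(trees = structure(vector("list", 4), class = "multiPhylo"),
               origin = c("optimal", "nni1", "nni1", "nni2"),
               ids = letters[1:4])
  class(pool) <- "rad_tree_pool"
  # trees 2 and 4 collapse to the same pruned representative (index 2)
  tb <- fake_table("L1", c(-100, -104.5), index_map = c(1L, 2L, 1L, 2L))
  ft <- favor_disfavor(list(tb), pool, partition_config(min_trees = 1L))
  expect_equal(ft$n_favoring, c(1L, 0L, 1L, 0L))
  expect_equal(ft$n_disfavoring, c(0L, 1L, 0L, 1L))
})

test_that("the support regression flags constructed outliers only", {
  set.seed(29)
  ll <- seq(-1000, -900, length.out = 50)
  counts <- 500 + 2 * ll + rnorm(50, 0, 3)
  favor <- data.frame(tree_index = 1:50,
                      origin = c("optimal", rep("nni1", 49)),
                      total_ll = ll, n_favoring = counts,
                      n_disfavoring = 0)
  reg <- support_regression(favor)
  expect_equal(reg$slope, 2, tolerance = 0.1)

  # exact linearity: zero residual SD, no outliers
  exact <- favor; exact$n_favoring <- 500 + 2 * ll
  rex <- suppressWarnings(support_regression(exact))  # zero-residual lm note
  expect_lt(rex$sigma, 1e-8)
  expect_false(any(rex$table$outlier))

  # inflate one tree by 10 residual SDs
  infl <- favor
  infl$n_favoring[25] <- infl$n_favoring[25] + 10 * reg$sigma
  rinf <- support_regression(infl)
  expect_true(rinf$table$outlier[25])
  expect_lte(sum(rinf$table$outlier), 3L)

  flat <- favor; flat$total_ll <- -950
  expect_error(support_regression(flat), "degenerate regressor")
  expect_error(support_regression(favor[1:2, ]), "at least 3")
})

test_that("likelihood-island trimming keeps the upper mode", {
  favor <- data.frame(tree_index = 1:6, origin = "nni1",
                      total_ll = c(-100, -101, -102, -300, -301, -302),
                      n_favoring = 1:6, n_disfavoring = 0)
  class(favor) <- c("rad_favor_table", "data.frame")
  expect_identical(nrow(trim_likelihood_islands(favor, -1e6)), 6L)
  expect_error(trim_likelihood_islands(favor, -50), "every tree")
  up <- trim_likelihood_islands(favor, -200)
  expect_equal(up$tree_index, 1:3)
})

test_that("the full fit returns a classed object with working methods", {
  set.seed(37)
  tr <- random_tree(8, 0.2)
  # long loci so single loci can discriminate among neighboring topologies
  cfg <- sim_config(n_taxa = 8, n_loci = 40, locus_length = 200,
                    tree_depth = 0.2, site_dropout_rate = 0,
                    coverage_retain_prob = 1, rng_seed = 37)
  st <- simulate_loci(tr, cfg)
  fit <- rad_partition(st$loci, optimal = tr, n_permuted = 14L, rng_seed = 3,
                       config = partition_config(min_trees = 10L),
                       optimize = FALSE)
  expect_s3_class(fit, "rad_partition")
  expect_named(coef(fit), c("intercept", "slope"))
  expect_output(print(fit), "rad_partition")
  s <- summary(fit)
  expect_true(s$optimal_is_top)
  expect_equal(nrow(fit$favor), 15L)
  # plot method draws without error
  tmp <- tempfile(fileext = ".pdf")
  grDevices::pdf(tmp)
  expect_silent(plot(fit))
  expect_silent(plot(fit, which = "disfavor"))
  grDevices::dev.off()
  expect_true(file.exists(tmp))
})
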