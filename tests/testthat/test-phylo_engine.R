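test_that("site likelihoods hit closed forms on two-taxon trees", {
  # identical sequences, (near-)zero branch lengths: per-site LL = log pi(base)
  tr <- ape::read.tree(text = "(a:0,b:0);")
  m <- rbind(a = c("A", "C", "G", "T"), b = c("A", "C", "G", "T"))
  bf <- c(0.1, 0.2, 0.3, 0.4)
  ll <- site_log_likelihoods(m, tr, subst_model(bf))
  expect_equal(ll, log(bf), tolerance = 1e-6)

  # Jukes-Cantor closed form, single rate category
  d <- 0.27
  trd <- ape::read.tree(text = sprintf("(a:%f,b:%f);", d / 2, d / 2))
  m2 <- rbind(a = c("A", "A"), b = c("A", "G"))
  jc <- subst_model(n_categories = 1L)
  ll2 <- site_log_likelihoods(m2, trd, jc)
  p_same <- 1 / 4 + 3 / 4 * exp(-4 * d / 3)
  p_diff <- 1 / 4 - 1 / 4 * exp(-4 * d / 3)
  expect_equal(ll2, log(0.25 * c(p_same, p_diff)), tolerance = 1e-8)
})

test_that("pruning likelihood equals exhaustive enumeration on small instances", {
  set.seed(31)
  for (i in 1:8) {
    n <- sample(4:6, 1)
    tr <- random_tree(n, 0.15)
    m <- random_alignment(n, sample(3:6, 1), p_missing = 0.15)
    if (i %% 2 == 0) m[1, 1] <- sample(c("R", "Y", "M"), 1)
    mod <- random_model()
    mine <- site_log_likelihoods(m, tr, mod)
    orc <- oracle_site_loglik(m, tr, mod$base_freqs, mod$rates,
                              mod$alpha, mod$n_categories)
    expect_equal(mine, orc, tolerance = 1e-8)
  }
})

test_that("total likelihood is invariant under re-rooting (pulley principle)", {
  set.seed(32)
  tr <- random_tree(7, 0.1)
  m <- random_alignment(7, 40)
  mod <- subst_model(c(0.3, 0.2, 0.3, 0.2), c(1, 2, 1, 1, 2, 1), 0.6)
  ref <- sum(site_log_likelihoods(m, tr, mod))
  for (og in c("t2", "t5", "t7")) {
    rr <- ape::unroot(ape::root(tr, og, resolve.root = TRUE))
    expect_equal(sum(site_log_likelihoods(m, rr, mod)), ref,
                 tolerance = 1e-8)
  }
})

test_that("one rate category reduces GTR+GAMMA to plain GTR", {
  set.seed(33)
  tr <- random_tree(5, 0.1)
  m <- random_alignment(5, 20)
  bf <- c(0.28, 0.22, 0.26, 0.24)
  rates <- c(1.5, 3, 0.8, 1.2, 2.5, 1)
  k1 <- site_log_likelihoods(m, tr, subst_model(bf, rates, alpha = 7,
                                                n_categories = 1L))
  orc <- oracle_site_loglik(m, tr, bf, rates, k = 1L)
  expect_equal(k1, orc, tolerance = 1e-8)
})

test_that("branch lengths are recovered, clamped, and stable at the optimum", {
  # recovery: two taxa separated by 0.1 substitutions/site, 10,000 sites
  truth <- ape::read.tree(text = "(a:0.05,b:0.05);")
  mod <- subst_model(n_categories = 1L)
  set.seed(41)
  sim <- toupper(as.character(
    phangorn::simSeq(truth, l = 10000, Q = mod$rates, bf = mod$base_freqs)))
  fit <- optimize_branch_lengths(sim, truth, mod)
  expect_lt(abs(sum(fit$tree$edge.length) - 0.1), 0.02)

  # identical sequences drive every branch to the lower clamp
  same <- rbind(a = rep("A", 60), b = rep("A", 60),
                c = rep("A", 60), d = rep("A", 60))
  q <- ape::read.tree(text = "((a:0.1,b:0.1):0.1,(c:0.1,d:0.1):0.1);")
  flat <- optimize_branch_lengths(same, q, mod)
  expect_true(all(flat$tree$edge.length <= 1e-6))

  # re-optimizing an optimum changes the likelihood by less than tol
  set.seed(42)
  tr <- random_tree(5, 0.1)
  m <- toupper(as.character(
    phangorn::simSeq(tr, l = 300, Q = mod$rates, bf = mod$base_freqs)))
  once <- optimize_branch_lengths(m, tr, mod, tol = 1e-3)
  twice <- optimize_branch_lengths(m, once$tree, mod, tol = 1e-3)
  expect_lt(abs(twice$loglik - once$loglik), 1e-2)
})

test_that("model estimation recovers frequencies and rate ratios", {
  set.seed(51)
  tr <- random_tree(6, 0.15)
  rates <- c(1, 2, 1, 1, 2, 1)
  sim <- toupper(as.character(
    phangorn::simSeq(tr, l = 20000, Q = rates, bf = rep(0.25, 4))))
  est <- estimate_model(sim, tr, n_categories = 1L)
  expect_true(all(abs(est$base_freqs - 0.25) < 0.02))
  # AG/AC exchangeability ratio simulated at 2
  expect_lt(abs(est$rates[2] / est$rates[1] - 2) / 2, 0.25)
})

test_that("Fitch steps match brute force, including ambiguity and missing", {
  q <- ape::read.tree(text = "((w:1,x:1):1,(y:1,z:1):1);")
  # grouping unlike states forces two changes
  m <- rbind(w = "A", x = "C", y = "A", z = "C")
  expect_equal(fitch_steps(m, q), 2L)
  expect_equal(oracle_fitch(m, q), 2L)

  expect_equal(fitch_steps(rbind(w = "A", x = "A", y = "A", z = "A"), q), 0L)
  expect_equal(fitch_steps(rbind(w = "A", x = "N", y = "N", z = "N"), q), 0L)

  set.seed(61)
  for (i in 1:5) {
    n <- sample(4:6, 1)
    tr <- random_tree(n)
    m <- random_alignment(n, 10, p_missing = 0.2)
    m[sample(length(m), 3)] <- sample(c("R", "Y", "S"), 3, replace = TRUE)
    expect_equal(fitch_steps(m, tr), oracle_fitch(m, tr))
  }
})

test_that("character classification counts variable, PI, and excluded sites", {
  m <- rbind(a = c("A", "A", "N", "A"),
             b = c("A", "A", "N", "T"),
             c = c("G", "A", "N", "-"),
             d = c("G", "G", "N", "T"))
  cc <- classify_characters(m)
  expect_equal(cc$n_sites, 4L)
  expect_equal(cc$n_variable, 3L)          # cols 1, 2, 4
  expect_equal(cc$n_parsimony_informative, 1L)  # only col 1 (2 A's, 2 G's)
  expect_equal(cc$n_all_missing_excluded, 1L)
  expect_equal(cc$missing_proportion, 5 / 16)
})

test_that("consistency index measures homoplasy and never exceeds 1", {
  q <- ape::read.tree(text = "((w:1,x:1):1,(y:1,z:1):1);")
  m <- rbind(w = "A", x = "C", y = "A", z = "C")
  expect_equal(consistency_index(m, q), 0.5)

  # homoplasy-free: one change on the internal edge
  m2 <- rbind(w = c("A", "C"), x = c("A", "C"), y = c("G", "C"), z = c("G", "C"))
  expect_equal(consistency_index(m2, q), 1)

  set.seed(71)
  for (i in 1:5) {
    n <- sample(4:6, 1)
    tr <- random_tree(n)
    m <- random_alignment(n, 30, p_missing = 0.1)
    steps <- fitch_steps(m, tr)
    if (steps > 0) expect_lte(consistency_index(m, tr), 1)
  }

  # CI weakly decreases as homoplasy is injected
  set.seed(72)
  tr6 <- random_tree(6, 0.05)
  clean <- toupper(as.character(phangorn::simSeq(tr6, l = 400)))
  noisy <- clean
  idx <- sample(length(noisy), 150)
  noisy[idx] <- sample(c("A", "C", "G", "T"), 150, replace = TRUE)
  expect_lte(consistency_index(noisy, tr6), consistency_index(clean, tr6))
})

test_that("NNI hill climbing recovers strong-signal topologies", {
  set.seed(81)
  mod <- subst_model(n_categories = 1L)
  tr <- random_tree(6, 0.2)
  sim <- toupper(as.character(
    phangorn::simSeq(tr, l = 2000, Q = mod$rates, bf = mod$base_freqs)))

  # starting at the truth: no move
  at_truth <- nni_hill_climb(sim, mod, tr)
  expect_equal(at_truth$n_moves, 0L)
  expect_equal(phangorn::RF.dist(at_truth$tree, tr), 0)

  # one NNI away: exactly one move back
  near <- nni_neighbors(tr)[[1]]
  back <- nni_hill_climb(sim, mod, near)
  expect_equal(phangorn::RF.dist(back$tree, tr), 0)
  expect_equal(back$n_moves, 1L)

  # from a remote start
  for (s in 1:3) {
    set.seed(100 + s)
    start <- random_tree(6, 0.1, taxa = tr$tip.label)
    got <- nni_hill_climb(sim, mod, start)
    expect_equal(phangorn::RF.dist(got$tree, tr), 0)
  }
})

test_that("bootstrap support is deterministic and strong under strong signal", {
  set.seed(91)
  mod <- subst_model(n_categories = 1L)
  tr <- random_tree(6, 0.25)
  sim <- toupper(as.character(
    phangorn::simSeq(tr, l = 1500, Q = mod$rates, bf = mod$base_freqs)))
  bs <- bootstrap_support(sim, mod, reps = 20L, rng_seed = 5L, reference = tr)
  expect_true(all(bs$support >= 95))
  bs2 <- bootstrap_support(sim, mod, reps = 20L, rng_seed = 5L, reference = tr)
  expect_identical(bs$support, bs2$support)

  same <- matrix("A", 4, 30, dimnames = list(paste0("t", 1:4), NULL))
  expect_warning(deg <- bootstrap_support(same, mod, reps = 2L, rng_seed = 1L,
                                          reference = random_tree(4)),
                 "no variable sites")
  expect_true(deg$degenerate)
  expect_error(bootstrap_support(sim, mod, reps = 0L), "reps")
})
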