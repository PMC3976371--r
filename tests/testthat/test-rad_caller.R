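test_that("within-individual clustering respects depth and similarity rules", {
  L <- 50L
  r <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  cfg <- caller_config()

  ten <- cluster_within_individual(rad_readset("i", rep(r, 10)), cfg)
  expect_length(ten, 1L)
  expect_equal(ten[[1]]$depth, 10L)

  five <- cluster_within_individual(rad_readset("i", rep(r, 5)), cfg)
  expect_length(five, 0L)

  # 4/50 mismatches = 92% identity joins at 0.88
  rv <- strsplit(r, "")[[1]]
  cyc <- c(A = "C", C = "G", G = "T", T = "A")  # always a mismatch
  rv[1:4] <- cyc[rv[1:4]]
  r2 <- paste(rv, collapse = "")
  both <- cluster_within_individual(rad_readset("i", c(rep(r, 8), rep(r2, 8))),
                                    cfg)
  expect_length(both, 1L)
  expect_equal(both[[1]]$depth, 16L)

  # reverse-complemented copies join the same stack and are re-oriented
  mix <- cluster_within_individual(
    rad_readset("i", c(rep(r, 6), rep(radpartition:::revcomp(r), 6))), cfg)
  expect_length(mix, 1L)
  expect_equal(mix[[1]]$depth, 12L)

  expect_length(cluster_within_individual(rad_readset("i", character(0)), cfg),
                0L)
})

test_that("retained reads are partitioned among stacks", {
  set.seed(21)
  L <- 40L
  centers <- replicate(3, paste(sample(c("A", "C", "G", "T"), L, TRUE),
                                collapse = ""))
  reads <- unlist(lapply(centers, function(cc) {
    sapply(1:8, function(i) {
      v <- strsplit(cc, "")[[1]]
      j <- sample(L, 2)                      # 2/40 = 95% identity
      v[j] <- sample(c("A", "C", "G", "T"), 2, TRUE)
      paste(v, collapse = "")
    })
  }))
  stacks <- cluster_within_individual(rad_readset("i", reads),
                                      caller_config(min_depth = 1L))
  expect_equal(sum(vapply(stacks, `[[`, integer(1), "depth")), length(reads))
})

test_that("error/heterozygosity estimation finds the boundary on clean data", {
  r <- paste(rep("ACGTG", 10), collapse = "")
  st <- rad_stack("i", rep(r, 20))
  est <- estimate_error_het(list(st))
  expect_lt(est$epsilon, 1e-4)
  expect_lt(est$het, 1e-4)
  expect_true(est$stable)
})

test_that("a balanced polymorphic column pushes heterozygosity above zero", {
  mono <- rad_stack("i", rep(paste(rep("A", 30), collapse = ""), 20))
  hetcol <- rad_stack("i", c(rep(paste0("A", paste(rep("C", 29), collapse = "")), 10),
                             rep(paste0("G", paste(rep("C", 29), collapse = "")), 10)))
  est <- estimate_error_het(list(mono, hetcol))
  expect_gt(est$het, 1e-4)
})

test_that("error and heterozygosity are recovered from simulated stacks", {
  eps <- 0.01; het <- 0.005
  truth <- replicate(100, paste(sample(c("A", "C", "G", "T"), 20, TRUE),
                                collapse = ""))
  stacks <- lapply(seq_along(truth), function(i) {
    rs <- simulate_reads(truth[i], 20, eps, het, rng_seed = 1000L + i)
    rad_stack("i", rs$reads)
  })
  est <- estimate_error_het(stacks)     # 2,000 columns total
  expect_lt(abs(est$epsilon - eps) / eps, 0.5)
  expect_lt(abs(est$het - het) / het, 0.5)
})

test_that("estimates tighten as column count grows", {
  eps <- 0.01; het <- 0.01
  rel_err <- function(n_loci, seed) {
    truth <- replicate(n_loci, paste(sample(c("A", "C", "G", "T"), 25, TRUE),
                                     collapse = ""))
    stacks <- lapply(seq_along(truth), function(i) {
      rad_stack("i", simulate_reads(truth[i], 15, eps, het,
                                    rng_seed = seed * 997L + i)$reads)
    })
    est <- estimate_error_het(stacks)
    c(abs(est$epsilon - eps) / eps, abs(est$het - het) / het)
  }
  set.seed(5)
  small <- sapply(1:8, function(s) rel_err(20, s))    # 500 columns
  large <- sapply(1:8, function(s) rel_err(200, s))   # 5,000 columns
  expect_lt(median(large[1, ]), median(small[1, ]) + 1e-9)
  expect_lt(median(large[2, ]), median(small[2, ]) + 1e-9)
})

test_that("binomial consensus calls follow the genotype posteriors", {
  est <- structure(list(epsilon = 0.001, het = 0.01, loglik = 0,
                        n_columns = 100L, stable = TRUE),
                   class = "error_het_estimate")
  cfg <- caller_config(min_depth = 2L)

  hom <- rad_stack("i", rep("A", 6))
  expect_equal(call_consensus(hom, est, cfg)$sequence, "A")

  both <- rad_stack("i", c(rep("A", 3), rep("G", 3)))
  cons <- call_consensus(both, est, cfg)
  expect_equal(cons$sequence, "R")
  expect_equal(cons$n_het_sites, 1L)

  thin <- rad_stack("i", c("A", "G"))
  expect_equal(call_consensus(thin, est, cfg)$sequence, "N")
})

test_that("a posterior threshold of 1 yields all-N calls at finite depth", {
  est <- structure(list(epsilon = 0.01, het = 0.01, loglik = 0,
                        n_columns = 100L, stable = TRUE),
                   class = "error_het_estimate")
  st <- rad_stack("i", rep("ACGTACGTAC", 30))
  cons <- call_consensus(st, est, caller_config(posterior_threshold = 1.0))
  expect_equal(cons$sequence, paste(rep("N", 10), collapse = ""))
})

test_that("error-free homozygous stacks reproduce the generating sequence", {
  set.seed(9)
  for (i in 1:5) {
    truth <- paste(sample(c("A", "C", "G", "T"), 50, TRUE), collapse = "")
    rs <- simulate_reads(truth, 15, 0, 0, rng_seed = 77L + i)
    st <- rad_stack("i", rs$reads)
    est <- estimate_error_het(list(st))
    expect_equal(call_consensus(st, est)$sequence, truth)
  }
})

test_that("paralog flags fire on excess heterozygosity and haplotypes", {
  est <- structure(list(epsilon = 0.001, het = 0.05, loglik = 0,
                        n_columns = 100L, stable = TRUE),
                   class = "error_het_estimate")
  # four het columns -> too_many_hets at the default cap of 3
  a <- paste(c(rep("A", 4), rep("T", 20)), collapse = "")
  b <- paste(c(rep("C", 4), rep("T", 20)), collapse = "")
  st <- rad_stack("i", c(rep(a, 10), rep(b, 10)))
  cons <- call_consensus(st, est, caller_config(min_depth = 2L))
  expect_gte(cons$n_het_sites, 4L)
  expect_true("too_many_hets" %in% cons$flags)

  # three read-phased combinations at two het sites -> too_many_haplotypes
  h1 <- paste(c("A", "A", rep("T", 20)), collapse = "")
  h2 <- paste(c("C", "C", rep("T", 20)), collapse = "")
  h3 <- paste(c("A", "C", rep("T", 20)), collapse = "")
  st3 <- rad_stack("i", c(rep(h1, 8), rep(h2, 8), rep(h3, 8)))
  cons3 <- call_consensus(st3, est, caller_config(min_depth = 2L))
  expect_gt(cons3$n_haplotypes, 2L)
  expect_true("too_many_haplotypes" %in% cons3$flags)
})

test_that("plurality consensus breaks ties alphabetically and handles N", {
  loc <- rad_locus("L1", c(a = "AAN", b = "AGN", c = "GGN"))
  # col1 {A,A,G} -> A; col2 {A,G,G} -> G; col3 all N -> N
  expect_equal(consensus_of_alignment(loc), "AGN")
  tie <- rad_locus("L2", c(a = "A", b = "G"))
  expect_equal(consensus_of_alignment(tie), "A")
})
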