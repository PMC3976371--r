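# Independent oracles: exhaustive-enumeration likelihood and parsimony,
# written from first principles (own rate matrix, own eigendecomposition, own
# gamma discretization) so they share no code path with the package.

BASES <- c("A", "C", "G", "T")

# GTR rate matrix: Q[i,j] = s_ij * pi_j, diagonal = -rowsum, scaled so the
# expected substitution rate  -sum(pi_i Q_ii) = 1.
oracle_gtr_Q <- function(bf, rates) {
  s <- matrix(0, 4, 4)
  s[1, 2] <- rates[1]; s[1, 3] <- rates[2]; s[1, 4] <- rates[3]
  s[2, 3] <- rates[4]; s[2, 4] <- rates[5]; s[3, 4] <- rates[6]
  s <- s + t(s)
  Q <- s * rep(bf, each = 4)
  diag(Q) <- -rowSums(Q)
  Q / sum(-bf * diag(Q))
}

# Transition probabilities exp(Q t) via the symmetrized eigendecomposition
# (valid for reversible Q).
oracle_pmatrix <- function(Q, bf, t) {
  D <- diag(sqrt(bf)); Di <- diag(1 / sqrt(bf))
  B <- D %*% Q %*% Di
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  P <- Di %*% e$vectors %*% diag(exp(e$values * t)) %*% t(e$vectors) %*% D
  pmax(P, 0)
}

# Mean-of-quantile discrete gamma category rates.
oracle_gamma_rates <- function(alpha, k) {
  if (k == 1L) return(1)
  q <- stats::qgamma((1:(k - 1)) / k, alpha, alpha)
  p <- stats::pgamma(q, alpha + 1, alpha)
  k * diff(c(0, p, 1))
}

oracle_char_set <- function(ch) {
  two <- list(M = c("A", "C"), R = c("A", "G"), W = c("A", "T"),
              S = c("C", "G"), Y = c("C", "T"), K = c("G", "T"))
  if (ch %in% BASES) return(ch)
  if (ch %in% names(two)) return(two[[ch]])
  BASES
}

# Exhaustive per-site log-likelihoods: sums over all 4^(n internal) state
# assignments, tips marginalized over their compatible states, averaged over
# gamma categories with equal weights.
oracle_site_loglik <- function(mat, tree, bf, rates, alpha = 1, k = 1L) {
  tree <- ape::unroot(tree)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  internals <- sort(unique(tree$edge[tree$edge[, 1L] >= root, 1L]))
  internals <- sort(unique(c(internals, tree$edge[tree$edge[, 2L] > ntip, 2L])))
  Q <- oracle_gtr_Q(bf, rates)
  gr <- oracle_gamma_rates(alpha, k)
  nint <- length(internals)
  stopifnot(nint <= 5L)  # enumeration guard
  assigns <- as.matrix(expand.grid(rep(list(1:4), nint)))
  out <- numeric(ncol(mat))
  for (s in seq_len(ncol(mat))) {
    tipsets <- lapply(seq_len(ntip),
                      function(i) match(oracle_char_set(mat[tree$tip.label[i], s]),
                                        BASES))
    lik_cat <- numeric(length(gr))
    for (g in seq_along(gr)) {
      P <- lapply(seq_len(nrow(tree$edge)),
                  function(e) oracle_pmatrix(Q, bf, gr[g] * tree$edge.length[e]))
      tot <- 0
      for (a in seq_len(nrow(assigns))) {
        state_of <- function(node) assigns[a, match(node, internals)]
        term <- bf[state_of(root)]
        for (e in seq_len(nrow(tree$edge))) {
          par <- tree$edge[e, 1L]; child <- tree$edge[e, 2L]
          ps <- state_of(par)
          term <- term * if (child <= ntip)
            sum(P[[e]][ps, tipsets[[child]]]) else P[[e]][ps, state_of(child)]
          if (term == 0) break
        }
        tot <- tot + term
      }
      lik_cat[g] <- tot
    }
    out[s] <- log(mean(lik_cat))
  }
  out
}

# Brute-force Fitch length of one site: minimum over all internal-node state
# assignments of the number of edges whose endpoint states differ; tips choose
# the best member of their compatible set independently.
oracle_fitch_site <- function(states, tree) {
  tree <- ape::unroot(tree)
  ntip <- length(tree$tip.label)
  internals <- sort(unique(tree$edge[, 1L][tree$edge[, 1L] > ntip]))
  internals <- sort(unique(c(internals, tree$edge[, 2L][tree$edge[, 2L] > ntip])))
  nint <- length(internals)
  assigns <- as.matrix(expand.grid(rep(list(1:4), nint)))
  tipsets <- lapply(seq_len(ntip),
                    function(i) match(oracle_char_set(states[[tree$tip.label[i]]]),
                                      BASES))
  best <- Inf
  for (a in seq_len(nrow(assigns))) {
    state_of <- function(node) assigns[a, match(node, internals)]
    cost <- 0
    for (e in seq_len(nrow(tree$edge))) {
      par <- tree$edge[e, 1L]; child <- tree$edge[e, 2L]
      ps <- state_of(par)
      cost <- cost + if (child <= ntip)
        min(as.integer(tipsets[[child]] != ps)) else
          as.integer(state_of(child) != ps)
      if (cost >= best) break
    }
    best <- min(best, cost)
  }
  best
}

oracle_fitch <- function(mat, tree) {
  sum(vapply(seq_len(ncol(mat)), function(s) {
    states <- as.list(mat[, s]); names(states) <- rownames(mat)
    if (all(unlist(states) %in% c("N", "-", "?"))) return(0L)
    as.integer(oracle_fitch_site(states, tree))
  }, integer(1)))
}

# Random GTR+GAMMA model for property tests.
random_model <- function() {
  bf <- as.numeric(stats::runif(4, 0.5, 2)); bf <- bf / sum(bf)
  rates <- c(stats::runif(5, 0.3, 3), 1)
  k <- sample(c(1L, 4L), 1L)
  subst_model(bf, rates, alpha = stats::runif(1, 0.3, 2), n_categories = k)
}
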