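#' GTR+GAMMA substitution model
#'
#' General time-reversible nucleotide model with discrete-gamma rate
#' heterogeneity (equal-weight categories, rates by the mean-of-quantile
#' discretization).
#'
#' @param base_freqs Equilibrium frequencies (A, C, G, T); must be positive
#'   and sum to 1.
#' @param rates Six GTR exchangeabilities in the order AC, AG, AT, CG, CT, GT;
#'   the last is the reference and is fixed to 1.
#' @param alpha Gamma shape; large values approach rate homogeneity.
#' @param n_categories Number of discrete rate categories (default 4; 1 turns
#'   the gamma off).
#' @return List of class `subst_model`.
#' @export
subst_model <- function(base_freqs = rep(0.25, 4),
                        rates = rep(1, 6), alpha = 1, n_categories = 4L) {
  stopifnot(length(base_freqs) == 4L, all(base_freqs > 0),
            abs(sum(base_freqs) - 1) < 1e-8,
            length(rates) == 6L, all(rates > 0), alpha > 0, n_categories >= 1L)
  rates <- rates / rates[6L]
  structure(list(base_freqs = unname(base_freqs), rates = unname(rates),
                 alpha = alpha, n_categories = as.integer(n_categories)),
            class = "subst_model")
}

#' @export
print.subst_model <- function(x, ...) {
  cat(sprintf("<subst_model> GTR+G: pi=(%s) rates=(%s) alpha=%.3g k=%d\n",
              paste(sprintf("%.3f", x$base_freqs), collapse = ","),
              paste(sprintf("%.3g", x$rates), collapse = ","),
              x$alpha, x$n_categories))
  invisible(x)
}

# Convert an alignment character matrix (taxa x sites, uppercase, IUPAC codes
# and N/-/? allowed) to phyDat, dropping columns that are missing in every
# taxon (they carry no likelihood and are excluded from analysis).
#' @keywords internal
matrix_to_phydat <- function(matrix, drop_all_missing = TRUE) {
  stopifnot(is.matrix(matrix), !is.null(rownames(matrix)))
  if (drop_all_missing && ncol(matrix) > 0L) {
    keep <- !apply(matrix, 2L, function(col) all(is_missing_char(col)))
    matrix <- matrix[, keep, drop = FALSE]
  }
  if (ncol(matrix) == 0L) return(NULL)
  phangorn::phyDat(matrix, type = "DNA")
}

# Shared pml construction: checks taxa, clamps zero/absent branch lengths to
# the lower bound so the optimizer has a valid starting point.
#' @keywords internal
make_pml <- function(matrix, tree, model, min_edge = 1e-8) {
  dat <- matrix_to_phydat(matrix)
  if (is.null(dat)) stop("alignment has no usable (non-all-missing) columns")
  if (!setequal(rownames(matrix), tree$tip.label))
    stop("alignment taxa and tree tips differ: ",
         paste(c(setdiff(rownames(matrix), tree$tip.label),
                 setdiff(tree$tip.label, rownames(matrix))), collapse = ", "))
  if (is.null(tree$edge.length))
    tree$edge.length <- rep(0.1, nrow(tree$edge))
  tree$edge.length <- pmax(tree$edge.length, min_edge)
  if (length(tree$tip.label) > 3L && ape::is.rooted(tree))
    tree <- ape::unroot(tree)
  k <- model$n_categories
  phangorn::pml(tree, dat, bf = model$base_freqs, Q = model$rates,
                k = k, shape = if (k > 1L) model$alpha else 1)
}

#' Per-site log-likelihoods under GTR+GAMMA
#'
#' Felsenstein pruning over the GTR rate matrix, averaged over the discrete
#' gamma categories. 'N', '-' and IUPAC ambiguity codes enter as partial
#' states (conditional likelihood 1 on every compatible base). Columns missing
#' in all taxa are excluded.
#'
#' @param matrix Character matrix (taxa x sites) with taxon rownames matching
#'   the tree's tips.
#' @param tree `phylo` with branch lengths (substitutions/site).
#' @param model A [subst_model()].
#' @return Numeric vector of per-site log-likelihoods (one per retained
#'   column); the total log-likelihood is its sum. Zero-length alignments give
#'   an empty vector.
#' @export
site_log_likelihoods <- function(matrix, tree, model = subst_model()) {
  if (ncol(matrix) == 0L) return(numeric(0))
  fit <- make_pml(matrix, tree, model)
  unname(fit$siteLik[attr(fit$data, "index")])
}

#' Optimize branch lengths on a fixed topology
#'
#' Maximizes the GTR+GAMMA likelihood over branch lengths only, keeping the
#' topology and model fixed. Branch lengths are constrained to
#' `[1e-8, 10]` substitutions/site.
#'
#' @inheritParams site_log_likelihoods
#' @param tol Convergence tolerance on the log-likelihood (default 1e-3).
#' @param max_rounds Optimization round cap; non-convergence returns the best
#'   tree found with `converged = FALSE` and a warning.
#' @return List: `tree` (optimized), `loglik`, `converged`.
#' @export
optimize_branch_lengths <- function(matrix, tree, model = subst_model(),
                                    tol = 1e-3, max_rounds = 20L) {
  if (length(tree$tip.label) == 2L) {
    # single free parameter: the path between the two tips
    obj <- function(d) {
      t2 <- tree
      t2$edge.length <- rep(d / nrow(tree$edge), nrow(tree$edge))
      sum(site_log_likelihoods(matrix, t2, model))
    }
    opt <- stats::optimize(obj, c(1e-8, 10), maximum = TRUE, tol = 1e-6)
    out <- tree
    out$edge.length <- rep(opt$maximum / nrow(tree$edge), nrow(tree$edge))
    return(list(tree = out, loglik = opt$objective, converged = TRUE))
  }
  fit <- make_pml(matrix, tree, model)
  # phangorn's epsilon is relative to |logLik|; convert the absolute tol
  eps <- tol / max(1, abs(fit$logLik))
  res <- tryCatch(
    phangorn::optim.pml(fit, optEdge = TRUE,
                        control = phangorn::pml.control(
                          epsilon = eps, maxit = max_rounds, trace = 0)),
    error = function(e) NULL)
  if (is.null(res)) {
    warning("branch-length optimization failed; returning the input tree")
    return(list(tree = fit$tree, loglik = fit$logLik, converged = FALSE))
  }
  out <- res$tree
  out$edge.length <- pmin(pmax(out$edge.length, 1e-8), 10)
  list(tree = out, loglik = res$logLik, converged = TRUE)
}

#' Estimate GTR+GAMMA model parameters
#'
#' Base frequencies are set to the empirical frequencies of the alignment
#' (bases absent from the data floored at 1e-4 and renormalized); the six GTR
#' exchangeabilities and the gamma shape are then optimized jointly with the
#' branch lengths by cyclic maximization.
#'
#' @inheritParams site_log_likelihoods
#' @return A [subst_model()] with an extra attribute `"loglik"`.
#' @export
estimate_model <- function(matrix, tree, n_categories = 4L) {
  counts <- table(factor(matrix[matrix %in% .bases], levels = .bases))
  bf <- pmax(as.numeric(counts), 1e-4)
  bf <- bf / sum(bf)
  fit <- make_pml(matrix, tree, subst_model(bf, n_categories = n_categories))
  res <- phangorn::optim.pml(fit, optEdge = TRUE, optQ = TRUE,
                             optGamma = n_categories > 1L,
                             control = phangorn::pml.control(trace = 0))
  out <- subst_model(bf, res$Q / res$Q[6L],
                     alpha = if (n_categories > 1L) res$shape else 1,
                     n_categories = n_categories)
  attr(out, "loglik") <- res$logLik
  attr(out, "tree") <- res$tree
  out
}

#' Fitch parsimony length of an alignment on a tree
#'
#' Sum over sites of the minimum number of state changes under Fitch
#' parsimony. IUPAC ambiguity codes are treated as the set of their bases;
#' sites missing in all taxa contribute zero.
#'
#' @inheritParams site_log_likelihoods
#' @return Integer total number of steps.
#' @export
fitch_steps <- function(matrix, tree) {
  dat <- matrix_to_phydat(matrix, drop_all_missing = FALSE)
  if (is.null(dat)) return(0L)
  as.integer(phangorn::fitch(ape::unroot(tree), dat))
}

#' Classify alignment characters
#'
#' Counts variable and parsimony-informative columns (IUPAC two-fold codes
#' expanded to their constituent bases, 'N'/'-' ignored), columns missing in
#' every taxon (excluded from analysis), and the overall missing-data
#' proportion (fraction of cells that are 'N' or '-').
#'
#' @param matrix Character matrix (taxa x sites).
#' @return List of class `character_census`: `n_sites`, `n_variable`,
#'   `n_parsimony_informative`, `n_all_missing_excluded`,
#'   `missing_proportion`.
#' @export
classify_characters <- function(matrix) {
  n_sites <- ncol(matrix)
  nv <- 0L; np <- 0L; nx <- 0L
  for (j in seq_len(n_sites)) {
    col <- matrix[, j]
    if (all(is_missing_char(col))) { nx <- nx + 1L; next }
    tab <- column_base_table(col)
    if (length(tab) >= 2L) {
      nv <- nv + 1L
      if (sum(tab >= 2L) >= 2L) np <- np + 1L
    }
  }
  structure(list(n_sites = n_sites, n_variable = nv,
                 n_parsimony_informative = np,
                 n_all_missing_excluded = nx,
                 missing_proportion = if (length(matrix))
                   mean(is_missing_char(matrix)) else 0),
            class = "character_census")
}

#' @export
print.character_census <- function(x, ...) {
  cat(sprintf("<character_census> %d sites: %d variable, %d PI, %d all-missing, %.1f%% missing cells\n",
              x$n_sites, x$n_variable, x$n_parsimony_informative,
              x$n_all_missing_excluded, 100 * x$missing_proportion))
  invisible(x)
}

# Minimum conceivable steps for one column: distinct fully resolved
# (unambiguous, non-missing) states minus one. Ambiguous cells are skipped so
# the minimum never exceeds the set-based Fitch length.
#' @keywords internal
min_steps_column <- function(col) {
  res <- col[col %in% .bases]
  max(0L, length(unique(res)) - 1L)
}

#' Consistency index of an alignment on a tree
#'
#' CI = (sum over sites of the minimum conceivable number of changes, i.e.
#' distinct resolved states minus one) divided by the Fitch parsimony length.
#' 1 means no homoplasy. When the alignment requires zero steps the CI is
#' reported as 1 with a message.
#'
#' @inheritParams site_log_likelihoods
#' @return Numeric in (0, 1].
#' @export
consistency_index <- function(matrix, tree) {
  steps <- fitch_steps(matrix, tree)
  if (steps == 0L) {
    message("zero parsimony steps: CI reported as 1")
    return(1)
  }
  minsum <- sum(vapply(seq_len(ncol(matrix)),
                       function(j) min_steps_column(matrix[, j]), integer(1)))
  minsum / steps
}

#' Maximum-likelihood tree search by NNI hill climbing
#'
#' From `start`, repeatedly evaluates all unique 1-step NNI neighbors with
#' branch lengths re-optimized, moves to the best strictly improving neighbor,
#' and stops at a local optimum. Deterministic given its inputs.
#'
#' @inheritParams site_log_likelihoods
#' @param start Starting `phylo` (binary; rooted input is unrooted).
#' @param tol Minimum log-likelihood gain to accept a move (default 1e-4).
#' @param max_moves Cap on accepted moves (default 50).
#' @return List: `tree` (branch-length-optimized local optimum), `loglik`,
#'   `n_moves`.
#' @export
nni_hill_climb <- function(matrix, model = subst_model(), start,
                           tol = 1e-4, max_moves = 50L) {
  cur <- optimize_branch_lengths(matrix, ape::unroot(start), model)
  moves <- 0L
  repeat {
    if (moves >= max_moves) break
    nb <- nni_neighbors(cur$tree)
    cand <- lapply(nb, function(t) optimize_branch_lengths(matrix, t, model))
    lls <- vapply(cand, `[[`, numeric(1), "loglik")
    best <- which.max(lls)
    if (lls[best] <= cur$loglik + tol) break
    cur <- cand[[best]]
    moves <- moves + 1L
  }
  list(tree = cur$tree, loglik = cur$loglik, n_moves = moves)
}

# Neighbor-joining starting tree from pairwise Hamming distances; falls back
# to a topology-less caterpillar when distances are degenerate (e.g. identical
# sequences).
#' @keywords internal
distance_start_tree <- function(matrix) {
  dat <- matrix_to_phydat(matrix)
  tr <- tryCatch({
    d <- phangorn::dist.hamming(dat)
    if (any(!is.finite(d))) stop("non-finite distances")
    ape::nj(d)
  }, error = function(e) NULL)
  if (is.null(tr) || !ape::is.binary(ape::unroot(tr)))
    tr <- ape::unroot(ape::stree(nrow(matrix), type = "left",
                                 tip.label = rownames(matrix)))
  tr <- ape::unroot(tr)
  tr$edge.length <- rep(0.05, nrow(tr$edge))
  tr
}

# Non-trivial bipartitions of a tree as canonical side strings.
#' @keywords internal
tree_bipartitions <- function(tree) {
  labs <- tree$tip.label
  n <- length(labs)
  ref <- min(labs)
  out <- character(0)
  for (cl in ape::prop.part(ape::unroot(tree))) {
    s <- labs[cl]
    if (length(s) <= 1L || length(s) >= n - 1L) next
    if (ref %in% s) s <- setdiff(labs, s)
    out <- c(out, paste(sort(s), collapse = ","))
  }
  unique(out)
}

#' Nonparametric bootstrap support
#'
#' Resamples alignment columns with replacement; each replicate is analyzed by
#' [nni_hill_climb()] from a distance-based starting tree, and support for
#' every internal bipartition of the reference tree is the percentage of
#' replicate trees containing it. "Mean bootstrap" is the unweighted mean over
#' the reference tree's internal bipartitions.
#'
#' @inheritParams site_log_likelihoods
#' @param reps Number of bootstrap replicates (>= 1; 200 in full-scale runs,
#'   smaller values are adequate for quick checks).
#' @param rng_seed Integer seed; identical seeds give identical supports.
#' @param reference Reference `phylo`; default is the ML tree found by
#'   [nni_hill_climb()] on the full matrix.
#' @return List of class `rad_bootstrap`: `support` (named percentage vector,
#'   one entry per internal bipartition of the reference), `mean_bootstrap`,
#'   `reference`, `degenerate` (TRUE when the matrix has no variable sites,
#'   in which case supports are 0 and flagged).
#' @export
bootstrap_support <- function(matrix, model = subst_model(), reps = 100L,
                              rng_seed = 1L, reference = NULL) {
  if (reps < 1L) stop("reps must be >= 1")
  if (is.null(reference))
    reference <- nni_hill_climb(matrix, model, distance_start_tree(matrix))$tree
  ref_bip <- tree_bipartitions(reference)
  census <- classify_characters(matrix)
  if (census$n_variable == 0L) {
    warning("no variable sites: bootstrap supports are undefined, reported 0")
    support <- stats::setNames(rep(0, length(ref_bip)), ref_bip)
    return(structure(list(support = support, mean_bootstrap = 0,
                          reference = reference, degenerate = TRUE),
                     class = "rad_bootstrap"))
  }
  hits <- stats::setNames(numeric(length(ref_bip)), ref_bip)
  boot_cols <- with_seed(rng_seed, {
    lapply(seq_len(reps),
           function(i) sample.int(ncol(matrix), ncol(matrix), replace = TRUE))
  })
  for (i in seq_len(reps)) {
    bm <- matrix[, boot_cols[[i]], drop = FALSE]
    fit <- nni_hill_climb(bm, model, distance_start_tree(bm))
    bip <- tree_bipartitions(fit$tree)
    hits[ref_bip %in% bip] <- hits[ref_bip %in% bip] + 1
  }
  support <- 100 * hits / reps
  structure(list(support = support, mean_bootstrap = mean(support),
                 reference = reference, degenerate = FALSE),
            class = "rad_bootstrap")
}

#' @export
print.rad_bootstrap <- function(x, ...) {
  cat(sprintf("<rad_bootstrap> %d internal bipartitions, mean support %.1f%%%s\n",
              length(x$support), x$mean_bootstrap,
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}
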