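#' Configuration for the partitioned RAD analysis
#'
#' @param ll_window Log-likelihood window: a locus favors trees within
#'   `ll_window` of its best tree and disfavors trees within `ll_window` of
#'   its worst (default 2.0; ties at the boundary included).
#' @param min_trees Minimum unique pruned trees a locus must retain (default
#'   20).
#' @param min_ll_range Minimum spread (max - min) of a locus's per-tree
#'   log-likelihoods; flatter loci are uninformative about tree choice and are
#'   excluded (default 4.0). Keeping `min_ll_range > 2 * ll_window` ensures no
#'   tree is simultaneously favored and disfavored by one locus.
#' @param min_individuals Minimum individuals per locus (default 4).
#' @param require_pi Drop loci without parsimony-informative characters
#'   (default TRUE).
#' @param pi_level Prediction-interval level for outlier flagging (default
#'   0.95).
#' @return List of class `partition_config`.
#' @export
partition_config <- function(ll_window = 2.0, min_trees = 20L,
                             min_ll_range = 4.0, min_individuals = 4L,
                             require_pi = TRUE, pi_level = 0.95) {
  stopifnot(ll_window > 0, min_ll_range >= 0, pi_level > 0, pi_level < 1)
  structure(list(ll_window = ll_window, min_trees = as.integer(min_trees),
                 min_ll_range = min_ll_range,
                 min_individuals = as.integer(min_individuals),
                 require_pi = isTRUE(require_pi), pi_level = pi_level),
            class = "partition_config")
}

#' Filter loci for the partitioned analysis and prune the pool per locus
#'
#' Drops loci with fewer than `min_individuals` individuals, loci without
#' parsimony-informative characters (when `require_pi`), loci whose
#' individuals overlap the pool's taxa in fewer than 4 tips, and loci whose
#' unique pruned-tree count falls below `min_trees`.
#'
#' @param loci List of [rad_locus()].
#' @param pool A [build_tree_pool()] result.
#' @param cfg A [partition_config()].
#' @return List: `loci` (included), `pruned` (matching list of
#'   [prune_and_dedup()] results), `dropped` (data.frame locus_id / reason).
#' @export
filter_partition_loci <- function(loci, pool, cfg = partition_config()) {
  taxa <- pool$trees[[1]]$tip.label
  inc <- list(); pruned <- list()
  drop_id <- character(0); drop_reason <- character(0)
  for (l in loci) {
    reason <- NULL
    if (locus_n_individuals(l) < cfg$min_individuals) {
      reason <- "min_individuals"
    } else if (cfg$require_pi && locus_site_counts(l)$n_pi == 0L) {
      reason <- "no_PI"
    } else {
      keep <- intersect(locus_individuals(l), taxa)
      if (length(keep) < 4L) {
        reason <- "too_few_pool_taxa"
      } else {
        pr <- prune_and_dedup(pool, keep)
        if (length(pr$trees) < cfg$min_trees) reason <- "min_trees"
        else {
          inc[[length(inc) + 1L]] <- l
          pruned[[length(pruned) + 1L]] <- pr
        }
      }
    }
    if (!is.null(reason)) {
      drop_id <- c(drop_id, l$locus_id)
      drop_reason <- c(drop_reason, reason)
    }
  }
  list(loci = inc, pruned = pruned,
       dropped = data.frame(locus_id = drop_id, reason = drop_reason,
                            stringsAsFactors = FALSE))
}

#' Per-locus log-likelihoods over a pruned tree set
#'
#' Evaluates the locus alignment on every unique pruned tree, optionally
#' re-optimizing branch lengths per tree (the default; disable to reuse the
#' inherited lengths). Trees whose evaluation fails get `-Inf` and are ignored
#' by the window logic. Loci whose log-likelihood range (max - min over
#' finite values) falls below `min_ll_range` are flagged excluded.
#'
#' @param locus A [rad_locus()].
#' @param pruned A [prune_and_dedup()] result for this locus's taxa.
#' @param model A [subst_model()].
#' @param min_ll_range Exclusion threshold on the spread (default 4.0).
#' @param optimize Re-optimize branch lengths per tree (default TRUE).
#' @return List of class `locus_tree_table`: `locus_id`, `loglik` (one per
#'   unique pruned tree), `index_map`, `ll_range`, `excluded`.
#' @export
locus_tree_table <- function(locus, pruned, model = subst_model(),
                             min_ll_range = 4.0, optimize = TRUE) {
  sub <- locus$seqs[intersect(rownames(locus$seqs),
                              pruned$trees[[1]]$tip.label), , drop = FALSE]
  dat <- matrix_to_phydat(sub)                 # built once, shared by trees
  lls <- vapply(pruned$trees, function(tr) {
    tryCatch({
      if (optimize) optimize_branch_lengths(sub, tr, model)$loglik
      else {
        tr$edge.length <- pmax(tr$edge.length %||% rep(0.1, nrow(tr$edge)),
                               1e-8)
        phangorn::pml(tr, dat, bf = model$base_freqs, Q = model$rates,
                      k = model$n_categories,
                      shape = if (model$n_categories > 1L) model$alpha
                              else 1)$logLik
      }
    }, error = function(e) -Inf)
  }, numeric(1))
  fin <- lls[is.finite(lls)]
  rng <- if (length(fin) >= 2L) max(fin) - min(fin) else 0
  structure(list(locus_id = locus$locus_id, loglik = lls,
                 index_map = pruned$index_map, ll_range = rng,
                 excluded = rng < min_ll_range),
            class = "locus_tree_table")
}

#' Count loci favoring and disfavoring each pool tree
#'
#' Per locus, trees within `ll_window` log-likelihood points of the locus's
#' best tree are favored and trees within `ll_window` of its worst tree are
#' disfavored (boundaries inclusive); every pool tree inherits the status of
#' its pruned representative through the locus's index map. Tables flagged
#' excluded contribute nothing.
#'
#' @param tables List of [locus_tree_table()] results.
#' @param pool The [build_tree_pool()] the tables were computed against.
#' @param cfg A [partition_config()].
#' @param total_ll Optional numeric vector of total-data log-likelihoods per
#'   pool tree (see [pool_total_loglik()]), carried into the output.
#' @return data.frame of class `rad_favor_table`: `tree_index`, `origin`,
#'   `total_ll`, `n_favoring`, `n_disfavoring`; attribute `n_loci` = number of
#'   contributing loci.
#' @export
favor_disfavor <- function(tables, pool, cfg = partition_config(),
                           total_ll = NULL) {
  np <- length(pool$trees)
  fav <- integer(np); dis <- integer(np)
  used <- 0L
  for (tb in tables) {
    if (isTRUE(tb$excluded)) next
    fin <- is.finite(tb$loglik)
    if (!any(fin)) next
    used <- used + 1L
    hi <- max(tb$loglik[fin]); lo <- min(tb$loglik[fin])
    f_rep <- fin & tb$loglik >= hi - cfg$ll_window
    d_rep <- fin & tb$loglik <= lo + cfg$ll_window
    fav <- fav + as.integer(f_rep[tb$index_map])
    dis <- dis + as.integer(d_rep[tb$index_map])
  }
  out <- data.frame(tree_index = seq_len(np), origin = pool$origin,
                    total_ll = if (is.null(total_ll)) NA_real_ else total_ll,
                    n_favoring = fav, n_disfavoring = dis,
                    stringsAsFactors = FALSE)
  attr(out, "n_loci") <- used
  class(out) <- c("rad_favor_table", "data.frame")
  out
}

#' Total-data log-likelihood of every pool tree
#'
#' Evaluates each pool tree against the concatenated supermatrix, with branch
#' lengths re-optimized per tree by default.
#'
#' @param matrix Character supermatrix (taxa x sites) covering the pool's
#'   taxa.
#' @param pool A [build_tree_pool()] result.
#' @param model A [subst_model()].
#' @param optimize Re-optimize branch lengths per tree (default TRUE).
#' @return Numeric vector, one log-likelihood per pool tree.
#' @export
pool_total_loglik <- function(matrix, pool, model = subst_model(),
                              optimize = TRUE) {
  vapply(pool$trees, function(tr) {
    if (optimize) optimize_branch_lengths(matrix, tr, model)$loglik
    else sum(site_log_likelihoods(matrix, tr, model))
  }, numeric(1))
}

#' Remove poorly supported likelihood islands
#'
#' Drops pool trees whose total-data log-likelihood falls below a user-chosen
#' cut before the support regression, so the regression is fit within a single
#' likelihood distribution. The cut is chosen by inspection of the
#' likelihood profile, not auto-detected.
#'
#' @param favor A [favor_disfavor()] table with `total_ll` filled in.
#' @param ll_cut Keep trees with `total_ll > ll_cut`.
#' @return The filtered favor table.
#' @export
trim_likelihood_islands <- function(favor, ll_cut) {
  if (all(is.na(favor$total_ll))) stop("favor table has no total_ll")
  out <- favor[!is.na(favor$total_ll) & favor$total_ll > ll_cut, ,
               drop = FALSE]
  if (nrow(out) == 0L)
    stop("ll_cut ", ll_cut, " removes every tree")
  attr(out, "n_loci") <- attr(favor, "n_loci")
  class(out) <- class(favor)
  out
}

#' Regress per-tree locus support on tree likelihood
#'
#' When the candidate trees draw from a single likelihood distribution, the
#' number of loci favoring a tree is expected to be linear in the tree's total
#' log-likelihood. Each tree is treated as an independent data point in an
#' ordinary least-squares fit, and a prediction interval at `level` flags
#' outlier trees with more favoring loci than their likelihood predicts
#' (only the upper side is flagged; the lower bound is reported).
#'
#' @param favor A [favor_disfavor()] table with `total_ll` filled (optionally
#'   trimmed by [trim_likelihood_islands()]).
#' @param level Prediction-interval level (default 0.95).
#' @return List of class `rad_support_regression`: `slope`, `intercept`,
#'   `sigma` (residual SD), `level`, `table` (per tree: predicted, lower,
#'   upper, outlier), `lm` (the underlying fit).
#' @export
support_regression <- function(favor, level = 0.95) {
  if (nrow(favor) < 3L) stop("need at least 3 trees for the regression")
  if (any(is.na(favor$total_ll))) stop("favor table has no total_ll")
  if (stats::var(favor$total_ll) == 0)
    stop("zero variance in tree log-likelihoods: degenerate regressor")
  fit <- stats::lm(n_favoring ~ total_ll, data = favor)
  # intervals evaluated at the fitted trees themselves (suppresses the
  # "future responses" note, which is exactly the intended use)
  pred <- suppressWarnings(
    stats::predict(fit, interval = "prediction", level = level))
  tab <- data.frame(tree_index = favor$tree_index, origin = favor$origin,
                    total_ll = favor$total_ll,
                    n_favoring = favor$n_favoring,
                    n_disfavoring = favor$n_disfavoring,
                    predicted = pred[, "fit"], lower = pred[, "lwr"],
                    upper = pred[, "upr"],
                    outlier = favor$n_favoring > pred[, "upr"],
                    stringsAsFactors = FALSE)
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 sigma = summary(fit)$sigma, level = level,
                 table = tab, lm = fit),
            class = "rad_support_regression")
}

#' @export
print.rad_support_regression <- function(x, ...) {
  cat(sprintf("<rad_support_regression> n_favoring = %.4g + %.4g * LL (sigma %.3g)\n",
              x$intercept, x$slope, x$sigma))
  out <- x$table$tree_index[x$table$outlier]
  cat(if (length(out))
        paste0("  trees above the ", 100 * x$level, "% prediction interval: ",
               paste(out, collapse = ", "), "\n")
      else paste0("  no trees above the ", 100 * x$level,
                  "% prediction interval\n"))
  invisible(x)
}

#' Partitioned RAD analysis
#'
#' The full analysis: build (or accept) the pool of NNI-permuted candidate
#' trees around the optimal tree, filter loci and prune the pool per locus,
#' tabulate per-locus tree log-likelihoods, count favoring/disfavoring loci
#' per tree within the log-likelihood window, evaluate each pool tree's
#' total-data likelihood on the concatenated supermatrix, optionally trim
#' poorly supported likelihood islands, and regress favoring counts on total
#' likelihood with a prediction interval to flag topologies supported by more
#' loci than expected.
#'
#' @param loci List of [rad_locus()].
#' @param optimal Optimal `phylo` tree (ignored when `pool` is supplied).
#' @param model A [subst_model()] shared by all loci.
#' @param config A [partition_config()].
#' @param n_permuted,rng_seed Passed to [build_tree_pool()] when `pool` is
#'   NULL.
#' @param pool Optional prebuilt [build_tree_pool()] result.
#' @param ll_cut Optional likelihood-island cut passed to
#'   [trim_likelihood_islands()].
#' @param optimize Re-optimize branch lengths per tree in the per-locus
#'   tables (default TRUE; turning it off is much faster and reuses the pool
#'   trees' branch lengths as-is).
#' @param optimize_total Re-optimize branch lengths per tree for the
#'   total-data likelihoods on the supermatrix (default TRUE; this is the
#'   regression's x-axis, where optimization matters most).
#' @return Object of class `rad_partition`: `pool`, `config`, `favor`
#'   (favor/disfavor table with total LLs), `regression`
#'   ([support_regression()] result), `tables`, `dropped`, `n_loci_used`.
#' @seealso [plot.rad_partition()], [summary.rad_partition()]
#' @export
rad_partition <- function(loci, optimal = NULL, model = subst_model(),
                          config = partition_config(), n_permuted = 200L,
                          rng_seed = 1L, pool = NULL, ll_cut = NULL,
                          optimize = TRUE, optimize_total = TRUE) {
  if (is.null(pool)) {
    if (is.null(optimal)) stop("supply either `optimal` or a prebuilt `pool`")
    pool <- build_tree_pool(optimal, n_permuted, rng_seed)
  }
  flt <- filter_partition_loci(loci, pool, config)
  if (length(flt$loci) == 0L)
    stop("no loci pass the partition filters")
  tables <- mapply(locus_tree_table, flt$loci, flt$pruned,
                   MoreArgs = list(model = model,
                                   min_ll_range = config$min_ll_range,
                                   optimize = optimize),
                   SIMPLIFY = FALSE)
  taxa <- pool$trees[[1]]$tip.label
  sm <- concatenate_loci(loci, union(taxa, unlist(lapply(loci,
                                                         locus_individuals))))
  total_ll <- pool_total_loglik(sm$matrix[taxa, , drop = FALSE], pool, model,
                                optimize = optimize_total)
  favor <- favor_disfavor(tables, pool, config, total_ll = total_ll)
  trimmed <- if (is.null(ll_cut)) favor
             else trim_likelihood_islands(favor, ll_cut)
  reg <- support_regression(trimmed, level = config$pi_level)
  structure(list(pool = pool, config = config, favor = favor,
                 regression = reg, tables = tables, dropped = flt$dropped,
                 n_loci_used = attr(favor, "n_loci"), ll_cut = ll_cut),
            class = "rad_partition")
}

#' @export
print.rad_partition <- function(x, ...) {
  best <- x$favor$tree_index[which.max(x$favor$n_favoring)]
  cat(sprintf("<rad_partition> %d pool trees, %d loci used (%d dropped)\n",
              nrow(x$favor), x$n_loci_used, nrow(x$dropped)))
  cat(sprintf("  most-favored tree: #%d (%s, %d loci); optimal tree: %d loci\n",
              best, x$favor$origin[best], max(x$favor$n_favoring),
              x$favor$n_favoring[1L]))
  print(x$regression)
  invisible(x)
}

#' Summarize a partitioned RAD analysis
#'
#' @param object A `rad_partition`.
#' @param ... Unused.
#' @return List: the regression table, the dropped-locus tally, counts of
#'   outlier trees, and whether the optimal tree holds the top favoring count.
#' @export
summary.rad_partition <- function(object, ...) {
  tab <- object$regression$table
  out <- list(regression_table = tab,
              dropped = table(object$dropped$reason),
              n_outliers = sum(tab$outlier),
              outlier_trees = tab$tree_index[tab$outlier],
              optimal_is_top =
                object$favor$n_favoring[1L] == max(object$favor$n_favoring),
              n_loci_used = object$n_loci_used)
  class(out) <- "summary.rad_partition"
  out
}

#' @export
print.summary.rad_partition <- function(x, ...) {
  cat("Partitioned RAD analysis of", x$n_loci_used, "loci\n")
  cat("  optimal tree holds the top favoring count:",
      if (x$optimal_is_top) "yes" else "NO", "\n")
  cat("  trees above the prediction interval:",
      if (x$n_outliers) paste(x$outlier_trees, collapse = ", ") else "none",
      "\n")
  if (nrow(x$regression_table) <= 20L) print(x$regression_table)
  invisible(x)
}

#' Coefficients of the support regression
#'
#' @param object A `rad_partition`.
#' @param ... Unused.
#' @return Named vector `(intercept, slope)`.
#' @export
coef.rad_partition <- function(object, ...) {
  c(intercept = object$regression$intercept, slope = object$regression$slope)
}

#' Plot a partitioned RAD analysis
#'
#' Scatter of per-tree favoring (or disfavoring) locus counts against
#' total-data log-likelihood, with the fitted regression line and prediction
#' interval; the optimal tree is the filled red point, flagged outliers are
#' circled.
#'
#' @param x A `rad_partition`.
#' @param which `"favor"` (with regression and interval) or `"disfavor"`.
#' @param ... Passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.rad_partition <- function(x, which = c("favor", "disfavor"), ...) {
  which <- match.arg(which)
  f <- x$favor
  if (which == "disfavor") {
    plot(f$total_ll, f$n_disfavoring, pch = 3,
         xlab = "tree log-likelihood", ylab = "loci disfavoring tree", ...)
    points(f$total_ll[1L], f$n_disfavoring[1L], pch = 19, col = "red")
    return(invisible(x))
  }
  tab <- x$regression$table
  plot(f$total_ll, f$n_favoring, pch = 3,
       xlab = "tree log-likelihood", ylab = "loci favoring tree", ...)
  o <- order(tab$total_ll)
  lines(tab$total_ll[o], tab$predicted[o])
  lines(tab$total_ll[o], tab$lower[o], lty = 2)
  lines(tab$total_ll[o], tab$upper[o], lty = 2)
  points(f$total_ll[1L], f$n_favoring[1L], pch = 19, col = "red")
  if (any(tab$outlier))
    points(tab$total_ll[tab$outlier], tab$n_favoring[tab$outlier],
           pch = 1, cex = 2, col = "blue")
  invisible(x)
}
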