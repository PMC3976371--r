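#' Configuration for the matched-subsampling comparison
#'
#' @param n_replicates Number of random null subsamples (default 100).
#' @param length_window Inclusive aligned-length window (bp) from which both
#'   the observed and the null loci are drawn (default c(50, 55)).
#' @param evalue_cutoff E-value below which a hit marks a locus as
#'   EST-associated (default 1e-15).
#' @param rng_seed Integer seed; subsamples are deterministic per
#'   (seed, replicate index).
#' @return List of class `subsample_config`.
#' @export
subsample_config <- function(n_replicates = 100L, length_window = c(50L, 55L),
                             evalue_cutoff = 1e-15, rng_seed = 1L) {
  stopifnot(n_replicates >= 1L, length(length_window) == 2L,
            length_window[1L] <= length_window[2L], evalue_cutoff > 0)
  structure(list(n_replicates = as.integer(n_replicates),
                 length_window = as.integer(length_window),
                 evalue_cutoff = evalue_cutoff,
                 rng_seed = as.integer(rng_seed)),
            class = "subsample_config")
}

#' Partition loci by expressed-sequence homology
#'
#' EST-associated loci have at least one hit with `evalue < cutoff`; the
#' non-EST set is loci with no hit at any E-value. Loci whose only hits sit
#' above the cutoff belong to neither set and are reported separately.
#'
#' @param loci List of [rad_locus()].
#' @param hits A [parse_hit_table()] result (parsed at `max_evalue = Inf` so
#'   weak hits are still visible to the "no hit at any level" rule).
#' @param cutoff E-value threshold (default 1e-15).
#' @return List: `est`, `non_est`, `ambiguous` (each a list of loci).
#' @export
partition_by_est <- function(loci, hits, cutoff = 1e-15) {
  ids <- vapply(loci, function(l) l$locus_id, character(1))
  unknown <- setdiff(unique(hits$locus_id), ids)
  if (length(unknown))
    warning("hit table references unknown loci (ignored): ",
            paste(utils::head(unknown, 5L), collapse = ", "),
            if (length(unknown) > 5L) ", ...")
  strong <- unique(hits$locus_id[hits$evalue < cutoff])
  any_hit <- unique(hits$locus_id)
  list(est = loci[ids %in% strong],
       non_est = loci[!(ids %in% any_hit)],
       ambiguous = loci[(ids %in% any_hit) & !(ids %in% strong)])
}

#' Draw one matched null subsample of loci
#'
#' Samples exactly `n` loci uniformly without replacement from the loci whose
#' aligned length falls inside the configured window. Deterministic per
#' (seed, replicate index); different indices give different samples.
#'
#' @param loci Candidate loci (typically the non-EST set).
#' @param n Sample size (the size of the observed EST set).
#' @param cfg A [subsample_config()].
#' @param replicate_index Which replicate this is (1-based).
#' @return List of `n` loci.
#' @export
matched_subsample <- function(loci, n, cfg = subsample_config(),
                              replicate_index = 1L) {
  lens <- vapply(loci, locus_length, integer(1))
  eligible <- which(lens >= cfg$length_window[1L] &
                    lens <= cfg$length_window[2L])
  if (length(eligible) < n)
    stop("only ", length(eligible), " loci inside the length window ",
         "but ", n, " requested (short by ", n - length(eligible), ")")
  pick <- with_seed(cfg$rng_seed * 10007L + replicate_index,
                    sample(eligible, n))
  loci[pick]
}

#' Phylogenetic-informativeness statistics for a set of loci
#'
#' Concatenates the loci, infers a maximum-likelihood tree (distance start,
#' optional NNI hill climb, branch lengths optimized), and computes the
#' statistic bundle: parsimony steps, variable and parsimony-informative
#' character counts, consistency index, aligned length, missing-data
#' proportion, proportion of branch length in the tips, and mean bootstrap.
#'
#' @param loci List of [rad_locus()].
#' @param taxa Taxon set for the supermatrix (default: union over loci).
#' @param model A [subst_model()].
#' @param search `"nni"` for hill climbing or `"start"` to keep the
#'   distance-based topology (branch lengths still optimized).
#' @param bootstrap_reps Bootstrap replicates for mean bootstrap; 0 skips the
#'   bootstrap and reports `NA` (default 0, since the bootstrap dominates run
#'   time).
#' @param rng_seed Seed for the bootstrap resampling.
#' @return List of class `stat_block`: `steps`, `n_variable`, `n_pi`, `ci`,
#'   `aligned_length`, `missing_proportion`, `tip_proportion`,
#'   `mean_bootstrap`, plus the inferred `tree`.
#' @export
informativeness_stats <- function(loci, taxa = NULL, model = subst_model(),
                                  search = c("nni", "start"),
                                  bootstrap_reps = 0L, rng_seed = 1L) {
  search <- match.arg(search)
  stopifnot(length(loci) > 0L)
  if (is.null(taxa))
    taxa <- sort(unique(unlist(lapply(loci, locus_individuals))))
  sm <- concatenate_loci(loci, taxa)
  m <- sm$matrix
  census <- classify_characters(m)
  start <- distance_start_tree(m)
  fit <- if (search == "nni") nni_hill_climb(m, model, start)
         else optimize_branch_lengths(m, start, model)
  steps <- fitch_steps(m, fit$tree)
  ci <- if (steps == 0L) 1 else suppressMessages(consistency_index(m, fit$tree))
  mb <- NA_real_
  if (bootstrap_reps > 0L)
    mb <- bootstrap_support(m, model, reps = bootstrap_reps,
                            rng_seed = rng_seed,
                            reference = fit$tree)$mean_bootstrap
  structure(list(steps = steps,
                 n_variable = census$n_variable,
                 n_pi = census$n_parsimony_informative,
                 ci = ci,
                 aligned_length = ncol(m),
                 missing_proportion = census$missing_proportion,
                 tip_proportion = tip_branch_proportion(fit$tree),
                 mean_bootstrap = mb,
                 tree = fit$tree),
            class = "stat_block")
}

#' @export
print.stat_block <- function(x, ...) {
  cat(sprintf("<stat_block> %d bp: steps %d, variable %d, PI %d, CI %.3f, missing %.3f, tips %.3f, mean bootstrap %s\n",
              x$aligned_length, x$steps, x$n_variable, x$n_pi, x$ci,
              x$missing_proportion, x$tip_proportion,
              if (is.na(x$mean_bootstrap)) "NA"
              else sprintf("%.1f", x$mean_bootstrap)))
  invisible(x)
}

# Statistics compared between the observed and null blocks.
.stat_names <- c("steps", "n_variable", "n_pi", "ci", "aligned_length",
                 "missing_proportion", "tip_proportion", "mean_bootstrap")

#' Two-tailed resampling p-values against a null distribution of statistics
#'
#' For each statistic, counts the null values strictly more extreme than the
#' observed value in the direction away from the null mean and doubles the
#' tail fraction: `p = min(1, 2k/R)`. When no null value is more extreme the
#' result is reported as a bound at the test's resolution (`< 2/R`;
#' one-sided resolution `1/R` available via `tails = 1`).
#'
#' @param observed A `stat_block` (or named numeric vector).
#' @param null_blocks List of `stat_block`s (or a matrix with statistics in
#'   columns), at least 2.
#' @param tails 2 (default) doubles the tail count; 1 gives the one-sided
#'   test.
#' @return data.frame of class `rad_resampling_test`: `statistic`, `observed`,
#'   `null_mean`, `null_sd`, `k`, `p` (numeric, bounded below by `tails/R`
#'   when `k = 0`), `p_label` (prints `"<2/R"` style bounds).
#' @export
resampling_pvalues <- function(observed, null_blocks, tails = 2L) {
  as_vec <- function(b) {
    v <- unlist(b[intersect(.stat_names, names(b))])
    v[.stat_names[.stat_names %in% names(v)]]
  }
  obs <- as_vec(observed)
  nulls <- if (is.matrix(null_blocks)) null_blocks
           else do.call(rbind, lapply(null_blocks, as_vec))
  if (nrow(nulls) < 2L) stop("need at least 2 null blocks")
  R <- nrow(nulls)
  rows <- lapply(names(obs), function(s) {
    v <- nulls[, s]
    v <- v[!is.na(v)]
    o <- obs[[s]]
    if (is.na(o) || length(v) < 2L)
      return(data.frame(statistic = s, observed = o, null_mean = NA_real_,
                        null_sd = NA_real_, k = NA_integer_, p = NA_real_,
                        p_label = NA_character_, stringsAsFactors = FALSE))
    mu <- mean(v); sdv <- stats::sd(v)
    if (sdv == 0 && o == mu) {
      return(data.frame(statistic = s, observed = o, null_mean = mu,
                        null_sd = 0, k = NA_integer_, p = 1,
                        p_label = "1", stringsAsFactors = FALSE))
    }
    k <- if (o >= mu) sum(v > o) else sum(v < o)
    p <- min(1, tails * k / length(v))
    lab <- if (k == 0L) sprintf("<%g", tails / length(v)) else sprintf("%g", p)
    if (k == 0L) p <- tails / length(v)   # bound at the test's resolution
    data.frame(statistic = s, observed = o, null_mean = mu, null_sd = sdv,
               k = k, p = p, p_label = lab, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("rad_resampling_test", "data.frame")
  out
}

#' Compare EST-associated loci to matched non-EST subsamples
#'
#' Computes the informativeness statistics once for the observed
#' (EST-associated) loci inside the length window, then for `n_replicates`
#' matched null subsamples of the same size drawn from the non-EST loci, and
#' reports the null mean, SD, and resampling p-value per statistic.
#'
#' @param est_loci,non_est_loci Partitioned loci (see [partition_by_est()]).
#' @param taxa Taxon set shared by both supermatrices.
#' @param cfg A [subsample_config()].
#' @param ... Passed on to [informativeness_stats()] (model, search,
#'   bootstrap_reps).
#' @return List of class `rad_est_comparison`: `test`
#'   ([resampling_pvalues()] table), `observed` (`stat_block`), `null_blocks`.
#' @export
est_compare <- function(est_loci, non_est_loci, taxa = NULL,
                        cfg = subsample_config(), ...) {
  lens <- vapply(est_loci, locus_length, integer(1))
  obs_loci <- est_loci[lens >= cfg$length_window[1L] &
                       lens <= cfg$length_window[2L]]
  if (length(obs_loci) == 0L)
    stop("no EST loci inside the length window")
  observed <- informativeness_stats(obs_loci, taxa, ...)
  nulls <- lapply(seq_len(cfg$n_replicates), function(r) {
    informativeness_stats(
      matched_subsample(non_est_loci, length(obs_loci), cfg, r), taxa, ...)
  })
  structure(list(test = resampling_pvalues(observed, nulls),
                 observed = observed, null_blocks = nulls),
            class = "rad_est_comparison")
}

#' @export
print.rad_est_comparison <- function(x, ...) {
  cat("EST vs non-EST matched-subsample comparison (",
      length(x$null_blocks), " null replicates)\n", sep = "")
  tab <- x$test
  tab$null <- sprintf("%.4g ± %.3g", tab$null_mean, tab$null_sd)
  print(tab[, c("statistic", "observed", "null", "p_label")],
        row.names = FALSE)
  invisible(x)
}
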