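#' Configuration for the consensus caller
#'
#' Bundles the clustering and genotype-calling thresholds used within
#' individuals.
#'
#' @param similarity Ungapped identity required to join a stack (default 0.88).
#' @param min_depth Minimum reads per stack; shallower stacks are discarded
#'   (default 6).
#' @param max_het_sites Maximum heterozygous positions tolerated per locus
#'   within an individual before the locus is flagged (default 3).
#' @param max_haplotypes Maximum read-phased haplotypes per locus within an
#'   individual; more indicates paralogy (default 2).
#' @param posterior_threshold Minimum genotype posterior to emit a call;
#'   columns below it are written 'N' (default 0.95).
#' @param check_revcomp Also test each read's reverse complement against stack
#'   centroids (default TRUE), since reads come off either strand.
#' @return A list of class `caller_config`.
#' @export
caller_config <- function(similarity = 0.88, min_depth = 6L,
                          max_het_sites = 3L, max_haplotypes = 2L,
                          posterior_threshold = 0.95, check_revcomp = TRUE) {
  stopifnot(similarity > 0, similarity <= 1, min_depth >= 1,
            posterior_threshold > 0, posterior_threshold <= 1)
  structure(list(similarity = similarity, min_depth = as.integer(min_depth),
                 max_het_sites = as.integer(max_het_sites),
                 max_haplotypes = as.integer(max_haplotypes),
                 posterior_threshold = posterior_threshold,
                 check_revcomp = isTRUE(check_revcomp)),
            class = "caller_config")
}

#' Construct a read stack
#'
#' A stack is the pile of equal-length reads from one individual presumed to
#' derive from a single locus, plus its per-column base counts ('N' excluded).
#'
#' @param individual_id Individual label.
#' @param reads Character vector of equal-length reads (oriented consistently).
#' @return Object of class `rad_stack` with `reads`, `depth`, and
#'   `base_counts` (4 x L integer matrix, rows A,C,G,T).
#' @export
rad_stack <- function(individual_id, reads) {
  stopifnot(length(reads) >= 1L)
  m <- seqs_to_matrix(reads)
  counts <- vapply(seq_len(ncol(m)), function(j) {
    tabulate(match(m[, j], .bases), 4L)
  }, integer(4))
  rownames(counts) <- .bases
  structure(list(individual_id = individual_id, reads = toupper(reads),
                 depth = length(reads), base_counts = counts),
            class = "rad_stack")
}

#' @export
print.rad_stack <- function(x, ...) {
  cat("<rad_stack> ", x$individual_id, ": depth ", x$depth, ", ",
      ncol(x$base_counts), " bp\n", sep = "")
  invisible(x)
}

#' Cluster one individual's reads into stacks
#'
#' Greedy centroid clustering: unique reads are sorted by multiplicity (ties
#' broken lexicographically) and scanned in order; each read joins the first
#' existing centroid whose ungapped identity (forward or, optionally, reverse
#' complement) is at least `similarity`, otherwise it founds a new centroid.
#' Reads joined via reverse complement are stored re-oriented to the centroid
#' strand. Stacks shallower than `min_depth` are discarded.
#'
#' @param readset A [rad_readset()] of equal-length reads.
#' @param cfg A [caller_config()].
#' @return List of [rad_stack()] objects (possibly empty).
#' @export
cluster_within_individual <- function(readset, cfg = caller_config()) {
  reads <- readset$reads
  if (length(reads) == 0L) return(list())
  if (length(unique(nchar(reads))) != 1L)
    stop("individual ", readset$individual_id, ": reads of unequal length")
  tab <- table(reads)
  ord <- order(-as.integer(tab), names(tab))
  uniq <- names(tab)[ord]
  mult <- as.integer(tab)[ord]
  umat <- seqs_to_matrix(uniq)
  centroids <- list()          # centroid base vectors
  members <- list()            # per-cluster list of (oriented read, count)
  for (i in seq_along(uniq)) {
    fwd <- umat[i, ]
    rev <- if (cfg$check_revcomp)
      strsplit(revcomp(uniq[i]), "", fixed = TRUE)[[1]] else NULL
    placed <- FALSE
    for (k in seq_along(centroids)) {
      if (ungapped_identity(fwd, centroids[[k]]) >= cfg$similarity) {
        members[[k]][[length(members[[k]]) + 1L]] <- list(uniq[i], mult[i])
        placed <- TRUE; break
      }
      if (!is.null(rev) &&
          ungapped_identity(rev, centroids[[k]]) >= cfg$similarity) {
        members[[k]][[length(members[[k]]) + 1L]] <-
          list(paste(rev, collapse = ""), mult[i])
        placed <- TRUE; break
      }
    }
    if (!placed) {
      centroids[[length(centroids) + 1L]] <- fwd
      members[[length(members) + 1L]] <- list(list(uniq[i], mult[i]))
    }
  }
  stacks <- lapply(members, function(mm) {
    rds <- unlist(lapply(mm, function(e) rep(e[[1]], e[[2]])))
    rad_stack(readset$individual_id, rds)
  })
  stacks[vapply(stacks, function(s) s$depth >= cfg$min_depth, logical(1))]
}

# ---- joint error / heterozygosity likelihood --------------------------------

# Log-likelihood of one column's sorted base counts under a homozygote (true
# base = the top count; errors uniform to the other three at rate eps) and
# under an equal-dosage heterozygote of the top two bases. Multinomial
# coefficients cancel between the two hypotheses only partially, so they are
# kept. `cnt` is a 4-vector sorted decreasingly.
.col_loglik <- function(cnt, eps) {
  n <- sum(cnt)
  lcoef <- lgamma(n + 1) - sum(lgamma(cnt + 1))
  p_homo <- c(1 - eps, rep(eps / 3, 3))
  ll_homo <- lcoef + sum(cnt * log(p_homo))
  p_major <- (1 - eps) / 2 + eps / 6
  p_het <- c(p_major, p_major, rep(eps / 3, 2))
  ll_het <- lcoef + sum(cnt * log(p_het))
  c(homo = ll_homo, het = ll_het)
}

# Collapse stacks to unique sorted count patterns with multiplicities.
#' @keywords internal
count_patterns <- function(stacks) {
  cols <- do.call(cbind, lapply(stacks, function(s) s$base_counts))
  if (is.null(cols) || ncol(cols) == 0L)
    stop("no stack columns available for estimation")
  cols <- cols[, colSums(cols) > 0L, drop = FALSE]
  if (ncol(cols) == 0L) stop("all stack columns are entirely N")
  sorted <- apply(cols, 2L, function(v) sort(v, decreasing = TRUE))
  key <- apply(sorted, 2L, paste, collapse = ",")
  tab <- table(key)
  pat <- do.call(rbind, lapply(strsplit(names(tab), ","), as.integer))
  list(patterns = pat, weights = as.integer(tab))
}

#' Jointly estimate sequencing error and heterozygosity
#'
#' Maximizes, over error rate \eqn{\epsilon} and heterozygosity \eqn{H}, the
#' product over all stack columns of
#' \eqn{(1-H)\,P_{homo}(counts\mid\epsilon) + H\,P_{het}(counts\mid\epsilon)},
#' where the homozygote model takes the most frequent base as truth with
#' errors uniform over the other three, and the heterozygote model draws each
#' read from one of the two most frequent bases with probability 1/2 before
#' applying error. Columns are pooled across stacks and depths.
#'
#' @param stacks List of [rad_stack()] objects.
#' @param min_columns Below this many usable columns the estimate is flagged
#'   unstable (default 10).
#' @return List of class `error_het_estimate` with elements `epsilon`, `het`,
#'   `loglik`, `n_columns`, `stable`.
#' @export
estimate_error_het <- function(stacks, min_columns = 10L) {
  cp <- count_patterns(stacks)
  negll <- function(par) {
    eps <- par[1L]; h <- par[2L]
    lls <- apply(cp$patterns, 1L, .col_loglik, eps = eps)
    # log( (1-h) e^{ll_homo} + h e^{ll_het} ) via log-sum-exp
    a <- log(1 - h) + lls["homo", ]
    b <- log(h) + lls["het", ]
    m <- pmax(a, b)
    -sum(cp$weights * (m + log(exp(a - m) + exp(b - m))))
  }
  fit <- stats::nlminb(c(0.005, 0.005), negll,
                       lower = c(1e-9, 1e-9), upper = c(0.499, 0.499))
  structure(list(epsilon = fit$par[1L], het = fit$par[2L],
                 loglik = -fit$objective,
                 n_columns = sum(cp$weights),
                 stable = sum(cp$weights) >= min_columns),
            class = "error_het_estimate")
}

#' @export
print.error_het_estimate <- function(x, ...) {
  cat(sprintf("<error_het_estimate> epsilon = %.3g, het = %.3g (logLik %.2f, %d columns%s)\n",
              x$epsilon, x$het, x$loglik, x$n_columns,
              if (x$stable) "" else ", UNSTABLE"))
  invisible(x)
}

# Genotype posteriors for one column of base counts. Returns the argmax
# genotype (e.g. "A" or "AG") and its posterior. Priors: (1-H)/4 per
# homozygote, H/6 per unordered heterozygote pair.
#' @keywords internal
genotype_posterior <- function(cnt, eps, het) {
  n <- sum(cnt)
  if (n == 0L) return(list(genotype = "N", posterior = 0))
  logp <- numeric(0); labs <- character(0)
  for (b in 1:4) {
    p <- rep(eps / 3, 4); p[b] <- 1 - eps
    logp <- c(logp, log((1 - het) / 4) + sum(cnt * log(p)))
    labs <- c(labs, .bases[b])
  }
  for (b1 in 1:3) for (b2 in (b1 + 1):4) {
    p <- rep(eps / 3, 4)
    p[c(b1, b2)] <- (1 - eps) / 2 + eps / 6
    logp <- c(logp, log(het / 6) + sum(cnt * log(p)))
    labs <- c(labs, paste0(.bases[b1], .bases[b2]))
  }
  m <- max(logp)
  post <- exp(logp - m); post <- post / sum(post)
  i <- which.max(post)
  list(genotype = labs[i], posterior = post[i])
}

#' Call a diploid consensus sequence from a stack
#'
#' Per column, computes the posterior over the four homozygotes and six
#' unordered heterozygote pairs from the estimated error rate and
#' heterozygosity, and calls the argmax genotype only when its posterior
#' reaches `posterior_threshold`; otherwise the column is 'N'. Heterozygous
#' calls are written as IUPAC two-fold codes. The locus is flagged when it has
#' more than `max_het_sites` heterozygous positions or when read-phased
#' haplotypes exceed `max_haplotypes` (paralog signal; such loci are discarded
#' downstream).
#'
#' @param stack A [rad_stack()].
#' @param est An [estimate_error_het()] result (epsilon is clamped to 1e-9
#'   from below to avoid log(0)).
#' @param cfg A [caller_config()].
#' @return Object of class `rad_consensus`: `individual_id`, `sequence`,
#'   `n_het_sites`, `n_haplotypes`, `flags` (character vector, possibly empty).
#' @export
call_consensus <- function(stack, est, cfg = caller_config()) {
  eps <- max(est$epsilon, 1e-9)
  het <- min(max(est$het, 1e-9), 0.499)
  L <- ncol(stack$base_counts)
  calls <- character(L)
  het_sites <- integer(0)
  het_pairs <- list()
  for (j in seq_len(L)) {
    g <- genotype_posterior(stack$base_counts[, j], eps, het)
    if (g$genotype == "N" || g$posterior < cfg$posterior_threshold) {
      calls[j] <- "N"
    } else if (nchar(g$genotype) == 1L) {
      calls[j] <- g$genotype
    } else {
      calls[j] <- .het_codes[[g$genotype]]
      het_sites <- c(het_sites, j)
      het_pairs[[length(het_pairs) + 1L]] <- strsplit(g$genotype, "")[[1]]
    }
  }
  n_hap <- count_haplotypes(stack, het_sites)
  flags <- character(0)
  if (length(het_sites) > cfg$max_het_sites) flags <- c(flags, "too_many_hets")
  if (n_hap > cfg$max_haplotypes) flags <- c(flags, "too_many_haplotypes")
  if (stack$depth < cfg$min_depth) flags <- c(flags, "low_depth")
  structure(list(individual_id = stack$individual_id,
                 sequence = paste(calls, collapse = ""),
                 n_het_sites = length(het_sites),
                 n_haplotypes = n_hap, flags = flags),
            class = "rad_consensus")
}

# Phase heterozygous sites by read co-occurrence: the distinct combinations of
# alleles observed across the called het sites within single reads, counted as
# haplotypes when seen at least twice.
#' @keywords internal
count_haplotypes <- function(stack, het_sites) {
  if (length(het_sites) == 0L) return(1L)
  m <- seqs_to_matrix(stack$reads)
  combos <- apply(m[, het_sites, drop = FALSE], 1L, paste, collapse = "")
  combos <- combos[!grepl("N", combos, fixed = TRUE)]
  if (length(combos) == 0L) return(1L)
  tab <- table(combos)
  max(1L, sum(tab >= 2L))
}

#' @export
print.rad_consensus <- function(x, ...) {
  cat("<rad_consensus> ", x$individual_id, ": ", nchar(x$sequence), " bp, ",
      x$n_het_sites, " het site(s), ", x$n_haplotypes, " haplotype(s)",
      if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]"),
      "\n", sep = "")
  invisible(x)
}

#' Majority-rule consensus of a locus alignment
#'
#' Per column, the plurality base among `{A,C,G,T}` (IUPAC codes expanded to
#' their constituent bases), ties broken alphabetically; columns with no
#' resolved base become 'N'.
#'
#' @param locus A [rad_locus()].
#' @return Single consensus sequence string.
#' @export
consensus_of_alignment <- function(locus) {
  stopifnot(nrow(locus$seqs) > 0L)
  out <- vapply(seq_len(ncol(locus$seqs)), function(j) {
    tab <- column_base_table(locus$seqs[, j])
    if (length(tab) == 0L) return("N")
    names(tab)[which.max(tab)]   # which.max takes the first = alphabetical
  }, character(1))
  paste(out, collapse = "")
}
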