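#' Configuration for the RAD-data simulator
#'
#' Defaults emulate a 20-taxon RAD study of a shallow radiation sequenced at
#' moderate coverage: 50-bp loci, GTR+GAMMA evolution, restriction-site
#' dropout structured along the tree plus independent coverage thinning tuned
#' to give a roughly 60%-complete matrix, and diploid read stacks with a
#' realistic Illumina error rate.
#'
#' @param n_taxa Number of taxa (default 20).
#' @param n_loci Number of loci to simulate (default 1000).
#' @param locus_length Locus length in bp (default 50).
#' @param model A [subst_model()] (default equal-frequency GTR, alpha 1).
#' @param tree_depth Expected root-to-tip path length in substitutions/site
#'   (default 0.05).
#' @param site_dropout_rate Restriction-site mutation rate per unit branch
#'   length: on each branch the cut site is lost with probability
#'   `1 - exp(-rate * branch_length)` and all descendant tips lose the locus
#'   (default 5).
#' @param coverage_retain_prob Independent per-(taxon, locus) retention
#'   probability emulating sequencing coverage (default 0.75).
#' @param read_depth_mean Mean (Poisson) reads per retained locus per
#'   individual (default 20).
#' @param epsilon Per-base sequencing error rate (default 0.005).
#' @param het Per-site heterozygosity (default 0.005).
#' @param min_individuals Loci retained only when at least this many
#'   individuals survive dropout (default 4).
#' @param rng_seed Integer seed (default 1).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_taxa = 20L, n_loci = 1000L, locus_length = 50L,
                       model = subst_model(), tree_depth = 0.05,
                       site_dropout_rate = 5, coverage_retain_prob = 0.75,
                       read_depth_mean = 20, epsilon = 0.005, het = 0.005,
                       min_individuals = 4L, rng_seed = 1L) {
  stopifnot(n_taxa >= 4L, n_loci >= 1L, locus_length >= 1L, tree_depth > 0,
            site_dropout_rate >= 0, coverage_retain_prob > 0,
            coverage_retain_prob <= 1, epsilon >= 0, epsilon < 0.5,
            het >= 0, het < 0.5)
  structure(list(n_taxa = as.integer(n_taxa), n_loci = as.integer(n_loci),
                 locus_length = as.integer(locus_length), model = model,
                 tree_depth = tree_depth,
                 site_dropout_rate = site_dropout_rate,
                 coverage_retain_prob = coverage_retain_prob,
                 read_depth_mean = read_depth_mean, epsilon = epsilon,
                 het = het, min_individuals = as.integer(min_individuals),
                 rng_seed = as.integer(rng_seed)),
            class = "sim_config")
}

#' Expected number of restriction-enzyme cut sites
#'
#' Under an independent-base genome model with the given GC content
#' (`piC = piG = gc/2`, `piA = piT = (1-gc)/2`), the expected number of motif
#' occurrences is the genome length times the product of the per-position
#' base probabilities. A 500-Mb genome at 40% GC carries about 72,000
#' occurrences of the 6-bp PstI site CTGCAG, against roughly 2,860 for an
#' 8-bp cutter like SbfI (CCTGCAGG) — the reason enzyme choice controls locus
#' count.
#'
#' @param genome_length Genome size in bases.
#' @param gc_content GC fraction in (0, 1).
#' @param motif Recognition sequence over `{A,C,G,T}`.
#' @return Expected count (numeric).
#' @examples
#' expected_cut_sites(5e8, 0.40, "CTGCAG")  # 72000
#' @export
expected_cut_sites <- function(genome_length, gc_content, motif) {
  stopifnot(genome_length > 0, gc_content > 0, gc_content < 1)
  ch <- strsplit(toupper(motif), "", fixed = TRUE)[[1]]
  if (!all(ch %in% .bases))
    stop("motif must contain only A/C/G/T; got ",
         paste(setdiff(ch, .bases), collapse = ", "))
  p <- ifelse(ch %in% c("C", "G"), gc_content / 2, (1 - gc_content) / 2)
  genome_length * prod(p)
}

#' Simulate a random species tree
#'
#' Topology uniform over labeled unrooted binary topologies (sequential
#' random edge splitting); branch lengths are i.i.d. exponential, rescaled so
#' the mean root-to-tip path length (half the mean pairwise tip distance)
#' equals `tree_depth`.
#'
#' @param n_taxa Number of taxa (>= 4); tips are labeled `t1 ... tn`.
#' @param tree_depth Target mean root-to-tip length (substitutions/site).
#' @param rng_seed Integer seed.
#' @return An unrooted binary `phylo`.
#' @export
simulate_tree <- function(n_taxa, tree_depth = 0.05, rng_seed = 1L) {
  stopifnot(n_taxa >= 4L)
  with_seed(rng_seed, {
    tr <- ape::rtopology(n_taxa, rooted = FALSE,
                         tip.label = paste0("t", seq_len(n_taxa)))
    tr$edge.length <- stats::rexp(nrow(tr$edge), 1)
    depth <- mean(ape::cophenetic.phylo(tr)[upper.tri(diag(n_taxa))]) / 2
    tr$edge.length <- tr$edge.length * tree_depth / depth
    tr
  })
}

# Simulate one alignment of `len` sites on `tree` under the model, with
# per-site rates drawn from the discrete gamma (sites are simulated per rate
# category and re-interleaved). Returns a character matrix taxa x len.
#' @keywords internal
simulate_alignment <- function(tree, len, model) {
  k <- model$n_categories
  rates <- if (k > 1L) phangorn::discrete.gamma(model$alpha, k) else 1
  cat_of_site <- sample.int(length(rates), len, replace = TRUE)
  out <- matrix(NA_character_, length(tree$tip.label), len,
                dimnames = list(tree$tip.label, NULL))
  for (c in seq_along(rates)) {
    idx <- which(cat_of_site == c)
    if (length(idx) == 0L) next
    sim <- phangorn::simSeq(tree, l = length(idx), Q = model$rates,
                            bf = model$base_freqs, rate = rates[c])
    out[, idx] <- toupper(as.character(sim))[rownames(out), , drop = FALSE]
  }
  out
}

# Phylogenetically structured dropout: the restriction site is lost on each
# branch with probability 1 - exp(-rate * length); every tip below a loss
# loses the locus. Returns a logical presence vector named by tip.
#' @keywords internal
dropout_presence <- function(tree, rate) {
  ntip <- length(tree$tip.label)
  present <- rep(TRUE, ntip)
  names(present) <- tree$tip.label
  if (rate <= 0) return(present)
  lost_node <- rep(FALSE, max(tree$edge))
  # breadth-first from the basal node so parents are settled before children
  queue <- ntip + 1L
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    out <- which(tree$edge[, 1L] == v)
    for (i in out) {
      child <- tree$edge[i, 2L]
      lost_node[child] <- lost_node[v] ||
        (stats::runif(1) < 1 - exp(-rate * tree$edge.length[i]))
      if (child > ntip) queue <- c(queue, child)
    }
  }
  present[lost_node[seq_len(ntip)]] <- FALSE
  present
}

#' Simulate RAD loci with known truth
#'
#' Per locus: evolve a `locus_length`-bp alignment along the tree under
#' GTR+GAMMA; apply restriction-site dropout (branch-wise loss inherited by
#' descendants) and then independent coverage thinning; keep the locus when at
#' least `min_individuals` individuals survive.
#'
#' @param tree The true `phylo` (e.g. from [simulate_tree()]).
#' @param cfg A [sim_config()]; `cfg$rng_seed` drives all randomness.
#' @param switch_trees Optional `multiPhylo` of alternative gene trees; each
#'   locus evolves on one of them (uniformly drawn) with probability
#'   `switch_prob` instead of on `tree`. A cheap stand-in for gene-tree
#'   heterogeneity from incomplete lineage sorting.
#' @param switch_prob Per-locus probability of switching (default 0).
#' @return List of class `sim_truth`: `loci` (list of [rad_locus()] holding
#'   only surviving individuals), `presence` (taxa x simulated-loci binary
#'   matrix, including loci later discarded), `alignments` (full truth
#'   alignments for every simulated locus), `locus_tree` (0 = species tree,
#'   else index into `switch_trees`), `tree`, `config`.
#' @export
simulate_loci <- function(tree, cfg = sim_config(), switch_trees = NULL,
                          switch_prob = 0) {
  stopifnot(switch_prob >= 0, switch_prob <= 1,
            switch_prob == 0 || length(switch_trees) >= 1L)
  with_seed(cfg$rng_seed, {
    taxa <- tree$tip.label
    loci <- list()
    alignments <- vector("list", cfg$n_loci)
    locus_tree <- integer(cfg$n_loci)
    presence <- matrix(0L, length(taxa), cfg$n_loci,
                       dimnames = list(taxa, sprintf("L%06d", seq_len(cfg$n_loci))))
    for (i in seq_len(cfg$n_loci)) {
      gene_tree <- tree
      if (switch_prob > 0 && stats::runif(1) < switch_prob) {
        locus_tree[i] <- sample.int(length(switch_trees), 1L)
        gene_tree <- switch_trees[[locus_tree[i]]]
      }
      aln <- simulate_alignment(gene_tree, cfg$locus_length, cfg$model)
      alignments[[i]] <- aln
      keep <- dropout_presence(tree, cfg$site_dropout_rate) &
        (stats::runif(length(taxa)) < cfg$coverage_retain_prob)
      presence[names(keep)[keep], i] <- 1L
      if (sum(keep) >= cfg$min_individuals) {
        loci[[length(loci) + 1L]] <-
          rad_locus(colnames(presence)[i], aln[names(keep)[keep], , drop = FALSE])
      }
    }
    names(alignments) <- colnames(presence)
    structure(list(loci = loci, presence = presence,
                   alignments = alignments, locus_tree = locus_tree,
                   tree = tree, config = cfg),
              class = "sim_truth")
  })
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("<sim_truth> %d/%d loci retained on %d taxa (completeness %.2f)\n",
              length(x$loci), x$config$n_loci, nrow(x$presence),
              mean(x$presence)))
  invisible(x)
}

#' Expected overlap of two thinned technical replicates
#'
#' Two independent thinnings of one locus set at retention probabilities `ra`
#' and `rb` share, in expectation, `ra*rb / (ra + rb - ra*rb)` of their union
#' — the closed form behind the observed 43--64% replicate overlaps.
#'
#' @param ra,rb Retention probabilities in (0, 1].
#' @return Expected shared/union fraction.
#' @export
expected_replicate_overlap <- function(ra, rb) {
  stopifnot(ra > 0, ra <= 1, rb > 0, rb <= 1)
  ra * rb / (ra + rb - ra * rb)
}

#' Simulate a technical-replicate presence pair
#'
#' Thins one underlying presence row twice, independently, emulating two
#' sequencing runs of the same library.
#'
#' @param presence_row Binary (or logical) vector: which loci the individual
#'   truly has.
#' @param retain_a,retain_b Per-run retention probabilities in (0, 1].
#' @param rng_seed Optional seed; `NULL` uses the ambient RNG state.
#' @return List with binary vectors `a` and `b`.
#' @export
simulate_replicate_pair <- function(presence_row, retain_a, retain_b,
                                    rng_seed = NULL) {
  stopifnot(retain_a > 0, retain_a <= 1, retain_b > 0, retain_b <= 1)
  draw <- function() {
    p <- as.integer(presence_row > 0)
    list(a = p * as.integer(stats::runif(length(p)) < retain_a),
         b = p * as.integer(stats::runif(length(p)) < retain_b))
  }
  if (is.null(rng_seed)) draw() else with_seed(rng_seed, draw())
}

#' Simulate a read stack for one locus of one individual
#'
#' Draws a diploid genotype from the truth sequence (each site heterozygous
#' with probability `het`, the second allele uniform over the other bases),
#' then `Poisson(depth_mean)` reads, each copied from a random allele with
#' per-base errors to a uniform other base at rate `epsilon`. Qualities are
#' constant Phred 40.
#'
#' @param truth_seq Truth sequence string (or character vector of bases).
#' @param depth_mean Mean read depth.
#' @param epsilon Per-base error rate in `[0, 0.5)`.
#' @param het Per-site heterozygosity in `[0, 0.5)`.
#' @param individual_id Label for the returned read set.
#' @param rng_seed Optional seed; `NULL` uses the ambient RNG state.
#' @return A [rad_readset()].
#' @export
simulate_reads <- function(truth_seq, depth_mean, epsilon, het,
                           individual_id = "ind", rng_seed = NULL) {
  stopifnot(epsilon >= 0, epsilon < 0.5, het >= 0, het < 0.5)
  base <- if (length(truth_seq) == 1L)
    strsplit(toupper(truth_seq), "", fixed = TRUE)[[1]] else toupper(truth_seq)
  L <- length(base)
  draw <- function() {
    allele1 <- base
    allele2 <- base
    hs <- which(stats::runif(L) < het & base %in% .bases)
    for (j in hs)
      allele2[j] <- sample(setdiff(.bases, base[j]), 1L)
    n <- stats::rpois(1L, depth_mean)
    reads <- character(n)
    for (r in seq_len(n)) {
      rd <- if (stats::runif(1) < 0.5) allele1 else allele2
      err <- which(stats::runif(L) < epsilon & rd %in% .bases)
      for (j in err) rd[j] <- sample(setdiff(.bases, rd[j]), 1L)
      reads[r] <- paste(rd, collapse = "")
    }
    rad_readset(individual_id, reads,
                matrix(40L, n, L))
  }
  if (is.null(rng_seed)) draw() else with_seed(rng_seed, draw())
}
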