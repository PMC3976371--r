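#' Canonical identifier of an unrooted topology
#'
#' Two trees get the same id iff their unrooted topologies are identical. The
#' id is built from the set of non-trivial bipartitions, each represented by
#' the side not containing the alphabetically first taxon, with taxa sorted
#' within sides and sides sorted overall. Invariant under re-rooting,
#' rotation, and ladderization.
#'
#' @param tree An object of class `phylo`.
#' @return Character scalar id. Trees with fewer than 4 taxa all map to the
#'   single id `"DEGENERATE<n>"` for their taxon count (no non-trivial splits
#'   exist).
#' @export
canonical_id <- function(tree) {
  labs <- tree$tip.label
  n <- length(labs)
  if (n < 4L) return(paste0("DEGENERATE", n))
  ref <- min(labs)
  pp <- ape::prop.part(tree)
  sides <- character(0)
  for (cl in pp) {
    s <- labs[cl]
    if (length(s) <= 1L || length(s) >= n - 1L) next
    if (ref %in% s) s <- setdiff(labs, s)
    sides <- c(sides, paste(sort(s), collapse = ","))
  }
  paste0(n, "t:", paste(sort(unique(sides)), collapse = ";"))
}

#' Unique 1-step NNI neighbors of a tree
#'
#' Enumerates every nearest-neighbor-interchange rearrangement across all
#' internal edges of an unrooted binary tree and deduplicates by
#' [canonical_id()]. An unrooted binary tree on n taxa has exactly `2(n-3)`
#' distinct NNI neighbors. Branch lengths of the source tree are carried over
#' (swapped subtrees keep their lengths); they serve as starting values for
#' re-optimization.
#'
#' @param tree `phylo`, unrooted binary (rooted input is unrooted first).
#' @return `multiPhylo` list of unique neighbor topologies.
#' @export
nni_neighbors <- function(tree) {
  tree <- ape::unroot(tree)
  if (!ape::is.binary(tree))
    stop("NNI requires a binary tree; resolve multifurcations first")
  if (length(tree$tip.label) < 4L) stop("NNI requires at least 4 taxa")
  nb <- phangorn::nni(tree)
  # expand the shared-tip-label compression so elements are self-contained
  nb <- lapply(seq_along(nb), function(i) nb[[i]])
  ids <- vapply(nb, canonical_id, character(1))
  nb <- nb[!duplicated(ids)]
  class(nb) <- "multiPhylo"
  nb
}

#' Build the candidate pool of NNI-permuted trees
#'
#' The pool holds the optimal tree, all of its unique 1-step NNI neighbors,
#' and uniformly sampled (without replacement, seeded) unique 2-step NNI
#' topologies — neighbors of neighbors, excluding the optimal tree and the
#' 1-step set — until `n_permuted` permuted trees are collected. For a
#' 20-taxon tree this is the 201-tree pool: 1 optimal + 34 one-step + 166
#' two-step.
#'
#' @param optimal `phylo`, the globally optimal unrooted binary tree.
#' @param n_permuted Total number of permuted (non-optimal) trees (default
#'   200). Must be at least the number of 1-step neighbors.
#' @param rng_seed Integer seed making the 2-step sample deterministic.
#' @return List of class `rad_tree_pool`: `trees` (`multiPhylo`, optimal
#'   first), `origin` (`"optimal"`, `"nni1"`, `"nni2"`), `ids` (canonical
#'   ids, all distinct).
#' @export
build_tree_pool <- function(optimal, n_permuted = 200L, rng_seed = 1L) {
  optimal <- ape::unroot(optimal)
  id0 <- canonical_id(optimal)
  nni1 <- nni_neighbors(optimal)
  ids1 <- vapply(nni1, canonical_id, character(1))
  if (n_permuted < length(nni1))
    stop("n_permuted (", n_permuted, ") is less than the ", length(nni1),
         " unique 1-step NNI neighbors")
  n2 <- n_permuted - length(nni1)
  trees2 <- list(); ids2 <- character(0)
  if (n2 > 0L) {
    seen <- c(id0, ids1)
    for (t1 in nni1) {
      for (t2 in nni_neighbors(t1)) {
        id <- canonical_id(t2)
        if (id %in% seen || id %in% ids2) next
        trees2[[length(trees2) + 1L]] <- t2
        ids2 <- c(ids2, id)
      }
    }
    if (length(trees2) < n2)
      stop("only ", length(trees2), " unique 2-step NNI topologies exist; ",
           "maximum n_permuted is ", length(nni1) + length(trees2))
    pick <- with_seed(rng_seed, sample.int(length(trees2), n2))
    trees2 <- trees2[pick]; ids2 <- ids2[pick]
  }
  trees <- c(list(optimal), unclass(nni1), trees2)
  class(trees) <- "multiPhylo"
  structure(list(trees = trees,
                 origin = c("optimal", rep("nni1", length(nni1)),
                            rep("nni2", length(trees2))),
                 ids = c(id0, ids1, ids2)),
            class = "rad_tree_pool")
}

#' @export
print.rad_tree_pool <- function(x, ...) {
  cat(sprintf("<rad_tree_pool> %d trees (1 optimal, %d nni1, %d nni2) on %d taxa\n",
              length(x$trees), sum(x$origin == "nni1"),
              sum(x$origin == "nni2"), length(x$trees[[1]]$tip.label)))
  invisible(x)
}

#' Prune a tree pool to a taxon subset and deduplicate
#'
#' Restricts every pool tree to `keep_taxa` (suppressing degree-2 vertices,
#' with incident branch lengths summed) and keeps one representative per
#' distinct pruned topology, recording for each pool tree the index of its
#' representative.
#'
#' @param pool A `rad_tree_pool`.
#' @param keep_taxa Character vector, at least 4 taxa, subset of the pool's.
#' @return List of class `rad_pruned_set`: `trees` (`multiPhylo` of unique
#'   pruned representatives), `ids`, `index_map` (integer, one entry per pool
#'   tree).
#' @export
prune_and_dedup <- function(pool, keep_taxa) {
  all_taxa <- pool$trees[[1]]$tip.label
  if (!all(keep_taxa %in% all_taxa))
    stop("keep_taxa not in pool: ",
         paste(setdiff(keep_taxa, all_taxa), collapse = ", "))
  if (length(keep_taxa) < 4L)
    stop("need at least 4 taxa to prune to (got ", length(keep_taxa),
         "); loci this sparse should have been filtered out")
  pruned <- lapply(pool$trees, ape::keep.tip, tip = keep_taxa)
  ids <- vapply(pruned, canonical_id, character(1))
  uniq <- !duplicated(ids)
  reps <- pruned[uniq]
  class(reps) <- "multiPhylo"
  structure(list(trees = reps, ids = ids[uniq],
                 index_map = match(ids, ids[uniq])),
            class = "rad_pruned_set")
}

#' Proportion of total branch length in terminal branches
#'
#' @param tree `phylo` with branch lengths.
#' @return Sum of terminal branch lengths over the total branch length.
#' @export
tip_branch_proportion <- function(tree) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  tot <- sum(tree$edge.length)
  if (tot == 0) stop("total branch length is zero")
  tip <- tree$edge[, 2L] <= length(tree$tip.label)
  sum(tree$edge.length[tip]) / tot
}

#' Ratio of basal to replicate-subtending branch lengths
#'
#' Quantifies how substitutions apportion to deep versus terminal branches:
#' the summed lengths of the `n_basal` internal branches nearest the root
#' (breadth-first from the outgroup attachment) divided by the summed lengths
#' of the terminal branches subtending each technical-replicate pair. Each
#' replicate pair must be sister in the tree.
#'
#' @param tree `phylo` with branch lengths.
#' @param replicate_pairs List of 2-long character vectors of tip labels.
#' @param outgroup Tip label used to root the tree and define "basal".
#' @param n_basal How many basal internal branches to sum (default 3).
#' @return Numeric ratio; `Inf` (with a warning) when the replicate branches
#'   sum to zero.
#' @export
basal_terminal_ratio <- function(tree, replicate_pairs, outgroup,
                                 n_basal = 3L) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  rt <- ape::root(ape::unroot(tree), outgroup, resolve.root = TRUE)
  ntip <- length(rt$tip.label)
  root <- ntip + 1L
  # breadth-first depth of every node from the root
  depth <- rep(NA_integer_, max(rt$edge))
  depth[root] <- 0L
  queue <- root
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    kids <- rt$edge[rt$edge[, 1L] == v, 2L]
    depth[kids] <- depth[v] + 1L
    queue <- c(queue, kids[kids > ntip])
  }
  internal <- which(rt$edge[, 2L] > ntip)
  og_tip <- which(rt$tip.label == outgroup)
  # drop the zero-length edge introduced by resolve.root (sister to outgroup)
  og_parent <- rt$edge[rt$edge[, 2L] == og_tip, 1L]
  internal <- internal[!(rt$edge[internal, 1L] == og_parent &
                           rt$edge.length[internal] == 0)]
  ord <- internal[order(depth[rt$edge[internal, 2L]], rt$edge[internal, 2L])]
  if (length(ord) < n_basal)
    stop("tree has only ", length(ord), " internal edges below the root")
  basal_sum <- sum(rt$edge.length[ord[seq_len(n_basal)]])
  term <- 0
  for (p in replicate_pairs) {
    tips <- match(p, rt$tip.label)
    if (anyNA(tips)) stop("unknown replicate tip: ",
                          paste(p[is.na(tips)], collapse = ", "))
    par <- rt$edge[match(tips, rt$edge[, 2L]), 1L]
    if (par[1L] != par[2L])
      stop("replicate pair not sister in tree: ", paste(p, collapse = " / "))
    term <- term + sum(rt$edge.length[match(tips, rt$edge[, 2L])])
  }
  if (term == 0) {
    warning("replicate terminal branches sum to zero: ratio is infinite")
    return(Inf)
  }
  basal_sum / term
}
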