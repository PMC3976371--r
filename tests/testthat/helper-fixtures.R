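# Small fixture builders shared across test files.

# Random aligned character matrix with optional missing cells and ambiguity.
random_alignment <- function(ntaxa, nsites, p_missing = 0,
                             taxa = paste0("t", seq_len(ntaxa))) {
  m <- matrix(sample(c("A", "C", "G", "T"), ntaxa * nsites, replace = TRUE),
              ntaxa, nsites, dimnames = list(taxa, NULL))
  if (p_missing > 0)
    m[stats::runif(length(m)) < p_missing] <- "N"
  m
}

# Random unrooted binary tree with exponential branch lengths.
random_tree <- function(ntaxa, mean_edge = 0.1,
                        taxa = paste0("t", seq_len(ntaxa))) {
  tr <- ape::unroot(ape::rtree(ntaxa, tip.label = taxa))
  tr$edge.length <- stats::rexp(nrow(tr$edge), 1 / mean_edge)
  tr
}

# A locus whose rows are identical copies of one random sequence.
invariant_locus <- function(id, inds, len = 50L) {
  s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
             collapse = "")
  rad_locus(id, stats::setNames(rep(s, length(inds)), inds))
}

# Fabricate a locus_tree_table without running the engine.
fake_table <- function(locus_id, loglik, index_map = seq_along(loglik),
                       min_ll_range = 4.0) {
  fin <- loglik[is.finite(loglik)]
  rng <- if (length(fin) >= 2L) max(fin) - min(fin) else 0
  structure(list(locus_id = locus_id, loglik = loglik, index_map = index_map,
                 ll_range = rng, excluded = rng < min_ll_range),
            class = "locus_tree_table")
}

# Write a temporary FASTQ file from reads + integer qualities.
write_tmp_fastq <- function(reads, quals, offset = 33L) {
  path <- tempfile(fileext = ".fastq")
  con <- file(path, "w")
  for (i in seq_along(reads)) {
    writeLines(c(paste0("@r", i), reads[i], "+",
                 rawToChar(as.raw(quals[[i]] + offset))), con)
  }
  close(con)
  path
}
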