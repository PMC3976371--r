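#' Cluster consensus sequences into loci across individuals
#'
#' Greedy centroid clustering of all per-individual consensus sequences at an
#' ungapped-identity threshold (reverse complements checked). Clusters that
#' contain two or more sequences from the same individual are discarded as
#' putative paralogs; clusters with fewer than `min_individuals` distinct
#' individuals are discarded. Surviving clusters become loci with stable,
#' deterministic ids (`L000001`, ... in centroid-founding order).
#'
#' @param consensus Named list: individual id -> character vector of that
#'   individual's consensus sequences (equal length across all individuals).
#' @param similarity Identity threshold (default 0.88).
#' @param min_individuals Minimum distinct individuals per locus (default 4;
#'   the stricter analysis uses 10).
#' @param check_revcomp Also compare reverse complements (default TRUE).
#' @return List of [rad_locus()] objects.
#' @export
cluster_across_individuals <- function(consensus, similarity = 0.88,
                                       min_individuals = 4L,
                                       check_revcomp = TRUE) {
  ind <- rep(names(consensus), lengths(consensus))
  seqs <- toupper(unlist(consensus, use.names = FALSE))
  if (length(seqs) == 0L) return(list())
  ord <- order(seqs)
  seqs <- seqs[ord]; ind <- ind[ord]
  centroids <- list()
  members <- list()
  for (i in seq_along(seqs)) {
    fwd <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    rev <- if (check_revcomp) strsplit(revcomp(seqs[i]), "", fixed = TRUE)[[1]]
           else NULL
    placed <- FALSE
    for (k in seq_along(centroids)) {
      if (length(fwd) == length(centroids[[k]]) &&
          ungapped_identity(fwd, centroids[[k]]) >= similarity) {
        members[[k]][[length(members[[k]]) + 1L]] <- list(ind[i], seqs[i])
        placed <- TRUE; break
      }
      if (!is.null(rev) && length(rev) == length(centroids[[k]]) &&
          ungapped_identity(rev, centroids[[k]]) >= similarity) {
        members[[k]][[length(members[[k]]) + 1L]] <-
          list(ind[i], paste(rev, collapse = ""))
        placed <- TRUE; break
      }
    }
    if (!placed) {
      centroids[[length(centroids) + 1L]] <- fwd
      members[[length(members) + 1L]] <- list(list(ind[i], seqs[i]))
    }
  }
  out <- list()
  for (k in seq_along(members)) {
    inds <- vapply(members[[k]], `[[`, character(1), 1L)
    if (anyDuplicated(inds)) next                       # paralog signal
    if (length(inds) < min_individuals) next
    sq <- vapply(members[[k]], `[[`, character(1), 2L)
    names(sq) <- inds
    out[[length(out) + 1L]] <-
      rad_locus(sprintf("L%06d", length(out) + 1L), sq)
  }
  out
}

#' Apply the among-individual locus filters
#'
#' A locus is discarded when any column carries a heterozygous (IUPAC two-fold)
#' call in more than `max_shared_het_individuals` individuals (shared
#' heterozygosity at one position across many individuals indicates paralogy),
#' or when its variable-site count exceeds `max_variable_sites`.
#'
#' @param locus A [rad_locus()].
#' @param max_shared_het_individuals Default 2.
#' @param max_variable_sites Default 10.
#' @return List with `keep` (logical) and `reason` (`NA`, `"shared_het"`, or
#'   `"too_variable"`).
#' @export
apply_locus_filters <- function(locus, max_shared_het_individuals = 2L,
                                max_variable_sites = 10L) {
  het <- matrix(locus$seqs %in% names(.het_bases), nrow(locus$seqs))
  if (any(colSums(het) > max_shared_het_individuals))
    return(list(keep = FALSE, reason = "shared_het"))
  if (locus_site_counts(locus)$n_variable > max_variable_sites)
    return(list(keep = FALSE, reason = "too_variable"))
  list(keep = TRUE, reason = NA_character_)
}

#' Concatenate loci into a supermatrix
#'
#' Loci are laid end-to-end in ascending `locus_id` order; cells for absent
#' (taxon, locus) pairs are filled with 'N'. Records the half-open 0-based
#' column span of every locus, the matrix completeness (fraction of present
#' (taxon, locus) cells), the mean number of individuals per locus, and the
#' indices of columns that are entirely 'N' across taxa (excluded from
#' analysis downstream).
#'
#' @param loci List of [rad_locus()].
#' @param taxa Ordered character vector of taxa; must cover every individual
#'   appearing in `loci`.
#' @return List of class `rad_supermatrix`: `matrix` (taxa x total length),
#'   `locus_spans` (data.frame locus_id/start/end, 0-based half-open),
#'   `completeness`, `mean_individuals_per_locus`, `all_n_columns`.
#' @export
concatenate_loci <- function(loci, taxa) {
  if (anyDuplicated(taxa)) stop("duplicate taxon label: ",
                                taxa[duplicated(taxa)][1L])
  ids <- vapply(loci, function(l) l$locus_id, character(1))
  loci <- loci[order(ids)]
  ids <- sort(ids)
  total <- sum(vapply(loci, locus_length, integer(1)))
  m <- matrix("N", length(taxa), total, dimnames = list(taxa, NULL))
  spans <- data.frame(locus_id = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE)
  pos <- 0L
  present <- 0L
  for (l in loci) {
    inds <- locus_individuals(l)
    if (!all(inds %in% taxa))
      stop("locus ", l$locus_id, " contains individuals not in taxa: ",
           paste(setdiff(inds, taxa), collapse = ", "))
    w <- locus_length(l)
    m[inds, (pos + 1L):(pos + w)] <- l$seqs
    spans <- rbind(spans, data.frame(locus_id = l$locus_id, start = pos,
                                     end = pos + w, stringsAsFactors = FALSE))
    present <- present + length(inds)
    pos <- pos + w
  }
  completeness <- if (length(loci) == 0L) {
    warning("no loci: completeness undefined, reported as 1.0")
    1.0
  } else present / (length(taxa) * length(loci))
  mean_ind <- if (length(loci) == 0L) NA_real_ else
    present / length(loci)
  all_n <- if (total > 0L)
    which(apply(m, 2L, function(col) all(is_missing_char(col)))) else integer(0)
  structure(list(matrix = m, locus_spans = spans,
                 completeness = completeness,
                 mean_individuals_per_locus = mean_ind,
                 all_n_columns = all_n),
            class = "rad_supermatrix")
}

#' @export
print.rad_supermatrix <- function(x, ...) {
  cat(sprintf("<rad_supermatrix> %d taxa x %d sites, %d loci, %.1f%% complete\n",
              nrow(x$matrix), ncol(x$matrix), nrow(x$locus_spans),
              100 * x$completeness))
  invisible(x)
}

#' Split a supermatrix back into its loci
#'
#' Inverse of [concatenate_loci()] up to taxa absent from a locus (rows that
#' are entirely 'N' within a span are dropped).
#'
#' @param sm A `rad_supermatrix`.
#' @return List of [rad_locus()].
#' @export
split_supermatrix <- function(sm) {
  lapply(seq_len(nrow(sm$locus_spans)), function(i) {
    sp <- sm$locus_spans[i, ]
    block <- sm$matrix[, (sp$start + 1L):sp$end, drop = FALSE]
    keep <- !apply(block, 1L, function(r) all(is_missing_char(r)))
    rad_locus(sp$locus_id, block[keep, , drop = FALSE])
  })
}

#' Locus presence-absence matrix
#'
#' @param loci List of [rad_locus()].
#' @param taxa Ordered taxa (default: union of individuals across loci).
#' @return Binary integer matrix, taxa x loci, dimnames set.
#' @export
presence_absence <- function(loci, taxa = NULL) {
  ids <- vapply(loci, function(l) l$locus_id, character(1))
  if (is.null(taxa))
    taxa <- sort(unique(unlist(lapply(loci, locus_individuals))))
  pa <- matrix(0L, length(taxa), length(loci), dimnames = list(taxa, ids))
  for (i in seq_along(loci))
    pa[intersect(locus_individuals(loci[[i]]), taxa), i] <- 1L
  pa
}

#' Jaccard distances from a presence-absence matrix
#'
#' `d(i,j) = 1 - shared / union` over scored loci; pairs sharing no scored
#' loci get distance 1 with a warning, and taxa with zero loci are flagged.
#'
#' @param pa Binary matrix, taxa x loci.
#' @return Symmetric numeric matrix with zero diagonal, values in `[0,1]`.
#' @export
jaccard_matrix <- function(pa) {
  if (nrow(pa) < 2L) stop("need at least 2 taxa")
  zero <- rowSums(pa) == 0L
  if (any(zero))
    warning("taxa with zero loci (distances set to 1): ",
            paste(rownames(pa)[zero], collapse = ", "))
  inter <- pa %*% t(pa)
  n <- diag(inter)
  uni <- outer(n, n, "+") - inter
  d <- 1 - ifelse(uni > 0, inter / uni, 0)
  if (any(uni == 0 & !diag(nrow(pa))))
    warning("taxon pair(s) sharing no scored loci: distance set to 1")
  d[uni == 0] <- 1
  diag(d) <- 0
  dimnames(d) <- list(rownames(pa), rownames(pa))
  d
}

#' Locus overlap report for technical-replicate pairs
#'
#' For each (A, B) pair reports the per-run locus counts, the relative
#' increase `(B - A) / A`, the shared (intersection) and total (union) locus
#' counts, and the overlap `shared / total` — the summary used to judge
#' combinability of sequencing runs.
#'
#' @param pa Binary presence-absence matrix, taxa x loci.
#' @param pairs List of 2-long character vectors `(taxonA, taxonB)`.
#' @return data.frame with columns `taxon_a`, `taxon_b`, `loci_a`, `loci_b`,
#'   `increase`, `shared`, `total`, `overlap`.
#' @export
replicate_overlap_report <- function(pa, pairs) {
  rows <- lapply(pairs, function(p) {
    if (!all(p %in% rownames(pa)))
      stop("unknown taxon in replicate pair: ",
           paste(setdiff(p, rownames(pa)), collapse = ", "))
    a <- pa[p[1L], ] > 0; b <- pa[p[2L], ] > 0
    na <- sum(a); nb <- sum(b)
    shared <- sum(a & b); total <- sum(a | b)
    data.frame(taxon_a = p[1L], taxon_b = p[2L], loci_a = na, loci_b = nb,
               increase = if (na > 0) (nb - na) / na else NA_real_,
               shared = shared, total = total,
               overlap = if (total > 0) shared / total else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a supermatrix and its locus-partition file
#'
#' The alignment goes out as relaxed Phylip; the partition file lists one
#' line per locus in the RAxML style `DNA, <locus_id> = <start>-<end>` with
#' 1-based inclusive coordinates (converted from the internal 0-based
#' half-open spans).
#'
#' @param sm A `rad_supermatrix`.
#' @param phylip_path Output alignment path.
#' @param partition_path Optional partition-file path.
#' @return `phylip_path`, invisibly.
#' @export
write_supermatrix <- function(sm, phylip_path, partition_path = NULL) {
  write_phylip(sm$matrix, phylip_path)
  if (!is.null(partition_path)) {
    writeLines(sprintf("DNA, %s = %d-%d", sm$locus_spans$locus_id,
                       sm$locus_spans$start + 1L, sm$locus_spans$end),
               partition_path)
  }
  invisible(phylip_path)
}
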