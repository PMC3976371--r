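#' Construct a RAD locus
#'
#' A locus is a short across-individual alignment: one consensus sequence per
#' individual, all the same aligned length (typically 50--99 bp for RAD data).
#' Sequences are stored uppercase as a character matrix with one column per
#' aligned position; rows are named by individual.
#'
#' @param locus_id Character scalar identifier.
#' @param seqs Either a named character vector of equal-length sequence strings
#'   or a character matrix (rows = individuals, columns = positions) with
#'   rownames.
#' @return An object of class `rad_locus` with elements `locus_id` and `seqs`
#'   (character matrix).
#' @examples
#' rad_locus("L1", c(a = "ACGT", b = "ACGA"))
#' @export
rad_locus <- function(locus_id, seqs) {
  if (is.matrix(seqs)) {
    m <- seqs
    m[] <- toupper(m)
  } else {
    m <- seqs_to_matrix(seqs)
  }
  if (is.null(rownames(m)) || anyNA(rownames(m)) || any(rownames(m) == ""))
    stop("locus ", locus_id, ": every row must be named by individual")
  if (anyDuplicated(rownames(m)))
    stop("locus ", locus_id, ": duplicate individual ",
         rownames(m)[duplicated(rownames(m))][1L])
  structure(list(locus_id = as.character(locus_id), seqs = m),
            class = "rad_locus")
}

#' @export
print.rad_locus <- function(x, ...) {
  cat("<rad_locus> ", x$locus_id, ": ", nrow(x$seqs), " individuals x ",
      ncol(x$seqs), " bp\n", sep = "")
  invisible(x)
}

#' Number of individuals in a locus
#' @param locus A `rad_locus`.
#' @return Integer count of rows.
#' @export
locus_n_individuals <- function(locus) nrow(locus$seqs)

#' Aligned length of a locus
#' @param locus A `rad_locus`.
#' @return Integer number of aligned columns.
#' @export
locus_length <- function(locus) ncol(locus$seqs)

#' Individuals present in a locus
#' @param locus A `rad_locus`.
#' @return Character vector of individual ids.
#' @export
locus_individuals <- function(locus) rownames(locus$seqs)

# Per-column census used by variable/PI counting: expands IUPAC two-fold codes
# into their constituent bases; 'N' and '-' are ignored.
#' @keywords internal
column_base_table <- function(col) {
  col <- col[!is_missing_char(col)]
  if (length(col) == 0L) return(integer(0))
  tab <- integer(4); names(tab) <- .bases
  for (ch in col) {
    st <- char_states(ch)
    if (length(st) <= 2L) tab[st] <- tab[st] + 1L
  }
  tab[tab > 0L]
}

#' Count variable and parsimony-informative sites in a locus
#'
#' A column is variable when, after expanding IUPAC two-fold codes into their
#' constituent bases, at least two distinct bases occur among non-missing
#' individuals; it is parsimony-informative when at least two bases are each
#' carried by two or more individuals. 'N' and '-' are ignored.
#'
#' @param locus A `rad_locus`.
#' @return List with integer elements `n_variable` and `n_pi`.
#' @export
locus_site_counts <- function(locus) {
  nv <- 0L; np <- 0L
  for (j in seq_len(ncol(locus$seqs))) {
    tab <- column_base_table(locus$seqs[, j])
    if (length(tab) >= 2L) {
      nv <- nv + 1L
      if (sum(tab >= 2L) >= 2L) np <- np + 1L
    }
  }
  list(n_variable = nv, n_pi = np)
}
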