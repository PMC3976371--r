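# Internal helpers shared across modules.

# IUPAC two-fold ambiguity codes for unordered heterozygote pairs, and the
# reverse map from code to its constituent bases.
.het_codes <- c(AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K")
.het_bases <- list(M = c("A", "C"), R = c("A", "G"), W = c("A", "T"),
                   S = c("C", "G"), Y = c("C", "T"), K = c("G", "T"))
.bases <- c("A", "C", "G", "T")

.revcomp_map <- c(A = "T", C = "G", G = "C", T = "A", N = "N", "-" = "-",
                  M = "K", R = "Y", W = "W", S = "S", Y = "R", K = "M")

#' @keywords internal
revcomp <- function(x) {
  stopifnot(is.character(x))
  vapply(x, function(s) {
    ch <- rev(strsplit(s, "", fixed = TRUE)[[1]])
    out <- .revcomp_map[ch]
    if (anyNA(out)) stop("cannot reverse-complement character(s): ",
                         paste(unique(ch[is.na(out)]), collapse = ", "))
    paste(out, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Split sequence strings into a character matrix (rows = sequences).
#' @keywords internal
seqs_to_matrix <- function(seqs) {
  if (length(seqs) == 0L) return(matrix(character(0), 0, 0))
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop("sequences have unequal lengths: ", paste(unique(lens), collapse = ", "))
  m <- matrix(toupper(unlist(strsplit(seqs, "", fixed = TRUE))),
              nrow = length(seqs), byrow = TRUE)
  rownames(m) <- names(seqs)
  m
}

#' @keywords internal
matrix_to_seqs <- function(m) {
  if (nrow(m) == 0L) return(stats::setNames(character(0), character(0)))
  stats::setNames(apply(m, 1L, paste, collapse = ""), rownames(m))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards.  All package-level randomness funnels
# through this so results are reproducible per seed without clobbering the
# session RNG.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Ungapped pairwise identity between two equal-length base vectors: matches /
# comparable sites, where a site is comparable when neither base is 'N' or '-'.
#' @keywords internal
ungapped_identity <- function(a, b) {
  ok <- a != "N" & b != "N" & a != "-" & b != "-"
  if (!any(ok)) return(0)
  sum(a[ok] == b[ok]) / sum(ok)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Expand one alignment character into the set of plain bases it is compatible
# with ('N'/'-'/'?' -> all four; IUPAC two-fold codes -> their pair).
#' @keywords internal
char_states <- function(ch) {
  if (ch %in% .bases) return(ch)
  if (ch %in% names(.het_bases)) return(.het_bases[[ch]])
  .bases
}

#' @keywords internal
is_missing_char <- function(x) x == "N" | x == "-" | x == "?"
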