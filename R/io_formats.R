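#' Construct a set of reads for one individual
#'
#' Holds equal-length nucleotide reads and their per-base Phred qualities for
#' one individual. Masked positions are 'N'.
#'
#' @param individual_id Label for the individual.
#' @param reads Character vector of reads over `{A,C,G,T,N}`, all equal length.
#' @param qualities Integer matrix (reads x positions) of Phred scores, or a
#'   list of integer vectors, one per read. May be `NULL` when qualities are
#'   unknown (e.g. simulated error-free reads).
#' @return An object of class `rad_readset`.
#' @export
rad_readset <- function(individual_id, reads, qualities = NULL) {
  reads <- unname(toupper(reads))
  lens <- unique(nchar(reads))
  if (length(lens) > 1L)
    stop("individual ", individual_id, ": reads of unequal length (",
         paste(lens, collapse = ", "), ")")
  if (!is.null(qualities)) {
    if (is.list(qualities)) {
      nq <- lengths(qualities)
      bad <- which(nq != nchar(reads))
      if (length(bad))
        stop("individual ", individual_id, ": read ", bad[1L],
             " has ", nq[bad[1L]], " quality scores for ",
             nchar(reads)[bad[1L]], " bases")
      qualities <- do.call(rbind, qualities)
    }
    if (length(reads) && (nrow(qualities) != length(reads) ||
                          ncol(qualities) != lens))
      stop("individual ", individual_id,
           ": quality matrix does not match read dimensions")
    storage.mode(qualities) <- "integer"
  }
  structure(list(individual_id = as.character(individual_id),
                 reads = reads, qualities = qualities),
            class = "rad_readset")
}

#' @export
print.rad_readset <- function(x, ...) {
  cat("<rad_readset> ", x$individual_id, ": ", length(x$reads), " reads",
      if (length(x$reads)) paste0(" x ", nchar(x$reads[1L]), " bp"), "\n",
      sep = "")
  invisible(x)
}

#' Read fixed-length reads from a FASTQ file
#'
#' Parses FASTQ via Biostrings and returns a [rad_readset()]. A fixed-width
#' prefix (barcode plus retained restriction-recognition bases) can be trimmed,
#' and reads can optionally be truncated to a common length. The Phred offset
#' is configurable (33 for Sanger/Illumina 1.8+, 64 for Illumina 1.3--1.7).
#'
#' @param path FASTQ file (optionally gzipped).
#' @param individual_id Label for the individual; defaults to the file name
#'   without extension.
#' @param trim_prefix Number of leading bases to drop (default 10: a 5-bp
#'   barcode plus 5 retained recognition bases).
#' @param truncate_to Optional read length to cut all reads down to after
#'   trimming; reads shorter than this are dropped.
#' @param phred_offset ASCII offset of the quality encoding (default 33).
#' @return A [rad_readset()].
#' @export
read_fastq_reads <- function(path, individual_id = NULL, trim_prefix = 10L,
                             truncate_to = NULL, phred_offset = 33L) {
  if (is.null(individual_id))
    individual_id <- sub("\\.(fastq|fq)(\\.gz)?$", "", basename(path))
  sr <- Biostrings::readDNAStringSet(path, format = "fastq",
                                     with.qualities = TRUE)
  reads <- as.character(sr)
  quals <- as.character(S4Vectors::mcols(sr)$qualities)
  if (length(reads) == 0L)
    return(rad_readset(individual_id, character(0), NULL))
  qint <- lapply(quals, function(q) as.integer(charToRaw(q)) - phred_offset)
  bad <- which(vapply(qint, function(v) any(v < 0L), logical(1)))
  if (length(bad))
    stop("FASTQ record ", bad[1L], " in ", path,
         ": quality below offset ", phred_offset,
         " (wrong --phred-offset?)")
  if (trim_prefix > 0L) {
    reads <- substring(reads, trim_prefix + 1L)
    qint <- lapply(qint, function(v) v[-seq_len(min(trim_prefix, length(v)))])
  }
  if (!is.null(truncate_to)) {
    keep <- nchar(reads) >= truncate_to
    reads <- substr(reads[keep], 1L, truncate_to)
    qint <- lapply(qint[keep], function(v) v[seq_len(truncate_to)])
  }
  lens <- nchar(reads)
  if (length(unique(lens)) > 1L)
    stop("FASTQ ", path, ": reads of unequal length after trimming; ",
         "pass truncate_to to enforce a common length")
  rad_readset(individual_id, reads, qint)
}

#' Write a read set as FASTQ
#'
#' @param readset A [rad_readset()]. When qualities are absent, a constant
#'   Phred 40 is written.
#' @param path Output file.
#' @param phred_offset ASCII offset (default 33).
#' @return `path`, invisibly.
#' @export
write_fastq_reads <- function(readset, path, phred_offset = 33L) {
  n <- length(readset$reads)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(n)) {
    q <- if (is.null(readset$qualities)) rep(40L, nchar(readset$reads[i]))
         else readset$qualities[i, ]
    writeLines(c(paste0("@", readset$individual_id, "_", i),
                 readset$reads[i], "+",
                 rawToChar(as.raw(q + phred_offset))), con)
  }
  invisible(path)
}

#' Mask low-quality bases and drop N-rich reads
#'
#' Every base with Phred quality below `phred_min` is replaced by 'N'; reads
#' whose post-masking fraction of N's exceeds `max_n_fraction` (strictly) are
#' dropped. Surviving reads keep their input order. Idempotent.
#'
#' @param readset A [rad_readset()] with qualities.
#' @param phred_min Minimum Phred score to keep a base (default 20).
#' @param max_n_fraction Maximum tolerated fraction of N's per read; reads with
#'   a strictly greater fraction are removed (default 0.05).
#' @return A masked [rad_readset()].
#' @export
mask_low_quality_reads <- function(readset, phred_min = 20L,
                                   max_n_fraction = 0.05) {
  if (length(readset$reads) == 0L) return(readset)
  if (is.null(readset$qualities))
    stop("individual ", readset$individual_id,
         ": cannot mask reads without qualities")
  m <- seqs_to_matrix(readset$reads)
  m[readset$qualities < phred_min] <- "N"
  nfrac <- rowMeans(m == "N")
  keep <- nfrac <= max_n_fraction
  rad_readset(readset$individual_id,
              unname(matrix_to_seqs(m))[keep],
              readset$qualities[keep, , drop = FALSE])
}

#' Parse a multi-locus ".loci" alignment file
#'
#' Reads the pipe-delimited ".loci" dialect: blocks of `taxon<space>sequence`
#' lines, each block terminated by a delimiter line starting with `//` and
#' carrying the locus index after a `|`. Sequences are uppercased; IUPAC
#' ambiguity codes and gaps are preserved.
#'
#' @param path Path to a .loci file.
#' @return List of [rad_locus()] objects.
#' @export
parse_loci_file <- function(path) {
  lines <- readLines(path)
  loci <- list()
  block <- character(0)
  taxa <- character(0)
  k <- 0L
  for (ln in lines) {
    if (!nzchar(trimws(ln))) next
    if (startsWith(ln, "//")) {
      k <- k + 1L
      id <- sub("^//[^|]*\\|", "", ln)
      id <- trimws(gsub("\\|", "", id))
      if (!nzchar(id)) id <- as.character(k)
      if (length(block) == 0L) stop("locus ", id, ": empty block")
      if (anyDuplicated(taxa))
        stop("locus ", id, ": duplicate taxon ",
             taxa[duplicated(taxa)][1L])
      if (length(unique(nchar(block))) != 1L)
        stop("locus ", id, ": ragged block (sequence lengths ",
             paste(unique(nchar(block)), collapse = ", "), ")")
      names(block) <- taxa
      loci[[length(loci) + 1L]] <- rad_locus(paste0("L", id), block)
      block <- character(0); taxa <- character(0)
    } else {
      parts <- strsplit(trimws(ln), "[ \t]+")[[1]]
      if (length(parts) != 2L)
        stop("malformed sequence line in ", path, ": ", ln)
      taxa <- c(taxa, sub("^>", "", parts[1L]))
      block <- c(block, toupper(parts[2L]))
    }
  }
  if (length(block))
    stop("trailing sequence block without a // delimiter in ", path)
  loci
}

#' Write loci in the ".loci" multi-locus alignment format
#'
#' @param loci List of [rad_locus()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_loci_file <- function(loci, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(loci)) {
    loc <- loci[[i]]
    seqs <- matrix_to_seqs(loc$seqs)
    w <- max(nchar(names(seqs))) + 2L
    writeLines(paste0(formatC(names(seqs), width = -w), seqs), con)
    writeLines(paste0("//", strrep(" ", max(1L, w - 2L)),
                      "|", sub("^L", "", loc$locus_id), "|"), con)
  }
  invisible(path)
}

#' Read a relaxed Phylip alignment
#'
#' Sequential relaxed Phylip: a header line `ntaxa nsites`, then one line per
#' taxon with whitespace-delimited name (up to 250 characters, no spaces) and
#' sequence. Missing cells are 'N'; gaps '-' are preserved verbatim.
#'
#' @param path Input file.
#' @return Character matrix (taxa x sites) with taxon rownames.
#' @export
read_phylip <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty Phylip file: ", path)
  hdr <- strsplit(trimws(lines[1L]), "[ \t]+")[[1]]
  if (length(hdr) != 2L || anyNA(suppressWarnings(as.integer(hdr))))
    stop("malformed Phylip header in ", path, ": ", lines[1L])
  ntax <- as.integer(hdr[1L]); nsite <- as.integer(hdr[2L])
  body <- lines[-1L]
  if (length(body) != ntax)
    stop("Phylip header in ", path, " claims ", ntax, " taxa but body has ",
         length(body))
  parts <- strsplit(trimws(body), "[ \t]+")
  bad <- which(lengths(parts) != 2L)
  if (length(bad))
    stop("malformed Phylip sequence line ", bad[1L] + 1L, " in ", path)
  nm <- vapply(parts, `[`, character(1), 1L)
  sq <- toupper(vapply(parts, `[`, character(1), 2L))
  if (any(nchar(sq) != nsite))
    stop("Phylip header in ", path, " claims ", nsite,
         " sites but sequence lengths are ",
         paste(unique(nchar(sq)), collapse = ", "))
  if (anyDuplicated(nm)) stop("duplicate taxon in ", path, ": ",
                              nm[duplicated(nm)][1L])
  names(sq) <- nm
  seqs_to_matrix(sq)
}

#' Write a relaxed Phylip alignment
#'
#' @param matrix Character matrix (taxa x sites) with taxon rownames, or a
#'   named character vector of equal-length sequences.
#' @param path Output file.
#' @return `path`, invisibly. [read_phylip()] of the written file reproduces
#'   taxon order, names, and sequences exactly.
#' @export
write_phylip <- function(matrix, path) {
  if (!is.matrix(matrix)) matrix <- seqs_to_matrix(matrix)
  seqs <- matrix_to_seqs(matrix)
  if (any(grepl("[ \t]", names(seqs))))
    stop("taxon names may not contain whitespace in relaxed Phylip")
  writeLines(c(paste(nrow(matrix), ncol(matrix)),
               paste(names(seqs), seqs)), path)
  invisible(path)
}

#' Parse a 12-column BLAST-tabular hit file
#'
#' Reads the standard `-outfmt 6` tab-separated dialect (query, subject,
#' identity, length, mismatches, gap opens, qstart, qend, sstart, send,
#' evalue, bitscore) and keeps hits with E-value strictly below `max_evalue`.
#'
#' @param path Input TSV. Lines starting with `#` are skipped.
#' @param max_evalue Retain rows with `evalue < max_evalue` (default `Inf`,
#'   i.e. keep everything).
#' @param database_tag Optional label recorded for all rows (e.g. which EST
#'   database was searched).
#' @return A data.frame of class `rad_hit_table` with columns `locus_id`,
#'   `target_id`, `evalue`, `database_tag`.
#' @export
parse_hit_table <- function(path, max_evalue = Inf, database_tag = NA_character_) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !startsWith(lines, "#")
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    out <- data.frame(locus_id = character(0), target_id = character(0),
                      evalue = numeric(0), database_tag = character(0),
                      stringsAsFactors = FALSE)
    class(out) <- c("rad_hit_table", "data.frame")
    return(out)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 12L)
  if (length(bad))
    stop("hit table ", path, " line ", lineno[bad[1L]],
         ": expected 12 tab-separated columns")
  ev <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1), 11L)))
  if (anyNA(ev))
    stop("hit table ", path, " line ", lineno[which(is.na(ev))[1L]],
         ": non-numeric E-value")
  if (any(ev < 0))
    stop("hit table ", path, " line ", lineno[which(ev < 0)[1L]],
         ": negative E-value")
  out <- data.frame(locus_id = vapply(parts, `[`, character(1), 1L),
                    target_id = vapply(parts, `[`, character(1), 2L),
                    evalue = ev,
                    database_tag = database_tag,
                    stringsAsFactors = FALSE)
  out <- out[out$evalue < max_evalue, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("rad_hit_table", "data.frame")
  out
}
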