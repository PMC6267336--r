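#' Genome-constitution statistics from a feature table
#'
#' Computes, per feature category, the number of bases (over the union of
#' that category's intervals) and the percent of the genome, rounded
#' half-even to 2 decimals.  The intergenic fraction is the complement of
#' the union of the three functional categories (`coding_exon`, `rRNA`,
#' `tRNA`); `plastid_derived` and `repeat` are overlays and do not reduce
#' it.
#'
#' @param features Feature `data.frame` with columns `type`, `start`,
#'   `end` (0-based half-open) -- the `$features` of a
#'   [circular_genome()] works directly (types `rRNA`/`tRNA` may appear as
#'   `rrna`/`trna`; matching is case-insensitive).
#' @param genome_length Genome length in bases (> 0).
#' @return `data.frame`: `category`, `bases`, `percent`, including an
#'   `intergenic` row.
#' @export
feature_fraction_stats <- function(features, genome_length) {
  stopifnot(genome_length > 0)
  if (nrow(features) && any(features$end > genome_length |
                            features$start < 0L)) {
    stop("feature interval outside [0, genome_length)")
  }
  cats <- c("coding_exon", "rRNA", "tRNA", "plastid_derived", "repeat",
            "other")
  type <- tolower(features$type)
  bases <- vapply(cats, function(cat) {
    sel <- type == tolower(cat)
    if (!any(sel)) return(0L)
    union_bases(features$start[sel], features$end[sel], genome_length)
  }, 0L)
  functional <- tolower(c("coding_exon", "rRNA", "tRNA"))
  fsel <- type %in% functional
  func_bases <- if (any(fsel)) {
    union_bases(features$start[fsel], features$end[fsel], genome_length)
  } else 0L
  out <- data.frame(category = c(cats, "intergenic"),
                    bases = c(bases, genome_length - func_bases),
                    stringsAsFactors = FALSE)
  out$percent <- round(100 * out$bases / genome_length, 2)
  out
}

#' Concatenate per-block alignments into a supermatrix
#'
#' Blocks (gene or collinear-block alignments) are concatenated
#' column-wise; taxa absent from a block are padded with gap characters.
#' Partition boundaries tile the matrix exactly.
#'
#' @param alignments Named list of alignments; each alignment is a named
#'   character vector (taxon -> aligned sequence, equal widths within a
#'   block).
#' @return A `Supermatrix`: list with `taxa`, `matrix` (named character
#'   vector of concatenated rows), `partitions` (`data.frame`: `block`,
#'   `start`, `end`, 0-based half-open columns).
#' @export
concatenate_supermatrix <- function(alignments) {
  stopifnot(length(alignments) >= 1L)
  if (is.null(names(alignments))) {
    names(alignments) <- paste0("block_", seq_along(alignments))
  }
  for (bn in names(alignments)) {
    a <- alignments[[bn]]
    if (anyDuplicated(names(a))) {
      stop("duplicate taxon within block '", bn, "'")
    }
    if (length(unique(nchar(a))) != 1L) {
      stop("ragged alignment in block '", bn, "'")
    }
  }
  taxa <- unique(unlist(lapply(alignments, names)))
  widths <- vapply(alignments, function(a) nchar(a[[1]]), 0L)
  ends <- cumsum(widths)
  rows <- stats::setNames(rep("", length(taxa)), taxa)
  for (bn in names(alignments)) {
    a <- alignments[[bn]]
    w <- nchar(a[[1]])
    pad <- strrep("-", w)
    rows <- paste0(rows, ifelse(taxa %in% names(a),
                                unname(a[taxa]), pad))
    names(rows) <- taxa
  }
  part <- data.frame(block = names(alignments),
                     start = c(0L, ends[-length(ends)]), end = ends,
                     stringsAsFactors = FALSE)
  stopifnot(part$end[length(ends)] == nchar(rows[[1]]))  # exact tiling
  structure(list(taxa = taxa, matrix = rows, partitions = part),
            class = "Supermatrix")
}

#' @export
print.Supermatrix <- function(x, ...) {
  cat(sprintf("Supermatrix: %d taxa x %d characters in %d partition(s)\n",
              length(x$taxa), nchar(x$matrix[[1]]), nrow(x$partitions)))
  invisible(x)
}

#' Write a supermatrix
#'
#' `write_supermatrix_fasta()` writes plain FASTA;
#' `write_supermatrix_phylip()` writes relaxed PHYLIP (name, space,
#' sequence); `write_partitions()` writes a RAxML-style partition file
#' (`DNA, name = start-end` in 1-based inclusive coordinates).
#'
#' @param sm A `Supermatrix`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_supermatrix_fasta <- function(sm, path) {
  write_fasta(sm$matrix, path)
}

#' @rdname write_supermatrix_fasta
#' @export
write_supermatrix_phylip <- function(sm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(" %d %d", length(sm$taxa), nchar(sm$matrix[[1]])), con)
  writeLines(paste(names(sm$matrix), sm$matrix), con)
  invisible(path)
}

#' @rdname write_supermatrix_fasta
#' @export
write_partitions <- function(sm, path) {
  writeLines(sprintf("DNA, %s = %d-%d", sm$partitions$block,
                     sm$partitions$start + 1L, sm$partitions$end), path)
  invisible(path)
}

#' Count parsimony-informative characters
#'
#' A column is parsimony-informative when at least two distinct states
#' (A, C, G, T only; gaps and ambiguity codes are not states) each occur
#' in at least two taxa.
#'
#' @param alignment Named character vector of equal-length aligned
#'   sequences, a `Supermatrix`, or a character matrix (rows = taxa).
#' @return List: `n_pic`, `n_columns`, `percent` (2 decimals,
#'   round-half-even).
#' @export
count_parsimony_informative <- function(alignment) {
  if (inherits(alignment, "Supermatrix")) alignment <- alignment$matrix
  if (is.matrix(alignment)) {
    mat <- toupper(alignment)
  } else {
    if (length(unique(nchar(alignment))) != 1L) {
      stop("ragged alignment: unequal row lengths")
    }
    mat <- do.call(rbind, strsplit(toupper(alignment), "", fixed = TRUE))
  }
  if (nrow(mat) < 4L) {
    warning("fewer than 4 rows; no column can be parsimony-informative ",
            "in a meaningful tree sense")
  }
  ncol_a <- ncol(mat)
  n_pic <- 0L
  for (j in seq_len(ncol_a)) {
    tab <- table(mat[, j])
    tab <- tab[names(tab) %in% DNA_BASES4]
    if (sum(tab >= 2L) >= 2L) n_pic <- n_pic + 1L
  }
  list(n_pic = n_pic, n_columns = ncol_a,
       percent = round(100 * n_pic / ncol_a, 2))
}

#' Percent helper used for printed headline numbers
#'
#' @param part,whole Numerator and denominator.
#' @return `100 * part / whole`, rounded half-even to 2 decimals.
#' @export
percent_of <- function(part, whole) {
  stopifnot(whole > 0)
  round(100 * part / whole, 2)
}
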