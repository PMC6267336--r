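#' @useDynLib mitorecomb, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import Biostrings
#' @import IRanges
NULL

DNA_BASES4 <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#'
#' @param x A single character string of DNA (IUPAC letters).
#' @return The reverse complement as a character string.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Extract a substring from a circular sequence
#'
#' Coordinates are 0-based and half-open throughout the package; `start` is
#' taken modulo the sequence length and the extracted window wraps around the
#' origin (and may wrap more than once when `len` exceeds the circle length,
#' as a long sequencing read on a small circle would).
#'
#' @param seq Character string (the circle).
#' @param start 0-based start position (any integer; reduced mod length).
#' @param len Number of bases to extract.
#' @return Character string of length `len`.
#' @export
circ_substr <- function(seq, start, len) {
  L <- nchar(seq)
  stopifnot(L > 0L, len >= 0L)
  if (len == 0L) return("")
  s <- ((start %% L) + L) %% L
  reps <- ceiling((s + len) / L)
  substr(strrep(seq, reps), s + 1L, s + len)
}

#' Rotate a circular sequence so that position `k` becomes the origin
#'
#' @param seq Character string.
#' @param k 0-based position of the new origin.
#' @return Rotated character string of the same length.
#' @export
rotate_seq <- function(seq, k) {
  circ_substr(seq, k, nchar(seq))
}

#' Test whether two circular sequences are the same circle
#'
#' Equality up to rotation and, optionally, up to reverse complement.
#'
#' @param a,b Character strings.
#' @param ignore_strand Also accept the reverse complement of `b`.
#' @return Logical scalar.
#' @export
same_circle <- function(a, b, ignore_strand = TRUE) {
  if (nchar(a) != nchar(b)) return(FALSE)
  if (grepl(b, strrep(a, 2L), fixed = TRUE)) return(TRUE)
  ignore_strand && grepl(revcomp(b), strrep(a, 2L), fixed = TRUE)
}

## Random sequence at a target GC; vectorised draw, used by every generator.
random_dna <- function(n, gc = 0.5) {
  if (n == 0L) return("")
  paste(sample(DNA_BASES4, n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' GC content of a sequence
#'
#' (G+C)/(A+C+G+T); ambiguity codes are excluded from the denominator.
#'
#' @param seq Character string or `Biostrings::DNAString`.
#' @param as_percent Return percent rounded to 2 decimals instead of a
#'   fraction (round-half-even, as all printed percentages in this package).
#' @return Numeric scalar.
#' @export
gc_content <- function(seq, as_percent = FALSE) {
  if (is.character(seq)) seq <- Biostrings::DNAString(seq)
  f <- Biostrings::letterFrequency(seq, letters = DNA_BASES4)
  tot <- sum(f)
  if (tot == 0) stop("sequence contains no unambiguous A/C/G/T bases")
  gc <- unname((f[["C"]] + f[["G"]]) / tot)
  if (as_percent) round(100 * gc, 2) else gc
}

#' Circular genome container
#'
#' A light S3 container for one circular genome: the sequence, an optional
#' feature table (0-based half-open intervals) and, for synthetic genomes,
#' the generator's ground truth.
#'
#' @param seq Character string (uppercase DNA).
#' @param id Genome identifier.
#' @param features `data.frame` with columns `feature_id`, `type`, `start`,
#'   `end`, `strand` (0-based half-open, strand `"+"`/`"-"`).
#' @param truth Arbitrary list of generator ground truth.
#' @return An object of class `CircularGenome`.
#' @export
circular_genome <- function(seq, id = "genome", features = empty_features(),
                            truth = list()) {
  stopifnot(is.character(seq), length(seq) == 1L, nchar(seq) > 0L)
  structure(list(seq = toupper(seq), id = id, length = nchar(seq),
                 features = features, truth = truth),
            class = "CircularGenome")
}

empty_features <- function() {
  data.frame(feature_id = character(), type = character(),
             start = integer(), end = integer(), strand = character(),
             stringsAsFactors = FALSE)
}

#' @export
print.CircularGenome <- function(x, ...) {
  cat(sprintf("CircularGenome '%s': %d bp, GC %.2f%%, %d feature(s)\n",
              x$id, x$length, 100 * gc_content(x$seq), nrow(x$features)))
  invisible(x)
}

#' @export
length.CircularGenome <- function(x) x$length

as_genome <- function(x) {
  if (inherits(x, "CircularGenome")) x else circular_genome(as.character(x))
}

## ---- interval helpers (0-based half-open, circular-aware) ----

## Split intervals that run past the origin into their two linear pieces,
## then return an IRanges (1-based closed, as IRanges requires).
circular_iranges <- function(start, end, L) {
  stopifnot(all(end > start))
  width <- pmin.int(end - start, L)
  start <- ((start %% L) + L) %% L
  end <- start + width
  wrap <- end > L
  s1 <- c(start, rep(0L, sum(wrap)))
  e1 <- c(pmin.int(end, L), (end[wrap] - L))
  IRanges::IRanges(start = s1 + 1L, end = e1)
}

## Total bases covered by the union of circular intervals.
union_bases <- function(start, end, L) {
  if (length(start) == 0L) return(0L)
  sum(IRanges::width(IRanges::reduce(circular_iranges(start, end, L))))
}

## ---- FASTA / FASTQ / GFF3 / TSV I/O ----

#' Read and write FASTA
#'
#' Thin wrappers over [Biostrings::readDNAStringSet()] /
#' [Biostrings::writeXStringSet()] returning plain named character vectors.
#'
#' @param path File path.
#' @param seqs Named character vector of sequences.
#' @return `read_fasta` returns a named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(unlist(seqs))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read and write FASTQ read sets
#'
#' Reads are held in a plain `data.frame` with columns `read_id`, `seq`,
#' `qual` plus any simulation-truth columns.  Truth columns are encoded as
#' `key=value` tokens after the read id on the FASTQ header line and are
#' recovered by `read_fastq()`.
#'
#' @param reads `data.frame` with at least `read_id`, `seq`, `qual`.
#' @param path File path.
#' @return `read_fastq` returns a reads `data.frame`.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("read_id", "seq", "qual") %in% names(reads)))
  extra <- setdiff(names(reads), c("read_id", "seq", "qual"))
  hdr <- reads$read_id
  for (k in extra) hdr <- paste0(hdr, " ", k, "=", reads[[k]])
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(reads) > 0L) {
    writeLines(paste0("@", hdr, "\n", reads$seq, "\n+\n", reads$qual), con)
  }
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) {
    return(data.frame(read_id = character(), seq = character(),
                      qual = character(), stringsAsFactors = FALSE))
  }
  if (length(lines) %% 4L != 0L) {
    stop("malformed FASTQ: ", length(lines), " lines is not a multiple of 4")
  }
  i <- seq(1L, length(lines), by = 4L)
  bad <- which(substr(lines[i], 1, 1) != "@")
  if (length(bad)) stop("malformed FASTQ record at index ", bad[1])
  hdr <- sub("^@", "", lines[i])
  seq <- lines[i + 1L]
  qual <- lines[i + 3L]
  if (any(nchar(seq) != nchar(qual))) {
    stop("malformed FASTQ record at index ",
         which(nchar(seq) != nchar(qual))[1], ": seq/qual length mismatch")
  }
  toks <- strsplit(hdr, " ", fixed = TRUE)
  out <- data.frame(read_id = vapply(toks, `[`, "", 1L), seq = seq,
                    qual = qual, stringsAsFactors = FALSE)
  kv <- lapply(toks, function(t) t[-1][grepl("=", t[-1], fixed = TRUE)])
  keys <- unique(sub("=.*$", "", unlist(kv)))
  for (k in keys) {
    out[[k]] <- vapply(kv, function(t) {
      hit <- grep(paste0("^", k, "="), t, value = TRUE)
      if (length(hit)) sub("^[^=]*=", "", hit[1]) else NA_character_
    }, "")
  }
  out
}

#' Write a feature table as GFF3
#'
#' Internal 0-based half-open intervals are converted to the 1-based closed
#' convention of GFF3.
#'
#' @param features Feature `data.frame` (see [circular_genome()]).
#' @param path File path.
#' @param seqid Sequence name for column 1.
#' @return `read_gff3` returns a feature `data.frame` in package convention.
#' @export
write_gff3 <- function(features, path, seqid = "genome") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(features) > 0L) {
    writeLines(paste(seqid, "mitorecomb", features$type,
                     features$start + 1L, features$end, ".",
                     features$strand, ".",
                     paste0("ID=", features$feature_id), sep = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_gff3
#' @export
read_gff3 <- function(path) {
  lines <- grep("^#", readLines(path), invert = TRUE, value = TRUE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(empty_features())
  f <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
  data.frame(feature_id = sub("^ID=", "", sub(";.*$", "", f[, 9])),
             type = f[, 3], start = as.integer(f[, 4]) - 1L,
             end = as.integer(f[, 5]), strand = f[, 7],
             stringsAsFactors = FALSE)
}

## Mean Phred quality of a quality string (Phred+33, arithmetic mean).
mean_phred <- function(qual) {
  vapply(qual, function(q) {
    if (!nchar(q)) return(NA_real_)
    mean(as.integer(charToRaw(q)) - 33L)
  }, 0, USE.NAMES = FALSE)
}

## Phred+33 quality string from integer qualities.
phred_string <- function(q) {
  rawToChar(as.raw(pmin.int(pmax.int(as.integer(round(q)), 0L), 60L) + 33L))
}
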