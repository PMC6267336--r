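#' @title Dispersed repeat detection on circular genomes
#' @description
#' `find_repeats()` detects dispersed repeat pairs (direct and inverted) on
#' a circular genome by exact k-mer seeding on the doubled sequence,
#' grouping of seeds by diagonal, and extension along each seeded diagonal
#' to the maximal gapless window whose identity stays at or above the
#' threshold.  Identity is matches / alignment columns.  Tandem hits
#' (copies closer than their own length) and self-overlapping hits are
#' excluded; hits sharing more than half of both copy intervals are merged,
#' keeping the longest.
#' @name repeat_finder
NULL

empty_repeat_pairs <- function() {
  data.frame(id = character(), start1 = integer(), end1 = integer(),
             start2 = integer(), end2 = integer(), orientation = character(),
             length = integer(), identity = numeric(),
             stringsAsFactors = FALSE)
}

## Positions (0-based) of shared k-mers between two strings, as a list of
## seed pairs grouped by diagonal d = pos2 - pos1.  K-mers occurring more
## than `max_occ` times in either string are skipped (low-complexity guard).
seed_diagonals <- function(s1, s2, k = 21L, max_occ = 64L,
                           self = identical(s1, s2)) {
  n1 <- nchar(s1); n2 <- nchar(s2)
  if (n1 < k || n2 < k) return(integer())
  km1 <- substring(s1, 1:(n1 - k + 1L), k:n1)
  km2 <- if (self) km1 else substring(s2, 1:(n2 - k + 1L), k:n2)
  if (self) {
    tab <- table(km1)
    shared <- names(tab)[tab >= 2L & tab <= max_occ]
  } else {
    shared <- intersect(km1, km2)
    if (length(shared)) {
      c1 <- table(km1[km1 %in% shared]); c2 <- table(km2[km2 %in% shared])
      shared <- shared[c1[shared] <= max_occ & c2[shared] <= max_occ]
    }
  }
  if (!length(shared)) return(integer())
  p1 <- split(which(km1 %in% shared) - 1L, km1[km1 %in% shared])
  p2 <- if (self) p1 else split(which(km2 %in% shared) - 1L,
                                km2[km2 %in% shared])
  diags <- integer()
  for (kmer in names(p1)) {
    a <- p1[[kmer]]; b <- p2[[kmer]]
    d <- as.vector(outer(b, a, "-"))
    diags <- c(diags, d)
  }
  unique(diags[diags != 0L | !self])
}

## Maximal-scoring segments with identity >= t and length >= min_len along
## one diagonal.  `m` is the logical match vector.  Each run of >= min_core
## consecutive matches is a core; cores are extended in both directions by
## X-drop on a +1/-1 match/mismatch score (the extension stops once the
## running score falls `xdrop` below its maximum, and the segment ends at
## the score maximum).  This reports the high-identity core of a repeat
## rather than a threshold-identity window padded with mismatching flank.
## Returns a data.frame of 0-based half-open [a, b) offsets with match
## counts, or NULL.
diagonal_segments <- function(m, t, min_len, min_core = 15L, xdrop = 25L) {
  n <- length(m)
  if (n < min_len) return(NULL)
  r <- rle(m)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cores <- which(r$values & r$lengths >= min_core)
  if (!length(cores)) return(NULL)
  cs0 <- c(0L, cumsum(ifelse(m, 1L, -1L)))  # cs0[i+1] = prefix score
  seg_a <- integer(); seg_b <- integer()
  for (ci in cores) {
    a <- starts[ci]; b <- ends[ci]          # 1-based inclusive core
    ## right: maximise cs0[j+1], stop after dropping xdrop below the max
    j <- b; best <- cs0[b + 1L]; bj <- b
    while (j < n) {
      j <- j + 1L
      if (cs0[j + 1L] > best) { best <- cs0[j + 1L]; bj <- j }
      if (best - cs0[j + 1L] > xdrop) break
    }
    ## left: minimise cs0[i], same X-drop rule
    i <- a; low <- cs0[a]; ai <- a
    while (i > 1L) {
      i <- i - 1L
      if (cs0[i] < low) { low <- cs0[i]; ai <- i }
      if (cs0[i] - low > xdrop) break
    }
    seg_a <- c(seg_a, ai); seg_b <- c(seg_b, bj)
  }
  segs <- IRanges::reduce(IRanges::IRanges(seg_a, seg_b))
  a <- IRanges::start(segs) - 1L            # back to 0-based half-open
  b <- IRanges::end(segs)
  cm <- cumsum(c(0L, m))
  matches <- cm[b + 1L] - cm[a + 1L]
  len <- b - a
  keep <- len >= min_len & matches / len >= t
  if (!any(keep)) return(NULL)
  data.frame(a = a[keep], b = b[keep], matches = matches[keep])
}

## All maximal gapless high-identity matches between two strings (linear,
## 0-based half-open coordinates in each).
pairwise_gapless_hits <- function(s1, s2, min_len, min_identity, k = 21L,
                                  self = identical(s1, s2)) {
  diags <- seed_diagonals(s1, s2, k = k, self = self)
  n1 <- nchar(s1); n2 <- nchar(s2)
  r1 <- charToRaw(s1); r2 <- charToRaw(s2)
  out <- list()
  for (d in diags) {
    i0 <- max(0L, -d)                       # 0-based start in s1
    i1 <- min(n1, n2 - d)                   # 0-based end (exclusive) in s1
    if (i1 - i0 < min_len) next
    m <- r1[(i0 + 1L):i1] == r2[(i0 + d + 1L):(i1 + d)]
    w <- diagonal_segments(m, min_identity, min_len)
    if (is.null(w)) next
    out[[length(out) + 1L]] <- data.frame(
      s1_start = i0 + w$a, s1_end = i0 + w$b,
      s2_start = i0 + d + w$a, s2_end = i0 + d + w$b,
      matches = w$matches)
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

#' Find dispersed repeats on a circular genome
#'
#' @param genome A [circular_genome()] or character sequence.
#' @param min_len Minimum alignment length in bases (default 50, the
#'   conventional lower bound for recombination-capable repeats).
#' @param min_identity Minimum identity fraction (default 0.95).
#' @param k Seed k-mer length.
#' @return `RepeatPair` table: one row per pair with columns `id`,
#'   `start1`, `end1`, `start2`, `end2` (0-based half-open, circular),
#'   `orientation`, `length`, `identity`, sorted by length descending.
#'   Non-ACGT characters never match (mismatch-only treatment).
#' @export
find_repeats <- function(genome, min_len = 50L, min_identity = 0.95,
                         k = 21L) {
  genome <- as_genome(genome)
  if (genome$length == 0L) stop("empty sequence")
  if (genome$length < 2L * min_len) {
    stop("genome length ", genome$length, " is shorter than 2 * min_len")
  }
  L <- genome$length
  D <- strrep(genome$seq, 2L)

  hits <- list()
  fwd <- pairwise_gapless_hits(D, D, min_len, min_identity, k = k,
                               self = TRUE)
  if (!is.null(fwd)) {
    fwd$orientation <- "direct"
    hits[[1]] <- fwd
  }
  R <- revcomp(D)
  inv <- pairwise_gapless_hits(D, R, min_len, min_identity, k = k,
                               self = FALSE)
  if (!is.null(inv)) {
    ## map copy2 from revcomp coordinates back onto D
    tmp <- inv$s2_start
    inv$s2_start <- 2L * L - inv$s2_end
    inv$s2_end <- 2L * L - tmp
    inv$orientation <- "inverted"
    hits[[2]] <- inv
  }
  if (!length(hits)) return(empty_repeat_pairs())
  h <- do.call(rbind, hits)
  h$length <- h$s1_end - h$s1_start
  h <- h[h$length <= L, , drop = FALSE]

  ## canonicalise to circle coordinates: put the lower copy start first
  a1 <- h$s1_start %% L
  a2 <- h$s2_start %% L
  swap <- a2 < a1
  t1 <- ifelse(swap, a2, a1); t2 <- ifelse(swap, a1, a2)
  h$start1 <- t1; h$end1 <- t1 + h$length
  h$start2 <- t2; h$end2 <- t2 + h$length
  ## drop self hits, overlapping copies and tandem arrangements: the
  ## circular gap between the copies must be at least the repeat length
  gap_fwd <- h$start2 - h$start1
  dist <- pmin(gap_fwd, L - gap_fwd)          # circular start distance
  keep <- dist >= 2L * h$length
  h <- h[keep, , drop = FALSE]
  if (!nrow(h)) return(empty_repeat_pairs())
  h$identity <- h$matches / h$length

  ## de-duplicate (each pair is seen from both copies and both genome
  ## copies of the doubled sequence); then merge near-duplicates sharing
  ## >50% of both copy intervals, keeping the longest
  h <- h[order(-h$length, h$start1, h$start2), , drop = FALSE]
  key <- paste(h$start1, h$start2, h$length, h$orientation)
  h <- h[!duplicated(key), , drop = FALSE]
  kept <- rep(TRUE, nrow(h))
  ov <- function(s1, e1, s2, e2) {
    pmax(0L, pmin(e1, e2) - pmax(s1, s2))
  }
  for (i in seq_len(nrow(h))) {
    if (!kept[i]) next
    if (i == nrow(h)) break
    j <- (i + 1L):nrow(h)
    same <- h$orientation[j] == h$orientation[i]
    o1 <- ov(h$start1[j], h$end1[j], h$start1[i], h$end1[i])
    o2 <- ov(h$start2[j], h$end2[j], h$start2[i], h$end2[i])
    dup <- same & o1 > 0.5 * h$length[j] & o2 > 0.5 * h$length[j]
    kept[j][dup] <- FALSE
  }
  h <- h[kept, , drop = FALSE]
  h$id <- paste0("r", seq_len(nrow(h)))
  rownames(h) <- NULL
  h[, c("id", "start1", "end1", "start2", "end2", "orientation",
        "length", "identity")]
}

#' Repeat size-class statistics
#'
#' Classifies repeat pairs by alignment length into small (< 100 bp),
#' intermediate (100--1000 bp) and large (> 1 kb) classes and reports, per
#' class and in total, the fraction of the genome covered by the union of
#' all repeat copy intervals (overlaps counted once).
#'
#' @param pairs `RepeatPair` table from [find_repeats()].
#' @param genome_length Genome length in bases.
#' @return List with `n_repeats`, `total_repeat_bases`, `class_counts`,
#'   `class_bases`, `class_percent` (percent of genome, 2 decimals) and
#'   `total_percent`.
#' @export
classify_repeats <- function(pairs, genome_length) {
  stopifnot(genome_length > 0)
  cls <- c("small", "intermediate", "large")
  assign_class <- function(len) {
    ifelse(len < 100L, "small", ifelse(len <= 1000L, "intermediate", "large"))
  }
  counts <- stats::setNames(integer(3), cls)
  bases <- stats::setNames(integer(3), cls)
  if (nrow(pairs)) {
    pcls <- assign_class(pairs$length)
    for (cl in cls) {
      sel <- pcls == cl
      counts[cl] <- sum(sel)
      if (any(sel)) {
        p <- pairs[sel, , drop = FALSE]
        bases[cl] <- union_bases(c(p$start1, p$start2), c(p$end1, p$end2),
                                 genome_length)
      }
    }
  }
  total_bases <- if (nrow(pairs)) {
    union_bases(c(pairs$start1, pairs$start2), c(pairs$end1, pairs$end2),
                genome_length)
  } else 0L
  list(n_repeats = nrow(pairs), total_repeat_bases = total_bases,
       class_counts = counts, class_bases = bases,
       class_percent = round(100 * bases / genome_length, 2),
       total_percent = round(100 * total_bases / genome_length, 2))
}

#' Fraction of the genome covered by repeats
#'
#' Union of all repeat copy intervals divided by genome length, as percent
#' rounded to 2 decimals (capped at 100).
#'
#' @inheritParams classify_repeats
#' @return Numeric scalar (percent).
#' @export
repeat_fraction <- function(pairs, genome_length) {
  stopifnot(genome_length > 0)
  if (!nrow(pairs)) return(0)
  b <- union_bases(c(pairs$start1, pairs$start2), c(pairs$end1, pairs$end2),
                   genome_length)
  round(100 * min(b, genome_length) / genome_length, 2)
}
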