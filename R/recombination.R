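#' Filter long reads by length and mean quality
#'
#' Keeps reads with length >= `min_len` and arithmetic mean Phred quality
#' >= `min_q` (both boundaries inclusive), the standard pre-filter for ONT
#' data before structural analysis.
#'
#' @param reads Reads `data.frame` (`read_id`, `seq`, `qual`) or a FASTQ
#'   path.
#' @param min_len Minimum read length in bases.
#' @param min_q Minimum mean Phred quality.
#' @return Filtered reads `data.frame`.
#' @export
filter_long_reads <- function(reads, min_len = 500L, min_q = 7) {
  if (is.character(reads) && length(reads) == 1L) reads <- read_fastq(reads)
  if (nrow(reads) == 0L) return(reads)
  keep <- nchar(reads$seq) >= min_len & mean_phred(reads$qual) >= min_q
  reads[keep, , drop = FALSE]
}

.pdict_cache <- new.env(parent = emptyenv())

## PDict preprocessing is expensive for long patterns; junction windows are
## reused across many classify calls, so memoise per pattern set.
cached_pdict <- function(pats) {
  key <- paste(pats, collapse = "|")
  hit <- get0(key, envir = .pdict_cache, inherits = FALSE)
  if (!is.null(hit)) return(hit)
  if (length(ls(.pdict_cache)) > 32L) {
    rm(list = ls(.pdict_cache), envir = .pdict_cache)
  }
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(pats))
  assign(key, pd, envir = .pdict_cache)
  pd
}

## k-mer anchor of `pattern` inside `read`: modal diagonal offset of exact
## shared k-mers, or NA when fewer than `min_hits` consistent seeds exist.
anchor_offset <- function(pattern, read_kmers, k, min_hits = 3L,
                          tol = 60L) {
  np <- nchar(pattern)
  if (np < k) return(NA_integer_)
  at <- seq(1L, np - k + 1L, by = max(1L, k %/% 2L))
  pk <- substring(pattern, at, at + k - 1L)
  hit <- match(pk, read_kmers$kmer)
  ok <- !is.na(hit)
  if (sum(ok) < min_hits) return(NA_integer_)
  ## a k-mer may occur at several read positions; use the first occurrence
  offs <- read_kmers$pos[hit[ok]] - (at[ok] - 1L)
  dens <- sort(offs)
  ## largest cluster of offsets within +/- tol
  best <- 0L; best_off <- NA_integer_
  for (i in seq_along(dens)) {
    n_in <- sum(dens >= dens[i] - tol & dens <= dens[i] + tol)
    if (n_in > best) {
      best <- n_in
      best_off <- as.integer(stats::median(
        dens[dens >= dens[i] - tol & dens <= dens[i] + tol]))
    }
  }
  if (best < min_hits) NA_integer_ else best_off
}

read_kmer_index <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(list(kmer = character(), pos = integer()))
  km <- substring(seq, 1:(n - k + 1L), k:n)
  first <- !duplicated(km)
  list(kmer = km[first], pos = which(first) - 1L)
}

## Align one junction window inside one read orientation; returns a score
## row or NULL.  Exact containment short-circuits the aligner.
align_window_in_read <- function(wseq, rseq, rkidx, min_identity, k = 13L) {
  wlen <- nchar(wseq); rlen <- nchar(rseq)
  if (wlen > rlen) return(NULL)
  hit <- regexpr(wseq, rseq, fixed = TRUE)
  if (hit > 0L) {
    return(list(score = wlen, identity = 1))
  }
  off <- anchor_offset(wseq, rkidx, k)
  if (is.na(off)) return(NULL)
  slack <- max(20L, round(0.08 * wlen))
  if (off < -slack || off + wlen > rlen + slack) return(NULL)  # not end-to-end
  pad <- max(30L, round(0.1 * wlen))
  s0 <- max(0L, off - pad)
  s1 <- min(rlen, off + wlen + pad)
  seg <- substr(rseq, s0 + 1L, s1)
  if (nchar(seg) < wlen * (1 - 0.1)) return(NULL)
  a <- banded_glocal(wseq, seg, band = pad + 40L)
  identity <- a$matches / a$aln_len
  if (identity < min_identity) return(NULL)
  list(score = a$score, identity = identity)
}

#' Classify long reads as supporting the master or alternative conformation
#'
#' Each read is compared, on both strands, against the four junction
#' windows of one repeat pair (see [extract_junctions()]).  A read is
#' informative only if at least one window aligns end-to-end *within* the
#' read at identity >= `min_identity` -- i.e. the read spans the full
#' repeat copy plus both flank anchors.  Exact window containment is tested
#' first (the common case for error-free reads); otherwise the window is
#' anchored by shared k-mers and aligned with a banded affine aligner.
#' The read is labelled by the higher-scoring side (MC vs AC); ties and
#' unalignable reads are uninformative.
#'
#' @param reads Reads `data.frame` (or FASTQ path).
#' @param junctions The 4 junction windows of one repeat, from
#'   [extract_junctions()].
#' @param min_identity Minimum alignment identity for an informative label
#'   (default 0.75, permissive enough for ONT error rates).
#' @return `ReadSupport` `data.frame`: `read_id`, `repeat_id`, `label`
#'   (`"MC"`/`"AC"`/`"uninformative"`), `score_mc`, `score_ac`, `identity`.
#' @export
classify_reads <- function(reads, junctions, min_identity = 0.75) {
  if (is.character(reads) && length(reads) == 1L) reads <- read_fastq(reads)
  stopifnot(all(c("MC-J1", "MC-J2", "AC-J1", "AC-J2") %in% names(junctions)))
  rid <- junctions[[1]]$repeat_id
  n <- nrow(reads)
  out <- data.frame(read_id = reads$read_id,
                    repeat_id = rep(rid, n),
                    label = rep("uninformative", n),
                    score_mc = rep(NA_real_, n), score_ac = rep(NA_real_, n),
                    identity = rep(NA_real_, n), stringsAsFactors = FALSE)
  if (n == 0L) return(out)
  wseq <- vapply(junctions, `[[`, "", "seq")
  is_mc <- grepl("^MC", names(wseq))
  pats <- c(wseq, vapply(wseq, revcomp, ""))
  pat_mc <- c(is_mc, is_mc)

  ## fast path: exact containment of any window, vectorised across reads
  ## (all patterns share one width, so one Aho-Corasick pass suffices; the
  ## PDict preprocessing is cached since junctions are reused across calls)
  subj <- Biostrings::DNAStringSet(reads$seq)
  rlen_max <- max(nchar(reads$seq))
  exact <- matrix(FALSE, n, length(pats))
  if (min(nchar(pats)) <= rlen_max) {
    long_enough <- nchar(reads$seq) >= max(nchar(pats))
    if (any(long_enough)) {
      pd <- cached_pdict(unname(pats))
      exact[long_enough, ] <-
        t(Biostrings::vcountPDict(pd, subj[long_enough]) > 0L)
    }
  }
  wlen <- nchar(pats)
  mc_best <- rep(-Inf, n); ac_best <- rep(-Inf, n)
  for (j in which(pat_mc)) mc_best[exact[, j]] <- pmax(mc_best[exact[, j]],
                                                       wlen[j])
  for (j in which(!pat_mc)) ac_best[exact[, j]] <- pmax(ac_best[exact[, j]],
                                                        wlen[j])
  id_mc <- ifelse(is.finite(mc_best), 1, NA_real_)
  id_ac <- ifelse(is.finite(ac_best), 1, NA_real_)

  ## pre-screen for the alignment path: a read without an exact hit is only
  ## worth aligning if both edge 13-mers of some window (same orientation)
  ## occur in it -- a cheap necessary condition for spanning that window
  ## end-to-end, and one that error-free reads can only meet by truly
  ## spanning it
  need <- which(!is.finite(mc_best) & !is.finite(ac_best))
  if (length(need)) {
    pk <- 13L
    probes <- c(substr(pats, 1L, pk),
                substr(pats, wlen - pk + 1L, wlen))
    pdp <- cached_pdict(unname(probes))
    ph <- t(Biostrings::vcountPDict(pdp, subj[need]) > 0L)
    k8 <- length(pats)
    cand_need <- rowSums(ph[, 1:k8, drop = FALSE] &
                         ph[, k8 + (1:k8), drop = FALSE]) > 0L
    for (i in need[cand_need]) {
      rseq_f <- reads$seq[i]
      rseq_r <- revcomp(rseq_f)
      for (rseq in c(rseq_f, rseq_r)) {
        rki <- read_kmer_index(rseq, 13L)
        for (j in seq_along(wseq)) {
          a <- align_window_in_read(wseq[j], rseq, rki, min_identity)
          if (is.null(a)) next
          if (is_mc[j] && a$score > mc_best[i]) {
            mc_best[i] <- a$score; id_mc[i] <- a$identity
          }
          if (!is_mc[j] && a$score > ac_best[i]) {
            ac_best[i] <- a$score; id_ac[i] <- a$identity
          }
        }
      }
    }
  }

  any_hit <- is.finite(mc_best) | is.finite(ac_best)
  out$score_mc[any_hit] <- ifelse(is.finite(mc_best[any_hit]),
                                  mc_best[any_hit], NA_real_)
  out$score_ac[any_hit] <- ifelse(is.finite(ac_best[any_hit]),
                                  ac_best[any_hit], NA_real_)
  mc_lab <- is.finite(mc_best) & (!is.finite(ac_best) | mc_best > ac_best)
  ac_lab <- is.finite(ac_best) & (!is.finite(mc_best) | ac_best > mc_best)
  out$label[mc_lab] <- "MC"
  out$label[ac_lab] <- "AC"
  out$identity[mc_lab] <- id_mc[mc_lab]
  out$identity[ac_lab] <- id_ac[ac_lab]
  out
}

#' @rdname classify_reads
#' @param read A single-row reads `data.frame` (or list with `read_id`,
#'   `seq`).
#' @export
classify_read <- function(read, junctions, min_identity = 0.75) {
  df <- as.data.frame(read, stringsAsFactors = FALSE)
  classify_reads(df, junctions, min_identity = min_identity)
}

#' Estimate the recombination frequency at one repeat
#'
#' Frequency = n_AC / (n_MC + n_AC) over informative reads, with a 95%
#' confidence interval: exact (Clopper-Pearson) when fewer than 30
#' informative reads, otherwise a normal approximation with continuity
#' correction.  With no informative reads the estimate is flagged
#' undefined rather than raising an error.
#'
#' @param supports `ReadSupport` `data.frame` for one repeat (from
#'   [classify_reads()]).
#' @return `FrequencyEstimate` list: `repeat_id`, `n_mc`, `n_ac`,
#'   `frequency`, `ci_lower`, `ci_upper`, `defined`.
#' @export
estimate_frequency <- function(supports) {
  rid <- unique(supports$repeat_id)
  if (length(rid) > 1L) {
    stop("supports mix several repeats: ", paste(rid, collapse = ", "))
  }
  if (length(rid) == 0L) rid <- NA_character_
  n_mc <- sum(supports$label == "MC")
  n_ac <- sum(supports$label == "AC")
  n <- n_mc + n_ac
  if (n == 0L) {
    return(list(repeat_id = rid, n_mc = 0L, n_ac = 0L,
                frequency = NA_real_, ci_lower = NA_real_,
                ci_upper = NA_real_, defined = FALSE))
  }
  p <- n_ac / n
  if (n < 30L) {
    ci <- as.numeric(stats::binom.test(n_ac, n)$conf.int)
  } else {
    half <- 1.959964 * sqrt(p * (1 - p) / n) + 0.5 / n
    ci <- c(max(0, p - half), min(1, p + half))
  }
  list(repeat_id = rid, n_mc = n_mc, n_ac = n_ac, frequency = p,
       ci_lower = ci[1], ci_upper = ci[2], defined = TRUE)
}

#' Correlate recombination frequency with repeat length
#'
#' @param estimates List of `FrequencyEstimate`s (defined ones are used).
#' @param lengths Numeric vector of repeat lengths, parallel to
#'   `estimates`.
#' @return List with `n`, `pearson_r`, `spearman_rho`; coefficients are
#'   `NA` (with a warning) when the frequencies have zero variance.
#' @export
correlate_length_frequency <- function(estimates, lengths) {
  stopifnot(length(estimates) == length(lengths))
  ok <- vapply(estimates, `[[`, TRUE, "defined")
  f <- vapply(estimates, `[[`, 0, "frequency")[ok]
  l <- lengths[ok]
  if (length(f) < 3L) {
    stop("need >= 3 repeats with defined frequency estimates, have ",
         length(f))
  }
  if (stats::sd(f) == 0 || stats::sd(l) == 0) {
    warning("zero variance in frequencies or lengths; correlation undefined")
    return(list(n = length(f), pearson_r = NA_real_,
                spearman_rho = NA_real_))
  }
  list(n = length(f),
       pearson_r = stats::cor(l, f, method = "pearson"),
       spearman_rho = stats::cor(l, f, method = "spearman"))
}

## Place one read on the master circle by exact k-mer probes; returns
## 0-based start or NA.  `D` is the doubled genome string.
place_read_mc <- function(rseq, D, L, k = 31L, min_probes = 3L,
                          min_span = 0.9) {
  rlen <- nchar(rseq)
  if (rlen < k) return(NA_integer_)
  for (orient in 1:2) {
    s <- if (orient == 1L) rseq else revcomp(rseq)
    at <- unique(pmax(1L, round(seq(1L, rlen - k + 1L, length.out = 9L))))
    probes <- substring(s, at, at + k - 1L)
    starts <- integer(); offs <- integer()
    for (pi in seq_along(probes)) {
      m <- Biostrings::matchPattern(probes[pi], D)
      if (length(m) == 0L || length(m) > 8L) next
      g <- Biostrings::start(m) - 1L
      starts <- c(starts, (g - (at[pi] - 1L)) %% L)
      offs <- c(offs, rep(at[pi] - 1L, length(g)))
    }
    if (length(starts) < min_probes) next
    tol <- max(60L, round(0.15 * rlen))
    tabs <- sort(starts)
    best_n <- 0L; best_s <- NA_integer_
    for (v in unique(tabs)) {
      inwin <- (starts - v) %% L <= tol | (v - starts) %% L <= tol
      if (sum(inwin) > best_n) { best_n <- sum(inwin); best_s <- v }
    }
    if (best_n < min_probes) next
    inwin <- (starts - best_s) %% L <= tol | (best_s - starts) %% L <= tol
    span <- diff(range(offs[inwin])) + k
    if (span < min_span * rlen) next
    return(best_s)
  }
  NA_integer_
}

#' Minimal set of master-conformation reads tiling the circle
#'
#' Places each read on the master circle (exact k-mer probes, both
#' strands; a read is MC-consistent when one collinear placement covers at
#' least `min_span` of its length), then solves the minimal circular
#' interval cover exactly with the standard greedy-from-each-start
#' algorithm.  When the placed reads leave part of the circle uncovered the
#' result is flagged infeasible and the uncovered intervals are reported.
#'
#' @param reads Reads `data.frame` (or FASTQ path).
#' @param genome A [circular_genome()].
#' @param min_span Minimum fraction of the read that the placement must
#'   cover.
#' @return List: `feasible`, `count`, `read_ids`, `n_placed`, `gaps`
#'   (`data.frame` of uncovered 0-based half-open intervals when
#'   infeasible).
#' @export
find_master_tiling <- function(reads, genome, min_span = 0.9) {
  if (is.character(reads) && length(reads) == 1L) reads <- read_fastq(reads)
  genome <- as_genome(genome)
  L <- genome$length
  D <- strrep(genome$seq, 2L)
  starts <- integer(); lens <- integer(); ids <- character()
  for (i in seq_len(nrow(reads))) {
    s <- place_read_mc(reads$seq[i], D, L, min_span = min_span)
    if (!is.na(s)) {
      starts <- c(starts, s)
      lens <- c(lens, min(nchar(reads$seq[i]), L))
      ids <- c(ids, reads$read_id[i])
    }
  }
  cov <- minimal_circular_cover(starts, lens, L)
  c(cov, list(read_ids = if (cov$feasible) ids[cov$idx] else character(),
              n_placed = length(starts)))
}

## Exact minimal circular interval cover.  Intervals are (start, len) on a
## circle of length L, 0-based.  Returns feasible flag, count, idx of a
## minimal cover, and gaps when infeasible.
minimal_circular_cover <- function(starts, lens, L) {
  n <- length(starts)
  if (n == 0L) {
    return(list(feasible = FALSE, count = NA_integer_, idx = integer(),
                gaps = data.frame(start = 0L, end = L)))
  }
  lens <- pmin.int(lens, L)
  if (any(lens >= L)) {
    return(list(feasible = TRUE, count = 1L,
                idx = which(lens >= L)[1], gaps = NULL))
  }
  ## coverage check first
  covered <- union_bases(starts, starts + lens, L)
  if (covered < L) {
    ir <- IRanges::reduce(circular_iranges(starts, starts + lens, L))
    gp <- IRanges::gaps(ir, start = 1L, end = L)
    return(list(feasible = FALSE, count = NA_integer_, idx = integer(),
                gaps = data.frame(start = IRanges::start(gp) - 1L,
                                  end = IRanges::end(gp))))
  }
  best <- Inf; best_idx <- integer()
  ends <- starts + lens  # may exceed L (unwrapped)
  for (s0 in seq_len(n)) {
    ## unwrap all intervals relative to starts[s0]
    rs <- (starts - starts[s0]) %% L
    re <- rs + lens
    sel <- s0; reach <- lens[s0]
    ok <- TRUE
    while (reach < L) {
      cand <- which(rs <= reach & re > reach)
      ## also intervals wrapping past L relative to origin
      if (!length(cand)) { ok <- FALSE; break }
      nxt <- cand[which.max(re[cand])]
      sel <- c(sel, nxt); reach <- re[nxt]
      if (length(sel) > n) { ok <- FALSE; break }
    }
    if (ok && length(sel) < best) { best <- length(sel); best_idx <- sel }
  }
  if (!is.finite(best)) {
    return(list(feasible = FALSE, count = NA_integer_, idx = integer(),
                gaps = data.frame(start = integer(), end = integer())))
  }
  list(feasible = TRUE, count = as.integer(best), idx = best_idx,
       gaps = NULL)
}
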