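## Shared fixtures and independent oracles.  Fixtures are built once per
## test run and memoised here to keep the suite fast.

.fx <- new.env(parent = emptyenv())

## 20 kb genome with one exact inverted 681 bp pair and one direct 300 bp
## pair -- the workhorse for repeat/conformation/read tests
fx_genome <- function() {
  if (is.null(.fx$g)) {
    .fx$g <- generate_genome(genome_spec(
      length = 20000L, gc = 0.45,
      repeats = data.frame(length = c(681L, 300L),
                           orientation = c("inverted", "direct"),
                           identity = c(1, 1)),
      seed = 11L))
  }
  .fx$g
}

## 6-taxon eventful family over a 60 kb ancestor with 8 genes
fx_family <- function() {
  if (is.null(.fx$fam)) {
    .fx$fam <- generate_genome_family(family_spec(
      n_taxa = 6L,
      ancestor = genome_spec(
        length = 60000L, gc = 0.45,
        genes = data.frame(gene = paste0("g", 1:8),
                           length = rep(c(900L, 1200L), 4),
                           strand = rep(c("+", "-"), 4)),
        seed = 5L),
      gain_rate = 1, loss_rate = 1, gene_del_rate = 0.7, inv_rate = 0.7,
      seed = 42L))
  }
  .fx$fam
}

fx_family_blocks <- function() {
  if (is.null(.fx$fam_bt)) {
    .fx$fam_bt <- find_collinear_blocks(fx_family()$genomes,
                                        min_block = 500L)
  }
  .fx$fam_bt
}

writeLines_tmp <- function(lines) {
  f <- tempfile()
  writeLines(lines, f)
  f
}

## random DNA string at 45% GC (local RNG, not the package generators)
rand_seq <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c(0.275, 0.225, 0.225, 0.275)), collapse = "")
}

## Brute-force repeat oracle: scans EVERY diagonal of seq vs itself
## (direct) and vs its reverse complement (inverted) and reports whether
## any gapless window of length >= min_len has identity >= min_identity,
## using a prefix-sum window-existence test -- an algorithm independent
## of the package's seed-and-extend path.  `require_dispersed` restricts
## direct hits to non-overlapping copies.
oracle_any_pair <- function(seq, min_len = 50L, min_identity = 0.95,
                            require_dispersed = TRUE) {
  n <- nchar(seq)
  r1 <- charToRaw(seq)
  rcv <- charToRaw(paste(rev(strsplit(chartr("ACGT", "TGCA", seq), "",
                                      fixed = TRUE)[[1]]), collapse = ""))
  for (orient in c("direct", "inverted")) {
    rb <- if (orient == "direct") r1 else rcv
    dmin <- if (orient == "direct" && require_dispersed) min_len else 1L
    for (d in dmin:(n - min_len)) {
      len <- n - d
      m <- as.numeric(r1[1:len] == rb[(1 + d):n])
      f <- cumsum(c(0, m - min_identity))
      lo <- cummin(f[1:(len - min_len + 1L)])
      if (any(f[(min_len + 1L):(len + 1L)] >= lo)) return(TRUE)
    }
  }
  FALSE
}

## PIC oracle: explicit enumeration over all unordered base pairs per
## column -- a column is informative iff some pair of distinct bases each
## occurs in >= 2 rows
oracle_pic <- function(rows) {
  ch <- do.call(rbind, strsplit(toupper(rows), "", fixed = TRUE))
  bases <- c("A", "C", "G", "T")
  n_pic <- 0L
  for (j in seq_len(ncol(ch))) {
    inf <- FALSE
    for (x in 1:3) for (y in (x + 1):4) {
      if (sum(ch[, j] == bases[x]) >= 2L &&
          sum(ch[, j] == bases[y]) >= 2L) inf <- TRUE
    }
    n_pic <- n_pic + inf
  }
  n_pic
}

## occupancy-count classification oracle
oracle_fragment_class <- function(occupancy, n_genomes) {
  vapply(occupancy, function(o) {
    if (o == n_genomes) "core" else if (o == 1L) "specific" else "variable"
  }, "")
}

## exhaustive minimal circular cover for <= 12 intervals
oracle_min_cover <- function(starts, lens, L) {
  n <- length(starts)
  stopifnot(n <= 12L)
  covered_all <- function(idx) {
    hit <- rep(FALSE, L)
    for (i in idx) {
      p <- (starts[i] %% L) + seq_len(min(lens[i], L)) - 1L
      hit[(p %% L) + 1L] <- TRUE
    }
    all(hit)
  }
  best <- Inf
  for (msk in seq_len(2^n - 1L)) {
    idx <- which(bitwAnd(msk, 2^(seq_len(n) - 1L)) > 0L)
    if (length(idx) >= best) next
    if (covered_all(idx)) best <- length(idx)
  }
  if (is.finite(best)) as.integer(best) else NA_integer_
}

## plant a repeat pair into a random backbone with the given per-copy
## mismatch positions (deterministic fixture for threshold tests)
plant_pair <- function(backbone, copy, at1, at2, mismatch_at = integer(),
                       inverted = FALSE) {
  stopifnot(at2 > at1 + nchar(copy))
  copy2 <- strsplit(copy, "", fixed = TRUE)[[1]]
  for (p in mismatch_at) {
    copy2[p] <- setdiff(c("A", "C", "G", "T"), copy2[p])[1]
  }
  copy2 <- paste(copy2, collapse = "")
  if (inverted) {
    copy2 <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(copy2)))
  }
  substr(backbone, at1 + 1L, at1 + nchar(copy)) <- copy
  substr(backbone, at2 + 1L, at2 + nchar(copy)) <- copy2
  backbone
}
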