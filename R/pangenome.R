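#' @title Pan-mitogenome fragment classification
#' @description
#' Collinear blocks shared across a set of genomes are classified into
#' core fragments (present in all genomes), variable fragments (present in
#' a proper subset of at least two) and specific fragments (unique to one
#' genome), and summarised as pan/core accumulation curves over random
#' genome orderings.
#' @name pangenome
NULL

empty_block_table <- function() {
  structure(list(blocks = list(), n_genomes = 0L,
                 genome_ids = character()), class = "BlockTable")
}

block_table <- function(blocks, genome_ids) {
  structure(list(blocks = blocks, n_genomes = length(genome_ids),
                 genome_ids = genome_ids), class = "BlockTable")
}

#' @export
print.BlockTable <- function(x, ...) {
  cat(sprintf("BlockTable: %d block(s) over %d genome(s)\n",
              length(x$blocks), x$n_genomes))
  invisible(x)
}

#' Summarise a BlockTable as a data.frame
#'
#' @param x A `BlockTable`.
#' @param ... Unused.
#' @return `data.frame` with one row per block: `block_id`, `occupancy`,
#'   `length` (mean member span), `gc` (mean over members when sequences
#'   were available), `genomes` (comma-separated member ids).
#' @method as.data.frame BlockTable
#' @export
as.data.frame.BlockTable <- function(x, ...) {
  if (!length(x$blocks)) {
    return(data.frame(block_id = character(), occupancy = integer(),
                      length = numeric(), gc = numeric(),
                      genomes = character(), stringsAsFactors = FALSE))
  }
  data.frame(
    block_id = vapply(x$blocks, `[[`, "", "block_id"),
    occupancy = vapply(x$blocks, function(b) nrow(b$members), 0L),
    length = vapply(x$blocks, `[[`, 0, "length"),
    gc = vapply(x$blocks, function(b) {
      if (is.null(b$gc)) NA_real_ else b$gc
    }, 0),
    genomes = vapply(x$blocks, function(b)
      paste(b$members$genome, collapse = ","), ""),
    stringsAsFactors = FALSE)
}

new_block <- function(block_id, members, gc = NULL) {
  list(block_id = block_id, members = members,
       length = mean(members$end - members$start), gc = gc)
}

#' Read alignment blocks from a MAF file
#'
#' Parses Mugsy-style MAF (multiple alignment format): each `a` block's
#' `s` lines give one member per genome.  Sequence names must be
#' genome-qualified (`genome.contig`); the text before the first `.` is
#' the genome id.  Minus-strand coordinates are converted to this
#' package's forward-strand 0-based half-open convention.  A duplicate
#' genome within one block keeps the longer row, with a warning.
#'
#' @param path MAF file path.
#' @return A `BlockTable`.
#' @export
read_blocks <- function(path) {
  lines <- readLines(path)
  blocks <- list()
  genome_ids <- character()
  cur <- NULL
  bi <- 0L
  flush <- function() {
    if (is.null(cur) || nrow(cur) == 0L) return()
    if (anyDuplicated(cur$genome)) {
      warning("duplicate genome within one MAF block; keeping longest row")
      cur <- cur[order(-(cur$end - cur$start)), , drop = FALSE]
      cur <- cur[!duplicated(cur$genome), , drop = FALSE]
    }
    bi <<- bi + 1L
    blocks[[bi]] <<- new_block(sprintf("maf_%04d", bi),
                               cur[order(cur$genome), , drop = FALSE])
    genome_ids <<- union(genome_ids, cur$genome)
  }
  for (ln in lines) {
    if (startsWith(ln, "a")) {
      flush()
      cur <- data.frame(genome = character(), start = integer(),
                        end = integer(), strand = character(),
                        stringsAsFactors = FALSE)
    } else if (startsWith(ln, "s") && !is.null(cur)) {
      f <- strsplit(trimws(ln), "[ \t]+")[[1]]
      if (length(f) < 7L) stop("malformed MAF s line: ", ln)
      src <- f[2]; start <- as.integer(f[3]); size <- as.integer(f[4])
      strand <- f[5]; src_size <- as.integer(f[6])
      genome <- sub("\\..*$", "", src)
      s0 <- if (strand == "-") src_size - start - size else start
      cur <- rbind(cur, data.frame(genome = genome, start = s0,
                                   end = s0 + size, strand = strand,
                                   stringsAsFactors = FALSE))
    }
  }
  flush()
  block_table(blocks, sort(genome_ids))
}

#' @rdname read_blocks
#' @param table A `BlockTable`.
#' @param src_sizes Named integer vector of genome lengths (needed to
#'   express minus-strand rows in MAF's strand-relative coordinates).
#' @param seqs Optional named list of genome sequences to write the
#'   aligned text; otherwise `N` placeholders of the right length are
#'   written (coordinates and strands round-trip either way).
#' @export
write_blocks <- function(table, path, src_sizes, seqs = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##maf version=1", con)
  for (b in table$blocks) {
    writeLines("a score=0", con)
    for (i in seq_len(nrow(b$members))) {
      m <- b$members[i, ]
      size <- m$end - m$start
      start <- if (m$strand == "-") src_sizes[[m$genome]] - m$end
               else m$start
      txt <- if (!is.null(seqs) && !is.null(seqs[[m$genome]])) {
        s <- substr(seqs[[m$genome]], m$start + 1L, m$end)
        if (m$strand == "-") revcomp(s) else s
      } else strrep("N", size)
      writeLines(paste("s", paste0(m$genome, ".chr"), start, size,
                       m$strand, src_sizes[[m$genome]], txt, sep = " "),
                 con)
    }
    writeLines("", con)
  }
  invisible(path)
}

## unique k-mer anchors of one genome: k-mers occurring exactly once,
## canonicalised by strand (lexicographic min of k-mer and its revcomp)
unique_anchors <- function(seq, k) {
  n <- nchar(seq)
  km <- substring(seq, 1:(n - k + 1L), k:n)
  rc <- strsplit(as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(seq))), "", fixed = TRUE)[[1]]
  kmrc <- substring(paste(rc, collapse = ""), 1:(n - k + 1L), k:n)
  kmrc <- rev(kmrc)                       # kmrc[i] = revcomp of km[i]
  canon <- pmin(km, kmrc)
  strand <- ifelse(km <= kmrc, "+", "-")
  keep <- !(duplicated(canon) | duplicated(canon, fromLast = TRUE))
  list(kmer = canon[keep], pos = which(keep) - 1L, strand = strand[keep])
}

#' Find collinear blocks across genomes by shared unique k-mer anchors
#'
#' A deliberately simple whole-genome aligner for synthetic and validation
#' use: k-mers that occur exactly once in every genome containing them are
#' anchors; runs of anchors with an identical genome-membership signature
#' and collinear positions (allowing strand flips per genome) become
#' blocks.  Residual regions of each genome not covered by any
#' multi-genome block are emitted as occupancy-1 (genome-specific) blocks.
#' Real analyses should ingest a Mugsy MAF via [read_blocks()] instead.
#'
#' @param genomes Named list of [circular_genome()]s or character
#'   sequences.
#' @param min_block Minimum block length in bases in every member.
#' @param k Anchor k-mer length.
#' @param max_jump Maximum positional jump between consecutive anchors
#'   within one block.
#' @return A `BlockTable` with per-block `gc` filled in.
#' @export
find_collinear_blocks <- function(genomes, min_block = 500L, k = 21L,
                                  max_jump = 100L) {
  stopifnot(length(genomes) >= 2L)
  if (is.null(names(genomes))) {
    names(genomes) <- paste0("g", seq_along(genomes))
  }
  gs <- lapply(genomes, function(g) as_genome(g)$seq)
  ids <- names(gs)
  G <- length(ids)
  anch <- lapply(gs, unique_anchors, k = k)

  ## global anchor table indexed by k-mer id: per-genome position/strand
  ukmers <- unique(unlist(lapply(anch, `[[`, "kmer"), use.names = FALSE))
  nk <- length(ukmers)
  pos_mat <- matrix(NA_integer_, nk, G, dimnames = list(NULL, ids))
  str_fwd <- matrix(NA, nk, G, dimnames = list(NULL, ids))
  kid_of <- list()
  for (gi in seq_len(G)) {
    a <- anch[[gi]]
    kid <- match(a$kmer, ukmers)
    kid_of[[gi]] <- kid
    pos_mat[kid, gi] <- a$pos
    str_fwd[kid, gi] <- a$strand == "+"
  }
  present <- !is.na(pos_mat)
  occ <- rowSums(present)
  ## membership signature as a bitmask (safe as a double for <= 50 genomes)
  sig_all <- as.vector(present %*% (2 ^ (seq_len(G) - 1L)))

  used <- rep(FALSE, nk)
  blocks <- list()
  bi <- 0L
  for (pi in seq_len(G)) {
    pivot <- ids[pi]
    kid <- kid_of[[pi]]
    sel <- occ[kid] >= 2L & !used[kid]
    if (!any(sel)) next
    kid <- kid[sel]
    ord <- order(pos_mat[kid, pi])
    kid <- kid[ord]
    pp <- pos_mat[kid, pi]
    pfwd <- str_fwd[kid, pi]
    sig <- sig_all[kid]
    n_a <- length(kid)
    ## break runs on signature change or a non-collinear step in any member
    run_id <- integer(n_a)
    rid <- 0L
    memb_idx <- which(present[kid[1], ])
    for (i in seq_len(n_a)) {
      newrun <- i == 1L || sig[i] != sig[i - 1L] ||
        pp[i] - pp[i - 1L] > max_jump + k
      if (!newrun) {
        for (g in memb_idx) {
          if (g == pi) next
          rel1 <- str_fwd[kid[i - 1L], g] == pfwd[i - 1L]
          rel2 <- str_fwd[kid[i], g] == pfwd[i]
          step <- pos_mat[kid[i], g] - pos_mat[kid[i - 1L], g]
          ok <- rel1 == rel2 &&
            ((rel1 && step > 0L && step <= max_jump + k) ||
             (!rel1 && step < 0L && -step <= max_jump + k))
          if (!ok) { newrun <- TRUE; break }
        }
      }
      if (newrun) {
        rid <- rid + 1L
        memb_idx <- which(present[kid[i], ])
      }
      run_id[i] <- rid
    }
    for (r in split(seq_len(n_a), run_id)) {
      memb <- which(present[kid[r[1]], ])
      if (length(memb) < 2L) next
      first <- kid[r[1]]; last <- kid[r[length(r)]]
      mem <- data.frame(genome = ids[memb], start = 0L, end = 0L,
                        strand = "+", stringsAsFactors = FALSE)
      okblock <- TRUE
      for (mi in seq_along(memb)) {
        g <- memb[mi]
        p1 <- pos_mat[first, g]; p2 <- pos_mat[last, g]
        s0 <- min(p1, p2); s1 <- max(p1, p2) + k
        if (s1 - s0 < min_block) { okblock <- FALSE; break }
        mem$start[mi] <- s0; mem$end[mi] <- s1
        mem$strand[mi] <- if (g == pi) "+"
          else if (str_fwd[first, g] == pfwd[r[1]]) "+" else "-"
      }
      if (!okblock) next
      bi <- bi + 1L
      gcs <- vapply(seq_len(nrow(mem)), function(i) {
        gc_content(substr(gs[[mem$genome[i]]], mem$start[i] + 1L,
                          mem$end[i]))
      }, 0)
      blocks[[bi]] <- new_block(sprintf("blk_%04d", bi), mem,
                                gc = mean(gcs))
      used[kid[r]] <- TRUE
    }
  }

  ## residual (unaligned) regions become genome-specific blocks
  for (gid in ids) {
    L <- nchar(gs[[gid]])
    covered <- IRanges::IRanges()
    for (b in blocks) {
      m <- b$members[b$members$genome == gid, , drop = FALSE]
      if (nrow(m)) {
        covered <- c(covered, IRanges::IRanges(m$start + 1L, m$end))
      }
    }
    gaps <- IRanges::gaps(IRanges::reduce(covered), start = 1L, end = L)
    gaps <- gaps[IRanges::width(gaps) >= min_block]
    for (i in seq_along(gaps)) {
      bi <- bi + 1L
      s0 <- IRanges::start(gaps)[i] - 1L; s1 <- IRanges::end(gaps)[i]
      mem <- data.frame(genome = gid, start = s0, end = s1, strand = "+",
                        stringsAsFactors = FALSE)
      blocks[[bi]] <- new_block(
        sprintf("spec_%s_%03d", gid, i), mem,
        gc = gc_content(substr(gs[[gid]], s0 + 1L, s1)))
    }
  }
  block_table(blocks, ids)
}

#' Classify blocks into core, variable and specific fragments
#'
#' Core: present in all `n_genomes`; specific: present in exactly one;
#' variable: anything in between.  Per-genome totals count each genome's
#' member interval union per class; GC is computed from the genome
#' sequences when supplied.
#'
#' @param blocks A `BlockTable`.
#' @param n_genomes Number of genomes in the comparison (defaults to the
#'   table's).
#' @param genomes Optional named list of genome sequences for per-genome
#'   GC.
#' @return List with `per_block` (`data.frame`: `block_id`, `occupancy`,
#'   `class`) and `per_genome` (`data.frame`: `genome`, `class`, `bases`,
#'   `gc`).
#' @export
classify_fragments <- function(blocks, n_genomes = blocks$n_genomes,
                               genomes = NULL) {
  tab <- as.data.frame(blocks)
  if (any(tab$occupancy > n_genomes)) {
    stop("block occupancy exceeds n_genomes")
  }
  tab$class <- ifelse(tab$occupancy == n_genomes, "core",
                      ifelse(tab$occupancy == 1L, "specific", "variable"))
  per_genome <- list()
  for (gid in blocks$genome_ids) {
    for (cl in c("core", "variable", "specific")) {
      ivs <- list()
      for (j in which(tab$class == cl)) {
        m <- blocks$blocks[[j]]$members
        m <- m[m$genome == gid, , drop = FALSE]
        if (nrow(m)) ivs[[length(ivs) + 1L]] <- m
      }
      if (length(ivs)) {
        m <- do.call(rbind, ivs)
        ir <- IRanges::reduce(IRanges::IRanges(m$start + 1L, m$end))
        bases <- sum(IRanges::width(ir))
        gc <- if (!is.null(genomes) && !is.null(genomes[[gid]])) {
          seqs <- substr(rep(as_genome(genomes[[gid]])$seq,
                             length(ir)),
                         IRanges::start(ir), IRanges::end(ir))
          gc_content(paste(seqs, collapse = ""))
        } else NA_real_
      } else {
        bases <- 0L; gc <- NA_real_
      }
      per_genome[[length(per_genome) + 1L]] <-
        data.frame(genome = gid, class = cl, bases = bases, gc = gc,
                   stringsAsFactors = FALSE)
    }
  }
  list(per_block = tab[, c("block_id", "occupancy", "class")],
       per_genome = do.call(rbind, per_genome))
}

#' Pan- and core-genome accumulation curves
#'
#' For each subset size k = 1..N, over up to `max_perms` random genome
#' orderings (all N! orderings when fewer), pan(k) is the total length of
#' blocks present in at least one of the first k genomes (each block
#' counted once) and core(k) the total length of blocks present in all
#' first k.  Block length is the mean member span.  Reported per k as
#' median and quartiles.
#'
#' @param blocks A `BlockTable`.
#' @param max_perms Maximum number of sampled genome orderings.
#' @param seed Integer seed (sampling is deterministic given it).
#' @return List with `curve` (`data.frame`: `k`, `pan_q1`, `pan_median`,
#'   `pan_q3`, `core_q1`, `core_median`, `core_q3`) and `n_perms`.
#' @export
accumulation_curves <- function(blocks, max_perms = 500L, seed = 1L) {
  N <- blocks$n_genomes
  stopifnot(N >= 2L)
  ids <- blocks$genome_ids
  tab <- as.data.frame(blocks)
  memb <- lapply(blocks$blocks, function(b) b$members$genome)
  lens <- tab$length

  perms <- if (factorial(N) <= max_perms) {
    all_permutations(ids)
  } else {
    set.seed(seed)
    lapply(seq_len(max_perms), function(i) sample(ids))
  }
  np <- length(perms)
  pan <- matrix(0, np, N); core <- matrix(0, np, N)
  for (p in seq_len(np)) {
    ord <- perms[[p]]
    for (k in seq_len(N)) {
      first_k <- ord[seq_len(k)]
      pan[p, k] <- sum(lens[vapply(memb, function(m)
        any(first_k %in% m), TRUE)])
      core[p, k] <- sum(lens[vapply(memb, function(m)
        all(first_k %in% m), TRUE)])
    }
  }
  q <- function(mat, p) apply(mat, 2L, stats::quantile, probs = p,
                              names = FALSE)
  list(curve = data.frame(
         k = seq_len(N),
         pan_q1 = q(pan, 0.25), pan_median = q(pan, 0.5),
         pan_q3 = q(pan, 0.75),
         core_q1 = q(core, 0.25), core_median = q(core, 0.5),
         core_q3 = q(core, 0.75)),
       n_perms = np,
       pan = pan, core = core)
}

all_permutations <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in all_permutations(x[-i])) {
      out[[length(out) + 1L]] <- c(x[i], rest)
    }
  }
  out
}
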