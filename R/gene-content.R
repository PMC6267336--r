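#' Search contigs for protein-coding genes
#'
#' Seed-and-extend homology search of each database gene against a set of
#' contigs (both strands): exact shared k-mers anchor candidate loci, each
#' locus is scored by gapless extension, and the best hit per gene decides
#' the call.  A gene is `present` when its best hit reaches
#' `min_identity` and covers at least `min_cov` of the gene length,
#' `fragmentary` when a hit exists below coverage, `absent` otherwise.
#'
#' @param contigs Named character vector of contig sequences (or FASTA
#'   path).
#' @param gene_db Named character vector of gene sequences (or FASTA
#'   path); names must be unique.
#' @param min_identity Minimum hit identity (default 0.7).
#' @param min_cov Minimum aligned fraction of the gene length (default
#'   0.5).
#' @param k Seed k-mer length.
#' @return `GeneHit` `data.frame`: `gene`, `contig`, `aligned_fraction`,
#'   `identity`, `status`.
#' @export
search_genes <- function(contigs, gene_db, min_identity = 0.7,
                         min_cov = 0.5, k = 15L) {
  if (is.character(contigs) && length(contigs) == 1L && file.exists(contigs))
    contigs <- read_fasta(contigs)
  if (is.character(gene_db) && length(gene_db) == 1L &&
      file.exists(gene_db))
    gene_db <- read_fasta(gene_db)
  if (is.null(names(gene_db)) || anyDuplicated(names(gene_db))) {
    stop("gene database must have unique gene ids")
  }
  if (is.null(names(contigs))) names(contigs) <- paste0("contig_",
                                                        seq_along(contigs))
  out <- data.frame(gene = names(gene_db), contig = NA_character_,
                    aligned_fraction = 0, identity = NA_real_,
                    status = "absent", stringsAsFactors = FALSE)
  for (gi in seq_along(gene_db)) {
    gseq <- gene_db[[gi]]
    glen <- nchar(gseq)
    best <- NULL
    for (ci in seq_along(contigs)) {
      for (cseq in c(contigs[[ci]], revcomp(contigs[[ci]]))) {
        hits <- pairwise_gapless_hits(gseq, cseq,
                                      min_len = min(glen, 60L),
                                      min_identity = min_identity,
                                      k = k, self = FALSE)
        if (is.null(hits)) next
        ## merge hits on the gene axis: aligned fraction counts the union
        ir <- IRanges::reduce(IRanges::IRanges(hits$s1_start + 1L,
                                               hits$s1_end))
        cov <- sum(IRanges::width(ir)) / glen
        idn <- sum(hits$matches) / sum(hits$s1_end - hits$s1_start)
        if (is.null(best) || cov > best$cov ||
            (cov == best$cov && idn > best$idn)) {
          best <- list(contig = names(contigs)[ci], cov = cov, idn = idn)
        }
      }
    }
    if (!is.null(best)) {
      out$contig[gi] <- best$contig
      out$aligned_fraction[gi] <- min(1, best$cov)
      out$identity[gi] <- best$idn
      out$status[gi] <- if (best$cov >= min_cov) "present" else "fragmentary"
    }
  }
  out
}

#' Validate gene presence by sequencing depth
#'
#' Second step of the two-step presence call: short reads are placed on
#' the gene sequence by exact matching (both strands) and the mean
#' per-base depth over the gene is compared with the genome-wide mean
#' depth.  Ratio >= `high` is `present`, <= `low` is `absent`, anything
#' between is `uncertain` (for manual review).
#'
#' @param gene_seq Gene sequence (character).
#' @param reads Reads `data.frame` (or FASTQ path), e.g. from
#'   [simulate_short_reads()].
#' @param genome_mean_depth Genome-wide mean depth (> 0).
#' @param low,high Depth-ratio thresholds.
#' @return List: `status`, `gene_depth`, `ratio`.
#' @export
validate_presence_by_depth <- function(gene_seq, reads, genome_mean_depth,
                                       low = 0.1, high = 0.5) {
  if (genome_mean_depth <= 0) stop("genome_mean_depth must be > 0")
  if (is.character(reads) && length(reads) == 1L) reads <- read_fastq(reads)
  glen <- nchar(gene_seq)
  if (nrow(reads) == 0L) {
    warning("no reads supplied; gene called absent")
    return(list(status = "absent", gene_depth = 0, ratio = 0))
  }
  gsub <- Biostrings::DNAString(gene_seq)
  cover <- integer(glen)
  widths <- nchar(reads$seq)
  for (w in unique(widths)) {
    sel <- which(widths == w)
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(reads$seq[sel]))
    for (subject in list(gsub, Biostrings::reverseComplement(gsub))) {
      m <- Biostrings::matchPDict(pd, subject)
      st <- unlist(lapply(m, Biostrings::start), use.names = FALSE)
      if (!length(st)) next
      ir <- IRanges::IRanges(st, width = w)
      cv <- IRanges::coverage(ir, width = glen)
      cover <- cover + as.integer(cv)
    }
  }
  gene_depth <- mean(cover)
  ratio <- gene_depth / genome_mean_depth
  status <- if (ratio >= high) "present" else if (ratio <= low) "absent"
            else "uncertain"
  list(status = status, gene_depth = gene_depth, ratio = ratio)
}

## Karlin-Altschul-style translation of an E-value cutoff into a minimum
## gapless score at +1/-1 scoring (lambda and K for equal base
## frequencies).  Used to mirror a BLASTN stringency threshold without a
## full statistics engine.
score_for_evalue <- function(evalue, m, n, lambda = 1.33, K = 0.621) {
  ceiling((log(K * as.numeric(m) * as.numeric(n)) - log(evalue)) / lambda)
}

#' Detect plastid-derived fragments in a mitogenome
#'
#' Gapless seed-and-extend search of the mitogenome against a plastome,
#' both strands.  Hits must be at least `min_len` long and score at least
#' `min_score` (match +1 / mismatch -1); by default `min_score` is derived
#' from an E-value-like stringency of 1e-50 for the two sequence lengths,
#' mirroring the conventional BLASTN cutoff for organelle transfer
#' detection.
#'
#' @param mito Mitogenome sequence (character or [circular_genome()]).
#' @param plastome Plastome sequence (character or [circular_genome()]).
#' @param min_len Minimum fragment length (default 100).
#' @param min_score Minimum alignment score; `NULL` derives it from
#'   `evalue`.
#' @param evalue Stringency used to derive `min_score` when that is
#'   `NULL`.
#' @param min_identity Minimum identity of a reported fragment.
#' @return `data.frame`: `mito_start`, `mito_end`, `plastome_start`,
#'   `plastome_end`, `strand`, `length`, `identity`, `score`; plus the
#'   total transferred bases as attribute `total_bases`.
#' @export
find_plastid_derived <- function(mito, plastome, min_len = 100L,
                                 min_score = NULL, evalue = 1e-50,
                                 min_identity = 0.7) {
  mito <- as_genome(mito)$seq
  pl <- as_genome(plastome)$seq
  if (!nchar(mito) || !nchar(pl)) stop("empty sequence")
  if (is.null(min_score)) {
    min_score <- score_for_evalue(evalue, nchar(mito), nchar(pl))
  }
  res <- list()
  for (strand in c("+", "-")) {
    target <- if (strand == "+") pl else revcomp(pl)
    hits <- pairwise_gapless_hits(mito, target, min_len = min_len,
                                  min_identity = min_identity,
                                  k = 21L, self = FALSE)
    if (is.null(hits)) next
    len <- hits$s1_end - hits$s1_start
    score <- hits$matches - (len - hits$matches)
    ps <- hits$s2_start; pe <- hits$s2_end
    if (strand == "-") {
      tmp <- ps
      ps <- nchar(pl) - pe
      pe <- nchar(pl) - tmp
    }
    res[[strand]] <- data.frame(
      mito_start = hits$s1_start, mito_end = hits$s1_end,
      plastome_start = ps, plastome_end = pe, strand = strand,
      length = len, identity = hits$matches / len, score = score,
      stringsAsFactors = FALSE)
  }
  out <- if (length(res)) do.call(rbind, res) else {
    data.frame(mito_start = integer(), mito_end = integer(),
               plastome_start = integer(), plastome_end = integer(),
               strand = character(), length = integer(),
               identity = numeric(), score = numeric(),
               stringsAsFactors = FALSE)
  }
  out <- out[out$length >= min_len & out$score >= min_score, , drop = FALSE]
  rownames(out) <- NULL
  total <- if (nrow(out)) {
    sum(IRanges::width(IRanges::reduce(
      IRanges::IRanges(out$mito_start + 1L, out$mito_end))))
  } else 0L
  attr(out, "total_bases") <- total
  out
}

#' Find open reading frames on a circular sequence
#'
#' ATG-to-stop spans longer than `min_len` in all six frames; the scan is
#' circular-aware (ORFs may cross the origin).  Within one frame, the
#' first ATG after the previous stop opens the ORF (maximal ORFs).
#'
#' @param seq Character sequence or [circular_genome()].
#' @param min_len Minimum ORF length in bases, stop codon included
#'   (> comparison; warns when not a multiple of 3).
#' @param both_strands Scan the reverse strand too.
#' @return `data.frame`: `start`, `end` (0-based half-open on the forward
#'   strand of the circle; `end` may exceed the genome length for
#'   origin-crossing ORFs), `strand`, `length`.
#' @export
find_orfs <- function(seq, min_len = 300L, both_strands = TRUE) {
  g <- as_genome(seq)
  if (min_len %% 3L != 0L) {
    warning("min_len ", min_len, " is not a multiple of 3")
  }
  L <- g$length
  scan_strand <- function(s, strand) {
    D <- strrep(s, 2L)                    # circular-aware
    out <- list()
    stops <- c("TAA", "TAG", "TGA")
    for (fr in 0:2) {
      starts_at <- seq(fr + 1L, nchar(D) - 2L, by = 3L)
      cod <- substring(D, starts_at, starts_at + 2L)
      is_stop <- cod %in% stops
      is_atg <- cod == "ATG"
      open <- NA_integer_
      for (i in seq_along(cod)) {
        if (is.na(open) && is_atg[i]) open <- i
        if (!is.na(open) && is_stop[i]) {
          s0 <- starts_at[open] - 1L      # 0-based
          e0 <- starts_at[i] + 2L         # end incl. stop codon
          len <- e0 - s0
          if (len > min_len && len <= L && s0 < L) {
            out[[length(out) + 1L]] <- c(s0, e0)
          }
          open <- NA_integer_
        }
      }
    }
    if (!length(out)) return(NULL)
    m <- do.call(rbind, out)
    m <- m[!duplicated(m[, 1] %% L), , drop = FALSE]
    data.frame(start = m[, 1], end = m[, 2], strand = strand,
               length = m[, 2] - m[, 1], stringsAsFactors = FALSE)
  }
  res <- scan_strand(g$seq, "+")
  if (both_strands) {
    rc <- scan_strand(revcomp(g$seq), "-")
    if (!is.null(rc)) {
      ## map reverse-strand coordinates to forward-strand 0-based
      s <- L - (rc$start %% L) - rc$length
      rc$start <- ifelse(s < 0L, s + L, s)
      rc$end <- rc$start + rc$length
      res <- rbind(res, rc)
    }
  }
  if (is.null(res)) {
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), length = integer(),
                      stringsAsFactors = FALSE))
  }
  res[order(res$start), , drop = FALSE]
}

#' Flag a gene copy as a pseudogene
#'
#' A gene copy is flagged when translation of the observed sequence in the
#' reference frame hits a stop codon before `frac` (default 90%) of the
#' reference gene length -- a premature termination.
#'
#' @param observed Observed gene sequence (in-frame, 5' to 3').
#' @param reference Reference (intact) gene sequence.
#' @param frac Fraction of the reference length before which a stop is
#'   premature.
#' @return Logical scalar.
#' @export
flag_pseudogene <- function(observed, reference, frac = 0.9) {
  stops <- c("TAA", "TAG", "TGA")
  n <- nchar(observed)
  if (n < 3L) return(TRUE)
  at <- seq(1L, n - 2L, by = 3L)
  cod <- substring(observed, at, at + 2L)
  hit <- which(cod %in% stops)
  if (!length(hit)) return(FALSE)
  first_stop_end <- at[hit[1]] + 2L
  first_stop_end < frac * nchar(reference)
}

#' Build a gene presence/absence matrix across taxa
#'
#' @param calls `data.frame` with columns `taxon`, `gene`, `status`
#'   (values `present`, `absent` or `pseudogene`).
#' @param gene_order Optional character vector fixing row order; default
#'   alphabetical.
#' @return Character matrix genes x taxa (taxa in input order), ready for
#'   writing as TSV or drawing as a heat map.  Missing or conflicting
#'   duplicate calls raise an error naming the cell.
#' @export
build_presence_matrix <- function(calls, gene_order = NULL) {
  stopifnot(all(c("taxon", "gene", "status") %in% names(calls)))
  taxa <- unique(calls$taxon)
  genes <- if (is.null(gene_order)) sort(unique(calls$gene)) else gene_order
  dup <- duplicated(calls[, c("taxon", "gene")])
  if (any(dup)) {
    key <- paste(calls$taxon, calls$gene)
    for (k in unique(key[dup])) {
      st <- unique(calls$status[key == k])
      if (length(st) > 1L) {
        stop("conflicting duplicate calls for (gene, taxon) cell: ", k)
      }
    }
    calls <- calls[!dup, , drop = FALSE]
  }
  m <- matrix(NA_character_, length(genes), length(taxa),
              dimnames = list(genes, taxa))
  for (i in seq_len(nrow(calls))) {
    m[calls$gene[i], calls$taxon[i]] <- calls$status[i]
  }
  miss <- which(is.na(m), arr.ind = TRUE)
  if (nrow(miss)) {
    stop("missing call for gene '", genes[miss[1, 1]], "' in taxon '",
         taxa[miss[1, 2]], "'")
  }
  m
}
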