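#' Specification of a synthetic genome family
#'
#' A star phylogeny: each taxon's genome is derived independently from one
#' ancestral circular genome by structural events -- segment gains
#' (insertion of novel sequence), segment losses, deletions of whole genes
#' and inversions.  Event counts per taxon are Poisson with the given
#' rates.  All event breakpoints (across all taxa) partition the ancestor
#' into segments whose per-taxon retention is recorded as ground truth,
#' emulating the fragment structure seen across related plant mitogenomes.
#'
#' @param n_taxa Number of taxa (>= 2).
#' @param ancestor A [genome_spec()] for the ancestral genome.
#' @param gain_rate,loss_rate,gene_del_rate,inv_rate Expected number of
#'   events of each kind per taxon.
#' @param gain_len,loss_len,inv_len Length ranges (bases) for gain, loss
#'   and inversion events.
#' @param seed Integer seed.
#' @return A `FamilySpec` list.
#' @export
family_spec <- function(n_taxa, ancestor = genome_spec(length = 60000L),
                        gain_rate = 1, loss_rate = 1, gene_del_rate = 0.5,
                        inv_rate = 0.5, gain_len = c(2000L, 8000L),
                        loss_len = c(1000L, 5000L), inv_len = c(2000L, 8000L),
                        seed = 1L) {
  stopifnot(n_taxa >= 2L, gain_rate >= 0, loss_rate >= 0,
            gene_del_rate >= 0, inv_rate >= 0)
  structure(list(n_taxa = as.integer(n_taxa), ancestor = ancestor,
                 gain_rate = gain_rate, loss_rate = loss_rate,
                 gene_del_rate = gene_del_rate, inv_rate = inv_rate,
                 gain_len = gain_len, loss_len = loss_len,
                 inv_len = inv_len, seed = as.integer(seed)),
            class = "FamilySpec")
}

## sample an interval of width in `range` avoiding `avoid` (IRanges) and
## NULL-able containment constraint; up to `tries` rejections, else NA
sample_event_interval <- function(L, range, avoid, genes = NULL,
                                  allow_contain_genes = FALSE,
                                  tries = 500L) {
  for (i in seq_len(tries)) {
    w <- sample.int(range[2] - range[1] + 1L, 1L) + range[1] - 1L
    if (w >= L - 200L) next
    s <- sample.int(L - w, 1L) - 1L
    iv <- IRanges::IRanges(s + 1L, s + w)
    if (length(avoid) && sum(IRanges::countOverlaps(iv, avoid))) next
    if (!is.null(genes) && length(genes)) {
      ov <- IRanges::findOverlaps(iv, genes)
      if (length(ov)) {
        if (!allow_contain_genes) next
        ## genes must be fully inside the interval, never cut by it
        gh <- genes[S4Vectors::subjectHits(ov)]
        if (any(IRanges::start(gh) < s + 1L | IRanges::end(gh) > s + w)) next
      }
    }
    return(c(s, s + w))
  }
  NULL
}

#' Generate a family of related circular genomes with ground truth
#'
#' @param spec A [family_spec()].
#' @return List with `genomes` (named list of [circular_genome()]s),
#'   and `truth`: `segments` (`data.frame` of ancestral/gained segments),
#'   `presence` (segments x taxa logical matrix), `placements` (where each
#'   retained segment sits in each taxon's genome), `gene_presence`
#'   (genes x taxa logical matrix, when the ancestor has genes) and
#'   `events` (per-taxon event log).  A warning (not an error) is raised
#'   when no ancestral segment survives in all taxa.
#' @export
generate_genome_family <- function(spec) {
  stopifnot(inherits(spec, "FamilySpec"))
  anc <- generate_genome(spec$ancestor)
  set.seed(spec$seed)
  L <- anc$length
  taxa <- sprintf("taxon_%02d", seq_len(spec$n_taxa))
  gene_tab <- if (!is.null(anc$truth$genes)) anc$truth$genes$table else NULL
  gene_iv <- if (!is.null(gene_tab)) {
    IRanges::IRanges(gene_tab$start + 1L, gene_tab$end)
  } else IRanges::IRanges()

  ## ---- sample events per taxon ----
  events <- list()
  for (t in taxa) {
    avoid <- IRanges::IRanges()
    ev <- list(loss = list(), inv = list(), gene_del = character(),
               gain = list())
    for (i in seq_len(stats::rpois(1L, spec$loss_rate))) {
      iv <- sample_event_interval(L, spec$loss_len, avoid, gene_iv,
                                  allow_contain_genes = FALSE)
      if (is.null(iv)) next
      ev$loss[[length(ev$loss) + 1L]] <- iv
      avoid <- c(avoid, IRanges::IRanges(iv[1] + 1L, iv[2]))
    }
    for (i in seq_len(stats::rpois(1L, spec$inv_rate))) {
      iv <- sample_event_interval(L, spec$inv_len, avoid, gene_iv,
                                  allow_contain_genes = TRUE)
      if (is.null(iv)) next
      ev$inv[[length(ev$inv) + 1L]] <- iv
      avoid <- c(avoid, IRanges::IRanges(iv[1] + 1L, iv[2]))
    }
    if (!is.null(gene_tab) && nrow(gene_tab)) {
      n_del <- min(stats::rpois(1L, spec$gene_del_rate), nrow(gene_tab))
      if (n_del > 0L) {
        cand <- gene_tab$gene[!vapply(seq_len(nrow(gene_tab)), function(i)
          sum(IRanges::countOverlaps(gene_iv[i], avoid)) > 0L, TRUE)]
        del <- sample(cand, min(n_del, length(cand)))
        ev$gene_del <- del
        for (g in del) {
          i <- match(g, gene_tab$gene)
          avoid <- c(avoid, gene_iv[i])
        }
      }
    }
    for (i in seq_len(stats::rpois(1L, spec$gain_rate))) {
      w <- sample.int(spec$gain_len[2] - spec$gain_len[1] + 1L, 1L) +
        spec$gain_len[1] - 1L
      for (try in 1:200) {
        p <- sample.int(L - 1L, 1L)
        pin <- IRanges::IRanges(p + 1L, p + 1L)
        if (sum(IRanges::countOverlaps(pin, avoid)) == 0L &&
            sum(IRanges::countOverlaps(pin, gene_iv)) == 0L) {
          ev$gain[[length(ev$gain) + 1L]] <-
            list(at = p, seq = random_dna(w, spec$ancestor$gc))
          break
        }
      }
    }
    events[[t]] <- ev
  }

  ## ---- global breakpoints -> ancestral segments ----
  bp <- c(0L, L)
  for (t in taxa) {
    ev <- events[[t]]
    for (iv in ev$loss) bp <- c(bp, iv)
    for (iv in ev$inv) bp <- c(bp, iv)
    for (g in ev$gene_del) {
      i <- match(g, gene_tab$gene)
      bp <- c(bp, gene_tab$start[i], gene_tab$end[i])
    }
    for (gn in ev$gain) bp <- c(bp, gn$at)
  }
  bp <- sort(unique(bp))
  seg <- data.frame(seg_id = sprintf("seg_%03d", seq_len(length(bp) - 1L)),
                    origin = "ancestral",
                    anc_start = bp[-length(bp)], anc_end = bp[-1],
                    stringsAsFactors = FALSE)
  seg$length <- seg$anc_end - seg$anc_start

  ## gained segments
  for (t in taxa) {
    for (gi in seq_along(events[[t]]$gain)) {
      gn <- events[[t]]$gain[[gi]]
      seg <- rbind(seg, data.frame(
        seg_id = sprintf("gain_%s_%d", t, gi), origin = paste0("gain:", t),
        anc_start = NA_integer_, anc_end = NA_integer_,
        length = nchar(gn$seq), stringsAsFactors = FALSE))
    }
  }

  presence <- matrix(FALSE, nrow(seg), length(taxa),
                     dimnames = list(seg$seg_id, taxa))
  anc_rows <- seg$origin == "ancestral"
  for (t in taxa) {
    ev <- events[[t]]
    lost <- IRanges::IRanges()
    for (iv in ev$loss) lost <- c(lost, IRanges::IRanges(iv[1] + 1L, iv[2]))
    for (g in ev$gene_del) {
      i <- match(g, gene_tab$gene)
      lost <- c(lost, gene_iv[i])
    }
    keep <- rep(TRUE, sum(anc_rows))
    if (length(lost)) {
      segiv <- IRanges::IRanges(seg$anc_start[anc_rows] + 1L,
                                seg$anc_end[anc_rows])
      keep <- IRanges::countOverlaps(segiv, lost) == 0L
    }
    presence[which(anc_rows)[keep], t] <- TRUE
    presence[seg$origin == paste0("gain:", t), t] <- TRUE
  }

  ## ---- assemble taxon genomes, tracking placements ----
  genomes <- list()
  placements <- data.frame(seg_id = character(), taxon = character(),
                           start = integer(), end = integer(),
                           strand = character(), stringsAsFactors = FALSE)
  anc_seg_idx <- which(anc_rows)
  for (t in taxa) {
    ev <- events[[t]]
    inv_of <- function(s0, s1) {
      for (iv in ev$inv) if (s0 >= iv[1] && s1 <= iv[2]) return(iv[1])
      NA_integer_
    }
    gains_at <- stats::setNames(
      lapply(events[[t]]$gain, `[[`, "seq"),
      vapply(events[[t]]$gain, function(g) as.character(g$at), ""))
    gain_ids <- stats::setNames(
      sprintf("gain_%s_%d", t, seq_along(events[[t]]$gain)),
      names(gains_at))

    parts <- character(); part_seg <- character(); part_strand <- character()
    emit <- function(seqs, segids, strands) {
      parts <<- c(parts, seqs)
      part_seg <<- c(part_seg, segids)
      part_strand <<- c(part_strand, strands)
    }
    pend_inv <- NULL  # list(seqs, segids) accumulated inside one inversion
    flush_inv <- function() {
      if (!is.null(pend_inv) && length(pend_inv$seqs)) {
        rcs <- vapply(rev(pend_inv$seqs), revcomp, "", USE.NAMES = FALSE)
        emit(rcs, rev(pend_inv$segids), rep("-", length(rcs)))
      }
      pend_inv <<- NULL
    }
    cur_inv <- NA_integer_
    for (si in anc_seg_idx) {
      s0 <- seg$anc_start[si]; s1 <- seg$anc_end[si]
      ## gains inserted at this segment's start boundary
      gkey <- as.character(s0)
      if (!is.null(gains_at[[gkey]])) {
        flush_inv(); cur_inv <- NA_integer_
        emit(gains_at[[gkey]], gain_ids[[gkey]], "+")
      }
      if (!presence[si, t]) { flush_inv(); cur_inv <- NA_integer_; next }
      iv0 <- inv_of(s0, s1)
      sseq <- substr(anc$seq, s0 + 1L, s1)
      if (is.na(iv0)) {
        flush_inv(); cur_inv <- NA_integer_
        emit(sseq, seg$seg_id[si], "+")
      } else {
        if (!identical(iv0, cur_inv)) flush_inv()
        cur_inv <- iv0
        if (is.null(pend_inv)) pend_inv <- list(seqs = character(),
                                                segids = character())
        pend_inv$seqs <- c(pend_inv$seqs, sseq)
        pend_inv$segids <- c(pend_inv$segids, seg$seg_id[si])
      }
    }
    flush_inv()
    gkey <- as.character(L)
    if (!is.null(gains_at[[gkey]])) emit(gains_at[[gkey]], gain_ids[[gkey]],
                                         "+")
    offs <- cumsum(c(0L, nchar(parts)))
    placements <- rbind(placements, data.frame(
      seg_id = part_seg, taxon = t, start = offs[-length(offs)],
      end = offs[-1], strand = part_strand, stringsAsFactors = FALSE))
    genomes[[t]] <- circular_genome(paste(parts, collapse = ""), id = t)
  }

  if (!any(rowSums(presence[anc_rows, , drop = FALSE]) ==
           length(taxa))) {
    warning("no ancestral segment survives in all taxa")
  }

  gene_presence <- NULL
  if (!is.null(gene_tab) && nrow(gene_tab)) {
    gene_presence <- matrix(TRUE, nrow(gene_tab), length(taxa),
                            dimnames = list(gene_tab$gene, taxa))
    for (t in taxa) gene_presence[events[[t]]$gene_del, t] <- FALSE
  }

  list(genomes = genomes,
       truth = list(segments = seg, presence = presence,
                    placements = placements,
                    gene_presence = gene_presence, events = events,
                    ancestor = anc))
}
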