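#' Specification of a synthetic circular mitogenome
#'
#' Describes a circular genome to be generated with planted features whose
#' coordinates become ground truth: dispersed repeat pairs (direct or
#' inverted, at a chosen identity), plastid-derived insertions and
#' protein-coding-gene-like ORFs.  The defaults emulate a plant mitogenome:
#' a ~200 kb circle at ~45% GC.
#'
#' @param length Genome length in bases.
#' @param gc Target GC fraction in `[0, 1]`.
#' @param repeats `data.frame` (or NULL) with columns `length`,
#'   `orientation` (`"direct"`/`"inverted"`), `identity` (fraction in
#'   `[0.90, 1]`) and optionally `spacing` (approximate distance between
#'   copy starts in bases; `NA` = random).
#' @param plastid_inserts `data.frame` (or NULL) with columns `length`
#'   (100--3000 bases) and `donor` (donor identifier).
#' @param genes `data.frame` (or NULL) with columns `gene`, `length` and
#'   `strand`.  Lengths divisible by 3 are planted as intact ORFs
#'   (ATG ... stop).
#' @param seed Integer seed; every generator in the package is
#'   deterministic given its seed.
#' @return A `GenomeSpec` list.
#' @export
genome_spec <- function(length = 200000L, gc = 0.45, repeats = NULL,
                        plastid_inserts = NULL, genes = NULL, seed = 1L) {
  stopifnot(length > 0, gc >= 0, gc <= 1)
  if (!is.null(repeats) && nrow(repeats)) {
    if (is.null(repeats$spacing)) repeats$spacing <- NA_real_
    if (is.null(repeats$identity)) repeats$identity <- 1.0
    stopifnot(all(repeats$orientation %in% c("direct", "inverted")),
              all(repeats$identity >= 0.90 & repeats$identity <= 1))
  }
  planted <- sum(if (is.null(repeats)) 0 else 2 * sum(repeats$length),
                 if (is.null(plastid_inserts)) 0 else sum(plastid_inserts$length),
                 if (is.null(genes)) 0 else sum(genes$length))
  if (planted >= length) {
    stop("infeasible packing: planted features total ", planted,
         " bases on a ", length, " bp genome")
  }
  structure(list(length = as.integer(length), gc = gc, repeats = repeats,
                 plastid_inserts = plastid_inserts, genes = genes,
                 seed = as.integer(seed)),
            class = "GenomeSpec")
}

## Sample a start for an interval of width w avoiding `occupied` (IRanges),
## with a guard margin so neighbouring planted features cannot chain into
## one longer homology.  Returns 0-based start, or stops with a packing
## error after `tries` rejections.
place_interval <- function(w, L, occupied, margin = 30L, tries = 2000L,
                           lo = 0L, hi = NULL) {
  if (is.null(hi)) hi <- L - w
  if (hi < lo) stop("infeasible packing: feature of ", w,
                    " bp does not fit on a ", L, " bp genome")
  for (i in seq_len(tries)) {
    s <- sample.int(hi - lo + 1L, 1L) + lo - 1L
    cand <- IRanges::IRanges(s + 1L - margin, s + w + margin)
    if (length(occupied) == 0L ||
        sum(IRanges::countOverlaps(cand, occupied)) == 0L) {
      return(s)
    }
  }
  stop("infeasible packing: could not place a ", w,
       " bp feature without overlap after ", tries, " attempts")
}

## Mutate a sequence with substitutions only, to an exact target identity.
mutate_to_identity <- function(seq, identity) {
  n <- nchar(seq)
  k <- round((1 - identity) * n)
  if (k == 0L) return(seq)
  pos <- sample.int(n - 2L, k) + 1L  # keep the first/last base intact
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (p in pos) ch[p] <- sample(setdiff(DNA_BASES4, ch[p]), 1L)
  paste(ch, collapse = "")
}

## Random ORF of `len` bases (must be divisible by 3): ATG, no internal
## stop codons, terminal stop.
random_orf <- function(len, gc) {
  stopifnot(len %% 3 == 0L, len >= 9L)
  ncod <- len / 3L - 2L
  stops <- c("TAA", "TAG", "TGA")
  cod <- character(ncod)
  i <- 1L
  while (i <= ncod) {
    c3 <- random_dna(3L, gc)
    if (!(c3 %in% stops)) { cod[i] <- c3; i <- i + 1L }
  }
  paste0("ATG", paste(cod, collapse = ""), sample(stops, 1L))
}

#' Generate a synthetic circular genome with ground truth
#'
#' Builds a random backbone at the requested GC and plants the features of
#' the spec at non-overlapping positions.  Repeat pairs are planted as two
#' copies of one random template, the second copy substitution-mutated to
#' the requested identity and reverse-complemented for inverted pairs.
#' All planted coordinates, sequences and donor fragments are recorded in
#' `$truth`; the feature table doubles as a GFF3-ready annotation.
#'
#' @param spec A [genome_spec()].
#' @return A [circular_genome()] with `$features` and `$truth` filled in.
#'   `$truth$repeats` is a `RepeatPair` table (see [find_repeats()]),
#'   `$truth$plastid` records insert coordinates and donor sequences,
#'   `$truth$genes` records gene coordinates and sequences.
#' @export
generate_genome <- function(spec) {
  stopifnot(inherits(spec, "GenomeSpec"))
  set.seed(spec$seed)
  L <- spec$length
  seq_ch <- strsplit(random_dna(L, spec$gc), "", fixed = TRUE)[[1]]
  occupied <- IRanges::IRanges()
  features <- empty_features()
  truth <- list(repeats = empty_repeat_pairs(), plastid = NULL, genes = NULL)

  put <- function(s, frag) {
    ch <- strsplit(frag, "", fixed = TRUE)[[1]]
    seq_ch[(s + 1L):(s + length(ch))] <<- ch
    occupied <<- c(occupied, IRanges::IRanges(s + 1L, s + nchar(frag)))
  }
  add_feat <- function(id, type, s, w, strand = "+") {
    features <<- rbind(features, data.frame(
      feature_id = id, type = type, start = s, end = s + w,
      strand = strand, stringsAsFactors = FALSE))
  }

  rp <- spec$repeats
  if (!is.null(rp) && nrow(rp)) {
    for (i in seq_len(nrow(rp))) {
      w <- as.integer(rp$length[i])
      template <- random_dna(w, spec$gc)
      copy2 <- mutate_to_identity(template, rp$identity[i])
      if (rp$orientation[i] == "inverted") copy2 <- revcomp(copy2)
      sp <- rp$spacing[i]
      s1 <- place_interval(w, L, occupied,
                           hi = if (is.na(sp)) NULL else L - w - sp - 200L)
      put(s1, template)
      if (is.na(sp)) {
        ## dispersed pair: circular start distance at least twice the
        ## repeat length, so the pair is never tandem-like
        for (try in 1:2000) {
          s2 <- place_interval(w, L, occupied)
          dd <- abs(s2 - s1)
          if (min(dd, L - dd) >= 2L * w + 100L) break
          s2 <- NA_integer_
        }
        if (is.na(s2)) stop("infeasible packing: could not disperse a ",
                            w, " bp repeat pair")
      } else {
        s2 <- place_interval(w, L, occupied, lo = s1 + round(sp) - 100L,
                             hi = min(L - w, s1 + round(sp) + 100L))
      }
      put(s2, copy2)
      ## force a mismatch just outside each planted copy so the planted
      ## coordinates are the true maximal extent of the homology
      comp1 <- c(A = "T", C = "G", G = "C", T = "A")
      at <- function(p) seq_ch[((p %% L) + L) %% L + 1L]
      fix_pos <- function(p, forbidden) {
        p <- ((p %% L) + L) %% L
        if (seq_ch[p + 1L] == forbidden) {
          seq_ch[p + 1L] <<- sample(setdiff(DNA_BASES4, forbidden), 1L)
        }
      }
      if (rp$orientation[i] == "direct") {
        fix_pos(s2 - 1L, at(s1 - 1L))
        fix_pos(s2 + w, at(s1 + w))
      } else {
        fix_pos(s2 - 1L, comp1[[at(s1 + w)]])
        fix_pos(s2 + w, comp1[[at(s1 - 1L)]])
      }
      id <- paste0("r", i)
      nmm <- round((1 - rp$identity[i]) * w)
      truth$repeats <- rbind(truth$repeats, data.frame(
        id = id, start1 = min(s1, s2), end1 = min(s1, s2) + w,
        start2 = max(s1, s2), end2 = max(s1, s2) + w,
        orientation = rp$orientation[i], length = w,
        identity = (w - nmm) / w, stringsAsFactors = FALSE))
      add_feat(paste0(id, "_copy1"), "repeat", min(s1, s2), w)
      add_feat(paste0(id, "_copy2"), "repeat", max(s1, s2), w,
               if (rp$orientation[i] == "inverted") "-" else "+")
    }
  }

  pl <- spec$plastid_inserts
  if (!is.null(pl) && nrow(pl)) {
    ptab <- data.frame(insert_id = character(), donor = character(),
                       start = integer(), end = integer(),
                       stringsAsFactors = FALSE)
    donor_seq <- character()
    for (i in seq_len(nrow(pl))) {
      w <- as.integer(pl$length[i])
      frag <- random_dna(w, spec$gc)
      s <- place_interval(w, L, occupied)
      put(s, frag)
      id <- paste0("pt", i)
      ptab <- rbind(ptab, data.frame(insert_id = id,
                                     donor = as.character(pl$donor[i]),
                                     start = s, end = s + w,
                                     stringsAsFactors = FALSE))
      donor_seq[id] <- frag
      add_feat(id, "plastid_derived", s, w)
    }
    truth$plastid <- list(table = ptab, fragments = donor_seq)
  }

  gn <- spec$genes
  if (!is.null(gn) && nrow(gn)) {
    gtab <- data.frame(gene = character(), start = integer(),
                       end = integer(), strand = character(),
                       stringsAsFactors = FALSE)
    gseq <- character()
    for (i in seq_len(nrow(gn))) {
      w <- as.integer(gn$length[i])
      gs <- if (w %% 3 == 0L && w >= 9L) random_orf(w, spec$gc)
            else random_dna(w, spec$gc)
      strand <- as.character(gn$strand[i])
      s <- place_interval(w, L, occupied)
      put(s, if (strand == "-") revcomp(gs) else gs)
      gtab <- rbind(gtab, data.frame(gene = as.character(gn$gene[i]),
                                     start = s, end = s + w,
                                     strand = strand,
                                     stringsAsFactors = FALSE))
      gseq[as.character(gn$gene[i])] <- gs
      add_feat(as.character(gn$gene[i]), "coding_exon", s, w, strand)
    }
    truth$genes <- list(table = gtab, sequences = gseq)
  }

  circular_genome(paste(seq_ch, collapse = ""),
                  id = paste0("synthetic_", spec$seed),
                  features = features, truth = truth)
}
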