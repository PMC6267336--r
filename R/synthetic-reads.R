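#' Parameters for ONT-like long-read simulation
#'
#' Read lengths are lognormal: `sdlog = length_sd` and
#' `meanlog = log(length_mean) - length_sd^2/2`, so the arithmetic mean of
#' simulated lengths equals `length_mean` while keeping the heavy right
#' tail characteristic of nanopore runs.  Error rates are per-base
#' substitution / insertion / deletion probabilities.  `ac_fractions`
#' gives, per repeat id, the fraction of molecules sampled from that
#' repeat's alternative conformation instead of the master circle.
#'
#' @param n_reads Number of reads (overrides `target_depth` when given).
#' @param target_depth Fold coverage used to derive `n_reads` from the
#'   genome length when `n_reads` is `NULL`.
#' @param length_mean Mean read length in bases (ONT-scale default 20 kb).
#' @param length_sd `sdlog` of the lognormal length distribution.
#' @param sub_rate,ins_rate,del_rate Per-base error rates; their sum must
#'   be < 0.5.
#' @param ac_fractions Named numeric vector, repeat id -> fraction in
#'   `[0, 0.5)` (the master conformation stays the majority form).
#' @param q_mean,q_sd Mean and sd of per-read mean Phred quality.
#' @param seed Integer seed.
#' @return A `ReadSimParams` list.
#' @export
read_sim_params <- function(n_reads = NULL, target_depth = NULL,
                            length_mean = 20000, length_sd = 0.35,
                            sub_rate = 0.05, ins_rate = 0.025,
                            del_rate = 0.025, ac_fractions = numeric(),
                            q_mean = 12, q_sd = 3, seed = 1L) {
  stopifnot(sub_rate >= 0, ins_rate >= 0, del_rate >= 0,
            sub_rate + ins_rate + del_rate < 0.5)
  if (length(ac_fractions)) {
    stopifnot(!is.null(names(ac_fractions)),
              all(ac_fractions >= 0), all(ac_fractions < 0.5),
              sum(ac_fractions) < 0.5)
  }
  structure(list(n_reads = n_reads, target_depth = target_depth,
                 length_mean = length_mean, length_sd = length_sd,
                 sub_rate = sub_rate, ins_rate = ins_rate,
                 del_rate = del_rate, ac_fractions = ac_fractions,
                 q_mean = q_mean, q_sd = q_sd, seed = as.integer(seed)),
            class = "ReadSimParams")
}

## Apply substitution/insertion/deletion errors to one sequence.
apply_errors <- function(seq, sub, ins, del) {
  if (sub + ins + del == 0) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(ch)
  u <- stats::runif(n)
  is_sub <- u < sub
  is_del <- u >= sub & u < sub + del
  is_ins <- u >= sub + del & u < sub + del + ins
  if (any(is_sub)) {
    ch[is_sub] <- vapply(ch[is_sub],
                         function(b) sample(setdiff(DNA_BASES4, b), 1L), "",
                         USE.NAMES = FALSE)
  }
  if (any(is_ins)) {
    ch[is_ins] <- paste0(sample(DNA_BASES4, sum(is_ins), replace = TRUE),
                         ch[is_ins])
  }
  if (any(is_del)) ch <- ch[!is_del]
  paste(ch, collapse = "")
}

#' Simulate ONT-like long reads from a mixture of genome conformations
#'
#' Molecules are drawn from the master conformation (MC) or, with the
#' probabilities in `params$ac_fractions`, from the alternative
#' conformation (AC) generated by recombination at one of the supplied
#' repeat pairs.  For direct-repeat ACs (two subgenomic circles) the
#' source circle is chosen proportional to its length.  Start positions
#' are uniform on the source circle; reads longer than the circle wrap.
#' Each read carries its truth in extra columns (`src`, `true_start`,
#' `strand`), which [write_fastq()] encodes into the header.
#'
#' @param genome A [circular_genome()] (the master conformation).
#' @param repeats `RepeatPair` table (see [find_repeats()]); only ids named
#'   in `params$ac_fractions` are used.
#' @param params A [read_sim_params()].
#' @return Reads `data.frame` (`read_id`, `seq`, `qual`, `src`,
#'   `true_start`, `strand`).
#' @export
simulate_long_reads <- function(genome, repeats = empty_repeat_pairs(),
                                params = read_sim_params()) {
  genome <- as_genome(genome)
  set.seed(params$seed)
  L <- genome$length
  af <- params$ac_fractions
  if (length(af) && !all(names(af) %in% repeats$id)) {
    stop("ac_fractions name repeat id(s) not present in `repeats`: ",
         paste(setdiff(names(af), repeats$id), collapse = ", "))
  }
  n <- if (!is.null(params$n_reads)) params$n_reads
       else round(params$target_depth * L / params$length_mean)
  empty <- data.frame(read_id = character(), seq = character(),
                      qual = character(), src = character(),
                      true_start = integer(), strand = character(),
                      stringsAsFactors = FALSE)
  if (n == 0L) return(empty)

  ## source circles: MC + each AC's circle(s)
  circles <- list(list(src = "MC", seq = genome$seq))
  prob <- c(1 - sum(af))
  for (rid in names(af)) {
    conf <- build_alternative_conformation(
      genome, repeats[repeats$id == rid, , drop = FALSE])
    cl <- vapply(conf$circles, function(c) nchar(c$seq), 0)
    for (j in seq_along(conf$circles)) {
      circles[[length(circles) + 1L]] <-
        list(src = paste0("AC:", rid), seq = conf$circles[[j]]$seq)
      prob <- c(prob, af[[rid]] * cl[j] / sum(cl))
    }
  }

  which_circle <- sample.int(length(circles), n, replace = TRUE, prob = prob)
  lens <- pmax.int(50L, round(stats::rlnorm(
    n, meanlog = log(params$length_mean) - params$length_sd^2 / 2,
    sdlog = params$length_sd)))
  strand <- sample(c("+", "-"), n, replace = TRUE)
  rq <- stats::rnorm(n, params$q_mean, params$q_sd)
  u <- stats::runif(n)
  seqs <- character(n)
  starts <- integer(n)
  for (ci in seq_along(circles)) {
    idx <- which(which_circle == ci)
    if (!length(idx)) next
    Lc <- nchar(circles[[ci]]$seq)
    s <- as.integer(floor(u[idx] * Lc))
    D <- strrep(circles[[ci]]$seq, ceiling(max(lens[idx]) / Lc) + 1L)
    seqs[idx] <- substring(D, s + 1L, s + lens[idx])
    starts[idx] <- s
  }
  neg <- strand == "-"
  if (any(neg)) {
    seqs[neg] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(seqs[neg])))
  }
  if (params$sub_rate + params$ins_rate + params$del_rate > 0) {
    seqs <- vapply(seqs, apply_errors, "", params$sub_rate,
                   params$ins_rate, params$del_rate, USE.NAMES = FALSE)
  }
  ## one quality value per read (its mean quality), constant along the read
  qch <- strsplit(phred_string(pmax(2, rq)), "", fixed = TRUE)[[1]]
  quals <- strrep(qch, nchar(seqs))
  data.frame(read_id = sprintf("read_%06d", seq_len(n)), seq = seqs,
             qual = quals,
             src = vapply(circles, `[[`, "", "src")[which_circle],
             true_start = starts, strand = strand, stringsAsFactors = FALSE)
}

#' Simulate paired short reads at uniform coverage
#'
#' Error-free Illumina-like pairs with uniform fragment starts on the
#' circle; the number of pairs is `depth * L / (2 * read_len)`.
#'
#' @param genome A [circular_genome()] or character template sequence.
#' @param depth Target fold coverage (> 0).
#' @param read_len Read length in bases (must not exceed genome length).
#' @param insert Fragment length (default `2.5 * read_len`).
#' @param seed Integer seed.
#' @return Reads `data.frame` with both mates as rows (`read_id`, `seq`,
#'   `qual`, `mate`, `true_start`).
#' @export
simulate_short_reads <- function(genome, depth, read_len = 150L,
                                 insert = NULL, seed = 1L) {
  genome <- as_genome(genome)
  stopifnot(depth > 0)
  L <- genome$length
  if (read_len > L) stop("read_len (", read_len, ") exceeds genome length (",
                         L, ")")
  if (is.null(insert)) insert <- min(L, round(2.5 * read_len))
  insert <- max(insert, 2L * read_len)
  set.seed(seed)
  n <- round(depth * L / (2 * read_len))
  if (n == 0L) {
    return(data.frame(read_id = character(), seq = character(),
                      qual = character(), mate = integer(),
                      true_start = integer(), stringsAsFactors = FALSE))
  }
  fs <- sample.int(L, n, replace = TRUE) - 1L
  r1 <- vapply(fs, function(s) circ_substr(genome$seq, s, read_len), "")
  r2 <- vapply(fs, function(s)
    revcomp(circ_substr(genome$seq, s + insert - read_len, read_len)), "")
  q <- strrep("I", read_len)
  data.frame(
    read_id = rep(sprintf("frag_%06d", seq_len(n)), 2L),
    seq = c(r1, r2), qual = q, mate = rep(1:2, each = n),
    true_start = c(fs, (fs + insert - read_len) %% L),
    stringsAsFactors = FALSE)
}
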