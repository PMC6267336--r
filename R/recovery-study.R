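#' Parameter-recovery study for the recombination-frequency estimator
#'
#' Runs the full simulate-classify-estimate pipeline repeatedly against a
#' fixed study genome (a 6 kb circle carrying one 300 bp inverted repeat
#' at identity 1) and known alternative-conformation fractions, and
#' summarises estimator bias and confidence-interval coverage.  Reads are
#' simulated error-free so the study isolates the sampling properties of
#' the estimator; classification accuracy under sequencing error is a
#' separate concern.  The number of reads per replicate is chosen from the
#' junction geometry so that about `n_informative` reads span a junction.
#'
#' @param fractions True alternative-conformation fractions to recover.
#' @param n_seeds Replicates per fraction.
#' @param n_informative Target number of informative reads per replicate.
#' @param seed Master seed; all replicate seeds derive from it.
#' @param length_mean,length_sd Read-length distribution of the study.
#' @return `data.frame` with one row per fraction: `true_frac`,
#'   `mean_estimate`, `bias`, `ci_coverage`, `mean_n_informative`,
#'   `n_seeds`.
#' @export
run_frequency_recovery <- function(fractions = c(0.005, 0.01, 0.02, 0.044),
                                   n_seeds = 100L, n_informative = 5000L,
                                   seed = 1L, length_mean = 2500,
                                   length_sd = 0.2) {
  gsp <- genome_spec(
    length = 6000L, gc = 0.45,
    repeats = data.frame(length = 300L, orientation = "inverted",
                         identity = 1, spacing = 3000L),
    seed = 20181118L)
  g <- generate_genome(gsp)
  tr <- g$truth$repeats
  flank <- 150L
  J <- extract_junctions(g, tr[1, ], flank = flank)

  ## expected informative fraction from the junction geometry: a read of
  ## length l spans a junction window (width w) starting anywhere in an
  ## arc of length l - w + 1; two junctions, union of the two arcs
  set.seed(seed)
  wlen <- 2L * flank + tr$length[1]
  L <- g$length
  j1 <- tr$start1[1] - flank           # window starts (mod L)
  j2 <- tr$start2[1] - flank
  lens <- pmax.int(50L, round(stats::rlnorm(
    20000L, meanlog = log(length_mean) - length_sd^2 / 2,
    sdlog = length_sd)))
  p_span <- function(l) {
    a <- max(0L, min(l - wlen + 1L, L))  # arc length per junction
    if (a == 0L) return(0)
    sep <- (j2 - j1) %% L
    ov <- max(0L, a - min(sep, L - sep)) + max(0L, a - max(sep, L - sep))
    min(L, 2L * a - ov) / L
  }
  p_inf <- mean(vapply(lens, p_span, 0))
  n_reads <- as.integer(ceiling(n_informative / p_inf))
  rep_seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                                 length(fractions) * n_seeds),
                      nrow = n_seeds)

  out <- data.frame()
  for (fi in seq_along(fractions)) {
    f <- fractions[fi]
    est <- numeric(n_seeds); cover <- logical(n_seeds)
    ninf <- integer(n_seeds)
    for (s in seq_len(n_seeds)) {
      pr <- read_sim_params(n_reads = n_reads, length_mean = length_mean,
                            length_sd = length_sd, sub_rate = 0,
                            ins_rate = 0, del_rate = 0,
                            ac_fractions = c(r1 = f),
                            seed = rep_seeds[s, fi])
      reads <- simulate_long_reads(g, tr, pr)
      fe <- estimate_frequency(classify_reads(reads, J))
      est[s] <- fe$frequency
      cover[s] <- fe$ci_lower <= f && f <= fe$ci_upper
      ninf[s] <- fe$n_mc + fe$n_ac
    }
    out <- rbind(out, data.frame(
      true_frac = f, mean_estimate = mean(est),
      bias = mean(est) - f, ci_coverage = mean(cover),
      mean_n_informative = mean(ninf), n_seeds = n_seeds))
  }
  out
}
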