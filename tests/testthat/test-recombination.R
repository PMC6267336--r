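test_that("long-read filtering applies inclusive length and quality bounds", {
  reads <- data.frame(
    read_id = c("short_goodq", "bound", "long_badq"),
    seq = c(strrep("A", 499), strrep("A", 500), strrep("A", 600)),
    qual = c(strrep("?", 499),      # Q30
             strrep("(", 500),      # Q7.0 exactly
             strrep("%", 600)),     # Q4
    stringsAsFactors = FALSE)
  kept <- filter_long_reads(reads, min_len = 500L, min_q = 7)
  expect_identical(kept$read_id, "bound")
  expect_equal(nrow(filter_long_reads(reads[0, , drop = FALSE])), 0L)
})

test_that("noiseless reads classify exactly against simulation truth", {
  g <- fx_genome()
  tr <- g$truth$repeats
  J <- extract_junctions(g, tr[tr$orientation == "inverted", ],
                         flank = 100L)
  pr <- read_sim_params(n_reads = 2000L, length_mean = 4000,
                        length_sd = 0.2, sub_rate = 0, ins_rate = 0,
                        del_rate = 0, ac_fractions = c(r1 = 0.06),
                        seed = 99L)
  reads <- simulate_long_reads(g, tr, pr)
  sup <- classify_reads(reads, J)
  lab <- sup$label != "uninformative"
  expect_gt(sum(lab), 200L)
  ## zero classification errors against truth labels
  expect_identical(sup$label[lab] == "AC",
                   reads$src[lab] == "AC:r1")
  ## frequency is invariant to read order
  perm <- sample(nrow(reads))
  sup_p <- classify_reads(reads[perm, ], J)
  expect_equal(sum(sup_p$label == "AC"), sum(sup$label == "AC"))
  expect_equal(sum(sup_p$label == "MC"), sum(sup$label == "MC"))
})

test_that("a read inside a flank never spanning the repeat is uninformative", {
  g <- fx_genome()
  pair <- g$truth$repeats[g$truth$repeats$orientation == "inverted", ]
  J <- extract_junctions(g, pair, flank = 200L)
  ## read entirely within the left flank of copy 1
  flank_read <- circ_substr(g$seq, pair$start1 - 1500L, 1200L)
  sup <- classify_read(list(read_id = "fl", seq = flank_read), J)
  expect_identical(sup$label, "uninformative")
  ## read spanning the full window is informative
  span_read <- circ_substr(g$seq, pair$start1 - 300L,
                           (pair$end1 - pair$start1) + 600L)
  sup2 <- classify_read(list(read_id = "sp", seq = span_read), J)
  expect_identical(sup2$label, "MC")
})

test_that("classification under ONT-like error stays >99% correct", {
  g <- fx_genome()
  tr <- g$truth$repeats
  J <- extract_junctions(g, tr[tr$orientation == "inverted", ],
                         flank = 100L)
  pr <- read_sim_params(n_reads = 1000L, length_mean = 4000,
                        length_sd = 0.2, sub_rate = 0.03, ins_rate = 0.01,
                        del_rate = 0.01, ac_fractions = c(r1 = 0.2),
                        seed = 5L)
  reads <- simulate_long_reads(g, tr, pr)
  sup <- classify_reads(reads, J)
  lab <- sup$label != "uninformative"
  expect_gt(sum(lab), 30L)
  acc <- mean((sup$label[lab] == "AC") == (reads$src[lab] == "AC:r1"))
  expect_gt(acc, 0.99)
  expect_true(all(sup$identity[lab] >= 0.75))
})

test_that("frequency estimates follow AC/(AC+MC) with sensible intervals", {
  mk <- function(n_mc, n_ac) {
    n <- n_mc + n_ac
    data.frame(read_id = as.character(seq_len(n)),
               repeat_id = rep("r1", n),
               label = c(rep("MC", n_mc), rep("AC", n_ac)),
               score_mc = rep(NA_real_, n), score_ac = rep(NA_real_, n),
               identity = rep(1, n), stringsAsFactors = FALSE)
  }
  expect_equal(estimate_frequency(mk(100L, 0L))$frequency, 0)
  e <- estimate_frequency(mk(95L, 5L))
  expect_equal(e$frequency, 0.05)
  expect_true(e$ci_lower <= 0.05 && 0.05 <= e$ci_upper)
  ## exact interval for tiny n
  e2 <- estimate_frequency(mk(10L, 2L))
  bt <- binom.test(2, 12)$conf.int
  expect_equal(c(e2$ci_lower, e2$ci_upper), as.numeric(bt))
  ## zero informative reads: flagged, not an error
  e0 <- estimate_frequency(mk(0L, 0L))
  expect_false(e0$defined)
  expect_true(is.na(e0$frequency))
  ## mixed repeats are rejected
  bad <- mk(1L, 1L); bad$repeat_id <- c("r1", "r2")
  expect_error(estimate_frequency(bad), "several repeats")
})

test_that("length-frequency correlation reports both coefficients", {
  mk_est <- function(f) list(repeat_id = "x", n_mc = 100L, n_ac = 10L,
                             frequency = f, ci_lower = 0, ci_upper = 1,
                             defined = TRUE)
  lens <- seq(100, 700, by = 100)
  ests <- lapply(lens / 20000, mk_est)
  r <- correlate_length_frequency(ests, lens)
  expect_equal(r$pearson_r, 1)
  expect_equal(r$spearman_rho, 1)
  expect_equal(r$n, 7L)
  ## constant frequencies: flagged NA
  expect_warning(r0 <- correlate_length_frequency(
    lapply(rep(0.05, 4), mk_est), 1:4), "zero variance")
  expect_true(is.na(r0$pearson_r))
  expect_error(correlate_length_frequency(lapply(c(0.1, 0.2), mk_est),
                                          1:2), ">= 3")
})

test_that("master tiling finds the exact minimal circular read cover", {
  g <- generate_genome(genome_spec(length = 30000L, gc = 0.45, seed = 77L))
  pr <- read_sim_params(n_reads = 40L, length_mean = 9000, length_sd = 0.15,
                        sub_rate = 0, ins_rate = 0, del_rate = 0,
                        seed = 4L)
  reads <- simulate_long_reads(g, params = pr)
  til <- find_master_tiling(reads, g)
  expect_true(til$feasible)
  expect_equal(til$n_placed, 40L)
  ## all 40 reads place; the greedy-exact cover equals the brute force on
  ## a 12-read subset
  sub <- reads[1:12, , drop = FALSE]
  til12 <- find_master_tiling(sub, g)
  brute <- oracle_min_cover(sub$true_start, nchar(sub$seq), 30000L)
  if (til12$feasible) {
    expect_equal(til12$count, brute)
  } else {
    expect_true(is.na(brute))
  }
  ## single wraparound read covers alone
  one <- data.frame(read_id = "w", seq = circ_substr(g$seq, 123L, 30050L),
                    qual = "I", stringsAsFactors = FALSE)
  expect_equal(find_master_tiling(one, g)$count, 1L)
  ## coverage gap is reported as an interval
  gap <- minimal_circular_cover(c(0L, 15000L), c(5000L, 5000L), 30000L)
  expect_false(gap$feasible)
  expect_equal(nrow(gap$gaps), 2L)
})
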