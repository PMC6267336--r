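test_that("generate_genome plants features at recorded coordinates", {
  g <- fx_genome()
  expect_s3_class(g, "CircularGenome")
  expect_equal(g$length, 20000L)
  expect_lt(abs(gc_content(g$seq) - 0.45), 0.01)

  tr <- g$truth$repeats
  expect_equal(nrow(tr), 2L)
  inv <- tr[tr$orientation == "inverted", ]
  c1 <- substr(g$seq, inv$start1 + 1, inv$end1)
  c2 <- substr(g$seq, inv$start2 + 1, inv$end2)
  expect_identical(revcomp(c1), c2)     # exact inverted pair
  dir <- tr[tr$orientation == "direct", ]
  expect_identical(substr(g$seq, dir$start1 + 1, dir$end1),
                   substr(g$seq, dir$start2 + 1, dir$end2))

  ## determinism and the degenerate featureless spec
  g2 <- generate_genome(genome_spec(
    length = 20000L, gc = 0.45,
    repeats = data.frame(length = c(681L, 300L),
                         orientation = c("inverted", "direct"),
                         identity = c(1, 1)),
    seed = 11L))
  expect_identical(g$seq, g2$seq)
  g0 <- generate_genome(genome_spec(length = 10000L, gc = 0.5, seed = 1L))
  expect_equal(g0$length, 10000L)
  expect_equal(nrow(g0$features), 0L)
})

test_that("infeasible packing raises an explicit error", {
  expect_error(genome_spec(length = 1000L,
                           repeats = data.frame(length = 600L,
                                                orientation = "direct",
                                                identity = 1)),
               "packing")
  sp <- genome_spec(length = 3000L,
                    repeats = data.frame(length = c(700L, 700L),
                                         orientation = c("direct", "direct"),
                                         identity = c(1, 1)),
                    seed = 1L)
  expect_error(generate_genome(sp), "packing")
})

test_that("noiseless long reads are exact circular substrings with honest truth labels", {
  g <- fx_genome()
  tr <- g$truth$repeats
  pr <- read_sim_params(n_reads = 100L, length_mean = 4000, length_sd = 0.2,
                        sub_rate = 0, ins_rate = 0, del_rate = 0, seed = 21L)
  reads <- simulate_long_reads(g, tr, pr)
  expect_equal(nrow(reads), 100L)
  D2 <- strrep(g$seq, 2L)
  for (i in seq_len(nrow(reads))) {
    s <- reads$seq[i]
    if (reads$strand[i] == "-") s <- revcomp(s)
    expect_true(grepl(s, D2, fixed = TRUE))
    ## header start coordinate is the true origin
    expect_identical(substr(D2, reads$true_start[i] + 1,
                            reads$true_start[i] + nchar(s)), s)
  }
  ## empty request, and unknown repeat id in the mixture
  expect_equal(nrow(simulate_long_reads(g, tr,
                                        read_sim_params(n_reads = 0L))), 0L)
  expect_error(simulate_long_reads(g, tr, read_sim_params(
    n_reads = 5L, ac_fractions = c(nosuch = 0.1))), "nosuch")
})

test_that("long-read truth AC fraction and length mean match the request", {
  g <- fx_genome()
  tr <- g$truth$repeats
  pr <- read_sim_params(n_reads = 10000L, length_mean = 3000,
                        length_sd = 0.3, sub_rate = 0, ins_rate = 0,
                        del_rate = 0, ac_fractions = c(r1 = 0.05),
                        seed = 33L)
  reads <- simulate_long_reads(g, tr, pr)
  frac <- mean(reads$src == "AC:r1")
  se <- sqrt(0.05 * 0.95 / 10000)
  expect_lt(abs(frac - 0.05), 3 * se)
  expect_lt(abs(mean(nchar(reads$seq)) - 3000) / 3000, 0.1)
  ## determinism
  reads2 <- simulate_long_reads(g, tr, pr)
  expect_identical(reads$seq, reads2$seq)
})

test_that("short-read simulation hits the requested depth uniformly", {
  g <- generate_genome(genome_spec(length = 10000L, gc = 0.45, seed = 8L))
  sr <- simulate_short_reads(g, depth = 50, read_len = 150L, seed = 2L)
  expect_equal(nrow(sr), 2L * round(50 * 10000 / (2 * 150)))
  total <- sum(nchar(sr$seq))
  expect_lt(abs(total / 10000 - 50) / 50, 0.1)
  expect_error(simulate_short_reads(g, depth = 10, read_len = 20000L),
               "exceeds")
  sr2 <- simulate_short_reads(g, depth = 50, read_len = 150L, seed = 2L)
  expect_identical(sr$seq, sr2$seq)
})

test_that("genome family bookkeeping records gains, losses and gene deletions", {
  ## no evolution: identical genomes, all segments everywhere
  fs0 <- family_spec(n_taxa = 4L,
                     ancestor = genome_spec(length = 20000L, seed = 5L),
                     gain_rate = 0, loss_rate = 0, gene_del_rate = 0,
                     inv_rate = 0, seed = 1L)
  fam0 <- generate_genome_family(fs0)
  expect_length(fam0$genomes, 4L)
  expect_true(all(vapply(fam0$genomes, function(g)
    identical(g$seq, fam0$genomes[[1]]$seq), TRUE)))
  expect_true(all(fam0$truth$presence))

  ## eventful family: per-event truth
  fs <- family_spec(
    n_taxa = 5L,
    ancestor = genome_spec(length = 40000L, gc = 0.45,
                           genes = data.frame(gene = paste0("g", 1:6),
                                              length = rep(900L, 6),
                                              strand = "+"),
                           seed = 5L),
    gain_rate = 1, loss_rate = 1, gene_del_rate = 1, inv_rate = 0.5,
    seed = 42L)
  fam <- generate_genome_family(fs)
  tru <- fam$truth
  for (t in names(fam$genomes)) {
    ev <- tru$events[[t]]
    ## every gained segment is present in exactly its owner
    for (gi in seq_along(ev$gain)) {
      sid <- sprintf("gain_%s_%d", t, gi)
      expect_identical(unname(tru$presence[sid, ]),
                       names(fam$genomes) == t)
      ## and its sequence sits verbatim in the owner's genome
      pl <- tru$placements[tru$placements$seg_id == sid, ]
      expect_identical(substr(fam$genomes[[t]]$seq, pl$start + 1, pl$end),
                       ev$gain[[gi]]$seq)
    }
    ## gene deletions are reflected in the gene presence matrix
    for (gdel in ev$gene_del) {
      expect_false(tru$gene_presence[gdel, t])
    }
  }
  ## placements reconstruct each genome exactly
  for (t in names(fam$genomes)) {
    pl <- tru$placements[tru$placements$taxon == t, ]
    expect_equal(max(pl$end), fam$genomes[[t]]$length)
  }
  ## determinism
  fam2 <- generate_genome_family(fs)
  expect_identical(fam$genomes[[3]]$seq, fam2$genomes[[3]]$seq)
})

test_that("fastq and gff3 round-trip through the writers", {
  reads <- data.frame(read_id = c("a", "b"),
                      seq = c("ACGTACGT", "GGGTTTAA"),
                      qual = c("IIIIIIII", "########"),
                      src = c("MC", "AC:r1"),
                      stringsAsFactors = FALSE)
  fq <- tempfile(fileext = ".fastq")
  write_fastq(reads, fq)
  back <- read_fastq(fq)
  expect_identical(back$seq, reads$seq)
  expect_identical(back$src, reads$src)
  expect_error(read_fastq(writeLines_tmp(c("@a", "ACGT", "+"))),
               "multiple of 4")

  g <- fx_genome()
  gff <- tempfile(fileext = ".gff3")
  write_gff3(g$features, gff)
  back <- read_gff3(gff)
  expect_identical(back$start, g$features$start)
  expect_identical(back$end, g$features$end)
  expect_identical(back$type, g$features$type)
})
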