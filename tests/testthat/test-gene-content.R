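test_that("gene search separates present, fragmentary and absent", {
  set.seed(2)
  gene <- mitorecomb:::random_orf(900L, 0.45)
  contig <- paste0(rand_seq(3000, 601), gene, rand_seq(2500, 602))
  hits <- search_genes(c(ctg1 = contig), c(nad1 = gene))
  expect_identical(hits$status, "present")
  expect_equal(hits$identity, 1)
  expect_equal(hits$aligned_fraction, 1)
  ## orientation invariance, and invariance to splitting outside the hit
  expect_identical(search_genes(c(ctg1 = revcomp(contig)),
                                c(nad1 = gene))$status, "present")
  split_cont <- c(a = substr(contig, 1, 2000),
                  b = substr(contig, 2001, nchar(contig)))
  expect_identical(search_genes(split_cont, c(nad1 = gene))$status,
                   "present")
  ## 40% of the gene -> fragmentary
  frag <- paste0(rand_seq(2000, 603), substr(gene, 1, 360),
                 rand_seq(2000, 604))
  h3 <- search_genes(c(ctg1 = frag), c(nad1 = gene))
  expect_identical(h3$status, "fragmentary")
  expect_lt(abs(h3$aligned_fraction - 0.4), 0.02)
  ## absent
  expect_identical(search_genes(c(ctg1 = rand_seq(4000, 605)),
                                c(nad1 = gene))$status, "absent")
  expect_error(search_genes(c(ctg1 = contig),
                            c(nad1 = gene, nad1 = gene)), "unique")
})

test_that("depth validation tracks simulated coverage", {
  g <- generate_genome(genome_spec(
    length = 10000L, gc = 0.45,
    genes = data.frame(gene = "nad9", length = 900L, strand = "+"),
    seed = 8L))
  gt <- g$truth$genes$table
  gseq <- substr(g$seq, gt$start + 1L, gt$end)
  sr <- simulate_short_reads(g, depth = 40, read_len = 100L, seed = 2L)
  v <- validate_presence_by_depth(gseq, sr, genome_mean_depth = 40)
  expect_identical(v$status, "present")
  expect_lt(abs(v$ratio - 1), 0.25)
  ## ratio scales linearly with coverage
  sr2 <- simulate_short_reads(g, depth = 20, read_len = 100L, seed = 3L)
  v2 <- validate_presence_by_depth(gseq, sr2, genome_mean_depth = 40)
  expect_lt(abs(v2$ratio - 0.5), 0.15)
  ## read order invariance
  vperm <- validate_presence_by_depth(gseq, sr[sample(nrow(sr)), ], 40)
  expect_equal(vperm$gene_depth, v$gene_depth)
  ## gene deleted from the template: ratio ~ 0
  del <- paste0(substr(g$seq, 1, gt$start),
                substr(g$seq, gt$end + 1L, g$length))
  sr3 <- simulate_short_reads(circular_genome(del), depth = 40,
                              read_len = 100L, seed = 4L)
  v3 <- validate_presence_by_depth(gseq, sr3, genome_mean_depth = 40)
  expect_identical(v3$status, "absent")
  expect_lt(v3$ratio, 0.05)
  expect_error(validate_presence_by_depth(gseq, sr, 0), "> 0")
  expect_warning(v0 <- validate_presence_by_depth(
    gseq, sr[0, , drop = FALSE], 40), "no reads")
  expect_identical(v0$status, "absent")
})

test_that("plastid-derived fragments obey the length and stringency cutoffs", {
  g <- generate_genome(genome_spec(
    length = 30000L, gc = 0.45,
    plastid_inserts = data.frame(length = c(2555L, 80L),
                                 donor = c("d1", "d2")),
    seed = 3L))
  ptr <- g$truth$plastid
  plastome <- paste0(rand_seq(10000, 701), ptr$fragments[["pt1"]],
                     rand_seq(8000, 702), ptr$fragments[["pt2"]],
                     rand_seq(5000, 703))
  fr <- find_plastid_derived(g, plastome)
  ## the 2555 bp insert is recovered (local alignment may add a few
  ## coincidentally matching flank bases); the 80 bp insert is below
  ## min_len and excluded
  expect_equal(nrow(fr), 1L)
  expect_lte(fr$mito_start, ptr$table$start[1])
  expect_gte(fr$mito_end, ptr$table$end[1])
  expect_lt(fr$mito_end - fr$mito_start - 2555L, 50L)
  expect_gte(attr(fr, "total_bases"), 2555L)
  ## unrelated sequences: empty
  none <- find_plastid_derived(rand_seq(10000, 704), rand_seq(10000, 705))
  expect_equal(nrow(none), 0L)
  ## a 120 bp perfect transfer passes min_len but fails a stringency set
  ## beyond its maximal score
  mito <- plant_pair(rand_seq(8000, 706), rand_seq(120, 707), 1000L, 4000L)
  frag <- substr(mito, 1001, 1120)
  pl2 <- paste0(rand_seq(3000, 708), frag, rand_seq(3000, 709))
  expect_gt(nrow(find_plastid_derived(mito, pl2, min_score = 100L)), 0L)
  expect_equal(nrow(find_plastid_derived(mito, pl2, min_score = 130L)), 0L)
})

test_that("ORF finding is circular-aware and respects the length cutoff", {
  set.seed(4)
  orf <- mitorecomb:::random_orf(2064L, 0.45)
  ## in-frame stop immediately upstream pins the reported start
  seqq <- paste0(rand_seq(2000, 801), "TAATAA", orf, rand_seq(2000, 802))
  o <- find_orfs(seqq, min_len = 300L)
  expect_true(any(o$start == 2006L & o$length == 2064L & o$strand == "+"))
  ## reverse strand
  o2 <- find_orfs(revcomp(seqq), min_len = 300L)
  expect_true(any(o2$length == 2064L & o2$strand == "-"))
  ## an ORF crossing the origin is still found
  rot <- rotate_seq(seqq, 2006L + 1000L)   # origin now inside the ORF
  o3 <- find_orfs(rot, min_len = 300L)
  expect_true(any(o3$length == 2064L))
  ## only stop codons: nothing
  expect_equal(nrow(find_orfs(strrep("TAA", 200L), min_len = 300L)), 0L)
  expect_warning(find_orfs(rand_seq(900, 803), min_len = 100L),
                 "multiple of 3")
})

test_that("premature stops are flagged as pseudogenes", {
  set.seed(5)
  gene <- mitorecomb:::random_orf(600L, 0.45)
  expect_false(flag_pseudogene(gene, gene))
  mutant <- gene
  substr(mutant, 28, 30) <- "TAA"          # stop at codon 10
  expect_true(flag_pseudogene(mutant, gene))
  ## stop after 90% of the reference is not premature
  late <- gene
  substr(late, 583, 585) <- "TAA"
  expect_false(flag_pseudogene(late, gene))
})

test_that("presence matrices are complete, ordered and conflict-checked", {
  calls <- expand.grid(taxon = c("t1", "t2", "t3"),
                       gene = c("atp1", "cox1", "nad1", "rps1"),
                       stringsAsFactors = FALSE)
  calls$status <- "present"
  calls$status[calls$taxon == "t2" & calls$gene == "rps1"] <- "absent"
  calls$status[calls$taxon == "t3" & calls$gene == "atp1"] <- "pseudogene"
  m <- build_presence_matrix(calls)
  expect_equal(dim(m), c(4L, 3L))
  expect_identical(m["rps1", "t2"], "absent")
  expect_identical(m["atp1", "t3"], "pseudogene")
  ## missing cell errors with its name
  expect_error(build_presence_matrix(calls[-1, ]), "missing call")
  ## conflicting duplicates error; agreeing duplicates are deduplicated
  clash <- rbind(calls, data.frame(taxon = "t1", gene = "atp1",
                                   status = "absent"))
  expect_error(build_presence_matrix(clash), "conflicting")
  agree <- rbind(calls, calls[1, ])
  expect_silent(build_presence_matrix(agree))
})
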