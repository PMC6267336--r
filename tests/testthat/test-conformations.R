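test_that("inverted-pair recombination is an involution on the circle", {
  g <- fx_genome()
  pair <- g$truth$repeats[g$truth$repeats$orientation == "inverted", ]
  ac <- build_alternative_conformation(g, pair)
  expect_length(ac$circles, 1L)
  expect_equal(nchar(ac$circles[[1]]$seq), g$length)
  expect_false(same_circle(g$seq, ac$circles[[1]]$seq))
  ## apply again with the pair's coordinates on the AC circle
  p2 <- pair
  ra <- ac$circles[[1]]$repeat_at
  p2$start1 <- ra[1, 1]; p2$end1 <- ra[1, 2]
  p2$start2 <- ra[2, 1]; p2$end2 <- ra[2, 2]
  back <- build_alternative_conformation(
    circular_genome(ac$circles[[1]]$seq), p2)
  expect_true(same_circle(back$circles[[1]]$seq, g$seq))
})

test_that("direct-pair recombination yields two subgenomic circles with conserved length", {
  g <- fx_genome()
  pair <- g$truth$repeats[g$truth$repeats$orientation == "direct", ]
  ac <- build_alternative_conformation(g, pair)
  expect_length(ac$circles, 2L)
  lens <- vapply(ac$circles, function(c) nchar(c$seq), 0)
  expect_equal(sum(lens), g$length)
  d <- (pair$start2 - pair$start1) %% g$length
  expect_setequal(lens, c(d, g$length - d))

  ## a 60 bp toy built by hand: circle sizes d + r and L - d - r, where d
  ## is the inter-copy gap and r the repeat length
  r <- "ACGTACGTAC"                          # 10 bp repeat
  toy <- paste0(r, "TTTTTGGGGG", r, "CCCCCAAAAATTTTTGGGGGCCCCCAAAAA")
  tp <- data.frame(id = "t", start1 = 0L, end1 = 10L, start2 = 20L,
                   end2 = 30L, orientation = "direct", length = 10L,
                   identity = 1, stringsAsFactors = FALSE)
  act <- build_alternative_conformation(toy, tp)
  lens <- sort(vapply(act$circles, function(c) nchar(c$seq), 0))
  expect_equal(lens, c(20, 40))              # (d + r, L - d - r) = (10+10, 60-20)
  expect_true(same_circle(act$circles[[1]]$seq,
                          paste0(r, "TTTTTGGGGG")))
})

test_that("degenerate abutting copies raise an error naming the pair", {
  toy <- paste0("ACGTACGTAC", "ACGTACGTAC", strrep("T", 40))
  tp <- data.frame(id = "bad", start1 = 0L, end1 = 10L, start2 = 10L,
                   end2 = 20L, orientation = "direct", length = 10L,
                   identity = 1, stringsAsFactors = FALSE)
  expect_error(build_alternative_conformation(toy, tp), "bad")
})

test_that("junction windows are diagnostic: MC windows in MC only, AC windows in AC only", {
  g <- fx_genome()
  D2 <- strrep(g$seq, 2L)
  for (orient in c("inverted", "direct")) {
    pair <- g$truth$repeats[g$truth$repeats$orientation == orient, ]
    J <- extract_junctions(g, pair, flank = 100L)
    expect_named(J, c("MC-J1", "MC-J2", "AC-J1", "AC-J2"))
    wl <- (pair$end1 - pair$start1) + 200L
    expect_true(all(vapply(J, function(j) nchar(j$seq), 0) == wl))
    expect_true(grepl(J[["MC-J1"]]$seq, D2, fixed = TRUE))
    expect_true(grepl(J[["MC-J2"]]$seq, D2, fixed = TRUE))
    for (acj in c("AC-J1", "AC-J2")) {
      expect_false(grepl(J[[acj]]$seq, D2, fixed = TRUE))
      expect_false(grepl(revcomp(J[[acj]]$seq), D2, fixed = TRUE))
    }
    ## AC windows are literal substrings of the AC circles
    ac <- build_alternative_conformation(g, pair)
    acd <- paste(vapply(ac$circles, function(c) strrep(c$seq, 2L), ""),
                 collapse = "|")
    expect_true(grepl(J[["AC-J1"]]$seq, acd, fixed = TRUE))
    expect_true(grepl(J[["AC-J2"]]$seq, acd, fixed = TRUE))
  }
  ## window length arithmetic: flank 300 + repeat 681 + flank 300
  pair <- g$truth$repeats[g$truth$repeats$orientation == "inverted", ]
  J <- extract_junctions(g, pair, flank = 300L)
  expect_equal(nchar(J[["MC-J1"]]$seq), 1281L)
})

test_that("junction extraction swaps roles when applied to the AC circle", {
  g <- fx_genome()
  pair <- g$truth$repeats[g$truth$repeats$orientation == "inverted", ]
  J <- extract_junctions(g, pair, flank = 100L)
  ac <- build_alternative_conformation(g, pair)
  p2 <- pair
  ra <- ac$circles[[1]]$repeat_at
  p2$start1 <- ra[1, 1]; p2$end1 <- ra[1, 2]
  p2$start2 <- ra[2, 1]; p2$end2 <- ra[2, 2]
  J2 <- extract_junctions(circular_genome(ac$circles[[1]]$seq), p2,
                          flank = 100L)
  expect_setequal(c(J2[["MC-J1"]]$seq, J2[["MC-J2"]]$seq),
                  c(J[["AC-J1"]]$seq, J[["AC-J2"]]$seq))
  expect_setequal(c(J2[["AC-J1"]]$seq, J2[["AC-J2"]]$seq),
                  c(J[["MC-J1"]]$seq, J[["MC-J2"]]$seq))
})

test_that("too-large flanks are rejected with guidance", {
  g <- fx_genome()
  pair <- g$truth$repeats[g$truth$repeats$orientation == "direct", ]
  d <- (pair$start2 - pair$start1) %% g$length
  small_circle <- min(d, g$length - d)
  expect_error(extract_junctions(g, pair, flank = small_circle + 100L),
               "smaller flank")
})
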