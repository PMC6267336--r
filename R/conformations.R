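#' Construct the alternative conformation for one repeat pair
#'
#' Homologous recombination between the two copies of a dispersed repeat
#' rearranges the circular genome.  For an *inverted* pair the product is a
#' single isomeric circle in which the segment between the two copies is
#' reverse-complemented; for a *direct* pair the product is two subgenomic
#' circles, each carrying one repeat copy.  Total sequence length is
#' conserved in both cases.  When the two copies are not identical, the
#' repeat sequence written at each novel junction is copy 1's (the
#' crossover position within the repeat is unidentifiable from reads).
#'
#' @param genome A [circular_genome()] or character sequence.
#' @param pair One-row `RepeatPair` table (see [find_repeats()]) detected
#'   on (or planted in) this genome.
#' @return A `Conformation`: list with `id` (`"AC:<repeat id>"`), `circles`
#'   (each a list with `seq` and `repeat_at`, the 0-based half-open
#'   coordinates of the repeat copy on that circle) and `provenance`.
#' @export
build_alternative_conformation <- function(genome, pair) {
  genome <- as_genome(genome)
  pair <- as.data.frame(pair)
  stopifnot(nrow(pair) == 1L)
  L <- genome$length
  r <- pair$end1 - pair$start1
  ## rotate so copy 1 starts at the origin; copy coordinates become
  ## copy1 = [0, r), copy2 = [a2, b2)
  rot <- rotate_seq(genome$seq, pair$start1)
  a2 <- ((pair$start2 - pair$start1) %% L + L) %% L
  b2 <- a2 + (pair$end2 - pair$start2)
  if (a2 <= r || b2 >= L) {
    stop("degenerate repeat pair '", pair$id,
         "': copies abut or overlap, no intervening segment on both sides")
  }
  copy1 <- substr(rot, 1L, r)

  if (pair$orientation == "inverted") {
    ## isomer: segment between end of copy1 and start of copy2 reversed;
    ## copy2 is rewritten as revcomp(copy1) (crossover within the repeat)
    mid <- substr(rot, r + 1L, a2)
    tail <- substr(rot, b2 + 1L, L)
    seq <- paste0(copy1, revcomp(mid), revcomp(copy1), tail)
    circles <- list(list(seq = seq, repeat_at = rbind(c(0L, r), c(a2, a2 + r))))
  } else {
    ## two subgenomic circles, split at the copy starts
    c1 <- paste0(copy1, substr(rot, r + 1L, a2))
    c2 <- paste0(copy1, substr(rot, b2 + 1L, L))
    circles <- list(list(seq = c1, repeat_at = rbind(c(0L, r))),
                    list(seq = c2, repeat_at = rbind(c(0L, r))))
  }
  total <- sum(vapply(circles, function(c) nchar(c$seq), 0))
  stopifnot(total == L)  # length conservation, by construction
  structure(list(id = paste0("AC:", pair$id), circles = circles,
                 provenance = list(repeat_id = pair$id,
                                   orientation = pair$orientation,
                                   rotation = pair$start1)),
            class = "Conformation")
}

#' @export
print.Conformation <- function(x, ...) {
  cat(sprintf("Conformation %s: %d circle(s) of %s bp\n", x$id,
              length(x$circles),
              paste(vapply(x$circles, function(c) nchar(c$seq), 0),
                    collapse = " + ")))
  invisible(x)
}

junction_window <- function(id, seq, flank, repeat_id) {
  structure(list(id = id, seq = seq, flank = flank, repeat_id = repeat_id),
            class = "JunctionWindow")
}

#' Extract diagnostic junction windows for a repeat pair
#'
#' Returns the four windows that discriminate the master conformation (MC)
#' from the alternative conformation (AC) at one repeat: each window is
#' `flank` bases of left flank + the repeat copy + `flank` bases of right
#' flank.  The two MC windows are literal substrings of the master circle;
#' the two AC windows are chimeras pairing copy 1's flank on one side with
#' copy 2's (orientation-adjusted) flank on the other, and occur in the
#' alternative conformation only.  A long read spanning one of these
#' windows end-to-end is informative for the conformation it came from.
#'
#' @param genome A [circular_genome()] or character sequence.
#' @param pair One-row `RepeatPair` table.
#' @param flank Flank length in bases (>= 50); `flank` plus the repeat
#'   length must fit in the smallest recombination-product circle.
#' @return Named list of 4 `JunctionWindow`s: `MC-J1`, `MC-J2`, `AC-J1`,
#'   `AC-J2`.
#' @export
extract_junctions <- function(genome, pair, flank = 300L) {
  genome <- as_genome(genome)
  pair <- as.data.frame(pair)
  stopifnot(nrow(pair) == 1L, flank >= 50L)
  r <- pair$end1 - pair$start1
  conf <- build_alternative_conformation(genome, pair)
  min_circle <- min(vapply(conf$circles, function(c) nchar(c$seq), 0))
  if (flank + r >= min_circle) {
    stop("flank ", flank, " too large: flank + repeat length (",
         flank + r, ") must be smaller than the smallest circle (",
         min_circle, " bp); use a smaller flank")
  }
  win <- function(seq, at) circ_substr(seq, at[1] - flank,
                                       (at[2] - at[1]) + 2L * flank)
  out <- list(
    `MC-J1` = junction_window("MC-J1",
      win(genome$seq, c(pair$start1, pair$end1)), flank, pair$id),
    `MC-J2` = junction_window("MC-J2",
      win(genome$seq, c(pair$start2, pair$end2)), flank, pair$id))
  k <- 1L
  for (circ in conf$circles) {
    for (j in seq_len(nrow(circ$repeat_at))) {
      out[[paste0("AC-J", k)]] <- junction_window(
        paste0("AC-J", k), win(circ$seq, circ$repeat_at[j, ]),
        flank, pair$id)
      k <- k + 1L
    }
  }
  out
}
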