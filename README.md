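# mitorecomb

Structural analysis of plant mitochondrial genomes from long reads.

Plant mitogenomes are circular, repeat-rich and structurally fluid:
dispersed repeat pairs mediate homologous recombination that flips the
segment between inverted copies (an isomeric circle) or splits the genome
at direct copies (subgenomic circles).  These alternative conformations
(AC) coexist with the master conformation (MC) at low frequency.  A long
read that spans a repeat copy plus flanking anchors on both sides reveals
which conformation its molecule had, so the recombination frequency at a
repeat is estimated as

    f = n_AC / (n_AC + n_MC)

over informative reads, with a binomial confidence interval.

The package implements, in pure R plus a small C++ aligner:

* **Repeat detection** on circular genomes (`find_repeats`): k-mer
  seeded, X-drop extended gapless pairs (direct and inverted), ≥ 50 bp at
  ≥ 95% identity by default, with size-class statistics
  (`classify_repeats`) and genome fraction (`repeat_fraction`).
* **Conformation construction** (`build_alternative_conformation`) and
  diagnostic junction windows (`extract_junctions`).
* **Read classification and frequency estimation**
  (`filter_long_reads`, `classify_reads`, `estimate_frequency`,
  `correlate_length_frequency`, `find_master_tiling`).
* **Pan-mitogenome analysis** (`read_blocks` for Mugsy-style MAF,
  `find_collinear_blocks`, `classify_fragments` into
  core/variable/specific fragments, `accumulation_curves`).
* **Gene content** (`search_genes`, `validate_presence_by_depth`,
  `find_plastid_derived`, `find_orfs`, `flag_pseudogene`,
  `build_presence_matrix`).
* **Genome statistics** (`feature_fraction_stats`, `gc_content`,
  `concatenate_supermatrix`, `count_parsimony_informative`).
* **Synthetic data with ground truth** (`generate_genome`,
  `simulate_long_reads`, `simulate_short_reads`,
  `generate_genome_family`), so the whole pipeline is testable offline.

See the vignette (`vignettes/mitogenome-structure.Rmd`) for the model,
parameter choices and design decisions.

## Worked example

```r
library(mitorecomb)

g <- generate_genome(genome_spec(
  length = 20000, gc = 0.45,
  repeats = data.frame(length = c(681, 300),
                       orientation = c("inverted", "direct"),
                       identity = c(1, 1)),
  seed = 11))

(rp <- find_repeats(g))
#>   id start1 end1 start2  end2 orientation length identity
#> 1 r1    997 1678  10627 11308    inverted    681        1
#> 2 r2   6999 7299  15619 15919      direct    300        1

J <- extract_junctions(g, rp[1, ], flank = 100)
reads <- simulate_long_reads(g, rp, read_sim_params(
  n_reads = 3000, length_mean = 4000, length_sd = 0.2,
  sub_rate = 0, ins_rate = 0, del_rate = 0,
  ac_fractions = c(r1 = 0.05), seed = 99))
est <- estimate_frequency(classify_reads(reads, J))
str(est[c("n_mc", "n_ac", "frequency", "ci_lower", "ci_upper")])
#> List of 5
#>  $ n_mc     : int 913
#>  $ n_ac     : int 51
#>  $ frequency: num 0.0529
#>  $ ci_lower : num 0.0383
#>  $ ci_upper : num 0.0676
```

The two planted repeats are recovered at their exact coordinates, and
the recombination frequency estimated from 964 informative reads
(0.0529, CI 0.038–0.068) brackets the simulated AC fraction of 0.05.

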