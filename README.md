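# mazfkit

Characterizing the sequence specificity of MazF-nd1 — the endoribonucleolytic
toxin of the MazEF toxin–antitoxin module of *Nitrospira* strain ND1 — and
predicting its intracellular targets. The package is written for
microbiologists and bioinformaticians working on toxin–antitoxin systems who
need the three computational stages of such a characterization as tested,
reusable functions:

1. **Cleavage-site calling.** In a 5′-end-capture sequencing assay only
   barcode-ligated (cleavage-derived) fragment starts are mapped, so a
   cleavage site is a step in coverage. Sites are called by the relative
   coverage increase rci<sub>i</sub> = cov<sub>i</sub>/cov<sub>i−1</sub>,
   keeping positions with coverage ≥ 5000 on both sides and ranking a global
   top 50; ±5 nt flanks are summarized as a position-frequency matrix with
   per-column information content (2 − H bits). MazF-nd1 cuts between the two
   adenines of its tetrads (A↓ACU), so the motif spans offsets −1..+2 around
   the called position.
2. **Kinetic ranking.** Fluorometric cleavage traces of candidate-tetrad
   probes are normalized to percent (RNase control = 100, no enzyme = 0),
   fitted to the integrated rate equation F(t) = F<sub>max</sub>[1 −
   exp(−kt)], and ranked by the initial reaction velocity F′(0) =
   F<sub>max</sub>·k; primary motifs must exceed all others by at least
   fivefold.
3. **Genome scan.** Each CDS of length L is scored by K (observed motif
   starts, overlaps allowed), p = f<sub>A</sub>²f<sub>C</sub>(f<sub>U</sub> +
   f<sub>G</sub>) + f<sub>A</sub>²f<sub>U</sub>² from its own base
   composition, E = p(L − 3), and the upper-tail binomial probability
   P = Σ<sub>i=K</sub><sup>L−3</sup> C(L−3, i) p<sup>i</sup>(1−p)<sup>L−3−i</sup>.
   Small P flags MazF-sensitive genes; K = 0 flags MazF-tolerant ones.

Seeded generators (`gen_random_rna()`, `plant_motifs()`,
`simulate_cleavage_coverage()`, `simulate_fluorescence()`, `gen_cds_set()`)
produce every input with known ground truth, so the pipeline is fully
testable offline. The packaged reference tables (`nd1_probe_panel()`,
`nd1_reported_kinetics()`, `nd1_reported_sensitive_genes()`,
`nd1_reported_tolerant_genes()`) carry the reported characterization values
used as simulation parameters and worked examples.

## Worked example

The `analysis/` scripts run the three stages end to end on synthetic data;
each step also works interactively:

```r
library(mazfkit)

# simulate a substrate with four planted AACU cleavage sites
pos  <- c(200L, 400L, 600L, 800L)                  # called position = second A
seq1 <- plant_motifs(gen_random_rna(1000, seed = 1), "AACU", pos - 1L)
cfg  <- sim_config(seed = 2, depth = 35000, read_length = 150)
prof <- simulate_cleavage_coverage(seq1, planted_sites(pos, 0.005), cfg)

calls <- call_sites(prof, min_coverage = 5000, top_n = 50)
head(calls[, 1:5], 4)
#>   reference_id position coverage former_coverage      rci
#> 1          ref      600    70548           52817 1.335706
#> 2          ref      200    70003           52499 1.333416
#> 3          ref      400    70264           52796 1.330858
#> 4          ref      800    70004           52635 1.329990
```

The four planted positions head the ranking with rci ≈ 1.33 (site starts are
50× the per-position background rate, read length 150, so the step is a third
of the background coverage), and their flanks read AACU at offsets −1..+2.
Running the whole workflow:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_call_cleavage_sites.R
Rscript analysis/03_fit_kinetics.R
Rscript analysis/04_scan_genome.R
```

prints, among other things:

```
50 calls; recall of planted sites among them: 1.00
consensus at offsets -1..+2: AACU
top candidate tetrads: AACU (20), GGUC (2), GUCU (2)
primary motifs: AACU, AACG, AAUU (fold separation 5.76)
100 tolerant (K = 0) genes; matches scrubbed ground truth: TRUE
reported-P check: max relative deviation 0.00367
```

i.e. all 20 planted sites are recovered among the top 50 calls and tally
first; the kinetic fits on noisy triplicate traces separate AACU/AACG/AAUU
from the eleven near-motifs by more than fivefold; the genome scan extracts
exactly the 100 motif-scrubbed genes as tolerant; and the recomputed binomial
tails match the reported worked-example P values to within 0.4 %. Stage
tables land under `results/`.

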