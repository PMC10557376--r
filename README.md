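# scopebac

Analysis toolkit for **single-bacterium proteomics by carrier-assisted
isobaric multiplexing** (SCoPE-MS with TMT-10plex). A bacterium carries only
a few femtograms of protein — two orders of magnitude below a mammalian
cell — so single-cell identifications sit at the edge of what reporter-ion
quantification can support, and naive FDR control at the PSM level is not
enough. `scopebac` implements the full desk-side analysis for this design:

* **Synthetic data generation** for the study layout: 16 TMT-10plex sets,
  each with two 250-cell carrier-proteome (CP) channels, three single-cell
  and three double-cell channels in alternating order, and two empty
  channels — with incomplete TMT labeling, stochastic per-channel peptide
  detection, isobaric ratio compression and configurable empty-channel
  background.
* **PSM table I/O**: a documented TSV dialect using the annotated-sequence
  convention `[R].DAIHAAK.[A]`, plus a minimal mzTab-style PSM export.
* **Three-layer validation filtering**: consensus q-value filtering over
  two validators (Percolator-style and target-decoy, `q <= 0.05` in
  *either*), removal of common contaminants (keratins, trypsin), a
  channel-occupancy cutoff (>= 25% of the 96 single/double channels with
  nonzero abundance) and a bulk-abundance-rank cutoff (top 25% of the bulk
  proteome).
* **Reporter-ion quantification**: protein groups as sums of peptide
  abundances, per-set normalization to the single-cell channel mean, and the
  channel-class comparison — double/single enrichment, carrier factor, and a
  test that empty channels are statistically indistinguishable from zero.
* **Bulk-proteome summaries**: extraction-method comparison (two-sample t
  on log2 abundances with Benjamini–Hochberg control), detection-count
  differences and the ribosomal share of total protein abundance.

## The model in brief

Channel loads per set are `(250, 250, 1, 2, 1, 2, 1, 2, 0, 0)` cells.
Relative to the single-cell load, a channel with true ratio `r` is observed
under isobaric co-isolation interference as

```
r_obs = 1 + (r - 1)(1 - c),   c in [0, 1]
```

so with the default compression `c = 0.4` the true double/single ratio 2 is
observed as 1.6 (a 60% enrichment), and the interference-free limit
(`c = 0`) restores the theoretical carrier/single ratio of 250. A peptide's
channel-occupancy statistic is

```
occupancy = 100 * #{single/double channels with abundance > 0} / 96
```

Class ratios are estimated from paired within-set log-ratios (geometric
estimator), which is unbiased under multiplicative noise; the arithmetic
mean-of-normalized-values estimator is also available.

## Worked example

```r
library(scopebac)

cfg    <- run_config(generator_config(seed = 1))
report <- run_pipeline(cfg)

report$filter_stages
#>          stage    unit  n_in n_out
#> 1          fdr     PSM 13184 11707
#> 2 contaminants     PSM 11707 10537
#> 3    aggregate peptide   742   742
#> 4    occupancy peptide   742   150
#> 5    bulk_rank peptide   150    51

report$labeling_efficiency_percent
#> [1] 75.25789
report$class_comparison$enrichment_double_vs_single_percent
#> [1] 57.19928
report$class_comparison$carrier_factor
#> [1] 167.1035
report$class_comparison$empty_indistinguishable_from_zero
#> [1] TRUE
report$bulk$ribosomal_share_percent
#> [1] 11.49038
```

Reading the output: of 13,184 simulated PSMs, 11,707 pass the dual-validator
FDR filter and 10,537 remain after contaminant removal; they collapse to 742
peptides, of which 150 clear the 25% occupancy cutoff and 51 (42 proteins)
also sit in the top quartile of the bulk proteome. The labeling efficiency
estimate recovers the 75% completeness of the generator; the double-cell
channels run ~57% above the single-cell channels for this seed (60% in
expectation under compression 0.4); the carrier factor falls well below the
theoretical 250 because compression shrinks large ratios the hardest; and
the empty channels are indistinguishable from zero (no carry-over).

A thin command-line front end is installed with the package
(`system.file("cli", "scopebac", package = "scopebac")`) with subcommands
`simulate`, `convert`, `validate`, `filter`, `quantify`, `bulk-compare` and
`run`.

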