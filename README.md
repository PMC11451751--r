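# midtail

Middle-down quantification of histone H3 tail proteoforms from chimeric
EThcD tandem mass spectra of sortase-ligated, TMT 6-plex labelled tail
peptides.

## The problem

The N-terminal tail of histone H3 carries combinatorial patterns of
post-translational modifications — acetylation and methylation of K4, K9,
K14, K18, K23, K27, phosphorylation of S/T, rarer acylations — whose
co-occurrence on a single tail ("proteoforms" such as
H3K9acK14acK23acK27me2) is invisible to bottom-up proteomics. An
engineered sortase can cleave the tail at the APXTG motif (between T32 and
G33) directly in nuclear acid extracts and ligate a GGGH-containing tag
peptide whose histidine carries a TMT 6-plex label, so that six
treatment/replicate samples can be multiplexed and the intact ~4 kDa tails
analyzed by EThcD. `midtail` implements the downstream computation: from
centroided MS2 spectra and a search-engine PSM export to per-proteoform
relative abundances, per-channel reporter signals, and differential
statistics between treatment conditions.

## The method

For each scan, with PSMs filtered to posterior error probability ≤ 0.05 and
delta-mod score ≥ 10, the theoretical a/b/c/y/z fragment ladders of each
assigned proteoform (fixed TMT6plex +229.162932 Da on His, fixed C-terminal
ligation offset +76.1001 Da, variable acetyl/methyl/phospho/propionyl
deltas; z ions in the z-dot convention; NH3/H2O neutral losses; charges up
to 4) are matched against the peaks at 15 ppm. A match is *confirmed* when
a +1 heavy-isotope companion (1.003355/z) is present. Confirmed peak
intensity is credited to its PSM, with peaks shared by k co-isolated PSMs
split 1/k, and the relative abundance of proteoform *i* is

    abundance_i = (confirmed intensity attributed to i) / (total confirmed attributed intensity)

TMT reporter intensities (channels 126–131) are extracted at the same
tolerance, corrected for label isotopic impurities by solving the impurity
mixing system, and channel-normalized so every channel's mean (or median)
over PSM-bearing scans equals the largest channel's. Scans with ≥ 2
reporters per treatment condition whose PSMs all share one proteoform are
grouped; the difference of condition means of log2 reporter signal is the
log2 fold change, tested with a two-sided Welch t-test (significant at raw
p < 0.05; BH q-values reported alongside). Site-level marginals (e.g. K9ac
= the summed abundance of every proteoform carrying it) support Pearson
comparison with bottom-up site-abundance tables.

A seeded simulator generates ground-truth mixtures as chimeric charge-8
spectra (precursors 480–540 m/z) with isotope envelopes, noise peaks, ppm
jitter, TMT reporters with channel-loading imbalance and configurable
log-normal noise, and matching PSM tables with a stated fraction of rows
generated to fail the score filters — so every pipeline stage is testable
without any raw data.

## Worked example

```r
library(midtail)

cfg <- simulation_config(seed = 42)   # 5-proteoform mixture, 200 scans,
sim <- simulate_dataset(cfg)          # default: the quadruply-modified tail
                                      # up 1.35 log2 units under treatment
fit <- quantify_proteoforms(sim$spectra, sim$psms, sim$design)
fit
```

```
Middle-down proteoform quantification
 268 PSMs in, 233 accepted; 200 scans annotated
 5 proteoforms with confirmed intensity, 5 quantifiable by reporters
 top proteoforms by abundance:
   H3                                       0.311
   H3K9acK14acK23acK27me2                   0.222
   H3K9ac                                   0.214
   H3K14acK23acK27me2                       0.185
   H3K18acK23ac                             0.068
```

The abundances are the attributed-intensity fractions (they sum to 1) and
recover the simulated mixture — the truth here is the across-channel mean
fraction of each proteoform, e.g. 0.313 for the unmodified tail. The
differential test then recovers the injected condition effect:

```r
diff_proteoforms(fit)
```

```
           proteoform_id log2fc  p_value  q_value significant
1                     H3 -0.287 1.21e-09 2.02e-09        TRUE
2     H3K14acK23acK27me2 -0.257 1.01e-04 1.01e-04        TRUE
3           H3K18acK23ac -0.367 5.23e-05 6.54e-05        TRUE
4                 H3K9ac -0.494 5.83e-18 1.46e-17        TRUE
5 H3K9acK14acK23acK27me2  1.364 6.05e-64 3.03e-63        TRUE
```

H3K9acK14acK23acK27me2 is estimated up 1.364 log2 units (true value
1.350); the other proteoforms show the compensatory decrease of their
fractions (true value −0.343), since fractions must still sum to 1 in the
treated channels. `write_results(fit, diff_proteoforms(fit), "out/")`
writes deterministic TSV tables; `volcano_table()` and the `plot()`
methods provide figure-ready output. A thin command-line wrapper is
installed at `system.file("scripts", "midtail", package = "midtail")`
(`midtail simulate|quant|diff`).

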