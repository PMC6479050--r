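# bindexpr

Does a chromatin factor directly activate or repress the genes that change
when it is lost?  `bindexpr` integrates a factor's ChIP-seq binding with
RNA-seq differential expression to answer that question, the way it is asked
for SWI/SNF-family factors such as BRD9 in rhabdoid tumour cells: classify
the factor's peaks by co-occupancy with a partner factor (e.g. SMARCA4),
annotate where each class binds, profile chromatin-mark signal around the
peaks in paired conditions, score every gene's *regulatory potential* by
exponential distance decay, test up- and down-regulated gene groups against
static genes, and call direct targets.

The core statistic is the regulatory potential of gene *g*,

```
S_g = sum_{i=1..k} exp(-(0.5 + 4 * Delta_i)),    Delta_i = |d_i| / 100 kb
```

summed over the *k* peaks whose midpoint lies within 100 kb of the gene's
TSS (a peak on the TSS contributes `exp(-0.5) ≈ 0.6065`; one at 10 kb,
`Delta = 0.1`, contributes `exp(-0.9)`).  Activating/repressive function is
inferred by one-sided two-sample Kolmogorov–Smirnov tests comparing the
`S_g` distribution of the top-500 up- (and down-) regulated genes against
non-differential "static" genes; direct targets are bound (`S_g > 0`)
differential genes ranked by the rank product of binding and expression
ranks.

Because the analyses are exercised on synthetic data, the package ships a
seeded study generator (`simulate_study()`) that plants direct targets with
known truth: peaks enriched near target TSSs, partial co-occupancy between
two peak sets, piecewise-constant signal tracks whose knockout changes are
coupled to expression direction, and a DESeq2-shaped expression table.

## Worked example

The `analysis/` scripts run the whole workflow on the demo study
(`simulation_config(seed = 1)`: 100 Mb genome, 2000 genes, 200 planted
up- and 200 down-targets, 1000 + 1000 peaks) and write tables under
`results/demo/`:

```sh
Rscript analysis/01_simulate.R          # synthetic study -> standard formats
Rscript analysis/02_classify_peaks.R    # co-occupancy classes, annotation, widths
Rscript analysis/03_signal_profiles.R   # binned profiles, site changes, correlation
Rscript analysis/04_beta_targets.R      # regulatory potential, KS inference, targets
Rscript analysis/05_distance_analysis.R # nearest-binding distances by gene group
```

Stage 4 prints, for this seed:

```
KS activating/repressive inference (one-sided, group > static):
 peaks group   n     D p_one_sided
   all    up 500 0.297    0.00e+00
   all  down 500 0.264    0.00e+00
     I    up 500 0.172    2.72e-09
     I  down 500 0.123    4.17e-05
    II    up 500 0.170    4.29e-09
    II  down 500 0.168    6.73e-09

Direct targets: 450 up, 449 down; top up-targets: g0090, g1648, g1475, g0089, g1406
Recall of planted targets: up 1.00, down 1.00
```

Binding is enriched near both up- and down-regulated genes relative to the
static background (small one-sided KS p for both groups, in every peak
class), i.e. the simulated factor both activates and represses — and all
planted targets are recovered in the direct-target lists.  Stage 5 shows the
complementary distance view (medians 17.3/19.5 kb for regulated genes vs
42.1 kb for static, Mann–Whitney p < 1e-20), and stage 3 the positive
correlation between knockout signal change and expression change in both
TSS-proximal and TSS-distal strata (Spearman rho 0.41 and 0.19).

`run_pipeline()` chains the same stages in one call and is byte-identical
across repeated runs on the same configuration.

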