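# guidephase

Nucleosomes impede Cas9's access to genomic DNA, and that leaves a
signature in pooled CRISPR screens: highly active sgRNAs concentrate in
regions of low nucleosome occupancy, and average guide activity around
transcription start sites oscillates out of phase with the ~190 bp
nucleosome repeat. `guidephase` is an R package for screen analysts and
chromatin biologists that turns raw sgRNA count tables into that analysis:

- **Screen scoring** — per-guide phenotypes
  `p = [log2((RPM_B + c)/(RPM_A + c)) − median(negative controls)] / doublings`,
  replicate-averaged; per-gene effect sizes (signed mean of the strongest 3
  phenotypes by absolute value), Mann-Whitney confidence against negative
  controls, an effect Z score standardized against size-matched
  pseudo-genes resampled from the controls, and the composite hit score
  `S = |z · log10 p|` with inclusive threshold 20; per-guide **activity
  scores** `a_i = p_i / m_g` with `m_g` the gene's strongest-3 mean, so the
  strongest 3 average exactly 1; phenotype-signed Z scores for tiling
  screens.
- **Occupancy** — dense per-base signal tracks from bedGraph/wiggle,
  target-site occupancy as the mean over protospacer + PAM, and
  TSS-relative averaged signal honoring gene strand.
- **Periodicity** — 50 bp windowed activity profiles (minimum 10 guides per
  window), zero-phase order-4 Butterworth smoothing at 0.03 of Nyquist,
  peak/trough/amplitude extraction, and the median inter-peak spacing as a
  nucleosome repeat-length estimate.
- **Association** — occupancy bins (dedicated `=0` bin, right-closed 0.2
  bins) with two-tailed Mann-Whitney tests against the zero bin, OLS fits
  of activity on {occupancy, length, sequence score}, and residual
  correction that removes the sequence + length component exactly.
- **Synthetic data** — a generator that emulates phased occupancy tracks,
  tiling libraries, occupancy-suppressed true activity, and
  negative-binomial screen counts with full ground truth, so the whole
  pipeline runs and is testable offline.

See `vignettes/activity-occupancy-methods.Rmd` for the model details and
design choices.

## Worked example

Generate a synthetic screen and run the whole recovery analysis in one
call:

```r
library(guidephase)
cfg <- synthetic_config(n_genes = 12, seed = 7)
res <- analyze_synthetic_screen(cfg, null_pseudogenes = 2000)
res$periodicity
#> periodicity_result: 8 peak(s)
#>   peak0 at -2 bp (0.496), amplitude 0.460
#>   peak1 at +211 bp (0.472), amplitude 0.408
#>   peak2 at +403 bp (0.487), amplitude 0.316
#>   peak3 at +590 bp (0.527), amplitude 0.289
#>   ...
res$median_peak_spacing        # 187 bp
res$profile_anticorrelation    # -0.981
res$fits$occupancy$r2          # 0.348
res$fits$all$r2                # 0.556
```

Activity peaks sit in the linkers between phased nucleosomes: the median
spacing (187 bp) recovers the generator's 190 bp repeat, the windowed
activity profile is strongly anti-correlated with the TSS-relative
occupancy profile (−0.98), occupancy alone explains a third of activity
variance, and adding guide length and sequence score raises the fit —
nested OLS fits can only increase R².

The same stages run file-to-file: `generate_screen_data(cfg, dir)` writes
counts/library/track/TSS/FPKM inputs, and `run_pipeline(pipeline_config(...))`
executes score → occupancy → profile → associate, writing per-stage TSV/JSON
outputs plus a run manifest. A thin CLI wraps the same functions:

```sh
exec/guidephase simulate --out-dir sim --seed 1
exec/guidephase run --config pipeline.yaml
```

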