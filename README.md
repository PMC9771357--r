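# pcmli

Cerebellar Purkinje cells (PCs) send axon collaterals onto a small subset of
inner-molecular-layer basket cells — the PC-MLIs — forming a non-reciprocal
inhibitory feedback circuit: a PC that pauses releases its PC-MLIs, whose
firing then deepens the pause in *neighboring* PCs (disinhibition). `pcmli`
is an R package for studying what this circuit does to cerebellar learning.
It provides:

* a spiking-network simulation of eyelid conditioning (mossy-fiber /
  climbing-fiber coding of CS and US, granule/Golgi sheet, PCs, molecular
  layer interneurons, deep nuclei, virtual eyelid read-out) in which the
  PC→PC-MLI projection can be toggled, with timing-gated parallel-fiber
  LTD/LTP (a granule burst 100–300 ms before a climbing-fiber spike is
  depressed, otherwise potentiated) and a mossy-fiber→nucleus rule;
* the analysis stack used on recordings of this circuit: conditioned-response
  (CR) measures on 1-kHz eyelid traces (0.3-mm criterion, two-step onset
  detection), causal-kernel firing rates (one-sided Gaussian, 25-ms SD),
  trial-wise rate–behavior correlations classified by a two-Gaussian mixture
  with a 0.95-posterior cutoff, spike/pause/burst-triggered cross-correlograms
  with inter-spike-interval shuffle nulls (|Z| ≥ 3.34, Bonferroni over 60
  bins), the lead-lag statistic ΔPC − ΔMLI (fraction of each cell's full rate
  change completed before CR onset), and the in vitro analyses: IPSC-train
  depression fits, readily-releasable-pool (RRP) and mobilization estimation
  from cumulative charge, quantal metrics, IPSC detection, and optogenetic
  input-field / footprint mapping with a convergence estimate;
* seeded synthetic-data generators with recorded ground truth for every input
  the analyses consume.

Everything user-facing takes and returns plain data frames/tibbles; fitted
objects have `tidy()`/`glance()` methods and `autoplot()` plots.

## Worked example

Train a desk-scale network (1/6-scale granule sheet, 2,000 granule cells;
full-size readout circuit) for ten 108-trial sessions at ISI 500 and ask how
MLI activity relates to the virtual CR:

```r
library(pcmli)

cfg <- sim_config(seed = 11, scale_factor = 1/6, feedback_enabled = TRUE)
run <- run_training(cfg, n_sessions = 10, isi = 500, seed = 21)
tail(tidy(run), 2)
#> # A tibble: 2 × 5
#>   session n_trials cr_rate mean_cr_amplitude mean_onset_ms
#>     <int>    <int>   <dbl>             <dbl>         <dbl>
#> 1       9      108       1              1.18          35.6
#> 2      10      108       1              1.26          39.7

corr <- mli_cr_correlations(run)   # one r per basket/stellate cell
fit  <- fit_two_gaussian_mixture(corr$r, equal_variance = TRUE)
fit
#> <pcmli_mixture> means -0.013 / 0.335 (sd 0.069 / 0.069, weights 0.98 / 0.02)
#>   skewness 1.31; cutoff r* = 0.251 at 0.95 membership; bimodal by BIC
```

The CR rate and amplitude grow across sessions (acquisition). With feedback
enabled the per-unit correlations split into two populations: a large one
centered near zero (ordinary MLIs) and a small strongly correlated one — and
the units in the high component are exactly the nine wired PC-MLIs. Rebuilding
the same network with `feedback_enabled = FALSE` removes the high component;
units classified at or above the fitted cutoff are the simulation's
"putative PC-MLIs", mirroring how the in vivo classification works.

The same functions run on data rather than simulations — e.g.
`cr_measures()` on a recorded eyelid trace, `spike_triggered_correlogram()`
on two sorted spike trains, or `estimate_pool()` on an IPSC train:

```r
spec  <- ipsc_gen_spec(preset = "depleting", seed = 1)  # two-pool synapse
train <- gen_ipsc_trains(spec)
tidy(estimate_pool(train, mean_quantal_charge = spec$q_charge))
#> # A tibble: 4 × 2
#>   quantity                   value
#>   <chr>                      <dbl>
#> 1 rrp_pc                    17.2
#> 2 rrp_quanta                95.6
#> 3 mobilization_pc_per_stim   0.187
#> 4 mobilization_quanta_per_s 51.9
```

The y-intercept of the cumulative-charge regression recovers the planted
100-quantum pool within a few percent; the slope is the vesicle-mobilization
rate.

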