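---
title: "Modeling Purkinje-cell feedback to molecular-layer interneurons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling Purkinje-cell feedback to molecular-layer interneurons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`pcmli` packages two things that belong together: a spiking-network
simulation of cerebellar eyelid conditioning in which the feedback
projection from Purkinje cells (PCs) onto a subset of inner-molecular-layer
basket cells (the "PC-MLIs") can be switched on or off, and the analysis
procedures used to characterize that circuit in recordings — conditioned
response (CR) measures on eyelid traces, causal-kernel firing rates,
trial-wise neural-behavioral correlations with a two-Gaussian
classification, triggered cross-correlograms with shuffle nulls, the
lead-lag (dPC − dMLI) statistic, and the in vitro short-term-plasticity and
optogenetic-mapping analyses. Seeded synthetic-data generators provide
ground-truthed inputs for every stage, so the full stack is testable without
any recordings.

## The network model

The circuit is a parasagittal cerebellar stripe: 600 mossy fibers (MFs),
12,000 granule cells, 900 Golgi cells, 24 PCs, 96 basket cells (9 designated
PC-MLIs), 240 stellate cells, 8 deep-nucleus (DCN) cells and 4 climbing
fibers (CFs). Granule cells, Golgi cells and MF glomeruli live on a 2-D
sheet; each projection is drawn randomly inside a geometric eligibility span
(squares for MF and Golgi inputs, narrow transverse rectangles for granule
axons, which run as parallel fibers), with fixed convergence: every granule
cell receives exactly four MFs, and every granule cell places one
parallel-fiber (PF) synapse on one PC, so there are as many PF->PC synapses
as granule cells.

Every cell is a conductance-based point neuron on a fixed 1-ms clock
(`dt = 1`): a forward-Euler membrane update from leak plus per-afferent
synaptic conductances (each an exponentially decaying accumulator,
incremented per presynaptic spike with a one-step delay), a spike when the
potential crosses an adaptive threshold, reset to the leak reversal, and a
threshold that jumps by `d_theta` per spike and relaxes with `tau_theta`.
Threshold adaptation, not a potential-based refractory term, carries
spike-rate adaptation and caps tonic rates. The forward-Euler step at
`dt = 1` ms constrains total conductance per cell to stay well below
2 ms^-1; all default gains respect this with a wide margin.

The same update exists twice on purpose: `advance_timestep()` is the
readable R reference, and the compiled trial runner reproduces it exactly
(the suite holds them to 1e-9 agreement over 10,000 steps against a scalar
integrator written independently in the tests).

### Operating points

Numerical conductances, reversals and threshold parameters are not uniquely
determined by the circuit's described behavior, so they are this package's
calibration, frozen in `default_neuron_params()`:

* **PCs and DCN cells are pacemakers** (leak reversal above baseline
  threshold) firing at roughly 80-95 Hz and 15-25 Hz; PF input modulates
  the PC around that operating point, which is what makes learned PF
  depression read out as a rate pause.
* **Granule cells** are sparse (~3-6 Hz) and summation-selective: the MF
  synapse's 6-ms time constant lets a sustained 80-100 Hz tonic-CS fiber
  drive its targets to 12-18 Hz while background fibers (1-40 Hz) mostly
  produce isolated coincidence spikes. Golgi feedback keeps the sheet
  sparse.
* **MLIs** fire at 20-40 Hz. PC-MLIs receive, in addition, strong and slow
  (25-ms) inhibition from their one or two presynaptic PCs — slow because
  transmission at this synapse has a large asynchronous component — which
  keeps them at a few Hz at rest and makes them sensitive, nearly linear
  detectors of decreases in their PCs' rates. PC-MLIs in turn contact every
  non-partner PC with strong perisomatic synapses, closing a disinhibition
  loop: a PC pause releases PC-MLIs, whose firing deepens the pause in
  neighboring PCs. The loop respects non-reciprocity: no PC inhibits, via a
  PC-MLI, itself (checked exhaustively in the tests).

### Desk-scale runs

`sim_config(scale_factor = 1/6)` scales the granule-layer populations (MFs,
granule cells, Golgi cells — 2,000 granule cells at 1/6) while the readout
circuit (PCs, MLIs, DCN, CFs) keeps its full population counts, so
readout-side population statistics are preserved at a sixth of the cost.
Because each granule cell makes one PF synapse, scaling the sheet reduces
PF convergence per PC; the per-spike PF increment is rescaled by exactly
that factor, preserving the PC's mean input conductance. All training-based
results in the tests and the acceptance script use this 1/6 scale, ten
108-trial sessions per run — sizes chosen so a full battery (feedback on
and off, two ISIs) completes in minutes on one core.

## Conditioning protocol

A session is 12 nine-trial blocks (108 trials), each block starting with a
CS-alone trial followed by eight paired trials; the tone CS co-terminates
with the 50-ms US, so CS duration is ISI + 50 ms. 3% of MFs are phasic-CS
fibers (a 100-ms burst at CS onset), 3% tonic-CS fibers (80-100 Hz for the
CS), 5.2% nucleo-cortical collaterals whose rate follows smoothed DCN
output, and the rest background (1-40 Hz); outside the CS, CS fibers revert
to a background rate drawn like any other fiber's. All MF activity is
Bernoulli per millisecond at `rate x dt`. The US drives one spike in each
CF; CFs also fire spontaneously at 1 Hz.

Two deliberate additions where the verbal protocol under-determines the
dynamics:

* **Nucleo-olivary feedback.** The probability that CFs respond to the US
  declines linearly with the expressed CR amplitude (to a floor of 0.1 at
  3 mm; `protocol_config()`). Without it, timing-gated LTD has no brake:
  every eligible synapse is eventually driven to the weight floor and the
  learned pause never stabilizes, with or without feedback. With it,
  learning self-limits at the point where depression and the remaining
  potentiation balance — which is also what lets feedback *economize*
  plasticity: the feedback loop reaches criterion CRs with less net LTD, so
  CF suppression engages earlier and fewer synapses reach the strong-LTD
  tail.
* **The eyelid plant.** The virtual eyelid is the DCN population rate
  passed through two causal exponential stages — a 20-ms readout kernel and
  a 40-ms plant stage representing lid mechanics — then baseline-subtracted
  and scaled (0.08 mm/Hz, calibrated once on a trained ISI-500 run, capped
  at 6 mm full closure). A physical lid cannot follow millisecond rate
  fluctuations; without the plant stage, spiking shot noise from eight DCN
  cells swamps the 0.3-mm CR criterion.

Inter-trial intervals are drawn uniformly from 20-40 s and recorded per
trial, but the network is not stepped through them; dynamical state simply
carries across trials. The 10-s pre-trial baseline epochs consumed by the
correlogram analyses are simulated explicitly with `run_baseline()`.

## Plasticity

Two rules run after every trial, implemented by the same exported functions
the user calls on their own data:

* **PF -> PC** (`apply_pf_pc_plasticity()`): every granule-cell *threshold
  burst* — at least 2 spikes within a 10-ms sliding window, burst time =
  first spike — depresses its synapse by `ltd_step` if a CF spike follows
  100-300 ms later, otherwise potentiates it by `ltp_step`; weights clip to
  [0, 1]. Step sizes (0.035 / 0.011) were tuned so acquisition reaches an
  asymptote within about ten ISI-500 sessions. Their ratio matters more
  than their size: with 1-Hz spontaneous CF activity a random burst is
  eligible with probability ~0.18, so `ltp/(ltd + ltp) ~ 0.24` keeps
  background synapses at a stable attractor (pressed against the weight
  ceiling) while CS-driven synapses, whose in-window burst probability is
  several times higher during paired trials, fall toward the floor. Initial
  PF weights start at the ceiling — the background attractor — so training
  reshapes the CS-driven synapses rather than the whole distribution, and
  trained runs show net depression at many synapses and net potentiation at
  essentially none.
* **MF -> DCN** (`apply_mf_dcn_plasticity()`): MF synapses active during an
  abrupt pause in the PC population rate (below 25% of baseline for at
  least 50 ms) depress, those active during strong PC activity (above 150%)
  potentiate.

A `locus` switch selects where the timing rule acts: `"pf_pc"` (default),
`"pf_mli"`, or `"both"`. At the MLI locus the rule's sign is inverted
(potentiation inside the CF window): an MLI must *increase* its CS-driven
firing to push PCs down and drive a CR, so a depressing rule there could
never support acquisition. This is an interpretive choice, flagged here.
One further interpretation: LTP is a fixed per-burst step, not graded by
the CF-free interval length.

## Analyses

* **CR measures.** Baseline = mean of the 200-ms pre-CS segment; amplitude
  = position minus baseline at US onset; a trial is a CR at >= 0.3 mm before
  the US; criterion latency is the first 0.3-mm crossing. Onset uses a
  two-step algorithm: find the first sample exceeding baseline + 4 pre-CS
  SDs sustained for 20 ms, then fit a line to the following 20 ms and
  report its baseline crossing. The 4-SD/20-ms constants are exposed; the
  200-ms pre-CS segment doubles as the onset-detection baseline window.
  Recorded traces are low-pass filtered first (zero-phase 4th-order
  Butterworth at 50 Hz — eyelid kinematics live below ~20 Hz); virtual
  traces are already smooth and skip the filter.
* **Rates.** `instantaneous_rate()` uses a one-sided (causal) Gaussian
  kernel, SD 25 ms, unit area — estimates at time t depend only on spikes
  at or before t, so US-evoked activity cannot leak backward into the CS.
  PC rates normalize to the pre-CS baseline; MLI rates normalize to the CS
  maximum of the session-averaged rate, which equalizes cells whose
  CR-related increases span 2- to 10-fold. Correlations are unaffected by
  either normalization (Pearson r is affine-invariant), which also settles
  whether raw or normalized rates enter the trial-wise correlation.
* **Correlations and classification.** Per CR trial, the zero-lag Pearson
  correlation between rate and eyelid position from 150 ms before CS onset
  through US onset; per-unit means are fit with a two-Gaussian mixture (EM
  via mclust; the one-component fit is kept for BIC comparison, and the
  G = 2 fit takes whichever of the equal- or free-variance models BIC
  prefers). The classification cutoff is the smallest r with posterior
  membership >= 0.95 in the higher-mean component; a density-ratio variant
  of the cutoff is available, since "0.95 probability that the two fitted
  distributions were different" admits both readings.
* **Correlograms.** Target spikes are binned at 1 ms over +/-30 ms around
  every trigger spike within the baseline epochs. The null permutes the
  trigger train's inter-spike intervals within each epoch — preserving rate
  and the ISI marginal while destroying timing — and supplies per-bin means
  and SDs for normalization and Z-scores. Significance: at least 2 bins
  (excluding lag 0, which is unusable for same-tetrode pairs) at
  |Z| >= 3.34, i.e. two-sided 5% Bonferroni-corrected over the 60 usable
  bins. Pause (burst) triggers are the starts of the largest (smallest)
  `percentile` fraction of trigger inter-spike intervals — ceiling count,
  ties included, and a selection that cannot discriminate (a constant-ISI
  train) is an error; their significance rule compares post- versus pre-lag
  significant-bin counts.
* **Lead-lag.** For a PC/PC-MLI pair, the pre-CR fraction of the PC's full
  decrease minus the PC-MLI's full increase (dPC − dMLI; positive = PC
  leads) is computed on every usable trial — those whose CR onset leaves a
  full 100-ms (ISI 250) or 150-ms (longer ISIs) post-onset window before
  the US — and averaged within the pair. Computing fractions per trial,
  rather than on onset-aligned trial-averaged rates, is deliberate: aligned
  averaging presumes responses track CR onset trial by trial, and when part
  of the response is stimulus-locked (as in this simulation) it biases the
  fraction of the more step-like cell toward one.
* **In vitro stack.** Depression trains are normalized to the first IPSC
  and fit with exponential-plus-plateau; the cumulative-charge regression
  over the last 20 stimuli yields RRP (intercept) and mobilization (slope;
  per-stimulus, multiplied by frequency for per-second rates). Input maps
  keep pixels with IPSC detection probability >= 0.5 across repeats and drop
  single-pixel islands (4-connectivity — the strict reading of
  "single-pixel areas"); footprints require spikes in *every* repeat.
  Quantal conversion divides by the mean spontaneous-event charge (or
  amplitude x fitted decay when only amplitudes exist).

## Synthetic data

The generators emulate the statistical structure the analyses consume, not
the biophysics: sigmoidal CRs with drawn onsets and amplitudes; PC rates
that drop (logistic in time) a configurable lead before MLI rates rise;
per-spike inhibitory PC->MLI coupling in baseline epochs (thinned
inhomogeneous Poisson processes — pause-triggered MLI increases emerge from
the same coupling, because long PC intervals leave the MLI unsuppressed); a
two-pool vesicle model with binomial release, baseline plus
activity-dependent mobilization, and sweep averaging (the `pc_mli` preset
holds its steady state near half the initial amplitude across 10-100 Hz,
with per-second mobilization growing with frequency; the `depleting` preset
is the regime in which the cumulative-charge method recovers the planted
pool accurately); photostimulation grids with planted fields and Poisson
spontaneous contamination; and labeled two-Gaussian correlation samples.
Every generator is seeded, deterministic, and carries its ground truth
(`write_ground_truth()` writes the sidecar JSON).

What passing tests on these generators shows — and what it does not: the
analysis stack recovers planted structure of the *kind* the recordings
contain (rates, couplings, pools, fields) at realistic noise, but the
generators do not reproduce real recordings' full covariance structure,
non-stationarity, or sorting artifacts.

## Known limitations

* Granule-layer temporal coding is coarse: CS-driven granule cells are
  active through most of the CS rather than tiling it, so learned pauses
  (and virtual CRs) begin earlier and ramp more gently than well-timed
  conditioned responses; the feedback comparisons are directional, not
  quantitative reproductions.
* Single-compartment neurons with threshold adaptation; no complex-spike
  waveforms, gap junctions, or candelabrum/Lugaro cells.
* Sub-millisecond latencies (the 1.15-ms IPSC latency measured at this
  synapse) are unrepresentable on the 1-ms clock; every connection delivers
  with a one-step delay.
* The in vivo unit-type classification from waveform features is out of
  scope: spike trains arrive already sorted and labeled. A convenience
  heuristic (PC if baseline > 40 Hz with a complex-spike flag) exists in
  the analysis code paths but is explicitly non-canonical.
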