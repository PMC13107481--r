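# mecnonlocal

Analysis pipeline for detecting and characterizing **nonlocal spatial
coding** in medial entorhinal cortex (MEC) population recordings on a
linearized X-maze — the phenomenon in which, during immobility, the decoded
position of the neural population jumps to places far from the animal,
most prominently the reward sites at the other end of the maze.

The package is aimed at systems neuroscientists who want to run (or audit)
this analysis chain end to end: a switching-dynamics Bayesian position
decoder, track-graph geometry with analytic chance levels, shuffle-based
single-unit statistics, sharp-wave-ripple (SWR) detection, MEC–CA1
spike-timing coordination, and a synthetic-session generator with known
ground truth so every stage is testable without any recording.

## The model

Spikes from all units are binned at 2 ms and decoded against 2-cm rate maps
λ_c(x) fit on movement (>2 cm/s). The latent state is the pair
(dynamic I_t, position x_t) with three movement dynamics — stationary
(x_{t+1} = x_t), continuous (Gaussian random walk, σ = 1 bin per step,
measured in track distance so transitions follow the maze graph), and
fragmented (uniform jumps) — switching with total probability 0.02 per step.
Emissions are independent Poisson, n_{t,c} ~ Pois(λ_c(x_t)·Δt). A
forward–backward smoother yields the acausal posterior
P(x_t, I_t | n_{1:T}); the decoded position is argmax_x Σ_I P(x, I | n).

A 2-ms bin is **nonlocal** when the track distance between decoded and actual
position is ≥ 20 cm, restricted to immobility (< 2 cm/s, sub-second/sub-2-cm
gaps merged) and to confidence-kept bins (posterior spread ≤ 400 cm², i.e.
posterior SD ≤ 20 cm). Chance levels for where nonlocal content may point
are pure geometry: for a mouse at a sample reward port, 210 cm of the 230-cm
track lies ≥ 20 cm away, so the five maze segments have chance
10/210, 70/210, 30/210, 80/210, 20/210.

## Worked example

The numbered scripts under `analysis/` run the whole workflow on one
synthetic session (30 trials, ~9 simulated minutes, 100 MEC + 15 CA1 units,
127 injected remote-reactivation events):

```sh
Rscript analysis/01_simulate.R      # session + ground truth -> results/session
Rscript analysis/02_decode.R        # switching-dynamics decode
Rscript analysis/03_nonlocal.R      # immobility, nonlocal bouts, segment stats
Rscript analysis/04_cells.R         # fields, composition, recruitment, ablation
Rscript analysis/05_lfp_cofiring.R  # SWRs, overlap shuffle, MEC-CA1 pairs
Rscript analysis/06_report.R        # headline table
```

With the default seed this prints, stage by stage:

```
movement decode error: 1.56 cm (CV 2.06 cm, shuffled control 45.1 cm); 7.8% of bins low-confidence
nonlocal: 87% of immobility bouts with content, 13.2% of immobile time; event recall 0.98,
  precision 0.98; choice-reward nonlocal content predicts correctness at 55.6%
fields: 85/100 units with >=1 field; 65/100 preferentially recruited; removing decoded-field
  spikes drops nonlocal 13.2% -> 5.7%
SWR: 93 detected (recall 1.00 vs injected); overlap with nonlocal at chance; cofiring:
  1.7% pairs sig local (100% of truly coupled pairs recovered)
```

Reading these: the decoder tracks the running animal to within ~1.6 cm
(a temporally shuffled control model fails at ~45 cm, confirming the decode
uses spatial tuning); 98% of the generator's injected remote events are
recovered as nonlocal bouts and 98% of detected bouts correspond to a real
injected event; deleting the spikes of remote-field cells during each bout
more than halves the nonlocal fraction, showing those cells carry it; ripples
are detected perfectly but overlap nonlocal coding only at chance — as they
should, since the generator places them independently; and the 1–10-ms
co-firing test recovers exactly the MEC→CA1 pairs that were coupled by
construction. `results/06_report.tsv` collects the same numbers as a table.

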