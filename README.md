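# telegaps

Detection-**gap** analysis of acoustic **tele**metry data.

Passive acoustic arrays record presence only, and most of a tagged animal's
time passes between detections. For obligate swimmers (ram-ventilating
sharks that cannot rest motionless), a long absence from the array is
evidence of movement away from it — so the gaps themselves carry
behavioural information. `telegaps` turns per-individual detection
sequences into movement events, classifies each event as *restricted*
(on-reef) or *out-of-range* (wider, off-reef) activity, and models the
drivers of out-of-range movement. It is aimed at movement ecologists
working with receiver arrays whose coverage is deliberately sparse —
remote reef systems, large MPAs — where finer-scale positioning is
impractical at scale.

## Method at a glance

* **Events.** Consecutive detections of one individual define a movement:
  a *recursion* (same receiver — a self-loop in the movement network) or a
  *transition* (different receivers). Recursions under 6 min are treated
  as missed detections and dropped; for transitions, the relative
  deviation from expected time, `RDET = (d / v) / t_obs` (great-circle
  distance over species swim speed, divided by observed duration), filters
  implausibly fast movements (RDET > 5).
* **Classification.** Per species, log gap durations (recursions) and log
  RDET (transitions) are split into two classes by Fisher's exact
  dynamic-programming partition — the contiguous 2-partition minimising
  within-class sum of squares. Gaps longer than the recursion threshold,
  and transitions slower than the RDET threshold, are labelled
  out-of-range (1); ties go to restricted (0).
* **Inference.** A binomial GLMM (logit link) with crossed random
  intercepts for individual and receiver:
  `logit P(out-of-range) = Xβ + u_tag + u_receiver`,
  fixed effects species, sex, log size, diel period, season and species
  interactions. All marginality-respecting submodels are ranked by AICc;
  nested (more complex, worse-scoring) models are removed; a single
  survivor is refitted, a dominant model (weight ≥ 0.9) reported, and
  otherwise coefficients are model-averaged with unconditional SEs.
  Reported alongside: Nakagawa marginal/conditional R², variance
  components, conditional modes of the random effects, and a
  cross-validated AUC on an 80/20 movement-level split.
* **Simulation.** A synthetic generator builds an atoll-like array and a
  two-state movement process with known ground truth, so the whole chain
  is testable offline. See the vignette
  (`vignettes/detection-gap-analysis.Rmd`) for the model, assumptions,
  parameter defaults and limitations.

## Worked example

Simulate a study and run the full pipeline:

```r
library(telegaps)

cfg <- sim_config(seed = 42)
sim <- simulate_telemetry(cfg)
write_sim_bundle(sim, "bundle")

rc <- default_config()
rc$paths <- list(detections  = "bundle/detections.csv",
                 receivers   = "bundle/receivers.csv",
                 individuals = "bundle/individuals.csv",
                 output_dir  = "out")
res <- run_gap_analysis(rc)
res$thresholds
```

```
     species recursion_threshold_min transition_rdet_threshold
1: gray_reef                   40.80                 0.1391676
2: silvertip                   44.35                 0.1526611
```

Gray reef recursions longer than ~41 min (silvertip: ~44 min), and
transitions with RDET below ~0.139 (0.153), are labelled out-of-range.
The run log reports every filter: here 91,409 detections became 18,647
labelled movements after 72,737 sub-6-min recursions were removed.

```r
res$summary_tables$by_species
```

```
     species     n n_out  pct_out pct_restricted
1: gray_reef 11186   706 6.311461       93.68854
2: silvertip  7461   611 8.189251       91.81075
```

Silvertips make proportionally more out-of-range movements than gray reef
sharks, as simulated. Selection retained no dominant single model here
(`res$selection$type` is `"averaged"`), so coefficients are model-averaged;
`res$r2` gives R²m = 0.006 / R²c = 0.061 (fixed effects explain little,
individual heterogeneity more — `res$varcomp` shows σ²_tag = 0.17 versus
σ²_receiver = 0.017), and the held-out AUC is 0.612. Comparing the labels
against the generator's ground truth
(`evaluate_recovery(res$labelled, sim$truth, cfg)`) gives 99.3% label
accuracy.

A thin CLI wraps the same functions
(`exec/telegaps <simulate|classify|model|run|report> --config cfg.yaml
--seed N --out DIR`); an annotated config template is in
`inst/extdata/example-config.yaml`.

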