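# shinglmcc

Monosynaptic connectivity inference from spike-train cross-correlograms, for
researchers analyzing large parallel extracellular recordings (spike-sorted
unit times, e.g. from high-density probes).

## The problem and the methods

A synapse between two recorded neurons shows up in their cross-correlogram
(CC) — the histogram of spike-pair lags within ±W ms — as a hump (excitatory)
or dip (inhibitory) a few ms from zero lag. But shared background input
creates CC structure in *unconnected* pairs: brain oscillations produce
smooth undulation, and nondifferentiable common rate fluctuations (e.g. an
Ornstein–Uhlenbeck or Markov-switching rate, both with CC
`mu^2 + sigma^2 * exp(-2|t|/tau_r)`) produce a cusp at the origin. Naive
flat-null tests misread both as connections.

The package implements three detectors over one GLM family
`lambda(t) = exp(a(t) + J_pos f(t) + J_neg f(-t))`, with
`f(t) = exp(-(t-d)/tau_s)` for `t > d` the synaptic kernel:

* **Classical CC** — exact Poisson band around a flat baseline
  (Bonferroni-corrected), the historical reference method;
* **GLMCC** — the background `a(t)` absorbs undulation under a
  first-derivative smoothness prior `exp(-(1/gamma) ∫ (da/dt)^2 dt)`;
* **ShinGLMCC** — the prior is switched to the second derivative applied
  separately on each half of the lag axis with continuity (but not
  smoothness) at zero, so `a(t)` may bend into a cusp at no cost.

Connections are detected per direction with a Wilks likelihood-ratio test:
`D = log L(J = Jhat) - log L(J = 0)`, detect when `2D` exceeds the
chi-square(1) upper-alpha quantile (default `alpha = 1e-4`), with
`(tau_s, d)` searched over {1,2,3,4} × {1,2,3} ms by penalized likelihood.

Also included, as first-class tested code: doubly stochastic pair generators
(sinusoid, Gabor, OU, telegraph, mixtures) with their closed-form CCs, an
injected-synapse generator for recovery benchmarks, a multi-timescale
adaptive-threshold (MAT) spiking-network simulator with log-normal
excitatory connectivity for ground-truth data, and macro-averaged Matthews
correlation scoring of estimated connection matrices.

## Worked example

```r
library(shinglmcc)

# A pair with a known excitatory connection (J = 1, tau_s = 2 ms, d = 2 ms)
pair <- inject_synaptic_pair(r_pre = 5, r_post = 5, J = 1.0,
                             tau_s = 2, d = 2, duration = 3600, seed = 1)
cc  <- cross_correlogram(pair$spikes, ref = 1, tgt = 2)
dec <- lr_decide(cc, method = "shin")
tidy(dec)
#> # A tibble: 2 × 6
#>     pre  post       J      D detected sign
#>   <dbl> <dbl>   <dbl>  <dbl> <lgl>    <chr>
#> 1     1     2  1.09   65.2   TRUE     excitatory
#> 2     2     1 -0.0902  0.344 FALSE    none
```

The forward direction is detected as excitatory with coupling close to the
injected `J = 1` (`2D = 130 >> z_alpha = 15.1`); the reverse direction is
correctly rejected. `autoplot(dec$fit)` overlays the fitted background and
total intensity on the correlogram.

Estimating and scoring a whole matrix from simulated ground truth:

```r
cfg  <- mat_config(n = 30, n_exc = 24, duration = 600, A = 1.2)
net  <- build_network(cfg, seed = 1)
sim  <- simulate_mat_network(cfg, net, seed = 1)
conn <- estimate_connectivity(sim, method = "shin")
evaluate_connectivity(net, conn)
#> # Connectivity evaluation
#> # A tibble: 2 × 8
#>   category      TP    FP    FN    TN     FPR   FNR   MCC
#>   <chr>      <int> <int> <int> <int>   <dbl> <dbl> <dbl>
#> 1 excitatory    18     0     6   785 0       0.25  0.863
#> 2 inhibitory    41     1     6   822 0.00122 0.128 0.919
#> macro MCC = 0.8907
```

ShinGLMCC recovers most detectable edges in 10 minutes of data with almost
no false positives at the strict default `alpha = 1e-4`. The excitatory
category counts only ground-truth conductances above the 0.01 detectability
floor (most log-normal excitatory weights fall below it); weaker edges are
excluded from scoring rather than counted as negatives.

A shell front end wraps the same pipeline:

```sh
exec/shinglmcc simulate --n 100 --duration 600 --A 1.2 --seed 1 --out sim/
exec/shinglmcc estimate --in sim/spikes.txt --method shin --out est/
exec/shinglmcc evaluate --truth sim/truth_edges.tsv --edges est/edges.tsv \
                        --n-units 100 --out eval/
```

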