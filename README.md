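# sptkinetics

Single-molecule tracking of chromatin-associated proteins — HP1-family
proteins such as Swi6 and Chp2 in fission yeast, and their binding partners
— produces tables of localizations grouped into short trajectories. Hidden
in those tables are the quantities that describe how a protein engages
chromatin: how many **mobility states** it occupies, the **diffusion
coefficient** and **weight fraction** of each, the **rate constants** for
switching between chromatin-bound and free states, the true **dissociation
rate** once photobleaching is removed, and whether bound molecules
**cluster** in nuclear space. sptkinetics computes all of these from plain
localization CSVs, and ships a simulator that generates data with exactly
the statistical structure the estimators assume, so every stage is testable
end to end.

The models, briefly (details in `vignette("sptkinetics-methods")`):

* **Mobility states.** Per-frame displacements follow a K-state hidden
  Markov model: each coordinate of a step is N(0, 2·D_k·Δt + 2σ²_loc) given
  the state, with per-frame Markov switching. A Gibbs sampler
  (forward-filtering backward-sampling + conjugate updates) yields posterior
  D_k, weight fractions π_k and the per-frame transition matrix T; BIC on
  the marginal step likelihood selects K.
* **Rate constants.** A Bayesian Synthetic Likelihood Metropolis sampler
  turns T (per 40 ms frame) into continuous-time rates k_ij (s⁻¹): fine
  0.4 ms binomial transition simulations define a Gaussian synthetic
  likelihood; multiplicative Student-t(10) proposals and a Jeffreys 1/k
  prior complete the posterior. For two states the matrix logarithm of T is
  an exact oracle the sampler is validated against.
* **Residence times.** Time-lapse imaging with constant integration time
  τ_int and variable dark delays gives apparent exponential rates obeying
  k_app·τ_TL = k_diss·τ_TL + k_bleaching·τ_int; weighted linear regression
  separates dissociation from photobleaching, and mean dwell = 1/k_diss.
* **Spatial clustering.** Edge-corrected Ripley K on circular nuclei,
  H(r) = √(K/π) − r, per-cell curves aggregated by localization density,
  normalized against trajectory-matched resampled controls to remove the
  clustering that trajectory autocorrelation alone produces.

## Worked example

Simulate a two-state protein (bound: D = 0.008 µm²/s, free: 0.22 µm²/s,
per-frame transition matrix [[0.99, 0.01], [0.12, 0.88]]), then recover the
states and the rate constants:

```r
library(sptkinetics)

T2  <- matrix(c(0.99, 0.01, 0.12, 0.88), 2, 2, byrow = TRUE)
cfg <- sim_config(K = 2, D = c(0.008, 0.22), T_frame = T2,
                  n_tracks = 400, min_len = 5, seed = 7)
ts  <- simulate_trajectories(cfg)
ts
#> <trajectory_set> 9811 localizations in 400 tracks across 1 cell(s)
#>   dt_frame = 0.04 s, sigma_loc = 0.02 um, ground-truth states present

fit <- infer_states(ts, hmm_config(K = 2, iterations = 400,
                                   burn_in = 100, seed = 1))
occupancy_and_transitions(fit)
#> # A tibble: 2 × 6
#>   state D_um2_s     D_sd     pi p_to_1 p_to_2
#> 1     1 0.00782 0.000190 0.918   0.990 0.0104
#> 2     2 0.198   0.00777  0.0820  0.130 0.870
```

State 1 is the chromatin-bound population: D̂ = 0.0078 µm²/s (truth 0.008),
92% of steps, and a 1.0% per-frame probability of unbinding — all within
the posterior uncertainty of the simulated truth. Converting the per-frame
matrix into continuous-time rates:

```r
obs  <- observed_transitions(fit$T_frame, dt_exp = 0.04, n_obs = fit$n_steps)
post <- infer_rate_constants(obs, bsl_config(n_sim = 1000,
                                             chain_length = 15000,
                                             burn_in = 3000, seed = 2))
tidy(post)
#> # A tibble: 2 × 6
#>   term   from    to estimate hdi_lower hdi_upper
#> 1 k_1_2     1     2    0.279     0.233     0.343
#> 2 k_2_1     2     1    3.59      2.98      4.34

mean_dwell_time(post$rates[["k_1_2"]])
#> [1] 3.578648
```

The bound state dissociates at ≈ 0.28 s⁻¹ (mean dwell ≈ 3.6 s) and rebinds
at ≈ 3.6 s⁻¹. Separating true dissociation from photobleaching with
simulated time-lapse data (truth: k_diss = 0.26 s⁻¹, k_bleaching = 1.5 s⁻¹):

```r
dw <- simulate_timelapse_dwells(timelapse_config(
  tau_int = 0.2, tau_delays = c(0, 0.3, 0.8, 1.8, 3.8),
  k_diss_true = 0.26, k_bleach_true = 1.5, n_molecules = 5000, seed = 3))
fit_dissociation(dw, method = "geometric")
#> <dwell_fit> k_diss = 0.2523 +/- 0.00691 1/s; k_bleaching = 1.513 +/- 0.0285 1/s
#>   mean dwell time: 3.964 s
```

Each fitted object has `tidy()`, `glance()` and `autoplot()` methods;
`normalized_H()` and `render_heatmap()` cover the spatial analyses; and
`run_pipeline()` chains everything with per-stage seeds and a manifest. A
command-line wrapper lives at `inst/scripts/spt_pipeline.R`.

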