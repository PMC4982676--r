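# stdpmotifs

Spike-timing-dependent plasticity (STDP) in a recurrent network couples the
fate of every synapse to the activity — and therefore to the connectivity —
of the whole circuit. `stdpmotifs` implements an exact theory of that
coupling for networks of linear Poisson (Hawkes-type) spiking neurons,
together with a stochastic spiking simulator and the full plasticity
dynamics, so that the spontaneous emergence of **wide synfire chains** and
**self-connected assemblies** from random initial connectivity can be
reproduced and probed on a desk machine. It is aimed at computational
neuroscientists studying self-organization of neural circuits under local
plasticity rules.

## The theory in brief

Neuron `i` fires Poisson spikes at intensity
`λ_i(t) = Σ_k W_ik (a * S_k)(t) + b_i`, with a unit-area synaptic kernel
`a(t) = a0 exp(−(t−d)/τ1)(1 − exp(−(t−d)/τ2))`. For slow learning, the mean
drift of a synapse under an STDP window `F` is the overlap
`Δ_ij = ∫ F(τ) C_ij(τ) dτ` with the stationary spike correlation `C`, which
is available exactly:

    Δ = f0 r rᵀ + (1/2π) ∫ dω F̃(−ω) (I − ã(ω)W)⁻¹ D (I − ã(−ω)Wᵀ)⁻¹

Expanding the inverses in powers of `W` expresses the drift as a sum over
**structural motifs** `{α, β}` — a source neuron reaching the post-synaptic
neuron through `α` synapses and the pre-synaptic neuron through `β` — each
weighted by a coefficient `f_{α,β} = ∫ F·c_{α,β}` that depends only on the
window and the kernel. Third-order motifs such as `{2,1}` couple synapses of
*different* neurons and are what makes wide (grouped) structures possible;
the synaptic latency `d` selectively suppresses the low-order coefficients
and thereby opens a window in which chains form spontaneously. The full
dynamics add heterosynaptic competition, self-depression, constant growth,
hard bounds and balanced inhibition. A k-means-based **chain score** in
[0, 1] quantifies how close a weight matrix is to an ideal wide chain (or
assembly partition).

## Worked example

Motif coefficients with and without a 6 ms synaptic latency, then chain
formation under the full dynamics at that latency:

```r
library(stdpmotifs)
Fa <- make_stdp("antisymmetric")
sapply(c(0, 0.006), function(d) {
  k <- make_alpha_kernel(latency_d = d)
  c(f10 = motif_coefficient(Fa, k, 1, 0),
    f20 = motif_coefficient(Fa, k, 2, 0),
    f21 = motif_coefficient(Fa, k, 2, 1))
})
#>      [,1]  [,2]
#> f10 703.7 247.4
#> f20 198.3   9.4
#> f21 236.6 215.9
```

The latency cuts the first-order coefficient `f10` by ~65 % and the
second-order `f20` by ~95 %, while the chain-promoting third-order `f21`
barely moves (−9 %) — precisely the regime in which chains can win.

```r
cfg <- figure_preset("fig7_latency_sweep", latency_d = 0.006,
                     max_iters = 5000)
W0 <- generate_initial_weights(20, 5, cfg$w_max, scale = 1.5, seed = 1)
traj <- run_deterministic(W0, cfg)
chain_score(W0, wrap = TRUE)               # random initial weights
#> chain score: 0.489923 (best k = 2)
chain_score(traj$final_state, wrap = TRUE) # after plasticity
#> chain score: 0.997119 (best k = 4)
```

Starting from uniform random weights (score ≈ 0.49, no structure), the
dynamics self-organize into a near-perfect wide synfire chain — four ordered
groups of five neurons, score ≈ 0.997 — within the equivalent of a few
simulated hours. `run_stochastic()` reproduces the same trajectory from
actual spikes when the learning rate is small, and `run_experiment()` sweeps
latency, self-depression or motif coefficients over grids with several
random initializations.

## Acceptance script

`scripts/acceptance.R` recomputes the package's two
calibration targets from scratch by running the package itself: the
numerical integral of the default synaptic kernel after normalization, and
the chain score assigned to an exact 20-neuron, 4-group feed-forward block
matrix built programmatically. Run it from the repository root:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

It writes one JSON object with a numeric `value` (and the problem size `n`)
per target.
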