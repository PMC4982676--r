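---
title: "Motif expansion of STDP drift: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motif expansion of STDP drift: models, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stdpmotifs)
```

# The model

`stdpmotifs` studies how spike-timing-dependent plasticity (STDP) reshapes
the connectivity of a recurrent network of *linear Poisson* (Hawkes-type)
spiking neurons. Neuron $i$ fires as an inhomogeneous Poisson process with
intensity

$$\lambda_i(t) = \sum_k W_{ik} \int^t a(t - t')\, S_k(t')\, dt' + b_i,$$

where $S_k$ is the spike train of neuron $k$, $b_i$ a constant external
input, and $a(t)$ the post-synaptic current kernel

$$a(t) = a_0\, e^{-(t-d)/\tau_1}\left(1 - e^{-(t-d)/\tau_2}\right),
\qquad t > d,$$

normalized to unit area ($\tau_1 = 5$ ms, $\tau_2 = 1$ s by default; $d$ is
the synaptic latency). Unit area gives synaptic efficacies a concrete
meaning: a synapse of weight 1 adds on average one spike to its
post-synaptic target per pre-synaptic spike — a fact the test suite verifies
directly on the stochastic simulator.

With all-to-all spike pairing, the expected change per unit time of a
synaptic efficacy (the *drift*) is the overlap of the STDP window $F$ with
the stationary pair correlation,
$\Delta_{ij} = \int F(\tau)\, C_{ij}(\tau)\, d\tau$. Because the network is
linear, $C$ is known exactly in the frequency domain, which yields the exact
drift

$$\Delta^{\mathrm{STDP}} = f_0\, r r^T + \frac{1}{2\pi} \int d\omega\,
\tilde F(-\omega)\, (I - \tilde a(\omega) W)^{-1} D
(I - \tilde a(-\omega) W^T)^{-1},$$

with $r = (I - W)^{-1} b$ the stationary rates, $D = \mathrm{diag}(r)$ and
$f_0 = \tilde F(0)$ the window area. Expanding the matrix inverses in powers
of $W$ rewrites the drift as a sum over *structural motifs*: a source neuron
reaching the post-synaptic neuron through $\alpha$ synapses and the
pre-synaptic neuron through $\beta$ synapses contributes
$f_{\alpha\beta}\, [W^\alpha D (W^\beta)^T]_{ij}$, with the motif
coefficient

$$f_{\alpha\beta} = \int F(t)\, c_{\alpha\beta}(t)\, dt, \qquad
c_{\alpha\beta} = \underbrace{a * \cdots * a}_{\alpha}\; * \;
\underbrace{\bar a * \cdots * \bar a}_{\beta}, \quad \bar a(t) = a(-t).$$

The package computes coefficients both this way (`method = "time"`) and via
the equivalent frequency-domain integral (`method = "frequency"`); the two
routes agree to better than $10^{-3}$ relative through fifth order for all
three window families, which the tests assert.

The full plasticity dynamics combine the STDP drift with heterosynaptic
competition (row- and column-sum excesses over a total bound
$W_{\max} = M\, w_{\max}$ penalized at rate $\psi$), self-depression
($-\mu W$), constant growth ($+\gamma$) and hard per-synapse bounds
$[0, w_{\max}]$. Balanced inhibition — a row-constant inhibitory component
that cancels each neuron's summed excitation — keeps the rates pinned at
$b$ and stabilizes the spiking network.

# Tunable parameters

| parameter | meaning | default | why |
|---|---|---|---|
| $\tau_1, \tau_2, d$ | kernel decay, saturation, latency | 5 ms, 1 s, 0 | reference kernel |
| window family | antisymmetric / mexican-hat / asymmetric | antisymmetric | chain experiments |
| $N$, $M$ | neurons, group-size parameter | 20, 5 | reference network scale |
| $W_{\max}$, $w_{\max}$ | total and per-synapse bounds | 0.9, $0.9/M$ | see note below |
| $b$ | external input | 15 Hz (5 Hz assemblies) | cortical-range rates |
| $\eta, \psi, \mu, \gamma$ | learning, competition, depression, growth rates | per preset | per-experiment presets |
| `step_cap` | adaptive-Euler max weight change per step | 0.02 | per-experiment presets |
| `dt` | stochastic Euler step | 0.25 ms | resolves the ms-scale kernel rise |

**The $w_{\max}$ scale.** The bounds admit two parameterizations: a
per-synapse bound of order $0.9 M$ would put row sums near
$0.9 M^2 \approx 22$ and make the linear network violently unstable (the
theory requires all eigenvalues of $W$ below 1 in magnitude). The package
therefore fixes the *total* per-neuron bound at $W_{\max} \in \{0.85,
0.9\}$ — safely below the stability limit of 1 — with the per-synapse bound
$w_{\max} = W_{\max}/M$, and draws initial weights on
$[0, s\, w_{\max} M/N] \subset [0, 0.09]$. With this scale every preset is
stable and chain formation takes hours of biological time at
$\eta \sim 10^{-7}$, the expected scale for this class of models.

**Learning-rate bookkeeping.** The weight equation can be read with
$\eta$ multiplying only the STDP term or all plasticity terms. With $\mu$,
$\psi$, $\gamma$ at their preset values *unscaled*, self-depression
($\mu \approx 4500\,/\mathrm{s}$) would crush every weight to
$\gamma/\mu$ within a second and STDP could never shape the connectivity;
the effective self-depression rate must be $\eta\mu$. The package therefore
multiplies *all* plasticity terms by $\eta$ (switch:
`eta_scales_slow_terms = FALSE` selects the other reading). For
deterministic runs with the adaptive step this choice only fixes the time
units; the fixed points are identical.

One consequence: the competition excess at equilibrium is set by the ratio
of the drift scale to $\psi$, roughly 4–6 % of $W_{\max}$ at the preset value
$\psi = 5\cdot 10^4$, not arbitrarily small. The tests assert that the
excess stays below 10 % and shrinks when $\psi$ grows, which is the
mechanistically correct statement in this parameterization.

**Asymmetric window sign.** An all-positive "STDP" window is a
potentiation-only rule: it makes the reciprocal-synapse coefficient
$f_{0,1}$ positive, whereas chain formation requires mutual suppression of
reciprocal synapses ($f_{0,1} < 0$). The asymmetric family therefore
defaults to a negative depression branch, $A_- = -0.525/\tau_1^-$ — a
genuinely asymmetric window with unequal lobes and *positive* net area
(normalized to $+150$); a positive $A_-$ remains one constructor argument
away.

# What the generator emulates — and what a green test does not establish

`generate_initial_weights()` *is* the stated world of the experiments:
i.i.d. uniform weights on $[0, s\, w_{\max} M/N]$ with $s = 1$ or $1.5$,
zero diagonal. `simulate_spikes()` realizes the linear Poisson model by
per-step Bernoulli draws at 0.25 ms. Real cortical tissue differs in ways
the model deliberately ignores: refractoriness, conductance-based synapses,
heterogeneous kernels and delays, structured external input, and nonlinear
(e.g. leaky integrate-and-fire) spike generation. A green suite therefore
establishes internal consistency of theory, simulator and score, and
reproduction of the *model's* phenomenology — not a statement about
biological circuits.

# Numerical choices

* **Grids.** Kernels and windows are tabulated at 0.05 ms steps over a span
  chosen so the discarded tail mass is below $10^{-8}$; the ms-scale decay
  constants make these spans a few hundred ms despite the second-scale
  saturation factors. Motif correlations extend the span with the motif
  order to avoid FFT wrap-around.
* **Transforms.** Kernel and window transforms use closed forms (differences
  of complex poles; Gaussian-polynomial for the mexican hat), validated in
  the tests against dense-grid numerical transforms.
* **Frequency integral of the exact drift.** Uniform grid on
  $[0, 3\cdot 10^4]$ rad/s at 2 rad/s, folding negative frequencies by
  conjugate symmetry; all poles sit at least $1/\tau_1 \approx 200$ rad/s
  from the real axis, so this grid oversamples every feature. A tail check
  errors out if the integrand has not decayed at the grid edge. Agreement
  with the independent time-domain route is at the $10^{-8}$ level on random
  stable networks.
* **Time-domain correlations.** `correlation_time()` inverse-FFTs the
  spectrum; the Poisson delta atom and the rate baseline are carried
  symbolically, never as grid spikes. The reconstruction exhibits Gibbs
  ringing of order 0.1–1 % confined to ±2 ms around the kernel-onset kink
  (the spectrum decays only as $\omega^{-2}$); tests compare away from the
  kink or in integrated form.
* **Stochastic engine.** Filtered histories and exponential-window STDP are
  carried as exact per-neuron exponential traces (no history buffers, no
  pairing truncation); mexican-hat pairing uses a windowed pair scan with a
  tail cutoff at $F/F_{\max} \sim 10^{-16}$. Intensities are floored at 0
  before the Bernoulli draw (the linear model formally admits negative
  intensities; flooring is the standard regularization). The slow terms are applied every step, scaled by `dt`.
* **Adaptive Euler.** Each deterministic step scales `h` so the largest
  element change equals `step_cap`, then clips to $[0, w_{\max}]$;
  convergence is declared when the post-clip change stays below
  $e^{-15} \approx 3.1\cdot 10^{-7}$ for 10 consecutive iterations.
* **Degenerate inputs.** All-zero matrices score with $A/\max(A)$ defined as
  0; duplicate neuron profiles short-circuit the clustering with a
  degeneracy flag; empty spike trains yield zero correlograms with an
  `empty` flag.

# Design choices where the definition was open

* **Score normalization.** Defining the chain score as one minus a
  normalized squared distance between the max-scaled weight matrix and the
  ideal binary matrix leaves the normalizer open. The package uses
  $x = \|A/\max A - B\|_F^2 / \|B\|_F^2$, which makes an ideal matrix score
  exactly 1 and bounds the score in $[0, 1]$ after clipping.
* **Head group and $k$ range.** The head of the greedy ordering is maximized
  over all groups (deterministic, can only raise the score) instead of a
  random choice; $k$ ranges over $2 \ldots \lfloor N/2\rfloor$ by default.
* **Ring closure.** Chains that emerge in a recurrent network close into
  rings — at the competition steady state every group must project
  somewhere. A perfect emergent ring scores only ≈ 0.70 against the open
  chain ideal but ≈ 1 against the ring-closed ideal, so the
  self-organization experiments score with `wrap = TRUE`, while
  `chain_score()` defaults to the open ideal (which calibrates the ideal
  open chain to exactly 1).
* **Motif-table runs without input.** The selected-motif experiments use
  $b = 0$, under which the literal expansion would give $r = 0$ and no
  dynamics; the package sets $r \equiv 1$ there, absorbing the uniform rate
  factor into the hand-set coefficients.
* **Inhibition in the theory.** The balanced inhibitory component enters
  both the simulator and the drift theory by default (switchable), since
  with uniform input it pins $r = b$ and is what the plasticity experiments
  used; coefficient illustrations use the excitatory-only structure.

# Desk-scale reductions

The reference experiments average ten random initializations and run tens of
simulated hours. The in-package tests reduce this to: three initializations
for the latency-window property (third- vs second-order truncated dynamics,
which track the exact dynamics); 10 min and 1 h records for the
drift-vs-simulation scatter comparison; and, for the stochastic/
deterministic collapse, two learning rates × two initializations compared
on the $\eta t$ axis over the rise of the chain score ($\eta t \le
7\cdot10^{-3}$, i.e. 5–10 simulated hours). Full-duration runs remain
available through `run_experiment()` and the command-line `sweep`.

# Known limitations

* Only pair-based, weight-independent (additive) STDP; no triplet rules, no
  multiplicative soft bounds, no short-term plasticity.
* One kernel per network; per-synapse heterogeneity is out of scope (the
  adjacency mask is accepted by the containers, and honored by the
  deterministic engine, but the stochastic engine rejects masked states).
* The exact-drift deterministic engine recomputes a frequency integral per
  step and is therefore orders of magnitude slower than the truncated
  engine; the fact — verified by the tests — that third-order truncation
  predicts the emergence regimes is what makes desk-scale sweeps feasible.
* Pointwise time-domain correlograms carry Gibbs ringing near the onset
  kink, as discussed above; integrated quantities (drifts, coefficients) are
  unaffected.

# A worked mini-example

```{r example, eval = FALSE}
# chain formation at the chain-forming preset (latency 6 ms), one init
cfg <- figure_preset("fig7_latency_sweep", latency_d = 0.006,
                     max_iters = 5000)
W0 <- generate_initial_weights(20, 5, cfg$w_max, scale = 1.5, seed = 1)
traj <- run_deterministic(W0, cfg)
chain_score(traj$final_state, wrap = TRUE)
```
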