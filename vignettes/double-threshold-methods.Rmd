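---
title: "Recovering structural topology from functional connectivity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recovering structural topology from functional connectivity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ddtnet)
```

`ddtnet` is built around one question: given a full, noisy functional
connectivity matrix (CM) estimated from parallel spike trains, which entries
correspond to real synapses?  This vignette explains the models and the
numerical choices behind each stage, what the synthetic benchmark does and
does not emulate, and the known limits of the approach.

## The double-threshold algorithm

Every thresholding method here maps a signed CM (entry `[i, j]` = estimated
influence of neuron *i* on neuron *j*; positive excitatory, negative
inhibitory) to a pruned functional matrix (FM) with the same sign
convention.

The double threshold (DDT) works in two passes:

1. **Global pass.** The positive and negative non-zero entries are pooled
   separately; entries strictly beyond `mu + n_exc * sd` (positive) or
   `mu - n_inh * sd` (negative) form `T1CM`, the rest form the rejected
   matrix `RM`.  Sample standard deviations are used throughout
   (denominator n-1; the second pass often sees very small samples, and the
   sample SD is the conservative choice).
2. **Row-wise pass.** For each non-zero `RM[i, j]`, the other same-sign
   non-zero entries of row *i* of `RM` provide an estimate of what neuron
   *i*'s spurious connection values look like: if *i* and *x* are not
   connected, train *x* behaves like a pseudo-shuffled version of train *j*,
   so the row is a surrogate null distribution obtained for free.  The
   element-specific threshold is `TM[i, j] = mu_(i, not j) + m_exc *
   sd_(i, not j)` (minus `m_inh * sd` for negative candidates), with the
   element itself always excluded from the statistics.  Entries strictly
   beyond their own threshold are recovered into `T2CM`, and
   `FM = T1CM + T2CM` (disjoint by construction).

Parameter defaults follow the benchmark settings: `n_exc = 1`, `n_inh = 2`,
`m_exc = m_inh = 3`.  The inhibitory first-pass multiplier is stricter
because negative CM entries are fewer and their null is wider; the row-wise
multiplier is larger because a row offers only a few hundred samples at
most.  Both inequalities are strict, so a degenerate spread (`sd = 0`) keeps
nothing rather than everything.

Two numerical guards apply in the second pass.  An element whose row offers
fewer than `min_candidates` other same-sign entries stays rejected; the
default is 2, the minimum for a sample SD to exist.  A stricter minimum can
be set (the pseudo-surrogate argument is only sound when spurious entries
vastly outnumber real ones in the row), but the default keeps the algorithm
applicable to very small networks, where any larger minimum would disable
the second pass entirely.

The comparison methods share the sign convention: the hard threshold (HT) is
exactly the first DDT pass; the density threshold (DT) keeps the `M_e`
largest positive and `M_i` most negative entries (ties broken row-major for
determinism), and is calibrated per matrix to the DDT link counts so the two
methods are compared at identical network size; the shuffle threshold (SH)
re-estimates each pair's strength against `n_shuffles` timing-shuffled
copies of the target train and applies a one-sided z-test at level `alpha`
(default 0.01) on the tail matching the entry's sign.  SH shuffles only the
target train of each ordered pair, and surrogates are drawn once per train
and re-used across sources.

## The connectivity estimator

Any estimator producing a signed CM can be plugged in
(`estimate_cm(..., estimator = )`), e.g. a spiking-probability-edge
estimator; the built-in default is a signed delayed cross-correlation:

* For each ordered pair, spike times are binned (1 ms) and the occurrences of
  the target firing 1..30 ms after the source are histogrammed.  Lag 0 is
  excluded — simultaneous spikes carry no direction.  The 30 ms window covers
  the 1-20 ms conduction delays plus the width of the synaptic correlation
  hump.
* Sliding sums over a 5-bin window are compared with the pair's mean count
  per lag.  The 5 ms width matches the observed width of the
  excitation-driven hump (delivery at the conduction delay plus 1-4 ms of
  integration to threshold); the per-pair mean absorbs co-modulation that
  inflates every lag equally, which is the dominant contamination in
  synchronously bursting networks.
* The dominant deviation decides the call: a window peak (excess counts at
  some lag) is evidence of excitation, a window trough (missing counts,
  i.e. post-synaptic suppression) of inhibition.  The signed deviation is
  divided by the geometric mean of the two spike counts so values are
  comparable across firing-rate differences.

On statistically independent trains the statistic is approximately centred
on zero with small skew (the peak and trough competitions nearly cancel);
the property suite checks this on homogeneous Poisson pairs.  This
near-symmetric null is what makes the sign-split statistics of the
thresholding methods meaningful.

Alternative summarizations were evaluated on simulated benchmarks before
freezing this design: single-lag extremes lose broad humps, median and
late-lag baselines bias the null off zero, flanking-window (edge-filter)
contrasts suppress legitimate broad peaks, and per-pair z-normalization
destroys the cross-pair comparability that the global first threshold needs.

## Structural generators

All generators share the population layout: neurons `1..n_excitatory`
(default 400) are excitatory regular-spiking, the rest (default 100)
inhibitory fast-spiking.  Excitatory links are positive and may target
anyone; inhibitory links are negative and target excitatory neurons only.
Initial weights are N(7, 1) for excitatory and N(-7, 1) for inhibitory
links, clipped away from zero (floor 0.1 in magnitude) so sign invariants
cannot be violated by the tail of the Gaussian.  Excitatory conduction
delays are uniform on the integers 1..20 ms and drawn per link (the
alternative — one delay shared by all links of a neuron — is equally
compatible with the model description; per-link draws give the estimator no
shortcut); inhibitory delays are fixed at 1 ms.  At the defaults every
generator produces exactly 20,000 links.

* **Random (RND).**  Every neuron picks `out_degree` (default 40) distinct
  targets uniformly.  In-degrees are binomial, mean excitatory in-degree
  exactly 32 and inhibitory-onto-excitatory in-degree exactly 10 by
  counting.
* **Small-world (SW).**  A directed ring lattice on the excitatory
  population (`out_degree/2` neighbours per side) is rewired with
  probability 0.3 per link (Watts-Strogatz).  A small number of links is
  then *translated* — their targets moved onto inhibitory neurons.  How many
  to translate is genuinely open; the package uses 4 per interneuron on
  average (with every interneuron guaranteed one), the minimum that reliably
  recruits the inhibitory population while preserving the lattice clustering
  that carries the small-world signature.  The inhibitory block is connected
  at random.
* **Scale-free (SF).**  Out-degree sequences are drawn per block from
  preferential attachment with shifted-linear kernel: attachment probability
  proportional to `degree - m/2`.  The negative offset steepens the
  asymptotic degree exponent from the textbook value 3 to 2.5, the middle of
  the range reported for neuronal recordings.  Targets are then
  assigned uniformly per row — the row shuffle: it removes most bidirectional
  pairs and makes in-degrees binomial while preserving each row's
  out-degree, so the network has scale-free *out*- and normal *in*-degree
  distributions.
* **Modular.**  Weakly coupled Bernoulli blocks (defaults: two excitatory
  modules of 175, one inhibitory module of 100, `intra_p = 0.15`,
  `inter_p = 0.01`).  This generator is parameterized rather than calibrated:
  the quantitative settings of the original modular networks are not public,
  so it carries no reference values.

## The simulator

Izhikevich dynamics (`v' = 0.04 v^2 + 5v + 140 - u + I`, spike cutoff 30 mV)
with regular-spiking parameters (a = 0.02, b = 0.2, c = -65, d = 8) for
excitatory and fast-spiking (a = 0.1, same b, c, d) for inhibitory neurons.
Integration uses the reference scheme for this model: a 1 ms grid with the
membrane potential advanced in two 0.5 ms half-steps and the recovery
variable in one full step.  The Euler overshoot above the 30 mV cutoff is
clamped before the recovery update so that every spike cycle is identical;
without the clamp, the recovery increment depends on the (meaningless)
overshoot magnitude and tonic firing acquires artificial jitter.  A
single-neuron test checks the integrator against a 0.01 ms reference
integration.

Synaptic delivery is event-based: a spike of *i* at *t* adds `w[i, j]` to
*j*'s input current at `t + delay[i, j]` (ring buffer over the maximum
delay).  STDP acts on excitatory weights only, with exponential windows
(`A+ = 0.1`, `A- = 0.12`, `tau = 20 ms`), nearest-neighbour pre/post pairing
evaluated at arrival times, clipping to `[0, w_max]` (`w_max = 10`), and a
freeze at `stdp_freeze_time` (default 300 s of a 900 s run) after which
weights stay constant — the weight matrices at the freeze and at the end are
returned and tested for identity.  Pairing convention (nearest-spike rather
than all-to-all) is a design choice; the model description does not fix it.

Two noise drives are available.  The default `"kick"` injects a fixed
current (20) into one uniformly chosen neuron per millisecond — the
convention of the delay/STDP network model this simulator follows; note its
per-neuron rate scales inversely with network size.  `"gaussian"` adds
independent N(0, `noise_amp`^2) current to every neuron each millisecond and
is the right choice for small networks, where a per-millisecond kick would
be far too strong.  The noise model and amplitude are recorded in the run
metadata, since the dynamical regime depends on them.

At the 500-neuron defaults the kick drive produces the in vitro-like regime
the benchmark needs: a few spikes per second per neuron, network-wide
synchronized bursts, and an STDP weight distribution that spreads towards
both clip boundaries.  Exact firing/bursting rates are sensitive to the
unspecified noise parameters, so the suite checks qualitative bands
(sustained non-saturated firing, presence of bursts), not point values.

## Benchmark protocol and problem sizes

The canonical pipeline is: generate structural network, simulate 900 s
(STDP frozen at 300 s), estimate the CM from the full recording, threshold,
score.  Simulations run the full 15-minute recording because the compiled
simulator makes them cheap (tens of seconds); the acceptance script runs the
degree sweep at k = 30/40/50 with one realization per k, plus two further
realizations at k = 40 for the functional degree-distribution fits, and six
networks per topology for the structural statistics.  Those sizes keep the
whole script in the minutes range on one CPU while staying at the full benchmark
network size (500 neurons, 20,000 links).

Scoring uses the three-class confusion matrix over ordered off-diagonal
pairs (excitatory / absent / inhibitory by sign) and accuracy = correctly
classified pairs over all pairs.  The denominator includes the true
negatives: leaving them out (as shorthand forms of the formula sometimes
do) would allow values above 1.  Missed links are pooled as false negatives
regardless of sign.

## Topology metrics

Clustering coefficient and path length are computed on the binarized,
symmetrized graph (an undirected edge wherever either direction exists):
the pair-count denominator of the clustering coefficient is undirected, and
applying it to a directed graph would double-count.  Nodes with fewer than
two neighbours contribute zero clustering; unreachable pairs are excluded
from the path length and their fraction is reported.  The small-world index
is `(C/C_rand)/(L/L_rand)` with the reference values averaged over 20
Erdős–Rényi G(n, m) graphs with the same node and edge counts.  Twenty references
keep the ensemble noise well below the spread across network realizations.

Degree-distribution fits: the Gaussian family is a least-squares fit of a
normal density to the unit-bin histogram (via `minpack.lm`), reporting mean,
SD and R²; the power-law family is a linear fit of log10 frequency against
log10 degree over non-empty bins.  Both are also available on complementary
cumulative distributions (`cumulative = TRUE`), which is less sensitive to
tail binning; density fitting is the default and is what the reference
Gaussian statistics use.  Hubs are nodes whose total degree (in + out; a
knob) is at least one SD above the network mean; a regular graph has no hubs
by definition (zero spread), avoiding the degenerate all-hubs reading.

## The five-neuron worked example, honestly

`run_five_neuron_example()` reproduces the classic illustration: 5
excitatory neurons, 7 links, 900 s of activity, estimate, DDT with the
walk-through setting `n = 1, m = 1`.  At this size the algorithm's own
premise is strained: 7 of 20 ordered pairs are true links, so the
"rejected row" that the second pass uses as a null distribution is heavily
contaminated by signal, and two-step chains (i to k to j) produce secondary
correlation peaks that a generic cross-correlation cannot distinguish from
direct links.  With the built-in estimator the example recovers all 7 links
exactly in roughly a third of random seeds — the function reports whether
the current seed did.  A front end with sharper effective-connection
filtering can be plugged in via `estimate_cm(estimator = ...)`.  The
500-neuron benchmark, where spurious entries outnumber real ones 11 to 1
per row, is the regime the algorithm is designed for.

## Known limitations

* Correlation-based estimation degrades at low firing rates; the modular
  regime (sparser, less synchronous) is supported by the generator and
  simulator but carries no calibrated reference values.
* The SH method is faithful but quadratic in neurons times shuffles; at the
  500-neuron scale it is exercised only at reduced surrogate counts.
* Inhibitory links are detected through missing spikes, which needs a
  sufficient baseline rate in the target; inhibitory recovery is therefore
  systematically harder than excitatory, visible in the confusion matrices.
* Simulated dynamics emulate dissociated cortical cultures (synchronized
  bursting, 80/20 balance); passing benchmarks here does not certify
  performance on regimes the generator does not produce (strong spatial
  structure, pathological synchrony, non-stationary rates).
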