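---
title: "Modelling artefact evolution and attention with categorical hidden Markov models"
author: "artefactHMM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling artefact evolution and attention with categorical hidden Markov models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(artefactHMM)
```

## The model

`artefactHMM` treats an artefact class — the running example is a generic
knapping tool — as a categorical hidden Markov model. The hidden state
$s_t$ is the material shape the artefact takes in period $t$
(`rounded`, `squared`, `sharp`); the observation $o_t$ is the function that
shape affords and that leaves traces in the archaeological record
(`crushing`, `cracking`, `cutting`). Three parameter blocks define the joint
distribution

$$P(s_{1:T}, o_{1:T}) \;=\; D(s_1)\,\prod_{t=1}^{T} A(o_t \mid s_t)
\prod_{t=2}^{T} B(s_t \mid s_{t-1}),$$

where $A$ is the likelihood (shape $\to$ afforded function), $B$ the
shape-transition matrix across periods, and $D$ the initial shape
distribution. Two conventions hold everywhere in the package:

* **columns are the categorical distributions** — `A[o, s]` is a
  distribution over observations for each fixed state column, and
  out-of-tolerance columns are rejected, never silently renormalised;
* **`B` maps time $t-1$ to $t$** — column $j$ of a slice is the
  distribution over the next state given previous state $j$. `B` may carry
  several action-conditioned slices; the default configuration has a single
  uncontrolled slice named `advance`.

The same structure serves two roles. A `GenerativeModel` is the agent's (or
the analyst's) beliefs; a `GenerativeProcess` is the environment's true
parameters, from which `simulateTrajectory()` and `generateRecord()` draw
data. Keeping them as distinct classes makes explicit which side of the
agent/environment divide a function expects.

The uncontrolled-versus-controlled status of the transition model in the
visual-foraging setting is genuinely open; the package supports both (a
single slice, or one slice per action) and asserts neither as canonical. The
bundled `foraging_grid` uses a single reading-order cycle,
`foraging_grid_controlled` adds four movement actions; they are otherwise
identical.

## Inference and forecasting

`forwardFilter()` implements the exact forward recursion
$Q(s_t \mid o_{1:t}) \propto A(o_t \mid \cdot)\, [B\,Q_{t-1}]$ (with $D$ in
place of $B Q_0$ at the first step). The test suite checks it against
brute-force enumeration of all $|S|^T$ state sequences on random models; the
two agree to $10^{-10}$. An observation sequence with zero likelihood under
the model stops with a "degenerate evidence" error rather than returning NaN
posteriors — silent propagation of an impossible-evidence state would poison
every downstream quantity. `predictStates()` iterates a `B` slice without
evidence, and `predictObservations()` returns $A\,Q$.

## Environmental precision

Each column of a parameter matrix carries Shannon entropy
$H(p) = -\sum_k p_k \log p_k$; summing over columns gives the environmental
entropy of the whole matrix, the quantity `environmentalPrecision()` reports.
Entropy is reported in nats (natural logarithm) throughout — this makes the
closed-form anchors ($\log K$ for a uniform $K$-vector) exact; a
`base = 2` argument on `columnEntropy()` is cosmetic output only.

"Precision" is used directionally (high precision = low entropy) rather than
by a fixed formula, so the report carries both the raw summed entropy and a
normalised scalar $1 - H_{\text{total}}/H_{\text{max}}$ with
$H_{\text{max}} = n_{\text{cols}} \log n_{\text{rows}}$, defined as 1 when
$H_{\text{max}} = 0$. The normalised value is 1 exactly when every column is
one-hot (a fully deterministic shape–function or shape–shape mapping) and 0
for an all-uniform matrix. Gaussian-style precision as inverse covariance is
out of scope: the package is strictly categorical.

Substantively, high precision of $A$ in a trained model suggests shapes were
reliably used for specific functions (specialisation); high precision of $B$
suggests shapes persisted or progressed reliably across periods
(transmission). Those readings are interpretive, not computed claims.

## Gain control

Covert attention — reweighting sensory evidence — is implemented as
temperature scaling of likelihood columns: `applyGainControl(A, gamma)`
raises each column entrywise to the power $\gamma \ge 0$ and renormalises.
$\gamma > 1$ sharpens, $\gamma < 1$ flattens, $\gamma = 1$ is the identity.
The boundary case $\gamma = 0$ follows a documented convention: structural
zeros are preserved (an affordance the environment rules out cannot be
conjured by inattention) and the column becomes uniform over its support.
For strictly positive $A$, total entropy is non-increasing in $\gamma$ on
$\gamma \ge 1$, a property the suite checks on a grid.

## The count-based learning rule

Parameters are learned by counting: a piece of evidence for a mapping adds
`+1` (or any positive weight) to the corresponding cell of a count matrix,
and column-normalisation turns accumulated counts into parameters — a cell
at weight 0.3 becomes 1.3, and against a competitor at 0.7 normalises to
0.65 versus 0.35. Two interpretive choices were open:

* **Persistent counts.** The update is applied to persistent evidence
  weights, not to already-normalised probabilities: the probability-space
  reading is not closed under repeated evidence (adding 1 to a probability
  and renormalising forgets how much evidence the column has already
  absorbed), whereas counts make repeated updates commutative and
  order-invariant.
* **Fractional weights.** Evidence need not be empirical finds; weaker
  theoretical evidence can be added with fractional weight, so
  `incrementCounts()` accepts any positive weight.

`learnFromRecord()` tallies a tabulated record (site, period, shape,
function) into the three count blocks: co-occurring shape/function rows feed
$A$; pairs of rows at *consecutive* periods within the same site feed $B$
(period gaps contribute nothing — a site with periods 1 and 3 says nothing
direct about one-step change); each site's earliest-period shape feeds $D$.
Missing fields are skipped by exactly the tallies that need them, never
imputed. Default priors are zero (pure frequency counting, matching the
literal +1-on-evidence scheme); a uniform pseudo-count argument exists for
records that leave cells unobserved, since a zero-sum column cannot be
normalised and is reported as an error naming the column.

## Salience as expected information gain

Overt attention scores candidate actions by how much they are expected to
teach the agent about the hidden state. No formula for salience is fixed by
the verbal treatment, so the package adopts the standard epistemic-value
measure from the discrete active-inference literature. With predictive state
prior $Q' = B_a Q$ and predictive observation distribution $P(o) = A Q'$,

$$\mathrm{EIG}(a) \;=\; \sum_o P(o)\; \mathrm{KL}\!\left[\,Q'(\cdot \mid o)
\,\|\, Q'\,\right],$$

the expected KL divergence between post-observation posterior and prior —
algebraically the mutual information between next state and next observation
under the model. The two qualitative limits hold by construction and are
enforced as tests: an action whose outcome is already known (one-hot
predictive belief) has zero salience, and an uninformative likelihood
(identical columns) makes every action worthless. The gain is bounded above
by the entropy of $Q'$. Numerically, round-off can leave a gain a few
$10^{-16}$ below zero; values above $-10^{-12}$ are clamped to 0 and
anything more negative is an error.

Action selection is purely epistemic and single-step: no preference
(pragmatic) term and no multi-step policies, both deliberately out of scope.
Ties are broken by the earliest action in the supplied order, which makes
the loop deterministic given the seed. An alternative reading of the
"uncertain likelihood ⇒ looking is useless" limit via Dirichlet parameter
uncertainty (rather than a flat $A$) is coherent but not implemented; the
flat-$A$ reading is what the gain-control coupling test exercises.

`runActiveLoop()` couples the pieces: filter the initial observation, then
repeatedly score actions, act, let the environment transition and emit under
the chosen action, and update the belief by Bayes. Model and process must
share state, observation and action labels.

## The synthetic record generator

No external artefact datasets are required: `generateRecord()` produces
records from a known `GenerativeProcess`, which makes parameter-recovery
claims testable. Per site it samples a shape trajectory from $D$ then $B$,
emits one function observation per period from $A$, and then blanks each
shape/function field independently with probability `missingness`. One find
per (site, period) keeps the $B$ tallies well-defined; richer assemblages
are emulated by replicate sites. The generator emulates sampling noise and
missingness only — it does not model taphonomy (differential preservation by
material), spatial structure within sites, or survivorship bias; record
frequencies are taken to reflect use frequencies. Recovery results on
synthetic records therefore show statistical consistency of the counting
rule, not robustness to those real-world distortions.

`degradePrecision()` is the environmental counterpart of gain control:
column-wise convex mixing toward uniform,
$(1-\lambda)\,M_{\cdot j} + \lambda/K$. Degraded visibility is described in
the source literature only by example, so mixing was chosen as the minimal
deterministic operator with the right anchors ($\lambda = 0$ identity,
$\lambda = 1$ all-uniform) and, by concavity of entropy, monotone entropy
along $\lambda$.

## Bundled configurations and fixture choices

Two worked configurations ship with the package, built in code and validated
at load time. Several details are fixture choices the narrative leaves open,
not claims:

* `foraging_grid` completes the 2×2 grid beyond the two named
  location/colour pairs with `down-left` → `red`, `down-right` → `green`,
  and a deterministic reading-order cycle UL → UR → DL → DR → UL;
* `knapping_tool_deterministic` fixes $A$ as the identity on
  (rounded → crushing, squared → cracking, sharp → cutting) and $B$ as the
  progression rounded → squared → sharp with **sharp absorbing** — the
  progression's endpoint behaviour is underdetermined, and absorption is the
  simplest completion; $D$ is one-hot on `rounded` (the narrative starts
  from multipurpose round hammers) and configurable by constructing a model
  directly;
* `knapping_tool_uniform` is the matching zero-precision panel (all-uniform
  $A$, $B$, $D$).

## Numerical and design choices

* Stochasticity tolerance $10^{-9}$ on column sums; invalid inputs are
  rejected at construction with a message naming the offending column.
* Every sampling function takes one explicit integer seed, runs under a
  transient RNG state, and restores the caller's `.Random.seed`:
  `simulateTrajectory()`, `generateRecord()` and `runActiveLoop()` are pure
  functions of their arguments.
* Entropy uses the $0 \log 0 = 0$ convention, so deterministic columns score
  exactly 0.
* Model JSON stores matrices column-wise (each inner array one
  distribution), uses full-precision decimal output, and write–read–write
  is byte-identical.

## Problem sizes

The statistical checks in the suite use records of 2 000 rows (likelihood
recovery to per-column L1 0.05) and 5 000 rows (learned-entropy fidelity to
0.1 nats at both a near-deterministic and a near-uniform environment),
100 random models for the filtering–enumeration equivalence, and 50 random
instances for the salience/mutual-information and degradation-monotonicity
properties. These sizes were chosen so that sampling error sits comfortably
inside each tolerance for a 3-state, 3-observation artefact model.

## Limitations

Estimation is supervised counting of (shape, function) evidence; there is no
Baum–Welch/EM from observation-only sequences, no multi-step policy
evaluation, no pragmatic value, and no continuous state spaces. The package
models one artefact class at a time; comparative questions (many artefact
classes, shared environments) must be composed by the user.
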