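---
title: "Modelling and quantifying stand-alone RNA switches"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and quantifying stand-alone RNA switches}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(switchmap)
```

# The problem

A stand-alone RNA switch is a single RNA molecule that senses a small-molecule
input — here the metabolite FMN binding its 11-nt aptamer — and responds by
re-folding so that an output element (the 19-nt MS2 coat-protein hairpin, or a
light-up aptamer) either forms or unforms. Because nothing is consumed and no
transcription machinery is involved, such switches are reversible and
self-contained, which makes them attractive as fluorescent sensors. The
quantity of merit is the **activation ratio** (AR): the fold change in the
observed reporter dissociation constant, $K_{D,\mathrm{obs}}$, between the off
state (weak reporter binding) and the on state (strong reporter binding).

`switchmap` implements the quantitative machinery around this measurement:
the equilibrium model that bounds the AR, a transparent ligand-aware folding
engine used for design scores, the cluster-level binding-curve quantification
used by massively parallel array assays, sequence-space analysis of design
collections, and seeded generators that produce every input with ground truth
retained.

# The three-state model and the AR ceiling

The ensemble of a switch is coarse-grained into three states with
dimensionless Boltzmann weights: the reporter-competent fold ($w_R$), the
fold with the input aptamer formed ($w_A$), and everything else ($w_O$).
Ligand at concentration $L$ binds the formed aptamer with intrinsic constant
$K_d^{in}$ and multiplies that state's weight by $(1 + L/K_d^{in})$. In the
titration regime the observed reporter affinity is the intrinsic affinity
diluted by the reporter-competent fraction:

$$
f_R(L) = \frac{w_R}{w_R + w_A\,(1 + L/K_d^{in}) + w_O},
\qquad
K_{D,\mathrm{obs}}(L) = \frac{K_d^{rep}}{f_R(L)}.
$$

The AR of a single-aptamer switch can never exceed the free-energy budget of
one binding event at the trigger concentration:

$$
AR \le AR_{\max} = 1 + \frac{L_{trigger}}{K_d^{in}},
$$

with equality approached when $w_O \to 0$ and $w_A \gg w_R$. For the FMN
aptamer the package carries an intrinsic $K_d^{in}$ of 1.53 µM and a trigger
concentration of 200 µM (`fmn_constants()`), giving a ceiling of about 132;
a first-order delta-method propagation of the Kd standard error (0.39 µM) is
available through `ar_max_delta()` and yields a spread of about ±33. These
constants are the values used for every ceiling and limit line the package
draws.

```{r}
k <- fmn_constants()
ar_max(k$trigger_conc, k$kd_input)
ar_max_delta(k$trigger_conc, k$kd_input, k$kd_se)$sd
```

**Polarity.** The formula above describes an OFF-type response: ligand
stabilises the competitor, so binding weakens with ligand. ON switches nest
the formed aptamer inside the reporter-competent fold, so the same bonus
multiplies $w_R$ instead (`bound_state = "reporter"`). Both orientations obey
the same ceiling; `activation_ratio()` orients the Kd ratio so that AR > 1
always means switching in the designed direction.

**Intensity versus Kd fold change.** Literature switches are often quoted as
intensity fold changes at one reporter concentration $P$. Treating reporter
binding explicitly, `intensity_ratio()` shows this equals the AR only in the
limit $P \to 0$ and decays to 1 as $P$ saturates both states; at
$P = K_{D,\mathrm{obs}}^{on}/100$ the two agree within about
$(1 - 1/AR)\,\%$. This is why the package quantifies switches from full
titrations rather than single-concentration intensities.

# The folding engine

Design-time scores need equilibrium base-pair probabilities in the presence
and absence of ligand. External folding engines are deliberately out of
scope; instead the package ships a minimal, fully transparent model whose
exactness can be proven against exhaustive enumeration:

* per-pair energies only (defaults GC = −3, AU = −2, GU = −1 kcal/mol at
  T = 310 K), no stacking or loop terms;
* non-crossing structures, hairpin gap ≥ 3;
* the unfolded chain has weight 1.

`partition_function()` runs an inside/outside dynamic program over this
grammar. The inside recursion is the standard interval decomposition; pair
probabilities are obtained by an outside pass processed outermost-span first,
where the contribution of every enclosing pair is accumulated with a matrix
product per span (exact, and fast enough for the ~60-nt designs the
generators produce). `enumerate_structures()` (capped at 18 nt) is the exact
oracle: the suite checks the dynamic program against Boltzmann averages over
the enumerated list to 1e-9 on hundreds of random sequences.

**Ligand bonus.** A structure counts as ligand-binding when *all* closing
pairs of the input motif are formed (the minimal formed-motif criterion; full
segment pairing is not required). The bonus then follows exactly from the
coupled equilibrium:

$$
Z(L) = Z_{free} + \frac{L}{K_d^{in}}\, Z_{motif},
$$

where $Z_{motif}$ is a constrained run in which the closing-pair positions
may neither stay unpaired nor pair elsewhere. Pair probabilities are the
corresponding mixture of the two runs. With $L = 0$ the free ensemble is
returned bit for bit, and if the closing pairs cannot form at all the bonus
simply never applies.

**The x ratio.** A widely used design score is the ratio of the
predicted pairing probability of the outermost base pair(s) of the split
aptamer without versus with ligand. Because the bonus can only promote the
input motif, that raw ratio is ≤ 1; `x_ratio()` therefore reports a
polarity-oriented `score` (the reciprocal when needed, so "higher is better"
holds) and preserves the raw ratio alongside. For multi-helix split aptamers
the "outermost" pair defaults to the closing pair(s) of widest span, which is
configurable — no published convention exists for that case.

**Element annotation.** `annotate_elements()` reproduces the functional-map
view of a design: motif positions keep their motif label; any other position
pairing a motif position with probability above a threshold in either ligand
state becomes that motif's *complement*; remaining positions are *static*
(paired elsewhere) or *unpaired*. The threshold defaults to 0.5 — a majority
vote of the ensemble — because no published value exists; it is exposed as an
argument.

# Array-style quantification

Each cluster of an array experiment yields one titration of reporter
fluorescence against concentration, fitted to the Langmuir isotherm
$f(c) = f_{min} + (f_{max} - f_{min})\,c/(K_d + c)$. Fit behaviour is fully
deterministic: starts are $f_{min} = \min y$, $f_{max} = \max y$,
$K_d$ = geometric mean of the grid; bounds are
$K_d \in [0.1 \times c_{min}, 10 \times c_{max}]$; a fit at a bound, or with
zero intensity variance, or with an inverted curve is flagged rather than
trusted (Levenberg–Marquardt via \pkg{minpack.lm}).

The headline $K_{D,\mathrm{obs}}$ of a design-condition is the fit of the
**median-aggregated** titration (per-concentration median over clusters) —
robust to aberrant clusters — while per-cluster fits are retained for
uncertainty: the AR interval comes from a seeded bootstrap (1000 draws,
percentile interval) that resamples clusters with replacement and takes the
ratio of the per-cluster Kd medians. Replicate concordance is the squared
Pearson correlation of $\log_{10} K_{D,\mathrm{obs}}$, in log space because
observed Kds span decades.

Box statistics for round-by-round summaries use linear-interpolation
quantiles (R type 7), whiskers at the most extreme observations within
1.5 IQR of the quartiles, and an explicit outlier list.

**Toggling.** For reversibility series (ligand exchanged 0 ↔ trigger each
cycle), the per-cycle response is the intensity minus the mean of its two
opposite-state neighbours. The degradation rate comes from a log-linear fit
of amplitude against cycle index on interior ligand-present cycles
($rate = 1 - e^{slope}$). Classification thresholds: *flat* when the median
amplitude is below 3 noise SDs (noise estimated from lag-2, i.e. same-state,
differences); *inverted* when the observed direction opposes the declared
polarity; *degraded* above 0.5 %/cycle decay; otherwise *consistent*. The
0.5 % threshold separates "minor functional degradation" from a visible decay
over a ~50-cycle assay (0.5 %/cycle compounds to ~22 % signal loss).

# The synthetic-data generators

`generate_library()` draws designs at desk scale with every ground-truth
parameter retained. Defaults (all in `sim_defaults()`):

* 200 designs × 30 clusters per condition × a 10-point half-log reporter
  grid (0.5 nM – 15.8 µM) — small enough to run in tens of seconds, large
  enough for stable medians;
* three-state weights $w_A \sim$ log-uniform(0.2, 5), $w_O \sim$
  log-uniform(0.05, 0.5) with $w_R = 1$; $K_d^{in} \sim$ log-uniform(1, 10) µM,
  $K_d^{rep} \sim$ log-uniform(1, 5) nM; trigger 200 µM. These ranges keep
  true observed Kds inside the titration grid (true ARs roughly 4–120) so
  that recovery is an estimation problem, not an extrapolation problem;
* noise: lognormal cluster saturation ($\sigma_{log} = 0.3$, emulating
  cluster-size variation), 5 % multiplicative shot noise, additive background
  SD 0.03 (units of mean saturation). No published noise model exists; these
  defaults sit between the noiseless and high-noise regimes the tests
  exercise;
* cluster counts, when not fixed, follow a negative binomial truncated to
  [1, 112].

Sequences carry the canonical split FMN aptamer halves and the MS2 hairpin
implanted in a random background with an explicit G–C closing pair, so every
design is locatable by the folding engine. Two emulation gaps are worth
stating: the drawn three-state weights are **not** derived from the implanted
sequence's folding energies (the thermodynamic truth and the sequence are
independent draws), and array image artefacts (registration, bleed-through,
surface chemistry) are not modelled. Passing recovery tests therefore
demonstrate correctness of the quantification given the stated noise model,
not robustness to every failure mode of real chips.

Toggling series decay as $(1-r)^{cycle}$ on the toggled amplitude; reactivity
profiles are gamma-distributed per base (shape 5; mean 1.0 unpaired, 0.15
paired), and `classify_reactivity_states()` reads the schedule back from the
positions whose pairing differs between the two conformations, assuming both
states are visited.

All generators take an explicit integer seed and are bit-reproducible.

# Design-space analysis

Designs within Levenshtein distance < 5 of each other (strict inequality;
unit costs, no affine gaps) are "mods"; families are connected components of
the mod graph, labelled by smallest member id and invariant to input order.
Distance trees are neighbor-joining on the edit-distance matrix (via
\pkg{ape}) — a presentational clustering, not phylogenetic inference: no
substitution model is implied, and duplicate sequences collapse to
zero-length branches.

# End-to-end closure

The suite closes the loop: generate a library, simulate titrations at default
noise, quantify, and compare with truth. At the default scale the median
absolute relative AR error is documented to stay below 15 % with bootstrap
interval coverage of at least 90 %; a 52-cycle toggling series with 1 %/cycle
decay is recovered within 20 %. Problem sizes in the tests and in
`scripts/acceptance.R` (200 designs, 30 clusters, 10 concentrations, 52
cycles, 200 oracle sequences of 8–14 nt, 10^4 ceiling draws) are the
package's chosen desk-scale defaults.

# Known limitations

* The energy model has no stacking, loop, or coaxial terms; pair
  probabilities are qualitatively, not quantitatively, comparable with
  nearest-neighbour engines. The model object is pluggable for that reason.
* No pseudoknots (non-crossing grammar).
* One input aptamer per design: the ceiling and its limit lines do not apply
  to double-aptamer constructs, which can legitimately exceed 1 + L/Kd.
* Equilibrium only — activation kinetics are out of scope.
* The bootstrap interval treats clusters as exchangeable; spatially
  structured chip artefacts would violate that.
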