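---
title: "Models and methods behind epsdigest"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind epsdigest}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epsdigest)
```

`epsdigest` analyses the stepwise enzymatic breakdown of extracellular
polymeric substances (EPS) as seen by untargeted LC–MS over a 24 h in-vitro
digest, together with the carbon-budget and community-response arithmetic
that places that breakdown in its ecological context. This vignette
explains the models, the parameters that matter, the numerical choices, and
what the synthetic data generator does and does not emulate.

## The depolymerization model

Each tracked lineage of breakdown is a **kinetic chain**
(`build_chain()`): an ordered series of species with strictly decreasing
neutral monoisotopic mass, connected by irreversible first-order cleavages,

$$S_1 \xrightarrow{k_1} S_2 \xrightarrow{k_2} \cdots \xrightarrow{k_{n-1}} S_n,
  \qquad k_n = 0 .$$

The terminal stage is absorbing, so the summed amount is conserved — a
deliberate idealisation: the tracked "amount" is a signal proportional to
the mass flowing down one lineage, not a molecule count, and stoichiometric
multiplication on cleavage is folded into that proportionality (one tracked
fragment per stage).

With all rates pairwise distinct (the absorbing $k_n = 0$ included), the
stage amounts follow the closed-form solution of the linear decay chain,

$$A_i(t) = A_0 \Big(\textstyle\prod_{j<i} k_j\Big)
  \sum_{j \le i} \frac{e^{-k_j t}}{\prod_{l \le i,\, l \ne j}(k_l - k_j)} ,$$

whose qualitative behaviour is exactly the three observed temporal classes:
$A_1$ decays monotonically, interior stages rise and fall with the first
intermediate peaking at $t^* = \ln(k_2/k_1)/(k_2 - k_1)$, and the terminal
stage accumulates monotonically.

**Degenerate chains.** The closed form divides by pairwise rate
differences, so chains whose nonzero rates coincide (relative gap below
$10^{-8}$) are flagged and integrated numerically with `deSolve::lsoda`
(relative tolerance $10^{-10}$). The flag rather than a silent limit form
keeps the analytic path simple and the degenerate path honest; the two
paths agree to better than $10^{-4}$ absolute (per unit initial amount) on
random distinct-rate chains, which the test suite checks, and mass is
conserved to $10^{-6}$ relative.

## What the synthetic generator emulates

`digest_scenario()` describes a multi-digest experiment; its defaults are
the package's reference conditions and are used by the test suite and the
acceptance script.

- **Three digests**, one per EPS source, sampled hourly from 0 to 24 h. The
  real experiment was sampled continuously by an autosampler without a
  stated cadence; an hourly grid is a realistic injection cycle for an
  LC method of a few minutes and is configurable.
- **Chain layout per digest**: 10 chains ending in *shared* terminal
  masses (free amino acids, hexosamine, N-acetylhexosamine and their
  dimers — the convergent small products of protein and amino-sugar
  polysaccharide hydrolysis, identical across digests), 2 chains ending in
  digest-specific low-mass terminals, and 1 two-stage chain ending in a
  digest-specific *high-mass* fragment (1,420–1,550 Da), emulating partial
  digestion. Substrates sit at 1,500–1,690 Da, just inside the acquisition
  window; intermediates are digest-specific. This plants the size-resolved
  sharing structure: small terminal products recur across digests, large
  ones do not.
- **Rates** are drawn from 0.4–1.1 h⁻¹ with a minimum pairwise gap of
  0.04 h⁻¹. The lower bound makes substrates and intermediates decay to
  near the detection floor within 24 h (cleanly "decreased"/"bell"); the
  gap keeps chains well away from the degenerate regime.
- **Noise** is multiplicative log-normal per observation with CV 0.2
  (`sdlog = sqrt(log(1 + CV²))`, mean-corrected), the standard shape for
  LC–MS intensity error; m/z and retention time receive small per-digest
  jitter (0.8 ppm, 0.01 min) so cross-digest alignment is non-trivial but
  solvable within the 8 ppm / 0.1 min tolerances.
- **Censoring**: intensities below the detection floor are reported as
  missing, which is what produces the enormous log₂ fold changes of
  terminal products rising from invisible baselines. The floor defaults to
  $10^{-4}\times$ the initial substrate signal. This value is deliberate:
  an accumulation rule of log₂FC ≥ 10 needs the terminal plateau to exceed
  $2^{10} = 1024\times$ the imputed baseline, so a floor at $10^{-3}$ of
  the substrate signal (log₂ ratio ≈ 9.97) would make the rule
  unsatisfiable under mass conservation; $10^{-4}$ leaves ≈ 3.3 log₂ units
  of headroom against noise and the floor-quantile imputation.
- **Adducts**: m/z is the neutral mass minus a proton (negative mode,
  default) or plus a proton (positive mode); ions outside the 50–1,700 m/z
  acquisition window are absent from the table. (The upper end of the
  instrument range is quoted both as 1,700 and as an 1,800 m/z detection
  limit in the source material; both are accepted as window
  configurations, and the default size bins extend to 1,800.)

**What it does not emulate**: chromatographic peak shapes, isotope
envelopes, in-source fragmentation, adducts beyond [M±H], ionization
suppression, enzyme saturation (Michaelis–Menten), or polymer chain-length
distributions beyond the tracked stages. Classifier recovery on this
generator therefore demonstrates correctness of the rules under the assumed
noise model, not robustness to every artefact of real spectra.

## The temporal classifier

`classify_profile()` applies rules in a fixed order; the first match wins:

1. **increased**: $\log_2(I_{24}/I_0) \ge \tau_\uparrow$ with
   $\tau_\uparrow = 10$ — the only numerically fixed selection rule in the
   source workflow, kept inclusive (≥).
2. **bell**: median-smoothed (window 3) interior maximum at least
   `bell_prominence` = 2 times *both* endpoints.
3. **decreased**: $\log_2(I_{24}/I_0) \le -\tau_\downarrow$ with
   $\tau_\downarrow = 1$.
4. otherwise **unclassified**.

The decreased and bell thresholds are not numerically specified by the
source description ("decreased steadily", "bell-shaped"); 2-fold is the
smallest change reliably distinguishable above 20% multiplicative noise,
and both are exposed as `classifier_params()` and reported with results.
Missing and zero intensities are imputed at the 1% quantile of the digest's
nonzero intensities before ratios are formed — reproducing large fold
changes from censored baselines without infinities. The 3-point moving
median removes single-timepoint spikes that would otherwise fake a bell;
`runmed(endrule = "keep")` leaves the endpoints untouched so the smoother
cannot alter the fold-change rules.

Across digests, an ion is assigned its category if the rule fires in at
least one digest; conflicts resolve by the precedence
increased > bell > decreased, because the accumulation rule is the only
externally fixed one and therefore dominates. Raising $\tau_\uparrow$ can
only shrink the increased set (a monotonicity the tests assert).

## Alignment and sharing

`align_ions()` is transitive single linkage over the pair relation
$|\Delta m/z| / \overline{m/z} \le$ 8 ppm and $|\Delta RT| \le$ 0.1 min,
restricted to one ionization mode. A union–find over a sorted sliding
window gives the same partition as the all-pairs oracle (tested to
equivalence on random feature sets) at $O(n \log n)$ typical cost, and
clusters are numbered by their lowest (m/z, RT) member so output is
invariant to row and digest order. `sharing_by_mz()` then counts an
aligned ion as shared when its cluster spans ≥ 2 digests; bins are
half-open $[{\rm low}, {\rm high})$ and "above 1,400 m/z" is the unbounded
bin $[1400, \infty)$.

## Exact-mass annotation

Peptide candidates are enumerated as amino-acid *compositions* (multisets),
since mass is order-independent: 10,625 compositions stand for 168,420
sequences at length ≤ 4, and each entry carries its multinomial sequence
count. Masses are monoisotopic throughout — Q-TOF exact-mass matching —
with residue and sugar masses derived from elemental formulas
(C 12 exactly, H 1.00782503, N 14.00307400, O 15.99491462), water
18.010565 Da and proton 1.007276 Da. Annotation considers only
protonation/deprotonation ([M+H]⁺/[M−H]⁻, differing by exactly two proton
masses); other adducts were not part of the source workflow and are out of
scope. Matches within the ppm tolerance (default 5) are returned sorted by
absolute error and are explicitly putative: isomers, and the isobaric
Leu/Ile and Gly-Gly/Asn pairs, cannot be distinguished. The MS² class
filter keeps rows with intensity explained ≥ 0.5, isotope score ≥ 5 *if
present*, and most-specific class probability ≥ 0.75 (inclusive).

## Budget, composition and fluorescence

`carbon_budget()` treats CO₂ as the exact remainder
$100 - ({\rm biomass} + {\rm EPS} + {\rm LMW})$, so the balance closes by
construction, and derives the EPS share of exudate
$100 \cdot {\rm EPS}/({\rm EPS} + {\rm LMW})$, flagging the degenerate
all-zero case as `NA` rather than guessing. Carbon-percent budgets and
dry-mass yields (`eps_yield()`, mg per g chitin) are kept as separate
quantities: converting between them would need a carbon-content assumption
the measurements do not supply.

Monosaccharide weight fractions are MW-weighted molar concentrations,
$w_i = c_i M_i / \sum_j c_j M_j$; the bundled table holds the 17 quantified
standards with monoisotopic masses, and anhydro (in-chain, minus one
water) masses are selectable for polymer-basis accounting.
`mock_medium()` includes sugars strictly above 1 µM (the stated inclusion
rule) plus protein as bovine serum albumin in mg/L — the concentration
unit used in the formulation protocol; a conflicting mg/mL figure
elsewhere in the source text is treated as a typographical inconsistency.

`coble_peaks()` integrates the two humic-like fluorescence windows — M
(Ex 290–310 / Em 370–410 nm, marine) and C (Ex 320–360 / Em 420–460 nm,
visible) — with inclusive bounds on the 5 nm acquisition grid. The
statistic is the window *mean* rather than the sum, so values are
comparable across windows of different area; the sum is available via
`statistic = "sum"`. The integral is linear in the grid, which the tests
exploit.

## Community comparison

Bray–Curtis dissimilarity is computed directly from its definition
$\sum_i |u_i - v_i| / \sum_i (u_i + v_i)$ and cross-checked against
`vegan::vegdist` in the tests. Fold changes versus the inoculum use
$\log_2(a_c / \max(a_{\rm inoc}, f))$ with floor $f = 1/30{,}000$, the
detection limit implied by one read at the filtered per-sample read depth;
species undetected in a condition are *masked*, not zero-filled, since
absence has no finite fold change. For Ward clustering the masked cells
are imputed at the matrix minimum — preserving the "absent = most
depleted" ordering a fold-change heatmap conveys — and rows are clustered
with `stats::hclust(method = "ward.D2")` on Euclidean distances, the
geometry Ward's variance criterion presumes. The merge sequence equals an
exhaustive greedy minimum-ΔESS oracle on small matrices (tested), heights
are non-decreasing, and ties fall back to `hclust`'s ordering. Top-taxa
summaries break abundance ties lexicographically by species name.

## Problem sizes and determinism

The reference analyses are desk-scale by design: the default scenario has
130 ion species across 3 digests (3,750 table rows) and runs in well under
a second; the noise-recovery analysis uses a scaled-up scenario of ~1,000
ion species; oracle-equivalence checks run at ≤ 100 features (alignment),
1,000 m/z values (annotation) and ≤ 8 rows (Ward). All stochastic steps —
scenario construction, dataset generation, every randomized test — are
driven by explicit integer seeds through `withr::with_seed`, so identical
seeds give byte-identical outputs.

## Known limitations

- One tracked species per chain stage; no branching topologies or
  stoichiometric fan-out.
- The classifier's endpoint rule is sensitive to the imputation floor by
  construction; datasets whose detection floor sits within $2^{10}$ of the
  terminal plateau cannot show "increased" ions under the strict rule, a
  property inherent to the rule rather than to this implementation.
- Annotation is exact-mass only; no isotope-envelope or fragmentation
  evidence is used, and candidates are putative.
- The sharing statistic treats an aligned cluster as one ion; over-merged
  clusters (tolerances too wide) inflate sharing.
- Readers are provided for the supplementary spreadsheet layout, but the
  package ships no measured data; all bundled examples are synthetic.
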