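---
title: "Model and methods: epigenetic aging of simulated intestinal crypts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: epigenetic aging of simulated intestinal crypts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryptdrift)
```

`cryptdrift` couples three models — a promoter-level epigenome, a random
genome with a transcription-factor (TF) network, and an individual cell-based
3D crypt — to ask how repeated, successful DNA damage repair (DDR) can leave
permanent DNA-methylation scars in a fast-renewing tissue. This vignette is
the package's own account of the model, its assumptions, the tunable
parameters, the numerical choices, and what the test suite does and does not
establish.

## 1. The DNA-methylation equation and its bistability

The promoter methylation level $m_{CpG} \in [0,1]$ is treated as
deterministic and is updated only at cell division (both maintenance and de
novo DNMTs are assumed active only post-replication). Per division,

$$\Delta m_{CpG} = D_{novo}(m_4, m_{27})\,(1 - m_{CpG})
                 - \bigl(1 - D_{main}(m_{CpG})\bigr)\, m_{CpG},$$

with a methylation-dependent maintenance probability
$D_{main}(m) = D_{main,0}\,/\,(1 + e^{E_{m,0} + E_{m,1} m})$ and a
histone-state-gated de novo probability
$D_{novo}(m_4, m_{27}) = D_{novo,0}\,(1 + e^{-E_{CpG27} m_{27}})\,/\,
(1 + e^{E_{CpG4} m_4 - E_{CpG27} m_{27}})$.

Sign convention: maintenance activity must not decrease with the methylation
level (cooperative recruitment of DNMT1 to methylated CpG neighbourhoods),
which requires $E_{m,1} \le 0$; the constructor enforces it. Note that
$D_{novo} \equiv D_{novo,0}$ on the whole line $m_4 = 0$ (numerator and
denominator coincide), so unprotected promoters always feel the full de novo
pressure, whether or not they carry H3K27me3.

### Calibrated constants

The source literature fixes the structure of the equations and a few anchor
values ($D_{novo,0} = 0.1$ in homeostasis, $0.3$ during repair,
$D_{main,0} = 0.99$ for the bistable regime) but not the energy constants.
The shipped defaults,

| parameter | default | role |
|---|---|---|
| `d_novo_0` | 0.1 | max de novo probability / division (homeostasis) |
| `d_main_0` | 0.99 | max maintenance probability / division |
| `e_m_0` | 11.2 | DNMT1 accessibility energy |
| `e_m_1` | −40 | DNMT1 methylation-coupling energy |
| `e_cpg4` | 20 | H3K4me3 suppression of de novo DNMTs |
| `e_cpg27` | 10 | H3K27me3 recruitment of de novo DNMTs |

were calibrated (see `scripts/calibrate.R`) so that the fixed-point
structure realizes, at $D_{main,0}=0.99$:

* a bistable $D_{novo}$ window of about $(0.008, 0.26)$ — in particular a
  three-root interval below the homeostatic 0.1 and hysteresis between the
  branches;
* no mono-stable *high* histone state anywhere on the $(m_4, m_{27})$ square
  at $D_{novo,0} = 0.1$, and a non-empty mono-stable-high region at the
  repair value 0.3;
* mono-stable *low* methylation for H3K4me3-dominated promoters
  ($m_4 > 0.5$, $m_{27} < 0.5$).

With these constants the low root at $D_{novo}=0.1$ sits at $m\approx 0.091$,
the unstable root at $\approx 0.31$, the high root at $\approx 0.91$. The
division map then yields the central DDR asymmetry: a single repair division
at $D_{novo,0}=0.3$ lifts an H3K27me3 target from 0.091 to $\approx 0.27$ —
still below the basin boundary, hence transient — while two *consecutive*
repair divisions reach $\approx 0.33$ and escape permanently. At
$D_{novo,0}=0.2$ the map under sustained repair has its own stable low point
($\approx 0.17$), so arbitrarily many consecutive repairs (the "5-fold damage
frequency" scenario) can never cross the boundary. Permanent switches at 0.3
but none at 0.2 are therefore structural, not tuned test outcomes.

## 2. Histone dynamics

Each promoter carries `n_nucleosomes = L_reg/200` nucleosomes (default 20)
with independent boolean H3K4me3/H3K27me3 marks. Per 1 h step and nucleosome:

* gain of H3K4me3 with probability
  $q_{4,\max}\,\theta_4(T)\,c(\nu)\,(1 - w_4 m_{CpG})$, where
  $\theta_4(T) = T^h/(K_4^h + T^h)$ is an activating Hill gate
  ($K_4 = 0.5$, $h = 4$), $c(\nu) = c_0 + (1-c_0)\nu$ is nearest-neighbour
  cooperativity ($\nu$ = fraction of like-marked neighbours, $c_0 = 0.3$),
  and $w_4 = 0.9$ is the methylation weakening of HMT binding;
* gain of H3K27me3 symmetrically with the repressive gate
  $\theta_{27}(T) = K_{27}^h/(K_{27}^h + T^h)$, $K_{27} = 0.25$;
* loss with constant probabilities `cde4`, `cde27` (default 0.05/h).

Transcription is $T = \mathrm{drive} \cdot (1 + \beta_4 m_4)/(1 + \beta_{27}
m_{27})$ with $\beta_4 = 0.5$, $\beta_{27} = 1.5$; the drive comes from the
TF network (below). $T$ deliberately never depends on $m_{CpG}$ —
transcriptional silencing precedes promoter methylation in the model's
causality, not vice versa.

**A deliberate trade-off.** With strong transcription–mark feedback
($\beta_{27} \gtrsim 3$) genes whose TF drive sits near the gate thresholds
become *metastable*: a whole gene can flip its regulatory state in one cell,
and the flipped state can then fix in the stem cell pool by neutral drift —
at any time, weeks or months into a run. Such flips produce slow
lineage-mean methylation trends that contradict the intended behaviour of
damage-free aging (tracks stationary after 2–3 weeks in enterocytes, 6–8
weeks in stem cells). The shipped defaults therefore use a weaker feedback
and higher basal nucleation, which makes borderline genes mix ergodically
within single lifetimes while preserving clearly separated H3K4me3-target
and H3K27me3-target classes. The cost is that persistent bivalent
"switcher" genes are rarer than with strong feedback; the package keeps all
coefficients in `epigenome_params(hmt = ...)` so the strong-feedback regime
remains available.

## 3. Random genome and TF network

Genomes are assembled from `n_genes` random genes of fixed lengths
(regulatory region 4000 bases → 20 nucleosomes, promoter 500, coding 900, all
uniform over a 4-letter alphabet). The TF of gene $i$ recognizes the base
complement of its first 8 coding bases; occurrences (overlapping) of that
word in gene $j$'s regulatory region create the edge $i \to j$ with the
occurrence count as weight. The TF's sign is the G/C parity of the word
(even = activator). The drive on gene $j$ is
$\mathrm{logistic}\bigl(30\,(GC_j - 0.5) + \sum_i s_i w_{ij} T_i\bigr)$: the
promoter GC content supplies a gene-specific basal drive that spreads genes
over the whole activity range and thereby seeds the split into transcribed
(H3K4me3) and repressed (H3K27me3) promoter classes. All of this is
deterministic given the genome, and the genome stream is independent of the
crypt stream, so the genome layer is provably decoupled from lineage dynamics
(tested bit-identical with the payload on and off).

These choices reconstruct an architecture whose original matching rule is
not restated in the available text; any deterministic, seedable rule
preserves the design. They are *not* meant to model real promoters: no
motif statistics, no genome evolution.

## 4. The crypt model

Cells are soft spheres (diameter 1) confined to a test-tube surface
(hemisphere radius 4 + cylinder, orifice at height 10.4), relaxed by
overdamped pairwise linear springs (repulsion inside the rest length,
adhesion out to 1.3 diameters; 10 substeps/h with mobility×step 0.08).
Proliferation pressure alone transports cells to the orifice, where they are
shed. The Wnt field decays exponentially with height
($\lambda = 2.1$); Notch is induced by secretory (PC/GC) neighbours within
0.95 diameters and saturates as $n/(n+0.5)$.

Lineage logic: stem cells are re-evaluated every step against the rule table
(with a 10% hysteresis margin on the Wnt threshold 0.82); an uncovered stem
cell commits to the Paneth fate at 0.8/h; newborn cells outside the niche
without secretory contact become Goblet cells with probability 0.33.
PC and GC are terminal and postmitotic; PCs are anchored (mobility ×0.02)
and replaced after ~22 days; enterocytes keep cycling (18–24 h) below 55% of
the crypt height and may revert to ISC if pushed back into the niche. ISCs
cycle in 24 h ± 20%.

Terminal commitment (rather than hourly re-specification of all cells) is a
deliberate deviation from a literal reading of the rule table: re-evaluating
committed secretory cells every hour drives the secretory fraction above
one half and cannot reproduce the published census. The calibrated defaults
self-organize to ≈ 9.0 ISC / 31.6 PC / 58.3 GC / 217.6 EC (10 crypts ×
90 days), matching the published 9 (±4) / 32 (±3) / 59 (±6) / 222 (±10).
Geometry, thresholds, commitment probabilities, and the Paneth lifetime are
the calibration dials; everything else was held at its first sensible value.

## 5. DNA damage and repair

Each gene of each newly born *proliferative* cell is damaged with probability
`p_damage = 0.02` per cycle (two repairs per 100 genes, cell and cycle).
Repair occupies a fixed 12 h window placed uniformly so it completes within
the cycle; cycles are never extended; there is no permanent damage state, no
apoptosis, no fitness cost. While the window is open, `cde4` is multiplied by
0.1 (H3K4me3 demethylase repression) and $D_{novo,0}$ is raised to 0.3.
Because DNMTs act only at division, the elevated $D_{novo,0}$ is *carried
into the methylation update of the division that ends the damaged cycle* —
without this carry rule repair could never touch $m_{CpG}$. Postmitotic
cells never draw damage (the damage probability is defined per division).

## 6. Numerical and statistical choices

* **Time**: 1 h step; hours internally, days in user-facing interfaces.
* **Fixed points**: sign-change bracketing on a 4001-point grid + bisection
  to machine tolerance; roots accepted at $|\Delta m| < 10^{-9}$; stability
  by central difference with $h = 10^{-6}$. The test oracle is an
  independent $10^{-4}$ sign-change scan.
* **RNG**: four named streams (genome, crypt, histone, damage) as saved
  `.Random.seed` states split from one master seed; C++ kernels draw from an
  internal xoshiro256++ generator seeded from the active stream per call.
  Division batches consume a fixed number of draws per daughter so streams
  stay replayable across configurations.
* **Switch detection**: a crossing is classified against the unstable root
  of the methylation equation at the gene's prevailing histone state
  (fallback 0.5 when mono-stable) and must persist — in the cell or its
  descendants — for ≥ 5 stem-cell cycles; each switch is attributed to the
  most recent repair event on the lineage line within a 5-cycle lookback.
  The persistence requirement separates transient repair excursions from
  permanent switches; 5 cycles is an analysis choice, exposed as `k_cycles`.
* **Stationarity testing**: Mann–Kendall (Kendall rank correlation against
  time) on lineage-mean tracks thinned to weekly points, family-wise
  $\alpha = 0.01$ with Bonferroni correction across genes. Thinning keeps
  the samples effectively independent (enterocytes turn over in 2–3 days).
* **Degenerate inputs**: coincident cells are nudged apart
  deterministically; empty lineages yield `NA` tracks; zero observed
  switches flag the fixation estimate as undefined rather than returning 0.

## 7. What the synthetic world does and does not establish

The random genome emulates *regulatory diversity* (a spread of basal drives
and a sparse signed TF network), not real sequence biology. The crypt
reproduces census, neutral drift, monoclonal conversion, and the
conveyor-belt flux, but has no villus, no explicit stroma, no molecular
Wnt/Notch pathways, and its mechanics constants are calibration artifacts.
A green test therefore establishes: the methylation equation's bistability
and hysteresis; the self-organized census; equilibration and absence of
damage-free switches; repair-driven, H3K27me3-biased permanent switches with
the published 0.3-vs-0.2 asymmetry; and the $1/N_{ISC}$ neutral fixation
law. It does *not* establish quantitative agreement with any experimental
methylome or ChIP dataset, per-CpG stochastic methylation (deliberately out
of scope — the promoter-level difference equation assumes CpG-rich
promoters), hemimethylation, or active demethylation.

## 8. Known limitations

* Lineage-mean tracks of strongly bimodal "switcher" genes equilibrate on
  the monoclonal-conversion timescale; with the shipped (weak-feedback)
  kinetics this mode is suppressed, with strong feedback it reappears.
* The Paneth/stem ratio is controlled jointly by the Notch contact radius,
  the commitment rate and the Paneth lifetime; the printed census pins this
  combination only loosely, and other combinations reproduce it equally
  well.
* Newick export writes one tree per founder; trees from long runs are large
  and intended for programmatic consumption (e.g. `ape::read.tree`), not
  visual inspection.
* With ~320 cells and 30–100 genes a 300-day run takes minutes; the design
  favours exact reproducibility over parallel speed (single-threaded by
  construction).
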