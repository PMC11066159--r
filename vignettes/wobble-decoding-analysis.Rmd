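---
title: "Quantifying wobble decoding and inosine editing of A34-anticodon tRNAs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying wobble decoding and inosine editing of A34-anticodon tRNAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wobbleA34)
```

## The measurement problem

Nearly every tRNA gene encoded with adenosine at anticodon position 34 (the
wobble position, which pairs the third codon base in antiparallel
orientation) is post-transcriptionally deaminated to inosine. Unmodified A34
tRNAs are therefore almost absent from nature, and their decoding behaviour
is poorly characterized. Orthogonal translation machinery offers a way in:
an introduced tRNA/aminoacyl-tRNA synthetase pair that does not cross-react
with the host's machinery can be given any anticodon, and its decoding of
each codon in a box can be measured *in vivo* as the efficiency with which
it reassigns that codon to its own amino acid.

`wobbleA34` implements the quantitative layer of such an experiment for a
fluorescence-based reassignment screen in *E. coli* paired with Sanger
sequencing of reverse-transcribed tRNAs:

1. **Screen quantification** (`normalize_measurement()`,
   `aggregate_replicates()`, `apply_lod()`): raw mean per-cell fluorescence
   is bracketed between a 0% and a 100% reference construct, mapped
   affinely to a reassignment efficiency (RE, percent), aggregated over
   biological replicates, and censored at the assay's limit of detection.
2. **Discrimination statistics** (`discrimination_ratio()`,
   `discrimination_floor()`, `min_detectable_inosine_fraction()`): the
   U3:C3 discrimination ratio and the detectability model linking the two.
3. **Trace quantification** (`read_abif()`, `locate_anticodon()`,
   `integrate_peak()`, `estimate_inosine_fraction()`,
   `call_modification()`): A-to-I editing at position 34 estimated from the
   T:C signal of the sequenced cDNA strand.
4. **Wobble concordance** (`predicted_codon_set()`,
   `wobble_concordance()`): observed decoded sets scored against classical
   and expanded wobble rule sets.
5. **Synthetic data** (`simulate_trace()`, `simulate_screen()`,
   `paper_fixture()`): generators that emulate the study's data so the full
   pipeline runs, and is tested, without any external files.

## The reassignment efficiency and its censoring

A measured fluorescence $x$ with references $r_0$ and $r_{100}$ gives

$$RE = 100\,\frac{x - r_0}{r_{100} - r_0}\ (\%),$$

reported as mean ± sample standard deviation (denominator $n-1$; biological
replicates) over typically 12 replicates. Values are deliberately not
clipped to $[0, 100]$: negative normalized values are informative about
noise and remain visible in audit output.

The limit of detection (LOD), set by residual cell and media fluorescence,
is **0.2%**. Censoring is strict: a mean *below* 0.2% is flagged
`below_lod`; exactly 0.2% counts as detected. The boundary choice is
arbitrary in principle, but the reported data never sit on it (the smallest
detected value in the packaged table is 0.27%). Censored cells keep an `NA`
mean rather than zero, because the ratio statistics must substitute the
LOD, not zero, for a censored term.

## The U3:C3 discrimination ratio

For one tRNA decoding the U- and C-ending codons of its box at efficiencies
$RE_U$ and $RE_C$, the discrimination ratio is

$$\frac{RE_U}{RE_U + RE_C},$$

expressed as integer shares of 100 ("91:9" means 91 of 100 orthogonal
incorporation events select the U-ending codon). Because both efficiencies
belong to the same tRNA species, aminoacylation efficiency and competition
with the endogenous tRNA pool cancel: the statistic is invariant under any
common rescaling of both inputs, which makes tRNAs of very different
absolute activity comparable.

When $RE_C$ is censored, the package reports the **floor**
$RE_U / (RE_U + LOD)$, flagged `is_floor` and printed with a `≥` prefix:
substituting the largest value the censored term could have had makes the
result a lower bound on the true U share.

Rounding is half-up on the U share, with the C share defined as the
complement — this convention reproduces every published ratio we checked
(55:45, 68:32, 56:44, 59:41, 52:48, 91:9, 76:24, ≥95:5). One published
value (76:24 for the leucine-box tRNA) differs by two share points from the
ratio of its published table means (74:26), presumably because it was
computed from unrounded means; the regression tests compare that single
ratio with a two-point tolerance rather than absorbing the discrepancy.
The half-up rounding adds a guard of $10^{-9}$ before the floor so that
shares landing exactly on a half in exact arithmetic (e.g. $6.6/17.6$)
are not misrounded by binary representation error.

```{r ratios}
ratios <- ratio_table(fixture_re_table())
ratios[ratios$anticodon %in% c("ACG", "AUG", "ACA"),
       c("anticodon", "re_u", "re_c", "ratio")]
```

## The detectability model

Inosine at position 34 pairs strongly with C3, unmodified adenosine only
weakly, so a tRNA population with modified fraction $f_I$ decodes the
C-ending codon at approximately $RE_C = f_I \, RE_U$ (linear mixing).
Modification is detectable as anomalous C-ending decoding once $RE_C$
clears $k \times LOD$:

$$f_{\min} = \min\!\left(1, \frac{k \cdot LOD}{RE_U}\right).$$

The detection multiple defaults to $k = 2$ (an anomaly should clear the
detection limit with some margin, not merely touch it); it is the unique
constant consistent with both published anchors of the model — 2%
detectable modification at $RE_U = 20\%$ and 40% at $RE_U = 1\%$ — and it
is overridable wherever it appears.

## Trace quantification

The sequenced strand is the reverse complement of the tRNA, so the three
called bases covering the anticodon read as the DNA form of the targeted
codon, and tRNA position 34 — the 5′-most anticodon base — is the **third**
base of that triplet in sequencing order (a tRNA with anticodon AAA yields
the sequenced triplet TTT). Reverse transcriptase reads inosine as
guanosine and incorporates C; unmodified A templates only T. The modified
fraction is therefore estimated as

$$\hat f = \frac{A_C}{A_C + A_T}$$

from baseline-subtracted peak areas at that position.

Numerical choices, all configurable:

* **Localization** is reference-driven: the anticodon triplet is found by
  exact match of 12 flanking bases on each side (the triplet itself is a
  wildcard, since a mixed position may be miscalled), falling back to a
  minimal-edit-distance placement capped at 3 edits; absent or ambiguous
  context is an error, never a guess.
* **Integration window**: half the local inter-peak spacing on each side of
  the called peak, trapezoidal rule at unit sample spacing.
* **Baseline**: per channel, the median of the signal over samples at least
  one typical peak spacing away from that base's own called peaks. The
  median of baseline-dominated samples tracks the true baseline level both
  with and without noise; a low percentile (a tempting alternative) sits
  about 1.6 noise-sd below the true baseline under noise, which inflates
  every area and biases small fractions upward by 2–3 percentage points.
  Excluding each base's own peaks keeps the estimate exact on noise-free
  traces. Negative baseline-subtracted samples are clamped to zero.
* **Area, not height**, is the primary estimator; peak height can be read
  off the same object if wanted.
* **Calling** requires two gates: an absolute 5% visibility threshold (the
  level clearly evident above chromatogram baselines) *and* a 3-sigma gate
  against the trace's own noise floor, measured by running the estimator at
  every other called T position of the same trace. The second gate prevents
  a noisy baseline from being called modified.

A known limitation: when the base adjacent to the quantified position is
itself a T or C (as in the leucine-box triplet CTT), the neighbouring
peak's Gaussian tail leaks a small amount (under one percentage point at
default morphology) into the integration window. The synthetic reference
flanks are designed so this never happens on the flank side, mirroring how
a quantification amplicon would be designed; the residual within-triplet
case is inherent to window integration and is covered by the stochastic
tolerances rather than hidden.

```{r trace}
ref <- reference_cdna("AAG")
spec <- trace_spec(toupper(ref),
                   mixed_positions = list("15" = c(T = 0.85, C = 0.15)),
                   seed = 1)
chrom <- simulate_trace(spec)
locus <- locate_anticodon(chrom, ref)
estimate_inosine_fraction(integrate_peak(chrom, locus$trace_index))
```

## Wobble rule sets and concordance

Four rule sets map a position-34 base to the codon third bases it can read
(ordinal preference only — no published pairing strengths exist to
calibrate weights, so the engine deliberately stays order-based):
`crick_original` (A34 reads U3 only; I34 reads U, C, A), `expanded_a34`
(A34 preference U > C > G > A), `inosine`, and `two_out_of_three` (all four
box members when both prefix pairs are G:C, classical rules otherwise).
Custom rule sets load from YAML via `load_wobble_rules()`.

`wobble_concordance()` classifies each anticodon from its measured decoded
set (codons above the LOD) with precedence
`inosine_like > two_out_of_three > wobble_consistent > anomalous`:
modification evidence overrides pairing-only explanations, since a
partially edited tRNA population decoding U- and C-ending codons tells us
about inosine, not about A34 pairing.

## What the synthetic generators do and do not emulate

`simulate_trace()` builds four-channel electropherograms from Gaussian
peaks (spacing 12 samples, sigma 2.5, amplitude 1000, baseline 20, noise
sd 10 by default — typical analyzed capillary-trace morphology), splitting
amplitude at mixed positions, with majority-base calls and exact peak
centers. It does **not** simulate dye blobs, mobility shifts, peak-width
drift along the read, or base-caller errors beyond what mixing produces;
passing tests demonstrate correctness of the quantification arithmetic on
idealized traces, not robustness to instrument pathology. Real traces
should be inspected when calls sit near the gates.

`simulate_screen()` draws replicate fluorescence values around a true
efficiency placed between the reference anchors, with per-replicate sd
expressed in percent of the reference range. Defaults — references at 150
and 25150 arbitrary units, 12 replicates, 0.5% sd — were chosen once to
respect the published standard deviations (roughly 0.1–1.1%); plate-position
effects, growth differences and gating are out of scope.

`paper_fixture()` ships the published per-anticodon efficiency table (15
anticodons; the arginine-box row is stored under anticodon ACG, which the
text identifies as the tRNA targeting CGU) with censoring flags, the three
known modification fractions (1.0 for ACG, 0.5 for AUG — "nearly 1:1" — and
0.15 for AAG), and published ratio texts where one exists.

## Problem sizes and determinism

All simulations in the tests and the acceptance script run at the study's
own scale: 15 traces of 27 bases (336 samples per channel) and screens of
12 replicates, which complete in seconds. Every stochastic generator takes
an explicit seed and is bitwise reproducible; `run_all()` writes
byte-identical reports for identical configuration and seed.
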