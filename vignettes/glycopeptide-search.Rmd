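---
title: "Open glycan search and three-level FDR control for intact glycopeptides"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Open glycan search and three-level FDR control for intact glycopeptides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycosearch)
```

## The problem

An intact N-glycopeptide couples two unknowns in one precursor: the
peptide backbone and the glycan attached to its sequon (N-X-S/T, X ≠ P).
Stepped-collision-energy HCD spectra contain evidence for both at once —
Y ions (glycan fragments that retain the whole peptide), b/y backbone
fragments, and low-mass oxonium ions diagnostic of glycosylation.
`glycosearch` identifies glycopeptide–spectrum matches (GPSMs) from such
spectra and, critically, controls the false discovery rate at three
levels: the glycan, the peptide, and the glycopeptide pair. Engines that
control only the peptide level can report confidently wrong glycans;
the three-level model treats a GPSM as false whenever *either* part is
wrong.

## The search procedure

**Coarse glycan open search.** For a spectrum with precursor neutral
mass $M$ and each glycan $g$ in the database, the implied backbone mass
is $M - \mathrm{mass}(g)$. Every Y-ion delta of $g$ (one per distinct
mass of a root-containing subtree, plus Y0) is matched at charges
$1..z-1$ within the fragment tolerance (±20 ppm default), and $g$ is
scored by the number of distinct matched deltas. Glycans with fewer
than 2 matched trimannosyl-core ions (the ladder pep, +HexNAc,
+2HexNAc, +2HexNAc+1..3Hex) are discarded; the top 100 candidates are
kept. This filter is the engine's main specificity device: a candidate
whose implied backbone is wrong must hit two core positions by chance
at 20 ppm.

**Peptide lookup and fine scoring.** Candidate peptides are binary-
searched in a mass-sorted index of digested sequon peptides (targets
and decoys, variable modifications expanded) within ±5 ppm of the
backbone mass. Each (glycan, peptide) pair is then scored:

$$\mathrm{Score}_G = \Big[\sum_i \log(\mathrm{inten}_i)\,
  \big(1 - |\mathrm{merr}_i/\mathrm{tol}_i|^4\big)\Big]\,
  \mathrm{ratio}_\mathrm{ion}^{\,\alpha}\,
  \mathrm{ratio}_\mathrm{core}^{\,\beta}$$

over matched Y-ion peaks, with $\mathrm{ratio}_\mathrm{ion}$ the
fraction of theoretical Y deltas matched and
$\mathrm{ratio}_\mathrm{core}$ the same for core ions. The peptide
score has the same form over b/y peaks with a single exponent
$\gamma$, and the combined score is the convex combination
$\mathrm{Score}_{GP} = w\,\mathrm{Score}_G + (1-w)\,\mathrm{Score}_P$.
The shipped constants are $\alpha = 0.56$, $\beta = 0.42$,
$\gamma = 0.94$, $w = 0.35$.

Numerical choices the formulas leave open:

* **Intensity normalization.** Peak intensities are scaled so the base
  peak equals $e^2$; a base-peak match contributes 2 and scores are
  invariant to overall spectrum scale. Contributions are floored at
  zero so that adding a matched peak can never lower a score.
* **Tolerance ratio.** $\mathrm{merr}_i/\mathrm{tol}_i$ is evaluated in
  ppm at each matched peak, which equals the Da ratio at that m/z.
* **Peak assignment.** Each observed peak may satisfy at most one
  theoretical ion per series; the nearest-mass interpretation wins.
* **Matching charges.** Y ions at charges $1..z-1$; b/y at 1–2. MS2
  input is assumed deisotoped/charge-deconvoluted upstream.
* **Peptide evidence.** A peptide candidate with no matched backbone
  fragment is not reported: a peptide search engine only returns
  fragment-supported candidates, and a GPSM whose peptide part is pure
  mass coincidence carries no identification evidence.
* **Ties.** Exact score ties are broken by a deterministic string hash
  rather than lexicographically. Decoy sequences are reversals, so
  their leading characters are not exchangeable with targets, and a
  lexicographic tie-break measurably biased target–decoy competition.
  A spectrum whose best target and best decoy explanations tie on all
  three scores is *undecidable* and yields no GPSM at all; resolving
  such ties by any coin degrades FDR calibration because q-value
  selection preferentially harvests the lucky side of the coin.
* **Oxonium ions** (HexNAc 204.087, HexHexNAc 366.140, …) are annotated
  in reports but never scored.

## Decoys and the three-level FDR model

A GPSM is false when its glycan or its peptide is wrong, so with
$G$/$P$ denoting those events,

$$\widehat{\mathrm{FDR}}(x) = \widehat{\mathrm{FDR}}_G(x) +
  \widehat{\mathrm{FDR}}_P(x) - \widehat{\mathrm{FDR}}_{G\cap P}(x),$$

estimated at score cutoff $x$ (counts use $\ge x$) by decoy ratios:
glycan-decoy-with-target-peptide counts over target–target counts for
$\widehat{\mathrm{FDR}}_G$, the mirror ratio for
$\widehat{\mathrm{FDR}}_P$, and both-decoy counts for the joint term.
q-values are the running minimum of this curve over descending score;
the reported set is the targets with $q \le 0.01$.

**Glycan decoys** preserve the target's composition (hence precursor
mass) and its Y0, and shift every other Y delta by a uniform offset in
±30 Da, rejecting offsets within 1 Da of any target delta. Core flags
travel with their deltas so decoys face the same coarse filter.
The offset distribution is a replaceable strategy; an optional
two-component mixture refinement of the glycan FDR (decoys anchoring
the incorrect component) is available but the plain decoy ratio is the
default, as is a documented +1 pseudo-count option (off by default).

**Peptide decoys** are pseudo-reversed at the *peptide* level: the
interior of each digested J-marked peptide is reversed, the C-terminal
K/R anchor stays, and the J travels with its residue. We first
implemented protein-level reversal, but reversal destroys N-X-S/T
sequons, so most target glycopeptides had no mass-matched decoy
competitor and the peptide-level FDR under-counted badly (realized
false proportions an order of magnitude above the estimate on the
benchmark). Peptide-level reversal guarantees one mass-matched,
tryptic, J-carrying decoy per target peptidoform. Palindromic peptides
whose decoy equals the target are kept and flagged by their `DECOY_`
protein id.

## Search-engine-independent validation

Two estimators audit the reported FDR without using the search scores:

* **Isotope pairing.** In an equimolar unlabeled/^15^N/^13^C mixture,
  the elemental composition of a *correct* identification predicts its
  labeled partners at shifts of $n_N \times 0.9970349$ and
  $n_C \times 1.0033548$ Da. For each GPSM the three channels are
  sought in MS1 within ±5 ppm over a ±60 s retention window (apex =
  maximum summed intensity); a missing partner or a ratio outside
  [1/2, 2] yields NaN. The FDR estimate is the target NaN fraction
  divided by the decoy NaN fraction (decoys, being false, measure the
  NaN test's sensitivity), computed per run and averaged.
* **Entrapment.** With a foreign-species database mixed in, any
  accepted GPSM whose peptide or glycan carries only entrapment tags is
  a certain false positive; the estimate is the fraction of such GPSMs
  (entries shared between partitions never count).

Neither validator sees composition-preserving errors: a shuffled
peptide of identical residue content has identical labeled masses, and
a same-composition topology error is invisible to both. This is a
property of the methods themselves, not of this implementation, and the
benchmark (below) deliberately includes that blind error class.

## The synthetic benchmark

`synth_benchmark()` emulates the labeled-yeast validation design: 1000
MS/MS spectra per seed, half true and half deliberately false, with MS1
scans carrying each analyte's isotope triplet at ~1:1:1 (log-normal
channel noise, CV 5%), a native protein/glycan partition and an
entrapment partition (60 + 30 proteins of 150–350 residues; 25 + 15 + 5
shared glycans grown from the trimannosyl core). Spectra contain Y
ions, b/y ions and oxonium peaks with detection probabilities 0.8 /
0.6 / 0.9, log-normal intensities, 3 ppm fragment and 0.5 ppm precursor
jitter, and ~80 uniform noise peaks drawn from the lower intensity
quartile — all configurable, chosen once as plausible for SCE-HCD data.

False spectra come in four constructions:

* `wrong_peptide` (50%): a random-composition foreign peptide whose
  mass falls within tolerance of an indexed peptidoform — the error
  class both validators can see;
* `shuffled_peptide` (20%): a composition-preserving shuffle of a
  database peptide (C-terminal anchor kept) — mass-identical to its
  source, invisible to the validators, visible to peptide decoys;
* `shifted_precursor` (20%): a real glycopeptide with a wrongly picked
  precursor (its MS1 triplet sits at the true mass);
* `noise` (10%): noise-only spectra at plausible precursor masses.

A same-composition "wrong glycan" mode is deliberately absent: at the
engine's composition-level reporting granularity such a spectrum is a
*correct* identification, and no two distinct small compositions over
{Hex, HexNAc, Fuc, NeuAc, NeuGc} fall within 5 ppm of each other, so a
composition-level mass-compatible wrong glycan does not exist. For the
same reason, correctness against the truth manifest is scored on the
glycan composition and the J-normalized backbone sequence: sequon
placement and glycan topology carry no mass information, and site
localization is out of scope.

What passing calibration tests shows — and does not show — about real
data: the generator produces idealized centroided peaks with Gaussian
ppm errors, independent fragment detection, no chromatographic peak
shapes, no isotope envelopes beyond channel monoisotopes, and an error
population matched to what target-decoy competition models. Real
spectra add correlated fragmentation, co-isolation and calibration
drift; the tests certify the *logic* of the pipeline, not instrument
robustness.

## Calibration of the score constants

Taking logs of $\mathrm{Score}_G$ gives a form linear in
$(\alpha, \beta)$, so ranking correct above incorrect candidates within
each spectrum is a pairwise learning-to-rank problem. A linear SVM on
within-spectrum feature differences (e1071, cost 1, no scaling) fits
the direction; dividing by the sum-term coefficient identifies the
exponents. Pairwise differencing cancels per-spectrum intensity scale,
so the fit is invariant to uniform intensity rescaling. The combined
weight $w$ is not identified by that linearization and is grid-searched
to maximize accepted identifications at fixed FDR on a benchmark set.
The shipped constants are frozen; calibration is optional tooling.

## Problem sizes and runtimes

The test suite's calibration experiment runs 20 seeds × 1000 spectra
against 90 glycan entries (targets + decoys) and a ~5000-row
peptidoform index — about 15 s per seed on one core. The engine-oracle
equivalence checks use ≤ 20 glycans × ≤ 100-protein-derived indices,
where exhaustive pair scoring stays cheap; Y-ion enumeration is checked
against bitmask subtree enumeration for trees of up to 8 residues.
These sizes were chosen so every property is exercised end to end while
a full check remains a coffee-break affair.

## Known limitations

* Glycan topology is reported as given by the database; distinct
  structures with one composition tie exactly and are not distinguished.
* Site localization among multiple sequons of one backbone is not
  attempted (mass-equivalent; reported J placement follows the
  database entry).
* The decoy-ratio FDR assumes exchangeable target/decoy false matches;
  pseudo-reversed decoys approximate but do not perfectly achieve this
  (residues flanking cleavage sites are not exchangeable under
  reversal), which is the usual limitation of reversed decoys.
* ETD/EThcD c/z ions, semi-tryptic digestion, O-glycosite scoring and
  retention-time modeling are out of scope; O-glycan databases can be
  searched as alternative glycan databases.
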