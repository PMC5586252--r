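---
title: "Scoring PP2A-B56 docking motifs: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring PP2A-B56 docking motifs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(b56motif)
```

## The scoring model

B56-family regulatory subunits of PP2A recognise a short linear motif in
disordered regions of substrates and inhibitors. `b56motif` represents
this element as a 9-position frame, `[LMFI]-x-x-[ILV]-x-E-x-x-x`:

* **Anchors.** Position 1 (best L, similar M/F/I) and position 4 (best
  I, similar L/V) insert into the hydrophobic docking pocket; position 6
  is strictly glutamate. Aspartate, or a phosphorylated serine or
  threonine, does not substitute at position 6, so
  `find_motif_windows()` rejects `pS`/`pT` there by construction.
* **Flanks.** Positions 2, 7, 8 and 9 face a basic rim of the pocket
  that favours negative charge. The N-score counts, over these four
  positions only, `N = numDE + numST − numKR`. Each residue feeds
  exactly one counter; S/T are counted because phosphorylation converts
  them into (doubly) negative residues.
* **Anchor-dependent threshold.** Affinity lost at the anchors must be
  repaid at the flanks: the minimum N is 1 with both best anchors, 2
  with one similar substitution, 4 with two.
* **Classification.** A window whose acidic flanks alone reach the
  minimum (`numDE − numKR ≥ min N`) is *intrinsic*; one that reaches it
  only with S/T counted is *phosphorylation-responsive*, with the
  contributing S/T positions reported; anything else fails.

Two scanning modes exist because the two halves of a typical analysis
need them: `consensus-only` reports every pattern match regardless of N
(useful when reproducing curated example tables), `n-rule` applies the
threshold (the proteome-scale search).

### The flank-counting convention

Published example tables in this literature are not internally
consistent about whether the invariant E at position 6 is included in
the "D/E count" of a window; under a position-6-inclusive convention
half of the curated rows change by one. This package counts **flanks
only** ({2, 7, 8, 9}), the convention under which the scoring rule and
the anchor thresholds are stated. The bundled
`b56_intrinsic_examples()` table records an expected count only for
rows consistent with that convention (`NA` otherwise), and
position-9 S/T is always reported even where curated annotations omit
it (e.g. a window whose ninth residue is serine).

### Plk1 sites and disorder

`predict_plk1_sites()` implements the single positional rule that
defines the Plk1 consensus — S/T with D, E or N two residues upstream —
with no surrounding-sequence weighting; the first two residues of a
sequence have no −2 context and are never called. Kinase prediction
beyond Plk1 is out of scope; user-supplied phosphosite tables are joined
onto candidate rows instead.

Disorder annotation uses a windowed charge–hydropathy score of the
FoldIndex form (Kyte–Doolittle hydropathy rescaled to [0, 1], window
21 residues, truncated at the termini, sign flipped so larger = more
disordered). It is a deliberately simple, dependency-free heuristic: it
captures the charged/low-hydropathy signature of disordered acidic
regions but, unlike pairwise-energy predictors, it has no notion of
residue context, and uniform-random sequence sits near its zero. For
that reason `scan_proteome()` **annotates** disorder by default but does
not filter on it (`min_disorder = NULL`); a hard cutoff, or an external
per-residue score table from a dedicated predictor, can be supplied.

## ProP-PD count processing

Sequencing counts from phage selections are processed per bait:

* **Cutoff.** "Count cutoff 1" is interpreted as *strictly greater
  than 1*: every observed peptide has at least one read, so a
  `≥ 1` rule would retain everything. The comparison mode is a flag
  (`mode = "gt"`/`"ge"`).
* **Promiscuity.** Peptides passing the cutoff in more than
  `max_bait_fraction` (default 0.5) of the supplied baits are removed
  everywhere. Historic cross-dataset occurrence lists are not available,
  so promiscuity is judged within the supplied baits.
* **Rescue.** Below-cutoff peptides containing at least one consensus
  window are added back with provenance `rescued`; the reported ligand
  set is the disjoint union of above-cutoff and rescued peptides.

The two filters commute, which the test suite checks on random tables.

## Motif discovery

`enumerate_candidate_motifs()` is a compact overrepresentation search in
the SLiMFinder tradition: templates have at most 3 defined positions
(single residues or the hydrophobic class `[LMFIV]`) spanning at most 9
residues — enough to express a 3-anchor consensus — and support is the
number of peptides containing at least one occurrence. The p-value is a
binomial upper tail with per-peptide occurrence probability
`1 − (1 − p_match)^windows` under the background frequencies, treating
positions as independent (an approximation that ignores overlapping
windows; it is slightly conservative for the sparse templates used
here). Correction is Bonferroni over the full enumerated space
(262,857 templates at the defaults), optionally Benjamini–Hochberg.
With mixed peptide lengths the per-peptide occurrence probabilities are
averaged before the binomial tail — exact for the fixed-length libraries
the generator produces.

`build_consensus()` aligns peptides on the first occurrence of a seed
template, builds a 9-position frequency matrix, and admits residues
whose frequency exceeds `inclusion_threshold` (default 2) times
background; positions with no enriched residue become wildcards, the
anchors are restricted to their consensus alphabets and position 6 is
forced to E.

## The synthetic-data generator

The generator is the package's stand-in for the experimental inputs and
defines the conditions under which the pipeline is tested:

* **Proteome.** i.i.d. residues, uniform by default (overridable with an
  empirical 20-vector), 100–300 residues per protein. Real disordered
  regions are compositionally biased and have correlated structure; the
  generator makes no attempt at either, so passing tests demonstrate
  correctness of the machinery, not performance on real proteomes.
* **Planted truth.** Non-overlapping 9-mers conforming to the consensus:
  intrinsic plants realise their target N with D/E, phospho-responsive
  plants with S/T only (keeping the intrinsic score at 0), decoys
  violate exactly one constraint — D at position 6 — so a rejection is
  attributable to the strict-E rule. Remaining window positions draw
  from non-scoring residues so the planted N is exact.
* **Library.** 16-mer tiles stepping by 9 (7-residue overlap), plus a
  final C-terminus-anchored tile. Note an inherent property of this
  design: a 9-residue window can straddle a tile boundary and then lies
  complete in no tile, which is why tile-level recall of planted motifs
  is below 1 even with perfect processing.
* **Counts.** Negative binomial (mean `base_mean`, variance
  `mu + mu²/dispersion`) — the standard overdispersed model for
  sequencing counts; the underlying report gives no distributional
  detail, and no calibrated real-data noise model is available.
  Background mean defaults to 0.2 (most tiles unobserved, as in real
  selections); tiles containing a planted window are enriched 20-fold
  in one bait assigned to that window; a 5% promiscuous fraction is
  enriched in every bait. Phage amplification cycles and PCR/barcode
  errors are not modelled.
* **Binding traces.** Forward 1:1 Langmuir kinetics with Gaussian sensor
  noise; 400 s association, 300 s dissociation, matching a typical
  sensor program.

## Fitting: numerical choices

* **BLI.** Global least squares over all traces (shared kon, koff,
  Rmax) via Levenberg–Marquardt on log-parameters — positivity without
  constrained optimisation — multi-started from a 3×3 grid
  (kon ∈ {1e3, 1e5, 1e7} M⁻¹s⁻¹, koff ∈ {1e−4, 3e−3, 1e−1} s⁻¹).
  KD = koff/kon is derived, never free. A zero-concentration trace is
  treated as the reference blank and subtracted point-wise. Per-trace
  Rmax, mass-transport limitation and baseline drift are not modelled
  (the plain instrument-style 1:1 model). Whether a global or per-trace
  fit was used historically is unstated; global is the stricter
  contract and is what this package implements.
* **ITC.** Dilution-corrected single-site Wiseman isotherm
  (`Mt = M0(1 − v/2V0)`, `Xt = X0(v/V0)(1 − v/2V0)`, trapezoidal
  displaced-volume term on the injection heats), fitted for
  (Ka, ΔH, n) with multi-start over Ka. A Wiseman c-value outside
  [1, 1000] triggers a reliability warning, not an error; all-zero heats
  short-circuit to a flagged degenerate ΔH → 0 fit. For a ~7 µM binder
  titrated into a 20–50 µM cell the c-value is only ~4–7, and the Kd
  estimate is accordingly noise-sensitive: under 5% heat noise its
  relative error varies from under 1% to several tens of percent across
  noise realisations. BLI-derived affinities tend to run tighter than
  ITC for this interaction class; that discrepancy is a property of the
  measurements, not something the models reconcile.
* **Competition.** The two-ligand single-site equilibrium is solved by
  bracketed root-finding on the free-receptor concentration (the mass
  balance is monotone on [0, P_total]), followed by Newton polishing to
  drive mass-balance residuals to ~1e−9 relative. The test suite checks
  it against the exact closed-form cubic solution.

## Problem sizes in the test suite

The suite validates the scanner against an independent
regex-lookahead oracle on 10⁴ random 30-mers, plants 70 windows in a
500-protein proteome for recall/leakage, runs 100 seeded
discovery replicates at 50% planted support, and exercises every fit on
noiseless and noisy seeded traces. These sizes keep the default test run
to a few minutes while leaving each statistical check well-powered.

## Known limitations

* The disorder heuristic is not a substitute for a modern predictor;
  treat its absolute threshold as arbitrary and prefer external scores
  for proteome-scale filtering.
* Discovery's background model is i.i.d.; compositional bias in real
  disordered regions will inflate significance of composition-driven
  templates.
* The binding models assume 1:1 stoichiometry throughout; heterogeneous
  or 2:1 binding, and instrument file formats, are out of scope.
* Promiscuity filtering within two or three baits is a weak proxy for
  filtering against large historical phage-display occurrence lists.
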