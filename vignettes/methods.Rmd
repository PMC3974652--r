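---
title: "Methods: from genome scan to tissue regulatory networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from genome scan to tissue regulatory networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirnaome)
```

# Overview

`mirnaome` re-implements, end to end, a genome-to-network microRNA
analysis of the kind used to characterize a mammalian miRNAome from
custom tiling arrays and small-RNA sequencing:

1. **Homology scan** — find pre-miRNA loci conserved from a cross-species
   reference collection.
2. **De-novo discovery** — scan the genome for locally stable stem-loops,
   filter them by canonical pre-miRNA criteria, and classify them with a
   triplet-element sequence/structure model.
3. **Endpoint calling** — reconstruct mature miRNA 5'/3' termini from
   tiling-array fluorescence via a leave-one-out bootstrap, with spike-in
   calibration to molar amounts.
4. **Confidence classification** — grade hairpins by small-RNA read
   coverage of the mature interval.
5. **Target and network inference** — seed-match target prediction on
   3'UTRs, expression anti-correlation filtering, and per-tissue bipartite
   (permissive/repressive) regulatory networks.

Every stage consumes inputs that the `synthetic_data` generators can
produce with planted ground truth, so the full pipeline is testable
offline. This vignette records the models, parameter choices and their
rationale, and what the synthetic world does and does not establish.

# The synthetic world

`sim_config()` fixes the stated world once:

* **Hairpins**: perfect inverted repeats (stem 30–45 bp, terminal loop
  4–15 nt) then point-mutated at 5% per site. This gives precursors of
  64–105 nt with free energies far below the −27 kcal/mol filter, i.e.
  unambiguous positives, while the 5% mutation rate is a realistic level
  of stem imperfection (real pre-miRNAs carry a handful of mismatches and
  small bulges per stem).
* **Decoys**: tRNA-like cloverleafs (an acceptor stem plus three short
  arms — many loops, exactly the structure the ≤2-loop rule rejects) and
  CDS-like codon-structured sequence (weakly structured), mirroring the
  negative classes used to train the original classifier.
* **Matures**: the first/last 22 nt of each arm; IDs carry the arm so
  miRNA/miRNA* analyses are exercisable.
* **Fluorescence**: log-normal (multiplicative) noise, `noise_sd = 0.3`
  on the natural-log scale, background 5×10⁴ units, and a planted
  endpoint probe at `signal_fold = 10` above background. Log-normal noise
  is the microarray convention (positive, heteroscedastic); no specific
  platform noise model is claimed, so this is a stand-in, parameterized
  so tests can vary it.
* **Spike-ins**: eight titration points with a log-log-linear response
  spanning 10⁻¹⁸–10⁻¹⁴ mol, the linear range such spike-in assays
  typically achieve.
* **Reads**: full-length mature copies with Poisson counts
  (`coverage_mean` = expected reads per mature = per-nt coverage, since
  reads are full length), uniform mismatches, plus decoy-region reads so
  the "discard reads mapping elsewhere" rule has something to discard.
* **Expression**: planted (miRNA, target) pairs share a latent profile
  with a sign flip; with noise variance `s² = −1/r − 1` the expected
  Pearson correlation is exactly the configured `r` (−0.9 by default over
  14 tissues, a typical multi-organ panel size). Sponge
  lincRNAs use the same latent without the sign flip. This is achieved by
  construction, not rejection sampling. Planted targets also receive an
  exact seed-complement site in their 3'UTR.

What a green test establishes: the algorithms recover exactly what was
planted, at the stated noise. What it does not establish: performance on
real genomes (repeats, composition bias, isochores), real array artifacts
(spatial effects, probe affinity), or sequencing error structure beyond
uniform mismatches — all deliberately out of the generators' scope.

# De-novo discovery: the folding engine

External thermodynamic folders are not available offline, so the scan
uses a built-in nearest-neighbor engine (C++): Turner-style stacking
energies over the six canonical pair types, tabulated hairpin/bulge/
internal-loop penalties with logarithmic extrapolation, and **no
multibranch loops** — the object of interest is a single fold-back.
Three design choices matter and were driven by failure modes observed on
planted data:

* **Minimum helix length 3 bp.** Unconstrained maximum-pairing models
  decorate terminal loops with 1–2 bp artifact helices, which fragment
  the loop into several unpaired runs and break the ≤2-loop filter.
* **1×1 mismatches live inside helices** (penalty +1 kcal/mol). A point
  mutation in a stem must fold as a 1×1 internal loop — a 1-nt unpaired
  run the loop filter ignores — not split the helix. Without this, two
  mutations 2 nt apart forced a merged 4×4 loop and genuine precursors
  failed the loop count.
* **Block extraction.** A candidate is the energetically best contiguous
  run of helices connected by small (≤2 nt per side) loops; outer helix
  segments contributing less than `trim_delta = 3` kcal/mol are trimmed.
  This stops accidental background pairing across large loops from
  absorbing a genuine stem-loop into a sprawling low-quality structure.

The engine is a documented surrogate: energies are approximate, the
helix walk is greedy, and no claim of equivalence to a published folder
is made. It is pluggable (`engine` argument) so a real folder can be
dropped in. The filter thresholds themselves — length strictly between
54 and 217 nt, energy strictly below −27 kcal/mol, at most 2 loops of
3–30 nt, any unpaired run over 30 nt disqualifying — are configuration
(`hairpin_filter_config()`), with the loop-counting convention that every
unpaired run of 3–30 nt (terminal, internal-loop side or bulge) counts
as one loop and 1–2 nt runs are ignored.

# The triplet classifier

Candidates are encoded as the classic 32-bin triplet vector: for each
interior position, the paired/unpaired state of (left, self, right) —
bracket orientation collapsed — crossed with the middle base. The
classifier is ridge-penalized logistic regression (IRLS). Two deliberate
choices:

* the probability is an exact monotone function of the linear margin, so
  the acceptance rule "probability strictly greater than 0.998" is a
  well-defined operating point on the margin;
* the default ridge is tiny (10⁻⁵): with nearly separable classes the
  fitted probabilities must be able to saturate beyond 0.998, which a
  strongly regularized model cannot do. The penalty exists only to keep
  the IRLS solve non-singular under perfect separation.

The Drosha-site scorer is a pluggable interface whose shipped surrogate
uses structure only (total stem pairs vs the ~22 bp two-turn lower stem
the Microprocessor requires, plus a penalty per extra terminal loop),
sign-calibrated so canonical hairpins score below 0. It is explicitly
**not** the original proprietary model.

# RAKE endpoint calling

For each probe group (22 probes for the 3'-end assay, 16 for the
5'-end), each probe is held out in turn and 10,000 groups of size k−1
are resampled with replacement from the remaining k−1 values; the
probability is the fraction of resampled means strictly below the
held-out value. The comparator is the held-out probe's own value — the
only choice under which high-fluorescence probes receive high
probabilities. A position is called when its probability exceeds the
end-type threshold (0.75 for 3', 0.65 for 5', relaxed 0.58 flagged
low-stringency) in **all** replicates (4 for 3', 3 for 5'); a
majority-rule mode sits behind a flag. The bootstrap RNG is seeded per
(hairpin, arm, replicate) from a master seed, so results do not depend
on processing order.

Mature reconstruction pairs 5'/3' calls on the same arm, keeps lengths
in 18–26 nt (the field's range of lengths compatible with a mature
miRNA), ranks pairs by joint probability with deterministic
tie-breaks (higher mean fluorescence, then 5'-most), and emits the
underscore ID convention `prefix_chrom_start_stop_strand_arm` built from
the hairpin interval.

Spike-in calibration is a least-squares line in log-log space; a
non-monotone titration is an error, and fluorescence below the fitted
value at the lowest spike is reported as missing (below detection, the
"grey square" semantics). The miRNA matrix normalization anchors a
lowess intensity-dependent correction on the spikes (median shift when
fewer than four spikes are present), which exactly undoes global scale
changes and leaves identical replicate arrays untouched.

# Confidence classes

Reads aligning to any annotated non-miRNA transcript are discarded
wholesale; the rest must carry ≤2 mismatches and ≤3 alignments.
Coverage is per-base depth over the mature interval ("averaged
coverage" is read as a per-base mean; a per-read alternative would be a
different, coarser statistic). Labels: high ⟺ mean ≥ 10, medium ⟺
3 ≤ mean < 10, low otherwise.

# Targets and networks

Seeds are mature positions 2–7; sites are exact reverse complements in
the UTR, classified 6mer / 7mer-1A / 7mer-m8 / 8mer by the 3'-A and the
position-8 match. Sites within 15 nt of the UTR's 5' boundary are
excluded (the conventional rule against sites too close to the stop
codon; an alternative 3'-terminus reading is available via
configuration). There is no single standard anti-correlation cut in the
field; the default is −0.7, a
conventional strong-negative threshold, exposed in the interface and
recorded in all outputs.

A tissue network joins interaction edges between same-state mRNAs and
targeting edges that match the regulatory sign logic: down-miRNA →
up-mRNA edges form the *permissive* side, up-miRNA → down-mRNA the
*repressive* side; edges violating both are dropped for that tissue.
Node state is the sign of log2(tissue / across-tissue mean) with a
configurable dead-zone (default 0, pure sign — log2-ratio coloring has
no canonical cutoff); below-detection nodes are excluded. Modules are
connected components per side with a deterministic ordering; fancier
community detection is a declared non-goal.

Satellite analyses: hierarchical tissue clustering (average linkage,
1 − Pearson) with feature-resampling node support; per-hairpin 5p/3p
log-ratio profiles and cross-arm correlations with missing-value
propagation; exact hypergeometric family enrichment; and lincRNA sponge
detection as positive correlation ≥ 0.9 (configurable).

# Numerical choices and degenerate inputs

* Strict inequalities are preserved exactly where quoted (54/217 nt,
  −27 kcal/mol, 0.998, >40% overlap); ≥ is used where quoted as ≥ (10×
  and 3× coverage, 0.75/0.65/0.58 exceedance in the bootstrap).
* Correlation on zero-variance profiles is undefined; such pairs are
  excluded rather than imputed.
* Quantification at a calibration point's own fluorescence is protected
  against floating-point wobble (a 10⁻⁹ relative guard on the detection
  floor), as is the r = 1 boundary in sponge detection.
* `N` bases never pair and triplet windows containing `N` are skipped.
* Ties in canonical-mature selection and module ordering are broken
  deterministically, so outputs are stable across runs and platforms.

# Known limitations

* The folding engine is a surrogate; absolute energies are approximate
  and branched structures are unrepresented (by design for hairpin
  search, but tRNA cloverleafs fold as their best single arm).
* The Drosha-site scorer is a labeled stand-in, not the original model.
* Whole-genome-scale performance is a non-goal: the homology scan is
  O(genome × reference) per precursor and intended for desk-scale
  inputs.
* Genome-scale discovery counts from real assemblies are not reproduced
  here — they would require a real assembly, real array data and an
  interaction-database snapshot; tests verify behavior on planted
  synthetic data plus small arithmetic consistency checks instead.
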