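---
title: "deltaBind: OLS k-mer models of TF binding and variant-effect inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{deltaBind: OLS k-mer models of TF binding and variant-effect inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Universal protein-binding microarrays (uPBMs) measure a transcription
factor's binding intensity against tens of thousands of 60-bp probes, each a
36-bp random variable region followed by a constant 24-bp primer complement
used for double-stranding.  deltaBind models the natural log of the probe
intensity as an additive function of 6-mer content:

$$Y = X\beta + \epsilon, \qquad \epsilon \sim N(0, \sigma^2 I),$$

where row $i$ of $X$ counts the occurrences of each 6-mer in probe $i$.  A
6-mer and its reverse complement are the same variable (a TF does not know
which strand it reads), giving $p = (4^6 + 4^3)/2 = 2080$ canonical
features.  The whole 60-bp probe is scanned, constant primer included,
because the protein can bind anywhere on the molecule.

The fit is ordinary least squares: $\hat\beta = (X'X)^{-1}X'Y$, with
$\hat\Sigma = \hat\sigma^2 (X'X)^{-1}$ and $\hat\sigma^2 = \mathrm{RSS} /
(n-p)$.  **No intercept is included.**  This is not an oversight: every row
of $X$ sums to the constant $L - k + 1 = 55$, so the ones vector already
lies in the column span and an explicit intercept column would make the
design exactly singular.  A consequence worth knowing: any constant
baseline in the log intensities is absorbed as a uniform $+\mu/55$ shift of
all coefficients.  Variant contrasts (below) sum to zero, so this shift
never reaches a prediction.

## Variant effects as linear contrasts

A single-nucleotide variant changes only the 6-mers overlapping it: six
windows in an 11-bp span centered on the position.  Writing $c$ for the
per-feature count difference (mutant minus wild type; at most twelve
canonical features change, and the entries always sum to zero), the
predicted binding change is

$$\Delta = c'\hat\beta, \qquad
  t = \frac{c'\hat\beta}{\sqrt{c'\hat\Sigma c}},$$

and $H_0: c'\beta = 0$ is tested with this statistic.  With $n - p$ in the
tens of thousands for real uPBM data the $t$ reference distribution is
indistinguishable from standard normal, so the package reports the normal
z-score and two-sided P-value; `contrastTest()` also returns the exact
Student-t P-value, and a test asserts the two agree to better than $10^{-4}$
once $n - p \ge 10{,}000$.  The sign convention is mutant minus wild type:
positive $\Delta$ means gain of binding.

Degenerate cases are pinned down by convention: an all-zero contrast
(identity variant) returns $(\Delta, z, p) = (0, 0, 1)$; a zero standard
error with a non-zero estimate (a noise-free model) is an error rather than
an infinite z-score.

## Binding status from 8-mer E-scores

Effect sizes answer "how much", E-scores answer "is it a site at all".  For
each allele the 17-bp window around the variant (8 bp of context each side)
is classified from its ten overlapping 8-mers: **bound** if two consecutive
overlapping 8-mers (adjacent start offsets, 7-bp overlap) both have E-score
$> 0.4$; **unbound** if all ten are $< 0.35$; **ambiguous** otherwise.  The
inequalities are strict exactly as printed: a score of 0.4 does not
support a bound call, and a score of exactly 0.35 blocks an unbound call.
Both thresholds are user-adjustable (`--escore-bound`,
`--escore-unbound`); the wild-type and mutant calls combine into one of
nine transition labels such as `unbound>bound`.  E-score lookup is strand
symmetric by construction, and tables listing all $4^8$ 8-mers or one per
reverse-complement pair are both accepted (conflicting scores within a
pair are rejected, not averaged).

## Numerical choices

* **Solver.**  $X$ is held sparse; the normal equations are solved through
  the Cholesky factor of $X'X$ when it is positive definite and
  well-conditioned (estimated condition number below $10^{10}$).
  Otherwise the symmetric eigendecomposition is used, small eigenvalues
  (below $p \cdot \epsilon \cdot 100$ relative) are truncated, the
  minimum-norm solution is taken, and the model is flagged rank deficient.
  Contrasts on rank-deficient models are tested for estimability — the
  contrast must be orthogonal to the null space to $10^{-8}$ relative — and
  error otherwise.
* **Strand-exact arithmetic.**  Contrast contributions are accumulated in
  sorted canonical-feature order, so a variant and its reverse-complement
  image produce bitwise-identical $(\Delta, se, z, p)$; swapping the two
  alleles negates $\Delta$ and $z$ exactly and preserves $p$.
* **Cross-validation QC.**  Following the training-data QC rule, 5-fold
  cross-validation (seeded shuffle; Pearson correlation on the log scale)
  is summarized on the 10% and 20% of probes with the highest observed
  intensity — those carry the binding signal — and a dataset passes when
  both correlations reach 0.2.  The fold count and correlation flavour are
  this package's declared defaults, recorded in the QC metadata; the
  top-fraction cutoff is `ceiling(f * n)` probes after sorting by
  decreasing intensity with ties broken by input order.
* **Log base.**  Natural log.  The base only rescales $\beta$ uniformly
  and cancels from every z-score and P-value.
* **12-mer tables.**  Precomputed tables are keyed by (11-bp wild-type
  context, alternate base) — $4^{12}$ keys with identity rows included (the
  default; a flag omits them).  Rows are generated streaming in
  lexicographic key order; values are stored as IEEE float32 (the P-value
  as $-\log_{10} p$ to preserve small values), so lookups reproduce direct
  computation exactly at stored precision.  Complete tables are addressed
  by offset arithmetic without an in-memory index; partial tables carry
  sorted keys and use binary search.  Identity rows store exact zeros.
* **Coordinates.**  Genomic inputs are 1-based (VCF convention); the
  17-bp context spans positions $\mathrm{pos}-8 \ldots \mathrm{pos}+8$.
  All inputs are read on the forward strand of the supplied FASTA —
  loss-free, because both the model and the status rule are strand
  symmetric.  Soft-masked bases are upper-cased; an N in the window skips
  the record with reason `ambiguous_base`.  No genome ships with the
  package and no liftover is performed; assembly names are provenance
  labels only.

## The synthetic-data generator

Real uPBM training data cannot ship with a package, so `simulateUPBM()`
generates datasets from a planted ground truth that the rest of the
package can be validated against end to end:

* probes are uniform random 36-mers plus the fixed primer complement;
* `betaTrue` is motif-like: the canonical feature of a consensus 6-mer
  (default `TGACGT`) gets amplitude 3.0 natural-log units, features one
  mismatch away get 1.0, everything else 0;
* log intensity = counts $\cdot$ `betaTrue` + baseline 7.0 + $N(0,
  0.5^2)$, exponentiated back to fluorescence scale.

The defaults are chosen once to look like a strong, specific TF on a real
array: a consensus occurrence multiplies intensity about 20-fold, a single
mismatch about 2.7-fold, the baseline corresponds to ~1100 fluorescence
units, and the resulting probe dynamic range of ~4–5 natural-log units with
replicate-scale noise sd 0.5 matches what practitioners see.  The
simulated E-score table ranks every canonical 8-mer by the summed
`betaTrue` of its three constituent 6-mers and rescales ranks into
$(-0.5, 0.5)$, which reproduces the qualitative shape of real E-score
distributions (consensus-bearing 8-mers near +0.5, background mass near
zero).

What the generator deliberately does **not** emulate: position effects
within the probe, sequence-composition biases of real arrays (real uPBMs
use de Bruijn designs that cover all 10-mers evenly, not uniform random
sequence), saturation of the scanner, spatial artefacts, or replicate
structure.  Passing tests on synthetic data therefore validate the
inference machinery under the model's own assumptions — they do not certify
accuracy on any particular real TF.

### Evaluation scale and what the numbers mean

The package's reference evaluation (tests and `scripts/acceptance.R`) uses
5,000 probes per simulated dataset, 2,000 null contrasts for calibration,
and a 36-bp mutagenesis library around a planted site — sizes chosen so
the whole evaluation runs in about a minute on one CPU while keeping
$n > p$.

One number deserves a caveat it earns honestly.  At 5,000 probes the
design has $n/p \approx 2.4$ and heavily collinear overlapping k-mer
counts, so $\mathrm{tr}\,(X'X)^{-1} \approx 800$: individual coefficients
are estimated with standard errors of ~0.3 natural-log units.  Against a
sparse planted motif of realistic amplitude this caps the
coefficient-recovery Pearson correlation near 0.3–0.4, and pushing it to
0.9 would require a planted effect around $e^{18}$-fold in intensity —
nothing a PBM has ever measured.  Yet the *variant-effect* correlation on
the same fit is ~0.98: the sparse zero-sum contrasts live in
well-conditioned directions of the design, so their errors largely cancel.
This is exactly why the method reports contrasts, never raw coefficients,
and the acceptance script reports both numbers so the distinction stays
visible.

## Known limitations

* Single-nucleotide substitutions only; indels and multi-nucleotide
  variants are out of scope.
* One model per TF per dataset; no positional weighting, gapped k-mers or
  interaction terms beyond 6-mer counts, and no regularization (by
  design — the covariance of the OLS estimate is what powers the test).
* Intensities are taken as already normalized; no spatial or array-level
  correction is applied before the log transform, and rows with
  non-positive intensities are dropped, not shifted.
* The bound/unbound rule depends entirely on the supplied E-score table;
  binding status is never inferred from model coefficients.
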