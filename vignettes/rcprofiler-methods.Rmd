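---
title: "Reference Coverage Profiles: model, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference Coverage Profiles: model, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(rcprofiler)
```

# The problem

Read-depth CNV calling compares the observed depth of coverage of a genome
with the depth expected under two copies. The difficulty is that expected
depth is far from uniform: it fluctuates strongly from locus to locus in a
way that is only partially explained by global covariates such as %GC, and
the fluctuation pattern is shared across genomes sequenced with the same
technology and pipeline. Normalizing a genome against its own global mean
therefore floods the caller with false positives, while normalizing against
a *cohort-derived per-locus expectation* — a Reference Coverage Profile
(RCP) — removes the shared structure and leaves a clean copy-number signal.
This package implements that whole chain on a compressed coverage
representation, together with population annotation, trio-based validation,
and a synthetic-cohort generator that makes every stage testable without any
external data.

# The pipeline

For each genome $g$ and 1-kb bin $i$:

1. **Condense.** Per-base depth is averaged over non-overlapping 20-bp
   windows and stored in one byte per window. Depth up to 200 is stored
   verbatim; depth $d \in (200, 2700)$ as
   $\lfloor\sqrt{d-200}\rfloor + 200$; depth $\ge 2700$ goes, unbinned, to
   an overflow sidecar. Decoding returns the midpoint of a byte's preimage
   interval, which minimizes the worst-case absolute error; the round-trip
   error is bounded by $2\sqrt{\max(d-200,0)}+1$. The 20-bp window is
   justified by the autocorrelation of depth over sub-read-length
   distances ([coverage_autocorr()]).
2. **Stratify by %GC.** The genome is split into 1-kb bins and 25 buckets of
   approximately equal genomic span, delimited by rank-based %GC cutoffs
   (type-1 empirical quantiles; a value equal to a cutoff belongs to the
   lower bucket). Rank-based cutoffs keep extreme-%GC strata populated.
   Bins more than half N are masked.
3. **Scale.** Genome $g$'s *characteristic coverage vector* $C_g$ holds its
   total autosomal coverage per bucket (overflow windows excluded); a cohort
   *target vector* $T$ is the entry-wise geometric mean of the $C_g$
   (computed in log space). Scaled coverage is
   $s_g(i) = r_g(i)\, T_{b(i)} / C_{g,b(i)}$ where $b(i)$ is bin $i$'s
   bucket: each genome's per-bucket totals are equalized to the target, which
   removes both sequencing depth and per-bucket %GC bias. (Dividing raw
   coverage by the target alone cannot remove the genome's own depth; that
   literal variant is available behind `literal_divide` for comparison.)
4. **Build the RCP.** Per bin, the diploid level $L(i)$ and the MAD across
   the cohort are estimated as described below, with a support count; bins
   with fewer than 20 genomes or missing in more than half the cohort are
   masked.
5. **Normalize.** The normalized coverage profile is
   $\mathrm{NCP}_g(i) = 100\, s_g(i)/L(i)$ (percent of diploid). Bins whose
   RCP level is below 10% of the genome-wide median level are masked
   rather than divided by a near-zero.
6. **Segment.** A five-state Gaussian HMM (states 0–4 = observed copies,
   emission means 0/50/100/150/200%) is decoded by Viterbi per chromosome;
   runs of constant state become `CopyNumberSegment`s annotated with the
   median NCP, and downstream with population genotype and allele
   frequencies from a founder panel.

# The diploid-level estimator

For most bins the cohort median is the diploid level. The median is trusted
when the bin is effectively a single cluster: MAD/median $\le 0.15$
(`dispersion_trigger`) *and* at most 5% of genomes (`outlier_frac`) lie
farther than a quarter of the median from it. The second guard matters
because the median of a near-balanced two-cluster mixture (e.g. a deletion
allele frequency near 0.3, where the diploid cluster holds about half the
cohort) can land *between* clusters while the MAD stays deceptively small.

Otherwise the bin is modeled as clusters at integer multiples of an unknown
haploid level $h$. Candidate $h$ values on a grid (200 points from
$q_{0.9}/\mathrm{copy\_cap}$ to $1.05\, q_{0.9}$ of the positive values) are
scored by

$$\mathrm{score}(h) = -\sum_i \frac{(x_i - k_i h)^2}{2 (c\, h)^2}
  \;-\; \lambda\, X^2(k),$$

with $k_i = \mathrm{round}(x_i/h)$ capped at `copy_cap`, $c$ =
`cluster_cv` (0.12) and $\lambda$ = `hwe_weight` (2). Two deliberate
choices:

* **No Gaussian normalization term.** With the $-n\log(c\,h)$ term
  included, halving $h$ always gains $n\log 2$ on data with *no* cluster
  structure (the wrapped residual variance scales with $h^2$), so
  arbitrarily small haploid levels win. On normalized residuals alone,
  structureless data scores equally at every $h$ while genuine clusters
  reward the largest $h$ that aligns them — the parsimonious reading.
* **HWE penalty via a haplotype convolution.** From the assignments we
  estimate per-haplotype dosage frequencies (deleted $q$, reference,
  duplicated $p$), convolve two haplotypes into an expected copy-number
  distribution, and take the $\chi^2$ distance to the observed counts. For
  a single biallelic CNV this reduces to the familiar
  $p^2 / 2pq / q^2$ proportions. This is what disambiguates aliased
  solutions: at deletion allele frequency 0.8 the hemizygous cluster is the
  mode, and reading it as diploid implies a wildly non-HWE genotype
  distribution, while reading it as one copy fits HWE exactly.

The winning $h$ is refined by least squares
($h \leftarrow \sum x_i k_i / \sum k_i^2$, twice), then three guards apply
in order:

1. **Re-anchoring with a modal prior.** If the modal nonzero cluster is not
   copy 2, $h$ is re-anchored so that it is, unless that worsens the
   penalized score by more than `modal_prior` (0.5) per genome. The prior
   encodes "the most abundant cluster is the expected ploidy"; only strong
   HWE evidence (the aliasing case above, where the deficit is several
   units per genome) overrides it.
2. **No-cluster-evidence fallback.** Quantizing *any* data to a grid of
   spacing $h$ leaves mean squared residuals of about $h^2/12$; if the best
   fit cannot beat half of that, the "clusters" are an artifact of
   quantizing a smeared unimodal bin, and the median is returned. This
   criterion is independent of the assumed cluster width, which matters
   because multiplicative noise widens high-copy clusters.
3. **Two-sided fallback.** Assignments implying a deletion *and* a
   duplication segregating at the same bin (each side above 5% of genomes)
   fall back to the median with a warning; a single biallelic CNV model
   does not describe such bins.

All constants live in `rcp_params()` and are validated by the parameter
recovery suite (200 genomes × 5000 bins, deletion allele frequencies
0.05–0.8 plus duplications), not fitted to any published number.

# HMM defaults

The supplementary material specifying the original segmentation model is
not reproducible here, so emission standard deviations default to
(12, 12, 12, 18, 30)% — state 4 widened because it is open-ended upward —
with self-transition probability $1-10^{-4}$ (remainder split equally),
initial distribution (0.001, 0.01, 0.978, 0.01, 0.001), and ties broken
toward the lower state. Masked bins emit uniformly so the path bridges them
on transition structure alone. Posterior decoding is available behind
`decoding = "posterior"`. These defaults are validated by the synthetic
recall/precision suite; all are overridable through `hmm_params()`.

A consequence of the sticky transitions worth knowing: two same-state
events separated by fewer than about six diploid bins are merged into one
call (the two transition penalties outweigh the emission cost of bridging
the gap). The synthetic benchmarks therefore place planted events at least
12 bins apart, so that recall and precision measure detection of isolated
events; resolving closer event pairs requires either weaker self-transitions
or sub-bin breakpoint evidence, which is out of scope.

# The synthetic cohort generator

`simulate_cohort()` emulates exactly the structure the method assumes:

* a shared reference model with per-bin lognormal locus effects
  (median 1, `locus_sd` 0.25) and per-bin %GC drawn around 0.41 ± 0.05,
  matching the genome-wide regime of the human reference — wide enough to
  populate all 25 buckets;
* per-genome mean depth uniform in 35–45× (the ">40×" regime) and a
  *smooth* per-genome %GC bias curve
  $\exp(a z + b(z^2-1))$, $z = (\mathrm{gc}-0.41)/0.1$, $a,b \sim
  N(0, 0.1)$. The bias is smooth in %GC rather than an independent factor
  per bucket because that is how GC bias behaves in sequencing data — and
  because a per-bucket step bias keyed to the generator's own buckets would
  be unremovable in principle whenever the analysis re-derives buckets from
  sequence (bins flipping buckets at a cutoff would keep their full bias);
* Poisson per-base sampling; at `"window"` resolution the 20-bp window
  means are drawn directly as $\mathrm{Pois}(20\lambda)/20$, which is
  statistically identical to averaging 20 per-base draws and 20× cheaper
  (`"base"` resolution exists to exercise `condense()` itself);
* CNV alleles planted at stated population frequencies, two Bernoulli
  haplotypes per founder (Hardy–Weinberg by construction), children
  inheriting one haplotype per parent per locus;
* `simulate_scaled_cohort()` additionally short-circuits to bin-level
  scaled profiles (lognormal residual noise, default 5%) — the right level
  for studying the diploid-level estimator on 200-genome cohorts.

What the generator does *not* model: mapability artifacts, interspersed
repeat mismapping (LINE1/Alu), overdispersion beyond Poisson (a dispersion
knob would be the first extension), read-level error, and breakpoints off
the 1-kb lattice. Passing the synthetic suite therefore demonstrates the
*algorithmic* correctness of the chain, not robustness to every artifact of
real sequencing data.

# Numerical and convention choices

* Window means are rounded half-up before encoding; the overflow sidecar
  keeps the unrounded mean. Coverage exactly 2700 goes to overflow, keeping
  encodable bytes ≤ 250 with 255 as the sentinel and 251–254 reserved.
* Terminal partial windows and bins average over the bases/windows that
  exist, avoiding systematic deflation at chromosome ends.
* Geometric means are computed in log space; zero entries are excluded from
  the affected entry with a warning rather than annihilating it.
* The published GRCh37 cutoff list is available as a preset
  (`grch37_gc_cutoffs()`, with one transposed adjacent pair restored to
  ascending order); cutoffs are recomputed from the reference in use by
  default.
* Trio expected states use the parsimonious haplotype model (state $s$
  splits into its most balanced haplotype pair; state 4 is open-ended and
  transmits two or three copies); the full 25-pair table is checked against
  a brute-force enumeration oracle. Bins with a missing member state are
  never counted discordant.
* `shuffle_trios()` draws derangements of fathers and mothers
  independently, so no child is ever re-paired with a true parent.

# Problem sizes used in the validation suite

The test and acceptance runs use cohorts sized so the whole suite runs on a
laptop-class machine: 200 genomes × 5000 bins for estimator recovery,
28 genomes × 0.9 Mb at 40× (window resolution) for end-to-end calling, and
12 trios × 0.6 Mb for concordance. These sizes were chosen as the smallest
at which the binomial noise on the reported proportions is comfortably
below the thresholds being checked.

# Known limitations

* Breakpoints are bin-resolution (±1–2 kb); precise breakpoints require
  read-level evidence.
* Events closer together than the HMM persistence length merge (above).
* The estimator assumes at most one biallelic CNV per bin; multi-allelic
  loci fall back to the median.
* Sex chromosomes are excluded from scaling and trio evaluation; haploid
  regions appear downstream as state 1, never in the RCP.
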