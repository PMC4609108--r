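---
title: "Isoform quantification from exon-level counts: model and methods"
author: "exonLDM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isoform quantification from exon-level counts: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exonLDM)
```

# The problem

Two obstacles stand between RNA-Seq read counts and accurate expression
estimates. First, alternative splicing makes many reads ambiguous: a read
falling in an exon shared by several isoforms of a gene cannot be attributed
to its isoform of origin directly. Second, read coverage along a transcript
is not uniform — positional, sequence and mappability biases differ between
genes, and recent work shows they differ between isoforms of the same gene,
so a bias model shared across all genes cannot capture them.

exonLDM addresses both with a per-gene latent-variable model over *exon-level
fragment counts*. Working at exon rather than read resolution keeps the
computation light (the data for a gene is a short vector of counts, not
millions of reads) while still letting the model learn an isoform- and
exon-specific *read sequencing rate* — the per-exon emission profile that
absorbs coverage bias.

# Gene-model expansion

A gene's annotated transcripts are expanded into a set of counting bins
("exon units"):

* **Overlap splitting.** Overlapping annotated exons are cut at every exon
  boundary, so the resulting body units are pairwise disjoint and cover
  exactly the union of the annotated exons. A fragment can then never be
  counted twice because two isoforms describe overlapping intervals.
* **Junction units.** For every ordered pair of units adjacent in some
  annotated isoform, an artificial junction unit of length $2(L-1)$ is
  created ($L$ = read length): the last $L-1$ bases of the upstream unit
  followed by the first $L-1$ bases of the downstream one. Any read that
  crosses the splice boundary aligns inside this window and is counted in
  the junction bin *only* — it is evidence for the splice, not for either
  flanking exon. Junctions carry much of the isoform-discriminating signal.
* **Noise isoform.** One extra isoform containing *every* unit of the gene
  is appended. Fragments produced by noise or by undiscovered isoforms,
  which fit no annotated isoform well, can be absorbed here instead of
  distorting the annotated estimates.

A $K\times E$ binary compatibility mask records which of the $K$ isoforms
(annotated + noise) may emit which of the $E$ units.

```{r}
toy <- gene_from_exons("toy", "chr1", list(
  I1 = data.frame(start = c(100, 700), end = c(300, 900)),
  I2 = data.frame(start = c(100, 400, 1000), end = c(300, 600, 1200))))
gm <- expand_gene_model(toy, read_length = 50)
gm$compat
```

# Counting and normalization

Alignments are made against the annotated transcriptome (one reference per
isoform), one SAM/BAM per lane. Each fragment (a read, or a mate pair whose
span runs from the leftmost to the rightmost aligned base) is projected onto
the exon units of its gene:

* span inside one body unit → that unit;
* span entirely inside one junction window → the junction unit only;
* any other span → every body unit it overlaps, once per fragment.

Fragments aligning to several isoforms of one gene are deduplicated to the
union of their assignments; fragments hitting several genes are dropped and
reported. Raw tallies are then divided by unit length in bases
($n_{li} = \mathrm{raw}_{li}/\ell_i$), removing the trivial exon-length
effect so that $n$ measures the per-base frequency of observing each unit.

# The model

For one gene observed on $L$ lanes of a single library:

1. per lane, isoform fractions $\theta_l \sim \mathrm{Dirichlet}(\alpha)$;
2. per observed exon occurrence, an isoform label
   $t \sim \mathrm{Multinomial}(1, \theta_l)$;
3. the exon unit itself, $e \sim \mathrm{Multinomial}(1, \beta^{t})$,

where row $\beta^{k}$ is the isoform-specific sequencing rate over units,
constrained to zero off isoform $k$'s support and summing to one. The lanes
are technical replicates sharing $\alpha$ and $\beta$ but each with its own
$\theta_l$; this between-lane variation is what identifies $\beta$
separately from the fractions. $\beta$ is deliberately *not* shared across
biological samples.

Inference is by variational EM with
$q(\theta_l) = \mathrm{Dirichlet}(\eta_l)$ and per-(lane, unit)
responsibilities $\lambda$. Because observations of the same unit are
exchangeable, $\lambda$ is computed once per unit and weighted by $n_{lj}$ —
identical to per-read updates for integer counts and well defined for
fractional ones. The E-step alternates

$$\lambda_{ljk} \propto \beta_{kj}\,
  \exp\{\psi(\eta_{lk}) - \psi(\textstyle\sum_k \eta_{lk})\},\qquad
  \eta_{lk} = \alpha_k + \sum_j n_{lj}\lambda_{ljk}$$

to a fixed point ($\psi$ = digamma; $\lambda$ normalized over isoforms per
unit). The M-step sets
$\beta_{kj} \propto \sum_l n_{lj}\lambda_{ljk}$ on the support and updates
$\alpha$ by Newton–Raphson on the Dirichlet term of the bound, using the
diagonal-plus-rank-one Hessian for an $O(K)$ solve with step halving to keep
$\alpha > 0$. The traced objective is the full evidence lower bound
(expected log joint plus the entropy of $q$) — that is the quantity EM
provably never decreases, and the fit records it per iteration.

## Observation weights

The Dirichlet-Multinomial treats $N_l = \sum_i n_{li}$ as the number of
observations in lane $l$, so the *scale* of the weights matters, not only
their profile. Per-base normalized counts alone would shrink a
2,000-fragment gene to an effective $N_l \approx 10$, leaving the posterior
essentially prior-dominated (in that regime the estimated concentration
diverges while the fractions freeze at their first-iteration allocation).
The fit therefore rescales the normalized profile so its total equals the
raw fragment tally: length bias is removed by the profile, statistical
information by the fragment count. The per-base scale is still what enters
the FPKM formula below.

## Keeping the noise isoform honest

The noise isoform's support is every unit, so if its emission row were
re-estimated freely it could specialize into a copy of any annotated
isoform — a background topic that absorbs real signal (in simulations it
captured 10–50% of a gene's mass and degraded fraction recovery badly).
Its row is therefore held at the unbiased uniform value throughout EM
(`ldm_control(update_noise_beta = )` restores the free update): a uniform
emission can only explain unstructured residue, which is exactly the role
the component is meant to play. Skipping one coordinate block of the M-step
leaves the ascent guarantee intact. With the frozen row, data simulated
from annotated isoforms only yields median fitted noise fractions of a few
tenths of a percent.

## Numerical choices

* Unbiased initialization: $\alpha = \mathbf 1$, $\beta$ uniform on each
  support, $\lambda$ mask-uniform. A deterministic relative perturbation of
  $10^{-3}$ (`init_jitter`) is applied to the annotated $\beta$ rows: the
  exactly symmetric start is a stationary point whenever two isoforms have
  interchangeable supports, and the fixed pattern breaks such ties without
  randomness.
* Tolerances (all in `ldm_control()`): inner E-step $10^{-6}$ max-abs
  $\lambda$ change (cap 200); outer EM $10^{-6}$ relative bound change
  (cap 1000); $\alpha$ gradient max-norm $10^{-8}$ (cap 100, floor
  $10^{-10}$, up to 20 step halvings).
* $\beta$ support entries get an additive $10^{-10}$ pseudocount before row
  normalization so observed units never face an exactly zero emission.
* Genes with no counts are skipped and reported as zero expression; genes
  with a single annotated isoform bypass EM entirely (direct FPKM).
* When per-lane posteriors coincide, the maximum-likelihood $\alpha$
  diverges ($\hat\alpha \to \infty$ at fixed fractions). The fit is still
  well behaved — the fractions are what is reported — but comparisons
  against per-observation reference implementations are only meaningful on
  data with real between-lane variation.

# Expression and uncertainty

The reported isoform fraction is the prior mean
$\langle\theta_k\rangle = \alpha_k / \sum_k \alpha_k$, and isoform FPKM is

$$f_k = \frac{10^9\,\theta_k}{N_s} \sum_{l,i} n_{li},$$

with $N_s$ the total mapped fragments of the sample. No explicit division
by isoform length appears: $\sum_{li} n_{li}$ is already a per-base
quantity, and $10^9 = 10^3 (\text{kb}) \times 10^6 (\text{per million})$
turns it into FPKM units. Gene expression is the sum of isoform FPKMs;
the noise isoform is always reported but excluded from the gene total by
default (`include_noise` restores the strict sum over all $K$). Measurement
uncertainty comes from $M = 100$ (default) Monte-Carlo draws
$\theta^{(m)} \sim \mathrm{Dirichlet}(\hat\alpha)$ pushed through the same
formula; the per-isoform and gene-level sample variances can be propagated
into downstream differential-expression machinery. Single-isoform genes use
plain FPKM under a uniform-coverage assumption.

# The simulator

The generator mirrors the model's own stochastic process at two levels.
*Count level*: $\theta_l \sim \mathrm{Dirichlet}(\alpha)$ per lane, then
per fragment an isoform label and a unit from $\beta^{t}$; tallies are
normalized exactly as the counting module does. *Read level*: additionally
a position within the unit — uniform start for a single-end read of length
$L$; for paired ends a fragment length from $\mathcal N(206, 19.6^2)$
(mean 206, *standard deviation* 19.6), rounded and clamped to
$[L, \text{unit length}]$, then a uniform start. The lower clamp is $L$
rather than $2L$: mates of a short fragment simply overlap, and junction
units (length $2L-2$) must remain reachable. Reads are emitted as FASTQ
(synthetic seeded A/C/G/T unit sequences when no FASTA is given) plus an
optional pre-projected SAM against the annotated transcriptome, so the
counting module can consume simulator output without an external aligner;
counting that SAM reproduces the simulated count matrix *exactly*, for both
modes. Every draw (isoform, unit, start, pre- and post-truncation length)
is recorded in a seed-stamped truth table, including the truncation shift
of the fragment-length law.

Default study conditions used by the bundled checks: genes of 4–8 body
exons and 2–4 annotated isoforms with pairwise-distinct exon subsets
(`random_gene()`); $\alpha_k \sim U(0.5, 5)$; true emission rows
proportional to unit length times a lognormal bias with log-sd 0.4
(`random_hyperparameters()`) — fragment landing probability scales with
exon length to first order, and the lognormal factor is the isoform- and
exon-specific bias the model exists to capture; 3 lanes and 2,000 fragments
per lane per gene; the noise isoform receives no simulated mass. Because
the generative fractions count *fragments* while the model's $\theta$
lives on the length-normalized scale, recovery checks compare against each
isoform's true share of normalized fragment mass (identical to the fragment
share when unit lengths are equal).

What the simulator does **not** emulate: sequencing errors and quality
variation, fragments straddling several units (each simulated fragment
belongs to one unit, junction units being the modelled straddle),
positional bias *within* a unit, multimapping across genes, and annotation
errors. Passing tests therefore demonstrate correctness of the machinery
and recoverability under the model's own assumptions, not performance on
real libraries.

# Known limitations

* With few lanes and isoforms whose unit supports nest inside one another,
  fractions are only weakly identified; the likelihood surface has
  near-equivalent basins and EM keeps whichever the unbiased start leads
  to. Junction units mitigate but do not remove this.
* The Dirichlet concentration estimate is unstable when lanes are
  near-identical (only its normalized form — the fractions — is then
  meaningful).
* Counting treats the transcriptome alignment as given; no realignment or
  mismatch modelling is attempted, and cross-gene multimappers are dropped
  rather than allocated.

# Problem sizes used in the bundled checks

The test-suite and the acceptance script run entirely on synthetic data
generated at run time: 50 genes × 3 lanes × 2,000 fragments for fraction
recovery, 100 random instances ($K \le 4$, $E \le 12$) for bound
monotonicity, $10^5$ paired fragments for the fragment-length law, and
small ($K \le 3$, $E \le 5$) instances for exact-oracle comparisons.
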