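---
title: "Methods: causal graph-based discovery and prediction for case-control GWAS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: causal graph-based discovery and prediction for case-control GWAS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`causalgwas` implements a multivariate, causal graph-based analysis of
case-control SNP genotype data. Instead of ranking SNPs one at a time, it
searches for **Markov boundaries** of the binary phenotype: minimal SNP sets
that render every other SNP conditionally independent of case/control status.
Under the usual causal discovery assumptions (causal Markov condition,
adjacency faithfulness relaxed to allow equivalent variables, correct
statistical decisions, causal sufficiency) a Markov boundary coincides with
the phenotype's local causal pathway, and it is simultaneously the maximally
predictive and maximally parsimonious feature set. Because genotype data can
contain statistically indistinguishable SNPs (most visibly, pairs in complete
LD), the boundary need not be unique; the TIE\* wrapper enumerates the whole
family of information-equivalent boundaries rather than reporting an
arbitrary representative.

The package covers the full study shape around that core: quality-control
filters, an audit of missing-genotype patterns, kernel ridge regression
signatures over each discovered boundary, hold-out evaluation with DeLong
confidence intervals for the AUC, a resampling robustness protocol, and a
conditional-independence audit of externally reported marker SNPs. A
synthetic-data generator with planted ground truth makes every stage testable
without access-controlled cohort data.

# The G² test and its reliability guard

All independence decisions use the likelihood-ratio statistic for discrete
variables,

$$G^2 = 2 \sum_s \sum_{t,x} O_{s,t,x} \log\frac{O_{s,t,x}}{E_{s,t,x}},$$

summed over the strata $s$ of the conditioning configuration, with
product-margin expectations within each stratum and zero cells contributing
nothing. Degrees of freedom accumulate $(r_s - 1)(c_s - 1)$ per non-empty
stratum, counting only levels with non-zero stratum marginals — the standard
treatment of empty margins. The p-value is the upper tail of
$\chi^2_{df}$.

Sparse contingency tables make the asymptotic test untrustworthy, so every
test carries a **reliability flag** based on the average-cell-count rule:
the test is reliable only when $n \ge c \cdot L_T L_X \prod_i L_{Z_i}$, with
$c = 5$ samples per cell by default and $L$ the observed level counts. An
unreliable test yields *no decision*: callers must not conclude independence
from it. This asymmetry is deliberate — concluding dependence from a thin
table merely keeps a SNP around, while concluding independence would
eliminate it irrevocably.

The same arithmetic bounds the conditioning-set size: with $n$ subjects, a
binary target and ternary SNPs, at most
$\lfloor \log_3 (n / (5 \cdot 2 \cdot 3)) \rfloor$ conditioning SNPs can be
afforded. At $n = 1366$ this gives 3, the default `max_k`. The `floor` is
computed with a $10^{-9}$ epsilon so that exact powers of the base do not
fall to the lower integer through floating-point logarithms.

# GLL Markov boundary induction

`gll_mb()` is a semi-interleaved inclusion/elimination instantiation of
Generalized Local Learning:

1. **Prioritization.** Every SNP is tested marginally against the phenotype;
   those with a reliable test rejecting independence at `alpha` (default
   0.05) become candidates, ordered by ascending p-value with ties broken by
   genomic position.
2. **Interleaved elimination.** Candidates are admitted in order. After each
   admission, every current member $x$ is tested against all subsets $S$ of
   the other members with $|S| \le$ `max_k`; if any reliable test declares
   $x \perp$ phenotype $\mid S$, $x$ is removed and never readmitted.

The one-pass, no-readmission policy bounds runtime and matches the
elimination description of the GLL family; the test multiplicity works *for*
false-positive control (a weakly associated null SNP only needs one of its
many subset tests to come out independent to be dropped) while truly causal
SNPs, dependent given everything, survive all of them. No spouse-recovery
phase is implemented: in GWAS designs the phenotype has no downstream
variables with independent causes, so the parents-and-children set already
equals the Markov boundary.

Which variant of the GLL family (HITON-PC vs HITON-MB semantics) the
original analyses used is not recoverable from the published description;
the semi-interleaved parents-and-children instantiation implemented here is
one concrete admissible member of the family, and all of its orderings and
tie-breaks are fully specified so results are deterministic.

# TIE\*: enumerating equivalent boundaries

`tie_star()` first obtains the reference boundary $M_0$ on the full SNP set,
then repeatedly re-runs GLL with subsets $G$ of the discovered boundaries'
union withheld (sizes $1 \ldots$ `max_equivalence_subset`, increasing size,
lexicographic within size). A re-discovered boundary $M_G$ is accepted iff
`verify_equivalence()` holds: every SNP of $M_0$ missing from $M_G$ is
rendered conditionally independent of the phenotype by some subset of $M_G$
of size $\le$ `max_k` under a reliable test. Accepted boundaries extend the
union and thereby the withheld-subset queue; the capped subset lattice is
finite, so the procedure terminates.

`max_equivalence_subset` defaults to 2. The observed multiplicity in real
cohorts arises from single-SNP substitutions (complete-LD pairs), which a
size-1 withholding already discovers; size 2 adds a margin for pairs of
substitutable SNPs while keeping the subset lattice small. The full lattice
is exponential and out of reach for routine use. The exact
subset-generating function of the original TIE\* formulation is published
only in supplementary material; the instantiation here is an admissible
choice verified by its own equivalence criterion, not a byte-for-byte
reproduction.

# Quality control

`apply_qc()` applies three SNP filters in fixed order, each counted on the
survivors of the previous step: call rate strictly above 95%, pooled minor
allele frequency strictly above 1%, and a Hardy-Weinberg
goodness-of-fit test at $\alpha = 10^{-5}$ (1-df $\chi^2$ of observed
genotype counts against $p^2, 2pq, q^2$ expectations). The strict
inequalities follow the conventional phrasings ">95%" and "above 1%". HWE is
computed in controls by default — the standard GWAS practice, since true
associations distort genotype frequencies in cases — and is configurable to
the pooled cohort; which cohort the original study used is not stated in its
methods. An exact HWE test is a non-goal; at the $10^{-5}$ threshold the
$\chi^2$ approximation serves the filtering purpose.

# Predictive signatures

Genotypes enter the classifier as 0/1/2 dosages, missing calls imputed to
the training-set mode (few survive QC), and each column centered and scaled
by training statistics; test sets always reuse the stored parameters.
Kernel ridge regression with the radial basis kernel
$K(x, y) = \exp(-\gamma \lVert x - y \rVert^2)$ solves the dual system
$(K + \lambda I)c = y$ with the binary labels regressed as real 0/1; the
continuous score is used for ranking, so AUC is the natural metric.
Hyperparameters are selected by stratified 10-fold cross-validation
maximizing mean fold AUC, with ties resolved toward the smaller $\gamma$ and
larger $\lambda$ (the more regularized model). The ridge grid is
$\lambda \in \{10^{-10}, 10^{-8}, \ldots, 1\}$. The kernel-width grid scales
inversely with the number of SNPs in the model,
$\gamma \in \{2^{j}/n_{\text{snps}} : j = -3, \ldots, 3\}$: with
standardized columns, $\lVert x - y \rVert^2$ grows linearly in the number
of features, so $\gamma \propto 1/n$ keeps the kernel's effective scale
stable across signature sizes. During tuning the kernel is eigendecomposed
once per (fold, $\gamma$) and reused across the whole $\lambda$ grid.

# Evaluation

Hold-out evaluation splits the cohort per stratum with round-half-up
rounding at a 2/3 training fraction, preserving the case:control ratio to
within one subject. AUC is the Mann-Whitney statistic with half-credit
ties; its confidence interval is DeLong's placement-value form
$\widehat{AUC} \pm z \sqrt{S_{10}/m + S_{01}/n}$, truncated to $[0,1]$,
collapsing to a point when the variance degenerates (e.g. perfect
separation). The resampling protocol repeats the whole chain — split,
TIE\*, per-boundary tuning and fitting, held-out scoring — over many random
splits and aggregates the AUC distribution and each SNP's selection
frequency (membership in at least one boundary of that split); a failing
split is recorded with its index rather than dropped.

# Audits

**Missingness.** The calls matrix is binarized (1 = missing), each
missing-value SNP's indicator is tested against the phenotype with the
marginal G² test under BH-FDR, locus enrichment of significant SNPs uses
the hypergeometric upper tail, and a kernel ridge classifier is fit on the
binarized matrix over a stratified split. Under MCAR this classifier sits at
chance; phenotype-dependent missingness makes it predictive — a data-quality
red flag that argues for removing missing-value SNPs before discovery. The
locus is a user-supplied coordinate window, since locus membership rules
are dataset-specific; in synthetic runs it is ground-truth-defined.

**Known-SNP audit.** For each externally reported marker SNP,
`ci_audit()` reports whether it is marginally associated and, if so, the
first (minimal) subset of a discovered boundary — searched in increasing
size up to `max_subset`, default 4 — whose reliable test renders it
conditionally independent of the phenotype. Markers already in the boundary
are flagged and excluded; markers absent from the assay are reported, not
errored.

# The synthetic generator

`generate_dataset()` emulates exactly the features the pipeline exercises:

- **LD** by first-order haplotype copying within blocks: each haplotype
  allele is copied from the previous SNP with probability `ld_rho`, else
  drawn fresh at that SNP's MAF (uniform in `maf_range`). This is the
  smallest mechanism producing tunable $r^2$ decay; it is not a coalescent
  model and makes no attempt at realistic recombination maps or allele
  frequency spectra.
- **Phenotype** via a logistic model over planted causal dosages, with
  case-control ascertainment by rejection sampling until both quotas are
  met — mirroring separate case/control recruitment.
- **Complete-LD duplicates** as exact column copies ($r^2 = 1$),
  reproducing the deterministic substitution structure that drives boundary
  multiplicity; noisy high-LD pairs are available through `ld_rho` instead.
- **Missingness** applied last: uniform MCAR, plus per-SNP extra missing
  probability in cases (NMAR) for designated SNPs.

A single integer seed drives one stated RNG stream, and the caller's RNG
state is restored on exit. What the generator does *not* emulate —
population structure, genotyping batch effects, sex chromosomes, rare
variants — bounds what green tests certify: they demonstrate correctness of
the algorithms under the stated generative assumptions, not performance on
any real cohort.

# Test problem sizes and numerical choices

The test suite exercises the discovery stack at 2,000 subjects and
500 SNPs (50 seeded replicates for the recovery properties; five planted
causal SNPs with log-odds effects in $[0.5, 1.2]$, MAF 0.1–0.4, LD blocks of
10 at copying rate 0.5), the resampling protocol at 600 subjects, 30 SNPs
and 100 splits, and the missingness audit at 600 subjects and 200 SNPs with
a 15% extra case-missingness cluster. These sizes were chosen so that each
property is measured with comfortable statistical margin while the whole
suite remains quick to run routinely. Oracles are independent of the code
paths they check: brute-force cell loops for G², literal draw enumeration
for the hypergeometric tail, explicit `qr.solve` for the KRR dual system,
exhaustive pair counting for AUC, and Monte-Carlo coverage for the DeLong
interval.

Numerical guards worth knowing about: constant encoded columns get scale 1;
the kernel distance matrix is clamped at 0 before exponentiation; a singular
dual system at $\lambda = 0$ (duplicate rows) raises an error advising
$\lambda > 0$; ties in allele counts orient the lexicographically smaller
allele as minor; and all stochastic functions take explicit seeds, keeping
every pipeline stage bit-reproducible.

# Known limitations

- Conditional-independence tests are asymptotic; the reliability heuristic
  is a guard, not a guarantee, at small $n$.
- The elimination pass never readmits SNPs, so a causal SNP discarded early
  (by an unlucky reliable test) cannot return; the resampling protocol is
  the intended instrument for detecting such instability.
- TIE\*'s equivalence search is capped; equivalence classes only reachable
  by withholding more than `max_equivalence_subset` SNPs at once are not
  enumerated.
- The KRR signature models genotypes only; covariates (e.g. a binary
  shared-epitope status) are carried by the dataset container but not
  entered into the kernel.
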