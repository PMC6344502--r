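---
title: "Class prediction with an asymmetric diluted Hopfield network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Class prediction with an asymmetric diluted Hopfield network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hopclass)
```

## The model

A Hopfield network is a fully connected set of $N$ binary units
$x_i \in \{-1, +1\}$ with symmetric, zero-diagonal weights $W_{ij}$,
evolving by asynchronous updates $x_i \leftarrow \mathrm{sign}(h_i)$,
$h_i = \sum_j W_{ij} x_j$. The quadratic energy
$E = -\tfrac12 \sum_{ij} W_{ij} x_i x_j$ is a Lyapunov function of these
dynamics, so every trajectory ends in a local minimum. Patterns written
into $W$ by the Hebb rule $W_{ij} = \tfrac1N \sum_\mu \xi^\mu_i \xi^\mu_j$
become such minima as long as the load $p/N$ stays below the storage
capacity ($\approx 0.138$ for random uncorrelated patterns).

`hopclass` uses this machinery for single-sample class prediction: class
$\mu$'s gene signature defines a template $\xi^\mu$ (+1 on its own genes,
−1 elsewhere) over the union of all signature genes, a sample's binarized
expression state is the corrupted input, and retrieval of a template is a
class call. Gene signatures, however, are nearly a partition of the gene
union, so the $p$ templates are strongly *anti*-correlated — far from the
random-pattern regime — and two modifications are needed.

**Binary weights.** The modified Hebb rule
$W_{ij} = \tfrac{p}{2N}(\sum_\mu \xi^\mu_i \xi^\mu_j + 2 - p)$ collapses,
for non-overlapping signatures, to $W_{ij} = +p/N$ within a class and
$-p/N$ across classes. `hebb_weights_modified()` evaluates the general
formula (so overlapping signatures are tolerated, with a warning) and the
test suite asserts its equivalence to the block form on random
non-overlapping layouts.

**Asymmetric diluted dynamics.** States are extended to
$x_i \in \{-1, 0, +1\}$. A unit may switch $-1 \to +1$, but a prescribed
$+1 \to -1$ switch instead *eliminates* the unit ($x_i := 0$,
permanently): a gene whose up-signal contradicts the emerging class is
treated as noise and silenced, not inverted. Zero units (absent genes,
cutoff-excluded genes, eliminated genes) never re-enter the dynamics. A
zero local field changes nothing; this tie rule keeps the current state
and preserves the Lyapunov argument. Because units only move
$-1 \to +1 \to 0$, the asymmetric dynamics cannot cycle; the default cap
of 100 sweeps is a safety bound, with early exit when a sweep changes
nothing.

## The classification pipeline

1. *Weights.* Build the template bank and weight matrix from the
   signatures (GMT input via `read_gmt()`).
2. *Preprocessing.* Drop genes outside every signature; binarize the
   sample as $x_i^0 = \mathrm{sign}(\mathrm{log2ratio}(A_i))$, with 0 for
   absent genes, zero values and exact ties. Two ratio conventions are
   supported: values that already are log2 ratios (default), or
   intensities binarized against each gene's cohort median
   (`ratio_mode = "gene_median_log2ratio"`), covering two-channel arrays
   and single-channel/RNA-seq data respectively.
3. *Classification.* Evolve the state; convergence is declared when at
   least `match_threshold` (default 95%) of the genes active at $t = 0$
   match a template, eliminated genes counting as mismatches. Signatures
   larger than $\Gamma$ (default 200) are subsampled to $\Gamma$ random
   genes, the excluded genes entering at state 0; the run is repeated
   $M = 100$ times with fresh subsamples and the plurality class over the
   $M$ votes (ties, or a plurality of non-converged replicas, give
   "unclassified") is the primary call. When no signature exceeds
   $\Gamma$ there is nothing to resample — the $M$ replicas are the same
   experiment — so a single replica is run; this makes results exactly
   independent of $M$ for small-signature problems.
4. *Confidence.* The energy of the full binarized state is compared
   against the energies of `n_permutations` (default 1000) random
   reshuffles of the sample's values across the signature genes, keeping
   only reshuffles that classify to the same class (each classified with
   `null_replicas` replicas). The p-value is lower-tail with an add-one
   pseudocount, $p = (1 + \#\{E_{null} \le E_{obs}\})/(1 + k)$: stored
   templates are energy minima, so "significantly low" energy means
   "significantly close to the attractor". An empty null ($k = 0$) yields
   $p = 1$ and a low-confidence flag. FDR is Benjamini–Hochberg across
   the classified samples of the run (via `stats::p.adjust`);
   unclassified samples carry no p-value and do not enter the family.
5. *Secondary class.* For $p \ge 3$, the winning signature's genes are
   deleted, the $(p-1)$-class network rebuilt, and the classification
   repeated; the resulting call characterizes samples that mix two
   expression programs.

Reshuffling is confined to the filtered signature genes: shuffling over
all measured genes would make the null's value pool depend arbitrarily on
platform gene count. Observed and null energies are computed on the full,
un-pruned state, which makes the observed statistic deterministic; the
permuted samples' classes are still decided by the full $\Gamma/M$
pipeline.

## Choosing $\Gamma$: the storage bound

$\Gamma$ balances two pressures. It should be of the order of the
smallest signature, so classes compete on even terms and small, cleaner
signatures are not drowned out. But the working network must stay large
enough for reliable recall: a stored bit is unstable with probability
$P_{error} = \tfrac12[1 - \mathrm{erf}(\sqrt{N/2p})]$, and requiring
error-free recall of a whole pattern, $(1 - P_{error})^N > 0.99$, leads
via the asymptotic expansion of $\mathrm{erf}$ to the self-consistent
bound $N > p\,\ln(Np/0.0002\pi)$. `storage_bound_size()` solves it by
fixed-point iteration: the minimal sizes are 51 at $p = 4$ and 82 at
$p = 6$, so for the practically relevant $2 \ll p \ll 6$ the threshold
lies between roughly 70 and 100 genes. Since class templates are
correlated (harder than the random-pattern assumption behind the bound),
the default $\Gamma = 200$ keeps the working network comfortably above
it.

```{r bound}
storage_bound_size(6)
recall_probability(storage_bound_size(4), 4)
```

## Numerical and design choices

* **Sweep scheduling.** Each sweep visits all nodes once in a fresh
  uniformly random order from the run's seeded generator; convergence is
  checked per sweep (order-robust and cheap), not per single update.
* **Tie rules.** $h_i = 0$ keeps the current state; a value exactly at
  its reference binarizes to 0; an exact vote tie between classes — or
  two templates tied at the same best match fraction — is reported as
  "unclassified" rather than silently resolved.
* **Randomness discipline.** One master seed; per-sample, per-stage child
  streams are derived from it and the sample identifier, so a sample's
  call does not depend on which other samples share the matrix (except
  through cohort medians in `gene_median_log2ratio` mode), and reruns are
  byte-identical.
* **Local fields.** The dense matrix-vector product is the ground truth
  (C++ inner loops); the class-sum shortcut
  $h_i = (p/N)(2S_{c(i)} - S - x_i)$, valid for non-overlapping
  signatures, is exposed and property-tested against it at $10^{-12}$.
* **Missing data.** Absent signature genes, `NA` cells and non-numeric
  cells all enter at state 0, where they exert no force on the dynamics.

## Template stability is conditional

The class templates are *not* unconditionally fixed points of the
asymmetric dynamics. For the ternary template of class $\mu$, the field
at a gene of another class $c$ is $(p/N)(N + 1 - 2N_c - 2N_\mu)$: it is
negative (stable) only when every class pair covers a majority of the
network, $N_c + N_\mu > (N+1)/2$. Any two-class layout satisfies this;
balanced three-class layouts do; four or more balanced classes sit
exactly at the margin ($+p/N$) and a large block of down-regulated genes
can "lift" an unrelated class. The package documents and tests stability
on layouts meeting the condition, and this is also why clean multi-class
calls degrade when one signature dwarfs the others — the motivation for
the $\Gamma$ cutoff in the first place.

## What the synthetic generator emulates — and what it does not

`synth_spec()`/`simulate_cohort()` draw per-gene log2 ratios for a sample
of class $c$ as Normal($+$`effect`, `sigma`) on its own signature genes,
Normal($-$`effect`, `sigma`) on other signature genes and
Normal(0, `sigma`) on noise genes, then negate each signature gene's
value with probability `flip_prob`; mixture weights replace the class
mean by a convex combination. Defaults — three classes of 60/80/100
genes (sizes satisfying the pairwise stability condition), 10 samples
per class, `effect` 1.5 (about three-fold), `sigma` 0.5,
`flip_prob` 0 — represent a moderate, mildly imbalanced signature panel.
The generator provides a clean dial from trivially recoverable
(`flip_prob = 0`) to pure noise (`flip_prob = 0.5`); it does *not*
emulate platform artifacts, probe effects, count dispersion or
correlated gene modules, so a perfect score on clean synthetic cohorts
demonstrates correctness of the pipeline, not expected field accuracy on
real tumors.

The p-value calibration check runs on pure-noise cohorts (two balanced
50-gene signatures, `flip_prob = 0.5`) at `match_threshold = 0.7`: at the
default 0.95 threshold noise samples are — correctly — never classified,
so no p-values would exist to calibrate, and on much smaller networks the
energy, a function of a single integer class-sum difference, is too
discrete for a Kolmogorov–Smirnov comparison against the uniform.

## Problem sizes used by the test suite

The shipped tests run the full capacity scan at $N = 500$ with 20 trials
per load (a couple of minutes of CPU), classification checks on cohorts
of 9–30 samples with networks of 30–830 genes, and calibration on 200
noise samples with 200 permutations of 10 null replicas each. These sizes
were chosen to give stable seeded outcomes at interactive runtimes;
nothing in the method depends on them.

## Known limitations

* **Finite-size capacity bias.** Initializing *at* a stored pattern and
  relaxing measures a dynamical capacity inflated by metastability: above
  the thermodynamic transition the state can stay trapped near the
  pattern. At $N = 500$ the retrieved fraction crosses 50% near
  $p/N \approx 0.165$–$0.17$, drifting toward 0.138 only slowly as $N$
  grows (we observe $\approx 0.155$ at $N = 2000$). `estimate_capacity()`
  reports the protocol's honest answer with its Monte-Carlo standard
  error; it is an upper bound on the thermodynamic capacity.
* **Empty nulls on strongly separated samples.** When no reshuffle of a
  sample re-creates its class pattern, the permutation null conditioned
  on the same class is empty and the p-value defaults to 1 with a flag —
  conservative, and worth reporting alongside the vote fraction.
* **Vote-threshold interaction.** On very small networks (a handful of
  genes per class) a single elimination already violates the 95%
  criterion; toy problems need a lower `match_threshold` to express their
  qualitative behavior.
* **Overlapping signatures** are accepted via the general weight formula
  but the class-sum shortcut, the block form and the stability analysis
  no longer apply; a warning is emitted.
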