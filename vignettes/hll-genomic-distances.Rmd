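---
title: "Estimating genomic distances with HyperLogLog k-mer sketches"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating genomic distances with HyperLogLog k-mer sketches}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kmersketch)
```

## The problem

Comparative genomics constantly asks "how similar are these two sequence
collections?" at scales where alignment is hopeless: all-pairs comparisons
over tens of thousands of assemblies, or screening a sequencing run against
a reference database. The standard reduction replaces each collection by
its set of canonical k-mers and compares sets: the Jaccard coefficient
$J = |A \cap B| / |A \cup B|$, the containment $|A \cap B|/|A|$, the
overlap $|A \cap B|/\min(|A|,|B|)$, and the Mash distance
$d = -\tfrac{1}{k}\ln\frac{2J}{1+J}$, a proxy for one minus average
nucleotide identity.

Materializing the k-mer sets is the expensive part. This package keeps only
a **HyperLogLog (HLL) sketch** of each set — an array of $m = 2^p$ one-byte
registers — and estimates all four cardinalities from register arrays
alone. MinHash (bottom-k) and Bloom-filter sketches are provided as
baselines, an exact hash-set mode as ground truth, and a count-min filter
removes error k-mers from reads at sketching time.

## The sketch

Each canonical k-mer code is hashed with Thomas Wang's 64-bit reversible
mix. The hash $h$ splits into a $p$-bit prefix (the register index, taken
from the most significant bits) and a $q = 64-p$ bit suffix; register $j$
stores

$$M_j = \max \{\, \mathrm{LZC}(\text{suffix}) + 1 \,\}$$

over all hashes routed to it, where LZC is the leading-zero count of the
suffix as a $q$-bit string. Storing LZC + 1 keeps 0 unambiguous as "never
touched". Since LZC $\le 63$, register values fit in 6 bits, and a sketch
costs exactly $2^p$ bytes. Two properties make the structure composable:

* **Union homomorphism.** The sketch of $A \cup B$ is the element-wise
  maximum of the two register arrays — exactly, not approximately. Tests
  verify byte equality between "sketch of concatenated streams" and
  "max of per-stream sketches".
* **Order and duplicate invariance.** Registers only grow via max, so the
  sketch is a pure function of the input *set*.

## Estimators

Let $z = n/m$ be the unknown rate of distinct items per register. Under
the usual uniform-hash and Poisson assumptions, a register value $V$
satisfies $P(V \le v) = e^{-z\varphi(v)}$ with tail weight
$\varphi(v) = 2^{-v}$ for $0 \le v \le q$ and $\varphi(q{+}1) = 0$.

**Corrected harmonic mean.** The classical estimate
$E = \alpha m^2 / \sum_j 2^{-M_j}$ with $\alpha = 1/(2\ln 2)$, switching to
linear counting $m\ln(m/C_0)$ when $E \le 2.5m$ and some registers are
still empty ($C_0 > 0$). We keep $\alpha$ fixed at $1/(2\ln 2)$ rather
than the classical $m$-dependent corrections; at the default $m = 1024$
the difference is well below the estimator's standard error, and the fixed
constant is what the estimator here is defined to be. No large-range
correction is applied: with 64-bit hashes, hash collisions are irrelevant
at any cardinality this package targets.

**Maximum likelihood (default).** The register histogram
$C_0, \dots, C_{q+1}$ is multinomial with cell probabilities
$P_z(0) = e^{-z}$, $P_z(v) = e^{-z2^{-v}} - e^{-z2^{-(v-1)}}$,
$P_z(q{+}1) = 1 - e^{-z2^{-q}}$ (they telescope to 1). `estimate_mle()`
finds the root of the score $\mathrm{d}L/\mathrm{d}z$ with the secant
method, initialized from the harmonic-mean estimate. Numerical choices
that matter:

* the iteration runs in the reciprocal coordinate $x = 1/z$, where the
  score is nearly linear over the plausible range (for registers far from
  the transition zone the score is exactly of the form $Ax - B$), so the
  secant is Newton-quality from the first step;
* the second starting point is placed 0.1% from the first — wide enough
  that the divided difference is numerically clean, close enough that the
  first step is not wasted cancelling an arbitrary offset;
* every step is guarded by a sign-change bracket (bisection fallback), the
  stopping rule is a relative step below $10^{-9}$ with a hard cap of 64
  iterations, and the reported iteration count is the first update whose
  iterate lies within that tolerance of the converged value — the solver
  spends one further (counted internally, reported separately) update
  detecting that no motion remains;
* an empty sketch returns 0; a fully saturated sketch (every register at
  $q+1$) carries no finite information and returns `Inf` as an explicit
  sentinel rather than a silently huge number.

Across a census of 1000 simulated sketches (cardinalities $10^1$–$10^8$,
$p \in \{8,10,12,14,16\}$) the maximum iteration count observed is 3; the
test suite also checks the estimate against an independent golden-section
maximization of the same likelihood to $10^{-6}$ relative.

**Joint maximum likelihood.** For a pair of sketches, the registers are
modelled as a three-component Poisson mixture — rates
$\lambda_a/m, \lambda_b/m, \lambda_x/m$ for items unique to $A$, unique to
$B$, and shared. The joint CDF of a register pair is
$F(a,b) = \exp(-z_a\varphi(a) - z_b\varphi(b) - z_x\varphi(\min(a,b)))$,
the pmf its two-dimensional difference, and the likelihood is accumulated
over the tally of (value-in-A, value-in-B) pairs — an algebraic regrouping
of the per-register sum that the tests verify to $10^{-10}$.
`estimate_jmle()` maximizes by cyclic coordinate ascent (golden-section
line search per coordinate, shared-component first), initialized from
inclusion-exclusion of marginal MLEs, stopping when a full cycle moves
every coordinate by less than $10^{-6}$ relative (cap 100 cycles). This
estimates intersection cardinality *directly*; the alternative for the
marginal estimators is inclusion-exclusion
$\widehat{|A \cap B|} = \hat n_A + \hat n_B - \hat n_{A\cup B}$, floored
at 0 because the estimators are noisy and downstream ratios must stay in
$[0,1]$. Coordinate ascent rather than a quasi-Newton method is a
deliberate choice: each one-dimensional slice of this likelihood is
unimodal and cheap, boundary optima ($\lambda_a = 0$ for near-identical
inputs) are handled exactly, and the tests pin the result against a dense
3-D grid-refinement oracle to $10^{-3}$ relative.

## Baselines and the read filter

* **Bottom-k MinHash** keeps the $s$ smallest distinct hash values; the
  Jaccard estimate is the shared fraction of the bottom-$s$ of the union,
  and cardinalities come from the classic order-statistic estimator
  $(s-1) \cdot 2^{64} / v_s$. At 8 bytes per hash, $s = 2^p/8$ matches the
  byte budget of an HLL with $2^p$ registers.
* **Bloom filters** of $2^b$ bits with $h$ index functions (block
  rotations of one Wang hash). Cardinality estimates are either naive
  ($X/h$ set bits) or collision-aware
  ($-(2^b/h)\ln(1 - X/2^b)$, the inverted expected-occupancy map);
  pair cardinalities use the bitwise-OR union filter and
  inclusion-exclusion.
* **Count-min sketch** ($d \times w$ counters, conservative update — only
  rows at the current minimum are incremented) pre-filters sequencing
  reads: a k-mer enters the HLL only once its estimated count reaches
  `min_count`. Estimates are one-sided (never undercount), verified
  exhaustively against an exact counter on collision-heavy streams.
  Defaults $d = 4$, $w = 2^{20}$ hold count estimates for millions of
  distinct k-mers in 16 MB; `min_count = 1` disables the filter, the
  right default for assembled genomes.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `k` | 31 | k-mer length (1–32, so a 2-bit code fits one 64-bit word); 31 is the standard choice for genome-scale comparisons |
| `p` | 10 | log2 register count; the sketch is $2^p$ bytes. 1 kB gives ~3.2% cardinality RSE, accurate enough for genome triage |
| `canonical` | TRUE | treat a k-mer and its reverse complement as equal; strand-symmetric sketches |
| `estimator` | "mle" | "original", "mle", "jmle" — jmle is the most accurate for intersections and the slowest |
| `min_count` | 1 | count-min threshold for FASTQ input |

Non-ACGT characters (N, IUPAC ambiguity codes) abort the current window,
which restarts after the offending base — no masking or substitution, so
sketches are deterministic in the input bytes. Lowercase (soft-masked)
bases are uppercased: sketch content should not depend on a masking
convention.

## The synthetic benchmark

`accuracy_experiment()` reproduces the accuracy study design on synthetic
sets: pairs of random 64-bit integers with exact planted intersections,
fed through the same Wang-hash insert path as k-mers (uniform random
inputs make any further hashing ideal by construction). The generator
draws values as splitmix64 images of disjoint counter blocks — a 64-bit
bijection, so the block cardinalities and the intersection are exact with
no rejection step, and every trial is reproducible from its seed.

The default grid is the full study design: larger-set sizes
$2^{14}, 2^{18}, 2^{22}$, size ratios $2^0$–$2^{12}$ (powers of 8), and
target $J \in \{0.00022, 0.0465, 0.111, 0.33, 0.6, 0.818\}$, keeping the
36 feasible combinations (a set $c$ times larger than its partner caps
$J$ at $1/c$; `intersection_for_jaccard()` enforces the bound). Sketch
sizes are $2^{10}$–$2^{16}$ bytes for both HLL and MinHash; 100 trials
per cell, with per-trial seeds derived from one root seed.

Error is reported per cell, method and sketch size as mean |error|, mean
squared error, and the per-trial maximum. The headline summaries quoted in
the README are the **maximum over cells of the per-cell mean absolute
error**. The per-cell mean is the right unit for a "never exceeded"
statement about a results table: the per-trial maximum over thousands of
draws of a ~2%-sd estimator grows with the trial count and would bound no
implementation, whereas the per-cell mean is a stable property of the
estimator under the study conditions. Both statistics are in the output
for readers who want the other view.

What the synthetic harness does **not** emulate: real genomes share
repeated and low-complexity sequence, so their k-mer sets are not uniform
random draws; FASTQ error models, coverage bias and strand artefacts are
also out of scope. Passing the grid shows the estimators do their job on
ideal sets of known overlap; the exact hash-set mode (`exact_jaccard()`,
`--method exact`) exists precisely so users can spot-check sketch accuracy
on their own data.

Problem sizes used by the checked-in checks (chosen to keep the default
runs in the minutes range on one core): the test suite runs the 36-cell
grid at 40 trials per cell and a 250-sketch iteration census to $10^7$;
the acceptance script runs 100 trials per cell, the full 1000-sketch
census to $10^8$, and 500 trials of $10^6$ insertions for the standard
error constant.

## Interfaces

Everything is callable from R (`sketch_file()`, `pair_statistics()`,
`all_pairs()`, `accuracy_experiment()`, ...). A thin command-line front
end (`inst/cli/kmersketch`, or `cli_main()` from R) exposes the two-phase
workflow — `sketch` writes one binary sketch file per input
(`input.hll.k31.p10`; magic `"HLLS"`, version, p, k, flags, then the raw
registers, byte-exact round trip), `dist` compares sketch files and/or
sequence files (sequences are sketched in memory with numerically
identical results) and writes TSV or PHYLIP matrices. Every invocation is
a pure function of its arguments and input bytes; `--workers` changes wall
time only, never values or order (inputs are sketched largest-first
internally for load balance, which is unobservable in the output).

## Known limitations

* Cardinalities above ~$10^{15}$ approach the exact-representation limit
  of doubles in reports, well beyond any k-mer use.
* The JMLE costs roughly an order of magnitude more than the MLE per pair
  (tally plus three-coordinate ascent); `mle` is therefore the default.
* Bottom-k cardinalities (not Jaccard) are order-statistic estimates with
  higher variance than HLL's at matched size.
* Sparse-register representations for very small sets inside very large
  sketch arrays are not implemented; 5-bit register packing (values fit 6
  bits, and only 6 of 8 bits are used) is likewise left on the table.
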