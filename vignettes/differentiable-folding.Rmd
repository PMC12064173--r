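---
title: "Differentiable RNA folding: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differentiable RNA folding: models, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psifold)
```

This vignette is the package's account of the science it implements: the
thermodynamic model, the expected-partition dynamic program and its adjoint,
the numerical machinery (per-nucleotide scaling, gradient checkpointing),
and the two design applications — inverse folding toward a target secondary
structure and stability–CAI mRNA design. It also records the design choices
that were genuinely open, and what the test suite does and does not
establish.

## The ensemble model

A secondary structure $s$ on a sequence $\pi$ of length $n$ is a
non-crossing set of base pairs (AU, UA, CG, GC, GU, UG) in which every
hairpin loop encloses at least $\theta = 3$ unpaired nucleotides. The
Boltzmann ensemble assigns the structure weight
$e^{-E(s\mid\pi)/kT}$, and the partition function is

$$Z_\pi \;=\; \sum_{s \in \mathcal S(\pi)} e^{-E(s\mid\pi)/kT},$$

with the empty structure contributing weight 1, so $Z_\pi \ge 1$ and the
ensemble free energy $\mathrm{EFE} = -kT \log Z_\pi$ is non-positive. The
default $kT = 0.61633$ kcal/mol corresponds to 37&nbsp;°C.

$E(s\mid\pi)$ decomposes over loops in the nearest-neighbor fashion:

* **hairpins**: size-indexed initiation plus a terminal penalty (0.5
  kcal/mol by default) when the closing pair is not GC/CG;
* **stacks**: a directional table over ordered pairs of pairs;
* **bulge and internal loops**: size-indexed initiation (total unpaired
  size capped at 30; larger loops get weight zero) plus the terminal
  penalty on *both* closing pairs;
* **multiloops**: the affine model $a + b\cdot\text{branches} +
  c\cdot\text{unpaired}$, where branches counts the closing pair;
* **exterior loop**: zero cost.

Coaxial stacking, dangling ends, terminal mismatches and tetraloop bonuses
are deliberately out of scope. This keeps every loop term a function of its
size(s) and closing-pair identities only, which is what lets both the
brute-force oracle stay exact and the expected-partition tables below stay
small (no conditioning beyond interval endpoints is ever needed). Lonely
(isolated) pairs are allowed — prohibiting them is a plausible extension but
complicates the recursions without changing any tested property.

### Toy parameters

The shipped tables (also at `inst/extdata/params_toy.txt`) are chosen at
Turner-like magnitudes: hairpin initiation 5.4–6.4 kcal/mol for sizes 3–9,
stacks built additively from per-pair increments
($s(\mathrm{GC}) = -1.65$, $s(\mathrm{AU}) = -0.55$,
$s(\mathrm{GU}) = -0.35$; a stack costs the sum of its two pairs'
increments, which automatically satisfies the thermodynamic symmetry
$\Delta G(pq) = \Delta G(\bar q\bar p)$), bulges 2.8–4.4, internal loops
1.5–2.0, multiloop $(a,b,c) = (3.4, 0.4, 0)$. Initiation tables extend
beyond their largest tabulated size $m_0$ by the Jacobson–Stockmayer form
$E(m) = E(m_0) + 1.75\,kT \log(m/m_0)$. Parameters load from a plain
key–value text format (`read_energy_params()`); the ViennaRNA/Turner
`.par` dialect is intentionally not parsed.

## The expected partition function

A *sequence distribution* $\Psi$ is an $n \times 4$ row-stochastic matrix:
independent categorical distributions over $\{A, C, G, U\}$ per position.
The package computes, exactly,

$$Z_\Psi \;=\; \mathbb E_{\pi \sim \Psi}\!\left[Z_\pi\right]
 \;=\; \sum_{\pi} \Big(\prod_i \psi_i(\pi_i)\Big) Z_\pi,$$

a weighted sum over all $4^n$ sequences, not a sample average. The key
observation is that each loop weight touches at most the identities of its
closing pairs, so interior identities can be marginalized as soon as a
helix closes. The inside table therefore conditions on the nucleotide
identities at its interval endpoints:
$\hat Z^b_{i,j}(a,b)$ is the expected weight of the ensemble inside
$[i, j]$ given that $(i, j)$ pair with identities $(a, b)$, a $4\times4$
block per cell. Four auxiliary scalar tables carry everything else:

* $\hat Z^{bm}_{i,j} = \sum_{a,b}\psi_i(a)\psi_j(b)\hat Z^b_{i,j}(a,b)$
  (a closed helix with its endpoint probabilities folded in — usable by
  multiloops and the exterior, because no excluded energy term looks back
  inside);
* $\hat Z^{bau}$, the same with the terminal-penalty factor, consumed by
  internal/bulge closings;
* $\hat Z^{m1}, \hat Z^m$, the standard one-branch / at-least-one-branch
  multiloop accumulators (scalars, since branch identities are already
  marginalized).

The stack term is the only place two $4\times4$ blocks couple (a
$16\times16$ contraction through the stack table). Complexity is
$O(n^2(n + c^2 + 256))$ with $c$ the internal-loop cap; internal loops use
the straightforward double loop over left/right sizes up to the cap, which
is the reference implementation any optimized variant must reproduce to
$10^{-10}$ relative. A one-hot $\Psi$ reproduces the discrete partition
function exactly; the package also ships an independent discrete McCaskill
kernel, so that equivalence is a genuine cross-check rather than a
tautology.

### Per-nucleotide scaling

Partition values grow exponentially in $n$ and overflow doubles near
$\log Z \approx 709$. Rather than computing in log-space — where addition
must be approximated, and the gradient of the approximation is not an
approximation of the gradient — every table entry spanning $\ell$
nucleotides is stored multiplied by $s^{-\ell}$ for a scale constant $s$,
and $n \log s$ is added back to the reported $\log Z$. Results are
independent of $s$ to machine precision (a tested invariant); a good choice
for long sequences is $s \approx e^{\log Z / n}$, and the constant is
exposed as a parameter because no single schedule suits every input.

### Exact gradients and checkpointing

$Z_\Psi$ is multilinear in the rows of $\Psi$ (another tested invariant),
and `expected_partition(grad = TRUE)` returns the exact gradient
$\partial \log Z_\Psi / \partial \Psi$ via a hand-written reverse-mode
adjoint of the dynamic program, validated entrywise against central finite
differences. One convention matters: positions that no energy term touches
(for example every position when $n < \theta + 2$) never enter the
computation — their simplex normalization is implicit — so their partials
are exactly zero, and at $n = 4$ the gradient of $\log Z \equiv 0$ is the
zero matrix. Callers optimize through a row-wise softmax, which is
insensitive to this convention (it annihilates constant row shifts).

The backward pass needs the forward tables. Storing all of them costs
$O(n^2)$ blocks; instead, the scalar tables are always kept (they are
small) and the $4\times4$ inside tables are retained only every
$k$-th anti-diagonal per parity chain (the stack recursion couples span
$L$ to span $L-2$), then replayed segment-wise on demand during the
backward sweep. Because bulge/internal and multiloop terms route through
the retained scalars, a single previous diagonal suffices to recompute the
next — the textbook chain-checkpointing setting. Caller-visible values are
identical for every `checkpoint_every` (tested to $10^{-8}$ relative,
observed exact); only the memory/recompute trade-off moves, with
$k \approx \sqrt n$ the balanced choice.

## Structure design

The design score of $\Psi$ for a target structure $s$ is the ratio of
expectations

$$p(s, \Psi) \;=\;
\frac{\mathbb E_\Psi\!\left[e^{-E(s\mid\pi)/kT}\right]}
     {\mathbb E_\Psi\!\left[Z_\pi\right]} \;\in\; [0, 1],$$

and the loss is $-\log p$. The exact form of a distribution-level target
objective is a convention; this one is pinned by its one-hot limit, where
it is exactly the Boltzmann probability of $s$ for that discrete sequence —
the quantity the field reports. The numerator factorizes over the
structure's helix tree (positions are independent and only closing-pair
identities carry energy), and its gradient comes from one upward and one
downward message-passing sweep with $4\times4$ messages.

`optimize_direct()` runs Adam (defaults: 500 steps, learning rate 0.05; no
optimizer is prescribed by the problem, so these are exposed flags) on an
unconstrained logits matrix mapped to $\Psi$ by row-wise softmax, starting
from the uniform distribution plus a small seeded jitter
($\sigma = 0.01$) that breaks the symmetry of the uniform start.
`optimize_generator()` instead trains the weights of a fully connected
network (fixed 16-dimensional input vector drawn once from the seed, two
tanh hidden layers of 64 units, linear $4n$ output; architecture is a
flag) whose output logits produce $\Psi$ — overparameterization as a tool
against the non-convex design landscape, with gradients flowing end-to-end
through the folding DP and the network. Both paths return the
*best* iterate, and the reported probability is recomputed from the decoded
discrete sequence (per-position argmax, ties toward A < C < G < U) with the
discrete kernel — never from $\Psi$.

On the 11-nucleotide single-stem hairpin the direct path reaches
$p > 0.99$; both paths find all-GC stems whose probabilities differ only in
the fifth decimal (distinct but energetically equivalent solutions). Such
probabilities are meaningfully reported to three decimals, so the test
suite counts two designs within $10^{-3}$ as tied when comparing the
generator against the direct path across seeds.

## mRNA design

For a protein of length $L$ the design variable is the full
$3L \times 4$ nucleotide-level $\Psi$ (the partition function operates at
nucleotide level; a codon-level parameterization is a non-goal). Three
smooth functionals combine:

* **coding probability** $P_{\mathrm{code}}(\Psi) = \prod_k \sum_{c \,:\,
  \mathrm{code}(c) = a_k} p_k(c)$, where $p_k$ is the induced marginal over
  the 64 codons at codon position $k$ (a product of three $\Psi$ rows);
* **expected CAI**: the classical codon adaptation index — the geometric
  mean of relative adaptiveness weights $w$ — is undefined for continuous
  sequences. The package defines
  $$\widehat{\mathrm{CAI}}(\Psi) = \prod_k
    \frac{\sum_{c\,\sim\,a_k} p_k(c)\, w(c)^{1/L}}
         {\sum_{c\,\sim\,a_k} p_k(c)},$$
  the product over codon positions of the conditional expectation of the
  per-codon CAI factor given coding. Among the plausible generalizations
  (conditional vs unconditional, arithmetic vs geometric aggregation) this
  one was chosen because it factorizes position-wise (an $O(64L)$
  evaluation with closed-form gradients) and reduces *exactly* to the
  classical CAI at every one-hot coding $\Psi$ — the limit that any
  convention must respect, and the contract the tests enforce;
* **stability**: $\mathrm{EFE}(\Psi) = -kT\log Z_\Psi$.

The loss is
$$\mathrm{EFE}(\Psi)
 + \lambda_{\mathrm{cai}} \max(0,\; \mathrm{floor} - \widehat{\mathrm{CAI}})^2
 - \lambda_{\mathrm{code}} \log P_{\mathrm{code}},$$
with defaults $\lambda_{\mathrm{cai}} = 100\,kT$ and
$\lambda_{\mathrm{code}} = 10\,kT$, scale-matched to the free-energy term.
The CAI constraint is a squared hinge rather than a hard constraint (smooth,
inactive once satisfied); the coding term enters as a log because it is the
natural barrier keeping mass on coding support and vanishes exactly at a
coding one-hot, so a warm start's loss is exactly its EFE.

Warm starts embed a known coding sequence as a near-one-hot $\Psi$ with
$\varepsilon = 10^{-3}$ off-mass per nucleotide (keeping gradients finite
off the simplex vertex; $\varepsilon = 0$ is allowed with a warning).
Every iterate is decoded with `decode_coding()` — per-codon argmax
restricted to synonymous codons, so the output *always* translates to the
target protein — and scored by its discrete EFE and classical CAI. The
reported design is selected lexicographically: iterates whose decoded CAI
meets the floor, then minimum decoded EFE, then (among EFE ties, which are
iterates decoding to the same sequence) the highest coding probability.
With a floor-satisfying warm start the initial iterate is always a
candidate, so the reported EFE can never exceed the warm start's — the
"single initialization, never worse" property — while the tie-break favors
late, concentrated iterates whose coding probability approaches 1.

Two behaviors of the continuous formulation at toy scale are worth
knowing. First, because $Z_\Psi$ is an expectation, probability mass on
*non-coding* high-$Z$ neighbors raises $Z_\Psi$; mass therefore leaks until
the coding log-barrier balances, and in basins where the best coding
sequence folds weakly the equilibrium coding probability can settle a few
percent below 1 under the default $\lambda_{\mathrm{code}}$. Second, a
warm start whose CAI is below the floor makes "never worsen the EFE" and
"meet the floor" jointly unattainable in principle; a CAI-constrained run
should be seeded with a sequence that already satisfies the constraint
(as a constraint-respecting reference solution would be), for which
`random_coding_sequence(min_cai = )` provides a deterministic generator.

## Oracles, fixtures and what the tests show

Every DP answer is anchored to an independent brute force:
`enumerate_structures()` (recursion on the last position, mirroring the
counting recurrence $f(m) = f(m-1) + \sum_k f(k-1)f(m-k-1)$, which is also
tested against it for all $n \le 14$), `brute_partition()` (full structure
enumeration, $n \lesssim 14$), `brute_expected_partition()` (all $4^n$
sequences, $n \le 8$), and entrywise central finite differences for every
gradient. Deterministic fixtures (`make_fixture()`) supply random
sequences, random distributions, near-one-hot embeddings and hairpin
targets; the same (kind, n, seed) always reproduces the same bytes.

Problem sizes used by the default suite: oracle equivalence at $n \le 12$
(structures) and $n \le 7$ (sequences); one-hot consistency to $n = 60$;
gradient checks at $n \le 15$; scale/checkpoint invariance at
$n \in \{30, 100\}$; design at $n = 11$ (500 steps, 10 seeds) and a
5-residue peptide (300 steps). These sizes make the full enumeration exact
and keep the suite at desk scale; the kernels themselves handle several
hundred nucleotides (forward $n = 400$ in seconds).

The synthetic generator emulates the *mathematical* study conditions —
independent per-position distributions, uniform random sequences, toy
energies — not real data: no Turner 2004 parameters, no mismatch/dangle
terms, no natural codon-usage tables, no experimentally determined
structures. Passing tests therefore establish algorithmic correctness
(DP = enumeration, adjoint = derivative, invariances hold, design
optimizers reach their documented optima on toy targets), not predictive
accuracy on biological RNA.

## Known limitations

* The energy model excludes mismatch-, dangle- and coaxial-stacking terms;
  absolute free energies are not comparable to Turner-parameter tools.
* Design scales: the expected-partition gradient is $O(n^3)$ time per step
  in this implementation, comfortable to a few hundred nucleotides, and the
  mRNA path evaluates a discrete fold per iterate for its honesty
  guarantees ($O(n^3)$ each), which dominates for long proteins.
* Pseudoknots, base-pair probability matrices, minimum-free-energy
  structures and suboptimal sampling are out of scope.
* The expected-CAI definition is one of several defensible generalizations;
  only its one-hot limit is canonical.
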