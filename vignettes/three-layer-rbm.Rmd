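---
title: "A three-layer RBM wavefunction solver for molecular qubit Hamiltonians"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A three-layer RBM wavefunction solver for molecular qubit Hamiltonians}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbmqs)
```

## The model

`rbmqs` computes ground-state energies of small electronic-structure
Hamiltonians with a neural-network trial wavefunction.  The pipeline is

1. one- and two-electron integrals (FCIDUMP) → second-quantized Hamiltonian,
   optionally reduced to an active space;
2. Jordan–Wigner transformation → a qubit Hamiltonian
   $H = \sum_t c_t\, P_t$, each $P_t$ a tensor product of Pauli operators,
   one qubit per spin orbital;
3. variational minimization of $\langle H\rangle$ over a restricted
   Boltzmann machine (RBM) ansatz with an extra sign layer.

A basis state is written as spins $\sigma_i \in \{-1,+1\}$, one per qubit,
with $\sigma_i = +1$ meaning qubit $i$ in $|1\rangle$ (orbital occupied).
The wavefunction coefficient at $x = (\sigma_1,\dots,\sigma_n)$ is

$$\psi(x) = \sqrt{\tilde P(x)}\; s(x), \qquad
\tilde P(x) = e^{\sum_i a_i\sigma_i}\prod_{j=1}^m
  2\cosh\Big(b_j + \sum_i w_{ij}\sigma_i\Big),$$

the closed-form marginalization of the hidden layer, and

$$s(x) = \tanh\Big(\sum_i d_i\sigma_i + c\Big)$$

is the sign layer.  An RBM amplitude alone is non-negative, which cannot
represent the sign structure of fermionic ground states; $s(x)$ supplies the
sign as a smooth multiplicative factor in $(-1,1)$ — we use the smooth value
rather than thresholding it to $\pm 1$, consistent with the weight
$|\phi(x)s(x)|^2$ in the energy functional.  Trainable parameters are
$(a, b, w, d, c)$: $nm + 2n + m + 1$ real numbers.

The objective is the Rayleigh quotient

$$\langle H\rangle
  = \frac{\sum_{x,x'} \psi(x)\,\langle x|H|x'\rangle\,\psi(x')}
         {\sum_x \psi(x)^2} \;\ge\; E_0,$$

so every iterate upper-bounds the true ground energy $E_0$ (in exact
enumeration mode; the sampled estimator is noisy and can dip below, see
below).  Gradients use the local energy
$E_{loc}(x) = \langle x|H|\psi\rangle/\psi(x)$ and the log-derivatives
$D_{p_k}(x) = \partial_{p_k}\log(\sqrt{\tilde P(x)}\,s(x))$:

$$\partial_{p_k}\langle H\rangle
  = 2\left(\langle E_{loc} D_{p_k}\rangle
     - \langle E_{loc}\rangle\langle D_{p_k}\rangle\right),$$

with expectations under weights $\propto \tilde P(x)\,s(x)^2$.  Training is
plain constant-rate gradient descent (learning rate 0.01 by default, the
value that is small enough to avoid overshooting the narrow tanh-sign
valleys); the optimizer is deliberately minimal and pluggable.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `m` | `2 * n_qubits` | hidden units; more hidden units enlarge the amplitude family |
| `learning_rate` | 0.01 | constant gradient-descent step (Hartree-free) |
| `iterations` | 20000 exact / 2000 sampled | optimization budget |
| `samples_per_iteration` | 2000 | accepted samples per step (sampled mode) |
| `init_range` | 0.02 | uniform initialization half-width; keeps tanh away from its vanishing-gradient regime |
| `k` | `max(1, sum(abs(w)))` | sampler flattening constant, recomputed each iteration |
| `restarts` | 1 (3 in the recovery tests) | independent seeds, keep the lowest minimum (local-minimum guard) |

The reported observable of a run is the *minimum* energy over all
iterations, not the final iterate.

## The quantum Gibbs sampler, simulated classically

Sampled mode estimates the visible distribution from a simulation of a
two-register controlled-rotation circuit.  The joint law over
$y = (\sigma, h)$ is the RBM Gibbs distribution
$P(y) \propto e^{E(y)}$ with
$E(y) = \sum_i a_i\sigma_i + \sum_j b_j h_j + \sum_{ij} w_{ij}\sigma_i h_j$.
The circuit samples the flattened law $Q(y) \propto P(y)^{1/k}$:

* single-qubit rotations $\theta_i = 2\arcsin\sqrt{e^{a_i/k}/(e^{a_i/k} +
  e^{-a_i/k})}$ (and $\gamma_j$ for hidden units) prepare the independent
  product law $O(y)$;
* per coupling $(i,j)$ an ancilla is rotated and measured; it succeeds with
  probability $e^{(w_{ij}\sigma_i h_j - |w_{ij}|)/k}$, and the first failure
  restarts the whole attempt;
* accepted configurations therefore occur with probability $\propto Q(y)$;
  raising the accepted frequencies to the power $k$ and normalizing recovers
  $P(y)$ exactly (an algebraic identity, checked to $10^{-12}$ in the tests).

The simulation draws the measurement statistics directly (independent
Bernoullis plus the product acceptance probability), which has exactly the
same output law as a state-vector simulation followed by projective ancilla
measurements, at $O(nm)$ cost per attempt.  The acceptance probability is
bounded below by $e^{-2\sum_{ij}|w_{ij}|/k}$, so the automatic choice
$k = \sum_{ij}|w_{ij}|$ (floored at 1 for the early-training regime where
all couplings are tiny) guarantees a rate of at least $e^{-2}\approx 0.135$.
No schedule for $k$ beyond this recomputation is imposed; the multiplier is
configurable.

Power-$k$ recovery on finite samples is biased for rare configurations:
frequencies estimated with relative error $\varepsilon$ are distorted to
$k\varepsilon$ after exponentiation, and never-observed states get
probability zero.  The batch object reports an effective-sample-size
diagnostic, and exact enumeration is always the reference.

## Numerical choices

* **Log-space amplitudes.**  $\cosh$ overflows for arguments beyond ~350;
  all amplitude arithmetic is on $\log\tilde P$, with signs carried
  separately.  Ratios $\psi(x')/\psi(x)$ exponentiate differences.
* **Sign floor.**  States with $|s(x)| \le 10^{-12}$ are excluded from all
  weighted averages: their weight vanishes quadratically while $E_{loc}$
  and $D$ divide by $s$.  Exclusions are logged per iteration
  (`n_effective`); a single surviving state yields a zero covariance
  gradient rather than an abort.
* **Basis encoding.**  $\sigma_i = +1 \leftrightarrow |1\rangle$, so
  $\langle x|Z_i|x\rangle = -\sigma_i$; qubit 0 is the most significant bit
  of the state index.  Declared once and used everywhere (files, tables,
  matrices).
* **Real Hamiltonians only.**  A Pauli term with an odd number of Y factors
  has imaginary matrix elements in the computational basis; such terms are
  rejected at load time because the real-amplitude ansatz cannot represent
  complex ground states.  Jordan–Wigner output is verified real after
  simplification (coefficients below $10^{-12}$ dropped, imaginary residues
  above $10^{-10}$ are an error).
* **Diagonalization oracle.**  Dense symmetric `eigen()` up to 10 qubits, a
  Lanczos iteration with full reorthogonalization on the sparse matrix up
  to the 14-qubit cap.  The cap is a desk-scale resource guard, not a hard
  algorithmic limit.
* **Frozen core.**  The textbook construction: the constant absorbs
  $\sum_f 2h_{ff} + \sum_{ff'}(2(ff|f'f') - (ff'|f'f))$ and active
  one-electron integrals gain the frozen mean field.  Correctness is
  defined by a constrained-diagonalization oracle in the tests (the reduced
  spectrum must equal the full Fock-space spectrum restricted to
  determinants with frozen orbitals doubly occupied), not by formula
  citation.

## What the synthetic generator emulates — and what it does not

`generate_fixture()` draws random few-body Pauli strings (defaults: `2 n`
terms, locality ≤ 2, coefficients uniform on $(-1,1)$ Hartree, even Y
count).  This reproduces the *shape* of Jordan–Wigner electronic
Hamiltonians — few-body real Pauli terms of mixed sign at the Hartree scale
— but not their physics: no particle-number structure, no two-determinant
dominance, no geometry dependence.

One consequence matters for testing: the sign layer is a *linear threshold*
function of the spins, so the ansatz can only represent ground states whose
sign pattern is linearly separable in $\sigma$.  Random Pauli fixtures can
violate this (a 3-qubit example with a provably non-separable sign pattern
appears at generator seed 42), in which case no amount of training reaches
the exact energy.  The ground-state recovery tests therefore use fixtures
whose exact sign pattern is separable — verified by a perceptron
feasibility check, not by training — plus a synthetic hydrogen-molecule-like
4-qubit Hamiltonian (`inst/extdata/h2_sto3g_like_synthetic.fcidump`, toy
STO-3G-scale integrals, *not* published reference data) whose
two-determinant ground state mirrors the molecular setting the method was
designed for.  Passing these tests shows the optimizer recovers energies
*within the representable family*; it does not certify arbitrary
Hamiltonians, and the linear sign layer is the model's main known
limitation.

## Transfer learning along a scan

A potential-energy-surface scan is an ordered list of Hamiltonians.  With
transfer on, point $i>1$ starts from the best parameters of point $i-1$ and
runs for $\lceil \text{iterations}/40\rceil$ steps.  The protocol's premise
is that adjacent points are small perturbations of each other; the test
family $H(\lambda) = -\lambda Z_0 - (1-\lambda) X_0$ uses
$\lambda = 0.40, 0.45, \dots, 0.60$ (closed-form ground energy
$-\sqrt{\lambda^2 + (1-\lambda)^2}$), a step size chosen to honour that
premise — with jumps of 0.2 in $\lambda$ the warm-started budget can no
longer track the rotating ground state and the protocol degrades, which is
the expected failure mode rather than a defect.

## Problem sizes used in the test suite

Oracle-equivalence checks run 100 random Hamiltonian/parameter pairs up to
4 qubits and Jordan–Wigner comparisons up to 3 spatial orbitals (64-dim
Fock spaces); gradient checks use 100 random points against central finite
differences ($h = 10^{-6}$); sampler checks use $10^5$ accepted samples for
the total-variation comparison and 50 random models for the acceptance
bound; recovery runs use 20000 exact-mode iterations with 3 restarts and
2000 sampled-mode iterations at 2000 samples per iteration.  These sizes
were chosen so the whole suite exercises every oracle at high precision on
a single desk-class core.

## Known limitations

* The sign layer is a linear classifier over spins (see above).
* Plain gradient descent can be trapped by local minima; the multi-seed
  restart is a guard, not a cure.
* Sampled-mode energies are noisy estimators; their minimum over iterations
  is biased slightly low (a few mHa at the tested sizes).
* The spin-symmetry two-qubit reduction used by some references for water
  is not implemented; active-space freezing/discarding is the only
  reduction.
* Integrals are consumed, never computed: geometry → FCIDUMP is upstream of
  this package.
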