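---
title: "Nuclear-spin-bath echo decoherence: model, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nuclear-spin-bath echo decoherence: model, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ccecho)
```

## The physical model

`ccecho` treats one electron spin-1/2 surrounded by a bath of proton
spins-1/2 in a strong static field.  Within each electron projection
$m_S = \pm 1/2$ the nuclei evolve under the conditional Hamiltonians

$$
H_\pm \;=\; \sum_n \Big[ -\omega_I I_z^n \pm \tfrac12 \big(A_{zz}^n I_z^n
          + A_{zx}^n I_x^n + A_{zy}^n I_y^n\big) \Big]
        \;+\; \sum_{m<n} b_{mn}\big(I_+^m I_-^n + I_-^m I_+^n
          - 4 I_z^m I_z^n\big),
$$

with $\omega_I = \gamma_H B_0$ the proton Zeeman frequency (143.9 MHz at
the default 3.38 T).  All couplings are geometric: the hyperfine
components come from the point-dipole interaction with the electron
($A_{zz} = D(3\cos^2\theta - 1)$, pseudo-secular magnitude
$3D|\sin\theta\cos\theta|$, $D = (\mu_0/4\pi)\gamma_e\gamma_H\hbar/r^3$,
Fermi-contact part zero), and $b_{mn} =
(\mu_0/4\pi)\gamma_H^2\hbar(3\cos^2\theta_{mn}-1)/(4 r_{mn}^3)$ is fixed
by requiring that $b(I_+I_- + I_-I_+ - 4I_zI_z)$ reproduce the truncated
homonuclear dipolar Hamiltonian (the same normalization that gives the
familiar 46 kHz rigid-pair splitting of gypsum water).  There are no
relaxation terms: the echo decay that emerges is fully coherent,
driven entirely by nuclear flip-flops whose energy cost is the hyperfine
difference $\omega_{mn} = (A_m - A_n)/2$.

Pulses are ideal, instantaneous and electron-only; the initial state is
the high-temperature one (electron polarization, maximally mixed
nuclei).  Under these assumptions the echo amplitude of a cluster is the
coherence-pathway overlap

$$
V = 2^{-N}\,\mathrm{Re}\,\mathrm{Tr}\big[W_A W_B^\dagger\big],
$$

with branch propagators assembled from $U_\pm(t) = e^{-iH_\pm t}$ for the
Hahn ($\pi/2-\tau-\pi-\tau$) and refocused
($\pi/2-\tau_1-\pi-(\tau_1{+}\tau_2)-\pi-\tau_2$) sequences.  The package
carries an independent brute-force oracle (`exact_oracle()`): explicit
density-matrix propagation through the pulse sequence on the full
$2^{N+1}$-dimensional space, with explicit electron rotations.  The test
suite holds the two routes together to $10^{-10}$, which is the basis for
trusting everything built on the trace formula.

A point worth recording: with only secular hyperfine plus flip-flop terms
the refocused echo is exactly symmetric under
$\tau_1 \leftrightarrow \tau_2$ (the suite verifies this to $10^{-10}$).
The pseudo-secular extension breaks that symmetry weakly — the deviation
grows with the square of the pseudo-secular couplings, an ESEEM-type
cross term, and stays below $10^{-4}$ for realistic clusters.  Both
behaviours are asserted in the acceptance tests; claims of exact
symmetry refer to the secular model.

## Cluster-correlation expansion

The bath signal is factorized over clusters,
$V = \prod_C \tilde V_C$ with
$\tilde V_C = V_C / \prod_{C'\subsetneq C}\tilde V_{C'}$, which is exact
when all subsets are included and is truncated at cluster size $k$
(k-CCE).  Clusters are read off a coupling graph whose edges are proton
pairs with $|b_{mn}|/2\pi$ at or above a threshold (default 1.58 kHz); a
cluster is retained when it is *connected* in that graph.  The stricter
reading — every intra-cluster pair above threshold — is available as
`rule = "all_pairs"`; connectivity is the default because it is the only
rule that scales naturally to clusters of size 3 and 4 and is standard
CCE practice.  The decay itself is nearly insensitive to the threshold
choice here: weak pairs are either far from the electron (small
hyperfine difference, already included via strong edges) or deep in the
frozen core where flip-flops are quenched.

Sub-clusters missing from the list (for example a below-threshold pair
inside a connected triple) contribute a correlation factor of 1.  Where a
$\tilde V$ denominator magnitude falls below `guard` ($10^{-6}$) the
factor is set to 1 at that grid point; such points lie deep in the
decayed region, and the acceptance runs never trigger the guard.

Convergence follows the expected pattern, asserted in the suite on a
scaled bath: 1-CCE (no nucleus-nucleus couplings) shows no decay at all,
only shallow pseudo-secular ESEEM; 2-CCE produces the decay; 3-CCE
compresses it visibly along the $\tau_1=\tau_2$ diagonal, where the pair
exponent vanishes and pair contributions are only fourth order in $b$,
so three-spin terms enter at the leading surviving order; 4-CCE changes
the 3-CCE diagonal by less than 0.06 at the probe points.  Production
simulations therefore use 3-CCE; quick exploration is fine at 2-CCE.

Powder averaging uses Lebedev grids (orders 6, 14, 26; default 14 —
adequate because the orientation dependence of the powder-averaged decay
is smooth).  Orientation-dependent excitation efficiency of rectangular
pulses is available through `excitation_weights()`, but the default is
ideal (uniform) weighting: the resonance-offset model of a specific
radical requires g/A tensors that are deliberately outside the bath
model.

## The synthetic bath: what it emulates and what it does not

`generate_bath()` stands in for a solvated-radical snapshot.  Its
defaults are the study conditions: proton density 0.0668 per cubic
angstrom (pure water; water/glycerol 80:20 differs negligibly), a 12 A
cutoff around the electron, a 2.5 A electron exclusion radius and a
1.5 A proton hard-sphere minimum.  Partial protonation thins protons
independently (deuterons are removed, not simulated: their flip-flop
couplings are ~40x weaker, a documented limitation).

One structural feature of a molecular solvent is kept, because the decay
depends on it: protons arrive in covalently bound *geminal pairs* (H-O-H,
H-C-H) at fixed short separation, 1.51 A for water.  The modulation depth
of a pair scales as $(2b_{mn}/\omega_{mn})^2$ and $b \propto 1/r_{HH}^3$,
so the closest pairs dominate the decay, and a structureless uniform
gas of protons at the same density systematically underestimates it.
The generator therefore places geminal pairs (uniformly positioned and
oriented) by default; `pair_fraction = 0` gives the plain uniform bath
for comparison.  Features deliberately *not* modelled: hydrogen-bond
network orientation correlations, the distinct glycerol H-H distances,
the radical's own protons, and the frozen-glass disorder of a real
molecular-dynamics snapshot.  Passing tests on this generator
demonstrate the decoherence mechanism and the decay-map phenomenology;
they do not certify agreement with any particular measured sample, and
the simulated phase-memory time at the default conditions
(about 4.3 microseconds at 3-CCE, stretch exponent about 2.7, as
recomputed by `scripts/acceptance.R`) should be read with that gap in
mind.

## Linked-cluster analytics

For the secular pair model, the lowest-order term of the refocused echo
in the nucleus-nucleus couplings is

$$
\langle V_2\rangle = -\sum_{m\neq n}
\frac{2 b_{mn}^2}{\omega_{mn}^2}
\big(\cos\omega_{mn}\tau_1 - \cos\omega_{mn}\tau_2\big)^2 ,
$$

an ordered-pair sum; degenerate pairs ($\omega_{mn}=0$) contribute zero,
their continuous limit.  Whether the printed sum is over ordered or
unordered pairs is fixed empirically, not by convention: the suite
requires $\ln V \to \langle V_2\rangle$ for a single pair as
$b \to 0$ with the error shrinking faster than $b^2$, and only the
ordered sum passes.  `factorize()` then splits any echo map as
$V = e^{\langle V_2\rangle} f$; since
$\langle V_2\rangle \le 0$ with equality on the diagonal, $e^{-\langle
V_2\rangle} \ge 1$ and the residual $f$ (all higher orders) is computed
without division hazards.  $e^{\langle V_2\rangle}$ carries the
dynamical-decoupling ridge structure; $f$ carries the decay along the
total evolution time.  The balance of the two — decoupling gain rising
with $\tau_1$ against total-time loss — is what places the optimal
$\tau_1$ strictly between 0 and $\tau_2$ once $\tau_2$ is long enough.

## Decay-map analysis choices

* **Ridge**: per $\tau_2$ slice, the discrete argmax over $\tau_1$ with
  three-point parabolic refinement (exact for a locally parabolic peak);
  ties break toward smaller $\tau_1$; an all-flat slice returns
  $\tau_1^* = 0$ with a `"flat"` flag; boundary maxima are flagged and
  not refined.
* **Deviation onset**: the smallest $\tau_2$ from which
  $\tau_2 - \tau_1^*$ exceeds a tolerance *persistently* (through the end
  of the grid).  The default tolerance is one $\tau_1$ grid step; the
  persistence rule makes the onset robust to ESEEM wiggles in the ridge.
  No persistent deviation returns `NA` ("none").
* **Stretched-exponential fits** use the total evolution time ($t=2\tau$
  for a two-pulse decay — the `echo_trace` method applies the factor
  automatically) with deterministic multi-start initialization
  ($x_0 \in \{0.8, 1.5, 2.5\}$, $T_M$ from the 1/e crossing) and
  box-constrained Levenberg-Marquardt ($0.05 \le x \le 4$).
  Uncertainties come from the curvature of the least-squares objective.

## Problem sizes and determinism

The shipped tests and the acceptance script run on deliberately scaled
problems, chosen as the smallest sizes that still exercise every claim:
oracle equivalences on 3-5-proton baths over a 20 x 20 delay grid;
decay maps for a >= 300-proton bath (11 A cutoff) at 2-CCE on 16 x 16
and 3-CCE on 12 x 12 grids; the acceptance simulation on full 12 A baths
(about 480 protons) with 40 Hahn delays and three seeds.  Every random
draw flows through an explicit seed (baths save theirs; fits are
deterministic), and bath generation restores the caller's RNG state, so
identical commands reproduce identical files.

## Known limitations

* Point-dipole hyperfine with zero contact term; no DFT-derived tensors.
* Ideal pulses: no finite-pulse evolution, no instantaneous diffusion,
  no electron or nuclear $T_1$; the coherent decay is the only mechanism.
* Spin-1/2 bath only; deuteration = removal.
* The synthetic bath reproduces density and geminal pairing, not full
  molecular structure; absolute timescales for real samples inherit that
  approximation.
* `exact_oracle()` is exponential in bath size and practical to ~10
  protons; it is a verification tool, not a production path.
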