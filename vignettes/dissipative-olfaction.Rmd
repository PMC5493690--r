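---
title: "Dissipative inelastic electron tunneling rates for odorant recognition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissipative inelastic electron tunneling rates for odorant recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(odortunnel)
```

## The model

The vibrational theory of olfaction proposes that an olfactory receptor fires
when an electron tunnels from a donor to an acceptor site *inelastically*,
dumping the donor–acceptor energy gap into a vibrational transition of the
bound odorant. `odortunnel` implements the dissipative version of this model
in which the odorant vibration is not a harmonic mode but the *contorsional*
mode of a non-planar molecule: an atom group oscillating between the two wells
of an asymmetric double-well potential. Truncated to its lowest doublet, the
mode is a two-level system spanned by the localised handed states $|L\rangle$,
$|R\rangle$,

$$H_{od} = -\omega_z \sigma_z + \omega_x \sigma_x,$$

with $\omega_x$ the tunneling frequency (inter-well conversion) and
$\omega_z$ the asymmetry frequency (the net bias from chiral interactions
with the receptor). Its eigenstates are rotated from the handed basis by the
mixing angle $\theta = \tfrac12\arctan(\omega_x/\omega_z)$. For chiral
odorants the two handed states are the two enantiomeric configurations, which
is what lets the model address enantiomer discrimination.

The electron is a two-site system (donor energy $\varepsilon_D$, acceptor
$\varepsilon_A$, gap $\varepsilon$, hopping $\Delta$), coupled to the odorant
through $\gamma_D$, $\gamma_A$ and to a harmonic bath representing the
receptor protein and solvent. A polaron transformation diagonalises the
unperturbed problem, leaving shifted site energies

$$\eta_{A} = -\tfrac{\omega_z}{2}\cos\!\Big\{\arctan\tfrac{\omega_x+\gamma_A}{\omega_z}\Big\},
\qquad
\eta_{D} = -\tfrac{\omega_z}{2}\cos\!\Big\{\arctan\tfrac{\omega_x-\gamma_D}{\omega_z}\Big\},$$

and a dressed mixing angle
$\upsilon = \tfrac12[\arctan\tfrac{\omega_x+\gamma_A}{\omega_z} +
\arctan\tfrac{\omega_x-\gamma_D}{\omega_z}]$. Second-order perturbation
theory in $\Delta$, a stationary bath, and the Markov limit give transfer
rates of Marcus form. The elastic channel (odorant untouched) is

$$\Gamma_{el} = \Delta^2\sqrt{\frac{\pi}{k_BT\,E_r}}\,
  \exp\Big\{-\frac{(\varepsilon-E_r)^2}{4 k_BT\, E_r}\Big\},$$

with $E_r = \int_0^\infty J(\omega)/\omega\, d\omega$ the bath reorganization
energy ($E_r = J_0\lambda$ for the default spectrum). Each inelastic channel
($|L\rangle\to|E_2\rangle$, $|R\rangle\to|E_2\rangle$,
$|E_1\rangle\to|E_2\rangle$, and the high-pressure flip
$|R\rangle\to|L\rangle$) is a trigonometric combination in $\theta,\upsilon$
of the same Gaussian with its argument shifted by $\pm(\eta_D-\eta_A)$ or
$\pm(\eta_A+\eta_D)$; `closed_form_rate()` evaluates them from a per-channel
kernel decomposition, and the test suite checks that decomposition against a
literal term-by-term transcription of the formulas.

## Units and conventions

All energies are ordinary frequencies in Hz ($\hbar = 1$): the thermal energy
enters as $k_BT/h$ using the Planck (not reduced) constant, and times in the
dynamical integrals are conjugate to frequencies in Hz (phases $x\,t$, no
$2\pi$). This convention reproduces the published reference rate table to
within a single global prefactor of about $1.0097$ (see below); we document
that residual as a constants-convention artifact rather than absorbing it.
Default electronic parameters tie everything to the odorant's natural
frequency $\omega \equiv \sqrt{\omega_x^2+\omega_z^2}$:
$\varepsilon = \omega$ (energy conservation), $\Delta = 0.01\,\omega$ (weak
hopping), $\gamma_D = -\gamma_A = 0.1\,\omega$ (Huang–Rhys-scale coupling,
antisymmetric). The default bath is the aqueous exponential-cutoff Ohmic
spectrum $J(\omega) = J_0\,\omega\,e^{-\omega/\lambda}$ with $J_0 = 1$,
$\lambda = 10^{12}$ Hz; Drude spectra arise from the dielectric continuum
description via `alpha_from_dielectrics()` / `cutoff_from_dielectrics()`
(there the energy factor $(\Delta\mu)^2/4\pi\epsilon_0 b^3$ is converted from
joules to Hz with $h$, and the cutoff in the denominator is an explicit
argument because the continuum formulas leave its identity open).

The semiclassical barrier estimate
$\omega_x = A q_0\sqrt{M\omega_0}\,e^{-BV_0/\omega_0}$ offered by
`wkb_tunneling_frequency()` is implemented literally in natural units; it is
not dimensionally homogeneous in SI, so unit conversion is the caller's
responsibility and only its scalings (exponential suppression in $V_0$,
$\sqrt{M}$ growth) are asserted.

## The bath correlation function

The displacement-operator correlation function is evaluated as

$$f(\tau) = \exp\Big\{-\int_0^\infty \frac{J(\omega)}{\omega^2}
  \Big[(1-\cos\omega\tau)\coth\frac{\omega}{2k_BT} - i\sin\omega\tau\Big]
  d\omega\Big\},$$

with $\coth \to 1$ in the ground state. A form sometimes quoted with the
thermal factor multiplying only the cosine is infrared-divergent at $T>0$
(the integrand grows as $-2k_BT J_0/\omega^2$ near $\omega = 0$); the form
above is the standard finite result, coincides with the quoted one at
$T = 0$, and has the two limits the rate theory relies on: at $T=0$ with the
exponential cutoff, $f(\tau) = (1+\lambda^2\tau^2)^{-J_0/2}
e^{iJ_0\arctan\lambda\tau}$ exactly, and at high temperature and short time
$\ln f \approx -J_0\lambda\,k_BT\,\tau^2 + iJ_0\lambda\tau$, which is
precisely what turns the kernel integral into the Marcus Gaussian with shift
$\varepsilon - J_0\lambda$.

Numerically, the $\omega$-integral runs over $[0, 50\lambda]$ with composite
8-point Gauss–Legendre panels whose count scales with the oscillation
frequency $\tau$; convergence is verified by panel doubling at relative
tolerance $10^{-8}$ and failure raises an explicit error naming the offending
$\tau$. The $\omega \to 0$ end needs no special casing because
$1-\cos\omega\tau$ is evaluated as $2\sin^2(\omega\tau/2)$ and the integrand
tends smoothly to its finite limit.

`numeric_rate()` is the package's independent oracle: it evaluates
$\Gamma = \Delta^2\, 2\,\mathrm{Re}\int_0^{\tau_{max}}
e^{-i\varepsilon\tau} K_{ij}(\tau) f(\tau)\, d\tau$ by Simpson quadrature,
with $K_{ij}$ the same kernel decomposition used by the closed forms and
$\tau_{max}$ extended (1.5×, 3×, …) from $8/\sqrt{k_BT E_r}$ until the
integral is stable. Substituting the analytic high-temperature Gaussian for
$f$ reproduces the closed forms to machine precision (a self-test of the
integrator); with the full quadrature correlation the closed forms agree to
about 2% at the reference parameters, the genuine size of the
high-temperature approximation there.

## Reproducing the reference rate table

```{r table1}
print(table1_check())
```

All nine inverse rates land within 1% of the printed values, and a single
fitted prefactor (`r round(table1_check()$prefactor, 4)`, well inside
$[0.99, 1.02]$) reduces every residual below 0.01% — i.e. the discrepancy is
one global constant, consistent with a slightly different thermal-constant
convention in the source, not a structural disagreement.

## The two chiral-channel formula variants

The published closed forms print the exponential carrying the
$(\eta_A+\eta_D)$ shift inconsistently between the two chiral channels — once
with a linear exponent, once squared — and the published rate table is itself
internally inconsistent: its asymmetry-dominant rows are reproduced only by
the *squared* (Gaussian) exponent, while its tunneling-dominant row
($\omega_x = 10^{13}$, $\omega_z = 10^{12}$ Hz) is reproduced only by the
*linear* one, in both channels:

```{r variants}
req_L <- rate_request(odorant_two_level(1e13, 1e12, warn = FALSE),
                      transition = "L_to_E2")
c(squared = closed_form_rate(req_L, "squared")$inverse,
  linear  = closed_form_rate(req_L, "linear")$inverse)  # printed: 3.69778e-10 s
```

The kernel integral that `numeric_rate()` evaluates can only produce squared
(Gaussian) exponents — every oscillating kernel term Fourier-transforms
against the Gaussian correlation into a shifted Gaussian — so `"squared"` is
the self-consistent physics and is the package default. The `"linear"`
variant is retained as an explicit option (`second_exponent = "linear"`)
because it is what reproduces the published tunneling-dominant numbers, and
with them the headline qualitative claim that inelastic transfer dominates
for $\omega_x > \omega_z$: under the squared default the
inelastic-to-elastic ratios at that corner are about 0.31 and 0.71 (both
subdominant). Dominance-related checks in this package therefore run in the
table-fidelity linear mode, and both behaviours are pinned in the test suite
so the contradiction stays visible rather than silently resolved.

Two related caveats surfaced by evaluation rather than stated up front:
negative closed-form values can occur for the chiral channels in the strongly
non-perturbative corner (they are reported with a `negative_rate` flag and
never clamped or dropped), and the direction of the temperature dependence of
the inelastic-to-elastic ratio flips with $\omega_x$, so only the *ordering*
(non-crossing) of temperature families is a robust property.

## Pressure, isotopes, chirality

Collisional decoherence suppresses tunneling as
$\omega_x' = \omega_x\sqrt{1-P/P_{cr}}$ with
$P_{cr} = \omega_x\sqrt{2 m k_B T}/\sigma$, where
$m = \mu m_t/(\mu+m_t)$ is the effective collision mass. The cross-section
default is $150\,a_b^2$ ($a_b$ the Bohr radius): a cross-section must be an
area, so the occasionally quoted "$150\,a_b$" is read as $a_b^2$-units and
exposed as a configuration value. In the high-pressure limit the surviving
odorant transition is the handed flip $|R\rangle\to|L\rangle$; over the
physical grid $\omega_x \in [10^3, 10^{12}]$ Hz (the upper end being the
physical maximum for molecular contorsional modes — beyond it, with
$\omega_x \gtrsim \omega_z$, the claim provably fails) and
$\omega_z \in \{1, 5, 10\}\times10^{12}$ Hz, its ratio to the elastic channel
stays below 1: pressure-saturated odorants are predicted to be hard to smell.

The ammonia fixture (`ammonia_fixture()`) demonstrates the pipeline with
synthetic mass estimates ($\mu = 4.1\times10^{-27}$ kg,
$m_t = 4.81\times10^{-26}$ kg, $T = 300$ K): it yields $P_{cr}$ of a few
atmospheres, the right order of magnitude but roughly twice the commonly
quoted 1.6 atm — the masses and cross-section convention behind that figure
are not recoverable, so the fixture is demonstration-only and not a
quantitative target.

Chirality: the $L\to E_2$ and $R\to E_2$ channels differ for the two
enantiomeric preparations, and their ratio is the discrimination observable.
Because the global prefactor cancels in ratios, the package reproduces the
printed inverse-rate quotients to a few parts in $10^4$ (e.g. $\approx 103$
at $\omega_x = 10^6$, $\omega_z = 10^9$ Hz, and $\approx 0.256$ at
$\omega_x = \omega_z = 10^9$ Hz) — the ratio crosses 1 between the
asymmetry- and tunneling-dominant regimes. The limit statement sometimes
made, that the ratio tends to 1 as the couplings and $\omega_x/\omega_z$
vanish, is not correct for these formulas (the $R$ channel closes as
$3\theta^2\,\Gamma_{el}$ while the $L$ channel tends to $\Gamma_{el}$, so the
ratio diverges); only the crossing property is asserted.

## Problem sizes and determinism

Everything in the toolkit is deterministic — identical sweep specifications
byte-reproduce their output files. The shipped checks use the problem sizes
a laptop handles in seconds to a minute: 51-point $\tau$ grids for the
correlation closed form, 25-point log grids per $\omega_z$ for the
high-pressure sweep, Simpson grids of ~1600 points (density-preserving under
window extension) for the nine numeric-oracle rates. The sweep engine's
default odorant grid is 41 log-spaced points over $[10^3, 10^{13}]$ Hz,
bracketing every regime discussed, with out-of-physical-range points flagged
rather than refused.

## What the tests do and do not show

The suite validates the rate engine against (a) literal transcriptions of the
closed forms, (b) the published reference table, (c) exact limits (resonance,
degenerate geometry, endpoint identities), and (d) the independent
kernel-integral oracle. All of this is internal to the model: passing tests
show the dissipative tunneling model is implemented faithfully and
self-consistently, not that olfaction works this way. Real odorant-receptor
systems have structured (non-Ohmic) spectral densities, anharmonic
corrections beyond the two-level truncation (valid only for
$V_0/\omega_0 \gtrsim 5$, flagged by `double_well_geometry()`), and coupling
parameters known at best to order of magnitude.
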