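---
title: "Methods: isotherm analysis and mixing thermodynamics in monolayer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: isotherm analysis and mixing thermodynamics in monolayer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(monolayer)
```

## The measurement and the model

A Langmuir trough compresses a one-molecule-thick film at the air/water
interface while a Wilhelmy balance records the surface pressure $\pi$ (mN/m)
against the mean molecular area $A$ (Å²/molecule). From a single compression
branch this package derives three families of quantities.

**Elasticity and phase state.** The surface compressibility modulus

$$C_s^{-1} = -A \left(\frac{\partial \pi}{\partial A}\right)_T$$

measures the in-plane stiffness of the film. Its maximum over the compression
is the conventional phase diagnostic (Davies--Rideal): gaseous up to
12.5 mN/m, liquid-expanded (LE) up to 50 mN/m, liquid-condensed (LC) in
100--250 mN/m, solid above 250 mN/m; the open interval (50, 100) is labelled
LE-LC. The LE and LC boundaries are the classical quoted ones; the G cutoff
and the LE-LC label fill the gaps in the convention, with right-closed
boundaries so that a value of exactly 50 is still LE (films a few mN/m above
50 are conventionally described as "slightly above" the LE limit, i.e. not
LE). A transition pressure $\pi_{tr}$ separating a gradual rise of
$C_s^{-1}$ from a steeper one is located as the deepest interior local
minimum of the profile, falling back to the breakpoint of a two-segment
piecewise-linear fit when the profile has no interior minimum; the breakpoint
is only reported when the second slope exceeds twice the first, so
single-regime profiles legitimately have no $\pi_{tr}$.

**Hysteresis.** For a compression--decompression cycle the enclosed loop

$$\oint A\, d\pi \;=\; \int_{\pi_{lo}}^{\pi_{hi}}
  \left[A_{comp}(\pi) - A_{dec}(\pi)\right] d\pi$$

is the irreversible work per molecule of one cycle (Å² mN/m =
$10^{-23}$ J). Integration runs over the pressure axis, not the area axis:
this matches the free-energy convention below and is insensitive to lateral
shifts between the branches. The sign is kept: crossing branches produce
partial cancellation, which is reported rather than clipped. A dimensionless
`relative` value normalises the loop by the compression work over the same
pressure range.

**Mixing thermodynamics (the core computation).** For a mixed film of
composition $X_1, X_2$ the additivity rule predicts
$A_{add}(\pi) = X_1 A_1(\pi) + X_2 A_2(\pi)$; the deviation
$\Delta A = A_{exp} - A_{add}$ diagnoses interactions (negative: unlike-pair
attraction, compaction, miscibility; positive: like-pair attraction, a
tendency to demix). The Goodrich construction integrates the isotherms
themselves:

$$\Delta G_{exc}^{\pi} = N_A \left( \int_0^{\pi} A_{mix}\, d\pi
 - X_1 \int_0^{\pi} A_1\, d\pi - X_2 \int_0^{\pi} A_2\, d\pi \right),
\qquad
\Delta G_{mix}^{\pi} = \Delta G_{exc}^{\pi}
 + RT\left(X_1 \ln X_1 + X_2 \ln X_2\right).$$

Negative $\Delta G_{mix}^{\pi}$ means the mixed film is more stable than the
pure films. A ternary protein/lipid/lipid film with an equimolar lipid pair is
treated as pseudo-binary - protein versus "the lipid mixture" - with the
lipid fraction counting every lipid molecule, so a spreading ratio $1{:}m{:}m$
gives $X_{protein} = 1/(1+2m)$ (`ratio_to_molefractions()`). This matches how
such series are tabulated (1:45:45 prints as $X = 0.011$); comparisons with
printed values use round-half-away-from-zero (`round_printed()`).

## Numerical choices

- **Single-valuedness.** $\Delta G_{exc}$ needs $A(\pi)$; a compression branch
  is therefore truncated at its first global pressure maximum before any
  interpolation, and tied pressures contribute their mean area. Collapse
  detection (`detect_collapse()`) runs on the untruncated branch.
- **Derivative.** Central differences after Savitzky--Golay smoothing
  (default window 11, order 2, endpoints fitted with shifted one-sided
  windows so polynomials up to the fit order are reproduced exactly).
  Endpoints of the grid are excluded from the profile. Smoothing can be
  disabled for noiseless curves.
- **Integration.** Composite trapezoid on the union of all curves' knots plus
  a uniform refinement (default 201 nodes) - deterministic, and exact for the
  piecewise-linear interpolants it integrates. Doubling the refinement moves
  $\Delta G_{exc}$ by well under 0.1% on smooth curves.
- **Lower bound.** The Goodrich integral starts at $\pi = 0$. A curve that
  lifts off at $\pi_0 > 0$ is extended down to zero at its constant lift-off
  area (below lift-off the molecular area barely changes at these scales);
  the flat-segment contribution is reported separately
  (`extension_contribution`) so its influence is always visible.
- **Ties and tie-breaks.** Equal areas average their pressures on read; the
  modulus maximum at tied values takes the lowest pressure; plateau runs in
  the modulus profile are summarised by their median (zero on an ideal
  plateau, robust to the contaminated edge secants).
- **Collapse.** Detected when the pressure maximum is followed by at least 3
  points more than 0.5 mN/m below it, or by at least 3 inter-point slopes
  below 5% of the pre-maximum median slope; both thresholds are conventions
  and are exposed as arguments.

## The synthetic generator

No trough data ships with the package; the generator provides fixtures whose
derived quantities have closed forms, so every analysis routine can be tested
against an independent oracle.

- **Equation of state.** $A(\pi) = A_\infty + (A_0 - A_\infty) e^{-\pi/\pi_c}$.
  Chosen over a Volmer form $kT/(A-\omega)$ because it has finite area at
  $\pi = 0$, making $\int_0^\pi A\,d\pi$ exact with no extension, while the
  extension rule can still be stress-tested by generating curves that start
  above zero. Closed forms: $C_s^{-1}(\pi) = \pi_c A/(A - A_\infty)$ and
  $\int_0^\pi A\,d\pi' = A_\infty \pi + (A_0-A_\infty)\pi_c(1-e^{-\pi/\pi_c})$.
- **Interaction.** Mixtures follow
  $A_{mix} = \sum X_i A_i + \beta X_1 X_2 e^{-\pi/\pi_d}$, giving
  $\Delta A(\pi) = \beta X_1 X_2 e^{-\pi/\pi_d}$ and
  $\Delta G_{exc}^\pi = N_A \beta X_1 X_2 \pi_d (1-e^{-\pi/\pi_d})
  \times 10^{-23}$ J/mol. $\beta < 0$ is condensing (miscibility-like),
  $\beta > 0$ expanding (separation-like).
- **Noise.** Gaussian, on pressure (the measured signal on a Wilhelmy
  balance), truncated at $\pi \ge 0$, default $\sigma = 0.1$ mN/m, seeded.
- **The synthetic study dataset** (`study_dataset()`) fixes the study
  conditions: an expanded protein-like film ($A_0 = 250$, $A_\infty = 40$ Å²,
  $\pi_c = 15$ mN/m) compressed to 35 mN/m without collapse; a condensed
  lipid-like film ($A_0 = 60$, $A_\infty = 38$ Å², $\pi_c = 18$ mN/m)
  collapsing at 45 mN/m; six mixtures at the ratio series 1:86:86 ... 1:1:1
  ($X$ = 1/173, 1/118, 1/91, 1/21, 1/5, 1/3) with $\beta = -5$ Å²,
  $\pi_d = 10$ mN/m; one cycle with offset $2e^{-\pi/10}$ Å²; 200
  points/branch (a typical trough export density); $T = 308.15$ K; scan
  pressures 3, 6, 9, 12 mN/m (four pressures below the transition region).
- **$\beta$ diagnostic.** `estimate_beta()` recovers the amplitude as a least
  squares fit of the measured $\Delta A(\pi)$ on the basis
  $X_1X_2 e^{-\pi/\pi_d}$ over a low-pressure grid after smoothing -
  algebraically $\Delta A(0)/(X_1X_2)$ extrapolated along the model's own
  decay, which averages the pressure noise instead of relying on a single
  interpolated point.

**What the generator does not emulate.** Real isotherms have LE-LC coexistence
plateaus with temperature-dependent width, film-loss drift, speed-dependent
hysteresis and instrument-specific sampling; the exponential EoS has none of
these, and its modulus grows without bound as $A \to A_\infty$, so a fixture
compressed close to collapse can exceed the LC band (the collapsing lipid
fixture tops out near 400 mN/m, formally "S"). Passing tests therefore
demonstrate the correctness of the numerics and the unit chain, not that any
real film obeys the exponential EoS.

## A worked pass

```{r example}
dir <- file.path(tempdir(), "demo")
man <- cmd_simulate(dir, seed = 1)
out <- file.path(tempdir(), "report")
res <- cmd_analyze(
  file.path(dir, grep("^mixture_", man$files, value = TRUE)),
  file.path(dir, c("protein.csv", "lipids.csv")),
  out_dir = out, cycle_paths = file.path(dir, "cycle.csv"))
summary(res$mixing)
head(res$mixing, 4)
res$elasticity[["protein"]]
hysteresis_area(read_cycle(file.path(dir, "cycle.csv"))[[1]])
```

## Known limitations

- The pseudo-binary treatment ignores any non-equimolarity of the lipid pair;
  compositions are reduced to a single protein fraction.
- $\pi_{tr}$ from the modulus profile need not coincide with the kink seen on
  the isotherm itself; the profile-based value is the one reported.
- The breakpoint fall-back for $\pi_{tr}$ assumes at most two linear regimes;
  richer profiles are summarised by their deepest minimum only.
- The hysteresis metric is the enclosed loop only; no viscoelastic relaxation
  model is fitted.
- Equilibrium spreading pressure $\pi_0$ is carried as metadata
  (`liftoff_pressure`) and never enters the integrals, which always start at
  $\pi = 0$ under the constant-area extension.
```
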