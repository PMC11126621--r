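---
title: "Acoustic phononic-crystal sensing of breath CO2: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Acoustic phononic-crystal sensing of breath CO2: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pncsense)
```

## The sensing principle

Dry exhaled breath (DEB) is, to a good approximation, a four-component gas
mixture: N2 78%, O2 16%, CO2 5% and Ar 1% by volume in a healthy subject.
Because CO2 is much denser and slower (acoustically) than the other
components, the effective sound speed of the mixture is a sensitive,
monotone proxy for its CO2 content.  `pncsense` simulates an acoustic sensor
that converts this sound-speed change into a frequency readout:

* a main duct (cross-section `S1`) is loaded periodically, every `d1`, with a
  pair of side branches at the same axial position — one closed stub (length
  `d2`, cross-section `S2`) and one open stub (`d3`, `S3`);
* the periodic loading opens phononic band gaps, frequency intervals in which
  sound cannot propagate along the duct;
* a defect guide of length `dd` at the centre of the chain breaks the
  periodicity and pulls one (or more) sharply localised transmission
  resonances into each gap;
* the resonance frequency of such a defect mode scales exactly in proportion
  to the sound speed of the filling gas, so a CO2-induced speed change reads
  out as a frequency shift.

The package computes the transmittance of the finite chain by the acoustic
transfer-matrix method (TMM), the band structure of the infinite chain from
the Bloch dispersion relation, and from these the full set of sensor
indicators.

## The acoustic model

Plane waves in a duct segment of length $L$ and characteristic impedance
$Z = \rho c / S$ propagate according to the two-port (ABCD) matrix

$$
M(L, Z) \;=\;
\begin{pmatrix}
\cos kL & \mathrm{j} Z \sin kL\\[2pt]
\mathrm{j}\sin kL / Z & \cos kL
\end{pmatrix},
\qquad k = \frac{2\pi f}{c}.
$$

The side branches act as a shunt admittance at the loading plane:
$y_O = -\mathrm{j}\cot(k d_3)/Z_3$ for the open stub,
$y_C = +\mathrm{j}\tan(k d_2)/Z_2$ for the closed stub, and the combined load
is $y_{OC} = y_O + y_C$.  One unit cell is the symmetric sandwich

$$
M_{\text{cell}} = M(d_1/2, Z_1)\,
\begin{pmatrix}1 & 0\\ y_{OC} & 1\end{pmatrix}
M(d_1/2, Z_1),
$$

and the full sensor is
$M_{\text{cell}}^{\,n}\; M(d_d, Z_d)\; M_{\text{cell}}^{\,n}$ with $n$ mirror
cells on each side of the defect guide, fed and terminated by semi-infinite
ducts of admittance $Y_1 = S_1/(\rho c)$.  The power transmittance is

$$
t = \frac{2 Y_1}{(A_{11} + A_{12} Y_1)\,Y_1 + A_{21} + A_{22} Y_1},
\qquad T(\%) = 100\,|t|^2 .
$$

Every element is lossless and reciprocal (all matrices are unimodular), so
$0 \le T \le 100$ identically, and the whole spectrum depends on the medium
only through $c$ (an overall rescaling of $\rho$ rescales all impedances
together and cancels).  Consequently the defect-peak frequency obeys the
standing-wave proportionality $f_R \propto c$ *exactly* in this model — a
property the test suite checks to 0.1% and that underpins the linear CO2
calibration.

The infinite chain's Bloch dispersion is

$$
\cos(Kd) = \cos(k d_1) + \tfrac{\mathrm{j}}{2} Z_1 y_{OC} \sin(k d_1),
\qquad d = d_1 ,
$$

which is real because $y_{OC}$ is purely imaginary; $|\cos(Kd)| > 1$ marks a
band gap.  The same relation can be written with the inverse Green surface
functions of the two resonators, $g_c^{-1} = -\mathrm{j} y_2 \tan(k d_2)$ and
$g_o^{-1} = +\mathrm{j} y_3 \cot(k d_3)$ with $y_i = S_i/(\rho c)$, whose sum
equals $-y_{OC}$; the package exposes both forms and the test suite verifies
their algebraic equivalence at sampled frequencies.

Gas mixtures follow the volume-fraction-weighted rules
$c_{\text{mix}} = \sum \alpha_i \rho_i c_i / \sum \alpha_i \rho_i$ and
$\rho_{\text{mix}} = \sum \alpha_i \rho_i$, using the built-in
room-temperature pure-gas table (CO2 1.8393 kg/m³, 267 m/s; Ar 1.661, 319;
O2 1.314, 326; air 1.2047, 343; N2 1.165, 349).

**Assumptions.**  Plane-wave (single-mode) propagation, i.e. all transverse
dimensions well below half a wavelength; a stationary, dry sample at room
temperature; no viscothermal wall losses, temperature gradients or mean flow.
These idealisations matter most for the narrowest resonances — see
*Limitations*.

## Reference designs and the enrichment convention

Two named configurations ship with the package (`fixture_configs()`,
`inst/extdata/*.yaml`):

* `initial`: `d1 = 10` cm, `d2 = d3 = 6` cm, `dd = 33` cm, `S1 = Sd = 1` cm²,
  `S2 = S3 = 0.9` cm², operating on the defect mode in the **third** band gap
  (about 1715–2010 Hz in air);
* `optimized`: identical except `d1 = 20` cm and `dd = 100` cm, operating on
  the tracked mode near 1800 Hz.

**Mirror size.**  Each Bragg mirror has ten unit cells (`n_cells = 10` per
side, 21 elements in total).  The mirror depth controls the defect-mode
linewidth exponentially (roughly a factor 3.7 per added cell for these
designs); ten cells per side reproduces the reported confinement of the
reference designs, e.g. a linewidth of 0.558 Hz for a 20 cm defect guide at
the initial duct length.

**CO2 enrichment units.**  The enrichment argument of `deb_mixture()` is
calibrated so that one unit adds 0.01 percentage point of CO2 volume
fraction: 100 units take CO2 from 5% to 6%.  The displaced volume is taken
proportionally from N2, O2 and Ar (their 78:16:1 ratios are preserved).  This
is a convention, not physics: which gas the added CO2 displaces is not
observable from the mixture rules alone, and plausible alternatives (e.g.
renormalising all four gases, or displacing N2 only) change the speed drop
across the full range — and hence the calibration slope — by roughly 5%.
Quantities that are ratios with respect to the same mixture pair (the
sensitivity `S`, for instance) are insensitive to this choice at the 1%
level.

## Numerical methods

**Vectorised kernel.**  All spectra are computed by a vectorised 2×2 complex
cascade; the matrix-valued API (`unit_cell_matrix()` etc.) is the scalar
reference implementation and the two routes are cross-checked in the tests.

**Branch poles.**  The stub admittances diverge where `sin(k d3) = 0` or
`cos(k d2) = 0`.  A sampled frequency landing within `1e-12` of a pole is
nudged by a relative `1e-9`, which returns the correct lossless limit
(`T -> 0`) instead of `NaN`.

**Locating ultra-narrow resonances.**  The optimised design's defect mode has
a converged full width at half maximum of `2.8e-4` Hz at 1800 Hz
(Q ≈ 6.4×10⁶).  No practical uniform grid resolves this, and a naive
argmax over a coarse spectrum misses the peak entirely.  The locator instead
uses a structural property of the lossless mirror-symmetric chain: the
normalised transmission denominator
$A_{11} + A_{12}Y_1 + A_{21}/Y_1 + A_{22}$ has real part $A_{11}+A_{22}$
(the matrix trace), which crosses zero at a symmetric resonance while
otherwise growing like the Bragg attenuation inside a gap.  Zero crossings of
the trace on a 0.05 Hz grid are bracketed, refined by `stats::uniroot`, and
the transmittance maximum is then polished by iterative 41-point grid
shrinking to below `1e-8` Hz.  The linewidth is resolved by bisection on each
flank for the `T = T_peak/2` crossings.  Half maximum is defined relative to
the peak transmittance, not relative to 100%.

**Mode selection.**  A long defect guide supports several cavity harmonics
per gap (a 1 m guide spaces them by roughly $c/2d_d \approx 170$ Hz), and
near-degenerate "dark" crossings with vanishing transmittance also exist.
The sensing mode is therefore selected inside an explicit band gap
(`gap = 3` for the initial design) or operating window
(`f_window = c(1700, 1910)` for the optimised design, wide enough to contain
the tracked mode at every enrichment level); among candidates above the 1%
transmittance threshold the highest peak wins, with ties (within one
percentage point) broken toward the narrower peak.

**Band-gap edges** are refined by bisection on $|\cos(Kd)| - 1$ to `1e-3` Hz
from a 0.25 Hz scan.  The low-frequency cut-off region (the open stubs short
the duct as $f \to 0$) counts as the first gap, which makes the gap
containing the initial design's defect mode the third.

**Determinant conditioning.**  Unimodularity is exact in exact arithmetic,
but deep inside a gap the assembled product's entries grow to ~10¹⁰ and the
determinant's floating-point cancellation error scales with the square of the
entry magnitude.  The tests therefore check `|det - 1| < 1e-9` absolutely for
single cells and relative to $|A_{11}A_{22}| + |A_{12}A_{21}|$ for assembled
products.

**Default problem sizes.**  Figure-quality spectra use a 0.1–3000 Hz grid at
0.05 Hz; gap scans use 0.25 Hz; peak location uses the adaptive scheme above.
A full metrics report (two peak locations plus a linewidth) takes a few tens
of milliseconds, a six-level calibration about 0.1 s.

## Readout resolution versus converged linewidths

A point that matters when comparing with grid-sampled (simulated or
measured) spectra: **a finite scan step cannot report the converged peak
transmittance or linewidth of a resonance much narrower than the step.**
Sampling a lossless resonance of true width $\Gamma$ on a grid of step
$h \gg \Gamma$ reads a peak transmittance of
$T_{\text{obs}} = 100/(1 + (2\delta/\Gamma)^2)$ (with $\delta$ the offset of
the nearest sample, up to $h/2$) and an interpolated width of order $h$
rather than $\Gamma$.  For the optimised design, a readout grid of a few
times $10^{-4}$ Hz turns the converged $T = 100\%$, $\Gamma = 2.8\times
10^{-4}$ Hz mode into an apparent ~70% peak of width ~$5\times10^{-4}$ Hz,
and correspondingly halves the apparent figure of merit, quality factor and
SNR.  `pncsense` always reports converged values: peak transmittance of this
lossless, mirror-symmetric network is exactly 100% at resonance (a direct
consequence of unitarity plus reciprocity), and linewidths are bisection
limits, not grid readouts.  Derived indicators obey their defining identities
(`FoM * FWHM = S`, `Q * FWHM = f_R`, `LoD * 20 * S * Q = f_R`) to machine
precision by construction.

For the same reason, one-parameter design studies ranked by converged figure
of merit need not agree with rankings based on grid-limited readouts: under
converged linewidths the figure of merit keeps improving past the point where
an under-resolved readout appears to deteriorate (the apparent peak
transmittance collapses once the mode is much narrower than the scan step).
`select_optimum()` implements the formal criterion — maximal FoM among rows
with peak transmittance of at least 50%, ties toward higher Q — and the sweep
tables expose every ingredient so alternative criteria are one argument away.

## Sensor indicators

With $f_R$ the baseline peak frequency, $\Delta f_R$ the shift over the full
enrichment range (0 → 100 units, endpoints), and $\Delta c$ the corresponding
effective-speed difference:

| quantity | definition | units |
|---|---|---|
| sensitivity | $S = \Delta f_R / \Delta c$ | Hz m⁻¹ s |
| figure of merit | $\mathrm{FoM} = S / \mathrm{FWHM}$ | m⁻¹ s |
| quality factor | $Q = f_R / \mathrm{FWHM}$ | — |
| detection limit | $\mathrm{LoD} = f_R / (20\, S\, Q)$ | m s⁻¹ |
| signal-to-noise | $\mathrm{SNR} = \Delta f_R / \mathrm{FWHM}$ | — |
| resolution | $\mathrm{RS} = 2\,\mathrm{FWHM} / (3\,\mathrm{SNR}^{1/4})$ | — |

SNR here is the deterministic shift-to-linewidth ratio, not a measured noise
figure, and the factor 20 in the detection limit is adopted as the field's
convention.  The CO2 calibration (`calibration_fit()`) is an ordinary
least-squares line of $f_R$ on the enrichment level; because $f_R \propto c$
exactly and $c$ is almost affine in the CO2 fraction over 5–6%, the six-level
fit is linear to $R^2 > 0.9999$.

```{r metrics, eval = FALSE}
met <- sensor_metrics(optimized_geometry(), f_window = c(1700, 1910))
cal <- calibration_fit(seq(0, 100, 20), geometry = optimized_geometry(),
                       f_window = c(1700, 1910))
```

## What the shipped configurations emulate — and what they do not

The YAML fixtures describe the idealised laboratory set-up: a rigid-walled
duct network filled with a stationary, dried breath sample of known
composition.  Real capnography data differ in ways the model deliberately
omits: humidity and VOC content (assumed removed by a dryer), temperature
drift (which shifts all pure-gas constants), viscothermal boundary-layer
losses, and transducer noise.  Passing the package's tests therefore
demonstrates internal correctness of the lossless model and its numerics —
not that a physical device achieves the computed Q or detection limit.

## Limitations

* **Lossless idealisation.**  Viscothermal losses, neglected here, impose a
  floor on the achievable linewidth and pull the resonance transmittance
  below 100%; the computed FoM, Q, SNR and LoD are upper bounds on any
  physical realisation, and the narrower the converged mode the larger the
  relative effect.
* **Plane-wave regime.**  Cross-sections of ~1 cm² keep the first transverse
  mode far above 3 kHz, but the model is silent about 3-D effects at branch
  junctions (end corrections), which shift resonances by a few percent in
  practice.
* **Mixture convention.**  The enrichment mapping fixes how added CO2
  displaces the other gases (see above); slope-like quantities inherit a ~5%
  convention uncertainty.
* **Mode bookkeeping.**  The operating window must be chosen so the tracked
  mode stays inside it across the studied concentration range; the defaults
  shipped with the fixtures do this for 0–100 enrichment units.
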