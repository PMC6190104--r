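---
title: "EmbryoServo: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EmbryoServo: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(EmbryoServo)
```

## The problem

Microinjecting genetic material into zebrafish embryos is routine in
developmental biology and is increasingly delegated to robotic systems: a
motorized inverted microscope images a petri dish of chorionated embryos in
bright field, and a robot arm drives a pulled glass micropipette into the
yolk of each one. The robot sees only what the camera sees, so three image
computations carry the whole procedure:

1. **autofocus** — find the stage position that brings the embryo into
   focus;
2. **embryo detection** — locate the embryo center and extent in the
   in-focus image, robustly against uneven illumination;
3. **pipette-tip localization** — find the needle tip, from which the
   pixel displacement tip-to-center is the servo command.

EmbryoServo implements these three stages and the end-to-end servo loop as
a hardware-free library. A seeded synthetic scene generator stands in for
the microscope, so every stage can be validated against exact ground
truth.

## Synthetic scenes

A scene is a bright-field view of a chorionated embryo: a bright
background (default 200), a dark elliptical membrane annulus (default
intensity 80, thickness 10 px) whose outer boundary is the embryo ellipse,
a darker yolk disc filling most of the interior (default 150), and
low-amplitude seeded texture (sd 6) inside the embryo so that focus
criteria have fine detail to respond to. A pipette is rendered as a dark
constant-slope taper entering from an image edge and ending at the tip
pixel; the fixed taper slope makes the near-tip shape identical across
scenes, which is what justifies matching all scenes with one template.

Defocus is modeled as an isotropic Gaussian point-spread function with

$$\sigma(z) = \sigma_0 + s\,|z - z_f|,$$

by default $\sigma_0 = 0.5$ px and $s = 0.012$ px/µm. The true optics are
unknown; a Gaussian PSF with linearly growing width is the simplest model
that produces the unimodal, single-peaked focus curves a real
through-focus stack shows. Uneven illumination is a smooth multiplicative
gain field (bilinear between four corner gains, or radial) plus an
additive offset, applied after blurring; sensor noise is additive Gaussian
(default sd 2), applied last, before clamping to 8-bit. Every render is
bit-reproducible from its parameters and seed.

The generator emulates geometry, shading and defocus — not photorealism.
It does not model debris, touching embryos, meniscus shadows, chromatic
effects, or non-Gaussian sensor noise, so passing tests demonstrate
correctness of the algorithms under controlled conditions, not field
performance on arbitrary micrographs.

Default study conditions used throughout the tests: a 512 px field whose
embryo spans roughly 55–65% of the image width (the proportion a 4x
objective gives a chorionated embryo on a 1280x1024 sensor), illumination
severities ramping from perfectly even to a linear gradient whose dark
side gain is 0.4, and 14-scene injection suites matching the scale of a
typical bench experiment. Through-focus stacks use 31 frames at 200 µm;
autofocus batches use a 256 px field so that a 50-stage comparison against
an exhaustive oracle stays cheap.

## Focus criteria and the two-phase search

Three classical sharpness scores are implemented exactly as summations
over observed pixels (no padding; sums only over pixels whose operands
exist):

* **Brenner gradient** $\sum_{x,y} [I(x{+}2,y) - I(x,y)]^2$, horizontal
  direction only;
* **Tenengrad** $\sum_{x,y} S_x^2 + S_y^2$ with the standard ±1/±2 Sobel
  stencils, over interior pixels;
* **normalized variance** $\frac{1}{\mu}\sum_{x,y}(I - \mu)^2$, evaluated
  literally without a $1/N$ factor — only relative behavior across a stack
  matters, and the literal form keeps the implementation auditable against
  its definition.

On the standard synthetic stack all three peak at the true focal frame,
and the Brenner curve has the narrowest full width at half maximum
(`curveFWHM`, linear interpolation at the 0.5 crossings). Narrowness plus
its lowest cost per pixel is why the Brenner score drives the controller.

The depth of field of the emulated optics,
$DF = 10^{-3}\,\frac{7}{AM} + \frac{\lambda}{2A^2}$ (millimetres), bounds
a useful fine step. `depthOfField` evaluates the formula literally; with
$A = 0.1$, $M = 40$, $\lambda = 550$ nm it gives 29.25 µm, and the result
scales directly with the wavelength and magnification convention chosen,
so the function takes all three explicitly rather than fixing a value.

The controller scans coarsely (200 µm) from `zStart`, classifying each
consecutive score triplet as increasing / decreasing / indeterminate with
a slack of `epsilon` times the running maximum score. A decreasing trend
after an increasing one brackets the peak. The fine phase then *moves
back* from the stop position in 50 µm steps until the fine scores fall
off their own peak, and the best-scoring position visited is returned.

Two numerical choices deserve explanation:

* **Trend tolerance.** Far from focus the Brenner score is dominated by
  sensor noise and jitters by roughly a percent of the running maximum per
  step, while genuine steps on the peak's flank are tens of percent of it.
  A tolerance of $10^{-6}$ lets tail jitter fire spurious rise-then-fall
  brackets millimetres from focus; the default `epsilon = 0.02` sits an
  order of magnitude above the noise scale and an order below the signal
  scale.
* **Fine-phase bracket.** The coarse scan stops two coarse steps past the
  best coarse sample, so the continuous peak lies up to three coarse steps
  behind the stop position. Scanning *backwards from the stop position*
  until the fine scores decrease covers that whole interval; a fixed
  two-coarse-step backtrack followed by a forward scan would leave up to
  one coarse step of it unexplored and can miss the peak by more than one
  fine step. The backward scan is also what a physical stage does — it
  simply reverses with the finer step.

If the first coarse trend is decreasing (scan started above focus) the
direction is reversed once, provided a reverse step stays in range.
Degenerate inputs — a monotone score over the whole range, an exhausted
evaluation budget — return `converged = FALSE` with the best position
visited. In a noise-flat tail no trend is detectable by design; the
controller then walks the range and reports non-convergence rather than
guessing.

## Embryo detection under uneven illumination

A single global threshold fails on unevenly lit fields because the
histogram mixes illumination with reflectance. The adaptive rule
thresholds every pixel against its own neighborhood: with $A_{ij}$ the
weighted mean of the $b \times b$ block around pixel $(i,j)$,

$$T_{ij} = A_{ij} - \mathit{param1},$$

and pixels brighter than $T_{ij}$ map to 255, all others to 0. The weights
are Gaussian by default (sigma tied to $b/6$), uniform by flag; borders
are replicate-padded so $A$ is defined everywhere without darkening the
edges. Because $A$ tracks any smooth gain field, the dark membrane stays
below threshold on both the bright and the shadowed side.

The two parameters are *circulated*: block sizes ascend over
`bRange` (odd values, default 7–51) with offsets `param1Range` (default
5, 7) as the inner loop. For each combination the largest dark connected
component's boundary is traced and an ellipse is fitted to it by the
direct least-squares conic fit with the built-in ellipse constraint
(Fitzgibbon's method in the Halir–Flusser numerically stable
formulation — implemented here, as no installed package provides it). The
first combination whose fitted major-axis length $L$ falls in the
acceptance band wins. Ascending-$b$-outer order is chosen because smaller
blocks are cheaper to compute and a single reported $(b, \mathit{param1})$
pair per embryo is wanted; the ordering affects which pair is reported,
not whether the embryo is found.

The acceptance band defaults to $[0.45, 0.95] \times$ the shorter image
dimension: at the emulated magnification an embryo fills roughly half the
field, so a plausible chorion major axis must be commensurate with it.
The band is fully configurable.

Contours are traced on the dark (0-valued) phase, because membrane pixels
darker than their local mean map to 0 under the rule above. Coordinates
are 0-based throughout, x = column, y = row; centers are sub-pixel.

The Otsu baseline (`detectEmbryoOtsu`; in-package histogram
implementation, cross-checked in the tests against an exhaustive search
over all 256 cuts) runs the same contour-and-fit pipeline after a global
threshold. On evenly lit scenes the two agree to within 2 px of center;
on the strongest synthetic gradients the global threshold absorbs the
dark half of the field into the foreground and the Otsu center lands tens
of pixels off (or the fit leaves the band), which is precisely the
contrast that motivates the adaptive rule.

## Pipette-tip localization

The pipette is rigid and its orientation fixed, so plain template
matching suffices. Matching quality at window origin $(i, j)$ starts from
the sum of squared deviations $e = \sum (f - g)^2$, expanded as
$\sum f^2 + \sum g^2 - 2\sum fg$; with $g$ fixed, $\sum fg$ carries the
match information, and normalizing by the window energy gives the
measure that survives illumination change:

$$M[i,j] = \frac{\sum_{k,l} g[k,l]\, f[i+k, j+l]}
                {\left(\sum_{k,l} f^2[i+k, j+l]\right)^{1/2}}.$$

`locateTemplate` evaluates $M$ at every valid origin and returns the
first row-major origin attaining the maximum — the sequential
compare-and-record rule, under which only a strictly larger value
displaces the recorded best. Identically zero windows score 0 by
convention so flat dark regions never win. Correlation and window energy
are both accumulated template-pixel-by-template-pixel, which makes scores
of identical windows bitwise equal and the tie-break exact.

A template stores the offsets $(L, H)$ from its origin to the tip, so a
match at $(i, j)$ yields tip $x = j + L$, $y = i + H$ (i indexes rows, j
columns; L is horizontal, H vertical). `defaultTipTemplate` builds the
template from a clean pipette-only render, exploiting the generator's
fixed taper slope.

The pipeline treats the tip as found only if the match quality — the
cosine $M / \lVert g \rVert$, which Cauchy–Schwarz bounds by 1 — exceeds
`tipScoreMin` (default 0.975). Against the default template a flat
window's cosine is 0.898 and windows of unrelated scene structure stay
below about 0.965, while genuine matches exceed 0.99; the default sits
between the two scales.

## The servo loop

For each scene: autofocus the simulated stage; detect the embryo on the
in-focus capture; locate the tip; command the displacement
$(\Delta x, \Delta y) = (c_x - t_x,\; c_y - t_y)$. The "move" is
simulated by re-rendering the scene with the pipette translated by the
commanded displacement; the tip is then re-localized and the residual
tip-to-center distance recorded as `finalError`. A scene succeeds when
every stage succeeded and the residual is at most `successTolerance`
(default 10 px, about half of a 20 µm tip diameter at the emulated
magnification). Axial penetration and deposit are recorded as no-op
events — no mechanics are modeled. Stage failures are recorded per scene,
never raised, so a suite always yields a complete report.

## Known limitations

* The generator's illumination severities are the package's own choice;
  no quantitative nonuniformity measurements exist to calibrate against.
* Detection assumes one embryo per field; multiple chorions merging into
  one dark component would defeat the largest-contour rule.
* Template matching is not rotation- or scale-invariant, by design.
* The blur model caps sigma at an eighth of the image side; stages
  millimetres from focus in small test canvases are rendered at that cap,
  which only flattens an already featureless tail.
* `EBImage` supplies blur, connected-component labeling, boundary tracing
  and image I/O; its 4-connected labeling means a one-pixel diagonal
  contour can fragment, which the default `bRange` avoids by producing
  thick membrane components.
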