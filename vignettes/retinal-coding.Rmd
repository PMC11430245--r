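---
title: "Parallel retinal coding: model, datapath emulation and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parallel retinal coding: model, datapath emulation and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retinaKMP)
```

## The model

Primate vision splits the retinal image into three parallel ganglion-to-LGN
streams. This package computes all three from an RGB raster, treating the R,
G and B bytes as the L (long-), M (medium-) and S (short-wavelength) cone
planes:

* **K pathway** (koniocellular, blue–yellow): an S-cone center opposed by a
  "yellow" surround, the average of the L and M surrounds,
  $C_K = S_{cen} - (M_{per} + L_{per})/2$. Active across the whole retina.
* **M pathway** (midget, two-color red–green): a single-cone red center
  against a green surround, $C_M = (L_{cen} - M_{per})/2$. Restricted to the
  fovea, where one midget ganglion cell wires to one cone.
* **P pathway** (homochromatic): center and surround draw on the *same* cone
  classes, $C_P = (L_{cen} - L_{per})/2 + (M_{cen} - M_{per})/2$. Restricted
  to the periphery, with receptive fields growing with eccentricity.

Published descriptions of this three-channel scheme attach the letters K, M
and P inconsistently to the formulas in different places; this package fixes
the taxonomy above — K blue–yellow everywhere, M two-color inside the fovea,
P homochromatic outside — and keeps it consistent across code, tests and
outputs. Likewise, the blue–yellow decomposition is implemented as
$C_K = (S_{cen}-M_{per})/2 + (S_{cen}-L_{per})/2$, the only sign choice
under which the decomposition equals the direct form; the equivalence is
asserted to $10^{-12}$ in the test suite, as is the corresponding P identity
$(L_{cen}-L_{per})/2+(M_{cen}-M_{per})/2 =
(L_{cen}-M_{per})/2+(M_{cen}-L_{per})/2$.

Each receptive field follows Rodieck's difference-of-Gaussians. We model the
center and surround as *disjoint* regions — a center disc of radius
`centerRadius` and its complementary ring — because the corresponding
hardware wires center cells and surround cells to different adder inputs;
the classical overlapping-DoG (both Gaussians spanning the grid) is
available via `style = "overlapping"`. Each region's Gaussian weights are
renormalized to unit sum, so every channel's response to uniform input is
zero by construction; the published formulation leaves the convolution's
scaling open, and unit region gain is the choice that makes the opponent
property exact.

All three channels are assembled from four center-minus-surround
*computational primitives* `(X_cen − Y_per)/2` on the plane pairs R−G, B−G,
B−R and G−R (`primitiveResponse()`). The R−G output is shared by the M and P
pathways; `channelMaps()` exploits exactly that structure, and the resource
model (`resourceReport()`) accounts for the duplicate it avoids.

## Parameters that matter

| parameter | units | default | why |
|---|---|---|---|
| `size` (K, M fields) | px | 3 | smallest odd window with a center and a ring; the hardware reference design is 3×3 |
| `centerRadius` | px | 0.5 | single-pixel center, the foveal midget wiring; for eccentricity-grown P fields it scales as `(size−1)/4` |
| `sigmaCenter` | px | `centerRadius/2` (≥ 0.25) | any positive width satisfies the model (a single-pixel center normalizes to weight 1 regardless); the invariants — unit region gain, radial symmetry — are what the model fixes, so the defaults are deliberately simple |
| `sigmaSurround` | px | `size/3` | places the surround Gaussian's useful mass on the ring |
| `pixelsPerDegree` | px/deg | 10 | the image-to-visual-angle link is scene-dependent and never implied by the image itself, so it is an explicit required parameter |
| `foveaHalfAngle` | deg | 2.5 | half of the ~5° high-acuity center |
| `rfIntercept`, `rfSlope` | px, px/deg | 3, 0.5 | eccentricity growth of the P field: monotone non-decreasing is the only property the biology fixes; a linear profile snapped up to odd integers is the simplest such choice, and a tabulated profile can be supplied |
| `fractionBits` | bits | off (1–24) | shift-add fixed point; error per weight ≤ 2^−(f+1) |

`foveaExtent(d, halfAngle)` returns `d·tan(halfAngle)` — 43.7 mm at 1 m,
56.8 mm at 1.3 m. Whether that number is a radius or a diameter of the
perceived circle is ambiguous in the source material ("a 43.7 mm circle");
the API therefore calls it an *extent* and reproduces the printed mapping
without adjudicating the geometry.

## The datapath emulation

`streamConvolve()` reproduces the raster-scan hardware delivery: `size − 1`
line buffers of the image width plus a `size × size` register window make a
full receptive field readable in parallel each cycle; the first valid output
appears after `(size−1)·width + size` ingested pixels (one pixel per cycle;
no clock modeling). Its output is *bit-identical* to `batchConvolve()`
because both evaluate the same expression, `sum(window * kernel)`, over
identical windows — an equality the tests check on hundreds of seeded random
images.

`vectorProductTree()` computes the per-pixel dot product both ways the
hardware could: one simultaneous multiply level followed by a balanced
binary adder tree (critical path `1 + ⌈log₂ n⌉` stages — 5 for n = 9), or a
sequential multiply-accumulate chain (one multiply stage plus n accumulate
stages — 10 for n = 9). The sequential formula `n + 1` is stated explicitly
here because only the two endpoints (10 and 5 at n = 9) are published; this
is the unique consistent stage accounting. With quantized weights both modes
run in exact integer arithmetic and agree bit for bit; the accumulator is
asserted (not saturated) to stay inside exact-integer range, which holds for
8-bit inputs whenever `f + 8 + ⌈log₂ n⌉ + 1 ≤ 53`.

Radial symmetry means a field stores one weight per distinct squared radius
(`distinctWeightCount()`): 3 slots for 3×3, 6 for 5×5. Weights quantize to
signed numerators over `2^f` with round-half-to-even (reproducible and
bias-free), and each numerator's set bits form the shift schedule that
replaces the multiplier.

The LUT cost tables in `inst/extdata/lut_costs.yaml` are published FPGA
synthesis figures supplied as *configuration inputs*; this package does not
synthesize hardware. The accounting narrative quotes 313 LUTs for the shared
red–green unit while the per-unit table lists 316; both are preserved, and
the bundled `rg_shared_cost: 313` is the value consistent with the published
1710-LUT without-sharing total (1397 + 313). The corresponding 5×5 "about
16%" figure has no reconstructible denominator in the published totals and
is not modeled.

## Numerical choices

Responses are evaluated in *deviation form* about the window's center
sample: since both regions have unit gain,
$X_{cen} - Y_{per} = \sum_i w^c_i (X_i - x_0) - \sum_j w^s_j (Y_j - y_0) +
(x_0 - y_0)$ exactly. Computing this form makes the opponent cancellation on
uniform input exact *in floating point* (every product is exactly zero) and
makes offset invariance exact for integer-valued planes — properties the
direct weighted-sum order only achieves to rounding error. The two
evaluation orders agree to ~$10^{-13}$ on 8-bit data; the test oracles use
the direct order precisely so the comparison is meaningful.

Other choices: region weight sums are validated to 1 within $10^{-12}$;
`rfSizeAt()` snaps the profile up to the smallest odd integer (never below
1); empty center or surround regions are configuration errors rather than
silently degenerate fields; a fovea mask with no pixels downgrades the M
channel to an empty map with a warning, since an image framed entirely in
the periphery is a legitimate input; 16-bit image input is rejected, not
rescaled, because the model is defined over 8-bit cone values.

## What the synthetic fixtures do and do not show

`generateFixture()` provides uniform fields (opponent null tests), color
discs (e.g. blue-on-yellow, the K-channel probe), bipartite edges and seeded
uniform noise (engine-equivalence and oracle tests). These are deterministic
byte-valued rasters: they exercise every arithmetic path, the region gating
and the streaming machinery exactly, but they contain no natural-image
statistics — no spatial correlation structure, no photometric noise, no
camera processing. Passing tests therefore certify the *computation*, not
perceptual claims about natural scenes; runs on photographs use the same
code paths via `readImage()`.

Problem sizes in the test suite — patches at 3×3 and 5×5, images from 5 to
64 pixels a side, 200 random images for the streaming/batch equality, 1000
patches for the algebraic identities, 10,000 weights for the quantization
bound — were chosen so each property is exercised across its structural
cases (odd/even tree widths, both field sizes, all three region-gating
regimes) while the whole suite stays interactive.

## Known limitations

* No temporal dynamics, adaptation, rod input or LGN relay modeling: maps
  are instantaneous opponent responses.
* The RGB→LMS default is the identity, as in the modeled design; a
  colorimetric 3×3 matrix can be supplied but no ICC-aware color management
  is attempted.
* The hardware emulation is algorithm-level only: no HDL, synthesis, timing
  or power figures are produced, and the cost model is exactly as good as
  the cost table supplied to it.
* Eccentricity growth of the P field is a monotone profile with a
  configurable slope, not a fit to anatomical data.
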