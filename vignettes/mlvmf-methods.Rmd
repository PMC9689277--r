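---
title: "Two-round directional-Laplacian detection of impulse noise: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-round directional-Laplacian detection of impulse noise: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlvmf)
```

## The problem

"Salt and pepper" impulse noise replaces random pixels of an 8-bit image with
one of the two extreme intensities, 0 or 255. It arises from transmission
errors, sensor dust and faulty memory, and it is particularly damaging to
medical radiographs, where downstream edge detection, segmentation and
automated diagnosis all degrade with the corrupted pixels. A good impulse
filter is *switching*: it first decides which pixels are corrupted and then
replaces only those, leaving everything else untouched. Both halves matter.
A missed impulse survives to bias later analysis; a false detection smooths a
pixel that carried real signal.

`mlvmf` implements such a switching filter for RGB (and grayscale-as-RGB)
images, together with the apparatus needed to study it: a seeded noise
simulator with ground-truth masks, phantom image generators, a vector median
baseline, and PSNR/NCD quality metrics.

## The detector

A noisy pixel is a local intensity outlier, so the natural probe is the
Laplacian (the sum of second spatial derivatives): any discrete Laplacian
stencil responds zero on constant patches and strongly on an isolated spike.
Rather than one isotropic stencil, the detector uses a bank of *directional*
5×5 zero-sum stencils, one per orientation, and takes the per-pixel
**minimum** of the absolute responses. The minimum is the conservative
choice: a pixel is only suspicious if it looks like an outlier from *every*
direction. A genuine edge or line produces a large response across it but a
near-zero response along it, so edges survive; an isolated impulse has no
quiet direction.

Concretely, for kernel $K_i$ and channel $I_j$ ($j = 1,2,3$ for red, green,
blue) the variation measurement is the absolute convolution response

$$V_{ij}(x,y) = \left| (K_i \otimes I_j)(x,y) \right|,$$

and one scan with the 8 kernels of a round produces $8 \times 3 = 24$
measurements per pixel, summarized by their minimum $M(x,y)$. The pixel is
declared an impulse when two tests pass:

1. $M(x,y) > T$ — the variation floor exceeds the threshold, and
2. the pixel's intensity *on the channel attaining the minimum* is exactly 0
   or 255.

The second rule is what keeps false positives near zero on real scenes:
high-contrast structure is common, but high-contrast structure whose value is
exactly an extreme is almost always noise. Detected pixels are replaced by
the vector median of their 3×3 neighborhood, and the rest pass through
byte-identical.

### The two kernel banks

The first-round bank K1–K8 covers orientations $0, \pi/8, \pi/4, \ldots,
7\pi/8$ — a rotation step of $\pi/8$, twice as fine as the $\pi/4$ step of
the four classic directional Laplacians, which is what a 5×5 window can
resolve. Each kernel places a $-1$ on the four lattice cells that best
approximate the line through the center at its orientation and carries a
$+4$ center; for the axis and diagonal orientations these are the exact line
cells at offsets 1 and 2, and for the $\pi/8$ family they are the
nearest-lattice cells the discrete grid offers (e.g. the $\pi/8$ kernel uses
$(0,\pm1)$ and $(\mp1,\pm2)$). All weights are integers and unnormalized;
the threshold lives on this raw response scale, and any rescaling of the
weights must rescale $T$ identically.

A high noise percentage creates **collisions**: two or more equal-valued
impulses that are 4- or 8-connected. A corrupted neighbor on a kernel's
negative cells cancels the center's response, so a cluster can hide itself
from round one (a horizontal run of five salt pixels zeroes the horizontal
kernel's response at its middle pixel, and the minimum rule then clears it).
The second-round bank K9–K16 is built for exactly this case: the same eight
orientations, but restricted to the ring at Chebyshev distance 2, so the
eight direct neighbors of the center carry weight exactly 0. After round one
has replaced the impulses it could see, round two re-scans the intermediate
image; a surviving impulse is then judged only against its outer ring, which
round one has largely cleaned. Exactly two rounds are run — the second bank
covers the collision geometry a 5×5 window can express, and iterating
further mostly re-tests pixels the 0/255 rule already released.

### Parameters

| parameter | default | meaning |
|---|---|---|
| `threshold` | 75 | variation floor on the raw integer-kernel scale (for a first-round kernel, $4\,\Delta$ where $\Delta$ is the center-to-neighborhood contrast, so 75 corresponds to a contrast of about 19 gray levels) |
| `norm` | `"L1"` | vector-median distance; L1 is integer-exact and the classic choice, L2 available |
| `border` | `"replicate"` | edge pixels are extended outward so all pixels, borders included, get 24 measurements; zero padding would manufacture spurious border responses |
| noise `mode` | `"monochrome"` | one corruption draw per pixel, all channels set together — the natural model for gray radiographs; `"channelwise"` models independent channel errors |
| `salt_fraction` | 0.5 | even salt/pepper split, the usual convention |

The same threshold is applied in both rounds. The argmin over the 24
measurements breaks ties toward the smallest (kernel id, channel id) pair,
and the vector median breaks distance-sum ties toward the earliest window
position in raster order; both rules are arbitrary but fixed, so results are
bit-reproducible.

## Replacement

The vector median of a 3×3 window is the member vector minimizing the sum of
distances to all other members — always an existing color, never an invented
blend, which is why it is preferred over channelwise medians for color data.
Replacement uses batch semantics: all replacement vectors are computed from
the round's input image before any pixel is written, so the output is
independent of scan order. The alternative (sequential in-place replacement,
where later windows see earlier repairs) propagates information in raster
order and makes the result depend on an arbitrary traversal; batch semantics
was chosen for reproducibility and order-independence.

## Quality metrics

PSNR uses the channel-averaged MSE of the 8-bit data,
$\mathrm{PSNR} = 10\log_{10}(255^2/\mathrm{MSE})$ in dB ($\log_{10}$ is the
standard dB convention; typical restoration values of 20–40 dB are only
consistent with it). Identical images are reported as the `Inf` sentinel.
NCD is the normalized color difference
$\sum\lVert(Y,U,V)-(Y_c,U_c,V_c)\rVert / \sum\lVert(Y,U,V)\rVert$ computed
in unquantized YUV. The RGB→YUV matrix is the analog BT.601 convention
($Y = 0.299R+0.587G+0.114B$, $U = 0.492(B-Y)$, $V = 0.877(R-Y)$); no
specific matrix is canonical for NCD, so the choice is documented here and
exposed as an attribute so an alternate convention can be swapped in and
compared. An all-black reference makes the NCD denominator zero and raises
an explicit error rather than returning NaN.

## What the synthetic phantoms emulate — and what they do not

The generator produces piecewise-smooth 8-bit scenes: `flat` (constant),
`gradient` (a linear ramp, on which every symmetric zero-sum kernel responds
zero up to rounding), `blocks` (constant tiles with step edges of at least
60 levels, the edge-heavy stress case), and `chest_like` (dark elliptical
lung fields, bright rib-like arcs and a mediastinum column on a vertical
gradient with mild seeded low-frequency illumination — the geometry, not the
physics, of a chest radiograph). All values stay in [1, 254] so every
planted 0/255 impulse is a real change, and `plant_collision` places
4-/8-connected equal-valued clusters at known positions for the two-round
tests.

These phantoms deliberately lack texture, film grain, anatomical clutter and
quantum noise. Passing tests on them show that the detector's logic is
correct (recall on isolated impulses, collision recovery, edge tolerance,
zero false positives when no clean value is extreme), not that the default
threshold is optimal for any particular clinical archive; on real images
with fine texture whose local contrast exceeds ~19 levels *and* whose values
reach exact extremes, false detections are possible and only the 0/255 rule
limits them.

## Numerical choices and degenerate inputs

All convolutions are integer arithmetic on doubles (exact well below 2^53),
so oracle comparisons in the test suite assert exact equality, not
tolerances. Images must be 8-bit; 16-bit input is rejected rather than
rescaled, because the 0/255 rule is meaningless after silent rescaling.
Grayscale files are replicated to three channels on load and collapse back
to one channel when saved as PGM. A noise percentage of 0 returns the input
byte-identical; 100% with `salt_fraction` 1 saturates the image. The
corruption masks record positions whose stored value actually changed, so
"corrupting" a pixel that already sat at the drawn extreme is not counted —
the mask is exactly the set of differing samples.

## Evaluation protocol

`evaluate_filters()` reproduces the standard benchmark layout: for each
(image, noise level, seed) it corrupts, filters, and scores PSNR and NCD
against the clean reference. The package's own acceptance run uses the two
structured 256×256 phantoms at noise levels 3, 5, 10, 20 and 30% with a
handful of seeds — sizes chosen to match the common 256×256 benchmark images
while keeping a full sweep comfortably inside a coffee break — and checks
the ordering MLVMF ≥ VMF > noisy on mean PSNR in every cell. On these runs
the two-round filter beats the whole-image vector median by several dB at
every level (the gap grows with noise, where the collision round matters
most), while touching only 10–30% of pixels.

```{r, eval = FALSE}
ph <- make_phantom("chest_like", 256, 256, seed = 8)
noisy <- add_salt_pepper(ph, noise_spec(10, seed = 1))$noisy
res <- mlvmf(noisy)
psnr(ph, res$restored)$psnr_db
```

## Known limitations

* Non-extreme ("random-valued") impulse noise is invisible to the 0/255
  rule by design; the filter targets salt-and-pepper corruption only.
* Very large same-valued clusters (diameter beyond the 5×5 window) can
  survive both rounds; the second bank sees past one ring of corrupted
  neighbors, not two.
* Pixels whose true value is exactly 0 or 255 in a high-variation
  neighborhood (e.g. specular highlights on a dark edge) can be falsely
  replaced; on radiograph-like content with values inside (0, 255) this
  does not occur.
* The threshold is global and fixed; no per-image adaptation is attempted.
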