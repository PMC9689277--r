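# mlvmf — two-round impulse-noise removal for 8-bit images

`mlvmf` removes "salt and pepper" impulse noise — random pixels forced to
the extreme intensities 0 or 255 by transmission errors, sensor dust or bad
memory — from 8-bit RGB and grayscale images, with chest radiographs as the
motivating use case. It is a *switching* filter: it first identifies the
corrupted pixels, then replaces only those, so clean pixels pass through
byte-identical.

## The method

Detection uses a bank of sixteen 5×5 zero-sum directional Laplacian
stencils, eight per round, at orientations 0, π/8, π/4, …, 7π/8. For each
kernel K<sub>i</sub> (i = 1…16) and color channel I<sub>j</sub> (j = 1, 2, 3
for red, green, blue) the variation measurement is the absolute convolution
response

> V<sub>ij</sub>(x, y) = | (K<sub>i</sub> ⊗ I<sub>j</sub>)(x, y) |

giving 24 measurements per pixel per scan. A pixel is declared an impulse
when the **minimum** M(x, y) of its 24 measurements exceeds a threshold
*T* (default 75) *and* its intensity on the channel attaining that minimum
is exactly 0 or 255. The minimum rule spares genuine edges (an edge always
has a quiet direction); the extreme-value rule spares high-contrast clean
structure. Detected pixels are replaced by the **vector median** of their
3×3 neighborhood — the window color minimizing the sum of L1 distances to
all other window colors, always an existing color.

Clusters of equal-valued impulses ("collisions", 4- or 8-connected) can
cancel each other's responses and hide from this scan. A second round
therefore re-scans the once-filtered image with eight kernels restricted to
the ring at Chebyshev distance 2 — the eight direct neighbors carry weight
exactly 0 — so a clustered impulse is judged only against its outer,
already-cleaned ring. Exactly two rounds are run.

The package also provides the seeded noise simulator with ground-truth
masks, phantom generators (`flat`, `gradient`, `blocks`, `chest_like`), a
whole-image vector median baseline (`vmf_full`), and the PSNR (dB,
channel-averaged MSE) and NCD (normalized color difference in BT.601 YUV)
quality metrics.

## Worked example

```r
library(mlvmf)

ph  <- make_phantom("chest_like", 256, 256, seed = 8)   # clean phantom
rec <- add_salt_pepper(ph, noise_spec(10, seed = 1))    # 10% monochrome noise
res <- mlvmf(rec$noisy)                                 # two-round filter
res
#> <mlvmf_result: 256 x 256 image, T = 75, L1 norm>
#>   flagged: 6598 (round 1) + 3 (round 2)

psnr(ph, rec$noisy)$psnr_db      # 15.30 dB  -- the corrupted image
psnr(ph, res$restored)$psnr_db   # 33.52 dB  -- after filtering
ncd(ph, res$restored)            # 0.00219   -- residual color distortion
```

About 10% of the pixels were flagged (matching the injected noise rate; the
three round-2 detections are impulses whose clustered neighbors blinded the
first scan), PSNR improves by ~18 dB, and every unflagged pixel is
byte-identical to the input. `evaluate_filters()` runs the full benchmark
grid (images × noise levels × filters × seeds) and returns a tidy table of
PSNR/NCD rows.

A command-line front end covering the same operations (`kernels`, `phantom`,
`inject`, `detect`, `vmf`, `denoise`, `metrics`, `bench`) ships at
`inst/cli/mlvmf.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/mlvmf.R", package = "mlvmf"))')" \
    denoise --threshold 75 in.png out.png --report report.json
```

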