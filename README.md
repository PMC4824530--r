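# hpft

Piecewise-homographic registration of endoscopic-style image pairs and
sequences, with a complete precision / robustness / uniformity evaluation
scheme and a seeded synthetic-scene generator.

## The problem

Registering gastroscopic frames is hard: the stomach wall deforms, the
camera moves freely, lighting is non-uniform, and wet mucosa throws
saturated specular highlights that move with the light rather than the
tissue. Global rigid models fail, and fully non-rigid models are
under-constrained. This package implements a middle ground: the organ
surface is treated as a mosaic of small planar patches, so that locally
the mapping between two views is a homography — in its six-parameter
affine form

    m' = H m,   H = | a b c |
                    | d e f |
                    | 0 0 1 |

determined exactly by the three vertex correspondences of a triangle.
Matched interest points are Delaunay-triangulated; each triangle's affine
map is validated by the normalized cross-correlation (Dif_H) of its warped
interior, and triangles that fail are split at their incircle center. The
center is matched along the intersection of its epipolar line with the
corresponding triangle (candidates every 1 px, accepted only when the
nearest/second-nearest ratio of the 32-element SIFT descriptor distance
V = Σ(e_i − e_i')² stays below 0.8 and V_min < ε), in both directions.
The loop repeats to a fixpoint, producing a dense set of matched points
and validated patches.

The evaluation scheme tracks features forward through a sequence and back:
PPV (precision percent validation) is the fraction of the 200-feature
budget returning within 4 px; trajectory forward/backward distributions
are compared by Kullback–Leibler divergence; robustness re-registers under
injected Gaussian noise and scores each point's positional covariance
(RPV = robust fraction of the FB-reliable count); uniformity is a
chi-square statistic of the match coordinates.

For whom: anyone needing feature-level registration of smooth deformable
surfaces with built-in self-validation — endoscopic mosaicking, lesion
tracking, or as a reference implementation of the patch-split registration
scheme on fully synthetic, reproducible ground truth.

## A worked example

```r
library(hpft)

# a synthetic scene with exact ground truth: 560x480 texture, mild affine
# viewpoint change, additive noise (sigma 5 gray levels)
th <- 3 * pi / 180
H  <- rbind(c(cos(th) * 1.03, -sin(th),        8),
            c(sin(th),         cos(th) * 1.03, -5),
            c(0, 0, 1))
tex   <- generate_textured_plane(560, 480, seed = 1)
scene <- warp_scene(tex, H, noise_sigma = 5, seed = 2)

fit <- hpft(scene$reference, scene$target, control = hpft_control(seed = 1))
print(fit)
#> Homographic Patch Feature Transform registration
#>   560 x 480 images; 150 matched points (150 initial inliers), 283 matched patches
#>   converged after 1 iteration(s)

summary(fit)
#> Matched points: 150 (initial: 150)
#> Matched patches: 283, covering 78.5% of the frame
#> Patch NCC: min 0.912, median 0.960, max 0.987
#> Iterations: 1

# how close are the matches to the known truth?
truth <- cbind(fit$matches$x_ref, fit$matches$y_ref, 1) %*% t(H)
err   <- sqrt((truth[, 1] - fit$matches$x_tgt)^2 +
              (truth[, 2] - fit$matches$y_tgt)^2)
mean(err < 2)
#> [1] 0.9933333
```

A single plane is validated almost everywhere in one loop — every
triangle's affine map passes NCC validation, so nothing needs splitting.
On a folded (two-plane) scene the trace shows the iterative refinement:
patches straddling the fold fail validation, their incircle centers are
matched along epipolar segments, and the match set grows until the fold is
resolved:

```r
pw   <- generate_piecewise_planar_scene(560, 480, n_patches = 2, seed = 5)
pfit <- hpft(pw$reference, pw$target, control = hpft_control(seed = 1))
pfit$trace
#>   iteration matches patches new_points new_patches
#> 1         1     154     276          3         276
#> 2         2     158     282          4           6
#> 3         3     161     291          3           9
#> 4         4     162     296          1           5
#> 5         5     162     296          0           0
```

Sequence evaluation runs the full scheme (numbers from the shipped
10-frame, 320x240, noise-sigma-5 sequence):

```r
sq <- generate_affine_sequence(10, 320, 240, seed = 11, noise_sigma = 5)
ev <- evaluate_sequence(sq, hpft_control(seed = 1), sigmas = c(2, 5, 10), M = 9)
print(ev)
#> HPFT sequence evaluation
#>   initial features: 200; FB-reliable (<= 4 px): 195
#>   PPV: 0.975   RPV: 0.272
#>   D_KL pass: 185 (D_KL / FB ratio 0.95)
#>   uniformity: ux 61.9, uy 62.3
```

PPV 0.975 means 195 of the 200 budgeted features survive the
forward-and-back trip within 4 px; the D_KL/FB ratio of 0.95 says the
divergence check confirms almost all of them. The low RPV reflects a real
property of the default stress test: with noise at sigma 10 injected into
both images, single-feature localization jitter exceeds the 0.25 px that a
0.8 stability score requires (see the methods vignette for the analysis).

A thin command-line front end covers the four workflows:

```sh
inst/cli/hpft synth    --kind piecewise --size 560x480 --n-patches 6 --seed 1 --out scene/
inst/cli/hpft register scene/reference.png scene/target.png --out results/
inst/cli/hpft track    frames/ --config run.yaml --out results/
inst/cli/hpft evaluate frames/ --noise 2,5,10 --reps 9 --seed 1 --out report.json
```

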