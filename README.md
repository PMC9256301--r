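# snakeseg

Active contour ("snake") segmentation of 2-D grayscale images — such as
vertebral bodies in spinal MRI slices — with gradient vector flow (GVF)
external forces and a prior-knowledge force that combines a GVF term with
an outward-normal balloon term under a reciprocal centroid-distance
weight. The package is aimed at researchers studying deformable-model
segmentation who need a reproducible, fully scriptable 2-D testbed:
every component (energies, forces, evolution, phantoms, evaluation) is an
ordinary R function returning tibbles or plain matrices.

## The model

A snake is a closed curve $L(s)$ minimizing

$$E = \int_0^1 \tfrac12\big(\alpha|L'|^2 + \beta|L''|^2\big) + E_{ext}(L(s))\,ds,$$

evolved by $L_t = \alpha L'' - \beta L'''' + F_{ext}$. Three external
force models are provided:

| model | $F_{ext}$ | behavior |
|---|---|---|
| `classic` | $-\nabla E_{ext}$ | short capture range, cannot enter concavities |
| `gvf` | $B(x,y)$, the diffused gradient-vector-flow field of the edge map | long capture range, reaches into concavities |
| `prior_gvf` | $\frac{1}{\lVert L - C\rVert}\,(k_1 B + k_2 N)$ | balloon term $N$ drives flat regions, GVF term holds edges, reciprocal distance to the contour centroid $C$ damps and smooths |

Dice overlap ($2|A\cap B|/(|A|+|B|)$) against analytic ground truth from
the built-in phantom generator (disk, U-shape concavity, noisy perturbed
vertebral body, two-vertebra distractor scene) quantifies each model.

## Worked example

```r
library(snakeseg)

ph  <- generate_phantom(phantom_spec("disk"))       # analytic ground truth
fit <- run_snake(ph$image, ph$suggested_init,
                 snake_params(max_iter = 500), force_model = "prior_gvf")
glance(fit, truth = ph$target)
#> # A tibble: 1 x 6
#>   force_model n_points iterations converged final_displacement  dice
#>   <chr>          <int>      <int> <lgl>                  <dbl> <dbl>
#> 1 prior_gvf        127        500 FALSE                0.00329 0.998
autoplot(fit, init = ph$suggested_init)             # image + contours
```

The one-row `glance()` says the contour (127 resampled points) expanded
from the seed circle to the disk boundary and overlaps the truth mask at
Dice 0.998. The full three-model comparison over the four-phantom suite:

```r
cmd_benchmark(seed = 1, out_dir = "bench")
#> classic    mean dice 0.0003
#> gvf        mean dice 0.5476
#> prior_gvf  mean dice 0.9734
```

— the classic snake never reaches the boundary from a small interior
seed, plain GVF solves the disk but fails the concavity and leaks through
the weak edge of the distractor scene, and the prior-guided force
segments all four phantoms. `bench/report.csv` holds the per-phantom
rows.

A command-line wrapper with `segment`, `phantom`, `gvf` and `benchmark`
subcommands is installed at
`system.file("cli", "snakeseg.R", package = "snakeseg")`.

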