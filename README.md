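# cellforce

Estimation of the mechanical forces a migrating cell exerts on its membrane,
from nothing more than a segmented time-lapse video.

## The problem and the approach

Forces at the membrane of a migrating cell — F-actin driven protrusion at the
leading edge, myosin-driven retraction at the rear — are notoriously hard to
measure directly. `cellforce` infers them by *fitting a mechanical model to
the observed motion*. The cell is represented by a phase field
$\phi(\bar{x},\bar{t})$ on the unit square ($\phi\approx+1$ inside,
$-1$ outside; the zero level set is the membrane), evolving under a forced,
volume-constrained Allen–Cahn equation — a diffuse-interface approximation
of forced mean curvature flow:

$$\bar\epsilon\,\bar\tau\,\partial_{\bar t}\phi
  = \bar\delta\,\bar\epsilon\,\Delta\phi
  - \frac{\bar\delta}{\bar\epsilon}G'(\phi)
  + \bar\eta + \lambda(\bar t),
  \qquad \nabla\phi\cdot\nu = 0 \text{ on } \partial\bar\Omega,$$

with $G(\phi)=\tfrac14(1-\phi^2)^2$, surface tension $\bar\delta$, friction
$\bar\tau$, interfacial width $\bar\epsilon$, a spatially constant Lagrange
multiplier $\lambda$ tracking the segmented cell area, and an unknown
membrane force density $\bar\eta$ supported near the membrane
($\bar\eta>0$: protrusion, $\bar\eta<0$: retraction).

Given two consecutive segmented frames, the force is the minimiser of

$$J(\eta;\phi)=\frac{\theta}{2}\int_0^1\!\!\int_{\bar\Omega}\bar\eta^2
 \;+\; \frac12\sum_i\int_{\bar\Omega}\bigl(\phi(\bar t_i)-\phi_{obs,i}\bigr)^2,$$

computed by projected gradient descent with the **exact adjoint of the
discrete scheme** (semi-implicit IMEX, sparse Cholesky, discretise-then-
optimise), so the gradient matches finite differences to ~1e-9. Frame pairs
are chained through the video; per pair the package reports membrane length,
accumulated protrusion/retraction force in pN and the membrane percentage
under each, and a diffuse-interface Euler number that counts cells and
flags division or fusion events automatically.

Physical units enter through the characteristic scales $L$ (domain, µm),
$T$ (duration, s) and $F$ (force, pN): $\bar\tau=\tau L^2/(F\,T)$,
$\bar\delta=\delta/F$, and a fitted $\bar\eta$ converts back to pN/µm as
$\eta=\bar\eta F/L$.

## Worked example

Track a synthetic bright-on-dark cell translating across a 100 µm field of
view (five frames, 60 s apart) and summarise the fitted forces:

```r
library(cellforce)

movie <- makeTranslatingDiskMovie(n_frames = 5, npix = 128, v = c(0.2, 0),
                                  L = 100, TI = 60, seed = 7)
cfg <- runConfig(domain_length_um = 100, total_time_s = 240,
                 frame_interval_s = 60, eps_bar = 0.05, RTS = 5,
                 grid_n = 64, output_dir = "run1")
man <- runTracking(cfg, movie)
read.csv("run1/forces.csv")
```

```
  frame_pair avg_membrane_length_um total_protrusion_pN protrusion_pct total_retraction_pN retraction_pct
1        1-2               118.7843            121.3037       80.45715            7.822338       19.54285
2        2-3               118.7317            120.7055       81.62297            6.815890       18.37703
3        3-4               118.6839            120.4717       80.60583            7.058419       19.39417
4        4-5               118.6930            120.9546       80.53268            7.136268       19.46732
```

Reading the table: the reconstructed membrane is ≈119 µm long (a 20 µm-radius
cell, slightly smoothed by segmentation); because the cell translates
rigidly, protrusion dominates (≈120 pN accumulated over the 5 reconstructed
steps of each pair, on ~80% of the membrane — the leading edge) while weak
retraction acts on the trailing ~20%. `run1/euler.csv` holds the
cell-count trace (constant 1 here; it steps to 2 at a division), and
`run1/manifest.json` records the configuration, per-pair convergence and
objective values. A command-line wrapper with `generate`, `segment`,
`track`, `summarize` and `count` subcommands lives in `inst/cli/cellforce.R`.

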