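# fluororeg

Rigid 3D2D registration of individual vertebrae from a CT-like
attenuation volume to two angulated fluoroscopic views, for navigated
spine surgery. The registration needs no bone- or table-mounted
instruments and no C-arm tracking or calibration: the unknown relative
pose between the two views is recovered from radiopaque skin-marker
spheres, and each vertebra is then registered separately, which absorbs
inter-vertebral motion between the preoperative CT and the
intraoperative scene.

The package contains the full experimental chain: a procedural spine
phantom with ground-truth per-vertebra poses, a ray-driven DRR
projector, the similarity measure and optimizer, marker detection /
correspondence / relative-pose estimation, the two-stage registration
driver, and a target-registration-error (TRE) evaluation harness with
rotation-angle-difference (RAD) sweep experiments.

## The method

Candidate poses are scored by comparing digitally reconstructed
radiographs (DRRs) of the segmented vertebra against the fluoroscopic
images with a gradient-difference similarity

$$S = \sum_{i,j} \frac{A_v}{A_v + I_{\mathrm{diffV}}(i,j)^2}
    + \sum_{i,j} \frac{A_h}{A_h + I_{\mathrm{diffH}}(i,j)^2},
\qquad
I_{\mathrm{diffV}} = \frac{dI_{\mathrm{fl}}}{di} - s\frac{dI_{\mathrm{DRR}}}{di},
\quad
I_{\mathrm{diffH}} = \frac{dI_{\mathrm{fl}}}{dj} - s\frac{dI_{\mathrm{DRR}}}{dj},
$$

maximized over the 6-DOF rigid pose `q = (tx, ty, tz, wx, wy, wz)` with
CMA-ES, in two stages: a coarse single-view registration of two
adjacent vertebrae, then a per-vertebra registration against both views
simultaneously, with the view-2 geometry given by composing view 1 with
the marker-estimated relative pose (an Umeyama-based alternating
triangulation/alignment scheme). Accuracy is quantified by the TRE at
the vertebral body center, with the left pedicle center as a second
landmark indicating rotational error, and summarized by median/IQR with
Tukey-fence outliers. See the methods vignette
(`vignettes/fluororeg-methods.Rmd`) for models, parameter defaults and
design decisions.

## Worked example

Simulate a complete test case (five vertebrae, eight skin markers,
opposed ±45° views, realistic noise), register it, and evaluate against
the known ground truth:

```r
library(fluororeg)

tc <- makeTestCase(caseConfig(angulations = c(-45, 45)), seed = 42)
tc
#> SpineTestCase: 5 vertebrae, 8 markers, nominal RAD 90 deg (true 93.33)
#>   views 256 x 256 px, seed 42

run <- registerCase(tc, registrationConfig(), seed = 1)
sprintf("estimated RAD: %.2f deg (true %.2f)",
        run$radEstimate, rad(trueRelativePose(tc)))
#> "estimated RAD: 93.16 deg (true 93.33)"

tab <- evaluateCase(tc, run)
tab[, c("label", "status", "tre", "ex", "ey", "ez", "rotIndicator")]
#>   label     status   tre     ex     ey      ez rotIndicator
#> 1   T11 registered 0.113 -0.096  0.059 -0.0058       0.2613
#> 2   T12 registered 0.043  0.035  0.012 -0.0221      -0.0029
#> 3    L1 registered 0.153 -0.124 -0.028 -0.0850       0.0575
#> 4    L2 registered 0.080  0.057  0.042  0.0355       0.0199
#> 5    L3 registered 0.098 -0.092  0.013  0.0307       0.0455

s <- summarizeTre(tab$tre)
sprintf("median TRE %.2f mm [IQR %.2f-%.2f], max %.2f mm", s$median, s$q1, s$q3, s$max)
#> "median TRE 0.10 mm [IQR 0.08-0.11], max 0.15 mm"
```

The C-arm angulations are jittered by ±3° around their declared values
(the true RAD of 93.33° vs the nominal 90°); the marker chain recovers
the actual relative pose to a fraction of a degree, and all five
vertebrae register to ~0.1 mm at the body center on this noise level.
`tre` is the body-center TRE in mm, `ex`/`ey`/`ez` its signed patient-axis
components (+z dorsal), and `rotIndicator` the pedicle-minus-body TRE
difference.

A command-line front end wraps the same functions
(`inst/cli/fluororeg`): subcommands `phantom`, `simulate`, `register`,
`evaluate`, `sweep`; every output directory carries a manifest and the
resolved configuration.

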