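# srrf

Super-resolution radial fluctuations (SRRF) reconstruction for
fluorescence image sequences, with a blinking-fluorophore EMCCD
simulator and resolution metrics, in R.

## Who this is for

Fluorescence microscopists and image-analysis developers who want
super-resolved images from ordinary widefield/TIRF/confocal image
sequences of blinking or fluctuating fluorophores — without detecting
and fitting single molecules, and therefore also at emitter densities
where localization microscopy breaks down. The package also serves as a
reproducible in-silico benchmark: it simulates the full imaging chain
(ground-truth structures, two-state photoswitching, Gaussian PSF, EMCCD
noise) and measures resolution with standard criteria.

## The method

Each frame \(I_t\) is transformed into a sub-pixel *radiality* map: for
every centre \(c\) on an \(M\times\) magnified grid, \(N\) points
\(p_k\) on a ring of radius \(r\) probe the interpolated image gradient
\(g(p_k)\), and

\[ R_t(c) = \frac{1}{N}\sum_k s_k\left(1-\frac{\min(d_k,r)}{r}\right)^2,
\qquad
s_k = \operatorname{sign}\,\langle g(p_k),\, c-p_k\rangle, \]

where \(d_k\) is the perpendicular distance from \(c\) to the gradient
line through \(p_k\). \(R = 1\) at the centre of a radially symmetric
PSF, 0 on flat fields, and is independent of the intensity scale. After
optional intensity/gradient weighting, the radiality stack is collapsed
pixel-wise by a temporal statistic — mean, pairwise auto-correlation
\(\mathrm{mean}_t[\delta R_t \delta R_{t+\ell}]\) (default, lag 0), or
SOFI-style auto-cumulants \(\kappa_2\ldots\kappa_4\) — into one
super-resolved image. Emitter-driven radiality peaks recur in time;
noise-driven peaks decorrelate and vanish.

## Worked example

Two fluorophores 135 nm apart (one PSF standard deviation — far below
the ~320 nm diffraction limit), blinking independently over 100 frames:

```r
library(srrf)

cam   <- camera_model()                 # 100 nm px, sigma 135 nm, EMCCD
field <- emitter_field(rbind(c(-67.5, 0), c(67.5, 0)),
                       mean_photon_rate = 6e4)
movie <- simulate_movie(field, blink_kinetics(0.2, 0.8), cam,
                        n_frames = 100, seed = 21)

img <- srrf_reconstruct(movie$stack,
                        radiality_settings(magnification = 10),
                        temporal_settings("pairwise_correlation"))

fov <- movie$stack$metadata$fov
xs  <- (seq_len(ncol(img$values)) - 0.5) * img$pixel_size_nm + fov$x0_nm
rows <- abs((seq_len(nrow(img$values)) - 0.5) * img$pixel_size_nm +
            fov$y0_nm) < 100
prof <- data.frame(position_nm = xs[abs(xs) < 250],
                   intensity   = colMeans(img$values[rows, abs(xs) < 250]))
sparrow_resolved(prof)[c("resolved", "separation_nm")]
#> $resolved
#> [1] TRUE
#> $separation_nm
#> [1] 70
```

The SRRF image shows two Sparrow-resolved maxima (their apparent
separation is pulled inward at this distance, as for any overlapping
pair), while the diffraction-limited temporal mean of the same movie is
a single blob:

```r
dl <- temporal_mean(movie$stack$frames, 100)
pd <- data.frame(position_nm = (seq_len(ncol(dl$values)) - 0.5) * 100 +
                     fov$x0_nm,
                 intensity = colMeans(dl$values))
sparrow_resolved(pd)$resolved
#> [1] FALSE
```

A command-line interface wrapping the same functions ships in
`inst/scripts/srrf` (subcommands `simulate`, `run`, `frc`, `profile`,
`visibility`, `dnn`, `average`; every run writes a `manifest.json` with
the full configuration and seed).

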