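# reoct — resolution-enhanced OCT by coherent averaging and computational bandwidth expansion

`reoct` is an R toolkit for **resolution-enhanced optical coherence
tomography (RE-OCT)**: enhancing the transverse resolution of a beam-scanned
OCT system *beyond its aberration-free limit* without touching the optics.
It is aimed at researchers working with complex-valued (magnitude + phase)
OCT tomograms who want to trade earned signal-to-noise ratio for
resolution, and at anyone studying noise, dynamic range, and phase
correlation in coherent imaging.

## The idea

Most beam-scanned OCT systems use a Gaussian beam that under-fills the
objective aperture (telecentric scanning), so the transverse
spatial-frequency spectrum of an en face tomogram is a smooth Gaussian that
sinks into the system noise floor well before the sampling Nyquist limit
`k_Nyq = pi / pitch`.  The information capacity of the system,

    C = (2 Lx Bx + 1)(2 Ly By + 1)(2 Lz Bz + 1)(2 T B_T + 1) log2(1 + s/n),

is invariant — but its terms can be exchanged.  Coherently averaging N
successively acquired complex frames reduces the noise power `n` by a
factor N (random-phase noise cancels; phase-stable signal survives),
raising the spatial-frequency dynamic range

    DR = 10 log10( |S(0)|^2 / mean |N(k)|^2 )

by `10 log10(N)` dB.  That headroom is then spent by **bandwidth
expansion**: the spectrum is multiplied by the radially symmetric
Gaussian-ratio magnitude mask

    gain(kr) = exp[ (kr^2 / (2 sigma_k^2)) (1 − 1/b^2) ],

which stretches the fitted Gaussian amplitude spectrum
(`sigma_k -> b sigma_k`) and thus narrows the magnitude PSF by the BE
factor `b`.  The achieved **RE factor** (baseline FWHM / enhanced FWHM)
divided by `b` is the **efficiency**: 1 in the noise-free limit, and
decreasing with `b` once expansion runs into the noise floor — the
phase-correlation limit of the spectrum bounds what any expansion can
recover.

The package implements the full pipeline — frame registration (bulk shift +
global phase), coherent/incoherent averaging, paraxial refocus, spectrum
model fit, BE mask, zero-pad upsampling — plus the metrology (noise
intensity, DR, phase-correlation limit, 32-angle radial Gaussian PSF fits,
SBR, efficiency) and a synthetic coherent-imaging simulator that generates
phantom stacks and paired noise images with explicit seeds.

## Worked example

Simulate a nine-particle phantom (2.1 µm magnitude-PSF FWHM, 0.4 µm/pixel,
noise set for a ~30 dB single-shot DR) with a paired noise stack, then run
RE-OCT with N = 100 and b = 2.0:

```r
library(reoct)

particles <- data.frame(x_um = c(16, 48, 80, 18, 52, 84, 20, 50, 84),
                        y_um = c(16, 20, 18, 50, 50, 52, 82, 84, 84),
                        amplitude = 1)
spec0 <- phantom_spec(grid_size = 256, pitch = 0.4, particles = particles,
                      psf_magnitude_fwhm = 2.1)
s0 <- to_spectrum(coherent_average(synthesize_stack(spec0, 1)))
noise_sigma <- sqrt(Mod(s0$values[s0$dc_row, s0$dc_col])^2 / (10^3 * 256^2))

spec  <- phantom_spec(grid_size = 256, pitch = 0.4, particles = particles,
                      psf_magnitude_fwhm = 2.1, noise_sigma = noise_sigma, seed = 1)
stack <- synthesize_stack(spec, 100)
noise <- synthesize_noise_stack(256, 256, noise_sigma = noise_sigma,
                                n_frames = 100, seed = 2)

dr1   <- dynamic_range(coherent_average(stack, 1),   coherent_average(noise, 1))
dr100 <- dynamic_range(coherent_average(stack, 100), coherent_average(noise, 100))
sprintf("single-shot DR: %.1f dB ; coherent-average DR (N=100): %.1f dB",
        dr1$dr_db, dr100$dr_db)
#> "single-shot DR: 29.8 dB ; coherent-average DR (N=100): 50.0 dB"

res <- run_reoct(stack, noise, reoct_config(n = 100, be_factor = 2.0, upsample = 4))
res$report
#> <resolution_report> n = 9 particles | FWHM 1.318 +/- 0.012 um (baseline 2.103 um)
#>   RE factor 1.596 at BE factor 2.00 -> efficiency 0.798 | SBR 30.8 dB
```

Averaging 100 frames earned 20 dB of dynamic range; spending it at b = 2.0
narrowed the measured PSF from 2.10 µm to 1.32 µm (RE factor 1.6) at
efficiency 0.80 — short of 1 because the expansion already reaches into the
suppressed noise floor.  A noise-free run of the same sweep keeps the
efficiency within 0.03 of 1 at every b up to 2.4.

A thin command-line front end over the same functions ships in
`inst/cli/reoct.R` (subcommands `simulate`, `register`, `average`,
`spectrum`, `phase-limit`, `enhance`, `sweep`, `fig3`, `info-capacity`),
reading/writing HDF5 stacks (`real`/`imag` planes of shape (N, H, W) with
pitch and provenance attributes).

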