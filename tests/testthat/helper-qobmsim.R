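# Shared fixtures and independent oracles for the test suite.

tiny_system <- function(n = 32L, pixel_um = 0.25)
  optical_system(0.72, 0.6, pixel_um, c(n, n))

# Direct double-loop evaluation of the weak-object transfer functions on
# the circular DFT lattice: the independent oracle for compute_wotf.
wotf_bruteforce <- function(pupil, weights) {
  nr <- nrow(pupil); nc <- ncol(pupil)
  Gam <- matrix(0 + 0i, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ri <- ((seq_len(nr) - 1L + i - 1L) %% nr) + 1L
    ci <- ((seq_len(nc) - 1L + j - 1L) %% nc) + 1L
    Gam[i, j] <- sum(weights * Conj(pupil) * pupil[ri, ci])
  }
  neg <- function(m) m[c(1L, nr:2L), c(1L, nc:2L)]
  Gn <- neg(Gam)
  list(H_abs = -(Gam + Conj(Gn)), H_ph = 1i * (Gam - Conj(Gn)),
       B = sum(weights * Mod(pupil)^2))
}

# Band-limited pure-phase phantom: white noise restricted to an annulus
# of the frequency lattice and scaled to a given peak phase.
bandlimited_phase <- function(grid, f_lo_frac = 0.1, f_hi_frac = 0.7,
                              peak = 0.3, seed = 1) {
  nr <- grid$shape[1]; nc <- grid$shape[2]
  fc <- grid$f_cutoff
  band <- grid$fr >= f_lo_frac * fc & grid$fr <= f_hi_frac * fc
  set.seed(seed)
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  zb <- Re(stats::fft(stats::fft(z) * band, inverse = TRUE)) / (nr * nc)
  list(phase = zb / max(abs(zb)) * peak, band = band)
}

# RMS of the in-band component of (rec - truth), as a fraction of `peak`.
band_rmse_frac <- function(rec, truth, band, peak) {
  err <- Re(stats::fft(stats::fft(rec - truth) * band, inverse = TRUE)) /
    length(rec)
  sqrt(mean(err^2)) / peak
}

# Lattice cosine phase pattern with integer frequency indices (ki, kj).
lattice_cosine <- function(n, ki, kj, a = 0.05) {
  r <- matrix(seq_len(n) - 1, n, n)
  c_ <- matrix(seq_len(n) - 1, n, n, byrow = TRUE)
  a * cos(2 * pi * (ki * r / n + kj * c_ / n))
}

small_phantom_args <- function()
  list(n_nuclei = 3L, nucleus_radius_um = c(2, 3), n_inclusions = 1L,
       inclusion_radius_um = c(0.8, 1.2))
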