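#' Describe the imaging system
#'
#' Bundles the optical parameters that define the pupil and the discrete
#' frequency lattice used by every transfer-function computation: the
#' illumination wavelength, the objective numerical aperture, the
#' object-plane pixel pitch and the simulation grid size.
#'
#' The pupil cutoff frequency is \code{na_objective / wavelength_um}
#' (cycles/um). If that cutoff exceeds the grid Nyquist frequency
#' \code{1 / (2 * pixel_um)}, the grid undersamples the optical passband and
#' a warning is raised; the object is still constructed.
#'
#' @param wavelength_um illumination wavelength in micrometres (> 0).
#' @param na_objective objective numerical aperture, in (0, 1].
#' @param pixel_um object-plane sampling in micrometres per pixel (> 0).
#' @param shape integer vector \code{c(rows, cols)}; both even and >= 16.
#' @return An object of class \code{qobm_system}.
#' @examples
#' sys <- optical_system(0.72, 0.6, 0.25, c(256, 256))
#' sys$f_cutoff  # NA / lambda = 0.8333 cycles/um
#' @export
optical_system <- function(wavelength_um, na_objective, pixel_um,
                           shape = c(256L, 256L)) {
  stopifnot(is.numeric(wavelength_um), length(wavelength_um) == 1L,
            wavelength_um > 0,
            is.numeric(na_objective), length(na_objective) == 1L,
            na_objective > 0, na_objective <= 1,
            is.numeric(pixel_um), length(pixel_um) == 1L, pixel_um > 0,
            is.numeric(shape), length(shape) == 2L)
  shape <- as.integer(shape)
  if (any(shape < 16L) || any(shape %% 2L != 0L))
    stop("shape must be c(rows, cols) with both even and >= 16")
  f_cutoff <- na_objective / wavelength_um
  f_nyquist <- 1 / (2 * pixel_um)
  if (f_cutoff > f_nyquist)
    warning(sprintf(paste0(
      "pupil cutoff %.4g cycles/um exceeds the grid Nyquist frequency ",
      "%.4g cycles/um; the passband is undersampled at pixel_um = %g"),
      f_cutoff, f_nyquist, pixel_um))
  structure(list(wavelength_um = wavelength_um,
                 na_objective = na_objective,
                 pixel_um = pixel_um,
                 shape = shape,
                 f_cutoff = f_cutoff),
            class = "qobm_system")
}

#' @export
print.qobm_system <- function(x, ...) {
  cat(sprintf(
    "qOBM optical system: lambda %g um, NA %g, pixel %g um, grid %dx%d\n",
    x$wavelength_um, x$na_objective, x$pixel_um, x$shape[1], x$shape[2]))
  cat(sprintf("  pupil cutoff NA/lambda = %.6g cycles/um\n", x$f_cutoff))
  invisible(x)
}

# DFT frequency coordinates for an even-length axis, in cycles/um.
fft_freq <- function(n, d) c(0:(n / 2 - 1), -(n / 2):(-1)) / (n * d)

#' Discrete spatial-frequency lattice of an optical system
#'
#' Builds the 2-D DFT frequency lattice matching \code{sys$shape}:
#' \code{fx} varies along columns, \code{fy} along rows, both in cycles/um,
#' with zero frequency at element (1, 1) exactly once.
#'
#' @param sys an \code{\link{optical_system}}.
#' @return An object of class \code{qobm_grid} with matrices \code{fx},
#'   \code{fy}, \code{fr} (radial frequency) and the scalar \code{f_cutoff}.
#' @export
frequency_grid <- function(sys) {
  stopifnot(inherits(sys, "qobm_system"))
  nr <- sys$shape[1]; nc <- sys$shape[2]
  fxv <- fft_freq(nc, sys$pixel_um)
  fyv <- fft_freq(nr, sys$pixel_um)
  fx <- matrix(fxv, nr, nc, byrow = TRUE)
  fy <- matrix(fyv, nr, nc)
  structure(list(fx = fx, fy = fy, fr = sqrt(fx^2 + fy^2),
                 f_cutoff = sys$f_cutoff, shape = sys$shape),
            class = "qobm_grid")
}

# Index permutation mapping each lattice frequency u to -u (DC and the
# unpaired Nyquist sample map to themselves).
reflect_index <- function(n) c(1L, n:2L)

# Sample-wise reflection of a lattice map through the frequency origin.
reflect_origin <- function(m) {
  m[reflect_index(nrow(m)), reflect_index(ncol(m)), drop = FALSE]
}

#' Ideal circular pupil
#'
#' Unaberrated binary pupil of the objective: 1 inside the cutoff
#' \code{NA / lambda}, 0 outside. Aberrations and apodization are out of
#' scope of this model.
#'
#' @param sys an \code{\link{optical_system}}.
#' @param grid the matching \code{\link{frequency_grid}}.
#' @return Numeric matrix over the lattice (real-valued pupil).
#' @export
make_pupil <- function(sys, grid) {
  stopifnot(inherits(sys, "qobm_system"), inherits(grid, "qobm_grid"),
            identical(grid$shape, sys$shape))
  (grid$fr <= grid$f_cutoff + 1e-12) * 1
}

qobm_arms <- c("+x", "-x", "+y", "-y")

#' Oblique effective-source distribution for one illumination arm
#'
#' Parametric model of the effective source seen by one oblique
#' back-illumination arm: an offset Gaussian in pupil (frequency)
#' coordinates, centred at \code{offset_frac * f_cutoff} along the arm's
#' axis with width \code{width_frac * f_cutoff}. The "-x" and "-y" arms are
#' constructed by reflecting the "+x"/"+y" weights through the frequency
#' origin, so opposing arms are exact sample-wise mirror pairs.
#'
#' In the physical instrument the oblique source arises from multiple
#' scattering of the off-axis fibre illumination; this parametric stand-in
#' captures the source obliquity and extent that generate phase contrast
#' without a light-transport simulation.
#'
#' @param sys an \code{\link{optical_system}}.
#' @param grid the matching \code{\link{frequency_grid}}.
#' @param arm one of \code{"+x"}, \code{"-x"}, \code{"+y"}, \code{"-y"}.
#' @param offset_frac radial offset of the source centroid as a fraction of
#'   the pupil cutoff, in [0, 2]. Default 0.8.
#' @param width_frac Gaussian width (sigma) as a fraction of the cutoff
#'   (> 0). Default 0.35.
#' @return An object of class \code{qobm_source} with fields
#'   \code{weights} (nonnegative matrix), \code{label} and \code{params}.
#' @export
make_source <- function(sys, grid, arm, offset_frac = 0.8,
                        width_frac = 0.35) {
  stopifnot(inherits(sys, "qobm_system"), inherits(grid, "qobm_grid"))
  if (!(is.character(arm) && length(arm) == 1L && arm %in% qobm_arms))
    stop(sprintf("unknown arm label '%s'; valid labels are %s",
                 as.character(arm)[1],
                 paste(sprintf("'%s'", qobm_arms), collapse = ", ")))
  stopifnot(offset_frac >= 0, offset_frac <= 2, width_frac > 0)
  fc <- grid$f_cutoff
  cx <- if (arm %in% c("+x", "-x")) offset_frac * fc else 0
  cy <- if (arm %in% c("+y", "-y")) offset_frac * fc else 0
  sigma <- width_frac * fc
  w <- exp(-((grid$fx - cx)^2 + (grid$fy - cy)^2) / (2 * sigma^2))
  if (arm %in% c("-x", "-y")) w <- reflect_origin(w)
  structure(list(weights = w, label = arm,
                 params = list(offset_frac = offset_frac,
                               width_frac = width_frac)),
            class = "qobm_source")
}

#' Restrict a source to its strongest samples
#'
#' Keeps the \code{n_max} largest weights (zeroing the rest). Used to bound
#' the cost of the partially coherent Abbe-sum simulator while evaluating
#' the matched weak-object transfer functions on the same truncated source.
#'
#' @param source a \code{\link{make_source}} result.
#' @param n_max maximum number of nonzero samples to keep.
#' @return A \code{qobm_source} with at most \code{n_max} nonzero weights.
#' @export
truncate_source <- function(source, n_max = 200L) {
  stopifnot(inherits(source, "qobm_source"), n_max >= 1)
  w <- source$weights
  nz <- which(w > 0)
  if (length(nz) > n_max) {
    keep <- nz[order(w[nz], decreasing = TRUE)[seq_len(n_max)]]
    w2 <- w * 0
    w2[keep] <- w[keep]
    source$weights <- w2
  }
  source
}

#' Weak-object transfer functions of one illumination arm
#'
#' Computes the partially coherent weak-object transfer functions (WOTFs)
#' for a source/pupil pair. Writing the object transmittance as
#' \code{t(r) = exp(-mu(r) + i*phi(r)) ~ 1 - mu + i*phi}, the image
#' spectrum of one arm obeys
#' \deqn{I(u) = B \delta(u) + H_{abs}(u) \hat\mu(u) + H_{ph}(u) \hat\phi(u)}
#' with lattice sums (circular indexing on the DFT lattice)
#' \deqn{B = \sum_{u'} S(u') |P(u')|^2}
#' \deqn{\Gamma(u) = \sum_{u'} S(u') P^*(u') P(u'+u)}
#' \deqn{H_{abs}(u) = -[\Gamma(u) + \Gamma^*(-u)], \quad
#'       H_{ph}(u) = i[\Gamma(u) - \Gamma^*(-u)].}
#' \eqn{\Gamma} is evaluated by FFT cross-correlation; for the real pupil
#' and nonnegative source used here \eqn{\Gamma} is analytically real and
#' its FFT roundoff imaginary part is discarded. \code{H_ph} is assembled
#' from a single \eqn{\Gamma} array so that \code{H_ph(0) = 0} and the
#' Hermitian antisymmetry \code{H_ph(-u) = Conj(H_ph(u))} hold exactly in
#' floating point: a symmetric (on-axis) source gives no linear phase
#' contrast, and any source gives none at zero frequency, which is the
#' low-frequency insensitivity characteristic of DPC-type reconstruction.
#'
#' @param sys an \code{\link{optical_system}}.
#' @param grid the matching \code{\link{frequency_grid}}.
#' @param pupil pupil map from \code{\link{make_pupil}}.
#' @param source a \code{\link{make_source}} result on the same lattice.
#' @return An object of class \code{qobm_wotf}: complex matrices
#'   \code{H_abs} and \code{H_ph}, background scalar \code{B} and
#'   \code{source_label}.
#' @export
compute_wotf <- function(sys, grid, pupil, source) {
  stopifnot(inherits(grid, "qobm_grid"), inherits(source, "qobm_source"),
            identical(dim(pupil), dim(source$weights)),
            identical(dim(pupil), grid$shape))
  S <- source$weights
  P <- pupil
  B <- sum(S * Mod(P)^2)
  if (B <= 0) stop("dark field: B = 0 (source does not overlap the pupil)")
  A <- S * Conj(P)
  n <- length(P)
  Gamma <- stats::fft(stats::fft(P) * Conj(stats::fft(A)),
                      inverse = TRUE) / n
  if (!is.complex(P) && !is.complex(S)) Gamma <- Re(Gamma)
  Gneg <- reflect_origin(Gamma)
  structure(list(H_abs = -(Gamma + Conj(Gneg)),
                 H_ph = 1i * (Gamma - Conj(Gneg)),
                 B = B,
                 source_label = source$label),
            class = "qobm_wotf")
}

#' @export
print.qobm_wotf <- function(x, ...) {
  cat(sprintf("qOBM WOTF (arm %s): B = %.6g, max |H_ph| = %.6g\n",
              x$source_label, x$B, max(Mod(x$H_ph))))
  invisible(x)
}

#' Transfer function of a normalized DPC image
#'
#' For a differential phase contrast image formed from an opposing arm pair
#' as (I_a - I_b) / (I_a + I_b), the linear operator taking the phase
#' spectrum to the DPC spectrum under the weak-object, pure-phase
#' approximation is
#' \deqn{H_{dpc}(u) = (H_{ph,a}(u) - H_{ph,b}(u)) / (B_a + B_b).}
#'
#' @param tf_a,tf_b \code{\link{compute_wotf}} results for the two arms of
#'   one opposing pair.
#' @return Complex matrix over the lattice.
#' @export
dpc_transfer <- function(tf_a, tf_b) {
  stopifnot(inherits(tf_a, "qobm_wotf"), inherits(tf_b, "qobm_wotf"),
            identical(dim(tf_a$H_ph), dim(tf_b$H_ph)))
  denom <- tf_a$B + tf_b$B
  if (denom == 0) stop("B_a + B_b = 0: cannot normalize the DPC transfer")
  (tf_a$H_ph - tf_b$H_ph) / denom
}

#' Build the full optical chain for a four-arm qOBM system
#'
#' Convenience constructor: frequency grid, pupil, the four oblique
#' sources, their WOTFs and the two DPC transfer maps (x pair: +x/-x,
#' y pair: +y/-y), all from one set of source parameters.
#'
#' @param sys an \code{\link{optical_system}}.
#' @param offset_frac,width_frac source parameters shared by all four arms
#'   (see \code{\link{make_source}}).
#' @return A list with \code{grid}, \code{pupil}, \code{sources},
#'   \code{tfs} (both named by arm), \code{H_x} and \code{H_y}.
#' @export
build_optics <- function(sys, offset_frac = 0.8, width_frac = 0.35) {
  grid <- frequency_grid(sys)
  pupil <- make_pupil(sys, grid)
  sources <- lapply(stats::setNames(qobm_arms, qobm_arms), function(a)
    make_source(sys, grid, a, offset_frac, width_frac))
  tfs <- lapply(sources, function(s) compute_wotf(sys, grid, pupil, s))
  list(grid = grid, pupil = pupil, sources = sources, tfs = tfs,
       H_x = dpc_transfer(tfs[["+x"]], tfs[["-x"]]),
       H_y = dpc_transfer(tfs[["+y"]], tfs[["-y"]]))
}
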