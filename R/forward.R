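ifft2 <- function(m) stats::fft(m, inverse = TRUE) / length(m)

#' Simulate the four raw oblique-illumination intensity images
#'
#' Forward model of one qOBM field under the weak-object approximation.
#' For each arm the noiseless intensity is
#' \deqn{I = B + F^{-1}[H_{abs} \hat\mu + H_{ph} \hat\phi]}
#' (real part; the Hermitian symmetry of the transfer functions makes the
#' imaginary residual pure roundoff, and an error is raised if it exceeds
#' 1e-10 relative). Optional shot noise replaces each pixel by a scaled
#' Poisson draw with \code{photon_scale} expected photons per pixel at the
#' background level B: \code{I <- rpois(photon_scale * I / B) * B /
#' photon_scale}, seeded for reproducibility.
#'
#' The weak-object linearization can produce slightly negative intensities
#' for strong phantoms; these are not clipped in the noiseless output but
#' their count is recorded in \code{exposure$n_negative} (and negative
#' Poisson rates are clamped to 0, counted in \code{exposure$n_clamped}).
#'
#' @param ph a \code{\link{generate_phantom}} result (or any object with
#'   \code{phase} and \code{absorption} matrices).
#' @param tfs named list of \code{\link{compute_wotf}} results for arms
#'   \code{"+x"}, \code{"-x"}, \code{"+y"}, \code{"-y"} on the phantom grid.
#' @param noise \code{"none"} or \code{"poisson"}.
#' @param photon_scale expected photons per pixel at background. Default 1e4.
#' @param seed RNG seed for the noise draw (required when
#'   \code{noise = "poisson"}).
#' @return An object of class \code{qobm_frames}: \code{frames} (named list
#'   of intensity matrices) and \code{exposure} metadata.
#' @export
simulate_intensities <- function(ph, tfs, noise = c("none", "poisson"),
                                 photon_scale = 1e4, seed = NULL) {
  noise <- match.arg(noise)
  stopifnot(is.list(tfs), all(qobm_arms %in% names(tfs)))
  phase <- if (inherits(ph, "qobm_phantom")) ph$phase else ph
  mu <- if (inherits(ph, "qobm_phantom")) ph$absorption
        else matrix(0, nrow(phase), ncol(phase))
  if (!identical(dim(phase), dim(tfs[["+x"]]$H_ph)))
    stop("phantom and transfer functions are on different grids")
  PHI <- stats::fft(phase)
  MU <- stats::fft(mu)
  if (noise == "poisson" && is.null(seed))
    stop("seed is required for poisson noise")
  frames <- list()
  n_negative <- 0L
  n_clamped <- 0L
  for (arm in qobm_arms) {
    tf <- tfs[[arm]]
    field <- ifft2(tf$H_abs * MU + tf$H_ph * PHI)
    scale <- max(abs(Re(field)), tf$B)
    if (max(abs(Im(field))) > 1e-10 * scale)
      stop(sprintf("imaginary residual of arm %s exceeds 1e-10 relative", arm))
    I <- tf$B + Re(field)
    n_negative <- n_negative + sum(I < 0)
    if (noise == "poisson") {
      lam <- photon_scale * I / tf$B
      n_clamped <- n_clamped + sum(lam < 0)
      lam[lam < 0] <- 0
      I <- with_seed(seed + match(arm, qobm_arms), {
        matrix(stats::rpois(length(lam), lam), nrow(lam), ncol(lam))
      }) * tf$B / photon_scale
    }
    frames[[arm]] <- I
  }
  structure(list(frames = frames,
                 exposure = list(noise = noise,
                                 photon_scale = photon_scale,
                                 seed = seed,
                                 n_negative = n_negative,
                                 n_clamped = n_clamped)),
            class = "qobm_frames")
}

#' @export
print.qobm_frames <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("qOBM raw frame set: 4 arms, %dx%d px, noise = %s\n",
              d[1], d[2], x$exposure$noise))
  invisible(x)
}

#' Simulate a depth stack of raw frame sets
#'
#' Applies \code{\link{simulate_intensities}} to each slice of a phantom
#' stack independently (no inter-slice crosstalk is modelled); slice order
#' is preserved and the slice spacing is recorded in the result. The
#' default spacing of 1.5 um matches typical qOBM Z-scan acquisition steps.
#'
#' @param ph_stack list of phantoms sharing one grid.
#' @param tfs per-arm transfer functions (see
#'   \code{\link{simulate_intensities}}).
#' @param noise,photon_scale,seed noise model passed per slice; under
#'   Poisson noise each slice uses a seed derived from \code{seed} and the
#'   slice index.
#' @param slice_spacing_um depth step between slices, um. Default 1.5.
#' @return Class \code{qobm_zstack}: \code{slices} (list of
#'   \code{qobm_frames}) and \code{slice_spacing_um}.
#' @export
simulate_zstack <- function(ph_stack, tfs, noise = c("none", "poisson"),
                            photon_scale = 1e4, seed = NULL,
                            slice_spacing_um = 1.5) {
  noise <- match.arg(noise)
  if (length(ph_stack) == 0) stop("empty phantom stack")
  slices <- lapply(seq_along(ph_stack), function(i)
    simulate_intensities(ph_stack[[i]], tfs, noise, photon_scale,
                         seed = if (is.null(seed)) NULL else seed + 1000L * i))
  structure(list(slices = slices, slice_spacing_um = slice_spacing_um),
            class = "qobm_zstack")
}

# Circularly shift a spectrum so that entry (1,1) moves to the lattice
# index of source point s (0-based offsets di, dj).
shift_spectrum <- function(m, di, dj) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- ((seq_len(nr) - 1L - di) %% nr) + 1L
  ci <- ((seq_len(nc) - 1L - dj) %% nc) + 1L
  m[ri, ci, drop = FALSE]
}

#' Partially coherent Abbe-sum reference simulator
#'
#' Reference forward model without the weak-object linearization: the full
#' transmittance \code{t = exp(-mu + i*phi)} is imaged coherently for each
#' source sample (tilted illumination = circular spectrum shift, pupil
#' filtering, squared modulus) and the intensities are summed with the
#' source weights. On weak phantoms this bounds the linearization error of
#' \code{\link{simulate_intensities}}; it is exact for the partially
#' coherent model at any object strength but costs one FFT per source
#' sample, so the source is usually truncated first with
#' \code{\link{truncate_source}}.
#'
#' @param ph phantom (as in \code{\link{simulate_intensities}}).
#' @param pupil pupil map.
#' @param source a \code{qobm_source}; only its nonzero weights are summed.
#' @return Intensity matrix on the same absolute scale as the linear model
#'   (background term equals \code{sum(S * |P|^2)}).
#' @export
simulate_abbe <- function(ph, pupil, source) {
  stopifnot(inherits(source, "qobm_source"))
  phase <- if (inherits(ph, "qobm_phantom")) ph$phase else ph
  mu <- if (inherits(ph, "qobm_phantom")) ph$absorption
        else matrix(0, nrow(phase), ncol(phase))
  stopifnot(identical(dim(phase), dim(pupil)))
  t_obj <- exp(-mu + 1i * phase)
  That <- stats::fft(t_obj)
  w <- source$weights
  nz <- which(w > 0, arr.ind = TRUE)
  I <- matrix(0, nrow(phase), ncol(phase))
  for (k in seq_len(nrow(nz))) {
    di <- nz[k, 1] - 1L
    dj <- nz[k, 2] - 1L
    field <- ifft2(pupil * shift_spectrum(That, di, dj))
    I <- I + w[nz[k, 1], nz[k, 2]] * Mod(field)^2
  }
  I
}

#' Abbe-sum frame set for all four arms
#'
#' Convenience wrapper running \code{\link{simulate_abbe}} for each arm of
#' a four-source set (each truncated to \code{n_max} samples).
#'
#' @param ph phantom.
#' @param pupil pupil map.
#' @param sources named list of the four arm sources.
#' @param n_max per-arm source-sample budget. Default 200.
#' @return A \code{qobm_frames} object (noise-free).
#' @export
simulate_intensities_abbe <- function(ph, pupil, sources, n_max = 200L) {
  stopifnot(all(qobm_arms %in% names(sources)))
  frames <- lapply(stats::setNames(qobm_arms, qobm_arms), function(a)
    simulate_abbe(ph, pupil, truncate_source(sources[[a]], n_max)))
  structure(list(frames = frames,
                 exposure = list(noise = "none", model = "abbe",
                                 n_max = n_max,
                                 n_negative = 0L, n_clamped = 0L)),
            class = "qobm_frames")
}
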