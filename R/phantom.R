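# Label codes shared by the phantom, metrics and I/O modules.
LABEL_BACKGROUND <- 0L
LABEL_NUCLEUS <- 1L
LABEL_INCLUSION <- 2L

# Evaluate an expression with a private, seeded RNG stream, restoring the
# caller's RNG state afterwards so phantom generation never perturbs it.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Gaussian-correlated random texture with exact sample mean 0 and sample
# standard deviation `sd` (FFT filtering with a Gaussian of width sigma_um).
smooth_texture <- function(nr, nc, pixel_um, sd, sigma_um) {
  if (sd <= 0) return(matrix(0, nr, nc))
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  fx <- matrix(fft_freq(nc, pixel_um), nr, nc, byrow = TRUE)
  fy <- matrix(fft_freq(nr, pixel_um), nr, nc)
  K <- exp(-2 * pi^2 * sigma_um^2 * (fx^2 + fy^2))
  s <- Re(stats::fft(stats::fft(z) * K, inverse = TRUE)) / (nr * nc)
  s <- s - mean(s)
  s / stats::sd(s) * sd
}

# Smoothstep disk profile: 1 on the plateau, falling smoothly to 0 at
# radius r over an edge band of width `edge` (um); identically 0 outside r.
disk_profile <- function(d, r, edge) {
  w <- pmin(1, pmax(0, (r - d) / edge))
  w * w * (3 - 2 * w)
}

# Rejection-sample n non-overlapping disk centres/radii inside the field,
# also avoiding any disks already in `avoid` (data.frame cx, cy, r).
place_disks <- function(n, r_range, Lx, Ly, sep_um, avoid = NULL,
                        max_attempts = 200L * max(n, 1L), what = "disk") {
  placed <- data.frame(cx = numeric(0), cy = numeric(0), r = numeric(0))
  attempts <- 0L
  while (nrow(placed) < n) {
    if (attempts >= max_attempts)
      stop(sprintf(
        "could not place %d %ss after %d attempts (placed %d); the packing is infeasible",
        n, what, attempts, nrow(placed)))
    attempts <- attempts + 1L
    r <- stats::runif(1, r_range[1], r_range[2])
    if (2 * r >= Lx || 2 * r >= Ly) next
    cx <- stats::runif(1, r, Lx - r)
    cy <- stats::runif(1, r, Ly - r)
    others <- rbind(placed, avoid)
    if (nrow(others) > 0) {
      d2 <- (others$cx - cx)^2 + (others$cy - cy)^2
      if (any(d2 < (others$r + r + sep_um)^2)) next
    }
    placed <- rbind(placed, data.frame(cx = cx, cy = cy, r = r))
  }
  placed
}

#' Generate a seeded synthetic tissue field
#'
#' Builds a 2-D phantom emulating a thick-tissue qOBM field of view in its
#' fresh (unstained) state: cell nuclei as non-overlapping smooth disks of
#' modestly elevated phase, a correlated cytoplasmic phase texture over the
#' whole field, and optionally a few small bright round inclusions standing
#' in for the high-phase lipid-droplet-like objects seen outside cells.
#' Phase is in radians (positive = refractive index above background);
#' absorption is a small constant attenuation map. The same seed always
#' produces a bit-identical phantom, and the caller's RNG state is left
#' untouched.
#'
#' Nuclei and inclusions use a smoothstep radial profile (plateau at the
#' stated phase level, smooth fall-off to 0 at the disk edge) added on top
#' of the background texture, so nuclear pixels keep sub-nuclear texture.
#' Labels partition the field into background (0), nucleus (1) and
#' inclusion (2); a pixel's label is decided by disk membership, with
#' inclusions placed to avoid nuclei.
#'
#' @param sys an \code{\link{optical_system}} (defines grid and pixel size).
#' @param n_nuclei number of nuclei to place (>= 0). Default 12.
#' @param nucleus_radius_um radius range (um), uniform draw. Default c(3, 6).
#' @param nucleus_phase plateau phase of a nucleus above background, radians.
#'   Default 0.15 (fresh tissue: modest nuclear contrast).
#' @param background_sd standard deviation of the background phase texture,
#'   radians. Default 0.08.
#' @param background_scale_um correlation length of the texture. Default 1.5.
#' @param n_inclusions number of bright inclusions. Default 3.
#' @param inclusion_radius_um inclusion radius range (um). Default c(0.8, 1.5).
#' @param inclusion_phase inclusion plateau phase, radians. Default 0.6.
#' @param absorption constant amplitude attenuation per pixel (>= 0).
#'   Default 0.01.
#' @param seed integer RNG seed; same seed, same phantom. Default 1.
#' @param max_attempts rejection-sampling budget for disk placement.
#' @return An object of class \code{qobm_phantom}: matrices \code{phase},
#'   \code{absorption}, integer matrix \code{labels}, and \code{meta}
#'   (parameters, seed, placed-disk table, weak-object \code{regime} flag:
#'   "weak" if max |phase| <= 1 rad and max absorption <= 0.2, else
#'   "nonlinear").
#' @export
generate_phantom <- function(sys,
                             n_nuclei = 12L,
                             nucleus_radius_um = c(3, 6),
                             nucleus_phase = 0.15,
                             background_sd = 0.08,
                             background_scale_um = 1.5,
                             n_inclusions = 3L,
                             inclusion_radius_um = c(0.8, 1.5),
                             inclusion_phase = 0.6,
                             absorption = 0.01,
                             seed = 1L,
                             max_attempts = NULL) {
  stopifnot(inherits(sys, "qobm_system"),
            n_nuclei >= 0, n_inclusions >= 0, absorption >= 0,
            background_sd >= 0, length(nucleus_radius_um) == 2L,
            nucleus_radius_um[1] > 0,
            nucleus_radius_um[2] >= nucleus_radius_um[1])
  if (n_nuclei > 0 && nucleus_radius_um[1] < 2 * sys$pixel_um)
    stop(sprintf("nucleus radii must be >= 2 pixels (%g um at pixel_um = %g)",
                 2 * sys$pixel_um, sys$pixel_um))
  nr <- sys$shape[1]; nc <- sys$shape[2]; px <- sys$pixel_um
  Lx <- nc * px; Ly <- nr * px
  with_seed(seed, {
    phase <- smooth_texture(nr, nc, px, background_sd, background_scale_um)
    labels <- matrix(LABEL_BACKGROUND, nr, nc)
    X <- matrix((seq_len(nc) - 0.5) * px, nr, nc, byrow = TRUE)
    Y <- matrix((seq_len(nr) - 0.5) * px, nr, nc)

    nuclei <- place_disks(n_nuclei, nucleus_radius_um, Lx, Ly,
                          sep_um = 0.5, what = "nucleus",
                          max_attempts = if (is.null(max_attempts))
                            200L * max(n_nuclei, 1L) else max_attempts)
    for (k in seq_len(nrow(nuclei))) {
      d <- sqrt((X - nuclei$cx[k])^2 + (Y - nuclei$cy[k])^2)
      r <- nuclei$r[k]
      phase <- phase + nucleus_phase * disk_profile(d, r, edge = 0.25 * r)
      labels[d <= r] <- LABEL_NUCLEUS
    }

    inclusions <- place_disks(n_inclusions, inclusion_radius_um, Lx, Ly,
                              sep_um = 0.5, avoid = nuclei,
                              what = "inclusion",
                              max_attempts = if (is.null(max_attempts))
                                200L * max(n_inclusions, 1L) else max_attempts)
    for (k in seq_len(nrow(inclusions))) {
      d <- sqrt((X - inclusions$cx[k])^2 + (Y - inclusions$cy[k])^2)
      r <- inclusions$r[k]
      phase <- phase + inclusion_phase * disk_profile(d, r, edge = 0.3 * r)
      labels[d <= r] <- LABEL_INCLUSION
    }

    absmap <- matrix(absorption, nr, nc)
    regime <- if (max(abs(phase)) <= 1 && max(absmap) <= 0.2) "weak"
              else "nonlinear"
    structure(list(
      phase = phase, absorption = absmap, labels = labels,
      meta = list(seed = as.integer(seed),
                  pixel_um = px, shape = sys$shape,
                  n_nuclei = n_nuclei,
                  nucleus_radius_um = nucleus_radius_um,
                  nucleus_phase = nucleus_phase,
                  background_sd = background_sd,
                  background_scale_um = background_scale_um,
                  n_inclusions = n_inclusions,
                  inclusion_radius_um = inclusion_radius_um,
                  inclusion_phase = inclusion_phase,
                  absorption = absorption,
                  nuclei = nuclei, inclusions = inclusions,
                  regime = regime,
                  state = "fresh")),
      class = "qobm_phantom")
  })
}

#' @export
print.qobm_phantom <- function(x, ...) {
  cat(sprintf(
    "qOBM tissue phantom (%s, %s regime): %dx%d px, %d nuclei, %d inclusions\n",
    x$meta$state, x$meta$regime, nrow(x$phase), ncol(x$phase),
    nrow(x$meta$nuclei), nrow(x$meta$inclusions)))
  cat(sprintf("  phase range [%.4g, %.4g] rad, whole-field SD %.4g rad\n",
              min(x$phase), max(x$phase), stats::sd(x$phase)))
  invisible(x)
}

#' Acetowhitening transform parameters
#'
#' Parametric model of the acetic-acid staining effect on the phase map:
#' chromatin condensation raises the nuclear refractive index
#' (multiplicative \code{nuclear_gain} on nuclear phase) while non-nuclear
#' structures become more homogeneous (\code{homogenization} mixes the
#' background phase toward its mean). Inclusions (lipid-droplet-like
#' objects) are left unchanged by default.
#'
#' @param nuclear_gain multiplicative factor >= 1 on nuclear phase.
#'   Default 1.8.
#' @param homogenization mixing weight in [0, 1] pulling background pixels
#'   toward the background mean (1 = fully homogenized). Default 0.7.
#' @param inclusion_gain factor applied to inclusion phase. Default 1.
#' @param background_mode \code{"global"} (mix toward the global background
#'   mean) or \code{"local"} (toward a Gaussian local mean of scale
#'   \code{local_scale_um}).
#' @param local_scale_um scale of the local mean for
#'   \code{background_mode = "local"}. Default 5.
#' @return An object of class \code{qobm_aa_params}.
#' @export
aa_params <- function(nuclear_gain = 1.8, homogenization = 0.7,
                      inclusion_gain = 1,
                      background_mode = c("global", "local"),
                      local_scale_um = 5) {
  background_mode <- match.arg(background_mode)
  stopifnot(nuclear_gain >= 1, homogenization >= 0, homogenization <= 1,
            inclusion_gain > 0, local_scale_um > 0)
  structure(list(nuclear_gain = nuclear_gain,
                 homogenization = homogenization,
                 inclusion_gain = inclusion_gain,
                 background_mode = background_mode,
                 local_scale_um = local_scale_um),
            class = "qobm_aa_params")
}

# Gaussian local mean of `values` over the pixels where mask is TRUE.
masked_local_mean <- function(values, mask, pixel_um, sigma_um) {
  nr <- nrow(values); nc <- ncol(values)
  fx <- matrix(fft_freq(nc, pixel_um), nr, nc, byrow = TRUE)
  fy <- matrix(fft_freq(nr, pixel_um), nr, nc)
  K <- exp(-2 * pi^2 * sigma_um^2 * (fx^2 + fy^2))
  blur <- function(m) Re(stats::fft(stats::fft(m) * K, inverse = TRUE)) /
    (nr * nc)
  num <- blur(values * mask)
  den <- blur(mask * 1)
  out <- num / pmax(den, 1e-9)
  out
}

#' Apply the acetowhitening (acetic-acid) transform to a phantom
#'
#' Nucleus pixels are scaled by \code{nuclear_gain}, background pixels are
#' mixed toward the background mean phase by the \code{homogenization}
#' weight, and inclusion pixels are scaled by \code{inclusion_gain}.
#' Labels and absorption are unchanged, so fresh/stained pairs stay
#' pixel-comparable (real stained tissue deforms; the simulator
#' deliberately keeps geometry fixed so supervised comparisons remain
#' possible).
#'
#' @param ph a \code{\link{generate_phantom}} result.
#' @param p an \code{\link{aa_params}} object.
#' @return A new \code{qobm_phantom} with transformed phase;
#'   \code{meta$aa} records the parameters and \code{meta$state} becomes
#'   \code{"aa"}.
#' @export
apply_aa_transform <- function(ph, p = aa_params()) {
  stopifnot(inherits(ph, "qobm_phantom"), inherits(p, "qobm_aa_params"))
  phase <- ph$phase
  lab <- ph$labels
  nuc <- lab == LABEL_NUCLEUS
  bg <- lab == LABEL_BACKGROUND
  inc <- lab == LABEL_INCLUSION
  phase[nuc] <- p$nuclear_gain * phase[nuc]
  if (any(bg)) {
    if (p$background_mode == "global") {
      m <- mean(ph$phase[bg])
      phase[bg] <- (1 - p$homogenization) * ph$phase[bg] +
        p$homogenization * m
    } else {
      M <- masked_local_mean(ph$phase, bg, ph$meta$pixel_um,
                             p$local_scale_um)
      phase[bg] <- (1 - p$homogenization) * ph$phase[bg] +
        p$homogenization * M[bg]
    }
  }
  phase[inc] <- p$inclusion_gain * phase[inc]
  out <- ph
  out$phase <- phase
  out$meta$aa <- unclass(p)
  out$meta$state <- "aa"
  out$meta$regime <- if (max(abs(phase)) <= 1 && max(ph$absorption) <= 0.2)
    "weak" else "nonlinear"
  out
}
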