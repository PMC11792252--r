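#' Default pipeline configuration
#'
#' The full configuration tree with every block at its default: a
#' 720-nm, 0.6-NA system on a 512 x 512 grid at 0.25 um/pixel, the
#' default phantom and acetowhitening parameters, noiseless acquisition,
#' alpha = 1e-3 reconstruction and a 50-field-per-group comparison.
#' User YAML files (see \code{\link{load_config}}) override these values;
#' unknown keys are rejected.
#'
#' @return Nested list (a \code{RunConfig}).
#' @export
default_config <- function() {
  list(
    seed = 1L,
    output_dir = "qobm_run",
    save_images = TRUE,
    optical = list(wavelength_um = 0.72, na_objective = 0.6,
                   pixel_um = 0.25, shape = c(512L, 512L)),
    arms = list(offset_frac = 0.8, width_frac = 0.35),
    phantom = list(n_nuclei = 12L, nucleus_radius_um = c(3, 6),
                   nucleus_phase = 0.15, background_sd = 0.08,
                   background_scale_um = 1.5, n_inclusions = 3L,
                   inclusion_radius_um = c(0.8, 1.5),
                   inclusion_phase = 0.6, absorption = 0.01),
    aa = list(nuclear_gain = 1.8, homogenization = 0.7,
              inclusion_gain = 1, background_mode = "global",
              local_scale_um = 5),
    noise = list(model = "none", photon_scale = 1e4),
    reconstruction = list(alpha = 1e-3),
    metrics = list(n_fields = 50L, var_equal = FALSE, bonferroni = FALSE)
  )
}

merge_config <- function(base, user, path = "") {
  for (k in names(user)) {
    here <- if (nzchar(path)) paste0(path, ".", k) else k
    if (!k %in% names(base))
      stop(sprintf("unknown configuration key '%s'", here))
    if (is.list(base[[k]]) && !is.null(names(base[[k]]))) {
      if (!is.list(user[[k]]))
        stop(sprintf("configuration key '%s' must be a block", here))
      base[[k]] <- merge_config(base[[k]], user[[k]], here)
    } else {
      base[[k]] <- user[[k]]
    }
  }
  base
}

validate_config <- function(cfg) {
  with(cfg$optical,
       invisible(optical_system(wavelength_um, na_objective, pixel_um,
                                shape)))
  stopifnot(cfg$arms$offset_frac >= 0, cfg$arms$offset_frac <= 2,
            cfg$arms$width_frac > 0)
  do.call(aa_params, cfg$aa)
  if (!cfg$noise$model %in% c("none", "poisson"))
    stop(sprintf("noise.model must be 'none' or 'poisson', got '%s'",
                 cfg$noise$model))
  stopifnot(cfg$noise$photon_scale > 0,
            cfg$reconstruction$alpha > 0,
            cfg$metrics$n_fields >= 2,
            cfg$phantom$n_nuclei >= 0,
            cfg$phantom$nucleus_phase >= 0,
            cfg$phantom$background_sd >= 0,
            cfg$phantom$absorption >= 0)
  cfg
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML configuration, overlays it on
#' \code{\link{default_config}}, rejects unknown keys and validates every
#' block against the preconditions of the module it feeds before any
#' computation starts.
#'
#' @param path YAML file path, or NULL for pure defaults.
#' @param overrides optional named list applied after the file (same
#'   semantics).
#' @return Validated configuration list.
#' @export
load_config <- function(path = NULL, overrides = NULL) {
  cfg <- default_config()
  if (!is.null(path)) cfg <- merge_config(cfg, yaml::read_yaml(path))
  if (!is.null(overrides)) cfg <- merge_config(cfg, overrides)
  cfg$seed <- as.integer(cfg$seed)
  cfg$optical$shape <- as.integer(cfg$optical$shape)
  cfg$metrics$n_fields <- as.integer(cfg$metrics$n_fields)
  validate_config(cfg)
}
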