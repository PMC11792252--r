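# Scaled-down study conditions used for replicated statistical
# calibration: a 64 x 64 field at 0.5 um/pixel (32 um field of view) with
# three nuclei and one inclusion, so that thousands of full
# phantom -> frames -> reconstruction chains stay affordable. The phase
# levels and acetowhitening parameters are the package defaults.
#' Scaled-down field settings for replicated studies
#'
#' Returns the small-field study configuration (optical system plus
#' phantom arguments) used by \code{\link{aa_sd_groups}} when many
#' replicate fields are needed.
#'
#' @return List with \code{sys} (an \code{\link{optical_system}}) and
#'   \code{phantom_args}.
#' @export
small_field_settings <- function() {
  list(sys = optical_system(0.72, 0.6, 0.5, c(64L, 64L)),
       phantom_args = list(n_nuclei = 3L, nucleus_radius_um = c(2, 3),
                           n_inclusions = 1L,
                           inclusion_radius_um = c(0.8, 1.2)))
}

#' Per-image phase SDs for a fresh / acetowhitened group pair
#'
#' Generates \code{n_fields} seeded phantom fields, applies the
#' acetowhitening transform to each, optionally pushes both states
#' through the forward model and reconstruction, and returns the
#' per-image whole-field phase SDs of both groups. With
#' \code{aa_null = TRUE} the "fresh" group is replaced by a second,
#' independently seeded acetowhitened group (identical generator
#' settings), giving a null pair for calibration.
#'
#' @param n_fields images per group.
#' @param seed root seed; field seeds are derived from it.
#' @param sys,optics optical system and \code{\link{build_optics}} result
#'   (defaults: \code{\link{small_field_settings}}).
#' @param phantom_args extra arguments to \code{\link{generate_phantom}}.
#' @param aa an \code{\link{aa_params}} object.
#' @param alpha reconstruction regularization.
#' @param reconstruct reconstruct phase before measuring (TRUE) or measure
#'   the phantom phase directly (FALSE, cheaper).
#' @param aa_null generate a null pair (two AA groups) instead of
#'   fresh/AA.
#' @return data.frame with columns \code{a} and \code{b}: per-image SDs of
#'   the two groups (fresh/AA, or AA/AA under the null).
#' @export
aa_sd_groups <- function(n_fields, seed, sys = NULL, optics = NULL,
                         phantom_args = NULL, aa = aa_params(),
                         alpha = 1e-3, reconstruct = TRUE,
                         aa_null = FALSE) {
  if (is.null(sys)) {
    st <- small_field_settings()
    sys <- st$sys
    if (is.null(phantom_args)) phantom_args <- st$phantom_args
  }
  if (is.null(phantom_args)) phantom_args <- list()
  if (reconstruct && is.null(optics)) optics <- build_optics(sys)
  one_sd <- function(ph) {
    if (!reconstruct) return(phase_std(ph$phase))
    fr <- simulate_intensities(ph, optics$tfs)
    phase_std(reconstruct_field(fr, optics$H_x, optics$H_y, alpha))
  }
  gen <- function(i) do.call(generate_phantom, c(
    list(sys = sys, seed = derive_seed(seed, "field", i)), phantom_args))
  a <- b <- numeric(n_fields)
  for (i in seq_len(n_fields)) {
    ph <- gen(i)
    if (aa_null) {
      ph2 <- gen(i + n_fields)
      a[i] <- one_sd(apply_aa_transform(ph, aa))
      b[i] <- one_sd(apply_aa_transform(ph2, aa))
    } else {
      a[i] <- one_sd(ph)
      b[i] <- one_sd(apply_aa_transform(ph, aa))
    }
  }
  data.frame(a = a, b = b)
}

#' Type-I error rate of the two-sample t test under a Gaussian null
#'
#' Draws \code{n_rep} seeded pairs of N(0, 1) samples of size \code{n} and
#' returns the fraction rejected at \code{level}: a direct calibration
#' check of \code{\link{welch_ttest}}.
#'
#' @param n_rep number of replicates.
#' @param n sample size per group.
#' @param level nominal significance level. Default 0.05.
#' @param seed root seed.
#' @return Observed rejection rate.
#' @export
ttest_type1_rate <- function(n_rep = 200L, n = 50L, level = 0.05,
                             seed = 1L) {
  rej <- with_seed(seed, {
    vapply(seq_len(n_rep), function(i) {
      welch_ttest(stats::rnorm(n), stats::rnorm(n))$p_value < level
    }, logical(1))
  })
  mean(rej)
}

#' Rejection rate over replicated fresh-vs-AA group studies
#'
#' Runs \code{n_rep} independent replicates of the scaled-down group
#' study (\code{\link{aa_sd_groups}}) and returns the fraction of
#' replicates in which the two-sample t test on per-image phase SDs
#' rejects at \code{level}. With \code{aa_null = TRUE} this measures the
#' type-I rate under identical generator settings; with the default it
#' measures the power to detect the acetowhitening effect.
#'
#' @inheritParams aa_sd_groups
#' @param n_rep number of replicates.
#' @param level significance level. Default 0.05.
#' @return Observed rejection rate.
#' @export
aa_rejection_rate <- function(n_rep = 100L, n_fields = 50L, seed = 1L,
                              level = 0.05, reconstruct = TRUE,
                              aa_null = FALSE, aa = aa_params()) {
  st <- small_field_settings()
  optics <- if (reconstruct) build_optics(st$sys) else NULL
  rej <- vapply(seq_len(n_rep), function(r) {
    g <- aa_sd_groups(n_fields, seed = derive_seed(seed, "replicate", r),
                      sys = st$sys, optics = optics,
                      phantom_args = st$phantom_args, aa = aa,
                      reconstruct = reconstruct, aa_null = aa_null)
    welch_ttest(g$a, g$b)$p_value < level
  }, logical(1))
  mean(rej)
}
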