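as_phase_matrix <- function(img) {
  if (inherits(img, "qobm_phase")) img$phase
  else if (is.matrix(img)) img
  else stop("expected a qobm_phase object or a numeric matrix")
}

#' Standard deviation of a phase image
#'
#' Sample standard deviation (denominator n - 1) of the phase values over
#' an optional mask or the whole image. Per-image whole-field phase SD is
#' the summary statistic used for the fresh-versus-stained group analysis:
#' acetowhitening concentrates phase contrast into nuclei while
#' homogenizing the rest of the field, lowering this statistic.
#'
#' @param img a \code{qobm_phase} object or numeric matrix.
#' @param mask optional logical matrix of the same shape selecting pixels.
#' @return Scalar standard deviation (radians).
#' @export
phase_std <- function(img, mask = NULL) {
  m <- as_phase_matrix(img)
  v <- if (is.null(mask)) as.vector(m) else {
    stopifnot(identical(dim(mask), dim(m)))
    m[mask]
  }
  if (length(v) < 2) stop("fewer than 2 pixels selected")
  stats::sd(v)
}

#' Nuclear contrast-to-noise ratio
#'
#' Operationalizes nuclear contrast enhancement as
#' \deqn{CNR = (\bar\phi_{nucleus} - \bar\phi_{background}) /
#'       s_{background}}
#' using the phantom's label masks (nucleus = 1, background = 0).
#'
#' @param img a \code{qobm_phase} object or numeric matrix.
#' @param labels integer label matrix of the same shape.
#' @return Scalar CNR (dimensionless).
#' @export
nuclear_cnr <- function(img, labels) {
  m <- as_phase_matrix(img)
  stopifnot(identical(dim(labels), dim(m)))
  nuc <- m[labels == LABEL_NUCLEUS]
  bg <- m[labels == LABEL_BACKGROUND]
  if (length(nuc) == 0 || length(bg) < 2)
    stop("nucleus and background classes must both be non-empty")
  s <- stats::sd(bg)
  if (s == 0) stop("zero background standard deviation: CNR undefined")
  (mean(nuc) - mean(bg)) / s
}

#' Two-sample t test (Welch by default)
#'
#' Unequal-variance two-sample t statistic
#' \deqn{t = (\bar x - \bar y) / \sqrt{s_x^2/n_x + s_y^2/n_y}}
#' with Welch-Satterthwaite degrees of freedom and a two-sided p value
#' from the t distribution. \code{var_equal = TRUE} gives the pooled
#' Student variant.
#'
#' @param x,y numeric vectors, each of length >= 2 with nonzero variance.
#' @param var_equal use the pooled-variance Student statistic instead of
#'   Welch. Default FALSE.
#' @return Class \code{qobm_ttest}: \code{t_stat}, \code{dof} (fractional
#'   for Welch), \code{p_value}, \code{group_sizes}, \code{method}.
#' @export
welch_ttest <- function(x, y, var_equal = FALSE) {
  stopifnot(is.numeric(x), is.numeric(y))
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2) stop("each sample needs at least 2 observations")
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 && vy == 0) stop("degenerate samples: both variances are zero")
  if (var_equal) {
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    se <- sqrt(sp2 * (1 / nx + 1 / ny))
    dof <- nx + ny - 2
  } else {
    ax <- vx / nx; ay <- vy / ny
    se <- sqrt(ax + ay)
    dof <- (ax + ay)^2 / (ax^2 / (nx - 1) + ay^2 / (ny - 1))
  }
  if (se == 0) stop("degenerate samples: zero standard error")
  t_stat <- (mean(x) - mean(y)) / se
  p <- 2 * stats::pt(-abs(t_stat), dof)
  structure(list(t_stat = t_stat, dof = dof, p_value = p,
                 group_sizes = c(nx, ny),
                 method = if (var_equal) "student" else "welch"),
            class = "qobm_ttest")
}

#' @export
print.qobm_ttest <- function(x, ...) {
  cat(sprintf("Two-sample %s t test: t = %.4g, dof = %.4g, p = %.4g\n",
              x$method, x$t_stat, x$dof, x$p_value))
  invisible(x)
}

#' Group analysis of per-image phase standard deviations
#'
#' For each named group of phase images, computes the per-image whole-field
#' phase SD, per-group summaries, all pairwise two-sample t tests, and a
#' violin/box figure of the SD distributions — the comparison used to ask
#' whether stained (physically or virtually) image populations share a
#' phase-variability distribution and differ from fresh ones.
#'
#' @param groups named list; each element a list of \code{qobm_phase}
#'   objects or matrices (>= 2 images per group).
#' @param var_equal pooled-variance flag passed to
#'   \code{\link{welch_ttest}}.
#' @param bonferroni add a Bonferroni-adjusted column to the pairwise
#'   table. Default FALSE (raw p values).
#' @return Class \code{qobm_group_summary}: data frames \code{per_image}
#'   (group, image_id, phase_sd), \code{summary} (group, n, mean_sd,
#'   sd_of_sd), \code{tests} (group_a, group_b, t, dof, p[, p_bonferroni])
#'   and a ggplot object \code{plot}.
#' @export
group_summary <- function(groups, var_equal = FALSE, bonferroni = FALSE) {
  stopifnot(is.list(groups), length(groups) >= 2,
            !is.null(names(groups)), all(nzchar(names(groups))))
  for (g in names(groups))
    if (length(groups[[g]]) < 2)
      stop(sprintf("group '%s' has fewer than 2 images", g))
  per_image <- do.call(rbind, lapply(names(groups), function(g) {
    sds <- vapply(groups[[g]], phase_std, numeric(1))
    data.frame(group = g, image_id = seq_along(sds), phase_sd = sds)
  }))
  summary <- do.call(rbind, lapply(names(groups), function(g) {
    sds <- per_image$phase_sd[per_image$group == g]
    data.frame(group = g, n = length(sds), mean_sd = mean(sds),
               sd_of_sd = stats::sd(sds))
  }))
  pairs <- utils::combn(names(groups), 2)
  tests <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    tt <- welch_ttest(per_image$phase_sd[per_image$group == a],
                      per_image$phase_sd[per_image$group == b],
                      var_equal = var_equal)
    data.frame(group_a = a, group_b = b, t = tt$t_stat, dof = tt$dof,
               p = tt$p_value)
  }))
  if (bonferroni)
    tests$p_bonferroni <- pmin(1, tests$p * nrow(tests))
  plt <- ggplot2::ggplot(per_image,
                         ggplot2::aes(x = .data$group, y = .data$phase_sd,
                                      fill = .data$group)) +
    ggplot2::geom_violin(alpha = 0.5, show.legend = FALSE) +
    ggplot2::geom_boxplot(width = 0.15, outlier.size = 0.6,
                          show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "per-image phase SD (rad)",
                  title = "Distribution of phase standard deviations") +
    ggplot2::theme_minimal()
  structure(list(per_image = per_image, summary = summary, tests = tests,
                 plot = plt),
            class = "qobm_group_summary")
}

#' @export
print.qobm_group_summary <- function(x, ...) {
  cat("qOBM group summary of per-image phase SD\n")
  print(x$summary, row.names = FALSE)
  cat("pairwise tests:\n")
  print(x$tests, row.names = FALSE)
  invisible(x)
}
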