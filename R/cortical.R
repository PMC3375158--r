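#' Fraction of granules within the cortical shell of one cell
#'
#' Classifies each granule centroid as cortical when its minimal Euclidean
#' distance to the membrane outline is at most `shell_thickness_nm`
#' (closed shell: a granule exactly at the threshold counts as cortical).
#' Distance is measured from the centroid, not the granule edge; granule
#' radii (tens of nm) are well below the 500 nm scale of the statistic.
#'
#' @param scene a `granule_scene` (see [generate_em_scene()]) or a list with
#'   fields `cell_id`, `stage_class`, `boundary` (nm vertex matrix) and
#'   `granules` (nm centroid matrix).
#' @param shell_thickness_nm shell thickness in nm; default 500, the
#'   published definition of the peripheral docking region.
#' @return one-row data frame (class `shell_result`): `cell_id`,
#'   `stage_class`, `n_total`, `n_cortical`, `fraction`.
#' @examples
#' sc <- generate_em_scene(sg_preset("em_interphase", n_cells = 1, seed = 1))[[1]]
#' cortical_fraction(sc)
#' @export
cortical_fraction <- function(scene, shell_thickness_nm = 500) {
  stopifnot(shell_thickness_nm > 0)
  if (is.null(scene$granules) || nrow(scene$granules) == 0L) {
    stop("scene has no granules; fraction undefined")
  }
  d <- dist_to_polygon(scene$granules, scene$boundary)
  n_total <- length(d)
  n_cortical <- sum(d <= shell_thickness_nm)
  out <- data.frame(
    cell_id = scene$cell_id,
    stage_class = if (is.null(scene$stage_class)) NA_character_ else scene$stage_class,
    n_total = n_total,
    n_cortical = n_cortical,
    fraction = n_cortical / n_total,
    stringsAsFactors = FALSE
  )
  class(out) <- c("shell_result", class(out))
  out
}

#' Cortical fractions for a list of scenes
#'
#' @param scenes list of `granule_scene` objects.
#' @param shell_thickness_nm shell thickness in nm.
#' @return data frame with one row per cell.
#' @export
cortical_fractions <- function(scenes, shell_thickness_nm = 500) {
  do.call(rbind, lapply(scenes, cortical_fraction,
                        shell_thickness_nm = shell_thickness_nm))
}

#' Two-sample comparison of per-cell cortical percentages
#'
#' Classical (pooled-variance) Student's t-test on per-cell cortical
#' percentages, the test the study applied to its interphase-versus-
#' metaphase comparison. A Welch option is provided but the pooled test is
#' the default. Observations are the per-cell fractions expressed in
#' percent.
#'
#' @param results_a,results_b data frames of shell results (from
#'   [cortical_fraction()] / [cortical_fractions()]) for the two groups.
#' @param var_equal pooled-variance test when `TRUE` (default); Welch
#'   otherwise.
#' @return a `group_comparison` list: per-group mean/sd/n (percent), `t`,
#'   `df`, `p_value`, and `p_floor` flag (`TRUE` when the pooled variance is
#'   zero with unequal means, so p underflows the machine floor).
#' @export
compare_groups <- function(results_a, results_b, var_equal = TRUE) {
  xa <- 100 * results_a$fraction
  xb <- 100 * results_b$fraction
  if (length(xa) < 2L || length(xb) < 2L) {
    stop("need at least 2 cells per group")
  }
  compare_group_summaries(mean(xa), stats::sd(xa), length(xa),
                          mean(xb), stats::sd(xb), length(xb),
                          var_equal = var_equal)
}

#' Group comparison from summary statistics
#'
#' Summary-statistic entry path for the same pooled (or Welch) two-sample
#' t-test, for use when only group means, standard deviations and cell
#' counts are available (the study publishes its comparison in this form).
#'
#' @param mean_a,sd_a,n_a,mean_b,sd_b,n_b group summaries (percent scale by
#'   convention, but any common scale works).
#' @param var_equal pooled-variance test when `TRUE` (default).
#' @return a `group_comparison` list (see [compare_groups()]).
#' @examples
#' compare_group_summaries(70, 3, 3, 13, 4, 3)
#' @export
compare_group_summaries <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b,
                                    var_equal = TRUE) {
  stopifnot(n_a >= 2L, n_b >= 2L, sd_a >= 0, sd_b >= 0)
  delta <- mean_a - mean_b
  if (var_equal) {
    df <- n_a + n_b - 2
    sp2 <- ((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / df
    se <- sqrt(sp2 * (1 / n_a + 1 / n_b))
  } else {
    va <- sd_a^2 / n_a; vb <- sd_b^2 / n_b
    se <- sqrt(va + vb)
    df <- if (se == 0) n_a + n_b - 2 else
      (va + vb)^2 / (va^2 / (n_a - 1) + vb^2 / (n_b - 1))
  }
  p_floor <- FALSE
  if (se == 0) {
    if (delta == 0) {
      tstat <- 0; p <- 1
    } else {
      tstat <- sign(delta) * Inf
      p <- .Machine$double.xmin
      p_floor <- TRUE
    }
  } else {
    tstat <- delta / se
    p <- 2 * stats::pt(-abs(tstat), df)
    if (p == 0) {
      p <- .Machine$double.xmin
      p_floor <- TRUE
    }
  }
  structure(
    list(
      mean_a = mean_a, sd_a = sd_a, n_a = as.integer(n_a),
      mean_b = mean_b, sd_b = sd_b, n_b = as.integer(n_b),
      t = tstat, df = df, p_value = p, p_floor = p_floor,
      var_equal = var_equal
    ),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Two-sample %s t-test on per-cell cortical percentages\n",
              if (x$var_equal) "pooled" else "Welch"))
  cat(sprintf("  group A: mean %.2f sd %.2f n %d\n", x$mean_a, x$sd_a, x$n_a))
  cat(sprintf("  group B: mean %.2f sd %.2f n %d\n", x$mean_b, x$sd_b, x$n_b))
  cat(sprintf("  t = %.4f, df = %.3g, p = %s%.3g\n",
              x$t, x$df, if (x$p_floor) "< " else "", x$p_value))
  invisible(x)
}
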