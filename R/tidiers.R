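# broom-style tidy()/glance() methods for the package's fitted objects.

#' Tidy a standardized OLS fit
#'
#' @param x A [standardized_ols()] object.
#' @param ... Unused.
#' @return Tibble with one row per predictor: `outcome`, `term`, `beta`,
#'   `se`, `t`, `df`, `p`, `n`.
#' @method tidy std_ols
#' @export
tidy.std_ols <- function(x, ...) {
  x$results
}

#' Model-level summary of a standardized OLS fit
#'
#' @param x A [standardized_ols()] object.
#' @param ... Unused.
#' @return One-row tibble: `r.squared`, `adj.r.squared`, `sigma`, `df`, `n`.
#' @method glance std_ols
#' @export
glance.std_ols <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, adj.r.squared = x$adj_r_squared,
                 sigma = x$sigma, df = x$df, n = x$n)
}

#' Tidy a Procrustes alignment
#'
#' @param x A [gpa()] object.
#' @param ... Unused.
#' @return The aligned coordinates as a tibble (`face_id`, `point`, `x`,
#'   `y`).
#' @method tidy facecue_gpa
#' @export
tidy.facecue_gpa <- function(x, ...) {
  x$aligned
}

#' Alignment-level summary of a Procrustes fit
#'
#' @param x A [gpa()] object.
#' @param ... Unused.
#' @return One-row tibble: `n_faces`, `n_points`, `iterations`, `rms`.
#' @method glance facecue_gpa
#' @export
glance.facecue_gpa <- function(x, ...) {
  tibble::tibble(n_faces = length(x$ids), n_points = x$n_points,
                 iterations = x$iterations, rms = x$rms)
}

#' Tidy a dimorphism axis
#'
#' @param x A [dimorphism_axis()] object.
#' @param ... Unused.
#' @return Tibble with one row per landmark: the female and male mean
#'   positions and the per-landmark displacement (`dx`, `dy`).
#' @method tidy dimorphism_axis
#' @export
tidy.dimorphism_axis <- function(x, ...) {
  tibble::tibble(
    point = seq_len(x$n_points),
    female_x = x$female_mean[, 1L], female_y = x$female_mean[, 2L],
    male_x = x$male_mean[, 1L], male_y = x$male_mean[, 2L],
    dx = x$male_mean[, 1L] - x$female_mean[, 1L],
    dy = x$male_mean[, 2L] - x$female_mean[, 2L]
  )
}

#' Tidy an analysis result
#'
#' @param x A [run_analysis()] result.
#' @param ... Unused.
#' @return The effect table: one row per (sample, focal predictor, outcome,
#'   term) with `beta`, `t`, `df`, `p`, `bf10`, `n`.
#' @method tidy facecue_analysis
#' @export
tidy.facecue_analysis <- function(x, ...) {
  x$effects
}

#' Run-level summary of an analysis result
#'
#' @param x A [run_analysis()] result.
#' @param ... Unused.
#' @return One-row tibble with model counts and sample sizes.
#' @method glance facecue_analysis
#' @export
glance.facecue_analysis <- function(x, ...) {
  tibble::tibble(
    n_models = nrow(x$log$models),
    n_input = x$log$n_input,
    n_full = if ("full" %in% x$log$models$sample) {
      max(x$log$models$n[x$log$models$sample == "full"])
    } else NA_integer_,
    n_fathers_only = if ("fathers_only" %in% x$log$models$sample) {
      max(x$log$models$n[x$log$models$sample == "fathers_only"])
    } else NA_integer_,
    winsor_k = x$log$settings$winsor_k,
    prior_scale = x$log$settings$prior_scale
  )
}
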