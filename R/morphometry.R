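# Generalized Procrustes Analysis and the vector-method sexual-dimorphism
# score. All alignment is partial Procrustes: translation and scale removed,
# rotation only (no reflection — faces have handedness, and a mirrored
# delineation must not alias as shape change).

# Optimal rotation R (det = +1) minimizing ||X %*% R - target||_F.
optimal_rotation <- function(x, target) {
  m <- crossprod(x, target)
  sv <- svd(m)
  d <- sign(det(sv$u %*% t(sv$v)))
  sv$u %*% diag(c(1, d)) %*% t(sv$v)
}

center_scale_shape <- function(m) {
  cm <- colMeans(m)
  m <- sweep(m, 2L, cm)
  cs <- sqrt(sum(m^2))
  if (cs <= .Machine$double.eps) {
    abort("degenerate configuration: zero centroid size",
          class = "facecue_shape_error")
  }
  m / cs
}

#' Procrustes superimposition of one configuration onto another
#'
#' Centres both configurations, scales each to unit centroid size, and finds
#' the rotation (reflections disallowed) minimising the summed squared
#' distance between them.
#'
#' @param a,b Landmark configurations (single-face tidy tables or n x 2
#'   matrices) with the same number of points (at least 3).
#' @return A list with `rotation` (the 2 x 2 rotation applied to `a`),
#'   `distance` (the residual root-summed-squared Procrustes distance), and
#'   `aligned` (the transformed `a`).
#' @export
#' @examples
#' tri <- cbind(c(0, 1, 0), c(0, 0, 1))
#' align_pair(tri, tri)$distance  # 0
align_pair <- function(a, b) {
  ma <- as_landmark_matrix(a)
  mb <- as_landmark_matrix(b)
  if (nrow(ma) != nrow(mb)) {
    abort("configurations must have the same number of landmarks",
          class = "facecue_shape_error")
  }
  if (nrow(ma) < 3L) {
    abort("need at least 3 landmarks", class = "facecue_shape_error")
  }
  ua <- center_scale_shape(ma)
  ub <- center_scale_shape(mb)
  r <- optimal_rotation(ua, ub)
  aligned <- ua %*% r
  list(rotation = r, distance = sqrt(sum((aligned - ub)^2)), aligned = aligned)
}

#' Generalized Procrustes Analysis
#'
#' Iterative superimposition of two or more landmark configurations: each is
#' centred and scaled to unit centroid size, rotated to the current consensus,
#' and the consensus (coordinate-wise mean shape) recomputed, until the
#' consensus changes by less than `tol` (Frobenius norm).
#'
#' @param landmarks Tidy landmark table (`face_id`, `point`, `x`, `y`) with at
#'   least two faces sharing one landmark count.
#' @param tol Convergence tolerance on the consensus update. Default `1e-10`.
#' @param max_iter Maximum number of sweeps before aborting. Default 100;
#'   GPA ordinarily converges in a handful of iterations.
#'
#' @return An object of class `facecue_gpa`: a list with `aligned` (tidy
#'   tibble of aligned coordinates), `consensus` (tibble `point`, `x`, `y`),
#'   `ids`, `n_points`, `iterations`, and `rms` (root-mean-square residual
#'   around the consensus). Every aligned shape has centroid (0, 0) and unit
#'   centroid size.
#' @seealso [dimorphism_axis()], [score_faces()], [align_pair()]
#' @export
gpa <- function(landmarks, tol = 1e-10, max_iter = 100L) {
  arr <- as_landmark_array(landmarks)
  n_faces <- dim(arr)[3L]
  if (n_faces < 2L) {
    abort("GPA needs at least 2 configurations", class = "facecue_shape_error")
  }
  if (dim(arr)[1L] < 3L) {
    abort("need at least 3 landmarks", class = "facecue_shape_error")
  }
  for (i in seq_len(n_faces)) arr[, , i] <- center_scale_shape(arr[, , i])
  consensus <- arr[, , 1L]
  iter <- 0L
  delta <- Inf
  while (iter < max_iter) {
    iter <- iter + 1L
    for (i in seq_len(n_faces)) {
      arr[, , i] <- arr[, , i] %*% optimal_rotation(arr[, , i], consensus)
    }
    new_consensus <- apply(arr, c(1L, 2L), mean)
    delta <- sqrt(sum((new_consensus - consensus)^2))
    consensus <- new_consensus
    if (delta < tol) break
  }
  if (delta >= tol) {
    abort(sprintf(
      "GPA did not converge in %d iterations (last consensus change %.3e)",
      max_iter, delta
    ), class = "facecue_convergence_error")
  }
  rms <- sqrt(mean(apply(arr, 3L, function(s) sum((s - consensus)^2))))
  structure(
    list(
      aligned = array_to_tidy(arr),
      consensus = tibble::tibble(point = seq_len(dim(arr)[1L]),
                                 x = consensus[, 1L], y = consensus[, 2L]),
      ids = dimnames(arr)[[3L]],
      n_points = dim(arr)[1L],
      iterations = iter,
      rms = rms
    ),
    class = "facecue_gpa"
  )
}

#' @export
print.facecue_gpa <- function(x, ...) {
  cat(sprintf(
    "Generalized Procrustes alignment: %d faces x %d landmarks (%d iterations, rms %.4g)\n",
    length(x$ids), x$n_points, x$iterations, x$rms
  ))
  invisible(x)
}

aligned_tbl <- function(x) {
  if (inherits(x, "facecue_gpa")) x$aligned else x
}

#' Sexual-dimorphism axis between female and male mean shapes
#'
#' Computes the coordinate-wise mean shape of female and of male reference
#' faces (which must come from one joint Procrustes alignment together with
#' any faces to be scored) and the difference vector male mean minus female
#' mean in flattened shape space. Projection of a face onto this axis is the
#' vector-method masculinity score.
#'
#' @param aligned A [gpa()] result or its tidy aligned-coordinate tibble.
#' @param sex A data frame with columns `face_id` and `sex` (values `"female"`
#'   or `"male"`); faces missing from it are ignored (e.g., the target faces).
#' @return An object of class `dimorphism_axis`: list with `female_mean` and
#'   `male_mean` (n x 2 matrices), `axis` (length-2n vector, all x then all y
#'   coordinates), `norm_sq`, `n_female`, `n_male`, `n_points`.
#' @export
dimorphism_axis <- function(aligned, sex) {
  tbl <- aligned_tbl(aligned)
  stopifnot(is.data.frame(sex), all(c("face_id", "sex") %in% names(sex)))
  sex_map <- setNames(as.character(sex$sex), as.character(sex$face_id))
  arr <- as_landmark_array(tbl)
  ids <- dimnames(arr)[[3L]]
  sexes <- sex_map[ids]
  f_idx <- which(!is.na(sexes) & sexes == "female")
  m_idx <- which(!is.na(sexes) & sexes == "male")
  if (length(f_idx) < 1L || length(m_idx) < 1L) {
    abort("need at least one female and one male reference face")
  }
  mean_shape <- function(idx) {
    apply(arr[, , idx, drop = FALSE], c(1L, 2L), mean)
  }
  fm <- mean_shape(f_idx)
  mm <- mean_shape(m_idx)
  axis <- flatten_shape(mm) - flatten_shape(fm)
  norm_sq <- sum(axis^2)
  if (norm_sq <= .Machine$double.eps) {
    abort("degenerate dimorphism axis: female and male means coincide",
          class = "facecue_degenerate_axis_error")
  }
  structure(
    list(female_mean = fm, male_mean = mm, axis = axis, norm_sq = norm_sq,
         n_female = length(f_idx), n_male = length(m_idx),
         n_points = dim(arr)[1L]),
    class = "dimorphism_axis"
  )
}

#' @export
print.dimorphism_axis <- function(x, ...) {
  cat(sprintf(
    "Dimorphism axis: %d landmarks, %d female + %d male references, |v| = %.4g\n",
    x$n_points, x$n_female, x$n_male, sqrt(x$norm_sq)
  ))
  invisible(x)
}

#' Score faces along the sexual-dimorphism axis
#'
#' Projects each aligned face onto the female-to-male axis. The raw score is
#' the affine position along the axis, `s = (x - m_F) . v / |v|^2`, so the
#' female mean scores 0 and the male mean scores 1; higher scores are more
#' male-like. The scaled score is the z-score of the raw scores across the
#' supplied faces.
#'
#' @param aligned A [gpa()] result or aligned tidy coordinate tibble. The
#'   faces must come from the same joint alignment that produced `axis`.
#' @param axis A [dimorphism_axis()].
#' @param scale Compute the z-scored `scaled` column (default `TRUE`);
#'   requires at least two faces with non-zero raw-score spread.
#' @return A tibble (subclass `dimorphism_scores`) with columns `face_id`,
#'   `raw`, and (when `scale`) `scaled`; attribute `orientation` records that
#'   higher = more male-like.
#' @export
score_faces <- function(aligned, axis, scale = TRUE) {
  stopifnot(inherits(axis, "dimorphism_axis"))
  arr <- as_landmark_array(aligned_tbl(aligned))
  if (dim(arr)[1L] != axis$n_points) {
    abort("faces and axis disagree on landmark count",
          class = "facecue_shape_error")
  }
  f_flat <- flatten_shape(axis$female_mean)
  raw <- apply(arr, 3L, function(s) {
    sum((flatten_shape(s) - f_flat) * axis$axis)
  }) / axis$norm_sq
  out <- tibble::tibble(face_id = dimnames(arr)[[3L]], raw = unname(raw))
  if (scale) {
    if (nrow(out) < 2L) {
      abort("scaled scores are undefined for a single face; use scale = FALSE")
    }
    s <- sd(out$raw)
    if (s <= .Machine$double.eps) {
      abort("scaled scores are undefined: raw scores have zero spread")
    }
    out$scaled <- (out$raw - mean(out$raw)) / s
  }
  structure(out, class = c("dimorphism_scores", class(out)),
            orientation = "higher = more male-like")
}
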