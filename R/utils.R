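# Internal helpers shared across modules.

# Coerce a tidy landmark table (face_id, point, x, y) for one face, or an
# n x 2 matrix, into an n x 2 coordinate matrix.
as_landmark_matrix <- function(x) {
  if (is.matrix(x)) {
    if (ncol(x) != 2L) abort("landmark matrix must have 2 columns (x, y)")
    storage.mode(x) <- "double"
    return(x)
  }
  if (is.data.frame(x)) {
    if (!all(c("x", "y") %in% names(x))) {
      abort("landmark data frame needs columns `x` and `y`")
    }
    if ("face_id" %in% names(x) && length(unique(x$face_id)) > 1L) {
      abort("expected landmarks for a single face; got several `face_id`s")
    }
    if ("point" %in% names(x)) x <- x[order(x$point), , drop = FALSE]
    return(cbind(x = as.double(x$x), y = as.double(x$y)))
  }
  abort("cannot interpret input as a landmark configuration")
}

# Split a tidy landmark table into an n_points x 2 x n_faces array, faces in
# first-appearance order. Errors on heterogeneous point counts.
as_landmark_array <- function(landmarks) {
  stopifnot(is.data.frame(landmarks))
  if (!all(c("face_id", "x", "y") %in% names(landmarks))) {
    abort("landmark table needs columns face_id, x, y")
  }
  ids <- unique(as.character(landmarks$face_id))
  counts <- table(factor(as.character(landmarks$face_id), levels = ids))
  if (length(unique(as.integer(counts))) != 1L) {
    abort(
      "all faces must share one landmark count",
      class = "facecue_shape_error"
    )
  }
  n_pt <- as.integer(counts[[1L]])
  ord <- order(match(as.character(landmarks$face_id), ids))
  lm_sorted <- landmarks[ord, , drop = FALSE]
  if ("point" %in% names(lm_sorted)) {
    lm_sorted <- lm_sorted[order(match(as.character(lm_sorted$face_id), ids),
                                 lm_sorted$point), , drop = FALSE]
  }
  arr <- array(NA_real_, dim = c(n_pt, 2L, length(ids)),
               dimnames = list(NULL, c("x", "y"), ids))
  arr[, 1L, ] <- matrix(lm_sorted$x, nrow = n_pt)
  arr[, 2L, ] <- matrix(lm_sorted$y, nrow = n_pt)
  if (!all(is.finite(arr))) abort("landmark coordinates must be finite")
  arr
}

array_to_tidy <- function(arr) {
  ids <- dimnames(arr)[[3L]]
  n_pt <- dim(arr)[1L]
  tibble::tibble(
    face_id = rep(ids, each = n_pt),
    point = rep(seq_len(n_pt), times = length(ids)),
    x = as.vector(arr[, 1L, ]),
    y = as.vector(arr[, 2L, ])
  )
}

centroid_size <- function(m) {
  cm <- colMeans(m)
  sqrt(sum((m[, 1L] - cm[1L])^2 + (m[, 2L] - cm[2L])^2))
}

# Flattening convention everywhere: all x coordinates, then all y coordinates.
flatten_shape <- function(m) c(m[, 1L], m[, 2L])

sig_stars <- function(p) {
  dplyr::case_when(
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ ""
  )
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x < lower || x > upper) {
    abort(sprintf("`%s` must be a single number in [%s, %s]",
                  name, format(lower), format(upper)))
  }
  invisible(x)
}
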