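test_that("align_pair is exact on identity and similarity copies", {
  a <- random_config(20, 1)
  expect_equal(align_pair(a, a)$distance, 0, tolerance = 1e-12)
  b <- apply_similarity(a, 37 * pi / 180, 2.3, c(14, -6))
  expect_lt(align_pair(a, b)$distance, 1e-9)
  r <- align_pair(a, b)$rotation
  expect_equal(det(r), 1, tolerance = 1e-12)
})

test_that("align_pair rejects mismatched or degenerate input", {
  expect_error(align_pair(random_config(5, 1), random_config(6, 1)),
               class = "facecue_shape_error")
  flat <- cbind(rep(1, 4), rep(2, 4))  # all points coincide: zero size
  expect_error(align_pair(flat, random_config(4, 1)),
               class = "facecue_shape_error")
})

test_that("align_pair matches the rotation grid-search oracle", {
  tri_a <- cbind(c(0, 1, 0), c(0, 0, 1))
  tri_b <- cbind(c(0, 0, -2), c(0, 2, 0))
  expect_equal(align_pair(tri_a, tri_b)$distance,
               grid_search_distance(tri_a, tri_b), tolerance = 1e-4)
  for (seed in 1:6) {
    a <- random_config(12, seed)
    b <- random_config(12, seed + 100)
    expect_equal(align_pair(a, b)$distance, grid_search_distance(a, b),
                 tolerance = 1e-4)
  }
})

test_that("GPA collapses identical copies onto the consensus", {
  a <- random_config(15, 2)
  lm <- purrr::map_dfr(1:4, function(i) {
    tibble::tibble(face_id = paste0("f", i), point = 1:15,
                   x = a[, 1], y = a[, 2])
  })
  g <- gpa(lm)
  consensus <- as.matrix(g$consensus[c("x", "y")])
  for (id in g$ids) {
    s <- as.matrix(dplyr::filter(g$aligned, face_id == id)[c("x", "y")])
    expect_lt(max(abs(s - consensus)), 1e-12)
  }
})

test_that("GPA removes similarity transforms and satisfies its invariants", {
  a <- random_config(30, 5)
  set.seed(11)
  lm <- purrr::map_dfr(1:6, function(i) {
    m <- apply_similarity(a, runif(1, -pi, pi), runif(1, 0.5, 2),
                          runif(2, -100, 100))
    tibble::tibble(face_id = paste0("f", i), point = 1:30,
                   x = m[, 1], y = m[, 2])
  })
  g <- gpa(lm)
  shapes <- split(g$aligned[c("x", "y")], g$aligned$face_id)
  for (s in shapes) {
    m <- as.matrix(s)
    expect_lt(max(abs(colMeans(m))), 1e-9)        # centroid at origin
    expect_equal(sqrt(sum(m^2)), 1, tolerance = 1e-9)  # unit centroid size
  }
  # all aligned shapes agree (pure similarity copies)
  ref <- as.matrix(shapes[[1]])
  for (s in shapes[-1]) expect_lt(max(abs(as.matrix(s) - ref)), 1e-8)
  # consensus equals the coordinate-wise mean of the aligned shapes
  mean_shape <- Reduce(`+`, lapply(shapes, as.matrix)) / length(shapes)
  expect_lt(max(abs(mean_shape - as.matrix(g$consensus[c("x", "y")]))), 1e-9)
})

test_that("GPA rejects heterogeneous landmark counts and lone shapes", {
  lm <- dplyr::bind_rows(
    tibble::tibble(face_id = "a", point = 1:5,
                   x = rnorm(5), y = rnorm(5)),
    tibble::tibble(face_id = "b", point = 1:6,
                   x = rnorm(6), y = rnorm(6))
  )
  expect_error(gpa(lm), class = "facecue_shape_error")
  expect_error(gpa(dplyr::filter(lm, face_id == "a")),
               class = "facecue_shape_error")
})

test_that("two-configuration GPA agrees with align_pair", {
  a <- random_config(18, 7)
  b <- random_config(18, 8)
  lm <- dplyr::bind_rows(
    tibble::tibble(face_id = "a", point = 1:18, x = a[, 1], y = a[, 2]),
    tibble::tibble(face_id = "b", point = 1:18, x = b[, 1], y = b[, 2])
  )
  g <- gpa(lm)
  sa <- as.matrix(dplyr::filter(g$aligned, face_id == "a")[c("x", "y")])
  sb <- as.matrix(dplyr::filter(g$aligned, face_id == "b")[c("x", "y")])
  expect_equal(sqrt(sum((sa - sb)^2)), align_pair(a, b)$distance,
               tolerance = 1e-6)
})

make_aligned_sample <- function(shapes, ids) {
  purrr::map2_dfr(shapes, ids, function(m, id) {
    tibble::tibble(face_id = id, point = seq_len(nrow(m)),
                   x = m[, 1], y = m[, 2])
  })
}

test_that("dimorphism axis is the difference of sex means and antisymmetric", {
  s1 <- random_config(10, 1) / 1000
  s2 <- random_config(10, 2) / 1000
  tbl <- make_aligned_sample(list(s1, s1, s2, s2, s2),
                             c("f1", "f2", "m1", "m2", "m3"))
  sex <- tibble::tibble(face_id = c("f1", "f2", "m1", "m2", "m3"),
                        sex = c("female", "female", "male", "male", "male"))
  ax <- dimorphism_axis(tbl, sex)
  expect_equal(ax$axis, c(s2[, 1] - s1[, 1], s2[, 2] - s1[, 2]),
               tolerance = 1e-12)
  sex_swapped <- dplyr::mutate(sex, sex = ifelse(sex == "male", "female",
                                                 "male"))
  ax2 <- dimorphism_axis(tbl, sex_swapped)
  expect_equal(ax2$axis, -ax$axis, tolerance = 1e-12)
  # identical sex means are degenerate
  tbl_same <- make_aligned_sample(list(s1, s1), c("f1", "m1"))
  expect_error(
    dimorphism_axis(tbl_same,
                    tibble::tibble(face_id = c("f1", "m1"),
                                   sex = c("female", "male"))),
    class = "facecue_degenerate_axis_error"
  )
})

test_that("projection scores hit the endpoints and obey linearity", {
  s1 <- random_config(12, 3) / 1000
  s2 <- random_config(12, 4) / 1000
  mid <- (s1 + s2) / 2
  sex <- tibble::tibble(face_id = c("f1", "m1"),
                        sex = c("female", "male"))
  ax <- dimorphism_axis(make_aligned_sample(list(s1, s2), c("f1", "m1")), sex)
  tbl <- make_aligned_sample(list(s1, s2, mid), c("t0", "t1", "thalf"))
  sc <- score_faces(tbl, ax)
  expect_equal(sc$raw[sc$face_id == "t0"], 0, tolerance = 1e-12)
  expect_equal(sc$raw[sc$face_id == "t1"], 1, tolerance = 1e-12)
  # explicit dot-product oracle for the midpoint
  v <- c(s2[, 1] - s1[, 1], s2[, 2] - s1[, 2])
  oracle_mid <- sum((c(mid[, 1], mid[, 2]) - c(s1[, 1], s1[, 2])) * v) /
    sum(v^2)
  expect_equal(sc$raw[sc$face_id == "thalf"], oracle_mid, tolerance = 1e-12)
  expect_equal(oracle_mid, 0.5, tolerance = 1e-12)
  # z-scored column has mean 0 and sd 1
  expect_equal(mean(sc$scaled), 0, tolerance = 1e-9)
  expect_equal(sd(sc$scaled), 1, tolerance = 1e-9)
})

test_that("components orthogonal to the axis leave scores unchanged", {
  s1 <- random_config(12, 5) / 1000
  s2 <- random_config(12, 6) / 1000
  sex <- tibble::tibble(face_id = c("f1", "m1"), sex = c("female", "male"))
  ax <- dimorphism_axis(make_aligned_sample(list(s1, s2), c("f1", "m1")), sex)
  set.seed(9)
  w <- rnorm(24)
  w <- w - sum(w * ax$axis) / ax$norm_sq * ax$axis  # orthogonalize
  target <- s1 + 0.3 * matrix(ax$axis, ncol = 2)
  bumped <- target + matrix(w, ncol = 2)
  sc <- score_faces(make_aligned_sample(list(target, bumped), c("a", "b")),
                    ax, scale = FALSE)
  expect_lt(abs(diff(sc$raw)), 1e-9)
  expect_equal(sc$raw[1], 0.3, tolerance = 1e-9)
})

test_that("single-face scaling request errors", {
  s1 <- random_config(12, 5) / 1000
  s2 <- random_config(12, 6) / 1000
  sex <- tibble::tibble(face_id = c("f1", "m1"), sex = c("female", "male"))
  ax <- dimorphism_axis(make_aligned_sample(list(s1, s2), c("f1", "m1")), sex)
  one <- make_aligned_sample(list(s1), "solo")
  expect_error(score_faces(one, ax))
  expect_silent(score_faces(one, ax, scale = FALSE))
})

test_that("male references outscore female references and known positions are recovered", {
  cfg <- tiny_cfg(seed = 5)
  faces <- gen_faces(cfg)
  g <- gpa(faces$landmarks)
  refs <- dplyr::filter(faces$meta, role != "participant")
  ax <- dimorphism_axis(g, refs[c("face_id", "sex")])
  sc_refs <- score_faces(
    dplyr::filter(g$aligned, face_id %in% refs$face_id), ax, scale = FALSE
  )
  by_sex <- dplyr::left_join(sc_refs, refs, by = "face_id") |>
    dplyr::group_by(sex) |>
    dplyr::summarise(m = mean(raw))
  expect_gt(by_sex$m[by_sex$sex == "male"], by_sex$m[by_sex$sex == "female"])

  pp <- dplyr::filter(faces$meta, role == "participant")
  sc <- score_faces(dplyr::filter(g$aligned, face_id %in% pp$face_id), ax)
  expect_gt(cor(sc$raw, pp$t_true[match(sc$face_id, pp$face_id)]), 0.8)
})

test_that("raw scores are invariant to similarity transforms of all inputs", {
  cfg <- tiny_cfg(seed = 8)
  faces <- gen_faces(cfg)
  score_all <- function(landmarks) {
    g <- gpa(landmarks)
    refs <- dplyr::filter(faces$meta, role != "participant")
    ax <- dimorphism_axis(g, refs[c("face_id", "sex")])
    sc <- score_faces(g$aligned, ax, scale = FALSE)
    sc$raw[order(sc$face_id)]
  }
  base <- score_all(faces$landmarks)
  set.seed(123)
  transformed <- faces$landmarks |>
    dplyr::group_by(face_id) |>
    dplyr::group_modify(function(d, key) {
      m <- apply_similarity(cbind(d$x, d$y), runif(1, -pi, pi),
                            runif(1, 0.5, 2), runif(2, -200, 200))
      dplyr::mutate(d, x = m[, 1], y = m[, 2])
    }) |>
    dplyr::ungroup()
  expect_lt(max(abs(score_all(transformed) - base)), 1e-6)
})
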