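# Synthetic-study generator. Emulates the study's inputs with known ground
# truth: a stylized 131-landmark face template, a hidden dimorphism direction
# in shape space, reference faces of both sexes, participant faces positioned
# along the direction, rater pools producing 1-10 ratings of three traits,
# and 1-5 Likert self-report scales with a participant exclusion funnel.
#
# The generator is linear-Gaussian with ordinal discretization at the
# measurement step: the simplest structure that satisfies every assumption
# the downstream analysis makes (linearity, additive noise).

#' Configuration for the synthetic-study generator
#'
#' Defaults reproduce the emulated study's design: 259 participant faces (156
#' fathers) with 131 landmarks each, 49 female + 53 male reference faces, a
#' rater pool of 422 with roughly 33.55 ratings per face per trait, 1-5
#' Likert self-reports, and an exclusion funnel of 28 (no photo) + 21 (low
#' seriousness) + 2 (language) + 1 duplicated enrolment applied to the
#' recruited roster. True effects default to zero for dimorphism and negative
#' for attractiveness on perceived and desired involvement.
#'
#' @param seed Integer seed; every `gen_*` function derives its stream from
#'   it, so equal configurations give bit-identical data.
#' @param n_landmarks Landmarks per face (default 131).
#' @param n_ref_female,n_ref_male Reference faces per sex (49, 53).
#' @param n_participants Participant faces surviving exclusions (259).
#' @param n_fathers Number of participants who are fathers (156).
#' @param ratings_per_face_per_trait Expected ratings per face and trait
#'   (default 33.55).
#' @param rater_pool Named vector of rater counts by sex
#'   (`male`, `female`, `other`); default 140/240/42.
#' @param low_seriousness_rate Probability a rater is flagged as not serious
#'   (seriousness below 5); default 0.01, about 4 of 422 in expectation.
#' @param landmark_noise_sd Isotropic per-landmark delineation noise, pixels
#'   (default 6; about 9% of the dimorphism-axis length, comfortably below
#'   the 25% at which score recovery starts to degrade).
#' @param dimorphism_scale Length of the female-to-male displacement as a
#'   fraction of the template's centroid size (default 0.04 — facial shape
#'   dimorphism is a subtle signal).
#' @param ref_spread Within-sex SD of the true axis position, in units where
#'   the female mean sits at 0 and the male mean at 1 (default 0.35).
#' @param participant_spread SD of participant positions around the male mean
#'   (participants are all men; default 0.5).
#' @param rating_scale,rating_noise_sd,rater_bias_sd Linear map from latent
#'   trait (z units) to the 10-point scale: a rating is
#'   `round(5.5 + rating_scale * latent + bias + noise)` clamped to 1-10,
#'   with per-rater bias SD `rater_bias_sd` and residual SD
#'   `rating_noise_sd` (defaults 1.5, 1.5, 0.5).
#' @param item_scale,item_noise_sd Same idea for 5-point scale items:
#'   `round(3 + item_scale * latent + noise)` clamped to 1-5 (defaults 0.9,
#'   0.8).
#' @param fis_na_rate Probability an FIS item is marked not applicable
#'   (default 0.08).
#' @param outcome_cor Residual correlations among the self-report latents:
#'   named vector with `nfs_fis_involved` (0.6), `nfs_fis_desired` (0.1),
#'   `fis_involved_desired` (0.1).
#' @param predictor_cor Correlations of the latent attractiveness and
#'   masculinity judgements with the true dimorphism position:
#'   `dimorphism_attractiveness` (0.16), `dimorphism_masculinity` (0.28).
#' @param true_effects Named list mapping each outcome
#'   (`perceived_paternal_involvement`, `nfs`, `fis_involved`,
#'   `fis_desired`) to a vector of standardized effects of `dimorphism` and
#'   `attractiveness`. Defaults: all dimorphism effects 0; attractiveness
#'   -0.44 on perceived involvement and -0.13 on desired involvement.
#' @param exclusion_counts Exact injected exclusion-flag counts for the
#'   roster, named `no_photo`, `seriousness`, `language`, `duplicate`
#'   (defaults 28, 21, 2, 1; the duplicate enrolment contributes two roster
#'   records for one participant).
#' @return A validated list of class `facecue_sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_landmarks = 131L,
                       n_ref_female = 49L,
                       n_ref_male = 53L,
                       n_participants = 259L,
                       n_fathers = 156L,
                       ratings_per_face_per_trait = 33.55,
                       rater_pool = c(male = 140L, female = 240L, other = 42L),
                       low_seriousness_rate = 0.01,
                       landmark_noise_sd = 6,
                       dimorphism_scale = 0.04,
                       ref_spread = 0.35,
                       participant_spread = 0.5,
                       rating_scale = 1.5,
                       rating_noise_sd = 1.5,
                       rater_bias_sd = 0.5,
                       item_scale = 0.9,
                       item_noise_sd = 0.8,
                       fis_na_rate = 0.08,
                       outcome_cor = c(nfs_fis_involved = 0.6,
                                       nfs_fis_desired = 0.1,
                                       fis_involved_desired = 0.1),
                       predictor_cor = c(dimorphism_attractiveness = 0.16,
                                         dimorphism_masculinity = 0.28),
                       true_effects = list(
                         perceived_paternal_involvement =
                           c(dimorphism = 0, attractiveness = -0.44),
                         nfs = c(dimorphism = 0, attractiveness = 0),
                         fis_involved = c(dimorphism = 0, attractiveness = 0),
                         fis_desired = c(dimorphism = 0, attractiveness = -0.13)
                       ),
                       exclusion_counts = c(no_photo = 28L, seriousness = 21L,
                                            language = 2L, duplicate = 1L)) {
  cfg <- as.list(environment())
  counts <- c(cfg$n_landmarks, cfg$n_ref_female, cfg$n_ref_male,
              cfg$n_participants, cfg$n_fathers, cfg$rater_pool)
  if (any(counts < 1L)) abort("all counts must be positive")
  if (cfg$n_landmarks < 3L) abort("n_landmarks must be >= 3")
  if (cfg$n_fathers > cfg$n_participants) {
    abort("n_fathers cannot exceed n_participants")
  }
  sds <- c(cfg$landmark_noise_sd, cfg$rating_noise_sd, cfg$rater_bias_sd,
           cfg$item_noise_sd)
  if (any(sds < 0)) abort("noise SDs must be >= 0")
  effs <- unlist(cfg$true_effects)
  if (any(abs(effs) >= 1)) abort("|true effects| must be < 1")
  structure(cfg, class = "facecue_sim_config")
}

#' @export
print.facecue_sim_config <- function(x, ...) {
  cat(sprintf(
    "Synthetic-study config: seed %d, %d participants (%d fathers), %d+%d refs, %d landmarks\n",
    x$seed, x$n_participants, x$n_fathers, x$n_ref_female, x$n_ref_male,
    x$n_landmarks
  ))
  invisible(x)
}

# Deterministic stylized face template: landmarks on three elliptical rings
# (outline, upper features, lower features) in image coordinates (y down),
# with a mild asymmetric wobble so the configuration has no exact symmetry.
face_template <- function(n_landmarks) {
  n1 <- ceiling(n_landmarks * 0.45)
  n2 <- ceiling(n_landmarks * 0.30)
  n3 <- n_landmarks - n1 - n2
  ring <- function(n, a, b, cx, cy, phase) {
    th <- seq(0, 2 * pi, length.out = n + 1L)[seq_len(n)] + phase
    wob <- 1 + 0.08 * sin(3 * th + 0.7)
    cbind(x = cx + a * wob * cos(th), y = cy + b * wob * sin(th))
  }
  pts <- rbind(
    ring(n1, 170, 220, 256, 300, 0.00),
    ring(n2, 95, 60, 256, 240, 0.35),
    ring(n3, 60, 80, 256, 370, 0.80)
  )
  unname(pts)
}

# Unit direction in flattened shape space orthogonal to the similarity group
# tangent at the template (translations, scaling, rotation), so the injected
# dimorphism is pure shape change that GPA cannot remove.
dimorphism_direction <- function(template) {
  n <- nrow(template)
  tc <- sweep(template, 2L, colMeans(template))
  basis <- cbind(
    c(rep(1, n), rep(0, n)) / sqrt(n),
    c(rep(0, n), rep(1, n)) / sqrt(n),
    flatten_shape(tc) / sqrt(sum(tc^2)),
    flatten_shape(cbind(-tc[, 2L], tc[, 1L])) / sqrt(sum(tc^2))
  )
  d <- rnorm(2L * n)
  d <- d - basis %*% crossprod(basis, d)
  as.vector(d / sqrt(sum(d^2)))
}

similarity_transform <- function(m, angle, scale, shift) {
  r <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2L, 2L)
  sweep(scale * m %*% r, 2L, shift, "+")
}

#' Generate synthetic reference and participant faces
#'
#' Builds the template, a hidden dimorphism direction, sex mean shapes offset
#' along it (female at position 0, male at 1), and draws reference faces
#' around their sex mean and participant faces at positions `t` around the
#' male mean. Each face gets isotropic landmark noise and a random similarity
#' transform (rotation, translation, positive scaling), exercising the
#' Procrustes invariances downstream.
#'
#' @param cfg A [sim_config()].
#' @return List with `landmarks` (tidy landmark tibble, references then
#'   participants), `meta` (tibble `face_id`, `role`, `sex`, `is_father`,
#'   `t_true`), and `truth` (list: `template`, `direction`, `axis_length` in
#'   pixels).
#' @export
gen_faces <- function(cfg) {
  stopifnot(inherits(cfg, "facecue_sim_config"))
  set.seed(cfg$seed)
  template <- face_template(cfg$n_landmarks)
  n <- cfg$n_landmarks
  direction <- dimorphism_direction(template)
  axis_length <- cfg$dimorphism_scale * centroid_size(template)
  delta <- matrix(direction * axis_length, ncol = 2L)

  meta <- tibble::tibble(
    face_id = c(sprintf("F%03d", seq_len(cfg$n_ref_female)),
                sprintf("M%03d", seq_len(cfg$n_ref_male)),
                sprintf("P%03d", seq_len(cfg$n_participants))),
    role = rep(c("ref_female", "ref_male", "participant"),
               c(cfg$n_ref_female, cfg$n_ref_male, cfg$n_participants)),
    sex = rep(c("female", "male", "male"),
              c(cfg$n_ref_female, cfg$n_ref_male, cfg$n_participants)),
    t_true = c(rnorm(cfg$n_ref_female, 0, cfg$ref_spread),
               rnorm(cfg$n_ref_male, 1, cfg$ref_spread),
               rnorm(cfg$n_participants, 1, cfg$participant_spread))
  )
  meta$is_father <- FALSE
  meta$is_father[meta$role == "participant"][
    sample.int(cfg$n_participants, cfg$n_fathers)] <- TRUE

  shapes <- purrr::map(seq_len(nrow(meta)), function(i) {
    s <- template + meta$t_true[[i]] * delta +
      matrix(rnorm(2L * n, 0, cfg$landmark_noise_sd), ncol = 2L)
    similarity_transform(
      s,
      angle = runif(1, -pi / 6, pi / 6),
      scale = runif(1, 0.7, 1.4),
      shift = runif(2, -80, 80)
    )
  })
  landmarks <- purrr::map2_dfr(shapes, meta$face_id, function(s, id) {
    tibble::tibble(face_id = id, point = seq_len(n), x = s[, 1L], y = s[, 2L])
  })
  list(
    landmarks = landmarks,
    meta = meta,
    truth = list(template = template, direction = direction,
                 axis_length = axis_length)
  )
}

# Latent judgement/outcome traits for participants, in z units. The
# correlations with the true dimorphism position and the configured true
# effects define the generating model the analysis tries to recover.
#' Latent trait values for the synthetic participants
#'
#' Draws, per participant, standard-normal latent attractiveness and
#' perceived masculinity correlated with the true dimorphism position, and
#' the latent perceived-involvement judgement as the configured linear
#' function of dimorphism and attractiveness plus Gaussian noise.
#'
#' @param cfg A [sim_config()].
#' @param meta The `meta` table from [gen_faces()] (or any table with
#'   `face_id`, `role`, `t_true`).
#' @return Tibble `face_id`, `t_z`, `attractiveness`, `masculinity`, `ppi`
#'   (all z-scaled latents) for participants only.
#' @export
gen_latent_traits <- function(cfg, meta) {
  stopifnot(inherits(cfg, "facecue_sim_config"))
  set.seed(cfg$seed + 1L)
  pp <- meta[meta$role == "participant", , drop = FALSE]
  n <- nrow(pp)
  t_z <- as.vector(scale(pp$t_true))
  r_a <- cfg$predictor_cor[["dimorphism_attractiveness"]]
  r_m <- cfg$predictor_cor[["dimorphism_masculinity"]]
  attract <- r_a * t_z + sqrt(1 - r_a^2) * rnorm(n)
  masc <- r_m * t_z + sqrt(1 - r_m^2) * rnorm(n)
  b <- cfg$true_effects$perceived_paternal_involvement
  var_lin <- b[["dimorphism"]]^2 + b[["attractiveness"]]^2 +
    2 * b[["dimorphism"]] * b[["attractiveness"]] * r_a
  if (var_lin >= 1) abort("true effects imply latent variance >= 1")
  ppi <- b[["dimorphism"]] * t_z + b[["attractiveness"]] * attract +
    sqrt(1 - var_lin) * rnorm(n)
  tibble::tibble(face_id = pp$face_id, t_z = t_z, attractiveness = attract,
                 masculinity = masc, ppi = ppi)
}

discretize_rating <- function(latent, scale, noise) {
  pmin(10, pmax(1, round(5.5 + scale * latent + noise)))
}

discretize_item <- function(latent, scale, noise) {
  pmin(5, pmax(1, round(3 + scale * latent + noise)))
}

#' Generate synthetic rating records
#'
#' Each rater is assigned one trait and rates a random subset of the faces on
#' the 10-point scale: the face's latent trait value is mapped linearly to
#' the scale, perturbed by a per-rater bias and residual noise, rounded, and
#' clamped to 1-10. Low-seriousness raters are injected at the configured
#' rate.
#'
#' @param cfg A [sim_config()].
#' @param latents Latent traits from [gen_latent_traits()].
#' @return Tibble of rating records: `rater_id`, `face_id`, `trait`, `value`,
#'   `rater_sex`, `seriousness`.
#' @export
gen_ratings <- function(cfg, latents) {
  stopifnot(inherits(cfg, "facecue_sim_config"))
  set.seed(cfg$seed + 2L)
  pool <- cfg$rater_pool
  n_raters <- sum(pool)
  raters <- tibble::tibble(
    rater_id = sprintf("R%04d", seq_len(n_raters)),
    rater_sex = rep(names(pool), pool)[sample.int(n_raters)],
    trait = RATING_TRAITS[(sample.int(n_raters) %% 3L) + 1L],
    flagged = runif(n_raters) < cfg$low_seriousness_rate
  )
  raters$seriousness <- ifelse(raters$flagged,
                               sample(1:4, n_raters, replace = TRUE),
                               sample(5:7, n_raters, replace = TRUE))
  raters$bias <- rnorm(n_raters, 0, cfg$rater_bias_sd)
  latent_cols <- c(attractiveness = "attractiveness",
                   perceived_masculinity = "masculinity",
                   perceived_paternal_involvement = "ppi")
  n_faces <- nrow(latents)
  purrr::map_dfr(RATING_TRAITS, function(tr) {
    rt <- raters[raters$trait == tr, , drop = FALSE]
    p_include <- cfg$ratings_per_face_per_trait / nrow(rt)
    if (p_include > 1) {
      abort(sprintf(
        "ratings_per_face_per_trait = %.1f not achievable with %d raters on trait %s",
        cfg$ratings_per_face_per_trait, nrow(rt), tr
      ), class = "facecue_design_error")
    }
    grid <- tidyr::expand_grid(
      rater_idx = seq_len(nrow(rt)),
      face_idx = seq_len(n_faces)
    )
    grid <- grid[runif(nrow(grid)) < p_include, , drop = FALSE]
    latent <- latents[[latent_cols[[tr]]]][grid$face_idx]
    tibble::tibble(
      rater_id = rt$rater_id[grid$rater_idx],
      face_id = latents$face_id[grid$face_idx],
      trait = tr,
      value = as.integer(discretize_rating(
        latent, cfg$rating_scale,
        rt$bias[grid$rater_idx] + rnorm(nrow(grid), 0, cfg$rating_noise_sd)
      )),
      rater_sex = rt$rater_sex[grid$rater_idx],
      seriousness = rt$seriousness[grid$rater_idx]
    )
  })
}

# Correlated self-report latents: configured linear effects of dimorphism and
# attractiveness plus residuals with the configured residual correlations.
self_report_latents <- function(cfg, latents) {
  n <- nrow(latents)
  r_a <- cfg$predictor_cor[["dimorphism_attractiveness"]]
  oc <- cfg$outcome_cor
  sigma <- matrix(c(
    1, oc[["nfs_fis_involved"]], oc[["nfs_fis_desired"]],
    oc[["nfs_fis_involved"]], 1, oc[["fis_involved_desired"]],
    oc[["nfs_fis_desired"]], oc[["fis_involved_desired"]], 1
  ), 3L, 3L)
  resid <- matrix(rnorm(n * 3L), n, 3L) %*% chol(sigma)
  out <- purrr::imap(list(nfs = cfg$true_effects$nfs,
                          fis_involved = cfg$true_effects$fis_involved,
                          fis_desired = cfg$true_effects$fis_desired),
                     function(b, nm) {
    var_lin <- b[["dimorphism"]]^2 + b[["attractiveness"]]^2 +
      2 * b[["dimorphism"]] * b[["attractiveness"]] * r_a
    if (var_lin >= 1) abort("true effects imply latent variance >= 1")
    k <- match(nm, c("nfs", "fis_involved", "fis_desired"))
    b[["dimorphism"]] * latents$t_z +
      b[["attractiveness"]] * latents$attractiveness +
      sqrt(1 - var_lin) * resid[, k]
  })
  tibble::as_tibble(out)
}

rate_items <- function(latent, n_items, cfg, na_rate = 0) {
  n <- length(latent)
  m <- matrix(
    discretize_item(rep(latent, times = n_items), cfg$item_scale,
                    rnorm(n * n_items, 0, cfg$item_noise_sd)),
    nrow = n
  )
  if (na_rate > 0) m[matrix(runif(n * n_items) < na_rate, n)] <- NA
  m
}

#' Generate synthetic self-report questionnaire responses
#'
#' Produces the wide participant table the scales module consumes: NFS items
#' (9, 1-5, no missing), FIS reported- and desired-involvement items (20
#' each, 1-5, "not applicable" injected at the configured rate), exclusion
#' flags, and the recruitment roster around the kept participants (extra
#' records carrying the no-photo / low-seriousness / language / duplicate
#' flags, the duplicate enrolment appearing as two records of one
#' participant).
#'
#' @param cfg A [sim_config()].
#' @param latents Latent traits from [gen_latent_traits()].
#' @param meta Face metadata from [gen_faces()].
#' @return Wide tibble, one row per roster record: `participant_id`,
#'   `is_father`, `has_photo`, `seriousness`, `language_issue`, `duplicate`,
#'   `nfs_1..9`, `fisR_1..20`, `fisD_1..20`. Attribute `"truth"` holds the
#'   latent outcome values of the kept participants.
#' @export
gen_self_reports <- function(cfg, latents, meta) {
  stopifnot(inherits(cfg, "facecue_sim_config"))
  set.seed(cfg$seed + 3L)
  sr <- self_report_latents(cfg, latents)
  pp <- meta[meta$role == "participant", , drop = FALSE]
  n <- nrow(latents)

  kept <- tibble::tibble(
    participant_id = latents$face_id,
    is_father = pp$is_father[match(latents$face_id, pp$face_id)],
    has_photo = TRUE,
    seriousness = sample(5:7, n, replace = TRUE),
    language_issue = FALSE,
    duplicate = FALSE
  )
  item_block <- function(lat, na_rate) {
    nfs <- rate_items(lat$nfs, 9L, cfg, na_rate = 0)
    fisr <- rate_items(lat$fis_involved, 20L, cfg, na_rate = na_rate)
    fisd <- rate_items(lat$fis_desired, 20L, cfg, na_rate = na_rate)
    colnames(nfs) <- paste0("nfs_", 1:9)
    colnames(fisr) <- paste0("fisR_", 1:20)
    colnames(fisd) <- paste0("fisD_", 1:20)
    tibble::as_tibble(cbind(nfs, fisr, fisd))
  }
  kept <- dplyr::bind_cols(kept, item_block(sr, cfg$fis_na_rate))

  ec <- cfg$exclusion_counts
  n_extra_people <- sum(ec)
  extra_lat <- tibble::as_tibble(
    as.data.frame(matrix(rnorm(n_extra_people * 3L), ncol = 3L,
                         dimnames = list(NULL, c("nfs", "fis_involved",
                                                 "fis_desired"))))
  )
  extras <- tibble::tibble(
    participant_id = c(sprintf("XNP%02d", seq_len(ec[["no_photo"]])),
                       sprintf("XSR%02d", seq_len(ec[["seriousness"]])),
                       sprintf("XLG%02d", seq_len(ec[["language"]])),
                       sprintf("XDP%02d", seq_len(ec[["duplicate"]]))),
    reason = rep(names(ec), ec),
    is_father = runif(n_extra_people) < cfg$n_fathers / cfg$n_participants
  )
  extras$has_photo <- extras$reason != "no_photo"
  extras$seriousness <- ifelse(extras$reason == "seriousness",
                               sample(1:4, n_extra_people, replace = TRUE),
                               sample(5:7, n_extra_people, replace = TRUE))
  extras$language_issue <- extras$reason == "language"
  extras$duplicate <- extras$reason == "duplicate"
  extras <- dplyr::bind_cols(extras[setdiff(names(extras), "reason")],
                             item_block(extra_lat, cfg$fis_na_rate))
  # a duplicated enrolment = one participant, two roster records
  dup_rows <- extras[extras$duplicate, , drop = FALSE]
  roster <- dplyr::bind_rows(kept, extras, dup_rows)
  roster <- roster[sample.int(nrow(roster)), , drop = FALSE]
  attr(roster, "truth") <- dplyr::bind_cols(
    tibble::tibble(participant_id = latents$face_id), sr
  )
  roster
}

#' Generate a complete synthetic study
#'
#' Runs [gen_faces()], [gen_latent_traits()], [gen_ratings()], and
#' [gen_self_reports()] under one configuration and bundles the results.
#'
#' @param cfg A [sim_config()].
#' @return An object of class `facecue_study`: list with `landmarks`,
#'   `face_meta`, `ratings`, `self_reports`, `truth` (latent traits plus the
#'   landmark-space ground truth), and `config`.
#' @seealso [analyse_study()] for the end-to-end analysis of the bundle.
#' @export
simulate_study <- function(cfg = sim_config()) {
  faces <- gen_faces(cfg)
  latents <- gen_latent_traits(cfg, faces$meta)
  ratings <- gen_ratings(cfg, latents)
  self_reports <- gen_self_reports(cfg, latents, faces$meta)
  structure(
    list(
      landmarks = faces$landmarks,
      face_meta = faces$meta,
      ratings = ratings,
      self_reports = self_reports,
      truth = list(latents = latents, shape = faces$truth,
                   self_report_latents = attr(self_reports, "truth")),
      config = cfg
    ),
    class = "facecue_study"
  )
}

#' @export
print.facecue_study <- function(x, ...) {
  cat(sprintf(
    "Synthetic study: %d faces (%d participants), %d rating records, %d roster records\n",
    length(unique(x$landmarks$face_id)),
    sum(x$face_meta$role == "participant"),
    nrow(x$ratings), nrow(x$self_reports)
  ))
  invisible(x)
}

#' Generate a participant-level analysis table directly
#'
#' The measurement-level arm of the generator: draws the same latent-trait
#' model as [simulate_study()] but simulates the *measurements* (the
#' dimorphism score with its landmark-noise-induced error, per-face rating
#' means over a fixed number of discretized ratings, and scored self-report
#' scales) without constructing landmark files or individual raters. Used for
#' calibration and recovery experiments where thousands of replicate studies
#' are needed.
#'
#' @param cfg A [sim_config()].
#' @return Analysis-ready tibble with columns `participant_id`, `is_father`,
#'   `objective_dimorphism`, `perceived_masculinity`, `attractiveness`,
#'   `perceived_paternal_involvement`, `nfs`, `fis_involved`, `fis_desired`;
#'   attribute `"truth"` holds the latent values.
#' @export
gen_analysis_data <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "facecue_sim_config"))
  set.seed(cfg$seed + 4L)
  n <- cfg$n_participants
  t_true <- rnorm(n, 1, cfg$participant_spread)
  t_z <- as.vector(scale(t_true))
  r_a <- cfg$predictor_cor[["dimorphism_attractiveness"]]
  r_m <- cfg$predictor_cor[["dimorphism_masculinity"]]
  attract <- r_a * t_z + sqrt(1 - r_a^2) * rnorm(n)
  masc <- r_m * t_z + sqrt(1 - r_m^2) * rnorm(n)
  b <- cfg$true_effects$perceived_paternal_involvement
  var_lin <- b[["dimorphism"]]^2 + b[["attractiveness"]]^2 +
    2 * b[["dimorphism"]] * b[["attractiveness"]] * r_a
  ppi <- b[["dimorphism"]] * t_z + b[["attractiveness"]] * attract +
    sqrt(1 - var_lin) * rnorm(n)
  latents <- tibble::tibble(face_id = sprintf("P%03d", seq_len(n)),
                            t_z = t_z, attractiveness = attract,
                            masculinity = masc, ppi = ppi)
  sr <- self_report_latents(cfg, latents)

  # dimorphism score: true position plus the projection of isotropic landmark
  # noise onto the (unit) axis direction, in axis-length units
  axis_length <- cfg$dimorphism_scale *
    centroid_size(face_template(cfg$n_landmarks))
  score <- t_true + rnorm(n, 0, cfg$landmark_noise_sd / axis_length)

  m <- max(1L, round(cfg$ratings_per_face_per_trait))
  rating_mean <- function(latent) {
    vals <- discretize_rating(
      rep(latent, times = m), cfg$rating_scale,
      rnorm(n * m, 0, sqrt(cfg$rater_bias_sd^2 + cfg$rating_noise_sd^2))
    )
    rowMeans(matrix(vals, nrow = n))
  }
  scale_score <- function(latent, n_items) {
    rowMeans(rate_items(latent, n_items, cfg, na_rate = 0))
  }
  out <- tibble::tibble(
    participant_id = latents$face_id,
    is_father = seq_len(n) %in% sample.int(n, cfg$n_fathers),
    objective_dimorphism = score,
    perceived_masculinity = rating_mean(masc),
    attractiveness = rating_mean(attract),
    perceived_paternal_involvement = rating_mean(ppi),
    nfs = scale_score(sr$nfs, 9L),
    fis_involved = scale_score(sr$fis_involved, 20L),
    fis_desired = scale_score(sr$fis_desired, 20L)
  )
  attr(out, "truth") <- dplyr::bind_cols(latents, sr)
  out
}
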