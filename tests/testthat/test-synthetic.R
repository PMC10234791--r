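test_that("the generator is bit-identical under a fixed seed", {
  cfg <- tiny_cfg(seed = 21)
  a <- simulate_study(cfg)
  b <- simulate_study(tiny_cfg(seed = 21))
  expect_identical(a$landmarks, b$landmarks)
  expect_identical(a$ratings, b$ratings)
  expect_identical(a$self_reports, b$self_reports)
  c <- simulate_study(tiny_cfg(seed = 22))
  expect_false(identical(a$landmarks, c$landmarks))
})

test_that("config validation rejects impossible designs", {
  expect_error(sim_config(n_landmarks = 2), "n_landmarks")
  expect_error(sim_config(n_fathers = 300), "n_fathers")
  expect_error(sim_config(landmark_noise_sd = -1), "noise")
  expect_error(sim_config(true_effects = list(
    perceived_paternal_involvement = c(dimorphism = 0, attractiveness = -1.2),
    nfs = c(dimorphism = 0, attractiveness = 0),
    fis_involved = c(dimorphism = 0, attractiveness = 0),
    fis_desired = c(dimorphism = 0, attractiveness = 0)
  )), "true effects")
  expect_error(
    gen_ratings(tiny_cfg(ratings_per_face_per_trait = 500),
                gen_latent_traits(tiny_cfg(),
                                  gen_faces(tiny_cfg())$meta)),
    class = "facecue_design_error"
  )
})

test_that("noiseless faces are recovered perfectly along the axis", {
  cfg <- tiny_cfg(seed = 31, landmark_noise_sd = 0)
  faces <- gen_faces(cfg)
  g <- gpa(faces$landmarks)
  refs <- dplyr::filter(faces$meta, role != "participant")
  ax <- dimorphism_axis(g, refs[c("face_id", "sex")])
  pp <- dplyr::filter(faces$meta, role == "participant")
  sc <- score_faces(dplyr::filter(g$aligned, face_id %in% pp$face_id), ax,
                    scale = FALSE)
  expect_gt(cor(sc$raw, pp$t_true[match(sc$face_id, pp$face_id)]), 0.999)
})

test_that("rater filtering removes exactly the flagged raters", {
  cfg <- tiny_cfg(seed = 33, low_seriousness_rate = 0.08)
  latents <- gen_latent_traits(cfg, gen_faces(cfg)$meta)
  rec <- gen_ratings(cfg, latents)
  flagged <- unique(rec$rater_id[rec$seriousness < 5])
  expect_gt(length(flagged), 0)
  kept <- filter_raters(rec)
  expect_setequal(exclusion_report(kept)$rater_id, flagged)
  expect_false(any(kept$rater_id %in% flagged))
  # one trait per rater by construction
  expect_true(all(tapply(rec$trait, rec$rater_id,
                         function(tr) length(unique(tr))) == 1))
})

test_that("noise-free ratings reproduce the discretized latent trait", {
  cfg <- tiny_cfg(seed = 34, rating_noise_sd = 0, rater_bias_sd = 0)
  latents <- gen_latent_traits(cfg, gen_faces(cfg)$meta)
  rec <- gen_ratings(cfg, latents)
  agg <- aggregate_trait(rec, "attractiveness")
  expected <- pmin(10, pmax(1, round(5.5 + cfg$rating_scale *
                                       latents$attractiveness)))
  expect_equal(agg$mean_rating,
               expected[match(agg$face_id, latents$face_id)])
})

test_that("aggregate means track latents better with more ratings per face", {
  cor_at <- function(rpf) {
    cfg <- tiny_cfg(seed = 35, ratings_per_face_per_trait = rpf)
    latents <- gen_latent_traits(cfg, gen_faces(cfg)$meta)
    agg <- aggregate_trait(gen_ratings(cfg, latents), "attractiveness")
    cor(agg$mean_rating,
        latents$attractiveness[match(agg$face_id, latents$face_id)])
  }
  expect_gt(cor_at(18), cor_at(3))
})

test_that("rating coverage at the default design lands near its target", {
  cfg <- sim_config(seed = 36)
  latents <- gen_latent_traits(cfg, gen_faces(cfg)$meta)
  agg <- aggregate_trait(gen_ratings(cfg, latents))
  cov <- coverage_check(agg)
  expect_gt(attr(cov, "mean_ratings_per_face"), 30)
  expect_lt(attr(cov, "mean_ratings_per_face"), 37)
})

test_that("self-report latents carry the configured correlation structure", {
  cfg <- sim_config(seed = 37, n_participants = 4000, n_fathers = 2000)
  sim <- gen_analysis_data(cfg)
  truth <- attr(sim, "truth")
  expect_lt(abs(cor(truth$nfs, truth$fis_involved) - 0.6), 0.05)
  expect_lt(abs(cor(truth$nfs, truth$fis_desired) - 0.1), 0.08)
  # scored scales inherit the structure, attenuated by item noise
  expect_gt(cor(sim$nfs, sim$fis_involved), 0.4)
  expect_lt(abs(cor(sim$nfs, sim$fis_desired)), 0.25)
})

test_that("zero item noise makes scored scales equal the discretized latent", {
  cfg <- tiny_cfg(seed = 38, item_noise_sd = 0, fis_na_rate = 0)
  faces <- gen_faces(cfg)
  latents <- gen_latent_traits(cfg, faces$meta)
  roster <- gen_self_reports(cfg, latents, faces$meta)
  truth <- attr(roster, "truth")
  kept <- apply_participant_exclusions(roster)
  sc <- score_scales(kept)
  m <- match(truth$participant_id, sc$participant_id)
  expect_equal(sc$nfs[m],
               pmin(5, pmax(1, round(3 + cfg$item_scale * truth$nfs))))
  expect_equal(sc$fis_desired[m],
               pmin(5, pmax(1, round(3 + cfg$item_scale * truth$fis_desired))))
})

test_that("the default exclusion funnel reproduces the recruitment numbers", {
  cfg <- sim_config(seed = 39)
  faces <- gen_faces(cfg)
  roster <- gen_self_reports(cfg, gen_latent_traits(cfg, faces$meta),
                             faces$meta)
  expect_equal(nrow(roster), 312L)
  kept <- apply_participant_exclusions(roster)
  expect_equal(nrow(kept), 259L)
  rep <- exclusion_report(kept)
  expect_equal(rep$n_participants, c(28L, 21L, 2L, 1L))
  expect_equal(sum(rep$n_records), 312L - 259L)
})

test_that("gen_analysis_data is deterministic with the documented columns", {
  cfg <- tiny_cfg(seed = 40)
  a <- gen_analysis_data(cfg)
  b <- gen_analysis_data(tiny_cfg(seed = 40))
  expect_identical(a, b)
  expect_named(a, c("participant_id", "is_father", "objective_dimorphism",
                    "perceived_masculinity", "attractiveness",
                    "perceived_paternal_involvement", "nfs", "fis_involved",
                    "fis_desired"))
  expect_equal(sum(a$is_father), cfg$n_fathers)
  expect_true(all(a$nfs >= 1 & a$nfs <= 5))
  expect_true(all(a$attractiveness >= 1 & a$attractiveness <= 10))
})
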