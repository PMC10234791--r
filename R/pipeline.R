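# Orchestration: dimorphism scores + rating aggregates + scale scores ->
# winsorised standardized regressions with JZS Bayes factors, in the layout
# of the study's result tables (rows = outcomes, column pairs = focal
# predictor and the attractiveness covariate).

ANALYSIS_OUTCOMES <- c("nfs", "fis_involved", "fis_desired",
                       "perceived_paternal_involvement")
ANALYSIS_PREDICTORS <- c("objective_dimorphism", "perceived_masculinity")
ANALYSIS_VARS <- c(ANALYSIS_PREDICTORS, "attractiveness", ANALYSIS_OUTCOMES)

#' Assemble the participant-level analysis table
#'
#' Joins face dimorphism scores, aggregated trait ratings, and scored
#' self-report scales into the one-row-per-participant table consumed by
#' [run_analysis()]. Participant face identifiers must match across inputs.
#'
#' @param scores Output of [score_faces()] for the participant faces (the
#'   `scaled` column becomes `objective_dimorphism`).
#' @param trait_means Output of [aggregate_trait()] covering the three rated
#'   traits for one rater subgroup.
#' @param involvement Output of [score_scales()] after
#'   [apply_participant_exclusions()]; must contain `participant_id`,
#'   `is_father`, `nfs`, `fis_involved`, `fis_desired`.
#' @return Analysis tibble with one row per participant present in
#'   `involvement`.
#' @export
build_analysis_table <- function(scores, trait_means, involvement) {
  stopifnot(is.data.frame(scores), is.data.frame(trait_means),
            is.data.frame(involvement))
  ratings_wide <- trait_means |>
    dplyr::select("face_id", "trait", "mean_rating") |>
    tidyr::pivot_wider(names_from = "trait", values_from = "mean_rating")
  involvement |>
    dplyr::select("participant_id", "is_father", "nfs", "fis_involved",
                  "fis_desired") |>
    dplyr::left_join(
      scores |>
        tibble::as_tibble() |>
        dplyr::select("face_id", objective_dimorphism = "scaled"),
      by = c(participant_id = "face_id")
    ) |>
    dplyr::left_join(ratings_wide, by = c(participant_id = "face_id"))
}

winsorize_sample <- function(d, vars, k) {
  clipped <- integer(0)
  for (v in vars) {
    orig <- d[[v]]
    d[[v]] <- winsorize(orig, k = k)
    clipped[[v]] <- sum(d[[v]] != orig, na.rm = TRUE)
  }
  list(data = d, clipped = tibble::tibble(variable = vars,
                                          n_clipped = unname(clipped)))
}

#' Run the full cue-accuracy analysis
#'
#' For each requested sample (full / fathers only) and focal facial metric
#' (objective shape dimorphism / perceived masculinity), winsorises all
#' continuous variables within the sample, computes the outcome correlation
#' matrix, and fits one standardized regression per outcome with the focal
#' metric and (optionally) attractiveness as predictors, reporting the
#' standardized beta, t, p, and the JZS inclusion Bayes factor per effect.
#' Analyses are complete-case per model; the run log records exclusions,
#' winsorised counts, and per-model n.
#'
#' @param data Analysis table from [build_analysis_table()],
#'   [gen_analysis_data()], or [replicate_from_csv()].
#' @param predictors Focal predictors to analyse; any of
#'   `"objective_dimorphism"`, `"perceived_masculinity"` (default both).
#' @param samples Sample subsets; any of `"full"`, `"fathers_only"`
#'   (default both).
#' @param outcomes Outcome variables (default all four).
#' @param include_attractiveness Include attractiveness as a covariate
#'   (default `TRUE`); the robustness variant drops it.
#' @param winsor_k Winsorisation threshold in SD units (default 3).
#' @param prior_scale JZS prior scale (default `sqrt(2)/2`).
#' @param alpha Significance level used for the stars column (default 0.05).
#' @return Object of class `facecue_analysis`: list with `effects` (tidy
#'   effect table), `correlations` (outcome correlations per sample), and
#'   `log` (settings, per-model n, winsorised counts). Use [tidy()],
#'   [glance()], [autoplot()], [effect_table()], [write_analysis_tables()].
#' @export
run_analysis <- function(data,
                         predictors = ANALYSIS_PREDICTORS,
                         samples = c("full", "fathers_only"),
                         outcomes = ANALYSIS_OUTCOMES,
                         include_attractiveness = TRUE,
                         winsor_k = 3,
                         prior_scale = sqrt(2) / 2,
                         alpha = 0.05) {
  predictors <- match.arg(predictors, ANALYSIS_PREDICTORS, several.ok = TRUE)
  samples <- match.arg(samples, c("full", "fathers_only"), several.ok = TRUE)
  outcomes <- match.arg(outcomes, ANALYSIS_OUTCOMES, several.ok = TRUE)
  if (length(outcomes) == 0L) abort("at least one outcome is required")
  needed <- unique(c("is_father", predictors, outcomes,
                     if (include_attractiveness) "attractiveness"))
  missing <- setdiff(needed, names(data))
  if (length(missing)) {
    abort(sprintf("missing input columns: %s",
                  paste(missing, collapse = ", ")),
          class = "facecue_schema_error")
  }

  winsor_log <- list()
  effects <- list()
  correlations <- list()
  model_log <- list()
  cont_vars <- intersect(ANALYSIS_VARS, names(data))

  for (smp in samples) {
    d <- if (smp == "fathers_only") {
      dplyr::filter(data, .data$is_father)
    } else data
    if (nrow(d) == 0L) {
      abort(sprintf("requested sample `%s` is empty", smp),
            class = "facecue_sample_error")
    }
    w <- winsorize_sample(d, cont_vars, winsor_k)
    d <- w$data
    winsor_log[[smp]] <- dplyr::mutate(w$clipped, sample = smp,
                                       .before = 1L)

    if (length(outcomes) >= 2L) {
      pairs <- utils::combn(outcomes, 2L, simplify = FALSE)
      correlations[[smp]] <- purrr::map_dfr(pairs, function(pr) {
        ct <- pearson(d[[pr[[1L]]]], d[[pr[[2L]]]])
        dplyr::mutate(ct, sample = smp, var1 = pr[[1L]], var2 = pr[[2L]],
                      .before = 1L)
      })
    }

    for (focal in predictors) {
      preds <- unique(c(focal,
                        if (include_attractiveness) "attractiveness"))
      for (out in outcomes) {
        fit <- standardized_ols(d, out, preds)
        res <- fit$results
        res$bf10 <- unname(vapply(res$term, function(tm) {
          jzs_bf(d, out, preds, focal = tm, prior_scale = prior_scale)
        }, 1))
        res$sig <- sig_stars(res$p)
        res <- dplyr::mutate(res, sample = smp, focal = focal, .before = 1L)
        effects[[length(effects) + 1L]] <- res
        model_log[[length(model_log) + 1L]] <- tibble::tibble(
          sample = smp, focal = focal, outcome = out,
          n = fit$n, df = fit$df, r_squared = fit$r_squared
        )
      }
    }
  }

  structure(
    list(
      effects = dplyr::bind_rows(effects),
      correlations = dplyr::bind_rows(correlations),
      log = list(
        settings = list(
          predictors = predictors, samples = samples, outcomes = outcomes,
          include_attractiveness = include_attractiveness,
          winsor_k = winsor_k, prior_scale = prior_scale, alpha = alpha,
          package_version = as.character(utils::packageVersion("facecue"))
        ),
        n_input = nrow(data),
        models = dplyr::bind_rows(model_log),
        winsorised = dplyr::bind_rows(winsor_log)
      )
    ),
    class = "facecue_analysis"
  )
}

#' @export
print.facecue_analysis <- function(x, ...) {
  s <- x$log$settings
  cat(sprintf(
    "Cue-accuracy analysis: %d models (%s x %s), attractiveness covariate: %s\n",
    nrow(x$log$models),
    paste(s$predictors, collapse = "/"), paste(s$samples, collapse = "/"),
    ifelse(s$include_attractiveness, "yes", "no")
  ))
  print(x$effects)
  invisible(x)
}

#' Effect table in the published layout
#'
#' Rows are outcomes; column pairs are (beta, t) for the focal facial metric
#' and, when present, the attractiveness covariate, with significance stars
#' on the t values.
#'
#' @param x A [run_analysis()] result.
#' @param sample,focal Which sample / focal predictor's table to lay out.
#' @return A tibble, one row per outcome.
#' @export
effect_table <- function(x, sample = "full", focal = "objective_dimorphism") {
  stopifnot(inherits(x, "facecue_analysis"))
  eff <- dplyr::filter(x$effects, .data$sample == !!sample,
                       .data$focal == !!focal)
  if (nrow(eff) == 0L) {
    abort("no effects for that sample/focal combination in this analysis")
  }
  eff |>
    dplyr::mutate(t_lab = sprintf("%.2f%s", .data$t, .data$sig)) |>
    dplyr::select("outcome", "term", "beta", "t_lab") |>
    tidyr::pivot_wider(names_from = "term",
                       values_from = c("beta", "t_lab"),
                       names_vary = "slowest")
}

#' Write analysis tables to disk
#'
#' Writes `table1.csv` (outcome correlations), `table2.csv` to `table5.csv`
#' (one per focal predictor x sample, in the order objective dimorphism
#' full / fathers-only, then perceived masculinity full / fathers-only, when
#' present), `bayes_factors.csv`, and `runlog.json`.
#'
#' @param x A [run_analysis()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_analysis_tables <- function(x, dir) {
  stopifnot(inherits(x, "facecue_analysis"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  p1 <- file.path(dir, "table1.csv")
  readr::write_csv(x$correlations, p1)
  paths <- c(paths, p1)
  grid <- expand.grid(sample = c("full", "fathers_only"),
                      focal = ANALYSIS_PREDICTORS,
                      stringsAsFactors = FALSE)
  tbl_i <- 2L
  for (i in seq_len(nrow(grid))) {
    sel <- dplyr::filter(x$effects, .data$sample == grid$sample[[i]],
                         .data$focal == grid$focal[[i]])
    if (nrow(sel) == 0L) next
    p <- file.path(dir, sprintf("table%d.csv", tbl_i))
    readr::write_csv(effect_table(x, grid$sample[[i]], grid$focal[[i]]), p)
    paths <- c(paths, p)
    tbl_i <- tbl_i + 1L
  }
  pb <- file.path(dir, "bayes_factors.csv")
  readr::write_csv(
    dplyr::select(x$effects, "sample", "focal", "outcome", "term", "bf10"),
    pb
  )
  pl <- file.path(dir, "runlog.json")
  jsonlite::write_json(x$log, pl, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(c(paths, pb, pl))
}

#' Re-run the analysis on an externally supplied table (replication mode)
#'
#' Reads a CSV whose columns match the analysis-table contract (scores and
#' rating means already computed) and runs the identical analysis. No
#' network access is performed; the run log is marked as replication mode.
#'
#' @param path CSV file with columns `participant_id`, `is_father`, the
#'   focal predictors, `attractiveness`, and the outcome columns.
#' @param ... Passed to [run_analysis()].
#' @return A `facecue_analysis` object.
#' @export
replicate_from_csv <- function(path, ...) {
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("participant_id", "is_father", ANALYSIS_VARS)
  missing <- setdiff(required, names(data))
  if (length(missing)) {
    abort(sprintf("replication CSV is missing columns: %s",
                  paste(missing, collapse = ", ")),
          class = "facecue_schema_error")
  }
  res <- run_analysis(data, ...)
  res$log$mode <- "replication"
  res$log$source <- basename(path)
  res
}

#' End-to-end analysis of a synthetic study bundle
#'
#' Runs the complete pipeline on a [simulate_study()] bundle: joint
#' Procrustes alignment of reference and participant faces, dimorphism axis
#' from the references, projection scores for the participants, rater
#' filtering and per-face aggregation, participant exclusions and scale
#' scoring, and finally [run_analysis()].
#'
#' @param study A `facecue_study` bundle.
#' @param rater_subgroup `"all"` (default), `"male_raters"`, or
#'   `"female_raters"` — which raters' aggregates feed the analysis.
#' @param seriousness_threshold Rater/participant seriousness cut-off
#'   (default 5).
#' @param ... Passed to [run_analysis()].
#' @return A list with `analysis` (the `facecue_analysis`), `table` (the
#'   assembled analysis table), `scores`, `gpa`, `axis`, and the exclusion
#'   reports.
#' @export
analyse_study <- function(study, rater_subgroup = "all",
                          seriousness_threshold = 5L, ...) {
  stopifnot(inherits(study, "facecue_study"))
  alignment <- gpa(study$landmarks)
  refs <- dplyr::filter(study$face_meta,
                        .data$role %in% c("ref_female", "ref_male"))
  axis <- dimorphism_axis(alignment, refs[c("face_id", "sex")])
  participant_ids <- study$face_meta$face_id[
    study$face_meta$role == "participant"]
  scores <- alignment$aligned |>
    dplyr::filter(.data$face_id %in% participant_ids) |>
    score_faces(axis)

  kept_ratings <- filter_raters(study$ratings,
                                threshold = seriousness_threshold)
  trait_means <- aggregate_trait(kept_ratings, subgroup = rater_subgroup)

  kept_participants <- apply_participant_exclusions(
    study$self_reports, threshold = seriousness_threshold
  )
  involvement <- score_scales(kept_participants)

  table <- build_analysis_table(scores, trait_means, involvement)
  analysis <- run_analysis(table, ...)
  analysis$log$exclusions <- list(
    raters = exclusion_report(kept_ratings),
    participants = exclusion_report(kept_participants)
  )
  list(analysis = analysis, table = table, scores = scores,
       gpa = alignment, axis = axis,
       rater_exclusions = exclusion_report(kept_ratings),
       participant_exclusions = exclusion_report(kept_participants))
}
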