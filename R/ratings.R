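# Rater-level exclusions and per-face aggregation of subjective trait
# ratings (attractiveness, perceived masculinity, perceived paternal
# involvement), each rated on a 1-10 scale by a pool of raters who each see
# one trait and a random subset of faces.

RATING_TRAITS <- c("attractiveness", "perceived_masculinity",
                   "perceived_paternal_involvement")

#' Drop raters who did not take the survey seriously
#'
#' Removes all records of raters whose self-reported seriousness score (1-7)
#' falls below the threshold. The exclusion report is attached as the
#' `"exclusions"` attribute and retrievable via [exclusion_report()].
#'
#' @param records Tibble of rating records with at least `rater_id` and
#'   `seriousness` (one seriousness value per rater).
#' @param threshold Minimum acceptable seriousness; raters scoring below it
#'   are excluded. Default 5 on the 7-point honesty scale.
#' @return The kept records, with attribute `"exclusions"`: a tibble of
#'   excluded `rater_id`, their `seriousness`, and `n_records` dropped.
#' @export
filter_raters <- function(records, threshold = 5L) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L) {
    out <- tibble::as_tibble(records)
    attr(out, "exclusions") <- tibble::tibble(
      rater_id = character(), seriousness = integer(), n_records = integer()
    )
    return(out)
  }
  if (any(is.na(records$seriousness))) {
    abort("every rating record must carry a seriousness score")
  }
  excluded <- records |>
    dplyr::filter(.data$seriousness < threshold) |>
    dplyr::count(.data$rater_id, .data$seriousness, name = "n_records") |>
    dplyr::arrange(.data$rater_id)
  kept <- records |>
    dplyr::filter(.data$seriousness >= threshold) |>
    tibble::as_tibble()
  attr(kept, "exclusions") <- tibble::as_tibble(excluded)
  kept
}

#' Exclusion report of a filtering step
#'
#' @param x Output of [filter_raters()] or [apply_participant_exclusions()].
#' @return The exclusion-report tibble recorded by the filtering step.
#' @export
exclusion_report <- function(x) {
  attr(x, "exclusions")
}

#' Aggregate ratings into per-face trait means
#'
#' Computes, for each face, the arithmetic mean and count of ratings of one
#' trait, optionally restricted to male or female raters (raters of other or
#' unknown sex contribute to `"all"` only).
#'
#' @param records Rating records (pre-filtered with [filter_raters()]), with
#'   columns `face_id`, `trait`, `value`, and `rater_sex` when a subgroup is
#'   requested.
#' @param trait Trait to aggregate; one of `"attractiveness"`,
#'   `"perceived_masculinity"`, `"perceived_paternal_involvement"`, or `NULL`
#'   to aggregate every trait present.
#' @param subgroup `"all"` (default), `"male_raters"`, or `"female_raters"`.
#' @return Tibble with columns `face_id`, `trait`, `subgroup`, `mean_rating`,
#'   `n_ratings` (faces with no contributing rating are omitted).
#' @export
aggregate_trait <- function(records, trait = NULL, subgroup = "all") {
  stopifnot(is.data.frame(records))
  subgroup <- match.arg(subgroup, c("all", "male_raters", "female_raters"))
  if (!is.null(trait)) {
    if (!all(trait %in% RATING_TRAITS)) {
      abort(sprintf("unknown trait label: %s",
                    paste(setdiff(trait, RATING_TRAITS), collapse = ", ")),
            class = "facecue_trait_error")
    }
    records <- dplyr::filter(records, .data$trait %in% !!trait)
  } else if (!all(unique(records$trait) %in% RATING_TRAITS)) {
    abort(sprintf("unknown trait label: %s",
                  paste(setdiff(unique(records$trait), RATING_TRAITS),
                        collapse = ", ")),
          class = "facecue_trait_error")
  }
  if (subgroup == "male_raters") {
    records <- dplyr::filter(records, .data$rater_sex == "male")
  } else if (subgroup == "female_raters") {
    records <- dplyr::filter(records, .data$rater_sex == "female")
  }
  records |>
    dplyr::group_by(.data$face_id, .data$trait) |>
    dplyr::summarise(
      mean_rating = mean(.data$value),
      n_ratings = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(subgroup = subgroup, .after = "trait") |>
    dplyr::arrange(.data$trait, .data$face_id)
}

#' Check rating coverage against a minimum per face and trait
#'
#' Flags every face-by-trait cell whose rating count falls below the minimum
#' (30 raters per attribute is the conventional stability threshold for
#' aggregated face judgements).
#'
#' @param scores Aggregated trait scores from [aggregate_trait()].
#' @param minimum Minimum acceptable `n_ratings`; default 30.
#' @return Tibble `face_id`, `trait`, `n_ratings`, `flagged`, with attributes
#'   `"mean_ratings_per_face"` (overall mean count) and `"minimum"`.
#' @export
coverage_check <- function(scores, minimum = 30L) {
  stopifnot(is.data.frame(scores), "n_ratings" %in% names(scores))
  out <- scores |>
    dplyr::transmute(.data$face_id, .data$trait, .data$n_ratings,
                     flagged = .data$n_ratings < minimum)
  attr(out, "mean_ratings_per_face") <- mean(out$n_ratings)
  attr(out, "minimum") <- minimum
  out
}
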