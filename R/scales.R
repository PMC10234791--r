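# Scoring of the self-report paternal-involvement instruments:
#   NFS          - nurturant fathering, 9 items, 1-5, no "not applicable"
#   FIS_involved - reported involvement across 20 domains, 1-5, NA allowed
#   FIS_desired  - desired involvement across 20 domains, 1-5, NA allowed
# All three are scored as the mean of applicable (non-NA) items, keeping the
# instruments on a common 1-5 range; higher = more (desired) involvement.

SCALE_ITEMS <- c(NFS = 9L, FIS_involved = 20L, FIS_desired = 20L)

#' Score one self-report scale response
#'
#' @param values Integer item responses in 1-5; `NA` marks a "not applicable"
#'   response (allowed on the FIS subscales only).
#' @param instrument One of `"NFS"`, `"FIS_involved"`, `"FIS_desired"`.
#' @param n_items Expected item count; defaults to the instrument's published
#'   length (9 for NFS, 20 per FIS subscale). Override only for toy
#'   instruments in examples.
#' @return The mean of applicable items (a value in \[1, 5\]), or `NA` if all
#'   items were marked not applicable (FIS only).
#' @export
#' @examples
#' score_scale(c(4, NA, 2), "FIS_involved", n_items = 3)  # 3
score_scale <- function(values,
                        instrument = c("NFS", "FIS_involved", "FIS_desired"),
                        n_items = NULL) {
  instrument <- match.arg(instrument)
  n_items <- n_items %||% SCALE_ITEMS[[instrument]]
  if (length(values) != n_items) {
    abort(sprintf("%s expects %d items, got %d", instrument, n_items,
                  length(values)),
          class = "facecue_scale_error")
  }
  if (instrument == "NFS" && anyNA(values)) {
    abort("NFS has no not-applicable option; NA items are not allowed",
          class = "facecue_scale_error")
  }
  ok <- !is.na(values)
  if (any(values[ok] < 1 | values[ok] > 5)) {
    abort("item responses must lie in 1-5", class = "facecue_scale_error")
  }
  if (!any(ok)) return(NA_real_)
  mean(values[ok])
}

#' Score all self-report scales for a participant table
#'
#' Expects one row per participant with item columns `nfs_1`..`nfs_9`,
#' `fisR_1`..`fisR_20` (reported involvement), and `fisD_1`..`fisD_20`
#' (desired involvement); `NA` is permitted in the FIS columns only.
#'
#' @param data Wide participant tibble; any non-item columns (e.g.
#'   `participant_id`, `is_father`) are carried through.
#' @return Tibble with the carried-through columns plus `nfs`,
#'   `fis_involved`, `fis_desired`.
#' @export
score_scales <- function(data) {
  stopifnot(is.data.frame(data))
  item_cols <- function(prefix, n) {
    cols <- paste0(prefix, seq_len(n))
    missing <- setdiff(cols, names(data))
    if (length(missing)) {
      abort(sprintf("missing item columns: %s",
                    paste(missing, collapse = ", ")),
            class = "facecue_scale_error")
    }
    as.matrix(data[cols])
  }
  nfs_m <- item_cols("nfs_", 9L)
  fisr_m <- item_cols("fisR_", 20L)
  fisd_m <- item_cols("fisD_", 20L)
  if (anyNA(nfs_m)) {
    abort("NFS has no not-applicable option; NA items are not allowed",
          class = "facecue_scale_error")
  }
  rng <- range(c(nfs_m, fisr_m, fisd_m), na.rm = TRUE)
  if (rng[1L] < 1 || rng[2L] > 5) {
    abort("item responses must lie in 1-5", class = "facecue_scale_error")
  }
  keep <- data[setdiff(names(data), c(colnames(nfs_m), colnames(fisr_m),
                                      colnames(fisd_m)))]
  tibble::as_tibble(keep) |>
    dplyr::mutate(
      nfs = rowMeans(nfs_m),
      fis_involved = rowMeans(fisr_m, na.rm = TRUE),
      fis_desired = rowMeans(fisd_m, na.rm = TRUE)
    ) |>
    dplyr::mutate(
      fis_involved = ifelse(is.nan(.data$fis_involved), NA_real_,
                            .data$fis_involved),
      fis_desired = ifelse(is.nan(.data$fis_desired), NA_real_,
                           .data$fis_desired)
    )
}

#' Apply the participant exclusion funnel
#'
#' Removes participants in the study's fixed order: no usable photograph,
#' low seriousness (below `threshold` on the 7-point honesty scale), language
#' issues, then duplicate enrolments. A duplicate enrolment contributes
#' several records for one participant, and the duplicate step removes all of
#' them; the report therefore counts both records and participants per
#' reason, and the record counts always sum to `nrow(input) - nrow(kept)`.
#'
#' @param data Participant tibble with columns `participant_id`, `has_photo`,
#'   `seriousness`, `language_issue`, `duplicate`.
#' @param threshold Seriousness cut-off (exclusive); default 5.
#' @return The kept rows, with attribute `"exclusions"`: tibble of `reason`,
#'   `n_records`, `n_participants` (retrievable via [exclusion_report()]).
#' @export
apply_participant_exclusions <- function(data, threshold = 5L) {
  needed <- c("participant_id", "has_photo", "seriousness", "language_issue",
              "duplicate")
  missing <- setdiff(needed, names(data))
  if (length(missing)) {
    abort(sprintf("missing columns: %s", paste(missing, collapse = ", ")))
  }
  steps <- list(
    no_photo = function(d) !d$has_photo,
    seriousness = function(d) d$seriousness < threshold,
    language = function(d) d$language_issue,
    duplicate = function(d) d$duplicate
  )
  kept <- tibble::as_tibble(data)
  report <- purrr::imap_dfr(steps, function(pred, reason) {
    drop <- pred(kept)
    drop[is.na(drop)] <- FALSE
    removed <- kept[drop, , drop = FALSE]
    kept <<- kept[!drop, , drop = FALSE]
    tibble::tibble(
      reason = reason,
      n_records = nrow(removed),
      n_participants = length(unique(removed$participant_id))
    )
  })
  attr(kept, "exclusions") <- report
  kept
}
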