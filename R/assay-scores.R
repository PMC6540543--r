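#' Nuclear staining intensity score
#'
#' German semiquantitative rubric: no staining = 0, weak = 1, moderate = 2,
#' strong = 3.
#'
#' @param category Character vector with values among `"none"`, `"weak"`,
#'   `"moderate"`, `"strong"`.
#' @return Integer scores 0-3.
#' @export
#' @examples
#' intensity_score(c("none", "moderate", "strong"))
intensity_score <- function(category) {
  map <- c(none = 0L, weak = 1L, moderate = 2L, strong = 3L)
  bad <- !(category %in% names(map))
  if (any(bad)) {
    abort(sprintf("unknown intensity category: %s (expected none/weak/moderate/strong).",
                  paste(unique(category[bad]), collapse = ", ")))
  }
  unname(map[category])
}

#' Extent-of-positive-cells score
#'
#' Bins the percentage of positively stained cells: 0-5% = 0, 5-25% = 1,
#' 26-50% = 2, 51-75% = 3, 76-100% = 4. Percentages are rounded to the
#' nearest integer before binning; exactly 5% falls in the higher bin (score
#' 1), matching the printed lower bound of that bin.
#'
#' @param positive_fraction Percentages in `[0, 100]`.
#' @return Integer scores 0-4.
#' @export
#' @examples
#' extent_score(c(0, 5, 60, 100))
extent_score <- function(positive_fraction) {
  if (any(is.na(positive_fraction)) || any(positive_fraction < 0) ||
      any(positive_fraction > 100)) {
    abort("`positive_fraction` must lie in [0, 100].")
  }
  p <- round(positive_fraction)
  ifelse(p < 5, 0L,
    ifelse(p <= 25, 1L,
      ifelse(p <= 50, 2L,
        ifelse(p <= 75, 3L, 4L))))
}

#' Immunoreactivity score (IRS) and expression bin
#'
#' The final score is intensity (0-3) times extent (0-4), ranging 0-12, and
#' is binned as low (0-7), medium (8-10), high (11-12).
#'
#' @param intensity Integer intensity scores 0-3 (see [intensity_score()]).
#' @param extent Integer extent scores 0-4 (see [extent_score()]).
#' @return Tibble with `score` (0-12) and `bin` (`low`/`medium`/`high`).
#' @export
#' @examples
#' irs(3, 4)
irs <- function(intensity, extent) {
  if (any(!intensity %in% 0:3)) abort("`intensity` must be an integer in 0..3.")
  if (any(!extent %in% 0:4)) abort("`extent` must be an integer in 0..4.")
  score <- as.integer(intensity) * as.integer(extent)
  tibble(score = score,
         bin = ifelse(score <= 7, "low", ifelse(score <= 10, "medium", "high")))
}

#' Score a table of immunohistochemistry observations
#'
#' Tidy wrapper over [intensity_score()], [extent_score()] and [irs()].
#'
#' @param observations Tibble with columns `intensity_category` and
#'   `positive_fraction`.
#' @return The input with `intensity`, `extent`, `score` and `bin` columns
#'   appended.
#' @export
score_ihc <- function(observations) {
  need <- c("intensity_category", "positive_fraction")
  if (!all(need %in% names(observations))) {
    abort("`observations` needs columns intensity_category and positive_fraction.")
  }
  out <- as_tibble(observations)
  out$intensity <- intensity_score(out$intensity_category)
  out$extent <- extent_score(out$positive_fraction)
  dplyr::bind_cols(out, irs(out$intensity, out$extent))
}

#' Relative expression by the 2^-ddCt method
#'
#' `dCt = ct_target - ct_reference` for the sample and for the calibrator;
#' `ddCt` is their difference and the relative expression (fold change) is
#' `2^-ddCt`. Shifting all four cycle counts by a constant leaves the fold
#' unchanged.
#'
#' @param ct_target,ct_reference Sample cycle thresholds for the target and
#'   reference (housekeeping) gene.
#' @param ct_target_cal,ct_reference_cal Calibrator cycle thresholds.
#' @return Tibble with `dct`, `ddct`, `fold`.
#' @export
#' @examples
#' fold_change_ddct(20, 18, 22, 18)  # fold = 4
fold_change_ddct <- function(ct_target, ct_reference, ct_target_cal,
                             ct_reference_cal) {
  cts <- list(ct_target, ct_reference, ct_target_cal, ct_reference_cal)
  for (ct in cts) {
    if (any(!is.finite(ct)) || any(ct <= 0)) {
      abort("cycle counts must be positive and finite.")
    }
  }
  dct <- ct_target - ct_reference
  ddct <- dct - (ct_target_cal - ct_reference_cal)
  tibble(dct = dct, ddct = ddct, fold = 2^(-ddct))
}
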