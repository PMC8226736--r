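# Assessment statistics for IVPT model predictions. All errors are
# residuals standardised by the observed replicate SD, squared; the
# per-IVPT total is the sum over the three reported outputs (skin wash,
# SC accumulation, cumulative dermal delivery).

#' SD-weighted squared error of one prediction
#'
#' `((obs_mean - pred) / obs_sd)^2`. Vectorised over its arguments.
#'
#' @param obs_mean Observed mean (µg/cm²).
#' @param pred Model prediction (µg/cm²).
#' @param obs_sd Observed replicate SD (µg/cm², must be > 0).
#' @param label Optional record label(s) used in error messages.
#' @return Dimensionless squared error.
#' @export
#' @examples
#' weighted_sq_error(1.41, 1.35, 0.13)
weighted_sq_error <- function(obs_mean, pred, obs_sd, label = NULL) {
  bad <- !is.na(obs_sd) & obs_sd <= 0
  if (any(bad)) {
    which_bad <- if (!is.null(label)) paste(label[bad], collapse = ", ")
                 else paste(which(bad), collapse = ", ")
    stop("observed SD must be > 0 (offending record: ", which_bad,
         "); encode rounded-to-zero SDs as missing instead", call. = FALSE)
  }
  ((obs_mean - pred) / obs_sd)^2
}

#' Per-IVPT weighted error breakdown
#'
#' Computes the skin-wash, SC-accumulation and dermal-delivery weighted
#' squared errors and their total for each row of an observation table
#' joined with predictions. Terms whose observed SD is missing (zero
#' SDs are rounded in printed tables and stored as missing) are
#' excluded from the total, with a warning naming the records.
#'
#' @param data A data frame with columns `sw_mean`, `sw_sd`, `sw_pred`,
#'   `sc_mean`, `sc_sd`, `sc_pred`, `dd_mean`, `dd_sd`, `dd_pred`
#'   (see [model_predictions()] to select a model's prediction columns
#'   from the bundled fixture format), plus any identifying columns.
#' @return The input tibble with columns `e_sw2`, `e_sc2`, `e_dd2`
#'   (NA where the SD is missing) and `e_total2` (sum over available
#'   terms) appended.
#' @export
ivpt_error <- function(data) {
  need <- c("sw_mean", "sw_sd", "sw_pred", "sc_mean", "sc_sd", "sc_pred",
            "dd_mean", "dd_sd", "dd_pred")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop("`data` is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  lab <- if ("compound" %in% names(data)) data$compound
         else as.character(seq_len(nrow(data)))
  term <- function(mean, pred, sd) {
    out <- rep(NA_real_, length(mean))
    ok <- !is.na(sd)
    out[ok] <- weighted_sq_error(mean[ok], pred[ok], sd[ok], lab[ok])
    out
  }
  res <- dplyr::mutate(
    tibble::as_tibble(data),
    e_sw2 = term(.data$sw_mean, .data$sw_pred, .data$sw_sd),
    e_sc2 = term(.data$sc_mean, .data$sc_pred, .data$sc_sd),
    e_dd2 = term(.data$dd_mean, .data$dd_pred, .data$dd_sd)
  )
  n_missing <- sum(is.na(res$e_sw2), is.na(res$e_sc2), is.na(res$e_dd2))
  if (n_missing > 0) {
    dropped <- unique(lab[is.na(res$e_sw2) | is.na(res$e_sc2) |
                            is.na(res$e_dd2)])
    warning(n_missing, " error term(s) excluded for missing SDs (",
            paste(dropped, collapse = ", "), ")", call. = FALSE)
  }
  dplyr::mutate(
    res,
    e_total2 = rowSums(cbind(.data$e_sw2, .data$e_sc2, .data$e_dd2),
                       na.rm = TRUE)
  )
}

#' Aggregate error breakdowns by solvent
#'
#' Componentwise sums of the per-IVPT weighted squared errors, grouped
#' by solvent.
#'
#' @param errors Output of [ivpt_error()] (must contain a `solvent`
#'   column).
#' @return A tibble with one row per solvent: `n_ivpt`, `e_sw2`,
#'   `e_sc2`, `e_dd2`, `e_total2`.
#' @export
aggregate_errors <- function(errors) {
  stopifnot(nrow(errors) > 0, "solvent" %in% names(errors))
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(errors), .data$solvent),
    n_ivpt = dplyr::n(),
    e_sw2 = sum(.data$e_sw2, na.rm = TRUE),
    e_sc2 = sum(.data$e_sc2, na.rm = TRUE),
    e_dd2 = sum(.data$e_dd2, na.rm = TRUE),
    e_total2 = sum(.data$e_total2, na.rm = TRUE),
    .groups = "drop"
  )
}

#' Mass-balance error of a prediction against an observation
#'
#' Difference, in percentage points of the dose, between the modelled
#' and observed recovered fractions:
#' `100 * (pred_sw + pred_sc + pred_dd) / dose -
#'  100 * (sw_mean + sc_mean + dd_mean) / dose`.
#'
#' @param data A data frame with columns `dose`, `sw_mean`, `sc_mean`,
#'   `dd_mean`, `sw_pred`, `sc_pred`, `dd_pred`.
#' @return Numeric vector of mass-balance errors (percentage points).
#' @export
mass_balance_error <- function(data) {
  if (any(data$dose <= 0)) stop("`dose` must be > 0", call. = FALSE)
  100 * (data$sw_pred + data$sc_pred + data$dd_pred) / data$dose -
    100 * (data$sw_mean + data$sc_mean + data$dd_mean) / data$dose
}

#' Is a prediction within an n-fold band of the observation?
#'
#' `TRUE` iff both values are positive and their ratio lies in
#' `[1/factor, factor]` (inclusive); a zero observation or prediction
#' is never within fold. Symmetric in its first two arguments.
#'
#' @param obs_mean Observed mean(s).
#' @param pred Prediction(s).
#' @param factor Fold factor (> 1, default 10).
#' @return Logical vector.
#' @export
#' @examples
#' within_fold(9.05, 9.33)
#' within_fold(0.14, 3.62) # ratio ~25.9
within_fold <- function(obs_mean, pred, factor = 10) {
  check_scalar(factor, "factor", positive = TRUE)
  if (factor <= 1) stop("`factor` must be > 1", call. = FALSE)
  ratio <- pred / obs_mean
  obs_mean > 0 & pred > 0 & ratio >= 1 / factor & ratio <= factor
}

#' Does a prediction overpredict the observation?
#'
#' Strict comparison: ties are not overpredictions.
#'
#' @param obs_mean Observed mean(s).
#' @param pred Prediction(s).
#' @return Logical vector, `TRUE` where `pred > obs_mean`.
#' @export
overprediction_flag <- function(obs_mean, pred) {
  pred > obs_mean
}

#' AIC difference between two fitted models
#'
#' Treats each model's minimised objective as `-2 log L` up to a common
#' additive constant (which cancels in the difference):
#' `delta = (2 k_B + obj_B) - (2 k_A + obj_A)`. Negative values favour
#' model B.
#'
#' @param objective_a,objective_b Minimised objective values.
#' @param k_a,k_b Number of calibrated parameters (>= 1).
#' @return The AIC difference (B relative to A).
#' @export
aic_difference <- function(objective_a, k_a, objective_b, k_b) {
  if (k_a < 1 || k_b < 1) stop("parameter counts must be >= 1",
                               call. = FALSE)
  (2 * k_b + objective_b) - (2 * k_a + objective_a)
}

#' Select one model's prediction columns from an assessment table
#'
#' The bundled assessment fixture carries both models' predictions in
#' columns `sw_pred_a`, `sw_pred_b`, etc. This helper copies one
#' model's columns into the `sw_pred`/`sc_pred`/`dd_pred` names that
#' [ivpt_error()] and friends expect.
#'
#' @param data Assessment table (e.g. [hewitt_ivpt()]).
#' @param model `"A"` or `"B"` (case-insensitive).
#' @return `data` with `sw_pred`, `sc_pred`, `dd_pred` columns added.
#' @export
model_predictions <- function(data, model) {
  model <- tolower(match.arg(toupper(model), c("A", "B")))
  cols <- paste0(c("sw_pred_", "sc_pred_", "dd_pred_"), model)
  miss <- setdiff(cols, names(data))
  if (length(miss)) {
    stop("`data` is missing prediction columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  data$sw_pred <- data[[cols[1]]]
  data$sc_pred <- data[[cols[2]]]
  data$dd_pred <- data[[cols[3]]]
  tibble::as_tibble(data)
}

#' Per-solvent prediction quality counts
#'
#' Counts, per solvent, how often the model overpredicts dermal
#' delivery and how often each output falls within `factor`-fold of the
#' observed mean. Invariant to row order.
#'
#' @param data A table with observed means and `sw_pred`/`sc_pred`/
#'   `dd_pred` columns (see [model_predictions()]).
#' @param factor Fold factor (default 10).
#' @return A tibble with one row per solvent: `n_ivpt`,
#'   `dd_overpredicted`, `sw_within_fold`, `sc_within_fold`,
#'   `dd_within_fold`.
#' @export
assessment_counts <- function(data, factor = 10) {
  stopifnot("solvent" %in% names(data))
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(data), .data$solvent),
    n_ivpt = dplyr::n(),
    dd_overpredicted = sum(overprediction_flag(.data$dd_mean,
                                               .data$dd_pred)),
    sw_within_fold = sum(within_fold(.data$sw_mean, .data$sw_pred,
                                     factor)),
    sc_within_fold = sum(within_fold(.data$sc_mean, .data$sc_pred,
                                     factor)),
    dd_within_fold = sum(within_fold(.data$dd_mean, .data$dd_pred,
                                     factor)),
    .groups = "drop"
  )
}
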