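#' Cohort summary table
#'
#' Per-group counts with percentages among patients (half-up rounding to
#' one decimal, the convention of clinical tables), age mean and sd,
#' operated counts, and Engel outcome proportions among operated patients
#' (Class I = seizure freedom, Classes II-IV = seizure recurrence).
#'
#' @param subjects Subject table.
#' @return A tibble with one row per group present (control, FLE, TLE);
#'   empty input yields an empty tibble.
#' @export
#' @examples
#' cohort_summary(simulate_cohort(cohort_spec(seed = 3))$subjects)
cohort_summary <- function(subjects) {
  if (nrow(subjects) == 0) {
    return(tibble(group = character(), n = integer(), pct_patients = double(),
                  age_mean = double(), age_sd = double(), n_operated = integer(),
                  n_seizure_free = integer(), pct_seizure_free = double(),
                  n_recurrence = integer(), pct_recurrence = double()))
  }
  n_patients <- sum(subjects$group != "control")
  subjects |>
    group_by(.data$group) |>
    summarise(
      n = n(),
      pct_patients = if (.data$group[1] == "control" || n_patients == 0) NA_real_
                     else round_half_up(100 * n() / n_patients, 1),
      age_mean = mean(.data$age),
      age_sd = sd(.data$age),
      n_operated = sum(.data$operated),
      n_seizure_free = sum(.data$engel_class == "I"),
      pct_seizure_free = if (sum(.data$operated) == 0) NA_real_
                         else round_half_up(100 * sum(.data$engel_class == "I") /
                                              sum(.data$operated), 1),
      n_recurrence = sum(.data$engel_class %in% c("II", "III", "IV")),
      pct_recurrence = if (sum(.data$operated) == 0) NA_real_
                       else round_half_up(100 * sum(.data$engel_class %in%
                                                      c("II", "III", "IV")) /
                                            sum(.data$operated), 1),
      .groups = "drop"
    ) |>
    arrange(factor(.data$group, levels = c("control", "FLE", "TLE")))
}
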