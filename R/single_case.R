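#' Crawford-Howell single-case t-test
#'
#' Compares a single observation against a small control sample, treating the
#' case as a sample of size one. The statistic inflates the standard error by
#' `sqrt((n + 1) / n)` to account for the case being outside the control
#' sample:
#'
#' \deqn{t = \frac{x - \bar{c}}{s_c \sqrt{(n + 1) / n}}, \quad df = n - 1}
#'
#' with `s_c` the sample (n - 1 denominator) standard deviation of the
#' controls and a two-tailed p-value from the t distribution.
#'
#' @param x The case observation (scalar), e.g. one patient's beta value at
#'   a probe.
#' @param controls Numeric vector of at least two control observations with
#'   non-zero variance.
#' @return A tibble with one row: `t`, `df`, `p`.
#' @examples
#' crawford_howell(0.20, c(0.50, 0.52, 0.48, 0.50))
#' @export
crawford_howell <- function(x, controls) {
  controls <- controls[!is.na(controls)]
  n <- length(controls)
  if (n < 2) abort("Crawford-Howell test needs at least 2 controls.")
  s <- sd(controls)
  if (!is.finite(s) || s == 0) {
    abort("Control values have zero variance; the test is degenerate.")
  }
  t <- (x - mean(controls)) / (s * sqrt((n + 1) / n))
  df <- n - 1
  tibble::tibble(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Vectorized Crawford-Howell over the rows of a probes x controls matrix.
ch_test_rows <- function(x, ctrl) {
  n <- ncol(ctrl)
  m <- rowMeans(ctrl)
  s <- sqrt(rowSums((ctrl - m)^2) / (n - 1))
  t <- (x - m) / (s * sqrt((n + 1) / n))
  list(
    control_mean = m, control_sd = s, t = t, df = n - 1,
    p = 2 * pt(-abs(t), n - 1)
  )
}

#' Per-probe single-case DMP calling for one patient
#'
#' Runs the Crawford-Howell test at every probe of one patient against the
#' control group of the matrix and applies the differentially methylated
#' position (DMP) rule: a probe passes iff the methylation difference
#' `delta_beta = beta_patient - mean(beta_controls)` exceeds the effect-size
#' gate in absolute value **and** the test is nominally significant — both
#' inequalities strict (`|delta_beta| > delta_threshold`,
#' `p < p_threshold`). No multiple-testing correction is applied at the
#' probe level: the rule deliberately combines a raw p-value with the
#' effect-size gate.
#'
#' Probes with a missing value in the patient or any control, or with zero
#' control variance, are skipped (dropped from the output with a message).
#'
#' @param beta A filtered (and normally BMIQ-normalized) [beta_matrix()]
#'   with at least two controls.
#' @param patient Patient sample id (default: all patients, stacked).
#' @param delta_threshold Effect-size gate on `|delta_beta|` (default 0.2,
#'   i.e. a > 20 percentage-point methylation difference).
#' @param p_threshold Significance gate (default 0.05).
#' @return A tibble with one row per probe and patient: `patient_id`,
#'   `probe_id`, `beta_patient`, `control_mean`, `control_sd`, `delta_beta`,
#'   `t`, `df`, `p`, `direction` (`"hyper"`/`"hypo"`), `passes`.
#' @export
call_dmps <- function(beta, patient = NULL, delta_threshold = 0.2,
                      p_threshold = 0.05) {
  stopifnot(inherits(beta, "beta_matrix"))
  ctrl_ids <- control_samples(beta)
  if (length(ctrl_ids) < 2) {
    abort("DMP calling needs at least 2 control samples.")
  }
  patients <- patient %||% patient_samples(beta)
  bad <- setdiff(patients, patient_samples(beta))
  if (length(bad)) {
    abort(paste0("Not patient sample(s): ", paste(bad, collapse = ", ")))
  }
  ctrl <- beta$values[, ctrl_ids, drop = FALSE]
  ok_ctrl <- rowSums(is.na(ctrl)) == 0
  purrr::map_dfr(patients, function(p_id) {
    x <- beta$values[, p_id]
    ok <- ok_ctrl & !is.na(x)
    res <- ch_test_rows(x[ok], ctrl[ok, , drop = FALSE])
    degenerate <- res$control_sd == 0
    if (any(degenerate) || any(!ok)) {
      inform(sprintf(
        "%s: skipped %d probe(s) (missing values or zero control variance).",
        p_id, sum(!ok) + sum(degenerate)
      ))
    }
    tibble::tibble(
      patient_id = p_id,
      probe_id = rownames(beta$values)[ok][!degenerate],
      beta_patient = unname(x[ok][!degenerate]),
      control_mean = unname(res$control_mean[!degenerate]),
      control_sd = unname(res$control_sd[!degenerate]),
      delta_beta = .data$beta_patient - .data$control_mean,
      t = unname(res$t[!degenerate]),
      df = res$df,
      p = unname(res$p[!degenerate]),
      direction = ifelse(.data$delta_beta >= 0, "hyper", "hypo"),
      passes = abs(.data$delta_beta) > delta_threshold & .data$p < p_threshold
    )
  })
}

#' Summarize DMP calls for one patient
#'
#' Counts hyper- and hypomethylated passing DMPs and expresses them as a
#' percentage of the analyzed panel (by default the number of probes tested
#' for that patient, i.e. the post-QC panel; set `panel_size` to the array
#' size to report array-scale percentages).
#'
#' @param calls A tibble from [call_dmps()] for a single patient.
#' @param panel_size Denominator for the percentages (default: number of
#'   rows in `calls`).
#' @return One-row tibble: `n_hyper`, `n_hypo`, `pct_hyper`, `pct_hypo`, and
#'   the share of hyper calls among all passing DMPs (`pct_hyper_of_dmps`).
#' @export
count_dmps <- function(calls, panel_size = NULL) {
  if (length(unique(calls$patient_id)) > 1) {
    abort("`count_dmps()` summarizes one patient; use `summarize_patient_counts()` for a cohort.")
  }
  panel_size <- panel_size %||% nrow(calls)
  n_hyper <- sum(calls$passes & calls$direction == "hyper")
  n_hypo <- sum(calls$passes & calls$direction == "hypo")
  n_pass <- n_hyper + n_hypo
  tibble::tibble(
    n_hyper = n_hyper,
    n_hypo = n_hypo,
    pct_hyper = if (panel_size > 0) 100 * n_hyper / panel_size else 0,
    pct_hypo = if (panel_size > 0) 100 * n_hypo / panel_size else 0,
    pct_hyper_of_dmps = if (n_pass > 0) 100 * n_hyper / n_pass else 0,
    pct_hypo_of_dmps = if (n_pass > 0) 100 * n_hypo / n_pass else 0
  )
}
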