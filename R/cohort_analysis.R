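#' Group-level DMP discovery (patients vs controls)
#'
#' Tests every probe for a mean methylation difference between the patient
#' and control groups and keeps probes whose absolute mean difference
#' exceeds `delta_threshold` with a p-value below `p_threshold` (both
#' strict). The per-probe test is Welch's unequal-variance t-test by
#' default (`test = "wilcoxon"` switches to the Mann-Whitney U test).
#'
#' @param beta A [beta_matrix()] with at least two samples per role.
#' @param delta_threshold Gate on `|mean(patients) - mean(controls)|`
#'   (default 0.2).
#' @param p_threshold Significance gate (default 0.05).
#' @param test `"welch"` or `"wilcoxon"`.
#' @return A tibble of the member probes: `probe_id`, `mean_control`,
#'   `mean_patient`, `mean_delta`, `p`.
#' @export
group_dmps <- function(beta, delta_threshold = 0.2, p_threshold = 0.05,
                       test = c("welch", "wilcoxon")) {
  stopifnot(inherits(beta, "beta_matrix"))
  test <- match.arg(test)
  ctrl <- beta$values[, control_samples(beta), drop = FALSE]
  pat <- beta$values[, patient_samples(beta), drop = FALSE]
  if (ncol(ctrl) < 2 || ncol(pat) < 2) {
    abort("Group comparison needs at least 2 samples per role.")
  }
  mc <- rowMeans(ctrl)
  mp <- rowMeans(pat)
  delta <- mp - mc
  p <- if (test == "welch") {
    welch_p_rows(pat, ctrl)
  } else {
    vapply(seq_len(nrow(ctrl)), function(i) {
      suppressWarnings(wilcox.test(pat[i, ], ctrl[i, ])$p.value)
    }, numeric(1))
  }
  tibble::tibble(
    probe_id = rownames(beta$values),
    mean_control = unname(mc), mean_patient = unname(mp),
    mean_delta = unname(delta), p = unname(p)
  ) |>
    dplyr::filter(
      abs(.data$mean_delta) > delta_threshold, .data$p < p_threshold
    )
}

# row-wise Welch t-test p-values (two-sided)
welch_p_rows <- function(x, y) {
  nx <- ncol(x)
  ny <- ncol(y)
  mx <- rowMeans(x)
  my <- rowMeans(y)
  vx <- rowSums((x - mx)^2) / (nx - 1)
  vy <- rowSums((y - my)^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  t <- (mx - my) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  2 * pt(-abs(t), df)
}

#' Hierarchical clustering of samples on a DMP set
#'
#' Clusters the samples of a beta matrix restricted to a set of
#' discriminating probes (typically the group-level DMP set), using
#' agglomerative clustering with Euclidean distance and average linkage —
#' the common defaults for methylation heatmaps. The result is
#' deterministic for a given input, and the flat cluster labels at `k`
#' groups are invariant (up to relabeling) under permutation of the sample
#' columns.
#'
#' @param beta A [beta_matrix()].
#' @param probes Probe ids to cluster on (e.g. `group_dmps(beta)$probe_id`);
#'   must be non-empty.
#' @param k Number of flat clusters to cut (default 2, mirroring the split
#'   of an imprinting-disorder cohort into its two epigenotype categories).
#' @param method Linkage method for [stats::hclust()].
#' @return A list of class `sample_clustering`: `hclust` (the dendrogram),
#'   `labels` (tibble `sample_id`, `role`, `cluster`), and the probe set
#'   used.
#' @export
cluster_samples <- function(beta, probes, k = 2, method = "average") {
  stopifnot(inherits(beta, "beta_matrix"))
  if (length(probes) < 2) {
    abort("Clustering needs at least 2 probes.")
  }
  m <- t(beta$values[probes, , drop = FALSE])
  hc <- hclust(dist(m, method = "euclidean"), method = method)
  cl <- cutree(hc, k = k)
  structure(
    list(
      hclust = hc,
      labels = tibble::tibble(
        sample_id = names(cl),
        role = unname(beta$roles[names(cl)]),
        cluster = unname(cl)
      ),
      probes = probes
    ),
    class = "sample_clustering"
  )
}

#' @export
print.sample_clustering <- function(x, ...) {
  cat(sprintf(
    "<sample_clustering> %d samples on %d probes, %d clusters\n",
    nrow(x$labels), length(x$probes), length(unique(x$labels$cluster))
  ))
  print(table(x$labels$role, x$labels$cluster))
  invisible(x)
}

#' @export
tidy.sample_clustering <- function(x, ...) x$labels

#' @export
autoplot.sample_clustering <- function(object, ...) {
  dend <- object$hclust
  ord <- dend$labels[dend$order]
  df <- dplyr::mutate(object$labels,
    sample_id = factor(.data$sample_id, levels = ord)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$sample_id, 1,
    fill = factor(.data$cluster)
  )) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$role), angle = 90, size = 3) +
    ggplot2::scale_y_continuous(NULL, breaks = NULL) +
    ggplot2::labs(
      x = "sample (dendrogram order)", fill = "cluster"
    ) +
    ggplot2::theme_minimal()
}

#' Per-patient DMP count table
#'
#' Builds the cohort summary table: for every patient the number of hyper-
#' and hypomethylated passing DMPs and their percentage of the analyzed
#' panel.
#'
#' @param calls DMP calls from [call_dmps()] covering all patients.
#' @param panel_size Percentage denominator (default: probes tested per
#'   patient; set to the array probe count for array-scale percentages).
#' @param digits Decimal places for the percentage columns (default 3,
#'   matching how such tables are usually reported).
#' @return A tibble: `patient_id`, `n_hyper`, `pct_hyper`, `n_hypo`,
#'   `pct_hypo`.
#' @export
summarize_patient_counts <- function(calls, panel_size = NULL, digits = 3) {
  calls |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::group_modify(function(df, key) {
      n <- panel_size %||% nrow(df)
      tibble::tibble(
        n_hyper = sum(df$passes & df$direction == "hyper"),
        pct_hyper = round(100 * .data$n_hyper / n, digits),
        n_hypo = sum(df$passes & df$direction == "hypo"),
        pct_hypo = round(100 * .data$n_hypo / n, digits)
      )
    }) |>
    dplyr::ungroup()
}
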