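#' Probe-level quality control
#'
#' Removes probes unfit for analysis, in a fixed documented order so the
#' per-rule counts are deterministic:
#'
#' 1. **detection** — detection p-value >= `detection_threshold` in any
#'    sample (`mode = "any_sample"`, the default and strictest reading) or
#'    in all samples (`mode = "all_samples"`); skipped when the matrix
#'    carries no detection p-values;
#' 2. **snp** — probes flagged as overlapping a single-nucleotide
#'    polymorphism;
#' 3. **cross_reactive** — probes flagged as cross-hybridizing;
#' 4. **sex_chromosome** — probes on chrX or chrY;
#' 5. **missing** — probes with an `NA` beta in any sample.
#'
#' Each removed probe is counted against the *first* rule it trips, so the
#' per-rule counts plus the retained count always sum to the input probe
#' count. Filtering is idempotent and independent of input row order.
#'
#' @param beta A [beta_matrix()].
#' @param manifest Probe manifest covering every probe in `beta`.
#' @param detection_threshold Detection p-value threshold (default 0.05;
#'   probes are kept when p < threshold).
#' @param mode `"any_sample"` (drop if any sample fails) or `"all_samples"`
#'   (drop only if every sample fails).
#' @return A list with `beta` (the filtered [beta_matrix()]) and `report`
#'   (tibble: `rule`, `n_removed`, plus one `retained` row).
#' @examples
#' cat <- demo_idmr_catalog()
#' sim <- simulate_cohort(cohort_config(n_patients = 2, seed = 1), cat)
#' filter_probes(sim$beta, sim$manifest)$report
#' @export
filter_probes <- function(beta, manifest,
                          detection_threshold = 0.05,
                          mode = c("any_sample", "all_samples")) {
  stopifnot(inherits(beta, "beta_matrix"))
  mode <- match.arg(mode)
  probes <- rownames(beta$values)
  missing <- setdiff(probes, manifest$probe_id)
  if (length(missing)) {
    abort(sprintf(
      "%d probe(s) in the beta matrix are absent from the manifest (e.g. %s).",
      length(missing), missing[1]
    ))
  }
  man <- manifest[match(probes, manifest$probe_id), ]

  fail_detection <- if (is.null(beta$detection_p)) {
    rep(FALSE, length(probes))
  } else {
    fails <- beta$detection_p >= detection_threshold
    if (mode == "any_sample") {
      rowSums(fails) > 0
    } else {
      rowSums(fails) == ncol(fails)
    }
  }
  rules <- list(
    detection = fail_detection,
    snp = man$snp_flag,
    cross_reactive = man$cross_reactive_flag,
    sex_chromosome = man$chrom %in% c("chrX", "chrY"),
    missing = rowSums(is.na(beta$values)) > 0
  )
  removed_by <- rep(NA_character_, length(probes))
  for (rule in names(rules)) {
    hit <- rules[[rule]] & is.na(removed_by)
    removed_by[hit] <- rule
  }
  keep <- is.na(removed_by)
  report <- tibble::tibble(
    rule = c(names(rules), "retained"),
    n_probes = c(
      unname(vapply(names(rules),
        function(r) sum(removed_by == r, na.rm = TRUE), integer(1)
      )),
      sum(keep)
    )
  )
  list(
    beta = subset_beta(beta, probes = probes[keep]),
    report = report
  )
}
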