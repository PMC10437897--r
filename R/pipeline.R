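#' Run the full MLID detection pipeline
#'
#' Chains every analysis stage on an in-memory cohort: probe-level QC
#' ([filter_probes()]), per-sample BMIQ normalization ([bmiq_normalize()]),
#' per-patient single-case DMP calling ([call_dmps()]), region-level
#' aberrant-iDMR calling ([call_regions()]), epigenotype assignment at the
#' 11p15.5 imprinting control regions ([assign_epigenotype()]) and MLID
#' classification ([classify_mlid()]), plus the cohort-level summaries
#' ([summarize_patient_counts()], [group_dmps()], [cluster_samples()]).
#' Any stage failure aborts with a stage-tagged message. The run is fully
#' deterministic for fixed inputs.
#'
#' @param beta A [beta_matrix()] with >= 1 control and >= 1 patient.
#' @param manifest Probe manifest tibble.
#' @param catalog iDMR catalog tibble (must contain both imprinting control
#'   regions named by `icr1`/`icr2`).
#' @param delta_threshold,p_threshold DMP thresholds (defaults 0.2 / 0.05).
#' @param min_significant,min_consecutive Region-rule thresholds
#'   (defaults 4 / 2).
#' @param detection_threshold,detection_mode Passed to [filter_probes()].
#' @param normalize Run BMIQ normalization (default `TRUE`).
#' @param region_rule Passed to [call_regions()].
#' @param icr1,icr2 Names of the imprinting control regions in the catalog.
#' @param group_level Also compute group DMPs and sample clustering
#'   (needs >= 2 samples per role; default `TRUE` when possible).
#' @return An object of class `mlid_run`: a list with `filter_report`,
#'   `bmiq_audit`, `dmp_calls`, `dmp_summary`, `region_calls`,
#'   `epigenotypes`, `mlid`, optional `group_dmps` and `clustering`, and
#'   the `config` used.
#' @examples
#' cat <- demo_idmr_catalog()
#' cfg <- cohort_config(
#'   n_patients = 2, n_background_probes = 300,
#'   planted_events = data.frame(
#'     patient_id = c("P1", "P1"),
#'     region = c("KCNQ1OT1:TSS-DMR", "PPIEL:Ex1-DMR"),
#'     direction = "LoM", effect_size = 0.3
#'   ),
#'   seed = 42
#' )
#' sim <- simulate_cohort(cfg, cat)
#' run <- run_mlid_pipeline(sim$beta, sim$manifest, sim$catalog,
#'   group_level = FALSE
#' )
#' tidy(run)
#' @export
run_mlid_pipeline <- function(beta, manifest, catalog,
                              delta_threshold = 0.2, p_threshold = 0.05,
                              min_significant = 4, min_consecutive = 2,
                              detection_threshold = 0.05,
                              detection_mode = "any_sample",
                              normalize = TRUE,
                              region_rule = "significant_probes",
                              icr1 = "H19/IGF2:IG-DMR",
                              icr2 = "KCNQ1OT1:TSS-DMR",
                              group_level = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("[stage %s] %s", name, conditionMessage(e)))
    })
  }
  stopifnot(inherits(beta, "beta_matrix"))
  if (!length(control_samples(beta)) || !length(patient_samples(beta))) {
    abort("[stage input] need at least one control and one patient sample.")
  }

  qc <- stage("qc", filter_probes(beta, manifest,
    detection_threshold = detection_threshold, mode = detection_mode
  ))
  norm <- if (normalize) {
    stage("normalize", bmiq_normalize(qc$beta, manifest))
  } else {
    qc$beta
  }
  calls <- stage("dmp", call_dmps(norm,
    delta_threshold = delta_threshold, p_threshold = p_threshold
  ))
  probe_map <- stage("regions", map_probes_to_regions(manifest, catalog))
  region_calls <- stage("regions", call_regions(calls, probe_map, catalog,
    min_significant = min_significant, min_consecutive = min_consecutive,
    rule = region_rule
  ))
  epigenotypes <- stage(
    "epigenotype",
    assign_epigenotype(region_calls, icr1 = icr1, icr2 = icr2)
  )
  mlid <- stage(
    "mlid",
    classify_mlid(region_calls, epigenotypes, icr1 = icr1, icr2 = icr2)
  )
  dmp_summary <- stage("cohort", summarize_patient_counts(calls))

  group_level <- group_level %||%
    (length(control_samples(beta)) >= 2 && length(patient_samples(beta)) >= 2)
  gd <- clustering <- NULL
  if (isTRUE(group_level)) {
    gd <- stage("cohort", group_dmps(norm,
      delta_threshold = delta_threshold, p_threshold = p_threshold
    ))
    if (nrow(gd) >= 2) {
      clustering <- stage("cohort", cluster_samples(norm, gd$probe_id, k = 2))
    }
  }

  structure(
    list(
      filter_report = qc$report,
      bmiq_audit = if (normalize) bmiq_audit(norm),
      normalized = norm,
      dmp_calls = calls,
      dmp_summary = dmp_summary,
      region_calls = region_calls,
      epigenotypes = epigenotypes,
      mlid = mlid,
      group_dmps = gd,
      clustering = clustering,
      config = list(
        delta_threshold = delta_threshold, p_threshold = p_threshold,
        min_significant = min_significant, min_consecutive = min_consecutive,
        detection_threshold = detection_threshold,
        detection_mode = detection_mode, normalize = normalize,
        region_rule = region_rule, icr1 = icr1, icr2 = icr2,
        genome_build = "hg19"
      )
    ),
    class = "mlid_run"
  )
}

#' @export
print.mlid_run <- function(x, ...) {
  cat(sprintf(
    "<mlid_run> %d probes retained, %d patients, %d MLID-positive\n",
    x$filter_report$n_probes[x$filter_report$rule == "retained"],
    nrow(x$mlid), sum(x$mlid$mlid)
  ))
  print(tidy(x))
  invisible(x)
}

#' @export
tidy.mlid_run <- function(x, ...) {
  x$mlid |>
    dplyr::mutate(
      disease_regions = purrr::map_chr(
        .data$disease_regions, paste,
        collapse = ";"
      ),
      additional_regions = purrr::map_chr(
        .data$additional_regions, paste,
        collapse = ";"
      )
    )
}

#' @export
glance.mlid_run <- function(x, ...) {
  tibble::tibble(
    n_probes_retained =
      x$filter_report$n_probes[x$filter_report$rule == "retained"],
    n_patients = nrow(x$mlid),
    n_mlid = sum(x$mlid$mlid),
    n_group_dmps = if (is.null(x$group_dmps)) NA_integer_ else nrow(x$group_dmps)
  )
}

#' Write pipeline artifacts to a directory
#'
#' Serializes every table of an [run_mlid_pipeline()] result: the QC filter
#' report (JSON), per-sample normalization audit, per-patient DMP tables,
#' region calls, MLID reports (JSON + TSV), cohort summaries, and a
#' run-metadata JSON with the configuration and package version.
#'
#' @param run An `mlid_run` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run_outputs <- function(run, dir) {
  stopifnot(inherits(run, "mlid_run"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(dir, ...)
  jsonlite::write_json(run$filter_report, out("filter_report.json"),
    dataframe = "rows", auto_unbox = TRUE
  )
  if (!is.null(run$bmiq_audit)) {
    jsonlite::write_json(run$bmiq_audit, out("bmiq_audit.json"),
      dataframe = "rows", auto_unbox = TRUE, digits = NA
    )
  }
  readr::write_tsv(run$dmp_calls, out("dmp_calls.tsv"))
  readr::write_tsv(run$dmp_summary, out("dmp_summary.tsv"))
  readr::write_tsv(run$region_calls, out("region_calls.tsv"))
  readr::write_tsv(tidy(run), out("mlid_reports.tsv"))
  jsonlite::write_json(tidy(run), out("mlid_reports.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA
  )
  if (!is.null(run$group_dmps)) {
    readr::write_tsv(run$group_dmps, out("group_dmps.tsv"))
  }
  if (!is.null(run$clustering)) {
    readr::write_tsv(run$clustering$labels, out("cluster_labels.tsv"))
  }
  jsonlite::write_json(
    list(
      package = "mlidscan",
      version = as.character(utils::packageVersion("mlidscan")),
      config = run$config
    ),
    out("run_metadata.json"),
    auto_unbox = TRUE
  )
  invisible(dir)
}

#' Run the pipeline from files
#'
#' File-level entry point used by the command-line wrapper: reads the beta
#' matrix, manifest and iDMR catalog (TSV), runs [run_mlid_pipeline()] and
#' writes all artifacts to `output_dir`. Configuration can come from a YAML
#' file with keys matching the argument names of [run_mlid_pipeline()] plus
#' `beta`, `manifest`, `catalog`, `detection_p`, `roles`
#' (`sample_id: role` mapping) and `output_dir`.
#'
#' @param config Path to a YAML config file, or an equivalent named list.
#' @return The `mlid_run` object, invisibly.
#' @export
run_pipeline_files <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  required <- c("beta", "manifest", "catalog", "roles", "output_dir")
  missing <- setdiff(required, names(config))
  if (length(missing)) {
    abort(paste0("Config lacks key(s): ", paste(missing, collapse = ", ")))
  }
  for (key in c("beta", "manifest", "catalog")) {
    if (!file.exists(config[[key]])) {
      abort(sprintf("Input file for '%s' not found: %s", key, config[[key]]))
    }
  }
  roles <- unlist(config$roles)
  beta <- read_beta_matrix(config$beta, roles,
    detection_path = config$detection_p
  )
  manifest <- read_probe_manifest(config$manifest)
  catalog <- read_idmr_catalog(config$catalog)
  opts <- config[intersect(names(config), c(
    "delta_threshold", "p_threshold", "min_significant", "min_consecutive",
    "detection_threshold", "detection_mode", "normalize", "region_rule",
    "icr1", "icr2", "group_level"
  ))]
  run <- do.call(run_mlid_pipeline, c(
    list(beta = beta, manifest = manifest, catalog = catalog), opts
  ))
  write_run_outputs(run, config$output_dir)
  invisible(run)
}
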