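#' Region-level aberrant-iDMR calling
#'
#' Aggregates per-probe DMP calls into per-region verdicts. A region is
#' called aberrantly methylated for a patient when, among its probes taken
#' in genomic order,
#'
#' * at least `min_significant` probes pass the DMP rule,
#' * at least `min_consecutive` adjacent probes (adjacent among the region's
#'   mapped probes, not genome-wide) pass with the same direction, and
#' * all passing probes agree in direction (mixed-direction regions are
#'   never called aberrant; they are flagged `direction = "mixed"` for
#'   review).
#'
#' `rule = "significant_probes"` (default) requires `min_significant`
#' *significant* probes; the alternative `rule = "mapped_probes"` requires
#' only that the region be covered by at least `min_significant` probes
#' (the consecutive-run condition still applies).
#'
#' Regions with no mapped probes yield a row with `n_probes = 0` and
#' `aberrant = FALSE`. Results do not depend on the input order of
#' `probe_map` or `calls` (probes are sorted internally).
#'
#' @param calls DMP calls from [call_dmps()] (any number of patients).
#' @param probe_map Probe-to-region map from [map_probes_to_regions()].
#' @param catalog iDMR catalog tibble.
#' @param min_significant Minimum number of significant probes (default 4).
#' @param min_consecutive Minimum run of same-direction significant probes
#'   (default 2).
#' @param rule See above.
#' @return A tibble with one row per patient and catalog region:
#'   `patient_id`, `region`, `n_probes`, `n_significant`,
#'   `max_consecutive`, `mean_abs_delta` (mean `|delta_beta|` over the
#'   significant probes, `NA` when none), `direction`
#'   (`hypo`/`hyper`/`mixed`/`none`), `excluded`, `aberrant`.
#' @export
call_regions <- function(calls, probe_map, catalog,
                         min_significant = 4, min_consecutive = 2,
                         rule = c("significant_probes", "mapped_probes")) {
  rule <- match.arg(rule)
  probe_map <- dplyr::arrange(probe_map, .data$chrom, .data$pos)
  patients <- unique(calls$patient_id)
  grid <- tidyr::expand_grid(
    patient_id = patients, region = catalog$name
  )
  joined <- probe_map |>
    dplyr::inner_join(
      calls[c("patient_id", "probe_id", "delta_beta", "direction", "passes")],
      by = "probe_id", relationship = "many-to-many"
    )
  purrr::pmap_dfr(grid, function(patient_id, region) {
    rows <- joined[joined$patient_id == patient_id & joined$region == region, ]
    rows <- rows[order(rows$pos), ]
    summarize_region(
      patient_id, region, rows,
      min_significant, min_consecutive, rule
    )
  }) |>
    dplyr::left_join(
      dplyr::select(catalog, region = "name", "excluded"),
      by = "region"
    ) |>
    dplyr::mutate(aberrant = .data$aberrant_rule) |>
    dplyr::select(-"aberrant_rule") |>
    dplyr::relocate("excluded", .before = "aberrant")
}

summarize_region <- function(patient_id, region, rows,
                             min_significant, min_consecutive, rule) {
  sig <- rows$passes
  n_sig <- sum(sig)
  dirs <- unique(rows$direction[sig])
  direction <- if (n_sig == 0) {
    "none"
  } else if (length(dirs) == 1) {
    dirs
  } else {
    "mixed"
  }
  max_run <- max_same_direction_run(rows$passes, rows$direction)
  n_req <- if (rule == "significant_probes") n_sig else nrow(rows)
  tibble::tibble(
    patient_id = patient_id,
    region = region,
    n_probes = nrow(rows),
    n_significant = n_sig,
    max_consecutive = max_run,
    mean_abs_delta = if (n_sig) mean(abs(rows$delta_beta[sig])) else NA_real_,
    direction = direction,
    aberrant_rule = n_req >= min_significant &&
      max_run >= min_consecutive &&
      direction %in% c("hypo", "hyper")
  )
}

# longest run of consecutive passing probes sharing one direction
max_same_direction_run <- function(passes, direction) {
  if (!length(passes) || !any(passes)) {
    return(0L)
  }
  key <- ifelse(passes, direction, "-")
  r <- rle(key)
  runs <- r$lengths[r$values %in% c("hypo", "hyper")]
  if (length(runs)) max(runs) else 0L
}

#' Assign the 11p15.5 disease epigenotype
#'
#' Derives each patient's imprinting-disorder epigenotype from the region
#' calls at the two 11p15.5 imprinting control regions: ICR1
#' (H19/IGF2:IG-DMR) and ICR2 (KCNQ1OT1:TSS-DMR). Hypomethylation of ICR2
#' gives IC2-LoM (the common Beckwith-Wiedemann epigenotype),
#' hypermethylation of ICR1 gives IC1-GoM (rarer BWS), hypomethylation of
#' ICR1 gives IC1-LoM (Silver-Russell), and ICR2 hypermethylation is
#' labelled IC2-GoM for completeness. With neither region aberrant the
#' label is `"none"`. Should both ICRs be aberrant, the label follows the
#' region with the larger mean `|delta_beta|` and both regions are recorded
#' as disease regions.
#'
#' @param region_calls Output of [call_regions()].
#' @param icr1,icr2 Catalog names of the two imprinting control regions.
#' @return A tibble with one row per patient: `patient_id`, `epigenotype`,
#'   and a list-column `disease_regions` of the ICR region name(s) driving
#'   the call.
#' @export
assign_epigenotype <- function(region_calls,
                               icr1 = "H19/IGF2:IG-DMR",
                               icr2 = "KCNQ1OT1:TSS-DMR") {
  for (r in c(icr1, icr2)) {
    if (!r %in% region_calls$region) {
      abort(sprintf("Region calls lack the imprinting control region '%s'.", r))
    }
  }
  region_calls |>
    dplyr::filter(.data$region %in% c(icr1, icr2)) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::group_modify(function(df, key) {
      lab <- function(row) {
        if (!row$aberrant) {
          return(NA_character_)
        }
        ic <- if (row$region == icr1) "IC1" else "IC2"
        dir <- if (row$direction == "hypo") "LoM" else "GoM"
        paste0(ic, "-", dir)
      }
      df$label <- vapply(seq_len(nrow(df)), function(i) lab(df[i, ]), character(1))
      hit <- df[!is.na(df$label), ]
      if (nrow(hit) == 0) {
        tibble::tibble(epigenotype = "none", disease_regions = list(character()))
      } else {
        # both ICRs aberrant: label by the larger mean |delta beta|,
        # but keep both as disease regions
        lead <- hit[which.max(hit$mean_abs_delta), ]
        tibble::tibble(
          epigenotype = lead$label,
          disease_regions = list(hit$region)
        )
      }
    }) |>
    dplyr::ungroup()
}

#' Classify multi-locus imprinting disturbance (MLID)
#'
#' A patient has MLID when at least one iDMR *other than* the disease
#' region(s) driving the epigenotype is aberrantly methylated. Regions
#' flagged `excluded` in the catalog (e.g. the polymorphically imprinted
#' VTRNA2-1) never count toward the verdict.
#'
#' @param region_calls Output of [call_regions()].
#' @param epigenotypes Output of [assign_epigenotype()]; computed from
#'   `region_calls` when `NULL`.
#' @param icr1,icr2 Passed to [assign_epigenotype()] when it is computed
#'   here.
#' @return A tibble with one row per patient: `patient_id`, `epigenotype`,
#'   list-columns `disease_regions` and `additional_regions`,
#'   `n_additional`, and the logical `mlid` verdict.
#' @export
classify_mlid <- function(region_calls, epigenotypes = NULL,
                          icr1 = "H19/IGF2:IG-DMR",
                          icr2 = "KCNQ1OT1:TSS-DMR") {
  epigenotypes <- epigenotypes %||%
    assign_epigenotype(region_calls, icr1 = icr1, icr2 = icr2)
  epigenotypes |>
    dplyr::rowwise() |>
    dplyr::group_map(function(row, ...) {
      extra <- region_calls |>
        dplyr::filter(
          .data$patient_id == row$patient_id,
          .data$aberrant,
          !.data$excluded,
          !.data$region %in% unlist(row$disease_regions)
        )
      tibble::tibble(
        patient_id = row$patient_id,
        epigenotype = row$epigenotype,
        disease_regions = row$disease_regions,
        additional_regions = list(extra$region),
        n_additional = nrow(extra),
        mlid = nrow(extra) >= 1
      )
    }) |>
    dplyr::bind_rows()
}

#' Tile plot of per-patient region calls
#'
#' A compact overview of the region-level results: patients on the x axis,
#' iDMRs on the y axis, tiles coloured by direction of aberrant methylation
#' and labelled with the mean `|delta_beta|` and the number of significant
#' probes.
#'
#' @param region_calls Output of [call_regions()].
#' @param aberrant_only Show only aberrant region/patient pairs as coloured
#'   tiles (default `TRUE`; non-aberrant pairs stay blank).
#' @return A ggplot object.
#' @export
plot_region_calls <- function(region_calls, aberrant_only = TRUE) {
  df <- if (aberrant_only) {
    dplyr::filter(region_calls, .data$aberrant)
  } else {
    region_calls
  }
  ggplot2::ggplot(df, ggplot2::aes(.data$patient_id, .data$region)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$direction), colour = "grey30") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf(
      "%.2f (%d)", .data$mean_abs_delta, .data$n_significant
    )), size = 2.8) +
    ggplot2::scale_fill_manual(
      values = c(hypo = "#6baed6", hyper = "#fd8d3c", mixed = "grey70"),
      drop = FALSE
    ) +
    ggplot2::scale_y_discrete(limits = rev(sort(unique(region_calls$region)))) +
    ggplot2::labs(x = NULL, y = NULL, fill = "direction") +
    ggplot2::theme_minimal()
}
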