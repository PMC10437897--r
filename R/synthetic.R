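#' Configuration for a synthetic methylation cohort
#'
#' Describes an EPIC-like cohort with known ground truth, emulating a small
#' imprinting-disorder study: a handful of healthy controls, patients carrying
#' planted epimutations (loss or gain of methylation, possibly mosaic) at
#' named iDMRs, imprinted regions sitting near 50% methylation in controls,
#' a bimodal background of non-imprinted CpGs, Infinium type II distributional
#' compression for the normalizer to correct, and occasional detection
#' failures.
#'
#' Defaults mirror a typical single-centre imprinting-disorder cohort: four
#' controls, fifteen patients, imprinted regions at mean beta 0.5 with
#' between-sample standard deviation 0.02 (imprinted DMRs in blood are tightly
#' regulated around hemimethylation), and roughly five type II probes for
#' every type I probe as on the EPIC array.
#'
#' @param n_controls,n_patients Number of control / patient samples.
#' @param probes_per_region Probes placed evenly inside each catalog region.
#' @param n_background_probes Probes outside all regions (bimodal beta mix).
#' @param control_idmr_mean Mean control beta at iDMR probes.
#' @param control_sd Between-sample beta standard deviation.
#' @param planted_events Data frame with columns `patient_id`, `region`,
#'   `direction` (`"LoM"` or `"GoM"`), `effect_size` (delta-beta magnitude in
#'   (0, 0.5]) and optionally `mosaic_fraction` in (0, 1] (default 1, i.e.
#'   the epimutation is present in every cell). `NULL` for a null cohort.
#' @param type2_fraction Fraction of probes of Infinium design type II.
#' @param detection_fail_rate Probability that a cell's detection p-value
#'   exceeds 0.05.
#' @param background_flag_fraction Fraction of background probes flagged as
#'   SNP-associated, as cross-reactive, and placed on chrX/chrY (each),
#'   feeding the QC filter.
#' @param seed Integer seed; every draw is reproducible from it.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_controls = 4,
                          n_patients = 15,
                          probes_per_region = 8,
                          n_background_probes = 2000,
                          control_idmr_mean = 0.5,
                          control_sd = 0.02,
                          planted_events = NULL,
                          type2_fraction = 0.8,
                          detection_fail_rate = 0.001,
                          background_flag_fraction = 0.02,
                          seed = 1L) {
  stopifnot(
    n_controls >= 1, n_patients >= 1, probes_per_region >= 1,
    n_background_probes >= 0,
    control_idmr_mean > 0, control_idmr_mean < 1,
    control_sd > 0,
    type2_fraction >= 0, type2_fraction <= 1,
    detection_fail_rate >= 0, detection_fail_rate < 1,
    background_flag_fraction >= 0, background_flag_fraction <= 1
  )
  if (!is.null(planted_events)) {
    planted_events <- tibble::as_tibble(planted_events)
    if (!"mosaic_fraction" %in% names(planted_events)) {
      planted_events$mosaic_fraction <- 1
    }
    required <- c("patient_id", "region", "direction", "effect_size")
    missing <- setdiff(required, names(planted_events))
    if (length(missing)) {
      abort(paste0(
        "`planted_events` lacks column(s): ", paste(missing, collapse = ", ")
      ))
    }
    if (!all(planted_events$direction %in% c("LoM", "GoM"))) {
      abort("Event `direction` must be 'LoM' or 'GoM'.")
    }
    if (any(planted_events$effect_size <= 0 | planted_events$effect_size > 0.5)) {
      abort("`effect_size` must lie in (0, 0.5].")
    }
    if (any(planted_events$mosaic_fraction <= 0 |
      planted_events$mosaic_fraction > 1)) {
      abort("`mosaic_fraction` must lie in (0, 1].")
    }
    shifted <- control_idmr_mean +
      ifelse(planted_events$direction == "GoM", 1, -1) *
        planted_events$effect_size
    if (any(shifted < 0 | shifted > 1)) {
      abort("control_idmr_mean +/- effect_size must stay inside [0, 1].")
    }
  }
  structure(
    list(
      n_controls = as.integer(n_controls),
      n_patients = as.integer(n_patients),
      probes_per_region = as.integer(probes_per_region),
      n_background_probes = as.integer(n_background_probes),
      control_idmr_mean = control_idmr_mean,
      control_sd = control_sd,
      planted_events = planted_events,
      type2_fraction = type2_fraction,
      detection_fail_rate = detection_fail_rate,
      background_flag_fraction = background_flag_fraction,
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

# Run code under a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Moment-matched beta-distribution shapes for given mean and sd. The sd is
# capped just below the feasibility bound sqrt(m (1 - m)) so extreme means
# stay inside the beta family instead of erroring.
beta_shapes <- function(mean, sd) {
  cap <- 0.8 * sqrt(mean * (1 - mean))
  sd <- pmin(sd, cap)
  nu <- mean * (1 - mean) / sd^2 - 1
  list(shape1 = mean * nu, shape2 = (1 - mean) * nu)
}

# Fixed monotone compression applied to Infinium type II probes: an affine
# shrink of the logit toward 0 (beta 0.5), imitating the reduced dynamic
# range of type II chemistry. BMIQ is expected to (partially) undo it.
compress_type2 <- function(beta, lambda = 0.8) {
  plogis(lambda * qlogis(pmin(pmax(beta, 1e-6), 1 - 1e-6)))
}

#' Generate a synthetic probe manifest over an iDMR catalog
#'
#' Places `probes_per_region` probes at closed-form even spacing inside every
#' catalog region (positions `start + round(i * (end - start) / (k - 1))`,
#' midpoint when `k = 1`), plus background probes well away from any region.
#' Design types are drawn per probe with probability `type2_fraction` of
#' type II. A `background_flag_fraction` of background probes is flagged
#' SNP-associated, another slice cross-reactive, and another is placed on
#' chrX/chrY, so the QC filter has something to remove.
#'
#' @param config A [cohort_config()].
#' @param catalog iDMR catalog tibble (see [read_idmr_catalog()]).
#' @return A probe manifest tibble (see [read_probe_manifest()]), with an
#'   extra logical column `in_region` for convenience.
#' @export
generate_manifest <- function(config, catalog) {
  stopifnot(inherits(config, "cohort_config"))
  if (nrow(catalog) == 0) abort("Catalog must be non-empty.")
  k <- config$probes_per_region
  too_narrow <- (catalog$end - catalog$start + 1) < k
  if (any(too_narrow)) {
    abort(sprintf(
      "Region(s) too narrow for %d probes: %s", k,
      paste(catalog$name[too_narrow], collapse = ", ")
    ))
  }
  with_seed(config$seed + 1L, {
    region_probes <- purrr::pmap_dfr(
      catalog[c("name", "chrom", "start", "end")],
      function(name, chrom, start, end) {
        pos <- if (k == 1) {
          as.integer(floor((start + end) / 2))
        } else {
          as.integer(start + round((seq_len(k) - 1) * (end - start) / (k - 1)))
        }
        tibble::tibble(chrom = chrom, pos = pos, in_region = TRUE)
      }
    )
    nb <- config$n_background_probes
    background <- if (nb > 0) {
      n_flag <- floor(config$background_flag_fraction * nb)
      # background lives far out on chr2 where no catalog region sits; the
      # XY slice goes to chrX/chrY so the sex-chromosome rule fires
      chroms <- rep("chr2", nb)
      if (n_flag > 0) {
        xy_idx <- seq(2 * n_flag + 1, min(3 * n_flag, nb))
        chroms[xy_idx] <- rep(c("chrX", "chrY"), length.out = length(xy_idx))
      }
      tibble::tibble(
        chrom = chroms,
        pos = as.integer(230e6 + seq_len(nb) * 500L),
        in_region = FALSE,
        snp_flag = seq_len(nb) <= n_flag,
        cross_reactive_flag = seq_len(nb) > n_flag & seq_len(nb) <= 2 * n_flag
      )
    } else {
      tibble::tibble(
        chrom = character(), pos = integer(), in_region = logical(),
        snp_flag = logical(), cross_reactive_flag = logical()
      )
    }
    region_probes$snp_flag <- FALSE
    region_probes$cross_reactive_flag <- FALSE
    probes <- dplyr::bind_rows(region_probes, background)
    probes |>
      dplyr::mutate(
        probe_id = sprintf("cg%07d", dplyr::row_number()),
        design_type = ifelse(
          runif(dplyr::n()) < config$type2_fraction, "II", "I"
        ),
        cgi_context = ifelse(.data$in_region, "island", "open_sea"),
        genic_context = ifelse(.data$in_region, "promoter", "intergenic")
      ) |>
      dplyr::select(
        "probe_id", "chrom", "pos", "design_type", "snp_flag",
        "cross_reactive_flag", "cgi_context", "genic_context", "in_region"
      )
  })
}

#' Generate a synthetic beta-value cohort with planted epimutations
#'
#' Draws control and patient beta values probe by probe from moment-matched
#' beta distributions (so values respect \[0, 1\] without clipping):
#' iDMR probes centre on `control_idmr_mean`; background probes follow a
#' bimodal mixture mostly near 0 or 1. For each planted event the affected
#' patient's mean at the region's probes is shifted by
#' `direction * effect_size * mosaic_fraction` — mosaicism acts as a linear
#' attenuation of the shift, the bulk signal of a mixture of epimutated and
#' normal cells. Type II probes are then passed through a fixed monotone
#' logit-shrink compression, and detection p-values are drawn so that
#' `detection_fail_rate` of cells fail the 0.05 threshold.
#'
#' @param config A [cohort_config()].
#' @param manifest Manifest from [generate_manifest()] (or any manifest with
#'   an `in_region` column consistent with `catalog`).
#' @param catalog iDMR catalog tibble.
#' @return A list with elements `beta` (a [beta_matrix()] with detection
#'   p-values) and `truth` (tibble: one row per planted event with the
#'   realized mean delta-beta over the region's probes, measured on the
#'   generated matrix).
#' @export
generate_cohort <- function(config, manifest, catalog) {
  stopifnot(inherits(config, "cohort_config"))
  sample_ids <- c(
    paste0("C", seq_len(config$n_controls)),
    paste0("P", seq_len(config$n_patients))
  )
  roles <- setNames(
    rep(c("control", "patient"), c(config$n_controls, config$n_patients)),
    sample_ids
  )
  events <- config$planted_events
  if (!is.null(events)) {
    bad <- setdiff(events$region, catalog$name)
    if (length(bad)) {
      abort(paste0("Planted event region(s) not in catalog: ",
        paste(bad, collapse = ", ")))
    }
    bad <- setdiff(events$patient_id, sample_ids[roles == "patient"])
    if (length(bad)) {
      abort(paste0("Planted event patient(s) not in cohort: ",
        paste(bad, collapse = ", ")))
    }
  }
  probe_map <- map_probes_to_regions(manifest, catalog)
  n_probe <- nrow(manifest)
  n_samp <- length(sample_ids)

  with_seed(config$seed + 2L, {
    # per-probe baseline mean: iDMR probes at the imprinted set point,
    # background drawn from a bimodal (mostly hypo/hyper) mixture
    base_mean <- rep(config$control_idmr_mean, n_probe)
    bg <- which(!manifest$probe_id %in% probe_map$probe_id)
    if (length(bg)) {
      comp <- sample(c("lo", "hi", "mid"), length(bg),
        replace = TRUE, prob = c(0.45, 0.45, 0.10)
      )
      mu <- numeric(length(bg))
      mu[comp == "lo"] <- rbeta(sum(comp == "lo"), 2, 18)
      mu[comp == "hi"] <- rbeta(sum(comp == "hi"), 18, 2)
      mu[comp == "mid"] <- runif(sum(comp == "mid"), 0.3, 0.7)
      base_mean[bg] <- pmin(pmax(mu, 0.02), 0.98)
    }

    # mean shift per probe x sample from planted events
    mean_mat <- matrix(base_mean, n_probe, n_samp,
      dimnames = list(manifest$probe_id, sample_ids)
    )
    if (!is.null(events) && nrow(events)) {
      for (i in seq_len(nrow(events))) {
        ev <- events[i, ]
        probes <- probe_map$probe_id[probe_map$region == ev$region]
        shift <- ifelse(ev$direction == "GoM", 1, -1) *
          ev$effect_size * ev$mosaic_fraction
        mean_mat[probes, ev$patient_id] <-
          pmin(pmax(mean_mat[probes, ev$patient_id] + shift, 0.01), 0.99)
      }
    }

    shp <- beta_shapes(as.vector(mean_mat), config$control_sd)
    values <- matrix(
      rbeta(n_probe * n_samp, shp$shape1, shp$shape2),
      n_probe, n_samp,
      dimnames = dimnames(mean_mat)
    )
    type2 <- manifest$design_type == "II"
    values[type2, ] <- compress_type2(values[type2, , drop = FALSE])

    fails <- matrix(
      runif(n_probe * n_samp) < config$detection_fail_rate,
      n_probe, n_samp
    )
    detection_p <- matrix(runif(n_probe * n_samp, 0, 0.05), n_probe, n_samp,
      dimnames = dimnames(values)
    )
    detection_p[fails] <- runif(sum(fails), 0.05, 1)

    beta <- beta_matrix(values, roles, detection_p = detection_p)

    truth <- if (is.null(events) || !nrow(events)) {
      tibble::tibble(
        patient_id = character(), region = character(),
        direction = character(), effect_size = numeric(),
        mosaic_fraction = numeric(), realized_delta_beta = numeric()
      )
    } else {
      ctrl <- values[, roles == "control", drop = FALSE]
      purrr::pmap_dfr(events, function(patient_id, region, direction,
                                       effect_size, mosaic_fraction, ...) {
        probes <- probe_map$probe_id[probe_map$region == region]
        realized <- mean(
          values[probes, patient_id] - rowMeans(ctrl[probes, , drop = FALSE])
        )
        tibble::tibble(
          patient_id = patient_id, region = region, direction = direction,
          effect_size = effect_size, mosaic_fraction = mosaic_fraction,
          realized_delta_beta = realized
        )
      })
    }
    list(beta = beta, truth = truth)
  })
}

#' Simulate a complete synthetic cohort
#'
#' Convenience wrapper chaining [generate_manifest()] and [generate_cohort()].
#'
#' @param config A [cohort_config()].
#' @param catalog iDMR catalog tibble.
#' @return A list with `beta`, `manifest`, `catalog`, `truth`.
#' @examples
#' cat <- demo_idmr_catalog()
#' cfg <- cohort_config(
#'   n_patients = 2, n_background_probes = 200,
#'   planted_events = data.frame(
#'     patient_id = "P1", region = "KCNQ1OT1:TSS-DMR",
#'     direction = "LoM", effect_size = 0.3
#'   ),
#'   seed = 7
#' )
#' sim <- simulate_cohort(cfg, cat)
#' sim$truth
#' @export
simulate_cohort <- function(config, catalog) {
  manifest <- generate_manifest(config, catalog)
  cohort <- generate_cohort(config, manifest, catalog)
  list(
    beta = cohort$beta, manifest = manifest,
    catalog = catalog, truth = cohort$truth
  )
}

#' Bundled demonstration iDMR catalog
#'
#' Loads the small iDMR catalog shipped with the package. It contains the
#' imprinted regions most relevant to Beckwith-Wiedemann and Silver-Russell
#' syndrome analyses (the 11p15.5 imprinting control regions ICR1 =
#' H19/IGF2:IG-DMR and ICR2 = KCNQ1OT1:TSS-DMR) plus commonly co-disturbed
#' loci (PPIEL, FAM50B, DIRAS3, NAP1L5, PLAGL1, IGF1R, WRB, MEG3, PEG10) and
#' the polymorphically imprinted VTRNA2-1 region (pre-flagged excluded).
#' PPIEL and FAM50B carry literature hg19 coordinates; the remaining
#' intervals are synthetic placeholders of realistic width, intended for
#' demonstrations and simulation, not for annotating real arrays. Supply
#' your own full catalog for real data.
#'
#' @return An iDMR catalog tibble.
#' @export
demo_idmr_catalog <- function() {
  read_idmr_catalog(
    system.file("extdata", "idmr_catalog_synthetic.tsv",
      package = "mlidscan", mustWork = TRUE
    )
  )
}
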