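#' Beta-value matrix container
#'
#' Bundles a probes-by-samples matrix of methylation fractions (beta values,
#' methylated signal over total signal, in \[0, 1\]) with the role of each
#' sample (control or patient) and an optional matched matrix of detection
#' p-values. This is the object every analysis stage of the package consumes
#' and returns.
#'
#' @param values Numeric matrix, probes in rows (rownames = probe ids),
#'   samples in columns (colnames = sample ids). Values in \[0, 1\]; `NA`
#'   allowed as an explicit missing-value sentinel.
#' @param roles Sample roles: either a named character vector
#'   (`c(sample = "control", ...)`) or a data frame with columns
#'   `sample_id` and `role`. Roles must be `"control"` or `"patient"`.
#' @param detection_p Optional numeric matrix of detection p-values with the
#'   same dimnames as `values`.
#'
#' @return An object of class `beta_matrix`: a list with elements `values`,
#'   `roles` (named character vector) and `detection_p` (matrix or `NULL`).
#' @examples
#' m <- matrix(0.5, 3, 2, dimnames = list(paste0("cg", 1:3), c("C1", "P1")))
#' beta_matrix(m, c(C1 = "control", P1 = "patient"))
#' @export
beta_matrix <- function(values, roles, detection_p = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix of beta values.")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("`values` must have probe ids as rownames and sample ids as colnames.")
  }
  if (anyDuplicated(rownames(values))) {
    abort("Duplicate probe ids in beta matrix.")
  }
  rng <- range(values, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1) {
    abort(sprintf(
      "Beta values must lie in [0, 1]; observed range [%.4g, %.4g].",
      rng[1], rng[2]
    ))
  }
  roles <- as_role_map(roles)
  missing_roles <- setdiff(colnames(values), names(roles))
  if (length(missing_roles)) {
    abort(paste0(
      "No role given for sample(s): ",
      paste(missing_roles, collapse = ", ")
    ))
  }
  roles <- roles[colnames(values)]
  if (!is.null(detection_p)) {
    if (!is.matrix(detection_p) ||
      !identical(dim(detection_p), dim(values))) {
      abort("`detection_p` must be a matrix with the same shape as `values`.")
    }
    dimnames(detection_p) <- dimnames(values)
  }
  structure(
    list(values = values, roles = roles, detection_p = detection_p),
    class = "beta_matrix"
  )
}

as_role_map <- function(roles) {
  if (is.data.frame(roles)) {
    if (!all(c("sample_id", "role") %in% names(roles))) {
      abort("A role data frame needs columns `sample_id` and `role`.")
    }
    roles <- setNames(as.character(roles$role), roles$sample_id)
  }
  if (is.null(names(roles)) || any(names(roles) == "")) {
    abort("`roles` must be named by sample id.")
  }
  bad <- setdiff(unique(roles), c("control", "patient"))
  if (length(bad)) {
    abort(paste0("Unknown sample role(s): ", paste(bad, collapse = ", ")))
  }
  roles
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat(sprintf(
    "<beta_matrix> %d probes x %d samples (%d control, %d patient)%s\n",
    nrow(x$values), ncol(x$values),
    sum(x$roles == "control"), sum(x$roles == "patient"),
    if (is.null(x$detection_p)) "" else ", with detection p-values"
  ))
  invisible(x)
}

#' @export
dim.beta_matrix <- function(x) dim(x$values)

#' Sample ids by role
#'
#' @param x A [beta_matrix()].
#' @return Character vector of sample ids.
#' @export
control_samples <- function(x) names(x$roles)[x$roles == "control"]

#' @rdname control_samples
#' @export
patient_samples <- function(x) names(x$roles)[x$roles == "patient"]

#' @export
as_tibble.beta_matrix <- function(x, ...) {
  tibble::as_tibble(x$values, rownames = "probe_id") |>
    tidyr::pivot_longer(-"probe_id",
      names_to = "sample_id", values_to = "beta"
    ) |>
    dplyr::mutate(role = unname(x$roles[.data$sample_id]))
}

#' Subset a beta matrix by probe and/or sample
#'
#' @param x A [beta_matrix()].
#' @param probes Probe ids (or logical/integer index) to keep; `NULL` keeps all.
#' @param samples Sample ids to keep; `NULL` keeps all.
#' @return A [beta_matrix()].
#' @export
subset_beta <- function(x, probes = NULL, samples = NULL) {
  probes <- probes %||% rownames(x$values)
  samples <- samples %||% colnames(x$values)
  beta_matrix(
    x$values[probes, samples, drop = FALSE],
    x$roles[samples],
    detection_p = if (!is.null(x$detection_p)) {
      x$detection_p[probes, samples, drop = FALSE]
    }
  )
}

normalize_chrom <- function(chrom) {
  chrom <- as.character(chrom)
  ifelse(grepl("^chr", chrom), chrom, paste0("chr", chrom))
}

#' Read and write beta-value matrices
#'
#' The on-disk format is TSV: first column `probe_id`, remaining columns one
#' per sample (header = sample ids), cells numeric beta values in \[0, 1\]
#' (`NA` allowed). Row and column order are preserved exactly, so
#' `write_beta_matrix()` followed by `read_beta_matrix()` is the identity on
#' values and ordering.
#'
#' @param path TSV file path.
#' @param roles Sample roles as in [beta_matrix()].
#' @param detection_path Optional TSV of detection p-values, same layout.
#' @return `read_beta_matrix()` returns a [beta_matrix()];
#'   `write_beta_matrix()` returns `path` invisibly.
#' @export
read_beta_matrix <- function(path, roles, detection_path = NULL) {
  values <- read_named_matrix(path)
  detection_p <- NULL
  if (!is.null(detection_path)) {
    detection_p <- read_named_matrix(detection_path, check_range = FALSE)
    if (!identical(dimnames(detection_p), dimnames(values))) {
      abort("Detection p-value table does not match the beta matrix layout.")
    }
  }
  beta_matrix(values, roles, detection_p = detection_p)
}

read_named_matrix <- function(path, check_range = TRUE) {
  header <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]]
  if (length(header) < 1 || header[1] != "probe_id") {
    abort(sprintf(
      "Malformed header in %s: first column must be `probe_id`.", path
    ))
  }
  # parse numerics via strtod (correctly rounded), not vroom's fast path
  df <- suppressWarnings(readr::read_tsv(path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  ))
  if (ncol(df) < 2) abort(sprintf("%s has no sample columns.", path))
  for (j in seq_along(df)[-1]) {
    raw <- df[[j]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(num) & !is.na(raw) & raw != "NA")
    if (length(bad)) {
      abort(sprintf("Non-numeric cell(s) in %s (e.g. row %d).", path, bad[1]))
    }
    df[[j]] <- num
  }
  if (anyDuplicated(df$probe_id)) {
    abort(sprintf("Duplicate probe ids in %s.", path))
  }
  m <- as.matrix(df[-1])
  rownames(m) <- df$probe_id
  if (check_range) {
    rng <- range(m, na.rm = TRUE)
    if (rng[1] < 0 || rng[2] > 1) {
      abort(sprintf("Beta values in %s outside [0, 1].", path))
    }
  }
  m
}

#' @param x A [beta_matrix()].
#' @rdname read_beta_matrix
#' @export
write_beta_matrix <- function(x, path, detection_path = NULL) {
  stopifnot(inherits(x, "beta_matrix"))
  write_named_matrix(x$values, path)
  if (!is.null(detection_path)) {
    if (is.null(x$detection_p)) {
      abort("No detection p-values to write.")
    }
    write_named_matrix(x$detection_p, detection_path)
  }
  invisible(path)
}

write_named_matrix <- function(m, path) {
  # %.17g guarantees bit-exact round-trip of doubles through text
  df <- tibble::as_tibble(m, rownames = "probe_id")
  df[-1] <- lapply(df[-1], function(v) {
    out <- sprintf("%.17g", v)
    out[is.na(v)] <- NA_character_
    out
  })
  readr::write_tsv(df, path)
}

#' Read a probe manifest
#'
#' A manifest describes the array probes: genomic location, Infinium design
#' type and QC annotation. TSV columns: `probe_id`, `chrom`, `pos` (1-based),
#' `design_type` (`I`/`II`), `snp_flag`, `cross_reactive_flag` (logical or
#' 0/1), and optionally `cgi_context` (island/shore/shelf/open_sea, default
#' `open_sea`) and `genic_context` (promoter/body/3utr/intergenic, default
#' `intergenic`). Chromosome names are normalized to `chr`-prefixed form.
#'
#' @param path TSV file path.
#' @return A tibble, one row per probe.
#' @export
read_probe_manifest <- function(path) {
  df <- readr::read_tsv(path,
    col_types = readr::cols(
      probe_id = readr::col_character(),
      chrom = readr::col_character(),
      pos = readr::col_double(),
      design_type = readr::col_character(),
      .default = readr::col_guess()
    ),
    progress = FALSE
  )
  validate_manifest(df)
}

validate_manifest <- function(df) {
  required <- c("probe_id", "chrom", "pos", "design_type")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    abort(paste0("Manifest lacks column(s): ", paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(df$probe_id)) abort("Duplicate probe ids in manifest.")
  if (any(df$pos < 1)) abort("Manifest positions must be >= 1 (1-based).")
  if (!all(df$design_type %in% c("I", "II"))) {
    abort("`design_type` must be 'I' or 'II'.")
  }
  df <- dplyr::mutate(df,
    chrom = normalize_chrom(.data$chrom),
    pos = as.integer(.data$pos),
    snp_flag = as.logical(.data$snp_flag %||% FALSE),
    cross_reactive_flag = as.logical(.data$cross_reactive_flag %||% FALSE)
  )
  if (!"cgi_context" %in% names(df)) df$cgi_context <- "open_sea"
  if (!"genic_context" %in% names(df)) df$genic_context <- "intergenic"
  df$cgi_context[is.na(df$cgi_context)] <- "open_sea"
  df$genic_context[is.na(df$genic_context)] <- "intergenic"
  bad <- setdiff(df$cgi_context, c("island", "shore", "shelf", "open_sea"))
  if (length(bad)) abort(paste0("Unknown cgi_context: ", paste(bad, collapse = ", ")))
  bad <- setdiff(df$genic_context, c("promoter", "body", "3utr", "intergenic"))
  if (length(bad)) abort(paste0("Unknown genic_context: ", paste(bad, collapse = ", ")))
  tibble::as_tibble(df)
}

#' Read an imprinted-DMR catalog
#'
#' The catalog lists imprinted differentially methylated regions (iDMRs) as
#' 1-based, fully closed genomic intervals with the parental origin of
#' methylation. TSV columns: `chrom`, `start`, `end`, `name`,
#' `methylated_allele` (`maternal`/`paternal`) and optionally `excluded`
#' (logical). Regions of the polymorphically imprinted VTRNA2-1 locus are
#' flagged `excluded = TRUE` automatically (they are hypomethylated in a
#' sizeable fraction of the general population and therefore never contribute
#' to an MLID verdict) unless the file explicitly sets `excluded = FALSE`.
#' The returned catalog is sorted by (chrom, start). Coordinates are assumed
#' to be on a single genome build (the package default is hg19); no liftover
#' is performed.
#'
#' @param path BED-like TSV file path.
#' @param auto_exclude Region name patterns always flagged excluded when the
#'   file does not say otherwise. Default: VTRNA2-1.
#' @return A tibble with columns `name`, `chrom`, `start`, `end`,
#'   `methylated_allele`, `excluded`, sorted by (chrom, start).
#' @export
read_idmr_catalog <- function(path, auto_exclude = "VTRNA2-1") {
  df <- readr::read_tsv(path,
    col_types = readr::cols(
      chrom = readr::col_character(),
      start = readr::col_double(),
      end = readr::col_double(),
      name = readr::col_character(),
      methylated_allele = readr::col_character(),
      .default = readr::col_guess()
    ),
    progress = FALSE
  )
  had_excluded <- "excluded" %in% names(df)
  if (!had_excluded) df$excluded <- NA
  idmr_catalog(df, auto_exclude = auto_exclude)
}

#' @param regions Data frame with the catalog columns (see
#'   [read_idmr_catalog()]); `excluded` may be `NA` to mean "apply the
#'   automatic rule".
#' @rdname read_idmr_catalog
#' @export
idmr_catalog <- function(regions, auto_exclude = "VTRNA2-1") {
  required <- c("chrom", "start", "end", "name", "methylated_allele")
  missing <- setdiff(required, names(regions))
  if (length(missing)) {
    abort(paste0("Catalog lacks column(s): ", paste(missing, collapse = ", ")))
  }
  if (!"excluded" %in% names(regions)) regions$excluded <- NA
  if (anyDuplicated(regions$name)) abort("Duplicate region names in catalog.")
  if (any(regions$start > regions$end)) {
    abort("Catalog contains region(s) with start > end.")
  }
  bad <- setdiff(regions$methylated_allele, c("maternal", "paternal"))
  if (length(bad)) {
    abort(paste0("Unknown methylated_allele: ", paste(bad, collapse = ", ")))
  }
  auto <- Reduce(`|`, lapply(auto_exclude, function(p) {
    grepl(p, regions$name, fixed = TRUE)
  }), rep(FALSE, nrow(regions)))
  regions$excluded <- ifelse(is.na(regions$excluded), auto,
    as.logical(regions$excluded)
  )
  regions |>
    dplyr::mutate(
      chrom = normalize_chrom(.data$chrom),
      start = as.integer(.data$start),
      end = as.integer(.data$end)
    ) |>
    dplyr::select(
      "name", "chrom", "start", "end", "methylated_allele", "excluded"
    ) |>
    dplyr::arrange(.data$chrom, .data$start) |>
    tibble::as_tibble()
}

#' @rdname read_idmr_catalog
#' @param catalog A catalog tibble.
#' @export
write_idmr_catalog <- function(catalog, path) {
  readr::write_tsv(
    catalog[c("chrom", "start", "end", "name", "methylated_allele", "excluded")],
    path
  )
  invisible(path)
}

#' Map probes to iDMR regions
#'
#' A probe belongs to a region iff it lies on the same chromosome and
#' `start <= pos <= end` (closed interval, both boundaries inclusive).
#' Probes falling in no region are omitted from the result. Output order is
#' genomic (regions by chrom/start, probes by position within each region)
#' regardless of the input row order, so the mapping is idempotent and
#' order-independent.
#'
#' @param manifest Probe manifest tibble (see [read_probe_manifest()]).
#' @param catalog iDMR catalog tibble (see [read_idmr_catalog()]).
#' @return A tibble with columns `region`, `probe_id`, `chrom`, `pos`.
#' @export
map_probes_to_regions <- function(manifest, catalog) {
  manifest <- dplyr::mutate(manifest, chrom = normalize_chrom(.data$chrom))
  catalog |>
    dplyr::select(region = "name", "chrom", "start", "end") |>
    dplyr::inner_join(
      dplyr::select(manifest, "probe_id", "chrom", "pos"),
      by = "chrom", relationship = "many-to-many"
    ) |>
    dplyr::filter(.data$pos >= .data$start, .data$pos <= .data$end) |>
    dplyr::arrange(.data$chrom, .data$start, .data$pos) |>
    dplyr::select("region", "probe_id", "chrom", "pos")
}
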