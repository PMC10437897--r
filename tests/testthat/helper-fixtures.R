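# Small in-code fixtures shared across test files.

toy_catalog <- function() {
  idmr_catalog(tibble::tibble(
    chrom = c("chr1", "chr11", "chr11", "chr5"),
    start = c(100L, 1000L, 5000L, 9000L),
    end = c(1000L, 2000L, 6000L, 9900L),
    name = c(
      "PPIEL:Ex1-DMR", "H19/IGF2:IG-DMR", "KCNQ1OT1:TSS-DMR", "VTRNA2-1:DMR"
    ),
    methylated_allele = c("maternal", "paternal", "maternal", "maternal")
  ))
}

# A probe map + DMP-call pair realizing a given significance pattern along
# one region (probes in genomic order).
pattern_fixture <- function(pattern, directions = "hypo", delta = 0.3,
                            region = "KCNQ1OT1:TSS-DMR", chrom = "chr11",
                            start_pos = 5000L, patient = "P1") {
  k <- length(pattern)
  directions <- rep(directions, length.out = k)
  probes <- sprintf("%s_p%02d", gsub("[^A-Za-z0-9]", "", region), seq_len(k))
  map <- tibble::tibble(
    region = region, probe_id = probes, chrom = chrom,
    pos = start_pos + seq_len(k) * 10L
  )
  calls <- tibble::tibble(
    patient_id = patient,
    probe_id = probes,
    delta_beta = ifelse(
      pattern == 1, ifelse(directions == "hypo", -delta, delta), 0.01
    ),
    p = ifelse(pattern == 1, 0.001, 0.9),
    direction = ifelse(pattern == 1, directions, "hyper"),
    passes = pattern == 1
  )
  list(map = map, calls = calls)
}

# Stack pattern fixtures for several regions of one patient, with empty
# calls for catalog regions not mentioned.
multi_region_fixture <- function(specs, catalog, patient = "P1") {
  maps <- list()
  calls <- list()
  for (i in seq_along(specs)) {
    s <- specs[[i]]
    reg <- catalog[catalog$name == s$region, ]
    fx <- pattern_fixture(s$pattern,
      directions = s$direction, region = s$region,
      chrom = reg$chrom, start_pos = reg$start, patient = patient
    )
    maps[[i]] <- fx$map
    calls[[i]] <- fx$calls
  }
  list(map = dplyr::bind_rows(maps), calls = dplyr::bind_rows(calls))
}

# Tiny beta matrix with explicit control/patient values per probe.
toy_beta <- function(control_values, patient_values,
                     probe_ids = NULL, detection_p = NULL) {
  ctrl <- do.call(rbind, control_values)
  pat <- do.call(rbind, patient_values)
  m <- cbind(ctrl, pat)
  probe_ids <- probe_ids %||% sprintf("cg%03d", seq_len(nrow(m)))
  colnames(m) <- c(
    paste0("C", seq_len(ncol(ctrl))), paste0("P", seq_len(ncol(pat)))
  )
  rownames(m) <- probe_ids
  roles <- setNames(
    rep(c("control", "patient"), c(ncol(ctrl), ncol(pat))), colnames(m)
  )
  beta_matrix(m, roles, detection_p = detection_p)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
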