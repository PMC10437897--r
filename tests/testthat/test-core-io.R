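test_that("beta matrix validates values, roles and shape", {
  m <- matrix(0.5, 3, 2, dimnames = list(paste0("cg", 1:3), c("C1", "P1")))
  roles <- c(C1 = "control", P1 = "patient")
  b <- beta_matrix(m, roles)
  expect_s3_class(b, "beta_matrix")
  expect_identical(dim(b), c(3L, 2L))
  expect_identical(control_samples(b), "C1")
  expect_identical(patient_samples(b), "P1")

  bad <- m
  bad[1, 1] <- 1.2
  expect_error(beta_matrix(bad, roles), "\\[0, 1\\]")
  expect_error(beta_matrix(m, c(C1 = "control")), "No role")
  expect_error(beta_matrix(m, c(C1 = "ctrl", P1 = "patient")), "Unknown")
  dup <- rbind(m, m[1, , drop = FALSE])
  expect_error(beta_matrix(dup, roles), "Duplicate")
})

test_that("beta matrix TSV round-trip is the identity on values and order", {
  set.seed(42)
  m <- matrix(runif(20), 5, 4, dimnames = list(
    sprintf("cg%05d", sample(1:99999, 5)), c("C1", "C2", "P1", "P2")
  ))
  roles <- setNames(c("control", "control", "patient", "patient"), colnames(m))
  dp <- matrix(runif(20, 0, 0.04), 5, 4, dimnames = dimnames(m))
  b <- beta_matrix(m, roles, detection_p = dp)
  path <- withr::local_tempfile(fileext = ".tsv")
  dpath <- withr::local_tempfile(fileext = ".tsv")
  write_beta_matrix(b, path, detection_path = dpath)
  b2 <- read_beta_matrix(path, roles, detection_path = dpath)
  expect_identical(b2$values, b$values)
  expect_identical(b2$detection_p, b$detection_p)
  expect_identical(rownames(b2$values), rownames(m))
  expect_identical(colnames(b2$values), colnames(m))
})

test_that("malformed beta TSVs are rejected", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("probe_id\tS1", "cg1\t1.2"), path)
  expect_error(read_beta_matrix(path, c(S1 = "control")), "outside")
  writeLines(c("id\tS1", "cg1\t0.5"), path)
  expect_error(read_beta_matrix(path, c(S1 = "control")), "Malformed header")
  writeLines(c("probe_id\tS1", "cg1\t0.5", "cg1\t0.4"), path)
  expect_error(read_beta_matrix(path, c(S1 = "control")), "Duplicate")
  writeLines(c("probe_id\tS1", "cg1\tabc"), path)
  expect_error(read_beta_matrix(path, c(S1 = "control")), "Non-numeric")
})

test_that("iDMR catalog parses published intervals and auto-excludes VTRNA2-1", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "chrom\tstart\tend\tname\tmethylated_allele",
    "chr6\t3849096\t3849469\tFAM50B:TSS-DMR\tmaternal",
    "chr1\t39559298\t39559744\tPPIEL:Ex1-DMR\tmaternal",
    "chr5\t135416100\t135416800\tVTRNA2-1:DMR\tmaternal"
  ), path)
  cat <- read_idmr_catalog(path)
  expect_identical(nrow(cat), 3L)
  # sorted by (chrom, start), not file order
  expect_identical(cat$name[1], "PPIEL:Ex1-DMR")
  ppiel <- cat[cat$name == "PPIEL:Ex1-DMR", ]
  fam50b <- cat[cat$name == "FAM50B:TSS-DMR", ]
  expect_identical(ppiel$end - ppiel$start + 1L, 447L)
  expect_identical(fam50b$end - fam50b$start + 1L, 374L)
  expect_true(cat$excluded[cat$name == "VTRNA2-1:DMR"])
  expect_false(any(cat$excluded[cat$name != "VTRNA2-1:DMR"]))

  # explicit excluded column overrides the automatic rule
  writeLines(c(
    "chrom\tstart\tend\tname\tmethylated_allele\texcluded",
    "chr5\t135416100\t135416800\tVTRNA2-1:DMR\tmaternal\tFALSE"
  ), path)
  expect_false(read_idmr_catalog(path)$excluded)
})

test_that("catalog rejects inverted intervals and duplicate names", {
  base <- tibble::tibble(
    chrom = "chr1", start = 200L, end = 100L,
    name = "X:DMR", methylated_allele = "maternal"
  )
  expect_error(idmr_catalog(base), "start > end")
  dup <- tibble::tibble(
    chrom = "chr1", start = c(1L, 50L), end = c(10L, 60L),
    name = "X:DMR", methylated_allele = "maternal"
  )
  expect_error(idmr_catalog(dup), "Duplicate")
})

test_that("probe-region mapping is boundary-inclusive and matches brute force", {
  cat <- toy_catalog()
  manifest <- tibble::tibble(
    probe_id = sprintf("cg%02d", 1:4),
    chrom = "chr1",
    pos = c(99L, 100L, 1000L, 1001L),
    design_type = "II", snp_flag = FALSE, cross_reactive_flag = FALSE
  )
  map <- map_probes_to_regions(manifest, cat)
  expect_setequal(map$probe_id, c("cg02", "cg03")) # both boundaries inclusive

  set.seed(7)
  rand <- tibble::tibble(
    probe_id = sprintf("cg%03d", 1:40),
    chrom = sample(c("chr1", "chr11", "chr5", "chr2"), 40, replace = TRUE),
    pos = sample(1:12000, 40),
    design_type = "I", snp_flag = FALSE, cross_reactive_flag = FALSE
  )
  got <- map_probes_to_regions(rand, cat)
  want <- oracle_probe_membership(rand, cat)
  expect_setequal(
    paste(got$region, got$probe_id),
    paste(want$region, want$probe_id)
  )

  # order-independence: shuffled input, genomic output order
  shuffled <- rand[sample(nrow(rand)), ]
  got2 <- map_probes_to_regions(shuffled, cat)
  expect_identical(got, got2)
  expect_false(is.unsorted(got$pos[got$region == got$region[1]]))
})

test_that("chromosome names are normalized to chr-prefixed form", {
  manifest <- tibble::tibble(
    probe_id = "cg1", chrom = "11", pos = 1500L,
    design_type = "I", snp_flag = FALSE, cross_reactive_flag = FALSE
  )
  map <- map_probes_to_regions(manifest, toy_catalog())
  expect_identical(map$region, "H19/IGF2:IG-DMR")
})
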