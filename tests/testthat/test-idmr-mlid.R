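region_call_for <- function(pattern, direction = "hypo", ...,
                            region = "KCNQ1OT1:TSS-DMR") {
  fx <- pattern_fixture(pattern, directions = direction, region = region)
  call_regions(fx$calls, fx$map, toy_catalog(), ...) |>
    dplyr::filter(.data$region == !!region)
}

test_that("region rule: [1,1,0,1,1] hypo is aberrant, [1,0,1,0,1] is not", {
  rc <- region_call_for(c(1, 1, 0, 1, 1))
  expect_identical(rc$n_significant, 4L)
  expect_identical(rc$max_consecutive, 2L)
  expect_identical(rc$direction, "hypo")
  expect_true(rc$aberrant)

  rc2 <- region_call_for(c(1, 0, 1, 0, 1))
  expect_identical(rc2$n_significant, 3L)
  expect_false(rc2$aberrant) # fails the >= 4 significant probes condition
})

test_that("a strongly hypomethylated region is called with its mean effect", {
  # 10 passing hypo probes at |delta beta| 0.26, as for a planted FAM50B-like
  # loss of methylation
  fx <- pattern_fixture(rep(1, 10), directions = "hypo", delta = 0.26)
  rc <- call_regions(fx$calls, fx$map, toy_catalog()) |>
    dplyr::filter(.data$region == "KCNQ1OT1:TSS-DMR")
  expect_true(rc$aberrant)
  expect_identical(rc$direction, "hypo")
  expect_identical(rc$n_significant, 10L)
  expect_equal(rc$mean_abs_delta, 0.26)
})

test_that("mixed-direction regions are flagged and never aberrant", {
  fx <- pattern_fixture(rep(1, 6), directions = rep(c("hypo", "hyper"), 3))
  rc <- call_regions(fx$calls, fx$map, toy_catalog()) |>
    dplyr::filter(.data$region == "KCNQ1OT1:TSS-DMR")
  expect_identical(rc$direction, "mixed")
  expect_false(rc$aberrant)
  # consecutive runs must share direction
  expect_identical(rc$max_consecutive, 1L)
})

test_that("regions with no mapped probes yield a non-aberrant row", {
  fx <- pattern_fixture(c(1, 1, 1, 1))
  rc <- call_regions(fx$calls, fx$map, toy_catalog())
  empty <- rc[rc$region == "PPIEL:Ex1-DMR", ]
  expect_identical(empty$n_probes, 0L)
  expect_false(empty$aberrant)
  expect_identical(nrow(rc), nrow(toy_catalog()))
})

test_that("mapped_probes rule needs coverage, not significance, at the count gate", {
  # 5 mapped probes, 2 consecutive significant: fails the default rule,
  # passes the coverage-based alternative
  fx <- pattern_fixture(c(1, 1, 0, 0, 0))
  strict <- call_regions(fx$calls, fx$map, toy_catalog()) |>
    dplyr::filter(.data$region == "KCNQ1OT1:TSS-DMR")
  loose <- call_regions(fx$calls, fx$map, toy_catalog(),
    rule = "mapped_probes"
  ) |>
    dplyr::filter(.data$region == "KCNQ1OT1:TSS-DMR")
  expect_false(strict$aberrant)
  expect_true(loose$aberrant)
})

test_that("region calls match the brute-force rule on random patterns", {
  set.seed(23)
  for (i in 1:60) {
    k <- sample(4:12, 1)
    pattern <- rbinom(k, 1, 0.5)
    dirs <- sample(c("hypo", "hyper"), k, replace = TRUE)
    min_sig <- sample(2:5, 1)
    min_consec <- sample(2:3, 1)
    fx <- pattern_fixture(pattern, directions = dirs)
    rc <- call_regions(fx$calls, fx$map, toy_catalog(),
      min_significant = min_sig, min_consecutive = min_consec
    ) |>
      dplyr::filter(.data$region == "KCNQ1OT1:TSS-DMR")
    want <- oracle_region_aberrant(pattern == 1, dirs, min_sig, min_consec)
    expect_identical(rc$aberrant, want)
  }
})

test_that("raising either region threshold never adds aberrant regions", {
  set.seed(31)
  for (i in 1:25) {
    k <- sample(5:10, 1)
    fx <- pattern_fixture(rbinom(k, 1, 0.6),
      directions = sample(c("hypo", "hyper"), k, replace = TRUE)
    )
    base <- call_regions(fx$calls, fx$map, toy_catalog(),
      min_significant = 3, min_consecutive = 2
    )
    for (args in list(c(4, 2), c(3, 3), c(5, 3))) {
      stricter <- call_regions(fx$calls, fx$map, toy_catalog(),
        min_significant = args[1], min_consecutive = args[2]
      )
      expect_true(all(base$aberrant | !stricter$aberrant))
    }
  }
})

test_that("region calls are invariant to probe input order", {
  fx <- pattern_fixture(c(1, 1, 0, 1, 1))
  shuffle <- sample(nrow(fx$map))
  rc1 <- call_regions(fx$calls, fx$map, toy_catalog())
  rc2 <- call_regions(
    fx$calls[rev(seq_len(nrow(fx$calls))), ], fx$map[shuffle, ], toy_catalog()
  )
  expect_identical(rc1, rc2)
})

test_that("epigenotypes derive from the two imprinting control regions", {
  cat <- toy_catalog()
  # IC2-LoM (common BWS epigenotype)
  fx <- multi_region_fixture(
    list(list(region = "KCNQ1OT1:TSS-DMR", pattern = rep(1, 6), direction = "hypo")),
    cat
  )
  rc <- call_regions(fx$calls, fx$map, cat)
  eg <- assign_epigenotype(rc)
  expect_identical(eg$epigenotype, "IC2-LoM")
  expect_identical(unlist(eg$disease_regions), "KCNQ1OT1:TSS-DMR")

  # IC1-GoM (rarer BWS epigenotype)
  fx <- multi_region_fixture(
    list(list(region = "H19/IGF2:IG-DMR", pattern = rep(1, 6), direction = "hyper")),
    cat
  )
  eg <- assign_epigenotype(call_regions(fx$calls, fx$map, cat))
  expect_identical(eg$epigenotype, "IC1-GoM")

  # IC1-LoM (Silver-Russell)
  fx <- multi_region_fixture(
    list(list(region = "H19/IGF2:IG-DMR", pattern = rep(1, 6), direction = "hypo")),
    cat
  )
  eg <- assign_epigenotype(call_regions(fx$calls, fx$map, cat))
  expect_identical(eg$epigenotype, "IC1-LoM")

  # no aberrant ICR
  fx <- multi_region_fixture(
    list(list(region = "KCNQ1OT1:TSS-DMR", pattern = c(1, 0, 1, 0), direction = "hypo")),
    cat
  )
  eg <- assign_epigenotype(call_regions(fx$calls, fx$map, cat))
  expect_identical(eg$epigenotype, "none")
})

test_that("both ICRs aberrant: label follows the larger effect, both recorded", {
  cat <- toy_catalog()
  fx <- multi_region_fixture(
    list(
      list(region = "KCNQ1OT1:TSS-DMR", pattern = rep(1, 6), direction = "hypo"),
      list(region = "H19/IGF2:IG-DMR", pattern = rep(1, 6), direction = "hyper")
    ),
    cat
  )
  fx$calls$delta_beta[grepl("H19", fx$calls$probe_id)] <- 0.4
  eg <- assign_epigenotype(call_regions(fx$calls, fx$map, cat))
  expect_identical(eg$epigenotype, "IC1-GoM")
  expect_setequal(
    unlist(eg$disease_regions), c("KCNQ1OT1:TSS-DMR", "H19/IGF2:IG-DMR")
  )
})

test_that("a missing imprinting control region is an error", {
  fx <- pattern_fixture(rep(1, 4), region = "PPIEL:Ex1-DMR", chrom = "chr1",
    start_pos = 100L)
  rc <- call_regions(fx$calls, fx$map, toy_catalog()[1, ])
  expect_error(assign_epigenotype(rc), "imprinting control region")
})

test_that("MLID requires an aberrant non-excluded region beyond the disease locus", {
  cat <- toy_catalog()
  # IC2-LoM plus PPIEL hypomethylation -> MLID with one additional region
  fx <- multi_region_fixture(
    list(
      list(region = "KCNQ1OT1:TSS-DMR", pattern = rep(1, 6), direction = "hypo"),
      list(region = "PPIEL:Ex1-DMR", pattern = rep(1, 4), direction = "hypo")
    ),
    cat
  )
  rc <- call_regions(fx$calls, fx$map, cat)
  rep <- classify_mlid(rc)
  expect_true(rep$mlid)
  expect_identical(rep$n_additional, 1L)
  expect_identical(unlist(rep$additional_regions), "PPIEL:Ex1-DMR")

  # IC2-LoM plus only the excluded polymorphic region -> no MLID
  fx2 <- multi_region_fixture(
    list(
      list(region = "KCNQ1OT1:TSS-DMR", pattern = rep(1, 6), direction = "hypo"),
      list(region = "VTRNA2-1:DMR", pattern = rep(1, 5), direction = "hypo")
    ),
    cat
  )
  rc2 <- call_regions(fx2$calls, fx2$map, cat)
  expect_true(rc2$aberrant[rc2$region == "VTRNA2-1:DMR"])
  rep2 <- classify_mlid(rc2)
  expect_false(rep2$mlid)
  expect_identical(rep2$n_additional, 0L)

  # disease region itself never counts as additional
  rep1_disease <- unlist(rep$disease_regions)
  expect_false(any(rep1_disease %in% unlist(rep$additional_regions)))
})

test_that("an extensively disturbed patient reports every additional region", {
  cat <- idmr_catalog(tibble::tibble(
    chrom = "chr1",
    start = seq(100L, by = 2000L, length.out = 9),
    end = seq(1000L, by = 2000L, length.out = 9),
    name = c(
      "H19/IGF2:IG-DMR", "KCNQ1OT1:TSS-DMR", sprintf("extra%d:DMR", 1:7)
    ),
    methylated_allele = "maternal"
  ))
  specs <- c(
    list(list(region = "KCNQ1OT1:TSS-DMR", pattern = rep(1, 6), direction = "hypo")),
    lapply(sprintf("extra%d:DMR", 1:7), function(r) {
      list(region = r, pattern = rep(1, 5), direction = "hypo")
    })
  )
  fx <- multi_region_fixture(specs, cat)
  rep <- classify_mlid(call_regions(fx$calls, fx$map, cat))
  expect_true(rep$mlid)
  expect_identical(rep$n_additional, 7L)
})
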