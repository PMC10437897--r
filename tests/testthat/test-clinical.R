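test_that("BWS consensus score reproduces consistent published profiles", {
  # macroglossia + lateralized overgrowth (cardinal), ear anomalies +
  # facial nevus (suggestive) -> 6, classical
  s <- bws_score(
    cardinal = c("macroglossia", "lateralized_overgrowth"),
    suggestive = c("ear_creases_pits", "facial_nevus")
  )
  expect_identical(s$score, 6L)
  expect_true(s$classical)

  # macroglossia + exomphalos (cardinal), ear anomalies (suggestive) -> 5
  s <- bws_score(
    cardinal = c("macroglossia", "exomphalos"),
    suggestive = "ear_creases_pits"
  )
  expect_identical(s$score, 5L)
  expect_true(s$classical)

  empty <- bws_score()
  expect_identical(empty$score, 0L)
  expect_false(empty$classical)

  # threshold: 2 cardinal = 4 points is already classical
  expect_true(bws_score(cardinal = c("macroglossia", "exomphalos"))$classical)
  expect_false(bws_score(cardinal = "macroglossia", suggestive = "lga")$classical)

  expect_error(bws_score(cardinal = "macrosomia"), "Unknown cardinal")
  expect_error(bws_score(suggestive = "big_ears"), "Unknown suggestive")
})

test_that("NH-CSS scores one point per present item", {
  expect_identical(
    nhcss_score(c(
      "sga", "postnatal_growth_failure", "relative_macrocephaly",
      "body_asymmetry"
    )),
    4L
  )
  expect_identical(
    nhcss_score(c(
      "sga", "postnatal_growth_failure", "relative_macrocephaly",
      "body_asymmetry", "feeding_difficulty_low_bmi"
    )),
    5L
  )
  expect_identical(nhcss_score(nhcss_features), 6L)
  expect_identical(nhcss_score(), 0L)
  expect_error(nhcss_score("tall"), "Unknown NH-CSS")
})

test_that("score_cohort scores mixed BWS/SRS profiles row-wise", {
  profiles <- tibble::tibble(
    patient_id = c(rep("BWS2", 4), rep("SRS1", 4)),
    syndrome = rep(c("BWS", "SRS"), each = 4),
    feature = c(
      "macroglossia", "lateralized_overgrowth", "ear_creases_pits",
      "facial_nevus",
      "sga", "postnatal_growth_failure", "relative_macrocephaly",
      "body_asymmetry"
    ),
    category = c(
      "cardinal", "cardinal", "suggestive", "suggestive",
      NA, NA, NA, NA
    )
  )
  out <- score_cohort(profiles)
  expect_identical(out$score[out$patient_id == "BWS2"], 6L)
  expect_identical(out$score[out$patient_id == "SRS1"], 4L)
})

test_that("pyrosequencing SDS is plain standardization", {
  ctrl <- c(48, 50, 52, 50, 49, 51)
  expect_equal(pyroseq_sds(mean(ctrl), ctrl), 0)
  expect_equal(pyroseq_sds(mean(ctrl) + 2 * sd(ctrl), ctrl), 2)
  set.seed(8)
  for (i in 1:20) {
    panel <- rnorm(20, 50, 3)
    x <- runif(1, 20, 80)
    expect_equal(
      pyroseq_sds(x, panel),
      (x - mean(panel)) / sd(panel),
      tolerance = 1e-12
    )
  }
  expect_error(pyroseq_sds(50, c(50, 50)), "zero standard deviation")
  expect_error(pyroseq_sds(50, 50), "at least 2")
})

test_that("Fisher exact reproduces published group-comparison p-values", {
  expect_equal(round(fisher_exact_2x2(5, 4, 2, 1), 3), 1.000)
  expect_equal(round(fisher_exact_2x2(1, 8, 1, 2), 3), 0.455)
  expect_equal(round(fisher_exact_2x2(3, 6, 2, 1), 3), 0.523)
})

test_that("Fisher exact equals full enumeration on all small tables", {
  for (n in 2:12) {
    for (a in 0:n) {
      for (b in 0:(n - a)) {
        for (c in 0:(n - a - b)) {
          d <- n - a - b - c
          if (a + b == 0 || c + d == 0 || a + c == 0 || b + d == 0) next
          expect_equal(
            fisher_exact_2x2(a, b, c, d),
            oracle_fisher_p(a, b, c, d),
            tolerance = 1e-9
          )
        }
      }
    }
  }
})

test_that("Fisher exact rejects degenerate tables", {
  expect_error(fisher_exact_2x2(0, 0, 1, 2), "positive margins")
  expect_error(fisher_exact_2x2(-1, 1, 1, 1), "non-negative")
  expect_error(fisher_exact_2x2(0.5, 1, 1, 1), "non-negative")
})

test_that("Mann-Whitney exact p matches permutation enumeration", {
  set.seed(12)
  for (i in 1:25) {
    m <- sample(2:5, 1)
    n <- sample(2:5, 1)
    x <- round(rnorm(m, 0, 10), 6)
    y <- round(rnorm(n, 1, 10), 6)
    got <- mann_whitney(x, y)
    expect_equal(got$p, oracle_mann_whitney(x, y), tolerance = 1e-12)
  }
})

test_that("Mann-Whitney extremes and identical samples behave", {
  # complete separation gives the minimal U and smallest exact p
  x <- 1:4
  y <- 11:14
  got <- mann_whitney(x, y)
  expect_identical(unname(got$U), 0)
  expect_equal(got$p, 2 / choose(8, 4), tolerance = 1e-12)
  # identical samples: U at the null centre, p = 1
  got2 <- mann_whitney(c(1, 3, 5), c(1, 3, 5))
  expect_equal(unname(got2$U), 4.5)
  expect_gte(got2$p, 0.9)
})

test_that("MLID group comparison dispatches the right test per variable type", {
  set.seed(14)
  data <- tibble::tibble(
    patient_id = sprintf("B%02d", 1:12),
    mlid = rep(c(FALSE, TRUE), c(9, 3)),
    gestational_age = c(rnorm(9, 36.6, 2.8), rnorm(3, 38.7, 1.5)),
    female = c(rep(TRUE, 5), rep(FALSE, 4), TRUE, TRUE, FALSE),
    art = c(TRUE, rep(FALSE, 8), TRUE, FALSE, FALSE)
  )
  tab <- compare_mlid_groups(data)
  expect_identical(
    tab$test[tab$variable == "gestational_age"], "mann_whitney"
  )
  expect_identical(tab$test[tab$variable == "female"], "fisher_exact")
  expect_equal(
    tab$p[tab$variable == "female"], fisher_exact_2x2(5, 4, 2, 1),
    tolerance = 1e-12
  )
  expect_equal(round(tab$p[tab$variable == "art"], 3), 0.455)
})
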