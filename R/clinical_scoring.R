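#' Clinical feature vocabularies
#'
#' Closed vocabularies used by the clinical scores. `bws_cardinal_features`
#' and `bws_suggestive_features` feed the Beckwith-Wiedemann consensus
#' score (2 and 1 point(s) per present feature respectively);
#' `nhcss_features` are the six Netchine-Harbison items for Silver-Russell
#' syndrome (1 point each).
#'
#' @format Character vectors of feature tokens.
#' @export
bws_cardinal_features <- c(
  "macroglossia", "exomphalos", "lateralized_overgrowth",
  "multifocal_wilms", "hyperinsulinism", "pathology"
)

#' @rdname bws_cardinal_features
#' @export
bws_suggestive_features <- c(
  "lga", "facial_nevus", "polyhydramnios_placentomegaly",
  "ear_creases_pits", "transient_hypoglycemia", "embryonal_tumor",
  "organomegaly", "umbilical_hernia_diastasis"
)

#' @rdname bws_cardinal_features
#' @export
nhcss_features <- c(
  "sga", "postnatal_growth_failure", "relative_macrocephaly",
  "protruding_forehead", "body_asymmetry", "feeding_difficulty_low_bmi"
)

check_features <- function(features, vocabulary, what) {
  bad <- setdiff(features, vocabulary)
  if (length(bad)) {
    abort(paste0(
      "Unknown ", what, " feature token(s): ", paste(bad, collapse = ", ")
    ))
  }
  unique(features)
}

#' Beckwith-Wiedemann consensus clinical score
#'
#' Scores a patient's phenotype with the BWS consensus system: 2 points per
#' cardinal feature present and 1 point per suggestive feature. A total of
#' 4 or more qualifies as classical BWS.
#'
#' @param cardinal Character vector of present cardinal features (tokens
#'   from [bws_cardinal_features]).
#' @param suggestive Character vector of present suggestive features
#'   (tokens from [bws_suggestive_features]).
#' @return One-row tibble: `score`, `classical`.
#' @examples
#' bws_score(
#'   cardinal = c("macroglossia", "lateralized_overgrowth"),
#'   suggestive = c("ear_creases_pits", "facial_nevus")
#' )
#' @export
bws_score <- function(cardinal = character(), suggestive = character()) {
  cardinal <- check_features(cardinal, bws_cardinal_features, "cardinal")
  suggestive <- check_features(suggestive, bws_suggestive_features, "suggestive")
  score <- 2L * length(cardinal) + length(suggestive)
  tibble::tibble(score = score, classical = score >= 4)
}

#' Netchine-Harbison clinical score (NH-CSS)
#'
#' Scores a patient for Silver-Russell syndrome: 1 point for each of the
#' six NH-CSS items present (small for gestational age, postnatal growth
#' failure, relative macrocephaly at birth, protruding forehead, body
#' asymmetry, feeding difficulties and/or low BMI).
#'
#' @param features Character vector of present items (tokens from
#'   [nhcss_features]).
#' @return Integer score in 0..6.
#' @examples
#' nhcss_score(c(
#'   "sga", "postnatal_growth_failure",
#'   "relative_macrocephaly", "body_asymmetry"
#' ))
#' @export
nhcss_score <- function(features = character()) {
  features <- check_features(features, nhcss_features, "NH-CSS")
  length(features)
}

#' Score a cohort of clinical profiles
#'
#' Data-frame-first wrapper over [bws_score()] and [nhcss_score()]: takes a
#' long table of present features and returns one scored row per patient.
#'
#' @param profiles Tibble with columns `patient_id`, `syndrome`
#'   (`"BWS"`/`"SRS"`), `feature`, and for BWS rows a `category`
#'   (`"cardinal"`/`"suggestive"`).
#' @return Tibble: `patient_id`, `syndrome`, `score`, `classical`
#'   (BWS only; `NA` for SRS).
#' @export
score_cohort <- function(profiles) {
  profiles |>
    dplyr::group_by(.data$patient_id, .data$syndrome) |>
    dplyr::group_modify(function(df, key) {
      if (key$syndrome == "BWS") {
        bws_score(
          cardinal = df$feature[df$category == "cardinal"],
          suggestive = df$feature[df$category == "suggestive"]
        )
      } else {
        tibble::tibble(
          score = nhcss_score(df$feature), classical = NA
        )
      }
    }) |>
    dplyr::ungroup()
}

#' Standard deviation score against a matched control panel
#'
#' Standardizes a subject's measurement (e.g. a pyrosequencing mean %mC at
#' an imprinting control region) against a panel of matched controls:
#' `SDS = (x - mean(controls)) / sd(controls)` with the sample (n - 1)
#' standard deviation.
#'
#' @param x Subject value.
#' @param controls Numeric vector of at least 2 control values with
#'   non-zero standard deviation.
#' @return The standard deviation score (numeric scalar; vectorized in `x`).
#' @export
pyroseq_sds <- function(x, controls) {
  controls <- controls[!is.na(controls)]
  if (length(controls) < 2) abort("Need at least 2 control values.")
  s <- sd(controls)
  if (!is.finite(s) || s == 0) abort("Control panel has zero standard deviation.")
  (x - mean(controls)) / s
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value for a 2x2 contingency table
#' `rbind(c(a, b), c(c, d))` by the point-probability convention: the sum
#' of hypergeometric probabilities of all tables (with the observed
#' margins) no more likely than the observed one.
#'
#' @param a,b,c,d Non-negative integer cell counts (row-wise).
#' @return Two-sided p-value (numeric scalar).
#' @examples
#' fisher_exact_2x2(5, 4, 2, 1) # 1
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("Cell counts must be non-negative integers.")
  }
  m <- matrix(counts, nrow = 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    abort("Fisher's exact test needs positive margins.")
  }
  fisher.test(m)$p.value
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two independent samples. For small samples
#' (`length(x) + length(y) <= 12`, no ties) the p-value is exact; larger or
#' tied samples use the normal approximation with the tie-corrected
#' variance.
#'
#' @param x,y Numeric vectors (both non-empty).
#' @return One-row tibble: `U` (the statistic for `x`), `p` (two-sided).
#' @export
mann_whitney <- function(x, y) {
  if (!length(x) || !length(y)) abort("Both samples must be non-empty.")
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- (length(x) + length(y) <= 12) && !ties
  res <- suppressWarnings(
    wilcox.test(x, y, exact = use_exact, correct = FALSE)
  )
  tibble::tibble(U = unname(res$statistic), p = res$p.value)
}

#' Compare clinical variables between MLID groups
#'
#' Builds a comparison table in the style of a mono-locus vs multi-locus
#' clinical table: numeric variables are compared with the Mann-Whitney U
#' test, logical (presence/absence) variables with Fisher's exact test.
#' Variables constant across all patients get `p = NA`.
#'
#' @param data Tibble with one row per patient, a logical `mlid` column,
#'   and the clinical variables to compare (numeric or logical).
#' @return Tibble: `variable`, `test`, group summaries
#'   (`mono`, `multi`: mean +/- sd or n (%)), `p`.
#' @export
compare_mlid_groups <- function(data) {
  stopifnot("mlid" %in% names(data), is.logical(data$mlid))
  vars <- setdiff(names(data), c("patient_id", "mlid"))
  purrr::map_dfr(vars, function(v) {
    x <- data[[v]][!data$mlid]
    y <- data[[v]][data$mlid]
    if (is.numeric(data[[v]])) {
      p <- if (length(unique(c(x, y))) > 1) mann_whitney(x, y)$p else NA_real_
      tibble::tibble(
        variable = v, test = "mann_whitney",
        mono = sprintf("%.1f ± %.1f", mean(x), sd(x)),
        multi = sprintf("%.1f ± %.1f", mean(y), sd(y)),
        p = p
      )
    } else if (is.logical(data[[v]])) {
      p <- if (sum(x) + sum(y) > 0 && sum(!x) + sum(!y) > 0) {
        fisher_exact_2x2(sum(x), sum(!x), sum(y), sum(!y))
      } else {
        NA_real_
      }
      tibble::tibble(
        variable = v, test = "fisher_exact",
        mono = sprintf("%d (%.1f%%)", sum(x), 100 * mean(x)),
        multi = sprintf("%d (%.1f%%)", sum(y), 100 * mean(y)),
        p = p
      )
    } else {
      tibble::tibble(
        variable = v, test = NA_character_,
        mono = NA_character_, multi = NA_character_, p = NA_real_
      )
    }
  })
}
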