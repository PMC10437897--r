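#' Fit a three-state beta mixture to methylation values
#'
#' Models a vector of beta values as a mixture of three beta distributions
#' corresponding to the unmethylated (U), hemimethylated (H) and methylated
#' (M) states, fitted by expectation-maximization. Initialization is
#' deterministic: probes are cut at the empirical terciles and each
#' component's shape parameters are moment-matched to its slice, so repeated
#' fits on the same data are identical. The M-step maximizes each
#' component's weighted beta log-likelihood numerically (L-BFGS-B on
#' log-shape parameters, warm-started), so the observed-data log-likelihood
#' is non-decreasing across iterations. Components are relabeled at the end
#' so their means are increasing (U < H < M), and each value is assigned to
#' the state with the highest posterior probability, ties broken toward H.
#'
#' @param x Numeric vector of beta values; values are clipped into
#'   `[eps, 1 - eps]` before fitting (the beta density is undefined at 0/1).
#' @param k Number of components; only 3 is supported.
#' @param max_iter Maximum EM iterations.
#' @param tol Convergence tolerance on the log-likelihood increment.
#' @param eps Clipping constant.
#' @return An object of class `beta_mixture_fit`: shapes, weights, component
#'   means, per-value state assignments and posteriors, the log-likelihood
#'   trace, `converged` flag and iteration count.
#' @examples
#' set.seed(1)
#' x <- c(rbeta(200, 2, 18), rbeta(100, 10, 10), rbeta(200, 18, 2))
#' fit <- fit_beta_mixture(x)
#' tidy(fit)
#' @export
fit_beta_mixture <- function(x, k = 3, max_iter = 500, tol = 1e-6,
                             eps = 1e-6) {
  if (k != 3) abort("Only the three-state (U/H/M) mixture is supported.")
  x <- x[!is.na(x)]
  if (length(x) < 30) {
    abort("Need at least 30 non-missing values to fit the mixture.")
  }
  x <- pmin(pmax(x, eps), 1 - eps)
  n <- length(x)

  # deterministic tercile initialization
  cuts <- quantile(x, c(1 / 3, 2 / 3))
  grp <- findInterval(x, cuts, rightmost.closed = FALSE) + 1L
  shape1 <- shape2 <- weights <- numeric(k)
  for (j in seq_len(k)) {
    xs <- x[grp == j]
    m <- mean(xs)
    v <- var(xs)
    if (!is.finite(v) || v < 1e-10) {
      abort("Degenerate mixture component: a tercile slice has ~zero variance.")
    }
    nu <- max(m * (1 - m) / v - 1, 1e-3)
    shape1[j] <- m * nu
    shape2[j] <- (1 - m) * nu
    weights[j] <- length(xs) / n
  }

  # The weighted beta log-likelihood depends on the data only through the
  # sufficient statistics S1 = sum(w log x), S2 = sum(w log(1 - x)) and
  # W = sum(w), so each M-step maximization is O(1) in the number of values:
  #   l(a, b) = (a - 1) S1 + (b - 1) S2 - W log B(a, b)
  log_x <- log(x)
  log_1mx <- log1p(-x)
  comp_nll <- function(par, s1, s2, w_tot) {
    a <- exp(par[1])
    b <- exp(par[2])
    -((a - 1) * s1 + (b - 1) * s2 - w_tot * lbeta(a, b))
  }
  comp_grad <- function(par, s1, s2, w_tot) {
    a <- exp(par[1])
    b <- exp(par[2])
    dga <- digamma(a + b)
    c(
      -a * (s1 - w_tot * (digamma(a) - dga)),
      -b * (s2 - w_tot * (digamma(b) - dga))
    )
  }

  loglik <- numeric(0)
  converged <- FALSE
  iter <- 0L
  resp <- matrix(0, n, k)
  repeat {
    iter <- iter + 1L
    dens <- vapply(
      seq_len(k),
      function(j) weights[j] * dbeta(x, shape1[j], shape2[j]),
      numeric(n)
    )
    tot <- rowSums(dens)
    tot[tot < 1e-300] <- 1e-300
    ll <- sum(log(tot))
    loglik <- c(loglik, ll)
    if (iter > 1 && abs(ll - loglik[iter - 1]) < tol) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    resp <- dens / tot
    weights <- colMeans(resp)
    if (any(weights < 1e-4)) {
      abort("Degenerate mixture component: weight collapsed below 1e-4.")
    }
    for (j in seq_len(k)) {
      opt <- optim(c(log(shape1[j]), log(shape2[j])),
        comp_nll,
        gr = comp_grad,
        s1 = sum(resp[, j] * log_x),
        s2 = sum(resp[, j] * log_1mx),
        w_tot = sum(resp[, j]),
        method = "L-BFGS-B",
        lower = log(1e-3), upper = log(1e6)
      )
      shape1[j] <- exp(opt$par[1])
      shape2[j] <- exp(opt$par[2])
    }
  }

  means <- shape1 / (shape1 + shape2)
  ord <- order(means)
  shape1 <- shape1[ord]
  shape2 <- shape2[ord]
  weights <- weights[ord]
  means <- means[ord]
  dens <- vapply(
    seq_len(k),
    function(j) weights[j] * dbeta(x, shape1[j], shape2[j]),
    numeric(n)
  )
  post <- dens / pmax(rowSums(dens), 1e-300)
  colnames(post) <- c("U", "H", "M")
  # argmax posterior; exact ties resolved toward the hemimethylated state
  pick <- max.col(post[, c("H", "U", "M"), drop = FALSE], ties.method = "first")
  states <- c("H", "U", "M")[pick]

  structure(
    list(
      shape1 = setNames(shape1, c("U", "H", "M")),
      shape2 = setNames(shape2, c("U", "H", "M")),
      weights = setNames(weights, c("U", "H", "M")),
      means = setNames(means, c("U", "H", "M")),
      states = states,
      posterior = post,
      loglik = loglik,
      converged = converged,
      iterations = iter,
      n = n
    ),
    class = "beta_mixture_fit"
  )
}

#' @export
print.beta_mixture_fit <- function(x, ...) {
  cat(sprintf(
    "<beta_mixture_fit> n = %d, %d iterations (%s)\n", x$n, x$iterations,
    if (x$converged) "converged" else "not converged"
  ))
  print(round(rbind(mean = x$means, weight = x$weights), 3))
  invisible(x)
}

#' @export
tidy.beta_mixture_fit <- function(x, ...) {
  tibble::tibble(
    state = c("U", "H", "M"),
    shape1 = unname(x$shape1),
    shape2 = unname(x$shape2),
    mean = unname(x$means),
    weight = unname(x$weights),
    n_assigned = as.integer(table(factor(x$states, c("U", "H", "M"))))
  )
}

#' @export
glance.beta_mixture_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    logLik = tail(x$loglik, 1),
    iterations = x$iterations,
    converged = x$converged
  )
}

#' @export
autoplot.beta_mixture_fit <- function(object, ...) {
  grid <- seq(0.001, 0.999, length.out = 400)
  comp <- purrr::map_dfr(c("U", "H", "M"), function(s) {
    tibble::tibble(
      state = s, beta = grid,
      density = object$weights[s] *
        dbeta(grid, object$shape1[s], object$shape2[s])
    )
  })
  ggplot2::ggplot(comp, ggplot2::aes(.data$beta, .data$density,
    colour = .data$state
  )) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = expression(beta), y = "mixture density",
      colour = "state"
    ) +
    ggplot2::theme_minimal()
}

#' Beta-mixture quantile (BMIQ) normalization of one sample
#'
#' Corrects the distributional bias of Infinium type II probes against type I
#' probes within a single sample. Three-state beta mixtures are fitted
#' separately to the type I and type II values; each type II probe is
#' assigned to its maximum-posterior state and then
#'
#' * U-state values are quantile-mapped onto the type I U component,
#'   `b' = F_U1^-1(F_U2(b))`;
#' * M-state values are quantile-mapped onto the type I M component;
#' * H-state values are carried by an affine dilation that places them
#'   between the images of the U/M boundaries, preserving the empirical gaps
#'   between the states.
#'
#' Type I values are returned bit-identical; the transform is monotone
#' within each state and all outputs lie in \[0, 1\]. Normalization is
#' strictly per-sample: no information is shared across samples.
#'
#' @param betas Numeric vector of beta values for one sample (`NA` passed
#'   through untouched).
#' @param design_types Character vector (`"I"`/`"II"`) aligned with `betas`.
#' @param max_iter,tol,eps Passed to [fit_beta_mixture()].
#' @return Numeric vector of normalized beta values, same length and order;
#'   attributes `fit_type1` and `fit_type2` carry the two mixture fits.
#' @export
bmiq_normalize_sample <- function(betas, design_types, max_iter = 500,
                                  tol = 1e-6, eps = 1e-6) {
  stopifnot(length(betas) == length(design_types))
  if (!all(design_types %in% c("I", "II"))) {
    abort("`design_types` must be 'I' or 'II'.")
  }
  is2 <- design_types == "II"
  if (!any(is2)) {
    return(betas)
  }
  ok1 <- !is.na(betas) & !is2
  ok2 <- !is.na(betas) & is2
  if (sum(ok1) < 30 || sum(ok2) < 30) {
    abort("Need at least 30 non-missing probes of each design type.")
  }
  fit1 <- fit_beta_mixture(betas[ok1], max_iter = max_iter, tol = tol, eps = eps)
  fit2 <- fit_beta_mixture(betas[ok2], max_iter = max_iter, tol = tol, eps = eps)

  x2 <- pmin(pmax(betas[ok2], eps), 1 - eps)
  st <- fit2$states
  out2 <- x2

  map_state <- function(v, s) {
    qbeta(
      pbeta(v, fit2$shape1[s], fit2$shape2[s]),
      fit1$shape1[s], fit1$shape2[s]
    )
  }
  if (any(st == "U")) out2[st == "U"] <- map_state(x2[st == "U"], "U")
  if (any(st == "M")) out2[st == "M"] <- map_state(x2[st == "M"], "M")

  if (any(st == "H")) {
    if (!any(st == "U") || !any(st == "M")) {
      abort("Degenerate state assignment: missing U or M state among type II probes.")
    }
    max_u <- max(x2[st == "U"])
    min_m <- min(x2[st == "M"])
    max_u_n <- max(out2[st == "U"])
    min_m_n <- min(out2[st == "M"])
    h <- x2[st == "H"]
    min_h <- min(h)
    max_h <- max(h)
    gap_lo <- min_h - max_u
    gap_hi <- min_m - max_h
    lo <- max_u_n + gap_lo
    hi <- min_m_n - gap_hi
    hf <- if (max_h > min_h) (hi - lo) / (max_h - min_h) else 1
    if (!is.finite(hf) || hf <= 0) hf <- 1
    out2[st == "H"] <- lo + (h - min_h) * hf
  }

  out <- betas
  out[ok2] <- pmin(pmax(out2, 0), 1)
  attr(out, "fit_type1") <- fit1
  attr(out, "fit_type2") <- fit2
  out
}

#' BMIQ-normalize every sample of a beta matrix
#'
#' Applies [bmiq_normalize_sample()] column by column using the manifest's
#' design types. A per-sample audit of the two mixture fits is attached as
#' the `"bmiq_audit"` attribute (retrieve with [bmiq_audit()]).
#'
#' @param beta A [beta_matrix()].
#' @param manifest Probe manifest covering all probes in `beta`.
#' @inheritParams bmiq_normalize_sample
#' @return A [beta_matrix()] with type II probes normalized per sample.
#' @export
bmiq_normalize <- function(beta, manifest, max_iter = 500, tol = 1e-6,
                           eps = 1e-6) {
  stopifnot(inherits(beta, "beta_matrix"))
  probes <- rownames(beta$values)
  missing <- setdiff(probes, manifest$probe_id)
  if (length(missing)) {
    abort(sprintf("%d probe(s) missing from the manifest.", length(missing)))
  }
  design <- manifest$design_type[match(probes, manifest$probe_id)]
  values <- beta$values
  audit <- list()
  for (s in colnames(values)) {
    norm <- bmiq_normalize_sample(values[, s], design,
      max_iter = max_iter, tol = tol, eps = eps
    )
    f1 <- attr(norm, "fit_type1")
    f2 <- attr(norm, "fit_type2")
    audit[[s]] <- tibble::tibble(
      sample_id = s,
      design_type = c("I", "II"),
      converged = c(f1$converged, f2$converged),
      iterations = c(f1$iterations, f2$iterations),
      logLik = c(tail(f1$loglik, 1), tail(f2$loglik, 1)),
      mean_U = c(f1$means["U"], f2$means["U"]),
      mean_H = c(f1$means["H"], f2$means["H"]),
      mean_M = c(f1$means["M"], f2$means["M"])
    )
    values[, s] <- as.numeric(norm)
  }
  out <- beta_matrix(values, beta$roles, detection_p = beta$detection_p)
  attr(out, "bmiq_audit") <- dplyr::bind_rows(audit)
  out
}

#' @rdname bmiq_normalize
#' @param x A matrix returned by [bmiq_normalize()].
#' @export
bmiq_audit <- function(x) attr(x, "bmiq_audit")
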