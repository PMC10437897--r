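# Independent brute-force oracles used to cross-check the package's
# implementations. These deliberately share no code with the package.

# Two-sided Fisher p by full enumeration of tables with the observed margins
# (point-probability convention).
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b
  c1 <- a + c
  n <- a + b + c + d
  xs <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- vapply(xs, function(x) dhyper(x, c1, n - c1, r1), numeric(1))
  p_obs <- dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Exact two-sided Mann-Whitney p by enumerating every group assignment.
oracle_mann_whitney <- function(x, y) {
  m <- length(x)
  pooled <- c(x, y)
  n_tot <- length(pooled)
  u_of <- function(idx) {
    xx <- pooled[idx]
    yy <- pooled[-idx]
    sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
  }
  u_obs <- u_of(seq_len(m))
  u_all <- combn(n_tot, m, u_of)
  p_lo <- mean(u_all <= u_obs)
  p_hi <- mean(u_all >= u_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# Crawford-Howell via a generic pooled two-sample formulation with a
# singleton case group (the singleton contributes no degrees of freedom).
oracle_single_case_t <- function(x, controls) {
  n <- length(controls)
  sp <- sqrt(sum((controls - mean(controls))^2) / (n - 1))
  t <- (x - mean(controls)) / (sp * sqrt(1 / n + 1))
  list(t = t, df = n - 1, p = 2 * stats::pt(-abs(t), n - 1))
}

# Region rule by direct scan: direction-consistent, enough significant
# probes, and a long-enough same-direction run of adjacent significant
# probes.
oracle_region_aberrant <- function(passes, directions, min_sig, min_consec) {
  n_sig <- sum(passes)
  dirs <- unique(directions[passes])
  if (n_sig < min_sig || length(dirs) != 1) {
    return(FALSE)
  }
  best <- 0
  run <- 0
  for (i in seq_along(passes)) {
    if (passes[i] && (run == 0 || directions[i] == last_dir)) {
      run <- run + 1
      last_dir <- directions[i]
    } else if (passes[i]) {
      run <- 1
      last_dir <- directions[i]
    } else {
      run <- 0
    }
    best <- max(best, run)
  }
  best >= min_consec
}

# Interval membership by scanning every probe x region pair.
oracle_probe_membership <- function(manifest, catalog) {
  hits <- list()
  for (i in seq_len(nrow(manifest))) {
    for (j in seq_len(nrow(catalog))) {
      same_chr <- sub("^chr", "", manifest$chrom[i]) ==
        sub("^chr", "", catalog$chrom[j])
      if (same_chr && manifest$pos[i] >= catalog$start[j] &&
        manifest$pos[i] <= catalog$end[j]) {
        hits[[length(hits) + 1]] <- data.frame(
          region = catalog$name[j], probe_id = manifest$probe_id[i]
        )
      }
    }
  }
  if (length(hits)) do.call(rbind, hits) else data.frame(
    region = character(), probe_id = character()
  )
}
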