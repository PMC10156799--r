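#' Annualized change of a metric
#'
#' `(followup - baseline) / followup_years`: longitudinal changes are
#' normalised to the follow-up interval so subjects with different intervals
#' are comparable.
#'
#' @param baseline,followup metric values (vectorised).
#' @param followup_years follow-up interval in years (> 0).
#' @return per-year change.
#' @export
annualized_delta <- function(baseline, followup, followup_years) {
  stopifnot(all(followup_years > 0))
  if (any(is.na(baseline)) || any(is.na(followup)))
    stop("metric missing at one timepoint")
  (followup - baseline) / followup_years
}

stat_result <- function(statistic, p_value, effect, n, method,
                        achieved_power = NA_real_) {
  stopifnot(is.na(p_value) || (p_value >= 0 && p_value <= 1))
  structure(list(statistic = unname(statistic), p_value = unname(p_value),
                 effect = effect, n = n, method = method,
                 achieved_power = achieved_power),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("%s: stat = %.4g, p = %.4g (n = %s)\n", x$method,
              x$statistic, x$p_value, paste(x$n, collapse = "/")))
  invisible(x)
}

#' Two-group comparison (Wilcoxon rank-sum)
#'
#' Two-sided rank-sum test; the null distribution is exact (enumeration)
#' when both groups have at most 10 observations and there are no ties,
#' otherwise the normal approximation with tie correction is used. Cohort
#' sizes here are small enough that exactness matters.
#'
#' @param values_a,values_b numeric vectors, each of length >= 2.
#' @return a `stat_result`; `effect` is the difference of group medians.
#' @export
group_compare <- function(values_a, values_b) {
  stopifnot(length(values_a) >= 2, length(values_b) >= 2)
  if (length(unique(c(values_a, values_b))) == 1L)
    warning("all observations tied; comparison degenerate")
  exact <- length(values_a) <= 10 && length(values_b) <= 10
  ht <- suppressWarnings(wilcox.test(values_a, values_b, exact = exact,
                                     correct = TRUE))
  stat_result(ht$statistic, ht$p.value,
              effect = c(median_diff = median(values_a) - median(values_b)),
              n = c(length(values_a), length(values_b)),
              method = "Wilcoxon rank-sum")
}

#' Paired change test (Wilcoxon signed-rank)
#'
#' Two-sided signed-rank test of the deltas against zero; zeros are dropped
#' first, and the exact null distribution is used for up to 15 nonzero
#' deltas (no ties).
#'
#' @param deltas numeric vector of paired changes.
#' @return a `stat_result`; `effect` is the median delta.
#' @export
paired_change_test <- function(deltas) {
  nz <- deltas[deltas != 0]
  if (!length(nz)) stop("all deltas are zero")
  if (length(deltas) < 2) stop("need at least 2 deltas")
  exact <- length(nz) <= 15
  ht <- suppressWarnings(wilcox.test(nz, exact = exact, correct = TRUE))
  stat_result(ht$statistic, ht$p.value,
              effect = c(median_delta = median(deltas)),
              n = length(nz), method = "Wilcoxon signed-rank")
}

# Spearman rho with average ranks on ties
spearman_rho <- function(x, y) {
  cor(rank(x, ties.method = "average"), rank(y, ties.method = "average"))
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Rank correlation with permutation p-value
#'
#' Spearman's rho (average ranks on ties) with a two-sided permutation
#' p-value: exact over all `n!` permutations for `n <= 8`, otherwise a
#' seeded Monte-Carlo sample of permutations.
#'
#' @param x,y numeric vectors, length >= 3.
#' @param n_perm Monte-Carlo permutations when `n > 8` (default 1e5).
#' @param seed seed for the Monte-Carlo sample.
#' @return a `stat_result`; `effect` is rho.
#' @export
rank_correlation <- function(x, y, n_perm = 1e5, seed = 1L) {
  n <- length(x)
  stopifnot(n >= 3, length(y) == n)
  if (sd(x) == 0 || sd(y) == 0) stop("constant input")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  rho <- cor(rx, ry)
  tol <- 1e-12
  if (n <= 8) {
    perms <- all_permutations(n)
    rhos <- as.vector(cor(rx, t(matrix(ry[perms], nrow(perms), n))))
    p <- mean(abs(rhos) >= abs(rho) - tol)
  } else {
    p <- with_private_seed(seed, function() {
      hits <- 0L
      block <- 1e4L
      done <- 0L
      while (done < n_perm) {
        b <- min(block, n_perm - done)
        pm <- replicate(b, sample.int(n))
        rhos <- as.vector(cor(rx, matrix(ry[pm], n, b)))
        hits <- hits + sum(abs(rhos) >= abs(rho) - tol)
        done <- done + b
      }
      (1 + hits) / (n_perm + 1)
    })
  }
  stat_result(rho, p, effect = c(rho = rho), n = n,
              method = "Spearman rank correlation (permutation)")
}

#' Ordinary least-squares fit
#'
#' Simple linear regression `y ~ x`: slope, intercept, R-squared and the
#' two-sided p-value of the slope.
#'
#' @param x,y numeric vectors, length >= 3.
#' @return a `stat_result`; `effect` carries `slope`, `intercept` and
#'   `r_squared`.
#' @export
linear_fit <- function(x, y) {
  n <- length(x)
  stopifnot(n >= 3, length(y) == n)
  if (sd(x) == 0) stop("zero variance in x")
  fit <- lm(y ~ x)
  sm <- suppressWarnings(summary(fit))   # exact fits trip a precision warning
  stat_result(statistic = sm$coefficients["x", "t value"],
              p_value = sm$coefficients["x", "Pr(>|t|)"],
              effect = c(slope = unname(coef(fit)[2]),
                         intercept = unname(coef(fit)[1]),
                         r_squared = sm$r.squared),
              n = n, method = "ordinary least squares")
}

#' Monte-Carlo post-hoc power
#'
#' Simulates the observed effect under a normal model with plug-in moments
#' and reports the fraction of simulated datasets in which the matching
#' test rejects at `alpha`. Supported designs: `"ranksum"` (two groups with
#' means/SDs `mean_a`, `sd_a`, `mean_b`, `sd_b` and sizes `n_a`, `n_b`),
#' `"signrank"` (one sample, `mean_d`, `sd_d`, `n`), and `"spearman"`
#' (bivariate normal with correlation `rho`, `n`).
#'
#' @param design one of `"ranksum"`, `"signrank"`, `"spearman"`.
#' @param params named list of moments and sample sizes (see above).
#' @param alpha test level (default 0.05).
#' @param n_sims number of simulations (>= 1000).
#' @param seed RNG seed.
#' @return achieved power in `[0, 1]`.
#' @export
posthoc_power <- function(design = c("ranksum", "signrank", "spearman"),
                          params, alpha = 0.05, n_sims = 2000L, seed = 1L) {
  design <- match.arg(design)
  stopifnot(n_sims >= 1000)
  with_private_seed(seed, function() {
    rej <- logical(n_sims)
    for (i in seq_len(n_sims)) {
      p <- switch(design,
        ranksum = {
          a <- rnorm(params$n_a, params$mean_a, params$sd_a)
          b <- rnorm(params$n_b, params$mean_b, params$sd_b)
          suppressWarnings(wilcox.test(a, b, exact = TRUE)$p.value)
        },
        signrank = {
          d <- rnorm(params$n, params$mean_d, params$sd_d)
          suppressWarnings(wilcox.test(d, exact = TRUE)$p.value)
        },
        spearman = {
          x <- rnorm(params$n)
          y <- params$rho * x + sqrt(1 - params$rho^2) * rnorm(params$n)
          suppressWarnings(cor.test(x, y, method = "spearman")$p.value)
        })
      rej[i] <- p < alpha
    }
    mean(rej)
  })
}

#' Simulate a longitudinal Fontan cohort metric table
#'
#' Generates the long-format table the statistics stage consumes: per
#' subject and region, baseline and follow-up values of the five regional
#' metrics, a follow-up interval, and a baseline IVC flow-distribution
#' fraction. Metric scales are loosely matched to a Fontan TCPC at rest
#' (peak velocities a few tens of cm/s, stasis tens of percent); annual
#' drifts default to zero so the simulated cohort is stable, mirroring a
#' clinically stable population.
#'
#' @param n_subjects number of subjects (default 10).
#' @param followup_years_mean,followup_years_sd follow-up interval moments
#'   (defaults 4.4 and 2.6 years, floored at 0.6).
#' @param annual_drift named numeric: mean per-year change per metric
#'   (default all zero).
#' @param noise_cv coefficient of variation of measurement noise.
#' @param seed RNG seed.
#' @return data.frame in long format: `subject`, `region`, `metric`,
#'   `baseline`, `followup`, `followup_years`, `fd_ivc_baseline`.
#' @export
simulate_cohort <- function(n_subjects = 10L,
                            followup_years_mean = 4.4,
                            followup_years_sd = 2.6,
                            annual_drift = NULL,
                            noise_cv = 0.08,
                            seed = 1L) {
  metrics <- c(peak_velocity_p98 = 0.6, stasis_mean = 30,
               ke_mean = 5e-5, el_tot_mean = 2e-6, el_mean_mean = 2e-6)
  drift <- stats::setNames(rep(0, length(metrics)), names(metrics))
  if (!is.null(annual_drift)) drift[names(annual_drift)] <- annual_drift
  regs <- names(region_names())
  with_private_seed(seed, function() {
    rows <- list()
    for (s in seq_len(n_subjects)) {
      fy <- max(0.6, rnorm(1, followup_years_mean, followup_years_sd))
      fd <- min(0.95, max(0.05, rnorm(1, 0.5, 0.18)))
      for (rg in regs) {
        for (m in names(metrics)) {
          base_true <- metrics[[m]] * exp(rnorm(1, 0, 0.35))
          fup_true <- base_true + drift[[m]] * metrics[[m]] * fy
          rows[[length(rows) + 1L]] <- data.frame(
            subject = sprintf("S%02d", s), region = rg, metric = m,
            baseline = base_true * (1 + rnorm(1, 0, noise_cv)),
            followup = fup_true * (1 + rnorm(1, 0, noise_cv)),
            followup_years = fy, fd_ivc_baseline = fd)
        }
      }
    }
    do.call(rbind, rows)
  })
}

#' Longitudinal analysis of a cohort metric table
#'
#' Runs the statistics stage over a long-format cohort table: annualized
#' deltas per subject/region/metric, signed-rank stability tests of each
#' regional metric, rank-sum comparisons of annualized deltas between
#' subjects with equal vs unequal baseline IVC flow distribution, and the
#' Spearman + linear-regression association between annualized changes in
#' energy loss and peak velocity in the connection region. No
#' multiple-testing correction is applied; the number of tests run is
#' reported alongside.
#'
#' @param cohort data.frame as produced by [simulate_cohort()].
#' @param region region for the association analysis (default
#'   `"connection"`).
#' @param seed seed for permutation p-values.
#' @return list: `deltas` (data.frame), `stability` (signed-rank results
#'   per region/metric), `group_comparison` (rank-sum results per metric),
#'   `association` (Spearman + OLS of d(EL)/dt on d(peak velocity)/dt),
#'   `n_tests`.
#' @export
analyze_cohort <- function(cohort, region = "connection", seed = 1L) {
  need <- c("subject", "region", "metric", "baseline", "followup",
            "followup_years", "fd_ivc_baseline")
  stopifnot(all(need %in% names(cohort)))
  cohort$delta <- annualized_delta(cohort$baseline, cohort$followup,
                                   cohort$followup_years)
  n_tests <- 0L
  stability <- list()
  for (rg in unique(cohort$region)) for (m in unique(cohort$metric)) {
    d <- cohort$delta[cohort$region == rg & cohort$metric == m]
    if (length(d) >= 2 && any(d != 0)) {
      stability[[paste(rg, m, sep = ".")]] <- paired_change_test(d)
      n_tests <- n_tests + 1L
    }
  }
  subj <- unique(cohort[, c("subject", "fd_ivc_baseline")])
  unequal <- subj$subject[subj$fd_ivc_baseline < 0.30 |
                            subj$fd_ivc_baseline > 0.70]
  group_comparison <- list()
  if (length(unequal) >= 2 && nrow(subj) - length(unequal) >= 2) {
    for (m in unique(cohort$metric)) {
      d <- cohort[cohort$region == region & cohort$metric == m, ]
      a <- d$delta[d$subject %in% unequal]
      b <- d$delta[!d$subject %in% unequal]
      group_comparison[[m]] <- group_compare(a, b)
      n_tests <- n_tests + 1L
    }
  }
  el <- cohort[cohort$region == region & cohort$metric == "el_tot_mean", ]
  pv <- cohort[cohort$region == region &
                 cohort$metric == "peak_velocity_p98", ]
  ord <- match(el$subject, pv$subject)
  association <- NULL
  if (nrow(el) >= 3 && all(!is.na(ord))) {
    association <- list(
      spearman = rank_correlation(pv$delta[ord], el$delta, seed = seed),
      ols = linear_fit(pv$delta[ord], el$delta))
    n_tests <- n_tests + 2L
  }
  list(deltas = cohort, stability = stability,
       group_comparison = group_comparison, association = association,
       n_tests = n_tests)
}
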