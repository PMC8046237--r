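# ---- cohort parameters -----------------------------------------------------

default_epic_marginals <- function() {
  list(
    urinary = c(mean = 87.5, sd = 12.1),
    bowel = c(mean = 93.4, sd = 9.3),
    sexual = c(mean = 49.6, sd = 26.3),
    hormonal = c(mean = 91.0, sd = 11.0),
    uf = c(mean = 93.3, sd = 10.7),
    ub = c(mean = 84.0, sd = 14.8),
    uirr = c(mean = 86.8, sd = 12.6),
    uinc = c(mean = 91.6, sd = 14.0),
    bf = c(mean = 93.2, sd = 8.5),
    bb = c(mean = 94.6, sd = 9.6),
    sf = c(mean = 43.7, sd = 26.9),
    sb = c(mean = 64.0, sd = 32.9),
    hf = c(mean = 88.7, sd = 13.6),
    hb = c(mean = 93.0, sd = 10.3)
  )
}

default_utility_correlations <- function() {
  c(
    urinary = 0.38, bowel = 0.34, sexual = 0.18, hormonal = 0.55,
    uf = 0.31, ub = 0.36, uirr = 0.36, uinc = 0.27,
    bf = 0.30, bb = 0.32, sf = 0.17, sb = 0.16, hf = 0.43, hb = 0.53
  )
}

#' Calibration parameters of the synthetic cohort generator
#'
#' Defaults emulate a low-risk prostate-cancer trial cohort at baseline: a
#' ceiling-inflated, bimodal EQ-5D utility distribution (55% at full health;
#' continuous component a scaled Beta on \[0.28, 1) with mode near 0.8 whose
#' mixture has mean 0.90 and SD 0.13), EPIC domain and sub-domain scores with
#' the trial's published means/SDs truncated to \[0, 100\], utility-score
#' Pearson correlations at the published values, and demographics (age
#' 66.4 +/- 7.3 years, 17.5% non-White, 6.2% Zubrod 1, 79.7% PSA >= 4).
#'
#' @param n Default cohort size (the trial's domain-complete estimation
#'   cohort, 565).
#' @param p_ceiling Probability of utility exactly 1.
#' @param utility_lower Lower bound of the continuous utility component.
#' @param utility_shape1,utility_shape2 Beta shape parameters of the
#'   continuous component on the \[utility_lower, 1) interval.
#' @param epic_marginals Named list (by score signature) of `c(mean, sd)`
#'   targets on the observed, truncated-to-\[0,100\] scale.
#' @param utility_correlations Named numeric vector of observed-scale Pearson
#'   targets between utility and each score.
#' @param score_latent_correlation Latent (copula-scale) correlation between
#'   any two scores. Pairwise score-score correlations are not published for
#'   this population; 0.4 is a placeholder assumption, user-overridable.
#' @param age_mean,age_sd,race_other_rate,zubrod_rate,psa_ge4_rate
#'   Demographic calibration; demographics are drawn independently of scores.
#' @return An object of class `cohort_params`.
#' @export
cohort_params <- function(n = 565L,
                          p_ceiling = 0.55,
                          utility_lower = 0.28,
                          utility_shape1 = 6.66,
                          utility_shape2 = 2.97,
                          epic_marginals = default_epic_marginals(),
                          utility_correlations = default_utility_correlations(),
                          score_latent_correlation = 0.4,
                          age_mean = 66.4, age_sd = 7.3,
                          race_other_rate = 0.175,
                          zubrod_rate = 0.062,
                          psa_ge4_rate = 0.797) {
  stopifnot(p_ceiling >= 0, p_ceiling <= 1,
            utility_lower >= 0, utility_lower < 1,
            utility_shape1 > 0, utility_shape2 > 0,
            age_sd > 0,
            abs(score_latent_correlation) < 1)
  unknown <- setdiff(names(epic_marginals), names(score_signatures))
  if (length(unknown)) {
    stop(sprintf("unknown score(s) in epic_marginals: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  for (nm in names(epic_marginals)) {
    m <- epic_marginals[[nm]]
    if (is.na(m["mean"]) || is.na(m["sd"]) || m["sd"] <= 0) {
      stop(sprintf("marginal for '%s' needs a mean and a positive sd", nm), call. = FALSE)
    }
  }
  missing_corr <- setdiff(names(epic_marginals), names(utility_correlations))
  if (length(missing_corr)) {
    stop(sprintf("utility_correlations lacks targets for: %s",
                 paste(missing_corr, collapse = ", ")), call. = FALSE)
  }
  for (r in c(race_other_rate, zubrod_rate, psa_ge4_rate)) {
    stopifnot(r >= 0, r <= 1)
  }
  structure(
    list(n = as.integer(n), p_ceiling = p_ceiling,
         utility_lower = utility_lower,
         utility_shape1 = utility_shape1, utility_shape2 = utility_shape2,
         epic_marginals = epic_marginals,
         utility_correlations = utility_correlations[names(epic_marginals)],
         score_latent_correlation = score_latent_correlation,
         age_mean = age_mean, age_sd = age_sd,
         race_other_rate = race_other_rate, zubrod_rate = zubrod_rate,
         psa_ge4_rate = psa_ge4_rate),
    class = "cohort_params"
  )
}

# ---- marginal quantile maps ------------------------------------------------

# Quantile function of the mixture utility margin: a point mass at 1 with
# weight p_ceiling occupying the upper tail, otherwise a Beta rescaled to
# [lower, 1). High latent quantiles therefore map to full health.
utility_quantile <- function(p, params) {
  w <- 1 - params$p_ceiling
  out <- rep(1, length(p))
  cont <- p < w
  if (any(cont)) {
    q <- stats::qbeta(p[cont] / w, params$utility_shape1, params$utility_shape2)
    out[cont] <- params$utility_lower + (1 - params$utility_lower) * q
  }
  out
}

# Moment-matched scaled Beta on [0, 100]. The Beta family reaches every
# feasible (mean, sd) pair on a bounded interval — unlike a truncated normal,
# whose sd at a mean of ~93 tops out near 7 — and for high-mean, high-sd
# scores it naturally produces the left-skewed shape with a pile-up at 100
# that bounded instrument scores show.
solve_beta_parent <- function(target_mean, target_sd, hi = 100) {
  m <- target_mean / hi
  v <- (target_sd / hi)^2
  if (v >= m * (1 - m)) {
    stop(sprintf(
      "marginal (mean %.1f, sd %.1f) is infeasible on [0, %g]: sd^2 must be below mean*(%g - mean)",
      target_mean, target_sd, hi, hi), call. = FALSE)
  }
  nu <- m * (1 - m) / v - 1
  c(shape1 = m * nu, shape2 = (1 - m) * nu)
}

score_quantile <- function(p, shape1, shape2, hi = 100) {
  hi * stats::qbeta(p, shape1, shape2)
}

# ---- latent correlation calibration ---------------------------------------

# The Pearson targets are stated on the observed scale; the copula's latent
# correlations must be inflated to survive the margin transforms (notably the
# 55% ceiling mass). Calibration inverts corr_obs(rho_latent) by bisection on
# a fixed common-random-numbers sample, so the inner function is smooth and
# monotone in rho.
.calibration_cache <- new.env(parent = emptyenv())

calibrate_generator <- function(params, m = 16384L, calib_seed = 20070423L) {
  key <- paste(
    format(c(params$p_ceiling, params$utility_lower, params$utility_shape1,
             params$utility_shape2, unlist(params$epic_marginals),
             params$utility_correlations, params$score_latent_correlation),
           digits = 15),
    collapse = "|"
  )
  hit <- .calibration_cache[[key]]
  if (!is.null(hit)) return(hit)

  scores <- names(params$epic_marginals)
  parents <- lapply(params$epic_marginals, function(mrg) {
    solve_beta_parent(mrg[["mean"]], mrg[["sd"]])
  })
  crn <- with_seed(calib_seed, list(z = stats::rnorm(m), e = stats::rnorm(m)))
  u_obs <- utility_quantile(stats::pnorm(crn$z), params)
  latent <- numeric(length(scores)); names(latent) <- scores
  for (s in scores) {
    par_s <- parents[[s]]
    obs_corr <- function(rho) {
      z2 <- rho * crn$z + sqrt(1 - rho^2) * crn$e
      x <- score_quantile(stats::pnorm(z2), par_s[["shape1"]], par_s[["shape2"]])
      stats::cor(u_obs, x)
    }
    target <- params$utility_correlations[[s]]
    lo <- -0.9999; hi <- 0.9999
    if (obs_corr(hi) < target || obs_corr(lo) > target) {
      stop(sprintf(
        "correlation target %.2f for '%s' is infeasible under these margins (attainable range is about [%.2f, %.2f])",
        target, s, obs_corr(lo), obs_corr(hi)), call. = FALSE)
    }
    for (i in 1:20) {
      mid <- (lo + hi) / 2
      if (obs_corr(mid) < target) lo <- mid else hi <- mid
    }
    latent[s] <- (lo + hi) / 2
  }

  d <- length(scores) + 1L
  R <- matrix(params$score_latent_correlation, d, d)
  diag(R) <- 1
  R[1, -1] <- latent
  R[-1, 1] <- latent
  dimnames(R) <- list(c("utility", scores), c("utility", scores))
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-8) {
    R_pd <- as.matrix(Matrix::nearPD(R, corr = TRUE)$mat)
    drift <- max(abs(R_pd[1, -1] - latent))
    if (drift > 0.025) {
      stop(paste0(
        "correlation targets are jointly infeasible; nearest feasible utility-score latent correlations:\n",
        paste(sprintf("  %s: %.3f", scores, R_pd[1, -1]), collapse = "\n")
      ), call. = FALSE)
    }
    R <- R_pd
  }
  calib <- list(scores = scores, parents = parents, latent = latent,
                R = R, chol_R = chol(R))
  .calibration_cache[[key]] <- calib
  calib
}

# ---- cohort generation -----------------------------------------------------

#' Generate a synthetic trial-like cohort
#'
#' Draws a latent multivariate normal with the calibrated correlation matrix
#' (utility plus all configured EPIC scores), then maps each margin through
#' its quantile function: the utility margin through the ceiling-inflated
#' mixture (point mass at 1 in the upper tail, scaled Beta below), each score
#' margin through a scaled Beta on \[0, 100\] moment-matched to its target
#' mean and SD. Demographics are drawn independently at the
#' configured rates. Fully reproducible by seed; the (deterministic)
#' correlation calibration is computed once per parameter set and cached.
#'
#' @param params A [cohort_params()].
#' @param n Number of records (defaults to `params$n`).
#' @param seed Integer seed.
#' @return Patient table (data frame) with columns `id`, `eq5d`,
#'   `epic_urinary`...`epic_hormonal`, `epic_uf`...`epic_hb`, `age`,
#'   `race_other`, `zubrod`, `psa_ge4`.
#' @examples
#' cohort <- generate_cohort(cohort_params(), n = 200, seed = 1)
#' mean(cohort$eq5d)
#' @export
generate_cohort <- function(params = cohort_params(), n = params$n, seed) {
  stopifnot(inherits(params, "cohort_params"), n >= 1L)
  calib <- calibrate_generator(params)
  d <- length(calib$scores) + 1L
  with_seed(seed, {
    Z <- matrix(stats::rnorm(n * d), nrow = n) %*% calib$chol_R
    P <- stats::pnorm(Z)
    out <- data.frame(id = seq_len(n))
    out$eq5d <- utility_quantile(P[, 1L], params)
    for (j in seq_along(calib$scores)) {
      s <- calib$scores[j]
      par_s <- calib$parents[[s]]
      out[[score_signatures[[s]]]] <- score_quantile(
        P[, j + 1L], par_s[["shape1"]], par_s[["shape2"]]
      )
    }
    out$age <- pmax(stats::rnorm(n, params$age_mean, params$age_sd), 18)
    out$race_other <- stats::rbinom(n, 1L, params$race_other_rate)
    out$zubrod <- stats::rbinom(n, 1L, params$zubrod_rate)
    out$psa_ge4 <- stats::rbinom(n, 1L, params$psa_ge4_rate)
    out
  })
}

# ---- linear-truth generator (parameter-recovery harness) -------------------

#' Generate data from a known linear model, optionally censored at 1
#'
#' A harness for parameter-recovery assertions: draws a design matrix, forms
#' `y* = X beta + Normal(0, sigma)` and, when `censor` is on, observes
#' `y = min(y*, 1)`. The generative truth is returned alongside the data.
#'
#' @param beta_true Named numeric vector of coefficients; the first element
#'   must be the intercept `(Intercept)`.
#' @param sigma_true Noise standard deviation (>= 0).
#' @param n Number of observations.
#' @param seed Integer seed.
#' @param censor Censor the outcome above at 1?
#' @param design `"uniform"` (regressors iid U(0,1)) or `"normal"`
#'   (iid standard normal).
#' @return List with `X` (design matrix), `y` (observed response),
#'   `y_latent`, `beta_true`, `sigma_true`, `censored_fraction`.
#' @export
generate_linear_truth <- function(beta_true, sigma_true, n, seed,
                                  censor = FALSE,
                                  design = c("uniform", "normal")) {
  design <- match.arg(design)
  stopifnot(sigma_true >= 0, n >= 1L)
  if (is.null(names(beta_true)) || names(beta_true)[1L] != "(Intercept)") {
    stop("beta_true must be named, with '(Intercept)' first", call. = FALSE)
  }
  p <- length(beta_true) - 1L
  with_seed(seed, {
    Xr <- if (p > 0L) {
      matrix(if (design == "uniform") stats::runif(n * p) else stats::rnorm(n * p),
             nrow = n)
    } else {
      matrix(numeric(0), nrow = n, ncol = 0L)
    }
    X <- cbind(1, Xr)
    colnames(X) <- names(beta_true)
    y_latent <- drop(X %*% beta_true) + stats::rnorm(n, sd = sigma_true)
    y <- if (censor) pmin(y_latent, 1) else y_latent
    list(X = X, y = y, y_latent = y_latent, beta_true = beta_true,
         sigma_true = sigma_true,
         censored_fraction = if (censor) mean(y_latent >= 1) else 0)
  })
}
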