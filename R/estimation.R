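# ---- design specifications -------------------------------------------------

#' Define a model specification (design matrix recipe)
#'
#' The model-development battery organises candidate specifications into six
#' groups by the data they require: group 1 uses the four EPIC domain scores
#' only, group 2 the ten sub-domain scores only; groups 3 and 4 add the
#' demographic covariates (age, race); groups 5 and 6 add the clinical
#' covariates (Zubrod performance status, PSA category). Within a group,
#' score and age polynomials (powers 2 and 3) and race-by-score or
#' Zubrod-by-score products give the individual specifications.
#'
#' @param group Integer 1-6.
#' @param score_powers Subset of `c(1, 2, 3)`; powers of each EPIC score to
#'   include (power 1 is always sensible and is the default).
#' @param age_powers Subset of `c(1, 2, 3)`; only allowed for groups 3-6.
#' @param interactions Subset of `c("race:score", "zubrod:score")`;
#'   `"race:score"` needs group >= 3, `"zubrod:score"` group >= 5.
#' @param label Free-text label (e.g. `"6i"`); defaults to a generated one.
#' @return An object of class `design_spec`.
#' @export
design_spec <- function(group, score_powers = 1L, age_powers = integer(0),
                        interactions = character(0), label = NULL) {
  stopifnot(length(group) == 1L, group %in% 1:6)
  group <- as.integer(group)
  score_powers <- sort(unique(as.integer(score_powers)))
  age_powers <- sort(unique(as.integer(age_powers)))
  stopifnot(all(score_powers %in% 1:3), all(age_powers %in% 1:3))
  interactions <- unique(interactions)
  stopifnot(all(interactions %in% c("race:score", "zubrod:score")))
  if (group < 3L && (length(age_powers) || length(interactions))) {
    stop("groups 1-2 admit no demographic or clinical regressors", call. = FALSE)
  }
  if (group < 5L && "zubrod:score" %in% interactions) {
    stop("zubrod:score products require group 5 or 6", call. = FALSE)
  }
  if (is.null(label)) {
    label <- sprintf("g%d_p%s%s%s", group, paste(score_powers, collapse = ""),
                     if (length(age_powers)) paste0("_a", paste(age_powers, collapse = "")) else "",
                     if (length(interactions)) paste0("_", paste(sub(":score", "x", interactions), collapse = "")) else "")
  }
  structure(
    list(group = group, score_powers = score_powers, age_powers = age_powers,
         interactions = interactions, label = label),
    class = "design_spec"
  )
}

#' Canonical regressor list of a specification
#'
#' Columns appear in a documented canonical order: score powers (all scores
#' at power 1, then power 2, then power 3), age powers, race, Zubrod,
#' race-by-score products, Zubrod-by-score products, and the PSA category
#' last. This order also fixes stepwise tie-breaking.
#'
#' @param spec A `design_spec`.
#' @return Character vector of regressor signatures (intercept excluded).
#' @export
spec_regressors <- function(spec) {
  stopifnot(inherits(spec, "design_spec"))
  scores <- if (spec$group %% 2L == 1L) {
    c("urinary", "bowel", "sexual", "hormonal")
  } else {
    c("uf", "ub", "uirr", "uinc", "bf", "bb", "sf", "sb", "hf", "hb")
  }
  sigs <- character(0)
  for (p in spec$score_powers) {
    sigs <- c(sigs, if (p == 1L) scores else paste0(scores, "^", p))
  }
  if (spec$group >= 3L) {
    for (p in spec$age_powers) {
      sigs <- c(sigs, if (p == 1L) "age" else paste0("age^", p))
    }
    sigs <- c(sigs, "race_other")
  }
  if (spec$group >= 5L) sigs <- c(sigs, "zubrod")
  if ("race:score" %in% spec$interactions) {
    sigs <- c(sigs, paste0(scores, ":race_other"))
  }
  if ("zubrod:score" %in% spec$interactions) {
    sigs <- c(sigs, paste0(scores, ":zubrod"))
  }
  if (spec$group >= 5L) sigs <- c(sigs, "psa_ge4")
  sigs
}

#' Build a design matrix and response vector from patient records
#'
#' Records that are not complete cases for the specification's group (or that
#' lack an observed utility, when one is required) are dropped and counted.
#' Polynomial columns are literal powers of the 0-100 scores or of age in
#' years; interaction columns are elementwise products.
#'
#' @param records Patient table (standard column names).
#' @param spec A `design_spec`.
#' @param require_utility Keep only records with a non-missing `eq5d` and
#'   return it as the response (default `TRUE`).
#' @return List with `X` (numeric matrix, first column `(Intercept)`),
#'   `y` (response vector or `NULL`), `rows_used` (row indices kept),
#'   `n_dropped`, and `spec`.
#' @export
build_design_matrix <- function(records, spec, require_utility = TRUE) {
  stopifnot(inherits(spec, "design_spec"))
  records <- as.data.frame(records)
  keep <- complete_cases(records, spec$group, require_utility = require_utility)
  n_dropped <- sum(!keep)
  used <- which(keep)
  if (!length(used)) {
    stop("no usable records: every record fails the complete-case rule for this group",
         call. = FALSE)
  }
  sub <- records[used, , drop = FALSE]
  sigs <- spec_regressors(spec)
  X <- cbind(`(Intercept)` = rep(1, nrow(sub)))
  for (sig in sigs) X <- cbind(X, eval_signature(sig, sub))
  colnames(X) <- c("(Intercept)", sigs)
  y <- if (require_utility) as.numeric(sub$eq5d) else NULL
  list(X = X, y = y, rows_used = used, n_dropped = n_dropped, spec = spec)
}

# ---- fit-result container --------------------------------------------------

new_fit_result <- function(form, coefficients, scale_sigma = NA_real_,
                           se = NULL, loglik = NA_real_, n_used,
                           converged = TRUE, df_residual = NA_integer_,
                           part1 = NULL, part2 = NULL, ceiling = NA_real_,
                           upper_censor = NA_real_) {
  structure(
    list(form = form, coefficients = coefficients, scale_sigma = scale_sigma,
         se = se, loglik = loglik, n_used = n_used, converged = converged,
         df_residual = df_residual, part1 = part1, part2 = part2,
         ceiling = ceiling, upper_censor = upper_censor),
    class = "fit_result"
  )
}

#' @exportS3Method base::print
print.fit_result <- function(x, ...) {
  cat(sprintf("%s fit on %d records%s\n", toupper(x$form), x$n_used,
              if (!x$converged) " (DID NOT CONVERGE)" else ""))
  if (x$form == "two_part") {
    cat("Part 1 (logistic, P[at ceiling]):\n")
    print(round(x$part1$coefficients, 6))
    cat("Part 2 (OLS below ceiling):\n")
    print(round(x$part2$coefficients, 6))
  } else {
    print(round(x$coefficients, 6))
    cat(sprintf("sigma = %.6f", x$scale_sigma))
    if (is.finite(x$loglik)) cat(sprintf(", log-likelihood = %.4f", x$loglik))
    cat("\n")
  }
  invisible(x)
}

check_design <- function(X, y) {
  if (!is.matrix(X)) X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (nrow(X) != length(y)) stop("nrow(X) must equal length(y)", call. = FALSE)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[seq(qrX$rank + 1L, ncol(X))]]
    stop(sprintf("design matrix is rank deficient; collinear column(s): %s",
                 paste(dropped, collapse = ", ")), call. = FALSE)
  }
  X
}

# ---- OLS -------------------------------------------------------------------

#' Ordinary least squares fit
#'
#' Minimises the residual sum of squares via the QR decomposition. The
#' reported `scale_sigma` is the maximum-likelihood residual scale
#' `sqrt(RSS/n)` (not the unbiased variant), so that a Tobit fit on
#' censoring-free data reduces to it exactly.
#'
#' @param X Numeric design matrix including an intercept column.
#' @param y Numeric response vector.
#' @return A `fit_result` with coefficients, standard errors, the normal
#'   log-likelihood, and residual degrees of freedom.
#' @export
fit_ols <- function(X, y) {
  X <- check_design(X, y)
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop("need more rows than columns for OLS", call. = FALSE)
  fit <- lm.fit(X, y)
  beta <- fit$coefficients
  res <- y - drop(X %*% beta)
  rss <- sum(res^2)
  sigma_mle <- sqrt(rss / n)
  s2_unbiased <- rss / (n - p)
  XtX_inv <- chol2inv(qr.R(qr(X)))
  se <- sqrt(pmax(diag(XtX_inv) * s2_unbiased, 0))
  names(se) <- colnames(X)
  loglik <- sum(dnorm(res, sd = sigma_mle, log = TRUE))
  new_fit_result("ols", beta, scale_sigma = sigma_mle, se = se,
                 loglik = loglik, n_used = n, df_residual = n - p)
}

# ---- Tobit (upper-censored normal ML) -------------------------------------

tobit_negll <- function(par, X, y, cens, U) {
  p <- ncol(X)
  beta <- par[seq_len(p)]
  sigma <- exp(par[p + 1L])
  mu <- drop(X %*% beta)
  ll <- 0
  if (any(!cens)) {
    ll <- ll + sum(dnorm(y[!cens], mean = mu[!cens], sd = sigma, log = TRUE))
  }
  if (any(cens)) {
    ll <- ll + sum(pnorm((mu[cens] - U) / sigma, log.p = TRUE))
  }
  -ll
}

tobit_negll_grad <- function(par, X, y, cens, U) {
  p <- ncol(X)
  beta <- par[seq_len(p)]
  sigma <- exp(par[p + 1L])
  mu <- drop(X %*% beta)
  gbeta <- numeric(p); glogs <- 0
  if (any(!cens)) {
    r <- (y[!cens] - mu[!cens]) / sigma
    gbeta <- gbeta + drop(crossprod(X[!cens, , drop = FALSE], r / sigma))
    glogs <- glogs + sum(r^2 - 1)
  }
  if (any(cens)) {
    a <- (mu[cens] - U) / sigma
    # inverse Mills ratio, stable in the lower tail
    lambda <- exp(dnorm(a, log = TRUE) - pnorm(a, log.p = TRUE))
    gbeta <- gbeta + drop(crossprod(X[cens, , drop = FALSE], lambda / sigma))
    glogs <- glogs - sum(lambda * a)
  }
  -c(gbeta, glogs)
}

#' Tobit fit for an upper-censored outcome
#'
#' Maximum-likelihood estimation of the censored-normal model: the latent
#' outcome is `N(X beta, sigma^2)` but is observed only up to `upper_censor`
#' (here, the utility ceiling at 1). Censoring is detected by exact equality
#' `y == upper_censor` — tariff scoring returns exactly 1 only for full
#' health, so no tolerance band is used. Uncensored observations contribute
#' the normal density, censored ones the upper-tail probability. `sigma` is
#' parameterised on the log scale during optimisation; analytic gradients are
#' used, with standard errors from the numerically differentiated Hessian.
#'
#' @param X Numeric design matrix including an intercept column.
#' @param y Numeric response.
#' @param upper_censor Ceiling value (default 1).
#' @param maxit Iteration budget for the BFGS optimiser.
#' @return A `fit_result` with coefficients, `scale_sigma`, log-likelihood
#'   and a convergence flag. Non-convergence within the budget is flagged
#'   (`converged = FALSE`) and coefficient access should be treated as
#'   unreliable.
#' @export
fit_tobit <- function(X, y, upper_censor = 1.0, maxit = 500L) {
  X <- check_design(X, y)
  cens <- y == upper_censor
  if (all(cens)) {
    stop("all observations are censored at the ceiling; Tobit parameters are unidentified",
         call. = FALSE)
  }
  if (any(y > upper_censor)) {
    stop("response exceeds the declared censoring bound", call. = FALSE)
  }
  start_fit <- lm.fit(X, y)
  start <- c(start_fit$coefficients,
             log(max(sqrt(mean(start_fit$residuals^2)), 1e-4)))
  opt <- stats::optim(
    start, tobit_negll, gr = tobit_negll_grad,
    X = X, y = y, cens = cens, U = upper_censor,
    method = "BFGS", control = list(maxit = maxit, reltol = 1e-12)
  )
  p <- ncol(X)
  beta <- opt$par[seq_len(p)]
  names(beta) <- colnames(X)
  sigma <- unname(exp(opt$par[p + 1L]))
  converged <- opt$convergence == 0L
  se <- rep(NA_real_, p)
  if (converged) {
    H <- try(stats::optimHess(opt$par, tobit_negll, gr = tobit_negll_grad,
                              X = X, y = y, cens = cens, U = upper_censor),
             silent = TRUE)
    if (!inherits(H, "try-error")) {
      V <- try(solve(H), silent = TRUE)
      if (!inherits(V, "try-error")) se <- sqrt(pmax(diag(V)[seq_len(p)], 0))
    }
  }
  names(se) <- colnames(X)
  new_fit_result("tobit", beta, scale_sigma = sigma, se = se,
                 loglik = -opt$value, n_used = nrow(X), converged = converged,
                 df_residual = nrow(X) - p - 1L, upper_censor = upper_censor)
}

#' Predictions from a Tobit fit
#'
#' Three prediction policies are exposed: `latent` returns the latent mean
#' `X beta`; `truncate_at_1` (the default) truncates the latent mean at the
#' censoring bound, consistent with published Tobit prediction maxima of
#' exactly 1.00; `censored_expectation` returns the closed-form expectation
#' of the censored outcome `E[min(Y*, U)]` under the fitted normal.
#'
#' @param fit A converged Tobit `fit_result`.
#' @param X Design matrix (same columns as at fit time).
#' @param policy One of `"truncate_at_1"`, `"latent"`,
#'   `"censored_expectation"`.
#' @return Numeric vector of predictions.
#' @export
predict_tobit <- function(fit, X,
                          policy = c("truncate_at_1", "latent", "censored_expectation")) {
  stopifnot(inherits(fit, "fit_result"), fit$form == "tobit")
  policy <- match.arg(policy)
  if (!fit$converged) stop("refusing to predict from a non-converged Tobit fit", call. = FALSE)
  mu <- drop(as.matrix(X) %*% fit$coefficients)
  U <- fit$upper_censor
  switch(policy,
    latent = mu,
    truncate_at_1 = pmin(mu, U),
    censored_expectation = {
      a <- (U - mu) / fit$scale_sigma
      mu * pnorm(a) - fit$scale_sigma * dnorm(a) + U * (1 - pnorm(a))
    }
  )
}

# ---- two-part model --------------------------------------------------------

#' Two-part fit for a ceiling-inflated outcome
#'
#' Part 1 is a logistic regression on the indicator of being at the ceiling
#' (full health, `y == ceiling`); part 2 is an OLS regression on the strict
#' subset below the ceiling. The combined prediction is the expectation
#' `p * ceiling + (1 - p) * yhat2`, with `p` the part-1 probability — a
#' modelling choice documented here because the recombination rule is rarely
#' stated explicitly in mapping studies. When the data contain no ceiling
#' observations, part 1 degenerates to `p == 0` and the combined prediction
#' equals the part-2 OLS prediction exactly. Complete separation in part 1 is
#' flagged as non-convergence.
#'
#' @param X Numeric design matrix including an intercept column.
#' @param y Numeric response.
#' @param ceiling Ceiling value (default 1), detected by exact equality.
#' @return A `fit_result` of form `"two_part"` carrying both parts.
#' @export
fit_two_part <- function(X, y, ceiling = 1.0) {
  X <- check_design(X, y)
  at_ceiling <- y == ceiling
  below <- !at_ceiling
  if (sum(below) < ncol(X) + 1L || length(unique(y[below])) < 2L) {
    stop("part 2 (below-ceiling OLS) is not estimable: fewer than two distinct outcome values below the ceiling",
         call. = FALSE)
  }
  converged <- TRUE
  if (any(at_ceiling)) {
    separated <- FALSE
    g <- withCallingHandlers(
      stats::glm.fit(X, as.numeric(at_ceiling), family = stats::binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)) ||
            grepl("did not converge", conditionMessage(w))) {
          separated <<- TRUE
        }
        invokeRestart("muffleWarning")
      }
    )
    if (separated || !g$converged) converged <- FALSE
    p1_coef <- g$coefficients
    names(p1_coef) <- colnames(X)
    p1_se <- tryCatch({
      sw <- sqrt(g$weights)
      R <- qr.R(qr(X * sw))
      sqrt(pmax(diag(chol2inv(R)), 0))
    }, error = function(e) rep(NA_real_, ncol(X)))
    names(p1_se) <- colnames(X)
    part1 <- list(coefficients = p1_coef, se = p1_se, n = nrow(X),
                  deviance = g$deviance)
  } else {
    part1 <- NULL # degenerate: no ceiling mass, p identically zero
  }
  part2 <- fit_ols(X[below, , drop = FALSE], y[below])
  new_fit_result("two_part", coefficients = part2$coefficients,
                 loglik = NA_real_, n_used = nrow(X), converged = converged,
                 part1 = part1, part2 = part2, ceiling = ceiling)
}

#' @rdname fit_two_part
#' @param fit A two-part `fit_result`.
#' @export
predict_two_part <- function(fit, X) {
  stopifnot(inherits(fit, "fit_result"), fit$form == "two_part")
  X <- as.matrix(X)
  p <- if (is.null(fit$part1)) {
    rep(0, nrow(X))
  } else {
    stats::plogis(drop(X %*% fit$part1$coefficients))
  }
  yhat2 <- drop(X %*% fit$part2$coefficients)
  p * fit$ceiling + (1 - p) * yhat2
}

#' Predict from any fit result
#'
#' Dispatches on the functional form: OLS returns the linear predictor,
#' Tobit applies the requested prediction policy (default `truncate_at_1`),
#' and two-part returns the combined expectation.
#'
#' @param object A `fit_result`.
#' @param X Design matrix with the columns used at fit time.
#' @param policy Tobit prediction policy (ignored for other forms).
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.fit_result <- function(object, X, policy = "truncate_at_1", ...) {
  switch(object$form,
    ols = drop(as.matrix(X) %*% object$coefficients),
    tobit = predict_tobit(object, X, policy = policy),
    two_part = predict_two_part(object, X)
  )
}

fit_by_form <- function(X, y, form, upper_censor = 1.0) {
  switch(form,
    ols = fit_ols(X, y),
    tobit = fit_tobit(X, y, upper_censor = upper_censor),
    two_part = fit_two_part(X, y, ceiling = upper_censor),
    stop(sprintf("unknown functional form '%s'", form), call. = FALSE)
  )
}

# ---- stepwise forward selection -------------------------------------------

# Two-sided p-value for the named term in a fitted model. For OLS this is the
# usual t test; for Tobit a Wald z from the inverse Hessian; for two-part the
# smaller of the term's Wald p-values in the two parts (a term is worth
# keeping if either part needs it).
term_p_value <- function(fit, term) {
  if (fit$form == "ols") {
    t <- fit$coefficients[[term]] / fit$se[[term]]
    return(2 * stats::pt(-abs(t), df = fit$df_residual))
  }
  if (fit$form == "tobit") {
    z <- fit$coefficients[[term]] / fit$se[[term]]
    return(2 * stats::pnorm(-abs(z)))
  }
  if (fit$form == "two_part") {
    p2 <- {
      t <- fit$part2$coefficients[[term]] / fit$part2$se[[term]]
      2 * stats::pt(-abs(t), df = fit$part2$df_residual)
    }
    p1 <- if (!is.null(fit$part1) && is.finite(fit$part1$se[[term]])) {
      z <- fit$part1$coefficients[[term]] / fit$part1$se[[term]]
      2 * stats::pnorm(-abs(z))
    } else {
      1
    }
    return(min(p1, p2))
  }
  stop("unknown form")
}

#' Forward stepwise selection with a stay criterion
#'
#' Iteratively adds the candidate regressor with the smallest entry p-value
#' below `sle`; after each addition, removes any included regressor whose
#' p-value exceeds `slstay`. Entry and stay thresholds default to 0.25 — the
#' conventional permissive level for building parsimonious prediction models.
#' Ties are broken by the canonical column order of the candidate matrix, so
#' the procedure is deterministic. Weak hierarchy is enforced by default: a
#' product term may enter only once both its parents are in the model
#' (`hierarchy = FALSE` lifts this).
#'
#' @param X Candidate design matrix including an `(Intercept)` column;
#'   non-intercept columns form the candidate pool, named by regressor
#'   signature.
#' @param y Numeric response.
#' @param form `"ols"`, `"tobit"` or `"two_part"` (p-values: t test, Wald,
#'   and the smaller of the two parts' Wald tests, respectively).
#' @param sle Significance level required for entry.
#' @param slstay Significance level required to remain.
#' @param hierarchy Enforce weak hierarchy for product terms?
#' @param upper_censor Ceiling passed through to Tobit/two-part fits.
#' @return List with `fit` (the final `fit_result`), `selected` (signatures
#'   in order of entry) and `steps` (a data frame log of additions/removals).
#' @export
stepwise_forward <- function(X, y, form = "ols", sle = 0.25, slstay = 0.25,
                             hierarchy = TRUE, upper_censor = 1.0) {
  X <- check_design(X, y)
  if (!"(Intercept)" %in% colnames(X)) {
    stop("candidate matrix must include an '(Intercept)' column", call. = FALSE)
  }
  pool <- setdiff(colnames(X), "(Intercept)")
  selected <- character(0)
  steps <- list()
  refit <- function(sel) {
    fit_by_form(X[, c("(Intercept)", sel), drop = FALSE], y, form,
                upper_censor = upper_censor)
  }
  eligible <- function(sel) {
    cand <- setdiff(pool, sel)
    if (!hierarchy) return(cand)
    ok <- vapply(cand, function(sig) {
      if (!grepl(":", sig, fixed = TRUE)) return(TRUE)
      parents <- strsplit(sig, ":", fixed = TRUE)[[1L]]
      all(parents %in% sel)
    }, logical(1))
    cand[ok]
  }
  max_steps <- 4L * length(pool) + 4L
  for (iter in seq_len(max_steps)) {
    cand <- eligible(selected)
    if (!length(cand)) break
    pvals <- vapply(cand, function(sig) {
      tryCatch(term_p_value(refit(c(selected, sig)), sig),
               error = function(e) 1)
    }, numeric(1))
    best <- which.min(pvals) # which.min takes the first minimum: canonical-order tie-break
    if (!(pvals[best] < sle)) break
    selected <- c(selected, cand[best])
    steps[[length(steps) + 1L]] <- data.frame(
      action = "add", term = cand[best], p_value = pvals[best]
    )
    # stay check: drop terms whose p-value has risen above slstay
    repeat {
      if (!length(selected)) break
      fit <- refit(selected)
      pv <- vapply(selected, function(sig) term_p_value(fit, sig), numeric(1))
      worst <- which.max(pv)
      if (pv[worst] > slstay) {
        steps[[length(steps) + 1L]] <- data.frame(
          action = "remove", term = selected[worst], p_value = pv[worst]
        )
        selected <- selected[-worst]
      } else {
        break
      }
    }
  }
  fit <- refit(selected)
  list(
    fit = fit, selected = selected,
    steps = if (length(steps)) do.call(rbind, steps) else
      data.frame(action = character(0), term = character(0), p_value = numeric(0))
  )
}

# ---- fit -> mapping model --------------------------------------------------

#' Freeze a fit into a mapping model
#'
#' Converts an OLS or Tobit `fit_result` (linear scoring rules) into a
#' [mapping_model()] so it can be registered, serialised and applied with
#' [predict_utility()]. For a Tobit fit the latent-mean coefficients are
#' frozen; apply clipping downstream if the truncated policy is wanted.
#' Two-part fits have no single linear representation and are rejected.
#'
#' @param fit A `fit_result` of form `"ols"` or `"tobit"`.
#' @param name Model name.
#' @param group Specification group 1-6.
#' @param clip_predictions Clip at 1 when applied?
#' @return A `mapping_model`.
#' @export
as_mapping_model <- function(fit, name, group, clip_predictions = FALSE) {
  stopifnot(inherits(fit, "fit_result"))
  if (fit$form == "two_part") {
    stop("a two-part fit has no single linear coefficient set; keep it as a fit_result",
         call. = FALSE)
  }
  coefs <- fit$coefficients
  if (!"(Intercept)" %in% names(coefs)) {
    stop("fit lacks an '(Intercept)' coefficient", call. = FALSE)
  }
  mapping_model(
    name = name, group = group, form = fit$form,
    intercept = coefs[["(Intercept)"]],
    terms = coefs[setdiff(names(coefs), "(Intercept)")],
    clip_predictions = clip_predictions
  )
}
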