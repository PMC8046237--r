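# ---- estimation / validation split ----------------------------------------

#' Split records into estimation and validation cohorts
#'
#' Draws a uniformly random, seed-reproducible split. The estimation cohort
#' gets `ceiling(fraction * n)` records (so a 70% split of 1,092 records
#' yields 765 estimation and 327 validation records), the remainder forms the
#' validation cohort.
#'
#' @param records Patient table (>= 10 records).
#' @param fraction Estimation fraction, default 0.70.
#' @param seed Integer seed.
#' @return An object of class `split_assignment`: list with `assignment`
#'   (factor `"estimation"`/`"validation"`, one per record), `estimation` and
#'   `validation` (row indices), `fraction` and `seed`.
#' @export
split_estimation_validation <- function(records, fraction = 0.70, seed) {
  records <- as.data.frame(records)
  n <- nrow(records)
  if (n < 10L) stop("need at least 10 records to split", call. = FALSE)
  stopifnot(fraction > 0, fraction <= 1)
  n_est <- min(n, as.integer(ceiling(fraction * n)))
  est_idx <- sort(with_seed(seed, sample.int(n, n_est)))
  assignment <- factor(rep("validation", n), levels = c("estimation", "validation"))
  assignment[est_idx] <- "estimation"
  structure(
    list(assignment = assignment, estimation = est_idx,
         validation = setdiff(seq_len(n), est_idx),
         fraction = fraction, seed = seed),
    class = "split_assignment"
  )
}

# Seeded fold assignment: a random permutation sliced into k contiguous
# blocks, remainder records going one-per-fold to the first folds.
fold_assignment <- function(n, k, seed) {
  perm <- with_seed(seed, sample.int(n))
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  fold <- integer(n)
  pos <- 1L
  for (f in seq_len(k)) {
    fold[perm[seq(pos, length.out = sizes[f])]] <- f
    pos <- pos + sizes[f]
  }
  fold
}

# ---- k-fold cross-validation ----------------------------------------------

#' k-fold cross-validation of one specification and functional form
#'
#' Splits the complete cases into `k` folds, fits the model on `k - 1` folds
#' and predicts the held-out fold, so each record is predicted exactly once
#' by a model that never saw it. The per-fold predicted residual sums of
#' squares (PRESS) are accumulated and the cross-validated
#' `RMSE = sqrt(sum(PRESS) / n)` — PRESS is summed over folds before
#' dividing by the total record count, which differs from averaging per-fold
#' RMSEs when folds are unequal.
#'
#' @param records Patient table with observed `eq5d`.
#' @param spec A [design_spec()].
#' @param form `"ols"`, `"tobit"` or `"two_part"`.
#' @param k Number of folds (default 5); `k = n` gives leave-one-out.
#' @param seed Integer seed for the fold assignment.
#' @param policy Tobit prediction policy (default `"truncate_at_1"`).
#' @param label Report label; defaults to `spec$label`.
#' @return An object of class `cv_report`: label, form, `fold_press`,
#'   `rmse`, `mae`, a prediction summary (mean, sd, min, max), `n`,
#'   `n_terms`, `incomplete` flag and any failed folds.
#' @export
kfold_cross_validate <- function(records, spec, form = "ols", k = 5L, seed,
                                 policy = "truncate_at_1", label = NULL) {
  dm <- build_design_matrix(records, spec, require_utility = TRUE)
  X <- dm$X; y <- dm$y
  n <- nrow(X)
  if (n < 2L * k && k < n) stop("need at least 2k records for k-fold CV", call. = FALSE)
  if (k > n) stop("more folds than records", call. = FALSE)
  fold <- fold_assignment(n, k, seed)
  fold_press <- rep(NA_real_, k)
  failed <- integer(0)
  preds <- rep(NA_real_, n)
  for (f in seq_len(k)) {
    hold <- fold == f
    fit <- tryCatch(
      fit_by_form(X[!hold, , drop = FALSE], y[!hold], form),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      failed <- c(failed, f)
      next
    }
    p <- predict(fit, X[hold, , drop = FALSE], policy = policy)
    preds[hold] <- p
    fold_press[f] <- sum((y[hold] - p)^2)
  }
  ok <- !is.na(preds)
  n_ok <- sum(ok)
  rmse <- if (n_ok) sqrt(sum(fold_press, na.rm = TRUE) / n_ok) else NA_real_
  mae <- if (n_ok) mean(abs(y[ok] - preds[ok])) else NA_real_
  pred_summary <- if (n_ok) {
    c(mean = mean(preds[ok]), sd = stats::sd(preds[ok]),
      min = min(preds[ok]), max = max(preds[ok]))
  } else {
    c(mean = NA_real_, sd = NA_real_, min = NA_real_, max = NA_real_)
  }
  structure(
    list(
      label = label %||% dm$spec$label, form = form, k = k, seed = seed,
      fold_press = fold_press, rmse = rmse, mae = mae,
      prediction_summary = pred_summary,
      n = n_ok, n_terms = ncol(X) - 1L,
      incomplete = length(failed) > 0L, failed_folds = failed
    ),
    class = "cv_report"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @exportS3Method base::print
print.cv_report <- function(x, ...) {
  cat(sprintf("%d-fold CV of %s '%s' on %d records%s\n", x$k, toupper(x$form),
              x$label, x$n, if (x$incomplete) " [INCOMPLETE]" else ""))
  cat(sprintf("  RMSE %.5f, MAE %.5f\n", x$rmse, x$mae))
  s <- x$prediction_summary
  cat(sprintf("  predicted: %.2f +/- %.2f, range [%.2f, %.2f]\n",
              s["mean"], s["sd"], s["min"], s["max"]))
  invisible(x)
}

# ---- external validation ---------------------------------------------------

#' Score a frozen mapping model against a validation cohort
#'
#' Applies a frozen [mapping_model()] (no refitting) to records with observed
#' utilities and reports the out-of-sample error and a prediction summary in
#' the usual report columns (mean, SD, minimum, maximum, RMSE, MAE).
#'
#' @param model A `mapping_model`.
#' @param records Patient table; must contain a non-missing `eq5d` column.
#' @return An object of class `validation_report`.
#' @export
external_validate <- function(model, records) {
  records <- as.data.frame(records)
  if (!"eq5d" %in% names(records) || anyNA(records$eq5d)) {
    stop("external validation requires observed utilities in column 'eq5d'",
         call. = FALSE)
  }
  pred <- predict_utility(model, records)$predicted_utility
  obs <- records$eq5d
  res <- pred - obs
  structure(
    list(
      label = model$name, n = length(obs),
      rmse = sqrt(mean(res^2)), mae = mean(abs(res)),
      prediction_summary = c(mean = mean(pred), sd = stats::sd(pred),
                             min = min(pred), max = max(pred)),
      n_terms = length(model$terms)
    ),
    class = "validation_report"
  )
}

#' @exportS3Method base::print
print.validation_report <- function(x, ...) {
  cat(sprintf("External validation of '%s' on %d records\n", x$label, x$n))
  s <- x$prediction_summary
  cat(sprintf("  predicted %.2f +/- %.2f, range [%.2f, %.2f]\n",
              s["mean"], s["sd"], s["min"], s["max"]))
  cat(sprintf("  RMSE %.6f, MAE %.6f\n", x$rmse, x$mae))
  invisible(x)
}

# ---- model ranking ---------------------------------------------------------

#' Rank candidate models by RMSE
#'
#' Orders cross-validation or validation reports by ascending RMSE; ties are
#' broken in favour of the model with fewer regressors, then by label.
#'
#' @param reports List of `cv_report` and/or `validation_report` objects.
#' @return Data frame with columns `rank`, `label`, `form`, `rmse`, `mae`,
#'   `n_terms`, `n`.
#' @export
rank_models <- function(reports) {
  if (inherits(reports, "cv_report") || inherits(reports, "validation_report")) {
    reports <- list(reports)
  }
  stopifnot(length(reports) >= 1L)
  tab <- do.call(rbind, lapply(reports, function(r) {
    data.frame(
      label = r$label, form = r$form %||% "frozen", rmse = r$rmse, mae = r$mae,
      n_terms = r$n_terms, n = r$n
    )
  }))
  ord <- order(tab$rmse, tab$n_terms, tab$label)
  tab <- tab[ord, , drop = FALSE]
  tab <- cbind(rank = seq_len(nrow(tab)), tab)
  rownames(tab) <- NULL
  tab
}

# ---- Bland-Altman agreement ------------------------------------------------

#' Bland-Altman agreement between observed and predicted utilities
#'
#' Computes per-record (mean, difference) pairs with differences defined as
#' `predicted - observed`, and the 95% limits of agreement
#' `mean difference +/- 1.96 * SD(differences)`.
#'
#' @param observed,predicted Equal-length numeric vectors.
#' @return List with `data` (data frame of `mean` and `difference`),
#'   `mean_difference`, `sd_difference`, `lower_limit`, `upper_limit`.
#' @export
bland_altman <- function(observed, predicted) {
  if (length(observed) != length(predicted)) {
    stop("'observed' and 'predicted' must have the same length", call. = FALSE)
  }
  d <- predicted - observed
  m <- (predicted + observed) / 2
  md <- mean(d)
  sdd <- if (length(d) > 1L) stats::sd(d) else 0
  list(
    data = data.frame(mean = m, difference = d),
    mean_difference = md, sd_difference = sdd,
    lower_limit = md - 1.96 * sdd, upper_limit = md + 1.96 * sdd
  )
}
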