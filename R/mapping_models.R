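# Regressor signatures are short canonical names; each main effect maps to a
# column of the patient table. Products are written "a:b" and powers "age^2".
score_signatures <- c(
  urinary = "epic_urinary", bowel = "epic_bowel",
  sexual = "epic_sexual", hormonal = "epic_hormonal",
  uf = "epic_uf", ub = "epic_ub", uirr = "epic_uirr", uinc = "epic_uinc",
  bf = "epic_bf", bb = "epic_bb", sf = "epic_sf", sb = "epic_sb",
  hf = "epic_hf", hb = "epic_hb"
)
covariate_signatures <- c(
  age = "age", race_other = "race_other", zubrod = "zubrod", psa_ge4 = "psa_ge4"
)

# Evaluate one regressor signature against a patient table. Handles main
# effects, integer powers ("age^2") and two-way products ("uf:zubrod").
eval_signature <- function(sig, records) {
  if (grepl(":", sig, fixed = TRUE)) {
    parts <- strsplit(sig, ":", fixed = TRUE)[[1L]]
    return(Reduce(`*`, lapply(parts, eval_signature, records = records)))
  }
  if (grepl("^", sig, fixed = TRUE)) {
    parts <- strsplit(sig, "^", fixed = TRUE)[[1L]]
    pow <- suppressWarnings(as.integer(parts[2L]))
    if (is.na(pow)) stop(sprintf("malformed power in regressor '%s'", sig), call. = FALSE)
    return(eval_signature(parts[1L], records)^pow)
  }
  col <- c(score_signatures, covariate_signatures)[sig]
  if (is.na(col)) stop(sprintf("unknown regressor '%s'", sig), call. = FALSE)
  if (!col %in% names(records)) {
    stop(sprintf("input table lacks column '%s' required by regressor '%s'", col, sig),
         call. = FALSE)
  }
  v <- records[[col]]
  if (anyNA(v)) {
    stop(sprintf("regressor '%s' (column '%s') has missing values", sig, col),
         call. = FALSE)
  }
  as.numeric(v)
}

signature_base_names <- function(sig) {
  parts <- strsplit(sig, ":", fixed = TRUE)[[1L]]
  sub("\\^[0-9]+$", "", parts)
}

#' Construct a mapping model
#'
#' A mapping model is a named, frozen linear scoring rule
#' `utility = intercept + sum(coefficient * regressor)` predicting an EQ-5D
#' utility from EPIC scores and optional demographic/clinical covariates.
#' Regressors are written with canonical signatures: domain scores
#' (`urinary`, `bowel`, `sexual`, `hormonal`), sub-domain scores (`uf`, `ub`,
#' `uirr`, `uinc`, `bf`, `bb`, `sf`, `sb`, `hf`, `hb`), covariates (`age`,
#' `race_other`, `zubrod`, `psa_ge4`), powers (`age^2`) and products
#' (`uf:zubrod`).
#'
#' @param name Unique model label.
#' @param group Specification group, integer 1-6.
#' @param form Functional form the coefficients came from:
#'   `"ols"`, `"tobit"` or `"two_part"`.
#' @param intercept Numeric intercept.
#' @param terms Named numeric vector of coefficients; names are regressor
#'   signatures and must be unique.
#' @param clip_predictions Truncate predictions at 1? Off by default: the
#'   published algorithms were not clipped (reported OLS prediction maxima
#'   exceed 1), so clipping is an explicit opt-in for downstream QALY use.
#' @return An object of class `mapping_model`.
#' @export
mapping_model <- function(name, group, form = c("ols", "tobit", "two_part"),
                          intercept, terms, clip_predictions = FALSE) {
  form <- match.arg(form)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  stopifnot(group %in% 1:6, is.numeric(intercept), length(intercept) == 1L)
  terms <- unlist(terms)
  if (is.null(names(terms)) || any(!nzchar(names(terms)))) {
    stop("every term must be named by its regressor signature", call. = FALSE)
  }
  if (anyDuplicated(names(terms))) {
    stop("duplicate regressor signature in model terms", call. = FALSE)
  }
  for (sig in names(terms)) {
    bases <- signature_base_names(sig)
    unknown <- setdiff(bases, names(c(score_signatures, covariate_signatures)))
    if (length(unknown)) {
      stop(sprintf("unknown regressor base '%s' in signature '%s'",
                   unknown[1L], sig), call. = FALSE)
    }
  }
  structure(
    list(name = name, group = as.integer(group), form = form,
         intercept = as.numeric(intercept), terms = terms,
         clip_predictions = isTRUE(clip_predictions)),
    class = "mapping_model"
  )
}

#' @exportS3Method base::print
print.mapping_model <- function(x, ...) {
  cat(sprintf("Mapping model '%s' (group %d, %s)\n", x$name, x$group, x$form))
  cat(sprintf("  intercept: %s\n", format(x$intercept)))
  for (sig in names(x$terms)) {
    cat(sprintf("  %+.9g * %s\n", x$terms[[sig]], sig))
  }
  if (x$clip_predictions) cat("  predictions clipped at 1\n")
  invisible(x)
}

#' Required input columns of a mapping model
#' @param model A `mapping_model`.
#' @return Character vector of patient-table column names the model needs.
#' @export
model_required_columns <- function(model) {
  bases <- unique(unlist(lapply(names(model$terms), signature_base_names)))
  unname(c(score_signatures, covariate_signatures)[bases])
}

#' Published reduced mapping model (specification group 6)
#'
#' The best-performing parsimonious EPIC-to-EQ5D algorithm: an OLS model on
#' the urinary and hormonal function/bother sub-domain scores, Zubrod
#' performance status, and a urinary-function-by-Zubrod product. Coefficients
#' are stored at full published precision and never rounded at evaluation
#' time.
#'
#' @return A `mapping_model` with seven published coefficients
#'   (intercept included).
#' @examples
#' m <- builtin_reduced_model_6()
#' predict_utility(m, data.frame(epic_uf = 90, epic_ub = 85,
#'                               epic_hf = 90, epic_hb = 95, zubrod = 0))
#' @export
builtin_reduced_model_6 <- function() {
  mapping_model(
    name = "reduced_6", group = 6L, form = "ols",
    intercept = 0.248541,
    terms = c(
      "uf" = 0.000748,
      "ub" = 0.001134,
      "hf" = 0.000968,
      "hb" = 0.004404,
      "zubrod" = -0.376487,
      "uf:zubrod" = 0.003562
    )
  )
}

#' Published full mapping model 6i (specification group 6)
#'
#' The best-performing full algorithm: an OLS model on all ten EPIC
#' sub-domain scores, an age cubic, race, Zubrod performance status, the ten
#' sub-domain-by-Zubrod products, and the PSA >= 4 indicator — 26 published
#' coefficients plus the intercept. Age enters as raw years (no centering),
#' exactly as published.
#'
#' @return A `mapping_model`.
#' @export
builtin_full_model_6i <- function() {
  mapping_model(
    name = "full_6i", group = 6L, form = "ols",
    intercept = 2.922434,
    terms = c(
      "uf" = 0.003627,
      "ub" = 0.004125,
      "uirr" = -0.003625,
      "uinc" = -0.002242,
      "bf" = -0.0000058476,
      "bb" = -0.000690,
      "sf" = 0.000589,
      "sb" = -0.000244,
      "hf" = 0.000721,
      "hb" = 0.004691,
      "age" = -0.126445,
      "age^2" = 0.001997,
      "age^3" = -0.000010336,
      "race_other" = 0.009922,
      "zubrod" = -0.456669,
      "uf:zubrod" = 0.016593,
      "ub:zubrod" = 0.008613,
      "uirr:zubrod" = -0.011,
      "uinc:zubrod" = -0.011342,
      "bf:zubrod" = 0.000711,
      "bb:zubrod" = 0.003675,
      "sf:zubrod" = -0.001631,
      "sb:zubrod" = 0.00008517,
      "hf:zubrod" = -0.000201,
      "hb:zubrod" = -0.002221,
      "psa_ge4" = 0.000332
    )
  )
}

#' Predict EQ-5D utilities from a mapping model
#'
#' Evaluates `intercept + sum(coefficient * regressor)` literally against the
#' patient table, product and power terms included. Predictions are raw
#' unless the model carries `clip_predictions` (or `clip` is set), in which
#' case they are truncated at 1.
#'
#' @param model A `mapping_model`.
#' @param records Patient table (data frame, standard column names). Every
#'   column the model's regressors need must be present and non-missing.
#' @param clip Override the model's clipping flag.
#' @return A data frame of class `prediction_record` with columns
#'   `model_name`, `predicted_utility`, and the input columns used.
#' @export
predict_utility <- function(model, records, clip = model$clip_predictions) {
  stopifnot(inherits(model, "mapping_model"))
  records <- as.data.frame(records)
  pred <- rep(model$intercept, nrow(records))
  for (sig in names(model$terms)) {
    pred <- pred + model$terms[[sig]] * eval_signature(sig, records)
  }
  if (isTRUE(clip)) pred <- pmin(pred, 1)
  if (any(!is.finite(pred))) {
    stop("non-finite prediction; check input ranges", call. = FALSE)
  }
  used <- intersect(model_required_columns(model), names(records))
  out <- cbind(
    data.frame(model_name = model$name, predicted_utility = pred),
    records[used]
  )
  class(out) <- c("prediction_record", "data.frame")
  out
}

# ---- model registry --------------------------------------------------------

#' Mapping-model registry
#'
#' A registry holds named mapping models. A fresh registry is pre-populated
#' with the two built-ins published in full (`reduced_6` and `full_6i`);
#' further candidates (e.g. from supplementary coefficient sets or
#' re-estimation runs) are added from JSON model files or
#' [register_model()] without code changes.
#'
#' @return An environment-backed registry object of class `model_registry`.
#' @export
model_registry <- function() {
  reg <- new.env(parent = emptyenv())
  class(reg) <- "model_registry"
  register_model(builtin_reduced_model_6(), reg)
  register_model(builtin_full_model_6i(), reg)
  reg
}

#' @rdname model_registry
#' @param model A `mapping_model` to add.
#' @param registry A `model_registry`.
#' @export
register_model <- function(model, registry) {
  stopifnot(inherits(model, "mapping_model"), inherits(registry, "model_registry"))
  if (model$name %in% ls(registry)) {
    stop(sprintf("a model named '%s' is already registered", model$name), call. = FALSE)
  }
  assign(model$name, model, envir = registry)
  invisible(registry)
}

#' @rdname model_registry
#' @param name Model name to retrieve.
#' @export
get_model <- function(name, registry) {
  stopifnot(inherits(registry, "model_registry"))
  if (!name %in% ls(registry)) {
    stop(sprintf("no model named '%s' in registry (have: %s)", name,
                 paste(sort(ls(registry)), collapse = ", ")), call. = FALSE)
  }
  get(name, envir = registry)
}

#' @rdname model_registry
#' @export
list_models <- function(registry) {
  stopifnot(inherits(registry, "model_registry"))
  sort(ls(registry))
}

# ---- JSON round-trip -------------------------------------------------------

#' Read and write mapping-model JSON files
#'
#' A model file holds either one model object or an array of them; each
#' object has fields `name`, `group`, `form`, `intercept`, `terms` (a
#' signature-to-coefficient map) and optionally `clip_predictions`.
#'
#' @param path File path.
#' @return `read_models()` returns a list of `mapping_model`s.
#' @export
read_models <- function(path) {
  if (!file.exists(path)) stop(sprintf("model file not found: %s", path), call. = FALSE)
  raw <- jsonlite::read_json(path)
  if (!is.null(raw$name)) raw <- list(raw)
  lapply(raw, function(m) {
    for (field in c("name", "group", "form", "intercept", "terms")) {
      if (is.null(m[[field]])) {
        stop(sprintf("model entry lacks required field '%s' in %s", field, path),
             call. = FALSE)
      }
    }
    mapping_model(m$name, m$group, m$form, m$intercept, unlist(m$terms),
                  clip_predictions = isTRUE(m$clip_predictions))
  })
}

#' @rdname read_models
#' @param models A `mapping_model` or list of them.
#' @export
write_models <- function(models, path) {
  if (inherits(models, "mapping_model")) models <- list(models)
  payload <- lapply(models, function(m) {
    list(name = m$name, group = m$group, form = m$form,
         intercept = m$intercept, terms = as.list(m$terms),
         clip_predictions = m$clip_predictions)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
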