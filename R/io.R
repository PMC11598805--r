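MODEL_SCHEMA_VERSION <- 1L

CORE_COLUMNS <- c("participant_code", "weight_kg", "height_cm",
                  "body_area_m2", "age_years", "sex", "diuresis_ml")

known_columns <- function() {
  c(CORE_COLUMNS,
    as.vector(outer(METALS,
                    c("_blood_ugml", "_urine_ugml", "_water_mgl",
                      "_soil_mgkg", "_retention"), paste0)))
}

#' Read a cohort CSV
#'
#' Reads and validates a comma-separated, '.'-decimal cohort table with a
#' mandatory header.  The core columns (participant code, weight, height,
#' body area, age, sex, diuresis) are required; per-metal columns
#' \code{<metal>_blood_ugml}, \code{_urine_ugml}, \code{_water_mgl},
#' \code{_soil_mgkg} and optional \code{_retention} are validated when
#' present, and unknown columns trigger a warning.  Rows violating the
#' subject invariants (non-positive weight/height/diuresis, age < 1, sex
#' outside \{0,1\}, negative concentrations, retention outside (0;1)) are
#' rejected with their row numbers reported.
#'
#' @param path path to the CSV file.
#' @return validated cohort data.frame.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cohort <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(cohort) == 0L)
    stop("cohort file has no data rows: ", path, call. = FALSE)
  validate_cohort(cohort)
}

#' @rdname read_cohort
#' @param cohort cohort data.frame to validate or write.
#' @export
validate_cohort <- function(cohort) {
  stopifnot(is.data.frame(cohort))
  missing_cols <- setdiff(CORE_COLUMNS, names(cohort))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  unknown <- setdiff(names(cohort), known_columns())
  if (length(unknown))
    warning("unknown column(s) ignored by the pipeline: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  num_cols <- setdiff(intersect(names(cohort), known_columns()),
                      "participant_code")
  for (col in num_cols) {
    if (!is.numeric(cohort[[col]]))
      stop("column '", col, "' is not numeric", call. = FALSE)
    bad <- which(!is.finite(cohort[[col]]) & !is.na(cohort[[col]]))
    if (length(bad))
      stop("non-finite value in column '", col, "', row(s) ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  bad <- with(cohort,
    weight_kg <= 0 | height_cm <= 0 | body_area_m2 <= 0 |
    age_years < 1 | !(sex %in% c(0, 1)) | diuresis_ml <= 0)
  for (col in grep("_(blood_ugml|urine_ugml|water_mgl|soil_mgkg)$",
                   names(cohort), value = TRUE))
    bad <- bad | (!is.na(cohort[[col]]) & cohort[[col]] < 0)
  for (col in grep("_retention$", names(cohort), value = TRUE))
    bad <- bad | (!is.na(cohort[[col]]) &
                    (cohort[[col]] <= 0 | cohort[[col]] >= 1))
  bad[is.na(bad)] <- FALSE
  if (any(bad)) {
    message(sum(bad), " row(s) rejected for invariant violations: rows ",
            paste(utils::head(which(bad), 20L), collapse = ", "))
    cohort <- cohort[!bad, , drop = FALSE]
  }
  if (nrow(cohort) == 0L)
    stop("no valid rows remain after validation", call. = FALSE)
  rownames(cohort) <- NULL
  cohort
}

#' Write a cohort CSV
#'
#' @inheritParams read_cohort
#' @param path destination path.
#' @return the path, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(is.data.frame(cohort))
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Persist a double-loop model as JSON
#'
#' One JSON document embedding both trained blocks (layer sizes, weights,
#' activation specs), the confidence weights, the normalisation parameters
#' of each block and the fit metadata, under a schema version field.  The
#' numeric representation uses full precision so a reloaded model
#' reproduces forward outputs exactly.
#'
#' @param model a fitted [double_loop()] model.
#' @param path destination path.
#' @return the path, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "double_loop"))
  ser_block <- function(b) list(
    n_inputs = b$model$n_inputs, n_hidden = b$model$n_hidden,
    w1 = as.vector(t(b$model$w1)), b1 = b$model$b1,
    w2 = as.vector(b$model$w2), b2 = b$model$b2,
    hidden = unclass(b$model$hidden), output = unclass(b$model$output),
    seed = b$model$seed,
    norm = lapply(b$norm, function(p) if (is.null(p)) NULL else unclass(p)),
    features = b$dataset$features,
    train_error = b$train_report[c("min", "max", "mean", "n")],
    test_error = b$test_report[c("min", "max", "mean", "n")])
  doc <- list(
    schema_version = MODEL_SCHEMA_VERSION,
    metal = model$metal, seed = model$seed,
    n_hidden = model$n_hidden, zscore = model$zscore,
    config = unclass(model$config),
    weights = list(a_l = model$weights$a_l, a_s = model$weights$a_s,
                   err_l = model$weights$err_l, err_s = model$weights$err_s,
                   scheme = model$weights$scheme),
    blocks = list(long = ser_block(model$blocks$long),
                  short = ser_block(model$blocks$short)))
  ## 17 significant digits: doubles survive the decimal round trip exactly
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Load a persisted double-loop model
#'
#' @param path path to a JSON file written by [save_model()].
#' @return a \code{double_loop} model usable with [predict.double_loop()]
#'   (the training data are not stored, so residual/plot methods that need
#'   them are unavailable on a loaded model).
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    stop("cannot parse model file: ", conditionMessage(e),
                         call. = FALSE))
  if (is.null(doc$schema_version) ||
      doc$schema_version != MODEL_SCHEMA_VERSION)
    stop("model schema version mismatch: file has '",
         doc$schema_version %||% "none", "', expected ",
         MODEL_SCHEMA_VERSION, call. = FALSE)
  de_block <- function(b) {
    spec <- function(s) activation_spec(s$kind, s$curvature, s$gain)
    model <- structure(
      list(w1 = matrix(b$w1, b$n_hidden, b$n_inputs, byrow = TRUE),
           b1 = b$b1, w2 = matrix(b$w2, 1L, b$n_hidden), b2 = b$b2,
           hidden = spec(b$hidden), output = spec(b$output),
           n_inputs = b$n_inputs, n_hidden = b$n_hidden, seed = b$seed),
      class = "mlp_block")
    norm <- lapply(b$norm, function(p) {
      if (is.null(p) || length(p) == 0L) return(NULL)
      norm_params(p$kind, p$center, p$scale, isTRUE(p$clip))
    })
    rep_of <- function(r) structure(c(r, list(per_example = NULL)),
                                    class = "error_report")
    list(model = model, norm = norm, dataset = list(features = b$features),
         train_report = rep_of(b$train_error), test_report = rep_of(b$test_error))
  }
  weights <- confidence_weights(doc$weights$err_l, doc$weights$err_s,
                                metal = doc$metal,
                                inverse = doc$weights$scheme ==
                                  "inverse_error")
  structure(
    list(metal = doc$metal,
         blocks = list(long = de_block(doc$blocks$long),
                       short = de_block(doc$blocks$short)),
         weights = weights, seed = doc$seed,
         config = do.call(rprop_config, doc$config[c(
           "eta_minus", "eta_plus", "delta_init", "delta_min", "delta_max",
           "epochs")]),
         n_hidden = doc$n_hidden, zscore = isTRUE(doc$zscore),
         call = NULL),
    class = "double_loop")
}
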