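#' Fit a double-loop retention model for one metal
#'
#' Trains the two exposure blocks of the double-loop model — a long-term
#' block (7 inputs: physiology + drinking-water + soil metal content) and a
#' short-term block (6 inputs: physiology + drinking-water only) — each on
#' its own 80/20 split of its own assembled dataset, then combines them
#' into the closed-loop model by error-weighted fusion.  Each block is a
#' single-hidden-layer perceptron (5 tanh(0.7x) hidden neurons, linear
#' output) trained by full-batch resilient backpropagation; features and
#' target are affinely mapped to \eqn{[-1,1]} on the training split only.
#'
#' @param cohort cohort data.frame in the cohort CSV schema
#'   (see [read_cohort()] and [simulate_cohort()]).
#' @param metal one of \code{"zn"}, \code{"cr"}, \code{"cu"}, \code{"pb"}.
#' @param seed integer seed governing the split and the weight
#'   initialisation of both blocks.
#' @param config an [rprop_config()]; lower \code{epochs} for quick runs.
#' @param n_hidden hidden-layer width (default 5).
#' @param test_fraction held-out fraction per block (default 0.2).
#' @param inverse_error_weights use the conventional inverse-error
#'   confidence scheme instead of the error-proportional one
#'   (default \code{FALSE}; see [confidence_weights()]).
#' @param zscore also standardise features (z-score fitted on the training
#'   split) before the \eqn{[-1,1]} map (default \code{FALSE}).
#' @param gross_filter apply the one-pass [clean_gross_errors()] filter to
#'   the exposure columns (water, soil) before training, dropping subjects
#'   with outlying concentrations, as the data-cleaning stage of the
#'   method prescribes (default \code{FALSE}).
#' @param k_sigma rejection band of the gross-error filter (default 3).
#' @return object of class \code{"double_loop"}: the two trained blocks
#'   with their normalisation parameters and train/test [error_report()]s,
#'   the [confidence_weights()], and fit metadata.
#' @examples
#' coh <- simulate_cohort(cohort_config(n = 120, seed = 1))
#' fit <- double_loop(coh, "zn", seed = 1,
#'                    config = rprop_config(epochs = 300))
#' fit
#' head(predict(fit, coh))
#' @export
double_loop <- function(cohort, metal = METALS, seed,
                        config = rprop_config(), n_hidden = 5,
                        test_fraction = 0.2,
                        inverse_error_weights = FALSE, zscore = FALSE,
                        gross_filter = FALSE, k_sigma = 3) {
  metal <- match.arg(metal)
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  if (gross_filter)
    cohort <- filter_exposure_outliers(cohort, metal, k_sigma)
  blocks <- list(
    long  = fit_block(assemble_dataset(cohort, metal, "long_term"),
                      seed = block_seed(seed, 1L), config = config,
                      n_hidden = n_hidden, test_fraction = test_fraction,
                      split_seed = seed, zscore = zscore),
    short = fit_block(assemble_dataset(cohort, metal, "short_term"),
                      seed = block_seed(seed, 2L), config = config,
                      n_hidden = n_hidden, test_fraction = test_fraction,
                      split_seed = seed, zscore = zscore))
  ## closed loop is built only after both blocks are trained and tested
  weights <- confidence_weights(blocks$long$test_report$mean,
                                blocks$short$test_report$mean,
                                metal = metal,
                                inverse = inverse_error_weights)
  structure(
    list(metal = metal, blocks = blocks, weights = weights,
         seed = seed, config = config, n_hidden = n_hidden,
         test_fraction = test_fraction, zscore = zscore,
         call = match.call()),
    class = "double_loop")
}

block_seed <- function(seed, k) as.integer((seed + 7919L * k) %% 2147483647L)

## Drop subjects whose water or soil concentration for this metal is a
## gross error (one-pass k-sigma rule on each exposure column).
filter_exposure_outliers <- function(cohort, metal, k_sigma = 3) {
  keep <- seq_len(nrow(cohort))
  for (col in paste0(metal, c("_water_mgl", "_soil_mgkg"))) {
    if (!col %in% names(cohort)) next
    v <- cohort[[col]][keep]
    ok <- !is.na(v)
    retained <- clean_gross_errors(ifelse(ok, v, mean(v, na.rm = TRUE)),
                                   k_sigma)
    keep <- keep[union(retained, which(!ok))]
    keep <- sort(keep)
  }
  cohort[keep, , drop = FALSE]
}

## Train one exposure block on its own split of its own dataset.
fit_block <- function(ds, seed, config, n_hidden = 5, test_fraction = 0.2,
                      split_seed = seed, zscore = FALSE) {
  if (nrow(ds$x) < 20L)
    stop("need at least 20 usable records to train a block (got ",
         nrow(ds$x), ")", call. = FALSE)
  split <- split_train_test(nrow(ds$x), test_fraction, seed = split_seed)
  fit_block_idx(ds, split$train, split$test, seed, config, n_hidden, zscore)
}

fit_block_idx <- function(ds, train_idx, test_idx, seed, config,
                          n_hidden = 5, zscore = FALSE) {
  x_tr <- ds$x[train_idx, , drop = FALSE]
  y_tr <- ds$y[train_idx]
  z_params <- NULL
  if (zscore) {
    zf <- zscore_fit(x_tr)
    x_tr <- zf$x
    z_params <- zf$params
  }
  xf <- range_fit(x_tr)
  yf <- range_fit(matrix(y_tr, ncol = 1L, dimnames = list(NULL, "retention")))
  model <- mlp_init(ncol(ds$x), n_hidden, seed = seed)
  fit <- mlp_train(model, xf$x, drop(yf$x), config)
  norm <- list(z = z_params, x = xf$params, y = yf$params)
  train_report <- mlp_evaluate(fit$model, xf$x, drop(yf$x))
  test_report <- block_report(fit$model, norm, ds, test_idx)
  list(model = fit$model, norm = norm, dataset = ds,
       train_idx = train_idx, test_idx = test_idx,
       history = fit$history, best_epoch = fit$best_epoch,
       final_loss = fit$final_loss,
       train_report = train_report, test_report = test_report)
}

## Error report of a trained block on dataset rows, normalised scale.
block_report <- function(model, norm, ds, idx) {
  x <- ds$x[idx, , drop = FALSE]
  if (!is.null(norm$z)) x <- apply_norm(x, norm$z)
  pred <- mlp_forward(model, apply_norm(x, norm$x))
  ref <- drop(apply_norm(matrix(ds$y[idx], ncol = 1L), norm$y))
  error_report(pred, ref)
}

## Forward pass of one block on cohort-schema rows, on the retention scale.
block_predict <- function(block, newdata, metal, exposure, clip = FALSE) {
  feats <- block_features(metal, exposure)
  missing_cols <- setdiff(feats, names(newdata))
  if (length(missing_cols))
    stop("missing feature(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  x <- as.matrix(newdata[, feats, drop = FALSE])
  if (!is.null(block$norm$z)) x <- apply_norm(x, block$norm$z)
  out <- mlp_forward(block$model, apply_norm(x, block$norm$x))
  r <- drop(invert_norm(matrix(out, ncol = 1L), block$norm$y))
  oob <- r <= 0 | r >= 1
  if (any(oob) && !clip)
    warning(sum(oob), " block output(s) outside (0;1) on the retention scale",
            call. = FALSE)
  if (clip) r <- pmin(pmax(r, 1e-6), 1 - 1e-6)
  r
}

#' Confidence coefficients from block test errors
#'
#' The closed-loop fusion weights each block by a confidence coefficient
#' derived from its aggregate test error.  The default scheme is
#' error-proportional, exactly as the method prescribes:
#' \deqn{a_l = \frac{Err^T(l)}{Err^T(l) + Err^T(s)}, \quad
#'       a_s = \frac{Err^T(s)}{Err^T(l) + Err^T(s)}}
#' (the larger weight goes to the block with the larger test error).  The
#' conventional inverse-error alternative is available with
#' \code{inverse = TRUE} for comparison.
#'
#' @param err_l aggregate test error of the long-term block (>= 0).
#' @param err_s aggregate test error of the short-term block (>= 0);
#'   the two must not both be zero.
#' @param metal optional metal label carried along for reporting.
#' @param inverse use inverse-error weighting (default \code{FALSE}).
#' @return object of class \code{"confidence_weights"} with \code{a_l},
#'   \code{a_s} (non-negative, summing to 1), the source errors and the
#'   scheme used.
#' @examples
#' confidence_weights(0.1183, 0.0849)   # a_l ~ 0.5822, a_s ~ 0.4178
#' @export
confidence_weights <- function(err_l, err_s, metal = NULL, inverse = FALSE) {
  stopifnot(is.numeric(err_l), is.numeric(err_s),
            length(err_l) == 1L, length(err_s) == 1L)
  if (err_l < 0 || err_s < 0)
    stop("block errors must be non-negative", call. = FALSE)
  if (err_l + err_s <= 0)
    stop("both block errors are zero: confidence weights are undefined",
         call. = FALSE)
  if (inverse) {
    if (err_l == 0 || err_s == 0) {
      a_l <- as.numeric(err_l == 0)
    } else {
      a_l <- (1 / err_l) / (1 / err_l + 1 / err_s)
    }
  } else {
    a_l <- err_l / (err_l + err_s)
  }
  structure(list(a_l = a_l, a_s = 1 - a_l, err_l = err_l, err_s = err_s,
                 metal = metal,
                 scheme = if (inverse) "inverse_error" else
                   "error_proportional"),
            class = "confidence_weights")
}

#' @export
print.confidence_weights <- function(x, ...) {
  cat(sprintf("Confidence weights (%s%s): a_l = %.4f, a_s = %.4f\n",
              x$scheme, if (is.null(x$metal)) "" else paste0(", ", x$metal),
              x$a_l, x$a_s))
  invisible(x)
}

#' Fuse the two block outputs
#'
#' Convex combination of the long- and short-term retention estimates with
#' the block confidence coefficients:
#' \eqn{Retention = a_l Retention^l + a_s Retention^s}.  The fused value
#' always lies within the interval spanned by the two block outputs.
#'
#' @param retention_l,retention_s block outputs on the retention scale
#'   (vectorised).
#' @param weights a [confidence_weights()] object, or a numeric vector
#'   \code{c(a_l, a_s)} summing to 1.
#' @return fused retention values.
#' @export
fuse <- function(retention_l, retention_s, weights) {
  if (inherits(weights, "confidence_weights"))
    weights <- c(weights$a_l, weights$a_s)
  if (length(weights) != 2L || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-9)
    stop("'weights' must be two non-negative coefficients summing to 1",
         call. = FALSE)
  if (any(!is.finite(retention_l)) || any(!is.finite(retention_s)))
    stop("block outputs must be finite", call. = FALSE)
  weights[1L] * retention_l + weights[2L] * retention_s
}

#' Predict retention for new subjects
#'
#' Applies each block's stored normalisation, runs both forward passes,
#' inverse-maps the outputs to the retention scale and fuses them with the
#' model's confidence coefficients.  Raw block outputs may fall outside
#' (0;1) for inputs far from the training range; they are reported with a
#' warning unless \code{clip = TRUE}.
#'
#' @param object a fitted [double_loop()] model.
#' @param newdata cohort-schema data.frame carrying all 7 long-term
#'   features for the model's metal.
#' @param clip clip block outputs into (0;1)? Default \code{FALSE}.
#' @param ... unused.
#' @return data.frame with columns \code{retention_l}, \code{retention_s}
#'   and \code{retention} (the fused estimate), one row per subject.
#' @export
predict.double_loop <- function(object, newdata, clip = FALSE, ...) {
  stopifnot(is.data.frame(newdata))
  r_l <- block_predict(object$blocks$long, newdata, object$metal,
                       "long_term", clip = clip)
  r_s <- block_predict(object$blocks$short, newdata, object$metal,
                       "short_term", clip = clip)
  data.frame(retention_l = r_l, retention_s = r_s,
             retention = fuse(r_l, r_s, object$weights))
}

#' @export
print.double_loop <- function(x, digits = 4, ...) {
  cat("Double-loop retention model —", toupper(x$metal), "\n")
  cat(sprintf("  long block : %d-%d-1, train err %.*g, test err %.*g\n",
              x$blocks$long$model$n_inputs, x$n_hidden,
              digits, x$blocks$long$train_report$mean,
              digits, x$blocks$long$test_report$mean))
  cat(sprintf("  short block: %d-%d-1, train err %.*g, test err %.*g\n",
              x$blocks$short$model$n_inputs, x$n_hidden,
              digits, x$blocks$short$train_report$mean,
              digits, x$blocks$short$test_report$mean))
  cat(sprintf("  confidence : a_l = %.4f, a_s = %.4f (%s)\n",
              x$weights$a_l, x$weights$a_s, x$weights$scheme))
  invisible(x)
}

#' @export
summary.double_loop <- function(object, ...) {
  rep_row <- function(r) c(min = r$min, max = r$max, mean = r$mean, n = r$n)
  tab <- rbind(
    `long / train`  = rep_row(object$blocks$long$train_report),
    `long / test`   = rep_row(object$blocks$long$test_report),
    `short / train` = rep_row(object$blocks$short$train_report),
    `short / test`  = rep_row(object$blocks$short$test_report))
  structure(list(metal = object$metal, errors = tab,
                 weights = object$weights, seed = object$seed,
                 epochs = object$config$epochs),
            class = "summary.double_loop")
}

#' @export
print.summary.double_loop <- function(x, ...) {
  cat("Double-loop retention model —", toupper(x$metal), "\n")
  cat(sprintf("  seed %d, %d RPROP epochs per block\n", x$seed, x$epochs))
  cat("\nSquared errors (normalised scale):\n")
  print(signif(x$errors, 4))
  cat("\n")
  print(x$weights)
  invisible(x)
}

#' @export
coef.double_loop <- function(object, ...) {
  lapply(object$blocks, function(b)
    list(w1 = b$model$w1, b1 = b$model$b1, w2 = b$model$w2, b2 = b$model$b2))
}

#' @export
fitted.double_loop <- function(object, ...) {
  ## fused fit on the long block's dataset rows (full cohort after drops);
  ## the short block's features are a subset of the long block's columns
  ds <- object$blocks$long$dataset
  predict(object, as.data.frame(ds$x))$retention
}

#' @export
residuals.double_loop <- function(object, ...) {
  ds <- object$blocks$long$dataset
  ds$y - fitted(object)
}

#' @export
plot.double_loop <- function(x, ...) {
  ds <- x$blocks$long$dataset
  ord <- order(ds$y)
  fit <- suppressWarnings(fitted(x))
  graphics::plot(ds$y[ord], type = "l", lwd = 2,
                 xlab = "subjects (ordered by reference retention)",
                 ylab = "retention",
                 main = paste("Closed-loop retention —", toupper(x$metal)),
                 ylim = range(c(ds$y, fit)), ...)
  graphics::lines(fit[ord], col = "firebrick")
  graphics::legend("topleft", c("reference", "fused model"),
                   col = c("black", "firebrick"), lwd = c(2, 1), bty = "n")
  invisible(x)
}

#' Sequential-shift k-fold cross-validation of the double-loop model
#'
#' Re-trains both blocks \code{k} times; fold \code{j} tests the contiguous
#' window of 1/k of the rows selected by sequential shift from the first
#' element (see [sequential_shift_folds()]), training on the remainder.
#' Weights are re-initialised to small random values per fold.  A fold
#' whose training data is degenerate (e.g. a constant feature) is marked
#' failed and the remaining folds proceed.
#'
#' @inheritParams double_loop
#' @param k number of folds (default 5).
#' @return object of class \code{"double_loop_cv"}: per-fold
#'   [error_report()]s for each block and the fused output (retention
#'   scale), plus a mean/sd summary across folds.
#' @export
cross_validate <- function(cohort, metal = METALS, k = 5, seed,
                           config = rprop_config(), n_hidden = 5,
                           inverse_error_weights = FALSE, zscore = FALSE,
                           gross_filter = FALSE, k_sigma = 3) {
  metal <- match.arg(metal)
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  if (gross_filter)
    cohort <- filter_exposure_outliers(cohort, metal, k_sigma)
  ds_l <- assemble_dataset(cohort, metal, "long_term")
  ds_s <- assemble_dataset(cohort, metal, "short_term")
  n <- nrow(ds_l$x)
  if (n < 5L * k) stop("need at least ", 5L * k, " rows for ", k,
                       "-fold validation", call. = FALSE)
  folds <- sequential_shift_folds(n, k)
  out <- vector("list", k)
  for (j in seq_len(k)) {
    test_idx <- folds[[j]]
    train_idx <- setdiff(seq_len(n), test_idx)
    out[[j]] <- tryCatch({
      bl <- fit_block_idx(ds_l, train_idx, test_idx,
                          seed = block_seed(seed, 10L * j + 1L),
                          config = config, n_hidden = n_hidden,
                          zscore = zscore)
      bs <- fit_block_idx(ds_s, train_idx, test_idx,
                          seed = block_seed(seed, 10L * j + 2L),
                          config = config, n_hidden = n_hidden,
                          zscore = zscore)
      w <- confidence_weights(bl$test_report$mean, bs$test_report$mean,
                              metal = metal, inverse = inverse_error_weights)
      nd <- as.data.frame(ds_l$x[test_idx, , drop = FALSE])
      r_l <- suppressWarnings(block_predict(bl, nd, metal, "long_term"))
      r_s <- suppressWarnings(block_predict(bs, nd, metal, "short_term"))
      fused <- error_report(fuse(r_l, r_s, w), ds_l$y[test_idx])
      list(long = bl$test_report, short = bs$test_report, weights = w,
           fused = fused, failed = FALSE)
    }, error = function(e) list(failed = TRUE, message = conditionMessage(e)))
  }
  summarise_cv(out, metal, k, seed, folds)
}

summarise_cv <- function(folds_out, metal, k, seed, folds) {
  ok <- !vapply(folds_out, `[[`, logical(1L), "failed")
  mean_of <- function(what)
    vapply(folds_out[ok], function(f) f[[what]]$mean, numeric(1L))
  summary <- if (any(ok)) {
    rbind(long  = c(mean = mean(mean_of("long")),  sd = stats::sd(mean_of("long"))),
          short = c(mean = mean(mean_of("short")), sd = stats::sd(mean_of("short"))),
          fused = c(mean = mean(mean_of("fused")), sd = stats::sd(mean_of("fused"))))
  } else NULL
  structure(list(metal = metal, k = k, seed = seed, folds = folds_out,
                 fold_indices = folds, failed = which(!ok),
                 summary = summary),
            class = "double_loop_cv")
}

#' @export
print.double_loop_cv <- function(x, ...) {
  cat(sprintf("%d-fold sequential-shift validation — %s (seed %d)\n",
              x$k, toupper(x$metal), x$seed))
  if (length(x$failed))
    cat("  failed fold(s):", paste(x$failed, collapse = ", "), "\n")
  if (!is.null(x$summary)) {
    cat("  mean squared error across folds (blocks on the normalised",
        "scale,\n  fused on the retention scale):\n")
    print(signif(x$summary, 4))
  }
  invisible(x)
}
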