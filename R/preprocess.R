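## Feature sets for the two exposure blocks.  Order is fixed and documented:
## the long-term block sees soil as well; the short-term block does not.
LONG_FEATURES  <- c("weight_kg", "height_cm", "body_area_m2", "age_years",
                    "sex", "water_mgl", "soil_mgkg")
SHORT_FEATURES <- setdiff(LONG_FEATURES, "soil_mgkg")

METALS <- c("zn", "cr", "cu", "pb")

#' One-pass gross-error filter
#'
#' Retains the indices of values lying within \code{mean +/- k_sigma * sd}
#' of the series (sample standard deviation), in a single pass.  A constant
#' series has zero spread and nothing is flagged.
#'
#' @param values numeric vector with at least 3 finite values.
#' @param k_sigma rejection band half-width in standard deviations
#'   (default 3).
#' @return integer vector of retained indices; the number of removed values
#'   is reported as a message when positive.
#' @export
clean_gross_errors <- function(values, k_sigma = 3) {
  if (length(values) < 3L || any(!is.finite(values)))
    stop("need at least 3 finite values for gross-error filtering",
         call. = FALSE)
  if (!is.numeric(k_sigma) || length(k_sigma) != 1L || k_sigma <= 0)
    stop("'k_sigma' must be a single positive number", call. = FALSE)
  m <- mean(values)
  s <- stats::sd(values)
  if (s == 0) return(seq_along(values))
  keep <- which(abs(values - m) <= k_sigma * s)
  removed <- length(values) - length(keep)
  if (removed > 0L)
    message(removed, " value(s) removed as gross errors (", k_sigma,
            "-sigma band)")
  keep
}

#' Z-score standardisation
#'
#' Centres and scales each column to zero mean and unit variance
#' (population standard deviation).  Returns the fitted parameters so the
#' transform is exactly invertible.
#'
#' @param x numeric matrix (or data.frame of numerics).
#' @return list with \code{x} (standardised matrix) and \code{params}
#'   (a \code{norm_params} object of kind \code{"zscore"}).
#' @seealso [apply_norm()], [invert_norm()]
#' @export
zscore_fit <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 rows to standardise", call. = FALSE)
  mu <- colMeans(x)
  sd_pop <- sqrt(colMeans(sweep(x, 2L, mu)^2))
  bad <- which(sd_pop <= 0)
  if (length(bad))
    stop("zero-spread column(s): ",
         paste(colname_or_idx(x, bad), collapse = ", "), call. = FALSE)
  params <- norm_params("zscore", center = mu, scale = sd_pop)
  list(x = apply_norm(x, params), params = params)
}

#' Affine scaling to the symmetric unit interval [-1, 1]
#'
#' Fits per-column min/max and maps \code{x -> 2 (x - min)/(max - min) - 1}.
#' Fitted columns span exactly \eqn{[-1,1]}; values outside the fitted range
#' extrapolate beyond it unless \code{clip = TRUE}.
#'
#' @param x numeric matrix (or data.frame of numerics).
#' @param clip clip transformed values into \eqn{[-1,1]}? Default \code{FALSE}.
#' @return list with \code{x} (scaled matrix) and \code{params}
#'   (a \code{norm_params} object of kind \code{"range"}).
#' @export
range_fit <- function(x, clip = FALSE) {
  x <- as.matrix(x)
  lo <- apply(x, 2L, min)
  hi <- apply(x, 2L, max)
  bad <- which(hi <= lo)
  if (length(bad))
    stop("constant column(s), cannot scale to [-1,1]: ",
         paste(colname_or_idx(x, bad), collapse = ", "), call. = FALSE)
  params <- norm_params("range", center = lo, scale = hi - lo, clip = clip)
  list(x = apply_norm(x, params), params = params)
}

norm_params <- function(kind, center, scale, clip = FALSE) {
  structure(list(kind = kind, center = center, scale = scale, clip = clip),
            class = "norm_params")
}

colname_or_idx <- function(x, idx) {
  nm <- colnames(x)
  if (is.null(nm)) paste0("column ", idx) else nm[idx]
}

#' Apply fitted normalisation parameters
#'
#' @param x numeric matrix or vector with the same columns the parameters
#'   were fitted on.
#' @param params a \code{norm_params} object from [zscore_fit()] or
#'   [range_fit()].
#' @return transformed matrix.
#' @export
apply_norm <- function(x, params) {
  stopifnot(inherits(params, "norm_params"))
  x <- as.matrix(x)
  if (ncol(x) != length(params$center))
    stop("column count does not match fitted normalisation parameters",
         call. = FALSE)
  z <- sweep(sweep(x, 2L, params$center), 2L, params$scale, "/")
  if (params$kind == "range") {
    z <- 2 * z - 1
    if (isTRUE(params$clip)) z <- pmin(pmax(z, -1), 1)
  }
  z
}

#' Invert fitted normalisation parameters
#'
#' Exact inverse of [apply_norm()]; the round trip is the identity to
#' floating-point accuracy.
#'
#' @inheritParams apply_norm
#' @return matrix on the original scale.
#' @export
invert_norm <- function(x, params) {
  stopifnot(inherits(params, "norm_params"))
  x <- as.matrix(x)
  if (params$kind == "range") x <- (x + 1) / 2
  sweep(sweep(x, 2L, params$scale, "*"), 2L, params$center, "+")
}

#' Assemble a per-metal training dataset
#'
#' Selects the feature columns of one exposure block for one metal, in the
#' fixed documented order (weight, height, body area, age, sex, water and —
#' long-term only — soil), attaches the retention target, and drops rows
#' with missing values (the dropped count is reported).  If the cohort table
#' has no \code{<metal>_retention} column the target is computed from the
#' biosubstrate columns via [clearance_reberg()] and [retention_series()].
#'
#' @param cohort cohort data.frame in the cohort CSV schema (see
#'   [read_cohort()]).
#' @param metal one of \code{"zn"}, \code{"cr"}, \code{"cu"}, \code{"pb"}.
#' @param exposure \code{"long_term"} (7 features) or \code{"short_term"}
#'   (6 features).
#' @return list of class \code{"retention_dataset"}: \code{x} feature matrix,
#'   \code{y} retention targets in (0;1), \code{codes} participant codes,
#'   \code{metal}, \code{exposure}, \code{features}.
#' @export
assemble_dataset <- function(cohort, metal = METALS,
                             exposure = c("long_term", "short_term")) {
  metal <- match.arg(metal)
  exposure <- match.arg(exposure)
  stopifnot(is.data.frame(cohort))
  feats <- block_features(metal, exposure)
  target_col <- paste0(metal, "_retention")
  if (!target_col %in% names(cohort))
    cohort[[target_col]] <- cohort_retention(cohort, metal)
  need <- c(feats, target_col)
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols))
    stop("cohort lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  sub <- cohort[, need, drop = FALSE]
  ok <- stats::complete.cases(sub)
  if (!all(ok))
    message(sum(!ok), " row(s) dropped for missing fields")
  sub <- sub[ok, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no usable rows after dropping missing fields",
                            call. = FALSE)
  if (nrow(sub) < 60L || nrow(sub) > 242L)
    warning("dataset has ", nrow(sub),
            " rows, outside the expected 60-242 range", call. = FALSE)
  codes <- if ("participant_code" %in% names(cohort))
    cohort$participant_code[ok] else seq_len(nrow(cohort))[ok]
  x <- as.matrix(sub[, feats, drop = FALSE])
  colnames(x) <- feats
  structure(
    list(x = x, y = sub[[target_col]], codes = codes,
         metal = metal, exposure = exposure, features = feats),
    class = "retention_dataset")
}

block_features <- function(metal, exposure) {
  base <- if (exposure == "long_term") LONG_FEATURES else SHORT_FEATURES
  vapply(base, function(f) {
    switch(f,
           water_mgl = paste0(metal, "_water_mgl"),
           soil_mgkg = paste0(metal, "_soil_mgkg"),
           f)
  }, character(1L), USE.NAMES = FALSE)
}

## Retention target from biosubstrate columns when not provided directly.
cohort_retention <- function(cohort, metal) {
  need <- c(paste0(metal, c("_urine_ugml", "_blood_ugml")), "diuresis_ml",
            "body_area_m2")
  if (!all(need %in% names(cohort)))
    stop("cohort has neither '", metal, "_retention' nor the biosubstrate ",
         "columns (", paste(need, collapse = ", "),
         ") needed to compute it", call. = FALSE)
  cl <- clearance_reberg(cohort[[need[1L]]], cohort[[need[2L]]],
                         cohort$diuresis_ml, cohort$body_area_m2)
  retention_series(cl)$retention
}

#' @export
print.retention_dataset <- function(x, ...) {
  cat(sprintf("Retention dataset: metal %s, %s block, %d x %d features\n",
              x$metal, sub("_", "-", x$exposure), nrow(x$x), ncol(x$x)))
  invisible(x)
}

#' Seeded random train/test split
#'
#' Uniform sampling without replacement of \code{round(n * test_fraction)}
#' test rows; the split is disjoint, exhaustive and reproducible for equal
#' seeds.
#'
#' @param n number of rows (at least 5).
#' @param test_fraction fraction of rows in the test set, in (0,1);
#'   default 0.2.
#' @param seed integer seed (required, so splits are always reproducible).
#' @return list with integer index vectors \code{train} and \code{test}.
#' @export
split_train_test <- function(n, test_fraction = 0.2, seed) {
  if (n < 5L) stop("need at least 5 rows to split", call. = FALSE)
  if (!is.numeric(test_fraction) || test_fraction <= 0 || test_fraction >= 1)
    stop("'test_fraction' must lie strictly between 0 and 1", call. = FALSE)
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  n_test <- round(n * test_fraction)
  test <- local_seed(seed, sort(sample.int(n, n_test)))
  list(train = setdiff(seq_len(n), test), test = test)
}

## Run expr under a temporary RNG state; restores the caller's state.
local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Contiguous fold windows by sequential shift
#'
#' Splits \code{1..n} into \code{k} contiguous test windows, fold \code{j}
#' (1-based) testing rows \code{(floor((j-1) n/k) + 1) .. floor(j n/k)}.
#' The windows are pairwise disjoint and partition the full index range, so
#' every \code{n >= k} is handled.
#'
#' @param n number of rows.
#' @param k number of folds (default 5, i.e. each window is 20\% of the
#'   sample, shifted sequentially from the first element).
#' @return list of \code{k} integer index vectors.
#' @export
sequential_shift_folds <- function(n, k = 5) {
  if (n < k) stop("'n' must be at least 'k'", call. = FALSE)
  bounds <- floor((0:k) * n / k)
  lapply(seq_len(k), function(j) seq.int(bounds[j] + 1L, bounds[j + 1L]))
}
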