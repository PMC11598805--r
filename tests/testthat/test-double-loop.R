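test_that("confidence weights follow the error-proportional formula", {
  w <- confidence_weights(0.1183, 0.0849)
  expect_equal(w$a_l, 0.1183 / (0.1183 + 0.0849), tolerance = 1e-12)
  expect_equal(w$a_l + w$a_s, 1, tolerance = 1e-12)
  # symmetry and boundary
  expect_equal(confidence_weights(0.2, 0.2)$a_l, 0.5)
  w0 <- confidence_weights(0, 0.3)
  expect_equal(c(w0$a_l, w0$a_s), c(0, 1))
  expect_error(confidence_weights(0, 0), "undefined")
  expect_error(confidence_weights(-0.1, 0.2), "non-negative")
})

test_that("confidence weights are scale invariant", {
  set.seed(4)
  for (i in 1:50) {
    e <- runif(2, 1e-6, 1)
    w1 <- confidence_weights(e[1], e[2])
    for (c_scale in c(1e-3, 0.7, 1e4)) {
      w2 <- confidence_weights(c_scale * e[1], c_scale * e[2])
      expect_equal(w2$a_l, w1$a_l, tolerance = 1e-12)
      expect_equal(w2$a_s, w1$a_s, tolerance = 1e-12)
    }
  }
})

test_that("inverse-error scheme favours the more accurate block", {
  w <- confidence_weights(0.1, 0.3, inverse = TRUE)
  expect_gt(w$a_l, w$a_s)
  expect_equal(w$a_l, 0.75)
  expect_equal(confidence_weights(0, 0.3, inverse = TRUE)$a_l, 1)
})

test_that("fusion is the convex combination of the block outputs", {
  expect_equal(fuse(0.4, 0.6, c(0.5, 0.5)), 0.5)
  expect_equal(fuse(0.37, 0.9, c(1, 0)), 0.37)
  w <- confidence_weights(0.5821, 0.4178)  # renormalised printed weights
  expect_equal(fuse(0.2, 0.8, w), w$a_l * 0.2 + w$a_s * 0.8)
  expect_equal(fuse(0.2, 0.8, w), 0.4507, tolerance = 5e-4)
  expect_error(fuse(0.2, 0.8, c(0.6, 0.5)), "summing to 1")
  # convexity property over random inputs
  set.seed(6)
  for (i in 1:100) {
    r <- runif(2); a <- runif(1)
    f <- fuse(r[1], r[2], c(a, 1 - a))
    expect_gte(f, min(r) - 1e-12)
    expect_lte(f, max(r) + 1e-12)
  }
})

test_that("double-loop fit is deterministic and self-consistent", {
  coh <- small_cohort(n = 80)
  fit1 <- double_loop(coh, "zn", seed = 7, config = quick_config())
  fit2 <- double_loop(coh, "zn", seed = 7, config = quick_config())
  expect_equal(fit1$blocks$long$test_report, fit2$blocks$long$test_report)
  expect_equal(fit1$weights$a_l, fit2$weights$a_l)
  expect_equal(fit1$blocks$long$model$n_inputs, 7)
  expect_equal(fit1$blocks$short$model$n_inputs, 6)
  expect_equal(fit1$weights$a_l + fit1$weights$a_s, 1, tolerance = 1e-12)
  # predictions: fused lies between blocks; near-zero-residual training
  # rows come back close to their reference
  pred <- suppressWarnings(predict(fit1, coh))
  expect_true(all(pred$retention >= pmin(pred$retention_l, pred$retention_s) - 1e-12))
  expect_true(all(pred$retention <= pmax(pred$retention_l, pred$retention_s) + 1e-12))
  resid <- abs(pred$retention - coh$zn_retention)
  expect_lt(median(resid), 0.15)
})

test_that("prediction demands the full feature set and flags range escapes", {
  coh <- small_cohort(n = 80)
  fit <- double_loop(coh, "zn", seed = 7, config = quick_config())
  expect_error(predict(fit, coh[, setdiff(names(coh), "zn_soil_mgkg")]),
               "zn_soil_mgkg")
  # force a block output out of (0;1): shift the long block's output bias
  # far beyond the fitted target range and observe the escape is reported
  shifted <- fit
  shifted$blocks$long$model$b2 <- shifted$blocks$long$model$b2 + 10
  expect_warning(predict(shifted, coh[1, ]), "outside")
  expect_silent(predict(shifted, coh[1, ], clip = TRUE))
  clipped <- predict(shifted, coh[1, ], clip = TRUE)
  expect_true(all(clipped >= 0 & clipped <= 1))
})

test_that("a degenerate feature column refuses block training", {
  coh <- small_cohort(n = 80)
  coh$zn_water_mgl <- 0.2
  expect_error(double_loop(coh, "zn", seed = 1, config = quick_config()),
               "constant")
})

test_that("blocks train separately: short block ignores soil", {
  coh <- small_cohort(n = 80)
  fit <- double_loop(coh, "zn", seed = 3, config = quick_config())
  coh2 <- coh
  coh2$zn_soil_mgkg <- rev(coh2$zn_soil_mgkg)
  fit2 <- double_loop(coh2, "zn", seed = 3, config = quick_config())
  expect_equal(fit2$blocks$short$test_report$mean,
               fit$blocks$short$test_report$mean)
  expect_false(isTRUE(all.equal(fit2$blocks$long$test_report$mean,
                                fit$blocks$long$test_report$mean)))
})

test_that("model accessors: summary, coef, fitted, residuals, plot", {
  coh <- small_cohort(n = 80)
  fit <- double_loop(coh, "cu", seed = 5, config = quick_config())
  s <- summary(fit)
  expect_equal(dim(s$errors), c(4, 4))
  expect_true(all(s$errors[, "min"] <= s$errors[, "mean"]))
  cf <- coef(fit)
  expect_equal(dim(cf$long$w1), c(5, 7))
  expect_equal(dim(cf$short$w1), c(5, 6))
  ft <- suppressWarnings(fitted(fit))
  rs <- suppressWarnings(residuals(fit))
  expect_equal(length(ft), 80)
  expect_equal(rs, fit$blocks$long$dataset$y - ft)
  tmp <- tempfile(fileext = ".png")
  grDevices::png(tmp)
  expect_invisible(suppressWarnings(plot(fit)))
  grDevices::dev.off()
  expect_true(file.exists(tmp))
  unlink(tmp)
  expect_output(print(fit), "Double-loop")
})

test_that("cross-validation windows partition rows and errors are sane", {
  coh <- small_cohort(n = 100, seed = 33)
  cv <- cross_validate(coh, "zn", k = 5, seed = 2, config = quick_config())
  expect_length(cv$folds, 5)
  expect_equal(sort(unlist(cv$fold_indices)), 1:100)
  expect_length(cv$failed, 0)
  expect_equal(cv$folds[[1]]$long$n, 20)
  expect_true(all(is.finite(cv$summary)))
  # a fold-degenerate feature fails that fold but not the others
  coh2 <- coh
  coh2$zn_water_mgl[21:100] <- 0.2   # folds 2..5 train on constant water
  cv2 <- suppressWarnings(
    cross_validate(coh2, "zn", k = 5, seed = 2, config = quick_config()))
  expect_true(length(cv2$failed) >= 1)
  expect_true(length(cv2$failed) < 5)
})
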