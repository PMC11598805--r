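test_that("activation registry matches closed forms and derivatives", {
  a <- activation_eval(activation_spec("tanh", 0.7), 0)
  expect_equal(a$value, 0)
  expect_equal(a$deriv, 0.7)
  expect_equal(activation_eval(activation_spec("tanh", 0.7), 1)$value,
               tanh(0.7))
  expect_equal(activation_eval(activation_spec("sigmoid"), 0)$value, 0.5)
  expect_equal(activation_eval(activation_spec("linear", gain = 2), 3)$value, 6)
  expect_equal(activation_eval(activation_spec("relu"), -2)$value, 0)
  expect_equal(activation_eval(activation_spec("threshold"), 2)$value, 1)
  # deep-negative selu approaches -lambda*alpha
  expect_equal(activation_eval(activation_spec("selu"), -40)$value,
               -1.0507 * 1.6732, tolerance = 1e-6)
  expect_error(activation_spec("softplus"))
})

test_that("initialisation is seeded, shaped, and within [-0.5, 0.5]", {
  m1 <- mlp_init(7, 5, seed = 99)
  m2 <- mlp_init(7, 5, seed = 99)
  expect_identical(m1, m2)
  expect_equal(dim(m1$w1), c(5, 7))
  expect_equal(dim(m1$w2), c(1, 5))
  expect_true(all(abs(c(m1$w1, m1$w2)) <= 0.5))
  expect_equal(c(m1$b1, m1$b2), rep(0, 6))
  expect_false(identical(m1$w1, mlp_init(7, 5, seed = 100)$w1))
  expect_error(mlp_init(0, 5, seed = 1), "positive")
})

test_that("forward pass: bias-only nets, hand value, output linearity", {
  m <- mlp_init(3, 4, seed = 1)
  m$w1[] <- 0; m$w2[] <- 0; m$b2 <- 0.3
  expect_equal(mlp_forward(m, matrix(rnorm(15), 5, 3)), rep(0.3, 5))
  # 1-1-1 net with unit weights: output = tanh(0.7 * 1)
  m1 <- mlp_init(1, 1, seed = 1)
  m1$w1[] <- 1; m1$b1[] <- 0; m1$w2[] <- 1; m1$b2 <- 0
  expect_equal(mlp_forward(m1, matrix(1)), tanh(0.7))
  # doubling the output layer doubles the output
  m2 <- m1; m2$w2 <- 2 * m1$w2; m2$b2 <- 2 * m1$b2
  x <- matrix(rnorm(6), 6, 1)
  expect_equal(mlp_forward(m2, x), 2 * mlp_forward(m1, x))
  expect_error(mlp_forward(m1, matrix(1, 1, 2)), "columns")
})

test_that("backprop gradient matches central finite differences", {
  set.seed(5)
  for (rep in 1:10) {
    ni <- sample(1:7, 1); nh <- sample(1:5, 1)
    m <- mlp_init(ni, nh, seed = rep)
    x <- matrix(rnorm(4 * ni), 4, ni)
    y <- rnorm(4)
    g <- flat_grad(mlp_gradient(m, x, y)$grad)
    fd <- fd_gradient(m, x, y)
    expect_equal(g, fd, tolerance = 1e-6)
  }
})

test_that("gradient is zero at perfect fit and batch-duplication invariant", {
  m <- mlp_init(3, 2, seed = 8)
  x <- matrix(rnorm(12), 4, 3)
  y <- mlp_forward(m, x)
  g <- flat_grad(mlp_gradient(m, x, y)$grad)
  expect_equal(g, rep(0, length(g)))
  y2 <- rnorm(4)
  g1 <- flat_grad(mlp_gradient(m, x, y2)$grad)
  g2 <- flat_grad(mlp_gradient(m, rbind(x, x), c(y2, y2))$grad)
  expect_equal(g1, g2)
  expect_error(mlp_gradient(m, x[0, , drop = FALSE], numeric(0)), "empty")
})

test_that("RPROP step follows the adaptive step-size rule", {
  cfg <- rprop_config()
  # zero gradient: nothing moves
  st <- rprop_step(c(1, 2), c(0, 0), NULL, cfg)
  expect_equal(st$w, c(1, 2))
  expect_equal(st$state$delta, c(0.5, 0.5))
  # repeated same-sign gradient: steps 0.5, 0.6, 0.72 (x1.2 growth)
  w <- 0; state <- NULL
  steps <- numeric(3)
  for (i in 1:3) {
    st <- rprop_step(w, 1, state, cfg)
    steps[i] <- w - st$w
    w <- st$w; state <- st$state
  }
  expect_equal(steps, c(0.5, 0.6, 0.72))
  # sign flip: delta halves and the direction update is skipped once
  st <- rprop_step(w, -1, state, cfg)
  expect_equal(st$w, w)                      # no move on the flip step
  expect_equal(st$state$delta, 0.72 * 0.5)
  expect_equal(st$state$prev_grad, 0)
  expect_error(rprop_step(0, NaN, NULL, cfg), "weight 1")
})

test_that("RPROP step sizes stay within [delta_min, delta_max]", {
  cfg <- rprop_config(delta_min = 1e-4, delta_max = 2)
  set.seed(13)
  w <- rep(0, 4); state <- NULL
  for (i in 1:300) {
    st <- rprop_step(w, sample(c(-1, 1), 4, replace = TRUE), state, cfg)
    w <- st$w; state <- st$state
    expect_true(all(state$delta >= cfg$delta_min - 1e-15))
    expect_true(all(state$delta <= cfg$delta_max + 1e-15))
  }
})

test_that("scalar RPROP minimises (w-3)^2 to 1e-4 within 200 steps", {
  w <- 0; state <- NULL
  cfg <- rprop_config()
  for (i in 1:200) {
    st <- rprop_step(w, 2 * (w - 3), state, cfg)
    w <- st$w; state <- st$state
    if (abs(w - 3) < 1e-4) break
  }
  expect_lt(abs(w - 3), 1e-4)
  expect_lte(i, 200)
})

test_that("training fits a 1-D sine and retains best-so-far weights", {
  set.seed(2)
  x <- matrix(seq(-1, 1, length.out = 50))
  y <- sin(pi * x[, 1])
  fit <- mlp_train(mlp_init(1, 5, seed = 21), x, y,
                   rprop_config(epochs = 10000))
  expect_length(fit$history, 10000)
  expect_lt(fit$best_loss, 0.01)
  expect_lte(fit$best_loss, min(fit$history))
  expect_lte(fit$best_loss, fit$final_loss)
  # deterministic forward: equal model + input give identical output
  expect_identical(mlp_forward(fit$model, x), mlp_forward(fit$model, x))
})

test_that("with linear hidden activation the net reduces to an affine map", {
  set.seed(31)
  n <- 60
  x <- matrix(runif(3 * n, -1, 1), n, 3)
  y <- drop(x %*% c(0.4, -0.3, 0.2)) + 0.1
  m <- mlp_init(3, 4, seed = 3,
                hidden = activation_spec("linear"))
  fit <- mlp_train(m, x, y, rprop_config(epochs = 2000))
  ls_resid <- mean(lm.fit(cbind(1, x), y)$residuals^2)
  expect_lt(fit$best_loss, ls_resid + 1e-4)
})

test_that("error reports are per-example squares with exact aggregates", {
  r <- error_report(c(0.1, 0.3), c(0, 0))
  expect_equal(r$per_example, c(0.01, 0.09))
  expect_equal(r$mean, 0.05)
  expect_equal(r$min, 0.01)
  expect_equal(r$max, 0.09)
  r0 <- error_report(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r0$mean, 0)
  # duplicating a dataset leaves the mean unchanged
  p <- rnorm(10); o <- rnorm(10)
  expect_equal(error_report(c(p, p), c(o, o))$mean, error_report(p, o)$mean)
  expect_true(r$min <= r$mean && r$mean <= r$max)
})
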