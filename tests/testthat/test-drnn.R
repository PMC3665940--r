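test_that("an isolated unit relaxes monotonically to the sigmoid midpoint", {
  p <- drnn_init(1, seed = 1, n_in = 0, n_out = 0)
  p$W[] <- 0; p$T[] <- 1; p$I[] <- 0
  inp <- matrix(numeric(0), nrow = 201, ncol = 0)
  fwd <- drnn_forward(p, inp, dt = 0.01, y0 = 1)
  y <- fwd$Y[, 1]
  expect_true(all(diff(y) < 0))              # decays toward F(0) = 0.5
  expect_equal(y[201], 0.5 + 0.5 * (1 - 0.01)^200, tolerance = 1e-10)
})

test_that("with zero weights every unit relaxes to F(0) + bias", {
  p <- drnn_init(2, seed = 2, n_in = 0, n_out = 0)
  p$W[] <- 0; p$T[] <- 0.2
  p$I <- c(0.3, -0.1)
  inp <- matrix(numeric(0), nrow = 801, ncol = 0)
  fwd <- drnn_forward(p, inp, dt = 0.01)
  expect_equal(unname(fwd$Y[801, ]), 0.5 + p$I, tolerance = 1e-6)
})

test_that("Euler trajectories converge under grid refinement", {
  p <- drnn_init(3, seed = 3, n_in = 0, n_out = 0)
  run <- function(dt) {
    K <- round(1 / dt)
    fwd <- drnn_forward(p, matrix(numeric(0), K + 1, 0), dt = dt)
    fwd$Y[K + 1, ]
  }
  y1 <- run(0.01); y2 <- run(0.005); y0 <- run(0.0005)
  e1 <- max(abs(y1 - y0)); e2 <- max(abs(y2 - y0))
  expect_lt(e2, e1)                          # refinement reduces error
  expect_equal(e1 / e2, 2, tolerance = 0.3)  # first-order convergence
})

test_that("cost matches closed forms and direct summation", {
  tgt <- matrix(runif(101 * 2), 101, 2)
  expect_identical(drnn_cost(tgt, tgt, 0.01), 0)
  # constant offset delta over 1 s -> E = delta^2 / 2
  delta <- 0.37
  out <- tgt; out[, 1] <- out[, 1] + delta
  expect_equal(drnn_cost(out, tgt, 0.01), 0.5 * delta^2, tolerance = 1e-12)
  expect_error(drnn_cost(out[1:50, ], tgt, 0.01), "shape error")
})

test_that("adjoint gradients match finite differences", {
  set.seed(100)
  for (s in 1:3) {
    p <- tiny_net(sample(1:3, 1), seed = s)
    K <- sample(10:50, 1); dt <- 0.01
    inp <- matrix(rnorm((K + 1) * 2), K + 1, 2)
    tgt <- matrix(runif((K + 1) * 2, 0.2, 0.8), K + 1, 2)
    fwd <- drnn_forward(p, inp, dt = dt)
    bk <- drnn_backward(p, fwd, inp, tgt, dt)
    # cost agrees with the plain-R summation (independent route)
    outs <- fwd$Y[, which(p$roles == "output"), drop = FALSE]
    expect_equal(bk$E, drnn_cost(outs, tgt, dt), tolerance = 1e-12)
    n <- length(p$T)
    w_idx <- sample(n * n, 8); t_idx <- sample(n, 3)
    fd <- fd_gradients(p, inp, tgt, dt, w_idx = w_idx, t_idx = t_idx)
    expect_equal(bk$gW[w_idx], fd$gW, tolerance = 1e-4)
    expect_equal(bk$gT[t_idx], fd$gT, tolerance = 1e-4)
    # terminal adjoint condition holds exactly
    expect_true(all(bk$P[nrow(bk$P), ] == 0))
  }
})

test_that("zero tracking error silences the adjoint and all gradients", {
  p <- tiny_net(2, seed = 9)
  K <- 30
  inp <- matrix(rnorm((K + 1) * 2), K + 1, 2)
  fwd <- drnn_forward(p, inp, dt = 0.01)
  tgt <- fwd$Y[, which(p$roles == "output"), drop = FALSE]
  bk <- drnn_backward(p, fwd, inp, tgt, 0.01)
  expect_identical(bk$E, 0)
  expect_true(all(bk$P == 0))
  expect_true(all(bk$gW == 0))
  expect_true(all(bk$gT == 0))
})

test_that("too-coarse integration steps are refused", {
  p <- drnn_init(2, seed = 4)
  p$T[] <- 0.05
  inp <- matrix(0, 101, 6)
  expect_error(drnn_forward(p, inp, dt = 0.05), "stability error")
})

test_that("training collapses the cost on an easy task", {
  pat <- tiny_pattern()
  m <- drnn_train(pat, 1, training_config(n_iterations = 2000, seed = 5))
  expect_gte(m$loss[1] / m$E_best, 100)
  # loss is non-increasing on a trailing-window median
  med <- stats::runmed(m$loss, 201)
  expect_lte(med[length(med)], med[1])
})

test_that("a single pattern and a one-element pattern list train identically", {
  pat <- tiny_pattern()
  cfg <- training_config(n_iterations = 200, seed = 6)
  m1 <- drnn_train(pat, 2, cfg)
  m2 <- drnn_train(list(pat), 2, cfg)
  expect_identical(m1$params$W, m2$params$W)
  expect_identical(m1$params$T, m2$params$T)
})

test_that("summed multi-pattern gradients are permutation invariant", {
  p <- drnn_init(3, seed = 7)
  pats <- lapply(c(0.6, 0.8, 1.0), function(f) tiny_pattern(f1 = f))
  grad_sum <- function(order) {
    gW <- 0; gT <- 0
    for (i in order) {
      inp <- pats[[i]]$inputs
      tgt <- cpgdrnn:::targets_to_activation(pats[[i]]$targets, c(0.1, 0.9))
      fwd <- drnn_forward(p, inp)
      bk <- drnn_backward(p, fwd, inp, tgt)
      gW <- gW + bk$gW; gT <- gT + bk$gT
    }
    list(gW = gW, gT = gT)
  }
  g1 <- grad_sum(1:3); g2 <- grad_sum(3:1)
  expect_equal(g1$gW, g2$gW, tolerance = 1e-12)
  expect_equal(g1$gT, g2$gT, tolerance = 1e-12)
})

test_that("non-finite inputs trigger recovery and an eventual clean failure", {
  pat <- tiny_pattern()
  pat$inputs$signals[10, 1] <- NaN
  expect_error(drnn_train(pat, 1, training_config(n_iterations = 50, seed = 1)),
               "divergence")
})

test_that("trained parameters stay finite with positive time constants", {
  pat <- tiny_pattern()
  m <- drnn_train(pat, 3, training_config(n_iterations = 500, seed = 8))
  expect_true(all(is.finite(m$params$W)))
  expect_true(all(m$params$T > 0))
})

test_that("prediction is a pure forward pass in normalized space", {
  pat <- tiny_pattern()
  cfg <- training_config(n_iterations = 500, seed = 10)
  m <- drnn_train(pat, 2, cfg)
  before <- m$params
  pred <- drnn_predict(m, pat$inputs)
  expect_identical(m$params, before)
  expect_equal(dim(pred), dim(pat$targets))
  # consistency with the forward trajectories of the stored parameters
  fwd <- drnn_forward(m$params, pat$inputs)
  outs <- fwd$Y[, which(m$params$roles == "output"), drop = FALSE]
  expect_equal(unname(pred), unname((outs - 0.5) / 0.4), tolerance = 1e-12)
})

test_that("zero-amplitude inputs relax the outputs to a fixed point", {
  pat <- tiny_pattern()
  m <- drnn_train(pat, 2, training_config(n_iterations = 300, seed = 11))
  pred <- drnn_predict(m, matrix(0, 1501, 6), dt = 0.01)
  n <- nrow(pred)
  expect_equal(pred[n, ], pred[n - 1, ], tolerance = 1e-4)
})

test_that("restart selection is reproducible and monotone in pool size", {
  pat <- tiny_pattern()
  cfg <- training_config(n_iterations = 300, seed = 21)
  r1 <- drnn_train_restarts(pat, 2, cfg, n_restarts = 1)
  r3a <- drnn_train_restarts(pat, 2, cfg, n_restarts = 3)
  r3b <- drnn_train_restarts(pat, 2, cfg, n_restarts = 3)
  expect_identical(r3a$params$W, r3b$params$W)
  expect_identical(r3a$restarts, r3b$restarts)
  # restart seeds are a stable prefix: more restarts can only improve SI
  expect_identical(r1$restarts$seed[1], r3a$restarts$seed[1])
  expect_gte(r3a$mean_si, r1$mean_si)
  # n_restarts = 1 is plain training under the derived seed
  cfg1 <- cfg; cfg1$seed <- r1$restarts$seed[1]
  m <- drnn_train(pat, 2, cfg1)
  expect_identical(r1$params$W, m$params$W)
})

test_that("parameter checkpoints round-trip losslessly", {
  pat <- tiny_pattern()
  m <- drnn_train(pat, 2, training_config(n_iterations = 200, seed = 12))
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  save_drnn(m, f1)
  m2 <- load_drnn(f1)
  save_drnn(m2, f2)
  expect_identical(readLines(f1), readLines(f2))
  # forward outputs identical before and after the round trip
  p1 <- drnn_predict(m, pat$inputs)
  p2 <- drnn_predict(m2, pat$inputs)
  expect_identical(p1, p2)
  # corrupted checkpoints are refused
  bad <- tempfile(fileext = ".json")
  writeLines("{not json", bad)
  expect_error(load_drnn(bad), "format error")
  jsonlite::write_json(list(format = "other"), bad, auto_unbox = TRUE)
  expect_error(load_drnn(bad), "format error")
})
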