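test_that("hippocampal forward pass produces bounded, reproducible activations", {
  set.seed(42)
  st <- hippocampal_state(5, 8)
  p <- c(1, 0, 1, 0, 0)
  st1 <- hip_forward(st, p)
  expect_length(st1$last_hidden, 8)
  expect_length(st1$last_recon, 5)
  expect_true(all(st1$last_hidden >= 0 & st1$last_hidden <= 1))
  expect_true(all(st1$last_recon >= 0 & st1$last_recon <= 1))
  st2 <- hip_forward(st, p)
  expect_identical(st1$last_hidden, st2$last_hidden)
  expect_error(hip_forward(st, c(1, 0)), "width")
})

test_that("single-unit reconstruction equals the composed layer evaluations", {
  st <- hippocampal_state(1, 1)
  st$layer1 <- const_qlayer(matrix(1, 1, 1))
  st$layer2 <- const_qlayer(matrix(1, 1, 1))
  p <- 0.8
  h1 <- layer_forward(st$layer1, encode_input(p))
  h2 <- layer_forward(st$layer2, encode_input(h1$a))
  st <- hip_forward(st, p)
  expect_equal(st$last_hidden, h1$a)
  expect_equal(st$last_recon, h2$a)
})

test_that("instar update follows the gated attraction rule", {
  cfg <- learning_config(mu = 0.1, instar_contrast = 1)
  st <- hippocampal_state(1, 1)
  st$layer1 <- const_qlayer(matrix(0.5, 1, 1), matrix(0.5, 1, 1),
                            matrix(0.5, 1, 1))
  up <- instar_update(st, p = 1, a_h1 = 1, cfg)
  expect_equal(up$layer1$W[1, 1], 0.55)
  expect_equal(up$layer1$eps[1, 1], 0.55)
  expect_equal(up$layer1$theta[1, 1], 0.55)

  # zero learning rate and zero gating both freeze the state
  same <- instar_update(st, 1, 1, learning_config(mu = 0))
  expect_identical(same$layer1, st$layer1)
  same2 <- instar_update(st, 1, a_h1 = 0, cfg)
  expect_identical(same2$layer1, st$layer1)
})

test_that("outstar update follows the printed rule and both target modes", {
  st <- hippocampal_state(1, 1)
  st$layer2 <- const_qlayer(matrix(0.2, 1, 1), matrix(0.2, 1, 1),
                            matrix(0.2, 1, 1))
  cfg <- learning_config(mu = 0.1)
  up <- outstar_update(st, a_h1 = 1, a_h2 = 0.6, p = 0.9, cfg)
  expect_equal(up$layer2$W[1, 1], 0.24)

  cfg2 <- learning_config(mu = 0.1, outstar_target_mode = "input_target")
  up2 <- outstar_update(st, a_h1 = 1, a_h2 = 0.6, p = 0.9, cfg2)
  expect_equal(up2$layer2$W[1, 1], 0.2 + 0.1 * (0.9 - 0.2) * 1)

  frozen <- outstar_update(st, a_h1 = 0, a_h2 = 0.6, p = 0.9, cfg)
  expect_identical(frozen$layer2, st$layer2)
})

test_that("instar contracts geometrically to the cue under constant gating", {
  # with constant p and constant gate c: |W(k) - p| = (1 - mu c)^k |W(0) - p|
  mu <- 0.15
  gate <- 0.6
  p <- c(1, 0, 1, 0, 0)
  cfg <- learning_config(mu = mu, instar_contrast = 1)
  st <- hippocampal_state(5, 3)
  set.seed(5)
  st$layer1 <- const_qlayer(matrix(runif(15), 5, 3), matrix(runif(15), 5, 3),
                            matrix(runif(15), 5, 3))
  w0 <- st$layer1$W
  for (k in 1:50) {
    st <- instar_update(st, p, rep(gate, 3), cfg)
    expect_equal(st$layer1$W - p, (1 - mu * gate)^k * (w0 - p),
                 tolerance = 1e-10)
  }
})

test_that("outstar converges geometrically to the drive pattern", {
  mu <- 0.2
  a1 <- rep(0.5, 3)
  a2 <- c(0.9, 0.1)
  cfg <- learning_config(mu = mu)
  st <- hippocampal_state(2, 3)
  set.seed(6)
  st$layer2 <- const_qlayer(matrix(runif(6), 3, 2), matrix(runif(6), 3, 2),
                            matrix(runif(6), 3, 2))
  w0 <- st$layer2$W
  tgt <- matrix(a2, 3, 2, byrow = TRUE)
  for (k in 1:50) {
    st <- outstar_update(st, a1, a2, p = a2, cfg)
    expect_equal(st$layer2$W - tgt, (1 - mu * 0.5)^k * (w0 - tgt),
                 tolerance = 1e-10)
  }
})

test_that("training trial reduces reconstruction error on a repeated cue", {
  p <- c(1, 0, 1, 0, 0)
  cfg <- learning_config(mu = 0.1, outstar_target_mode = "input_target")
  finals <- vapply(1:11, function(s) {
    set.seed(s)
    st <- hippocampal_state(5, 8)
    first <- hip_train_trial(st, p, cfg)
    st <- first$state
    err <- first$recon_error
    for (k in 2:200) {
      out <- hip_train_trial(st, p, cfg)
      st <- out$state
      err <- out$recon_error
    }
    err - first$recon_error
  }, numeric(1))
  expect_lt(median(finals), 0)
})

test_that("zero learning rate keeps the reconstruction error constant", {
  set.seed(9)
  st <- hippocampal_state(5, 4)
  cfg <- learning_config(mu = 0)
  errs <- vapply(1:10, function(k) {
    out <- hip_train_trial(st, c(0.5, 0.5, 1, 0, 0), cfg)
    st <<- out$state
    out$recon_error
  }, numeric(1))
  expect_equal(errs, rep(errs[1], 10))
})

test_that("updates preserve shapes and finiteness", {
  set.seed(11)
  st <- hippocampal_state(5, 6)
  cfg <- learning_config(mu = 0.7)
  for (k in 1:40) {
    st <- hip_train_trial(st, runif(5), cfg)$state
  }
  expect_identical(dim(st$layer1$W), c(5L, 6L))
  expect_identical(dim(st$layer2$W), c(6L, 5L))
  for (lay in list(st$layer1, st$layer2)) {
    expect_true(all(is.finite(lay$W)))
    expect_true(all(is.finite(lay$eps)))
    expect_true(all(is.finite(lay$theta)))
  }
})
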