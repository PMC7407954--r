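test_that("model construction is seed-deterministic", {
  a <- chcq(lesioned = TRUE, seed = 5)
  b <- chcq(lesioned = TRUE, seed = 5)
  expect_identical(a$cortex, b$cortex)
  expect_identical(a$hippocampus, b$hippocampus)
})

test_that("full initialization copy makes the cortical layer the hippocampal one", {
  m <- chcq(coupling = coupling_config(lambda_init = 1), seed = 3,
            hip_us = FALSE)
  expect_identical(m$cortex$layer1, m$hippocampus$layer1)

  half <- chcq(coupling = coupling_config(lambda_init = 0.5), seed = 3,
               hip_us = FALSE)
  raw <- chcq(coupling = coupling_config(lambda_init = 0), seed = 3,
              hip_us = FALSE)
  expect_equal(half$cortex$layer1$W,
               0.5 * raw$cortex$layer1$W + 0.5 * raw$hippocampus$layer1$W)

  les <- chcq(lesioned = TRUE, coupling = coupling_config(lambda_init = 1),
              seed = 3, hip_us = FALSE)
  expect_identical(les$cortex$layer1, raw$cortex$layer1)

  # with the US input line present, only the shared cue rows map across
  us <- chcq(coupling = coupling_config(lambda_init = 1), seed = 3)
  expect_equal(nrow(us$hippocampus$layer1$W), us$r + 1L)
  expect_identical(us$cortex$layer1$W,
                   us$hippocampus$layer1$W[seq_len(us$r), ])
})

test_that("adaptive transfer blends toward the hippocampal parameters", {
  m <- chcq(coupling = coupling_config(lambda_init = 0, lambda_trial = 0.5),
            seed = 8, hip_us = FALSE)
  before <- m$cortex$layer1$W
  hip <- m$hippocampus$layer1$W
  m2 <- adaptive_transfer(m)
  expect_equal(m2$cortex$layer1$W, 0.5 * before + 0.5 * hip)

  id <- chcq(coupling = coupling_config(lambda_init = 0, lambda_trial = 0),
             seed = 8)
  expect_identical(adaptive_transfer(id)$cortex, id$cortex)

  full <- chcq(coupling = coupling_config(lambda_init = 0, lambda_trial = 1),
               seed = 8, hip_us = FALSE)
  expect_identical(adaptive_transfer(full)$cortex$layer1,
                   full$hippocampus$layer1)

  les <- lesion(m)
  expect_warning(out <- adaptive_transfer(les), "no-op")
  expect_identical(out$cortex, les$cortex)
})

test_that("transfer noise is reproducible from the model's own stream", {
  build <- function() {
    chcq(coupling = coupling_config(lambda_trial = 0.25, noise_sigma = 0.1),
         seed = 12)
  }
  a <- adaptive_transfer(build())
  b <- adaptive_transfer(build())
  expect_identical(a$cortex$layer1, b$cortex$layer1)
  # and noise actually perturbs relative to the noiseless blend
  clean <- adaptive_transfer(
    chcq(coupling = coupling_config(lambda_trial = 0.25), seed = 12))
  expect_false(identical(a$cortex$layer1$W, clean$cortex$layer1$W))
})

test_that("lesioning is idempotent and severs hippocampal influence exactly", {
  m <- chcq(seed = 2)
  l1 <- lesion(m)
  l2 <- lesion(l1)
  expect_identical(l1$lesioned, l2$lesioned)

  p <- c(1, 0, 1, 0, 0)
  trace <- function(model, n = 15) {
    vapply(seq_len(n), function(k) {
      out <- model_trial(model, p, TRUE)
      model <<- out$model
      out$cr
    }, numeric(1))
  }
  # same cortical seed, different hippocampal seeds: identical once lesioned
  a <- chcq(lesioned = TRUE, seed = 9, hip_seed = 101L)
  b <- chcq(lesioned = TRUE, seed = 9, hip_seed = 202L)
  expect_identical(trace(a), trace(b))

  # a lesioned model reduces to the bare cortical network
  bare <- chcq(lesioned = TRUE, seed = 9)
  cor_only <- bare$cortex
  cfg <- bare$learning
  direct <- vapply(1:15, function(k) {
    out <- cor_train_trial(cor_only, p, TRUE, cfg)
    cor_only <<- out$state
    out$record$cr
  }, numeric(1))
  expect_identical(trace(chcq(lesioned = TRUE, seed = 9)), direct)
})

test_that("intact coupling makes hippocampal parameters matter", {
  p <- c(1, 0, 1, 0, 0)
  trace <- function(model, n = 20) {
    vapply(seq_len(n), function(k) {
      out <- model_trial(model, p, TRUE)
      model <<- out$model
      out$cr
    }, numeric(1))
  }
  a <- trace(chcq(seed = 9, hip_seed = 101L))
  b <- trace(chcq(seed = 9, hip_seed = 202L))
  expect_false(identical(a, b))
})

test_that("frozen learning keeps the CR constant across trials", {
  m <- chcq(learning = learning_config(mu = 0), seed = 6)
  p <- c(1, 0, 1, 0, 0)
  crs <- vapply(1:10, function(k) {
    out <- model_trial(m, p, TRUE)
    m <<- out$model
    out$cr
  }, numeric(1))
  expect_equal(crs, rep(crs[1], 10))
})

test_that("degenerate pre-activations recover by re-randomizing the unit", {
  m <- chcq(lesioned = TRUE, seed = 3)
  # engineer a zero pre-activation in the cortical hidden layer: one unit
  # whose weight column is zero and whose threshold phasor cancels nothing
  m$cortex$layer1$W[] <- 0
  m$cortex$layer1$theta[] <- 0
  # v_j = 0*phasors - phasor(0) = -1 (fine); now force exact cancellation
  m$cortex$layer1$W[1, 1] <- 1
  m$cortex$layer1$theta[, 1] <- 0
  # with input angle 0 on line 1: v_1 = 1 - 1 = 0 -> degenerate
  out <- model_trial(m, c(0, 0, 0, 0, 0), FALSE)
  expect_gte(out$model$n_reinits, 1L)
  expect_true(out$cr >= 0 && out$cr <= 1)
})

test_that("print and summary surface the system state", {
  m <- chcq(lesioned = TRUE, seed = 1)
  expect_output(print(m), "lesioned")
  expect_output(print(m), "Q = 6")
  out <- model_trial(m, c(1, 0, 1, 0, 0), TRUE)
  s <- summary(out$model)
  expect_s3_class(s, "summary.chcq")
  expect_output(print(s), "1 trials run")
})

test_that("checkpoints round-trip through plain-text serialization", {
  dir <- tempfile("chcq-ckpt-")
  m <- chcq(seed = 17)
  out <- model_trial(m, c(1, 0, 1, 0, 0), TRUE)
  m <- out$model
  save_model(m, dir)
  expect_true(file.exists(file.path(dir, "params.csv")))
  expect_true(file.exists(file.path(dir, "manifest.json")))
  m2 <- load_model(dir)
  expect_equal(m2$cortex$layer1, m$cortex$layer1)
  expect_equal(m2$hippocampus$layer2, m$hippocampus$layer2)
  expect_equal(m2$n_trials, m$n_trials)
  expect_equal(m2$learning$mu, m$learning$mu)
  unlink(dir, recursive = TRUE)
})
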