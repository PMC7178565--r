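variants <- c("unet", "gru3", "unet_gru3", "urnet")

test_that("every variant maps windows to same-length probability rows", {
  for (v in variants) {
    for (L in c(30L, 60L)) {
      cfg <- urnet_config(v, preset = "tiny", n_levels = 2,
                          pool_factors = c(2, 3), kernel_size = 5)
      m <- build_model(cfg, window_length = L, seed = 1)
      p <- predict_probs(m, matrix(rnorm(L * 3), L, 3))
      expect_equal(dim(p), c(L, 8L, 3L))
      expect_equal(apply(p, c(1, 3), sum), matrix(1, L, 3), tolerance = 1e-5)
      expect_true(all(p >= 0 & p <= 1))
    }
  }
})

test_that("window length must be divisible by the pooling product", {
  cfg <- urnet_config("unet", preset = "tiny")
  expect_error(build_model(cfg, window_length = 301), class = "segcall_error_config")
  expect_silent(m <- build_model(cfg, window_length = 300, seed = 1))
  # gru3 has no pooling, so any length works
  expect_silent(build_model(urnet_config("gru3", preset = "tiny"),
                            window_length = 301, seed = 1))
})

test_that("recurrent enhancements strictly add parameters", {
  counts <- vapply(variants, function(v) {
    n_params(build_model(urnet_config(v, preset = "tiny"), 300, seed = 1))
  }, numeric(1))
  expect_gt(counts[["urnet"]], counts[["unet_gru3"]])
  expect_gt(counts[["unet_gru3"]], counts[["unet"]])
})

test_that("config validation rejects inconsistent settings", {
  expect_error(urnet_config("unet", n_levels = 2, filters = c(8, 16, 32)),
               class = "segcall_error_config")
  expect_error(urnet_config("unet", kernel_size = 4), class = "segcall_error_config")
})

test_that("training reduces the loss and is seed-reproducible", {
  ds <- make_dataset(6, 200, window_length = 60, seed = 21)
  cfg <- urnet_config("unet", preset = "tiny", n_levels = 2, pool_factors = c(2, 3),
                      kernel_size = 5)
  m <- build_model(cfg, window_length = 60, seed = 2)
  fit <- train_model(m, ds, epochs = 3, batch_size = 16, seed = 2)
  expect_lte(fit$history$loss[3], fit$history$loss[1])
  fit2 <- train_model(m, ds, epochs = 3, batch_size = 16, seed = 2)
  expect_identical(fit$history, fit2$history)
  expect_error(train_model(m, list(signal = matrix(0, 60, 0),
                                   labels = matrix(0L, 60, 0))),
               class = "segcall_error_invalid")
})

test_that("tidiers and plots expose the fit", {
  ds <- make_dataset(3, 150, window_length = 60, seed = 22)
  cfg <- urnet_config("unet", preset = "tiny", n_levels = 2, pool_factors = c(2, 3),
                      kernel_size = 5)
  fit <- train_model(build_model(cfg, 60, seed = 1), ds, epochs = 1,
                     batch_size = 8, seed = 1)
  expect_equal(nrow(tidy(fit)), 1L)
  g <- glance(fit)
  expect_equal(g$variant, "unet")
  expect_equal(g$n_params, n_params(fit))
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("checkpoints round-trip through save and load", {
  ds <- make_dataset(3, 150, window_length = 60, seed = 23)
  cfg <- urnet_config("unet", preset = "tiny", n_levels = 2, pool_factors = c(2, 3),
                      kernel_size = 5)
  fit <- train_model(build_model(cfg, 60, seed = 3), ds, epochs = 1,
                     batch_size = 8, seed = 3)
  path <- withr::local_tempfile(fileext = ".json")
  save_model(fit, path)
  restored <- load_model(path)
  x <- matrix(rnorm(60 * 2), 60, 2)
  expect_equal(predict_probs(restored, x), predict_probs(fit, x), tolerance = 1e-12)
})
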