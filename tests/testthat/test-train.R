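test_that("training separates smooth pulses from spikes on an easy toy", {
  # 200 events: headers are smooth pulses, non-headers narrow spikes
  tr <- make_toy_data(70, 70, seed0 = 0, nh_archetype = "spike")
  va <- make_toy_data(30, 30, seed0 = 700, nh_archetype = "spike")
  fit <- fit_bilstm(tr, net = tiny_net,
                    cfg = training_config(alpha = 0.002, batch_size = 8,
                                          lambda = 1e-4, epochs = 3,
                                          seed = 1),
                    validation = va)
  pred <- predict(fit, va$x)
  m <- classification_metrics(confusion_counts(pred, va$y))
  expect_gte(m$sensitivity, 0.95)
  expect_gte(m$specificity, 0.95)
  expect_equal(nrow(fit$history), 3L)
  expect_true(all(is.finite(fit$history$train_loss)))
})

test_that("training is bit-reproducible for a fixed seed", {
  tr <- make_toy_data(12, 12, seed0 = 40)
  cfg <- training_config(alpha = 0.005, batch_size = 8, epochs = 2, seed = 5)
  f1 <- fit_bilstm(tr, net = tiny_net, cfg = cfg)
  f2 <- fit_bilstm(tr, net = tiny_net, cfg = cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$params, f2$params)
})

test_that("training is invariant to event file order under a fixed seed", {
  ds <- make_labeled_set(10, 14, seed0 = 55)
  cfg <- training_config(alpha = 0.005, batch_size = 8, epochs = 1, seed = 6)
  f1 <- fit_bilstm(ds, net = tiny_net, cfg = cfg)
  set.seed(99)
  f2 <- fit_bilstm(ds[sample.int(24)], net = tiny_net, cfg = cfg)
  expect_identical(f1$params, f2$params)
})

test_that("stronger L2 regularization shrinks the learned weights", {
  tr <- make_toy_data(20, 20, seed0 = 80)
  base <- list(alpha = 0.005, batch_size = 8, epochs = 3, seed = 2)
  f_small <- fit_bilstm(tr, net = tiny_net,
                        cfg = do.call(training_config,
                                      c(base, list(lambda = 1e-8))))
  f_large <- fit_bilstm(tr, net = tiny_net,
                        cfg = do.call(training_config,
                                      c(base, list(lambda = 1e-1))))
  expect_lt(headrec:::weight_norm(f_large$params),
            headrec:::weight_norm(f_small$params))
})

test_that("training loss decreases over the first epochs on the easy toy", {
  drops <- vapply(1:5, function(s) {
    tr <- make_toy_data(25, 25, seed0 = 100 * s, nh_archetype = "spike")
    f <- fit_bilstm(tr, net = tiny_net,
                    cfg = training_config(alpha = 0.002, batch_size = 8,
                                          lambda = 1e-4, epochs = 2,
                                          seed = s))
    f$history$train_loss[1] - f$history$train_loss[2]
  }, numeric(1))
  expect_gt(mean(drops), 0)
})

test_that("fitted models expose the standard modelling methods", {
  tr <- make_toy_data(15, 15, seed0 = 130)
  fit <- fit_bilstm(tr, net = tiny_net,
                    cfg = training_config(alpha = 0.005, batch_size = 8,
                                          epochs = 1, seed = 3))
  expect_output(print(fit), "Bidirectional LSTM")
  expect_type(coef(fit), "list")
  p <- predict(fit, tr$x, type = "prob")
  expect_equal(dim(p), c(30L, 2L))
  cl <- predict(fit, tr$x)
  expect_true(all(cl %in% c("VH", "NH")))
  r <- residuals(fit, tr)
  expect_length(r, 30L)
  expect_true(all(is.finite(r)))
  expect_error(fit_bilstm(list(x = tr$x[0, , , drop = FALSE],
                               y = character(0))), "empty|labels")
})

test_that("models survive a round trip through the text serialisation", {
  tr <- make_toy_data(10, 10, seed0 = 160)
  fit <- fit_bilstm(tr, net = tiny_net,
                    cfg = training_config(alpha = 0.005, batch_size = 8,
                                          epochs = 1, seed = 4))
  f <- withr::local_tempfile(fileext = ".yaml")
  write_bilstm(fit, f)
  back <- read_bilstm(f)
  x <- headrec:::znorm_array(tr$x[1:4, , , drop = FALSE])
  expect_equal(bilstm_forward(back$params, x),
               bilstm_forward(fit$params, x), tolerance = 1e-9)
})
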