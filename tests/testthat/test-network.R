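test_that("the residual U-Net maps shapes and starts at identity", {
  model <- build_network(network_config(depth = 3, base_filters = 8),
                         seed = 60)
  x <- matrix(runif(128 * 128), 128)
  y <- unet_apply(model, x)
  expect_identical(dim(y), dim(x))
  # zero-initialized head: exact identity before training
  expect_identical(y, x)
  expect_error(unet_apply(model, matrix(0, 100, 100)), "multiples")
})

test_that("capacity grows with the filter budget", {
  n8 <- count_params(build_network(network_config(3, 8), seed = 1))
  n16 <- count_params(build_network(network_config(3, 16), seed = 1))
  n32 <- count_params(build_network(network_config(3, 32), seed = 1))
  expect_lt(n8, n16)
  expect_lt(n16, n32)
})

test_that("batched forward equals image-at-a-time forward", {
  model <- build_network(network_config(2, 4), seed = 61)
  withr::local_seed(61)
  model$params[["out.W"]][] <- rnorm(length(model$params[["out.W"]]),
                                     sd = 0.1)
  imgs <- lapply(1:3, function(i) matrix(runif(48 * 48), 48))
  xb <- array(unlist(imgs), dim = c(48, 48, 3))
  yb <- mitorestore:::unet_forward(model, xb)$y
  for (i in 1:3)
    expect_equal(yb[, , i], unet_apply(model, imgs[[i]]), tolerance = 1e-5)
})

test_that("backprop agrees with a directional derivative of the loss", {
  withr::local_seed(62)
  model <- build_network(network_config(2, 4), seed = 62)
  model$params[["out.W"]][] <- rnorm(length(model$params[["out.W"]]),
                                     sd = 0.1)
  patches <- lapply(1:2, function(i) toy_patch(100 + i))
  sp <- scop_params()
  bg <- mitorestore:::batch_loss_grad(model, patches, sp)
  # unit direction over all parameters
  dir <- lapply(model$params, function(w) {
    d <- rnorm(length(w))
    if (is.matrix(w)) dim(d) <- dim(w)
    d
  })
  nrm <- sqrt(sum(unlist(dir)^2))
  dir <- lapply(dir, `/`, nrm)
  analytic <- sum(vapply(names(dir), function(nm)
    sum(bg$grads[[nm]] * dir[[nm]]), numeric(1)))
  eps <- 1e-3
  shift <- function(s) {
    m <- model
    m$params <- mapply(function(w, d) w + s * d, model$params, dir,
                       SIMPLIFY = FALSE)
    mitorestore:::batch_loss_grad(m, patches, sp, want_grad = FALSE)$loss
  }
  fd <- (shift(eps) - shift(-eps)) / (2 * eps)
  expect_lt(abs(fd - analytic) / max(abs(fd), 1e-8), 0.05)
})

test_that("prediction pads, restores and crops arbitrary sizes", {
  model <- build_network(network_config(3, 4), seed = 63)
  withr::local_seed(63)
  img <- matrix(rgamma(300 * 517, 3, 0.05), 300, 517)
  pred <- predict_image(model, img)
  expect_identical(dim(pred), c(300L, 517L))
  # identity model: prediction is exactly the normalized input
  expect_equal(pred, percentile_normalize(img), tolerance = 1e-12)
  # plane stacks restore plane by plane
  stack <- array(rgamma(64 * 64 * 3, 3, 0.05), dim = c(64, 64, 3))
  ps <- predict_image(model, stack)
  expect_identical(dim(ps), dim(stack))
  expect_equal(ps[, , 2], percentile_normalize(stack[, , 2]),
               tolerance = 1e-12)
  # a degenerate plane is skipped with a warning, others survive
  stack[, , 2] <- 1
  expect_warning(ps2 <- predict_image(model, stack), "skipped")
  expect_true(all(is.na(ps2[, , 2])))
  expect_false(anyNA(ps2[, , 1]))
})
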