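test_that("every head's spatial output matches its input patch", {
  x <- array(rnorm(16^3), c(1, 16, 16, 16))
  for (v in c("baseline", "dual_a", "dual_b", "dual_c", "dual_d")) {
    net <- buildNetwork(tiny_config(v, C = 5L), seed = 1L)
    fw <- BoneBEM:::.net_forward(net, x, cache = FALSE)
    expect_equal(dim(fw$multi), c(5L, 16L, 16L, 16L), info = v)
    if (v == "baseline") expect_null(fw$binary)
    else expect_equal(dim(fw$binary), c(2L, 16L, 16L, 16L), info = v)
  }
  deep <- buildNetwork(networkConfig("baseline", nClassesMulti = 3L,
                                     levels = 3L, channels = c(4L, 8L, 12L)),
                       seed = 1L)
  expect_error(BoneBEM:::.net_forward(deep, array(0, c(1, 10, 10, 10))),
               "divisible")
})

test_that("parameter counts match the closed-form accounting for all variants", {
  ch <- c(4L, 8L)
  for (v in c("baseline", "dual_a", "dual_b", "dual_c", "dual_d")) {
    net <- buildNetwork(networkConfig(v, nClassesMulti = 7L, levels = 2L,
                                      channels = ch), seed = 1L)
    expect_equal(countParameters(net), expected_param_count(v, 7L, ch),
                 info = v)
  }
  # a lone 1x1x1 convolution 32 -> 2 carries 32*2 weights + 2 biases
  p <- BoneBEM:::.init_conv(32L, 2L, 1L, list(), "head")
  expect_equal(sum(lengths(p)), 66L)
  # dual_a adds exactly one extra 1x1x1 2-class head over the baseline
  base <- buildNetwork(tiny_config("baseline"), seed = 1L)
  duala <- buildNetwork(tiny_config("dual_a"), seed = 1L)
  expect_equal(countParameters(duala) - countParameters(base), 4L * 2L + 2L)
})

test_that("network configs are validated", {
  expect_error(networkConfig(channels = c(8L, 8L), levels = 2L),
               "increasing")
  expect_error(networkConfig(nClassesMulti = 1L), "at least 2")
  expect_error(networkConfig(channels = c(8L, 16L)), "one width per level")
})

test_that("analytic gradients agree with central differences", {
  set.seed(4)
  cfg <- networkConfig("dual_b", nClassesMulti = 3L, levels = 2L,
                       channels = c(3L, 5L))
  net <- buildNetwork(cfg, seed = 2L)
  x <- array(rnorm(8^3), c(1, 8, 8, 8))
  lab <- array(sample(0:2, 8^3, TRUE), c(8, 8, 8))
  lossOf <- function(params) {
    m <- new("UNet3D", config = net@config, params = params)
    fw <- BoneBEM:::.net_forward(m, x, cache = FALSE)
    BoneBEM:::.ce_dice_loss(fw$multi, lab)$loss +
      BoneBEM:::.ce_dice_loss(fw$binary, (lab > 0) + 0L)$loss
  }
  fw <- BoneBEM:::.net_forward(net, x, cache = TRUE)
  gM <- BoneBEM:::.ce_dice_loss(fw$multi, lab, grad = TRUE)$grad
  gB <- BoneBEM:::.ce_dice_loss(fw$binary, (lab > 0) + 0L, grad = TRUE)$grad
  grads <- BoneBEM:::.net_backward(net, fw, gM, gB)
  eps <- 1e-5
  set.seed(9)
  for (nm in sample(names(net@params), 8L)) {
    i <- sample(length(net@params[[nm]]), 1L)
    p <- net@params
    p[[nm]][i] <- p[[nm]][i] + eps
    up <- lossOf(p)
    p[[nm]][i] <- p[[nm]][i] - 2 * eps
    dn <- lossOf(p)
    num <- (up - dn) / (2 * eps)
    expect_lt(abs(num - grads[[nm]][i]) /
                max(1e-6, abs(num) + abs(grads[[nm]][i])), 1e-4)
  }
})

test_that("weight initialisation is deterministic in the seed", {
  a <- buildNetwork(tiny_config("dual_d"), seed = 3L)
  b <- buildNetwork(tiny_config("dual_d"), seed = 3L)
  expect_identical(a@params, b@params)
})
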