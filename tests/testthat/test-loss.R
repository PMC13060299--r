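test_that("GNLL matches its closed forms", {
  t0 <- matrix(1.5, 3, 2)
  expect_equal(gnll(t0, t0, t0 * 0 + 1), 0.5 * log(2 * pi))
  expect_equal(gnll(t0, t0 + 1, t0 * 0 + 1), 0.5 + 0.5 * log(2 * pi))
  # doubling the variance at target == mean adds half log 2 per entry
  expect_equal(gnll(t0, t0, t0 * 0 + 2) - gnll(t0, t0, t0 * 0 + 1),
               0.5 * log(2))
  expect_error(gnll(t0, t0, t0 * 0), class = "cytoformer_numeric_error")
  expect_error(gnll(t0, t0[1:2, ], t0 * 0 + 1),
               class = "cytoformer_dimension_error")
  expect_equal(gnll(numeric(0), numeric(0), numeric(0)), 0)
})

make_loss_fixture <- function(n = 4, m = 3, V = 5, seed = 2) {
  set.seed(seed)
  slots <- c(1, 3, 4)
  tg <- list(expression = matrix(rnorm(n * m), n, m),
             percentile = matrix(runif(n * m), n, m),
             density = matrix(rnorm(n * m), n, m))
  mk_view <- function(pattern, mask, dropped = integer(0)) {
    structure(list(masked_events = tg$expression * mask, mask = mask,
                   pattern = pattern, dropped_markers = dropped),
              class = "masked_view")
  }
  mask_u <- matrix(rbinom(n * m, 1, 0.6), n, m)
  mask_m <- matrix(1, n, m); mask_m[, 2] <- 0
  views <- list(mk_view("uniform_random", mask_u),
                mk_view("marker_wise", mask_m))
  ho <- lapply(1:2, function(k) {
    lapply(stats::setNames(1:3, c("X", "P", "D")), function(t)
      list(mean = matrix(rnorm(n * V), n, V),
           var = matrix(exp(rnorm(n * V)), n, V)))
  })
  list(tg = tg, views = views, ho = ho, slots = slots, n = n, m = m, V = V)
}

test_that("pretrain loss equals the weighted sum of its 12 components", {
  fx <- make_loss_fixture()
  cfg <- pretrain_loss_config(beta_unmasked = 0.3, w_x = 1.5, w_p = 0.7,
                              w_d = 2, w_uniform = 0.4, w_markerwise = 0.6)
  pl <- pretrain_loss(fx$tg, fx$views, fx$ho, cfg, fx$slots)
  expect_length(pl$components, 12)
  wt <- c(X = 1.5, P = 0.7, D = 2)
  wk <- c(uniform_random = 0.4, marker_wise = 0.6)
  manual <- 0
  for (pat in names(wk)) for (t in names(wt)) {
    manual <- manual + wk[[pat]] * wt[[t]] *
      (pl$components[[paste(pat, t, "masked", sep = ".")]] +
         0.3 * pl$components[[paste(pat, t, "unmasked", sep = ".")]])
  }
  expect_equal(pl$total, manual, tolerance = 1e-10)
})

test_that("beta = 0 makes the loss independent of unmasked predictions", {
  fx <- make_loss_fixture()
  cfg <- pretrain_loss_config(beta_unmasked = 0)
  base <- pretrain_loss(fx$tg, fx$views, fx$ho, cfg, fx$slots)$total
  ho2 <- fx$ho
  # perturb predictions only where entries are unmasked-measured
  for (k in 1:2) {
    cls <- cytoformer:::entry_classes(fx$views[[k]])
    for (t in c("X", "P", "D")) {
      mh <- ho2[[k]][[t]]$mean
      sub <- mh[, fx$slots]
      sub[cls$unmasked] <- sub[cls$unmasked] + 7
      mh[, fx$slots] <- sub
      ho2[[k]][[t]]$mean <- mh
    }
  }
  expect_equal(pretrain_loss(fx$tg, fx$views, ho2, cfg, fx$slots)$total,
               base)
})

test_that("perturbing unmeasured vocabulary slots never changes the loss", {
  fx <- make_loss_fixture()
  cfg <- pretrain_loss_config()
  base <- pretrain_loss(fx$tg, fx$views, fx$ho, cfg, fx$slots)$total
  ho2 <- fx$ho
  unmeasured <- setdiff(seq_len(fx$V), fx$slots)
  for (k in 1:2) for (t in c("X", "P", "D")) {
    ho2[[k]][[t]]$mean[, unmeasured] <- 1e6
    ho2[[k]][[t]]$var[, unmeasured] <- 1e-6
  }
  expect_identical(pretrain_loss(fx$tg, fx$views, ho2, cfg, fx$slots)$total,
                   base)
})

test_that("pattern-weight selection and scaling behave linearly", {
  fx <- make_loss_fixture()
  only_u <- pretrain_loss(fx$tg, fx$views, fx$ho,
                          pretrain_loss_config(w_uniform = 1,
                                               w_markerwise = 0),
                          fx$slots)
  manual_u <- cytoformer:::sum_view_loss(
    only_u$components[grep("^uniform", names(only_u$components))],
    pretrain_loss_config(w_uniform = 1, w_markerwise = 0), 1)
  expect_equal(only_u$total, manual_u, tolerance = 1e-12)
  # multiplying both pattern weights by c scales the total by c
  base <- pretrain_loss(fx$tg, fx$views, fx$ho, pretrain_loss_config(),
                        fx$slots)$total
  tripled <- pretrain_loss(fx$tg, fx$views, fx$ho,
                           pretrain_loss_config(w_uniform = 1.5,
                                                w_markerwise = 1.5),
                           fx$slots)$total
  expect_equal(tripled, 3 * base, tolerance = 1e-10)
})

test_that("hand-built all-masked instance matches the closed-form composition", {
  # 2 cells x 2 markers, all entries masked, perfect means, unit variances:
  # each of the three targets contributes 1/2 log(2 pi) per pattern
  n <- 2; m <- 2; V <- 2
  tg <- list(expression = matrix(rnorm(4), 2), percentile = matrix(runif(4), 2),
             density = matrix(rnorm(4), 2))
  mask0 <- matrix(0, n, m)
  views <- list(
    structure(list(masked_events = tg$expression * 0, mask = mask0,
                   pattern = "uniform_random", dropped_markers = integer(0)),
              class = "masked_view"),
    structure(list(masked_events = tg$expression * 0, mask = mask0,
                   pattern = "marker_wise", dropped_markers = integer(0)),
              class = "masked_view"))
  ho <- lapply(1:2, function(k)
    list(X = list(mean = tg$expression, var = matrix(1, n, V)),
         P = list(mean = tg$percentile, var = matrix(1, n, V)),
         D = list(mean = tg$density, var = matrix(1, n, V))))
  cfg <- pretrain_loss_config(w_uniform = 0.5, w_markerwise = 0.5)
  pl <- pretrain_loss(tg, views, ho, cfg, 1:2)
  want <- (1 + 1 + 1) * 0.5 * log(2 * pi) * (0.5 + 0.5)
  expect_equal(pl$total, want, tolerance = 1e-12)
})

test_that("a view with no masked entries warns and contributes zero", {
  fx <- make_loss_fixture()
  v <- fx$views[[1]]
  v$mask <- matrix(1, fx$n, fx$m)
  expect_warning(
    pl <- pretrain_loss(fx$tg, list(v), fx$ho[1], pretrain_loss_config(),
                        fx$slots),
    regexp = "no masked")
  expect_equal(unname(pl$components["uniform_random.X.masked"]), 0)
})
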