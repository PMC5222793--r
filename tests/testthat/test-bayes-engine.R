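test_that("priors normalize and center correctly on the grid", {
  g <- csf_param_grid()
  u <- build_prior(g, "uniform")
  expect_equal(as.vector(u$mass), rep(1 / prod(g$sizes), prod(g$sizes)))
  p <- build_prior(g)
  expect_equal(sum(p$mass), 1, tolerance = 1e-12)
  expect_true(all(p$mass >= 0))
  # marginal mode of the log10 M axis at a node nearest the prior mean
  # (the even-length axis straddles the mean with two equidistant nodes)
  marg <- marginal_mass(p, 1)
  expect_equal(abs(g$axes$M[which.max(marg)] - 2.00),
               min(abs(g$axes$M - 2.00)), tolerance = 1e-12)
})

test_that("prior marginal moments match dense 1-D quadrature", {
  g <- csf_param_grid()
  p <- build_prior(g)
  for (d in c(1, 4)) {
    marg <- marginal_mass(p, d)
    mu <- sum(g$axes[[d]] * marg)
    sd_grid <- sqrt(sum(marg * (g$axes[[d]] - mu)^2))
    # dense quadrature of the same truncated normal
    x <- seq(min(g$axes[[d]]), max(g$axes[[d]]), length.out = 20001)
    w <- dnorm(x, g$prior_mean[d], g$prior_sd[d]); w <- w / sum(w)
    mu_q <- sum(x * w)
    sd_q <- sqrt(sum(w * (x - mu_q)^2))
    expect_equal(mu, mu_q, tolerance = 1e-6)
    # the beta axis has only 8 nodes, so its discretized spread deviates at
    # the percent level
    expect_equal(sd_grid, sd_q, tolerance = 0.04)
  }
})

test_that("posterior equals a brute-force node-by-node computation", {
  g <- tiny_grid()
  lg <- run_session("staircase", 30, "normal", seed = 1)$log
  post <- infer_csf(lg, g, approx = FALSE)
  expect_equal(as.vector(post$mass), as.vector(brute_force_posterior(lg, g)),
               tolerance = 1e-12)
})

test_that("sequential updating equals the batch product", {
  g <- tiny_grid()
  lg <- run_session("staircase", 25, "normal", seed = 7)$log
  post_seq <- build_prior(g)
  for (i in seq_len(nrow(lg))) {
    post_seq <- update_posterior(post_seq, lg$sf_cpd[i], lg$contrast[i],
                                 lg$response[i])
    expect_equal(sum(post_seq$mass), 1, tolerance = 1e-12)
  }
  post_batch <- infer_csf(lg, g, approx = FALSE)
  expect_lt(max(abs(post_seq$mass - post_batch$mass)), 1e-10)
})

test_that("inference is invariant to trial order", {
  g <- tiny_grid()
  lg <- run_session("psi", 20, "normal", seed = 3)$log
  post1 <- infer_csf(lg, g)
  set.seed(42)
  post2 <- infer_csf(lg[sample(nrow(lg)), ], g)
  expect_lt(max(abs(post1$mass - post2$mass)), 1e-10)
})

test_that("a chance-level likelihood leaves the posterior unchanged", {
  # every node of this grid has delta ~= 0.5, so P = 0.5 for any stimulus
  g <- csf_param_grid(sizes = c(4, 4, 4, 3, 2),
                      prior_mean = c(2, -0.3, 0.78, 0.62, log10(0.5)),
                      prior_diag = c(0.5, 0.5, 0.5, 0.11, 1e-9))
  p0 <- build_prior(g)
  p1 <- update_posterior(p0, sf = 4, contrast = 0.01, response = 1)
  expect_equal(p1$mass, p0$mass, tolerance = 1e-6)
})

test_that("a point-mass posterior stays a point mass under updating", {
  g <- tiny_grid()
  p <- build_prior(g)
  m <- array(0, g$sizes); m[3, 2, 2, 2, 1] <- 1
  p$mass <- m
  p2 <- update_posterior(p, sf = 4, contrast = 0.05, response = 1)
  expect_equal(which(p2$mass == 1), which(m == 1))
})

test_that("an impossible trial log raises a degeneracy error", {
  # all grid nodes have enormous sensitivity and a vanishing lapse rate, so
  # a full-contrast miss has likelihood exactly zero in double precision
  g <- csf_param_grid(sizes = c(3, 3, 3, 2, 2),
                      prior_mean = c(9, -0.3, 0.78, 0.9, -400),
                      prior_diag = c(0.01, 0.01, 0.01, 0.01, 0.02))
  p <- build_prior(g)
  expect_error(update_posterior(p, sf = 1, contrast = 1, response = 0),
               "zero")
  expect_error(infer_csf(data.frame(sf_cpd = 1, contrast = 1, response = 0),
                         g, approx = FALSE), "zero")
})

test_that("empty logs return the prior and responses are validated", {
  g <- tiny_grid()
  post <- infer_csf(data.frame(sf_cpd = numeric(), contrast = numeric(),
                               response = numeric()), g)
  expect_equal(post$mass, build_prior(g)$mass)
  expect_error(infer_csf(data.frame(sf_cpd = 1, contrast = 0.1, response = 2),
                         g), "0 or 1")
})

test_that("point estimates are marginal means in log10 space", {
  g <- tiny_grid()
  p <- build_prior(g)
  # two-node mass 0.25/0.75 along the M axis averages the axis values
  m <- array(0, g$sizes)
  m[1, 2, 2, 2, 2] <- 0.25
  m[5, 2, 2, 2, 2] <- 0.75
  p$mass <- m
  est <- point_estimate(p)
  expect_equal(unname(est$log10["M"]),
               0.25 * g$axes$M[1] + 0.75 * g$axes$M[5], tolerance = 1e-12)
  expect_equal(unname(est$log10["A"]), g$axes$A[2])
  expect_equal(est$linear, 10^est$log10)
  # the prior alone estimates the prior mean (symmetric truncation)
  expect_equal(unname(point_estimate(build_prior(g))$log10),
               g$prior_mean, tolerance = 1e-10)
})

test_that("estimated CSF composes the point estimate with the CSF formula", {
  g <- tiny_grid()
  p <- build_prior(g)
  sfs <- stimulus_grid()$sfs
  est <- point_estimate(p)$linear
  expect_equal(estimated_csf(p, sfs),
               csf_sensitivity(sfs, est[["M"]], est[["A"]], est[["F"]]),
               tolerance = 1e-12)
  expect_true(all(estimated_csf(p, sfs) > 0))
  # a point mass at the normal observer's parameters recovers its CSF
  l10 <- log10(c(100, 0.8, 4, 4, 0.02))
  gx <- csf_param_grid(sizes = c(3, 3, 3, 3, 3), prior_mean = l10,
                       prior_diag = rep(0.2, 5), span_sd = 1)
  px <- build_prior(gx)
  m <- array(0, gx$sizes); m[2, 2, 2, 2, 2] <- 1
  px$mass <- m
  expect_equal(estimated_csf(px, sfs), normal_truth(sfs), tolerance = 1e-10)
})

test_that("informative trials reduce posterior entropy", {
  g <- small_grid()
  h0 <- posterior_entropy(build_prior(g))
  drops <- vapply(1:20, function(i) {
    lg <- run_session("staircase", 48, "normal", seed = 100 + i)$log
    h0 - posterior_entropy(infer_csf(lg, g, approx = FALSE))
  }, numeric(1))
  expect_true(all(drops > 0))
})

test_that("the fast tabulated likelihood path matches the exact path", {
  lg <- run_session("staircase", 108, "normal", seed = 5)$log
  for (g in list(csf_param_grid(), small_grid())) {
    pe <- infer_csf(lg, g, approx = FALSE)
    pa <- infer_csf(lg, g, approx = TRUE)
    expect_lt(max(abs(point_estimate(pe)$log10 - point_estimate(pa)$log10)),
              2e-3)
    expect_lt(max(abs(20 * log10(estimated_csf(pe) / estimated_csf(pa)))),
              0.05)
  }
})
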