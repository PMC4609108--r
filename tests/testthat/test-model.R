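test_that("initialization is unbiased: flat alpha, uniform-on-support beta,
           mask-uniform responsibilities", {
  compat <- rbind(k1 = c(1L, 1L, 0L, 0L),
                  k2 = c(1L, 1L, 1L, 0L),
                  k3 = c(1L, 1L, 1L, 1L))
  st <- ldm_initialize(compat, n_lanes = 2)
  expect_equal(unname(st$alpha), c(1, 1, 1))
  expect_equal(unname(st$beta[1, ]), c(1/2, 1/2, 0, 0))
  expect_equal(unname(st$beta[2, ]), c(1/3, 1/3, 1/3, 0))
  expect_equal(unname(st$beta[3, ]), rep(1/4, 4))
  # a unit allowed by 2 of 3 isoforms starts at (1/2, 1/2, 0) after masking
  expect_equal(unname(st$lambda[[1]][, 3]), c(0, 1/2, 1/2))
  expect_equal(unname(st$eta[1, ]), c(1, 1, 1))
  # jitter perturbs only non-noise rows and keeps rows stochastic
  stj <- ldm_initialize(compat, 1, noise_row = 3, init_jitter = 1e-3)
  expect_equal(unname(stj$beta[3, ]), rep(1/4, 4))
  expect_false(all(stj$beta[1, 1:2] == 1/2))
  expect_equal(rowSums(stj$beta), c(k1 = 1, k2 = 1, k3 = 1))
})

test_that("E-step handles the degenerate and symmetric cases exactly", {
  # K = 1: everything belongs to the only component
  n <- c(2, 3, 1)
  es1 <- ldm_e_step(n, alpha = 2, beta = matrix(1/3, 1, 3),
                    compat = matrix(1L, 1, 3))
  expect_equal(unname(es1$lambda), matrix(1, 1, 3))
  expect_equal(unname(es1$eta), 2 + sum(n))

  # full symmetry: uniform beta on identical supports, equal counts
  compat <- matrix(1L, 3, 4)
  es2 <- ldm_e_step(rep(5, 4), alpha = rep(1, 3),
                    beta = matrix(1/4, 3, 4), compat = compat)
  expect_equal(unname(es2$lambda), matrix(1/3, 3, 4))
  expect_equal(unname(es2$eta), rep(1 + 20/3, 3))

  # responsibilities are a distribution per unit and respect the mask
  inst <- random_instance(101)
  st <- ldm_initialize(inst$compat, 1)
  es3 <- ldm_e_step(inst$raw[1, ], st$alpha, st$beta, inst$compat)
  expect_equal(unname(colSums(es3$lambda)), rep(1, ncol(inst$compat)))
  expect_true(all(es3$lambda[inst$compat == 0] == 0))
  expect_true(all(es3$eta >= st$alpha))
})

test_that("beta M-step matches a literal per-observation double sum and
           keeps exact zeros off support", {
  for (seed in c(3, 17)) {
    inst <- random_instance(seed)
    f <- plain_fit(inst$raw, inst$compat, outer = 5)
    expect_true(all(f$beta[inst$compat == 0] == 0))
    expect_equal(unname(rowSums(f$beta)), rep(1, nrow(inst$compat)))
    # literal Eq-5 style double sum over replicated unit-weight observations
    acc <- matrix(0, nrow(inst$compat), ncol(inst$compat))
    for (l in seq_len(nrow(inst$raw)))
      for (j in seq_len(ncol(inst$raw)))
        if (inst$raw[l, j] > 0)
          acc[, j] <- acc[, j] + inst$raw[l, j] * f$lambda[[l]][, j]
    acc <- acc * inst$compat
    expect_equal(unname(f$beta), unname(sweep(acc, 1, rowSums(acc), "/")),
                 tolerance = 1e-12)
  }
  # single full-support component: beta row = normalized counts
  raw <- matrix(c(4L, 6L, 10L), 1, 3)
  lam <- list(matrix(1, 1, 3))
  b <- ldm_m_step_beta(lam, raw, matrix(1L, 1, 3), pseudocount = 0)
  expect_equal(unname(b[1, ]), c(0.2, 0.3, 0.5))
})

test_that("Newton-Raphson alpha maximizes the Dirichlet bound term", {
  set.seed(5)
  eta <- matrix(rgamma(4 * 3, 5, 0.5), 4, 3)
  a0 <- rep(1, 3)
  res <- ldm_m_step_alpha(eta, a0)
  # ascent over the start
  expect_gte(dirichlet_objective(res$alpha, eta),
             dirichlet_objective(a0, eta))
  expect_true(res$converged)
  # matches the black-box optimizer
  g <- digamma(eta) - digamma(rowSums(eta)); s <- colSums(g)
  o <- stats::optim(log(a0), function(la) {
    a <- exp(la)
    -(nrow(eta) * (lgamma(sum(a)) - sum(lgamma(a))) + sum((a - 1) * s))
  }, method = "BFGS", control = list(maxit = 1000, reltol = 1e-15))
  expect_equal(res$alpha, exp(o$par), tolerance = 1e-4)
})

test_that("alpha is recovered from many lanes of a known symmetric prior", {
  set.seed(42)
  K <- 3; L <- 400; a_true <- rep(2, K)
  # lanes with theta ~ Dirichlet(2,2,2) observed through many draws: eta
  # approximates the true posterior N*theta + alpha-ish mass
  th <- rdirichlet(L, a_true)
  eta <- th * 500 + 1
  res <- ldm_m_step_alpha(eta, rep(1, K),
                          ldm_control(alpha_max = 500))
  expect_equal(unname(res$alpha), a_true, tolerance = 0.25)
})

test_that("the variational bound is non-decreasing across EM iterations", {
  for (seed in 1:15) {
    inst <- random_instance(seed, K_max = 4, E_max = 12, lanes = 3,
                            depth = 150)
    fit <- suppressWarnings(ldm_fit(inst$raw, inst$compat,
                                    ldm_control(outer_max = 80)))
    expect_true(trace_monotone(fit$elbo_trace), label = paste("seed", seed))
  }
})

test_that("aggregated fixed point equals the naive per-observation oracle", {
  for (seed in c(1, 2, 5)) {
    inst <- random_instance(seed)
    f <- plain_fit(inst$raw, inst$compat, outer = 60)
    o <- oracle_per_observation_fit(inst$raw, inst$compat, outer = 60)
    expect_equal(unname(f$beta), unname(o$beta), tolerance = 1e-3)
    expect_equal(unname(f$eta), unname(o$eta), tolerance = 1e-3)
    for (l in seq_len(nrow(inst$raw))) {
      seen <- which(inst$raw[l, ] > 0)
      expect_equal(unname(f$lambda[[l]][, seen]),
                   unname(o$lambda[[l]][, seen]), tolerance = 1e-3)
    }
  }
})

test_that("variational posterior mean matches grid integration on
           2-isoform toys", {
  set.seed(11)
  beta <- rbind(c(0.4, 0.6, 0, 0), c(0.2, 0.2, 0.3, 0.3))
  compat <- (beta > 0) * 1L
  for (i in 1:5) {
    alpha <- runif(2, 0.5, 3)
    n <- round(runif(4, 0, 20))
    es <- ldm_e_step(n, alpha, beta, compat,
                     control = ldm_control(inner_tol = 1e-12))
    vb <- es$eta[1] / sum(es$eta)
    expect_lt(abs(vb - grid_posterior_mean(alpha, beta, n)), 0.05)
  }
})

test_that("fit recovers simulated fractions and absorbs little noise", {
  gm <- expand_gene_model(random_gene(4), 50)
  hp <- random_hyperparameters(gm, seed = 1004)
  tr <- simulate_counts(gm, hp$alpha, hp$beta, lanes = 3,
                        fragments_per_lane = 3000, seed = 2004)
  fit <- suppressWarnings(ldm_fit(tr$counts, gm))
  est <- fit$alpha / sum(fit$alpha)
  ann <- names(hp$alpha)
  # truth on the model's scale: share of length-normalized mass per isoform
  lu <- stats::setNames(gm$units$length, gm$units$id)
  mass <- tapply(1 / lu[tr$fragments$unit], tr$fragments$isoform, sum)
  truth <- as.numeric(mass[ann] / sum(mass))
  expect_lt(max(abs(unname(est[ann]) - truth)), 0.07)
  expect_lt(est[["noise"]], min(truth))
  expect_true(fit$converged)
  # support zeros stay exact zeros after the full fit
  expect_true(all(fit$beta[gm$compat == 0] == 0))
  expect_true(all(vapply(fit$lambda, function(l)
    all(l[gm$compat == 0] == 0), logical(1))))
})

test_that("all-zero counts short-circuit to a skip", {
  gm <- toy_model()
  raw <- matrix(0L, 2, 7, dimnames = list(NULL, gm$units$id))
  fit <- ldm_fit(normalize_counts(raw, gm$units$length, "toy", 10), gm)
  expect_true(fit$skipped)
})

test_that("the fit is deterministic given identical inputs", {
  gm <- toy_model()
  hp <- random_hyperparameters(gm, seed = 9)
  tr <- simulate_counts(gm, hp$alpha, hp$beta, lanes = 2,
                        fragments_per_lane = 400, seed = 31)
  f1 <- ldm_fit(tr$counts, gm)
  f2 <- ldm_fit(tr$counts, gm)
  expect_identical(f1$alpha, f2$alpha)
  expect_identical(f1$elbo_trace, f2$elbo_trace)
})
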