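# Shared fixtures and independent oracles for the test suite.

# Classic 4-exon, 2-isoform toy gene: I1 skips e2 (adjacency e1-e3), I2 skips
# e3 (adjacencies e1-e2, e2-e4). Expansion with L = 50 yields junction units
# e1-e3, e1-e2, e2-e4 plus the noise isoform: K = 3, E = 7.
toy_gene <- function() {
  gene_from_exons("toy", "chr1", list(
    I1 = data.frame(start = c(100, 700), end = c(300, 900)),
    I2 = data.frame(start = c(100, 400, 1000), end = c(300, 600, 1200))))
}

toy_model <- function(L = 50) expand_gene_model(toy_gene(), L)

# Brute-force base-by-base partition oracle: returns, for a set of exon
# spans, the sorted disjoint intervals covering their union, split at every
# position where the set of covering exons changes.
bruteforce_partition <- function(spans) {
  lo <- min(spans$start); hi <- max(spans$end)
  cover <- sapply(lo:(hi - 1), function(p)
    paste(which(spans$start <= p & spans$end > p), collapse = ","))
  runs <- rle(cover)
  ends <- lo + cumsum(runs$lengths)
  starts <- c(lo, ends[-length(ends)])
  keep <- runs$values != ""
  data.frame(start = starts[keep], end = ends[keep])
}

# Naive per-observation variational EM: each unit j of lane l is replicated
# raw[l, j] times as a unit-weight observation, and the classic per-document
# LDA updates are applied literally (one responsibility vector per
# observation, beta by a double sum over observations). The alpha update
# sees only eta, carries no aggregation, and is verified separately against
# a black-box optimizer, so both implementations share it here; mixing two
# alpha solvers would otherwise let rounding-level differences flip the
# trajectory near symmetric saddle points.
oracle_per_observation_fit <- function(raw, compat, outer = 100) {
  L <- nrow(raw); K <- nrow(compat); E <- ncol(compat)
  obs <- lapply(seq_len(L), function(l) rep(seq_len(E), raw[l, ]))
  alpha <- rep(1, K)
  beta <- compat / rowSums(compat)
  eta <- matrix(1, L, K)
  lam <- vector("list", L)
  for (it in seq_len(outer)) {
    for (l in seq_len(L)) {
      eta_l <- eta[l, ]
      for (inner in 1:1000) {
        w <- exp(digamma(eta_l) - digamma(sum(eta_l)))
        lm <- matrix(0, length(obs[[l]]), K)
        for (i in seq_along(obs[[l]])) {
          v <- beta[, obs[[l]][i]] * w
          lm[i, ] <- v / sum(v)
        }
        eta_new <- alpha + colSums(lm)
        conv <- max(abs(eta_new - eta_l)) < 1e-12
        eta_l <- eta_new
        if (conv) break
      }
      lam[[l]] <- lm
      eta[l, ] <- eta_l
    }
    bnew <- matrix(0, K, E)
    for (l in seq_len(L))
      for (i in seq_along(obs[[l]]))
        bnew[, obs[[l]][i]] <- bnew[, obs[[l]][i]] + lam[[l]][i, ]
    bnew <- bnew * compat
    beta <- bnew / pmax(rowSums(bnew), 1e-300)
    alpha <- ldm_m_step_alpha(eta, alpha,
                              ldm_control(alpha_tol = 1e-12))$alpha
  }
  lamu <- lapply(seq_len(L), function(l) {
    m <- matrix(NA_real_, K, E)
    for (j in seq_len(E)) {
      i <- which(obs[[l]] == j)[1]
      if (!is.na(i)) m[, j] <- lam[[l]][i, ]
    }
    m
  })
  list(alpha = alpha, beta = beta, eta = eta, lambda = lamu)
}

# The aggregated implementation run under the oracle's exact conditions
# (no init jitter, no noise-row freezing, no smoothing) for a fixed number
# of outer iterations.
plain_fit <- function(raw, compat, outer = 100) {
  ctrl <- ldm_control(init_jitter = 0, update_noise_beta = TRUE,
                      inner_tol = 1e-12, inner_max = 1000, pseudocount = 0,
                      alpha_tol = 1e-12)
  st <- ldm_initialize(compat, nrow(raw))
  alpha <- st$alpha; beta <- st$beta; eta <- st$eta; lambda <- st$lambda
  for (it in seq_len(outer)) {
    for (l in seq_len(nrow(raw))) {
      es <- ldm_e_step(raw[l, ], alpha, beta, compat, eta = eta[l, ],
                       control = ctrl)
      lambda[[l]] <- es$lambda
      eta[l, ] <- es$eta
    }
    beta <- ldm_m_step_beta(lambda, raw, compat, 0)
    alpha <- ldm_m_step_alpha(eta, alpha, ctrl)$alpha
  }
  list(alpha = alpha, beta = beta, eta = eta, lambda = lambda)
}

# Random small instance with genuine between-lane variation: odd lanes draw
# from the random profile sorted decreasing, even lanes from it sorted
# increasing. Strong between-lane contrast keeps the maximum-likelihood
# alpha finite (near-identical lanes drive the Dirichlet concentration to
# infinity), so fixed points are well-defined and comparable across
# implementations.
random_instance <- function(seed, K_max = 3, E_max = 5, lanes = 2,
                            depth = 60) {
  set.seed(seed)
  K <- sample(2:K_max, 1)
  E <- sample(3:E_max, 1)
  compat <- matrix(0L, K, E)
  for (k in seq_len(K)) compat[k, sample(E, sample(2:E, 1))] <- 1L
  compat[K, ] <- 1L
  rownames(compat) <- paste0("k", seq_len(K))
  colnames(compat) <- paste0("u", seq_len(E))
  p <- stats::rgamma(E, 1) + 0.05
  p <- p / sum(p)
  raw <- t(sapply(seq_len(lanes), function(l) {
    pl <- sort(p, decreasing = l %% 2 == 1)
    stats::rmultinom(1, depth, pl)[, 1]
  }))
  list(compat = compat, raw = raw)
}

# Dirichlet part of the bound, written independently of the package.
dirichlet_objective <- function(alpha, eta) {
  g <- digamma(eta) - digamma(rowSums(eta))
  nrow(eta) * (lgamma(sum(alpha)) - sum(lgamma(alpha))) +
    sum(sweep(matrix(g, nrow = nrow(eta)), 2L, alpha - 1, "*"))
}

# Exact posterior mean of theta_1 for a 2-isoform model by grid integration
# over the 1-simplex, under the same weighted likelihood the model uses.
grid_posterior_mean <- function(alpha, beta, n, grid = 4001) {
  th <- seq(1e-4, 1 - 1e-4, length.out = grid)
  logpost <- stats::dbeta(th, alpha[1], alpha[2], log = TRUE) +
    sapply(th, function(t) sum(n * log(t * beta[1, ] + (1 - t) * beta[2, ])))
  w <- exp(logpost - max(logpost))
  sum(th * w) / sum(w)
}

# ELBO trace monotone within relative tolerance?
trace_monotone <- function(trace, rel = 1e-8) {
  if (length(trace) < 2) return(TRUE)
  all(diff(trace) >= -rel * pmax(1, abs(trace[-length(trace)])))
}

# Write a minimal transcriptome SAM file (references = isoform ids).
write_test_sam <- function(path, sq, records) {
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:%s\tLN:%d", names(sq), as.integer(sq)),
               records), path)
  path
}
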