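## Latent Dirichlet-Multinomial model, variational EM ------------------------
##
## Per gene: each lane l of a single library draws its own isoform-fraction
## vector theta_l ~ Dirichlet(alpha); each observed exon-unit occurrence in
## that lane draws an isoform label t ~ Multinomial(1, theta_l) and then the
## unit itself from the isoform-specific emission row beta[t, ], which is the
## isoform- and exon-specific read sequencing rate (zero off the isoform's
## exon support). Observations of the same unit are exchangeable, so the
## variational responsibilities lambda are computed once per (lane, unit) and
## weighted by the length-normalized count n[l, j]; this is identical to the
## per-observation updates for integer counts and well-defined for
## fractional ones.
##
## q(theta_l) = Dirichlet(eta_l), q(t | lane l, unit j) = Multinomial(lambda).
## E-step fixed point (per lane):
##   lambda[k, j] propto beta[k, j] * exp(digamma(eta_k) - digamma(sum eta))
##   eta_k        = alpha_k + sum_j n[l, j] * lambda[k, j]
## M-step: beta[k, j] propto sum_l n[l, j] * lambda_l[k, j] on the support;
## alpha by Newton-Raphson on the Dirichlet term of the bound, using the
## diagonal-plus-rank-one Hessian structure.

#' Control parameters for the variational EM fit
#'
#' @param inner_tol max-abs change in lambda ending the per-lane E-step fixed
#'   point (default 1e-6).
#' @param inner_max cap on E-step fixed-point iterations (default 200).
#' @param outer_tol relative change in the evidence lower bound ending EM
#'   (default 1e-6).
#' @param outer_max cap on EM iterations (default 1000).
#' @param alpha_tol gradient max-norm ending the Newton solve for alpha
#'   (default 1e-8).
#' @param alpha_max cap on Newton iterations (default 100).
#' @param pseudocount additive smoothing applied to beta support entries
#'   before row normalization, avoiding exact-zero emission for observed
#'   units (default 1e-10).
#' @param update_noise_beta if `FALSE` (default) the noise isoform's emission
#'   row stays at its unbiased uniform-over-all-units value throughout EM, so
#'   the noise component can only explain an unstructured background and
#'   cannot specialize into a copy of an annotated isoform; set `TRUE` to
#'   re-estimate it like every other row.
#' @param init_jitter relative size of the deterministic perturbation applied
#'   to the annotated beta rows at initialization (default 1e-3). The exactly
#'   symmetric uniform start is a stationary point of EM whenever two
#'   isoforms have interchangeable supports; the fixed jitter pattern breaks
#'   such ties without introducing randomness. Set 0 to disable.
#' @return a list of class `ldm_control`.
#' @export
ldm_control <- function(inner_tol = 1e-6, inner_max = 200,
                        outer_tol = 1e-6, outer_max = 1000,
                        alpha_tol = 1e-8, alpha_max = 100,
                        pseudocount = 1e-10, update_noise_beta = FALSE,
                        init_jitter = 1e-3) {
  structure(list(inner_tol = inner_tol, inner_max = inner_max,
                 outer_tol = outer_tol, outer_max = outer_max,
                 alpha_tol = alpha_tol, alpha_max = alpha_max,
                 pseudocount = pseudocount,
                 update_noise_beta = update_noise_beta,
                 init_jitter = init_jitter),
            class = "ldm_control")
}

#' Unbiased initialization of hyperparameters and variational state
#'
#' alpha starts at all ones (no isoform preference); each beta row is uniform
#' over the isoform's compatibility support and exactly zero elsewhere; each
#' lane's eta starts at alpha; lambda starts uniform over the isoforms whose
#' support contains the unit.
#'
#' A fixed multiplicative jitter pattern (`1 + init_jitter * sin(k * j)`,
#' renormalized) is applied to the non-noise beta rows: with two isoforms of
#' interchangeable support the perfectly symmetric start is a stationary
#' point EM cannot leave, and the deterministic pattern breaks the tie
#' without randomness.
#'
#' @param compat K x E 0/1 compatibility mask (noise row all ones).
#' @param n_lanes number of lanes.
#' @param noise_row index of the noise isoform's row (left unjittered), or
#'   `NULL`.
#' @param init_jitter relative jitter size (see [ldm_control()]).
#' @return list with `alpha` (K), `beta` (K x E), `eta` (lanes x K), `lambda`
#'   (list per lane of K x E responsibility matrices).
#' @export
ldm_initialize <- function(compat, n_lanes, noise_row = NULL,
                           init_jitter = 0) {
  K <- nrow(compat); E <- ncol(compat)
  alpha <- stats::setNames(rep(1, K), rownames(compat))
  beta <- sweep(compat, 1L, rowSums(compat), "/")
  if (init_jitter > 0) {
    pert <- 1 + init_jitter * sin(outer(seq_len(K), seq_len(E)))
    if (!is.null(noise_row)) pert[noise_row, ] <- 1
    beta <- beta * pert
    beta <- sweep(beta, 1L, rowSums(beta), "/")
  }
  lam0 <- sweep(compat, 2L, pmax(colSums(compat), 1L), "/")
  eta <- matrix(alpha, n_lanes, K, byrow = TRUE,
                dimnames = list(NULL, rownames(compat)))
  list(alpha = alpha, beta = beta, eta = eta,
       lambda = rep(list(lam0), n_lanes))
}

#' One lane's E-step fixed point
#'
#' Alternates the lambda and eta updates until the responsibilities
#' stabilize. lambda columns are normalized over isoforms for every unit
#' (the variational factor of a multinomial must normalize); support zeros
#' are preserved exactly.
#'
#' @param n length-E vector of normalized counts for the lane.
#' @param alpha current Dirichlet hyperparameter (length K).
#' @param beta current K x E emission matrix (row-stochastic on support).
#' @param compat K x E 0/1 mask.
#' @param eta optional warm-start eta row.
#' @param control an [ldm_control()].
#' @return list with `lambda` (K x E) and `eta` (length K).
#' @export
ldm_e_step <- function(n, alpha, beta, compat, eta = NULL,
                       control = ldm_control()) {
  K <- nrow(beta)
  if (is.null(eta)) eta <- alpha
  lam <- matrix(0, K, ncol(beta), dimnames = dimnames(beta))
  lam_old <- lam + Inf
  for (it in seq_len(control$inner_max)) {
    w <- exp(digamma(eta) - digamma(sum(eta)))   # length K
    lam <- beta * w                              # rows scaled by w
    cs <- colSums(lam)
    pos <- cs > 0
    lam[, pos] <- sweep(lam[, pos, drop = FALSE], 2L, cs[pos], "/")
    if (any(!pos)) {  # no isoform emits this unit: fall back to mask-uniform
      cc <- colSums(compat[, !pos, drop = FALSE])
      lam[, !pos] <- sweep(compat[, !pos, drop = FALSE], 2L, pmax(cc, 1L), "/")
    }
    eta <- alpha + as.vector(lam %*% n)
    if (any(!is.finite(eta)) || any(!is.finite(lam)))
      stop("numerical failure in E-step")
    if (max(abs(lam - lam_old)) < control$inner_tol) break
    lam_old <- lam
  }
  list(lambda = lam, eta = eta)
}

#' M-step update of the emission matrix beta
#'
#' `beta[k, j] propto sum_l n[l, j] * lambda_l[k, j]` on the compatibility
#' support, row-normalized; entries off the support stay exactly zero. Rows
#' that collected no mass fall back to uniform-on-support.
#'
#' @param lambda list (per lane) of K x E responsibility matrices.
#' @param n lanes x E matrix of normalized counts.
#' @param compat K x E 0/1 mask.
#' @param pseudocount additive smoothing on support entries.
#' @return row-stochastic K x E matrix.
#' @export
ldm_m_step_beta <- function(lambda, n, compat, pseudocount = 1e-10) {
  acc <- matrix(0, nrow(compat), ncol(compat), dimnames = dimnames(compat))
  for (l in seq_along(lambda))
    acc <- acc + sweep(lambda[[l]], 2L, n[l, ], "*")
  acc <- acc * compat + pseudocount * compat
  rs <- rowSums(acc)
  empty <- rs <= 0
  if (any(empty)) {
    acc[empty, ] <- compat[empty, , drop = FALSE]
    rs[empty] <- rowSums(compat[empty, , drop = FALSE])
  }
  sweep(acc, 1L, rs, "/")
}

## Dirichlet portion of the bound and its Newton maximizer -------------------

dirichlet_term <- function(alpha, g) {
  # g: lanes x K matrix of E[log theta_lk] = digamma(eta_lk) - digamma(sum)
  L <- nrow(g)
  L * (lgamma(sum(alpha)) - sum(lgamma(alpha))) +
    sum(sweep(g, 2L, alpha - 1, "*"))
}

#' M-step update of alpha by Newton-Raphson
#'
#' Maximizes the alpha-dependent part of the bound,
#' `sum_l [log Gamma(sum alpha) - sum_k log Gamma(alpha_k)
#'        + sum_k (alpha_k - 1) (digamma(eta_lk) - digamma(sum_k eta_lk))]`,
#' with Newton steps solved in O(K) through the diagonal-plus-rank-one
#' Hessian. Positivity is kept by step halving (up to 20 halvings, floor
#' 1e-10); a step is only accepted if it does not decrease the objective, so
#' the EM bound cannot move down here.
#'
#' @param eta lanes x K matrix of variational Dirichlet parameters.
#' @param alpha current value (length K), used as the starting point.
#' @param control an [ldm_control()].
#' @return list with `alpha`, `converged`, `objective`.
#' @export
ldm_m_step_alpha <- function(eta, alpha, control = ldm_control()) {
  g <- digamma(eta) - digamma(rowSums(eta))   # lanes x K
  if (is.null(dim(g))) g <- matrix(g, nrow = 1L)
  L <- nrow(g)
  s <- colSums(g)
  obj <- dirichlet_term(alpha, g)
  converged <- FALSE
  for (it in seq_len(control$alpha_max)) {
    grad <- L * (digamma(sum(alpha)) - digamma(alpha)) + s
    if (max(abs(grad)) < control$alpha_tol) { converged <- TRUE; break }
    q <- -L * trigamma(alpha)                 # Hessian diagonal
    z <- L * trigamma(sum(alpha))             # rank-one coefficient
    b <- sum(grad / q) / (1 / z + sum(1 / q))
    step <- (grad - b) / q                    # H^{-1} grad (Sherman-Morrison)
    accepted <- FALSE
    for (h in seq_len(20)) {
      cand <- alpha - step
      if (all(cand > 0)) {
        cand <- pmax(cand, 1e-10)
        cobj <- dirichlet_term(cand, g)
        if (is.finite(cobj) && cobj >= obj - 1e-12 * abs(obj)) {
          alpha <- cand; obj <- cobj; accepted <- TRUE; break
        }
      }
      step <- step / 2
    }
    if (!accepted) break
  }
  list(alpha = alpha, converged = converged, objective = obj)
}

#' Evidence lower bound of the fit
#'
#' Expected log joint under q plus the entropy of q; this full bound (not the
#' expected log joint alone) is what EM is guaranteed not to decrease, so it
#' is what the fit traces.
#'
#' @param alpha,beta current hyperparameters.
#' @param eta lanes x K variational Dirichlet parameters.
#' @param lambda list per lane of K x E responsibilities.
#' @param n lanes x E normalized counts.
#' @return scalar bound value.
#' @export
ldm_elbo <- function(alpha, beta, eta, lambda, n) {
  g <- digamma(eta) - digamma(rowSums(eta))
  if (is.null(dim(g))) g <- matrix(g, nrow = 1L)
  lb <- ifelse(beta > 0, log(beta), 0)
  total <- dirichlet_term(alpha, g)
  for (l in seq_len(nrow(n))) {
    lam <- lambda[[l]]
    w <- sweep(lam, 2L, n[l, ], "*")          # K x E weights
    total <- total + sum(w * g[l, ])          # E[log p(t | theta)]
    total <- total + sum(w * lb)              # E[log p(e | t, beta)]
    total <- total - sum(w * ifelse(lam > 0, log(lam), 0))  # H[q(t)]
    # entropy of q(theta_l)
    e <- eta[l, ]
    total <- total - (lgamma(sum(e)) - sum(lgamma(e)) + sum((e - 1) * g[l, ]))
  }
  total
}

#' Fit the model for one gene by variational EM
#'
#' Alternates per-lane E-steps with the beta and alpha M-steps until the
#' relative change of the bound drops below `control$outer_tol` or
#' `control$outer_max` iterations are reached. Deterministic given inputs
#' and control. Genes with no positive count are flagged `skipped` (the
#' expression layer reports them as zero).
#'
#' @param counts an `exon_counts` object (or a plain lanes x E matrix of
#'   normalized counts).
#' @param gene_model a `gene_model` (or a bare compat mask).
#' @param control an [ldm_control()].
#' @return an `ldm_fit`: alpha, beta, eta, lambda, elbo_trace, converged,
#'   n_iterations, skipped, gene_id.
#' @export
ldm_fit <- function(counts, gene_model, control = ldm_control()) {
  n <- if (inherits(counts, "exon_counts")) counts$normalized else counts
  compat <- if (inherits(gene_model, "gene_model")) gene_model$compat
            else gene_model
  gene_id <- if (inherits(gene_model, "gene_model")) gene_model$gene_id
             else "gene"
  if (!all(dim(n)[2] == ncol(compat))) stop("counts/model dimension mismatch")
  if (sum(n) <= 0) {
    return(structure(list(gene_id = gene_id, skipped = TRUE,
                          converged = FALSE, elbo_trace = numeric(0),
                          alpha = NULL, beta = NULL, eta = NULL,
                          lambda = NULL, n_iterations = 0L),
                     class = "ldm_fit"))
  }
  # Observation weights: the length-normalized profile rescaled so the total
  # weight equals the raw fragment tally. N = sum_i n_i plays the role of the
  # number of observed exons in the Dirichlet-Multinomial, so its scale must
  # be commensurate with the fragment count; the per-base profile alone would
  # shrink the evidence by roughly the mean unit length.
  if (inherits(counts, "exon_counts") && sum(counts$raw) > 0)
    n <- n * sum(counts$raw) / sum(n)
  noise_row <- if (inherits(gene_model, "gene_model"))
    which(gene_model$isoforms$is_noise)
  else match("noise", rownames(compat))
  if (length(noise_row) == 0L || all(is.na(noise_row))) noise_row <- NULL
  st <- ldm_initialize(compat, nrow(n), noise_row = noise_row,
                       init_jitter = control$init_jitter)
  alpha <- st$alpha; beta <- st$beta; eta <- st$eta; lambda <- st$lambda
  beta_noise0 <- if (!is.null(noise_row)) beta[noise_row, ] else NULL
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(control$outer_max)) {
    for (l in seq_len(nrow(n))) {
      es <- ldm_e_step(n[l, ], alpha, beta, compat, eta = eta[l, ],
                       control = control)
      lambda[[l]] <- es$lambda
      eta[l, ] <- es$eta
    }
    beta <- ldm_m_step_beta(lambda, n, compat, control$pseudocount)
    if (!control$update_noise_beta && !is.null(noise_row))
      beta[noise_row, ] <- beta_noise0
    alpha <- ldm_m_step_alpha(eta, alpha, control)$alpha
    bound <- ldm_elbo(alpha, beta, eta, lambda, n)
    if (!is.finite(bound)) stop("numerical failure fitting gene ", gene_id)
    trace <- c(trace, bound)
    if (it > 1L) {
      rel <- abs(trace[it] - trace[it - 1L]) /
        max(1, abs(trace[it - 1L]))
      if (rel < control$outer_tol) { converged <- TRUE; break }
    }
  }
  structure(list(gene_id = gene_id, skipped = FALSE, alpha = alpha,
                 beta = beta, eta = eta, lambda = lambda, elbo_trace = trace,
                 converged = converged, n_iterations = length(trace)),
            class = "ldm_fit")
}

#' @export
print.ldm_fit <- function(x, ...) {
  if (isTRUE(x$skipped)) {
    cat("ldm_fit", x$gene_id, ": skipped (no counts)\n")
  } else {
    cat("ldm_fit", x$gene_id, ": K =", length(x$alpha),
        ", iterations =", x$n_iterations,
        ", converged =", x$converged, "\n")
    cat("  <theta> =", round(x$alpha / sum(x$alpha), 4), "\n")
  }
  invisible(x)
}
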