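## Expression representation -------------------------------------------------
##
## The fitted Dirichlet hyperparameter alpha carries the underlying isoform
## fractions: <theta_k> = alpha_k / sum(alpha). FPKM of isoform k is
##   f_k = 1e9 * theta_k / N_s * sum_{l,i} n_{l,i}
## with n the per-base length-normalized unit counts (so no further division
## by isoform length appears: summing per-base densities over the gene's
## units and lanes already yields a per-kilobase quantity once the 1e9
## = 1e3 (kb) * 1e6 (per million) factor is applied). Gene expression is the
## sum of isoform FPKMs; the noise isoform is reported but excluded from the
## gene total by default. Measurement uncertainty comes from M Monte-Carlo
## draws theta^(m) ~ Dirichlet(alpha) pushed through the same formula.

noise_index <- function(noise, nms) {
  i <- if (is.character(noise)) match(noise, nms) else as.integer(noise)
  i[!is.na(i)]
}

#' Posterior-mean isoform fractions from alpha
#'
#' @param alpha positive Dirichlet vector.
#' @return fractions `alpha / sum(alpha)` (sums to one).
#' @export
isoform_fraction <- function(alpha) {
  if (any(alpha <= 0)) stop("alpha must be positive")
  alpha / sum(alpha)
}

#' Draw from a Dirichlet distribution
#'
#' Gamma-ratio construction; rows are simplex vectors.
#'
#' @param n number of draws.
#' @param alpha concentration vector.
#' @return n x K matrix.
#' @export
rdirichlet <- function(n, alpha) {
  K <- length(alpha)
  x <- matrix(stats::rgamma(n * K, shape = rep(alpha, each = n)), n, K)
  sw <- sweep(x, 1L, rowSums(x), "/")
  colnames(sw) <- names(alpha)
  sw
}

#' Isoform and gene FPKM from fractions and counts
#'
#' @param theta isoform-fraction vector (length K, sums to 1).
#' @param counts an `exon_counts` with positive `N_s`.
#' @param noise name or index of the noise isoform, or `NULL`.
#' @param include_noise if `FALSE` (default) the noise isoform's FPKM is
#'   reported but left out of the gene total.
#' @return list with `isoform` (named vector f_k) and `gene` (scalar).
#' @export
fpkm <- function(theta, counts, noise = NULL, include_noise = FALSE) {
  if (is.na(counts$N_s) || counts$N_s <= 0)
    stop("N_s (total mapped fragments) must be positive")
  f <- 1e9 * theta / counts$N_s * sum(counts$normalized)
  gene <- if (is.null(noise) || include_noise) sum(f)
          else sum(f[-noise_index(noise, names(f))])
  list(isoform = f, gene = gene)
}

#' Monte-Carlo measurement uncertainty of expression
#'
#' Draws `M` samples theta^(m) ~ Dirichlet(alpha), applies the FPKM formula
#' to each, and reports the per-isoform and gene-level sample variances.
#' Reproducible under `seed`.
#'
#' @param alpha fitted Dirichlet vector.
#' @param counts an `exon_counts`.
#' @param M number of draws (>= 2; default 100).
#' @param seed integer seed.
#' @inheritParams fpkm
#' @return list with `theta_samples` (M x K), `fpkm_samples` (M x K),
#'   `fpkm_variance` (per isoform), `gene_fpkm_variance`.
#' @export
sample_uncertainty <- function(alpha, counts, M = 100, seed = 1,
                               noise = NULL, include_noise = FALSE) {
  stopifnot(M >= 2)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  th <- rdirichlet(M, alpha)
  scale <- 1e9 * sum(counts$normalized) / counts$N_s
  fs <- th * scale
  keep <- if (is.null(noise) || include_noise) seq_along(alpha)
          else setdiff(seq_along(alpha), noise_index(noise, names(alpha)))
  list(theta_samples = th, fpkm_samples = fs,
       fpkm_variance = apply(fs, 2L, stats::var),
       gene_fpkm_variance = stats::var(rowSums(fs[, keep, drop = FALSE])))
}

#' Direct FPKM for single-isoform genes
#'
#' For a gene with exactly one annotated isoform no mixture needs to be
#' resolved; expression is the plain FPKM under a uniform read distribution:
#' `1e9 * fragments / (N_s * isoform length in bases)`.
#'
#' @param fragment_total raw fragment count for the gene (all lanes).
#' @param isoform_length transcript length in bases (> 0).
#' @param N_s total mapped fragments for the sample.
#' @return scalar FPKM.
#' @export
single_isoform_expression <- function(fragment_total, isoform_length, N_s) {
  if (!is.finite(isoform_length) || isoform_length <= 0)
    stop("invalid model: non-positive isoform length")
  if (is.na(N_s) || N_s <= 0) stop("N_s must be positive")
  1e9 * fragment_total / (N_s * isoform_length)
}

#' Full expression estimate for one fitted gene
#'
#' Combines the fraction, FPKM and uncertainty layers into the per-gene
#' record written to the expression tables.
#'
#' @param fit an `ldm_fit` (possibly skipped).
#' @param counts the matching `exon_counts`.
#' @param gene_model the matching `gene_model`.
#' @param M Monte-Carlo sample count.
#' @param seed integer seed for the uncertainty draws.
#' @param include_noise include the noise isoform in the gene FPKM total.
#' @return an `expression_estimate`: gene_id, table (isoform rows with
#'   theta_mean, fpkm, fpkm_variance, is_noise), gene_fpkm,
#'   gene_fpkm_variance, M, seed, theta_samples.
#' @export
gene_expression <- function(fit, counts, gene_model, M = 100, seed = 1,
                            include_noise = FALSE) {
  iso <- gene_model$isoforms
  noise_id <- iso$id[iso$is_noise]
  if (isTRUE(fit$skipped)) {
    tab <- data.frame(gene_id = gene_model$gene_id, isoform_id = iso$id,
                      is_noise = iso$is_noise, theta_mean = NA_real_,
                      fpkm = 0, fpkm_variance = 0)
    return(structure(list(gene_id = gene_model$gene_id, table = tab,
                          gene_fpkm = 0, gene_fpkm_variance = 0,
                          M = M, seed = seed, theta_samples = NULL,
                          skipped = TRUE),
                     class = "expression_estimate"))
  }
  theta <- isoform_fraction(fit$alpha)
  fk <- fpkm(theta, counts, noise = noise_id, include_noise = include_noise)
  unc <- sample_uncertainty(fit$alpha, counts, M = M, seed = seed,
                            noise = noise_id, include_noise = include_noise)
  tab <- data.frame(gene_id = gene_model$gene_id, isoform_id = names(theta),
                    is_noise = names(theta) %in% noise_id,
                    theta_mean = as.numeric(theta),
                    fpkm = as.numeric(fk$isoform),
                    fpkm_variance = as.numeric(unc$fpkm_variance))
  structure(list(gene_id = gene_model$gene_id, table = tab,
                 gene_fpkm = fk$gene,
                 gene_fpkm_variance = unc$gene_fpkm_variance,
                 M = M, seed = seed, theta_samples = unc$theta_samples,
                 skipped = FALSE),
            class = "expression_estimate")
}

#' @export
print.expression_estimate <- function(x, ...) {
  cat("expression_estimate", x$gene_id,
      if (isTRUE(x$skipped)) "(skipped)" else "", "\n")
  print(x$table[, c("isoform_id", "theta_mean", "fpkm", "fpkm_variance")],
        row.names = FALSE)
  cat("gene FPKM:", x$gene_fpkm, "( variance", x$gene_fpkm_variance, ")\n")
  invisible(x)
}
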