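## Single-run orchestration --------------------------------------------------
##
## expand -> count -> fit -> express, one call. Genes are processed
## independently (results do not depend on processing order), single-isoform
## genes take the direct-FPKM shortcut and skip the EM, and every run writes
## a JSON report describing its configuration, skipped genes and dropped
## fragments, so runs are self-describing and reproducible.

#' Quantify isoform and gene expression from annotation plus alignments
#'
#' @param annotation GTF/GFF path.
#' @param alignments named character vector of per-lane SAM/BAM paths
#'   (names are lane labels).
#' @param read_length read length `L` in bases.
#' @param out_dir output directory (created if absent); set `NULL` to skip
#'   writing files.
#' @param M Monte-Carlo sample count for measurement uncertainty.
#' @param seed integer seed (uncertainty sampling only; the fit itself is
#'   deterministic).
#' @param include_noise include the noise isoform in gene FPKM totals.
#' @param control an [ldm_control()].
#' @return invisibly, a list with `expression` (isoform-level data.frame),
#'   `genes` (gene-level data.frame), `fits`, `counts`, `models`, `report`.
#' @export
run_quantify <- function(annotation, alignments, read_length,
                         out_dir = NULL, M = 100, seed = 1,
                         include_noise = FALSE, control = ldm_control()) {
  for (p in c(annotation, alignments))
    if (!file.exists(p)) stop("input not found: ", p)
  genes <- parse_annotation(annotation)
  models <- expand_annotation(genes, read_length)
  cf <- count_fragments(alignments, models)
  counts <- lapply(models, function(gm)
    normalize_counts(cf$raw[[gm$gene_id]], gm$units$length, gm$gene_id,
                     N_s = cf$N_s))
  fits <- list()
  est <- list()
  skipped <- character(0)
  unconverged <- character(0)
  for (g in names(models)) {
    gm <- models[[g]]
    n_annot <- sum(!gm$isoforms$is_noise)
    if (n_annot == 1L) {
      iso_id <- gm$isoforms$id[!gm$isoforms$is_noise]
      f <- single_isoform_expression(
        sum(counts[[g]]$raw), gm$isoforms$length[!gm$isoforms$is_noise],
        cf$N_s)
      tab <- data.frame(gene_id = g, isoform_id = iso_id, is_noise = FALSE,
                        theta_mean = 1, fpkm = f, fpkm_variance = 0)
      est[[g]] <- structure(list(gene_id = g, table = tab, gene_fpkm = f,
                                 gene_fpkm_variance = 0, M = M, seed = seed,
                                 theta_samples = NULL, skipped = FALSE),
                            class = "expression_estimate")
      next
    }
    fit <- ldm_fit(counts[[g]], gm, control)
    fits[[g]] <- fit
    if (isTRUE(fit$skipped)) skipped <- c(skipped, g)
    else if (!fit$converged) unconverged <- c(unconverged, g)
    est[[g]] <- gene_expression(fit, counts[[g]], gm, M = M, seed = seed,
                                include_noise = include_noise)
  }
  expression <- do.call(rbind, c(lapply(est, `[[`, "table"),
                                 list(make.row.names = FALSE)))
  gene_tab <- data.frame(
    gene_id = names(est),
    gene_fpkm = vapply(est, `[[`, numeric(1), "gene_fpkm"),
    gene_fpkm_variance = vapply(est, `[[`, numeric(1), "gene_fpkm_variance"),
    row.names = NULL)
  report <- list(
    annotation = annotation, lanes = as.list(alignments),
    read_length = read_length, M = M, seed = seed,
    include_noise = include_noise, control = unclass(control),
    N_s = cf$N_s, counting = cf$stats,
    n_genes = length(models), skipped_genes = skipped,
    unconverged_genes = unconverged)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(expression, file.path(out_dir, "isoform_expression.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(gene_tab, file.path(out_dir, "gene_expression.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_gene_models(models, file.path(out_dir, "gene_models"))
    write_counts_tsv(counts, file.path(out_dir, "exon_counts.tsv"))
    jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(list(expression = expression, genes = gene_tab, fits = fits,
                 counts = counts, models = models, report = report))
}

#' Simulate a dataset from an annotation
#'
#' Expands the annotation, draws per-gene hyperparameters (alpha uniform in
#' `alpha_range` over annotated isoforms; beta rows Dirichlet-uniform over
#' each isoform's support) unless supplied, and runs the read-level
#' simulator per gene, writing FASTQ, per-lane SAM and truth tables.
#'
#' @param annotation GTF/GFF path.
#' @param out_dir output directory.
#' @param read_length read length `L`.
#' @param mode `"paired"` or `"single"`.
#' @param lanes lanes simulated.
#' @param fragments_per_gene fragments per gene per lane.
#' @param seed integer seed.
#' @param alpha_range range for the per-isoform Dirichlet concentrations.
#' @return invisibly, named list of `sim_truth` per gene.
#' @export
run_simulate <- function(annotation, out_dir, read_length,
                         mode = c("paired", "single"), lanes = 3,
                         fragments_per_gene = 1000, seed = 1,
                         alpha_range = c(0.5, 5)) {
  mode <- match.arg(mode)
  models <- expand_annotation(parse_annotation(annotation), read_length)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  for (gi in seq_along(models)) {
    gm <- models[[gi]]
    hp <- random_hyperparameters(gm, seed = seed + gi)
    out[[gm$gene_id]] <- simulate_reads(
      gm, hp$alpha, hp$beta, mode = mode, lanes = lanes,
      fragments_per_lane = fragments_per_gene, seed = seed + gi,
      fastq_prefix = file.path(out_dir, gm$gene_id),
      sam_path = file.path(out_dir, paste0(gm$gene_id, ".sam")))
    write_sim_truth(out[[gm$gene_id]],
                    file.path(out_dir, paste0(gm$gene_id, ".truth")))
  }
  invisible(out)
}

#' Random annotated-isoform hyperparameters for a gene model
#'
#' alpha_k ~ Uniform(`alpha_range`) per annotated isoform. Each beta row is
#' proportional to unit length modulated by a lognormal exon-specific bias:
#' `beta[k, j] propto length_j * exp(N(0, bias_sd))` on the isoform's
#' support, zero elsewhere. To first order a fragment's landing probability
#' scales with the exon's length; the lognormal factor is the isoform- and
#' exon-specific sequencing bias the model is built to capture. The noise
#' isoform gets no mass: simulated data comes from annotated isoforms only.
#'
#' @param gene_model a `gene_model`.
#' @param seed integer seed.
#' @param alpha_range concentration range.
#' @param bias_sd log-scale standard deviation of the per-exon sequencing
#'   bias (default 0.4, i.e. multiplicative factors mostly within 2.2-fold).
#' @return list with named `alpha` and `beta` (annotated rows x all units).
#' @export
random_hyperparameters <- function(gene_model, seed = 1,
                                   alpha_range = c(0.5, 5), bias_sd = 0.4) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  ann <- gene_model$isoforms$id[!gene_model$isoforms$is_noise]
  alpha <- stats::setNames(
    stats::runif(length(ann), alpha_range[1], alpha_range[2]), ann)
  beta <- matrix(0, length(ann), nrow(gene_model$units),
                 dimnames = list(ann, gene_model$units$id))
  len <- stats::setNames(gene_model$units$length, gene_model$units$id)
  for (k in ann) {
    sup <- gene_model$iso_units[[k]]
    w <- len[sup] * exp(stats::rnorm(length(sup), 0, bias_sd))
    beta[k, sup] <- w / sum(w)
  }
  list(alpha = alpha, beta = beta)
}
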