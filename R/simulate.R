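## Generative simulator ------------------------------------------------------
##
## Mirrors the model's own generative process. Count level: per lane draw
## theta_l ~ Dirichlet(alpha); per fragment draw an isoform label
## t ~ Multinomial(1, theta_l) and an exon unit e ~ Multinomial(1, beta[t, ]);
## tally and length-normalize exactly as the counting module does. Read
## level: additionally place each fragment inside its unit -- uniform start
## for a single-end read of length L, and for paired-end a fragment length
## from Normal(206, sd 19.6) (rounded, clamped to [L, unit length]) with a
## uniform start -- and emit FASTQ plus an optional pre-projected SAM against
## the annotated transcriptome, so the counting module can consume the
## simulator's output without an external aligner. Every draw is recorded in
## a truth table.

#' Simulate exon-level counts with ground truth
#'
#' `alpha`/`beta` may cover all isoforms of the model or only the annotated
#' ones (rows matched by name); isoforms absent from `alpha` are simply
#' never drawn, which is how data "from annotated isoforms only" is made.
#'
#' @param gene_model a `gene_model`.
#' @param alpha named positive Dirichlet vector over the simulated isoforms.
#' @param beta matrix of emission rows (rownames = isoform ids, columns =
#'   unit ids in model order), each row summing to 1 on the isoform support.
#' @param lanes number of lanes.
#' @param fragments_per_lane fragments drawn per lane.
#' @param seed integer seed.
#' @param N_s sample-wide fragment total recorded in the counts (defaults to
#'   `lanes * fragments_per_lane`).
#' @return a `sim_truth`: alpha, theta (lanes x K), fragments (data.frame
#'   lane, fragment_id, isoform, unit), raw counts matrix, `counts`
#'   (an `exon_counts`), seed.
#' @export
simulate_counts <- function(gene_model, alpha, beta, lanes = 3,
                            fragments_per_lane = 1000, seed = 1,
                            N_s = lanes * fragments_per_lane) {
  stopifnot(all(alpha > 0), nrow(beta) == length(alpha))
  units <- gene_model$units$id
  if (is.null(colnames(beta))) colnames(beta) <- units
  if (is.null(names(alpha))) names(alpha) <- rownames(beta)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  theta <- rdirichlet(lanes, alpha)
  rownames(theta) <- paste0("lane", seq_len(lanes))
  frs <- vector("list", lanes)
  raw <- matrix(0L, lanes, length(units),
                dimnames = list(rownames(theta), units))
  for (l in seq_len(lanes)) {
    if (fragments_per_lane > 0) {
      iso <- sample(names(alpha), fragments_per_lane, replace = TRUE,
                    prob = theta[l, ])
      unit <- character(fragments_per_lane)
      for (k in unique(iso)) {       # vectorized per isoform, order-stable
        sel <- iso == k
        unit[sel] <- sample(colnames(beta), sum(sel), replace = TRUE,
                            prob = beta[k, ])
      }
      frs[[l]] <- data.frame(
        lane = rownames(theta)[l],
        fragment_id = sprintf("frag_l%d_%06d", l, seq_len(fragments_per_lane)),
        isoform = iso, unit = unit, row.names = NULL)
      tab <- table(factor(unit, levels = units))
      raw[l, ] <- as.integer(tab)
    }
  }
  fragments <- do.call(rbind, frs)
  counts <- normalize_counts(raw, gene_model$units$length,
                             gene_model$gene_id, N_s = N_s)
  structure(list(alpha = alpha, theta = theta, fragments = fragments,
                 raw = raw, counts = counts, seed = seed,
                 gene_id = gene_model$gene_id),
            class = "sim_truth")
}

#' Random nucleotide sequences for a gene model's units
#'
#' Synthetic uniform A/C/G/T sequences (one per unit, junction units
#' included), used when no real exon FASTA is supplied so that read-level
#' simulation is self-contained.
#'
#' @param gene_model a `gene_model`.
#' @param seed integer seed.
#' @return named character vector of sequences, one per unit.
#' @export
synthetic_unit_sequences <- function(gene_model, seed = 1) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  u <- gene_model$units
  stats::setNames(vapply(u$length, function(len)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1)), u$id)
}

revcomp <- function(s) {
  chartr("ACGTacgt", "TGCAtgca",
         vapply(s, function(x) paste(rev(strsplit(x, "")[[1]]), collapse = ""),
                character(1), USE.NAMES = FALSE))
}

# host transcript carrying a unit: for junction units, an annotated isoform
# containing that adjacency; for body units, any annotated isoform using it.
host_isoform <- function(gm, unit) {
  ann <- gm$isoforms$id[!gm$isoforms$is_noise]
  row <- gm$units[gm$units$id == unit, ]
  if (isTRUE(row$is_junction)) {
    for (k in ann) {
      ids <- gm$iso_units[[k]]
      if (unit %in% ids) {
        lay <- isoform_layout(gm, k)
        if (unit %in% lay$junctions$unit) return(k)
      }
    }
    return(NA_character_)
  }
  for (k in ann) if (unit %in% gm$iso_units[[k]]) return(k)
  NA_character_
}

#' Simulate reads (FASTQ, optional SAM) with ground truth
#'
#' Count-level draws as in [simulate_counts()], then per fragment a position
#' inside its unit. Single-end: uniform start, read length `L`. Paired-end:
#' fragment length drawn from Normal(`frag_mean`, `frag_sd`), rounded and
#' clamped to `[L, unit length]` (mates may overlap for short fragments),
#' uniform start; mates are emitted forward/reverse-complement. Fragments
#' landing in a body unit shorter than `L` are redrawn (bounded retries,
#' then skipped and reported). The optional SAM is written against the
#' annotated transcriptome (one reference per annotated isoform; each
#' fragment is placed on a host isoform containing its unit), so piping it
#' through [count_fragments()] reproduces the truth counts exactly.
#'
#' @inheritParams simulate_counts
#' @param sequences named unit sequences; defaults to
#'   [synthetic_unit_sequences()] under the same seed.
#' @param mode `"single"` or `"paired"`.
#' @param read_length read length `L` (defaults to the model's).
#' @param frag_mean,frag_sd paired-end fragment-length law (206, 19.6).
#' @param fastq_prefix path prefix for FASTQ output (`_1`/`_2` suffixes in
#'   paired mode), or `NULL` to skip writing.
#' @param sam_path optional per-lane SAM output; a `%s` in the path is
#'   replaced by the lane label, otherwise `.laneN` is inserted.
#' @return a `sim_truth` with additional per-fragment columns (host isoform,
#'   start within unit, fragment length, raw Gaussian length before
#'   clamping), `files` listing outputs, and `skipped_fragments`.
#' @export
simulate_reads <- function(gene_model, alpha, beta, mode = c("paired", "single"),
                           read_length = gene_model$read_length,
                           frag_mean = 206, frag_sd = 19.6,
                           lanes = 3, fragments_per_lane = 1000, seed = 1,
                           sequences = NULL, fastq_prefix = NULL,
                           sam_path = NULL,
                           N_s = lanes * fragments_per_lane) {
  mode <- match.arg(mode)
  L <- as.integer(read_length)
  if (is.null(sequences)) sequences <- synthetic_unit_sequences(gene_model, seed)
  ulen <- stats::setNames(gene_model$units$length, gene_model$units$id)
  feasible <- names(ulen)[ulen >= L]
  truth <- simulate_counts(gene_model, alpha, beta, lanes = lanes,
                           fragments_per_lane = fragments_per_lane,
                           seed = seed, N_s = N_s)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed + 1L)
  fr <- truth$fragments
  skipped <- 0L
  if (!is.null(fr) && nrow(fr) > 0L) {
    # redraw fragments whose unit cannot hold a read (bounded retries)
    for (tries in seq_len(100L)) {
      bad <- which(!(fr$unit %in% feasible))
      if (length(bad) == 0L) break
      for (i in bad) {
        k <- fr$isoform[i]
        fr$unit[i] <- sample(colnames(truth$counts$raw), 1L,
                             prob = beta[k, ])
      }
    }
    bad <- which(!(fr$unit %in% feasible))
    if (length(bad) > 0L) {
      skipped <- length(bad)
      warning(skipped, " fragment(s) skipped: no unit long enough for reads")
      fr <- fr[-bad, , drop = FALSE]
    }
    # recompute raw counts after any redraws/skips
    for (l in seq_len(nrow(truth$raw))) {
      sel <- fr$lane == rownames(truth$raw)[l]
      truth$raw[l, ] <- as.integer(table(factor(fr$unit[sel],
                                                levels = colnames(truth$raw))))
    }
    truth$counts <- normalize_counts(truth$raw, gene_model$units$length,
                                     gene_model$gene_id, N_s = N_s)
    fr$host <- vapply(fr$unit, function(u) host_isoform(gene_model, u),
                      character(1))
    n <- nrow(fr)
    if (mode == "paired") {
      fr$raw_length <- stats::rnorm(n, frag_mean, frag_sd)
      fr$frag_length <- pmin(pmax(round(fr$raw_length), L), ulen[fr$unit])
    } else {
      fr$raw_length <- NA_real_
      fr$frag_length <- L
    }
    fr$start <- floor(stats::runif(n) * (ulen[fr$unit] - fr$frag_length + 1L))
    truth$fragments <- fr
  }
  truth$skipped_fragments <- skipped
  truth$mode <- mode
  truth$read_length <- L

  files <- character(0)
  if (!is.null(fastq_prefix) && !is.null(fr) && nrow(fr) > 0L) {
    seq1 <- substr(sequences[fr$unit], fr$start + 1L, fr$start + L)
    if (mode == "paired") {
      e <- fr$start + fr$frag_length
      seq2 <- revcomp(substr(sequences[fr$unit], e - L + 1L, e))
      q <- strrep("I", L)
      f1 <- paste0(fastq_prefix, "_1.fastq")
      f2 <- paste0(fastq_prefix, "_2.fastq")
      writeLines(as.vector(rbind(paste0("@", fr$fragment_id, "/1"),
                                 seq1, "+", q)), f1)
      writeLines(as.vector(rbind(paste0("@", fr$fragment_id, "/2"),
                                 seq2, "+", q)), f2)
      files <- c(files, f1, f2)
    } else {
      f1 <- paste0(fastq_prefix, ".fastq")
      writeLines(as.vector(rbind(paste0("@", fr$fragment_id),
                                 seq1, "+", strrep("I", L))), f1)
      files <- c(files, f1)
    }
  }
  if (!is.null(sam_path) && !is.null(fr) && nrow(fr) > 0L) {
    files <- c(files, write_sim_sam(gene_model, truth, sam_path))
  }
  truth$files <- files
  truth
}

# transcript-coordinate position of a fragment inside its unit
transcript_pos <- function(gm, host, unit, start) {
  lay <- isoform_layout(gm, host)
  i <- match(unit, lay$body$unit)
  if (!is.na(i)) return(lay$body$tstart[i] + start)
  j <- match(unit, lay$junctions$unit)
  lay$junctions$wstart[j] + start
}

#' Write the simulator's alignments as per-lane SAM files
#'
#' Reference sequences are the annotated isoforms (transcript coordinates);
#' each simulated fragment appears at its true position on its host isoform.
#' Paired mates carry proper-pair FLAGs (99/147).
#'
#' @param gene_model a `gene_model`.
#' @param truth a `sim_truth` from [simulate_reads()].
#' @param sam_path output path; `%s` is replaced by the lane label, otherwise
#'   `.<lane>` is appended before the extension.
#' @return character vector of files written.
#' @export
write_sim_sam <- function(gene_model, truth, sam_path) {
  gm <- gene_model
  L <- truth$read_length
  ann <- gm$isoforms$id[!gm$isoforms$is_noise]
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           vapply(ann, function(k)
             sprintf("@SQ\tSN:%s\tLN:%d", k,
                     as.integer(isoform_layout(gm, k)$tlen)), character(1)))
  fr <- truth$fragments
  out <- character(0)
  for (lane in rownames(truth$raw)) {
    sel <- fr[fr$lane == lane, , drop = FALSE]
    path <- if (grepl("%s", sam_path, fixed = TRUE)) sprintf(sam_path, lane)
            else sub("(\\.[^.]+)?$", paste0(".", lane, "\\1"), sam_path)
    lines <- hdr
    if (nrow(sel) > 0L) {
      tp <- mapply(function(h, u, s) transcript_pos(gm, h, u, s),
                   sel$host, sel$unit, sel$start)
      if (truth$mode == "paired") {
        p1 <- as.integer(tp) + 1L
        p2 <- as.integer(tp + sel$frag_length - L) + 1L
        lines <- c(lines,
          sprintf("%s\t99\t%s\t%d\t60\t%dM\t=\t%d\t%d\t*\t*",
                  sel$fragment_id, sel$host, p1, L, p2, sel$frag_length),
          sprintf("%s\t147\t%s\t%d\t60\t%dM\t=\t%d\t%d\t*\t*",
                  sel$fragment_id, sel$host, p2, L, p1, -sel$frag_length))
      } else {
        lines <- c(lines,
          sprintf("%s\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t*\t*",
                  sel$fragment_id, sel$host, as.integer(tp) + 1L, L))
      }
    }
    writeLines(lines, path)
    out <- c(out, path)
  }
  out
}

#' Generate a random synthetic gene structure
#'
#' Draws a plausible multi-isoform gene for simulation studies: `n_exons`
#' body exons of 100-300 bases separated by 50-200 base gaps, and
#' `n_isoforms` annotated isoforms, each a random subset of at least two
#' exons. Isoform exon subsets are guaranteed pairwise distinct (two real
#' transcripts of a gene never share an identical exon composition), which
#' also keeps their expanded unit supports distinguishable.
#'
#' @param seed integer seed.
#' @param n_isoforms number of annotated isoforms (default drawn from 2:4).
#' @param n_exons number of body exons (default drawn from 4:8).
#' @return a `raw_gene` structure.
#' @export
random_gene <- function(seed, n_isoforms = NULL, n_exons = NULL) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  if (is.null(n_exons)) n_exons <- sample(4:8, 1)
  if (is.null(n_isoforms)) n_isoforms <- sample(2:4, 1)
  len <- sample(100:300, n_exons, replace = TRUE)
  start <- cumsum(c(100, len[-n_exons] + sample(50:200, n_exons - 1,
                                                replace = TRUE)))
  subsets <- list()
  txs <- list()
  for (k in seq_len(n_isoforms)) {
    for (try in 1:100) {
      keep <- sort(sample(n_exons, max(2, stats::rbinom(1, n_exons, 0.7))))
      key <- paste(keep, collapse = ",")
      if (!key %in% names(subsets)) break
    }
    subsets[[key]] <- TRUE
    txs[[paste0("I", k)]] <- data.frame(start = start[keep],
                                        end = start[keep] + len[keep])
  }
  gene_from_exons(paste0("gene", seed), "chr1", txs)
}

#' Write a simulation truth table to TSV
#'
#' @param truth a `sim_truth`.
#' @param prefix output path prefix (writes `<prefix>.fragments.tsv`,
#'   `<prefix>.theta.tsv`, `<prefix>.counts.tsv`).
#' @export
write_sim_truth <- function(truth, prefix) {
  utils::write.table(truth$fragments, paste0(prefix, ".fragments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  th <- data.frame(lane = rownames(truth$theta), truth$theta,
                   check.names = FALSE)
  utils::write.table(th, paste0(prefix, ".theta.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ct <- data.frame(lane = rownames(truth$raw), truth$raw, check.names = FALSE)
  utils::write.table(ct, paste0(prefix, ".counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(prefix)
}
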