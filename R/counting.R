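## Fragment counting ---------------------------------------------------------
##
## Per-lane transcriptome alignments (reference sequences = annotated
## isoforms) are projected onto a gene's exon units and tallied into the
## L_lanes x E count matrix the model consumes. A fragment spanning an
## exon-exon boundary entirely within a junction window increments the
## junction unit only (a junction-spanning read is evidence for the splice,
## not for either flanking exon); any other fragment increments every body
## unit its span covers, each at most once per fragment. Counts are then
## normalized per base of unit length to remove exon-length bias.

#' Assign one fragment span to exon units of an isoform
#'
#' `span` is `[s, e)` in the transcript coordinates of `isoform_id`. The
#' assignment rule is: (i) a span lying inside a single body unit maps to
#' that unit; (ii) a span lying entirely inside one junction window (the
#' `2(L-1)`-wide interval centred on an adjacency boundary) maps to the
#' junction unit only; (iii) otherwise the span maps to every body unit it
#' overlaps.
#'
#' @param gm a `gene_model`.
#' @param isoform_id annotated isoform the alignment refers to.
#' @param s,e 0-based half-open span in transcript coordinates.
#' @return character vector of unit ids (possibly empty).
#' @export
assign_span <- function(gm, isoform_id, s, e) {
  lay <- isoform_layout(gm, isoform_id)
  if (e <= s || e > lay$tlen || s < 0) {
    ov <- lay$body$unit[lay$body$tstart < e & lay$body$tend > s]
    return(as.character(ov))  # clipped/degenerate: whatever body it touches
  }
  b <- lay$body
  inside <- which(b$tstart <= s & b$tend >= e)
  if (length(inside) == 1L) return(b$unit[inside])
  j <- lay$junctions
  if (nrow(j) > 0L) {
    injx <- which(j$wstart <= s & j$wend >= e)
    if (length(injx) >= 1L) return(j$unit[injx[1L]])
  }
  b$unit[b$tstart < e & b$tend > s]
}

#' Assign a fragment (one read or a mate pair) to exon units
#'
#' Single-end: the read's own span is assigned with [assign_span()].
#' Paired-end: the fragment span runs from the leftmost to the rightmost
#' aligned base of the two mates in transcript coordinates; the span is
#' assigned as a whole, so interior units covered only by the unsequenced
#' insert are still counted, and a fragment confined to one junction window
#' counts to the junction unit only.
#'
#' @param gm a `gene_model`.
#' @param isoform_id annotated isoform id.
#' @param starts,ends integer vectors (length 1 or 2) of the mates' 0-based
#'   half-open spans in transcript coordinates.
#' @return character vector of unit ids the fragment counts toward.
#' @export
assign_fragment <- function(gm, isoform_id, starts, ends) {
  assign_span(gm, isoform_id, min(starts), max(ends))
}

cigar_ref_width <- function(cigar) {
  ops <- gregexpr("\\d+[MIDNSHP=X]", cigar)
  vapply(seq_along(cigar), function(i) {
    m <- regmatches(cigar[i], ops[i])[[1]]
    if (length(m) == 0L) return(0L)
    n <- as.integer(sub("[MIDNSHP=X]$", "", m))
    op <- sub("^\\d+", "", m)
    sum(n[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1))
}

read_lane_alignments <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                             indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE))
  res <- Rsamtools::scanBam(path, param = p)[[1]]
  data.frame(qname = res$qname, flag = res$flag,
             rname = as.character(res$rname),
             start = res$pos - 1L,
             end = res$pos - 1L + cigar_ref_width(res$cigar),
             stringsAsFactors = FALSE)
}

#' Count fragments per exon unit and lane
#'
#' Reads one SAM/BAM file per lane (alignments against the annotated
#' transcriptome; reference names are isoform ids), groups primary records by
#' fragment name, projects each fragment onto the owning gene's exon units
#' and tallies raw counts. A fragment aligned to several isoforms of the
#' same gene is deduplicated to the union of its per-isoform assignments;
#' fragments hitting more than one gene are dropped (and reported).
#' A paired record whose mate is missing is treated as single-end.
#'
#' @param lane_files named character vector of SAM/BAM paths; names are lane
#'   labels (unnamed files are labelled `lane1..`).
#' @param models named list of `gene_model` objects.
#' @return list with `raw` (named list of lanes x units integer matrices, one
#'   per gene), `stats` (data.frame per lane: fragments_mapped,
#'   fragments_assigned, fragments_cross_gene, fragments_unassigned) and
#'   `N_s` (total mapped fragments across lanes, used as the per-sample
#'   denominator of FPKM).
#' @export
count_fragments <- function(lane_files, models) {
  if (is.null(names(lane_files)) || any(names(lane_files) == ""))
    names(lane_files) <- paste0("lane", seq_along(lane_files))
  iso2gene <- do.call(c, unname(lapply(models, function(gm) {
    ids <- gm$isoforms$id[!gm$isoforms$is_noise]
    stats::setNames(rep(gm$gene_id, length(ids)), ids)
  })))
  lanes <- names(lane_files)
  raw <- lapply(models, function(gm)
    matrix(0L, nrow = length(lanes), ncol = nrow(gm$units),
           dimnames = list(lanes, gm$units$id)))
  stats <- data.frame(lane = lanes, fragments_mapped = 0L,
                      fragments_assigned = 0L, fragments_cross_gene = 0L,
                      fragments_unassigned = 0L)
  for (li in seq_along(lane_files)) {
    al <- read_lane_alignments(lane_files[[li]])
    al <- al[al$rname %in% names(iso2gene), , drop = FALSE]
    if (nrow(al) == 0L) next
    al <- al[order(al$qname, al$rname, al$start), , drop = FALSE]
    grp <- split(seq_len(nrow(al)), al$qname)
    stats$fragments_mapped[li] <- length(grp)
    for (idx in grp) {
      gids <- unique(iso2gene[al$rname[idx]])
      if (length(gids) > 1L) {
        stats$fragments_cross_gene[li] <- stats$fragments_cross_gene[li] + 1L
        next
      }
      gm <- models[[gids]]
      units <- character(0)
      for (iso in unique(al$rname[idx])) {
        sub <- idx[al$rname[idx] == iso]
        units <- c(units, assign_fragment(gm, iso, al$start[sub], al$end[sub]))
      }
      units <- unique(units)
      if (length(units) == 0L) {
        stats$fragments_unassigned[li] <- stats$fragments_unassigned[li] + 1L
        next
      }
      raw[[gids]][li, units] <- raw[[gids]][li, units] + 1L
      stats$fragments_assigned[li] <- stats$fragments_assigned[li] + 1L
    }
  }
  list(raw = raw, stats = stats, N_s = sum(stats$fragments_mapped))
}

#' Length-normalize a raw count matrix
#'
#' Divides each unit's tally by the unit length in bases, removing the
#' exon-length bias in fragment counts; `n[l, i] = raw[l, i] / length_i`.
#' Per-lane totals `N_l = sum_i n[l, i]` are recorded, together with the
#' sample-wide mapped-fragment total `N_s` used by the FPKM formula.
#'
#' @param raw lanes x units integer matrix.
#' @param unit_lengths positive unit lengths in bases (model order).
#' @param gene_id gene identifier.
#' @param N_s total mapped fragments for the sample.
#' @return an `exon_counts` object (gene_id, raw, normalized, N_per_lane,
#'   unit_lengths, N_s).
#' @export
normalize_counts <- function(raw, unit_lengths, gene_id = "gene", N_s = NA) {
  if (any(!is.finite(unit_lengths)) || any(unit_lengths <= 0))
    stop("invalid gene model: non-positive unit length")
  if (ncol(raw) != length(unit_lengths))
    stop("raw matrix and unit_lengths disagree")
  normalized <- sweep(raw, 2L, unit_lengths, "/")
  structure(list(gene_id = gene_id, raw = raw, normalized = normalized,
                 N_per_lane = rowSums(normalized),
                 unit_lengths = unit_lengths, N_s = N_s),
            class = "exon_counts")
}

#' @export
print.exon_counts <- function(x, ...) {
  cat("exon_counts", x$gene_id, ":", nrow(x$raw), "lane(s) x", ncol(x$raw),
      "units;", sum(x$raw), "unit tallies; N_s =", x$N_s, "\n")
  invisible(x)
}

#' Write per-gene counts as a tidy TSV
#'
#' Columns: gene_id, lane, unit_id, raw, normalized. Round-trips through
#' [read_counts_tsv()] given the matching gene models.
#'
#' @param counts named list of `exon_counts`.
#' @param path output TSV path.
#' @export
write_counts_tsv <- function(counts, path) {
  rows <- do.call(rbind, lapply(counts, function(x) {
    data.frame(gene_id = x$gene_id,
               lane = rep(rownames(x$raw), ncol(x$raw)),
               unit_id = rep(colnames(x$raw), each = nrow(x$raw)),
               raw = as.vector(x$raw),
               normalized = as.vector(x$normalized))
  }))
  rows$N_s <- counts[[1]]$N_s
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-gene count TSV written by [write_counts_tsv()]
#'
#' @param path TSV path.
#' @param models named list of `gene_model` objects supplying unit lengths.
#' @return named list of `exon_counts`.
#' @export
read_counts_tsv <- function(path, models) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  out <- list()
  for (g in unique(df$gene_id)) {
    sub <- df[df$gene_id == g, , drop = FALSE]
    gm <- models[[g]]
    lanes <- unique(sub$lane)
    raw <- matrix(0L, length(lanes), nrow(gm$units),
                  dimnames = list(lanes, gm$units$id))
    raw[cbind(match(sub$lane, lanes), match(sub$unit_id, gm$units$id))] <-
      sub$raw
    out[[g]] <- normalize_counts(raw, gm$units$length, g, N_s = sub$N_s[1])
  }
  out
}
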