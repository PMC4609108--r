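## Gene-model expansion ------------------------------------------------------
##
## A gene's annotated transcripts are turned into the working structure the
## model consumes: a set of disjoint "exon units" (overlapping annotated exons
## are split at every boundary), artificial junction units of length 2(L-1)
## spanning each exon-exon adjacency observed in an annotated isoform, and an
## appended "noise" isoform containing every unit, which absorbs reads from
## noise and from undiscovered isoforms.
##
## Internal coordinates are 0-based half-open; GTF I/O converts from/to
## 1-based inclusive. Strand is recorded but never used for exon arithmetic.

#' Build a raw gene structure from exon coordinates
#'
#' Constructor used by tests, the simulator and the GTF reader alike. Exon
#' coordinates are 0-based half-open.
#'
#' @param gene_id gene identifier.
#' @param chrom chromosome name.
#' @param transcripts named list; each element is a two-column matrix or
#'   data.frame of exon `start`/`end` (0-based half-open) for one transcript.
#' @param strand `"+"`, `"-"` or `"*"`; recorded only.
#' @return a `raw_gene` list (gene_id, chrom, strand, transcripts).
#' @export
gene_from_exons <- function(gene_id, chrom, transcripts, strand = "*") {
  stopifnot(is.list(transcripts), length(transcripts) >= 1L,
            !is.null(names(transcripts)))
  transcripts <- lapply(transcripts, function(tx) {
    tx <- as.data.frame(tx)
    names(tx)[1:2] <- c("start", "end")
    if (nrow(tx) == 0L) stop("transcript with no exons")
    if (any(tx$end <= tx$start)) stop("exon with non-positive length")
    tx[order(tx$start), , drop = FALSE]
  })
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 transcripts = transcripts),
            class = "raw_gene")
}

#' Parse a GTF/GFF annotation into raw gene structures
#'
#' Exon features are grouped by `gene_id` then `transcript_id`. Genes whose
#' transcripts span several chromosomes or strands are rejected with a
#' warning. Coordinates are converted to the internal 0-based half-open
#' convention.
#'
#' @param path GTF (or GFF) file path.
#' @return named list of `raw_gene` structures (possibly empty).
#' @export
parse_annotation <- function(path) {
  if (file.info(path)$size == 0) return(structure(list(), names = character(0)))
  gr <- tryCatch(rtracklayer::import(path),
                 error = function(e) stop("failed to parse annotation '", path,
                                          "': ", conditionMessage(e)))
  md <- S4Vectors::mcols(gr)
  if (!is.null(md$type)) gr <- gr[tolower(as.character(md$type)) == "exon"]
  md <- S4Vectors::mcols(gr)
  if (length(gr) == 0L) return(structure(list(), names = character(0)))
  gid <- as.character(md$gene_id)
  tid <- as.character(md$transcript_id)
  bad <- is.na(gid) | is.na(tid) | gid == "" | tid == ""
  if (any(bad)) {
    warning(sum(bad), " exon record(s) without gene_id/transcript_id skipped")
    gr <- gr[!bad]; gid <- gid[!bad]; tid <- tid[!bad]
  }
  out <- list()
  for (g in unique(gid)) {
    sel <- gid == g
    chroms <- unique(as.character(GenomicRanges::seqnames(gr[sel])))
    strands <- unique(as.character(GenomicRanges::strand(gr[sel])))
    if (length(chroms) > 1L || length(strands) > 1L) {
      warning("gene ", g, " spans multiple chromosomes/strands; skipped")
      next
    }
    txs <- split(seq_len(sum(sel)), tid[sel])
    sub <- gr[sel]
    tx_list <- lapply(txs, function(idx) {
      data.frame(start = GenomicRanges::start(sub)[idx] - 1L,
                 end = GenomicRanges::end(sub)[idx])
    })
    out[[g]] <- gene_from_exons(g, chroms, tx_list, strands)
  }
  out
}

#' Write raw gene structures back to GTF
#'
#' Inverse of [parse_annotation()]: internal 0-based half-open coordinates are
#' converted back to 1-based inclusive GTF records, one `exon` feature per
#' exon.
#'
#' @param genes list of `raw_gene` structures.
#' @param path output file path.
#' @export
write_annotation <- function(genes, path) {
  rows <- list()
  for (g in genes) {
    for (tx in names(g$transcripts)) {
      ex <- g$transcripts[[tx]]
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = g$chrom, start = ex$start + 1L, end = ex$end,
        strand = g$strand, gene_id = g$gene_id, transcript_id = tx)
    }
  }
  if (length(rows) == 0L) { writeLines(character(0), path); return(invisible(path)) }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    df$chrom, IRanges::IRanges(df$start, df$end),
    strand = ifelse(df$strand %in% c("+", "-"), df$strand, "*"))
  S4Vectors::mcols(gr)$type <- "exon"
  S4Vectors::mcols(gr)$gene_id <- df$gene_id
  S4Vectors::mcols(gr)$transcript_id <- df$transcript_id
  S4Vectors::mcols(gr)$source <- "exonLDM"
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Split overlapping exons into disjoint units
#'
#' All exon spans of one gene are cut at every distinct exon boundary
#' (sweep-line over breakpoints), so that the returned units are pairwise
#' disjoint and cover exactly the union of the input spans. Each transcript's
#' membership is remapped to the units its original exons cover. This avoids
#' counting a fragment twice when annotated exons overlap.
#'
#' @param gene a `raw_gene` structure.
#' @return list with `units` (data.frame: id, start, end, length) ordered by
#'   coordinate and `memberships` (named list of unit-id vectors per
#'   transcript, in transcript order).
#' @export
split_overlapping_exons <- function(gene) {
  spans <- do.call(rbind, unname(gene$transcripts))
  bp <- sort(unique(c(spans$start, spans$end)))
  cand <- data.frame(start = bp[-length(bp)], end = bp[-1])
  covered <- vapply(seq_len(nrow(cand)), function(i) {
    any(spans$start <= cand$start[i] & spans$end >= cand$end[i])
  }, logical(1))
  units <- cand[covered, , drop = FALSE]
  units$id <- paste0("e", seq_len(nrow(units)))
  units$length <- units$end - units$start
  rownames(units) <- NULL
  memberships <- lapply(gene$transcripts, function(tx) {
    keep <- vapply(seq_len(nrow(units)), function(i) {
      any(tx$start <= units$start[i] & tx$end >= units$end[i])
    }, logical(1))
    units$id[keep]
  })
  list(units = units[, c("id", "start", "end", "length")],
       memberships = memberships)
}

#' Enumerate junction units implied by annotated isoforms
#'
#' One junction unit is created per distinct ordered pair of exon units
#' adjacent (consecutive) in at least one annotated isoform, after overlap
#' splitting. A junction unit joins the last `L - 1` bases of the upstream
#' unit with the first `L - 1` bases of the downstream unit, so its length is
#' `2 * (L - 1)`; a read spanning the corresponding exon-exon boundary aligns
#' within this unit. Duplicated adjacencies across isoforms collapse to one
#' unit.
#'
#' @param units unit table from [split_overlapping_exons()].
#' @param memberships per-transcript unit-id lists (transcript order).
#' @param read_length read length `L` in bases (`>= 2`).
#' @return data.frame of junction units: id (`"a-b"`), start, end, length,
#'   part1, part2.
#' @export
build_junction_exons <- function(units, memberships, read_length) {
  if (!is.numeric(read_length) || read_length < 2)
    stop("read_length must be >= 2")
  L <- as.integer(read_length)
  pairs <- unique(do.call(rbind, lapply(memberships, function(ids) {
    if (length(ids) < 2L) return(NULL)
    cbind(ids[-length(ids)], ids[-1])
  })))
  if (is.null(pairs) || nrow(pairs) == 0L)
    return(data.frame(id = character(0), start = integer(0), end = integer(0),
                      length = integer(0), part1 = character(0),
                      part2 = character(0)))
  idx <- stats::setNames(seq_len(nrow(units)), units$id)
  data.frame(
    id = paste0(pairs[, 1], "-", pairs[, 2]),
    start = units$end[idx[pairs[, 1]]] - (L - 1L),
    end = units$start[idx[pairs[, 2]]] + (L - 1L),
    length = 2L * (L - 1L),
    part1 = pairs[, 1], part2 = pairs[, 2],
    row.names = NULL)
}

#' Expand a raw gene into the model's working structure
#'
#' Runs overlap splitting, junction construction and noise-isoform appending,
#' and assembles the K x E isoform-exon compatibility mask. The appended
#' noise isoform contains every unit of the gene (all-ones compatibility
#' row); annotated isoform ordering is preserved, so K = annotated + 1.
#'
#' @param gene a `raw_gene` structure.
#' @param read_length read length `L` used for junction units.
#' @return a `gene_model` object: gene_id, chrom, strand, read_length,
#'   `units` (body units first, then junction units; columns id, start, end,
#'   length, is_junction, part1, part2), `isoforms` (data.frame id, is_noise,
#'   length), `iso_units` (named list of unit ids per isoform) and `compat`
#'   (K x E 0/1 matrix, dimnames isoform x unit).
#' @export
expand_gene_model <- function(gene, read_length) {
  sp <- split_overlapping_exons(gene)
  jx <- build_junction_exons(sp$units, sp$memberships, read_length)
  body <- sp$units
  body$is_junction <- FALSE
  body$part1 <- NA_character_
  body$part2 <- NA_character_
  if (nrow(jx) > 0L) {
    jx$is_junction <- TRUE
    units <- rbind(body, jx[, names(body)])
  } else units <- body
  rownames(units) <- NULL

  iso_units <- lapply(sp$memberships, function(ids) {
    if (length(ids) >= 2L && nrow(jx) > 0L) {
      adj <- paste0(ids[-length(ids)], "-", ids[-1])
      c(ids, adj[adj %in% jx$id])
    } else ids
  })
  iso_len <- vapply(sp$memberships, function(ids) {
    sum(body$length[match(ids, body$id)])
  }, numeric(1))
  noise_id <- make.unique(c(names(iso_units), "noise"))[length(iso_units) + 1L]
  iso_units[[noise_id]] <- units$id
  isoforms <- data.frame(
    id = names(iso_units),
    is_noise = c(rep(FALSE, length(sp$memberships)), TRUE),
    length = c(iso_len, sum(body$length)),
    row.names = NULL)

  compat <- matrix(0L, nrow = nrow(isoforms), ncol = nrow(units),
                   dimnames = list(isoforms$id, units$id))
  for (k in seq_along(iso_units)) compat[k, iso_units[[k]]] <- 1L

  structure(list(gene_id = gene$gene_id, chrom = gene$chrom,
                 strand = gene$strand, read_length = as.integer(read_length),
                 units = units, isoforms = isoforms, iso_units = iso_units,
                 compat = compat),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat("gene_model", x$gene_id, ":", nrow(x$units), "units (",
      sum(x$units$is_junction), "junction ),", nrow(x$isoforms),
      "isoforms (incl. noise), L =", x$read_length, "\n")
  invisible(x)
}

#' Expand every gene of an annotation
#'
#' @param genes list of `raw_gene` structures (from [parse_annotation()]).
#' @param read_length read length `L`.
#' @return named list of `gene_model` objects.
#' @export
expand_annotation <- function(genes, read_length) {
  lapply(genes, expand_gene_model, read_length = read_length)
}

## Transcript-coordinate maps used by counting and the read simulator --------

#' Transcript coordinate layout of an annotated isoform
#'
#' The transcript coordinate system of an isoform is the concatenation of its
#' body exon units in genomic order. Junction units do not occupy their own
#' transcript interval; instead each adjacency (a, b) of the isoform defines
#' a window of width `2 * (L - 1)` centred on the boundary, and any read (or
#' fragment span) falling entirely inside that window is evidence for the
#' junction unit.
#'
#' @param gm a `gene_model`.
#' @param isoform_id an annotated isoform id.
#' @return list with `body` (data.frame unit, tstart, tend), `junctions`
#'   (data.frame unit, wstart, wend) and `tlen` (transcript length in bases).
#' @keywords internal
isoform_layout <- function(gm, isoform_id) {
  ids <- gm$iso_units[[isoform_id]]
  body_ids <- ids[!gm$units$is_junction[match(ids, gm$units$id)]]
  len <- gm$units$length[match(body_ids, gm$units$id)]
  tend <- cumsum(len)
  tstart <- tend - len
  body <- data.frame(unit = body_ids, tstart = tstart, tend = tend)
  L <- gm$read_length
  jx <- NULL
  if (length(body_ids) >= 2L) {
    a <- body_ids[-length(body_ids)]
    b <- body_ids[-1]
    jid <- paste0(a, "-", b)
    keep <- jid %in% gm$units$id
    if (any(keep)) {
      bnd <- tend[-length(tend)][keep]
      jx <- data.frame(unit = jid[keep], wstart = bnd - (L - 1L),
                       wend = bnd + (L - 1L))
    }
  }
  if (is.null(jx))
    jx <- data.frame(unit = character(0), wstart = integer(0),
                     wend = integer(0))
  list(body = body, junctions = jx, tlen = sum(len))
}

## TSV round-trip of the expanded model --------------------------------------

#' Write expanded gene models to a TSV pair
#'
#' Emits a unit table (`<prefix>.units.tsv`: gene_id, unit_id, chrom, start,
#' end, length, is_junction, part1, part2) and a membership table
#' (`<prefix>.isoforms.tsv`: gene_id, isoform_id, is_noise, length, unit_id in
#' model order). The pair round-trips through [read_gene_models()].
#'
#' @param models named list of `gene_model` objects.
#' @param prefix output path prefix.
#' @return invisibly, the two file paths.
#' @export
write_gene_models <- function(models, prefix) {
  up <- paste0(prefix, ".units.tsv")
  ip <- paste0(prefix, ".isoforms.tsv")
  ut <- do.call(rbind, lapply(models, function(gm) {
    data.frame(gene_id = gm$gene_id, unit_id = gm$units$id, chrom = gm$chrom,
               strand = gm$strand, read_length = gm$read_length,
               start = gm$units$start, end = gm$units$end,
               length = gm$units$length, is_junction = gm$units$is_junction,
               part1 = gm$units$part1, part2 = gm$units$part2)
  }))
  it <- do.call(rbind, lapply(models, function(gm) {
    do.call(rbind, lapply(seq_len(nrow(gm$isoforms)), function(k) {
      data.frame(gene_id = gm$gene_id, isoform_id = gm$isoforms$id[k],
                 is_noise = gm$isoforms$is_noise[k],
                 iso_length = gm$isoforms$length[k],
                 unit_id = gm$iso_units[[k]])
    }))
  }))
  utils::write.table(ut, up, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(it, ip, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(units = up, isoforms = ip))
}

#' Read expanded gene models back from the TSV pair
#'
#' @param prefix path prefix used in [write_gene_models()].
#' @return named list of `gene_model` objects.
#' @export
read_gene_models <- function(prefix) {
  ut <- utils::read.table(paste0(prefix, ".units.tsv"), sep = "\t",
                          header = TRUE, stringsAsFactors = FALSE,
                          na.strings = "NA")
  it <- utils::read.table(paste0(prefix, ".isoforms.tsv"), sep = "\t",
                          header = TRUE, stringsAsFactors = FALSE)
  models <- list()
  for (g in unique(ut$gene_id)) {
    u <- ut[ut$gene_id == g, , drop = FALSE]
    i <- it[it$gene_id == g, , drop = FALSE]
    units <- data.frame(id = u$unit_id, start = u$start, end = u$end,
                        length = u$length, is_junction = u$is_junction,
                        part1 = as.character(u$part1),
                        part2 = as.character(u$part2))
    iso_ids <- unique(i$isoform_id)
    iso_units <- lapply(iso_ids, function(id) i$unit_id[i$isoform_id == id])
    names(iso_units) <- iso_ids
    isoforms <- data.frame(
      id = iso_ids,
      is_noise = vapply(iso_ids, function(id)
        i$is_noise[i$isoform_id == id][1], logical(1)),
      length = vapply(iso_ids, function(id)
        i$iso_length[i$isoform_id == id][1], numeric(1)),
      row.names = NULL)
    compat <- matrix(0L, length(iso_ids), nrow(units),
                     dimnames = list(iso_ids, units$id))
    for (k in seq_along(iso_units)) compat[k, iso_units[[k]]] <- 1L
    models[[g]] <- structure(
      list(gene_id = g, chrom = u$chrom[1], strand = u$strand[1],
           read_length = u$read_length[1], units = units, isoforms = isoforms,
           iso_units = iso_units, compat = compat),
      class = "gene_model")
  }
  models
}
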