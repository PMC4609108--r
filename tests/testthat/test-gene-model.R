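test_that("GTF parsing groups exons by gene and transcript and round-trips", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\ttest\texon\t101\t300\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'chr1\ttest\texon\t701\t900\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'chr1\ttest\texon\t101\t300\t.\t+\t.\tgene_id "g1"; transcript_id "t2";',
    'chr1\ttest\texon\t401\t600\t.\t+\t.\tgene_id "g1"; transcript_id "t2";',
    'chr1\ttest\texon\t951\t1100\t.\t+\t.\tgene_id "g1"; transcript_id "t2";'),
    gtf)
  genes <- parse_annotation(gtf)
  expect_length(genes, 1L)
  expect_named(genes, "g1")
  expect_length(genes$g1$transcripts, 2L)
  expect_equal(nrow(genes$g1$transcripts$t1), 2L)
  expect_equal(nrow(genes$g1$transcripts$t2), 3L)
  # 1-based inclusive GTF -> 0-based half-open internal
  expect_equal(genes$g1$transcripts$t1$start, c(100, 700))
  expect_equal(genes$g1$transcripts$t1$end, c(300, 900))

  # empty file -> empty collection
  empty <- tempfile(fileext = ".gtf")
  file.create(empty)
  expect_length(parse_annotation(empty), 0L)

  # writer round-trip of the toy gene
  out <- tempfile(fileext = ".gtf")
  write_annotation(list(toy_gene()), out)
  back <- parse_annotation(out)
  expect_named(back, "toy")
  expect_equal(lapply(back$toy$transcripts, function(x) x[c("start", "end")]),
               lapply(toy_gene()$transcripts, function(x) x[c("start", "end")]))
})

test_that("genes spanning multiple chromosomes or strands are rejected", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\ttest\texon\t101\t200\t.\t+\t.\tgene_id "gX"; transcript_id "t1";',
    'chr2\ttest\texon\t101\t200\t.\t+\t.\tgene_id "gX"; transcript_id "t2";',
    'chr1\ttest\texon\t101\t200\t.\t+\t.\tgene_id "gY"; transcript_id "t3";'),
    gtf)
  expect_warning(genes <- parse_annotation(gtf), "multiple chromosomes")
  expect_named(genes, "gY")
})

test_that("overlapping exons split into disjoint units preserving the union", {
  g <- gene_from_exons("g", "chr1", list(
    A = data.frame(start = 100, end = 200),
    B = data.frame(start = 150, end = 250)))
  sp <- split_overlapping_exons(g)
  expect_equal(sp$units$start, c(100, 150, 200))
  expect_equal(sp$units$end, c(150, 200, 250))
  expect_equal(sp$memberships$A, c("e1", "e2"))
  expect_equal(sp$memberships$B, c("e2", "e3"))

  # already-disjoint exons come back unchanged (up to relabeling)
  g2 <- gene_from_exons("g", "chr1", list(
    A = data.frame(start = c(100, 300), end = c(200, 400))))
  sp2 <- split_overlapping_exons(g2)
  expect_equal(sp2$units$start, c(100, 300))
  expect_equal(sp2$units$end, c(200, 400))
})

test_that("random overlap patterns match the base-by-base partition oracle", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(2:10, 1)
    start <- sample(0:400, n, replace = TRUE)
    spans <- data.frame(start = start, end = start + sample(10:150, n, TRUE))
    tx <- lapply(seq_len(n), function(i) spans[i, , drop = FALSE])
    names(tx) <- paste0("t", seq_len(n))
    sp <- split_overlapping_exons(gene_from_exons("g", "chr1", tx))
    oracle <- bruteforce_partition(spans)
    # oracle merges touching runs with identical cover; the sweep keeps every
    # breakpoint, so compare covered base sets and disjointness instead
    covered <- unlist(mapply(seq, sp$units$start, sp$units$end - 1,
                             SIMPLIFY = FALSE))
    covered_oracle <- unlist(mapply(seq, oracle$start, oracle$end - 1,
                                    SIMPLIFY = FALSE))
    expect_equal(sort(covered), sort(covered_oracle))
    expect_equal(anyDuplicated(covered), 0L)
    # each unit lies within or outside every exon, never across its boundary
    for (i in seq_len(nrow(sp$units)))
      expect_true(all(spans$start <= sp$units$start[i] |
                      spans$start >= sp$units$end[i]))
  }
})

test_that("junction units follow annotated adjacencies with length 2(L-1)", {
  gm <- toy_model(L = 50)
  jx <- gm$units[gm$units$is_junction, ]
  expect_setequal(jx$id, c("e1-e3", "e1-e2", "e2-e4"))
  expect_true(all(jx$length == 2 * (50 - 1)))

  # single-exon isoform contributes no junctions
  g1 <- gene_from_exons("g", "chr1",
                        list(A = data.frame(start = 100, end = 300)))
  sp <- split_overlapping_exons(g1)
  expect_equal(nrow(build_junction_exons(sp$units, sp$memberships, 50)), 0L)

  # a chain isoform yields #exons - 1 junctions
  g2 <- gene_from_exons("g", "chr1", list(
    A = data.frame(start = c(0, 200, 400), end = c(100, 300, 500))))
  sp2 <- split_overlapping_exons(g2)
  jx2 <- build_junction_exons(sp2$units, sp2$memberships, 50)
  expect_equal(jx2$id, c("e1-e2", "e2-e3"))

  expect_error(build_junction_exons(sp2$units, sp2$memberships, 1),
               "read_length")
})

test_that("junction set is invariant under isoform order permutation", {
  g <- toy_gene()
  perm <- gene_from_exons("toy", "chr1", rev(g$transcripts))
  j1 <- expand_gene_model(g, 50)
  j2 <- expand_gene_model(perm, 50)
  expect_setequal(j1$units$id[j1$units$is_junction],
                  j2$units$id[j2$units$is_junction])
})

test_that("noise isoform covers all units and compat mask is well-formed", {
  gm <- toy_model()
  expect_equal(nrow(gm$isoforms), 3L)        # 2 annotated + noise
  expect_equal(ncol(gm$compat), 7L)          # 4 body + 3 junction units
  noise <- gm$isoforms$id[gm$isoforms$is_noise]
  expect_equal(unname(gm$compat[noise, ]), rep(1L, 7))
  expect_true(all(rowSums(gm$compat) >= 1))
  expect_true(all(colSums(gm$compat) >= 1))
  # annotated row sums: body exons + own adjacencies
  expect_equal(sum(gm$compat["I1", ]), 2 + 1)   # e1, e3 + e1-e3
  expect_equal(sum(gm$compat["I2", ]), 3 + 2)   # e1, e2, e4 + e1-e2, e2-e4
  # single annotated isoform still gains a noise companion
  g1 <- gene_from_exons("g", "chr1",
                        list(A = data.frame(start = 100, end = 300)))
  expect_equal(nrow(expand_gene_model(g1, 50)$isoforms), 2L)
})

test_that("expanded models round-trip through the TSV pair", {
  models <- list(toy = toy_model())
  prefix <- tempfile()
  write_gene_models(models, prefix)
  back <- read_gene_models(prefix)
  expect_equal(back$toy$units, models$toy$units)
  expect_equal(back$toy$compat, models$toy$compat)
  expect_equal(back$toy$isoforms$is_noise, models$toy$isoforms$is_noise)
})
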