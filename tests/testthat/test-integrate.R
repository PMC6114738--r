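ann_fixture <- function() {
  gm <- gene_models(
    data.frame(gene_id = "gA", chrom = "chr1", start = 1000L, end = 2000L,
               strand = "+"),
    data.frame(gene_id = "gA", chrom = "chr1", start = 1000L, end = 1200L))
  cgis <- data.table::data.table(chrom = "chr1", start = 8000L,
                                 end = 8500L, strand = ".", label = "CGI")
  list(gm = gm, cgis = cgis)
}

mk_dmr <- function(start, end, direction = "hyper", chrom = "chr1") {
  data.table::data.table(dmr_id = seq_along(start), chrom = chrom,
                         start = start, end = end,
                         n_sites = 3L, sign_dir = 1L, q_value = 0.01,
                         mean_diff = ifelse(direction == "hyper", .3, -.3),
                         direction = direction)
}

test_that("annotate_dmrs applies feature precedence and intergenic calls", {
  fx <- ann_fixture()
  ## inside the gene span but in the exon gap -> intron
  a1 <- annotate_dmrs(mk_dmr(1500L, 1600L), fx$gm, fx$cgis)
  expect_equal(a1$gene_id, "gA")
  expect_equal(a1$feature, "intron")

  ## far from everything -> intergenic (promoter [ -1000, 1000) )
  a2 <- annotate_dmrs(mk_dmr(5000L, 5100L), fx$gm, fx$cgis)
  expect_true(is.na(a2$gene_id))
  expect_equal(a2$feature, "intergenic")

  ## spanning promoter and exon -> promoter wins
  a3 <- annotate_dmrs(mk_dmr(900L, 1100L), fx$gm, fx$cgis)
  expect_equal(a3$feature, "promoter")

  ## CGI and shore flags are independent of gene hits
  a4 <- annotate_dmrs(mk_dmr(8100L, 8200L), fx$gm, fx$cgis)
  expect_true(a4$in_cgi)
  a5 <- annotate_dmrs(mk_dmr(7000L, 7100L), fx$gm, fx$cgis)
  expect_true(a5$in_shore)
  expect_false(a5$in_cgi)
})

test_that("annotate_dmrs agrees with a brute-force overlap scan", {
  set.seed(61)
  for (rep in 1:10) {
    ng <- sample(3:8, 1)
    starts <- sort(sample(seq(3000L, 50000L, by = 100L), ng)) +
      cumsum(rep(5000L, ng))
    gm <- gene_models(
      data.frame(gene_id = paste0("g", seq_len(ng)), chrom = "chr1",
                 start = starts, end = starts + 2000L,
                 strand = sample(c("+", "-"), ng, replace = TRUE)),
      data.frame(gene_id = paste0("g", seq_len(ng)), chrom = "chr1",
                 start = starts, end = starts + 2000L))
    nd <- sample(3:10, 1)
    ds <- sample.int(80000L, nd)
    dmrs <- mk_dmr(sort(ds), sort(ds) + sample(200:3000, nd, replace = TRUE))
    ann <- annotate_dmrs(dmrs, gm,
                         cgis = data.table::data.table(
                           chrom = character(), start = integer(),
                           end = integer(), strand = character(),
                           label = character()))
    prom <- promoters_of(gm, 2000L)
    for (i in seq_len(nd)) {
      hit_genes <- sort(unique(c(
        gm$genes$gene_id[dmrs$start[i] < gm$genes$end &
                           dmrs$end[i] > gm$genes$start],
        prom$gene_id[dmrs$start[i] < prom$end & dmrs$end[i] > prom$start])))
      got <- ann$gene_id[ann$dmr_id == dmrs$dmr_id[i]]
      if (length(hit_genes) == 0) {
        expect_true(all(is.na(got)))
      } else {
        expect_equal(sort(got), hit_genes)
      }
    }
  }
})

test_that("DMG sets partition by direction with ambivalent genes in both", {
  fx <- ann_fixture()
  ann <- annotate_dmrs(
    mk_dmr(c(1100L, 1500L), c(1150L, 1600L), c("hyper", "hypo")),
    fx$gm, fx$cgis)
  sets <- build_dmg_sets(ann)
  expect_equal(sets$hyper, "gA")
  expect_equal(sets$hypo, "gA")
  expect_equal(sets$ambivalent, "gA")

  ann2 <- annotate_dmrs(mk_dmr(1100L, 1150L, "hyper"), fx$gm, fx$cgis)
  sets2 <- build_dmg_sets(ann2)
  expect_equal(sets2$hyper, "gA")
  expect_equal(sets2$hypo, character(0))

  ## conservation: |hyper| + |hypo| >= genes hit by any DMR
  n_hit <- length(unique(stats::na.omit(ann$gene_id)))
  expect_gte(length(sets$hyper) + length(sets$hypo), n_hit)
})

test_that("filter_degs enforces both thresholds with correct boundaries", {
  expr <- data.table::data.table(
    gene_id = c("a", "b", "c", "d", "e"),
    log_fc = c(1.5, 0.5, -2.0, 1.0, 3.0),
    q_value = c(0.01, 0.001, 0.05, 0.01, NA))
  res <- filter_degs(expr)
  expect_equal(res$up, "a")
  ## boundary: q = 0.05 kept, |log_fc| = 1 dropped, missing q skipped
  expect_equal(res$down, "c")
  expect_equal(res$n_missing_q, 1)

  ## idempotent and order-invariant
  res2 <- filter_degs(res$degs)
  expect_equal(sort(res2$degs$gene_id), sort(res$degs$gene_id))
  res3 <- filter_degs(expr[5:1, ])
  expect_equal(res3$up, res$up)
  expect_equal(res3$down, res$down)
})

test_that("overlap_dmg_deg intersects ids and reports concordance", {
  dmgs <- list(hyper = c("A", "B"), hypo = "C", ambivalent = character(0))
  degs <- list(up = c("B", "D"), down = "C")
  ov <- overlap_dmg_deg(dmgs, degs)
  expect_equal(ov$gene_id, c("B", "C"))
  expect_equal(ov$meth_direction, c("hyper", "hypo"))
  expect_equal(ov$expr_sign, c("up", "down"))
  expect_equal(ov$concordant, c(FALSE, FALSE))
  expect_equal(nrow(overlap_dmg_deg(
    list(hyper = "X", hypo = character(0), ambivalent = character(0)),
    list(up = "Y", down = character(0)))), 0)
})

test_that("gene_meth_profile extracts per-group series over the gene", {
  gm <- gene_models(
    data.frame(gene_id = "g", chrom = "chr1", start = 1000L, end = 2000L,
               strand = "+"),
    data.frame(gene_id = "g", chrom = "chr1", start = 1000L, end = 2000L))
  pos <- seq(0L, 4000L, by = 100L)
  mat <- mk_mat("chr1", pos, meth = 6L, total = 10L)
  pr <- gene_meth_profile("g", gm, mat, flank = 500L)
  expect_true(all(pr$anagen == 0.6))
  expect_true(all(pr$telogen == 0.6))
  expect_true(all(pr$pos >= 500L & pr$pos < 2500L))
  ## flank 0 restricts to the gene span
  pr0 <- gene_meth_profile("g", gm, mat, flank = 0L)
  expect_true(all(pr0$pos >= 1000L & pr0$pos < 2000L))
  expect_error(gene_meth_profile("nope", gm, mat), "unknown gene")
})
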