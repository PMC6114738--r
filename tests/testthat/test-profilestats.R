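test_that("cpg_oe follows the Gardiner-Garden form", {
  expect_equal(cpg_oe("ATAT"), 0)
  expect_equal(cpg_oe("CGCG"), 2.0)   # (2 * 4) / (2 * 2)
  expect_equal(cpg_oe("ACGT"), 4.0)   # (1 * 4) / (1 * 1)
  expect_equal(cpg_oe("CCCC"), 0)     # no G
  ## reverse complement preserves CpG count, hence the ratio
  set.seed(13)
  for (i in 1:10) {
    s <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
               collapse = "")
    rc <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(s)))
    expect_equal(cpg_oe(rc), cpg_oe(s))
  }
})

test_that("window_density reproduces pooled levels and conserves counts", {
  ## constant level 0.5 everywhere -> every covered window 0.5
  mat <- mk_mat("chr1", seq(0, 9999, by = 50), meth = 5L, total = 10L)
  wd <- window_density(mat, window = 1000L)
  expect_true(all(wd$level == 0.5))

  ## empty chromosome -> all windows missing
  wd2 <- window_density(mat, window = 1000L,
                        chrom_lengths = c(chr1 = 10000L, chr2 = 3000L))
  expect_true(all(is.na(wd2$level[wd2$chrom == "chr2"])))
  expect_equal(sum(wd2$chrom == "chr2"), 3 * 2)  # 3 windows x 2 groups

  ## random methylome: each window equals the brute-force pooled mean and
  ## total counts are conserved
  set.seed(17)
  n <- 400
  pos <- sort(sample.int(20000L, n))
  total <- matrix(rpois(n * 4, 12), n)
  meth <- matrix(rbinom(n * 4, as.vector(total), 0.4), n)
  mat3 <- mk_mat("chr1", pos, meth = meth, total = total)
  wd3 <- window_density(mat3, window = 5000L, min_cov = 1L)
  pc <- pooled_counts(mat3)
  for (g in c("anagen", "telogen")) {
    for (ws in unique(wd3$start)) {
      in_w <- pos >= ws & pos < ws + 5000L & pc$total[, g] >= 1
      expected <- region_level(pc$meth[in_w, g], pc$total[in_w, g])
      got <- wd3$level[wd3$group == g & wd3$start == ws]
      expect_equal(got, expected)
    }
    expect_equal(sum(wd3$meth[wd3$group == g], na.rm = TRUE),
                 sum(pc$meth[, g]))
  }
})

flat_fixture <- function(level_num = 7L, level_den = 10L) {
  pos <- seq(0, 29999, by = 37)
  mat <- mk_mat("chr1", pos, meth = level_num, total = level_den)
  gm <- gene_models(
    data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
               start = c(5000L, 14000L), end = c(9000L, 20000L),
               strand = c("+", "-")),
    data.frame(gene_id = c("g1", "g1", "g2", "g2"), chrom = "chr1",
               start = c(5000L, 7000L, 14000L, 17000L),
               end = c(6000L, 9000L, 15000L, 20000L)))
  cgis <- data.table::data.table(chrom = "chr1", start = 25000L,
                                 end = 26000L, strand = ".", label = "CGI")
  list(mat = mat, gm = gm, cgis = cgis)
}

test_that("metaprofile of a flat methylome is flat in every class", {
  fx <- flat_fixture()
  mp <- metaprofile(fx$mat, fx$gm, fx$cgis)
  expect_true(all(abs(mp$level - 0.7) < 1e-12))
  expect_setequal(unique(mp$feature_class),
                  c("promoter", "gene_body", "gene_body_flank", "exon",
                    "intron", "CGI", "CGI_shore"))
})

test_that("metaprofile is invariant to gene list order", {
  fx <- flat_fixture()
  set.seed(3)
  n <- 200
  pos <- sort(sample.int(30000L, n))
  total <- matrix(rpois(n * 4, 15), n)
  meth <- matrix(rbinom(n * 4, as.vector(total), 0.5), n)
  mat <- mk_mat("chr1", pos, meth = meth, total = total)
  mp1 <- metaprofile(mat, fx$gm, fx$cgis)
  gm_rev <- gene_models(fx$gm$genes[2:1, ], fx$gm$exons)
  mp2 <- metaprofile(mat, gm_rev, fx$cgis)
  data.table::setorder(mp1, feature_class, context, group, bin)
  data.table::setorder(mp2, feature_class, context, group, bin)
  expect_equal(mp1, mp2)
})

test_that("mirrored minus-strand gene gives the identical profile", {
  ## a plus-strand gene over a methylome, and its mirror image: a
  ## minus-strand gene at the reflected coordinates over the reflected
  ## methylome, must produce identical binned profiles
  L <- 10000L
  set.seed(23)
  n <- 150
  pos <- sort(sample.int(L - 1L, n))
  total <- matrix(rpois(n * 4, 15), n)
  meth <- matrix(rbinom(n * 4, as.vector(total), runif(n)), n)
  mat_f <- mk_mat("chr1", pos, meth = meth, total = total)
  ## mirror: position p -> L - 1 - p, rows reversed to stay sorted
  mat_r <- mk_mat("chr1", rev(L - 1L - pos),
                  meth = meth[rev(seq_len(n)), ],
                  total = total[rev(seq_len(n)), ])
  gs <- 3000L; ge <- 7000L
  gm_f <- gene_models(
    data.frame(gene_id = "g", chrom = "chr1", start = gs, end = ge,
               strand = "+"),
    data.frame(gene_id = "g", chrom = "chr1", start = gs, end = ge))
  gm_r <- gene_models(
    data.frame(gene_id = "g", chrom = "chr1", start = L - ge,
               end = L - gs, strand = "-"),
    data.frame(gene_id = "g", chrom = "chr1", start = L - ge,
               end = L - gs))
  cg <- data.table::data.table(chrom = character(), start = integer(),
                               end = integer(), strand = character(),
                               label = character())
  mp_f <- metaprofile(mat_f, gm_f, cg, min_cov = 1L)
  mp_r <- metaprofile(mat_r, gm_r, cg, min_cov = 1L)
  for (cls in c("gene_body", "promoter", "gene_body_flank")) {
    a <- mp_f[mp_f$feature_class == cls, ]
    b <- mp_r[mp_r$feature_class == cls, ]
    expect_equal(a, b, info = cls)
  }
})

test_that("chromosome feature correlations match the closed form", {
  s <- data.table::data.table(
    chrom = c("c1", "c2", "c3"),
    length = c(1L, 2L, 3L), mean_level = c(2, 4, 7),
    cpg_count = c(10L, 10L, 10L), cpg_oe = c(0.3, 0.2, 0.1),
    gene_count = c(8L, 6L, 3L), repeat_count = c(4L, 8L, 14L))
  cc <- chrom_feature_correlations(s)
  ## closed-form Pearson r for (1,2,3) vs (2,4,7)
  x <- c(1, 2, 3); y <- c(2, 4, 7); n <- 3
  r_manual <- (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  expect_equal(cc$r[cc$feature == "length"], r_manual, tolerance = 1e-12)
  ## exact linear relations
  expect_equal(cc$r[cc$feature == "repeat_count"], 1)
  expect_equal(cc$r[cc$feature == "gene_count"], -1)
  ## zero-variance feature -> NA sentinel
  expect_true(is.na(cc$r[cc$feature == "cpg_count"]))
})

test_that("sample correlations are symmetric with unit diagonal", {
  ## two samples drawn from the same level vector at 30x correlate > 0.9
  set.seed(29)
  n <- 2000
  lev <- runif(n)
  total <- matrix(rpois(n * 4, 30), n)
  meth <- matrix(rbinom(n * 4, as.vector(total), rep(lev, 4)), n)
  mat <- mk_mat("chr1", seq_len(n) * 10L, meth = meth, total = total)
  sc <- sample_correlation(mat)
  expect_equal(diag(sc), stats::setNames(rep(1, 4), colnames(mat$meth)))
  expect_equal(sc, t(sc))
  expect_true(all(sc[upper.tri(sc)] > 0.9))

  ## reordering sites identically in every sample leaves r unchanged
  mat2 <- mk_mat("chr1", seq_len(n) * 10L,
                 meth = meth[n:1, , drop = FALSE],
                 total = total[n:1, , drop = FALSE])
  expect_equal(sample_correlation(mat2), sc)
})
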