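test_that("smoothing preserves constants and isolated sites", {
  pos <- sort(sample.int(50000L, 300))
  mat <- mk_mat("chr1", pos, meth = 5L, total = 10L)
  for (deg in 0:1) {
    sm <- smooth_methylome(mat, degree = deg)
    expect_true(all(abs(sm - 0.5) < 1e-12))
  }
  ## isolated single site on its own chromosome keeps its raw level
  mat1 <- mk_mat(c("chrA", rep("chrB", 20)),
                 c(1000L, seq(100L, 2000L, by = 100L)),
                 meth = c(9L, rep(2L, 20)), total = 10L)
  sm1 <- smooth_methylome(mat1)
  expect_equal(unname(sm1[1, 1]), 0.9)
})

test_that("degree-0 smoothing equals the brute-force weighted mean", {
  set.seed(41)
  n <- 200
  pos <- sort(sample.int(20000L, n))
  total <- matrix(rpois(n * 4, 10) + 1L, n)
  meth <- matrix(rbinom(n * 4, as.vector(total), runif(n)), n)
  mat <- mk_mat("chr1", pos, meth = meth, total = total)
  sm <- smooth_methylome(mat, half_window = 500, min_sites = 10,
                         degree = 0L)
  for (s in colnames(mat$meth)) {
    oracle <- bf_smooth0(pos, mat$meth[, s] / mat$total[, s],
                         mat$total[, s], pos, 500, 10)
    expect_equal(unname(sm[, s]), pmin(pmax(oracle, 0), 1),
                 tolerance = 1e-10)
  }
})

test_that("windows with no group difference give t = 0, p = 1", {
  pos <- seq(0L, 2000L, by = 20L)
  mat <- mk_mat("chr1", pos, meth = 5L, total = 10L)
  sm <- smooth_methylome(mat)
  win <- scan_windows(mat, sm)
  expect_true(all(win$t_stat == 0))
  expect_true(all(win$p_value == 1))
})

test_that("clearly separated groups give significant windows", {
  set.seed(43)
  n <- 101
  pos <- seq(0L, 2000L, by = 20L)
  total <- matrix(30L, n, 6)
  meth <- cbind(matrix(rbinom(n * 3, 30, 0.2), n),
                matrix(rbinom(n * 3, 30, 0.8), n))
  mat <- mk_mat("chr1", pos, meth = meth, total = total, n_rep = 3)
  sm <- smooth_methylome(mat)
  win <- scan_windows(mat, sm)
  expect_true(all(abs(win$t_stat) > 5))
  expect_true(all(win$q_value < 0.01))
  expect_true(all(win$mean_b > win$mean_a))
})

test_that("BH correction over four hand-computed p-values", {
  q <- methcycle:::bh_adjust(c(0.01, 0.02, 0.03, 0.04))
  expect_equal(q, rep(0.04, 4))
})

test_that("differential sites require both the window and the site rule", {
  pos <- c(100L, 500L, 5000L)
  diffs <- c(0.30, 0.20, 0.30)
  meth <- cbind(matrix(rep(round(20 * 0.40), 3), 3, 3),
                matrix(round(20 * (0.40 + diffs)), 3, 3))
  mat <- mk_mat("chr1", pos, meth = meth,
                total = matrix(20L, 3, 6), n_rep = 3)
  ## one significant window covering [0, 1000), none over pos 5000
  win <- data.table::data.table(
    chrom = "chr1", start = c(0L, 4900L), end = c(1000L, 5900L),
    mean_a = 0.4, mean_b = 0.6, t_stat = 5, p_value = c(0.001, 0.5),
    q_value = c(0.01, 0.5), n_sites_window = 3L)
  fl <- differential_sites(mat, win, min_cov = 1L)
  ## site 1: diff 0.30 in a significant window -> flagged
  ## site 2: diff 0.20 <= 0.25 -> not flagged despite the window
  ## site 3: diff 0.30 but no significant window -> not flagged
  expect_equal(fl$pos, 100L)
  expect_equal(fl$sign_dir, 1L)
  expect_equal(fl$min_q, 0.01)
})

test_that("lowering min_diff never shrinks the flagged set", {
  set.seed(47)
  n <- 80
  pos <- sort(sample.int(3000L, n))
  total <- matrix(20L, n, 6)
  meth <- cbind(matrix(rbinom(n * 3, 20, 0.4), n),
                matrix(rbinom(n * 3, 20, runif(n, 0.4, 0.9)), n))
  mat <- mk_mat("chr1", pos, meth = meth, total = total, n_rep = 3)
  win <- data.table::data.table(
    chrom = "chr1", start = 0L, end = 3000L, mean_a = .4, mean_b = .6,
    t_stat = 5, p_value = 0.001, q_value = 0.001, n_sites_window = n)
  prev <- NULL
  for (md in c(0.35, 0.25, 0.15, 0.05)) {
    fl <- differential_sites(mat, win, min_diff = md, min_cov = 1L)
    if (!is.null(prev)) expect_true(all(prev$pos %in% fl$pos))
    prev <- fl
  }
})

test_that("merge_dmrs applies the gap, size and sign rules", {
  fl <- data.table::data.table(
    chrom = "chr1", pos = c(100L, 200L, 300L), strand = "+",
    diff = 0.3, sign_dir = 1L, min_q = 0.01)
  d <- merge_dmrs(fl)
  expect_equal(nrow(d), 1)
  expect_equal(d$start, 100L)
  expect_equal(d$end, 301L)
  expect_equal(d$n_sites, 3L)

  ## two sites only: below the minimum
  expect_equal(nrow(merge_dmrs(fl[1:2, ])), 0)

  ## gap 400 > 300 splits into runs of 2 and 1: no DMR
  fl2 <- data.table::copy(fl)
  fl2$pos <- c(100L, 200L, 600L)
  expect_equal(nrow(merge_dmrs(fl2)), 0)

  ## opposite signs never co-merge
  fl3 <- data.table::copy(fl)
  fl3$sign_dir <- c(1L, -1L, 1L)
  fl3$diff <- c(0.3, -0.3, 0.3)
  expect_equal(nrow(merge_dmrs(fl3)), 0)
})

test_that("merge_dmrs equals the brute-force oracle on random inputs", {
  set.seed(53)
  for (rep in 1:200) {
    n <- sample.int(50, 1)
    fl <- data.table::data.table(
      chrom = sample(c("c1", "c2"), n, replace = TRUE),
      pos = sample.int(3000L, n),
      strand = "+",
      sign_dir = sample(c(-1L, 1L), n, replace = TRUE),
      min_q = runif(n, 0, 0.05))
    fl <- unique(fl, by = c("chrom", "pos"))
    fl$diff <- fl$sign_dir * 0.3
    got <- merge_dmrs(fl)
    want <- bf_merge(fl)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got) > 0) {
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
      expect_equal(got$n_sites, want$n_sites)
      expect_equal(got$sign_dir, want$sign_dir)
    }
  }
})

test_that("merging already-merged support sites is idempotent", {
  set.seed(59)
  fl <- data.table::data.table(
    chrom = "chr1", pos = sort(sample.int(5000L, 40)), strand = "+",
    sign_dir = rep(c(1L, -1L), 20), min_q = 0.01)
  fl$diff <- fl$sign_dir * 0.3
  d1 <- merge_dmrs(fl)
  sup <- attr(d1, "support")
  fl2 <- merge(fl, sup[, c("chrom", "pos", "strand")],
               by = c("chrom", "pos", "strand"))
  d2 <- merge_dmrs(fl2)
  expect_equal(d1[, -"dmr_id"], d2[, -"dmr_id"])
})

test_that("label_direction computes pooled differences and direction", {
  pos <- c(100L, 200L, 300L)
  meth <- cbind(matrix(8L, 3, 3), matrix(16L, 3, 3))   # 0.4 vs 0.8
  mat <- mk_mat("chr1", pos, meth = meth, total = matrix(20L, 3, 6),
                n_rep = 3)
  fl <- data.table::data.table(chrom = "chr1", pos = pos, strand = "+",
                               diff = 0.4, sign_dir = 1L, min_q = 0.01)
  d <- label_direction(merge_dmrs(fl), mat)
  expect_equal(d$direction, "hyper")
  expect_equal(d$mean_diff, 0.4)

  ## telogen lower -> hypo
  mat2 <- mk_mat("chr1", pos,
                 meth = cbind(matrix(10L, 3, 3), matrix(2L, 3, 3)),
                 total = matrix(20L, 3, 6), n_rep = 3)
  fl2 <- data.table::copy(fl)
  fl2$sign_dir <- -1L; fl2$diff <- -0.4
  d2 <- label_direction(merge_dmrs(fl2), mat2)
  expect_equal(d2$direction, "hypo")
  expect_equal(d2$mean_diff, 0.1 - 0.5)
})
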