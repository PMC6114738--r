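## dmrcall: smoothed sliding-window detection of differentially methylated
## regions between two groups, followed by the four-rule merge of
## differential cytosines into DMRs.
##
## The statistic follows the BSmooth idea: per-sample local-regression
## smoothing of site levels, per-window per-sample mean smoothed levels,
## a Welch t-test between groups per window, and BH correction over all
## tested windows. Sites carry the effect-size rule (|pooled group
## difference| > min_diff), windows carry the FDR rule.

#' Smooth per-sample methylation levels along each chromosome
#'
#' Each sample's raw site levels (`meth/total`, weighted by coverage) are
#' smoothed by kernel-weighted local regression (tricube kernel, degree 0
#' or 1). The window around each site spans `half_window` bp on each side
#' and is expanded until it holds at least `min_sites` covered sites.
#' Smoothing never crosses chromosome boundaries.
#'
#' @param mat A `MethylomeMatrix`.
#' @param half_window Half-width of the smoothing window in bp
#'   (default 500).
#' @param min_sites Minimum covered sites per smoothing window
#'   (default 10).
#' @param degree Local fit degree, 0 (weighted mean) or 1 (weighted line;
#'   default).
#' @return Numeric matrix of smoothed levels in `[0, 1]`, sites x samples
#'   (`NA` on chromosomes where a sample has no coverage), with the
#'   smoothing parameters attached as attribute `"params"`.
#' @export
smooth_methylome <- function(mat, half_window = 500, min_sites = 10L,
                             degree = 1L) {
  stopifnot(half_window >= 1, min_sites >= 1, degree %in% c(0L, 1L))
  sites <- mat$sites
  out <- matrix(NA_real_, nrow(sites), ncol(mat$meth),
                dimnames = list(NULL, colnames(mat$meth)))
  for (chr in unique(sites$chrom)) {
    idx <- which(sites$chrom == chr)
    p <- as.numeric(sites$pos[idx])
    for (s in colnames(mat$meth)) {
      tot <- mat$total[idx, s]
      cov_i <- tot >= 1
      if (!any(cov_i)) next
      out[idx, s] <- smooth_sites_cpp(
        p[cov_i], mat$meth[idx, s][cov_i] / tot[cov_i],
        as.numeric(tot[cov_i]), p, half_window, as.integer(min_sites),
        as.integer(degree))
    }
  }
  attr(out, "params") <- list(half_window = half_window,
                              min_sites = min_sites, degree = degree)
  out
}

## Vectorised Welch t-test over rows; xa, xb: windows x samples matrices.
## Returns list(t, p) for the contrast b - a.
welch_rows <- function(xa, xb) {
  na <- rowSums(!is.na(xa)); nb <- rowSums(!is.na(xb))
  ma <- rowMeans(xa, na.rm = TRUE); mb <- rowMeans(xb, na.rm = TRUE)
  va <- rowSums((xa - ma)^2, na.rm = TRUE) / pmax(na - 1, 1)
  vb <- rowSums((xb - mb)^2, na.rm = TRUE) / pmax(nb - 1, 1)
  se2 <- va / na + vb / nb
  t <- (mb - ma) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / pmax(na - 1, 1) +
                   (vb / nb)^2 / pmax(nb - 1, 1))
  zero <- !is.na(se2) & se2 == 0
  t[zero & (mb == ma)] <- 0
  t[zero & (mb > ma)] <- Inf
  t[zero & (mb < ma)] <- -Inf
  p <- 2 * stats::pt(-abs(t), df)
  p[zero & (mb == ma)] <- 1
  p[zero & (mb != ma)] <- 0
  bad <- na < 2 | nb < 2
  t[bad] <- NA_real_; p[bad] <- NA_real_
  list(t = t, p = p)
}

#' Test sliding windows for a group difference in smoothed methylation
#'
#' Tiles each chromosome with windows of `window` bp advanced by `step`
#' bp. Within a window, each sample's summary is the mean smoothed level
#' over its covered sites; the two groups' summaries are compared with a
#' Welch t-test and p-values are Benjamini-Hochberg corrected over all
#' tested windows.
#'
#' @param mat A `MethylomeMatrix`.
#' @param smoothed Matrix from [smooth_methylome()].
#' @param window,step Window size and step in bp (defaults 1000 and 100).
#' @param min_window_sites Minimum sites in a window for it to be tested
#'   (default 3).
#' @param min_cov Per-sample coverage floor for a site to count as covered
#'   in a window summary (default 4).
#' @param group_a,group_b The two group labels; the tested contrast is
#'   `group_b - group_a` (defaults `"anagen"`, `"telogen"`).
#' @return `data.table` of tested windows: `chrom`, `start`, `end`,
#'   `mean_a`, `mean_b`, `t_stat`, `p_value`, `q_value`, `n_sites_window`.
#' @export
scan_windows <- function(mat, smoothed, window = 1000L, step = 100L,
                         min_window_sites = 3L, min_cov = 4L,
                         group_a = "anagen", group_b = "telogen") {
  sites <- mat$sites
  cols_a <- group_samples(mat, group_a)
  cols_b <- group_samples(mat, group_b)
  stopifnot(length(cols_a) >= 2, length(cols_b) >= 2)
  samp <- c(cols_a, cols_b)

  per_chrom <- lapply(unique(sites$chrom), function(chr) {
    idx <- which(sites$chrom == chr)
    p <- sites$pos[idx]
    len <- max(p) + 1L
    starts <- seq(0L, len - 1L, by = as.integer(step))
    lo <- findInterval(starts - 0.5, p) + 1L
    hi <- findInterval(starts + as.integer(window) - 0.5, p)
    nsite <- hi - lo + 1L
    keep <- nsite >= min_window_sites
    if (!any(keep)) return(NULL)
    starts <- starts[keep]; lo <- lo[keep]; hi <- hi[keep]
    nsite <- nsite[keep]

    summ <- matrix(NA_real_, length(starts), length(samp),
                   dimnames = list(NULL, samp))
    for (s in samp) {
      sm <- smoothed[idx, s]
      ok <- mat$total[idx, s] >= min_cov & !is.na(sm)
      cs <- cumsum(ifelse(ok, sm, 0))
      cn <- cumsum(ok)
      tot <- cs[hi] - ifelse(lo > 1, cs[lo - 1], 0)
      cnt <- cn[hi] - ifelse(lo > 1, cn[lo - 1], 0)
      summ[, s] <- ifelse(cnt > 0, tot / cnt, NA_real_)
    }
    cbind(data.table::data.table(chrom = chr, start = starts,
                                 end = starts + as.integer(window),
                                 n_sites_window = nsite),
          data.table::as.data.table(summ))
  })
  win <- data.table::rbindlist(per_chrom[!vapply(per_chrom, is.null,
                                                 logical(1))])
  if (nrow(win) == 0)
    return(data.table::data.table(chrom = character(), start = integer(),
                                  end = integer(), mean_a = numeric(),
                                  mean_b = numeric(), t_stat = numeric(),
                                  p_value = numeric(), q_value = numeric(),
                                  n_sites_window = integer()))
  xa <- as.matrix(win[, cols_a, with = FALSE])
  xb <- as.matrix(win[, cols_b, with = FALSE])
  wt <- welch_rows(xa, xb)
  out <- win[, c("chrom", "start", "end", "n_sites_window"), with = FALSE]
  out$mean_a <- rowMeans(xa, na.rm = TRUE)
  out$mean_b <- rowMeans(xb, na.rm = TRUE)
  out$t_stat <- wt$t
  out$p_value <- wt$p
  tested <- !is.na(out$p_value)
  out$q_value <- NA_real_
  out$q_value[tested] <- bh_adjust(out$p_value[tested])
  out[, c("chrom", "start", "end", "mean_a", "mean_b", "t_stat", "p_value",
          "q_value", "n_sites_window"), with = FALSE]
}

#' Flag differential cytosines
#'
#' A site is differential when (1) it lies inside at least one window with
#' `q_value < fdr` and (2) its own pooled between-group level difference
#' exceeds `min_diff` in absolute value. The signed difference is
#' `group_b - group_a` (telogen minus anagen by default).
#'
#' @param mat A `MethylomeMatrix`.
#' @param windows Output of [scan_windows()].
#' @param min_diff Minimum absolute pooled level difference, exclusive
#'   (default 0.25).
#' @param fdr Window q-value threshold, exclusive (default 0.05).
#' @param min_cov Minimum pooled per-group coverage at a site (default 4).
#' @param group_a,group_b Group labels (defaults `"anagen"`, `"telogen"`).
#' @return `data.table` of flagged sites: `chrom`, `pos`, `strand`, `diff`,
#'   `sign_dir` (+1/-1), `min_q` (smallest q among covering significant
#'   windows).
#' @export
differential_sites <- function(mat, windows, min_diff = 0.25, fdr = 0.05,
                               min_cov = 4L, group_a = "anagen",
                               group_b = "telogen") {
  sig <- windows[!is.na(windows$q_value) & windows$q_value < fdr]
  empty <- data.table::data.table(chrom = character(), pos = integer(),
                                  strand = character(), diff = numeric(),
                                  sign_dir = integer(), min_q = numeric())
  if (nrow(sig) == 0) return(empty)

  sites <- mat$sites
  ma <- rowSums(mat$meth[, group_samples(mat, group_a), drop = FALSE])
  ta <- rowSums(mat$total[, group_samples(mat, group_a), drop = FALSE])
  mb <- rowSums(mat$meth[, group_samples(mat, group_b), drop = FALSE])
  tb <- rowSums(mat$total[, group_samples(mat, group_b), drop = FALSE])
  covered <- ta >= min_cov & tb >= min_cov
  diff <- ifelse(covered, mb / tb - ma / ta, NA_real_)

  site_gr <- GenomicRanges::GRanges(sites$chrom,
                                    IRanges::IRanges(sites$pos + 1L,
                                                     sites$pos + 1L))
  sig_gr <- as_granges0(sig)
  hits <- GenomicRanges::findOverlaps(site_gr, sig_gr)
  if (length(hits) == 0) return(empty)
  hq <- data.table::data.table(site = S4Vectors::queryHits(hits),
                               q = sig$q_value[S4Vectors::subjectHits(hits)])
  minq <- hq[, .(min_q = min(q)), by = "site"]

  flag_idx <- minq$site[!is.na(diff[minq$site]) &
                          abs(diff[minq$site]) > min_diff]
  if (length(flag_idx) == 0) return(empty)
  out <- data.table::data.table(
    chrom = sites$chrom[flag_idx], pos = sites$pos[flag_idx],
    strand = sites$strand[flag_idx], diff = diff[flag_idx],
    sign_dir = ifelse(diff[flag_idx] > 0, 1L, -1L),
    min_q = minq$min_q[match(flag_idx, minq$site)])
  data.table::setorder(out, chrom, pos, strand)
  out[]
}

#' Merge differential cytosines into DMRs
#'
#' Same-sign flagged sites whose consecutive gaps are at most `max_gap` bp
#' form candidate regions; candidates with at least `min_sites` sites
#' become DMRs. Sites of opposite sign never co-merge (each sign is merged
#' independently, so oppositely-signed DMRs may interleave). The DMR span
#' runs from its first to one past its last supporting site.
#'
#' @param flagged Output of [differential_sites()].
#' @param max_gap Maximum gap between consecutive supporting sites in bp
#'   (default 300; larger gaps split).
#' @param min_sites Minimum supporting sites per DMR (default 3).
#' @return `data.table` of DMRs: `chrom`, `start`, `end`, `n_sites`,
#'   `sign_dir`, `q_value` (minimum window q over supporting sites), with
#'   the site-to-DMR assignment attached as attribute `"support"`.
#' @export
merge_dmrs <- function(flagged, max_gap = 300L, min_sites = 3L) {
  empty <- data.table::data.table(chrom = character(), start = integer(),
                                  end = integer(), n_sites = integer(),
                                  sign_dir = integer(), q_value = numeric())
  if (nrow(flagged) == 0) {
    attr(empty, "support") <- data.table::data.table(
      dmr_id = integer(), chrom = character(), pos = integer(),
      strand = character())
    return(empty)
  }
  fl <- data.table::copy(data.table::as.data.table(flagged))
  data.table::setorder(fl, chrom, pos, strand)
  fl[, run := {
    gap_break <- c(FALSE, diff(pos) > max_gap)
    cumsum(gap_break)
  }, by = c("chrom", "sign_dir")]

  fl[, run_key := paste(chrom, sign_dir, run, sep = "\r")]
  dmrs <- fl[, .(chrom = chrom[1], start = min(pos), end = max(pos) + 1L,
                 n_sites = .N, sign_dir = sign_dir[1],
                 q_value = min(min_q)),
             by = "run_key"]
  dmrs <- dmrs[n_sites >= min_sites]
  data.table::setorder(dmrs, chrom, start, sign_dir)
  dmrs$dmr_id <- seq_len(nrow(dmrs))
  support <- merge(fl, dmrs[, c("run_key", "dmr_id"), with = FALSE],
                   by = "run_key")[, c("dmr_id", "chrom", "pos", "strand"),
                                   with = FALSE]
  data.table::setorder(support, dmr_id, pos)
  out <- dmrs[, c("dmr_id", "chrom", "start", "end", "n_sites", "sign_dir",
                  "q_value"), with = FALSE]
  attr(out, "support") <- support[]
  out
}

#' Label DMR direction and region-level effect size
#'
#' `mean_diff` is the pooled `group_b` level minus the pooled `group_a`
#' level over each DMR's supporting sites; direction is `hyper` (higher in
#' `group_b`, i.e. telogen by default) when `mean_diff > 0`, else `hypo`.
#'
#' @param dmrs Output of [merge_dmrs()] (with its `"support"` attribute).
#' @param mat A `MethylomeMatrix`.
#' @param group_a,group_b Group labels (defaults `"anagen"`, `"telogen"`).
#' @return The DMR table with `mean_diff` and `direction` columns.
#' @export
label_direction <- function(dmrs, mat, group_a = "anagen",
                            group_b = "telogen") {
  support <- attr(dmrs, "support")
  if (nrow(dmrs) == 0) {
    dmrs$mean_diff <- numeric(0); dmrs$direction <- character(0)
    return(dmrs)
  }
  skey <- paste(mat$sites$chrom, mat$sites$pos, mat$sites$strand, sep = "\r")
  idx <- match(paste(support$chrom, support$pos, support$strand, sep = "\r"),
               skey)
  if (anyNA(idx))
    stop_mc("support sites missing from the methylome matrix")
  ma <- rowSums(mat$meth[, group_samples(mat, group_a), drop = FALSE])
  ta <- rowSums(mat$total[, group_samples(mat, group_a), drop = FALSE])
  mb <- rowSums(mat$meth[, group_samples(mat, group_b), drop = FALSE])
  tb <- rowSums(mat$total[, group_samples(mat, group_b), drop = FALSE])
  eff <- data.table::data.table(dmr_id = support$dmr_id,
                                ma = ma[idx], ta = ta[idx],
                                mb = mb[idx], tb = tb[idx])
  agg <- eff[, .(mean_diff = sum(mb) / sum(tb) - sum(ma) / sum(ta)),
             by = "dmr_id"]
  out <- merge(dmrs, agg, by = "dmr_id", sort = TRUE)
  stopifnot(all(out$mean_diff != 0))
  out$direction <- ifelse(out$mean_diff > 0, "hyper", "hypo")
  attr(out, "support") <- support
  out[]
}

#' Full DMR-calling pipeline
#'
#' Subsets the matrix to one context (CG by default), smooths each sample,
#' scans 1000/100 bp sliding windows with a Welch t-test and BH
#' correction, flags differential sites (window `q < fdr`, site
#' `|difference| > min_diff`), merges same-sign runs (gap <= `max_gap`,
#' >= `min_sites` sites) and labels direction.
#'
#' @param mat A `MethylomeMatrix`.
#' @param context Context analysed (default `"CG"`).
#' @param half_window,smooth_min_sites,degree Smoothing parameters
#'   (see [smooth_methylome()]).
#' @param window,step,min_window_sites Window scan parameters
#'   (see [scan_windows()]).
#' @param min_diff,fdr Site and window thresholds
#'   (see [differential_sites()]).
#' @param max_gap,min_sites Merge parameters (see [merge_dmrs()]).
#' @param min_cov Coverage floor used throughout (default 4).
#' @param group_a,group_b Group labels (defaults `"anagen"`, `"telogen"`).
#' @return List with `dmrs` (directed DMR table), `windows`, `flagged`
#'   and `smoothed`.
#' @export
call_dmrs <- function(mat, context = "CG", half_window = 500,
                      smooth_min_sites = 10L, degree = 1L,
                      window = 1000L, step = 100L, min_window_sites = 3L,
                      min_diff = 0.25, fdr = 0.05, max_gap = 300L,
                      min_sites = 3L, min_cov = 4L,
                      group_a = "anagen", group_b = "telogen") {
  sub <- subset_sites(mat, mat$sites$context == context)
  smoothed <- smooth_methylome(sub, half_window = half_window,
                               min_sites = smooth_min_sites, degree = degree)
  windows <- scan_windows(sub, smoothed, window = window, step = step,
                          min_window_sites = min_window_sites,
                          min_cov = min_cov, group_a = group_a,
                          group_b = group_b)
  flagged <- differential_sites(sub, windows, min_diff = min_diff, fdr = fdr,
                                min_cov = min_cov, group_a = group_a,
                                group_b = group_b)
  dmrs <- merge_dmrs(flagged, max_gap = max_gap, min_sites = min_sites)
  dmrs <- label_direction(dmrs, sub, group_a = group_a, group_b = group_b)
  list(dmrs = dmrs, windows = windows, flagged = flagged,
       smoothed = smoothed)
}

#' Write DMRs as BED6+ and TSV
#'
#' BED columns: chrom, start, end, name (`direction`), score
#' (`round(1000 * |mean_diff|)`), strand (`.`); the TSV carries the full
#' table.
#'
#' @param dmrs Directed DMR table from [label_direction()].
#' @param bed_path,tsv_path Output paths (either may be `NULL`).
#' @export
write_dmrs <- function(dmrs, bed_path = NULL, tsv_path = NULL) {
  if (!is.null(bed_path)) {
    bed <- data.table::data.table(
      chrom = dmrs$chrom, start = dmrs$start, end = dmrs$end,
      name = dmrs$direction, score = round(1000 * abs(dmrs$mean_diff)),
      strand = ".")
    data.table::fwrite(bed, bed_path, sep = "\t", quote = FALSE,
                       col.names = FALSE, eol = "\n")
  }
  if (!is.null(tsv_path)) {
    cols <- c("dmr_id", "chrom", "start", "end", "n_sites", "mean_diff",
              "direction", "q_value")
    data.table::fwrite(dmrs[, cols, with = FALSE], tsv_path, sep = "\t",
                       quote = FALSE, eol = "\n")
  }
  invisible(dmrs)
}
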