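## profilestats: descriptive methylome summaries — large-window densities,
## feature meta-profiles, CpG observed/expected ratios and correlation
## analyses between samples and with genomic features.

#' Mean methylation level in large tiling windows
#'
#' Chromosomes are tiled with non-overlapping windows and each window's
#' level is the pooled (coverage-weighted) methylation over its sites, per
#' context and group. Windows without covered sites are reported with
#' `NA` level.
#'
#' @param mat A `MethylomeMatrix`.
#' @param window Window size in bp (default 300000).
#' @param chrom_lengths Named integer vector of contig lengths; defaults to
#'   the last covered site + 1 per contig.
#' @param min_cov Minimum pooled group coverage for a site to contribute
#'   (default 4).
#' @return `data.table` with `chrom`, `start`, `end`, `context`, `group`,
#'   `meth`, `total`, `level`.
#' @export
window_density <- function(mat, window = 300000L, chrom_lengths = NULL,
                           min_cov = 4L) {
  stopifnot(window >= 1)
  sites <- mat$sites
  if (is.null(chrom_lengths)) {
    chrom_lengths <- vapply(split(sites$pos, sites$chrom), max, numeric(1)) + 1
  }
  pc <- pooled_counts(mat)
  grps <- colnames(pc$meth)
  contexts <- sort(unique(sites$context))

  per_group <- lapply(grps, function(g) {
    m <- pc$meth[, g]; t <- pc$total[, g]
    ok <- t >= min_cov
    dt <- data.table::data.table(
      chrom = sites$chrom[ok],
      start = (sites$pos[ok] %/% as.integer(window)) * as.integer(window),
      context = sites$context[ok], meth = m[ok], total = t[ok])
    agg <- dt[, .(meth = sum(meth), total = sum(total)),
              by = c("chrom", "start", "context")]
    agg$group <- g
    agg
  })
  agg <- data.table::rbindlist(per_group)

  grid <- data.table::rbindlist(lapply(names(chrom_lengths), function(chr) {
    starts <- seq(0L, max(0L, as.integer(chrom_lengths[[chr]]) - 1L),
                  by = as.integer(window))
    data.table::CJ(chrom = chr, start = starts, context = contexts,
                   group = grps)
  }))
  out <- merge(grid, agg, by = c("chrom", "start", "context", "group"),
               all.x = TRUE)
  out$end <- pmin(out$start + as.integer(window),
                  as.integer(chrom_lengths[out$chrom]))
  out$level <- ifelse(!is.na(out$total) & out$total > 0,
                      out$meth / out$total, NA_real_)
  data.table::setorder(out, chrom, start, context, group)
  out[, c("chrom", "start", "end", "context", "group", "meth", "total",
          "level"), with = FALSE]
}

## Index sites of one chromosome falling in [s, e); pos must be sorted.
sites_in_interval <- function(pos, s, e) {
  lo <- findInterval(s - 0.5, pos) + 1L
  hi <- findInterval(e - 0.5, pos)
  if (hi < lo) integer(0) else lo:hi
}

#' Meta-profiles of methylation over genomic feature classes
#'
#' Pools methylation into ordered bins over six feature classes: promoters
#' (fixed-width bins covering `flank` bp upstream of the TSS, 5' to 3'),
#' gene bodies, exons, introns and CpG islands (each instance scaled to
#' `n_bins`), CGI shores (fixed-width bins over the `shore_width` bp on
#' each side of an island, bin 0 adjacent to the island) and a 3' gene
#' flank. Minus-strand genes are flipped so bin 0 is always 5'/upstream.
#'
#' @param mat A `MethylomeMatrix`.
#' @param genes A `gene_models` object.
#' @param cgis `data.table` of CGI intervals (0-based half-open).
#' @param n_bins Bins per scaled feature (default 50).
#' @param flank Promoter / 3'-flank width in bp (default 2000).
#' @param bin_width Width of fixed bins in bp (default 100).
#' @param shore_width Shore width on each side of a CGI (default 2000).
#' @param min_cov Minimum pooled group coverage per contributing site
#'   (default 4).
#' @return `data.table` with `feature_class`, `bin`, `context`, `group`,
#'   `meth`, `total`, `level`.
#' @export
metaprofile <- function(mat, genes, cgis, n_bins = 50L, flank = 2000L,
                        bin_width = 100L, shore_width = 2000L, min_cov = 4L) {
  sites <- mat$sites
  pc <- pooled_counts(mat)
  pos_by_chrom <- split(seq_len(nrow(sites)), sites$chrom)

  ## assignments: list of data.tables (site_idx, bin) per class
  collect <- list()
  add <- function(class, site_idx, bin) {
    if (length(site_idx) == 0) return()
    collect[[length(collect) + 1]] <<- data.table::data.table(
      feature_class = class, site_idx = site_idx, bin = as.integer(bin))
  }

  scaled_bins <- function(p, s, e, flip) {
    rel <- (p - s) / (e - s)
    if (flip) rel <- 1 - rel - 1e-9
    pmin(pmax(floor(rel * n_bins), 0L), n_bins - 1L)
  }

  g <- genes$genes
  proms <- promoters_of(genes, width = flank)
  for (i in seq_len(nrow(g))) {
    idx_all <- pos_by_chrom[[g$chrom[i]]]
    if (is.null(idx_all)) next
    p <- sites$pos[idx_all]
    flip <- g$strand[i] == "-"

    ii <- sites_in_interval(p, g$start[i], g$end[i])
    add("gene_body", idx_all[ii],
        scaled_bins(p[ii], g$start[i], g$end[i], flip))

    pr <- proms[proms$gene_id == g$gene_id[i], ]
    if (nrow(pr) == 1) {
      ii <- sites_in_interval(p, pr$start, pr$end)
      if (length(ii) > 0) {
        off <- if (flip) pr$end - 1L - sites$pos[idx_all[ii]]
               else sites$pos[idx_all[ii]] - pr$start
        add("promoter", idx_all[ii],
            pmin(off %/% as.integer(bin_width),
                 as.integer(flank) %/% as.integer(bin_width) - 1L))
      }
    }

    fs <- if (flip) g$start[i] - as.integer(flank) else g$end[i]
    fe <- if (flip) g$start[i] else g$end[i] + as.integer(flank)
    ii <- sites_in_interval(p, max(0L, fs), fe)
    if (length(ii) > 0) {
      off <- if (flip) g$start[i] - 1L - sites$pos[idx_all[ii]]
             else sites$pos[idx_all[ii]] - g$end[i]
      add("gene_body_flank", idx_all[ii],
          pmin(off %/% as.integer(bin_width),
               as.integer(flank) %/% as.integer(bin_width) - 1L))
    }
  }

  e <- genes$exons
  strand_of <- stats::setNames(g$strand, g$gene_id)
  for (i in seq_len(nrow(e))) {
    idx_all <- pos_by_chrom[[e$chrom[i]]]
    if (is.null(idx_all)) next
    p <- sites$pos[idx_all]
    ii <- sites_in_interval(p, e$start[i], e$end[i])
    add("exon", idx_all[ii],
        scaled_bins(p[ii], e$start[i], e$end[i],
                    strand_of[[e$gene_id[i]]] == "-"))
  }
  intr <- introns_of(genes)
  for (i in seq_len(nrow(intr))) {
    idx_all <- pos_by_chrom[[intr$chrom[i]]]
    if (is.null(idx_all)) next
    p <- sites$pos[idx_all]
    ii <- sites_in_interval(p, intr$start[i], intr$end[i])
    add("intron", idx_all[ii],
        scaled_bins(p[ii], intr$start[i], intr$end[i],
                    strand_of[[intr$gene_id[i]]] == "-"))
  }

  cgis <- data.table::as.data.table(cgis)
  cgi_gr <- if (nrow(cgis) > 0) as_granges0(cgis) else NULL
  for (i in seq_len(nrow(cgis))) {
    idx_all <- pos_by_chrom[[cgis$chrom[i]]]
    if (is.null(idx_all)) next
    p <- sites$pos[idx_all]
    ii <- sites_in_interval(p, cgis$start[i], cgis$end[i])
    add("CGI", idx_all[ii],
        scaled_bins(p[ii], cgis$start[i], cgis$end[i], FALSE))

    n_shore_bins <- as.integer(shore_width) %/% as.integer(bin_width)
    for (side in c("left", "right")) {
      ss <- if (side == "left") max(0L, cgis$start[i] - as.integer(shore_width))
            else cgis$end[i]
      se <- if (side == "left") cgis$start[i]
            else cgis$end[i] + as.integer(shore_width)
      ii <- sites_in_interval(p, ss, se)
      if (length(ii) == 0) next
      sp <- sites$pos[idx_all[ii]]
      ## drop shore positions that fall inside another island
      in_cgi <- GenomicRanges::countOverlaps(
        GenomicRanges::GRanges(cgis$chrom[i],
                               IRanges::IRanges(sp + 1L, sp + 1L)),
        cgi_gr) > 0
      ii <- ii[!in_cgi]; sp <- sp[!in_cgi]
      if (length(ii) == 0) next
      dist <- if (side == "left") cgis$start[i] - 1L - sp else sp - cgis$end[i]
      add("CGI_shore", idx_all[ii],
          pmin(dist %/% as.integer(bin_width), n_shore_bins - 1L))
    }
  }

  assign_dt <- data.table::rbindlist(collect)
  if (nrow(assign_dt) == 0)
    stop_mc("no features overlap any site")

  grps <- colnames(pc$meth)
  out <- data.table::rbindlist(lapply(grps, function(grp) {
    m <- pc$meth[, grp]; t <- pc$total[, grp]
    a <- assign_dt[t[assign_dt$site_idx] >= min_cov]
    dt <- data.table::data.table(
      feature_class = a$feature_class, bin = a$bin,
      context = sites$context[a$site_idx],
      meth = m[a$site_idx], total = t[a$site_idx])
    res <- dt[, .(meth = sum(meth), total = sum(total)),
              by = c("feature_class", "bin", "context")]
    res$group <- grp
    res
  }))
  out$level <- ifelse(out$total > 0, out$meth / out$total, NA_real_)
  data.table::setorder(out, feature_class, context, group, bin)
  out[]
}

#' CpG observed/expected ratio
#'
#' Gardiner-Garden form: `(N_CpG * L) / (N_C * N_G)`, with 0 returned when
#' the sequence contains no C or no G.
#'
#' @param seq Character vector of sequences (each of length >= 2).
#' @return Numeric vector of ratios.
#' @export
cpg_oe <- function(seq) {
  vapply(seq, function(s) {
    L <- nchar(s)
    stopifnot(L >= 2)
    n_c <- L - nchar(gsub("C", "", s, fixed = TRUE))
    n_g <- L - nchar(gsub("G", "", s, fixed = TRUE))
    if (n_c == 0 || n_g == 0) return(0)
    n_cg <- length(gregexpr("CG", s, fixed = TRUE)[[1]])
    if (n_cg == 1 && gregexpr("CG", s, fixed = TRUE)[[1]][1] == -1L)
      n_cg <- 0
    (n_cg * L) / (n_c * n_g)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Per-chromosome methylation and sequence-feature summaries
#'
#' @param mat A `MethylomeMatrix`.
#' @param genome Named character vector of contig sequences.
#' @param genes A `gene_models` object.
#' @param repeats `data.table` of repeat intervals.
#' @param chroms Contigs to summarise (default: all contigs with sites,
#'   which lets callers exclude a spike-in contig).
#' @param min_cov Minimum pooled coverage per contributing site.
#' @return `data.table` with `chrom`, `length`, `mean_level`, `cpg_count`,
#'   `cpg_oe`, `gene_count`, `repeat_count`.
#' @export
chrom_summaries <- function(mat, genome, genes, repeats,
                            chroms = NULL, min_cov = 4L) {
  if (is.null(chroms)) chroms <- sort(unique(mat$sites$chrom))
  tot <- rowSums(mat$total)
  met <- rowSums(mat$meth)
  data.table::rbindlist(lapply(chroms, function(chr) {
    idx <- mat$sites$chrom == chr & tot >= min_cov
    seq <- genome[[chr]]
    n_cg <- length(unlist(regmatches(seq, gregexpr("CG", seq, fixed = TRUE))))
    data.table::data.table(
      chrom = chr,
      length = nchar(seq),
      mean_level = region_level(met[idx], tot[idx]),
      cpg_count = n_cg,
      cpg_oe = cpg_oe(seq),
      gene_count = sum(genes$genes$chrom == chr),
      repeat_count = sum(repeats$chrom == chr)
    )
  }))
}

#' Correlations between chromosome methylation and genomic features
#'
#' Pearson correlation (and p-value) of per-chromosome mean methylation
#' level against chromosome length, CpG count, CpG o/e ratio, gene count
#' and repeat count.
#'
#' @param summaries Output of [chrom_summaries()], >= 3 rows.
#' @return `data.table` with `feature`, `r`, `p`; `NA` where a feature has
#'   zero variance.
#' @export
chrom_feature_correlations <- function(summaries) {
  stopifnot(nrow(summaries) >= 3)
  feats <- c("length", "cpg_count", "cpg_oe", "gene_count", "repeat_count")
  data.table::rbindlist(lapply(feats, function(f) {
    x <- summaries[[f]]; y <- summaries$mean_level
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      data.table::data.table(feature = f, r = NA_real_, p = NA_real_)
    } else {
      ct <- stats::cor.test(x, y, method = "pearson")
      data.table::data.table(feature = f, r = unname(ct$estimate),
                             p = ct$p.value)
    }
  }))
}

#' Pairwise sample correlation of per-site methylation levels
#'
#' For each sample pair, Pearson correlation over sites covered at or
#' above `min_cov` in both samples, restricted to one context.
#'
#' @param mat A `MethylomeMatrix`.
#' @param context Context to use (default `"CG"`).
#' @param min_cov Per-sample coverage floor (default 4).
#' @return Symmetric correlation matrix with unit diagonal; `NA` entries
#'   where a pair shares no adequately covered sites.
#' @export
sample_correlation <- function(mat, context = "CG", min_cov = 4L) {
  keep <- mat$sites$context == context
  meth <- mat$meth[keep, , drop = FALSE]
  total <- mat$total[keep, , drop = FALSE]
  samp <- colnames(meth)
  n <- length(samp)
  stopifnot(n >= 2)
  out <- matrix(NA_real_, n, n, dimnames = list(samp, samp))
  diag(out) <- 1
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- total[, i] >= min_cov & total[, j] >= min_cov
      if (!any(ok)) next
      r <- stats::cor(meth[ok, i] / total[ok, i],
                      meth[ok, j] / total[ok, j])
      out[i, j] <- out[j, i] <- r
    }
  }
  out
}
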