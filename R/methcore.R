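## methcore: the per-site layer — context classification, methylation
## calling against the spike-in conversion error, and level computation.

# ---- MethylomeMatrix --------------------------------------------------------

#' Construct a methylome matrix
#'
#' The pipeline's central container: an ordered table of strand-resolved
#' cytosine sites shared by all samples, with per-sample methylated and
#' total read counts and a group label per sample.
#'
#' @param sites data.frame with `chrom`, `pos` (0-based), `strand`
#'   (`+`/`-`), `context` (`CG`/`CHG`/`CHH`); one row per site, sorted by
#'   `(chrom, pos, strand)`.
#' @param meth,total Integer matrices, `nrow(sites)` x n_samples, with
#'   matching column names (sample names).
#' @param groups Named character vector mapping each sample name to its
#'   group (e.g. `"anagen"` or `"telogen"`).
#' @return A `MethylomeMatrix` object.
#' @export
methylome_matrix <- function(sites, meth, total, groups) {
  sites <- data.table::as.data.table(sites)
  stopifnot(all(c("chrom", "pos", "strand", "context") %in% names(sites)))
  if (!identical(colnames(meth), colnames(total)))
    stop_mc("meth and total matrices must have identical sample columns")
  if (nrow(meth) != nrow(sites) || nrow(total) != nrow(sites))
    stop_mc("count matrices must have one row per site")
  if (!all(colnames(meth) %in% names(groups)))
    stop_mc("every sample needs a group label")
  if (any(meth < 0) || any(total < 0) || any(meth > total))
    stop_mc("counts must satisfy 0 <= meth_count <= total_count")
  if (!all(sites$context %in% c("CG", "CHG", "CHH")))
    stop_mc("context must be one of CG, CHG, CHH")
  data.table::setorder(sites, chrom, pos, strand)
  structure(
    list(sites = sites[], meth = meth, total = total,
         groups = groups[colnames(meth)]),
    class = "MethylomeMatrix"
  )
}

#' @export
print.MethylomeMatrix <- function(x, ...) {
  cat(sprintf(
    "MethylomeMatrix: %d sites x %d samples (%s)\n contexts: %s\n",
    nrow(x$sites), ncol(x$meth),
    paste(sprintf("%s=%d", names(table(x$groups)), table(x$groups)),
          collapse = ", "),
    paste(sprintf("%s=%d", names(table(x$sites$context)),
                  table(x$sites$context)), collapse = ", ")))
  invisible(x)
}

#' Sample names of one group
#' @param mat A `MethylomeMatrix`.
#' @param group Group label.
#' @return Character vector of sample names.
#' @export
group_samples <- function(mat, group) {
  names(mat$groups)[mat$groups == group]
}

#' Pooled per-group counts
#'
#' Sums methylated and total counts across the samples of each group.
#'
#' @param mat A `MethylomeMatrix`.
#' @return List of two matrices `meth` and `total`, one column per group.
#' @export
pooled_counts <- function(mat) {
  grps <- sort(unique(mat$groups))
  meth <- vapply(grps, function(g) {
    cols <- group_samples(mat, g)
    rowSums(mat$meth[, cols, drop = FALSE])
  }, numeric(nrow(mat$sites)))
  total <- vapply(grps, function(g) {
    cols <- group_samples(mat, g)
    rowSums(mat$total[, cols, drop = FALSE])
  }, numeric(nrow(mat$sites)))
  list(meth = meth, total = total)
}

#' Assemble a methylome matrix from per-sample site tables
#'
#' Takes the union of all sites; samples without coverage at a site get
#' `meth = total = 0`.
#'
#' @param tables Named list of per-sample site tables
#'   (as from [read_site_table()]).
#' @param groups Named character vector sample -> group.
#' @return A `MethylomeMatrix`.
#' @export
methylome_from_tables <- function(tables, groups) {
  stopifnot(length(tables) >= 1, !is.null(names(tables)))
  key_cols <- c("chrom", "pos", "strand", "context")
  scaffold <- unique(data.table::rbindlist(
    lapply(tables, function(t) t[, key_cols, with = FALSE])))
  data.table::setorder(scaffold, chrom, pos, strand)
  n <- nrow(scaffold)
  meth <- matrix(0L, n, length(tables),
                 dimnames = list(NULL, names(tables)))
  total <- meth
  skey <- paste(scaffold$chrom, scaffold$pos, scaffold$strand, sep = "\r")
  for (s in names(tables)) {
    t <- tables[[s]]
    idx <- match(paste(t$chrom, t$pos, t$strand, sep = "\r"), skey)
    meth[idx, s] <- as.integer(t$meth_count)
    total[idx, s] <- as.integer(t$total_count)
  }
  methylome_matrix(scaffold, meth, total, groups)
}

#' Restrict a methylome matrix to chosen sites
#' @param mat A `MethylomeMatrix`.
#' @param idx Logical or integer row index over sites.
#' @return A `MethylomeMatrix` with the selected sites.
#' @export
subset_sites <- function(mat, idx) {
  methylome_matrix(mat$sites[idx], mat$meth[idx, , drop = FALSE],
                   mat$total[idx, , drop = FALSE], mat$groups)
}

# ---- context classification -------------------------------------------------

#' Classify the sequence context of a cytosine
#'
#' Context is read 3'-ward on the site's own strand: `CG` if the next base
#' is G, `CHG` if the base after next is G, `CHH` otherwise (H is A, C or
#' T). On the minus strand the site is a G in the reference and context is
#' read toward lower coordinates on the complement. Positions with fewer
#' than the required downstream bases are classified by truncation: a
#' lone trailing C (or leading G on minus) is `CHH`; a terminal `CG`
#' dinucleotide is still `CG`.
#'
#' @param genome_seq A single contig sequence (character scalar).
#' @param pos Integer vector of 0-based positions.
#' @param strand `"+"` or `"-"` (recycled).
#' @return Character vector: `"CG"`, `"CHG"`, `"CHH"`, or `NA` where the
#'   base at `pos` is not a cytosine on the requested strand.
#' @export
classify_context <- function(genome_seq, pos, strand = "+") {
  n <- nchar(genome_seq)
  stopifnot(all(pos >= 0), all(pos < n))
  strand <- rep_len(strand, length(pos))
  base_at <- function(p) {
    out <- rep(NA_character_, length(p))
    ok <- p >= 0 & p < n
    if (any(ok))
      out[ok] <- substring(genome_seq, p[ok] + 1L, p[ok] + 1L)
    out
  }
  b0 <- base_at(pos)
  out <- rep(NA_character_, length(pos))

  plus <- strand == "+"
  is_c <- plus & b0 == "C"
  b1 <- base_at(pos + 1L)
  b2 <- base_at(pos + 2L)
  out[is_c] <- ifelse(
    !is.na(b1[is_c]) & b1[is_c] == "G", "CG",
    ifelse(!is.na(b2[is_c]) & b2[is_c] == "G", "CHG", "CHH"))

  minus <- strand == "-"
  is_g <- minus & b0 == "G"
  m1 <- base_at(pos - 1L)  # complement G means reference C
  m2 <- base_at(pos - 2L)
  out[is_g] <- ifelse(
    !is.na(m1[is_g]) & m1[is_g] == "C", "CG",
    ifelse(!is.na(m2[is_g]) & m2[is_g] == "C", "CHG", "CHH"))
  out
}

#' Enumerate all cytosine sites of a genome
#'
#' @param genome Named character vector of contig sequences.
#' @param contexts Contexts to keep (default all three).
#' @return `data.table` with `chrom`, `pos` (0-based), `strand`, `context`,
#'   sorted by `(chrom, pos, strand)`.
#' @export
find_cytosines <- function(genome, contexts = c("CG", "CHG", "CHH")) {
  per_contig <- lapply(names(genome), function(chr) {
    b <- strsplit(genome[[chr]], "", fixed = TRUE)[[1]]
    n <- length(b)
    nxt1 <- c(b[-1], NA)
    nxt2 <- c(b[-(1:2)], NA, NA)
    prv1 <- c(NA, b[-n])
    prv2 <- c(NA, NA, b[-((n - 1):n)])

    p_idx <- which(b == "C")
    p_ctx <- ifelse(!is.na(nxt1[p_idx]) & nxt1[p_idx] == "G", "CG",
                    ifelse(!is.na(nxt2[p_idx]) & nxt2[p_idx] == "G",
                           "CHG", "CHH"))
    m_idx <- which(b == "G")
    m_ctx <- ifelse(!is.na(prv1[m_idx]) & prv1[m_idx] == "C", "CG",
                    ifelse(!is.na(prv2[m_idx]) & prv2[m_idx] == "C",
                           "CHG", "CHH"))
    data.table::data.table(
      chrom = chr,
      pos = c(p_idx, m_idx) - 1L,
      strand = rep(c("+", "-"), c(length(p_idx), length(m_idx))),
      context = c(p_ctx, m_ctx)
    )
  })
  dt <- data.table::rbindlist(per_contig)
  dt <- dt[context %in% contexts]
  data.table::setorder(dt, chrom, pos, strand)
  dt[]
}

# ---- conversion rate --------------------------------------------------------

#' Estimate the bisulfite conversion rate from spike-in sites
#'
#' The lambda spike-in is unmethylated, so any read reporting methylation
#' there is a conversion failure. The rate is `1 - sum(meth) / sum(total)`
#' over all spike-in sites.
#'
#' @param meth_count,total_count Integer vectors of per-site counts on the
#'   spike-in contig (all samples may be pooled).
#' @return List with `rate`, `error` (`1 - rate`) and `n_sites`.
#' @export
estimate_conversion <- function(meth_count, total_count) {
  stopifnot(length(meth_count) == length(total_count))
  tt <- sum(as.numeric(total_count))
  if (length(total_count) == 0 || tt == 0)
    stop_mc("conversion rate undefined: no covered spike-in sites")
  rate <- 1 - sum(as.numeric(meth_count)) / tt
  list(rate = rate, error = 1 - rate, n_sites = sum(total_count > 0))
}

#' Conversion estimate from a methylome matrix's spike-in contig
#'
#' Pools all samples' counts on the designated contig.
#'
#' @param mat A `MethylomeMatrix`.
#' @param contig Name of the unmethylated spike-in contig
#'   (default `"lambda"`).
#' @return As [estimate_conversion()].
#' @export
lambda_conversion <- function(mat, contig = "lambda") {
  idx <- mat$sites$chrom == contig
  if (!any(idx))
    stop_mc("no sites on spike-in contig '%s'", contig)
  estimate_conversion(rowSums(mat$meth[idx, , drop = FALSE]),
                      rowSums(mat$total[idx, , drop = FALSE]))
}

# ---- methylation calling ----------------------------------------------------

#' Call methylated cytosines by a binomial test against conversion error
#'
#' For each site, the one-sided binomial tail
#' `P(X >= meth | n = total, p = conversion_error)` asks whether the
#' observed methylated reads exceed what conversion failure alone would
#' produce. P-values are Benjamini-Hochberg corrected over all tested
#' sites (those with `total >= 1`); a site is called when its q-value is
#' below `alpha`.
#'
#' @param meth_count,total_count Integer vectors (one sample's counts).
#' @param conversion_error Per-read false-methylation probability, in
#'   (0, 1).
#' @param alpha Significance level after correction (default 0.05).
#' @return Logical vector; `FALSE` for uncovered sites.
#' @export
call_methylated <- function(meth_count, total_count, conversion_error,
                            alpha = 0.05) {
  stopifnot(conversion_error > 0, conversion_error < 1)
  called <- rep(FALSE, length(meth_count))
  tested <- total_count >= 1
  if (!any(tested)) return(called)
  p <- stats::pbinom(meth_count[tested] - 1, total_count[tested],
                     conversion_error, lower.tail = FALSE)
  q <- bh_adjust(p)
  called[tested] <- q < alpha
  called
}

#' Per-sample methylation-call matrix
#'
#' Applies [call_methylated()] independently to each sample column.
#'
#' @param mat A `MethylomeMatrix`.
#' @param conversion_error Per-read false-methylation probability.
#' @param alpha Significance level (default 0.05).
#' @return Logical matrix, sites x samples.
#' @export
call_matrix <- function(mat, conversion_error, alpha = 0.05) {
  out <- vapply(colnames(mat$meth), function(s) {
    call_methylated(mat$meth[, s], mat$total[, s], conversion_error, alpha)
  }, logical(nrow(mat$sites)))
  colnames(out) <- colnames(mat$meth)
  out
}

# ---- levels -----------------------------------------------------------------

#' Per-site methylation level
#'
#' @param meth_count,total_count Count vectors.
#' @return `meth / total`; `NA` where `total` is 0.
#' @export
site_level <- function(meth_count, total_count) {
  ifelse(total_count > 0, meth_count / total_count, NA_real_)
}

#' Pooled region methylation level
#'
#' Coverage-weighted: the region's level is `sum(meth) / sum(total)` over
#' its sites, not the mean of per-site levels.
#'
#' @param meth_count,total_count Count vectors over the region's sites.
#' @return Pooled fraction; `NA` for an uncovered or empty region.
#' @export
region_level <- function(meth_count, total_count) {
  tt <- sum(as.numeric(total_count))
  if (length(total_count) == 0 || tt == 0) return(NA_real_)
  sum(as.numeric(meth_count)) / tt
}

#' Per-group methylation calls on pooled counts
#'
#' Pools each group's counts across its replicates and applies
#' [call_methylated()]; the standard route for a per-group inventory of
#' methylated cytosines.
#'
#' @param mat A `MethylomeMatrix`.
#' @param conversion_error Per-read false-methylation probability.
#' @param alpha Significance level (default 0.05).
#' @return Logical matrix, sites x groups.
#' @export
call_group_matrix <- function(mat, conversion_error, alpha = 0.05) {
  pc <- pooled_counts(mat)
  out <- vapply(colnames(pc$meth), function(g) {
    call_methylated(pc$meth[, g], pc$total[, g], conversion_error, alpha)
  }, logical(nrow(mat$sites)))
  colnames(out) <- colnames(pc$meth)
  out
}

#' Context proportions of called methylated cytosines per group
#'
#' For each group the fractions of called mCs falling in CG, CHG and CHH
#' context are returned (summing to 1). `calls` may have one column per
#' group (pooled calls, [call_group_matrix()]) or one column per sample
#' ([call_matrix()]); in the latter case a site counts as methylated in a
#' group when called in at least one of its samples.
#'
#' @param mat A `MethylomeMatrix`.
#' @param calls Logical matrix, sites x groups or sites x samples.
#' @return Matrix with one row per group and columns `CG`, `CHG`, `CHH`.
#' @export
mc_proportions <- function(mat, calls) {
  grps <- sort(unique(mat$groups))
  by_group <- setequal(colnames(calls), grps)
  ctx_levels <- c("CG", "CHG", "CHH")
  out <- matrix(NA_real_, length(grps), 3,
                dimnames = list(grps, ctx_levels))
  for (g in grps) {
    grp_called <- if (by_group) calls[, g] else
      rowSums(calls[, group_samples(mat, g), drop = FALSE]) > 0
    if (!any(grp_called))
      stop_mc("no called methylated sites in group '%s'", g)
    tab <- table(factor(mat$sites$context[grp_called], levels = ctx_levels))
    out[g, ] <- as.numeric(tab) / sum(tab)
  }
  out
}
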