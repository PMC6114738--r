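## Independent oracles and small fixture builders shared across tests.

## Brute-force DMR merger: for each chromosome and sign, walk the sorted
## positions and emit every maximal gap-bounded run with enough sites.
## Written as an explicit loop, independent of the vectorised
## implementation under test.
bf_merge <- function(flagged, max_gap = 300, min_sites = 3) {
  rows <- list()
  for (ch in sort(unique(flagged$chrom))) {
    for (sg in c(-1L, 1L)) {
      p <- sort(flagged$pos[flagged$chrom == ch & flagged$sign_dir == sg])
      if (length(p) == 0) next
      run <- p[1]
      flush <- function(run) {
        if (length(run) >= min_sites)
          rows[[length(rows) + 1]] <<- data.frame(
            chrom = ch, start = min(run), end = max(run) + 1L,
            n_sites = length(run), sign_dir = sg)
      }
      if (length(p) > 1) {
        for (x in p[-1]) {
          if (x - run[length(run)] <= max_gap) {
            run <- c(run, x)
          } else {
            flush(run)
            run <- x
          }
        }
      }
      flush(run)
    }
  }
  if (length(rows) == 0)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), n_sites = integer(),
                      sign_dir = integer()))
  out <- do.call(rbind, rows)
  out[order(out$chrom, out$start, out$sign_dir), , drop = FALSE]
}

## Brute-force degree-0 smoother: direct weighted mean per evaluation
## point, expanding the window nearest-first until min_sites are in.
bf_smooth0 <- function(pos, level, wt, eval_pos, half_window, min_sites) {
  vapply(eval_pos, function(c0) {
    inside <- which(abs(pos - c0) <= half_window)
    outside <- setdiff(order(abs(pos - c0)), inside)
    while (length(inside) < min_sites && length(outside) > 0) {
      inside <- c(inside, outside[1])
      outside <- outside[-1]
    }
    if (length(inside) == 0) return(NA_real_)
    band <- max(half_window, max(abs(pos[inside] - c0)) + 1)
    u <- abs(pos[inside] - c0) / band
    w <- wt[inside] * (1 - u^3)^3
    sum(w * level[inside]) / sum(w)
  }, numeric(1))
}

## Small methylome matrix from parallel vectors; counts recycled across
## samples unless given as matrices.
mk_mat <- function(chrom, pos, meth, total, strand = "+", context = "CG",
                   n_rep = 2, groups = c("anagen", "telogen")) {
  n <- length(pos)
  sites <- data.frame(chrom = rep_len(chrom, n), pos = pos,
                      strand = rep_len(strand, n),
                      context = rep_len(context, n))
  samples <- as.vector(t(outer(groups, seq_len(n_rep), paste, sep = "_")))
  gl <- stats::setNames(rep(groups, each = n_rep), samples)
  if (is.matrix(meth)) {
    m <- meth; t <- total
  } else {
    m <- matrix(rep_len(meth, n), n, length(samples))
    t <- matrix(rep_len(total, n), n, length(samples))
  }
  colnames(m) <- colnames(t) <- samples
  methylome_matrix(sites, m, t, gl)
}

## Random valid site table (0-based internal representation).
random_site_table <- function(n, seed) {
  set.seed(seed)
  total <- rpois(n, 15)
  data.table::data.table(
    chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
    pos = sample.int(100000L, n),
    strand = sample(c("+", "-"), n, replace = TRUE),
    context = sample(c("CG", "CHG", "CHH"), n, replace = TRUE),
    meth_count = vapply(total, function(t) sample.int(t + 1L, 1) - 1L,
                        integer(1)),
    total_count = total)
}

## Phred+33 quality string of constant score.
qual_str <- function(score, n) {
  paste(rep(intToUtf8(score + 33L), n), collapse = "")
}
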