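## integrate: DMR-to-gene annotation (DMGs), DEG threshold filtering of an
## expression results table, and the DMG x DEG overlap, plus per-gene
## methylation series for browser-style views.

#' Annotate DMRs with gene and CGI context
#'
#' A gene is hit when the DMR overlaps its promoter or gene span by at
#' least 1 bp. Within a gene the feature class follows the precedence
#' promoter > exon > intron. CGI and shore flags are computed
#' independently of gene hits; DMRs hitting no gene are intergenic.
#'
#' @param dmrs Directed DMR table (from [label_direction()]).
#' @param genes A `gene_models` object.
#' @param cgis `data.table` of CGI intervals.
#' @param promoter_width Promoter width upstream of the TSS in bp
#'   (default 2000); set to 0 to restrict DMG membership to gene spans.
#' @param shore_width Shore width on each side of a CGI (default 2000).
#' @return `data.table` with one row per (DMR, gene hit) — or one row with
#'   `gene_id = NA` for intergenic DMRs — and columns `dmr_id`, `chrom`,
#'   `start`, `end`, `direction`, `gene_id`, `feature`, `in_cgi`,
#'   `in_shore`.
#' @export
annotate_dmrs <- function(dmrs, genes, cgis, promoter_width = 2000L,
                          shore_width = 2000L) {
  if (nrow(dmrs) == 0)
    return(data.table::data.table(dmr_id = integer(), chrom = character(),
                                  start = integer(), end = integer(),
                                  direction = character(),
                                  gene_id = character(), feature = character(),
                                  in_cgi = logical(), in_shore = logical()))
  dmr_gr <- as_granges0(dmrs)

  cgis <- data.table::as.data.table(cgis)
  in_cgi <- rep(FALSE, nrow(dmrs))
  in_shore <- rep(FALSE, nrow(dmrs))
  if (nrow(cgis) > 0) {
    cgi_gr <- as_granges0(cgis)
    in_cgi <- GenomicRanges::countOverlaps(dmr_gr, cgi_gr) > 0
    shores <- data.table::rbindlist(list(
      data.table::data.table(chrom = cgis$chrom,
                             start = pmax(0L, cgis$start -
                                            as.integer(shore_width)),
                             end = cgis$start),
      data.table::data.table(chrom = cgis$chrom, start = cgis$end,
                             end = cgis$end + as.integer(shore_width))
    ))[end > start]
    if (nrow(shores) > 0) {
      shore_gr <- GenomicRanges::setdiff(as_granges0(shores), cgi_gr)
      in_shore <- GenomicRanges::countOverlaps(dmr_gr, shore_gr) > 0
    }
  }

  g <- genes$genes
  prom <- if (promoter_width > 0) promoters_of(genes, promoter_width) else
    g[0, c("gene_id", "chrom", "start", "end", "strand"), with = FALSE]
  gene_gr <- as_granges0(g)
  GenomicRanges::strand(gene_gr) <- "*"
  exon_gr <- as_granges0(genes$exons)
  prom_gr <- if (nrow(prom) > 0) {
    pg <- as_granges0(prom); GenomicRanges::strand(pg) <- "*"; pg
  } else NULL

  span_hits <- GenomicRanges::findOverlaps(dmr_gr, gene_gr)
  hit_dt <- data.table::data.table(
    dmr_row = S4Vectors::queryHits(span_hits),
    gene_id = g$gene_id[S4Vectors::subjectHits(span_hits)])
  if (!is.null(prom_gr)) {
    prom_hits <- GenomicRanges::findOverlaps(dmr_gr, prom_gr)
    hit_dt <- unique(data.table::rbindlist(list(
      hit_dt,
      data.table::data.table(
        dmr_row = S4Vectors::queryHits(prom_hits),
        gene_id = prom$gene_id[S4Vectors::subjectHits(prom_hits)]))))
  }

  classify_hit <- function(dmr_row, gid) {
    dr <- dmr_gr[dmr_row]
    if (!is.null(prom_gr)) {
      pi <- which(prom$gene_id == gid)
      if (length(pi) > 0 &&
          GenomicRanges::countOverlaps(dr, prom_gr[pi]) > 0)
        return("promoter")
    }
    ei <- which(genes$exons$gene_id == gid)
    if (length(ei) > 0 && GenomicRanges::countOverlaps(dr, exon_gr[ei]) > 0)
      return("exon")
    "intron"
  }

  rows <- lapply(seq_len(nrow(dmrs)), function(i) {
    hits <- hit_dt[hit_dt$dmr_row == i, ]
    base <- data.table::data.table(
      dmr_id = dmrs$dmr_id[i], chrom = dmrs$chrom[i], start = dmrs$start[i],
      end = dmrs$end[i], direction = dmrs$direction[i],
      in_cgi = in_cgi[i], in_shore = in_shore[i])
    if (nrow(hits) == 0) {
      base$gene_id <- NA_character_
      base$feature <- "intergenic"
      return(base)
    }
    out <- base[rep(1, nrow(hits))]
    out$gene_id <- hits$gene_id
    out$feature <- vapply(hits$gene_id, function(gid) classify_hit(i, gid),
                          character(1))
    out
  })
  out <- data.table::rbindlist(rows, use.names = TRUE, fill = TRUE)
  data.table::setorder(out, dmr_id, gene_id, na.last = TRUE)
  out[, c("dmr_id", "chrom", "start", "end", "direction", "gene_id",
          "feature", "in_cgi", "in_shore"), with = FALSE]
}

#' Build hyper- and hypo-DMG sets from annotated DMRs
#'
#' A gene is a hyper DMG if supported by at least one hyper DMR and a hypo
#' DMG if supported by at least one hypo DMR; genes supported by both
#' appear in both sets and are reported as ambivalent.
#'
#' @param annotated Output of [annotate_dmrs()].
#' @return List with character vectors `hyper`, `hypo` and `ambivalent`.
#' @export
build_dmg_sets <- function(annotated) {
  hit <- annotated[!is.na(annotated$gene_id), ]
  hyper <- sort(unique(hit$gene_id[hit$direction == "hyper"]))
  hypo <- sort(unique(hit$gene_id[hit$direction == "hypo"]))
  list(hyper = hyper, hypo = hypo, ambivalent = intersect(hyper, hypo))
}

#' Filter an expression table into DEG sets
#'
#' A gene is differentially expressed when `q_value <= max_q` and
#' `|log_fc| > min_abs_lfc` (boundary q kept, boundary fold change
#' dropped). Records with missing q-values are skipped and counted.
#'
#' @param expr `data.table` with `gene_id`, `log_fc`, `q_value`; positive
#'   `log_fc` means higher expression in the second (telogen) group.
#' @param max_q Q-value ceiling (default 0.05, inclusive).
#' @param min_abs_lfc Absolute log fold-change floor (default 1,
#'   exclusive).
#' @return List with character vectors `up`, `down`, the filtered table
#'   `degs`, and `n_missing_q`.
#' @export
filter_degs <- function(expr, max_q = 0.05, min_abs_lfc = 1) {
  expr <- data.table::as.data.table(expr)
  miss <- is.na(expr$q_value)
  ok <- !miss & expr$q_value <= max_q & abs(expr$log_fc) > min_abs_lfc
  kept <- expr[ok, ]
  list(up = sort(kept$gene_id[kept$log_fc > 0]),
       down = sort(kept$gene_id[kept$log_fc < 0]),
       degs = kept[],
       n_missing_q = sum(miss))
}

#' Overlap DMG and DEG gene sets
#'
#' @param dmgs Output of [build_dmg_sets()].
#' @param degs Output of [filter_degs()].
#' @return `data.table` with one row per overlapping gene: `gene_id`,
#'   `meth_direction` (`hyper`/`hypo`/`ambivalent`), `expr_sign`
#'   (`up`/`down`) and `concordant` (hypermethylation with
#'   down-regulation, or hypomethylation with up-regulation).
#' @export
overlap_dmg_deg <- function(dmgs, degs) {
  dmg_all <- union(dmgs$hyper, dmgs$hypo)
  deg_all <- union(degs$up, degs$down)
  genes <- sort(intersect(dmg_all, deg_all))
  meth_dir <- ifelse(genes %in% dmgs$ambivalent, "ambivalent",
                     ifelse(genes %in% dmgs$hyper, "hyper", "hypo"))
  expr_sign <- ifelse(genes %in% degs$up, "up", "down")
  data.table::data.table(
    gene_id = genes, meth_direction = meth_dir, expr_sign = expr_sign,
    concordant = (meth_dir == "hyper" & expr_sign == "down") |
      (meth_dir == "hypo" & expr_sign == "up"))
}

#' Per-position group methylation levels across one gene
#'
#' Extracts the pooled per-group levels at every covered site within the
#' gene span plus `flank` bp on each side, in genomic orientation (not
#' strand-flipped), as in a genome-browser view.
#'
#' @param gene_id Gene identifier.
#' @param genes A `gene_models` object.
#' @param mat A `MethylomeMatrix`.
#' @param flank Flank in bp on each side (default 2000).
#' @param min_cov Minimum pooled group coverage per site (default 4).
#' @param group_a,group_b Group labels (defaults `"anagen"`, `"telogen"`).
#' @return `data.table` with `pos`, `context`, and one level column per
#'   group; empty (with a warning) for genes without covered sites.
#' @export
gene_meth_profile <- function(gene_id, genes, mat, flank = 2000L,
                              min_cov = 4L, group_a = "anagen",
                              group_b = "telogen") {
  sel <- which(genes$genes$gene_id == gene_id)
  g <- genes$genes[sel, ]
  if (nrow(g) != 1) stop_mc("unknown gene '%s'", gene_id)
  s <- max(0L, g$start - as.integer(flank))
  e <- g$end + as.integer(flank)
  idx <- which(mat$sites$chrom == g$chrom & mat$sites$pos >= s &
                 mat$sites$pos < e)
  ma <- rowSums(mat$meth[idx, group_samples(mat, group_a), drop = FALSE])
  ta <- rowSums(mat$total[idx, group_samples(mat, group_a), drop = FALSE])
  mb <- rowSums(mat$meth[idx, group_samples(mat, group_b), drop = FALSE])
  tb <- rowSums(mat$total[idx, group_samples(mat, group_b), drop = FALSE])
  keep <- ta >= min_cov & tb >= min_cov
  out <- data.table::data.table(
    pos = mat$sites$pos[idx][keep],
    context = mat$sites$context[idx][keep],
    a = ma[keep] / ta[keep], b = mb[keep] / tb[keep])
  data.table::setnames(out, c("a", "b"), c(group_a, group_b))
  if (nrow(out) == 0)
    warning(sprintf("gene '%s' has no adequately covered sites", gene_id))
  data.table::setorder(out, pos)
  out[]
}
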