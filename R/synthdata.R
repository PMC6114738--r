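## synthdata: seeded generator of every input the pipeline consumes, with
## recorded ground truth. It emulates the structure of a two-stage skin
## WGBS experiment: 3 replicates per group, CG-dominated methylation that
## is high in gene bodies and low at promoters/CGIs, a dip around
## transcription start sites, low CHG/CHH methylation slightly elevated at
## CGIs and shores, a small global CG hypermethylation offset in telogen,
## planted DMRs of known location/effect, an unmethylated lambda spike-in
## contig, and an expression table with planted DEGs.

#' Simulation configuration
#'
#' Defaults describe the study conditions every preset starts from. All
#' levels are methylation fractions in `[0, 1]`; expected site levels are
#' clamped into that range after all effects are added.
#'
#' @param seed Integer seed; fully determines all outputs.
#' @param chrom_lengths Named vector of autosome-like contig lengths
#'   (default two 1 Mb contigs).
#' @param lambda_length Length of the unmethylated spike-in contig
#'   (default 48502, the lambda phage genome size).
#' @param lambda_name Spike-in contig name (default `"lambda"`).
#' @param gc_content Background GC fraction (default 0.42).
#' @param cpg_depletion Probability that a background CpG dinucleotide is
#'   disrupted, producing realistic CpG o/e below 1 outside islands
#'   (default 0.75).
#' @param n_cgi CGIs per contig (default 15); `cgi_length` gives the
#'   min/max island length; `cgi_gc` the island GC fraction.
#' @param n_genes Genes per contig (default 40); `gene_length` min/max
#'   span; `exon_range` min/max exon count per gene.
#' @param cg_body,cg_promoter,cg_cgi Baseline CG methylation in gene
#'   bodies / background (0.75), promoters (0.15) and CGIs (0.15).
#' @param chg_level,chh_level Baseline CHG (0.02) and CHH (0.01) levels.
#' @param shore_elevation Added CHG/CHH methylation within a CGI or its
#'   2 kb shores (default 0.03).
#' @param tss_dip_depth,tss_dip_width Depth (0.10) and half-width in bp
#'   (400) of the V-shaped methylation dip centred on each TSS.
#' @param telogen_offset Global CG offset added to the telogen group
#'   (default +0.03).
#' @param n_dmrs Planted DMR count (default 10); `dmr_width` min/max width
#'   in bp; `dmr_delta` the between-group difference; directions alternate
#'   hyper/hypo. The effect is split symmetrically (anagen
#'   `-delta/2`, telogen `+delta/2`) so expected levels stay inside
#'   `[0, 1]` at any local baseline.
#' @param n_deg Planted DEG count (default 15); `n_deg_dmr_overlap` of
#'   them (default 5) are genes that also host a planted DMR, exercising
#'   the DMG x DEG overlap.
#' @param depth,nb_size Mean sequencing depth per site (20) and negative
#'   binomial size parameter controlling overdispersion (10).
#' @param wobble_conc Concentration of the beta-distributed replicate
#'   wobble around each expected level (default 200; larger = less
#'   biological replicate variance).
#' @param n_rep Replicates per group (default 3).
#' @param conversion_error True bisulfite conversion failure rate
#'   (default 0.005).
#' @param contexts Cytosine contexts simulated on the autosome-like
#'   contigs (the spike-in always carries all contexts).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       chrom_lengths = c(chr1 = 1000000L, chr2 = 1000000L),
                       lambda_length = 48502L, lambda_name = "lambda",
                       gc_content = 0.42, cpg_depletion = 0.75,
                       n_cgi = 15L, cgi_length = c(500L, 2000L),
                       cgi_gc = 0.60,
                       n_genes = 40L, gene_length = c(2000L, 10000L),
                       exon_range = c(2L, 5L),
                       cg_body = 0.75, cg_promoter = 0.15, cg_cgi = 0.15,
                       chg_level = 0.02, chh_level = 0.01,
                       shore_elevation = 0.03,
                       tss_dip_depth = 0.10, tss_dip_width = 400L,
                       telogen_offset = 0.03,
                       n_dmrs = 10L, dmr_width = c(1000L, 3000L),
                       dmr_delta = 0.3,
                       n_deg = 15L, n_deg_dmr_overlap = 5L,
                       depth = 20, nb_size = 10,
                       wobble_conc = 200, n_rep = 3L,
                       conversion_error = 0.005,
                       contexts = c("CG", "CHG", "CHH")) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_deg_dmr_overlap <= cfg$n_deg,
            cfg$n_deg_dmr_overlap <= cfg$n_dmrs || cfg$n_dmrs == 0,
            cfg$dmr_delta >= 0, cfg$depth > 0)
  class(cfg) <- "sim_config"
  cfg
}

#' Preset simulation configurations
#'
#' * `small` — two 300 kb contigs, all contexts, 6 planted DMRs; quick
#'   structural checks.
#' * `null` — one 1 Mb contig, CG context, no telogen offset, no planted
#'   DMRs: both groups share identical generative parameters.
#' * `recovery` — two 1 Mb contigs, CG context, 50 planted DMRs
#'   (1-3 kb, delta 0.3, mixed directions), 5 of them in genes that are
#'   also planted DEGs.
#'
#' @param preset One of `"small"`, `"null"`, `"recovery"`.
#' @param seed Integer seed.
#' @return A `sim_config`.
#' @export
preset_config <- function(preset = c("small", "null", "recovery"),
                          seed = 1L) {
  preset <- match.arg(preset)
  switch(preset,
    small = sim_config(
      seed = seed, chrom_lengths = c(chr1 = 300000L, chr2 = 300000L),
      n_cgi = 8L, n_genes = 15L, n_dmrs = 6L, n_deg = 10L,
      n_deg_dmr_overlap = 3L),
    null = sim_config(
      seed = seed, chrom_lengths = c(chr1 = 1000000L),
      telogen_offset = 0, n_dmrs = 0L, n_deg = 0L, n_deg_dmr_overlap = 0L,
      contexts = "CG"),
    recovery = sim_config(
      seed = seed, chrom_lengths = c(chr1 = 1000000L, chr2 = 1000000L),
      n_dmrs = 50L, n_deg = 15L, n_deg_dmr_overlap = 5L,
      contexts = "CG"))
}

## Place n non-overlapping intervals on one contig, keeping min_gap bp
## from each other and from every `forbidden` interval. Errors when the
## configuration cannot be placed.
place_intervals <- function(n, len_range, chrom_len, forbidden = NULL,
                            min_gap = 0L, max_tries = 5000L) {
  placed <- data.table::data.table(start = integer(0), end = integer(0))
  if (n == 0) return(placed)
  clashes <- function(s, e) {
    blk <- rbind(placed,
                 if (!is.null(forbidden) && nrow(forbidden) > 0)
                   forbidden[, c("start", "end"), with = FALSE])
    if (is.null(blk) || nrow(blk) == 0) return(FALSE)
    any(s - min_gap < blk$end & e + min_gap > blk$start)
  }
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      w <- sample(len_range[1]:len_range[2], 1)
      if (chrom_len <= w + 2L) break
      s <- sample.int(chrom_len - w - 1L, 1)
      if (!clashes(s, s + w)) {
        placed <- rbind(placed,
                        data.table::data.table(start = s, end = s + w))
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stop_mc("could not place %d interval(s) of %d-%d bp on a %d bp contig",
              n, len_range[1], len_range[2], chrom_len)
  }
  data.table::setorder(placed, start)
  placed[]
}

## Random sequence as a character vector of bases.
random_bases <- function(n, gc) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

#' Generate a synthetic genome with annotations and planted truth
#'
#' Builds contig sequences (CpG-depleted background, CpG-rich islands),
#' non-overlapping gene models with exons, CGI and repeat intervals, an
#' unmethylated spike-in contig, and the planted-DMR truth table. Half of
#' the CGIs are anchored at gene TSSs, the rest placed freely.
#'
#' @param config A `sim_config`.
#' @return List with `genome` (named character vector), `genes`
#'   (`gene_models`), `cgis`, `repeats` (interval tables) and `truth`
#'   (list with `dmrs`, `conversion_error`, `config`).
#' @export
make_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  if (any(config$gene_length[2] >= config$chrom_lengths))
    stop_mc("gene_length exceeds a chromosome length")

  genes_l <- list(); exons_l <- list(); cgis_l <- list(); reps_l <- list()
  dmrs_l <- list(); genome <- character(0)
  dir_cycle <- c("hyper", "hypo")
  n_chrom <- length(config$chrom_lengths)
  dmr_per_chrom <- diff(round(seq(0, config$n_dmrs, length.out = n_chrom + 1)))
  overlap_per_chrom <- diff(round(seq(0, config$n_deg_dmr_overlap,
                                      length.out = n_chrom + 1)))
  dmr_idx <- 0L

  for (ci in seq_along(config$chrom_lengths)) {
    chr <- names(config$chrom_lengths)[ci]
    len <- as.integer(config$chrom_lengths[[ci]])

    ## gene spans, separated enough that promoters and flanks stay clear
    gsp <- place_intervals(config$n_genes, config$gene_length, len,
                           min_gap = 2500L)
    gsp$gene_id <- sprintf("%s_g%03d", chr, seq_len(nrow(gsp)))
    gsp$strand <- sample(c("+", "-"), nrow(gsp), replace = TRUE)

    ## CGIs: half at TSSs, half free
    n_tss_cgi <- min(nrow(gsp), config$n_cgi %/% 2L)
    tss_pick <- if (n_tss_cgi > 0)
      sample(seq_len(nrow(gsp)), n_tss_cgi) else integer(0)
    cgi_tss <- data.table::rbindlist(c(
      list(data.table::data.table(start = integer(), end = integer())),
      lapply(tss_pick, function(i) {
        w <- sample(config$cgi_length[1]:config$cgi_length[2], 1)
        tss <- if (gsp$strand[i] == "-") gsp$end[i] - 1L else gsp$start[i]
        s <- max(0L, tss - w %/% 2L)
        data.table::data.table(start = s, end = min(len, s + w))
      })))
    cgi_free <- place_intervals(config$n_cgi - n_tss_cgi, config$cgi_length,
                                len, forbidden = cgi_tss, min_gap = 3000L)
    cgi <- rbind(cgi_tss, cgi_free)
    data.table::setorder(cgi, start)

    ## sequence: background, then island composition, then background
    ## CpG depletion
    b <- random_bases(len, config$gc_content)
    cgi_mask <- rep(FALSE, len)
    for (i in seq_len(nrow(cgi))) {
      span <- (cgi$start[i] + 1L):cgi$end[i]
      b[span] <- random_bases(length(span), config$cgi_gc)
      cgi_mask[span] <- TRUE
    }
    is_cg <- b[-len] == "C" & b[-1] == "G" & !cgi_mask[-len]
    hit <- which(is_cg)
    hit <- hit[stats::runif(length(hit)) < config$cpg_depletion]
    if (length(hit) > 0)
      b[hit + 1L] <- sample(c("A", "T"), length(hit), replace = TRUE)
    genome[chr] <- paste(b, collapse = "")

    ## exons: alternate exon/intron segments spanning the gene
    for (i in seq_len(nrow(gsp))) {
      k <- sample(config$exon_range[1]:config$exon_range[2], 1)
      n_seg <- 2L * k - 1L
      w <- stats::runif(n_seg, 0.5, 1.5)
      bounds <- gsp$start[i] +
        round(cumsum(w) / sum(w) * (gsp$end[i] - gsp$start[i]))
      bounds <- c(gsp$start[i], bounds)
      bounds[length(bounds)] <- gsp$end[i]
      seg_s <- bounds[-length(bounds)]; seg_e <- bounds[-1]
      ex <- seq(1, n_seg, by = 2)
      keep <- seg_e[ex] > seg_s[ex]
      exons_l[[length(exons_l) + 1]] <- data.table::data.table(
        gene_id = gsp$gene_id[i], chrom = chr,
        start = seg_s[ex][keep], end = seg_e[ex][keep])
    }
    genes_l[[length(genes_l) + 1]] <- data.table::data.table(
      gene_id = gsp$gene_id, chrom = chr, start = gsp$start, end = gsp$end,
      strand = gsp$strand)
    cgis_l[[length(cgis_l) + 1]] <- data.table::data.table(
      chrom = chr, start = cgi$start, end = cgi$end, strand = ".",
      label = "CGI")
    rp <- place_intervals(30L, c(200L, 2000L), len)
    reps_l[[length(reps_l) + 1]] <- data.table::data.table(
      chrom = chr, start = rp$start, end = rp$end, strand = ".",
      label = "repeat")

    ## planted DMRs: some inside host genes (future DEG overlap), the
    ## rest intergenic, far from genes and from each other
    n_d <- dmr_per_chrom[ci]
    n_ov <- overlap_per_chrom[ci]
    if (n_d > 0) {
      host_ok <- which(gsp$end - gsp$start >= config$dmr_width[1] + 400L)
      if (n_ov > length(host_ok))
        stop_mc("not enough long genes to host overlap DMRs on %s", chr)
      hosts <- if (n_ov > 0) sample(host_ok, n_ov) else integer(0)
      d_host <- data.table::rbindlist(c(
        list(data.table::data.table(start = integer(), end = integer(),
                                    gene_id = character())),
        lapply(hosts, function(i) {
        w <- sample(config$dmr_width[1]:
                      min(config$dmr_width[2], gsp$end[i] - gsp$start[i] -
                            400L), 1)
        s <- gsp$start[i] + 200L +
          sample.int(gsp$end[i] - gsp$start[i] - w - 400L + 1L, 1) - 1L
        data.table::data.table(start = s, end = s + w,
                               gene_id = gsp$gene_id[i])
      })))
      forb <- rbind(
        gsp[, c("start", "end"), with = FALSE],
        if (nrow(d_host) > 0) d_host[, c("start", "end"), with = FALSE])
      d_free <- place_intervals(n_d - n_ov, config$dmr_width, len,
                                forbidden = forb, min_gap = 2500L)
      d_free$gene_id <- rep(NA_character_, nrow(d_free))
      dd <- rbind(d_host, d_free)
      data.table::setorder(dd, start)
      dd$chrom <- chr
      dd$delta <- config$dmr_delta
      dd$direction <- dir_cycle[(dmr_idx + seq_len(nrow(dd)) - 1L) %% 2L + 1L]
      dmr_idx <- dmr_idx + nrow(dd)
      dmrs_l[[length(dmrs_l) + 1]] <- dd
    }
  }

  genome[config$lambda_name] <- paste(
    random_bases(as.integer(config$lambda_length), 0.50), collapse = "")

  truth_dmrs <- if (length(dmrs_l) > 0) {
    data.table::rbindlist(dmrs_l)[, c("chrom", "start", "end", "delta",
                                      "direction", "gene_id"), with = FALSE]
  } else {
    data.table::data.table(chrom = character(), start = integer(),
                           end = integer(), delta = numeric(),
                           direction = character(), gene_id = character())
  }
  empty_genes <- data.table::data.table(
    gene_id = character(), chrom = character(), start = integer(),
    end = integer(), strand = character())
  empty_exons <- data.table::data.table(
    gene_id = character(), chrom = character(), start = integer(),
    end = integer())
  gm <- gene_models(data.table::rbindlist(c(list(empty_genes), genes_l)),
                    data.table::rbindlist(c(list(empty_exons), exons_l)))

  ## planted DMRs must each contain enough CG sites to be callable
  if (nrow(truth_dmrs) > 0) {
    cg <- find_cytosines(genome[names(config$chrom_lengths)], "CG")
    for (i in seq_len(nrow(truth_dmrs))) {
      n_cg <- sum(cg$chrom == truth_dmrs$chrom[i] &
                    cg$pos >= truth_dmrs$start[i] &
                    cg$pos < truth_dmrs$end[i])
      if (n_cg < 3)
        stop_mc("planted DMR %s:%d-%d contains only %d CG sites",
                truth_dmrs$chrom[i], truth_dmrs$start[i],
                truth_dmrs$end[i], n_cg)
    }
  }

  list(genome = genome, genes = gm,
       cgis = data.table::rbindlist(cgis_l),
       repeats = data.table::rbindlist(reps_l),
       truth = list(dmrs = truth_dmrs,
                    conversion_error = config$conversion_error,
                    config = config))
}

## Expected methylation level per site per group, before noise.
expected_levels <- function(gen, sites, config) {
  n <- nrow(sites)
  base <- numeric(n)
  is_cg <- sites$context == "CG"
  base[is_cg] <- config$cg_body
  base[sites$context == "CHG"] <- config$chg_level
  base[sites$context == "CHH"] <- config$chh_level

  in_any <- function(intervals) {
    hit <- rep(FALSE, n)
    if (nrow(intervals) == 0) return(hit)
    gr <- GenomicRanges::GRanges(sites$chrom,
                                 IRanges::IRanges(sites$pos + 1L,
                                                  sites$pos + 1L))
    hit <- GenomicRanges::countOverlaps(gr, as_granges0(intervals)) > 0
    hit
  }

  proms <- promoters_of(gen$genes, 2000L)
  in_prom <- in_any(proms)
  base[is_cg & in_prom] <- pmin(base[is_cg & in_prom], config$cg_promoter)
  in_cgi <- in_any(gen$cgis)
  base[is_cg & in_cgi] <- pmin(base[is_cg & in_cgi], config$cg_cgi)

  ## V-shaped dip centred on each TSS
  tss <- tss_of(gen$genes)
  for (i in seq_len(nrow(tss))) {
    idx <- which(sites$chrom == tss$chrom[i] &
                   abs(sites$pos - tss$tss[i]) <= config$tss_dip_width)
    if (length(idx) == 0) next
    frac <- 1 - abs(sites$pos[idx] - tss$tss[i]) / config$tss_dip_width
    base[idx] <- pmax(0, base[idx] - config$tss_dip_depth * frac)
  }

  ## CHG/CHH elevation at islands and shores
  shores <- data.table::rbindlist(list(
    gen$cgis[, .(chrom, start = pmax(0L, start - 2000L), end = end + 2000L)]))
  in_shore_or_cgi <- in_any(shores)
  non_cg <- !is_cg & in_shore_or_cgi
  base[non_cg] <- base[non_cg] + config$shore_elevation

  lev_a <- base
  lev_b <- base
  lev_b[is_cg] <- lev_b[is_cg] + config$telogen_offset

  td <- gen$truth$dmrs
  for (i in seq_len(nrow(td))) {
    idx <- which(is_cg & sites$chrom == td$chrom[i] &
                   sites$pos >= td$start[i] & sites$pos < td$end[i])
    if (length(idx) == 0) next
    half <- td$delta[i] / 2
    if (td$direction[i] == "hyper") {
      lev_a[idx] <- lev_a[idx] - half; lev_b[idx] <- lev_b[idx] + half
    } else {
      lev_a[idx] <- lev_a[idx] + half; lev_b[idx] <- lev_b[idx] - half
    }
  }
  list(anagen = clamp01(lev_a), telogen = clamp01(lev_b))
}

#' Simulate per-sample methylation count tables
#'
#' Builds the cytosine scaffold from the generated genome, computes each
#' site's expected level per group (context baselines, promoter/CGI
#' hypomethylation, TSS dip, shore CHG/CHH elevation, telogen offset,
#' planted DMR effects, clamped to `[0, 1]`), then draws per sample:
#' coverage from a negative binomial, a beta-distributed replicate wobble
#' around the expected level, and methylated reads from a binomial whose
#' success probability adds the conversion error on the unmethylated
#' fraction. The spike-in contig is unmethylated by construction.
#'
#' @param gen Output of [make_genome()].
#' @param config The same `sim_config`.
#' @return List with `mat` (a `MethylomeMatrix`), and `truth_levels`
#'   (site table with the noise-free expected level per group).
#' @export
simulate_methylome <- function(gen, config) {
  set.seed(config$seed + 1L)
  main <- gen$genome[setdiff(names(gen$genome), config$lambda_name)]
  sites <- rbind(find_cytosines(main, config$contexts),
                 find_cytosines(gen$genome[config$lambda_name]))
  data.table::setorder(sites, chrom, pos, strand)

  lev <- expected_levels(gen, sites, config)
  is_lambda <- sites$chrom == config$lambda_name
  lev$anagen[is_lambda] <- 0
  lev$telogen[is_lambda] <- 0

  n <- nrow(sites)
  samples <- c(sprintf("anagen_%d", seq_len(config$n_rep)),
               sprintf("telogen_%d", seq_len(config$n_rep)))
  groups <- stats::setNames(rep(c("anagen", "telogen"),
                                each = config$n_rep), samples)
  meth <- matrix(0L, n, length(samples), dimnames = list(NULL, samples))
  total <- meth
  for (s in samples) {
    p <- if (groups[[s]] == "anagen") lev$anagen else lev$telogen
    cov <- stats::rnbinom(n, mu = config$depth, size = config$nb_size)
    inner <- p > 0 & p < 1
    p_rep <- p
    p_rep[inner] <- stats::rbeta(sum(inner),
                                 p[inner] * config$wobble_conc,
                                 (1 - p[inner]) * config$wobble_conc)
    p_obs <- p_rep + (1 - p_rep) * config$conversion_error
    meth[, s] <- as.integer(stats::rbinom(n, cov, p_obs))
    total[, s] <- as.integer(cov)
  }
  truth_levels <- data.table::data.table(
    sites, anagen = lev$anagen, telogen = lev$telogen)
  list(mat = methylome_matrix(sites, meth, total, groups),
       truth_levels = truth_levels)
}

#' Simulate a differential-expression results table
#'
#' Genes hosting a planted DMR (the designated overlap genes) and a
#' further `n_deg - n_deg_dmr_overlap` DMR-free genes are planted as DEGs
#' (`|log_fc| > 1`, `q <= 0.05`); every other gene receives null noise
#' (`log_fc ~ N(0, 0.3)`, `q` uniform above 0.05).
#'
#' @param gen Output of [make_genome()].
#' @param config The same `sim_config`.
#' @return List with `expr` (gene_id, log_fc, q_value) and `truth_degs`
#'   (planted DEG table with an `overlaps_dmr` flag).
#' @export
simulate_expression <- function(gen, config) {
  set.seed(config$seed + 2L)
  ids <- gen$genes$genes$gene_id
  if (config$n_deg > length(ids))
    stop_mc("more planted DEGs (%d) than genes (%d)", config$n_deg,
            length(ids))
  host_genes <- stats::na.omit(gen$truth$dmrs$gene_id)

  ## genes touched by any planted DMR (span or promoter) are ineligible
  ## as DMR-free DEGs
  touched <- character(0)
  if (nrow(gen$truth$dmrs) > 0) {
    dmr_gr <- as_granges0(gen$truth$dmrs)
    g <- gen$genes$genes
    span_gr <- as_granges0(g); GenomicRanges::strand(span_gr) <- "*"
    prom <- promoters_of(gen$genes, 2000L)
    prom_gr <- as_granges0(prom); GenomicRanges::strand(prom_gr) <- "*"
    touched <- union(
      g$gene_id[unique(S4Vectors::subjectHits(
        GenomicRanges::findOverlaps(dmr_gr, span_gr)))],
      prom$gene_id[unique(S4Vectors::subjectHits(
        GenomicRanges::findOverlaps(dmr_gr, prom_gr)))])
  }
  free <- setdiff(ids, touched)
  n_extra <- config$n_deg - length(host_genes)
  if (n_extra > length(free))
    stop_mc("not enough DMR-free genes for %d planted DEGs", n_extra)
  extra <- if (n_extra > 0) sample(free, n_extra) else character(0)
  deg_ids <- c(host_genes, extra)

  expr <- data.table::data.table(
    gene_id = ids,
    log_fc = stats::rnorm(length(ids), 0, 0.3),
    q_value = stats::runif(length(ids), 0.051, 1))
  planted <- match(deg_ids, ids)
  expr$log_fc[planted] <- sample(c(-1, 1), length(planted), replace = TRUE) *
    stats::runif(length(planted), 1.5, 3)
  expr$q_value[planted] <- stats::runif(length(planted), 0.001, 0.049)

  list(expr = expr[],
       truth_degs = data.table::data.table(
         gene_id = deg_ids,
         log_fc = expr$log_fc[planted],
         q_value = expr$q_value[planted],
         overlaps_dmr = deg_ids %in% host_genes))
}

#' Simulate a complete dataset
#'
#' Runs [make_genome()], [simulate_methylome()] and
#' [simulate_expression()] under one configuration.
#'
#' @param config A `sim_config` (or preset name via [preset_config()]).
#' @return List with `genome`, `genes`, `cgis`, `repeats`, `mat`,
#'   `truth_levels`, `expr` and `truth` (dmrs, degs, conversion error,
#'   config).
#' @export
simulate_dataset <- function(config) {
  gen <- make_genome(config)
  methy <- simulate_methylome(gen, config)
  exprs <- simulate_expression(gen, config)
  gen$truth$degs <- exprs$truth_degs
  list(genome = gen$genome, genes = gen$genes, cgis = gen$cgis,
       repeats = gen$repeats, mat = methy$mat,
       truth_levels = methy$truth_levels, expr = exprs$expr,
       truth = gen$truth)
}

#' Write a simulated dataset to disk
#'
#' Emits the full input bundle: genome FASTA, gene GTF, CGI and repeat
#' BEDs, one site table per sample, the expression TSV and a truth JSON.
#'
#' @param sim Output of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_sim_bundle <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genome_fasta(sim$genome, file.path(dir, "genome.fa"))
  write_gene_models(sim$genes, file.path(dir, "genes.gtf"))
  write_intervals(sim$cgis, file.path(dir, "cgi.bed"))
  write_intervals(sim$repeats, file.path(dir, "repeats.bed"))
  for (s in colnames(sim$mat$meth)) {
    st <- data.table::data.table(sim$mat$sites,
                                 meth_count = sim$mat$meth[, s],
                                 total_count = sim$mat$total[, s])
    write_site_table(st, file.path(dir, sprintf("%s.sites.tsv", s)))
  }
  write_expression_table(sim$expr, file.path(dir, "expression.tsv"))
  jsonlite::write_json(
    list(dmrs = sim$truth$dmrs, degs = sim$truth$degs,
         conversion_error = sim$truth$conversion_error),
    file.path(dir, "truth.json"), dataframe = "rows", na = "null",
    auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Score recovery of planted DMRs
#'
#' @param dmrs Called DMR table (with `direction`).
#' @param truth_dmrs Planted truth table from the generator.
#' @return List with `sensitivity` (fraction of planted DMRs overlapped by
#'   at least one call), `precision_bases` (fraction of called bases lying
#'   inside planted DMRs), `direction_agreement` (fraction of recovered
#'   planted DMRs whose overlapping calls all carry the planted
#'   direction), `n_called`, `n_truth`.
#' @export
score_recovery <- function(dmrs, truth_dmrs) {
  n_truth <- nrow(truth_dmrs)
  n_called <- nrow(dmrs)
  if (n_truth == 0 || n_called == 0) {
    return(list(sensitivity = if (n_truth == 0) NA_real_ else 0,
                precision_bases = if (n_called == 0) NA_real_ else 0,
                direction_agreement = NA_real_,
                n_called = n_called, n_truth = n_truth))
  }
  call_gr <- as_granges0(dmrs)
  truth_gr <- as_granges0(truth_dmrs)
  hits <- GenomicRanges::findOverlaps(truth_gr, call_gr)
  recovered <- unique(S4Vectors::queryHits(hits))
  sens <- length(recovered) / n_truth

  inter <- sum(IRanges::width(GenomicRanges::intersect(
    GenomicRanges::reduce(call_gr), GenomicRanges::reduce(truth_gr))))
  prec <- inter / sum(IRanges::width(GenomicRanges::reduce(call_gr)))

  agree <- vapply(recovered, function(ti) {
    calls <- S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == ti]
    all(dmrs$direction[calls] == truth_dmrs$direction[ti])
  }, logical(1))
  list(sensitivity = sens, precision_bases = prec,
       direction_agreement = if (length(agree) > 0) mean(agree) else
         NA_real_,
       n_called = n_called, n_truth = n_truth)
}
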