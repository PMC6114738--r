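## io_formats: readers/writers for every external format the pipeline
## touches, plus the read-level QC rules applied before alignment.
##
## Conventions: in memory every coordinate is 0-based half-open [start,end).
## Site tables and GTF are 1-based on disk, BED is 0-based half-open, so the
## readers/writers shift at the boundary and nowhere else.

# ---- FASTA ------------------------------------------------------------------

#' Read a genome FASTA into a named character vector
#'
#' @param path Path to a FASTA file.
#' @return Named character vector, one element per contig (names are the
#'   first whitespace-delimited token of each header).
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  names(ss) <- sub("\\s.*$", "", names(ss))
  stats::setNames(as.character(ss), names(ss))
}

#' Write a named character vector of contigs as FASTA
#'
#' @param genome Named character vector of contig sequences.
#' @param path Output path.
#' @export
write_genome_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

# ---- FASTQ and read-level QC ------------------------------------------------

#' Read a FASTQ file into a reads table
#'
#' @param path Path to an (uncompressed or gzipped) FASTQ file.
#' @return `data.table` with columns `id`, `seq`, `qual` (Phred+33 encoded
#'   quality string).
#' @export
read_fastq <- function(path) {
  ss <- Biostrings::readDNAStringSet(path, format = "fastq",
                                     with.qualities = TRUE)
  data.table::data.table(
    id = sub("\\s.*$", "", names(ss)),
    seq = as.character(ss),
    qual = as.character(S4Vectors::mcols(ss)$qualities)
  )
}

#' Write a reads table as FASTQ
#'
#' @param reads `data.table` as produced by [read_fastq()].
#' @param path Output path.
#' @export
write_fastq <- function(reads, path) {
  lines <- as.vector(rbind(paste0("@", reads$id), reads$seq, "+", reads$qual))
  writeLines(lines, path)
  invisible(path)
}

## Per-read integer Phred scores from a Phred+33 string.
phred_scores <- function(qual) lapply(qual, function(q) utf8ToInt(q) - 33L)

#' Filter raw bisulfite reads and summarise the survivors
#'
#' Applies, in order, the three whole-read removal rules used to produce
#' "clean reads": (1) reads containing the 3' adapter sequence are removed;
#' (2) reads whose fraction of N bases exceeds `max_n_frac` are removed;
#' (3) reads in which at least `lowqual_frac` of bases have Phred score
#' `<= lowqual_phred` are removed. Q20, Q30 and GC content are then
#' computed over all bases of the surviving reads.
#'
#' @param reads `data.table` with columns `id`, `seq`, `qual` (Phred+33).
#' @param adapter Adapter sequence matched as an exact substring; `NULL` or
#'   `""` disables the adapter rule.
#' @param max_n_frac Maximum tolerated fraction of N bases (default 0.10).
#' @param lowqual_phred Phred score at or below which a base counts as low
#'   quality (default 5).
#' @param lowqual_frac Fraction of low-quality bases at or above which the
#'   read is removed (default 0.50).
#' @return List with `reads` (the survivors, unchanged) and `report`, a list
#'   with counts `n_input`, `n_adapter_removed`, `n_n_removed`,
#'   `n_lowqual_removed`, `n_clean` and fractions `q20`, `q30`, `gc`.
#' @export
filter_reads <- function(reads, adapter = NULL, max_n_frac = 0.10,
                         lowqual_phred = 5L, lowqual_frac = 0.50) {
  stopifnot(max_n_frac >= 0, max_n_frac <= 1,
            lowqual_frac >= 0, lowqual_frac <= 1, lowqual_phred >= 0)
  bad_len <- nchar(reads$seq) != nchar(reads$qual)
  if (any(bad_len)) {
    stop_mc("malformed read '%s': %d bases but %d quality scores",
            reads$id[which(bad_len)[1]],
            nchar(reads$seq)[which(bad_len)[1]],
            nchar(reads$qual)[which(bad_len)[1]])
  }
  n_input <- nrow(reads)

  keep <- rep(TRUE, n_input)
  if (!is.null(adapter) && nzchar(adapter)) {
    hit <- grepl(adapter, reads$seq, fixed = TRUE)
  } else {
    hit <- rep(FALSE, n_input)
  }
  n_adapter <- sum(hit)
  keep <- keep & !hit

  len <- nchar(reads$seq)
  n_frac <- ifelse(len > 0,
                   vapply(gregexpr("N", reads$seq, fixed = TRUE),
                          function(m) sum(m > 0L), integer(1)) / len, 0)
  hit_n <- keep & (n_frac > max_n_frac)
  n_n <- sum(hit_n)
  keep <- keep & !hit_n

  lq_frac <- vapply(phred_scores(reads$qual), function(p) {
    if (length(p) == 0) return(0)
    mean(p <= lowqual_phred)
  }, numeric(1))
  hit_lq <- keep & (lq_frac >= lowqual_frac)
  n_lq <- sum(hit_lq)
  keep <- keep & !hit_lq

  survivors <- reads[keep, ]
  all_phred <- unlist(phred_scores(survivors$qual))
  n_bases <- length(all_phred)
  gc <- if (nrow(survivors) > 0) {
    bases <- unlist(strsplit(survivors$seq, "", fixed = TRUE))
    mean(bases %in% c("G", "C"))
  } else NA_real_

  report <- list(
    n_input = n_input,
    n_adapter_removed = n_adapter,
    n_n_removed = n_n,
    n_lowqual_removed = n_lq,
    n_clean = nrow(survivors),
    q20 = if (n_bases > 0) mean(all_phred >= 20L) else NA_real_,
    q30 = if (n_bases > 0) mean(all_phred >= 30L) else NA_real_,
    gc = gc
  )
  list(reads = survivors, report = report)
}

#' Mark positional duplicates among aligned reads
#'
#' Reads aligning to the same place on the same strand are treated as PCR /
#' optical duplicates: exactly one read per `(chrom, start, strand)` key is
#' kept, the first encountered in input order.
#'
#' @param alignments data.frame with columns `chrom`, `start`, `strand`.
#' @return Integer vector of kept row indices (ascending).
#' @export
mark_duplicates <- function(alignments) {
  key <- paste(alignments$chrom, alignments$start, alignments$strand,
               sep = "\r")
  which(!duplicated(key))
}

# ---- per-sample cytosine site tables ---------------------------------------

site_table_cols <- c("chrom", "pos", "strand", "context",
                     "meth_count", "total_count")

#' Read a per-sample cytosine methylation count table
#'
#' The file is tab-delimited with header columns `chrom`, `pos` (1-based),
#' `strand`, `context`, `meth_count`, `total_count`. Positions are shifted
#' to the internal 0-based convention on read.
#'
#' @param path Path to the table.
#' @return `data.table` with the same columns, `pos` 0-based.
#' @export
read_site_table <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = c("chrom", "strand",
                                                          "context")))
  if (nrow(dt) == 0) {
    return(data.table::data.table(chrom = character(), pos = integer(),
                                  strand = character(), context = character(),
                                  meth_count = integer(),
                                  total_count = integer()))
  }
  missing <- setdiff(site_table_cols, names(dt))
  if (length(missing) > 0)
    stop_mc("site table %s lacks column(s): %s", path,
            paste(missing, collapse = ", "))
  bad <- which(dt$meth_count > dt$total_count)
  if (length(bad) > 0)
    stop_mc("site table %s line %d: meth_count %d exceeds total_count %d",
            path, bad[1] + 1L, dt$meth_count[bad[1]], dt$total_count[bad[1]])
  dt$pos <- as.integer(dt$pos) - 1L
  dt[]
}

#' Write a per-sample cytosine methylation count table
#'
#' Exact inverse of [read_site_table()]: internal 0-based positions are
#' written 1-based; `write_site_table(read_site_table(f)) == f` byte for
#' byte for files produced by this writer.
#'
#' @param sites `data.table` with the site-table columns, `pos` 0-based.
#' @param path Output path.
#' @export
write_site_table <- function(sites, path) {
  out <- data.table::as.data.table(sites)[, site_table_cols, with = FALSE]
  out$pos <- as.integer(out$pos) + 1L
  data.table::fwrite(out, path, sep = "\t", quote = FALSE, eol = "\n")
  invisible(path)
}

# ---- gene models (GTF) ------------------------------------------------------

#' Read gene models from a GTF file
#'
#' Parses `gene` and `exon` features. GTF 1-based inclusive coordinates are
#' converted to internal 0-based half-open. Exons must lie within their
#' gene's span.
#'
#' @param path Path to a GTF file.
#' @return A `gene_models` object: list with `genes`
#'   (`gene_id, chrom, start, end, strand`) and `exons`
#'   (`gene_id, chrom, start, end`), both 0-based half-open, sorted.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  type <- as.character(gr$type)
  gid <- as.character(gr$gene_id)
  df <- data.table::data.table(
    gene_id = gid,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = type
  )
  genes <- df[type == "gene", c("gene_id", "chrom", "start", "end", "strand")]
  exons <- df[type == "exon", c("gene_id", "chrom", "start", "end")]
  gene_models(genes, exons)
}

#' Construct a gene-models object
#'
#' @param genes data.frame with `gene_id`, `chrom`, `start`, `end`, `strand`
#'   (0-based half-open).
#' @param exons data.frame with `gene_id`, `chrom`, `start`, `end`.
#' @return A `gene_models` object.
#' @export
gene_models <- function(genes, exons) {
  genes <- data.table::as.data.table(genes)
  exons <- data.table::as.data.table(exons)
  data.table::setorder(genes, chrom, start, gene_id)
  data.table::setorder(exons, chrom, start, gene_id)
  span <- genes[, .(gene_id, gstart = start, gend = end)]
  chk <- merge(exons, span, by = "gene_id")
  bad <- chk[start < chk$gstart | end > chk$gend]
  if (nrow(bad) > 0)
    stop_mc("exon [%d,%d) of gene '%s' lies outside the gene span",
            bad$start[1], bad$end[1], bad$gene_id[1])
  structure(list(genes = genes[], exons = exons[]), class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("gene_models: %d genes, %d exons on %d contig(s)\n",
              nrow(x$genes), nrow(x$exons),
              length(unique(x$genes$chrom))))
  invisible(x)
}

#' Write gene models as GTF
#'
#' Inverse of [read_gene_models()] for files in the canonical dialect this
#' writer emits (one `gene` line then its `exon` lines, coordinates 1-based
#' inclusive, `gene_id` attribute only).
#'
#' @param gm A `gene_models` object.
#' @param path Output path.
#' @export
write_gene_models <- function(gm, path) {
  g <- gm$genes
  e <- gm$exons
  lines <- character(0)
  for (i in seq_len(nrow(g))) {
    gid <- g$gene_id[i]
    attr_str <- sprintf("gene_id \"%s\";", gid)
    lines <- c(lines, paste(g$chrom[i], "methcycle", "gene", g$start[i] + 1L,
                            g$end[i], ".", g$strand[i], ".", attr_str,
                            sep = "\t"))
    ex <- e[e$gene_id == gid, ]
    if (nrow(ex) > 0) {
      lines <- c(lines, paste(ex$chrom, "methcycle", "exon", ex$start + 1L,
                              ex$end, ".", g$strand[i], ".", attr_str,
                              sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Transcription start sites of gene models
#'
#' @param gm A `gene_models` object.
#' @return `data.table` with `gene_id`, `chrom`, `strand` and `tss`, the
#'   0-based position of the first transcribed base (`start` for `+` genes,
#'   `end - 1` for `-` genes, i.e. the 1-based gene end coordinate).
#' @export
tss_of <- function(gm) {
  g <- gm$genes
  data.table::data.table(
    gene_id = g$gene_id, chrom = g$chrom, strand = g$strand,
    tss = ifelse(g$strand == "-", g$end - 1L, g$start)
  )
}

#' Strand-aware promoter intervals
#'
#' @param gm A `gene_models` object.
#' @param width Promoter width in bp upstream of the TSS (default 2000).
#' @return `data.table` of 0-based half-open intervals abutting each TSS on
#'   its 5' side, clipped at 0.
#' @export
promoters_of <- function(gm, width = 2000L) {
  g <- gm$genes
  start <- ifelse(g$strand == "-", g$end, pmax(0L, g$start - as.integer(width)))
  end <- ifelse(g$strand == "-", g$end + as.integer(width), g$start)
  data.table::data.table(gene_id = g$gene_id, chrom = g$chrom,
                         start = as.integer(start), end = as.integer(end),
                         strand = g$strand)[end > start]
}

#' Intron intervals derived as gaps between sorted exons
#'
#' @param gm A `gene_models` object.
#' @return `data.table` with `gene_id`, `chrom`, `start`, `end` (0-based
#'   half-open), one row per intron.
#' @export
introns_of <- function(gm) {
  e <- data.table::as.data.table(gm$exons)
  data.table::setorder(e, gene_id, start)
  e[, {
    if (.N < 2) {
      list(chrom = character(0), start = integer(0), end = integer(0))
    } else {
      list(chrom = chrom[-1], start = end[-.N], end = start[-1])
    }
  }, by = gene_id][end > start]
}

# ---- BED intervals ----------------------------------------------------------

#' Read BED intervals
#'
#' @param path Path to a BED (3+ column) file.
#' @param label Label to attach to every interval (e.g. `"CGI"`,
#'   `"repeat"`).
#' @return `data.table` with `chrom`, `start`, `end` (0-based half-open, as
#'   in the file), `strand`, `label`.
#' @export
read_intervals <- function(path, label = "interval") {
  gr <- rtracklayer::import(path, format = "bed")
  s <- as.character(GenomicRanges::strand(gr))
  s[s == "*"] <- "."
  data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = s,
    label = label
  )
}

#' Write intervals as 3-column BED
#'
#' @param intervals data.frame with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param path Output path.
#' @export
write_intervals <- function(intervals, path) {
  out <- data.table::data.table(chrom = intervals$chrom,
                                start = intervals$start,
                                end = intervals$end)
  data.table::fwrite(out, path, sep = "\t", quote = FALSE,
                     col.names = FALSE, eol = "\n")
  invisible(path)
}

# ---- expression tables ------------------------------------------------------

#' Read a differential-expression results table
#'
#' @param path Tab-delimited file with header `gene_id`, `log_fc`,
#'   `q_value`.
#' @return `data.table` with those columns.
#' @export
read_expression_table <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  missing <- setdiff(c("gene_id", "log_fc", "q_value"), names(dt))
  if (length(missing) > 0)
    stop_mc("expression table %s lacks column(s): %s", path,
            paste(missing, collapse = ", "))
  dt[]
}

#' Write a differential-expression results table
#'
#' @param expr data.frame with `gene_id`, `log_fc`, `q_value`.
#' @param path Output path.
#' @export
write_expression_table <- function(expr, path) {
  out <- data.table::as.data.table(expr)[, c("gene_id", "log_fc", "q_value"),
                                         with = FALSE]
  data.table::fwrite(out, path, sep = "\t", quote = FALSE, eol = "\n")
  invisible(path)
}
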