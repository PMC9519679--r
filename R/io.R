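#' Write SV records to a VCF 4.2 file
#'
#' One record per row; interval SV carry `SVTYPE`, `END` and `SVLEN` in
#' INFO, translocations are emitted as paired `BND` records linked by
#' `MATEID`. Internal 0-based half-open starts are converted to 1-based
#' `POS` (the first affected base; no anchor-base padding is applied
#' because no sequence is tracked).
#'
#' @param records an `sv_records` data frame (one sample)
#' @param path output path (plain text `.vcf`)
#' @param sample_name sample column name; default: the records' sample
#' @return `path`, invisibly
#' @export
write_sv_vcf <- function(records, path,
                         sample_name = unique(records$sample)[1]) {
  if (is.na(sample_name)) sample_name <- "SAMPLE"
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=svharvest",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">",
    "##INFO=<ID=MATEID,Number=1,Type=String,Description=\"Mate breakend\">",
    "##INFO=<ID=CALLER,Number=1,Type=String,Description=\"Source caller\">",
    "##INFO=<ID=TAG,Number=1,Type=String,Description=\"Annotation tag\">",
    "##FILTER=<ID=lowQual,Description=\"Failed caller filter\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_name, sep = "\t"))
  lines <- character(0)
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    filt <- if (isTRUE(r$filter_pass)) "PASS" else "lowQual"
    if (r$sv_type == "TRA") {
      id1 <- sprintf("tra%05d_1", i); id2 <- sprintf("tra%05d_2", i)
      alt1 <- sprintf("N[%s:%d[", r$mate_chrom, r$mate_pos + 1L)
      alt2 <- sprintf("N[%s:%d[", r$chrom, r$start + 1L)
      info1 <- sprintf("SVTYPE=BND;MATEID=%s;CALLER=%s", id2, r$caller)
      info2 <- sprintf("SVTYPE=BND;MATEID=%s;CALLER=%s", id1, r$caller)
      lines <- c(lines,
                 paste(r$chrom, r$start + 1L, id1, "N", alt1, ".", filt,
                       info1, "GT", r$genotype, sep = "\t"),
                 paste(r$mate_chrom, r$mate_pos + 1L, id2, "N", alt2, ".",
                       filt, info2, "GT", r$genotype, sep = "\t"))
    } else {
      info <- sprintf("SVTYPE=%s;END=%d%s;CALLER=%s%s", r$sv_type, r$end,
                      if (is.na(r$length)) "" else
                        sprintf(";SVLEN=%d", r$length),
                      r$caller,
                      if (is.na(r$tag)) "" else sprintf(";TAG=%s", r$tag))
      lines <- c(lines,
                 paste(r$chrom, r$start + 1L, sprintf("sv%05d", i), "N",
                       sprintf("<%s>", r$sv_type), ".", filt, info, "GT",
                       r$genotype, sep = "\t"))
    }
  }
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Read an SV VCF written by [write_sv_vcf()]
#'
#' Requires the `vcfR` package. Paired breakend records are folded back
#' into single translocation records.
#'
#' @param path path to a VCF file
#' @param sample sample label to attach (default: VCF sample column name)
#' @return an `sv_records` data frame
#' @export
read_sv_vcf <- function(path, sample = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) return(sv_records())
  if (is.null(sample))
    sample <- colnames(v@gt)[2] %||% "SAMPLE"
  gt <- if (ncol(v@gt) >= 2) sub(":.*", "", v@gt[, 2]) else
    rep("1/1", nrow(fix))
  info_get <- function(key) {
    m <- regmatches(fix$INFO,
                    regexpr(paste0("(^|;)", key, "=[^;]+"), fix$INFO))
    out <- rep(NA_character_, nrow(fix))
    hit <- grepl(paste0(key, "="), fix$INFO)
    out[hit] <- sub(paste0(".*", key, "="), "",
                    regmatches(fix$INFO, regexpr(paste0(key, "=[^;]*"),
                                                 fix$INFO)))
    out
  }
  svtype <- info_get("SVTYPE")
  endv <- suppressWarnings(as.integer(info_get("END")))
  svlen <- suppressWarnings(as.integer(info_get("SVLEN")))
  caller <- info_get("CALLER"); caller[is.na(caller)] <- "unknown"
  tag <- info_get("TAG")
  pos <- as.integer(fix$POS)
  is_bnd <- svtype == "BND"
  rows <- list()
  seen_mate <- character(0)
  for (i in seq_len(nrow(fix))) {
    if (is_bnd[i]) {
      if (fix$ID[i] %in% seen_mate) next
      mate <- regmatches(fix$ALT[i],
                         regexpr("[^\\[\\]]+:[0-9]+", fix$ALT[i],
                                 perl = TRUE))
      if (length(mate) == 0L)
        stop("cannot parse breakend mate from ALT: ", fix$ALT[i])
      mc <- sub(":.*", "", mate); mp <- as.integer(sub(".*:", "", mate))
      seen_mate <- c(seen_mate, info_get("MATEID")[i])
      rows[[length(rows) + 1L]] <- data.frame(
        sample = sample, caller = caller[i], chrom = fix$CHROM[i],
        start = pos[i] - 1L, end = pos[i] - 1L, sv_type = "TRA",
        length = NA_integer_, genotype = gt[i],
        filter_pass = fix$FILTER[i] %in% c("PASS", "."),
        tag = tag[i], mate_chrom = mc, mate_pos = mp - 1L,
        stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        sample = sample, caller = caller[i], chrom = fix$CHROM[i],
        start = pos[i] - 1L,
        end = if (!is.na(endv[i])) endv[i] else pos[i] - 1L,
        sv_type = svtype[i], length = svlen[i], genotype = gt[i],
        filter_pass = fix$FILTER[i] %in% c("PASS", "."),
        tag = tag[i], mate_chrom = NA_character_, mate_pos = NA_integer_,
        stringsAsFactors = FALSE)
    }
  }
  validate_sv_records(do.call(rbind, rows))
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

#' Write genomic intervals as BED (0-based half-open)
#'
#' @param intervals data frame `chrom`, `start`, `end`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_bed <- function(intervals, path) {
  utils::write.table(intervals[, c("chrom", "start", "end")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a BED file of intervals
#'
#' Uses `rtracklayer` when available, plain parsing otherwise.
#'
#' @param path BED path
#' @return data frame `chrom`, `start`, `end` (0-based half-open)
#' @export
read_bed <- function(path) {
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gr <- rtracklayer::import(path, format = "BED")
    return(data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
                      start = BiocGenerics::start(gr) - 1L,
                      end = BiocGenerics::end(gr),
                      stringsAsFactors = FALSE))
  }
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  data.frame(chrom = df[[1]], start = df[[2]], end = df[[3]],
             stringsAsFactors = FALSE)
}

#' Read gene models (with exon structure) from GFF3
#'
#' Requires `rtracklayer`. Features of type `gene` define gene bodies;
#' `exon` features are attached to their gene via the `Parent`/`ID`
#' hierarchy (direct parent or via an mRNA).
#'
#' @param path GFF3 path
#' @return a list with `genes` and `exons` data frames suitable for
#'   [genome_annotation()] (0-based half-open coordinates)
#' @export
read_genes_gff3 <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("reading GFF3 requires the rtracklayer package")
  gr <- rtracklayer::import(path, format = "GFF3")
  md <- as.data.frame(gr)
  gene_rows <- md$type == "gene"
  genes <- data.frame(gene_id = as.character(md$ID[gene_rows]),
                      chrom = as.character(md$seqnames[gene_rows]),
                      start = md$start[gene_rows] - 1L,
                      end = md$end[gene_rows],
                      strand = as.character(md$strand[gene_rows]),
                      stringsAsFactors = FALSE)
  parent_of <- function(rows) {
    vapply(md$Parent[rows], function(p)
      if (length(p)) as.character(p[1]) else NA_character_, character(1))
  }
  mrna_rows <- which(md$type == "mRNA")
  mrna_parent <- stats::setNames(parent_of(mrna_rows),
                                 as.character(md$ID[mrna_rows]))
  exon_rows <- which(md$type == "exon")
  ep <- parent_of(exon_rows)
  gene_of <- ifelse(ep %in% genes$gene_id, ep, mrna_parent[ep])
  keep <- !is.na(gene_of)
  exons <- data.frame(gene_id = gene_of[keep],
                      start = md$start[exon_rows][keep] - 1L,
                      end = md$end[exon_rows][keep],
                      stringsAsFactors = FALSE)
  list(genes = genes, exons = exons)
}

#' Write a multi-sample SV cluster VCF
#'
#' One row per cluster with per-sample `GT` derived from the
#' presence/absence matrix (`1/1` carriers, `0/0` otherwise).
#'
#' @param clusters cluster table from [cluster_svs()]
#' @param presence clusters x samples matrix from [genotype_clusters()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_cluster_vcf <- function(clusters, presence, path) {
  samples <- colnames(presence)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=svharvest",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  lines <- vapply(seq_len(nrow(clusters)), function(i) {
    r <- clusters[i, ]
    gts <- ifelse(presence[r$cluster_id, ] == 1L, "1/1", "0/0")
    info <- sprintf("SVTYPE=%s;END=%d%s",
                    if (r$sv_type == "TRA") "BND" else r$sv_type, r$end,
                    if (is.na(r$length)) "" else
                      sprintf(";SVLEN=%d", r$length))
    paste(c(r$chrom, r$start + 1L, r$cluster_id, "N",
            sprintf("<%s>", r$sv_type), ".", "PASS", info, "GT", gts),
          collapse = "\t")
  }, character(1))
  writeLines(c(hdr, lines), path)
  invisible(path)
}
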