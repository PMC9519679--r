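#' Genome annotation container
#'
#' @param genes data frame `gene_id`, `chrom`, `start`, `end`, `strand`
#'   (0-based half-open gene body); the transcription start site (TSS) is
#'   `start` on the + strand and `end - 1` on the - strand
#' @param exons data frame `gene_id`, `start`, `end` (must lie within the
#'   gene body)
#' @param te data frame `chrom`, `start`, `end`: transposable-element
#'   intervals
#' @param pericentromere data frame `chrom`, `start`, `end`
#' @param chrom_lengths named numeric vector of chromosome lengths
#' @return a list of class `genome_annotation`
#' @export
genome_annotation <- function(genes, exons = NULL, te = NULL,
                              pericentromere = NULL, chrom_lengths) {
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
  if (is.null(exons))
    exons <- data.frame(gene_id = character(), start = integer(),
                        end = integer(), stringsAsFactors = FALSE)
  if (is.null(te)) te <- empty
  if (is.null(pericentromere)) pericentromere <- empty
  if (nrow(exons) > 0L) {
    gi <- match(exons$gene_id, genes$gene_id)
    if (anyNA(gi)) stop("exon gene_id not found in genes")
    if (any(exons$start < genes$start[gi] | exons$end > genes$end[gi]))
      stop("exons must lie within their gene body")
  }
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  structure(list(genes = genes, exons = exons, te = te,
                 pericentromere = pericentromere,
                 chrom_lengths = chrom_lengths),
            class = "genome_annotation")
}

## overlaps between cluster intervals and a feature track, per chromosome
#' @keywords internal
.overlap_hits <- function(clusters, feat) {
  hits <- list()
  for (ch in intersect(unique(clusters$chrom), unique(feat$chrom))) {
    ci <- which(clusters$chrom == ch)
    fi <- which(feat$chrom == ch)
    q <- IRanges::IRanges(clusters$start[ci] + 1L,
                          pmax(clusters$end[ci], clusters$start[ci] + 1L))
    s <- IRanges::IRanges(feat$start[fi] + 1L, feat$end[fi])
    ov <- IRanges::findOverlaps(q, s)
    if (length(ov))
      hits[[length(hits) + 1L]] <-
        data.frame(ci = ci[S4Vectors::queryHits(ov)],
                   fi = fi[S4Vectors::subjectHits(ov)])
  }
  if (length(hits) == 0L) return(data.frame(ci = integer(), fi = integer()))
  do.call(rbind, hits)
}

#' Classify SV clusters by gene context
#'
#' Assigns each cluster every label whose feature its interval intersects:
#' `up5k` / `down5k` for the 5 kb windows off the gene's 5' / 3' end
#' (strand-aware), `exon` / `intron` for the exonic and intronic
#' sub-intervals of the gene body, and `intergenic` iff no gene-associated
#' label applies.
#'
#' @param clusters data frame with `id` (or `cluster_id`), `chrom`,
#'   `start`, `end` (0-based half-open; insertions/translocations may have
#'   `end == start`)
#' @param annotation a [genome_annotation()]
#' @param flank width of the up/downstream windows in bp (default 5000)
#' @return a data frame `id`, `label`, `gene_id` with one row per
#'   (cluster, label, gene) combination; intergenic rows carry `NA`
#'   `gene_id`
#' @export
classify_gene_association <- function(clusters, annotation, flank = 5000L) {
  if (!"id" %in% names(clusters) && "cluster_id" %in% names(clusters))
    clusters$id <- clusters$cluster_id
  bad <- setdiff(unique(clusters$chrom),
                 c(unique(annotation$genes$chrom),
                   names(annotation$chrom_lengths)))
  if (length(bad) > 0L)
    stop("cluster chromosome(s) absent from annotation: ",
         paste(bad, collapse = ", "))
  g <- annotation$genes
  plus <- g$strand == "+"
  feats <- list()
  add <- function(label, chrom, start, end, gene_id) {
    ok <- end > start
    if (any(ok))
      feats[[length(feats) + 1L]] <<-
        data.frame(label = label, chrom = chrom[ok],
                   start = start[ok], end = end[ok],
                   gene_id = gene_id[ok], stringsAsFactors = FALSE)
  }
  add("up5k", g$chrom,
      ifelse(plus, pmax(0L, g$start - flank), g$end),
      ifelse(plus, g$start, g$end + flank), g$gene_id)
  add("down5k", g$chrom,
      ifelse(plus, g$end, pmax(0L, g$start - flank)),
      ifelse(plus, g$end + flank, g$start), g$gene_id)
  if (nrow(annotation$exons) > 0L) {
    ex <- annotation$exons
    exch <- g$chrom[match(ex$gene_id, g$gene_id)]
    add("exon", exch, ex$start, ex$end, ex$gene_id)
    ## introns = gene body minus exons
    for (gid in unique(ex$gene_id)) {
      gr <- g[g$gene_id == gid, ]
      exi <- ex[ex$gene_id == gid, , drop = FALSE]
      body <- IRanges::IRanges(gr$start + 1L, gr$end)
      exr <- IRanges::reduce(IRanges::IRanges(exi$start + 1L, exi$end))
      intr <- IRanges::setdiff(body, exr)
      if (length(intr))
        add("intron", rep(gr$chrom, length(intr)),
            IRanges::start(intr) - 1L, IRanges::end(intr),
            rep(gid, length(intr)))
    }
  } else {
    ## no exon structure: whole gene body counts as exon
    add("exon", g$chrom, g$start, g$end, g$gene_id)
  }
  feat <- do.call(rbind, feats)
  hits <- .overlap_hits(clusters, feat)
  out <- if (nrow(hits) > 0L)
    unique(data.frame(id = clusters$id[hits$ci],
                      label = feat$label[hits$fi],
                      gene_id = feat$gene_id[hits$fi],
                      stringsAsFactors = FALSE))
  else data.frame(id = character(), label = character(),
                  gene_id = character(), stringsAsFactors = FALSE)
  inter <- setdiff(clusters$id, out$id)
  if (length(inter) > 0L)
    out <- rbind(out, data.frame(id = inter, label = "intergenic",
                                 gene_id = NA_character_,
                                 stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Flag SV clusters overlapping transposable elements
#'
#' Interval SV (deletions, duplications, inversions, INDELs and
#' resolved-length insertions) are TE-derived iff some TE interval covers
#' at least 80% of the cluster and the cluster covers at least 80% of the
#' TE (reciprocal overlap). Unresolved-length insertions are TE iff their
#' breakpoint lies inside a TE; translocations iff at least one of the two
#' breakpoints does.
#'
#' @param clusters data frame with `chrom`, `start`, `end`, `sv_type`,
#'   `length` (NA for unresolved), and `mate_chrom`/`mate_pos` for
#'   translocations
#' @param te data frame `chrom`, `start`, `end` (0-based half-open)
#' @param min_reciprocal reciprocal-overlap threshold (default 0.8)
#' @return logical vector, one entry per cluster row
#' @export
annotate_te <- function(clusters, te, min_reciprocal = 0.8) {
  n <- nrow(clusters)
  out <- logical(n)
  if (n == 0L || nrow(te) == 0L) return(out)
  inside_te <- function(chrom, pos) {
    res <- logical(length(pos))
    for (ch in intersect(unique(chrom), unique(te$chrom))) {
      sel <- which(chrom == ch)
      ti <- te[te$chrom == ch, , drop = FALSE]
      q <- IRanges::IRanges(pos[sel] + 1L, pos[sel] + 1L)
      s <- IRanges::IRanges(ti$start + 1L, ti$end)
      hit <- IRanges::findOverlaps(q, s)
      res[sel[unique(S4Vectors::queryHits(hit))]] <- TRUE
    }
    res
  }
  has_len <- !is.na(clusters$length) & clusters$end > clusters$start &
    clusters$sv_type != "TRA"
  if (any(has_len)) {
    sub <- clusters[has_len, , drop = FALSE]
    hits <- .overlap_hits(sub, te)
    if (nrow(hits) > 0L) {
      ov_start <- pmax(sub$start[hits$ci], te$start[hits$fi])
      ov_end <- pmin(sub$end[hits$ci], te$end[hits$fi])
      ov <- ov_end - ov_start
      cl_len <- sub$end[hits$ci] - sub$start[hits$ci]
      te_len <- te$end[hits$fi] - te$start[hits$fi]
      good <- ov >= min_reciprocal * cl_len & ov >= min_reciprocal * te_len
      out[which(has_len)[unique(hits$ci[good])]] <- TRUE
    }
  }
  ins_unk <- clusters$sv_type == "INS" & is.na(clusters$length)
  if (any(ins_unk))
    out[ins_unk] <- inside_te(clusters$chrom[ins_unk],
                              clusters$start[ins_unk])
  tra <- clusters$sv_type == "TRA"
  if (any(tra)) {
    bp1 <- inside_te(clusters$chrom[tra], clusters$start[tra])
    bp2 <- inside_te(clusters$mate_chrom[tra], clusters$mate_pos[tra])
    out[tra] <- bp1 | bp2
  }
  out
}

#' Detect SV hotspots in fixed genomic windows
#'
#' Counts clusters (by representative start) in non-overlapping windows
#' per chromosome, fits a Poisson with the chromosome's mean window count
#' (lambda), and flags windows whose count exceeds the 99th percentile
#' `q99 = qpois(0.99, lambda)` as hotspots. Also reports the fraction of
#' hotspot windows whose midpoint falls in a pericentromeric interval.
#'
#' @param clusters data frame with `chrom`, `start`
#' @param chrom_lengths named numeric vector
#' @param pericentromere optional data frame `chrom`, `start`, `end`
#' @param window window size in bp (default 1 Mb)
#' @return a list with `windows` (data frame `chrom`, `start`, `end`,
#'   `count`, `lambda`, `q99`, `hotspot`), `lambda` (per chromosome),
#'   and `peri_hotspot_fraction`
#' @export
detect_hotspots <- function(clusters, chrom_lengths,
                            pericentromere = NULL, window = 1e6) {
  rows <- list(); lam <- numeric(0)
  for (ch in names(chrom_lengths)) {
    L <- chrom_lengths[[ch]]
    n_win <- max(1L, ceiling(L / window))
    if (L < window)
      message("chromosome ", ch, " shorter than one window; using a ",
              "single truncated window")
    starts <- (seq_len(n_win) - 1L) * window
    ends <- pmin(starts + window, L)
    pos <- clusters$start[clusters$chrom == ch]
    counts <- tabulate(pmin(floor(pos / window) + 1L, n_win), nbins = n_win)
    lambda <- mean(counts)
    q99 <- stats::qpois(0.99, lambda)
    rows[[length(rows) + 1L]] <-
      data.frame(chrom = ch, start = starts, end = ends, count = counts,
                 lambda = lambda, q99 = q99, hotspot = counts > q99,
                 stringsAsFactors = FALSE)
    lam[ch] <- lambda
  }
  win <- do.call(rbind, rows)
  peri_frac <- NA_real_
  hs <- win[win$hotspot, , drop = FALSE]
  if (!is.null(pericentromere) && nrow(hs) > 0L) {
    mid <- (hs$start + hs$end) / 2
    inp <- vapply(seq_len(nrow(hs)), function(i) {
      p <- pericentromere[pericentromere$chrom == hs$chrom[i], ,
                          drop = FALSE]
      any(mid[i] >= p$start & mid[i] < p$end)
    }, logical(1))
    peri_frac <- mean(inp)
  }
  list(windows = win, lambda = lam, peri_hotspot_fraction = peri_frac)
}

#' Positional profile of variants around transcription start sites
#'
#' For every offset in `[-flank, +flank]` relative to each gene's TSS
#' (strand-oriented: upstream is negative), counts how many SV cluster
#' intervals cover the position and how many SNV sit exactly on it,
#' aggregated over all genes. Also returns the proportion difference
#' track `1 - count / max(count)` per variant class.
#'
#' @param clusters data frame `chrom`, `start`, `end` (intervals;
#'   `end == start` contributes the single start position)
#' @param snvs data frame `chrom`, `pos`
#' @param annotation a [genome_annotation()]
#' @param flank profile half-width in bp (default 5000)
#' @return data frame `offset`, `sv_count`, `snv_count`, `sv_propdiff`,
#'   `snv_propdiff`
#' @export
tss_profile <- function(clusters, snvs, annotation, flank = 5000L) {
  offsets <- (-flank):flank
  width <- length(offsets)
  sv_cnt <- numeric(width); snv_cnt <- numeric(width)
  g <- annotation$genes
  gene_win <- data.frame(chrom = g$chrom, start = pmax(0L, g$tss - flank),
                         end = g$tss + flank + 1L, stringsAsFactors = FALSE)
  ## SV clusters: interval coverage (diff-array accumulation per gene hit)
  cl <- clusters
  cl$end2 <- pmax(cl$end, cl$start + 1L)   # point events cover one bp
  hits <- .overlap_hits(data.frame(chrom = cl$chrom, start = cl$start,
                                   end = cl$end2), gene_win)
  diffarr <- numeric(width + 1L)
  for (h in seq_len(nrow(hits))) {
    ci <- hits$ci[h]; gi <- hits$fi[h]
    off1 <- cl$start[ci] - g$tss[gi]
    off2 <- cl$end2[ci] - 1L - g$tss[gi]
    if (g$strand[gi] == "-") { tmp <- -off2; off2 <- -off1; off1 <- tmp }
    off1 <- max(off1, -flank); off2 <- min(off2, flank)
    if (off1 > off2) next
    i1 <- off1 + flank + 1L; i2 <- off2 + flank + 1L
    diffarr[i1] <- diffarr[i1] + 1
    diffarr[i2 + 1L] <- diffarr[i2 + 1L] - 1
  }
  sv_cnt <- cumsum(diffarr[seq_len(width)])
  ## SNV: exact positions
  if (nrow(snvs) > 0L) {
    shits <- .overlap_hits(data.frame(chrom = snvs$chrom, start = snvs$pos,
                                      end = snvs$pos + 1L), gene_win)
    for (h in seq_len(nrow(shits))) {
      si <- shits$ci[h]; gi <- shits$fi[h]
      off <- snvs$pos[si] - g$tss[gi]
      if (g$strand[gi] == "-") off <- -off
      if (abs(off) <= flank)
        snv_cnt[off + flank + 1L] <- snv_cnt[off + flank + 1L] + 1
    }
  }
  propdiff <- function(x) if (max(x) > 0) 1 - x / max(x) else rep(0, length(x))
  data.frame(offset = offsets, sv_count = sv_cnt, snv_count = snv_cnt,
             sv_propdiff = propdiff(sv_cnt),
             snv_propdiff = propdiff(snv_cnt))
}
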