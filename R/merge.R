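#' Filter one sample's SV calls before cross-sample merging
#'
#' Applies the per-sample retention rules: only calls passing the caller
#' filter with homozygous alternative genotype (`1/1`) are kept;
#' replacement-annotated deletions (tag `RPL`) are removed; calls whose
#' interval lies entirely inside an N-run of the reference are removed;
#' calls longer than 1 Mb are removed. Among interval calls of the same
#' sample whose footprints overlap, only the smallest survives (ties
#' broken towards the leftmost start, then by caller priority).
#' Translocations and unresolved-length insertions have no interval
#' footprint and are exempt from the overlap rule.
#'
#' @param calls `sv_records` of one sample
#' @param ref a `ref_skeleton` (supplies the N-mask); may be `NULL` to
#'   skip the N-region rule
#' @param caller_priority optional character vector ordering callers for
#'   tie-breaks; defaults to order of appearance
#' @return the filtered `sv_records`
#' @export
filter_sample_calls <- function(calls, ref = NULL,
                                caller_priority = unique(calls$caller)) {
  if (nrow(calls) == 0L) return(calls)
  if (length(unique(calls$sample)) > 1L)
    stop("filter_sample_calls expects calls of a single sample")
  keep <- calls$filter_pass & calls$genotype == "1/1" &
    (is.na(calls$tag) | calls$tag != "RPL") &
    (is.na(calls$length) | calls$length <= 1e6)
  calls <- calls[keep, , drop = FALSE]
  if (!is.null(ref) && nrow(ref$n_mask) > 0L && nrow(calls) > 0L) {
    drop <- logical(nrow(calls))
    for (ch in unique(calls$chrom)) {
      nm <- ref$n_mask[ref$n_mask$chrom == ch, , drop = FALSE]
      if (nrow(nm) == 0L) next
      sel <- which(calls$chrom == ch)
      q <- IRanges::IRanges(calls$start[sel] + 1L,
                            pmax(calls$end[sel], calls$start[sel] + 1L))
      s <- IRanges::IRanges(nm$start + 1L, nm$end)
      hits <- IRanges::findOverlaps(q, s, type = "within")
      drop[sel[unique(S4Vectors::queryHits(hits))]] <- TRUE
    }
    calls <- calls[!drop, , drop = FALSE]
  }
  ## smallest-SV conflict resolution among overlapping interval calls
  has_int <- !is.na(calls$length) & calls$end > calls$start
  intv <- calls[has_int, , drop = FALSE]
  rest <- calls[!has_int, , drop = FALSE]
  if (nrow(intv) > 1L) {
    pri <- match(intv$caller, caller_priority)
    ord <- order(intv$length, intv$start, pri)
    kept_by_chrom <- list()
    keep2 <- logical(nrow(intv))
    for (i in ord) {
      ch <- intv$chrom[i]
      cur <- kept_by_chrom[[ch]]
      cand <- IRanges::IRanges(intv$start[i] + 1L, intv$end[i])
      if (is.null(cur) || length(IRanges::findOverlaps(cand, cur)) == 0L) {
        kept_by_chrom[[ch]] <- if (is.null(cur)) cand else c(cur, cand)
        keep2[i] <- TRUE
      }
    }
    intv <- intv[keep2, , drop = FALSE]
  }
  out <- rbind(intv, rest)
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  validate_sv_records(out)
}

## clustering tolerances per length category: gap to nearest member start,
## and max breakpoint offset versus the cluster representative
#' @keywords internal
.cluster_tol <- function(sv_type, category) {
  if (sv_type == "TRA") return(c(gap = 50, bp = 50))
  if (sv_type == "INS" && is.na(category)) return(c(gap = 20, bp = 10))
  if (category %in% c("A", "INDEL")) return(c(gap = 20, bp = 10))
  c(gap = 50, bp = 50)
}

#' Cluster filtered SV calls across samples
#'
#' Within one SV type and chromosome, records are scanned in coordinate
#' order and joined to an open cluster when (a) the distance to the
#' cluster's nearest member start is below 20 bp (category A / INDELs) or
#' 50 bp (B--E) and (b) both breakpoints differ from the cluster's running
#' representative (member-wise median) by less than 10 bp (A / INDELs) or
#' 50 bp (B--E). Unresolved-length insertions cluster on the start
#' position alone (tolerance 10 bp); translocations require both
#' breakpoints to agree within 50 bp. Every record lands in exactly one
#' cluster; among several admissible open clusters the one with the
#' smallest total breakpoint offset wins.
#'
#' @param filtered `sv_records` pooled over samples (already passed
#'   through [filter_sample_calls()])
#' @return a list with `clusters` (data frame `cluster_id`, `chrom`,
#'   `start`, `end`, `sv_type`, `length`, `n_members`) and `members`
#'   (the input records plus a `cluster_id` column)
#' @export
cluster_svs <- function(filtered) {
  if (nrow(filtered) == 0L)
    return(list(clusters = data.frame(cluster_id = character(),
                                      chrom = character(), start = integer(),
                                      end = integer(), sv_type = character(),
                                      length = integer(),
                                      n_members = integer(),
                                      stringsAsFactors = FALSE),
                members = cbind(filtered, cluster_id = character(0))))
  ord <- order(filtered$sv_type, filtered$chrom, filtered$start,
               filtered$end, filtered$sample, filtered$caller)
  df <- filtered[ord, , drop = FALSE]
  df$category <- suppressWarnings(
    classify_length_category(df$length, df$sv_type))
  cluster_id <- integer(nrow(df))
  ## open clusters: parallel lists of member index vectors + summaries
  reps <- list()
  next_id <- 0L
  cur_key <- c("", "")
  open <- integer(0)   # ids of open clusters for current (type, chrom)
  for (i in seq_len(nrow(df))) {
    key <- c(df$sv_type[i], df$chrom[i])
    if (!identical(key, cur_key)) { open <- integer(0); cur_key <- key }
    tol <- .cluster_tol(df$sv_type[i],
                        if (is.na(df$length[i])) NA_character_
                        else df$category[i])
    ## close clusters too far behind to ever accept a new member
    if (length(open)) {
      maxstart <- vapply(open, function(k) reps[[k]]$max_start, numeric(1))
      open <- open[df$start[i] - maxstart < tol["gap"]]
    }
    ## candidate open clusters satisfying both clauses
    best <- NA_integer_; best_d <- Inf
    for (k in open) {
      r <- reps[[k]]
      ds <- abs(df$start[i] - r$rep_start)
      if (df$sv_type[i] == "TRA") {
        dm <- abs(df$mate_pos[i] - r$rep_mate)
        if (is.na(dm) || ds >= tol["bp"] || dm >= tol["bp"]) next
        d <- ds + dm
      } else if (is.na(df$length[i]) && df$sv_type[i] == "INS") {
        if (ds >= tol["bp"]) next
        d <- ds
      } else {
        de <- abs(df$end[i] - r$rep_end)
        if (ds >= tol["bp"] || de >= tol["bp"]) next
        d <- ds + de
      }
      if (d < best_d) { best_d <- d; best <- k }
    }
    if (is.na(best)) {
      next_id <- next_id + 1L
      reps[[next_id]] <- list(members = i,
                              rep_start = df$start[i],
                              rep_end = df$end[i],
                              rep_mate = df$mate_pos[i],
                              max_start = df$start[i])
      open <- c(open, next_id)
      cluster_id[i] <- next_id
    } else {
      r <- reps[[best]]
      r$members <- c(r$members, i)
      r$rep_start <- round(stats::median(df$start[r$members]))
      r$rep_end <- round(stats::median(df$end[r$members]))
      if (df$sv_type[i] == "TRA")
        r$rep_mate <- round(stats::median(df$mate_pos[r$members]))
      r$max_start <- max(r$max_start, df$start[i])
      reps[[best]] <- r
      cluster_id[i] <- best
    }
  }
  ids <- sprintf("svc%06d", cluster_id)
  clusters <- do.call(rbind, lapply(seq_len(next_id), function(k) {
    r <- reps[[k]]
    m <- r$members
    data.frame(cluster_id = sprintf("svc%06d", k),
               chrom = df$chrom[m[1]],
               start = as.integer(r$rep_start),
               end = as.integer(r$rep_end),
               sv_type = df$sv_type[m[1]],
               length = as.integer(round(stats::median(df$length[m]))),
               n_members = length(m), stringsAsFactors = FALSE)
  }))
  members <- df
  members$category <- NULL
  members$cluster_id <- ids
  list(clusters = clusters, members = members)
}

#' Genotype SV clusters across samples
#'
#' Presence/absence genotyping: `presence[i, s] = 1` iff sample `s`
#' contributed a member record to cluster `i`. The minor allele frequency
#' is `min(f, 1 - f)` with `f` the carrier fraction.
#'
#' @param clustering result of [cluster_svs()]
#' @param sample_ids character vector of all cohort samples (must cover
#'   every member's sample)
#' @return a list with `presence` (clusters x samples 0/1 matrix) and
#'   `maf` (named numeric vector)
#' @export
genotype_clusters <- function(clustering, sample_ids) {
  members <- clustering$members
  unknown <- setdiff(unique(members$sample), sample_ids)
  if (length(unknown) > 0L)
    stop("member samples not in sample_ids: ",
         paste(unknown, collapse = ", "))
  ids <- clustering$clusters$cluster_id
  presence <- matrix(0L, length(ids), length(sample_ids),
                     dimnames = list(ids, sample_ids))
  if (nrow(members) > 0L)
    presence[cbind(match(members$cluster_id, ids),
                   match(members$sample, sample_ids))] <- 1L
  f <- rowMeans(presence)
  maf <- pmin(f, 1 - f)
  list(presence = presence, maf = maf)
}
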