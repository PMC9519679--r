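#' Summarize an SV cluster census
#'
#' Takes per-type cluster counts plus the number of singleton clusters
#' (present in exactly one line) and derives the totals and shares a
#' survey report needs: the grand total over SV types, each type's
#' percentage, and the singleton percentage.
#'
#' @param counts data frame with columns `kind` (`"by_type"` or
#'   `"singleton"`), `sv_type` and `count`, or a path to a TSV file with
#'   those columns
#' @return a list with `total` (sum over `by_type` rows), `per_type`
#'   (data frame `sv_type`, `count`, `percent`), `n_singleton`,
#'   `singleton_percent` (rounded to one decimal, as conventionally
#'   printed)
#' @export
sv_cluster_summary <- function(counts) {
  if (is.character(counts))
    counts <- utils::read.table(counts, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
  stopifnot(all(c("kind", "sv_type", "count") %in% names(counts)))
  by_type <- counts[counts$kind == "by_type", , drop = FALSE]
  total <- sum(by_type$count)
  singleton <- counts$count[counts$kind == "singleton"]
  n_singleton <- if (length(singleton)) singleton[1] else NA_real_
  list(total = total,
       per_type = data.frame(sv_type = by_type$sv_type,
                             count = by_type$count,
                             percent = round(100 * by_type$count / total, 1),
                             stringsAsFactors = FALSE),
       n_singleton = n_singleton,
       singleton_percent = round(100 * n_singleton / total, 1))
}

#' Load published caller benchmark profiles
#'
#' Reads the bundled table of single-caller sensitivity/precision values
#' (percent) per SV type and length category, observed in a published
#' short-read benchmarking study of the barley genome at 25x coverage,
#' and turns each caller's rows into a [caller_profile()] whose
#' sensitivity and false-positive density reproduce those operating
#' points in the call-level simulator.
#'
#' @param sv_type SV type to load profiles for (default `"DEL"`)
#' @param path the profile table (default: the bundled fixture)
#' @param breakpoint_jitter_sd,length_jitter_sd jitter applied by every
#'   profile (bp)
#' @return a named list of `caller_profile` objects, ordered Manta,
#'   GRIDSS, Pindel, Delly, Lumpy, NGSEP (callers without an entry for
#'   `sv_type` are omitted)
#' @export
load_caller_benchmark_profiles <- function(sv_type = "DEL",
                                           path = system.file(
                                             "extdata",
                                             "caller_benchmark_profiles.tsv",
                                             package = "svharvest"),
                                           breakpoint_jitter_sd = 2,
                                           length_jitter_sd = 2) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  tab <- tab[tab$sv_type == sv_type, , drop = FALSE]
  order_pref <- c("Manta", "GRIDSS", "Pindel", "Delly", "Lumpy", "NGSEP")
  callers <- intersect(order_pref, unique(tab$caller))
  out <- lapply(callers, function(cn) {
    rows <- tab[tab$caller == cn, , drop = FALSE]
    caller_profile(
      cn,
      sensitivity = 0, precision_target = 1,
      breakpoint_jitter_sd = breakpoint_jitter_sd,
      length_jitter_sd = length_jitter_sd,
      het_miscall_rate = 0, fail_filter_rate = 0,
      table = data.frame(sv_type = rows$sv_type, category = rows$category,
                         sensitivity = rows$sensitivity_pct / 100,
                         precision_target = rows$precision_pct / 100,
                         stringsAsFactors = FALSE))
  })
  stats::setNames(out, callers)
}
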