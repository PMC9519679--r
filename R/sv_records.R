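#' SV call records
#'
#' The package represents SV calls, truth events, and INDELs as a plain
#' data frame with one row per call ("sv_records" data frame). Coordinates
#' are 0-based, half-open internally: a deletion of length L occupies
#' `[start, start + L)` and `end - start == length` for DEL/DUP/INV/INDEL.
#' Insertions are anchored at `start` (with `end == start`); their `length`
#' may be `NA` when the caller did not resolve it. Translocations are
#' breakpoint pairs: `start` is the first breakpoint and (`mate_chrom`,
#' `mate_pos`) the second; their `length` is `NA`.
#'
#' @param sample sample identifier(s)
#' @param caller caller identifier(s)
#' @param chrom chromosome name(s)
#' @param start 0-based start position(s)
#' @param end end position(s) (half-open); equal to `start` for insertions
#' @param sv_type one of `"DEL"`, `"INS"`, `"DUP"`, `"INV"`, `"TRA"`,
#'   `"INDEL"`
#' @param length event length in bp, `NA` if unknown
#' @param genotype `"0/0"`, `"0/1"` or `"1/1"`
#' @param filter_pass logical, `TRUE` if the call passed the caller filter
#' @param tag free annotation tag (e.g. `"RPL"` for Pindel replacements)
#' @param mate_chrom,mate_pos second breakpoint for translocations
#' @return a data frame of class `c("sv_records", "data.frame")`
#' @export
sv_records <- function(sample = character(), caller = character(),
                       chrom = character(), start = integer(),
                       end = integer(), sv_type = character(),
                       length = NA_integer_, genotype = "1/1",
                       filter_pass = TRUE, tag = NA_character_,
                       mate_chrom = NA_character_, mate_pos = NA_integer_) {
  n <- max(lengths(list(sample, caller, chrom, start, end, sv_type)))
  if (n == 0L) {
    df <- data.frame(sample = character(), caller = character(),
                     chrom = character(), start = integer(), end = integer(),
                     sv_type = character(), length = integer(),
                     genotype = character(), filter_pass = logical(),
                     tag = character(), mate_chrom = character(),
                     mate_pos = integer(), stringsAsFactors = FALSE)
  } else {
    df <- data.frame(sample = rep_len(as.character(sample), n),
                     caller = rep_len(as.character(caller), n),
                     chrom = rep_len(as.character(chrom), n),
                     start = rep_len(as.integer(start), n),
                     end = rep_len(as.integer(end), n),
                     sv_type = rep_len(as.character(sv_type), n),
                     length = rep_len(as.integer(length), n),
                     genotype = rep_len(as.character(genotype), n),
                     filter_pass = rep_len(as.logical(filter_pass), n),
                     tag = rep_len(as.character(tag), n),
                     mate_chrom = rep_len(as.character(mate_chrom), n),
                     mate_pos = rep_len(as.integer(mate_pos), n),
                     stringsAsFactors = FALSE)
  }
  validate_sv_records(df)
}

#' @keywords internal
validate_sv_records <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("sample", "caller", "chrom", "start", "end", "sv_type",
            "length", "genotype", "filter_pass", "tag", "mate_chrom",
            "mate_pos")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("sv_records missing columns: ", paste(miss, collapse = ", "))
  bad_type <- !df$sv_type %in% c("DEL", "INS", "DUP", "INV", "TRA", "INDEL")
  if (any(bad_type))
    stop("unknown sv_type: ", paste(unique(df$sv_type[bad_type]),
                                    collapse = ", "))
  if (any(df$end < df$start, na.rm = TRUE))
    stop("sv_records with end < start")
  if (any(df$sv_type == "TRA" & (is.na(df$mate_chrom) | is.na(df$mate_pos))))
    stop("translocation records must carry a mate breakpoint")
  class(df) <- unique(c("sv_records", class(df)))
  df
}

#' Length-category bounds
#'
#' SV length categories used throughout the package: INDEL 2--49 bp,
#' A 50--300 bp, B 0.3--5 kb, C 5--50 kb, D 50--250 kb, E 0.25--1 Mb.
#' Bins are upper-inclusive: the nominal overlap of the printed ranges at
#' e.g. 300 bp is resolved towards the smaller category, so the bins are
#' \[2,49\], \[50,300\], (300,5000\], (5000,5e4\], (5e4,2.5e5\], (2.5e5,1e6\].
#'
#' @return a data frame with columns `category`, `lower`, `upper`
#'   (both inclusive bounds of the bin)
#' @export
length_category_bounds <- function() {
  data.frame(category = c("INDEL", "A", "B", "C", "D", "E"),
             lower = c(2, 50, 301, 5001, 50001, 250001),
             upper = c(49, 300, 5000, 50000, 250000, 1000000),
             stringsAsFactors = FALSE)
}

#' Classify SV lengths into length categories
#'
#' @param length integer vector of SV lengths in bp; `NA` allowed
#'   (unknown-length insertions/translocations)
#' @param sv_type optional character vector of SV types, used to resolve
#'   unknown lengths: unknown-length insertions default to category `"A"`,
#'   translocations to `"ABCDE"` (they are matched with a single tolerance
#'   across the whole 50 bp -- 1 Mb range)
#' @return character vector of categories; lengths outside \[2, 1e6\] map to
#'   `NA` with a warning (out-of-range records are excluded from scoring)
#' @examples
#' classify_length_category(c(49, 50, 300, 301, 5000, 250001))
#' @export
classify_length_category <- function(length, sv_type = NULL) {
  b <- length_category_bounds()
  out <- rep(NA_character_, length(length))
  for (i in seq_len(nrow(b))) {
    sel <- !is.na(length) & length >= b$lower[i] & length <= b$upper[i]
    out[sel] <- b$category[i]
  }
  if (!is.null(sv_type)) {
    out[is.na(length) & sv_type == "INS"] <- "A"
    out[sv_type == "TRA"] <- "ABCDE"
  }
  oor <- !is.na(length) & (length < 2 | length > 1e6) &
    (is.null(sv_type) || TRUE)
  if (!is.null(sv_type)) oor <- oor & sv_type != "TRA"
  if (any(oor))
    warning(sum(oor), " record(s) with length outside [2, 1e6] tagged",
            " out-of-range and excluded")
  out
}
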