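#' Breakpoint tolerances for truth matching
#'
#' A call matches a truth event when every applicable clause holds:
#' INDELs: both breakpoints within 2 bp and length difference within 5 bp;
#' category A SV: breakpoints within 10 bp and length difference within
#' 20 bp; categories B--E: breakpoints and length difference within 50 bp;
#' insertions with unresolved length: start within 10 bp; translocations:
#' both breakpoints within 50 bp.
#'
#' @keywords internal
.tolerance_for <- function(sv_type, category) {
  if (sv_type == "INDEL") return(c(bp = 2, len = 5))
  if (sv_type == "TRA")   return(c(bp = 50, len = Inf))
  if (identical(category, "A")) return(c(bp = 10, len = 20))
  c(bp = 50, len = 50)
}

## Enumerate tolerance-compatible (ref, qry) pairs with their breakpoint
## distance. Both inputs restricted to one sv_type. Returns a data frame
## (ri, qi, dist) where dist is |d start| + |d end| (+ mate distance for
## translocations). Used by match_calls and by combination deduplication.
#' @keywords internal
.eligible_pairs <- function(ref, qry, sv_type) {
  out <- list()
  for (ch in intersect(unique(ref$chrom), unique(qry$chrom))) {
    ri_all <- which(ref$chrom == ch)
    qi_all <- which(qry$chrom == ch)
    if (length(ri_all) == 0L || length(qi_all) == 0L) next
    ro <- ri_all[order(ref$start[ri_all])]
    rstart <- ref$start[ro]
    for (qi in qi_all) {
      qs <- qry$start[qi]
      ## widest possible start tolerance is 50 bp
      lo <- findInterval(qs - 50 - 0.5, rstart) + 1L
      hi <- findInterval(qs + 50 + 0.5, rstart)
      if (hi < lo) next
      for (k in lo:hi) {
        ri <- ro[k]
        cat_r <- classify_length_category(ref$length[ri], ref$sv_type[ri])
        unknown_ins <- sv_type == "INS" &&
          (is.na(qry$length[qi]) || is.na(ref$length[ri]))
        if (sv_type == "TRA") {
          if (is.na(qry$mate_chrom[qi]) || is.na(ref$mate_chrom[ri])) next
          if (qry$mate_chrom[qi] != ref$mate_chrom[ri]) next
          ds <- abs(qs - rstart[k])
          dm <- abs(qry$mate_pos[qi] - ref$mate_pos[ri])
          if (ds <= 50 && dm <= 50)
            out[[length(out) + 1L]] <- c(ri, qi, ds + dm)
          next
        }
        if (unknown_ins) {
          ds <- abs(qs - rstart[k])
          if (ds <= 10) out[[length(out) + 1L]] <- c(ri, qi, ds)
          next
        }
        if (sv_type == "INDEL") {
          ## the two sides of an INDEL are its anchor and its length:
          ## anchor within 2 bp and length within 5 bp (the end position
          ## is implied by the pair and not constrained separately)
          ds <- abs(qs - rstart[k])
          dl <- abs(qry$length[qi] - ref$length[ri])
          if (ds <= 2 && !is.na(dl) && dl <= 5)
            out[[length(out) + 1L]] <- c(ri, qi, ds)
          next
        }
        tol <- .tolerance_for(sv_type, cat_r)
        ds <- abs(qs - rstart[k])
        de <- abs(qry$end[qi] - ref$end[ri])
        dl <- abs(qry$length[qi] - ref$length[ri])
        if (ds <= tol["bp"] && de <= tol["bp"] &&
            (is.na(dl) || dl <= tol["len"]))
          out[[length(out) + 1L]] <- c(ri, qi, ds + de)
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(ri = integer(), qi = integer(), dist = numeric()))
  m <- do.call(rbind, out)
  data.frame(ri = m[, 1], qi = m[, 2], dist = m[, 3])
}

#' Match a call set against a truth set
#'
#' One-to-one matching of calls to truth events of a single SV type under
#' the breakpoint/length tolerances (see [.tolerance_for]). Eligible
#' (truth, call) pairs are assigned greedily by increasing breakpoint
#' distance (sum of start and end offsets), ties broken towards the
#' leftmost call; an alternating-path repair then guarantees the matching
#' has maximum cardinality (equal to exhaustive optimal assignment).
#'
#' @param truth,calls `sv_records` data frames restricted to one SV type
#' @param sv_type the SV type being scored
#' @param category optional length category (`"INDEL"`, `"A"`..`"E"`, or
#'   `"ABCDE"` for translocations); when given, truth and calls are
#'   restricted to records of that category before matching
#' @return a list with components `tp`, `fp`, `fn` (counts) and `pairs`
#'   (data frame of matched `truth_idx`, `call_idx` into the restricted
#'   sets, plus `truth_row`, `call_row` into the original inputs)
#' @export
match_calls <- function(truth, calls, sv_type, category = NULL) {
  if (any(truth$sv_type != sv_type) || any(calls$sv_type != sv_type))
    stop("match_calls: truth and calls must contain only sv_type ", sv_type)
  t_keep <- seq_len(nrow(truth))
  c_keep <- seq_len(nrow(calls))
  if (!is.null(category) && !identical(category, "ABCDE")) {
    tcat <- suppressWarnings(
      classify_length_category(truth$length, truth$sv_type))
    ccat <- suppressWarnings(
      classify_length_category(calls$length, calls$sv_type))
    t_keep <- which(!is.na(tcat) & tcat == category)
    c_keep <- which(!is.na(ccat) & ccat == category)
  }
  tr <- truth[t_keep, , drop = FALSE]
  cl <- calls[c_keep, , drop = FALSE]
  pairs <- .eligible_pairs(tr, cl, sv_type)
  if (nrow(pairs) > 0L) {
    ord <- order(pairs$dist, cl$start[pairs$qi], pairs$qi, pairs$ri)
    pairs <- pairs[ord, , drop = FALSE]
  }
  match_t <- integer(nrow(tr)); match_c <- integer(nrow(cl))
  for (i in seq_len(nrow(pairs))) {
    ri <- pairs$ri[i]; qi <- pairs$qi[i]
    if (match_t[ri] == 0L && match_c[qi] == 0L) {
      match_t[ri] <- qi; match_c[qi] <- ri
    }
  }
  ## augmenting-path repair: greedy alone can strand a truth event whose
  ## only compatible call was claimed by a truth that had an alternative;
  ## alternating-path augmentation restores maximum cardinality without
  ## disturbing the greedy preference order (edges tried nearest-first)
  if (nrow(pairs) > 0L && any(match_t == 0L)) {
    adj <- split(pairs$qi, factor(pairs$ri, levels = seq_len(nrow(tr))))
    seen <- logical(nrow(cl))
    augment <- function(ri) {
      for (qi in adj[[ri]]) {
        if (seen[qi]) next
        seen[qi] <<- TRUE
        if (match_c[qi] == 0L || augment(match_c[qi])) {
          match_t[ri] <<- qi; match_c[qi] <<- ri
          return(TRUE)
        }
      }
      FALSE
    }
    for (ri in which(match_t == 0L)) {
      seen[] <- FALSE
      augment(ri)
    }
  }
  mt <- which(match_t > 0L)
  tp <- length(mt)
  list(tp = tp, fp = nrow(cl) - tp, fn = nrow(tr) - tp,
       pairs = data.frame(truth_idx = mt, call_idx = match_t[mt],
                          truth_row = t_keep[mt],
                          call_row = c_keep[match_t[mt]]))
}

#' Sensitivity, precision and F1 from match counts
#'
#' Sensitivity = TP/(TP+FN), precision = TP/(TP+FP), F1 = their harmonic
#' mean. A zero denominator yields `NA` (propagated as missing, never 0).
#'
#' @param m a match result as returned by [match_calls()], or a list with
#'   `tp`, `fp`, `fn`
#' @return a list with `sensitivity`, `precision`, `f1`
#' @examples
#' compute_metrics(list(tp = 8, fp = 0, fn = 2))
#' @export
compute_metrics <- function(m) {
  stopifnot(m$tp >= 0, m$fp >= 0, m$fn >= 0)
  s <- if (m$tp + m$fn > 0) m$tp / (m$tp + m$fn) else NA_real_
  p <- if (m$tp + m$fp > 0) m$tp / (m$tp + m$fp) else NA_real_
  f1 <- if (!is.na(s) && !is.na(p) && (s + p) > 0) 2 * p * s / (p + s)
        else NA_real_
  list(sensitivity = s, precision = p, f1 = f1)
}

#' Parse a caller-combination expression
#'
#' Grammar: `expr := term ('|' term)*`, `term := factor ('&' factor)*`,
#' `factor := caller | '(' expr ')'`. Whitespace is ignored.
#'
#' @param x a string such as `"Manta|GRIDSS|(Lumpy&NGSEP)"`
#' @return a parse tree: a character leaf or `list(op = "|"/"&",
#'   args = list(...))`
#' @export
parse_combination <- function(x) {
  toks <- regmatches(x, gregexpr("[A-Za-z0-9_.]+|[|&()]", x))[[1]]
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  take <- function() { t <- peek(); pos <<- pos + 1L; t }
  parse_factor <- function() {
    t <- take()
    if (is.na(t)) stop("unexpected end of combination expression")
    if (t == "(") {
      e <- parse_expr()
      if (!identical(take(), ")")) stop("missing ')' in expression")
      return(e)
    }
    if (t %in% c("|", "&", ")")) stop("unexpected '", t, "' in expression")
    t
  }
  parse_term <- function() {
    args <- list(parse_factor())
    while (identical(peek(), "&")) { take(); args <- c(args, list(parse_factor())) }
    if (length(args) == 1L) args[[1]] else list(op = "&", args = args)
  }
  parse_expr <- function() {
    args <- list(parse_term())
    while (identical(peek(), "|")) { take(); args <- c(args, list(parse_term())) }
    if (length(args) == 1L) args[[1]] else list(op = "|", args = args)
  }
  e <- parse_expr()
  if (pos <= length(toks)) stop("trailing tokens in expression: ",
                                paste(toks[pos:length(toks)], collapse = ""))
  e
}

#' Format a combination parse tree as a string
#'
#' AND sub-expressions nested inside an OR are parenthesized, e.g.
#' `X|(Y&Z)`.
#'
#' @param expr a parse tree (see [parse_combination()])
#' @return a single string
#' @export
format_combination <- function(expr) {
  fmt <- function(e, parent) {
    if (is.character(e)) return(e)
    inner <- vapply(e$args, fmt, character(1), parent = e$op)
    s <- paste(inner, collapse = e$op)
    if (e$op == "&" && identical(parent, "|")) paste0("(", s, ")") else s
  }
  fmt(expr, NA_character_)
}

#' @keywords internal
.combination_leaves <- function(expr) {
  if (is.character(expr)) return(expr)
  unlist(lapply(expr$args, .combination_leaves))
}

## rows of `a` that have at least one tolerance-compatible partner in `b`
#' @keywords internal
.has_match <- function(a, b, sv_type) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(logical(nrow(a)))
  p <- .eligible_pairs(b, a, sv_type)   # ref = b, qry = a
  seq_len(nrow(a)) %in% p$qi
}

#' Combine per-caller call sets under a boolean expression
#'
#' OR takes the union of member call sets with cross-caller
#' deduplication: a call is a duplicate if it is tolerance-compatible with
#' a call already in the union, and the surviving representative is the
#' one from the earlier caller in expression order. AND keeps the calls of
#' the first member that have a tolerance-compatible partner in every
#' other member; the first caller's coordinates are reported.
#'
#' @param expr a combination string or parse tree
#' @param callsets named list of `sv_records` data frames, one per caller;
#'   list order defines caller priority
#' @param sv_type SV type to combine
#' @return an `sv_records` data frame of combined calls
#' @export
combine_callsets <- function(expr, callsets, sv_type) {
  if (is.character(expr) && length(expr) == 1L && !expr %in% names(callsets))
    expr <- parse_combination(expr)
  ev <- function(e) {
    if (is.character(e)) {
      if (!e %in% names(callsets)) stop("unknown caller: ", e)
      cs <- callsets[[e]]
      return(cs[cs$sv_type == sv_type, , drop = FALSE])
    }
    sets <- lapply(e$args, ev)
    if (e$op == "|") {
      u <- sets[[1]]
      for (s in sets[-1]) {
        if (nrow(s) == 0L) next
        dup <- .has_match(s, u, sv_type)
        u <- rbind(u, s[!dup, , drop = FALSE])
      }
      return(u)
    }
    ## AND
    res <- sets[[1]]
    for (s in sets[-1]) {
      keep <- .has_match(res, s, sv_type)
      res <- res[keep, , drop = FALSE]
    }
    res
  }
  ev(expr)
}

#' Score a caller combination against truth
#'
#' @inheritParams combine_callsets
#' @param truth truth `sv_records`
#' @param category optional length category restriction (see
#'   [match_calls()])
#' @return a list with `sensitivity`, `precision`, `f1`, `tp`, `fp`, `fn`
#' @export
evaluate_combination <- function(expr, callsets, truth, sv_type,
                                 category = NULL) {
  combined <- combine_callsets(expr, callsets, sv_type)
  m <- match_calls(truth[truth$sv_type == sv_type, , drop = FALSE],
                   combined, sv_type, category)
  c(compute_metrics(m), m[c("tp", "fp", "fn")])
}

#' Per-caller, per-category benchmark table
#'
#' @param callsets named list of per-caller `sv_records`
#' @param truth truth `sv_records`
#' @param sv_type SV type to score
#' @param categories categories to score; default: categories present in
#'   the truth set
#' @return data frame with columns `caller`, `sv_type`, `category`, `tp`,
#'   `fp`, `fn`, `sensitivity`, `precision`, `f1`
#' @export
benchmark_callers <- function(callsets, truth, sv_type, categories = NULL) {
  tr <- truth[truth$sv_type == sv_type, , drop = FALSE]
  if (is.null(categories)) {
    if (sv_type == "TRA") categories <- "ABCDE"
    else categories <- sort(unique(suppressWarnings(
      classify_length_category(tr$length, tr$sv_type))))
    categories <- categories[!is.na(categories)]
  }
  rows <- list()
  for (cn in names(callsets)) {
    cs <- callsets[[cn]]
    cs <- cs[cs$sv_type == sv_type, , drop = FALSE]
    for (cat in categories) {
      m <- match_calls(tr, cs, sv_type, cat)
      met <- compute_metrics(m)
      rows[[length(rows) + 1L]] <-
        data.frame(caller = cn, sv_type = sv_type, category = cat,
                   tp = m$tp, fp = m$fp, fn = m$fn,
                   sensitivity = met$sensitivity, precision = met$precision,
                   f1 = met$f1, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Select the best caller combination under a precision floor
#'
#' Two-step procedure: (1) all callers whose measured precision meets the
#' floor in every length category are combined with OR; (2) the remaining
#' callers are combined with AND, and if that AND combination meets the
#' floor in every category it is OR-ed into the step-1 expression,
#' otherwise it is dropped. If neither step yields a member, the single
#' caller with the highest mean F1 is returned with a warning.
#'
#' @param per_caller data frame as produced by [benchmark_callers()]
#' @param callsets named list of per-caller `sv_records` (order = caller
#'   priority)
#' @param truth truth `sv_records`
#' @param sv_type SV type
#' @param precision_floor minimum precision required in every category
#'   (default 0.95)
#' @return a list with `expr` (parse tree) and `label` (string form)
#' @export
select_best_combination <- function(per_caller, callsets, truth, sv_type,
                                    precision_floor = 0.95) {
  callers <- names(callsets)
  categories <- unique(per_caller$category)
  passes <- vapply(callers, function(cn) {
    pc <- per_caller[per_caller$caller == cn, , drop = FALSE]
    if (nrow(pc) == 0L) return(FALSE)
    all(is.na(pc$precision) | pc$precision >= precision_floor)
  }, logical(1))
  step1 <- callers[passes]
  rest <- callers[!passes]
  members <- as.list(step1)
  if (length(rest) >= 2L) {
    and_expr <- list(op = "&", args = as.list(rest))
    prec <- vapply(categories, function(cat) {
      evaluate_combination(and_expr, callsets, truth, sv_type, cat)$precision
    }, numeric(1))
    if (all(is.na(prec) | prec >= precision_floor))
      members <- c(members, list(and_expr))
  }
  if (length(members) == 0L) {
    mean_f1 <- vapply(callers, function(cn) {
      pc <- per_caller[per_caller$caller == cn, , drop = FALSE]
      mean(pc$f1, na.rm = TRUE)
    }, numeric(1))
    best <- callers[which.max(mean_f1)]
    warning("no caller or AND combination met the precision floor; ",
            "returning the single caller with highest mean F1: ", best)
    return(list(expr = best, label = best))
  }
  expr <- if (length(members) == 1L) members[[1]]
          else list(op = "|", args = members)
  list(expr = expr, label = format_combination(expr))
}
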