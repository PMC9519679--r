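test_that("category-A deletion tolerances accept and reject as specified", {
  truth <- rec(start = 10000L, length = 200L)
  tp_call <- rec(start = 10005L, length = 190L, caller = "x")
  m <- match_calls(truth, tp_call, "DEL")
  expect_identical(c(m$tp, m$fp, m$fn), c(1L, 0L, 0L))
  fp_call <- rec(start = 10012L, length = 200L, caller = "x")
  m2 <- match_calls(truth, fp_call, "DEL")
  expect_identical(c(m2$tp, m2$fp, m2$fn), c(0L, 1L, 1L))
})

test_that("empty call set yields pure false negatives", {
  truth <- rec(start = seq(1000L, 7000L, by = 1000L), length = 100L)
  m <- match_calls(truth, empty_records(), "DEL")
  expect_identical(c(m$tp, m$fp, m$fn), c(0L, 0L, 7L))
})

test_that("INDEL tolerance: anchor within 2 bp and length within 5 bp", {
  truth <- rec(start = 500L, length = 10L, sv_type = "INDEL")
  ok <- rec(start = 501L, length = 14L, sv_type = "INDEL", caller = "x")
  expect_identical(match_calls(truth, ok, "INDEL")$tp, 1L)
  far <- rec(start = 503L, length = 10L, sv_type = "INDEL", caller = "x")
  expect_identical(match_calls(truth, far, "INDEL")$tp, 0L)
  long <- rec(start = 500L, length = 16L, sv_type = "INDEL", caller = "x")
  expect_identical(match_calls(truth, long, "INDEL")$tp, 0L)
})

test_that("unknown-length insertions match on start within 10 bp", {
  truth <- rec(start = 2000L, length = NA_integer_, sv_type = "INS")
  near <- rec(start = 2009L, length = NA_integer_, sv_type = "INS",
              caller = "x")
  expect_identical(match_calls(truth, near, "INS")$tp, 1L)
  far <- rec(start = 2011L, length = NA_integer_, sv_type = "INS",
             caller = "x")
  expect_identical(match_calls(truth, far, "INS")$tp, 0L)
})

test_that("translocations require both breakpoints within 50 bp", {
  truth <- rec(start = 5000L, length = NA_integer_, sv_type = "TRA",
               mate_chrom = "chr2", mate_pos = 90000L)
  ok <- rec(start = 5040L, length = NA_integer_, sv_type = "TRA",
            caller = "x", mate_chrom = "chr2", mate_pos = 90049L)
  expect_identical(match_calls(truth, ok, "TRA")$tp, 1L)
  bad_mate <- rec(start = 5000L, length = NA_integer_, sv_type = "TRA",
                  caller = "x", mate_chrom = "chr2", mate_pos = 90051L)
  expect_identical(match_calls(truth, bad_mate, "TRA")$tp, 0L)
})

test_that("mixed sv_type input is rejected", {
  truth <- rec(start = 100L, length = 100L)
  calls <- rec(start = 100L, length = 100L, sv_type = "DUP", caller = "x")
  expect_error(match_calls(truth, calls, "DEL"), "sv_type")
})

test_that("bookkeeping identities hold on random instances", {
  for (seed in 1:25) {
    inst <- random_match_instance(seed)
    m <- match_calls(inst$truth, inst$calls, "DEL")
    expect_identical(m$tp + m$fn, nrow(inst$truth))
    expect_identical(m$tp + m$fp, nrow(inst$calls))
    expect_false(any(duplicated(m$pairs$truth_idx)))
    expect_false(any(duplicated(m$pairs$call_idx)))
  }
})

test_that("compute_metrics reproduces the worked values", {
  m <- compute_metrics(list(tp = 8, fp = 0, fn = 2))
  expect_equal(m$sensitivity, 0.8)
  expect_equal(m$precision, 1)
  expect_equal(round(m$f1, 3), 0.889)
  z <- compute_metrics(list(tp = 0, fp = 0, fn = 5))
  expect_equal(z$sensitivity, 0)
  expect_true(is.na(z$precision))
  expect_true(is.na(z$f1))
  ## harmonic mean of sensitivity 0.890 and precision 0.991
  f1 <- 2 * 0.991 * 0.890 / (0.991 + 0.890)
  expect_equal(round(f1, 3), 0.938)
})

test_that("F1 lies between its inputs and below their arithmetic mean", {
  set.seed(7)
  for (i in 1:50) {
    tp <- sample(1:50, 1); fp <- sample(0:20, 1); fn <- sample(0:20, 1)
    m <- compute_metrics(list(tp = tp, fp = fp, fn = fn))
    expect_gte(m$f1, min(m$sensitivity, m$precision) - 1e-12)
    expect_lte(m$f1, max(m$sensitivity, m$precision) + 1e-12)
    expect_lte(m$f1, (m$sensitivity + m$precision) / 2 + 1e-12)
  }
})

test_that("combination expressions parse and format round-trip", {
  e <- parse_combination("Manta|GRIDSS|Pindel|Delly|(Lumpy&NGSEP)")
  expect_identical(format_combination(e),
                   "Manta|GRIDSS|Pindel|Delly|(Lumpy&NGSEP)")
  expect_identical(format_combination(parse_combination("A & B | C")),
                   "(A&B)|C")
  expect_error(parse_combination("A|"), "unexpected end")
  expect_error(parse_combination("(A|B"), "missing")
})

test_that("single-caller combination is the identity", {
  truth <- rec(start = seq(1000L, 20000L, by = 1000L), length = 150L)
  set.seed(11)
  calls <- rec(start = truth$start + sample(-3:3, nrow(truth), TRUE),
               length = 150L, caller = "X")
  callsets <- list(X = calls)
  direct <- compute_metrics(match_calls(truth, calls, "DEL"))
  via_expr <- evaluate_combination("X", callsets, truth, "DEL")
  expect_equal(via_expr$sensitivity, direct$sensitivity)
  expect_equal(via_expr$precision, direct$precision)
})

test_that("OR unions disjoint sensitivities; AND zeroes disjoint FPs", {
  truth <- rec(start = seq(1000L, 100000L, by = 1000L), length = 150L)
  n <- nrow(truth)
  a <- rec(start = truth$start[1:60], length = 150L, caller = "A")
  b <- rec(start = truth$start[61:100], length = 150L, caller = "B")
  callsets <- list(A = a, B = b)
  res <- evaluate_combination("A|B", callsets, truth, "DEL")
  expect_gte(res$sensitivity, 0.60)
  expect_equal(res$sensitivity, 1)
  ## AND with disjoint FP sets
  a2 <- rbind(a, rec(start = 500000L, length = 150L, caller = "A"))
  b2 <- rbind(rec(start = truth$start[1:60], length = 150L, caller = "B"),
              rec(start = 700000L, length = 150L, caller = "B"))
  both <- evaluate_combination("A&B",
                               list(A = as_records(a2), B = as_records(b2)),
                               truth, "DEL")
  expect_identical(both$fp, 0L)
})

test_that("OR never lowers TP below a member; AND never raises FP above", {
  set.seed(21)
  truth <- rec(start = seq(2000L, 60000L, by = 600L), length = 150L)
  mk <- function(nm) {
    keep <- runif(nrow(truth)) < 0.7
    tp <- rec(start = truth$start[keep] + sample(-3:3, sum(keep), TRUE),
              length = 150L, caller = nm)
    fp <- rec(start = sample(70000:90000, 5), length = 150L, caller = nm)
    rbind(tp, fp)
  }
  callsets <- list(P = as_records(mk("P")), Q = as_records(mk("Q")))
  single <- lapply(names(callsets), function(cn)
    match_calls(truth, callsets[[cn]], "DEL"))
  or_res <- evaluate_combination("P|Q", callsets, truth, "DEL")
  and_res <- evaluate_combination("P&Q", callsets, truth, "DEL")
  for (s in single) {
    expect_gte(or_res$tp, s$tp)
    expect_lte(and_res$fp, s$fp)
  }
})

test_that("combination selection handles all three specified scenarios", {
  sc <- combo_scenario()
  tab <- benchmark_callers(sc$good, sc$truth, "DEL")
  sel <- select_best_combination(tab, sc$good, sc$truth, "DEL")
  expect_identical(sel$label, "X|(Y&Z)")

  tab_all <- benchmark_callers(sc$all_pass, sc$truth, "DEL")
  sel_all <- select_best_combination(tab_all, sc$all_pass, sc$truth, "DEL")
  expect_identical(sel_all$label, "X|Y|Z")

  tab_bad <- benchmark_callers(sc$bad_and, sc$truth, "DEL")
  sel_bad <- select_best_combination(tab_bad, sc$bad_and, sc$truth, "DEL")
  expect_identical(sel_bad$label, "X")
})

test_that("fallback returns the best mean-F1 caller with a warning", {
  truth <- rec(start = seq(5000L, 50000L, by = 1000L), length = 150L)
  noisy <- function(nm, n_tp, n_fp) {
    rbind(rec(start = truth$start[seq_len(n_tp)], length = 150L,
              caller = nm),
          rec(start = seq(200000L, by = 5000L, length.out = n_fp),
              length = 150L, caller = nm))
  }
  callsets <- list(U = as_records(noisy("U", 40, 30)),
                   V = as_records(noisy("V", 20, 40)))
  tab <- benchmark_callers(callsets, truth, "DEL")
  expect_warning(sel <- select_best_combination(tab, callsets, truth, "DEL"),
                 "highest mean F1")
  expect_identical(sel$label, "U")
})

test_that("unknown caller leaf raises a lookup error", {
  truth <- rec(start = 1000L, length = 150L)
  expect_error(combine_callsets("Nope", list(X = truth), "DEL"),
               "unknown caller")
})
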