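## Shared fixtures and brute-force oracles used across the test files.

## Quick builders -----------------------------------------------------------

rec <- function(start, length, sv_type = "DEL", chrom = "chr1",
                sample = "s1", caller = "c1", genotype = "1/1",
                filter_pass = TRUE, tag = NA_character_,
                mate_chrom = NA_character_, mate_pos = NA_integer_) {
  n <- max(length(start), length(length), length(sv_type))
  start <- rep_len(as.integer(start), n)
  length <- rep_len(as.integer(length), n)
  type_v <- rep_len(sv_type, n)
  end <- ifelse(type_v %in% c("INS", "TRA") | is.na(length),
                start, start + length)
  sv_records(sample = sample, caller = caller, chrom = chrom,
             start = start, end = end, sv_type = sv_type, length = length,
             genotype = genotype, filter_pass = filter_pass, tag = tag,
             mate_chrom = mate_chrom, mate_pos = mate_pos)
}

empty_records <- function() sv_records()

as_records <- function(df) svharvest:::validate_sv_records(df)

## Deterministic three-caller scenario for combination selection ------------
## Truth: 20 deletions in each length category. X is clean everywhere;
## Y and Z each add disjoint false positives that push their precision
## below 0.95 in every category; their AND is clean. `all_pass` replaces
## Y/Z with clean callers; `bad_and` makes the Y and Z false positives
## coincide so the AND stays below the floor.

combo_scenario <- function() {
  b <- length_category_bounds()
  b <- b[b$category != "INDEL", ]
  lens <- rep(as.integer(b$lower + 50), each = 20)
  starts <- as.integer(cumsum(rep(2e6, length(lens))))
  truth <- rec(start = starts, length = lens, sample = "t",
               caller = "truth")
  clean <- function(nm) rec(start = starts, length = lens, sample = "t",
                            caller = nm)
  fps <- function(nm, shift) {
    fp_start <- as.integer(starts + 1e6 + shift)
    rbind(clean(nm),
          rec(start = fp_start[seq(1, length(fp_start), by = 5)],
              length = lens[seq(1, length(lens), by = 5)],
              sample = "t", caller = nm))
  }
  list(truth = truth,
       good = list(X = clean("X"),
                   Y = as_records(fps("Y", 0L)),
                   Z = as_records(fps("Z", 200000L))),
       all_pass = list(X = clean("X"), Y = clean("Y"), Z = clean("Z")),
       bad_and = list(X = clean("X"),
                      Y = as_records(fps("Y", 0L)),
                      Z = as_records(fps("Z", 0L))))
}

## Maximum-cardinality matching by brute force ------------------------------
## Exhaustive search over all one-to-one assignments (injections) of truth
## records to tolerance-compatible calls; returns the maximum number of
## matched pairs. Only usable for small instances (<= 8 x 8).

brute_force_max_tp <- function(truth, calls, sv_type) {
  p <- svharvest:::.eligible_pairs(truth, calls, sv_type)
  nt <- nrow(truth)
  nc <- nrow(calls)
  if (nt == 0L || nc == 0L || nrow(p) == 0L) return(0L)
  adj <- lapply(seq_len(nt), function(i) p$qi[p$ri == i])
  used <- logical(nc)
  recurse <- function(i) {
    if (i > nt) return(0L)
    best <- recurse(i + 1L)
    for (q in adj[[i]]) {
      if (used[q]) next
      used[q] <<- TRUE
      best <- max(best, 1L + recurse(i + 1L))
      used[q] <<- FALSE
    }
    best
  }
  recurse(1L)
}

## Random matching instance with deliberate breakpoint conflicts ------------
## Truth events packed tightly relative to the category-A tolerance so that
## calls are frequently eligible for more than one truth record.

random_match_instance <- function(seed) {
  set.seed(seed)
  nt <- sample(1:8, 1)
  truth <- rec(start = sort(sample(0:150, nt)), length = 100L,
               sample = "t", caller = "truth")
  nc <- sample(1:8, 1)
  cs <- integer(nc); cl <- integer(nc)
  for (j in seq_len(nc)) {
    if (runif(1) < 0.75) {
      i <- sample(nt, 1)
      cs[j] <- truth$start[i] + sample(-14:14, 1)
      cl[j] <- 100L + sample(-25:25, 1)
    } else {
      cs[j] <- sample(0:200, 1)
      cl[j] <- sample(60:140, 1)
    }
  }
  calls <- rec(start = cs, length = cl, sample = "t", caller = "x")
  list(truth = truth, calls = calls)
}

## Brute-force TE annotation oracle -----------------------------------------

brute_force_te <- function(clusters, te, min_reciprocal = 0.8) {
  vapply(seq_len(nrow(clusters)), function(i) {
    cli <- clusters[i, ]
    if (cli$sv_type == "TRA") {
      hit <- function(ch, pos) any(te$chrom == ch & pos >= te$start &
                                     pos < te$end)
      return(hit(cli$chrom, cli$start) || hit(cli$mate_chrom, cli$mate_pos))
    }
    if (cli$sv_type == "INS" && is.na(cli$length))
      return(any(te$chrom == cli$chrom & cli$start >= te$start &
                   cli$start < te$end))
    sel <- te[te$chrom == cli$chrom, , drop = FALSE]
    if (nrow(sel) == 0L) return(FALSE)
    ov <- pmin(cli$end, sel$end) - pmax(cli$start, sel$start)
    any(ov >= min_reciprocal * (cli$end - cli$start) &
          ov >= min_reciprocal * (sel$end - sel$start))
  }, logical(1))
}

## Kernel-ridge prediction oracle -------------------------------------------
## Same variance components as gblup_predict, but predictions through the
## full-variance formulation u = sg2 * G_ts V^{-1} (y - mu) with
## V = sg2 * G_tt + se2 * I (an algebraically equivalent, independently
## coded path).

kernel_ridge_oracle <- function(G, y, train_idx, test_idx) {
  if (inherits(G, "g_matrix")) G <- G$G
  ytr <- y[train_idx]
  Gtt <- G[train_idx, train_idx, drop = FALSE]
  fit <- reml_kernel(ytr, matrix(1, length(ytr), 1L), Gtt)
  mu <- fit$beta[1]
  if (fit$sigma_g2 <= 0 || fit$lambda < 1e-12)
    return(rep(mu, length(test_idx)))
  V <- fit$sigma_g2 * Gtt + fit$sigma_e2 * diag(length(train_idx))
  u <- fit$sigma_g2 * G[test_idx, train_idx, drop = FALSE] %*%
    solve(V, ytr - mu)
  as.numeric(mu + u)
}

## Small shared annotation fixture ------------------------------------------

toy_annotation <- function() {
  genes <- data.frame(
    gene_id = c("g1", "g2"),
    chrom = c("chr1", "chr1"),
    start = c(20000L, 60000L),
    end = c(26000L, 64000L),
    strand = c("+", "-"),
    stringsAsFactors = FALSE)
  exons <- data.frame(
    gene_id = c("g1", "g1", "g2"),
    start = c(20000L, 24000L, 60000L),
    end = c(21000L, 26000L, 64000L),
    stringsAsFactors = FALSE)
  genome_annotation(genes, exons,
                    chrom_lengths = c(chr1 = 1e5))
}

## Draw a multivariate normal vector with covariance sg2*K + se2*I ----------

draw_polygenic <- function(K, sg2, se2) {
  eg <- eigen(K, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  n <- nrow(K)
  as.numeric(eg$vectors %*% (sqrt(sg2 * d) * stats::rnorm(n))) +
    stats::rnorm(n, 0, sqrt(se2))
}
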