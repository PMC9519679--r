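#' Simulate a reference-genome skeleton
#'
#' Generates chromosome lengths, a track of N-runs (assembly gaps), a
#' pericentromeric track centered on each chromosome midpoint, and
#' centromere midpoints. No nucleotide sequence is generated: downstream
#' operations only need coordinates and masks.
#'
#' @param chrom_lengths integer vector of chromosome lengths in bp
#'   (named or unnamed; unnamed chromosomes are called `chr1`, `chr2`, ...);
#'   each must be at least 1e5
#' @param n_block_density expected number of N-runs per bp (default
#'   1e-6, i.e. one gap per Mb); N-run lengths are uniform 100--1000 bp
#' @param pericentromere_fraction fraction of each chromosome covered by
#'   the pericentromeric interval, in `[0, 1)`
#' @param seed integer seed; identical seeds give identical skeletons
#' @return a list of class `ref_skeleton` with elements `chromosomes`
#'   (data frame `name`, `length`), `n_mask`, `pericentromere` (data
#'   frames `chrom`, `start`, `end`; 0-based half-open), `centromere`
#'   (data frame `chrom`, `pos`)
#' @export
simulate_reference <- function(chrom_lengths, n_block_density = 1e-6,
                               pericentromere_fraction = 0.257,
                               seed = 1L) {
  if (any(chrom_lengths < 1e5))
    stop("chromosome lengths must be >= 1e5 bp")
  if (pericentromere_fraction < 0 || pericentromere_fraction >= 1)
    stop("pericentromere_fraction must be in [0, 1)")
  nm <- names(chrom_lengths)
  if (is.null(nm)) nm <- paste0("chr", seq_along(chrom_lengths))
  set.seed(seed)
  n_mask <- list(); peri <- list(); centro <- list()
  for (i in seq_along(chrom_lengths)) {
    L <- chrom_lengths[i]
    k <- stats::rpois(1, n_block_density * L)
    if (k > 0) {
      st <- sort(sample.int(L - 1000L, k, replace = TRUE))
      en <- pmin(st + sample(100:1000, k, replace = TRUE), L)
      ir <- IRanges::reduce(IRanges::IRanges(st + 1L, en))  # merge overlaps
      n_mask[[i]] <- data.frame(chrom = nm[i],
                                start = IRanges::start(ir) - 1L,
                                end = IRanges::end(ir),
                                stringsAsFactors = FALSE)
    }
    mid <- floor(L / 2)
    half <- floor(pericentromere_fraction * L / 2)
    if (half > 0)
      peri[[i]] <- data.frame(chrom = nm[i],
                              start = max(0L, mid - half),
                              end = min(L, mid + half),
                              stringsAsFactors = FALSE)
    centro[[i]] <- data.frame(chrom = nm[i], pos = mid,
                              stringsAsFactors = FALSE)
  }
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
  structure(list(
    chromosomes = data.frame(name = nm,
                             length = as.numeric(chrom_lengths),
                             stringsAsFactors = FALSE),
    n_mask = if (length(n_mask)) do.call(rbind, n_mask) else empty,
    pericentromere = if (length(peri)) do.call(rbind, peri) else empty,
    centromere = do.call(rbind, centro)),
    class = "ref_skeleton")
}

#' Default per-category SV mutation rates
#'
#' Events per bp per SV type: 1.9e-6 for categories A--C and INDELs,
#' 3.8e-6 for D, and 1.9e-7 for E.
#'
#' @return named numeric vector over `INDEL`, `A`..`E`
#' @export
default_sv_rates <- function() {
  c(INDEL = 1.9e-6, A = 1.9e-6, B = 1.9e-6, C = 1.9e-6,
    D = 3.8e-6, E = 1.9e-7)
}

#' Simulate a truth set of SV events
#'
#' Per chromosome, SV type and length category, the event count is drawn
#' from a Poisson distribution with mean `rate * chromosome length`;
#' lengths are uniform within the category bounds; positions are uniform
#' with rejection sampling so that no two events of the same truth set
#' overlap. Translocations are breakpoint pairs (no interval footprint);
#' they are matched downstream with a single tolerance across the whole
#' 50 bp -- 1 Mb range.
#'
#' @param ref a `ref_skeleton`
#' @param rates named per-category event rate per bp (default
#'   [default_sv_rates()])
#' @param types SV types to simulate
#' @param sample_id sample label attached to every record
#' @param seed integer seed
#' @return an `sv_records` data frame (truth calls, genotype `1/1`)
#' @export
simulate_truth_svs <- function(ref, rates = default_sv_rates(),
                               types = c("DEL", "INS", "DUP", "INV",
                                         "INDEL", "TRA"),
                               sample_id = "truth", seed = 1L) {
  if (any(rates < 0)) stop("rates must be non-negative")
  b <- length_category_bounds()
  set.seed(seed)
  rows <- list()
  for (ci in seq_len(nrow(ref$chromosomes))) {
    ch <- ref$chromosomes$name[ci]
    L <- ref$chromosomes$length[ci]
    occupied <- IRanges::IRanges()
    for (tp in types) {
      cats <- if (tp == "INDEL") "INDEL" else setdiff(names(rates), "INDEL")
      for (cat in cats) {
        rate <- if (cat %in% names(rates)) rates[[cat]] else 0
        if (rate == 0) next
        n <- stats::rpois(1, rate * L)
        if (n == 0) next
        lo <- b$lower[b$category == cat]; hi <- b$upper[b$category == cat]
        for (j in seq_len(n)) {
          len <- sample(lo:hi, 1L)
          if (tp == "TRA") {
            s <- sample.int(L - 1L, 1L)
            m <- sample.int(L - 1L, 1L)
            rows[[length(rows) + 1L]] <- data.frame(
              sample = sample_id, caller = "truth", chrom = ch,
              start = s, end = s, sv_type = "TRA", length = NA_integer_,
              genotype = "1/1", filter_pass = TRUE, tag = NA_character_,
              mate_chrom = ch, mate_pos = m, stringsAsFactors = FALSE)
            next
          }
          if (len >= L - 1) {
            warning("chromosome ", ch, " too small for a category-", cat,
                    " event; skipped")
            next
          }
          placed <- FALSE
          for (att in 1:50) {
            s <- sample.int(L - len, 1L)
            cand <- IRanges::IRanges(s + 1L, s + len)
            if (length(IRanges::findOverlaps(cand, occupied)) == 0L) {
              occupied <- c(occupied, cand)
              e <- if (tp == "INS") s else s + len
              rows[[length(rows) + 1L]] <- data.frame(
                sample = sample_id, caller = "truth", chrom = ch,
                start = s, end = e, sv_type = tp, length = len,
                genotype = "1/1", filter_pass = TRUE, tag = NA_character_,
                mate_chrom = NA_character_, mate_pos = NA_integer_,
                stringsAsFactors = FALSE)
              placed <- TRUE
              break
            }
          }
          if (!placed)
            warning("could not place a category-", cat, " ", tp,
                    " event without overlap on ", ch, "; skipped")
        }
      }
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else sv_records()
  attr(df, "rates") <- rates
  validate_sv_records(df)
}

#' Construct a caller error profile
#'
#' Describes one caller's behavior per (SV type, length category):
#' sensitivity, target precision (used to set the false-positive density),
#' Gaussian breakpoint and length jitter, heterozygous-miscall rate and
#' filter-failure rate. Scalar arguments are recycled over all
#' type/category combinations; a data frame `table` with columns
#' `sv_type`, `category` plus any of the rate columns overrides the
#' scalars for the rows it names.
#'
#' @param caller_name caller label
#' @param sensitivity,precision_target,breakpoint_jitter_sd,length_jitter_sd,het_miscall_rate,fail_filter_rate
#'   scalar defaults applied to every (sv_type, category) cell
#' @param table optional per-(sv_type, category) override data frame
#' @return a data frame of class `caller_profile`
#' @export
caller_profile <- function(caller_name, sensitivity = 0.8,
                           precision_target = 0.99,
                           breakpoint_jitter_sd = 2,
                           length_jitter_sd = 2,
                           het_miscall_rate = 0.02,
                           fail_filter_rate = 0.02,
                           table = NULL) {
  types <- c("DEL", "INS", "DUP", "INV", "TRA", "INDEL")
  cats <- c("INDEL", "A", "B", "C", "D", "E", "ABCDE")
  grid <- expand.grid(sv_type = types, category = cats,
                      stringsAsFactors = FALSE)
  grid <- grid[(grid$sv_type == "INDEL") == (grid$category == "INDEL"), ]
  grid <- grid[(grid$sv_type == "TRA") == (grid$category == "ABCDE"), ]
  grid$sensitivity <- sensitivity
  grid$precision_target <- precision_target
  grid$breakpoint_jitter_sd <- breakpoint_jitter_sd
  grid$length_jitter_sd <- length_jitter_sd
  grid$het_miscall_rate <- het_miscall_rate
  grid$fail_filter_rate <- fail_filter_rate
  if (!is.null(table)) {
    for (i in seq_len(nrow(table))) {
      sel <- grid$sv_type == table$sv_type[i] &
        grid$category == table$category[i]
      for (col in intersect(names(table),
                            c("sensitivity", "precision_target",
                              "breakpoint_jitter_sd", "length_jitter_sd",
                              "het_miscall_rate", "fail_filter_rate")))
        grid[[col]][sel] <- table[[col]][i]
    }
  }
  probs <- c("sensitivity", "precision_target", "het_miscall_rate",
             "fail_filter_rate")
  for (p in probs)
    if (any(grid[[p]] < 0 | grid[[p]] > 1))
      stop("profile probabilities must lie in [0, 1]: ", p)
  if (any(grid$breakpoint_jitter_sd < 0) || any(grid$length_jitter_sd < 0))
    stop("jitter SDs must be non-negative")
  attr(grid, "caller_name") <- caller_name
  class(grid) <- c("caller_profile", class(grid))
  grid
}

#' Simulate an imperfect call set from a truth set
#'
#' Each truth record is recovered with the profile's per-type/category
#' sensitivity; recovered breakpoints (and lengths) receive independent
#' Gaussian jitter rounded to whole bp. False positives are placed
#' uniformly at a density chosen so that the expected precision equals
#' the profile's `precision_target`. Genotypes are `1/1`, downgraded to
#' `0/1` at the heterozygous-miscall rate; the filter flag fails at the
#' filter-failure rate.
#'
#' @param truth truth `sv_records`
#' @param profile a [caller_profile()]
#' @param ref the `ref_skeleton` the truth was simulated on (used to
#'   place false positives)
#' @param seed integer seed
#' @return an `sv_records` data frame of calls
#' @export
simulate_callset <- function(truth, profile, ref, seed = 1L) {
  set.seed(seed)
  cname <- attr(profile, "caller_name")
  truth$category <- suppressWarnings(
    classify_length_category(truth$length, truth$sv_type))
  n <- nrow(truth)
  key_t <- paste(truth$sv_type, truth$category)
  key_p <- paste(profile$sv_type, profile$category)
  pi <- match(key_t, key_p)
  known <- !is.na(pi)
  sens <- rep(0, n); bp_sd <- len_sd <- rep(0, n)
  het <- fail <- rep(0, n)
  sens[known] <- profile$sensitivity[pi[known]]
  bp_sd[known] <- profile$breakpoint_jitter_sd[pi[known]]
  len_sd[known] <- profile$length_jitter_sd[pi[known]]
  het[known] <- profile$het_miscall_rate[pi[known]]
  fail[known] <- profile$fail_filter_rate[pi[known]]
  keep <- known & stats::runif(n) <= sens
  tp <- truth[keep, , drop = FALSE]
  m <- nrow(tp)
  if (m > 0L) {
    s <- as.integer(round(tp$start + stats::rnorm(m, 0, bp_sd[keep])))
    point <- tp$sv_type %in% c("INS", "TRA")
    len <- ifelse(is.na(tp$length), NA_integer_,
                  pmax(2L, as.integer(round(
                    tp$length + stats::rnorm(m, 0, len_sd[keep])))))
    e <- ifelse(point, s, s + len)
    mp <- ifelse(tp$sv_type == "TRA",
                 as.integer(round(tp$mate_pos +
                                    stats::rnorm(m, 0, bp_sd[keep]))),
                 NA_integer_)
    gt <- ifelse(stats::runif(m) < het[keep], "0/1", "1/1")
    fflag <- stats::runif(m) >= fail[keep]
    rows <- list(data.frame(
      sample = tp$sample, caller = cname, chrom = tp$chrom,
      start = s, end = as.integer(e), sv_type = tp$sv_type,
      length = as.integer(len), genotype = gt, filter_pass = fflag,
      tag = NA_character_, mate_chrom = tp$mate_chrom,
      mate_pos = as.integer(mp), stringsAsFactors = FALSE))
  } else rows <- list()
  ## false positives: expected count per (type, category) so that
  ## E[TP] / (E[TP] + E[FP]) = precision_target
  b <- length_category_bounds()
  chroms <- ref$chromosomes
  samp <- if (nrow(truth)) truth$sample[1] else "sample"
  for (tp in unique(truth$sv_type)) {
    for (cat in unique(truth$category[truth$sv_type == tp])) {
      if (is.na(cat)) next
      pr <- profile[profile$sv_type == tp & profile$category == cat, ,
                    drop = FALSE]
      if (nrow(pr) == 0L || pr$precision_target >= 1 ||
          pr$precision_target <= 0) next
      n_truth <- sum(truth$sv_type == tp & truth$category == cat,
                     na.rm = TRUE)
      exp_tp <- pr$sensitivity * n_truth
      if (exp_tp <= 0) next
      n_fp <- stats::rpois(1, exp_tp * (1 - pr$precision_target) /
                             pr$precision_target)
      if (n_fp == 0) next
      lo <- b$lower[b$category == cat]; hi <- b$upper[b$category == cat]
      if (length(lo) == 0L) { lo <- 50; hi <- 1e6 }   # TRA: whole range
      for (j in seq_len(n_fp)) {
        ci <- sample.int(nrow(chroms), 1L)
        L <- chroms$length[ci]
        len <- sample(lo:min(hi, L - 2), 1L)
        s <- sample.int(max(1, L - len), 1L)
        e <- if (tp %in% c("INS", "TRA")) s else s + len
        rows[[length(rows) + 1L]] <- data.frame(
          sample = samp, caller = cname, chrom = chroms$name[ci],
          start = s, end = e, sv_type = tp,
          length = if (tp == "TRA") NA_integer_ else as.integer(len),
          genotype = "1/1", filter_pass = TRUE, tag = NA_character_,
          mate_chrom = if (tp == "TRA") chroms$name[ci] else NA_character_,
          mate_pos = if (tp == "TRA") sample.int(L - 1L, 1L)
                     else NA_integer_,
          stringsAsFactors = FALSE)
      }
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else sv_records()
  validate_sv_records(df)
}

#' Cohort specification for the synthetic inbred panel
#'
#' @param n_samples number of inbred lines (default 23)
#' @param prop_singleton proportion of SV loci carried by exactly one
#'   line (default 0.5, emulating the roughly half-singleton site
#'   frequency spectrum seen in diverse inbred panels)
#' @param beta_shape1,beta_shape2 Beta parameters for the carrier
#'   frequency of non-singleton loci
#' @return a list of class `cohort_spec`
#' @export
cohort_spec <- function(n_samples = 23L, prop_singleton = 0.5,
                        beta_shape1 = 0.6, beta_shape2 = 3) {
  if (n_samples < 2) stop("n_samples must be >= 2")
  if (prop_singleton < 0 || prop_singleton > 1)
    stop("prop_singleton must be in [0, 1]")
  structure(list(n_samples = as.integer(n_samples),
                 prop_singleton = prop_singleton,
                 beta_shape1 = beta_shape1, beta_shape2 = beta_shape2),
            class = "cohort_spec")
}

#' Simulate a full cohort: genotypes, expression and phenotypes
#'
#' Draws SV loci on the reference skeleton, assigns each locus a
#' presence/absence vector over the cohort (singletons with probability
#' `prop_singleton`, otherwise a Beta-distributed carrier frequency),
#' derives per-sample truth sets, builds a log-normal expression matrix in
#' which a fraction of gene-associated loci shift the expression of their
#' gene, and generates replicated multi-environment phenotypes
#' `y_ijk = mu + E_j + G_i + (GxE)_ij + e_ijk` where the genotypic value
#' `G_i` is a linear combination of SV presence scaled to entry-mean
#' heritability `h2`.
#'
#' @param ref a `ref_skeleton`
#' @param spec a [cohort_spec()]
#' @param annotation a `genome_annotation` supplying the genes, or `NULL`
#'   to skip the expression layer
#' @param sv_expr_effect SD of the expression effect (log2 units) added
#'   per carried copy of an effect locus
#' @param prop_effect_loci fraction of gene-associated loci that carry an
#'   expression effect (default 0.3)
#' @param h2 entry-mean heritability of the simulated trait, in `[0, 1]`
#' @param n_env number of environments
#' @param n_rep number of replicates per environment
#' @param n_causal number of SV loci contributing to the genotypic value
#' @param rates per-category locus rates (default [default_sv_rates()])
#' @param seed integer seed
#' @return a list with `loci` (truth `sv_records` of the segregating
#'   loci), `presence` (loci x samples 0/1 matrix), `sample_truth`
#'   (named list of per-sample `sv_records`), `expression` (genes x
#'   samples matrix), `effect_loci` (data frame locus, gene, beta),
#'   `phenotypes` (long data frame genotype, environment, replicate,
#'   value), `true_g` (named genotypic values)
#' @export
simulate_cohort_omics <- function(ref, spec = cohort_spec(),
                                  annotation = NULL,
                                  sv_expr_effect = 1,
                                  prop_effect_loci = 0.3,
                                  h2 = 0.5, n_env = 7L, n_rep = 2L,
                                  n_causal = 50L,
                                  rates = default_sv_rates(),
                                  seed = 1L) {
  if (h2 < 0 || h2 > 1) stop("h2 must lie in [0, 1]")
  set.seed(seed)
  loci <- simulate_truth_svs(ref, rates,
                             types = c("DEL", "INS", "DUP", "INV"),
                             sample_id = "locus",
                             seed = sample.int(2^30, 1))
  n_loci <- nrow(loci)
  n <- spec$n_samples
  samples <- sprintf("inbred%02d", seq_len(n))
  presence <- matrix(0L, n_loci, n,
                     dimnames = list(sprintf("locus%05d", seq_len(n_loci)),
                                     samples))
  for (l in seq_len(n_loci)) {
    if (stats::runif(1) < spec$prop_singleton) {
      presence[l, sample.int(n, 1L)] <- 1L
    } else {
      repeat {
        f <- stats::rbeta(1, spec$beta_shape1, spec$beta_shape2)
        v <- stats::rbinom(n, 1L, f)
        if (sum(v) >= 1L) break
      }
      presence[l, ] <- v
    }
  }
  sample_truth <- lapply(samples, function(s) {
    sel <- presence[, s] == 1L
    df <- loci[sel, , drop = FALSE]
    if (nrow(df)) df$sample <- s
    validate_sv_records(df)
  })
  names(sample_truth) <- samples

  expression <- NULL; effect_loci <- NULL
  if (!is.null(annotation) && nrow(annotation$genes) > 0L) {
    genes <- annotation$genes$gene_id
    base <- stats::rnorm(length(genes), 5, 2)
    logexp <- matrix(stats::rnorm(length(genes) * n, 0, 0.5),
                     length(genes), n,
                     dimnames = list(genes, samples)) + base
    ctx <- classify_gene_association(
      data.frame(id = rownames(presence), chrom = loci$chrom,
                 start = loci$start, end = loci$end,
                 sv_type = loci$sv_type, stringsAsFactors = FALSE),
      annotation)
    ga <- ctx[ctx$label != "intergenic" & !is.na(ctx$gene_id), ,
              drop = FALSE]
    ga <- ga[!duplicated(paste(ga$id, ga$gene_id)), , drop = FALSE]
    if (nrow(ga) > 0L) {
      take <- stats::runif(nrow(ga)) < prop_effect_loci
      ga <- ga[take, , drop = FALSE]
      if (nrow(ga) > 0L) {
        beta <- sv_expr_effect * stats::rnorm(nrow(ga))
        for (i in seq_len(nrow(ga))) {
          g <- ga$gene_id[i]
          logexp[g, ] <- logexp[g, ] + beta[i] * presence[ga$id[i], ]
        }
        effect_loci <- data.frame(locus = ga$id, gene = ga$gene_id,
                                  beta = beta, stringsAsFactors = FALSE)
      }
    }
    expression <- 2^logexp
  }

  ## phenotypes: G_i from n_causal loci, standardized, scaled to h2 on the
  ## entry-mean level; non-genetic entry-mean variance (1 - h2) is split
  ## half into GxE and half into plot error
  causal <- sample.int(n_loci, min(n_causal, n_loci))
  w <- stats::rnorm(length(causal))
  g_raw <- as.numeric(t(presence[causal, , drop = FALSE]) %*% w)
  g <- if (h2 == 0 || stats::sd(g_raw) == 0) rep(0, n)
       else sqrt(h2) * (g_raw - mean(g_raw)) / stats::sd(g_raw)
  names(g) <- samples
  v_gxe <- (1 - h2) * n_env / 2
  v_eps <- (1 - h2) * n_env * n_rep / 2
  envs <- sprintf("env%d", seq_len(n_env))
  env_eff <- stats::rnorm(n_env, 0, 1)
  gxe <- matrix(stats::rnorm(n * n_env, 0, sqrt(v_gxe)), n, n_env)
  ph <- expand.grid(genotype = samples, environment = envs,
                    replicate = seq_len(n_rep), stringsAsFactors = FALSE)
  gi <- match(ph$genotype, samples); ej <- match(ph$environment, envs)
  ph$value <- 10 + env_eff[ej] + g[gi] + gxe[cbind(gi, ej)] +
    stats::rnorm(nrow(ph), 0, sqrt(v_eps))
  list(loci = loci, presence = presence, sample_truth = sample_truth,
       expression = expression, effect_loci = effect_loci,
       phenotypes = ph, true_g = g)
}
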