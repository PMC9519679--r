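test_that("reference skeleton is deterministic and honors the pericentromere fraction", {
  ref1 <- simulate_reference(1e7, seed = 5)
  ref2 <- simulate_reference(1e7, seed = 5)
  expect_identical(ref1, ref2)
  peri <- ref1$pericentromere
  expect_equal(sum(peri$end - peri$start), 0.257 * 1e7, tolerance = 1e-6)
  ref0 <- simulate_reference(1e7, pericentromere_fraction = 0, seed = 5)
  expect_identical(nrow(ref0$pericentromere), 0L)
  expect_error(simulate_reference(5e4), ">= 1e5")
})

test_that("reference intervals lie within the chromosome", {
  ref <- simulate_reference(c(chrA = 2e6, chrB = 5e6), seed = 9)
  for (track in list(ref$n_mask, ref$pericentromere)) {
    if (nrow(track) == 0L) next
    L <- ref$chromosomes$length[match(track$chrom, ref$chromosomes$name)]
    expect_true(all(track$start >= 0))
    expect_true(all(track$end <= L))
  }
})

test_that("truth simulation respects rates, bounds, and determinism", {
  ref <- simulate_reference(1e7, seed = 2)
  expect_identical(nrow(simulate_truth_svs(ref, rates = c(A = 0), seed = 3)),
                   0L)
  t1 <- suppressWarnings(simulate_truth_svs(ref, seed = 4))
  t2 <- suppressWarnings(simulate_truth_svs(ref, seed = 4))
  expect_identical(t1, t2)
  dd <- t1[t1$sv_type == "DEL", ]
  cat_d <- suppressWarnings(classify_length_category(dd$length))
  expect_true(all(dd$length[cat_d == "D"] > 50000 &
                    dd$length[cat_d == "D"] <= 250000))
})

test_that("category-A truth counts follow the Poisson law over seeds", {
  ref <- simulate_reference(1e7, seed = 1)
  n_seeds <- 60
  counts <- vapply(seq_len(n_seeds), function(s) {
    tr <- suppressWarnings(
      simulate_truth_svs(ref, rates = c(A = 1.9e-6), types = "DEL",
                         seed = s))
    nrow(tr)
  }, numeric(1))
  ## expected 19 events per seed; the summed count over seeds is
  ## Poisson(19 * n_seeds) up to rare placement rejections
  lambda <- 1.9e-6 * 1e7 * n_seeds
  expect_gte(sum(counts), qpois(0.005, lambda))
  expect_lte(sum(counts), qpois(0.995, lambda))
})

test_that("same-sample truth events never overlap", {
  ref <- simulate_reference(5e6, seed = 7)
  tr <- suppressWarnings(simulate_truth_svs(ref, types = "DEL", seed = 8))
  tr <- tr[order(tr$start), ]
  expect_true(all(tr$start[-1] >= tr$end[-nrow(tr)]))
})

test_that("identity profile reproduces truth coordinates exactly", {
  ref <- simulate_reference(1e7, seed = 11)
  tr <- suppressWarnings(simulate_truth_svs(
    ref, rates = c(A = 2e-6, B = 2e-6), types = c("DEL", "INS"), seed = 12))
  prof <- caller_profile("perfect", sensitivity = 1, precision_target = 1,
                         breakpoint_jitter_sd = 0, length_jitter_sd = 0,
                         het_miscall_rate = 0, fail_filter_rate = 0)
  cs <- simulate_callset(tr, prof, ref, seed = 13)
  expect_identical(nrow(cs), nrow(tr))
  expect_identical(cs$start, tr$start)
  expect_identical(cs$end, tr$end)
  expect_identical(cs$length, tr$length)
  expect_true(all(cs$genotype == "1/1"))
  expect_true(all(cs$filter_pass))
})

test_that("emission rate converges to the profile sensitivity", {
  ref <- simulate_reference(2e7, seed = 14)
  tr <- suppressWarnings(simulate_truth_svs(ref, rates = c(A = 5e-5),
                                            types = "DEL", seed = 15))
  prof <- caller_profile("c", sensitivity = 0.8, precision_target = 1,
                         het_miscall_rate = 0, fail_filter_rate = 0)
  frac <- vapply(1:60, function(s)
    nrow(simulate_callset(tr, prof, ref, seed = s)) / nrow(tr), numeric(1))
  expect_equal(mean(frac), 0.8, tolerance = 0.01)
})

test_that("measured precision converges to the precision target", {
  ref <- simulate_reference(2e7, seed = 16)
  tr <- suppressWarnings(simulate_truth_svs(ref, rates = c(A = 5e-5),
                                            types = "DEL", seed = 17))
  prof <- caller_profile("c", sensitivity = 0.8, precision_target = 0.75,
                         het_miscall_rate = 0, fail_filter_rate = 0)
  prec <- vapply(1:30, function(s) {
    cs <- simulate_callset(tr, prof, ref, seed = s)
    compute_metrics(match_calls(tr, cs, "DEL"))$precision
  }, numeric(1))
  expect_equal(mean(prec), 0.75, tolerance = 0.02)
})

test_that("caller profiles validate their probabilities and overrides", {
  expect_error(caller_profile("c", sensitivity = 1.2), "\\[0, 1\\]")
  expect_error(caller_profile("c", breakpoint_jitter_sd = -1),
               "non-negative")
  prof <- caller_profile("c", sensitivity = 0.5,
                         table = data.frame(sv_type = "DEL", category = "A",
                                            sensitivity = 0.9))
  expect_equal(prof$sensitivity[prof$sv_type == "DEL" &
                                  prof$category == "A"], 0.9)
  expect_equal(prof$sensitivity[prof$sv_type == "DEL" &
                                  prof$category == "B"], 0.5)
})

test_that("cohort simulation controls the singleton share and h2 = 0", {
  ref <- simulate_reference(1e7, seed = 21)
  spec <- cohort_spec(n_samples = 23)
  coh <- suppressWarnings(simulate_cohort_omics(
    ref, spec, rates = c(A = 5e-5), h2 = 0, seed = 22))
  expect_true(all(coh$true_g == 0))
  expect_identical(dim(coh$presence), c(nrow(coh$loci), 23L))
  expect_true(all(rowSums(coh$presence) >= 1))
  single <- mean(rowSums(coh$presence) == 1)
  n_loci <- nrow(coh$presence)
  ## loci drawn singleton with p = 0.5 plus occasional Beta-draws of one
  ## carrier; the share must sit at or a little above 0.5
  expect_gte(single, qbinom(0.005, n_loci, 0.5) / n_loci)
  expect_lte(single, 0.65)
  expect_error(simulate_cohort_omics(ref, spec, h2 = 1.5), "h2")
})

test_that("non-singleton carrier counts follow the conditional Beta-binomial", {
  ref <- simulate_reference(1e7, seed = 23)
  spec <- cohort_spec(n_samples = 23, prop_singleton = 0)
  counts <- integer(0)
  for (s in 1:5) {
    coh <- suppressWarnings(simulate_cohort_omics(
      ref, spec, rates = c(A = 5e-5), h2 = 0, seed = s))
    counts <- c(counts, rowSums(coh$presence))
  }
  ## expected pmf: P(k) proportional to integral Beta(f;0.6,3) Binom(k;23,f),
  ## conditioned on k >= 1
  pk <- vapply(1:23, function(k)
    integrate(function(f) dbeta(f, 0.6, 3) * dbinom(k, 23, f), 0, 1)$value,
    numeric(1))
  pk <- pk / sum(pk)
  obs <- tabulate(counts, nbins = 23)
  grp <- pmin(counts, 8)          # pool the sparse tail
  obs_g <- tabulate(grp, nbins = 8)
  exp_g <- c(pk[1:7], sum(pk[8:23])) * length(counts)
  chi2 <- sum((obs_g - exp_g)^2 / exp_g)
  expect_lte(chi2, qchisq(0.99, df = 7))
})

test_that("cohort phenotypes decompose as specified and are reproducible", {
  ref <- simulate_reference(1e7, seed = 25)
  ann <- toy_annotation()
  ann$chrom_lengths <- c(chr1 = 1e7)
  coh1 <- suppressWarnings(simulate_cohort_omics(
    ref, cohort_spec(), annotation = ann, rates = c(A = 5e-5),
    h2 = 0.5, n_env = 4, n_rep = 2, seed = 26))
  coh2 <- suppressWarnings(simulate_cohort_omics(
    ref, cohort_spec(), annotation = ann, rates = c(A = 5e-5),
    h2 = 0.5, n_env = 4, n_rep = 2, seed = 26))
  expect_identical(coh1$phenotypes, coh2$phenotypes)
  ph <- coh1$phenotypes
  expect_identical(nrow(ph), 23L * 4L * 2L)
  expect_true(all(coh1$expression >= 0))
  ## genotypic values standardized to (sample) variance h2
  expect_equal(var(coh1$true_g), 0.5, tolerance = 1e-8)
})
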