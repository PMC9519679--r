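test_that("gene-context labels follow the 5 kb, exon and intron definitions", {
  ann <- toy_annotation()
  ## g1: + strand, body 20000-26000, exons 20000-21000 and 24000-26000,
  ## intron 21000-24000
  clusters <- data.frame(
    id = c("junction", "far_up", "in_up5k", "inter"),
    chrom = "chr1",
    start = c(20900L, 13000L, 16000L, 40000L),
    end = c(21200L, 13400L, 16400L, 40400L),
    stringsAsFactors = FALSE)
  out <- classify_gene_association(clusters, ann)
  lab <- function(id) sort(out$label[out$id == id])
  expect_identical(lab("junction"), c("exon", "intron"))
  expect_identical(lab("far_up"), "intergenic")   # 6-7 kb upstream of g1
  expect_identical(lab("in_up5k"), "up5k")
  expect_identical(lab("inter"), "intergenic")
  ## intergenic is exclusive of every gene-associated label
  for (id in unique(out$id)) {
    l <- out$label[out$id == id]
    expect_true(!("intergenic" %in% l) || length(l) == 1L)
  }
})

test_that("up/downstream windows are strand-aware", {
  ann <- toy_annotation()
  ## g2: - strand, body 60000-64000 => up5k is [64000, 69000),
  ## down5k is [55000, 60000)
  clusters <- data.frame(id = c("right_of_g2", "left_of_g2"),
                         chrom = "chr1",
                         start = c(65000L, 56000L),
                         end = c(65200L, 56200L),
                         stringsAsFactors = FALSE)
  out <- classify_gene_association(clusters, ann)
  expect_identical(out$label[out$id == "right_of_g2"], "up5k")
  expect_identical(out$label[out$id == "left_of_g2"], "down5k")
})

test_that("unknown cluster chromosome raises a lookup error", {
  ann <- toy_annotation()
  bad <- data.frame(id = "x", chrom = "chr9", start = 1L, end = 2L,
                    stringsAsFactors = FALSE)
  expect_error(classify_gene_association(bad, ann), "absent")
})

test_that("TE reciprocal-overlap rule matches the worked examples", {
  te <- data.frame(chrom = "chr1", start = 1100L, end = 2050L,
                   stringsAsFactors = FALSE)
  del <- data.frame(chrom = "chr1", start = 1000L, end = 2000L,
                    sv_type = "DEL", length = 1000L,
                    mate_chrom = NA_character_, mate_pos = NA_integer_,
                    stringsAsFactors = FALSE)
  ## overlap 900 bp: 0.90 of the SV and 0.947 of the TE -> TE-derived
  expect_true(annotate_te(del, te))
  te_low <- data.frame(chrom = "chr1", start = 1300L, end = 2300L,
                       stringsAsFactors = FALSE)
  ## overlap 700 bp = 0.70 of the SV -> not TE
  expect_false(annotate_te(del, te_low))
})

test_that("insertion and translocation TE rules use breakpoints", {
  te <- data.frame(chrom = "chr1", start = 5000L, end = 6000L,
                   stringsAsFactors = FALSE)
  ins <- data.frame(chrom = "chr1", start = c(5500L, 7000L),
                    end = c(5500L, 7000L), sv_type = "INS",
                    length = NA_integer_, mate_chrom = NA_character_,
                    mate_pos = NA_integer_, stringsAsFactors = FALSE)
  expect_identical(annotate_te(ins, te), c(TRUE, FALSE))
  tra <- data.frame(chrom = "chr1", start = c(100L, 100L),
                    end = c(100L, 100L), sv_type = "TRA", length = NA_integer_,
                    mate_chrom = "chr1", mate_pos = c(5500L, 8000L),
                    stringsAsFactors = FALSE)
  expect_identical(annotate_te(tra, te), c(TRUE, FALSE))
})

test_that("annotate_te agrees with a brute-force scan on random instances", {
  set.seed(41)
  for (i in 1:10) {
    n_cl <- 80; n_te <- 60
    st <- sample(0:100000, n_cl)
    len <- sample(50:2000, n_cl, TRUE)
    clusters <- data.frame(chrom = sample(c("chr1", "chr2"), n_cl, TRUE),
                           start = st, end = st + len, sv_type = "DEL",
                           length = len, mate_chrom = NA_character_,
                           mate_pos = NA_integer_, stringsAsFactors = FALSE)
    ts <- sample(0:100000, n_te)
    te <- data.frame(chrom = sample(c("chr1", "chr2"), n_te, TRUE),
                     start = ts, end = ts + sample(50:2000, n_te, TRUE),
                     stringsAsFactors = FALSE)
    expect_identical(annotate_te(clusters, te),
                     brute_force_te(clusters, te))
  }
})

test_that("hotspot threshold follows the Poisson 99th percentile", {
  ## counts 7,1,2,2,2,2,2,1,0,1 over ten 1 Mb windows: lambda = 2,
  ## q99 = 6, only the first window (count 7 > 6) is a hotspot
  counts <- c(7, 1, 2, 2, 2, 2, 2, 1, 0, 1)
  pos <- unlist(lapply(seq_along(counts), function(w)
    (w - 1) * 1e6 + seq_len(counts[w]) * 1000))
  clusters <- data.frame(chrom = "chr1", start = pos,
                         stringsAsFactors = FALSE)
  hs <- detect_hotspots(clusters, c(chr1 = 1e7))
  expect_equal(unname(hs$lambda), 2)
  expect_identical(unique(hs$windows$q99), 6)
  expect_identical(which(hs$windows$hotspot), 1L)
  ## cumulative pmf oracle for q99(2) = 6
  expect_lt(sum(dpois(0:5, 2)), 0.99)
  expect_gte(sum(dpois(0:6, 2)), 0.99)
})

test_that("constant integer counts yield no hotspots and q99 is monotone", {
  pos <- unlist(lapply(0:9, function(w) w * 1e6 + (1:3) * 1000))
  hs <- detect_hotspots(data.frame(chrom = "chr1", start = pos),
                        c(chr1 = 1e7))
  expect_false(any(hs$windows$hotspot))
  lam <- seq(0.2, 20, by = 0.2)
  expect_true(all(diff(qpois(0.99, lam)) >= 0))
})

test_that("short chromosomes produce a single truncated window with a message", {
  expect_message(
    hs <- detect_hotspots(data.frame(chrom = "tiny", start = c(1, 2)),
                          c(tiny = 5e5)),
    "truncated")
  expect_identical(nrow(hs$windows), 1L)
  expect_equal(hs$windows$end, 5e5)
})

test_that("pericentromeric hotspot fraction is reported", {
  counts <- c(9, 1, 1, 1, 9, 1, 1, 1, 1, 1)
  pos <- unlist(lapply(seq_along(counts), function(w)
    (w - 1) * 1e6 + seq_len(counts[w]) * 1000))
  peri <- data.frame(chrom = "chr1", start = 4e6, end = 6e6,
                     stringsAsFactors = FALSE)
  hs <- detect_hotspots(data.frame(chrom = "chr1", start = pos),
                        c(chr1 = 1e7), pericentromere = peri)
  ## two hotspot windows (counts 9); the one starting at 4 Mb is
  ## pericentromeric
  expect_identical(sum(hs$windows$hotspot), 2L)
  expect_equal(hs$peri_hotspot_fraction, 0.5)
})

test_that("TSS profile is strand-oriented and covers spanned offsets", {
  ann <- toy_annotation()
  ## g2 is on the - strand with TSS at 63999; a variant 100 bp 5' of the
  ## TSS sits at genomic 64099 and must appear at offset -100
  clusters <- data.frame(chrom = "chr1", start = 64099L, end = 64100L,
                         stringsAsFactors = FALSE)
  prof <- tss_profile(clusters, data.frame(chrom = character(),
                                           pos = integer()), ann)
  expect_identical(prof$sv_count[prof$offset == -100], 1)
  ## an SV spanning the TSS of g1 (+ strand, TSS 20000) covers every
  ## offset of its interval
  span <- data.frame(chrom = "chr1", start = 19990L, end = 20011L,
                     stringsAsFactors = FALSE)
  prof2 <- tss_profile(span, data.frame(chrom = character(),
                                        pos = integer()), ann)
  expect_true(all(prof2$sv_count[prof2$offset %in% -10:10] >= 1))
  expect_equal(sum(prof2$sv_count), 21)
  ## no variants -> all-zero profile
  prof0 <- tss_profile(data.frame(chrom = character(), start = integer(),
                                  end = integer()),
                       data.frame(chrom = character(), pos = integer()),
                       ann)
  expect_true(all(prof0$sv_count == 0) && all(prof0$snv_count == 0))
})
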