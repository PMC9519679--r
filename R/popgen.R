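#' Linkage disequilibrium r-squared between two biallelic variants
#'
#' Inbred lines are treated as haploid haplotypes (presence/absence
#' coding), so `r^2 = D^2 / (pA qA pB qB)` with `D = pAB - pA pB` computed
#' on haplotype frequencies -- identical to the squared Pearson
#' correlation of the 0/1 vectors on the shared non-missing samples.
#'
#' @param a,b numeric/integer 0/1 vectors over the same samples; `NA`
#'   allowed
#' @return r-squared in `[0, 1]`, or `NA` when either vector is
#'   monomorphic on the shared non-missing samples or fewer than two
#'   shared samples remain
#' @examples
#' ld_r2(c(1, 1, 0, 0), c(1, 1, 1, 0))  # 1/3
#' @export
ld_r2 <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length")
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 2L) return(NA_real_)
  a <- a[ok]; b <- b[ok]
  pa <- mean(a); pb <- mean(b)
  if (pa %in% c(0, 1) || pb %in% c(0, 1)) return(NA_real_)
  d <- mean(a * b) - pa * pb
  d^2 / (pa * (1 - pa) * pb * (1 - pb))
}

#' Fraction of SV clusters (and of their closest SNV) tagged by nearby SNV
#'
#' For each SV cluster, tests whether any SNV within `window` bp of the
#' cluster's representative start reaches `r^2 >= threshold` with the
#' cluster's presence vector; the analysis is repeated with the cluster's
#' closest SNV as the focal variant (against the other SNV in the same
#' window). Clusters with no SNV in the window (or, for the SNV-focal
#' pass, no second SNV) are excluded from the respective denominator.
#'
#' @param cluster_pos numeric vector of cluster representative positions
#' @param presence clusters x samples 0/1 matrix (rows follow
#'   `cluster_pos`)
#' @param snv_pos numeric vector of SNV positions (same chromosome),
#'   sorted or not
#' @param snv_geno SNV x samples 0/1 matrix (rows follow `snv_pos`)
#' @param window search window in bp (default 1000)
#' @param threshold r-squared threshold (default 0.6)
#' @return a list with `sv_fraction`, `snv_fraction`, `n_sv_tested`,
#'   `n_snv_tested`
#' @export
ld_linkage_summary <- function(cluster_pos, presence, snv_pos, snv_geno,
                               window = 1000, threshold = 0.6) {
  ord <- order(snv_pos)
  snv_pos <- snv_pos[ord]
  snv_geno <- snv_geno[ord, , drop = FALSE]
  sv_hit <- logical(0); snv_hit <- logical(0)
  for (i in seq_along(cluster_pos)) {
    lo <- findInterval(cluster_pos[i] - window - 0.5, snv_pos) + 1L
    hi <- findInterval(cluster_pos[i] + window + 0.5, snv_pos)
    if (hi < lo) next
    idx <- lo:hi
    r2 <- vapply(idx, function(j) ld_r2(presence[i, ], snv_geno[j, ]),
                 numeric(1))
    sv_hit <- c(sv_hit, any(r2 >= threshold, na.rm = TRUE))
    if (length(idx) >= 2L) {
      focal <- idx[which.min(abs(snv_pos[idx] - cluster_pos[i]))]
      others <- setdiff(idx, focal)
      r2f <- vapply(others, function(j)
        ld_r2(snv_geno[focal, ], snv_geno[j, ]), numeric(1))
      snv_hit <- c(snv_hit, any(r2f >= threshold, na.rm = TRUE))
    }
  }
  list(sv_fraction = if (length(sv_hit)) mean(sv_hit) else NA_real_,
       snv_fraction = if (length(snv_hit)) mean(snv_hit) else NA_real_,
       n_sv_tested = length(sv_hit), n_snv_tested = length(snv_hit))
}

#' Windowed nucleotide diversity for presence/absence variants
#'
#' Per-site diversity uses the unbiased estimator for `n` haploid
#' sequences, `pi_site = (n / (n - 1)) * 2 p (1 - p)` (equivalently
#' `2 k (n - k) / (n (n - 1))` with `k` carriers), summed over variant
#' sites per window and divided by the window length.
#'
#' @param pos variant positions
#' @param carriers number of samples carrying the variant at each
#'   position
#' @param n total number of (non-missing) samples; must be >= 2
#' @param chrom_length chromosome length in bp
#' @param window window size in bp (default 1e5)
#' @return data frame `start`, `end`, `pi`
#' @export
pi_windows <- function(pos, carriers, n, chrom_length, window = 1e5) {
  if (n < 2) stop("nucleotide diversity needs at least 2 samples")
  p <- carriers / n
  site_pi <- (n / (n - 1)) * 2 * p * (1 - p)
  n_win <- max(1L, ceiling(chrom_length / window))
  wi <- pmin(floor(pos / window) + 1L, n_win)
  sums <- vapply(seq_len(n_win), function(k) sum(site_pi[wi == k]),
                 numeric(1))
  starts <- (seq_len(n_win) - 1) * window
  ends <- pmin(starts + window, chrom_length)
  data.frame(start = starts, end = ends, pi = sums / (ends - starts))
}

#' Correlation between two windowed diversity tracks
#'
#' @param pi_a,pi_b data frames as returned by [pi_windows()] over the
#'   same windows
#' @return Pearson correlation of the `pi` columns over shared windows
#' @export
pi_track_correlation <- function(pi_a, pi_b) {
  m <- merge(pi_a, pi_b, by = c("start", "end"))
  stats::cor(m$pi.x, m$pi.y)
}
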