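#' Scan configuration
#'
#' Window and threshold settings shared by the diversity, F_ST and XP-EHH
#' scans. Defaults resolve a ~130-kb sweep with at least six overlapping
#' windows inside it.
#'
#' @param window_bp window span in bp.
#' @param step_bp step between window starts (sliding windows when
#'   `step_bp < window_bp`).
#' @param top_quantile genome-wide empirical outlier quantile (0.95 flags
#'   the top 5% of windows).
#' @param min_sites_per_window windows with fewer segregating sites get NaN.
#' @param ehh_truncation EHH value at which haplotype extension stops.
#' @param max_gap_bp EHH extension is cut where adjacent sites are farther
#'   apart than this.
#' @param edge_policy what to do when EHH never drops below
#'   `ehh_truncation` before the chromosome edge: `"clip"` keeps the
#'   partial integral (clips are counted), `"discard"` yields NaN.
#' @param core_maf_min minimum pooled MAF for a site to serve as an XP-EHH
#'   core.
#' @return a `scan_config` list.
#' @export
scan_config <- function(window_bp = 20000, step_bp = 2000, top_quantile = 0.95,
                        min_sites_per_window = 3, ehh_truncation = 0.05,
                        max_gap_bp = 200000, edge_policy = c("clip", "discard"),
                        core_maf_min = 0.05) {
  if (!(step_bp > 0 && step_bp <= window_bp)) abort("need 0 < step_bp <= window_bp")
  if (!(top_quantile > 0.5 && top_quantile < 1)) abort("top_quantile must be in (0.5, 1)")
  structure(list(window_bp = as.integer(window_bp), step_bp = as.integer(step_bp),
                 top_quantile = top_quantile,
                 min_sites_per_window = as.integer(min_sites_per_window),
                 ehh_truncation = ehh_truncation, max_gap_bp = max_gap_bp,
                 edge_policy = match.arg(edge_policy),
                 core_maf_min = core_maf_min),
            class = "scan_config")
}

#' Sliding windows along a chromosome
#'
#' 0-based half-open windows `[start0, end)` from 0 to `chrom_length_bp`;
#' the terminal window may be shorter.
#'
#' @param chrom chromosome name.
#' @param chrom_length_bp chromosome length.
#' @param config a [scan_config()].
#' @return tibble `chrom`, `start0`, `end`.
#' @export
make_windows <- function(chrom, chrom_length_bp, config = scan_config()) {
  starts <- seq(0L, max(0L, chrom_length_bp - 1L), by = config$step_bp)
  starts <- starts[starts < chrom_length_bp]
  tibble::tibble(chrom = chrom, start0 = as.integer(starts),
                 end = as.integer(pmin(starts + config$window_bp, chrom_length_bp)))
}

#' Per-site nucleotide diversity
#'
#' Mean number of pairwise differences at one site among `n` sampled
#' chromosomes of which `k` carry the alternate allele:
#' `2 k (n - k) / (n (n - 1))`.
#'
#' @param k alternate-allele count(s).
#' @param n non-missing chromosome count(s), `n >= 2`.
#' @return numeric, same length as `k`.
#' @export
site_pi <- function(k, n) {
  if (any(n < 2)) abort("site_pi needs n >= 2 chromosomes")
  if (any(k < 0 | k > n)) abort("need 0 <= k <= n")
  2 * k * (n - k) / (n * (n - 1))
}

# sum of per-site values over each window, via cumulative sums on the
# (sorted) site positions; also returns the per-window segregating count
window_sums <- function(windows, pos, values, seg) {
  cs_val <- c(0, cumsum(values))
  cs_seg <- c(0, cumsum(as.numeric(seg)))
  lo <- findInterval(windows$start0, pos)       # sites with pos <= start0
  hi <- findInterval(windows$end, pos)          # sites with pos <= end
  list(sum = cs_val[hi + 1L] - cs_val[lo + 1L],
       n_seg = as.integer(cs_seg[hi + 1L] - cs_seg[lo + 1L]))
}

#' Windowed nucleotide diversity
#'
#' Sums [site_pi()] over the sites of each window and divides by the full
#' window span in bp. Windows covering fewer segregating (cohort-variant)
#' sites than `config$min_sites_per_window` are NaN: the gate guards
#' against data-sparse windows, while a window that is well covered but
#' monomorphic *within* the population legitimately reports zero
#' diversity (the hallmark of a swept region).
#'
#' @param x a [hap_matrix].
#' @param pop_map tibble `accession`, `subpop`.
#' @param pop subpopulation code(s) defining the chromosome set.
#' @param config a [scan_config()].
#' @param chrom_length_bp chromosome length; defaults to the last site
#'   position.
#' @param stat_name track label, default `pi_<pop>`.
#' @return a stat-track tibble `chrom`, `start0`, `end`, `stat`, `value`,
#'   `n_sites`.
#' @export
windowed_pi <- function(x, pop_map, pop, config = scan_config(),
                        chrom_length_bp = NULL,
                        stat_name = paste0("pi_", paste(pop, collapse = ""))) {
  rows <- pop_rows(x, pop_map, pop)
  if (length(rows) < 2) abort("need >= 2 chromosomes for pi")
  a <- x$alleles[rows, , drop = FALSE]
  n <- colSums(!is.na(a))
  k <- colSums(a, na.rm = TRUE)
  ok <- n >= 2
  pi_site <- numeric(ncol(a))
  pi_site[ok] <- site_pi(k[ok], n[ok])
  seg <- site_maf(x) > 0  # variant in the cohort, not just in this pop

  if (is.null(chrom_length_bp)) chrom_length_bp <- max(x$sites$pos)
  win <- make_windows(x$sites$chrom[1], chrom_length_bp, config)
  ws <- window_sums(win, x$sites$pos, pi_site, seg)
  value <- ws$sum / (win$end - win$start0)
  value[ws$n_seg < config$min_sites_per_window] <- NaN
  as_stat_track(tibble::tibble(win, stat = stat_name, value = value,
                               n_sites = ws$n_seg))
}

#' Diversity ratio between two populations
#'
#' `pi_A / pi_B` per window; elevated values point to reduced diversity in
#' population B (e.g. a sweep in cultivars when A is wild). NaN where
#' `pi_B` is zero or either input is NaN.
#'
#' @param track_a,track_b stat tracks on identical windows.
#' @param stat_name track label.
#' @return a stat-track tibble.
#' @export
pi_ratio <- function(track_a, track_b, stat_name = "pi_ratio") {
  if (!identical(track_a[c("chrom", "start0", "end")],
                 track_b[c("chrom", "start0", "end")])) {
    abort("tracks must share identical windows")
  }
  value <- ifelse(is.na(track_a$value) | is.na(track_b$value) | track_b$value == 0,
                  NaN, track_a$value / track_b$value)
  as_stat_track(tibble::tibble(track_a[c("chrom", "start0", "end")],
                               stat = stat_name, value = value,
                               n_sites = pmin(track_a$n_sites, track_b$n_sites)))
}

#' Hudson F_ST components at one site
#'
#' Sample-size-corrected numerator and the between-population heterozygosity
#' denominator:
#' `num = (p1 - p2)^2 - p1 (1 - p1) / (n1 - 1) - p2 (1 - p2) / (n2 - 1)`,
#' `den = p1 (1 - p2) + p2 (1 - p1)`.
#' Windowed F_ST is the ratio of the summed numerators to the summed
#' denominators (ratio of averages), which is robust to unequal sample
#' sizes.
#'
#' @param p1,p2 alternate-allele frequencies in the two populations.
#' @param n1,n2 chromosome counts (must be >= 2).
#' @return tibble `num`, `den`.
#' @export
hudson_fst_site <- function(p1, n1, p2, n2) {
  if (any(n1 <= 1) || any(n2 <= 1)) abort("hudson_fst_site needs n >= 2 in both populations")
  if (any(p1 < 0 | p1 > 1 | p2 < 0 | p2 > 1)) abort("frequencies must lie in [0, 1]")
  tibble::tibble(
    num = (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1),
    den = p1 * (1 - p2) + p2 * (1 - p1)
  )
}

#' Windowed Hudson F_ST between two subpopulations
#'
#' Ratio-of-averages windowing of [hudson_fst_site()]; the reported value is
#' clipped to \[0, 1\] and the raw (possibly negative) ratio is kept in the
#' `raw` column. Windows whose denominator sum is zero, or with fewer
#' segregating sites than `config$min_sites_per_window`, are NaN.
#'
#' @inheritParams windowed_pi
#' @param pop_a,pop_b the two subpopulation codes.
#' @return a stat-track tibble with columns `value` (clipped) and `raw`.
#' @export
windowed_fst <- function(x, pop_map, pop_a, pop_b, config = scan_config(),
                         chrom_length_bp = NULL, stat_name = "fst") {
  ra <- pop_rows(x, pop_map, pop_a)
  rb <- pop_rows(x, pop_map, pop_b)
  if (length(ra) < 2 || length(rb) < 2) abort("need >= 2 chromosomes per population")
  A <- x$alleles[ra, , drop = FALSE]
  B <- x$alleles[rb, , drop = FALSE]
  n1 <- colSums(!is.na(A)); n2 <- colSums(!is.na(B))
  ok <- n1 >= 2 & n2 >= 2
  p1 <- ifelse(ok, colSums(A, na.rm = TRUE) / n1, NA_real_)
  p2 <- ifelse(ok, colSums(B, na.rm = TRUE) / n2, NA_real_)
  num <- den <- numeric(ncol(A))
  hf <- hudson_fst_site(p1[ok], n1[ok], p2[ok], n2[ok])
  num[ok] <- hf$num
  den[ok] <- hf$den
  seg <- ok & den > 0

  if (is.null(chrom_length_bp)) chrom_length_bp <- max(x$sites$pos)
  win <- make_windows(x$sites$chrom[1], chrom_length_bp, config)
  s_num <- window_sums(win, x$sites$pos, num, seg)
  s_den <- window_sums(win, x$sites$pos, den, seg)
  raw <- ifelse(s_den$sum > 0, s_num$sum / s_den$sum, NaN)
  raw[s_num$n_seg < config$min_sites_per_window] <- NaN
  as_stat_track(tibble::tibble(win, stat = stat_name,
                               value = pmin(pmax(raw, 0), 1), raw = raw,
                               n_sites = s_num$n_seg))
}
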