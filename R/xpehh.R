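#' Extended haplotype homozygosity at a given extent
#'
#' The probability that two randomly drawn chromosomes of the population
#' carry identical allele strings over the sites between the core and the
#' extent (the extent site included; the core site itself does not
#' partition, so EHH at the core is 1 by definition): with group sizes
#' `c_g` over `n` chromosomes, `EHH = sum choose(c_g, 2) / choose(n, 2)`.
#' Chromosomes hitting a missing allele inside the span leave the
#' computation and `n` is decremented.
#'
#' @param x a phased [hap_matrix].
#' @param rows chromosome-row indices of the population (see [pop_rows()]).
#' @param core_index,extent_index 1-based site indices; the extent must lie
#'   on the side of the core given by `direction`.
#' @param direction `"left"` or `"right"`.
#' @return a single EHH value in \[0, 1\], or NaN when fewer than two
#'   chromosomes remain.
#' @export
ehh_at <- function(x, rows, core_index, extent_index,
                   direction = c("right", "left")) {
  direction <- match.arg(direction)
  if (!x$phased) abort("EHH requires a phased matrix")
  if (direction == "right" && extent_index < core_index) {
    abort("extent must be >= core for direction 'right'")
  }
  if (direction == "left" && extent_index > core_index) {
    abort("extent must be <= core for direction 'left'")
  }
  if (extent_index == core_index) return(1)
  span <- if (direction == "right") (core_index + 1L):extent_index
          else (core_index - 1L):extent_index
  a <- x$alleles[rows, span, drop = FALSE]
  complete <- stats::complete.cases(a)
  n <- sum(complete)
  if (n < 2) return(NaN)
  key <- apply(a[complete, , drop = FALSE], 1, paste, collapse = "")
  cg <- table(key)
  sum(choose(cg, 2)) / choose(n, 2)
}

#' EHH decay curve from a core site
#'
#' @inheritParams ehh_at
#' @return tibble `direction`, `site_index`, `distance_bp`, `ehh`.
#' @export
ehh_curve <- function(x, rows, core_index) {
  pos <- x$sites$pos
  one_side <- function(idx, dir) {
    tibble::tibble(
      direction = dir, site_index = idx,
      distance_bp = abs(pos[idx] - pos[core_index]),
      ehh = vapply(idx, function(e) ehh_at(x, rows, core_index, e, dir), numeric(1))
    )
  }
  dplyr::bind_rows(
    one_side(core_index:1L, "left"),
    one_side(core_index:ncol(x$alleles), "right")
  )
}

#' Integrated EHH (iHH) at core sites
#'
#' Trapezoidal integral of the EHH decay curve over physical distance (bp),
#' left plus right flank, each truncated at the first extent where EHH
#' drops below `config$ehh_truncation` or cut where the inter-site gap
#' exceeds `config$max_gap_bp`. When a flank reaches the chromosome edge
#' first, `edge_policy = "clip"` keeps the partial integral (the number of
#' clipped cores is attached as attribute `n_clipped`) while `"discard"`
#' gives NaN.
#'
#' @param x a phased [hap_matrix].
#' @param rows chromosome rows of the population.
#' @param core_index 1-based site index (or vector of indices).
#' @param config a [scan_config()].
#' @return numeric vector of iHH values (bp), one per core.
#' @export
ihh <- function(x, rows, core_index, config = scan_config()) {
  if (!x$phased) abort("iHH requires a phased matrix")
  ihh_scan_cpp(x$alleles[rows, , drop = FALSE], x$sites$pos,
               as.integer(core_index) - 1L,
               config$ehh_truncation, config$max_gap_bp,
               config$edge_policy == "clip")
}

#' Raw XP-EHH score
#'
#' `ln(iHH_A / iHH_B)`. With A = cultivar and B = wild, positive scores
#' mean longer haplotypes — a sweep — in cultivars. NaN when either iHH is
#' zero, non-finite or missing.
#'
#' @param ihh_a,ihh_b integrated EHH in populations A and B.
#' @return numeric vector of raw scores.
#' @export
xpehh_raw <- function(ihh_a, ihh_b) {
  ok <- is.finite(ihh_a) & is.finite(ihh_b) & ihh_a > 0 & ihh_b > 0
  # log(a) - log(b) rather than log(a/b): antisymmetry under population
  # swap is then exact in floating point
  ifelse(ok, log(ihh_a) - log(ihh_b), NaN)
}

#' Genome-wide normalization of XP-EHH
#'
#' Z-scores against the mean and population standard deviation (divide by
#' N) of all finite raw scores, so the normalized track has mean 0 and sd 1
#' over finite entries.
#'
#' @param raw numeric vector of raw scores (NaN allowed).
#' @return numeric vector of z-scores, NaN preserved.
#' @export
normalize_xpehh <- function(raw) {
  fin <- is.finite(raw)
  if (sum(fin) < 2) abort("need >= 2 finite raw scores to normalize")
  m <- mean(raw[fin])
  s <- sqrt(mean((raw[fin] - m)^2))
  if (s == 0) abort("raw XP-EHH scores are constant; cannot normalize")
  ifelse(fin, (raw - m) / s, NaN)
}

#' Cross-population XP-EHH scan
#'
#' Computes iHH in both populations at every core site (pooled MAF of the
#' two populations >= `config$core_maf_min`), the raw score
#' `ln(iHH_A / iHH_B)` and its genome-wide z-score.
#'
#' @param x a phased [hap_matrix].
#' @param pop_map tibble `accession`, `subpop`.
#' @param pop_a,pop_b subpopulation codes; convention A = cultivar (`"C"`),
#'   B = wild (`"S"`), so positive scores indicate a cultivar sweep.
#' @param config a [scan_config()].
#' @return tibble `chrom`, `pos`, `site_index`, `ihh_a`, `ihh_b`, `raw`,
#'   `znorm`; attribute `n_clipped` counts edge-clipped cores.
#' @export
xpehh_scan <- function(x, pop_map, pop_a = "C", pop_b = "S",
                       config = scan_config()) {
  ra <- pop_rows(x, pop_map, pop_a)
  rb <- pop_rows(x, pop_map, pop_b)
  pooled_maf <- site_maf(x, c(ra, rb))
  cores <- which(pooled_maf >= config$core_maf_min)
  if (length(cores) < 2) abort("fewer than 2 core sites pass the MAF floor")
  ia <- ihh(x, ra, cores, config)
  ib <- ihh(x, rb, cores, config)
  raw <- xpehh_raw(ia, ib)
  out <- tibble::tibble(
    chrom = x$sites$chrom[cores], pos = x$sites$pos[cores],
    site_index = cores, ihh_a = as.numeric(ia), ihh_b = as.numeric(ib),
    raw = raw, znorm = normalize_xpehh(raw)
  )
  attr(out, "n_clipped") <- (attr(ia, "n_clipped") %||% 0L) +
    (attr(ib, "n_clipped") %||% 0L)
  out
}

#' Windowed XP-EHH track
#'
#' Per-window maximum of the normalized per-site scores (NaN where a window
#' contains no core site).
#'
#' @param scores output of [xpehh_scan()].
#' @param config a [scan_config()].
#' @param chrom_length_bp chromosome length; defaults to the last core
#'   position.
#' @return a stat-track tibble with `stat = "xpehh_norm"`.
#' @export
xpehh_track <- function(scores, config = scan_config(), chrom_length_bp = NULL) {
  if (is.null(chrom_length_bp)) chrom_length_bp <- max(scores$pos)
  win <- make_windows(scores$chrom[1], chrom_length_bp, config)
  fin <- is.finite(scores$znorm)
  pos <- scores$pos[fin]
  z <- scores$znorm[fin]
  value <- purrr::map2_dbl(win$start0, win$end, function(s, e) {
    inw <- pos > s & pos <= e
    if (!any(inw)) NaN else max(z[inw])
  })
  n_sites <- purrr::map2_int(win$start0, win$end, function(s, e) {
    sum(pos > s & pos <= e)
  })
  as_stat_track(tibble::tibble(win, stat = "xpehh_norm", value = value,
                               n_sites = n_sites))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
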