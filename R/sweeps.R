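#' Empirical genome-wide threshold
#'
#' Order-statistic threshold on the finite window values of a track: the
#' ceiling(q * W)-th smallest value, with W the finite count. A window is
#' flagged iff its value is strictly greater than the threshold, so a
#' tie-free track with W divisible by 1/(1-q) flags exactly (1-q) * W
#' windows.
#'
#' @param track a stat-track tibble (or a bare numeric vector of values).
#' @param top_quantile the genome-wide quantile, default 0.95 (top 5%).
#' @param min_windows minimum number of finite values required for the
#'   threshold to be considered genome-wide (error below it).
#' @return the threshold value.
#' @export
empirical_threshold <- function(track, top_quantile = 0.95, min_windows = 20) {
  v <- if (is.numeric(track)) track else track$value
  v <- v[is.finite(v)]
  if (length(v) < max(2, min_windows)) {
    abort("too few finite window values for an empirical threshold")
  }
  sort(v)[ceiling(top_quantile * length(v))]
}

#' Call selective-sweep regions from multiple statistics
#'
#' A window supports a sweep when at least `min_support` of the supplied
#' statistics exceed their genome-wide thresholds there (strict `>`; NaN
#' windows never flag). Supporting windows whose starts are within
#' `step + merge_gap_bp` of each other merge into one region, so with
#' `merge_gap_bp = 0` only consecutive windows merge and a one-window hole
#' splits a region unless `merge_gap_bp >= step`.
#'
#' @param tracks named list of stat-track tibbles sharing identical
#'   windows (e.g. `pi_ratio`, `fst`, `xpehh_norm`).
#' @param thresholds named numeric vector of per-statistic thresholds; by
#'   default computed with [empirical_threshold()] at `top_quantile`.
#' @param min_support how many statistics must flag a window (1-3);
#'   default 3 requires coincident signals from all methods.
#' @param merge_gap_bp gap tolerance when merging supporting windows.
#' @param top_quantile used only when `thresholds` is NULL.
#' @return tibble of regions: `chrom`, `start0`, `end`, `n_windows`,
#'   `stats` (comma-joined statistics exceeding their threshold anywhere in
#'   the region) and one `peak_<stat>` column per track.
#' @export
call_sweeps <- function(tracks, thresholds = NULL, min_support = 3,
                        merge_gap_bp = 0, top_quantile = 0.95) {
  stopifnot(length(tracks) >= 1)
  if (is.null(names(tracks)) || any(names(tracks) == "")) {
    names(tracks) <- vapply(tracks, function(t) t$stat[1], character(1))
  }
  win <- tracks[[1]][c("chrom", "start0", "end")]
  for (t in tracks[-1]) {
    if (!identical(t[c("chrom", "start0", "end")], win)) {
      abort("all tracks must share identical windows")
    }
  }
  if (is.null(thresholds)) {
    thresholds <- vapply(tracks, function(t) {
      tryCatch(empirical_threshold(t, top_quantile), error = function(e) NA_real_)
    }, numeric(1))
    dropped <- names(tracks)[is.na(thresholds)]
    if (length(dropped)) {
      warn(paste0("no genome-wide threshold for ",
                  paste(dropped, collapse = ", "),
                  " (too few finite windows); the statistic cannot flag windows"))
    }
  }
  flags <- vapply(names(tracks), function(nm) {
    thr <- thresholds[[nm]]
    v <- tracks[[nm]]$value
    if (is.na(thr)) rep(FALSE, length(v)) else is.finite(v) & v > thr
  }, logical(nrow(win)))
  if (is.null(dim(flags))) flags <- matrix(flags, nrow = 1, dimnames = list(NULL, names(tracks)))
  support <- rowSums(flags)
  idx <- which(support >= min_support)

  empty <- tibble::tibble(chrom = character(), start0 = integer(), end = integer(),
                          n_windows = integer(), stats = character())
  for (nm in names(tracks)) empty[[paste0("peak_", nm)]] <- numeric()
  if (!length(idx)) return(empty)

  step <- if (nrow(win) > 1) min(diff(sort(unique(win$start0)))) else win$end[1] - win$start0[1]
  starts <- win$start0[idx]
  brk <- c(TRUE, diff(starts) > step + merge_gap_bp)
  grp <- cumsum(brk)

  purrr::map_dfr(split(idx, grp), function(ii) {
    reg <- tibble::tibble(
      chrom = win$chrom[ii[1]],
      start0 = min(win$start0[ii]),
      end = max(win$end[ii]),
      n_windows = length(ii),
      stats = paste(names(tracks)[colSums(flags[ii, , drop = FALSE]) > 0],
                    collapse = ",")
    )
    for (nm in names(tracks)) {
      v <- tracks[[nm]]$value[ii]
      reg[[paste0("peak_", nm)]] <- if (any(is.finite(v))) max(v[is.finite(v)]) else NaN
    }
    reg
  })
}

#' Annotate sweep regions with overlapping intervals
#'
#' Half-open interval intersection of regions against a gene/QTL annotation
#' track; overlapping names are grouped by category into one column per
#' category (comma-joined, empty when none).
#'
#' @param regions output of [call_sweeps()].
#' @param annotation tibble from [read_bed()]: `chrom`, `start0`, `end`,
#'   `name`, `category`.
#' @return `regions` with one extra column per annotation category.
#' @export
annotate_regions <- function(regions, annotation) {
  cats <- sort(unique(annotation$category))
  for (cat in cats) regions[[cat]] <- ""
  if (!nrow(regions) || !nrow(annotation)) return(regions)
  for (i in seq_len(nrow(regions))) {
    hit <- annotation$chrom == regions$chrom[i] &
      annotation$start0 < regions$end[i] &
      annotation$end > regions$start0[i]
    for (cat in cats) {
      nm <- annotation$name[hit & annotation$category == cat]
      regions[[cat]][i] <- paste(nm, collapse = ",")
    }
  }
  regions
}
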