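# Fixtures and independent oracles shared across the suite.

# random phased haplotype matrix (no missing data unless asked)
rand_hap_matrix <- function(n_acc = 4, n_sites = 20, seed = 1, p = NULL,
                            spacing = 10L) {
  set.seed(seed)
  if (is.null(p)) p <- stats::runif(n_sites, 0.1, 0.9)
  alleles <- sapply(p, function(pp) stats::rbinom(2L * n_acc, 1L, pp))
  alleles <- matrix(as.integer(alleles), nrow = 2L * n_acc)
  sites <- tibble::tibble(
    chrom = "chr1", pos = as.integer(seq_len(n_sites) * spacing),
    ref = "A", alt = "T", is_indel = FALSE
  )
  hap_matrix(alleles, sites, sprintf("acc%02d", seq_len(n_acc)))
}

# config small enough for per-test simulation
small_sim_config <- function(seed = 1, ...) {
  sim_config(n_ancestral = 60, n_bottleneck = 20, n_landrace = 80,
             n_cultivar = 80, t_split = 15, t_subsplit = 18, t_total = 50,
             n_sites = 200, chrom_length_bp = 1e5,
             sample_sizes = c(S = 15, L = 15, C = 15), seed = seed, ...)
}

# brute-force mean pairwise difference per bp over a window
bf_window_pi <- function(alleles, pos, start0, end) {
  in_win <- pos > start0 & pos <= end
  a <- alleles[, in_win, drop = FALSE]
  n <- nrow(a)
  tot <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) tot <- tot + sum(a[i, ] != a[j, ], na.rm = TRUE)
  }
  tot / choose(n, 2) / (end - start0)
}

# independently coded Hudson site components
bf_hudson_site <- function(p1, n1, p2, n2) {
  list(num = (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1),
       den = p1 * (1 - p2) + p2 * (1 - p1))
}

# Prim's algorithm, independent of igraph, on a distance matrix
bf_mst_cost <- function(D) {
  n <- nrow(D)
  if (n < 2) return(0)
  in_tree <- c(TRUE, rep(FALSE, n - 1))
  cost <- 0
  for (step in seq_len(n - 1)) {
    best <- Inf
    bi <- NA
    for (j in which(!in_tree)) {
      m <- min(D[in_tree, j])
      if (m < best) { best <- m; bi <- j }
    }
    in_tree[bi] <- TRUE
    cost <- cost + best
  }
  cost
}

bf_hamming <- function(strings) {
  X <- do.call(rbind, lapply(strings, function(s) as.integer(strsplit(s, "")[[1]])))
  as.matrix(stats::dist(X, method = "manhattan"))
}

# exhaustive minimal-letter CLD: a letter is a set of groups that are
# pairwise non-significant (a clique of the sharing graph); the minimal
# letter count is the smallest number of cliques that covers every group
# and every non-significant pair. Enumerates ALL cliques (not just
# maximal ones) and searches covers by increasing size.
bf_cld_min_letters <- function(share) {
  n <- nrow(share)
  diag(share) <- TRUE
  verts <- seq_len(n)
  subsets <- unlist(lapply(verts, function(k) combn(n, k, simplify = FALSE)),
                    recursive = FALSE)
  is_clique <- vapply(subsets, function(s) all(share[s, s]), logical(1))
  cliques <- subsets[is_clique]
  pairs <- which(share & upper.tri(share), arr.ind = TRUE)
  pair_in <- function(cl, e) all(pairs[e, ] %in% cl)
  for (k in seq_along(cliques)) {
    for (sel in combn(length(cliques), k, simplify = FALSE)) {
      cl <- cliques[sel]
      if (length(unique(unlist(cl))) < n) next
      ok <- TRUE
      for (e in seq_len(nrow(pairs))) {
        if (!any(vapply(cl, pair_in, logical(1), e = e))) { ok <- FALSE; break }
      }
      if (ok) return(k)
    }
  }
  n
}

# sharing relation implied by emitted letter strings
letters_to_share <- function(letters_vec) {
  n <- length(letters_vec)
  out <- matrix(TRUE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      li <- strsplit(letters_vec[i], "")[[1]]
      lj <- strsplit(letters_vec[j], "")[[1]]
      out[i, j] <- length(intersect(li, lj)) > 0
    }
  }
  out
}

# recovery helper: scan a cohort and call sweeps at min_support 2
scan_and_call <- function(cohort, cfg, min_support = 2) {
  sc <- scan_config()
  hm <- cohort$haplotypes
  pm <- cohort$population_map
  pi_s <- windowed_pi(hm, pm, "S", sc, cfg$chrom_length_bp)
  pi_c <- windowed_pi(hm, pm, "C", sc, cfg$chrom_length_bp)
  tracks <- list(
    pi_ratio = pi_ratio(pi_s, pi_c),
    fst = windowed_fst(hm, pm, "C", "S", sc, cfg$chrom_length_bp),
    xpehh_norm = xpehh_track(xpehh_scan(hm, pm, "C", "S", sc), sc,
                             cfg$chrom_length_bp)
  )
  suppressWarnings(call_sweeps(tracks, min_support = min_support))
}

# minimal stat-track construction for window-level tests
as_track_for_test <- function(windows, values, stat = "pi_S") {
  haplosweep:::as_stat_track(tibble::tibble(
    windows, stat = stat, value = values,
    n_sites = rep(1L, nrow(windows))
  ))
}
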