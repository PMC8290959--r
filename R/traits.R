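#' Two-sample Student's t-test
#'
#' Classical pooled-variance two-sample t (df = n_x + n_y - 2) with a Welch
#' variant behind `welch = TRUE`. Degenerate inputs are handled explicitly:
#' zero pooled variance gives p = 1 when the means are equal and p = 0
#' (with a warning) when they differ.
#'
#' @param x,y numeric samples, each of length >= 2 (missing values
#'   dropped).
#' @param welch use the Welch (unequal-variance) statistic instead.
#' @return tibble `t`, `df`, `p_value`.
#' @export
student_t_test <- function(x, y, welch = FALSE) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) abort("each sample needs >= 2 values")
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y)) {
      return(tibble::tibble(t = 0, df = length(x) + length(y) - 2, p_value = 1))
    }
    warn("zero variance with unequal means; p = 0")
    return(tibble::tibble(t = sign(mean(x) - mean(y)) * Inf,
                          df = length(x) + length(y) - 2, p_value = 0))
  }
  tt <- stats::t.test(x, y, var.equal = !welch)
  tibble::tibble(t = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value)
}

#' Compact letter display
#'
#' Assigns letters to groups so that two groups share at least one letter
#' exactly when their pairwise p-value is >= `alpha`. Groups must be
#' supplied in descending order of trait mean, so letter `a` marks the
#' highest-mean cluster. The assignment uses a minimal edge-clique cover of
#' the non-significance graph (exact search for up to 12 groups,
#' insert-and-absorb beyond), which yields the fewest possible letters.
#'
#' @param pairwise_p symmetric matrix of pairwise p-values (diagonal
#'   ignored), rows/columns ordered by descending group mean.
#' @param alpha significance level, default 0.05.
#' @return character vector of letter strings, one per group.
#' @export
compact_letter_display <- function(pairwise_p, alpha = 0.05) {
  p <- as.matrix(pairwise_p)
  n <- nrow(p)
  if (n != ncol(p)) abort("p matrix must be square")
  diag(p) <- 1
  if (any(abs(p - t(p)) > 1e-12, na.rm = TRUE)) abort("p matrix must be symmetric")
  if (n == 1) return("a")
  share <- p >= alpha  # groups sharing a letter

  cliques <- if (n <= 12) {
    minimal_clique_cover(share)
  } else {
    insert_absorb(share)
  }
  # order letter classes by their highest-mean (lowest-index) member
  cliques <- cliques[order(vapply(cliques, min, numeric(1)),
                           -lengths(cliques))]
  letters_out <- character(n)
  for (i in seq_along(cliques)) {
    for (g in cliques[[i]]) {
      letters_out[g] <- paste0(letters_out[g], letters[i])
    }
  }
  letters_out
}

# exact minimum edge-clique cover (also covering isolated vertices) via
# exhaustive search over maximal cliques of the sharing graph
minimal_clique_cover <- function(share) {
  n <- nrow(share)
  g <- igraph::graph_from_adjacency_matrix(share & !diag(TRUE, n),
                                           mode = "undirected")
  mc <- lapply(igraph::max_cliques(g), as.integer)
  mc <- mc[order(vapply(mc, min, integer(1)), -lengths(mc))]
  edges <- which(share & upper.tri(share), arr.ind = TRUE)
  covers_all <- function(sel) {
    cl <- mc[sel]
    verts <- unique(unlist(cl))
    if (length(verts) < n) return(FALSE)
    if (!nrow(edges)) return(TRUE)
    all(vapply(seq_len(nrow(edges)), function(e) {
      any(vapply(cl, function(cc) all(edges[e, ] %in% cc), logical(1)))
    }, logical(1)))
  }
  for (m in seq_along(mc)) {
    combos <- utils::combn(length(mc), m, simplify = FALSE)
    for (sel in combos) {
      if (covers_all(sel)) return(mc[sel])
    }
  }
  mc
}

# Piepho-style insert-and-absorb: start with one letter for all groups,
# split on significant pairs, absorb subset letters
insert_absorb <- function(share) {
  n <- nrow(share)
  classes <- list(seq_len(n))
  sig <- which(!share & upper.tri(share), arr.ind = TRUE)
  for (e in seq_len(nrow(sig))) {
    i <- sig[e, 1]; j <- sig[e, 2]
    hit <- vapply(classes, function(cl) all(c(i, j) %in% cl), logical(1))
    for (h in which(hit)) {
      cl <- classes[[h]]
      classes[[h]] <- setdiff(cl, i)
      classes <- c(classes, list(setdiff(cl, j)))
    }
    # absorb: drop classes contained in another (duplicates keep the first)
    keep <- rep(TRUE, length(classes))
    for (a in seq_along(classes)) {
      for (b in seq_along(classes)) {
        if (a == b || !keep[a] || !keep[b]) next
        sub_ab <- all(classes[[a]] %in% classes[[b]])
        if (sub_ab && (length(classes[[a]]) < length(classes[[b]]) || a > b)) {
          keep[a] <- FALSE
        }
      }
    }
    classes <- classes[keep]
  }
  classes[lengths(classes) > 0]
}

#' Haplotype-group trait association
#'
#' Compares 100-seed weight, fatty-acid content and protein content across
#' haplotype groups: per-group summaries, all pairwise Student's t-tests
#' (per-pair alpha, no multiple-testing correction unless `bonferroni`),
#' and a compact letter display per trait with letters ordered by
#' descending mean. Missing trait values are dropped pairwise; groups with
#' fewer than two observations are reported but untested.
#'
#' @param traits trait tibble (`accession` + numeric trait columns).
#' @param accession_groups tibble `accession`, `group` (e.g. from
#'   [assign_accession_groups()]); accessions with NA group are excluded
#'   and tallied.
#' @param alpha per-pair significance level.
#' @param subpop optional subpopulation filter (e.g. `"C"` to compare only
#'   cultivars); requires `pop_map`.
#' @param pop_map tibble `accession`, `subpop` (only needed with
#'   `subpop`).
#' @param welch use Welch t-tests.
#' @param bonferroni Bonferroni-adjust the pairwise p-values before
#'   thresholding.
#' @return a `trait_association` object with elements `summary` (group x
#'   trait statistics and letters), `pairwise` (all tests), `alpha`,
#'   `exclusions`.
#' @export
associate_groups <- function(traits, accession_groups, alpha = 0.05,
                             subpop = NULL, pop_map = NULL, welch = FALSE,
                             bonferroni = FALSE) {
  dat <- dplyr::inner_join(traits, accession_groups, by = "accession")
  n_unlabelled <- sum(is.na(dat$group))
  dat <- dplyr::filter(dat, !is.na(.data$group))
  n_filtered <- 0L
  if (!is.null(subpop)) {
    if (is.null(pop_map)) abort("subpop filtering requires pop_map")
    keep <- pop_map$accession[pop_map$subpop %in% subpop]
    n_filtered <- sum(!dat$accession %in% keep)
    dat <- dplyr::filter(dat, .data$accession %in% keep)
  }
  trait_cols <- setdiff(names(traits), "accession")
  long <- tidyr::pivot_longer(dat, dplyr::all_of(trait_cols),
                              names_to = "trait", values_to = "value")
  long <- dplyr::filter(long, !is.na(.data$value))

  summary_tbl <- dplyr::summarise(
    dplyr::group_by(long, .data$trait, .data$group),
    n = dplyr::n(), mean = mean(.data$value), sd = sd(.data$value),
    median = median(.data$value),
    q1 = unname(quantile(.data$value, 0.25)),
    q3 = unname(quantile(.data$value, 0.75)),
    .groups = "drop"
  )

  pairwise <- purrr::map_dfr(trait_cols, function(tr) {
    sub <- dplyr::filter(long, .data$trait == tr)
    by_grp <- split(sub$value, sub$group)
    by_grp <- by_grp[vapply(by_grp, length, integer(1)) >= 2]
    if (length(by_grp) < 2) return(tibble::tibble())
    combos <- utils::combn(names(by_grp), 2, simplify = FALSE)
    purrr::map_dfr(combos, function(pr) {
      tt <- student_t_test(by_grp[[pr[1]]], by_grp[[pr[2]]], welch = welch)
      tibble::tibble(trait = tr, group1 = pr[1], group2 = pr[2],
                     t = tt$t, df = tt$df, p_value = tt$p_value)
    })
  })
  if (!nrow(pairwise)) {
    pairwise <- tibble::tibble(trait = character(), group1 = character(),
                               group2 = character(), t = numeric(),
                               df = numeric(), p_value = numeric())
  }
  if (nrow(pairwise) && bonferroni) {
    pairwise <- dplyr::mutate(
      dplyr::group_by(pairwise, .data$trait),
      p_value = pmin(1, .data$p_value * dplyr::n())
    )
    pairwise <- dplyr::ungroup(pairwise)
  }

  # letters per trait, groups ordered by descending mean
  summary_tbl$letter <- NA_character_
  for (tr in unique(summary_tbl$trait)) {
    sm <- dplyr::arrange(dplyr::filter(summary_tbl, .data$trait == tr),
                         dplyr::desc(.data$mean))
    grps <- sm$group[sm$n >= 2]
    if (length(grps) < 1) next
    pm <- matrix(1, length(grps), length(grps), dimnames = list(grps, grps))
    pw <- dplyr::filter(pairwise, .data$trait == tr)
    for (r in seq_len(nrow(pw))) {
      if (pw$group1[r] %in% grps && pw$group2[r] %in% grps) {
        pm[pw$group1[r], pw$group2[r]] <- pw$p_value[r]
        pm[pw$group2[r], pw$group1[r]] <- pw$p_value[r]
      }
    }
    lt <- compact_letter_display(pm, alpha)
    for (gi in seq_along(grps)) {
      summary_tbl$letter[summary_tbl$trait == tr &
                           summary_tbl$group == grps[gi]] <- lt[gi]
    }
  }

  structure(list(summary = summary_tbl, pairwise = pairwise, alpha = alpha,
                 exclusions = c(unlabelled = n_unlabelled,
                                subpop_filtered = n_filtered)),
            class = "trait_association")
}

#' @export
print.trait_association <- function(x, ...) {
  cat(sprintf("<trait_association> %d traits, alpha = %g\n",
              length(unique(x$summary$trait)), x$alpha))
  print(x$summary)
  invisible(x)
}

#' Tidy a trait-association fit
#'
#' One row per pairwise comparison, broom style.
#'
#' @param x a `trait_association`.
#' @param ... unused.
#' @return the `pairwise` tibble.
#' @export
tidy.trait_association <- function(x, ...) x$pairwise

#' One-row-per-trait overview of a trait association
#'
#' @param x a `trait_association`.
#' @param ... unused.
#' @return tibble `trait`, `n_groups`, `n_obs`, `min_p`, `all_significant`.
#' @export
glance.trait_association <- function(x, ...) {
  sm <- dplyr::summarise(dplyr::group_by(x$summary, .data$trait),
                         n_groups = dplyr::n(), n_obs = sum(.data$n),
                         .groups = "drop")
  pw <- dplyr::summarise(dplyr::group_by(x$pairwise, .data$trait),
                         min_p = min(.data$p_value),
                         all_significant = all(.data$p_value < x$alpha),
                         .groups = "drop")
  dplyr::left_join(sm, pw, by = "trait")
}
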