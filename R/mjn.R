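#' Median-joining haplotype network
#'
#' Builds the median-joining network of a haplotype table under Hamming
#' distance: (1) the minimum-spanning network (all links that participate
#' in some minimum spanning tree, with tolerance `epsilon`); (2) for every
#' pair of network links sharing a node, the coordinate-wise majority
#' (median) vector of the three haplotypes is added as an inferred node
#' when it reduces the total connection cost (minimum-spanning-tree weight
#' of the node set); (3) repeated to a fixed point; (4) median vectors of
#' degree <= 1 are pruned. Ties are broken deterministically by
#' lexicographic allele string, so a fixed input order yields an identical
#' network.
#'
#' @param table a `hap_table` from [collapse_haplotypes()]; allele strings
#'   must be distinct.
#' @param epsilon non-negative tolerance widening the set of feasible
#'   links (0 = strict median joining).
#' @return an `mj_network`: list with `graph` (igraph, edge attribute
#'   `weight` = Hamming distance), `nodes` and `edges` tibbles, `epsilon`,
#'   and `cost` (total MST weight over the final node set).
#' @export
mj_network <- function(table, epsilon = 0) {
  if (nrow(table) < 2) abort("need >= 2 haplotypes for a network")
  if (anyDuplicated(table$allele_string)) {
    abort("duplicate allele strings; collapse haplotypes first")
  }
  if (epsilon < 0) abort("epsilon must be >= 0")

  str_to_vec <- function(s) as.integer(strsplit(s, "")[[1]])
  X <- do.call(rbind, lapply(table$allele_string, str_to_vec))
  labels <- table$haplotype
  is_median <- rep(FALSE, nrow(X))
  n_mv <- 0L

  mst_cost <- function(M) {
    if (nrow(M) < 2) return(0)
    D <- as.matrix(stats::dist(M, method = "manhattan"))
    g <- igraph::graph_from_adjacency_matrix(D, mode = "undirected", weighted = TRUE)
    sum(igraph::E(igraph::mst(g))$weight)
  }

  msn_edges <- function(M, eps) {
    D <- as.matrix(stats::dist(M, method = "manhattan"))
    g <- igraph::graph_from_adjacency_matrix(D, mode = "undirected", weighted = TRUE)
    mst <- igraph::mst(g)
    n <- nrow(M)
    # minimax distance = max edge weight on the (unique) MST path
    mm <- matrix(0, n, n)
    for (u in seq_len(n - 1)) {
      paths <- igraph::shortest_paths(mst, from = u, to = (u + 1):n,
                                      weights = NA, output = "epath")$epath
      for (j in seq_along(paths)) {
        mm[u, u + j] <- mm[u + j, u] <- max(igraph::E(mst)$weight[paths[[j]]])
      }
    }
    idx <- which(upper.tri(D) & D <= mm + eps, arr.ind = TRUE)
    tibble::tibble(i = idx[, 1], j = idx[, 2],
                   weight = D[cbind(idx[, 1], idx[, 2])])
  }

  repeat {
    edges <- msn_edges(X, epsilon)
    cur_cost <- mst_cost(X)
    # connected triplets: two links sharing a node
    adj <- split(c(edges$j, edges$i), c(edges$i, edges$j))
    cand <- list()
    for (u in as.integer(names(adj))) {
      nb <- sort(unique(adj[[as.character(u)]]))
      if (length(nb) < 2) next
      for (a in seq_len(length(nb) - 1)) {
        for (b in (a + 1):length(nb)) {
          trio <- X[c(u, nb[a], nb[b]), , drop = FALSE]
          med <- as.integer(colSums(trio) >= 2)
          key <- paste(med, collapse = "")
          if (!is.null(cand[[key]])) next
          cand[[key]] <- med
        }
      }
    }
    existing <- apply(X, 1, paste, collapse = "")
    cand <- cand[setdiff(names(cand), existing)]
    if (!length(cand)) break
    reductions <- vapply(cand, function(m) cur_cost - mst_cost(rbind(X, m)),
                         numeric(1))
    best <- reductions > 0
    if (!any(best)) break
    ord <- order(-reductions, names(cand))
    pick <- ord[best[ord]][1]
    X <- rbind(X, cand[[pick]])
    n_mv <- n_mv + 1L
    labels <- c(labels, sprintf("mv%02d", n_mv))
    is_median <- c(is_median, TRUE)
  }

  # prune median vectors of degree <= 1, then recompute the network
  repeat {
    edges <- msn_edges(X, epsilon)
    deg <- tabulate(c(edges$i, edges$j), nbins = nrow(X))
    drop <- which(is_median & deg <= 1)
    if (!length(drop)) break
    X <- X[-drop, , drop = FALSE]
    labels <- labels[-drop]
    is_median <- is_median[-drop]
  }

  strings <- apply(X, 1, paste, collapse = "")
  pops <- intersect(c("S", "L", "C"), names(table))
  nodes <- tibble::tibble(haplotype = labels, allele_string = strings,
                          is_median = is_median)
  counts <- table[match(nodes$allele_string, table$allele_string), c(pops, "total")]
  for (p in c(pops, "total")) {
    nodes[[p]] <- ifelse(is.na(counts[[p]]), 0, counts[[p]])
  }
  edges_tbl <- tibble::tibble(from = labels[edges$i], to = labels[edges$j],
                              weight = edges$weight)
  g <- igraph::graph_from_data_frame(edges_tbl, directed = FALSE,
                                     vertices = nodes)
  structure(list(graph = g, nodes = nodes, edges = edges_tbl,
                 epsilon = epsilon, cost = mst_cost(X)),
            class = "mj_network")
}

#' @export
print.mj_network <- function(x, ...) {
  cat(sprintf("<mj_network> %d observed + %d median nodes, %d links, cost %g\n",
              sum(!x$nodes$is_median), sum(x$nodes$is_median),
              nrow(x$edges), x$cost))
  invisible(x)
}

#' Assign haplotypes to major groups
#'
#' Cuts long links of the median-joining network and takes connected
#' components as major groups. Method `"edge_cut"` removes links with
#' mutational distance >= `cutoff`; method `"target_k"` finds the smallest
#' cutoff yielding exactly `k` components that contain observed haplotypes.
#' Groups are labelled H_I, H_II, ... by descending wild-subpopulation (S)
#' chromosome count, so H_I is the wild-enriched group.
#'
#' @param network an [mj_network()].
#' @param method `"target_k"` or `"edge_cut"`.
#' @param k target number of observed-haplotype groups (method
#'   `"target_k"`).
#' @param cutoff distance cutoff (method `"edge_cut"`).
#' @return a `hap_groups` tibble: `haplotype`, `allele_string`, `group`,
#'   `is_median`; attributes `method` and `cutoff`.
#' @export
assign_major_groups <- function(network, method = c("target_k", "edge_cut"),
                                k = 3, cutoff = NULL) {
  method <- match.arg(method)
  g <- network$graph
  w <- igraph::E(g)$weight
  comp_at <- function(cut) {
    h <- igraph::delete_edges(g, which(w >= cut))
    igraph::components(h)$membership
  }
  n_obs_groups <- function(membership) {
    length(unique(membership[!network$nodes$is_median]))
  }
  if (method == "edge_cut") {
    if (is.null(cutoff)) abort("edge_cut needs a cutoff")
  } else {
    cands <- c(sort(unique(w)), max(w) + 1)
    counts <- vapply(cands, function(c) n_obs_groups(comp_at(c)), integer(1))
    hit <- which(counts == k)
    if (!length(hit)) {
      abort(paste0("no cutoff yields ", k, " groups; achievable: ",
                   paste(sort(unique(counts)), collapse = ", ")))
    }
    cutoff <- cands[hit[1]]
  }
  memb <- comp_at(cutoff)

  nodes <- network$nodes
  nodes$component <- memb
  obs <- dplyr::filter(nodes, !.data$is_median)
  comp_rank <- dplyr::summarise(
    dplyr::group_by(obs, .data$component),
    s_count = sum(.data$S), total = sum(.data$total),
    first_hap = min(.data$haplotype), .groups = "drop"
  )
  comp_rank <- dplyr::arrange(comp_rank, dplyr::desc(.data$s_count),
                              dplyr::desc(.data$total), .data$first_hap)
  comp_rank$group <- paste0("H_", as.character(utils::as.roman(seq_len(nrow(comp_rank)))))
  key <- setNames(comp_rank$group, comp_rank$component)
  out <- tibble::tibble(
    haplotype = nodes$haplotype,
    allele_string = nodes$allele_string,
    group = unname(key[as.character(nodes$component)]),
    is_median = nodes$is_median
  )
  class(out) <- c("hap_groups", class(out))
  attr(out, "method") <- method
  attr(out, "cutoff") <- cutoff
  out
}

#' Map accessions to haplotype groups
#'
#' Accession-level grouping for trait association: an accession homozygous
#' at all retained gene-region sites inherits its haplotype's group;
#' heterozygous accessions and accessions with missing alleles are excluded
#' (tallied in the `exclusions` attribute).
#'
#' @param x the gene-region [hap_matrix] used for haplotyping.
#' @param groups an [assign_major_groups()] result.
#' @return tibble `accession`, `group` (NA when excluded); attribute
#'   `exclusions`.
#' @export
assign_accession_groups <- function(x, groups) {
  a <- x$alleles
  odd <- seq(1L, nrow(a), 2L)
  h1 <- a[odd, , drop = FALSE]
  h2 <- a[odd + 1L, , drop = FALSE]
  comp <- stats::complete.cases(h1) & stats::complete.cases(h2)
  hom <- comp & rowSums(h1 != h2) == 0L
  strings <- apply(h1, 1, paste, collapse = "")
  key <- setNames(groups$group, groups$allele_string)
  grp <- unname(ifelse(hom, key[strings], NA_character_))
  out <- tibble::tibble(accession = x$accessions, group = grp)
  attr(out, "exclusions") <- c(heterozygous = sum(comp & !hom),
                               missing = sum(!comp))
  out
}

#' Export a median-joining network
#'
#' Writes the network as GraphML or DOT via igraph.
#'
#' @param network an [mj_network()].
#' @param path output path.
#' @param format `"graphml"` or `"dot"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path, format = c("graphml", "dot")) {
  format <- match.arg(format)
  igraph::write_graph(network$graph, path, format = format)
  invisible(path)
}
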