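mk_hap_table <- function(strings, S = NULL, L = NULL, C = NULL) {
  n <- length(strings)
  if (is.null(S)) S <- rep(2, n)
  if (is.null(L)) L <- rep(0, n)
  if (is.null(C)) C <- rep(0, n)
  out <- tibble::tibble(haplotype = sprintf("hap%02d", seq_len(n)),
                        allele_string = strings, S = S, L = L, C = C,
                        total = S + L + C)
  class(out) <- c("hap_table", class(out))
  out
}

test_that("two haplotypes give a single weighted edge and no medians", {
  net <- mj_network(mk_hap_table(c("000", "111")))
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$weight, 3)
  expect_false(any(net$nodes$is_median))
  expect_equal(net$cost, 3)
})

test_that("the 000/110/011 triplet gains the 010 median star", {
  net <- mj_network(mk_hap_table(c("000", "110", "011")))
  med <- net$nodes[net$nodes$is_median, ]
  expect_equal(nrow(med), 1)
  expect_identical(med$allele_string, "010")
  expect_equal(net$cost, 3)  # three unit edges beat the MST cost of 4
  expect_equal(sort(net$edges$weight), c(1, 1, 1))
})

test_that("a perfect mutational path yields the path with no medians", {
  net <- mj_network(mk_hap_table(c("000", "100", "110", "111")))
  expect_false(any(net$nodes$is_median))
  expect_equal(nrow(net$edges), 3)
  expect_true(all(net$edges$weight == 1))
  expect_equal(net$cost, 3)
})

test_that("median insertion never exceeds the observed MST cost", {
  set.seed(31)
  for (i in 1:50) {
    n_hap <- sample(3:8, 1)
    n_sites <- sample(4:10, 1)
    strings <- unique(replicate(n_hap, paste(rbinom(n_sites, 1, 0.5), collapse = "")))
    if (length(strings) < 2) next
    net <- mj_network(mk_hap_table(strings))
    expect_lte(net$cost, bf_mst_cost(bf_hamming(strings)) + 1e-9)
    # all observed haplotypes are nodes; medians have degree >= 2
    expect_true(all(strings %in% net$nodes$allele_string))
    deg <- table(factor(c(net$edges$from, net$edges$to),
                        levels = net$nodes$haplotype))
    expect_true(all(deg[net$nodes$haplotype[net$nodes$is_median]] >= 2))
  }
})

test_that("the network build is deterministic", {
  strings <- c("0000", "1100", "0011", "1111", "1010")
  a <- mj_network(mk_hap_table(strings))
  b <- mj_network(mk_hap_table(strings))
  expect_identical(a$nodes, b$nodes)
  expect_identical(a$edges, b$edges)
})

test_that("duplicate allele strings are rejected", {
  expect_error(mj_network(mk_hap_table(c("01", "01"))), "duplicate")
})

test_that("edge_cut splits groups at the stated weight", {
  # star with unit edges -> cutoff 2 keeps everything together
  net <- mj_network(mk_hap_table(c("000", "110", "011")))
  g1 <- assign_major_groups(net, "edge_cut", cutoff = 2)
  expect_equal(length(unique(g1$group[!g1$is_median])), 1)

  # two tight clusters joined across >= 5 mutations -> cutoff 3 splits them
  strings <- c("000000", "100000", "111110", "111111")
  net2 <- mj_network(mk_hap_table(strings))
  g2 <- assign_major_groups(net2, "edge_cut", cutoff = 3)
  obs <- g2[!g2$is_median, ]
  expect_equal(length(unique(obs$group)), 2)
  expect_identical(obs$group[1], obs$group[2])
  expect_identical(obs$group[3], obs$group[4])
})

test_that("target_k recovers a generated three-cluster partition exactly", {
  set.seed(77)
  centers <- list(rep(0L, 12),
                  c(rep(1L, 6), rep(0L, 6)),
                  c(rep(0L, 6), rep(1L, 6)))
  strings <- character()
  truth <- integer()
  for (ci in seq_along(centers)) {
    for (v in 1:3) {
      h <- centers[[ci]]
      flip <- sample(12, sample(0:1, 1))  # within-cluster distance <= 1
      h[flip] <- 1L - h[flip]
      strings <- c(strings, paste(h, collapse = ""))
      truth <- c(truth, ci)
    }
  }
  keep <- !duplicated(strings)
  strings <- strings[keep]; truth <- truth[keep]
  net <- mj_network(mk_hap_table(strings))
  gr <- assign_major_groups(net, "target_k", k = 3)
  obs <- gr[!gr$is_median, ]
  got <- obs$group[match(strings, obs$allele_string)]
  # same partition as the generating clusters
  expect_equal(length(unique(got)), 3)
  for (ci in 1:3) {
    expect_equal(length(unique(got[truth == ci])), 1)
  }
})

test_that("unreachable target_k errors with achievable counts", {
  net <- mj_network(mk_hap_table(c("000", "111")))
  expect_error(assign_major_groups(net, "target_k", k = 5), "achievable")
})

test_that("group labels are ordered by wild enrichment", {
  strings <- c("000000", "111111")
  ht <- mk_hap_table(strings, S = c(0, 10), C = c(10, 0))
  gr <- assign_major_groups(mj_network(ht), "target_k", k = 2)
  obs <- gr[!gr$is_median, ]
  expect_identical(obs$group[obs$allele_string == "111111"], "H_I")
  expect_identical(obs$group[obs$allele_string == "000000"], "H_II")
})
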