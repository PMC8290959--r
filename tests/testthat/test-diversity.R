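test_that("site_pi matches pairwise-difference counting", {
  expect_equal(site_pi(0, 10), 0)
  expect_equal(site_pi(1, 2), 1)
  expect_equal(site_pi(2, 4), 4 / 6)  # 4 of 6 pairs differ
  expect_error(site_pi(0, 1), "n >= 2")
  expect_error(site_pi(5, 4), "k <= n")
})

test_that("windowed_pi equals the brute-force pairwise oracle", {
  pm <- NULL
  for (i in 1:100) {
    n_acc <- sample(2:5, 1)
    n_sites <- sample(5:50, 1)
    hm <- rand_hap_matrix(n_acc, n_sites, seed = i)
    pm <- tibble::tibble(accession = hm$accessions, subpop = "S")
    cfgw <- scan_config(window_bp = 200, step_bp = 200, min_sites_per_window = 1)
    tr <- windowed_pi(hm, pm, "S", cfgw, chrom_length_bp = n_sites * 10)
    for (w in seq_len(nrow(tr))) {
      if (!is.finite(tr$value[w])) next
      expect_equal(tr$value[w],
                   bf_window_pi(hm$alleles, hm$sites$pos, tr$start0[w], tr$end[w]),
                   tolerance = 1e-12)
    }
  }
})

test_that("pi is invariant under allele-label swap", {
  hm <- rand_hap_matrix(5, 30, seed = 42)
  pm <- tibble::tibble(accession = hm$accessions, subpop = "S")
  cfgw <- scan_config(window_bp = 100, step_bp = 100, min_sites_per_window = 1)
  t1 <- windowed_pi(hm, pm, "S", cfgw, 300)
  flip <- sample(30, 10)
  hm2 <- hm
  hm2$alleles[, flip] <- 1L - hm2$alleles[, flip]
  hm2 <- hap_matrix(hm2$alleles, hm2$sites, hm2$accessions)
  t2 <- windowed_pi(hm2, pm, "S", cfgw, 300)
  expect_equal(t1$value, t2$value, tolerance = 1e-15)
})

test_that("two haplotypes differing at one site give pi = 0.1 over 10 bp", {
  alleles <- rbind(c(0L), c(1L))
  sites <- tibble::tibble(chrom = "chr1", pos = 5L, ref = "A", alt = "T",
                          is_indel = FALSE)
  hm <- hap_matrix(alleles, sites, "acc1")
  pm <- tibble::tibble(accession = "acc1", subpop = "S")
  tr <- windowed_pi(hm, pm, "S", scan_config(window_bp = 10, step_bp = 10,
                                             min_sites_per_window = 1), 10)
  expect_equal(tr$value[1], 0.1)
})

test_that("pi_ratio divides guardedly and demands identical windows", {
  w <- tibble::tibble(chrom = "chr1", start0 = c(0L, 10L), end = c(10L, 20L))
  tA <- as_track_for_test(w, c(0.02, 0.01))
  tB <- as_track_for_test(w, c(0.005, 0))
  r <- pi_ratio(tA, tB)
  expect_equal(r$value[1], 4)
  expect_true(is.nan(r$value[2]))
  tA2 <- as_track_for_test(w, c(0.01, 0.01))
  expect_equal(pi_ratio(tA2, tA2)$value, c(1, 1))
  bad <- as_track_for_test(dplyr::mutate(w, start0 = start0 + 1L), c(1, 1))
  expect_error(pi_ratio(tA, bad), "identical windows")
})

test_that("hudson site components match the independent formula", {
  hf <- hudson_fst_site(1, 10, 0, 10)
  expect_equal(hf$num, 1)
  expect_equal(hf$den, 1)
  set.seed(99)
  for (i in 1:100) {
    p1 <- runif(1); p2 <- runif(1)
    n1 <- sample(2:50, 1); n2 <- sample(2:50, 1)
    got <- hudson_fst_site(p1, n1, p2, n2)
    want <- bf_hudson_site(p1, n1, p2, n2)
    expect_equal(got$num, want$num, tolerance = 1e-12)
    expect_equal(got$den, want$den, tolerance = 1e-12)
  }
  expect_error(hudson_fst_site(0.5, 1, 0.5, 10), "n >= 2")
})

test_that("complete fixation gives windowed F_ST of exactly 1", {
  alleles <- rbind(matrix(0L, 4, 10), matrix(1L, 4, 10))
  sites <- tibble::tibble(chrom = "chr1", pos = as.integer(1:10 * 10),
                          ref = "A", alt = "T", is_indel = FALSE)
  hm <- hap_matrix(alleles, sites, sprintf("a%d", 1:4))
  pm <- tibble::tibble(accession = sprintf("a%d", 1:4),
                       subpop = c("S", "S", "C", "C"))
  tr <- windowed_fst(hm, pm, "C", "S", scan_config(window_bp = 100, step_bp = 100,
                                                   min_sites_per_window = 1), 100)
  expect_equal(tr$value[1], 1)
})

test_that("randomly split pseudo-populations give median F_ST near zero", {
  set.seed(7)
  hm <- rand_hap_matrix(n_acc = 20, n_sites = 600, seed = 7, spacing = 200L)
  half <- sample(hm$accessions, 10)
  pm <- tibble::tibble(accession = hm$accessions,
                       subpop = ifelse(hm$accessions %in% half, "S", "C"))
  cfgw <- scan_config(window_bp = 2400, step_bp = 2400, min_sites_per_window = 3)
  tr <- windowed_fst(hm, pm, "C", "S", cfgw, 120000)
  expect_gte(sum(is.finite(tr$raw)), 50)
  expect_lt(abs(median(tr$raw, na.rm = TRUE)), 0.05)
})

test_that("a single-site window reduces to the site ratio", {
  alleles <- rbind(c(0L), c(1L), c(1L), c(1L))
  sites <- tibble::tibble(chrom = "chr1", pos = 5L, ref = "A", alt = "T",
                          is_indel = FALSE)
  hm <- hap_matrix(alleles, sites, c("a1", "a2"))
  pm <- tibble::tibble(accession = c("a1", "a2"), subpop = c("S", "C"))
  tr <- windowed_fst(hm, pm, "C", "S", scan_config(window_bp = 10, step_bp = 10,
                                                   min_sites_per_window = 1), 10)
  hf <- hudson_fst_site(1, 2, 0.5, 2)
  expect_equal(tr$raw[1], hf$num / hf$den)
})
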