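mk_gene_matrix <- function(strings, pops, positions = NULL) {
  # strings: one per accession, used for both chromosomes (homozygous)
  n_sites <- nchar(strings[1])
  alleles <- do.call(rbind, lapply(strings, function(s) {
    v <- as.integer(strsplit(s, "")[[1]])
    rbind(v, v)
  }))
  if (is.null(positions)) positions <- as.integer(seq_len(n_sites) * 100)
  sites <- tibble::tibble(chrom = "chr1", pos = positions, ref = "A",
                          alt = "T", is_indel = FALSE)
  accs <- sprintf("a%02d", seq_along(strings))
  list(hm = hap_matrix(alleles, sites, accs),
       pm = tibble::tibble(accession = accs, subpop = pops))
}

test_that("the MAF filter removes strictly below the cutoff and respects the region", {
  # 100 chromosomes: maf exactly 0.01 retained, 0.005 impossible -> use 200
  alleles <- matrix(0L, 200, 3)
  alleles[1:2, 1] <- 1L   # maf 0.01
  alleles[1, 2] <- 1L     # maf 0.005
  alleles[1:50, 3] <- 1L  # maf 0.25
  sites <- tibble::tibble(chrom = "chr1", pos = c(10L, 15L, 20L), ref = "A",
                          alt = "T", is_indel = FALSE)
  hm <- hap_matrix(alleles, sites, sprintf("a%03d", 1:100))
  kept <- extract_gene_variants(hm, "chr1:0-100", maf_min = 0.01)
  expect_identical(kept$sites$pos, c(10L, 20L))

  # region is half-open in 0-based coordinates: pos 20 (0-based 19) excluded
  # by [10, 19); pos 15 (0-based 14) included
  kept2 <- extract_gene_variants(hm, "chr1:9-19", maf_min = 0)
  expect_identical(kept2$sites$pos, c(10L, 15L))
  expect_warning(extract_gene_variants(hm, "chr1:5000-6000", 0.01), "no variants")
})

test_that("chromosome-mode collapse counts every phased chromosome", {
  g <- mk_gene_matrix(c("01", "01", "10"), c("S", "S", "C"))
  ht <- collapse_haplotypes(g$hm, g$pm, "chromosome")
  expect_identical(ht$allele_string, c("01", "10"))
  expect_equal(ht$total, c(4, 2))
  expect_equal(ht$S, c(4, 0))
  expect_equal(ht$C, c(0, 2))
})

test_that("accession-mode collapse excludes heterozygotes with a tally", {
  alleles <- rbind(c(0L, 0L), c(0L, 0L),   # hom 00
                   c(0L, 1L), c(1L, 0L),   # het at both sites
                   c(1L, 1L), c(1L, 1L))   # hom 11
  sites <- tibble::tibble(chrom = "chr1", pos = c(10L, 20L), ref = "A",
                          alt = "T", is_indel = FALSE)
  hm <- hap_matrix(alleles, sites, c("a1", "a2", "a3"))
  pm <- tibble::tibble(accession = c("a1", "a2", "a3"), subpop = c("S", "L", "C"))
  ht <- collapse_haplotypes(hm, pm, "accession")
  expect_identical(sort(ht$allele_string), c("00", "11"))
  expect_equal(sum(ht$total), 4)  # 2 accessions x 2 chromosomes
  expect_identical(attr(ht, "exclusions")[["heterozygous"]], 1L)
})

test_that("collapse conserves chromosome counts on random matrices", {
  for (i in 1:10) {
    hm <- rand_hap_matrix(n_acc = 8, n_sites = 6, seed = 300 + i)
    pm <- tibble::tibble(accession = hm$accessions,
                         subpop = rep(c("S", "L", "C"), length.out = 8))
    ht <- collapse_haplotypes(hm, pm, "chromosome")
    expect_equal(sum(ht$total), 16)
    expect_equal(ht$total, ht$S + ht$L + ht$C)
  }
})

test_that("haplotype frequencies sum to one per subpopulation", {
  g <- mk_gene_matrix(c("00", "00", "00", "00", "01"),
                      c("S", "S", "S", "S", "S"))
  ht <- collapse_haplotypes(g$hm, g$pm)
  fr <- haplotype_frequencies(ht)
  s <- fr[fr$subpop == "S", ]
  expect_equal(sum(s$prop), 1)
  expect_equal(sort(s$prop), c(0.2, 0.8))
  expect_true(all(is.nan(fr$prop[fr$subpop == "C"])))
})

test_that("the frequency-shift z-test matches prop.test without correction", {
  g <- mk_gene_matrix(rep(c("00", "11"), times = c(30, 20)),
                      rep(c("S", "C"), each = 25))
  ht <- collapse_haplotypes(g$hm, g$pm)
  net <- mj_network(ht)
  gr <- assign_major_groups(net, "target_k", k = 2)
  sh <- frequency_shift_test(ht, gr, "S", "C")
  for (r in seq_len(nrow(sh))) {
    pt <- prop.test(c(sh$count1[r], sh$count2[r]), c(sh$n1[r], sh$n2[r]),
                    correct = FALSE)
    expect_equal(sh$z[r]^2, unname(pt$statistic), tolerance = 1e-9)
    expect_equal(sh$p_value[r], pt$p.value, tolerance = 1e-9)
  }
})

test_that("accession grouping requires homozygosity and maps through haplotypes", {
  alleles <- rbind(c(0L, 0L), c(0L, 0L),
                   c(1L, 1L), c(1L, 1L),
                   c(0L, 1L), c(1L, 0L))
  sites <- tibble::tibble(chrom = "chr1", pos = c(10L, 20L), ref = "A",
                          alt = "T", is_indel = FALSE)
  hm <- hap_matrix(alleles, sites, c("a1", "a2", "a3"))
  pm <- tibble::tibble(accession = c("a1", "a2", "a3"),
                       subpop = c("S", "C", "C"))
  ht <- collapse_haplotypes(hm, pm, "accession")
  gr <- assign_major_groups(mj_network(ht), "target_k", k = 2)
  ag <- assign_accession_groups(hm, gr)
  expect_identical(is.na(ag$group), c(FALSE, FALSE, TRUE))
  expect_identical(attr(ag, "exclusions")[["heterozygous"]], 1L)
  expect_false(ag$group[1] == ag$group[2])
})

test_that("unmapped accessions are rejected", {
  g <- mk_gene_matrix(c("01", "10"), c("S", "C"))
  expect_error(collapse_haplotypes(g$hm, g$pm[1, ], "chromosome"), "missing")
})
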