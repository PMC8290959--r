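test_that("EHH is 1 at the core and follows brute-force grouping", {
  hm <- rand_hap_matrix(4, 10, seed = 1)
  rows <- 1:8
  expect_equal(ehh_at(hm, rows, 5, 5, "right"), 1)

  # 4 chromosomes splitting 2+2 at the first flanking site -> 2/6
  alleles <- rbind(c(0L, 0L), c(0L, 0L), c(0L, 1L), c(0L, 1L))
  sites <- tibble::tibble(chrom = "chr1", pos = c(10L, 20L), ref = "A",
                          alt = "T", is_indel = FALSE)
  hm2 <- hap_matrix(alleles, sites, c("a1", "a2"))
  expect_equal(ehh_at(hm2, 1:4, 1, 2, "right"), 1 / 3)

  # identical chromosomes stay at 1 everywhere
  hm3 <- hap_matrix(matrix(0L, 4, 5),
                    tibble::tibble(chrom = "chr1", pos = as.integer(1:5 * 10),
                                   ref = "A", alt = "T", is_indel = FALSE),
                    c("a1", "a2"))
  for (e in 1:5) expect_equal(ehh_at(hm3, 1:4, 3, e, if (e <= 3) "left" else "right"), 1)
})

test_that("EHH decays monotonically from 1 on random phased matrices", {
  for (i in 1:100) {
    hm <- rand_hap_matrix(n_acc = sample(2:6, 1), n_sites = sample(8:20, 1),
                          seed = 1000 + i)
    core <- sample(ncol(hm$alleles), 1)
    curve <- ehh_curve(hm, seq_len(nrow(hm$alleles)), core)
    for (d in c("left", "right")) {
      e <- curve$ehh[curve$direction == d]
      expect_equal(e[1], 1)
      expect_true(all(diff(e) <= 1e-12))
    }
  }
})

test_that("iHH matches an explicit trapezoid oracle", {
  # EHH stays 1 for 1000 bp right of the core, then collapses below truncation
  n <- 6
  alleles <- cbind(matrix(0L, n, 3), as.integer(seq_len(n) %% 2),
                   matrix(0L, n, 1))
  pos <- c(100L, 600L, 1100L, 1101L, 1200L)
  sites <- tibble::tibble(chrom = "chr1", pos = pos, ref = "A", alt = "T",
                          is_indel = FALSE)
  hm <- hap_matrix(alleles, sites, c("a1", "a2", "a3"))
  cfgs <- scan_config(ehh_truncation = 0.5, edge_policy = "clip")
  got <- ihh(hm, 1:n, 1, cfgs)

  # oracle: trapezoid over the curve computed with the R-level ehh_at
  curve <- ehh_curve(hm, 1:n, 1)
  trap <- function(d) {
    cc <- curve[curve$direction == d, ]
    area <- 0
    for (k in 2:nrow(cc)) {
      area <- area + 0.5 * (cc$ehh[k] + cc$ehh[k - 1]) *
        (cc$distance_bp[k] - cc$distance_bp[k - 1])
      if (cc$ehh[k] < cfgs$ehh_truncation) break
    }
    area
  }
  expect_equal(as.numeric(got), trap("right"), tolerance = 1e-9)
})

test_that("identical chromosomes clip to the full span; symmetry holds", {
  n_sites <- 9
  hm <- hap_matrix(matrix(0L, 4, n_sites),
                   tibble::tibble(chrom = "chr1",
                                  pos = as.integer(seq_len(n_sites) * 100),
                                  ref = "A", alt = "T", is_indel = FALSE),
                   c("a1", "a2"))
  cfgs <- scan_config(edge_policy = "clip")
  v <- ihh(hm, 1:4, 5, cfgs)
  expect_equal(as.numeric(v), 400 + 400)  # left span + right span
  expect_identical(attr(v, "n_clipped"), 1L)
  expect_true(is.na(as.numeric(ihh(hm, 1:4, 5, scan_config(edge_policy = "discard")))))

  # symmetric data around the core: left and right integrals equal
  sym <- cbind(1L - (1:4 > 2), matrix(0L, 4, 1), 1L - (1:4 > 2))
  hs <- hap_matrix(matrix(as.integer(sym), 4),
                   tibble::tibble(chrom = "chr1", pos = c(100L, 200L, 300L),
                                  ref = "A", alt = "T", is_indel = FALSE),
                   c("a1", "a2"))
  curve <- ehh_curve(hs, 1:4, 2)
  left <- curve[curve$direction == "left", ]
  right <- curve[curve$direction == "right", ]
  expect_equal(left$ehh, right$ehh)
})

test_that("raw XP-EHH is a log ratio, antisymmetric under population swap", {
  expect_equal(xpehh_raw(2, 2), 0)
  expect_equal(xpehh_raw(2, 1), log(2))
  expect_true(is.nan(xpehh_raw(0, 1)))
  expect_true(is.nan(xpehh_raw(1, NaN)))
  set.seed(5)
  a <- runif(50, 0.1, 10); b <- runif(50, 0.1, 10)
  expect_identical(xpehh_raw(a, b), -xpehh_raw(b, a))
})

test_that("genome-wide normalization gives mean 0 and sd 1 (population sd)", {
  expect_equal(normalize_xpehh(c(-1, 1)), c(-1, 1))
  expect_error(normalize_xpehh(c(2, 2, 2)), "constant")
  expect_error(normalize_xpehh(c(1, NaN)), "finite")
  set.seed(8)
  raw <- c(rnorm(200), NaN, NaN)
  z <- normalize_xpehh(raw)
  fin <- is.finite(z)
  expect_equal(mean(z[fin]), 0, tolerance = 1e-9)
  expect_equal(sqrt(mean(z[fin]^2)), 1, tolerance = 1e-9)
  expect_true(all(is.nan(z[!fin])))
})

test_that("xpehh_scan restricts cores by pooled MAF and aggregates by window max", {
  cfg <- small_sim_config(seed = 9)
  co <- simulate_domestication(cfg)
  xp <- xpehh_scan(co$haplotypes, co$population_map, "C", "S")
  pooled <- site_maf(co$haplotypes,
                     c(pop_rows(co$haplotypes, co$population_map, "C"),
                       pop_rows(co$haplotypes, co$population_map, "S")))
  expect_true(all(pooled[xp$site_index] >= 0.05))
  fin <- is.finite(xp$znorm)
  expect_equal(mean(xp$znorm[fin]), 0, tolerance = 1e-9)

  tr <- xpehh_track(xp, scan_config(), cfg$chrom_length_bp)
  w <- which(is.finite(tr$value))[1]
  inw <- xp$pos > tr$start0[w] & xp$pos <= tr$end[w] & fin
  expect_equal(tr$value[w], max(xp$znorm[inw]))
})

test_that("EHH demands a phased matrix", {
  hm <- rand_hap_matrix(3, 6, seed = 2)
  hm$phased <- FALSE
  expect_error(ehh_at(hm, 1:6, 2, 3), "phased")
  expect_error(ihh(hm, 1:6, 2), "phased")
})
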