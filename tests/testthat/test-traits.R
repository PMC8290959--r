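test_that("student_t_test matches the textbook pooled formula", {
  x <- c(1, 2, 3, 4); y <- c(3, 4, 5, 6)
  got <- student_t_test(x, y)
  # independently coded pooled-variance t and incomplete-beta CDF
  sp2 <- ((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
    (length(x) + length(y) - 2)
  t_want <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / length(x) + 1 / length(y)))
  df <- length(x) + length(y) - 2
  p_want <- pbeta(df / (df + t_want^2), df / 2, 0.5)
  expect_equal(got$t, t_want, tolerance = 1e-9)
  expect_equal(got$df, df)
  expect_equal(got$p_value, p_want, tolerance = 1e-9)
})

test_that("t statistic is antisymmetric and identical samples give p = 1", {
  got <- student_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(got$t, 0)
  expect_equal(got$p_value, 1)
  set.seed(13)
  x <- rnorm(10); y <- rnorm(12, 1)
  expect_equal(student_t_test(x, y)$t, -student_t_test(y, x)$t)
  expect_equal(student_t_test(x, y)$p_value, student_t_test(y, x)$p_value)
  # Welch variant differs when variances differ
  xv <- c(x, 5, -5)
  expect_false(isTRUE(all.equal(student_t_test(xv, y)$df,
                                student_t_test(xv, y, welch = TRUE)$df)))
})

test_that("degenerate zero-variance inputs follow the stated contract", {
  same <- student_t_test(c(2, 2, 2), c(2, 2))
  expect_equal(same$p_value, 1)
  expect_warning(diff <- student_t_test(c(2, 2, 2), c(3, 3)), "zero variance")
  expect_equal(diff$p_value, 0)
  expect_error(student_t_test(1, c(1, 2)), ">= 2")
})

test_that("compact letters reproduce the canonical small cases", {
  all_ns <- matrix(1, 3, 3)
  expect_identical(compact_letter_display(all_ns, 0.05), c("a", "a", "a"))

  all_sig <- matrix(0, 3, 3)
  expect_identical(compact_letter_display(all_sig, 0.05), c("a", "b", "c"))

  chain <- matrix(c(1, 0.5, 0.01,
                    0.5, 1, 0.5,
                    0.01, 0.5, 1), 3, 3)
  expect_identical(compact_letter_display(chain, 0.05), c("a", "ab", "b"))

  expect_error(compact_letter_display(matrix(c(1, 0.2, 0.4, 1), 2, 2)),
               "symmetric")
})

test_that("emitted letters encode exactly the thresholded p matrix, minimally", {
  set.seed(17)
  for (i in 1:60) {
    n <- sample(2:6, 1)
    p <- matrix(0, n, n)
    p[upper.tri(p)] <- runif(n * (n - 1) / 2)
    p <- p + t(p); diag(p) <- 1
    lt <- compact_letter_display(p, 0.3)
    share <- p >= 0.3
    expect_identical(unname(letters_to_share(lt)), unname(share | diag(TRUE, n)))
    n_letters <- length(unique(unlist(strsplit(lt, ""))))
    expect_equal(n_letters, bf_cld_min_letters(share))
  }
})

test_that("associate_groups recovers configured group differences", {
  cfg <- sim_config(seed = 4)
  labels <- tibble::tibble(accession = sprintf("a%03d", 1:150),
                           group = rep(c("H_I", "H_II", "H_III"), each = 50))
  traits <- simulate_traits(labels, cfg)
  fit <- associate_groups(traits, labels, alpha = 0.05)
  sm <- fit$summary
  m <- function(trait, g) sm$mean[sm$trait == trait & sm$group == g]
  expect_gt(m("seed_weight_100", "H_III"), m("seed_weight_100", "H_II"))
  expect_gt(m("seed_weight_100", "H_II"), m("seed_weight_100", "H_I"))
  expect_lt(m("protein_pct", "H_III"), m("protein_pct", "H_I"))
  expect_true(all(tidy(fit)$p_value < 0.05))
  expect_identical(sort(unique(sm$letter)), c("a", "b", "c"))
  gl <- glance(fit)
  expect_identical(gl$all_significant, rep(TRUE, 3))
})

test_that("zero-noise cohorts give exact means and fully distinct letters", {
  cfg <- sim_config(seed = 1)
  cfg$trait_noise_sd[] <- 0
  labels <- tibble::tibble(accession = sprintf("a%02d", 1:30),
                           group = rep(c("H_I", "H_II", "H_III"), each = 10))
  traits <- simulate_traits(labels, cfg)
  fit <- suppressWarnings(associate_groups(traits, labels))
  sm <- fit$summary
  expect_equal(sm$mean[sm$trait == "seed_weight_100" & sm$group == "H_III"],
               unname(cfg$baseline_traits["seed_weight_100"] +
                        cfg$effect_sizes$seed_weight_100[["H_III"]]))
  expect_true(all(suppressWarnings(tidy(fit))$p_value == 0))
})

test_that("the subpopulation filter excludes other accessions entirely", {
  cfg <- sim_config(seed = 2)
  labels <- tibble::tibble(accession = sprintf("a%03d", 1:90),
                           group = rep(c("H_I", "H_II", "H_III"), each = 30))
  pop_map <- tibble::tibble(accession = labels$accession,
                            subpop = rep(c("S", "C"), length.out = 90))
  traits <- simulate_traits(labels, cfg)
  fit <- associate_groups(traits, labels, subpop = "C", pop_map = pop_map)
  expect_equal(sum(fit$summary$n[fit$summary$trait == "protein_pct"]), 45)
  expect_equal(fit$exclusions[["subpop_filtered"]], 45)
  # NA-group accessions are tallied, not dropped silently
  labels$group[1] <- NA
  fit2 <- associate_groups(traits, labels)
  expect_equal(fit2$exclusions[["unlabelled"]], 1)
})
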