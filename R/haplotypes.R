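#' Extract gene-region variants under a MAF filter
#'
#' Restricts a haplotype matrix to the sites of a genomic region (0-based
#' half-open) and removes polymorphisms with minor allele frequency below
#' `maf_min` (strictly less: a site at exactly `maf_min` is retained).
#'
#' @param x a [hap_matrix].
#' @param region either a string `"chr:start-end"` (interpreted 0-based
#'   half-open) or a list/tibble row with `chrom`, `start0`, `end`.
#' @param maf_min MAF cutoff, default 0.01.
#' @return a [hap_matrix] over the retained sites (possibly zero sites,
#'   with a warning).
#' @export
extract_gene_variants <- function(x, region, maf_min = 0.01) {
  region <- parse_region(region)
  maf <- site_maf(x)
  keep <- x$sites$chrom == region$chrom &
    x$sites$pos - 1L >= region$start0 & x$sites$pos - 1L < region$end &
    maf >= maf_min
  if (!any(keep)) warn("no variants retained in the requested region")
  subset_sites(x, keep)
}

parse_region <- function(region) {
  if (is.character(region) && length(region) == 1L) {
    m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
    if (length(m) != 4L) abort("region string must look like 'chr15:3870000-4000000'")
    region <- list(chrom = m[2], start0 = as.integer(m[3]), end = as.integer(m[4]))
  }
  if (!all(c("chrom", "start0", "end") %in% names(region))) {
    abort("region needs chrom, start0 and end")
  }
  if (region$start0 >= region$end) abort("region start must be < end")
  region
}

#' Collapse chromosomes into gene-region haplotypes
#'
#' Builds the haplotype table: distinct allele strings over the retained
#' sites with chromosome counts per subpopulation. Mode `"chromosome"`
#' (default) counts every phased chromosome; mode `"accession"` counts only
#' accessions homozygous at all retained sites (twice each) and tallies
#' excluded heterozygotes, matching how near-fully-selfing crop panels are
#' usually tabulated. Strings containing missing alleles are excluded and
#' tallied in either mode.
#'
#' @param x a [hap_matrix] restricted to the gene region (see
#'   [extract_gene_variants()]).
#' @param pop_map tibble `accession`, `subpop`.
#' @param mode `"chromosome"` or `"accession"`.
#' @return a `hap_table` tibble: `haplotype` (ids in descending total
#'   count), `allele_string`, one count column per subpopulation (S, L, C)
#'   and `total`; attribute `exclusions` holds the het/missing tallies.
#' @export
collapse_haplotypes <- function(x, pop_map, mode = c("chromosome", "accession")) {
  mode <- match.arg(mode)
  check_pop_map(x, pop_map)
  if (!x$phased && mode == "chromosome") {
    abort("chromosome-mode haplotyping requires a phased matrix")
  }
  a <- x$alleles
  subpop_of_acc <- setNames(pop_map$subpop, pop_map$accession)
  acc_rows <- rep(x$accessions, each = 2L)

  n_het <- 0L
  n_missing <- 0L
  if (mode == "chromosome") {
    complete <- stats::complete.cases(a)
    n_missing <- sum(!complete) # chromosomes with a missing allele
    strings <- apply(a[complete, , drop = FALSE], 1, paste, collapse = "")
    subpops <- subpop_of_acc[acc_rows[complete]]
  } else {
    odd <- seq(1L, nrow(a), 2L)
    h1 <- a[odd, , drop = FALSE]
    h2 <- a[odd + 1L, , drop = FALSE]
    comp <- stats::complete.cases(h1) & stats::complete.cases(h2)
    hom <- comp & rowSums(h1 != h2) == 0L
    n_missing <- sum(!comp)
    n_het <- sum(comp & !hom)
    strings <- rep(apply(h1[hom, , drop = FALSE], 1, paste, collapse = ""), each = 2L)
    subpops <- rep(subpop_of_acc[x$accessions[hom]], each = 2L)
  }
  if (!length(strings)) abort("no complete haplotypes to collapse")

  pops <- c("S", "L", "C")
  tab <- table(factor(strings), factor(subpops, levels = pops))
  out <- tibble::as_tibble(as.data.frame.matrix(tab), rownames = "allele_string")
  out$total <- rowSums(out[pops])
  out <- dplyr::arrange(out, dplyr::desc(.data$total), .data$allele_string)
  out <- tibble::tibble(haplotype = sprintf("hap%02d", seq_len(nrow(out))), out)
  class(out) <- c("hap_table", class(out))
  attr(out, "exclusions") <- c(heterozygous = n_het, missing = n_missing)
  attr(out, "n_sites") <- ncol(a)
  out
}

#' Per-subpopulation haplotype (or group) frequencies
#'
#' Proportions of each haplotype within each subpopulation; with a group
#' assignment, counts are aggregated to major groups first. Proportions sum
#' to one within every non-empty subpopulation (an empty subpopulation
#' yields NaN).
#'
#' @param table a `hap_table` from [collapse_haplotypes()].
#' @param groups optional [assign_major_groups()] result; aggregates to
#'   groups.
#' @return tibble `unit`, `subpop`, `count`, `n`, `prop`.
#' @export
haplotype_frequencies <- function(table, groups = NULL) {
  if (!nrow(table)) abort("empty haplotype table")
  pops <- intersect(c("S", "L", "C"), names(table))
  tb <- table
  if (!is.null(groups)) {
    key <- setNames(groups$group, groups$haplotype)
    tb <- dplyr::mutate(tb, unit = unname(key[.data$haplotype]))
  } else {
    tb <- dplyr::mutate(tb, unit = .data$haplotype)
  }
  long <- tidyr::pivot_longer(tb[c("unit", pops)], dplyr::all_of(pops),
                              names_to = "subpop", values_to = "count")
  long <- dplyr::summarise(dplyr::group_by(long, .data$unit, .data$subpop),
                           count = sum(.data$count), .groups = "drop")
  long <- dplyr::mutate(dplyr::group_by(long, .data$subpop), n = sum(.data$count))
  long <- dplyr::ungroup(dplyr::mutate(long, prop = ifelse(.data$n > 0, .data$count / .data$n, NaN)))
  dplyr::arrange(long, .data$unit, factor(.data$subpop, levels = c("S", "L", "C")))
}

#' Haplotype-group frequency shift between subpopulations
#'
#' Two-proportion z-test (no continuity correction) of each group's
#' frequency in one subpopulation against another — the classic test for a
#' domestication shift of haplotype frequencies between wild accessions and
#' cultivars.
#'
#' @param table a `hap_table`.
#' @param groups an [assign_major_groups()] result.
#' @param pop1,pop2 subpopulation codes to compare (default wild S vs
#'   cultivar C).
#' @return tibble `group`, `count1`, `n1`, `count2`, `n2`, `prop1`,
#'   `prop2`, `z`, `p_value`.
#' @export
frequency_shift_test <- function(table, groups, pop1 = "S", pop2 = "C") {
  fr <- haplotype_frequencies(table, groups)
  f1 <- dplyr::filter(fr, .data$subpop == pop1)
  f2 <- dplyr::filter(fr, .data$subpop == pop2)
  out <- dplyr::inner_join(f1, f2, by = "unit", suffix = c("1", "2"))
  p_pool <- (out$count1 + out$count2) / (out$n1 + out$n2)
  se <- sqrt(p_pool * (1 - p_pool) * (1 / out$n1 + 1 / out$n2))
  z <- ifelse(se > 0, (out$prop1 - out$prop2) / se, 0)
  tibble::tibble(group = out$unit,
                 count1 = out$count1, n1 = out$n1,
                 count2 = out$count2, n2 = out$n2,
                 prop1 = out$prop1, prop2 = out$prop2,
                 z = z, p_value = 2 * pnorm(-abs(z)))
}
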