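#' Phased haplotype matrix
#'
#' The substrate of every statistic in the package: a matrix of alleles with
#' one row per chromosome (two consecutive rows per accession) and one column
#' per variant site, together with per-site metadata. Alleles are coded
#' `0` (reference), `1` (alternate) or `NA` (missing).
#'
#' @param alleles integer matrix, chromosomes x sites; row count must be even.
#' @param sites tibble with columns `chrom`, `pos` (1-based bp), `ref`, `alt`,
#'   `is_indel`; positions must be strictly increasing within a chromosome.
#'   A `maf` column is (re)computed from `alleles`.
#' @param accessions character vector of accession ids, one per *pair* of rows.
#' @param phased logical; `TRUE` unless any heterozygous genotype was read
#'   unphased. EHH-based statistics require a phased matrix.
#'
#' @return An object of class `hap_matrix`.
#' @export
hap_matrix <- function(alleles, sites, accessions, phased = TRUE) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  if (nrow(alleles) %% 2L != 0L) {
    abort("allele matrix must have an even number of rows (2 per accession)")
  }
  if (nrow(alleles) != 2L * length(accessions)) {
    abort("row count must equal 2 x number of accessions")
  }
  sites <- tibble::as_tibble(sites)
  needed <- c("chrom", "pos", "ref", "alt", "is_indel")
  missing_cols <- setdiff(needed, names(sites))
  if (length(missing_cols)) {
    abort(paste0("sites is missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (nrow(sites) != ncol(alleles)) {
    abort("sites must have one row per allele-matrix column")
  }
  if (nrow(sites) > 1L && any(diff(sites$pos) <= 0 & sites$chrom[-1] == sites$chrom[-nrow(sites)])) {
    abort("site positions must be strictly increasing within a chromosome")
  }
  bad <- alleles[!is.na(alleles)]
  if (length(bad) && !all(bad %in% c(0L, 1L))) {
    abort("alleles must be 0, 1 or NA (biallelic coding)")
  }
  rownames(alleles) <- paste0(rep(accessions, each = 2L), c("_1", "_2"))
  x <- structure(
    list(alleles = alleles, sites = sites, accessions = accessions,
         phased = isTRUE(phased)),
    class = "hap_matrix"
  )
  x$sites$maf <- site_maf(x)
  x
}

#' Minor-allele frequency per site
#'
#' MAF is computed over non-missing chromosomes and always lies in
#' \[0, 0.5\]; a monomorphic site has MAF 0.
#'
#' @param x a [hap_matrix].
#' @param rows optional chromosome-row subset over which to compute.
#' @return numeric vector, one value per site.
#' @export
site_maf <- function(x, rows = NULL) {
  a <- x$alleles
  if (!is.null(rows)) a <- a[rows, , drop = FALSE]
  n <- colSums(!is.na(a))
  k <- colSums(a, na.rm = TRUE)
  p <- ifelse(n > 0, k / n, 0)
  pmin(p, 1 - p)
}

#' @export
print.hap_matrix <- function(x, ...) {
  cat(sprintf(
    "<hap_matrix> %d accessions (%d chromosomes) x %d sites [%s]\n",
    length(x$accessions), nrow(x$alleles), ncol(x$alleles),
    if (x$phased) "phased" else "unphased"
  ))
  if (ncol(x$alleles)) {
    cat(sprintf("  %s:%d-%d\n", x$sites$chrom[1], min(x$sites$pos), max(x$sites$pos)))
  }
  invisible(x)
}

#' @export
dim.hap_matrix <- function(x) dim(x$alleles)

#' Subset a haplotype matrix by site
#'
#' @param x a [hap_matrix].
#' @param keep logical or integer index over sites.
#' @return a [hap_matrix] restricted to the selected sites (MAF recomputed).
#' @export
subset_sites <- function(x, keep) {
  hap_matrix(x$alleles[, keep, drop = FALSE], x$sites[keep, , drop = FALSE],
             x$accessions, x$phased)
}

#' Chromosome rows belonging to a subpopulation
#'
#' @param x a [hap_matrix].
#' @param pop_map tibble with columns `accession`, `subpop`.
#' @param pop subpopulation code (e.g. `"S"`, `"L"`, `"C"`); several codes
#'   may be given to pool subpopulations.
#' @return integer vector of row indices into `x$alleles`.
#' @export
pop_rows <- function(x, pop_map, pop) {
  check_pop_map(x, pop_map)
  accs <- pop_map$accession[pop_map$subpop %in% pop]
  idx <- which(x$accessions %in% accs)
  if (!length(idx)) abort(paste0("no accessions in subpopulation ", paste(pop, collapse = "/")))
  sort(c(2L * idx - 1L, 2L * idx))
}

check_pop_map <- function(x, pop_map) {
  unmapped <- setdiff(x$accessions, pop_map$accession)
  if (length(unmapped)) {
    abort(paste0("accessions missing from population map: ",
                 paste(head(unmapped, 5L), collapse = ", ")))
  }
  invisible(TRUE)
}
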