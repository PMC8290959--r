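#' Read a phased VCF into a haplotype matrix
#'
#' Accepts biallelic VCFv4.2 records with a GT field. Phased genotypes
#' (`0|1`) are split into two chromosome rows per sample in file order;
#' unphased genotypes are accepted only when homozygous (phase is then
#' unambiguous) — an unphased heterozygote marks the whole matrix unphased
#' and is counted in the `unphased_records` attribute. `.` alleles become
#' missing. MAF is computed per site over non-missing chromosomes.
#'
#' @param path path to a VCF (plain or bgzipped).
#' @return a [hap_matrix]; indel status is inferred from REF/ALT lengths.
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt, fixed = TRUE)
  if (any(multi)) {
    i <- which(multi)[1]
    abort(sprintf("multiallelic record at %s:%s (split or drop it first)",
                  fix[i, "CHROM"], fix[i, "POS"]))
  }
  fmt <- v@gt[, 1]
  if (!all(vapply(strsplit(fmt, ":", fixed = TRUE), function(f) "GT" %in% f, logical(1)))) {
    abort("GT missing from FORMAT in at least one record")
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1, dimnames = list(NULL, names(gt)))
  samples <- colnames(gt)

  n_sites <- nrow(gt)
  alleles <- matrix(NA_integer_, nrow = 2L * length(samples), ncol = n_sites)
  phased <- TRUE
  unphased_het <- 0L
  for (j in seq_along(samples)) {
    g <- gt[, j]
    g[is.na(g)] <- ".|."
    parts <- strsplit(g, "[|/]")
    bad <- lengths(parts) != 2L
    if (any(bad)) {
      # haploid-style entries like "." -> both alleles missing
      parts[bad] <- list(c(".", "."))
    }
    a1 <- vapply(parts, `[`, character(1), 1L)
    a2 <- vapply(parts, `[`, character(1), 2L)
    het_unphased <- grepl("/", g, fixed = TRUE) & a1 != a2 & a1 != "." & a2 != "."
    if (any(het_unphased)) {
      phased <- FALSE
      unphased_het <- unphased_het + sum(het_unphased)
    }
    alleles[2L * j - 1L, ] <- suppressWarnings(as.integer(a1))
    alleles[2L * j, ] <- suppressWarnings(as.integer(a2))
  }

  sites <- tibble::tibble(
    chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"],
    alt = alt,
    is_indel = nchar(fix[, "REF"]) != 1L | nchar(alt) != 1L
  )
  out <- hap_matrix(alleles, sites, samples, phased = phased)
  attr(out, "unphased_records") <- unphased_het
  out
}

#' Write a haplotype matrix as plain-text VCFv4.2
#'
#' Phased GT (`a|b`), biallelic records, 1-based positions; missing alleles
#' written as `.`.
#'
#' @param x a [hap_matrix].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s>", unique(x$sites$chrom)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", x$accessions), collapse = "\t")
  ), con)
  if (ncol(x$alleles) == 0L) return(invisible(path))
  a <- x$alleles
  a_chr <- ifelse(is.na(a), ".", as.character(a))
  odd <- seq(1L, nrow(a), 2L)
  gt <- matrix(paste(a_chr[odd, , drop = FALSE], a_chr[odd + 1L, , drop = FALSE], sep = "|"),
               nrow = length(odd))
  lines <- paste(
    x$sites$chrom, x$sites$pos, ".", x$sites$ref, x$sites$alt, ".", "PASS", ".", "GT",
    apply(gt, 2, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(lines, con)
  invisible(path)
}

#' Read a sample-to-subpopulation map
#'
#' Two tab-separated columns with a header: `accession`, `subpop`; codes
#' must be S (wild/soja), L (landrace) or C (cultivar).
#'
#' @param path TSV path.
#' @return tibble `accession`, `subpop`.
#' @export
read_population_map <- function(path) {
  m <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                       progress = FALSE)
  names(m)[1:2] <- c("accession", "subpop")
  if (anyDuplicated(m$accession)) {
    abort(paste0("duplicate accession in population map: ",
                 m$accession[duplicated(m$accession)][1]))
  }
  bad <- setdiff(unique(m$subpop), c("S", "L", "C"))
  if (length(bad)) {
    abort(paste0("unknown subpopulation code(s): ", paste(bad, collapse = ", ")))
  }
  tibble::as_tibble(m[, 1:2])
}

#' Read a per-accession trait table
#'
#' Tab-separated with header `accession`, `seed_weight_100`,
#' `fatty_acid_pct`, `protein_pct`. Empty fields become missing values,
#' never zero.
#'
#' @param path TSV path.
#' @return tibble with one row per accession.
#' @export
read_trait_table <- function(path) {
  tt <- readr::read_tsv(path, col_types = readr::cols(
    accession = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE)
  if (anyDuplicated(tt$accession)) {
    abort(paste0("duplicate accession in trait table: ",
                 tt$accession[duplicated(tt$accession)][1]))
  }
  num <- dplyr::select(tt, -"accession")
  if (any(unlist(num) <= 0, na.rm = TRUE)) abort("trait values must be positive")
  pct <- dplyr::select(num, dplyr::ends_with("_pct"))
  if (any(unlist(pct) > 100, na.rm = TRUE)) abort("percentage traits must be <= 100")
  tibble::as_tibble(tt)
}

#' Read gene/QTL annotation intervals (BED)
#'
#' BED3+ with optional `name` and `category` columns; coordinates are
#' 0-based half-open. Recognised categories: `gene`, `qtl_seed_size`,
#' `qtl_oil`, `qtl_protein`.
#'
#' @param path BED path (no header).
#' @return tibble `chrom`, `start0`, `end`, `name`, `category`.
#' @export
read_bed <- function(path) {
  b <- readr::read_tsv(path, col_names = FALSE,
                       col_types = readr::cols(.default = readr::col_character()),
                       progress = FALSE)
  if (ncol(b) < 3L) abort("BED needs at least 3 columns")
  out <- tibble::tibble(
    chrom = b[[1]],
    start0 = as.integer(b[[2]]),
    end = as.integer(b[[3]]),
    name = if (ncol(b) >= 4L) b[[4]] else sprintf("iv%03d", seq_len(nrow(b))),
    category = if (ncol(b) >= 5L) b[[5]] else "gene"
  )
  bad <- which(!(out$start0 < out$end))
  if (length(bad)) abort(sprintf("malformed BED line %d: start must be < end", bad[1]))
  out
}

#' Write a windowed statistic track
#'
#' BED-like TSV `chrom  start0  end  stat  value` (0-based half-open
#' windows, 6 decimal places, `NA` for NaN/missing), with a header line.
#'
#' @param track a stat-track tibble (see [windowed_pi()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stat_track <- function(track, path) {
  out <- tibble::tibble(
    chrom = track$chrom, start0 = track$start0, end = track$end,
    stat = track$stat,
    value = ifelse(is.finite(track$value), sprintf("%.6f", track$value), "NA")
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a track written by [write_stat_track()]
#' @param path TSV path.
#' @return stat-track tibble.
#' @export
read_stat_track <- function(path) {
  tr <- readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(), start0 = readr::col_integer(),
    end = readr::col_integer(), stat = readr::col_character(),
    value = readr::col_double()
  ), progress = FALSE)
  as_stat_track(tr)
}

as_stat_track <- function(x) {
  x <- tibble::as_tibble(x)
  if (!inherits(x, "stat_track")) class(x) <- c("stat_track", class(x))
  x
}
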