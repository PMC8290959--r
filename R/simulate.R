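#' Configuration for the domestication simulator
#'
#' Parameterises a forward-in-time Wright-Fisher scenario that mimics crop
#' domestication: an ancestral wild population, a domestication bottleneck
#' with positive selection at one focal site, a later split of the
#' domesticated lineage into landrace and cultivar subpopulations, and a
#' high selfing rate typical of soybean. Defaults are desk-scale: they
#' produce hundreds of segregating sites and a detectable sweep in seconds.
#'
#' @param n_ancestral,n_bottleneck,n_landrace,n_cultivar diploid population
#'   sizes of the wild population, the domestication bottleneck, and the two
#'   domesticated subpopulations.
#' @param t_split generation at which the domesticated lineage is founded
#'   from the wild population.
#' @param t_subsplit generation at which the domesticated lineage splits
#'   into landrace and cultivar. The default, `t_split + 3`, makes the
#'   founding bottleneck near-instantaneous (50 founder plants immediately
#'   multiplied), the standard instantaneous-bottleneck model.
#' @param t_total total number of generations simulated.
#' @param mu per-site per-generation mutation probability (0/1 flip).
#' @param r per-adjacent-site per-generation recombination probability.
#' @param selfing_rate probability that an offspring is produced by selfing.
#' @param s selection coefficient at the focal site; genotype fitnesses in
#'   the domesticated lineage are 1, 1 + s/2, 1 + s (additive). Selection
#'   never acts in the wild lineage (artificial selection only).
#' @param focal_index 1-based index of the site under selection.
#' @param chrom_length_bp,n_sites chromosome length and number of (evenly
#'   spaced) variant sites tracked.
#' @param p_polymorphic fraction of sites carrying standing variation at
#'   generation 0; initial derived-allele frequencies are uniform on
#'   \[0.05, 0.95\], emulating variation ascertained as common in a
#'   diversity panel.
#' @param init_focal_freq frequency of the adaptive allele among the
#'   bottleneck founder chromosomes at `t_split`. The copies are placed on
#'   a cluster of mutually near-identical founder chromosomes (one selfing
#'   lineage), emulating a single-origin variant that is absent from the
#'   wild lineage — the hard-sweep scenario in which the cultivar
#'   haplotype group is essentially missing from wild accessions.
#' @param n_linked number of sites flanking the focal site that carry
#'   private derived alleles of the adaptive lineage, so the swept
#'   haplotype is distinguished from wild haplotypes by `n_linked + 1`
#'   clustered variants in the gene region (default 9, i.e. ten variants
#'   in all).
#' @param sample_sizes named integer vector: accessions sampled per
#'   subpopulation, names `S` (wild/soja), `L` (landrace), `C` (cultivar).
#' @param baseline_traits named numeric: trait means for haplotype group
#'   H_I. Traits are `seed_weight_100` (g), `fatty_acid_pct` (% DW),
#'   `protein_pct` (% DW).
#' @param effect_sizes list of named numeric vectors (one per trait) giving
#'   the additive shift of groups H_I/H_II/H_III. Defaults follow the
#'   domestication syndrome: seed weight and oil rise, protein falls from
#'   group I to III.
#' @param trait_noise_sd named numeric: Gaussian noise s.d. per trait.
#' @param seed integer RNG seed; identical configs give bit-identical
#'   cohorts.
#'
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_ancestral = 500, n_bottleneck = 50,
                       n_landrace = 1000, n_cultivar = 1000,
                       t_split = 50, t_subsplit = NULL, t_total = 150,
                       mu = 1e-5, r = 2e-3, selfing_rate = 0.95,
                       s = 0.1, focal_index = NULL,
                       chrom_length_bp = 1e6, n_sites = 2000,
                       p_polymorphic = 0.8, init_focal_freq = 0.15,
                       n_linked = 9,
                       sample_sizes = c(S = 60, L = 80, C = 60),
                       baseline_traits = c(seed_weight_100 = 8,
                                           fatty_acid_pct = 16,
                                           protein_pct = 45),
                       effect_sizes = list(
                         seed_weight_100 = c(H_I = 0, H_II = 4, H_III = 8),
                         fatty_acid_pct  = c(H_I = 0, H_II = 2, H_III = 4),
                         protein_pct     = c(H_I = 0, H_II = -2, H_III = -4)),
                       trait_noise_sd = c(seed_weight_100 = 2,
                                          fatty_acid_pct = 1.5,
                                          protein_pct = 1.5),
                       seed = 1L) {
  if (is.null(focal_index)) focal_index <- as.integer(n_sites / 2)
  if (is.null(t_subsplit)) t_subsplit <- as.integer(t_split + 3L)
  cfg <- list(
    n_ancestral = as.integer(n_ancestral), n_bottleneck = as.integer(n_bottleneck),
    n_landrace = as.integer(n_landrace), n_cultivar = as.integer(n_cultivar),
    t_split = as.integer(t_split), t_subsplit = as.integer(t_subsplit),
    t_total = as.integer(t_total),
    mu = mu, r = r, selfing_rate = selfing_rate, s = s,
    focal_index = as.integer(focal_index),
    chrom_length_bp = as.integer(chrom_length_bp), n_sites = as.integer(n_sites),
    p_polymorphic = p_polymorphic, init_focal_freq = init_focal_freq,
    n_linked = as.integer(n_linked),
    sample_sizes = sample_sizes,
    baseline_traits = baseline_traits, effect_sizes = effect_sizes,
    trait_noise_sd = trait_noise_sd, seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  counts <- c(cfg$n_ancestral, cfg$n_bottleneck, cfg$n_landrace, cfg$n_cultivar)
  if (any(!is.finite(counts)) || any(counts < 2)) {
    abort("population sizes must be finite and >= 2")
  }
  rates <- c(mu = cfg$mu, r = cfg$r, selfing_rate = cfg$selfing_rate,
             p_polymorphic = cfg$p_polymorphic, init_focal_freq = cfg$init_focal_freq)
  if (any(!is.finite(rates)) || any(rates < 0) || any(rates > 1)) {
    abort("mu, r, selfing_rate, p_polymorphic and init_focal_freq must lie in [0, 1]")
  }
  if (!is.finite(cfg$s) || cfg$s < 0) abort("selection coefficient s must be finite and >= 0")
  if (cfg$focal_index < 1L || cfg$focal_index > cfg$n_sites) {
    abort("focal_index must lie in [1, n_sites]")
  }
  if (cfg$n_linked < 0L || cfg$n_linked >= cfg$n_sites) {
    abort("n_linked must lie in [0, n_sites)")
  }
  if (!(cfg$t_split < cfg$t_total)) abort("t_split must be < t_total")
  if (!(cfg$t_split <= cfg$t_subsplit && cfg$t_subsplit <= cfg$t_total)) {
    abort("t_subsplit must lie in [t_split, t_total]")
  }
  if (!all(c("S", "L", "C") %in% names(cfg$sample_sizes))) {
    abort("sample_sizes must be named with S, L and C")
  }
  invisible(cfg)
}

# Sites reserved for the adaptive haplotype: the focal site plus the
# n_linked nearest sites, which stay monomorphic in the standing
# population and become private variants of the injected lineage.
adaptive_sites <- function(cfg) {
  if (cfg$n_linked < 1L) return(cfg$focal_index)
  d <- abs(seq_len(cfg$n_sites) - cfg$focal_index)
  d[cfg$focal_index] <- -1L
  head(order(d, seq_len(cfg$n_sites)), cfg$n_linked + 1L)
}

# Initial standing variation: every polymorphic site starts at a uniform
# intermediate frequency (panel-ascertained common variation). The
# adaptive-haplotype sites start monomorphic; their variants enter at the
# domestication founding (see inject_focal_allele).
init_population <- function(cfg) {
  n_chrom <- 2L * cfg$n_ancestral
  m <- matrix(0L, nrow = n_chrom, ncol = cfg$n_sites)
  poly <- stats::runif(cfg$n_sites) < cfg$p_polymorphic
  poly[adaptive_sites(cfg)] <- FALSE
  counts <- integer(cfg$n_sites)
  if (any(poly)) {
    counts[poly] <- pmax(1L, pmin(n_chrom - 1L, as.integer(round(
      stats::runif(sum(poly), 0.05, 0.95) * n_chrom))))
  }
  for (j in which(counts > 0L)) {
    m[sample.int(n_chrom, counts[j]), j] <- 1L
  }
  m
}

# Place the adaptive haplotype at frequency init_focal_freq among the
# founding chromosomes as copies of a single founder chromosome — one
# favoured plant multiplied at the onset of domestication, so the sweep is
# hard (single origin). The lineage carries the derived allele at the
# focal site and the n_linked sites around it: a private gene-region
# haplotype, the way a cultivar-enriched haplotype group differs from wild
# haplotypes at a handful of clustered SNPs and In/Dels.
inject_focal_allele <- function(founders, cfg) {
  k <- round(cfg$init_focal_freq * nrow(founders))
  if (k < 1L) return(founders)
  seed_row <- sample.int(nrow(founders), 1L)
  d <- colSums(abs(t(founders) - founders[seed_row, ]))
  carriers <- order(d, seq_len(nrow(founders)))[seq_len(k)]
  founders[carriers, ] <- rep(founders[seed_row, ], each = k)
  founders[carriers, adaptive_sites(cfg)] <- 1L
  founders
}

sample_diploids <- function(pop, n, prefix) {
  n_dip <- nrow(pop) / 2L
  idx <- sort(sample.int(n_dip, n))
  rows <- as.vector(rbind(2L * idx - 1L, 2L * idx))
  list(alleles = pop[rows, , drop = FALSE],
       accessions = sprintf("%s%03d", prefix, seq_len(n)))
}

#' Simulate a domestication cohort
#'
#' Runs the Wright-Fisher scenario described in [sim_config()]: the wild
#' lineage evolves neutrally at its ancestral size for the whole simulation;
#' at `t_split` a bottleneck of `n_bottleneck` founders starts the
#' domesticated lineage, in which the focal allele is positively selected;
#' at `t_subsplit` that lineage splits into landrace and cultivar.
#' Accessions are then sampled from each subpopulation, and seed traits are
#' generated from the truth haplotype-group labels (focal-allele dosage:
#' 0/1/2 copies give groups H_I/H_II/H_III).
#'
#' Loss of the focal allele before sampling is not an error; the realized
#' frequency is reported in `$truth` so callers can resample with a new
#' seed.
#'
#' @param config a [sim_config()].
#' @return a `sim_cohort` list with elements `haplotypes` ([hap_matrix]),
#'   `population_map` (tibble `accession`, `subpop`), `traits` (tibble),
#'   and `truth` (focal position, realized focal frequency per
#'   subpopulation, per-accession group labels).
#' @export
simulate_domestication <- function(config) {
  validate_sim_config(config)
  cfg <- config
  set.seed(cfg$seed)

  positions <- unique(as.integer(round(seq(1, cfg$chrom_length_bp, length.out = cfg$n_sites))))
  if (length(positions) != cfg$n_sites) {
    abort("chrom_length_bp too short for n_sites distinct positions")
  }

  anc0 <- init_population(cfg)
  anc <- wf_evolve_cpp(anc0, cfg$n_ancestral, cfg$t_split, cfg$mu, cfg$r,
                       cfg$selfing_rate, 0, cfg$focal_index - 1L, FALSE)
  wild <- wf_evolve_cpp(anc, cfg$n_ancestral, cfg$t_total - cfg$t_split,
                        cfg$mu, cfg$r, cfg$selfing_rate, 0,
                        cfg$focal_index - 1L, FALSE)
  founders <- sample_diploids(anc, cfg$n_bottleneck, "F")$alleles
  founders <- inject_focal_allele(founders, cfg)
  dom <- wf_evolve_cpp(founders, cfg$n_bottleneck, cfg$t_subsplit - cfg$t_split,
                       cfg$mu, cfg$r, cfg$selfing_rate, cfg$s,
                       cfg$focal_index - 1L, TRUE)
  lr <- wf_evolve_cpp(dom, cfg$n_landrace, cfg$t_total - cfg$t_subsplit,
                      cfg$mu, cfg$r, cfg$selfing_rate, cfg$s,
                      cfg$focal_index - 1L, TRUE)
  cv <- wf_evolve_cpp(dom, cfg$n_cultivar, cfg$t_total - cfg$t_subsplit,
                      cfg$mu, cfg$r, cfg$selfing_rate, cfg$s,
                      cfg$focal_index - 1L, TRUE)

  sS <- sample_diploids(wild, cfg$sample_sizes[["S"]], "S")
  sL <- sample_diploids(lr, cfg$sample_sizes[["L"]], "L")
  sC <- sample_diploids(cv, cfg$sample_sizes[["C"]], "C")

  alleles <- rbind(sS$alleles, sL$alleles, sC$alleles)
  accessions <- c(sS$accessions, sL$accessions, sC$accessions)
  pop_map <- tibble::tibble(
    accession = accessions,
    subpop = rep(c("S", "L", "C"), times = c(length(sS$accessions),
                                             length(sL$accessions),
                                             length(sC$accessions)))
  )

  site_meta <- make_site_meta(positions)
  focal_pos <- positions[cfg$focal_index]

  # keep sites carrying at least one derived allele in the sample; always
  # keep the focal site so truth bookkeeping stays aligned
  carried <- colSums(alleles) > 0L
  carried[cfg$focal_index] <- TRUE
  hm <- hap_matrix(alleles[, carried, drop = FALSE],
                   site_meta[carried, , drop = FALSE], accessions)

  focal_col <- alleles[, cfg$focal_index]
  dose <- focal_col[seq(1, length(focal_col), 2)] + focal_col[seq(2, length(focal_col), 2)]
  groups <- tibble::tibble(
    accession = accessions,
    group = c("H_I", "H_II", "H_III")[dose + 1L]
  )
  freq_by <- vapply(split(focal_col, rep(pop_map$subpop, each = 2)), mean, numeric(1))
  truth <- list(
    focal_pos = focal_pos,
    focal_freq = freq_by[c("S", "L", "C")],
    groups = groups,
    focal_lost = all(focal_col == 0L)
  )

  traits <- simulate_traits(groups, cfg)

  structure(list(haplotypes = hm, population_map = pop_map,
                 traits = traits, truth = truth, config = cfg),
            class = "sim_cohort")
}

# ref/alt pairs, with ~10% short indels so both marker types flow through
# the pipeline as they do in resequencing panels
make_site_meta <- function(positions) {
  n <- length(positions)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
  is_indel <- stats::runif(n) < 0.1
  alt[is_indel] <- paste0(ref[is_indel], alt[is_indel])
  tibble::tibble(chrom = "chr1", pos = positions, ref = ref, alt = alt,
                 is_indel = is_indel)
}

#' Generate haplotype-group-driven seed traits
#'
#' Each trait value is `baseline + group effect + Gaussian noise`. Default
#' effect signs mirror the domestication syndrome: 100-seed weight and
#' fatty-acid content increase while protein content decreases from group
#' H_I to H_III.
#'
#' @param group_labels tibble with columns `accession` and `group`.
#' @param config a [sim_config()]; uses its `baseline_traits`,
#'   `effect_sizes`, `trait_noise_sd` and `seed` (trait generation has its
#'   own RNG substream so the same config always yields the same table).
#' @return tibble `accession`, `seed_weight_100`, `fatty_acid_pct`,
#'   `protein_pct`.
#' @export
simulate_traits <- function(group_labels, config) {
  cfg <- config
  if (!all(c("accession", "group") %in% names(group_labels))) {
    abort("group_labels needs columns accession and group")
  }
  if (any(is.na(group_labels$group))) abort("every accession must be labelled")
  set.seed(cfg$seed + 1L)
  n <- nrow(group_labels)
  out <- tibble::tibble(accession = group_labels$accession)
  for (tr in names(cfg$baseline_traits)) {
    eff <- cfg$effect_sizes[[tr]]
    unknown <- setdiff(unique(group_labels$group), names(eff))
    if (length(unknown)) {
      abort(paste0("no effect size for group(s) ", paste(unknown, collapse = ", "),
                   " in trait ", tr))
    }
    out[[tr]] <- cfg$baseline_traits[[tr]] + unname(eff[group_labels$group]) +
      rnorm(n, 0, cfg$trait_noise_sd[[tr]])
  }
  out
}

#' Write a simulated cohort to disk
#'
#' Emits the exact formats the pipeline consumes: a plain-text VCFv4.2 with
#' phased GT, a population-map TSV, a trait TSV and a truth JSON. The VCF
#' round-trips losslessly through [read_vcf()].
#'
#' @param cohort a `sim_cohort` from [simulate_domestication()].
#' @param out_dir output directory (created if needed).
#' @return named character vector of the four file paths.
#' @export
write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    vcf = file.path(out_dir, "cohort.vcf"),
    popmap = file.path(out_dir, "popmap.tsv"),
    traits = file.path(out_dir, "traits.tsv"),
    truth = file.path(out_dir, "truth.json")
  )
  write_vcf(cohort$haplotypes, paths[["vcf"]])
  readr::write_tsv(cohort$population_map, paths[["popmap"]])
  readr::write_tsv(cohort$traits, paths[["traits"]])
  truth <- cohort$truth
  jsonlite::write_json(
    list(focal_pos = truth$focal_pos,
         focal_freq = as.list(truth$focal_freq),
         focal_lost = truth$focal_lost,
         groups = truth$groups),
    paths[["truth"]], auto_unbox = TRUE, digits = NA
  )
  paths
}
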