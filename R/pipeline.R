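#' Pipeline run configuration
#'
#' Bundles every setting for a full simulate -> scan -> XP-EHH -> sweep
#' call -> haplotype -> network -> association run. When `vcf` is NULL the
#' cohort is simulated with `sim`; otherwise the given files are read.
#'
#' @param out_dir output directory for all artifacts.
#' @param vcf,popmap,traits,annotations optional input paths (phased VCF,
#'   population-map TSV, trait TSV, BED annotation track).
#' @param sim a [sim_config()] used when no VCF is given.
#' @param scan a [scan_config()].
#' @param pop_a,pop_b populations contrasted in the scans (cultivar vs
#'   wild).
#' @param min_support statistics required to flag a sweep window.
#' @param merge_gap_bp gap tolerance for region merging.
#' @param hap_region gene region for haplotyping (`"chr:start-end"`), or
#'   NULL to use a window of `2 * hap_halfwidth` bp centred on the
#'   midpoint of the strongest called sweep region (or on the genome-wide
#'   F_ST peak when no region was called).
#' @param hap_halfwidth half-width in bp of the default haplotyping
#'   region (default 5000, i.e. a 10-kb candidate-gene zoom).
#' @param maf_min haplotyping MAF filter.
#' @param hap_mode `"chromosome"` or `"accession"` haplotype counting.
#' @param n_groups target number of major haplotype groups.
#' @param alpha significance level for trait tests.
#' @param assoc_subpop optional subpopulation filter for the association
#'   stage (e.g. `"C"`).
#' @param seed master seed; each stage derives its own substream
#'   (`seed + stage index`) so stages are individually rerunnable yet
#'   jointly deterministic.
#' @return a `run_config` list.
#' @export
run_config <- function(out_dir, vcf = NULL, popmap = NULL, traits = NULL,
                       annotations = NULL, sim = sim_config(),
                       scan = scan_config(), pop_a = "C", pop_b = "S",
                       min_support = 3, merge_gap_bp = 0,
                       hap_region = NULL, hap_halfwidth = 5000, maf_min = 0.01,
                       hap_mode = "chromosome", n_groups = 3, alpha = 0.05,
                       assoc_subpop = NULL, seed = 1L) {
  if (!is.null(vcf)) {
    for (p in c(vcf, popmap, traits)) {
      if (!is.null(p) && !file.exists(p)) abort(paste0("input does not exist: ", p))
    }
  }
  structure(list(out_dir = out_dir, vcf = vcf, popmap = popmap,
                 traits = traits, annotations = annotations, sim = sim,
                 scan = scan, pop_a = pop_a, pop_b = pop_b,
                 min_support = min_support, merge_gap_bp = merge_gap_bp,
                 hap_region = hap_region, hap_halfwidth = as.integer(hap_halfwidth),
                 maf_min = maf_min,
                 hap_mode = hap_mode, n_groups = n_groups, alpha = alpha,
                 assoc_subpop = assoc_subpop, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full sweep-to-association pipeline
#'
#' Executes all seven stages, writes every intermediate artifact under
#' `config$out_dir`, and returns (and writes) a JSON manifest with the
#' config hash, per-stage wall-clock seconds, warning counters and md5
#' checksums of every artifact. A rerun with the same config and seed
#' reproduces identical checksums. Any stage error aborts with the stage
#' name after flushing the partial manifest.
#'
#' @param config a [run_config()].
#' @return the manifest, invisibly (list; also written to
#'   `manifest.json`).
#' @export
run_pipeline <- function(config) {
  cfg <- config
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package = as.character(utils::packageVersion("haplosweep")),
    seed = cfg$seed,
    # hash the scientific configuration, not the output location
    config_hash = rlang::hash(unclass(cfg)[setdiff(names(cfg), "out_dir")]),
    stages = list()
  )
  env <- new.env(parent = emptyenv())
  stage_i <- 0L

  flush_manifest <- function() {
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  stage <- function(name, fun) {
    stage_i <<- stage_i + 1L
    set.seed(cfg$seed + stage_i)
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e) {
      manifest$stages[[name]] <<- list(status = "error", message = conditionMessage(e))
      flush_manifest()
      abort(paste0("stage '", name, "' failed: ", conditionMessage(e)))
    })
    outputs <- res$outputs %||% character()
    sums <- if (length(outputs)) as.list(tools::md5sum(outputs)) else list()
    manifest$stages[[name]] <<- list(
      status = "ok",
      seconds = round(proc.time()[["elapsed"]] - t0, 3),
      outputs = sums,
      warnings = res$warnings %||% list()
    )
    flush_manifest()
    invisible(res)
  }

  out <- function(...) file.path(cfg$out_dir, ...)

  stage("simulate", function() {
    if (is.null(cfg$vcf)) {
      sim_cfg <- cfg$sim
      sim_cfg$seed <- cfg$seed
      cohort <- simulate_domestication(sim_cfg)
      paths <- write_cohort(cohort, out("data"))
      env$hm <- cohort$haplotypes
      env$pop_map <- cohort$population_map
      env$traits <- cohort$traits
      env$truth <- cohort$truth
      env$chrom_length <- sim_cfg$chrom_length_bp
      list(outputs = unname(paths))
    } else {
      env$hm <- read_vcf(cfg$vcf)
      env$pop_map <- read_population_map(cfg$popmap)
      if (is.null(cfg$traits)) abort("trait table path is required")
      env$traits <- read_trait_table(cfg$traits)
      env$chrom_length <- max(env$hm$sites$pos)
      list(outputs = character())
    }
  })

  stage("scan", function() {
    env$pi_b <- windowed_pi(env$hm, env$pop_map, cfg$pop_b, cfg$scan,
                            env$chrom_length)
    env$pi_a <- windowed_pi(env$hm, env$pop_map, cfg$pop_a, cfg$scan,
                            env$chrom_length)
    env$ratio <- pi_ratio(env$pi_b, env$pi_a)  # pi_wild / pi_cultivar
    env$fst <- windowed_fst(env$hm, env$pop_map, cfg$pop_a, cfg$pop_b,
                            cfg$scan, env$chrom_length)
    paths <- c(out("pi_b.tsv"), out("pi_a.tsv"), out("pi_ratio.tsv"), out("fst.tsv"))
    write_stat_track(env$pi_b, paths[1]); write_stat_track(env$pi_a, paths[2])
    write_stat_track(env$ratio, paths[3]); write_stat_track(env$fst, paths[4])
    list(outputs = paths)
  })

  stage("xpehh", function() {
    env$xp <- xpehh_scan(env$hm, env$pop_map, cfg$pop_a, cfg$pop_b, cfg$scan)
    env$xp_track <- xpehh_track(env$xp, cfg$scan, env$chrom_length)
    p1 <- out("xpehh_sites.tsv"); p2 <- out("xpehh.tsv")
    readr::write_tsv(env$xp, p1, progress = FALSE)
    write_stat_track(env$xp_track, p2)
    list(outputs = c(p1, p2),
         warnings = list(edge_clips = attr(env$xp, "n_clipped")))
  })

  stage("callsweeps", function() {
    tracks <- list(pi_ratio = env$ratio, fst = env$fst,
                   xpehh_norm = env$xp_track)
    env$thresholds <- vapply(tracks, empirical_threshold, numeric(1),
                             top_quantile = cfg$scan$top_quantile)
    env$regions <- call_sweeps(tracks, env$thresholds,
                               min_support = cfg$min_support,
                               merge_gap_bp = cfg$merge_gap_bp)
    if (!is.null(cfg$annotations)) {
      env$regions <- annotate_regions(env$regions, read_bed(cfg$annotations))
    }
    p <- out("sweep_regions.tsv")
    readr::write_tsv(env$regions, p, progress = FALSE)
    list(outputs = p)
  })

  stage("haplotype", function() {
    region <- cfg$hap_region
    fallback <- 0L
    if (is.null(region)) {
      # candidate-gene zoom: hap_halfwidth around the F_ST peak of the
      # strongest called region (or the genome-wide peak if none called)
      if (nrow(env$regions)) {
        top <- dplyr::arrange(env$regions, dplyr::desc(.data$n_windows))[1, ]
        mid <- (top$start0 + top$end) %/% 2L
        chrom <- top$chrom
      } else {
        fallback <- 1L
        peak <- which.max(env$fst$value)
        mid <- (env$fst$start0[peak] + env$fst$end[peak]) %/% 2L
        chrom <- env$fst$chrom[peak]
      }
      region <- list(chrom = chrom,
                     start0 = max(0L, mid - cfg$hap_halfwidth),
                     end = mid + cfg$hap_halfwidth)
    }
    env$gene_hm <- extract_gene_variants(env$hm, region, cfg$maf_min)
    env$hap_table <- collapse_haplotypes(env$gene_hm, env$pop_map, cfg$hap_mode)
    p <- out("haplotypes.tsv")
    readr::write_tsv(env$hap_table, p, progress = FALSE)
    list(outputs = p,
         warnings = c(as.list(attr(env$hap_table, "exclusions")),
                      list(region_fallback = fallback)))
  })

  stage("network", function() {
    env$net <- mj_network(env$hap_table)
    # nearest achievable group count when exactly n_groups is impossible
    n_obs <- sum(!env$net$nodes$is_median)
    k_used <- NA_integer_
    for (k_try in c(cfg$n_groups, cfg$n_groups + seq_len(max(0, n_obs - cfg$n_groups)),
                    rev(seq_len(cfg$n_groups - 1)))) {
      got <- tryCatch(assign_major_groups(env$net, "target_k", k = k_try),
                      error = function(e) NULL)
      if (!is.null(got)) { env$groups <- got; k_used <- k_try; break }
    }
    if (is.null(env$groups)) abort("no achievable group count")
    env$freqs <- haplotype_frequencies(env$hap_table, env$groups)
    env$shift <- frequency_shift_test(env$hap_table, env$groups,
                                      cfg$pop_b, cfg$pop_a)
    p <- c(out("network.graphml"), out("hap_groups.tsv"),
           out("group_freqs.tsv"), out("freq_shift.tsv"))
    write_network(env$net, p[1])
    readr::write_tsv(env$groups, p[2], progress = FALSE)
    readr::write_tsv(env$freqs, p[3], progress = FALSE)
    readr::write_tsv(env$shift, p[4], progress = FALSE)
    list(outputs = p, warnings = list(n_groups_used = k_used))
  })

  stage("associate", function() {
    acc_groups <- assign_accession_groups(env$gene_hm, env$groups)
    env$assoc <- associate_groups(env$traits, acc_groups, alpha = cfg$alpha,
                                  subpop = cfg$assoc_subpop,
                                  pop_map = env$pop_map)
    p <- c(out("trait_summary.tsv"), out("trait_pairwise.tsv"))
    readr::write_tsv(env$assoc$summary, p[1], progress = FALSE)
    readr::write_tsv(env$assoc$pairwise, p[2], progress = FALSE)
    list(outputs = p,
         warnings = as.list(attr(acc_groups, "exclusions")))
  })

  manifest$results <- list(
    n_regions = nrow(env$regions),
    n_haplotypes = nrow(env$hap_table),
    thresholds = as.list(env$thresholds)
  )
  flush_manifest()
  res <- list(manifest = manifest, regions = env$regions,
              hap_table = env$hap_table, groups = env$groups,
              freqs = env$freqs, shift = env$shift,
              association = env$assoc, truth = env$truth %||% NULL)
  invisible(res)
}
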