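#' Configuration for a full pipeline run
#'
#' Collects the input paths and every tunable threshold in one place, so
#' a run is a pure function of (inputs, config, seed). The defaults
#' expect the layout produced by [write_panel()].
#'
#' @param dir Panel directory (as written by [write_panel()]); the
#'   individual paths below default relative to it.
#' @param endo_vcf,mt_vcf,nuc_vcf VCF paths.
#' @param depth_dir Directory of `<sample>_<contig>.tsv` depth tables.
#' @param assoc_regions_bed BED of candidate nuclear regions for
#'   association; `NULL` disables the association stage's region
#'   restriction, `NA` means no regions (empty association table).
#' @param region_mt,region_endo Nuclear normalisation intervals
#'   (named vectors `c(start=, end=)` on the nuclear contig) for the two
#'   titre estimates.
#' @param min_breadth,min_depth Infection thresholds (strict).
#' @param max_missing Site missingness ceiling.
#' @param density_window_bp,density_max_snps SNP-density mask
#'   parameters.
#' @param coverage_mask_factor High-coverage mask multiple.
#' @param window_bp Diversity window width.
#' @param replicates Coalescent null replicates.
#' @param min_count Association minor-allele-count floor.
#' @param alpha Association p-value cutoff.
#' @param ploidy_factor Titre ploidy convention (1 = plain depth ratio).
#' @param seed Seed for the simulation stages, echoed in every output.
#' @return A list of class `panel_config`.
#' @export
panel_config <- function(dir,
                         endo_vcf = file.path(dir, "endo.vcf"),
                         mt_vcf = file.path(dir, "mt.vcf"),
                         nuc_vcf = file.path(dir, "nuc.vcf"),
                         depth_dir = file.path(dir, "depth"),
                         assoc_regions_bed = file.path(dir, "assoc_regions.bed"),
                         region_mt = c(start = 1L, end = 12000L),
                         region_endo = c(start = 15001L, end = 30000L),
                         min_breadth = 0.90, min_depth = 1.0,
                         max_missing = 0.10,
                         density_window_bp = 2000L, density_max_snps = 20L,
                         coverage_mask_factor = 3.0,
                         window_bp = 10000L,
                         replicates = 2000L,
                         min_count = 3L,
                         alpha = 9e-6,
                         ploidy_factor = 1.0,
                         seed = 1L) {
  stopifnot(max_missing >= 0, max_missing <= 1, replicates >= 1,
            alpha > 0, alpha <= 1, window_bp > 0, coverage_mask_factor > 0)
  structure(as.list(environment()), class = "panel_config")
}

#' Run the full panel analysis
#'
#' Executes every stage on the configured inputs: VCF reading and QC,
#' infection calling, coverage masking, titre estimation and the
#' mt-endo relationship, windowed diversity plus fixed-S coalescent
#' null tests of Tajima's D, cross-genome LD, genealogy summaries, and
#' nuclear SNP association against both titres (single-trait and
#' multivariate). Any stage failure aborts with a stage-labelled error.
#'
#' @param config A [panel_config()].
#' @return Object of class `pipeline_result`: a list of tibbles
#'   (`infection`, `titres`, `windowed`, `null_tests`, `cross_ld`,
#'   `genealogy`, `association`, `hits`) plus `titre_fit`, `masks`,
#'   `filter_reports` and a `manifest` echoing config and seed.
#' @export
run_pipeline <- function(config) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "': ", conditionMessage(e),
           call. = FALSE))
  }
  matrices <- stage("read_vcf", {
    list(endo = read_vcf_matrix(config$endo_vcf, contig = "endo"),
         mt = read_vcf_matrix(config$mt_vcf, contig = "mt"),
         nuc = read_vcf_matrix(config$nuc_vcf, contig = "nuc"))
  })
  pre_counts <- purrr::map_int(matrices, n_sites)
  qcd <- stage("variant_qc", purrr::map(
    matrices[c("endo", "mt")], qc_matrix,
    max_missing = config$max_missing,
    window_bp = config$density_window_bp,
    max_snps = config$density_max_snps))
  samples <- matrices$endo$samples
  profiles <- stage("read_depth", {
    out <- purrr::map(samples, function(smp) {
      purrr::map(c(endo = "endo", mt = "mt", nuc = "nuc"), function(cg) {
        read_depth_table(file.path(config$depth_dir,
                                   paste0(smp, "_", cg, ".tsv")),
                         sample = smp, contig = cg)
      })
    })
    names(out) <- samples
    out
  })
  infection <- stage("infect", infection_table(
    purrr::map(profiles, "endo"),
    min_breadth = config$min_breadth, min_depth = config$min_depth))
  cov_masks <- stage("coverage_mask", purrr::map(
    c(endo = "endo", mt = "mt"),
    function(cg) mask_high_coverage(purrr::map(profiles, cg),
                                    factor = config$coverage_mask_factor)))
  titres <- stage("titre", {
    panel <- purrr::map(profiles, function(p) {
      list(mt = p$mt, endo = p$endo,
           nuc_mt = slice_profile(p$nuc, config$region_mt[["start"]],
                                  min(config$region_mt[["end"]],
                                      length(p$nuc$depth))),
           nuc_endo = slice_profile(p$nuc, config$region_endo[["start"]],
                                    min(config$region_endo[["end"]],
                                        length(p$nuc$depth))))
    })
    titre_table(panel, masks = cov_masks,
                ploidy_factor = config$ploidy_factor)
  })
  titre_wide <- titres |>
    dplyr::select("sample", "target", "titre") |>
    tidyr::pivot_wider(names_from = "target", values_from = "titre")
  fit <- stage("titre_relationship",
               titre_relationship(titre_wide$mt, titre_wide$endo))
  windowed <- stage("diversity", purrr::map_dfr(
    qcd, windowed_stats, window_bp = config$window_bp))
  null_seeds <- with_seed(config$seed,
                          sample.int(.Machine$integer.max - 1L, 2L))
  null_tests <- stage("nulltest", purrr::imap_dfr(qcd, function(m, cg) {
    if (n_sites(m) < 1L) return(NULL)
    nt <- null_test(tajimas_d(m), n = n_samples(m), S = n_sites(m),
                    R = config$replicates, statistic = "D", tail = "lower",
                    seed = null_seeds[[match(cg, names(qcd))]])
    dplyr::mutate(tidy(nt), contig = cg, .before = 1)
  }))
  ld <- stage("ld", inter_genome_r2(qcd$endo, qcd$mt))
  genealogy <- stage("genealogy", purrr::map_dfr(qcd, genealogy_summary))
  assoc <- stage("assoc", {
    regions <- if (is.null(config$assoc_regions_bed)) NULL
               else if (length(config$assoc_regions_bed) == 1L &&
                          is.na(config$assoc_regions_bed)) genomic_intervals()
               else read_bed(config$assoc_regions_bed)
    G <- prepare_genotypes(matrices$nuc, regions,
                           min_count = config$min_count,
                           max_missing = config$max_missing)
    ord <- match(G$samples, titre_wide$sample)
    dplyr::bind_rows(
      dplyr::mutate(single_trait_assoc(G, titre_wide$mt[ord]),
                    phenotype = "mt"),
      dplyr::mutate(single_trait_assoc(G, titre_wide$endo[ord]),
                    phenotype = "endo"),
      dplyr::mutate(
        multivariate_assoc(G, cbind(titre_wide$mt, titre_wide$endo)[ord, ,
                                                                    drop = FALSE]),
        phenotype = "mt+endo"))
  })
  hits <- stage("hits", report_hits(assoc, alpha = config$alpha))
  structure(list(
    infection = infection,
    titres = titres,
    titre_fit = fit,
    windowed = windowed,
    null_tests = null_tests,
    cross_ld = glance(ld),
    cross_ld_pairs = tidy(ld),
    genealogy = genealogy,
    association = assoc,
    hits = hits,
    masks = cov_masks,
    filter_reports = purrr::map(qcd, filter_report),
    site_counts = tibble::tibble(
      contig = c("endo", "mt", "nuc"),
      pre_qc = as.integer(pre_counts[c("endo", "mt", "nuc")]),
      post_qc = c(n_sites(qcd$endo), n_sites(qcd$mt), NA_integer_)),
    manifest = list(config = unclass(config), seed = config$seed,
                    null_seeds = null_seeds,
                    package_version = as.character(utils::packageVersion("cytopop")))
  ), class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> seed ", x$manifest$seed, "\n", sep = "")
  cat("  infected lines: ", sum(x$infection$status == "infected"), "/",
      nrow(x$infection), "\n", sep = "")
  cat("  titre fit: r = ", sprintf("%.3f", x$titre_fit$correlation),
      ", p = ", format(x$titre_fit$p.value, digits = 3), "\n", sep = "")
  cat("  null tests:\n")
  print(x$null_tests[, c("contig", "observed", "p.value")])
  cat("  mean cross-genome r2: ",
      format(x$cross_ld$mean_r2, digits = 3), "\n", sep = "")
  cat("  association hits (p < ", x$manifest$config$alpha, "): ",
      nrow(x$hits), "\n", sep = "")
  invisible(x)
}

#' Write a pipeline result bundle as TSV tables plus a JSON manifest
#'
#' @param result A [run_pipeline()] result.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_result_bundle <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tables <- c("infection", "titres", "windowed", "null_tests",
              "cross_ld", "genealogy", "association", "hits")
  for (tb in tables)
    readr::write_tsv(result[[tb]], file.path(dir, paste0(tb, ".tsv")),
                     progress = FALSE)
  for (cg in names(result$masks))
    if (nrow(result$masks[[cg]]))
      write_bed(result$masks[[cg]],
                file.path(dir, paste0("mask_", cg, ".bed")))
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}
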