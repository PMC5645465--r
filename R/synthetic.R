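#' Configuration for the synthetic panel generator
#'
#' Defaults mirror the shape of the study system the package targets: a
#' panel of 167 inbred haploid-coded lines whose endosymbiont and mtDNA
#' genomes both spread recently (star-like genealogies, 78 and 90
#' segregating sites), log-normal titres with mean (SD) 5.56 (2.45) for
#' the endosymbiont and 33.85 (15.5) for mtDNA, a positive mt-endo titre
#' correlation, Poisson sequencing depth at 30x nuclear coverage, and one
#' planted causal nuclear SNP affecting both titres. Organelle contigs
#' default to 20 kb desk-scale stand-ins for the real genome sizes;
#' per-site quantities scale accordingly.
#'
#' @param n Number of lines (default 167).
#' @param s_endo,s_mt Segregating sites per organelle genome (78, 90).
#' @param mode_endo,mode_mt Genealogy mode, `"recent_sweep"` (founder
#'   haplotype plus low-count mutations) or `"neutral"` (fixed-S
#'   coalescent draw).
#' @param len_endo,len_mt,len_nuc Contig lengths in bp.
#' @param s_nuc Nuclear SNP count inside the candidate regions.
#' @param titre_mean,titre_sd Named numeric (`mt`, `endo`): target
#'   natural-scale titre means and SDs.
#' @param titre_cor Log-scale correlation between the two titres
#'   (default 0.4).
#' @param causal Tibble with columns `maf`, `beta_mt`, `beta_endo`
#'   describing planted causal nuclear SNPs; betas are in units of
#'   log-titre SD per alternate allele. Default: one SNP at MAF 0.3 with
#'   beta 1.5 on both titres.
#' @param nuclear_coverage Mean nuclear read depth (default 30).
#' @param anomaly Interval tibble (with extra column `factor`) of
#'   high-coverage blocks multiplied into the organelle depth rate,
#'   emulating repeated elements. Default: one 300-bp block at 4x on the
#'   endosymbiont contig.
#' @param seed Master seed; all stage substreams derive from it.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n = 167L,
                             s_endo = 78L, s_mt = 90L,
                             mode_endo = "recent_sweep",
                             mode_mt = "recent_sweep",
                             len_endo = 20000L, len_mt = 20000L,
                             len_nuc = 30000L, s_nuc = 200L,
                             titre_mean = c(mt = 33.85, endo = 5.56),
                             titre_sd = c(mt = 15.5, endo = 2.45),
                             titre_cor = 0.4,
                             causal = tibble::tibble(maf = 0.3,
                                                     beta_mt = 1.5,
                                                     beta_endo = 1.5),
                             nuclear_coverage = 30,
                             anomaly = tibble::tibble(contig = "endo",
                                                      start = 2001L,
                                                      end = 2300L,
                                                      factor = 4),
                             seed = 1L) {
  stopifnot(n >= 2L, s_endo >= 0L, s_mt >= 0L, nuclear_coverage > 0,
            abs(titre_cor) < 1, all(titre_sd > 0), all(titre_mean > 0))
  structure(list(
    n = as.integer(n), s_endo = as.integer(s_endo), s_mt = as.integer(s_mt),
    mode_endo = match.arg(mode_endo, c("recent_sweep", "neutral")),
    mode_mt = match.arg(mode_mt, c("recent_sweep", "neutral")),
    len_endo = as.integer(len_endo), len_mt = as.integer(len_mt),
    len_nuc = as.integer(len_nuc), s_nuc = as.integer(s_nuc),
    titre_mean = titre_mean, titre_sd = titre_sd, titre_cor = titre_cor,
    causal = causal, nuclear_coverage = nuclear_coverage,
    anomaly = anomaly,
    # nuclear normalisation regions used for titre estimation
    region_mt = c(start = 1L, end = as.integer(min(12000L, len_nuc))),
    region_endo = c(start = as.integer(min(15001L, len_nuc)),
                    end = as.integer(len_nuc)),
    seed = as.integer(seed)
  ), class = "generator_config")
}

#' Simulate an organelle variant matrix
#'
#' `"recent_sweep"` mode emulates the aftermath of a recent single-origin
#' spread phenomenologically: one founder haplotype, with each of the `S`
#' mutations carried by a small number of lines (carrier counts drawn
#' from a geometric distribution with mean 1.3), so many sequences stay
#' identical — a star genealogy. `"neutral"` mode draws a fixed-S
#' standard coalescent sample via [simulate_genealogy()] and
#' [sprinkle_fixed_s()].
#'
#' @param mode `"recent_sweep"` or `"neutral"`.
#' @param n Number of lines.
#' @param S Segregating sites.
#' @param seq_length Contig length (default 20000).
#' @param contig Contig id.
#' @param seed Optional seed.
#' @return A [variant_matrix()].
#' @export
generate_organelle_matrix <- function(mode = c("recent_sweep", "neutral"),
                                      n, S, seq_length = 20000L,
                                      contig = "organelle", seed = NULL) {
  mode <- match.arg(mode)
  if (S == 0L) {
    return(variant_matrix(matrix(integer(), nrow = n, ncol = 0),
                          integer(), contig, seq_length,
                          ref = character(), alt = character()))
  }
  if (mode == "neutral") {
    return(with_seed(seed, {
      tree <- simulate_genealogy(n)
      sprinkle_fixed_s(tree, S, seq_length = seq_length, contig = contig)
    }))
  }
  with_seed(seed, {
    al <- matrix(0L, nrow = n, ncol = S)
    counts <- pmin(1L + stats::rgeom(S, prob = 1 / 1.3), n - 1L)
    for (s in seq_len(S)) al[sample.int(n, counts[s]), s] <- 1L
    pos <- sort(sample.int(seq_length, S))
    ref <- sample(c("A", "C", "G", "T"), S, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L),
                  "")
    variant_matrix(al, pos, contig, seq_length, ref = ref, alt = alt)
  })
}

#' Simulate nuclear genotypes in the candidate regions
#'
#' Independent biallelic SNPs with allele frequencies uniform on
#' `maf_range`; planted causal SNPs (from `causal`) are generated at
#' their configured minor-allele frequencies and their positions
#' recorded in the `causal_positions` attribute.
#'
#' @param n Lines.
#' @param S Background SNP count.
#' @param seq_length Contig length.
#' @param causal Causal-SNP tibble (see [generator_config()]).
#' @param maf_range Background allele-frequency range.
#' @param contig Contig id.
#' @param seed Optional seed.
#' @return A [variant_matrix()] with attribute `causal_positions`.
#' @export
generate_nuclear_matrix <- function(n, S, seq_length = 30000L,
                                    causal = NULL,
                                    maf_range = c(0.05, 0.5),
                                    contig = "nuc", seed = NULL) {
  n_causal <- if (is.null(causal)) 0L else nrow(causal)
  with_seed(seed, {
    total <- S + n_causal
    freqs <- stats::runif(total, maf_range[1], maf_range[2])
    if (n_causal) freqs[seq_len(n_causal)] <- causal$maf
    al <- matrix(0L, nrow = n, ncol = total)
    for (s in seq_len(total)) {
      repeat {
        col <- stats::rbinom(n, 1L, freqs[s])
        if (sum(col) %in% seq_len(n - 1L)) break  # keep sites polymorphic
      }
      al[, s] <- col
    }
    pos <- sort(sample.int(seq_length, total))
    perm <- sample.int(total)  # causal sites land at random coordinates
    al <- al[, perm, drop = FALSE]
    ref <- sample(c("A", "C", "G", "T"), total, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L),
                  "")
    out <- variant_matrix(al, pos, contig, seq_length, ref = ref, alt = alt)
    # column k of the permuted matrix is original column perm[k], so
    # original causal column c sits at index match(c, perm)
    attr(out, "causal_positions") <-
      if (n_causal) pos[match(seq_len(n_causal), perm)] else integer()
    out
  })
}

#' Simulate titre phenotypes
#'
#' Log-titres are `baseline + sum(beta * sigma_log * allele) + noise`,
#' with the bivariate normal noise correlated at `titre_cor` and scaled
#' so the total log-variance hits the configured target; baselines are
#' set so the natural-scale means match the configured means in
#' expectation. Ground-truth effects are recorded.
#'
#' @param config A [generator_config()].
#' @param nuclear A [generate_nuclear_matrix()] result (carrying causal
#'   positions).
#' @param noise Set `FALSE` for the noise-free limit: titres become a
#'   deterministic function of genotype (classes differ by exactly
#'   `exp(beta * sigma_log)`-fold), useful for validating effect
#'   plumbing.
#' @param seed Optional seed.
#' @return Tibble `sample`, `mt_titre`, `endo_titre`; ground truth in
#'   attribute `truth` (causal positions, betas, log-scale parameters).
#' @export
generate_titres <- function(config, nuclear, noise = TRUE, seed = NULL) {
  n <- config$n
  cpos <- attr(nuclear, "causal_positions") %||% integer()
  causal <- config$causal
  if (nrow(causal) && length(cpos) != nrow(causal))
    stop("causal SNPs not present in the nuclear matrix", call. = FALSE)
  par <- purrr::map(c(mt = "mt", endo = "endo"), function(t) {
    m <- config$titre_mean[[t]]; s <- config$titre_sd[[t]]
    sig2 <- log(1 + (s / m)^2)
    list(mu = log(m) - sig2 / 2, sigma = sqrt(sig2))
  })
  with_seed(seed, {
    g <- matrix(0, nrow = n, ncol = max(1L, nrow(causal)))
    if (nrow(causal)) {
      idx <- match(cpos, nuclear$positions)
      g <- nuclear$alleles[, idx, drop = FALSE]
      g[is.na(g)] <- 0L
    }
    logt <- purrr::imap(par, function(p, t) {
      beta <- if (nrow(causal)) causal[[paste0("beta_", t)]] else numeric()
      gen <- if (length(beta)) drop(g %*% (beta * p$sigma)) else rep(0, n)
      gvar <- stats::var(gen)
      # shrink the noise so total log-variance stays near the target
      # (floored at 10% so the phenotype never degenerates)
      resid_sd <- if (noise) sqrt(max(p$sigma^2 - gvar, 0.1 * p$sigma^2)) else 0
      list(gen = gen - mean(gen), resid_sd = resid_sd, p = p)
    })
    z1 <- stats::rnorm(n)
    z2 <- config$titre_cor * z1 +
      sqrt(1 - config$titre_cor^2) * stats::rnorm(n)
    mt <- unname(exp(logt$mt$p$mu + logt$mt$gen + logt$mt$resid_sd * z1))
    endo <- unname(exp(logt$endo$p$mu + logt$endo$gen +
                         logt$endo$resid_sd * z2))
    out <- tibble::tibble(sample = nuclear$samples, mt_titre = mt,
                          endo_titre = endo)
    attr(out, "truth") <- list(
      causal_positions = cpos, causal = causal,
      log_params = par,
      resid_sd = c(mt = logt$mt$resid_sd, endo = logt$endo$resid_sd))
    out
  })
}

#' Simulate per-base depth profiles for a panel
#'
#' Nuclear depth is Poisson at the configured coverage; organelle depth
#' is Poisson at coverage x titre, with any configured anomaly blocks
#' multiplying the rate (these are what [mask_high_coverage()] should
#' recover).
#'
#' @param titres Tibble from [generate_titres()].
#' @param config A [generator_config()].
#' @param seed Optional seed.
#' @return Named list (by sample) of named lists of [depth_profile()]s:
#'   `endo`, `mt`, `nuc`.
#' @export
generate_depth_profiles <- function(titres, config, seed = NULL) {
  lens <- c(endo = config$len_endo, mt = config$len_mt,
            nuc = config$len_nuc)
  rate_mult <- purrr::map(names(lens), function(cg) {
    mult <- rep(1, lens[[cg]])
    a <- config$anomaly[config$anomaly$contig == cg, ]
    for (r in seq_len(nrow(a)))
      mult[a$start[r]:a$end[r]] <- a$factor[r]
    mult
  })
  names(rate_mult) <- names(lens)
  with_seed(seed, {
    out <- purrr::map(seq_len(nrow(titres)), function(i) {
      smp <- titres$sample[i]
      lam <- c(endo = config$nuclear_coverage * titres$endo_titre[i],
               mt = config$nuclear_coverage * titres$mt_titre[i],
               nuc = config$nuclear_coverage)
      purrr::imap(lam, function(l, cg) {
        depth_profile(stats::rpois(lens[[cg]], l * rate_mult[[cg]]),
                      smp, cg)
      })
    })
    names(out) <- titres$sample
    out
  })
}

#' Generate a complete synthetic panel
#'
#' Runs every generator stage under substreams derived from the master
#' seed, so the panel is an exact function of its configuration.
#'
#' @param config A [generator_config()].
#' @return Object of class `synthetic_panel`: `config`, `matrices`
#'   (endo/mt/nuc [variant_matrix()]s), `titres` (with truth attribute),
#'   `profiles`, `references` (random reference sequences consistent
#'   with the variant ref alleles), `regions` (candidate association
#'   regions), and `stage_seeds`.
#' @export
generate_panel <- function(config = generator_config()) {
  stage_seeds <- with_seed(config$seed,
                           sample.int(.Machine$integer.max - 1L, 6L))
  names(stage_seeds) <- c("endo", "mt", "nuc", "titre", "depth", "ref")
  samples <- sprintf("line%03d", seq_len(config$n))
  relabel <- function(m) { m$samples <- samples; rownames(m$alleles) <- samples; m }
  endo <- relabel(generate_organelle_matrix(config$mode_endo, config$n,
                                            config$s_endo, config$len_endo,
                                            "endo", stage_seeds[["endo"]]))
  mt <- relabel(generate_organelle_matrix(config$mode_mt, config$n,
                                          config$s_mt, config$len_mt,
                                          "mt", stage_seeds[["mt"]]))
  nuc <- generate_nuclear_matrix(config$n, config$s_nuc, config$len_nuc,
                                 causal = config$causal,
                                 contig = "nuc", seed = stage_seeds[["nuc"]])
  cpos <- attr(nuc, "causal_positions")
  nuc2 <- relabel(nuc)
  attr(nuc2, "causal_positions") <- cpos
  titres <- generate_titres(config, nuc2, seed = stage_seeds[["titre"]])
  profiles <- generate_depth_profiles(titres, config,
                                      seed = stage_seeds[["depth"]])
  references <- with_seed(stage_seeds[["ref"]], purrr::imap(
    list(endo = endo, mt = mt, nuc = nuc2),
    function(m, cg) {
      bases <- sample(c("A", "C", "G", "T"), m$seq_length, replace = TRUE)
      if (n_sites(m)) bases[m$positions] <- m$ref
      paste(bases, collapse = "")
    }))
  structure(list(
    config = config,
    matrices = list(endo = endo, mt = mt, nuc = nuc2),
    titres = titres,
    profiles = profiles,
    references = references,
    regions = genomic_intervals("nuc", 1L, config$len_nuc),
    stage_seeds = stage_seeds
  ), class = "synthetic_panel")
}

#' @export
print.synthetic_panel <- function(x, ...) {
  cat("<synthetic_panel> ", x$config$n, " lines; S(endo) = ",
      n_sites(x$matrices$endo), " [", x$config$mode_endo, "], S(mt) = ",
      n_sites(x$matrices$mt), " [", x$config$mode_mt, "], S(nuc) = ",
      n_sites(x$matrices$nuc), "; seed ", x$config$seed, "\n", sep = "")
  invisible(x)
}

#' Write a synthetic panel to disk in standard formats
#'
#' Emits one VCF per genome, per-sample per-contig genomecov-style depth
#' tables (`depth/<sample>_<contig>.tsv`), reference FASTAs, BED files of
#' the causal-SNP and anomaly-block ground truth, and a JSON manifest
#' recording the configuration and stage seeds — all in the dialects the
#' package's readers consume.
#'
#' @param panel A [generate_panel()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_panel <- function(panel, dir) {
  dir.create(file.path(dir, "depth"), recursive = TRUE, showWarnings = FALSE)
  for (cg in names(panel$matrices))
    write_matrix_vcf(panel$matrices[[cg]], file.path(dir, paste0(cg, ".vcf")))
  for (cg in names(panel$references))
    writeLines(c(paste0(">", cg), wrap_seq(panel$references[[cg]])),
               file.path(dir, paste0("ref_", cg, ".fa")))
  for (smp in names(panel$profiles))
    for (cg in names(panel$profiles[[smp]]))
      write_depth_table(panel$profiles[[smp]][[cg]],
                        file.path(dir, "depth", paste0(smp, "_", cg, ".tsv")))
  truth <- attr(panel$titres, "truth")
  if (length(truth$causal_positions))
    write_bed(genomic_intervals("nuc", truth$causal_positions,
                                truth$causal_positions),
              file.path(dir, "causal_truth.bed"))
  if (nrow(panel$config$anomaly))
    write_bed(panel$config$anomaly[, c("contig", "start", "end")],
              file.path(dir, "anomaly_truth.bed"))
  write_bed(panel$regions, file.path(dir, "assoc_regions.bed"))
  readr::write_tsv(panel$titres, file.path(dir, "true_titres.tsv"),
                   progress = FALSE)
  cfg <- panel$config
  cfg$causal <- as.data.frame(cfg$causal)
  cfg$anomaly <- as.data.frame(cfg$anomaly)
  jsonlite::write_json(
    list(config = unclass(cfg), stage_seeds = as.list(panel$stage_seeds),
         samples = names(panel$profiles)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
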