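no_causal <- tibble::tibble(maf = numeric(), beta_mt = numeric(),
                            beta_endo = numeric())

test_that("sweep mode with S = 0 leaves all sequences identical", {
  m <- generate_organelle_matrix("recent_sweep", n = 20, S = 0,
                                 seq_length = 1000L, seed = 1)
  expect_equal(n_sites(m), 0L)
})

test_that("sweep panels are star-like at study scale", {
  m <- generate_organelle_matrix("recent_sweep", n = 167, S = 90,
                                 seq_length = 20000L, seed = 2)
  gs <- genealogy_summary(m)
  expect_gt(gs$frac_nonunique, 0.4)
  # carrier counts are low (geometric mean 1.3): mostly singletons
  expect_gt(mean(colSums(m$alleles) == 1L), 0.5)
})

test_that("neutral mode honours the fixed-S contract", {
  m <- generate_organelle_matrix("neutral", n = 30, S = 25,
                                 seq_length = 5000L, seed = 3)
  expect_equal(n_sites(m), 25L)
  counts <- colSums(m$alleles)
  expect_true(all(counts >= 1 & counts <= 29))
})

test_that("titres hit the configured means, SDs and correlation", {
  cfg <- generator_config(causal = no_causal, titre_cor = 0, seed = 10)
  nuc <- generate_nuclear_matrix(cfg$n, 20, causal = no_causal, seed = 11)
  tt <- generate_titres(cfg, nuc, seed = 12)
  # CLT bands at n = 167 (3 SE)
  expect_lt(abs(mean(tt$mt_titre) - 33.85), 3 * 15.5 / sqrt(167))
  expect_lt(abs(mean(tt$endo_titre) - 5.56), 3 * 2.45 / sqrt(167))
  expect_lt(abs(sd(tt$mt_titre) / 15.5 - 1), 0.35)
  expect_lt(abs(sd(tt$endo_titre) / 2.45 - 1), 0.35)
})

test_that("the log-scale titre correlation is near its target", {
  cfg <- generator_config(causal = no_causal, titre_cor = 0.4, seed = 13)
  nuc <- generate_nuclear_matrix(cfg$n, 10, causal = no_causal, seed = 14)
  tt <- generate_titres(cfg, nuc, seed = 15)
  r <- cor(log(tt$mt_titre), log(tt$endo_titre))
  # Fisher-z 3 SE band around 0.4 at n = 167
  expect_lt(abs(atanh(r) - atanh(0.4)), 3 / sqrt(167 - 3))
})

test_that("noise-free titres differ between genotype classes by exp(beta*sigma)", {
  causal <- tibble::tibble(maf = 0.4, beta_mt = 1, beta_endo = 0.5)
  cfg <- generator_config(n = 50, causal = causal, seed = 16)
  nuc <- generate_nuclear_matrix(50, 5, causal = causal, seed = 17)
  tt <- generate_titres(cfg, nuc, noise = FALSE, seed = 18)
  truth <- attr(tt, "truth")
  g <- nuc$alleles[, match(truth$causal_positions, nuc$positions)]
  sig_mt <- truth$log_params$mt$sigma
  ratio <- mean(tt$mt_titre[g == 1]) / mean(tt$mt_titre[g == 0])
  expect_equal(ratio, exp(1 * sig_mt), tolerance = 1e-10)
  sig_endo <- truth$log_params$endo$sigma
  ratio2 <- mean(tt$endo_titre[g == 1]) / mean(tt$endo_titre[g == 0])
  expect_equal(ratio2, exp(0.5 * sig_endo), tolerance = 1e-10)
})

test_that("depth profiles are Poisson at coverage x titre, with anomalies", {
  cfg <- generator_config(n = 3, len_endo = 10000L, len_mt = 10000L,
                          len_nuc = 10000L, seed = 20)
  tt <- tibble::tibble(sample = c("a", "b", "c"),
                       mt_titre = c(30, 10, 5), endo_titre = c(5, 5, 0))
  prof <- generate_depth_profiles(tt, cfg, seed = 21)
  unmasked <- setdiff(seq_len(10000L), 2001:2300)
  expect_equal(mean(prof$a$endo$depth[unmasked]), 30 * 5,
               tolerance = 0.05)
  expect_equal(mean(prof$b$mt$depth), 30 * 10, tolerance = 0.05)
  expect_equal(mean(prof$c$nuc$depth), 30, tolerance = 0.05)
  # titre 0 -> empty organelle profile -> scored uninfected
  expect_true(all(prof$c$endo$depth == 0L))
  call <- classify_infection(coverage_summary(prof$c$endo))
  expect_equal(call$status, "uninfected")
  # the planted 4x anomaly block is recovered by the coverage mask
  iv <- mask_high_coverage(list(prof$a$endo, prof$b$endo), factor = 3)
  expect_equal(nrow(iv), 1L)
  expect_lt(abs(iv$start - 2001L), 5)
  expect_lt(abs(iv$end - 2300L), 5)
})

test_that("panels round-trip through disk exactly", {
  cfg <- generator_config(n = 8, s_endo = 12, s_mt = 15, s_nuc = 20,
                          len_endo = 2000L, len_mt = 2000L, len_nuc = 3000L,
                          seed = 22)
  panel <- generate_panel(cfg)
  dir <- withr::local_tempdir()
  write_panel(panel, dir)
  for (cg in c("endo", "mt", "nuc")) {
    m <- read_vcf_matrix(file.path(dir, paste0(cg, ".vcf")))
    expect_equal(unname(m$alleles), unname(panel$matrices[[cg]]$alleles))
    expect_equal(m$positions, panel$matrices[[cg]]$positions)
  }
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(man$config$seed, 22L)
  expect_equal(length(list.files(file.path(dir, "depth"))), 8L * 3L)
  p <- read_depth_table(file.path(dir, "depth", "line001_endo.tsv"),
                        sample = "line001")
  expect_equal(p$depth, panel$profiles$line001$endo$depth)
  # regeneration from (config, seed) is exact
  panel2 <- generate_panel(cfg)
  expect_equal(panel2$titres$mt_titre, panel$titres$mt_titre)
  expect_identical(panel2$matrices$endo$alleles, panel$matrices$endo$alleles)
})

test_that("titre estimates recover generator ground truth at 30x", {
  cfg <- generator_config(n = 25, s_endo = 20, s_mt = 20, s_nuc = 30,
                          len_endo = 10000L, len_mt = 10000L,
                          len_nuc = 20000L, seed = 23)
  panel <- generate_panel(cfg)
  masks <- list(endo = cfg$anomaly[cfg$anomaly$contig == "endo",
                                   c("contig", "start", "end")])
  est <- purrr::imap_dfr(panel$profiles, function(p, smp) {
    dplyr::bind_rows(
      relative_copy_number(p$mt, slice_profile(p$nuc, 1L, 10000L)),
      relative_copy_number(p$endo, slice_profile(p$nuc, 10001L, 20000L),
                           mask = masks$endo))
  })
  wide <- tidyr::pivot_wider(est[, c("sample", "target", "titre")],
                             names_from = "target", values_from = "titre")
  truth <- panel$titres
  expect_gt(cor(wide$mt, truth$mt_titre), 0.98)
  expect_gt(cor(wide$endo, truth$endo_titre), 0.98)
})
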