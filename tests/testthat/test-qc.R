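test_that("biallelic-SNP filter removes indels and multiallelic records", {
  rec <- tibble::tibble(
    chrom = "c", pos = 1:3, id = ".",
    ref = c("A", "A", "A"), alt = c("C", "AT", "C,G"),
    gt_a = "0/0"
  )
  out <- filter_biallelic_snps(rec)
  expect_equal(nrow(out), 1L)
  rep_ <- filter_report(out)
  expect_equal(rep_$removed[rep_$rule == "indel"], 1L)
  expect_equal(rep_$removed[rep_$rule == "non_biallelic"], 1L)

  all_snp <- tibble::tibble(chrom = "c", pos = 1:4, id = ".",
                            ref = "A", alt = "G", gt_a = "0/0")
  expect_equal(nrow(filter_biallelic_snps(all_snp)), 4L)

  # 10-record mixed fixture: hand count 5 clean SNPs
  mixed <- tibble::tibble(
    chrom = "c", pos = 1:10, id = ".",
    ref = c("A", "AT", "G", "C", "T", "A", "G", "GG", "C", "A"),
    alt = c("C", "A", "T", "C,T", "A", "ATT", "C", "G", "T", "*")
  )
  out2 <- filter_biallelic_snps(mixed)
  expect_equal(nrow(out2), 5L)
  rep2 <- filter_report(out2)
  expect_equal(sum(rep2$removed), 5L)
  expect_equal(rep2$retained[rep2$rule == "non_biallelic"], 5L)
  expect_error(filter_biallelic_snps(
    tibble::tibble(chrom = "c", pos = 1L, id = ".", ref = "A", alt = NA)),
    "ALT")
})

test_that("missingness filter is strict at the threshold", {
  al <- matrix(0L, nrow = 10, ncol = 3)
  al[1:2, 1] <- NA  # 20% missing -> removed
  al[1, 2] <- NA    # exactly 10% -> retained
  m <- variant_matrix(al, c(1L, 2L, 3L), "c", 10L)
  out <- filter_missingness(m, 0.10)
  expect_equal(out$positions, c(2L, 3L))
  expect_equal(filter_report(out)$removed, 1L)
})

test_that("missingness filter matches a brute-force recount and edge settings", {
  withr::local_seed(7)
  m <- rand_matrix(n = 10, S = 50, miss = 0.12)
  out <- filter_missingness(m, 0.10)
  keep_brute <- vapply(seq_len(n_sites(m)), function(s)
    mean(is.na(m$alleles[, s])) <= 0.10, TRUE)
  expect_equal(out$positions, m$positions[keep_brute])
  # max_missing = 1 is the identity
  expect_equal(n_sites(filter_missingness(m, 1)), n_sites(m))
  # max_missing = 0 keeps only fully called sites
  full <- filter_missingness(m, 0)
  expect_true(all(colSums(is.na(full$alleles)) == 0))
})

test_that("filters commute with sample reordering", {
  withr::local_seed(11)
  m <- rand_matrix(n = 8, S = 30, miss = 0.15)
  perm <- sample(n_samples(m))
  mp <- variant_matrix(m$alleles[perm, , drop = FALSE], m$positions,
                       m$contig, m$seq_length, ref = m$ref, alt = m$alt,
                       samples = m$samples[perm])
  expect_equal(filter_missingness(m, 0.1)$positions,
               filter_missingness(mp, 0.1)$positions)
  expect_equal(filter_minor_count(m, 2)$positions,
               filter_minor_count(mp, 2)$positions)
})

test_that("SNP-density mask flags dense clusters and nothing else", {
  # 40 SNPs within one 2-kb span, threshold 20 -> one interval covering it
  dense <- sort(sample(3000:4999, 40))
  iv <- mask_snp_dense_regions(dense, "c", 10000L, 2000L, 20L)
  expect_equal(nrow(iv), 1L)
  expect_true(iv$start <= min(dense) && iv$end >= max(dense))
  # uniform 1 SNP per 2 kb -> nothing
  sparse <- seq(1000L, 19000L, by = 2000L)
  expect_equal(nrow(mask_snp_dense_regions(sparse, "c", 20000L)), 0L)
})

test_that("density mask equals the brute-force sliding-window scan", {
  withr::local_seed(5)
  for (rep in 1:5) {
    L <- 6000L; w <- 500L; k <- 4L
    pos <- sort(sample.int(L, 60))
    iv <- mask_snp_dense_regions(pos, "c", L, w, k)
    got <- interval_mask(iv, L)
    expect_equal(got, brute_density_mask(pos, L, w, k))
    # disjoint and sorted after merging
    if (nrow(iv) > 1) expect_true(all(iv$start[-1] > iv$end[-nrow(iv)] + 0))
  }
})

test_that("qc_matrix chains missingness and density mask with bookkeeping", {
  withr::local_seed(3)
  m <- rand_matrix(n = 10, S = 40, miss = 0.05)
  out <- qc_matrix(m, max_missing = 0.10, window_bp = 500L, max_snps = 5L)
  rep_ <- filter_report(out)
  expect_setequal(rep_$rule, c("missingness", "density_mask"))
  expect_equal(sum(rep_$removed) + n_sites(out), n_sites(m))
})
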