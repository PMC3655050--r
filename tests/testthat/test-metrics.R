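test_that("IA matches hand computations and its invariances", {
  t1 <- rbind(c(0, 1, 2))
  m <- rbind(c(TRUE, TRUE, TRUE))
  expect_equal(imputation_accuracy(t1, t1, m), 1)
  expect_equal(imputation_accuracy(rbind(c(0, 0, 0)), rbind(c(2, 2, 2)), m), 0)
  # truth (0,1,2), imputed (0,2,2): mean |diff| = 1/3, IA = 1 - 1/6
  expect_equal(imputation_accuracy(t1, rbind(c(0, 2, 2)), m), 1 - 1 / 6)
  # allele relabeling applied to both sides leaves IA unchanged
  set.seed(2)
  tr <- matrix(sample(0:2, 40, replace = TRUE), 4)
  im <- tr + matrix(runif(40, -0.3, 0.3), 4)
  im <- pmin(pmax(im, 0), 2)
  msk <- matrix(TRUE, 4, 10)
  expect_equal(imputation_accuracy(tr, im, msk),
               imputation_accuracy(2 - tr, 2 - im, msk))
  expect_error(imputation_accuracy(tr, im, msk & FALSE), "no evaluated")
})

test_that("per-SNP R2 matches direct computation and is affine-invariant", {
  truth <- cbind(c(0, 0, 1, 2))
  imput <- cbind(c(0.1, 0, 1.2, 1.8))
  msk <- cbind(rep(TRUE, 4))
  r <- r2_per_snp(truth, imput, msk)
  expect_equal(unname(r$per_snp), 0.9737705, tolerance = 1e-6)
  # perfect and sign-flipped imputation both give R2 = 1
  expect_equal(unname(r2_per_snp(truth, truth, msk)$per_snp), 1)
  expect_equal(unname(r2_per_snp(truth, 2 - truth, msk)$per_snp), 1)
  # affine transformation per marker leaves R2 unchanged
  expect_equal(unname(r2_per_snp(truth, 0.3 + 0.5 * imput, msk)$per_snp),
               unname(r$per_snp))
  # zero-variance markers are excluded from the summary
  t2 <- cbind(truth, 1)
  i2 <- cbind(imput, c(1, 1, 1, 1))
  r2 <- r2_per_snp(t2, i2, cbind(msk, TRUE))
  expect_true(is.na(r2$per_snp[2]))
  expect_equal(r2$n_defined, 1)
  expect_error(r2_per_snp(cbind(c(1, 1)), cbind(c(1, 1)), cbind(c(TRUE, TRUE))),
               "undefined")
})

test_that("haplotyping accuracy counts relative-phase errors", {
  mk_phased <- function(pat) {
    # build a phased_parent-like object with hard calls
    list(p10 = as.numeric(pat), p01 = as.numeric(1 - pat))
  }
  snps <- paste0("s", 1:4)
  t_pat <- matrix(c(1, 0, 1, 0), 1, dimnames = list("i1", snps))
  t_mat <- 1 - t_pat
  # identical phase
  expect_equal(haplotyping_accuracy(t_pat, t_mat,
                                    list(i1 = mk_phased(c(1, 0, 1, 0))))$accuracy, 1)
  # globally swapped haplotypes: relative phase preserved
  expect_equal(haplotyping_accuracy(t_pat, t_mat,
                                    list(i1 = mk_phased(c(0, 1, 0, 1))))$accuracy, 1)
  # one switch after marker 2: 3 pairs, 1 erroneous
  res <- haplotyping_accuracy(t_pat, t_mat,
                              list(i1 = mk_phased(c(1, 0, 0, 1))))
  expect_equal(res$n_pairs, 3)
  expect_equal(res$accuracy, 2 / 3)
  # non-het markers are excluded
  t_pat2 <- matrix(c(1, 1, 1, 0), 1, dimnames = list("i1", snps))
  t_mat2 <- matrix(c(0, 1, 0, 1), 1, dimnames = list("i1", snps))
  res2 <- haplotyping_accuracy(t_pat2, t_mat2,
                               list(i1 = mk_phased(c(1, 0, 1, 0))))
  expect_equal(res2$n_pairs, 2)   # het at markers 1, 3, 4 only
})

test_that("uncertain-phase fraction counts below-threshold positions", {
  snps <- paste0("s", 1:20)
  cert <- rep(1, 20); cert[c(3, 8, 15)] <- 0.6
  ph <- list(i1 = list(certainty = cert))
  het <- matrix(TRUE, 1, 20, dimnames = list("i1", snps))
  res <- uncertain_phase_fraction(ph, het, NULL, snps, 0.95)
  expect_equal(res$fraction, 0.15)
  expect_equal(res$n, 20)
  # all certain / all uncertain extremes
  expect_equal(uncertain_phase_fraction(list(i1 = list(certainty = rep(1, 20))),
                                        het, NULL, snps)$fraction, 0)
  expect_equal(uncertain_phase_fraction(list(i1 = list(certainty = rep(0.5, 20))),
                                        het, NULL, snps)$fraction, 1)
  # tagSNP excluded from the denominator
  res_tag <- uncertain_phase_fraction(ph, het, snps[1:10], snps)
  expect_equal(res_tag$n, 10)
  expect_error(uncertain_phase_fraction(ph, het & FALSE, NULL, snps),
               "no non-tagSNP")
})

test_that("stratified accuracy returns binned means and drops empty bins", {
  vals <- c(0.2, 0.8)
  cov <- c(0.05, 0.45)
  tab <- stratified_accuracy(vals, cov, breaks = c(0, 0.1, 0.2, 0.5))
  expect_equal(tab$mean, c(0.2, 0.8))
  expect_equal(tab$n, c(1, 1))
  expect_equal(nrow(tab), 2)   # the (0.1, 0.2] bin is absent, not zero
  const <- stratified_accuracy(rep(0.9, 50), runif(50), seq(0, 1, 0.25))
  expect_true(all(abs(const$mean - 0.9) < 1e-12))
})

test_that("extreme-MAF markers impute as well as intermediate-MAF ones", {
  # pedigree information makes accuracy insensitive to founder MAF
  pop <- medium_population(n_snp = 120, seed = 57)
  truth <- pop$drop$geno
  tags <- select_tagsnp_even(pop$map, 24)
  obs <- apply_genotyping_scenario(truth, pop$ped,
                                   scenario_spec("HD", "HD", "LowD"), tags)
  imp <- run_imputation(obs, pop$ped, pop$map)
  f2 <- generation_ids(pop$ped, "F2")
  r2 <- r2_per_snp(truth[f2, ], imp$dosage,
                   f2_eval_mask(truth[f2, ], pop$map, tags))
  maf_f0 <- marker_maf(truth[generation_ids(pop$ped, "F0"), ])
  lo <- mean(r2$per_snp[maf_f0 < 0.1], na.rm = TRUE)
  hi <- mean(r2$per_snp[maf_f0 > 0.3], na.rm = TRUE)
  expect_lt(abs(lo - hi), 0.05)
  # and the binned view is populated
  tab <- stratified_accuracy(r2$per_snp, maf_f0, seq(0, 0.5, 0.1))
  expect_gt(nrow(tab), 1)
})

test_that("tag distance covariate is zero at tags and positive elsewhere", {
  map <- even_map(10, 9)
  tags <- select_tagsnp_even(map, 3)
  d <- distance_to_nearest_tag(map, tags)
  expect_true(all(d[map$snp %in% tags$snp] == 0))
  expect_true(all(d[!map$snp %in% tags$snp] > 0))
})
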