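test_that("family splitting partitions litters at the progeny cap", {
  ped <- build_pedigree(2, 2, 1, 1, 12, max_litter_size = 12)
  units <- split_families(ped, max_progeny = 10)
  expect_equal(vapply(units, function(u) length(u$f2), numeric(1)), c(10, 2))
  expect_equal(length(unique(vapply(units, `[[`, "", "litter"))), 1)

  ped1 <- build_pedigree(2, 2, 1, 1, 1)
  u1 <- split_families(ped1)
  expect_equal(length(u1), 1)
  expect_equal(length(u1[[1]]$f2), 1)
  expect_equal(length(u1[[1]]$f0), 4)

  ped_full <- build_pedigree()
  units_full <- split_families(ped_full)
  sizes <- vapply(units_full, function(u) length(u$f2), numeric(1))
  expect_true(all(sizes <= 10))
  expect_equal(sum(sizes), 932)
  expect_equal(sort(unlist(lapply(units_full, `[[`, "f2"))),
               sort(generation_ids(ped_full, "F2")))
})

test_that("all-HD scenario reproduces truth exactly (IA = R2 = 1)", {
  pop <- small_population(n_f2 = 20, n_snp = 50, seed = 9)
  truth <- pop$drop$geno
  obs <- apply_genotyping_scenario(truth, pop$ped,
                                   scenario_spec("HD", "HD", "HD"))
  imp <- run_imputation(obs, pop$ped, pop$map)
  f2 <- generation_ids(pop$ped, "F2")
  expect_equal(imp$dosage, truth[f2, ] + 0, tolerance = 1e-9)
  mask <- matrix(TRUE, length(f2), ncol(truth))
  expect_equal(imputation_accuracy(truth[f2, ], imp$dosage, mask), 1,
               tolerance = 1e-9)
  r2 <- r2_per_snp(truth[f2, ], imp$dosage, mask)
  expect_equal(r2$summary, 1, tolerance = 1e-9)
})

test_that("imputed dosages are unbiased at the marker level", {
  pop <- medium_population(n_snp = 100, seed = 29)
  truth <- pop$drop$geno
  qc <- qc_filter(truth, qc_config(), map = pop$map)
  truth <- qc$genos; map <- qc$map
  tags <- select_tagsnp_even(map, 15)
  obs <- apply_genotyping_scenario(truth, pop$ped,
                                   scenario_spec("HD", "HD", "LowD"), tags)
  imp <- run_imputation(obs, pop$ped, map)
  f2 <- generation_ids(pop$ped, "F2")
  non_tag <- !(map$snp %in% tags$snp)
  diff_mean <- colMeans(imp$dosage[, non_tag]) -
    colMeans(truth[f2, non_tag])
  expect_lt(mean(abs(diff_mean)), 0.05)
  expect_true(all(imp$dosage >= -1e-9 & imp$dosage <= 2 + 1e-9))
})

test_that("HD parents give more certain F1 phase than LowD parents", {
  pop <- medium_population(n_snp = 120, seed = 41)
  truth <- pop$drop$geno
  tags <- select_tagsnp_even(pop$map, 20)
  cert <- function(sc) {
    obs <- apply_genotyping_scenario(truth, pop$ped, sc, tags)
    imp <- run_imputation(obs, pop$ped, pop$map)
    mean(vapply(imp$f1_phase, function(p) mean(p$certainty, na.rm = TRUE),
                numeric(1)))
  }
  c_hd <- cert(scenario_spec("HD", "HD", "LowD"))
  c_lowd <- cert(scenario_spec("HD", "LowD", "LowD"))
  expect_gt(c_hd, c_lowd)
})

test_that("accuracy is monotone in tagSNP density across replicates", {
  ks <- c(5, 12, 30)
  wins <- 0L
  for (seed in 1:5) {
    pop <- medium_population(n_snp = 90, seed = 100 + seed)
    truth <- pop$drop$geno
    f2 <- generation_ids(pop$ped, "F2")
    ias <- vapply(ks, function(k) {
      tags <- select_tagsnp_even(pop$map, k)
      obs <- apply_genotyping_scenario(truth, pop$ped,
                                       scenario_spec("HD", "HD", "LowD"),
                                       tags)
      imp <- run_imputation(obs, pop$ped, pop$map)
      imputation_accuracy(truth[f2, ], imp$dosage,
                          f2_eval_mask(truth[f2, ], pop$map, tags))
    }, numeric(1))
    if (all(diff(ias) >= -1e-6)) wins <- wins + 1L
  }
  expect_gte(wins, 3L)   # majority ordering over replicates
})

test_that("the pipeline is deterministic given identical inputs", {
  pop <- small_population(n_f2 = 15, n_snp = 40, seed = 77)
  truth <- pop$drop$geno
  tags <- select_tagsnp_even(pop$map, 8)
  obs <- apply_genotyping_scenario(truth, pop$ped,
                                   scenario_spec("HD", "HD", "LowD"), tags)
  a <- run_imputation(obs, pop$ped, pop$map)
  b <- run_imputation(obs, pop$ped, pop$map)
  expect_identical(a$dosage, b$dosage)
})
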