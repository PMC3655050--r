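test_that("founder simulation is seed-deterministic and seed-sensitive", {
  map <- even_map(80, 20)
  mod <- breed_model()
  a <- simulate_founder_haplotypes(map, mod, c(3, 3), seed = 5)
  b <- simulate_founder_haplotypes(map, mod, c(3, 3), seed = 5)
  c <- simulate_founder_haplotypes(map, mod, c(3, 3), seed = 6)
  expect_identical(a, b)
  expect_false(identical(a$haps, c$haps))
  expect_equal(dim(a$haps), c(12, 80))
  expect_true(all(a$haps %in% 0:1))
  expect_equal(a$breed, rep(c("A", "B"), each = 6))
})

test_that("degenerate breed model collapses to identical haplotypes", {
  map <- even_map(50, 10)
  mod <- breed_model(n_ancestral = 1, switch_rate = 0, flip_rate = 0)
  pan <- simulate_founder_haplotypes(map, mod, c(4, 4), seed = 1)
  for (b in c("A", "B")) {
    h <- pan$haps[pan$breed == b, ]
    expect_true(all(apply(h, 2, function(x) length(unique(x)) == 1)))
  }
})

test_that("calibrated model yields high within-breed adjacent LD", {
  # defaults were fixed by this calibration: mean adjacent r2 > 0.4 at 60K
  # density, estimated over 200 founder haplotypes of one breed
  map <- even_map(1405, 64.2)
  pan <- simulate_founder_haplotypes(map, breed_model(), c(100, 1), seed = 2)
  h <- pan$haps[pan$breed == "A", ]
  r2 <- vapply(seq_len(ncol(h) - 1), function(j) {
    suppressWarnings(cor(h[, j], h[, j + 1])^2)
  }, numeric(1))
  expect_gt(mean(r2, na.rm = TRUE), 0.4)
})

test_that("pedigree defaults reproduce the study population shape", {
  ped <- build_pedigree()
  expect_equal(as.vector(table(ped$generation)[c("F0", "F1", "F2")]),
               c(19, 56, 932))
  f2 <- ped[ped$generation == "F2", ]
  gen <- setNames(ped$generation, ped$id)
  expect_true(all(gen[f2$sire] == "F1"))
  expect_true(all(gen[f2$dam] == "F1"))
  # four distinct F0 grandparents each
  gp <- cbind(ped$sire[match(f2$sire, ped$id)],
              ped$dam[match(f2$sire, ped$id)],
              ped$sire[match(f2$dam, ped$id)],
              ped$dam[match(f2$dam, ped$id)])
  expect_true(all(apply(gp, 1, function(x) length(unique(x)) == 4)))
})

test_that("no F1 x F1 mating shares an F0 parent, exhaustively", {
  ped <- build_pedigree()
  f2 <- ped[ped$generation == "F2", ]
  matings <- unique(f2[, c("sire", "dam")])
  for (i in seq_len(nrow(matings))) {
    ps <- ped[ped$id == matings$sire[i], c("sire", "dam")]
    pd <- ped[ped$id == matings$dam[i], c("sire", "dam")]
    expect_equal(length(intersect(unlist(ps), unlist(pd))), 0)
  }
})

test_that("minimal pedigree is a single 7-individual family", {
  ped <- build_pedigree(2, 2, 1, 1, 1)
  expect_equal(nrow(ped), 7)
  expect_equal(sum(ped$generation == "F2"), 1)
  validate_pedigree(ped)
})

test_that("meiosis crossover counts follow the Poisson model", {
  map <- even_map(30, 64.2)
  expect_equal(morgan_length(map), 0.642)
  haps <- rbind(rep(0L, 30), rep(1L, 30))
  set.seed(99)
  counts <- replicate(10000, simulate_meiosis(haps, map)$record$n_xo)
  lam <- 0.642
  # Monte Carlo mean within 3 SE of the Poisson mean
  expect_lt(abs(mean(counts) - lam), 3 * sqrt(lam / 10000))
  # chi-square goodness of fit at alpha = 0.01
  brk <- c(0, 1, 2, Inf)
  obs <- table(cut(counts, c(-1, 0, 1, Inf)))
  p <- c(dpois(0, lam), dpois(1, lam), 1 - ppois(1, lam))
  expect_gt(stats::chisq.test(obs, p = p)$p.value, 0.01)
})

test_that("zero genetic length gives a crossover-free copy", {
  map <- even_map(20, 10, cm_per_mb = 0)
  haps <- rbind(rep(0L, 20), rep(1L, 20))
  res <- simulate_meiosis(haps, map, seed = 3)
  expect_equal(res$record$n_xo, 0)
  expect_true(all(res$gamete == haps[res$record$start, ]))
})

test_that("gene dropping respects Mendelian certainty and bookkeeping", {
  pop <- small_population(n_f2 = 30, n_snp = 40, seed = 21)
  drop <- pop$drop; ped <- pop$ped
  # child haplotype allele equals the parent haplotype chosen by the record
  for (id in c(generation_ids(ped, "F1"), generation_ids(ped, "F2")[1:5])) {
    sire <- ped$sire[ped$id == id]
    orig <- drop$orig_pat[id, ]
    parent_h <- rbind(drop$hap_pat[sire, ], drop$hap_mat[sire, ])
    expect_equal(unname(drop$hap_pat[id, ]),
                 parent_h[cbind(orig, seq_along(orig))])
  }
  # fixed-difference marker: AA x aa -> every offspring dosage 1
  f0 <- generation_ids(ped, "F0")
  f1 <- generation_ids(ped, "F1")
  for (j in seq_len(ncol(drop$geno))) {
    s <- drop$geno[ped$sire[ped$id == f1[1]], j]
    d <- drop$geno[ped$dam[ped$id == f1[1]], j]
    if (s == 2 && d == 0) expect_equal(drop$geno[f1[1], j], 1)
  }
})

test_that("segregation at double-heterozygous matings is 1:2:1", {
  # founders fixed for alternative alleles -> all F1 het at every marker
  map <- even_map(25, 20)
  ped <- build_pedigree(2, 2, 1, 1, 600)
  founders <- simulate_founder_haplotypes(
    map, breed_model(n_ancestral = 1, switch_rate = 0, flip_rate = 0),
    c(2, 2), seed = 1, ids = generation_ids(ped, "F0"))
  founders$haps[founders$breed == "A", ] <- 1L
  founders$haps[founders$breed == "B", ] <- 0L
  drop <- gene_drop(founders, ped, map, seed = 8)
  f1 <- generation_ids(ped, "F1")
  expect_true(all(drop$geno[f1, ] == 1))
  g <- drop$geno[generation_ids(ped, "F2"), ]
  freq <- table(factor(g, levels = 0:2)) / length(g)
  expect_equal(unname(as.vector(freq)), c(0.25, 0.5, 0.25), tolerance = 0.05)
})

test_that("gene dropping is reproducible under a fixed seed", {
  a <- small_population(seed = 31)
  b <- small_population(seed = 31)
  expect_identical(a$drop$geno, b$drop$geno)
  expect_identical(a$drop$hap_pat, b$drop$hap_pat)
})

test_that("scenario masking hits exactly the untyped cells", {
  pop <- small_population(n_f2 = 10, n_snp = 30)
  truth <- pop$drop$geno
  tags <- select_tagsnp_even(pop$map, 6)
  n_tag <- length(tags$snp)
  obs <- apply_genotyping_scenario(truth, pop$ped,
                                   scenario_spec("HD", "HD", "LowD"), tags)
  f2 <- generation_ids(pop$ped, "F2")
  expect_equal(unname(rowSums(is.na(obs[f2, ]))), rep(30 - n_tag, 10))
  expect_equal(obs[generation_ids(pop$ped, "F1"), ],
               truth[generation_ids(pop$ped, "F1"), ])

  expect_equal(apply_genotyping_scenario(truth, pop$ped,
                                         scenario_spec("HD", "HD", "HD")),
               truth)

  obs2 <- apply_genotyping_scenario(truth, pop$ped,
                                    scenario_spec("HD", "LowD", "LowD"), tags)
  f1 <- generation_ids(pop$ped, "F1")
  non_tag <- setdiff(colnames(truth), tags$snp)
  expect_true(all(is.na(obs2[f1, non_tag])))
  expect_true(all(is.na(obs2[f2, non_tag])))
  expect_equal(obs2[generation_ids(pop$ped, "F0"), ],
               truth[generation_ids(pop$ped, "F0"), ])

  expect_error(apply_genotyping_scenario(truth, pop$ped,
                                         scenario_spec("HD", "HD", "LowD")),
               "tagSNP")
})
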