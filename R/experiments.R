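#' Simulate a complete study population
#'
#' Convenience wrapper: founder haplotypes for the two breeds (sires =
#' breed A, dams = breed B), then gene dropping through the pedigree.
#'
#' @param map A `genetic_map`.
#' @param model A `breed_model`.
#' @param ped An `f2_pedigree`.
#' @param seed Integer seed (one seed drives founders and meioses).
#' @return List with `map`, `ped`, `founders` and `drop` (a `gene_drop`).
#' @export
simulate_study_population <- function(map, model = breed_model(),
                                      ped = build_pedigree(), seed = 1) {
  f0 <- ped[ped$generation == "F0", ]
  set.seed(seed)
  founders <- simulate_founder_haplotypes(
    map, model, n_per_breed = c(sum(f0$sex == "M"), sum(f0$sex == "F")),
    ids = f0$id)
  drop <- gene_drop(founders, ped, map)
  list(map = map, ped = ped, founders = founders, drop = drop)
}

#' Experiment configuration for the scenario grid
#'
#' @param map A `genetic_map` (default: the 64.2 Mb / 1,405 marker
#'   chromosome-12 analog at 60K density).
#' @param model A `breed_model`.
#' @param ped An `f2_pedigree`.
#' @param k_values Segment counts for evenly spaced tag panels (one run
#'   per density).
#' @param scenarios Named list of `scenario_spec`s.
#' @param seeds Integer vector of replicate seeds (distinct).
#' @param qc A `qc_config`.
#' @param certainty_threshold Phase-certainty threshold for the
#'   uncertain-phase diagnostic.
#' @param max_progeny Family-unit cap.
#' @return List of class `experiment_config`.
#' @export
experiment_config <- function(map = even_map(1405, 64.2),
                              model = breed_model(),
                              ped = build_pedigree(),
                              k_values = c(31, 80, 214),
                              scenarios = list(
                                f1hd = scenario_spec("HD", "HD", "LowD"),
                                f1lowd = scenario_spec("HD", "LowD", "LowD")),
                              seeds = 1:10,
                              qc = qc_config(),
                              certainty_threshold = 0.95,
                              max_progeny = 10) {
  stopifnot(length(seeds) >= 1, !anyDuplicated(seeds))
  structure(list(map = map, model = model, ped = ped, k_values = k_values,
                 scenarios = scenarios, seeds = seeds, qc = qc,
                 certainty_threshold = certainty_threshold,
                 max_progeny = max_progeny),
            class = "experiment_config")
}

#' Run the genotyping-scenario grid
#'
#' For every replicate seed: simulate the population, apply QC, select an
#' evenly spaced tag panel at each density, mask genotypes per scenario,
#' impute the F2 and compute accuracy and phase diagnostics. F0/F1 phasing
#' is shared across tag densities whenever the F0/F1 observations are
#' identical (both generations at HD), since the F2 panel does not enter
#' parent phasing.
#'
#' @param cfg An `experiment_config`.
#' @param verbose Print per-cell progress?
#' @return A tidy `data.frame`, one row per (seed, scenario, density):
#'   columns `seed`, `scenario`, `method`, `k`, `n_tags`,
#'   `mean_spacing_mb`, `ia`, `r2_mean`, `uncertain_phase`,
#'   `n_phase_positions`, `hap_accuracy`, `n_hap_pairs`, `n_eval_cells`,
#'   `n_conflicts`.
#' @export
run_scenario_grid <- function(cfg = experiment_config(), verbose = FALSE) {
  rows <- list()
  for (seed in cfg$seeds) {
    pop <- simulate_study_population(cfg$map, cfg$model, cfg$ped, seed = seed)
    qc <- qc_filter(pop$drop$geno, cfg$qc, ped = pop$ped, map = pop$map)
    map_qc <- qc$map
    truth <- pop$drop$geno[, map_qc$snp, drop = FALSE]
    hap_pat <- pop$drop$hap_pat[, map_qc$snp, drop = FALSE]
    hap_mat <- pop$drop$hap_mat[, map_qc$snp, drop = FALSE]
    f1_ids <- generation_ids(pop$ped, "F1")
    f2_ids <- generation_ids(pop$ped, "F2")
    f1_het <- truth[f1_ids, , drop = FALSE] == 1

    for (sc_name in names(cfg$scenarios)) {
      sc <- cfg$scenarios[[sc_name]]
      phase_cache <- NULL
      for (k in cfg$k_values) {
        tags <- select_tagsnp_even(map_qc, k)
        obs <- apply_genotyping_scenario(truth, pop$ped, sc, tags)
        reuse_phase <- all(sc[c("F0", "F1")] == "HD")
        imp <- run_imputation(obs, pop$ped, map_qc,
                              max_progeny = cfg$max_progeny,
                              f0_phase = if (reuse_phase) phase_cache$f0,
                              f1_phase = if (reuse_phase) phase_cache$f1)
        if (reuse_phase && is.null(phase_cache)) {
          phase_cache <- list(f0 = imp$f0_phase, f1 = imp$f1_phase)
        }
        non_tag <- !(map_qc$snp %in% tags$snp)
        mask <- matrix(FALSE, nrow(truth), ncol(truth),
                       dimnames = dimnames(truth))
        mask[f2_ids, non_tag] <- TRUE
        imputed <- truth * NA_real_
        imputed[f2_ids, ] <- imp$dosage
        ia <- imputation_accuracy(truth, imputed, mask)
        r2 <- r2_per_snp(truth[f2_ids, , drop = FALSE], imp$dosage,
                         matrix(rep(non_tag, each = length(f2_ids)),
                                nrow = length(f2_ids)))
        upf <- uncertain_phase_fraction(imp$f1_phase, f1_het, tags,
                                        map_qc$snp,
                                        cfg$certainty_threshold)
        hap <- haplotyping_accuracy(hap_pat[f1_ids, , drop = FALSE],
                                    hap_mat[f1_ids, , drop = FALSE],
                                    imp$f1_phase,
                                    markers = map_qc$snp[non_tag])
        rows[[length(rows) + 1L]] <- data.frame(
          seed = seed, scenario = sc_name, method = "even", k = k,
          n_tags = length(tags$snp), mean_spacing_mb = tags$mean_spacing_mb,
          ia = ia, r2_mean = r2$summary,
          uncertain_phase = upf$fraction, n_phase_positions = upf$n,
          hap_accuracy = hap$accuracy, n_hap_pairs = hap$n_pairs,
          n_eval_cells = sum(mask), n_conflicts = imp$n_conflicts,
          stringsAsFactors = FALSE)
        if (verbose) {
          message(sprintf("seed %d %s k=%d: IA=%.4f R2=%.4f unc=%.3f hap=%.3f",
                          seed, sc_name, k, ia, r2$summary, upf$fraction,
                          hap$accuracy))
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Summarize a scenario grid into the study's headline quantities
#'
#' Aggregates a [run_scenario_grid()] table over replicates: replicate-mean
#' IA per (scenario, density), pooled uncertain-phase percentages (weighted
#' by evaluated positions) and pooled haplotyping accuracy (weighted by
#' pair counts).
#'
#' @param tab Output of [run_scenario_grid()].
#' @return A list with `ia` (data.frame scenario x k with mean IA, mean R2
#'   and cell counts), `uncertain_phase_pct` and `hap_accuracy` (named by
#'   scenario, at the densest panel in the grid).
#' @export
summarize_grid <- function(tab) {
  ia <- do.call(rbind, lapply(split(tab, tab[, c("scenario", "k")]), function(d) {
    data.frame(scenario = d$scenario[1], k = d$k[1],
               mean_spacing_mb = mean(d$mean_spacing_mb),
               mean_ia = mean(d$ia), mean_r2 = mean(d$r2_mean),
               n_cells = sum(d$n_eval_cells), n_reps = nrow(d),
               stringsAsFactors = FALSE)
  }))
  rownames(ia) <- NULL
  k_dense <- max(tab$k)
  dense <- tab[tab$k == k_dense, ]
  pool <- function(d, value, weight) sum(d[[value]] * d[[weight]]) / sum(d[[weight]])
  upf <- vapply(split(dense, dense$scenario), pool, numeric(1),
                value = "uncertain_phase", weight = "n_phase_positions")
  hap <- vapply(split(dense, dense$scenario), pool, numeric(1),
                value = "hap_accuracy", weight = "n_hap_pairs")
  list(ia = ia[order(ia$scenario, ia$k), ],
       uncertain_phase_pct = 100 * upf, hap_accuracy = hap,
       k_dense = k_dense)
}

#' Genotyping cost ratio of the all-HD design over the imputation design
#'
#' Cost of typing every generation at high density divided by the cost of
#' typing F0 and F1 at high density and the F2 at low density, with the
#' low-density price normalized to 1. With the study population shape
#' (about 20 F0, 56 F1, 1000 F2) and HD costing twice LowD the ratio is
#' 1.9: the imputation design genotypes 1.9 times more animals per unit
#' cost.
#'
#' @param n_f0,n_f1,n_f2 Animals per generation.
#' @param hd_price Price of an HD genotyping, in LowD units (default 2).
#' @return The cost ratio (scalar).
#' @export
#' @examples
#' cost_ratio(20, 56, 1000)
cost_ratio <- function(n_f0, n_f1, n_f2, hd_price = 2) {
  stopifnot(n_f0 > 0, n_f1 > 0, n_f2 >= 0, hd_price > 0)
  ((n_f0 + n_f1 + n_f2) * hd_price) /
    ((n_f0 + n_f1) * hd_price + n_f2 * 1)
}
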