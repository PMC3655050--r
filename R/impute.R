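#' Split the F2 into litter-based family units
#'
#' Each unit holds the four F0 grandparents, the two F1 parents and at most
#' `max_progeny` F2 from one litter; larger litters are split into several
#' units sharing the same F0/F1 members. Units partition the F2.
#'
#' @param ped An `f2_pedigree`.
#' @param max_progeny Maximum F2 per unit (default 10).
#' @return List of `family_unit` lists with elements `litter`, `sire`,
#'   `dam`, `f0` (4 grandparent ids) and `f2` (progeny ids).
#' @export
split_families <- function(ped, max_progeny = 10) {
  stopifnot(max_progeny >= 1)
  f2 <- ped[ped$generation == "F2", ]
  if (any(is.na(f2$sire) | is.na(f2$dam))) stop("F2 with unknown parent")
  units <- list()
  for (lit in unique(f2$litter)) {
    rows <- f2[f2$litter == lit, ]
    sire <- rows$sire[1]; dam <- rows$dam[1]
    gp <- c(ped$sire[ped$id == sire], ped$dam[ped$id == sire],
            ped$sire[ped$id == dam], ped$dam[ped$id == dam])
    chunks <- split(rows$id, (seq_len(nrow(rows)) - 1L) %/% max_progeny)
    for (ch in chunks) {
      units[[length(units) + 1L]] <-
        structure(list(litter = lit, sire = sire, dam = dam, f0 = gp,
                       f2 = ch), class = "family_unit")
    }
  }
  units
}

#' Impute the F2 of one family unit
#'
#' Runs the 4-state grandparental-origin HMM for every F2 in the unit,
#' conditional on the phased F1 parents (posterior haplotype allele
#' probabilities) and the F2's own observed tagSNP genotypes. Observed
#' genotypes are reproduced exactly; untyped markers receive the posterior
#' expected dosage.
#'
#' @param unit A `family_unit`.
#' @param sire_phase,dam_phase `phased_parent` objects for the unit's F1
#'   sire and dam.
#' @param obs Observed dosage matrix containing the unit's F2 rows.
#' @param map A `genetic_map`.
#' @return List with `dosage` (F2 x markers matrix of expected dosages)
#'   and `n_conflicts`.
#' @export
impute_f2 <- function(unit, sire_phase, dam_phase, obs, map) {
  theta <- haldane(marker_gaps_morgan(map))
  sire_trans <- rbind(sire_phase$pat, sire_phase$mat)
  dam_trans <- rbind(dam_phase$pat, dam_phase$mat)
  dosage <- matrix(NA_real_, length(unit$f2), nrow(map),
                   dimnames = list(unit$f2, map$snp))
  n_conf <- 0L
  for (id in unit$f2) {
    res <- impute_child(obs[id, ], sire_trans, dam_trans, theta)
    dosage[id, ] <- res$dosage
    n_conf <- n_conf + sum(res$conflicts)
  }
  list(dosage = dosage, n_conflicts = n_conf)
}

#' Run the full linkage-based imputation pipeline
#'
#' Orchestrates the whole chain on one chromosome: phase the F0 by
#' transmission, phase every F1 parent with the origin HMM, split the F2
#' into litter-based family units, and impute every F2 at every marker.
#' Deterministic given its inputs.
#'
#' @param obs Observed (scenario-masked) dosage matrix.
#' @param ped An `f2_pedigree`.
#' @param map A `genetic_map` matching the columns of `obs`.
#' @param max_progeny Family-unit cap on F2 progeny.
#' @param f0_phase,f1_phase Optional precomputed phasing results (reused
#'   when imputing several tag panels under identical F0/F1 observations).
#' @return List of class `imputation_result`: `dosage` (F2 x markers),
#'   `f1_phase` (named list of `phased_parent`), `f0_phase`, `units`,
#'   `n_conflicts`.
#' @export
run_imputation <- function(obs, ped, map, max_progeny = 10,
                           f0_phase = NULL, f1_phase = NULL) {
  stopifnot(identical(colnames(obs), map$snp))
  if (is.null(f0_phase)) f0_phase <- phase_f0_by_transmission(obs, ped, map)
  if (is.null(f1_phase)) {
    f1_ids <- unique(c(ped$sire[ped$generation == "F2"],
                       ped$dam[ped$generation == "F2"]))
    f1_phase <- lapply(setNames(f1_ids, f1_ids), phase_f1_origin_hmm,
                       obs = obs, ped = ped, f0_phase = f0_phase, map = map)
  }
  units <- split_families(ped, max_progeny)
  f2_ids <- generation_ids(ped, "F2")
  dosage <- matrix(NA_real_, length(f2_ids), nrow(map),
                   dimnames = list(f2_ids, map$snp))
  n_conf <- 0L
  for (u in units) {
    res <- impute_f2(u, f1_phase[[u$sire]], f1_phase[[u$dam]], obs, map)
    dosage[u$f2, ] <- res$dosage
    n_conf <- n_conf + res$n_conflicts
  }
  structure(list(dosage = dosage, f1_phase = f1_phase, f0_phase = f0_phase,
                 units = units, n_conflicts = n_conf),
            class = "imputation_result")
}
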