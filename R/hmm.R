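#' Impute one child from parental transmission probabilities
#'
#' Core grandparental-origin HMM used both to phase F1 individuals against
#' their phased F0 parents and to impute F2 individuals from their phased
#' F1 parents. The hidden state at each marker is the ordered pair of
#' origins (which of the sire's two haplotypes the paternal gamete carries,
#' and likewise for the dam); the two gametes recombine independently with
#' Haldane recombination fractions per marker gap, and the prior at the
#' first marker is uniform. Emissions compare the child's observed dosage
#' with the parental allele probabilities; missing genotypes emit 1.
#'
#' Markers whose observed genotype has zero probability under every state
#' (a conflict surviving QC) are flagged and treated as missing, so they
#' are imputed from flanking information.
#'
#' @param g Length-M observed dosage vector (0/1/2/NA) for the child.
#' @param sire_trans,dam_trans 2 x M matrices: row u gives P(transmitted
#'   allele = 1 | parental origin u) per marker for the sire resp. dam.
#' @param theta Length M-1 recombination fractions between adjacent
#'   markers (see [haldane()]).
#'
#' @return List with elements
#'   `gamma` (4 x M posterior origin-state probabilities),
#'   `gprob` (3 x M posterior genotype distribution),
#'   `dosage` (expected dosage in `[0, 2]`),
#'   `pat`, `mat` (posterior P(allele = 1) of the paternal and maternal
#'   gamete),
#'   `p10`, `p01` (posterior of the two heterozygous phase configurations),
#'   `certainty` (phase certainty, `max(p10, p01) / (p10 + p01)`, NA where
#'   the genotype is certainly homozygous),
#'   `conflicts` (logical per marker), and `loglik`.
#' @export
impute_child <- function(g, sire_trans, dam_trans, theta) {
  m <- length(g)
  stopifnot(dim(sire_trans) == c(2, m), dim(dam_trans) == c(2, m),
            length(theta) == m - 1)
  pa <- sire_trans[c(1, 1, 2, 2), , drop = FALSE]   # state order (u,v):
  pb <- dam_trans[c(1, 2, 1, 2), , drop = FALSE]    # 11, 12, 21, 22
  j00 <- (1 - pa) * (1 - pb)
  j10 <- pa * (1 - pb)
  j01 <- (1 - pa) * pb
  j11 <- pa * pb

  emiss <- matrix(1, 4, m)
  obs <- which(!is.na(g))
  if (length(obs)) {
    e <- j00[, obs, drop = FALSE]
    g1 <- g[obs] == 1; g2 <- g[obs] == 2
    e[, g1] <- j10[, obs[g1], drop = FALSE] + j01[, obs[g1], drop = FALSE]
    e[, g2] <- j11[, obs[g2], drop = FALSE]
    emiss[, obs] <- e
  }
  conflicts <- apply(emiss, 2, max) == 0
  if (any(conflicts)) emiss[, conflicts] <- 1
  fb <- .fb4(emiss, theta)
  gamma <- fb$posterior

  # posterior of a state is 0 wherever its emission is 0, so 0/0 -> 0
  w <- gamma / emiss
  w[emiss == 0] <- 0
  q00 <- colSums(w * j00); q10 <- colSums(w * j10)
  q01 <- colSums(w * j01); q11 <- colSums(w * j11)
  known <- !is.na(g) & !conflicts
  k0 <- known & g == 0; k1 <- known & g == 1; k2 <- known & g == 2
  q00[k0] <- 1; q10[k0] <- 0; q01[k0] <- 0; q11[k0] <- 0
  q00[k1] <- 0; q11[k1] <- 0
  q00[k2] <- 0; q10[k2] <- 0; q01[k2] <- 0; q11[k2] <- 1

  het <- q10 + q01
  certainty <- ifelse(het > 0, pmax(q10, q01) / het, NA_real_)
  list(gamma = gamma,
       gprob = rbind(p0 = q00, p1 = het, p2 = q11),
       dosage = het + 2 * q11,
       pat = q10 + q11, mat = q01 + q11,
       p10 = q10, p01 = q01,
       certainty = certainty,
       conflicts = conflicts,
       loglik = fb$loglik)
}
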