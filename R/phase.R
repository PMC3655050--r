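#' Phase F0 founders by Mendelian transmission
#'
#' Resolves each F0 individual's two haplotypes from transmissions to its
#' F1 offspring. At a heterozygous F0 marker the allele transmitted to an
#' offspring is deducible when the offspring is homozygous, or heterozygous
#' with the other parent homozygous. Deduced transmissions are chained
#' along the chromosome: each offspring's gamete rarely recombines, so
#' consecutive deduced alleles usually come from the same founder
#' haplotype. Markers are processed in map order and each offspring casts a
#' vote weighted by the log-odds of no recombination (Haldane) since its
#' last informative marker. Heterozygous markers with no deducible
#' transmission stay unresolved and carry 50/50 allele probabilities
#' downstream.
#'
#' @param obs Observed dosage matrix (individuals x markers).
#' @param ped An `f2_pedigree`.
#' @param map A `genetic_map` matching the columns of `obs`.
#' @return A named list (one element per F0 id) of class `f0_phase`; each
#'   element has `trans` (2 x M matrix of P(allele = 1 | haplotype)),
#'   `h1`, `h2` (hard allele calls, NA where unresolved) and `resolved`
#'   (logical per marker).
#' @export
phase_f0_by_transmission <- function(obs, ped, map) {
  f0 <- generation_ids(ped, "F0")
  f1 <- ped[ped$generation == "F1", ]
  m <- nrow(map)
  cm <- map$cm
  out <- list()
  for (p in f0) {
    g_p <- obs[p, ]
    trans <- rbind(g_p / 2, g_p / 2)          # hom markers: allele known
    trans[, is.na(g_p)] <- 0.5
    resolved <- !is.na(g_p) & g_p != 1
    h1 <- h2 <- ifelse(resolved, g_p / 2, NA_real_)

    kids <- f1[f1$sire == p | f1$dam == p, ]
    het <- which(!is.na(g_p) & g_p == 1)
    if (nrow(kids) > 0 && length(het) > 0) {
      # deduced transmitted allele per child x het marker
      tmat <- matrix(NA_integer_, nrow(kids), length(het))
      for (ci in seq_len(nrow(kids))) {
        other <- if (kids$sire[ci] == p) kids$dam[ci] else kids$sire[ci]
        g_c <- obs[kids$id[ci], het]
        g_o <- obs[other, het]
        t <- rep(NA_integer_, length(het))
        t[!is.na(g_c) & g_c == 0] <- 0L
        t[!is.na(g_c) & g_c == 2] <- 1L
        d1 <- !is.na(g_c) & g_c == 1 & !is.na(g_o)
        t[d1 & g_o == 0] <- 1L
        t[d1 & g_o == 2] <- 0L
        tmat[ci, ] <- t
      }
      orient <- integer(nrow(kids))           # +1: child carries h1; -1: h2
      lastpos <- rep(NA_real_, nrow(kids))
      for (k in seq_along(het)) {
        j <- het[k]
        tj <- tmat[, k]
        ded <- which(!is.na(tj))
        if (length(ded) == 0L) next
        inf <- ded[orient[ded] != 0L]
        score <- 0
        if (length(inf)) {
          th <- haldane((cm[j] - lastpos[inf]) / 100)
          wgt <- log((1 - th) / pmax(th, 1e-12))
          score <- sum(orient[inf] * (2 * tj[inf] - 1) * wgt)
        }
        a1 <- if (score > 0) 1L else if (score < 0) 0L else tj[ded[1]]
        h1[j] <- a1; h2[j] <- 1 - a1
        trans[1, j] <- a1; trans[2, j] <- 1 - a1
        resolved[j] <- TRUE
        orient[ded] <- ifelse(tj[ded] == a1, 1L, -1L)
        lastpos[ded] <- cm[j]
      }
    }
    out[[p]] <- list(trans = trans, h1 = h1, h2 = h2, resolved = resolved)
  }
  structure(out, class = "f0_phase")
}

#' Phase one F1 individual with the grandparental-origin HMM
#'
#' Runs the origin HMM for an F1 individual conditional on its phased F0
#' parents and its own observed genotypes (high or low density). When the
#' F1 is typed at low density the emissions at untyped markers are vacuous
#' and its alleles are inferred from the origin posteriors and the F0
#' haplotypes alone.
#'
#' @param id F1 individual id.
#' @param obs Observed dosage matrix.
#' @param ped An `f2_pedigree`.
#' @param f0_phase Result of [phase_f0_by_transmission()].
#' @param map A `genetic_map`.
#' @return A `phased_parent`: the [impute_child()] output plus `id`, where
#'   `pat`/`mat` are the posterior allele probabilities of the two
#'   haplotypes and `certainty` the per-marker phase certainty.
#' @export
phase_f1_origin_hmm <- function(id, obs, ped, f0_phase, map) {
  row <- which(ped$id == id)
  if (length(row) != 1L || ped$generation[row] != "F1") {
    stop("id must name one F1 individual")
  }
  res <- impute_child(obs[id, ],
                      f0_phase[[ped$sire[row]]]$trans,
                      f0_phase[[ped$dam[row]]]$trans,
                      haldane(marker_gaps_morgan(map)))
  res$id <- id
  class(res) <- "phased_parent"
  res
}
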