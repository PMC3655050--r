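#' Simulate one meiosis
#'
#' Draws a gamete from a parent's phased haplotype pair. The crossover count
#' is Poisson with mean equal to the chromosome length in Morgans (no
#' interference, consistent with the Haldane map function); crossover
#' positions are i.i.d. uniform on the physical chromosome; the gamete
#' starts from a fair-coin choice of parental haplotype and alternates at
#' each crossover.
#'
#' @param parent_haps 2 x M integer matrix (0/1 alleles): the parent's
#'   paternal (row 1) and maternal (row 2) haplotypes over `map`.
#' @param map A `genetic_map`.
#' @param seed Optional integer seed.
#'
#' @return List with `gamete` (length-M 0/1 vector) and `record`, a meiosis
#'   record holding `n_xo`, `xo_bp` (crossover positions in bp), `start`
#'   (starting haplotype, 1 = grandpaternal) and `origin` (per-marker origin
#'   in {1, 2}).
#' @export
simulate_meiosis <- function(parent_haps, map, seed = NULL) {
  stopifnot(is.matrix(parent_haps), nrow(parent_haps) == 2,
            ncol(parent_haps) == nrow(map))
  if (!is.null(seed)) set.seed(seed)
  lambda <- morgan_length(map)
  n_xo <- rpois(1, lambda)
  xo_bp <- sort(runif(n_xo, 0, attr(map, "length_mb") * 1e6))
  start <- sample(1:2, 1)
  origin <- 1L + (start - 1L + findInterval(map$bp, xo_bp)) %% 2L
  gamete <- parent_haps[cbind(origin, seq_len(ncol(parent_haps)))]
  list(gamete = gamete,
       record = list(n_xo = n_xo, xo_bp = xo_bp, start = start,
                     origin = origin))
}

#' Gene dropping through a pedigree
#'
#' Propagates founder haplotypes through the pedigree by simulated meioses:
#' F1 haplotypes are gametes of their F0 parents, F2 haplotypes gametes of
#' their F1 parents. Retains full phase and grandparental-origin truth for
#' later evaluation of imputation and phasing.
#'
#' @param founders A `haplotype_panel` covering every F0 in `ped`.
#' @param ped An `f2_pedigree`.
#' @param map A `genetic_map`.
#' @param seed Optional integer seed.
#'
#' @return A list of class `gene_drop` with matrices (individuals x markers,
#'   rownames = ids): `geno` (true dosages 0/1/2), `hap_pat`/`hap_mat`
#'   (phased 0/1 alleles, paternal/maternal), `orig_pat`/`orig_mat`
#'   (grandparental origins in {1, 2}, NA for F0), plus `meioses`, a list
#'   per child id with elements `pat` and `mat` meiosis records (each also
#'   carrying `child` and `parent` ids).
#' @export
gene_drop <- function(founders, ped, map, seed = NULL) {
  stopifnot(inherits(founders, "haplotype_panel"), inherits(map, "genetic_map"))
  if (!is.null(seed)) set.seed(seed)
  m <- nrow(map)
  ids <- ped$id
  f0 <- generation_ids(ped, "F0")
  if (!all(f0 %in% founders$id)) {
    stop("pedigree/panel mismatch: founder haplotypes missing for some F0")
  }
  hap_pat <- hap_mat <- matrix(NA_integer_, length(ids), m,
                               dimnames = list(ids, map$snp))
  orig_pat <- orig_mat <- matrix(NA_integer_, length(ids), m,
                                 dimnames = list(ids, map$snp))
  for (id in f0) {
    rows <- which(founders$id == id)
    hap_pat[id, ] <- founders$haps[rows[1], ]
    hap_mat[id, ] <- founders$haps[rows[2], ]
  }
  meioses <- list()
  children <- ped[ped$generation != "F0", ]
  children <- children[order(match(children$generation, c("F1", "F2"))), ]
  for (i in seq_len(nrow(children))) {
    id <- children$id[i]
    sire <- children$sire[i]; dam <- children$dam[i]
    mp <- simulate_meiosis(rbind(hap_pat[sire, ], hap_mat[sire, ]), map)
    mm <- simulate_meiosis(rbind(hap_pat[dam, ], hap_mat[dam, ]), map)
    hap_pat[id, ] <- mp$gamete
    hap_mat[id, ] <- mm$gamete
    orig_pat[id, ] <- mp$record$origin
    orig_mat[id, ] <- mm$record$origin
    meioses[[id]] <- list(pat = c(mp$record, child = id, parent = sire),
                          mat = c(mm$record, child = id, parent = dam))
  }
  structure(list(geno = hap_pat + hap_mat, hap_pat = hap_pat,
                 hap_mat = hap_mat, orig_pat = orig_pat, orig_mat = orig_mat,
                 meioses = meioses),
            class = "gene_drop")
}

#' Genotyping scenario
#'
#' Which panel each generation is typed with: `"HD"` (all markers),
#' `"LowD"` (tagSNP only) or `"none"` (not genotyped).
#'
#' @param f0,f1,f2 Panel per generation.
#' @return A named character vector of class `scenario_spec`.
#' @export
#' @examples
#' scenario_spec("HD", "HD", "LowD")
scenario_spec <- function(f0 = "HD", f1 = "HD", f2 = "LowD") {
  sc <- c(F0 = f0, F1 = f1, F2 = f2)
  if (!all(sc %in% c("HD", "LowD", "none"))) {
    stop("panels must be one of 'HD', 'LowD', 'none'")
  }
  structure(sc, class = "scenario_spec")
}

#' Mask a truth genotype matrix according to a genotyping scenario
#'
#' HD generations keep every marker; LowD generations keep only the tagSNP
#' and have all other markers set to missing; `none` generations are fully
#' missing. The truth matrix is left untouched.
#'
#' @param truth Individuals x markers dosage matrix (rownames = ids).
#' @param ped An `f2_pedigree` covering the rows of `truth`.
#' @param scenario A `scenario_spec`.
#' @param tag_set A `tag_set` (or character vector of marker ids); required
#'   when any generation is LowD.
#' @return The observed genotype matrix (same shape, `NA` where untyped).
#' @export
apply_genotyping_scenario <- function(truth, ped, scenario, tag_set = NULL) {
  stopifnot(inherits(scenario, "scenario_spec"))
  tags <- tag_ids(tag_set)
  if (any(scenario == "LowD") && length(tags) == 0L) {
    stop("a LowD generation requires a tagSNP set")
  }
  if (length(tags) && !all(tags %in% colnames(truth))) {
    stop("tag set contains markers absent from the genotype matrix")
  }
  obs <- truth
  for (g in names(scenario)) {
    ids <- intersect(generation_ids(ped, g), rownames(truth))
    if (length(ids) == 0L) {
      if (!g %in% ped$generation) {
        stop("scenario names generation ", g, " absent from the pedigree")
      }
      next
    }
    if (scenario[[g]] == "none") {
      obs[ids, ] <- NA_integer_
    } else if (scenario[[g]] == "LowD") {
      obs[ids, setdiff(colnames(truth), tags)] <- NA_integer_
    }
  }
  obs
}
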