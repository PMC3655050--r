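#' QC configuration
#'
#' Thresholds of the data-editing rules applied to genotype matrices before
#' tag selection and imputation.
#'
#' @param max_snp_missing Maximum per-marker missing rate (markers above are
#'   dropped).
#' @param max_animal_missing Maximum per-animal missing rate.
#' @param min_maf Minimum minor allele frequency.
#' @param drop_unmapped Drop markers absent from the map?
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(max_snp_missing = 0.10, max_animal_missing = 0.10,
                      min_maf = 0.01, drop_unmapped = TRUE) {
  vals <- c(max_snp_missing, max_animal_missing, min_maf)
  if (any(vals < 0) || any(vals > 1)) stop("QC thresholds must be in [0, 1]")
  structure(list(max_snp_missing = max_snp_missing,
                 max_animal_missing = max_animal_missing,
                 min_maf = min_maf, drop_unmapped = drop_unmapped),
            class = "qc_config")
}

# Transmittable allele sets per dosage: 0 -> {0}, 1 -> {0,1}, 2 -> {1}.
# A trio (s, d, c) is consistent iff some ts in T(s), td in T(d) sum to c.
trio_consistent <- function(s, d, c) {
  if (is.na(c)) return(TRUE)
  ts <- if (is.na(s)) 0:1 else switch(s + 1L, 0L, 0:1, 1L)
  td <- if (is.na(d)) 0:1 else switch(d + 1L, 0L, 0:1, 1L)
  c %in% outer(ts, td, `+`)
}

# 4 x 4 x 4 lookup over dosage codes {0,1,2,NA->4th level} for fast
# vectorized trio checks; built once at load from trio_consistent().
.trio_table <- local({
  lv <- list(0L, 1L, 2L, NA_integer_)
  arr <- array(NA, c(4, 4, 4))
  for (s in 1:4) for (d in 1:4) for (c in 1:4) {
    arr[s, d, c] <- trio_consistent(lv[[s]], lv[[d]], lv[[c]])
  }
  arr
})

.dosage_code <- function(g) ifelse(is.na(g), 4L, as.integer(g) + 1L)

#' Mask Mendelian inconsistencies
#'
#' For every child with at least one genotyped parent, any dosage
#' combination impossible under Mendelian transmission (e.g. parent 0 with
#' child 2, or parents 2 x 2 with child 1) sets the child's genotype to
#' missing at that marker. Parents are untouched; checks are duo/trio level
#' only, matching per-genotype masking (no multi-generation constraint
#' propagation).
#'
#' @param genos Individuals x markers dosage matrix (0/1/2/NA).
#' @param ped An `f2_pedigree`; parents referenced must be rows of `genos`
#'   when genotyped.
#' @return List with `genos` (masked matrix) and `n_masked`.
#' @export
mask_mendelian_inconsistencies <- function(genos, ped) {
  kids <- ped[!is.na(ped$sire) | !is.na(ped$dam), ]
  kids <- kids[kids$id %in% rownames(genos), ]
  n_masked <- 0L
  for (i in seq_len(nrow(kids))) {
    id <- kids$id[i]
    g_s <- if (!is.na(kids$sire[i]) && kids$sire[i] %in% rownames(genos))
      genos[kids$sire[i], ] else rep(NA_integer_, ncol(genos))
    g_d <- if (!is.na(kids$dam[i]) && kids$dam[i] %in% rownames(genos))
      genos[kids$dam[i], ] else rep(NA_integer_, ncol(genos))
    g_c <- genos[id, ]
    bad <- !.trio_table[cbind(.dosage_code(g_s), .dosage_code(g_d),
                              .dosage_code(g_c))]
    if (any(bad)) {
      genos[id, bad] <- NA_integer_
      n_masked <- n_masked + sum(bad)
    }
  }
  list(genos = genos, n_masked = n_masked)
}

#' Genotype quality control
#'
#' Applies the data-editing rules in a fixed order: (1) drop markers absent
#' from the map; (2) mask Mendelian inconsistencies; (3) drop animals with
#' missing rate above threshold; (4) drop markers with missing rate above
#' threshold; (5) drop markers with MAF below threshold (MAF computed on the
#' retained animals). The order is fixed because overlapping filters make
#' rule-wise counts order-dependent. Rules 3-5 are iterated to a fixed
#' point (dropping markers can raise animal missing rates and vice versa),
#' so the output satisfies every rule jointly and the filter is idempotent.
#'
#' @param genos Individuals x markers dosage matrix (0/1/2/NA).
#' @param cfg A `qc_config`.
#' @param ped Optional `f2_pedigree` enabling the Mendelian rule.
#' @param map Optional `genetic_map` enabling the unmapped-marker rule.
#' @return List of class `qc_result`: `genos` (filtered matrix), `map`
#'   (filtered map or NULL) and `report`, a list with counts
#'   `snp_unmapped`, `geno_mendelian_masked`, `animals_missing`,
#'   `snp_missing`, `snp_low_maf`, and retained dimensions.
#' @export
qc_filter <- function(genos, cfg = qc_config(), ped = NULL, map = NULL) {
  stopifnot(is.matrix(genos))
  in_animals <- nrow(genos); in_snps <- ncol(genos)
  report <- list(snp_unmapped = 0L, geno_mendelian_masked = 0L,
                 animals_missing = 0L, snp_missing = 0L, snp_low_maf = 0L)

  if (!is.null(map) && isTRUE(cfg$drop_unmapped)) {
    keep <- colnames(genos) %in% map$snp
    report$snp_unmapped <- sum(!keep)
    genos <- genos[, keep, drop = FALSE]
  }
  if (!is.null(ped)) {
    mm <- mask_mendelian_inconsistencies(genos, ped)
    genos <- mm$genos
    report$geno_mendelian_masked <- mm$n_masked
  }
  # Animal-missingness, marker-missingness and MAF interact (dropping
  # markers changes animal missing rates and vice versa), so the three
  # rules are iterated, in the stated order, until a fixed point where the
  # output satisfies all of them jointly. This makes the filter idempotent.
  repeat {
    changed <- FALSE
    keep_a <- rowMeans(is.na(genos)) <= cfg$max_animal_missing
    if (!all(keep_a)) {
      report$animals_missing <- report$animals_missing + sum(!keep_a)
      genos <- genos[keep_a, , drop = FALSE]
      changed <- TRUE
    }
    if (nrow(genos) == 0L) {
      stop("QC removed all animals; report: ",
           paste(names(report), unlist(report), sep = "=", collapse = ", "))
    }
    keep_s <- colMeans(is.na(genos)) <= cfg$max_snp_missing
    if (!all(keep_s)) {
      report$snp_missing <- report$snp_missing + sum(!keep_s)
      genos <- genos[, keep_s, drop = FALSE]
      changed <- TRUE
    }
    maf <- marker_maf(genos)
    keep_maf <- !is.na(maf) & maf >= cfg$min_maf
    if (!all(keep_maf)) {
      report$snp_low_maf <- report$snp_low_maf + sum(!keep_maf)
      genos <- genos[, keep_maf, drop = FALSE]
      changed <- TRUE
    }
    if (ncol(genos) == 0L) {
      stop("QC removed all markers; report: ",
           paste(names(report), unlist(report), sep = "=", collapse = ", "))
    }
    if (!changed) break
  }
  report$animals_retained <- nrow(genos)
  report$snp_retained <- ncol(genos)
  report$animals_in <- in_animals
  report$snp_in <- in_snps
  if (!is.null(map)) map <- subset_map(map, colnames(genos))
  structure(list(genos = genos, map = map, report = report),
            class = "qc_result")
}

#' Minor allele frequencies of a dosage matrix
#' @param genos Individuals x markers dosage matrix.
#' @return Per-marker MAF (NA for markers with no genotypes).
#' @export
marker_maf <- function(genos) {
  p <- colMeans(genos, na.rm = TRUE) / 2
  pmin(p, 1 - p)
}
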