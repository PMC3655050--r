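#' Allelic-dosage imputation accuracy (IA)
#'
#' `IA = 1 - sum(|g - ghat|) / (2 * n)`, i.e. one minus half the mean
#' absolute difference between true and imputed allelic dosage over the
#' evaluated genotypes. Equals 1 for perfect imputation and 0 under
#' maximal dosage error (true 0 imputed as 2 or vice versa).
#'
#' @param truth True dosage matrix (0/1/2).
#' @param imputed Imputed dosage matrix in `[0, 2]`, same shape.
#' @param mask Logical matrix selecting the evaluated cells (typically the
#'   scenario-masked non-tagSNP cells of the imputed generation).
#' @return IA (scalar in `[0, 1]`).
#' @export
#' @examples
#' imputation_accuracy(rbind(c(0, 1, 2)), rbind(c(0, 2, 2)),
#'                     rbind(c(TRUE, TRUE, TRUE)))
imputation_accuracy <- function(truth, imputed, mask = NULL) {
  stopifnot(all(dim(truth) == dim(imputed)))
  if (is.null(mask)) mask <- !is.na(truth)
  cells <- mask & !is.na(truth) & !is.na(imputed)
  n <- sum(cells)
  if (n == 0L) stop("no evaluated cells")
  1 - sum(abs(truth[cells] - imputed[cells])) / (2 * n)
}

#' Per-SNP imputation R-squared
#'
#' Squared Pearson correlation between true and imputed dosages across the
#' evaluated animals, per marker. Markers with zero variance in either
#' vector (or fewer than 2 evaluated animals) are undefined and excluded
#' from the summary, which is the unweighted mean over defined markers
#' (`pooled = TRUE` instead computes one squared correlation over all
#' evaluated cells).
#'
#' @inheritParams imputation_accuracy
#' @param pooled Also report the pooled-cells squared correlation?
#' @return List with `per_snp` (named vector, NA where undefined),
#'   `summary` (mean over defined markers), `n_defined`, and `pooled`.
#' @export
r2_per_snp <- function(truth, imputed, mask = NULL, pooled = FALSE) {
  stopifnot(all(dim(truth) == dim(imputed)))
  if (is.null(mask)) mask <- !is.na(truth)
  cells <- mask & !is.na(truth) & !is.na(imputed)
  per <- vapply(seq_len(ncol(truth)), function(j) {
    i <- cells[, j]
    if (sum(i) < 2) return(NA_real_)
    x <- truth[i, j]; y <- imputed[i, j]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    cor(x, y)^2
  }, numeric(1))
  names(per) <- colnames(truth)
  if (all(is.na(per))) stop("R2 undefined at every marker")
  out <- list(per_snp = per, summary = mean(per, na.rm = TRUE),
              n_defined = sum(!is.na(per)))
  out$pooled <- if (pooled) cor(truth[cells], imputed[cells])^2 else NA_real_
  out
}

# Inferred phase orientation per marker: TRUE if allele 1 sits on the
# paternal haplotype, NA where the heterozygous posterior mass is zero.
phase_orientation <- function(ph) {
  ifelse(ph$p10 + ph$p01 > 0, ph$p10 >= ph$p01, NA)
}

#' Haplotyping accuracy against true phase
#'
#' Fraction of consecutive heterozygous-marker pairs whose inferred
#' relative phase (whether the same haplotype carries allele 1 at both
#' markers) matches the gene-dropped truth, pooled over individuals.
#' Whole-chromosome haplotype relabeling does not count as error since
#' only relative phase is compared. Individuals with fewer than two
#' heterozygous markers contribute no pairs.
#'
#' @param truth_pat,truth_mat True paternal/maternal haplotype matrices
#'   (individuals x markers, 0/1) from [gene_drop()].
#' @param phased Named list of `phased_parent` objects (names = ids).
#' @param markers Optional marker ids restricting the evaluation (e.g.
#'   non-tagSNP only).
#' @return List with `accuracy` (scalar) and `n_pairs`.
#' @export
haplotyping_accuracy <- function(truth_pat, truth_mat, phased,
                                 markers = NULL) {
  snps <- colnames(truth_pat)
  keep <- if (is.null(markers)) rep(TRUE, length(snps)) else snps %in% markers
  ok <- 0L; n <- 0L
  for (id in names(phased)) {
    het <- which(keep & truth_pat[id, ] + truth_mat[id, ] == 1)
    if (length(het) < 2) next
    o_true <- truth_pat[id, het] == 1
    o_inf <- phase_orientation(phased[[id]])[het]
    def <- !is.na(o_inf)
    idx <- het[def]
    if (length(idx) < 2) next
    same_true <- diff(o_true[def]) == 0
    same_inf <- diff(o_inf[def]) == 0
    ok <- ok + sum(same_true == same_inf)
    n <- n + length(idx) - 1L
  }
  if (n == 0L) stop("no consecutive heterozygous pairs to evaluate")
  list(accuracy = ok / n, n_pairs = n)
}

#' Fraction of non-tagSNP with uncertain phase
#'
#' Proportion of evaluated heterozygous non-tagSNP positions whose phase
#' certainty (posterior probability of the more likely phase
#' configuration, conditional on heterozygosity) falls below `threshold`,
#' pooled over individuals.
#'
#' @param phased Named list of `phased_parent` objects.
#' @param het_mask Logical matrix (individuals x markers, rownames
#'   covering `names(phased)`) marking heterozygous positions (typically
#'   from the true genotypes).
#' @param tags Tag set (`tag_set` or marker ids) excluded from evaluation.
#' @param snps Marker ids labelling the columns.
#' @param threshold Certainty threshold (default 0.95).
#' @return List with `fraction`, `n` (positions evaluated) and
#'   `n_uncertain`.
#' @export
uncertain_phase_fraction <- function(phased, het_mask, tags, snps,
                                     threshold = 0.95) {
  non_tag <- !(snps %in% tag_ids(tags))
  n <- 0L; unc <- 0L
  for (id in names(phased)) {
    pos <- which(non_tag & het_mask[id, ])
    cert <- phased[[id]]$certainty[pos]
    cert[is.na(cert)] <- 0            # model puts no mass on heterozygous
    n <- n + length(pos)
    unc <- unc + sum(cert < threshold)
  }
  if (n == 0L) stop("no non-tagSNP heterozygous positions to evaluate")
  list(fraction = unc / n, n = n, n_uncertain = unc)
}

#' Accuracy stratified by a marker covariate
#'
#' Binned means of per-SNP R2 (or any per-marker accuracy) against a
#' covariate such as founder MAF, distance to the nearest tagSNP (use
#' log10 base pairs) or absolute founder-breed frequency difference.
#' Empty bins are absent from the output rather than reported as zero.
#'
#' @param values Per-marker accuracy values (NA ignored).
#' @param covariate Per-marker covariate.
#' @param breaks Bin breaks passed to [cut()].
#' @return data.frame with `bin`, `mid`, `mean`, `n`.
#' @export
stratified_accuracy <- function(values, covariate, breaks) {
  stopifnot(length(values) == length(covariate))
  keep <- !is.na(values) & !is.na(covariate)
  bin <- cut(covariate[keep], breaks, include.lowest = TRUE)
  agg <- tapply(values[keep], bin, mean)
  cnt <- tapply(values[keep], bin, length)
  present <- !is.na(agg)
  mids <- (breaks[-length(breaks)] + breaks[-1]) / 2
  data.frame(bin = names(agg)[present], mid = mids[present],
             mean = unname(agg[present]), n = unname(cnt[present]),
             stringsAsFactors = FALSE)
}

#' Distance from each marker to the nearest tagSNP
#' @param map A `genetic_map`.
#' @param tags Tag set.
#' @return Per-marker distance in base pairs (0 for tagSNP).
#' @export
distance_to_nearest_tag <- function(map, tags) {
  tag_bp <- map$bp[map$snp %in% tag_ids(tags)]
  vapply(map$bp, function(p) min(abs(p - tag_bp)), numeric(1))
}
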