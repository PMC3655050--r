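#' Construct a genetic map
#'
#' A genetic map holds marker identities, physical positions (1-based base
#' pairs, strictly increasing) and the physical-to-genetic conversion used
#' throughout the package. Genetic positions are derived from physical
#' positions with a constant rate (default 1 cM per Mb), the convention used
#' for pig linkage maps when no high-resolution recombination map exists.
#'
#' @param bp Integer vector of physical positions in base pairs, 1-based and
#'   strictly increasing.
#' @param length_mb Chromosome length in Mb; all positions must lie within
#'   it. Defaults to the last marker position.
#' @param chrom Chromosome label.
#' @param snp Marker identifiers; generated when missing.
#' @param cm_per_mb Recombination rate in cM per Mb (scalar, >= 0).
#'
#' @return A `data.frame` of class `genetic_map` with columns `chrom`,
#'   `snp`, `cm`, `bp`, and attributes `length_mb` and `cm_per_mb`.
#' @export
#' @examples
#' gm <- genetic_map(c(1e6, 2e6, 5e6), length_mb = 10)
#' morgan_length(gm)
genetic_map <- function(bp, length_mb = NULL, chrom = "1", snp = NULL,
                        cm_per_mb = 1) {
  bp <- as.numeric(bp)
  if (length(bp) == 0L) stop("empty map: no marker positions supplied")
  if (any(!is.finite(bp)) || any(bp < 1)) stop("positions must be >= 1")
  if (is.unsorted(bp, strictly = TRUE)) {
    stop("positions must be strictly increasing")
  }
  if (is.null(length_mb)) length_mb <- bp[length(bp)] / 1e6
  if (length_mb <= 0) stop("chromosome length must be positive")
  if (bp[length(bp)] > length_mb * 1e6 + 0.5) {
    stop("marker positions exceed the chromosome length")
  }
  if (cm_per_mb < 0) stop("cm_per_mb must be >= 0")
  if (is.null(snp)) {
    snp <- sprintf("snp%0*d", nchar(length(bp)), seq_along(bp))
  }
  map <- data.frame(chrom = as.character(chrom), snp = as.character(snp),
                    cm = bp / 1e6 * cm_per_mb, bp = bp,
                    stringsAsFactors = FALSE)
  attr(map, "length_mb") <- length_mb
  attr(map, "cm_per_mb") <- cm_per_mb
  class(map) <- c("genetic_map", "data.frame")
  map
}

#' Evenly spaced marker map
#'
#' Places `n_snp` markers at (rounded) equal intervals from position 1 to the
#' end of the chromosome, emulating a dense SNP array at a given density
#' (e.g. 1,405 markers over a 64.2 Mb chromosome gives the 60K-chip density
#' of roughly one marker every 0.046 Mb).
#'
#' @param n_snp Number of markers.
#' @param length_mb Chromosome length in Mb.
#' @inheritParams genetic_map
#' @return A `genetic_map`.
#' @export
even_map <- function(n_snp, length_mb, chrom = "1", cm_per_mb = 1) {
  if (n_snp < 1) stop("need at least one marker")
  bp <- if (n_snp == 1L) round(length_mb * 5e5) else
    round(seq(1, length_mb * 1e6, length.out = n_snp))
  genetic_map(bp, length_mb = length_mb, chrom = chrom, cm_per_mb = cm_per_mb)
}

#' Chromosome length in Morgans
#'
#' The expected number of crossovers per meiosis on the chromosome, i.e. the
#' mean of the Poisson crossover-count distribution used in gene dropping.
#' A 64.2 Mb chromosome at 1 cM/Mb has length 64.2 cM = 0.642 M.
#'
#' @param map A `genetic_map`.
#' @return Length in Morgans (scalar).
#' @export
morgan_length <- function(map) {
  attr(map, "length_mb") * attr(map, "cm_per_mb") / 100
}

#' Map distances between adjacent markers, in Morgans
#' @param map A `genetic_map`.
#' @return Numeric vector of length `nrow(map) - 1`.
#' @export
marker_gaps_morgan <- function(map) {
  diff(map$cm) / 100
}

#' Restrict a genetic map to a subset of markers
#'
#' @param map A `genetic_map`.
#' @param snps Marker ids to keep (order taken from the map).
#' @return A `genetic_map` over the retained markers, with the original
#'   chromosome length and cM/Mb rate.
#' @export
subset_map <- function(map, snps) {
  keep <- map$snp %in% snps
  if (!any(keep)) stop("no markers retained")
  genetic_map(map$bp[keep], length_mb = attr(map, "length_mb"),
              chrom = map$chrom[1], snp = map$snp[keep],
              cm_per_mb = attr(map, "cm_per_mb"))
}

#' Haldane map function
#'
#' Converts genetic distance to recombination fraction under no
#' interference: theta = (1 - exp(-2 d)) / 2 for d in Morgans.
#'
#' @param d Genetic distance in Morgans (>= 0).
#' @return Recombination fraction in `[0, 0.5)`.
#' @export
haldane <- function(d) {
  if (any(d < 0)) stop("map distance must be >= 0")
  (1 - exp(-2 * d)) / 2
}
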