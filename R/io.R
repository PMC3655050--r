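#' Write genotypes as PLINK text files
#'
#' Writes `<prefix>.ped` / `<prefix>.map` in PLINK text format: alleles
#' coded 1/2 (dosage counts allele 2), missing as 0; map columns are
#' chromosome, marker id, genetic position (cM) and physical position (bp).
#'
#' @param genos Individuals x markers dosage matrix (0/1/2/NA).
#' @param map A `genetic_map` matching the columns.
#' @param prefix Output path prefix.
#' @param ped Optional `f2_pedigree` supplying parentage and sex.
#' @return Invisibly the two file paths.
#' @export
write_plink <- function(genos, map, prefix, ped = NULL) {
  stopifnot(identical(colnames(genos), map$snp))
  ids <- rownames(genos)
  sire <- dam <- rep("0", length(ids)); sex <- rep("0", length(ids))
  if (!is.null(ped)) {
    i <- match(ids, ped$id)
    sire <- ifelse(is.na(ped$sire[i]), "0", ped$sire[i])
    dam <- ifelse(is.na(ped$dam[i]), "0", ped$dam[i])
    sex <- ifelse(ped$sex[i] == "M", "1", "2")
  }
  a1 <- ifelse(is.na(genos), "0", ifelse(genos == 2, "2", "1"))
  a2 <- ifelse(is.na(genos), "0", ifelse(genos >= 1, "2", "1"))
  inter <- matrix("", nrow(genos), 2L * ncol(genos))
  inter[, seq(1, by = 2, length.out = ncol(genos))] <- a1
  inter[, seq(2, by = 2, length.out = ncol(genos))] <- a2
  lines <- paste(ids, ids, sire, dam, sex, "-9",
                 apply(inter, 1, paste, collapse = " "))
  ped_file <- paste0(prefix, ".ped"); map_file <- paste0(prefix, ".map")
  writeLines(lines, ped_file)
  write.table(data.frame(map$chrom, map$snp, map$cm, map$bp),
              map_file, quote = FALSE, row.names = FALSE, col.names = FALSE,
              sep = "\t")
  invisible(c(ped_file, map_file))
}

#' Read PLINK text genotypes
#'
#' @param prefix Path prefix of `<prefix>.ped` / `<prefix>.map`.
#' @param length_mb,cm_per_mb Map attributes (length defaults to the last
#'   marker position).
#' @return List with `genos` (dosage matrix, allele 2 counted), `map`
#'   (a `genetic_map`) and `fam` (id, sire, dam, sex).
#' @export
read_plink <- function(prefix, length_mb = NULL, cm_per_mb = 1) {
  mp <- read.table(paste0(prefix, ".map"), header = FALSE,
                   col.names = c("chrom", "snp", "cm", "bp"),
                   colClasses = c("character", "character", "numeric",
                                  "numeric"))
  map <- genetic_map(mp$bp, length_mb = length_mb, chrom = mp$chrom[1],
                     snp = mp$snp, cm_per_mb = cm_per_mb)
  pd <- read.table(paste0(prefix, ".ped"), header = FALSE,
                   colClasses = "character")
  if (ncol(pd) != 6 + 2 * nrow(mp)) stop("ped/map marker counts disagree")
  al <- as.matrix(pd[, -(1:6), drop = FALSE])
  a1 <- al[, seq(1, by = 2, length.out = nrow(mp)), drop = FALSE]
  a2 <- al[, seq(2, by = 2, length.out = nrow(mp)), drop = FALSE]
  genos <- (a1 == "2") + (a2 == "2")
  genos[a1 == "0" | a2 == "0"] <- NA
  dimnames(genos) <- list(pd[, 2], mp$snp)
  fam <- data.frame(id = pd[, 2],
                    sire = ifelse(pd[, 3] == "0", NA, pd[, 3]),
                    dam = ifelse(pd[, 4] == "0", NA, pd[, 4]),
                    sex = c("0" = NA, "1" = "M", "2" = "F")[pd[, 5]],
                    stringsAsFactors = FALSE)
  list(genos = genos, map = map, fam = fam)
}

#' Write / read a pedigree table
#'
#' Comma-separated with header `id,sire,dam,sex,generation,litter`;
#' unknown parents and litters written as 0.
#'
#' @param ped An `f2_pedigree`.
#' @param file Path.
#' @return `write_pedigree`: invisibly the path; `read_pedigree`: an
#'   `f2_pedigree`.
#' @export
write_pedigree <- function(ped, file) {
  out <- ped
  out$sire[is.na(out$sire)] <- "0"
  out$dam[is.na(out$dam)] <- "0"
  out$litter[is.na(out$litter)] <- "0"
  write.table(out, file, quote = FALSE, row.names = FALSE, sep = ",")
  invisible(file)
}

#' @rdname write_pedigree
#' @export
read_pedigree <- function(file) {
  ped <- read.table(file, header = TRUE, sep = ",", colClasses = "character")
  for (col in c("sire", "dam", "litter")) {
    ped[[col]][ped[[col]] %in% c("0", "NA", "")] <- NA_character_
  }
  class(ped) <- c("f2_pedigree", "data.frame")
  validate_pedigree(ped)
  ped
}

#' Write / read phased haplotypes
#'
#' One line per haplotype: individual id, haplotype index (1 = paternal),
#' then one 0/1 allele per marker, whitespace-separated.
#'
#' @param hap_pat,hap_mat Individuals x markers 0/1 matrices.
#' @param file Path.
#' @return `write_haplotypes`: invisibly the path; `read_haplotypes`: a
#'   list with `hap_pat`, `hap_mat`.
#' @export
write_haplotypes <- function(hap_pat, hap_mat, file) {
  ids <- rownames(hap_pat)
  lines <- character(2L * length(ids))
  for (i in seq_along(ids)) {
    lines[2 * i - 1] <- paste(ids[i], 1, paste(hap_pat[i, ], collapse = " "))
    lines[2 * i] <- paste(ids[i], 2, paste(hap_mat[i, ], collapse = " "))
  }
  writeLines(lines, file)
  invisible(file)
}

#' @rdname write_haplotypes
#' @export
read_haplotypes <- function(file) {
  tab <- read.table(file, header = FALSE, colClasses = "character")
  ids <- unique(tab[, 1])
  al <- matrix(as.integer(as.matrix(tab[, -(1:2), drop = FALSE])),
               nrow = nrow(tab))
  pat <- al[tab[, 2] == "1", , drop = FALSE]
  mat <- al[tab[, 2] == "2", , drop = FALSE]
  rownames(pat) <- tab[tab[, 2] == "1", 1]
  rownames(mat) <- tab[tab[, 2] == "2", 1]
  list(hap_pat = pat[ids, , drop = FALSE], hap_mat = mat[ids, , drop = FALSE])
}
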