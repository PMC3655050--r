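#' Build a three-generation F2 pedigree
#'
#' Constructs an F0/F1/F2 pedigree of the shape used in F2 resource
#' populations: unrelated F0 boars and sows of two divergent breeds, F1
#' offspring assigned round-robin to the F0 matings, and F2 progeny produced
#' by F1 x F1 matings that avoid full- and half-sib pairs (no mating shares
#' an F0 parent). F2 are grouped into litters of at most `max_litter_size`.
#'
#' Defaults reproduce the study population shape: 4 sire-breed boars, 15
#' dam-breed sows, 56 F1 (6 males, 50 females) and 932 F2.
#'
#' @param n_f0_sires,n_f0_dams Founder counts (breed A males, breed B
#'   females).
#' @param n_f1_males,n_f1_females F1 counts used as F2 parents.
#' @param n_f2 Number of F2 progeny.
#' @param max_litter_size Maximum F2 per litter (litters larger than the
#'   family-unit cap exercise family splitting downstream).
#'
#' @return A `data.frame` of class `f2_pedigree` with columns `id`, `sire`,
#'   `dam`, `sex` ("M"/"F"), `generation` ("F0"/"F1"/"F2") and `litter`
#'   (non-NA for F2 only).
#' @export
#' @examples
#' ped <- build_pedigree()
#' table(ped$generation)
build_pedigree <- function(n_f0_sires = 4, n_f0_dams = 15, n_f1_males = 6,
                           n_f1_females = 50, n_f2 = 932,
                           max_litter_size = 12) {
  stopifnot(n_f0_sires >= 1, n_f0_dams >= 1, n_f1_males >= 1,
            n_f1_females >= 1, n_f2 >= 1, max_litter_size >= 1)
  n_f0 <- n_f0_sires + n_f0_dams
  f0_id <- sprintf("F0_%02d", seq_len(n_f0))
  f0_sires <- f0_id[seq_len(n_f0_sires)]
  f0_dams <- f0_id[n_f0_sires + seq_len(n_f0_dams)]

  # F0 matings: each dam to one sire, round-robin over sires
  pair_sire <- f0_sires[(seq_len(n_f0_dams) - 1L) %% n_f0_sires + 1L]
  n_f1 <- n_f1_males + n_f1_females
  pair_of_f1 <- (seq_len(n_f1) - 1L) %% n_f0_dams + 1L
  f1_id <- sprintf("F1_%02d", seq_len(n_f1))
  f1_sex <- rep(c("M", "F"), c(n_f1_males, n_f1_females))
  f1_sire <- pair_sire[pair_of_f1]
  f1_dam <- f0_dams[pair_of_f1]

  # F1 x F1 matings avoiding shared F0 parents
  males <- which(f1_sex == "M")
  females <- which(f1_sex == "F")
  mate_of <- integer(length(females))
  turn <- 0L
  for (i in seq_along(females)) {
    f <- females[i]
    ok <- males[f1_sire[males] != f1_sire[f] & f1_dam[males] != f1_dam[f]]
    if (length(ok) == 0L) {
      stop("impossible mating constraints: F1 female ", f1_id[f],
           " has no non-sib F1 male available")
    }
    mate_of[i] <- ok[turn %% length(ok) + 1L]
    turn <- turn + 1L
  }

  # F2 assigned round-robin to matings, then chunked into litters
  mating <- (seq_len(n_f2) - 1L) %% length(females) + 1L
  f2_id <- sprintf("F2_%04d", seq_len(n_f2))
  f2_sire <- f1_id[mate_of[mating]]
  f2_dam <- f1_id[females[mating]]
  f2_litter <- character(n_f2)
  for (mi in unique(mating)) {
    idx <- which(mating == mi)
    chunk <- (seq_along(idx) - 1L) %/% max_litter_size + 1L
    f2_litter[idx] <- sprintf("L%02d.%d", mi, chunk)
  }
  ped <- data.frame(
    id = c(f0_id, f1_id, f2_id),
    sire = c(rep(NA_character_, n_f0), f1_sire, f2_sire),
    dam = c(rep(NA_character_, n_f0), f1_dam, f2_dam),
    sex = c(rep("M", n_f0_sires), rep("F", n_f0_dams), f1_sex,
            rep_len(c("M", "F"), n_f2)),
    generation = rep(c("F0", "F1", "F2"), c(n_f0, n_f1, n_f2)),
    litter = c(rep(NA_character_, n_f0 + n_f1), f2_litter),
    stringsAsFactors = FALSE
  )
  class(ped) <- c("f2_pedigree", "data.frame")
  validate_pedigree(ped)
  ped
}

#' Validate the structural invariants of an F2 pedigree
#'
#' Checks generation-wise parentage (F0 founders, F1 from F0, F2 from F1),
#' parental sexes, and that no F2's parents share an F0 parent.
#'
#' @param ped An `f2_pedigree`.
#' @return Invisibly `TRUE`; stops on violation.
#' @export
validate_pedigree <- function(ped) {
  stopifnot(is.data.frame(ped),
            all(c("id", "sire", "dam", "sex", "generation") %in% names(ped)))
  gen <- setNames(ped$generation, ped$id)
  sex <- setNames(ped$sex, ped$id)
  f0 <- ped$generation == "F0"
  if (any(!is.na(ped$sire[f0])) || any(!is.na(ped$dam[f0]))) {
    stop("F0 individuals must have no parents")
  }
  for (g in c("F1", "F2")) {
    pg <- if (g == "F1") "F0" else "F1"
    rows <- ped$generation == g
    if (any(is.na(ped$sire[rows])) || any(is.na(ped$dam[rows]))) {
      stop(g, " individuals must have both parents recorded")
    }
    if (any(gen[ped$sire[rows]] != pg) || any(gen[ped$dam[rows]] != pg)) {
      stop(g, " parents must belong to generation ", pg)
    }
    if (any(sex[ped$sire[rows]] != "M") || any(sex[ped$dam[rows]] != "F")) {
      stop("sires must be male and dams female")
    }
  }
  f2 <- ped[ped$generation == "F2", ]
  if (nrow(f2)) {
    sire_par <- ped[match(f2$sire, ped$id), c("sire", "dam")]
    dam_par <- ped[match(f2$dam, ped$id), c("sire", "dam")]
    shared <- sire_par$sire == dam_par$sire | sire_par$dam == dam_par$dam
    if (any(shared)) stop("full- or half-sib F1 mating detected")
  }
  invisible(TRUE)
}

#' Ids of one generation
#' @param ped An `f2_pedigree`.
#' @param generation "F0", "F1" or "F2".
#' @return Character vector of ids.
#' @export
generation_ids <- function(ped, generation) {
  ped$id[ped$generation == generation]
}
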