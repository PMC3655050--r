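# Shared fixtures and independent oracles, all built in code.

# Small population: 2x2 F0, 2 F1, configurable F2, short map.
small_population <- function(n_f2 = 40, n_snp = 60, length_mb = 30,
                             seed = 11, model = breed_model()) {
  map <- even_map(n_snp, length_mb)
  ped <- build_pedigree(n_f0_sires = 2, n_f0_dams = 2, n_f1_males = 1,
                        n_f1_females = 1, n_f2 = n_f2)
  pop <- simulate_study_population(map, model, ped, seed = seed)
  pop
}

# Mid-size population with the full pedigree shape but a short chromosome,
# for pipeline-level checks at desk scale.
medium_population <- function(n_snp = 150, length_mb = 30, seed = 7) {
  map <- even_map(n_snp, length_mb)
  ped <- build_pedigree(n_f2 = 200)
  simulate_study_population(map, breed_model(), ped, seed = seed)
}

f2_eval_mask <- function(truth_f2, map, tags) {
  non_tag <- !(map$snp %in% tag_ids(tags))
  matrix(rep(non_tag, each = nrow(truth_f2)), nrow = nrow(truth_f2),
         dimnames = dimnames(truth_f2))
}

# Independent forward-backward oracle: enumerate every joint origin path
# of the two gametes and accumulate exact posteriors.
enumerate_child_posterior <- function(g, sire_trans, dam_trans, theta) {
  m <- length(g)
  gam_paths <- as.matrix(expand.grid(rep(list(1:2), m)))
  path_prob <- function(p) 0.5 * prod(ifelse(diff(p) == 0, 1 - theta, theta))
  post <- matrix(0, 4, m)
  q <- matrix(0, 4, m)   # rows: p00, p10, p01, p11 of the allele pair
  tot <- 0
  for (i in seq_len(nrow(gam_paths))) {
    u <- gam_paths[i, ]
    pu <- path_prob(u)
    pa <- sire_trans[cbind(u, seq_len(m))]
    for (j in seq_len(nrow(gam_paths))) {
      v <- gam_paths[j, ]
      pb <- dam_trans[cbind(v, seq_len(m))]
      e00 <- (1 - pa) * (1 - pb); e10 <- pa * (1 - pb)
      e01 <- (1 - pa) * pb; e11 <- pa * pb
      e <- ifelse(is.na(g), 1,
                  ifelse(g == 0, e00, ifelse(g == 1, e10 + e01, e11)))
      w <- pu * path_prob(v) * prod(e)
      if (w == 0) next
      tot <- tot + w
      s <- (u - 1) * 2 + v
      for (k in seq_len(m)) post[s[k], k] <- post[s[k], k] + w
      # allele-pair posterior conditional on the data
      c00 <- ifelse(is.na(g), e00, ifelse(g == 0, 1, 0))
      c10 <- ifelse(is.na(g), e10, ifelse(g == 1, e10 / (e10 + e01), 0))
      c01 <- ifelse(is.na(g), e01, ifelse(g == 1, e01 / (e10 + e01), 0))
      c11 <- ifelse(is.na(g), e11, ifelse(g == 2, 1, 0))
      q <- q + w * rbind(c00, c10, c01, c11)
    }
  }
  list(gamma = post / tot, q = q / tot)
}

# Independent trio-consistency oracle by explicit allele enumeration.
trio_ok_oracle <- function(s, d, c) {
  if (is.na(c)) return(TRUE)
  ts <- if (is.na(s)) 0:1 else unique(c(floor(s / 2), ceiling(s / 2)))
  td <- if (is.na(d)) 0:1 else unique(c(floor(d / 2), ceiling(d / 2)))
  any(outer(ts, td, `+`) == c)
}

# Brute-force minimum LD cover over all non-empty subsets (<= 15 markers).
min_cover_size <- function(covers) {
  n <- ncol(covers)
  poly <- diag(covers)
  for (size in 1:n) {
    for (sel in utils::combn(n, size, simplify = FALSE)) {
      covered <- rowSums(covers[, sel, drop = FALSE]) > 0
      if (all(covered[poly])) return(size)
    }
  }
  n
}
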