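# Brute-force enumeration oracles, independent of the package's summation
# kernels. Feasible only for tiny cohorts; used to pin the analytic code.

# Unrelated cohort: enumerate every placement of n_A alternative alleles
# among the 2N haploid slots (all equally likely), pair consecutive slots
# into diploids, take the first n_affected diploids as affected, and weight
# each allele-count class by theta / n_A.
oracle_unrelated <- function(n_affected, n_controls, mode, x, y, theta) {
  n <- n_affected + n_controls
  total <- 0
  for (n_a in seq_len(2L * n)) {
    placements <- utils::combn(2L * n, n_a)
    pass <- 0L
    for (j in seq_len(ncol(placements))) {
      slot <- integer(2L * n)
      slot[placements[, j]] <- 1L
      g <- slot[c(TRUE, FALSE)] + slot[c(FALSE, TRUE)]
      carrier <- if (mode == "recessive") g == 2L else g >= 1L
      ca <- sum(carrier[seq_len(n_affected)])
      cc <- sum(carrier) - ca
      if (ca >= x && cc <= y) pass <- pass + 1L
    }
    total <- total + theta / n_a * pass / ncol(placements)
  }
  total
}

# Full-sib cohort: enumerate every ordered genotype vector of the N sibs
# (3^N of them), with per-sib probabilities given the parental mating type;
# no multinomial coefficients are used anywhere.
oracle_fullsib <- function(n_affected, n_controls, mode, x, y, theta) {
  mt <- mating_type_expectations(theta)
  n <- n_affected + n_controls
  genos <- as.matrix(expand.grid(rep(list(0:2), n)))
  total <- 0
  for (t in seq_len(nrow(mt))) {
    p <- c(mt$p_rr[t], mt$p_ra[t], mt$p_aa[t])
    for (j in seq_len(nrow(genos))) {
      gv <- genos[j, ]
      prob <- prod(p[gv + 1L])
      if (prob == 0) next
      carrier <- if (mode == "recessive") gv == 2L else gv >= 1L
      ca <- sum(carrier[seq_len(n_affected)])
      cc <- sum(carrier) - ca
      if (ca >= x && cc <= y) total <- total + mt$snv_weight[t] * prob
    }
  }
  total
}
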