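#' Mating-type decomposition of SNV sites segregating in a nuclear family
#'
#' The four founder haplotypes of a nuclear family (two parents) plus the
#' reference sequence are modelled as five haploid exomes randomly sampled
#' from the population. Sites with `n_A` alternative alleles among the four
#' parental haplotypes occur at rate \eqn{\theta / n_A}; splitting the
#' `n_A = 2` class by how the two alternative alleles fall over the two
#' parents (RR x AA versus RA x RA) gives five parental mating types with
#' site rates \eqn{\theta, \theta/6, \theta/3, \theta/3, \theta/4}. Each
#' mating type determines the Mendelian offspring genotype distribution.
#'
#' The rates sum to \eqn{\theta H_4}: only four founder haplotypes carry
#' variation regardless of the number of sibs.
#'
#' @inheritParams expected_sfs_derived
#'
#' @return A data frame with one row per mating type: `label`, `snv_weight`
#'   (expected number of sites of that type), and the offspring genotype
#'   probabilities `p_rr`, `p_ra`, `p_aa`.
#'
#' @examples
#' mating_type_expectations(13333)
#' @export
mating_type_expectations <- function(theta) {
  theta <- as_theta(theta)
  data.frame(
    label = c("RRxRA", "RRxAA", "RAxRA", "RAxAA", "AAxAA"),
    snv_weight = theta * c(1, 1 / 6, 1 / 3, 1 / 3, 1 / 4),
    p_rr = c(1 / 2, 0, 1 / 4, 0, 0),
    p_ra = c(1 / 2, 1, 1 / 2, 1 / 2, 0),
    p_aa = c(0, 0, 1 / 4, 1 / 2, 1),
    stringsAsFactors = FALSE
  )
}

# Mixture bracket: sum over mating types of (weight / theta) times the
# per-sib genotype probabilities raised to the configuration counts, with
# 0^0 = 1 enforced by indicators rather than floating-point pow.
sib_bracket <- function(n_rr, n_ra, n_aa) {
  (n_aa == 0) * 0.5^(n_rr + n_ra) +
    (n_rr + n_aa == 0) / 6 +
    (1 / 3) * 0.5^(2 * n_rr + n_ra + 2 * n_aa) +
    (n_rr == 0) * (1 / 3) * 0.5^(n_ra + n_aa) +
    (n_rr + n_ra == 0) / 4
}

#' Expected number of SNVs showing a given full-sib genotype configuration
#'
#' Expected number of SNV sites at which `N = n_rr + n_ra + n_aa` full-sibs
#' of one nuclear family show exactly `n_rr` RR, `n_ra` RA and `n_aa` AA
#' genotypes. Given the parental mating type, sib genotypes are independent
#' multinomial draws from the Mendelian offspring distribution; the
#' expectation is the mating-type mixture of multinomial probabilities
#' weighted by the [mating_type_expectations()] site rates.
#'
#' @inheritParams expected_count_config
#'
#' @return Expected SNV count for the sib configuration.
#'
#' @examples
#' expected_sib_config(0, 0, 2, theta = 13333)  # 4722.10: both sibs AA
#' @export
expected_sib_config <- function(n_rr, n_ra, n_aa, theta) {
  theta <- as_theta(theta)
  check_count_vector(n_rr, "n_rr")
  check_count_vector(n_ra, "n_ra")
  check_count_vector(n_aa, "n_aa")
  n <- n_rr + n_ra + n_aa
  if (any(n < 1)) stop("at least one sib is required", call. = FALSE)
  coef <- exp(lfactorial(n) - lfactorial(n_rr) - lfactorial(n_ra) -
                lfactorial(n_aa))
  theta * coef * sib_bracket(n_rr, n_ra, n_aa)
}

# All compositions of n into (n_rr, n_ra, n_aa); one row per composition.
# n = 0 yields the single empty composition (0, 0, 0).
sib_compositions <- function(n) {
  n_rr <- unlist(lapply(0:n, function(i) rep.int(i, n - i + 1L)))
  n_ra <- unlist(lapply(0:n, function(i) 0:(n - i)))
  cbind(n_rr = n_rr, n_ra = n_ra, n_aa = n - n_rr - n_ra)
}

#' Expected candidate SNVs after filtering, affected full-sibs only
#'
#' Expected number of SNV sites at which at least `min_affected` of `n`
#' full-sibs are carriers (AA for recessive mode, AA or RA for dominant).
#' Because at most four founder haplotypes segregate, the stringent
#' (`min_affected = n`) expectation does not vanish for large sibships: it
#' converges to \eqn{3\theta/4} in dominant mode (sites where the parents
#' are RR x AA, RA x AA or AA x AA) and \eqn{\theta/4} in recessive mode
#' (AA x AA sites only).
#'
#' @param n Positive integer: number of affected sibs.
#' @inheritParams expected_filtered_no_controls
#'
#' @return Expected number of SNVs passing the filter.
#'
#' @examples
#' expected_sib_filtered_no_controls(100, "dominant", 100, 13333)  # 9999.75
#' @export
expected_sib_filtered_no_controls <- function(n,
                                              mode = c("dominant", "recessive"),
                                              min_affected, theta) {
  mode <- check_mode(mode)
  theta <- as_theta(theta)
  stopifnot(length(n) == 1L)
  check_count_vector(n, "n", minimum = 1L)
  check_count_vector(min_affected, "min_affected")
  if (min_affected > n) {
    warning(sprintf(
      "min_affected = %d exceeds the %d affected sibs; no site can pass",
      min_affected, n), call. = FALSE)
    return(0)
  }
  cfg <- sib_compositions(n)
  carriers <- if (mode == "recessive") cfg[, "n_aa"] else
    cfg[, "n_aa"] + cfg[, "n_ra"]
  keep <- carriers >= min_affected
  sum(expected_sib_config(cfg[keep, "n_rr"], cfg[keep, "n_ra"],
                          cfg[keep, "n_aa"], theta))
}

#' Expected number of SNVs for a split affected/control sib configuration
#'
#' Expected number of SNV sites at which `N_a` affected sibs show the
#' genotype counts `affected = c(n_rr, n_ra, n_aa)` and `N_c` control sibs
#' independently show `control = c(n_rr, n_ra, n_aa)`. Conditional on the
#' parental mating type the two groups are independent multinomials, so the
#' expectation is theta times the product of the two multinomial
#' coefficients times the mating-type mixture evaluated at the pooled
#' genotype counts.
#'
#' With an empty control triple this reduces exactly to
#' [expected_sib_config()].
#'
#' @param affected Integer triple `(n_rr, n_ra, n_aa)` for the affected sibs.
#' @param control Integer triple `(n_rr, n_ra, n_aa)` for the control sibs.
#' @inheritParams expected_sfs_derived
#'
#' @return Expected SNV count for the split configuration.
#'
#' @examples
#' ## one affected and one control sib, both AA
#' expected_sib_split_config(c(0, 0, 1), c(0, 0, 1), theta = 13333)  # 1944.40
#' @export
expected_sib_split_config <- function(affected, control = c(0L, 0L, 0L),
                                      theta) {
  theta <- as_theta(theta)
  if (length(affected) != 3L || length(control) != 3L) {
    stop("'affected' and 'control' must be triples (n_rr, n_ra, n_aa)",
         call. = FALSE)
  }
  check_count_vector(affected, "affected")
  check_count_vector(control, "control")
  if (sum(affected) < 1L) {
    stop("at least one affected sib is required", call. = FALSE)
  }
  lmult <- function(x) lfactorial(sum(x)) - sum(lfactorial(x))
  pooled <- affected + control
  theta * exp(lmult(affected) + lmult(control)) *
    sib_bracket(pooled[1L], pooled[2L], pooled[3L])
}

#' Expected candidate SNVs after case/control filtering, full-sib cohort
#'
#' Expected number of SNV sites retained by the joint filter "at least
#' `min_affected` of `n_affected` affected sibs are carriers AND at most
#' `max_controls` of `n_controls` control sibs are carriers" in a single
#' sibship. Sums [expected_sib_split_config()] over all pairs of affected
#' and control genotype compositions satisfying the filter.
#'
#' @param n_affected Positive integer: affected sibs `N_a`.
#' @param n_controls Nonnegative integer: control sibs `N_c`.
#' @inheritParams expected_filtered_casecontrol
#'
#' @return Expected number of SNVs passing the joint filter.
#'
#' @examples
#' expected_sib_filtered_casecontrol(10, 10, "dominant", 8, 2, 13333)  # 40.85
#' @export
expected_sib_filtered_casecontrol <- function(n_affected, n_controls,
                                              mode = c("dominant", "recessive"),
                                              min_affected, max_controls,
                                              theta) {
  mode <- check_mode(mode)
  theta <- as_theta(theta)
  check_count_vector(n_affected, "n_affected", minimum = 1L)
  check_count_vector(n_controls, "n_controls")
  check_count_vector(min_affected, "min_affected")
  check_count_vector(max_controls, "max_controls")
  if (min_affected > n_affected) {
    warning(sprintf(
      "min_affected = %d exceeds the %d affected sibs; no site can pass",
      min_affected, n_affected), call. = FALSE)
    return(0)
  }
  y <- min(max_controls, n_controls)

  carriers_of <- function(cfg) {
    if (mode == "recessive") cfg[, "n_aa"] else cfg[, "n_aa"] + cfg[, "n_ra"]
  }
  cfg_a <- sib_compositions(n_affected)
  cfg_a <- cfg_a[carriers_of(cfg_a) >= min_affected, , drop = FALSE]
  cfg_c <- sib_compositions(n_controls)
  cfg_c <- cfg_c[carriers_of(cfg_c) <= y, , drop = FALSE]
  if (nrow(cfg_a) == 0L || nrow(cfg_c) == 0L) return(0)

  lmult <- function(cfg) {
    lfactorial(rowSums(cfg)) - lfactorial(cfg[, 1L]) -
      lfactorial(cfg[, 2L]) - lfactorial(cfg[, 3L])
  }
  la <- lmult(cfg_a)
  lc <- lmult(cfg_c)
  ia <- rep(seq_len(nrow(cfg_a)), times = nrow(cfg_c))
  ic <- rep(seq_len(nrow(cfg_c)), each = nrow(cfg_a))
  bracket <- sib_bracket(cfg_a[ia, "n_rr"] + cfg_c[ic, "n_rr"],
                         cfg_a[ia, "n_ra"] + cfg_c[ic, "n_ra"],
                         cfg_a[ia, "n_aa"] + cfg_c[ic, "n_aa"])
  theta * sum(exp(la[ia] + lc[ic]) * bracket)
}
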