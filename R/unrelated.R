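#' Probability of a genotype configuration given the alternative allele count
#'
#' For `N` unrelated diploid individuals formed by randomly pairing `2N`
#' haploid sequences that carry `n_A` alternative alleles in total, the
#' probability that the genotype counts are `(n_RR, n_RA, n_AA)` is
#' \deqn{P(n_{RR}, n_{RA}, n_{AA} \mid n_A) =
#'   \frac{2^{n_{RA}} N!}{n_{RR}!\, n_{RA}!\, n_{AA}!} \cdot
#'   \frac{n_R!\, n_A!}{(2N)!},}
#' the distribution underlying the exact test of Hardy-Weinberg equilibrium.
#' Here `n_A = 2 n_AA + n_RA`, `n_R = 2 n_RR + n_RA` and
#' `N = n_RR + n_RA + n_AA`.
#'
#' @param n_rr,n_ra,n_aa Nonnegative integers: number of individuals with
#'   genotype RR (homozygous reference), RA (heterozygous) and AA (homozygous
#'   alternative).
#'
#' @return The configuration probability; configurations sharing the same
#'   `n_A` sum to 1.
#'
#' @examples
#' genotype_config_prob(0, 2, 0)  # 2/3: both of 2 individuals heterozygous
#' genotype_config_prob(1, 0, 1)  # 1/3
#' @export
genotype_config_prob <- function(n_rr, n_ra, n_aa) {
  check_count_vector(n_rr, "n_rr")
  check_count_vector(n_ra, "n_ra")
  check_count_vector(n_aa, "n_aa")
  n <- n_rr + n_ra + n_aa
  if (any(n < 1)) stop("at least one individual is required", call. = FALSE)
  n_a <- 2 * n_aa + n_ra
  n_r <- 2 * n_rr + n_ra
  exp(n_ra * log(2) +
        lfactorial(n) - lfactorial(n_rr) - lfactorial(n_ra) - lfactorial(n_aa) +
        lfactorial(n_r) + lfactorial(n_a) - lfactorial(2 * n))
}

#' Expected number of SNVs showing a given genotype configuration
#'
#' Expected number of exome SNV sites at which `N = n_rr + n_ra + n_aa`
#' unrelated individuals show exactly the genotype counts
#' `(n_rr, n_ra, n_aa)`. By the law of total expectation this factorises as
#' the expected number of sites with `n_A` alternative alleles,
#' \eqn{\theta / n_A}, times the configuration probability
#' [genotype_config_prob()].
#'
#' Configurations with `n_A = 0` (no alternative allele anywhere) are not SNV
#' sites and are rejected.
#'
#' @inheritParams genotype_config_prob
#' @inheritParams expected_sfs_derived
#'
#' @return Expected SNV count for the configuration.
#'
#' @examples
#' ## both of two individuals homozygous-alternative
#' expected_count_config(0, 0, 2, theta = 13333)  # 3333.25
#' @export
expected_count_config <- function(n_rr, n_ra, n_aa, theta) {
  theta <- as_theta(theta)
  p <- genotype_config_prob(n_rr, n_ra, n_aa)
  n_a <- 2 * n_aa + n_ra
  if (any(n_a < 1)) {
    stop("configuration has no alternative allele (n_A = 0); not an SNV site",
         call. = FALSE)
  }
  (theta / n_a) * p
}

# Log-space kernel, recessive parameterisation: expected count of sites with
# n_a alternative alleles and n_aa homozygous-alternative individuals among N.
# Admissible: max(0, n_a - N) <= n_aa <= floor(n_a / 2), n_aa <= N.
kernel_recessive <- function(n, n_a, n_aa, theta) {
  theta / n_a * exp(
    (n_a - 2 * n_aa) * log(2) +
      lfactorial(n) - lfactorial(n - n_a + n_aa) -
      lfactorial(n_a - 2 * n_aa) - lfactorial(n_aa) +
      lfactorial(2 * n - n_a) + lfactorial(n_a) - lfactorial(2 * n)
  )
}

# Dominant parameterisation: d = n_{AA+RA} carriers among N at a site with
# n_a alternative alleles. Admissible: ceil(n_a / 2) <= d <= min(n_a, N).
kernel_dominant <- function(n, n_a, d, theta) {
  theta / n_a * exp(
    (2 * d - n_a) * log(2) +
      lfactorial(n) - lfactorial(n - d) -
      lfactorial(2 * d - n_a) - lfactorial(n_a - d) +
      lfactorial(2 * n - n_a) + lfactorial(n_a) - lfactorial(2 * n)
  )
}

check_mode <- function(mode) {
  match.arg(mode, c("dominant", "recessive"))
}

# Admissible (n_a, carrier-count) grid for one value of n_a.
carrier_range <- function(n, n_a, mode) {
  if (mode == "recessive") {
    seq2(max(0L, n_a - n), n_a %/% 2L)
  } else {
    seq2(ceiling(n_a / 2), min(n_a, n))
  }
}

# seq(from, to) that is empty when from > to.
seq2 <- function(from, to) {
  if (from > to) integer(0) else seq.int(from, to)
}

#' Expected candidate SNVs after filtering, affected individuals only
#'
#' Expected number of SNV sites at which at least `min_affected` of `n`
#' unrelated affected individuals are carriers: genotype AA for a recessive
#' disease, AA or RA for a dominant disease. The sum runs over all admissible
#' (alternative allele count, carrier count) pairs; with `min_affected = 0`
#' no site is removed and the result is the spectrum total
#' \eqn{\theta H_{2N}} (harmonic number).
#'
#' A threshold exceeding `n` cannot be met by any configuration; the function
#' warns and returns 0.
#'
#' @param n Positive integer: number of unrelated affected individuals.
#' @param mode `"dominant"` or `"recessive"`.
#' @param min_affected Nonnegative integer `X`: minimum number of affected
#'   carriers a site must show to be retained.
#' @inheritParams expected_sfs_derived
#'
#' @return Expected number of SNVs passing the filter.
#'
#' @examples
#' expected_filtered_no_controls(2, "dominant", 2, theta = 13333)    # 12221.92
#' expected_filtered_no_controls(100, "recessive", 100, 13333)       # 66.67
#' @export
expected_filtered_no_controls <- function(n, mode = c("dominant", "recessive"),
                                          min_affected, theta) {
  mode <- check_mode(mode)
  theta <- as_theta(theta)
  stopifnot(length(n) == 1L)
  check_count_vector(n, "n", minimum = 1L)
  check_count_vector(min_affected, "min_affected")
  if (min_affected > n) {
    warning(sprintf(
      "min_affected = %d exceeds the %d affected individuals; no site can pass",
      min_affected, n), call. = FALSE)
    return(0)
  }
  total <- 0
  for (n_a in seq_len(2L * n)) {
    cc <- carrier_range(n, n_a, mode)
    cc <- cc[cc >= min_affected]
    if (length(cc) == 0L) next
    total <- total + sum(
      if (mode == "recessive") kernel_recessive(n, n_a, cc, theta)
      else kernel_dominant(n, n_a, cc, theta)
    )
  }
  total
}

#' Hypergeometric split of carriers between affected and control individuals
#'
#' When `n_affected` of `n_total` unrelated individuals are designated
#' affected at random, the number of carriers falling among the affected,
#' given `n_carriers_total` carriers overall, follows a hypergeometric
#' distribution:
#' \deqn{P(a) = \binom{c}{a} \binom{N - c}{N_a - a} \Big/ \binom{N}{N_a}.}
#'
#' @param n_carriers_total Nonnegative integer `c`: carriers among all
#'   `n_total` individuals.
#' @param n_carriers_affected Nonnegative integer `a`: carriers among the
#'   affected.
#' @param n_total Positive integer `N`.
#' @param n_affected Positive integer `N_a`, at most `n_total`.
#'
#' @return The split probability; over admissible `a` the values sum to 1.
#'
#' @examples
#' casecontrol_split_prob(2, 2, 4, 2)  # 1/6
#' @export
casecontrol_split_prob <- function(n_carriers_total, n_carriers_affected,
                                   n_total, n_affected) {
  check_count_vector(n_carriers_total, "n_carriers_total")
  check_count_vector(n_carriers_affected, "n_carriers_affected")
  check_count_vector(n_total, "n_total", minimum = 1L)
  check_count_vector(n_affected, "n_affected", minimum = 1L)
  if (any(n_affected > n_total) || any(n_carriers_total > n_total)) {
    stop("'n_affected' and 'n_carriers_total' may not exceed 'n_total'",
         call. = FALSE)
  }
  if (any(n_carriers_affected > pmin(n_carriers_total, n_affected)) ||
      any(n_carriers_total - n_carriers_affected > n_total - n_affected)) {
    stop("inadmissible carrier split", call. = FALSE)
  }
  exp(lchoose(n_carriers_total, n_carriers_affected) +
        lchoose(n_total - n_carriers_total, n_affected - n_carriers_affected) -
        lchoose(n_total, n_affected))
}

#' Expected candidate SNVs after case/control filtering, unrelated cohort
#'
#' Expected number of SNV sites retained by the joint filter "at least
#' `min_affected` of `n_affected` affected individuals are carriers AND at
#' most `max_controls` of `n_controls` control individuals are carriers", for
#' `N = n_affected + n_controls` unrelated individuals. Carrier means AA for
#' recessive mode and AA-or-RA for dominant mode.
#'
#' The expectation decomposes as (expected sites with a given total carrier
#' count) times (hypergeometric probability that the carriers split
#' admissibly between affected and controls), summed over the filter-passing
#' region. With `n_controls = 0` the result reduces exactly to
#' [expected_filtered_no_controls()].
#'
#' @param n_affected Positive integer: affected individuals `N_a`.
#' @param n_controls Nonnegative integer: control individuals `N_c`.
#' @param max_controls Nonnegative integer `Y`: maximum number of control
#'   carriers tolerated; values above `n_controls` are clamped (no
#'   constraint).
#' @inheritParams expected_filtered_no_controls
#'
#' @return Expected number of SNVs passing the joint filter.
#'
#' @examples
#' ## 9 affected + 1 control, all affected must carry, the control must not
#' expected_filtered_casecontrol(9, 1, "dominant", 9, 0, theta = 13333)
#' @export
expected_filtered_casecontrol <- function(n_affected, n_controls,
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
      "min_affected = %d exceeds the %d affected individuals; no site can pass",
      min_affected, n_affected), call. = FALSE)
    return(0)
  }
  if (n_controls == 0L) {
    return(expected_filtered_no_controls(n_affected, mode, min_affected, theta))
  }
  y <- min(max_controls, n_controls)
  n <- n_affected + n_controls
  total <- 0
  for (n_a in seq_len(2L * n)) {
    for (cc in carrier_range(n, n_a, mode)) {
      ## carriers among affected: admissible and filter-passing range
      a_lo <- max(min_affected, cc - n_controls, cc - y)
      a_hi <- min(cc, n_affected)
      if (a_lo > a_hi) next
      a <- seq2(a_lo, a_hi)
      kern <- if (mode == "recessive") kernel_recessive(n, n_a, cc, theta)
              else kernel_dominant(n, n_a, cc, theta)
      total <- total + kern *
        sum(casecontrol_split_prob(cc, a, n, n_affected))
    }
  }
  total
}

#' Closed form for the stringent recessive filter
#'
#' When all `n` affected individuals must be homozygous-alternative, the only
#' contributing sites are those where every one of the `2n` sampled alleles
#' is alternative, so the expected count is simply \eqn{\theta / (2N)} -- the
#' `n_A = 2N` entry of the alternative-allele spectrum.
#'
#' @inheritParams expected_filtered_no_controls
#' @return `theta / (2 * n)`.
#' @examples
#' closed_form_recessive_stringent(100, 13333)  # 66.665
#' @export
closed_form_recessive_stringent <- function(n, theta) {
  theta <- as_theta(theta)
  check_count_vector(n, "n", minimum = 1L)
  theta / (2 * n)
}

#' Closed form for the stringent dominant filter
#'
#' When all `n` affected individuals must carry at least one alternative
#' allele, the carrier count equals `n` and the filtered expectation reduces
#' to the single-slice sum
#' \deqn{\sum_{n_A = N}^{2N} \frac{\theta}{n_A}\, 2^{2N - n_A}
#'   \frac{N!\, n_A!}{(n_A - N)!\, (2N)!}.}
#' This equals [expected_filtered_no_controls()] with
#' `min_affected = n` in dominant mode.
#'
#' @inheritParams expected_filtered_no_controls
#' @return Expected SNV count under the 100\% dominant filter.
#' @examples
#' closed_form_dominant_stringent(2, 13333)  # 12221.92
#' @export
closed_form_dominant_stringent <- function(n, theta) {
  theta <- as_theta(theta)
  check_count_vector(n, "n", minimum = 1L)
  n_a <- seq.int(n, 2L * n)
  sum(kernel_dominant(n, n_a, n, theta))
}
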