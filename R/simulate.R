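#' Monte-Carlo check of the unrelated-cohort expectations
#'
#' Simulates the sampling model behind the analytic expectations for
#' unrelated individuals and reports the Monte-Carlo mean number of sites
#' passing the filter. Per replicate, for every alternative allele count
#' `n_A` in `1..2N` a Poisson(\eqn{\theta / n_A}) number of independent sites
#' is drawn (the infinite-sites expectation is a rate over independent
#' sites); at each site the `n_A` alternative alleles are placed uniformly at
#' random among the `2N` haploid slots, consecutive slots are paired into
#' diploid individuals, the first `n_affected` individuals are labelled
#' affected (the placement is exchangeable, so this equals a uniform random
#' labelling), and the site is counted if it passes the carrier filter.
#'
#' The random placement is generated slot-pair by slot-pair as sequential
#' hypergeometric urn draws, which samples the uniform placement exactly
#' without ever evaluating the analytic configuration probability.
#'
#' Allele-count classes that cannot contain a passing site (`n_A <
#' min_affected` in dominant mode, `n_A < 2 * min_affected` in recessive
#' mode, since a carrier needs at least one / two alternative alleles) are
#' skipped when `prune = TRUE`; such sites contribute exactly zero to the
#' passing count, so the mean and standard error are unchanged. Set `prune =
#' FALSE` to simulate every class, e.g. when checking total site counts.
#'
#' @inheritParams expected_filtered_casecontrol
#' @param replicates Positive integer: number of independent replicates.
#' @param seed Integer: base seed. Replicate `r` uses its own RNG stream
#'   seeded with `seed + r`, so results are identical for identical
#'   `(arguments, seed)` and independent of execution order.
#' @param prune Logical: skip allele-count classes that provably cannot
#'   yield a passing site (default `TRUE`).
#'
#' @return An object of class `"snv_sim"`: list with `mean_count`,
#'   `std_error` (sample SD over replicates / sqrt(replicates)),
#'   `replicates`, `seed`, and `mean_total_sites` (mean number of simulated
#'   sites per replicate, for spectrum-total checks).
#'
#' @examples
#' sim <- simulate_unrelated(2, 0, "dominant", 2, theta = 13333,
#'                           replicates = 50, seed = 1)
#' sim$mean_count  # close to 12221.92
#' @export
simulate_unrelated <- function(n_affected, n_controls = 0L,
                               mode = c("dominant", "recessive"),
                               min_affected, max_controls = n_controls,
                               theta, replicates = 2000L, seed = 1L,
                               prune = TRUE) {
  mode <- check_mode(mode)
  theta <- as_theta(theta)
  check_count_vector(n_affected, "n_affected", minimum = 1L)
  check_count_vector(n_controls, "n_controls")
  check_count_vector(min_affected, "min_affected")
  check_count_vector(max_controls, "max_controls")
  check_count_vector(replicates, "replicates", minimum = 1L)
  n <- n_affected + n_controls
  y <- if (n_controls > 0L) min(max_controls, n_controls) else n_controls
  min_alt <- if (!prune) 1L else
    max(1L, if (mode == "recessive") 2L * min_affected else min_affected)

  classes <- seq2(min_alt, 2L * n)
  counts <- numeric(replicates)
  sites <- numeric(replicates)
  for (r in seq_len(replicates)) {
    set.seed(seed + r)
    m <- stats::rpois(length(classes), theta / classes)
    alt <- rep.int(classes, m)              # remaining alt alleles per site
    sites[r] <- length(alt)
    if (length(alt) == 0L) next
    slots <- 2L * n                          # remaining haploid slots
    carriers_a <- integer(length(alt))
    carriers_c <- integer(length(alt))
    for (ind in seq_len(n)) {
      g <- stats::rhyper(length(alt), alt, slots - alt, 2L)
      alt <- alt - g
      slots <- slots - 2L
      carrier <- if (mode == "recessive") g == 2L else g >= 1L
      if (ind <= n_affected) {
        carriers_a <- carriers_a + carrier
      } else {
        carriers_c <- carriers_c + carrier
      }
    }
    counts[r] <- sum(carriers_a >= min_affected & carriers_c <= y)
  }
  new_snv_sim(counts, sites, replicates, seed)
}

#' Monte-Carlo check of the full-sib expectations
#'
#' Simulates the nuclear-family sampling model: per replicate, for each of
#' the five parental mating types a Poisson number of sites is drawn with the
#' [mating_type_expectations()] rate, then the genotypes of `n_affected`
#' affected and `n_controls` control sibs are drawn independently from the
#' Mendelian offspring distribution of that mating type, and the site is
#' counted if it passes the carrier filter.
#'
#' When `prune = TRUE`, mating types whose offspring distribution gives the
#' carrier genotype probability zero are skipped whenever `min_affected >=
#' 1` (none of their sites can pass); means and standard errors are
#' unaffected.
#'
#' @inheritParams simulate_unrelated
#' @return An object of class `"snv_sim"`; see [simulate_unrelated()].
#'
#' @examples
#' sim <- simulate_fullsib(2, 0, "recessive", 2, theta = 13333,
#'                         replicates = 50, seed = 1)
#' sim$mean_count  # close to 4722.10
#' @export
simulate_fullsib <- function(n_affected, n_controls = 0L,
                             mode = c("dominant", "recessive"),
                             min_affected, max_controls = n_controls,
                             theta, replicates = 2000L, seed = 1L,
                             prune = TRUE) {
  mode <- check_mode(mode)
  theta <- as_theta(theta)
  check_count_vector(n_affected, "n_affected", minimum = 1L)
  check_count_vector(n_controls, "n_controls")
  check_count_vector(min_affected, "min_affected")
  check_count_vector(max_controls, "max_controls")
  check_count_vector(replicates, "replicates", minimum = 1L)
  y <- if (n_controls > 0L) min(max_controls, n_controls) else n_controls

  mt <- mating_type_expectations(theta)
  p_carrier <- if (mode == "recessive") mt$p_aa else mt$p_aa + mt$p_ra
  use <- if (prune && min_affected >= 1L) p_carrier > 0 else
    rep(TRUE, nrow(mt))

  counts <- numeric(replicates)
  sites <- numeric(replicates)
  for (r in seq_len(replicates)) {
    set.seed(seed + r)
    pass <- 0L
    for (t in which(use)) {
      m <- stats::rpois(1L, mt$snv_weight[t])
      sites[r] <- sites[r] + m
      if (m == 0L) next
      p <- c(mt$p_rr[t], mt$p_ra[t], mt$p_aa[t])
      ga <- stats::rmultinom(m, n_affected, p)
      ca <- if (mode == "recessive") ga[3L, ] else ga[2L, ] + ga[3L, ]
      if (n_controls > 0L) {
        gc <- stats::rmultinom(m, n_controls, p)
        cc <- if (mode == "recessive") gc[3L, ] else gc[2L, ] + gc[3L, ]
      } else {
        cc <- 0L
      }
      pass <- pass + sum(ca >= min_affected & cc <= y)
    }
    counts[r] <- pass
  }
  new_snv_sim(counts, sites, replicates, seed)
}

new_snv_sim <- function(counts, sites, replicates, seed) {
  structure(
    list(mean_count = mean(counts),
         std_error = stats::sd(counts) / sqrt(replicates),
         replicates = replicates,
         seed = seed,
         mean_total_sites = mean(sites)),
    class = "snv_sim"
  )
}

#' @export
print.snv_sim <- function(x, ...) {
  cat("Monte-Carlo SNV count\n")
  cat(sprintf("  mean  : %.4f\n", x$mean_count))
  cat(sprintf("  SE    : %.4f\n", x$std_error))
  cat(sprintf("  reps  : %d (seed %d)\n", x$replicates, x$seed))
  invisible(x)
}
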