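#' Estimate the exome-wide scaled mutation rate theta
#'
#' Estimates the scaled mutation rate \eqn{\theta = 4 \times PopSize \times
#' \mu} for the whole exome mutational target from the number of SNVs observed
#' in a single diploid exome. One diploid exome corresponds to a sample of
#' \eqn{n = 2} haploid sequences, so the expected number of sites carrying at
#' least one alternative allele is \eqn{E[M'_1] + E[M'_2] = \theta + \theta/2
#' = 3\theta/2}. Setting this equal to the observed count \eqn{S} gives the
#' moment estimator \eqn{\hat\theta = 2S/3}.
#'
#' The default reporting convention truncates \eqn{2S/3} toward zero to an
#' integer, so that 20,000 SNVs per exome yields \eqn{\hat\theta = 13{,}333}
#' (not 13,333.33). The untruncated estimate is always retained in the
#' returned object.
#'
#' @param snvs_per_exome Positive number: observed count of heterozygous plus
#'   homozygous-alternative SNV sites in one diploid exome. Roughly 20,000 for
#'   a human exome.
#'
#' @return An object of class `"theta_model"`: a list with elements
#'   \describe{
#'     \item{`theta`}{the integer-truncated estimate `trunc(2 * S / 3)`,}
#'     \item{`theta_exact`}{the untruncated estimate `2 * S / 3`,}
#'     \item{`snvs_per_exome`}{the input `S`.}
#'   }
#'
#' @examples
#' estimate_theta(20000)          # theta = 13333
#' estimate_theta(30000)$theta    # 20000 (2S/3 already integral)
#'
#' @seealso [expected_sfs_alternative()] for the spectrum the estimator
#'   inverts.
#' @export
estimate_theta <- function(snvs_per_exome) {
  if (!is.numeric(snvs_per_exome) || length(snvs_per_exome) != 1L ||
      !is.finite(snvs_per_exome) || snvs_per_exome <= 0) {
    stop("'snvs_per_exome' must be a single positive number", call. = FALSE)
  }
  exact <- 2 * snvs_per_exome / 3
  structure(
    list(theta = trunc(exact), theta_exact = exact,
         snvs_per_exome = snvs_per_exome),
    class = "theta_model"
  )
}

#' @export
print.theta_model <- function(x, ...) {
  cat("Scaled mutation rate estimate (theta = 4 * PopSize * mu)\n")
  cat(sprintf("  SNVs per diploid exome (S): %g\n", x$snvs_per_exome))
  cat(sprintf("  theta (truncated 2S/3):     %g\n", x$theta))
  cat(sprintf("  theta (exact 2S/3):         %.6g\n", x$theta_exact))
  invisible(x)
}

# Accept either a bare nonnegative number or a theta_model.
as_theta <- function(theta) {
  if (inherits(theta, "theta_model")) theta <- theta$theta
  if (!is.numeric(theta) || length(theta) != 1L || !is.finite(theta) ||
      theta < 0) {
    stop("'theta' must be a single nonnegative number or a theta_model",
         call. = FALSE)
  }
  as.numeric(theta)
}

#' Expected site frequency spectrum of the derived allele
#'
#' Under the neutral Wright-Fisher infinite-sites model, the expected number
#' of segregating sites at which `i` of `n` sampled haploid sequences carry
#' the mutant (derived) allele is \eqn{E[M_i] = \theta / i}, for
#' \eqn{1 \le i \le n - 1}. The formula does not involve the sample size `n`.
#'
#' @param i Positive integer (vectorised): derived allele count.
#' @param theta Nonnegative scaled mutation rate, or a
#'   [`theta_model`][estimate_theta] object.
#'
#' @return Expected SNV count(s) `theta / i`.
#'
#' @examples
#' expected_sfs_derived(1:3, 13333)  # 13333.00 6666.50 4444.33
#' @export
expected_sfs_derived <- function(i, theta) {
  theta <- as_theta(theta)
  check_count_vector(i, "i", minimum = 1L)
  theta / i
}

#' Expected site frequency spectrum in reference/alternative coordinates
#'
#' In exome analysis the mutant/ancestral status of an allele is unknown;
#' sites are recorded as reference (R, matching the reference genome) versus
#' alternative (A). Treating the reference sequence as one extra haploid
#' sequence randomly sampled from the same population, the expected number of
#' sites at which `n_alt` of `n` sampled haploid sequences carry the
#' alternative allele is again \eqn{\theta / n_{alt}} -- identical in form to
#' the derived spectrum, but valid up to `n_alt = n` (all sampled alleles may
#' differ from the reference).
#'
#' @param n_alt Positive integer (vectorised): alternative allele count; may
#'   equal the haploid sample size.
#' @inheritParams expected_sfs_derived
#'
#' @return Expected SNV count(s) `theta / n_alt`.
#'
#' @examples
#' ## expected SNVs seen in one diploid exome: theta * (1 + 1/2) = 3 theta / 2
#' sum(expected_sfs_alternative(1:2, 13333))
#' @export
expected_sfs_alternative <- function(n_alt, theta) {
  theta <- as_theta(theta)
  check_count_vector(n_alt, "n_alt", minimum = 1L)
  theta / n_alt
}

# Shared argument validation: vector of integers >= minimum.
check_count_vector <- function(x, name, minimum = 0L) {
  if (!is.numeric(x) || length(x) < 1L || anyNA(x) ||
      any(x != floor(x)) || any(x < minimum)) {
    stop(sprintf("'%s' must contain integers >= %d", name, minimum),
         call. = FALSE)
  }
  invisible(x)
}

# Harmonic number H_n = 1 + 1/2 + ... + 1/n; H_0 = 0.
harmonic <- function(n) {
  if (n == 0) return(0)
  sum(1 / seq_len(n))
}
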