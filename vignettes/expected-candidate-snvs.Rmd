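---
title: "Expected candidate SNV counts under genotype filtering: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Expected candidate SNV counts under genotype filtering: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snvexpect)
```

## The question the package answers

A genotype filter for a Mendelian exome study keeps a variant site when at
least $X$ of $N_a$ affected individuals are carriers and at most $Y$ of
$N_c$ controls are. "Carrier" means homozygous-alternative (AA) for a
recessive disease and AA-or-heterozygous (AA/RA) for a dominant one. Under
the assumption of *no genetic heterogeneity* — one causal variant, so every
other variant is independent of phenotype — the number of non-causal sites
surviving the filter is a random variable whose expectation this package
computes exactly. That expectation is the figure of merit for study design:
it tells you how long the candidate list will be before any biological
prioritisation.

## Model and assumptions

**Site frequency spectrum.** The exome is modelled as an infinite-sites
mutational target evolving under neutral Wright–Fisher dynamics at constant
population size. For $n$ haploid sequences sampled from the population, the
expected number of sites with $i$ derived alleles is $E[M_i] = \theta/i$,
$1 \le i \le n-1$, with $\theta = 4 \cdot PopSize \cdot \mu$. Because exome
pipelines call variants against a reference genome rather than an ancestral
state, the package works in reference/alternative coordinates: treating the
reference as one extra haploid sample from the same population and summing
the two ways a site can arise (reference allele mutant or ancestral) gives
$E[M'_{n_A}] = \theta/n_A$ for $1 \le n_A \le n$ — the same form, now valid
when *all* sampled alleles differ from the reference.

**Unrelated cohorts.** $N$ diploids are $2N$ haploid samples randomly paired.
Conditional on $n_A$ alternative alleles at a site, the genotype counts
$(n_{RR}, n_{RA}, n_{AA})$ follow the Hardy–Weinberg-exact distribution
$$P(n_{RR}, n_{RA}, n_{AA} \mid n_A) = \frac{2^{n_{RA}} N!}
{n_{RR}!\,n_{RA}!\,n_{AA}!} \cdot \frac{n_R!\,n_A!}{(2N)!},$$
and the expected number of sites showing a configuration is $\theta/n_A$
times that probability. Filtered expectations sum this kernel over the
admissible region; when the cohort splits into affected and controls, the
carrier count splits hypergeometrically because the labelling is independent
of genotype (every non-causal site is a null site).

**Full-sib cohorts.** For $N$ sibs in one nuclear family, only the four
parental haplotypes (plus the reference, for coordinates) are population
samples. Sites decompose by parental mating type — RR×RA, RR×AA, RA×RA,
RA×AA, AA×AA — with expected counts $\theta, \theta/6, \theta/3, \theta/3,
\theta/4$. The $n_A=2$ frequency class ($\theta/2$) splits into RR×AA
($\theta/6$) and RA×RA ($\theta/3$) according to the random pairing of
$\{R,R,A,A\}$ into two parents. Given the mating type, sib genotypes are
i.i.d. Mendelian draws, so genotype counts are multinomial, and affected and
control sibs are independent multinomials. The mating-type rates sum to
$\theta H_4$: a sibship of any size only ever exposes four founder
haplotypes, which is why sib-only filtering saturates — the stringent
dominant filter converges to $\theta/6 + \theta/3 + \theta/4 = 3\theta/4$
(mating types whose offspring are all carriers) and the recessive one to
$\theta/4$ (AA×AA only), instead of decaying to zero as for unrelated
cohorts.

**What is deliberately not modelled.** Population growth, selection against
non-synonymous variants, and the mosaic ancestry of the reference sequence
all skew real spectra toward rare variants; no skewed-spectrum option is
provided, so the computed counts are smooth-model baselines. Public-database
filtering (dbSNP, 1000 Genomes), genetic heterogeneity and gene-level
aggregation, and pedigrees other than a single sibship are out of scope.
Penetrance and phenocopy are not modelled mechanistically; they are absorbed
into the thresholds $X$ and $Y$, which is exactly how practitioners loosen
filters.

## Parameters

| parameter | meaning | default / rationale |
|---|---|---|
| `theta` | exome-wide scaled mutation rate $4 \cdot PopSize \cdot \mu$ (sites) | 13,333 in the CLI and `expected_snvs()`, from $3\theta/2 = 20{,}000$ SNVs per diploid exome |
| `snvs_per_exome` | observed SNVs in one diploid exome, input to `estimate_theta()` | no default; ~20,000 for humans, but capture, calling and ancestry shift it |
| `min_affected` ($X$) | minimum affected carriers | required; $X = N_a$ is the stringent filter |
| `max_controls` ($Y$) | maximum control carriers | 0 (no carrier tolerated) when controls are present |
| `min_affected_frac`, `max_controls_frac` | fractional thresholds | resolved as $X = \lceil p_a N_a \rceil$, $Y = \lfloor p_c N_c \rfloor$ |
| `replicates`, `seed` | Monte-Carlo effort and reproducibility | 2,000 replicates resolve the analytic values to a fraction of a percent |

`estimate_theta()` truncates $2S/3$ toward zero by default (13,333, not
13,333.33) because every published reference value is consistent with the
truncated estimate — e.g. the no-filter single-exome total prints as
$3\theta/2 = 19{,}999.50$; the untruncated value is kept in the returned
object for exact work.

## Numerical choices

* **Log-gamma arithmetic.** Every multinomial/hypergeometric coefficient is
  assembled in log space via `lfactorial()`/`lchoose()` and exponentiated
  once per term. At $N \le 200$ haploids the error is orders of magnitude
  below the 0.01 at which results are read; probability normalisations hold
  to $10^{-12}$ in the tests.
* **Enumeration bounds.** For a site with $n_A$ alternative alleles among
  $2N$, the admissible carrier counts are $\max(0, n_A - N) \le n_{AA} \le
  \lfloor n_A/2 \rfloor$ (recessive) and $\lceil n_A/2 \rceil \le
  n_{AA+RA} \le \min(n_A, N)$ (dominant); these are provably the
  configurations with nonnegative genotype counts, and brute-force
  enumeration over all allele placements confirms the sums to $10^{-9}$
  relative at small $N$.
* **$0^0 = 1$.** The mating-type mixture contains terms like
  $(1/2)^{n_{RR}+n_{RA}} 0^{n_{AA}}$; these are evaluated with explicit
  indicators (`n_aa == 0`), never floating-point `0^0`.
* **Unsatisfiable filters.** $X > N_a$ is a valid query whose answer is an
  empty sum: the functions warn and return 0 rather than error. $Y$ above
  $N_c$ is clamped to $N_c$ (no constraint).
* **Fraction resolution.** "At least 80%" of 5 affected means $X = 4$
  (smallest count satisfying the fraction); "at most 20%" of 5 controls
  means $Y = 1$ (largest count satisfying it) — ceiling and floor
  respectively, with a $10^{-9}$ guard so that binary representation of,
  say, $0.9 \times 50$ cannot push an integral product across the rounding
  boundary.
* **Ties and degenerate inputs.** $n_A = 0$ configurations are rejected (a
  site with no alternative allele is not an SNV); an empty control group
  reduces the case/control paths bit-for-bit to the affected-only paths.

## The Monte-Carlo oracle

The simulator exists to check the algebra, not to replace it. Site counts
per frequency class are Poisson — the infinite-sites expectation is a rate
over independent sites — with mean $\theta/n_A$ (unrelated) or the
mating-type rate (sibs). For unrelated cohorts each site's $n_A$ alternative
alleles are placed uniformly among the $2N$ haploid slots by sequential
urn draws (one hypergeometric draw per diploid), so the placement is
simulated exactly without ever evaluating the analytic configuration
probability it is meant to check. For sibs, affected and control genotype
counts are independent multinomial draws from the offspring law. Replicate
$r$ runs on its own RNG stream seeded `seed + r`, making results
reproducible and order-independent. Frequency classes that provably cannot
contain a passing site ($n_A < X$ dominant, $n_A < 2X$ recessive) are
skipped by default; such sites contribute exactly zero to the passing count,
so means and standard errors are unchanged (set `prune = FALSE` to simulate
them, as the spectrum-total test does).

Simulated means agree with the analytic values within 4 standard errors at
2,000 replicates across designs spanning both modes and both relatedness
settings. What passing these checks shows is internal consistency of model
and code; it does not show that real exomes follow the smooth neutral
spectrum (they do not, quite — see the assumptions above).

## Design notes

* The full-sib case/control sum enumerates affected × control genotype
  compositions, $O(N_a^2 N_c^2)$ pairs with vectorised kernels — transparent
  and instant at the sample sizes of interest ($N \le 100$), in preference
  to a closed-form convolution that exists for no published reference point.
* The stringent dominant closed form is implemented as the
  $n_{AA+RA} = N$ slice of the general dominant kernel summed over
  $n_A = N..2N$, and is tested equal to the general summation path for
  $N \le 20$.
* The published grids the package reproduces (`reproduce_table(2:5)`) print
  two decimals, so grid tests use absolute tolerance 0.02. Two
  internal inconsistencies of the source values are known: the worked
  two-individual dominant sum appears both as 12,221.91 and 12,221.92
  (the exact value is $11\theta/12 = 12{,}221.91\overline{6}$, within 0.02
  of both), and the full-sib recessive $N=10$ case/control cell appears as
  200.19 in the grid but 200.09 in running text — the model reproduces
  200.19, and the tests assert that value.
* With no filter at all ($X = 0$) the full-sib total is $\theta H_4$,
  which counts sites segregating in the parents even when every sampled sib
  is RR; the unrelated total is $\theta H_{2N}$, sites visible in the
  sampled exomes. The two models therefore coincide at $N = 1$ only for
  filters demanding at least one carrier — the case that matters in
  practice.
* Problem sizes in the test suite: brute-force placement oracles run at
  $N \le 3$ (unrelated) and $N \le 4$ sibs, where full enumeration is
  exact and instant; Monte-Carlo checks use 2,000 replicates at $N \le 10$;
  grid reproduction covers all published cells up to $N = 100$, which
  completes in well under a minute.

## Limitations

The counts are expectations; the package deliberately does not provide the
variance or the distribution of the candidate count, nor per-gene rates,
power under locus heterogeneity, or VCF-driven filtering of real cohorts.
The $\theta$ estimate inherits everything uncertain about "SNVs per exome"
— capture design, caller, ancestry — and results scale linearly in
$\theta$, so users with a better local estimate should pass it explicitly.
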