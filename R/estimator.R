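#' Pool pathogenic allele frequencies within a population
#'
#' Sums the per-variant pathogenic allele frequencies \eqn{q_i} for one
#' reference population, the quantity \eqn{\sum_i q_i} on which both the
#' carrier-frequency and prevalence formulas operate. Each variant
#' contributes \eqn{q_i = AC_i / AN_i} when allele counts are available
#' in that population, or its reported allele frequency when only a
#' frequency is available (for the pooled `"all"` population,
#' `af_global` is the fallback). Variants with no data in the population
#' contribute zero and are tallied in `n_missing` rather than silently
#' dropped, because reference-cohort subpopulation coverage varies.
#'
#' The effective allele number entering the downstream binomial
#' confidence interval is a modelling choice, set by `an_strategy`:
#' a summary (`"mean"`, `"median"`, `"min"`) of the per-variant
#' \eqn{AN_i} observed in the population, or `"fixed:N"` for an external
#' cohort size (e.g. `"fixed:282912"` for the 141,456 individuals of
#' gnomAD v2.1.1).
#'
#' @param variants A validated variant tibble, already passed through
#'   [filter_for_estimation()].
#' @param population One population code from
#'   `gnomad_populations(include_all = TRUE)`.
#' @param an_strategy `"mean"`, `"median"`, `"min"`, or `"fixed:N"`.
#' @return A one-row tibble with columns `population`, `q_sum`,
#'   `ac_total`, `an_effective` (`NA` when no strategy input is
#'   available), `n_variants`, `n_missing`, and `n_with_counts`.
#' @examples
#' pool_allele_frequencies(tmprss6_missense_variants(), "all",
#'                         an_strategy = "fixed:282912")
#' @export
pool_allele_frequencies <- function(variants, population,
                                    an_strategy = "mean") {
  validate_variants(variants)
  if (length(population) != 1 ||
      !population %in% gnomad_populations(include_all = TRUE)) {
    stop_config("population must be one of: %s",
                paste(gnomad_populations(include_all = TRUE),
                      collapse = ", "))
  }
  strategy <- parse_an_strategy(an_strategy)
  n <- nrow(variants)
  col <- function(stem) {
    nm <- paste0(stem, "_", population)
    if (nm %in% names(variants)) variants[[nm]] else rep(NA_real_, n)
  }
  ac <- col("ac")
  an <- col("an")
  af <- col("af")
  if (population == "all" && "af_global" %in% names(variants)) {
    af[is.na(af)] <- variants$af_global[is.na(af)]
  }
  has_counts <- !is.na(ac) & !is.na(an)
  if (any(has_counts & an <= 0)) {
    stop_validation("an_%s must be positive for every contributing record",
                    population)
  }
  q <- ifelse(has_counts, ac / an, af)
  contributing <- !is.na(q)
  tibble(
    population = population,
    q_sum = sum(q[contributing]),
    ac_total = sum(ac[has_counts]),
    an_effective = effective_an(an[has_counts], strategy),
    n_variants = n,
    n_missing = sum(!contributing),
    n_with_counts = sum(has_counts)
  )
}

parse_an_strategy <- function(an_strategy) {
  if (!is.character(an_strategy) || length(an_strategy) != 1) {
    stop_config("an_strategy must be a single string")
  }
  if (startsWith(an_strategy, "fixed:")) {
    n <- suppressWarnings(as.numeric(sub("^fixed:", "", an_strategy)))
    if (is.na(n) || n < 1) {
      stop_config("an_strategy 'fixed:N' needs a positive allele number N")
    }
    return(list(kind = "fixed", n = n))
  }
  if (!an_strategy %in% c("mean", "median", "min")) {
    stop_config("an_strategy must be mean, median, min, or fixed:N")
  }
  list(kind = an_strategy, n = NA_real_)
}

effective_an <- function(an_values, strategy) {
  if (strategy$kind == "fixed") return(strategy$n)
  if (length(an_values) == 0) return(NA_real_)
  switch(strategy$kind,
    mean = mean(an_values),
    median = median(an_values),
    min = min(an_values)
  )
}

#' Hardy-Weinberg genetic prevalence from pathogenic allele frequencies
#'
#' For an autosomal recessive disorder under Hardy-Weinberg equilibrium
#' with random mating, a haplotype is disease-causing with probability
#' \eqn{1 - \prod_i (1 - q_i)} over the independent pathogenic alleles
#' \eqn{q_i}, and an affected individual carries two such haplotypes, so
#' the genetic prevalence is \eqn{[1 - \prod_i (1 - q_i)]^2}. For the
#' rare-variant regime this is approximated to first order by
#' \eqn{(\sum_i q_i)^2}.
#'
#' @param q_list Numeric vector of per-variant pathogenic allele
#'   frequencies, each in `[0, 1]`.
#' @param method `"exact"` for \eqn{[1 - \prod(1 - q_i)]^2}, `"approx"`
#'   for \eqn{(\sum q_i)^2}.
#' @return The prevalence as a fraction in `[0, 1]`.
#' @examples
#' genetic_prevalence(c(0.01, 0.02))            # 8.8804e-04
#' genetic_prevalence(c(0.01, 0.02), "approx")  # 9e-04
#' @export
genetic_prevalence <- function(q_list, method = c("exact", "approx")) {
  method <- match.arg(method)
  q_list <- as.numeric(q_list)
  if (any(is.na(q_list)) || any(q_list < 0 | q_list > 1)) {
    stop_validation("every q must lie in [0, 1]")
  }
  if (length(q_list) == 0) return(0)
  switch(method,
    exact = (1 - prod(1 - q_list))^2,
    approx = min(sum(q_list), 1)^2
  )
}

#' Hardy-Weinberg carrier frequency from the pooled allele frequency
#'
#' The heterozygous-carrier proportion for a pooled pathogenic allele
#' frequency \eqn{q = \sum_i q_i} is \eqn{2(1 - q)q}, approximated by
#' \eqn{2q} when \eqn{q} is small. The exact value never exceeds the
#' approximation, with equality only at \eqn{q = 0}.
#'
#' @param q_sum Pooled pathogenic allele frequency in `[0, 1]`
#'   (vectorized).
#' @param method `"exact"` for \eqn{2(1 - q)q}, `"approx"` for
#'   \eqn{2q}.
#' @return The carrier frequency as a fraction.
#' @examples
#' carrier_frequency(0.25)            # 0.375
#' carrier_frequency(0.25, "approx")  # 0.5
#' @export
carrier_frequency <- function(q_sum, method = c("exact", "approx")) {
  method <- match.arg(method)
  q_sum <- as.numeric(q_sum)
  if (any(is.na(q_sum)) || any(q_sum < 0 | q_sum > 1)) {
    stop_validation("q_sum must lie in [0, 1]")
  }
  switch(method,
    exact = 2 * (1 - q_sum) * q_sum,
    approx = 2 * q_sum
  )
}

#' Wilson score interval for a binomial proportion
#'
#' The confidence interval obtained by inverting the normal-approximation
#' score test: all proportions \eqn{p} with
#' \eqn{|\hat p - p| \le z \sqrt{p(1-p)/n}}, which gives the closed form
#' \deqn{\frac{\hat p + z^2/2n}{1 + z^2/n} \pm
#'       \frac{z}{1 + z^2/n}\sqrt{\hat p(1-\hat p)/n + z^2/4n^2}.}
#' Unlike the Wald interval it always lies within `[0, 1]`, contains
#' \eqn{\hat p}, and behaves well at extreme counts: the lower bound is
#' exactly 0 when `ac = 0` and the upper exactly 1 when `ac = an`. The
#' critical value is the full-precision two-sided normal quantile
#' (1.959964... at the 95% level), not a rounded 1.96.
#'
#' @param ac Number of successes (allele count), `0 <= ac <= an`.
#'   Vectorized with `an`.
#' @param an Number of trials (allele number), `>= 1`.
#' @param level Two-sided confidence level in `(0, 1)`.
#' @return A tibble with columns `low` and `high`.
#' @examples
#' wilson_interval(286, 282912)
#' @export
wilson_interval <- function(ac, an, level = 0.95) {
  if (length(level) != 1 || is.na(level) || level <= 0 || level >= 1) {
    stop_validation("level must lie strictly between 0 and 1")
  }
  if (any(is.na(ac)) || any(is.na(an)) || any(an < 1)) {
    stop_validation("an must be >= 1")
  }
  if (any(ac < 0) || any(ac > an)) {
    stop_validation("ac must satisfy 0 <= ac <= an")
  }
  z <- qnorm(1 - (1 - level) / 2)
  p <- ac / an
  denom <- 1 + z^2 / an
  centre <- (p + z^2 / (2 * an)) / denom
  half <- (z / denom) * sqrt(p * (1 - p) / an + z^2 / (4 * an^2))
  low <- pmax(0, centre - half)
  high <- pmin(1, centre + half)
  # the score equation's boundary roots are exactly 0 and 1; don't let a
  # floating-point ulp in sqrt() pull them off the boundary
  low[p == 0] <- 0
  high[p == 1] <- 1
  tibble(low = low, high = high)
}

#' Estimate prevalence and carrier frequency for one population
#'
#' Turns a pooled allele frequency into point estimates and 95%-style
#' confidence intervals on both reporting scales. A single Wilson score
#' interval is computed on the allele scale for the pooled count
#' `ac_total / an_effective` (when any contributing variant lacked
#' counts, the pooled count is reconstructed as
#' `round(q_sum * an_effective)`); its endpoints are then mapped through
#' the carrier transform \eqn{q \mapsto 2(1-q)q} (or \eqn{2q}) and the
#' prevalence transform \eqn{q \mapsto q^2}. Both transforms are
#' monotone increasing on \eqn{[0, 1/2]}, so endpoint mapping propagates
#' the interval exactly, with no delta-method approximation.
#'
#' @param pooled A one-row tibble from [pool_allele_frequencies()].
#' @param level Confidence level, default 0.95.
#' @param method `"approx"` (the reporting convention: \eqn{2q} and
#'   \eqn{q^2}) or `"exact"`.
#' @return A list with elements `prevalence` and `carrier`, each a
#'   one-row tibble with `population`, `point`, `ci_low`, `ci_high` on
#'   the fraction scale, plus `per_million` (prevalence) or
#'   `per_thousand` (carrier) scaled and rounded to 2 decimals for
#'   reporting.
#' @examples
#' pooled <- pool_allele_frequencies(tmprss6_missense_variants(), "all",
#'                                   an_strategy = "fixed:282912")
#' estimate_population(pooled)
#' @export
estimate_population <- function(pooled, level = 0.95,
                                method = c("approx", "exact")) {
  method <- match.arg(method)
  needed <- c("population", "q_sum", "ac_total", "an_effective",
              "n_variants", "n_missing", "n_with_counts")
  if (!is.data.frame(pooled) || nrow(pooled) != 1 ||
      !all(needed %in% names(pooled))) {
    stop_validation("pooled must be a one-row result of pool_allele_frequencies()")
  }
  if (is.na(pooled$an_effective)) {
    stop_validation(paste0(
      "no effective allele number for population '%s'; ",
      "supply an_strategy = 'fixed:N' or per-variant allele numbers"),
      pooled$population)
  }
  q <- pooled$q_sum
  an <- pooled$an_effective
  n_contributing <- pooled$n_variants - pooled$n_missing
  ac <- if (pooled$n_with_counts == n_contributing && n_contributing > 0) {
    pooled$ac_total
  } else {
    round(q * an)
  }
  ac <- min(max(ac, 0), an)
  wi <- wilson_interval(ac, an, level)
  carrier_pts <- carrier_frequency(c(q, wi$low, wi$high), method)
  prev_pts <- c(genetic_prevalence(q, method),
                genetic_prevalence(wi$low, method),
                genetic_prevalence(wi$high, method))
  list(
    prevalence = tibble(
      population = pooled$population,
      point = prev_pts[1], ci_low = prev_pts[2], ci_high = prev_pts[3],
      per_million = round(prev_pts[1] * 1e6, 2)
    ),
    carrier = tibble(
      population = pooled$population,
      point = carrier_pts[1], ci_low = carrier_pts[2],
      ci_high = carrier_pts[3],
      per_thousand = round(carrier_pts[1] * 1e3, 2)
    )
  )
}
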