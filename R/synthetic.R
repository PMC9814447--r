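#' Per-population allele numbers of the gnomAD v2.1.1 cohort
#'
#' Twice the combined exome + genome individual counts of gnomAD v2.1.1
#' (141,456 individuals in total), the diploid allele numbers the
#' synthetic cohort generator samples at by default.
#'
#' @return A named numeric vector of allele numbers summing to 282,912.
#' @export
gnomad_v2_an <- function() {
  2 * c(afr = 12487, amr = 17720, asj = 5185, eas = 9977, fin = 12562,
        nfe = 64603, sas = 15308, oth = 3614)
}

default_consequence_mix <- function() {
  # Observed spectrum of the 86 curated TMPRSS6 P/LP variants: 40
  # missense-class, 20 frameshift, 17 nonsense, 9 splice (split 5/4).
  c(missense = 40, frameshift = 20, nonsense = 17,
    splice_acceptor = 5, splice_donor = 4) / 86
}

#' Configure a synthetic gnomAD-like cohort
#'
#' Describes a cohort with known truth: per-variant, per-population true
#' pathogenic allele frequencies, the number of alleles genotyped in
#' each population, and the label mix. [generate_cohort()] samples
#' allele counts binomially at these frequencies, so the estimation
#' pipeline can be checked against the truth it was fed.
#'
#' Decoy records — variants that must be removed by
#' [filter_for_estimation()] — can be added to exercise the filter:
#' half are classified benign/likely benign/uncertain, half are
#' pathogenic but carry a disqualifying gnomAD quality flag.
#'
#' @param true_q True pathogenic allele frequencies: a matrix with one
#'   row per variant and one column per population (named as in `an`),
#'   a vector of per-variant frequencies shared across populations, or a
#'   single frequency used for `n_variants` variants.
#' @param n_variants Number of causal variants when `true_q` is scalar.
#' @param an Named vector of alleles genotyped per population; defaults
#'   to the gnomAD v2.1.1 cohort via [gnomad_v2_an()].
#' @param consequence_mix Named proportions over
#'   [variant_consequences()] categories, summing to 1; defaults to the
#'   observed spectrum of the curated TMPRSS6 variant set.
#' @param p_likely_pathogenic Probability that a causal variant is
#'   labelled likely_pathogenic rather than pathogenic.
#' @param n_decoys Number of decoy records to append (default 0).
#' @param decoy_q True frequency of each decoy allele.
#' @param seed Integer seed; the generator is fully deterministic given
#'   the configuration.
#' @return A list of class `synthetic_cohort_config`.
#' @examples
#' cfg <- synthetic_cohort_config(true_q = 2e-5, n_variants = 50, seed = 1)
#' cohort <- generate_cohort(cfg)
#' @export
synthetic_cohort_config <- function(true_q, n_variants = NULL,
                                    an = gnomad_v2_an(),
                                    consequence_mix = default_consequence_mix(),
                                    p_likely_pathogenic = 0.45,
                                    n_decoys = 0, decoy_q = 1e-5,
                                    seed = 1L) {
  if (is.null(names(an)) || any(!nzchar(names(an)))) {
    stop_config("an must be a named vector of per-population allele numbers")
  }
  unknown <- setdiff(names(an), gnomad_populations())
  if (length(unknown) > 0) {
    stop_config("unknown population code(s) in an: %s",
                paste(unknown, collapse = ", "))
  }
  if (any(is.na(an)) || any(an < 2)) {
    stop_config("every population allele number must be >= 2")
  }
  if (is.matrix(true_q)) {
    if (is.null(colnames(true_q)) ||
        !setequal(colnames(true_q), names(an))) {
      stop_config("true_q matrix columns must match the populations in an")
    }
    qmat <- true_q[, names(an), drop = FALSE]
  } else {
    if (length(true_q) == 1) {
      if (is.null(n_variants) || n_variants < 1) {
        stop_config("scalar true_q needs n_variants >= 1")
      }
      true_q <- rep(true_q, n_variants)
    }
    qmat <- matrix(true_q, nrow = length(true_q), ncol = length(an),
                   dimnames = list(NULL, names(an)))
  }
  if (any(is.na(qmat)) || any(qmat < 0 | qmat > 1)) {
    stop_config("every true_q must lie in [0, 1]")
  }
  if (is.null(names(consequence_mix)) ||
      !all(names(consequence_mix) %in% variant_consequences()) ||
      abs(sum(consequence_mix) - 1) > 1e-8 || any(consequence_mix < 0)) {
    stop_config("consequence_mix must be named proportions over %s summing to 1",
                paste(variant_consequences(), collapse = ", "))
  }
  if (length(p_likely_pathogenic) != 1 || is.na(p_likely_pathogenic) ||
      p_likely_pathogenic < 0 || p_likely_pathogenic > 1) {
    stop_config("p_likely_pathogenic must lie in [0, 1]")
  }
  if (n_decoys < 0 || decoy_q < 0 || decoy_q > 1) {
    stop_config("n_decoys must be >= 0 and decoy_q in [0, 1]")
  }
  if (length(seed) != 1 || is.na(seed)) {
    stop_config("seed must be a single integer")
  }
  structure(
    list(true_q = qmat, an = an, consequence_mix = consequence_mix,
         p_likely_pathogenic = p_likely_pathogenic,
         n_decoys = as.integer(n_decoys), decoy_q = decoy_q,
         seed = as.integer(seed)),
    class = "synthetic_cohort_config"
  )
}

#' Generate a gnomAD-like synthetic cohort
#'
#' Samples a variant table in the package's TSV dialect from a
#' [synthetic_cohort_config()]. Each causal variant's allele count in
#' each population is drawn `Binomial(AN_pop, q)` at its true frequency;
#' the pooled `all` population aggregates counts and allele numbers
#' across populations. Decoy records (excluded classifications or
#' disqualifying flags) are sampled after the causal records, so for a
#' fixed seed the causal allele counts are identical whether or not
#' decoys are requested — adding decoys cannot move the estimates.
#'
#' @param config A `synthetic_cohort_config`.
#' @return A validated variant tibble.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "synthetic_cohort_config")) {
    stop_config("config must be created with synthetic_cohort_config()")
  }
  withr::with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(config) {
  qmat <- config$true_q
  an <- config$an
  pops <- names(an)
  n <- nrow(qmat)
  ac <- matrix(0, nrow = n, ncol = length(pops),
               dimnames = list(NULL, pops))
  for (j in seq_along(pops)) {
    ac[, j] <- rbinom(n, size = an[j], prob = qmat[, j])
  }
  consequence <- sample(names(config$consequence_mix), n, replace = TRUE,
                        prob = config$consequence_mix)
  classification <- sample(c("likely_pathogenic", "pathogenic"), n,
                           replace = TRUE,
                           prob = c(config$p_likely_pathogenic,
                                    1 - config$p_likely_pathogenic))
  nd <- config$n_decoys
  if (nd > 0) {
    dac <- matrix(0, nrow = nd, ncol = length(pops),
                  dimnames = list(NULL, pops))
    for (j in seq_along(pops)) {
      dac[, j] <- rbinom(nd, size = an[j], prob = config$decoy_q)
    }
    n_class <- ceiling(nd / 2)
    d_class <- c(sample(c("uncertain", "likely_benign", "benign"),
                        n_class, replace = TRUE),
                 rep("pathogenic", nd - n_class))
    d_flags <- c(rep("", n_class),
                 sample(estimation_excluded_flags(), nd - n_class,
                        replace = TRUE))
    ac <- rbind(ac, dac)
    consequence <- c(consequence,
                     sample(names(config$consequence_mix), nd,
                            replace = TRUE, prob = config$consequence_mix))
    classification <- c(classification, d_class)
    flags <- c(rep("", n), d_flags)
  } else {
    flags <- rep("", n)
  }
  total <- n + nd
  bases <- c("A", "C", "G", "T")
  ref <- bases[(seq_len(total) - 1) %% 4 + 1]
  alt <- bases[seq_len(total) %% 4 + 1]
  out <- tibble(
    chrom = "22",
    pos = 37461000L + 3L * seq_len(total),
    ref = ref, alt = alt,
    hgvs_c = NA_character_, hgvs_p = NA_character_,
    consequence = consequence, classification = classification,
    flags = flags, category_override = NA_character_,
    af_global = NA_real_
  )
  for (pop in pops) {
    out[[paste0("ac_", pop)]] <- ac[, pop]
    out[[paste0("an_", pop)]] <- rep(unname(an[pop]), total)
  }
  out$ac_all <- rowSums(ac)
  out$an_all <- rep(sum(an), total)
  out <- derive_frequencies(out)
  canonical <- intersect(variant_columns(), names(out))
  out <- out[, c(canonical, setdiff(names(out), canonical))]
  validate_variants(out)
  out
}

#' Simulate genotype-level disease prevalence
#'
#' An independent stochastic oracle for the Hardy-Weinberg prevalence
#' formula. Each individual receives two independent haplotypes; a
#' haplotype carries some pathogenic allele with probability
#' \eqn{1 - \prod_i (1 - q_i)} (independent biallelic sites, no
#' linkage); an individual is affected iff both haplotypes are
#' pathogenic. The observed affected fraction converges to the exact
#' prevalence \eqn{[1 - \prod_i(1 - q_i)]^2} as the sample grows.
#'
#' @param q_list Per-variant pathogenic allele frequencies, with
#'   `sum(q_list) <= 1`.
#' @param n_individuals Number of simulated individuals.
#' @param seed Integer seed.
#' @return Observed affected fraction.
#' @examples
#' simulate_genotype_prevalence(c(0.05), n_individuals = 1e5, seed = 7)
#' @export
simulate_genotype_prevalence <- function(q_list, n_individuals, seed) {
  q_list <- as.numeric(q_list)
  if (any(is.na(q_list)) || any(q_list < 0 | q_list > 1)) {
    stop_validation("every q must lie in [0, 1]")
  }
  if (sum(q_list) > 1) {
    stop_validation("sum of q_list must not exceed 1")
  }
  if (length(n_individuals) != 1 || is.na(n_individuals) ||
      n_individuals < 1) {
    stop_validation("n_individuals must be >= 1")
  }
  p_hap <- 1 - prod(1 - q_list)
  n <- as.integer(n_individuals)
  withr::with_seed(seed, {
    affected <- 0
    done <- 0L
    chunk <- 1000000L
    while (done < n) {
      m <- min(chunk, n - done)
      h1 <- runif(m) < p_hap
      h2 <- runif(m) < p_hap
      affected <- affected + sum(h1 & h2)
      done <- done + m
    }
    affected / n
  })
}

#' Monte-Carlo coverage of the Wilson score interval
#'
#' Draws allele counts `Binomial(an, true_q)` repeatedly, computes the
#' Wilson interval for each replicate, and reports the fraction of
#' intervals containing the true frequency — the empirical coverage,
#' nominally `level`.
#'
#' @param true_q True allele frequency.
#' @param an Alleles sampled per replicate.
#' @param reps Number of replicates, at least 100.
#' @param level Confidence level of the intervals.
#' @param seed Integer seed.
#' @return The coverage fraction.
#' @examples
#' ci_coverage_study(1e-3, an = 282912, reps = 200, seed = 11)
#' @export
ci_coverage_study <- function(true_q, an, reps, level = 0.95, seed = 1L) {
  if (length(true_q) != 1 || is.na(true_q) || true_q < 0 || true_q > 1) {
    stop_validation("true_q must lie in [0, 1]")
  }
  if (reps < 100) {
    stop_validation("reps must be at least 100")
  }
  withr::with_seed(seed, {
    ac <- rbinom(reps, size = an, prob = true_q)
    wi <- wilson_interval(ac, an, level)
    mean(wi$low <= true_q & true_q <= wi$high)
  })
}
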