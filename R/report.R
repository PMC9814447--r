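#' Configuration for a stratified prevalence report
#'
#' Bundles the estimation options shared by [build_report()] and the
#' command-line wrapper. The effective allele number strategy defaults
#' to `"fixed:<2 * cohort_size>"` when a cohort size (number of
#' individuals) is supplied, mirroring a diploid reference cohort, and
#' otherwise to the mean of the per-variant allele numbers.
#'
#' @param level Two-sided confidence level, default 0.95.
#' @param method `"approx"` (the reporting convention) or `"exact"`.
#' @param an_strategy `"mean"`, `"median"`, `"min"`, or `"fixed:N"`;
#'   `NULL` to derive from `cohort_size`.
#' @param cohort_size Number of individuals in the reference cohort
#'   (e.g. 141456 for gnomAD v2.1.1), used only when `an_strategy` is
#'   `NULL`.
#' @param gate_an Minimum effective allele number below which a
#'   population is reported `not_analysed` rather than given a numeric
#'   estimate (default 10000 alleles). Reference panels leave some
#'   ancestries too thinly sampled for a meaningful rare-allele
#'   estimate.
#' @param seed Optional integer recorded in the report metadata when the
#'   input was simulated.
#' @return A list of class `carrierprev_config`.
#' @export
report_config <- function(level = 0.95, method = c("approx", "exact"),
                          an_strategy = NULL, cohort_size = NULL,
                          gate_an = 10000, seed = NULL) {
  method <- match.arg(method)
  if (length(level) != 1 || is.na(level) || level <= 0 || level >= 1) {
    stop_config("level must lie strictly between 0 and 1")
  }
  if (length(gate_an) != 1 || is.na(gate_an) || gate_an < 0) {
    stop_config("gate_an must be a non-negative allele number")
  }
  if (is.null(an_strategy)) {
    an_strategy <- if (!is.null(cohort_size)) {
      if (cohort_size < 1) stop_config("cohort_size must be positive")
      sprintf("fixed:%d", as.integer(2 * cohort_size))
    } else {
      "mean"
    }
  }
  parse_an_strategy(an_strategy) # validate early
  structure(
    list(level = level, method = method, an_strategy = an_strategy,
         gate_an = gate_an, seed = seed),
    class = "carrierprev_config"
  )
}

#' Build a stratified prevalence and carrier-frequency report
#'
#' Runs the full estimation pipeline over a curated variant table:
#' validates, applies the pathogenicity and quality-flag filter once,
#' pools allele frequencies per requested population, and produces one
#' report row per population with the prevalence (per million births)
#' and carrier frequency (per thousand individuals) and their confidence
#' intervals. Populations with no contributing data, or with an
#' effective allele number below the configured gate, are reported with
#' status `not_analysed` and carry no numbers.
#'
#' @param variants A validated variant tibble (filtering is applied
#'   here; pre-filtered input gives the same result).
#' @param populations Population codes to report; `"all"` denotes the
#'   pooled global population.
#' @param config A [report_config()].
#' @return An object of class `prevalence_report`: a list with `rows`
#'   (tibble: `population`, `status`, `prev_per_million`,
#'   `prev_ci_low_pm`, `prev_ci_high_pm`, `carrier_per_thousand`,
#'   `carrier_ci_low_pt`, `carrier_ci_high_pt`, full precision) and
#'   `metadata` (filter tallies and the configuration used).
#' @examples
#' build_report(tmprss6_missense_variants(), populations = "all",
#'              config = report_config(cohort_size = 141456))
#' @export
build_report <- function(variants,
                         populations = c("afr", "amr", "eas", "nfe",
                                         "sas", "all"),
                         config = report_config()) {
  if (!inherits(config, "carrierprev_config")) {
    stop_config("config must be created with report_config()")
  }
  if (length(populations) == 0) {
    stop_config("at least one population must be requested")
  }
  unknown <- setdiff(populations, gnomad_populations(include_all = TRUE))
  if (length(unknown) > 0) {
    stop_config("unknown population code(s): %s",
                paste(unknown, collapse = ", "))
  }
  validate_variants(variants)
  kept <- filter_for_estimation(variants)
  excluded_class <- sum(is.na(variants$classification) |
                        !variants$classification %in%
                          c("pathogenic", "likely_pathogenic"))
  excluded_flag <- nrow(variants) - excluded_class - nrow(kept)
  rows <- purrr::map_dfr(populations, function(pop) {
    pooled <- pool_allele_frequencies(kept, pop,
                                      an_strategy = config$an_strategy)
    degenerate <- (pooled$n_variants - pooled$n_missing) == 0 ||
      is.na(pooled$an_effective) ||
      pooled$an_effective < config$gate_an
    if (degenerate) {
      return(tibble(
        population = pop, status = "not_analysed",
        prev_per_million = NA_real_, prev_ci_low_pm = NA_real_,
        prev_ci_high_pm = NA_real_, carrier_per_thousand = NA_real_,
        carrier_ci_low_pt = NA_real_, carrier_ci_high_pt = NA_real_
      ))
    }
    est <- estimate_population(pooled, level = config$level,
                               method = config$method)
    tibble(
      population = pop, status = "analysed",
      prev_per_million = est$prevalence$point * 1e6,
      prev_ci_low_pm = est$prevalence$ci_low * 1e6,
      prev_ci_high_pm = est$prevalence$ci_high * 1e6,
      carrier_per_thousand = est$carrier$point * 1e3,
      carrier_ci_low_pt = est$carrier$ci_low * 1e3,
      carrier_ci_high_pt = est$carrier$ci_high * 1e3
    )
  })
  structure(
    list(
      rows = rows,
      metadata = list(
        n_variants_input = nrow(variants),
        n_excluded_classification = excluded_class,
        n_excluded_flag = excluded_flag,
        n_included = nrow(kept),
        an_strategy = config$an_strategy,
        level = config$level,
        method = config$method,
        gate_an = config$gate_an,
        seed = config$seed,
        populations = populations
      )
    ),
    class = "prevalence_report"
  )
}

#' @export
print.prevalence_report <- function(x, ...) {
  md <- x$metadata
  cat(sprintf(
    "Prevalence report: %d/%d variants included (%d excluded by classification, %d by flag)\n",
    md$n_included, md$n_variants_input, md$n_excluded_classification,
    md$n_excluded_flag))
  cat(sprintf("method = %s, level = %g, an_strategy = %s, gate = %g alleles\n",
              md$method, md$level, md$an_strategy, md$gate_an))
  print(x$rows, ...)
  invisible(x)
}

fmt2 <- function(x) {
  ifelse(is.na(x), "", sprintf("%.2f", round(x, 2)))
}

report_display <- function(report) {
  r <- report$rows
  tibble(
    population = r$population,
    status = r$status,
    prevalence_per_million = fmt2(r$prev_per_million),
    prevalence_95ci = ifelse(r$status == "analysed",
                             sprintf("[%s, %s]", fmt2(r$prev_ci_low_pm),
                                     fmt2(r$prev_ci_high_pm)), ""),
    carrier_per_thousand = fmt2(r$carrier_per_thousand),
    carrier_95ci = ifelse(r$status == "analysed",
                          sprintf("[%s, %s]", fmt2(r$carrier_ci_low_pt),
                                  fmt2(r$carrier_ci_high_pt)), "")
  )
}

#' Render a prevalence report
#'
#' Serializes a [build_report()] result. Display values are rounded
#' half-even to 2 decimals on the reporting scales (per million for
#' prevalence, per thousand for carriers) with confidence intervals as
#' `[low, high]`; the JSON format additionally carries the
#' full-precision rows and metadata, and round-trips through
#' [report_from_json()] without loss. Rendering is pure: the same report
#' always yields byte-identical text.
#'
#' @param report A `prevalence_report`.
#' @param format `"markdown"`, `"csv"`, or `"json"`.
#' @return A single string.
#' @export
render_report <- function(report, format = c("markdown", "csv", "json")) {
  if (!inherits(report, "prevalence_report")) {
    stop_config("report must be created with build_report()")
  }
  if (is.character(format) && length(format) > 1) format <- format[1]
  if (!is.character(format) || length(format) != 1 ||
      !format %in% c("markdown", "csv", "json")) {
    stop_config("unknown format; use markdown, csv, or json")
  }
  disp <- report_display(report)
  switch(format,
    csv = readr::format_csv(disp),
    markdown = render_markdown(disp),
    json = jsonlite::toJSON(
      list(metadata = report$metadata,
           rows = report$rows,
           display = disp),
      auto_unbox = TRUE, digits = NA, na = "null", null = "null",
      pretty = TRUE
    )
  )
}

render_markdown <- function(disp) {
  header <- paste0("| ", paste(names(disp), collapse = " | "), " |")
  rule <- paste0("|", paste(rep("---", ncol(disp)), collapse = "|"), "|")
  body <- apply(disp, 1, function(row) {
    paste0("| ", paste(row, collapse = " | "), " |")
  })
  paste(c(header, rule, body, ""), collapse = "\n")
}

#' Reconstruct a prevalence report from its JSON rendering
#'
#' @param text JSON produced by `render_report(report, "json")`.
#' @return A `prevalence_report` equal to the one that was rendered.
#' @export
report_from_json <- function(text) {
  parsed <- jsonlite::fromJSON(text)
  rows <- as_tibble(parsed$rows)
  md <- parsed$metadata
  md$populations <- as.character(md$populations)
  if (is.null(md$seed)) md["seed"] <- list(NULL)
  structure(list(rows = rows, metadata = md), class = "prevalence_report")
}
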