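#' Controlled vocabularies for curated variant tables
#'
#' The package works with gnomAD v2 population codes, a closed set of
#' molecular consequences, ACMG/AMP-style classification labels, and the
#' gnomAD quality flags that disqualify a variant from frequency-based
#' estimation.
#'
#' @param include_all If `TRUE`, append the pooled global population
#'   code `"all"`.
#' @return A character vector of codes.
#' @examples
#' gnomad_populations()
#' estimation_excluded_flags()
#' @export
gnomad_populations <- function(include_all = FALSE) {
  c("afr", "amr", "asj", "eas", "fin", "nfe", "sas", "oth",
    if (include_all) "all")
}

#' @rdname gnomad_populations
#' @export
variant_consequences <- function() {
  c("missense", "synonymous", "frameshift", "nonsense",
    "splice_acceptor", "splice_donor", "start_lost")
}

#' @rdname gnomad_populations
#' @export
ptv_consequences <- function() {
  c("frameshift", "nonsense", "splice_acceptor", "splice_donor")
}

#' @rdname gnomad_populations
#' @export
variant_classifications <- function() {
  c("pathogenic", "likely_pathogenic", "uncertain", "likely_benign",
    "benign")
}

#' @rdname gnomad_populations
#' @export
estimation_excluded_flags <- function() {
  c("low_confidence_pLoF", "LCR", "not_LoF")
}

# Canonical column order for the TSV dialect.
variant_columns <- function() {
  pops <- gnomad_populations(include_all = TRUE)
  c("chrom", "pos", "ref", "alt", "hgvs_c", "hgvs_p", "consequence",
    "classification", "flags", "category_override", "af_global",
    as.vector(rbind(paste0("ac_", pops), paste0("an_", pops),
                    paste0("af_", pops))))
}

variant_label <- function(variants, i) {
  sprintf("%s:%s %s>%s", variants$chrom[i], variants$pos[i],
          variants$ref[i], variants$alt[i])
}

split_flags <- function(flags) {
  flags[is.na(flags)] <- ""
  strsplit(flags, ";", fixed = TRUE)
}

#' Read a curated variant table
#'
#' Reads population-stratified allele counts and frequencies for curated
#' disease-causing variants, either from the package's tab-separated
#' dialect or from a gnomAD-style VCF slice.
#'
#' The TSV dialect is UTF-8, tab-delimited, with `#` comment lines and a
#' header row. Required columns: `chrom`, `pos` (1-based, GRCh37), `ref`,
#' `alt`, `consequence`, `classification`. Optional columns: `hgvs_c`,
#' `hgvs_p`, `flags` (semicolon-separated), `category_override`,
#' `af_global`, and per-population triples `ac_<pop>` / `an_<pop>` /
#' `af_<pop>` for the codes in [gnomad_populations()] plus `all`.
#' Whenever both `ac_<pop>` and `an_<pop>` are present, `af_<pop>` is
#' (re)computed as their quotient, so frequency and counts can never
#' disagree. `af_global` defaults to `af_all` when absent.
#'
#' VCF input (VCF 4.2, read via the VariantAnnotation package) must carry
#' `AC` and `AN` INFO keys and may carry per-population `AC_<pop>` /
#' `AN_<pop>` keys in the gnomAD v2 naming. Multi-allelic sites are
#' decomposed into one record per ALT allele. A non-PASS FILTER value is
#' recorded as a `filter:<value>` flag. Consequence and classification
#' are not encoded in gnomAD VCFs and come back `NA`; such records are
#' never treated as pathogenic by [filter_for_estimation()].
#'
#' @param path Path to the input file.
#' @param dialect `"tsv"` or `"vcf"`.
#' @return A tibble with one row per variant (per ALT allele for VCF),
#'   validated by [validate_variants()].
#' @seealso [write_variant_table()], [tmprss6_missense_variants()]
#' @examples
#' read_variant_table(tmprss6_missense_path())
#' @export
read_variant_table <- function(path, dialect = c("tsv", "vcf")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop_format("file does not exist: %s", path)
  }
  variants <- switch(dialect,
    tsv = read_variant_tsv(path),
    vcf = read_variant_vcf(path)
  )
  validate_variants(variants)
}

read_variant_tsv <- function(path) {
  raw <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  required <- c("chrom", "pos", "ref", "alt", "consequence", "classification")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop_format("missing required column(s): %s",
                paste(missing, collapse = ", "))
  }
  out <- as_tibble(raw)
  out$pos <- as.integer(out$pos)
  for (col in c("hgvs_c", "hgvs_p", "flags", "category_override")) {
    if (!col %in% names(out)) out[[col]] <- NA_character_
  }
  out$flags[is.na(out$flags)] <- ""
  out$category_override[which(out$category_override == "")] <- NA_character_
  num_cols <- grep("^(af_|ac_|an_)", names(out), value = TRUE)
  for (col in num_cols) out[[col]] <- as.numeric(out[[col]])
  out <- derive_frequencies(out)
  canonical <- intersect(variant_columns(), names(out))
  out[, c(canonical, setdiff(names(out), canonical))]
}

# AF is forced to AC/AN wherever both counts exist; af_global mirrors the
# pooled-population frequency when only one of the two is given.
derive_frequencies <- function(variants) {
  for (pop in gnomad_populations(include_all = TRUE)) {
    ac <- paste0("ac_", pop)
    an <- paste0("an_", pop)
    af <- paste0("af_", pop)
    if (ac %in% names(variants) && an %in% names(variants)) {
      have <- !is.na(variants[[ac]]) & !is.na(variants[[an]])
      if (!af %in% names(variants)) variants[[af]] <- NA_real_
      variants[[af]][have] <- variants[[ac]][have] / variants[[an]][have]
    }
  }
  if (!"af_global" %in% names(variants)) variants$af_global <- NA_real_
  if ("af_all" %in% names(variants)) {
    take <- is.na(variants$af_global) & !is.na(variants$af_all)
    variants$af_global[take] <- variants$af_all[take]
  }
  variants
}

#' Validate a variant table
#'
#' Checks the invariants of the curated-variant data model: positions are
#' 1-based and positive, consequences and classifications come from the
#' closed vocabularies, `0 <= AC <= AN` with `AN >= 1` in every
#' population, allele frequencies agree with `AC/AN` wherever both counts
#' are present, `af_global` lies in `[0, 1]`, and flag tokens are either
#' known gnomAD quality flags or `filter:` annotations carried over from
#' a VCF FILTER column.
#'
#' @param variants A variant tibble.
#' @return The input, invisibly unchanged, if valid; otherwise a
#'   validation error naming the offending record.
#' @export
validate_variants <- function(variants) {
  required <- c("chrom", "pos", "ref", "alt", "consequence", "classification")
  missing <- setdiff(required, names(variants))
  if (length(missing) > 0) {
    stop_format("missing required column(s): %s",
                paste(missing, collapse = ", "))
  }
  if (nrow(variants) == 0) return(invisible(variants))
  bad_pos <- which(is.na(variants$pos) | variants$pos < 1)
  if (length(bad_pos) > 0) {
    stop_validation("pos must be a positive 1-based coordinate (row %d)",
                    bad_pos[1])
  }
  check_vocab(variants$consequence, variant_consequences(), "consequence")
  check_vocab(variants$classification, variant_classifications(),
              "classification")
  if ("category_override" %in% names(variants)) {
    check_vocab(variants$category_override, variant_consequences(),
                "category_override")
  }
  for (pop in gnomad_populations(include_all = TRUE)) {
    check_population_counts(variants, pop)
  }
  if ("af_global" %in% names(variants)) {
    bad_af <- which(!is.na(variants$af_global) &
                    (variants$af_global < 0 | variants$af_global > 1))
    if (length(bad_af) > 0) {
      stop_validation("af_global outside [0, 1] for %s",
                      variant_label(variants, bad_af[1]))
    }
  }
  known <- estimation_excluded_flags()
  flags <- if ("flags" %in% names(variants)) variants$flags else
    character(nrow(variants))
  for (i in seq_len(nrow(variants))) {
    toks <- split_flags(flags[i])[[1]]
    toks <- toks[nzchar(toks)]
    bad <- toks[!(toks %in% known | startsWith(toks, "filter:"))]
    if (length(bad) > 0) {
      stop_validation("unknown flag '%s' for %s (allowed: %s or filter:<value>)",
                      bad[1], variant_label(variants, i),
                      paste(known, collapse = ", "))
    }
  }
  invisible(variants)
}

check_vocab <- function(values, allowed, what) {
  bad <- which(!is.na(values) & !(values %in% allowed))
  if (length(bad) > 0) {
    stop_validation("unknown %s '%s' (allowed: %s)", what, values[bad[1]],
                    paste(allowed, collapse = ", "))
  }
}

check_population_counts <- function(variants, pop) {
  ac_col <- paste0("ac_", pop)
  an_col <- paste0("an_", pop)
  af_col <- paste0("af_", pop)
  if (!ac_col %in% names(variants) || !an_col %in% names(variants)) {
    return(invisible(NULL))
  }
  ac <- variants[[ac_col]]
  an <- variants[[an_col]]
  have <- !is.na(ac) & !is.na(an)
  bad_an <- which(have & an < 1)
  if (length(bad_an) > 0) {
    stop_validation("an_%s must be >= 1 for %s", pop,
                    variant_label(variants, bad_an[1]))
  }
  bad_ac <- which(have & (ac < 0 | ac > an))
  if (length(bad_ac) > 0) {
    stop_validation("ac_%s (%g) outside [0, an_%s = %g] for %s", pop,
                    ac[bad_ac[1]], pop, an[bad_ac[1]],
                    variant_label(variants, bad_ac[1]))
  }
  if (af_col %in% names(variants)) {
    af <- variants[[af_col]]
    chk <- which(have & !is.na(af))
    off <- chk[abs(af[chk] - ac[chk] / an[chk]) > 1e-12]
    if (length(off) > 0) {
      stop_validation("af_%s disagrees with ac_%s/an_%s for %s", pop, pop,
                      pop, variant_label(variants, off[1]))
    }
  }
  invisible(NULL)
}

#' Write a curated variant table
#'
#' Serializes a validated variant tibble to the package's TSV dialect.
#' Reading the file back with [read_variant_table()] reproduces the
#' records field for field.
#'
#' @param variants A validated variant tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(variants, path) {
  validate_variants(variants)
  out <- variants
  if ("flags" %in% names(out)) out$flags[is.na(out$flags)] <- ""
  readr::write_tsv(out, path, na = "")
  invisible(path)
}

#' Keep only the variants usable for frequency-based estimation
#'
#' Applies the two inclusion rules used throughout the package: a variant
#' contributes to carrier-frequency and prevalence estimation only if it
#' is classified pathogenic or likely pathogenic (benign, likely benign,
#' uncertain, and unclassified records are dropped) and it carries none
#' of the gnomAD quality flags in [estimation_excluded_flags()]
#' (low-confidence pLoF, low-complexity region, or "Not LoF"). Input
#' order is preserved; the operation is idempotent.
#'
#' @param variants A validated variant tibble.
#' @return The qualifying subset, in input order.
#' @export
filter_for_estimation <- function(variants) {
  validate_variants(variants)
  if (nrow(variants) == 0) return(variants)
  keep_class <- !is.na(variants$classification) &
    variants$classification %in% c("pathogenic", "likely_pathogenic")
  flagged <- vapply(split_flags(variants$flags), function(toks) {
    any(toks %in% estimation_excluded_flags())
  }, logical(1))
  variants[keep_class & !flagged, , drop = FALSE]
}

#' Count variants by molecular consequence
#'
#' Tallies records per consequence and reports the aggregate
#' protein-truncating count (frameshift + nonsense + splice
#' acceptor/donor). When a `category_override` column is present its
#' value replaces the consequence for counting purposes; this is how
#' initiator-codon substitutions conventionally tabulated with the
#' missense set are counted without relabelling them.
#'
#' @param variants A validated variant tibble.
#' @return A named integer vector with one entry per consequence in
#'   [variant_consequences()], an `unknown` entry for records without a
#'   consequence call, and a `ptv` aggregate. All entries except `ptv`
#'   sum to `nrow(variants)`.
#' @examples
#' categorize_consequences(read_variant_table(tmprss6_missense_path()))
#' @export
categorize_consequences <- function(variants) {
  validate_variants(variants)
  effective <- variants$consequence
  if ("category_override" %in% names(variants)) {
    override <- variants$category_override
    effective[!is.na(override)] <- override[!is.na(override)]
  }
  cats <- variant_consequences()
  counts <- vapply(cats, function(k) sum(effective == k, na.rm = TRUE),
                   integer(1))
  counts <- c(counts, unknown = sum(is.na(effective)))
  c(counts, ptv = sum(counts[ptv_consequences()]))
}

#' Map protein positions between the two TMPRSS6 isoforms
#'
#' TMPRSS6 has two protein isoforms: the MANE canonical 802-residue
#' protein and an 811-residue isoform, used in much of the older
#' literature, whose translation starts at an upstream alternate start
#' codon that prepends nine residues (MLLLFHSKRM up to the shared Met).
#' Residue `i` of the canonical protein is residue `i + 9` of the long
#' isoform; residues 1-9 of the long isoform have no canonical image.
#'
#' @param position Protein residue index (vectorized), `>= 1`.
#' @param direction `"canonical_to_long"` (add 9) or
#'   `"long_to_canonical"` (subtract 9).
#' @return The mapped residue index.
#' @examples
#' map_isoform_position(203, "canonical_to_long") # 212
#' @export
map_isoform_position <- function(position,
                                 direction = c("canonical_to_long",
                                               "long_to_canonical")) {
  direction <- match.arg(direction)
  offset <- 811L - 802L
  if (any(is.na(position)) || any(position < 1)) {
    stop_validation("position must be >= 1")
  }
  if (direction == "canonical_to_long") {
    position + offset
  } else {
    if (any(position <= offset)) {
      stop_validation(
        "long-isoform residues 1-%d have no canonical equivalent", offset)
    }
    position - offset
  }
}

#' Packaged TMPRSS6 missense variant fixture
#'
#' Forty pathogenic/likely pathogenic TMPRSS6 missense-class variants
#' (38 missense plus the two initiator-codon substitutions counted with
#' them) present in gnomAD v2.1.1, with global minor allele frequencies.
#' These underlie iron-refractory iron deficiency anaemia (IRIDA), an
#' autosomal recessive disorder.
#'
#' @return `tmprss6_missense_path()` returns the path to the packaged TSV;
#'   `tmprss6_missense_variants()` returns the parsed, validated tibble.
#' @export
tmprss6_missense_path <- function() {
  system.file("extdata", "tmprss6_missense_gnomad.tsv",
              package = "carrierprev", mustWork = TRUE)
}

#' @rdname tmprss6_missense_path
#' @export
tmprss6_missense_variants <- function() {
  read_variant_table(tmprss6_missense_path())
}
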