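# gnomAD-style VCF reading. Kept behind read_variant_table(dialect =
# "vcf"); VariantAnnotation does the parsing and the per-ALT expansion of
# Number=A INFO fields.
read_variant_vcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    stop_config("reading VCF input requires the VariantAnnotation package")
  }
  vcf <- VariantAnnotation::readVcf(path)
  vcf <- VariantAnnotation::expand(vcf)
  info <- VariantAnnotation::info(vcf)
  if (!all(c("AC", "AN") %in% names(info))) {
    stop_format("VCF INFO must carry AC and AN keys")
  }
  rr <- SummarizedExperiment::rowRanges(vcf)
  n <- length(rr)
  filt <- as.character(rr$FILTER)
  flags <- ifelse(is.na(filt) | filt %in% c("PASS", "."), "",
                  paste0("filter:", filt))
  out <- tibble(
    chrom = as.character(GenomeInfoDb::seqnames(rr)),
    pos = BiocGenerics::start(rr),
    ref = as.character(VariantAnnotation::ref(vcf)),
    alt = as.character(VariantAnnotation::alt(vcf)),
    hgvs_c = NA_character_,
    hgvs_p = NA_character_,
    consequence = NA_character_,
    classification = NA_character_,
    flags = flags,
    category_override = NA_character_,
    ac_all = as.numeric(info$AC),
    an_all = as.numeric(rep_len(info$AN, n))
  )
  for (pop in gnomad_populations()) {
    ac_key <- paste0("AC_", pop)
    an_key <- paste0("AN_", pop)
    if (all(c(ac_key, an_key) %in% names(info))) {
      out[[paste0("ac_", pop)]] <- as.numeric(info[[ac_key]])
      out[[paste0("an_", pop)]] <- as.numeric(rep_len(info[[an_key]], n))
    }
  }
  out <- derive_frequencies(out)
  canonical <- intersect(variant_columns(), names(out))
  out[, c(canonical, setdiff(names(out), canonical))]
}
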