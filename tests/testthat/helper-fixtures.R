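# Build a minimal variant tibble in the package's TSV dialect.
make_variants <- function(n = 1, classification = "pathogenic",
                          consequence = "missense", flags = "", ...) {
  tibble::tibble(
    chrom = "22",
    pos = 37461000L + seq_len(n),
    ref = "A",
    alt = "G",
    hgvs_c = NA_character_,
    hgvs_p = NA_character_,
    consequence = rep_len(consequence, n),
    classification = rep_len(classification, n),
    flags = rep_len(flags, n),
    ...
  )
}

write_tsv_fixture <- function(df, path = withr::local_tempfile(
                                fileext = ".tsv",
                                .local_envir = parent.frame())) {
  readr::write_tsv(df, path, na = "")
  path
}

# Independent Wilson oracle: both interval endpoints are roots of the
# score equation (phat - p)^2 = z^2 p (1 - p) / n, solved numerically
# rather than via the closed form under test.
wilson_oracle <- function(ac, an, level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  phat <- ac / an
  f <- function(p) (phat - p)^2 - z^2 * p * (1 - p) / an
  # f has a sign change strictly inside (0, phat) and (phat, 1); nudge
  # the brackets off the boundary roots at phat = 0 and phat = 1
  low <- if (ac == 0) 0 else {
    uniroot(f, c(0, min(phat, 1 - 1e-9)), tol = 1e-14)$root
  }
  high <- if (ac == an) 1 else {
    uniroot(f, c(max(phat, 1e-12), 1), tol = 1e-14)$root
  }
  c(low = low, high = high)
}

# A tiny gnomAD-style VCF slice with per-population AC/AN INFO keys and
# one multi-allelic site.
write_vcf_fixture <- function(path = withr::local_tempfile(
                                fileext = ".vcf",
                                .local_envir = parent.frame())) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AC,Number=A,Type=Integer,Description=\"Allele count\">",
    "##INFO=<ID=AN,Number=1,Type=Integer,Description=\"Allele number\">",
    "##INFO=<ID=AC_afr,Number=A,Type=Integer,Description=\"AC afr\">",
    "##INFO=<ID=AN_afr,Number=1,Type=Integer,Description=\"AN afr\">",
    "##INFO=<ID=AC_nfe,Number=A,Type=Integer,Description=\"AC nfe\">",
    "##INFO=<ID=AN_nfe,Number=1,Type=Integer,Description=\"AN nfe\">",
    "##FILTER=<ID=RF,Description=\"Random forest\">",
    "##contig=<ID=22>",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    paste("22", "37494466", ".", "G", "T", ".", "PASS",
          "AC=5;AN=1000;AC_afr=2;AN_afr=200;AC_nfe=3;AN_nfe=600",
          sep = "\t"),
    paste("22", "37491614", ".", "A", "G,T", ".", "PASS",
          "AC=4,2;AN=2000;AC_afr=1,0;AN_afr=400;AC_nfe=3,2;AN_nfe=1200",
          sep = "\t"),
    paste("22", "37480819", ".", "G", "A", ".", "RF",
          "AC=1;AN=500;AC_afr=0;AN_afr=100;AC_nfe=1;AN_nfe=300",
          sep = "\t")
  )
  writeLines(lines, path)
  path
}
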