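#' @name io
#' @title Plain-text readers and writers for pipeline tables
#'
#' @description Cohorts, gene panels and trio records travel as
#' tab-separated tables with headers; variant tables can additionally be
#' written as minimal VCF 4.2 with annotations in INFO keys (GENE, CSQ,
#' LOF_HC, MPC, CADD, AC, AN, HOM, AF_FIN and other per-population AF keys,
#' REF_AC, REF_HOM, IN_CONTROLS). Configs round-trip through YAML.
NULL

#' @rdname io
#' @param x table to write.
#' @param path file path.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}

#' @rdname io
#' @param config a \code{\link{sim_config}}.
#' @export
write_config_yaml <- function(config, path) {
  cfg <- unclass(config)
  # named vectors become YAML mappings so names survive the round trip
  for (nm in c("severity_probs", "comorbidity_probs"))
    cfg[[nm]] <- as.list(cfg[[nm]])
  yaml::write_yaml(cfg, path, precision = 17)
  invisible(path)
}

#' @rdname io
#' @export
read_config_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (nm in c("severity_probs", "comorbidity_probs", "pgs_traits"))
    if (!is.null(cfg[[nm]])) cfg[[nm]] <- unlist(cfg[[nm]])
  do.call(sim_config, cfg)
}

#' Write a variant table as minimal VCF 4.2
#'
#' @param variants variant table (see \code{\link{simulate_variant_table}}).
#' @param path output path (uncompressed .vcf).
#' @return the path, invisibly.
#' @export
write_variants_vcf <- function(variants, path) {
  info_keys <- c(GENE = "String", CSQ = "String", LOF_HC = "Integer",
                 MPC = "Float", CADD = "Float", AC = "Integer",
                 AN = "Integer", HOM = "Integer", AF_FIN = "Float",
                 AF_NFE = "Float", AF_AFR = "Float", AF_EAS = "Float",
                 REF_AC = "Integer", REF_HOM = "Integer",
                 IN_CONTROLS = "Integer")
  hdr <- c("##fileformat=VCFv4.2",
           sprintf('##INFO=<ID=%s,Number=1,Type=%s,Description="%s">',
                   names(info_keys), info_keys, names(info_keys)),
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  fmt <- function(x) ifelse(is.na(x), ".", sprintf("%.12g", x))
  info <- paste0(
    "GENE=", variants$gene, ";CSQ=", variants$consequence,
    ";LOF_HC=", as.integer(variants$lof_hc),
    ";MPC=", fmt(variants$mpc), ";CADD=", fmt(variants$cadd),
    ";AC=", variants$ac_insample, ";AN=", variants$an_insample,
    ";HOM=", variants$hom_insample,
    ";AF_FIN=", fmt(variants$af_fin), ";AF_NFE=", fmt(variants$af_nfe),
    ";AF_AFR=", fmt(variants$af_afr), ";AF_EAS=", fmt(variants$af_eas),
    ";REF_AC=", variants$ref_ac, ";REF_HOM=", variants$ref_hom,
    ";IN_CONTROLS=", as.integer(variants$present_in_controls))
  body <- paste(variants$chrom, variants$pos, variants$variant_id,
                variants$ref, variants$alt, ".", "PASS", info, sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a minimal VCF back into a variant table
#'
#' Uses \pkg{vcfR} to parse the records and INFO fields written by
#' \code{\link{write_variants_vcf}}.
#'
#' @param path VCF path.
#' @return variant data.frame in the package's column layout.
#' @export
read_variants_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- v@fix
  gi <- function(key, num = TRUE) {
    x <- vcfR::extract.info(v, element = key)
    if (num) suppressWarnings(as.numeric(x)) else x
  }
  data.frame(
    variant_id = fx[, "ID"], chrom = fx[, "CHROM"],
    pos = as.integer(fx[, "POS"]), ref = fx[, "REF"], alt = fx[, "ALT"],
    gene = gi("GENE", FALSE), consequence = gi("CSQ", FALSE),
    lof_hc = gi("LOF_HC") == 1,
    mpc = gi("MPC"), cadd = gi("CADD"),
    ac_insample = as.integer(gi("AC")), an_insample = as.integer(gi("AN")),
    hom_insample = as.integer(gi("HOM")),
    af_fin = gi("AF_FIN"), af_nfe = gi("AF_NFE"),
    af_afr = gi("AF_AFR"), af_eas = gi("AF_EAS"),
    ref_ac = as.integer(gi("REF_AC")), ref_hom = as.integer(gi("REF_HOM")),
    present_in_controls = gi("IN_CONTROLS") == 1,
    stringsAsFactors = FALSE)
}
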