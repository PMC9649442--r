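#' Feature schema for the binary genomic alteration matrix
#'
#' The reference schema describes the 186 binary genomic alterations used for
#' cohort stratification: 58 coding drivers, 36 recurrent copy-number
#' alterations (CNAs), 44 noncoding drivers, 12 pathway-burden indicators,
#' 28 global genome features (mutational-signature exposures, telomere
#' metrics, lesion burdens) and the 8 genomic-complexity (GC) groups. Each
#' feature carries a binarization rule: `presence` (lesion present/absent)
#' or `median` (continuous value dichotomized at the cohort median).
#'
#' The schema ships as a versioned YAML file; users may substitute their own
#' (for example with different driver panels) as long as the same fields are
#' present. All category-count checks downstream are driven by the schema,
#' not hard-coded.
#'
#' @param path Path to a schema YAML file. Defaults to the reference schema
#'   shipped with the package.
#' @return An object of class `FeatureSchema`: a list with `features`
#'   (data.frame: `id`, `category`, `rule`), `category_counts` (named
#'   integer vector) and `version`.
#' @export
#' @examples
#' sch <- feature_schema()
#' sum(sch$category_counts)  # 186
feature_schema <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "feature_schema.yaml", package = "cllstrat")
  }
  raw <- yaml::read_yaml(path)
  feats <- do.call(rbind, lapply(raw$features, function(f) {
    data.frame(id = f$id, category = f$category, rule = f$rule,
               stringsAsFactors = FALSE)
  }))
  new_feature_schema(feats, version = raw$version %||% "unversioned")
}

#' Construct a FeatureSchema from a feature table
#'
#' @param features data.frame with columns `id`, `category`, `rule`.
#' @param version Version string recorded in the object.
#' @return A `FeatureSchema`.
#' @export
new_feature_schema <- function(features, version = "custom") {
  stopifnot(all(c("id", "category", "rule") %in% names(features)))
  if (anyDuplicated(features$id) > 0L)
    abort2("duplicate feature ids in schema", "cllstrat_schema_error")
  valid <- c("coding_driver", "recurrent_cna", "noncoding_driver",
             "pathway", "global", "gc_group")
  if (!all(features$category %in% valid))
    abort2("unknown feature category in schema", "cllstrat_schema_error")
  counts <- table(factor(features$category, levels = valid))
  structure(list(features = features,
                 category_counts = setNames(as.integer(counts), valid),
                 version = version),
            class = "FeatureSchema")
}

#' @export
print.FeatureSchema <- function(x, ...) {
  cat("FeatureSchema (version ", x$version, "): ",
      nrow(x$features), " features\n", sep = "")
  print(x$category_counts)
  invisible(x)
}

#' The 17 binary genome-wide measures used for genomic-complexity MCA
#'
#' Four burden/length measures are dichotomized at the cohort median
#' (`median` rule); the remaining thirteen are presence/absence flags.
#'
#' @return data.frame with columns `id` and `rule`, exactly 17 rows.
#' @export
mca_measures <- function() {
  data.frame(
    id = c("snv_count", "indel_count", "telomere_length", "telomere_content",
           "sv_breakpoint", "cna", "cn_gain", "cn_loss", "cnloh", "trisomy",
           "aneuploidy", "cn_gain_excl_trisomy", "cn_loss_excl_aneuploidy",
           "cnloh_excl_whole_chrom", "inversion", "translocation",
           "chromothripsis"),
    rule = c(rep("median", 4L), rep("presence", 13L)),
    stringsAsFactors = FALSE
  )
}

# Internal builder for the reference schema; the shipped YAML is generated
# from this table (kept for regeneration, not exported).
default_feature_table <- function() {
  coding <- c("TP53", "ATM", "NOTCH1", "SF3B1", "BIRC3", "MYD88", "XPO1",
              "POT1", "CHD2", "EGR2", "BRAF", "KRAS", "NRAS", "DDX3X",
              "FBXW7", "MED12", "NFKBIE", "RPS15", "ZMYM3", "TRAF3",
              "BAZ2A", "IKZF3", "SETD2", "ASXL1", "BCOR", "CREBBP", "MGA",
              "NXF1", "PTPN11", "RIPK1", "SAMHD1", "ZNF292", "IRF2BP2",
              "SMCHD1", "PCM1", "KLHL6", "ITPKB", "CCND2", "FAM50A",
              "GPS2", "PIM1", "CARD11", "TNFAIP3", "ARID1A", "KMT2D",
              "SPEN", "DTX1", "FUBP1", "U2AF1", "ELF4", "IRF4", "BTG1",
              "BCL2", "MAP2K1", "CHEK2", "PAX5", "TCF4", "HIST1H1E")
  cna <- c("del13q14.2", "tri12", "del11q22.3", "del17p13.1", "del6q21",
           "del8p21", "gain8q24", "del18p11.32", "del1q42.2", "gain2p25.3",
           "del3p21.31", "del9p21.3", "gain17q21.31", "del10q24",
           "del14q24", "gain18q21", "del15q15.1", "del7q31", "gain19p13",
           "del4p15", "del2q37", "gain3q26", "del5q31", "gain1q23",
           "del12p13", "gain21q22", "del16q12", "gain20q13", "del22q11",
           "delXp22", "gain5p15", "del19q13", "gain7p22", "del20p12",
           "gain9q34", "del6p25")
  noncoding <- c("NOTCH1_3UTR", "IGLL5_5UTR", "BCL2_5UTR", "NFKBIZ_3UTR",
                 "BIRC3_prom", "IKZF3_prom", "TP53_prom", "BACH2_prom",
                 paste0("PAX5_enh", 1:6), paste0("BCL6_enh", 1:7),
                 "LEF1_prom", "BTG2_prom", "ZNF292_prom", "CXCR4_3UTR",
                 "TCL1A_enh", "MIR142_prom", "ST6GAL1_enh", "DLEU2_prom",
                 "RHOH_5UTR", "BCL7A_prom", "IRF8_enh", "EBF1_enh",
                 "IKZF1_prom", "FOXO1_enh", "CD79B_prom", "POU2F2_enh",
                 "SPIB_prom", "ARID5B_enh", "KLF2_prom", "ZEB2_enh",
                 "CIITA_prom", "BANK1_enh", "BLK_prom")
  pathway <- c("DNA_damage_cell_cycle", "RNA_ribosome_processing",
               "NOTCH_signaling", "NFKB_signaling", "BCR_signaling",
               "MAPK_RAS", "PI3K_AKT", "WNT_signaling",
               "Chromatin_remodeling", "JAK_STAT", "Apoptosis_BCL2",
               "Transcription_factor_network")
  glob <- c("SBS1", "SBS5", "SBS8", "SBS9", "SBS18", "DBS2", "DBS11",
            "ID2", "ID83C", "telomere_length_short", "telomere_content_low",
            "snv_burden_high", "indel_burden_high", "sv_burden_high",
            "translocation_any", "inversion_any", "duplication_any",
            "kataegis_any", "chromothripsis", "aneuploidy", "cnloh_any",
            "whole_genome_doubling", "breakpoint_count_high",
            "del_count_high", "gain_count_high", "clonal_fraction_high",
            "subclonal_burden_high", "driver_count_high")
  gc <- paste0("GC", 1:8)
  rbind(
    data.frame(id = paste0("CD_", coding), category = "coding_driver",
               rule = "presence", stringsAsFactors = FALSE),
    data.frame(id = paste0("CNA_", cna), category = "recurrent_cna",
               rule = "presence", stringsAsFactors = FALSE),
    data.frame(id = paste0("NC_", noncoding), category = "noncoding_driver",
               rule = "presence", stringsAsFactors = FALSE),
    data.frame(id = paste0("PW_", pathway), category = "pathway",
               rule = "presence", stringsAsFactors = FALSE),
    data.frame(id = paste0("GL_", glob), category = "global",
               rule = c(rep("median", 14L), rep("presence", 8L),
                        rep("median", 6L)),
               stringsAsFactors = FALSE),
    data.frame(id = gc, category = "gc_group", rule = "presence",
               stringsAsFactors = FALSE)
  )
}
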