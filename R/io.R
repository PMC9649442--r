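#' Write a synthetic cohort to disk
#'
#' Emits the feature matrix as a patients x features {0,1} TSV, the clinical
#' covariates and survival records as TSVs, and a JSON sidecar with the true
#' subgroup labels and the generating spec's scalar parameters.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the written file paths.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fm <- file.path(dir, "feature_matrix.tsv")
  cl <- file.path(dir, "clinical.tsv")
  sv <- file.path(dir, "survival.tsv")
  js <- file.path(dir, "truth.json")
  write.table(cohort$feature_matrix$values, fm, sep = "\t", quote = FALSE,
              col.names = NA)
  write.table(cohort$covariates, cl, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(cohort$survival, sv, sep = "\t", quote = FALSE,
              row.names = FALSE)
  spec <- cohort$spec
  jsonlite::write_json(
    list(true_labels = as.list(cohort$true_labels),
         n_patients = spec$n_patients, ighv_split = spec$ighv_split,
         noise_flip_prob = spec$noise_flip_prob,
         censor_rate = spec$censor_rate, seed = spec$seed),
    js, auto_unbox = TRUE, digits = NA)
  invisible(c(fm, cl, sv, js))
}

#' Read a feature-matrix TSV written by [write_cohort()]
#'
#' @param path TSV path.
#' @param schema Optional [feature_schema()] to attach (validated).
#' @return Matrix, or `BinaryFeatureMatrix` when a schema is supplied.
#' @export
read_feature_matrix <- function(path, schema = NULL) {
  m <- as.matrix(read.table(path, sep = "\t", header = TRUE,
                            row.names = 1L, check.names = FALSE))
  storage.mode(m) <- "integer"
  if (is.null(schema)) m else new_binary_feature_matrix(m, schema)
}

#' Write variant calls as a minimal VCF v4.2
#'
#' One-sample somatic VCF with depth/alt-read/annotation INFO fields
#' sufficient to round-trip the filter engine's inputs. Positions are
#' 1-based per VCF.
#'
#' @param calls Variant table (see [generate_variant_table()]).
#' @param path Output path.
#' @param sample_id Sample name written in the header.
#' @return Invisibly, `path`.
#' @export
write_variant_vcf <- function(calls, path, sample_id = "TUMOR") {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=cllstrat",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Tumor depth\">",
    "##INFO=<ID=AD,Number=1,Type=Integer,Description=\"Tumor alt reads\">",
    "##INFO=<ID=NDP,Number=1,Type=Integer,Description=\"Normal depth\">",
    "##INFO=<ID=POPAF,Number=1,Type=Float,Description=\"Population AF\">",
    "##INFO=<ID=VQSR,Number=1,Type=Float,Description=\"VQSR score\">",
    "##INFO=<ID=PANEL,Number=1,Type=Float,Description=\"Somatic panel Phred\">",
    paste0("#", paste(c("CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO"), collapse = "\t")))
  body <- if (nrow(calls) == 0L) character(0) else
    paste(calls$chrom, calls$pos, ".", calls$ref, calls$alt,
          calls$quality_score, calls$filter_flag,
          sprintf("DP=%d;AD=%d;NDP=%d;POPAF=%g;VQSR=%g;PANEL=%g",
                  calls$tumor_depth, calls$tumor_alt_reads,
                  calls$normal_depth, calls$population_af,
                  calls$vqsr_score, calls$somatic_panel_phred),
          sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a VCF written by [write_variant_vcf()] back into a variant table
#'
#' @param path VCF path.
#' @return data.frame with the filter engine's column contract.
#' @export
read_variant_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (length(body) == 0L) return(empty_variant_table()[, 1:15])
  f <- strsplit(body, "\t", fixed = TRUE)
  info_val <- function(info, key) {
    m <- regmatches(info, regexpr(paste0(key, "=[^;]+"), info))
    as.numeric(sub(paste0(key, "="), "", m))
  }
  info <- vapply(f, `[[`, "", 8L)
  data.frame(
    chrom = vapply(f, `[[`, "", 1L),
    pos = as.integer(vapply(f, `[[`, "", 2L)),
    ref = vapply(f, `[[`, "", 4L),
    alt = vapply(f, `[[`, "", 5L),
    tumor_depth = as.integer(info_val(info, "DP")),
    tumor_alt_reads = as.integer(info_val(info, "AD")),
    normal_depth = as.integer(info_val(info, "NDP")),
    filter_flag = vapply(f, `[[`, "", 7L),
    quality_score = as.numeric(vapply(f, `[[`, "", 6L)),
    population_af = info_val(info, "POPAF"),
    vqsr_score = info_val(info, "VQSR"),
    recurrence_cohort_af = 0,
    repeat_overlap = FALSE,
    indel_proximity_flag = FALSE,
    somatic_panel_phred = info_val(info, "PANEL"),
    stringsAsFactors = FALSE)
}

#' Write intervals as BED (0-based half-open)
#'
#' @param intervals data.frame with `chrom`, `start`, `end` and optional
#'   `name`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(intervals, path) {
  df <- intervals[, c("chrom", "start", "end")]
  if ("name" %in% names(intervals)) df$name <- intervals$name
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write CNA segments as a SEG-style TSV (1-based inclusive)
#'
#' @param segments CNA segment data.frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_seg <- function(segments, path) {
  write.table(segments, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
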