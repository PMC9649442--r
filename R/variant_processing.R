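#' Somatic SNV/indel filter policy
#'
#' Thresholds for the somatic small-variant filter chain. Defaults follow a
#' stringent whole-genome pipeline: tumor depth strictly greater than 10,
#' allele fraction at least 0.05, PASS flag with quality strictly greater
#' than 30, population allele frequency below 0.05 (catalog) and 0.01
#' (cohort germline), cohort somatic recurrence at most 5%, VQSR score at
#' least 2.75 when present, and somatic panel-of-normals Phred at least 80.
#'
#' @param min_depth Tumor depth threshold (strict `>`), default 10.
#' @param min_af Minimum tumor allele fraction (`>=`), default 0.05.
#' @param min_quality Quality score threshold (strict `>`), default 30.
#' @param max_population_af Catalog population AF cut (`<`), default 0.05.
#' @param max_germline_af Cohort germline AF cut (`<`), default 0.01.
#' @param max_cohort_recurrence Somatic cohort recurrence cut (`<=`),
#'   default 0.05.
#' @param min_vqsr VQSR score floor; records with `vqsr_score < min_vqsr`
#'   are removed when the field is present (NA ignores the rule).
#' @param min_somatic_panel_phred Panel-of-normals Phred floor (`>=`).
#' @return A `FilterPolicy` list.
#' @export
filter_policy <- function(min_depth = 10, min_af = 0.05, min_quality = 30,
                          max_population_af = 0.05, max_germline_af = 0.01,
                          max_cohort_recurrence = 0.05, min_vqsr = 2.75,
                          min_somatic_panel_phred = 80) {
  vals <- c(min_depth, min_af, min_quality, max_population_af,
            max_germline_af, max_cohort_recurrence, min_vqsr,
            min_somatic_panel_phred)
  if (any(vals < 0))
    abort2("all thresholds must be nonnegative", "cllstrat_config_error")
  structure(list(min_depth = min_depth, min_af = min_af,
                 min_quality = min_quality,
                 max_population_af = max_population_af,
                 max_germline_af = max_germline_af,
                 max_cohort_recurrence = max_cohort_recurrence,
                 min_vqsr = min_vqsr,
                 min_somatic_panel_phred = min_somatic_panel_phred),
            class = "FilterPolicy")
}

#' Filter somatic SNV/indel calls
#'
#' Applies the policy's rules in the order they are defined; each removed
#' record is annotated with the first failing rule. Kept records satisfy
#' every rule. Rules whose annotation column is absent or NA are skipped
#' for that record (non-VQSR caller dialects, missing panel scores).
#'
#' @param calls data.frame of `VariantCall` records (see
#'   [generate_variant_table()] for the column contract).
#' @param policy A [filter_policy()].
#' @return list with `kept` and `removed` data.frames; `removed` has a
#'   `reason` column naming the first failing rule.
#' @export
filter_snv_indels <- function(calls, policy = filter_policy()) {
  stopifnot(inherits(policy, "FilterPolicy"))
  if (nrow(calls) == 0L)
    return(list(kept = calls, removed = cbind(calls, reason = character(0))))
  if (any(calls$tumor_depth < 0, na.rm = TRUE))
    abort2("negative tumor depth", "cllstrat_validation_error")
  if (any(calls$tumor_alt_reads > calls$tumor_depth, na.rm = TRUE))
    abort2("alt reads exceed depth", "cllstrat_validation_error")

  vaf <- ifelse(calls$tumor_depth > 0,
                calls$tumor_alt_reads / calls$tumor_depth, 0)
  col <- function(nm) if (nm %in% names(calls)) calls[[nm]] else NA
  # ordered rule list: TRUE = record fails this rule
  rules <- list(
    min_depth = !(calls$tumor_depth > policy$min_depth),
    min_af = !(vaf >= policy$min_af),
    filter_flag = col("filter_flag") != "PASS",
    min_quality = !(col("quality_score") > policy$min_quality),
    max_population_af = col("population_af") >= policy$max_population_af,
    max_germline_af = col("germline_af") >= policy$max_germline_af,
    max_cohort_recurrence =
      col("recurrence_cohort_af") > policy$max_cohort_recurrence,
    repeat_overlap = col("repeat_overlap") %in% TRUE,
    indel_proximity = col("indel_proximity_flag") %in% TRUE,
    min_vqsr = col("vqsr_score") < policy$min_vqsr,
    somatic_panel = col("somatic_panel_phred") < policy$min_somatic_panel_phred
  )
  reason <- rep(NA_character_, nrow(calls))
  for (nm in names(rules)) {
    fail <- rules[[nm]]
    fail[is.na(fail)] <- FALSE   # missing annotation: rule not applicable
    hit <- fail & is.na(reason)
    reason[hit] <- nm
  }
  kept <- calls[is.na(reason), , drop = FALSE]
  removed <- calls[!is.na(reason), , drop = FALSE]
  removed$reason <- reason[!is.na(reason)]
  list(kept = kept, removed = removed)
}

#' Cancer cell fraction from VAF, purity and local copy number
#'
#' Standard purity/copy-number rescaling:
#' `ccf = vaf * (purity * CN + (1 - purity) * 2) / (purity * multiplicity)`.
#' When `multiplicity` is `NULL` it is estimated as
#' `max(1, round(vaf * (purity*CN + (1-purity)*2) / purity))`, i.e. the
#' integer copy count most consistent with the observed VAF.
#'
#' @param vaf Variant allele fraction in \[0,1\].
#' @param purity Tumor purity in (0,1].
#' @param local_total_cn Local total copy number in the tumor (integer >= 1).
#' @param multiplicity Copies of the chromosome carrying the variant, or
#'   `NULL` to estimate.
#' @return list with `ccf` and logical `capped` (TRUE when the raw estimate
#'   exceeded 1.05 and was reported capped at that value).
#' @export
compute_ccf <- function(vaf, purity, local_total_cn, multiplicity = NULL) {
  if (purity <= 0 || purity > 1)
    abort2("purity must lie in (0,1]", "cllstrat_domain_error")
  if (vaf < 0 || vaf > 1)
    abort2("vaf must lie in [0,1]", "cllstrat_domain_error")
  denom_cn <- purity * local_total_cn + (1 - purity) * 2
  if (is.null(multiplicity))
    multiplicity <- max(1, round(vaf * denom_cn / purity))
  if (multiplicity > local_total_cn)
    abort2("multiplicity exceeds local copy number",
           "cllstrat_validation_error")
  ccf <- vaf * denom_cn / (purity * multiplicity)
  capped <- ccf > 1.05
  list(ccf = if (capped) 1.05 else ccf, capped = capped)
}

#' Merge structural-variant calls across callers
#'
#' A consensus breakpoint pair is reported when two or more callers report
#' the same SV type with both break-ends within `tolerance` base pairs
#' (matching orientations and chromosomes). Representative coordinates are
#' the per-break-end medians across the supporting callers.
#'
#' @param calls_by_caller Named list (one element per caller) of data.frames
#'   with columns `type`, `chrom1`, `pos1`, `ori1`, `chrom2`, `pos2`, `ori2`
#'   and optionally `allele_fraction`.
#' @param tolerance Break-end matching tolerance in bp (default 100).
#' @return data.frame of consensus pairs with an `n_callers` column.
#' @export
merge_sv_consensus <- function(calls_by_caller, tolerance = 100) {
  if (length(calls_by_caller) < 2L)
    abort2("need calls from at least two callers", "cllstrat_config_error")
  all_calls <- do.call(rbind, lapply(names(calls_by_caller), function(cl) {
    df <- calls_by_caller[[cl]]
    if (is.null(df) || nrow(df) == 0L) return(NULL)
    df$caller <- cl
    df
  }))
  if (is.null(all_calls) || nrow(all_calls) == 0L)
    return(data.frame())
  n <- nrow(all_calls)
  # union-find over pairwise-compatible calls from different callers
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  compatible <- function(i, j) {
    a <- all_calls[i, ]; b <- all_calls[j, ]
    a$type == b$type && a$chrom1 == b$chrom1 && a$chrom2 == b$chrom2 &&
      a$ori1 == b$ori1 && a$ori2 == b$ori2 &&
      abs(a$pos1 - b$pos1) <= tolerance && abs(a$pos2 - b$pos2) <= tolerance
  }
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    if (all_calls$caller[i] != all_calls$caller[j] && compatible(i, j)) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  root <- vapply(seq_len(n), find, 0L)
  out <- lapply(split(seq_len(n), root), function(idx) {
    grp <- all_calls[idx, , drop = FALSE]
    callers <- unique(grp$caller)
    if (length(callers) < 2L) return(NULL)
    data.frame(type = grp$type[1L],
               chrom1 = grp$chrom1[1L],
               pos1 = as.integer(round(median(grp$pos1))),
               ori1 = grp$ori1[1L],
               chrom2 = grp$chrom2[1L],
               pos2 = as.integer(round(median(grp$pos2))),
               ori2 = grp$ori2[1L],
               allele_fraction = if ("allele_fraction" %in% names(grp))
                 median(grp$allele_fraction) else NA_real_,
               n_callers = length(callers),
               callers = paste(sort(callers), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) data.frame() else { rownames(out) <- NULL; out }
}

#' Filter copy-number alteration segments
#'
#' Drops segments with quality below `min_quality` (default 10), removes
#' segments overlapping a supplied centromere/telomere exclusion track,
#' merges adjacent same-state segments on the same chromosome, and keeps
#' only merged segments longer than `min_length` (default 100 kb).
#'
#' @param segments data.frame with columns `chrom`, `start`, `end`
#'   (1-based inclusive), `type` (gain/loss/cnLOH), `total_copy_number`,
#'   `quality`.
#' @param exclusion Optional data.frame (`chrom`, `start`, `end`) of regions
#'   to exclude; a missing track triggers a warning and is skipped.
#' @param min_quality Quality floor (segments with `quality < min_quality`
#'   are removed).
#' @param min_length Minimum merged segment length in bp; segments of
#'   `length <= min_length` are dropped (strictly greater than kept).
#' @param merge_gap Maximum gap in bp between same-state segments merged as
#'   continuous (default 1).
#' @return data.frame of kept (possibly merged) segments.
#' @export
filter_cna <- function(segments, exclusion = NULL, min_quality = 10,
                       min_length = 1e5, merge_gap = 1) {
  if (nrow(segments) == 0L) return(segments)
  if (any(segments$start >= segments$end))
    abort2("segment start must be < end", "cllstrat_validation_error")
  seg <- segments[is.na(segments$quality) | segments$quality >= min_quality,
                  , drop = FALSE]
  if (is.null(exclusion)) {
    warning("no centromere/telomere exclusion track supplied; proceeding")
  } else if (nrow(seg) > 0L) {
    drop <- logical(nrow(seg))
    for (i in seq_len(nrow(exclusion))) {
      drop <- drop | (seg$chrom == exclusion$chrom[i] &
                        seg$start <= exclusion$end[i] &
                        seg$end >= exclusion$start[i])
    }
    seg <- seg[!drop, , drop = FALSE]
  }
  if (nrow(seg) == 0L) return(seg)
  # merge adjacent same-state segments per chromosome, then length filter
  seg <- seg[order(seg$chrom, seg$type, seg$start), , drop = FALSE]
  merged <- list()
  cur <- seg[1L, , drop = FALSE]
  if (nrow(seg) > 1L) for (i in seq(2L, nrow(seg))) {
    s <- seg[i, , drop = FALSE]
    same <- s$chrom == cur$chrom && s$type == cur$type &&
      identical(s$total_copy_number, cur$total_copy_number) &&
      s$start <= cur$end + merge_gap
    if (same) {
      cur$end <- max(cur$end, s$end)
      cur$quality <- max(cur$quality, s$quality)
    } else {
      merged[[length(merged) + 1L]] <- cur
      cur <- s
    }
  }
  merged[[length(merged) + 1L]] <- cur
  out <- do.call(rbind, merged)
  out <- out[(out$end - out$start + 1L) > min_length, , drop = FALSE]
  rownames(out) <- NULL
  out
}
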