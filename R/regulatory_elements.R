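#' @importFrom IRanges IRanges reduce intersect start end
NULL

# intervals: data.frame(chrom, start, end), 0-based half-open internally.
check_intervals <- function(df, what = "intervals") {
  if (any(df$end <= df$start))
    abort2(paste0(what, ": end must be > start (0-based half-open)"),
           "cllstrat_validation_error")
  invisible(TRUE)
}

# per-chromosome IRanges helper (half-open [start,end) -> IRanges start+1..end)
as_ir <- function(df) IRanges::IRanges(start = df$start + 1L, end = df$end)
from_ir <- function(ir, chrom) {
  data.frame(chrom = chrom, start = IRanges::start(ir) - 1L,
             end = IRanges::end(ir), stringsAsFactors = FALSE)
}

#' Build the regulatory-element catalog
#'
#' The catalog is the merged intersection of open-chromatin (ATAC) and
#' H3K27ac peak tracks. Each resulting element is annotated with the
#' chromatin-state class supported by at least two per-sample segmentations
#' (`promoter`, `enhancer`, `UTR5`, `UTR3`); elements whose state is seen in
#' fewer than two samples are emitted with the state unassigned. When
#' IGHV-subgroup tracks are supplied, elements present only in the u- or
#' m-IGHV track are flagged `u-only` / `m-only`, otherwise `common`.
#'
#' @param atac,h3k27ac data.frames (`chrom`, `start`, `end`), 0-based
#'   half-open.
#' @param state_tracks list (one per sample) of data.frames with columns
#'   `chrom`, `start`, `end`, `state`.
#' @param subgroup_tracks Optional list with elements `u` and `m`, each an
#'   interval data.frame.
#' @return data.frame catalog: `chrom`, `start`, `end`, `re_type`,
#'   `state_support`, `ighv_specificity`.
#' @export
build_re_catalog <- function(atac, h3k27ac, state_tracks = list(),
                             subgroup_tracks = NULL) {
  check_intervals(atac, "atac"); check_intervals(h3k27ac, "h3k27ac")
  chroms <- intersect(unique(atac$chrom), unique(h3k27ac$chrom))
  cat_list <- lapply(chroms, function(ch) {
    a <- IRanges::reduce(as_ir(atac[atac$chrom == ch, , drop = FALSE]))
    k <- IRanges::reduce(as_ir(h3k27ac[h3k27ac$chrom == ch, , drop = FALSE]))
    ov <- IRanges::intersect(a, k)
    if (length(ov) == 0L) return(NULL)
    from_ir(ov, ch)
  })
  catalog <- do.call(rbind, cat_list)
  if (is.null(catalog))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), re_type = character(),
                      state_support = integer(),
                      ighv_specificity = character(),
                      stringsAsFactors = FALSE))

  catalog$re_type <- NA_character_
  catalog$state_support <- 0L
  if (length(state_tracks) > 0L) {
    for (i in seq_len(nrow(catalog))) {
      votes <- character(0)
      for (tr in state_tracks) {
        hit <- tr$chrom == catalog$chrom[i] & tr$start < catalog$end[i] &
          tr$end > catalog$start[i]
        if (any(hit)) {
          # the sample's state with the largest overlap of this element
          olap <- pmin(tr$end[hit], catalog$end[i]) -
            pmax(tr$start[hit], catalog$start[i])
          votes <- c(votes, tr$state[hit][which.max(olap)])
        }
      }
      if (length(votes) > 0L) {
        tab <- sort(table(votes), decreasing = TRUE)
        if (tab[1L] >= 2L) {
          catalog$re_type[i] <- names(tab)[1L]
          catalog$state_support[i] <- as.integer(tab[1L])
        } else {
          catalog$state_support[i] <- as.integer(tab[1L])
        }
      }
    }
  }
  catalog$ighv_specificity <- "common"
  if (!is.null(subgroup_tracks)) {
    in_track <- function(track, i) {
      any(track$chrom == catalog$chrom[i] & track$start < catalog$end[i] &
            track$end > catalog$start[i])
    }
    for (i in seq_len(nrow(catalog))) {
      u <- in_track(subgroup_tracks$u, i)
      m <- in_track(subgroup_tracks$m, i)
      catalog$ighv_specificity[i] <-
        if (u && !m) "u-only" else if (m && !u) "m-only" else "common"
    }
  }
  rownames(catalog) <- NULL
  catalog
}

#' Link enhancers to target genes within TADs
#'
#' For every catalog element, every gene whose interval lies in the same TAD
#' is tested by Pearson correlation between the element's signal (e.g.
#' H3K27ac) and the gene's expression across shared samples. BH-FDR is
#' applied across all tested pairs; links with `r >= r_min` and
#' `FDR <= fdr_max` are kept. Pairs with a constant vector are skipped with
#' a warning.
#'
#' @param catalog RE catalog (or any interval data.frame with rownames or an
#'   `re_id` column matching `signal` rows).
#' @param signal RE x sample numeric matrix.
#' @param expr gene x sample numeric matrix.
#' @param tads data.frame (`chrom`, `start`, `end`, `tad_id`), 0-based
#'   half-open.
#' @param gene_intervals data.frame (`gene`, `chrom`, `start`, `end`).
#' @param r_min Minimum Pearson correlation (default 0.3).
#' @param fdr_max Maximum BH-FDR (default 0.05).
#' @return data.frame of links: `re_id`, `gene`, `pearson_r`, `p`, `fdr`,
#'   `tad_id`.
#' @export
link_enhancer_targets <- function(catalog, signal, expr, tads,
                                  gene_intervals, r_min = 0.3,
                                  fdr_max = 0.05) {
  shared <- intersect(colnames(signal), colnames(expr))
  if (length(shared) < 3L)
    abort2("need at least three shared samples", "cllstrat_validation_error")
  signal <- signal[, shared, drop = FALSE]
  expr <- expr[, shared, drop = FALSE]
  re_ids <- catalog$re_id %||% rownames(signal)

  tad_of <- function(chrom, start, end) {
    hit <- tads$chrom == chrom & tads$start <= start & tads$end >= end
    if (!any(hit)) NA_character_ else tads$tad_id[which(hit)[1L]]
  }
  re_tad <- vapply(seq_len(nrow(catalog)), function(i)
    tad_of(catalog$chrom[i], catalog$start[i], catalog$end[i]), "")
  gene_tad <- vapply(seq_len(nrow(gene_intervals)), function(i)
    tad_of(gene_intervals$chrom[i], gene_intervals$start[i],
           gene_intervals$end[i]), "")

  rows <- list()
  skipped <- 0L
  for (i in seq_len(nrow(catalog))) {
    if (is.na(re_tad[i])) next
    genes <- gene_intervals$gene[!is.na(gene_tad) & gene_tad == re_tad[i]]
    x <- signal[re_ids[i], ]
    if (sd(x) == 0) { skipped <- skipped + 1L; next }
    for (g in genes) {
      y <- expr[g, ]
      if (sd(y) == 0) { skipped <- skipped + 1L; next }
      ct <- cor.test(x, y, method = "pearson")
      rows[[length(rows) + 1L]] <- data.frame(
        re_id = re_ids[i], gene = g, pearson_r = unname(ct$estimate),
        p = ct$p.value, tad_id = re_tad[i], stringsAsFactors = FALSE)
    }
  }
  if (skipped > 0L)
    warning(skipped, " constant signal/expression vector(s) skipped")
  tested <- do.call(rbind, rows)
  if (is.null(tested)) return(data.frame())
  tested$fdr <- bh_fdr(tested$p)
  out <- tested[tested$pearson_r >= r_min & tested$fdr <= fdr_max, ,
                drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Test a regulatory element for mutation recurrence, hotspots and kataegis
#'
#' The recurrence p-value is the upper binomial tail
#' `P(X >= n_mutated_samples)` with
#' `X ~ Binom(n_samples, 1 - exp(-background_rate * length))`. A single-site
#' hotspot is any position mutated in at least `hotspot_min` samples; the
#' kataegis flag is raised when one sample carries at least `kataegis_min`
#' mutations within a `kataegis_window`-bp window inside the element.
#'
#' @param re One catalog row (list/data.frame with `chrom`, `start`, `end`).
#' @param mutations data.frame (`sample`, `chrom`, `pos`) of somatic SNVs
#'   (1-based positions).
#' @param n_samples Cohort size.
#' @param background_rate Background mutation rate per bp per sample (> 0).
#' @param hotspot_min Samples per site to call a hotspot (default 3).
#' @param kataegis_min Mutations per window per sample (default 6).
#' @param kataegis_window Window size in bp (default 1000).
#' @return list with `n_mutated_samples`, `p_recurrence`,
#'   `hotspot_positions`, `kataegis_flag`.
#' @export
test_re_recurrence <- function(re, mutations, n_samples, background_rate,
                               hotspot_min = 3L, kataegis_min = 6L,
                               kataegis_window = 1000L) {
  if (background_rate <= 0)
    abort2("background_rate must be > 0", "cllstrat_domain_error")
  len <- re$end - re$start
  if (len <= 0)
    abort2("zero-length regulatory element", "cllstrat_validation_error")
  inside <- mutations$chrom == re$chrom & mutations$pos > re$start &
    mutations$pos <= re$end
  mut <- mutations[inside, , drop = FALSE]
  n_mut <- length(unique(mut$sample))
  pr <- 1 - exp(-background_rate * len)
  p <- if (n_mut == 0L) 1 else
    pbinom(n_mut - 1L, n_samples, pr, lower.tail = FALSE)
  pos_tab <- table(unique(mut[, c("sample", "pos")])$pos)
  hotspots <- as.integer(names(pos_tab)[pos_tab >= hotspot_min])
  kataegis <- FALSE
  for (s in unique(mut$sample)) {
    ps <- sort(mut$pos[mut$sample == s])
    if (length(ps) >= kataegis_min) {
      for (j in seq_len(length(ps) - kataegis_min + 1L)) {
        if (ps[j + kataegis_min - 1L] - ps[j] <= kataegis_window) {
          kataegis <- TRUE; break
        }
      }
    }
    if (kataegis) break
  }
  list(n_mutated_samples = n_mut, p_recurrence = p,
       hotspot_positions = hotspots, kataegis_flag = kataegis)
}

#' Test a whole catalog for recurrently mutated elements
#'
#' Applies [test_re_recurrence()] per element and BH-FDR across the catalog.
#'
#' @inheritParams test_re_recurrence
#' @param catalog RE catalog data.frame.
#' @param fdr_max Significance threshold on the FDR (default 0.1).
#' @return data.frame with per-element counts, p-values, FDR and a
#'   `significant` flag.
#' @export
test_re_catalog <- function(catalog, mutations, n_samples, background_rate,
                            fdr_max = 0.1, ...) {
  res <- lapply(seq_len(nrow(catalog)), function(i)
    test_re_recurrence(catalog[i, ], mutations, n_samples,
                       background_rate, ...))
  out <- catalog
  out$n_mutated_samples <- vapply(res, `[[`, 0L, "n_mutated_samples")
  out$p_recurrence <- vapply(res, `[[`, 0, "p_recurrence")
  out$kataegis_flag <- vapply(res, `[[`, FALSE, "kataegis_flag")
  out$n_hotspots <- vapply(res, function(r) length(r$hotspot_positions), 0L)
  out$fdr <- bh_fdr(out$p_recurrence)
  out$significant <- out$fdr < fdr_max
  out
}

#' Call allelic skew between WGS and a functional assay
#'
#' A variant is skewed when the assay VAF differs from the WGS VAF by more
#' than 0.1 in absolute value and the assay covers the site at least
#' `min_depth` times; positive differences are `alt-skewed`, negative
#' `ref-skewed`, small differences `none`, shallow sites `insufficient`.
#'
#' @param wgs_vaf,assay_vaf VAFs in \[0,1\].
#' @param assay_depth Assay read depth at the site.
#' @param min_depth Depth floor (default 10).
#' @param band Skew threshold on the VAF difference (default 0.1).
#' @return Character scalar: one of `ref-skewed`, `alt-skewed`, `none`,
#'   `insufficient`.
#' @export
call_allelic_skew <- function(wgs_vaf, assay_vaf, assay_depth,
                              min_depth = 10L, band = 0.1) {
  stopifnot(assay_depth >= 0)
  if (assay_depth < min_depth) return("insufficient")
  diff <- assay_vaf - wgs_vaf
  if (diff > band) "alt-skewed"
  else if (diff < -band) "ref-skewed"
  else "none"
}

#' Expression contrast between mutated and wild-type samples
#'
#' Ratio of mean expression (TPM) in mutated vs wild-type samples and a
#' two-sided Welch t-test p-value (Satterthwaite degrees of freedom). With a
#' single mutated sample the ratio is returned and the p-value is NA.
#'
#' @param tpm_mut,tpm_wt Numeric expression vectors, each non-empty.
#' @return list with `ratio`, `t`, `df`, `p` and a `note` for degenerate
#'   cases.
#' @export
expression_contrast <- function(tpm_mut, tpm_wt) {
  if (length(tpm_mut) == 0L || length(tpm_wt) == 0L)
    abort2("both groups must be non-empty", "cllstrat_validation_error")
  mwt <- mean(tpm_wt)
  ratio <- if (mwt == 0) NA_real_ else mean(tpm_mut) / mwt
  note <- if (mwt == 0) "wild-type mean is zero; ratio undefined" else NA
  if (length(tpm_mut) < 2L || length(tpm_wt) < 2L ||
      (sd(tpm_mut) == 0 && sd(tpm_wt) == 0)) {
    if (sd(c(tpm_mut, tpm_wt)) == 0 && length(tpm_mut) >= 2L)
      return(list(ratio = ratio, t = 0, df = NA_real_, p = 1, note = note))
    return(list(ratio = ratio, t = NA_real_, df = NA_real_, p = NA_real_,
                note = note %||% "variance undefined for n < 2"))
  }
  tt <- t.test(tpm_mut, tpm_wt, var.equal = FALSE)
  list(ratio = ratio, t = unname(tt$statistic),
       df = unname(tt$parameter), p = tt$p.value, note = note)
}
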