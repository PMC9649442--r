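#' Weighted Stouffer combination of p-values
#'
#' Transforms each p-value to a normal quantile `z_i = qnorm(1 - p_i)` and
#' returns `1 - pnorm(sum(w_i z_i) / sqrt(sum(w_i^2)))`. Equal weights give
#' the unweighted Stouffer method; the result is invariant to rescaling the
#' weights.
#'
#' @param p Numeric vector of p-values in (0,1).
#' @param w Nonnegative weights, same length as `p` (default equal).
#' @return Combined p-value.
#' @export
combine_stouffer_weighted <- function(p, w = rep(1, length(p))) {
  check_pw(p, w)
  p <- clamp_p(p)
  z <- qnorm(1 - p)
  1 - pnorm(sum(w * z) / sqrt(sum(w^2)))
}

#' Weighted harmonic-mean combination of p-values
#'
#' Returns the normalized weighted harmonic mean `sum(w) / sum(w / p)`. The
#' raw harmonic mean is used as a ranking statistic (no Landau-distribution
#' calibration); it is bounded by the minimum and maximum of the inputs and
#' anti-conservative as a standalone test for small numbers of tests.
#'
#' @inheritParams combine_stouffer_weighted
#' @return Combined p-value.
#' @export
combine_hmp_weighted <- function(p, w = rep(1, length(p))) {
  check_pw(p, w)
  p <- clamp_p(p)
  sum(w) / sum(w / p)
}

check_pw <- function(p, w) {
  if (length(p) < 1L || length(p) != length(w))
    abort2("p and w must be non-empty and of equal length",
           "cllstrat_validation_error")
  if (all(w == 0))
    abort2("weights must not all be zero", "cllstrat_validation_error")
  if (any(w < 0))
    abort2("weights must be nonnegative", "cllstrat_validation_error")
  invisible(TRUE)
}

clamp_p <- function(p, eps = 1e-15) {
  if (any(p <= 0 | p >= 1)) {
    warning("p-values at 0 or 1 clamped to [eps, 1-eps]")
    p <- pmin(pmax(p, eps), 1 - eps)
  }
  p
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values with monotonicity enforcement, order-preserving
#' in the input. Thin wrapper over [stats::p.adjust()].
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted q-values, same order as input.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0L)
    abort2("p must be non-empty", "cllstrat_validation_error")
  p.adjust(p, method = "BH")
}

#' Select candidate coding drivers by multi-algorithm voting (method 1)
#'
#' A gene is selected when at least two of the four per-algorithm FDRs fall
#' below `alpha` (method 1A), or when the FDR of the weighted-Stouffer or
#' weighted-harmonic-mean combined p-value does (method 1B). The provenance
#' column records which route(s) fired.
#'
#' @param results data.frame with columns `gene`, `p1`..`p4` (per-algorithm
#'   p-values over a common gene universe).
#' @param alpha FDR significance threshold (default 0.05).
#' @param weights Length-4 nonnegative algorithm weights (default equal).
#' @return data.frame with per-gene FDRs, combined statistics, logical
#'   `selected` and a `route` provenance string.
#' @export
select_drivers_method1 <- function(results, alpha = 0.05,
                                   weights = rep(1, 4)) {
  pcols <- grep("^p[0-9]+$", names(results), value = TRUE)
  if (length(pcols) != 4L)
    abort2("results must carry exactly four p-value columns p1..p4",
           "cllstrat_validation_error")
  P <- as.matrix(results[, pcols])
  if (any(!is.finite(P)))
    abort2("non-finite p-values", "cllstrat_validation_error")
  fdr_alg <- apply(P, 2L, bh_fdr)
  if (is.null(dim(fdr_alg)))   # single-gene input: apply drops dimensions
    fdr_alg <- matrix(fdr_alg, nrow = 1L)
  n_sig <- rowSums(fdr_alg < alpha)
  p_st <- apply(P, 1L, combine_stouffer_weighted, w = weights)
  p_hm <- apply(P, 1L, combine_hmp_weighted, w = weights)
  fdr_st <- bh_fdr(p_st)
  fdr_hm <- bh_fdr(p_hm)
  route <- character(nrow(results))
  r1a <- n_sig >= 2L
  r_st <- fdr_st < alpha
  r_hm <- fdr_hm < alpha
  route <- mapply(function(a, s, h) {
    paste(c(if (a) "2of4", if (s) "stouffer", if (h) "hmp"), collapse = "+")
  }, r1a, r_st, r_hm)
  data.frame(gene = results$gene,
             fdr_alg1 = fdr_alg[, 1L], fdr_alg2 = fdr_alg[, 2L],
             fdr_alg3 = fdr_alg[, 3L], fdr_alg4 = fdr_alg[, 4L],
             combined_p_stouffer = p_st, combined_p_hmp = p_hm,
             fdr_stouffer = fdr_st, fdr_hmp = fdr_hm,
             selected = r1a | r_st | r_hm,
             route = ifelse(route == "", NA_character_, route),
             stringsAsFactors = FALSE)
}

#' Baseline per-gene recurrence test
#'
#' A simple length-adjusted binomial recurrence test so the discovery
#' pipeline runs end-to-end without external algorithm output: for each gene,
#' the number of mutated samples is compared against
#' `Binom(n_samples, 1 - exp(-background_rate * length))`.
#'
#' @param mutated_samples Named integer vector: mutated-sample count per gene.
#' @param gene_length Named numeric vector of coding lengths (bp), same genes.
#' @param n_samples Cohort size.
#' @param background_rate Background mutation rate per bp per sample.
#' @return data.frame with `gene`, `p`.
#' @export
gene_recurrence_test <- function(mutated_samples, gene_length, n_samples,
                                 background_rate) {
  stopifnot(length(mutated_samples) == length(gene_length))
  pr <- 1 - exp(-background_rate * gene_length)
  p <- pbinom(mutated_samples - 1L, n_samples, pr, lower.tail = FALSE)
  data.frame(gene = names(mutated_samples), p = as.numeric(p),
             stringsAsFactors = FALSE)
}

#' Minimally affected regions recurrently hit by CNAs
#'
#' For each alteration type (gain/loss) a sweep-line over per-sample merged
#' segment endpoints finds maximal intervals where the number of distinct
#' covering samples is at least `min_samples`; within each such interval the
#' maximum-coverage core (the minimal overlap region) is reported, with its
#' peak sample count. Coordinates are 1-based inclusive.
#'
#' @param segments data.frame with columns `sample`, `chrom`, `start`, `end`
#'   (1-based inclusive), `type` in `{gain, loss}`.
#' @param min_samples Minimum number of distinct samples (default 4).
#' @param annotation Optional gene annotation data.frame (`gene`, `chrom`,
#'   `start`, `end`) used to list member genes per region.
#' @return data.frame of regions: `chrom`, `start`, `end`, `type`,
#'   `n_samples`, `member_genes`.
#' @export
minimally_affected_regions <- function(segments, min_samples = 4L,
                                       annotation = NULL) {
  if (nrow(segments) == 0L) return(data.frame())
  out <- list()
  for (ty in unique(segments$type)) {
    st <- segments[segments$type == ty, , drop = FALSE]
    for (ch in unique(st$chrom)) {
      sc <- st[st$chrom == ch, , drop = FALSE]
      # merge per sample so one sample never counts twice at a base
      per_sample <- lapply(split(sc, sc$sample), merge_intervals_1b)
      ivs <- do.call(rbind, per_sample)
      if (is.null(ivs) || nrow(ivs) == 0L) next
      # sweep-line: +1 at start, -1 at end+1 (1-based inclusive)
      ev <- rbind(data.frame(pos = ivs$start, d = 1L),
                  data.frame(pos = ivs$end + 1L, d = -1L))
      ev <- stats::aggregate(d ~ pos, data = ev, FUN = sum)
      ev <- ev[order(ev$pos), , drop = FALSE]
      cov <- cumsum(ev$d)
      # piecewise-constant coverage on [pos_i, pos_{i+1}-1]
      seg_start <- ev$pos[-length(ev$pos)]
      seg_end <- ev$pos[-1L] - 1L
      seg_cov <- cov[-length(cov)]
      ok <- seg_cov >= min_samples & seg_start <= seg_end
      if (!any(ok)) next
      # group contiguous qualifying pieces into maximal intervals
      runs <- split(which(ok), cumsum(c(1L, diff(which(ok)) != 1L)))
      for (r in runs) {
        peak <- max(seg_cov[r])
        core <- r[seg_cov[r] == peak]
        # first maximal-coverage run inside the region is the reported core
        core_runs <- split(core, cumsum(c(1L, diff(core) != 1L)))
        cr <- core_runs[[1L]]
        out[[length(out) + 1L]] <- data.frame(
          chrom = ch, start = seg_start[cr[1L]],
          end = seg_end[cr[length(cr)]], type = ty,
          n_samples = peak, stringsAsFactors = FALSE)
      }
    }
  }
  regions <- do.call(rbind, out)
  if (is.null(regions)) return(data.frame())
  regions <- regions[order(regions$chrom, regions$start), , drop = FALSE]
  rownames(regions) <- NULL
  regions$member_genes <- ""
  if (!is.null(annotation)) {
    for (i in seq_len(nrow(regions))) {
      hit <- annotation$chrom == regions$chrom[i] &
        annotation$start <= regions$end[i] &
        annotation$end >= regions$start[i]
      regions$member_genes[i] <- paste(annotation$gene[hit], collapse = ",")
    }
  }
  regions
}

# merge overlapping/adjacent 1-based inclusive intervals of one sample
merge_intervals_1b <- function(df) {
  df <- df[order(df$start), , drop = FALSE]
  if (nrow(df) <= 1L) return(df[, c("start", "end"), drop = FALSE])
  starts <- df$start; ends <- df$end
  out_s <- starts[1L]; out_e <- ends[1L]
  res <- list()
  for (i in seq(2L, nrow(df))) {
    if (starts[i] <= out_e + 1L) {
      out_e <- max(out_e, ends[i])
    } else {
      res[[length(res) + 1L]] <- c(out_s, out_e)
      out_s <- starts[i]; out_e <- ends[i]
    }
  }
  res[[length(res) + 1L]] <- c(out_s, out_e)
  m <- do.call(rbind, res)
  data.frame(start = m[, 1L], end = m[, 2L])
}

#' Focality and recurrence scores for a gene (CNA + SNV integration)
#'
#' Following the MutComFocal construction: for every sample whose lesions
#' cover the gene, the recurrence contribution is `1 / (number of lesions in
#' that sample)` and the focality contribution is `1 / (number of genes
#' spanned by the lesion covering the gene)` (the minimum across covering
#' lesions when several do). Both sums are normalized by cohort size and the
#' combined score is their product.
#'
#' @param gene Gene symbol.
#' @param lesions data.frame with columns `sample`, `chrom`, `start`, `end`
#'   (lesion footprints, 1-based inclusive).
#' @param annotation Gene annotation data.frame (`gene`, `chrom`, `start`,
#'   `end`).
#' @param n_samples Cohort size used for normalization (default: number of
#'   distinct samples in `lesions`).
#' @return list with `gene`, `recurrence_score`, `focality_score`,
#'   `combined_score`, `n_altered_samples`.
#' @export
focality_recurrence <- function(gene, lesions, annotation,
                                n_samples = length(unique(lesions$sample))) {
  g <- annotation[annotation$gene == gene, , drop = FALSE]
  if (nrow(g) != 1L)
    abort2("gene not present (once) in annotation", "cllstrat_validation_error")
  rec <- 0; foc <- 0; altered <- 0L
  for (s in unique(lesions$sample)) {
    ls <- lesions[lesions$sample == s, , drop = FALSE]
    covers <- ls$chrom == g$chrom & ls$start <= g$end & ls$end >= g$start
    if (!any(covers)) next
    altered <- altered + 1L
    rec <- rec + 1 / nrow(ls)
    spans <- vapply(which(covers), function(i) {
      n_genes <- sum(annotation$chrom == ls$chrom[i] &
                       annotation$start <= ls$end[i] &
                       annotation$end >= ls$start[i])
      if (n_genes == 0L)
        abort2("lesion spans zero annotated genes",
               "cllstrat_validation_error")
      n_genes
    }, 0L)
    foc <- foc + 1 / min(spans)
  }
  rec <- rec / n_samples
  foc <- foc / n_samples
  list(gene = gene, recurrence_score = rec, focality_score = foc,
       combined_score = rec * foc, n_altered_samples = altered)
}

#' Select candidate drivers from focality/recurrence scores (method 2)
#'
#' A gene is a candidate driver when it carries at least `min_snv`
#' SNVs/indels in the coding sequence, both its focality and recurrence
#' scores exceed `score_threshold`, and its mechanism of action agrees with
#' the CNA direction (loss for tumor-suppressor genes, gain for oncogenes).
#' Genes failing only the SNV/indel count form the permissive list.
#'
#' @param fr data.frame with columns `gene`, `recurrence_score`,
#'   `focality_score`, `snv_indel_count`, `mechanism` (`TSG`, `oncogene`,
#'   `unknown`) and `cna_type` (`loss`/`gain`).
#' @param score_threshold Threshold both scores must exceed; default the
#'   95th percentile of the cohort combined-score distribution.
#' @param min_snv Minimum coding SNV/indel count (default 5).
#' @return list with `candidates` and `permissive` character vectors.
#' @export
select_drivers_method2 <- function(fr,
                                   score_threshold =
                                     unname(quantile(
                                       fr$recurrence_score * fr$focality_score,
                                       0.95)),
                                   min_snv = 5L) {
  concordant <- (fr$mechanism == "TSG" & fr$cna_type == "loss") |
    (fr$mechanism == "oncogene" & fr$cna_type == "gain")
  scores_ok <- fr$recurrence_score > score_threshold &
    fr$focality_score > score_threshold
  base <- scores_ok & concordant
  candidates <- fr$gene[base & fr$snv_indel_count >= min_snv]
  permissive <- fr$gene[base & fr$snv_indel_count < min_snv]
  list(candidates = candidates, permissive = permissive)
}
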