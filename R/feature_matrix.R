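#' Construct a BinaryFeatureMatrix
#'
#' @param values patients x features matrix in {0,1} with dimnames.
#' @param schema A [feature_schema()] whose ids match the columns.
#' @return A `BinaryFeatureMatrix` list (`patients`, `values`, `schema`).
#' @export
new_binary_feature_matrix <- function(values, schema) {
  if (anyNA(values))
    abort2("feature matrix must not contain missing values",
           "cllstrat_validation_error")
  if (!all(values %in% c(0L, 1L)))
    abort2("feature matrix must be binary", "cllstrat_validation_error")
  if (!identical(colnames(values), schema$features$id))
    abort2("matrix columns must match schema feature ids (in order)",
           "cllstrat_schema_error")
  structure(list(patients = rownames(values), values = values,
                 schema = schema),
            class = "BinaryFeatureMatrix")
}

#' @export
print.BinaryFeatureMatrix <- function(x, ...) {
  cat("BinaryFeatureMatrix:", nrow(x$values), "patients x",
      ncol(x$values), "features\n")
  invisible(x)
}

#' Binarize a continuous variable at the cohort median
#'
#' Returns 1 when the value is greater than or equal to the cohort median
#' (computed over non-missing values), 0 otherwise. Ties at the median map
#' to 1.
#'
#' @param values Numeric vector with at least one non-missing value.
#' @return Integer vector in {0,1} (NA preserved).
#' @export
binarize_continuous <- function(values) {
  if (all(is.na(values)))
    abort2("all values missing", "cllstrat_validation_error")
  med <- median(values, na.rm = TRUE)
  as.integer(values >= med)
}

#' Combine SNV/indel and CNA presence for a coding driver (union)
#'
#' @param snv_present,cna_present Aligned binary vectors.
#' @return Element-wise OR as integer.
#' @export
combine_gene_feature <- function(snv_present, cna_present) {
  if (length(snv_present) != length(cna_present))
    abort2("length mismatch", "cllstrat_validation_error")
  as.integer(snv_present | cna_present)
}

#' Merge significantly co-occurring same-chromosome CNA features
#'
#' Computes the mean-square contingency coefficient (phi) for every pair of
#' CNA features on the same chromosome,
#' `phi = (ad - bc) / sqrt((a+b)(c+d)(a+c)(b+d))` on the 2x2 presence table,
#' and union-merges the transitive closure of pairs with `phi > phi_min`.
#' Degenerate (all-0 or all-1) features have undefined phi and are never
#' merged.
#'
#' @param cna_features patients x features binary matrix (CNA features only).
#' @param chrom_of Named character vector: chromosome per feature id.
#' @param phi_min Merge threshold (default 0.3).
#' @return list with `matrix` (merged features, columns named by joined ids)
#'   and `clusters` (list of merged id groups).
#' @export
merge_cooccurring_cnas <- function(cna_features, chrom_of, phi_min = 0.3) {
  ids <- colnames(cna_features)
  k <- length(ids)
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (k > 1L) for (i in seq_len(k - 1L)) for (j in seq(i + 1L, k)) {
    if (chrom_of[ids[i]] != chrom_of[ids[j]]) next
    ph <- phi_2x2(cna_features[, i], cna_features[, j])
    if (!is.na(ph) && ph > phi_min) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  root <- vapply(seq_len(k), find, 0L)
  groups <- split(ids, root)
  cols <- lapply(groups, function(g) {
    as.integer(rowSums(cna_features[, g, drop = FALSE]) > 0L)
  })
  m <- do.call(cbind, cols)
  colnames(m) <- vapply(groups, paste, "", collapse = "+")
  rownames(m) <- rownames(cna_features)
  # preserve input feature order via first member
  ord <- order(vapply(groups, function(g) match(g[1L], ids), 0L))
  list(matrix = m[, ord, drop = FALSE], clusters = unname(groups[ord]))
}

#' Phi (mean-square contingency) coefficient for two binary vectors
#' @param x,y Binary vectors.
#' @return phi, or NA when a margin is degenerate.
#' @export
phi_2x2 <- function(x, y) {
  a <- sum(x == 1 & y == 1); b <- sum(x == 1 & y == 0)
  c_ <- sum(x == 0 & y == 1); d <- sum(x == 0 & y == 0)
  denom <- sqrt(as.numeric(a + b) * (c_ + d) * (a + c_) * (b + d))
  if (denom == 0) return(NA_real_)
  (a * d - b * c_) / denom
}

#' Prevalence filter for binary features
#'
#' Drops features with fewer than `min_count` carriers; noncoding-driver
#' features additionally require prevalence strictly above `nc_min_prev`
#' of the cohort.
#'
#' @param matrix patients x features binary matrix.
#' @param categories Optional named character vector (per feature id) used
#'   for the noncoding rule; features labelled `noncoding_driver` get the
#'   extra prevalence requirement.
#' @param min_count Minimum carrier count (default 5).
#' @param nc_min_prev Minimum prevalence for noncoding drivers (default
#'   0.05, strict `>`).
#' @return The filtered matrix.
#' @export
prevalence_filter <- function(matrix, categories = NULL, min_count = 5L,
                              nc_min_prev = 0.05) {
  if (ncol(matrix) == 0L || nrow(matrix) == 0L) return(matrix)
  counts <- colSums(matrix)
  keep <- counts >= min_count
  if (!is.null(categories)) {
    nc <- categories[colnames(matrix)] == "noncoding_driver"
    nc[is.na(nc)] <- FALSE
    keep <- keep & (!nc | counts / nrow(matrix) > nc_min_prev)
  }
  matrix[, keep, drop = FALSE]
}

# VEP-style consequence terms counted as functional for mutational burden
functional_consequences <- c(
  "splice_acceptor_variant", "splice_donor_variant", "stop_gained",
  "frameshift_variant", "stop_lost", "start_lost",
  "transcript_amplification", "inframe_insertion", "inframe_deletion",
  "missense_variant", "protein_altering_variant",
  "incomplete_terminal_codon_variant")

#' Per-patient driver counts
#'
#' Three counts per patient: (1) total mutational burden = number of
#' variants with a functional exonic consequence; (2) number of mutated
#' coding driver genes (SNVs/indels in the schema's coding-driver panel);
#' (3) number of mutated coding (SNVs/indels and CNAs) plus noncoding
#' drivers.
#'
#' @param lesions data.frame with columns `gene` (or feature id for
#'   CNAs/noncoding), `lesion_class` in `{snv_indel, cna, noncoding}` and
#'   `consequence` (VEP term, for snv_indel rows).
#' @param schema A [feature_schema()]; coding-driver gene symbols are the
#'   schema ids stripped of their `CD_` prefix.
#' @return list `n_functional`, `n_coding_driver`, `n_all_driver`.
#' @export
count_drivers <- function(lesions, schema = feature_schema()) {
  feats <- schema$features
  driver_genes <- sub("^CD_", "", feats$id[feats$category == "coding_driver"])
  nc_ids <- feats$id[feats$category == "noncoding_driver"]
  cna_ids <- feats$id[feats$category == "recurrent_cna"]

  snv <- lesions[lesions$lesion_class == "snv_indel", , drop = FALSE]
  known <- snv$consequence %in% functional_consequences
  other <- setdiff(unique(snv$consequence[!known]),
                   c("synonymous_variant", "intergenic_variant",
                     "intron_variant", "upstream_gene_variant",
                     "downstream_gene_variant", "non_coding_transcript_variant"))
  if (length(other) > 0L)
    warning("unknown consequence term(s) counted as non-functional: ",
            paste(head(other, 3L), collapse = ", "))
  n_functional <- sum(known)

  coding_mut_genes <- unique(snv$gene[known & snv$gene %in% driver_genes])
  n_coding_driver <- length(coding_mut_genes)

  cna <- lesions[lesions$lesion_class == "cna", , drop = FALSE]
  nc <- lesions[lesions$lesion_class == "noncoding", , drop = FALSE]
  cna_hits <- unique(cna$gene[cna$gene %in%
                                c(cna_ids, sub("^CNA_", "", cna_ids))])
  nc_hits <- unique(nc$gene[nc$gene %in%
                              c(nc_ids, sub("^NC_", "", nc_ids))])
  # the three namespaces (gene symbols, CNA features, noncoding features)
  # are disjoint, so the union count is the sum
  n_all <- length(coding_mut_genes) + length(cna_hits) + length(nc_hits)
  list(n_functional = n_functional, n_coding_driver = n_coding_driver,
       n_all_driver = n_all)
}

#' Merge two pathway lists, preferring the first for shared names
#'
#' @param primary,secondary Character vectors of pathway names (the primary
#'   definition wins for names present in both).
#' @return Character vector of unique pathway names.
#' @export
merge_pathway_lists <- function(primary, secondary) {
  unique(c(primary, setdiff(secondary, primary)))
}

#' Per-pathway mutated-patient burden
#'
#' Counts, for each pathway, the patients carrying at least one qualifying
#' lesion in a member gene. The `mode` selects which lesions qualify:
#' `driver_panel` (SNVs/indels in coding drivers), `exome_high_impact`
#' (driver panel plus high-impact exonic consequences in any gene),
#' `driver_plus_noncoding` (driver panel plus noncoding drivers) or `all`.
#' A gene belonging to several pathways increments each of them.
#'
#' @param lesions_by_patient Named list (per patient) of lesion data.frames
#'   as in [count_drivers()].
#' @param pathway_defs Named list: pathway -> character vector of gene
#'   symbols.
#' @param mode One of `driver_panel`, `exome_high_impact`,
#'   `driver_plus_noncoding`, `all`.
#' @param schema A [feature_schema()].
#' @return Named integer vector of mutated-patient counts per pathway.
#' @export
pathway_burden <- function(lesions_by_patient, pathway_defs,
                           mode = c("driver_panel", "exome_high_impact",
                                    "driver_plus_noncoding", "all"),
                           schema = feature_schema()) {
  mode <- match.arg(mode)
  if (length(pathway_defs) == 0L)
    abort2("pathway_defs must be non-empty", "cllstrat_config_error")
  feats <- schema$features
  driver_genes <- sub("^CD_", "", feats$id[feats$category == "coding_driver"])
  high_impact <- c("splice_acceptor_variant", "splice_donor_variant",
                   "stop_gained", "frameshift_variant", "stop_lost",
                   "start_lost")
  qualifying_genes <- function(les) {
    snv <- les[les$lesion_class == "snv_indel", , drop = FALSE]
    g <- character(0)
    if (mode %in% c("driver_panel", "exome_high_impact",
                    "driver_plus_noncoding", "all"))
      g <- c(g, snv$gene[snv$gene %in% driver_genes &
                           snv$consequence %in% functional_consequences])
    if (mode %in% c("exome_high_impact", "all"))
      g <- c(g, snv$gene[snv$consequence %in% high_impact])
    if (mode %in% c("driver_plus_noncoding", "all")) {
      nc <- les[les$lesion_class == "noncoding", , drop = FALSE]
      g <- c(g, sub("^NC_", "", nc$gene))
    }
    unique(g)
  }
  counts <- setNames(integer(length(pathway_defs)), names(pathway_defs))
  for (les in lesions_by_patient) {
    g <- qualifying_genes(les)
    for (pw in names(pathway_defs)) {
      if (any(g %in% pathway_defs[[pw]]))
        counts[pw] <- counts[pw] + 1L
    }
  }
  counts
}
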