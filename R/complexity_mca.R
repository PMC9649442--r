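#' Multiple correspondence analysis of binary genome-wide measures
#'
#' Correspondence analysis of the complete disjunctive (indicator) matrix:
#' each binary variable contributes two categories (absent/present). The
#' standardized residual matrix
#' `S = D_r^{-1/2} (P - r c') D_c^{-1/2}` is decomposed by SVD; squared
#' singular values are the principal inertias (eigenvalues). For Q binary
#' variables with all 2Q categories observed the total inertia is
#' `(J - Q)/Q = 1`. Category contributions per dimension sum to one;
#' variable contributions aggregate the variable's two categories. No
#' Benzecri correction is applied.
#'
#' Constant columns (variables with a single observed category) are dropped
#' with a warning before the decomposition.
#'
#' @param input patients x variables binary matrix (0/1) with column names;
#'   typically the 17 measures of [mca_measures()].
#' @return An `MCAResult` list: `eigenvalues`, `category_coordinates`
#'   (principal coordinates, categories x dims), `variable_contributions`
#'   (variables x dims), `row_coordinates`, `total_inertia`, `variables`.
#' @export
run_mca <- function(input) {
  if (is.data.frame(input)) input <- as.matrix(input)
  if (nrow(input) < 2L)
    abort2("need at least two patients", "cllstrat_validation_error")
  if (!all(input %in% c(0L, 1L)))
    abort2("input must be binary", "cllstrat_validation_error")
  const <- apply(input, 2L, function(x) length(unique(x)) == 1L)
  if (any(const)) {
    warning("dropping constant variable(s): ",
            paste(colnames(input)[const], collapse = ", "))
    input <- input[, !const, drop = FALSE]
  }
  qn <- ncol(input)
  if (qn == 0L)
    abort2("no non-constant variables", "cllstrat_validation_error")
  vars <- colnames(input) %||% paste0("V", seq_len(qn))

  # complete disjunctive table: absent and present category per variable
  Z <- matrix(0L, nrow(input), 2L * qn)
  Z[, seq(1L, 2L * qn, by = 2L)] <- 1L - input
  Z[, seq(2L, 2L * qn, by = 2L)] <- input
  colnames(Z) <- as.vector(rbind(paste0(vars, ":0"), paste0(vars, ":1")))

  P <- Z / sum(Z)
  r <- rowSums(P)
  cm <- colSums(P)
  S <- diag(1 / sqrt(r)) %*% (P - outer(r, cm)) %*% diag(1 / sqrt(cm))
  sv <- svd(S)
  keep <- sv$d > 1e-12
  d <- sv$d[keep]
  eig <- d^2
  # category principal coordinates and contributions
  Gs <- diag(1 / sqrt(cm)) %*% sv$v[, keep, drop = FALSE]   # standard coords
  G <- sweep(Gs, 2L, d, `*`)                                # principal coords
  ctr <- sweep(Gs^2, 1L, cm, `*`)                           # sums to 1 per dim
  rownames(G) <- rownames(ctr) <- colnames(Z)
  var_idx <- rep(seq_len(qn), each = 2L)
  vctr <- rowsum(ctr, var_idx)
  rownames(vctr) <- vars
  Frow <- sweep(diag(1 / sqrt(r)) %*% sv$u[, keep, drop = FALSE], 2L, d, `*`)
  rownames(Frow) <- rownames(input)

  structure(list(eigenvalues = eig,
                 category_coordinates = G,
                 variable_contributions = vctr,
                 row_coordinates = Frow,
                 total_inertia = sum(eig),
                 variables = vars),
            class = "MCAResult")
}

#' Select the most discriminating variables from an MCA
#'
#' Dimensions are retained by the mean-eigenvalue (Kaiser-style) rule. With
#' the default `weighting = "excess"`, each retained dimension is weighted
#' by its inertia in excess of the mean eigenvalue — the independence
#' baseline around which noise dimensions fluctuate — so a variable that
#' merely owns a barely-retained dimension cannot outrank variables that
#' drive the dominant axes. `weighting = "raw"` sums unweighted
#' contributions over the retained dimensions. Ties are broken by input
#' variable order.
#'
#' @param result An [run_mca()] result.
#' @param k Number of variables to return (default 3).
#' @param weighting `"excess"` (default) or `"raw"`.
#' @return Character vector of `k` variable names, contribution-ordered.
#' @export
select_top_variables <- function(result, k = 3L,
                                 weighting = c("excess", "raw")) {
  stopifnot(inherits(result, "MCAResult"))
  weighting <- match.arg(weighting)
  if (k > length(result$variables))
    abort2("k exceeds the number of variables", "cllstrat_validation_error")
  lam <- result$eigenvalues
  keep <- lam > mean(lam)
  if (!any(keep)) keep[1L] <- TRUE
  w <- if (weighting == "excess") pmax(lam - mean(lam), 0) else
    as.numeric(keep)
  score <- as.vector(result$variable_contributions %*% w)
  ord <- order(-score, seq_along(score))   # ties: schema order
  result$variables[ord][seq_len(k)]
}

#' Assign genomic-complexity (GC) groups from three binary variables
#'
#' Patients are mapped onto the 2^3 = 8 presence/absence patterns of the
#' three selected variables (canonically CN loss, CN gain, trisomy). Labels
#' follow binary order of the bit triplet `(v1, v2, v3)`:
#' `(0,0,0) -> GC1`, `(0,0,1) -> GC2`, ..., `(1,1,1) -> GC8`.
#'
#' @param matrix patients x measures binary matrix.
#' @param vars Character vector of exactly three column names.
#' @return list with `assignment` (named factor patient -> GC group) and
#'   `group_definition` (data.frame mapping each GC label to its bits).
#' @export
assign_gc_groups <- function(matrix, vars) {
  if (length(vars) != 3L || !all(vars %in% colnames(matrix)))
    abort2("vars must name three columns of the matrix",
           "cllstrat_validation_error")
  bits <- matrix[, vars, drop = FALSE]
  code <- bits[, 1L] * 4L + bits[, 2L] * 2L + bits[, 3L] + 1L
  labels <- paste0("GC", 1:8)
  assignment <- factor(labels[code], levels = labels)
  names(assignment) <- rownames(matrix)
  def <- data.frame(group = labels,
                    v1 = rep(0:1, each = 4L),
                    v2 = rep(rep(0:1, each = 2L), 2L),
                    v3 = rep(0:1, 4L))
  names(def)[2:4] <- vars
  list(assignment = assignment, group_definition = def)
}

#' Conventional genomic complexity flag
#'
#' A patient is conventionally complex when it carries at least
#' `threshold` CNAs.
#'
#' @param cna_counts Nonnegative integer vector of CNA counts per patient.
#' @param threshold Minimum CNA count (default 4).
#' @return Logical vector.
#' @export
conventional_complexity <- function(cna_counts, threshold = 4L) {
  if (any(cna_counts < 0))
    abort2("counts must be nonnegative", "cllstrat_validation_error")
  cna_counts >= threshold
}

#' Derive the 17-measure binary MCA input from a cohort feature matrix
#'
#' Convenience bridge for synthetic cohorts: maps global features of the
#' reference schema onto the 17 genomic measures (burden bins onto the
#' median-binned measures, lesion flags onto presence measures). Measures
#' without a counterpart are derived from related columns or set to 0.
#'
#' @param fm A `BinaryFeatureMatrix` built on the reference schema.
#' @return patients x 17 binary matrix with [mca_measures()] ids as columns.
#' @export
mca_input_from_features <- function(fm) {
  V <- fm$values
  g <- function(id) if (id %in% colnames(V)) V[, id] else
    integer(nrow(V))
  cn_gain <- g("GL_gain_count_high")
  cn_loss <- g("GL_del_count_high")
  trisomy <- g("CNA_tri12")
  out <- cbind(
    snv_count = g("GL_snv_burden_high"),
    indel_count = g("GL_indel_burden_high"),
    telomere_length = g("GL_telomere_length_short"),
    telomere_content = g("GL_telomere_content_low"),
    sv_breakpoint = g("GL_breakpoint_count_high"),
    cna = as.integer(cn_gain | cn_loss | g("GL_cnloh_any")),
    cn_gain = cn_gain,
    cn_loss = cn_loss,
    cnloh = g("GL_cnloh_any"),
    trisomy = trisomy,
    aneuploidy = g("GL_aneuploidy"),
    cn_gain_excl_trisomy = as.integer(cn_gain & !trisomy),
    cn_loss_excl_aneuploidy = as.integer(cn_loss & !g("GL_aneuploidy")),
    cnloh_excl_whole_chrom = g("GL_cnloh_any"),
    inversion = g("GL_inversion_any"),
    translocation = g("GL_translocation_any"),
    chromothripsis = g("GL_chromothripsis")
  )
  rownames(out) <- rownames(V)
  stopifnot(identical(colnames(out), mca_measures()$id))
  out
}
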