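#' Build the NMF input matrix for one IGHV stratum
#'
#' Appends the binarized clinical covariates to the genomic feature matrix:
#' percent germline identity of the IGHV gene (`MS`, >= median), age
#' (>= median) and sex (male = 1), then transposes to features x samples as
#' the factorization expects. Fitting is per IGHV stratum.
#'
#' On real cohorts the covariates carry signal and belong in the input; in
#' the synthetic generator they are drawn independently of the planted
#' subgroups, so appending them adds genuine non-subgroup structure that the
#' factorization will (correctly) detect. Planted-structure analyses should
#' therefore set `include_covariates = FALSE`.
#'
#' @param cohort A [generate_cohort()] result (or any list with
#'   `feature_matrix` and `covariates`).
#' @param stratum `"u"` or `"m"`.
#' @param include_covariates Append the binarized MS/age/sex columns
#'   (default TRUE).
#' @return Features x samples binary matrix.
#' @export
nmf_input <- function(cohort, stratum = c("u", "m"),
                      include_covariates = TRUE) {
  stratum <- match.arg(stratum)
  keep <- cohort$covariates$ighv == stratum
  X <- cohort$feature_matrix$values[keep, , drop = FALSE]
  if (include_covariates) {
    cov <- cohort$covariates[keep, , drop = FALSE]
    X <- cbind(X,
               MS = binarize_continuous(cov$pct_germline),
               age_high = binarize_continuous(cov$age),
               sex_male = as.integer(cov$sex == "M"))
  }
  t(X)
}

#' Extract genomic signatures from a fitted NMF model
#'
#' Basis columns are normalized by their maximum; features with normalized
#' weight at or above `cutoff` are the signature's defining features.
#' Signatures are labelled `<stratum>-GS1..k` in order of decreasing total
#' patient load (row sums of `H`).
#'
#' @param model An [fit_nmf_offset()] model.
#' @param cutoff Defining-feature threshold on the max-normalized weight
#'   (default 0.5).
#' @param stratum Label prefix (default `"u"`).
#' @return list of `GenomicSignature` lists (`label`, `feature_weights`,
#'   `defining_features`, `empty_flag`), ordered by load.
#' @export
extract_signatures <- function(model, cutoff = 0.5, stratum = "u") {
  W <- model$W
  rownames(W) <- model$features
  load <- rowSums(model$H)
  ord <- order(-load)
  sigs <- lapply(seq_along(ord), function(i) {
    col <- ord[i]
    w <- W[, col]
    mx <- max(w)
    wn <- if (mx > 0) w / mx else w
    defining <- names(wn)[wn >= cutoff]
    if (length(defining) == 0L)
      warning("signature ", i, " has an empty defining set")
    list(label = paste0(stratum, "-GS", i),
         feature_weights = wn,
         raw_weights = w,
         defining_features = defining,
         empty_flag = length(defining) == 0L)
  })
  sigs
}

#' Assign a sample to signatures by forward-selection deconvolution
#'
#' Finds the nonnegative linear combination of signature profiles that best
#' reconstructs the sample's (normalized) feature vector, in the style of
#' signature-deconvolution tools: starting from an empty set, each step
#' re-optimizes one signature's weight (golden-section search) and keeps the
#' change that most reduces the sum-of-squares reconstruction error; the
#' loop stops when the error improvement falls below `tol`. Weights below
#' `discard` (as a fraction) are zeroed and the rest renormalized to
#' proportions. The label is the argmax proportion.
#'
#' @param x Binary (or nonnegative) feature vector aligned to the signature
#'   feature space.
#' @param signatures List from [extract_signatures()] (uses
#'   `feature_weights`).
#' @param tol Error-improvement stopping threshold (default 1e-3).
#' @param discard Minimum retained proportion (default 0.06).
#' @param max_steps Safety cap on selection steps.
#' @return A `SubgroupAssignment` list: `proportions` (named, sums to 1),
#'   `label`, `sse`, `flagged` (TRUE for an all-zero input, assigned uniform
#'   proportions).
#' @export
deconvolve_sample <- function(x, signatures, tol = 1e-3, discard = 0.06,
                              max_steps = 50L) {
  if (length(signatures) == 0L)
    abort2("signatures must be non-empty", "cllstrat_config_error")
  S <- vapply(signatures, function(s) {
    w <- s$feature_weights
    w / sum(w)
  }, numeric(length(signatures[[1L]]$feature_weights)))
  labels <- vapply(signatures, `[[`, "", "label")
  colnames(S) <- labels
  rownames(S) <- names(signatures[[1L]]$feature_weights)
  # align the sample to the signature feature space (the fit may have
  # dropped all-zero feature rows)
  if (!is.null(rownames(S)) && !is.null(names(x))) {
    missing <- setdiff(rownames(S), names(x))
    if (length(missing) > 0L)
      abort2("sample vector lacks signature feature(s)",
             "cllstrat_validation_error")
    x <- x[rownames(S)]
  } else if (length(x) != nrow(S)) {
    abort2("sample vector not aligned to signature feature space",
           "cllstrat_validation_error")
  }
  if (sum(x) == 0) {
    k <- length(signatures)
    return(list(proportions = setNames(rep(1 / k, k), labels),
                label = labels[1L], sse = NA_real_, flagged = TRUE))
  }
  xn <- x / sum(x)
  k <- ncol(S)
  w <- rep(0, k)
  sse <- function(w) sum((xn - as.vector(S %*% w))^2)
  err <- sse(w)
  for (step in seq_len(max_steps)) {
    best_err <- err; best_j <- 0L; best_wj <- NA_real_
    for (j in seq_len(k)) {
      opt <- optimize(function(v) { w2 <- w; w2[j] <- v; sse(w2) },
                      interval = c(0, 10))
      if (opt$objective < best_err - 1e-12) {
        best_err <- opt$objective; best_j <- j; best_wj <- opt$minimum
      }
    }
    if (best_j == 0L || err - best_err < tol) break
    w[best_j] <- best_wj
    err <- best_err
  }
  props <- if (sum(w) > 0) w / sum(w) else rep(1 / k, k)
  props[props < discard] <- 0
  props <- props / sum(props)
  names(props) <- labels
  list(proportions = props, label = labels[which.max(props)],
       sse = err, flagged = FALSE)
}

#' Deconvolve every sample of a matrix
#'
#' @param V Features x samples matrix aligned to the signatures.
#' @param signatures List from [extract_signatures()].
#' @param ... Passed to [deconvolve_sample()].
#' @return list with `proportions` (samples x signatures matrix) and
#'   `labels` (named character vector).
#' @export
deconvolve_matrix <- function(V, signatures, ...) {
  res <- lapply(seq_len(ncol(V)), function(j)
    deconvolve_sample(V[, j], signatures, ...))
  P <- do.call(rbind, lapply(res, `[[`, "proportions"))
  rownames(P) <- colnames(V)
  labels <- vapply(res, `[[`, "", "label")
  names(labels) <- colnames(V)
  list(proportions = P, labels = labels)
}

#' Cluster signature proportions with a Gaussian mixture
#'
#' Fits Gaussian mixtures over a component-count grid with [mclust::Mclust()]
#' and keeps the most parsimonious model within `bic_tol` BIC units of the
#' optimum (mclust maximizes its BIC). Degenerate inputs (duplicate rows
#' only) fall back to a single cluster with a warning.
#'
#' @param proportions Samples x signatures matrix.
#' @param g_grid Component-count grid (default 1:6).
#' @param bic_tol Parsimony tolerance in BIC units (default 2).
#' @return list with `cluster` (integer vector), `g` (chosen component
#'   count), `model_name`.
#' @export
cluster_assignments <- function(proportions, g_grid = 1:6, bic_tol = 2) {
  if (nrow(proportions) < 2L)
    abort2("need at least two patients", "cllstrat_validation_error")
  if (nrow(unique(as.data.frame(proportions))) == 1L) {
    warning("all proportion rows identical; returning a single cluster")
    return(list(cluster = rep(1L, nrow(proportions)), g = 1L,
                model_name = "degenerate"))
  }
  bic <- tryCatch(
    suppressWarnings(mclust::mclustBIC(proportions, G = g_grid,
                                       verbose = FALSE)),
    error = function(e) NULL)
  if (is.null(bic)) {
    warning("mixture fit failed; returning a single cluster")
    return(list(cluster = rep(1L, nrow(proportions)), g = 1L,
                model_name = "degenerate"))
  }
  # parsimony: smallest G within bic_tol of the best BIC (mclust maximizes)
  B <- as.matrix(bic)
  vals <- suppressWarnings(apply(B, 1L, max, na.rm = TRUE))
  gs <- as.integer(rownames(B))
  ok <- is.finite(vals)
  best <- max(vals[ok])
  g_choice <- min(gs[ok][vals[ok] >= best - bic_tol])
  model_name <- colnames(B)[which.max(B[as.character(g_choice), ])]
  fit <- tryCatch(
    suppressWarnings(mclust::summaryMclustBIC(bic, proportions,
                                              G = g_choice,
                                              modelNames = model_name)),
    error = function(e) NULL)
  if (is.null(fit) || length(fit$classification) == 0L) {
    warning("mixture fit failed; returning a single cluster")
    return(list(cluster = rep(1L, nrow(proportions)), g = 1L,
                model_name = "degenerate"))
  }
  list(cluster = as.integer(fit$classification), g = as.integer(fit$G),
       model_name = fit$modelName)
}

#' Cosine similarity between two nonnegative weight vectors
#'
#' @param a,b Nonzero numeric vectors of equal length.
#' @return `a . b / (||a|| ||b||)`.
#' @export
cosine_similarity <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0)
    abort2("zero vector in cosine similarity", "cllstrat_validation_error")
  sum(a * b) / (na * nb)
}

#' Match two signature sets by optimal cosine similarity
#'
#' Builds the pairwise cosine-similarity matrix between the signatures of
#' two independent fits and finds the one-to-one matching that maximizes the
#' mean similarity (exact search over permutations; signature counts are
#' small).
#'
#' @param sig_a,sig_b Signature lists from [extract_signatures()] of equal
#'   length.
#' @return list with `pairs` (data.frame `a`, `b`, `cosine`) and
#'   `mean_cosine`.
#' @export
match_signatures <- function(sig_a, sig_b) {
  ka <- length(sig_a); kb <- length(sig_b)
  if (ka != kb)
    abort2("signature sets must have equal size", "cllstrat_validation_error")
  # align on shared features: independent fits may have dropped different
  # all-zero rows
  na_ <- names(sig_a[[1L]]$feature_weights)
  nb_ <- names(sig_b[[1L]]$feature_weights)
  common <- if (!is.null(na_) && !is.null(nb_)) intersect(na_, nb_) else NULL
  getw <- function(s, nms) if (is.null(nms)) s$feature_weights
          else s$feature_weights[nms]
  M <- matrix(0, ka, kb)
  for (i in seq_len(ka)) for (j in seq_len(kb))
    M[i, j] <- cosine_similarity(getw(sig_a[[i]], common),
                                 getw(sig_b[[j]], common))
  bp <- best_permutation(M)
  pairs <- data.frame(a = vapply(sig_a, `[[`, "", "label"),
                      b = vapply(sig_b[bp$perm], `[[`, "", "label"),
                      cosine = M[cbind(seq_len(ka), bp$perm)],
                      stringsAsFactors = FALSE)
  list(pairs = pairs, mean_cosine = mean(pairs$cosine), perm = bp$perm)
}

#' Hold-out validation of the NMF subgroup classifier
#'
#' Splits the samples of one stratum into a training fraction and a held-out
#' test set, fits the offset NMF at rank `k` on the training samples,
#' matches the training signatures to the full-data signatures by cosine
#' similarity, assigns every sample by deconvolution under both fits, and
#' cross-tabulates the held-out samples' training-fit labels against their
#' full-data labels.
#'
#' @param V Features x samples matrix (one stratum).
#' @param k NMF rank.
#' @param train_frac Training fraction (default 0.8).
#' @param seed Integer seed for the split and both fits.
#' @param stratum Label prefix for signatures.
#' @param max_iter,tol Passed to [fit_nmf_offset()].
#' @return list with `confusion` (test samples: full-data x training
#'   labels), `n_agree`, `n_test`, `test_samples`, `full_labels`,
#'   `train_labels`, `mean_cosine` of the signature matching.
#' @export
split_validate <- function(V, k, train_frac = 0.8, seed = 1L,
                           stratum = "u", max_iter = 500L, tol = 1e-5) {
  m <- ncol(V)
  if (m < 5L)
    abort2("stratum too small to split", "cllstrat_config_error")
  set.seed(seed, kind = "Mersenne-Twister")
  n_train <- round(train_frac * m)
  train_idx <- sort(sample.int(m, n_train))
  test_idx <- setdiff(seq_len(m), train_idx)

  full_fit <- fit_nmf_offset(V, k, seed = derive_seed(seed, 11L),
                             max_iter = max_iter, tol = tol)
  train_fit <- fit_nmf_offset(V[, train_idx, drop = FALSE], k,
                              seed = derive_seed(seed, 23L),
                              max_iter = max_iter, tol = tol)
  sig_full <- extract_signatures(full_fit, stratum = stratum)
  sig_train <- extract_signatures(train_fit, stratum = stratum)
  mt <- match_signatures(sig_full, sig_train)
  # relabel training signatures with their matched full-data labels
  for (i in seq_along(sig_train)) {
    j <- which(mt$perm == i)
    sig_train[[i]]$label <- sig_full[[j]]$label
  }
  full_assign <- deconvolve_matrix(V, sig_full)
  train_assign <- deconvolve_matrix(V, sig_train)
  test_samples <- colnames(V)[test_idx]
  fl <- full_assign$labels[test_samples]
  tl <- train_assign$labels[test_samples]
  lev <- vapply(sig_full, `[[`, "", "label")
  confusion <- table(full_data = factor(fl, levels = lev),
                     training = factor(tl, levels = lev))
  list(confusion = confusion, n_agree = sum(fl == tl),
       n_test = length(test_idx), test_samples = test_samples,
       full_labels = fl, train_labels = tl, mean_cosine = mt$mean_cosine)
}
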