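#' Fit an offset non-negative matrix factorization
#'
#' Factorizes a nonnegative matrix `V` (features x samples) as
#' `V ~ W H + b 1'` with nonnegative basis `W` (features x k), loadings `H`
#' (k x samples) and a per-feature offset `b` absorbing the shared baseline.
#' Multiplicative updates minimize the generalized Kullback-Leibler
#' divergence; the objective is non-increasing at every step (the offset is
#' the update of an extra basis column whose loading row is fixed at one).
#' Iteration stops when the relative objective change falls below `tol` or
#' after `max_iter` iterations.
#'
#' @param V Nonnegative features x samples matrix; all-zero rows are dropped
#'   with a warning (their updates are degenerate).
#' @param k Rank, `k < min(dim(V))`.
#' @param seed Integer seed for the random nonnegative initialization.
#' @param max_iter Maximum iterations (default 500).
#' @param tol Relative objective-change tolerance (default 1e-5).
#' @param track_objective Keep the per-iteration objective trace.
#' @return An `NMFModel` list: `W`, `H`, `offset`, `k`, `final_objective`,
#'   `objective_trace` (if tracked), `iterations`, `seed`, `features`,
#'   `samples`.
#' @export
fit_nmf_offset <- function(V, k, seed = 1L, max_iter = 500L, tol = 1e-5,
                           track_objective = FALSE) {
  if (is.data.frame(V)) V <- as.matrix(V)
  if (any(V < 0)) abort2("V must be nonnegative", "cllstrat_validation_error")
  if (k >= min(dim(V)))
    abort2("k must be smaller than both dimensions",
           "cllstrat_validation_error")
  zero_rows <- rowSums(V) == 0
  if (any(zero_rows)) {
    warning("dropping ", sum(zero_rows), " all-zero feature row(s)")
    V <- V[!zero_rows, , drop = FALSE]
  }
  n <- nrow(V); m <- ncol(V)
  set.seed(seed, kind = "Mersenne-Twister")
  W <- matrix(runif(n * k, 0.05, 1), n, k)
  H <- matrix(runif(k * m, 0.05, 1), k, m)
  b <- pmax(rowMeans(V), 1e-4)
  eps <- .Machine$double.eps

  kl <- function(Vhat) {
    ratio <- ifelse(V > 0, V * log(V / Vhat), 0)
    sum(ratio - V + Vhat)
  }
  Vhat <- W %*% H + b
  obj <- kl(Vhat)
  trace <- if (track_objective) numeric(max_iter) else NULL
  it <- 0L
  repeat {
    it <- it + 1L
    R <- V / pmax(Vhat, eps)
    # KL multiplicative updates
    W <- W * (R %*% t(H)) / pmax(matrix(colSums(t(H)), n, k, byrow = TRUE), eps)
    Vhat <- W %*% H + b
    R <- V / pmax(Vhat, eps)
    H <- H * (t(W) %*% R) / pmax(matrix(colSums(W), k, m), eps)
    Vhat <- W %*% H + b
    R <- V / pmax(Vhat, eps)
    b <- b * rowSums(R) / m
    Vhat <- W %*% H + b
    new_obj <- kl(Vhat)
    if (track_objective) trace[it] <- new_obj
    rel <- abs(obj - new_obj) / max(abs(obj), eps)
    obj <- new_obj
    if (it >= max_iter || rel < tol) break
  }
  structure(list(W = W, H = H, offset = b, k = k, final_objective = obj,
                 objective_trace = if (track_objective) trace[seq_len(it)],
                 iterations = it, seed = seed,
                 features = rownames(V), samples = colnames(V)),
            class = "NMFModel")
}

#' @export
print.NMFModel <- function(x, ...) {
  cat("NMFModel: rank", x$k, "on", nrow(x$W), "features x", ncol(x$H),
      "samples; KL =", signif(x$final_objective, 6), "after", x$iterations,
      "iterations\n")
  invisible(x)
}

#' Rank estimation by consensus clustering and cophenetic correlation
#'
#' For every candidate rank, `n_runs` random restarts are fitted; samples
#' are co-clustered by the argmax of `H` (ties to the lowest signature
#' index) and the consensus matrix is the co-assignment frequency. The
#' cophenetic coefficient correlates the consensus-implied distances with
#' the cophenetic distances of their average-linkage hierarchical
#' clustering. The same statistic is computed on a row-wise shuffled copy of
#' the data as an overfitting control.
#'
#' @param V Features x samples nonnegative matrix.
#' @param k_grid Integer vector of candidate ranks (values >= 2; rank 1 has
#'   a degenerate all-ones consensus and is reported NA if supplied).
#' @param n_runs Restarts per rank (>= 10).
#' @param seed Integer seed; run seeds are derived from it.
#' @param max_iter,tol Passed to [fit_nmf_offset()].
#' @param randomized Also evaluate on shuffled data (default TRUE).
#' @return A `RankEstimate` list: `k_grid`, `cophenetic`,
#'   `cophenetic_randomized`, `consensus` (list of matrices), `best_k`
#'   (argmax of cophenetic on the observed data).
#' @export
estimate_rank <- function(V, k_grid = 2:6, n_runs = 30L, seed = 1L,
                          max_iter = 1000L, tol = 1e-6, randomized = TRUE) {
  if (is.data.frame(V)) V <- as.matrix(V)
  if (n_runs < 10L)
    abort2("n_runs must be >= 10", "cllstrat_config_error")
  if (max(k_grid) >= ncol(V))
    abort2("k_max must be below the number of samples",
           "cllstrat_validation_error")
  coph_for <- function(M, k, seed0) {
    m <- ncol(M)
    C <- matrix(0, m, m)
    for (r in seq_len(n_runs)) {
      fit <- fit_nmf_offset(M, k, seed = derive_seed(seed0, r),
                            max_iter = max_iter, tol = tol)
      lab <- apply(fit$H, 2L, which.max)   # ties: lowest index
      C <- C + outer(lab, lab, `==`)
    }
    C <- C / n_runs
    if (all(C == 1)) return(list(coph = NA_real_, consensus = C))
    d <- as.dist(1 - C)
    hc <- hclust(d, method = "average")
    list(coph = cor(d, cophenetic(hc)), consensus = C)
  }
  set.seed(seed, kind = "Mersenne-Twister")
  Vrand <- t(apply(V, 1L, sample))   # shuffle each feature across samples
  coph <- coph_rand <- rep(NA_real_, length(k_grid))
  consensus <- vector("list", length(k_grid))
  for (i in seq_along(k_grid)) {
    k <- k_grid[i]
    if (k < 2L) next
    res <- coph_for(V, k, derive_seed(seed, 1000L + k))
    coph[i] <- res$coph
    consensus[[i]] <- res$consensus
    if (randomized)
      coph_rand[i] <- coph_for(Vrand, k, derive_seed(seed, 2000L + k))$coph
  }
  best_k <- k_grid[which.max(coph)]
  structure(list(k_grid = k_grid, cophenetic = coph,
                 cophenetic_randomized = coph_rand,
                 consensus = consensus, best_k = best_k, n_runs = n_runs),
            class = "RankEstimate")
}

#' @export
print.RankEstimate <- function(x, ...) {
  df <- data.frame(k = x$k_grid, cophenetic = round(x$cophenetic, 4),
                   randomized = round(x$cophenetic_randomized, 4))
  print(df, row.names = FALSE)
  cat("best k:", x$best_k, "\n")
  invisible(x)
}
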