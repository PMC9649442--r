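#' @importFrom stats pnorm qnorm rbinom rpois rnorm runif rexp median sd
#'   cor cutree hclust as.dist cophenetic p.adjust fisher.test t.test
#'   cor.test pbinom optimize setNames complete.cases quantile
#' @importFrom utils head write.table read.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stop with a classed condition
#' @noRd
abort2 <- function(msg, class) {
  stop(structure(class = c(class, "cllstrat_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Derive a child seed from a master seed
#'
#' Keeps derived seeds within 32-bit integer range so `set.seed()` accepts
#' them on every platform.
#' @noRd
derive_seed <- function(seed, offset) {
  # keep intermediates below 2^53 so the offset is never lost to rounding
  s <- (as.numeric(seed) %% 2147483647) * 48271 %% 2147483647
  as.integer((s + as.numeric(offset) * 1000003 + 1) %% 2147483647)
}

#' Optimal one-to-one column matching by brute-force permutation search
#'
#' Maximizes the sum of `score[i, perm[i]]` over permutations. Used to match
#' signatures across independent NMF fits; k is always small (<= 8).
#' @noRd
best_permutation <- function(score) {
  k <- nrow(score)
  stopifnot(ncol(score) == k)
  perms <- permutations_int(k)
  best <- NULL
  best_val <- -Inf
  for (i in seq_len(nrow(perms))) {
    p <- perms[i, ]
    v <- sum(score[cbind(seq_len(k), p)])
    if (v > best_val) {
      best_val <- v
      best <- p
    }
  }
  list(perm = best, value = best_val)
}

permutations_int <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_int(k - 1L)
  out <- matrix(0L, nrow = k * nrow(sub), ncol = k)
  row <- 1L
  for (lead in seq_len(k)) {
    rest <- setdiff(seq_len(k), lead)
    for (j in seq_len(nrow(sub))) {
      out[row, ] <- c(lead, rest[sub[j, ]])
      row <- row + 1L
    }
  }
  out
}
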