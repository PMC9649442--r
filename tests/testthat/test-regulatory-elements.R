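test_that("catalog is the intersection of peak tracks with state consensus", {
  atac <- data.frame(chrom = "chr1", start = 100L, end = 200L)
  k27 <- data.frame(chrom = "chr1", start = 150L, end = 250L)
  states <- list(
    data.frame(chrom = "chr1", start = 0L, end = 300L, state = "enhancer"),
    data.frame(chrom = "chr1", start = 0L, end = 300L, state = "enhancer")
  )
  cat1 <- build_re_catalog(atac, k27, states)
  expect_identical(nrow(cat1), 1L)
  expect_identical(cat1$start, 150L)
  expect_identical(cat1$end, 200L)
  expect_identical(cat1$re_type, "enhancer")
  expect_gte(cat1$state_support, 2L)

  # state in a single sample: entry kept, type unassigned
  cat2 <- build_re_catalog(atac, k27, states[1])
  expect_identical(nrow(cat2), 1L)
  expect_true(is.na(cat2$re_type))

  # disjoint tracks: empty catalog
  far <- data.frame(chrom = "chr1", start = 5000L, end = 6000L)
  expect_identical(nrow(build_re_catalog(atac, far, states)), 0L)

  # catalog is order-commutative in the peak tracks
  a2 <- data.frame(chrom = "chr1", start = c(400L, 100L),
                   end = c(600L, 200L))
  k2 <- data.frame(chrom = "chr1", start = c(150L, 380L),
                   end = c(250L, 800L))
  expect_identical(build_re_catalog(a2, k2, states)[, 1:3],
                   build_re_catalog(k2, a2, states)[, 1:3])

  expect_error(
    build_re_catalog(data.frame(chrom = "chr1", start = 10L, end = 5L),
                     k27, states),
    class = "cllstrat_validation_error")

  # IGHV-specific flags
  sub <- list(u = data.frame(chrom = "chr1", start = 140L, end = 210L),
              m = data.frame(chrom = "chr2", start = 0L, end = 1L))
  cat3 <- build_re_catalog(atac, k27, states, subgroup_tracks = sub)
  expect_identical(cat3$ighv_specificity, "u-only")
})

test_that("enhancer-gene linking stays inside TADs and recovers planted pairs", {
  pairs <- data.frame(re = 1:8, gene = 1:8)
  g <- generate_re_signal(100, 20, 20, pairs, rho = 0.8, seed = 13)
  catalog <- g$re_intervals
  links <- link_enhancer_targets(catalog, g$signal, g$expr, g$tads,
                                 g$gene_intervals)
  # links never cross a TAD boundary
  for (i in seq_len(nrow(links))) {
    re_t <- g$re_tad[match(links$re_id[i], catalog$re_id)]
    gene_t <- g$gene_tad[match(links$gene[i], g$gene_intervals$gene)]
    expect_identical(re_t, gene_t)
  }
  # planted pairs recovered at high rate
  planted <- paste0("RE", pairs$re, ":", "G", pairs$gene)
  found <- paste0(links$re_id, ":", links$gene)
  expect_gte(mean(planted %in% found), 0.95)

  # identical vectors give r = 1 and a link
  g1 <- generate_re_signal(30, 3, 3, data.frame(re = 2, gene = 2),
                           rho = 1, seed = 14)
  l1 <- link_enhancer_targets(g1$re_intervals, g1$signal, g1$expr,
                              g1$tads, g1$gene_intervals)
  expect_true(any(l1$re_id == "RE2" & l1$gene == "G2" &
                    abs(l1$pearson_r - 1) < 1e-12))
})

test_that("re recurrence p-values follow the exact binomial tail", {
  re <- list(chrom = "chr5", start = 1000L, end = 2000L)  # 1 kb
  # exhaustive-summation oracle for the binomial tail
  tail_oracle <- function(x, n, pr) {
    sum(vapply(x:n, function(k)
      choose(n, k) * pr^k * (1 - pr)^(n - k), 0))
  }
  muts <- data.frame(
    sample = paste0("s", 1:6), chrom = "chr5",
    pos = as.integer(seq(1100, 1900, length.out = 6)))
  r <- test_re_recurrence(re, muts, n_samples = 485,
                          background_rate = 1e-6)
  pr <- 1 - exp(-1e-6 * 1000)
  expect_equal(r$p_recurrence, tail_oracle(6L, 485L, pr), tolerance = 1e-9)
  expect_identical(r$n_mutated_samples, 6L)
  expect_false(r$kataegis_flag)

  # no mutations: p = 1, no flags
  r0 <- test_re_recurrence(re, muts[0, ], 485, 1e-6)
  expect_equal(r0$p_recurrence, 1)
  expect_identical(length(r0$hotspot_positions), 0L)

  # hotspot: same position in three samples
  hs <- data.frame(sample = c("a", "b", "c"), chrom = "chr5", pos = 1500L)
  rh <- test_re_recurrence(re, hs, 485, 1e-6)
  expect_identical(rh$hotspot_positions, 1500L)

  # kataegis: six mutations within 1 kb in one sample
  kat <- data.frame(sample = "a", chrom = "chr5",
                    pos = as.integer(seq(1100, 1600, length.out = 6)))
  expect_true(test_re_recurrence(re, kat, 485, 1e-6)$kataegis_flag)

  expect_error(test_re_recurrence(list(chrom = "chr5", start = 5L, end = 5L),
                                  muts, 485, 1e-6),
               class = "cllstrat_validation_error")
})

test_that("recurrence p-values are uniform under a matched null", {
  set.seed(77)
  n_res <- 1000L
  n_samples <- 50L
  rate <- 2e-4
  len <- 1000L
  pr <- 1 - exp(-rate * len)
  # simulate per-RE mutated-sample counts under the null and test
  ps <- vapply(seq_len(n_res), function(i) {
    hits <- which(rbinom(n_samples, 1L, pr) == 1L)
    muts <- if (length(hits) == 0L)
      data.frame(sample = character(), chrom = character(), pos = integer())
    else
      data.frame(sample = paste0("s", hits), chrom = "chr1",
                 pos = sample.int(len, length(hits), replace = TRUE))
    test_re_recurrence(list(chrom = "chr1", start = 0L, end = len),
                       muts, n_samples, rate)$p_recurrence
  }, 0)
  # discrete p-values: compare against the exact null CDF by checking that
  # P(p <= alpha) <= alpha (validity) at several alphas, and that the KS
  # distance to uniform is within what the discreteness allows
  for (alpha in c(0.01, 0.05, 0.1, 0.25)) {
    expect_lte(mean(ps <= alpha), alpha + 3 * sqrt(alpha / n_res))
  }
})

test_that("allelic skew calls follow the band and depth rules", {
  expect_identical(call_allelic_skew(0.5, 0.65, 12), "alt-skewed")
  expect_identical(call_allelic_skew(0.5, 0.55, 50), "none")
  expect_identical(call_allelic_skew(0.5, 0.8, 8), "insufficient")
  expect_identical(call_allelic_skew(0.5, 0.35, 12), "ref-skewed")
  # symmetry: negating the difference flips the call
  set.seed(8)
  for (i in 1:20) {
    w <- runif(1, 0.2, 0.8); d <- runif(1, -0.4, 0.4)
    a <- call_allelic_skew(w, w + d, 30)
    b <- call_allelic_skew(w, w - d, 30)
    flipped <- c(`alt-skewed` = "ref-skewed", `ref-skewed` = "alt-skewed",
                 none = "none")
    expect_identical(unname(flipped[a]), b)
  }
})

test_that("expression contrast reproduces a hand Welch computation", {
  mut <- c(10, 12, 11); wt <- c(5, 6, 5, 6)
  out <- expression_contrast(mut, wt)
  # textbook Welch: t = (m1-m2)/sqrt(s1^2/n1 + s2^2/n2)
  t_hand <- (mean(mut) - mean(wt)) /
    sqrt(var(mut) / 3 + var(wt) / 4)
  df_hand <- (var(mut) / 3 + var(wt) / 4)^2 /
    ((var(mut) / 3)^2 / 2 + (var(wt) / 4)^2 / 3)
  expect_equal(out$t, t_hand)
  expect_equal(out$df, df_hand)
  expect_equal(out$p, 2 * pt(-abs(t_hand), df_hand))
  expect_equal(out$ratio, mean(mut) / mean(wt))
  # identical groups: ratio 1, p = 1
  same <- expression_contrast(c(3, 4, 5), c(3, 4, 5))
  expect_equal(same$ratio, 1)
  expect_equal(same$p, 1)
  # single mutated sample: ratio defined, p NA
  single <- expression_contrast(10, wt)
  expect_equal(single$ratio, 10 / mean(wt))
  expect_true(is.na(single$p))
})
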