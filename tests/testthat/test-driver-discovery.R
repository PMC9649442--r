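# brute-force BH step-up oracle
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  for (i in seq(n - 1L, 1L)) if (n > 1L) q[i] <- min(q[i], q[i + 1L])
  out <- numeric(n)
  out[o] <- pmin(q, 1)
  out
}

test_that("stouffer combination matches the closed form", {
  expect_equal(combine_stouffer_weighted(rep(0.5, 4)), 0.5)
  expect_equal(combine_stouffer_weighted(0.05), 0.05)
  # p = 0.05 x4 equal weights: Z = 4 * qnorm(0.95) / 2
  expected <- 1 - pnorm(4 * qnorm(0.95) / sqrt(4))
  expect_equal(combine_stouffer_weighted(rep(0.05, 4)), expected)
  expect_equal(expected, 4.97e-4, tolerance = 1e-2)
  # invariance to weight rescaling; equal weights = unweighted
  p <- c(0.01, 0.2, 0.6, 0.04)
  expect_equal(combine_stouffer_weighted(p, c(1, 2, 3, 4)),
               combine_stouffer_weighted(p, c(2, 4, 6, 8)))
  expect_warning(combine_stouffer_weighted(c(0.5, 1)), "clamped")
})

test_that("weighted harmonic mean combination matches direct formula", {
  expect_equal(combine_hmp_weighted(rep(0.3, 4)), 0.3)
  expect_equal(combine_hmp_weighted(c(0.01, 1 - 1e-15)), 2 / 101,
               tolerance = 1e-10)
  set.seed(1)
  for (i in 1:20) {
    p <- runif(5, 0.001, 0.999)
    w <- runif(5, 0.1, 2)
    h <- combine_hmp_weighted(p, w)
    expect_gte(h, min(p))
    expect_lte(h, max(p))
  }
})

test_that("bh_fdr equals the brute-force step-up on all 5-permutations", {
  base <- c(0.001, 0.02, 0.04, 0.3, 0.9)
  perms <- cllstrat:::permutations_int(5L)
  for (i in seq_len(nrow(perms))) {
    p <- base[perms[i, ]]
    expect_equal(bh_fdr(p), bh_oracle(p))
  }
  expect_equal(bh_fdr(0.05), 0.05)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
})

test_that("method-1 selection honors 2-of-4 and combined routes", {
  # gene universe where per-algorithm FDR is easy to reason about
  res <- data.frame(gene = paste0("G", 1:20),
                    p1 = 1, p2 = 1, p3 = 1, p4 = 1)
  res[1, c("p1", "p2")] <- c(1e-6, 1e-6)      # 2-of-4 route
  res[2, "p1"] <- 1e-8                        # single algorithm only
  res$p1[3:20] <- runif(18, 0.5, 0.99)
  set.seed(2)
  out <- suppressWarnings(select_drivers_method1(res, alpha = 0.05))
  expect_true(out$selected[1])
  expect_match(out$route[1], "2of4")
  # all-1 p-values are never selected
  expect_false(any(out$selected[10:20] &
                     is.na(out$route[10:20])))
  dull <- data.frame(gene = "X", p1 = 0.999, p2 = 0.999, p3 = 0.999,
                     p4 = 0.999)
  expect_false(suppressWarnings(select_drivers_method1(dull))$selected)
  expect_error(select_drivers_method1(data.frame(gene = "X", p1 = 0.5)),
               class = "cllstrat_validation_error")
})

test_that("minimally affected regions match a per-base coverage oracle", {
  # oracle: count per-base coverage on a toy chromosome
  oracle_regions <- function(segments, min_samples) {
    L <- 10000L
    cov <- integer(L)
    for (s in unique(segments$sample)) {
      mask <- logical(L)
      ss <- segments[segments$sample == s, ]
      for (i in seq_len(nrow(ss))) mask[ss$start[i]:ss$end[i]] <- TRUE
      cov <- cov + mask
    }
    ok <- cov >= min_samples
    if (!any(ok)) return(NULL)
    runs <- rle(ok)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    regs <- data.frame(start = starts[runs$values], end = ends[runs$values])
    # core: max coverage inside each region (first maximal run)
    cores <- lapply(seq_len(nrow(regs)), function(i) {
      idx <- regs$start[i]:regs$end[i]
      peak <- max(cov[idx])
      at <- idx[cov[idx] == peak]
      first <- at[c(1L, which(diff(at) != 1L) + 1L)][1L]
      len <- rle(cov[first:regs$end[i]] == peak)$lengths[1L]
      data.frame(start = first, end = first + len - 1L, n = peak)
    })
    do.call(rbind, cores)
  }
  set.seed(31)
  for (trial in 1:10) {
    n_seg <- sample(6:14, 1)
    segments <- data.frame(
      sample = paste0("s", sample(1:6, n_seg, replace = TRUE)),
      chrom = "chr1",
      start = sample.int(9000, n_seg),
      type = "loss")
    segments$end <- pmin(10000L, segments$start +
                           sample.int(3000, n_seg))
    got <- minimally_affected_regions(segments, min_samples = 3L)
    want <- oracle_regions(segments, 3L)
    if (is.null(want)) {
      expect_identical(nrow(got), 0L)
    } else {
      expect_equal(nrow(got), nrow(want))
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
      expect_equal(got$n_samples, want$n)
    }
  }
})

test_that("region calling respects the four-sample floor", {
  seg <- function(s) data.frame(sample = s, chrom = "chr1", start = 100L,
                                end = 500L, type = "gain")
  four <- do.call(rbind, lapply(paste0("p", 1:4), seg))
  out <- minimally_affected_regions(four)
  expect_identical(nrow(out), 1L)
  expect_identical(out$start, 100L)
  expect_identical(out$end, 500L)
  three <- do.call(rbind, lapply(paste0("p", 1:3), seg))
  expect_identical(nrow(minimally_affected_regions(three)), 0L)
  # staggered: core is the intersection of all five
  five <- data.frame(sample = paste0("p", 1:5), chrom = "chr1",
                     start = c(100L, 120L, 140L, 160L, 180L),
                     end = c(400L, 420L, 440L, 460L, 480L), type = "loss")
  out5 <- minimally_affected_regions(five, min_samples = 4L)
  core <- out5[out5$n_samples == 5L, ]
  expect_identical(core$start, 180L)
  expect_identical(core$end, 400L)
})

test_that("focality/recurrence contributions follow the definitions", {
  ann <- data.frame(gene = paste0("g", 1:10), chrom = "chr1",
                    start = seq(1000L, 10000L, by = 1000L),
                    end = seq(1400L, 10400L, by = 1000L))
  # one sample, one single-gene lesion -> rec = foc = 1 (normalized by n=1)
  les <- data.frame(sample = "s1", chrom = "chr1", start = 1000L,
                    end = 1400L)
  fr <- focality_recurrence("g1", les, ann)
  expect_equal(fr$recurrence_score, 1)
  expect_equal(fr$focality_score, 1)
  # lesion spanning all 10 genes -> focality contribution 0.1
  big <- data.frame(sample = "s1", chrom = "chr1", start = 1000L,
                    end = 10400L)
  fr2 <- focality_recurrence("g5", big, ann)
  expect_equal(fr2$focality_score, 0.1)
  # unaltered gene -> zero scores
  fr3 <- focality_recurrence("g9", les, ann)
  expect_equal(fr3$combined_score, 0)
  expect_error(focality_recurrence("nope", les, ann),
               class = "cllstrat_validation_error")
})

test_that("method-2 selection gates on counts, scores and mechanism", {
  fr <- data.frame(
    gene = c("a", "b", "c", "d"),
    recurrence_score = c(0.5, 0.5, 0.5, 0.01),
    focality_score = c(0.5, 0.5, 0.5, 0.01),
    snv_indel_count = c(5L, 4L, 7L, 9L),
    mechanism = c("TSG", "TSG", "oncogene", "TSG"),
    cna_type = c("loss", "loss", "loss", "loss"))
  out <- select_drivers_method2(fr, score_threshold = 0.1, min_snv = 5L)
  expect_identical(out$candidates, "a")    # c: oncogene in loss region
  expect_identical(out$permissive, "b")    # fails only the count
})
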