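test_that("filter rules remove records with the first failing reason", {
  cases <- list(
    list(call = passing_call(tumor_depth = 8L, tumor_alt_reads = 4L),
         reason = "min_depth"),
    list(call = passing_call(tumor_depth = 100L, tumor_alt_reads = 4L),
         reason = "min_af"),
    list(call = passing_call(filter_flag = "LowQual"),
         reason = "filter_flag"),
    list(call = passing_call(quality_score = 30), reason = "min_quality"),
    list(call = passing_call(population_af = 0.05),
         reason = "max_population_af"),
    list(call = passing_call(recurrence_cohort_af = 0.06),
         reason = "max_cohort_recurrence"),
    list(call = passing_call(repeat_overlap = TRUE),
         reason = "repeat_overlap"),
    list(call = passing_call(vqsr_score = 2.74), reason = "min_vqsr"),
    list(call = passing_call(somatic_panel_phred = 79),
         reason = "somatic_panel")
  )
  for (cs in cases) {
    res <- filter_snv_indels(cs$call)
    expect_identical(nrow(res$kept), 0L)
    expect_identical(res$removed$reason, cs$reason)
  }
  # boundary: depth strictly greater than 10; AF >= 0.05 kept
  res <- filter_snv_indels(passing_call(tumor_depth = 10L,
                                        tumor_alt_reads = 5L))
  expect_identical(res$removed$reason, "min_depth")  # 10 is not > 10
  res1 <- filter_snv_indels(passing_call(tumor_depth = 11L,
                                         tumor_alt_reads = 5L))
  expect_identical(nrow(res1$kept), 1L)              # 11 > 10 passes
  res2 <- filter_snv_indels(passing_call(tumor_depth = 20L,
                                         tumor_alt_reads = 1L))
  expect_identical(nrow(res2$kept), 1L)  # AF = 0.05 exactly passes
})

test_that("filtering is idempotent, partitions input, and is monotone", {
  vt <- generate_variant_table(500, purity = 0.6, seed = 21)
  vt$quality_score[1:50] <- 10           # plant failures
  vt$vqsr_score[51:80] <- 1
  res <- filter_snv_indels(vt)
  expect_identical(nrow(res$kept) + nrow(res$removed), nrow(vt))
  again <- filter_snv_indels(res$kept)
  expect_identical(again$kept, res$kept)
  expect_identical(nrow(again$removed), 0L)
  # tightening a threshold never grows the kept set
  tight <- filter_snv_indels(vt, filter_policy(min_depth = 40))
  expect_lte(nrow(tight$kept), nrow(res$kept))
  expect_true(all(interaction(tight$kept$chrom, tight$kept$pos) %in%
                    interaction(res$kept$chrom, res$kept$pos)))
  # empty input
  e <- filter_snv_indels(vt[0, ])
  expect_identical(nrow(e$kept), 0L)
  expect_identical(nrow(e$removed), 0L)
})

test_that("ccf follows the purity/copy-number rescaling", {
  expect_equal(compute_ccf(0.5, 1, 2, 1)$ccf, 1.0)
  expect_equal(compute_ccf(0, 0.7, 3, 1)$ccf, 0)
  expect_equal(compute_ccf(0.4, 0.8, 2, 1)$ccf, 1.0)  # 0.4*(1.6+0.4)/0.8
  expect_error(compute_ccf(0.5, 0, 2, 1), class = "cllstrat_domain_error")
  # linear in vaf, decreasing in multiplicity
  c1 <- compute_ccf(0.1, 0.8, 4, 1)$ccf
  c2 <- compute_ccf(0.2, 0.8, 4, 1)$ccf
  expect_equal(c2, 2 * c1)
  expect_lt(compute_ccf(0.2, 0.8, 4, 2)$ccf, c2)
  # capping flag above 1.05
  over <- compute_ccf(0.9, 0.6, 2, 1)
  expect_true(over$capped)
  expect_equal(over$ccf, 1.05)
  # multiplicity estimation: clonal het at purity 1, CN 2
  est <- compute_ccf(0.5, 1, 2)
  expect_equal(est$ccf, 1.0)
})

test_that("sv consensus requires two callers within tolerance", {
  sv <- function(pos1, pos2, type = "deletion")
    data.frame(type = type, chrom1 = "chr2", pos1 = pos1, ori1 = "+",
               chrom2 = "chr2", pos2 = pos2, ori2 = "-",
               allele_fraction = 0.3, stringsAsFactors = FALSE)
  calls <- list(delly = sv(1000, 5000), lumpy = sv(1010, 5005),
                manta = sv(99000, 120000))
  out <- merge_sv_consensus(calls, tolerance = 100)
  expect_identical(nrow(out), 1L)
  expect_identical(out$n_callers, 2L)
  expect_identical(out$pos1, 1005L)  # median of supporters

  expect_error(merge_sv_consensus(calls["delly"]),
               class = "cllstrat_config_error")

  # boundary: offset == tolerance merges, tolerance + 1 does not
  at <- merge_sv_consensus(list(a = sv(1000, 5000), b = sv(1100, 5000)),
                           tolerance = 100)
  expect_identical(nrow(at), 1L)
  past <- merge_sv_consensus(list(a = sv(1000, 5000), b = sv(1101, 5000)),
                             tolerance = 100)
  expect_identical(nrow(past), 0L)

  # different type never merges
  mixed <- merge_sv_consensus(list(a = sv(1000, 5000),
                                   b = sv(1000, 5000, "duplication")))
  expect_identical(nrow(mixed), 0L)
})

test_that("cna filter drops low quality and short segments, merges adjacent", {
  seg <- function(start, end, type = "loss", q = 30, cn = 1L)
    data.frame(chrom = "chr3", start = start, end = end, type = type,
               total_copy_number = cn, quality = q, stringsAsFactors = FALSE)
  # 99 kb segment dropped, quality 9 dropped
  expect_identical(
    nrow(suppressWarnings(filter_cna(seg(1e6, 1e6 + 98999)))), 0L)
  expect_identical(
    nrow(suppressWarnings(filter_cna(seg(1e6, 2e6, q = 9)))), 0L)
  # two adjacent 60 kb same-state segments merge to 120 kb and survive
  two <- rbind(seg(1e6, 1e6 + 59999), seg(1e6 + 60000, 1e6 + 119999))
  out <- suppressWarnings(filter_cna(two))
  expect_identical(nrow(out), 1L)
  expect_equal(out$end - out$start + 1, 120000)
  # exclusion track removes overlapping segments
  excl <- data.frame(chrom = "chr3", start = 1.5e6, end = 1.6e6)
  expect_identical(nrow(filter_cna(seg(1e6, 2e6), exclusion = excl)), 0L)
  expect_warning(filter_cna(seg(1e6, 2e6)), "exclusion")
})
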