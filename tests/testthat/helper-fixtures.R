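# Shared fixtures built in code.

# tiny two-subgroup spec with deterministic features (prevalence 0 or 1)
make_deterministic_spec <- function(noise = 0, seed = 11L) {
  sch <- feature_schema()
  ids <- sch$features$id
  on_a <- setNames(rep(1, 10), ids[1:10])
  on_b <- setNames(rep(1, 10), ids[11:20])
  profiles <- list(
    subgroup_profile("A", "u", on_a, hazard_scale = 30, background = 0),
    subgroup_profile("B", "u", on_b, hazard_scale = 60, background = 0)
  )
  cohort_spec(n_patients = 20L, subgroup_profiles = profiles,
              ighv_split = 1, noise_flip_prob = noise, censor_rate = 0,
              schema = sch, seed = seed)
}

# variant record passing every default filter rule
passing_call <- function(...) {
  base <- data.frame(
    chrom = "chr1", pos = 1000L, ref = "A", alt = "T",
    tumor_depth = 60L, tumor_alt_reads = 20L, normal_depth = 55L,
    filter_flag = "PASS", quality_score = 50, population_af = 0,
    vqsr_score = 10, recurrence_cohort_af = 0.01, repeat_overlap = FALSE,
    indel_proximity_flag = FALSE, somatic_panel_phred = 120,
    stringsAsFactors = FALSE)
  mods <- list(...)
  for (nm in names(mods)) base[[nm]] <- mods[[nm]]
  base
}

# small rank-2 planted binary matrix for NMF tests (features x samples)
make_planted_matrix <- function(n_per = 30L, n_feat = 40L, noise = 0.02,
                                seed = 5L) {
  set.seed(seed)
  blocks <- list(1:15, 21:35)
  prob <- matrix(0.02, n_feat, 2L * n_per)
  prob[blocks[[1]], 1:n_per] <- 0.9
  prob[blocks[[2]], (n_per + 1L):(2L * n_per)] <- 0.9
  V <- matrix(rbinom(length(prob), 1L, prob), n_feat)
  flip <- matrix(rbinom(length(prob), 1L, noise), n_feat)
  V <- abs(V - flip)
  rownames(V) <- paste0("f", seq_len(n_feat))
  colnames(V) <- paste0("s", seq_len(2L * n_per))
  attr(V, "truth") <- rep(1:2, each = n_per)
  V
}
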