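#' Define a synthetic subgroup profile
#'
#' A subgroup is characterized by its IGHV stratum, the prevalence of each
#' binary genomic feature among its members, a mixing weight within its
#' stratum, and an exponential event-time scale (months) used to draw
#' survival times.
#'
#' @param label Subgroup identifier (e.g. `"u-GS1"`).
#' @param ighv_stratum `"u"` (unmutated IGHV) or `"m"` (hypermutated).
#' @param feature_prevalence Named numeric vector in \[0,1\]: probability that
#'   a member of this subgroup carries each feature. Names must be feature
#'   ids from the schema; features not named default to `background`.
#' @param hazard_scale Positive mean event time in months.
#' @param weight Nonnegative mixing weight within the stratum.
#' @param background Prevalence for features not listed (default 0.03).
#' @return A `SubgroupProfile` list.
#' @export
subgroup_profile <- function(label, ighv_stratum = c("u", "m"),
                             feature_prevalence, hazard_scale,
                             weight = 1, background = 0.03) {
  ighv_stratum <- match.arg(ighv_stratum)
  if (any(feature_prevalence < 0 | feature_prevalence > 1))
    abort2("prevalence values must lie in [0,1]", "cllstrat_config_error")
  if (hazard_scale <= 0)
    abort2("hazard_scale must be positive", "cllstrat_config_error")
  structure(list(label = label, ighv_stratum = ighv_stratum,
                 feature_prevalence = feature_prevalence,
                 hazard_scale = hazard_scale, weight = weight,
                 background = background),
            class = "SubgroupProfile")
}

#' Define a synthetic cohort specification
#'
#' @param n_patients Total number of patients.
#' @param subgroup_profiles List of [subgroup_profile()] objects covering one
#'   or both IGHV strata.
#' @param ighv_split Fraction of patients labelled u-IGHV (ignored for a
#'   stratum with no profiles).
#' @param noise_flip_prob Probability that any feature bit is flipped after
#'   the Bernoulli draw (symmetric noise).
#' @param censor_rate Expected fraction of censored survival records,
#'   achieved by independent uniform censoring.
#' @param schema A [feature_schema()]; prevalence names are validated
#'   against it.
#' @param seed Integer seed; the whole cohort is a deterministic function of
#'   the spec including this seed.
#' @return A `CohortSpec` list.
#' @export
cohort_spec <- function(n_patients, subgroup_profiles, ighv_split = 0.5,
                        noise_flip_prob = 0, censor_rate = 0.3,
                        schema = feature_schema(), seed = 1L) {
  if (length(subgroup_profiles) == 0L)
    abort2("subgroup_profiles must be non-empty", "cllstrat_config_error")
  if (n_patients < 1L)
    abort2("n_patients must be positive", "cllstrat_config_error")
  for (p in c(noise_flip_prob, ighv_split, censor_rate))
    if (p < 0 || p > 1)
      abort2("probabilities must lie in [0,1]", "cllstrat_config_error")
  ids <- schema$features$id
  for (pr in subgroup_profiles) {
    unknown <- setdiff(names(pr$feature_prevalence), ids)
    if (length(unknown) > 0L)
      abort2(paste0("prevalence references unknown feature id(s): ",
                    paste(head(unknown, 3L), collapse = ", ")),
             "cllstrat_schema_error")
  }
  structure(list(n_patients = as.integer(n_patients),
                 subgroup_profiles = subgroup_profiles,
                 ighv_split = ighv_split,
                 noise_flip_prob = noise_flip_prob,
                 censor_rate = censor_rate,
                 schema = schema, seed = as.integer(seed)),
            class = "CohortSpec")
}

#' Reference study-condition cohort specification
#'
#' Returns the default synthetic twin of a chemoimmunotherapy trial cohort:
#' 243 u-IGHV patients drawn from three subgroup profiles and 168 m-IGHV
#' patients from two, each subgroup defined by a block of high-prevalence
#' features (0.85) against a low background (0.03), with symmetric bit-flip
#' noise 0.05. Subgroup-specific exponential event-time scales give the
#' u-stratum progressively worse outcomes than the m-stratum.
#'
#' @param seed Integer seed.
#' @param noise_flip_prob Bit-flip noise probability (default 0.05).
#' @return A `CohortSpec`.
#' @export
cll_cohort_spec <- function(seed = 1L, noise_flip_prob = 0.05) {
  sch <- feature_schema()
  ids <- sch$features$id
  # 12 defining features per subgroup, disjoint blocks spread across
  # categories so each signature mixes drivers, CNAs and global features.
  blocks <- list(
    u1 = c("CD_TP53", "CNA_del17p13.1", "CD_NOTCH1", "CNA_del11q22.3",
           "CD_ATM", "GL_snv_burden_high", "GL_telomere_length_short",
           "PW_DNA_damage_cell_cycle", "CD_XPO1", "CNA_del9p21.3",
           "GL_ID83C", "NC_TP53_prom"),
    u2 = c("CD_SF3B1", "CNA_tri12", "CD_BIRC3", "PW_NOTCH_signaling",
           "GL_SBS8", "CD_EGR2", "CNA_gain8q24", "NC_NOTCH1_3UTR",
           "GL_sv_burden_high", "CD_NFKBIE", "CNA_gain2p25.3",
           "PW_NFKB_signaling"),
    u3 = c("CD_MED12", "CD_DDX3X", "CNA_del13q14.2", "GL_SBS1",
           "NC_PAX5_enh1", "CD_CHD2", "CNA_del6q21", "PW_BCR_signaling",
           "GL_breakpoint_count_high", "NC_BIRC3_prom", "CD_ZMYM3",
           "CNA_del15q15.1"),
    m1 = c("CD_MYD88", "GL_SBS9", "CNA_del13q14.2", "NC_IGLL5_5UTR",
           "CD_KLHL6", "PW_Apoptosis_BCL2", "NC_BCL2_5UTR", "CD_BCL2",
           "GL_telomere_content_low", "CNA_del4p15", "NC_BACH2_prom",
           "GL_DBS11"),
    m2 = c("CD_CCND2", "CNA_gain18q21", "NC_BCL6_enh1", "PW_JAK_STAT",
           "GL_SBS5", "CD_IRF4", "CNA_gain19p13", "NC_CXCR4_3UTR",
           "CD_BTG1", "GL_ID2", "NC_IKZF3_prom", "CNA_gain21q22")
  )
  stopifnot(all(unlist(blocks) %in% ids))
  prev <- function(block) setNames(rep(0.85, length(block)), block)
  profiles <- list(
    subgroup_profile("u-GS1", "u", prev(blocks$u1), hazard_scale = 24),
    subgroup_profile("u-GS2", "u", prev(blocks$u2), hazard_scale = 40),
    subgroup_profile("u-GS3", "u", prev(blocks$u3), hazard_scale = 60),
    subgroup_profile("m-GS1", "m", prev(blocks$m1), hazard_scale = 80),
    subgroup_profile("m-GS2", "m", prev(blocks$m2), hazard_scale = 110)
  )
  cohort_spec(n_patients = 411L, subgroup_profiles = profiles,
              ighv_split = 243 / 411, noise_flip_prob = noise_flip_prob,
              censor_rate = 0.3, schema = sch, seed = seed)
}

#' Generate a synthetic cohort
#'
#' Patients are assigned to IGHV strata by the spec's split (deterministic
#' counts), then to subgroups by the stratum mixing weights. Each patient's
#' binary features are drawn Bernoulli(prevalence of its subgroup) and then
#' flipped with probability `noise_flip_prob`. Survival times are
#' exponential with the subgroup's scale, censored by an independent uniform
#' time calibrated to the spec's censoring rate. Covariates follow the
#' trial-cohort demographics: age from a discretized normal centred at 65,
#' sex ~ Bernoulli(0.7 male), percent germline identity of the IGHV gene
#' drawn above 98 for u-IGHV and below it for m-IGHV.
#'
#' @param spec A [cohort_spec()].
#' @return A `SyntheticCohort` list: `feature_matrix` (patients x features,
#'   0/1, `BinaryFeatureMatrix`), `true_labels`, `covariates` data.frame,
#'   `survival` data.frame (`patient`, `time`, `event`, `endpoint`), and the
#'   `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "CohortSpec"))
  set.seed(spec$seed, kind = "Mersenne-Twister")
  sch <- spec$schema
  ids <- sch$features$id
  n <- spec$n_patients

  strata <- vapply(spec$subgroup_profiles, function(p) p$ighv_stratum, "")
  has_u <- any(strata == "u"); has_m <- any(strata == "m")
  n_u <- if (!has_m) n else if (!has_u) 0L else round(n * spec$ighv_split)
  ighv <- c(rep("u", n_u), rep("m", n - n_u))

  assign_stratum <- function(stratum, count) {
    idx <- which(strata == stratum)
    if (count > 0L && length(idx) == 0L)
      abort2(paste0("no subgroup profile for stratum '", stratum, "'"),
             "cllstrat_config_error")
    if (count == 0L) return(integer(0))
    w <- vapply(spec$subgroup_profiles[idx], function(p) p$weight, 0)
    sample(idx, count, replace = TRUE, prob = w / sum(w))
  }
  prof_idx <- integer(n)
  prof_idx[ighv == "u"] <- assign_stratum("u", sum(ighv == "u"))
  prof_idx[ighv == "m"] <- assign_stratum("m", sum(ighv == "m"))
  labels <- vapply(spec$subgroup_profiles[prof_idx], function(p) p$label, "")

  # prevalence matrix: profiles x features
  pmat <- t(vapply(spec$subgroup_profiles, function(p) {
    v <- rep(p$background, length(ids))
    v[match(names(p$feature_prevalence), ids)] <- p$feature_prevalence
    v
  }, numeric(length(ids))))
  prob <- pmat[prof_idx, , drop = FALSE]
  X <- matrix(rbinom(n * length(ids), 1L, as.vector(prob)), nrow = n)
  if (spec$noise_flip_prob > 0) {
    flip <- matrix(rbinom(n * length(ids), 1L, spec$noise_flip_prob),
                   nrow = n)
    X <- abs(X - flip)
  }
  patients <- sprintf("P%04d", seq_len(n))
  dimnames(X) <- list(patients, ids)

  age <- pmin(95, pmax(30, round(rnorm(n, 65, 9))))
  sex <- ifelse(rbinom(n, 1L, 0.7) == 1L, "M", "F")
  pct_germline <- ifelse(ighv == "u", 100 - runif(n, 0, 2),
                         98 - runif(n, 0, 8))
  covariates <- data.frame(patient = patients, age = age, sex = sex,
                           ighv = ighv, pct_germline = pct_germline,
                           stringsAsFactors = FALSE)

  scales <- vapply(spec$subgroup_profiles[prof_idx],
                   function(p) p$hazard_scale, 0)
  ev_time <- rexp(n, rate = 1 / scales)
  survival <- do.call(rbind, lapply(c("PFS", "OS"), function(ep) {
    t_ev <- if (ep == "PFS") ev_time else ev_time * runif(n, 1.2, 2.2)
    # uniform censoring on [0, U], U solved per patient so that
    # P(T > C) = censor_rate for T ~ Exp(scale), C ~ Uniform(0, U);
    # OS uses the effective scale after the 1.2-2.2x stretch (mean 1.7)
    cfrac <- spec$censor_rate
    eff <- if (ep == "PFS") scales else scales * 1.7
    t_cen <- if (cfrac <= 0) rep(Inf, n) else {
      U <- vapply(eff, function(s) censor_upper(s, cfrac), 0)
      runif(n, 0, U)
    }
    data.frame(patient = patients, time = pmax(pmin(t_ev, t_cen), 1e-3),
               event = as.integer(t_ev <= t_cen), endpoint = ep,
               stringsAsFactors = FALSE)
  }))

  structure(list(feature_matrix = new_binary_feature_matrix(X, sch),
                 true_labels = setNames(labels, patients),
                 covariates = covariates, survival = survival,
                 spec = spec),
            class = "SyntheticCohort")
}

# Upper bound U of uniform censoring such that P(T > C) = target for
# T ~ Exp(mean = scale), C ~ Uniform(0, U). P(censored) = (s/U)(1-exp(-U/s))
# decreases monotonically in U from 1 to 0; solved by uniroot.
censor_upper <- function(scale, target) {
  f <- function(U) (scale / U) * (1 - exp(-U / scale)) - target
  stats::uniroot(f, c(scale * 1e-6, scale * 1e5))$root
}

#' @export
print.SyntheticCohort <- function(x, ...) {
  cat("SyntheticCohort:", nrow(x$feature_matrix$values), "patients x",
      ncol(x$feature_matrix$values), "features;",
      length(unique(x$true_labels)), "planted subgroups\n")
  invisible(x)
}

#' Generate a synthetic somatic variant table
#'
#' Draws VCF-like SNV records whose read support reflects tumor purity,
#' local total copy number and clonality: the expected variant allele
#' fraction is `purity * multiplicity * ccf / (purity * CN + (1-purity) * 2)`.
#' Depths are Poisson around `mean_depth`; alt reads are binomial at the
#' expected VAF. Records carry every annotation the filter engine inspects
#' (quality, population AF, VQSR score, cohort recurrence, repeat and indel
#' proximity flags, somatic-panel Phred).
#'
#' @param n_variants Number of variants (>= 0).
#' @param purity Tumor purity in (0,1].
#' @param cn_profile Optional data.frame of CNA segments (`chrom`, `start`,
#'   `end`, `total_copy_number`); variants falling in a segment use its copy
#'   number, otherwise 2.
#' @param seed Integer seed.
#' @param mean_depth Mean sequencing depth (default 80).
#' @param clonal_fraction Fraction of variants that are clonal (CCF 1);
#'   subclonal variants draw CCF ~ Uniform(0.1, 0.6).
#' @return data.frame of `VariantCall` records.
#' @export
generate_variant_table <- function(n_variants, purity, cn_profile = NULL,
                                   seed = 1L, mean_depth = 80,
                                   clonal_fraction = 0.8) {
  if (purity <= 0 || purity > 1)
    abort2("purity must lie in (0,1]", "cllstrat_domain_error")
  if (n_variants < 0)
    abort2("n_variants must be >= 0", "cllstrat_domain_error")
  set.seed(seed, kind = "Mersenne-Twister")
  if (n_variants == 0L) return(empty_variant_table())

  chrom <- paste0("chr", sample(1:22, n_variants, replace = TRUE))
  pos <- sample.int(1e8, n_variants, replace = TRUE)
  cn <- rep(2L, n_variants)
  if (!is.null(cn_profile) && nrow(cn_profile) > 0L) {
    for (i in seq_len(nrow(cn_profile))) {
      hit <- chrom == cn_profile$chrom[i] & pos >= cn_profile$start[i] &
        pos <= cn_profile$end[i]
      cn[hit] <- cn_profile$total_copy_number[i]
    }
  }
  mult <- pmin(pmax(1L, rbinom(n_variants, 1L, 0.15) + 1L), cn)
  ccf <- ifelse(runif(n_variants) < clonal_fraction, 1,
                runif(n_variants, 0.1, 0.6))
  evaf <- purity * mult * ccf / (purity * cn + (1 - purity) * 2)
  depth <- pmax(1L, rpois(n_variants, mean_depth))
  alt <- rbinom(n_variants, depth, pmin(evaf, 1))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_variants, replace = TRUE)
  altb <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
  data.frame(
    chrom = chrom, pos = pos, ref = ref, alt = altb,
    tumor_depth = depth, tumor_alt_reads = alt,
    normal_depth = pmax(1L, rpois(n_variants, mean_depth)),
    filter_flag = "PASS",
    quality_score = round(runif(n_variants, 35, 90), 1),
    population_af = 0,
    vqsr_score = round(runif(n_variants, 3, 20), 2),
    recurrence_cohort_af = round(runif(n_variants, 0, 0.04), 4),
    repeat_overlap = FALSE,
    indel_proximity_flag = FALSE,
    somatic_panel_phred = round(runif(n_variants, 85, 200), 1),
    true_ccf = ccf, true_multiplicity = mult, local_total_cn = cn,
    stringsAsFactors = FALSE
  )
}

empty_variant_table <- function() {
  data.frame(chrom = character(), pos = integer(), ref = character(),
             alt = character(), tumor_depth = integer(),
             tumor_alt_reads = integer(), normal_depth = integer(),
             filter_flag = character(), quality_score = numeric(),
             population_af = numeric(), vqsr_score = numeric(),
             recurrence_cohort_af = numeric(), repeat_overlap = logical(),
             indel_proximity_flag = logical(),
             somatic_panel_phred = numeric(), true_ccf = numeric(),
             true_multiplicity = integer(), local_total_cn = integer(),
             stringsAsFactors = FALSE)
}

#' Generate correlated regulatory-element signal and expression matrices
#'
#' Lays out `n_res` regulatory elements and `n_genes` genes across a set of
#' topologically associated domains (TADs). For each planted link the gene's
#' expression is built from the RE's signal with population Pearson
#' correlation `rho`; all other pairs are independent standard normals.
#'
#' @param n_samples Number of samples (columns).
#' @param n_res Number of regulatory elements.
#' @param n_genes Number of genes.
#' @param linked_pairs data.frame with columns `re` and `gene` (1-based
#'   indices); both members of a pair are placed in the same TAD.
#' @param rho Population correlation for linked pairs, |rho| <= 1.
#' @param seed Integer seed.
#' @param n_tads Number of TADs (default 10).
#' @return list with `signal` (n_res x n_samples), `expr`
#'   (n_genes x n_samples), `tads` (data.frame `chrom`,`start`,`end`,
#'   `tad_id`), `re_tad`, `gene_tad` (TAD index per RE / gene) and
#'   `re_intervals`, `gene_intervals`.
#' @export
generate_re_signal <- function(n_samples, n_res, n_genes, linked_pairs,
                               rho, seed = 1L, n_tads = 10L) {
  if (abs(rho) > 1)
    abort2("|rho| must be <= 1", "cllstrat_domain_error")
  set.seed(seed, kind = "Mersenne-Twister")
  re_tad <- sort(rep_len(seq_len(n_tads), n_res))
  gene_tad <- sort(rep_len(seq_len(n_tads), n_genes))
  if (!is.null(linked_pairs) && nrow(linked_pairs) > 0L) {
    # co-locate planted pairs: gene inherits the RE's TAD
    gene_tad[linked_pairs$gene] <- re_tad[linked_pairs$re]
  }
  signal <- matrix(rnorm(n_res * n_samples), nrow = n_res)
  expr <- matrix(rnorm(n_genes * n_samples), nrow = n_genes)
  if (!is.null(linked_pairs) && nrow(linked_pairs) > 0L) {
    for (i in seq_len(nrow(linked_pairs))) {
      r <- linked_pairs$re[i]; g <- linked_pairs$gene[i]
      if (re_tad[r] != gene_tad[g])
        abort2("linked pair spans two TADs", "cllstrat_config_error")
      noise <- if (abs(rho) == 1) 0 else rnorm(n_samples)
      expr[g, ] <- rho * signal[r, ] + sqrt(1 - rho^2) * noise
    }
  }
  tad_size <- 1e6
  tads <- data.frame(chrom = "chr1",
                     start = (seq_len(n_tads) - 1L) * tad_size,
                     end = seq_len(n_tads) * tad_size,
                     tad_id = paste0("TAD", seq_len(n_tads)),
                     stringsAsFactors = FALSE)
  place <- function(tad_idx, width) {
    off <- runif(length(tad_idx), 0.05, 0.9) * tad_size
    start <- as.integer((tad_idx - 1L) * tad_size + off)
    data.frame(chrom = "chr1", start = start, end = start + width,
               stringsAsFactors = FALSE)
  }
  re_int <- place(re_tad, 500L)
  re_int$re_id <- paste0("RE", seq_len(n_res))
  gene_int <- place(gene_tad, 2000L)
  gene_int$gene <- paste0("G", seq_len(n_genes))
  rownames(signal) <- re_int$re_id
  rownames(expr) <- gene_int$gene
  colnames(signal) <- colnames(expr) <- paste0("S", seq_len(n_samples))
  list(signal = signal, expr = expr, tads = tads,
       re_tad = re_tad, gene_tad = gene_tad,
       re_intervals = re_int, gene_intervals = gene_int)
}
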