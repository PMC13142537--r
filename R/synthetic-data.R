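#' Configuration for a synthetic single-neuron cohort
#'
#' Defines the statistical structure of a simulated tau-accumulation cohort:
#' a latent tau continuum across cells from several donors, proteins that
#' respond to tau linearly or with a single hinge (early or late breakpoint),
#' donor random intercepts, Gaussian measurement noise on the log2 scale and
#' a logistic intensity-dependent (MNAR) detection curve.
#'
#' Response-class fractions may sum to at most 1; the remainder are null
#' proteins with zero slopes. Defaults emulate a layer-II single-neuron
#' cohort: tau spanning log2 intensities 12-19, an early hinge at 14 and a
#' late hinge at 17, cells called pTau-positive above log2 tau 16.
#'
#' @param n_cells number of cells (samples).
#' @param n_donors number of donors; cells are assigned to donors uniformly.
#' @param n_proteins number of proteins, including the tau row itself.
#' @param frac_linear_up,frac_linear_down,frac_early_break,frac_late_break
#'   proportions of proteins in each responding class.
#' @param tau_range numeric length-2, (lo, hi) of the latent log2 tau
#'   continuum.
#' @param breakpoint_early,breakpoint_late hinge positions in log2 tau units;
#'   must satisfy lo < early < late < hi.
#' @param slope_scale magnitude of the responding slopes (log2 intensity per
#'   log2 tau).
#' @param donor_sd SD of donor random intercepts (log2 units).
#' @param noise_sd SD of measurement noise (log2 units); must be > 0.
#' @param missing_midpoint,missing_steepness logistic detection curve:
#'   an entry of value v is retained with probability
#'   `plogis((v - missing_midpoint) * missing_steepness)`.
#' @param ptau_threshold latent log2 tau above which a cell is labelled
#'   pTau-positive.
#' @param label_noise_prob probability that a cell's pTau label is flipped
#'   (emulates borderline AT8 immunoreactivity); default 0.
#' @param pool_size for `capture = "mini_pool"`, number of cells averaged
#'   per pool before noise.
#' @param capture `"single_cell"` or `"mini_pool"`.
#' @param baseline_mean,baseline_sd distribution of per-protein baseline
#'   log2 intensities.
#' @param seed integer seed; all randomness derives from it.
#'
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_cells = 200, n_donors = 8, n_proteins = 1000,
                          frac_linear_up = 0.1, frac_linear_down = 0.1,
                          frac_early_break = 0.05, frac_late_break = 0.05,
                          tau_range = c(12, 19),
                          breakpoint_early = 14, breakpoint_late = 17,
                          slope_scale = 0.5, donor_sd = 0.5, noise_sd = 0.3,
                          missing_midpoint = 14, missing_steepness = 1,
                          ptau_threshold = 16, label_noise_prob = 0,
                          pool_size = 20, capture = "single_cell",
                          seed = 1L) {
  cfg <- list(n_cells = as.integer(n_cells), n_donors = as.integer(n_donors),
              n_proteins = as.integer(n_proteins),
              frac_linear_up = frac_linear_up,
              frac_linear_down = frac_linear_down,
              frac_early_break = frac_early_break,
              frac_late_break = frac_late_break,
              tau_range = as.numeric(tau_range),
              breakpoint_early = breakpoint_early,
              breakpoint_late = breakpoint_late,
              slope_scale = slope_scale, donor_sd = donor_sd,
              noise_sd = noise_sd,
              missing_midpoint = missing_midpoint,
              missing_steepness = missing_steepness,
              ptau_threshold = ptau_threshold,
              label_noise_prob = label_noise_prob,
              pool_size = as.integer(pool_size), capture = capture,
              baseline_mean = 17, baseline_sd = 1.5,
              seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  chk <- function(ok, field, msg) {
    if (!ok) stop("invalid cohort_config field '", field, "': ", msg)
  }
  chk(cfg$n_cells >= 2, "n_cells", "need at least 2 cells")
  chk(cfg$n_donors >= 1 && cfg$n_donors <= cfg$n_cells, "n_donors",
      "must be in [1, n_cells]")
  chk(cfg$n_proteins >= 2, "n_proteins", "need at least 2 proteins")
  fr <- c(cfg$frac_linear_up, cfg$frac_linear_down,
          cfg$frac_early_break, cfg$frac_late_break)
  chk(all(fr >= 0 & fr <= 1), "frac_*", "fractions must lie in [0, 1]")
  chk(sum(fr) <= 1 + 1e-12, "frac_*", "fractions must sum to <= 1")
  chk(length(cfg$tau_range) == 2 && cfg$tau_range[1] < cfg$tau_range[2],
      "tau_range", "must be (lo, hi) with lo < hi")
  chk(cfg$tau_range[1] < cfg$breakpoint_early, "breakpoint_early",
      "must exceed tau_range lo")
  chk(cfg$breakpoint_early < cfg$breakpoint_late, "breakpoint_late",
      "must exceed breakpoint_early")
  chk(cfg$breakpoint_late < cfg$tau_range[2], "breakpoint_late",
      "must be below tau_range hi")
  chk(cfg$noise_sd > 0, "noise_sd", "must be > 0")
  chk(cfg$donor_sd >= 0, "donor_sd", "must be >= 0")
  chk(cfg$label_noise_prob >= 0 && cfg$label_noise_prob <= 1,
      "label_noise_prob", "must lie in [0, 1]")
  chk(cfg$capture %in% c("single_cell", "mini_pool"), "capture",
      "must be 'single_cell' or 'mini_pool'")
  chk(cfg$pool_size >= 1, "pool_size", "must be >= 1")
  invisible(cfg)
}

# internal: per-class protein counts; remainder are null proteins.
response_class_counts <- function(cfg) {
  n <- cfg$n_proteins - 1L  # one row is reserved for tau itself
  counts <- c(linear_up = round(cfg$frac_linear_up * cfg$n_proteins),
              linear_down = round(cfg$frac_linear_down * cfg$n_proteins),
              early_break = round(cfg$frac_early_break * cfg$n_proteins),
              late_break = round(cfg$frac_late_break * cfg$n_proteins))
  # rounding can push past capacity; trim the largest classes back
  while (sum(counts) > n) counts[which.max(counts)] <-
      counts[which.max(counts)] - 1L
  c(counts, null = n - sum(counts))
}

# internal: continuous hinge response around bp with slopes a1 (before) and
# a2 (after); value 0 at the left end of the tau range so baselines stay
# interpretable.
hinge_response <- function(tau, lo, bp, a1, a2) {
  a1 * (pmin(tau, bp) - lo) + a2 * pmax(tau - bp, 0)
}

#' Generate a synthetic cohort with ground truth
#'
#' Draws latent log2 tau uniformly over `tau_range`, assigns cells to donors,
#' and builds each protein's expectation as
#' baseline + piecewise-linear response to latent tau + donor intercept,
#' observed with Gaussian log2 noise. One row, `"MAPT"`, is the tau protein
#' itself (latent tau plus noise). In mini-pool mode, `pool_size` cell-level
#' expectations are averaged per pool before noise is added.
#'
#' @param config a [cohort_config()].
#' @return list with elements `matrix` (a complete [proteome_matrix()];
#'   apply [inject_missingness()] for MNAR dropout) and `truth` (list with
#'   data.frames `cells` and `proteins`).
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  cfg <- config
  withr_seed <- set_local_seed(cfg$seed)
  on.exit(withr_seed(), add = TRUE)

  n <- cfg$n_cells
  lo <- cfg$tau_range[1]; hi <- cfg$tau_range[2]
  tau <- runif(n, lo, hi)
  donor <- sprintf("D%02d", sample(rep_len(seq_len(cfg$n_donors), n)))
  donor_eff <- rnorm(cfg$n_donors, 0, cfg$donor_sd)
  names(donor_eff) <- sprintf("D%02d", seq_len(cfg$n_donors))
  ptau <- ifelse(tau > cfg$ptau_threshold, "positive", "negative")
  if (cfg$label_noise_prob > 0) {
    flip <- runif(n) < cfg$label_noise_prob
    ptau[flip] <- ifelse(ptau[flip] == "positive", "negative", "positive")
  }

  counts <- response_class_counts(cfg)
  classes <- rep(names(counts), counts)
  classes <- sample(classes)  # shuffle so classes are not row-ordered
  np <- cfg$n_proteins
  baseline <- rnorm(np - 1L, cfg$baseline_mean, cfg$baseline_sd)
  sgn <- sample(c(-1, 1), np - 1L, replace = TRUE)
  a1 <- numeric(np - 1L); a2 <- numeric(np - 1L)
  bp <- rep(NA_real_, np - 1L)
  a1[classes == "linear_up"] <- cfg$slope_scale
  a2[classes == "linear_up"] <- cfg$slope_scale
  a1[classes == "linear_down"] <- -cfg$slope_scale
  a2[classes == "linear_down"] <- -cfg$slope_scale
  eb <- classes == "early_break"
  a1[eb] <- sgn[eb] * cfg$slope_scale; a2[eb] <- 0
  bp[eb] <- cfg$breakpoint_early
  lb <- classes == "late_break"
  a1[lb] <- 0; a2[lb] <- sgn[lb] * cfg$slope_scale
  bp[lb] <- cfg$breakpoint_late

  # cell-level expectations (proteins x cells), tau row first
  expect <- matrix(0, np, n)
  expect[1, ] <- tau
  for (j in seq_len(np - 1L)) {
    b <- if (is.na(bp[j])) cfg$breakpoint_early else bp[j]
    expect[j + 1L, ] <- baseline[j] + hinge_response(tau, lo, b, a1[j], a2[j])
  }
  expect <- expect + rep(donor_eff[donor], each = np)
  expect[1, ] <- tau  # tau row carries no donor shift

  protein_ids <- c("MAPT", sprintf("PROT%04d", seq_len(np - 1L)))

  if (cfg$capture == "mini_pool") {
    # average pool_size contiguous cells (grouped within donor) per pool
    ord <- order(donor, tau)
    pool_of <- ceiling(seq_len(n) / cfg$pool_size)
    n_pool <- max(pool_of)
    pooled <- matrix(0, np, n_pool)
    pool_tau <- numeric(n_pool); pool_donor <- character(n_pool)
    for (p in seq_len(n_pool)) {
      idx <- ord[pool_of == p]
      pooled[, p] <- rowMeans(expect[, idx, drop = FALSE])
      pool_tau[p] <- mean(tau[idx])
      pool_donor[p] <- donor[idx[1]]
    }
    expect <- pooled
    tau <- pool_tau; donor <- pool_donor
    ptau <- ifelse(tau > cfg$ptau_threshold, "positive", "negative")
    n <- n_pool
  }

  values <- expect + matrix(rnorm(np * n, 0, cfg$noise_sd), np, n)
  sample_ids <- sprintf("S%03d", seq_len(n))
  dimnames(values) <- list(protein_ids, sample_ids)

  samples <- data.frame(sample_id = sample_ids, donor_id = donor,
                        ptau_status = ptau, capture = cfg$capture,
                        stringsAsFactors = FALSE)
  pm <- proteome_matrix(values, samples)

  truth <- list(
    cells = data.frame(sample_id = sample_ids, donor_id = donor,
                       tau_latent = tau, ptau_status = ptau,
                       donor_intercept = unname(donor_eff[donor]),
                       stringsAsFactors = FALSE),
    proteins = data.frame(protein_id = protein_ids,
                          class = c("tau", classes),
                          baseline = c(NA_real_, baseline),
                          alpha1 = c(NA_real_, a1),
                          alpha2 = c(NA_real_, a2),
                          breakpoint = c(NA_real_, bp),
                          stringsAsFactors = FALSE),
    config = cfg)
  list(matrix = pm, truth = truth)
}

#' Apply intensity-dependent (MNAR) missingness
#'
#' Each entry is independently retained with probability
#' `plogis((value - missing_midpoint) * missing_steepness)`, so low-abundance
#' measurements drop out preferentially, as in DIA proteomics. Removed
#' entries become `NA` and are cleared in the detection mask.
#'
#' @param matrix a complete [proteome_matrix()].
#' @param config the [cohort_config()] providing the logistic curve and seed.
#' @return a [proteome_matrix()] with missing entries.
#' @export
inject_missingness <- function(matrix, config) {
  validate_cohort_config(config)
  if (anyNA(matrix$values)) stop("'matrix' must be complete before injection")
  restore <- set_local_seed(config$seed + 1L)
  on.exit(restore(), add = TRUE)
  p_keep <- stats::plogis((matrix$values - config$missing_midpoint) *
                            config$missing_steepness)
  keep <- matrix(runif(length(p_keep)) < p_keep, nrow(p_keep), ncol(p_keep))
  values <- matrix$values
  values[!keep] <- NA_real_
  proteome_matrix(values, matrix$samples)
}

#' Simulate a phosphopeptide layer with controllable occupancy excess
#'
#' Per-cell phospho intensity is
#' `a0 + a1 * tau + donor intercept + beta_true * [pTau-positive] + noise`,
#' the generative counterpart of the random-intercept model fitted by
#' [fit_random_intercept_lmm()]: `beta_true` is the log2 occupancy excess in
#' pTau-positive cells beyond what tau abundance predicts.
#'
#' @param matrix a [proteome_matrix()] containing the tau row.
#' @param truth ground-truth list from [generate_cohort()].
#' @param beta_true injected log2 excess (e.g. 1.16 corresponds to a
#'   2.2-fold occupancy increase).
#' @param occupancy_noise_sd residual SD of the phospho layer (log2 units).
#' @param a0,a1 intercept and tau slope of the baseline occupancy relation.
#' @param donor_sd SD of the layer's donor random intercepts.
#' @param site site label, e.g. `"pT231"`.
#' @param tau_id row holding tau intensities.
#' @param seed integer seed.
#' @return data.frame with one row per sample: `sample_id`, `donor_id`,
#'   `ptau_status`, `site`, `tau`, `intensity`; `beta_true` and the drawn
#'   donor intercepts attached as attributes.
#' @export
generate_phospho_layer <- function(matrix, truth, beta_true = 1.16,
                                   occupancy_noise_sd = 0.3,
                                   a0 = 2, a1 = 0.8, donor_sd = 0.5,
                                   site = "pT231", tau_id = "MAPT",
                                   seed = 1L) {
  if (!tau_id %in% rownames(matrix$values))
    stop("tau row '", tau_id, "' not found in matrix")
  restore <- set_local_seed(as.integer(seed) + 2L)
  on.exit(restore(), add = TRUE)
  tau <- matrix$values[tau_id, ]
  if (anyNA(tau)) stop("tau row has undetected entries; impute or filter first")
  donors <- sort(unique(matrix$samples$donor_id))
  donor_eff <- rnorm(length(donors), 0, donor_sd)
  names(donor_eff) <- donors
  pos <- matrix$samples$ptau_status == "positive"
  y <- a0 + a1 * tau + donor_eff[matrix$samples$donor_id] +
    beta_true * pos + rnorm(length(tau), 0, occupancy_noise_sd)
  out <- data.frame(sample_id = matrix$samples$sample_id,
                    donor_id = matrix$samples$donor_id,
                    ptau_status = matrix$samples$ptau_status,
                    site = site, tau = unname(tau), intensity = unname(y),
                    stringsAsFactors = FALSE)
  attr(out, "beta_true") <- beta_true
  attr(out, "donor_intercepts") <- donor_eff
  out
}

# internal: set the RNG seed locally, returning a restorer closure
set_local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }
}
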