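#' Remove contaminant proteins
#'
#' Drops rows whose protein ID carries the contaminant prefix that DIA
#' search engines prepend (keratins, trypsin, etc.).
#'
#' @param matrix a [proteome_matrix()].
#' @param prefix contaminant ID prefix; default `"Cont_"`.
#' @return the matrix without contaminant rows.
#' @export
remove_contaminants <- function(matrix, prefix = "Cont_") {
  hit <- startsWith(rownames(matrix$values), prefix)
  if (all(hit)) warning("all ", sum(hit), " proteins are contaminants; ",
                        "returning an empty matrix")
  message(sum(hit), " contaminant protein(s) removed")
  subset_pm(matrix, rows = !hit)
}

#' Filter proteins by group-wise detection rate
#'
#' A protein is kept when its detection fraction is at least `min_frac`
#' (inclusive) in the pTau-positive group or in the pTau-negative group.
#' Detection means observed before imputation. The conventional thresholds
#' are 0.7 for mini-pool cohorts and 0.3 for single-cell cohorts.
#'
#' @param matrix a [proteome_matrix()].
#' @param min_frac minimum detection fraction in at least one group.
#' @return the filtered matrix.
#' @export
filter_proteins_by_detection <- function(matrix, min_frac = 0.7) {
  pos <- matrix$samples$ptau_status == "positive"
  if (!any(pos)) stop("pTau-positive group is empty")
  if (!any(!pos)) stop("pTau-negative group is empty")
  frac_pos <- rowMeans(matrix$detected[, pos, drop = FALSE])
  frac_neg <- rowMeans(matrix$detected[, !pos, drop = FALSE])
  keep <- frac_pos >= min_frac | frac_neg >= min_frac
  message(sum(!keep), " protein(s) below detection threshold removed")
  subset_pm(matrix, rows = keep)
}

#' Filter low-quality cells
#'
#' Two sequential sample filters: first, samples with fewer than
#' `min_proteins` detected proteins are removed; then, among the remaining
#' samples, those whose observed tau intensity falls below the
#' `tau_low_percentile`-th percentile (linear-interpolation percentile,
#' `stats::quantile` type 7) are removed. Samples where tau itself is
#' undetected cannot be placed on the tau axis and are removed with the
#' percentile step.
#'
#' @param matrix a [proteome_matrix()].
#' @param min_proteins minimum detected-protein count per sample.
#' @param tau_low_percentile percentile cutoff (0-100) on observed tau.
#' @param tau_id protein ID of the tau row.
#' @return the filtered matrix.
#' @export
filter_cells <- function(matrix, min_proteins = 1000,
                         tau_low_percentile = 5, tau_id = "MAPT") {
  if (!tau_id %in% rownames(matrix$values))
    stop("tau row '", tau_id, "' not found in matrix")
  n_det <- colSums(matrix$detected)
  keep1 <- n_det >= min_proteins
  message(sum(!keep1), " sample(s) removed with < ", min_proteins,
          " detected proteins")
  pm <- subset_pm(matrix, cols = keep1)
  tau <- pm$values[tau_id, ]
  tau[!pm$detected[tau_id, ]] <- NA
  cut <- stats::quantile(tau, tau_low_percentile / 100, na.rm = TRUE,
                         type = 7, names = FALSE)
  keep2 <- !is.na(tau) & tau >= cut
  message(sum(is.na(tau)), " sample(s) removed with undetected tau; ",
          sum(!keep2 & !is.na(tau)), " below the ", tau_low_percentile,
          "th tau percentile (cut = ", format(cut, digits = 4), ")")
  subset_pm(pm, cols = keep2)
}

#' Impute missing values from a downshifted normal distribution
#'
#' Perseus-style MNAR imputation: per sample, missing entries are drawn from
#' `Normal(mu - downshift * sigma, (width * sigma)^2)` where `mu` and `sigma`
#' are the mean and SD of that sample's observed values, placing imputed
#' values in the low-abundance tail where undetected proteins are expected
#' to lie. Observed values are never altered; imputed positions are flagged
#' in the `imputed` mask.
#'
#' @param matrix a [proteome_matrix()] of log2 intensities.
#' @param width SD of the imputation distribution as a fraction of the
#'   sample SD; default 0.3.
#' @param downshift shift of the imputation mean below the sample mean, in
#'   sample SDs; default 1.8.
#' @param seed integer seed.
#' @return a complete [proteome_matrix()].
#' @export
impute_downshifted_normal <- function(matrix, width = 0.3, downshift = 1.8,
                                      seed = 1L) {
  restore <- set_local_seed(as.integer(seed))
  on.exit(restore(), add = TRUE)
  values <- matrix$values
  imputed <- matrix$imputed
  for (j in seq_len(ncol(values))) {
    obs <- values[matrix$detected[, j], j]
    miss <- is.na(values[, j])
    if (!any(miss)) next
    if (length(obs) < 2)
      stop("sample '", colnames(values)[j],
           "' has fewer than 2 observed values; cannot impute")
    mu <- mean(obs); sigma <- stats::sd(obs)
    values[miss, j] <- rnorm(sum(miss), mu - downshift * sigma,
                             width * sigma)
    imputed[miss, j] <- TRUE
  }
  message(sum(imputed & !matrix$imputed), " value(s) imputed")
  proteome_matrix(values, matrix$samples, detected = matrix$detected,
                  imputed = imputed)
}

#' Run the full preprocessing chain
#'
#' Convenience wrapper applying, in order: contaminant removal, group-wise
#' detection filtering, cell-quality filtering (single-cell mode only) and
#' downshifted-normal imputation.
#'
#' @param matrix a [proteome_matrix()].
#' @param capture `"single_cell"` or `"mini_pool"`; selects the detection
#'   threshold (0.3 vs 0.7) and whether cell filters apply.
#' @param min_frac,min_proteins,tau_low_percentile,tau_id,width,downshift,seed
#'   stage parameters, see the individual steps.
#' @return a complete [proteome_matrix()].
#' @export
preprocess_matrix <- function(matrix, capture = c("single_cell", "mini_pool"),
                              min_frac = NULL, min_proteins = 1000,
                              tau_low_percentile = 5, tau_id = "MAPT",
                              width = 0.3, downshift = 1.8, seed = 1L) {
  capture <- match.arg(capture)
  if (is.null(min_frac))
    min_frac <- if (capture == "single_cell") 0.3 else 0.7
  pm <- remove_contaminants(matrix)
  pm <- filter_proteins_by_detection(pm, min_frac = min_frac)
  if (capture == "single_cell")
    pm <- filter_cells(pm, min_proteins = min_proteins,
                       tau_low_percentile = tau_low_percentile,
                       tau_id = tau_id)
  impute_downshifted_normal(pm, width = width, downshift = downshift,
                            seed = seed)
}
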