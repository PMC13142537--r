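#' Proteome matrix container
#'
#' A `proteome_matrix` bundles a proteins x samples matrix of log2
#' intensities with an explicit detection mask and per-sample metadata.
#' Undetected entries hold `NA` in `values` until imputation; after
#' [impute_downshifted_normal()] they hold imputed draws and are flagged in
#' the `imputed` mask, so "detected" always means observed by the instrument,
#' never rescued by imputation.
#'
#' @param values numeric matrix, proteins in rows (rownames = protein IDs),
#'   samples in columns (colnames = sample IDs). `NA` marks undetected
#'   entries.
#' @param samples data.frame of sample metadata with columns `sample_id`,
#'   `donor_id`, `ptau_status` (`"positive"`/`"negative"`) and `capture`
#'   (`"single_cell"`/`"mini_pool"`), one row per column of `values`.
#' @param detected optional logical matrix of the same shape as `values`;
#'   defaults to `!is.na(values)`.
#' @param imputed optional logical matrix marking entries filled by
#'   imputation; defaults to all-`FALSE`.
#'
#' @return An object of class `proteome_matrix` with elements `values`,
#'   `detected`, `imputed` and `samples`.
#' @export
proteome_matrix <- function(values, samples, detected = NULL, imputed = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values))) {
    if (nrow(values) > 0)
      stop("'values' must carry protein IDs as rownames")
    rownames(values) <- character(0)
  }
  if (is.null(colnames(values))) {
    if (ncol(values) > 0)
      stop("'values' must carry sample IDs as colnames")
    colnames(values) <- character(0)
  }
  if (anyDuplicated(rownames(values)))
    stop("duplicate protein IDs: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample IDs: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  samples <- validate_sample_meta(samples)
  if (!identical(colnames(values), samples$sample_id))
    stop("colnames(values) must equal samples$sample_id (same order)")
  if (is.null(detected)) detected <- !is.na(values)
  if (is.null(imputed)) {
    imputed <- matrix(FALSE, nrow(values), ncol(values),
                      dimnames = dimnames(values))
  }
  stopifnot(is.logical(detected), identical(dim(detected), dim(values)),
            is.logical(imputed), identical(dim(imputed), dim(values)))
  dimnames(detected) <- dimnames(values)
  dimnames(imputed) <- dimnames(values)
  if (any(!detected & !imputed & !is.na(values)))
    stop("entries neither detected nor imputed must be NA")
  structure(list(values = values, detected = detected, imputed = imputed,
                 samples = samples),
            class = "proteome_matrix")
}

validate_sample_meta <- function(samples) {
  if (!is.data.frame(samples)) stop("'samples' must be a data.frame")
  need <- c("sample_id", "donor_id", "ptau_status", "capture")
  miss <- setdiff(need, names(samples))
  if (length(miss)) stop("sample metadata lacks column(s): ",
                         paste(miss, collapse = ", "))
  samples$sample_id <- as.character(samples$sample_id)
  samples$donor_id <- as.character(samples$donor_id)
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample IDs in metadata")
  bad <- setdiff(unique(samples$ptau_status), c("positive", "negative"))
  if (length(bad)) stop("ptau_status must be 'positive' or 'negative', got: ",
                        paste(bad, collapse = ", "))
  bad <- setdiff(unique(samples$capture), c("single_cell", "mini_pool"))
  if (length(bad)) stop("capture must be 'single_cell' or 'mini_pool', got: ",
                        paste(bad, collapse = ", "))
  rownames(samples) <- NULL
  samples
}

#' @export
print.proteome_matrix <- function(x, ...) {
  cat(sprintf("proteome_matrix: %d proteins x %d samples\n",
              nrow(x$values), ncol(x$values)))
  det <- mean(x$detected)
  cat(sprintf("  detected: %.1f%% of entries; imputed: %d entries\n",
              100 * det, sum(x$imputed)))
  cat(sprintf("  samples: %d donors; %d pTau-positive / %d pTau-negative\n",
              length(unique(x$samples$donor_id)),
              sum(x$samples$ptau_status == "positive"),
              sum(x$samples$ptau_status == "negative")))
  invisible(x)
}

#' @export
dim.proteome_matrix <- function(x) dim(x$values)

# internal: subset rows/columns keeping all masks aligned
subset_pm <- function(pm, rows = NULL, cols = NULL) {
  if (is.null(rows)) rows <- seq_len(nrow(pm$values))
  if (is.null(cols)) cols <- seq_len(ncol(pm$values))
  proteome_matrix(pm$values[rows, cols, drop = FALSE],
                  pm$samples[cols, , drop = FALSE],
                  detected = pm$detected[rows, cols, drop = FALSE],
                  imputed = pm$imputed[rows, cols, drop = FALSE])
}

# internal: stop unless matrix has been imputed (no NA left)
assert_complete <- function(pm, what) {
  if (anyNA(pm$values))
    stop(what, " requires a complete (imputed) matrix; run ",
         "impute_downshifted_normal() first")
  invisible(pm)
}
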