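#' Read a protein x sample intensity matrix from TSV
#'
#' Expects a tab-separated file with protein IDs in the first column and
#' sample IDs in the header; empty cells or `NA` mark undetected entries.
#' When sample metadata is supplied the orientation is cross-checked
#' against its sample IDs and the matrix transposed if samples were in
#' rows; an orientation that matches neither axis is an error.
#'
#' @param path TSV file of intensities.
#' @param meta_path optional TSV of sample metadata (columns `sample_id`,
#'   `donor_id`, `ptau_status`, `capture`). Without metadata, placeholder
#'   metadata is built (unknown donor, negative, single_cell) with a
#'   warning.
#' @param sep field separator; default tab.
#' @return a [proteome_matrix()].
#' @export
read_matrix <- function(path, meta_path = NULL, sep = "\t") {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""), quote = "",
                           comment.char = "")
  ids <- as.character(raw[[1]])
  if (anyDuplicated(ids))
    stop("duplicate protein ID(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- raw[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    if (!is.numeric(vals[[j]])) {
      bad <- which(!is.na(vals[[j]]) &
                     is.na(suppressWarnings(as.numeric(vals[[j]]))))
      if (length(bad))
        stop("non-numeric cell at row ", bad[1], ", column '",
             names(vals)[j], "'")
      vals[[j]] <- as.numeric(vals[[j]])
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  if (!is.null(meta_path)) {
    samples <- read_sample_meta(meta_path, sep = sep)
    in_cols <- all(colnames(m) %in% samples$sample_id)
    in_rows <- all(rownames(m) %in% samples$sample_id)
    if (in_cols && in_rows)
      stop("matrix orientation is ambiguous: both axes match sample IDs")
    if (!in_cols && !in_rows)
      stop("neither matrix axis matches the metadata sample IDs")
    if (in_rows) m <- t(m)
    samples <- samples[match(colnames(m), samples$sample_id), , drop = FALSE]
  } else {
    warning("no sample metadata supplied; using placeholders")
    samples <- data.frame(sample_id = colnames(m), donor_id = "unknown",
                          ptau_status = "negative", capture = "single_cell",
                          stringsAsFactors = FALSE)
  }
  proteome_matrix(m, samples)
}

#' @rdname read_matrix
#' @param matrix a [proteome_matrix()] to write; undetected entries are
#'   written as `NA`.
#' @export
write_matrix <- function(matrix, path, meta_path = NULL, sep = "\t") {
  v <- matrix$values
  v[!matrix$detected & !matrix$imputed] <- NA
  df <- data.frame(protein_id = rownames(v), v, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  if (!is.null(meta_path))
    utils::write.table(matrix$samples, meta_path, sep = sep, quote = FALSE,
                       row.names = FALSE)
  invisible(path)
}

read_sample_meta <- function(path, sep = "\t") {
  validate_sample_meta(utils::read.table(path, header = TRUE, sep = sep,
                                         stringsAsFactors = FALSE,
                                         quote = "", comment.char = ""))
}

#' Read gene sets in GMT format
#'
#' Tab-separated, one set per line: name, description, then member IDs.
#'
#' @param path GMT file.
#' @return named list of character vectors; descriptions attached as
#'   attribute `descriptions`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad))
    stop("GMT line(s) with fewer than 3 fields: ",
         paste(utils::head(bad, 5), collapse = ", "))
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, character(1), 1)
  if (anyDuplicated(names(sets))) stop("duplicate gene-set names in GMT")
  attr(sets, "descriptions") <- vapply(parts, `[[`, character(1), 2)
  sets
}

#' Assemble a pipeline configuration
#'
#' Capture mode selects the field defaults: detection `min_frac` 0.3
#' (single-cell) vs 0.7 (mini-pool), cluster `k` 6 vs 4, trajectory method
#' tau proxy vs diffusion pseudotime. Unknown keys are rejected.
#'
#' @param capture `"single_cell"` or `"mini_pool"`.
#' @param ... overrides of the per-stage defaults; see the individual
#'   stage functions for meanings.
#' @return a named list of class `pipeline_config`.
#' @export
pipeline_config <- function(capture = c("single_cell", "mini_pool"), ...) {
  capture <- match.arg(capture)
  cfg <- list(capture = capture,
              min_frac = if (capture == "single_cell") 0.3 else 0.7,
              min_proteins = 1000, tau_low_percentile = 5,
              tau_id = "MAPT", impute_width = 0.3, impute_downshift = 1.8,
              trajectory_method = if (capture == "single_cell")
                "tau_proxy" else "diffusion_pseudotime",
              root_sample = NULL, k_graph = 10, knn_dm = 5,
              n_components = 5, n_bins = 5,
              cluster_k = if (capture == "single_cell") 6L else 4L,
              q_threshold = 0.05, n_boot = 1000, mad_threshold = 3,
              range_lo = 0.20, range_hi = 0.80, seed = 1L)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown configuration key(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full analysis pipeline
#'
#' Orchestrates preprocessing, trajectory construction, the correlation
#' screen, clustering of significant proteins, proteostasis pathway trends
#' and the breakpoint analysis, writing every stage output as TSV under
#' `out_dir` together with a JSON run manifest (seed, parameters, stage
#' row counts).
#'
#' @param matrix a raw [proteome_matrix()] (with missing values).
#' @param config a [pipeline_config()].
#' @param out_dir output directory; created if absent.
#' @return invisibly, a list with the in-memory stage results
#'   (`preprocessed`, `trajectory`, `associations`, `clusters`, `scores`,
#'   `trends`, `breakpoints`, `manifest`).
#' @export
run_pipeline <- function(matrix, config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  pm <- stage("preprocess", preprocess_matrix(
    matrix, capture = config$capture, min_frac = config$min_frac,
    min_proteins = config$min_proteins,
    tau_low_percentile = config$tau_low_percentile,
    tau_id = config$tau_id, width = config$impute_width,
    downshift = config$impute_downshift, seed = config$seed))
  write_matrix(pm, file.path(out_dir, "matrix_preprocessed.tsv"),
               file.path(out_dir, "sample_metadata.tsv"))

  traj <- stage("trajectory", {
    if (config$trajectory_method == "tau_proxy") {
      tau_proxy_ordering(pm, tau_id = config$tau_id)
    } else {
      root <- config$root_sample
      if (is.null(root)) stop("diffusion pseudotime requires 'root_sample'")
      diffusion_pseudotime(pm, root_sample = root, k_graph = config$k_graph,
                           knn_dm = config$knn_dm,
                           n_components = config$n_components)
    }
  })
  utils::write.table(as.data.frame(traj)[, c("sample_id", "value")],
                     file.path(out_dir, "trajectory.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  assoc <- stage("correlate",
                 correlate_with_axis(pm, traj,
                                     q_threshold = config$q_threshold))
  utils::write.table(assoc, file.path(out_dir, "associations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  clusters <- NULL
  if (sum(assoc$significant) >= config$cluster_k) {
    clusters <- stage("cluster",
                      cluster_significant(pm, assoc, k = config$cluster_k,
                                          trajectory = traj))
    utils::write.table(
      data.frame(protein_id = names(clusters$labels),
                 cluster = unname(clusters$labels)),
      file.path(out_dir, "clusters.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }

  scores <- NULL; trends <- NULL
  defs <- builtin_definitions()
  have <- vapply(defs, function(d)
    length(resolve_members(d, rownames(pm$values))) > 0, logical(1))
  if (any(have)) {
    scores <- lapply(defs[have], function(d) pathway_score(pm, d))
    score_tab <- data.frame(sample_id = pm$samples$sample_id,
                            lapply(scores, unname), check.names = FALSE)
    utils::write.table(score_tab, file.path(out_dir, "pathway_scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (identical(attr(traj, "method"), "tau_proxy")) {
      bins <- bin_by_tau(traj, n_bins = config$n_bins)
      trends <- do.call(rbind, lapply(names(scores), function(nm) {
        cbind(score = nm, binned_trend(scores[[nm]], bins))
      }))
      utils::write.table(trends, file.path(out_dir, "pathway_trends.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  bp <- NULL
  if (identical(attr(traj, "method"), "tau_proxy")) {
    bp <- stage("breakpoints", run_breakpoint_analysis(
      pm, traj, n_boot = config$n_boot, seed = config$seed,
      mad_threshold = config$mad_threshold, range_lo = config$range_lo,
      range_hi = config$range_hi, exclude = config$tau_id))
    utils::write.table(bp$table, file.path(out_dir, "breakpoints.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  manifest <- list(package_version = as.character(
                     utils::packageVersion("tautraj")),
                   seed = config$seed,
                   capture = config$capture,
                   parameters = config[setdiff(names(config), "capture")],
                   n_proteins = nrow(pm$values),
                   n_samples = ncol(pm$values),
                   n_significant = sum(assoc$significant),
                   stages = list.files(out_dir, pattern = "\\.tsv$"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(list(preprocessed = pm, trajectory = traj, associations = assoc,
                 clusters = clusters, scores = scores, trends = trends,
                 breakpoints = bp, manifest = manifest))
}
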