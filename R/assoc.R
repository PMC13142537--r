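#' Benjamini-Hochberg adjustment
#'
#' Step-up BH false-discovery-rate adjustment with monotonicity enforcement,
#' returned in the input order. Thin validated wrapper over
#' `stats::p.adjust(method = "BH")`.
#'
#' @param pvalues numeric vector of p-values in [0, 1]; `NA` allowed and
#'   passed through.
#' @return q-values in the input order.
#' @export
bh_adjust <- function(pvalues) {
  ok <- is.na(pvalues) | (pvalues >= 0 & pvalues <= 1)
  if (!all(ok)) stop("p-values outside [0, 1] at position(s): ",
                     paste(which(!ok), collapse = ", "))
  stats::p.adjust(pvalues, method = "BH")
}

#' Correlate every protein with the trajectory axis
#'
#' Pearson correlation of each protein's (imputed) log2 intensity profile
#' with the trajectory value, with the usual two-sided t-test on n - 2
#' degrees of freedom and BH correction across proteins. Zero-variance
#' proteins have an undefined correlation; they are flagged and excluded
#' from the FDR so they do not deflate the BH denominator.
#'
#' @param matrix a complete [proteome_matrix()].
#' @param trajectory a `trajectory_result` covering the same samples.
#' @param q_threshold significance threshold on the BH q-value
#'   (default 0.05).
#' @return data.frame with columns `protein_id`, `r`, `p`, `q`,
#'   `significant`, `rank` (by |r| among significant proteins, 1 = largest)
#'   and `zero_variance`.
#' @export
correlate_with_axis <- function(matrix, trajectory, q_threshold = 0.05) {
  assert_complete(matrix, "correlate_with_axis")
  axis <- align_axis(matrix, trajectory)
  v <- matrix$values
  n <- ncol(v)
  if (n < 3) stop("need at least 3 samples for a correlation test")
  sds <- apply(v, 1, stats::sd)
  zero_var <- sds == 0 | stats::sd(axis) == 0
  r <- rep(NA_real_, nrow(v))
  r[!zero_var] <- as.vector(stats::cor(t(v[!zero_var, , drop = FALSE]), axis))
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  q <- rep(NA_real_, length(p))
  q[!zero_var] <- bh_adjust(p[!zero_var])
  sig <- !is.na(q) & q < q_threshold
  rk <- rep(NA_integer_, length(r))
  rk[sig] <- rank(-abs(r[sig]), ties.method = "first")
  if (any(zero_var))
    warning(sum(zero_var), " zero-variance protein(s) excluded from FDR")
  data.frame(protein_id = rownames(v), r = r, p = p, q = q,
             significant = sig, rank = rk, zero_variance = zero_var,
             stringsAsFactors = FALSE)
}

# internal: trajectory values aligned to matrix column order
align_axis <- function(matrix, trajectory) {
  idx <- match(colnames(matrix$values), trajectory$sample_id)
  if (anyNA(idx))
    stop("trajectory does not cover sample(s): ",
         paste(colnames(matrix$values)[is.na(idx)], collapse = ", "))
  trajectory$value[idx]
}

#' Cluster significant proteins
#'
#' Z-scores each significant protein across samples, computes Euclidean
#' pairwise distances and applies Ward's minimum-variance linkage
#' (`hclust(method = "ward.D2")`, the Euclidean-distance form of Ward's
#' method), cutting the tree into exactly `k` clusters. The returned
#' z-score matrix has its columns ordered by the trajectory axis, ready for
#' heatmap display.
#'
#' @param matrix a complete [proteome_matrix()].
#' @param records association table from [correlate_with_axis()].
#' @param k number of clusters (4 for mini-pool, 6 for single-cell in the
#'   defaults used here).
#' @param trajectory a `trajectory_result` used to order columns.
#' @return list with `labels` (named integer cluster per protein),
#'   `zscores` (proteins x samples, columns in axis order) and the `hclust`
#'   tree.
#' @export
cluster_significant <- function(matrix, records, k, trajectory) {
  assert_complete(matrix, "cluster_significant")
  sig_ids <- records$protein_id[records$significant]
  if (length(sig_ids) < k)
    stop("only ", length(sig_ids), " significant proteins; need at least k = ", k)
  z <- t(scale(t(matrix$values[sig_ids, , drop = FALSE])))
  tree <- stats::hclust(stats::dist(z), method = "ward.D2")
  labels <- stats::cutree(tree, k = k)
  axis <- align_axis(matrix, trajectory)
  z <- z[, order(axis), drop = FALSE]
  list(labels = labels, zscores = z, tree = tree)
}

#' Screen a curated protein panel
#'
#' Intersects a curated panel (e.g. cell-death proteins) with the detected
#' proteome and reports per-protein association with the trajectory axis,
#' with BH correction computed within the panel. The intensity table is
#' returned with samples ordered by the axis.
#'
#' @param matrix a complete [proteome_matrix()].
#' @param panel character vector of protein IDs; duplicates are dropped
#'   with a warning.
#' @param trajectory a `trajectory_result`.
#' @return list with `detected` (IDs found), `n_detected`, `stats`
#'   (association records restricted to the panel, q within panel) and
#'   `intensities` (panel proteins x samples, axis order); empty panel
#'   intersection yields an empty report with a warning.
#' @export
screen_panel <- function(matrix, panel, trajectory) {
  if (!length(panel)) stop("panel is empty")
  if (anyDuplicated(panel)) {
    warning("duplicate panel IDs de-duplicated")
    panel <- unique(panel)
  }
  found <- intersect(panel, rownames(matrix$values))
  if (!length(found)) {
    warning("no panel protein detected in the matrix")
    return(list(detected = character(), n_detected = 0L,
                stats = NULL, intensities = NULL))
  }
  sub <- subset_pm(matrix, rows = rownames(matrix$values) %in% found)
  stats <- correlate_with_axis(sub, trajectory)
  axis <- align_axis(sub, trajectory)
  list(detected = found, n_detected = length(found), stats = stats,
       intensities = sub$values[, order(axis), drop = FALSE])
}

#' Hypergeometric over-representation analysis
#'
#' One-sided enrichment test per gene set: with the background as the
#' population, set members in the background as successes and the query as
#' the draw, the p-value is `P(X >= overlap)`; BH correction across sets.
#' Sets with no member in the background are skipped with a warning.
#'
#' @param query character vector of protein IDs; must be a subset of
#'   `background`.
#' @param gene_sets named list of character vectors (e.g. from
#'   [read_gmt()]).
#' @param background character vector defining the tested universe
#'   (typically all proteins passing detection filters).
#' @return data.frame with columns `set_name`, `overlap`, `set_size`
#'   (within background), `query_size`, `background_size`, `p`, `q`.
#' @export
ora_hypergeometric <- function(query, gene_sets, background) {
  query <- unique(query); background <- unique(background)
  extra <- setdiff(query, background)
  if (length(extra))
    stop("query contains ID(s) outside the background: ",
         paste(utils::head(extra, 5), collapse = ", "))
  n_bg <- length(background)
  n_q <- length(query)
  rows <- lapply(names(gene_sets), function(nm) {
    set_bg <- intersect(unique(gene_sets[[nm]]), background)
    if (!length(set_bg)) {
      warning("gene set '", nm, "' has no member in the background; skipped")
      return(NULL)
    }
    ov <- length(intersect(set_bg, query))
    p <- stats::phyper(ov - 1, length(set_bg), n_bg - length(set_bg), n_q,
                       lower.tail = FALSE)
    data.frame(set_name = nm, overlap = ov, set_size = length(set_bg),
               query_size = n_q, background_size = n_bg, p = p,
               stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows))
    return(data.frame(set_name = character(), overlap = integer(),
                      set_size = integer(), query_size = integer(),
                      background_size = integer(), p = numeric(),
                      q = numeric(), stringsAsFactors = FALSE))
  rows$q <- bh_adjust(rows$p)
  rows
}
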