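#' Trajectory result container
#'
#' A data.frame with one row per sample (`sample_id`, `value`) plus
#' attributes `method` (`"tau_proxy"` or `"diffusion_pseudotime"`),
#' `root_sample` and `parameters`. For the tau proxy, `value` is the log2
#' tau intensity; for diffusion pseudotime it is the min-max scaled
#' diffusion distance from the root, in [0, 1] with the root at 0.
#'
#' @param values named numeric vector of per-sample trajectory values.
#' @param method ordering method.
#' @param root_sample root sample ID or `NA`.
#' @param parameters list of method parameters.
#' @keywords internal
trajectory_result <- function(values, method, root_sample = NA_character_,
                              parameters = list()) {
  out <- data.frame(sample_id = names(values), value = unname(values),
                    stringsAsFactors = FALSE)
  attr(out, "method") <- method
  attr(out, "root_sample") <- root_sample
  attr(out, "parameters") <- parameters
  class(out) <- c("trajectory_result", "data.frame")
  out
}

#' Order samples by tau abundance
#'
#' Uses log2 tau (MAPT) intensity as a proxy for pseudotime: the per-sample
#' trajectory value is the tau intensity itself. Rank ties are broken by
#' stable sample-ID order; an all-tied axis is flagged degenerate.
#'
#' @param matrix a complete (imputed) [proteome_matrix()].
#' @param tau_id protein ID of the tau row.
#' @return a `trajectory_result`; ranks are in column `rank` and a logical
#'   attribute `degenerate` flags a constant axis.
#' @export
tau_proxy_ordering <- function(matrix, tau_id = "MAPT") {
  if (!tau_id %in% rownames(matrix$values))
    stop("tau row '", tau_id, "' not found in matrix")
  assert_complete(matrix, "tau_proxy_ordering")
  tau <- matrix$values[tau_id, ]
  out <- trajectory_result(tau, "tau_proxy",
                           parameters = list(tau_id = tau_id))
  out$rank <- rank(tau, ties.method = "first")
  attr(out, "degenerate") <- length(unique(tau)) == 1L
  if (attr(out, "degenerate"))
    warning("all samples have identical tau; ordering follows sample-ID order")
  out
}

#' Diffusion-map pseudotime from a root sample
#'
#' Orders samples along a low-dimensional manifold: PCA reduction, a kNN
#' graph with an adaptive Gaussian kernel (per-sample bandwidth = distance
#' to the `knn_dm`-th neighbour), row-normalised Markov transition matrix,
#' eigendecomposition, and a multiscale diffusion space built from the top
#' `n_components` non-trivial eigenvectors weighted by
#' `lambda / (1 - lambda)`. Pseudotime is the Euclidean distance from the
#' root in that space, min-max scaled to [0, 1].
#'
#' The eigenvector sign convention (largest-magnitude entry positive) makes
#' the result deterministic; the kernel is symmetrised so that the Markov
#' chain is reversible and the spectrum real.
#'
#' @param matrix a complete [proteome_matrix()].
#' @param root_sample sample ID used as the origin of the trajectory
#'   (conventionally the most pTau-negative sample).
#' @param k_graph neighbours in the kNN graph (default 10).
#' @param knn_dm neighbour index setting the adaptive bandwidth (default 5).
#' @param n_components non-trivial diffusion components kept (default 5).
#' @param n_pcs PCA dimensions used for distances (default 50, capped at
#'   the data rank).
#' @return a `trajectory_result` with values in [0, 1], root at 0.
#' @export
diffusion_pseudotime <- function(matrix, root_sample, k_graph = 10,
                                 knn_dm = 5, n_components = 5, n_pcs = 50) {
  assert_complete(matrix, "diffusion_pseudotime")
  n <- ncol(matrix$values)
  if (n < n_components + 2)
    stop("need at least n_components + 2 = ", n_components + 2, " samples")
  ids <- colnames(matrix$values)
  if (!root_sample %in% ids)
    stop("root sample '", root_sample, "' not found")
  k_graph <- min(k_graph, n - 1L)
  knn_dm <- min(knn_dm, k_graph)

  x <- t(matrix$values)
  n_pcs <- min(n_pcs, n - 1L, ncol(x))
  pcs <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = n_pcs)$x
  d <- as.matrix(stats::dist(pcs))

  # adaptive kernel on the union-symmetrised kNN graph
  w <- matrix(0, n, n)
  sigma <- numeric(n)
  nn_idx <- vector("list", n)
  for (i in seq_len(n)) {
    ord <- order(d[i, ])[-1]          # drop self
    nn_idx[[i]] <- ord[seq_len(k_graph)]
    sigma[i] <- d[i, ord[knn_dm]]
  }
  if (any(sigma == 0)) sigma[sigma == 0] <- min(sigma[sigma > 0], 1e-12)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    j <- nn_idx[[i]]
    adj[i, j] <- TRUE
    # floor far-edge weights above double underflow so an edge present in
    # the kNN graph always carries connectivity
    w[i, j] <- pmax(exp(-d[i, j]^2 / (sigma[i] * sigma[j])),
                    .Machine$double.xmin)
  }
  w <- pmax(w, t(w))  # symmetrise: keep an edge if either endpoint has it
  adj <- adj | t(adj)

  comp <- graph_components(adj)
  if (max(comp) > 1L) {
    sizes <- table(comp)
    stop("kNN graph is disconnected (", max(comp), " components of sizes ",
         paste(sizes, collapse = ", "), "); increase k_graph")
  }

  # reversible Markov chain via the symmetric normalisation
  deg <- rowSums(w)
  s <- w / sqrt(deg %o% deg)
  es <- eigen(s, symmetric = TRUE)
  lam <- es$values[seq_len(n_components + 1L)]
  vec <- es$vectors[, seq_len(n_components + 1L), drop = FALSE]
  phi <- vec / sqrt(deg)              # right eigenvectors of the Markov matrix
  lam <- lam[-1L]; phi <- phi[, -1L, drop = FALSE]  # drop trivial component
  lam <- pmin(lam, 1 - 1e-10)
  for (j in seq_len(ncol(phi))) {     # fixed sign convention
    k <- which.max(abs(phi[, j]))
    if (phi[k, j] < 0) phi[, j] <- -phi[, j]
  }
  ms <- sweep(phi, 2, lam / (1 - lam), `*`)

  root <- match(root_sample, ids)
  pt <- sqrt(rowSums(sweep(ms, 2, ms[root, ], `-`)^2))
  rng <- range(pt)
  pt <- if (diff(rng) > 0) (pt - rng[1]) / diff(rng) else pt * 0
  names(pt) <- ids
  trajectory_result(pt, "diffusion_pseudotime", root_sample = root_sample,
                    parameters = list(k_graph = k_graph, knn_dm = knn_dm,
                                      n_components = n_components,
                                      n_pcs = n_pcs))
}

# internal: connected components of an undirected adjacency (logical matrix)
graph_components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (start in seq_len(n)) {
    if (comp[start] > 0L) next
    cur <- cur + 1L
    queue <- start
    comp[start] <- cur
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Bin samples into equal-width tau intervals
#'
#' Divides the observed tau range into `n_bins` equal-width bins. Internal
#' bins are left-closed/right-open; the last bin includes the maximum, so
#' every sample is assigned. Bins are labelled 0 to `n_bins - 1`.
#'
#' @param trajectory a tau-proxy `trajectory_result`.
#' @param n_bins number of bins (default 5).
#' @return integer vector of bin labels named by sample ID; bin edges are
#'   attached as attribute `edges`.
#' @export
bin_by_tau <- function(trajectory, n_bins = 5) {
  if (!identical(attr(trajectory, "method"), "tau_proxy"))
    stop("binning is defined on a tau-proxy trajectory")
  if (n_bins < 2) stop("n_bins must be at least 2")
  x <- trajectory$value
  if (min(x) == max(x)) stop("degenerate tau range: min equals max")
  edges <- seq(min(x), max(x), length.out = n_bins + 1L)
  bins <- findInterval(x, edges, rightmost.closed = TRUE) - 1L
  names(bins) <- trajectory$sample_id
  attr(bins, "edges") <- edges
  bins
}
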