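#' Remove outliers beyond a MAD threshold
#'
#' Flags values further than `threshold` scaled median absolute deviations
#' (MAD x 1.4826, the normal-consistent scaling) from the median. By
#' default the flagged values are excluded from fitting (trimming); with
#' `clip = TRUE` they are instead clipped to the threshold boundary.
#'
#' @param y numeric vector (length >= 5).
#' @param threshold MAD multiples; default 3.
#' @param clip clip instead of exclude.
#' @return list with `y` (cleaned vector, same length; clipped values when
#'   `clip = TRUE`), `keep` (logical, `FALSE` for excluded values; all
#'   `TRUE` when clipping) and `n_removed`.
#' @export
winsorize_mad <- function(y, threshold = 3, clip = FALSE) {
  if (length(y) < 5) stop("need at least 5 values")
  med <- stats::median(y)
  s <- stats::mad(y)  # 1.4826 scaling
  if (s == 0) {
    warning("MAD is zero; no outlier handling applied")
    return(list(y = y, keep = rep(TRUE, length(y)), n_removed = 0L))
  }
  out <- abs(y - med) > threshold * s
  if (clip) {
    y2 <- pmin(pmax(y, med - threshold * s), med + threshold * s)
    return(list(y = y2, keep = rep(TRUE, length(y)),
                n_removed = 0L, n_clipped = sum(out)))
  }
  list(y = y, keep = !out, n_removed = sum(out))
}

# internal: exact least squares at fixed breakpoints; returns NULL when the
# design is degenerate. Slopes are per-segment (alpha_1..alpha_{B+1}).
piecewise_ls <- function(x, y, psi) {
  if (length(psi) && (any(psi <= min(x)) || any(psi >= max(x)) ||
                      is.unsorted(psi, strictly = TRUE)))
    return(NULL)
  d <- cbind(1, x)
  for (b in psi) d <- cbind(d, pmax(x - b, 0))
  fit <- .lm.fit(d, y)
  if (fit$rank < ncol(d)) return(NULL)
  cf <- numeric(ncol(d))
  cf[fit$pivot] <- fit$coefficients
  rss <- sum(fit$residuals^2)
  slopes <- cumsum(cf[-1])
  list(psi = psi, intercept = cf[1], slopes = unname(slopes), rss = rss,
       fitted = y - fit$residuals, residuals = fit$residuals)
}

# internal: Muggeo-style iterative linearisation from starting breakpoints.
# Returns the best exact-LS solution visited plus a convergence flag.
muggeo_iterate <- function(x, y, psi, maxit = 30, tol = 1e-9) {
  rng <- diff(range(x))
  eps <- 1e-6 * rng
  best <- piecewise_ls(x, y, psi)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    u <- vapply(psi, function(b) pmax(x - b, 0), numeric(length(x)))
    v <- vapply(psi, function(b) -as.numeric(x > b), numeric(length(x)))
    d <- cbind(1, x, u, v)
    fit <- .lm.fit(d, y)
    if (fit$rank < ncol(d)) break
    cf <- numeric(ncol(d))
    cf[fit$pivot] <- fit$coefficients
    bcoef <- cf[2 + seq_along(psi)]
    gcoef <- cf[2 + length(psi) + seq_along(psi)]
    if (any(abs(bcoef) < 1e-12)) break
    step <- gcoef / bcoef
    psi_new <- sort(pmin(pmax(psi + step, min(x) + eps), max(x) - eps))
    if (length(psi_new) > 1 && any(diff(psi_new) < eps))
      psi_new <- psi_new + seq_along(psi_new) * eps  # pull apart collisions
    cand <- piecewise_ls(x, y, psi_new)
    if (!is.null(cand) && (is.null(best) || cand$rss < best$rss)) best <- cand
    if (max(abs(psi_new - psi)) < tol * rng) { converged <- TRUE; break }
    psi <- psi_new
  }
  list(best = best, psi = psi, converged = converged)
}

# internal: candidate breakpoints for initialisation. Midpoints between
# consecutive distinct x values when few, quantile-spaced otherwise.
candidate_breakpoints <- function(x, max_cand = 512) {
  xs <- sort(unique(x))
  mid <- (xs[-1] + xs[-length(xs)]) / 2
  if (length(mid) <= max_cand) return(mid)
  unname(stats::quantile(x, probs = seq(0.02, 0.98, length.out = max_cand),
                         type = 7))
}

#' Continuous piecewise-linear fit with a fixed number of breakpoints
#'
#' Least-squares fit of a continuous broken-line model with `n_breakpoints`
#' in {0, 1, 2}. Estimation combines an exhaustive scan of candidate
#' breakpoint positions (midpoints between consecutive x values),
#' Muggeo-type iterative linearisation of the breakpoint update (the gap
#' covariate trick) and bootstrap restarting: residuals of the incumbent
#' are resampled, the model refitted on the perturbed response, and the
#' resulting breakpoints re-evaluated by exact least squares on the
#' original data, keeping whichever solution has the lowest original-data
#' RSS. This escapes local optima of the non-convex profile RSS while
#' remaining deterministic for a fixed seed.
#'
#' The returned `slopes` are per-segment slopes (alpha_1 before the first
#' breakpoint, alpha_2 after it, ...), not slope changes.
#'
#' @param x ordering values (e.g. log2 tau); `y` response (conventionally
#'   z-scored upstream).
#' @param y numeric response.
#' @param n_breakpoints 0, 1 or 2.
#' @param n_boot bootstrap-restarting iterations (default 1000; 50 is
#'   plenty on cohorts of a few hundred cells).
#' @param seed integer seed for the bootstrap.
#' @return object of class `piecewise_fit`: `n_breakpoints`, `breakpoints`,
#'   `intercept`, `slopes`, `rss`, `n`, `bic`, `converged`.
#' @export
fit_piecewise <- function(x, y, n_breakpoints = 1, n_boot = 1000, seed = 1L) {
  b <- as.integer(n_breakpoints)
  if (b < 0 || b > 2) stop("n_breakpoints must be 0, 1 or 2")
  stopifnot(length(x) == length(y))
  n_distinct <- length(unique(x))
  need <- 2L * (b + 1L) + b
  if (n_distinct < need)
    stop("need at least ", need, " distinct x values for ", b,
         " breakpoint(s), got ", n_distinct)

  if (b == 0L) {
    ls <- piecewise_ls(x, y, numeric(0))
    return(new_piecewise_fit(ls, 0L, length(y), TRUE))
  }

  restore <- set_local_seed(as.integer(seed))
  on.exit(restore(), add = TRUE)

  cand <- candidate_breakpoints(x)
  if (b == 1L) {
    scans <- lapply(cand, function(ps) piecewise_ls(x, y, ps))
  } else {
    # coarse pair grid seeded with the one-breakpoint optimum
    coarse <- candidate_breakpoints(x, max_cand = 14)
    b1 <- fit_piecewise(x, y, 1L, n_boot = 0L, seed = seed)
    pool <- sort(unique(c(coarse, b1$breakpoints)))
    pairs <- utils::combn(pool, 2, simplify = FALSE)
    scans <- lapply(pairs, function(ps) piecewise_ls(x, y, ps))
  }
  scans <- Filter(Negate(is.null), scans)
  if (!length(scans)) stop("no admissible breakpoint configuration")
  best <- scans[[which.min(vapply(scans, `[[`, numeric(1), "rss"))]]

  polish <- muggeo_iterate(x, y, best$psi)
  converged <- polish$converged
  if (!is.null(polish$best) && polish$best$rss < best$rss) best <- polish$best

  for (i in seq_len(n_boot)) {
    y_star <- best$fitted + sample(best$residuals, replace = TRUE)
    pert <- muggeo_iterate(x, y_star, best$psi, maxit = 6)
    if (is.null(pert$best)) next
    cand_fit <- piecewise_ls(x, y, pert$best$psi)
    if (!is.null(cand_fit) && cand_fit$rss < best$rss - 1e-12) {
      re <- muggeo_iterate(x, y, cand_fit$psi)
      best <- if (!is.null(re$best) && re$best$rss < cand_fit$rss)
        re$best else cand_fit
      converged <- converged || re$converged
    }
  }
  new_piecewise_fit(best, b, length(y), converged)
}

new_piecewise_fit <- function(ls, b, n, converged) {
  fit <- structure(list(n_breakpoints = b, breakpoints = ls$psi,
                        intercept = ls$intercept, slopes = ls$slopes,
                        rss = ls$rss, n = n, bic = NA_real_,
                        converged = converged),
                   class = "piecewise_fit")
  fit$bic <- bic_piecewise(fit)
  fit
}

#' @export
print.piecewise_fit <- function(x, ...) {
  cat(sprintf("piecewise fit: %d breakpoint(s)", x$n_breakpoints))
  if (x$n_breakpoints > 0)
    cat(" at ", paste(format(x$breakpoints, digits = 4), collapse = ", "))
  cat(sprintf("\n  slopes: %s; RSS = %.4g; BIC = %.4g; converged: %s\n",
              paste(format(x$slopes, digits = 4), collapse = ", "),
              x$rss, x$bic, x$converged))
  invisible(x)
}

#' Bayesian information criterion of a piecewise fit
#'
#' `BIC = n * ln(RSS / n) + k * ln(n)` with `k = 2 + 2 * B`: intercept and
#' base slope, plus one slope change and one position per breakpoint. A
#' perfect fit (RSS = 0) returns `-Inf` with attribute `perfect_fit`.
#'
#' @param fit a `piecewise_fit`.
#' @return the BIC value.
#' @export
bic_piecewise <- function(fit) {
  stopifnot(inherits(fit, "piecewise_fit"))
  n <- fit$n
  k <- 2 + 2 * fit$n_breakpoints
  if (fit$rss <= 0) {
    out <- -Inf
    attr(out, "perfect_fit") <- TRUE
    return(out)
  }
  n * log(fit$rss / n) + k * log(n)
}

#' Select the breakpoint count by BIC
#'
#' Returns the minimum-BIC fit among the supplied candidates; exact ties go
#' to the model with fewer breakpoints. `NULL` entries (failed fits) are
#' skipped.
#'
#' @param fits list of `piecewise_fit` objects (typically B = 0, 1, 2).
#' @return the selected `piecewise_fit`.
#' @export
select_model <- function(fits) {
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits)) stop("all candidate fits failed")
  bics <- vapply(fits, function(f) as.numeric(f$bic), numeric(1))
  nb <- vapply(fits, `[[`, integer(1), "n_breakpoints")
  ord <- order(bics, nb)
  fits[[ord[1]]]
}

#' Retain one-breakpoint fits away from the range edges
#'
#' Keeps fits with exactly one breakpoint whose relative position
#' `(bp - min) / (max - min)` lies in `[lo, hi]` (inclusive), avoiding
#' edge-of-range artefacts.
#'
#' @param fits named list of selected `piecewise_fit` objects.
#' @param x_range numeric length-2, observed range of the tau axis.
#' @param lo,hi relative bounds; defaults 0.20 and 0.80.
#' @return the retained sub-list, with each fit gaining a
#'   `relative_position` element.
#' @export
filter_breakpoint_range <- function(fits, x_range, lo = 0.20, hi = 0.80) {
  stopifnot(length(x_range) == 2, x_range[1] < x_range[2])
  keep <- vapply(fits, function(f) {
    if (f$n_breakpoints != 1L) return(FALSE)
    rel <- (f$breakpoints - x_range[1]) / diff(x_range)
    rel >= lo && rel <= hi
  }, logical(1))
  out <- fits[keep]
  lapply(out, function(f) {
    f$relative_position <- (f$breakpoints - x_range[1]) / diff(x_range)
    f
  })
}

#' Stratify one-breakpoint proteins into four temporal modules
#'
#' The early/late cut is the minimum of a Gaussian kernel density estimate
#' (Silverman's rule-of-thumb bandwidth) of the breakpoint positions,
#' between the two largest modes; when the KDE is unimodal the median is
#' used and flagged. Modules combine timing with slope direction:
#' `early_up_plateau` (early, alpha1 > 0), `early_down_plateau` (early,
#' alpha1 < 0), `late_decline` (late, alpha2 < 0), `late_recover` (late,
#' alpha2 > 0). A zero slope is classified by the sign of the other
#' segment's slope; proteins with both slopes zero are left unassigned
#' with a warning.
#'
#' @param fits named list of retained one-breakpoint `piecewise_fit`
#'   objects (>= 10).
#' @return list with `assignments` (data.frame: `protein_id`, `breakpoint`,
#'   `timing`, `module`), `cut` (early/late boundary) and `unimodal`
#'   (logical fallback flag).
#' @export
stratify_modules <- function(fits) {
  if (length(fits) < 10)
    stop("need at least 10 retained fits, got ", length(fits))
  bp <- vapply(fits, function(f) f$breakpoints[1], numeric(1))
  cutres <- kde_valley(bp)
  timing <- ifelse(bp <= cutres$cut, "early", "late")
  a1 <- vapply(fits, function(f) f$slopes[1], numeric(1))
  a2 <- vapply(fits, function(f) f$slopes[2], numeric(1))
  module <- character(length(bp))
  for (i in seq_along(bp)) {
    s <- if (timing[i] == "early") a1[i] else a2[i]
    if (s == 0) s <- if (timing[i] == "early") a2[i] else a1[i]
    module[i] <- if (s == 0) NA_character_
    else if (timing[i] == "early" && s > 0) "early_up_plateau"
    else if (timing[i] == "early") "early_down_plateau"
    else if (s < 0) "late_decline"
    else "late_recover"
  }
  if (anyNA(module))
    warning(sum(is.na(module)), " protein(s) with flat segments unassigned")
  ids <- names(fits)
  if (is.null(ids)) ids <- sprintf("protein_%d", seq_along(fits))
  list(assignments = data.frame(protein_id = ids, breakpoint = unname(bp),
                                timing = unname(timing),
                                module = unname(module),
                                stringsAsFactors = FALSE),
       cut = cutres$cut, unimodal = cutres$unimodal)
}

# internal: valley of a Gaussian KDE between its two largest modes
kde_valley <- function(v) {
  dens <- stats::density(v, bw = "nrd0")
  y <- dens$y; x <- dens$x
  peaks <- which(diff(sign(diff(y))) == -2) + 1L
  if (length(peaks) < 2)
    return(list(cut = stats::median(v), unimodal = TRUE))
  top2 <- sort(peaks[order(-y[peaks])][1:2])
  valley_idx <- top2[1] + which.min(y[top2[1]:top2[2]]) - 1L
  list(cut = x[valley_idx], unimodal = FALSE)
}

#' Run the breakpoint analysis over a matrix
#'
#' Per protein, in order: MAD-based outlier removal, z-scoring of the
#' cleaned intensities, piecewise fits with 0, 1 and 2 breakpoints,
#' BIC model selection, retention of one-breakpoint fits inside the
#' central part of the tau range, and early/late module stratification.
#'
#' @param matrix a complete [proteome_matrix()].
#' @param trajectory a tau-proxy `trajectory_result`.
#' @param n_boot bootstrap-restarting iterations per fit.
#' @param seed integer seed; per-protein seeds are derived from it.
#' @param mad_threshold outlier threshold in MADs.
#' @param range_lo,range_hi relative breakpoint retention window.
#' @param exclude optional protein IDs to skip (e.g. the tau row itself).
#' @return list with `table` (per-protein report: selected model,
#'   parameters, retention, timing, module), `modules` (stratification
#'   result or `NULL` when fewer than 10 fits are retained), `cut`,
#'   `summary` (counts) and `x_range`.
#' @export
run_breakpoint_analysis <- function(matrix, trajectory, n_boot = 1000,
                                    seed = 1L, mad_threshold = 3,
                                    range_lo = 0.20, range_hi = 0.80,
                                    exclude = NULL) {
  assert_complete(matrix, "run_breakpoint_analysis")
  axis <- align_axis(matrix, trajectory)
  ids <- setdiff(rownames(matrix$values), exclude)
  x_range <- range(axis)
  selected <- vector("list", length(ids))
  names(selected) <- ids
  rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    y_raw <- matrix$values[ids[i], ]
    w <- winsorize_mad(y_raw, threshold = mad_threshold)
    x <- axis[w$keep]
    y <- as.vector(scale(y_raw[w$keep]))
    fits <- lapply(0:2, function(b) {
      tryCatch(fit_piecewise(x, y, b, n_boot = n_boot,
                             seed = seed + i * 7L + b),
               error = function(e) NULL)
    })
    sel <- tryCatch(select_model(fits), error = function(e) NULL)
    selected[[i]] <- sel
    rows[[i]] <- if (is.null(sel)) {
      data.frame(protein_id = ids[i], n_breakpoints = NA_integer_,
                 bp1 = NA_real_, bp2 = NA_real_, intercept = NA_real_,
                 alpha1 = NA_real_, alpha2 = NA_real_, alpha3 = NA_real_,
                 rss = NA_real_, bic = NA_real_, converged = FALSE,
                 n_outliers_removed = w$n_removed,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(protein_id = ids[i], n_breakpoints = sel$n_breakpoints,
                 bp1 = sel$breakpoints[1] %|na|% NA_real_,
                 bp2 = sel$breakpoints[2] %|na|% NA_real_,
                 intercept = sel$intercept,
                 alpha1 = sel$slopes[1] %|na|% NA_real_,
                 alpha2 = sel$slopes[2] %|na|% NA_real_,
                 alpha3 = sel$slopes[3] %|na|% NA_real_,
                 rss = sel$rss, bic = as.numeric(sel$bic),
                 converged = sel$converged,
                 n_outliers_removed = w$n_removed,
                 stringsAsFactors = FALSE)
    }
  }
  table <- do.call(rbind, rows)
  ok <- !vapply(selected, is.null, logical(1))
  retained <- filter_breakpoint_range(selected[ok], x_range,
                                      lo = range_lo, hi = range_hi)
  table$retained <- table$protein_id %in% names(retained)
  table$timing <- NA_character_
  table$module <- NA_character_
  modules <- NULL
  cut <- NA_real_
  if (length(retained) >= 10) {
    modules <- stratify_modules(retained)
    cut <- modules$cut
    idx <- match(modules$assignments$protein_id, table$protein_id)
    table$timing[idx] <- modules$assignments$timing
    table$module[idx] <- modules$assignments$module
  }
  nb <- table$n_breakpoints
  summary <- list(n_proteins = length(ids),
                  n_linear = sum(nb == 0, na.rm = TRUE),
                  n_nonlinear = sum(nb >= 1, na.rm = TRUE),
                  n_one_breakpoint = sum(nb == 1, na.rm = TRUE),
                  n_two_breakpoints = sum(nb == 2, na.rm = TRUE),
                  n_retained = length(retained),
                  module_counts = if (is.null(modules)) NULL
                    else table(modules$assignments$module, useNA = "no"))
  list(table = table, modules = modules, cut = cut, summary = summary,
       x_range = x_range)
}

# internal: first element or NA when absent
`%|na|%` <- function(a, b) if (length(a) == 0 || is.na(a[1])) b else a
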