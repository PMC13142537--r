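#' Filter PTM peptide reports
#'
#' Applies the DIA-NN report quality thresholds to a long-format PTM table,
#' with the printed strictness of each rule: `Lib.Q.Value < 0.5`,
#' `Global.Q.Value < 0.5`, `Lib.Peptidoform.Q.Value < 0.5`,
#' `Global.Peptidoform.Q.Value < 0.5`, `Q.Value < 0.01`, `PEP <= 0.05`,
#' `Peptidoform.Q.Value < 0.01`, `PTM.Site.Confidence > 0.9`. In
#' `"phospho"` mode a site-localization probability of at least 0.99 is
#' additionally required. Column names are matched case-insensitively with
#' dots and underscores interchangeable.
#'
#' @param records data.frame of PTM records.
#' @param mode `"phospho"` or `"kgg"` (Gly-Gly / K48-ubiquitin remnants).
#' @return the retained records; the retention count is reported via
#'   `message()`.
#' @export
apply_ptm_filters <- function(records, mode = c("phospho", "kgg")) {
  mode <- match.arg(mode)
  norm <- function(x) gsub("[._]", "_", tolower(x))
  cn <- norm(names(records))
  col <- function(name) {
    i <- match(norm(name), cn)
    if (is.na(i)) stop("required column '", name, "' is missing")
    records[[i]]
  }
  rules <- list(
    list("Lib.Q.Value", `<`, 0.5),
    list("Global.Q.Value", `<`, 0.5),
    list("Lib.Peptidoform.Q.Value", `<`, 0.5),
    list("Global.Peptidoform.Q.Value", `<`, 0.5),
    list("Q.Value", `<`, 0.01),
    list("PEP", `<=`, 0.05),
    list("Peptidoform.Q.Value", `<`, 0.01),
    list("PTM.Site.Confidence", `>`, 0.9))
  if (mode == "phospho")
    rules <- c(rules, list(list("Site.Localization.Probability", `>=`, 0.99)))
  keep <- rep(TRUE, nrow(records))
  for (rule in rules) keep <- keep & rule[[2]](col(rule[[1]]), rule[[3]])
  keep[is.na(keep)] <- FALSE
  message(sum(keep), " of ", nrow(records), " PTM record(s) retained")
  records[keep, , drop = FALSE]
}

#' Optional removal of the maximum-intensity outlier
#'
#' Reproducible handling of a single extreme value in a Gly-Gly intensity
#' vector: when `drop_max = TRUE`, the single maximum is set to `NA`. A tie
#' at the maximum is refused so the choice of which replicate to drop is
#' never silent.
#'
#' @param intensities numeric vector (length >= 2).
#' @param drop_max apply the policy? Default `FALSE` (identity).
#' @return the vector, with the maximum set to `NA` when requested.
#' @export
kgg_outlier_policy <- function(intensities, drop_max = FALSE) {
  if (length(intensities) < 2) stop("need at least 2 intensities")
  if (!drop_max) return(intensities)
  m <- max(intensities, na.rm = TRUE)
  at <- which(intensities == m)
  if (length(at) > 1)
    stop("tie at the maximum (", length(at),
         " values); resolve explicitly before applying the policy")
  intensities[at] <- NA_real_
  intensities
}

#' Convert a log2 effect to a fold change
#'
#' @param beta effect in log2 units.
#' @return `2^beta`.
#' @export
fold_change_from_log2 <- function(beta) {
  if (!all(is.finite(beta))) stop("beta must be finite")
  2^beta
}

# internal: REML fit of y = X b + Z u + e with a single random intercept per
# group; the variance ratio theta = sigma_u^2 / sigma_e^2 is profiled out and
# maximised in 1-D. Block structure of V = I + theta Z Z' gives closed-form
# V^{-1} products per group.
reml_fit <- function(y, X, group) {
  group <- as.character(group)
  n <- length(y); p <- ncol(X)
  g_levels <- sort(unique(group))
  g_idx <- split(seq_len(n), group)[g_levels]
  n_g <- lengths(g_idx)

  vinv_mult <- function(a, theta) {
    out <- a
    for (k in seq_along(g_idx)) {
      i <- g_idx[[k]]
      if (is.matrix(a)) {
        out[i, ] <- a[i, , drop = FALSE] -
          (theta / (1 + n_g[k] * theta)) *
          matrix(colSums(a[i, , drop = FALSE]), length(i), ncol(a),
                 byrow = TRUE)
      } else {
        out[i] <- a[i] - (theta / (1 + n_g[k] * theta)) * sum(a[i])
      }
    }
    out
  }

  profile <- function(theta) {
    vx <- vinv_mult(X, theta)
    xtvx <- crossprod(X, vx)
    beta <- solve(xtvx, crossprod(vx, y))
    r <- y - X %*% beta
    quad <- sum(r * vinv_mult(r, theta))
    logdet_v <- sum(log1p(n_g * theta))
    ll <- -0.5 * ((n - p) * log(quad) + logdet_v +
                    determinant(xtvx, logarithm = TRUE)$modulus[1])
    list(ll = as.numeric(ll), beta = as.vector(beta), r = as.vector(r),
         quad = quad, xtvx = xtvx)
  }

  # 1-D profile maximisation over log(theta), plus the boundary theta = 0
  obj <- function(lt) -profile(exp(lt))$ll
  opt <- stats::optimize(obj, interval = c(log(1e-8), log(1e8)),
                         tol = 1e-10)
  theta <- exp(opt$minimum)
  cand <- profile(theta)
  at0 <- profile(0)
  if (at0$ll >= cand$ll) { theta <- 0; cand <- at0 }

  sigma2_e <- cand$quad / (n - p)
  sigma2_u <- theta * sigma2_e
  blup <- vapply(seq_along(g_idx), function(k) {
    theta * sum(cand$r[g_idx[[k]]]) / (1 + n_g[k] * theta)
  }, numeric(1))
  names(blup) <- g_levels
  vcov_beta <- solve(cand$xtvx) * sigma2_e
  list(beta = cand$beta, vcov = vcov_beta, sigma2_u = sigma2_u,
       sigma2_e = sigma2_e, theta = theta, blup = blup,
       reml_loglik = cand$ll, n = n, groups = g_levels)
}

#' Random-intercept mixed model of phospho intensity on tau
#'
#' Fits `y = intercept + beta * x + u_donor + e` by restricted maximum
#' likelihood, with the donor intercept variance profiled out and maximised
#' in one dimension over the variance ratio. Intended for the baseline
#' occupancy relation in pTau-negative cells: the fixed slope `beta`
#' captures how phospho-site intensity scales with tau abundance, and the
#' donor random intercepts absorb between-donor offsets.
#'
#' @param y phospho log2 intensities.
#' @param x tau log2 intensities.
#' @param donor donor ID per observation.
#' @param subset optional logical vector selecting the observations to fit
#'   (e.g. pTau-negative samples).
#' @return object of class `lmm_fit`: `intercept`, `beta`, `beta_se`,
#'   `sigma2_donor`, `sigma2_resid`, `donor_intercepts` (empirical best
#'   predictions), `n`, `reml_loglik`.
#' @export
fit_random_intercept_lmm <- function(y, x, donor, subset = NULL) {
  if (!is.null(subset)) {
    y <- y[subset]; x <- x[subset]; donor <- donor[subset]
  }
  n <- length(y)
  stopifnot(length(x) == n, length(donor) == n)
  if (n < 4) stop("need at least 4 observations")
  if (length(unique(donor)) < 2) stop("need at least 2 donors")
  if (stats::sd(x) == 0) stop("singular design: x is constant")
  fit <- reml_fit(y, cbind(`(Intercept)` = 1, x = x), donor)
  structure(list(intercept = fit$beta[1], beta = fit$beta[2],
                 beta_se = sqrt(fit$vcov[2, 2]),
                 sigma2_donor = fit$sigma2_u, sigma2_resid = fit$sigma2_e,
                 donor_intercepts = fit$blup, n = fit$n,
                 reml_loglik = fit$reml_loglik),
            class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("random-intercept LMM (REML)\n")
  cat(sprintf("  slope beta = %.4f (SE %.4f), intercept = %.4f\n",
              x$beta, x$beta_se, x$intercept))
  cat(sprintf("  donor variance = %.4f, residual variance = %.4f, n = %d\n",
              x$sigma2_donor, x$sigma2_resid, x$n))
  invisible(x)
}

#' Phosphorylation excess beyond tau abundance
#'
#' Given a baseline fit on pTau-negative cells, computes residuals for all
#' cells: `y - (intercept + beta * x + donor intercept)`, using the fixed
#' part only for donors unseen in the baseline fit. Positive residuals in
#' pTau-positive cells indicate site occupancy beyond what tau abundance
#' predicts. The excess `beta_excess` is estimated by refitting the mixed
#' model on all cells with a pTau-status fixed effect, which matches the
#' residual framing but yields a standard error and Wald p-value; the
#' implied fold change is `2^beta_excess`.
#'
#' @param fit an `lmm_fit` from pTau-negative cells.
#' @param y,x,donor,ptau_status data for all cells; `ptau_status` in
#'   `{"positive", "negative"}`.
#' @return list with `residuals`, `group_means` (mean residual, SEM and n
#'   per status group), `beta_excess`, `beta_excess_se`, `p_value`,
#'   `fold_change` and the refitted `lmm_fit` (`refit`).
#' @export
phospho_excess <- function(fit, y, x, donor, ptau_status) {
  stopifnot(inherits(fit, "lmm_fit"))
  donor <- as.character(donor)
  u <- fit$donor_intercepts[donor]
  u[is.na(u)] <- 0  # donors unseen in the baseline fit: fixed part only
  res <- y - (fit$intercept + fit$beta * x + u)
  pos <- ptau_status == "positive"
  grp <- function(r) data.frame(
    mean = mean(r), sem = stats::sd(r) / sqrt(length(r)), n = length(r))
  group_means <- rbind(cbind(group = "negative", grp(res[!pos])),
                       cbind(group = "positive", grp(res[pos])))

  X <- cbind(`(Intercept)` = 1, x = x, ptau_positive = as.numeric(pos))
  refit <- reml_fit(y, X, donor)
  beta_excess <- refit$beta[3]
  se <- sqrt(refit$vcov[3, 3])
  p <- 2 * stats::pnorm(-abs(beta_excess / se))
  list(residuals = res, group_means = group_means,
       beta_excess = beta_excess, beta_excess_se = se, p_value = p,
       fold_change = fold_change_from_log2(beta_excess),
       refit = structure(list(intercept = refit$beta[1],
                              beta = refit$beta[2],
                              beta_excess = beta_excess,
                              sigma2_donor = refit$sigma2_u,
                              sigma2_resid = refit$sigma2_e,
                              donor_intercepts = refit$blup, n = refit$n,
                              reml_loglik = refit$reml_loglik),
                         class = "lmm_fit"))
}

#' Detection fraction per modified site and group
#'
#' @param records long data.frame with columns `site`, `sample_id` and
#'   `intensity` (`NA` = not detected in that sample).
#' @param groups named character vector mapping every sample ID to a group
#'   label; group sizes are the denominators.
#' @return data.frame with columns `site`, `group`, `n_detected`,
#'   `n_samples`, `fraction`.
#' @export
detection_fraction_by_group <- function(records, groups) {
  need <- c("site", "sample_id", "intensity")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records lack column(s): ",
                         paste(miss, collapse = ", "))
  unknown <- setdiff(records$sample_id, names(groups))
  if (length(unknown)) stop("sample(s) without a group label: ",
                            paste(utils::head(unknown, 5), collapse = ", "))
  g_sizes <- table(groups)
  out <- expand.grid(site = unique(records$site),
                     group = names(g_sizes), stringsAsFactors = FALSE)
  out$n_detected <- mapply(function(s, g) {
    r <- records[records$site == s & groups[records$sample_id] == g, ]
    sum(!is.na(r$intensity))
  }, out$site, out$group)
  out$n_samples <- as.integer(g_sizes[out$group])
  out$fraction <- out$n_detected / out$n_samples
  out[order(out$site, out$group), , drop = FALSE]
}
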