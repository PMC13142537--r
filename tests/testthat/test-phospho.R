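test_that("PTM filters apply each threshold with the printed strictness", {
  # six records violating one rule each plus one clean record
  tbl <- rbind(clean_ptm_record(),
               clean_ptm_record(lib_q_value = 0.6),
               clean_ptm_record(global_q_value = 0.5),
               clean_ptm_record(q_value = 0.02),
               clean_ptm_record(pep = 0.06),
               clean_ptm_record(peptidoform_q_value = 0.01),
               clean_ptm_record(ptm_site_confidence = 0.9))
  out <- suppressMessages(apply_ptm_filters(tbl, mode = "kgg"))
  expect_equal(nrow(out), 1L)
  # boundary semantics exactly as printed
  expect_equal(nrow(suppressMessages(
    apply_ptm_filters(clean_ptm_record(pep = 0.05), "kgg"))), 1L)
  expect_equal(nrow(suppressMessages(
    apply_ptm_filters(clean_ptm_record(q_value = 0.01), "kgg"))), 0L)
  # phospho mode additionally requires localization >= 0.99
  expect_equal(nrow(suppressMessages(apply_ptm_filters(
    clean_ptm_record(site_localization_probability = 0.98), "phospho"))), 0L)
  expect_equal(nrow(suppressMessages(apply_ptm_filters(
    clean_ptm_record(site_localization_probability = 0.99), "phospho"))), 1L)
  # dotted, capitalised column names are accepted
  dotted <- clean_ptm_record()
  names(dotted) <- c("Peptide", "Site", "Site.Localization.Probability",
                     "Lib.Q.Value", "Global.Q.Value",
                     "Lib.Peptidoform.Q.Value", "Global.Peptidoform.Q.Value",
                     "Q.Value", "PEP", "Peptidoform.Q.Value",
                     "PTM.Site.Confidence")
  expect_equal(nrow(suppressMessages(apply_ptm_filters(dotted, "phospho"))), 1L)
  expect_error(apply_ptm_filters(clean_ptm_record()[, -4], "kgg"),
               "Lib.Q.Value")
})

test_that("filtering is monotone in every threshold", {
  set.seed(33)
  n <- 300
  tbl <- data.frame(peptide = "X", site = "K48",
                    site_localization_probability = runif(n),
                    lib_q_value = runif(n), global_q_value = runif(n),
                    lib_peptidoform_q_value = runif(n),
                    global_peptidoform_q_value = runif(n),
                    q_value = runif(n, 0, 0.02), pep = runif(n, 0, 0.1),
                    peptidoform_q_value = runif(n, 0, 0.02),
                    ptm_site_confidence = runif(n))
  base <- suppressMessages(apply_ptm_filters(tbl, "kgg"))
  # relaxing PEP by doctoring the data never shrinks the retained set
  relaxed <- tbl
  relaxed$pep <- pmin(tbl$pep, 0.05)
  out <- suppressMessages(apply_ptm_filters(relaxed, "kgg"))
  expect_gte(nrow(out), nrow(base))
})

test_that("kgg outlier policy drops a unique maximum and refuses ties", {
  expect_equal(kgg_outlier_policy(c(1, 5, 9), drop_max = TRUE),
               c(1, 5, NA))
  expect_equal(kgg_outlier_policy(c(1, 5, 9)), c(1, 5, 9))
  expect_error(kgg_outlier_policy(c(1, 9, 9), drop_max = TRUE), "tie")
  expect_error(kgg_outlier_policy(5, drop_max = TRUE), "at least 2")
})

test_that("fold-change conversion is exact powers of two", {
  expect_equal(fold_change_from_log2(0), 1)
  expect_equal(fold_change_from_log2(1), 2)
  expect_equal(round(fold_change_from_log2(1.16), 1), 2.2)
  expect_error(fold_change_from_log2(Inf), "finite")
})

test_that("REML fit matches a brute-force grid search on a small toy", {
  set.seed(6)
  donor <- rep(c("A", "B", "C"), each = 4)
  x <- c(1, 2, 3, 4, 2, 3, 4, 5, 1, 3, 5, 7)
  y <- 0.5 + 0.9 * x + rep(c(-0.4, 0.1, 0.5), each = 4) + rnorm(12, 0, 0.2)
  fit <- fit_random_intercept_lmm(y, x, donor)
  # profiled REML criterion evaluated on a dense grid of variance ratios
  grid_reml <- function(theta) {
    ng <- table(donor)
    vinv <- diag(12)
    for (g in names(ng)) {
      i <- which(donor == g)
      vinv[i, i] <- diag(length(i)) -
        (theta / (1 + length(i) * theta)) * matrix(1, length(i), length(i))
    }
    X <- cbind(1, x)
    b <- solve(t(X) %*% vinv %*% X, t(X) %*% vinv %*% y)
    r <- y - X %*% b
    quad <- drop(t(r) %*% vinv %*% r)
    ll <- -0.5 * ((12 - 2) * log(quad) + sum(log(1 + as.vector(ng) * theta)) +
                    determinant(t(X) %*% vinv %*% X)$modulus[1])
    list(ll = ll, beta = b[2])
  }
  thetas <- exp(seq(log(1e-6), log(1e4), length.out = 20000))
  lls <- vapply(thetas, function(t) grid_reml(t)$ll, numeric(1))
  best <- grid_reml(thetas[which.max(lls)])
  expect_equal(fit$beta, best$beta, tolerance = 1e-4)
})

test_that("REML fit agrees with lme4 on simulated data", {
  set.seed(42)
  n <- 80
  donor <- rep(sprintf("D%d", 1:8), each = 10)
  u <- rnorm(8, 0, 0.6)
  x <- runif(n, 12, 19)
  y <- 1 + 0.8 * x + u[as.integer(factor(donor))] + rnorm(n, 0, 0.3)
  ours <- fit_random_intercept_lmm(y, x, donor)
  m <- lme4::lmer(y ~ x + (1 | donor), REML = TRUE)
  expect_equal(ours$beta, unname(lme4::fixef(m)[2]), tolerance = 1e-6)
  expect_equal(ours$sigma2_donor,
               as.data.frame(lme4::VarCorr(m))$vcov[1], tolerance = 1e-5)
  expect_equal(ours$beta_se, sqrt(as.matrix(stats::vcov(m))[2, 2]),
               tolerance = 1e-5)
})

test_that("with no donor variance the LMM slope equals OLS", {
  set.seed(9)
  n <- 60
  donor <- rep(sprintf("D%d", 1:6), each = 10)
  x <- runif(n, 10, 20)
  y <- 2 + 0.7 * x + rnorm(n, 0, 0.5)
  fit <- fit_random_intercept_lmm(y, x, donor)
  ols <- stats::coef(stats::lm(y ~ x))
  expect_lt(abs(fit$beta - ols[[2]]), 1e-6)
  expect_error(fit_random_intercept_lmm(y, rep(1, n), donor), "constant")
  expect_error(fit_random_intercept_lmm(y[1:10], x[1:10], donor[1:10]),
               "2 donors")
})

test_that("LMM slope is invariant to shifting x", {
  set.seed(10)
  donor <- rep(c("A", "B", "C", "D"), each = 8)
  x <- runif(32, 12, 19)
  y <- 1 + 0.8 * x + rep(rnorm(4, 0, 0.5), each = 8) + rnorm(32, 0, 0.3)
  f1 <- fit_random_intercept_lmm(y, x, donor)
  f2 <- fit_random_intercept_lmm(y, x + 100, donor)
  expect_equal(f1$beta, f2$beta, tolerance = 1e-8)
})

test_that("phospho excess recovers the injected occupancy shift", {
  cfg <- cohort_config(n_cells = 200, n_donors = 8, donor_sd = 0.5, seed = 5)
  co <- generate_cohort(cfg)
  ph <- generate_phospho_layer(co$matrix, co$truth, beta_true = 1.16,
                               occupancy_noise_sd = 0.3, seed = 5)
  neg <- ph$ptau_status == "negative"
  base <- fit_random_intercept_lmm(ph$intensity, ph$tau, ph$donor_id,
                                   subset = neg)
  ex <- phospho_excess(base, ph$intensity, ph$tau, ph$donor_id,
                       ph$ptau_status)
  expect_lt(abs(ex$beta_excess - 1.16), 4 * ex$beta_excess_se)
  # negative-cell residuals centre on zero by construction of the fit
  expect_lt(abs(mean(ex$residuals[neg])), 1e-8)
  expect_lt(ex$p_value, 0.001)
  # null injection: positive-group mean residual within 3 SEM of zero
  ph0 <- generate_phospho_layer(co$matrix, co$truth, beta_true = 0,
                                occupancy_noise_sd = 0.3, seed = 6)
  base0 <- fit_random_intercept_lmm(ph0$intensity, ph0$tau, ph0$donor_id,
                                    subset = ph0$ptau_status == "negative")
  ex0 <- phospho_excess(base0, ph0$intensity, ph0$tau, ph0$donor_id,
                        ph0$ptau_status)
  gp <- ex0$group_means[ex0$group_means$group == "positive", ]
  expect_lt(abs(gp$mean), 3 * gp$sem)
})

test_that("detection fractions equal brute-force counts", {
  rec <- data.frame(
    site = rep(c("T217", "T231"), each = 6),
    sample_id = rep(sprintf("S%d", 1:6), 2),
    intensity = c(10, 11, 12, 13, NA, NA,   # T217: 4/4 pos, 0/2 neg
                  NA, NA, NA, NA, NA, NA))  # T231: absent everywhere
  groups <- c(S1 = "positive", S2 = "positive", S3 = "positive",
              S4 = "positive", S5 = "negative", S6 = "negative")
  out <- detection_fraction_by_group(rec, groups)
  get <- function(s, g) out$fraction[out$site == s & out$group == g]
  expect_equal(get("T217", "positive"), 1)
  expect_equal(get("T217", "negative"), 0)
  expect_equal(get("T231", "positive"), 0)
  expect_equal(get("T231", "negative"), 0)
  # 8 of 10 positive samples: fraction 0.8
  rec2 <- data.frame(site = "T217", sample_id = sprintf("P%02d", 1:10),
                     intensity = c(rep(1, 8), NA, NA))
  g2 <- stats::setNames(rep("positive", 10), sprintf("P%02d", 1:10))
  expect_equal(detection_fraction_by_group(rec2, g2)$fraction, 0.8)
})
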