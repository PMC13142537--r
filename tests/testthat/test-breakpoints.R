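test_that("MAD winsorisation removes only points beyond the threshold", {
  w <- winsorize_mad(c(10, 10.1, 9.9, 10.05, 100))
  expect_equal(w$keep, c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_equal(w$n_removed, 1L)
  y <- c(9.8, 10, 10.1, 10.2, 9.9, 10.05)
  expect_true(all(winsorize_mad(y)$keep))
  # brute-force rule evaluation on a toy 10-vector
  set.seed(4)
  y2 <- c(rnorm(8), 6, -7)
  w2 <- winsorize_mad(y2, threshold = 3)
  manual <- abs(y2 - stats::median(y2)) <= 3 * stats::mad(y2)
  expect_equal(w2$keep, manual)
  expect_warning(winsorize_mad(rep(1, 6)), "MAD is zero")
  expect_error(winsorize_mad(1:4), "at least 5")
  # clipping mode keeps every point but bounds it
  yc <- c(10, 10.1, 9.9, 10.05, 100)
  wc <- winsorize_mad(yc, clip = TRUE)
  expect_true(all(wc$keep))
  expect_lte(max(wc$y), stats::median(yc) + 3 * stats::mad(yc))
})

test_that("a noiseless hinge is recovered exactly", {
  x <- seq(0, 10)
  y <- pmax(0, x - 5)
  f <- fit_piecewise(x, y, 1, n_boot = 10, seed = 1)
  expect_equal(f$breakpoints, 5, tolerance = 1e-6)
  expect_equal(f$slopes[1], 0, tolerance = 1e-6)
  expect_equal(f$slopes[2], 1, tolerance = 1e-6)
  expect_lt(f$rss, 1e-12)
  expect_true(f$converged)
})

test_that("the zero-breakpoint fit equals closed-form OLS", {
  set.seed(2)
  x <- runif(30); y <- 1 + 2 * x + rnorm(30, 0, 0.1)
  f <- fit_piecewise(x, y, 0)
  ols <- stats::coef(stats::lm(y ~ x))
  expect_equal(f$intercept, ols[[1]], tolerance = 1e-10)
  expect_equal(f$slopes, ols[[2]], tolerance = 1e-10)
  expect_equal(f$rss, sum(stats::residuals(stats::lm(y ~ x))^2),
               tolerance = 1e-10)
})

test_that("one-breakpoint fits are never beaten by an exhaustive grid", {
  set.seed(7)
  for (i in 1:50) {
    x <- sort(runif(30, 0, 10))
    y <- rnorm(30)
    f <- fit_piecewise(x, y, 1, n_boot = 20, seed = i)
    xs <- sort(unique(x))
    mids <- (xs[-1] + xs[-length(xs)]) / 2
    grid_rss <- min(vapply(mids, function(ps) {
      sum(.lm.fit(cbind(1, x, pmax(x - ps, 0)), y)$residuals^2)
    }, numeric(1)))
    expect_lte(f$rss, grid_rss * (1 + 1e-8))
  }
})

test_that("RSS is nested across breakpoint counts", {
  set.seed(12)
  for (i in 1:10) {
    x <- sort(runif(40, 0, 10))
    y <- rnorm(40) + 0.3 * x
    f0 <- fit_piecewise(x, y, 0)
    f1 <- fit_piecewise(x, y, 1, n_boot = 10, seed = i)
    f2 <- fit_piecewise(x, y, 2, n_boot = 10, seed = i)
    expect_lte(f1$rss, f0$rss + 1e-10)
    expect_lte(f2$rss, f1$rss + 1e-10)
  }
})

test_that("BIC follows n log(RSS/n) + k log(n) with k = 2 + 2B", {
  f <- structure(list(n_breakpoints = 0L, rss = 100, n = 100),
                 class = "piecewise_fit")
  expect_equal(bic_piecewise(f), 100 * log(1) + 2 * log(100))
  f1 <- structure(list(n_breakpoints = 1L, rss = 100, n = 100),
                  class = "piecewise_fit")
  expect_equal(bic_piecewise(f1) - bic_piecewise(f), 2 * log(100))
  f2 <- structure(list(n_breakpoints = 2L, rss = 10, n = 10),
                  class = "piecewise_fit")
  expect_equal(bic_piecewise(f2), 6 * log(10))
  fp <- structure(list(n_breakpoints = 1L, rss = 0, n = 10),
                  class = "piecewise_fit")
  expect_equal(as.numeric(bic_piecewise(fp)), -Inf)
  expect_true(attr(bic_piecewise(fp), "perfect_fit"))
})

test_that("model selection minimises BIC and breaks ties toward fewer breaks", {
  mk <- function(b, bic) structure(list(n_breakpoints = b, bic = bic),
                                   class = "piecewise_fit")
  expect_equal(select_model(list(mk(0L, 5), mk(1L, 3), mk(2L, 4)))$n_breakpoints,
               1L)
  expect_equal(select_model(list(mk(0L, 3), mk(1L, 3)))$n_breakpoints, 0L)
  expect_equal(select_model(list(NULL, mk(1L, 3), NULL))$n_breakpoints, 1L)
  expect_error(select_model(list(NULL, NULL)), "failed")
  # pure linear data: B = 0 wins in almost all replicates
  picks <- vapply(1:40, function(s) {
    set.seed(s)
    x <- runif(100, 0, 10)
    y <- as.vector(scale(1 + 0.5 * x + rnorm(100, 0, 0.3)))
    fits <- lapply(0:2, function(b) fit_piecewise(x, y, b, n_boot = 20,
                                                  seed = s))
    select_model(fits)$n_breakpoints
  }, integer(1))
  expect_gte(mean(picks == 0L), 0.95)
  # strong noiseless hinge: B = 1 wins
  x <- seq(0, 10, length.out = 50)
  y <- pmax(0, x - 4) + rnorm(50, 0, 0.01)
  fits <- lapply(0:2, function(b) fit_piecewise(x, y, b, n_boot = 20,
                                                seed = 3))
  expect_equal(select_model(fits)$n_breakpoints, 1L)
})

test_that("breakpoint range filter keeps the central window inclusively", {
  mk <- function(b, psi) structure(list(n_breakpoints = b,
                                        breakpoints = psi,
                                        slopes = c(1, 0)),
                                   class = "piecewise_fit")
  fits <- list(a = mk(1L, 12), b = mk(1L, 11), c = mk(1L, 18),
               d = mk(0L, numeric(0)), e = mk(1L, 15))
  out <- filter_breakpoint_range(fits, c(10, 20))
  expect_setequal(names(out), c("a", "c", "e"))  # 0.2 and 0.8 inclusive
  expect_equal(out$a$relative_position, 0.2)
  # brute-force check of the rule on the same toy set
  manual <- vapply(fits, function(f) f$n_breakpoints == 1 &&
                     (f$breakpoints - 10) / 10 >= 0.2 &&
                     (f$breakpoints - 10) / 10 <= 0.8, logical(1))
  expect_setequal(names(out), names(fits)[manual])
})

test_that("module stratification splits well-separated clusters correctly", {
  mk <- function(psi, a1, a2) structure(
    list(n_breakpoints = 1L, breakpoints = psi, slopes = c(a1, a2)),
    class = "piecewise_fit")
  set.seed(5)
  early <- lapply(rnorm(12, 14, 0.1), function(p) mk(p, 1, 0))
  late <- lapply(rnorm(12, 17, 0.1), function(p) mk(p, 0.2, -1))
  fits <- c(early, late)
  names(fits) <- sprintf("P%02d", seq_along(fits))
  st <- stratify_modules(fits)
  expect_false(st$unimodal)
  expect_gt(st$cut, 14.5); expect_lt(st$cut, 16.5)
  expect_equal(st$assignments$timing,
               rep(c("early", "late"), each = 12))
  expect_equal(st$assignments$module[1:12], rep("early_up_plateau", 12))
  expect_equal(st$assignments$module[13:24], rep("late_decline", 12))
  # definition cases
  one <- c(lapply(rnorm(10, 14, 0.1), function(p) mk(p, -1, 0)),
           lapply(rnorm(10, 17, 0.1), function(p) mk(p, 0, 1)))
  names(one) <- sprintf("Q%02d", 1:20)
  st2 <- stratify_modules(one)
  expect_equal(st2$assignments$module[1:10], rep("early_down_plateau", 10))
  expect_equal(st2$assignments$module[11:20], rep("late_recover", 10))
  expect_error(stratify_modules(fits[1:5]), "at least 10")
})

test_that("stratification is invariant to input order", {
  mk <- function(psi, a1, a2) structure(
    list(n_breakpoints = 1L, breakpoints = psi, slopes = c(a1, a2)),
    class = "piecewise_fit")
  set.seed(8)
  fits <- c(lapply(rnorm(10, 14, 0.2), function(p) mk(p, 1, 0)),
            lapply(rnorm(10, 17, 0.2), function(p) mk(p, 0, -1)))
  names(fits) <- sprintf("P%02d", 1:20)
  st1 <- stratify_modules(fits)
  perm <- sample(20)
  st2 <- stratify_modules(fits[perm])
  m <- match(st1$assignments$protein_id, st2$assignments$protein_id)
  expect_equal(st1$assignments$module, st2$assignments$module[m])
  expect_equal(st1$cut, st2$cut)
})

test_that("the full breakpoint analysis is deterministic and labels truth", {
  cfg <- recovery_config(seed = 61, n_cells = 120)
  co <- generate_cohort(cfg)
  tr <- tau_proxy_ordering(co$matrix)
  r1 <- suppressWarnings(run_breakpoint_analysis(co$matrix, tr, n_boot = 10,
                                                 seed = 2, exclude = "MAPT"))
  r2 <- suppressWarnings(run_breakpoint_analysis(co$matrix, tr, n_boot = 10,
                                                 seed = 2, exclude = "MAPT"))
  expect_identical(r1$table, r2$table)
  expect_false("MAPT" %in% r1$table$protein_id)
  truth <- co$truth$proteins
  tab <- merge(r1$table, truth, by = "protein_id")
  brk <- tab[tab$class %in% c("early_break", "late_break"), ]
  expect_gt(mean(brk$n_breakpoints == 1, na.rm = TRUE), 0.6)
  lin <- tab[tab$class %in% c("null", "linear_up", "linear_down"), ]
  expect_lt(mean(lin$n_breakpoints >= 1, na.rm = TRUE), 0.1)
})
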