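test_that("the burden formula is exact on constructed fixtures", {
  # no variants -> zero burden
  expect_identical(estimateBurden(emptyVariantTable(), 0.08)$beta_per_mb, 0)
  # two variants of VAF 0.02 with L = 0.08 Mb -> 1.0 per Mb per cell
  v <- rbind(variant_row(alt_count = 600L, depth = 30000L),
             variant_row(pos = 202L, alt_count = 600L, depth = 30000L))
  b <- estimateBurden(v, 0.08)
  expect_equal(b$beta_per_mb, 1.0, tolerance = 1e-12)
  expect_equal(b$beta_genome, 3000, tolerance = 1e-9)
  expect_error(estimateBurden(v, 0), "positive")
  # linearity: doubling every VAF doubles beta exactly
  v2 <- v; v2$alt_count <- v2$alt_count * 2L; v2$vaf <- v2$vaf * 2
  expect_equal(estimateBurden(v2, 0.08)$beta_per_mb, 2 * b$beta_per_mb,
               tolerance = 1e-12)
  # per-signature components conserve the total
  expos <- c(SBS5 = 0.75, SBS4 = 0.25)
  b2 <- estimateBurden(v, 0.08, exposureRow = expos)
  expect_equal(sum(b2$per_signature), b2$beta_per_mb, tolerance = 1e-9)
})

test_that("pack years and drink years follow their definitions", {
  expect_identical(packYears(2, 10), 20)
  expect_identical(packYears(1, 20), 20)
  expect_error(packYears(-1, 5), ">= 0")
  expect_identical(drinkYears(14, 1), 1)
  expect_identical(drinkYears(28, age = 68), (28 / 14) * 50)
  expect_error(drinkYears(-5, 1), ">= 0")
  expect_error(drinkYears(14), "years or age")
})

test_that("robust fits recover exact lines and resist gross outliers", {
  x <- c(0, 1, 2, 3, 4, 5, 6, 7)
  y <- 20 * x
  # a perfect line has zero robust scale; rlm warns about convergence there
  fit <- suppressWarnings(robustDoseResponse(y, x, paste0("P", seq_along(x)),
                                             ci_method = "asymptotic"))
  expect_equal(fit$slope, 20, tolerance = 1e-8)
  expect_lt(fit$ci95[2] - fit$ci95[1], 1e-6)
  # single gross outlier: the robust slope beats ordinary least squares
  set.seed(14)
  y2 <- 20 * x + rnorm(length(x), 0, 0.5)
  y2[8] <- 500
  rob <- robustDoseResponse(y2, x, paste0("P", seq_along(x)),
                            ci_method = "asymptotic")
  ols <- stats::coef(stats::lm(y2 ~ x))[2]
  expect_lt(abs(rob$slope - 20), abs(ols - 20))
  # grid-search M-estimation oracle at the fitted scale
  rfit <- MASS::rlm(y2 ~ x, psi = MASS::psi.huber, k = 1.345, maxit = 100)
  s <- rfit$s
  huber_rho <- function(r, k = 1.345) ifelse(abs(r) <= k, r^2 / 2,
                                             k * abs(r) - k^2 / 2)
  grid_a <- seq(-3, 3, by = 0.02)
  grid_b <- seq(15, 25, by = 0.02)
  obj <- outer(grid_a, grid_b, Vectorize(function(a, b) {
    sum(huber_rho((y2 - a - b * x) / s))
  }))
  best <- which(obj == min(obj), arr.ind = TRUE)[1, ]
  expect_lt(abs(rob$slope - grid_b[best[2]]), 0.05)
  # degenerate inputs
  expect_error(robustDoseResponse(y[1:3], x[1:3], paste0("P", 1:3)),
               ">= 4 patients")
  expect_error(robustDoseResponse(y, rep(1, 8), paste0("P", seq_along(x))),
               "exposure variance")
})

test_that("per-patient medians are taken before the regression", {
  # one patient contributes three samples; its median must be one point
  x <- c(1, 1, 1, 2, 3, 4)
  y <- c(10, 100, 1000, 40, 60, 80)
  pid <- c("A", "A", "A", "B", "C", "D")
  fit <- robustDoseResponse(y, x, pid, ci_method = "asymptotic")
  expect_identical(fit$n_patients, 4L)
  pa <- fit$points[fit$points$patient == "A", ]
  expect_identical(pa$burden, 100)
  expect_identical(pa$burden_min, 10)
  expect_identical(pa$burden_max, 1000)
})

test_that("Jonckheere-Terpstra matches exhaustive enumeration", {
  res <- jonckheereTerpstra(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_identical(res$method, "exact")
  expect_equal(res$statistic, 12)
  expect_equal(res$p_value, 1 / 90, tolerance = 1e-12)
  # all observations equal: statistic at its null mean, p >= 0.5
  res2 <- jonckheereTerpstra(list(c(1, 1), c(1, 1), c(1, 1)))
  sizes <- c(2, 2, 2); n <- 6
  expect_equal(res2$statistic, (n^2 - sum(sizes^2)) / 4)
  expect_gte(res2$p_value, 0.5)
  # perfectly decreasing trend: one-sided (increasing) p close to 1
  res3 <- jonckheereTerpstra(list(c(6, 5), c(4, 3), c(2, 1)))
  expect_gt(res3$p_value, 0.95)
  expect_error(jonckheereTerpstra(list(1:3)), "two ordered groups")
})

test_that("JT exact p agrees with enumeration across n <= 8 configurations", {
  set.seed(6)
  configs <- list(c(2, 2), c(3, 2), c(2, 2, 2), c(3, 3, 2), c(2, 3, 3))
  for (sizes in configs) {
    vals <- sample(1:20, sum(sizes))
    groups <- split(vals, rep(seq_along(sizes), sizes))
    res <- jonckheereTerpstra(groups, exact_max = 10)
    expect_identical(res$method, "exact")
    # independent oracle: directly enumerate index assignments
    perms <- utils::combn(sum(sizes), sizes[1], simplify = FALSE)
    # recursive enumeration (re-implemented here, not the package path)
    enum <- function(idx, sz) {
      if (length(sz) == 1) return(list(list(idx)))
      out <- list()
      for (ch in utils::combn(idx, sz[1], simplify = FALSE)) {
        for (rest in enum(setdiff(idx, ch), sz[-1])) {
          out[[length(out) + 1]] <- c(list(ch), rest)
        }
      }
      out
    }
    jt <- function(gs) {
      s <- 0
      for (i in seq_len(length(gs) - 1)) for (j in (i + 1):length(gs)) {
        for (x in gs[[i]]) s <- s + sum(gs[[j]] > x) + 0.5 * sum(gs[[j]] == x)
      }
      s
    }
    assignments <- enum(seq_len(sum(sizes)), sizes)
    stats_all <- vapply(assignments, function(a) {
      jt(lapply(a, function(ix) vals[ix]))
    }, numeric(1))
    expect_equal(res$p_value, mean(stats_all >= res$statistic - 1e-12),
                 tolerance = 1e-12, info = paste(sizes, collapse = "/"))
  }
})

test_that("JT large-sample approximation tracks the permutation option", {
  set.seed(8)
  groups <- list(rnorm(8, 0), rnorm(8, 0.8), rnorm(8, 1.6))
  approx <- jonckheereTerpstra(groups)
  expect_identical(approx$method, "normal")
  perm <- jonckheereTerpstra(groups, n_perm = 2000, seed = 99)
  expect_identical(perm$method, "permutation")
  expect_lt(abs(approx$p_value - perm$p_value), 0.02)
})

test_that("ageing equivalents divide slopes and scale by exposure", {
  expect_identical(ageingEquivalents(0, 6, 24), 0)
  expect_equal(ageingEquivalents(89, 6, 24), 22.25, tolerance = 1e-12)
  expect_equal(ageingEquivalents(20, 40, 43), 800 / 43, tolerance = 1e-12)
  expect_error(ageingEquivalents(89, 6, 0), "positive")
  res <- ageingEquivalentsFromDuration(300, 0.5, 24)
  expect_equal(res$rate_per_year, 600, tolerance = 1e-12)
  expect_equal(res$ageing_years, 12.5, tolerance = 1e-12)
})
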