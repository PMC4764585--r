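make_obs <- function(rates, times = c(5, 20, 40, 60, 80, 100), noise_sd = 0,
                     draws = 1) {
  purrr::imap_dfr(rates, function(rate, lin) {
    t <- rep(times, each = draws)
    tibble::tibble(pair_id = paste0(lin, "_", seq_along(t)), lineage = lin,
                   divergence_myr = t,
                   similarity = exp(rate * t) + stats::rnorm(length(t), 0, noise_sd))
  })
}

test_that("noiseless single-exponential data are recovered exactly", {
  obs <- make_obs(c(x = -0.005))
  fit <- fit_decay(obs, "naive")
  expect_equal(unname(fit$slopes[["all"]]), -0.005, tolerance = 1e-9)
  expect_equal(fit$intercept, 0, tolerance = 1e-9)
  expect_lt(fit$rss, 1e-9)
  expect_equal(fit$n_params, 2L)
})

test_that("noiseless two-lineage data give exact lineage-aware slopes", {
  obs <- make_obs(c(m = -0.003, i = -0.007))
  fit <- fit_decay(obs, "aware")
  expect_equal(unname(fit$slopes[c("m", "i")]), c(-0.003, -0.007),
               tolerance = 1e-9)
  expect_lt(fit$rss, 1e-9)
  expect_equal(fit$n_params, 3L)
})

test_that("naive fit equals the normal-equations oracle on noisy data", {
  set.seed(42)
  obs <- make_obs(c(x = -0.004), times = seq(5, 100, length.out = 20),
                  noise_sd = 0.01)
  fit <- fit_decay(obs, "naive")
  orc <- oracle_ols(obs$divergence_myr, log(obs$similarity))
  expect_equal(unname(fit$slopes[["all"]]), orc$slope, tolerance = 1e-10)
  expect_equal(fit$intercept, orc$intercept, tolerance = 1e-10)
  expect_equal(fit$rss, orc$rss, tolerance = 1e-10)
})

test_that("refitting the returned parameters reproduces the reported rss", {
  set.seed(7)
  obs <- make_obs(c(a = -0.004, b = -0.006), noise_sd = 0.005, draws = 2)
  for (kind in c("naive", "aware", "specific")) {
    fit <- fit_decay(obs, kind)
    y <- log(obs$similarity)
    t <- obs$divergence_myr
    pred <- if (kind == "specific") {
      fit$intercept[obs$lineage] + fit$slopes[obs$lineage] * t
    } else if (kind == "aware") {
      fit$intercept + fit$slopes[obs$lineage] * t
    } else {
      fit$intercept + fit$slopes[["all"]] * t
    }
    expect_equal(sum((y - pred)^2), fit$rss, tolerance = 1e-10)
  }
})

test_that("model nesting orders residual sums of squares", {
  set.seed(11)
  for (rep in 1:20) {
    obs <- make_obs(c(a = -0.002 - runif(1) / 200, b = -0.004, c = -0.008),
                    noise_sd = 0.02, draws = 2)
    obs <- obs[obs$similarity > 0, ]
    f0 <- fit_decay(obs, "naive")
    f1 <- fit_decay(obs, "aware")
    f2 <- fit_decay(obs, "specific")
    expect_lte(f1$rss, f0$rss + 1e-12)
    expect_lte(f2$rss, f1$rss + 1e-12)
  }
})

test_that("degenerate and invalid inputs raise the documented errors", {
  obs <- make_obs(c(x = -0.005))
  expect_error(fit_decay(obs[1:2, ], "naive"), class = "netdecay_df_error")
  neg <- obs
  neg$similarity <- -neg$similarity
  expect_error(fit_decay(neg, "naive"), class = "netdecay_empty_error")
  expect_warning(fit_decay(obs, "aware"), "one lineage")
  some_neg <- make_obs(c(a = -0.004, b = -0.006))
  some_neg$similarity[1] <- -0.1
  expect_warning(fit_decay(some_neg, "naive"), "non-positive")
})

test_that("chi-squared LRT statistic matches the direct formula", {
  set.seed(13)
  obs <- make_obs(c(a = -0.003, b = -0.009), noise_sd = 0.01, draws = 2)
  f0 <- fit_decay(obs, "naive")
  f1 <- fit_decay(obs, "aware")
  res <- lrt_compare(f0, f1, method = "lrt")
  n <- nrow(obs)
  expect_equal(res$statistic, n * log(f0$rss / f1$rss), tolerance = 1e-12)
  expect_equal(res$p_value,
               pchisq(n * log(f0$rss / f1$rss), df = 1, lower.tail = FALSE),
               tolerance = 1e-12)
  # F variant matches anova() on the equivalent lm fits
  fit_lm0 <- lm(log(similarity) ~ divergence_myr, data = obs)
  fit_lm1 <- lm(log(similarity) ~ divergence_myr:lineage, data = obs)
  a <- anova(fit_lm0, fit_lm1)
  resf <- lrt_compare(f0, f1, method = "ftest")
  expect_equal(resf$statistic, a$F[2], tolerance = 1e-8)
  expect_equal(resf$p_value, a$`Pr(>F)`[2], tolerance = 1e-8)
})

test_that("identical-rate zero-noise data give p = 1", {
  obs <- make_obs(c(a = -0.005, b = -0.005))
  f0 <- fit_decay(obs, "naive")
  f1 <- fit_decay(obs, "aware")
  expect_equal(lrt_compare(f0, f1)$p_value, 1)
})

test_that("nested-fit contract violations are rejected", {
  obs <- make_obs(c(a = -0.003, b = -0.009), noise_sd = 0.01)
  f0 <- fit_decay(obs, "naive")
  f1 <- fit_decay(obs, "aware")
  expect_error(lrt_compare(f1, f0), class = "netdecay_contract_error")
  f0b <- fit_decay(obs[-1, ], "naive")
  expect_error(lrt_compare(f0b, f1), class = "netdecay_contract_error")
})

test_that("extreme rate separation is detected almost always", {
  set.seed(17)
  hits <- 0L
  for (i in 1:200) {
    obs <- make_obs(c(a = -0.003, b = -0.010),
                    times = seq(4, 100, length.out = 15), noise_sd = 0.005)
    f0 <- fit_decay(obs, "naive")
    f1 <- fit_decay(obs, "aware")
    if (lrt_compare(f0, f1)$p_value < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / 200, 0.99)
})

test_that("effect size follows its definition and takes the max over pairs", {
  mk_fit <- function(s100) {
    obs <- purrr::imap_dfr(s100, function(s, lin) {
      tibble::tibble(lineage = lin, divergence_myr = c(5, 50, 100),
                     similarity = exp(log(s) / 100 * c(5, 50, 100)))
    })
    fit_decay(obs, "specific")
  }
  fit <- mk_fit(c(A = 0.30, B = 0.22))
  expect_equal(effect_size(fit), 8.0, tolerance = 1e-6)
  fit3 <- mk_fit(c(A = 0.60, B = 0.55, C = 0.30))
  expect_equal(effect_size(fit3), 30.0, tolerance = 1e-6)
  pairs <- effect_size(fit3, pairs = TRUE)
  expect_equal(nrow(pairs), 3L)
  expect_equal(sort(pairs$effect_size_pct), c(5, 25, 30), tolerance = 1e-6)
  # identical lineages: zero effect
  same <- mk_fit(c(A = 0.4, B = 0.4))
  expect_equal(effect_size(same), 0, tolerance = 1e-9)
  # single lineage undefined
  obs1 <- make_obs(c(x = -0.005))
  expect_error(effect_size(fit_decay(obs1, "specific")),
               class = "netdecay_contract_error")
})

test_that("verdict requires both significance and effect-size gates", {
  # slopes differing by a hair: p tiny at large n, effect ~2 pp at 100 Myrs
  set.seed(23)
  obs <- make_obs(c(a = -0.0050, b = -0.0053),
                  times = seq(2, 100, length.out = 40), noise_sd = 1e-4,
                  draws = 2)
  cmp <- compare_rates(obs)
  expect_lt(cmp$p_value, 0.01)
  expect_lt(cmp$effect_size_pct, 5)
  expect_equal(cmp$verdict, "indistinguishable")
  # and the invariant holds on every comparison
  for (i in 1:10) {
    o <- make_obs(c(a = -0.004, b = -0.004 - runif(1) / 150),
                  noise_sd = 0.01, draws = 2)
    o <- o[o$similarity > 0, ]
    cc <- suppressWarnings(compare_rates(o))
    expect_equal(cc$verdict == "different",
                 cc$p_value < cc$alpha && cc$effect_size_pct > cc$effect_threshold)
  }
})

test_that("well-separated rates yield 'different', equal rates do not", {
  set.seed(31)
  sep <- make_obs(c(a = -0.002, b = -0.010), noise_sd = 0.01, draws = 2)
  expect_equal(compare_rates(sep)$verdict, "different")
  same <- make_obs(c(a = -0.005, b = -0.005), noise_sd = 0.01, draws = 2)
  expect_equal(compare_rates(same)$verdict, "indistinguishable")
})

test_that("lineage-specific slopes recover simulated rates within 10%", {
  set.seed(37)
  for (i in 1:10) {
    obs <- make_obs(c(a = -0.003, b = -0.007),
                    times = seq(5, 100, length.out = 20), noise_sd = 0.005)
    fit <- fit_decay(obs, "specific")
    expect_lt(abs(fit$slopes[["a"]] + 0.003) / 0.003, 0.10)
    expect_lt(abs(fit$slopes[["b"]] + 0.007) / 0.007, 0.10)
  }
})

test_that("null p-values are uniform under the model's error assumptions", {
  # equal rates, Gaussian noise in log space (the fitted model's assumption);
  # the F test is exact here, so KS against U(0,1) must not reject
  set.seed(41)
  times <- c(2, 7, 13, 25, 45, 60, 91, 97)
  ps <- replicate(500, {
    obs <- purrr::map_dfr(c("a", "b"), function(lin) {
      t <- rep(times, 2)
      tibble::tibble(lineage = lin, divergence_myr = t,
                     similarity = exp(-0.005 * t + rnorm(length(t), 0, 0.02)))
    })
    compare_rates(obs)$p_value
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("tidy and glance summarise fits and comparisons", {
  set.seed(43)
  obs <- make_obs(c(a = -0.003, b = -0.007), noise_sd = 0.002, draws = 2)
  cmp <- compare_rates(obs)
  td <- tidy(cmp)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("lineage_a", "lineage_b", "predicted_a", "predicted_b",
                     "effect_size_pct"))
  gl <- glance(cmp)
  expect_equal(gl$n_lineages, 2L)
  tf <- tidy(fit_decay(obs, "specific"))
  expect_equal(nrow(tf), 2L)
  expect_s3_class(autoplot(cmp), "ggplot")
})

test_that("similarity tables round-trip through TSV", {
  set.seed(47)
  obs <- make_obs(c(a = -0.003, b = -0.007), noise_sd = 0.002)
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(obs, path)
  back <- read_similarity_tsv(path)
  expect_equal(back$similarity, obs$similarity)
  expect_equal(back$lineage, obs$lineage)
})
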