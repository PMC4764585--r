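#' Fit an exponential decay model to cross-species similarity data
#'
#' Cross-species similarity (a correlation, a retained fraction, a percent
#' identity ...) is modelled as an exponential decay over divergence time by
#' ordinary least squares in log-linear space:
#' \eqn{\log s = a + b t}, where \eqn{t} is the divergence time in millions of
#' years (Myrs) and \eqn{b} is the per-Myr decay rate. Three parameter-sharing
#' structures are available:
#'
#' * `"naive"` — one shared intercept and one shared slope for all lineages;
#' * `"aware"` — one shared intercept, one slope per lineage;
#' * `"specific"` — an independent intercept and slope per lineage.
#'
#' The naive and aware models are nested, so their residual sums of squares can
#' be compared with a likelihood ratio test ([lrt_compare()]); the specific
#' models are used to predict similarity at a time horizon for the effect size
#' ([effect_size()]).
#'
#' Because the fit runs on `log(similarity)`, non-positive similarities cannot
#' enter the fit; they are dropped with a warning and the count is recorded in
#' the returned object (`$n_dropped`).
#'
#' @param data A data frame with columns `similarity` (numeric),
#'   `divergence_myr` (numeric, >= 0) and `lineage` (character or factor).
#'   Extra columns (e.g. `pair_id`) are ignored.
#' @param model One of `"naive"`, `"aware"`, `"specific"`.
#' @return An object of class `decay_fit`: a list with `model_kind`,
#'   `intercept` (named per-lineage vector for `"specific"`, scalar otherwise),
#'   `slopes` (named per-lineage vector; length 1 named `"all"` for naive),
#'   `rss`, `n_obs`, `n_params`, `lineages` and `n_dropped`.
#' @examples
#' obs <- tibble::tibble(
#'   divergence_myr = rep(c(5, 20, 40, 60, 80, 100), 2),
#'   lineage = rep(c("mammals", "insects"), each = 6)
#' )
#' obs$similarity <- exp(ifelse(obs$lineage == "mammals", -0.005, -0.007) *
#'   obs$divergence_myr)
#' fit_decay(obs, "aware")
#' @seealso [compare_rates()] for the full significance + effect-size decision.
#' @export
fit_decay <- function(data, model = c("naive", "aware", "specific")) {
  model <- match.arg(model)
  obs <- validate_observations(data)

  keep <- obs$similarity > 0
  n_dropped <- sum(!keep)
  if (n_dropped > 0L) {
    if (!any(keep)) {
      stop_netdecay("all similarities are non-positive; nothing to fit",
                    class = "netdecay_empty_error")
    }
    warning(sprintf("dropped %d non-positive similarity value(s) before log transform",
                    n_dropped), call. = FALSE)
    obs <- obs[keep, , drop = FALSE]
  }

  y <- log(obs$similarity)
  t <- obs$divergence_myr
  g <- as.character(obs$lineage)
  lineages <- sort(unique(g))

  if (model == "aware" && length(lineages) == 1L) {
    warning("only one lineage present; lineage-aware model reduces to lineage-naive",
            call. = FALSE)
    model <- "naive"
  }

  fit <- switch(model,
    naive    = fit_decay_naive(y, t),
    aware    = fit_decay_aware(y, t, g, lineages),
    specific = fit_decay_specific(y, t, g, lineages)
  )
  fit$lineages <- lineages
  fit$n_dropped <- n_dropped
  structure(fit, class = "decay_fit")
}

validate_observations <- function(data) {
  if (!is.data.frame(data)) {
    stop_netdecay("`data` must be a data frame of similarity observations")
  }
  need <- c("similarity", "divergence_myr", "lineage")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0L) {
    stop_netdecay(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (nrow(data) == 0L) {
    stop_netdecay("no observations", class = "netdecay_empty_error")
  }
  if (any(!is.finite(data$similarity))) {
    stop_netdecay("`similarity` must be finite")
  }
  if (any(!is.finite(data$divergence_myr)) || any(data$divergence_myr < 0)) {
    stop_netdecay("`divergence_myr` must be finite and >= 0")
  }
  if (any(is.na(data$lineage))) {
    stop_netdecay("`lineage` must not contain missing values")
  }
  data
}

check_df <- function(n_obs, n_params, n_per_slope = NULL) {
  if (!is.null(n_per_slope) && any(n_per_slope < 3L)) {
    stop_netdecay("need at least 3 observations per free slope",
                  class = "netdecay_df_error")
  }
  if (n_obs <= n_params) {
    stop_netdecay("more parameters than observations",
                  class = "netdecay_df_error")
  }
  invisible(TRUE)
}

fit_decay_naive <- function(y, t) {
  n <- length(y)
  check_df(n, 2L, n_per_slope = n)
  tbar <- mean(t); ybar <- mean(y)
  sxx <- sum((t - tbar)^2)
  if (sxx == 0) stop_netdecay("all divergence times identical; slope not identifiable",
                              class = "netdecay_df_error")
  b <- sum((t - tbar) * (y - ybar)) / sxx
  a <- ybar - b * tbar
  r <- y - a - b * t
  list(model_kind = "naive", intercept = a, slopes = c(all = b),
       rss = sum(r^2), n_obs = n, n_params = 2L)
}

fit_decay_aware <- function(y, t, g, lineages) {
  n <- length(y)
  k <- length(lineages)
  n_per <- tabulate(factor(g, levels = lineages))
  check_df(n, k + 1L, n_per_slope = n_per)
  # shared intercept, per-lineage slope: solve (k+1) x (k+1) normal equations
  gi <- match(g, lineages)
  xtx <- matrix(0, k + 1L, k + 1L)
  xty <- numeric(k + 1L)
  xtx[1L, 1L] <- n
  xty[1L] <- sum(y)
  for (j in seq_len(k)) {
    sel <- gi == j
    st <- sum(t[sel])
    xtx[1L, j + 1L] <- xtx[j + 1L, 1L] <- st
    xtx[j + 1L, j + 1L] <- sum(t[sel]^2)
    xty[j + 1L] <- sum(t[sel] * y[sel])
  }
  beta <- solve(xtx, xty)
  a <- beta[1L]
  b <- beta[-1L]
  names(b) <- lineages
  r <- y - a - b[gi] * t
  list(model_kind = "aware", intercept = a, slopes = b,
       rss = sum(r^2), n_obs = n, n_params = k + 1L)
}

fit_decay_specific <- function(y, t, g, lineages) {
  k <- length(lineages)
  gi <- match(g, lineages)
  a <- b <- stats::setNames(numeric(k), lineages)
  rss <- 0
  for (j in seq_len(k)) {
    sel <- gi == j
    sub <- fit_decay_naive(y[sel], t[sel])
    a[j] <- sub$intercept
    b[j] <- sub$slopes[["all"]]
    rss <- rss + sub$rss
  }
  list(model_kind = "specific", intercept = a, slopes = b,
       rss = rss, n_obs = length(y), n_params = 2L * k)
}

#' Likelihood ratio test between nested decay fits
#'
#' Tests whether allowing per-lineage decay rates (the lineage-aware model)
#' improves the fit over a single shared rate (the lineage-naive model),
#' comparing the nested least-squares fits either by the extra-sum-of-squares
#' F statistic referred to \eqn{F(\Delta p,\; n - p_1)}, or by the Gaussian
#' likelihood ratio statistic \eqn{n \log(\mathrm{RSS}_0 / \mathrm{RSS}_1)}
#' referred to a chi-squared distribution with \eqn{\Delta p} degrees of
#' freedom.
#'
#' The F test is the default: it is what `anova()` computes on nested
#' least-squares fits in R, and it is exact under the Gaussian null at the
#' small sample sizes typical of cross-species similarity series, so null
#' p-values are uniform. The chi-squared likelihood ratio variant
#' (`method = "lrt"`) is asymptotically equivalent and provided for
#' sensitivity checks.
#'
#' @param fit_naive,fit_aware `decay_fit` objects fitted to the same
#'   observations, with `fit_aware` the richer model.
#' @param method `"ftest"` (default) or `"lrt"`.
#' @return A list with `statistic`, `df`, `p_value` and `method`.
#' @export
lrt_compare <- function(fit_naive, fit_aware, method = c("ftest", "lrt")) {
  method <- match.arg(method)
  stopifnot(inherits(fit_naive, "decay_fit"), inherits(fit_aware, "decay_fit"))
  if (fit_naive$n_obs != fit_aware$n_obs) {
    stop_netdecay("fits were not computed on the same observations",
                  class = "netdecay_contract_error")
  }
  if (fit_aware$n_params <= fit_naive$n_params) {
    stop_netdecay("`fit_aware` must have more parameters than `fit_naive` (nested models)",
                  class = "netdecay_contract_error")
  }
  n <- fit_naive$n_obs
  df <- fit_aware$n_params - fit_naive$n_params
  rss0 <- fit_naive$rss
  rss1 <- fit_aware$rss
  if (rss1 <= 0) {
    # perfect rich fit: p = 1 when the restricted fit is also perfect, else 0
    p <- if (rss0 <= .Machine$double.eps * n) 1 else 0
    stat <- if (p == 1) 0 else Inf
    return(list(statistic = stat, df = df, p_value = p, method = method))
  }
  if (method == "lrt") {
    stat <- n * log(rss0 / rss1)
    p <- stats::pchisq(stat, df = df, lower.tail = FALSE)
  } else {
    df2 <- n - fit_aware$n_params
    stat <- ((rss0 - rss1) / df) / (rss1 / df2)
    p <- stats::pf(stat, df, df2, lower.tail = FALSE)
  }
  list(statistic = stat, df = df, p_value = p, method = method)
}

#' Effect size: predicted similarity difference at a time horizon
#'
#' From the lineage-specific decay fits, predicts similarity for every lineage
#' at `horizon_myr` (default 100 Myrs) as \eqn{\exp(a_l + b_l \cdot h)} and
#' returns the absolute pairwise differences in percentage points. The headline
#' effect size is the maximum over lineage pairs, so a difference is declared
#' if any pair of lineages is predicted to differ.
#'
#' @param fit A `decay_fit` of kind `"specific"` with at least two lineages.
#' @param horizon_myr Prediction horizon in Myrs (default 100).
#' @param pairs If `TRUE`, return a tibble of all pairwise differences instead
#'   of the scalar maximum.
#' @return A scalar (percentage points), or a tibble with columns `lineage_a`,
#'   `lineage_b`, `predicted_a`, `predicted_b`, `effect_size_pct` when
#'   `pairs = TRUE`.
#' @export
effect_size <- function(fit, horizon_myr = 100, pairs = FALSE) {
  stopifnot(inherits(fit, "decay_fit"))
  if (fit$model_kind != "specific") {
    stop_netdecay("effect size is defined on lineage-specific fits",
                  class = "netdecay_contract_error")
  }
  ln <- fit$lineages
  if (length(ln) < 2L) {
    stop_netdecay("effect size needs at least two lineages",
                  class = "netdecay_contract_error")
  }
  pred <- exp(fit$intercept[ln] + fit$slopes[ln] * horizon_myr)
  idx <- utils::combn(seq_along(ln), 2L)
  eff <- abs(pred[idx[1L, ]] - pred[idx[2L, ]]) * 100
  if (!pairs) {
    return(max(eff))
  }
  tibble::tibble(
    lineage_a = ln[idx[1L, ]],
    lineage_b = ln[idx[2L, ]],
    predicted_a = unname(pred[idx[1L, ]]),
    predicted_b = unname(pred[idx[2L, ]]),
    effect_size_pct = unname(eff)
  )
}

#' Compare evolutionary divergence rates between lineages
#'
#' The full decision procedure: fit the lineage-naive, lineage-aware and
#' lineage-specific decay models to the observations, test naive vs aware with
#' a likelihood ratio test, compute the effect size at `horizon_myr` from the
#' specific fits, and issue a verdict. Rates are called `"different"` only when
#' the test is significant (`p < alpha`) *and* the effect size exceeds
#' `effect_threshold` percentage points; otherwise `"indistinguishable"`.
#'
#' @inheritParams fit_decay
#' @param alpha Significance level for the likelihood ratio test (default 0.05).
#' @param effect_threshold Minimum effect size in percentage points at the
#'   horizon for a difference to be called (default 5).
#' @param horizon_myr Effect-size prediction horizon in Myrs (default 100).
#' @param test `"ftest"` (default; the extra-sum-of-squares F test that
#'   `anova()` applies to nested fits) or `"lrt"` for the chi-squared
#'   likelihood ratio variant.
#' @return An object of class `rate_comparison`: a list with `p_value`,
#'   `effect_size_pct`, `effect_pairs` (tibble), `verdict`
#'   (`"different"` or `"indistinguishable"`), `fits` (the three `decay_fit`
#'   objects), the decision parameters, and `data` (the observations used).
#' @examples
#' set.seed(1)
#' obs <- simulate_two_lineages(power_config(base_rate = -0.005,
#'                                           rate_delta = 0.004,
#'                                           noise_sd = 0.005))
#' cmp <- compare_rates(obs)
#' cmp$verdict
#' @export
compare_rates <- function(data, alpha = 0.05, effect_threshold = 5,
                          horizon_myr = 100, test = c("ftest", "lrt")) {
  test <- match.arg(test)
  fits <- list(
    naive    = fit_decay(data, "naive"),
    aware    = fit_decay(data, "aware"),
    specific = fit_decay(data, "specific")
  )
  if (length(fits$naive$lineages) < 2L) {
    stop_netdecay("rate comparison needs at least two lineages",
                  class = "netdecay_contract_error")
  }
  lrt <- lrt_compare(fits$naive, fits$aware, method = test)
  eff_pairs <- effect_size(fits$specific, horizon_myr = horizon_myr, pairs = TRUE)
  eff <- max(eff_pairs$effect_size_pct)
  verdict <- if (lrt$p_value < alpha && eff > effect_threshold) {
    "different"
  } else {
    "indistinguishable"
  }
  structure(
    list(
      p_value = lrt$p_value,
      statistic = lrt$statistic,
      df = lrt$df,
      test = test,
      effect_size_pct = eff,
      effect_pairs = eff_pairs,
      verdict = verdict,
      fits = fits,
      alpha = alpha,
      effect_threshold = effect_threshold,
      horizon_myr = horizon_myr,
      data = tibble::as_tibble(data)
    ),
    class = "rate_comparison"
  )
}

#' Read a similarity observation table
#'
#' Reads a TSV with columns `pair_id`, `lineage`, `divergence_myr`,
#' `similarity` (extra columns kept) as produced by the layer analyses.
#'
#' @param path Path to a tab-separated file.
#' @return A tibble of similarity observations.
#' @export
read_similarity_tsv <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_observations(out)
  tibble::as_tibble(out)
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("<decay_fit> %s model: %d obs, %d params, RSS %.4g\n",
              x$model_kind, x$n_obs, x$n_params, x$rss))
  if (x$model_kind == "specific") {
    for (l in x$lineages) {
      cat(sprintf("  %s: log(s) = %.4f %+.6f * t\n", l, x$intercept[[l]], x$slopes[[l]]))
    }
  } else {
    for (l in names(x$slopes)) {
      cat(sprintf("  %s: log(s) = %.4f %+.6f * t\n", l, x$intercept, x$slopes[[l]]))
    }
  }
  invisible(x)
}

#' @export
print.rate_comparison <- function(x, ...) {
  cat("<rate_comparison>\n")
  cat(sprintf("  verdict: %s (p = %.3g, effect size %.2f pp at %g Myrs)\n",
              x$verdict, x$p_value, x$effect_size_pct, x$horizon_myr))
  cat(sprintf("  decision rule: p < %g and effect > %g pp; test: %s\n",
              x$alpha, x$effect_threshold, x$test))
  invisible(x)
}

#' Tidy a decay fit into one row per lineage
#'
#' @param x A `decay_fit`.
#' @param ... Unused.
#' @return A tibble with columns `model_kind`, `lineage`, `intercept`, `slope`.
#' @export
tidy.decay_fit <- function(x, ...) {
  if (x$model_kind == "specific") {
    tibble::tibble(model_kind = x$model_kind, lineage = x$lineages,
                   intercept = unname(x$intercept[x$lineages]),
                   slope = unname(x$slopes[x$lineages]))
  } else {
    tibble::tibble(model_kind = x$model_kind, lineage = names(x$slopes),
                   intercept = x$intercept, slope = unname(x$slopes))
  }
}

#' @rdname tidy.decay_fit
#' @export
glance.decay_fit <- function(x, ...) {
  tibble::tibble(model_kind = x$model_kind, rss = x$rss, n_obs = x$n_obs,
                 n_params = x$n_params,
                 sigma = sqrt(x$rss / (x$n_obs - x$n_params)))
}

#' Tidy the result of a rate comparison
#'
#' `tidy()` returns the pairwise effect-size table; `glance()` returns a
#' one-row summary with the p-value, maximum effect size and verdict.
#'
#' @param x A `rate_comparison`.
#' @param ... Unused.
#' @export
tidy.rate_comparison <- function(x, ...) {
  x$effect_pairs
}

#' @rdname tidy.rate_comparison
#' @export
glance.rate_comparison <- function(x, ...) {
  tibble::tibble(p_value = x$p_value, statistic = x$statistic, df = x$df,
                 test = x$test, effect_size_pct = x$effect_size_pct,
                 verdict = x$verdict, n_obs = x$fits$naive$n_obs,
                 n_lineages = length(x$fits$naive$lineages))
}

#' Plot a rate comparison
#'
#' Draws the similarity observations against divergence time, with the
#' lineage-naive fit (black dashed) and per-lineage lineage-specific fits
#' (coloured dashed), in the style used throughout the decay analyses.
#'
#' @param object A `rate_comparison`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rate_comparison <- function(object, ...) {
  obs <- object$data
  tmax <- max(obs$divergence_myr)
  grid <- tidyr::expand_grid(
    lineage = object$fits$specific$lineages,
    divergence_myr = seq(0, tmax, length.out = 101)
  )
  sp <- object$fits$specific
  grid$fit <- exp(sp$intercept[grid$lineage] + sp$slopes[grid$lineage] * grid$divergence_myr)
  naive <- tibble::tibble(
    divergence_myr = seq(0, tmax, length.out = 101),
    fit = exp(object$fits$naive$intercept +
                object$fits$naive$slopes[["all"]] * seq(0, tmax, length.out = 101))
  )
  ggplot2::ggplot(obs, ggplot2::aes(x = .data$divergence_myr, y = .data$similarity)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$lineage), alpha = 0.8) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$fit, colour = .data$lineage),
                       linetype = "dashed") +
    ggplot2::geom_line(data = naive, ggplot2::aes(y = .data$fit),
                       colour = "black", linetype = "dashed") +
    ggplot2::labs(
      x = "Divergence time (Myrs)", y = "Cross-species similarity",
      subtitle = sprintf("%s (p = %.3g, effect %.1f pp at %g Myrs)",
                         object$verdict, object$p_value,
                         object$effect_size_pct, object$horizon_myr)
    ) +
    ggplot2::theme_minimal()
}
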