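#' Tukey multiple comparison with compact letter display
#'
#' One-way ANOVA context: pairwise Tukey HSD p-values from the studentized
#' range distribution with the pooled mean square error, plus a compact
#' letter display ('a' = highest mean; groups sharing a letter are not
#' significantly different at `alpha`). Pairs with zero mean difference are
#' never significant, so all-identical data yields a single shared letter
#' even when the residual variance is zero.
#'
#' @param groups named list of numeric sample vectors (>= 2 groups, each
#'   n >= 2).
#' @param alpha significance level (default 0.05).
#' @return An object of class `seasonal_result`: list with `means`, `sds`,
#'   `n`, the pairwise `p` matrix, `letters` (named character vector) and
#'   `alpha`.
#' @export
tukey_cld <- function(groups, alpha = 0.05) {
  k <- length(groups)
  if (k < 2) stop("need at least 2 groups")
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("g", seq_len(k))
  n <- vapply(groups, length, 0L)
  if (any(n < 2)) stop("each group needs n >= 2")
  means <- vapply(groups, mean, 0)
  sds <- vapply(groups, sd, 0)
  df <- sum(n) - k
  mse <- sum((n - 1) * sds^2) / df
  p <- matrix(1, k, k, dimnames = list(names(groups), names(groups)))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    dm <- abs(means[i] - means[j])
    if (dm == 0) { pij <- 1 }
    else if (mse <= 0) { pij <- 0 }
    else {
      se <- sqrt(mse / 2 * (1 / n[i] + 1 / n[j]))
      pij <- ptukey(dm / se, nmeans = k, df = df, lower.tail = FALSE)
    }
    p[i, j] <- p[j, i] <- pij
  }
  letters_v <- cld_letters(means, p, alpha)
  structure(list(means = means, sds = sds, n = n, p = p,
                 letters = letters_v, alpha = alpha, df = df, mse = mse),
            class = "seasonal_result")
}

# Compact letters: groups ordered by descending mean; each maximal
# consecutive run of mutually non-significant groups gets one letter. With a
# common HSD threshold, non-significance is an interval graph in mean order,
# so runs are exactly the maximal cliques.
cld_letters <- function(means, p, alpha) {
  k <- length(means)
  ord <- order(means, decreasing = TRUE)
  ns <- p >= alpha
  runs <- list()
  for (s in seq_len(k)) {
    e <- s
    while (e < k && all(ns[ord[s:(e + 1)], ord[s:(e + 1)]])) e <- e + 1
    if (length(runs) == 0 || e > runs[[length(runs)]][2])
      runs[[length(runs) + 1]] <- c(s, e)
  }
  lab <- rep("", k)
  for (r in seq_along(runs)) {
    span <- runs[[r]][1]:runs[[r]][2]
    lab[ord[span]] <- paste0(lab[ord[span]], letters[r])
  }
  names(lab) <- names(means)
  lab
}

#' @rdname tukey_cld
#' @param x a `seasonal_result`.
#' @param ... ignored.
#' @export
print.seasonal_result <- function(x, ...) {
  cat(sprintf("Tukey multiple comparison (alpha = %g)\n", x$alpha))
  print(data.frame(mean = x$means, sd = x$sds, n = x$n,
                   letters = x$letters))
  invisible(x)
}

#' Average hourly growth rate between two stage means
#'
#' `rate = (mean_b - mean_a) / ((day_b - day_a) * 24)`, the linear seasonal
#' growth rate used to de-trend circadian series.
#'
#' @param mean_a,mean_b trait means at the two anchor days.
#' @param day_a,day_b anchor days (days after planting), `day_b > day_a`.
#' @return Rate in trait units per hour.
#' @export
hourly_rate <- function(mean_a, day_a, mean_b, day_b) {
  if (!(day_b > day_a)) stop("day_b must exceed day_a")
  (mean_b - mean_a) / ((day_b - day_a) * 24)
}

#' De-trend a circadian trait series
#'
#' Subtracts the linear seasonal growth accumulated since `t0`:
#' `corrected(t) = raw(t) - rate * hours(t - t0)`. With `t0` at the first
#' observation the first corrected value equals the first raw value.
#' A negative of the same call re-trends, so the round trip is exact.
#'
#' @param times `POSIXct` (or numeric hours) observation times.
#' @param values raw trait values.
#' @param rate hourly growth rate (trait units per hour).
#' @param t0 anchor time; defaults to the first observation.
#' @return Numeric vector of corrected values.
#' @export
detrend_series <- function(times, values, rate, t0 = times[1]) {
  if (inherits(times, "POSIXct")) {
    hours <- as.numeric(difftime(times, as.POSIXct(t0), units = "hours"))
  } else {
    hours <- as.numeric(times) - as.numeric(t0)
  }
  if (any(hours < -1e-9)) stop("t0 must not exceed the first timestamp")
  values - rate * hours
}

#' @rdname detrend_series
#' @export
retrend_series <- function(times, values, rate, t0 = times[1]) {
  detrend_series(times, values, -rate, t0)
}

#' Natural cubic-spline interpolation of an environmental series
#'
#' Interpolates the fixed-cadence records with a natural cubic spline (zero
#' second derivative at the ends), exact at the knots. Queries outside the
#' recorded span are rejected rather than extrapolated.
#'
#' @param env an `env_series` data frame (columns `time`, `par`,
#'   `temperature`, `rh`), or any data frame with a `time` column plus
#'   numeric columns.
#' @param query_times `POSIXct` query times within the recorded span.
#' @param vars which columns to interpolate.
#' @return Data frame with `time` and the interpolated columns.
#' @export
spline_interp <- function(env, query_times,
                          vars = c("par", "temperature", "rh")) {
  stopifnot(is.data.frame(env), "time" %in% names(env))
  x <- as.numeric(as.POSIXct(env$time))
  q <- as.numeric(as.POSIXct(query_times))
  if (any(q < min(x) - 1e-9) || any(q > max(x) + 1e-9))
    stop("query times outside the recorded span; extrapolation refused")
  vars <- intersect(vars, names(env))
  out <- data.frame(time = as.POSIXct(query_times))
  for (v in vars)
    out[[v]] <- spline(x, env[[v]], xout = q, method = "natural")$y
  out
}

p_tier <- function(p) {
  if (is.na(p)) return(NA_character_)
  if (p < 0.001) "p<0.001" else if (p < 0.01) "p<0.01"
  else if (p < 0.05) "p<0.05" else "ns"
}

#' Pearson environment-trait correlation with significance tier
#'
#' Sample Pearson correlation with a two-sided p-value from the
#' t-distribution on n - 2 degrees of freedom, plus the reporting tier
#' (`ns`, `p<0.05`, `p<0.01`, `p<0.001`). Constant input leaves r undefined
#' (`NA`, flagged by a warning).
#'
#' @param trait_values,env_values numeric vectors of equal length n >= 3.
#' @return A list with `r`, `p`, `tier`, `n`.
#' @export
pearson_env <- function(trait_values, env_values) {
  if (length(trait_values) != length(env_values))
    stop("vectors must have equal length")
  n <- length(trait_values)
  if (n < 3) stop("need n >= 3")
  if (sd(trait_values) == 0 || sd(env_values) == 0) {
    warning("constant input: Pearson r undefined")
    return(list(r = NA_real_, p = NA_real_, tier = NA_character_, n = n))
  }
  ct <- cor.test(trait_values, env_values, method = "pearson",
                 alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value,
       tier = p_tier(ct$p.value), n = n)
}

#' Circadian rhythm pipeline: aggregate, de-trend, correlate
#'
#' For each trait column: aggregates sample values to a per-moment mean
#' series, computes the hourly seasonal growth rate from the two anchor-day
#' means (rate 0 when no anchors are given, e.g. for the cold-stress
#' experiment which has no seasonal anchors), de-trends the series anchored
#' at the first observation moment, spline-interpolates the environmental
#' record to the observation moments, and correlates the corrected series
#' with PAR, RH and temperature.
#'
#' @param trait_table data frame with a `time` column (`POSIXct`), optional
#'   `id` column (plant or leaf id) and one column per trait.
#' @param env an `env_series` covering the observation span.
#' @param anchors optional list with `day_a`, `day_b` (days after planting)
#'   and named numeric vectors `mean_a`, `mean_b` of per-trait stage means;
#'   traits without anchors get rate 0.
#' @param traits trait column names; default all numeric non-id columns.
#' @return A list with `series` (long data frame: trait, time, raw,
#'   corrected, rate) and `correlations` (data frame: trait, factor, r, p,
#'   tier).
#' @export
circadian_pipeline <- function(trait_table, env, anchors = NULL,
                               traits = NULL) {
  stopifnot(is.data.frame(trait_table), "time" %in% names(trait_table))
  if (is.null(traits))
    traits <- setdiff(names(trait_table)[vapply(trait_table, is.numeric,
                                                TRUE)],
                      c("id", "plant", "leaf"))
  tt <- as.POSIXct(trait_table$time)
  moments <- sort(unique(tt))
  envq <- spline_interp(env, moments)
  series <- list()
  corr <- list()
  for (tr in traits) {
    raw <- vapply(moments, function(m)
      mean(trait_table[[tr]][tt == m], na.rm = TRUE), 0)
    rate <- 0
    if (!is.null(anchors) && tr %in% names(anchors$mean_a) &&
        tr %in% names(anchors$mean_b))
      rate <- hourly_rate(anchors$mean_a[[tr]], anchors$day_a,
                          anchors$mean_b[[tr]], anchors$day_b)
    corrected <- detrend_series(moments, raw, rate)
    series[[tr]] <- data.frame(trait = tr, time = moments, raw = raw,
                               corrected = corrected, rate = rate)
    for (fac in c("par", "rh", "temperature")) {
      pe <- pearson_env(corrected, envq[[fac]])
      corr[[paste(tr, fac)]] <- data.frame(
        trait = tr, factor = c(par = "PAR", rh = "RH",
                               temperature = "T")[[fac]],
        r = pe$r, p = pe$p, tier = pe$tier)
    }
  }
  list(series = do.call(rbind, c(series, list(make.row.names = FALSE))),
       correlations = do.call(rbind, c(corr, list(make.row.names = FALSE))))
}

#' Seasonal rhythm analysis across growth stages
#'
#' Runs [tukey_cld()] per trait on per-stage sample sets (for example one
#' value per plant per stage) and collects letters into a tidy table.
#'
#' @param trait_table data frame with a `stage` column (factor or
#'   character) and one numeric column per trait.
#' @param traits trait columns; default all numeric columns.
#' @param alpha significance level.
#' @return A data frame with one row per (trait, stage): mean, sd, n,
#'   letters.
#' @export
seasonal_analysis <- function(trait_table, traits = NULL, alpha = 0.05) {
  stopifnot(is.data.frame(trait_table), "stage" %in% names(trait_table))
  if (is.null(traits))
    traits <- names(trait_table)[vapply(trait_table, is.numeric, TRUE)]
  traits <- setdiff(traits, c("id", "plant", "leaf"))
  stages <- unique(as.character(trait_table$stage))
  out <- list()
  for (tr in traits) {
    groups <- lapply(stages, function(s)
      trait_table[[tr]][trait_table$stage == s &
                          !is.na(trait_table[[tr]])])
    names(groups) <- stages
    res <- tukey_cld(groups, alpha)
    out[[tr]] <- data.frame(trait = tr, stage = stages,
                            mean = unname(res$means), sd = unname(res$sds),
                            n = unname(res$n),
                            letters = unname(res$letters))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
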