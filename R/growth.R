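#' Extract lag, doubling time and efficiency from a growth curve
#'
#' The baseline is the median of the first three OD readings.  The curve
#' is smoothed with a centred moving average, the baseline-subtracted
#' signal `S` is log-transformed as `log(S + f)` with detection floor
#' `f = floor_frac * max(S)`, and the maximum specific growth rate
#' `mu_max` is the largest regression slope over sliding windows of
#' `slope_window` points whose mean signal lies within `eligible_range`
#' of the maximum (excluding the noisy near-baseline region and the
#' saturated plateau).  Then `doubling = log(2) / mu_max`, the lag is
#' where the tangent at the `mu_max` window intersects the baseline level
#' `log(f)`, and efficiency is the maximum smoothed OD minus the
#' baseline.  A curve is flagged non-growing when its efficiency is below
#' `0.05` OD or no positive eligible slope exists.
#'
#' Because the floor scales with the signal maximum, the doubling-time
#' estimate is invariant to rescaling the OD axis.
#'
#' @param curve Data.frame with columns `time_min` (strictly increasing)
#'   and `od`.
#' @param smoothing_window Centred moving-average width (points).
#' @param floor_frac Detection floor as a fraction of the signal maximum
#'   (matching [simulate_growth_curve()]).
#' @param slope_window Regression window width (points).
#' @param eligible_range Signal band (fractions of the maximum) in which
#'   slope windows are considered.
#' @return A list of class `growth_params` with `lag_min`,
#'   `doubling_min`, `efficiency_od`, `mu_max` and `non_grower`.
#' @export
#' @examples
#' gc <- simulate_growth_curve(120, 90, 1.0, noise_sd = 0)
#' extract_growth(gc)
extract_growth <- function(curve, smoothing_window = 3L, floor_frac = 0.1,
                           slope_window = 5L, eligible_range = c(0.2, 0.8)) {
  t <- curve$time_min; od <- curve$od
  if (length(t) < 10L) stop("need at least 10 samples")
  if (any(diff(t) <= 0)) stop("time must be strictly increasing")
  baseline <- median(od[1:3])
  non_grower <- function() structure(
    list(lag_min = NA_real_, doubling_min = NA_real_,
         efficiency_od = max(od) - baseline, mu_max = NA_real_,
         non_grower = TRUE), class = "growth_params")
  # centred moving average; raw values kept at the ends
  if (smoothing_window > 1L) {
    sm <- as.numeric(stats::filter(od, rep(1 / smoothing_window,
                                           smoothing_window), sides = 2))
    od_s <- ifelse(is.na(sm), od, sm)
  } else od_s <- od
  s <- od_s - baseline
  smax <- max(s)
  if (smax < 0.05) return(non_grower())
  f <- floor_frac * smax
  y <- log(pmax(s, 0) + f)
  n <- length(t); w <- slope_window
  if (n < w) return(non_grower())
  ks <- seq_len(n - w + 1L)
  best <- NULL
  for (k in ks) {
    idx <- k:(k + w - 1L)
    ms <- mean(s[idx])
    if (ms < eligible_range[1L] * smax || ms > eligible_range[2L] * smax)
      next
    tw <- t[idx]; yw <- y[idx]
    slope <- sum((tw - mean(tw)) * (yw - mean(yw))) / sum((tw - mean(tw))^2)
    if (is.null(best) || slope > best$slope)
      best <- list(slope = slope, tbar = mean(tw), ybar = mean(yw))
  }
  if (is.null(best) || best$slope <= 0) return(non_grower())
  mu <- best$slope
  # the tangent line for the lag intercept is estimated over the whole
  # exponential band (same line at zero noise, far more stable under
  # noise than a single 5-point window)
  band <- which(s >= eligible_range[1L] * smax &
                s <= eligible_range[2L] * smax)
  tangent <- best
  if (length(band) >= w) {
    tb <- t[band]; yb <- y[band]
    bslope <- sum((tb - mean(tb)) * (yb - mean(yb))) /
      sum((tb - mean(tb))^2)
    if (bslope > 0)
      tangent <- list(slope = bslope, tbar = mean(tb), ybar = mean(yb))
  }
  lag <- tangent$tbar + (log(f) - tangent$ybar) / tangent$slope
  structure(list(lag_min = lag, doubling_min = log(2) / mu,
                 efficiency_od = smax, mu_max = mu, non_grower = FALSE),
            class = "growth_params")
}

#' @export
print.growth_params <- function(x, ...) {
  if (x$non_grower) cat("growth_params: non-grower\n")
  else cat(sprintf(
    "growth_params: lag %.1f min, doubling %.1f min, efficiency %.3f OD\n",
    x$lag_min, x$doubling_min, x$efficiency_od))
  invisible(x)
}

#' Normalise one isolate's growth parameters to a reference
#'
#' Lag and doubling time are normalised as `log2(reference / isolate)` and
#' efficiency as `log2(isolate / reference)`, so that larger values always
#' mean better-than-reference performance.
#'
#' @param isolate,reference Lists (or `growth_params`) with `lag_min`,
#'   `doubling_min`, `efficiency_od`.
#' @return Named numeric vector with components `lag`, `rate`,
#'   `efficiency`.
#' @export
normalize_growth <- function(isolate, reference) {
  c(lag = log2(reference$lag_min / isolate$lag_min),
    rate = log2(reference$doubling_min / isolate$doubling_min),
    efficiency = log2(isolate$efficiency_od / reference$efficiency_od))
}

#' Build reference-normalised trait profiles
#'
#' @param params Data.frame with columns `strain`, `condition`,
#'   `lag_min`, `doubling_min`, `efficiency_od` and optionally `plate`
#'   (one row per replicate).
#' @param reference_strain Strain used as the per-plate (or per-condition)
#'   reference; its replicates are averaged.
#' @return Long data.frame `strain`, `condition`, `component`, `value`
#'   (`log2` ratios, components `lag`, `rate`, `efficiency`), averaged
#'   over replicates.
#' @export
normalize_profiles <- function(params, reference_strain = "BY4741") {
  stopifnot(all(c("strain", "condition", "lag_min", "doubling_min",
                  "efficiency_od") %in% names(params)))
  by_plate <- "plate" %in% names(params)
  key <- if (by_plate) paste(params$condition, params$plate, sep = "\r")
         else params$condition
  out <- list()
  for (k in unique(key)) {
    block <- params[key == k, , drop = FALSE]
    ref <- block[block$strain == reference_strain, , drop = FALSE]
    if (!nrow(ref)) next
    rmean <- list(lag_min = mean(ref$lag_min),
                  doubling_min = mean(ref$doubling_min),
                  efficiency_od = mean(ref$efficiency_od))
    iso <- block[block$strain != reference_strain, , drop = FALSE]
    for (st in unique(iso$strain)) {
      b <- iso[iso$strain == st, , drop = FALSE]
      imean <- list(lag_min = mean(b$lag_min),
                    doubling_min = mean(b$doubling_min),
                    efficiency_od = mean(b$efficiency_od))
      v <- normalize_growth(imean, rmean)
      out[[length(out) + 1L]] <- data.frame(
        strain = st, condition = b$condition[1L],
        component = names(v), value = unname(v), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Pairwise Pearson correlation of trait profiles
#'
#' @param profiles Long data.frame `strain`, `condition`, `component`,
#'   `value` (as from [normalize_profiles()]).
#' @param min_shared Pairs sharing fewer condition-component values are
#'   flagged (attribute `flagged`).
#' @return Strain-by-strain correlation matrix with unit diagonal.
#' @export
profile_correlation <- function(profiles, min_shared = 10L) {
  strains <- unique(profiles$strain)
  key <- paste(profiles$condition, profiles$component, sep = "\r")
  keys <- unique(key)
  m <- matrix(NA_real_, length(strains), length(keys),
              dimnames = list(strains, keys))
  m[cbind(profiles$strain, key)] <- profiles$value
  r <- diag(1, length(strains))
  dimnames(r) <- list(strains, strains)
  flagged <- character(0)
  for (i in seq_along(strains)) for (j in seq_len(i - 1L)) {
    shared <- which(!is.na(m[i, ]) & !is.na(m[j, ]))
    if (length(shared) >= 2L)
      r[i, j] <- r[j, i] <- cor(m[i, shared], m[j, shared])
    if (length(shared) < min_shared)
      flagged <- c(flagged, paste(strains[i], strains[j], sep = "~"))
  }
  attr(r, "flagged") <- flagged
  r
}

#' Differential traits between two strain groups
#'
#' Per condition-component two-sample t-test (equal-variance by default)
#' with Bonferroni correction over the number of tests performed.
#'
#' @param group_a,group_b Long data.frames `condition`, `component`,
#'   `value` (one row per strain or replicate).
#' @param alpha Significance level on the adjusted p-value.
#' @param var_equal Use the classical equal-variance t-test (`TRUE`) or
#'   Welch's (`FALSE`).
#' @return Data.frame of significant `condition`, `component` pairs with
#'   `p_raw` and `p_adj`; the full test table is attached as attribute
#'   `all_tests`.
#' @export
differential_traits <- function(group_a, group_b, alpha = 0.2,
                                var_equal = TRUE) {
  key_a <- paste(group_a$condition, group_a$component, sep = "\r")
  key_b <- paste(group_b$condition, group_b$component, sep = "\r")
  keys <- intersect(unique(key_a), unique(key_b))
  rows <- list()
  for (k in keys) {
    va <- group_a$value[key_a == k]
    vb <- group_b$value[key_b == k]
    if (length(va) < 2L || length(vb) < 2L) next
    p <- tryCatch(
      t.test(va, vb, var.equal = var_equal)$p.value,
      error = function(e) NA_real_)  # zero-variance identical groups
    parts <- strsplit(k, "\r", fixed = TRUE)[[1L]]
    rows[[length(rows) + 1L]] <- data.frame(
      condition = parts[1L], component = parts[2L], p_raw = p,
      stringsAsFactors = FALSE)
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(condition = character(), component = character(),
               p_raw = numeric(), stringsAsFactors = FALSE)
  tab$p_adj <- p.adjust(tab$p_raw, method = "bonferroni")
  sig <- tab[!is.na(tab$p_adj) & tab$p_adj < alpha, , drop = FALSE]
  rownames(sig) <- NULL
  attr(sig, "all_tests") <- tab
  sig
}
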