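#' Four-parameter logistic dose-response model
#'
#' `fourpl()` evaluates the 4PL viability model
#' \deqn{f(c) = d + \frac{a - d}{1 + (c/e)^h}}
#' where `upper` (a) is the low-concentration asymptote, `lower` (d) the
#' high-concentration asymptote, `inflection` (e, molar) the EC50 and
#' `hill` (h) the slope. With `hill > 0` viability decreases with
#' concentration; `f(inflection) = (a + d) / 2`.
#'
#' @param conc concentration(s), molar.
#' @param upper,lower,inflection,hill curve parameters.
#' @return viability value(s).
#' @export
fourpl <- function(conc, upper, lower, inflection, hill) {
  lower + (upper - lower) / (1 + (conc / inflection)^hill)
}

new_fourpl_fit <- function(upper, lower, inflection, hill, converged, rss,
                           n_points, non_identifiable = FALSE) {
  structure(
    list(upper = upper, lower = lower, inflection = inflection, hill = hill,
         converged = converged, rss = rss, n_points = n_points,
         non_identifiable = non_identifiable),
    class = "fourpl_fit"
  )
}

#' @export
print.fourpl_fit <- function(x, ...) {
  cat(sprintf(
    "<fourpl_fit> upper=%.4g lower=%.4g inflection=%.4g M hill=%.4g (%s, rss=%.3g, n=%d)%s\n",
    x$upper, x$lower, x$inflection, x$hill,
    if (x$converged) "converged" else "not converged", x$rss, x$n_points,
    if (x$non_identifiable) " [non-identifiable]" else ""))
  invisible(x)
}

fourpl_rss <- function(par, lx, v) {
  # par = (upper, lower, log10 inflection, hill); fit in log10-conc space
  f <- par[2] + (par[1] - par[2]) / (1 + 10^(par[4] * (lx - par[3])))
  sum((f - v)^2)
}

#' Fit a four-parameter logistic curve
#'
#' Least-squares fit of the 4PL model in log10-concentration space using
#' deterministic multi-start L-BFGS-B: starting inflection values are the
#' 10/25/50/75/90% quantiles of the measured log10 concentrations, with
#' extra shallow/steep Hill starts, so fits are reproducible without any
#' global RNG. The lowest-RSS converged solution wins and is polished by a
#' second optimizer pass.
#'
#' A flat response (all viabilities identical) returns a degenerate fit
#' with `upper == lower`, `hill = 0` and `non_identifiable = TRUE` rather
#' than an error.
#'
#' @param experiment a [dose_response_experiment()].
#' @param hill_bounds allowed Hill slope range; default `c(0.1, 10)`
#'   prevents divergence on sparse curves.
#' @param asym_margin how far asymptotes may drift beyond the observed
#'   viability range.
#' @return A `fourpl_fit` with fields `upper`, `lower`, `inflection`
#'   (molar), `hill`, `converged`, `rss`, `n_points`, `non_identifiable`.
#' @export
fit_4pl <- function(experiment, hill_bounds = c(0.1, 10), asym_margin = 0.5) {
  conc <- experiment$concentrations
  v <- experiment$viabilities
  n <- length(v)
  if (diff(range(v)) < 1e-12) {
    return(new_fourpl_fit(upper = v[1], lower = v[1],
                          inflection = stats::median(conc), hill = 0,
                          converged = TRUE, rss = 0, n_points = n,
                          non_identifiable = TRUE))
  }
  lx <- log10(conc)
  lo <- c(min(v) - asym_margin, min(v) - asym_margin, min(lx) - 3, hill_bounds[1])
  hi <- c(max(v) + asym_margin, max(v) + asym_margin, max(lx) + 3, hill_bounds[2])

  # data-derived starts: asymptotes from the curve ends, inflection from
  # concentration quantiles
  upper0 <- mean(v[seq_len(min(2, n))])
  lower0 <- mean(v[seq.int(max(1, n - 1), n)])
  if (upper0 < lower0) { tmp <- upper0; upper0 <- lower0; lower0 <- tmp }
  le_starts <- unname(stats::quantile(lx, c(0.1, 0.25, 0.5, 0.75, 0.9)))
  starts <- c(
    lapply(le_starts, function(le) c(upper0, lower0, le, 1)),
    list(c(upper0, lower0, stats::median(lx), 0.5),
         c(upper0, lower0, stats::median(lx), 3))
  )
  starts <- lapply(starts, function(p) pmin(pmax(p, lo), hi))

  best <- NULL
  best_conv <- NULL
  for (p0 in starts) {
    res <- tryCatch(
      stats::optim(p0, fourpl_rss, lx = lx, v = v, method = "L-BFGS-B",
                   lower = lo, upper = hi,
                   control = list(maxit = 1000, factr = 1e2)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$value < best$value) best <- res
    if (res$convergence == 0 &&
        (is.null(best_conv) || res$value < best_conv$value)) best_conv <- res
  }
  if (is.null(best)) {
    return(new_fourpl_fit(upper0, lower0, 10^stats::median(lx), 1,
                          converged = FALSE, rss = Inf, n_points = n))
  }
  converged <- !is.null(best_conv)
  sol <- if (converged) best_conv else best
  # polish the winning start for high-precision recovery on clean data
  polish <- tryCatch(
    stats::nlminb(sol$par, fourpl_rss, lx = lx, v = v,
                  lower = lo, upper = hi,
                  control = list(eval.max = 2000, iter.max = 1000,
                                 abs.tol = 0, rel.tol = 1e-15,
                                 x.tol = 1e-15)),
    error = function(e) NULL)
  if (!is.null(polish) && polish$objective <= sol$value) {
    sol <- list(par = polish$par, value = polish$objective)
  }
  new_fourpl_fit(upper = sol$par[1], lower = sol$par[2],
                 inflection = 10^sol$par[3], hill = sol$par[4],
                 converged = converged, rss = sol$value, n_points = n)
}

#' Standardized concentration range
#'
#' The fixed integration window used for range-independent AUDRC.
#' Defaults to 100 pM - 100 uM (1e-10 to 1e-4 M), a span of 6 orders of
#' magnitude that covers the therapeutic window of most approved
#' oncology compounds.
#'
#' @param cmin,cmax window bounds in molar; `cmin < cmax` required.
#' @return A `standard_range` object with `cmin`, `cmax`, and
#'   `log10_span = log10(cmax / cmin)`.
#' @export
standard_range <- function(cmin = 1e-10, cmax = 1e-4) {
  if (!is.finite(cmin) || !is.finite(cmax) || cmin <= 0 || cmax <= cmin) {
    stop_drp("standard_range requires 0 < cmin < cmax")
  }
  structure(list(cmin = cmin, cmax = cmax,
                 log10_span = log10(cmax / cmin)),
            class = "standard_range")
}

#' Absolute IC50 from a fitted curve
#'
#' Concentration at which the fitted curve crosses `threshold` viability,
#' solved in closed form:
#' `c = inflection * ((upper - t) / (t - lower))^(1/hill)`. This is the
#' "absolute" IC50 (50% of cells dead at the default threshold), distinct
#' from the inflection/EC50 parameter; the two coincide only when the
#' asymptotes are 1 and 0. Returns `NA` when the curve never reaches the
#' threshold (threshold not strictly between the asymptotes) or when
#' `hill == 0`.
#'
#' @param fit a converged `fourpl_fit`.
#' @param threshold viability level to cross; default 0.5.
#' @return concentration in molar, or `NA_real_` if undefined.
#' @export
absolute_ic50 <- function(fit, threshold = 0.5) {
  if (!fit$converged) stop_drp("absolute_ic50 requires a converged fit")
  if (fit$hill == 0) return(NA_real_)
  lo <- min(fit$upper, fit$lower)
  hi <- max(fit$upper, fit$lower)
  if (!(threshold > lo && threshold < hi)) return(NA_real_)
  ratio <- (fit$upper - threshold) / (threshold - fit$lower)
  fit$inflection * ratio^(1 / fit$hill)
}

#' Standardized AUDRC / AADRC
#'
#' Area under the fitted dose-response curve over a *fixed* log10
#' concentration window, normalized by the window width:
#' \deqn{AUDRC = \frac{1}{\log_{10} c_{max} - \log_{10} c_{min}}
#'   \int_{\log_{10} c_{min}}^{\log_{10} c_{max}}
#'   \mathrm{clamp}(f(10^x), 0, 1)\, dx}
#' computed by adaptive quadrature (absolute tolerance 1e-8). Fitted
#' viability is clamped to \[0, 1\] inside the integral so the score
#' respects its bounds even when asymptotes drift outside \[0, 1\].
#' AUDRC = 1 means no effect anywhere in the window; 0 means complete
#' killing. Because the window is fixed, identical curves measured over
#' different experimental concentration ranges get identical scores —
#' unlike [audrc_trapezoid_experimental()].
#'
#' `aadrc()` is the complement `1 - audrc()` (area *above* the curve,
#' i.e. total drug effect).
#'
#' @param fit a converged `fourpl_fit`.
#' @param range a [standard_range()].
#' @return value in \[0, 1\].
#' @export
audrc <- function(fit, range = standard_range()) {
  if (!fit$converged) stop_drp("audrc requires a converged fit")
  lo <- log10(range$cmin)
  hi <- log10(range$cmax)
  integrand <- function(x) {
    pmin(1, pmax(0, fourpl(10^x, fit$upper, fit$lower, fit$inflection, fit$hill)))
  }
  # clamping introduces kinks where the curve crosses 0 or 1; splitting the
  # window there keeps the integrand smooth on every sub-interval so the
  # adaptive rule actually reaches its tolerance
  crossings <- numeric(0)
  if (fit$hill != 0) {
    for (level in c(0, 1)) {
      lo_asym <- min(fit$upper, fit$lower)
      hi_asym <- max(fit$upper, fit$lower)
      if (level > lo_asym && level < hi_asym) {
        ratio <- (fit$upper - level) / (level - fit$lower)
        x_cross <- log10(fit$inflection) + log10(ratio) / fit$hill
        if (x_cross > lo && x_cross < hi) crossings <- c(crossings, x_cross)
      }
    }
  }
  breaks <- sort(unique(c(lo, crossings, hi)))
  val <- sum(vapply(seq_len(length(breaks) - 1), function(i) {
    stats::integrate(integrand, breaks[i], breaks[i + 1],
                     abs.tol = 1e-8, rel.tol = 1e-9,
                     subdivisions = 1000L)$value
  }, numeric(1)))
  val / (hi - lo)
}

#' @rdname audrc
#' @export
aadrc <- function(fit, range = standard_range()) {
  1 - audrc(fit, range)
}

#' Legacy experiment-range trapezoidal AUDRC
#'
#' The DrugCell-style score this framework argues against: trapezoidal
#' integration of the clamped *observed* viabilities over the experiment's
#' own log10-concentration range, normalized by that range's width. Because
#' the window follows each experiment, identical underlying curves sampled
#' over different concentration ranges receive different values — the
#' motivating inconsistency for the standardized [audrc()].
#'
#' @param experiment a [dose_response_experiment()].
#' @return normalized trapezoidal area (typically in \[0, 1\]).
#' @export
audrc_trapezoid_experimental <- function(experiment) {
  x <- log10(experiment$concentrations)
  y <- pmin(1, pmax(0, experiment$viabilities))
  width <- diff(range(x))
  area <- sum(diff(x) * (head(y, -1) + y[-1]) / 2)
  area / width
}

#' Normalize triplet responses
#'
#' * `minmax_global` / `minmax_per_drug`: linear map of each group onto
#'   \[0, 1\] (values near 0 = strong effect when responses are AUDRC-like).
#' * `center_per_drug` / `center_per_cell`: subtract each group's mean, so
#'   the mean response per drug (or per cell) is zero — highlighting
#'   differential effects across cells rather than potency differences
#'   across drugs.
#'
#' Groups with zero variance map to 0.5 (minmax) or 0 (center) with a
#' warning.
#'
#' @param dataset a [triplet_dataset()].
#' @param mode normalization mode.
#' @return a `triplet_dataset` with transformed responses; minmax modes are
#'   tagged `response_type = "normalized"`, center modes `"ln_ic50"`
#'   (unbounded scale).
#' @export
normalize_responses <- function(dataset,
                                mode = c("minmax_global", "minmax_per_drug",
                                         "center_per_drug", "center_per_cell")) {
  mode <- match.arg(mode)
  if (nrow(dataset) == 0) stop_drp("cannot normalize an empty dataset")
  records <- as_tibble(as.data.frame(dataset))
  group <- switch(mode,
                  minmax_global = rep("all", nrow(records)),
                  minmax_per_drug = records$drug_id,
                  center_per_drug = records$drug_id,
                  center_per_cell = records$cell_id)
  minmax <- grepl("^minmax", mode)
  out <- records$response
  degenerate <- character(0)
  for (g in unique(group)) {
    idx <- which(group == g)
    r <- records$response[idx]
    span <- diff(range(r))
    if (span < 1e-300) {
      out[idx] <- if (minmax) 0.5 else 0
      degenerate <- c(degenerate, g)
    } else if (minmax) {
      out[idx] <- (r - min(r)) / span
    } else {
      out[idx] <- r - mean(r)
    }
  }
  if (length(degenerate) > 0) {
    warn_drp("zero-variance normalization group(s): %s",
             paste(degenerate, collapse = ", "))
  }
  records$response <- out
  restore_triplets(records, dataset,
                   response_type = if (minmax) "normalized" else "ln_ic50")
}

#' Binarize responses into sensitivity calls
#'
#' Within each scope group (per drug, or globally), responses at or below
#' the `low_pct` percentile are called `"sensitive"`, those at or above the
#' `high_pct` percentile `"resistant"`, and everything between
#' `"undefined"`. Percentiles use linear interpolation
#' (`quantile(type = 7)`). Groups with fewer than 4 records are skipped
#' with a warning; a zero-variance group (every value is both at P_low and
#' P_high) is called all-`"undefined"` with a warning.
#'
#' @param dataset a [triplet_dataset()].
#' @param low_pct,high_pct percentile thresholds, `0 <= low < high <= 100`.
#' @param scope `"per_drug"` (default) or `"global"`.
#' @return tibble with columns `cell_id`, `drug_id`, `call` (factor with
#'   levels sensitive/resistant/undefined).
#' @export
binarize <- function(dataset, low_pct = 25, high_pct = 75,
                     scope = c("per_drug", "global")) {
  scope <- match.arg(scope)
  if (!(low_pct >= 0 && low_pct < high_pct && high_pct <= 100)) {
    stop_drp("need 0 <= low_pct < high_pct <= 100")
  }
  records <- as_tibble(as.data.frame(dataset))
  group <- if (scope == "per_drug") records$drug_id else rep("all", nrow(records))
  pieces <- list()
  for (g in unique(group)) {
    idx <- which(group == g)
    if (length(idx) < 4) {
      warn_drp("binarize: group '%s' has %d record(s) (< 4), skipped",
               g, length(idx))
      next
    }
    r <- records$response[idx]
    p_low <- unname(stats::quantile(r, low_pct / 100, type = 7))
    p_high <- unname(stats::quantile(r, high_pct / 100, type = 7))
    sens <- r <= p_low
    resist <- r >= p_high
    call <- rep("undefined", length(idx))
    call[sens & !resist] <- "sensitive"
    call[resist & !sens] <- "resistant"
    if (any(sens & resist)) {
      warn_drp("binarize: group '%s' is degenerate (ties span both thresholds); %d record(s) set undefined",
               g, sum(sens & resist))
    }
    pieces[[g]] <- tibble(cell_id = records$cell_id[idx],
                          drug_id = records$drug_id[idx],
                          call = call)
  }
  out <- if (length(pieces) > 0) bind_rows(pieces) else
    tibble(cell_id = character(), drug_id = character(), call = character())
  out$call <- factor(out$call, levels = c("sensitive", "resistant", "undefined"))
  out
}

#' Summarize dose-response fits as a table
#'
#' Fits every experiment and returns one row per experiment with the fitted
#' parameters and standardized scores, ready for CSV export.
#'
#' @param experiments list of [dose_response_experiment()].
#' @param range a [standard_range()].
#' @param ... passed to [fit_4pl()].
#' @return tibble with columns `experiment_id`, `cell_id`, `drug_id`,
#'   `upper`, `lower`, `inflection_M`, `hill`, `converged`, `rss`,
#'   `ic50_M`, `ln_ic50`, `audrc`, `aadrc`.
#' @export
fit_dose_response_table <- function(experiments, range = standard_range(), ...) {
  rows <- lapply(experiments, function(ex) {
    fit <- fit_4pl(ex, ...)
    ic50 <- if (fit$converged) absolute_ic50(fit) else NA_real_
    au <- if (fit$converged) audrc(fit, range) else NA_real_
    tibble(experiment_id = ex$experiment_id,
           cell_id = ex$cell_id, drug_id = ex$drug_id,
           upper = fit$upper, lower = fit$lower,
           inflection_M = fit$inflection, hill = fit$hill,
           converged = fit$converged, rss = fit$rss,
           ic50_M = ic50,
           ln_ic50 = ifelse(is.na(ic50), NA_real_, log(ic50)),
           audrc = au,
           aadrc = ifelse(is.na(au), NA_real_, 1 - au))
  })
  bind_rows(rows)
}
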