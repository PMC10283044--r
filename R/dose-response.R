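#' Read a long-format plate CSV
#'
#' Expected columns: `plate_id, assay, row, col, treatment, conc_um,
#' bio_rep, tech_rep, signal` and optionally `signal_ref` (the 650 nm
#' reference absorbance of the MTT readout) and `group` (e.g. sex labels).
#'
#' @param path CSV path.
#' @return data frame of well readings.
#' @export
read_plate_csv <- function(path) {
  if (!file.exists(path)) abort_config("plate file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  need <- c("plate_id", "assay", "treatment", "conc_um", "bio_rep",
            "tech_rep", "signal")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    abort_config("plate file is missing columns: ",
                 paste(miss, collapse = ", "))
  }
  df
}

#' Percent viability from MTT plate readings
#'
#' Blank handling subtracts the 650 nm reference from the 570 nm formazan
#' absorbance per well; each well is then expressed as a percentage of the
#' mean blank-corrected signal of that plate's DMSO vehicle-control wells.
#' Technical replicates are averaged within biological replicate, so the
#' unit of replication in downstream fitting and testing is the biological
#' replicate.  Vehicle-control wells are used only for normalization and do
#' not appear in the output.
#'
#' @param plate data frame of well readings (see [read_plate_csv()]) with
#'   `assay == "MTT"`; control wells are those with `treatment == "DMSO"`.
#' @return data frame with one row per compound x concentration x
#'   biological replicate: `compound, assay, conc_um, bio_rep, response,
#'   n_tech` (and `group` if present in the input).
#' @export
mtt_percent_viability <- function(plate) {
  plate <- plate[plate$assay == "MTT", , drop = FALSE]
  if (nrow(plate) == 0) abort_validation("no MTT wells in plate data")
  if (is.null(plate$signal_ref)) plate$signal_ref <- 0
  plate$corrected <- plate$signal - plate$signal_ref

  out <- lapply(split(plate, plate$plate_id), function(p) {
    ctrl <- p$corrected[p$treatment == "DMSO"]
    if (length(ctrl) == 0) {
      abort_validation("plate '", p$plate_id[1],
                       "' has no DMSO control wells; cannot normalize")
    }
    m <- mean(ctrl)
    if (m <= 0) {
      abort_data_quality("plate '", p$plate_id[1],
                         "' has non-positive mean control signal (", m, ")")
    }
    trt <- p[p$treatment != "DMSO", , drop = FALSE]
    trt$response <- 100 * trt$corrected / m
    trt
  })
  norm <- do.call(rbind, out)
  aggregate_tech_reps(norm)
}

#' Percent cytotoxicity from LDH plate readings
#'
#' Kit-style low/high-control scaling:
#' `% cytotoxicity = 100 * (signal - mean(low)) / (mean(high) - mean(low))`,
#' where low controls are untreated wells (spontaneous release,
#' `treatment == "low_control"`) and high controls are lysed wells (maximum
#' release, `treatment == "high_control"`), per plate.  Technical
#' replicates are averaged within biological replicate.
#'
#' @param plate data frame of well readings with `assay == "LDH"` carrying
#'   designated low- and high-control wells.
#' @return data frame as in [mtt_percent_viability()].
#' @export
ldh_percent_cytotoxicity <- function(plate) {
  plate <- plate[plate$assay == "LDH", , drop = FALSE]
  if (nrow(plate) == 0) abort_validation("no LDH wells in plate data")

  out <- lapply(split(plate, plate$plate_id), function(p) {
    low <- p$signal[p$treatment == "low_control"]
    high <- p$signal[p$treatment == "high_control"]
    if (length(low) == 0 || length(high) == 0) {
      abort_validation("plate '", p$plate_id[1],
                       "' lacks low_control and/or high_control wells")
    }
    lo <- mean(low); hi <- mean(high)
    if (hi <= lo) {
      abort_data_quality("plate '", p$plate_id[1],
                         "': high control (", hi,
                         ") does not exceed low control (", lo, ")")
    }
    trt <- p[!p$treatment %in% c("low_control", "high_control", "DMSO"), ,
             drop = FALSE]
    trt$response <- 100 * (trt$signal - lo) / (hi - lo)
    trt
  })
  norm <- do.call(rbind, out)
  aggregate_tech_reps(norm)
}

# average technical replicates within biological replicate
aggregate_tech_reps <- function(norm) {
  keys <- list(compound = norm$treatment, assay = norm$assay,
               conc_um = norm$conc_um, bio_rep = norm$bio_rep)
  if (!is.null(norm$group)) keys$group <- norm$group
  agg <- stats::aggregate(norm$response, by = keys,
                          FUN = mean)
  names(agg)[names(agg) == "x"] <- "response"
  n <- stats::aggregate(norm$response, by = keys, FUN = length)
  agg$n_tech <- n$x
  agg <- agg[order(agg$compound, agg$conc_um, agg$bio_rep), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Four-parameter logistic response function
#'
#' `y = bottom + (top - bottom) / (1 + 10^(hill * (log10_ic50 - log10 x)))`.
#' A negative hill slope gives a response decreasing in concentration
#' (viability); a positive slope an increasing one (cytotoxicity).
#'
#' @param conc_um concentrations, uM (> 0).
#' @param top,bottom upper/lower plateaus, percent.
#' @param hill hill slope.
#' @param log10_ic50 log10 of the midpoint concentration, uM.
#' @return predicted responses.
#' @export
four_pl <- function(conc_um, top, bottom, hill, log10_ic50) {
  bottom + (top - bottom) / (1 + 10^(hill * (log10_ic50 - log10(conc_um))))
}

# profiled grid search: for each (log10_ic50, hill) candidate the two
# plateaus enter linearly and are solved in closed form (bottom clamped at
# bottom_min); returns the best candidate and its profiled plateaus
profile_grid_4pl <- function(lx, y, l50_grid, hill_grid, bottom_min) {
  best <- list(sse = Inf)
  for (h in hill_grid) {
    theta <- 1 / (1 + 10^(h * outer(l50_grid, lx, "-")))  # m x n
    om <- 1 - theta
    a11 <- rowSums(om * om)
    a12 <- rowSums(om * theta)
    a22 <- rowSums(theta * theta)
    b1 <- as.vector(om %*% y)
    b2 <- as.vector(theta %*% y)
    det <- a11 * a22 - a12 * a12
    ok <- det > 1e-10
    bottom <- ifelse(ok, (b1 * a22 - b2 * a12) / det, mean(y))
    top <- ifelse(ok, (b2 * a11 - b1 * a12) / det, mean(y))
    clamp <- ok & (bottom < bottom_min)
    bottom[clamp] <- bottom_min
    top[clamp] <- (b2[clamp] - bottom_min * a12[clamp]) / a22[clamp]
    pred_sse <- vapply(seq_along(l50_grid), function(i) {
      sum((y - (bottom[i] + (top[i] - bottom[i]) * theta[i, ]))^2)
    }, numeric(1))
    # keep the canonical orientation (top >= bottom); every mirrored
    # candidate has an equivalent counterpart at -hill
    pred_sse[top < bottom] <- Inf
    i <- which.min(pred_sse)
    if (pred_sse[i] < best$sse) {
      best <- list(sse = pred_sse[i], top = top[i], bottom = bottom[i],
                   hill = h, log10_ic50 = l50_grid[i])
    }
  }
  best
}

#' Fit a four-parameter logistic concentration-response curve
#'
#' Least-squares fit of the 4PL on log10 concentration.  Starting values
#' come from a deterministic profile grid over `(log10_ic50, hill)` with
#' the plateaus profiled in closed form; the best grid point is refined by
#' Levenberg-Marquardt ([minpack.lm::nlsLM]) with the bottom plateau
#' bounded below.  A singular or failed refinement yields the grid solution
#' with `converged = FALSE`, never an exception.  Vehicle-control points
#' (concentration 0) are excluded from fitting: they cannot sit on a log
#' axis and are already consumed by normalization.
#'
#' The fit is flagged `censored` when no midpoint inside the tested range
#' is identified: non-convergence, an IC50 beyond `max_tested`, an effect
#' span (`top - bottom`) below `min_span` percent, or no detectable
#' concentration effect (partial F-test of the 4PL against the constant
#' model, p > `effect_alpha`).  The plateaus are reported in canonical
#' orientation (`top >= bottom`); the mirrored parameterization
#' `(bottom, top, -hill)` describes the same curve.
#'
#' @param data data frame with `conc_um` and `response` (percent), e.g. one
#'   compound's rows from [mtt_percent_viability()].
#' @param max_tested highest tested concentration, uM; defaults to the
#'   largest concentration in `data`.  Also the censoring bound.
#' @param bottom_min lower bound for the bottom plateau (default 0).
#' @param top_init fallback initialization of the top plateau, percent.
#' @param min_span minimum effect span (percent) for the midpoint to count
#'   as identified.
#' @param effect_alpha significance level of the partial F-test used to
#'   decide whether any concentration effect is present.
#' @return An object of class `four_pl_fit`: list with `top`, `bottom`,
#'   `hill`, `log10_ic50`, `ic50`, `converged`, `censored`,
#'   `censor_bound`, `effect_p`, `rmse`, `n`.
#' @export
fit_four_pl <- function(data, max_tested = NULL, bottom_min = 0,
                        top_init = 100, min_span = 10, effect_alpha = 0.05) {
  if (!all(c("conc_um", "response") %in% names(data))) {
    abort_validation("data must have columns 'conc_um' and 'response'")
  }
  pts <- data[data$conc_um > 0 & is.finite(data$response), , drop = FALSE]
  concs <- sort(unique(pts$conc_um))
  if (length(concs) < 4) {
    abort_insufficient_data("need >= 4 distinct positive concentrations, got ",
                            length(concs))
  }
  if (is.null(max_tested)) max_tested <- max(concs)
  lx <- log10(pts$conc_um)
  y <- pts$response

  l50_grid <- seq(log10(min(concs)) - 1, log10(max(concs)) + 2, by = 0.1)
  hill_grid <- c(-5, -3, -2, -1.5, -1, -0.7, -0.5, -0.3,
                 0.3, 0.5, 0.7, 1, 1.5, 2, 3, 5)
  g <- profile_grid_4pl(lx, y, l50_grid, hill_grid, bottom_min)
  start_top <- if (is.finite(g$top)) g$top else top_init
  start_bottom <- if (is.finite(g$bottom)) {
    max(bottom_min, min(g$bottom, start_top))
  } else bottom_min
  start <- list(top = start_top, bottom = start_bottom,
                hill = g$hill, log10_ic50 = g$log10_ic50)

  resid_fn <- function(p) {
    y - (p[["bottom"]] + (p[["top"]] - p[["bottom"]]) /
           (1 + 10^(p[["hill"]] * (p[["log10_ic50"]] - lx))))
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = unlist(start), fn = resid_fn,
      lower = c(top = -Inf, bottom = bottom_min, hill = -Inf,
                log10_ic50 = min(l50_grid) - 2),
      upper = c(top = Inf, bottom = Inf, hill = Inf,
                log10_ic50 = max(l50_grid) + 2),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)

  if (!is.null(fit)) {
    cf <- as.list(fit$par)
    converged <- fit$info %in% 1:3  # minpack convergence codes
  } else {
    cf <- start
    converged <- FALSE
  }
  pred <- four_pl(pts$conc_um, cf$top, cf$bottom, cf$hill, cf$log10_ic50)
  if (cf$top < cf$bottom) {  # canonical orientation: top is the upper plateau
    cf[c("top", "bottom")] <- cf[c("bottom", "top")]
    cf$hill <- -cf$hill
  }
  rmse <- sqrt(mean((y - pred)^2))
  span <- cf$top - cf$bottom
  ic50 <- 10^cf$log10_ic50

  # partial F-test of the 4PL against the constant model: is there any
  # concentration effect to locate a midpoint in?
  sse1 <- sum((y - pred)^2)
  sse0 <- sum((y - mean(y))^2)
  df2 <- nrow(pts) - 4
  effect_p <- if (sse1 <= .Machine$double.eps * sse0 && sse0 > 0) {
    0
  } else if (df2 > 0 && sse1 > 0) {
    f <- ((sse0 - sse1) / 3) / (sse1 / df2)
    stats::pf(max(f, 0), 3, df2, lower.tail = FALSE)
  } else {
    1
  }

  censored <- !converged || !is.finite(ic50) || ic50 > max_tested ||
    span < min_span || effect_p > effect_alpha
  structure(list(top = cf$top, bottom = cf$bottom, hill = cf$hill,
                 log10_ic50 = cf$log10_ic50,
                 ic50 = if (is.finite(ic50)) ic50 else NA_real_,
                 converged = converged, censored = censored,
                 censor_bound = max_tested, effect_p = effect_p,
                 rmse = rmse, n = nrow(pts)),
            class = "four_pl_fit")
}

#' @export
print.four_pl_fit <- function(x, ...) {
  cat("Four-parameter logistic fit (n =", x$n, "points)\n")
  cat(sprintf("  top = %.2f%%, bottom = %.2f%%, hill = %.3f\n",
              x$top, x$bottom, x$hill))
  if (x$censored) {
    cat(sprintf("  IC50: > %g uM (censored at the tested range)\n",
                x$censor_bound))
  } else {
    cat(sprintf("  IC50 = %.3g uM (log10 = %.3f)\n", x$ic50, x$log10_ic50))
  }
  cat(sprintf("  converged: %s, RMSE = %.2f%%\n", x$converged, x$rmse))
  invisible(x)
}

#' Report an IC50 with range censoring
#'
#' Reproduces the reporting convention of screening tables: a numeric IC50
#' when the fitted midpoint lies within the tested range, and the bound
#' with a ">" comparator (e.g. `">50"`) when the fit is censored, failed to
#' converge, or exceeds `max_tested`.  The comparator is returned as a
#' separate field so downstream code never parses the display string.
#'
#' @param fit a [fit_four_pl()] result.
#' @param max_tested highest tested concentration, uM; defaults to the
#'   fit's censor bound.
#' @return list with `display` (string), `cmp` (`"="` or `">"`), `value`
#'   (numeric), `approximate` (TRUE when convergence was marginal).
#' @export
report_ic50 <- function(fit, max_tested = NULL) {
  if (!inherits(fit, "four_pl_fit")) {
    abort_validation("fit must be a four_pl_fit object")
  }
  if (is.null(max_tested)) max_tested <- fit$censor_bound
  censored <- fit$censored || !fit$converged || is.na(fit$ic50) ||
    fit$ic50 > max_tested
  if (censored) {
    list(display = paste0(">", format(max_tested)), cmp = ">",
         value = max_tested, approximate = !fit$converged)
  } else {
    list(display = format(signif(fit$ic50, 3)), cmp = "=",
         value = fit$ic50, approximate = FALSE)
  }
}

#' Exact two-sided rank-sum test by complete enumeration
#'
#' Wilcoxon-Mann-Whitney rank-sum test with mid-ranks for ties and the
#' null distribution obtained by complete enumeration of all
#' `choose(n1 + n2, n1)` group assignments (feasible and exact for the
#' small per-group sizes of plate experiments; a normal approximation with
#' continuity correction is used beyond `max_exact_n` per group).  The
#' two-sided p-value is the null probability of a rank sum at least as far
#' from its expectation as observed.
#'
#' @param x,y numeric response vectors for the two groups.
#' @param max_exact_n enumerate exactly when both groups have at most this
#'   many observations (default 8).
#' @return list with `statistic` (rank sum of `x`), `p.value`, `method`.
#' @export
exact_rank_sum <- function(x, y, max_exact_n = 8) {
  if (!length(x) || !length(y)) abort_validation("both groups must be non-empty")
  nx <- length(x); ny <- length(y); n <- nx + ny
  r <- rank(c(x, y))  # mid-ranks under ties
  w_obs <- sum(r[seq_len(nx)])
  mu <- nx * (n + 1) / 2
  if (nx <= max_exact_n && ny <= max_exact_n) {
    idx <- utils::combn(n, nx)
    W <- colSums(matrix(r[idx], nrow = nx))
    p <- mean(abs(W - mu) >= abs(w_obs - mu) - 1e-9)
    method <- "exact enumeration"
  } else {
    p <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
    method <- "normal approximation"
  }
  list(statistic = w_obs, p.value = p, method = method)
}

#' Per-concentration nonparametric group comparison
#'
#' Compares two normalized dose-response datasets (e.g. male vs female
#' primary astrocytes) at each shared concentration with the exact
#' two-sided rank-sum test ([exact_rank_sum()]) on the per-biological-
#' replicate responses, followed by Holm step-down adjustment across the
#' concentration grid.
#'
#' @param a,b data frames with `conc_um`, `response`, `bio_rep` (as
#'   returned by [mtt_percent_viability()]); both must cover the same
#'   concentration grid.
#' @param alpha significance level applied to adjusted p-values.
#' @param adjust multiplicity adjustment method (see [stats::p.adjust()]).
#' @return An object of class `group_comparison`: data frame with
#'   `conc_um, statistic, p_raw, p_adj, n_a, n_b, significant`; attributes
#'   `alpha`, `adjust_method`, `verdict`.
#' @export
compare_groups <- function(a, b, alpha = 0.05, adjust = "holm") {
  for (df in list(a, b)) {
    if (!all(c("conc_um", "response") %in% names(df))) {
      abort_validation("datasets must have 'conc_um' and 'response' columns")
    }
  }
  ca <- sort(unique(a$conc_um)); cb <- sort(unique(b$conc_um))
  if (!identical(ca, cb)) {
    abort_validation("the two groups do not share the same concentration grid")
  }
  rows <- lapply(ca, function(conc) {
    xa <- a$response[a$conc_um == conc]
    xb <- b$response[b$conc_um == conc]
    t <- exact_rank_sum(xa, xb)
    data.frame(conc_um = conc, statistic = t$statistic, p_raw = t$p.value,
               n_a = length(xa), n_b = length(xb))
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p_raw, method = adjust)
  out$significant <- out$p_adj <= alpha
  out <- out[, c("conc_um", "statistic", "p_raw", "p_adj", "n_a", "n_b",
                 "significant")]
  verdict <- if (any(out$significant)) {
    paste0("significant differences at ",
           paste(out$conc_um[out$significant], collapse = ", "),
           " uM (adjusted p <= ", alpha, ")")
  } else {
    paste0("no significant differences at any concentration (adjusted p > ",
           alpha, ")")
  }
  structure(out, alpha = alpha, adjust_method = adjust, verdict = verdict,
            class = c("group_comparison", "data.frame"))
}
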