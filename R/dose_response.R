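# Dose-response processing for high-throughput viability screens: four-
# parameter logistic (4PL) curve fits on log10 concentration, normalized AUC
# summaries, the screen-level activity filter, and replicate QC. Viability is
# fraction-of-control; concentrations are molar. Lower AUC = more sensitive.

logistic4 <- function(logc, bottom, top, log_ec50, hill) {
  bottom + (top - bottom) / (1 + 10^(hill * (logc - log_ec50)))
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares 4PL fit of viability against log10(concentration), with
#' parameter bounds bottom in \[0,1\], top in \[0,1.5\], Hill slope in
#' \[0.1,10\] and the EC50 within two decades of the tested range. Replicate
#' viabilities at the same concentration are averaged before fitting. If the
#' bounded fit fails to converge the curve falls back to monotone linear
#' interpolation of the mean viabilities and the record is flagged
#' (`fallback = TRUE`).
#'
#' @param concentrations Molar concentrations (>= 4 distinct values).
#' @param viabilities Non-negative fraction-of-control viabilities, one per
#'   concentration entry (repeat concentration entries encode replicates).
#' @param drug_id,sample_id Optional identifiers carried on the result.
#' @return A `dose_response_curve`: list with `concentrations` (distinct,
#'   increasing), `viabilities` (replicate means), `fit_params`
#'   (top, bottom, ec50, hill), `auc`, and `fallback`.
#' @export
fit_curve <- function(concentrations, viabilities, drug_id = NA_character_,
                      sample_id = NA_character_) {
  stopifnot(length(concentrations) == length(viabilities))
  if (any(viabilities < 0)) stop("viabilities must be non-negative")
  conc <- sort(unique(concentrations))
  if (length(conc) < 4L) stop("need >=4 distinct concentrations")
  v <- vapply(conc, function(cc) mean(viabilities[concentrations == cc]),
              numeric(1L))
  lc <- log10(conc)

  curve <- list(drug_id = drug_id, sample_id = sample_id,
                concentrations = conc, viabilities = v,
                fit_params = c(top = NA_real_, bottom = NA_real_,
                               ec50 = NA_real_, hill = NA_real_),
                auc = NA_real_, fallback = FALSE)
  class(curve) <- "dose_response_curve"

  if (max(v) - min(v) < 1e-12) {  # flat response: top = bottom, no fit needed
    flat <- min(max(v[1L], 0), 1.5)
    curve$fit_params <- c(top = flat, bottom = min(flat, 1), ec50 = stats::median(conc),
                          hill = 1)
    curve$auc <- compute_auc(curve)
    return(curve)
  }

  lower <- c(bottom = 0, top = 0, log_ec50 = min(lc) - 2, hill = 0.1)
  upper <- c(bottom = 1, top = 1.5, log_ec50 = max(lc) + 2, hill = 10)
  start <- c(bottom = max(min(v), 0), top = min(max(v), 1.5),
             log_ec50 = stats::median(lc), hill = 1)
  start <- pmin(pmax(start, lower + 1e-6), upper - 1e-6)

  fit <- tryCatch({
    df <- data.frame(lc = lc, v = v)
    nl <- stats::nls(v ~ logistic4(lc, bottom, top, log_ec50, hill),
                     data = df, start = as.list(start), lower = lower,
                     upper = upper, algorithm = "port",
                     control = stats::nls.control(maxiter = 200, warnOnly = FALSE))
    stats::coef(nl)
  }, error = function(e) NULL)
  if (is.null(fit)) {
    fit <- tryCatch({
      obj <- function(th) sum((logistic4(lc, th[1L], th[2L], th[3L], th[4L]) - v)^2)
      op <- stats::optim(start, obj, method = "L-BFGS-B", lower = lower,
                         upper = upper, control = list(maxit = 500))
      if (op$convergence != 0) NULL else op$par
    }, error = function(e) NULL)
  }

  if (is.null(fit)) {
    curve$fallback <- TRUE
    curve$auc <- trapezoid_auc(lc, pmin(pmax(v, 0), 1))
    return(curve)
  }

  bottom <- unname(fit["bottom"]); top <- unname(fit["top"])
  hill <- unname(fit["hill"]); le50 <- unname(fit["log_ec50"])
  if (bottom > top) {  # increasing curve: re-express with bottom <= top
    tmp <- bottom; bottom <- top; top <- tmp; hill <- -hill
  }
  curve$fit_params <- c(top = top, bottom = bottom, ec50 = 10^le50, hill = hill)
  curve$auc <- compute_auc(curve)
  curve
}

trapezoid_auc <- function(lc, v) {
  w <- diff(lc)
  sum(w * (utils::head(v, -1L) + utils::tail(v, -1L)) / 2) / (max(lc) - min(lc))
}

#' Normalized AUC of a fitted dose-response curve
#'
#' Trapezoidal mean of the fitted viability (clipped to \[0,1\]) over the
#' tested log10-concentration range, normalized by the range width so values
#' are comparable across drugs with different concentration ranges. Returns a
#' value in \[0,1\]; 1 means no effect at any dose, 0 complete kill.
#'
#' @param curve A fitted `dose_response_curve`.
#' @param n_grid Number of grid points for the trapezoid rule.
#' @return AUC in \[0,1\].
#' @export
compute_auc <- function(curve, n_grid = 1001L) {
  stopifnot(inherits(curve, "dose_response_curve"))
  lc <- log10(curve$concentrations)
  if (curve$fallback || anyNA(curve$fit_params)) {
    return(trapezoid_auc(lc, pmin(pmax(curve$viabilities, 0), 1)))
  }
  p <- curve$fit_params
  if (p["top"] == p["bottom"]) {  # flat curve: AUC is the clipped constant, exactly
    return(unname(min(max(p["top"], 0), 1)))
  }
  grid <- seq(min(lc), max(lc), length.out = n_grid)
  v <- logistic4(grid, p["bottom"], p["top"], log10(p["ec50"]), p["hill"])
  trapezoid_auc(grid, pmin(pmax(v, 0), 1))
}

#' Screen-level activity filter
#'
#' Keeps the drugs that show activity (minimum fitted viability at or below
#' `threshold`) in at least `ceiling(sample_fraction * n)` samples. With the
#' defaults this is the "viability <= 50% in at least half the samples" rule
#' used to reduce a screen to its active panel.
#'
#' @param min_viability Numeric matrix, drugs x samples, of each pair's
#'   minimum fitted viability over the tested range.
#' @param threshold Viability cutoff defining activity (default 0.5).
#' @param sample_fraction Minimum fraction of samples in which a drug must be
#'   active (default 0.5).
#' @return Character vector of retained drug IDs (empty for empty input).
#' @export
activity_filter <- function(min_viability, threshold = 0.5,
                            sample_fraction = 0.5) {
  if (is.null(dim(min_viability)) || nrow(min_viability) == 0L) return(character(0L))
  need <- ceiling(sample_fraction * ncol(min_viability))
  n_active <- rowSums(min_viability <= threshold)
  rownames(min_viability)[n_active >= need]
}

#' Replicate consistency of AUC values
#'
#' Pearson correlation between duplicate AUC vectors, the screen QC statistic.
#'
#' @param auc_rep1,auc_rep2 Equal-length numeric vectors (length >= 3).
#' @return List with `r` and `pval`; `r` is `NA` (with a warning) if either
#'   replicate has zero variance.
#' @export
replicate_consistency <- function(auc_rep1, auc_rep2) {
  stopifnot(length(auc_rep1) == length(auc_rep2), length(auc_rep1) >= 3L)
  if (stats::sd(auc_rep1) == 0 || stats::sd(auc_rep2) == 0) {
    warning("zero variance in a replicate vector; correlation undefined")
    return(list(r = NA_real_, pval = NA_real_))
  }
  ct <- stats::cor.test(auc_rep1, auc_rep2, method = "pearson")
  list(r = unname(ct$estimate), pval = ct$p.value)
}
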