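# Univariate gene-drug association statistics: Pearson (or Spearman)
# correlation of each gene's expression with each drug's AUC across samples,
# t statistics and two-sided p-values, optional covariate adjustment (partial
# correlation), the Fisher z-transform used by the mixture model, and
# genome-wide Benjamini-Hochberg selection. Sign convention: negative r (high
# expression, low AUC) marks a sensitivity association.

#' Pairwise gene-drug association statistics
#'
#' Computes, for every gene-drug pair, the correlation between expression and
#' drug response across the shared samples, the t statistic
#' `t = r * sqrt(df / (1 - r^2))`, the two-sided p-value from the t
#' distribution, and the Fisher z-score `atanh(r) * sqrt(n - 3)`. With
#' covariates the statistics are partial correlations given the covariates
#' (equivalently, the gene coefficient test in a linear model of response on
#' expression plus covariates), with `df = n - 2 - ncol(covariates)`.
#' Zero-variance genes or drugs yield `NA` entries with a warning. Missing
#' values are handled pairwise-complete, with `n_used` recorded per pair.
#'
#' @param X Expression matrix, genes x samples.
#' @param Y Drug response matrix, drugs x samples, sample-aligned with `X`.
#' @param covariates Optional samples x c numeric matrix of covariates.
#' @param rank_based If `TRUE`, Spearman correlations (ranks are taken before
#'   the Pearson machinery; p-values use the t approximation).
#' @return An `association_table`: list with `gene_ids`, `drug_ids`, and
#'   genes x drugs matrices `r`, `t`, `pval`, `z`, `n_used`.
#' @export
pairwise_association <- function(X, Y, covariates = NULL, rank_based = FALSE) {
  assert_aligned(X, Y)
  n <- ncol(X)
  if (n < 4L) stop("need at least 4 samples")
  Xv <- X
  Yv <- Y
  if (rank_based) {
    Xv <- t(apply(X, 1L, rank, na.last = "keep"))
    Yv <- t(apply(Y, 1L, rank, na.last = "keep"))
    dimnames(Xv) <- dimnames(X); dimnames(Yv) <- dimnames(Y)
  }
  n_cov <- 0L
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    stopifnot(nrow(covariates) == n)
    if (qr(cbind(1, covariates))$rank < ncol(covariates) + 1L) {
      # rank-deficient design (e.g. a constant covariate duplicating the
      # intercept): drop the redundant columns rather than refuse
      keep <- logical(ncol(covariates))
      Q <- matrix(1, n, 1L)
      for (j in seq_len(ncol(covariates))) {
        cand <- cbind(Q, covariates[, j])
        if (qr(cand)$rank == ncol(cand)) { keep[j] <- TRUE; Q <- cand }
      }
      covariates <- covariates[, keep, drop = FALSE]
    }
    n_cov <- ncol(covariates)
    if (n_cov > 0L) {
      qrC <- qr(cbind(1, covariates))
      Xv <- t(qr.resid(qrC, t(Xv)))
      Yv <- t(qr.resid(qrC, t(Yv)))
      dimnames(Xv) <- dimnames(X); dimnames(Yv) <- dimnames(Y)
    }
  }
  df <- n - 2L - n_cov
  if (df < 1L) stop("not enough residual degrees of freedom")

  sd_x <- apply(Xv, 1L, stats::sd, na.rm = TRUE)
  sd_y <- apply(Yv, 1L, stats::sd, na.rm = TRUE)
  bad_x <- which(!is.finite(sd_x) | sd_x == 0)
  bad_y <- which(!is.finite(sd_y) | sd_y == 0)
  if (length(bad_x) || length(bad_y)) {
    warning(length(bad_x), " zero-variance gene(s) and ", length(bad_y),
            " zero-variance drug(s) marked missing")
  }
  if (anyNA(Xv) || anyNA(Yv)) {
    r <- suppressWarnings(stats::cor(t(Xv), t(Yv), use = "pairwise.complete.obs"))
    n_used <- crossprod(t(!is.na(Xv)) * 1, t(!is.na(Yv)) * 1)
  } else {
    r <- suppressWarnings(stats::cor(t(Xv), t(Yv)))
    n_used <- matrix(n, nrow(X), nrow(Y))
  }
  dimnames(r) <- list(rownames(X), rownames(Y))
  dimnames(n_used) <- dimnames(r)
  if (length(bad_x)) r[bad_x, ] <- NA_real_
  if (length(bad_y)) r[, bad_y] <- NA_real_

  df_pair <- pmax(n_used - 2L - n_cov, 0L)
  rr <- pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
  tstat <- rr * sqrt(df_pair / (1 - rr^2))
  pval <- 2 * stats::pt(-abs(tstat), df = pmax(df_pair, 1L))
  pval[pval == 0] <- .Machine$double.xmin
  z <- fisher_z_matrix(r, n_used)

  structure(list(gene_ids = rownames(X), drug_ids = rownames(Y),
                 r = r, t = tstat, pval = pval, z = z, n_used = n_used,
                 df = df, method = if (rank_based) "spearman" else "pearson",
                 n_covariates = n_cov),
            class = "association_table")
}

fisher_z_matrix <- function(r, n) {
  rr <- pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
  atanh(rr) * sqrt(pmax(n - 3, 0))
}

#' Fisher z-transform of a correlation
#'
#' `z = atanh(r) * sqrt(n - 3)`, approximately standard normal under the
#' null of no association, so association magnitudes are comparable across
#' genes and drugs. Correlations at exactly +/-1 are clipped to `1 - 1e-12`
#' with a warning.
#'
#' @param r Correlation(s) in \[-1, 1\].
#' @param n Sample count(s), > 3.
#' @return z score(s).
#' @export
fisher_z <- function(r, n) {
  stopifnot(all(n > 3))
  if (any(abs(r) >= 1, na.rm = TRUE)) {
    warning("|r| = 1 clipped to 1 - 1e-12")
  }
  rr <- pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
  atanh(rr) * sqrt(n - 3)
}

#' Genome-wide Benjamini-Hochberg pair selection
#'
#' BH step-up over all supplied p-values jointly (the "genome-wide FDR"
#' scope), returning the pairs whose adjusted p-value is at or below `q`.
#'
#' @param assoc An `association_table`, or a numeric vector of p-values.
#' @param q FDR level (default 0.1).
#' @param per_drug If `TRUE` and `assoc` is a table, BH is applied separately
#'   within each drug instead of jointly.
#' @return For a table input: a `significant_pairs` data frame with columns
#'   `gene_id`, `drug_id`, `r`, `pval`, `q_value`, plus attributes
#'   `q_threshold` and `drug_universe`. For a vector input: an integer vector
#'   of selected indices.
#' @export
bh_select <- function(assoc, q = 0.1, per_drug = FALSE) {
  if (is.numeric(assoc)) {
    if (length(assoc) == 0L) return(integer(0L))
    stopifnot(all(assoc > 0 & assoc <= 1, na.rm = TRUE))
    padj <- stats::p.adjust(assoc, method = "BH")
    return(which(!is.na(padj) & padj <= q))
  }
  stopifnot(inherits(assoc, "association_table"))
  p <- assoc$pval
  if (per_drug) {
    padj <- apply(p, 2L, stats::p.adjust, method = "BH")
    dimnames(padj) <- dimnames(p)
  } else {
    padj <- matrix(stats::p.adjust(p, method = "BH"), nrow(p), ncol(p),
                   dimnames = dimnames(p))
  }
  sel <- which(!is.na(padj) & padj <= q, arr.ind = TRUE)
  out <- data.frame(gene_id = assoc$gene_ids[sel[, 1L]],
                    drug_id = assoc$drug_ids[sel[, 2L]],
                    r = assoc$r[sel], pval = p[sel], q_value = padj[sel],
                    stringsAsFactors = FALSE)
  out <- out[order(out$pval, out$gene_id, out$drug_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "q_threshold") <- q
  attr(out, "drug_universe") <- assoc$drug_ids
  attr(out, "scope") <- if (per_drug) "per-drug" else "genome-wide"
  class(out) <- c("significant_pairs", "data.frame")
  out
}
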