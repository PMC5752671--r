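# The genes x 5 driver-feature matrix (mutation, expression hubness,
# regulator annotation, CNV, methylation) and the expression-hubness
# estimator. Hubness is a gene's neighbour count in a network inferred from an
# expression compendium; hub genes are candidate tumour drivers, so the count
# enters the model as prior evidence of marker potential.

DRIVER_FEATURES <- c("mutation", "hubness", "regulator", "cnv", "methylation")

#' Infer a gene network and per-gene hubness from an expression panel
#'
#' Two estimators are provided. `"lasso"` (default) performs per-gene sparse
#' neighbourhood regression of each gene on all others over a shared penalty
#' grid, keeps edge i-j if either direction selects it (OR rule), and picks
#' the penalty whose resulting mean degree is closest to `target_degree`.
#' `"correlation"` keeps the top `p * target_degree / 2` gene pairs by
#' absolute Pearson correlation. Constant-expression genes are excluded from
#' regressions and get degree 0 (warning).
#'
#' @param expression_panel Genes x samples numeric matrix (the inference
#'   compendium, not the screen data). Fewer than 20 samples triggers a
#'   warning: degree estimates become very noisy.
#' @param method `"lasso"` (neighbourhood selection) or `"correlation"`.
#' @param target_degree Sparsity control: desired mean degree of the network.
#' @return A `gene_network`: list with `gene_ids`, sparse symmetric binary
#'   `adjacency`, and the per-gene `degree` vector (the hubness feature).
#' @export
infer_hubness <- function(expression_panel, method = c("lasso", "correlation"),
                          target_degree = 5) {
  method <- match.arg(method)
  p <- nrow(expression_panel)
  n <- ncol(expression_panel)
  stopifnot(p >= 3L)
  if (n < 20L) warning("hubness inferred from <20 samples will be noisy")
  genes <- rownames(expression_panel)
  if (is.null(genes)) genes <- paste0("g", seq_len(p))
  sds <- apply(expression_panel, 1L, stats::sd)
  const <- sds == 0
  if (any(const)) {
    warning(sum(const), " constant-expression gene(s) excluded (degree 0)")
  }
  ok <- which(!const)
  Z <- t(scale(t(expression_panel[ok, , drop = FALSE])))  # genes standardized

  if (method == "correlation") {
    R <- stats::cor(t(Z))
    diag(R) <- 0
    a <- abs(R[upper.tri(R)])
    n_edges <- min(length(a), max(1L, round(p * target_degree / 2)))
    thr <- sort(a, decreasing = TRUE)[n_edges]
    A_ok <- (abs(R) >= thr) & upper.tri(R)
    idx <- which(A_ok, arr.ind = TRUE)
  } else {
    X <- t(Z)  # samples x genes
    k <- length(ok)
    # shared penalty grid anchored at the largest absolute inner product
    lam_max <- 0
    for (i in seq_len(k)) {
      lam_max <- max(lam_max, max(abs(crossprod(X[, -i, drop = FALSE], X[, i]))) / n)
    }
    lams <- exp(seq(log(lam_max), log(lam_max * 1e-2), length.out = 30L))
    sel <- vector("list", k)
    for (i in seq_len(k)) {
      fit <- glmnet::glmnet(X[, -i, drop = FALSE], X[, i], alpha = 1,
                            lambda = lams, standardize = FALSE)
      nz <- fit$beta != 0  # (k-1) x n_lambda logical
      rownames(nz) <- as.character(seq_len(k))[-i]
      sel[[i]] <- nz
    }
    # mean degree per lambda under the OR rule, via the union edge count
    best <- NULL
    best_gap <- Inf
    for (l in seq_along(lams)) {
      pairs <- matrix(0L, k, k)
      for (i in seq_len(k)) {
        js <- as.integer(rownames(sel[[i]])[sel[[i]][, l]])
        pairs[i, js] <- 1L
      }
      pairs <- (pairs | t(pairs))
      md <- sum(pairs) / p  # 2 * edges / p
      gap <- abs(md - target_degree)
      if (gap < best_gap) { best_gap <- gap; best <- pairs }
    }
    idx <- which(best & upper.tri(best), arr.ind = TRUE)
  }

  adj <- Matrix::sparseMatrix(i = ok[idx[, 1L]], j = ok[idx[, 2L]], x = 1,
                              dims = c(p, p), symmetric = TRUE)
  dimnames(adj) <- list(genes, genes)
  degree <- Matrix::rowSums(adj)
  names(degree) <- genes
  structure(list(gene_ids = genes, adjacency = adj, degree = degree,
                 method = method, target_degree = target_degree),
            class = "gene_network")
}

#' Assemble and standardize the driver-feature matrix
#'
#' Combines the five per-gene driver evidence vectors into a genes x 5 matrix
#' over the union of their gene universes. Genes missing a feature are imputed
#' with that feature's minimum observed value (flagged). Each column is then
#' z-scored (population variance); a constant column is set to all zeros with
#' a warning, since its weight would be unidentifiable.
#'
#' @param mutation Per-gene mutation evidence (binary or mutation frequency),
#'   named numeric vector.
#' @param hubness Per-gene network degree (e.g. from [infer_hubness()]).
#' @param regulator Per-gene binary regulator annotation.
#' @param cnv,methylation Per-gene continuous scores.
#' @return A `driver_features` object: list with `gene_ids`, `feature_names`,
#'   `raw` and `standardized` genes x 5 matrices, `imputed` counts and
#'   `constant` flags.
#' @export
assemble_features <- function(mutation, hubness, regulator, cnv, methylation) {
  feats <- list(mutation = mutation, hubness = hubness, regulator = regulator,
                cnv = cnv, methylation = methylation)
  for (nm in names(feats)) {
    if (is.null(names(feats[[nm]]))) stop("feature '", nm, "' must be a named vector")
  }
  genes <- Reduce(union, lapply(feats, names))
  raw <- matrix(NA_real_, length(genes), 5L,
                dimnames = list(genes, DRIVER_FEATURES))
  imputed <- integer(5L)
  names(imputed) <- DRIVER_FEATURES
  for (j in seq_along(feats)) {
    v <- feats[[j]]
    raw[names(v), j] <- v
    miss <- is.na(raw[, j])
    imputed[j] <- sum(miss)
    if (any(miss)) raw[miss, j] <- min(v, na.rm = TRUE)
  }
  std <- standardize_features(raw)
  structure(list(gene_ids = genes, feature_names = DRIVER_FEATURES,
                 raw = raw, standardized = std, imputed = imputed,
                 constant = attr(std, "constant")),
            class = "driver_features")
}

#' Column-wise z-scoring with population variance
#'
#' Standardizes each column to mean 0, unit (population) variance. Constant
#' columns become all zeros with a warning. Idempotent: standardizing an
#' already-standardized matrix is a no-op to machine precision.
#'
#' @param m Numeric matrix (genes x features).
#' @return Matrix of the same shape; attribute `"constant"` flags zeroed
#'   columns.
#' @export
standardize_features <- function(m) {
  out <- m
  constant <- logical(ncol(m))
  names(constant) <- colnames(m)
  for (j in seq_len(ncol(m))) {
    mu <- mean(m[, j])
    s <- sqrt(mean((m[, j] - mu)^2))
    if (s == 0) {
      constant[j] <- TRUE
      out[, j] <- 0
    } else {
      out[, j] <- (m[, j] - mu) / s
    }
  }
  if (any(constant)) {
    warning("constant feature column(s) set to zero: ",
            paste(colnames(m)[constant], collapse = ", "))
  }
  attr(out, "constant") <- constant
  out
}
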