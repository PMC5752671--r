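# Evaluation statistics for marker robustness: the left-out consistency rate,
# per-gene drug-class specificity (DCS) with a drug-label permutation null,
# hierarchical-clustering class enrichment of the AUC matrix, class-specific
# conserved marker tables, and drug-response prediction scored by Spearman
# correlation with one-sided Wilcoxon signed-rank method comparisons.

#' Consistency rate of top-ranked associations in left-out data
#'
#' For each `N` in `N_grid`, takes the top `q x N` pairs (q = number of
#' drugs; "top N genes per drug on average") of a method's pair ranking,
#' intersects them with the discovery-significant set (genome-wide BH at
#' level `q_fdr`), and computes the fraction of those pairs that replicate in
#' the validation data: validation p-value below `replication_alpha` with the
#' same association sign. Pairs outside the shared gene/drug universe of the
#' two data sets are excluded first (validation platforms typically cover
#' fewer genes).
#'
#' @param ranking Data frame (`gene_id`, `drug_id`) in rank order, e.g. from
#'   [rank_pairs_by_method()].
#' @param discovery_assoc,validation_assoc `association_table`s from the
#'   discovery and validation data.
#' @param N_grid Integer vector of subset sizes.
#' @param q_fdr FDR level defining discovery significance (default 0.1).
#' @param replication_alpha Validation p-value threshold (default 0.05).
#' @return A `consistency_curve` data frame: `N`, `total`, `replicated`,
#'   `rate` (`NA` where `total` is 0).
#' @export
consistency_rate <- function(ranking, discovery_assoc, validation_assoc,
                             N_grid, q_fdr = 0.1, replication_alpha = 0.05) {
  stopifnot(inherits(discovery_assoc, "association_table"),
            inherits(validation_assoc, "association_table"))
  genes <- intersect(discovery_assoc$gene_ids, validation_assoc$gene_ids)
  drugs <- intersect(discovery_assoc$drug_ids, validation_assoc$drug_ids)
  if (length(genes) == 0L || length(drugs) == 0L) {
    stop("discovery and validation data share no genes or no drugs")
  }
  n_drugs <- length(discovery_assoc$drug_ids)

  sig <- bh_select(discovery_assoc, q = q_fdr)
  sig_key <- paste(sig$gene_id, sig$drug_id, sep = "\r")

  keep <- ranking$gene_id %in% genes & ranking$drug_id %in% drugs
  rk <- ranking[keep, , drop = FALSE]
  rk_key <- paste(rk$gene_id, rk$drug_id, sep = "\r")
  in_sig <- rk_key %in% sig_key

  vp <- validation_assoc$pval[cbind(match(rk$gene_id, validation_assoc$gene_ids),
                                    match(rk$drug_id, validation_assoc$drug_ids))]
  vr <- validation_assoc$r[cbind(match(rk$gene_id, validation_assoc$gene_ids),
                                 match(rk$drug_id, validation_assoc$drug_ids))]
  dr <- discovery_assoc$r[cbind(match(rk$gene_id, discovery_assoc$gene_ids),
                                match(rk$drug_id, discovery_assoc$drug_ids))]
  replicates <- !is.na(vp) & vp < replication_alpha &
    !is.na(vr) & !is.na(dr) & sign(vr) == sign(dr)

  out <- data.frame(N = as.integer(N_grid), total = NA_integer_,
                    replicated = NA_integer_, rate = NA_real_)
  for (k in seq_along(N_grid)) {
    budget <- min(n_drugs * N_grid[k], nrow(rk))
    head_idx <- seq_len(budget)
    tot <- sum(in_sig[head_idx])
    rep_n <- sum(in_sig[head_idx] & replicates[head_idx])
    out$total[k] <- tot
    out$replicated[k] <- rep_n
    out$rate[k] <- if (tot > 0L) rep_n / tot else NA_real_
  }
  class(out) <- c("consistency_curve", "data.frame")
  out
}

#' Per-class one-sided Fisher's exact p-values for an associated-drug set
#'
#' For each mechanism class, the hypergeometric upper-tail probability of the
#' observed overlap between a gene's associated drugs and the class, within
#' the active-drug universe. Multi-class drugs count in each of their classes.
#'
#' @param associated_drugs Character vector of drug IDs the gene is
#'   significantly associated with (non-empty subset of `universe`).
#' @param classes A `drug_class_annotation`.
#' @param universe Character vector: the active drug panel.
#' @return Named numeric vector of one-sided p-values, one per class present
#'   in the universe.
#' @export
class_fisher_p <- function(associated_drugs, classes, universe) {
  stopifnot(length(associated_drugs) >= 1L,
            all(associated_drugs %in% universe))
  M <- class_membership_matrix(classes, universe)
  K <- colSums(M)
  m <- length(associated_drugs)
  k <- colSums(M[associated_drugs, , drop = FALSE])
  U <- length(universe)
  p <- stats::phyper(k - 1, K, U - K, m, lower.tail = FALSE)
  names(p) <- colnames(M)
  p
}

#' Drug-class specificity (DCS) score of a gene
#'
#' `-log10` of the minimum one-sided Fisher's exact p-value over mechanism
#' classes: large when the gene's associated drugs concentrate in one class,
#' 0 when no class is enriched (e.g. the gene is associated with every drug).
#'
#' @inheritParams class_fisher_p
#' @return The DCS score (a non-negative scalar).
#' @export
dcs_score <- function(associated_drugs, classes, universe) {
  -log10(min(class_fisher_p(associated_drugs, classes, universe)))
}

# Vectorized DCS for a genes x drugs 0/1 association matrix. `M` is the
# drugs x classes membership matrix. Returns one score per row of A.
dcs_score_matrix <- function(A, M) {
  K <- colSums(M)
  U <- nrow(M)
  m <- rowSums(A)
  k <- A %*% M  # genes x classes overlaps
  p <- stats::phyper(k - 1, rep(K, each = nrow(A)), rep(U - K, each = nrow(A)),
                     m, lower.tail = FALSE)
  p <- matrix(p, nrow(A), ncol(M))
  -log10(apply(p, 1L, min))
}

#' Permutation test for drug-class specificity
#'
#' Shuffles the class-label assignment across drugs (each drug's class set
#' moves as a unit, preserving per-drug class counts), recomputes every
#' gene's DCS score per permutation, and reports per-gene empirical p-values
#' with add-one smoothing, plus a global p-value comparing the mean observed
#' DCS against the permuted means. `tie_break = "conservative"` (default)
#' counts permuted scores equal to the observed one in the exceedance count;
#' `"randomized"` splits ties uniformly at random, which makes the per-gene
#' p-values exactly uniform under exchangeability (used for calibration
#' checks on the discrete DCS statistic).
#'
#' @param gene_sets Named list (gene -> character vector of associated drugs)
#'   or a binary genes x drugs matrix. Genes with empty sets are excluded.
#' @param classes A `drug_class_annotation`.
#' @param universe Drug universe (default: all annotated drugs).
#' @param B Number of permutations (>= 100; default 1000).
#' @param seed Random seed; results are deterministic given the seed.
#' @param tie_break `"conservative"` or `"randomized"`.
#' @return List with `per_gene` (data frame `gene`, `dcs`, `empirical_p`),
#'   `global_p`, `B`, `seed`.
#' @export
dcs_permutation_test <- function(gene_sets, classes, universe = names(classes),
                                 B = 1000L, seed = 1L,
                                 tie_break = c("conservative", "randomized")) {
  tie_break <- match.arg(tie_break)
  stopifnot(B >= 100L)
  M <- class_membership_matrix(classes, universe)
  if (is.matrix(gene_sets)) {
    A <- (gene_sets[, universe, drop = FALSE] != 0) * 1
  } else {
    A <- matrix(0, length(gene_sets), length(universe),
                dimnames = list(names(gene_sets), universe))
    for (g in names(gene_sets)) A[g, gene_sets[[g]]] <- 1
  }
  nonempty <- rowSums(A) > 0
  if (!all(nonempty)) {
    warning(sum(!nonempty), " gene(s) with empty associated set excluded")
    A <- A[nonempty, , drop = FALSE]
  }
  obs <- dcs_score_matrix(A, M)

  set.seed(seed)
  n_gt <- numeric(nrow(A))
  n_eq <- numeric(nrow(A))
  perm_means <- numeric(B)
  for (b in seq_len(B)) {
    Mp <- M[sample(nrow(M)), , drop = FALSE]
    rownames(Mp) <- rownames(M)
    d <- dcs_score_matrix(A, Mp)
    n_gt <- n_gt + (d > obs + 1e-12)
    n_eq <- n_eq + (abs(d - obs) <= 1e-12)
    perm_means[b] <- mean(d)
  }
  if (tie_break == "conservative") {
    emp <- (1 + n_gt + n_eq) / (B + 1)
  } else {
    u <- stats::runif(nrow(A))
    emp <- (n_gt + u * (1 + n_eq)) / (B + 1)
  }
  global_p <- (1 + sum(perm_means >= mean(obs) - 1e-12)) / (B + 1)
  list(per_gene = data.frame(gene = rownames(A), dcs = obs, empirical_p = emp,
                             stringsAsFactors = FALSE, row.names = NULL),
       global_p = global_p, B = B, seed = seed)
}

#' Class-specific conserved marker table
#'
#' For each mechanism class, returns the high MERGE-scoring genes whose
#' patient-data associations are specific to the class (one-sided Fisher's
#' exact p below `alpha`) and conserved in the cell-line data (at least one
#' significant association with a drug of the class), ranked by MERGE score
#' with the top `top_per_class` retained.
#'
#' @param scores A `merge_scores` object.
#' @param patient_pairs,cellline_pairs `significant_pairs` data frames from
#'   [bh_select()] on the patient and cell-line associations (shared drug
#'   panel).
#' @param classes A `drug_class_annotation`.
#' @param universe Drug universe for the Fisher tests (default: the patient
#'   pair set's drug universe).
#' @param alpha Class-specificity threshold (default 0.05).
#' @param top_per_class Markers retained per class (default 3; `Inf` keeps
#'   all).
#' @return Data frame `class`, `gene`, `merge_score`, `class_p`,
#'   `conserved_drugs` (comma-separated).
#' @export
class_specific_markers <- function(scores, patient_pairs, cellline_pairs,
                                   classes, universe = NULL, alpha = 0.05,
                                   top_per_class = 3L) {
  stopifnot(inherits(scores, "merge_scores"))
  if (is.null(universe)) universe <- attr(patient_pairs, "drug_universe")
  if (is.null(universe)) stop("drug universe not available; pass `universe`")
  class_labels <- sort(unique(unlist(classes)))
  pat_sets <- split(patient_pairs$drug_id, patient_pairs$gene_id)
  cl_sets <- split(cellline_pairs$drug_id, cellline_pairs$gene_id)

  rows <- list()
  for (cl in class_labels) {
    members <- names(classes)[vapply(classes, function(x) cl %in% x, logical(1L))]
    members <- intersect(members, universe)
    if (length(members) == 0L) {
      warning("class '", cl, "' has no drugs in the universe; skipped")
      next
    }
    for (g in names(pat_sets)) {
      if (!(g %in% names(scores$m))) next
      pv <- class_fisher_p(pat_sets[[g]], classes, universe)
      if (!(cl %in% names(pv)) || pv[cl] >= alpha) next
      conserved <- intersect(intersect(cl_sets[[g]], members), universe)
      if (length(conserved) == 0L) next
      rows[[length(rows) + 1L]] <- data.frame(
        class = cl, gene = g, merge_score = unname(scores$m[g]),
        class_p = unname(pv[cl]),
        conserved_drugs = paste(sort(conserved), collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(class = character(0L), gene = character(0L),
                      merge_score = numeric(0L), class_p = numeric(0L),
                      conserved_drugs = character(0L)))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$class, -out$merge_score, out$gene), , drop = FALSE]
  if (is.finite(top_per_class)) {
    out <- do.call(rbind, lapply(split(out, out$class), utils::head,
                                 n = top_per_class))
  }
  rownames(out) <- NULL
  out
}

# Leaf sets of every internal node of an hclust tree, as a list of integer
# vectors of leaf indices.
hclust_node_leaves <- function(hc) {
  n <- length(hc$order)
  leaves <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    kids <- hc$merge[i, ]
    get <- function(k) if (k < 0) -k else leaves[[k]]
    leaves[[i]] <- c(get(kids[1L]), get(kids[2L]))
  }
  leaves
}

#' Drug-class enrichment in the AUC dendrogram
#'
#' Standardizes each drug's AUC row (mean 0, sd 1 across samples), clusters
#' drugs by agglomerative hierarchical clustering (average linkage, Euclidean
#' distance), and scans every internal dendrogram node of size 2..q-1 for
#' one-sided Fisher enrichment of each mechanism class with more than one
#' drug. A class counts as "clustered" if any node is enriched at
#' `enrichment_alpha`.
#'
#' @param Y Drug-response matrix, drugs x samples (>= 2 drugs).
#' @param classes A `drug_class_annotation`.
#' @param enrichment_alpha Fisher p-value cutoff (default 0.06).
#' @return Number of multi-drug classes enriched in some branch; the per-class
#'   best p-values are attached as attribute `"detail"`, the tree as
#'   `"hclust"`.
#' @export
cluster_class_enrichment <- function(Y, classes, enrichment_alpha = 0.06) {
  q <- nrow(Y)
  stopifnot(q >= 2L)
  sds <- apply(Y, 1L, stats::sd)
  Z <- Y
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant AUC row(s) left unstandardized")
  }
  ok <- sds > 0
  Z[ok, ] <- (Y[ok, , drop = FALSE] - rowMeans(Y[ok, , drop = FALSE])) / sds[ok]
  hc <- stats::hclust(stats::dist(Z), method = "average")
  nodes <- hclust_node_leaves(hc)
  nodes <- nodes[lengths(nodes) >= 2L & lengths(nodes) <= q - 1L]

  M <- class_membership_matrix(classes, rownames(Y))
  multi <- colSums(M) > 1L
  best_p <- stats::setNames(rep(1, sum(multi)), colnames(M)[multi])
  for (leaf_set in nodes) {
    m <- length(leaf_set)
    k <- colSums(M[leaf_set, multi, drop = FALSE])
    p <- stats::phyper(k - 1, colSums(M[, multi, drop = FALSE]),
                       q - colSums(M[, multi, drop = FALSE]), m,
                       lower.tail = FALSE)
    best_p <- pmin(best_p, p)
  }
  count <- sum(best_p <= enrichment_alpha)
  attr(count, "detail") <- best_p
  attr(count, "hclust") <- hc
  count
}

# Ridge regression with the penalty chosen by generalized cross-validation
# over a log-spaced grid, via the SVD of the centered design. Returns a
# prediction function. (No installed package offers GCV-tuned ridge with the
# predict interface needed here; glmnet tunes by CV folds instead.)
ridge_gcv <- function(X, y, lambdas = NULL) {
  n <- nrow(X)
  mx <- colMeans(X)
  my <- mean(y)
  Xc <- sweep(X, 2L, mx)
  yc <- y - my
  sv <- svd(Xc)
  d2 <- sv$d^2
  if (is.null(lambdas)) {
    scale <- max(d2, 1)
    lambdas <- scale * 10^seq(-6, 2, length.out = 40L)
  }
  uty <- drop(crossprod(sv$u, yc))
  best <- NULL
  best_gcv <- Inf
  for (lam in lambdas) {
    shrink <- d2 / (d2 + lam)
    fitted <- drop(sv$u %*% (shrink * uty))
    eff_df <- sum(shrink)
    rss <- sum((yc - fitted)^2)
    gcv <- n * rss / (n - eff_df)^2
    if (is.finite(gcv) && gcv < best_gcv) { best_gcv <- gcv; best <- lam }
  }
  shrink <- sv$d / (d2 + best)
  beta <- drop(sv$v %*% (shrink * uty))
  list(lambda = best,
       predict = function(newX) drop(sweep(as.matrix(newX), 2L, mx) %*% beta) + my)
}

#' Predict drug response in held-out samples
#'
#' Per-drug predictors trained on `(train_X, train_Y)` and applied to
#' `test_X`. `"merge"` takes, for each drug, the `genes_per_drug` genes with
#' the highest MERGE scores among those whose training-data association
#' p-value is below `alpha_screen` for that drug (falling back to the top
#' genes by training p-value when none pass) and fits ridge regression with
#' the penalty chosen by generalized cross-validation. `"ridge"` is the same
#' without prioritization (all genes). `"elasticnet"` fits a per-drug elastic
#' net (mixing 0.5, seeded CV). `"multitask"` is a shared-support
#' approximation: one gene support chosen by aggregate association evidence
#' across all drugs, then per-drug ridge on it. Drugs with constant training
#' response are predicted at the training mean and flagged.
#'
#' @param train_X,train_Y Aligned training expression and response matrices.
#' @param test_X Expression for the held-out samples (gene universes are
#'   intersected).
#' @param model A fitted `merge_model` (required for `"merge"`).
#' @param D The `driver_features` used for the fit (required for `"merge"`).
#' @param method Predictor family.
#' @param genes_per_drug Number of genes per drug (default 10; `Inf` = all).
#' @param alpha_screen Training association screen (default 0.05).
#' @param seed Seed for elastic-net CV folds.
#' @return Matrix drugs x test samples of predicted response; attribute
#'   `"flagged"` lists drugs predicted at the training mean.
#' @export
predict_response <- function(train_X, train_Y, test_X, model = NULL, D = NULL,
                             method = c("merge", "ridge", "elasticnet",
                                        "multitask"),
                             genes_per_drug = 10L, alpha_screen = 0.05,
                             seed = 1L) {
  method <- match.arg(method)
  assert_aligned(train_X, train_Y)
  if (ncol(train_X) < 5L) stop("need at least 5 training samples")
  genes <- intersect(rownames(train_X), rownames(test_X))
  if (length(genes) == 0L) stop("train and test share no genes")
  train_X <- train_X[genes, , drop = FALSE]
  test_X <- test_X[genes, , drop = FALSE]

  assoc <- pairwise_association(train_X, train_Y)
  m_scores <- NULL
  if (method == "merge") {
    if (is.null(model) || is.null(D)) {
      stop("method 'merge' needs a fitted model and its driver features")
    }
    m_scores <- merge_scores(model, D)$m
    m_scores <- m_scores[intersect(names(m_scores), genes)]
  }
  shared_support <- NULL
  if (method == "multitask") {
    evidence <- rowMeans(-log10(pmax(assoc$pval, .Machine$double.xmin)),
                         na.rm = TRUE)
    k <- min(if (is.finite(genes_per_drug)) genes_per_drug else length(genes),
             length(genes))
    shared_support <- names(sort(evidence, decreasing = TRUE))[seq_len(k)]
  }

  drugs <- rownames(train_Y)
  pred <- matrix(NA_real_, length(drugs), ncol(test_X),
                 dimnames = list(drugs, colnames(test_X)))
  flagged <- character(0L)
  for (j in seq_along(drugs)) {
    y <- train_Y[j, ]
    if (stats::sd(y) == 0) {
      pred[j, ] <- mean(y)
      flagged <- c(flagged, drugs[j])
      next
    }
    sel <- switch(method,
      merge = {
        pv <- assoc$pval[, j]
        cand <- names(pv)[!is.na(pv) & pv < alpha_screen]
        cand <- intersect(cand, names(m_scores))
        if (length(cand) == 0L) {
          cand <- names(sort(pv))[seq_len(min(if (is.finite(genes_per_drug))
            genes_per_drug else length(genes), length(genes)))]
        }
        k <- min(if (is.finite(genes_per_drug)) genes_per_drug else
          length(cand), length(cand))
        ord <- if (length(intersect(cand, names(m_scores)))) {
          names(sort(m_scores[intersect(cand, names(m_scores))],
                     decreasing = TRUE))
        } else cand
        ord[seq_len(min(k, length(ord)))]
      },
      ridge = genes,
      multitask = shared_support,
      elasticnet = genes)
    if (length(sel) == 0L) {
      pred[j, ] <- mean(y)
      flagged <- c(flagged, drugs[j])
      next
    }
    if (method == "elasticnet") {
      set.seed(seed + j)
      cv <- glmnet::cv.glmnet(t(train_X), y, alpha = 0.5,
                              nfolds = min(5L, ncol(train_X)))
      pred[j, ] <- drop(stats::predict(cv, newx = t(test_X), s = "lambda.min"))
    } else {
      fit <- ridge_gcv(t(train_X[sel, , drop = FALSE]), y)
      pred[j, ] <- fit$predict(t(test_X[sel, , drop = FALSE]))
    }
  }
  attr(pred, "flagged") <- flagged
  pred
}

#' Per-drug Spearman prediction report
#'
#' Spearman rank correlation between predicted and actual held-out response,
#' per drug, plus the mean over drugs with a defined correlation (constant
#' actual response gives `NA`).
#'
#' @param predicted,actual Drugs x samples matrices with matching dimnames.
#' @return A `prediction_report`: list with `per_drug` (named rho vector) and
#'   `mean_rho`.
#' @export
prediction_report <- function(predicted, actual) {
  stopifnot(identical(rownames(predicted), rownames(actual)),
            identical(colnames(predicted), colnames(actual)))
  rho <- vapply(seq_len(nrow(actual)), function(j) {
    if (stats::sd(actual[j, ]) == 0 || stats::sd(predicted[j, ]) == 0) {
      return(NA_real_)
    }
    suppressWarnings(stats::cor(predicted[j, ], actual[j, ],
                                method = "spearman"))
  }, numeric(1L))
  names(rho) <- rownames(actual)
  structure(list(per_drug = rho, mean_rho = mean(rho, na.rm = TRUE)),
            class = "prediction_report")
}

#' One-sided Wilcoxon signed-rank comparison of two prediction reports
#'
#' Tests whether method A's per-drug Spearman correlations exceed method B's
#' (alternative "greater") by the exact signed-rank test over the shared drug
#' set; zero differences are dropped, and if all differences are zero the
#' p-value is 1.
#'
#' @param report_a,report_b `prediction_report`s (or named rho vectors) over
#'   the same drugs (>= 6).
#' @return One-sided p-value.
#' @export
compare_methods <- function(report_a, report_b) {
  a <- if (inherits(report_a, "prediction_report")) report_a$per_drug else report_a
  b <- if (inherits(report_b, "prediction_report")) report_b$per_drug else report_b
  stopifnot(identical(names(a), names(b)))
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 6L) stop("need >= 6 drugs with defined correlations")
  d <- a - b
  if (all(d == 0)) return(1)
  suppressWarnings(
    stats::wilcox.test(a, b, paired = TRUE, alternative = "greater")$p.value)
}
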