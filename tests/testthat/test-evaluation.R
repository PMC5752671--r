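# -- consistency rate --------------------------------------------------------

test_that("consistency rate is 1 when validation data equal discovery data", {
  dat <- generate_dataset(p = 150L, q = 8L, n = 25L, seed = 41L)
  assoc <- pairwise_association(dat$X, dat$Y)
  rk <- rank_pairs_by_method("pearson", dat$X, dat$Y, assoc = assoc)
  cc <- consistency_rate(rk, assoc, assoc, N_grid = c(1L, 5L, 20L, 150L))
  ok <- cc$total > 0
  expect_true(any(ok))
  # every discovery-significant pair trivially has p < .05 and matching sign
  expect_true(all(cc$rate[ok] == 1))
  expect_true(all(diff(cc$total) >= 0))
})

test_that("consistency rate matches hand enumeration on a tiny example", {
  genes <- paste0("g", 1:4); drugs <- "d1"; samples <- paste0("s", 1:10)
  fake_assoc <- function(pv, r) {
    structure(list(gene_ids = genes, drug_ids = drugs,
                   r = matrix(r, 4, 1, dimnames = list(genes, drugs)),
                   t = matrix(0, 4, 1), n_used = matrix(10, 4, 1),
                   pval = matrix(pv, 4, 1, dimnames = list(genes, drugs)),
                   z = matrix(0, 4, 1), df = 8, method = "pearson",
                   n_covariates = 0L),
              class = "association_table")
  }
  # all four pairs BH-significant at q=0.1; two replicate (p<0.05, same sign)
  disc <- fake_assoc(c(0.001, 0.002, 0.003, 0.004), c(1, 1, -1, -1))
  val <- fake_assoc(c(0.01, 0.20, 0.01, 0.01), c(1, 1, -1, 1))
  rk <- data.frame(gene_id = genes, drug_id = drugs)
  cc <- consistency_rate(rk, disc, val, N_grid = 4L)
  expect_identical(cc$total, 4L)
  expect_identical(cc$replicated, 2L)  # g2 fails p, g4 fails sign
  expect_equal(cc$rate, 0.5)
})

test_that("rank-based consistency is invariant to monotone response maps", {
  dat <- generate_dataset(p = 100L, q = 6L, n = 20L, seed = 44L)
  rep1 <- generate_validation_replicate(dat$truth, 20L, 0.8, seed = 45L)
  disc <- pairwise_association(dat$X, dat$Y, rank_based = TRUE)
  rk <- rank_pairs_by_method("spearman", dat$X, dat$Y, assoc = disc)
  v1 <- pairwise_association(rep1$X, rep1$Y, rank_based = TRUE)
  Y2 <- rep1$Y^3  # strictly monotone transform preserving sign
  v2 <- pairwise_association(rep1$X, Y2, rank_based = TRUE)
  g <- c(1L, 5L, 20L)
  expect_equal(consistency_rate(rk, disc, v1, g)$rate,
               consistency_rate(rk, disc, v2, g)$rate)
})

# -- DCS ---------------------------------------------------------------------

test_that("dcs_score matches hypergeometric enumeration exactly", {
  # universe of 53 drugs, one class of 4; a gene hitting exactly that class
  drugs <- sprintf("d%02d", 1:53)
  ann <- structure(c(lapply(drugs[1:4], function(d) "target"),
                     lapply(drugs[5:53], function(d) "other")),
                   class = "drug_class_annotation")
  names(ann) <- drugs
  expect_equal(dcs_score(drugs[1:4], ann, drugs),
               -log10(1 / choose(53, 4)), tolerance = 1e-10)
  # a singleton class hit by a single-drug association: p = 1/53
  ann2 <- ann; ann2[["d01"]] <- "solo"
  expect_equal(min(class_fisher_p("d01", ann2, drugs)), 1 / 53,
               tolerance = 1e-12)
  # association with every drug: no specificity
  expect_equal(dcs_score(drugs, ann, drugs), 0, tolerance = 1e-12)
})

test_that("dcs_score equals brute-force enumeration on small universes", {
  # exhaustive oracle: enumerate all subsets of the class with dhyper sums
  set.seed(3)
  drugs <- paste0("d", 1:12)
  ann <- structure(lapply(seq_along(drugs), function(i)
    c("A", "B", "C")[1L + (i %% 3L)]), class = "drug_class_annotation")
  names(ann) <- drugs
  for (rep in 1:10) {
    m <- sample(1:6, 1L)
    assoc_set <- sample(drugs, m)
    got <- dcs_score(assoc_set, ann, drugs)
    oracle <- -log10(min(vapply(c("A", "B", "C"), function(cl) {
      members <- names(ann)[vapply(ann, function(x) cl %in% x, logical(1L))]
      K <- length(members); k <- length(intersect(assoc_set, members))
      sum(dhyper(k:min(K, m), K, 12 - K, m))
    }, numeric(1L))))
    expect_equal(got, oracle, tolerance = 1e-10)
  }
})

test_that("dcs permutation test is seed-deterministic with a resolution floor", {
  drugs <- sprintf("d%02d", 1:20)
  ann <- structure(as.list(rep(c("a", "b", "c", "d"), each = 5L)),
                   class = "drug_class_annotation")
  names(ann) <- drugs
  sets <- list(gene1 = drugs[1:5],    # exactly one intact class
               gene2 = drugs[c(1, 6, 11, 16)])  # maximally unspecific
  r1 <- dcs_permutation_test(sets, ann, B = 200L, seed = 7L)
  r2 <- dcs_permutation_test(sets, ann, B = 200L, seed = 7L)
  r3 <- dcs_permutation_test(sets, ann, B = 200L, seed = 8L)
  expect_identical(r1$per_gene, r2$per_gene)
  expect_false(identical(r1$per_gene$empirical_p, r3$per_gene$empirical_p))
  # an intact-class gene sits at the permutation resolution floor
  expect_equal(r1$per_gene$empirical_p[1L], 1 / 201, tolerance = 1e-12)
  expect_gt(r1$per_gene$empirical_p[2L], 0.5)
  expect_true(all(r1$per_gene$empirical_p > 0 & r1$per_gene$empirical_p <= 1))
})

# -- class-specific markers --------------------------------------------------

test_that("class_specific_markers applies specificity and conservation", {
  dat <- generate_dataset(p = 120L, q = 12L, n = 25L, seed = 13L)
  assoc <- pairwise_association(dat$X, dat$Y)
  m <- fit_merge(assoc, dat$D, seed = 13L)
  sc <- merge_scores(m, dat$D)
  pat <- bh_select(assoc, q = 0.3)
  # a faithful replicate supplies the conservation evidence
  rep1 <- generate_validation_replicate(dat$truth, 25L, 1, seed = 14L)
  cl <- bh_select(pairwise_association(rep1$X, rep1$Y), q = 0.3)

  tab <- suppressWarnings(
    class_specific_markers(sc, pat, cl, dat$classes, alpha = 0.05))
  if (nrow(tab)) {
    expect_true(all(tab$class_p < 0.05))
    expect_true(all(table(tab$class) <= 3L))
    # every reported marker really is conserved: its drugs are in the
    # cell-line pair set
    for (i in seq_len(nrow(tab))) {
      ds <- strsplit(tab$conserved_drugs[i], ",")[[1L]]
      expect_true(all(paste(tab$gene[i], ds) %in%
                        paste(cl$gene_id, cl$drug_id)))
    }
  }

  # empty cell-line pairs: the conservation filter empties every class
  empty <- cl[0L, , drop = FALSE]
  attr(empty, "drug_universe") <- attr(cl, "drug_universe")
  tab0 <- suppressWarnings(
    class_specific_markers(sc, pat, empty, dat$classes))
  expect_identical(nrow(tab0), 0L)

  # relaxing both filters returns every gene with a conserved association
  tab_all <- suppressWarnings(
    class_specific_markers(sc, pat, cl, dat$classes, alpha = 1,
                           top_per_class = Inf))
  expect_gte(nrow(tab_all), nrow(tab))
})

# -- clustering enrichment ---------------------------------------------------

test_that("two identical-response drug blocks are both enriched", {
  set.seed(31)
  n <- 20L
  base1 <- rnorm(n); base2 <- rnorm(n)
  Y <- rbind(matrix(rep(base1, 3), 3, byrow = TRUE) + rnorm(3 * n, 0, 0.05),
             matrix(rep(base2, 3), 3, byrow = TRUE) + rnorm(3 * n, 0, 0.05))
  dimnames(Y) <- list(paste0("d", 1:6), paste0("s", 1:n))
  ann <- structure(as.list(rep(c("c1", "c2"), each = 3L)),
                   class = "drug_class_annotation")
  names(ann) <- rownames(Y)
  cnt <- cluster_class_enrichment(Y, ann)
  expect_equal(as.integer(cnt), 2L)
  # exhaustive-node oracle on the same fixture
  detail <- attr(cnt, "detail")
  expect_true(all(detail <= 0.06))
})

test_that("cluster enrichment matches manual node enumeration and degrades
           under label shuffling", {
  set.seed(32)
  n <- 15L
  base <- rnorm(n)
  Y <- rbind(matrix(rep(base, 3), 3, byrow = TRUE) + rnorm(3 * n, 0, 0.1),
             matrix(rnorm(3 * n), 3, n))
  dimnames(Y) <- list(paste0("d", 1:6), paste0("s", 1:n))
  ann <- structure(as.list(rep(c("c1", "c2"), each = 3L)),
                   class = "drug_class_annotation")
  names(ann) <- rownames(Y)
  cnt <- cluster_class_enrichment(Y, ann)

  # manual enumeration over the same dendrogram
  Z <- t(scale(t(Y)))
  hc <- hclust(dist(Z), method = "average")
  merges <- list()
  for (i in 1:5) {
    kids <- hc$merge[i, ]
    get <- function(k) if (k < 0) -k else merges[[k]]
    merges[[i]] <- c(get(kids[1]), get(kids[2]))
  }
  manual <- 0L
  for (cl in c("c1", "c2")) {
    members <- which(unlist(ann) == cl)
    pbest <- 1
    for (s in merges[lengths(merges) <= 5]) {
      k <- length(intersect(s, members))
      pbest <- min(pbest, phyper(k - 1, 3, 3, length(s), lower.tail = FALSE))
    }
    if (pbest <= 0.06) manual <- manual + 1L
  }
  expect_identical(as.integer(cnt), manual)

  # shuffling class labels lowers the expected count
  shuf <- vapply(1:25, function(s) {
    set.seed(100 + s)
    ann_s <- ann
    names(ann_s) <- sample(names(ann))
    as.integer(cluster_class_enrichment(Y, ann_s))
  }, integer(1L))
  expect_lt(mean(shuf), as.integer(cnt) + 0.5)
})

# -- prediction --------------------------------------------------------------

test_that("prediction is exact on noiseless linear truth and reduces to ridge", {
  set.seed(51)
  n <- 20L
  X <- matrix(rnorm(40 * n), 40, n,
              dimnames = list(paste0("g", 1:40), paste0("s", 1:n)))
  Y <- rbind(d1 = 0.6 * X[3, ] - 0.4 * X[7, ], d2 = X[1, ])
  colnames(Y) <- colnames(X)
  pred <- predict_response(X, Y, X, method = "ridge")
  rep_ <- prediction_report(pred, Y)
  expect_true(all(rep_$per_drug > 0.999))

  # merge with genes_per_drug = all and no screen equals plain ridge
  dat <- generate_dataset(p = 40L, q = 3L, n = 20L, seed = 52L)
  assoc <- pairwise_association(dat$X, dat$Y)
  model <- fit_merge(assoc, dat$D, seed = 52L)
  p1 <- predict_response(dat$X, dat$Y, dat$X, model = model, D = dat$D,
                         method = "merge", genes_per_drug = Inf,
                         alpha_screen = 1 + 1e-9)
  p2 <- predict_response(dat$X, dat$Y, dat$X, method = "ridge")
  expect_equal(unclass(p1), unclass(p2), tolerance = 1e-6,
               ignore_attr = TRUE)

  # constant training response is flagged and predicted at the mean
  Yc <- Y; Yc[2, ] <- 0.4
  pc <- suppressWarnings(predict_response(X, Yc, X, method = "ridge"))
  expect_true("d2" %in% attr(pc, "flagged"))
  expect_true(all(pc["d2", ] == 0.4))
  rc <- prediction_report(pc, Yc)
  expect_true(is.na(rc$per_drug["d2"]))
})

test_that("compare_methods gives exact signed-rank tails", {
  a <- setNames(seq(0.2, 0.9, length.out = 8L), paste0("d", 1:8))
  set.seed(2)
  b <- a - runif(8L, 0.01, 0.2)  # distinct differences keep the test exact
  expect_equal(compare_methods(a, b), 1 / 2^8, tolerance = 1e-12)
  expect_equal(compare_methods(a, a), 1)
  # antisymmetry: reversing the comparison flips to the complementary tail
  expect_gt(compare_methods(b, a), 1 - 2 / 2^8 - 1e-9)
})
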