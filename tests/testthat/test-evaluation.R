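test_that("folds stratify positives with near-equal counts", {
  g <- sprintf("g%03d", 1:100)
  m20 <- mods_of(g[1:20])
  fa <- make_folds(m20, g, folds = 5, repeats = 2, seed = 3)
  for (r in 1:2) {
    cnt <- table(fa$fold_index[fa$repeat_index == r])
    expect_equal(unname(c(cnt)), rep(4L, 5), ignore_attr = TRUE)
  }
  # 22 positives over 5 folds: sizes {5,5,4,4,4}
  m22 <- mods_of(g[1:22])
  fa22 <- make_folds(m22, g, folds = 5, repeats = 1, seed = 3)
  expect_equal(sort(unname(c(table(fa22$fold_index)))), c(4L, 4L, 4L, 5L, 5L))
  # partition property: folds are disjoint and cover the module
  genes_seen <- sort(fa22$gene)
  expect_equal(genes_seen, sort(g[1:22]))
})

test_that("fold assignment is reproducible and validates inputs", {
  g <- sprintf("g%03d", 1:50)
  mods <- mods_of(g[1:20], g[21:45])
  fa1 <- make_folds(mods, g, folds = 5, repeats = 3, seed = 11)
  fa2 <- make_folds(mods, g, folds = 5, repeats = 3, seed = 11)
  expect_identical(fa1, fa2)
  expect_false(identical(fa1,
                         make_folds(mods, g, folds = 5, repeats = 3, seed = 12)))
  tiny <- mods_of(g[1:3])
  expect_error(make_folds(tiny, g, folds = 5), "M01")
})

test_that("precision at recall follows the step-function convention", {
  # perfect ranking: precision 1 everywhere
  r1 <- precision_at_recall(c("p1", "p2", "n1", "n2"), c("p1", "p2"))
  expect_equal(unname(r1), rep(1, 10))
  # interleaved: recall 0.5 at cutoff 1 (prec 1), recall 1.0 at cutoff 3 (2/3)
  r2 <- precision_at_recall(c("p1", "n1", "p2", "n2"), c("p1", "p2"),
                            levels = c(0.5, 1.0))
  expect_equal(unname(r2), c(1, 2/3))
  # positives last: recall 0.5 at cutoff 3 (1/3), recall 1.0 at cutoff 4 (1/2)
  r3 <- precision_at_recall(c("n1", "n2", "p1", "p2"), c("p1", "p2"),
                            levels = c(0.5, 1.0))
  expect_equal(unname(r3), c(1/3, 1/2))
  expect_error(precision_at_recall(c("a", "b"), character(0)), "empty")
  expect_error(precision_at_recall(c("a", "b"), "c"), "missing")
})

test_that("AUC uses the tie-averaged rank-sum formulation", {
  s <- c(a = 0.9, b = 0.8, c = 0.7, d = 0.6)
  expect_equal(auc_score(s, c("a", "b")), 1)           # perfect separation
  expect_equal(auc_score(s, c("a", "c")), 3/4)         # 3 of 4 pairs ordered
  expect_equal(auc_score(c(a = 1, b = 1, c = 1), "a"), 0.5)  # all tied
  expect_error(auc_score(s, c("a", "b", "c", "d")), "no negatives")
  expect_error(auc_score(s, character(0)), "no positives")
})

test_that("AUC equals brute-force pair counting on random score vectors", {
  set.seed(808)
  for (i in 1:40) {
    n <- sample(10:200, 1)
    scores <- round(runif(n), sample(1:3, 1))  # rounding induces ties
    names(scores) <- sprintf("c%03d", seq_len(n))
    npos <- sample(1:(n - 1), 1)
    pos <- sample(names(scores), npos)
    expect_equal(auc_score(scores, pos), brute_auc(scores, pos))
  }
})

test_that("cross-validation recovers a perfectly planted clique", {
  # 20-clique module plus a background ring with no cross edges: every
  # held-out positive is adjacent to training positives and no negative is
  genes <- sprintf("g%03d", 1:100)
  W <- matrix(0, 100, 100, dimnames = list(genes, genes))
  W[1:20, 1:20] <- 1; diag(W) <- 0
  for (i in 21:100) {
    j <- if (i == 100) 21 else i + 1
    W[i, j] <- W[j, i] <- 1
  }
  net <- gene_network(W, genes)
  mods <- module_collection(list(gene_module("CLIQUE", genes[1:20])))
  res <- run_cv(net, mods, "SNN", params = list(q = 1),
                folds = 5, repeats = 1, seed = 4)
  aucs <- res$records$value[res$records$metric == "auc"]
  expect_equal(aucs, rep(1, 5))
})

test_that("degenerate propagation gives chance-level ranking", {
  cfg <- synthetic_config(n_genes = 80, module_sizes = 20, p_in = 0.4,
                          p_out = 0.05, seed = 6)
  g <- generate_network(cfg)
  res <- run_cv(g$network, g$modules, "zhou", params = list(alpha = 1),
                folds = 5, repeats = 1, seed = 6)
  # with alpha = 1 every candidate keeps score 0: all ties, AUC 0.5
  aucs <- res$records$value[res$records$metric == "auc"]
  expect_equal(aucs, rep(0.5, 5))
})

test_that("identical seeds give byte-identical evaluation TSVs", {
  cfg <- synthetic_config(n_genes = 120, module_sizes = c(20, 24),
                          seed = 8)
  g <- generate_network(cfg)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  r1 <- run_cv(g$network, g$modules, "SKNN", folds = 5, repeats = 2, seed = 9)
  r2 <- run_cv(g$network, g$modules, "SKNN", folds = 5, repeats = 2, seed = 9)
  write_evaluation(r1, f1); write_evaluation(r2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(r1$records, r2$records)
})

test_that("per-module summaries aggregate folds then repeats", {
  cfg <- synthetic_config(n_genes = 120, module_sizes = c(20, 24), seed = 8)
  g <- generate_network(cfg)
  res <- run_cv(g$network, g$modules, "SAV", folds = 5, repeats = 2, seed = 9)
  ma <- module_auc(res)
  expect_equal(names(ma), c("M01", "M02"))
  a <- res$records[res$records$metric == "auc", ]
  expect_equal(unname(ma["M01"]), mean(a$value[a$module_id == "M01"]))
  expect_equal(mean_auc(res), mean(ma))
  expect_true(mean_precision_at(res, 0.2) >= 0 && mean_precision_at(res, 0.2) <= 1)
  expect_error(mean_precision_at(res, 0.33), "not in the result grid")
})

test_that("method comparison reports Wilcoxon tests and cardinality groups", {
  cfg <- synthetic_config(n_genes = 150, module_sizes = c(20, 25, 30), seed = 10)
  g <- generate_network(cfg)
  K <- q_step_rw_kernel(g$network, q = 2)
  r1 <- run_cv(g$network, g$modules, "SKNN", folds = 5, repeats = 1, seed = 10,
               kernel = K)
  r2 <- run_cv(g$network, g$modules, "SAV", folds = 5, repeats = 1, seed = 10,
               kernel = K)
  cmp <- compare_methods(list(r1, r2))
  expect_equal(nrow(cmp$wilcoxon), 1L)
  expect_true(cmp$wilcoxon$p_value >= 0 && cmp$wilcoxon$p_value <= 1)
  # a result compared with itself: all differences zero, p = 1 by convention
  cmp_self <- compare_methods(list(r1, r1))
  expect_equal(cmp_self$wilcoxon$p_value, 1)
  # one row per occupied cardinality group per method
  expect_equal(sort(unique(cmp$by_cardinality$group)), "20-100")
  expect_equal(nrow(cmp$by_cardinality), 2L)
  expect_true(all(c("n_modules", "mean_auc", "mean_precision") %in%
                    names(cmp$by_cardinality)))
  # different module sets are rejected
  g2 <- generate_network(synthetic_config(n_genes = 150,
                                          module_sizes = c(20, 25), seed = 10))
  r3 <- run_cv(g2$network, g2$modules, "SAV", folds = 5, repeats = 1, seed = 10)
  expect_error(compare_methods(list(r1, r3)), "different module sets")
})

test_that("a consistent AUC shift is detected with growing module count", {
  # synthetic per-module AUC tables fed straight into the comparison
  make_res <- function(aucs, method) {
    n <- length(aucs)
    ids <- sprintf("M%03d", seq_len(n))
    structure(list(
      records = data.frame(module_id = ids, method = method, repeat_index = 1,
                           fold_index = 1, metric = "auc", level = NA,
                           value = aucs, stringsAsFactors = FALSE),
      method = method,
      module_sizes = stats::setNames(rep(50L, n), ids),
      folds = 1, repeats = 1, seed = 1,
      params = list()), class = "evaluation_result")
  }
  set.seed(17)
  pvals <- vapply(c(10, 50, 100), function(n) {
    base <- runif(n, 0.6, 0.9)
    cmp <- compare_methods(list(make_res(pmin(base + 0.01, 1), "A"),
                                make_res(base, "B")),
                           precision_level = NA)
    cmp$wilcoxon$p_value
  }, numeric(1))
  expect_true(all(diff(pvals) < 0))
  expect_lt(pvals[3], 0.001)
})
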