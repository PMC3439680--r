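#' Stratified cross-validation folds for module positives
#'
#' Partitions each module's positive genes into `folds` test folds, repeated
#' `repeats` times. Only positives are partitioned: in the ranking task the
#' remaining genes carry no labels and are always available as candidates.
#' Fold positive counts differ by at most one (stratification). The
#' assignment is a deterministic function of `(seed, repeat_index)` and the
#' collection's module order, so any fold can be reconstructed exactly.
#'
#' @param modules a `module_collection` (every module needs at least `folds`
#'   members).
#' @param universe gene universe (recorded; members must be contained in it
#'   when provided).
#' @param folds number of folds (default 5).
#' @param repeats number of repetitions (default 5).
#' @param seed integer seed.
#' @return object of class `fold_assignment`: a data frame with columns
#'   `module_id`, `repeat_index`, `fold_index`, `gene`, plus attributes
#'   `folds`, `repeats`, `seed`.
#' @export
make_folds <- function(modules, universe = NULL, folds = 5, repeats = 5, seed = 1L) {
  stopifnot(folds >= 2, repeats >= 1)
  for (m in modules$modules) {
    if (length(m$members) < folds)
      stop("module '", m$module_id, "' has fewer positives (",
           length(m$members), ") than folds (", folds, ")")
    if (!is.null(universe) && length(setdiff(m$members, universe)) > 0)
      stop("module '", m$module_id, "' has members outside the universe")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  out <- vector("list", repeats * length(modules$modules))
  idx <- 0L
  for (r in seq_len(repeats)) {
    # one reproducible stream per repeat; kept below 2^31
    set.seed(as.integer((seed + 7919 * r) %% 2147483647L))
    for (m in modules$modules) {
      mem <- sort(m$members)
      perm <- sample(mem)
      fold <- rep_len(seq_len(folds), length(mem))
      idx <- idx + 1L
      out[[idx]] <- data.frame(module_id = m$module_id, repeat_index = r,
                               fold_index = fold, gene = perm,
                               stringsAsFactors = FALSE)
    }
  }
  fa <- do.call(rbind, out)
  rownames(fa) <- NULL
  structure(fa, folds = folds, repeats = repeats, seed = seed,
            class = c("fold_assignment", "data.frame"))
}

#' Precision at fixed recall levels
#'
#' For each recall level `r`, finds the smallest ranking cutoff whose recall
#' (fraction of test positives retrieved) is at least `r`, and reports the
#' precision `TP / cutoff` there. No interpolation is applied (step-function
#' convention).
#'
#' @param ranked character vector of genes, best first.
#' @param test_positives gene set to be retrieved (must be contained in
#'   `ranked`).
#' @param levels recall levels in (0, 1]; default 0.1 to 1.0 by 0.1.
#' @return named numeric vector, one precision per level.
#' @export
precision_at_recall <- function(ranked, test_positives,
                                levels = seq(0.1, 1, by = 0.1)) {
  test_positives <- unique(as.character(test_positives))
  if (length(test_positives) == 0) stop("test_positives is empty")
  if (length(setdiff(test_positives, ranked)) > 0)
    stop("test positives missing from the ranking")
  stopifnot(all(levels > 0), all(levels <= 1))
  hits <- ranked %in% test_positives
  tp <- cumsum(hits)
  rec <- tp / length(test_positives)
  prec <- tp / seq_along(ranked)
  out <- vapply(levels, function(lv) {
    cut <- which(rec >= lv - 1e-12)[1]
    prec[cut]
  }, numeric(1))
  stats::setNames(out, formatC(levels, format = "g"))
}

#' Area under the ROC curve
#'
#' Rank-sum (Mann-Whitney) formulation: the probability that a random
#' positive outscores a random negative, with tied scores receiving average
#' ranks (so an uninformative constant scoring yields 0.5).
#'
#' @param scores a `score_vector` or named numeric vector.
#' @param positives positive gene set; all other scored genes count as
#'   negatives.
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(scores, positives) {
  s <- if (inherits(scores, "score_vector")) scores$scores else scores
  if (is.null(names(s))) stop("scores must be named by gene")
  pos <- names(s) %in% .as_members(positives)
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0) stop("no positives among the scored genes")
  if (n0 == 0) stop("no negatives among the scored genes")
  r <- rank(s, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @keywords internal
.cardinality_group <- function(size) {
  cut(size, breaks = c(-Inf, 100, 200, 300, Inf),
      labels = c("20-100", "101-200", "201-300", "301+"))
}

#' @keywords internal
# score the candidate set for one training-positive set with one method
.score_fold <- function(method, train_pos, candidates, kernel = NULL,
                        norm_net = NULL, params = list()) {
  a <- if (is.null(params$alpha)) 0.5 else params$alpha
  k <- if (is.null(params$k)) 27 else params$k
  switch(method,
    SAV = score_av(kernel, train_pos, candidates)$scores,
    SNN = score_nn(kernel, train_pos, candidates)$scores,
    SKNN = score_knn(kernel, train_pos, candidates, k = k)$scores,
    zhou = {
      y0 <- label_vector(norm_net$genes, train_pos, "binary01")
      zhou_solve(norm_net, y0, alpha = a)$scores[candidates]
    },
    genemania = genemania_solve(norm_net, train_pos, alpha = a)$scores[candidates],
    labelprop = {
      y0 <- label_vector(norm_net$genes, train_pos, "binary01")
      labelprop_solve(norm_net, y0, clamp_set = train_pos)$scores[candidates]
    },
    stop("unknown method: ", method))
}

#' Run repeated stratified cross-validation for one ranking method
#'
#' For every module, repeat and fold: the module's positives outside the test
#' fold are the training labels; the candidate set is the held-out test
#' positives plus every gene never labeled positive for that module (training
#' positives are excluded — they would trivially rank on top). Candidates are
#' ranked by the requested method and precision-at-recall plus AUC are
#' recorded. Kernel construction and network normalization happen once, before
#' any fold, since neither uses labels.
#'
#' @param net a `gene_network` (raw adjacency; normalized/kernelized
#'   internally as each method requires).
#' @param modules a `module_collection` resolved against the network.
#' @param method one of `"SAV"`, `"SNN"`, `"SKNN"`, `"zhou"`, `"genemania"`,
#'   `"labelprop"`.
#' @param params method parameters: `a`, `q` (kernel methods; defaults 2, 2),
#'   `k` (SKNN; default 27), `alpha` (propagation; default 0.5).
#' @param folds,repeats,seed cross-validation layout (defaults 5, 5).
#' @param levels recall levels for the precision grid.
#' @param kernel optionally, a precomputed `kernel_gram` for the network
#'   (must match `params$a`, `params$q`); avoids rebuilding it across methods.
#' @return object of class `evaluation_result`: list with `records` (data
#'   frame: module_id, method, repeat_index, fold_index, metric, level,
#'   value), `method`, `module_sizes`, and the CV layout.
#' @export
run_cv <- function(net, modules, method, params = list(),
                   folds = 5, repeats = 5, seed = 1L,
                   levels = seq(0.1, 1, by = 0.1), kernel = NULL) {
  method <- match.arg(method, c("SAV", "SNN", "SKNN", "zhou", "genemania",
                                "labelprop"))
  qq <- if (is.null(params$q)) 2L else as.integer(params$q)
  aa <- if (is.null(params$a)) 2 else params$a
  kernel_based <- method %in% c("SAV", "SNN", "SKNN")
  norm_net <- NULL
  if (kernel_based) {
    if (is.null(kernel)) kernel <- q_step_rw_kernel(net, a = aa, q = qq)
    else stopifnot(identical(kernel$genes, net$genes))
  } else {
    norm_net <- if (inherits(net, "normalized_network")) net
                else laplacian_normalize(net)
  }
  fa <- make_folds(modules, universe = net$genes, folds = folds,
                   repeats = repeats, seed = seed)
  universe <- net$genes
  recs <- list()
  for (m in modules$modules) {
    mod_rows <- fa[fa$module_id == m$module_id, ]
    never_pos <- setdiff(universe, m$members)
    for (r in seq_len(repeats)) {
      rep_rows <- mod_rows[mod_rows$repeat_index == r, ]
      for (f in seq_len(folds)) {
        test_pos <- sort(rep_rows$gene[rep_rows$fold_index == f])
        train_pos <- sort(setdiff(m$members, test_pos))
        candidates <- sort(c(test_pos, never_pos))
        s <- .score_fold(method, train_pos, candidates, kernel = kernel,
                         norm_net = norm_net,
                         params = c(params, list(a = aa, q = qq)))
        ranked <- rank_genes(s)
        pr <- precision_at_recall(ranked, test_pos, levels)
        auc <- auc_score(s, test_pos)
        recs[[length(recs) + 1]] <- data.frame(
          module_id = m$module_id, method = method, repeat_index = r,
          fold_index = f,
          metric = c(rep("precision", length(levels)), "auc"),
          level = c(levels, NA),
          value = c(unname(pr), auc), stringsAsFactors = FALSE)
      }
    }
  }
  records <- do.call(rbind, recs)
  rownames(records) <- NULL
  structure(list(records = records, method = method,
                 module_sizes = module_sizes(modules),
                 folds = folds, repeats = repeats, seed = seed,
                 params = list(a = aa, q = qq,
                               k = if (is.null(params$k)) 27 else params$k,
                               alpha = if (is.null(params$alpha)) 0.5
                                       else params$alpha)),
            class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf("<evaluation_result> %s: %d modules, %d folds x %d repeats; mean AUC = %.4f\n",
              x$method, length(x$module_sizes), x$folds, x$repeats,
              mean_auc(x)))
  invisible(x)
}

#' Per-module mean AUC of an evaluation result
#'
#' AUCs averaged over folds and repeats, one value per module.
#'
#' @param result an `evaluation_result`.
#' @return named numeric vector (module -> mean AUC).
#' @export
module_auc <- function(result) {
  a <- result$records[result$records$metric == "auc", ]
  out <- tapply(a$value, a$module_id, mean)
  # restore collection order
  out[match(names(result$module_sizes), names(out))]
}

#' Grand mean AUC (over modules) of an evaluation result
#' @param result an `evaluation_result`.
#' @return a single number.
#' @export
mean_auc <- function(result) mean(module_auc(result))

#' Mean precision at one recall level, averaged over folds, repeats, modules
#' @param result an `evaluation_result`.
#' @param level recall level present in the result's grid.
#' @return a single number.
#' @export
mean_precision_at <- function(result, level = 0.2) {
  p <- result$records[result$records$metric == "precision" &
                        abs(result$records$level - level) < 1e-9, ]
  if (nrow(p) == 0) stop("recall level ", level, " not in the result grid")
  mean(tapply(p$value, p$module_id, mean))
}

#' Compare evaluation results across methods
#'
#' Performs pairwise two-sided Wilcoxon signed-rank tests on the per-module
#' mean AUCs (averaged across folds and repeats) of each pair of methods, and
#' tabulates per-cardinality-group mean AUC and mean precision at a chosen
#' recall level. When two methods produce identical per-module AUCs the
#' signed-rank statistic is undefined; the comparison reports p = 1 (no
#' detectable difference) by convention.
#'
#' @param results list of `evaluation_result` objects over the same modules.
#' @param precision_level recall level summarized in the group table
#'   (default 0.2).
#' @return list with `wilcoxon` (data frame: method_a, method_b, p_value) and
#'   `by_cardinality` (data frame: method, group, n_modules, mean_auc,
#'   mean_precision).
#' @export
compare_methods <- function(results, precision_level = 0.2) {
  stopifnot(length(results) >= 2)
  ids <- lapply(results, function(r) names(r$module_sizes))
  for (i in seq_along(results)[-1]) {
    if (!identical(sort(ids[[1]]), sort(ids[[i]])))
      stop("evaluation results cover different module sets")
  }
  methods <- vapply(results, `[[`, "", "method")
  if (anyDuplicated(methods))
    methods <- paste0(methods, ".", seq_along(methods))
  aucs <- lapply(results, module_auc)
  order_ids <- sort(ids[[1]])
  aucs <- lapply(aucs, function(a) a[order_ids])

  pairs <- utils::combn(seq_along(results), 2)
  wtab <- data.frame(method_a = methods[pairs[1, ]],
                     method_b = methods[pairs[2, ]],
                     p_value = apply(pairs, 2, function(pr) {
                       d <- aucs[[pr[1]]] - aucs[[pr[2]]]
                       if (all(d == 0)) return(1)
                       suppressWarnings(
                         stats::wilcox.test(aucs[[pr[1]]], aucs[[pr[2]]],
                                            paired = TRUE)$p.value)
                     }), stringsAsFactors = FALSE)

  rows <- list()
  for (i in seq_along(results)) {
    sizes <- results[[i]]$module_sizes[order_ids]
    grp <- .cardinality_group(sizes)
    prec <- vapply(order_ids, function(id)
      mean_precision_at_module(results[[i]], id, precision_level), numeric(1))
    for (g in levels(grp)) {
      sel <- grp == g
      if (!any(sel)) next
      rows[[length(rows) + 1]] <- data.frame(
        method = methods[i], group = g, n_modules = sum(sel),
        mean_auc = mean(aucs[[i]][sel]), mean_precision = mean(prec[sel]),
        stringsAsFactors = FALSE)
    }
  }
  list(wilcoxon = wtab, by_cardinality = do.call(rbind, rows))
}

#' @keywords internal
mean_precision_at_module <- function(result, module_id, level) {
  if (is.na(level)) return(NA_real_)
  sel <- which(result$records$metric == "precision" &
                 result$records$module_id == module_id &
                 abs(result$records$level - level) < 1e-9)
  if (length(sel) == 0) return(NA_real_)
  mean(result$records$value[sel])
}

#' Write an evaluation result as tidy TSV
#'
#' One row per (module, method, repeat, fold, metric, level, value);
#' deterministic ordering, so identical runs produce byte-identical files.
#'
#' @param result an `evaluation_result`.
#' @param path output path.
#' @export
write_evaluation <- function(result, path) {
  df <- result$records
  df$value <- formatC(df$value, digits = 15, format = "g")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
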