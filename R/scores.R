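#' @keywords internal
.as_members <- function(positives) {
  if (inherits(positives, "gene_module")) positives$members
  else unique(as.character(positives))
}

#' @keywords internal
.check_score_args <- function(K, positives, candidates) {
  stopifnot(inherits(K, "kernel_gram"))
  pos <- .as_members(positives)
  if (length(pos) == 0) stop("positive set is empty")
  missing_pos <- setdiff(pos, K$genes)
  if (length(missing_pos) > 0)
    stop("positive gene(s) not in kernel universe: ",
         paste(utils::head(missing_pos, 5), collapse = ", "))
  if (is.null(candidates)) candidates <- setdiff(K$genes, pos)
  candidates <- as.character(candidates)
  missing_c <- setdiff(candidates, K$genes)
  if (length(missing_c) > 0)
    stop("candidate gene(s) not in kernel universe: ",
         paste(utils::head(missing_c, 5), collapse = ", "))
  list(pos = pos, candidates = candidates)
}

#' @keywords internal
.score_vector <- function(genes, scores, method, module_id, params, ops) {
  structure(list(genes = genes,
                 scores = stats::setNames(as.numeric(scores), genes),
                 method = method, module_id = module_id, params = params),
            class = "score_vector", ops = ops)
}

#' @export
print.score_vector <- function(x, ...) {
  cat(sprintf("<score_vector> %s, module '%s', %d candidates\n",
              x$method, x$module_id, length(x$genes)))
  invisible(x)
}

#' Average kernelized score
#'
#' Scores each candidate gene `v` against a module's positive set `V_C` by the
#' (negated) average feature-space distance to the positives, evaluated
#' through kernel entries only:
#' `S_AV(v) = -K(v, v) + (2 / |V_C|) * sum_{x in V_C} K(v, x)`.
#' This drops from the full similarity only the term `mean_x K(x, x)`, which
#' is identical for all candidates; the `-K(v, v)` term is always kept because
#' q-step kernel diagonals are not constant for `q >= 2`. Higher score means
#' the gene is more likely to belong to the module.
#'
#' @param K a `kernel_gram`.
#' @param positives a `gene_module` or character vector of positive genes
#'   (the training labels).
#' @param candidates genes to score; default all kernel genes not in
#'   `positives`. Positives may be included (e.g. held-out positives during
#'   cross-validation).
#' @return a `score_vector`. The attribute `ops` records the number of kernel
#'   entries read, which scales as `|candidates| * |V_C|`.
#' @export
score_av <- function(K, positives, candidates = NULL) {
  a <- .check_score_args(K, positives, candidates)
  Kvc <- K$K[a$candidates, a$pos, drop = FALSE]
  s <- -diag(K$K)[a$candidates] + 2 * rowMeans(Kvc)
  .score_vector(a$candidates, s, "SAV",
                if (inherits(positives, "gene_module")) positives$module_id else "",
                list(a = K$a, q = K$q),
                ops = length(Kvc) + length(a$candidates))
}

#' Nearest-neighbour kernelized score
#'
#' `S_NN(v) = 2 * max_{x in V_C} K(v, x)`: a candidate is scored by its single
#' most similar positive. This is the negated nearest-neighbour feature-space
#' distance after removing the diagonal terms, which are constant when all
#' `K(v, v)` are equal (exact for the one-step kernel; see
#' [score_full_similarity] for the un-simplified form).
#'
#' @inheritParams score_av
#' @return a `score_vector` (attribute `ops` as in [score_av]).
#' @export
score_nn <- function(K, positives, candidates = NULL) {
  a <- .check_score_args(K, positives, candidates)
  Kvc <- K$K[a$candidates, a$pos, drop = FALSE]
  s <- 2 * apply(Kvc, 1, max)
  .score_vector(a$candidates, s, "SNN",
                if (inherits(positives, "gene_module")) positives$module_id else "",
                list(a = K$a, q = K$q), ops = length(Kvc))
}

#' k-nearest-neighbour kernelized score
#'
#' `S_kNN(v) = 2 * sum over the k positives most similar to v of K(v, x)`.
#' With `k = 1` this is [score_nn]; with `k >= |V_C|` the sum runs over the
#' whole positive set (so it equals `|V_C| * (S_AV(v) + K(v, v))`). Ties in
#' `K(v, x)` at the k-th position are broken by lexicographic gene identifier,
#' making the selection deterministic.
#'
#' @inheritParams score_av
#' @param k number of most-similar positives summed (default 27, clamped to
#'   `|V_C|` when larger).
#' @return a `score_vector` (attribute `ops` as in [score_av]).
#' @export
score_knn <- function(K, positives, candidates = NULL, k = 27) {
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k != round(k))
    stop("parameter k must be a positive integer")
  a <- .check_score_args(K, positives, candidates)
  Kvc <- K$K[a$candidates, a$pos, drop = FALSE]
  kk <- min(k, length(a$pos))
  pos_names <- a$pos
  s <- apply(Kvc, 1, function(row) {
    ord <- order(-row, pos_names)
    2 * sum(row[ord[seq_len(kk)]])
  })
  .score_vector(a$candidates, s, "SKNN",
                if (inherits(positives, "gene_module")) positives$module_id else "",
                list(a = K$a, q = K$q, k = k), ops = length(Kvc))
}

#' Un-simplified kernel similarity scores
#'
#' The average and nearest-neighbour scores above drop diagonal kernel terms
#' under the premise that `K(v, v)` is the same for every gene. That premise
#' holds for the one-step random walk kernel but fails for its powers
#' (`q >= 2`), where the diagonal varies with local topology. This function
#' returns the full negated feature-space distance with every diagonal term
#' kept, so the approximation in the simplified forms can be audited:
#'
#' * `flavor = "average"`: `Sim_AV(v) = -K(v,v) + (2/|V_C|) sum_x K(v,x)
#'   - (1/|V_C|) sum_x K(x,x)` — differs from `S_AV` by a candidate-
#'   independent constant, so rankings are identical.
#' * `flavor = "nearest"`: `Sim_NN(v) = -min_x [K(v,v) - 2 K(v,x) + K(x,x)]`
#'   — can rank differently from `S_NN` when the diagonal is non-constant.
#'
#' @inheritParams score_av
#' @param flavor `"average"` or `"nearest"`.
#' @return a `score_vector` with method `full_sim_AV` or `full_sim_NN`.
#' @export
score_full_similarity <- function(K, positives, candidates = NULL,
                                  flavor = c("average", "nearest")) {
  flavor <- match.arg(flavor)
  a <- .check_score_args(K, positives, candidates)
  Kvc <- K$K[a$candidates, a$pos, drop = FALSE]
  dK <- diag(K$K)
  if (flavor == "average") {
    s <- -dK[a$candidates] + 2 * rowMeans(Kvc) - mean(dK[a$pos])
    method <- "full_sim_AV"
  } else {
    # distance to each positive: K(v,v) - 2K(v,x) + K(x,x); take the minimum
    d <- outer(dK[a$candidates], dK[a$pos], `+`) - 2 * Kvc
    s <- -apply(d, 1, min)
    method <- "full_sim_NN"
  }
  .score_vector(a$candidates, s, method,
                if (inherits(positives, "gene_module")) positives$module_id else "",
                list(a = K$a, q = K$q), ops = length(Kvc) + length(dK))
}

#' Rank genes by score
#'
#' Sorts genes by decreasing score; exact ties are broken by lexicographic
#' gene identifier, so the ranking is deterministic and independent of input
#' order.
#'
#' @param scores a `score_vector`, or a named numeric vector of scores.
#' @return character vector of genes, best first.
#' @export
rank_genes <- function(scores) {
  s <- if (inherits(scores, "score_vector")) scores$scores else scores
  if (is.null(names(s))) stop("scores must be named by gene")
  if (any(!is.finite(s))) stop("non-finite score(s): ",
                               paste(utils::head(names(s)[!is.finite(s)], 5),
                                     collapse = ", "))
  names(s)[order(-s, names(s), method = "radix")]
}

#' Write a ranking table
#'
#' @param scores a `score_vector`.
#' @param path output TSV path (columns: module_id, gene, score, rank,
#'   method, q, a, k).
#' @export
write_ranking <- function(scores, path) {
  ranked <- rank_genes(scores)
  p <- scores$params
  df <- data.frame(module_id = scores$module_id, gene = ranked,
                   score = unname(scores$scores[ranked]),
                   rank = seq_along(ranked), method = scores$method,
                   q = if (is.null(p$q)) NA else p$q,
                   a = if (is.null(p$a)) NA else p$a,
                   k = if (is.null(p$k)) NA else p$k)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
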