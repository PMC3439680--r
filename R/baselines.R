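#' Construct an initial label vector
#'
#' Encodes the a-priori knowledge fed to the propagation methods. Under the
#' `binary01` scheme training positives get 1 and every other gene 0. Under
#' the `cost_sensitive` scheme (the GeneMANIA convention, useful when
#' positives are rare) positives get `+(n - n_pos) / n` and all other genes
#' `-(n_pos) / n`, so the mean initial label is zero.
#'
#' @param genes ordered gene universe.
#' @param positives a `gene_module` or character vector of positive genes.
#' @param scheme `"binary01"` or `"cost_sensitive"`.
#' @return object of class `label_vector` with fields `genes`, `y0`, `scheme`.
#' @export
label_vector <- function(genes, positives, scheme = c("binary01", "cost_sensitive")) {
  scheme <- match.arg(scheme)
  genes <- as.character(genes)
  pos <- .as_members(positives)
  if (length(setdiff(pos, genes)) > 0) stop("positive gene(s) not in universe")
  is_pos <- genes %in% pos
  n <- length(genes); npos <- sum(is_pos)
  y0 <- if (scheme == "binary01") as.numeric(is_pos)
        else ifelse(is_pos, (n - npos) / n, -npos / n)
  structure(list(genes = genes, y0 = stats::setNames(y0, genes),
                 scheme = scheme), class = "label_vector")
}

#' @keywords internal
.propagation_result <- function(genes, scores, method, alpha = NA_real_,
                                iterations_used = 0L, converged = TRUE) {
  structure(list(genes = genes,
                 scores = stats::setNames(as.numeric(scores), genes),
                 method = method, alpha = alpha,
                 iterations_used = as.integer(iterations_used),
                 converged = converged),
            class = c("propagation_result", "score_vector"))
}

#' @keywords internal
# conjugate gradient for SPD systems; A supplied as a matrix
.cg_solve <- function(A, b, tol = 1e-8, max_iter = 10 * length(b)) {
  x <- numeric(length(b))
  r <- b
  p <- r
  rs <- sum(r * r)
  it <- 0L
  while (sqrt(rs) > tol && it < max_iter) {
    Ap <- as.numeric(A %*% p)
    alpha <- rs / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    rs_new <- sum(r * r)
    p <- r + (rs_new / rs) * p
    rs <- rs_new
    it <- it + 1L
  }
  list(x = x, iterations = it, converged = sqrt(rs) <= tol)
}

#' Gaussian random field score propagation
#'
#' Finds the score vector `S*` minimizing the convex objective
#' `alpha * sum_i (s_i - s0_i)^2 + (1 - alpha) * sum_ij w_ij (s_i - s_j)^2`,
#' balancing fidelity to the initial labels against smoothness over the
#' network. The unique minimizer solves the linear system
#' `(alpha I + (1 - alpha) L) S* = alpha S0` with `L = D - W` the
#' combinatorial Laplacian of the working (normalized) adjacency. Solved
#' directly for moderate networks, by conjugate gradient (tolerance 1e-8)
#' above `cg_threshold` genes.
#'
#' @param net a `normalized_network` (the quadratic form is applied to the
#'   Laplacian of the normalized matrix, matching the integration pipeline).
#' @param y0 a `label_vector` on the same gene universe.
#' @param alpha trade-off in (0, 1]; `alpha = 1` returns `S0` exactly,
#'   `alpha = 0` is rejected (the objective loses uniqueness).
#' @param solver `"auto"` (direct below `cg_threshold`), `"direct"`, `"cg"`.
#' @param cg_threshold network size above which `"auto"` switches to
#'   conjugate gradient (default 5000).
#' @return a `propagation_result` (also usable as a `score_vector`).
#' @examples
#' W <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("A","B"), c("A","B")))
#' nn <- laplacian_normalize(gene_network(W))
#' zhou_solve(nn, label_vector(c("A","B"), "A"), alpha = 0.5)$scores
#' # (2/3, 1/3)
#' @export
zhou_solve <- function(net, y0, alpha = 0.5,
                       solver = c("auto", "direct", "cg"),
                       cg_threshold = 5000) {
  solver <- match.arg(solver)
  stopifnot(inherits(y0, "label_vector"))
  if (!identical(y0$genes, net$genes))
    stop("label vector and network universes differ")
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha > 1)
    stop("alpha must lie in (0, 1]; alpha = 0 loses uniqueness of the minimizer")
  n <- length(net$genes)
  if (alpha == 1)
    return(.propagation_result(net$genes, y0$y0, "zhou", alpha))
  L <- -(1 - alpha) * net$W
  diag(L) <- diag(L) + alpha + (1 - alpha) * rowSums(net$W)
  b <- alpha * y0$y0
  if (solver == "cg" || (solver == "auto" && n > cg_threshold)) {
    sol <- .cg_solve(L, b)
    if (!sol$converged) warning("conjugate gradient did not converge")
    .propagation_result(net$genes, sol$x, "zhou", alpha,
                        iterations_used = sol$iterations,
                        converged = sol$converged)
  } else {
    x <- tryCatch(solve(L, b),
                  error = function(e) stop("propagation system is singular: ",
                                           conditionMessage(e)))
    .propagation_result(net$genes, x, "zhou", alpha)
  }
}

#' Evaluate the Gaussian-field propagation objective
#'
#' `alpha * sum_i (s_i - s0_i)^2 + (1 - alpha) * sum_i sum_j w_ij (s_i - s_j)^2`,
#' with the double sum over ordered pairs. Used to check the minimizer
#' property of [zhou_solve].
#'
#' @param net a `normalized_network`.
#' @param s candidate score vector (same order as `net$genes`).
#' @param y0 a `label_vector`.
#' @param alpha trade-off parameter.
#' @return the objective value (a single number).
#' @export
propagation_objective <- function(net, s, y0, alpha) {
  s <- as.numeric(s)
  d <- outer(s, s, `-`)
  alpha * sum((s - y0$y0)^2) + (1 - alpha) * sum(net$W * d^2)
}

#' GeneMANIA-style cost-sensitive propagation
#'
#' Identical solver to [zhou_solve], but the initial labels use the
#' cost-sensitive scheme (`+(n-)/n` for positives, `-(n+)/n` otherwise),
#' which compensates for the strong class imbalance typical of gene
#' prioritization, where positives are a small fraction of the network.
#'
#' @param net a `normalized_network`.
#' @param positives a `gene_module` or character vector; must be a non-empty
#'   strict subset of the universe.
#' @inheritParams zhou_solve
#' @return a `propagation_result` with method `"genemania"`.
#' @export
genemania_solve <- function(net, positives, alpha = 0.5,
                            solver = c("auto", "direct", "cg"),
                            cg_threshold = 5000) {
  pos <- .as_members(positives)
  if (length(pos) == 0) stop("positive set is empty")
  if (length(pos) >= length(net$genes))
    stop("positives must be a strict subset of the gene universe")
  y0 <- label_vector(net$genes, pos, scheme = "cost_sensitive")
  res <- zhou_solve(net, y0, alpha = alpha, solver = solver,
                    cg_threshold = cg_threshold)
  res$method <- "genemania"
  res
}

#' Harmonic label propagation with clamped labels
#'
#' Minimizes the smoothness objective `sum_ij w_ij (s_i - s_j)^2` while
#' holding the scores of the clamped genes fixed at their initial values.
#' The minimizer is the harmonic solution: every unlabeled gene's score is
#' the weighted mean of its neighbours' scores,
#' `s_u = sum_j w_uj s_j / sum_j w_uj`. Solved directly on the unlabeled
#' block, `S_U = (D_UU - W_UU)^{-1} W_UL S_L`, or by iterative
#' propagate-and-clamp sweeps.
#'
#' An unlabeled gene with no path to any clamped gene is unconstrained up to
#' a constant; its score is set to 0 with a warning.
#'
#' @param net a `normalized_network` (any `gene_network` works; weights need
#'   only be non-negative).
#' @param y0 a `label_vector` providing the clamped values.
#' @param clamp_set genes whose scores are held at `y0` (non-empty).
#' @param tol iterative-solver convergence tolerance on the max-abs update.
#' @param max_iter iteration cap for the iterative solver.
#' @param solver `"direct"` (default) or `"iterative"`.
#' @return a `propagation_result`; clamped entries equal `y0` exactly and
#'   `converged` reports whether the max-abs update fell below `tol`
#'   (always `TRUE` for the direct solver).
#' @export
labelprop_solve <- function(net, y0, clamp_set, tol = 1e-6, max_iter = 10000,
                            solver = c("direct", "iterative")) {
  solver <- match.arg(solver)
  stopifnot(inherits(y0, "label_vector"))
  if (!identical(y0$genes, net$genes))
    stop("label vector and network universes differ")
  clamp_set <- as.character(clamp_set)
  if (length(clamp_set) == 0) stop("clamp_set must be non-empty")
  if (length(setdiff(clamp_set, net$genes)) > 0)
    stop("clamp_set gene(s) not in universe")
  genes <- net$genes
  clamped <- genes %in% clamp_set
  s <- y0$y0
  if (all(clamped))
    return(.propagation_result(genes, s, "labelprop"))

  W <- net$W
  # genes unreachable from the clamp set are unconstrained; pin them to 0
  reach <- clamped
  frontier <- which(clamped)
  while (length(frontier) > 0) {
    nb <- which(colSums(W[frontier, , drop = FALSE] > 0) > 0 & !reach)
    reach[nb] <- TRUE
    frontier <- nb
  }
  if (any(!reach)) {
    warning(sum(!reach), " gene(s) have no path to any clamped gene; scores set to 0")
    s[!reach] <- 0
  }
  u <- which(!clamped & reach)
  l <- which(clamped)
  if (length(u) > 0) {
    if (solver == "direct") {
      A <- -W[u, u, drop = FALSE]
      diag(A) <- diag(A) + rowSums(W[u, , drop = FALSE])
      b <- as.numeric(W[u, l, drop = FALSE] %*% s[l])
      s[u] <- solve(A, b)
      res <- .propagation_result(genes, s, "labelprop")
    } else {
      deg_u <- rowSums(W[u, , drop = FALSE])
      it <- 0L; delta <- Inf
      while (delta > tol && it < max_iter) {
        new_u <- as.numeric(W[u, , drop = FALSE] %*% s) / deg_u
        delta <- max(abs(new_u - s[u]))
        s[u] <- new_u
        it <- it + 1L
      }
      res <- .propagation_result(genes, s, "labelprop",
                                 iterations_used = it,
                                 converged = delta <= tol)
    }
  } else {
    res <- .propagation_result(genes, s, "labelprop")
  }
  res
}

#' Ridge-regression weighted network integration
#'
#' Learns one non-negative weight per network so that the weighted sum of
#' adjacency matrices best predicts module co-membership of gene pairs, then
#' returns the weighted-sum network `W* = sum_i w_i W^(i)`. The regression
#' design is built jointly over all modules: for each module, every
#' within-module pair enters with target +1 and an equal number of pairs with
#' at least one endpoint outside the module is sampled uniformly with target
#' -1 (class-balanced per module). Predictors are the networks' entries at
#' those pairs; the ridge system `(X'X + lambda I) w = X't` is solved, any
#' negative weight is clipped to zero and the system re-solved over the
#' remaining networks.
#'
#' @param nets list of `normalized_network` objects on an identical universe.
#' @param modules a `module_collection` resolved against that universe.
#' @param ridge_lambda ridge penalty (default 1.0).
#' @param seed integer seed for the negative-pair sampling (default 1), so
#'   the learned weights are reproducible.
#' @return list with `weights` (named non-negative numeric, one per network)
#'   and `network` (the integrated `gene_network`).
#' @export
sw_integrate <- function(nets, modules, ridge_lambda = 1.0, seed = 1L) {
  stopifnot(length(nets) >= 1, length(modules$modules) >= 1)
  g0 <- nets[[1]]$genes
  for (nt in nets) if (!identical(nt$genes, g0))
    stop("networks must share an identical, identically-ordered gene universe")
  n <- length(g0)
  net_names <- vapply(seq_along(nets), function(i) {
    nm <- nets[[i]]$name
    if (is.null(nm) || !nzchar(nm)) paste0("net", i) else nm
  }, "")
  if (anyDuplicated(net_names))
    net_names <- paste0(net_names, ".", seq_along(net_names))

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed %% .Machine$integer.max))

  rows_i <- integer(0); rows_j <- integer(0); target <- numeric(0)
  for (m in modules$modules) {
    mem <- match(intersect(m$members, g0), g0)
    if (length(mem) < 2) next
    pr <- utils::combn(sort(mem), 2)
    npos <- ncol(pr)
    rows_i <- c(rows_i, pr[1, ]); rows_j <- c(rows_j, pr[2, ])
    target <- c(target, rep(1, npos))
    # sample negatives: pairs with >= 1 endpoint outside the module
    got <- 0L
    while (got < npos) {
      ii <- sample.int(n, npos - got, replace = TRUE)
      jj <- sample.int(n, npos - got, replace = TRUE)
      # exclude self pairs and within-module draws
      ok <- ii != jj & !(ii %in% mem & jj %in% mem)
      ii <- ii[ok]; jj <- jj[ok]
      take <- seq_len(min(length(ii), npos - got))
      rows_i <- c(rows_i, pmin(ii[take], jj[take]))
      rows_j <- c(rows_j, pmax(ii[take], jj[take]))
      target <- c(target, rep(-1, length(take)))
      got <- got + length(take)
    }
  }
  if (length(target) == 0) stop("no usable module pairs for the regression design")
  lin <- (rows_j - 1L) * n + rows_i
  X <- vapply(nets, function(nt) nt$W[lin], numeric(length(lin)))
  X <- matrix(X, ncol = length(nets))
  active <- seq_along(nets)
  w <- numeric(length(nets))
  repeat {
    Xa <- X[, active, drop = FALSE]
    A <- crossprod(Xa) + ridge_lambda * diag(length(active))
    wa <- solve(A, crossprod(Xa, target))
    if (all(wa >= 0)) { w[active] <- wa; break }
    active <- active[wa >= 0]
    if (length(active) == 0)
      stop("all network weights clipped to zero: no network is informative for module co-membership")
  }
  names(w) <- net_names
  Wstar <- Reduce(`+`, Map(function(nt, wi) wi * nt$W, nets, w))
  list(weights = w,
       network = gene_network(Wstar, g0, name = "sw_integrated"))
}

#' @keywords internal
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

#' @keywords internal
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Write integration weights as TSV
#' @param weights named numeric vector from [sw_integrate].
#' @param path output path (columns: network, weight).
#' @export
write_weights <- function(weights, path) {
  utils::write.table(data.frame(network = names(weights),
                                weight = unname(weights)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
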