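#' Configuration for the planted-module network generator
#'
#' The generator emulates the structure guilt-by-association methods exploit:
#' genes of the same module interact more often (`p_in`) than background
#' pairs (`p_out`) — a planted-partition (stochastic-block-style) topology.
#' Defaults produce a 1000-gene network with ten modules of 20 to 60 genes,
#' `p_in = 0.3`, `p_out = 0.01` and constant unit weights.
#'
#' @param n_genes number of genes.
#' @param module_sizes integer vector of planted module sizes (default ten
#'   modules, sizes evenly spread from 20 to 60).
#' @param p_in within-module edge probability.
#' @param p_out background edge probability (`p_out <= p_in`).
#' @param weight_dist `"constant"` (weight 1) or `"uniform"` (weights drawn
#'   from `runif(weight_lo, weight_hi)`).
#' @param weight_lo,weight_hi range of the uniform weight distribution.
#' @param overlap_fraction fraction of each module's genes shared with the
#'   previous module (default 0).
#' @param seed integer seed; the generator is fully reproducible from it.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 1000,
                             module_sizes = round(seq(20, 60, length.out = 10)),
                             p_in = 0.3, p_out = 0.01,
                             weight_dist = c("constant", "uniform"),
                             weight_lo = 0.5, weight_hi = 1.5,
                             overlap_fraction = 0, seed = 1L) {
  weight_dist <- match.arg(weight_dist)
  module_sizes <- as.integer(module_sizes)
  stopifnot(n_genes >= 2, all(module_sizes >= 2),
            p_out >= 0, p_in >= p_out, p_in <= 1,
            overlap_fraction >= 0, overlap_fraction < 1)
  unique_needed <- sum(module_sizes) -
    sum(floor(overlap_fraction * utils::tail(module_sizes, -1)))
  if (unique_needed > n_genes)
    stop("module sizes exceed n_genes after accounting for overlap")
  structure(list(n_genes = n_genes, module_sizes = module_sizes,
                 p_in = p_in, p_out = p_out, weight_dist = weight_dist,
                 weight_lo = weight_lo, weight_hi = weight_hi,
                 overlap_fraction = overlap_fraction,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' @keywords internal
# deterministic module membership layout: consecutive gene blocks, with
# overlap_fraction of each module's head shared with the previous module
.layout_modules <- function(config) {
  genes <- sprintf("g%06d", seq_len(config$n_genes))
  mods <- vector("list", length(config$module_sizes))
  nxt <- 1L
  prev <- integer(0)
  for (i in seq_along(config$module_sizes)) {
    sz <- config$module_sizes[i]
    n_shared <- if (i == 1) 0L else min(floor(config$overlap_fraction * sz),
                                        length(prev))
    shared <- if (n_shared > 0) utils::tail(prev, n_shared) else integer(0)
    fresh <- seq.int(nxt, length.out = sz - n_shared)
    nxt <- nxt + sz - n_shared
    idx <- c(shared, fresh)
    mods[[i]] <- gene_module(sprintf("M%02d", i), genes[idx],
                             sprintf("planted module %d (synthetic)", i))
    prev <- idx
  }
  list(genes = genes, modules = module_collection(mods, universe = genes))
}

#' @keywords internal
# Bernoulli edge draw over the full upper triangle with per-pair probability
.draw_adjacency <- function(genes, modules, p_in, p_out) {
  n <- length(genes)
  P <- matrix(p_out, n, n)
  for (m in modules$modules) {
    idx <- match(m$members, genes)
    P[idx, idx] <- p_in
  }
  U <- matrix(0, n, n)
  ut <- upper.tri(U)
  U[ut] <- stats::runif(sum(ut))
  A <- (U < P) & ut
  A | t(A)
}

#' Generate a synthetic network with planted modules
#'
#' Draws an undirected random graph over `n_genes` genes named
#' `g000001, g000002, ...`: each unordered pair within a planted module gets
#' an edge with probability `p_in`, every other pair with probability
#' `p_out`; weights follow `weight_dist`. A gene left isolated by the draw is
#' re-wired to one uniformly chosen partner (rather than deleted), keeping
#' `n_genes` exact so indexing is reproducible. Output is byte-identical for
#' identical configs.
#'
#' @param config a [synthetic_config].
#' @return list with `network` (a `gene_network` passing all loader
#'   validation) and `modules` (a `module_collection`).
#' @export
generate_network <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  lay <- .layout_modules(config)
  A <- .draw_adjacency(lay$genes, lay$modules, config$p_in, config$p_out)
  A <- .rewire_isolated(A)
  W <- .assign_weights(A, config)
  dimnames(W) <- list(lay$genes, lay$genes)
  list(network = gene_network(W, lay$genes, name = sprintf("synthetic_seed%d",
                                                           config$seed)),
       modules = lay$modules)
}

#' @keywords internal
.rewire_isolated <- function(A) {
  n <- nrow(A)
  iso <- which(rowSums(A) == 0)
  for (i in iso) {
    j <- sample(setdiff(seq_len(n), i), 1)
    A[i, j] <- A[j, i] <- TRUE
  }
  A
}

#' @keywords internal
.assign_weights <- function(A, config) {
  n <- nrow(A)
  W <- matrix(0, n, n)
  ut <- upper.tri(A) & A
  W[ut] <- if (config$weight_dist == "constant") 1
           else stats::runif(sum(ut), config$weight_lo, config$weight_hi)
  W + t(W)
}

#' Generate two complementary networks sharing the planted modules
#'
#' Emulates integrating functional networks built from different evidence:
#' both networks cover the same gene universe and the same planted modules,
#' but a `divergence` fraction of the informative (within-module) edges is
#' assigned to only one of the two networks, chosen uniformly. With
#' `divergence = 0` the networks are identical; with `divergence = 1` the
#' informative edges are disjoint, so each single network carries only part
#' of the signal and integration genuinely adds information. Background edges
#' and the remaining informative edges appear in both.
#'
#' @param config a [synthetic_config].
#' @param divergence fraction in \[0, 1\] of informative edges made exclusive
#'   to one network.
#' @return list with `network1`, `network2` (gene universes and ordering
#'   identical) and `modules`.
#' @export
generate_network_pair <- function(config, divergence) {
  stopifnot(inherits(config, "synthetic_config"),
            divergence >= 0, divergence <= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  lay <- .layout_modules(config)
  A <- .draw_adjacency(lay$genes, lay$modules, config$p_in, config$p_out)
  A <- .rewire_isolated(A)
  n <- nrow(A)
  within <- matrix(FALSE, n, n)
  for (m in lay$modules$modules) {
    idx <- match(m$members, lay$genes)
    within[idx, idx] <- TRUE
  }
  informative <- which(upper.tri(A) & A & within)
  n_split <- round(divergence * length(informative))
  split_edges <- if (n_split > 0) sample(informative, n_split) else integer(0)
  # each exclusive edge goes to network 1 or 2 with equal probability
  to_first <- if (n_split > 0) stats::runif(n_split) < 0.5 else logical(0)
  A1 <- A; A2 <- A
  drop1 <- split_edges[!to_first]   # edges kept only by network 2
  drop2 <- split_edges[to_first]
  A1[drop1] <- FALSE; A2[drop2] <- FALSE
  A1 <- A1 & upper.tri(A1); A1 <- A1 | t(A1)
  A2 <- A2 & upper.tri(A2); A2 <- A2 | t(A2)
  A1 <- .rewire_isolated(A1)
  A2 <- .rewire_isolated(A2)
  W1 <- .assign_weights(A1, config)
  W2 <- .assign_weights(A2, config)
  dimnames(W1) <- dimnames(W2) <- list(lay$genes, lay$genes)
  list(network1 = gene_network(W1, lay$genes,
                               name = sprintf("synthetic_seed%d_a", config$seed)),
       network2 = gene_network(W2, lay$genes,
                               name = sprintf("synthetic_seed%d_b", config$seed)),
       modules = lay$modules)
}

#' Write a synthetic config as a flat key-value file
#' @param config a `synthetic_config`.
#' @param path output path.
#' @export
write_config <- function(config, path) {
  kv <- vapply(names(unclass(config)), function(k)
    sprintf("%s=%s", k, paste(config[[k]], collapse = ",")), "")
  writeLines(kv, path)
  invisible(path)
}
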