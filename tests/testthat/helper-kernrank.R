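# shared generators and independent oracles for the test suite

# small random connected-ish network: Erdos-Renyi draw, isolated nodes rewired
rand_net <- function(n, p = 0.3, seed = 1, weights = c("constant", "uniform")) {
  weights <- match.arg(weights)
  set.seed(seed)
  genes <- sprintf("t%03d", seq_len(n))
  A <- matrix(0, n, n)
  ut <- upper.tri(A)
  A[ut] <- as.numeric(runif(sum(ut)) < p)
  A <- A + t(A)
  for (i in which(rowSums(A) == 0)) {
    j <- sample(setdiff(seq_len(n), i), 1)
    A[i, j] <- A[j, i] <- 1
  }
  if (weights == "uniform") {
    Wv <- matrix(0, n, n)
    Wv[ut] <- runif(sum(ut), 0.2, 1.5)
    Wv <- Wv + t(Wv)
    A <- A * Wv
  }
  dimnames(A) <- list(genes, genes)
  gene_network(A, genes, name = paste0("rand", seed))
}

# the 3-node path graph A-B-C with unit weights, used in several hand examples
path3_net <- function() {
  W <- matrix(c(0, 1, 0,
                1, 0, 1,
                0, 1, 0), 3, 3, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  gene_network(W)
}

# wrap an explicit Gram matrix as a kernel_gram (for hand-built examples)
manual_kernel <- function(K, a = 2, q = 1) {
  structure(list(genes = rownames(K), K = K, a = a, q = as.integer(q)),
            class = "kernel_gram")
}

# feature-space embedding phi(v) = Lambda^{1/2} U' e_v from the Gram matrix;
# columns are the embedded genes
phi_embed <- function(K) {
  e <- eigen(K$K, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  Phi <- diag(sqrt(lam), length(lam)) %*% t(e$vectors)
  colnames(Phi) <- K$genes
  Phi
}

# explicit feature-space distances between a candidate and the positive set:
# average, nearest and k-nearest (neighbours selected by kernel value, ties
# broken lexicographically, mirroring the scoring convention)
oracle_distances <- function(K, pos, candidates, k = NULL) {
  Phi <- phi_embed(K)
  sq <- function(v, x) sum((Phi[, v] - Phi[, x])^2)
  d_av <- d_nn <- d_knn <- numeric(length(candidates))
  names(d_av) <- names(d_nn) <- names(d_knn) <- candidates
  for (v in candidates) {
    d <- vapply(pos, function(x) sq(v, x), numeric(1))
    d_av[v] <- mean(d)
    d_nn[v] <- min(d)
    if (!is.null(k)) {
      kv <- K$K[v, pos]
      sel <- order(-kv, pos)[seq_len(min(k, length(pos)))]
      d_knn[v] <- sum(d[sel])
    }
  }
  # eigendecomposition reconstruction carries ~1e-16 noise that would break
  # exact ties (e.g. the many zero kernel entries) differently from the
  # kernel-entry route; snap both routes below 1e-9 before comparing ranks
  list(average = round(d_av, 9), nearest = round(d_nn, 9),
       k_nearest = if (is.null(k)) NULL else round(d_knn, 9))
}

# rank with ties snapped at the oracle's comparison precision
rank_snapped <- function(scores) {
  s <- if (inherits(scores, "score_vector")) scores$scores else scores
  rank_genes(round(s, 9))
}

# brute-force AUC: fraction of correctly ordered positive-negative pairs,
# ties counted 1/2
brute_auc <- function(scores, pos) {
  is_pos <- names(scores) %in% pos
  sp <- scores[is_pos]; sn <- scores[!is_pos]
  tot <- 0
  for (p in sp) tot <- tot + sum(p > sn) + 0.5 * sum(p == sn)
  tot / (length(sp) * length(sn))
}

# a tiny module collection over explicit members
mods_of <- function(...) {
  sets <- list(...)
  module_collection(lapply(seq_along(sets), function(i)
    gene_module(sprintf("M%02d", i), sets[[i]])))
}
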