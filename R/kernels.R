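#' One-step random walk kernel
#'
#' Builds the Gram matrix `K = (a - 1) I + D^{-1/2} W D^{-1/2}` from a
#' network's adjacency `W` with degree matrix `D`. Because the spectrum of the
#' normalized adjacency lies in `[-1, 1]`, any `a > 1` makes `K` positive
#' semidefinite, i.e. a valid kernel: each gene gets an implicit feature-space
#' embedding and `K(v, x)` is the inner product of the embeddings. Entries of
#' `K` thus quantify one-step random-walk similarity between genes.
#'
#' The kernel uses no labels, so it is built once per network and reused
#' across modules and cross-validation folds.
#'
#' @param net a `gene_network` (raw adjacency; normalization is applied here)
#'   with no isolated genes. A `normalized_network` or the output of
#'   [integrate_sum] is accepted and treated as a raw adjacency, keeping the
#'   kernel recipe identical for single and integrated networks.
#' @param a diagonal-shift parameter, must be `> 1`; default 2.
#' @return object of class `kernel_gram` with fields `genes`, `K`, `a`, `q`.
#' @examples
#' net <- gene_network(matrix(c(0, 1, 1, 0), 2, 2,
#'                            dimnames = list(c("A", "B"), c("A", "B"))))
#' one_step_rw_kernel(net)$K  # [[1,1],[1,1]]
#' @export
one_step_rw_kernel <- function(net, a = 2) {
  if (!is.numeric(a) || length(a) != 1 || a <= 1)
    stop("parameter a must be a single value larger than 1")
  deg <- rowSums(net$W)
  if (any(deg == 0))
    stop("isolated gene(s) present; run drop_isolated() first")
  s <- 1 / sqrt(deg)
  K <- net$W * (s %o% s)
  K <- (K + t(K)) / 2
  diag(K) <- diag(K) + (a - 1)
  dimnames(K) <- list(net$genes, net$genes)
  structure(list(genes = net$genes, K = K, a = a, q = 1L),
            class = "kernel_gram")
}

#' q-step random walk kernel
#'
#' The q-step kernel is the q-th matrix power of the one-step kernel,
#' `K_q = K^q`, computed by repeated multiplication. Powers preserve positive
#' semidefiniteness (eigenvalues are raised to the q-th power), and they
#' extend similarity to genes connected through paths of up to `q` edges:
#' with `q = 2` two genes sharing a common neighbour acquire a non-zero
#' kernel entry even without a direct edge. Note that for `q >= 2` the
#' diagonal of `K_q` is in general not constant.
#'
#' @inheritParams one_step_rw_kernel
#' @param q number of random walk steps (positive integer); default 2.
#' @return object of class `kernel_gram`.
#' @export
q_step_rw_kernel <- function(net, a = 2, q = 2) {
  if (!is.numeric(q) || length(q) != 1 || q < 1 || q != round(q))
    stop("parameter q must be a positive integer")
  k1 <- one_step_rw_kernel(net, a = a)
  kernel_power(k1, q)
}

#' Raise an existing kernel Gram matrix to an integer power
#'
#' Convenience for computing several step counts from one normalization pass:
#' `kernel_power(k1, q)` equals [q_step_rw_kernel] with the same `a` and `q`.
#'
#' @param kernel a `kernel_gram` with `q = 1`.
#' @param q target number of steps.
#' @return a `kernel_gram` with the given `q`.
#' @export
kernel_power <- function(kernel, q) {
  stopifnot(inherits(kernel, "kernel_gram"), kernel$q == 1L,
            q >= 1, q == round(q))
  K <- kernel$K
  if (q > 1) for (i in seq_len(q - 1)) K <- K %*% kernel$K
  structure(list(genes = kernel$genes, K = K, a = kernel$a, q = as.integer(q)),
            class = "kernel_gram")
}

#' @export
print.kernel_gram <- function(x, ...) {
  cat(sprintf("<kernel_gram> %d genes, a = %g, q = %d\n",
              length(x$genes), x$a, x$q))
  invisible(x)
}

#' Write / read a kernel Gram matrix cache
#'
#' The cache is a TSV matrix in the same dialect as the network matrix format
#' (first row and column carry gene names), with `a` and `q` recorded on a
#' leading comment line.
#'
#' @param kernel a `kernel_gram`.
#' @param path file path.
#' @export
write_kernel <- function(kernel, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# a=%.17g q=%d", kernel$a, kernel$q), con)
  writeLines(paste(c("gene", kernel$genes), collapse = "\t"), con)
  for (i in seq_along(kernel$genes)) {
    writeLines(paste(c(kernel$genes[i],
                       formatC(kernel$K[i, ], digits = 17, format = "g")),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_kernel
#' @export
read_kernel <- function(path) {
  hdr <- readLines(path, n = 1)
  m <- regmatches(hdr, regexec("^# a=([^ ]+) q=([0-9]+)$", hdr))[[1]]
  if (length(m) != 3) stop("kernel cache header malformed")
  tab <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                           check.names = FALSE, comment.char = "#")
  K <- as.matrix(tab)
  storage.mode(K) <- "double"
  K <- (K + t(K)) / 2
  structure(list(genes = rownames(K), K = K,
                 a = as.numeric(m[2]), q = as.integer(m[3])),
            class = "kernel_gram")
}
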