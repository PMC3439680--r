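#' Construct a gene network
#'
#' A `gene_network` is an undirected, weighted graph over a set of genes,
#' stored as a dense symmetric adjacency matrix with non-negative weights and
#' a zero diagonal. It is the common currency of the package: loaders,
#' normalizers, kernels and the synthetic generator all produce or consume it.
#'
#' @param W square numeric matrix of edge weights; row/column names are taken
#'   as gene identifiers unless `genes` is given.
#' @param genes character vector of gene identifiers (one per row of `W`).
#' @param name label for the network (used in reports and integration weights).
#' @param drop_self_loops if `TRUE` (default), any non-zero diagonal is zeroed
#'   with a warning; if `FALSE` a non-zero diagonal is an error.
#' @return An object of class `gene_network` with fields `genes`, `W`, `name`.
#' @examples
#' W <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
#' net <- gene_network(W)
#' @export
gene_network <- function(W, genes = NULL, name = "network",
                         drop_self_loops = TRUE) {
  if (!is.matrix(W) || !is.numeric(W)) stop("W must be a numeric matrix")
  if (nrow(W) != ncol(W)) stop("W must be square")
  if (is.null(genes)) genes <- rownames(W)
  if (is.null(genes)) stop("gene identifiers required (rownames of W or `genes`)")
  genes <- as.character(genes)
  if (length(genes) != nrow(W)) stop("length(genes) must equal nrow(W)")
  if (anyDuplicated(genes)) stop("duplicate gene identifiers")
  if (any(!is.finite(W))) stop("non-finite edge weights")
  if (any(W < 0)) stop("negative edge weights are not allowed")
  asym <- max(abs(W - t(W)))
  if (asym > 1e-9) stop("adjacency matrix is asymmetric beyond tolerance 1e-9 (max |W - t(W)| = ",
                        format(asym), ")")
  W <- (W + t(W)) / 2  # remove sub-tolerance asymmetry
  if (any(diag(W) != 0)) {
    if (!drop_self_loops) stop("non-zero diagonal (self-loops) present")
    warning("self-loops dropped (diagonal set to 0)")
    diag(W) <- 0
  }
  dimnames(W) <- list(genes, genes)
  structure(list(genes = genes, W = W, name = name), class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  ne <- sum(x$W[upper.tri(x$W)] > 0)
  cat(sprintf("<%s> '%s': %d genes, %d edges\n",
              paste(class(x), collapse = "/"), x$name, length(x$genes), ne))
  invisible(x)
}

#' Node degrees (weighted)
#' @param net a `gene_network` or `normalized_network`.
#' @return named numeric vector of row sums of the adjacency matrix.
#' @export
degrees <- function(net) {
  stats::setNames(rowSums(net$W), net$genes)
}

#' Load a gene network from disk
#'
#' Reads either a tab-separated edge list (`geneA geneB weight`, no header,
#' `#` comment lines allowed) or a square TSV adjacency matrix whose first row
#' and first column carry gene names. Edge lists are symmetrized: when the same
#' unordered pair appears more than once (in either order) the maximum weight
#' is kept. Self-loops are dropped with a warning.
#'
#' @param path file path.
#' @param format `"edgelist"` or `"matrix"`.
#' @param name network label; defaults to the file name.
#' @return a [gene_network].
#' @export
load_network <- function(path, format = c("edgelist", "matrix"), name = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(name)) name <- basename(path)
  if (format == "edgelist") {
    lines <- readLines(path)
    keep <- !grepl("^\\s*(#|$)", lines)
    idx <- which(keep)
    if (length(idx) == 0) stop("no edges in file: ", path)
    parts <- strsplit(lines[idx], "\t", fixed = TRUE)
    bad <- which(lengths(parts) != 3)
    if (length(bad) > 0)
      stop("parse error at line ", idx[bad[1]], ": expected 3 tab-separated fields, got ",
           lengths(parts)[bad[1]])
    ga <- vapply(parts, `[[`, "", 1L)
    gb <- vapply(parts, `[[`, "", 2L)
    w <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3L)))
    if (anyNA(w))
      stop("parse error at line ", idx[which(is.na(w))[1]], ": weight not numeric")
    if (any(w < 0))
      stop("validation error at line ", idx[which(w < 0)[1]], ": negative weight")
    self <- ga == gb
    if (any(self)) {
      warning(sum(self), " self-loop(s) dropped")
      ga <- ga[!self]; gb <- gb[!self]; w <- w[!self]
      if (length(ga) == 0) stop("no edges left after dropping self-loops")
    }
    genes <- sort(unique(c(ga, gb)))
    W <- matrix(0, length(genes), length(genes), dimnames = list(genes, genes))
    # max rule for duplicates, applied per direction then symmetrized by max
    ia <- match(ga, genes); ib <- match(gb, genes)
    for (e in seq_along(w)) {
      W[ia[e], ib[e]] <- max(W[ia[e], ib[e]], w[e])
    }
    W <- pmax(W, t(W))
    gene_network(W, genes, name = name, drop_self_loops = FALSE)
  } else {
    tab <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                             check.names = FALSE, comment.char = "#")
    W <- as.matrix(tab)
    if (nrow(W) != ncol(W)) stop("matrix file is not square")
    if (!identical(rownames(W), colnames(W)))
      stop("matrix row and column gene names do not match")
    storage.mode(W) <- "double"
    gene_network(W, rownames(W), name = name)
  }
}

#' Write a network as a tab-separated edge list
#'
#' Emits one row per unordered pair with positive weight, genes in
#' lexicographic order within and across rows, so output is deterministic.
#'
#' @param net a `gene_network`.
#' @param path output file.
#' @param digits significant digits used for weights.
#' @export
write_network <- function(net, path, digits = 10) {
  ord <- order(net$genes)
  W <- net$W[ord, ord]
  g <- net$genes[ord]
  ut <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  ut <- ut[order(ut[, 1], ut[, 2]), , drop = FALSE]
  lines <- sprintf("%s\t%s\t%s", g[ut[, 1]], g[ut[, 2]],
                   formatC(W[ut], digits = digits, format = "g"))
  writeLines(lines, path)
  invisible(path)
}

#' Remove genes with no interactions
#'
#' Guilt-by-association methods carry no information for a gene with zero
#' degree, and Laplacian normalization is undefined for it; such genes are
#' removed before any downstream step.
#'
#' @param net a `gene_network`.
#' @return a `gene_network` restricted to genes with at least one positive
#'   incident weight.
#' @export
drop_isolated <- function(net) {
  deg <- rowSums(net$W)
  keep <- deg > 0
  if (!any(keep)) stop("all genes are isolated (empty edge set)")
  if (all(keep)) return(net)
  gene_network(net$W[keep, keep, drop = FALSE], net$genes[keep],
               name = net$name)
}

#' Laplacian normalization of a network
#'
#' Rescales the adjacency by inverse square-root degrees,
#' `W_norm = D^{-1/2} W D^{-1/2}` with `d_ii = sum_j w_ij`. The result is
#' symmetric with entries in `[0, 1]` for non-negative inputs, and its
#' spectrum lies in `[-1, 1]` — the property underpinning the positive
#' semidefiniteness of the random-walk kernel.
#'
#' @param net a `gene_network` with no isolated genes.
#' @return an object of class `normalized_network` (fields `genes`, `W`,
#'   `name`); `W` holds the normalized matrix.
#' @export
laplacian_normalize <- function(net) {
  deg <- rowSums(net$W)
  if (any(deg == 0))
    stop("zero-degree gene(s) present; run drop_isolated() first")
  s <- 1 / sqrt(deg)
  Wn <- net$W * (s %o% s)
  Wn <- (Wn + t(Wn)) / 2
  dimnames(Wn) <- list(net$genes, net$genes)
  structure(list(genes = net$genes, W = Wn, name = net$name),
            class = c("normalized_network", "gene_network"))
}

#' Sum-integrate normalized networks
#'
#' Integrates networks over an identical gene universe by summing their
#' Laplacian-normalized adjacency matrices. The sum is returned as a raw
#' `gene_network`: it is re-normalized (or kernelized) downstream exactly like
#' a single network, keeping one uniform recipe for single and integrated data.
#'
#' @param nets list of `normalized_network` objects with identical gene order.
#' @param name label for the integrated network.
#' @return a `gene_network` with `W = sum_i W_norm^(i)`.
#' @export
integrate_sum <- function(nets, name = "integrated") {
  stopifnot(length(nets) >= 1)
  g0 <- nets[[1]]$genes
  for (nt in nets) {
    if (!identical(nt$genes, g0))
      stop("networks must share an identical, identically-ordered gene universe")
  }
  W <- Reduce(`+`, lapply(nets, `[[`, "W"))
  gene_network(W, g0, name = name)
}

#' Construct a gene module
#'
#' A named gene set used as the positive class of a ranking task.
#'
#' @param module_id unique identifier.
#' @param members character vector of member genes (deduplicated).
#' @param description free-text description.
#' @return object of class `gene_module`.
#' @export
gene_module <- function(module_id, members, description = "") {
  stopifnot(is.character(module_id), length(module_id) == 1, nchar(module_id) > 0)
  members <- unique(as.character(members))
  structure(list(module_id = module_id, members = members,
                 description = description), class = "gene_module")
}

#' @export
print.gene_module <- function(x, ...) {
  cat(sprintf("<gene_module> %s: %d genes\n", x$module_id, length(x$members)))
  invisible(x)
}

#' Construct a module collection
#'
#' @param modules list of [gene_module] objects with unique ids.
#' @param universe optional gene universe the modules are resolved against.
#' @return object of class `module_collection`.
#' @export
module_collection <- function(modules, universe = NULL) {
  ids <- vapply(modules, `[[`, "", "module_id")
  if (anyDuplicated(ids)) stop("duplicate module ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  structure(list(modules = stats::setNames(modules, ids), universe = universe),
            class = "module_collection")
}

#' @export
print.module_collection <- function(x, ...) {
  cat(sprintf("<module_collection> %d modules%s\n", length(x$modules),
              if (is.null(x$universe)) "" else
                sprintf(" over %d genes", length(x$universe))))
  invisible(x)
}

#' @export
length.module_collection <- function(x) length(x$modules)

#' Sizes of the modules in a collection
#' @param modules a `module_collection`.
#' @return named integer vector of member counts.
#' @export
module_sizes <- function(modules) {
  vapply(modules$modules, function(m) length(m$members), integer(1))
}

#' Load gene modules from a GMT file
#'
#' Each line is `name<TAB>description<TAB>gene1<TAB>gene2...` (the MSigDB
#' dialect). Genes repeated within a line are deduplicated; a repeated module
#' name across lines is an error.
#'
#' @param path GMT file path.
#' @return a [module_collection].
#' @export
load_modules <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- which(!grepl("^\\s*$", lines))
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad) > 0)
    stop("parse error at line ", keep[bad[1]],
         ": GMT lines need at least 3 tab-separated fields")
  mods <- lapply(parts, function(p) gene_module(p[1], p[-(1:2)], p[2]))
  module_collection(mods)
}

#' Write a module collection as a GMT file
#' @param modules a `module_collection`.
#' @param path output file.
#' @export
write_modules <- function(modules, path) {
  lines <- vapply(modules$modules, function(m) {
    paste(c(m$module_id,
            if (nzchar(m$description)) m$description else "na",
            m$members), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Align networks and modules to a common universe and filter small modules
#'
#' The working gene universe is the set of genes having at least one
#' interaction in every supplied network. All networks are re-indexed to that
#' universe in lexicographic order; module member sets are intersected with
#' it, and modules left with fewer than `min_module_size` members are removed
#' (small modules give unreliable cross-validated estimates).
#'
#' @param nets list of `gene_network` objects.
#' @param modules a `module_collection`.
#' @param min_module_size smallest module retained after intersection
#'   (default 20).
#' @return list with elements `networks` (re-indexed list) and `modules`
#'   (filtered collection, `universe` set).
#' @export
align_and_filter <- function(nets, modules, min_module_size = 20) {
  stopifnot(length(nets) >= 1)
  uni <- NULL
  for (nt in nets) {
    connected <- nt$genes[rowSums(nt$W) > 0]
    uni <- if (is.null(uni)) connected else intersect(uni, connected)
  }
  if (length(uni) == 0)
    stop("empty gene universe: no gene has interactions in every network")
  uni <- sort(uni)
  nets2 <- lapply(nets, function(nt) {
    gene_network(nt$W[uni, uni, drop = FALSE], uni, name = nt$name)
  })
  mods2 <- list()
  for (m in modules$modules) {
    mem <- sort(intersect(m$members, uni))
    if (length(mem) >= min_module_size)
      mods2[[length(mods2) + 1]] <- gene_module(m$module_id, mem, m$description)
  }
  list(networks = nets2,
       modules = module_collection(mods2, universe = uni))
}
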