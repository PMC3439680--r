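test_that("edge-list loader builds symmetric networks and applies the max rule", {
  f <- withr::local_tempfile()
  writeLines(c("A\tB\t1.0"), f)
  net <- load_network(f, "edgelist")
  expect_equal(net$genes, c("A", "B"))
  expect_equal(unname(net$W), matrix(c(0, 1, 1, 0), 2))

  # duplicate pair in both orders: maximum weight wins
  writeLines(c("A\tB\t0.5", "B\tA\t0.7"), f)
  expect_equal(load_network(f, "edgelist")$W["A", "B"], 0.7)

  # self-loop dropped with a warning
  writeLines(c("A\tA\t1.0", "A\tB\t0.3"), f)
  expect_warning(net <- load_network(f, "edgelist"), "self-loop")
  expect_equal(diag(net$W), c(A = 0, B = 0))

  # comment lines ignored
  writeLines(c("# a comment", "A\tB\t2"), f)
  expect_equal(load_network(f, "edgelist")$W["A", "B"], 2)
})

test_that("edge-list loader reports malformed input with line numbers", {
  f <- withr::local_tempfile()
  writeLines(c("A\tB\t1.0", "C\tD"), f)
  expect_error(load_network(f, "edgelist"), "line 2")
  writeLines(c("A\tB\tnot_a_number"), f)
  expect_error(load_network(f, "edgelist"), "line 1")
  writeLines(c("A\tB\t1.0", "B\tC\t-0.2"), f)
  expect_error(load_network(f, "edgelist"), "negative")
  expect_error(load_network(file.path(tempdir(), "nope.tsv")), "not found")
})

test_that("matrix loader validates shape and symmetry", {
  f <- withr::local_tempfile()
  writeLines(c("gene\tA\tB", "A\t0\t1", "B\t1\t0"), f)
  net <- load_network(f, "matrix")
  expect_equal(unname(net$W), matrix(c(0, 1, 1, 0), 2))
  writeLines(c("gene\tA\tB", "A\t0\t1", "B\t0.5\t0"), f)
  expect_error(load_network(f, "matrix"), "asymmetric")
})

test_that("edge list round-trips through write_network exactly", {
  net <- rand_net(15, p = 0.4, seed = 5, weights = "uniform")
  f <- withr::local_tempfile()
  write_network(net, f)
  back <- load_network(f, "edgelist")
  expect_equal(back$genes, net$genes)
  expect_equal(back$W, net$W, tolerance = 1e-9)
})

test_that("Laplacian normalization matches hand computations", {
  # unit degrees: unchanged
  W <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_equal(laplacian_normalize(gene_network(W))$W, W)
  # path graph: off-diagonal entries 1/sqrt(2) (degrees 1, 2, 1)
  nn <- laplacian_normalize(path3_net())
  expect_equal(nn$W["A", "B"], 1 / sqrt(2), tolerance = 1e-9)
  expect_equal(nn$W["B", "C"], 1 / sqrt(2), tolerance = 1e-9)
  expect_equal(nn$W["A", "C"], 0)
  # scaling invariance: 4/sqrt(4*4) = 1
  W4 <- matrix(c(0, 4, 4, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_equal(laplacian_normalize(gene_network(W4))$W["A", "B"], 1)
})

test_that("normalized entries stay in [0,1] and isolated genes are rejected", {
  for (s in 1:5) {
    nn <- laplacian_normalize(rand_net(30, p = 0.2, seed = s, weights = "uniform"))
    expect_true(all(nn$W >= 0 & nn$W <= 1 + 1e-12))
    expect_equal(nn$W, t(nn$W), tolerance = 1e-9)
  }
  W <- matrix(0, 3, 3, dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  W["A", "B"] <- W["B", "A"] <- 1
  expect_error(laplacian_normalize(gene_network(W)), "drop_isolated")
})

test_that("drop_isolated removes exactly the zero-degree genes", {
  W <- matrix(0, 3, 3, dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  W["A", "B"] <- W["B", "A"] <- 1
  net <- drop_isolated(gene_network(W))
  expect_equal(net$genes, c("A", "B"))
  # fully connected triangle: identity
  K3 <- matrix(1, 3, 3, dimnames = list(LETTERS[1:3], LETTERS[1:3])); diag(K3) <- 0
  expect_identical(drop_isolated(gene_network(K3))$genes, LETTERS[1:3])
  # empty edge set: error
  empty <- gene_network(matrix(0, 2, 2, dimnames = list(c("A","B"), c("A","B"))))
  expect_error(drop_isolated(empty), "isolated")
})

test_that("align_and_filter intersects universes and applies the size threshold", {
  set.seed(42)
  genes <- sprintf("g%03d", 1:80)
  mk <- function(gs) {
    W <- matrix(0, length(gs), length(gs), dimnames = list(gs, gs))
    # ring so nobody is isolated
    for (i in seq_along(gs)) {
      j <- if (i == length(gs)) 1 else i + 1
      W[i, j] <- W[j, i] <- 1
    }
    gene_network(W, gs)
  }
  net1 <- mk(genes)          # all 80
  net2 <- mk(genes[1:70])    # first 70
  mods <- mods_of(genes[1:19], genes[1:20], genes[21:45], genes[60:79])
  out <- align_and_filter(list(net1, net2), mods, min_module_size = 20)
  expect_equal(out$modules$universe, sort(genes[1:70]))
  # sizes after intersection: 19, 20, 25, 11 -> retain the 20 and the 25
  expect_equal(unname(module_sizes(out$modules)), c(20, 25))
  expect_true(all(vapply(out$networks, function(n)
    identical(n$genes, out$modules$universe), logical(1))))
  # modules already inside a single network's universe pass through unchanged
  out1 <- align_and_filter(list(net1), mods_of(genes[1:25]), min_module_size = 20)
  expect_equal(out1$modules$modules$M01$members, sort(genes[1:25]))
  # disjoint universes: empty intersection
  net3 <- mk(sprintf("x%03d", 1:10))
  expect_error(align_and_filter(list(net1, net3), mods), "empty")
})

test_that("integrate_sum adds normalized matrices and is order-independent", {
  g2 <- c("A", "B")
  n1 <- structure(list(genes = g2,
                       W = matrix(c(0, 1, 1, 0), 2, dimnames = list(g2, g2)),
                       name = "n1"),
                  class = c("normalized_network", "gene_network"))
  n2 <- n1; n2$W <- n2$W * 0.5; n2$name <- "n2"
  expect_equal(integrate_sum(list(n1))$W, n1$W)
  expect_equal(integrate_sum(list(n1, n1))$W, 2 * n1$W)
  expect_equal(integrate_sum(list(n1, n2))$W["A", "B"], 1.5)
  # commutative and associative
  n3 <- n1; n3$W <- n3$W * 0.25
  expect_equal(integrate_sum(list(n1, n2, n3))$W,
               integrate_sum(list(n3, n1, n2))$W)
  expect_equal(integrate_sum(list(integrate_sum(list(n1, n2)), n3))$W,
               integrate_sum(list(n1, integrate_sum(list(n2, n3))))$W)
  n4 <- n1; n4$genes <- c("A", "C"); dimnames(n4$W) <- list(n4$genes, n4$genes)
  expect_error(integrate_sum(list(n1, n4)), "universe")
})

test_that("GMT loader parses, deduplicates and rejects malformed files", {
  f <- withr::local_tempfile()
  writeLines(c("M1\tdesc\tA\tB\tC", "M2\tdesc\tA\tA\tB"), f)
  mods <- load_modules(f)
  expect_equal(length(mods), 2L)
  expect_equal(mods$modules$M1$members, c("A", "B", "C"))
  expect_equal(mods$modules$M2$members, c("A", "B"))  # within-line dedup
  writeLines(c("M1\tdesc\tA", "M1\tdesc\tB"), f)
  expect_error(load_modules(f), "duplicate")
  writeLines(c("M1\tdesc"), f)
  expect_error(load_modules(f), "line 1")
  # round trip
  writeLines(c("M1\tdesc\tA\tB\tC"), f)
  mods <- load_modules(f)
  f2 <- withr::local_tempfile()
  write_modules(mods, f2)
  expect_equal(load_modules(f2)$modules$M1$members, c("A", "B", "C"))
})

test_that("gene_network constructor enforces its invariants", {
  W <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_silent(gene_network(W))
  Wn <- W; Wn[1, 2] <- -1; Wn[2, 1] <- -1
  expect_error(gene_network(Wn), "negative")
  Wa <- W; Wa[1, 2] <- 1.1
  expect_error(gene_network(Wa), "asymmetric")
  Wd <- W; diag(Wd) <- 2
  expect_warning(gene_network(Wd), "self-loops")
})
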