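# Adjacency, clustering, module cut, eigengenes, module-trait correlation.

rand_fpkm <- function(v) {
  expression_matrix(v, rep(1000, nrow(v)),
                    rep("protein_coding", nrow(v)), "fpkm")
}

test_that("adjacency is |cor|^beta with unit diagonal on [0, 1]", {
  set.seed(41)
  v <- matrix(rlnorm(20 * 30, 2, 1), nrow = 20,
              dimnames = list(sprintf("g%02d", 1:20),
                              sprintf("c%02d", 1:30)))
  x <- rand_fpkm(v)
  A1 <- build_adjacency(x, config = module_config(soft_power = 1))
  C <- abs(cor(t(log2(v + 1))))
  expect_equal(unname(A1), unname(C), tolerance = 1e-12)
  A6 <- build_adjacency(x, config = module_config(soft_power = 6))
  expect_equal(unname(A6), unname(C^6), tolerance = 1e-12)
  expect_true(isSymmetric(A6))
  expect_true(all(A6 >= 0 & A6 <= 1))
  expect_equal(unname(diag(A6)), rep(1, 20))

  # a perfectly correlated pair has adjacency 1 for any beta
  v2 <- v
  v2[2, ] <- 2 * v2[1, ] + 1
  A <- build_adjacency(rand_fpkm(2^v2 - 1))  # log2(x+1) linearizes
  expect_equal(A[1, 2], 1, tolerance = 1e-12)

  # independent pairs at beta = 6, 53 cells: tiny expected adjacency
  set.seed(42)
  v3 <- matrix(rlnorm(40 * 53, 2, 1), nrow = 40,
               dimnames = list(sprintf("g%02d", 1:40),
                               sprintf("c%02d", 1:53)))
  A <- build_adjacency(rand_fpkm(v3))
  expect_lt(mean(A[upper.tri(A)]), 0.01)

  # constant gene: zero correlations with a warning
  v3[1, ] <- 7
  expect_warning(Ac <- build_adjacency(rand_fpkm(v3)), "constant")
  expect_equal(unname(Ac[1, -1]), rep(0, 39))
})

test_that("cluster_genes reproduces a hand-computed UPGMA trace", {
  D <- matrix(c(0, 0.1, 0.9,
                0.1, 0, 0.7,
                0.9, 0.7, 0), nrow = 3,
              dimnames = list(c("g1", "g2", "g3"), c("g1", "g2", "g3")))
  tree <- cluster_genes(1 - D)  # adjacency = 1 - dissimilarity here
  # merge 1: g1 + g2 at 0.1; merge 2: {g1,g2} + g3 at (0.9 + 0.7) / 2
  expect_equal(tree$height, c(0.1, 0.8))
  expect_identical(tree$labels[abs(tree$merge[1, ])], c("g1", "g2"))

  # permuting gene order yields an isomorphic tree (same heights)
  perm <- c(3, 1, 2)
  tree2 <- cluster_genes((1 - D)[perm, perm])
  expect_equal(tree2$height, tree$height)
})

test_that("cut_modules separates blocks, greys independents, merges twins", {
  # two blocks of near-identical genes -> two modules
  set.seed(43)
  f1 <- rnorm(40); f2 <- rnorm(40)
  v <- rbind(t(replicate(12, 2^(5 + f1 + rnorm(40, 0, 0.05)))),
             t(replicate(12, 2^(5 + f2 + rnorm(40, 0, 0.05)))))
  dimnames(v) <- list(sprintf("g%02d", 1:24), sprintf("c%02d", 1:40))
  x <- rand_fpkm(v)
  A <- build_adjacency(x)
  asg <- cut_modules(cluster_genes(A), x)
  expect_equal(length(setdiff(unique(asg), "grey")), 2)
  expect_equal(length(unique(asg[1:12])), 1)
  expect_equal(length(unique(asg[13:24])), 1)

  # all-independent genes -> all grey
  set.seed(44)
  vi <- matrix(rlnorm(60 * 53, 2, 1), nrow = 60,
               dimnames = list(sprintf("g%02d", 1:60),
                               sprintf("c%02d", 1:53)))
  xi <- rand_fpkm(vi)
  asg_i <- cut_modules(cluster_genes(build_adjacency(xi)), xi)
  expect_identical(unique(unclass(asg_i)), "grey")

  # two modules driven by the same factor are merged into one
  set.seed(45)
  f <- rnorm(40)
  vm <- t(replicate(24, 2^(5 + f + rnorm(40, 0, 0.3))))
  dimnames(vm) <- list(sprintf("g%02d", 1:24), sprintf("c%02d", 1:40))
  xm <- rand_fpkm(vm)
  asg_m <- cut_modules(cluster_genes(build_adjacency(xm)), xm)
  expect_equal(length(setdiff(unique(asg_m), "grey")), 1)
})

test_that("module eigengene recovers the latent factor with sign rule", {
  # module of identical genes: eigengene is the standardized profile
  set.seed(46)
  prof <- rlnorm(30, 3, 1)
  v <- t(replicate(11, prof))
  dimnames(v) <- list(sprintf("g%02d", 1:11), sprintf("c%02d", 1:30))
  eg <- module_eigengene(rand_fpkm(v), rownames(v))
  z <- log2(prof + 1)
  expect_equal(unname(eg$scores), unname((z - mean(z)) / sd(z)),
               tolerance = 1e-8)
  expect_equal(eg$var_explained, 1, tolerance = 1e-12)

  # planted one-factor module: |cor(eigengene, factor)| >= 0.9 and the
  # sign convention makes the correlation with module mean positive
  f <- rnorm(30)
  v2 <- t(replicate(15, 2^(4 + f + rnorm(30, 0, 0.4))))
  dimnames(v2) <- list(sprintf("g%02d", 1:15), sprintf("c%02d", 1:30))
  eg2 <- module_eigengene(rand_fpkm(v2), rownames(v2))
  expect_gte(abs(cor(eg2$scores, f)), 0.9)
  expect_gte(cor(eg2$scores, colMeans(log2(v2 + 1))), 0)
  expect_equal(sd(eg2$scores), 1, tolerance = 1e-12)
})

test_that("module_trait matches the closed-form t-distribution p-values", {
  set.seed(47)
  ME <- matrix(rnorm(30 * 3), ncol = 3,
               dimnames = list(sprintf("c%02d", 1:30),
                               c("blue", "brown", "turquoise")))
  trait <- rep(c(1, 0), each = 15)
  mt <- module_trait(ME, trait)
  expect_true(isSymmetric(mt$correlation))
  expect_equal(unname(diag(mt$correlation)), rep(1, 4))
  expect_identical(colnames(mt$correlation)[4], "white")
  # p-values against cor.test as an independent implementation
  for (i in 1:3) {
    ct <- cor.test(ME[, i], trait)
    expect_equal(mt$p_value[i, "white"], ct$p.value, tolerance = 1e-10)
    expect_equal(mt$correlation[i, "white"], unname(ct$estimate),
                 tolerance = 1e-12)
  }
  # an eigengene equal to the trait correlates exactly 1
  ME2 <- cbind(ME, exact = as.numeric(scale(trait)))
  mt2 <- module_trait(ME2, trait)
  expect_equal(mt2$correlation["exact", "white"], 1, tolerance = 1e-12)
  expect_lt(mt2$p_value["exact", "white"], 1e-12)
  expect_error(module_trait(ME, rep(1, 30)), "constant")
})

test_that("module assignment is equivariant under cell permutation", {
  fx <- gen_expression_cohort(expr_sim_params(n_ls = 20, n_ns = 10,
                                              n_genes = 600,
                                              n_de_genes = 0,
                                              n_modules = 3,
                                              module_size = 15, seed = 6))
  fpkm <- compute_fpkm(fx$matrix)
  genes <- names(fx$truth$module_assignments)
  cx1 <- run_coexpression(fpkm, genes, fx$truth$cell_labels == "LS")
  set.seed(48)
  perm <- sample(ncol(fpkm$values))
  fpkm_p <- fpkm[, perm]
  cx2 <- run_coexpression(fpkm_p, genes,
                          (fx$truth$cell_labels == "LS")[perm])
  expect_identical(unclass(cx1$assignment), unclass(cx2$assignment))
})
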