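test_that("simple matching distances count per-site state identity", {
  geno <- tibble::tibble(
    contig = "c1", pos = 0:2, ref_allele = "A", var_allele = "T",
    a = c("AA", "AB", "BB"),
    b = c("AA", "AB", "BB"),
    c = c("BB", "BB", "AA")
  )
  smd <- simple_matching_distance(geno)
  expect_equal(smd$distance["a", "b"], 0)
  expect_equal(smd$distance["a", "c"], 1)
  expect_equal(diag(smd$distance), c(a = 0, b = 0, c = 0))
  expect_true(isSymmetric(smd$distance))

  # missing entries are excluded pairwise
  geno$b[1] <- NA
  smd <- simple_matching_distance(geno)
  expect_equal(smd$n_compared["a", "b"], 2)
  expect_equal(smd$distance["a", "b"], 0)

  # an all-missing overlap is an error naming the pair
  geno$b <- c(NA, NA, NA)
  expect_error(simple_matching_distance(geno), "no comparable sites")
})

test_that("random matrices match the exhaustive per-site comparison oracle", {
  set.seed(19)
  for (r in 1:10) {
    states <- matrix(sample(c("AA", "AB", "BB", NA), 20 * 5, TRUE,
                            prob = c(.3, .3, .3, .1)), 20, 5,
                     dimnames = list(NULL, letters[1:5]))
    geno <- dplyr::bind_cols(
      tibble::tibble(contig = "c", pos = 0:19, ref_allele = "A",
                     var_allele = "T"),
      tibble::as_tibble(states)
    )
    smd <- simple_matching_distance(geno)
    for (i in 1:4) for (j in (i + 1):5) {
      both <- !is.na(states[, i]) & !is.na(states[, j])
      want <- 1 - sum(states[both, i] == states[both, j]) / sum(both)
      expect_equal(smd$distance[i, j], want)
      expect_equal(smd$n_compared[i, j], sum(both))
    }
  }
})

test_that("three taxa yield the closed-form star tree", {
  d <- matrix(c(0, .3, .4,
                .3, 0, .5,
                .4, .5, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tree <- neighbor_joining(d)
  expect_equal(nrow(tree$edge), 3)
  expect_equal(tree$Nnode, 1L)
  limb <- setNames(tree$edge.length, tree$tip.label[tree$edge[, 2]])
  expect_equal(limb[["a"]], (.3 + .4 - .5) / 2)
  expect_equal(limb[["b"]], (.3 + .5 - .4) / 2)
  expect_equal(limb[["c"]], (.4 + .5 - .3) / 2)
})

test_that("4-taxon additive matrices are solved exactly, as the LS oracle confirms", {
  set.seed(23)
  for (r in 1:10) {
    tr <- random_additive_tree(4)
    d <- tree_dist(tr)
    nj <- neighbor_joining(d)
    expect_equal(tree_dist(nj), d, tolerance = 1e-12)
    oracle <- oracle_nj4(d)
    expect_lt(oracle$rss, 1e-20)
    nj_splits <- tree_splits(nj)
    cherries <- nj_splits[vapply(nj_splits, length, 1L) == 2]
    expect_true(any(vapply(cherries, identical, TRUE, oracle$split[[1]]) |
                      vapply(cherries, identical, TRUE, oracle$split[[2]])))
  }
})

test_that("additive distances on 4-8 taxa are reproduced at machine precision", {
  set.seed(29)
  for (n in 4:8) {
    tr <- random_additive_tree(n)
    d <- tree_dist(tr)
    nj <- neighbor_joining(d)
    expect_equal(tree_dist(nj), d, tolerance = 1e-12)
    expect_equal(nrow(nj$edge), 2 * n - 3)
    # same unrooted topology as the ape reference implementation
    ref <- ape::nj(d)
    expect_equal(phangorn::RF.dist(ape::unroot(nj), ape::unroot(ref)), 0)
  }
})

test_that("Q-criterion ties break on the lexicographically smallest leaf pair", {
  # four equidistant taxa: every Q is tied; the (a, b) cherry must be chosen
  labs <- c("d", "b", "c", "a")
  d <- matrix(1, 4, 4, dimnames = list(labs, labs))
  diag(d) <- 0
  tree <- neighbor_joining(d)
  cherries <- tree_splits(tree)
  cherries <- cherries[vapply(cherries, length, 1L) == 2]
  expect_true(list(c("a", "b")) %in% cherries)
})

test_that("non-symmetric matrices are rejected and negatives can be clamped", {
  d <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(neighbor_joining(d), "symmetric|3 taxa")
  d3 <- matrix(c(0, .2, .9, .2, 0, .3, .9, .3, 0), 3, 3,
               dimnames = list(letters[1:3], letters[1:3]))
  tr <- neighbor_joining(d3)               # limb c of a is negative here
  expect_true(any(tr$edge.length < 0))
  tr2 <- neighbor_joining(d3, clamp_negative = TRUE)
  expect_true(all(tr2$edge.length >= 0))
})

test_that("groups diverged at F = 0.3 are monophyletic in the NJ tree", {
  gs <- alfalfa_groups()
  cfg <- panel_config(
    groups = gs, n_contigs = 60, sites_per_contig = 10,
    group_f = c(Group1 = 0.3, Group2 = 0.3, Group3 = 0.3),
    mean_depth = 60, depth_dispersion = Inf, error_rate = 0,
    quality_sd = 0, indel_rate = 0, seed = 47
  )
  panel <- simulate_panel(cfg)
  calls <- call_variants(panel$counts)
  geno <- core_set(calls, panel$counts)
  tree <- neighbor_joining(simple_matching_distance(geno))
  splits <- tree_splits(tree)
  all_tips <- sort(gs$genotype)
  has_split <- function(ids) {
    ids <- sort(ids)
    comp <- sort(setdiff(all_tips, ids))
    any(vapply(splits, identical, TRUE, ids) |
          vapply(splits, identical, TRUE, comp))
  }
  for (grp in c("Group1", "Group2", "Group3")) {
    expect_true(has_split(gs$genotype[gs$group == grp]), label = grp)
  }
})

test_that("newick output round-trips and quotes awkward labels", {
  d <- matrix(c(0, .3, .4, .3, 0, .5, .4, .5, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tree <- neighbor_joining(d)
  path <- withr::local_tempfile(fileext = ".nwk")
  nwk <- write_newick(tree, path)
  expect_match(nwk, "^\\(.*\\);$")
  back <- ape::read.tree(path)
  expect_setequal(back$tip.label, c("a", "b", "c"))
  expect_equal(tree_dist(back), tree_dist(tree), tolerance = 1e-6)

  # labels with spaces (e.g. "CW A-9") survive via Newick quoting; the
  # parentheses inside the quoted label must not break parsing (ape keeps
  # the quote characters themselves)
  tree$tip.label <- c("CW A-9", "plain", "als(o) bad")
  nwk <- write_newick(tree, path)
  back <- ape::read.tree(path)
  expect_setequal(gsub("^'|'$", "", back$tip.label),
                  c("CW A-9", "plain", "als(o) bad"))

  # larger round trip: topology preserved exactly
  set.seed(3)
  tr <- random_additive_tree(9)
  nj <- neighbor_joining(tree_dist(tr))
  write_newick(nj, path)
  back <- ape::read.tree(path)
  expect_equal(phangorn::RF.dist(ape::unroot(back), ape::unroot(nj)), 0)
})

test_that("PCA satisfies its spectral identities", {
  geno <- tibble::tibble(
    contig = "c1", pos = 0:3, ref_allele = "A", var_allele = "T",
    a = c("AA", "AA", "AB", "BB"),
    b = c("AA", "AA", "AB", "BB"),   # identical to a
    c = c("BB", "BB", "AA", "AA")
  )
  pca <- snp_pca(geno)
  sa <- as.numeric(pca$scores[pca$scores$genotype == "a", -1])
  sb <- as.numeric(pca$scores[pca$scores$genotype == "b", -1])
  expect_equal(sa, sb, tolerance = 1e-10)
  expect_equal(sum(pca$variance_fraction), 1)
  expect_true(all(diff(pca$variance_fraction) <= 1e-12))

  # constant matrix: no variance anywhere
  const <- dplyr::mutate(geno, a = "AA", b = "AA", c = "AA")
  pca0 <- snp_pca(const)
  expect_true(all(pca0$variance_fraction == 0))
})

test_that("PCA eigenvalues match the characteristic-polynomial roots", {
  geno <- tibble::tibble(
    contig = "c1", pos = 0:2, ref_allele = "A", var_allele = "T",
    a = c("AA", "AB", "BB"),
    b = c("AB", "BB", "AA"),
    c = c("BB", "AA", "AB")
  )
  pca <- snp_pca(geno)
  x <- rbind(c(0, 1, 2), c(1, 2, 0), c(2, 0, 1))
  xc <- scale(x, center = TRUE, scale = FALSE)
  cv <- crossprod(xc)  # eigenvalues of X'X are (n-1)-scaled covariances
  # characteristic polynomial coefficients of the 3x3 matrix, roots as oracle
  c0 <- -det(cv)
  c1 <- sum(diag(cv) * diag(cv)[c(2, 3, 1)]) - cv[1, 2]^2 - cv[1, 3]^2 - cv[2, 3]^2
  c2 <- -sum(diag(cv))
  roots <- sort(Re(polyroot(c(c0, c1, c2, 1))), decreasing = TRUE)
  got <- pca$sdev^2 * (nrow(x) - 1)
  expect_equal(got, roots[seq_along(got)], tolerance = 1e-8)
})

test_that("PCA scores are order-invariant up to sign", {
  set.seed(9)
  states <- matrix(sample(c("AA", "AB", "BB"), 60, TRUE), 12, 5,
                   dimnames = list(NULL, letters[1:5]))
  base <- dplyr::bind_cols(
    tibble::tibble(contig = "c", pos = 0:11, ref_allele = "A",
                   var_allele = "T"),
    tibble::as_tibble(states)
  )
  perm <- base[c(names(base)[1:4], "e", "c", "a", "b", "d")]
  p1 <- snp_pca(base)
  p2 <- snp_pca(perm)
  expect_equal(p1$variance_fraction, p2$variance_fraction, tolerance = 1e-10)
  for (k in 1:4) {
    s1 <- p1$scores[[paste0("PC", k)]][match(letters[1:5], p1$scores$genotype)]
    s2 <- p2$scores[[paste0("PC", k)]][match(letters[1:5], p2$scores$genotype)]
    expect_true(isTRUE(all.equal(s1, s2, tolerance = 1e-8)) ||
                  isTRUE(all.equal(s1, -s2, tolerance = 1e-8)))
  }
})

test_that("PCA separates diverged groups (positive silhouette on PC1-PC2)", {
  gs <- alfalfa_groups()
  cfg <- panel_config(
    groups = gs, n_contigs = 60, sites_per_contig = 10,
    group_f = c(Group1 = 0.3, Group2 = 0.3, Group3 = 0.3),
    mean_depth = 60, depth_dispersion = Inf, error_rate = 0,
    quality_sd = 0, indel_rate = 0, seed = 51
  )
  panel <- simulate_panel(cfg)
  geno <- core_set(call_variants(panel$counts), panel$counts)
  pca <- snp_pca(geno)
  xy <- as.matrix(pca$scores[c("PC1", "PC2")])
  lab <- gs$group[match(pca$scores$genotype, gs$genotype)]
  dmat <- as.matrix(dist(xy))
  sil <- vapply(seq_len(nrow(xy)), function(i) {
    a <- mean(dmat[i, lab == lab[i] & seq_len(nrow(xy)) != i])
    b <- min(vapply(setdiff(unique(lab), lab[i]), function(g) {
      mean(dmat[i, lab == g])
    }, double(1)))
    (b - a) / max(a, b)
  }, double(1))
  expect_gt(mean(sil), 0)
})

test_that("distance matrices export as PHYLIP square text", {
  d <- matrix(c(0, .25, .25, 0), 2, 2, dimnames = list(c("a", "b"), NULL))
  path <- withr::local_tempfile()
  write_distance_phylip(d, path)
  lines <- readLines(path)
  expect_equal(trimws(lines[1]), "2")
  expect_match(lines[2], "^a\\s+0\\.000000 0\\.250000$")
})
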