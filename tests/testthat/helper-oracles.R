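# Independent oracles: literal transcriptions and brute-force routines kept
# deliberately separate from the package implementation.

`%||%` <- function(x, y) if (is.null(x)) y else x

# literal per-genotype transcription of the three filter-cascade rules for
# one site given as plain vectors
oracle_verdict <- function(ref, var, qual, params = filter_params()) {
  supports <- logical(length(ref))
  for (g in seq_along(ref)) {
    depth <- ref[g] + var[g]
    supports[g] <- depth > 0 &&
      var[g] >= params$min_var_reads &&
      qual[g] >= params$min_mean_quality &&
      var[g] / depth >= params$min_var_fraction
  }
  if (!any(supports)) return("sample_support")
  if (!(sum(ref) + sum(var) > params$min_total_reads_exclusive)) {
    return("total_depth")
  }
  p <- oracle_chisq(ref, var)$p
  if (!(p < params$alpha)) return("contingency")
  "PASS"
}

# direct-formula Pearson chi-square on the 2 x K table (zero-depth columns
# dropped), p from the chi-square tail
oracle_chisq <- function(ref, var) {
  keep <- ref + var > 0
  ref <- ref[keep]
  var <- var[keep]
  if (length(ref) < 2) return(list(stat = NA_real_, p = 1))
  tab <- rbind(ref, var)
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum(ifelse(e > 0, (tab - e)^2 / e, 0))
  if (sum(var) == 0 || sum(ref) == 0) return(list(stat = stat, p = 1))
  list(stat = stat, p = pchisq(stat, df = ncol(tab) - 1, lower.tail = FALSE))
}

# one-site long tibble from plain vectors
site_tibble <- function(ref, var, qual = rep(30, length(ref)),
                        genotypes = sprintf("g%02d", seq_along(ref)),
                        contig = "c1", pos = 0L,
                        variant_class = "SNP") {
  tibble::tibble(
    contig = contig, pos = as.integer(pos), ref_allele = "A",
    var_allele = "T", variant_class = variant_class,
    genotype = factor(genotypes, levels = genotypes),
    ref_reads = as.numeric(ref), var_reads = as.numeric(var),
    mean_var_quality = as.numeric(qual)
  )
}

# random small site-count tables for cascade equivalence checks
random_sites <- function(n_sites, max_genotypes = 6, max_depth = 15,
                         genotypes = sprintf("g%02d", seq_len(max_genotypes))) {
  purrr::map_dfr(seq_len(n_sites), function(i) {
    depth <- sample.int(max_depth + 1, length(genotypes), replace = TRUE) - 1L
    var <- vapply(depth, function(d) sample.int(d + 1, 1) - 1L, integer(1))
    site_tibble(
      ref = depth - var, var = var,
      qual = round(runif(length(genotypes), 0, 41), 1),
      genotypes = genotypes,
      contig = sprintf("c%04d", i), pos = 0L
    )
  })
}

# brute-force Venn region tabulation over a logical flag matrix
oracle_venn <- function(flags, grps) {
  res <- list()
  for (i in seq_len(nrow(flags))) {
    z <- flags[i, ]
    if (any(is.na(z)) || !any(z)) next
    pat <- paste(as.integer(z), collapse = "")
    res[[pat]] <- (res[[pat]] %||% 0L) + 1L
  }
  res
}

# exhaustive 4-taxon NJ oracle: enumerate the 3 unrooted topologies, fit the
# 5 branch lengths by least squares on the 6 pairwise distances, return the
# best-fitting tree's split and lengths
oracle_nj4 <- function(d) {
  stopifnot(nrow(d) == 4)
  labs <- rownames(d)
  pairs <- list(c(1, 2), c(1, 3), c(1, 4))
  best <- NULL
  dv <- d[lower.tri(d)]  # order: (2,1),(3,1),(4,1),(3,2),(4,2),(4,3)
  pair_index <- rbind(c(2, 1), c(3, 1), c(4, 1), c(3, 2), c(4, 2), c(4, 3))
  for (pr in pairs) {
    cherry1 <- pr
    cherry2 <- setdiff(1:4, pr)
    # unknowns: e1..e4 (limbs of taxa 1..4), e5 internal
    design <- t(apply(pair_index, 1, function(ij) {
      row <- numeric(5)
      row[ij[1]] <- 1
      row[ij[2]] <- 1
      same_cherry <- (all(ij %in% cherry1)) || (all(ij %in% cherry2))
      if (!same_cherry) row[5] <- 1
      row
    }))
    fit <- stats::lm.fit(design, dv)
    rss <- sum(fit$residuals^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(
        rss = rss,
        split = list(sort(labs[cherry1]), sort(labs[cherry2])),
        lengths = stats::setNames(fit$coefficients,
                                  c(labs, "internal"))
      )
    }
  }
  best
}

# random binary unrooted tree with positive branch lengths, as an ape phylo
random_additive_tree <- function(n_taxa) {
  ape::rtree(n_taxa, rooted = FALSE, br = function(k) runif(k, 0.1, 1))
}

# unordered splits (as sorted tip-label sets) induced by internal edges
tree_splits <- function(tree) {
  n <- length(tree$tip.label)
  desc <- function(node) {
    if (node <= n) return(tree$tip.label[node])
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, desc))
  }
  internal <- tree$edge[tree$edge[, 2] > n, 2]
  lapply(internal, function(nd) sort(desc(nd)))
}

# path-length matrix of a phylo tree (via ape, independent of the NJ code)
tree_dist <- function(tree) {
  m <- ape::cophenetic.phylo(tree)
  m[order(rownames(m)), order(colnames(m))]
}
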