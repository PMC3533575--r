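#' Simple-matching distances between genotypes
#'
#' For each genotype pair, the distance is one minus the fraction of sites,
#' among those where both calls are non-missing, at which the two genotypes
#' carry identical states (exact match over `AA`/`AB`/`BB`).
#'
#' @param geno Wide genotype-matrix tibble (see [core_set()]).
#' @return An object of class `sm_dist`: a list with `distance` (symmetric
#'   named matrix, zero diagonal, entries in `[0, 1]`) and `n_compared`
#'   (matrix of per-pair comparable-site counts).
#' @export
#' @examples
#' gs <- group_spec(c("a", "b"), 4, "G")
#' gm <- tibble::tibble(contig = "c", pos = 0:2, ref_allele = "A",
#'                      var_allele = "T",
#'                      a = c("AA", "AB", "BB"), b = c("AA", "AB", "AA"))
#' simple_matching_distance(gm)$distance
simple_matching_distance <- function(geno) {
  genotypes <- matrix_genotypes(geno)
  if (length(genotypes) < 2) abort("need at least 2 genotypes")
  s <- state_matrix(geno, genotypes)
  obs <- !is.na(s)
  n_comp <- crossprod(obs)
  matches <- matrix(0, length(genotypes), length(genotypes))
  for (st in .STATES) {
    ind <- (s == st) & obs
    matches <- matches + crossprod(ind)
  }
  off <- n_comp == 0 & !diag(TRUE, length(genotypes))
  if (any(off)) {
    bad <- which(off, arr.ind = TRUE)[1, ]
    abort(sprintf("no comparable sites between '%s' and '%s'",
                  genotypes[bad[1]], genotypes[bad[2]]))
  }
  d <- 1 - matches / n_comp
  diag(d) <- 0
  dimnames(d) <- dimnames(n_comp) <- list(genotypes, genotypes)
  structure(list(distance = d, n_compared = n_comp), class = "sm_dist")
}

#' @export
print.sm_dist <- function(x, ...) {
  cat("<sm_dist>", nrow(x$distance), "genotypes\n")
  print(round(x$distance, 4))
  invisible(x)
}

#' @describeIn simple_matching_distance Tidy the pairwise distances into a
#'   long tibble (`genotype_a`, `genotype_b`, `distance`, `n_compared`), one
#'   row per unordered pair.
#' @param x An `sm_dist` object.
#' @param ... Unused.
#' @method tidy sm_dist
#' @export
tidy.sm_dist <- function(x, ...) {
  ids <- rownames(x$distance)
  pairs <- which(upper.tri(x$distance), arr.ind = TRUE)
  tibble(
    genotype_a = ids[pairs[, 1]],
    genotype_b = ids[pairs[, 2]],
    distance = x$distance[pairs],
    n_compared = as.integer(x$n_compared[pairs])
  )
}

#' Write a distance matrix in PHYLIP square format
#'
#' @param dist An `sm_dist` object or a symmetric matrix with dimnames.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_distance_phylip <- function(dist, path) {
  d <- if (inherits(dist, "sm_dist")) dist$distance else dist
  lines <- c(
    sprintf("%5d", nrow(d)),
    vapply(seq_len(nrow(d)), function(i) {
      paste0(formatC(rownames(d)[i], width = -12), " ",
             paste(sprintf("%.6f", d[i, ]), collapse = " "))
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Unweighted neighbor-joining tree
#'
#' Classical Saitou-Nei agglomeration: at each step the pair minimising the
#' Q-criterion `Q(i,j) = (n-2) d(i,j) - sum_k d(i,k) - sum_k d(j,k)` is
#' joined, with limb lengths from the standard formulas; the final three
#' nodes are joined into the central trifurcation of the unrooted tree. Ties
#' in Q are broken deterministically by the lexicographically smallest pair
#' of representative leaf labels. On an additive distance matrix the tree
#' reproduces all pairwise path lengths exactly.
#'
#' @param dist An `sm_dist` object or a symmetric numeric matrix (zero
#'   diagonal) with genotype names as dimnames; at least 3 taxa.
#' @param clamp_negative If `TRUE`, negative branch lengths (possible under
#'   classical NJ) are clamped to zero; default keeps them.
#' @return An unrooted tree of class `phylo` (ape-compatible: `edge`,
#'   `edge.length`, `tip.label`, `Nnode`), with `2n - 3` edges.
#' @export
neighbor_joining <- function(dist, clamp_negative = FALSE) {
  d <- if (inherits(dist, "sm_dist")) dist$distance else as.matrix(dist)
  if (!isSymmetric(unname(d), tol = 1e-8)) {
    abort("distance matrix must be symmetric")
  }
  n <- nrow(d)
  if (n < 3) abort("neighbor joining needs at least 3 taxa")
  labels <- rownames(d) %||% paste0("t", seq_len(n))

  # each active node: a nested-list subtree and its representative (the
  # lexicographically smallest leaf label it contains)
  nodes <- lapply(seq_len(n), function(i) list(leaf = labels[i]))
  reps <- labels
  D <- unname(d)

  join_pair <- function() {
    m <- nrow(D)
    r <- rowSums(D)
    q <- (m - 2) * D - outer(r, r, `+`)
    diag(q) <- Inf
    qmin <- min(q)
    cand <- which(q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- vapply(seq_len(nrow(cand)), function(i) {
      pr <- sort(c(reps[cand[i, 1]], reps[cand[i, 2]]))
      paste(pr, collapse = "\r")
    }, character(1))
    cand[order(key)[1], ]
  }

  while (nrow(D) > 3) {
    m <- nrow(D)
    ij <- join_pair()
    i <- ij[1]; j <- ij[2]
    r <- rowSums(D)
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    new_node <- list(children = list(nodes[[i]], nodes[[j]]),
                     lengths = c(li, lj))
    new_d <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], new_d[keep]),
                c(new_d[keep], 0))
    nodes <- c(nodes[keep], list(new_node))
    reps <- c(reps[keep], min(reps[c(i, j)]))
    D <- D2
  }

  la <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  lb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  lc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  ord <- order(reps)
  root <- list(children = nodes[ord],
               lengths = c(la, lb, lc)[ord])

  build_phylo(root, labels, clamp_negative)
}

# convert the nested-list tree into an ape-style phylo object, numbering
# internal nodes in preorder from the central node (n + 1)
build_phylo <- function(root, labels, clamp_negative) {
  n <- length(labels)
  edge_parent <- integer(0)
  edge_child <- integer(0)
  edge_len <- double(0)
  next_internal <- n + 1L

  visit <- function(node, parent_id, length_in) {
    if (!is.null(node$leaf)) {
      id <- match(node$leaf, labels)
    } else {
      id <- next_internal
      next_internal <<- next_internal + 1L
    }
    if (!is.na(parent_id)) {
      edge_parent <<- c(edge_parent, parent_id)
      edge_child <<- c(edge_child, id)
      edge_len <<- c(edge_len, length_in)
    }
    if (is.null(node$leaf)) {
      for (k in seq_along(node$children)) {
        visit(node$children[[k]], id, node$lengths[k])
      }
    }
    id
  }
  visit(root, NA_integer_, NA_real_)
  if (clamp_negative) edge_len <- pmax(edge_len, 0)
  structure(
    list(edge = cbind(edge_parent, edge_child, deparse.level = 0),
         edge.length = edge_len, tip.label = labels,
         Nnode = next_internal - n - 1L),
    class = "phylo", order = "cladewise"
  )
}

#' Write a tree as Newick text
#'
#' Branch lengths in fixed 6-decimal format; labels containing spaces or
#' Newick metacharacters are single-quoted. The written file parses back to
#' an isomorphic tree.
#'
#' @param tree A `phylo` object (e.g. from [neighbor_joining()]).
#' @param path File path.
#' @return The Newick string, invisibly.
#' @export
write_newick <- function(tree, path) {
  n <- length(tree$tip.label)
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  quote_label <- function(lab) {
    # quote unless the label is entirely Newick-safe characters
    if (grepl("^[A-Za-z0-9_.+/|-]+$", lab)) {
      lab
    } else {
      paste0("'", gsub("'", "''", lab), "'")
    }
  }
  fmt <- function(node_id, len) {
    body <- if (node_id <= n) {
      quote_label(tree$tip.label[node_id])
    } else {
      kids <- children[[as.character(node_id)]]
      paste0("(", paste(vapply(kids, function(e) {
        fmt(tree$edge[e, 2], tree$edge.length[e])
      }, character(1)), collapse = ","), ")")
    }
    if (is.na(len)) body else paste0(body, ":", sprintf("%.6f", len))
  }
  newick <- paste0(fmt(n + 1L, NA_real_), ";")
  writeLines(newick, path)
  invisible(newick)
}

#' Principal components analysis of a genotype matrix
#'
#' States are encoded `AA = 0`, `AB = 1`, `BB = 2`; missing entries are
#' imputed with the site mean; sites (columns) are centred; scores and
#' variances come from the singular value decomposition of the centred
#' genotypes x sites table. Variance fractions are eigenvalues over their
#' total (zero for a constant matrix).
#'
#' @param geno Wide genotype-matrix tibble (see [core_set()]).
#' @return An object of class `snp_pca`: `scores` (tibble, one row per
#'   genotype, columns `PC1..PCk`), `variance_fraction` (non-increasing,
#'   sums to 1 for a non-constant matrix), `sdev`, `n_sites`.
#' @export
#' @examples
#' gm <- tibble::tibble(contig = "c", pos = 0:3, ref_allele = "A",
#'                      var_allele = "T",
#'                      a = c("AA", "AA", "AB", "BB"),
#'                      b = c("AA", "AB", "AB", "BB"),
#'                      c = c("BB", "BB", "AA", "AA"))
#' snp_pca(gm)$variance_fraction
snp_pca <- function(geno) {
  genotypes <- matrix_genotypes(geno)
  if (length(genotypes) < 2 || nrow(geno) < 1) {
    abort("PCA needs at least 2 genotypes and 1 site")
  }
  s <- state_matrix(geno, genotypes)
  x <- matrix(match(s, .STATES) - 1, nrow = nrow(s))  # AA=0, AB=1, BB=2
  x <- t(x)  # genotypes x sites
  if (anyNA(x)) {
    mu <- colMeans(x, na.rm = TRUE)
    mu[is.nan(mu)] <- 0
    idx <- which(is.na(x), arr.ind = TRUE)
    x[idx] <- mu[idx[, 2]]
  }
  fit <- prcomp(x, center = TRUE, scale. = FALSE)
  ev <- fit$sdev^2
  total <- sum(ev)
  vf <- if (total > 0) ev / total else rep(0, length(ev))
  scores <- as_tibble(fit$x)
  scores <- bind_cols(tibble(genotype = genotypes), scores)
  structure(
    list(scores = scores, variance_fraction = vf, sdev = fit$sdev,
         n_sites = nrow(geno)),
    class = "snp_pca"
  )
}

#' @export
print.snp_pca <- function(x, ...) {
  cat("<snp_pca>", nrow(x$scores), "genotypes,", x$n_sites, "sites\n")
  k <- min(3, length(x$variance_fraction))
  cat("  variance explained:",
      paste(sprintf("PC%d %.2f%%", seq_len(k),
                    100 * x$variance_fraction[seq_len(k)]), collapse = ", "),
      "\n")
  invisible(x)
}

#' @describeIn snp_pca Tidy scores: one row per genotype x component with
#'   `score`.
#' @param x An `snp_pca` object.
#' @param ... Unused.
#' @method tidy snp_pca
#' @export
tidy.snp_pca <- function(x, ...) {
  x$scores %>%
    tidyr::pivot_longer(-"genotype", names_to = "component",
                        values_to = "score") %>%
    mutate(component = as.integer(sub("^PC", "", .data$component)))
}

#' @describeIn snp_pca One-row summary: genotype/site counts and the
#'   variance percentages of the first two components.
#' @method glance snp_pca
#' @export
glance.snp_pca <- function(x, ...) {
  tibble(
    n_genotypes = nrow(x$scores),
    n_sites = x$n_sites,
    pc1_variance_pct = 100 * x$variance_fraction[1],
    pc2_variance_pct = if (length(x$variance_fraction) > 1) {
      100 * x$variance_fraction[2]
    } else {
      NA_real_
    }
  )
}

#' @describeIn snp_pca Scatterplot of two principal components, optionally
#'   coloured by group.
#' @param object An `snp_pca` object.
#' @param groups Optional group-spec tibble used to colour points.
#' @param components Two component indices to plot.
#' @method autoplot snp_pca
#' @export
autoplot.snp_pca <- function(object, groups = NULL, components = c(1, 2),
                             ...) {
  df <- object$scores
  xc <- paste0("PC", components[1])
  yc <- paste0("PC", components[2])
  if (!is.null(groups)) {
    df <- left_join(df, select(groups, "genotype", "group"), by = "genotype")
  }
  pct <- function(k) sprintf("PC%d (%.2f%%)", k,
                             100 * object$variance_fraction[k])
  p <- ggplot2::ggplot(df, ggplot2::aes(.data[[xc]], .data[[yc]])) +
    ggplot2::labs(x = pct(components[1]), y = pct(components[2])) +
    ggplot2::theme_minimal()
  if (is.null(groups)) {
    p + ggplot2::geom_point()
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$group))
  }
}

#' Plot SNP density along anchored chromosomes
#'
#' Step plot of variants-per-kbp in fixed windows, faceted by chromosome.
#'
#' @param density Output of [snp_density_windows()].
#' @return A ggplot object.
#' @export
plot_snp_density <- function(density) {
  ggplot2::ggplot(density,
                  ggplot2::aes(x = (.data$start + .data$end) / 2e6,
                               y = .data$density)) +
    ggplot2::geom_col(width = (density$end[1] - density$start[1]) / 1e6) +
    ggplot2::facet_wrap(~chrom) +
    ggplot2::labs(x = "position (Mbp)", y = "SNPs per kbp") +
    ggplot2::theme_minimal()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
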