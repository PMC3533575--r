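# resolve group names or genotype ids to genotype id vectors
resolve_genotypes <- function(groups, x, level = "group") {
  if (all(x %in% groups[[level]])) {
    groups$genotype[groups[[level]] %in% x]
  } else if (all(x %in% groups$genotype)) {
    x
  } else {
    abort(sprintf("'%s' is neither a %s name nor a genotype id",
                  setdiff(x, c(groups[[level]], groups$genotype))[1], level))
  }
}

# polymorphism flag for a set of genotype columns: both alleles observed
# among the non-missing calls (any AB, or opposite homozygotes); NA when
# every call is missing
poly_flag <- function(s) {
  any_ab <- rowSums(s == "AB", na.rm = TRUE) > 0
  any_aa <- rowSums(s == "AA", na.rm = TRUE) > 0
  any_bb <- rowSums(s == "BB", na.rm = TRUE) > 0
  n_obs <- rowSums(!is.na(s))
  out <- any_ab | (any_aa & any_bb)
  out[n_obs == 0] <- NA
  out
}

#' Within-group polymorphism profile
#'
#' A SNP is polymorphic within a group iff, among the group's non-missing
#' calls, at least one genotype is `AB` or two genotypes carry opposite
#' homozygous states. A group with no non-missing call at a site has an
#' undefined (`NA`) flag there.
#'
#' @param geno Wide genotype-matrix tibble (see [core_set()]).
#' @param groups Group-spec tibble.
#' @param level `"group"` or `"subgroup"`: which grouping column to profile.
#' @return A tibble `contig`, `pos`, then one logical column per group.
#' @export
#' @examples
#' gs <- group_spec(c("a", "b", "c"), 4, c("G1", "G1", "G2"))
#' gm <- tibble::tibble(contig = "c1", pos = 0L, ref_allele = "A",
#'                      var_allele = "T", a = "AA", b = "BB", c = "AB")
#' group_polymorphism(gm, gs)
group_polymorphism <- function(geno, groups, level = c("group", "subgroup")) {
  level <- match.arg(level)
  members <- groups[!is.na(groups[[level]]), ]
  unknown <- setdiff(members$genotype, matrix_genotypes(geno))
  if (length(unknown) > 0) {
    abort(sprintf("genotype '%s' not present in the matrix", unknown[1]))
  }
  out <- select(geno, "contig", "pos")
  for (grp in unique(members[[level]])) {
    ids <- members$genotype[members[[level]] == grp]
    out[[grp]] <- poly_flag(state_matrix(geno, ids))
  }
  out
}

#' Exclusive Venn-region counts of a polymorphism profile
#'
#' Partitions the SNPs polymorphic in at least one group into the
#' `2^k - 1` exclusive membership regions of the k-group Venn diagram.
#' SNPs with an undefined flag in any group are excluded (and reported via
#' a message); SNPs polymorphic in no group fall outside every region.
#'
#' @param profile Output of [group_polymorphism()].
#' @param groups_order Optional character vector fixing the group order used
#'   for the pattern strings; defaults to profile column order.
#' @return A tibble `pattern` (k-digit 0/1 string), `region`
#'   (`&`-joined group names), `count`, covering all `2^k - 1` nonempty
#'   patterns (zero counts included).
#' @export
venn_regions <- function(profile, groups_order = NULL) {
  grps <- groups_order %||% setdiff(names(profile), c("contig", "pos"))
  if (length(grps) < 2) abort("venn_regions needs at least 2 groups")
  flags <- as.matrix(profile[grps])
  defined <- rowSums(is.na(flags)) == 0
  if (any(!defined)) {
    inform(sprintf("%d SNP(s) with an undefined group flag excluded from Venn totals",
                   sum(!defined)))
    flags <- flags[defined, , drop = FALSE]
  }
  flags <- flags[rowSums(flags) > 0, , drop = FALSE]
  pattern <- if (nrow(flags) > 0) {
    apply(flags, 1, function(z) paste(as.integer(z), collapse = ""))
  } else {
    character(0)
  }
  k <- length(grps)
  all_patterns <- vapply(seq_len(2^k - 1), function(i) {
    paste(as.integer(intToBits(i)[k:1]), collapse = "")
  }, character(1))
  counts <- table(factor(pattern, levels = all_patterns))
  tibble(
    pattern = all_patterns,
    region = vapply(all_patterns, function(pt) {
      paste(grps[strsplit(pt, "")[[1]] == "1"], collapse = "&")
    }, character(1)),
    count = as.integer(counts)
  )
}

#' Percentage helper for polymorphism accounting
#'
#' The percentage of a SNP total that a polymorphism count represents, as
#' printed in diversity summaries (e.g. "share of the core set polymorphic
#' within the elite group").
#'
#' @param n_polymorphic Count of polymorphic SNPs.
#' @param n_total Denominator count.
#' @param digits Rounding digits (1 matches the published style; use 0 for
#'   integer percentages).
#' @return Percentage (0-100).
#' @export
#' @examples
#' polymorphism_percentage(160901, 173947)
polymorphism_percentage <- function(n_polymorphic, n_total, digits = 1) {
  if (n_total <= 0) abort("n_total must be positive")
  round(100 * n_polymorphic / n_total, digits)
}

#' Fixed allelic differences between two groups
#'
#' SNPs at which all non-missing calls in one group are `AA` and all in the
#' other are `BB` (either orientation). A site qualifies only when both
#' groups have at least one non-missing call.
#'
#' @param geno Wide genotype-matrix tibble.
#' @param groups Group-spec tibble.
#' @param pair Character vector of two disjoint group names (or two vectors
#'   of genotype ids supplied as a list).
#' @return Tibble of qualifying SNPs: `contig`, `pos`, `state_first`,
#'   `state_second`.
#' @export
fixed_differences <- function(geno, groups, pair) {
  ids <- if (is.list(pair)) pair else {
    lapply(pair, function(p) resolve_genotypes(groups, p))
  }
  stopifnot(length(ids) == 2)
  if (length(intersect(ids[[1]], ids[[2]])) > 0) {
    abort("the two groups must be disjoint")
  }
  fixed_state <- function(g) {
    s <- state_matrix(geno, g)
    n_obs <- rowSums(!is.na(s))
    all_aa <- rowSums(s == "AA", na.rm = TRUE) == n_obs & n_obs > 0
    all_bb <- rowSums(s == "BB", na.rm = TRUE) == n_obs & n_obs > 0
    dplyr::case_when(all_aa ~ "AA", all_bb ~ "BB", TRUE ~ NA_character_)
  }
  s1 <- fixed_state(ids[[1]])
  s2 <- fixed_state(ids[[2]])
  keep <- !is.na(s1) & !is.na(s2) & s1 != s2
  geno %>%
    select("contig", "pos") %>%
    mutate(state_first = s1, state_second = s2) %>%
    filter(keep)
}

#' Candidate contigs from clustered group-private polymorphisms
#'
#' Scans for SNPs that are polymorphic within one set of genotypes (pooled
#' into a single set) while monomorphic (all non-missing calls the same
#' homozygote) across another, and reports the contigs carrying at least
#' `min_cluster` such SNPs — the pattern used to flag candidate
#' domestication or subspecies-differentiation genes.
#'
#' @param geno Wide genotype-matrix tibble.
#' @param groups Group-spec tibble.
#' @param polymorphic_in Group names (or genotype ids) pooled as the set in
#'   which the SNP must be polymorphic.
#' @param fixed_in Group names (or genotype ids) across which the SNP must
#'   be fixed; disjoint from `polymorphic_in`.
#' @param min_cluster Minimum qualifying SNPs for a contig to be reported.
#' @param label Criterion label stored with the result (e.g.
#'   `"domestication"`).
#' @return Tibble `contig`, `n_snps`, `positions` (list column), `label`,
#'   one row per reported contig. The full qualifying SNP list is attached
#'   as attribute `"qualifying"`.
#' @export
candidate_contigs <- function(geno, groups, polymorphic_in, fixed_in,
                              min_cluster = 5, label = NA_character_) {
  ids_poly <- resolve_genotypes(groups, polymorphic_in)
  ids_fixed <- resolve_genotypes(groups, fixed_in)
  if (length(intersect(ids_poly, ids_fixed)) > 0) {
    abort("polymorphic_in and fixed_in must be disjoint")
  }
  poly <- poly_flag(state_matrix(geno, ids_poly))
  sf <- state_matrix(geno, ids_fixed)
  n_obs <- rowSums(!is.na(sf))
  mono <- n_obs > 0 &
    (rowSums(sf == "AA", na.rm = TRUE) == n_obs |
       rowSums(sf == "BB", na.rm = TRUE) == n_obs)
  qualifying <- geno %>%
    select("contig", "pos") %>%
    filter(!is.na(poly) & poly & mono)
  out <- qualifying %>%
    group_by(.data$contig) %>%
    summarise(n_snps = dplyr::n(), positions = list(.data$pos),
              .groups = "drop") %>%
    filter(.data$n_snps >= min_cluster) %>%
    mutate(label = label)
  attr(out, "qualifying") <- qualifying
  out
}

#' SNP density in fixed genome windows
#'
#' Projects PASS variants onto their anchor coordinates and counts them in
#' fixed-origin half-open windows of `window` bp per chromosome, reporting
#' densities as variants per kbp (the convention of SNP-distribution plots
#' along reference pseudomolecules).
#'
#' @param calls Variant-call tibble from [call_variants()] (only PASS rows
#'   are counted).
#' @param contigs Contig metadata with `anchor_chromosome` and
#'   `anchor_position`; unanchored contigs are skipped with a message.
#' @param window Window size in bp.
#' @return Tibble `chrom`, `start`, `end`, `n`, `density` (variants per
#'   kbp), covering every window from 0 to the last anchored variant.
#' @export
snp_density_windows <- function(calls, contigs, window = 5e5) {
  pass <- calls %>%
    filter(.data$verdict == "PASS") %>%
    left_join(select(contigs, "contig", "anchor_chromosome", "anchor_position"),
              by = "contig")
  unanchored <- is.na(pass$anchor_chromosome) | is.na(pass$anchor_position)
  if (any(unanchored)) {
    inform(sprintf("%d PASS variant(s) on unanchored contigs skipped",
                   sum(unanchored)))
    pass <- pass[!unanchored, ]
  }
  if (nrow(pass) == 0) {
    return(tibble(chrom = character(), start = double(), end = double(),
                  n = integer(), density = double()))
  }
  pass <- mutate(pass, genome_pos = .data$anchor_position + .data$pos)
  pass %>%
    group_by(chrom = .data$anchor_chromosome) %>%
    dplyr::reframe({
      breaks <- seq(0, (max(.data$genome_pos) %/% window + 1) * window,
                    by = window)
      idx <- findInterval(.data$genome_pos, breaks)
      tibble(
        start = breaks[-length(breaks)],
        end = breaks[-1],
        n = tabulate(idx, nbins = length(breaks) - 1)
      )
    }) %>%
    mutate(density = .data$n / (window / 1000))
}

#' Write window densities as BEDGRAPH-style text
#'
#' Four columns (`chrom`, `start`, `end`, `density`), tab-separated, no
#' header.
#'
#' @param density Output of [snp_density_windows()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_density_bedgraph <- function(density, path) {
  readr::write_tsv(density[c("chrom", "start", "end", "density")], path,
                   col_names = FALSE, progress = FALSE)
  invisible(path)
}
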