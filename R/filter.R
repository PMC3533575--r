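#' Parameters of the SNP filter cascade
#'
#' Defaults follow the published cascade for transcriptome SNP discovery in
#' the 27-genotype panel: a variant is supported within a sample by at least
#' 2 variant reads, mean variant-base quality at least 20 and variant-read
#' frequency at least 20%; a site needs a total aligned read number strictly
#' greater than 20 across all samples; and the genotypic contingency test
#' must reject independence at p < 0.01.
#'
#' @param min_var_reads Minimum variant reads in a supporting genotype
#'   (inclusive).
#' @param min_mean_quality Minimum mean Phred quality of the variant-
#'   supporting bases (inclusive).
#' @param min_var_fraction Minimum variant-read fraction within a supporting
#'   genotype (inclusive).
#' @param min_total_reads_exclusive Total read count across all genotypes
#'   must be strictly greater than this.
#' @param alpha Contingency-test p-value threshold (strict `<`).
#' @param p_value_method `"chisq"` (Pearson chi-square with `K - 1` degrees
#'   of freedom) or `"permutation"` (read-label permutation preserving both
#'   table margins).
#' @param n_permutations Number of permutations when
#'   `p_value_method = "permutation"`.
#' @param seed Seed for the permutation null.
#' @return A list of class `filter_params`.
#' @export
filter_params <- function(min_var_reads = 2,
                          min_mean_quality = 20,
                          min_var_fraction = 0.20,
                          min_total_reads_exclusive = 20,
                          alpha = 0.01,
                          p_value_method = c("chisq", "permutation"),
                          n_permutations = 10000,
                          seed = 1L) {
  stopifnot(
    min_var_reads >= 0, min_mean_quality >= 0,
    min_var_fraction >= 0, min_var_fraction <= 1,
    min_total_reads_exclusive >= 0,
    alpha > 0, alpha < 1, n_permutations >= 1
  )
  structure(
    list(
      min_var_reads = min_var_reads,
      min_mean_quality = min_mean_quality,
      min_var_fraction = min_var_fraction,
      min_total_reads_exclusive = min_total_reads_exclusive,
      alpha = alpha,
      p_value_method = match.arg(p_value_method),
      n_permutations = as.integer(n_permutations),
      seed = as.integer(seed)
    ),
    class = "filter_params"
  )
}

support_flags <- function(counts, params) {
  depth <- counts$ref_reads + counts$var_reads
  depth > 0 &
    counts$var_reads >= params$min_var_reads &
    counts$mean_var_quality >= params$min_mean_quality &
    counts$var_reads / pmax(depth, 1) >= params$min_var_fraction
}

#' Sample-support filter for one site
#'
#' A genotype supports the variant iff it has at least `min_var_reads`
#' variant reads, mean variant-base quality at least `min_mean_quality`, and
#' a variant-read fraction (of its ref + var reads) at least
#' `min_var_fraction`. The site passes iff at least one genotype supports
#' it. Genotypes with zero total reads contribute no support.
#'
#' @param site Long site-counts tibble rows for a single site.
#' @param params A [filter_params()].
#' @return A list with `pass` (logical) and `supporting` (character vector
#'   of supporting genotype ids).
#' @export
sample_support_filter <- function(site, params = filter_params()) {
  ok <- support_flags(site, params)
  list(pass = any(ok), supporting = as.character(site$genotype[ok]))
}

#' Total-depth filter for one site
#'
#' Passes iff the summed read count (ref + var) over all genotypes is
#' strictly greater than `min_total_reads_exclusive`.
#'
#' @inheritParams sample_support_filter
#' @return Logical flag.
#' @export
total_depth_filter <- function(site, params = filter_params()) {
  sum(site$ref_reads + site$var_reads) > params$min_total_reads_exclusive
}

# Pearson chi-square on a 2 x K table given as ref/var count vectors;
# zero-depth columns are dropped. Returns statistic, df, p.
pearson_2xk <- function(ref, var) {
  keep <- (ref + var) > 0
  ref <- ref[keep]
  var <- var[keep]
  k <- length(ref)
  if (k < 2) {
    return(list(statistic = NA_real_, df = NA_integer_, p_value = 1,
                degenerate = TRUE))
  }
  tot <- sum(ref) + sum(var)
  e_ref <- sum(ref) * (ref + var) / tot
  e_var <- sum(var) * (ref + var) / tot
  term <- function(o, e) ifelse(e > 0, (o - e)^2 / e, 0)
  stat <- sum(term(ref, e_ref)) + sum(term(var, e_var))
  p <- if (sum(var) == 0 || sum(ref) == 0) 1 else
    pchisq(stat, df = k - 1, lower.tail = FALSE)
  list(statistic = stat, df = k - 1L, p_value = p, degenerate = FALSE)
}

permutation_p <- function(ref, var, stat_obs, n_perm) {
  keep <- (ref + var) > 0
  ref <- ref[keep]
  var <- var[keep]
  # canonical column order makes the permutation p-value invariant to
  # genotype column order (the statistic already is)
  ord <- order(ref, var)
  ref <- ref[ord]
  var <- var[ord]
  tables <- r2dtable(n_perm, c(sum(ref), sum(var)), ref + var)
  stats <- vapply(tables, function(tb) {
    pearson_2xk(tb[1, ], tb[2, ])$statistic
  }, double(1))
  (1 + sum(stats >= stat_obs - 1e-9)) / (1 + n_perm)
}

#' Genotypic contingency test for one site
#'
#' Tests independence of reference and variant alleles (rows) across the
#' genotypes (columns) in a 2 x K contingency table of read counts.
#' Genotypes with zero depth are dropped from the table. The default is the
#' Pearson chi-square statistic with `K - 1` degrees of freedom; permutation
#' mode shuffles allele labels among reads preserving column totals
#' (Patefield sampling) and reports
#' `p = (1 + #\{stat_perm >= stat_obs\}) / (1 + n_permutations)`.
#' A site whose variant (or reference) row sums to zero gets `p = 1`; with
#' fewer than two nonzero-depth genotypes the test is undefined and `p = 1`
#' is returned with a warning.
#'
#' @inheritParams sample_support_filter
#' @return A list with `statistic`, `df` and `p_value`.
#' @export
contingency_test <- function(site, params = filter_params()) {
  res <- pearson_2xk(site$ref_reads, site$var_reads)
  if (res$degenerate) {
    warn("contingency test undefined with fewer than 2 covered genotypes; p = 1")
    return(res[c("statistic", "df", "p_value")])
  }
  if (params$p_value_method == "permutation" &&
      sum(site$var_reads) > 0 && sum(site$ref_reads) > 0) {
    set.seed(params$seed)
    res$p_value <- permutation_p(site$ref_reads, site$var_reads,
                                 res$statistic, params$n_permutations)
  }
  res[c("statistic", "df", "p_value")]
}

#' Run the SNP filter cascade over a counts table
#'
#' Applies, in order, the sample-support filter, the total-depth filter and
#' the genotypic contingency test to every site. The verdict is `"PASS"` iff
#' all three stages pass; otherwise it records the first failing stage
#' (`"sample_support"`, `"total_depth"`, `"contingency"`). Diagnostics are
#' retained for every site regardless of verdict.
#'
#' @param counts Long site-counts tibble (see [read_counts_table()]).
#' @param params A [filter_params()].
#' @return A tibble with one row per site: keys (`contig`, `pos`,
#'   `ref_allele`, `var_allele`, `variant_class`), `passed_sample_support`,
#'   `supporting_genotypes` (list column), `total_reads`,
#'   `passed_total_depth`, `statistic`, `df`, `p_value`, `verdict`.
#' @export
#' @examples
#' panel <- simulate_panel(panel_config(n_contigs = 4, sites_per_contig = 3))
#' calls <- call_variants(panel$counts, filter_params())
#' table(calls$verdict)
call_variants <- function(counts, params = filter_params()) {
  counts <- arrange(counts, .data$contig, .data$pos,
                    as.integer(factor(.data$genotype, genotype_levels(counts))))
  key <- counts %>%
    distinct(.data$contig, .data$pos, .data$ref_allele, .data$var_allele,
             .data$variant_class)
  if (nrow(key) == 0) {
    return(mutate(key, passed_sample_support = logical(),
                  supporting_genotypes = list(), total_reads = double(),
                  passed_total_depth = logical(), statistic = double(),
                  df = integer(), p_value = double(), verdict = character()))
  }
  genotypes <- genotype_levels(counts)
  wide <- counts_matrices(counts, genotypes)
  depth <- wide$ref + wide$var

  supp <- matrix(support_flags(counts, params), nrow = nrow(counts) /
                   length(genotypes), byrow = TRUE)
  # counts are sorted site-major, genotype-minor (enforced by readers and
  # the simulator), so the matrix reshape above lines up with `key`
  passed_support <- rowSums(supp) > 0
  supporting <- lapply(seq_len(nrow(supp)), function(i) genotypes[supp[i, ]])

  total_reads <- rowSums(depth)
  passed_depth <- total_reads > params$min_total_reads_exclusive

  covered <- depth > 0
  k <- rowSums(covered)
  row_ref <- rowSums(wide$ref)
  row_var <- rowSums(wide$var)
  tot <- row_ref + row_var
  e_ref <- covered * row_ref * depth / pmax(tot, 1)
  e_var <- covered * row_var * depth / pmax(tot, 1)
  chi_term <- function(o, e) {
    out <- (o - e)^2 / e
    out[e == 0] <- 0
    out
  }
  stat <- rowSums(chi_term(covered * wide$ref, e_ref)) +
    rowSums(chi_term(covered * wide$var, e_var))
  p <- pchisq(stat, df = pmax(k - 1, 1), lower.tail = FALSE)
  p[row_var == 0 | row_ref == 0] <- 1
  degenerate <- k < 2
  if (any(degenerate)) {
    warn(sprintf("contingency test undefined at %d site(s) with fewer than 2 covered genotypes; p = 1",
                 sum(degenerate)))
    stat[degenerate] <- NA_real_
    p[degenerate] <- 1
  }
  if (params$p_value_method == "permutation") {
    set.seed(params$seed)
    redo <- which(!degenerate & row_var > 0 & row_ref > 0)
    for (i in redo) {
      p[i] <- permutation_p(wide$ref[i, ], wide$var[i, ], stat[i],
                            params$n_permutations)
    }
  }

  key %>%
    mutate(
      passed_sample_support = passed_support,
      supporting_genotypes = supporting,
      total_reads = total_reads,
      passed_total_depth = passed_depth,
      statistic = stat,
      df = ifelse(degenerate, NA_integer_, as.integer(pmax(k - 1, 0))),
      p_value = p,
      verdict = dplyr::case_when(
        !passed_support ~ "sample_support",
        !passed_depth ~ "total_depth",
        !(p < params$alpha) ~ "contingency",
        TRUE ~ "PASS"
      )
    )
}

# site-major matrices (sites x genotypes) of ref reads, var reads, quality
counts_matrices <- function(counts, genotypes = genotype_levels(counts)) {
  n_g <- length(genotypes)
  n_s <- nrow(counts) / n_g
  stopifnot(n_s == as.integer(n_s))
  shape <- function(x) matrix(x, nrow = n_s, ncol = n_g, byrow = TRUE,
                              dimnames = list(NULL, genotypes))
  list(ref = shape(counts$ref_reads), var = shape(counts$var_reads),
       qual = shape(counts$mean_var_quality))
}

#' Select SNPs eligible for high-resolution-melting assays
#'
#' A PASS SNP is HRM-eligible iff both flanking windows of `flank` bp are
#' free of any other PASS variant (SNP or InDel) on the same contig and lie
#' fully within the contig: a neighbouring PASS variant at distance
#' `d <= flank` disqualifies, as does a position closer than `flank` bp to
#' either contig end (the clean primer window would be truncated).
#'
#' @param calls Variant-call tibble from [call_variants()], sorted by
#'   `(contig, pos)`.
#' @param contigs Contig metadata tibble (`contig`, `length`).
#' @param flank Required clean flank length in bp.
#' @return Tibble of eligible PASS SNPs (`contig`, `pos`, `ref_allele`,
#'   `var_allele`, distances to the nearest PASS neighbours).
#' @export
hrm_eligible <- function(calls, contigs, flank = 18) {
  pass <- calls %>%
    filter(.data$verdict == "PASS") %>%
    arrange(.data$contig, .data$pos)
  missing_ctg <- setdiff(unique(pass$contig), contigs$contig)
  if (length(missing_ctg) > 0) {
    abort(sprintf("no length known for contig '%s'", missing_ctg[1]))
  }
  pass %>%
    group_by(.data$contig) %>%
    mutate(
      dist_prev = .data$pos - dplyr::lag(.data$pos),
      dist_next = dplyr::lead(.data$pos) - .data$pos
    ) %>%
    ungroup() %>%
    left_join(select(contigs, "contig", "length"), by = "contig") %>%
    filter(
      .data$variant_class == "SNP",
      is.na(.data$dist_prev) | .data$dist_prev > flank,
      is.na(.data$dist_next) | .data$dist_next > flank,
      .data$pos >= flank,
      .data$pos <= .data$length - 1 - flank
    ) %>%
    select("contig", "pos", "ref_allele", "var_allele",
           "dist_prev", "dist_next")
}
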