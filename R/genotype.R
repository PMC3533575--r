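#' Parameters of dosage-lumped genotype classification
#'
#' Read counts cannot reliably resolve allele dosage in an autotetraploid,
#' so every heterozygous dosage class (ABBB, AABB, AAAB) is lumped into one
#' `AB` state. The numeric cutoffs are this package's own: a genotype is
#' called homozygous when the minor-allele read fraction is at most
#' `max_hom_fraction`, chosen so a single miscalled read at depth 10 cannot
#' create a heterozygote, and a heterozygote additionally needs
#' `min_het_reads_each_allele` reads of each allele.
#'
#' @param min_genotype_depth Below this read depth the call is missing.
#' @param max_hom_fraction Homozygous when the variant fraction is
#'   `<= max_hom_fraction` (AA) or `>= 1 - max_hom_fraction` (BB); inclusive.
#' @param min_het_reads_each_allele Minimum reads of each allele for an AB
#'   call.
#' @return A list of class `call_params`.
#' @export
call_params <- function(min_genotype_depth = 10,
                        max_hom_fraction = 0.10,
                        min_het_reads_each_allele = 2) {
  stopifnot(
    min_genotype_depth >= 0,
    max_hom_fraction >= 0, max_hom_fraction < 0.5,
    min_het_reads_each_allele >= 0
  )
  structure(
    list(
      min_genotype_depth = min_genotype_depth,
      max_hom_fraction = max_hom_fraction,
      min_het_reads_each_allele = min_het_reads_each_allele
    ),
    class = "call_params"
  )
}

#' Classify read counts into AA / AB / BB / missing
#'
#' Vectorised over sites x genotypes. With depth `ref + var` below
#' `min_genotype_depth` the call is missing (`NA`); otherwise the variant
#' fraction `f = var / depth` gives `AA` when `f <= max_hom_fraction`, `BB`
#' when `f >= 1 - max_hom_fraction`, and `AB` in between provided both
#' alleles have at least `min_het_reads_each_allele` reads (else missing).
#'
#' @param ref_reads,var_reads Non-negative read counts (vectors).
#' @param params A [call_params()].
#' @return Character vector over `"AA"`, `"AB"`, `"BB"`, `NA`.
#' @export
#' @examples
#' classify_genotype(c(10, 5, 0, 9), c(0, 5, 12, 1))
classify_genotype <- function(ref_reads, var_reads, params = call_params()) {
  depth <- ref_reads + var_reads
  f <- var_reads / pmax(depth, 1)
  out <- dplyr::case_when(
    depth < params$min_genotype_depth ~ NA_character_,
    f <= params$max_hom_fraction ~ "AA",
    f >= 1 - params$max_hom_fraction ~ "BB",
    var_reads >= params$min_het_reads_each_allele &
      ref_reads >= params$min_het_reads_each_allele ~ "AB",
    TRUE ~ NA_character_
  )
  out
}

#' Build the core genotype matrix
#'
#' The core SNP set keeps PASS SNPs covered by at least
#' `min_genotype_depth` reads in *every* genotype, so that no call is
#' missing for depth reasons, and classifies every genotype at every kept
#' site with [classify_genotype()].
#'
#' @param calls Variant-call tibble from [call_variants()].
#' @param counts Long site-counts tibble the calls were made from.
#' @param params A [call_params()].
#' @return A wide genotype-matrix tibble: `contig`, `pos`, `ref_allele`,
#'   `var_allele`, then one character column per genotype with states
#'   `AA`/`AB`/`BB`/`NA`.
#' @export
core_set <- function(calls, counts, params = call_params()) {
  pass <- calls %>%
    filter(.data$verdict == "PASS", .data$variant_class == "SNP") %>%
    select("contig", "pos", "ref_allele", "var_allele")
  site_counts <- counts %>%
    dplyr::semi_join(pass, by = c("contig", "pos", "ref_allele", "var_allele"))
  deep <- site_counts %>%
    group_by(.data$contig, .data$pos) %>%
    filter(min(.data$ref_reads + .data$var_reads) >= params$min_genotype_depth) %>%
    ungroup()
  genotypes <- genotype_levels(counts)
  out <- deep %>%
    mutate(
      state = classify_genotype(.data$ref_reads, .data$var_reads, params),
      genotype = as.character(.data$genotype)
    ) %>%
    tidyr::pivot_wider(
      id_cols = c("contig", "pos", "ref_allele", "var_allele"),
      names_from = "genotype", values_from = "state"
    ) %>%
    arrange(.data$contig, .data$pos)
  for (g in setdiff(genotypes, names(out))) out[[g]] <- character(0)
  out[c("contig", "pos", "ref_allele", "var_allele", genotypes)]
}

# genotype id columns of a wide genotype matrix
matrix_genotypes <- function(geno) {
  setdiff(names(geno), c("contig", "pos", "ref_allele", "var_allele"))
}

# sites x genotypes character matrix of states
state_matrix <- function(geno, genotypes = matrix_genotypes(geno)) {
  as.matrix(geno[genotypes])
}

#' Per-genotype heterozygosity over the core set
#'
#' Heterozygosity of a genotype is the percentage of its classified
#' (non-missing) sites called `AB`.
#'
#' @param geno Wide genotype-matrix tibble (see [core_set()]).
#' @param genotype Optional character vector restricting which genotypes are
#'   reported.
#' @return A tibble `genotype`, `n_classified`, `heterozygosity_pct`.
#' @export
heterozygosity <- function(geno, genotype = NULL) {
  ids <- genotype %||% matrix_genotypes(geno)
  missing_ids <- setdiff(ids, matrix_genotypes(geno))
  if (length(missing_ids) > 0) {
    abort(sprintf("genotype '%s' not present in the matrix", missing_ids[1]))
  }
  s <- state_matrix(geno, ids)
  n_class <- colSums(!is.na(s))
  if (any(n_class == 0)) {
    abort(sprintf("heterozygosity undefined: genotype '%s' has no classified site",
                  ids[which(n_class == 0)[1]]))
  }
  tibble(
    genotype = ids,
    n_classified = as.integer(unname(n_class)),
    heterozygosity_pct = unname(100 * colSums(s == "AB", na.rm = TRUE) / n_class)
  )
}

#' Pool two diploid genotypes into a synthetic tetraploid
#'
#' Treats the four chromosomes of two diploids as one tetraploid-equivalent
#' genotype: the pooled call is missing if either call is missing, `AB` if
#' either is `AB` or the two homozygous states differ, else the shared
#' homozygous state.
#'
#' @param geno Wide genotype-matrix tibble.
#' @param groups Group-spec tibble (for the ploidy check).
#' @param id_a,id_b Diploid genotype ids to pool.
#' @param pooled_name Name of the resulting column.
#' @return Tibble `contig`, `pos`, `<pooled_name>`.
#' @export
pool_diploids <- function(geno, groups, id_a, id_b,
                          pooled_name = paste(id_a, id_b, sep = "+")) {
  ploidies <- setNames(groups$ploidy, groups$genotype)[c(id_a, id_b)]
  if (anyNA(ploidies) || any(ploidies != 2L)) {
    abort("pool_diploids requires two diploid genotypes")
  }
  a <- geno[[id_a]]
  b <- geno[[id_b]]
  pooled <- dplyr::case_when(
    is.na(a) | is.na(b) ~ NA_character_,
    a == "AB" | b == "AB" | a != b ~ "AB",
    TRUE ~ a
  )
  out <- select(geno, "contig", "pos")
  out[[pooled_name]] <- pooled
  out
}

#' Write / read a genotype matrix TSV
#'
#' Sites as rows, genotypes as columns, states `AA`/`AB`/`BB` with `NA` for
#' missing.
#'
#' @param geno Wide genotype-matrix tibble.
#' @param path File path.
#' @return `write_genotype_matrix()`: `path` invisibly;
#'   `read_genotype_matrix()`: the tibble.
#' @export
write_genotype_matrix <- function(geno, path) {
  readr::write_tsv(geno, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' @rdname write_genotype_matrix
#' @export
read_genotype_matrix <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    contig = readr::col_character(),
    pos = readr::col_integer(),
    ref_allele = readr::col_character(),
    var_allele = readr::col_character(),
    .default = readr::col_character()
  ), na = "NA", progress = FALSE)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
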