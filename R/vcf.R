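vcf_gt <- function(state, ploidy) {
  hom <- function(allele) vapply(ploidy, function(p) {
    paste(rep(allele, p), collapse = "/")
  }, character(1))
  dplyr::case_when(
    is.na(state) ~ "./.",
    state == "AA" ~ hom("0"),
    state == "BB" ~ hom("1"),
    state == "AB" ~ "0/1"
  )
}

#' Write variant calls (and optional genotype calls) as VCF 4.2
#'
#' Internal 0-based positions are converted to 1-based `POS`. The `FILTER`
#' column records the first failing cascade stage (`sample_support`,
#' `total_depth`, `contingency`) or `PASS`. When a genotype matrix is
#' supplied, `GT` encodes `AA` as `0/0` (`0/0/0/0` for tetraploids), `BB` as
#' `1/1` (`1/1/1/1`), `AB` as `0/1` with the dosage-lumped `FORMAT` flag
#' `DL=1` in tetraploids, and missing as `./.`; sites absent from the matrix
#' get missing genotypes.
#'
#' @param calls Variant-call tibble from [call_variants()].
#' @param path Output path.
#' @param geno Optional wide genotype-matrix tibble (see [core_set()]).
#' @param groups Group-spec tibble (required with `geno`, for ploidies).
#' @param contigs Optional contig metadata for `##contig` header lines.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, path, geno = NULL, groups = NULL,
                      contigs = NULL) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=tetrasnp",
    if (!is.null(contigs)) {
      sprintf("##contig=<ID=%s,length=%d>", contigs$contig, contigs$length)
    },
    "##FILTER=<ID=sample_support,Description=\"No genotype met the per-sample variant support thresholds\">",
    "##FILTER=<ID=total_depth,Description=\"Total aligned read count across genotypes not greater than the threshold\">",
    "##FILTER=<ID=contingency,Description=\"Genotypic contingency test did not reject independence\">",
    "##INFO=<ID=VC,Number=1,Type=String,Description=\"Variant class (SNP or InDel)\">",
    "##INFO=<ID=TR,Number=1,Type=Integer,Description=\"Total read count across genotypes\">",
    "##INFO=<ID=PV,Number=1,Type=Float,Description=\"Genotypic contingency test p-value\">"
  )
  cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  body <- calls %>%
    arrange(.data$contig, .data$pos) %>%
    mutate(
      line = sprintf(
        "%s\t%d\t.\t%s\t%s\t.\t%s\tVC=%s;TR=%d;PV=%s",
        .data$contig, .data$pos + 1L, .data$ref_allele, .data$var_allele,
        .data$verdict, .data$variant_class, as.integer(.data$total_reads),
        sprintf("%.4g", .data$p_value)
      )
    )
  if (!is.null(geno)) {
    if (is.null(groups)) abort("`groups` is required to write genotype columns")
    genotypes <- matrix_genotypes(geno)
    ploidy <- setNames(groups$ploidy, groups$genotype)[genotypes]
    header <- c(
      header,
      "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Dosage-lumped genotype call\">",
      "##FORMAT=<ID=DL,Number=1,Type=Integer,Description=\"1 when a heterozygous call lumps tetraploid dosage classes\">"
    )
    cols <- c(cols, "FORMAT", genotypes)
    keyed <- calls %>%
      arrange(.data$contig, .data$pos) %>%
      left_join(geno, by = c("contig", "pos", "ref_allele", "var_allele"))
    geno_text <- vapply(seq_len(nrow(keyed)), function(i) {
      states <- unlist(keyed[i, genotypes], use.names = FALSE)
      gt <- vcf_gt(states, ploidy)
      dl <- ifelse(is.na(states), ".",
                   ifelse(states == "AB" & ploidy == 4L, "1", "0"))
      paste(paste0(gt, ":", dl), collapse = "\t")
    }, character(1))
    body$line <- paste0(body$line, "\tGT:DL\t", geno_text)
  }
  writeLines(c(header, paste(cols, collapse = "\t"), body$line), path)
  invisible(path)
}

# truth VCF for a simulated panel: exact-dosage GT plus a DS dosage field
write_truth_vcf <- function(panel, path) {
  groups <- panel$groups
  genotypes <- groups$genotype
  sites <- arrange(panel$sites, .data$contig, .data$pos)
  dosage <- panel$truth %>%
    mutate(genotype = factor(.data$genotype, genotypes)) %>%
    arrange(.data$contig, .data$pos, as.integer(.data$genotype))
  dmat <- matrix(dosage$dosage, nrow = nrow(sites), byrow = TRUE)
  ploidy <- groups$ploidy
  gt_cache <- new.env()
  gt_of <- function(d, p) {
    key <- paste0(d, "_", p)
    if (is.null(gt_cache[[key]])) {
      gt_cache[[key]] <- paste(c(rep("0", p - d), rep("1", d)), collapse = "/")
    }
    gt_cache[[key]]
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=tetrasnp-simulator",
    "##INFO=<ID=VC,Number=1,Type=String,Description=\"Variant class (SNP or InDel)\">",
    "##INFO=<ID=PA,Number=1,Type=Float,Description=\"Ancestral variant-allele frequency\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"True dosage genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Integer,Description=\"True variant-allele dosage (0..ploidy)\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", genotypes), collapse = "\t")
  )
  lines <- vapply(seq_len(nrow(sites)), function(i) {
    cells <- vapply(seq_along(genotypes), function(j) {
      paste0(gt_of(dmat[i, j], ploidy[j]), ":", dmat[i, j])
    }, character(1))
    paste(c(
      sites$contig[i], sites$pos[i] + 1L, ".", sites$ref_allele[i],
      sites$var_allele[i], ".", ".",
      sprintf("VC=%s;PA=%.6f", sites$variant_class[i], sites$p_anc[i]),
      "GT:DS", cells
    ), collapse = "\t")
  }, character(1))
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Read true dosages back from a truth VCF
#'
#' Parses the `DS` field of a VCF written by [write_panel()] (via
#' \pkg{vcfR}) and restores the 0-based dosage tibble.
#'
#' @param path Path to the truth VCF.
#' @return A tibble `contig`, `pos`, `genotype`, `dosage`.
#' @export
read_truth_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(v@fix) == 0) {
    return(tibble(contig = character(), pos = integer(),
                  genotype = character(), dosage = integer()))
  }
  ds <- vcfR::extract.gt(v, element = "DS")
  genotypes <- colnames(ds)
  tibble(
    contig = rep(unname(v@fix[, "CHROM"]), times = length(genotypes)),
    pos = rep(as.integer(v@fix[, "POS"]) - 1L, times = length(genotypes)),
    genotype = rep(genotypes, each = nrow(ds)),
    dosage = as.integer(ds)
  ) %>%
    mutate(genotype = factor(.data$genotype, genotypes)) %>%
    arrange(.data$contig, .data$pos, as.integer(.data$genotype)) %>%
    mutate(genotype = as.character(.data$genotype))
}
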