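#' Describe a genotype panel and its grouping structure
#'
#' A group specification maps every genotype to its ploidy, its main group
#' and (optionally) a subgroup such as a commercial breeding program. It is
#' the tabular equivalent of the panel-description table of a germplasm
#' survey and is consumed by every group-aware operation in the package.
#'
#' @param genotype Character vector of unique genotype identifiers.
#' @param ploidy Integer vector (2 or 4), recycled if length 1.
#' @param group Character vector of main group labels.
#' @param subgroup Optional character vector of subgroup labels (`NA` where a
#'   genotype belongs to no subgroup).
#'
#' @return A tibble with columns `genotype`, `ploidy`, `group`, `subgroup`.
#' @export
#' @examples
#' group_spec(c("g1", "g2", "g3"), c(4, 4, 2), c("A", "A", "B"))
group_spec <- function(genotype, ploidy, group, subgroup = NA_character_) {
  genotype <- as.character(genotype)
  if (anyDuplicated(genotype)) {
    abort("genotype identifiers must be unique")
  }
  ploidy <- as.integer(rep_len(ploidy, length(genotype)))
  if (!all(ploidy %in% c(2L, 4L))) {
    abort("ploidy must be 2 or 4 for every genotype")
  }
  tibble(
    genotype = genotype,
    ploidy = ploidy,
    group = as.character(rep_len(group, length(genotype))),
    subgroup = as.character(rep_len(subgroup, length(genotype)))
  )
}

#' The 27-genotype alfalfa panel layout
#'
#' Returns the grouping structure of the mixed-ploidy alfalfa diversity panel
#' that this package's defaults emulate: 16 elite tetraploid *sativa*
#' genotypes from four commercial breeding programs (FGI, C/W, Pioneer, DL),
#' six cultivated tetraploid mapping-population parents, and five wild
#' genotypes (two diploid *caerulea*, two diploid *falcata*, one tetraploid
#' *falcata*).
#'
#' @return A group-spec tibble (see [group_spec()]) with 27 rows. The
#'   `subgroup` column carries the breeding program for Group1 genotypes and
#'   the subspecies for the wild Group3 genotypes.
#' @export
#' @examples
#' dplyr::count(alfalfa_groups(), group, ploidy)
alfalfa_groups <- function() {
  elite <- group_spec(
    genotype = c(
      "B75GH-402", "B85-912", "B85-920", "B86-220",
      "CW A-9", "CW B-7", "CW D-10", "CW I-4",
      "CV020017", "DW000577", "LH050543", "NL002724",
      "DL317", "DL833", "DL879W4", "DL263"
    ),
    ploidy = 4L,
    group = "Group1",
    subgroup = rep(c("FGI", "C/W", "Pioneer", "DL"), each = 4)
  )
  parents <- group_spec(
    genotype = c("95-608", "Altet-4", "NECS-141", "ABI408", "Gabes", "Magali-A"),
    ploidy = 4L,
    group = "Group2"
  )
  wild <- group_spec(
    genotype = c("PI243225-A", "PI577551-B", "PI631816-A", "PI251830-K", "WISFAL-6"),
    ploidy = c(2L, 2L, 2L, 2L, 4L),
    group = "Group3",
    subgroup = c("caerulea", "caerulea", "falcata", "falcata", "falcata")
  )
  bind_rows(elite, parents, wild)
}

#' Configure a synthetic mixed-ploidy panel
#'
#' Bundles every knob of the synthetic panel generator. The defaults emulate
#' the alfalfa diversity panel the package targets: 27 genotypes in three
#' groups ([alfalfa_groups()]), an average read depth of 56x per genotype,
#' weak differentiation among the cultivated pools and stronger divergence of
#' the wild material.
#'
#' @param groups Group-spec tibble ([group_spec()]); defaults to
#'   [alfalfa_groups()].
#' @param n_contigs Number of contigs to simulate.
#' @param sites_per_contig Variant sites placed on each contig.
#' @param contig_length Contig length in bp (positions are drawn within it).
#' @param maf_law Ancestral minor/variant allele frequency law: either
#'   `list(law = "uniform", min, max)` or `list(law = "beta", shape1, shape2)`.
#' @param group_f Named numeric vector of Balding-Nichols drift parameters F,
#'   one entry per group, each in `[0, 1)`. `F = 0` means the group frequency
#'   equals the ancestral frequency exactly.
#' @param mean_depth Mean sequencing depth per genotype per site (> 0).
#' @param depth_dispersion Negative-binomial size parameter for depth;
#'   `Inf` gives Poisson depth.
#' @param error_rate Per-read allele miscall probability in `[0, 1]`.
#' @param quality_mean,quality_sd Phred-scale law for the mean quality of the
#'   variant-supporting bases at a site.
#' @param indel_rate Fraction of sites simulated as short InDels instead of
#'   SNPs (they travel the same filter path, like in transcriptome surveys).
#' @param n_chromosomes Chromosomes of the anchor genome to which contigs are
#'   assigned for SNP-density windows; 0 leaves contigs unanchored.
#' @param seed Integer seed; fully determines the generated panel.
#'
#' @return A list of class `panel_config`.
#' @export
#' @examples
#' cfg <- panel_config(n_contigs = 10, sites_per_contig = 5, seed = 1)
#' cfg$mean_depth
panel_config <- function(groups = alfalfa_groups(),
                         n_contigs = 200,
                         sites_per_contig = 10,
                         contig_length = 1000,
                         maf_law = list(law = "uniform", min = 0.05, max = 0.95),
                         group_f = NULL,
                         mean_depth = 56,
                         depth_dispersion = 5,
                         error_rate = 0.005,
                         quality_mean = 30,
                         quality_sd = 5,
                         indel_rate = 0.035,
                         n_chromosomes = 8,
                         seed = 1L) {
  group_names <- unique(groups$group)
  if (is.null(group_f)) {
    # cultivated pools barely drifted apart; wild material clearly diverged
    group_f <- setNames(rep(0.05, length(group_names)), group_names)
    group_f[length(group_f)] <- 0.25
  }
  if (is.null(names(group_f))) names(group_f) <- group_names
  stopifnot(
    n_contigs >= 0, sites_per_contig >= 0, contig_length >= 1,
    mean_depth > 0, depth_dispersion > 0,
    error_rate >= 0, error_rate <= 1,
    quality_mean >= 0, quality_sd >= 0,
    indel_rate >= 0, indel_rate <= 1
  )
  if (!setequal(names(group_f), group_names)) {
    abort("group_f must carry one entry per group in `groups`")
  }
  if (any(group_f < 0) || any(group_f >= 1)) {
    abort("Balding-Nichols F must lie in [0, 1); F = 1 is a degenerate Beta")
  }
  if (sites_per_contig > contig_length) {
    abort("sites_per_contig cannot exceed contig_length")
  }
  structure(
    list(
      groups = groups, n_contigs = as.integer(n_contigs),
      sites_per_contig = as.integer(sites_per_contig),
      contig_length = as.integer(contig_length),
      maf_law = maf_law, group_f = group_f,
      mean_depth = mean_depth, depth_dispersion = depth_dispersion,
      error_rate = error_rate,
      quality_mean = quality_mean, quality_sd = quality_sd,
      indel_rate = indel_rate, n_chromosomes = as.integer(n_chromosomes),
      seed = as.integer(seed)
    ),
    class = "panel_config"
  )
}

draw_ancestral <- function(n, maf_law) {
  switch(maf_law$law,
    uniform = runif(n, maf_law$min, maf_law$max),
    beta = rbeta(n, maf_law$shape1, maf_law$shape2),
    abort("maf_law$law must be 'uniform' or 'beta'")
  )
}

#' Draw per-group site allele frequencies under the Balding-Nichols model
#'
#' Each site receives one ancestral variant-allele frequency `p` from the
#' configured law; each group then draws its own frequency from
#' `Beta(p (1 - F) / F, (1 - p)(1 - F) / F)`, whose mean is `p` and variance
#' `F p (1 - p)`. With `F = 0` the group frequency is exactly `p`.
#'
#' @param config A [panel_config()]. `config$seed` is *not* applied here;
#'   call [simulate_panel()] for a fully seeded run, or seed the RNG yourself.
#' @return A tibble with columns `contig`, `pos`, `ref_allele`, `var_allele`,
#'   `variant_class`, `p_anc`, and one row per site x group with `group` and
#'   `freq`.
#' @export
simulate_frequencies <- function(config) {
  stopifnot(inherits(config, "panel_config"))
  n_sites <- config$n_contigs * config$sites_per_contig
  contigs <- sprintf("contig%05d", seq_len(max(config$n_contigs, 1)))
  if (n_sites == 0) {
    return(tibble(
      contig = character(), pos = integer(), ref_allele = character(),
      var_allele = character(), variant_class = character(),
      p_anc = double(), group = character(), freq = double()
    ))
  }
  sites <- tibble(
    contig = rep(contigs[seq_len(config$n_contigs)],
                 each = config$sites_per_contig),
    pos = as.vector(replicate(
      config$n_contigs,
      sort(sample.int(config$contig_length, config$sites_per_contig) - 1L)
    ))
  )
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_sites, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
  is_indel <- runif(n_sites) < config$indel_rate
  # short insertions/deletions share the ref/var two-allele representation
  ins <- runif(n_sites) < 0.5
  ref_out <- ifelse(is_indel & !ins, paste0(ref, alt), ref)
  var_out <- ifelse(is_indel & ins, paste0(ref, alt),
                    ifelse(is_indel & !ins, ref, alt))
  sites <- sites %>%
    mutate(
      ref_allele = ref_out, var_allele = var_out,
      variant_class = if_else(is_indel, "InDel", "SNP"),
      p_anc = draw_ancestral(n_sites, config$maf_law)
    )
  groups <- names(config$group_f)
  out <- tidyr::crossing(sites, group = groups) %>%
    arrange(.data$contig, .data$pos, match(.data$group, groups))
  f <- config$group_f[out$group]
  p <- out$p_anc
  f_safe <- ifelse(f == 0, 0.5, f)  # placeholder; overwritten below
  freq <- rbeta(nrow(out), p * (1 - f_safe) / f_safe,
                (1 - p) * (1 - f_safe) / f_safe)
  freq[f == 0] <- p[f == 0]
  freq[p == 0] <- 0
  freq[p == 1] <- 1
  out$freq <- freq
  out
}

#' Draw true dosage genotypes from group frequencies
#'
#' Within each group, each genotype's variant-allele dosage is binomial
#' `Binom(ploidy, group frequency)`: tetrasomic (ploidy 4) or disomic
#' (ploidy 2) Hardy-Weinberg equilibrium within groups.
#'
#' @param freqs Frequency tibble from [simulate_frequencies()].
#' @param groups Group-spec tibble giving each genotype's group and ploidy.
#' @return A tibble `contig`, `pos`, `genotype`, `ploidy`, `dosage`.
#' @export
simulate_genotypes <- function(freqs, groups) {
  stopifnot(all(freqs$freq >= 0 & freqs$freq <= 1))
  out <- freqs %>%
    select("contig", "pos", "group", "freq") %>%
    dplyr::inner_join(groups, by = "group", relationship = "many-to-many") %>%
    arrange(.data$contig, .data$pos, match(.data$genotype, groups$genotype))
  out$dosage <- rbinom(nrow(out), out$ploidy, out$freq)
  select(out, "contig", "pos", "genotype", "ploidy", "dosage")
}

#' Simulate per-genotype read counts from true dosages
#'
#' Depth at each genotype x site is negative-binomial (Poisson when
#' `depth_dispersion = Inf`); each read carries the variant allele with
#' probability `dosage / ploidy`, miscalled with probability `error_rate`.
#' The mean Phred quality of variant-supporting bases is drawn from a
#' truncated normal law and is 0 where no variant read was observed.
#'
#' @param truth Dosage tibble from [simulate_genotypes()].
#' @param sites Site tibble carrying `contig`, `pos`, `ref_allele`,
#'   `var_allele`, `variant_class` (e.g. distinct rows of
#'   [simulate_frequencies()] output).
#' @param config A [panel_config()].
#' @return A long site-counts tibble: `contig`, `pos`, `ref_allele`,
#'   `var_allele`, `variant_class`, `genotype` (factor; levels record column
#'   order), `ref_reads`, `var_reads`, `mean_var_quality`, sorted by contig
#'   then position.
#' @export
simulate_read_counts <- function(truth, sites, config) {
  genotype_order <- config$groups$genotype
  n <- nrow(truth)
  depth <- if (is.infinite(config$depth_dispersion)) {
    rpois(n, config$mean_depth)
  } else {
    rnbinom(n, size = config$depth_dispersion, mu = config$mean_depth)
  }
  e <- config$error_rate
  p_var <- truth$dosage / truth$ploidy * (1 - e) +
    (1 - truth$dosage / truth$ploidy) * e
  var_reads <- rbinom(n, depth, p_var)
  qual <- round(pmin(pmax(rnorm(n, config$quality_mean, config$quality_sd), 0), 41), 1)
  qual[var_reads == 0] <- 0
  truth %>%
    mutate(
      genotype = factor(.data$genotype, levels = genotype_order),
      ref_reads = depth - var_reads,
      var_reads = var_reads,
      mean_var_quality = qual
    ) %>%
    left_join(
      distinct(sites, .data$contig, .data$pos, .data$ref_allele,
               .data$var_allele, .data$variant_class),
      by = c("contig", "pos")
    ) %>%
    select("contig", "pos", "ref_allele", "var_allele", "variant_class",
           "genotype", "ref_reads", "var_reads", "mean_var_quality") %>%
    arrange(.data$contig, .data$pos, as.integer(.data$genotype))
}

#' Generate a complete synthetic panel with known truth
#'
#' Runs [simulate_frequencies()], [simulate_genotypes()] and
#' [simulate_read_counts()] under the single seed in `config`, and assembles
#' contig metadata (lengths plus anchor coordinates on a pseudo-genome when
#' `n_chromosomes > 0`). Identical configs give identical panels.
#'
#' @param config A [panel_config()].
#' @return A list of class `snp_panel` with elements `config`, `groups`,
#'   `freqs`, `truth` (dosages), `sites` (per-site alleles, class and
#'   `true_snp` flag: variant present in at least one genotype), `counts`
#'   (long site-counts tibble) and `contigs` (metadata tibble).
#' @export
#' @examples
#' panel <- simulate_panel(panel_config(n_contigs = 5, sites_per_contig = 4))
#' dplyr::glimpse(panel$counts)
simulate_panel <- function(config) {
  stopifnot(inherits(config, "panel_config"))
  set.seed(config$seed)
  freqs <- simulate_frequencies(config)
  truth <- simulate_genotypes(freqs, config$groups)
  site_cols <- distinct(freqs, .data$contig, .data$pos, .data$ref_allele,
                        .data$var_allele, .data$variant_class, .data$p_anc)
  counts <- simulate_read_counts(truth, site_cols, config)
  sites <- truth %>%
    group_by(.data$contig, .data$pos) %>%
    summarise(true_snp = any(.data$dosage > 0), .groups = "drop") %>%
    left_join(site_cols, ., by = c("contig", "pos"))
  contigs <- tibble(
    contig = sprintf("contig%05d", seq_len(config$n_contigs)),
    length = config$contig_length
  )
  if (config$n_chromosomes > 0 && config$n_contigs > 0) {
    # round-robin anchoring on a pseudo-genome, contigs laid end to end
    chrom <- rep_len(seq_len(config$n_chromosomes), config$n_contigs)
    contigs <- contigs %>%
      mutate(
        anchor_chromosome = sprintf("chr%d", chrom),
        anchor_position = (dplyr::row_number() - 1L) %/%
          config$n_chromosomes * config$contig_length
      )
  } else {
    contigs$anchor_chromosome <- NA_character_
    contigs$anchor_position <- NA_integer_
  }
  structure(
    list(config = config, groups = config$groups, freqs = freqs,
         truth = truth, sites = sites, counts = counts, contigs = contigs),
    class = "snp_panel"
  )
}

#' @export
print.snp_panel <- function(x, ...) {
  cat("<snp_panel>\n")
  cat("  genotypes:", nrow(x$groups),
      sprintf("(%s)", paste(dplyr::count(x$groups, .data$group)$n, collapse = "/")), "\n")
  cat("  contigs:  ", nrow(x$contigs), "\n")
  cat("  sites:    ", nrow(x$sites), "\n")
  cat("  seed:     ", x$config$seed, "\n")
  invisible(x)
}

#' Write a synthetic panel to disk
#'
#' Emits the interchange files downstream stages consume: the wide
#' count-table TSV, the truth VCF (1-based positions, exact-dosage `GT` plus
#' a `DS` dosage field), the group config (YAML) and the contig metadata TSV.
#' Re-reading with [read_panel()] reproduces the objects; a fixed seed gives
#' byte-identical files.
#'
#' @param panel An `snp_panel` from [simulate_panel()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_panel <- function(panel, dir) {
  stopifnot(inherits(panel, "snp_panel"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_counts_table(panel$counts, file.path(dir, "counts.tsv"))
  write_groups(panel$groups, file.path(dir, "groups.yml"))
  write_contigs(panel$contigs, file.path(dir, "contigs.tsv"))
  write_truth_vcf(panel, file.path(dir, "truth.vcf"))
  invisible(dir)
}

#' Read back a panel directory written by [write_panel()]
#'
#' @param dir Directory containing `counts.tsv`, `groups.yml`, `contigs.tsv`
#'   and `truth.vcf`.
#' @return A list with `counts`, `groups`, `contigs` and `truth` (dosage
#'   tibble recovered from the VCF `DS` field).
#' @export
read_panel <- function(dir) {
  list(
    counts = read_counts_table(file.path(dir, "counts.tsv")),
    groups = read_groups(file.path(dir, "groups.yml")),
    contigs = read_contigs(file.path(dir, "contigs.tsv")),
    truth = read_truth_vcf(file.path(dir, "truth.vcf"))
  )
}
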