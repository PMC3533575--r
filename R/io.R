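#' Read a site-counts table
#'
#' Reads the wide TSV interchange dialect: one row per variant site with key
#' columns `contig`, `pos0` (0-based position), `ref_allele`, `var_allele`,
#' `variant_class`, followed by three columns per genotype named
#' `ref_reads:<genotype>`, `var_reads:<genotype>`,
#' `mean_var_quality:<genotype>`. Genotype column order in the file is
#' preserved as the factor levels of the `genotype` column.
#'
#' @param path Path to the TSV file.
#' @return A long tibble with columns `contig`, `pos`, `ref_allele`,
#'   `var_allele`, `variant_class`, `genotype`, `ref_reads`, `var_reads`,
#'   `mean_var_quality`, sorted by `(contig, pos)`.
#' @export
read_counts_table <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    contig = readr::col_character(),
    pos0 = readr::col_integer(),
    ref_allele = readr::col_character(),
    var_allele = readr::col_character(),
    variant_class = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE)
  probs <- readr::problems(raw)
  if (nrow(probs) > 0) {
    abort(sprintf("malformed counts table %s: line %d (%s)",
                  path, probs$row[1] + 1L, probs$expected[1]))
  }
  key_cols <- c("contig", "pos0", "ref_allele", "var_allele", "variant_class")
  if (!all(key_cols %in% names(raw))) {
    abort(sprintf("counts table %s lacks key columns: %s", path,
                  paste(setdiff(key_cols, names(raw)), collapse = ", ")))
  }
  geno_cols <- setdiff(names(raw), key_cols)
  genotypes <- unique(sub("^[^:]+:", "", geno_cols))
  expected <- as.vector(t(outer(
    c("ref_reads", "var_reads", "mean_var_quality"), genotypes, paste, sep = ":")))
  if (!setequal(geno_cols, expected)) {
    abort(sprintf("counts table %s: genotype columns must come in ref_reads:/var_reads:/mean_var_quality: triples", path))
  }
  if (nrow(raw) == 0) {
    return(tibble(
      contig = character(), pos = integer(), ref_allele = character(),
      var_allele = character(), variant_class = character(),
      genotype = factor(character(), levels = genotypes),
      ref_reads = double(), var_reads = double(), mean_var_quality = double()
    ))
  }
  dup <- duplicated(raw[c("contig", "pos0", "var_allele")])
  if (any(dup)) {
    abort(sprintf("counts table %s: duplicate site at line %d",
                  path, which(dup)[1] + 1L))
  }
  bad <- which(apply(raw[paste0("ref_reads:", genotypes)] < 0 |
                       raw[paste0("var_reads:", genotypes)] < 0 |
                       raw[paste0("mean_var_quality:", genotypes)] < 0, 1, any))
  if (length(bad) > 0) {
    abort(sprintf("counts table %s: negative count or quality at line %d",
                  path, bad[1] + 1L))
  }
  raw %>%
    rename(pos = "pos0") %>%
    tidyr::pivot_longer(
      cols = dplyr::all_of(geno_cols),
      names_to = c(".value", "genotype"), names_sep = ":"
    ) %>%
    mutate(genotype = factor(.data$genotype, levels = genotypes)) %>%
    arrange(.data$contig, .data$pos, as.integer(.data$genotype))
}

#' Write a site-counts table
#'
#' Inverse of [read_counts_table()]; the written file round-trips
#' byte-stably through read/write.
#'
#' @param counts Long site-counts tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts_table <- function(counts, path) {
  genotypes <- genotype_levels(counts)
  triple_cols <- as.vector(t(outer(
    c("ref_reads", "var_reads", "mean_var_quality"), genotypes, paste,
    sep = ":")))
  if (nrow(counts) == 0) {
    empty <- tibble(contig = character(), pos0 = integer(),
                    ref_allele = character(), var_allele = character(),
                    variant_class = character())
    for (cl in triple_cols) empty[[cl]] <- double()
    readr::write_tsv(empty, path, progress = FALSE)
    return(invisible(path))
  }
  wide <- counts %>%
    mutate(genotype = as.character(.data$genotype)) %>%
    tidyr::pivot_wider(
      id_cols = c("contig", "pos", "ref_allele", "var_allele", "variant_class"),
      names_from = "genotype",
      values_from = c("ref_reads", "var_reads", "mean_var_quality"),
      names_glue = "{.value}:{genotype}"
    ) %>%
    arrange(.data$contig, .data$pos) %>%
    rename(pos0 = "pos")
  ordered_cols <- c("contig", "pos0", "ref_allele", "var_allele",
                    "variant_class", triple_cols)
  readr::write_tsv(wide[ordered_cols], path, progress = FALSE)
  invisible(path)
}

# genotype column order of a long counts/genotype tibble
genotype_levels <- function(x) {
  if (is.factor(x$genotype)) levels(x$genotype) else unique(as.character(x$genotype))
}

#' Read a group configuration file
#'
#' The config is YAML with a `ploidy:` map (genotype -> 2 or 4), a `groups:`
#' map (group name -> list of genotype ids) and an optional `subgroups:` map.
#' Every genotype must appear in exactly one group (and at most one
#' subgroup); groups may only reference genotypes present in the ploidy map.
#'
#' @param path Path to the YAML file.
#' @return A group-spec tibble (see [group_spec()]).
#' @export
read_groups <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$ploidy) || is.null(cfg$groups)) {
    abort(sprintf("group config %s must define 'ploidy' and 'groups'", path))
  }
  genotypes <- names(cfg$ploidy)
  assign_level <- function(level, name) {
    out <- setNames(rep(NA_character_, length(genotypes)), genotypes)
    for (grp in names(level)) {
      ids <- as.character(level[[grp]])
      if (length(ids) == 0) abort(sprintf("%s '%s' is empty", name, grp))
      if (anyDuplicated(ids)) {
        abort(sprintf("duplicate genotype '%s' in %s '%s'",
                      ids[anyDuplicated(ids)], name, grp))
      }
      unknown <- setdiff(ids, genotypes)
      if (length(unknown) > 0) {
        abort(sprintf("%s '%s' references unknown genotype '%s'",
                      name, grp, unknown[1]))
      }
      already <- ids[!is.na(out[ids])]
      if (length(already) > 0) {
        abort(sprintf("genotype '%s' assigned to more than one %s",
                      already[1], name))
      }
      out[ids] <- grp
    }
    out
  }
  group_of <- assign_level(cfg$groups, "group")
  if (anyNA(group_of)) {
    abort(sprintf("genotype '%s' belongs to no group",
                  genotypes[which(is.na(group_of))[1]]))
  }
  subgroup_of <- if (!is.null(cfg$subgroups)) {
    assign_level(cfg$subgroups, "subgroup")
  } else {
    setNames(rep(NA_character_, length(genotypes)), genotypes)
  }
  group_spec(
    genotype = genotypes,
    ploidy = vapply(cfg$ploidy, as.integer, integer(1)),
    group = unname(group_of),
    subgroup = unname(subgroup_of)
  )
}

#' Write a group configuration file
#'
#' Inverse of [read_groups()].
#'
#' @param groups Group-spec tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_groups <- function(groups, path) {
  split_ids <- function(key) {
    keep <- !is.na(groups[[key]])
    lapply(split(groups$genotype[keep], groups[[key]][keep]), as.list)
  }
  cfg <- list(
    ploidy = setNames(as.list(as.integer(groups$ploidy)), groups$genotype),
    groups = split_ids("group")
  )
  if (any(!is.na(groups$subgroup))) cfg$subgroups <- split_ids("subgroup")
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Read / write contig metadata
#'
#' Contig metadata is a TSV with columns `contig`, `length` (bp) and optional
#' anchor coordinates (`anchor_chromosome`, `anchor_position`) on a reference
#' pseudomolecule, used for SNP-density windows.
#'
#' @param path Path to the TSV file.
#' @return `read_contigs()`: a tibble; `write_contigs()`: `path`, invisibly.
#' @export
read_contigs <- function(path) {
  out <- readr::read_tsv(path, col_types = readr::cols(
    contig = readr::col_character(),
    length = readr::col_integer(),
    anchor_chromosome = readr::col_character(),
    anchor_position = readr::col_integer()
  ), progress = FALSE)
  if (any(out$length <= 0)) abort("contig lengths must be positive")
  out
}

#' @rdname read_contigs
#' @param contigs Contig metadata tibble.
#' @export
write_contigs <- function(contigs, path) {
  readr::write_tsv(contigs, path, progress = FALSE)
  invisible(path)
}

#' Summarise contig lengths into bins
#'
#' Counts contigs per length bin and the proportion of the total each bin
#' holds, as in assembly summary tables. Bins are half-open `[lo, hi)`
#' intervals defined by strictly increasing `breaks` and must cover every
#' length in the table.
#'
#' @param contigs Contig metadata tibble (needs a `length` column), with at
#'   least one row.
#' @param breaks Strictly increasing numeric vector of bin edges; use `Inf`
#'   as the last edge for an open-ended top bin.
#' @return A tibble with `bin` (label), `lo`, `hi`, `n`, `proportion`
#'   (percent of all contigs).
#' @export
#' @examples
#' ctg <- tibble::tibble(contig = c("c1", "c2"), length = c(120L, 900L))
#' contig_length_summary(ctg, c(100, 250, 1000))
contig_length_summary <- function(contigs, breaks) {
  if (nrow(contigs) == 0) {
    abort("contig table is empty: bin proportions are undefined")
  }
  if (is.unsorted(breaks, strictly = TRUE)) {
    abort("breaks must be strictly increasing (overlapping bins rejected)")
  }
  lens <- contigs$length
  if (any(lens < breaks[1]) || any(lens >= breaks[length(breaks)])) {
    abort("breaks must cover all contig lengths")
  }
  idx <- findInterval(lens, breaks)
  lo <- breaks[-length(breaks)]
  hi <- breaks[-1]
  n <- tabulate(idx, nbins = length(lo))
  tibble(
    bin = sprintf("[%s, %s)", format(lo, trim = TRUE), format(hi, trim = TRUE)),
    lo = lo, hi = hi, n = n,
    proportion = 100 * n / length(lens)
  )
}

#' Proportion of contigs at least a given length
#'
#' Computed from a [contig_length_summary()] table; `min_length` must be one
#' of the bin edges so the query is exact.
#'
#' @param summary Output of [contig_length_summary()].
#' @param min_length Length threshold in bp (a bin lower edge).
#' @return Percentage of contigs with length >= `min_length`.
#' @export
proportion_at_least <- function(summary, min_length) {
  if (!min_length %in% summary$lo) {
    abort("min_length must coincide with a bin edge")
  }
  100 * sum(summary$n[summary$lo >= min_length]) / sum(summary$n)
}
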