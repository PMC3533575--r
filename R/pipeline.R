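#' Configure an end-to-end pipeline run
#'
#' Collects input paths, stage parameters and output location for
#' [run_full()]. Either point `counts`/`groups`/`contigs` at existing files,
#' or supply `simulate = panel_config(...)` to generate a synthetic panel
#' (written under `<out_dir>/panel/` and then consumed through the same
#' file-based path as real data).
#'
#' @param out_dir Output directory.
#' @param counts,groups,contigs Input file paths (ignored when `simulate`
#'   is given).
#' @param simulate Optional [panel_config()] replacing file inputs.
#' @param filter A [filter_params()].
#' @param call A [call_params()].
#' @param flank HRM clean-flank length in bp.
#' @param window SNP-density window in bp.
#' @param clamp_negative Clamp negative NJ branch lengths to zero.
#' @param candidates Candidate-contig criteria: a named list of
#'   `list(polymorphic_in =, fixed_in =, min_cluster =)` entries, or `NULL`
#'   to auto-detect the caerulea/falcata criteria when those subgroups
#'   exist.
#' @param seed Seed forwarded to stochastic stages (permutation tests).
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir,
                       counts = NULL, groups = NULL, contigs = NULL,
                       simulate = NULL,
                       filter = filter_params(),
                       call = call_params(),
                       flank = 18,
                       window = 5e5,
                       clamp_negative = FALSE,
                       candidates = NULL,
                       seed = 1L) {
  if (is.null(simulate) && (is.null(counts) || is.null(groups) || is.null(contigs))) {
    abort("run_config needs either `simulate` or all of counts/groups/contigs paths",
          class = "tetrasnp_config_error")
  }
  structure(
    list(out_dir = out_dir, counts = counts, groups = groups,
         contigs = contigs, simulate = simulate, filter = filter,
         call = call, flank = flank, window = window,
         clamp_negative = clamp_negative, candidates = candidates,
         seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Load a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [run_config()]; `filter:` and
#' `call:` sub-maps override individual [filter_params()] / [call_params()]
#' fields.
#'
#' @param path Path to the YAML config.
#' @param out_dir Optional override of the configured output directory.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, out_dir = NULL) {
  cfg <- yaml::read_yaml(path)
  filter <- do.call(filter_params, cfg$filter %||% list())
  call <- do.call(call_params, cfg$call %||% list())
  simulate <- if (!is.null(cfg$simulate)) do.call(panel_config, cfg$simulate)
  run_config(
    out_dir = out_dir %||% cfg$out_dir %||%
      abort("config must set out_dir", class = "tetrasnp_config_error"),
    counts = cfg$counts, groups = cfg$groups, contigs = cfg$contigs,
    simulate = simulate, filter = filter, call = call,
    flank = cfg$flank %||% 18, window = cfg$window %||% 5e5,
    clamp_negative = isTRUE(cfg$clamp_negative),
    candidates = cfg$candidates, seed = cfg$seed %||% 1L
  )
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
          class = "tetrasnp_stage_error")
  })
}

default_candidates <- function(groups) {
  subs <- unique(groups$subgroup)
  out <- list()
  cultivated <- groups$genotype[groups$group %in% c("Group1", "Group2")]
  if ("caerulea" %in% subs && length(cultivated) > 0) {
    out$domestication <- list(
      polymorphic_in = groups$genotype[groups$subgroup %in% "caerulea"],
      fixed_in = cultivated
    )
  }
  if ("falcata" %in% subs) {
    fixed <- groups$genotype[!groups$subgroup %in% "falcata"]
    out$falcata_differentiation <- list(
      polymorphic_in = groups$genotype[groups$subgroup %in% "falcata"],
      fixed_in = fixed
    )
  }
  out
}

#' Run the full discovery-to-structure pipeline
#'
#' Orchestrates ingest (or simulation), the SNP filter cascade, VCF export,
#' HRM-eligible selection, core-set genotyping, heterozygosity, group and
#' subgroup polymorphism accounting (Venn regions), fixed-difference and
#' candidate-contig scans, SNP-density windows, simple-matching distances,
#' the neighbor-joining tree and PCA, writing every artifact plus a
#' machine-readable JSON report of per-stage counts. A failing stage aborts
#' with the stage name; reruns with the same config are byte-identical.
#'
#' @param config A [run_config()].
#' @return The report, invisibly (a named list; also written as
#'   `report.json`).
#' @export
#' @examples
#' \donttest{
#' cfg <- run_config(tempfile(), simulate = panel_config(
#'   n_contigs = 20, sites_per_contig = 5, seed = 7))
#' report <- run_full(cfg)
#' report$counts$n_pass
#' }
run_full <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  report <- list(seed = config$seed, counts = list(), outputs = list())

  if (!is.null(config$simulate)) {
    panel_dir <- file.path(out, "panel")
    stage("simulate", {
      panel <- simulate_panel(config$simulate)
      write_panel(panel, panel_dir)
    })
    config$counts <- file.path(panel_dir, "counts.tsv")
    config$groups <- file.path(panel_dir, "groups.yml")
    config$contigs <- file.path(panel_dir, "contigs.tsv")
  }

  counts <- stage("ingest", read_counts_table(config$counts))
  groups <- stage("ingest", read_groups(config$groups))
  contigs <- stage("ingest", read_contigs(config$contigs))
  n_sites <- nrow(distinct(counts, .data$contig, .data$pos))
  report$counts$n_sites_in <- n_sites

  params <- config$filter
  params$seed <- config$seed
  calls <- stage("call", call_variants(counts, params))
  inform(sprintf("call: %d/%d sites PASS", sum(calls$verdict == "PASS"),
                 nrow(calls)))
  stage("call", write_vcf(calls, file.path(out, "calls.vcf"),
                          contigs = contigs))
  report$counts$n_pass <- sum(calls$verdict == "PASS")
  report$counts$n_pass_snp <- sum(calls$verdict == "PASS" &
                                    calls$variant_class == "SNP")
  report$counts$fail_by_stage <- as.list(table(calls$verdict[calls$verdict != "PASS"]))

  hrm <- stage("hrm", hrm_eligible(calls, contigs, config$flank))
  readr::write_tsv(hrm, file.path(out, "hrm_eligible.tsv"), progress = FALSE)
  report$counts$n_hrm_eligible <- nrow(hrm)

  geno <- stage("genotype", core_set(calls, counts, config$call))
  write_genotype_matrix(geno, file.path(out, "genotype_matrix.tsv"))
  report$counts$n_core <- nrow(geno)

  het <- stage("genotype", heterozygosity(geno))
  pooled <- list()
  diploids <- groups[groups$ploidy == 2L, ]
  for (sg in unique(stats::na.omit(diploids$subgroup))) {
    ids <- diploids$genotype[diploids$subgroup %in% sg]
    if (length(ids) == 2 && nrow(geno) > 0) {
      pool <- pool_diploids(geno, groups, ids[1], ids[2])
      st <- pool[[3]]
      if (any(!is.na(st))) {
        pooled[[sg]] <- tibble(
          genotype = names(pool)[3],
          n_classified = sum(!is.na(st)),
          heterozygosity_pct = 100 * sum(st == "AB", na.rm = TRUE) /
            sum(!is.na(st))
        )
      }
    }
  }
  het <- bind_rows(het, bind_rows(pooled))
  readr::write_tsv(het, file.path(out, "heterozygosity.tsv"), progress = FALSE)

  partition <- stage("partition", {
    profile <- group_polymorphism(geno, groups, "group")
    venn <- venn_regions(profile)
    readr::write_tsv(venn, file.path(out, "venn_groups.tsv"), progress = FALSE)
    res <- list(venn_groups = venn)
    # subgroup Venn within each group that has >= 2 subgroups, restricted to
    # the SNPs polymorphic within that group
    for (grp in unique(groups$group)) {
      subs <- unique(stats::na.omit(groups$subgroup[groups$group == grp]))
      if (length(subs) >= 2) {
        keep <- !is.na(profile[[grp]]) & profile[[grp]]
        sub_profile <- group_polymorphism(geno[keep, , drop = FALSE],
                                          groups, "subgroup")
        sub_profile <- sub_profile[c("contig", "pos", subs)]
        sub_venn <- venn_regions(sub_profile)
        fname <- sprintf("venn_subgroups_%s.tsv", gsub("\\W", "_", grp))
        readr::write_tsv(sub_venn, file.path(out, fname), progress = FALSE)
        res[[paste0("venn_subgroups_", grp)]] <- sub_venn
      }
    }
    res
  })
  report$counts$venn_total <- sum(partition$venn_groups$count)

  fixed <- stage("partition", {
    grp_names <- unique(groups$group)
    pairs <- utils::combn(grp_names, 2, simplify = FALSE)
    purrr::map(pairs, function(pr) {
      nrow(fixed_differences(geno, groups, pr))
    }) %>%
      setNames(vapply(pairs, paste, character(1), collapse = "|"))
  })
  report$counts$fixed_differences <- fixed

  cands <- config$candidates %||% default_candidates(groups)
  cand_report <- list()
  for (nm in names(cands)) {
    cc <- stage("partition", candidate_contigs(
      geno, groups,
      polymorphic_in = cands[[nm]]$polymorphic_in,
      fixed_in = cands[[nm]]$fixed_in,
      min_cluster = cands[[nm]]$min_cluster %||% 5,
      label = nm
    ))
    flat <- cc %>%
      mutate(positions = vapply(.data$positions, paste, character(1),
                                collapse = ","))
    readr::write_tsv(flat, file.path(out, sprintf("candidates_%s.tsv", nm)),
                     progress = FALSE)
    cand_report[[nm]] <- list(
      n_qualifying_snps = nrow(attr(cc, "qualifying")),
      n_contigs = nrow(cc)
    )
  }
  report$counts$candidates <- cand_report

  if (any(!is.na(contigs$anchor_chromosome))) {
    dens <- stage("density", snp_density_windows(calls, contigs,
                                                 config$window))
    write_density_bedgraph(dens, file.path(out, "snp_density.bedgraph"))
    report$counts$n_density_windows <- nrow(dens)
  }

  if (nrow(geno) >= 1 && length(matrix_genotypes(geno)) >= 3) {
    structure_res <- stage("structure", {
      smd <- simple_matching_distance(geno)
      write_distance_phylip(smd, file.path(out, "distances.phy"))
      tree <- neighbor_joining(smd, clamp_negative = config$clamp_negative)
      write_newick(tree, file.path(out, "tree.nwk"))
      pca <- snp_pca(geno)
      readr::write_tsv(pca$scores, file.path(out, "pca_scores.tsv"),
                       progress = FALSE)
      readr::write_tsv(
        tibble(component = seq_along(pca$variance_fraction),
               variance_fraction = pca$variance_fraction),
        file.path(out, "pca_variance.tsv"), progress = FALSE)
      list(pc1 = pca$variance_fraction[1], pc2 = pca$variance_fraction[2])
    })
    report$counts$pc1_variance_pct <- 100 * structure_res$pc1
    report$counts$pc2_variance_pct <- 100 * structure_res$pc2
  }

  # conservation: every downstream count is bounded by its input
  stopifnot(report$counts$n_pass <= report$counts$n_sites_in,
            report$counts$n_core <= report$counts$n_pass_snp)
  report$outputs <- as.list(sort(list.files(out, recursive = TRUE)))
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = 10)
  invisible(report)
}

#' Summarise an assay-validation concordance table
#'
#' Given per-SNP flags for a wet-lab validation campaign (was the assay
#' attempted, did it amplify, did the assay genotypes agree with the
#' sequence-predicted ones), reports the amplification rate
#' (amplified/attempted) and concordance rate (concordant/amplified) as
#' rounded percentages.
#'
#' @param validation Tibble with logical columns `attempted`, `amplified`,
#'   `concordant`.
#' @return A one-row tibble: `n_attempted`, `n_amplified`, `n_concordant`,
#'   `amplification_pct`, `concordance_pct`.
#' @export
#' @examples
#' summarize_validation(tibble::tibble(
#'   attempted = rep(TRUE, 10),
#'   amplified = rep(c(TRUE, FALSE), c(9, 1)),
#'   concordant = rep(c(TRUE, FALSE), c(8, 2))))
summarize_validation <- function(validation) {
  stopifnot(all(c("attempted", "amplified", "concordant") %in%
                  names(validation)))
  if (any(validation$amplified & !validation$attempted) ||
      any(validation$concordant & !validation$amplified)) {
    abort("flags must be nested: concordant => amplified => attempted")
  }
  n_att <- sum(validation$attempted)
  if (n_att == 0) abort("no assays attempted: rates undefined")
  n_amp <- sum(validation$amplified)
  if (n_amp == 0) {
    warn("no assay amplified: concordance undefined")
  }
  tibble(
    n_attempted = n_att,
    n_amplified = n_amp,
    n_concordant = sum(validation$concordant),
    amplification_pct = round(100 * n_amp / n_att),
    concordance_pct = if (n_amp > 0) {
      round(100 * sum(validation$concordant) / n_amp)
    } else {
      NA_real_
    }
  )
}
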