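test_that("sample support applies inclusive thresholds per genotype", {
  # boundary genotype: var = 2 of 10 reads, quality exactly 20
  site <- site_tibble(ref = c(8, 10), var = c(2, 0), qual = c(20, 0))
  res <- sample_support_filter(site)
  expect_true(res$pass)
  expect_equal(res$supporting, "g01")

  # no variant reads anywhere
  expect_false(sample_support_filter(site_tibble(c(9, 9), c(0, 0)))$pass)

  # quality just below threshold blocks support despite depth and fraction
  site <- site_tibble(ref = 5, var = 5, qual = 19.9)
  expect_false(sample_support_filter(site)$pass)

  # zero-depth genotypes contribute no support and raise no error
  site <- site_tibble(ref = c(0, 8), var = c(0, 4), qual = c(0, 30))
  expect_equal(sample_support_filter(site)$supporting, "g02")
})

test_that("total-depth filter is strictly greater than 20", {
  expect_false(total_depth_filter(site_tibble(c(10, 8), c(1, 1))))  # 20
  expect_true(total_depth_filter(site_tibble(c(10, 9), c(1, 1))))   # 21
  expect_false(total_depth_filter(site_tibble(numeric(0), numeric(0),
                                              genotypes = character(0))))
})

test_that("contingency test matches hand-computed values", {
  # identical allele proportions across genotypes: perfect independence
  res <- contingency_test(site_tibble(c(5, 5, 5), c(1, 1, 1)))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  # maximally dependent 2x2: all expected cells are 5, statistic 20
  res <- contingency_test(site_tibble(c(10, 0), c(0, 10)))
  expect_equal(res$statistic, 20)
  expect_equal(res$df, 1L)
  expect_equal(res$p_value, pchisq(20, 1, lower.tail = FALSE))
  expect_lt(res$p_value, 0.01)

  # permutation mode also retains the site; exhaustive null puts only the
  # two extreme tables at or beyond the observed statistic
  res_perm <- contingency_test(
    site_tibble(c(10, 0), c(0, 10)),
    filter_params(p_value_method = "permutation", n_permutations = 2000,
                  seed = 9)
  )
  expect_lt(res_perm$p_value, 0.01)

  # agreement with stats::chisq.test on a generic table
  site <- site_tibble(c(12, 30, 7), c(8, 10, 9))
  res <- contingency_test(site)
  ref <- suppressWarnings(stats::chisq.test(
    rbind(site$ref_reads, site$var_reads), correct = FALSE))
  expect_equal(res$statistic, unname(ref$statistic))
  expect_equal(res$p_value, unname(ref$p.value))
})

test_that("zero variant rows and near-empty tables degrade to p = 1", {
  res <- contingency_test(site_tibble(c(30, 40), c(0, 0)))
  expect_equal(res$p_value, 1)
  expect_warning(
    res <- contingency_test(site_tibble(c(30, 0), c(5, 0))),
    "fewer than 2"
  )
  expect_equal(res$p_value, 1)
})

test_that("chi-square p agrees with the permutation null when cells are large", {
  set.seed(31)
  tables <- list(
    list(ref = c(40, 35, 42, 38), var = c(12, 20, 15, 11)),
    list(ref = c(25, 30, 28), var = c(25, 18, 26)),
    list(ref = c(60, 55), var = c(20, 28))
  )
  n_perm <- 10000
  for (tb in tables) {
    site <- site_tibble(tb$ref, tb$var)
    p_chi <- contingency_test(site)$p_value
    p_perm <- contingency_test(
      site, filter_params(p_value_method = "permutation",
                          n_permutations = n_perm, seed = 17))$p_value
    se <- sqrt(p_perm * (1 - p_perm) / n_perm)
    expect_lt(abs(p_chi - p_perm), 3 * se + 1e-4)
  }
})

test_that("permutation p-values ignore genotype column order", {
  params <- filter_params(p_value_method = "permutation",
                          n_permutations = 500, seed = 23)
  site <- site_tibble(c(12, 3, 25, 8), c(4, 9, 2, 8))
  shuffled <- site[c(3, 1, 4, 2), ]
  expect_identical(contingency_test(site, params)$p_value,
                   contingency_test(shuffled, params)$p_value)
})

test_that("the cascade matches a literal transcription on random tables", {
  set.seed(1234)
  counts <- random_sites(1000)
  calls <- suppressWarnings(call_variants(counts))
  wide <- dplyr::group_by(counts, contig)
  oracle <- dplyr::summarise(
    wide,
    verdict = oracle_verdict(ref_reads, var_reads, mean_var_quality),
    .groups = "drop"
  )
  merged <- dplyr::left_join(calls, oracle, by = "contig",
                             suffix = c("", "_oracle"))
  expect_equal(merged$verdict, merged$verdict_oracle)
  expect_gt(dplyr::n_distinct(merged$verdict), 1)  # cascade actually exercised
})

test_that("raising any threshold never turns a failing site into PASS", {
  set.seed(99)
  counts <- random_sites(300)
  base <- suppressWarnings(call_variants(counts, filter_params()))
  stricter <- list(
    filter_params(min_var_reads = 4),
    filter_params(min_mean_quality = 30),
    filter_params(min_var_fraction = 0.35),
    filter_params(min_total_reads_exclusive = 40),
    filter_params(alpha = 0.001)
  )
  for (params in stricter) {
    res <- suppressWarnings(call_variants(counts, params))
    newly_passing <- setdiff(res$contig[res$verdict == "PASS"],
                             base$contig[base$verdict == "PASS"])
    expect_length(newly_passing, 0)
  }
})

test_that("noiseless panels are recovered exactly by the cascade", {
  cfg <- panel_config(n_contigs = 40, sites_per_contig = 5,
                      mean_depth = 50, depth_dispersion = Inf,
                      error_rate = 0, indel_rate = 0, quality_sd = 0,
                      seed = 21)
  panel <- simulate_panel(cfg)
  calls <- call_variants(panel$counts)

  dosage_profile <- panel$truth %>%
    dplyr::group_by(contig, pos) %>%
    dplyr::summarise(n_carrier = sum(dosage > 0),
                     n_noncarrier = sum(dosage == 0),
                     max_frac = max(dosage / ploidy),
                     .groups = "drop")
  merged <- dplyr::left_join(calls, dosage_profile, c("contig", "pos"))

  # sites without any variant carrier can never pass (no false positives)
  expect_true(all(merged$verdict[merged$n_carrier == 0] != "PASS"))
  # clearly biallelic, dosage-heterogeneous sites (some genotype carries the
  # variant at allele fraction >= 1/2, some genotype lacks it) are all
  # recovered at depth 50
  het_sites <- merged$n_noncarrier > 0 & merged$max_frac >= 0.5
  expect_true(all(merged$verdict[het_sites] == "PASS"))
  # a variant fixed in every genotype leaves no allele-frequency contrast:
  # the contingency stage correctly retains independence
  fixed_all <- dplyr::left_join(
    panel$truth %>%
      dplyr::group_by(contig, pos) %>%
      dplyr::summarise(all_fixed = all(dosage == ploidy), .groups = "drop"),
    merged, c("contig", "pos"))
  expect_true(all(fixed_all$verdict[fixed_all$all_fixed] == "contingency"))
})

test_that("uniform low-level noise fails sample support", {
  set.seed(5)
  n_geno <- 27
  site <- site_tibble(
    ref = rep(98, n_geno), var = rep(2, n_geno),  # 2% everywhere
    qual = rep(35, n_geno),
    genotypes = sprintf("g%02d", seq_len(n_geno))
  )
  calls <- call_variants(site)
  expect_equal(calls$verdict, "sample_support")
})

test_that("HRM eligibility requires clean full flanks on both sides", {
  contigs <- tibble::tibble(contig = "c1", length = 300L)
  make_calls <- function(pos, class = rep("SNP", length(pos)),
                         verdict = rep("PASS", length(pos))) {
    tibble::tibble(
      contig = "c1", pos = as.integer(pos), ref_allele = "A",
      var_allele = "T", variant_class = class, verdict = verdict
    )
  }
  # two PASS SNPs 10 bp apart exclude each other
  expect_equal(nrow(hrm_eligible(make_calls(c(100, 110)), contigs)), 0)
  # a lone mid-contig SNP is eligible
  expect_equal(nrow(hrm_eligible(make_calls(100), contigs)), 1)
  # neighbour at exactly the flank distance still disqualifies; one base
  # farther frees both
  expect_equal(nrow(hrm_eligible(make_calls(c(100, 118)), contigs)), 0)
  expect_equal(nrow(hrm_eligible(make_calls(c(100, 119)), contigs)), 2)
  # non-PASS neighbours are invisible; InDel neighbours are not
  expect_equal(nrow(hrm_eligible(
    make_calls(c(100, 110), verdict = c("PASS", "contingency")), contigs)), 1)
  expect_equal(nrow(hrm_eligible(
    make_calls(c(100, 110), class = c("SNP", "InDel")), contigs)), 0)
  # contig ends truncate the flank
  expect_equal(nrow(hrm_eligible(make_calls(17), contigs)), 0)
  expect_equal(nrow(hrm_eligible(make_calls(18), contigs)), 1)
  expect_equal(nrow(hrm_eligible(make_calls(281), contigs)), 1)
  expect_equal(nrow(hrm_eligible(make_calls(282), contigs)), 0)
})

test_that("HRM eligibility matches an exhaustive window scan on random layouts", {
  set.seed(77)
  contigs <- tibble::tibble(contig = sprintf("c%d", 1:20), length = 400L)
  flank <- 18
  for (rep in 1:5) {
    calls <- purrr::map_dfr(contigs$contig, function(ctg) {
      n <- sample(1:12, 1)
      tibble::tibble(
        contig = ctg, pos = sort(sample.int(400, n)) - 1L,
        ref_allele = "A", var_allele = "T",
        variant_class = sample(c("SNP", "InDel"), n, TRUE, prob = c(.8, .2)),
        verdict = sample(c("PASS", "sample_support"), n, TRUE, prob = c(.7, .3))
      )
    })
    got <- hrm_eligible(calls, contigs, flank)
    # oracle: for each PASS SNP scan every other PASS variant and the ends
    pass <- calls[calls$verdict == "PASS", ]
    want <- purrr::map_dfr(seq_len(nrow(pass)), function(i) {
      row <- pass[i, ]
      if (row$variant_class != "SNP") return(NULL)
      same <- pass[pass$contig == row$contig, ]
      others <- same[same$pos != row$pos, ]
      clean <- all(abs(others$pos - row$pos) > flank)
      len <- contigs$length[contigs$contig == row$contig]
      inside <- row$pos >= flank && row$pos <= len - 1 - flank
      if (clean && inside) row[c("contig", "pos")] else NULL
    })
    expect_equal(got[c("contig", "pos")],
                 dplyr::arrange(want, contig, pos))
  }
})
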