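make_design <- function(conditions = c("alt", "ref")) {
  tibble::tibble(
    sample_id = c("I-1", "I-2", "II-1", "II-2"),
    experiment_id = c("I", "I", "II", "II"),
    heavy_condition = conditions[c(2, 1, 2, 1)]
  )
}

# quant rows for one link across all four samples, doublet with the given
# condition ratio (alt/ref)
doublet_rows <- function(res_a, res_b, ratio, design,
                         conditions = c("alt", "ref"), base = 1e6) {
  purrr::map_dfr(seq_len(nrow(design)), function(i) {
    a_alt <- base * ratio
    a_ref <- base
    heavy1 <- design$heavy_condition[i] == conditions[1]
    tibble::tibble(
      sample_id = design$sample_id[i],
      peptide_pair_id = paste0(res_a, "-", res_b, "_p1"),
      res_a = res_a, res_b = res_b,
      area_light = if (heavy1) a_ref else a_alt,
      area_heavy = if (heavy1) a_alt else a_ref
    )
  })
}

test_that("peptide log ratios are condition-oriented, not label-oriented", {
  conditions <- c("alt", "ref")
  rec <- tibble::tibble(area_light = 4e6, area_heavy = 1e6)
  # light carries alt when ref is heavy: ratio = light/heavy
  expect_equal(peptide_log_ratio(rec, "ref", conditions), 2)
  # swapping the label orientation with the same areas negates the ratio
  expect_equal(peptide_log_ratio(rec, "alt", conditions), -2)
  expect_equal(
    peptide_log_ratio(tibble::tibble(area_light = 5, area_heavy = 5),
                      "ref", conditions), 0)
  expect_error(
    peptide_log_ratio(tibble::tibble(area_light = 0, area_heavy = 5),
                      "ref", conditions), "singlet")
})

test_that("median normalization zeroes the sample median", {
  expect_equal(normalize_sample(c(1, 2, 3)), c(-1, 0, 1))
  expect_equal(normalize_sample(rep(3.7, 5)), rep(0, 5))
  set.seed(11)
  for (n in c(5, 8, 101)) {
    x <- rnorm(n, mean = runif(1, -2, 2))
    expect_equal(median(normalize_sample(x)), 0)
  }
  expect_error(normalize_sample(numeric(0)), "empty")
})

test_that("residue-pair fold change is the median of supporting peptides", {
  expect_equal(residue_pair_fold_change(c(0.9, 1.0, 1.3)), 1.0)
  expect_equal(residue_pair_fold_change(2.2), 2.2)
  expect_equal(residue_pair_fold_change(c(1, 3)), 2)  # midpoint convention
  expect_error(residue_pair_fold_change(numeric(0)), "at least one")
})

test_that("Significance A matches the erfc definition and the normal-CDF
           oracle", {
  set.seed(7)
  values <- rnorm(200)
  expect_equal(significance_A(values, median(values)), 0.5)
  # symmetric sample: a query at the 84.13th percentile has z ~ 1
  sym <- seq(-3, 3, length.out = 1001)
  p84 <- significance_A(sym, quantile(sym, 0.8413, names = FALSE))
  expect_equal(p84, 0.5 * pracma::erfc(1 / sqrt(2)), tolerance = 1e-3)
  expect_equal(p84, 0.1587, tolerance = 1e-3)
  # oracle agreement to 1e-12 on random inputs
  for (i in 1:5) {
    v <- rnorm(50 + i * 10, sd = runif(1, 0.5, 2))
    q <- rnorm(20, sd = 3)
    expect_equal(significance_A(v, q), sigA_oracle(v, q),
                 tolerance = 1e-12)
  }
  # monotone decreasing in distance from the median on each side
  v <- rnorm(100)
  up <- significance_A(v, median(v) + seq(0, 5, by = 0.25))
  down <- significance_A(v, median(v) - seq(0, 5, by = 0.25))
  expect_true(all(diff(up) < 0))
  expect_true(all(diff(down) < 0))
  expect_true(all(up > 0 & up <= 0.5))
  # degenerate inputs are rejected
  expect_error(significance_A(rnorm(5), 0), "at least 8")
  expect_error(significance_A(rep(1, 50), 2), "spread")
})

test_that("replica rules accept consistent pairs and reject the rest", {
  design <- make_design()
  conditions <- c("alt", "ref")

  # consistent doublets across both experiments: averaged (normalization
  # disabled: a single-link sample would be centered onto itself)
  q <- doublet_rows(10, 80, ratio = 2, design)
  fc <- quantify_crosslinks(q, design, conditions, normalize = FALSE)
  expect_equal(fc$detection, "quantified")
  expect_equal(fc$fold_change, 1)
  expect_equal(fc$n_experiments, 2)

  # quantified in only one replica of each experiment: rejected
  q1 <- q[q$sample_id %in% c("I-1", "II-1"), ]
  fc1 <- quantify_crosslinks(q1, design, conditions, normalize = FALSE)
  expect_equal(fc1$detection, "rejected")
  expect_match(fc1$reject_reason, "replica")

  # singlet for the same condition in both replicas: unique candidate
  qs <- q
  heavy1 <- design$heavy_condition[match(qs$sample_id,
                                         design$sample_id)] == "alt"
  # keep only the ref-condition area: ref is heavy where alt carried light
  qs$area_light[heavy1] <- qs$area_light[heavy1]  # ref signal
  qs$area_heavy[heavy1] <- 0
  qs$area_light[!heavy1] <- 0                     # ref is heavy here
  fc2 <- quantify_crosslinks(qs, design, conditions, normalize = FALSE)
  expect_equal(fc2$detection, "singlet_condition2")

  # doublet in experiment I, singlet in experiment II: doublet wins, flagged
  qm <- dplyr::bind_rows(
    doublet_rows(10, 80, 2, design[design$experiment_id == "I", ]),
    {
      x <- doublet_rows(10, 80, 2, design[design$experiment_id == "II", ])
      h1 <- design$heavy_condition[match(x$sample_id,
                                         design$sample_id)] == "alt"
      x$area_heavy[h1] <- 0
      x$area_light[!h1] <- 0
      x
    }
  )
  fcm <- quantify_crosslinks(qm, design, conditions, normalize = FALSE)
  expect_equal(fcm$detection, "quantified")
  expect_equal(fcm$flag, "mixed_detection")
})

test_that("mixing bias is removed by normalization and effects recovered", {
  # planted bias shifts raw ratios; normalization recenters each sample
  links <- tibble::tibble(
    link_id = paste0(1:20, "-", 101:120), res_a = 1:20, res_b = 101:120,
    present_1 = TRUE, present_2 = TRUE
  )
  sim <- simulate_quant(links, conditions = c("alt", "ref"),
                        effects = NULL, noise_sd = 0,
                        mixing_bias = c(`I-1` = 0.7, `I-2` = -0.4,
                                        `II-1` = 0.2, `II-2` = 0.5),
                        seed = 3)
  # raw ratios of a sample all equal its bias
  raw <- peptide_log_ratio(sim$quant[sim$quant$sample_id == "I-1", ],
                           "ref", c("alt", "ref"))
  expect_equal(unique(round(raw, 10)), 0.7)
  fc <- quantify_crosslinks(sim$quant, sim$design, c("alt", "ref"))
  expect_equal(fc$fold_change, rep(0, 20), tolerance = 1e-10)
})

test_that("zero-area doublets and malformed tables are rejected with row
           numbers", {
  design <- make_design()
  q <- doublet_rows(10, 80, 2, design)
  q$area_light[2] <- 0
  q$area_heavy[2] <- 0
  expect_error(validate_quant_table(q, design, c("alt", "ref")), "rows 2")
  q2 <- doublet_rows(10, 80, 2, design)[, -1]
  expect_error(validate_quant_table(q2, design, c("alt", "ref")),
               "sample_id")
})

test_that("classification recovers planted categories on the two-state
           preset", {
  p <- simulate_two_state_preset(seed = 1)
  fc <- quantify_crosslinks(p$sim$quant, p$sim$design, p$conditions)
  cmp <- classify_crosslinks(fc)
  est <- tidy(cmp)[, c("link_id", "category")]
  joined <- dplyr::inner_join(est, p$sim$truth[, c("link_id", "category")],
                              by = "link_id", suffix = c("_est", "_true"))
  expect_equal(nrow(joined), nrow(p$sim$truth))
  recovery <- mean(as.character(joined$category_est) == joined$category_true)
  expect_gte(recovery, 0.95)
})

test_that("label-swap antisymmetry: swapping conditions negates fold changes
           and mirrors categories", {
  p <- simulate_two_state_preset(seed = 4)
  fwd <- classify_crosslinks(
    quantify_crosslinks(p$sim$quant, p$sim$design, p$conditions))
  rev <- classify_crosslinks(
    quantify_crosslinks(p$sim$quant, p$sim$design, rev(p$conditions)))
  j <- dplyr::inner_join(tidy(fwd), tidy(rev), by = "link_id",
                         suffix = c("_f", "_r"))
  expect_equal(nrow(j), nrow(tidy(fwd)))
  quant <- !is.na(j$fold_change_f)
  expect_equal(j$fold_change_f[quant], -j$fold_change_r[quant])
  mirror <- c(unique_1 = "unique_2", enriched_1 = "enriched_2",
              mutual = "mutual", enriched_2 = "enriched_1",
              unique_2 = "unique_1")
  expect_equal(unname(mirror[as.character(j$category_f)]),
               as.character(j$category_r))
})

test_that("all-null comparisons classify everything as mutual", {
  design <- make_design()
  q <- purrr::map_dfr(1:12, function(i) {
    doublet_rows(i, 100 + i, ratio = 2^(0.01 * (i - 6)), design)
  })
  cmp <- classify_crosslinks(quantify_crosslinks(q, design,
                                                 c("alt", "ref")))
  expect_true(all(cmp$category == "mutual"))
})

test_that("three-way merge partitions links and flags reference conflicts", {
  mk <- function(ids, ratios, conditions) {
    design <- make_design(conditions)
    q <- purrr::map_dfr(seq_along(ids), function(i) {
      doublet_rows(ids[i], 500 + ids[i], ratios[i], design,
                   conditions = conditions)
    })
    classify_crosslinks(quantify_crosslinks(q, design, conditions))
  }
  ids <- 1:10
  ratios <- 2^seq(-0.2, 0.2, length.out = 10)
  cmp_a <- mk(ids, ratios, c("alt1", "ref"))
  cmp_b <- mk(ids[1:8], ratios[1:8], c("alt2", "ref"))
  mw <- merge_three_way(cmp_a, cmp_b)
  expect_equal(nrow(mw), 10)
  expect_equal(sum(mw$venn_category == "all_three"), 8)
  expect_equal(sum(mw$venn_category == "a_ref"), 2)
  # categories partition the union
  expect_equal(sum(table(mw$venn_category)), nrow(mw))
  expect_error(merge_three_way(cmp_a, mk(ids, ratios, c("x", "otherref"))),
               "reference")

  # conflicting reference presence: unique to alt1 in A (ref absent), but
  # quantified (ref present) in B
  design <- make_design(c("alt1", "ref"))
  qa <- doublet_rows(77, 600, 2, design, conditions = c("alt1", "ref"))
  h1 <- design$heavy_condition[match(qa$sample_id,
                                     design$sample_id)] == "alt1"
  # keep only the alt1-condition signal in every sample
  qa$area_light[h1] <- 0
  qa$area_heavy[!h1] <- 0
  base <- purrr::map_dfr(1:9, function(i) {
    doublet_rows(i, 500 + i, 2^(0.02 * (i - 5)), design,
                 conditions = c("alt1", "ref"))
  })
  cmp_a2 <- classify_crosslinks(
    quantify_crosslinks(dplyr::bind_rows(base, qa), design,
                        c("alt1", "ref")))
  design_b <- make_design(c("alt2", "ref"))
  qb <- purrr::map_dfr(c(1:9, 77), function(i) {
    doublet_rows(i, if (i == 77) 600 else 500 + i, 1, design_b,
                 conditions = c("alt2", "ref"))
  })
  cmp_b2 <- classify_crosslinks(
    quantify_crosslinks(qb, design_b, c("alt2", "ref")))
  mw2 <- merge_three_way(cmp_a2, cmp_b2)
  expect_equal(sum(mw2$conflict), 1)
  expect_equal(mw2$link_id[mw2$conflict], "77-600")
})
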