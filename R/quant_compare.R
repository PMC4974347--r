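#' Validate a quantitation table
#'
#' A quantitation table has one row per cross-linked peptide pair per sample,
#' with columns `sample_id`, `peptide_pair_id`, `res_a`, `res_b`,
#' `area_light`, `area_heavy` (elution peak areas of the light- and
#' heavy-linker signals; zero or `NA` means not observed) and optionally
#' `type_a`, `type_b`. The experimental design table maps each `sample_id` to
#' an `experiment_id` and to `heavy_condition`, the condition whose protein
#' was cross-linked with the heavy reagent (the label swap exchanges this
#' between the two samples of an experiment).
#'
#' @param quant_tbl Quantitation table (data frame).
#' @param design Design table with columns `sample_id`, `experiment_id`,
#'   `heavy_condition`.
#' @param conditions Character vector of the two condition names,
#'   `c(condition1, condition2)`; fold changes are log2(condition1/condition2)
#'   and `condition2` is the reference.
#'
#' @return The validated quantitation tibble with a `detection` column
#'   (`"doublet"`, `"singlet"`), invisibly usable downstream. Malformed rows
#'   raise an error naming the offending row numbers.
#' @export
validate_quant_table <- function(quant_tbl, design, conditions) {
  quant_tbl <- tibble::as_tibble(quant_tbl)
  design <- tibble::as_tibble(design)
  needed <- c("sample_id", "peptide_pair_id", "res_a", "res_b",
              "area_light", "area_heavy")
  miss <- setdiff(needed, names(quant_tbl))
  if (length(miss) > 0) {
    stop("Quantitation table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!all(c("sample_id", "experiment_id", "heavy_condition") %in%
             names(design))) {
    stop("Design table needs sample_id, experiment_id, heavy_condition.",
         call. = FALSE)
  }
  if (length(conditions) != 2 || anyDuplicated(conditions)) {
    stop("`conditions` must name two distinct conditions.", call. = FALSE)
  }
  if (!all(design$heavy_condition %in% conditions)) {
    stop("Design `heavy_condition` values must be one of the two conditions.",
         call. = FALSE)
  }
  unknown <- !quant_tbl$sample_id %in% design$sample_id
  if (any(unknown)) {
    stop("Rows with sample_id absent from the design: rows ",
         paste(utils::head(which(unknown), 10), collapse = ", "),
         call. = FALSE)
  }
  al <- quant_tbl$area_light
  ah <- quant_tbl$area_heavy
  al[is.na(al)] <- 0
  ah[is.na(ah)] <- 0
  bad <- al < 0 | ah < 0
  if (any(bad)) {
    stop("Negative peak areas in rows: ",
         paste(utils::head(which(bad), 10), collapse = ", "), call. = FALSE)
  }
  none <- al == 0 & ah == 0
  if (any(none)) {
    stop("Rows with neither light nor heavy signal: rows ",
         paste(utils::head(which(none), 10), collapse = ", "), call. = FALSE)
  }
  quant_tbl$area_light <- al
  quant_tbl$area_heavy <- ah
  quant_tbl$detection <- ifelse(al > 0 & ah > 0, "doublet", "singlet")
  normalize_links(quant_tbl)
}

#' Per-peptide log2 fold change between conditions
#'
#' Converts light/heavy peak areas into a condition-oriented log2 ratio
#' (condition1 over condition2), using the sample's label orientation so the
#' ratio always refers to conditions, never to labels: if condition1 carried
#' the heavy linker, the ratio is heavy/light, otherwise light/heavy.
#'
#' @param rec One or more doublet quantitation rows (with `area_light`,
#'   `area_heavy`).
#' @param heavy_condition The condition cross-linked with the heavy reagent
#'   in the sample(s) (recycled to rows).
#' @inheritParams validate_quant_table
#' @return Numeric vector of log2(condition1/condition2) values.
#' @export
peptide_log_ratio <- function(rec, heavy_condition, conditions) {
  rec <- tibble::as_tibble(rec)
  if (any(rec$area_light <= 0 | rec$area_heavy <= 0, na.rm = FALSE)) {
    stop(paste0("peptide_log_ratio() is defined for doublet signals only; ",
                "singlet records belong to the unique-link path ",
                "(see quantify_crosslinks())."), call. = FALSE)
  }
  heavy_condition <- rep_len(heavy_condition, nrow(rec))
  a1 <- ifelse(heavy_condition == conditions[1], rec$area_heavy,
               rec$area_light)
  a2 <- ifelse(heavy_condition == conditions[1], rec$area_light,
               rec$area_heavy)
  log2(a1 / a2)
}

#' Median-center the log ratios of one sample
#'
#' Subtracts the sample median from every peptide-pair log ratio, correcting
#' systematic mixing-ratio bias between the pooled samples; the normalized
#' sample has median zero (midpoint convention for even counts).
#'
#' @param ratios Non-empty numeric vector of log2 ratios.
#' @return Numeric vector, median-centered.
#' @export
normalize_sample <- function(ratios) {
  if (length(ratios) == 0) {
    stop("Cannot normalize an empty ratio vector.", call. = FALSE)
  }
  ratios - stats::median(ratios)
}

#' Residue-pair fold change from supporting peptides
#'
#' The fold change of a cross-linked residue pair is the median of the
#' normalized log ratios of all peptide pairs supporting it (midpoint
#' convention for even counts).
#'
#' @param peptide_ratios Non-empty numeric vector.
#' @return The median.
#' @export
residue_pair_fold_change <- function(peptide_ratios) {
  if (length(peptide_ratios) == 0) {
    stop("A residue pair needs at least one supporting peptide ratio.",
         call. = FALSE)
  }
  stats::median(peptide_ratios)
}

#' Robust outlier p-value ("Significance A")
#'
#' Given a sample of log fold changes, tests whether a query value is an
#' outlier relative to the bulk using percentile-estimated one-sided spreads:
#' with m the median, the right spread is the 84.13th percentile minus m and
#' the left spread m minus the 15.87th percentile (each equals one standard
#' deviation for a Gaussian). The robust z-score of the query on its side is
#' converted to p = erfc(z / sqrt(2)) / 2, so p is in (0, 0.5] and values at
#' the median get p = 0.5.
#'
#' @param values Numeric vector (>= 8 values) defining the distribution.
#' @param query Numeric vector of values to test.
#' @return Numeric vector of p-values in (0, 0.5].
#' @export
significance_A <- function(values, query) {
  values <- values[is.finite(values)]
  if (length(values) < 8) {
    stop("significance_A() needs at least 8 finite values.", call. = FALSE)
  }
  m <- stats::median(values)
  qs <- stats::quantile(values, c(0.1587, 0.8413), names = FALSE, type = 7)
  sigma_l <- m - qs[1]
  sigma_r <- qs[2] - m
  if (sigma_l <= 0 || sigma_r <= 0) {
    stop("Zero spread on one side of the median; Significance A undefined.",
         call. = FALSE)
  }
  z <- ifelse(query >= m, (query - m) / sigma_r, (m - query) / sigma_l)
  0.5 * pracma::erfc(z / sqrt(2))
}

#' Quantify cross-links from a peptide-level table
#'
#' Runs the full quantitation pipeline: per-peptide condition-oriented log2
#' ratios, median normalization within each sample, the median-of-peptides
#' fold change per residue pair, label-swap replica validation within each
#' experiment, and averaging across experiments.
#'
#' Acceptance rules per experiment (two label-swapped samples): a link is
#' accepted as quantified when both samples see it as a doublet (the two
#' sample-level fold changes are averaged), and as a unique-link candidate
#' when both samples see a singlet for the same condition; anything else is
#' rejected with a reason code. Across experiments, doublet values are
#' averaged when present in both; a doublet in one experiment and a singlet
#' in the other resolves to the doublet value and is flagged
#' (`mixed_detection`).
#'
#' @inheritParams validate_quant_table
#' @param normalize Median-center each sample's peptide ratios before
#'   aggregation (default `TRUE`; disable only for diagnostic use on
#'   pre-normalized ratios).
#' @return A tibble with one row per cross-link: `link_id`, `res_a`, `res_b`,
#'   `detection` (`"quantified"`, `"singlet_condition1"`,
#'   `"singlet_condition2"`, `"rejected"`, `"conflict"`), `fold_change`,
#'   `n_supporting_peptides`, `n_experiments`, per-experiment values as a
#'   list column `experiment_values`, `flag` and `reject_reason`. Attribute
#'   `conditions` records the comparison orientation.
#' @export
quantify_crosslinks <- function(quant_tbl, design, conditions,
                                normalize = TRUE) {
  tbl <- validate_quant_table(quant_tbl, design, conditions)
  design <- tibble::as_tibble(design)
  tbl <- dplyr::left_join(
    tbl, design[, c("sample_id", "experiment_id", "heavy_condition")],
    by = "sample_id"
  )
  other <- function(cond) {
    ifelse(cond == conditions[1], conditions[2], conditions[1])
  }

  # peptide-level ratios, normalized per sample
  tbl$raw_ratio <- NA_real_
  dbl <- tbl$detection == "doublet"
  if (any(dbl)) {
    tbl$raw_ratio[dbl] <- peptide_log_ratio(tbl[dbl, ],
                                            tbl$heavy_condition[dbl],
                                            conditions)
  }
  tbl <- tbl |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(norm_ratio = if (normalize &&
                                   any(.data$detection == "doublet")) {
      .data$raw_ratio -
        stats::median(.data$raw_ratio[.data$detection == "doublet"])
    } else {
      .data$raw_ratio
    }) |>
    dplyr::ungroup()
  # condition observed by a singlet signal: the light signal belongs to the
  # condition that did not carry the heavy linker
  tbl$singlet_condition <- ifelse(
    tbl$detection == "singlet",
    ifelse(tbl$area_light > 0, other(tbl$heavy_condition),
           tbl$heavy_condition),
    NA_character_
  )

  # sample-level call per link: median of supporting peptides
  per_sample <- tbl |>
    dplyr::group_by(.data$experiment_id, .data$sample_id, .data$link_id,
                    .data$res_a, .data$res_b) |>
    dplyr::summarise(
      n_peptides = dplyr::n(),
      n_doublet = sum(.data$detection == "doublet"),
      value = if (any(.data$detection == "doublet")) {
        residue_pair_fold_change(
          .data$norm_ratio[.data$detection == "doublet"]
        )
      } else {
        NA_real_
      },
      singlet_condition = if (all(.data$detection == "singlet")) {
        if (length(unique(.data$singlet_condition)) == 1) {
          .data$singlet_condition[1]
        } else {
          "conflict"
        }
      } else {
        NA_character_
      },
      .groups = "drop"
    ) |>
    dplyr::mutate(call = dplyr::case_when(
      !is.na(.data$value) ~ "doublet",
      .data$singlet_condition == "conflict" ~ "conflict",
      TRUE ~ "singlet"
    ))

  per_experiment <- per_sample |>
    dplyr::group_by(.data$experiment_id, .data$link_id, .data$res_a,
                    .data$res_b) |>
    dplyr::summarise(
      res = list(combine_replica_pair(
        .data$call, .data$value, .data$singlet_condition,
        n_samples_in_experiment = 2
      )),
      n_peptides = sum(.data$n_peptides),
      .groups = "drop"
    ) |>
    tidyr::unnest_wider("res")

  out <- per_experiment |>
    dplyr::group_by(.data$link_id, .data$res_a, .data$res_b) |>
    dplyr::summarise(
      comb = list(combine_experiments(.data$status, .data$value,
                                      .data$singlet_condition,
                                      .data$reason)),
      n_supporting_peptides = sum(.data$n_peptides),
      n_experiments = sum(.data$status != "rejected"),
      experiment_values = list(stats::setNames(.data$value,
                                               .data$experiment_id)),
      .groups = "drop"
    ) |>
    tidyr::unnest_wider("comb")

  out$detection[out$detection == "singlet"] <-
    paste0("singlet_condition",
           match(out$singlet_condition[out$detection == "singlet"],
                 conditions))
  out <- dplyr::select(out, "link_id", "res_a", "res_b", "detection",
                       "fold_change", "n_supporting_peptides",
                       "n_experiments", "experiment_values", "flag",
                       "reject_reason")
  attr(out, "conditions") <- conditions
  out
}

# replica rule within one experiment (two label-swapped samples)
combine_replica_pair <- function(call, value, singlet_condition,
                                 n_samples_in_experiment = 2) {
  if (length(call) < n_samples_in_experiment) {
    return(list(status = "rejected", value = NA_real_,
                singlet_condition = NA_character_,
                reason = "not_in_both_replicas"))
  }
  if (all(call == "doublet")) {
    return(list(status = "doublet", value = mean(value),
                singlet_condition = NA_character_, reason = NA_character_))
  }
  if (all(call == "singlet") &&
      length(unique(singlet_condition)) == 1) {
    return(list(status = "singlet", value = NA_real_,
                singlet_condition = singlet_condition[1],
                reason = NA_character_))
  }
  list(status = "rejected", value = NA_real_,
       singlet_condition = NA_character_,
       reason = "inconsistent_between_replicas")
}

# combine experiment-level calls for one link
combine_experiments <- function(status, value, singlet_condition,
                                reason = NULL) {
  ok <- status != "rejected"
  if (!any(ok)) {
    why <- unique(stats::na.omit(reason))
    return(list(detection = "rejected", fold_change = NA_real_,
                singlet_condition = NA_character_, flag = NA_character_,
                reject_reason = if (length(why) > 0) {
                  paste(why, collapse = ";")
                } else {
                  "rejected_in_all_experiments"
                }))
  }
  status <- status[ok]
  value <- value[ok]
  singlet_condition <- singlet_condition[ok]
  if (all(status == "doublet")) {
    return(list(detection = "quantified", fold_change = mean(value),
                singlet_condition = NA_character_, flag = NA_character_,
                reject_reason = NA_character_))
  }
  if (all(status == "singlet")) {
    if (length(unique(singlet_condition)) == 1) {
      return(list(detection = "singlet", fold_change = NA_real_,
                  singlet_condition = singlet_condition[1],
                  flag = NA_character_, reject_reason = NA_character_))
    }
    return(list(detection = "conflict", fold_change = NA_real_,
                singlet_condition = NA_character_,
                flag = "conflicting_singlet_conditions",
                reject_reason = NA_character_))
  }
  # mixed doublet/singlet across experiments: resolve to the quantified call
  list(detection = "quantified",
       fold_change = mean(value[status == "doublet"]),
       singlet_condition = NA_character_, flag = "mixed_detection",
       reject_reason = NA_character_)
}

#' Classify quantified cross-links into five categories
#'
#' Links detected as a singlet for the same condition in both label-swapped
#' replicas are unique to that condition. Quantified links are tested with
#' [significance_A()] on the comparison's fold-change distribution: p below
#' `alpha` with a positive fold change means enriched in condition 1, with a
#' negative fold change enriched in condition 2; everything else is mutual.
#' When the quantified set is too small or has no spread for the outlier
#' test, all quantified links are reported mutual with `p_value = NA`.
#'
#' @param fc_tbl Output of [quantify_crosslinks()].
#' @param alpha Significance threshold (default 0.05, two-sided by
#'   construction of the one-sided spreads).
#' @return An `xl_comparison` tibble: the quantified and singlet links with
#'   `p_value` and `category` (`unique_1`, `enriched_1`, `mutual`,
#'   `enriched_2`, `unique_2`); rejected and conflicted links are kept in
#'   attribute `"dropped"`.
#' @export
classify_crosslinks <- function(fc_tbl, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  conditions <- attr(fc_tbl, "conditions")
  keep <- fc_tbl$detection %in% c("quantified", "singlet_condition1",
                                  "singlet_condition2")
  dropped <- fc_tbl[!keep, ]
  out <- fc_tbl[keep, ]
  quant <- out$detection == "quantified"
  out$p_value <- NA_real_
  vals <- out$fold_change[quant]
  if (sum(quant) > 0) {
    p <- tryCatch(significance_A(vals, vals), error = function(e) NULL)
    if (!is.null(p)) out$p_value[quant] <- p
  }
  out$category <- dplyr::case_when(
    out$detection == "singlet_condition1" ~ "unique_1",
    out$detection == "singlet_condition2" ~ "unique_2",
    !is.na(out$p_value) & out$p_value < alpha & out$fold_change > 0 ~
      "enriched_1",
    !is.na(out$p_value) & out$p_value < alpha & out$fold_change < 0 ~
      "enriched_2",
    TRUE ~ "mutual"
  )
  out$category <- factor(out$category, levels = xl_category_levels())
  attr(out, "conditions") <- conditions
  attr(out, "alpha") <- alpha
  attr(out, "dropped") <- dropped
  class(out) <- c("xl_comparison", class(out))
  out
}

xl_category_levels <- function() {
  c("unique_1", "enriched_1", "mutual", "enriched_2", "unique_2")
}

#' Category counts of a pairwise comparison
#'
#' @param cmp An `xl_comparison` from [classify_crosslinks()].
#' @return A tibble with `category` and `n` (all five categories, zero
#'   counts included), ordered unique_1, enriched_1, mutual, enriched_2,
#'   unique_2.
#' @export
category_counts <- function(cmp) {
  tab <- table(cmp$category)
  tibble::tibble(category = names(tab), n = as.integer(tab))
}

#' Merge two pairwise comparisons sharing their reference condition
#'
#' Combines, e.g., an A-versus-reference and a B-versus-reference comparison
#' into a three-way view. Each link's presence in {A, reference, B} is read
#' off its categories (a unique link is absent from the other condition; a
#' quantified link is present in both); links quantified in only one
#' comparison contribute no evidence about the unseen condition. Conflicting
#' presence calls for the shared reference (present in one comparison,
#' absent in the other) are flagged per link, never dropped silently.
#'
#' @param cmp_a,cmp_b `xl_comparison` objects whose `condition2` (the
#'   reference) is the same.
#' @return An `xl_threeway` tibble: one row per link in the union, with
#'   presence flags `in_a`, `in_ref`, `in_b`, the Venn `venn_category`
#'   (`a_only`, `b_only`, `ref_only`, `a_ref`, `b_ref`, `all_three`,
#'   `a_b_not_ref`), `conflict`, and the per-comparison categories.
#'   Attributes: `conditions` (a, ref, b) and `summary` (total, mutual to
#'   all three, unique to the reference, seventh-category count).
#' @export
merge_three_way <- function(cmp_a, cmp_b) {
  ca <- attr(cmp_a, "conditions")
  cb <- attr(cmp_b, "conditions")
  if (!identical(ca[2], cb[2])) {
    stop("The two comparisons must share their reference (condition2).",
         call. = FALSE)
  }
  presence <- function(cmp, nm) {
    tibble::tibble(
      link_id = cmp$link_id, res_a = cmp$res_a, res_b = cmp$res_b,
      "category_{nm}" := as.character(cmp$category),
      "in_cond_{nm}" := cmp$category %in% c("unique_1", "enriched_1",
                                            "mutual", "enriched_2"),
      "in_ref_{nm}" := cmp$category %in% c("enriched_1", "mutual",
                                           "enriched_2", "unique_2")
    )
  }
  m <- dplyr::full_join(presence(cmp_a, "a"), presence(cmp_b, "b"),
                        by = c("link_id", "res_a", "res_b"))
  m$conflict <- !is.na(m$in_ref_a) & !is.na(m$in_ref_b) &
    m$in_ref_a != m$in_ref_b
  m$in_a <- !is.na(m$in_cond_a) & m$in_cond_a
  m$in_b <- !is.na(m$in_cond_b) & m$in_cond_b
  m$in_ref <- (!is.na(m$in_ref_a) & m$in_ref_a) |
    (!is.na(m$in_ref_b) & m$in_ref_b)
  m$venn_category <- dplyr::case_when(
    m$in_a & m$in_ref & m$in_b ~ "all_three",
    m$in_a & m$in_ref ~ "a_ref",
    m$in_b & m$in_ref ~ "b_ref",
    m$in_ref ~ "ref_only",
    m$in_a & m$in_b ~ "a_b_not_ref",
    m$in_a ~ "a_only",
    TRUE ~ "b_only"
  )
  out <- dplyr::select(m, "link_id", "res_a", "res_b", "in_a", "in_ref",
                       "in_b", "venn_category", "conflict",
                       "category_a", "category_b")
  attr(out, "conditions") <- c(a = ca[1], ref = ca[2], b = cb[1])
  attr(out, "summary") <- list(
    n_total = nrow(out),
    n_all_three = sum(out$venn_category == "all_three"),
    n_ref_only = sum(out$venn_category == "ref_only"),
    n_seventh_category = sum(out$venn_category == "a_b_not_ref"),
    n_conflict = sum(out$conflict)
  )
  class(out) <- c("xl_threeway", class(out))
  out
}

#' Extract a modeling restraint set for one condition
#'
#' Links present in the chosen condition of a three-way merge become distance
#' restraints for integrative modeling. A link observed (with presence in
#' that condition) in both pairwise comparisons is assigned the
#' `"consistent"` uncertainty class; a link observed in only one comparison
#' the `"single"` class.
#'
#' @param merged An `xl_threeway` from [merge_three_way()].
#' @param condition Which condition's links to extract: `"ref"` (default),
#'   `"a"` or `"b"`.
#' @return A link tibble with `res_a`, `res_b`, `class`.
#' @export
modeling_restraint_set <- function(merged, condition = "ref") {
  condition <- match.arg(condition, c("ref", "a", "b"))
  flag <- switch(condition, ref = merged$in_ref, a = merged$in_a,
                 b = merged$in_b)
  keep <- merged[flag, ]
  n_seen <- (!is.na(keep$category_a)) + (!is.na(keep$category_b))
  tibble::tibble(
    res_a = keep$res_a, res_b = keep$res_b, link_id = keep$link_id,
    class = ifelse(n_seen >= 2, "consistent", "single")
  )
}

#' Write comparison results
#'
#' `write_comparison_tsv()` writes the per-link fold change, p-value and
#' category table; `comparison_summary_json()` writes the machine-readable
#' category counts of one or more comparisons (the numeric twin of a Venn /
#' category figure).
#'
#' @param cmp An `xl_comparison`.
#' @param path Output file path.
#' @export
write_comparison_tsv <- function(cmp, path) {
  out <- dplyr::select(tibble::as_tibble(cmp), -"experiment_values")
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @param ... Named `xl_comparison` / `xl_threeway` objects.
#' @rdname write_comparison_tsv
#' @export
comparison_summary_json <- function(path, ...) {
  objs <- list(...)
  payload <- lapply(objs, function(o) {
    if (inherits(o, "xl_threeway")) {
      attr(o, "summary")
    } else {
      cc <- category_counts(o)
      stats::setNames(as.list(cc$n), cc$category)
    }
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
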