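#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a pairwise comparison
#'
#' @param x An `xl_comparison`.
#' @param ... Unused.
#' @return A plain tibble, one row per classified cross-link.
#' @export
tidy.xl_comparison <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$experiment_values <- NULL
  out
}

#' @rdname tidy.xl_comparison
#' @export
glance.xl_comparison <- function(x, ...) {
  cc <- category_counts(x)
  n <- stats::setNames(as.list(cc$n), paste0("n_", cc$category))
  conditions <- attr(x, "conditions")
  tibble::as_tibble(c(
    list(condition1 = conditions[1], condition2 = conditions[2],
         n_quantified = nrow(x), alpha = attr(x, "alpha")),
    n
  ))
}

#' Tidy a three-way merge
#'
#' @param x An `xl_threeway`.
#' @param ... Unused.
#' @export
tidy.xl_threeway <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname tidy.xl_threeway
#' @export
glance.xl_threeway <- function(x, ...) {
  s <- attr(x, "summary")
  conditions <- attr(x, "conditions")
  tibble::tibble(
    condition_a = conditions[["a"]], condition_ref = conditions[["ref"]],
    condition_b = conditions[["b"]],
    n_total = s$n_total, n_all_three = s$n_all_three,
    n_ref_only = s$n_ref_only,
    n_seventh_category = s$n_seventh_category, n_conflict = s$n_conflict
  )
}

#' Tidy a sampled model ensemble
#'
#' @param x An `xl_ensemble`.
#' @param ... Unused.
#' @return One row per recorded model: `model`, `run`, `score`, psi values.
#' @export
tidy.xl_ensemble <- function(x, ...) {
  tibble::tibble(
    model = seq_along(x$scores), run = x$run, score = x$scores,
    psi_consistent = x$psis[, "consistent"], psi_single = x$psis[, "single"]
  )
}

#' @rdname tidy.xl_ensemble
#' @export
glance.xl_ensemble <- function(x, ...) {
  tibble::tibble(
    n_models = length(x$scores), n_beads = dim(x$coords)[2],
    n_runs = max(x$run), best_score = min(x$scores),
    acceptance_rate = x$acceptance_rate, swap_rate = x$swap_rate
  )
}

#' Tidy a clustering of solutions
#'
#' @param x An `xl_clusters`.
#' @param ... Unused.
#' @return One row per solution: `model`, `score`, `cluster`, `is_center`.
#' @export
tidy.xl_clusters <- function(x, ...) {
  tibble::tibble(
    model = x$solutions$model_index,
    score = x$solutions$scores,
    cluster = x$assignment,
    is_center = seq_along(x$assignment) %in% x$centers
  )
}

#' @rdname tidy.xl_clusters
#' @export
glance.xl_clusters <- function(x, ...) {
  tibble::tibble(
    k = x$k, best_cluster = x$best_cluster,
    sizes = paste(x$sizes, collapse = "/"),
    satisfaction = x$satisfaction[x$best_cluster]
  )
}
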