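# broom-style tidiers for the package's fitted objects.

#' Tidy a type-2 ROC
#'
#' @param x A `redecide_roc`.
#' @param ... Unused.
#' @return A tibble of ROC points (threshold, false-alarm rate, hit rate).
#' @export
tidy.redecide_roc <- function(x, ...) x$points

#' @rdname tidy.redecide_roc
#' @export
glance.redecide_roc <- function(x, ...) {
  tibble::tibble(a_roc = x$a_roc, n_error = x$n_error,
                 n_correct = x$n_correct, framing = x$framing)
}

#' Tidy a fitted GLM
#'
#' @param x A `redecide_glm_fit`.
#' @param ... Unused.
#' @return A tibble with one row per term: estimate, standard error, t
#'   statistic, p value and (where defined) VIF.
#' @export
tidy.redecide_glm_fit <- function(x, ...) {
  terms <- names(x$beta)
  vifs <- rep(NA_real_, length(terms))
  if (!is.null(x$vif)) vifs[match(names(x$vif), terms)] <- x$vif
  tibble::tibble(term = terms, estimate = unname(x$beta),
                 std.error = unname(x$se), statistic = unname(x$t),
                 p.value = unname(x$p), vif = vifs)
}

#' @rdname tidy.redecide_glm_fit
#' @export
glance.redecide_glm_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, sigma = x$sigma,
                 df.residual = x$df)
}

#' Tidy a connectivity result
#'
#' @param x A `redecide_connectivity`.
#' @param ... Unused.
#' @return A long tibble of ROI pairs and their per-condition trial-wise
#'   correlations.
#' @export
tidy.redecide_connectivity <- function(x, ...) {
  purrr::map_dfr(names(x$matrices), function(cd) {
    m <- x$matrices[[cd]]
    idx <- which(upper.tri(m), arr.ind = TRUE)
    tibble::tibble(condition = cd,
                   roi1 = rownames(m)[idx[, 1]],
                   roi2 = colnames(m)[idx[, 2]],
                   correlation = m[idx])
  })
}

#' Tidy a cohort summary
#'
#' @param x A `redecide_cohort_summary`.
#' @param ... Unused.
#' @return The per-session metrics tibble.
#' @export
tidy.redecide_cohort_summary <- function(x, ...) x$metrics

#' @rdname tidy.redecide_cohort_summary
#' @export
glance.redecide_cohort_summary <- function(x, ...) {
  tibble::tibble(
    n_participants = dplyr::n_distinct(x$metrics$participant),
    n_sessions = dplyr::n_distinct(x$metrics$session),
    mean_a_roc1 = mean(x$metrics$a_roc1, na.rm = TRUE),
    mean_accuracy1 = mean(x$metrics$accuracy1, na.rm = TRUE),
    mean_accuracy_change = mean(x$metrics$accuracy_change, na.rm = TRUE)
  )
}
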