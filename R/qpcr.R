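#' Relative expression by the comparative-Ct (2^-ddCt) method
#'
#' Technical replicates (repeated rows for the same target and sample) are
#' averaged on the Ct scale first. Per sample, `dCt = ct_target -
#' ct_reference`; per target, `ddCt = mean dCt(test group) - mean
#' dCt(calibrator group)`; relative expression is `2^(-ddCt)`, the fold
#' change of the test group over the calibrator. Amplification efficiency
#' is assumed to be 100% (the pure Livak model).
#'
#' @param records Tibble with columns `target_id`, `sample_id`, `group`,
#'   `ct_target`, `ct_reference`.
#' @param calibrator_group Group label used as calibrator; the remaining
#'   group is the test group.
#' @return A tibble: `target_id`, `ddct`, `fold_change`,
#'   `log2_fold_change`, `n_test`, `n_calibrator`.
#' @export
#' @examples
#' rec <- tibble::tibble(
#'   target_id = "CCND1",
#'   sample_id = c("CC_1", "CC_2", "GC_1", "GC_2"),
#'   group = c("CC", "CC", "GC", "GC"),
#'   ct_target = c(25, 25.4, 23, 23.4),
#'   ct_reference = c(18, 18.4, 18, 18.4))
#' relative_expression(rec, calibrator_group = "CC")
relative_expression <- function(records, calibrator_group) {
  records <- tibble::as_tibble(records)
  need <- c("target_id", "sample_id", "group", "ct_target", "ct_reference")
  stopifnot(all(need %in% names(records)))
  bad_ref <- records$sample_id[is.na(records$ct_reference)]
  if (length(bad_ref) > 0L) {
    stop("missing reference Ct for sample(s): ",
         paste(unique(bad_ref), collapse = ", "), call. = FALSE)
  }
  if (anyNA(records$ct_target) || any(records$ct_target <= 0) ||
      any(records$ct_reference <= 0) ||
      any(!is.finite(records$ct_target)) ||
      any(!is.finite(records$ct_reference))) {
    stop("Ct values must be positive and finite", call. = FALSE)
  }
  if (!calibrator_group %in% records$group) {
    stop("calibrator group '", calibrator_group, "' absent from records",
         call. = FALSE)
  }
  per_sample <- records |>
    dplyr::group_by(.data$target_id, .data$sample_id, .data$group) |>
    dplyr::summarise(ct_target = mean(.data$ct_target),
                     ct_reference = mean(.data$ct_reference),
                     .groups = "drop") |>
    dplyr::mutate(dct = .data$ct_target - .data$ct_reference)
  out <- per_sample |>
    dplyr::group_by(.data$target_id) |>
    dplyr::summarise(
      mean_dct_test = mean(.data$dct[.data$group != calibrator_group]),
      mean_dct_cal = mean(.data$dct[.data$group == calibrator_group]),
      n_test = sum(.data$group != calibrator_group),
      n_calibrator = sum(.data$group == calibrator_group),
      .groups = "drop")
  if (any(out$n_test == 0L) || any(out$n_calibrator == 0L)) {
    stop("every target needs samples in both groups", call. = FALSE)
  }
  out |>
    dplyr::mutate(ddct = .data$mean_dct_test - .data$mean_dct_cal,
                  fold_change = 2^(-.data$ddct),
                  log2_fold_change = -.data$ddct) |>
    dplyr::select("target_id", "ddct", "fold_change", "log2_fold_change",
                  "n_test", "n_calibrator")
}

#' RNA-seq vs RT-qPCR concordance
#'
#' Per shared target, a sign-agreement flag between the RNA-seq log2 fold
#' change and the log2 of the qPCR fold change, plus Spearman's rho across
#' the shared targets.
#'
#' @param rnaseq Tibble with columns `id`, `log2fc`.
#' @param qpcr Tibble with columns `target_id` (or `id`), `fold_change`,
#'   e.g. from [relative_expression()].
#' @return A list of class `qpcr_concordance`: `per_target` (tibble: `id`,
#'   `rnaseq_log2fc`, `qpcr_log2fc`, `agree`), `agreement` (fraction),
#'   `spearman_rho`.
#' @export
qpcr_concordance <- function(rnaseq, qpcr) {
  rnaseq <- tibble::as_tibble(rnaseq)
  qpcr <- tibble::as_tibble(qpcr)
  if ("target_id" %in% names(qpcr)) {
    qpcr <- dplyr::rename(qpcr, id = "target_id")
  }
  stopifnot(all(c("id", "log2fc") %in% names(rnaseq)),
            all(c("id", "fold_change") %in% names(qpcr)))
  tb <- dplyr::inner_join(rnaseq[, c("id", "log2fc")],
                          qpcr[, c("id", "fold_change")], by = "id")
  if (nrow(tb) == 0L) stop("no shared target ids", call. = FALSE)
  tb <- dplyr::mutate(tb,
                      rnaseq_log2fc = .data$log2fc,
                      qpcr_log2fc = log2(.data$fold_change),
                      agree = sign(.data$rnaseq_log2fc) ==
                        sign(.data$qpcr_log2fc)) |>
    dplyr::select("id", "rnaseq_log2fc", "qpcr_log2fc", "agree")
  rho <- if (nrow(tb) >= 3L) {
    spearman_rho(tb$rnaseq_log2fc, tb$qpcr_log2fc)
  } else NA_real_
  structure(list(per_target = tb,
                 agreement = mean(tb$agree),
                 spearman_rho = rho),
            class = "qpcr_concordance")
}

#' @export
print.qpcr_concordance <- function(x, ...) {
  cat("RNA-seq vs RT-qPCR concordance over ", nrow(x$per_target),
      " targets: ", round(100 * x$agreement, 1), "% sign agreement, ",
      "Spearman rho = ", signif(x$spearman_rho, 3), "\n", sep = "")
  invisible(x)
}

#' @rdname qpcr_concordance
#' @param x A `qpcr_concordance`.
#' @param ... Unused.
#' @export
tidy.qpcr_concordance <- function(x, ...) x$per_target

#' @rdname qpcr_concordance
#' @export
glance.qpcr_concordance <- function(x, ...) {
  tibble::tibble(n_targets = nrow(x$per_target), agreement = x$agreement,
                 spearman_rho = x$spearman_rho)
}
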