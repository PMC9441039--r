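#' FPKM normalization
#'
#' Fragments per kilobase of transcript per million mapped reads:
#' `FPKM[i, s] = 1e9 * C[i, s] / (N[s] * L[i])`, where `N[s]` is the column
#' total of raw counts and `L[i]` the transcript length in bp. Used for
#' mRNA and lncRNA, whose sequencing depth scales with length.
#'
#' @param x An [expr_mat()] of raw counts with lengths.
#' @return An `expr_mat` with `value_kind = "FPKM"`.
#' @export
#' @examples
#' tb <- tibble::tibble(id = "t1", length = 1000, s1 = 100)
#' m <- expr_mat(tb, "mRNA", c(s1 = "CC"))
#' # lone transcript: the column total is its own count
#' expr_values(fpkm_normalize(m))
fpkm_normalize <- function(x) {
  stopifnot(inherits(x, "expr_mat"))
  if (expr_kind(x) != "counts") {
    stop("fpkm_normalize() expects raw counts, got ", expr_kind(x),
         call. = FALSE)
  }
  if (!"length" %in% names(x)) {
    stop("FPKM requires transcript lengths", call. = FALSE)
  }
  m <- expr_values(x)
  totals <- colSums(m)
  if (any(totals <= 0)) {
    stop("zero column total in sample(s): ",
         paste(colnames(m)[totals <= 0], collapse = ", "), call. = FALSE)
  }
  fpkm <- 1e9 * sweep(m, 2, totals, "/") / x$length
  expr_replace_values(x, fpkm, "FPKM")
}

#' TPM normalization
#'
#' For miRNA matrices this is the small-RNA convention, tags per million:
#' `TPM[i, s] = 1e6 * C[i, s] / N[s]` with no length term. For mRNA/lncRNA
#' matrices the length-normalized definition is used:
#' `TPM[i, s] = 1e6 * (C[i, s]/L[i]) / sum_j (C[j, s]/L[j])`. Either way
#' every column sums to one million.
#'
#' @param x An [expr_mat()] of raw counts.
#' @return An `expr_mat` with `value_kind = "TPM"`.
#' @export
tpm_normalize <- function(x) {
  stopifnot(inherits(x, "expr_mat"))
  if (expr_kind(x) != "counts") {
    stop("tpm_normalize() expects raw counts, got ", expr_kind(x),
         call. = FALSE)
  }
  m <- expr_values(x)
  if (expr_class(x) != "miRNA") {
    if (!"length" %in% names(x)) stop("TPM for mRNA/lncRNA requires lengths",
                                      call. = FALSE)
    m <- m / x$length
  }
  totals <- colSums(m)
  if (any(totals <= 0)) {
    stop("zero column total in sample(s): ",
         paste(colnames(m)[totals <= 0], collapse = ", "), call. = FALSE)
  }
  tpm <- 1e6 * sweep(m, 2, totals, "/")
  expr_replace_values(x, tpm, "TPM")
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment of a family of p-values; a thin validating wrapper
#' around [stats::p.adjust()] so every module applies the same procedure.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted values in the input order, each `>=` its raw p-value
#'   and capped at 1.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Per-transcript differential-expression test
#'
#' A documented, pluggable stand-in for a full count-model DE fit: a Welch
#' two-sample t-test on `log2(value + pseudocount)`, comparing group B
#' against group A (A is the first group in the matrix's group ordering;
#' with the default study labels that is CC, so `log2fc > 0` means higher
#' in GC). Normalized values (FPKM/TPM) are the intended input. Externally
#' computed tables with columns `id`, `log2fc`, `p_value` can be supplied
#' to [filter_de()] directly, so results from a dedicated count model can
#' be substituted without touching the rest of the pipeline.
#'
#' When both groups have zero variance, the p-value is 1 if the means are
#' equal and 0 if they differ (a deterministic difference); this keeps the
#' output defined on degenerate rows.
#'
#' With `method = "moderated"` the per-transcript variance is moderated by
#' empirical-Bayes shrinkage toward the mean-variance trend
#' (limma's `lmFit()`/`eBayes()` on the same logged values). At two or
#' three replicates per group the unmoderated Welch test has so few
#' denominator degrees of freedom that genuinely shifted transcripts
#' rarely survive a BH gate over thousands of tests; moderation borrows
#' strength across transcripts and is the pipeline default. The reported
#' `log2fc` is identical under both methods.
#'
#' @param x An [expr_mat()], normally normalized values.
#' @param pseudocount Added before logging; default 1.
#' @param group_order Optional length-2 character giving (A, B); default is
#'   the order groups first appear in the matrix.
#' @param method `"welch"` (plain two-sample Welch t) or `"moderated"`
#'   (limma empirical-Bayes moderated t).
#' @return A tibble: `id`, `mean_A`, `mean_B`, `log2fc`, `p_value`.
#' @export
de_test <- function(x, pseudocount = 1, group_order = NULL,
                    method = c("welch", "moderated")) {
  method <- match.arg(method)
  stopifnot(inherits(x, "expr_mat"))
  groups <- expr_groups(x)
  lv <- if (is.null(group_order)) unique(unname(groups)) else group_order
  if (length(lv) != 2L) stop("exactly two groups are required", call. = FALSE)
  ia <- names(groups)[groups == lv[1]]
  ib <- names(groups)[groups == lv[2]]
  if (length(ia) < 2L || length(ib) < 2L) {
    stop("each group needs at least 2 samples", call. = FALSE)
  }
  m <- expr_values(x)
  la <- log2(m[, ia, drop = FALSE] + pseudocount)
  lb <- log2(m[, ib, drop = FALSE] + pseudocount)
  mean_a <- rowMeans(m[, ia, drop = FALSE])
  mean_b <- rowMeans(m[, ib, drop = FALSE])
  if (method == "welch") {
    ma <- rowMeans(la); mb <- rowMeans(lb)
    va <- apply(la, 1, stats::var); vb <- apply(lb, 1, stats::var)
    na <- length(ia); nb <- length(ib)
    se2 <- va / na + vb / nb
    tstat <- (mb - ma) / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
    degen <- se2 == 0
    p[degen] <- ifelse(abs(ma[degen] - mb[degen]) < 1e-12, 1, 0)
  } else {
    design <- cbind(intercept = 1,
                    groupB = as.numeric(c(ia, ib) %in% ib))
    fit <- limma::lmFit(cbind(la, lb), design)
    fit <- limma::eBayes(fit, trend = nrow(m) >= 50)
    p <- fit$p.value[, "groupB"]
    p[is.na(p)] <- 1
  }
  tibble::tibble(
    id = x$id,
    mean_A = unname(mean_a),
    mean_B = unname(mean_b),
    log2fc = unname(log2((mean_b + pseudocount) / (mean_a + pseudocount))),
    p_value = unname(p)
  )
}

#' Apply the differential-expression gates
#'
#' mRNA and lncRNA pass when `|log2fc| >= log2(fc_min)` and BH FDR
#' `< fdr_max`; miRNA pass on the raw p-value instead of the FDR
#' (`|log2fc| >= log2(fc_min)` and `p < p_max`). The defaults are the usual
#' two-fold / 0.05 gates. The FDR is computed here, across the supplied
#' family.
#'
#' @param de A tibble with columns `id`, `log2fc`, `p_value` (extra columns
#'   are kept), e.g. from [de_test()].
#' @param class_label `"mRNA"`, `"lncRNA"` or `"miRNA"` — selects which
#'   significance gate applies.
#' @param fc_min Minimum fold change (linear scale), default 2.
#' @param fdr_max FDR gate for mRNA/lncRNA, default 0.05.
#' @param p_max p-value gate for miRNA, default 0.05.
#' @return The input tibble with `fdr` and `call` (`"up"`, `"down"`,
#'   `"not_de"`) columns appended.
#' @export
filter_de <- function(de, class_label, fc_min = 2, fdr_max = 0.05,
                      p_max = 0.05) {
  class_label <- match.arg(class_label, c("mRNA", "lncRNA", "miRNA"))
  stopifnot(all(c("id", "log2fc", "p_value") %in% names(de)))
  de <- tibble::as_tibble(de)
  de$fdr <- bh_fdr(de$p_value)
  sig <- if (class_label == "miRNA") de$p_value < p_max else de$fdr < fdr_max
  pass <- sig & abs(de$log2fc) >= log2(fc_min)
  de$call <- dplyr::case_when(
    pass & de$log2fc > 0 ~ "up",
    pass ~ "down",
    .default = "not_de"
  )
  de$class <- class_label
  de
}

#' Volcano plot of a differential-expression table
#'
#' @param object A tibble from [filter_de()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_de_volcano <- function(object, ...) {
  stopifnot(all(c("log2fc", "p_value", "call") %in% names(object)))
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$log2fc,
                               y = -log10(pmax(.data$p_value, 1e-300)),
                               colour = .data$call)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(up = "#D55E00", down = "#0072B2",
                                            not_de = "grey70")) +
    ggplot2::labs(x = "log2 fold change (B vs A)", y = "-log10 p",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
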