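#' Upper-tail hypergeometric overlap probability
#'
#' Probability that two target sets drawn from a common miRNA universe
#' share at least the observed number of miRNAs: `P(X >= k)` for
#' `X ~ Hypergeometric(N, K, n)`, i.e.
#' `sum_{j=k}^{min(K,n)} C(K,j) C(N-K, n-j) / C(N,n)`.
#' Returns 1 when `k = 0`.
#'
#' @param k Observed shared count.
#' @param K Size of the first target set (miRNAs targeting the lncRNA).
#' @param n Size of the second target set (miRNAs targeting the mRNA).
#' @param N Universe size (distinct miRNAs considered).
#' @return The upper-tail probability; vectorized over all arguments.
#' @export
#' @examples
#' hypergeom_overlap_p(4, 4, 5, 10)  # 6/252
hypergeom_overlap_p <- function(k, K, n, N) {
  bad <- k < 0 | K < 0 | n < 0 | N < 0 | K > N | n > N | k > pmin(K, n) |
    k != round(k) | K != round(K) | n != round(n) | N != round(N)
  if (any(bad, na.rm = TRUE) || anyNA(bad)) {
    stop("invalid hypergeometric input: need 0 <= k <= min(K, n), K <= N, n <= N",
         call. = FALSE)
  }
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  # guard against tiny negative/overshoot from floating point
  pmin(pmax(p, 0), 1)
}

#' Spearman's rank correlation
#'
#' Pearson correlation of the average-rank vectors (ties get average
#' ranks). A constant vector leaves the coefficient undefined; `NA` is
#' returned with a warning rather than a silent 0.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return rho in \[-1, 1\], or `NA_real_` for degenerate input.
#' @export
spearman_rho <- function(x, y) {
  check_cor_input(x, y)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant vector: Spearman's rho is undefined", call. = FALSE)
    return(NA_real_)
  }
  stats::cor(x, y, method = "spearman")
}

#' Pearson's product-moment correlation
#'
#' @inheritParams spearman_rho
#' @return r in \[-1, 1\], or `NA_real_` for degenerate input.
#' @export
pearson_r <- function(x, y) {
  check_cor_input(x, y)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant vector: Pearson's r is undefined", call. = FALSE)
    return(NA_real_)
  }
  stats::cor(x, y, method = "pearson")
}

check_cor_input <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed", call. = FALSE)
  invisible(NULL)
}

#' Screening parameters for ceRNA pair inference
#'
#' Two named regimes cover the thresholds used at different stages of the
#' study design this package implements:
#'
#' * `lenient` (the default for network construction): a shared miRNA
#'   counts as evidence when Spearman's rho between it and each ceRNA is
#'   `<= -0.7`; the lncRNA-mRNA Pearson r must be `>= 0.9`; the
#'   shared-miRNA hypergeometric p must be `< 0.05`.
#' * `strict` (the reporting regime): rho `<= -0.95`, r `>= 0.95`,
#'   p `< 0.01`, plus a BH FDR gate on the hypergeometric test at `0.01`.
#'
#' Strict thresholds are nested inside the lenient ones, so the strict
#' network is always a subgraph of the lenient one.
#'
#' @param regime `"lenient"` or `"strict"`.
#' @param spearman_max,pearson_min,pair_p_max,pair_fdr_max Override any
#'   individual threshold; `pair_fdr_max = NULL` disables the FDR gate.
#' @param both_arms If `TRUE` (default) a shared miRNA must pass the
#'   Spearman screen against both the lncRNA and the mRNA; if `FALSE`,
#'   either arm suffices.
#' @return A list of class `cerna_params`.
#' @export
cerna_params <- function(regime = c("lenient", "strict"),
                         spearman_max = NULL, pearson_min = NULL,
                         pair_p_max = NULL, pair_fdr_max = NULL,
                         both_arms = TRUE) {
  regime <- match.arg(regime)
  defaults <- if (regime == "lenient") {
    list(spearman_max = -0.7, pearson_min = 0.9, pair_p_max = 0.05,
         pair_fdr_max = NULL)
  } else {
    list(spearman_max = -0.95, pearson_min = 0.95, pair_p_max = 0.01,
         pair_fdr_max = 0.01)
  }
  p <- list(
    regime = regime,
    spearman_max = spearman_max %||% defaults$spearman_max,
    pearson_min = pearson_min %||% defaults$pearson_min,
    pair_p_max = pair_p_max %||% defaults$pair_p_max,
    pair_fdr_max = if (is.null(pair_fdr_max)) defaults$pair_fdr_max else pair_fdr_max,
    both_arms = isTRUE(both_arms)
  )
  if (!(p$spearman_max < 0 && p$pearson_min > 0 && p$pearson_min <= 1 &&
        p$pair_p_max > 0 && p$pair_p_max <= 1)) {
    stop("thresholds out of range: need spearman_max < 0 < pearson_min <= 1, ",
         "0 < pair_p_max <= 1", call. = FALSE)
  }
  structure(p, class = "cerna_params")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Score candidate lncRNA-mRNA competing pairs
#'
#' For every (lncRNA, mRNA) pair sharing at least one miRNA in the
#' interaction table, the shared-miRNA overlap is tested against the
#' hypergeometric null (universe `N` = distinct miRNAs with at least one
#' interaction in the table; `K`, `n` = each partner's targeting-miRNA set
#' size; `k` = shared count), BH-adjusted across all scored pairs. A shared
#' miRNA counts as screen-passing evidence when its Spearman correlation
#' with the partner transcripts is at or below `spearman_max` (both arms by
#' default). A pair passes when the hypergeometric p is below `pair_p_max`
#' (and its FDR below `pair_fdr_max` when that gate is enabled), the
#' lncRNA-mRNA Pearson r is at least `pearson_min`, and at least one shared
#' miRNA passes the screen.
#'
#' The interaction table should already be restricted to the transcripts
#' and miRNAs of interest (the study scores differential RNAs only);
#' [run_cerna_pipeline()] performs that restriction.
#'
#' @param interactions Tibble with columns `mirna_id`, `transcript_id`,
#'   covering both lncRNA and mRNA targets.
#' @param lnc_expr,mrna_expr,mirna_expr Normalized [expr_mat()] objects
#'   sharing the same sample columns.
#' @param params A [cerna_params()] list.
#' @return A tibble of class `cerna_pairs`: `lncrna_id`, `mrna_id`, `k`,
#'   `K`, `n`, `N`, `hypergeom_p`, `hypergeom_fdr`, `pearson_r`,
#'   `n_screening_mirnas`, `shared_mirnas` (semicolon-joined), `passed`,
#'   `regime`.
#' @export
score_cerna_pairs <- function(interactions, lnc_expr, mrna_expr, mirna_expr,
                              params = cerna_params()) {
  stopifnot(inherits(params, "cerna_params"))
  empty <- tibble::tibble(
    lncrna_id = character(0), mrna_id = character(0), k = integer(0),
    K = integer(0), n = integer(0), N = integer(0),
    hypergeom_p = numeric(0), hypergeom_fdr = numeric(0),
    pearson_r = numeric(0), n_screening_mirnas = integer(0),
    shared_mirnas = character(0), passed = logical(0), regime = character(0))
  if (nrow(interactions) == 0L) {
    warning("empty interaction table: no pairs to score", call. = FALSE)
    return(structure(empty, class = c("cerna_pairs", class(empty))))
  }
  lnc_ids <- lnc_expr$id
  mrna_ids <- mrna_expr$id
  inter <- tibble::as_tibble(interactions)[, c("mirna_id", "transcript_id")]
  inter <- dplyr::distinct(inter)
  known <- c(lnc_ids, mrna_ids)
  unknown <- setdiff(inter$transcript_id, known)
  if (length(unknown) > 0L) {
    stop("interaction transcript(s) missing from expression matrices: ",
         paste(utils::head(unknown, 5L), collapse = ", "), call. = FALSE)
  }
  unknown_mi <- setdiff(inter$mirna_id, mirna_expr$id)
  if (length(unknown_mi) > 0L) {
    stop("interaction miRNA(s) missing from miRNA expression matrix: ",
         paste(utils::head(unknown_mi, 5L), collapse = ", "), call. = FALSE)
  }

  vl <- expr_values(lnc_expr); vm <- expr_values(mrna_expr)
  vmi <- expr_values(mirna_expr)
  samples <- colnames(vl)
  if (!identical(samples, colnames(vm)) || !identical(samples, colnames(vmi))) {
    stop("expression matrices must share identical sample columns",
         call. = FALSE)
  }

  targets_by_mirna <- split(inter$transcript_id, inter$mirna_id)
  mirnas_by_tx <- split(inter$mirna_id, inter$transcript_id)
  N <- length(targets_by_mirna)

  lnc_with_int <- intersect(lnc_ids, names(mirnas_by_tx))
  mrna_with_int <- intersect(mrna_ids, names(mirnas_by_tx))

  # precompute per-miRNA Spearman screens lazily, caching by (mirna, tx)
  rho_cache <- new.env(parent = emptyenv())
  rho_of <- function(mi, tx_id, tx_vals) {
    key <- paste0(mi, "\r", tx_id)
    if (!is.null(rho_cache[[key]])) return(rho_cache[[key]])
    r <- suppressWarnings(spearman_rho(vmi[mi, ], tx_vals))
    rho_cache[[key]] <- r
    r
  }

  rows <- list(); ri <- 0L
  for (lnc in lnc_with_int) {
    mi_l <- mirnas_by_tx[[lnc]]
    # candidate mRNAs: targets of this lncRNA's miRNAs
    cand <- unique(unlist(targets_by_mirna[mi_l], use.names = FALSE))
    cand <- intersect(cand, mrna_with_int)
    for (mr in cand) {
      mi_m <- mirnas_by_tx[[mr]]
      shared <- intersect(mi_l, mi_m)
      if (length(shared) == 0L) next
      k <- length(shared); K <- length(mi_l); n <- length(mi_m)
      p <- hypergeom_overlap_p(k, K, n, N)
      r_pair <- suppressWarnings(pearson_r(vl[lnc, ], vm[mr, ]))
      screen <- vapply(shared, function(mi) {
        r1 <- rho_of(mi, lnc, vl[lnc, ])
        r2 <- rho_of(mi, mr, vm[mr, ])
        if (is.na(r1) || is.na(r2)) return(FALSE)
        if (params$both_arms) {
          r1 <= params$spearman_max && r2 <= params$spearman_max
        } else {
          r1 <= params$spearman_max || r2 <= params$spearman_max
        }
      }, logical(1))
      ri <- ri + 1L
      rows[[ri]] <- tibble::tibble(
        lncrna_id = lnc, mrna_id = mr, k = k, K = K, n = n, N = N,
        hypergeom_p = p, pearson_r = r_pair,
        n_screening_mirnas = sum(screen),
        shared_mirnas = paste(sort(shared), collapse = ";"))
    }
  }
  if (ri == 0L) {
    warning("no lncRNA-mRNA pair shares a miRNA", call. = FALSE)
    return(structure(empty, class = c("cerna_pairs", class(empty))))
  }
  out <- dplyr::bind_rows(rows)
  out <- dplyr::arrange(out, .data$lncrna_id, .data$mrna_id)
  out$hypergeom_fdr <- bh_fdr(out$hypergeom_p)
  out$passed <- out$hypergeom_p < params$pair_p_max &
    !is.na(out$pearson_r) & out$pearson_r >= params$pearson_min &
    out$n_screening_mirnas >= 1L
  if (!is.null(params$pair_fdr_max)) {
    out$passed <- out$passed & out$hypergeom_fdr < params$pair_fdr_max
  }
  out$regime <- params$regime
  out <- dplyr::relocate(out, "hypergeom_fdr", .after = "hypergeom_p")
  structure(out, class = c("cerna_pairs", class(out)))
}

#' Over-representation test for user-supplied gene-set annotations
#'
#' Generic term-enrichment machinery (the GO/KEGG-style analysis) over a
#' user-supplied term-to-gene map: per term, the upper-tail hypergeometric
#' probability of the observed overlap between the query set and the term's
#' genes within the universe, BH-adjusted across terms. No annotation
#' database is bundled or downloaded.
#'
#' @param gene_set Character vector of query gene ids (subset of universe).
#' @param term_map Named list: term id -> character vector of member genes.
#' @param universe Character vector of all considered gene ids.
#' @return A tibble: `term`, `k`, `K`, `n`, `N`, `p_value`, `fdr`, ordered
#'   by `p_value`.
#' @export
overrepresentation_test <- function(gene_set, term_map, universe) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stop("empty universe", call. = FALSE)
  gene_set <- unique(as.character(gene_set))
  if (!all(gene_set %in% universe)) {
    stop("gene_set must be a subset of the universe", call. = FALSE)
  }
  if (length(term_map) == 0L || is.null(names(term_map))) {
    stop("term_map must be a named list of gene vectors", call. = FALSE)
  }
  N <- length(universe); n <- length(gene_set)
  res <- purrr::imap(term_map, function(genes, term) {
    genes <- intersect(unique(genes), universe)
    k <- length(intersect(genes, gene_set))
    tibble::tibble(term = term, k = k, K = length(genes), n = n, N = N,
                   p_value = hypergeom_overlap_p(k, length(genes), n, N))
  })
  out <- dplyr::bind_rows(res)
  out$fdr <- bh_fdr(out$p_value)
  dplyr::arrange(out, .data$p_value, .data$term)
}
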