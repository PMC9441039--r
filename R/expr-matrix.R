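#' Build an expression matrix tibble
#'
#' The package's central container for expression data is an ordinary tibble
#' with one row per transcript: an `id` column, an optional `length` column
#' (bp; required for mRNA and lncRNA so FPKM is defined), and one numeric
#' column per sample. Three attributes carry the metadata every downstream
#' operation needs: `class_label` (one of `"mRNA"`, `"lncRNA"`, `"miRNA"`),
#' `groups` (a named character vector mapping sample id to group label,
#' e.g. `"CC"` / `"GC"`), and `value_kind` (`"counts"`, `"FPKM"` or
#' `"TPM"`).
#'
#' @param values A data frame with columns `id`, optionally `length`, and
#'   one numeric column per sample.
#' @param class_label Transcript class: `"mRNA"`, `"lncRNA"` or `"miRNA"`.
#' @param groups Named character vector: `groups[sample_id]` is that
#'   sample's group label. Every sample column must appear exactly once.
#' @param value_kind `"counts"`, `"FPKM"` or `"TPM"`.
#'
#' @return A tibble of class `expr_mat` with the attributes described above.
#' @export
#' @examples
#' tb <- tibble::tibble(id = c("g1", "g2"), length = c(1000, 2000),
#'                      CC_1 = c(5, 0), GC_1 = c(9, 2))
#' m <- expr_mat(tb, "mRNA", c(CC_1 = "CC", GC_1 = "GC"))
#' expr_samples(m)
expr_mat <- function(values, class_label, groups, value_kind = "counts") {
  class_label <- match.arg(class_label, c("mRNA", "lncRNA", "miRNA"))
  value_kind <- match.arg(value_kind, c("counts", "FPKM", "TPM"))
  values <- tibble::as_tibble(values)
  if (!"id" %in% names(values)) {
    stop("expression table must have an 'id' column", call. = FALSE)
  }
  if (nrow(values) == 0L) {
    stop("expression table has no transcripts", call. = FALSE)
  }
  dup <- values$id[duplicated(values$id)]
  if (length(dup) > 0L) {
    stop("duplicated transcript id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  sample_ids <- setdiff(names(values), c("id", "length"))
  if (length(sample_ids) == 0L) {
    stop("expression table has no sample columns", call. = FALSE)
  }
  if (is.null(names(groups)) || !setequal(names(groups), sample_ids)) {
    stop("'groups' must be a named vector covering exactly the sample columns",
         call. = FALSE)
  }
  groups <- groups[sample_ids]
  for (s in sample_ids) {
    col <- values[[s]]
    if (!is.numeric(col)) {
      stop("non-numeric values in sample column '", s, "'", call. = FALSE)
    }
    if (anyNA(col) || any(col < 0)) {
      stop("negative or missing values in sample column '", s, "'",
           call. = FALSE)
    }
  }
  if (class_label != "miRNA") {
    if (!"length" %in% names(values)) {
      stop(class_label, " matrix requires a 'length' column", call. = FALSE)
    }
    if (anyNA(values$length) || any(values$length <= 0)) {
      stop("transcript lengths must be positive and complete", call. = FALSE)
    }
  }
  structure(values,
            class = c("expr_mat", class(tibble::tibble())),
            class_label = class_label,
            groups = groups,
            value_kind = value_kind)
}

#' @rdname expr_mat
#' @param x An `expr_mat`.
#' @export
expr_samples <- function(x) {
  setdiff(names(x), c("id", "length"))
}

#' @rdname expr_mat
#' @export
expr_groups <- function(x) attr(x, "groups")

#' @rdname expr_mat
#' @export
expr_class <- function(x) attr(x, "class_label")

#' @rdname expr_mat
#' @export
expr_kind <- function(x) attr(x, "value_kind")

#' Extract the numeric value matrix of an `expr_mat`
#'
#' @param x An `expr_mat`.
#' @return A numeric matrix, transcripts in rows (named by id), samples in
#'   columns.
#' @export
expr_values <- function(x) {
  samples <- expr_samples(x)
  m <- as.matrix(as.data.frame(x)[, samples, drop = FALSE])
  rownames(m) <- x$id
  m
}

# rebuild an expr_mat with the same metadata but new values
expr_replace_values <- function(x, m, value_kind) {
  out <- tibble::as_tibble(as.data.frame(x)[, intersect(c("id", "length"), names(x)),
                                            drop = FALSE])
  out <- dplyr::bind_cols(out, tibble::as_tibble(m))
  expr_mat(out, expr_class(x), expr_groups(x), value_kind)
}

#' Read a count matrix from TSV
#'
#' The expected layout is the one sequencing facilities typically deliver:
#' a header row of sample ids, a first column of transcript ids, and one
#' tab-separated numeric column per sample. Lengths for mRNA/lncRNA come
#' from a separate two-column TSV (`id`, `length`).
#'
#' @param path Path to the count TSV.
#' @param class_label `"mRNA"`, `"lncRNA"` or `"miRNA"`.
#' @param groups Named character vector mapping sample id to group.
#' @param lengths_path Optional path to the two-column length TSV; required
#'   unless `class_label == "miRNA"`.
#' @return An [expr_mat()] with `value_kind = "counts"`.
#' @export
read_counts <- function(path, class_label, groups, lengths_path = NULL) {
  tb <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(tb) == 0L || ncol(tb) < 2L) {
    stop("count file '", path, "' is empty or has no sample columns",
         call. = FALSE)
  }
  names(tb)[1] <- "id"
  tb$id <- as.character(tb$id)
  for (j in seq(2L, ncol(tb))) {
    if (!is.numeric(tb[[j]])) {
      stop("non-numeric cell in column '", names(tb)[j], "' of ", path,
           call. = FALSE)
    }
  }
  if (!is.null(lengths_path)) {
    len <- readr::read_tsv(lengths_path, col_names = c("id", "length"),
                           col_types = "cd", skip = 0, progress = FALSE)
    # tolerate a header row in the lengths file
    if (is.na(suppressWarnings(as.numeric(len$length[1])))) len <- len[-1, ]
    len$length <- as.numeric(len$length)
    missing <- setdiff(tb$id, len$id)
    if (length(missing) > 0L) {
      stop("missing length for transcript(s): ",
           paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
    }
    tb <- dplyr::left_join(tb, len, by = "id")
    tb <- dplyr::relocate(tb, "length", .after = "id")
  }
  expr_mat(tb, class_label, groups, "counts")
}

#' Write an expression matrix to TSV
#'
#' @param x An `expr_mat`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(x, path) {
  readr::write_tsv(tibble::as_tibble(as.data.frame(x)), path, progress = FALSE)
  invisible(path)
}
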