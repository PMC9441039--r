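#' Pipeline configuration
#'
#' A run is driven either by a `simulate` block (arguments to
#' [sim_config()]) or by a `data` block of file paths — exactly one of the
#' two. The `data` block needs `mrna_counts`, `lncrna_counts`,
#' `mirna_counts`, `mrna_lengths`, `lncrna_lengths`, `mrna_fasta`,
#' `lncrna_fasta`, `mirna_fasta`, and `groups` (named sample-to-group
#' mapping). Remaining fields tune the stages: `fc_min`, `fdr_max`,
#' `p_max` (DE gates), `min_site_type` (seed-match gate), and `regimes`
#' (any of `"lenient"`, `"strict"`).
#'
#' @param simulate Optional list of [sim_config()] arguments.
#' @param data Optional list of input paths as described above.
#' @param fc_min,fdr_max,p_max Differential-expression gates (see
#'   [filter_de()]).
#' @param min_site_type Weakest seed-site class counted by
#'   [predict_targets()]. The pipeline default is `"8mer"`, the
#'   highest-confidence site class: without conservation or context
#'   filtering, 7mer matches in multi-kilobase transcripts are dense
#'   enough by chance to swamp the shared-miRNA overlap test.
#' @param de_method DE test variant (see [de_test()]); the moderated test
#'   is the default because the pipeline targets small-replicate designs.
#' @param regimes Character vector of [cerna_params()] regimes to run.
#' @param seed Integer seed forwarded to the simulation block.
#' @return A validated list of class `cerna_config`.
#' @export
cerna_config <- function(simulate = NULL, data = NULL, fc_min = 2,
                         fdr_max = 0.05, p_max = 0.05,
                         min_site_type = "8mer", de_method = "moderated",
                         regimes = c("lenient", "strict"), seed = 1) {
  de_method <- match.arg(de_method, c("moderated", "welch"))
  if (is.null(simulate) == is.null(data)) {
    stop("exactly one of 'simulate' or 'data' must be given", call. = FALSE)
  }
  regimes <- match.arg(regimes, c("lenient", "strict"), several.ok = TRUE)
  min_site_type <- match.arg(min_site_type, SITE_TYPES)
  if (fc_min < 1 || fdr_max <= 0 || fdr_max > 1 || p_max <= 0 || p_max > 1) {
    stop("DE thresholds out of range", call. = FALSE)
  }
  if (!is.null(simulate)) {
    simulate$seed <- simulate$seed %||% seed
    simulate <- do.call(sim_config, simulate)
  }
  structure(list(simulate = simulate, data = data, fc_min = fc_min,
                 fdr_max = fdr_max, p_max = p_max,
                 min_site_type = min_site_type, de_method = de_method,
                 regimes = regimes, seed = as.integer(seed)),
            class = "cerna_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys are [cerna_config()]
#'   arguments.
#' @return A `cerna_config`.
#' @export
read_cerna_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$data) && !is.null(y$data$groups)) {
    y$data$groups <- unlist(y$data$groups)
  }
  do.call(cerna_config, y)
}

load_pipeline_inputs <- function(config) {
  if (!is.null(config$simulate)) {
    ds <- simulate_cerna_dataset(config$simulate)
    list(counts = ds$counts,
         seqs = list(mrna = ds$mrna_seqs, lncrna = ds$lncrna_seqs,
                     mirna = ds$mirna_seqs),
         truth = ds$truth, truth_de = ds$truth_de)
  } else {
    d <- config$data
    groups <- d$groups
    list(counts = list(
      mrna = read_counts(d$mrna_counts, "mRNA", groups, d$mrna_lengths),
      lncrna = read_counts(d$lncrna_counts, "lncRNA", groups,
                           d$lncrna_lengths),
      mirna = read_counts(d$mirna_counts, "miRNA", groups)),
      seqs = list(mrna = read_fasta_seqs(d$mrna_fasta),
                  lncrna = read_fasta_seqs(d$lncrna_fasta),
                  mirna = read_fasta_seqs(d$mirna_fasta)),
      truth = NULL, truth_de = NULL)
  }
}

#' Run the full ceRNA inference pipeline
#'
#' Stages: load or simulate inputs; normalize (FPKM for mRNA/lncRNA,
#' tags-per-million for miRNA); per-class differential expression with the
#' class-appropriate gates; seed-match target prediction restricted to the
#' differential transcripts and miRNAs; pair scoring under each requested
#' regime; network assembly and export (SIF, GraphML, edge TSV). When an
#' output directory is given, the DE tables, interaction table, pair
#' tables, network files, a summary JSON, a log of every threshold used,
#' and a YAML echo of the effective configuration are written there.
#'
#' @param config A [cerna_config()] or a path to a YAML file for
#'   [read_cerna_config()].
#' @param out_dir Optional output directory.
#' @param quiet Suppress progress messages.
#' @return A list of class `cerna_run`: `de` (named list of DE tibbles),
#'   `interactions`, `pairs` (named by regime), `networks` (named by
#'   regime), `summary`, `recovery` (when ground truth is available),
#'   `config`.
#' @export
run_cerna_pipeline <- function(config, out_dir = NULL, quiet = TRUE) {
  if (is.character(config)) config <- read_cerna_config(config)
  stopifnot(inherits(config, "cerna_config"))
  say <- function(...) if (!quiet) message("[cernet] ", ...)
  log_lines <- character(0)
  logit <- function(...) {
    line <- paste0(...)
    log_lines <<- c(log_lines, line)
    say(line)
  }

  stage <- "input"
  res <- tryCatch({
    inputs <- load_pipeline_inputs(config)
    logit("inputs: ", nrow(inputs$counts$mrna), " mRNA, ",
          nrow(inputs$counts$lncrna), " lncRNA, ",
          nrow(inputs$counts$mirna), " miRNA")

    stage <- "normalize"
    norm <- list(mrna = fpkm_normalize(inputs$counts$mrna),
                 lncrna = fpkm_normalize(inputs$counts$lncrna),
                 mirna = tpm_normalize(inputs$counts$mirna))

    stage <- "de"
    de <- purrr::imap(norm, function(x, cl) {
      filter_de(de_test(x, method = config$de_method), expr_class(x),
                fc_min = config$fc_min, fdr_max = config$fdr_max,
                p_max = config$p_max)
    })
    de_ids <- purrr::map(de, ~ .x$id[.x$call != "not_de"])
    logit("DE gates: fold change >= ", config$fc_min,
          ", FDR < ", config$fdr_max, " (mRNA/lncRNA), p < ", config$p_max,
          " (miRNA); DE counts mRNA=", length(de_ids$mrna),
          " lncRNA=", length(de_ids$lncrna),
          " miRNA=", length(de_ids$mirna))

    stage <- "targets"
    mir_seqs <- inputs$seqs$mirna[inputs$seqs$mirna$id %in% de_ids$mirna, ]
    tx_seqs <- dplyr::bind_rows(
      inputs$seqs$lncrna[inputs$seqs$lncrna$id %in% de_ids$lncrna, ],
      inputs$seqs$mrna[inputs$seqs$mrna$id %in% de_ids$mrna, ])
    interactions <- if (nrow(mir_seqs) == 0L || nrow(tx_seqs) == 0L) {
      tibble::tibble(mirna_id = character(0), transcript_id = character(0),
                     n_sites = integer(0), best_site_type = character(0),
                     sites = character(0))
    } else {
      predict_targets(mir_seqs, tx_seqs, config$min_site_type)
    }
    logit("seed matching (>= ", config$min_site_type, "): ",
          nrow(interactions), " interactions among DE RNAs")

    stage <- "cerna"
    sub_expr <- function(x, keep) {
      y <- x[x$id %in% keep, , drop = FALSE]
      expr_mat(tibble::as_tibble(as.data.frame(y)), expr_class(x),
               expr_groups(x), expr_kind(x))
    }
    pairs <- list(); networks <- list()
    for (reg in config$regimes) {
      pars <- cerna_params(reg)
      pr <- if (nrow(interactions) == 0L ||
                length(de_ids$lncrna) == 0L || length(de_ids$mrna) == 0L) {
        suppressWarnings(score_cerna_pairs(
          interactions[0, ], sub_expr(norm$lncrna, norm$lncrna$id[1]),
          sub_expr(norm$mrna, norm$mrna$id[1]),
          sub_expr(norm$mirna, norm$mirna$id[1]), pars))
      } else {
        score_cerna_pairs(interactions,
                          sub_expr(norm$lncrna, de_ids$lncrna),
                          sub_expr(norm$mrna, de_ids$mrna),
                          sub_expr(norm$mirna, de_ids$mirna), pars)
      }
      de_calls <- dplyr::bind_rows(de)[, c("id", "call")]
      networks[[reg]] <- build_network(pr, de_calls, pars)
      pairs[[reg]] <- pr
      logit(reg, " regime (rho <= ", pars$spearman_max, ", r >= ",
            pars$pearson_min, ", p < ", pars$pair_p_max,
            if (!is.null(pars$pair_fdr_max))
              paste0(", FDR < ", pars$pair_fdr_max) else "", "): ",
            sum(pr$passed), " passing of ", nrow(pr), " scored pairs")
    }

    stage <- "summary"
    count_calls <- function(d) list(up = sum(d$call == "up"),
                                    down = sum(d$call == "down"))
    summary <- list(
      de = purrr::map(de, count_calls),
      n_interactions = nrow(interactions),
      pairs = purrr::map(pairs, ~ list(scored = nrow(.x),
                                       passing = sum(.x$passed))),
      networks = purrr::map(networks, ~ .x$summary))
    recovery <- NULL
    if (!is.null(inputs$truth) && nrow(inputs$truth) > 0L) {
      recovery <- purrr::map(pairs, ~ cerna_recovery(.x, inputs$truth))
      summary$recovery <- recovery
    }

    list(de = de, interactions = interactions, pairs = pairs,
         networks = networks, summary = summary, recovery = recovery,
         truth = inputs$truth, config = config, log = log_lines)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    fp <- function(...) file.path(out_dir, ...)
    for (cl in names(res$de)) {
      readr::write_tsv(res$de[[cl]], fp(paste0("de_", cl, ".tsv")),
                       progress = FALSE)
    }
    readr::write_tsv(res$interactions, fp("interactions.tsv"),
                     progress = FALSE)
    for (reg in names(res$pairs)) {
      readr::write_tsv(tibble::as_tibble(res$pairs[[reg]]),
                       fp(paste0("pairs_", reg, ".tsv")), progress = FALSE)
      net <- res$networks[[reg]]
      export_network(net, fp(paste0("network_", reg, ".sif")), "sif")
      export_network(net, fp(paste0("network_", reg, ".graphml")), "graphml")
      export_network(net, fp(paste0("network_", reg, ".tsv")), "tsv")
    }
    jsonlite::write_json(res$summary, fp("summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(res$log, fp("run.log"))
    cfg_echo <- unclass(res$config)
    cfg_echo$simulate <- if (!is.null(cfg_echo$simulate)) unclass(cfg_echo$simulate)
    yaml::write_yaml(cfg_echo, fp("effective_config.yaml"))
  }
  structure(res, class = "cerna_run")
}

#' @export
print.cerna_run <- function(x, ...) {
  cat("ceRNA pipeline run\n")
  for (line in x$log) cat("  ", line, "\n", sep = "")
  invisible(x)
}

#' Recovery of planted sponge structure by a scored pair table
#'
#' Recall is counted over planted triples: a triple is recovered when its
#' lncRNA-mRNA pair passes and its miRNA is among the pair's shared
#' miRNAs. Pair-level recall and precision treat the distinct planted
#' (lncRNA, mRNA) pairs as ground truth against the passing pairs.
#'
#' @param pairs A `cerna_pairs` tibble.
#' @param truth A planted-triple tibble (`lncrna_id`, `mirna_id`,
#'   `mrna_id`).
#' @return A list: `recall_triples`, `recall_pairs`, `precision_pairs`,
#'   `n_passing`, `n_truth_pairs`.
#' @export
cerna_recovery <- function(pairs, truth) {
  stopifnot(is.data.frame(pairs), is.data.frame(truth))
  pass <- pairs[isTRUE_v(pairs$passed), , drop = FALSE]
  key <- function(a, b) paste(a, b, sep = "\r")
  truth_pairs <- unique(key(truth$lncrna_id, truth$mrna_id))
  pass_keys <- key(pass$lncrna_id, pass$mrna_id)
  shared <- stats::setNames(stringr::str_split(pass$shared_mirnas,
                                               stringr::fixed(";")),
                            pass_keys)
  hit_triple <- vapply(seq_len(nrow(truth)), function(i) {
    k <- key(truth$lncrna_id[i], truth$mrna_id[i])
    k %in% pass_keys && truth$mirna_id[i] %in% shared[[k]]
  }, logical(1))
  list(
    recall_triples = if (nrow(truth) > 0L) mean(hit_triple) else NA_real_,
    recall_pairs = if (length(truth_pairs) > 0L) {
      mean(truth_pairs %in% pass_keys)
    } else NA_real_,
    precision_pairs = if (nrow(pass) > 0L) {
      mean(pass_keys %in% truth_pairs)
    } else NA_real_,
    n_passing = nrow(pass),
    n_truth_pairs = length(truth_pairs))
}
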