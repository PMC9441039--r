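#' Simulation configuration for synthetic ceRNA benchmark data
#'
#' Defines a fully self-contained two-group RNA-seq study with planted
#' sponge structure. Counts are negative-binomial around per-transcript
#' log-normal baselines; planted differentially expressed transcripts get a
#' symmetric between-group mean shift of `planted_fold_change`; each
#' planted sponge unit (one lncRNA, one mRNA, `mirnas_per_sponge` miRNAs)
#' shares a latent per-sample factor that enters the two ceRNAs with
#' positive sign and the miRNAs with negative sign, producing the
#' anti-correlated miRNA / positively correlated ceRNA-pair signature the
#' screens look for. The unit's lncRNA and mRNA are differentially
#' expressed in the same direction and its miRNAs in the opposite
#' direction, the canonical sponge pattern. Each planted triple's miRNA
#' gets one exact 8mer seed site planted in both partner transcripts.
#'
#' `n_planted_triples` counts (lncRNA, miRNA, mRNA) triples; consecutive
#' `mirnas_per_sponge` triples share one lncRNA-mRNA pair, mirroring real
#' ceRNA pairs, which share several miRNAs — a single shared miRNA carries
#' no detectable hypergeometric signal.
#'
#' @param n_mrna,n_lncrna,n_mirna Universe sizes.
#' @param n_planted_triples Number of planted (lncRNA, miRNA, mRNA) triples.
#' @param n_samples_per_group Replicates per group (3, as in a typical
#'   3-vs-3 design).
#' @param nb_dispersion Negative-binomial dispersion phi (variance =
#'   mu + phi mu^2); must be positive.
#' @param planted_fold_change Between-group fold change for planted DE
#'   transcripts; must be >= 2.
#' @param planted_corr_strength Scale of the shared latent factor, in
#'   (0, 1].
#' @param seed Integer seed; identical seeds give bit-identical datasets.
#' @param mean_expression_log_mu,mean_expression_log_sigma Log-normal
#'   baseline mean parameters (natural-log scale).
#' @param mirnas_per_sponge miRNAs planted per sponge unit.
#' @param decoy_de_fraction Fraction of non-planted transcripts per class
#'   given a (direction-random) differential shift, so the DE gates see
#'   background positives that are not sponge-coordinated.
#' @param group_labels Length-2 character, default `c("CC", "GC")`.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_mrna = 2000, n_lncrna = 500, n_mirna = 300,
                       n_planted_triples = 50, n_samples_per_group = 3,
                       nb_dispersion = 0.005, planted_fold_change = 4,
                       planted_corr_strength = 0.9, seed = 1,
                       mean_expression_log_mu = log(200),
                       mean_expression_log_sigma = 1,
                       mirnas_per_sponge = 5,
                       decoy_de_fraction = 0.01,
                       group_labels = c("CC", "GC")) {
  cfg <- list(n_mrna = as.integer(n_mrna), n_lncrna = as.integer(n_lncrna),
              n_mirna = as.integer(n_mirna),
              n_planted_triples = as.integer(n_planted_triples),
              n_samples_per_group = as.integer(n_samples_per_group),
              nb_dispersion = nb_dispersion,
              planted_fold_change = planted_fold_change,
              planted_corr_strength = planted_corr_strength,
              seed = as.integer(seed),
              mean_expression_log_mu = mean_expression_log_mu,
              mean_expression_log_sigma = mean_expression_log_sigma,
              mirnas_per_sponge = as.integer(mirnas_per_sponge),
              decoy_de_fraction = decoy_de_fraction,
              group_labels = as.character(group_labels))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_mrna < 1 || n_lncrna < 1 || n_mirna < 1) {
      stop("universe sizes must be positive", call. = FALSE)
    }
    if (n_planted_triples < 0 ||
        n_planted_triples > min(n_mrna, n_lncrna, n_mirna)) {
      stop("n_planted_triples must lie in [0, min(n_mrna, n_lncrna, n_mirna)]",
           call. = FALSE)
    }
    if (n_samples_per_group < 2) {
      stop("need at least 2 samples per group", call. = FALSE)
    }
    if (!is.numeric(nb_dispersion) || nb_dispersion <= 0) {
      stop("nb_dispersion must be positive", call. = FALSE)
    }
    if (planted_fold_change < 2) {
      stop("planted_fold_change must be >= 2", call. = FALSE)
    }
    if (planted_corr_strength <= 0 || planted_corr_strength > 1) {
      stop("planted_corr_strength must be in (0, 1]", call. = FALSE)
    }
    if (mirnas_per_sponge < 1) {
      stop("mirnas_per_sponge must be >= 1", call. = FALSE)
    }
    if (decoy_de_fraction < 0 || decoy_de_fraction > 1) {
      stop("decoy_de_fraction must be in [0, 1]", call. = FALSE)
    }
    if (length(group_labels) != 2L || anyDuplicated(group_labels)) {
      stop("group_labels must be two distinct labels", call. = FALSE)
    }
  })
  invisible(cfg)
}

sim_ids <- function(cfg) {
  list(mrna = sprintf("mRNA_%04d", seq_len(cfg$n_mrna)),
       lncrna = sprintf("lncRNA_%04d", seq_len(cfg$n_lncrna)),
       mirna = sprintf("miRNA_%04d", seq_len(cfg$n_mirna)))
}

# planted triples: unit u owns lncRNA_u / mRNA_u and mirnas_per_sponge miRNAs
sim_truth_triples <- function(cfg) {
  if (cfg$n_planted_triples == 0L) {
    return(tibble::tibble(lncrna_id = character(0), mirna_id = character(0),
                          mrna_id = character(0), unit = integer(0)))
  }
  ids <- sim_ids(cfg)
  unit <- ((seq_len(cfg$n_planted_triples) - 1L) %/% cfg$mirnas_per_sponge) + 1L
  tibble::tibble(
    lncrna_id = ids$lncrna[unit],
    mirna_id = ids$mirna[seq_len(cfg$n_planted_triples)],
    mrna_id = ids$mrna[unit],
    unit = unit)
}

random_seq <- function(n, alphabet) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

#' Generate miRNA and transcript sequences with planted seed sites
#'
#' miRNAs are 21-23 nt RNA; transcripts are 500-2000 nt DNA. For every
#' planted triple, the 8mer site pattern of its miRNA (reverse complement
#' of seed nucleotides 2-8 plus a 3'-adjacent A) is written into both
#' partner transcripts at a recorded, non-overlapping position. Decoy
#' transcripts receive no planted sites; incidental matches can and do
#' occur, and the truth table — not sequence content — defines ground
#' truth.
#'
#' @param config A [sim_config()].
#' @return A list: `mirna_seqs`, `lncrna_seqs`, `mrna_seqs` (tibbles with
#'   `id`, `sequence`), `truth` (planted-triple tibble), `planted_sites`
#'   (tibble: `transcript_id`, `mirna_id`, `start`, `end`).
#' @export
simulate_sequences <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ids <- sim_ids(config)
  mirna_seqs <- vapply(seq_len(config$n_mirna), function(i) {
    random_seq(sample(21:23, 1L), c("A", "C", "G", "U"))
  }, character(1))
  names(mirna_seqs) <- ids$mirna
  gen_tx <- function(id_vec) {
    v <- vapply(seq_along(id_vec), function(i) {
      random_seq(sample(500:2000, 1L), c("A", "C", "G", "T"))
    }, character(1))
    stats::setNames(v, id_vec)
  }
  lnc_seqs <- gen_tx(ids$lncrna)
  mrna_seqs <- gen_tx(ids$mrna)
  truth <- sim_truth_triples(config)

  sites <- list(); si <- 0L
  occupied <- new.env(parent = emptyenv())  # transcript id -> matrix-free list of intervals
  plant <- function(seqs, tx_id, pattern) {
    L <- nchar(seqs[[tx_id]])
    w <- nchar(pattern)
    prev <- occupied[[tx_id]] %||% cbind(start = integer(0), end = integer(0))
    for (attempt in seq_len(1000L)) {
      st <- sample.int(L - w + 1L, 1L)
      en <- st + w - 1L
      if (!any(st <= prev[, "end"] & en >= prev[, "start"])) {
        substr(seqs[[tx_id]], st, en) <- pattern
        occupied[[tx_id]] <- rbind(prev, cbind(start = st, end = en))
        return(list(seqs = seqs, start = st, end = en))
      }
    }
    stop("could not place planted site in ", tx_id, call. = FALSE)
  }
  if (nrow(truth) > 0L) {
    for (t in seq_len(nrow(truth))) {
      pat <- seed_patterns(mirna_seqs[[truth$mirna_id[t]]])[["8mer"]]
      r <- plant(lnc_seqs, truth$lncrna_id[t], pat)
      lnc_seqs <- r$seqs
      si <- si + 1L
      sites[[si]] <- tibble::tibble(transcript_id = truth$lncrna_id[t],
                                    mirna_id = truth$mirna_id[t],
                                    start = r$start, end = r$end)
      r <- plant(mrna_seqs, truth$mrna_id[t], pat)
      mrna_seqs <- r$seqs
      si <- si + 1L
      sites[[si]] <- tibble::tibble(transcript_id = truth$mrna_id[t],
                                    mirna_id = truth$mirna_id[t],
                                    start = r$start, end = r$end)
    }
  }
  planted_sites <- if (si == 0L) {
    tibble::tibble(transcript_id = character(0), mirna_id = character(0),
                   start = integer(0), end = integer(0))
  } else dplyr::bind_rows(sites)
  list(
    mirna_seqs = tibble::tibble(id = names(mirna_seqs),
                                sequence = unname(mirna_seqs)),
    lncrna_seqs = tibble::tibble(id = names(lnc_seqs),
                                 sequence = unname(lnc_seqs)),
    mrna_seqs = tibble::tibble(id = names(mrna_seqs),
                               sequence = unname(mrna_seqs)),
    truth = truth,
    planted_sites = planted_sites)
}

#' Generate negative-binomial count matrices with planted structure
#'
#' See [sim_config()] for the generative model. The count stream is seeded
#' with `config$seed + 1`, independently of the sequence stream, so counts
#' are reproducible whether or not sequences were generated first.
#'
#' @param config A [sim_config()].
#' @param truth Planted-triple tibble from [simulate_sequences()] /
#'   [sim_truth_triples()].
#' @param lengths Optional named list with elements `lncrna`, `mrna` giving
#'   per-transcript bp lengths; when omitted (counts-only use) lengths are
#'   drawn uniformly from 500-2000 bp.
#' @return A list: `counts` (list of three [expr_mat()]: `mrna`, `lncrna`,
#'   `mirna`) and `truth_de` (tibble: `id`, `class`, `direction` in
#'   `c("up", "down")`, orientation B-vs-A).
#' @export
simulate_counts <- function(config, truth, lengths = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed((config$seed + 1L) %% .Machine$integer.max)
  ids <- sim_ids(config)
  ns <- config$n_samples_per_group
  samples <- c(paste0(config$group_labels[1], "_", seq_len(ns)),
               paste0(config$group_labels[2], "_", seq_len(ns)))
  groups <- stats::setNames(rep(config$group_labels, each = ns), samples)
  group_b <- groups == config$group_labels[2]

  if (is.null(lengths)) {
    lengths <- list(
      lncrna = sample(500:2000, config$n_lncrna, replace = TRUE),
      mrna = sample(500:2000, config$n_mrna, replace = TRUE))
  }

  n_units <- if (nrow(truth) > 0L) max(truth$unit) else 0L
  unit_dir <- if (n_units > 0L) sample(c(1, -1), n_units, replace = TRUE) else numeric(0)
  # latent per-sample factor, one per sponge unit
  z <- if (n_units > 0L) {
    matrix(stats::rnorm(n_units * length(samples)), nrow = n_units)
  } else matrix(0, 0, length(samples))

  # planted membership by class
  planted <- list(
    mrna = stats::setNames(rep(NA_integer_, config$n_mrna), ids$mrna),
    lncrna = stats::setNames(rep(NA_integer_, config$n_lncrna), ids$lncrna),
    mirna = stats::setNames(rep(NA_integer_, config$n_mirna), ids$mirna))
  if (nrow(truth) > 0L) {
    planted$lncrna[truth$lncrna_id] <- truth$unit
    planted$mrna[truth$mrna_id] <- truth$unit
    planted$mirna[truth$mirna_id] <- truth$unit
  }

  half_lfc <- log(config$planted_fold_change) / 2
  # log-sd of the shared factor; 0.15 keeps the within-group coupling strong
  # enough for the rank screens without drowning the group effect in
  # within-group variance (a 3-vs-3 Welch test has little to spare)
  latent_scale <- 0.08 * config$planted_corr_strength

  truth_de <- list(); ti <- 0L
  gen_class <- function(class_key, n, mirna_sign) {
    id_vec <- ids[[class_key]]
    base <- stats::rlnorm(n, config$mean_expression_log_mu,
                          config$mean_expression_log_sigma)
    unit_of <- planted[[class_key]]
    is_planted <- !is.na(unit_of)
    dir_vec <- rep(0, n)
    dir_vec[is_planted] <- mirna_sign * unit_dir[unit_of[is_planted]]
    # decoy DE: direction-random background shifts among non-planted ids
    n_decoy <- round(config$decoy_de_fraction * sum(!is_planted))
    if (n_decoy > 0L) {
      decoy_idx <- sample(which(!is_planted), n_decoy)
      dir_vec[decoy_idx] <- sample(c(1, -1), n_decoy, replace = TRUE)
    }
    log_mu <- outer(log(base), rep(0, length(samples)), "+")
    log_mu <- log_mu + outer(dir_vec * half_lfc, ifelse(group_b, 1, -1))
    if (n_units > 0L && any(is_planted)) {
      log_mu[is_planted, ] <- log_mu[is_planted, ] +
        mirna_sign * latent_scale * z[unit_of[is_planted], , drop = FALSE]
    }
    mu <- exp(log_mu)
    if (class_key != "mirna") {
      mu <- mu * lengths[[class_key]] / 1000
    }
    cnt <- matrix(stats::rnbinom(length(mu), mu = mu,
                                 size = 1 / config$nb_dispersion),
                  nrow = n, dimnames = list(id_vec, samples))
    de_ids <- dir_vec != 0
    if (any(de_ids)) {
      ti <<- ti + 1L
      truth_de[[ti]] <<- tibble::tibble(
        id = id_vec[de_ids],
        class = c(mrna = "mRNA", lncrna = "lncRNA", mirna = "miRNA")[[class_key]],
        direction = ifelse(dir_vec[de_ids] > 0, "up", "down"))
    }
    cnt
  }

  m_mrna <- gen_class("mrna", config$n_mrna, mirna_sign = 1)
  m_lnc <- gen_class("lncrna", config$n_lncrna, mirna_sign = 1)
  m_mi <- gen_class("mirna", config$n_mirna, mirna_sign = -1)

  to_expr <- function(m, class_label, len = NULL) {
    tb <- tibble::tibble(id = rownames(m))
    if (!is.null(len)) tb$length <- len
    tb <- dplyr::bind_cols(tb, tibble::as_tibble(m))
    expr_mat(tb, class_label, groups, "counts")
  }
  list(
    counts = list(
      mrna = to_expr(m_mrna, "mRNA", lengths$mrna),
      lncrna = to_expr(m_lnc, "lncRNA", lengths$lncrna),
      mirna = to_expr(m_mi, "miRNA")),
    truth_de = if (ti == 0L) {
      tibble::tibble(id = character(0), class = character(0),
                     direction = character(0))
    } else dplyr::bind_rows(truth_de))
}

#' Generate a complete synthetic ceRNA dataset
#'
#' Composes [simulate_sequences()] and [simulate_counts()]; transcript
#' lengths used by the count model are the actual generated sequence
#' lengths, so FPKM normalization is consistent with the FASTA output.
#'
#' @param config A [sim_config()].
#' @return A list of class `cerna_sim`: `config`, `counts` (three
#'   [expr_mat()]), `mirna_seqs`, `lncrna_seqs`, `mrna_seqs`, `truth`,
#'   `truth_de`, `planted_sites`.
#' @export
simulate_cerna_dataset <- function(config = sim_config()) {
  seqs <- simulate_sequences(config)
  lengths <- list(lncrna = nchar(seqs$lncrna_seqs$sequence),
                  mrna = nchar(seqs$mrna_seqs$sequence))
  cn <- simulate_counts(config, seqs$truth, lengths)
  structure(c(list(config = config), seqs, cn), class = "cerna_sim")
}

#' @export
print.cerna_sim <- function(x, ...) {
  cat("synthetic ceRNA dataset: ", x$config$n_mrna, " mRNA, ",
      x$config$n_lncrna, " lncRNA, ", x$config$n_mirna, " miRNA; ",
      nrow(x$truth), " planted triples; ",
      2L * x$config$n_samples_per_group, " samples\n", sep = "")
  invisible(x)
}

#' Write a synthetic dataset to a directory
#'
#' Writes the three count TSVs (first column `id`, header = sample ids),
#' two length TSVs, three FASTA files, the machine-readable truth tables
#' (planted triples, planted DE, planted sites), and a YAML echo of the
#' configuration.
#'
#' @param ds A `cerna_sim` from [simulate_cerna_dataset()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_sim_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "cerna_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(dir, ...)
  for (cl in c("mrna", "lncrna", "mirna")) {
    x <- ds$counts[[cl]]
    tb <- tibble::as_tibble(as.data.frame(x))
    readr::write_tsv(tb[, c("id", expr_samples(x))], fp(paste0(cl, "_counts.tsv")),
                     progress = FALSE)
    if (cl != "mirna") {
      readr::write_tsv(tb[, c("id", "length")], fp(paste0(cl, "_lengths.tsv")),
                       col_names = FALSE, progress = FALSE)
    }
  }
  write_fasta_seqs(ds$mirna_seqs, fp("mirna.fa"))
  write_fasta_seqs(ds$lncrna_seqs, fp("lncrna.fa"))
  write_fasta_seqs(ds$mrna_seqs, fp("mrna.fa"))
  readr::write_tsv(ds$truth, fp("truth_triples.tsv"), progress = FALSE)
  readr::write_tsv(ds$truth_de, fp("truth_de.tsv"), progress = FALSE)
  readr::write_tsv(ds$planted_sites, fp("truth_sites.tsv"), progress = FALSE)
  yaml::write_yaml(unclass(ds$config), fp("sim_config.yaml"))
  invisible(dir)
}

#' Read back a truth table written by [write_sim_dataset()]
#'
#' @param path Path to `truth_triples.tsv`.
#' @return A tibble with `lncrna_id`, `mirna_id`, `mrna_id`, `unit`.
#' @export
read_truth <- function(path) {
  readr::read_tsv(path, col_types = "ccci", progress = FALSE)
}
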