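SITE_TYPES <- c("8mer", "7mer-m8", "7mer-A1", "6mer")

revcomp_dna <- function(x) {
  chartr("ACGTU", "TGCAA", vapply(strsplit(x, "", fixed = TRUE),
                                  function(ch) paste(rev(ch), collapse = ""),
                                  character(1)))
}

# normalize an RNA/DNA string to upper-case DNA
as_dna <- function(x) chartr("u", "T", chartr("U", "T", toupper(x)))

#' Canonical seed-site patterns for a miRNA
#'
#' The seed is miRNA nucleotides 2-8. Site patterns are what the target
#' transcript must contain on its sense strand, written 5'->3' in DNA
#' alphabet: the reverse complement of the relevant seed span, optionally
#' followed by an A opposite miRNA position 1.
#'
#' * `6mer`    — revcomp(nt 2-7)
#' * `7mer-m8` — revcomp(nt 2-8)
#' * `7mer-A1` — revcomp(nt 2-7) + `"A"`
#' * `8mer`    — revcomp(nt 2-8) + `"A"`
#'
#' G:U wobble is not allowed: matching is exact.
#'
#' @param mirna_seq miRNA sequence, 5'->3', RNA or DNA alphabet, length >= 8.
#' @return Named character vector of the four patterns.
#' @export
#' @examples
#' seed_patterns("UAAGGCACGCGGUGAAUGCC")["8mer"]  # "GTGCCTTA"
seed_patterns <- function(mirna_seq) {
  stopifnot(is.character(mirna_seq), length(mirna_seq) == 1L)
  s <- as_dna(mirna_seq)
  if (nchar(s) < 8L) {
    stop("miRNA sequence must be at least 8 nt", call. = FALSE)
  }
  if (grepl("[^ACGT]", s)) {
    stop("invalid character in miRNA sequence", call. = FALSE)
  }
  seed27 <- substr(s, 2L, 7L)
  seed28 <- substr(s, 2L, 8L)
  c(`6mer` = revcomp_dna(seed27),
    `7mer-m8` = revcomp_dna(seed28),
    `7mer-A1` = paste0(revcomp_dna(seed27), "A"),
    `8mer` = paste0(revcomp_dna(seed28), "A"))
}

fixed_matches <- function(pattern, subject) {
  hits <- gregexpr(pattern, subject, fixed = TRUE)[[1]]
  if (hits[1] == -1L) integer(0) else as.integer(hits)
}

#' Find canonical seed-match sites on a transcript
#'
#' All occurrences of the four site patterns are located by exact substring
#' search; a lower-priority occurrence whose interval lies inside a
#' higher-priority site is suppressed, so a planted 8mer is reported once
#' as an 8mer rather than additionally as its embedded 7mers/6mer.
#' Priority: 8mer > 7mer-m8 > 7mer-A1 > 6mer. Positions are 1-based
#' inclusive on the sense strand of the supplied transcript.
#'
#' @param mirna_seq miRNA sequence (RNA or DNA alphabet).
#' @param transcript_seq Transcript sequence (RNA or DNA; normalized to DNA).
#' @return A tibble: `site_type`, `start`, `end`, ordered by `start`.
#' @export
find_seed_sites <- function(mirna_seq, transcript_seq) {
  pats <- seed_patterns(mirna_seq)
  tx <- as_dna(transcript_seq)
  if (nchar(tx) > 0L && grepl("[^ACGT]", tx)) {
    stop("invalid character in transcript sequence", call. = FALSE)
  }
  find_sites_impl(pats, tx)
}

# core scan over pre-built patterns; tx already normalized to DNA
find_sites_impl <- function(pats, tx) {
  if (nchar(tx) == 0L) {
    return(tibble::tibble(site_type = character(0), start = integer(0),
                          end = integer(0)))
  }
  kept_start <- integer(0); kept_end <- integer(0); kept_type <- character(0)
  for (ty in SITE_TYPES) {
    w <- nchar(pats[[ty]])
    starts <- fixed_matches(pats[[ty]], tx)
    for (st in starts) {
      en <- st + w - 1L
      contained <- any(kept_start <= st & en <= kept_end)
      if (!contained) {
        kept_start <- c(kept_start, st)
        kept_end <- c(kept_end, en)
        kept_type <- c(kept_type, ty)
      }
    }
  }
  out <- tibble::tibble(site_type = kept_type, start = kept_start,
                        end = kept_end)
  dplyr::arrange(out, .data$start, .data$end)
}

#' Predict miRNA-transcript interactions by seed matching
#'
#' One interaction per (miRNA, transcript) pair having at least one site of
#' type `min_site_type` or stronger. The default excludes bare 6mers, the
#' weakest canonical site class.
#'
#' @param mirnas,transcripts Either named character vectors of sequences or
#'   tibbles with columns `id` and `sequence`.
#' @param min_site_type Weakest site class that counts as evidence; one of
#'   `"8mer"`, `"7mer-m8"`, `"7mer-A1"`, `"6mer"`.
#' @return A tibble ordered by (`mirna_id`, `transcript_id`): `mirna_id`,
#'   `transcript_id`, `n_sites`, `best_site_type`, `sites`
#'   (semicolon-joined `start:end:type`). `n_sites` counts sites at or
#'   above `min_site_type`.
#' @export
predict_targets <- function(mirnas, transcripts, min_site_type = "7mer-A1") {
  min_site_type <- match.arg(min_site_type, SITE_TYPES)
  mirnas <- as_seq_vector(mirnas, "mirnas")
  transcripts <- as_seq_vector(transcripts, "transcripts")
  allowed <- SITE_TYPES[seq_len(match(min_site_type, SITE_TYPES))]
  tx_dna <- vapply(transcripts, as_dna, character(1))
  res <- vector("list", length(mirnas) * length(transcripts))
  idx <- 0L
  for (mi in names(mirnas)) {
    pats <- seed_patterns(mirnas[[mi]])  # validates once per miRNA
    for (tx in names(transcripts)) {
      sites <- find_sites_impl(pats, tx_dna[[tx]])
      sites <- sites[sites$site_type %in% allowed, , drop = FALSE]
      if (nrow(sites) > 0L) {
        idx <- idx + 1L
        best <- SITE_TYPES[min(match(sites$site_type, SITE_TYPES))]
        res[[idx]] <- tibble::tibble(
          mirna_id = mi, transcript_id = tx, n_sites = nrow(sites),
          best_site_type = best,
          sites = paste(sprintf("%d:%d:%s", sites$start, sites$end,
                                sites$site_type), collapse = ";"))
      }
    }
  }
  out <- if (idx == 0L) {
    tibble::tibble(mirna_id = character(0), transcript_id = character(0),
                   n_sites = integer(0), best_site_type = character(0),
                   sites = character(0))
  } else {
    dplyr::bind_rows(res[seq_len(idx)])
  }
  dplyr::arrange(out, .data$mirna_id, .data$transcript_id)
}

as_seq_vector <- function(x, what) {
  if (is.data.frame(x)) {
    stopifnot(all(c("id", "sequence") %in% names(x)))
    v <- stats::setNames(as.character(x$sequence), as.character(x$id))
  } else {
    v <- x
  }
  if (length(v) == 0L) stop("'", what, "' is empty", call. = FALSE)
  if (is.null(names(v)) || any(names(v) == "")) {
    stop("'", what, "' must be named by id", call. = FALSE)
  }
  if (anyDuplicated(names(v))) {
    stop("duplicate ids in '", what, "'", call. = FALSE)
  }
  v
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA path.
#' @return A tibble with columns `id`, `sequence`.
#' @export
read_fasta_seqs <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  tibble::tibble(id = sub("\\s.*$", "", names(ss)),
                 sequence = unname(as.character(ss)))
}

#' Write sequences to a FASTA file
#'
#' @param seqs Tibble with `id`, `sequence`, or a named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta_seqs <- function(seqs, path) {
  v <- as_seq_vector(seqs, "seqs")
  ss <- Biostrings::BStringSet(v)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}
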