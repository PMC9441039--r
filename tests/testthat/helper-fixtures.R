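# shared fixtures and independent oracles, built in code at test time

toy_groups <- function(n_per_group = 3, labels = c("CC", "GC")) {
  samples <- c(paste0(labels[1], "_", seq_len(n_per_group)),
               paste0(labels[2], "_", seq_len(n_per_group)))
  stats::setNames(rep(labels, each = n_per_group), samples)
}

toy_expr <- function(values, class_label = "mRNA", lengths = NULL,
                     groups = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) {
    rownames(values) <- paste0("t", seq_len(nrow(values)))
  }
  if (is.null(groups)) groups <- toy_groups(ncol(values) / 2)
  colnames(values) <- names(groups)
  tb <- tibble::tibble(id = rownames(values))
  if (class_label != "miRNA") {
    tb$length <- lengths %||% rep(1000, nrow(values))
  }
  tb <- dplyr::bind_cols(tb, tibble::as_tibble(values))
  expr_mat(tb, class_label, groups)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# exhaustive-enumeration oracle for the upper-tail hypergeometric overlap:
# draw every size-n subset of 1..N and count those sharing >= k elements
# with the reference set {1..K}
hyper_enum_p <- function(k, K, n, N) {
  if (k == 0) return(1)
  if (n == 0 || K == 0) return(if (k == 0) 1 else 0)
  cm <- utils::combn(N, n)
  mean(colSums(cm <= K) >= k)
}

# brute-force BH step-up from the definition: sort ascending, adj(i) =
# min_{j >= i} m p(j) / j, capped at 1, mapped back to input order
bh_bruteforce <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(m * ps[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[ord] <- adj
  out
}

# naive seed-site oracle: check every substring position for each of the
# four patterns, then apply the containment-priority rule independently
seed_sites_naive <- function(mirna_seq, transcript_seq) {
  pats <- seed_patterns(mirna_seq)
  tx <- chartr("Uu", "Tt", toupper(transcript_seq))
  found <- list()
  for (ty in c("8mer", "7mer-m8", "7mer-A1", "6mer")) {
    pat <- pats[[ty]]
    w <- nchar(pat)
    if (nchar(tx) >= w) {
      for (st in seq_len(nchar(tx) - w + 1)) {
        if (substr(tx, st, st + w - 1) == pat) {
          found[[length(found) + 1]] <- list(type = ty, start = st,
                                             end = st + w - 1)
        }
      }
    }
  }
  kept <- list()
  for (f in found) {  # found is already in priority order
    inside <- any(vapply(kept, function(g) {
      g$start <= f$start && f$end <= g$end
    }, logical(1)))
    if (!inside) kept[[length(kept) + 1]] <- f
  }
  if (length(kept) == 0) {
    return(tibble::tibble(site_type = character(0), start = integer(0),
                          end = integer(0)))
  }
  out <- tibble::tibble(site_type = vapply(kept, `[[`, "", "type"),
                        start = vapply(kept, function(x) as.integer(x$start), 1L),
                        end = vapply(kept, function(x) as.integer(x$end), 1L))
  out[order(out$start, out$end), ]
}

random_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n, TRUE),
                                collapse = "")
random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

# small-but-complete simulation config for fast integration tests
small_sim <- function(seed = 11, ...) {
  args <- list(n_mrna = 200, n_lncrna = 60, n_mirna = 40,
               n_planted_triples = 10, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}

# a one-pair network fixture: one passing competing pair sharing two miRNAs
toy_pairs <- function() {
  structure(tibble::tibble(
    lncrna_id = "lnc1", mrna_id = "m1", k = 2L, K = 2L, n = 2L, N = 2L,
    hypergeom_p = 0.01, hypergeom_fdr = 0.01, pearson_r = 0.95,
    n_screening_mirnas = 2L, shared_mirnas = "mi1;mi2", passed = TRUE,
    regime = "lenient"), class = c("cerna_pairs", class(tibble::tibble())))
}
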