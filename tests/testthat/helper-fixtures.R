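# Shared fixtures and independent oracles used across the suite.

# deterministic random sequence
random_seq <- function(n, seed = NULL, alphabet = c("A", "C", "G", "T"),
                       prob = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(alphabet, n, replace = TRUE, prob = prob), collapse = "")
}

# tiny genome with evenly spaced origins, suitable for window grids
make_toy_geometry <- function(seed = 1, chrom_length = 200000L,
                              n_origins = 6L, n_chrom = 1L) {
  set.seed(seed)
  seqs <- setNames(
    vapply(seq_len(n_chrom), function(i) random_seq(chrom_length), ""),
    paste0("chr", seq_len(n_chrom)))
  gen <- genome(seqs)
  mids <- round(seq(15000, chrom_length - 15000, length.out = n_origins))
  origins <- origin_set(chrom = rep(names(seqs)[1], n_origins),
                        start = mids - 150L, end = mids + 150L)
  list(genome = gen, origins = origins)
}

# per-position brute-force G4Hunter scorer (independent of the rle path)
g4_brute_positional <- function(seq) {
  ch <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  n <- length(ch)
  out <- numeric(n)
  for (i in seq_len(n)) {
    b <- ch[i]
    if (b == "G" || b == "C") {
      l <- i; while (l > 1 && ch[l - 1] == b) l <- l - 1
      r <- i; while (r < n && ch[r + 1] == b) r <- r + 1
      out[i] <- if (b == "G") min(r - l + 1, 4) else -min(r - l + 1, 4)
    }
  }
  out
}

# brute-force pairwise isolation oracle
isolation_oracle <- function(origins, radius) {
  n <- nrow(origins)
  vapply(seq_len(n), function(i) {
    same <- origins$chrom == origins$chrom[i]
    d <- abs(origins$midpoint[same] - origins$midpoint[i])
    sum(d <= radius) == 1L   # only itself within the radius
  }, logical(1))
}

# brute-force transitive-closure clustering oracle (single linkage)
cluster_oracle <- function(origins, link, min_span, min_origins) {
  out <- list()
  for (ch in unique(origins$chrom)) {
    m <- sort(origins$midpoint[origins$chrom == ch])
    n <- length(m)
    grp <- seq_len(n)
    repeat {
      changed <- FALSE
      for (i in seq_len(n)) for (j in seq_len(n)) {
        if (abs(m[i] - m[j]) <= link && grp[i] != grp[j]) {
          grp[grp == grp[j]] <- grp[i]; changed <- TRUE
        }
      }
      if (!changed) break
    }
    for (g in unique(grp)) {
      mm <- m[grp == g]
      if (length(mm) >= min_origins && (max(mm) - min(mm)) > min_span)
        out[[length(out) + 1L]] <- data.frame(chrom = ch, start = min(mm),
                                              end = max(mm))
    }
  }
  if (length(out)) {
    res <- do.call(rbind, out)
    res[order(res$chrom, res$start), , drop = FALSE]
  } else data.frame(chrom = character(), start = integer(), end = integer())
}

toy_catalog <- function() {
  read_catalog(system.file("extdata", "toy_catalog_synthetic.tsv",
                           package = "orimut"))
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)
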