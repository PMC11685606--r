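# Strand-resolved coverage-track profiling at origins (XR-seq style),
# reactive-dinucleotide composition correction, strand bias, and
# track-track correlation at origin domains.

#' Construct a strand-resolved binned coverage track
#'
#' @param plus,minus Named lists of numeric vectors (one per
#'   chromosome), binned at `resolution` bp; values must be >= 0.
#' @param resolution Bin width (bp), default 50.
#' @return Object of class `strand_track`.
#' @export
strand_track <- function(plus, minus, resolution = 50L) {
  stopifnot(identical(names(plus), names(minus)))
  for (ch in names(plus)) {
    stopifnot(length(plus[[ch]]) == length(minus[[ch]]),
              all(plus[[ch]] >= 0, na.rm = TRUE),
              all(minus[[ch]] >= 0, na.rm = TRUE))
  }
  structure(list(plus = plus, minus = minus, resolution = as.integer(resolution)),
            class = "strand_track")
}

#' Read / write strand tracks as bedGraph
#'
#' `read_strand_track()` reads a `.plus`/`.minus` bedGraph pair into
#' fixed-resolution bins (interval signal is apportioned to bins by
#' overlap fraction, i.e. values are treated as mean signal over the
#' interval). `write_strand_track()` writes one line per non-zero bin.
#'
#' @param plus_file,minus_file bedGraph paths.
#' @param chrom_lengths Named chromosome lengths.
#' @param resolution Bin width (bp).
#' @return A `strand_track`.
#' @export
read_strand_track <- function(plus_file, minus_file, chrom_lengths,
                              resolution = 50L) {
  read_one <- function(file) {
    arrs <- lapply(chrom_lengths, function(L) numeric(ceiling(L / resolution)))
    df <- utils::read.delim(file, header = FALSE, stringsAsFactors = FALSE,
                            col.names = c("chrom", "start", "end", "value"))
    for (i in seq_len(nrow(df))) {
      ch <- df$chrom[i]
      if (!ch %in% names(arrs)) next
      b0 <- df$start[i] %/% resolution
      b1 <- (df$end[i] - 1L) %/% resolution
      for (b in b0:b1) {
        lo <- max(df$start[i], b * resolution)
        hi <- min(df$end[i], (b + 1L) * resolution)
        arrs[[ch]][b + 1L] <- arrs[[ch]][b + 1L] + df$value[i] * (hi - lo) / resolution
      }
    }
    arrs
  }
  strand_track(read_one(plus_file), read_one(minus_file), resolution)
}

#' @rdname read_strand_track
#' @param track A `strand_track`.
#' @export
write_strand_track <- function(track, plus_file, minus_file) {
  write_one <- function(arrs, file) {
    rows <- list()
    for (ch in names(arrs)) {
      v <- arrs[[ch]]
      nz <- which(!is.na(v) & v != 0)
      if (length(nz))
        rows[[ch]] <- data.frame(chrom = ch,
                                 start = (nz - 1L) * track$resolution,
                                 end = nz * track$resolution,
                                 value = v[nz], stringsAsFactors = FALSE)
    }
    df <- if (length(rows)) do.call(rbind, rows) else
      data.frame(chrom = character(), start = integer(), end = integer(),
                 value = numeric())
    utils::write.table(df, file, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  write_one(track$plus, plus_file)
  write_one(track$minus, minus_file)
  invisible(c(plus_file, minus_file))
}

#' Reactive-dinucleotide sets for UV photoproducts
#'
#' CPD lesions form at TT dinucleotides (per the antibody used for that
#' readout); 6-4PP adducts form at CC, CT and TC.
#'
#' @param lesion `"CPD"` or `"64PP"`, or `"custom"` with `dinucs`.
#' @param dinucs For `"custom"`: character vector of dinucleotides.
#' @return Object of class `reactive_set`: list(label, dinucs).
#' @export
reactive_set <- function(lesion = c("CPD", "64PP", "custom"), dinucs = NULL) {
  lesion <- match.arg(lesion)
  d <- switch(lesion, CPD = "TT", `64PP` = c("CC", "CT", "TC"),
              custom = toupper(dinucs))
  if (!length(d) || any(grepl("[^ACGT]", d)) || any(nchar(d) != 2L))
    stop("reactive set must be non-empty dinucleotides over ACGT")
  structure(list(label = lesion, dinucs = d), class = "reactive_set")
}

# per-origin slice of one strand array, anchored at the midpoint
.slice_profile <- function(arrs, origins, span, resolution) {
  if (span %% resolution != 0L) stop("resolution must divide span")
  half_bins <- (span %/% 2L) %/% resolution
  ncols <- 2L * half_bins
  m <- matrix(NA_real_, nrow(origins), ncols)
  for (i in seq_len(nrow(origins))) {
    v <- arrs[[origins$chrom[i]]]
    centre_bin <- origins$midpoint[i] %/% resolution    # 0-based
    bins <- (centre_bin - half_bins):(centre_bin + half_bins - 1L)
    inb <- bins >= 0L & bins < length(v)
    m[i, inb] <- v[bins[inb] + 1L]
  }
  colnames(m) <- seq.int(-half_bins, half_bins - 1L) * resolution
  m
}

#' Strand-resolved signal profiles at origins
#'
#' Re-anchors a binned track at origin midpoints and reports per-offset
#' means (one matrix per strand). Origins clipped by chromosome ends are
#' padded with missing values.
#'
#' @param track A `strand_track`.
#' @param origins An `origin_set`.
#' @param span Total profile width (bp) centred on the midpoint; the
#'   track resolution must divide it.
#' @return List of class `profile_matrix`: `offsets`, per-strand
#'   matrices `plus`/`minus` (origins x bins), and `summary`
#'   (data.frame with per-offset mean and SEM per strand).
#' @export
profile_at_origins <- function(track, origins, span = 20000L) {
  p <- .slice_profile(track$plus, origins, span, track$resolution)
  m <- .slice_profile(track$minus, origins, span, track$resolution)
  sem <- function(col) {
    v <- col[!is.na(col)]
    if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_
  }
  offs <- as.integer(colnames(p))
  summary <- data.frame(
    offset = offs,
    plus_mean = colMeans(p, na.rm = TRUE), plus_sem = apply(p, 2L, sem),
    minus_mean = colMeans(m, na.rm = TRUE), minus_sem = apply(m, 2L, sem))
  structure(list(offsets = offs, plus = p, minus = m, summary = summary,
                 resolution = track$resolution),
            class = "profile_matrix")
}

#' Mean signal over origin domains
#'
#' Weighted mean of binned signal within midpoint +/- `halfwidth` per
#' origin (bins weighted by their overlap with the domain); used for
#' cross-track correlations at origins.
#'
#' @param track A `strand_track`.
#' @param origins An `origin_set`.
#' @param halfwidth Domain half-width (bp), default 500.
#' @param strand `"both"` (sum of strands), `"plus"` or `"minus"`.
#' @return Numeric vector, one mean per origin.
#' @export
mean_origin_signal <- function(track, origins, halfwidth = 500L,
                               strand = c("both", "plus", "minus")) {
  strand <- match.arg(strand)
  res <- track$resolution
  out <- numeric(nrow(origins))
  for (i in seq_len(nrow(origins))) {
    ch <- origins$chrom[i]
    v <- switch(strand,
                both = track$plus[[ch]] + track$minus[[ch]],
                plus = track$plus[[ch]], minus = track$minus[[ch]])
    lo <- origins$midpoint[i] - halfwidth
    hi <- origins$midpoint[i] + halfwidth
    b0 <- max(0L, lo %/% res); b1 <- min(length(v) - 1L, (hi - 1L) %/% res)
    if (b1 < b0) { out[i] <- NA_real_; next }
    bins <- b0:b1
    w <- pmin(hi, (bins + 1L) * res) - pmax(lo, bins * res)
    out[i] <- sum(v[bins + 1L] * w) / sum(w)
  }
  out
}

# count occurrences of fixed patterns per bin on one strand.
# A dinucleotide occupying plus-strand positions (i, i+1) is assigned to
# the bin of i; minus-strand dinucleotides are counted as their reverse
# complements on the plus sequence.
.dinuc_bin_counts <- function(genome, chrom, dinucs, strand, resolution) {
  s <- genome$seq[[chrom]]
  nbins <- ceiling(genome$lengths[[chrom]] / resolution)
  counts <- numeric(nbins)
  pats <- if (strand == "+") dinucs else revcomp(dinucs)
  for (p in unique(pats)) {
    m <- gregexpr(paste0("(?=", p, ")"), s, perl = TRUE)[[1]]
    if (m[1] == -1L) next
    b <- (as.integer(m) - 1L) %/% resolution
    counts <- counts + tabulate(b + 1L, nbins = nbins)
  }
  counts
}

#' Correct a track for reactive-dinucleotide composition
#'
#' Divides each bin's signal by the number of reactive dinucleotides
#' read 5' to 3' on the strand carrying the signal; bins with no
#' reactive dinucleotide become missing.
#'
#' @param track A `strand_track`.
#' @param genome A `genome`.
#' @param reactive A [reactive_set()].
#' @return A `strand_track` with corrected (possibly NA) values.
#' @export
dinuc_correct <- function(track, genome, reactive) {
  res <- track$resolution
  plus <- track$plus; minus <- track$minus
  for (ch in names(plus)) {
    cp <- .dinuc_bin_counts(genome, ch, reactive$dinucs, "+", res)
    cm <- .dinuc_bin_counts(genome, ch, reactive$dinucs, "-", res)
    n <- length(plus[[ch]])
    cp <- cp[seq_len(n)]; cm <- cm[seq_len(n)]
    plus[[ch]] <- ifelse(cp > 0, plus[[ch]] / cp, NA_real_)
    minus[[ch]] <- ifelse(cm > 0, minus[[ch]] / cm, NA_real_)
  }
  out <- structure(list(plus = plus, minus = minus, resolution = res),
                   class = "strand_track")
  out
}

#' Strand bias across origin windows
#'
#' Rebins a profile to `grid` bp, computes per-offset
#' `log2((plus + eps) / (minus + eps))`, and re-labels strands as
#' leading/lagging template by the package fork convention (offset >= 0:
#' plus strand = lagging template; mirrored left of the origin).
#'
#' @param profile A `profile_matrix` from [profile_at_origins()].
#' @param grid Output window width (bp); must be a multiple of the
#'   profile resolution.
#' @param eps Pseudocount, default 0.5.
#' @return data.frame `offset`, `plus`, `minus` (rebinned means),
#'   `bias_plus_minus`, `bias_lagging_leading`.
#' @export
strand_bias <- function(profile, grid = 100L, eps = 0.5) {
  res <- profile$resolution
  if (grid %% res != 0L) stop("grid must be a multiple of the profile resolution")
  fac <- grid %/% res
  offs <- profile$offsets
  group <- floor(offs / grid) * grid
  pm <- tapply(profile$summary$plus_mean, group, mean, na.rm = TRUE)
  mm <- tapply(profile$summary$minus_mean, group, mean, na.rm = TRUE)
  offset <- as.integer(names(pm))
  bias_pm <- log2((pm + eps) / (mm + eps))
  right <- offset >= 0L
  lag <- ifelse(right, pm, mm)
  lead <- ifelse(right, mm, pm)
  data.frame(offset = offset, plus = as.numeric(pm), minus = as.numeric(mm),
             bias_plus_minus = as.numeric(bias_pm),
             bias_lagging_leading = as.numeric(log2((lag + eps) / (lead + eps))),
             row.names = NULL)
}
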