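# SV classification and signatures, break-end profiles at origins and
# G4s, CNV signature classes, origin-coverage excess within CNV
# segments, and permutation tests for breakpoint-origin overlap.

SV_TYPES <- c("INS", "DEL", "DUP", "INV", "ITX")

# length bins, lower-open / upper-closed, in bp
SV_LENGTH_BREAKS <- c(0, 100, 500, 1000, 5000, 10000, 1e5, 1e6, Inf)
SV_LENGTH_LABELS <- c("0-0.1kb", "0.1-0.5kb", "0.5-1kb", "1-5kb", "5-10kb",
                      "10-100kb", "0.1-1Mb", ">1Mb")
CNV_LENGTH_BREAKS <- c(0, 1e5, 1e6, 2e6, 3e6, 5e6, 1e7, Inf)
CNV_LENGTH_LABELS <- c("0-0.1Mb", "0.1-1Mb", "1-2Mb", "2-3Mb", "3-5Mb",
                       "5-10Mb", ">10Mb")
CN_CLASS_BREAKS <- c(-1, 0, 1, 2, 4, 8, Inf)
CN_CLASS_LABELS <- c("0", "1", "2", "3-4", "5-8", "9+")

.bin_label <- function(x, breaks, labels) {
  as.character(cut(x, breaks = breaks, labels = labels, right = TRUE))
}

#' Classify raw break-end pairs into SV records
#'
#' Intra-chromosomal pairs (break ends ordered by position) are
#' classified by orientation: tail then head = DEL, head then tail =
#' DUP, same orientation = INV; zero-span records carrying an inserted
#' sequence = INS. Inter-chromosomal pairs are ITX (no length). Records
#' with missing orientation are dropped with a tally.
#'
#' @param bends data.frame with columns `sample_id`, `chrom1`, `pos1`,
#'   `orient1`, `chrom2`, `pos2`, `orient2` and optionally `inserted`
#'   (inserted sequence for INS calls).
#' @return data.frame of class `sv_set` with `sv_type` and `length`
#'   columns (length NA for ITX); attribute `dropped`.
#' @export
classify_sv <- function(bends) {
  ok <- !is.na(bends$orient1) & !is.na(bends$orient2) &
    bends$orient1 %in% c("head", "tail") & bends$orient2 %in% c("head", "tail")
  dropped <- sum(!ok)
  b <- bends[ok, , drop = FALSE]
  # order intra-chromosomal ends by position
  swap <- b$chrom1 == b$chrom2 & b$pos1 > b$pos2
  tmp <- b[swap, c("chrom2", "pos2", "orient2")]
  b[swap, c("chrom2", "pos2", "orient2")] <- b[swap, c("chrom1", "pos1", "orient1")]
  b[swap, c("chrom1", "pos1", "orient1")] <- tmp
  inter <- b$chrom1 != b$chrom2
  span <- ifelse(inter, NA_integer_, abs(b$pos2 - b$pos1))
  ins_seq <- if ("inserted" %in% names(b)) !is.na(b$inserted) & nzchar(b$inserted)
             else rep(FALSE, nrow(b))
  type <- rep(NA_character_, nrow(b))
  type[inter] <- "ITX"
  intra <- !inter
  same <- intra & b$orient1 == b$orient2
  type[same] <- "INV"
  type[intra & b$orient1 == "tail" & b$orient2 == "head"] <- "DEL"
  type[intra & b$orient1 == "head" & b$orient2 == "tail"] <- "DUP"
  type[intra & span == 0L & ins_seq] <- "INS"
  out <- data.frame(sample_id = b$sample_id,
                    chrom1 = b$chrom1, pos1 = b$pos1, orient1 = b$orient1,
                    chrom2 = b$chrom2, pos2 = b$pos2, orient2 = b$orient2,
                    sv_type = type, length = span, stringsAsFactors = FALSE)
  attr(out, "dropped") <- dropped
  class(out) <- c("sv_set", "data.frame")
  out
}

#' SV signature: type x length-bin frequencies
#'
#' SVs with at least one break end inside `regions` (or all SVs when
#' `regions` is NULL) are binned by type and length; ITX forms a single
#' length-free class. Length bins are lower-open/upper-closed:
#' 0-0.1, 0.1-0.5, 0.5-1, 1-5, 5-10, 10-100 kb, 0.1-1 Mb, >1 Mb.
#'
#' @param svs An `sv_set`.
#' @param regions Optional interval data.frame.
#' @return Named numeric vector of class frequencies (sums to 1 when
#'   any SV is counted); attribute `counts` holds raw counts.
#' @export
sv_signature <- function(svs, regions = NULL) {
  classes <- c(as.vector(outer(setdiff(SV_TYPES, "ITX"), SV_LENGTH_LABELS,
                               function(t, l) paste(t, l, sep = ":"))), "ITX")
  if (!is.null(regions)) {
    in1 <- .in_regions(svs$chrom1, svs$pos1, regions)
    in2 <- .in_regions(svs$chrom2, svs$pos2, regions)
    svs <- svs[in1 | in2, , drop = FALSE]
  }
  lab <- ifelse(svs$sv_type == "ITX", "ITX",
                paste(svs$sv_type,
                      .bin_label(svs$length, SV_LENGTH_BREAKS, SV_LENGTH_LABELS),
                      sep = ":"))
  counts <- table(factor(lab, levels = classes))
  freq <- as.numeric(counts)
  tot <- sum(freq)
  out <- setNames(if (tot > 0) freq / tot else freq, classes)
  attr(out, "counts") <- setNames(as.integer(counts), classes)
  out
}

#' Break-end fold-change profile across origin windows
#'
#' Per offset window: break-end density divided by the mean flank
#' density (background); undefined (all-NA folds) when the flank
#' density is zero, flagged.
#'
#' @param svs An `sv_set`.
#' @param grid A `window_grid`.
#' @return data.frame `offset`, `count`, `density`, `fold`; attribute
#'   `flank_density`.
#' @export
breakend_profile <- function(svs, grid) {
  bends <- data.frame(chrom = c(svs$chrom1, svs$chrom2),
                      pos = c(svs$pos1, svs$pos2), stringsAsFactors = FALSE)
  hits <- .grid_hits(bends$chrom, bends$pos, grid)
  k <- length(grid$offsets)
  counts <- tabulate(hits$window, nbins = k)
  dens <- counts / (grid$width * nrow(grid$origins))
  flank <- .flank_offsets(grid)
  bg <- mean(dens[flank])
  fold <- if (bg > 0) dens / bg else rep(NA_real_, k)
  if (bg == 0) warning("zero flank break-end density; fold change undefined")
  out <- data.frame(offset = grid$offsets, count = counts,
                    density = dens, fold = fold)
  attr(out, "flank_density") <- bg
  out
}

#' Break-end counts around G4 motif starts
#'
#' Counts break ends at `binwidth`-nt resolution relative to each
#' motif's `core_start`, oriented by the motif strand (minus-strand
#' motifs are mirrored), and reports the break-end base identity. The
#' `within_tol` summary counts break ends within `tol` bp of the core
#' start.
#'
#' @param svs An `sv_set`.
#' @param motifs A `g4_motif_set`.
#' @param genome A `genome` (for break-end base identity).
#' @param span Profile half-width (bp).
#' @param binwidth Resolution (nt), default 5.
#' @param tol Proximity window (bp), default 5.
#' @return List: `profile` (data.frame `offset`, `count`), `within_tol`
#'   count, `base_table` (break-end base identities, oriented).
#' @export
breakends_near_g4 <- function(svs, motifs, genome, span = 100L,
                              binwidth = 5L, tol = 5L) {
  bends <- data.frame(chrom = c(svs$chrom1, svs$chrom2),
                      pos = c(svs$pos1, svs$pos2), stringsAsFactors = FALSE)
  edges <- seq.int(-span, span, by = binwidth)
  counts <- integer(length(edges) - 1L)
  within <- 0L
  bases <- character()
  for (i in seq_len(nrow(motifs))) {
    ch <- motifs$chrom[i]; cs <- motifs$core_start[i]
    sel <- which(bends$chrom == ch & abs(bends$pos - cs) <= span)
    if (!length(sel)) next
    off <- bends$pos[sel] - cs
    if (motifs$strand[i] == "-") off <- -off
    counts <- counts + as.integer(table(cut(off, breaks = edges,
                                            right = FALSE,
                                            include.lowest = TRUE)))
    within <- within + sum(abs(off) <= tol)
    b <- get_seq(genome, rep(ch, length(sel)), bends$pos[sel],
                 bends$pos[sel] + 1L)
    if (motifs$strand[i] == "-") b <- complement_base(b)
    bases <- c(bases, b)
  }
  list(profile = data.frame(offset = edges[-length(edges)], count = counts),
       within_tol = within,
       base_table = table(factor(bases, levels = BASES)))
}

#' Construct / validate CNV segments
#'
#' @param sample_id,chrom,start,end,total_cn,het_status Per-segment
#'   vectors; `het_status` in {LOH, Het}; `total_cn` >= 0.
#' @param ploidy Baseline ploidy for the gain/loss call, default 2.
#' @return data.frame of class `cnv_set` with a `cnv_kind` column
#'   (gain / loss / neutral).
#' @export
cnv_segments <- function(sample_id, chrom, start, end, total_cn, het_status,
                         ploidy = 2L) {
  total_cn <- as.integer(total_cn)
  if (any(total_cn < 0)) stop("negative copy number")
  if (any(end <= start)) stop("invalid segment intervals")
  if (!all(het_status %in% c("LOH", "Het"))) stop("het_status must be LOH or Het")
  out <- data.frame(sample_id = as.character(sample_id),
                    chrom = as.character(chrom),
                    start = as.integer(start), end = as.integer(end),
                    total_cn = total_cn, het_status = het_status,
                    cnv_kind = ifelse(total_cn > ploidy, "gain",
                                      ifelse(total_cn < ploidy, "loss", "neutral")),
                    stringsAsFactors = FALSE)
  class(out) <- c("cnv_set", "data.frame")
  out
}

#' CNV signature: LOH-status x copy-number class x length-bin frequencies
#'
#' Copy-number classes {0, 1, 2, 3-4, 5-8, 9+}; length bins
#' (lower-open/upper-closed) 0-0.1, 0.1-1, 1-2, 2-3, 3-5, 5-10, >10 Mb.
#'
#' @param segments A `cnv_set`.
#' @return Named numeric frequency vector over the 84 classes (sums to
#'   1); attribute `counts`.
#' @export
cnv_signature <- function(segments) {
  classes <- as.vector(outer(
    c("LOH", "Het"),
    as.vector(outer(CN_CLASS_LABELS, CNV_LENGTH_LABELS,
                    function(c, l) paste(c, l, sep = ":"))),
    function(h, cl) paste(h, cl, sep = ":")))
  len <- segments$end - segments$start
  lab <- paste(segments$het_status,
               .bin_label(segments$total_cn, CN_CLASS_BREAKS, CN_CLASS_LABELS),
               .bin_label(len, CNV_LENGTH_BREAKS, CNV_LENGTH_LABELS),
               sep = ":")
  counts <- table(factor(lab, levels = classes))
  freq <- as.numeric(counts); tot <- sum(freq)
  out <- setNames(if (tot > 0) freq / tot else freq, classes)
  attr(out, "counts") <- setNames(as.integer(counts), classes)
  out
}

#' Origin-midpoint coverage track
#'
#' Counts origin midpoints per fixed-width bin across the genome.
#'
#' @param origins An `origin_set`.
#' @param chrom_lengths Named chromosome lengths.
#' @param bin Bin width (bp), default 100 kb.
#' @return List of class `coverage_track`: per-chromosome count
#'   vectors, `bin`.
#' @export
origin_coverage_track <- function(origins, chrom_lengths, bin = 100000L) {
  arrs <- lapply(chrom_lengths, function(L) integer(ceiling(L / bin)))
  for (ch in unique(origins$chrom)) {
    if (!ch %in% names(arrs)) next
    b <- origins$midpoint[origins$chrom == ch] %/% bin
    arrs[[ch]] <- arrs[[ch]] + tabulate(b + 1L, nbins = length(arrs[[ch]]))
  }
  structure(list(values = arrs, bin = as.integer(bin)), class = "coverage_track")
}

# mean of a coverage track over [start, end), fractional bin overlap,
# truncated at chromosome edges (weights = covered fraction)
.track_mean <- function(track, chrom, start, end) {
  v <- track$values[[chrom]]
  bin <- track$bin
  L <- length(v) * bin
  lo <- max(0, start); hi <- min(L, end)
  if (hi <= lo) return(NA_real_)
  b0 <- lo %/% bin; b1 <- (hi - 1) %/% bin
  bins <- b0:b1
  w <- pmin(hi, (bins + 1) * bin) - pmax(lo, bins * bin)
  sum(v[bins + 1L] * w) / sum(w)
}

#' Origin-coverage excess across rescaled CNV segments
#'
#' Each segment (filtered to lengths in (`min_len`, `max_len`)) and its
#' two `flank`-bp flanking domains are rescaled to `n_win` equally
#' sized windows each; per-window mean origin coverage is averaged over
#' segments, and the excess is the in-segment value minus the mean over
#' flank windows. Windows truncated by chromosome ends contribute with
#' weight equal to their covered fraction.
#'
#' @param segments A `cnv_set` (or any interval data.frame).
#' @param track A `coverage_track` from [origin_coverage_track()].
#' @param flank Flank width (bp), default 2 Mb.
#' @param n_win Windows per part, default 100.
#' @param min_len,max_len Segment length filter (bp), default 100 kb
#'   and 5 Mb (exclusive).
#' @return List of class `enrichment_profile`: `window` (1..n_win,
#'   segment body), `segment_mean` per window, `flank_mean` (scalar),
#'   `excess` per window, `n_segments`.
#' @export
segment_origin_enrichment <- function(segments, track, flank = 2e6,
                                      n_win = 100L, min_len = 1e5,
                                      max_len = 5e6) {
  len <- segments$end - segments$start
  keep <- len > min_len & len < max_len & segments$chrom %in% names(track$values)
  seg <- segments[keep, , drop = FALSE]
  if (!nrow(seg)) stop("no segments in the length window")
  seg_mat <- matrix(NA_real_, nrow(seg), n_win)
  fl_mat <- matrix(NA_real_, nrow(seg), 2L * n_win)
  for (i in seq_len(nrow(seg))) {
    ch <- seg$chrom[i]
    sw <- (seg$end[i] - seg$start[i]) / n_win
    fw <- flank / n_win
    for (w in seq_len(n_win)) {
      seg_mat[i, w] <- .track_mean(track, ch,
                                   seg$start[i] + (w - 1) * sw,
                                   seg$start[i] + w * sw)
      fl_mat[i, w] <- .track_mean(track, ch,
                                  seg$start[i] - flank + (w - 1) * fw,
                                  seg$start[i] - flank + w * fw)
      fl_mat[i, n_win + w] <- .track_mean(track, ch,
                                          seg$end[i] + (w - 1) * fw,
                                          seg$end[i] + w * fw)
    }
  }
  seg_mean <- colMeans(seg_mat, na.rm = TRUE)
  flank_mean <- mean(fl_mat, na.rm = TRUE)
  structure(list(window = seq_len(n_win), segment_mean = seg_mean,
                 flank_mean = flank_mean, excess = seg_mean - flank_mean,
                 n_segments = nrow(seg)),
            class = "enrichment_profile")
}

#' Permutation test for breakpoint-target overlap
#'
#' Observed statistic: number of breakpoint intervals overlapping the
#' target set. Null: each breakpoint is re-placed uniformly at random
#' within its own chromosome (length-preserving), `n_perm` times.
#' P-value uses the plus-one estimator
#' `(1 + #\{null >= observed\}) / (n_perm + 1)`.
#'
#' @param breakpoints Interval data.frame (`chrom`, `start`, `end`);
#'   amplified-segment boundaries are conventionally 1-bp intervals.
#' @param targets Interval data.frame (e.g. 1-kb origin domains); must
#'   be non-empty.
#' @param chrom_lengths Named chromosome lengths.
#' @param n_perm Number of permutations, default 1000.
#' @param seed Optional integer seed for the permutation stream.
#' @return List of class `perm_test`: `observed`, `null` (length
#'   `n_perm`), `p_value`, `fold` (observed / mean null).
#' @export
boundary_permutation_test <- function(breakpoints, targets, chrom_lengths,
                                      n_perm = 1000L, seed = NULL) {
  if (!nrow(targets)) stop("empty target set")
  if (!is.null(seed)) set.seed(seed)
  # per-chromosome sorted disjoint target intervals for fast stabbing
  tgt <- lapply(split(targets, targets$chrom), function(df) {
    ir <- IRanges::reduce(IRanges::IRanges(df$start + 1L, df$end))
    cbind(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
  })
  count_overlaps <- function(chrom, start, end) {
    n <- 0L
    for (ch in unique(chrom)) {
      t <- tgt[[ch]]
      if (is.null(t)) next
      i <- which(chrom == ch)
      # interval [s,e) overlaps some target iff a target start < e and
      # target end > s; with sorted disjoint targets use findInterval
      s <- start[i]; e <- end[i]
      idx <- findInterval(e - 1L, t[, "start"])      # last target starting before e
      ok <- idx >= 1L & ifelse(idx >= 1L, t[pmax(idx, 1L), "end"] > s, FALSE)
      n <- n + sum(ok)
    }
    n
  }
  observed <- count_overlaps(breakpoints$chrom, breakpoints$start, breakpoints$end)
  widths <- breakpoints$end - breakpoints$start
  # vectorized null: all n_perm re-placements drawn at once, per chromosome
  null <- integer(n_perm)
  for (ch in unique(breakpoints$chrom)) {
    i <- which(breakpoints$chrom == ch)
    t <- tgt[[ch]]
    w <- rep(widths[i], times = n_perm)
    s <- floor(runif(length(i) * n_perm) * (chrom_lengths[[ch]] - w + 1))
    if (is.null(t)) next
    idx <- findInterval(s + w - 1L, t[, "start"])
    ok <- idx >= 1L
    ok[ok] <- t[idx[ok], "end"] > s[ok]
    null <- null + as.integer(rowsum(as.integer(ok),
                                     rep(seq_len(n_perm), each = length(i))))
  }
  pval <- (1 + sum(null >= observed)) / (n_perm + 1)
  structure(list(observed = observed, null = null, p_value = pval,
                 fold = if (mean(null) > 0) observed / mean(null) else NA_real_,
                 n_perm = n_perm),
            class = "perm_test")
}

#' Read SV break-end and CNV TSVs
#'
#' SV columns: `sample_id`, `chrom1`, `pos1`, `orient1`, `chrom2`,
#' `pos2`, `orient2` (optional `inserted`). CNV columns: `sample_id`,
#' `chrom`, `start`, `end`, `total_cn`, `het_status`.
#'
#' @param file Path.
#' @return `read_sv_tsv()`: classified `sv_set`; `read_cnv_tsv()`: a
#'   `cnv_set`.
#' @export
read_sv_tsv <- function(file) {
  classify_sv(utils::read.delim(file, stringsAsFactors = FALSE))
}

#' @rdname read_sv_tsv
#' @export
read_cnv_tsv <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  cnv_segments(df$sample_id, df$chrom, df$start, df$end, df$total_cn,
               df$het_status)
}
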