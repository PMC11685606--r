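# Genome container and origin geometry.
#
# Coordinates are 0-based half-open throughout the package; BED is read
# natively, 1-based tabular inputs are converted on load. The genome is
# held as uppercase character sequences (one per chromosome) so that
# substring slicing stays cheap; FASTA IO goes through Biostrings.

#' Construct a genome object
#'
#' @param seqs Named character vector or named list of single sequences
#'   (one per chromosome), alphabet A/C/G/T/N; lower case is upper-cased.
#' @param name Optional assembly name.
#' @return An object of class `genome` with elements `name`, `seq`
#'   (named character vector) and `lengths` (named integer vector).
#' @export
genome <- function(seqs, name = "synthetic") {
  nm <- names(seqs)
  seqs <- vapply(seqs, function(s) toupper(as.character(s)), character(1),
                 USE.NAMES = FALSE)
  names(seqs) <- nm
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("chromosome names must be present and unique")
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("non-ACGTN characters in chromosome(s): ",
         paste(names(seqs)[bad], collapse = ", "))
  structure(list(name = name, seq = seqs, lengths = setNames(nchar(seqs), names(seqs))),
            class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat("<genome>", x$name, "-", length(x$seq), "chromosome(s),",
      format(sum(x$lengths), big.mark = ","), "bp\n")
  invisible(x)
}

#' Read / write genomes as FASTA
#'
#' @param file Path to a FASTA file.
#' @param name Assembly name for the returned object.
#' @return `read_fasta()` returns a `genome`; `write_fasta()` returns
#'   `file` invisibly.
#' @export
read_fasta <- function(file, name = basename(file)) {
  ss <- Biostrings::readDNAStringSet(file)
  genome(setNames(as.character(ss), sub("\\s.*$", "", names(ss))), name = name)
}

#' @rdname read_fasta
#' @param gen A `genome` object.
#' @export
write_fasta <- function(gen, file) {
  ss <- Biostrings::DNAStringSet(gen$seq)
  Biostrings::writeXStringSet(ss, file, width = 70L)
  invisible(file)
}

#' Extract genome sequence (0-based half-open)
#'
#' @param gen A `genome`.
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open coordinates (vectorized).
#' @return Character vector of sequences.
#' @export
get_seq <- function(gen, chrom, start, end) {
  stopifnot(all(chrom %in% names(gen$seq)))
  len <- gen$lengths[chrom]
  if (any(start < 0) || any(end > len) || any(start >= end))
    stop("coordinates out of range")
  unname(substring(gen$seq[chrom], start + 1L, end))
}

#' Construct an origin set
#'
#' Replication-origin intervals with derived midpoints and the
#' domain/flank geometry used throughout: the *domain* is
#' midpoint +/- `domain_halfwidth` (default 500 bp, i.e. the 1-kb unit),
#' the *flank* is midpoint +/- `flank_halfwidth` (default 10 kb)
#' excluding the domain. Midpoint of an even-length interval is the
#' floor of the mean.
#'
#' @param chrom,start,end Interval coordinates (0-based half-open).
#' @param domain_halfwidth,flank_halfwidth Geometry in bp.
#' @param name Optional per-origin names.
#' @return A data.frame of class `origin_set` with columns `chrom`,
#'   `start`, `end`, `midpoint`, `isolated` (NA until
#'   [select_isolated()] is applied) and geometry attributes.
#' @export
origin_set <- function(chrom, start, end, domain_halfwidth = 500L,
                       flank_halfwidth = 10000L, name = NULL) {
  start <- as.integer(start); end <- as.integer(end)
  if (any(start < 0) || any(end <= start)) stop("invalid origin intervals")
  if (domain_halfwidth <= 0 || flank_halfwidth <= domain_halfwidth)
    stop("need 0 < domain_halfwidth < flank_halfwidth")
  out <- data.frame(chrom = as.character(chrom), start = start, end = end,
                    midpoint = (start + end) %/% 2L,
                    isolated = NA, stringsAsFactors = FALSE)
  if (!is.null(name)) out$name <- name
  attr(out, "domain_halfwidth") <- as.integer(domain_halfwidth)
  attr(out, "flank_halfwidth") <- as.integer(flank_halfwidth)
  class(out) <- c("origin_set", "data.frame")
  out
}

domain_halfwidth <- function(origins) attr(origins, "domain_halfwidth")
flank_halfwidth <- function(origins) attr(origins, "flank_halfwidth")

#' Read origins from BED or a headered TSV
#'
#' BED3/BED6 is 0-based half-open natively. The TSV form expects a
#' header with columns `chrom`, `start`, `end` (and optionally `name`);
#' set `one_based = TRUE` if its starts are 1-based inclusive.
#'
#' @param file Path.
#' @param one_based For the TSV form only.
#' @inheritParams origin_set
#' @return An `origin_set`.
#' @export
read_origins <- function(file, domain_halfwidth = 500L, flank_halfwidth = 10000L,
                         one_based = FALSE) {
  first <- readLines(file, n = 1L)
  if (grepl("^chrom\\b", first)) {
    df <- utils::read.delim(file, stringsAsFactors = FALSE)
    if (one_based) df$start <- df$start - 1L
  } else {
    df <- utils::read.delim(file, header = FALSE, stringsAsFactors = FALSE)
    names(df)[1:3] <- c("chrom", "start", "end")
    if (ncol(df) >= 4) names(df)[4] <- "name"
  }
  origin_set(df$chrom, df$start, df$end,
             domain_halfwidth = domain_halfwidth,
             flank_halfwidth = flank_halfwidth,
             name = if ("name" %in% names(df)) df$name else NULL)
}

#' Write intervals as BED
#'
#' @param x A data.frame with `chrom`, `start`, `end` and optionally
#'   `name`, `score`, `strand` columns (0-based half-open).
#' @param file Output path.
#' @export
write_bed <- function(x, file) {
  cols <- list(x$chrom, x$start, x$end)
  if (!is.null(x$name)) {
    cols <- c(cols, list(x$name,
                         if (is.null(x$score)) 0 else x$score,
                         if (is.null(x$strand)) "." else x$strand))
  }
  df <- do.call(data.frame, c(cols, stringsAsFactors = FALSE))
  utils::write.table(df, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' Read BED3/BED6 intervals
#'
#' @param file Path.
#' @return data.frame with chrom/start/end (+ name/score/strand if present).
#' @export
read_bed <- function(file) {
  df <- utils::read.delim(file, header = FALSE, stringsAsFactors = FALSE)
  names(df)[seq_len(min(6, ncol(df)))] <-
    c("chrom", "start", "end", "name", "score", "strand")[seq_len(min(6, ncol(df)))]
  df
}

# clip intervals to [0, chrom length); warns when clipping occurs
.clip_intervals <- function(df, chrom_lengths, what = "interval") {
  if (is.null(chrom_lengths)) return(df)
  len <- chrom_lengths[df$chrom]
  clipped <- df$start < 0 | df$end > len
  if (any(clipped)) {
    df$start <- pmax(df$start, 0L)
    df$end <- pmin(df$end, len)
    warning(sum(clipped), " ", what, "(s) clipped at chromosome ends")
  }
  df[df$end > df$start, , drop = FALSE]
}

#' Origin domains: the 1-kb regions centred on origin midpoints
#'
#' @param origins An `origin_set`.
#' @param chrom_lengths Optional named lengths used to clip intervals
#'   that would extend past a chromosome end (clipped with a warning).
#' @return data.frame of intervals `chrom`, `start`, `end`, `origin`
#'   (row index into `origins`).
#' @export
origin_domains <- function(origins, chrom_lengths = NULL) {
  hw <- domain_halfwidth(origins)
  df <- data.frame(chrom = origins$chrom,
                   start = origins$midpoint - hw,
                   end = origins$midpoint + hw,
                   origin = seq_len(nrow(origins)),
                   stringsAsFactors = FALSE)
  .clip_intervals(df, chrom_lengths, "domain")
}

#' Origin flanks: the +/-10 kb windows minus the domain
#'
#' @inheritParams origin_domains
#' @return data.frame of intervals with a `side` column (`"left"`,
#'   `"right"`) and `origin` index; total flank length 19 kb per origin
#'   at the defaults when unclipped.
#' @export
origin_flanks <- function(origins, chrom_lengths = NULL) {
  dhw <- domain_halfwidth(origins); fhw <- flank_halfwidth(origins)
  mid <- origins$midpoint
  df <- data.frame(
    chrom = rep(origins$chrom, 2L),
    start = c(mid - fhw, mid + dhw),
    end = c(mid - dhw, mid + fhw),
    origin = rep(seq_len(nrow(origins)), 2L),
    side = rep(c("left", "right"), each = nrow(origins)),
    stringsAsFactors = FALSE)
  .clip_intervals(df, chrom_lengths, "flank")
}

#' Keep origins with no neighbour within a radius
#'
#' An origin is *isolated* when no other origin midpoint lies within
#' `radius` bp of its own midpoint, i.e. its 2x`radius` window contains
#' a single origin. Idempotent.
#'
#' @param origins An `origin_set`.
#' @param radius Half-width of the exclusion window (bp).
#' @return The subset `origin_set` of isolated origins, `isolated` flag
#'   set to `TRUE`; the full set with flags is in attribute `"flags"`.
#' @export
select_isolated <- function(origins, radius = 10000L) {
  iso <- rep(TRUE, nrow(origins))
  for (ch in unique(origins$chrom)) {
    i <- which(origins$chrom == ch)
    m <- sort(origins$midpoint[i])
    ord <- order(origins$midpoint[i])
    if (length(m) > 1L) {
      gap_left <- c(Inf, diff(m))
      gap_right <- c(diff(m), Inf)
      iso[i[ord]] <- gap_left > radius & gap_right > radius
    }
  }
  out <- origins[iso, , drop = FALSE]
  out$isolated <- TRUE
  attr(out, "flags") <- iso
  attr(out, "domain_halfwidth") <- domain_halfwidth(origins)
  attr(out, "flank_halfwidth") <- flank_halfwidth(origins)
  class(out) <- class(origins)
  out
}

#' Call origin clusters by single-linkage chaining
#'
#' Midpoints within `link_distance` of the next midpoint on the same
#' chromosome are chained; emitted clusters must span more than
#' `min_span` bp and contain at least `min_origins` origins.
#'
#' @param origins An `origin_set`.
#' @param link_distance Chaining distance (bp).
#' @param min_span Minimum cluster span (bp), exclusive.
#' @param min_origins Minimum origins per cluster.
#' @return data.frame with one row per cluster (`chrom`, `start`, `end`,
#'   `span`, `n_origins`) plus attribute `"mean_origins"`.
#' @export
call_clusters <- function(origins, link_distance = 20000L,
                          min_span = 20000L, min_origins = 2L) {
  res <- list()
  for (ch in unique(origins$chrom)) {
    m <- sort(origins$midpoint[origins$chrom == ch])
    if (!length(m)) next
    brk <- c(0L, which(diff(m) > link_distance), length(m))
    for (j in seq_len(length(brk) - 1L)) {
      idx <- (brk[j] + 1L):brk[j + 1L]
      span <- m[idx[length(idx)]] - m[idx[1L]]
      if (length(idx) >= min_origins && span > min_span)
        res[[length(res) + 1L]] <- data.frame(
          chrom = ch, start = m[idx[1L]], end = m[idx[length(idx)]],
          span = span, n_origins = length(idx), stringsAsFactors = FALSE)
    }
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               span = integer(), n_origins = integer())
  attr(out, "mean_origins") <- if (nrow(out)) mean(out$n_origins) else NA_real_
  out
}

#' Match two origin sets by midpoint distance
#'
#' Greedy nearest-midpoint matching: candidate pairs with midpoint
#' distance below `tol` are accepted in increasing-distance order (ties
#' broken leftmost), each origin used at most once. Matched pairs are
#' treated as the same initiation site.
#'
#' @param a,b `origin_set`s on one assembly.
#' @param tol Maximum midpoint distance (bp, exclusive).
#' @return List with `pairs` (data.frame `a`, `b`, `distance`),
#'   `unmatched_a`, `unmatched_b` (row indices).
#' @export
match_origin_sets <- function(a, b, tol = 5000L) {
  cand <- list()
  for (ch in intersect(unique(a$chrom), unique(b$chrom))) {
    ia <- which(a$chrom == ch); ib <- which(b$chrom == ch)
    d <- abs(outer(a$midpoint[ia], b$midpoint[ib], "-"))
    hit <- which(d < tol, arr.ind = TRUE)
    if (nrow(hit))
      cand[[length(cand) + 1L]] <- data.frame(
        a = ia[hit[, 1L]], b = ib[hit[, 2L]],
        distance = d[hit], stringsAsFactors = FALSE)
  }
  pairs <- data.frame(a = integer(), b = integer(), distance = integer())
  if (length(cand)) {
    cand <- do.call(rbind, cand)
    cand <- cand[order(cand$distance, cand$a, cand$b), , drop = FALSE]
    used_a <- logical(nrow(a)); used_b <- logical(nrow(b))
    keep <- logical(nrow(cand))
    for (i in seq_len(nrow(cand))) {
      if (!used_a[cand$a[i]] && !used_b[cand$b[i]]) {
        keep[i] <- TRUE
        used_a[cand$a[i]] <- TRUE; used_b[cand$b[i]] <- TRUE
      }
    }
    pairs <- cand[keep, , drop = FALSE]
  }
  list(pairs = pairs,
       unmatched_a = setdiff(seq_len(nrow(a)), pairs$a),
       unmatched_b = setdiff(seq_len(nrow(b)), pairs$b))
}

#' Tile fixed-width windows across origin flanking regions
#'
#' Windows of `width` bp tile `[-flank_halfwidth, +flank_halfwidth)`
#' around every origin midpoint; offsets label each window's left edge
#' relative to the midpoint.
#'
#' @param origins An `origin_set`.
#' @param width Window width (bp); must divide `2 * flank_halfwidth`.
#' @return An object of class `window_grid`: list with `origins`,
#'   `width`, `offsets` (length `2*flank_halfwidth/width`).
#' @export
tile_windows <- function(origins, width = 100L) {
  fhw <- flank_halfwidth(origins)
  if ((2L * fhw) %% width != 0L)
    stop("width must divide 2*flank_halfwidth = ", 2L * fhw)
  structure(list(origins = origins, width = as.integer(width),
                 offsets = seq.int(-fhw, fhw - width, by = width)),
            class = "window_grid")
}

#' @export
print.window_grid <- function(x, ...) {
  cat("<window_grid>", length(x$offsets), "windows of", x$width, "bp x",
      nrow(x$origins), "origins\n")
  invisible(x)
}

#' Per-origin window intervals of a grid
#'
#' @param grid A `window_grid`.
#' @param chrom_lengths Optional clipping lengths; clipped windows keep
#'   their offset label but shrink.
#' @return data.frame `chrom`, `start`, `end`, `origin`, `offset`.
#' @export
grid_intervals <- function(grid, chrom_lengths = NULL) {
  o <- grid$origins
  n <- nrow(o); k <- length(grid$offsets)
  df <- data.frame(
    chrom = rep(o$chrom, each = k),
    start = rep(o$midpoint, each = k) + rep(grid$offsets, n),
    end = rep(o$midpoint, each = k) + rep(grid$offsets, n) + grid$width,
    origin = rep(seq_len(n), each = k),
    offset = rep(grid$offsets, n),
    stringsAsFactors = FALSE)
  if (!is.null(chrom_lengths)) {
    len <- chrom_lengths[df$chrom]
    df$start <- pmax(df$start, 0L)
    df$end <- pmin(df$end, len)
    df <- df[df$end > df$start, , drop = FALSE]
  }
  df
}

# Flank-window mask of a grid: windows lying entirely outside the domain.
.flank_offsets <- function(grid) {
  dhw <- domain_halfwidth(grid$origins)
  grid$offsets + grid$width <= -dhw | grid$offsets >= dhw
}
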