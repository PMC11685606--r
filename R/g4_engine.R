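# G4Hunter propensity scoring, quadruplex motif discovery, loop
# statistics, top-window extraction, and replication-oriented mutation
# profiles at G4s.

#' G4Hunter per-base scores
#'
#' Each G in a maximal G-run of length n scores min(n, 4); each C in a
#' maximal C-run scores -min(n, 4); A, T and N score 0. N breaks runs.
#'
#' @param seq A single DNA sequence (A/C/G/T/N, case-insensitive).
#' @return Integer vector of per-base scores in \[-4, 4\].
#' @export
g4hunter_positional <- function(seq) {
  seq <- toupper(seq)
  if (grepl("[^ACGTN]", seq)) stop("non-ACGTN character in sequence")
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  r <- rle(ch)
  val <- integer(length(r$lengths))
  isG <- r$values == "G"; isC <- r$values == "C"
  val[isG] <- pmin(r$lengths[isG], 4L)
  val[isC] <- -pmin(r$lengths[isC], 4L)
  rep(val, r$lengths)
}

#' G4Hunter score of a sequence
#'
#' Arithmetic mean of the per-base scores; antisymmetric under reverse
#' complement. Positive scores indicate quadruplex-forming propensity on
#' the plus strand, negative on the minus strand.
#'
#' @param seq A single non-empty DNA sequence.
#' @return Numeric score in \[-4, 4\].
#' @export
g4hunter_score <- function(seq) {
  if (!nchar(seq)) stop("empty sequence")
  mean(g4hunter_positional(seq))
}

# G-strand core pattern: lazy loops keep the parse deterministic
.G4_CORE_PLUS <- "G{3,}(?:[ACGT]{1,12}?G{3,}){3}"

.G4_PARSE <- "^(G{3,})([ACGT]{1,12}?)(G{3,})([ACGT]{1,12}?)(G{3,})([ACGT]{1,12}?)(G{3,})$"

# parse a plus-orientation core match into tracts/loops
.parse_core <- function(core) {
  m <- regexec(.G4_PARSE, core)[[1]]
  if (m[1] == -1L) return(NULL)
  lens <- attr(m, "match.length")[-1]
  starts <- m[-1] - 1L                   # 0-based within core
  list(tract_starts = starts[c(1, 3, 5, 7)],
       tract_lengths = lens[c(1, 3, 5, 7)],
       loops = lens[c(2, 4, 6)])
}

#' Find G-quadruplex motifs
#'
#' Matches the quadparser-style pattern
#' `N5 G3+ N1-12 G3+ N1-12 G3+ N1-12 G3+ N5` on both strands (the
#' C-form on the minus strand), with extended loop lengths of 1-12 nt.
#' Matches are non-overlapping per strand, taken leftmost with lazy
#' loops (deterministic). The G4H score is computed on the
#' flank-inclusive sequence and sign-normalized to the motif strand.
#' Motifs whose 5-base flanks would extend past a chromosome end are
#' dropped with a tally.
#'
#' @param genome A `genome`.
#' @param regions Optional interval data.frame restricting the search;
#'   default scans whole chromosomes.
#' @param max_loop Maximum loop length (nt), default 12.
#' @param flank Flanking bases included in the interval and score,
#'   default 5.
#' @return data.frame of class `g4_motif_set`: `chrom`, `start`, `end`
#'   (flank-inclusive, 0-based half-open), `strand`, `core_start`
#'   (0-based position of the first G of the first G-tract on the motif
#'   strand), `core_end`, `g4h` (positive magnitude), `g4h_signed`,
#'   list-columns `tract_starts`, `tract_lengths`, `loops`; attribute
#'   `dropped`.
#' @export
find_g4_motifs <- function(genome, regions = NULL, max_loop = 12L, flank = 5L) {
  if (is.null(regions))
    regions <- data.frame(chrom = names(genome$seq), start = 0L,
                          end = unname(genome$lengths), stringsAsFactors = FALSE)
  pat_plus <- gsub("12", as.character(max_loop), .G4_CORE_PLUS, fixed = TRUE)
  rows <- list(); dropped <- 0L
  for (ri in seq_len(nrow(regions))) {
    ch <- regions$chrom[ri]
    rs <- max(0L, regions$start[ri]); re <- min(genome$lengths[[ch]], regions$end[ri])
    s <- get_seq(genome, ch, rs, re)
    n_reg <- nchar(s)
    for (strand in c("+", "-")) {
      # the minus strand is scanned as the plus pattern on the reverse
      # complement, so motif calls are strand-closed by construction
      s_search <- if (strand == "+") s else revcomp(s)
      m <- gregexpr(pat_plus, s_search, perl = TRUE)[[1]]
      if (m[1] == -1L) next
      lens <- attr(m, "match.length")
      for (j in seq_along(m)) {
        core_len <- lens[j]
        core0 <- if (strand == "+") rs + m[j] - 1L
                 else rs + n_reg - (m[j] - 1L) - core_len   # reflected
        if (core0 - flank < 0L || core0 + core_len + flank > genome$lengths[[ch]]) {
          dropped <- dropped + 1L
          next
        }
        core_parse <- substr(s_search, m[j], m[j] + core_len - 1L)
        p <- .parse_core(core_parse)
        if (is.null(p)) { dropped <- dropped + 1L; next }
        full_seq <- get_seq(genome, ch, core0 - flank, core0 + core_len + flank)
        sc <- g4hunter_score(full_seq)
        signed <- if (strand == "+") sc else -sc
        core_start <- if (strand == "+") core0 else core0 + core_len - 1L
        core_end <- if (strand == "+") core0 + core_len else core0 - 1L
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = ch, start = core0 - flank, end = core0 + core_len + flank,
          strand = strand, core_start = core_start, core_end = core_end,
          core_length = core_len,
          g4h = abs(signed), g4h_signed = signed,
          tract_starts = I(list(p$tract_starts)),
          tract_lengths = I(list(p$tract_lengths)),
          loops = I(list(p$loops)),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               strand = character(), core_start = integer(),
               core_end = integer(), core_length = integer(),
               g4h = numeric(), g4h_signed = numeric(),
               tract_starts = I(list()), tract_lengths = I(list()),
               loops = I(list()))
  out <- out[order(out$chrom, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  class(out) <- c("g4_motif_set", "data.frame")
  out
}

#' G4H scores of mutation contexts
#'
#' Scores the +/- `halfwidth` bp window (2*halfwidth+1 nt) around each
#' mutation; windows truncated by chromosome ends are dropped with a
#' tally.
#'
#' @param snvs An `snv_table` subset.
#' @param genome A `genome`.
#' @param halfwidth Window half-width (bp), default 25 (51-nt windows).
#' @return data.frame `chrom`, `pos`, `g4h` with attribute `dropped`.
#' @export
mutation_context_g4h <- function(snvs, genome, halfwidth = 25L) {
  len <- genome$lengths[snvs$chrom]
  ok <- snvs$pos - halfwidth >= 0L & snvs$pos + halfwidth + 1L <= len
  sub <- snvs[ok, , drop = FALSE]
  seqs <- get_seq(genome, sub$chrom, sub$pos - halfwidth,
                  sub$pos + halfwidth + 1L)
  out <- data.frame(chrom = sub$chrom, pos = sub$pos,
                    g4h = vapply(seqs, g4hunter_score, numeric(1),
                                 USE.NAMES = FALSE),
                    stringsAsFactors = FALSE)
  attr(out, "dropped") <- sum(!ok)
  out
}

# nearest-origin midpoint for a set of positions (same chromosome)
.nearest_midpoint <- function(chrom, pos, origins) {
  mid <- rep(NA_integer_, length(pos))
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    m <- origins$midpoint[origins$chrom == ch]
    if (!length(m)) next
    m <- sort(m)
    idx <- findInterval(pos[i], m)
    lo <- pmax(idx, 1L); hi <- pmin(idx + 1L, length(m))
    pick <- ifelse(abs(pos[i] - m[lo]) <= abs(m[hi] - pos[i]), m[lo], m[hi])
    mid[i] <- pick
  }
  mid
}

#' Replication-oriented mutation profile at G4 motifs
#'
#' Offsets are measured from each motif's `core_start` along the
#' direction of replication: motifs right of their origin midpoint keep
#' genomic orientation (offset = pos - core_start); motifs left of the
#' midpoint are mirrored (offset = core_start - pos), and the co-reported
#' base track is read on the mirrored strand. Motifs spanning the
#' midpoint are assigned by the side of `core_start` (logged).
#'
#' @param snvs An `snv_table`.
#' @param motifs A `g4_motif_set`.
#' @param origins An `origin_set`.
#' @param genome A `genome` (for the G-frequency track).
#' @param span Profile half-width (bp) around `core_start`.
#' @return data.frame `offset` (-span..span), `count`, `g_freq`
#'   (frequency of G at that oriented offset over motifs).
#' @export
oriented_mutation_profile <- function(snvs, motifs, origins, genome, span = 30L) {
  mid <- .nearest_midpoint(motifs$chrom, motifs$core_start, origins)
  rightward <- motifs$core_start >= mid
  offsets <- -span:span
  counts <- setNames(integer(length(offsets)), offsets)
  gcount <- setNames(numeric(length(offsets)), offsets)
  gtot <- setNames(numeric(length(offsets)), offsets)
  for (i in seq_len(nrow(motifs))) {
    ch <- motifs$chrom[i]; cs <- motifs$core_start[i]
    sel <- snvs$chrom == ch & abs(snvs$pos - cs) <= span
    if (any(sel)) {
      off <- if (rightward[i]) snvs$pos[sel] - cs else cs - snvs$pos[sel]
      tb <- table(factor(off, levels = offsets))
      counts <- counts + as.integer(tb)
    }
    pos <- if (rightward[i]) cs + offsets else cs - offsets
    inb <- pos >= 0L & pos < genome$lengths[[ch]]
    bases <- rep(NA_character_, length(offsets))
    bases[inb] <- get_seq(genome, rep(ch, sum(inb)), pos[inb], pos[inb] + 1L)
    if (!rightward[i]) bases[inb] <- complement_base(bases[inb])
    gtot <- gtot + as.numeric(inb)
    gcount <- gcount + as.numeric(!is.na(bases) & bases == "G")
  }
  data.frame(offset = offsets, count = as.integer(counts),
             g_freq = ifelse(gtot > 0, gcount / gtot, NA_real_))
}

#' Loop-length statistics of G4 motifs
#'
#' @param motifs A `g4_motif_set`.
#' @param group Optional factor over motifs (e.g. mutated vs not).
#' @return List: `per_motif` (data.frame with `mean_loop`, `min_loop`,
#'   `max_loop`), `summary` (per group mean of per-motif mean loops).
#' @export
loop_stats <- function(motifs, group = NULL) {
  loops <- motifs$loops
  per <- data.frame(
    mean_loop = vapply(loops, function(x) mean(x), numeric(1)),
    min_loop = vapply(loops, function(x) min(x), numeric(1)),
    max_loop = vapply(loops, function(x) max(x), numeric(1)))
  summ <- NULL
  if (!is.null(group)) {
    summ <- aggregate(per$mean_loop, list(group = group),
                      function(v) c(mean = mean(v), n = length(v)))
    summ <- data.frame(group = summ$group, mean = summ$x[, "mean"],
                       n = summ$x[, "n"])
  }
  list(per_motif = per, summary = summ)
}

#' Highest-|G4H| sub-window of each peak
#'
#' Slides a `width`-nt window across each peak and reports the window
#' with the maximal absolute G4H score (ties resolved leftmost; window
#' sums are integers so ties are exact). Peaks shorter than `width`
#' use the whole peak, flagged.
#'
#' @param peaks Interval data.frame (`chrom`, `start`, `end`).
#' @param genome A `genome`.
#' @param width Sub-window width (nt), default 25.
#' @return data.frame: peak coordinates, `best_start`, `best_end`,
#'   `best_score` (signed), `best_strand` (`"+"` when score >= 0),
#'   `short` flag.
#' @export
g4access_top_window <- function(peaks, genome, width = 25L) {
  out <- vector("list", nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    ch <- peaks$chrom[i]; ps <- peaks$start[i]; pe <- peaks$end[i]
    s <- get_seq(genome, ch, ps, pe)
    sc <- g4hunter_positional(s)
    n <- length(sc)
    if (n <= width) {
      best_start <- ps; best_end <- pe
      best_sum <- sum(sc); best_w <- n; short <- TRUE
    } else {
      cs <- cumsum(c(0L, sc))
      sums <- cs[(width + 1L):(n + 1L)] - cs[1L:(n - width + 1L)]
      j <- which.max(abs(sums))          # first (leftmost) maximum
      best_start <- ps + j - 1L; best_end <- best_start + width
      best_sum <- sums[j]; best_w <- width; short <- FALSE
    }
    out[[i]] <- data.frame(chrom = ch, start = ps, end = pe,
                           best_start = best_start, best_end = best_end,
                           best_score = best_sum / best_w,
                           best_strand = if (best_sum >= 0) "+" else "-",
                           short = short, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Trinucleotide-context occurrences within G4 motifs
#'
#' Counts overlapping trinucleotides within each motif's flank-inclusive
#' sequence read 5' to 3' on the motif strand, collapsed to
#' pyrimidine-centred form and expanded over the 96 context classes
#' (each class inherits its central trinucleotide's occurrence). Used to
#' composition-normalize G4-restricted signatures.
#'
#' @param motifs A `g4_motif_set`.
#' @param genome A `genome`.
#' @return Named numeric 96-vector; attribute `occ32` carries the
#'   32-trinucleotide form.
#' @export
trinuc_in_motifs <- function(motifs, genome) {
  occ32 <- setNames(numeric(32L), trinuc_classes())
  if (nrow(motifs)) {
    seqs <- get_seq(genome, motifs$chrom, motifs$start, motifs$end)
    minus <- motifs$strand == "-"
    seqs[minus] <- revcomp(seqs[minus])
    tri <- Biostrings::trinucleotideFrequency(Biostrings::DNAStringSet(seqs))
    occ32 <- collapse_trinucs(colSums(tri))
  }
  out <- expand_trinuc_occ(occ32)
  attr(out, "occ32") <- occ32
  out
}

#' Write G4 motifs as BED6+ (score = G4H magnitude)
#'
#' Extra columns: core_start, core_length, tract lengths and loop
#' lengths as comma-joined strings.
#'
#' @param motifs A `g4_motif_set`.
#' @param file Output path.
#' @export
write_g4_bed <- function(motifs, file) {
  df <- data.frame(
    chrom = motifs$chrom, start = motifs$start, end = motifs$end,
    name = sprintf("g4_%d", seq_len(nrow(motifs))),
    score = round(motifs$g4h, 4), strand = motifs$strand,
    core_start = motifs$core_start, core_length = motifs$core_length,
    tracts = vapply(motifs$tract_lengths, paste, character(1), collapse = ","),
    loops = vapply(motifs$loops, paste, character(1), collapse = ","),
    stringsAsFactors = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}
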