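# Per-window mutation densities around origins, burden ratios,
# composition-corrected substitution rates, CpG partition, minor allele
# frequencies and cohort filters.

#' Construct / validate an SNV table
#'
#' @param sample_id,chrom,pos,ref,alt Per-record vectors; `pos` is
#'   0-based. `project` optional.
#' @param project Optional project labels.
#' @param genome Optional `genome`; when given, reference bases are
#'   checked against it and mismatches raise an error.
#' @return data.frame of class `snv_table`.
#' @export
snv_table <- function(sample_id, chrom, pos, ref, alt, project = NULL,
                      genome = NULL) {
  ref <- toupper(ref); alt <- toupper(alt)
  ok <- ref %in% BASES & alt %in% BASES
  if (!all(ok)) stop(sum(!ok), " records with non-ACGT ref/alt")
  if (any(ref == alt)) stop("records with ref == alt")
  df <- data.frame(sample_id = as.character(sample_id),
                   project = if (is.null(project)) NA_character_ else as.character(project),
                   chrom = as.character(chrom), pos = as.integer(pos),
                   ref = ref, alt = alt, stringsAsFactors = FALSE)
  if (!is.null(genome)) {
    gb <- get_seq(genome, df$chrom, df$pos, df$pos + 1L)
    bad <- which(gb != df$ref)
    if (length(bad))
      stop("reference mismatch at ", length(bad), " record(s), e.g. ",
           paste(utils::head(paste0(df$chrom[bad], ":", df$pos[bad],
                                    " ref=", df$ref[bad], " genome=", gb[bad]), 3),
                 collapse = "; "))
  }
  class(df) <- c("snv_table", "data.frame")
  df
}

#' Read an ICGC-style SNV TSV
#'
#' Expects a header with columns `sample_id`, `chrom`, `pos`, `ref`,
#' `alt` (plus optional `project`); `one_based = TRUE` converts 1-based
#' positions to the internal 0-based convention.
#'
#' @param file Path.
#' @param one_based Logical.
#' @param genome Optional `genome` for reference checking.
#' @return An `snv_table`.
#' @export
read_snv_tsv <- function(file, one_based = FALSE, genome = NULL) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  pos <- if (one_based) df$pos - 1L else df$pos
  snv_table(df$sample_id, df$chrom, pos, df$ref, df$alt,
            project = if ("project" %in% names(df)) df$project else NULL,
            genome = genome)
}

#' Write an SNV table as TSV (0-based positions)
#'
#' @param snvs An `snv_table`.
#' @param file Output path.
#' @export
write_snv_tsv <- function(snvs, file) {
  utils::write.table(as.data.frame(snvs), file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Filter a cohort by total and region mutation counts
#'
#' Retains samples with at least `min_total` mutations and, when a
#' region set is given, at least `min_region` mutations inside it
#' (the study-style 5,000-total / 50-at-origins filters).
#'
#' @param snvs An `snv_table`.
#' @param min_total Minimum per-sample total.
#' @param region Optional data.frame of intervals (`chrom`,`start`,`end`).
#' @param min_region Minimum per-sample count inside `region`.
#' @return Filtered `snv_table`; warns (does not error) when empty.
#' @export
filter_cohort <- function(snvs, min_total = 5000L, region = NULL,
                          min_region = 50L) {
  tot <- table(snvs$sample_id)
  keep <- names(tot)[tot >= min_total]
  if (!is.null(region)) {
    inreg <- snvs[.in_regions(snvs$chrom, snvs$pos, region), , drop = FALSE]
    rc <- table(factor(inreg$sample_id, levels = names(tot)))
    keep <- intersect(keep, names(rc)[rc >= min_region])
  }
  out <- snvs[snvs$sample_id %in% keep, , drop = FALSE]
  if (!nrow(out)) warning("no samples survive the cohort filter")
  out
}

# membership of positions in a set of intervals (0-based half-open)
.in_regions <- function(chrom, pos, regions) {
  hit <- logical(length(pos))
  for (ch in unique(regions$chrom)) {
    r <- regions[regions$chrom == ch, , drop = FALSE]
    i <- which(chrom == ch)
    if (!length(i)) next
    ir <- IRanges::IRanges(r$start + 1L, r$end)
    ov <- IRanges::overlapsAny(IRanges::IRanges(pos[i] + 1L, width = 1L), ir)
    hit[i] <- ov
  }
  hit
}

# assign mutations to (origin, offset-window) pairs of a grid; a mutation
# inside the flank window of several origins contributes once per origin
.grid_hits <- function(chrom, pos, grid) {
  o <- grid$origins
  fhw <- flank_halfwidth(o)
  out <- list(); skipped <- 0L
  chroms_grid <- unique(o$chrom)
  skipped <- sum(!(chrom %in% chroms_grid))
  for (ch in chroms_grid) {
    i <- which(chrom == ch)
    j <- which(o$chrom == ch)
    if (!length(i) || !length(j)) next
    q <- IRanges::IRanges(pos[i] + 1L, width = 1L)
    s <- IRanges::IRanges(o$midpoint[j] - fhw + 1L, o$midpoint[j] + fhw)
    ov <- IRanges::findOverlaps(q, s)
    if (!length(ov)) next
    mut <- i[S4Vectors_from(ov)]
    org <- j[S4Vectors_to(ov)]
    off <- pos[mut] - o$midpoint[org]
    out[[length(out) + 1L]] <- data.frame(
      record = mut, origin = org, offset_pos = off,
      window = (off + fhw) %/% grid$width + 1L, stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(record = integer(), origin = integer(),
               offset_pos = integer(), window = integer())
  attr(res, "skipped_chrom") <- skipped
  res
}

# thin wrappers so we do not Depend on S4Vectors at the namespace level
S4Vectors_from <- function(ov) as.integer(as.matrix(ov)[, 1L])
S4Vectors_to <- function(ov) as.integer(as.matrix(ov)[, 2L])

#' Mutation density profile across origin-anchored windows
#'
#' Per offset window: total mutations over all origins divided by total
#' covered bases (window width x number of origins, less clipping).
#'
#' @param snvs An `snv_table`.
#' @param grid A `window_grid` from [tile_windows()].
#' @param chrom_lengths Optional named lengths for edge clipping.
#' @return data.frame of class `density_profile` with `offset`, `count`,
#'   `covered_bp`, `density` (mutations/bp); attributes `n_origins` and
#'   `skipped_chrom`.
#' @export
density_profile <- function(snvs, grid, chrom_lengths = NULL) {
  hits <- .grid_hits(snvs$chrom, snvs$pos, grid)
  k <- length(grid$offsets)
  counts <- tabulate(hits$window, nbins = k)
  gi <- grid_intervals(grid, chrom_lengths)
  covered <- tapply(gi$end - gi$start,
                    factor((gi$offset + flank_halfwidth(grid$origins)) %/% grid$width + 1L,
                           levels = seq_len(k)), sum)
  covered[is.na(covered)] <- 0
  out <- data.frame(offset = grid$offsets, count = counts,
                    covered_bp = as.numeric(covered),
                    density = ifelse(covered > 0, counts / as.numeric(covered), NA_real_))
  if (attr(hits, "skipped_chrom") > 0)
    message(attr(hits, "skipped_chrom"),
            " mutation(s) on chromosomes absent from the grid were skipped")
  attr(out, "n_origins") <- nrow(grid$origins)
  attr(out, "skipped_chrom") <- attr(hits, "skipped_chrom")
  class(out) <- c("density_profile", "data.frame")
  out
}

#' Per-sample origin/flank mutation burden ratios
#'
#' Length-normalised mutation density in origin domains divided by the
#' density in origin flanks; samples with zero flank mutations yield
#' `NA` (undefined), never an error.
#'
#' @param snvs An `snv_table`.
#' @param origins An `origin_set`.
#' @param chrom_lengths Optional clipping lengths.
#' @return data.frame `sample_id`, `origin_count`, `flank_count`,
#'   `origin_density`, `flank_density`, `ratio`.
#' @export
burden_ratio <- function(snvs, origins, chrom_lengths = NULL) {
  dom <- origin_domains(origins, chrom_lengths)
  fla <- origin_flanks(origins, chrom_lengths)
  dom_bp <- sum(dom$end - dom$start)
  fla_bp <- sum(fla$end - fla$start)
  samples <- sort(unique(snvs$sample_id))
  in_dom <- .in_regions(snvs$chrom, snvs$pos, dom)
  in_fla <- .in_regions(snvs$chrom, snvs$pos, fla)
  oc <- table(factor(snvs$sample_id[in_dom], levels = samples))
  fc <- table(factor(snvs$sample_id[in_fla], levels = samples))
  od <- as.numeric(oc) / dom_bp
  fd <- as.numeric(fc) / fla_bp
  data.frame(sample_id = samples,
             origin_count = as.integer(oc), flank_count = as.integer(fc),
             origin_density = od, flank_density = fd,
             ratio = ifelse(fd > 0, od / fd, NA_real_),
             stringsAsFactors = FALSE)
}

#' Composition-corrected, background-subtracted substitution rates
#'
#' For each offset window and each of the six pyrimidine substitution
#' classes: mutation count divided by the occurrences of the class's
#' reference base (`context = "base"`: C plus G, or T plus A, collapsing
#' strands) or, for `context = "trinucleotide"`, the mean of per-context
#' rates over the 16 trinucleotide contexts of the class. The background
#' (unweighted mean over flank windows) is then subtracted, so rates may
#' be negative.
#'
#' @param snvs An `snv_table`.
#' @param genome A `genome`.
#' @param grid A `window_grid`.
#' @param context `"base"` or `"trinucleotide"`.
#' @return List of class `rate_panel`: `raw` and `corrected` matrices
#'   (offset x 6 classes), `background` (per class), `context`.
#' @export
corrected_rates <- function(snvs, genome, grid,
                            context = c("base", "trinucleotide")) {
  context <- match.arg(context)
  k <- length(grid$offsets)
  hits <- .grid_hits(snvs$chrom, snvs$pos, grid)
  rec <- snvs[hits$record, , drop = FALSE]
  norm <- pyrimidine_normalize(rec$ref, rec$alt)
  cls <- paste0(norm$ref, ">", norm$alt)
  counts <- matrix(0, nrow = k, ncol = 6L,
                   dimnames = list(NULL, SUBSTITUTIONS))
  tab <- table(factor(hits$window, levels = seq_len(k)),
               factor(cls, levels = SUBSTITUTIONS))
  counts[] <- as.numeric(tab)

  gi <- grid_intervals(grid, genome$lengths)
  win <- (gi$offset + flank_halfwidth(grid$origins)) %/% grid$width + 1L
  seqs <- get_seq(genome, gi$chrom, gi$start, gi$end)
  ss <- Biostrings::DNAStringSet(seqs)

  if (context == "base") {
    bf <- Biostrings::letterFrequency(ss, letters = c("C", "G", "T", "A"))
    occC <- tapply(bf[, "C"] + bf[, "G"], factor(win, levels = seq_len(k)), sum)
    occT <- tapply(bf[, "T"] + bf[, "A"], factor(win, levels = seq_len(k)), sum)
    occC[is.na(occC)] <- 0; occT[is.na(occT)] <- 0
    occ <- cbind(occC, occC, occC, occT, occT, occT)
    raw <- ifelse(occ > 0, counts / occ, NA_real_)
    dimnames(raw) <- list(NULL, SUBSTITUTIONS)
  } else {
    # per-window 32-trinuc occurrences; per-context rates averaged per class
    tri <- Biostrings::trinucleotideFrequency(ss)
    occ32 <- matrix(0, nrow = k, ncol = 32L,
                    dimnames = list(NULL, trinuc_classes()))
    for (w in seq_len(k)) {
      rows <- which(win == w)
      if (length(rows))
        occ32[w, ] <- collapse_trinucs(colSums(tri[rows, , drop = FALSE]))
    }
    ctx <- context_label(rec$ref, rec$alt,
                         get_seq(genome, rec$chrom, pmax(rec$pos - 1L, 0L), rec$pos),
                         get_seq(genome, rec$chrom, rec$pos + 1L,
                                 pmin(rec$pos + 2L, genome$lengths[rec$chrom])))
    ctab <- table(factor(hits$window, levels = seq_len(k)),
                  factor(ctx, levels = context_classes()))
    raw <- matrix(NA_real_, nrow = k, ncol = 6L,
                  dimnames = list(NULL, SUBSTITUTIONS))
    for (s in seq_along(SUBSTITUTIONS)) {
      cols <- which(.context_table$sub == SUBSTITUTIONS[s])
      rates <- matrix(NA_real_, nrow = k, ncol = length(cols))
      for (jj in seq_along(cols)) {
        o <- occ32[, .context_trinuc_idx[cols[jj]]]
        rates[, jj] <- ifelse(o > 0, as.numeric(ctab[, cols[jj]]) / o, NA_real_)
      }
      raw[, s] <- rowMeans(rates, na.rm = TRUE)
      raw[!is.finite(raw[, s]), s] <- NA_real_
    }
  }
  flank <- .flank_offsets(grid)
  background <- colMeans(raw[flank, , drop = FALSE], na.rm = TRUE)
  corrected <- sweep(raw, 2L, background, "-")
  structure(list(offsets = grid$offsets, raw = raw, corrected = corrected,
                 background = background, context = context),
            class = "rate_panel")
}

#' Partition C>T mutations by CpG context
#'
#' A pyrimidine-normalized C>T mutation is CpG when the base 3' of the
#' mutated C on the pyrimidine strand is G. Records at a chromosome end
#' lacking the +1 base are non-CpG by convention (logged via message).
#'
#' @param snvs An `snv_table` (non-C>T records are ignored).
#' @param genome A `genome`.
#' @return List with `cpg` and `non_cpg` `snv_table`s.
#' @export
cpg_partition <- function(snvs, genome) {
  norm <- pyrimidine_normalize(snvs$ref, snvs$alt)
  ct <- which(norm$ref == "C" & norm$alt == "T")
  sub <- snvs[ct, , drop = FALSE]
  flipped <- norm$pyr_strand[ct] == "-"
  nxt_pos <- ifelse(flipped, sub$pos - 1L, sub$pos + 1L)
  len <- genome$lengths[sub$chrom]
  inb <- nxt_pos >= 0L & nxt_pos < len
  if (any(!inb)) message(sum(!inb), " C>T record(s) at chromosome ends: non-CpG by convention")
  nxt <- rep(NA_character_, nrow(sub))
  nxt[inb] <- get_seq(genome, sub$chrom[inb], nxt_pos[inb], nxt_pos[inb] + 1L)
  is_cpg <- !is.na(nxt) & ifelse(flipped, nxt == "C", nxt == "G")
  list(cpg = sub[is_cpg, , drop = FALSE],
       non_cpg = sub[!is_cpg, , drop = FALSE])
}

#' Minor allele frequencies in fixed-width position bins
#'
#' The MAF of a variant is the number of samples carrying the identical
#' (chrom, pos, ref, alt) record divided by the number of screened
#' samples; variants are assigned to `bin`-bp bins for summaries.
#'
#' @param snvs An `snv_table`.
#' @param n_samples Number of screened samples.
#' @param bin Bin width (bp), default 100.
#' @return List with `variants` (per-variant `maf` and `bin_start`) and
#'   `bins` (per-bin mean MAF and variant count).
#' @export
minor_allele_frequency <- function(snvs, n_samples, bin = 100L) {
  stopifnot(n_samples >= 1L)
  key <- paste(snvs$chrom, snvs$pos, snvs$ref, snvs$alt, sep = ":")
  cnt <- table(key)
  u <- !duplicated(key)
  variants <- data.frame(chrom = snvs$chrom[u], pos = snvs$pos[u],
                         ref = snvs$ref[u], alt = snvs$alt[u],
                         count = as.integer(cnt[key[u]]),
                         stringsAsFactors = FALSE)
  variants$maf <- variants$count / n_samples
  variants$bin_start <- (variants$pos %/% bin) * bin
  bins <- aggregate(maf ~ chrom + bin_start, data = variants, FUN = mean)
  bins$n_variants <- aggregate(maf ~ chrom + bin_start, data = variants,
                               FUN = length)$maf
  list(variants = variants, bins = bins[order(bins$chrom, bins$bin_start), ])
}

#' Equal-count binned means with standard errors
#'
#' Bins `x` into `n_bins` quantile (equal-count) bins and reports the
#' mean and standard error of `y` per bin.
#'
#' @param x,y Paired finite numeric vectors.
#' @param n_bins Number of bins; must not exceed `length(x)`.
#' @return data.frame `bin`, `n`, `x_mean`, `y_mean`, `y_sem`.
#' @export
binned_means <- function(x, y, n_bins) {
  stopifnot(length(x) == length(y), all(is.finite(x)), all(is.finite(y)))
  if (n_bins > length(x)) stop("n_bins exceeds number of points")
  grp <- ceiling(rank(x, ties.method = "first") * n_bins / length(x))
  sem <- function(v) if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0
  data.frame(bin = seq_len(n_bins),
             n = as.integer(table(factor(grp, levels = seq_len(n_bins)))),
             x_mean = tapply(x, grp, mean),
             y_mean = tapply(y, grp, mean),
             y_sem = tapply(y, grp, sem),
             row.names = NULL)
}
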