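# 96-context mutation matrices, background-adjusted origin signatures,
# cosine clustering, non-negative exposure refitting, strand-resolved and
# local exposure profiles, consensus-context and WRCY analyses.

# contexts (5' base, 3' base) of SNV records on the plus strand; NA when
# out of range
.snv_flanks <- function(snvs, genome) {
  len <- genome$lengths[snvs$chrom]
  five <- rep(NA_character_, nrow(snvs))
  three <- rep(NA_character_, nrow(snvs))
  ok5 <- snvs$pos - 1L >= 0L
  ok3 <- snvs$pos + 2L <= len
  if (any(ok5)) five[ok5] <- get_seq(genome, snvs$chrom[ok5],
                                     snvs$pos[ok5] - 1L, snvs$pos[ok5])
  if (any(ok3)) three[ok3] <- get_seq(genome, snvs$chrom[ok3],
                                      snvs$pos[ok3] + 1L, snvs$pos[ok3] + 2L)
  data.frame(five = five, three = three, stringsAsFactors = FALSE)
}

#' Build the samples x 96-context mutation count matrix
#'
#' Each SNV (restricted to `regions` when given) contributes one count
#' to its pyrimidine-normalized trinucleotide context class. Records
#' whose context contains N (or lacks a flank at a chromosome end) are
#' dropped with a tally; reference mismatches raise an error.
#'
#' @param snvs An `snv_table`.
#' @param genome A `genome`.
#' @param regions Optional interval data.frame (`chrom`,`start`,`end`).
#' @return Integer matrix (samples x 96) with attribute `dropped`.
#' @export
build_context_matrix <- function(snvs, genome, regions = NULL) {
  if (!is.null(regions))
    snvs <- snvs[.in_regions(snvs$chrom, snvs$pos, regions), , drop = FALSE]
  gb <- if (nrow(snvs)) get_seq(genome, snvs$chrom, snvs$pos, snvs$pos + 1L) else character()
  bad <- which(gb != snvs$ref)
  if (length(bad))
    stop("reference mismatch for ", length(bad), " record(s): ",
         paste(utils::head(paste0(snvs$chrom[bad], ":", snvs$pos[bad]), 3), collapse = ", "))
  fl <- .snv_flanks(snvs, genome)
  lab <- rep(NA_character_, nrow(snvs))
  ok <- !is.na(fl$five) & !is.na(fl$three)
  lab[ok] <- context_label(snvs$ref[ok], snvs$alt[ok], fl$five[ok], fl$three[ok])
  keep <- !is.na(lab)
  samples <- sort(unique(snvs$sample_id))
  m <- table(factor(snvs$sample_id[keep], levels = samples),
             factor(lab[keep], levels = context_classes()))
  out <- matrix(as.integer(m), nrow = length(samples),
                dimnames = list(samples, context_classes()))
  attr(out, "dropped") <- sum(!keep)
  out
}

#' Pyrimidine-centred trinucleotide occurrences of regions
#'
#' Counts every overlapping trinucleotide in the (merged) regions, both
#' strands collapsed to the 32 pyrimidine-centred forms. Overlapping
#' input regions are merged first so no position is double-counted.
#'
#' @param genome A `genome`.
#' @param regions Interval data.frame (`chrom`,`start`,`end`).
#' @return Named numeric 32-vector in `trinuc_classes()` order.
#' @export
trinuc_occurrences <- function(genome, regions) {
  merged <- list()
  for (ch in unique(regions$chrom)) {
    r <- regions[regions$chrom == ch, , drop = FALSE]
    ir <- IRanges::reduce(IRanges::IRanges(r$start + 1L, r$end))
    merged[[ch]] <- data.frame(chrom = ch, start = IRanges::start(ir) - 1L,
                               end = IRanges::end(ir), stringsAsFactors = FALSE)
  }
  merged <- do.call(rbind, merged)
  merged <- .clip_intervals(merged, genome$lengths, "region")
  seqs <- get_seq(genome, merged$chrom, merged$start, merged$end)
  tri <- Biostrings::trinucleotideFrequency(Biostrings::DNAStringSet(seqs))
  collapse_trinucs(colSums(tri))
}

#' Background-adjusted origin signature
#'
#' Per context: origin-domain count divided by the domain occurrence of
#' its central trinucleotide, minus the same rate computed in the
#' flanks. With `floor = TRUE`, negative adjusted rates are set to zero
#' and the result renormalized into a probability signature.
#'
#' @param origin_counts,flank_counts Numeric 96-vectors of context counts.
#' @param origin_occ,flank_occ Numeric 32-vectors of trinucleotide
#'   occurrences (from [trinuc_occurrences()]).
#' @param floor Floor negatives and renormalize?
#' @return List of class `adjusted_signature`: `rates` (96, may be
#'   negative), `signature` (96 normalized weights or NULL when the
#'   floored vector is all zero, then `degenerate = TRUE`), and a
#'   `provenance` list sufficient to recompute.
#' @export
background_adjust <- function(origin_counts, flank_counts, origin_occ,
                              flank_occ, floor = TRUE) {
  stopifnot(length(origin_counts) == 96L, length(flank_counts) == 96L,
            length(origin_occ) == 32L, length(flank_occ) == 32L)
  oo <- expand_trinuc_occ(origin_occ)
  fo <- expand_trinuc_occ(flank_occ)
  if (any(origin_counts > 0 & oo == 0) || any(flank_counts > 0 & fo == 0))
    stop("nonzero context count with zero trinucleotide occurrence")
  orate <- ifelse(oo > 0, origin_counts / oo, 0)
  frate <- ifelse(fo > 0, flank_counts / fo, 0)
  rates <- setNames(orate - frate, context_classes())
  sig <- NULL; degenerate <- FALSE
  if (floor) {
    pos <- pmax(rates, 0)
    if (sum(pos) > 0) sig <- pos / sum(pos) else degenerate <- TRUE
  }
  structure(list(rates = rates, signature = sig, degenerate = degenerate,
                 floor = floor,
                 provenance = list(origin_counts = origin_counts,
                                   flank_counts = flank_counts,
                                   origin_occ = origin_occ,
                                   flank_occ = flank_occ)),
            class = "adjusted_signature")
}

#' Cosine similarity of two non-negative (or signed) vectors
#'
#' @param a,b Numeric vectors of equal length; zero vectors error.
#' @return Inner-product cosine.
#' @export
cosine_similarity <- function(a, b) {
  stopifnot(length(a) == length(b))
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine similarity undefined for zero vectors")
  sum(a * b) / (na * nb)
}

#' Per-sample background-adjusted signatures at origins
#'
#' Convenience wrapper: builds origin-domain and flank context matrices,
#' computes shared occurrence vectors, and returns the matrix of
#' adjusted rate vectors (one row per sample).
#'
#' @param snvs An `snv_table`.
#' @param genome A `genome`.
#' @param origins An `origin_set`.
#' @param floor Passed to [background_adjust()].
#' @return List: `rates` (samples x 96 adjusted rates), `signatures`
#'   (floored+normalized rows; NA rows where degenerate), `origin_counts`,
#'   `flank_counts`, occurrence vectors.
#' @export
origin_signatures <- function(snvs, genome, origins, floor = TRUE) {
  dom <- origin_domains(origins, genome$lengths)
  fla <- origin_flanks(origins, genome$lengths)
  mo <- build_context_matrix(snvs, genome, dom)
  mf <- build_context_matrix(snvs, genome, fla)
  samples <- sort(unique(c(rownames(mo), rownames(mf))))
  full <- function(m) {
    out <- matrix(0L, length(samples), 96L, dimnames = list(samples, context_classes()))
    out[rownames(m), ] <- m
    out
  }
  mo <- full(mo); mf <- full(mf)
  oo <- trinuc_occurrences(genome, dom)
  fo <- trinuc_occurrences(genome, fla)
  rates <- matrix(NA_real_, length(samples), 96L,
                  dimnames = list(samples, context_classes()))
  sigs <- rates
  for (i in seq_along(samples)) {
    adj <- background_adjust(mo[i, ], mf[i, ], oo, fo, floor = floor)
    rates[i, ] <- adj$rates
    if (!is.null(adj$signature)) sigs[i, ] <- adj$signature
  }
  list(rates = rates, signatures = sigs, origin_counts = mo, flank_counts = mf,
       origin_occ = oo, flank_occ = fo)
}

#' Cluster samples on cosine similarity of adjusted signatures
#'
#' Hierarchical agglomeration (average linkage) on distance
#' 1 - cosine; `k` picks the number of clusters.
#'
#' @param adjusted Numeric matrix, one row per sample (adjusted rates or
#'   signatures; rows must be non-zero).
#' @param k Number of clusters (<= rows).
#' @return List: `labels` (named integer vector), `hclust`, and
#'   `newick` (dendrogram serialization, when the ape package is
#'   available).
#' @export
cluster_samples <- function(adjusted, k) {
  n <- nrow(adjusted)
  if (is.null(n) || n < 2L) stop("need at least two rows to cluster")
  if (k > n) stop("k exceeds number of samples")
  cs <- matrix(1, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    cs[i, j] <- cs[j, i] <- cosine_similarity(adjusted[i, ], adjusted[j, ])
  }
  d <- stats::as.dist(1 - cs)
  hc <- stats::hclust(d, method = "average")
  labels <- stats::cutree(hc, k = k)
  names(labels) <- rownames(adjusted)
  newick <- NULL
  if (requireNamespace("ape", quietly = TRUE)) {
    hc2 <- hc; if (is.null(hc2$labels)) hc2$labels <- rownames(adjusted)
    newick <- ape::write.tree(ape::as.phylo(hc2))
  }
  list(labels = labels, hclust = hc, newick = newick)
}

#' Aggregate background-adjusted signature per cluster
#'
#' Pools origin-domain and flank mutation counts over the samples of
#' each cluster and background-adjusts the pooled counts.
#'
#' @param snvs An `snv_table`.
#' @param labels Named cluster labels covering the samples.
#' @param genome A `genome`.
#' @param origins An `origin_set`.
#' @return List per cluster of `adjusted_signature` objects; clusters
#'   with zero origin-domain mutations are flagged `degenerate`.
#' @export
aggregate_cluster_signature <- function(snvs, labels, genome, origins) {
  stopifnot(!is.null(names(labels)),
            all(unique(snvs$sample_id) %in% names(labels)))
  sigdat <- origin_signatures(snvs, genome, origins, floor = TRUE)
  out <- list()
  for (cl in sort(unique(labels))) {
    members <- names(labels)[labels == cl]
    members <- intersect(members, rownames(sigdat$origin_counts))
    oc <- colSums(sigdat$origin_counts[members, , drop = FALSE])
    fc <- colSums(sigdat$flank_counts[members, , drop = FALSE])
    out[[as.character(cl)]] <- background_adjust(
      oc, fc, sigdat$origin_occ, sigdat$flank_occ, floor = TRUE)
  }
  out
}

#' Fit non-negative signature exposures
#'
#' `mode = "plain"`: per-row non-negative least squares of the count
#' vector on the catalog. `mode = "strict"`: starting from the full
#' catalog, iteratively remove the signature whose removal least
#' degrades the reconstruction cosine, while the degradation stays
#' within `delta`; then refit on the survivors. Signatures whose fitted
#' contribution never reaches `min_contribution` in any row are zeroed.
#'
#' @param counts Numeric matrix (rows x 96), or a single 96-vector.
#' @param catalog Numeric matrix (96 x signatures), columns normalized.
#' @param mode `"plain"` or `"strict"`.
#' @param min_contribution Minimum fitted mutations for a signature to
#'   be retained anywhere (default 50; set 0 to disable).
#' @param delta Maximum tolerated reconstruction-cosine drop per
#'   removal in strict mode (default 0.004).
#' @return List of class `exposure_fit`: `exposures` (rows x
#'   signatures), `reconstruction_cosine` per row.
#' @export
fit_exposures <- function(counts, catalog, mode = c("plain", "strict"),
                          min_contribution = 50, delta = 0.004) {
  mode <- match.arg(mode)
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1L)
  stopifnot(ncol(counts) == nrow(catalog))
  if (any(counts < 0) || any(catalog < 0)) stop("negative inputs")
  nsig <- ncol(catalog)
  signames <- colnames(catalog)
  if (is.null(signames)) signames <- paste0("S", seq_len(nsig))
  nnls_fit <- function(A, b) {
    if (sum(b) == 0) return(numeric(ncol(A)))
    pracma::lsqnonneg(A, b)$x
  }
  expo <- matrix(0, nrow(counts), nsig, dimnames = list(rownames(counts), signames))
  rc <- rep(NA_real_, nrow(counts))
  for (i in seq_len(nrow(counts))) {
    b <- as.numeric(counts[i, ])
    active <- seq_len(nsig)
    x <- nnls_fit(catalog, b)
    if (mode == "strict" && sum(b) > 0) {
      cos_of <- function(idx) {
        xx <- nnls_fit(catalog[, idx, drop = FALSE], b)
        rec <- as.numeric(catalog[, idx, drop = FALSE] %*% xx)
        if (sum(rec^2) == 0) return(list(cos = 0, x = xx))
        list(cos = cosine_similarity(rec, b), x = xx)
      }
      cur <- cos_of(active)
      repeat {
        if (length(active) <= 1L) break
        trials <- lapply(seq_along(active), function(j) cos_of(active[-j]))
        coss <- vapply(trials, `[[`, numeric(1), "cos")
        best <- which.max(coss)
        if (cur$cos - coss[best] <= delta) {
          active <- active[-best]
          cur <- trials[[best]]
        } else break
      }
      x <- numeric(nsig)
      x[active] <- cur$x
    }
    expo[i, ] <- x
    rec <- as.numeric(catalog %*% x)
    rc[i] <- if (sum(rec^2) > 0 && sum(b^2) > 0) cosine_similarity(rec, b) else NA_real_
  }
  if (min_contribution > 0) {
    weak <- apply(expo, 2L, max) < min_contribution
    expo[, weak] <- 0
  }
  structure(list(exposures = expo, reconstruction_cosine = rc),
            class = "exposure_fit")
}

#' Flank-corrected local exposure profile across origin windows
#'
#' Pools mutations per offset window over all origins and samples,
#' fits exposures per window, then subtracts each signature's mean
#' flank-window exposure.
#'
#' @param snvs An `snv_table`.
#' @param genome A `genome`.
#' @param grid A `window_grid`.
#' @param catalog Catalog matrix (96 x signatures).
#' @param mode,min_contribution,delta Passed to [fit_exposures()];
#'   windows where a signature stays below `min_contribution` report 0
#'   for it before correction.
#' @return List: `offsets`, `exposure` (windows x signatures, raw),
#'   `corrected` (flank mean subtracted).
#' @export
local_exposure_profile <- function(snvs, genome, grid, catalog,
                                   mode = "plain", min_contribution = 50,
                                   delta = 0.004) {
  k <- length(grid$offsets)
  hits <- .grid_hits(snvs$chrom, snvs$pos, grid)
  rec <- snvs[hits$record, , drop = FALSE]
  fl <- .snv_flanks(rec, genome)
  ok <- !is.na(fl$five) & !is.na(fl$three)
  lab <- rep(NA_character_, nrow(rec))
  lab[ok] <- context_label(rec$ref[ok], rec$alt[ok], fl$five[ok], fl$three[ok])
  keep <- !is.na(lab)
  counts <- table(factor(hits$window[keep], levels = seq_len(k)),
                  factor(lab[keep], levels = context_classes()))
  counts <- matrix(as.numeric(counts), nrow = k,
                   dimnames = list(NULL, context_classes()))
  fit <- fit_exposures(counts, catalog, mode = mode,
                       min_contribution = min_contribution, delta = delta)
  flank <- .flank_offsets(grid)
  bg <- colMeans(fit$exposures[flank, , drop = FALSE])
  list(offsets = grid$offsets, exposure = fit$exposures,
       corrected = sweep(fit$exposures, 2L, bg, "-"))
}

#' Strand-resolved mutation counts across origin windows
#'
#' Assigns each pyrimidine-normalized mutation to the leading- or
#' lagging-strand template using the fork convention: for a rightward
#' fork (offset >= 0) the reference plus strand is the lagging-strand
#' template, mirrored for offset < 0. A mutation whose pyrimidine sits
#' on the plus strand therefore reports damage on the lagging template
#' right of the origin and on the leading template left of it.
#'
#' @param snvs An `snv_table`.
#' @param origins An `origin_set` (geometry source of `grid`).
#' @param genome A `genome` (unused beyond validation; kept for
#'   signature symmetry).
#' @param grid A `window_grid`.
#' @return data.frame `offset`, `leading`, `lagging` counts.
#' @export
strand_resolved_profile <- function(snvs, origins, genome, grid) {
  hits <- .grid_hits(snvs$chrom, snvs$pos, grid)
  rec <- snvs[hits$record, , drop = FALSE]
  norm <- pyrimidine_normalize(rec$ref, rec$alt)
  pyr_plus <- norm$pyr_strand == "+"
  right <- hits$offset_pos >= 0L          # offset 0 counted on the right side
  lagging <- pyr_plus == right            # plus-strand pyrimidine, rightward fork
  k <- length(grid$offsets)
  lead <- tabulate(hits$window[!lagging], nbins = k)
  lagg <- tabulate(hits$window[lagging], nbins = k)
  data.frame(offset = grid$offsets, leading = lead, lagging = lagg)
}

#' Position frequency matrix around mutated bases
#'
#' Base frequencies at offsets -halfwidth..+halfwidth around each
#' mutation, read on the pyrimidine-normalized strand (purine-reference
#' records contribute the reverse complement of their window). Windows
#' truncated by a chromosome end are dropped with a tally.
#'
#' @param snvs An `snv_table` subset.
#' @param genome A `genome`.
#' @param halfwidth Context half-width (bp), default 10.
#' @return 4 x (2*halfwidth+1) matrix (rows A,C,G,T; columns sum to 1)
#'   with attribute `dropped`.
#' @export
context_pfm <- function(snvs, genome, halfwidth = 10L) {
  if (!nrow(snvs)) stop("empty SNV subset")
  len <- genome$lengths[snvs$chrom]
  ok <- snvs$pos - halfwidth >= 0L & snvs$pos + halfwidth + 1L <= len
  sub <- snvs[ok, , drop = FALSE]
  seqs <- get_seq(genome, sub$chrom, sub$pos - halfwidth,
                  sub$pos + halfwidth + 1L)
  flip <- toupper(sub$ref) %in% c("A", "G")
  seqs[flip] <- revcomp(seqs[flip])
  w <- 2L * halfwidth + 1L
  m <- matrix(0, 4L, w, dimnames = list(BASES, as.character(-halfwidth:halfwidth)))
  chars <- matrix(unlist(strsplit(seqs, "", fixed = TRUE)), nrow = w)
  for (p in seq_len(w)) {
    tb <- table(factor(chars[p, ], levels = BASES))
    m[, p] <- as.numeric(tb)
  }
  tot <- colSums(m)
  m <- sweep(m, 2L, ifelse(tot > 0, tot, 1), "/")
  attr(m, "dropped") <- sum(!ok)
  m
}

.WRCY_PLUS <- "[AT][AG]C[CT]"   # C mutated at position 3 of the 4-mer
.WRCY_MINUS <- "[AG]G[CT][AT]"  # reverse complement; G at position 2

# WRCY membership of pyrimidine-normalized C records at given positions
.is_wrcy <- function(genome, chrom, pos, pyr_plus) {
  n <- length(pos)
  out <- logical(n)
  len <- genome$lengths[chrom]
  lo <- ifelse(pyr_plus, pos - 2L, pos - 1L)
  hi <- ifelse(pyr_plus, pos + 2L, pos + 3L)  # half-open [lo, hi)
  ok <- lo >= 0L & hi <= len
  if (any(ok)) {
    ctx <- get_seq(genome, chrom[ok], lo[ok], hi[ok])
    ctx[!pyr_plus[ok]] <- revcomp(ctx[!pyr_plus[ok]])
    out[ok] <- grepl(paste0("^", .WRCY_PLUS, "$"), ctx)
  }
  out
}

#' WRCY motif overlap across origin windows
#'
#' Per offset window: the fraction of C>T mutations whose context
#' matches the AID hotspot motif WRCY (W = A/T, R = A/G, C mutated,
#' Y = C/T; both strands), and the fraction of all C residues (either
#' strand) in the window sitting in a WRCY context.
#'
#' @param snvs An `snv_table`.
#' @param genome A `genome`.
#' @param grid A `window_grid`.
#' @return data.frame `offset`, `n_ct`, `mut_frac`, `c_total`, `c_frac`.
#' @export
wrcy_profile <- function(snvs, genome, grid) {
  k <- length(grid$offsets)
  hits <- .grid_hits(snvs$chrom, snvs$pos, grid)
  rec <- snvs[hits$record, , drop = FALSE]
  norm <- pyrimidine_normalize(rec$ref, rec$alt)
  ct <- norm$ref == "C" & norm$alt == "T"
  wrcy <- rep(FALSE, nrow(rec))
  if (any(ct))
    wrcy[ct] <- .is_wrcy(genome, rec$chrom[ct], rec$pos[ct],
                         norm$pyr_strand[ct] == "+")
  n_ct <- tabulate(hits$window[ct], nbins = k)
  n_wrcy <- tabulate(hits$window[ct & wrcy], nbins = k)

  # base composition: count C (plus) and G (minus-strand C) positions and
  # how many sit in WRCY context, per window, via regex scans
  gi <- grid_intervals(grid, genome$lengths)
  win <- (gi$offset + flank_halfwidth(grid$origins)) %/% grid$width + 1L
  c_tot <- numeric(k); c_wrcy <- numeric(k)
  seqs <- get_seq(genome, gi$chrom, gi$start, gi$end)
  nC <- Biostrings::letterFrequency(Biostrings::DNAStringSet(seqs), c("C", "G"))
  tot <- nC[, "C"] + nC[, "G"]
  count_pat <- function(s, pat) {
    m <- gregexpr(pat, s, perl = TRUE)[[1]]
    if (m[1] == -1L) 0L else length(m)
  }
  # overlapping WRCY matches are rare at these widths; use lookahead to
  # count every start position
  wp <- paste0("(?=", .WRCY_PLUS, ")")
  wm <- paste0("(?=", .WRCY_MINUS, ")")
  nw <- vapply(seqs, function(s) count_pat(s, wp) + count_pat(s, wm),
               integer(1), USE.NAMES = FALSE)
  for (w in seq_len(k)) {
    rows <- which(win == w)
    c_tot[w] <- sum(tot[rows]); c_wrcy[w] <- sum(nw[rows])
  }
  data.frame(offset = grid$offsets, n_ct = n_ct,
             mut_frac = ifelse(n_ct > 0, n_wrcy / n_ct, NA_real_),
             c_total = c_tot,
             c_frac = ifelse(c_tot > 0, c_wrcy / c_tot, NA_real_))
}

#' Read a COSMIC-style signature catalog TSV
#'
#' First column holds 96 context labels (`A[C>A]A` style); remaining
#' columns are signatures. Rows are reordered to the package context
#' order and columns normalized to sum 1.
#'
#' @param file Path.
#' @return Numeric matrix 96 x signatures.
#' @export
read_catalog <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE, check.names = FALSE)
  lab <- df[[1]]
  stopifnot(setequal(lab, context_classes()))
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- lab
  m <- m[context_classes(), , drop = FALSE]
  sweep(m, 2L, colSums(m), "/")
}
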