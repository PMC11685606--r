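# Expression-derived covariates: TPM, replicative-stress biomarker
# Z-scores, cyclin-based cell-cycle phase fractions, subtype labelling.

#' Transcripts per million from raw counts and exon lengths
#'
#' Per sample: `rate_g = count_g / length_g`;
#' `TPM_g = 1e6 * rate_g / sum(rate)`. All-zero samples are flagged and
#' reported as NA columns.
#'
#' @param counts Genes x samples non-negative count matrix.
#' @param exon_lengths Per-gene exon lengths (bp), positive, aligned to
#'   `rownames(counts)`.
#' @return List of class `expression_matrix`: `counts`, `tpm`,
#'   `exon_lengths`, `zero_samples` (names of flagged samples).
#' @export
tpm <- function(counts, exon_lengths) {
  stopifnot(nrow(counts) == length(exon_lengths), all(exon_lengths > 0),
            all(counts >= 0))
  rate <- counts / exon_lengths
  tot <- colSums(rate)
  zero <- tot == 0
  tpm_m <- sweep(rate, 2L, ifelse(zero, NA_real_, tot), "/") * 1e6
  structure(list(counts = counts, tpm = tpm_m, exon_lengths = exon_lengths,
                 zero_samples = colnames(counts)[zero]),
            class = "expression_matrix")
}

#' Biomarker Z-scores across samples
#'
#' Per panel gene: `(x - mean) / sd` over samples, population SD.
#' Zero-variance genes report all-zero rows, flagged.
#'
#' @param expr An `expression_matrix`.
#' @param panel Character vector of gene names (must be present).
#' @param use `"counts"` (the raw-count convention) or `"tpm"`.
#' @return Genes x samples Z matrix with attribute `flat_genes`.
#' @export
biomarker_zscores <- function(expr, panel, use = c("counts", "tpm")) {
  use <- match.arg(use)
  m <- if (use == "counts") expr$counts else expr$tpm
  missing <- setdiff(panel, rownames(m))
  if (length(missing))
    stop("panel genes absent: ", paste(missing, collapse = ", "))
  x <- m[panel, , drop = FALSE]
  mu <- rowMeans(x)
  pop_sd <- sqrt(rowMeans((x - mu)^2))
  flat <- pop_sd == 0
  z <- (x - mu) / ifelse(flat, 1, pop_sd)
  z[flat, ] <- 0
  attr(z, "flat_genes") <- rownames(x)[flat]
  z
}

#' Default cyclin class -> gene map
#'
#' Cyclin A: CCNA1/2; B: CCNB1/2; D: CCND1/2/3; E: CCNE1/2.
#'
#' @return Named list of gene vectors.
#' @export
cyclin_map <- function() {
  list(A = c("CCNA1", "CCNA2"), B = c("CCNB1", "CCNB2"),
       D = c("CCND1", "CCND2", "CCND3"), E = c("CCNE1", "CCNE2"))
}

#' Cell-cycle phase fractions from cyclin expression
#'
#' Class expression = sum of member TPMs. G1/S = E / (A+B+D+E);
#' S/G2 = A / total; G2/M = B / total. Fractions need not sum to 1
#' (cyclin D takes no phase of its own). Samples with zero total cyclin
#' expression are undefined (NA), flagged.
#'
#' @param expr An `expression_matrix`.
#' @param map Cyclin class map, default [cyclin_map()]; missing member
#'   genes contribute 0 but every class must have at least one present
#'   gene.
#' @return data.frame `sample_id`, `g1s`, `sg2`, `g2m` of class
#'   `phase_fractions`.
#' @export
cyclin_phase_fractions <- function(expr, map = cyclin_map()) {
  stopifnot(all(c("A", "B", "D", "E") %in% names(map)))
  m <- expr$tpm
  cls <- vapply(map, function(genes) {
    present <- intersect(genes, rownames(m))
    if (!length(present)) stop("no genes present for a cyclin class")
    colSums(m[present, , drop = FALSE])
  }, numeric(ncol(m)))
  if (is.null(dim(cls)))                       # single-sample edge case
    cls <- matrix(cls, nrow = 1L, dimnames = list(NULL, names(cls)))
  tot <- rowSums(cls)
  undef <- !is.finite(tot) | tot == 0
  safe <- ifelse(undef, NA_real_, tot)
  out <- data.frame(sample_id = colnames(m),
                    g1s = cls[, "E"] / safe,
                    sg2 = cls[, "A"] / safe,
                    g2m = cls[, "B"] / safe,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("phase_fractions", "data.frame")
  out
}

#' Label expression subtypes
#'
#' `mode = "embed+cluster"`: 2-component PCA embedding of log1p(TPM)
#' (standardized genes) followed by k-means with 20 random starts under
#' a fixed seed. `mode = "external"`: labels read verbatim from a
#' 2-column TSV (`sample_id`, `label`).
#'
#' @param expr An `expression_matrix`.
#' @param mode `"embed+cluster"` or `"external"`.
#' @param k Number of subtypes (embed+cluster mode), <= samples.
#' @param seed Seed for k-means restarts.
#' @param label_file Path for external mode.
#' @return Named character vector of per-sample labels.
#' @export
subtype_labels <- function(expr, mode = c("embed+cluster", "external"),
                           k = 3L, seed = 1L, label_file = NULL) {
  mode <- match.arg(mode)
  if (mode == "external") {
    df <- utils::read.delim(label_file, stringsAsFactors = FALSE)
    return(setNames(as.character(df$label), df$sample_id))
  }
  m <- expr$tpm
  n <- ncol(m)
  if (k > n) stop("k exceeds number of samples")
  if (n == 1L) return(setNames("1", colnames(m)))
  x <- t(log1p(m))
  keep <- apply(x, 2L, stats::sd) > 0
  x <- scale(x[, keep, drop = FALSE])
  emb <- stats::prcomp(x, rank. = 2L)$x
  set.seed(seed)
  km <- stats::kmeans(emb, centers = k, nstart = 20L)
  setNames(as.character(km$cluster), colnames(m))
}

#' Read expression counts and exon lengths
#'
#' Counts TSV: first column gene names, remaining columns samples.
#' Lengths TSV: columns `gene`, `length`.
#'
#' @param counts_file,lengths_file Paths.
#' @return An `expression_matrix` (via [tpm()]).
#' @export
read_expression <- function(counts_file, lengths_file) {
  cdf <- utils::read.delim(counts_file, stringsAsFactors = FALSE,
                           check.names = FALSE)
  m <- as.matrix(cdf[, -1, drop = FALSE])
  rownames(m) <- cdf[[1]]
  ldf <- utils::read.delim(lengths_file, stringsAsFactors = FALSE)
  len <- setNames(ldf$length, ldf$gene)[rownames(m)]
  tpm(m, len)
}
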