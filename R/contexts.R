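# Package-wide substitution / context conventions.
#
# Every SNV is expressed on the pyrimidine-containing strand (C or T
# reference); purine-reference records are reverse-complemented, flanking
# bases included. The 96 context classes are ordered substitution-major
# (C>A, C>G, C>T, T>A, T>C, T>G), then 5' base, then 3' base, each in
# A,C,G,T order -- the conventional COSMIC column order.

BASES <- c("A", "C", "G", "T")

SUBSTITUTIONS <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

.context_table <- local({
  grid <- expand.grid(three = BASES, five = BASES, sub = SUBSTITUTIONS,
                      stringsAsFactors = FALSE)
  grid <- grid[order(match(grid$sub, SUBSTITUTIONS),
                     match(grid$five, BASES),
                     match(grid$three, BASES)), ]
  ref <- substr(grid$sub, 1, 1)
  data.frame(
    label  = paste0(grid$five, "[", grid$sub, "]", grid$three),
    sub    = grid$sub,
    five   = grid$five,
    three  = grid$three,
    ref    = ref,
    trinuc = paste0(grid$five, ref, grid$three),
    stringsAsFactors = FALSE
  )
})

#' The 96 trinucleotide mutation context classes, in package order
#'
#' Substitution-major (C>A, C>G, C>T, T>A, T>C, T>G), then 5' and 3'
#' flanking base each in A,C,G,T order, e.g. `"A[C>A]A"`.
#'
#' @return Character vector of length 96.
#' @export
context_classes <- function() .context_table$label

#' The 32 pyrimidine-centred trinucleotides, in package order
#'
#' @return Character vector of length 32 (16 NCN then 16 NTN).
#' @export
trinuc_classes <- function() unique(.context_table$trinuc)

# index of each context's pyrimidine-centred trinucleotide into
# trinuc_classes()
.context_trinuc_idx <- match(.context_table$trinuc, unique(.context_table$trinuc))

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Complement / reverse-complement of base vectors and sequences
#'
#' `complement_base()` complements a vector of single bases;
#' `revcomp()` reverse-complements a character vector of sequences.
#' Both accept only A, C, G, T, N (case-insensitive, upper-cased).
#'
#' @param x Character vector.
#' @return Character vector of the same length.
#' @export
complement_base <- function(x) {
  out <- .COMPLEMENT[toupper(x)]
  if (anyNA(out)) stop("non-ACGTN base in input")
  unname(out)
}

#' @rdname complement_base
#' @export
revcomp <- function(x) {
  x <- toupper(x)
  if (any(grepl("[^ACGTN]", x))) stop("non-ACGTN base in input")
  vapply(x, function(s) {
    chartr("ACGTN", "TGCAN",
           paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

#' Pyrimidine-normalize substitution records
#'
#' Records whose reference base is a purine (A or G) are expressed on the
#' opposite strand: ref and alt are complemented and the flanking context
#' is reverse-complemented. The strand carrying the pyrimidine is
#' reported so downstream fork-strand logic can recover orientation.
#'
#' @param ref,alt Single-base character vectors.
#' @param five,three Optional 5'/3' flanking base vectors (plus strand).
#' @return A data.frame with columns `ref`, `alt`, `five`, `three` (if
#'   flanks given) and `pyr_strand` (`"+"` if the pyrimidine is on the
#'   input strand, `"-"` if the record was flipped).
#' @export
pyrimidine_normalize <- function(ref, alt, five = NULL, three = NULL) {
  ref <- toupper(ref); alt <- toupper(alt)
  flip <- ref %in% c("A", "G")
  out <- data.frame(ref = ref, alt = alt, pyr_strand = ifelse(flip, "-", "+"),
                    stringsAsFactors = FALSE)
  out$ref[flip] <- complement_base(ref[flip])
  out$alt[flip] <- complement_base(alt[flip])
  if (!is.null(five)) {
    five <- toupper(five); three <- toupper(three)
    out$five <- five; out$three <- three
    # flipping swaps the flanks and complements them
    out$five[flip] <- complement_base(three[flip])
    out$three[flip] <- complement_base(five[flip])
  }
  out
}

#' Map substitution records to 96-context class labels
#'
#' @param ref,alt Reference and alternate bases (any strand).
#' @param five,three Flanking bases on the same strand as `ref`.
#' @return Character vector of context labels; `NA` where the context
#'   contains an N or the substitution is invalid (ref == alt).
#' @export
context_label <- function(ref, alt, five, three) {
  norm <- pyrimidine_normalize(ref, alt, five, three)
  lab <- paste0(norm$five, "[", norm$ref, ">", norm$alt, "]", norm$three)
  lab[!(lab %in% .context_table$label)] <- NA_character_
  lab
}

#' Collapse a 64-trinucleotide count vector to pyrimidine-centred form
#'
#' @param counts64 Named numeric vector of counts over all 64 trinucleotides
#'   (names like "ACA"); purine-centred entries are folded onto their
#'   reverse complements.
#' @return Named numeric 32-vector in `trinuc_classes()` order.
#' @export
collapse_trinucs <- function(counts64) {
  tri32 <- trinuc_classes()
  out <- stats::setNames(numeric(32), tri32)
  nm <- names(counts64)
  centre <- substr(nm, 2, 2)
  key <- ifelse(centre %in% c("C", "T"), nm, revcomp(nm))
  keep <- key %in% tri32             # drops N-containing trinucs
  agg <- tapply(counts64[keep], key[keep], sum)
  out[names(agg)] <- agg
  out
}

#' Expand a 32-trinucleotide vector over the 96 context classes
#'
#' Each context class inherits the value of its central trinucleotide
#' (used to turn occurrence vectors into per-context denominators).
#'
#' @param occ32 Numeric 32-vector in `trinuc_classes()` order.
#' @return Named numeric 96-vector in `context_classes()` order.
#' @export
expand_trinuc_occ <- function(occ32) {
  stopifnot(length(occ32) == 32L)
  stats::setNames(as.numeric(occ32)[.context_trinuc_idx], context_classes())
}
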