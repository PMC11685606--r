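test_that("context matrices classify records on the pyrimidine strand", {
  gen <- genome(c(chr1 = "AAACGTTT"))
  # C at position 3 with context ACG -> A[C>T]G
  m <- build_context_matrix(snv_table("S1", "chr1", 3L, "C", "T"), gen)
  expect_equal(sum(m), 1L)
  expect_equal(unname(m["S1", "A[C>T]G"]), 1L)
  # the G at position 4 has plus-context CGT; a G>A there is the
  # reverse-complement twin A[C>T]G
  m2 <- build_context_matrix(snv_table("S1", "chr1", 4L, "G", "A"), gen)
  expect_equal(unname(m2["S1", "A[C>T]G"]), 1L)
  # reference mismatch errors
  expect_error(build_context_matrix(snv_table("S1", "chr1", 3L, "T", "A"), gen),
               "mismatch")
})

test_that("context matrix equals a per-record loop oracle", {
  geo <- make_toy_geometry(seed = 101, chrom_length = 100000L)
  set.seed(102)
  pos <- sample(2:99997, 10000)
  ref <- get_seq(geo$genome, "chr1", pos, pos + 1L)
  alt <- vapply(ref, function(r) sample(setdiff(c("A","C","G","T"), r), 1), "")
  snvs <- snv_table(sample(c("S1", "S2"), 10000, TRUE), "chr1", pos, ref,
                    unname(alt))
  m <- build_context_matrix(snvs, geo$genome)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  oracle <- matrix(0L, 2, 96, dimnames = list(c("S1", "S2"), context_classes()))
  for (i in seq_len(nrow(snvs))) {
    tri <- strsplit(get_seq(geo$genome, "chr1", snvs$pos[i] - 1L,
                            snvs$pos[i] + 2L), "")[[1]]
    r <- snvs$ref[i]; a <- snvs$alt[i]; five <- tri[1]; three <- tri[3]
    if (r %in% c("A", "G")) {
      r <- comp[r]; a <- comp[a]
      tmp <- comp[five]; five <- comp[three]; three <- tmp
    }
    lab <- paste0(five, "[", r, ">", a, "]", three)
    oracle[snvs$sample_id[i], lab] <- oracle[snvs$sample_id[i], lab] + 1L
  }
  expect_equal(m, oracle, ignore_attr = TRUE)
  # conservation: row sums equal classifiable record counts
  expect_equal(rowSums(m),
               c(S1 = sum(snvs$sample_id == "S1"),
                 S2 = sum(snvs$sample_id == "S2")) - c(0, 0),
               ignore_attr = TRUE)
})

test_that("trinucleotide occurrences collapse strands and merge regions", {
  gen <- genome(c(chr1 = "ACGT"))
  occ <- trinuc_occurrences(gen, data.frame(chrom = "chr1", start = 0L, end = 4L))
  # ACG (centre C) and CGT (centre G -> revcomp ACG): {ACG: 2}
  expect_equal(unname(occ["ACG"]), 2)
  expect_equal(sum(occ), 2)

  # poly-A reads as pyrimidine-centred TTT on the minus strand
  polyA <- genome(c(chr1 = strrep("A", 50)))
  occA <- trinuc_occurrences(polyA,
                             data.frame(chrom = "chr1", start = 0L, end = 50L))
  expect_equal(unname(occA["TTT"]), 48)
  expect_equal(sum(occA), 48)

  # overlapping regions are merged: counting twice would double
  g2 <- genome(c(chr1 = random_seq(10000, seed = 103)))
  r1 <- data.frame(chrom = "chr1", start = c(0L, 500L), end = c(1000L, 1500L))
  r2 <- data.frame(chrom = "chr1", start = 0L, end = 1500L)
  expect_equal(trinuc_occurrences(g2, r1), trinuc_occurrences(g2, r2))

  # random region equals a sliding-window oracle
  s <- get_seq(g2, "chr1", 2000, 3000)
  ch <- strsplit(s, "")[[1]]
  tris <- paste0(ch[1:998], ch[2:999], ch[3:1000])
  comp_rc <- function(x) revcomp(x)
  key <- ifelse(substr(tris, 2, 2) %in% c("C", "T"), tris, comp_rc(tris))
  oracle <- table(factor(key, levels = trinuc_classes()))
  got <- trinuc_occurrences(g2, data.frame(chrom = "chr1", start = 2000L,
                                           end = 3000L))
  expect_equal(as.numeric(got), as.numeric(oracle))
})

test_that("background adjustment subtracts occurrence-normalized flank rates", {
  oc <- setNames(numeric(96), context_classes()); oc["A[C>T]G"] <- 10
  fc <- setNames(numeric(96), context_classes()); fc["A[C>T]G"] <- 2
  occ <- setNames(rep(100, 32), trinuc_classes())
  adj <- background_adjust(oc, fc, occ, occ)
  expect_equal(unname(adj$rates["A[C>T]G"]), 10 / 100 - 2 / 100)
  expect_equal(unname(adj$signature["A[C>T]G"]), 1)
  expect_equal(sum(adj$signature), 1)

  # self-subtraction identity and degenerate flag
  adj0 <- background_adjust(oc, oc, occ, occ)
  expect_true(all(adj0$rates == 0))
  expect_true(adj0$degenerate)
  expect_null(adj0$signature)

  # inconsistent inputs: count without occurrence
  occ0 <- occ; occ0[] <- 0
  expect_error(background_adjust(oc, fc, occ0, occ0), "zero trinucleotide")
})

test_that("cosine similarity matches its definition", {
  a <- c(1, 0, 2); b <- c(0, 3, 0)
  expect_equal(cosine_similarity(a, a), 1)
  expect_equal(cosine_similarity(a, b), 0)
  set.seed(104)
  for (i in 1:20) {
    x <- runif(96); y <- runif(96)
    expect_equal(cosine_similarity(x, y),
                 sum(x * y) / sqrt(sum(x^2) * sum(y^2)), tolerance = 1e-12)
  }
  expect_error(cosine_similarity(rep(0, 3), a), "zero")
})

test_that("cosine clustering separates orthogonal signatures", {
  s1 <- c(rep(1, 48), rep(0, 48)); s2 <- c(rep(0, 48), rep(1, 48))
  m <- rbind(A1 = s1, A2 = s1 * 2, B1 = s2, B2 = s2 * 3)
  cl <- cluster_samples(m, k = 2)
  expect_equal(length(unique(cl$labels[c("A1", "A2")])), 1L)
  expect_equal(length(unique(cl$labels[c("B1", "B2")])), 1L)
  expect_false(cl$labels[["A1"]] == cl$labels[["B1"]])
  expect_equal(length(unique(cluster_samples(m, k = 4)$labels)), 4L)
  expect_error(cluster_samples(m, k = 5), "exceeds")
  expect_type(cl$newick, "character")
})

test_that("cluster aggregation pools counts before adjustment", {
  geo <- make_toy_geometry(seed = 105, n_origins = 8L, chrom_length = 400000L)
  set.seed(106)
  pos <- sample.int(400000L, 4000L) - 1L
  ref <- get_seq(geo$genome, "chr1", pos, pos + 1L)
  alt <- vapply(ref, function(r) sample(setdiff(c("A","C","G","T"), r), 1), "")
  snvs <- snv_table("S1", "chr1", pos, ref, unname(alt))
  # a second sample identical to the first
  snvs2 <- rbind(snvs, transform(snvs, sample_id = "S2"))
  class(snvs2) <- class(snvs)

  one <- aggregate_cluster_signature(snvs, c(S1 = 1L), geo$genome, geo$origins)
  per <- origin_signatures(snvs, geo$genome, geo$origins)
  expect_equal(one[["1"]]$rates, per$rates["S1", ])

  both <- aggregate_cluster_signature(snvs2, c(S1 = 1L, S2 = 1L),
                                      geo$genome, geo$origins)
  # pooling two identical samples leaves the signature unchanged
  expect_equal(both[["1"]]$signature, one[["1"]]$signature)
})

test_that("exposure fitting recovers noiseless mixtures exactly", {
  catalog <- cbind(S1 = c(rep(1 / 48, 48), rep(0, 48)),
                   S2 = c(rep(0, 48), rep(1 / 48, 48)))
  counts <- 1000 * (0.7 * catalog[, 1] + 0.3 * catalog[, 2])
  fit <- fit_exposures(counts, catalog, min_contribution = 0)
  expect_lt(max(abs(fit$exposures[1, ] - c(700, 300))), 1e-6)
  expect_gt(fit$reconstruction_cosine[1], 1 - 1e-12)

  # identity basis returns the counts themselves
  idb <- diag(96)
  cnt <- rpois(96, 5)
  fit2 <- fit_exposures(cnt, idb, min_contribution = 0)
  expect_equal(unname(fit2$exposures[1, ]), as.numeric(cnt))
})

test_that("exposure fit agrees with an independent constrained solver", {
  skip_if_not_installed("glmnet")
  set.seed(107)
  catalog <- matrix(runif(96 * 4), 96)
  catalog <- sweep(catalog, 2, colSums(catalog), "/")
  colnames(catalog) <- paste0("S", 1:4)
  y <- as.numeric(catalog %*% c(300, 0, 150, 0)) + abs(rnorm(96, sd = 2))
  fit <- fit_exposures(y, catalog, min_contribution = 0)
  g <- glmnet::glmnet(catalog, y, lambda = 0, lower.limits = 0,
                      intercept = FALSE, standardize = FALSE, thresh = 1e-12)
  expect_lt(max(abs(fit$exposures[1, ] - as.numeric(g$beta))), 0.5)
})

test_that("plain-mode residuals never grow when the catalog grows", {
  set.seed(108)
  catalog <- matrix(runif(96 * 5), 96)
  catalog <- sweep(catalog, 2, colSums(catalog), "/")
  colnames(catalog) <- paste0("S", 1:5)
  y <- rpois(96, 10)
  rss <- function(k) {
    f <- fit_exposures(y, catalog[, 1:k, drop = FALSE], min_contribution = 0)
    sum((y - as.numeric(catalog[, 1:k, drop = FALSE] %*% f$exposures[1, ]))^2)
  }
  r <- vapply(1:5, rss, numeric(1))
  expect_true(all(diff(r) <= 1e-8))
})

test_that("strict mode prunes inactive catalog signatures", {
  catalog <- toy_catalog()
  set.seed(109)
  mu <- 3000 * (0.5 * catalog[, "SBS_uv"] + 0.5 * catalog[, "SBS_g4"])
  ok <- 0L
  for (r in 1:10) {
    fit <- fit_exposures(rpois(96, mu), catalog, mode = "strict")
    act <- colnames(catalog)[fit$exposures[1, ] > 0]
    if (setequal(act, c("SBS_uv", "SBS_g4"))) ok <- ok + 1L
  }
  expect_gte(ok, 9L)
})

test_that("local exposure profiles peak only for origin-focal processes", {
  geo <- make_toy_geometry(seed = 110, n_origins = 8L, chrom_length = 400000L)
  catalog <- toy_catalog()
  grid <- tile_windows(geo$origins, 2000L)
  set.seed(111)
  # flat background everywhere + UV-like process confined to domains
  flatpos <- sample.int(400000L, 6000L) - 1L
  fref <- get_seq(geo$genome, "chr1", flatpos, flatpos + 1L)
  falt <- vapply(fref, function(r) sample(setdiff(c("A","C","G","T"), r), 1), "")
  dom_c <- integer(0)
  for (m in geo$origins$midpoint) {
    w <- (m - 450L):(m + 450L)
    b <- get_seq(geo$genome, "chr1", w, w + 1L)
    nxt <- get_seq(geo$genome, "chr1", w + 1L, w + 2L)
    dom_c <- c(dom_c, w[b == "C" & nxt %in% c("C", "T")])
  }
  uvpos <- sample(dom_c, 3000, replace = TRUE)
  uvpos <- uvpos[!duplicated(uvpos)]
  snvs <- snv_table("S1", "chr1", c(flatpos, uvpos),
                    c(fref, rep("C", length(uvpos))),
                    c(unname(falt), rep("T", length(uvpos))))
  snvs <- snvs[!duplicated(paste(snvs$chrom, snvs$pos)), , drop = FALSE]
  prof <- local_exposure_profile(snvs, geo$genome, grid, catalog,
                                 min_contribution = 10)
  uv <- prof$corrected[, "SBS_uv"]
  centre <- abs(grid$offsets + 1000L) <= 1000L
  expect_gt(mean(uv[centre]), 10 * max(0.1, abs(mean(uv[!centre]))))
  # the G4 signature, never planted, shows no centre excess
  g4 <- prof$corrected[, "SBS_g4"]
  expect_lt(mean(g4[centre]), mean(uv[centre]) / 10)
})

test_that("fork-strand assignment follows the side-of-origin convention", {
  geo <- make_toy_geometry(seed = 112, n_origins = 4L, chrom_length = 200000L)
  grid <- tile_windows(geo$origins, 100L)
  mid <- geo$origins$midpoint[1]
  # a plus-strand pyrimidine right of the midpoint -> lagging template
  p <- mid + 2000L
  while (!get_seq(geo$genome, "chr1", p, p + 1L) %in% c("C", "T")) p <- p + 1L
  ref <- get_seq(geo$genome, "chr1", p, p + 1L)
  right <- strand_resolved_profile(
    snv_table("S1", "chr1", p, ref, ifelse(ref == "C", "A", "G")),
    geo$origins, geo$genome, grid)
  expect_equal(sum(right$lagging), 1L)
  expect_equal(sum(right$leading), 0L)
  # mirrored left of the midpoint -> leading template
  q <- mid - 2000L
  while (!get_seq(geo$genome, "chr1", q, q + 1L) %in% c("C", "T")) q <- q + 1L
  refq <- get_seq(geo$genome, "chr1", q, q + 1L)
  left <- strand_resolved_profile(
    snv_table("S1", "chr1", q, refq, ifelse(refq == "C", "A", "G")),
    geo$origins, geo$genome, grid)
  expect_equal(sum(left$leading), 1L)

  # strand-symmetric mutations balance within 3 SE
  set.seed(113)
  pos <- sample.int(200000L, 8000L) - 1L
  r <- get_seq(geo$genome, "chr1", pos, pos + 1L)
  a <- vapply(r, function(x) sample(setdiff(c("A","C","G","T"), x), 1), "")
  sym <- strand_resolved_profile(snv_table("S1", "chr1", pos, r, unname(a)),
                                 geo$origins, geo$genome, grid)
  n_lead <- sum(sym$leading); n_lagg <- sum(sym$lagging)
  expect_lt(abs(n_lead - n_lagg), 3 * sqrt(n_lead + n_lagg))
})

test_that("context PFMs read the pyrimidine-normalized strand", {
  gen <- genome(c(chr1 = strrep("ACGTT", 100)))
  # identical contexts -> one-hot columns
  pos <- seq(6L, 480L, by = 5L)   # every C at the same phase
  pos <- pos[get_seq(gen, "chr1", pos, pos + 1L) == "C"]
  expect_gt(length(pos), 50L)
  pfm <- context_pfm(snv_table("S1", "chr1", pos, "C", "T"), gen, halfwidth = 2L)
  expect_true(all(apply(pfm, 2, max) == 1))
  expect_equal(colSums(pfm), rep(1, 5), ignore_attr = TRUE)

  # uniform random genome -> all frequencies near 0.25
  g2 <- genome(c(chr1 = random_seq(50000, seed = 114)))
  p2 <- sample(20:49979, 2000)
  r2 <- get_seq(g2, "chr1", p2, p2 + 1L)
  a2 <- vapply(r2, function(x) sample(setdiff(c("A","C","G","T"), x), 1), "")
  pfm2 <- context_pfm(snv_table("S1", "chr1", p2, r2, unname(a2)), g2, 10L)
  off_centre <- setdiff(colnames(pfm2), "0")
  expect_true(all(abs(pfm2[, off_centre] - 0.25) < 0.06))
})

test_that("WRCY profiles flag AID-motif C>T mutations", {
  # context AGCC: A=W, G=R, C mutated, C=Y -> match
  gen <- genome(c(chr1 = paste0(strrep("T", 20), "AGCC", strrep("T", 20),
                                "GGCC", strrep("T", 20))))
  o <- origin_set("chr1", 30L, 38L, domain_halfwidth = 10L,
                  flank_halfwidth = 30L)
  grid <- tile_windows(o, 10L)
  hit <- snv_table("S1", "chr1", 22L, "C", "T")     # inside AGCC
  miss <- snv_table("S1", "chr1", 46L, "C", "T")    # inside GGCC (G not W)
  wp_hit <- wrcy_profile(hit, gen, grid)
  wp_miss <- wrcy_profile(miss, gen, grid)
  expect_equal(sum(wp_hit$n_ct), 1L)
  expect_equal(wp_hit$mut_frac[!is.na(wp_hit$mut_frac)], 1)
  expect_equal(wp_miss$mut_frac[!is.na(wp_miss$mut_frac)], 0)
})

test_that("catalog files round-trip through the fixed context order", {
  catalog <- toy_catalog()
  expect_equal(dim(catalog), c(96L, 5L))
  expect_equal(rownames(catalog), context_classes())
  expect_equal(unname(colSums(catalog)), rep(1, 5), tolerance = 1e-6)
})
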