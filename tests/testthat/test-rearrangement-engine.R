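test_that("SV classification follows the orientation truth table", {
  mk <- function(o1, o2, c2 = "chr1", p2 = 5000L, ins = NA_character_)
    data.frame(sample_id = "S1", chrom1 = "chr1", pos1 = 1000L, orient1 = o1,
               chrom2 = c2, pos2 = p2, orient2 = o2, inserted = ins,
               stringsAsFactors = FALSE)
  expect_equal(classify_sv(mk("tail", "head"))$sv_type, "DEL")
  expect_equal(classify_sv(mk("tail", "head"))$length, 4000L)
  expect_equal(classify_sv(mk("head", "tail"))$sv_type, "DUP")
  expect_equal(classify_sv(mk("head", "head"))$sv_type, "INV")
  expect_equal(classify_sv(mk("tail", "tail"))$sv_type, "INV")
  expect_equal(classify_sv(mk("tail", "head", c2 = "chr2"))$sv_type, "ITX")
  expect_true(is.na(classify_sv(mk("tail", "head", c2 = "chr2"))$length))
  ins <- classify_sv(mk("tail", "head", p2 = 1000L, ins = "ACGT"))
  expect_equal(ins$sv_type, "INS")
  # break-end order is normalised: swapped DEL still reads DEL
  swapped <- mk("head", "tail"); swapped$pos1 <- 5000L; swapped$pos2 <- 1000L
  expect_equal(classify_sv(swapped)$sv_type, "DEL")
  # missing orientation drops the record with a tally
  bad <- mk(NA, "head")
  out <- classify_sv(bad)
  expect_equal(nrow(out), 0L)
  expect_equal(attr(out, "dropped"), 1L)
})

test_that("SV signatures bin types by length with upper-closed edges", {
  mk <- function(type, len) {
    o <- switch(type, DEL = c("tail", "head"), DUP = c("head", "tail"),
                INV = c("head", "head"))
    data.frame(sample_id = "S1", chrom1 = "chr1", pos1 = 1000L, orient1 = o[1],
               chrom2 = "chr1", pos2 = 1000L + len, orient2 = o[2],
               stringsAsFactors = FALSE)
  }
  sig <- sv_signature(classify_sv(mk("DUP", 450L)))
  expect_equal(unname(sig["DUP:0.1-0.5kb"]), 1)
  expect_equal(sum(sig), 1)

  itx <- classify_sv(data.frame(sample_id = "S1", chrom1 = "chr1",
                                pos1 = 10L, orient1 = "head", chrom2 = "chr2",
                                pos2 = 20L, orient2 = "head"))
  expect_equal(unname(sv_signature(itx)["ITX"]), 1)

  # printed bin edges land in the lower bin (lower-open/upper-closed)
  edges <- c(100, 500, 1000, 5000, 10000, 1e5, 1e6)
  labs <- c("0-0.1kb", "0.1-0.5kb", "0.5-1kb", "1-5kb", "5-10kb",
            "10-100kb", "0.1-1Mb")
  for (i in seq_along(edges)) {
    s <- sv_signature(classify_sv(mk("DEL", edges[i])))
    expect_equal(unname(s[paste0("DEL:", labs[i])]), 1)
    s2 <- sv_signature(classify_sv(mk("DEL", edges[i] + 1L)))
    expect_equal(unname(s2[paste0("DEL:", labs[i])]), 0)
  }
  big <- sv_signature(classify_sv(mk("DEL", 2e6)))
  expect_equal(unname(big["DEL:>1Mb"]), 1)

  # counts conserve records
  set.seed(401)
  types <- sample(c("DEL", "DUP", "INV"), 50, TRUE)
  lens <- round(10^runif(50, 1, 6.5))
  svs <- classify_sv(do.call(rbind, Map(mk, types, lens)))
  s <- sv_signature(svs)
  expect_equal(sum(attr(s, "counts")), 50L)
})

test_that("break-end fold profiles normalise by flank density", {
  geo <- make_toy_geometry(seed = 402, n_origins = 6L)
  grid <- tile_windows(geo$origins, 100L)
  # all break ends at midpoints -> spike in the offset-0 window
  svs <- classify_sv(data.frame(
    sample_id = "S1", chrom1 = "chr1", pos1 = geo$origins$midpoint,
    orient1 = "tail", chrom2 = "chr1", pos2 = geo$origins$midpoint + 150000L,
    orient2 = "head", stringsAsFactors = FALSE))
  expect_warning(prof <- breakend_profile(svs, grid), "zero flank")
  expect_equal(which.max(prof$count), which(prof$offset == 0L))

  # uniform break ends -> fold close to 1 everywhere it is defined
  set.seed(403)
  p1 <- sample.int(190000L, 4000L)
  svs2 <- classify_sv(data.frame(
    sample_id = "S1", chrom1 = "chr1", pos1 = p1, orient1 = "tail",
    chrom2 = "chr1", pos2 = p1 + 5L, orient2 = "head",
    stringsAsFactors = FALSE))
  prof2 <- breakend_profile(svs2, grid)
  expect_lt(abs(mean(prof2$fold, na.rm = TRUE) - 1), 0.1)
})

test_that("break ends near G4 starts are oriented and tallied", {
  core <- "GGGTGGGTGGGTGGG"
  gen <- genome(c(chr1 = paste0(strrep("A", 50), core, strrep("A", 50))))
  motifs <- find_g4_motifs(gen)
  bend_at <- function(p) classify_sv(data.frame(
    sample_id = "S1", chrom1 = "chr1", pos1 = p, orient1 = "head",
    chrom2 = "chr1", pos2 = p + 30L, orient2 = "tail",
    stringsAsFactors = FALSE))
  hit <- breakends_near_g4(bend_at(motifs$core_start[1]), motifs, gen,
                           span = 20L, tol = 5L)
  expect_equal(hit$profile$count[hit$profile$offset == 0L] >= 1L, TRUE)
  expect_gte(hit$within_tol, 1L)
  # 7 bp upstream: in the profile but outside the +/-5 summary
  far <- breakends_near_g4(bend_at(motifs$core_start[1] - 7L), motifs[1, ],
                           gen, span = 20L, tol = 5L)
  expect_equal(far$within_tol, 0L)
  expect_equal(sum(far$profile$count), 1L)
})

test_that("CNV classes combine LOH, copy-number and length bins", {
  seg <- cnv_segments("S1", "chr1", 0L, 2.5e6, 4L, "Het")
  sig <- cnv_signature(seg)
  expect_equal(unname(sig["Het:3-4:2-3Mb"]), 1)
  expect_equal(seg$cnv_kind, "gain")

  seg2 <- cnv_segments("S1", "chr1", 0L, 5e4, 0L, "LOH")
  expect_equal(unname(cnv_signature(seg2)["LOH:0:0-0.1Mb"]), 1)
  expect_equal(seg2$cnv_kind, "loss")

  expect_error(cnv_segments("S1", "chr1", 0L, 100L, -1L, "Het"), "negative")

  # boundary lengths 1 / 2 / 5 Mb land in the lower (upper-closed) bin
  lens <- c(1e6, 2e6, 5e6)
  labs <- c("0.1-1Mb", "1-2Mb", "3-5Mb")
  for (i in seq_along(lens)) {
    s <- cnv_signature(cnv_segments("S1", "chr1", 0L, lens[i], 2L, "Het"))
    expect_equal(unname(s[paste0("Het:2:", labs[i])]), 1)
  }
  # CN class edges: 2 vs 3, 4 vs 5, 8 vs 9
  for (cn in c(2L, 3L, 4L, 5L, 8L, 9L)) {
    cls <- c(`2` = "2", `3` = "3-4", `4` = "3-4", `5` = "5-8", `8` = "5-8",
             `9` = "9+")[[as.character(cn)]]
    s <- cnv_signature(cnv_segments("S1", "chr1", 0L, 5e5, cn, "LOH"))
    expect_equal(unname(s[paste0("LOH:", cls, ":0.1-1Mb")]), 1)
  }
})

test_that("origin coverage tracks count midpoints per bin", {
  o <- origin_set("chr1", c(10000L, 20000L, 30000L, 450000L),
                  c(10100L, 20100L, 30100L, 450100L))
  tr <- origin_coverage_track(o, c(chr1 = 5e5), bin = 100000L)
  expect_equal(tr$values$chr1, c(3L, 0L, 0L, 0L, 1L))
  expect_equal(sum(unlist(tr$values)), nrow(o))
  empty <- origin_coverage_track(o[0, ], c(chr1 = 5e5))
  expect_true(all(unlist(empty$values) == 0L))
})

test_that("segment enrichment rescales segments to fixed windows", {
  lens <- c(chr1 = 10e6)
  # uniform origins: excess near zero everywhere
  set.seed(404)
  mids <- sort(sample.int(10e6 - 20000L, 400L)) + 10000L
  o <- origin_set("chr1", mids - 50L, mids + 50L)
  tr <- origin_coverage_track(o, lens, bin = 100000L)
  seg <- cnv_segments(rep("S1", 10), "chr1",
                      seq(2.2e6, 6.4e6, length.out = 10),
                      seq(2.2e6, 6.4e6, length.out = 10) + 1.2e6, 3L, "Het")
  enr <- segment_origin_enrichment(seg, tr, n_win = 20L)
  expect_lt(max(abs(enr$excess)), 3 * sd(unlist(tr$values)) /
              sqrt(enr$n_segments) * 3 + 0.5)

  # origins concentrated at segment boundaries peak at windows 1 and n
  o2 <- origin_set("chr1", c(3.05e6, 4.45e6) - 50L, c(3.05e6, 4.45e6) + 50L)
  tr2 <- origin_coverage_track(o2, lens, bin = 100000L)
  seg2 <- cnv_segments("S1", "chr1", 3e6, 4.5e6, 3L, "Het")
  enr2 <- segment_origin_enrichment(seg2, tr2, n_win = 15L)
  inner <- enr2$segment_mean[2:14]
  expect_gt(enr2$segment_mean[1], max(inner))
  expect_gt(enr2$segment_mean[15], max(inner))
  # length filter
  expect_error(segment_origin_enrichment(
    cnv_segments("S1", "chr1", 0L, 5e4, 3L, "Het"), tr), "length")
})

test_that("permutation p-values use the plus-one estimator", {
  lens <- c(chr1 = 1e6)
  # targets cover 1% of the genome; breakpoints all inside targets
  tgt <- data.frame(chrom = "chr1", start = seq(0L, 9e5, by = 1e5),
                    end = seq(0L, 9e5, by = 1e5) + 1000L)
  bp <- data.frame(chrom = "chr1", start = seq(100L, 900L, by = 100L) +
                     rep(seq(0L, 9e5, by = 1e5), each = 1)[1:9],
                   end = NA)
  bp <- data.frame(chrom = "chr1",
                   start = seq(0L, 8e5, by = 1e5) + 500L)
  bp$end <- bp$start + 1L
  pt <- boundary_permutation_test(bp, tgt, lens, n_perm = 999L, seed = 405)
  expect_equal(pt$observed, 9L)
  expect_equal(pt$p_value, 1 / 1000)

  # whole-genome target: every placement overlaps -> p = 1
  all_t <- data.frame(chrom = "chr1", start = 0L, end = 1e6)
  pt2 <- boundary_permutation_test(bp, all_t, lens, n_perm = 99L, seed = 406)
  expect_equal(pt2$p_value, 1)
  expect_error(boundary_permutation_test(bp, all_t[0, ], lens), "empty")
})

test_that("SV and CNV TSV readers round-trip the writers", {
  sim <- simulate_genome(sim_config(seed = 407, n_chrom = 2,
                                    chrom_length = 5e5, n_origins = 10))
  svc <- simulate_sv_cnv(sim, n_sv = 40L, n_cnv = 30L, seed = 408)
  d <- tempfile(); dir.create(d)
  write_sim_inputs(sim, d, svcnv = svc)
  svs <- read_sv_tsv(file.path(d, "sv.tsv"))
  expect_equal(svs$sv_type, svc$svs$sv_type)
  cnvs <- read_cnv_tsv(file.path(d, "cnv.tsv"))
  expect_equal(cnvs$total_cn, svc$cnvs$total_cn)
  expect_equal(cnvs$cnv_kind, svc$cnvs$cnv_kind)
})
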