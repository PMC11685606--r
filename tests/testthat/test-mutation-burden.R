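test_that("cohort filters apply total and region thresholds", {
  set.seed(4)
  n <- c(A = 4999L, B = 5000L, C = 200L)
  snvs <- snv_table(rep(names(n), n), "chr1",
                    sample.int(1e6, sum(n)) - 1L, "C", "T")
  kept <- filter_cohort(snvs, min_total = 5000L)
  expect_setequal(unique(kept$sample_id), "B")
  expect_equal(nrow(filter_cohort(snvs, min_total = 0L)), nrow(snvs))

  # random cohort vs per-sample count oracle, with a region constraint
  region <- data.frame(chrom = "chr1", start = 0L, end = 1e5)
  got <- filter_cohort(snvs, min_total = 1000L, region = region,
                       min_region = 450L)
  tab <- table(snvs$sample_id)
  reg <- table(snvs$sample_id[snvs$pos < 1e5])
  want <- names(tab)[tab >= 1000 &
                     sapply(names(tab), function(s)
                       isTRUE(reg[s] >= 450) && !is.na(reg[s]))]
  expect_setequal(unique(got$sample_id), want)
})

test_that("density profiles count mutations per offset window", {
  geo <- make_toy_geometry(seed = 2)
  grid <- tile_windows(geo$origins, 100L)

  # all mutations exactly at midpoints -> only the offset-0 window loaded
  ref <- get_seq(geo$genome, geo$origins$chrom, geo$origins$midpoint,
                 geo$origins$midpoint + 1L)
  alt <- ifelse(ref == "A", "C", "A")
  at_mid <- snv_table("S1", geo$origins$chrom, geo$origins$midpoint, ref, alt)
  prof <- density_profile(at_mid, grid)
  expect_equal(prof$count[prof$offset == 0L], nrow(geo$origins))
  expect_equal(sum(prof$count[prof$offset != 0L]), 0L)

  # 20 mutations in one 100-bp window across 10 origins -> 0.02 /bp
  set.seed(8)
  geo10 <- make_toy_geometry(seed = 9, n_origins = 10L, chrom_length = 500000L)
  grid10 <- tile_windows(geo10$origins, 100L)
  host <- rep(seq_len(10L), length.out = 20L)
  pos <- geo10$origins$midpoint[host] + 300L + sample.int(100L, 20L, TRUE) - 1L
  ref <- get_seq(geo10$genome, "chr1", pos, pos + 1L)
  m <- snv_table(paste0("S", seq_len(20L)), "chr1", pos, ref,
                 ifelse(ref == "A", "G", "A"))
  p10 <- density_profile(m, grid10)
  expect_equal(p10$density[p10$offset == 300L], 20 / (100 * 10))

  # conservation: sum of counts equals mutations assigned to the grid
  set.seed(10)
  upos <- sample.int(200000L, 3000L) - 1L
  uref <- get_seq(geo$genome, "chr1", upos, upos + 1L)
  u <- snv_table("S1", "chr1", upos, uref, ifelse(uref == "T", "A", "T"))
  pu <- density_profile(u, grid)
  hits <- 0L
  for (i in seq_len(nrow(geo$origins)))
    hits <- hits + sum(abs(upos - geo$origins$midpoint[i]) < 10000L |
                       upos - geo$origins$midpoint[i] == -10000L)
  expect_equal(sum(pu$count), hits)

  # uniform mutations -> flat profile: essentially all windows within
  # 3 binomial SE of the global rate (a few 3-sigma excursions are
  # expected among 200 windows)
  rate <- mean(pu$density)
  se <- sqrt(rate * (1 - rate) / (100 * nrow(geo$origins)))
  expect_lte(sum(abs(pu$density - rate) >= 3 * se), 3L)
})

test_that("burden ratios are density ratios with safe zero handling", {
  geo <- make_toy_geometry(seed = 21, n_origins = 10L, chrom_length = 500000L)
  o <- geo$origins
  # 20 mutations in the 10 kb of domains, 19 in the 190 kb of flanks
  dpos <- rep(o$midpoint[1:10], 2)[1:20] + rep(c(-100L, 200L), 10)
  fpos <- o$midpoint[1:10][c(1:10, 1:9)] + 5000L + seq(0, 180, by = 10)[1:19]
  pos <- c(dpos, fpos)
  ref <- get_seq(geo$genome, "chr1", pos, pos + 1L)
  snvs <- snv_table("S1", "chr1", pos, ref, ifelse(ref == "C", "G", "C"))
  br <- burden_ratio(snvs, o)
  expect_equal(br$origin_count, 20L)
  expect_equal(br$flank_count, 19L)
  expect_equal(br$ratio, (20 / 10000) / (19 / 190000))

  # identical densities scale out: doubling every count keeps the ratio
  snvs2 <- rbind(snvs, transform(snvs, sample_id = "S1b"))
  snvs2$sample_id <- "S1"
  br2 <- burden_ratio(snvs2, o)
  expect_equal(br2$ratio, br$ratio)

  # zero flank mutations -> NA, not an error
  p <- o$midpoint[1] + 10L
  r <- get_seq(geo$genome, "chr1", p, p + 1L)
  only_dom <- snv_table("S3", "chr1", p, r, ifelse(r == "A", "C", "A"))
  br3 <- burden_ratio(only_dom, o)
  expect_true(is.na(br3$ratio))
})

test_that("burden ratio of homogeneous mutations concentrates at 1", {
  geo <- make_toy_geometry(seed = 31, n_origins = 8L, chrom_length = 400000L)
  set.seed(32)
  rows <- lapply(1:30, function(s) {
    pos <- sample.int(400000L, 2000L) - 1L
    data.frame(sample_id = sprintf("P%02d", s), pos = pos)
  })
  df <- do.call(rbind, rows)
  ref <- get_seq(geo$genome, "chr1", df$pos, df$pos + 1L)
  snvs <- snv_table(df$sample_id, "chr1", df$pos, ref,
                    ifelse(ref == "A", "T", "A"))
  br <- burden_ratio(snvs, geo$origins)
  mu <- mean(br$ratio, na.rm = TRUE)
  se <- sd(br$ratio, na.rm = TRUE) / sqrt(sum(!is.na(br$ratio)))
  expect_lt(abs(mu - 1), 3 * se + 0.15)
})

test_that("corrected rates normalize by reference-base occurrences", {
  # construct a genome whose first origin domain window is all A/T
  set.seed(41)
  base <- strsplit(random_seq(100000), "")[[1]]
  mid <- 50000L
  win <- (mid + 300):(mid + 399)              # offset +300 window
  atat <- sample(c("A", "T"), 100, TRUE)
  atat[1:50] <- "T"; atat[51:100] <- "A"      # exactly 50 T occurrences
  base[win + 1L] <- atat
  gen <- genome(c(chr1 = paste(base, collapse = "")))
  o <- origin_set("chr1", mid - 150L, mid + 150L)
  grid <- tile_windows(o, 100L)
  tpos <- mid + 300L + which(atat == "T")[1:2] - 1L
  snvs <- snv_table("S1", "chr1", tpos, "T", "G")
  rp <- corrected_rates(snvs, gen, grid, context = "base")
  w <- which(grid$offsets == 300L)
  # denominator collapses strands: 50 plus-strand Ts + 50 As (minus-strand
  # Ts) = 100 T opportunities
  expect_equal(unname(rp$raw[w, "T>G"]), 2 / 100)
  # corrected = raw - flank background
  expect_equal(unname(rp$corrected[w, "T>G"]),
               unname(rp$raw[w, "T>G"]) - rp$background[["T>G"]])
})

test_that("flat mutation processes give near-zero corrected rates", {
  geo <- make_toy_geometry(seed = 51, n_origins = 8L, chrom_length = 400000L)
  set.seed(52)
  pos <- sample.int(400000L, 20000L) - 1L
  ref <- get_seq(geo$genome, "chr1", pos, pos + 1L)
  alt <- vapply(ref, function(r) sample(setdiff(c("A","C","G","T"), r), 1), "")
  snvs <- snv_table("S1", "chr1", pos, ref, unname(alt))
  rp <- corrected_rates(snvs, geo$genome, tile_windows(geo$origins, 2000L))
  # pooled across classes, corrected rates hover around zero
  for (cl in colnames(rp$corrected)) {
    v <- rp$corrected[, cl]
    expect_lt(abs(mean(v, na.rm = TRUE)), 3 * sd(v, na.rm = TRUE) /
                sqrt(sum(!is.na(v))) + 1e-6)
  }
})

test_that("strand of reporting does not change the context class", {
  # a G>A record with plus-strand context CGT is the twin of A[C>T]G
  expect_equal(context_label("G", "A", "C", "T"), "A[C>T]G")
  expect_equal(context_label("C", "T", "A", "G"), "A[C>T]G")
  # all purine records map into the pyrimidine class set
  set.seed(61)
  ref <- sample(c("A", "G"), 200, TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(c("A","C","G","T"), r), 1), "")
  lab <- context_label(ref, unname(alt), sample(c("A","C","G","T"), 200, TRUE),
                       sample(c("A","C","G","T"), 200, TRUE))
  expect_true(all(lab %in% context_classes()))
})

test_that("CpG partition follows the pyrimidine-strand next base", {
  gen <- genome(c(chr1 = "AACGTACATG"))
  #                         0123456789 ; C at 2 followed by G -> CpG
  cpg <- snv_table("S1", "chr1", 2L, "C", "T")
  non <- snv_table("S1", "chr1", 7L, "A", "G")  # A at 7, not C>T
  p1 <- cpg_partition(cpg, gen)
  expect_equal(nrow(p1$cpg), 1L)
  # C at position 6 followed by A -> non-CpG
  p2 <- cpg_partition(snv_table("S1", "chr1", 6L, "C", "T"), gen)
  expect_equal(nrow(p2$non_cpg), 1L)
  # minus-strand record: G at 3 preceded by C on plus = CpG on pyr strand
  p3 <- cpg_partition(snv_table("S1", "chr1", 3L, "G", "A"), gen)
  expect_equal(nrow(p3$cpg), 1L)

  # random genome: partition sizes match a regex-scan oracle
  g2 <- genome(c(chr1 = random_seq(20000, seed = 62)))
  cpos <- which(strsplit(g2$seq[["chr1"]], "")[[1]] == "C") - 1L
  cpos <- cpos[cpos < 19999]
  snvs <- snv_table("S1", "chr1", cpos, "C", "T")
  part <- cpg_partition(snvs, g2)
  oracle_cpg <- length(gregexpr("(?=CG)", g2$seq[["chr1"]], perl = TRUE)[[1]])
  expect_equal(nrow(part$cpg), oracle_cpg)
  expect_equal(nrow(part$cpg) + nrow(part$non_cpg), length(cpos))
})

test_that("minor allele frequencies divide recurrence by cohort size", {
  snvs <- snv_table(c("A", "B", "C", "D"), "chr1", c(10L, 10L, 10L, 55L),
                    "C", "T")
  maf <- minor_allele_frequency(snvs, n_samples = 100L)
  expect_equal(maf$variants$maf[maf$variants$pos == 10L], 3 / 100)
  expect_equal(maf$variants$maf[maf$variants$pos == 55L], 1 / 100)
  expect_equal(maf$variants$bin_start, c(0L, 0L))
  # all variants private -> MAF 1/n everywhere
  priv <- snv_table(c("A", "B"), "chr1", c(1L, 2L), "C", "T")
  expect_true(all(minor_allele_frequency(priv, 50L)$variants$maf == 1 / 50))
})

test_that("binned means use equal-count bins and honest SEMs", {
  x <- seq_len(100)
  b <- binned_means(x, x, 4L)
  expect_equal(b$n, rep(25L, 4))
  expect_true(all(diff(b$y_mean) > 0))
  bc <- binned_means(x, rep(2, 100), 5L)
  expect_true(all(bc$y_sem == 0))
  expect_error(binned_means(1:3, 1:3, 10L), "exceeds")
  # monotone association: bin means track the trend
  set.seed(71)
  xs <- rnorm(400); ys <- xs + rnorm(400, sd = 0.5)
  bm <- binned_means(xs, ys, 10L)
  expect_gt(cor(bm$x_mean, bm$y_mean, method = "spearman"), 0.9)
})
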