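# Seeded generators producing every input the pipeline consumes, with
# planted effects recorded in a truth object so every analysis stage has
# parameter-recovery tests without any external data.
#
# One global seed fans out to fixed per-component child seeds so a
# partial re-run of one component reproduces its output exactly.

.child_seed <- function(seed, k) (as.integer(seed) + 97L * k) %% 2147483L + 7L

#' Simulation configuration
#'
#' Defaults define the package's reference study conditions: a
#' 2 x 5 Mb genome at GC 0.40 with 100 well-spaced origins, half of
#' them carrying a planted quadruplex in their 1-kb domain.
#'
#' @param seed Global integer seed; fully determines all outputs.
#' @param n_chrom,chrom_length,gc Genome shape.
#' @param n_origins,min_spacing Origin placement (rejection sampling
#'   honouring `min_spacing`).
#' @param origin_width Width of emitted origin intervals (bp).
#' @param fraction_with_g4 Fraction of origin domains receiving a
#'   planted G4 core (4 x GGG tracts, loops 1-7 nt).
#' @param decoys_per_origin Expected decoy G4 cores planted per origin
#'   flank region.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_chrom = 2L, chrom_length = 5e6,
                       gc = 0.40, n_origins = 100L, min_spacing = 25000L,
                       origin_width = 300L, fraction_with_g4 = 0.5,
                       decoys_per_origin = 0.3) {
  structure(list(seed = as.integer(seed), n_chrom = as.integer(n_chrom),
                 chrom_length = as.integer(chrom_length), gc = gc,
                 n_origins = as.integer(n_origins),
                 min_spacing = as.integer(min_spacing),
                 origin_width = as.integer(origin_width),
                 fraction_with_g4 = fraction_with_g4,
                 decoys_per_origin = decoys_per_origin),
            class = "sim_config")
}

# sample a random G4 core: 4 GGG tracts, loops 1-7 nt over {A,C,T}
# starting with T (guarantees an eligible T at the first tract's 3' edge)
.random_g4_core <- function() {
  loops <- replicate(3L, {
    len <- sample(1:7, 1L)
    paste(c("T", sample(c("A", "C", "T"), len - 1L, replace = TRUE)),
          collapse = "")
  })
  paste0("GGG", loops[1], "GGG", loops[2], "GGG", loops[3], "GGG")
}

#' Simulate a genome with planted origins and G4 motifs
#'
#' Bases are i.i.d. at the configured GC; origin midpoints are placed
#' by rejection sampling honouring `min_spacing` (error when the
#' chromosome capacity cannot hold them). G4 cores are written into a
#' configured fraction of origin domains (on a random strand, with a T
#' immediately 5' of the core) and, as decoys, into origin flanks.
#'
#' @param config A [sim_config()].
#' @return List: `genome`, `origins` (an `origin_set`), `g4_truth`
#'   (data.frame `chrom`, `core_start`, `core_length`, `strand`,
#'   `at_origin`, `origin`).
#' @export
simulate_genome <- function(config) {
  set.seed(.child_seed(config$seed, 1L))
  usable <- config$chrom_length - 2L * 10000L
  if (config$n_origins * config$min_spacing >
      as.numeric(config$n_chrom) * usable)
    stop("origin capacity violated: n_origins * min_spacing exceeds genome")
  p <- c((1 - config$gc) / 2, config$gc / 2, config$gc / 2, (1 - config$gc) / 2)
  seqs <- setNames(vector("character", config$n_chrom),
                   paste0("chr", seq_len(config$n_chrom)))
  for (i in seq_len(config$n_chrom))
    seqs[i] <- paste(sample(BASES, config$chrom_length, replace = TRUE, prob = p),
                     collapse = "")
  # origin midpoints, roughly balanced across chromosomes
  per <- diff(round(seq(0, config$n_origins, length.out = config$n_chrom + 1L)))
  mids <- list()
  for (i in seq_len(config$n_chrom)) {
    got <- integer(0)
    tries <- 0L
    while (length(got) < per[i]) {
      tries <- tries + 1L
      if (tries > 200L * per[i]) stop("origin placement failed (capacity)")
      cand <- sample.int(usable, 1L) + 10000L
      if (!length(got) || all(abs(got - cand) >= config$min_spacing))
        got <- c(got, cand)
    }
    mids[[i]] <- sort(got)
  }
  ow <- config$origin_width
  origins <- origin_set(
    chrom = rep(names(seqs), lengths(mids)),
    start = unlist(mids) - ow %/% 2L,
    end = unlist(mids) + (ow - ow %/% 2L))

  plant <- function(ch, core_start, strand) {
    core <- .random_g4_core()
    ins <- paste0("T", core)                 # T immediately 5' of the core
    if (strand == "-") ins <- revcomp(ins)
    s <- seqs[[ch]]
    lo <- core_start - (if (strand == "+") 1L else 0L)
    substr(s, lo + 1L, lo + nchar(ins)) <- ins
    seqs[[ch]] <<- s
    nchar(core)
  }
  g4 <- list()
  with_g4 <- which(runif(nrow(origins)) < config$fraction_with_g4)
  for (j in with_g4) {
    strand <- sample(c("+", "-"), 1L)
    off <- sample(seq.int(-350L, 300L), 1L)
    cs <- origins$midpoint[j] + off
    core_len <- plant(origins$chrom[j], cs, strand)
    g4[[length(g4) + 1L]] <- data.frame(
      chrom = origins$chrom[j],
      core_start = if (strand == "+") cs else cs + core_len - 1L,
      core_plus_start = cs, core_length = core_len, strand = strand,
      at_origin = TRUE, origin = j, stringsAsFactors = FALSE)
  }
  n_decoy <- stats::rpois(1L, config$decoys_per_origin * nrow(origins))
  for (d in seq_len(n_decoy)) {
    j <- sample.int(nrow(origins), 1L)
    strand <- sample(c("+", "-"), 1L)
    side <- sample(c(-1L, 1L), 1L)
    off <- side * sample(seq.int(2000L, 8000L), 1L)
    cs <- origins$midpoint[j] + off
    core_len <- plant(origins$chrom[j], cs, strand)
    g4[[length(g4) + 1L]] <- data.frame(
      chrom = origins$chrom[j],
      core_start = if (strand == "+") cs else cs + core_len - 1L,
      core_plus_start = cs, core_length = core_len, strand = strand,
      at_origin = FALSE, origin = j, stringsAsFactors = FALSE)
  }
  g4_truth <- if (length(g4)) do.call(rbind, g4) else
    data.frame(chrom = character(), core_start = integer(),
               core_plus_start = integer(), core_length = integer(),
               strand = character(), at_origin = logical(), origin = integer())
  structure(list(genome = genome(seqs), origins = origins, g4_truth = g4_truth),
            seed = config$seed)
}

# signed offset to the nearest origin midpoint on the same chromosome
.origin_offset <- function(chrom, pos, origins) {
  off <- rep(NA_integer_, length(pos))
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    m <- sort(origins$midpoint[origins$chrom == ch])
    if (!length(m)) next
    idx <- findInterval(pos[i], m)
    lo <- pmax(idx, 1L); hi <- pmin(idx + 1L, length(m))
    nearest <- ifelse(abs(pos[i] - m[lo]) <= abs(m[hi] - pos[i]), m[lo], m[hi])
    off[i] <- pos[i] - nearest
  }
  off
}

# enumerate eligible sites (0-based positions of the mutated pyrimidine,
# expressed as plus-strand ref/alt records) for the site-based processes
.process_sites <- function(process, sim, params) {
  gen <- sim$genome; origins <- sim$origins
  scan <- function(pat, offset_in_match) {
    rows <- list()
    for (ch in names(gen$seq)) {
      m <- gregexpr(pat, gen$seq[[ch]], perl = TRUE)[[1]]
      if (m[1] == -1L) next
      rows[[ch]] <- data.frame(chrom = ch,
                               pos = as.integer(m) - 1L + offset_in_match,
                               stringsAsFactors = FALSE)
    }
    if (length(rows)) do.call(rbind, rows) else
      data.frame(chrom = character(), pos = integer())
  }
  if (process == "aid_wrcy") {
    plus <- scan(paste0("(?=", .WRCY_PLUS, ")"), 2L)   # C at position 3
    minus <- scan(paste0("(?=", .WRCY_MINUS, ")"), 1L) # G at position 2
    plus$ref <- "C"; plus$alt <- "T"; plus$pyr_strand <- "+"
    minus$ref <- "G"; minus$alt <- "A"; minus$pyr_strand <- "-"
    sites <- rbind(plus, minus)
  } else if (process == "uv_ner_deficit") {
    p1 <- scan("(?=[CT]C)", 1L); p2 <- scan("(?=C[CT])", 0L)
    plus <- unique(rbind(p1, p2))
    m1 <- scan("(?=G[AG])", 0L); m2 <- scan("(?=[AG]G)", 1L)
    minus <- unique(rbind(m1, m2))
    plus$ref <- "C"; plus$alt <- "T"; plus$pyr_strand <- "+"
    minus$ref <- "G"; minus$alt <- "A"; minus$pyr_strand <- "-"
    sites <- rbind(plus, minus)
  } else if (process == "g4_tg") {
    tg <- sim$g4_truth[sim$g4_truth$at_origin, , drop = FALSE]
    if (!nrow(tg)) stop("process g4_tg: no planted origin G4s")
    rows <- list()
    for (i in seq_len(nrow(tg))) {
      ch <- tg$chrom[i]
      # first G-tract on the motif strand occupies core_start ..
      # core_start +/- 2 (tract length 3); eligible positions are within
      # 2 nt of either tract edge
      dirn <- if (tg$strand[i] == "+") 1L else -1L
      edges <- c(tg$core_start[i], tg$core_start[i] + dirn * 2L)
      cand <- unique(as.vector(outer(edges, -2:2 * dirn, "+")))
      cand <- cand[cand >= 0L & cand < gen$lengths[[ch]]]
      base <- get_seq(gen, rep(ch, length(cand)), cand, cand + 1L)
      want <- if (tg$strand[i] == "+") "T" else "A"
      cand <- cand[base == want]
      if (length(cand))
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = ch, pos = cand,
          ref = want, alt = if (want == "T") "G" else "C",
          pyr_strand = tg$strand[i], stringsAsFactors = FALSE)
    }
    if (!length(rows)) stop("process g4_tg: no eligible T sites")
    sites <- do.call(rbind, rows)
  } else stop("unknown site process: ", process)

  off <- .origin_offset(sites$chrom, sites$pos, origins)
  dhw <- domain_halfwidth(origins)
  in_dom <- !is.na(off) & abs(off) <= dhw
  w <- ifelse(in_dom, params$origin_fold, 1)
  sb <- params$strand_bias %||% 0
  if (sb != 0) {
    fhw <- flank_halfwidth(origins)
    near <- !is.na(off) & abs(off) <= fhw
    lag <- near & ((sites$pyr_strand == "+") == (off >= 0L))
    w[lag] <- w[lag] * (1 + sb)
  }
  sites$weight <- w
  sites$in_domain <- in_dom
  sites
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# expected 96-spectra of a site table: count space (weighted context
# distribution of in-domain sites) and rate space (divided by domain
# trinucleotide occurrences)
.site_spectrum <- function(sites, sim) {
  gen <- sim$genome
  dom <- origin_domains(sim$origins, gen$lengths)
  sub <- sites[sites$in_domain, , drop = FALSE]
  fl <- .snv_flanks(sub, gen)
  lab <- context_label(sub$ref, sub$alt, fl$five, fl$three)
  ok <- !is.na(lab)
  counts <- tapply(sub$weight[ok], factor(lab[ok], levels = context_classes()), sum)
  counts[is.na(counts)] <- 0
  counts <- setNames(as.numeric(counts), context_classes())
  occ <- expand_trinuc_occ(trinuc_occurrences(gen, dom))
  rate <- ifelse(occ > 0, counts / occ, 0)
  list(count_spectrum = counts / max(sum(counts), 1),
       rate_spectrum = if (sum(rate) > 0) rate / sum(rate) else rate)
}

#' Simulate a multi-sample SNV cohort with planted processes
#'
#' Each sample draws `Poisson(burden)` mutations from its cluster's
#' process mixture. The `flat` process is uniform over non-N positions
#' (alt uniform over the three other bases); `aid_wrcy` draws C>T at
#' WRCY-motif cytosines; `uv_ner_deficit` draws C>T at dipyrimidine
#' cytosines with an optional lagging-strand bias; `g4_tg` draws T>G
#' within 2 nt of the first G-tract edges of planted origin G4s. Site
#' processes multiply in-domain site weights by `origin_fold`.
#' Positions are unique per sample (collisions resampled).
#'
#' @param sim Output of [simulate_genome()].
#' @param clusters List of cluster specs: each
#'   `list(n_samples, burden, mixture = c(process = weight, ...),
#'   origin_fold, strand_bias)`.
#' @param seed Integer seed (defaults to the genome config seed + 2).
#' @return List: `snvs` (an `snv_table`), `truth` (cluster labels,
#'   per-process spectra in count and rate space, domain/flank site
#'   mass, geometry constants).
#' @export
simulate_snv_cohort <- function(sim, clusters, seed = NULL) {
  set.seed(if (is.null(seed)) .child_seed(attr(sim, "seed") %||% 1L, 2L)
           else as.integer(seed))
  gen <- sim$genome; origins <- sim$origins
  glen <- sum(gen$lengths)
  chrom_p <- gen$lengths / glen

  procs <- unique(unlist(lapply(clusters, function(cl) names(cl$mixture))))
  site_tabs <- list(); spectra <- list(); mass <- list()
  dom <- origin_domains(origins, gen$lengths)
  fla <- origin_flanks(origins, gen$lengths)
  dom_bp <- sum(dom$end - dom$start); fla_bp <- sum(fla$end - fla$start)
  for (pr in setdiff(procs, "flat")) {
    # per-process parameters are shared across clusters that use it;
    # take them from the first cluster mentioning the process
    params <- NULL
    for (cl in clusters) if (pr %in% names(cl$mixture)) {
      params <- list(origin_fold = cl$origin_fold %||% 1,
                     strand_bias = cl$strand_bias %||% 0)
      break
    }
    st <- .process_sites(pr, sim, params)
    site_tabs[[pr]] <- st
    spectra[[pr]] <- .site_spectrum(st, sim)
    in_fla <- .in_regions(st$chrom, st$pos, fla)
    mass[[pr]] <- list(domain = sum(st$weight[st$in_domain]),
                       flank = sum(st$weight[in_fla]),
                       total = sum(st$weight))
  }
  if ("flat" %in% procs)
    mass[["flat"]] <- list(domain = dom_bp, flank = fla_bp, total = glen)

  draw_flat <- function(n) {
    ch <- sample(names(gen$seq), n, replace = TRUE, prob = chrom_p)
    pos <- floor(runif(n) * gen$lengths[ch])
    ref <- get_seq(gen, ch, pos, pos + 1L)
    redo <- ref == "N"
    while (any(redo)) {
      pos[redo] <- floor(runif(sum(redo)) * gen$lengths[ch[redo]])
      ref[redo] <- get_seq(gen, ch[redo], pos[redo], pos[redo] + 1L)
      redo <- ref == "N"
    }
    alt <- vapply(ref, function(r) sample(setdiff(BASES, r), 1L), character(1))
    data.frame(chrom = ch, pos = as.integer(pos), ref = ref,
               alt = unname(alt), stringsAsFactors = FALSE)
  }
  draw_sites <- function(pr, n) {
    st <- site_tabs[[pr]]
    idx <- sample.int(nrow(st), n, replace = TRUE, prob = st$weight)
    st[idx, c("chrom", "pos", "ref", "alt"), drop = FALSE]
  }

  all_rows <- list()
  labels <- character(0)
  sample_i <- 0L
  for (ci in seq_along(clusters)) {
    cl <- clusters[[ci]]
    mix <- cl$mixture / sum(cl$mixture)
    for (s in seq_len(cl$n_samples)) {
      sample_i <- sample_i + 1L
      sid <- sprintf("S%03d", sample_i)
      labels[sid] <- as.character(ci)
      n <- stats::rpois(1L, cl$burden)
      if (n == 0L) next
      n_per <- stats::rmultinom(1L, n, mix)[, 1L]
      parts <- list()
      for (pr in names(mix)) {
        if (n_per[pr] == 0L) next
        parts[[pr]] <- if (pr == "flat") draw_flat(n_per[pr])
                       else draw_sites(pr, n_per[pr])
      }
      df <- do.call(rbind, parts)
      # unique positions per sample: resample collisions from the flat draw
      key <- paste(df$chrom, df$pos)
      tries <- 0L
      while (anyDuplicated(key) && tries < 50L) {
        dup <- duplicated(key)
        df[dup, ] <- draw_flat(sum(dup))
        key <- paste(df$chrom, df$pos)
        tries <- tries + 1L
      }
      df <- df[!duplicated(key), , drop = FALSE]
      df$sample_id <- sid
      all_rows[[sid]] <- df
    }
  }
  big <- do.call(rbind, all_rows)
  snvs <- if (is.null(big))
    structure(data.frame(sample_id = character(), project = character(),
                         chrom = character(), pos = integer(),
                         ref = character(), alt = character()),
              class = c("snv_table", "data.frame"))
  else snv_table(big$sample_id, big$chrom, big$pos, big$ref, big$alt,
                 genome = gen)
  truth <- list(labels = labels, spectra = spectra, site_mass = mass,
                dom_bp = dom_bp, fla_bp = fla_bp, genome_bp = glen,
                clusters = clusters)
  list(snvs = snvs, truth = truth)
}

#' Simulate strand-resolved repair coverage tracks
#'
#' Per bin and strand, counts are Poisson with mean
#' `rate_per_dinuc x reactive-dinucleotide count`, multiplied by
#' `deficit` inside origin domains and by `2^strand_bias` on the
#' lagging-template strand of each origin side (plus strand right of
#' the midpoint, minus strand left of it).
#'
#' @param sim Output of [simulate_genome()].
#' @param rate_per_dinuc Mean reads per reactive dinucleotide.
#' @param deficit Multiplier inside origin domains (e.g. 0.5).
#' @param strand_bias Log2 excess on the lagging-template strand within
#'   origin flanks.
#' @param lesion Reactive set label, default CPD.
#' @param resolution Bin width (bp), default 50.
#' @param seed Integer seed.
#' @return List: `track` (a `strand_track`), `reactive`.
#' @export
simulate_tracks <- function(sim, rate_per_dinuc = 2, deficit = 1,
                            strand_bias = 0, lesion = "CPD",
                            resolution = 50L, seed = 3L) {
  set.seed(as.integer(seed))
  gen <- sim$genome; origins <- sim$origins
  rs <- reactive_set(lesion)
  dhw <- domain_halfwidth(origins); fhw <- flank_halfwidth(origins)
  plus <- list(); minus <- list()
  for (ch in names(gen$seq)) {
    cp <- .dinuc_bin_counts(gen, ch, rs$dinucs, "+", resolution)
    cm <- .dinuc_bin_counts(gen, ch, rs$dinucs, "-", resolution)
    nb <- length(cp)
    centres <- (seq_len(nb) - 0.5) * resolution
    off <- .origin_offset(rep(ch, nb), as.integer(centres), origins)
    mup <- rate_per_dinuc * cp
    mum <- rate_per_dinuc * cm
    in_dom <- !is.na(off) & abs(off) <= dhw
    mup[in_dom] <- mup[in_dom] * deficit
    mum[in_dom] <- mum[in_dom] * deficit
    near <- !is.na(off) & abs(off) <= fhw
    right <- near & off >= 0; left <- near & off < 0
    mup[right] <- mup[right] * 2^strand_bias
    mum[left] <- mum[left] * 2^strand_bias
    plus[[ch]] <- stats::rpois(nb, mup)
    minus[[ch]] <- stats::rpois(nb, mum)
  }
  list(track = strand_track(plus, minus, resolution), reactive = rs)
}

#' Simulate SV break ends and CNV segments
#'
#' A configured fraction of SVs are ~100-bp duplications seeded at the
#' starts of planted origin G4 cores; the rest follow a uniform
#' type/length mixture. Amplified CNV segments (CN 3-4, Het) place each
#' boundary inside an origin domain with probability
#' `boundary_origin_fraction`; background segments (losses, LOH,
#' neutral) are placed uniformly.
#'
#' @param sim Output of [simulate_genome()].
#' @param n_sv,dup_at_g4_fraction SV counts and G4-seeded fraction.
#' @param n_cnv,amp_fraction,boundary_origin_fraction CNV counts,
#'   fraction amplified, and boundary placement probability.
#' @param n_samples Number of samples the events are spread over.
#' @param seed Integer seed.
#' @return List: `svs` (classified `sv_set`), `cnvs` (a `cnv_set`),
#'   `truth` (per-event flags: `sv_at_g4`, `cnv_amplified`,
#'   `cnv_boundary_origin` counts, generated type labels).
#' @export
simulate_sv_cnv <- function(sim, n_sv = 200L, dup_at_g4_fraction = 0.3,
                            n_cnv = 200L, amp_fraction = 0.5,
                            boundary_origin_fraction = 0.3,
                            n_samples = 10L, seed = 4L) {
  set.seed(as.integer(seed))
  gen <- sim$genome; origins <- sim$origins
  chroms <- names(gen$seq)
  chrom_p <- gen$lengths / sum(gen$lengths)
  dhw <- domain_halfwidth(origins)
  sids <- sprintf("S%03d", sample.int(n_samples, n_sv, replace = TRUE))

  g4o <- sim$g4_truth[sim$g4_truth$at_origin, , drop = FALSE]
  at_g4 <- runif(n_sv) < dup_at_g4_fraction & nrow(g4o) > 0
  rows <- vector("list", n_sv)
  gen_type <- character(n_sv)
  for (i in seq_len(n_sv)) {
    if (at_g4[i]) {
      j <- sample.int(nrow(g4o), 1L)
      ch <- g4o$chrom[j]
      p1 <- g4o$core_start[j] + sample(-1:1, 1L)
      p2 <- p1 + sample(80:120, 1L)
      rows[[i]] <- data.frame(sample_id = sids[i], chrom1 = ch, pos1 = p1,
                              orient1 = "head", chrom2 = ch, pos2 = p2,
                              orient2 = "tail", inserted = NA_character_,
                              stringsAsFactors = FALSE)
      gen_type[i] <- "DUP"
    } else {
      ty <- sample(c("DEL", "DUP", "INV", "ITX", "INS"), 1L,
                   prob = c(0.3, 0.25, 0.2, 0.15, 0.1))
      gen_type[i] <- ty
      ch <- sample(chroms, 1L, prob = chrom_p)
      if (ty == "ITX") {
        ch2 <- sample(setdiff(chroms, ch), 1L)
        rows[[i]] <- data.frame(sample_id = sids[i], chrom1 = ch,
                                pos1 = sample.int(gen$lengths[[ch]], 1L) - 1L,
                                orient1 = sample(c("head", "tail"), 1L),
                                chrom2 = ch2,
                                pos2 = sample.int(gen$lengths[[ch2]], 1L) - 1L,
                                orient2 = sample(c("head", "tail"), 1L),
                                inserted = NA_character_, stringsAsFactors = FALSE)
      } else if (ty == "INS") {
        p <- sample.int(gen$lengths[[ch]] - 1L, 1L) - 1L
        rows[[i]] <- data.frame(sample_id = sids[i], chrom1 = ch, pos1 = p,
                                orient1 = "tail", chrom2 = ch, pos2 = p,
                                orient2 = "head",
                                inserted = paste(sample(BASES, 20, TRUE),
                                                 collapse = ""),
                                stringsAsFactors = FALSE)
      } else {
        len <- round(10^runif(1L, 2, 6.3))
        p1 <- sample.int(max(gen$lengths[[ch]] - len - 1L, 1L), 1L) - 1L
        o <- switch(ty, DEL = c("tail", "head"), DUP = c("head", "tail"),
                    INV = rep(sample(c("head", "tail"), 1L), 2L))
        rows[[i]] <- data.frame(sample_id = sids[i], chrom1 = ch, pos1 = p1,
                                orient1 = o[1], chrom2 = ch, pos2 = p1 + len,
                                orient2 = o[2], inserted = NA_character_,
                                stringsAsFactors = FALSE)
      }
    }
  }
  bends <- do.call(rbind, rows)
  svs <- classify_sv(bends)

  # CNV segments
  amp <- runif(n_cnv) < amp_fraction
  seg <- vector("list", n_cnv)
  boundary_flags <- matrix(FALSE, n_cnv, 2L)
  for (i in seq_len(n_cnv)) {
    ch <- sample(chroms, 1L, prob = chrom_p)
    L <- gen$lengths[[ch]]
    if (amp[i]) {
      len <- round(runif(1L, 2e5, 2e6))
      omid <- origins$midpoint[origins$chrom == ch]
      b1_at <- runif(1L) < boundary_origin_fraction && length(omid) > 0
      start <- if (b1_at) sample(omid, 1L) + sample(seq.int(-dhw + 1L, dhw - 1L), 1L)
               else sample.int(max(L - len, 1L), 1L) - 1L
      end <- start + len
      b2_at <- runif(1L) < boundary_origin_fraction && length(omid) > 0
      if (b2_at) {
        cand <- omid[abs(omid - end) < 5e5 & omid > start + 1e5]
        if (length(cand)) end <- sample(rep(cand, 2L), 1L) +
            sample(seq.int(-dhw + 1L, dhw - 1L), 1L)
        else b2_at <- FALSE
      }
      start <- max(0L, min(start, L - 2L)); end <- min(L, max(end, start + 1e5))
      boundary_flags[i, ] <- c(b1_at, b2_at)
      seg[[i]] <- data.frame(sample_id = sprintf("S%03d", sample.int(n_samples, 1L)),
                             chrom = ch, start = as.integer(start),
                             end = as.integer(end),
                             total_cn = sample(3:4, 1L), het_status = "Het",
                             stringsAsFactors = FALSE)
    } else {
      len <- round(10^runif(1L, 4.5, 6.6))
      start <- sample.int(max(L - len, 1L), 1L) - 1L
      kind <- sample(c("loss", "loh", "neutral", "bigGain"), 1L,
                     prob = c(0.4, 0.3, 0.2, 0.1))
      cn <- switch(kind, loss = sample(0:1, 1L), loh = 2L, neutral = 2L,
                   bigGain = sample(5:12, 1L))
      het <- switch(kind, loss = "LOH", loh = "LOH", neutral = "Het",
                    bigGain = "Het")
      seg[[i]] <- data.frame(sample_id = sprintf("S%03d", sample.int(n_samples, 1L)),
                             chrom = ch, start = as.integer(start),
                             end = as.integer(start + len),
                             total_cn = cn, het_status = het,
                             stringsAsFactors = FALSE)
    }
  }
  segdf <- do.call(rbind, seg)
  cnvs <- cnv_segments(segdf$sample_id, segdf$chrom, segdf$start, segdf$end,
                       segdf$total_cn, segdf$het_status)
  list(svs = svs, cnvs = cnvs, bends = bends,
       truth = list(sv_at_g4 = at_g4, sv_type = gen_type,
                    cnv_amplified = amp, cnv_boundary_origin = boundary_flags))
}

#' Simulate an expression matrix with subtype structure
#'
#' Negative-binomial counts (size = 10) over lognormal baseline means;
#' stress-panel genes are shifted up in subtype 1, cyclin classes are
#' shifted to encode planted phase structure (subtype 1 cyclin-E-high,
#' subtype 2 cyclin-A-high, subtype 3 cyclin-B-high), and a block of
#' subtype marker genes separates the groups in expression space.
#'
#' @param n_genes,n_samples Matrix shape (samples split evenly over
#'   `n_subtypes`).
#' @param n_subtypes Number of subtypes, default 3.
#' @param stress_effect Fold shift of the stress panel in subtype 1.
#' @param cyclin_effect Fold shift of the subtype's cyclin class.
#' @param marker_effect Fold shift of each subtype's marker block (0
#'   disables subtype separation).
#' @param seed Integer seed.
#' @return List: `expr` (an `expression_matrix`), `panel` (stress gene
#'   names), `truth` (subtype labels).
#' @export
simulate_expression <- function(n_genes = 2000L, n_samples = 60L,
                                n_subtypes = 3L, stress_effect = 4,
                                cyclin_effect = 4, marker_effect = 4,
                                seed = 5L) {
  stopifnot(n_subtypes >= 2L)
  set.seed(as.integer(seed))
  cyc <- unlist(cyclin_map())
  panel <- sprintf("STRESS%02d", 1:20)
  markers <- split(sprintf("MARK%03d", 1:(30 * n_subtypes)),
                   rep(seq_len(n_subtypes), each = 30L))
  extra <- length(cyc) + length(panel) + 30L * n_subtypes
  genes <- unname(c(cyc, panel, unlist(markers),
                    sprintf("G%05d", seq_len(max(n_genes - extra, 0L)))))
  labels <- rep(seq_len(n_subtypes), length.out = n_samples)
  labels <- sort(labels)
  base_mu <- stats::setNames(exp(stats::rnorm(length(genes), log(100), 1)), genes)
  mu <- matrix(rep(base_mu, n_samples), ncol = n_samples,
               dimnames = list(genes, sprintf("S%03d", seq_len(n_samples))))
  mu[panel, labels == 1L] <- mu[panel, labels == 1L] * stress_effect
  phase_gene <- list(`1` = cyclin_map()$E, `2` = cyclin_map()$A,
                     `3` = cyclin_map()$B)
  for (st in seq_len(min(n_subtypes, 3L))) {
    g <- phase_gene[[as.character(st)]]
    mu[g, labels == st] <- mu[g, labels == st] * cyclin_effect
  }
  for (st in seq_len(n_subtypes))
    mu[markers[[st]], labels == st] <- mu[markers[[st]], labels == st] * marker_effect
  counts <- matrix(stats::rnbinom(length(mu), size = 10, mu = mu),
                   nrow = nrow(mu), dimnames = dimnames(mu))
  lens <- stats::setNames(sample(500:5000, length(genes), replace = TRUE), genes)
  list(expr = tpm(counts, lens), panel = panel,
       truth = setNames(as.character(labels), colnames(mu)))
}

#' Write all simulated inputs to a directory
#'
#' Emits the file dialects the package readers parse: genome FASTA,
#' origins BED, SNV/SV/CNV TSVs, per-strand bedGraphs, expression
#' counts + exon-length TSVs, and a truth JSON.
#'
#' @param sim Output of [simulate_genome()].
#' @param cohort Output of [simulate_snv_cohort()] (optional).
#' @param tracks Output of [simulate_tracks()] (optional).
#' @param svcnv Output of [simulate_sv_cnv()] (optional).
#' @param expression Output of [simulate_expression()] (optional).
#' @param dir Output directory (created).
#' @return `dir`, invisibly.
#' @export
write_sim_inputs <- function(sim, dir, cohort = NULL, tracks = NULL,
                             svcnv = NULL, expression = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(sim$genome, file.path(dir, "genome.fa"))
  write_bed(sim$origins, file.path(dir, "origins.bed"))
  if (!is.null(cohort))
    write_snv_tsv(cohort$snvs, file.path(dir, "snv.tsv"))
  if (!is.null(tracks))
    write_strand_track(tracks$track, file.path(dir, "repair.plus.bedgraph"),
                       file.path(dir, "repair.minus.bedgraph"))
  if (!is.null(svcnv)) {
    utils::write.table(svcnv$bends, file.path(dir, "sv.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(svcnv$cnvs)[
      , c("sample_id", "chrom", "start", "end", "total_cn", "het_status")],
      file.path(dir, "cnv.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(expression)) {
    cdf <- data.frame(gene = rownames(expression$expr$counts),
                      expression$expr$counts, check.names = FALSE)
    utils::write.table(cdf, file.path(dir, "counts.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(data.frame(gene = rownames(expression$expr$counts),
                                  length = expression$expr$exon_lengths),
                       file.path(dir, "exon_lengths.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  truth <- list(g4 = sim$g4_truth,
                snv = if (!is.null(cohort)) cohort$truth["labels"] else NULL,
                expression = if (!is.null(expression)) expression$truth else NULL)
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
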