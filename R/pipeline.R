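# Orchestration: validated run configuration, staged execution over the
# standard input files, TSV/JSON outputs and a reproducibility manifest.

#' Build / validate a run configuration
#'
#' @param genome_fa,origins_bed Required input paths.
#' @param snv_tsv,catalog_tsv,sv_tsv,cnv_tsv,track_plus,track_minus,
#'   counts_tsv,lengths_tsv Optional stage inputs; stages lacking their
#'   inputs are skipped.
#' @param out_dir Output directory.
#' @param min_total,min_origin_mutations Cohort filters (defaults 5000
#'   and 50).
#' @param k_clusters Clusters for the signature stage.
#' @param n_perm Permutations for the CNV boundary test.
#' @param seed Seed for all stochastic stages.
#' @param lesion Reactive-dinucleotide set for the repair stage.
#' @return Validated list of class `run_config`.
#' @export
run_config <- function(genome_fa, origins_bed, out_dir,
                       snv_tsv = NULL, catalog_tsv = NULL, sv_tsv = NULL,
                       cnv_tsv = NULL, track_plus = NULL, track_minus = NULL,
                       counts_tsv = NULL, lengths_tsv = NULL,
                       min_total = 5000L, min_origin_mutations = 50L,
                       n_perm = 1000L, k_clusters = 2L, seed = 1L,
                       lesion = "CPD") {
  cfg <- list(genome_fa = genome_fa, origins_bed = origins_bed,
              out_dir = out_dir, snv_tsv = snv_tsv,
              catalog_tsv = catalog_tsv, sv_tsv = sv_tsv, cnv_tsv = cnv_tsv,
              track_plus = track_plus, track_minus = track_minus,
              counts_tsv = counts_tsv, lengths_tsv = lengths_tsv,
              min_total = as.integer(min_total),
              min_origin_mutations = as.integer(min_origin_mutations),
              n_perm = as.integer(n_perm), k_clusters = as.integer(k_clusters),
              seed = as.integer(seed), lesion = lesion)
  if (cfg$min_total < 0 || cfg$min_origin_mutations < 0 || cfg$n_perm < 1)
    stop("thresholds must be positive")
  for (f in c("genome_fa", "origins_bed", "snv_tsv", "catalog_tsv", "sv_tsv",
              "cnv_tsv", "track_plus", "track_minus", "counts_tsv",
              "lengths_tsv")) {
    path <- cfg[[f]]
    if (!is.null(path) && !file.exists(path))
      stop("input file missing for ", f, ": ", path)
  }
  class(cfg) <- "run_config"
  cfg
}

#' Read a YAML run configuration
#'
#' @param file YAML path whose keys mirror [run_config()] arguments.
#' @return A `run_config`.
#' @export
read_run_config <- function(file) {
  do.call(run_config, yaml::read_yaml(file))
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the staged origin-mutagenesis pipeline
#'
#' Stages: regions -> burden -> signatures -> g4 -> repair (optional)
#' -> rearrangements (optional) -> features (optional); each stage only
#' runs when its inputs are present. Outputs are TSV/JSON files under
#' `out_dir`; a manifest (config hash, input checksums, per-stage
#' wall-times, warnings, output checksums) is written at the end.
#'
#' @param cfg A `run_config`.
#' @return The manifest list, invisibly; results on disk.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("orimut")),
    config = unclass(cfg),
    config_hash = .hash_obj(unclass(cfg)),
    inputs = list(), stages = list(), warnings = character(), outputs = list())
  for (f in c("genome_fa", "origins_bed", "snv_tsv", "catalog_tsv", "sv_tsv",
              "cnv_tsv", "track_plus", "track_minus", "counts_tsv",
              "lengths_tsv"))
    if (!is.null(cfg[[f]]))
      manifest$inputs[[f]] <- unname(tools::md5sum(cfg[[f]]))

  note <- function(w) manifest$warnings <<- c(manifest$warnings, conditionMessage(w))
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    withCallingHandlers(expr, warning = function(w) {
      note(w); invokeRestart("muffleWarning")
    })
    manifest$stages[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
  }
  out <- function(name) file.path(cfg$out_dir, name)

  # stage expressions are promises evaluated in this frame, so plain
  # assignment updates the pipeline state
  gen <- NULL; origins <- NULL; grid <- NULL; snvs <- NULL
  stage("regions", {
    gen <- read_fasta(cfg$genome_fa)
    origins <- read_origins(cfg$origins_bed)
    origins <- select_isolated(origins)
    grid <- tile_windows(origins, width = 100L)
    .write_tsv(as.data.frame(origins), out("origins_isolated.tsv"))
    cl <- call_clusters(read_origins(cfg$origins_bed))
    .write_tsv(cl, out("origin_clusters.tsv"))
  })

  if (!is.null(cfg$snv_tsv)) {
    stage("burden", {
      snvs <- read_snv_tsv(cfg$snv_tsv, genome = gen)
      snvs <- filter_cohort(snvs, min_total = cfg$min_total)
      prof <- density_profile(snvs, grid, gen$lengths)
      .write_tsv(as.data.frame(prof), out("density_profile.tsv"))
      br <- burden_ratio(snvs, origins, gen$lengths)
      .write_tsv(br, out("burden_ratios.tsv"))
    })
    stage("signatures", {
      dom <- origin_domains(origins, gen$lengths)
      cohort <- filter_cohort(snvs, min_total = 0L, region = dom,
                              min_region = cfg$min_origin_mutations)
      sig <- origin_signatures(cohort, gen, origins)
      .write_tsv(data.frame(sample_id = rownames(sig$rates), sig$rates,
                            check.names = FALSE), out("adjusted_rates.tsv"))
      if (nrow(sig$rates) >= 2L && cfg$k_clusters <= nrow(sig$rates)) {
        clu <- cluster_samples(sig$rates, k = cfg$k_clusters)
        .write_tsv(data.frame(sample_id = names(clu$labels),
                              cluster = clu$labels), out("clusters.tsv"))
        if (!is.null(clu$newick))
          writeLines(clu$newick, out("dendrogram.nwk"))
        agg <- aggregate_cluster_signature(cohort, clu$labels, gen, origins)
        sigs <- t(vapply(agg, function(a)
          if (is.null(a$signature)) rep(NA_real_, 96) else a$signature,
          numeric(96)))
        colnames(sigs) <- context_classes()
        .write_tsv(data.frame(cluster = rownames(sigs), sigs,
                              check.names = FALSE), out("cluster_signatures.tsv"))
      }
      if (!is.null(cfg$catalog_tsv)) {
        catalog <- read_catalog(cfg$catalog_tsv)
        cm <- build_context_matrix(cohort, gen)
        fit <- fit_exposures(cm, catalog, mode = "strict",
                             min_contribution = cfg$min_origin_mutations)
        .write_tsv(data.frame(sample_id = rownames(fit$exposures),
                              fit$exposures, check.names = FALSE),
                   out("exposures.tsv"))
      }
    })
    stage("g4", {
      motifs <- find_g4_motifs(gen)
      write_g4_bed(motifs, out("g4_motifs.bed"))
      norm <- pyrimidine_normalize(snvs$ref, snvs$alt)
      tg <- snvs[norm$ref == "T" & norm$alt == "G", , drop = FALSE]
      if (nrow(tg)) {
        sc <- mutation_context_g4h(tg, gen)
        .write_tsv(sc, out("tg_context_g4h.tsv"))
      }
    })
  }

  if (!is.null(cfg$track_plus) && !is.null(cfg$track_minus)) {
    stage("repair", {
      tr <- read_strand_track(cfg$track_plus, cfg$track_minus, gen$lengths)
      trc <- dinuc_correct(tr, gen, reactive_set(cfg$lesion))
      prof <- profile_at_origins(trc, origins, span = 20000L)
      .write_tsv(prof$summary, out("repair_profile.tsv"))
      .write_tsv(strand_bias(prof), out("repair_strand_bias.tsv"))
    })
  }

  if (!is.null(cfg$sv_tsv) || !is.null(cfg$cnv_tsv)) {
    stage("rearrangements", {
      if (!is.null(cfg$sv_tsv)) {
        svs <- read_sv_tsv(cfg$sv_tsv)
        dom <- origin_domains(origins, gen$lengths)
        sig <- sv_signature(svs, dom)
        .write_tsv(data.frame(class = names(sig), frequency = as.numeric(sig),
                              count = attr(sig, "counts")), out("sv_signature.tsv"))
        .write_tsv(breakend_profile(svs, grid), out("breakend_profile.tsv"))
      }
      if (!is.null(cfg$cnv_tsv)) {
        cnvs <- read_cnv_tsv(cfg$cnv_tsv)
        csig <- cnv_signature(cnvs)
        .write_tsv(data.frame(class = names(csig), frequency = as.numeric(csig),
                              count = attr(csig, "counts")),
                   out("cnv_signature.tsv"))
        track <- origin_coverage_track(origins, gen$lengths)
        amp <- cnvs[cnvs$cnv_kind == "gain", , drop = FALSE]
        if (nrow(amp)) {
          len <- amp$end - amp$start
          if (any(len > 1e5 & len < 5e6)) {
            enr <- segment_origin_enrichment(amp, track)
            .write_tsv(data.frame(window = enr$window,
                                  segment_mean = enr$segment_mean,
                                  excess = enr$excess),
                       out("cnv_origin_enrichment.tsv"))
          }
          bp <- data.frame(chrom = rep(amp$chrom, 2L),
                           start = c(amp$start, amp$end - 1L),
                           end = c(amp$start + 1L, amp$end))
          pt <- boundary_permutation_test(bp, origin_domains(origins, gen$lengths),
                                          gen$lengths, n_perm = cfg$n_perm,
                                          seed = cfg$seed)
          jsonlite::write_json(list(observed = pt$observed,
                                    p_value = pt$p_value, fold = pt$fold,
                                    n_perm = pt$n_perm),
                               out("boundary_permutation.json"),
                               auto_unbox = TRUE, digits = NA)
          }
      }
    })
  }

  if (!is.null(cfg$counts_tsv) && !is.null(cfg$lengths_tsv)) {
    stage("features", {
      expr <- read_expression(cfg$counts_tsv, cfg$lengths_tsv)
      .write_tsv(cyclin_phase_fractions(expr), out("phase_fractions.tsv"))
      lab <- subtype_labels(expr, k = min(cfg$k_clusters, ncol(expr$tpm)),
                            seed = cfg$seed)
      .write_tsv(data.frame(sample_id = names(lab), label = lab),
                 out("subtypes.tsv"))
    })
  }

  outs <- setdiff(list.files(cfg$out_dir, full.names = TRUE),
                  file.path(cfg$out_dir, "manifest.json"))
  manifest$outputs <- as.list(tools::md5sum(outs))
  names(manifest$outputs) <- basename(outs)
  # atomically: write then rename
  tmp <- tempfile(tmpdir = cfg$out_dir)
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  file.rename(tmp, file.path(cfg$out_dir, "manifest.json"))
  invisible(manifest)
}

.hash_obj <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(x, tmp, version = 2)
  unname(tools::md5sum(tmp))
}
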