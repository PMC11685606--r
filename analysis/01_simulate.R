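#!/usr/bin/env Rscript
# Builds the synthetic study cohort: a 2 x 5 Mb genome with 100
# well-spaced origins (half carrying planted G4 cores), a 30-sample SNV
# cohort split between an AID/WRCY-driven group, a UV-like group and
# a G4-targeted T>G group (origin-focused at fold 8), repair tracks with a
# planted origin NER deficit, G4-seeded duplications and
# origin-bounded amplifications, and a 3-subtype expression matrix.
# All downstream scripts read from results/simdata/.

library(orimut)

seed <- 20260925L
out <- "results/simdata"

sim <- simulate_genome(sim_config(seed = seed))
message(sprintf("genome: %d chromosomes, %s bp; %d origins (%d with G4)",
                length(sim$genome$seq),
                format(sum(sim$genome$lengths), big.mark = ","),
                nrow(sim$origins), sum(sim$g4_truth$at_origin)))

clusters <- list(
  list(n_samples = 12, burden = 3000,
       mixture = c(flat = 0.25, aid_wrcy = 0.75), origin_fold = 8),
  list(n_samples = 12, burden = 3000,
       mixture = c(flat = 0.25, uv_ner_deficit = 0.75), origin_fold = 8),
  list(n_samples = 12, burden = 3000,
       mixture = c(flat = 0.5, g4_tg = 0.5), origin_fold = 8))
cohort <- simulate_snv_cohort(sim, clusters, seed = seed + 1L)
message(sprintf("SNV cohort: %d samples, %s mutations",
                length(unique(cohort$snvs$sample_id)),
                format(nrow(cohort$snvs), big.mark = ",")))

tracks <- simulate_tracks(sim, rate_per_dinuc = 20, deficit = 0.5,
                          strand_bias = 1, seed = seed + 2L)
svcnv <- simulate_sv_cnv(sim, n_sv = 300L, dup_at_g4_fraction = 0.4,
                         n_cnv = 200L, amp_fraction = 0.5,
                         boundary_origin_fraction = 0.6, seed = seed + 3L)
expr <- simulate_expression(n_genes = 2000L, n_samples = 60L,
                            seed = seed + 4L)

write_sim_inputs(sim, out, cohort = cohort, tracks = tracks, svcnv = svcnv,
                 expression = expr)
saveRDS(cohort$truth, file.path(out, "snv_truth.rds"))
saveRDS(svcnv$truth, file.path(out, "svcnv_truth.rds"))
saveRDS(expr["truth"], file.path(out, "expr_truth.rds"))
message("inputs written under ", out)
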