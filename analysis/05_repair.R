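#!/usr/bin/env Rscript
# Strand-resolved repair profiling: reads the simulated XR-seq-style
# bedGraph pair, corrects for reactive-dinucleotide composition,
# profiles the signal at origins (recovering the planted NER deficit),
# and computes the fork-oriented strand bias.

library(orimut)

dir.create("results/repair", showWarnings = FALSE, recursive = TRUE)
gen <- read_fasta("results/simdata/genome.fa")
origins <- select_isolated(read_origins("results/simdata/origins.bed"))
track <- read_strand_track("results/simdata/repair.plus.bedgraph",
                           "results/simdata/repair.minus.bedgraph",
                           gen$lengths)

corr <- dinuc_correct(track, gen, reactive_set("CPD"))
prof <- profile_at_origins(corr, origins, span = 20000L)
write.table(prof$summary, "results/repair/profile.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

tot <- prof$summary$plus_mean + prof$summary$minus_mean
domw <- abs(prof$summary$offset + 25) <= 475
flaw <- abs(prof$summary$offset) > 600
message(sprintf("corrected repair signal, domain / flank: %.2f",
                mean(tot[domw], na.rm = TRUE) / mean(tot[flaw], na.rm = TRUE)))

sb <- strand_bias(prof)
write.table(sb, "results/repair/strand_bias.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message(sprintf("mean lagging/leading log2 bias in flanks: %.2f",
                mean(sb$bias_lagging_leading[abs(sb$offset + 50) > 600],
                     na.rm = TRUE)))

# anti-correlation of repair with mutation counts at origins
snvs <- read_snv_tsv("results/simdata/snv.tsv", genome = gen)
dom <- origin_domains(origins, gen$lengths)
per_origin_mut <- vapply(seq_len(nrow(origins)), function(i) {
  d <- dom[dom$origin == i, ]
  sum(snvs$chrom == d$chrom & snvs$pos >= d$start & snvs$pos < d$end)
}, numeric(1))
rep_mean <- mean_origin_signal(corr, origins)
rho <- cor(per_origin_mut, rep_mean, method = "spearman",
           use = "complete.obs")
message(sprintf("Spearman rho, origin mutation count vs corrected repair: %.2f",
                rho))
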