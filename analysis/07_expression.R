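#!/usr/bin/env Rscript
# Expression covariates: TPM normalisation, replicative-stress biomarker
# Z-scores, cyclin-based cell-cycle phase fractions, and subtype
# labelling by 2-component embedding + k-means, checked against the
# planted subtypes.

library(orimut)

dir.create("results/expression", showWarnings = FALSE, recursive = TRUE)
expr <- read_expression("results/simdata/counts.tsv",
                        "results/simdata/exon_lengths.tsv")
truth <- readRDS("results/simdata/expr_truth.rds")$truth
panel <- readLines(system.file("extdata", "stress_panel_synthetic.txt",
                               package = "orimut"))

lab <- subtype_labels(expr, k = 3L, seed = 1L)
tab <- table(lab, truth[names(lab)])
message("subtype x planted table:")
print(tab)
write.table(data.frame(sample_id = names(lab), subtype = lab,
                       planted = truth[names(lab)]),
            "results/expression/subtypes.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

z <- biomarker_zscores(expr, panel, use = "counts")
write.table(data.frame(gene = rownames(z), z, check.names = FALSE),
            "results/expression/stress_zscores.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
by_sub <- tapply(colMeans(z), truth[colnames(z)], mean)
message("mean stress-panel Z by planted subtype:")
print(round(by_sub, 2))

pf <- cyclin_phase_fractions(expr)
write.table(pf, "results/expression/phase_fractions.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("mean phase fractions by planted subtype:")
print(round(sapply(c("g1s", "sg2", "g2m"), function(cl)
  tapply(pf[[cl]], truth[pf$sample_id], mean)), 3))
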