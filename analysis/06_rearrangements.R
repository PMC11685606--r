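#!/usr/bin/env Rscript
# SV and CNV signatures: type x length class frequencies, break-end
# profiles at origins and at G4 starts, origin-coverage excess across
# rescaled amplified segments, and the boundary permutation test.

library(orimut)

dir.create("results/rearrangements", showWarnings = FALSE, recursive = TRUE)
gen <- read_fasta("results/simdata/genome.fa")
origins <- select_isolated(read_origins("results/simdata/origins.bed"))
svs <- read_sv_tsv("results/simdata/sv.tsv")
cnvs <- read_cnv_tsv("results/simdata/cnv.tsv")
dom <- origin_domains(origins, gen$lengths)

sig <- sv_signature(svs, dom)
write.table(data.frame(class = names(sig), frequency = as.numeric(sig),
                       count = attr(sig, "counts")),
            "results/rearrangements/sv_signature.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
top <- sort(sig[sig > 0], decreasing = TRUE)[1:3]
message("top SV classes at origins: ",
        paste(sprintf("%s (%.2f)", names(top), top), collapse = ", "))

grid <- tile_windows(origins, 100L)
bp_prof <- breakend_profile(svs, grid)
write.table(bp_prof, "results/rearrangements/breakend_profile.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
ctr <- abs(bp_prof$offset + 50) <= 450
message(sprintf("break-end fold change at origin domains: %.2f",
                mean(bp_prof$fold[ctr], na.rm = TRUE)))

motifs <- find_g4_motifs(gen)
in_dom <- orimut:::.in_regions(motifs$chrom, motifs$core_start, dom)
bn <- breakends_near_g4(svs, motifs[in_dom, ], gen, span = 100L)
write.table(bn$profile, "results/rearrangements/breakends_near_g4.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf("%d break ends within 5 bp of origin-G4 starts; base at break ends: %s",
                bn$within_tol,
                paste(names(bn$base_table), bn$base_table, collapse = " ")))

csig <- cnv_signature(cnvs)
write.table(data.frame(class = names(csig), frequency = as.numeric(csig),
                       count = attr(csig, "counts")),
            "results/rearrangements/cnv_signature.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

amp <- cnvs[cnvs$cnv_kind == "gain" & cnvs$total_cn <= 4, ]
track <- origin_coverage_track(origins, gen$lengths)
enr <- segment_origin_enrichment(amp, track, flank = 2e6)
write.table(data.frame(window = enr$window, segment_mean = enr$segment_mean,
                       excess = enr$excess),
            "results/rearrangements/origin_excess.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
edge <- mean(enr$excess[c(1:5, 96:100)]); mid <- mean(enr$excess[45:55])
message(sprintf("origin excess, boundary windows %.3f vs interior %.3f",
                edge, mid))

bpnt <- data.frame(chrom = rep(amp$chrom, 2),
                   start = c(amp$start, amp$end - 1L),
                   end = c(amp$start + 1L, amp$end))
pt <- boundary_permutation_test(bpnt, dom, gen$lengths, n_perm = 1000L,
                                seed = 7L)
message(sprintf("amplified-boundary overlap: observed %d, mean null %.1f, P = %.4g",
                pt$observed, mean(pt$null), pt$p_value))
jsonlite::write_json(list(observed = pt$observed, p_value = pt$p_value,
                          fold = pt$fold, n_perm = pt$n_perm),
                     "results/rearrangements/boundary_permutation.json",
                     auto_unbox = TRUE, digits = NA)
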