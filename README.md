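# orimut — origin-centric analysis of somatic mutagenesis

Constitutive replication origins — initiation sites that fire across
cell types — accumulate a focal excess of somatic mutations in cancer
genomes. `orimut` provides the full analytic stack for quantifying and
characterising that excess:

* **Origin geometry**: 1-kb origin domains (midpoint ± 500 bp), ±10 kb
  flanks, isolation and cluster filters, fixed-width window grids.
* **Mutation burden**: per-window density profiles, per-sample
  origin/flank **burden ratios**
  `r = (domain mutations / domain bp) / (flank mutations / flank bp)`,
  composition-corrected substitution rates, CpG partition, minor allele
  frequencies.
* **Signatures**: 96-context matrices (pyrimidine-normalized,
  substitution-major order), **background-adjusted origin signatures**

  `r_c = o_c / O_t(c) − f_c / F_t(c)`

  (domain counts over domain trinucleotide occurrences, minus the same
  rate in the flanks), average-linkage clustering on 1 − cosine,
  pooled cluster signatures, and non-negative least-squares exposure
  refitting with a strict backward-elimination mode.
* **G-quadruplexes**: G4Hunter per-base scores (G-runs score
  min(run, 4), C-runs the negative; sequence score = mean, antisymmetric
  under reverse complement), quadparser-style motif discovery
  `G3+ (N1–12 G3+)×3` with 5-base flanks, top-|G4H| 25-nt windows, and
  replication-oriented mutation/break-end profiles at G4 starts.
* **Repair**: strand-resolved 50-nt coverage tracks (bedGraph pairs),
  reactive-dinucleotide correction (CPD → TT; 6-4PP → CC/CT/TC),
  origin profiles and fork-oriented strand bias.
* **Rearrangements**: SV classification from break-end orientations
  (DEL/DUP/INV/INS/ITX), SV and CNV signature classes over the standard
  length/copy-number bins, origin-coverage excess across rescaled CNV
  segments, and a length-preserving permutation test for
  amplified-boundary enrichment at origin domains.
* **Expression covariates**: TPM, replicative-stress biomarker
  Z-scores, cyclin-based cell-cycle phase fractions, subtype labelling.
* **Synthetic cohorts**: a seeded generator that emits every input the
  pipeline consumes (FASTA, BED, SNV/SV/CNV TSVs, bedGraphs, counts)
  with planted, recoverable effects and a recorded truth object.

## Worked example

The `analysis/` scripts run the full workflow on a synthetic study
cohort (2 × 5 Mb genome, 100 origins, 36 tumours in three planted
groups — AID/WRCY-driven, UV-like with an origin repair deficit, and
G4-targeted T>G — each origin-focused at fold 8):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_burden.R
Rscript analysis/03_signatures.R
# ... through 07_expression.R
```

`02_burden.R` prints

```
origin/flank density enrichment: 5.73-fold
median per-sample burden ratio: 5.87 (IQR 5.06-6.29)
```

— the pooled mutation density in origin domains is ~5.7× the flank
density, and the per-sample burden ratio distribution sits near the
value implied by the planted fold-8 processes mixed with their flat
backgrounds. `03_signatures.R` then recovers the planted structure:

```
cluster x planted-group table:
     1  2  3
  1 12  0  0
  2  0 12  0
  3  0  0 12
cluster 1 aggregate: cosine 0.999 to WRCY, 0.577 to UV, 0.002 to G4-T>G
cluster 2 aggregate: cosine 0.605 to WRCY, 0.997 to UV, 0.006 to G4-T>G
cluster 3 aggregate: cosine 0.007 to WRCY, 0.010 to UV, 0.999 to G4-T>G
```

— cosine clustering of the background-adjusted origin signatures splits
the cohort exactly along the planted groups, and each cluster's pooled,
adjusted signature matches its planted spectrum at cosine ≥ 0.997.
`04_g4.R` links the T>G group to quadruplexes
(`T>G context |G4H|: mean 0.21 vs random T 0.15, one-sided
P = 1.2e-15`), `05_repair.R` recovers the planted origin NER deficit
(`corrected repair signal, domain / flank: 0.51` for a planted 0.5) and
lagging-strand bias (`0.98` for a planted 1.0), and
`06_rearrangements.R` finds duplication break ends at G4 starts and
origin-bounded amplifications
(`observed 117, mean null 2.0, P = 0.000999` at 1,000 permutations).

Equivalent single calls: `run_pipeline(run_config(...))` executes the
staged pipeline over any directory of standard input files and writes
TSV/JSON outputs plus a reproducibility manifest.

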