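# isotigr

De novo transcriptome assembly and annotation at desk scale, for the
situation every non-model-organism lab knows: short paired-end RNA-seq
reads, no reference genome, and the need to turn them into an annotated
transcript catalogue — including the detoxification enzymes (cytochrome
P450s, glutathione S-transferases, carboxylesterases) and insecticide
target-site genes that matter in pest insects such as tephritid fruit
flies.

The package implements the full workflow as tested, reusable R functions:

1. **Read filtering** — a read is kept only if ≥ 25 of its first 35 bases
   have Phred quality > 30, and it contains no `N` and no adapter; pairs
   with one surviving mate keep it as a single read.
2. **Multi-k de Bruijn assembly** — graphs at odd k (21–41) with canonical
   k-mers and read-supported edges; contigs are maximal unbranched paths;
   *isotigs* (putative splice forms) are bounded path enumerations through
   each connected component (*isogroup*), coverage-ranked.
3. **Homologue-keyed merging** — the k = 31 assembly is kept whole; isotigs
   from other k enter only when their best protein homologue (exact local
   alignment, > 60 aa, E < 1e−5, smallest E-value) is new.
4. **Quality metrics** — N50-style assembly statistics; per-base read-mapping
   depth; *completeness* of each isotig as the aligned fraction of its
   nearest homologue; the completeness-bin × median-coverage summary.
5. **Enzyme annotation** — EC-group assignment to the closest enzyme, with
   flexible-gap catalytic-site motifs (`GxSxG`, `FxxGxRxCxG`,
   `PxLxD-x(7,10)-SxAIxxYLxxK`, ...) arbitrating ambiguous assignments;
   coverage-based deduplication; collapsing of isotigs into putative genes
   by non-overlapping alignments on the reference enzyme.
6. **Target-site discovery** — translated six-frame × six-frame scans
   against reference genes at identity > 90%.
7. **Synthetic data** — a generator for transcriptomes with splice
   isoforms, lognormal expression, 90-bp paired reads with realistic
   quality decay, adapter/N contamination, planted motifs, and protein
   databases diverged to a controlled identity — every stage is testable
   against recorded ground truth.

## Worked example

```r
library(isotigr)

sim <- sim_config(n_genes = 15, isoform_probability = 0.2,
                  enzyme_fraction = 0.4, error_rate = 0, seed = 5)
cfg <- pipeline_config(sim = sim, k_values = c(29, 31, 33),
                       coverage = 25, read_mode = "tiled",
                       n_known_mrnas = 5)
m <- run_pipeline(cfg, "demo_run")
str(m$counts)
```

```
List of 13
 $ n_genes               : int 15
 $ n_transcripts         : int 20
 $ n_read_pairs          : int 1401
 $ reads_input           : int 2802
 $ reads_retained        : int 2802
 $ reads_paired          : int 2802
 $ reads_single          : int 0
 $ isotigs_per_k         :List of 3
  ..$ 29: int 20
  ..$ 31: int 20
  ..$ 33: int 20
 $ isotigs_merged        : int 20
 $ isotigs_with_homologue: int 20
 $ ec_predictions        : int 6
 $ putative_enzyme_genes : int 6
 $ validated_pairs       : int 5
```

Fifteen genes (five with a second splice isoform) produce 20 transcripts;
all 2,802 simulated reads pass the quality filter; each k recovers all 20
transcripts as isotigs, the merge keeps the k = 31 set (other k add no new
homologues), all 20 isotigs find their diverged database protein, the six
enzyme genes are predicted into their true EC groups and collapse to six
putative genes, and all five withheld "known mRNAs" validate at > 95%
identity. `demo_run/` contains the FASTQ/FASTA stage outputs, the TSV
reports (assembly statistics, merge tally, coverage, completeness bins, EC
predictions, gene tally, validation) and `manifest.json`, which is
byte-identical across reruns of the same configuration.

Individual stages are plain functions — `filter_read_pairs()`,
`build_graph()` / `extract_contigs()` / `build_isotigs()`,
`assign_homologues()`, `merge_multi_k()`, `map_reads()`,
`completeness_table()`, `predict_ec_batch()`, `collapse_genes()`,
`translated_scan()` — see the methods vignette
(`vignettes/assembly-annotation-methods.Rmd`) for the model behind each and
the parameter defaults. A thin command-line wrapper lives in
`inst/scripts/btdpipe.R`.

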