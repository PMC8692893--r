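# vnarseq

Cartilaginous fish make an antibody isotype that exists nowhere else: the
immunoglobulin new antigen receptor (IgNAR), a heavy-chain-only receptor
whose single variable domain (vNAR, ~12 kDa) is the smallest natural
antigen-binding unit known. Shark IgNAR loci are organised as *clusters* —
each locus carries its own V, D, J and C segments flanked by recombination
signal sequences (RSS) — rather than the translocon layout of mammalian Ig
loci. `vnarseq` is an R/Bioconductor-style toolkit for studying such a
system end to end, from genome to repertoire to antibody library:

1. **Germline mining** — scan a genome assembly for RSS
   (heptamer `CACAGTG` + 12/22/23-bp spacer + nonamer `ACAAAAACC`,
   under per-motif mismatch budgets, default 2 for the heptamer and 3 for
   the nonamer), locate V/D/J/C/Sec/Tm segments by seed-and-extend
   Smith–Waterman similarity search, assemble clusters, classify their
   completeness (a complete cluster = 1 V, 3 D, 1 J, 5 C, one secretory
   and one transmembrane tail, in genomic order), flag pre-joined
   (RSS-less, germline-fused) D segments, and export a germline database.
2. **Repertoire annotation** — QC single-end amplicon reads, assign V and
   J by two-stage alignment (batch local scoring, then an end-free global
   alignment refined by base-by-base matched extension into the
   junction), call D segments by near-exact junction matching, and cut
   the CDR3 between the FR3b cysteine codon and the FR4 tryptophan-motif
   codon, translated in the V frame.
3. **Repertoire statistics** — Shannon–Wiener diversity
   (H = −Σᵢ pᵢ ln pᵢ over clonotypes keyed by V call, J call and CDR3
   amino-acid sequence), Wu–Kabat positional variability
   (distinct residues ÷ frequency of the most common residue),
   V–J pairing matrices, top-n clonal mass, sequence uniqueness,
   clonotype overlap and time-course clonotype tracking.
4. **vNAR typing** — classify full-length vNAR amino-acid sequences into
   the cysteine-pattern taxonomy (types I–IV plus "new") from a
   region-labelled alignment (FR1 · CDR1 · FR2 · HV2 · FR3a · FR3b ·
   CDR3 · FR4), with the rule table shipped as editable YAML.
5. **Simulation** — fully seeded generators for germline genomes with
   planted clusters and RSS, V(D)J repertoire reads with configurable
   pairing frequencies, junctional diversity, somatic hypermutation,
   power-law clone sizes and sequencing error, and vNAR amino-acid
   libraries with configured type mixtures and uniqueness — each with a
   complete ground-truth table, so every pipeline stage can be tested as
   a parameter-recovery problem.

## Worked example

```r
library(vnarseq)

cfg <- simConfig(seed = 42)
cfg
#> SimConfig (seed 42)
#>   germline  : 7 cluster(s)
#>   repertoire: dominant pair IGNARV1|IGNARJ1 (96%), SHM 0.01, error 0.001
#>   library   : I=0.2% II=79.0% III=0.1% IV=1.9% new=18.8%

## mine the synthetic genome back with the generic pipeline
gen      <- makeSyntheticGenome(cfg)
rss      <- findRSS(gen$genome)
segs     <- scanSegments(gen$genome, gen$db$sequences, rss = rss)
clusters <- assembleClusters(segs)
clusters
#> IgNARClusterSet with 7 cluster(s), 77 segment(s)
#>   complete: 4  incomplete: 3
#>   clusters: IgNAR1, IgNAR2, IgNAR3, IgNAR4, IgNAR5, IgNAR6, IgNAR7

## simulate and annotate a repertoire sample
sim     <- simulateRepertoire(cfg, 5000, germline = gen$db)
sample1 <- annotateReads(sim$reads, gen$db, sampleID = "shark1_t1")
sample1
#> RepertoireSample 'shark1_t1' with 5000 read(s)
#>   pass QC: 5000  productive: 4563

vj <- vjPairMatrix(sample1)
round(100 * vj$matrix["IGNARV1", "IGNARJ1"], 1)
#> [1] 96.3                      # recovered dominant pairing share (%)
round(shannonIndex(sample1), 3)
#>  shannon evenness
#>    7.602    0.962             # CDR3 diversity in nats, Pielou evenness
round(topNCumulative(sample1, 100), 3)
#> [1] 0.189                     # mass of the 100 largest clonotypes

## classify a simulated vNAR library by cysteine pattern
lib  <- simulateVnarLibrary(cfg, 5000)
prof <- typeProfile(lib$sequences)
prof$types
#>   type count percent
#> 1    I     6    0.12
#> 2   II  3945   78.90
#> 3  III     4    0.08
#> 4   IV   108    2.16
#> 5  new   937   18.74
```

The mining run recovers exactly the planted locus architecture (seven
clusters, four complete, pre-joined D segments in clusters 2, 5 and 6);
the annotation recovers the configured 96% dominant V–J pairing; the
classifier recovers the configured type mixture. `runPipeline()` drives
all stages from a single YAML configuration and writes every artefact
(germline FASTA/TSV/GFF3, AIRR-style rearrangement TSV, QC and statistics
JSON) into one output directory, byte-reproducibly for a fixed seed.

## Package layout

| | |
|---|---|
| `R/rss.R`, `R/segments.R`, `R/clusters.R` | germline mining |
| `R/annotate.R` | read QC and V(D)J/CDR3 annotation |
| `R/stats.R` | repertoire statistics |
| `R/typing.R` | region assignment and cysteine-pattern typing |
| `R/simulate.R` | seeded genome / repertoire / library generators |
| `R/io.R` | FASTA/FASTQ IO and the YAML-driven pipeline driver |
| `src/align.cpp` | batch Smith–Waterman and end-free refinement core |
| `inst/extdata/` | vNAR reference frame, region table, type rule YAML |
| `vignettes/vnarseq-methods.Rmd` | models, parameters and design notes |
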