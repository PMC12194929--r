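# regcircuit

Mapping binding-site-based regulatory circuits across bacterial genomes.

Bacterial sigma factors (SFs) direct RNA polymerase to specific promoter
classes: the sigma70 family (housekeeping groups 1–2, FliA-like group 3,
RpoE-like group 4) recognizes −35 `TTGACA` / −10 `TATAAT` elements, while
sigma54 (RpoN) promoters carry the −24 `GC` / −12 `TGC` elements and
strictly require ATP-hydrolyzing activators — bacterial enhancer-binding
proteins (bEBPs) — that usually work inside two-component systems (TCSs)
with a histidine-kinase sensor (HKS). `regcircuit` re-implements, as a
tested and reusable R pipeline, the comparative-genomics inference chain
that maps these regulators and their target operons from standard genome
annotation products:

- **Orthology** — reciprocal best hits from an all-vs-all protein
  similarity table (E-value < 10⁻¹⁰, identity > 60%, query coverage ≥ 60%),
  clustered into ortholog groups, with the genome × OG copy-number matrix.
- **Regulator classification** — Pfam domain architectures (after >50%
  overlap resolution) drive a rule cascade: Sigma54_AID + Sigma54_CBD +
  Sigma54_DBD ⇒ RpoN; Sigma70_r1_2 + Sigma70_r3 ⇒ groups 1–2; a lone
  Sigma70_r3 ⇒ group 3 (FliA-like); Sigma70_r2 + Sigma70_r4_2 ⇒ group 4
  (RpoE-like). bEBPs are PF00158 + PF00072; HKS are HisKA + HATPase_c.
  bEBPs are paired with the nearest HKS in their own or flanking
  transcriptional unit, or reported as one-component regulators.
- **Transcriptional units** — same-strand gene runs joined when the
  intergenic gap is ≤ 40 bp ("more than 40 bases" breaks a unit), with
  strand-oriented upstream regions for motif work.
- **Motifs** — PWM construction from aligned sites, kth-order Markov
  backgrounds (k ≤ 4) with add-one smoothing, log-odds scanning with
  *exact* p-values from a dynamic program over the discretized score
  distribution, >50%-overlap site filtering, ZOOPS (zero-or-one occurrence
  per sequence) EM motif discovery, and Schneider–Stephens information
  content `R_seq(j) = 2 − (H_j + 3/(2·ln2·n))`.
- **Circuit assembly** — one edge per (regulator, target TU) supported by
  a surviving binding-site hit (p < 10⁻⁴) or by divergent colocalization
  (the HupR / *hupS-hupL* layout), merged when both apply.

A first-class synthetic-genome generator plants operon structure, domain
architectures, orthologs and PWM-sampled binding sites with known ground
truth, so every stage — and the end-to-end pipeline — is validated by
truth recovery rather than by fixtures.

## Worked example

```r
library(regcircuit)

# a 3-genome synthetic study with planted regulators and binding sites
cfg <- simulation_config(seed = 11)
gs  <- generate_genome_set(cfg)

# transcriptional units and upstream regions
tus <- infer_tus(gs$genes) |>
  extract_upstream(gs$genes, gs$sequences, max_len = 300)

# scan the planted PWMs over the upstream regions
pwms <- lapply(cfg$planted_motifs, function(m) m$pwm)
hits <- scan_sequences(pwms, upstream_sequences(tus), p_max = 1e-4) |>
  filter_overlaps()

edges <- assemble_network(hits, tus)
nrow(edges)
#> [1] 97
head(edges, 3)
#> # A tibble: 3 × 5
#>   regulator_id regulator_class target_tu_id  evidence best_site_pvalue
#>   <chr>        <chr>           <chr>         <chr>               <dbl>
#> 1 ntrC_like    bEBP            g1_chr_TU0004 site_hit     0.00000221
#> 2 ntrC_like    bEBP            g1_chr_TU0006 site_hit     0.00000221
#> 3 ntrC_like    bEBP            g1_chr_TU0012 site_hit     0.0000000596
```

Each row is a regulator→operon edge: the planted NtrC-like motif has a
significant binding site (exact p down to 6 × 10⁻⁸) in the upstream region of
the named transcriptional unit. Against the generator's truth this run
attains edge precision 0.96 and recall 0.92.

Classification and orthology work the same way from tables:

```r
calls <- classify_regulators(gs$domain_hits)
dplyr::count(calls, family)
#> # A tibble: 5 × 2
#>   family      n
#>   <chr>   <int>
#> 1 HKS         3
#> 2 bEBP        3
#> 3 none        3
#> 4 sigma54     3
#> 5 sigma70    12

ogs <- filter_similarity_hits(gs$similarity) |>
  reciprocal_best_hits(gs$genome_map) |>
  cluster_ogs(gs$genome_map)
og_count_matrix(ogs, cap = 2)   # the 0-2 copy-number view
```

Discovered motifs are ordinary objects with `tidy()`, `glance()` and
`autoplot()` methods; `run_pipeline()` executes the whole chain from files
(FASTA + GFF3 + domain/similarity tables + a MEME-format motif library)
and writes every intermediate plus a run manifest.

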