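# slimcore

Mapping short-linear-motif corepressor interactions from structure
ensembles, proteomes and functional genomics.

## What this is for

Oncogenic transcription factors can depend on a corepressor docked
through a five-residue short linear motif (SLiM) — the canonical case
being the PLDLS motif recognized by CTBP-family corepressors. Deciding
whether such an interaction is real, specific, and competable requires a
chain of computational analyses around the wet-lab work, and `slimcore`
packages that chain for R users:

* **Ensemble interface frequency** — per-residue interface calls
  (Shrake–Rupley ΔSASA or heavy-atom contacts) aggregated over an
  ensemble of predicted complex structures:
  $f(r) = \#\{\text{models where } r \text{ is interfacial}\}/n$, with
  consensus segments extracted as runs of $f \ge 0.5$.
* **Proteome motif scanning** — exhaustive wildcard scans (`P.DL.`),
  anchored ±15-aa context windows, amino-acid-class context clustering
  ($d = \sqrt{1 - s}$ over positional similarities), and repeat
  competitor/control construct design (4× motif windows + NLS, with
  PLDLS→PLASS inactivation).
* **Co-complex networks** — hypergeometric complex enrichment
  ($P[X \ge k]$, BH-adjusted) and cosine co-membership graphs with
  Louvain communities and Fruchterman–Reingold layout.
* **IP-MS differential enrichment** — valid-value filtering,
  left-censored imputation, Welch t with permutation FDR (250 label
  permutations), volcano calling at $|\log_2 FC| > 1$, $p < 0.05$.
* **ChIP signal correlation** — ±1000 bp peak-centred windows, bedGraph
  coverage integration, CPM normalization, winsorized heatmap matrices,
  and log10(+1) regression/correlation between tracks.
* **Seeded synthetic-data generators** for every stage, with planted
  ground truth, so the whole pipeline is testable offline.

Standard formats (FASTA, multi-model PDB, BED, bedGraph, Newick, TSV)
are read through strict validating wrappers over Biostrings, bio3d,
GenomicRanges and ape.

## Worked example

Generate a 25-model ensemble with a planted interface, score interface
frequency, and read off the consensus segment:

```r
library(slimcore)

g    <- gen_complex_ensemble(n_models = 25, jitter_sigma = 0.3, seed = 7)
freq <- ensemble_interface_frequency(g$ensemble, "A", "B")
consensus_segments(freq, "A")
#>   chain start_res end_res length segment mean_frequency
#> 1     A        10      14      5   KYVGW              1
```

Residues 10–14 of chain A are interfacial in 25/25 models — exactly the
planted contact run (`g$truth$planted_a`). On a synthetic proteome, scan
for the motif, inspect contexts, and assemble a 4× competitor plus its
motif-dead control:

```r
gp   <- gen_proteome(n_proteins = 200, n_planted = 12, seed = 7)
hits <- scan_motif(gp$proteome, "PLDLS")
head(hits, 2)
#>   protein_id start matched                             context
#> 1   prot0015   159   PLDLS KYVGWPQSDLKRDQLPLDLSGTFDNMHGMPHRKGI
#> 2   prot0022   167   PLDLS FGSWCQNHSGSWWRQPLDLSIMEKQDSTLMKWATA

build_competitor(hits$context[1:4], nls = "PKKKRKV")
#> competitor_construct: 147 aa, 4 x PLDLS, 4 repeat(s)
build_competitor(hits$context[1:4], nls = "PKKKRKV",
                 mutate = c(PLDLS = "PLASS"))
#> competitor_construct: 147 aa, 0 x PLDLS, 4 repeat(s)
```

Four 35-aa windows plus the SV40 NLS give a 147-aa construct carrying 4
motif copies; the PLASS control carries none. Whole analyses can also be
driven through the stage runner, which writes outputs plus a provenance
manifest and is byte-deterministic per seed:

```r
run_stage(run_config("ipms",
                     params  = list(perms = 250),
                     inputs  = list(matrix = "lfq.tsv",
                                    samples = "samples.tsv"),
                     output_dir = "de_out", seed = 7))
```

A thin CLI wrapper is included at `inst/cli/slimcore.R`
(`Rscript slimcore.R --config run.yaml`).

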