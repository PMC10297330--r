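# paircomm

Ligand-receptor crosstalk inference from bulk RNA-seq of cocultured cell
populations.

## The problem

When two cell types that talk to each other in vivo — here dermal papilla
cells (DPCs) and hair matrix cells (HMCs) of the hair follicle — are grown
alone and in direct coculture, the transcriptional response to coculture
carries the signature of their communication. `paircomm` turns a
gene-by-sample read-count matrix from such a design (2 cell types × 2
culture conditions × n replicates) into:

1. **Differential expression** per contrast, with a negative-binomial Wald
   test (median-of-ratios normalization, moderated method-of-moments
   dispersion, Benjamini-Hochberg FDR) and the conventional DEG rule
   |log2FC| ≥ 1 with adjusted p < 0.05;
2. **Role screening** of DEGs against a CellTalkDB-dialect ligand-receptor
   table and a transcription-factor catalog, plus cell-type signature genes
   from the between-coculture contrast;
3. **Scored ligand-receptor pairs** under two complementary strategies —
   strategy 1 pairs upregulated ligands and receptors from the
   coculture-vs-monoculture contrasts of sender and receiver; strategy 2
   splits the single contrast between the two cocultured cell types into a
   sender side and a receiver side. Every pair gets a communication score

   CS = FC_ligand × FC_receptor

   (linear fold changes), and pairs are classified autocrine or paracrine
   by whether sender and receiver coincide;
4. **Signaling axes** ligand → receptor → signaling protein(s) → TF, found
   by depth-bounded simple-path search over a user-supplied directed
   signaling network, restricted to genes expressed in the receiver cell
   and ending at TFs upregulated there; plus degree-based TF hub ranking
   and a hypergeometric gene-set enrichment utility.

A negative-binomial simulator generates the full 4-group design with
planted cell-type signatures, coculture-induced effects and known
ground-truth pairs and axes, so the whole pipeline is testable end to end
without any external download.

## Worked example

```r
library(paircomm)

sim <- simulate_experiment(sim_config(seed = 42))
sim$counts
#> count_matrix: 5000 genes x 12 samples
#> groups: DPC (n=3), DPCsCO (n=3), HMC (n=3), HMCsCO (n=3)

de <- nb_wald_test(sim$counts, c("DPCsCO", "DPC"), sim$annotation)
de
#> contrast_result: DPCsCO vs DPC (4999 genes tested, 1 excluded)
#>   up: 12  down: 0  ns: 4987  (|log2FC| >= 1, padj < 0.05)

pairs <- pairs_strategy1(de, de, default_lr_fixture())
pairs
#> crosstalk_pairs: 3 scored ligand->receptor pairs
#>   modes: autocrine (3)
#>  ligand  receptor sender receiver      mode strategy fc_ligand fc_receptor
#>     LEP      LEPR    DPC      DPC autocrine        1     7.877       9.115
#>   THBS1 TNFRSF11B    DPC      DPC autocrine        1     6.884      10.427
#>     IL6      EGFR    DPC      DPC autocrine        1     7.568       8.735
#>     cs
#>  71.80
#>  71.78
#>  66.10
```

The 12 genes called up in cocultured DPCs are exactly the planted
coculture-responsive molecules; passing the same contrast as sender and
receiver yields that cell's autocrine pairs, here the planted leptin,
thrombospondin and interleukin-6 loops, ranked by communication score
(e.g. LEP up 7.9-fold and LEPR up 9.1-fold gives CS ≈ 71.8).

For the whole pipeline — simulation (or TSV inputs), FPKM, QC, three
contrasts, role screening, all eight pair tables, axis search and a
recovery report against the planted truth — use one call:

```r
run_pipeline(pipeline_config(simulate = TRUE, seed = 42), "run1")
```

or, from a shell, the wrapper `inst/scripts/run_pipeline.R` with a YAML
config. Each run writes a `manifest.json` with parameters, seed and MD5
checksums of every output; identical configurations and seeds reproduce
outputs byte for byte.

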