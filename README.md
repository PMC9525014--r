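# binsage

Assembly-graph-aware metagenomic contig binning in R.

Metagenome assembly produces thousands of contigs from an unknown mixture
of genomes; *binning* groups them into putative genomes (MAGs). Most
binners use only contig-intrinsic signals — tetranucleotide composition and
read depth across samples — and ignore the assembly graph, whose
read-supported links between contigs are direct evidence that two
sequences come from the same genome. `binsage` combines both: it embeds
each contig's intrinsic features with a variational auto-encoder (VAE),
refines the embeddings with a GraphSAGE-style graph neural network trained
on the assembly graph with coverage-weighted edge sampling, and clusters
the concatenated embeddings with iterative medoid clustering. It is aimed
at long-read (e.g. Flye) assemblies whose GFA files carry per-edge read
coverage, and at anyone who wants a transparent, dependency-light R
implementation of graph-aware binning to study or extend.

## The model

Contig features are canonical tetranucleotide frequencies (136
dimensions, z-scored) plus per-sample depths (sum-normalized across
samples). The VAE encodes these into a latent vector per contig with a
two-part reconstruction loss — 10% weight on composition, 90% on
abundance — plus a KL divergence penalty toward N(0, I).

For the graph stage, an assembly graph G = (C, A) has A_uv = rc(u, v),
the read coverage of the link between contigs u and v. Positive training
edges for contig u are drawn with probability proportional to rc;
neighbor negatives with probability proportional to 1/rc (low-coverage
links are the likely inter-genome artifacts), mixed with random
non-neighbors; disconnected contigs draw random negatives. Each GraphSAGE
layer computes `h' = act(W [h_u || mean(h_neighbors)])`, and the final
layer's output z is trained with the coverage-scaled objective

    J(z_u) = -rc_norm(u, v) * log sigma(z_u . z_v)
             - Q * E_{vn ~ Pn} [ log sigma(-z_u . z_vn) ]

where rc_norm is the edge coverage divided by the graph-wide maximum and
Q is the number of negatives per positive. High-coverage links therefore
pull embeddings together strongly; dubious links barely matter.

The VAE and GNN embeddings are L2-normalized per block, concatenated and
clustered by iterative medoid clustering under cosine distance: grow a
bin around a density-optimal medoid within a radius picked from the
valley of the pairwise-distance histogram, repeat until every contig is
assigned. No cluster count is required. Bins can be scored against
single-copy marker genes (completeness / contamination, used to pick the
best training checkpoint) or against gold labels (bp-weighted purity,
completeness, F1, and HQ bins: >90% completeness and <5% contamination,
strict).

## Worked example

All inputs can be generated synthetically, so the example runs anywhere:

```r
library(binsage)

comm <- generate_community(stress_profile("easy", seed = 1))
res <- run_pipeline(
  gfa     = comm$files$gfa,
  depth   = comm$files$depth,
  markers = comm$files$markers,
  labels  = comm$files$labels,
  outdir  = "binsage_out",
  seed    = 1,
  vae     = vae_config(epochs = 200, seed = 1),
  gnn     = gnn_config(epochs = 40, seed = 1)
)
res
#> <pipeline_result> 100 contigs, 5 bins, ARI 1.000
glance(res$label_metrics)
#> # A tibble: 1 x 6
#>   average_purity average_completeness    f1 hq_count mq_count n_bins
#>            <dbl>                <dbl> <dbl>    <int>    <int>  <int>
#> 1              1                    1     1        5        5      5
```

The community plants 5 genomes split into 100 contigs with a
coverage-weighted assembly graph; the pipeline recovers all five as
high-quality bins (adjusted Rand index 1.0 against the planted labels)
and writes `bins.tsv` (contig → bin), the VAE/GNN loss traces and a
metrics table into `binsage_out/`. `autoplot(res$vae_fit)`,
`plot_embedding(res$embedding, color = res$bins)` and
`plot_bin_quality(res$label_metrics)` visualize training and results.

A thin command-line wrapper is included:

```sh
exec/binsage --graph assembly.gfa --depth depth.tsv --outdir out --seed 1
exec/binsage --profile easy --outdir demo --seed 1   # synthetic demo
```

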