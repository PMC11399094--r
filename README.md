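# spatialduet

Spatially aware integration of multi-omics data measured on the same tissue
section. Spatial assays now co-profile two or more molecular layers per
capture spot — transcripts plus surface proteins (ADT), or transcripts plus
chromatin (ATAC peaks, CUT&Tag histone marks) — and each layer resolves only
part of the tissue's anatomy. `spatialduet` learns a single joint spot
embedding from all layers and their spatial coordinates, together with
per-spot attention weights that say how much each graph and each modality
contributed. It is aimed at computational biologists analysing
SPOTS / CytAssist Visium RNA+protein, Stereo-CITE-seq, or spatial
ATAC/CUT&Tag–RNA data, and at methodologists who want a transparent,
dependency-light reference implementation of dual-attention graph
autoencoders for spatial data.

## The model

For each modality *m* with processed input **H**⁰ₘ (spots × d_in), two
binary KNN graphs are built over spots — a spatial graph on coordinates
(r = 3 nearest spots) and a feature graph on the embedding (k = 20) — and
normalised as Ã = D^(−1/2)(A + I)D^(−1/2). A graph-convolution encoder with
weights shared across the two graphs yields graph-specific representations

    H_s = σ(Ã_s H⁰ W + b),   H_f = σ(Ã_f H⁰ W + b),

fused per spot by within-modality attention (eᵗᵢ = qᵀ tanh(W h ᵗᵢ + b),
α = softmax over graphs, yᵢ = Σₜ αᵗᵢ hᵗᵢ); the M modality representations
are then fused by between-modality attention of the same form into the joint
embedding zᵢ = Σₘ βᵐᵢ yᵐᵢ. Training minimises, by full-batch Adam, a
weighted reconstruction loss Σₘ γₘ‖H⁰ₘ − Ĥₘ‖²_F (graph-conv decoders on the
spatial graph) plus a correspondence loss Σₘ γ′ₘ‖Yₘ − Ŷₘ‖²_F in which Yₘ is
passed through the *other* modality's decoder–encoder, aligning the
modality-specific manifolds. The gradients are hand-derived reverse-mode in
base R (verified against finite differences); no deep-learning framework is
required.

Per-modality preprocessing follows the field's standard recipes: RNA —
library-size log-normalisation, highly variable genes, PCA; protein — CLR
per spot, PCA; chromatin — TF-IDF + LSI; all reduced to a common input
dimension min(50, feature count).

## Worked example

The package ships a simulator reproducing the benchmark design in which
modality 1 (transcriptome-like, zero-inflated negative binomial) determines
spatial factors 1, 3 and 4, and modality 2 (proteome-like, negative
binomial) alone determines factor 2 — so no single modality can recover all
domains:

```r
library(spatialduet)

sim <- generate_benchmark("default", seed = 0)   # 50 x 50 grid, 2500 spots
fit <- duet(sim$dataset, duet_config(seed = 0), n_clusters = 5)
print(fit)
#> Dual-attention spatial multi-omics integration fit
#>   2500 spots, 2 modalities (rna, adt), latent dimension 64
#>   600 epochs, final loss 159269.7416 (recon 147736.3866 + corr 11533.3550)
#>   clusters: 5 spatial domains

summary(fit)
#> 2500 spots embedded in 64 dimensions; loss 200874.0859 -> 159269.7416 over 600 epochs
#> mean within-modality attention (rows = modalities):
#>     spatial feature
#> rna   0.497   0.503
#> adt   0.496   0.504
#> mean between-modality attention:
#>   rna   adt
#> 0.524 0.476

supervised_scores(fit$clusters, sim$truth$labels)
#> homogeneity mutual_information  v_measure    AMI    NMI    ARI
#>       0.787              0.948      0.790  0.787  0.790  0.842

best_match_f1(fit$clusters, sim$truth$labels, 2)   # the protein-only factor
#> 0.847
```

The joint clustering reaches ARI 0.84 against the ground truth and recovers
factor 2 (F1 0.85), which clustering the RNA modality alone cannot (F1
0.17); the between-modality weights lean towards the RNA layer (0.52),
which carries three of the four factors. Per-cluster Moran's I of the
recovered domains (`morans_i(fit$clusters, sim$dataset$coordinates)`) is
0.70–0.82, i.e. strongly spatially coherent.

`dataset_presets("spots_spleen")` etc. return the published per-technology
training settings; `plot(fit, "loss")`, `plot(fit, "domains")` and
`predict(fit, "beta")` expose the trace, the spatial domain map and the
attention weights. A thin CLI covering `simulate`, `run` and `evaluate`
lives in `inst/cli/duet.R`.

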