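# gnncv — graph-neural-network approximators for nucleation collective variables

Enhanced-sampling studies of nucleation need collective variables (CVs)
that measure how crystalline a particle system is — and need them with
gradients, at every MD step, because the bias force is the CV gradient.
The classical choices are expensive: the droplet-size count *n* (particles
whose smooth coordination number c\_i exceeds a threshold) and the
crystalline-domain count *n(Q6)* built from sixth-order Steinhardt bond
order parameters,

    c_i = Σ_j s(r_ij)                    s(r) = [1 − ((r−d0)/r0)^l] / [1 − ((r−d0)/r0)^m]
    q_6m(i) = Σ_j s(r_ij) Y_6m(r_ij) / Σ_j s(r_ij)
    Q6_i = Σ_j s(r_ij) Re⟨q̂_6(i), q̂_6(j)⟩ / Σ_j s(r_ij)
    n(Q6) = Σ_i F(Q6_i; σ)               F: smooth "more than σ" counter

`gnncv` implements these reference CVs with exact chain-rule gradients,
and a cheap permutation-invariant graph surrogate that learns them: node
embeddings of box-scaled coordinates, edge messages over minimum-image
displacement vectors r\_ij = x\_j − x\_i with constant edge weights, k
rounds of sum-pooled neighborhood updates, sum pooling over nodes, and an
MLP decoder trained on the cube root of n(Q6) (the crystallite radius).
A desk-scale Lennard-Jones Langevin simulator closes the loop: pulling
(moving restraint), umbrella sampling with WHAM, and well-tempered
metadynamics can all be driven by either the analytical CVs or a trained
model, so the whole train-then-bias workflow runs with no external data.

Everything is plain R (hand-coded reverse-mode gradients; no GPU, no
compiled code). See the methods vignette (`vignettes/gnncv-methods.Rmd`)
for the model, its assumptions, the numerical choices, and honest
limitations measured at desk scale.

## Worked example

Condense a droplet, label a pulling trajectory with analytical n(Q6),
train the default graph model (with rotational augmentation and
best-of-restarts, the package defaults), and check it on an independently
generated trajectory:

```r
library(gnncv)

gen  <- generate_nucleation_dataset(seed = 1211, n_frames = 150,
                                    steps_per_frame = 32)
test <- generate_nucleation_dataset(seed = 1999, n_frames = 60,
                                    steps_per_frame = 80)
fit  <- train_default_model(gen, seed = 77, epochs = 40, patience = 15,
                            n_restarts = 1)
ev   <- evaluate_model(fit$model, test$dataset, threshold_for_crystal = 0.5)
ev$pearson_r; ev$misclassified
```

prints (seeds as shown; ~12 minutes on one CPU)

```
[1] 0.9596806
[1] 0
```

i.e. the 1577-parameter model (latent dimension 8, two graph-convolution
layers, neighbor cutoff at the first RDF minimum, here r0 = 1.512) tracks
the analytical cube-root n(Q6) — labels spanning n(Q6) ≈ 12 to 110 —
across an independently generated droplet-to-crystal trajectory with
Pearson r ≈ 0.96, and never calls a non-crystalline frame crystalline.

A command-line surface (`inst/scripts/gnncv`) exposes the same pipeline
as subcommands: `rdf`, `label`, `train`, `predict`, `simulate`, `pull`,
`umbrella`, `metad`, `wham`, reading/writing extended-XYZ trajectories
and '#'-headed columnar text.

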