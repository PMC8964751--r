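# nridyn

Neural relational inference of residue–residue interaction networks from
molecular-dynamics-style trajectories, in pure R.

## The problem

Allosteric regulation — a binding event or mutation at one site changing
a protein's behaviour at a distant site — is carried by networks of
residue–residue interactions that are hard to read off a structure and
expensive to probe by simulation alone. Given only the motion of a
system (one point per residue per frame, e.g. Cα coordinates from an MD
trajectory), `nridyn` infers *which residues interact*: for every
ordered residue pair it returns a categorical posterior over K latent
edge types, where type 1 is a structural "nonedge". The learned graph is
then the substrate for downstream analyses: residue- and domain-level
interaction maps, shortest and suboptimal allosteric pathways with
betweenness centralities, and an alanine-scan stability score that can
be correlated against experimental unfolding free energies.

## The model

A variational autoencoder over discrete edge variables
`z_ij ∈ {1..K}`, trained by maximizing the evidence lower bound

```
L(Φ, θ) = E_q[ log p_θ(x | z) ] − KL[ q_Φ(z | x) ‖ p(z) ]
```

* **Encoder** `q_Φ(z_ij | x)`: a graph network on the fully connected
  residue graph. Each node's whole trajectory (position + velocity in
  x, y, z — six features per step) is embedded by a perceptron, two
  rounds of node→edge message passing with one edge→node aggregation in
  between build an embedding per ordered pair, and a softmax over K
  logits gives the posterior.
* **Sampling**: the Gumbel-softmax relaxation
  `z_ij = softmax((log q_ij + g)/τ)`, differentiable and approaching
  one-hot samples as `τ → 0`.
* **Decoder** `p_θ(x | z)`: a recurrent graph network. Per step, each
  ordered pair computes a message as the z-weighted sum of per-type
  message perceptrons (the nonedge type carries no message function);
  messages are aggregated per receiving node and gate a GRU-style
  recurrent unit together with the current input; the predicted mean of
  the next step is the current input plus an output transform, under a
  fixed-variance Gaussian likelihood.
* Defaults follow the canonical configuration: K = 4 edge types with
  prior (0.91, 0.03, 0.03, 0.03) favouring sparse graphs, τ = 0.5.

The reconstruction term is `Σ_j Σ_{t≥2} ‖x_j^t − μ_j^t‖² / (2σ²)` and
the KL term is the categorical divergence to the edge-type prior
(`Σ (log K − H(q))` under a uniform prior). Everything — including
reverse-mode automatic differentiation — is implemented in R and
verified against finite differences; see the methods vignette
(`vignettes/relational-inference-methods.Rmd`) for the model's
assumptions, tunable parameters and known limitations.

## Worked example

Interaction recovery is benchmarked on ensembles of spring-coupled
particle systems with known ground-truth graphs (`simulate_springs()`,
velocity-Verlet, energy-conserving). One window per system; held-out
systems are scored per window against their own graph:

```r
library(nridyn)
res <- benchmark_edge_recovery(seed = 1, n_systems = 300, epochs = 8)
res$accuracy_mean
res$valid_mse_first; res$valid_mse_last
```

which prints (about a minute on one CPU):

```
mean accuracy: 0.628
valid mse: 1.9 -> 0.541
```

i.e. after 8 epochs on 240 training systems the model already classifies
63% of ordered pairs correctly as edge/nonedge on unseen systems (0.5 is
chance), and validation reconstruction error has fallen almost 4-fold.
Longer training on larger ensembles improves this (e.g. ~0.74 at
40 epochs on 1000 training systems, ~0.79 at 80); the methods vignette
discusses why recovery from a *single* trajectory of a linear system is
not identifiable and how the ensemble benchmark avoids that.

The full pipeline is also exposed as a command line
(`inst/cli/nridyn.R`):

```sh
nridyn=$(Rscript -e 'cat(system.file("cli", "nridyn.R", package = "nridyn"))')
Rscript $nridyn simulate --nodes 5 --steps 2000 --seed 7 --out run/
Rscript $nridyn train --input run/trajectory.tsv --steps 200 \
        --window 30 --epochs 20 --seed 7 --out run/
Rscript $nridyn infer-edges --checkpoint run/checkpoint.json \
        --input run/trajectory.tsv --steps 200 --out run/
Rscript $nridyn pathways --input run/interactions.tsv \
        --sources 1 --sinks 5 --out run/
```

Every stage writes its artifacts, a resolved configuration and a log
under `--out`.

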