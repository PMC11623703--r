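# dfmol — discrete flow matching for 3D de novo molecule generation

`dfmol` is an R toolkit for studying **discrete flow matching (DFM)** on 3D
molecules. Generating a molecule means jointly generating continuous data
(atom coordinates) and categorical data (atom types, formal charges, and a
bond order for every atom pair). Flow matching handles the continuous part
naturally; for the categorical part several competing formulations exist,
and this package implements four of them behind one interface so they can
be trained, sampled and compared under identical conditions:

| Variant      | State space                  | Prior                  | Path / sampler                                 |
|--------------|------------------------------|------------------------|------------------------------------------------|
| `continuous` | R^D                          | standard Gaussian      | linear interpolant, Euler on (x̂₁ − x_t)/(1−t) |
| `simplex`    | probability simplex          | uniform on simplex     | linear interpolant (convexity keeps it closed) |
| `dirichlet`  | probability simplex          | uniform on simplex     | Dir(1 + β(t)·onehot(x₁)) paths, mixture field  |
| `ctmc`       | discrete classes + MASK      | all-MASK               | absorbing unmask jumps at rate dt/(1−t)        |

A molecule is a fully connected graph `g = (X, A, C, E)`; conditional
probability paths factorize over modalities, one small **denoiser** network
predicts the final molecule `ĝ₁(g_t)` from the current state, and training
minimizes the weighted joint objective
`L = η_X L_X + η_A L_A + η_C L_C + η_E L_E` (mean-squared error for
continuous-state modalities, cross-entropy for CTMC). Positions always use
the Euclidean flow; generation is Euler integration with evenly spaced
steps (default 100).

Around the generative core the package provides:

* **Molecule data model + SDF I/O** (V2000 write, V2000/V3000 read, formal
  charges via `M CHG`, explicit "none" bond class so the edge set is total);
* **Quality metrics**: valency-based stability (pure R), RDKit
  default-sanitization validity, MMFF94 single-point energy Jensen–Shannon
  divergence, SMARTS structural-alert rates (Dundee/Glaxo-style catalogs as
  TSV), out-of-distribution ring-system rates against a reference census,
  with 95% confidence intervals over repeated batches;
* **Assignment-time diagnostics**: for each atom, when its categorical
  state becomes final in `g_t` versus in `ĝ₁(g_t)` — the mechanism behind
  the performance gap between continuous and discrete-state formulations;
* **A synthetic toy-molecule distribution** with exactly computable size
  and marginal distributions, so trained models can be scored by total
  variation without external data;
* **An ablation driver** (`run_ablation()`) and a thin command-line front
  end (`inst/cli/dfmol`).

## Worked example

Train the CTMC and fully-continuous variants on the same toy data, sample
from each, and compare:

```r
library(dfmol)

cfg   <- toy_config()
train <- generate_toy_dataset(cfg, 150, seed = 11)

ctmc <- train_toy_denoiser(train, "ctmc",       epochs = 250, seed = 1, hidden = 48)
cont <- train_toy_denoiser(train, "continuous", epochs = 250, seed = 1, hidden = 48)

for (den in list(ctmc, cont)) {
  mols <- generate(den, 25, den$size_histogram,
                   sampler_config(den$variant, n_steps = 100, seed = 101,
                                  record = "argmax"))
  st  <- stability(mols)
  tv  <- tv_to_toy(mols, cfg)
  lag <- assignment_lag(mols)
  cat(sprintf("%-10s atoms stable %4.1f%%  toy TV %.3f  assignment lag %+.3f\n",
              den$variant, st["atoms_stable_pct"], tv$combined, lag$mean_lag))
}
```

```
ctmc       atoms stable 60.3%  toy TV 0.044  assignment lag +0.304
continuous atoms stable 29.8%  toy TV 0.102  assignment lag +0.182
```

Reading the numbers: `atoms stable` is the percentage of atoms whose
(element, charge, valency) triple is chemically allowed — the trained CTMC
model produces markedly more coherent valencies than the continuous
relaxation (an untrained model of either variant sits at ~0%). `toy TV` is
the total-variation distance between the pooled atom-type/bond-order
marginals of the sample and the exact marginals of the toy distribution
(0 = perfect recovery). `assignment lag` is the mean time by which an
atom's state trails the denoiser's decision about it along the generation
trajectory.

Fixture-level metrics work on any SDF:

```r
fx <- fixtures()
validity(list(fx$benzene))        # 100
length(ring_systems(fx$biphenyl)) # 2 (two disconnected benzene systems)
atom_valency(fx$benzene, 1)       # 4 (two aromatic bonds = 1.5 each + one C-H)
```

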