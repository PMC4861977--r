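# spcmodel

Multi-template protein model generation by stochastic point cloud sampling,
in R.

## The problem

Comparative (homology) modeling predicts the tertiary structure of a target
protein from the known structures of homologous *templates* and a
target–template sequence alignment. When several templates are available they
rarely agree everywhere: combining them can raise coverage and cancel noise,
but it also introduces structural inconsistency — and naive averaging of
disagreeing templates produces atom clashes and broken chains.

`spcmodel` is for structural bioinformaticians who have a target sequence, a
set of template Cα structures and an MSA relating them, and want a
full-length Cα-trace model plus a transparent account of how each template
contributed.

## The method

For each target residue *i*, the Cα positions `p_ij` of the superposed
covering templates *j* form a weighted point cloud with

- centroid `p_avg_i = (1/sw_i) Σ_j w_j · p_ij`,
- spread `wad_i = (1/sw_i) Σ_j w_j · ‖p_ij − p_avg_i‖` (the *weighted
  average distance*), where `sw_i = Σ_j w_j`.

The template weight `w_j` is the sum of five terms, each in [0, 1]: average
pairwise TM-score against the other templates, coverage, sequence identity,
a BLOSUM62 similarity term (negative scores *s* map to `e^s`, non-negative to
`s + 1`, scaled by 1/12), and `e^(−e-value)`.

Residues with `wad_i > 0.5 Å` are **unfixed**: their positions are resampled
from an isotropic trivariate normal `N(p_avg_i, wad_i² I)` under hard spatial
restraints — no two Cα closer than 3.5 Å (clash), adjacent Cα no farther than
4.5 Å (broken chain). A proposed model is accepted by a simulated-annealing
rule: downhill in energy always (temperature −1); uphill iff
`exp(−ΔE/T) > 0.5`, i.e. `ΔE < T·ln 2`, with temperature decrement
`d = 0.2·ΔE·(iter/N)`. The initial temperature and iteration count are
`clamp(1000/n_unfixed, 20, 100)`. The lowest-energy accepted model is the
prediction.

Residues covered by no template are built by constrained shell sampling
(3.5–4.5 Å from the growing anchor); an internal gap with `k` residues left
and anchor separation `d_AB` additionally restrains each new point to
`[max(3.5, dd(k−1)), max(4.5, max(3.8k, dd·k))]` of the far anchor, with
`dd = d_AB/(k+1)`. Targets whose selected templates fall into disconnected
coverage groups are split into domains, modeled separately, and rigidly
recombined by a moving–rotation search over an axis/angle grid.

## Worked example

The package ships a generator of self-contained synthetic cases (ground-truth
chain, noisy rotated templates, alignment), so everything below runs with no
downloads:

```r
library(spcmodel)
case <- make_case("multi-overlap", seed = 7)   # 60-residue target, 3 noisy templates
fit  <- spc_model(case$alignment, seed = 7)
fit
summary(fit)
```

prints

```
Multi-template Cα model for target1 ( 60 residues )
  templates selected: t3, t2, t1
  domains: 1  [1-60]
  unfixed residues: 32
  clashes (final model): 0

Template weights (five-term):
  id avg_tm coverage identity similarity e_term total
1 t1 0.7082     0.75        1     0.5556      1 4.014
2 t2 0.7379     0.85        1     0.5376      1 4.125
3 t3 0.7880     0.85        1     0.5523      1 4.190

Domains:
  D1 1-60  templates: t3,t2,t1  unfixed: 32  E: 5.796 -> 5.578  clashes: 1 -> 0
```

Reading this: all three templates were selected (t3 carries the highest
five-term weight and anchors the superposition); 32 residues had cloud spread
above 0.5 Å and were resampled; annealing lowered the pseudo-energy from 5.80
to 5.58 and removed the single clash of the initial weighted-average model.
Against the known ground truth of the synthetic case,

```r
tm_score(coef(fit), case$truth_xyz)
#> 0.903
```

`coef(fit)` returns the L×3 Cα coordinate matrix, `plot(fit)` draws the
annealing energy/clash traces, and `write_pdb_model(fit$model, "model.pdb")`
exports the trace as PDB.

A command-line wrapper is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/spcmodel.R", package="spcmodel"))')" \
    model --alignment case/alignment.fasta --output model.pdb --seed 7 \
    --report report.json --trace trace.tsv
```

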