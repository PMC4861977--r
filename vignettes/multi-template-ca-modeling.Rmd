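---
title: "Multi-template Cα modeling by stochastic point cloud sampling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-template Cα modeling by stochastic point cloud sampling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spcmodel)
```

## The model

`spcmodel` generates a Cα-trace model of a target protein from one or more
aligned template structures. Its central object is the per-residue *weighted
point cloud*: after the selected templates are rigidly superposed into a
common frame, the Cα atoms they contribute at target position $i$ form a
point set $\{p_{ij}\}$ with per-template weights $w_j$, summarized by

$$p^{avg}_i = \frac{1}{sw_i}\sum_j w_j\, p_{ij}, \qquad
  wad_i = \frac{1}{sw_i}\sum_j w_j\, \lVert p_{ij}-p^{avg}_i\rVert,
  \qquad sw_i=\sum_j w_j .$$

$wad_i$ (the weighted average distance) measures how much the templates
disagree about residue $i$. Residues with $wad_i \le 0.5$ Å are treated as
*fixed* at $p^{avg}_i$; residues with $wad_i > 0.5$ Å (strictly) are
*unfixed* and are resampled during optimization from an isotropic trivariate
normal $\mathcal N(p^{avg}_i,\; wad_i^2 I_3)$ — zero covariance between
coordinates by construction.

Key modeling assumptions:

* templates are pre-aligned to the target by sequence (we never do
  structure-based sequence alignment); after trimming, every template residue
  carries a target index and the template's own numbering is discarded;
* only Cα atoms are modeled; backbone completion and side chains are outside
  the package (hooks for external tools exist on the CLI);
* a model is physically acceptable when no two Cα are closer than 3.5 Å
  (clash) and consecutive Cα are no farther than 4.5 Å (broken chain).

## Template weighting, selection, filtering

Each template's weight is the sum of five terms, each in $[0,1]$: average
pairwise TM-score against the other templates, coverage, sequence identity,
a BLOSUM62-based similarity (a pairwise score $s<0$ maps to $e^s$, $s \ge 0$
to $s+1$, scaled by $1/12$ — the Trp–Trp maximum of 11 then scores exactly
1), and $e^{-\text{e-value}}$ (missing e-values count as 0, i.e. the term is
1). The raw terms are summed without re-normalization. With a single
template there are no TM-score peers; its average TM term is set to 1 so the
total remains comparable.

Selection keeps the top-weight template and then, scanning the rest in
descending weight, any candidate that either covers ≥ 10 contiguous target
residues nobody covers yet or has TM-score > 0.7 with the top template.
Selected templates are superposed within each overlap-connected group: the
group's highest-weight member is the center; every other template is fitted
over the residues it shares with its anchor (the center when possible,
otherwise the already-placed template sharing the most residues). We center
*per group* rather than globally because templates of different domains share
no residues with a single global center and would otherwise be unplaceable —
per-group centering feeds domain division exactly the frames it needs.

The superposition itself is a TM-score-style trimmed fit (`tm_superpose`):
Kabsch seeds on all shared residues and on contiguous windows, each iterated
by restriction to residues within $d_0$, keeping the highest-scoring
transform. The window seeds matter: a plain Kabsch frame is dragged by a
structurally inconsistent fragment, while a window inside the agreeing part
anchors the fit correctly. This mirrors the behavior of the reference
TM-score superposition program; small numeric differences from that program
are expected.

After superposition, structurally inconsistent regions are deleted: for each
non-top template, each maximal contiguous run of residues shared with
another selected template must reach TM-score 0.7 against at least one other
template. An inconsistent run longer than 5 residues is bisected and the
halves re-tested recursively, so a localized disagreement is removed without
discarding the agreeing remainder — the natural reading of "remove the
inconsistent region", since an all-or-nothing rule would delete whole
templates over a short damaged stretch. Sole-coverage residues are never
tested (removing them would orphan target positions).

## Optimization

The initial model takes $p^{avg}_i$ at covered residues; gaps are built once
at initialization (below) and frozen. Annealing then iterates:

1. **propose** — visit unfixed residues in ascending index; for each, draw up
   to 100 candidates from its cloud distribution and install the first one
   satisfying the clash/chain restraints against the *current working model*
   (so later residues see earlier moves); a residue with no valid candidate
   stays put;
2. **score** — a pluggable energy. The default is an intentionally simple
   Cα pseudo-energy: $\sum_{adj}(d-3.8)^2 + \sum_{nonadj}\max(0, 4.0-d)^2 +
   0.01\,(R_g - 2.2L^{0.38})^2$ — bond regularity, soft-sphere repulsion, and
   a weak radius-of-gyration restraint with the empirical globular scaling.
   It is deterministic and rigid-motion invariant. Any statistical potential
   can be plugged in via `energy_backend("external:<cmd>")`, which writes a
   PDB and reads one number from the command's stdout;
3. **accept** — downhill always (temperature drops by 1); uphill iff
   $e^{-\Delta E/T} > 0.5$, a deterministic threshold equivalent to
   $\Delta E < T\ln 2$; the uphill temperature decrement is
   $d = 0.2\,\Delta E\,(\mathrm{iter}/N)$, floored at $10^{-6}$ — positive,
   about 1 for a "basic" $\Delta E$ of 5, and growing through the run so the
   schedule accelerates. It is applied whether or not the uphill move is
   accepted.

$T_0 = N = \mathrm{clamp}(1000/n_{unfixed}, 20, 100)$ by default (a value
that may be fractional; the loop then runs $\lceil N\rceil$ iterations), or
$n_{unfixed}\cdot m$ with a user multiplier $m\in[1,500]$. The loop stops at
the iteration budget or when $T\le 0$. The reported model is the
lowest-energy accepted one (the initial model included); the last accepted
model is also kept on the result. A region covered by exactly one template
skips sampling entirely and copies the template backbone verbatim.

## Gaps and domains

Uncovered residues are grown by shell sampling: direction uniform on the
sphere, radius uniform in [3.5, 4.5] Å — the paper-level description
("sample points around A") leaves the distribution open, and the uniform
shell is the least-informative choice consistent with the restraints. Each
placement gets a budget of 500 draws; if none is clash-free, the candidate
with fewest clashes wins (ties to the larger minimum distance). Internal
gaps additionally restrain each point to
$[\max(3.5,\, dd(k-1)),\ \max(4.5,\, \max(3.8k,\, dd\,k))]$ of the far
anchor ($k$ residues remaining, $dd = d_{AB}/(k+1)$) — with $k=1$ this
collapses to [3.5, 4.5] on both sides, closing the chain. Gaps are built
once, N→C, and frozen during annealing: the cloud distributions are defined
only for covered residues, so resampling gap residues would have no
distribution to draw from.

When the selected templates split into groups sharing no residues, each
group's covered span becomes a domain (overlapping spans merge); an
uncovered linker between domains is divided at its midpoint, the odd residue
going left, and terminal runs attach to the adjacent domain. Domains are
modeled independently and combined left-to-right: translate the right domain
to a junction distance in [3.5, 4.5] Å; exit if the join already has < 15
inter-domain clashes, no severe clash and an intact junction; otherwise
shell-sample a junction point clash-free against the left domain (checked
against the left domain only), translate, and grid-search rotations about
the junction (axis components on a $[-1,1]$ grid of step 0.1, angles every
10°) for the fewest inter-domain clashes, stopping early at zero. "Severe
clash" is set at < 2.0 Å — left open at the method level, chosen here as the
point where Cα overlap cannot be relieved by local repacking. The left
domain's internal coordinates are never modified; the right domain moves
rigidly.

## Numerical choices and degenerate inputs

* $d_0 = 1.24(L-15)^{1/3} - 1.8$, clamped at 0.5 Å for short targets; TM
  comparisons of short filtered fragments are therefore strict.
* Cloud variance uses $wad_i^2$ on the covariance diagonal (standard
  deviation = $wad_i$ per coordinate): the stated rule — variance "set
  approximately by" the weighted average distance — does not fix the square;
  using $wad$ as a standard deviation keeps sampled displacement magnitudes
  commensurate with the observed template spread. A floor of $10^{-6}$ Å
  avoids a degenerate density.
* Kabsch on a rank-deficient (collinear) point set still returns the
  least-squares solution, flagged `degenerate`.
* Identical internal-gap anchors are an error; anchors closer than the
  nominal gap span are not (the bound formula remains defined).
* All randomness flows through R's global generator; seeding once at the
  entry point (`spc_model(..., seed = )`, `--seed`) makes whole runs
  bit-reproducible.
* GDT-TS uses one global Kabsch fit plus restarts on 20-residue windows,
  taking the best fraction per cutoff — an approximation of the full GDT
  search, used for evaluation only, never inside modeling.

## What the synthetic generator does and does not emulate

`make_case()` builds self-contained scenarios: a ground-truth chain (ideal
α-helix with 1.5 Å rise and 100°/residue — the helix radius is solved from
the 3.8 Å Cα–Cα constraint, giving ≈ 2.28 Å; a self-avoiding random walk; or
a planar zigzag whose $i,i{+}4$ spacing is exactly 8.2 Å, matching the
documented internal-gap example), plus rotated/translated noisy copies as
templates and the induced alignment. Template noise is isotropic Gaussian
with 3-D RMS displacement equal to `noise_sd` (so the Kabsch RMSD back onto
the truth ≈ `noise_sd`), followed by a bond-geometry repair that clamps
consecutive Cα distances back into [3.5, 4.5] Å — real homologous structures
diverge globally while keeping valid backbone geometry, and without the
repair a "template" can itself contain broken chains that no modeling method
should be expected to fix. The `inconsistent-template` scenario scrambles a
minority region of one template that overlaps the others, while that
template also contributes 30 residues of sole coverage — the configuration
in which region filtering, not template rejection, is the right response.

What passing these tests shows: the sampling, restraint, gap and combination
machinery behaves as specified under controlled noise. What it does not
show: performance on real homology targets — the generator produces neither
alignment errors, nor insertions/deletions, nor correlated evolutionary
divergence, nor non-globular topologies; sequence content is random, so
identity/similarity terms are exercised numerically but not biologically.

Scenario sizes are 40–112 residues with up to 3 templates, chosen so a full
end-to-end run takes about a second and the whole suite stays interactive;
the method itself has no size limit beyond the $O(L^2)$ energy and clash
checks.

## Known limitations

* The default pseudo-energy is a stand-in contract, not a statistical
  potential; model ranking beyond clash/chain quality should use an external
  scorer through the energy backend hook.
* The domain-boundary midpoint rule is a convention; biological domain
  boundaries inside an uncovered linker are not identifiable from coverage
  alone, and only the domain count is contractual.
* Filtering granularity (bisection down to 6-residue leaves) cannot isolate
  disagreements shorter than ~3 residues.
* Multi-chain targets, hetero-atoms, mmCIF input and NMR multi-model files
  are out of scope.
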