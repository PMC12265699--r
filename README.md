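# chitofib

Analysis toolkit for chitosan nanofibril models and molecular-dynamics
trajectories of them, aimed at studies of how external cues (such as a
uniform electric field) remodel fibril structure and hydration.

Chitosan — β-1,4-linked D-glucosamine — self-assembles in its neutral
form into crystalline nanofibrils of hydrogen-bonded sheets. The model
system here is a fibril of **4 antiparallel sheets × 6 parallel chains ×
20 glucosamine units**, built on the anhydrous chitosan unit cell
(P2₁2₁2₁, a = 8.129, b = 8.347, c = 10.311 Å). The package provides:

- **crystal builder** — P2₁2₁2₁ symmetry expansion of an asymmetric
  unit, lattice tiling into an oriented fibril with a full
  sheet/chain/residue topology map (and a packaged idealized
  glucosamine template, so everything runs without any download);
- **hydrogen bonds** — geometric detection (donor–acceptor distance
  < 3.5 Å and donor–H–acceptor angle > 135°, vertex at the hydrogen,
  minimum-image aware) with topological classification into
  intra-chain, intra-sheet, inter-sheet, chitosan–water and
  water–water, named-pair occupancies (O3′H–O5, O6H–O3′, N′H–O6,
  N′H–O4) and the fraction of maximal inter-chain H-bonds;
- **hydration** — bound (< 3.5 Å) / bulk (≥ 10 Å) water classes,
  interior-water counts in the slab between the two interior sheets,
  and water-bridged H-bonds (one water simultaneously bonded to two
  chitosan atoms; a water with n partners yields C(n,2) bridges);
- **geometry** — convex-hull volume by simplex decomposition
  (Vol = Σ |det(v₁−v₀, v₂−v₀, v₃−v₀)|/3!) with ΔVolume = Vᵢ − V₀
  against a reference state, end-to-end distances (O4 of unit 1 to O4
  of unit 20), heavy-atom RMSF after Kabsch superposition,
  sheet-stacking distance (COM–COM of the middle chains of sheets 2
  and 3) and the sheet-growth dimension;
- **dipoles** — μ = Σqᵢrᵢ from a plain-text charge table, chain-dipole
  angle against the chain vector (COM of unit 2 → unit 19), net fibril
  dipole (zero for an even number of antiparallel sheets), and
  water-dipole orientation distributions with a maximum-likelihood
  estimator for the axial concentration κ in
  P(θ) ∝ sin θ · exp(κ cos θ);
- **synthetic data** — a trajectory generator that plants every one of
  these observables geometrically (H-bonds by moving donor hydrogens
  into or out of criterion geometry, waters at bridge sites and in the
  interior slab, a stacking schedule, field-aligned bulk dipoles) and
  records the ground truth, so each estimator is validated by
  parameter recovery;
- **I/O and CLI** — PDB (multi-model), mmCIF (read), DCD (read/write,
  streaming), a JSON topology sidecar, tidy CSV outputs, JSON run
  manifests, and a `build | simulate | analyze | report` command-line
  surface.

## Worked example

```r
library(chitofib)

fib <- build_fibril()          # 4 x 6 x 20 default
fib$structure
#> <cf_structure> 6720 atoms, 24 chains, 0 waters
fib$topology
#> <cf_topology> 24 chains in 4 sheets x 6 chains, dp 20

# paired synthetic trajectories emulating field-off / field-on dewetting
sc <- generate_dewetting_scenario(fib, n_frames = 30, seed = 1)

occ <- hbond_occupancy(sc$field_on$trajectory, fib$topology,
                       instances = sc$field_on$truth$instances)
occ$table
#>      pair    category occupancy mean_count n_frames n_instances
#> 1 O3'H-O5 intra_chain    0.7957      362.8       30         456
#> 2 O6H-O3' intra_chain    0.0802       36.6       30         456
#> 3  N'H-O6 intra_sheet    0.5836      145.9       30         250
#> 4  N'H-O4 inter_sheet    0.6370      133.8       30         210

d_off <- sheet_stacking_distance(sc$field_off$trajectory, fib$topology)
d_on  <- sheet_stacking_distance(sc$field_on$trajectory,  fib$topology)
mean(d_on$stacking_distance) - mean(d_off$stacking_distance)
#> [1] -0.5008  # planted mean contraction: -0.500
```

The occupancies recover the planted per-frame formation probabilities
(0.80, 0.08, 0.58, 0.63 in the field-on arm), and the stacking
contrast recovers the planted schedule mean. Real MD observables are
analysed the same way after `read_pdb()` / `read_dcd()`.

From the shell:

```sh
Rscript inst/scripts/chitofib build --sheets 4 --chains 6 --dp 20 \
    --cell 8.129,8.347,10.311 -o fibril.pdb
Rscript inst/scripts/chitofib simulate --scenario --frames 50 --seed 1 -o sim/
Rscript inst/scripts/chitofib analyze all --traj sim/field_on.pdb \
    --topology sim/topology.json -o analysis/
Rscript inst/scripts/chitofib report --results analysis/ -o report/
```

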