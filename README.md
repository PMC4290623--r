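# homopharma

Proteins with similar binding environments are often inhibited by compounds
with similar topology, and the reverse — a fact heavily exploited in drug
repurposing and polypharmacology. `homopharma` identifies *Homopharma
groups*: sets of protein–ligand complexes that share (i) a conserved binding
environment, (ii) topologically similar bound compounds, and (iii) similar
conservation-weighted protein–compound interaction profiles. It is aimed at
structural bioinformaticians who have a query complex plus a list of
structurally matched candidate complexes (with residue correspondences) and
want to partition them into groups with a conserved sub-binding environment.

## Method

Starting from a query complex and candidate complexes:

1. **Pocket reservation.** Each candidate is rigidly superposed onto the
   query over corresponding residues (Kabsch, SVD with reflection
   correction); candidates with RMSD ≤ 3 Å are reserved.
2. **Compound reservation.** Bound compounds are compared by atom-pair (AP)
   topology descriptors — one multiset entry per heavy-atom pair, typed by
   (element, heavy-neighbour count, π-electron count) and topological
   distance — under multiset Tanimoto similarity
   T(A,B) = Σ<sub>p</sub> min(a<sub>p</sub>, b<sub>p</sub>) / Σ<sub>p</sub> max(a<sub>p</sub>, b<sub>p</sub>).
   Candidates with T ≥ 0.6 to the query compound are reserved.
3. **Interaction profiles.** Protein–ligand contacts are typed geometrically
   (electrostatic ≤ 4.0 Å between opposite formal charges; hydrogen bond
   ≤ 3.5 Å between donor/acceptor; van der Waals ≤ 4.5 Å; exclusive
   precedence in that order) and recorded per multiple-sequence-alignment
   column, separately for main-chain and side-chain atoms — a binary vector
   over columns × 3 types × 2 chain parts.
4. **Conservation-weighted similarity.** With N member complexes and
   f<sub>ik</sub> the number of complexes interacting at column *i* with
   type *k*, the conservation weight is W<sub>ik</sub> = f<sub>ik</sub>/N.
   Two profiles A, B with weighted channels a<sub>i</sub> = A<sub>i</sub>W<sub>i</sub>,
   b<sub>i</sub> = B<sub>i</sub>W<sub>i</sub> score

   Sc(A,B) = Σ a<sub>i</sub>b<sub>i</sub> / (Σ a<sub>i</sub>² + Σ b<sub>i</sub>² − Σ a<sub>i</sub>b<sub>i</sub>),

   a Tanimoto form that reduces to the set Jaccard index for binary profiles
   with unit weights.
5. **Two-way hierarchical clustering.** Complexes are clustered by average
   linkage on 1 − Sc and cut at similarity 0.6 to form groups; interaction
   channels are clustered the same way for heat-map ordering.

A benchmark module builds validation groups from a complex inventory
(union-find over shared proteins/compounds, a 50% density filter, and >50%
overlap merging), labels complex pairs positive/negative, and compares
protein, compound and interaction similarity by precision/recall/F sweeps
and ROC curves. A synthetic-fixture module generates deterministic toy
pockets with planted typed contacts, compound families with controlled AP
similarity, and planted group-recovery scenarios; every statistical claim in
the test suite is exercised against these fixtures with independent oracles.

## Worked example

```r
library(homopharma)

scen <- make_homopharma_scenario(scenario_spec(seed = 42, n_groups = 2,
                                               complexes_per_group = 4,
                                               pocket_size = 10))
fit <- run_scenario(scen)   # homopharma() on the scenario's query/candidates
print(fit)
#> Homopharma result: 8 complexes in 2 group(s)
#>   dropped: 0 by RMSD filter, 0 by compound similarity
#>   group 1: cplx_g1_1, cplx_g1_2, cplx_g1_3, cplx_g1_4
#>   group 2: cplx_g2_1, cplx_g2_2, cplx_g2_3, cplx_g2_4
summary(fit)
#> 8 complexes, 2 group(s) (sizes: 4, 4)
#> mean within-group Sc:  0.950
#> mean between-group Sc: 0.000
#> dropped: 0 (RMSD), 0 (compound topology)
#> group 1: 5 conserved channel(s)
#> group 2: 5 conserved channel(s)
head(fit$conserved[["1"]])
#>   column                 channel weight
#> 1      9 electrostatic.sidechain    1.0
#> 2      1         hbond.mainchain    1.0
#> 3      7         hbond.sidechain    1.0
#> 4      5           vdw.mainchain    1.0
#> 5      3           vdw.sidechain    0.5
```

The two planted pocket families are recovered exactly: within-group
conservation-weighted similarity is ~0.95 (one planted channel was dropped
by the 5% channel noise, visible as the 0.5-weight channel), between-group
similarity is 0. `plot(fit)` draws the two-way clustered heat map;
`predict(fit, newprofile)` assigns a new complex to the closest group;
`write_groups_json()`, `write_newick()` and `write_profile()` export the
results. The same operations are available from a shell via
`inst/exec/homopharma` (subcommands `filter-complexes`, `compound-sim`,
`rmsd-filter`, `profile`, `run`, `benchmark`, `make-fixtures`).

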