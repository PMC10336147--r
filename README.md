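# nanoirr

Irregularity indices are edge-additive topological descriptors of molecular
graphs: each edge `uv` contributes a symmetric, non-negative term that
vanishes when the two endpoint weights agree, so the index measures how far
the graph is from regular. They are used as QSPR/QSAR descriptors in
chemical graph theory. `nanoirr` evaluates eleven such forms

| name | per-edge contribution | | name | per-edge contribution |
|------|----------------------|-|------|----------------------|
| AL   | &#124;w_u − w_v&#124;            | | IRLF | &#124;w_u − w_v&#124; / √(w_u w_v) |
| IRL  | &#124;ln w_u − ln w_v&#124;      | | LA   | 2 &#124;w_u − w_v&#124; / (w_u + w_v) |
| IRRT | ½ &#124;w_u − w_v&#124;          | | IRDI | ln(1 + &#124;w_u − w_v&#124;) |
| IRF  | (w_u − w_v)²          | | IRGA | ln[(w_u + w_v) / (2 √(w_u w_v))] |
| IRA  | (w_u^−½ − w_v^−½)²    | | IRB  | (√w_u − √w_v)² |
| IRDIF| &#124;w_u/w_v − w_v/w_u&#124;    | | | |

under two vertex weightings: the classical degree `d(u)`, and the
neighborhood degree sum `δ(u) = Σ_{v~u} d(v)` (whose vertex total equals the
first Zagreb index `Σ d(u)²`). Because every form is edge-additive, the
*edge partition* — the multiset of unordered endpoint-weight pairs with
their frequencies — is a sufficient statistic, and the package evaluates
indices either from a graph or directly from a partition.

The package also ships:

* **generators** for the `HAC5C7[p,q]` and `HAC5C6C7[p,q]` pentagon/heptagon
  nanotube lattice graphs (circumference `p`, axial periods `q`, tube closed
  around `p`, open along `q`), built so that their neighborhood edge
  partitions are realized *exactly*, plus `validate_nanotube()` which checks
  every structural invariant;
* **exact closed forms**: for both families every class frequency is affine
  in `pq` and `p`, and the only `q`-dependent class is `(9,9)` which
  contributes nothing, so each index equals `coefficient × p`;
  `closed_form()` derives the coefficients in full precision;
* an **audit** (`errata_report()`, CLI `verify`) comparing the exact
  coefficients against the published values — two published coefficients are
  genuine arithmetic errata (HAC5C7 IRGA, HAC5C6C7 IRDI) and one published
  headline (HAC5C6C7 IRL = 9p) conflicts with its own derivation
  (2.5055p);
* reproduction of the published comparison grids
  (`index_grid()`, `published_grid()`, `compare_with_published()`).

A structural caveat the package documents rather than hides: the published
description of these families is internally inconsistent. The stated HAC5C7
vertex count `8pq + p` is incompatible with the family's own edge-partition
table (the handshake identity forces `8pq` vertices and `2p` vertices of
degree 2), and the HAC5C6C7 table is not realizable by *any* graph with
degrees in {2, 3}; the generator realizes the unique single-class graphical
repair, `(8,7) → (9,7)`. The methods vignette
(`vignettes/nanoirr-methods.Rmd`) carries the proofs.

## Worked example

Azulene (a pentagon and a heptagon sharing a bond — the repeating motif of
the C5C7 net) is shipped as a fixture:

```r
library(nanoirr)
g <- read_molgraph(system.file("extdata", "azulene.edgelist", package = "nanoirr"))
neighborhood_weights(g)
#> 0 1 2 3 4 5 6 7 8 9
#> 5 4 5 7 7 5 4 4 4 5
edge_partition(g)
#>   w_hi w_lo freq
#> 1    7    7    1
#> 2    7    5    4
#> 3    5    4    4
#> 4    4    4    2
evaluate_all(g, "neighborhood")[c("index", "value")]
#>    index       value
#> 1     AL 12.00000000
#> 2    IRL  2.23846315
#> 3   IRRT  6.00000000
#> ...
```

The two bridgehead atoms have `δ = 7`, the ring atoms 4 or 5; the Albertson
index 12 sums the weight gaps over the 11 bonds, and `IRRT = AL/2 = 6`.

For the nanotube families:

```r
tube <- hac5c7_graph(4, 4)     # 128 vertices, 188 edges
evaluate_index(tube, "IRF")    # 64  = closed-form coefficient 16 times p = 4
subset(errata_report("HAC5C7"), verdict == "erratum")
#>    index   computed published abs_diff verdict
#> 10  IRGA 0.03789441  1.269185 1.231291 erratum
index_grid("HAC5C7", pmax = 3)  # closed-form grid, full precision
#>   p q      source AL      IRL IRRT IRF        IRA    IRDIF     IRLF ...
#> 1 1 1 closed_form 10 1.370546    5  16 0.01062692 2.765873 1.373636
#> 2 2 2 closed_form 20 2.741092   10  32 0.02125385 5.531746 2.747271
#> 3 3 3 closed_form 30 4.111638   15  48 0.03188077 8.297619 4.120907
```

The same operations are available from a shell via the thin front end:

```sh
Rscript exec/nanoirr generate --family hac5c7 --p 4 --q 2 --output tube.edgelist
Rscript exec/nanoirr compute  --input tube.edgelist --weighting neighborhood
Rscript exec/nanoirr grid     --family hac5c7 --pmax 6 --presentation
Rscript exec/nanoirr verify   --family hac5c6c7
```

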