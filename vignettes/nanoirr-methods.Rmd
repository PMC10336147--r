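---
title: "Methods: neighborhood irregularity indices and nanotube lattice models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: neighborhood irregularity indices and nanotube lattice models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

A molecular graph here is a bare simple graph: atoms are vertices, bonds
are edges, with no elements, bond orders or geometry. An *irregularity
index* is an edge-additive invariant
$$I(G) = c \sum_{uv \in E(G)} f(w_u, w_v),$$
where $f$ is symmetric, non-negative, and zero on the diagonal
($f(x,x)=0$), $c$ is a rational prefactor, and $w$ is a positive vertex
weighting. `nanoirr` implements the eleven classical forms (AL, IRL, IRRT,
IRF, IRA, IRDIF, IRLF, LA, IRDI, IRGA, IRB, in that fixed order) under two
weightings: the vertex degree $d_u$, and the neighborhood degree sum
$\delta_u = \sum_{v \sim u} d_v$. The identity
$\sum_u \delta_u = \sum_u d_u^2$ (each vertex's degree is counted once by
each neighbour) links the two and is used as a property-based consistency
check throughout the tests.

Two conventions deserve a note because the printed sources are ambiguous:

* **IRGA** is read as $\sum \ln\frac{w_u+w_v}{2\sqrt{w_u w_v}}$ (log of the
  arithmetic-to-geometric mean ratio, non-negative by AM–GM). The
  alternative typography $\frac{\ln|w_u+w_v|}{2\sqrt{w_u w_v}}$ that appears
  in some derivations is treated as a typesetting artifact: only the first
  reading reproduces the published HAC5C6C7 coefficient 0.06449422104.
* **IRDI** uses the natural logarithm, $\sum \ln(1+|w_u-w_v|)$; published
  derivations work with $\ln 2$ and $\ln 3$ values.
* The leading 2 of LA and the $\tfrac12$ of IRRT are modelled as prefactors
  of otherwise shared kernels, so the exact relation
  $\mathrm{IRRT} = \mathrm{AL}/2$ holds structurally and is asserted
  exactly in the tests.

## Edge partitions as the computational core

Because every form is edge-additive, the multiset of unordered endpoint
weight pairs with multiplicities — the *edge partition* — determines every
index value. `edge_partition()` stores classes as ordered pairs
$(w_{hi}, w_{lo})$, $w_{hi} \ge w_{lo}$, sorted descending; `evaluate_index()`
sums `prefactor * freq * f(w_hi, w_lo)` in that fixed order, so a value
computed from a graph and from its extracted partition are *identical*, and
results are reproducible bit-for-bit across runs. Weights are exact
integers; contributions are evaluated in IEEE double precision with no
rounded intermediates. No computer-algebra layer is used: integer-valued
kernels (AL, IRRT, IRF) are exact in doubles, and the irrational ones carry
relative error of order $10^{-16}$, eleven orders of magnitude below the
smallest gap the audit needs to resolve (about $10^{-5}$).

Domain handling: an isolated vertex has $\delta = 0$. It never appears in
any edge, so partitions extracted from graphs contain only positive
weights; but a user-supplied partition may contain zeros, and the forms
with logs, ratios or (inverse) roots — IRL, IRA, IRDIF, IRLF, IRGA, IRB —
reject them with an error naming the index. `evaluate_all()` converts such
per-index errors into `NA` values with the message retained, computing the
remaining indices.

## The nanotube families

`HAC5C7[p,q]` and `HAC5C6C7[p,q]` are nanotube lattice graphs: `p` counts
the repeating columns around the circumference (the tube is closed, all
wiring is modulo `p`) and `q` the axial periods (the tube is open at both
ends). Both parameters must exceed 1; smaller values are rejected rather
than special-cased, because the families' partition tables are stated for
`p, q > 1`. An open boundary is what makes these graphs irregular at all:
the bulk is 3-regular with $\delta = 9$ everywhere, so the only classes
with unequal weights — the only contributors to any irregularity index —
sit in a boundary layer whose size is proportional to `p` alone. Two
consequences follow immediately and are asserted numerically in the tests:

* every index value is **independent of `q`** for fixed `p`, and
* every index has an exact **closed form `coefficient × p`**, obtained by
  summing class contributions weighted by the `p`-coefficients of the
  symbolic partition (`closed_form()`); the `pq`-coefficient is always
  zero because the lone `q`-dependent class is `(9,9)`.

### The published tables are not fully realizable — proofs

The package takes the families' published neighborhood partition tables as
authoritative for all closed forms, but an elementary counting argument
shows the accompanying structural claims cannot all hold, and the
generators follow the partitions.

**HAC5C7.** The table lists classes
$(9,9){:}\,12pq{-}9p$, $(9,8){:}\,2p$, $(9,7){:}\,p$, $(8,8){:}\,p$,
$(8,6){:}\,2p$, $(7,6){:}\,2p$. Only weights $\{6,7,8,9\}$ occur. A
degree-2 vertex has $\delta \le 6$, so in any realization with degrees in
$\{2,3\}$ every degree-2 vertex has weight exactly 6 (two degree-3
neighbours). Counting edge-endpoint slots at weight-6 vertices gives
$2p + 2p = 4p$, i.e. exactly $2p$ degree-2 vertices; weight-9/8/7 vertices
are degree 3 with $(24pq-15p)/3$, $6p/3$ and $3p/3$ members. Total:
$|V| = 8pq$, $|E| = 12pq - p$. The sometimes-quoted vertex count
$8pq + p$ would, with the same edge count and degree set, force $5p$
degree-2 vertices by the handshake identity — contradiction. The generator
therefore realizes the partition exactly on $8pq$ vertices, and
`validate_nanotube()` reports the published vertex count as a failed
*audit* row, separate from the realizable contract rows.

**HAC5C6C7.** The table lists
$(9,9){:}\,12pq{-}9p$, $(9,8){:}\,4p$, $(8,8){:}\,2p$, $(8,7){:}\,2p$,
$(8,6){:}\,4p$, $(7,6){:}\,4p$. Weight-8 slots total
$4p + 4p + 2p + 4p = 14p$, so there are $14p/3$ weight-8 vertices; but a
weight-8 vertex of degree 3 has neighbour degrees $(2,3,3)$ — exactly one
degree-2 neighbour — so the $(8,6)$ frequency also counts the weight-8
vertices: $4p \ne 14p/3$. *No* graph with degrees in $\{2,3\}$ realizes
this table, for any `p`. Replacing the single class $(8,7){:}\,2p$ by
$(9,7){:}\,2p$ — the class the sibling family's table has in that position —
restores all integrality and incidence constraints while preserving every
other frequency and the $12pq+7p$ edge total, and is the unique such
single-class repair; the generator builds that. The realized graph has
$8pq + 6p$ vertices, and its AL/IRRT/IRF values are $20p/10p/32p$ rather
than the published $18p/9p/26p$ — the package reports closed forms from the
published table (`realized = FALSE`, default) and from the generator's
partition (`realized = TRUE`) separately, and the validator flags the
discrepancy.

### Construction

Neither family's drawing can be copied faithfully (see above), so the
generators are *partition-faithful by construction*: layered unit cells
stitched modulo `p`, with boundary decoration chosen so that the degree
and neighborhood-weight classes come out exactly.

* HAC5C7: eight roles per column per period (`b, s, x, y, z, w1, w2, t`),
  twelve bonds per cell of which one crosses to the next period; cutting
  that bond at the two open ends leaves one degree-2 vertex per column per
  end, with the `s` row (weight 7) adjacent to two of them at the bottom
  and the paired `w` rows (weight 8) at the top.
* HAC5C6C7: a 3-regular bulk of $4p(2q-1)$ vertices (roles `a, b, c, d`
  per column per layer) leaving three bond stubs per column at each end,
  each end decorated with a five-vertex gadget per column (one weight-7
  vertex bridging two degree-2 vertices, plus an adjacent weight-8 pair).

The constructions are *not face-faithful*: they reproduce the families'
degree and weight structure (hence every index) exactly, but not the
pentagon/hexagon/heptagon face pattern of the drawings — for `p >= 3` the
shortest cycles are pentagons, while at the degenerate circumference
`p = 2` four-cycles appear, as in any nanotube model that thin. Since
every quantity this package computes is a function of the edge partition,
face structure is immaterial here. Rotating the circumferential origin is
an automorphism up to relabelling; the tests assert isomorphism and
identical partitions under rotation.

## The audit

`errata_report()` recomputes each family's eleven coefficients exactly and
compares them with the published values at an absolute tolerance of
`1e-3`. That threshold is not tunable folklore: published derivations
round intermediates to 6–8 significant digits, leaving honest gaps of
order $10^{-6}$ to $10^{-4}$, while the genuine slips are of order
$10^{-2}$ to $1$ — the two populations are separated by more than an order
of magnitude on both sides. The audit flags exactly two errata:

* HAC5C7 IRGA: published 1.26918503, exact
  $2\ln\frac{17}{2\sqrt{72}} + \ln\frac{16}{2\sqrt{63}} +
   2\ln\frac{14}{2\sqrt{48}} + 2\ln\frac{13}{2\sqrt{42}} \approx 0.0378944$
  (the published derivation mis-assembles its own per-class terms);
* HAC5C6C7 IRDI: published 8.553331516, exact
  $10\ln 2 + 4\ln 3 \approx 11.3259$ (the published numeric sum drops the
  final $4p\ln 2$ term);

plus one statement/derivation conflict: the HAC5C6C7 IRL headline `9p`
disagrees with its own worked derivation `2.505525927p`; the derivation
value is adopted as the comparator since it is what the published numeric
grid tabulates. The published comparison grids reproduce to their printed
two decimals within ±0.01 *except* the columns built on the two errata,
one grid cell printing 65.04 where 5.01 is meant, and four further cells
of the first family's table (IRL at `p=5,6`, IRLF at `p=4`, IRB at `p=6`)
that disagree with their own column's coefficient — the test suite keeps
those assertions failing as documentation of the published typos.

## Problem sizes and numerical checks in the tests

Structural invariants are checked for $(p,q) \in \{2..5\}^2$ (graphs up to
335 edges; generation is milliseconds). Closed-form/graph agreement is
asserted to $10^{-9}$, partition-vs-graph evaluation to exactly 0, and the
independent naive edge-loop oracle to $10^{-12}$. Oracle equivalence runs
exhaustively over all $2^{10}$ labelled graphs on five vertices (subsampled
deterministically in the long acceptance loop) plus seeded random graphs on
six and seven vertices; the first-Zagreb identity is asserted on 200 random
graphs. All randomness is seeded, so runs are reproducible.

## Limitations

* The generators model the families' *partition structure*, not their
  embedding; no coordinates, faces or torus variants are produced.
* Published-value comparisons cover the two families shipped; the index
  engine itself is generic and works on any simple graph or partition.
* Degree weighting is fully supported in the engine, but closed forms and
  audits are provided only for the neighborhood weighting, which is the
  weighting the published coefficient tables concern.
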