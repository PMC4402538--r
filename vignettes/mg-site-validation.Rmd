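---
title: "Validating and classifying Mg2+ sites in RNA crystal structures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating and classifying Mg2+ sites in RNA crystal structures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mgrna)
```

## Why validate at all

Mg²⁺ has the same electron count as water and Na⁺, and its X-ray
absorption edge lies outside the range of typical synchrotron
beamlines. In an electron-density map the three are indistinguishable,
so deposited RNA structures contain many magnesium ions that are
under-coordinated, displaced, or a different species altogether. What
*does* distinguish a genuine Mg²⁺ is chemistry: short, regular
Mg–O/N distances near 2.08/2.20 Å, a nearly ideal octahedron, a
bond-valence sum near the +2 oxidation state, and a B-factor consistent
with the surroundings. `mgrna` turns each of those expectations into a
quantitative test and only then asks the biological questions — which
RNA atoms coordinate the ion, in which arrangement, and whether the
arrangement matches a known binding motif.

## The model, stage by stage

### Two-step inner-sphere search

Simple distance cutoffs either miss genuine ligands in low-resolution
structures (where coordinates easily err by several tenths of an
Ångström) or, made generous, admit chemical nonsense. The two-step
search resolves the tension:

* **Step 1** accepts every O within `d_ideal_O + 0.5` = 2.58 Å and
  every N within `d_ideal_N + 0.5` = 2.70 Å, unconditionally.
* **Step 2** runs only if step 1 found fewer than six ligands. It scans
  the next 0.5 Å shell in ascending distance order and accepts a
  candidate only if
  1. it is not a second oxygen of a phosphate group that already
     contributes a ligand — a phosphate cannot chelate Mg²⁺
     bidentately;
  2. a nucleobase nitrogen is one of the six in-plane lone-pair
     nitrogens (A-N1, A-N3, A-N7, G-N3, G-N7, C-N3) — exocyclic amino
     nitrogens have no lone pair pointing at the ion;
  3. its angle at the ion with every already-accepted ligand exceeds
     50°, which keeps clashing "ligands" out.

The coordination number is simply the count of accepted ligands. We do
**not** cap CN at six: sites with CN > 6 are physically impossible for
Mg²⁺ and are retained with a flag, because they are diagnostic of
modeling errors rather than something to silently truncate.

Two choices here were genuinely open. The candidate **order** in step 2
matters because of the angle rule; we use ascending distance (ties
broken by chain, residue number, atom name), the only order that never
prefers a worse-fitting ligand to a better one. And the phosphate-group
identity behind rule (1) follows the covalent P–O bond (P within
1.9 Å), not residue numbering, so a bridging O3′ belongs to the
3′-neighbor's phosphate.

### Quality scores

With bond valences `V(d) = exp((r0 − d)/b)` (r₀ = 1.693 Å for Mg–O,
1.85 Å for Mg–N, b = 0.37 Å — the standard empirical parameterization,
exposed in `mg_config()$bv` so a custom distance–valence table can be
dropped in):

* `Qv = 1 − |ΣVᵢ − 2|/2`, clamped to [0, 1], measures agreement with
  the +2 oxidation state. Six waters at the ideal 2.08 Å give
  ΣV = 2.11 and Qv ≈ 0.946 — slightly over-bonded, as the standard
  parameterization implies for a perfect hexaaquamagnesium.
* `Qs = 1 − |ΣVᵢ·uᵢ|/ΣVᵢ` measures the symmetry of the arrangement; the
  valence-weighted unit vectors cancel exactly for an octahedron
  (Qs = 1), a five-vertex site scores exactly 0.8, and a single ligand
  scores 0. The raw vector-sum amplitude runs the wrong way (0 is
  perfect); we report the complement so that, like the other two
  scores, 1 is best.
* `Qe` compares the ion's B-factor and occupancy with a
  valence-weighted average over all non-hydrogen atoms within 4 Å
  (symmetry mates included):
  `min(O_m, O_e) · min((B_m/O_m)/(B_e/O_e), (B_e/O_e)/(B_m/O_m))`,
  which reduces to `min(B)/max(B)` at full occupancy. Weighting by the
  same exponential form (oxygen parameters for non-O/N neighbors — the
  weights only grade proximity, so the exact r₀ is immaterial there)
  makes the nearest atoms dominate.

The benchmark filter then requires an RNA-bound site, CN ∈ [4, 6],
Qv ≥ 0.5 ∧ Qs ≥ 0.6 ∧ Qe ≥ 0.5 and no non-(–N=) base nitrogen ligand.
The thresholds are configuration defaults, not constants.

### Outer sphere without explicit hydrogens

Deposited RNA structures rarely contain hydrogens, and the original
contact tools built around explicit H placement are external programs.
We use a self-contained geometric criterion instead: an inner-sphere
water and an RNA O/N form a hydrogen bond when their heavy-atom
distance lies in [2.4, 3.5] Å and the Mg–Ow–acceptor angle is at least
90°. The angle rule encodes the physics that the water's two donor
hydrogens and two acceptor lone pairs all point *away* from the ion it
coordinates; anything on the Mg-facing hemisphere cannot be
hydrogen-bonded to that water. All three numbers are configurable. This
is a deliberate, documented divergence from dot-surface contact
algorithms; it reproduces their qualitative behavior but not their
exact contact set.

Bonds aggregate into moieties — phosphate (P_out), ribose (R_out),
nucleobase (B_out) — counted once per residue part per site, and only
when that part does not itself coordinate the ion. Bridging O3′/O5′
atoms count as ribose *except* when their covalently connected
phosphate already contributes to the same site's inner or outer sphere,
in which case they fold into that phosphate moiety. Second-shell waters
are never traversed: only direct water→RNA bonds define the outer
sphere.

### Classes, types, names

Each validated site lands in exactly one class, tested in order:
another metal within 4 Å; a non-RNA, non-water inner ligand; at least
one RNA inner ligand (RNA-inner); water-only inner sphere with at least
one outer moiety (RNA-outer). Sites with neither RNA sphere are not
RNA-bound and stay unclassified.

Type names spell out the composition. RNA-inner: the O_ph count first
(with a cis/trans/fac/mer prefix when 2–4 O_ph are present, decided by
whether any O_ph pair exceeds a 135° angle at the ion), then O_r, O_b,
N_b tokens with multiplicities, joined by "•". The single most
populated branch — one O_ph and nothing else — is subdivided by the
number of outer-sphere phosphates, encoded as a `(+nP_out)` suffix so
the primary name stays comparable across branches. RNA-outer names come
directly from the moiety census (`2P_out•2B_out`). `parse_type_name()`
inverts the grammar exactly; note that four octahedral O_ph vertices
always contain an antipodal pair, so 4O_ph sites are necessarily
*trans* under the 135° rule.

### Motifs

The thirteen queries are pure predicates over a site's typed
composition plus sequence relations: "distant" means different chains
(symmetry copies of a chain count as different molecules) or a
separation of more than seven residues; "consecutive" means residues
i, i+1 of one chain. Overlapping hits are all reported — the queries
are independent, and e.g. every Y-clamp contains a 10-member-ring
phosphate pair by construction. Two readings were open: "two unrelated
10-member rings" (the 4O_ph variant) is implemented as two *disjoint*
consecutive pairs, and the purine-N7 seat's "3 or 4 downstream
phosphates" counts P_out moieties on the same chain as, and downstream
of, the lower purine.

### Normalized interaction frequencies

`F_atom(X) = p(Mg–X)/p(X)` divides the share of Mg–X interactions among
all RNA coordinating interactions in the benchmark sites by the share
of X among ligand-capable atoms (the four RNA ligand classes) in the
full dataset. Using the same atom universe in numerator and denominator
preserves the identity F = 1 ⇔ observed share equals background share,
and makes F invariant to duplicating structures — the property that
makes the statistic robust to dataset redundancy. A config switch
(`fatom_background = "all_rna_atoms"`) widens the denominator for
comparison.

## The synthetic-structure generator

`make_site_fixture()` and `make_battery()` build complete PDB files
whose ground truth is *analytic*: ligand atoms sit exactly on octahedral
vertices, every attached residue fragment points strictly away from the
ion (so no unplanned atom can enter a search shell), outer-sphere
acceptors hang radially off their water at 2.75 Å, and a covalently
linked four-nucleotide scaffold 20+ Å away satisfies the dataset
criteria without touching the site. The catalog of ~50 recipes covers
all four classes, more than twenty site types, all thirteen motifs,
CN 0–7, step-2 edge cases (same-phosphate pairs at 52°, angle-rule
rejections at 40°), partial occupancy, and two symmetry fixtures in
which one water arrives only via a lattice translation (P1) or a
two-fold screw operator (P2₁2₁2₁); for those two cells the scaffold
placement was chosen so that every symmetry image of every scaffold
atom stays more than 18 Å from the site. Identical seeds give
byte-identical files.

What the fixtures deliberately do **not** emulate: real A-form
stereochemistry (atom names and bond lengths are correct, torsions are
schematic), refinement artifacts beyond B/occupancy/coordinate jitter,
electron density, and crowded environments in which moiety assignment
is ambiguous. Passing the battery therefore demonstrates that every
*rule* is implemented exactly as specified — not that the rules
themselves are robust to all real-data pathologies. The worked-example
tests on seven public PDB entries (which require network access or a
local `tests/testthat/pdb_cache/`) are the bridge to real data.

## Numerical choices and degenerate inputs

* Hydrogens are dropped at parse time; alternate locations collapse to
  the highest-occupancy conformer (ties: first alternate id
  alphabetically).
* Symmetry operators come from REMARK 290 when present, otherwise from
  a built-in Hermann–Mauguin table of common RNA space groups; an
  unknown symbol degrades to identity-plus-lattice-translations with a
  warning, and a missing cell restricts searches to the asymmetric unit
  with a warning.
* Distance ties in candidate ordering break deterministically by chain,
  residue number, atom name, then symmetry operator — the accepted
  ligand set is invariant under atom input order.
* An empty inner sphere leaves Qv/Qs undefined (`NA`; the site fails
  the benchmark upstream); an empty 4 Å environment gives Qe = 0 with a
  warning. Qv is clamped to [0, 1] also for ΣV > 4.
* Atoms on special positions generate coincident symmetry copies; the
  neighbor search deduplicates physical positions to 10⁻³ Å.
* A placeholder `CRYST1 1 1 1 90 90 90 P 1` is treated as "no cell".

## Problem sizes in the shipped checks

The test suite and `scripts/acceptance.R` use 100-fixture batteries,
104 randomized oracle instances per oracle, and a 40-fixture battery at
0.1 Å jitter for the degradation check (the documented expectation is
≥ 95 % CN recovery; with the catalog's safety margins it sits at
100 %). These sizes give binomial noise well below the asserted
thresholds while keeping a full run in tens of seconds on one core.

## Known limitations

* The bond-valence parameterization is the standard exponential form;
  a published distance–valence lookup table would shift Qv by a few
  hundredths. The worked-example checks therefore compare at
  one-decimal precision.
* The hydrogen-bond criterion is geometric, not dot-based; outer-sphere
  moiety counts on real structures can differ near the 3.5 Å boundary.
* mmCIF support reads author ids (chain, residue numbering); label-id
  conventions are not offered.
* NMR and cryo-EM models, anisotropic B-factors and electron density
  are out of scope; metal identity is flagged, never re-assigned.
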