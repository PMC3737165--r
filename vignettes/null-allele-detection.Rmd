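---
title: "Detecting null alleles and deletions in three-generation intercross families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting null alleles and deletions in three-generation intercross families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nullscan)
```

## The problem

A null allele at a SNP is an allele that fails to amplify in the
genotyping assay — because a deletion removes the site, because a
polymorphism sits under the probe, or because the site is effectively
triallelic. The assay cannot see the null: a heterozygous carrier `[a,0]`
is called homozygous `aa`, and a null homozygote `[0,0]` is called
missing. In family data this produces a recognisable residue of Mendelian
incompatibilities and missing-value patterns, which is exactly the residue
genotyping errors also produce. `nullscan` separates the two in
three-generation intercross families, where three properties help:

* many F2 offspring per family, so a true null in an F1 parent should
  recur across offspring rather than appear once;
* genotyped F0 grandparents, so a putative null in an F1 parent can be
  traced to a plausible grandparental source;
* several families descending from shared founders, so true nulls should
  appear in more than one family at similar rates while errors are
  family-specific.

## The observation model and the hypothesis space

All reasoning is anchored in one observation model: `[a,0]` is called
`aa`, `[0,0]` is called missing, ordinary genotypes are called faithfully,
and an observed missing call is *uninformative* (it is compatible with any
true genotype — missingness also arises for technical reasons unrelated to
nulls).

A *null hypothesis* for a (marker, family) pair assigns to each F1 parent
one of: no null; one null beside a visible allele (`[a,0]`, only possible
when the parent is called `aa` or missing); or two nulls (`[0,0]`, only
when called missing). A hypothesis is retained when

1. every F2 call can be produced by some gamete pair under the model,
2. each parent's state is transmissible from its F0 pair, where an F0
   individual called homozygous may itself be a hidden carrier passing the
   null on (the **grandparent filter**: the null's source must be called
   homozygous or missing — a called heterozygote has both alleles and no
   room for a null), and
3. at least one parent actually carries a null.

The enumeration is exhaustive over this space (at most one null per
parental chromosome), so "no hypothesis survives" is a proof that nulls
alone cannot explain the marker, not a search failure. Per hypothesis the
putative F2 carriers are the offspring whose calls *cannot* be produced
without a null gamete, plus missing offspring when both parents can
transmit a null (the `[0,0]` reading).

## Incompatibilities

One incompatibility is one (parent, offspring) pair at one marker whose
calls violate Mendelian transmission; an offspring in conflict with both
parents counts twice, and F0–F1 pairs count the same way. At a biallelic
marker every pairwise conflict is a *different homozygotes* pair. Some
violations only emerge at the trio level (for example two `11` parents
with a `12` offspring); these carry kind `other` and are attributed to the
first parent by convention, since the culprit is not identifiable — the
classifier consumes only counts and the presence of different-homozygote
pairs, so the convention has no downstream effect. Missing calls never
generate incompatibilities.

## The five classes and two error categories

Conflicted markers that admit **no** null hypothesis are genotyping
errors: `err_diffhom` when any conflict is a different-homozygote pair,
`err_other` otherwise. Null-explainable markers are graded by how much
evidence they carry:

| category | definition |
|---|---|
| class 1 | > 1 incompatibility, not explainable by one genotyping error |
| class 2 | > 1 incompatibility, explainable by one genotyping error |
| class 3 | exactly 1 incompatibility (F0–F1) and both F1 parents the same homozygote, so no F2 conflict is possible |
| class 4 | exactly 1 incompatibility where a null should have hit more offspring |
| class 5 | the missing-value or het-absence pattern (below) |
| consistent | none of the above |

"Explainable by one genotyping error" is decided by a breadth-first edit
search (`min_error_explanation()`): the smallest number of
single-genotype substitutions — any individual, including F0, replaced by
another *called* genotype — that restores full three-generation
consistency without nulls. Replacement by missing is excluded: a missing
call is a wildcard, so allowing it would erase any conflict in one step
and the notion of "one error explains it" would be vacuous. The search is
capped (default 3; the classifier only needs to distinguish one edit from
more than one) and returns `cap + 1` beyond the cap.

Class 5 needs no incompatibility. Its **missing pattern** requires more
than `min_missing` (default 5) F2 offspring missing with both parents
called homozygous or missing, and a hypothesis in which *both* parents
carry a null (each missing F2 must receive a null from each parent, and
each carrier parent must pass the grandparent filter). Markers where all,
or all but one, F2 are missing are excluded — whole-assay failure, not
inheritance, is the parsimonious reading there — and more than one F2
must be genotyped. Its **het-absence pattern** requires both homozygote
classes (> 1 offspring each), no heterozygote, one parent missing and the
other heterozygous, with a hypothesis in which the missing parent is
`[0,0]`; its F0 pair must both be called homozygous or missing since each
transmits a null.

The categories are assigned in a fixed order (errors, class 1/2, class
3/4, class 5, consistent), so they are mutually exclusive and exhaustive —
a property the test suite fuzzes.

## Integrating two families

Per marker, the per-family categories reduce to one overall category:

* two different null classes among 1–4 → the numerically lower class;
* class 4 + class 5 → class 5 (class 4 is the weakest evidence; this is
  the one exception to the lower-class rule);
* any other pair involving class 5 → the numerically lower class. How
  e.g. class 2 + class 5 should resolve is genuinely open; extending the
  lower-class rule to every pair except class 4 is this package's choice;
* null class + error or consistent → the null class;
* two error categories → `err_diffhom` whenever at least one family shows
  a different-homozygote pair, else `err_other`;
* error + consistent → the error category.

The reduction is symmetric and, for more than two families, applied
pairwise left to right; all pairwise rules are order-independent. The
`both_families` flag records whether at least two families independently
show *any* null class — that is also the numerator of the summary's
"% in both families" for null rows (for error rows: error evidence in two
families).

## The mixture model

Let a null-allele class contain true nulls, occurring at equal rates in
the two families, and a fraction $x$ of error SNPs occurring at the
family-1 : family-2 ratio $r_e$ observed for the different-homozygotes
error category. The class's family ratio is then

$$ r = (1 - x) + x \, r_e \qquad\Rightarrow\qquad x = \frac{r - 1}{r_e - 1}. $$

Estimation requires $r_e > 1$ (an error category that is not family-1
enriched gives no leverage) and is attempted for classes with $r > 1$;
$r = 1$ legitimately yields $x = 0$ and $r = r_e$ yields $x = 1$. Writing
the family-2 class count as $N + e_2$ (nulls plus errors) and the
family-1 count as $N + r_e e_2$, the estimator's target is
$x = e_2/(N + e_2)$ — the error share of the class membership as listed
in the less error-prone family. The parameter-recovery test simulates
exactly this generative process at 2,000 markers and checks the estimate
against that target within a delta-method binomial tolerance; ratios are
computed from unrounded per-family counts, while reported estimates are
rounded to integer percent and the headline null/error rates to one
decimal, the precision at which such tables are conventionally read. A
family-2 count of zero leaves the ratio undefined (`NA`, not 0) and the
estimate unavailable.

## Deletion calling

A single-marker null cannot distinguish a deletion from a probe-site
polymorphism; linked nulls at *adjacent* markers in the *same
individuals* can. Adjacency means consecutive rows of the sorted marker
map — the panel's own resolution — not a bp window. For each consecutive
pair on a chromosome and each family, the caller looks for one hypothesis
at each marker sharing a carrier F1 parent and at least
`min_f2_carriers` (default 3) common putative F2 carriers; whether the
two markers needed identical carrier sets or merely an overlap is not
specified in the source analysis, and the intersection reading is used
here. Families supporting the same pair merge into one call. Runs longer
than two markers are reported as overlapping pairwise calls flagged
`run = TRUE` rather than silently merged. Sizes are the exact bp distance
between the two markers, reported in kb to one decimal; BED output
converts the 1-based inclusive positions to 0-based half-open intervals.

## The simulator

`simulate_intercross()` is a gene-drop simulation of the study design the
method was built for: one F0 grandfather siring all F1 parents, one
grandmother shared between consecutive families, two families of 23 and
25 F2 offspring, and 10,150 markers on 28 autosomes by default. Remaining
defaults are the package's own choices of realistic values where the
design leaves them open: founder allele-1 frequencies uniform on
(0.1, 0.9); 3% of markers receive an injected null in a random founder
haplotype (of the order of the detectable rate plus transmission loss);
per-call error rate 0.002 and missingness 0.01, typical array figures;
whole-assay failure rate 0.001. Deletion runs zero one founder haplotype
across consecutive markers and are transmitted as a single linked block —
one segregation draw per meiosis per run — because candidate regions are
orders of magnitude smaller than typical recombination distances at this
family size. All randomness flows from one seed; the same configuration
and seed reproduce the output bit for bit.

What the simulator does *not* emulate, and what passing tests therefore
do not show about real data: linkage and recombination between ordinary
markers (each segregates independently); divergent founder lines (founders
are drawn from a common frequency, so line-fixed markers are rare);
structured, probe-specific error processes (errors are uniform
substitutions among the other two genotypes); informative missingness
other than nulls and whole-assay failure; and intensity-level signal, so
the cluster-plot style of validation is out of reach by construction.

## Numerical choices and degenerate inputs

* Genotype calls are unordered pairs over alleles {1, 2}; `0 0` and
  half-missing calls (one allele 0) are both read as fully missing — the
  model has no half-calls.
* Positions are 1-based bp; only BED output is 0-based half-open.
* A lookup table over the 4³ parent–parent–offspring code combinations
  decides trio consistency; missing codes are wildcards throughout.
* Classification consumes only counts, the edit-search outcome and
  hypothesis existence, so multiple surviving hypotheses need no
  tie-break; all are retained as evidence and the deletion caller
  iterates over them.
* Empty inputs (no markers, no families, empty call sets) round-trip
  through every reader/writer as valid empty files.
* Shared individuals (the grandfather, a shared grandmother) are stored
  once and referenced by id, so an edit in the error search or a truth
  assignment in the simulator affects every family consistently.

Test problem sizes are chosen to exercise the combinatorics rather than
the clock: single-marker families for the class fixtures, 25–80 marker
simulations for pipeline properties, 500 random families against the
brute-force edit oracle, 2,000 markers for mixture recovery, and ten
seeded replicates for end-to-end deletion recovery.

## Limitations

The method sees only what segregation shows: nulls in founders that were
never transmitted, or transmitted into genotype configurations that
produce no incompatibility, are invisible, so detected rates are lower
bounds. Class 4 is retained as a class but is expected to be mostly
error — that is precisely what the mixture estimate quantifies. The
deletion caller nominates candidates; it does not refine breakpoints,
annotate genes, or validate against intensity data, all of which are
downstream of this package's scope.
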