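# rwibald

Branch-level classification of phylogenetic endemism: which branches of a
phylogeny contribute the most to phylogenetic endemism (PE), and whether
each of them represents **neo-**, **meso-**, or **paleo-endemism**.

Location-based methods such as CANAPE classify *grid cells* as centers of
endemism but summarize away which lineages are responsible.  This package
scores and classifies the *branches* themselves, so endemism type becomes
a per-branch trait that can be mapped onto the tree, used in phylogenetic
comparative methods, and drilled into per grid cell.  It is aimed at
spatial phylogenetics: researchers with a rooted phylogeny (phylogram or
chronogram) and taxon occurrences on equal-area grid cells.

## The method

Let `L_b` be the observed length of branch `b` (every non-root lineage
segment, terminal or internal), `T = sum(L_b)` the total tree length over
the `n` branches, and `r_b` the branch's range size — the number of grid
cells occupied by the branch, where an internal branch's range is the
union of its descendant terminals' ranges.  Four branch-length vectors
are compared:

* observed tree (OT): `L_b`
* comparison tree (CT): every branch gets the equal share `T / n`
* range-weighted observed tree (RWoT): `L_b / r_b`
* range-weighted comparison tree (RWcT): `(T / n) / r_b`

The per-branch scores are

```
RWiBaLD(b) = L_b / r_b - (T/n) / r_b        (range-weighted difference)
BaLD(b)    = L_b - T/n                      (unweighted difference)
```

so `RWiBaLD = BaLD / r` identically: range weighting shrinks the scores
of widespread branches toward zero, and what remains at the extremes is
driven by range-restricted branches.  Negative scores point toward
neo-endemism (restricted branches shorter than expected), positive toward
paleo-endemism (longer than expected).

Classification proceeds in three data-driven thresholding steps, each an
*elbow* (maximum Euclidean distance) cut on a ranked curve: rank the
values, draw the chord from the first to the last point, and cut at the
point farthest from the chord.

1. **Highly endemic branches** — rank all branches by RWcT length
   (equivalent to inverse range size) and keep branches at or above the
   elbow value.
2. **Score cutoffs** — apply the same elbow statistic separately to the
   positive and the negative halves of the RWiBaLD distribution (all
   branches; exact zeros belong to neither half), giving a paleo cutoff
   (>= 0) and a neo cutoff (<= 0).
3. **Categories** — a highly endemic branch is *neo* if its score is at
   or below the neo cutoff, *paleo* if at or above the paleo cutoff, and
   *meso* (range-restricted but of unremarkable length — a category
   invisible to methods that only contrast neo with paleo) in between.

## Worked example

Scores on a four-branch tree, by hand-checkable arithmetic
(`T = 10`, `n = 4`, so every comparison length is `2.5`):

```r
library(rwibald)
tree <- read_phylogeny("((A:1,B:2):3,C:4);")
occ <- occurrence_table(data.frame(
  terminal = c("A", "B", "B", "C"),
  cell     = c("c1", "c1", "c2", "c3")))
fit <- rwibald(tree, occ)
branch_table(fit)[, c("branch_id", "observed_length", "comparison_length",
                      "range_size", "rwibald", "bald", "category")]
#>   branch_id observed_length comparison_length range_size rwibald bald category
#> 1  node:A:2               3               2.5          2    0.25  0.5     none
#> 2         A               1               2.5          1   -1.50 -1.5     none
#> 3         B               2               2.5          2   -0.25 -0.5     none
#> 4         C               4               2.5          1    1.50  1.5     none
```

`C` is a single-cell branch much longer than the 2.5 equal share
(`rwibald = 4/1 - 2.5/1 = 1.5`, the paleo direction), `A` a single-cell
branch much shorter (neo direction).  With only two positive and two
negative scores, no elbow cutoffs exist on a tree this small, so no
branch is categorized (`none`).

On a realistic instance — here synthetic, with three planted branches per
endemism class among heavy-tailed background ranges on a 10 x 10 grid —
the full protocol runs and recovers the planted classes:

```r
sim <- simulate_endemism(seed = 42)
fit <- rwibald(sim$tree, sim$occurrences)
fit
#> RWiBaLD classification of 198 branches (100 terminals)
#>   highly endemic: 74 (RWcT cutoff 0.3082406)
#>   neo 25 | meso 45 | paleo 4
#>   score cutoffs: neo <= -0.3391163, paleo >= 0.4684004

table(truth = sim$truth$class[match(branch_table(fit)$branch_id,
                                    sim$truth$branch_id)],
      called = branch_table(fit)$category)
#>             called
#> truth        meso neo none paleo
#>   background   42  22  124     1
#>   meso          3   0    0     0
#>   neo           0   3    0     0
#>   paleo         0   0    0     3
```

All nine planted branches land in their true class.  The background
branches called neo/meso here are genuinely range-restricted short or
middling branches that the data-driven thresholds also pick up — the
selection is about the shape of the whole distribution, not the planted
truth.

`plot(fit)` draws the three ranked diagnostic curves (range restriction,
RWiBaLD with its two cutoffs, BaLD); `coef(fit)` returns the signed
scores as a continuous branch trait; `cell_composition(fit)` tallies
endemic branches per grid cell; `write_annotated_newick(fit)` exports the
tree with `[&category=...]` comments for tree viewers.  `run_rwibald()`
runs everything from input files to an output bundle (branch table CSV,
thresholds JSON, annotated Newick, per-cell CSVs, run log), and
`inst/cli/rwibald.R` is a thin command-line wrapper with `run`,
`scores-only` and `simulate` subcommands.

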