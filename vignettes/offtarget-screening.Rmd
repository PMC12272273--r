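---
title: "Screening dsRNA biopesticides for off-target silencing: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening dsRNA biopesticides for off-target silencing: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(offscreen)
```

## The screening model

A dsRNA biopesticide acts through RNAi: Dicer cleaves the delivered duplex
into ~21-nt siRNAs, and each siRNA can direct silencing of any transcript it
pairs with well enough. Off-target risk for a non-target organism (NTO) is
therefore a property of the *set of siRNAs* a construct can yield, not of
the construct as a whole. `offscreen` models that set conservatively and
screens it exhaustively.

**Dicing.** Dicer enzymes differ in their cleavage-site preferences across
species and no universal motif exists, so cleavage is treated as stochastic:
every window of length $k$ (default 21) along the construct's sense strand,
at 1-nt steps, is a candidate siRNA. A construct of length $L$ yields
$L - k + 1$ windows; windows with identical residues collapse to their first
occurrence (for a 398-nt construct with distinct 21-mers, 378 unique
fragments). We deliberately apply no thermodynamic selection or
cleavage-motif weighting — a fragment that is rarely produced in one species
may be common in another, and a risk screen should not bet against that.

**Orientation.** An siRNA duplex carries two potential guide strands. Dicing
is implemented on the sense strand only, and `enumerate_orientations()`
appends each fragment's reverse complement as an antisense guide —
mathematically equivalent to dicing both strands without double bookkeeping.
The default policy is `both`; `sense_only` reproduces a minimal
sense-strand-only reading. All downstream coordinates ("guide coordinates",
1..k from the guide's 5′ end) refer to the fragment as oriented in the hit,
so the seed interval means the same thing for either strand.

**Search.** Rather than a heuristic local aligner, every fragment is
compared against every transcript by an exhaustive ungapped scan: all
full-length placements on the transcript forward strand and all placements
of the fragment's reverse complement (reported as the transcript reverse
strand, mismatch positions mapped back to guide coordinates). For 21-nt
queries every funnel criterion is a function of a gapless placement —
identity count, longest perfect run, longest near-perfect stretch — and
gaps in a 21-nt siRNA:mRNA duplex are not part of any criterion, so nothing
is lost by restricting to ungapped placements, while seeding sensitivity
(hit lists that change with word size or database) is eliminated entirely.
Partial, overhanging placements are not evaluated; a shorter local match is
represented by the run statistics of the best full-length placement. The
inner loop is compiled (Rcpp) with a mismatch-budget early abort; the
placement set is identical to a naive position-by-position comparison,
which the test suite asserts against an independent R implementation of
exactly that comparison. `N` counts as a mismatch on either side —
ambiguity never earns an identity in a risk screen.

Hits below the scan floor `min_identities` (default 15, the loosest bound
any preset can need) are discarded at scan time. Within a
(fragment, transcript) pair hits sort by identities then position; the
global hit table sorts by (transcript, position, fragment), and placements
reached by residue-identical fragments are deduplicated — together this
makes every report byte-reproducible.

## The filter funnel

Three criteria decide whether a hit is a potential off-target site:

1. **Overall identity** — identities $\ge$ `min_total_identities` over the
   full fragment. The "~80% similarity" rule of thumb for 21-mers is
   resolved to the hard threshold $\ge 16/21$: a filter must be decidable,
   and 16 is the integer the 80% figure rounds to in common use.
2. **Near-perfect stretch** — a contiguous stretch of at least
   `min_near_perfect_len` aligned positions containing at most
   `max_mismatches_in_stretch` (default 2) mismatches. The stretch reading
   is the only non-trivial one: a full-length 21-mer with ≤ 2 mismatches
   trivially contains an 18-nt stretch, so the statistic is computed as the
   longest window with ≤ m mismatches (`run_statistics()`, two-pointer over
   the mismatch list, verified against exhaustive window enumeration).
3. **Seed identity** — no mismatch within guide positions
   `seed_start..seed_end` (closed interval, default 2–8). Seed pairing
   dominates both on- and off-target activity, so a single seed mismatch
   disqualifies a site. Position 1 is outside the seed by definition.

**Presets.** Published criteria for this funnel circulate in slightly
different variants, so the thresholds ship as named presets rather than one
hard-coded pair: `text` (16/18, the default), `figure6` (15/19, the variant
used for mismatch-class summaries), and `chen` (16/26, the dsRNA-level
criteria the siRNA rules descend from). The preset name is stamped into
every report. The chen preset's 26-nt near-perfect criterion is recorded
verbatim and is unsatisfiable on 21-nt fragments — under `and_chain` it
rejects everything, which the truth tables and tests document rather than
hide.

**Combination.** The criteria are listed as three numbered requirements
without an explicit boolean connective. The default reading is
`(1 OR 2) AND 3`: the ancestral dsRNA-level criteria are explicitly
disjunctive, and the seed criterion is described as a final filtering step.
The conjunctive reading `1 AND 2 AND 3` is also defensible, so both are
first-class (`combine_mode = "or_then_seed"` / `"and_chain"`) and every
report names the mode used.

A consequence worth knowing: at $k = 21$ with $m = 2$, criterion 2 can
never rescue a hit that fails criterion 1. If an 18-nt window holds ≤ 2
mismatches, at most 3 more positions lie outside it, so identities
$\ge 21 - 2 - 3 = 16$ — criterion 1 already passes (the same argument gives
$\ge 17$ for the 19-nt variant). Under `or_then_seed` criterion 2 is
therefore redundant at the default geometry; it binds only under
`and_chain`, where it *rejects* hits such as 16-identity sites with
scattered mismatches. Both behaviours are exercised by the planted-truth
fixtures.

Retained hits carry a class label,
`"<identities> bp (1–21), <n> mismatch(es)"` — identities, the aligned
span in guide coordinates (always the full fragment here, since only
full-length placements are evaluated), and the mismatch count. The label
format is versioned via the report's `schema_version` so it can evolve
without breaking parsers.

## The synthetic study system

`build_synthetic_db()` emulates the screened object — an NTO transcript
database — well enough to give every pipeline stage ground truth:
multi-record FASTA, transcript lengths uniform on 200–3000 nt (the bulk of
mRNA lengths), configurable GC (default 0.5), and planted sites constructed
from real construct fragments by deterministic mutation patterns:

| pattern | construction (guide coords) | sits on the boundary of |
|---|---|---|
| `perfect` | verbatim copy | everything passes |
| `one_mm_seed` | 1 substitution in 2–8 | seed criterion (must reject) |
| `one_mm_nonseed` | 1 substitution in {1, 9–21} | clean pass, 20 identities |
| `two_mm_nonseed` | 2 substitutions in 9–21 | criterion 2 budget edge |
| `near18_2mm` | substitutions at 1 and 21 | stretch spans the interior |
| `identity16` | 5 substitutions in 9–21, never all of 19–21 | criterion 1 exactly met, criterion 2 fails |
| `decoy_identity14` | 7 substitutions anywhere | below every threshold and the scan floor |

The `identity16` constraint (not all of positions 19–21 mutated) is what
makes its criterion-2 failure deterministic: the only 18-nt window that
could exclude three of its five mismatches is 1–18, which would require
exactly 19, 20, 21 to be the excluded ones. Expected retention under every
preset × combine mode follows from these rules in closed form and is
written into the truth table at generation time — the truth flags never
touch the search or filter code, so they are a genuinely independent
oracle.

**Background safety.** At the 15-identity scan floor, a random 21-nt locus
matches at least one of 756 fragment-strands with probability ~1.5%
($756 \times 2 \times P[\mathrm{Binom}(21, 0.25) \ge 15]$, before
accounting for the strong correlation between overlapping fragments), i.e.
tens of candidate collision loci per long transcript. Whole-transcript
rejection sampling would essentially never accept, so the generator
re-rolls *only the offending windows* (positions outside the planted site)
and re-scans until the transcript is clean, with a retry budget. Cleanliness
is guaranteed at the floor the database was built with — screening such a
database with a lower floor voids the no-background-hit guarantee.

**Recovery scoring.** Construct windows overlap by $k - 1$ nt, so a planted
site is inevitably also hit by fragments from neighbouring windows — and a
shifted fragment can legitimately pass every criterion (a seed mismatch at
guide position 5 of the source fragment sits at position 1, or outside the
fragment entirely, for a fragment shifted 4 nt; the other duplex strand
likewise has its own seed). `recovery_test()` therefore scores:

* **sensitivity** on the *exact* planted placement — source fragment,
  transcript, start, strand — of sites whose truth flag says "retained"
  under the scoring config;
* **seed rejection** on the exact placement of `one_mm_seed` plants (their
  shifted or opposite-strand derivatives may validly survive; the planted
  guide itself must not);
* **false positives** as retained hits whose placement overlaps *no*
  planted interval — attribution by locus, the same way a manual reviewer
  would credit a hit list.

Under these definitions the standard fixture (5 perfect, 10 non-seed
single-mismatch, 10 identity-16, 10 seed-mismatch, 10 decoy plants, 50
background transcripts) achieves sensitivity 1.0, seed rejection 1.0 and 0
false positives under both combine modes, across seeds — this is asserted
by the test suite at three fixed seeds and recomputed by
`scripts/acceptance.R` at an arbitrary one.

**What the generator does not emulate** — and hence what passing tests do
*not* show about real data: real transcriptome composition (codon bias,
repeats, low-complexity tracts, homologous gene families), expression
levels, splice isoforms, and sequencing-read databases (screening SRA-style
short reads multiplies hit counts through redundancy and is out of scope).
Against real NTO transcriptomes the pipeline's counts depend on the
database chosen, exactly as database choice dominates hit counts in
practice; the synthetic results validate the *machinery*, not any
organism-specific risk conclusion.

## Numerical and interface choices

* **Determinism.** Identical inputs and seed give byte-identical TSV/JSON
  outputs: fixed column orders, fixed sort keys with explicit tie-breaks,
  LF endings, UTF-8, 80-column FASTA wrapping. All randomness flows through
  R's RNG from a single seed.
* **Alphabet.** Sequences normalize to uppercase DNA on ingest (U→T —
  matching is done in DNA space); characters outside `A,C,G,T,U,N` are
  parse errors naming the record and line. `N` never matches.
* **Degenerate inputs.** Constructs shorter than $k$, fragments without a
  full seed ($k < 8$), empty databases and empty hit tables error or
  return well-formed empty results as documented; transcripts shorter than
  $k$ are skipped with a warning, never silently dropped. A scan floor
  above $k$ yields an empty hit table rather than an error — an
  unattainable threshold is a degenerate but meaningful setting.
* **Validation problem sizes.** The scan is checked against the naive
  comparator on 1000 random fragment × transcript pairs (transcripts up to
  3000 nt, floors 12–21, both strands); the stretch statistics against
  exhaustive window enumeration for *every* mismatch set of size ≤ 4 at
  $k = 21$; preset orderings on 10,000 random mismatch vectors; recovery on
  the standard fixture at three seeds. These sizes make the full suite
  complete in a couple of minutes on one core while covering the
  combinatorics that matter.
* **Interfaces.** The package functions are the primary surface. A thin
  command-line wrapper (`inst/scripts/offscreen.R`, `run` and `simulate`
  subcommands, optional YAML config) exists for shell pipelines; it adds no
  logic of its own.

## Known limitations

Only full-length ungapped placements are scored; bulged or gapped
siRNA:target duplexes, translational repression without cleavage, and
thermodynamic strand-selection asymmetry are not modelled. The funnel is
sequence-identity-only — no target-site accessibility, no
position-weighted seed scoring. Hit counts against real databases inherit
those databases' redundancy and completeness. And the 21-nt geometry is
load-bearing: at other $k$ the criterion-2 redundancy argument above
changes, and the synthetic plant patterns are defined for $k = 21$ only.
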