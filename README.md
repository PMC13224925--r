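# helixfuse

Antagonist-bound G protein-coupled receptors (GPCRs) are too small and too
flexible for reliable cryo-EM particle alignment on their own. A standard
remedy is to graft a rigid protein domain — a *fusion tag* acting as a
fiducial marker — into intracellular loop 3 (ICL3), splicing the tag's
terminal α-helices directly onto the ends of transmembrane helices TM5 and
TM6 so the added mass moves rigidly with the receptor. Finding domains that
can be grafted this way, and junctions at which the graft stays helical, is
a structural-bioinformatics problem: `helixfuse` implements the desk half of
that workflow for protein engineers and structural biologists.

The package covers three stages, each usable on its own:

1. **Geometric screening** of structure corpora (PDB/mmCIF) for candidate
   tags: chains whose N- and C-terminal helices are ≥ 8 residues long,
   start/end within 5 residues of the chain termini, point close to
   antiparallel, and place their splice-side Cα anchors ~10 Å apart. Each
   terminal-helix pair is measured — straight axes fitted to the Cα
   coordinates by principal direction, the inter-axis angle
   θ = arccos(d̂_N · d̂_C) ∈ [0°, 180°], and the anchor separation
   d = |Cα(N-helix first) − Cα(C-helix last)| — and ranked by a continuous
   score

       S(d, θ) = max(0, 1 − |d − d₀| / Δd) · max(0, (θ − θ_min) / (180° − θ_min)),

   with defaults d₀ = 10 Å, Δd = 8 Å, θ_min = 90°, so S = 1 exactly at an
   antiparallel pair separated by 10 Å. Keyword/assembly metadata filters
   automate the curation step that removes membrane, homo-oligomeric and
   designed proteins; anything the file does not state is reported
   `unknown`, never guessed.
2. **Chimera design**: splicing a tag sequence into a receptor in place of
   its ICL3 over a matrix of entry/exit junction points (entry = last
   retained receptor residue before the tag, exit = first retained after
   it), with optional point mutations, emitting FASTA ready for a structure
   predictor.
3. **Model triage**: scoring predicted fusion models for junction helical
   continuity (Cα-distance secondary-structure assignment over ±4-residue
   junction windows), junction confidence (pLDDT read from the B-factor
   column), Cα RMSD to a reference receptor conformation (SVD-based
   least-squares superposition with a reflection guard), and inter-domain
   heavy-atom clashes (< 3 Å, ≥ 3 residues apart in sequence).

A synthetic-structure generator (ideal helices, hairpins with exactly known
separation/angle, mock fusion models with planted clashes) makes the whole
pipeline testable without downloading a single structure.

## Worked example

Generate a seeded ten-file corpus with three planted positives, screen it,
and design the construct matrix for the best candidate:

```r
library(helixfuse)
library(dplyr)

dir <- file.path(tempdir(), "corpus")
manifest <- corpus_fixture(dir, n_files = 10, n_positives = 3, seed = 7)
report <- screen_corpus(dir)
glance(report)
#> # A tibble: 1 × 6
#>   n_chains n_files n_unreadable n_geometry_pass n_scored best_score
#>      <int>   <int>        <int>           <int>    <int>      <dbl>
#> 1       10      10            0               4        3      0.759

report |>
  select(entry_id, n_len, c_len, separation, angle, score, reason) |>
  head(5)
#> # A tibble: 5 × 7
#>   entry_id n_len c_len separation angle  score reason
#>   <chr>    <int> <int>      <dbl> <dbl>  <dbl> <chr>
#> 1 SYN001      11    12        9    168.  0.759 <NA>
#> 2 SYN002      12    12       11.5  166.  0.688 <NA>
#> 3 SYN003      12    14        7.5  170.  0.615 <NA>
#> 4 SYN004       6    13        8.5  169. NA     too_short_N
#> 5 SYN005      12    13        7    175. NA     offset_N
```

The three scored chains are exactly the planted positives; `SYN004` fails
only the eight-residue minimum helix length (`too_short_N`), `SYN005` only
the five-residue terminal-offset rule. (Four chains pass the geometry gates
but one of them carries an excluded `MEMBRANE PROTEIN` keyword, so only
three keep a score.) Ranking is by score: `SYN001` sits at 0.759 because
its anchors are 9 Å apart (separation factor 1 − 1/8) and its axes 168°
from parallel.

Designing the 5 × 5 junction matrix around a receptor's ICL3 (residues
235–244, receptor numbered 2–316) and splicing a 72-residue tag at the
control junctions:

```r
receptor <- numbered_sequence("A2AR", strrep("A", 315), first_auth = 2)
tag <- numbered_sequence("TAG", strrep("D", 72))
cand <- icl3_candidates(235, 244)       # entries 234..238, exits 241..245
constructs <- enumerate_constructs(receptor, tag, cand$entries, cand$exits)
nrow(constructs)                        # 25

splice_sequence(receptor, tag, entry = 234, exit = 245) |>
  select(name, length, junction_n, junction_c, deleted_start, deleted_end)
#> # A tibble: 1 × 6
#>   name               length junction_n junction_c deleted_start deleted_end
#>   <chr>               <int>      <int>      <int>         <dbl>       <dbl>
#> 1 A2AR_TAG_e234_x245    377        233        306           235         244
```

Residues 235–244 are deleted and the chimera is 305 receptor residues plus
the 72-residue tag. Predicted models of such constructs are then triaged
with `assess_model()` / `rank_assessments()`.

A command-line wrapper over the same functions ships in
`inst/cli/helixfuse.R` (`screen | design | assess | fixtures` subcommands).

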