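---
title: "Mining molecular dynamics data from generalist repositories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining molecular dynamics data from generalist repositories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdscout)
```

## The problem

Molecular dynamics (MD) simulations produce large, heterogeneous file sets —
coordinates, run parameters, topologies, binary trajectories — that
researchers increasingly deposit in generalist data repositories (Zenodo,
Figshare, OSF) rather than in a dedicated database. The result is data that
is technically public but practically invisible: free-text titles and
descriptions are too inconsistent for text search, much of the content sits
inside zip archives the repositories index only superficially, and nothing
ties a deposited `.xtc` trajectory to the force field, temperature or time
step it was produced with.

`mdscout` addresses this with three layers:

1. **Indexing** — the two-phase *explore and expand* strategy builds an
   index of datasets and of every file they contain.
2. **Content mining** — native readers for the Gromacs formats (`.gro`,
   `.mdp`, `.log`, binary `.xtc`) turn file content into annotations:
   molecular composition, simulation length, model resolution,
   thermostat/barostat, temperature.
3. **Exposure** — summary analytics, and a keyword search engine over the
   persisted index with TSV export.

Everything is testable offline through a synthetic-corpus generator that
writes repository fixtures with a known ground truth.

## Explore and expand

Text search over user-written metadata yields many false positives, but MD
engines emit files with characteristic extensions. The *explore* phase
therefore queries each repository for **file types** (`gro`, `mdp`, `xtc`,
`psf`, `prmtop`, ...), combined with an MD keyword (`"molecular dynamics"`,
`"gromacs"`, `"martini"`, ...) only where the extension alone is too
generic (`top`, `log`, `zip`, ...). The query list is configuration
(`query_config.yml`), not code.

The *expand* phase assumes that a dataset is coherent: if one file in it is
MD-related, the whole dataset is of interest. Every file of every candidate
dataset is catalogued, including the members of zip archives as reported by
the repository's preview page (Zenodo caps this preview at the first 1000
members; OSF offers none). File sizes come from API metadata and previews —
indexing transfers no data files.

Because keyword-gated archive queries can pull in datasets with no MD
content at all, a final **cleaning** step removes every dataset that does
not hold at least one file — plain or inside a previewed archive — whose
extension is on the curated list. Two deliberate choices here:

* The dataset, never the single file, is the unit of inclusion and
  exclusion.
* Generic container types found through keyword queries do not count as
  evidence: the packaged configuration lists `zip` under `clean_exclude`,
  so a dataset whose only "MD" file is the archive itself is removed unless
  a previewed member carries a real MD extension. The exclusion list is
  configuration and can be emptied.

## Reading Gromacs files

**`.gro`** is a fixed-column format. `parse_gro()` slices atom lines by
character position (residue number in columns 1–5, residue name 6–10, atom
name 11–15, atom number 16–20, coordinates as three `%8.3f` fields) instead
of splitting on whitespace, because deposited files routinely have merged
columns (a five-digit residue number runs straight into the residue name).
Velocities are detected from line length. A file whose atom count line
promises more atoms than the file holds fails with an "expected *n*, found
*m*" error rather than a silent short read.

**`.mdp`** is `key = value` text with `;` comments. Keys are normalized by
lowercasing and folding `-` to `_`, mirroring Gromacs, which treats the two
spellings interchangeably; the last occurrence of a repeated key wins, as in
Gromacs itself. The parser is *total*: arbitrary text never raises, and
unusable lines are only counted (`n_skipped`). Only `ref_t` is read for
temperatures; `gen_temp` and annealing schedules are deliberately ignored —
the analysis works with one starting temperature per file.

**`.xtc`** is big-endian XDR binary, one frame after another: magic number
1995, atom count, step, time, 3×3 box, then the coordinate payload
(plain floats for ≤ 9 atoms, otherwise a compressed block preceded by its
byte count). `read_xtc_info()` counts frames by *skipping* payloads without
decompressing them, so a multi-gigabyte trajectory costs a few kilobytes of
reads. A trailing partial frame sets `truncated` and is not counted; a bad
magic number mid-file reports the frame index. The fixture generator only
writes the uncompressed branch (the compression algorithm is out of scope);
the compressed *read* path is instead validated against an independent
trajectory toolchain (MDAnalysis) on files it writes — the test suite
generates five such files and compares atom and frame counts.

## From parsed files to annotations

* **Engine assignment** is a lookup from extension to engine. NAMD and
  CHARMM share their characteristic extensions and are pooled as
  `namd/charmm`. `.top` counts as Gromacs. The table is overridable YAML.
* **Composition** — every residue name in a `.gro` file is looked up
  (case-insensitively, padding stripped) in a dictionary mapping names to
  protein / lipid / nucleic / glucid / water_ions; unknown names count as
  `other`, so counts always sum to the atom count. The group label is the
  set of non-water categories joined with `+` in a fixed order (protein,
  lipid, nucleic, glucid, other); pure-solvent systems are
  `"water/ions only"`. Where a one-letter ion name collides with a
  ribonucleotide code (`K`, `NA`), the packaged dictionary resolves in
  favour of the ion, since bare one-letter nucleotide residue names are
  rare in deposited coordinate files; the dictionary is replaceable.
* **Simulation time** is `dt × nsteps`, reported in ns. It is the time the
  run was set up for, not evidence it completed.
* **Resolution** — all-atom force fields integrate at 1–4 fs; coarse-grained
  models (Martini and relatives) at 10 fs and above. The classifier uses
  `dt ≥ 0.01 ps → coarse-grain`, with the boundary itself classified
  coarse-grain because no atomistic force field runs at 10 fs. The class
  depends on `dt` only — varying `nsteps` can never change it.
* **Thermostat/barostat** values are matched case- and dash/underscore-
  insensitively against the algorithms the Gromacs documentation lists.
  Missing or `no` becomes `"none"`; anything unrecognized becomes
  `"invalid"`, is kept in the record, but is excluded from the flow counts
  so misspellings cannot masquerade as algorithms. `(none, none)` is a
  meaningful class — runs with neither coupling are typically
  minimizations.
* **Headline temperature** — `ref_t` carries one value per coupling group;
  deposited files overwhelmingly repeat one value. The default reduction is
  the first group's value; `max` and `mean` are available as a switch
  because no principled single answer exists for heterogeneous groups.
* **Production filter** — `md`/`sd` integrator and more than 1 ns of
  planned time. The threshold is strict (`> 1 ns`), so a 1 ns run does not
  qualify.

## Analytics conventions

* Sizes are decimal GB (10⁹ bytes), as repository UIs report them.
* Simulation-time reporting bands are `(1, 50]`, `(50, 1000]` and
  `(1000, ∞)` ns. Edge ownership (`(lo, hi]`) is a documented choice and
  the inner edges are a parameter.
* Temperature histogram bins are left-closed, right-open, anchored at
  multiples of the bin width.
* The per-repository summary carries a `total` row defined as the column
  sums (min/max for dates) — an invariant the tests enforce.
* The one-trajectory-per-dataset sample picks the lexicographically first
  plain file, falling back to the first archive member; any fixed
  deterministic rule would do, this one is auditable.
* Extension rankings break count ties alphabetically, again for
  auditability.

## The synthetic corpus and its manifest

`gen_corpus()` writes everything a harvest needs — paginated search-result
pages, dataset records, zip-preview HTML in each repository's dialect, real
STORED zip archives, and downloadable `.gro`/`.mdp`/`.log`/`.xtc` bodies —
from seeded draws, so the same seed reproduces the corpus byte for byte.
Its defaults emulate the structure of real deposits:

* a mixture of MD engines plus a large bucket of unclaimed extensions;
* all-atom (1–4 fs) and coarse-grain (≥ 10 fs) time-step regimes, planned
  runtimes spanning sub-ns to multi-µs;
* reference temperatures peaked at 298–310 K with minor mass from 100 to
  800 K;
* zip-heavy datasets: with the default archive probability and member
  counts, a corpus holds roughly seven times more files inside archives
  than directly — OSF archives stay opaque, as in a real harvest;
* planted false positives: datasets matched only through keyword-gated
  archive queries whose content is entirely non-MD, which the cleaning
  step must remove.

The generator simultaneously computes a **manifest** of every expected
downstream summary by direct enumeration over its own draws — it never
calls the indexing, parsing or analytics code. The only shared artifact is
the extension-to-engine table, which is data, not a code path. This makes
the manifest a brute-force oracle: the core end-to-end test regenerates 100
seeded corpora and requires the full
explore → expand → clean → parse → annotate → analyze chain to reproduce
the manifest *exactly* — engine counts, extension rankings, composition
groups, coupling flows, time bands, temperature bins and the per-repository
summary table.

What the synthetic corpus does **not** emulate: real compressed
trajectories (covered separately by toolchain parity), the messiness of
real free-text metadata, repository API drift, rate limits and outages, and
multi-version dataset records (exercised by targeted unit fixtures
instead). Passing the synthetic loop therefore demonstrates the internal
correctness of the pipeline, not robustness against live repository
surprises; the live transport exists but is intentionally thin.

## Problem sizes and runtime

The test suite runs entirely offline. The end-to-end loop uses 100 corpora
of ~9 datasets and ~300 indexed files each (a deliberate desk-scale choice:
per-dataset structure, not volume, is what the pipeline's correctness
depends on); parser property tests use hundreds of randomly composed
files. `scripts/acceptance.R` re-runs the whole pipeline on one seeded
corpus and writes the main computed quantities as JSON.

A real harvest of the three repositories is hours of rate-limited API
traffic and is not reproducible offline; the persisted-snapshot path
(`save_snapshot()` / `load_snapshot()`, Parquet) exists precisely so that a
harvest can be frozen, reloaded and re-analyzed without network access, and
the analytics accept any snapshot with the documented schema.

## Known limitations

* NAMD and CHARMM cannot be told apart by extension; they are reported as
  one engine.
* `.tpr`, `.trr`, `.edr` and topology files are counted by extension only;
  their binary/semantic content is not parsed.
* The simulation-time annotation reflects the configured `nsteps`, which
  may overstate (walltime kill) or understate (extended runs) reality.
* Biased and unbiased trajectories are not distinguished.
* The search engine does exact substring matching — no stemming, no fuzzy
  matching — so ranking stays auditable.
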