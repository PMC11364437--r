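# mdscout

Find, index and characterise molecular dynamics (MD) simulation data
scattered across generalist data repositories (Zenodo, Figshare, OSF).

MD files are deposited in these repositories by the hundreds of thousands,
but they are effectively invisible: metadata is free text of wildly varying
quality, and much of the content sits inside zip archives that the
repositories barely index. `mdscout` is for computational biophysicists and
data curators who want to locate that data, understand what is in it, and
search it.

## What it does

**Explore and expand indexing.** Instead of text search, datasets are found
by the file extensions MD engines emit (`.gro`, `.mdp`, `.xtc`, `.psf`,
`.prmtop`, ...), optionally gated by MD keywords where an extension is too
generic. Every file of every hit dataset is then catalogued — including zip
members read from the repositories' preview pages — and a cleaning step
drops datasets that turn out to contain no MD-typed file at all. All
repository access goes through a swappable transport, so the whole pipeline
runs offline against recorded or generated fixtures.

**Native Gromacs readers.**

* `parse_gro()` — fixed-column coordinate files, sliced by character
  position so merged columns parse; velocities auto-detected.
* `parse_mdp()` — run parameters with Gromacs key normalization
  (case- and `-`/`_`-insensitive, last occurrence wins); total on arbitrary
  text.
* `parse_log()` — Gromacs version and launch command line from run logs.
* `read_xtc_info()` — atom/frame counts and the time range of binary XDR
  trajectories by skipping coordinate payloads, without decompression.

**Annotation and analytics.** Per-file inference of MD engine, molecular
composition (protein / lipid / nucleic / glucid / water-ions census from
residue names), planned simulation time (`dt × nsteps`), all-atom vs
coarse-grain resolution (10 fs time-step cutoff), canonical
thermostat/barostat and headline temperature — then the corpus-level
summaries: per-repository statistics, engine and extension distributions,
cumulative distributions, composition group counts, thermostat–barostat
flows, simulation-time bands and temperature histograms.

**Search.** `search_index()` ranks datasets by the number of distinct
keywords matching title, description and file names, with conjunctive
filters (repository, engine, extension, date, size), and `export_tsv()`
writes one provenance-carrying row per matching file.

**Synthetic corpora.** `gen_corpus()` writes a complete seeded fixture tree
(search pages, dataset records, preview HTML, real zip archives, valid
`.gro`/`.mdp`/`.xtc` bodies) together with a ground-truth manifest computed
independently of the pipeline — the oracle the test suite checks the whole
chain against.

## Worked example

```r
library(mdscout)

# generate a synthetic three-repository corpus with known ground truth
dir <- tempfile("corpus")
gen_corpus(corpus_spec(seed = 42), dir)

# harvest it: explore -> expand -> clean
tr <- fixture_transport(dir)
index <- harvest_index(c("zenodo", "figshare", "osf"), tr)
index
#> MD index snapshot (harvested 2026-09-25)
#>   datasets: 7
#>   files:    54 plain + 240 zip members
#>   - zenodo: 3 datasets
#>   - figshare: 2 datasets
#>   - osf: 2 datasets

repository_summary(index)[, c(1, 2, 5, 7, 8, 9)]
#>   repository n_datasets n_files n_zip_files n_files_within_zip n_total_files
#> 1   figshare          2      15           2                175           190
#> 2        osf          2      19           2                  0            19
#> 3     zenodo          3      20           1                 65            85
#> 4      total          7      54           5                240           294
```

Nine datasets were found, two of which were false positives (keyword hits
whose archives hold no MD file) that the cleaning step removed. OSF shows
zero files within zip because it provides no archive preview. Downloading
and parsing the Gromacs content files then yields the annotations:

```r
ann <- annotate_index(index, tr)
upset_counts(ann$profiles)          # systems per molecular composition
#> water/ions only         protein   protein+lipid protein+nucleic
#>               4               3               2               1

coupling_flows(ann$mdp_annotations)[1:3, ]  # thermostat/barostat pairs
#>    thermostat          barostat count
#> 1   v-rescale              none     4
#> 2        none parrinello-rahman     2
#> 3 nose-hoover              none     2

td <- time_distribution(ann$mdp_annotations)
td$bands                            # production runs per time band
#>         band   resolution count
#> 1     (1,50]     all-atom     2
#> 2  (50,1000]     all-atom     2
#> 3 (1000,Inf]     all-atom     1
#> 4     (1,50] coarse-grain     2
#> 5  (50,1000] coarse-grain     0
#> 6 (1000,Inf] coarse-grain     0
```

Seven of the sixteen parsed `.mdp` files are production candidates
(md/sd integrator, planned time above 1 ns); most are short all-atom runs,
as the band counts show. Finally, the index is searchable and exportable:

```r
hits <- search_index(index, keywords = "molecular dynamics",
                     extension = "mdp")
export_tsv(hits, index, "hits.tsv")
```

A harvested index persists as two Parquet tables via `save_snapshot()` and
reloads with `load_snapshot()` for later analysis or searching, and the
same operations run from the shell through the bundled `mdscout` script
(`inst/cli/mdscout`): `index`, `analyze`, `search`, `gen-fixtures`,
`parse-gro`, `parse-mdp`, `xtc-info`.

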