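# Default harvesting queries: file types to search for, with a flag saying
# whether the extension is specific enough to be queried alone
# (keyword_required: false) or must be combined with an MD-related keyword
# to avoid false positives (keyword_required: true). Replaceable by the
# user; the keyword list is deliberately generic.
file_types:
  - {ext: gro, keyword_required: false}
  - {ext: mdp, keyword_required: false}
  - {ext: xtc, keyword_required: false}
  - {ext: trr, keyword_required: false}
  - {ext: tpr, keyword_required: false}
  - {ext: itp, keyword_required: false}
  - {ext: top, keyword_required: true}
  - {ext: edr, keyword_required: false}
  - {ext: psf, keyword_required: false}
  - {ext: dcd, keyword_required: true}
  - {ext: prmtop, keyword_required: false}
  - {ext: parm7, keyword_required: false}
  - {ext: inpcrd, keyword_required: false}
  - {ext: cms, keyword_required: false}
  - {ext: mae, keyword_required: true}
  - {ext: log, keyword_required: true}
  - {ext: zip, keyword_required: true}
keywords:
  - molecular dynamics
  - md simulation
  - gromacs
  - namd
  - charmm
  - amber
  - martini
  - coarse-grain
# Extensions that count as evidence of MD content during the cleaning step.
# Generic archive/container types found by keyword queries (zip) are
# excluded: a dataset must hold at least one genuinely MD-typed file,
# directly or inside a previewed archive, to stay in the index.
clean_exclude:
  - zip
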