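# Illustrative fossil placements for the example primate genus tree
# (example_tree.nwk). Taxa are real fossil primates but every topology
# choice and age here is APPROXIMATE and for demonstration only — edit
# freely; this file is not a curated calibration set.
#
# Each record: the fossil tip to add, the extant tip (or tip set, whose
# MRCA branch is used) it attaches below, the divergence (stem) age and
# the last-occurrence (tip) age, both in Ma.
- fossil_name: Proconsul
  attachment_lineage: [Homo, Pan, Gorilla, Pongo, Hylobates]
  stem_age_ma: 25
  tip_age_ma: 18
- fossil_name: Sivapithecus
  attachment_lineage: [Pongo]
  stem_age_ma: 12
  tip_age_ma: 8.5
- fossil_name: Australopithecus
  attachment_lineage: [Homo]
  stem_age_ma: 5
  tip_age_ma: 2.5
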