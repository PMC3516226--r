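# Chromosome-count scenario scripts for the published plant and animal
# lineage histories. Each entry starts from its clade ancestor's n and
# applies the printed event arithmetic (wgd doubles, wgt triples, +k
# fissions, -k fusions). stated_n is the chromosome number printed for the
# resulting intermediate or modern genome; three entries (chicken, human,
# chimpanzee) are flagged because their printed event counts do not satisfy
# the count law, and are shipped as printed rather than silently corrected.
plants:
  - id: monocot_intermediate
    role: intermediate
    start_n: 5
    steps: [wgd, "+4", "-2"]
    stated_n: 12
  - id: rice
    role: modern
    start_n: 12
    steps: []
    stated_n: 12
  - id: panicoideae_intermediate
    role: intermediate
    start_n: 12
    steps: ["+2", "-4"]
    stated_n: 10
  - id: sorghum
    role: modern
    start_n: 10
    steps: []
    stated_n: 10
  - id: maize
    role: modern
    start_n: 10
    steps: [wgd, "+7", "-17"]
    stated_n: 10
  - id: brachypodium
    role: modern
    start_n: 12
    steps: ["+7", "-14"]
    stated_n: 5
  - id: eudicot_intermediate
    role: intermediate
    start_n: 7
    steps: [wgt]
    stated_n: 21
  - id: grape
    role: modern
    start_n: 21
    steps: ["+2", "-4"]
    stated_n: 19
  - id: fragaria
    role: modern
    start_n: 21
    steps: ["+3", "-17"]
    stated_n: 7
  - id: cacao
    role: modern
    start_n: 21
    steps: ["+2", "-13"]
    stated_n: 10
  - id: malpighiales_intermediate
    role: intermediate
    start_n: 21
    steps: ["+6", "-15"]
    stated_n: 12
  - id: poplar
    role: modern
    start_n: 12
    steps: [wgd, "+4", "-9"]
    stated_n: 19
  - id: rosaceae_intermediate
    role: intermediate
    start_n: 21
    steps: ["+3", "-15"]
    stated_n: 9
  - id: apple
    role: modern
    start_n: 9
    steps: [wgd, "+4", "-5"]
    stated_n: 17
  - id: brassicales_intermediate
    role: intermediate
    start_n: 21
    steps: ["+10", "-22"]
    stated_n: 9
  - id: arabidopsis
    role: modern
    start_n: 9
    steps: [wgd, "-13"]
    stated_n: 5
  - id: papilionoideae_intermediate
    role: intermediate
    start_n: 21
    steps: ["+1", "-16"]
    stated_n: 6
  - id: soybean
    role: modern
    start_n: 6
    steps: [wgd, wgd, "+13", "-17"]
    stated_n: 20
animals:
  - id: vertebrate_2r_intermediate
    role: intermediate
    start_n: 10
    steps: [wgd, "+3"]
    stated_n: 23
  - id: gnathostome_intermediate
    role: intermediate
    start_n: 23
    steps: [wgd, "-6"]
    stated_n: 40
  - id: osteichthyes_intermediate
    role: intermediate
    start_n: 40
    steps: ["+1", "-10"]
    stated_n: 31
  - id: teleost_intermediate
    role: intermediate
    start_n: 31
    steps: ["+5", "-23"]
    stated_n: 13
  - id: medaka
    role: modern
    start_n: 13
    steps: [wgd, "+5", "-7"]
    stated_n: 24
  - id: amniote_intermediate
    role: intermediate
    start_n: 31
    steps: ["-1"]
    stated_n: 30
  - id: chicken
    role: modern
    start_n: 30
    steps: ["+1", "-3"]
    stated_n: 33
    flagged: true
  - id: opossum
    role: modern
    start_n: 30
    steps: ["+43", "-64"]
    stated_n: 9
  - id: laurasiatheria_intermediate
    role: intermediate
    start_n: 30
    steps: ["+57", "-22"]
    stated_n: 65
  - id: horse
    role: modern
    start_n: 65
    steps: ["+2", "-35"]
    stated_n: 32
  - id: dog
    role: modern
    start_n: 65
    steps: ["+6", "-32"]
    stated_n: 39
  - id: euarchontoglires_intermediate
    role: intermediate
    start_n: 30
    steps: ["+24", "-15"]
    stated_n: 39
  - id: mouse
    role: modern
    start_n: 39
    steps: ["+31", "-50"]
    stated_n: 20
  - id: human
    role: modern
    start_n: 39
    steps: ["+1", "-18"]
    stated_n: 23
    flagged: true
  - id: chimpanzee
    role: modern
    start_n: 39
    steps: ["+1", "-17"]
    stated_n: 24
    flagged: true
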