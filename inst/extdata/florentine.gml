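graph [
  node [
    id 0
    label "Acciaiuoli"
  ]
  node [
    id 1
    label "Albizzi"
  ]
  node [
    id 2
    label "Barbadori"
  ]
  node [
    id 3
    label "Bischeri"
  ]
  node [
    id 4
    label "Castellani"
  ]
  node [
    id 5
    label "Ginori"
  ]
  node [
    id 6
    label "Guadagni"
  ]
  node [
    id 7
    label "Lamberteschi"
  ]
  node [
    id 8
    label "Medici"
  ]
  node [
    id 9
    label "Pazzi"
  ]
  node [
    id 10
    label "Peruzzi"
  ]
  node [
    id 11
    label "Ridolfi"
  ]
  node [
    id 12
    label "Salviati"
  ]
  node [
    id 13
    label "Strozzi"
  ]
  node [
    id 14
    label "Tornabuoni"
  ]
  edge [
    source 0
    target 8
  ]
  edge [
    source 2
    target 8
  ]
  edge [
    source 8
    target 11
  ]
  edge [
    source 8
    target 14
  ]
  edge [
    source 1
    target 8
  ]
  edge [
    source 8
    target 12
  ]
  edge [
    source 4
    target 10
  ]
  edge [
    source 4
    target 13
  ]
  edge [
    source 2
    target 4
  ]
  edge [
    source 10
    target 13
  ]
  edge [
    source 3
    target 10
  ]
  edge [
    source 11
    target 13
  ]
  edge [
    source 3
    target 13
  ]
  edge [
    source 11
    target 14
  ]
  edge [
    source 6
    target 14
  ]
  edge [
    source 1
    target 5
  ]
  edge [
    source 1
    target 6
  ]
  edge [
    source 9
    target 12
  ]
  edge [
    source 3
    target 6
  ]
  edge [
    source 6
    target 7
  ]
]
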