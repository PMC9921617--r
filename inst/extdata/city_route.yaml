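# Hand-drawn city block for middle-level control runs: a 3 x 3 street
# grid whose crossings are junctions; walking halts automatically in
# front of each crossing. Synthetic scenario, not geo-accurate.
start: 1
nodes:
  - {id: 1, x: 0, "y": 0, junction: false}
  - {id: 2, x: 1, "y": 0, junction: true}
  - {id: 3, x: 2, "y": 0, junction: false}
  - {id: 4, x: 0, "y": 1, junction: true}
  - {id: 5, x: 1, "y": 1, junction: true}
  - {id: 6, x: 2, "y": 1, junction: true}
  - {id: 7, x: 0, "y": 2, junction: false}
  - {id: 8, x: 1, "y": 2, junction: true}
  - {id: 9, x: 2, "y": 2, junction: false}
edges:
  - {from: 1, to: 2}
  - {from: 2, to: 3}
  - {from: 4, to: 5}
  - {from: 5, to: 6}
  - {from: 7, to: 8}
  - {from: 8, to: 9}
  - {from: 1, to: 4}
  - {from: 4, to: 7}
  - {from: 2, to: 5}
  - {from: 5, to: 8}
  - {from: 3, to: 6}
  - {from: 6, to: 9}
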