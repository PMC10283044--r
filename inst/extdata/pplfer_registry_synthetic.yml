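# Synthetic PP-LFER registry (illustrative, not authoritative).
# Coefficient sets are patterned on published storage-lipid/water and
# muscle-protein/water systems (mass basis, L/kg, converted with the phase
# densities below) and an L-based air/water system.
lipid_water:
  phase_pair: lipid/water
  c: 0.55
  e: 0.78
  s: -1.10
  a: -0.25
  b: -3.90
  v: 3.35
  basis: mass
  density: 0.905
  note: "synthetic; patterned on storage lipid/water systems"
protein_water:
  phase_pair: protein/water
  c: -0.50
  e: 0.60
  s: -0.60
  a: -0.40
  b: -2.40
  v: 1.85
  basis: mass
  density: 1.36
  note: "synthetic; patterned on muscle protein/water systems"
air_water:
  phase_pair: air/water
  c: 1.271
  e: -0.822
  s: -2.743
  a: -3.904
  b: -4.814
  l: 0.213
  basis: volume
  note: "synthetic; patterned on L-based air/water systems"
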