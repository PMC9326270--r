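# Synthetic example environment: open layout, six destinations A-F.
# Distance and occupancy tables are invented illustrative values,
# NOT transcribed from any deposited study data.
name: open
destinations:
- A
- B
- C
- D
- E
- F
origin: O
distance_table:
  O: [2, 3, 5, 6, 8, 9]
  A: [0, 2, 4, 5, 7, 9]
  B: [2, 0, 3, 4, 6, 8]
  C: [4, 3, 0, 2, 4, 6]
  D: [5, 4, 2, 0, 3, 5]
  E: [7, 6, 4, 3, 0, 3]
  F: [9, 8, 6, 5, 3, 0]
occupancy_table:
  decision_1: [4, 1, 6, 2, 8, 3]
  decision_2: [2, 5, 1, 7, 3, 6]
  decision_3: [7, 2, 4, 1, 5, 2]
  decision_4: [1, 6, 3, 5, 2, 7]
  decision_5: [5, 3, 7, 2, 6, 1]
w_d: 1.5
w_o: 1.0
noise_mu: 0.0
noise_sigma: 1.4142135623730951
time_budget: 60.0
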