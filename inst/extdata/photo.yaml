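# Synthetic example environment: photo condition. Same layout as the
# open environment; occupancy constant across decisions (a snapshot of
# a real scene); 15-minute budget with noise N(1.5, 0.75) (variance).
# Invented illustrative values, NOT transcribed from any deposited data.
name: photo
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
  decision_1: [3, 5, 2, 6, 4, 1]
  decision_2: [3, 5, 2, 6, 4, 1]
  decision_3: [3, 5, 2, 6, 4, 1]
  decision_4: [3, 5, 2, 6, 4, 1]
  decision_5: [3, 5, 2, 6, 4, 1]
w_d: 0.2
w_o: 0.25
noise_mu: 1.5
noise_sigma: 0.8660254037844386
time_budget: 15.0
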