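# Synthetic example environment: closed layout (movement restricted by
# passageways, hence longer distances than the open layout).
# Invented illustrative values, NOT transcribed from any deposited data.
name: closed
destinations:
- A
- B
- C
- D
- E
- F
origin: O
distance_table:
  O: [3, 4, 7, 8, 9, 10]
  A: [0, 3, 6, 7, 9, 10]
  B: [3, 0, 4, 6, 8, 9]
  C: [6, 4, 0, 3, 6, 8]
  D: [7, 6, 3, 0, 4, 6]
  E: [9, 8, 6, 4, 0, 3]
  F: [10, 9, 8, 6, 3, 0]
occupancy_table:
  decision_1: [3, 1, 7, 2, 8, 4]
  decision_2: [1, 6, 2, 8, 3, 5]
  decision_3: [6, 2, 5, 1, 6, 2]
  decision_4: [2, 7, 3, 4, 1, 8]
  decision_5: [4, 3, 8, 2, 5, 1]
w_d: 1.2
w_o: 1.0
noise_mu: 0.0
noise_sigma: 1.4142135623730951
time_budget: 60.0
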