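# Reduced-alphabet catalog.
#
# Each entry defines a position-dependent partition of the 20 canonical
# one-letter amino-acid codes into equivalence classes over a fragment of
# odd length. `all_positions: full` is shorthand for "every letter is its
# own class at every position"; `all_positions: [[..],[..],...]` applies
# the same grouping at every position; `positions:` lists one grouping per
# fragment position. Letters not covered by any group fall into a single
# wildcard class when `wildcard: true`, otherwise compilation fails.
alphabets:
  - name: Full3
    fragment_length: 3
    all_positions: full
  - name: Full5
    fragment_length: 5
    all_positions: full
  - name: Full7
    fragment_length: 7
    all_positions: full
  - name: Full11
    fragment_length: 11
    all_positions: full
  # Example physicochemical grouping: aliphatic (GAVLI), sulfur-containing
  # (CM), aromatic (YWF), charged (DEKRH), polar/small (STNQP).
  - name: physchem5
    fragment_length: 5
    all_positions:
      - ["G", "A", "V", "L", "I"]
      - ["C", "M"]
      - ["Y", "W", "F"]
      - ["D", "E", "K", "R", "H"]
      - ["S", "T", "N", "Q", "P"]
  # Position-dependent example: exact identity at the central position,
  # coarse physicochemical classes at the tails (central residues exert a
  # stronger influence on the local conformation).
  - name: tailmerge5
    fragment_length: 5
    positions:
      - [["G", "A", "V", "L", "I"], ["C", "M"], ["Y", "W", "F"], ["D", "E", "K", "R", "H"], ["S", "T", "N", "Q", "P"]]
      - [["G", "A", "V", "L", "I"], ["C", "M"], ["Y", "W", "F"], ["D", "E", "K", "R", "H"], ["S", "T", "N", "Q", "P"]]
      - full
      - [["G", "A", "V", "L", "I"], ["C", "M"], ["Y", "W", "F"], ["D", "E", "K", "R", "H"], ["S", "T", "N", "Q", "P"]]
      - [["G", "A", "V", "L", "I"], ["C", "M"], ["Y", "W", "F"], ["D", "E", "K", "R", "H"], ["S", "T", "N", "Q", "P"]]
  # Reserved catalog names whose exact published memberships are not
  # available here; shipped as placeholders (tails merged into a single
  # class, G/P kept distinct where the name indicates) and flagged
  # unverified. Do not rely on these for reproduction of published models.
  - name: PB_W3
    fragment_length: 3
    all_positions: full
    unverified: true
  - name: PB_W7_tail_GP
    fragment_length: 7
    positions:
      - [["G"], ["P"], ["A", "V", "L", "I", "C", "M", "Y", "W", "F", "D", "E", "K", "R", "H", "S", "T", "N", "Q"]]
      - [["G"], ["P"], ["A", "V", "L", "I", "C", "M", "Y", "W", "F", "D", "E", "K", "R", "H", "S", "T", "N", "Q"]]
      - full
      - full
      - full
      - [["G"], ["P"], ["A", "V", "L", "I", "C", "M", "Y", "W", "F", "D", "E", "K", "R", "H", "S", "T", "N", "Q"]]
      - [["G"], ["P"], ["A", "V", "L", "I", "C", "M", "Y", "W", "F", "D", "E", "K", "R", "H", "S", "T", "N", "Q"]]
    unverified: true
  - name: PB_w11_tail
    fragment_length: 11
    positions:
      - [["G", "A", "V", "L", "I", "C", "M", "Y", "W", "F", "D", "E", "K", "R", "H", "S", "T", "N", "Q", "P"]]
      - [["G", "A", "V", "L", "I", "C", "M", "Y", "W", "F", "D", "E", "K", "R", "H", "S", "T", "N", "Q", "P"]]
      - [["G", "A", "V", "L", "I"], ["C", "M"], ["Y", "W", "F"], ["D", "E", "K", "R", "H"], ["S", "T", "N", "Q", "P"]]
      - [["G", "A", "V", "L", "I"], ["C", "M"], ["Y", "W", "F"], ["D", "E", "K", "R", "H"], ["S", "T", "N", "Q", "P"]]
      - full
      - full
      - full
      - [["G", "A", "V", "L", "I"], ["C", "M"], ["Y", "W", "F"], ["D", "E", "K", "R", "H"], ["S", "T", "N", "Q", "P"]]
      - [["G", "A", "V", "L", "I"], ["C", "M"], ["Y", "W", "F"], ["D", "E", "K", "R", "H"], ["S", "T", "N", "Q", "P"]]
      - [["G", "A", "V", "L", "I", "C", "M", "Y", "W", "F", "D", "E", "K", "R", "H", "S", "T", "N", "Q", "P"]]
      - [["G", "A", "V", "L", "I", "C", "M", "Y", "W", "F", "D", "E", "K", "R", "H", "S", "T", "N", "Q", "P"]]
    unverified: true
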