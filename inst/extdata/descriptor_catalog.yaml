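# Descriptor catalog: the printed top-ranked descriptor recipes.
#
# rmsd: protein-block RMSD statistic descriptors. `pb` is the protein-block
#   letter (a..p, single letter -> t-statistic descriptor) or a PB string
#   (length > 1 -> PB-string probability descriptor; this reading of
#   multi-letter entries is flagged `interpretation: pb_string`).
# periodic: periodicity descriptors over a property scale (period T in
#   residues, n_periods, decay strength A, power).
# physchem_window: windowed sums of a property scale between left and right
#   offsets from the target residue.
# Alphabets named PB_* carry placeholder definitions (see alphabets.yaml).
rmsd:
  - {rank: 1,  alphabet: Full5,         pb: acdddfb, offset: 0,  power: 1, interpretation: pb_string}
  - {rank: 2,  alphabet: Full5,         pb: pap,     offset: 0,  power: 1, interpretation: pb_string}
  - {rank: 3,  alphabet: Full5,         pb: ehjia,   offset: 0,  power: 1, interpretation: pb_string}
  - {rank: 4,  alphabet: Full5,         pb: mmmmm,   offset: 5,  power: 1, interpretation: pb_string}
  - {rank: 7,  alphabet: PB_W7_tail_GP, pb: mmmmmmm, offset: 0,  power: 1, interpretation: pb_string}
  - {rank: 11, alphabet: Full5,         pb: mmmmm,   offset: -4, power: 1, interpretation: pb_string}
  - {rank: 14, alphabet: Full5,         pb: pafkl,   offset: 0,  power: 1, interpretation: pb_string}
  - {rank: 16, alphabet: Full5,         pb: ddddd,   offset: 0,  power: 1, interpretation: pb_string}
  - {rank: 17, alphabet: Full5,         pb: klmmm,   offset: 2,  power: 1, interpretation: pb_string}
  - {rank: 22, alphabet: PB_w11_tail,   pb: pgb,     offset: 0,  power: 2, interpretation: pb_string}
  - {rank: 24, alphabet: PB_w11_tail,   pb: jia,     offset: 0,  power: 1, interpretation: pb_string}
  - {rank: 30, alphabet: PB_W3,         pb: acdddfb, offset: 0,  power: 1, interpretation: pb_string}
  - {rank: 31, alphabet: Full5,         pb: ddfbg,   offset: 0,  power: 1, interpretation: pb_string}
  - {rank: 34, alphabet: Full5,         pb: ghi,     offset: 0,  power: 1, interpretation: pb_string}
  - {rank: 36, alphabet: Full5,         pb: kln,     offset: -3, power: 2, interpretation: pb_string}
periodic:
  - {rank: 25, accession: KARS160108, T: 3.7,  n_T: 5, A: 1, power: 1}
  - {rank: 51, accession: MUNV940103, T: 10.0, n_T: 3, A: 1, power: 2}
  - {rank: 63, accession: MIYS990102, T: 3.6,  n_T: 7, A: 1, power: 1}
  - {rank: 77, accession: MUNV940102, T: 3.0,  n_T: 2, A: 1, power: 1}
physchem_window:
  - {rank: 6,  accession: MUNV940103, left: -5,  right: 6,  power: 1}
  - {rank: 8,  accession: PTIO830101, left: -5,  right: 6,  power: 1}
  - {rank: 21, accession: MUNV940102, left: -5,  right: 16, power: 3}
  - {rank: 35, accession: PTIO830101, left: -15, right: 16, power: 3}
  - {rank: 60, accession: PONP800104, left: -5,  right: 5,  power: 2}
  - {rank: 87, accession: PTIO830101, left: -5,  right: 5,  power: 3}
  - {rank: 93, accession: MUNV940103, left: -5,  right: 5,  power: 2}
other:
  - {rank: 12, kind: disorder, source: external, power: 3}
  - {rank: 73, kind: terminal_n, within: 3, power: 3}
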