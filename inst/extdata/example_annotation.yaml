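# Synthetic example of a per-chain helix annotation for
# Ballesteros-Weinstein numbering. Each segment lists its chain-local
# residue range and the anchor residue that carries the x.50 label; ICL2
# uses segment number 34 with the same offset rule. Residue numbers below
# are fabricated for the packaged toy systems and are not taken from any
# real receptor.
A:
  - segment: TM3
    start: 1
    end: 5
    anchor: 3
  - segment: ICL2
    start: 6
    end: 10
    anchor: 7
B:
  - segment: TM3
    start: 1
    end: 5
    anchor: 3
  - segment: ICL2
    start: 6
    end: 10
    anchor: 7
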