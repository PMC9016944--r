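# Taurine-reduction pathway grammars. Each step lists alternative
# requirements; a requirement is an AND-set of gene symbols that must all be
# present. Variant count = product of per-step alternative counts.
# Additional alternatives (e.g. further deamination or reduction routes) can
# be added by editing this file; the engine is grammar-driven.
pathways:
  - name: taurine_reduction_3step
    steps:
      - label: deamination
        alternatives:
          - [tpa]
          - [toa]
      - label: sulfoacetaldehyde cleavage
        alternatives:
          - [xsc]
      - label: terminal sulfite reduction
        alternatives:
          - [dsrA, dsrB]
          - [asrA, asrB, asrC]
    excluded_genes: []
  - name: taurine_reduction_4step
    steps:
      - label: deamination
        alternatives:
          - [tpa]
          - [toa]
      - label: sulfoacetaldehyde reduction
        alternatives:
          - [isfD]
      - label: isethionate cleavage
        alternatives:
          - [islA, islB]
      - label: terminal sulfite reduction
        alternatives:
          - [dsrA, dsrB]
          - [asrA, asrB, asrC]
    excluded_genes: []
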