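# Mevalonate / prenyl-pyrophosphate pathway: measured compounds and topology.
# Formulas are the free acids; retention times in minutes on the C18 method.
# `pool` names the kinetic pool a compound belongs to: IPP and DMAPP are
# isobaric, not chromatographically separated, and are read out as one signal.
name: mevalonate_prenyl_pyrophosphate
source_unit_carbons: 2   # acetyl-derived two-carbon building blocks
metabolites:
  - name: MEV
    formula: C6H12O4
    cas: "150-97-0"
    retention_time: 1.2
    pool: MEV
    quantifiable_ile: false   # low and variable ILE signal
  - name: M5P
    formula: C6H13O7P
    cas: "1189-94-2"
    retention_time: 1.2
    pool: M5P
    quantifiable_ile: true
  - name: M5PP
    formula: C6H14O10P2
    cas: "4872-34-8"
    retention_time: 0.9
    pool: M5PP
    quantifiable_ile: false   # low and variable ILE signal
  - name: IPP
    formula: C5H12O7P2
    cas: "358-71-4"
    retention_time: 1.2
    pool: IPP_DMAPP
    quantifiable_ile: true
  - name: DMAPP
    formula: C5H12O7P2
    cas: "358-72-5"
    retention_time: 1.2
    pool: IPP_DMAPP
    quantifiable_ile: true
  - name: GPP
    formula: C10H20O7P2
    cas: "763-10-0"
    retention_time: 5.7
    pool: GPP
    quantifiable_ile: true
  - name: FPP
    formula: C15H28O7P2
    cas: "13058-04-3"
    retention_time: 7.4
    pool: FPP
    quantifiable_ile: true
  - name: GGPP
    formula: C20H36O7P2
    cas: "6699-20-3"
    retention_time: 8.7
    pool: GGPP
    quantifiable_ile: true
reactions:
  - {type: source_feed, product: MEV, units: 3}
  - {type: linear_step, substrate: MEV, product: M5P}
  - {type: linear_step, substrate: M5P, product: M5PP}
  - {type: carbon_loss, substrate: M5PP, product: IPP_DMAPP}
  - {type: condensation, substrates: [IPP_DMAPP, IPP_DMAPP], product: GPP}
  - {type: condensation, substrates: [GPP, IPP_DMAPP], product: FPP}
  - {type: condensation, substrates: [FPP, IPP_DMAPP], product: GGPP}
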