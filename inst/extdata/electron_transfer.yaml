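# Electron-transfer enzymes and complexes: the edge set of the carrier
# re-oxidation graph. Carrier nodes are the cytosolic/membrane 2-electron
# pools (FdH2 tracked as the reduced-ferredoxin pool); sink nodes are the
# terminal disposal routes (H2, formate, O2 respiration, extracellular
# electron transfer). Multi-subunit complexes are only credited when their
# subunits co-localise in an operon (see complex_present()).
carriers: [NADH, NADPH, FdH2, ETFH2, quinol]
sinks: [h2_sink, formate_sink, o2_sink, eet_sink]

complexes:
  rnf:
    subunits: [rnfA, rnfB, rnfC, rnfD, rnfE, rnfG]
    colocalization: true
    edges: [[NADH, FdH2], [FdH2, NADH]]
  nfn:
    subunits: [nfnA, nfnB]
    colocalization: true
    edges: [[NADPH, NADH], [NADH, NADPH], [NADPH, FdH2], [FdH2, NADPH]]
  fix:
    subunits: [fixA, fixB]
    colocalization: true
    edges: [[ETFH2, quinol]]
  efd:
    subunits: [efdA, efdB]
    colocalization: true
    edges: [[ETFH2, FdH2]]
  flox_hdr:
    subunits: [floxA, floxB, hdrB2]
    colocalization: true
    edges: [[NADH, FdH2]]
  hyd_fefe_bif:
    subunits: [hydA, hydB, hydC]
    colocalization: true
    edges: [[NADH, h2_sink], [FdH2, h2_sink]]
    sink_class: h2
  ech:
    subunits: [echA, echB, echC]
    colocalization: true
    edges: [[FdH2, h2_sink]]
    sink_class: h2
  hyb:
    subunits: [hybA, hybB, hybC]
    colocalization: true
    edges: [[quinol, h2_sink]]
    sink_class: h2
  fdh_n:
    subunits: [fdnG, fdnH, fdnI]
    colocalization: true
    edges: [[quinol, formate_sink]]
    sink_class: formate
  bd_oxidase:
    subunits: [cydA, cydB]
    colocalization: true
    edges: [[quinol, o2_sink]]
    sink_class: o2

singles:
  fdh_h:
    gene: fdhA
    edges: [[FdH2, formate_sink]]
    sink_class: formate
  ndh:
    gene: ndh
    edges: [[NADH, quinol]]
  mhc_eet:
    gene: mhc
    sequence_rule: multiheme_cytochrome
    edges: [[quinol, eet_sink], [FdH2, eet_sink]]
    sink_class: eet
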