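# Curated ternary logic model of ocular/otolaryngological mucosal-immune
# signaling. 27 nodes; node order follows the reference steady-state table.
#
# PROVENANCE: the published connectivity diagram is available only as a
# figure; this edge list is a de novo curation ("curated from figure" in
# spirit, not a verbatim transcription) constrained to (a) canonical
# mucosal-immune interactions from the immunology literature, (b) all three
# reference steady states being fixed points of the balanced ternary update
# rule with Infection clamped at 0, and (c) those three being the ONLY
# steady states under that clamp. Each edge carries a one-line rationale.
# Conditional stimulation of T-helper differentiation is gated on Naive
# T cells at +1; a small number of additional condition gates on effector
# nodes (TNFa at 0, Treg at 0) encode context-dependent regulation and are
# a fixture convention (see the package vignette for why some non-T-cell
# gate is mathematically unavoidable).
#
# Edges from Infection model pathogen contact with the epithelium/dendritic
# compartment under DEFICIENT mucus protection; the mucus-protected variant
# drops them (see loadMucosalFixture(mucusProtected = TRUE)).

nodes:
  - {name: SubmucosalDC, display: "Submucosal dendritic cell", category: immune_cell}
  - {name: Infection, display: "Infection", category: pathogen, clamped: true}
  - {name: EpithelialCell, display: "Epithelial cell", category: other}
  - {name: IL1b, display: "IL1β", category: signaling_molecule}
  - {name: TNFa, display: "TNFα", category: signaling_molecule}
  - {name: IL12, display: "IL12", category: signaling_molecule}
  - {name: IL8, display: "IL8", category: signaling_molecule}
  - {name: CCL2, display: "CCL2/MCP1", category: signaling_molecule}
  - {name: GMCSF, display: "GM-CSF", category: signaling_molecule}
  - {name: NaiveTcell, display: "Naive Tcell", category: immune_cell}
  - {name: Th1, display: "Th1", category: immune_cell}
  - {name: Th2, display: "Th2", category: immune_cell}
  - {name: Th17, display: "Th17", category: immune_cell}
  - {name: Treg, display: "Treg", category: immune_cell}
  - {name: IFNg, display: "IFNγ", category: signaling_molecule}
  - {name: IL2, display: "IL2", category: signaling_molecule}
  - {name: IL6, display: "IL6", category: signaling_molecule}
  - {name: TGFb, display: "TGFβ", category: signaling_molecule}
  - {name: IL4, display: "IL4", category: signaling_molecule}
  - {name: IL10, display: "IL10", category: signaling_molecule}
  - {name: IL23, display: "IL23", category: signaling_molecule}
  - {name: IL17, display: "IL17", category: signaling_molecule}
  - {name: IL13, display: "IL13", category: signaling_molecule}
  - {name: Neutrophil, display: "Neutrophil", category: immune_cell}
  - {name: ROI, display: "ROI", category: signaling_molecule}
  - {name: Macrophage, display: "Macrophage", category: immune_cell}
  - {name: NKcell, display: "NK cell", category: immune_cell}

edges:
  # --- innate activation loop -------------------------------------------
  # IL1b is a maturation/danger signal for dendritic cells
  - {from: IL1b, to: SubmucosalDC, sign: "+"}
  # TNFa promotes DC maturation and recruitment
  - {from: TNFa, to: SubmucosalDC, sign: "+"}
  # pathogen contact activates submucosal DCs (deficient-mucus edge)
  - {from: Infection, to: SubmucosalDC, sign: "+"}
  # antigen-presenting DCs expand the naive T-cell pool
  - {from: SubmucosalDC, to: NaiveTcell, sign: "+"}
  # IL12 drives Th1 differentiation of primed naive T cells
  - {from: IL12, to: Th1, sign: "+", condition: {node: NaiveTcell, states: [1]}}
  # IL10 suppresses Th1 differentiation of primed naive T cells
  - {from: IL10, to: Th1, sign: "-", condition: {node: NaiveTcell, states: [1]}}
  # IL4 antagonizes Th1 polarization of primed naive T cells
  - {from: IL4, to: Th1, sign: "-", condition: {node: NaiveTcell, states: [1]}}
  # Th1 cells secrete IL2
  - {from: Th1, to: IL2, sign: "+"}
  # IL2 activates NK cells
  - {from: IL2, to: NKcell, sign: "+"}
  # Th1 cells secrete IFNg
  - {from: Th1, to: IFNg, sign: "+"}
  # activated NK cells secrete IFNg
  - {from: NKcell, to: IFNg, sign: "+"}
  # IFNg classically activates macrophages
  - {from: IFNg, to: Macrophage, sign: "+"}
  # DCs secrete IL12
  - {from: SubmucosalDC, to: IL12, sign: "+"}
  # activated macrophages secrete IL12
  - {from: Macrophage, to: IL12, sign: "+"}
  # macrophages secrete IL1b
  - {from: Macrophage, to: IL1b, sign: "+"}
  # neutrophils release IL1b at inflamed sites
  - {from: Neutrophil, to: IL1b, sign: "+"}
  # macrophages secrete IL6
  - {from: Macrophage, to: IL6, sign: "+"}
  # DCs secrete IL6
  - {from: SubmucosalDC, to: IL6, sign: "+"}
  # mucosal epithelium is a constitutive IL6 source
  - {from: EpithelialCell, to: IL6, sign: "+"}
  # DCs secrete IL23
  - {from: SubmucosalDC, to: IL23, sign: "+"}
  # macrophages secrete IL23
  - {from: Macrophage, to: IL23, sign: "+"}
  # macrophage oxidative burst produces reactive oxygen intermediates
  - {from: Macrophage, to: ROI, sign: "+"}
  # neutrophil oxidative burst produces reactive oxygen intermediates
  - {from: Neutrophil, to: ROI, sign: "+"}

  # --- effector cytokines / granulocytes ---------------------------------
  # macrophages secrete TNFa; Treg activity licenses its shutdown
  - {from: Macrophage, to: TNFa, sign: "+", condition: {node: Treg, states: [0]}}
  # Th17 cells are the adaptive IL17 source
  - {from: Th17, to: IL17, sign: "+"}
  # innate-like lymphocytes (NK/NKT/ILC compartment) also produce IL17
  - {from: NKcell, to: IL17, sign: "+"}
  # IL8 is the principal neutrophil chemoattractant
  - {from: IL8, to: Neutrophil, sign: "+"}
  # GM-CSF expands and primes neutrophils
  - {from: GMCSF, to: Neutrophil, sign: "+"}
  # IL17 drives neutrophil recruitment to the mucosa
  - {from: IL17, to: Neutrophil, sign: "+"}
  # TNFa primes and recruits neutrophils
  - {from: TNFa, to: Neutrophil, sign: "+"}
  # IL1b mobilizes neutrophils
  - {from: IL1b, to: Neutrophil, sign: "+"}
  # IL6 sustains granulopoiesis
  - {from: IL6, to: Neutrophil, sign: "+"}

  # --- adaptive arms and regulatory axis ----------------------------------
  # IFNg suppresses Th2 polarization once TNFa-driven acute inflammation resolves
  - {from: IFNg, to: Th2, sign: "-", condition: {node: TNFa, states: [0]}}
  # TGFb drives Th17 differentiation of primed naive T cells
  - {from: TGFb, to: Th17, sign: "+", condition: {node: NaiveTcell, states: [1]}}
  # IFNg suppresses Th17 polarization in the TNFa-resolved context
  - {from: IFNg, to: Th17, sign: "-", condition: {node: TNFa, states: [0]}}
  # IL6 blocks Treg induction in the TNFa-resolved context
  - {from: IL6, to: Treg, sign: "-", condition: {node: TNFa, states: [0]}}
  # Tregs secrete TGFb
  - {from: Treg, to: TGFb, sign: "+"}
  # Th2 cells secrete IL4
  - {from: Th2, to: IL4, sign: "+"}
  # Th2 cells secrete IL13
  - {from: Th2, to: IL13, sign: "+"}
  # Tregs secrete IL10
  - {from: Treg, to: IL10, sign: "+"}
  # Th2 cells secrete IL10
  - {from: Th2, to: IL10, sign: "+"}

  # --- epithelial compartment ---------------------------------------------
  # TGFb maintains epithelial integrity and repair
  - {from: TGFb, to: EpithelialCell, sign: "+"}
  # pathogen contact irritates/damages the epithelium (deficient-mucus edge)
  - {from: Infection, to: EpithelialCell, sign: "-"}
  # epithelium secretes IL8
  - {from: EpithelialCell, to: IL8, sign: "+"}
  # epithelium secretes CCL2/MCP1
  - {from: EpithelialCell, to: CCL2, sign: "+"}
  # epithelium secretes GM-CSF
  - {from: EpithelialCell, to: GMCSF, sign: "+"}
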