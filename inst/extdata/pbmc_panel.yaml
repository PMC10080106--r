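# 22-color PBMC immunophenotyping panel: marker <-> fluorophore assignment,
# heatmap category, titrated concentration (uL/test), approximate emission
# peak and primary excitation laser used to synthesize spectral signatures.
name: pbmc_panel
channels:
- {marker: CD126,    fluorophore: BV421,          category: activation, concentration: 1.25, peak_nm: 421, laser: violet}
- {marker: HLA-DR,   fluorophore: eFluor450,      category: activation, concentration: 1.25, peak_nm: 450, laser: violet}
- {marker: IgD,      fluorophore: BV480,          category: lineage,    concentration: 0.5,  peak_nm: 478, laser: violet}
- {marker: LiveDead, fluorophore: LD-Aqua,        category: viability,  concentration: 0.1,  peak_nm: 526, laser: violet}
- {marker: CD16,     fluorophore: BV570,          category: lineage,    concentration: 1.25, peak_nm: 570, laser: violet}
- {marker: IgG,      fluorophore: BV605,          category: lineage,    concentration: 2.5,  peak_nm: 605, laser: violet}
- {marker: CD4,      fluorophore: cFluorV610,     category: lineage,    concentration: 1.25, peak_nm: 613, laser: violet}
- {marker: CD56,     fluorophore: BV650,          category: lineage,    concentration: 0.5,  peak_nm: 645, laser: violet}
- {marker: CD95,     fluorophore: BV711,          category: activation, concentration: 1.25, peak_nm: 711, laser: violet}
- {marker: CD11b,    fluorophore: BV750,          category: lineage,    concentration: 1.25, peak_nm: 750, laser: violet}
- {marker: PD-1,     fluorophore: BV785,          category: inhibitory, concentration: 1.25, peak_nm: 785, laser: violet}
- {marker: CD11c,    fluorophore: BB515,          category: lineage,    concentration: 1.25, peak_nm: 515, laser: blue}
- {marker: CD69,     fluorophore: FITC,           category: activation, concentration: 1.25, peak_nm: 519, laser: blue}
- {marker: CD27,     fluorophore: PE,             category: lineage,    concentration: 1.25, peak_nm: 578, laser: blue}
- {marker: CD70,     fluorophore: PE-Dazzle594,   category: activation, concentration: 5,    peak_nm: 616, laser: blue}
- {marker: CD14,     fluorophore: PerCP-Cy5.5,    category: lineage,    concentration: 2.5,  peak_nm: 695, laser: blue}
- {marker: CD3,      fluorophore: PE-Cy7,         category: lineage,    concentration: 0.5,  peak_nm: 780, laser: blue}
- {marker: CD25,     fluorophore: APC,            category: activation, concentration: 2.5,  peak_nm: 660, laser: red}
- {marker: CD169,    fluorophore: AlexaFluor647,  category: activation, concentration: 2.5,  peak_nm: 668, laser: red}
- {marker: CD86,     fluorophore: APC-R700,       category: activation, concentration: 1.25, peak_nm: 719, laser: red}
- {marker: CD19,     fluorophore: APC-Cy7,        category: lineage,    concentration: 0.5,  peak_nm: 780, laser: red}
- {marker: CD38,     fluorophore: APC-Fire810,    category: activation, concentration: 2.5,  peak_nm: 812, laser: red}
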