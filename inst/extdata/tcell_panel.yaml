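# 22-color T-cell immunophenotyping panel (effector/memory states, T-helper
# lineages, activation and inhibitory receptors).
name: tcell_panel
channels:
- {marker: CCR7,     fluorophore: BV421,          category: maturation, concentration: 1.25, peak_nm: 421, laser: violet}
- {marker: CD45RO,   fluorophore: PacificBlue,    category: maturation, concentration: 2.5,  peak_nm: 455, laser: violet}
- {marker: TCRgd,    fluorophore: Horizon480,     category: lineage,    concentration: 2.5,  peak_nm: 478, laser: violet}
- {marker: LiveDead, fluorophore: LD-Aqua,        category: viability,  concentration: 0.1,  peak_nm: 526, laser: violet}
- {marker: CD8,      fluorophore: BV570,          category: lineage,    concentration: 0.5,  peak_nm: 570, laser: violet}
- {marker: CD134,    fluorophore: BV605,          category: activation, concentration: 1.25, peak_nm: 605, laser: violet}
- {marker: CD28,     fluorophore: BV650,          category: activation, concentration: 1.25, peak_nm: 645, laser: violet}
- {marker: CCR6,     fluorophore: BV711,          category: lineage,    concentration: 1.25, peak_nm: 711, laser: violet}
- {marker: CXCR5,    fluorophore: BV750,          category: lineage,    concentration: 1.25, peak_nm: 750, laser: violet}
- {marker: PD-1,     fluorophore: BV785,          category: inhibitory, concentration: 1.25, peak_nm: 785, laser: violet}
- {marker: CD69,     fluorophore: FITC,           category: activation, concentration: 1.25, peak_nm: 519, laser: blue}
- {marker: CTLA-4,   fluorophore: PE,             category: inhibitory, concentration: 2.5,  peak_nm: 578, laser: blue}
- {marker: CXCR3,    fluorophore: PE-Dazzle594,   category: lineage,    concentration: 2.5,  peak_nm: 616, laser: blue}
- {marker: CD45RA,   fluorophore: PerCP,          category: maturation, concentration: 0.5,  peak_nm: 677, laser: blue}
- {marker: CD71,     fluorophore: PerCP-Cy5.5,    category: activation, concentration: 2.5,  peak_nm: 695, laser: blue}
- {marker: CCR4,     fluorophore: PerCP-eFluor710, category: lineage,   concentration: 1.25, peak_nm: 710, laser: blue}
- {marker: CD4,      fluorophore: PE-Cy7,         category: lineage,    concentration: 0.5,  peak_nm: 780, laser: blue}
- {marker: CD25,     fluorophore: APC,            category: activation, concentration: 2.5,  peak_nm: 660, laser: red}
- {marker: ICOS,     fluorophore: AlexaFluor647,  category: activation, concentration: 5,    peak_nm: 668, laser: red}
- {marker: CD127,    fluorophore: APC-R700,       category: lineage,    concentration: 1.25, peak_nm: 719, laser: red}
- {marker: CD3,      fluorophore: APC-Cy7,        category: lineage,    concentration: 1.25, peak_nm: 780, laser: red}
- {marker: CD38,     fluorophore: APC-Fire810,    category: activation, concentration: 2.5,  peak_nm: 812, laser: red}
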