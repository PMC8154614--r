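# Packaged DPD bead library.
#
# Naming: a trailing "p" replaces the prime in bead tokens (OHp = OH', AM3p =
# AM3', C2p = C2', ACp = AC').  SSIP values are polarity parameters epsilon
# (positive = H-bond donor character, negative = acceptor), listed in
# descending |epsilon|.  volume is the van der Waals volume in A^3.  a_self
# (k_BT) and R_self (r_c) are the self repulsion and self contact radius.
#
# liquid holds the provenance of the reference-liquid concentration used for
# the SSIP speciation: a closely related molecule, its 25 C density (g/mL),
# molar mass (g/mol), and the divisor that maps the molecule concentration to
# the bead-liquid concentration (e.g. half of dimethoxyethane for EO and ACp,
# one quarter of n-octane for C2-type beads, one eighth for T1; the water bead
# represents two water molecules).  The effective concentration is
#   1000 * density / molar_mass / divisor   (mol/L).
schema: dpdchem-bead-library-1
beads:
  - name: W
    ssips: [-4.5, -4.5, 2.8, 2.8]
    volume: 42.0
    a_self: 25.00
    R_self: 1.000
    liquid: {molecule: water, density: 0.997, molar_mass: 18.015, divisor: 2}
  - name: ES
    ssips: [-5.5, -5.5, -2.6, 0.4, 0.4, 0.4, 0.4, 0.2, 0.2]
    volume: 68.8
    a_self: 22.00
    R_self: 1.141
    liquid: {molecule: methyl acetate, density: 0.932, molar_mass: 74.08, divisor: 1}
  - name: EO
    ssips: [-5.3, -5.3, 0.4, 0.4, 0.4, 0.4]
    volume: 48.7
    a_self: 22.50
    R_self: 1.116
    liquid: {molecule: 1,2-dimethoxyethane, density: 0.868, molar_mass: 90.12, divisor: 2}
  - name: ACp
    ssips: [-4.4, -4.4, -4.4, -4.4, 0.4]
    volume: 31.9
    a_self: 22.50
    R_self: 0.952
    liquid: {molecule: 1,2-dimethoxyethane, density: 0.868, molar_mass: 90.12, divisor: 2}
  - name: AM2
    ssips: [-7.9, -7.9, 2.9, -0.9, -0.9, 0.4, 0.4, 0.4, 0.4]
    volume: 73.2
    a_self: 22.00
    R_self: 1.172
    liquid: {molecule: N-methylacetamide, density: 0.957, molar_mass: 73.09, divisor: 1}
  - name: AM3p
    ssips: [-7.9, -7.9, -0.9, -0.9, 0.4, 0.4, 0.4, 0.4, 0.4, 0.4]
    volume: 85.6
    a_self: 22.00
    R_self: 1.236
    liquid: {molecule: N,N-dimethylacetamide, density: 0.937, molar_mass: 87.12, divisor: 1}
  - name: AM3
    ssips: [-7.9, -7.9, -0.9, -0.9, 0.4, 0.4, 0.4, 0.4, 0.4, 0.4, 0.4]
    volume: 92.1
    a_self: 22.00
    R_self: 1.266
    liquid: {molecule: N,N-dimethylacetamide, density: 0.937, molar_mass: 87.12, divisor: 1}
  - name: T1
    ssips: [0.4, 0.4, 0.4, -0.3]
    volume: 25.9
    a_self: 24.00
    R_self: 0.955
    liquid: {molecule: n-octane, density: 0.703, molar_mass: 114.23, divisor: 8}
  - name: T2
    ssips: [0.4, 0.4, 0.4, 0.4, 0.4, -0.3, -0.3]
    volume: 45.2
    a_self: 24.00
    R_self: 1.098
    liquid: {molecule: n-octane, density: 0.703, molar_mass: 114.23, divisor: 4}
  - name: C2
    ssips: [0.4, 0.4, 0.4, 0.4, -0.3, -0.3]
    volume: 38.9
    a_self: 22.00
    R_self: 1.074
    liquid: {molecule: n-octane, density: 0.703, molar_mass: 114.23, divisor: 4}
  - name: C2p
    ssips: [0.4, 0.4, 0.4, -0.3, -0.3]
    volume: 32.2
    a_self: 22.00
    R_self: 0.995
    liquid: {molecule: n-octane, density: 0.703, molar_mass: 114.23, divisor: 4}
  - name: OH1
    ssips: [-5.3, -5.3, 2.7, 0.4, 0.4, -0.3]
    volume: 34.7
    a_self: 14.00
    R_self: 0.980
    liquid: {molecule: methanol, density: 0.791, molar_mass: 32.04, divisor: 1}
  - name: OHp
    ssips: [-5.3, -5.3, 2.7, 0.4, -0.3]
    volume: 28.1
    a_self: 14.00
    R_self: 0.949
    liquid: {molecule: methanol, density: 0.791, molar_mass: 32.04, divisor: 1}
  - name: OH2
    ssips: [-5.3, -5.3, 2.7, 0.4, 0.4, 0.4, -0.3]
    volume: 43.8
    a_self: 18.00
    R_self: 1.012
    liquid: {molecule: ethanol, density: 0.789, molar_mass: 46.07, divisor: 1}
topologies: []
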