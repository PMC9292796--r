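description: Curated free-energy dataset for the tricyclic chalcogen antioxidant scaffolds
  PS/PSE/PTE with HO., HOO. and CH3OO. in water and pentyl ethanoate
checksums:
  channels: b2b758ca2c94e126dbcc0115ba9e1299
media:
  water:
    temperature: 298.15
    viscosity: 0.000891
    polarity_class: aqueous
    viscosity_provenance: literature default, 298.15 K
  pentyl_ethanoate:
    temperature: 298.15
    viscosity: 0.000862
    polarity_class: lipid
    viscosity_provenance: literature default
species:
  PS:
    role: antioxidant
    chalcogen: S
    stokes_radius: 3.6e-10
  PSE:
    role: antioxidant
    chalcogen: Se
    stokes_radius: 3.6e-10
  PTE:
    role: antioxidant
    chalcogen: Te
    stokes_radius: 3.6e-10
  HO:
    role: radical
    stokes_radius: 2.2e-10
  HOO:
    role: radical
    stokes_radius: 2.46e-10
  CH3OO:
    role: radical
    stokes_radius: 2.9e-10
marcus_region_hints:
- antioxidant: PSE
  radical: HO
  medium: water
  region: inverted
- antioxidant: PTE
  radical: HO
  medium: water
  region: inverted
notes:
  stokes_radii: Sphere-equivalent defaults; the source prints neither radii nor encounter
    distances, so all diffusion-limited entries are reproduced through runtime calibration
    of reaction distances and are never acceptance predictions
  typo_pte_5a: The tabulated RAF reaction energy for PTE site 5a in water is garbled
    in the source ('-38. .7'); encoded as -38.7, the evident reading
  ring_opening: PTE RAF site-5a adducts open the central ring; the original antioxidant
    is not recoverable
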