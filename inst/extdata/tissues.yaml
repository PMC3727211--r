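# Tissue dielectric properties at 128 MHz (3 T proton Larmor frequency).
# sigma in S/m, eps_r dimensionless, density in kg/m^3.
# Grey matter, white matter and implant values follow the modelling
# literature for this frequency; skin/skull/CSF conductivity+permittivity
# are standard 128 MHz literature values and the densities are generic
# textbook values (neither is device- or subject-specific).
tissues:
  air:        {sigma: 0.0,     eps_r: 1.0,   density: 1.2}
  skin:       {sigma: 0.52,    eps_r: 65.4,  density: 1100}
  skull:      {sigma: 0.067,   eps_r: 14.7,  density: 1900}
  csf:        {sigma: 2.14,    eps_r: 84.0,  density: 1010}
  wm:         {sigma: 0.34,    eps_r: 52.53, density: 1040}
  gm:         {sigma: 0.58,    eps_r: 73.51, density: 1040}
  conductor:  {sigma: 4.0e+6,  eps_r: 1.0,   density: 21450}
  insulation: {sigma: 1.0e-10, eps_r: 3.0,   density: 1100}
# basal-ganglia nuclei take grey-matter properties; medullary laminae take
# white-matter properties
aliases:
  caudate: gm
  putamen: gm
  gpe: gm
  gpi: gm
  iml: wm
  eml: wm
  grey_matter: gm
  white_matter: wm
labels:
  0: air
  1: skin
  2: skull
  3: csf
  4: wm
  10: caudate
  11: putamen
  12: gpe
  13: gpi
  20: eml
  21: iml
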