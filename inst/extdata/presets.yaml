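# Committed study presets. Units: um (length), 1/um (curvature).
#
# Wrinkle presets emulate the solvent-series substrates: C100 (pure-ethanol
# treatment; deep, high-curvature, more multiaxial wrinkles) and C70 (70%
# ethanol; shallow, low-curvature, more uniaxial wrinkles). Amplitudes match
# the printed peak-to-trough depths (155 and 30.8 um); lambda_c is calibrated
# once so the area-weighted mean |H| reproduces the printed statistics
# (0.019 and 0.009 1/um). Groove widths are the sacrificed statistic: a
# band-limited random-phase field ties width to lambda_c, while the real
# cusped wrinkles decouple them.
surfaces:
  FLAT:
    type: wrinkle
    lambda_c: 90
    A: 0
    anisotropy: 0
    bandwidth: 0.25
    seed: 100
    grid_n: 160
    spacing: 4
  C100:
    type: wrinkle
    lambda_c: 90
    A: 77.5
    anisotropy: 0.2
    bandwidth: 0.25
    seed: 101
    grid_n: 160
    spacing: 4
  C70:
    type: wrinkle
    lambda_c: 88
    A: 15.4
    anisotropy: 0.45
    bandwidth: 0.25
    seed: 70
    grid_n: 160
    spacing: 4
  # quasi-uniaxial groove surfaces at the two printed ridge-top
  # circumferential curvatures; theta = 0 is the groove (axial) direction
  uniaxial-low:
    type: groove
    K_perp: 0.011
    lambda: 60
    grid_n: 161
    spacing: 1
  uniaxial-high:
    type: groove
    K_perp: 0.018
    lambda: 60
    grid_n: 161
    spacing: 1
  # constructed surface whose curvature varies with the azimuth: three equal
  # cosine waves at 0/60/120 degrees; evaluation point is the common crest
  constructed-multiaxial:
    type: multiaxial
    amplitudes: [0.486, 0.486, 0.486]
    directions_deg: [0, 60, 120]
    wavelengths: [40, 40, 40]
    grid_n: 321
    spacing: 0.5

# Microgel presets at the three fabricated diameters; perturbation amplitude
# and harmonic band calibrated once against the printed absolute mean
# curvatures (0.040, 0.031, 0.017 1/um) with the quadric-fit estimator at
# the stated mesh resolution.
microgels:
  microgel-small:
    diameter: 97.2
    amplitude: 4.8
    l_min: 18
    l_max: 30
    seed: 7
    subdiv: 4
  microgel-moderate:
    diameter: 203.8
    amplitude: 8.8
    l_min: 14
    l_max: 24
    seed: 7
    subdiv: 5
  microgel-large:
    diameter: 532.4
    amplitude: 37
    l_min: 16
    l_max: 26
    seed: 7
    subdiv: 5

# Default generator sweep emulating the ethanol-fraction series: amplitudes
# from the C70 to the C100 depth scale crossed with wavelengths from below
# the C70 to the C100 groove scale. The sweep's area-weighted mean |H| range
# brackets the printed substrate statistics.
wrinkle_sweep:
  amplitudes: [15.4, 40, 77.5]
  wavelengths: [55, 90, 170]
  anisotropy: 0.35
  bandwidth: 0.25
  grid_n: 128
  spacing: 3
  base_seed: 20

# Cytoskeletal drug perturbations as parameter maps. *_factor entries
# multiply the field; *_set entries assign it; basal_fraction_set fixes
# N_f_b / (N_f_b + N_f_a) holding the total fiber count.
drugs:
  CN03:
    F_a0_factor: 2
    basal_fraction_set: 0.68
  Y27632:
    N_f_a_set: 0
    F_a0_factor: 0.5
  blebbistatin:
    F_a0_factor: 0.1
  latrunculinB:
    N_f_a_factor: 0.05
    N_f_b_factor: 0.05
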