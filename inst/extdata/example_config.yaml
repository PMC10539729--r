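# example simulation configuration (small, fast demonstration values)
density: 0.0668        # protons per cubic angstrom
cutoff: 8              # bath radius, angstrom
exclusion_e: 2.5       # minimum electron-proton distance, angstrom
min_hh: 1.5            # minimum inter-pair proton-proton distance, angstrom
protonation: 1.0
seed: 1
B0: 3.38               # tesla
k: 2                   # CCE truncation level
threshold_khz: 1.58    # cluster coupling threshold
lebedev: 14
sequence: refocused
tau1_us: [0, 8, 13]    # [start, stop, points]
tau2_us: [0, 8, 13]
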