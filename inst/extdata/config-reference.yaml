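# Reference configuration for stdbind::run_pipeline().
# Every key is optional; the values shown are the defaults.

seed: 1                    # master seed for all simulated stages
epsilon: 40                # ligand:protein concentration ratio (800 uM / 20 uM)
schedule: [0.5, 1, 1.5, 2, 3, 4, 5, 6]   # saturation times, seconds

noise:
  intensity_cv: 0.02       # multiplicative cv on simulated NMR intensities
  concentration_cv: 0.01   # multiplicative cv on dialysis concentrations

probe_sites:               # competition probe -> HSA site it blocks
  warfarin: site_I
  diazepam: site_II

ambiguity_threshold: 10    # percentage points between probe medians
secondary_tolerance: 10    # a site competes if its median < 100 - this
constrain_rate: true       # competition refits share the reference k_sat

# --- input selection (pick one NMR source; both are optional) -------------
# simulate:
#   ligand: 3-CMC          # or 4-CMC
#   probes: [diazepam, warfarin]
# intensity_table: path/to/intensities.csv

# --- binding-degree stage (optional) --------------------------------------
# dialysis:
#   simulate:
#     n_replicates: 5
#     methods: [ED, UF]
#   # or instead of simulate:
#   # table: path/to/dialysis.csv
#   # molar_mass: 233.7    # g/mol, to convert ug/mL rows to uM
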