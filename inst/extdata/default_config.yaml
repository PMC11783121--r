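# tamipd workflow configuration (all values shown are the package defaults;
# omit any key to keep its default)

model:
  tvc20: 31.3          # typical steady-state endoxifen at 20 mg, nM (reference patient)
  theta_as: 2.15       # CYP2D6 activity coefficient, log scale per activity unit
  theta_age: -0.2      # power-law exponent on age/ref_age
  theta_bmi: -0.3      # power-law exponent on BMI/ref_bmi
  theta_height: 0.0    # power-law exponent on height/ref_height
  ref_age: 57          # years (cohort median)
  ref_bmi: 26.2        # kg/m2
  ref_height: 168      # cm
  ref_as: 0.68         # activity units (cohort median)
  omega: 0.50          # between-patient SD of eta, log scale
  sigma: 0.20          # residual SD of a measured concentration, log scale
  t_half_acc: 14       # effective accumulation half-life, days

# per-allele CYP2D6 activity values; a fully active *1/*1 scores 1.0.
# duplications use the "xN" suffix and multiply the base value.
alleles:
  "*1": 0.5
  "*2": 0.5
  "*35": 0.5
  "*9": 0.3
  "*10": 0.25
  "*17": 0.25
  "*41": 0.25
  "*3": 0.0
  "*4": 0.0
  "*5": 0.0
  "*6": 0.0

thresholds:
  target_nM: 16               # therapeutic endoxifen threshold (>= is therapeutic)
  upper_nM: null              # optional upper bound of the therapeutic window (disabled)
  margin: 0                   # optional fractional margin on the threshold (off)
  mw_endoxifen: 373.5         # g/mol, for ng/mL <-> nM conversion (16 nM = 5.97 ng/mL)
  informative_cutoff_days: 22 # first day a sample is informative of steady state
  steady_state_day: 84        # first day an observation counts as steady state

simulation:
  preset: control             # "control" or "intervention" cohort structure
  nonadherent_fraction: 0     # fraction of virtual patients with reduced exposure
  nonadherence_multiplier: 0.5
  sample_days: [35, 90]       # 4-6-week visit midpoint and steady-state visit
  seed: 1
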