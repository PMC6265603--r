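# Default configuration for the shipped PI3K/Akt-OGT pathway variants.
#
# Single source of truth for initial markings (tokens, relative activity
# units) and transition rate constants (per time unit). All standard arc
# weights in the shipped nets are 1; the only non-unit weight anywhere is
# the threshold of the Metformin inhibitory arc below, which is a
# calibration choice (it sets the depth of proliferation inhibition at the
# default dose), as are the handful of rate constants that differ from the
# baseline value 1 or between variants (OGT-branch gains, supply/turnover
# rates). Tokens are relative levels, not concentrations; time units are
# dimensionless.
variants:
  normal_adipocyte:
    places:
      insulin: 1.0
      insulin_receptor: 1.0
      complex1: 0.0
      irs1_inactive: 1.0
      irs1_active: 0.05
      pi3k_inactive: 1.0
      pi3k_active: 0.05
      pip3: 0.05
      pdk1: 1.0
      mtorc2: 1.0
      akt_inactive: 1.0
      akt_active: 0.05
      glut4_internal: 1.0
      glut4_membrane: 0.05
      cell_survival: 0.1
      glucose: 1.0
      udp_glcnac: 0.5
      ogt_mrna: 1.0
      ogt: 1.0
      oga: 1.0
    rates:
      insulin_supply: 0.05
      insulin_decay: 0.01
      receptor_supply: 0.05
      receptor_decay: 0.05
      complex_formation: 0.1
      complex_dissociation: 0.05
      irs1_activation: 1.0
      irs1_deactivation: 0.1
      pi3k_activation: 1.0
      pi3k_deactivation: 0.1
      pip3_synthesis: 0.5
      pip3_degradation: 0.5
      pdk1_supply: 0.05
      pdk1_decay: 0.05
      mtorc2_supply: 0.05
      mtorc2_decay: 0.05
      akt_activation: 1.0
      akt_deactivation: 0.4
      glut4_translocation: 0.15
      glut4_internalisation: 0.1
      survival_signal: 0.01
      survival_decay: 0.05
      glucose_supply: 1.0
      glycolysis: 1.0
      hbp_flux: 0.04          # ~4% of glucose flux enters the HBP
      udp_glcnac_decay: 0.04
      ogt_transcription: 0.05
      ogt_mrna_decay: 0.05
      ogt_synthesis: 0.015
      ogt_decay: 0.015
      oga_supply: 0.05
      oga_decay: 0.05
      irs1_oglcnac: 0.05      # balanced O-GlcNAc cycling in the normal cell
      irs1_deglcnac: 0.05
      akt_oglcnac: 0.05
      akt_deglcnac: 0.05
  insulin_resistant_adipocyte:
    # Same topology as the normal adipocyte; OGT transcription is elevated
    # and the OGT-driven deactivation of IRS-1 and Akt runs at a 10-fold
    # higher gain (calibrated), overwhelming OGA-mediated removal.
    places:
      inherit: normal_adipocyte
    rates:
      inherit: normal_adipocyte
      ogt_transcription: 0.2
      irs1_oglcnac: 0.5
      akt_oglcnac: 0.5
  cancer_hyperglycemia:
    # Hyperglycemia: raised glucose supply rate and initial tokens feeding
    # the HBP; OGT targets Akt only (activating), enhances GLUT4 surface
    # expression and drives proliferation (survival gain calibrated).
    places:
      inherit: normal_adipocyte
      glucose: 7.0
    rates:
      inherit: normal_adipocyte
      glucose_supply: 7.0
      survival_signal: 0.03
      akt_oglcnac_activation: 0.6
      akt_deglcnac: 0.05
      glut4_ogt_translocation: 0.1
interventions:
  shrna:
    dose: 10.0            # initial shRNA tokens
    binding_rate: 1.0     # shrna + ogt_mrna -> degraded (both consumed)
  bzx:
    dose: 10.0            # initial BZX tokens; dose sweep presets below
    binding_rate: 1.0     # bzx + ogt -> inert covalent complex
  metformin:
    dose: 10.0
    turnover: 0.05        # supply/decay holding the drug at its dose level
    inhibition_threshold: 7.5   # inhibitory arc weight (calibrated)
sweep:
  bzx_doses: [10.0, 20.0, 30.0]
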