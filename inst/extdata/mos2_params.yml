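# Default nonbonded parameters for a 2H-MoS2 monolayer.
#
# PROVISIONAL VALUES. The sigma/epsilon/charge set below is a widely used
# MoS2 force-field parameterisation (Mo +0.6 e / S -0.3 e, neutral sheet per
# unit: q_Mo + 2*q_S = 0); replace it with the parameter set matching your
# own simulations. Units: sigma nm, epsilon kcal/mol, charge e.
species:
  Mo:
    sigma: 0.4200
    epsilon: 0.0135
    charge: 0.6
  S:
    sigma: 0.3130
    epsilon: 0.4612
    charge: -0.3
  # Element-keyed entries for protein atoms (CHARMM-like scales). Only
  # sigma/epsilon are read for non-sheet atoms: protein partial charges live
  # in the topology, so the charge fields below stay 0.
  C:
    sigma: 0.3670
    epsilon: 0.0700
    charge: 0.0
  "N":  # quoted: a bare N is YAML-1.1 boolean
    sigma: 0.3296
    epsilon: 0.2000
    charge: 0.0
  O:
    sigma: 0.3029
    epsilon: 0.1200
    charge: 0.0
  H:
    sigma: 0.0400
    epsilon: 0.0460
    charge: 0.0
combination_rule: lorentz-berthelot
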