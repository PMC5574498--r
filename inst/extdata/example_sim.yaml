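# Example simulation config: a newer analyzer ("sim_a") against a reference
# ("sim_b") on a food panel, with a positive propensity of sim_a for the
# dust-mite allergen.
n_patients: 40
analyzer_a: sim_a
analyzer_b: sim_b
panel: food
cutoff: 2
seed: 1
allergens:
  # large one-sided deltas cap the attainable kappa, so the discordant
  # allergens carry moderate targets
  - name: dermatophagoides farinae
    prevalence_a: 0.50
    kappa_target: 0.50
    propensity_delta: 0.20
  - name: house dust
    prevalence_a: 0.30
    kappa_target: 0.20
    propensity_delta: 0.25
  - name: cat
    prevalence_a: 0.07
    kappa_target: 0.65
  - name: milk
    prevalence_a: 0.04
    kappa_target: 0.80
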