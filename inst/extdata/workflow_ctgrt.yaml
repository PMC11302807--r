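# CTgRT (TrueBeam + CBCT) five-fraction SBRT process map, aggregated at
# (personnel x stage) granularity; same fixture conventions as the MRgRT
# map. Equipment/space are calibrated to the published modality totals
# (equipment 1343.97, space 74.85 USD): a 30-min CT simulation on the
# PET/CT simulator and room ([DERIVED] assumption), with the remaining
# machine/surface-imaging/immobilisation and vault minutes attached to the
# treatment stage; only modality-level totals are asserted.
metadata:
  provenance: >
    Personnel cells [DERIVED] from the published stage-cost grid divided by
    published CCRs; equipment/space minutes [DERIVED] from published
    modality totals; structure [PAPER].
modality: CTgRT
n_fractions: 5
stages:
  - consultation
  - simulation
  - planning
  - treatment
  - on-treatment visit
  - follow-up
steps:
  - id: ct_consult_cma
    label: Consultation intake (medical assistant)
    stage: consultation
    usages:
      - {resource: cma, minutes: 4.80/0.32}
  - id: ct_consult_nurse
    label: Consultation nursing
    stage: consultation
    usages:
      - {resource: nurse, minutes: 22.40/0.64}
  - id: ct_consult_md
    label: Consultation (attending physician)
    stage: consultation
    usages:
      - {resource: attending, minutes: 341.00/4.40}
  - id: ct_ct_sim
    label: CT simulation
    stage: simulation
    usages:
      - {resource: rtt, headcount: 2, minutes: 30}
      - {resource: eq_petct, minutes: 30}
      - {resource: room_petct, minutes: 30}
  - id: ct_sim_rtt
    label: Simulation setup and immobilisation (therapists)
    stage: simulation
    usages:
      - {resource: rtt, minutes: 213.00/0.71}
  - id: ct_sim_nurse
    label: Simulation nursing
    stage: simulation
    usages:
      - {resource: nurse, minutes: 2.56/0.64}
  - id: ct_sim_mp
    label: Simulation physics checks
    stage: simulation
    usages:
      - {resource: physicist, minutes: 278.46/2.34}
  - id: ct_sim_md
    label: Simulation oversight (attending)
    stage: simulation
    usages:
      - {resource: attending, minutes: 44.00/4.40}
  - id: ct_plan_mp
    label: Plan QA and review (physicist)
    stage: planning
    usages:
      - {resource: physicist, minutes: 163.80/2.34}
  - id: ct_plan_md
    label: Plan review and approval (attending)
    stage: planning
    usages:
      - {resource: attending, minutes: 154.00/4.40}
  - id: ct_plan_dos
    label: VMAT treatment planning (dosimetrist)
    stage: planning
    usages:
      - {resource: dosimetrist, minutes: 242.82/1.14}
  - id: ct_plan_res
    label: Contouring (resident)
    stage: planning
    usages:
      - {resource: resident, minutes: 33.63/0.59}
  - id: ct_tx_rtt
    label: Treatment delivery (therapists)
    stage: treatment
    per_fraction: true
    usages:
      - {resource: rtt, headcount: 2, minutes: 48}
  - id: ct_tx_mp
    label: Treatment physics coverage
    stage: treatment
    per_fraction: true
    usages:
      - {resource: physicist, minutes: 489.06/11.70}
  - id: ct_tx_md
    label: Treatment oversight (attending)
    stage: treatment
    per_fraction: true
    usages:
      - {resource: attending, minutes: 8}
  - id: ct_tx_machine
    label: Linac occupancy over the course
    stage: treatment
    usages:
      - {resource: eq_truebeam, minutes: 1247.67/4.56}
  - id: ct_tx_identify
    label: Surface imaging occupancy over the course
    stage: treatment
    usages:
      - {resource: eq_identify, minutes: 1247.67/4.56}
  - id: ct_tx_orfit
    label: Immobilisation system occupancy over the course
    stage: treatment
    usages:
      - {resource: eq_orfit, minutes: 1247.67/4.56}
  - id: ct_tx_vault
    label: Vault occupancy over the course
    stage: treatment
    usages:
      - {resource: vault_truebeam, minutes: 72.45/0.31}
  - id: ct_otv_cma
    label: On-treatment visit intake
    stage: on-treatment visit
    usages:
      - {resource: cma, minutes: 4.80/0.32}
  - id: ct_otv_nurse
    label: On-treatment visit nursing
    stage: on-treatment visit
    usages:
      - {resource: nurse, minutes: 9.60/0.64}
  - id: ct_otv_md
    label: On-treatment visit (attending)
    stage: on-treatment visit
    usages:
      - {resource: attending, minutes: 57.20/4.40}
  - id: ct_fu_cma
    label: Follow-up intake
    stage: follow-up
    usages:
      - {resource: cma, minutes: 4.80/0.32}
  - id: ct_fu_nurse
    label: Follow-up nursing
    stage: follow-up
    usages:
      - {resource: nurse, minutes: 12.80/0.64}
  - id: ct_fu_md
    label: Follow-up visit (attending)
    stage: follow-up
    usages:
      - {resource: attending, minutes: 132.00/4.40}
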