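# MRgRT five-fraction SBRT process map, aggregated at (personnel x stage)
# granularity. Personnel minutes are stored as exact "published_cost/ccr"
# fraction strings ([DERIVED], division oracle in place); the cost engine
# recomputes the published grid from them. Equipment/space usages are
# calibrated to the published modality totals (equipment 4471.15, space
# 199.04 USD): the 20-min CT simulation uses the PET/CT simulator and room,
# and the remainder is attached to the MRIdian machine and vault at the
# treatment stage ([DERIVED]; per-stage split assumed, only modality totals
# asserted). Per-fraction treatment minutes that divide evenly are stored as
# plain per-fraction numbers ([DERIVED], cost/(ccr*heads*5)).
metadata:
  provenance: >
    Personnel cells [DERIVED] from the published stage-cost grid divided by
    published CCRs; equipment/space minutes [DERIVED] from published
    modality totals; structure (stages, fraction count) [PAPER].
modality: MRgRT
n_fractions: 5
stages:
  - consultation
  - simulation
  - planning
  - treatment
  - on-treatment visit
  - follow-up
steps:
  - id: mr_consult_rtt
    label: Consultation support (therapist)
    stage: consultation
    usages:
      - {resource: rtt, minutes: 14.20/0.71}
  - id: mr_consult_cma
    label: Consultation intake (medical assistant)
    stage: consultation
    usages:
      - {resource: cma, minutes: 4.80/0.32}
  - id: mr_consult_nurse
    label: Consultation nursing
    stage: consultation
    usages:
      - {resource: nurse, minutes: 22.40/0.64}
  - id: mr_consult_md
    label: Consultation (attending physician)
    stage: consultation
    usages:
      - {resource: attending, minutes: 385.00/4.40}
  - id: mr_ct_sim
    label: CT simulation for electron density
    stage: simulation
    usages:
      - {resource: rtt, headcount: 2, minutes: 20}
      - {resource: eq_petct, minutes: 20}
      - {resource: room_petct, minutes: 20}
  - id: mr_mri_sim_rtt
    label: MRI simulation and setup (therapists)
    stage: simulation
    usages:
      - {resource: rtt, minutes: 121.41/0.71}
  - id: mr_sim_mp
    label: Simulation physics checks
    stage: simulation
    usages:
      - {resource: physicist, minutes: 29.25/2.34}
  - id: mr_sim_md
    label: Simulation oversight (attending)
    stage: simulation
    usages:
      - {resource: attending, minutes: 57.20/4.40}
  - id: mr_sim_dos
    label: Simulation dosimetry prep
    stage: simulation
    usages:
      - {resource: dosimetrist, minutes: 22.80/1.14}
  - id: mr_plan_mp
    label: Plan QA and review (physicist)
    stage: planning
    usages:
      - {resource: physicist, minutes: 124.02/2.34}
  - id: mr_plan_md
    label: Plan review and approval (attending)
    stage: planning
    usages:
      - {resource: attending, minutes: 154.00/4.40}
  - id: mr_plan_dos
    label: Treatment planning (dosimetrist)
    stage: planning
    usages:
      - {resource: dosimetrist, minutes: 222.30/1.14}
  - id: mr_plan_res
    label: Contouring (resident)
    stage: planning
    usages:
      - {resource: resident, minutes: 61.95/0.59}
  - id: mr_tx_rtt
    label: Treatment delivery and online adaption (therapists)
    stage: treatment
    per_fraction: true
    usages:
      - {resource: rtt, headcount: 3, minutes: 108}
  - id: mr_tx_mp
    label: Treatment delivery and online adaption (physicist)
    stage: treatment
    per_fraction: true
    usages:
      - {resource: physicist, minutes: 90}
  - id: mr_tx_md
    label: Adaptive plan direction (attending)
    stage: treatment
    per_fraction: true
    usages:
      - {resource: attending, minutes: 25}
  - id: mr_tx_dos
    label: Online replanning (dosimetrist)
    stage: treatment
    per_fraction: true
    usages:
      - {resource: dosimetrist, minutes: 80}
  - id: mr_tx_machine
    label: MR-Linac occupancy over the course
    stage: treatment
    usages:
      - {resource: eq_mridian, minutes: 4406.95/8.01}
  - id: mr_tx_vault
    label: Vault occupancy over the course
    stage: treatment
    usages:
      - {resource: vault_mridian, minutes: 197.44/0.36}
  - id: mr_otv_cma
    label: On-treatment visit intake
    stage: on-treatment visit
    usages:
      - {resource: cma, minutes: 4.80/0.32}
  - id: mr_otv_nurse
    label: On-treatment visit nursing
    stage: on-treatment visit
    usages:
      - {resource: nurse, minutes: 9.60/0.64}
  - id: mr_otv_md
    label: On-treatment visit (attending)
    stage: on-treatment visit
    usages:
      - {resource: attending, minutes: 57.20/4.40}
  - id: mr_fu_cma
    label: Follow-up intake
    stage: follow-up
    usages:
      - {resource: cma, minutes: 4.80/0.32}
  - id: mr_fu_nurse
    label: Follow-up nursing
    stage: follow-up
    usages:
      - {resource: nurse, minutes: 12.80/0.64}
  - id: mr_fu_md
    label: Follow-up visit (attending)
    stage: follow-up
    usages:
      - {resource: attending, minutes: 132.00/4.40}
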