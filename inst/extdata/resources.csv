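id,name,category,annual_cost,annual_days,daily_hours,ccr,useful_life_years,provenance
rtt,Radiation therapist,personnel,,260,8,0.71,,[PAPER] published CCR table
cma,Certified medical assistant,personnel,,260,8,0.32,,[PAPER] published CCR table
nurse,Nurse,personnel,,260,8,0.64,,[PAPER] published CCR table
physicist,Medical physicist,personnel,,260,8,2.34,,[PAPER] published CCR table
attending,Attending physician,personnel,,260,8,4.40,,[PAPER] published CCR table
dosimetrist,Dosimetrist,personnel,,260,8,1.14,,[PAPER] published CCR table
resident,MP & MD residents,personnel,,260,8,0.59,,[PAPER] published CCR table
vault_truebeam,TrueBeam vault,space,,260,10,0.31,25,[PAPER] published CCR table
vault_mridian,MRIdian vault,space,,260,10,0.36,25,[PAPER] published CCR table
room_petct,PET/CT room,space,,260,8,0.08,25,[PAPER] published CCR table
eq_truebeam,TrueBeam,equipment,,260,10,4.04,10,[PAPER] published CCR table
eq_mridian,MRIdian,equipment,,260,10,8.01,10,[PAPER] published CCR table
eq_petct,Cannon PET/CT Simulator,equipment,,260,8,3.21,10,[PAPER] published CCR table
eq_identify,Identify,equipment,,260,10,0.47,10,[PAPER] published CCR table
eq_orfit,Orfit SBRT solution,equipment,,260,10,0.05,10,[PAPER] published CCR table
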