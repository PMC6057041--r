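# method: dce
# group: P2
criterion_id,weight
physical_functioning,0.250
psychological_wellbeing,0.100
social_participation,0.100
resilience,0.100
enjoyment_of_life,0.150
person_centeredness,0.050
continuity_of_care,0.050
total_costs,0.200
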