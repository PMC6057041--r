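# method: dce
# group: P1
criterion_id,weight
physical_functioning,0.100
psychological_wellbeing,0.150
social_participation,0.125
resilience,0.050
enjoyment_of_life,0.300
person_centeredness,0.100
continuity_of_care,0.125
total_costs,0.050
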