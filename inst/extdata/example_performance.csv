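criterion_id,alt,mean,se
physical_functioning,intervention,60,0
physical_functioning,comparator,70,0
psychological_wellbeing,intervention,70,0
psychological_wellbeing,comparator,50,0
social_participation,intervention,3,0
social_participation,comparator,4,0
resilience,intervention,2,0
resilience,comparator,4,0
enjoyment_of_life,intervention,4,0
enjoyment_of_life,comparator,3,0
person_centeredness,intervention,4,0
person_centeredness,comparator,3,0
continuity_of_care,intervention,5,0
continuity_of_care,comparator,3,0
total_costs,intervention,8000,0
total_costs,comparator,6000,0
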