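text,category,status
Patient has atopic dermatitis.,1,affirmed
No atopic dermatitis on examination.,1,negated
Mother has atopic dermatitis.,1,experiencer_other
Rule out atopic dermatitis.,1,hypothetical
Patient reports hay fever this spring.,2,affirmed
Denies hay fever.,2,negated
Father has hay fever.,2,experiencer_other
Possible hay fever this season.,2,hypothetical
Patient has a peanut allergy.,3,affirmed
Negative for peanut allergy.,3,negated
Brother has a peanut allergy.,3,experiencer_other
Concern for peanut allergy.,3,hypothetical
Eczema present on both arms.,4,affirmed
No evidence of eczema.,4,negated
Grandmother has eczema.,4,experiencer_other
Return if eczema flares.,4,hypothetical
Pruritus noted at night.,5,affirmed
Without pruritus at this time.,5,negated
Sister has pruritus.,5,experiencer_other
Watch for pruritus with the new soap.,5,hypothetical
Using clobetasol ointment nightly.,6,affirmed
Not taking tacrolimus anymore.,6,negated
Mom uses hydrocortisone for her hands.,6,experiencer_other
May have clobetasol added at follow-up.,6,hypothetical
Asthma is stable.,7,affirmed
Never had asthma.,7,negated
Aunt has asthma.,7,experiencer_other
Rule out asthma.,7,hypothetical
Montelukast refilled today.,8,affirmed
Denied montelukast refill.,8,negated
Uncle takes montelukast.,8,experiencer_other
Could be started on montelukast.,8,hypothetical
Denies wheezing but continues albuterol.,7,negated
Denies wheezing but continues albuterol.,8,affirmed
Family history of atopic dermatitis.,1,experiencer_other
Asthma was ruled out.,7,negated
"If itching recurs, apply emollient.",5,hypothetical
"If itching recurs, apply emollient.",6,hypothetical
No rash; asthma is stable.,4,negated
No rash; asthma is stable.,7,affirmed
Possible flexural dermatitis.,4,hypothetical
Xerosis noted on exam.,5,affirmed
Hayfever symptoms controlled with montelukast.,2,affirmed
Hayfever symptoms controlled with montelukast.,8,affirmed
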