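"item","scale","gdi","phys","psych"
"sadness","psychological",TRUE,FALSE,TRUE
"irritability","psychological",TRUE,FALSE,TRUE
"nervousness","psychological",TRUE,FALSE,TRUE
"anxiety","psychological",TRUE,FALSE,TRUE
"lack_of_appetite","physical",TRUE,TRUE,FALSE
"lack_of_energy","physical",TRUE,TRUE,FALSE
"drowsiness","physical",TRUE,TRUE,FALSE
"pain","physical",TRUE,TRUE,FALSE
"constipation","physical",TRUE,TRUE,FALSE
"dry_mouth","physical",TRUE,TRUE,FALSE
"nausea","physical",FALSE,TRUE,FALSE
"vomiting","physical",FALSE,TRUE,FALSE
"change_in_taste","physical",FALSE,TRUE,FALSE
"feeling_bloated","physical",FALSE,TRUE,FALSE
"dizziness","physical",FALSE,TRUE,FALSE
"weight_loss","physical",FALSE,TRUE,FALSE
"difficulty_sleeping","physical",FALSE,FALSE,TRUE
"difficulty_concentrating","physical",FALSE,FALSE,TRUE
"cough","physical",FALSE,FALSE,FALSE
"skin_changes","physical",FALSE,FALSE,FALSE
"numbness_tingling","physical",FALSE,FALSE,FALSE
"urination_problems","physical",FALSE,FALSE,FALSE
"shortness_of_breath","physical",FALSE,FALSE,FALSE
"diarrhea","physical",FALSE,FALSE,FALSE
"sweats","physical",FALSE,FALSE,FALSE
"mouth_sores","physical",FALSE,FALSE,FALSE
"sexual_interest_problems","physical",FALSE,FALSE,FALSE
"itching","physical",FALSE,FALSE,FALSE
"difficulty_swallowing","physical",FALSE,FALSE,FALSE
"hair_loss","physical",FALSE,FALSE,FALSE
"swelling_arms_legs","physical",FALSE,FALSE,FALSE
"not_look_like_myself","physical",FALSE,FALSE,FALSE
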