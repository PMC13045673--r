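name,type,lower,upper,levels,description
patient_id,character,,,,Opaque unique patient identifier (required; never missing)
age,numeric,0,120,,Age in years at index date
sex,category,,,male|female,Sex
bmi,numeric,10,80,,Body mass index in kg/m2
smoking,category,,,current|ex|never,Smoking status
disease_duration,numeric,0,100,,CRS disease duration in years
n_ess,integer,0,,,Number of endoscopic sinus surgeries ever (band '>3' stored as 4)
n_scs_past_year,integer,0,,,Number of systemic corticosteroid courses in the past year (band '>3' stored as 4)
asthma,logical,,,,Physician- or self-reported asthma diagnosis
allergy,logical,,,,Allergy diagnosis
nerd,logical,,,,NSAID-exacerbated respiratory disease
snot22,integer,0,110,,Sino-Nasal Outcome Test-22 total score
lund_mackay,integer,0,24,,Lund-Mackay CT score
vas_tss,numeric,0,100,,VAS total sinus symptoms in mm
vas_nb,numeric,0,100,,VAS nasal blockage in mm
vas_los,numeric,0,100,,VAS loss of smell in mm
nps,integer,0,8,,Total nasal polyp score (0-4 per side)
bec,numeric,0,,,Blood eosinophil count in cells/uL
ige,numeric,0,,,Serum total IgE in IU/mL
biologic_initiated,logical,,,,Started a biologic for CRSwNP at the index date
incs,logical,,,,On intranasal corticosteroids
ics,logical,,,,On inhaled corticosteroids
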