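code,label
hypertension,Hypertension
dyslipidemia,Dyslipidemia
diabetes,Diabetes
cancer,Cancer
chronic_lung,Chronic lung disease
liver,Liver disease
heart,Heart disease
stroke,Stroke
kidney,Kidney disease
digestive,Digestive disease
emp,Emotional and mental problems
mrd,Memory-related disease
arthritis,Arthritis
asthma,Asthma
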