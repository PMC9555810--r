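covariate,level,n,pct
gender,Female,196,56.32
gender,Male,152,43.68
age_band,65-74,221,63.51
age_band,75-84,113,32.47
age_band,85 and above,14,4.02
education,Illiterate or barely literate,78,22.41
education,Primary school,97,27.87
education,Junior high school,92,26.44
education,Senior high school or technical secondary school,44,12.64
education,Junior college diploma or higher,37,10.63
residence_city,Urban (Yangzhou),87,25
residence_city,Urban (Nantong),88,25.29
residence_city,Rural (Yangzhou),86,24.71
residence_city,Rural (Nantong),87,25
living_condition,Living alone,155,44.54
living_condition,With spouse,193,55.46
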