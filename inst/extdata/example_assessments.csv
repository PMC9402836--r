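patient_id,nyha_class,dyspnoea_status,systolic_bp,diastolic_bp,hypotension_symptoms,rhythm,heart_rate,rhythm_new_onset,rhythm_symptomatic,weight_status,oedema_present,angina_status,uptitration_incomplete,poor_compliance_suspected,poor_social_support,depression_signs,hf_admissions_last_6mo,hf_admissions_last_12mo,ntprobnp_current,ntprobnp_previous,potassium,sodium,creatinine_current,creatinine_previous,gfr,haemoglobin,anaemia_chronicity
S00001,2,none_or_improved,111.72679700888693,76.6621388331987,FALSE,sinus,70.62164846807718,FALSE,FALSE,stable,FALSE,none_or_stable_ccs_le2,FALSE,FALSE,FALSE,FALSE,0,0,251.31024427711964,NA,4.000126780848951,141.3756469488144,249.89918490755372,NA,NA,7.903993961820379,NA
S00002,2,none_or_improved,128.11631873250008,61.155355661176145,FALSE,sinus,67.91088017169386,FALSE,FALSE,stable,FALSE,none_or_stable_ccs_le2,FALSE,FALSE,FALSE,FALSE,0,0,1099.6047387598082,NA,NA,137.18424776010215,74.70693232258782,78.93945822876013,57.78604979510419,8.96941519677639,NA
S00003,4,none_or_improved,117.37236025743186,67.59432628052309,FALSE,atrial_fibrillation,92.07057109102607,FALSE,FALSE,stable,FALSE,none_or_stable_ccs_le2,FALSE,FALSE,FALSE,FALSE,0,1,1075.236300029792,NA,3.9819988653063776,142.356506947428,91.8362730438821,97.73903409103029,NA,9.16476449407637,NA
S00004,2,none_or_improved,178.15002966672182,87.6540543558076,FALSE,sinus,66.8745193304494,FALSE,FALSE,stable,FALSE,none_or_stable_ccs_le2,FALSE,FALSE,FALSE,FALSE,0,0,293.75057503581047,NA,5.6073177754879,140.13290086761117,70.94461670145392,76.44154195207807,79.64958543190733,7.195431429799646,NA
S00005,2,none_or_improved,84.49066732730716,45.159172335639596,TRUE,sinus,65.1352713117376,FALSE,FALSE,stable,TRUE,none_or_stable_ccs_le2,FALSE,FALSE,FALSE,TRUE,0,0,NA,293.1673793245747,4.884120417525992,136.17996211908758,NA,96.57164258196428,62.47757563716732,7.772809314262122,NA
S00006,3,worse_on_exercise,136.24049292877316,77.46193664614111,FALSE,atrial_fibrillation,134.3569134606514,FALSE,FALSE,stable,FALSE,none_or_stable_ccs_le2,FALSE,FALSE,FALSE,FALSE,0,0,1412.854230813682,1506.9593817322718,3.6409889752278106,138.6628889851272,79.181603344623,76.90008447149191,45.52450771210715,6.818826429359614,NA
S00007,1,none_or_improved,133.97101221606135,68.80209613125771,FALSE,sinus,56.187905804254115,FALSE,FALSE,stable,TRUE,none_or_stable_ccs_le2,TRUE,FALSE,FALSE,FALSE,0,0,892.5420061917976,811.7759061239396,3.660763170034625,139.26252744533122,61.103860372677445,67.5787099265608,60.700395576423034,8.159882887545972,NA
S00008,1,worse_on_exercise,125.85363091900945,69.31666332529858,FALSE,sinus,63.68244331330061,FALSE,FALSE,increased_gt2kg_1week,TRUE,none_or_stable_ccs_le2,FALSE,FALSE,FALSE,FALSE,0,0,620.855422411114,642.7527413854739,4.426062326179817,141.4138888362795,103.76052850857377,108.74123989434653,77.86826523486525,8.849798680143431,NA
S00009,1,none_or_improved,119.26335478201509,59.113246873021126,FALSE,sinus,65.19408022984862,FALSE,FALSE,stable,FALSE,none_or_stable_ccs_le2,FALSE,FALSE,FALSE,FALSE,2,3,115.79303927719593,107.05872688759108,4.76601417195052,NA,86.23433764092624,NA,26.313810108229518,9.785575416730717,NA
S00010,2,none_or_improved,78.27765480568632,46.09464117139578,TRUE,sinus,92.00332637992688,FALSE,FALSE,stable,TRUE,none_or_stable_ccs_le2,FALSE,FALSE,FALSE,FALSE,1,1,NA,273.32694286576714,4.813425397058018,NA,74.23580599948764,78.4854250958758,74.55418787430972,NA,NA
S00011,3,none_or_improved,139.8335543461144,75.77814418822527,FALSE,atrial_fibrillation,85.24735804647207,FALSE,FALSE,stable,TRUE,none_or_stable_ccs_le2,FALSE,FALSE,FALSE,FALSE,0,0,188.93860816955566,NA,5.1210312938317655,136.69691894762218,95.51762606948614,NA,46.57802877598442,7.493631423963233,NA
S00012,1,worse_on_exercise,110.229721525684,72.67270682146773,FALSE,sinus,67.62099701911211,FALSE,FALSE,stable,FALSE,none_or_stable_ccs_le2,FALSE,FALSE,FALSE,FALSE,0,0,172.3658073693514,NA,NA,136.25326612778008,NA,96.73838142305613,42.36659999238327,NA,NA
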