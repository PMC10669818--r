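canonical_name,clinician_name,definition,category,data_type,canonical_unit,severity_scale,parent_level,context_tag,aliases
EF,LVEF,Left ventricular ejection fraction,left ventricle,continuous,%,,VentriclesMeasurements,left_ventricle,EF|LVEF|Ejection Fraction|Ejection Fraction (EF)
LVIDd,LVIDd,Left ventricular internal diameter in diastole,left ventricle,continuous,cm,,VentriclesMeasurements,left_ventricle,LVIDd
LVIDs,LVIDs,Left ventricular internal diameter in systole,left ventricle,continuous,cm,,VentriclesMeasurements,left_ventricle,LVIDs
LV Systolic Function,LVSF,Left ventricular systolic function grade,left ventricle,discrete,,lv_function,VentriclesFunction,left_ventricle,LV Systolic Function|LV systolic function|LVSF|LV function|systolic function@left_ventricle
IVS,IVSd,Interventricular septum thickness in diastole,left ventricle,continuous,cm,,VentriclesMeasurements,left_ventricle,IVS|IVSd
PWd,PWd,Posterior wall thickness in diastole,left ventricle,continuous,cm,,VentriclesMeasurements,left_ventricle,PWd
LVOT Diam,LVOTd,Left ventricular outflow tract diameter,left ventricle,continuous,cm,,VentriclesMeasurements,lvot,LVOT Diam|LVOT diameter|LVOTd|LVOT
LVOT VTI,LVOTvti,Left ventricular outflow tract velocity-time integral,left ventricle,continuous,cm,,VentriclesMeasurements,lvot,LVOT VTI|LVOTvti|VTI@lvot
LVOT Vmax,LVOTpv,Left ventricular outflow tract peak velocity,left ventricle,continuous,m/s,,VentriclesMeasurements,lvot,LVOT Vmax|Vmax@lvot|V max@lvot|Peak V@lvot
RV S',RV_TDI_S,Right ventricle tissue Doppler S wave velocity,right ventricle,continuous,cm/s,,VentriclesMeasurements,right_ventricle,RV S'|RV S' velocity
RVD1,RVD1,Right ventricle diameter at basal level,right ventricle,continuous,cm,,VentriclesMeasurements,right_ventricle,RVD1
RV TAPSE,TAPSE,Tricuspid annular plane systolic excursion,right ventricle,continuous,cm,,VentriclesMeasurements,right_ventricle,RV TAPSE|TAPSE
LA Area,LA_area,Left atrial area,left atrium,continuous,cm^2,,AtriaMeasurements,left_atrium,LA Area|LA area
LA Volume,LA_vol,Left atrial volume,left atrium,continuous,mL,,AtriaMeasurements,left_atrium,LA Volume|LA Vol|LA volume
RA Area,RA_area,Right atrial area,right atrium,continuous,cm^2,,AtriaMeasurements,right_atrium,RA Area|RA area
AV Stenosis,AS_sev,Aortic stenosis severity,aortic valve,discrete,,stenosis,ValvesFunction,aortic_valve,AV Stenosis|aortic stenosis|AS|AV stenosis|stenosis@aortic_valve|obstruction@aortic_valve
AR level,AR_sev,Aortic regurgitation severity,aortic valve,discrete,,regurgitation,ValvesFunction,aortic_valve,AR level|aortic regurgitation|AR|AV regurgitation|regurgitation@aortic_valve
AV Vmax,AVpv,Aortic valve peak velocity,aortic valve,continuous,m/s,,ValvesHaemodynamics,aortic_valve,AV Vmax|Ao Vmax|Vmax@aortic_valve|V max@aortic_valve|Peak V@aortic_valve
AV max PG,AVpg,Aortic valve peak pressure gradient,aortic valve,continuous,mmHg,,ValvesHaemodynamics,aortic_valve,AV max PG|AV peak PG|PPD@aortic_valve|max PG@aortic_valve|peak PG@aortic_valve
AV MPG,AVmg,Aortic valve mean pressure gradient,aortic valve,continuous,mmHg,,ValvesHaemodynamics,aortic_valve,AV MPG|AV mean PG|AV mean gradient|MPD@aortic_valve|MPG@aortic_valve|mean PG@aortic_valve
AR PHT,AVpht,Aortic regurgitation pressure half-time,aortic valve,continuous,ms,,ValvesHaemodynamics,aortic_valve,AR PHT|AV PHT|PHT@aortic_valve
AV VTI,AVvti,Aortic valve velocity-time integral,aortic valve,continuous,cm,,ValvesHaemodynamics,aortic_valve,AV VTI|Ao VTI|VTI@aortic_valve
MV Stenosis,MS_sev,Mitral stenosis severity,mitral valve,discrete,,stenosis,ValvesFunction,mitral_valve,MV Stenosis|mitral stenosis|MS|MV stenosis|stenosis@mitral_valve
MV Regurgitation Level,MR_sev,Mitral regurgitation severity,mitral valve,discrete,,regurgitation,ValvesFunction,mitral_valve,MV Regurgitation Level|mitral regurgitation|MR|MV regurgitation|regurgitation@mitral_valve
Lateral MAPSE,MAPSE,Lateral mitral annular plane systolic excursion,mitral valve,continuous,cm,,ValvesHaemodynamics,mitral_valve,Lateral MAPSE|MAPSE
Peak E Velocity,MV_E_vel,Mitral valve E wave velocity,mitral valve,continuous,m/s,,ValvesHaemodynamics,mitral_valve,Peak E Velocity|Peak E velocity|Peak E
Peak A Velocity,MV_A_vel,Mitral valve A wave velocity,mitral valve,continuous,m/s,,ValvesHaemodynamics,mitral_valve,Peak A Velocity|Peak A velocity|Peak A
DcT,MV_decT,Mitral valve deceleration time,mitral valve,continuous,ms,,ValvesHaemodynamics,mitral_valve,DcT|Dec T|deceleration time
E/A ratio,MV_Earatio,Mitral valve E/A ratio,mitral valve,continuous,dimensionless,,ValvesHaemodynamics,mitral_valve,E/A ratio|E/A|E:A ratio
Average E/E',MV_EE_avg,Mitral valve average E/E' ratio,mitral valve,continuous,dimensionless,,ValvesHaemodynamics,mitral_valve,Average E/E'|E/E' average|E/E'
Lateral S' Velocity,TDI_lat_S,Tissue Doppler lateral S wave velocity,mitral valve,continuous,cm/s,,ValvesHaemodynamics,mitral_valve,Lateral S' Velocity|Lateral S' velocity|Lateral S'
Lateral E' Velocity,TDI_lat_E,Tissue Doppler lateral E wave velocity,mitral valve,continuous,cm/s,,ValvesHaemodynamics,mitral_valve,Lateral E' Velocity|Lateral E' velocity|Lateral E'
Septal S' Velocity,TDI_sep_S,Tissue Doppler septal S wave velocity,mitral valve,continuous,cm/s,,ValvesHaemodynamics,mitral_valve,Septal S' Velocity|Septal S' velocity|Septal S'
Septal E' Velocity,TDI_sep_E,Tissue Doppler septal E wave velocity,mitral valve,continuous,cm/s,,ValvesHaemodynamics,mitral_valve,Septal E' Velocity|Septal E' velocity|Septal E'
TV Stenosis,TS_sev,Tricuspid stenosis severity,tricuspid valve,discrete,,stenosis,ValvesFunction,tricuspid_valve,TV Stenosis|tricuspid stenosis|TS|TV stenosis|stenosis@tricuspid_valve
TR level,TR_sev,Tricuspid regurgitation severity,tricuspid valve,discrete,,regurgitation,ValvesFunction,tricuspid_valve,TR level|tricuspid regurgitation|TR|TV regurgitation|regurgitation@tricuspid_valve
TR Vmax,TR_pv,Tricuspid regurgitation peak velocity,tricuspid valve,continuous,m/s,,ValvesHaemodynamics,tricuspid_valve,TR Vmax|Vmax@tricuspid_valve
TR max PG,TR_pg,Tricuspid regurgitation peak pressure gradient,tricuspid valve,continuous,mmHg,,ValvesHaemodynamics,tricuspid_valve,TR max PG|TR PG|max PG@tricuspid_valve
PV Stenosis,PS_sev,Pulmonary stenosis severity,pulmonary valve,discrete,,stenosis,ValvesFunction,pulmonary_valve,PV Stenosis|pulmonary stenosis|PS|PV stenosis|stenosis@pulmonary_valve
PV Vmax,PV_Vmax,Pulmonary valve maximum velocity,pulmonary valve,continuous,m/s,,ValvesHaemodynamics,pulmonary_valve,PV Vmax|Vmax@pulmonary_valve
Sinuses of Valsalva,AO_SOV,Sinus of Valsalva diameter,aorta,continuous,cm,,VesselsMeasurements,aorta,Sinuses of Valsalva|Sinus of Valsalva|SOV
Sinotubular Junction,AO_STJ,Aortic sinotubular junction diameter,aorta,continuous,cm,,VesselsMeasurements,aorta,Sinotubular Junction|STJ
Ascending Aorta,AO_ASC,Ascending aorta diameter,aorta,continuous,cm,,VesselsMeasurements,aorta,Ascending Aorta|Asc Ao|Asc Aorta
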