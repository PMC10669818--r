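report_id,outcome,value,unit,ordinal_label,negated,prosthetic
c01,AV Vmax,4.2,m/s,,FALSE,FALSE
c01,AV MPG,46,mmHg,,FALSE,FALSE
c01,AV VTI,103,cm,,FALSE,FALSE
c02,AV Vmax,4,m/s,,FALSE,FALSE
c02,AV MPG,42,mmHg,,FALSE,FALSE
c02,AV VTI,87.9,cm,,FALSE,FALSE
c03,AV VTI,36,cm,,FALSE,FALSE
c04,AV VTI,36,cm,,FALSE,FALSE
c05,AV Vmax,2.8,m/s,,FALSE,FALSE
c05,AV max PG,32,mmHg,,FALSE,FALSE
c05,AV MPG,19,mmHg,,FALSE,FALSE
c05,AV VTI,62.3,cm,,FALSE,FALSE
c06,AV Vmax,4,m/s,,FALSE,FALSE
c06,AV MPG,42,mmHg,,FALSE,FALSE
c06,AV VTI,87.9,cm,,FALSE,FALSE
c06,LVOT Diam,2.7,cm,,FALSE,FALSE
c06,LVOT Vmax,0.7,m/s,,FALSE,FALSE
c06,LVOT VTI,16.2,cm,,FALSE,FALSE
c07,AV Vmax,4.8,m/s,,FALSE,FALSE
c07,AV max PG,91,mmHg,,FALSE,FALSE
c07,AV MPG,57,mmHg,,FALSE,FALSE
c07,AV VTI,107,cm,,FALSE,FALSE
c08,AV MPG,54,mmHg,,FALSE,FALSE
c08,AV VTI,78,cm,,FALSE,FALSE
c09,AV VTI,61.3,cm,,FALSE,FALSE
c10,AV VTI,106,cm,,FALSE,FALSE
c11,AV VTI,78,cm,,FALSE,FALSE
d01,AR level,0,,none,TRUE,TRUE
d02,AR level,2,,mild,FALSE,TRUE
d03,AR level,0,,none,TRUE,TRUE
d04,AV Stenosis,0,,none,TRUE,FALSE
d04,AR level,1,,trivial,FALSE,FALSE
d04,AV Vmax,1.6,m/s,,FALSE,FALSE
d05,AV Stenosis,0,,none,TRUE,TRUE
d05,AR level,2,,mild,FALSE,TRUE
d06,AV Stenosis,0,,none,TRUE,TRUE
d06,AR level,0,,none,TRUE,TRUE
d07,AR level,2,,mild,FALSE,TRUE
d08,AR level,2,,mild,FALSE,FALSE
d09,AR level,2,,mild,FALSE,FALSE
d09,AV Vmax,1.5,m/s,,FALSE,FALSE
d10,AV Stenosis,3,,moderate,FALSE,FALSE
d10,AR level,1,,trivial,FALSE,FALSE
d11,AR level,4,,severe,FALSE,FALSE
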