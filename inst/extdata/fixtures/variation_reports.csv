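report_id,text
c01,"AV Vmax 4.2 m/s MPD 46 mmHg VTI 103 cm"
c02,"AV Vmax 4 m/s MPD 42 mmHg VTI 87.9 cm"
c03,"Ao VTI 36 cm; AVA (VTI) 1.8 cm^2"
c04,"Ao VTI 36 cm;"
c05,"Aortic Valve: Appears Trileaflet. Thickening of LCC/NCC with reduced mobility of these cusps. V max 2.8 m/s, PPD: 32 mmHg, MPD: 19 mmHg, VTI: 62.3 cm."
c06,"AV Vmax 4 m/s MPD 42 mmHg VTI 87.9 cm LVOT 2.7 cm Peak V = 0.7 m/s, MPD 1.2 mmHg, VTI 16.2 cm"
c07,"AV Vmax: 4.8 m/s, PPD: 91 mmHg, MPD: 57 mmHg, VTI: 107 cm"
c08,"AV mean PG: 54 mmHg. AV VTI: 78 cm. AVA VTI: 0.88 cm^2. AVAi VTI: 0.45 cm/m^2"
c09,"AV VTI 61.3 cm"
c10,"Ao VTI 106 cm;"
c11,"AV VTI: 78 cm."
d01,"Aortic Valve (biological AVR): AVR in situ, well seated. ... No significant regurgitation. ... Aorta:"
d02,"Aortic Valve (unclear imaging of AVR): ... AVR seen in situ with a mild paraprosthetic regurgitation. ... Aorta:"
d03,"Aortic Valve: ... with valve type/size in situ No aortic regurgitation Right Ventricle:"
d04,"Aortic Valve: ... No aortic stenosis. Trivial aortic regurgitation. AV Vmax: 1.6 m/s. Aorta:"
d05,"Aortic Valve (TAVI): ... No aortic stenosis/obstruction indicated. Trivial–mild paravalvular aortic regurgitation. ... Aorta:"
d06,"Aortic Valve: AVR in situ. ... No significant obstruction/stenosis indicated. No obvious aortic regurgitation. ... Aorta:"
d07,"Aortic Valve: ... Mild eccentric paravalvular aortic regurgitation seen. Aorta:"
d08,"Aortic Valve: ... Mild transvalvular aortic regurgitation. ..."
d09,"Aorta: Aortic Valve: ... Aortic regurgitation present ... Overall assessment is of mild aortic regurgitation. AV Vmax: 1.5 m/s. Aorta:"
d10,"Aortic Valve: ... ? BAV. Moderate AS. Trivial AR. ... Aorta:"
d11,"Aortic Valve: ... Overall assessment is of severe aortic regurgitation. ... Aorta:"
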