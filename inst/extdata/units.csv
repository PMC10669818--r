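from,to,factor
m,cm,100
cm,m,0.01
mm,cm,0.1
cm,mm,10
m,mm,1000
mm,m,0.001
s,ms,1000
ms,s,0.001
m/s,cm/s,100
cm/s,m/s,0.01
L,mL,1000
mL,L,0.001
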