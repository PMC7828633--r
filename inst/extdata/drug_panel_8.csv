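Drug,Mwt,logP,ion_class,pk_a,pk_b,Kpuu_ECF,Kpuu_LV,Kpuu_CM,BCRP,p_gp,OAT3,MRP4,CL_P,CL_T_ef,CL_T_in
caffeine,194.2,-0.07,Neutral,NA,-0.92,0.96,0.96,0.96,X,-,-,-,48.9,4.28,2.38
cephalexin,347.4,0.65,Zwitterion,3.26,7.23,0.015,0.015,0.015,-,-,X,-,37.4,2736,<0.01
codeine,299.4,1.39,Base,13.8,9.19,1,1,1,-,-,-,-,40.1,0.71,0.89
gabapentin,171.2,1.25,Zwitterion,4.63,9.91,0.13,0.13,0.13,-,-,-,-,51.9,347,<0.01
genistein,270.2,3.04,Acid,6.55,-5.3,0.04,0.04,0.04,X,X,-,-,42.3,1557,245
levetiracetam,170.2,-0.64,Neutral,16.1,-1.6,0.31,0.31,0.31,-,X,-,X,52.0,3.73,0.69
morphine,285.3,0.87,Base,10.3,9.12,0.23,0.23,0.23,-,X,-,-,41.0,30.2,0.34
thiopental,242.3,2.85,Acid,7.2,-3,0.9,0.9,0.9,-,-,-,-,44.2,569,508
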