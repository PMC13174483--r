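disease,parameter,kind,mid,lo,hi,sd,unit,note
COVID19,IL6,log_range,232,1,32768,NA,pg/mL,"232 (1-32768) pg/ml; five-decade range sampled log-uniformly"
COVID19,TNFA,log_range,25,1,1000,NA,pg/mL,"25 (1-1000) pg/ml; three-decade range sampled log-uniformly"
COVID19,IL1B,range,0.8,0,32,NA,pg/mL,"0.8 (0-32) pg/ml; zero lower bound, sampled uniformly"
COVID19,VII,range,1,0.55,1.70,NA,pct_ref,"0.5 mg/L (55%-170%); percent-of-normal range resolved against the mean-plasma reference"
COVID19,VIIa,range,1,0.6,1.3,NA,pct_ref,"0.2 mg/L (60%-130%); percent-of-normal range resolved against the mean-plasma reference (the printed mass value is ~40x the physiological free VIIa)"
COVID19,IX,mean_sd,7.5,NA,NA,3.795,mg/L,"7.5 mg/L +/-50.6%"
COVID19,X,mean_sd,11.1,NA,NA,3.0969,mg/L,"11.1 mg/L +/-27.9%"
COVID19,II,mean_sd,107.5,NA,NA,33.54,mg/L,"107.5 mg/L +/-31.2%"
COVID19,VIII,mean_sd,0.262,NA,NA,0.2696,mg/L,"0.262 mg/L +/-102.9%"
COVID19,V,mean_sd,11.7,NA,NA,5.2533,mg/L,"11.7 mg/L +/-44.9%"
COVID19,TFPI,point,1,NA,NA,NA,pct_ref,"70 ng/mL, the same value as the Normal column: read as the normal reference level"
COVID19,ATIII,mean_sd,0.8933,NA,NA,0.1349,pct_ref,"printed 0.134 (vs normal 0.15) +/-15.1%: 89% of the normal reference; resolved against the mean-plasma antithrombin"
T2DM,IL6,range,4.1,2.3,5.6,NA,pg/mL,"4.1 (2.3-5.6) pg/mL"
T2DM,TNFA,range,3.8,3.0,5.0,NA,pg/mL,"3.8 (3.0-5.0) pg/mL"
T2DM,IL1B,range,0.2,0.2,0.3,NA,pg/mL,"0.2 (0.2-0.3) pg/mL"
T2DM,VII,range,1,0.6,1.3,NA,pct_ref,"0.5 mg/L (60%-130%); percent of normal"
T2DM,VIIa,mean_sd,1.0825,NA,NA,0.2892,pct_ref,"0.2165 mg/L +/-26.72% against the 0.2 mg/L reference row: 108% +/- 29% of normal; percentage read as one SD"
T2DM,IX,range,1,0.6,1.3,NA,pct_ref,"5 mg/L (60%-130%); percent of normal"
T2DM,X,range,1,0.6,1.3,NA,pct_ref,"10 mg/L (60%-130%); percent of normal"
T2DM,II,range,1,0.6,1.3,NA,pct_ref,"100 mg/L (60%-130%); percent of normal"
T2DM,VIII,range,1,0.5,1.5,NA,pct_ref,"0.1 mg/L (50%-150%); percent of normal"
T2DM,V,range,1,0.6,1.3,NA,pct_ref,"10 mg/L (60%-130%); percent of normal"
T2DM,TFPI,mean_sd,197.56,NA,NA,94.88,pg/mL,"197.56 +/- 94.88 pg/ml as printed (orders of magnitude below the 70 ng/mL reference; kept as printed)"
T2DM,ATIII,point,1,NA,NA,NA,pct_ref,"printed 0.15, identical to the Normal column: the normal reference level"
SCD,IL6,mean_sd,60,NA,NA,7,pg/mL,"60 +/- 7 pg/ml"
SCD,TNFA,mean_sd,122.3,NA,NA,16.3,pg/mL,"122.3 +/- 16.3 pg/ml"
SCD,IL1B,range,3.5,0,27.26,NA,pg/mL,"3.5 (0.0-27.26) pg/mL; zero lower bound, sampled uniformly"
SCD,VII,mean_sd,0.62,NA,NA,0.0465,pct_ref,"0.31 mg/L +/-7.5% against the 0.5 mg/L reference: 62% of normal; percentage read as one SD"
SCD,VIIa,range,1,0.6,1.3,NA,pct_ref,"0.2 mg/L (60%-130%); percent of normal"
SCD,IX,range,1,0.6,1.3,NA,pct_ref,"5 mg/L (60%-130%); percent of normal"
SCD,X,mean_sd,0.66,NA,NA,0.066,pct_ref,"6.6 mg/L +/-10% against the 10 mg/L reference: 66% of normal (chronically depleted factor X pool)"
SCD,II,mean_sd,0.75,NA,NA,0.075,pct_ref,"75 mg/L +/-10% against the 100 mg/L reference: 75% of normal"
SCD,VIII,range,1,0.5,1.5,NA,pct_ref,"0.1 mg/L (50%-150%); percent of normal"
SCD,V,mean_sd,0.725,NA,NA,0.1269,pct_ref,"7.25 mg/L +/-17.5% against the 10 mg/L reference: 72.5% of normal; percentage read as one SD"
SCD,TFPI,point,1,NA,NA,NA,pct_ref,"70 ng/mL, the normal reference level"
SCD,ATIII,point,1,NA,NA,NA,pct_ref,"printed 0.15, the normal reference level"
HemophiliaA,IL6,point,NA,NA,NA,NA,baseline,"no cytokine range reported; sampled at the configured normal baseline"
HemophiliaA,IL1B,point,NA,NA,NA,NA,baseline,"no cytokine range reported; sampled at the configured normal baseline"
HemophiliaA,TNFA,point,NA,NA,NA,NA,baseline,"no cytokine range reported; sampled at the configured normal baseline"
HemophiliaA,VII,range,1,0.6,1.3,NA,pct_ref,"0.5 mg/L (60%-130%); percent of normal"
HemophiliaA,VIIa,range,1,0.6,1.3,NA,pct_ref,"0.2 mg/L (60%-130%); percent of normal"
HemophiliaA,IX,range,1,0.6,1.3,NA,pct_ref,"5 mg/L (60%-130%); percent of normal"
HemophiliaA,X,range,1,0.6,1.3,NA,pct_ref,"10 mg/L (60%-130%); percent of normal"
HemophiliaA,II,range,1,0.6,1.3,NA,pct_ref,"100 mg/L (60%-130%); percent of normal"
HemophiliaA,VIII,below_frac_ref,0.01,NA,NA,NA,pct_ref,"< 1% of normal factor VIII activity; sampled uniformly on (0, 1%] of the mean-plasma reference"
HemophiliaA,V,range,1,0.6,1.3,NA,pct_ref,"10 mg/L (60%-130%); percent of normal"
HemophiliaA,TFPI,point,1,NA,NA,NA,pct_ref,"70 ng/mL, the normal reference level"
HemophiliaA,ATIII,point,1,NA,NA,NA,pct_ref,"printed 0.15, the normal reference level"
Normal,IL6,point,NA,NA,NA,NA,baseline,"no cytokine range reported; sampled at the configured normal baseline"
Normal,IL1B,point,NA,NA,NA,NA,baseline,"no cytokine range reported; sampled at the configured normal baseline"
Normal,TNFA,point,NA,NA,NA,NA,baseline,"no cytokine range reported; sampled at the configured normal baseline"
Normal,VII,range,1,0.6,1.3,NA,pct_ref,"0.5 mg/L (60%-130%); percent of normal"
Normal,VIIa,range,1,0.6,1.3,NA,pct_ref,"0.2 mg/L (60%-130%); percent of normal"
Normal,IX,range,1,0.6,1.3,NA,pct_ref,"5 mg/L (60%-130%); percent of normal"
Normal,X,range,1,0.6,1.3,NA,pct_ref,"10 mg/L (60%-130%); percent of normal"
Normal,II,range,1,0.6,1.3,NA,pct_ref,"100 mg/L (60%-130%); percent of normal"
Normal,VIII,range,1,0.5,1.5,NA,pct_ref,"0.1 mg/L (50%-150%); percent of normal"
Normal,V,range,1,0.6,1.3,NA,pct_ref,"10 mg/L (60%-130%); percent of normal"
Normal,TFPI,point,1,NA,NA,NA,pct_ref,"70 ng/mL, the normal reference level"
Normal,ATIII,point,1,NA,NA,NA,pct_ref,"printed 0.15, the normal reference level"
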