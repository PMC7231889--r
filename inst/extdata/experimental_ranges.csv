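biomarker,protocol,lb,ub,units
AP_CL,nonpaced,1310.2,12798.5,ms
APD90,nonpaced,485.1,1393.8,ms
APD50,nonpaced,310.6,1059.6,ms
APD30,nonpaced,240.6,910.3,ms
AP_Tri90_30,nonpaced,132,741,ms
CaTr_CL,nonpaced,1310.1,12805.3,ms
CTD90,nonpaced,754.9,2897.5,ms
CTD50,nonpaced,463.8,1376.4,ms
CTD30,nonpaced,353.4,1065.2,ms
CaTr_tRise0peak,nonpaced,112.9,622.3,ms
CaTr_Tri90_30,nonpaced,104.8,1872.5,ms
AP_peak,nonpaced,17,57.7,mV
APD90,paced,514.3,1397.6,ms
APD50,paced,332.5,932.4,ms
APD30,paced,261.6,786.3,ms
AP_Tri90_30,paced,251.9,839.9,ms
CTD90,paced,863.2,1803,ms
CTD50,paced,510.5,1167.8,ms
CTD30,paced,382.7,983.7,ms
CaTr_tRise0peak,paced,96.5,473.8,ms
CaTr_Tri90_30,paced,438.6,1140.6,ms
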