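dataset,method,TP,FP,FN,precision_printed,recall_printed,f1_printed
HAR,novelty,166,16,13,0.91,0.93,0.92
ECG1,novelty,18,1,0,0.95,1.00,0.97
ECG2,novelty,155,9,13,0.95,0.92,0.93
EMG,novelty,695,68,33,0.91,0.95,0.93
HAR,window,169,9,10,0.95,0.94,0.95
ECG1,window,13,5,5,0.72,0.72,0.72
ECG2,window,139,13,29,0.91,0.83,0.87
EMG,window,608,123,120,0.83,0.84,0.83
HAR,binary,125,58,54,0.68,0.70,0.69
ECG1,binary,16,2,2,0.89,0.89,0.89
ECG2,binary,122,58,46,0.68,0.73,0.70
EMG,binary,351,413,377,0.46,0.48,0.47
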