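task,features,model,tp,fn,fp,tn,sensitivity,specificity,precision,recall,f1,accuracy,balanced_accuracy
mwl,EEG,LgR,736,181,362,431,0.80,0.54,0.67,0.80,0.73,0.68,0.67
mwl,EEG,MLP,776,141,293,500,0.85,0.63,0.73,0.85,0.78,0.75,0.74
mwl,EEG,SVM,342,575,138,655,0.37,0.83,0.71,0.37,0.50,0.58,0.60
mwl,EEG,RF,864,53,157,636,0.94,0.80,0.85,0.94,0.89,0.88,0.87
mwl,MI,LgR,688,229,410,383,0.75,0.48,0.63,0.75,0.68,0.63,0.62
mwl,MI,MLP,715,202,230,563,0.78,0.71,0.76,0.78,0.77,0.75,0.74
mwl,MI,SVM,576,341,146,647,0.63,0.81,0.80,0.63,0.70,0.72,0.72
mwl,MI,RF,783,134,175,618,0.85,0.78,0.82,0.85,0.84,0.82,0.82
event,EEG,LgR,17,224,14,483,0.07,0.97,0.55,0.07,0.13,0.68,0.52
event,EEG,MLP,83,158,62,435,0.34,0.88,0.57,0.34,0.43,0.70,0.61
event,EEG,SVM,186,55,164,333,0.77,0.67,0.53,0.77,0.63,0.70,0.72
event,EEG,RF,147,94,5,492,0.61,0.99,0.97,0.61,0.75,0.87,0.80
event,MI,LgR,75,166,55,442,0.31,0.89,0.58,0.31,0.40,0.70,0.60
event,MI,MLP,140,101,27,470,0.58,0.95,0.84,0.58,0.69,0.83,0.76
event,MI,SVM,207,34,128,369,0.86,0.74,0.62,0.86,0.72,0.78,0.80
event,MI,RF,209,32,12,485,0.87,0.98,0.95,0.87,0.90,0.94,0.92
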