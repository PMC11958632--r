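feature,chi_square,mutual_information,f_statistic,published_total,published_rank,consistent
age,4.501,0.001,3.452,7.954,11,TRUE
sex,1.465,2.802,5.525,9.792,9,TRUE
cp,12.11,6.351,14.945,43.396,3,FALSE
trestbps,2.866,4.232,1.383,8.481,10,TRUE
chol,4.627,6.612,0.472,11.711,8,TRUE
fbs,0.039,1.315,0.051,1.405,13,TRUE
restecg,0.576,2.344,1.237,4.157,12,TRUE
thalach,36.403,7.365,13.949,57.717,1,TRUE
exang,7.522,8.872,15.198,31.592,5,TRUE
oldpeak,14.042,15.663,14.684,44.389,2,TRUE
slope,1.895,7.99,8.761,18.646,7,TRUE
ca,12.843,11.819,11.687,36.349,4,TRUE
thal,1.121,4.365,8.655,24.14,6,FALSE
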