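model,seed,interval,method,scheme,scoring,n_tr,q2_loo,q2_lco,mae_loo,n_ts,r2_pred_test,mae_test,aard_train,aard_test,r2_pred_ext,aard_ext
M01,2,5,1,MO,NMAE,408,0.884,0.854,2.586,127,0.907,3.863,5.541,11.843,-0.335,15.931
M02,4,5,2,MO,NMAE,435,0.873,0.849,2.658,100,0.899,3.966,6.11,7.517,0.464,12.176
M03,1,4,2,MO,NMAE,408,0.898,0.854,2.775,127,0.865,2.569,6.063,5.418,-0.196,15.833
M04,5,4,2,MO,NMAE,409,0.898,0.855,2.771,126,0.862,2.584,6.057,5.446,-0.19,15.818
M05,4,5,1,MO,NMAE,435,0.871,0.839,2.635,100,0.898,4.039,5.965,7.538,0.392,11.838
M06,3,5,1,MO,NMAE,443,0.881,0.849,2.671,92,0.871,4.073,6.052,7.65,0.516,11.021
M07,1,3,1,MO,NMAE,359,0.901,0.862,2.369,176,0.836,4.223,5.222,9.331,-7.225,27.7
M08,4,5,1,MO,R2,435,0.883,0.858,2.854,100,0.855,4.695,6.6,8.456,0.466,11.45
M09,4,3,1,MO,NMAE,360,0.906,0.854,2.322,175,0.83,4.389,5.202,9.872,0.688,8.527
M10,1,2,2,CO,R2,301,0.931,0.903,1.66,234,0.754,6.03,4.208,12.754,0.734,7.777
M11,4,5,2,MO,5-fold,435,0.865,0.841,3,100,0.876,4.282,6.875,7.78,0.568,10.047
M12,4,3,2,MO,R2,360,0.908,0.882,2.608,175,0.783,5.134,5.805,11.155,0.862,4.418
M13,4,5,1,MO,5-fold,435,0.871,0.845,2.706,100,0.857,4.626,6.204,8.442,0.544,11.093
M14,1,4,1,MO,10-fold,408,0.869,0.849,3.34,127,0.847,2.05,7.344,3.943,0.352,11.642
M15,5,4,1,MO,10-fold,409,0.869,0.85,3.336,126,0.844,2.052,7.339,3.929,0.353,11.638
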