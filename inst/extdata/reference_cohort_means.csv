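participant_id,group,metric,vp,mr
student-1,student,theta_beta,4.315,4.417
student-1,student,alpha_amp,8.024,8.540
student-1,student,hr,97,96
student-1,student,eda,3.733,6.479
student-2,student,theta_beta,2.734,1.788
student-2,student,alpha_amp,10.228,12.443
student-2,student,hr,92,92
student-2,student,eda,0.525,2.438
student-3,student,theta_beta,4.306,3.425
student-3,student,alpha_amp,5.794,5.529
student-3,student,hr,66,65
student-3,student,eda,0.268,0.382
student-4,student,theta_beta,2.611,3.284
student-4,student,alpha_amp,7.040,7.157
student-4,student,hr,96,90
student-4,student,eda,0.265,7.090
neurosurgeon-1,neurosurgeon,theta_beta,3.016,3.131
neurosurgeon-1,neurosurgeon,alpha_amp,7.033,7.146
neurosurgeon-1,neurosurgeon,hr,87,95
neurosurgeon-1,neurosurgeon,eda,0.215,3.475
neurosurgeon-2,neurosurgeon,theta_beta,1.438,1.598
neurosurgeon-2,neurosurgeon,alpha_amp,6.023,6.223
neurosurgeon-2,neurosurgeon,hr,88,82
neurosurgeon-2,neurosurgeon,eda,5.788,14.539
neurosurgeon-3,neurosurgeon,theta_beta,1.986,1.679
neurosurgeon-3,neurosurgeon,alpha_amp,6.396,8.072
neurosurgeon-3,neurosurgeon,hr,75,76
neurosurgeon-3,neurosurgeon,eda,1.019,3.076
neurosurgeon-4,neurosurgeon,theta_beta,3.935,5.420
neurosurgeon-4,neurosurgeon,alpha_amp,10.725,9.606
neurosurgeon-4,neurosurgeon,hr,73,79
neurosurgeon-4,neurosurgeon,eda,0.538,0.540
postgraduate-1,postgraduate,theta_beta,2.439,2.532
postgraduate-1,postgraduate,alpha_amp,7.831,7.801
postgraduate-1,postgraduate,hr,75,70
postgraduate-1,postgraduate,eda,0.371,0.307
postgraduate-2,postgraduate,theta_beta,2.580,3.331
postgraduate-2,postgraduate,alpha_amp,20.523,13.933
postgraduate-2,postgraduate,hr,90,84
postgraduate-2,postgraduate,eda,0.387,4.516
postgraduate-3,postgraduate,theta_beta,1.971,1.823
postgraduate-3,postgraduate,alpha_amp,7.163,6.926
postgraduate-3,postgraduate,hr,77,79
postgraduate-3,postgraduate,eda,1.459,2.671
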