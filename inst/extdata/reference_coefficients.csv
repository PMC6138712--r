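# Optimized material coefficients (c1, c3 in MPa; c4 dimensionless) for ten
# human cadaver Achilles tendon specimens at five fascicle twist angles;
# transcribed from the published subject-by-subject table of a cadaveric
# modelling study. "Average"/"SD" rows are reproduced as printed (note: the
# printed averages are not the column means of the per-subject values).
coefficient,subject,angle_0,angle_15,angle_30,angle_45,angle_60
c1,1,38.07,38.18,46.00,75.39,78.00
c1,2,22.74,23.24,34.16,29.34,89.54
c1,3,43.13,30.15,27.34,29.82,29.81
c1,4,49.92,46.37,55.02,46.39,46.33
c1,5,164.18,146.57,148.07,146.52,143.10
c1,6,46.52,42.62,39.07,41.84,21.76
c1,7,40.20,14.28,40.06,14.65,31.62
c1,8,35.73,12.79,14.54,11.27,6.92
c1,9,25.38,24.68,21.97,23.40,21.61
c1,10,98.95,142.59,142.78,140.35,143.10
c1,Average,70.03,53.70,56.90,53.73,59.31
c1,SD,54.19,52.74,39.72,52.11,52.84
c3,1,11.57,12.92,13.00,3.41,9.10
c3,2,13.23,21.95,5.97,6.03,9.75
c3,3,2.21,6.28,1.64,2.91,3.08
c3,4,14.05,11.71,9.20,11.86,12.20
c3,5,31.73,36.18,37.29,34.98,37.37
c3,6,15.29,3.34,5.76,3.79,14.37
c3,7,4.98,4.06,5.82,4.82,1.79
c3,8,6.22,3.09,2.92,3.33,4.25
c3,9,7.90,1.68,2.76,2.50,3.77
c3,10,27.06,35.88,35.62,33.70,35.49
c3,Average,16.40,13.80,12.00,11.55,13.56
c3,SD,15.17,14.06,11.04,13.23,13.67
c4,1,30.65,30.67,24.00,1.12,9.00
c4,2,42.03,33.82,64.28,69.02,5.92
c4,3,97.37,70.23,124.02,99.77,99.79
c4,4,42.19,53.45,56.27,53.53,53.68
c4,5,2.95,2.68,2.40,2.81,2.91
c4,6,26.80,62.70,50.43,60.17,39.57
c4,7,83.34,127.14,80.12,117.72,155.45
c4,8,73.12,100.00,99.83,100.00,100.00
c4,9,14.59,83.82,70.14,74.02,64.76
c4,10,26.15,3.55,3.53,4.11,3.65
c4,Average,41.04,59.71,57.50,64.57,58.41
c4,SD,36.20,41.81,36.78,40.37,52.57
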