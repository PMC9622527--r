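metric,segment,units,group,mean,sd,n
diameter,AA,mm/m2,HLHS,28.0,2.5,10
diameter,AA,mm/m2,AM,20.6,4.7,6
diameter,TA,mm/m2,HLHS,27.7,2.7,10
diameter,TA,mm/m2,AM,20.1,2.5,6
diameter,DA1,mm/m2,HLHS,18.7,1.9,10
diameter,DA1,mm/m2,AM,14.5,1.3,6
diameter,DA2,mm/m2,HLHS,15.6,1.6,10
diameter,DA2,mm/m2,AM,13.0,0.8,6
wall_thickness,AA-TA,mm/m2,HLHS,3.7,0.9,10
wall_thickness,AA-TA,mm/m2,AM,2.9,0.2,6
wall_thickness,DA1-DA2,mm/m2,HLHS,2.9,0.6,10
wall_thickness,DA1-DA2,mm/m2,AM,2.4,0.1,6
curvature,AA,m-1/m2,HLHS,13.7,5.3,10
curvature,AA,m-1/m2,AM,21.5,3.8,6
curvature,TA,m-1/m2,HLHS,45.0,13.3,10
curvature,TA,m-1/m2,AM,40.3,10.4,6
curvature,DA1,m-1/m2,HLHS,31.3,11.2,10
curvature,DA1,m-1/m2,AM,22.7,4.2,6
curvature,DA2,m-1/m2,HLHS,4.6,1.9,10
curvature,DA2,m-1/m2,AM,4.4,0.7,6
peak_dp_tot,AA,mmHg,HLHS,2.34,0.95,10
peak_dp_tot,AA,mmHg,AM,4.17,2.95,6
peak_dp_tot,DA1,mmHg,HLHS,4.64,2.01,10
peak_dp_tot,DA1,mmHg,AM,3.22,2.62,6
peak_dp_tot,DA2,mmHg,HLHS,10.00,4.69,10
peak_dp_tot,DA2,mmHg,AM,10.22,4.31,6
peak_dp_kin,AA,mmHg,HLHS,1.50,0.41,10
peak_dp_kin,AA,mmHg,AM,2.88,1.24,6
peak_dp_kin,DA1,mmHg,HLHS,2.77,1.25,10
peak_dp_kin,DA1,mmHg,AM,5.42,3.41,6
peak_dp_kin,DA2,mmHg,HLHS,8.64,2.89,10
peak_dp_kin,DA2,mmHg,AM,10.33,4.07,6
peak_dp_adv,AA,mmHg,HLHS,1.29,0.98,10
peak_dp_adv,AA,mmHg,AM,2.17,2.36,6
peak_dp_adv,DA1,mmHg,HLHS,3.46,2.08,10
peak_dp_adv,DA1,mmHg,AM,1.35,1.38,6
peak_dp_adv,DA2,mmHg,HLHS,4.73,6.72,10
peak_dp_adv,DA2,mmHg,AM,1.23,0.99,6
ve_peak,AA,mJ/s,HLHS,0.27,0.09,10
ve_peak,AA,mJ/s,AM,0.40,0.02,6
ve_peak,DA1,mJ/s,HLHS,0.38,0.21,10
ve_peak,DA1,mJ/s,AM,0.39,0.09,6
ve_peak,DA2,mJ/s,HLHS,1.21,0.50,10
ve_peak,DA2,mJ/s,AM,0.74,0.35,6
pwv,AA,m/s,HLHS,4.3,0.8,10
pwv,AA,m/s,AM,3.2,0.9,6
pwv,TA,m/s,HLHS,3.7,0.4,10
pwv,TA,m/s,AM,3.6,0.6,6
pwv,DA1,m/s,HLHS,3.8,0.6,10
pwv,DA1,m/s,AM,4.3,0.8,6
pwv,DA2,m/s,HLHS,4.4,0.8,10
pwv,DA2,m/s,AM,4.9,0.6,6
elastic_modulus,AA,kPa,HLHS,154.6,51.5,10
elastic_modulus,AA,kPa,AM,91.1,44.9,6
elastic_modulus,TA,kPa,HLHS,123.1,31.2,10
elastic_modulus,TA,kPa,AM,107.4,35.2,6
elastic_modulus,DA1,kPa,HLHS,101.7,28.2,10
elastic_modulus,DA1,kPa,AM,125.0,36.1,6
elastic_modulus,DA2,kPa,HLHS,116.5,53.8,10
elastic_modulus,DA2,kPa,AM,142.5,29.9,6
elastic_modulus,DA-pooled,kPa,HLHS,111.5,40.8,10
elastic_modulus,DA-pooled,kPa,AM,136.6,29.6,6
saw_delta,DA1,mmHg,HLHS,3.34,2.11,10
saw_delta,DA1,mmHg,AM,1.09,1.05,6
t_peak_dp_tot,AA,ms,HLHS,89.0,31.5,10
t_peak_dp_tot,AA,ms,AM,64.3,14.6,6
t_peak_dp_tot,DA1,ms,HLHS,136.8,43.3,10
t_peak_dp_tot,DA1,ms,AM,68.5,36.2,6
t_peak_dp_tot,DA2,ms,HLHS,116.6,56.5,10
t_peak_dp_tot,DA2,ms,AM,86.9,35.6,6
t_peak_dp_kin,AA,ms,HLHS,73.9,23.1,10
t_peak_dp_kin,AA,ms,AM,60.5,15.9,6
t_peak_dp_kin,DA1,ms,HLHS,69.3,32.0,10
t_peak_dp_kin,DA1,ms,AM,62.7,26.8,6
t_peak_dp_kin,DA2,ms,HLHS,89.0,39.2,10
t_peak_dp_kin,DA2,ms,AM,73.1,30.0,6
t_zero_dp_kin,AA,ms,HLHS,153.8,39.5,10
t_zero_dp_kin,AA,ms,AM,126.9,23.2,6
t_zero_dp_kin,DA1,ms,HLHS,172.4,41.7,10
t_zero_dp_kin,DA1,ms,AM,147.1,14.8,6
t_zero_dp_kin,DA2,ms,HLHS,175.5,42.3,10
t_zero_dp_kin,DA2,ms,AM,157.4,22.6,6
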