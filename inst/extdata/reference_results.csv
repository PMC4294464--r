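year,observed,verhulst,verhulst_err,regression,regression_err,combined,combined_err
2002,109381,109381,0,110334,0.871,109595,0.196
2003,104372,104176,0.188,105103,0.700,104384,0.011
2004,99217,98859,0.361,97660,1.569,98590,0.632
2005,98738,93468,5.337,96681,2.083,94190,4.606
2006,89455,88042,1.580,89975,0.581,88476,1.094
2007,81649,82621,1.190,83033,1.695,82714,1.304
2008,73484,77246,5.119,72208,1.736,76114,3.579
2009,67159,71955,7.141,69830,3.977,71478,6.431
2010,65225,66785,2.392,64208,1.559,66206,1.504
2011,62387,61769,0.991,62035,0.564,61829,0.894
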