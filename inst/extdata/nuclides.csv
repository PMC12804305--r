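id,half_life_value,half_life_unit,emissions,daughters
H-3,4500.0,d,,
C-11,20.364,min,511:199.5,
C-14,2081925,d,,
N-13,9.965,min,511:199.6,
O-15,122.24,s,511:199.8,
F-18,109.77,min,511:193.5,
Na-22,950.57,d,1274.5:99.9,
Na-24,14.997,h,1368.6:100.0,
P-32,14.268,d,,
P-33,25.35,d,,
S-35,87.37,d,,
K-42,12.355,h,1524.6:18.1,
Ca-45,162.61,d,,
Ca-47,4.536,d,1297.1:67.0,
Sc-43,3.891,h,511:176.2,
Sc-44,3.97,h,1157.0:99.9;511:188.8,
Sc-47,3.3492,d,159.4:68.3,
Cr-51,27.704,d,320.1:9.91,
Mn-52,5.591,d,744.2:90.0;935.5:94.5,
Fe-52,8.275,h,168.7:99.2,
Fe-59,44.495,d,1099.2:56.5;1291.6:43.2,
Co-55,17.53,h,931.1:75.0,
Co-57,271.74,d,122.1:85.6;136.5:10.7,
Co-58,70.86,d,810.8:99.5,
Co-60,1925.28,d,1173.2:99.85;1332.5:99.98,
Cu-60,23.7,min,1332.5:88.0,
Cu-61,3.339,h,283.0:12.2;511:123.0,
Cu-62,9.67,min,511:195.6,
Cu-64,12.701,h,511:35.2;1345.8:0.475,
Cu-67,61.83,h,184.6:48.7,
Zn-62,9.186,h,596.6:26.0,
Zn-65,243.93,d,1115.5:50.0,
Ga-66,9.49,h,1039.2:37.0,
Ga-67,3.2617,d,93.3:38.8;184.6:21.4;300.2:16.6,
Ga-68,67.71,min,511:177.8;1077.3:3.22,
Ge-68,270.95,d,,Ga-68:1.0
As-72,26.0,h,834.0:81.0,
As-74,17.77,d,595.8:59.0,
As-77,38.79,h,239.0:1.59,
Se-73,7.15,h,361.2:97.0,
Se-75,119.78,d,264.7:58.9;136.0:58.5,
Br-76,16.2,h,559.1:74.0,
Br-77,57.04,h,239.0:23.1,
Rb-82,1.2575,min,511:190.9;776.5:15.1,
Sr-89,50.563,d,909.0:0.0096,
Sr-90,10512.5,d,,Y-90:1.0
Y-86,14.74,h,1076.6:82.5,
Y-90,64.05,h,,
Zr-89,78.41,h,909.0:99.0;511:45.5,
Nb-90,14.6,h,1129.2:92.7,
Mo-99,65.976,h,739.5:12.2,Tc-99m:0.8855
Tc-99m,6.0067,h,140.5:89.0,
Ru-97,2.8370,d,215.7:85.6,
Rh-105,35.36,h,319.1:19.1,
Pd-103,16.991,d,357.5:0.022,
Ag-111,7.45,d,342.1:6.7,
Cd-109,461.4,d,88.0:3.64,
In-111,2.8047,d,171.3:90.7;245.4:94.1,
In-113m,99.476,min,391.7:64.9,
Sn-117m,14.00,d,158.6:86.4,
Sb-119,38.19,h,23.9:16.5,
Te-123m,119.2,d,159.0:84.0,
I-123,13.2235,h,159.0:83.3,
I-124,4.176,d,602.7:62.9;511:45.0,
I-125,59.388,d,35.5:6.68,
I-131,8.0252,d,364.5:81.5,
Xe-133,5.2475,d,81.0:36.9,
Cs-131,9.689,d,29.5:21.1,
Cs-137,10976,d,,Ba-137m:0.944
Ba-133,3854.7,d,356.0:62.1;81.0:32.9,
Ba-137m,2.552,min,661.7:85.1,
La-135,19.5,h,480.5:1.52,
Ce-134,3.16,d,130.4:0.209,
Pr-142,19.12,h,1575.6:3.7,
Nd-140,3.37,d,,
Pm-149,53.08,h,286.0:3.1,
Sm-153,46.284,h,103.2:29.25,
Gd-153,240.4,d,97.4:29.0;103.2:21.1,
Tb-149,4.118,h,352.2:29.4,
Tb-152,17.5,h,344.3:63.5,
Tb-155,5.32,d,86.6:32.0;105.3:25.1,
Tb-161,6.89,d,74.6:10.2;25.7:23.2,
Ho-166,26.824,h,80.6:6.71,
Er-169,9.392,d,,
Tm-170,128.6,d,84.3:2.48,
Yb-175,4.185,d,396.3:13.2,
Lu-177,6.6443,d,208.4:10.4;112.9:6.2,
Re-186,3.7186,d,137.2:9.47,
Re-188,17.005,h,155.0:15.6,
Os-191,15.4,d,129.4:26.5,
Ir-192,73.829,d,316.5:82.9;468.1:47.8,
Pt-195m,4.010,d,98.9:11.7,
Au-198,2.6947,d,411.8:95.6,
Au-199,3.139,d,158.4:40.0,
Hg-197,64.14,h,77.4:18.7,
Tl-201,3.0421,d,167.4:10.0;135.3:2.6,
Tl-208,3.053,min,2614.5:99.75;583.2:85.0,
Tl-209,2.16,min,1567.1:99.7,
Pb-203,51.92,h,279.2:80.9,
Pb-209,3.234,h,,
Pb-212,10.6,h,238.6:43.6,Bi-212:1.0
Bi-212,60.55,min,727.3:6.67,Tl-208:0.3594;Po-212:0.6406
Bi-213,45.6,min,440.0:25.9,Po-213:0.9791;Tl-209:0.0209
Po-210,138.376,d,803.1:0.00122,
Po-212,2.99e-7,s,,
Po-213,3.72e-6,s,,
Po-216,0.145,s,,Pb-212:1.0
At-211,7.214,h,687.0:0.26,
At-217,0.0323,s,,Bi-213:1.0
Rn-220,55.6,s,,Po-216:1.0
Rn-222,3.8235,d,511.0:0.076,
Fr-221,4.80,min,218.0:11.4,At-217:1.0
Ra-223,11.43,d,269.5:13.9,
Ra-224,3.63,d,241.0:4.1,Rn-220:1.0
Ra-225,14.9,d,40.1:30.0,Ac-225:1.0
Ra-226,584049,d,186.2:3.64,Rn-222:1.0
Ac-225,9.92,d,99.8:1.01,Fr-221:1.0
Th-227,18.697,d,236.0:12.9,Ra-223:1.0
Th-232,5.049e12,d,,
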