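residue,hyd01,hyd02,hyd03,hyd04,hyd05,hyd06,hyd07,hyd08,hyd09,hyd10,hyd11,hyd12,hyd13,hyd14,hyd15,hyd16,ste01,ste02,ste03,ste04,ste05,ste06,ste07,ste08,ste09,ste10,ste11,ste12,ste13,ste14,ste15,ste16,ste17,ele01,ele02,ele03,ele04,ele05,ele06,ele07,ele08,ele09,ele10,ele11,ele12,ele13,ele14,ele15
category,hydrophobic,hydrophobic,hydrophobic,hydrophobic,hydrophobic,hydrophobic,hydrophobic,hydrophobic,hydrophobic,hydrophobic,hydrophobic,hydrophobic,hydrophobic,hydrophobic,hydrophobic,hydrophobic,steric,steric,steric,steric,steric,steric,steric,steric,steric,steric,steric,steric,steric,steric,steric,steric,steric,electronic,electronic,electronic,electronic,electronic,electronic,electronic,electronic,electronic,electronic,electronic,electronic,electronic,electronic,electronic
A,1.800,-0.500,0.948,-0.535,0.086,0.068,1.121,-0.063,-0.304,1.030,-0.727,0.904,-1.253,1.171,-0.093,0.307,71.080,88.600,129.000,0.046,1.078,-0.911,1.107,1.125,-1.486,1.490,1.427,-1.835,0.471,-1.025,-1.433,2.057,-1.620,0.000,6.000,8.100,-0.121,-0.039,-0.045,-0.023,-0.359,0.764,0.011,-0.131,0.334,0.159,-0.629,0.604
R,-4.500,3.000,-0.815,1.052,-1.470,1.011,-0.654,1.319,1.327,0.851,1.457,-1.107,1.682,0.885,-1.299,-2.057,156.190,173.400,274.000,0.291,-0.233,1.477,-0.483,-1.741,1.056,-0.314,-1.130,1.207,-0.877,0.812,0.954,-1.783,0.916,1.000,10.760,10.500,-1.888,2.676,1.729,2.215,-1.737,0.725,2.466,-0.533,0.106,-0.232,2.053,-2.330
N,-3.500,0.200,-0.888,-0.554,0.766,-0.211,0.854,1.053,-0.157,-0.509,0.529,-0.931,0.507,-1.156,-0.046,-0.601,114.100,114.100,195.000,0.134,0.948,0.109,0.577,0.171,0.202,0.556,0.174,-0.681,-0.333,0.398,-0.401,0.178,-0.755,0.000,5.410,11.600,-1.141,0.679,-0.388,-0.314,-1.024,-0.259,-0.076,1.174,0.598,-0.881,0.261,0.116
D,-3.500,3.000,-0.713,-0.305,-0.970,1.250,-2.084,0.341,1.291,0.491,1.635,-2.384,0.819,1.080,-1.684,-0.919,115.090,111.100,193.000,0.105,0.353,0.093,0.913,-0.456,-0.289,0.112,0.329,0.799,1.347,0.336,-1.183,-0.357,-0.382,-1.000,2.770,13.000,-0.893,-0.629,-2.173,-1.895,-0.628,-0.388,-2.279,1.959,2.885,-1.895,-2.170,2.176
C,2.500,-1.000,0.717,-2.170,0.272,1.011,0.939,-0.373,-0.470,0.663,-0.464,1.135,-0.902,-0.049,0.421,0.819,103.140,108.500,167.000,0.128,0.978,-0.088,0.581,0.061,-0.583,0.344,0.978,-0.493,-0.598,0.825,-0.646,0.233,-0.483,0.000,5.070,5.500,1.720,-0.800,0.353,-1.014,1.068,0.620,-0.348,-1.121,0.118,1.117,0.117,-0.241
Q,-3.500,0.200,-0.919,0.815,1.196,0.253,-1.196,-0.297,0.747,-0.486,1.297,-0.362,0.937,0.679,-0.443,-1.212,128.130,143.800,225.000,0.180,-0.446,1.022,0.213,-0.196,-0.129,0.012,-0.184,0.887,0.197,0.048,0.200,-0.549,0.337,0.000,5.650,10.500,-0.515,0.054,0.132,0.246,-0.894,-1.177,-0.635,1.299,0.402,-0.803,-0.374,0.025
E,-3.500,3.000,-0.437,2.043,-0.085,1.006,-1.521,1.740,1.646,-0.786,0.817,-1.270,1.175,0.954,-1.760,-1.186,129.120,138.400,223.000,0.151,-0.537,1.095,0.633,-0.123,1.082,-0.133,-0.157,-0.383,1.461,0.748,-0.051,-0.609,0.024,-1.000,3.220,12.300,-0.422,-0.761,-2.430,-0.742,-0.717,2.037,-1.858,1.810,1.651,-1.772,-2.245,2.083
G,-0.400,0.000,-0.307,0.360,-1.040,-0.336,-0.414,-0.307,0.051,0.371,0.004,-0.092,0.010,0.530,-0.117,0.068,57.050,60.100,104.000,0.000,2.344,-2.616,1.949,1.737,-1.332,1.451,2.216,-1.284,1.230,-2.448,-1.446,1.196,-1.983,0.000,5.970,9.000,-0.382,0.100,0.088,-0.164,-0.230,-1.402,0.403,-0.075,0.285,-0.171,-0.197,0.225
H,-3.200,-0.500,-1.261,-0.472,-0.828,-0.716,0.940,-0.287,0.367,-0.844,0.282,-0.231,1.005,0.715,-0.136,-0.400,137.140,153.200,224.000,0.230,0.303,-0.198,-0.243,-1.020,0.489,0.425,-0.436,1.077,-0.363,-0.339,0.493,-0.630,0.521,0.100,7.590,10.400,-0.997,0.859,0.395,0.936,-0.588,1.864,-0.113,0.720,0.795,-0.960,0.241,-0.380
I,4.500,-1.800,1.630,-0.343,0.360,0.901,0.083,-2.022,-1.219,0.562,-1.034,1.241,-1.724,-0.136,0.815,1.624,113.160,166.700,197.000,0.186,-0.987,-0.062,-0.784,0.581,0.313,-0.479,-0.064,0.686,-0.413,1.112,0.595,0.732,0.411,0.000,6.020,5.200,0.639,-0.829,-0.377,-0.298,1.314,-1.001,0.789,-1.182,-1.336,1.078,0.098,-0.293
L,3.800,-1.800,1.522,-0.230,-0.767,-0.104,-0.148,-0.668,-0.900,1.941,-0.809,1.022,-1.162,-0.561,1.466,1.212,113.160,166.700,201.000,0.186,-0.373,-0.659,-0.713,0.616,-0.674,-0.301,-0.230,-0.638,0.658,-0.909,0.314,0.821,0.319,0.000,5.980,4.900,1.437,-0.671,0.275,0.604,1.493,-0.285,-0.264,-1.020,-0.561,1.070,0.004,-0.132
K,-3.900,3.000,-1.106,1.702,-1.685,0.387,-1.120,1.121,1.514,-0.712,1.635,-1.014,1.138,1.641,-1.373,-1.413,128.170,168.600,236.000,0.219,-1.882,0.508,-0.126,-0.813,0.912,-0.138,-0.414,0.336,0.276,0.554,0.593,0.028,0.422,1.000,9.740,11.300,-1.499,2.476,1.599,2.383,-1.685,-1.153,1.476,-0.346,-0.469,-0.398,1.987,-1.881
M,1.900,-1.300,0.791,-1.099,-0.441,0.552,-0.633,-0.822,-0.646,0.447,-0.811,0.890,-0.615,-1.086,0.270,1.003,131.190,162.900,224.000,0.221,-0.815,0.725,-0.864,-0.040,0.026,0.000,-0.604,0.967,-0.201,-0.528,0.452,-0.392,0.437,0.000,5.740,5.700,1.010,-0.670,-0.244,-0.604,0.568,-0.990,0.390,-0.723,-0.807,1.194,-0.021,-0.123
F,2.800,-2.500,1.070,-0.807,0.186,-0.250,0.727,-1.215,-1.509,0.808,-0.851,1.025,-1.079,-1.016,0.941,0.997,147.180,189.900,240.000,0.290,-0.870,0.320,-1.122,-0.590,0.875,-0.779,-0.837,0.637,-0.697,-0.357,1.309,-0.851,0.984,0.000,5.480,5.200,0.686,-0.724,0.621,-0.192,1.193,-0.019,0.335,-0.917,-0.122,0.850,0.271,0.145
P,-1.600,0.000,-0.291,0.854,-0.137,-0.482,0.273,1.215,0.707,-1.151,0.457,-0.381,0.381,-0.799,0.020,-0.218,97.120,112.700,159.000,0.131,0.988,-1.719,0.375,0.787,-0.717,0.892,0.601,-0.311,0.917,-0.468,-0.452,0.652,-0.708,0.000,6.300,8.000,-0.402,-0.221,-0.231,0.213,-0.261,-0.058,-0.019,0.013,-0.573,-0.453,0.519,-0.263
S,-0.800,0.300,0.510,0.865,-0.421,-0.236,-0.155,0.861,0.043,-1.071,0.226,-0.068,0.010,0.062,-0.725,-0.316,87.080,89.000,155.000,0.062,0.830,-0.613,1.072,1.200,-1.216,0.387,0.978,-1.503,0.385,-0.879,-1.345,0.341,-1.101,0.000,5.680,9.200,0.156,0.149,-0.547,-0.237,0.010,-0.816,0.264,0.488,-0.709,-0.606,-0.101,-0.023
T,-0.700,-0.400,-0.247,0.217,1.049,0.228,-0.455,-0.271,0.714,0.536,0.037,-0.056,0.320,0.623,-0.029,0.305,101.100,116.100,172.000,0.108,0.460,-0.366,0.566,0.691,-0.191,1.010,0.588,-0.664,0.309,-0.762,-0.860,0.714,-0.598,0.000,5.600,8.600,0.057,-0.339,-0.283,-0.031,-0.316,-0.522,-0.009,0.636,-0.846,-0.349,0.056,0.338
W,-0.900,-3.400,-0.713,-0.800,2.392,-3.083,1.172,-1.516,-0.944,-1.694,-1.104,0.940,0.130,-1.456,1.411,0.854,186.210,227.800,285.000,0.409,-1.032,0.329,-2.232,-2.116,2.228,-3.097,-2.147,1.849,-2.768,1.673,2.009,-1.192,2.297,0.000,5.890,5.400,0.987,-0.520,0.889,-0.592,0.532,0.112,-0.595,-1.394,-1.362,0.976,0.075,-0.051
Y,-1.300,-2.300,-1.141,-0.442,0.910,-1.541,1.353,-0.062,-1.346,-1.527,-0.989,-0.154,0.090,-1.942,1.166,0.423,163.180,193.600,263.000,0.298,-0.779,1.381,-1.412,-0.832,0.880,-1.166,-1.342,-0.729,-1.355,1.549,1.390,-1.735,1.134,0.000,5.660,6.200,0.487,-0.434,-0.058,-0.861,1.066,1.160,0.067,-0.427,0.046,0.758,0.003,0.035
V,4.200,-1.500,1.650,-0.150,0.625,0.293,0.917,0.253,-0.913,1.081,-1.586,0.893,-1.468,-0.141,1.194,0.710,99.130,140.000,174.000,0.140,-0.326,0.174,-0.007,0.958,-1.448,-0.272,0.252,0.076,0.353,-0.339,-0.492,1.145,-0.172,0.000,5.960,5.900,1.081,-0.355,0.695,0.369,1.197,0.787,-0.004,-0.227,-0.436,1.318,0.054,-0.028
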