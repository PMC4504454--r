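"bin_center","density"
0.001953,0.542739
0.005859,0.687164
0.009766,0.860497
0.013672,1.06539
0.017578,1.30387
0.021484,1.57701
0.025391,1.88476
0.029297,2.22559
0.033203,2.59639
0.037109,2.99227
0.041016,3.40656
0.044922,3.83091
0.048828,4.25545
0.052734,4.66914
0.056641,5.06023
0.060547,5.41679
0.064453,5.72727
0.068359,5.98118
0.072266,6.16965
0.076172,6.28594
0.080078,6.32587
0.083984,6.28805
0.087891,6.17399
0.091797,5.98798
0.095703,5.73686
0.099609,5.42959
0.103516,5.07671
0.107422,4.6898
0.111328,4.2808
0.115234,3.86145
0.119141,3.44276
0.123047,3.03453
0.126953,2.64508
0.130859,2.28099
0.134766,1.94709
0.138672,1.64644
0.142578,1.38048
0.146484,1.14925
0.150391,0.951604
0.154297,0.785515
0.158203,0.648304
0.162109,0.536909
0.166016,0.448102
0.169922,0.378661
0.173828,0.325513
0.177734,0.285827
0.181641,0.257075
0.185547,0.237063
0.189453,0.223927
0.193359,0.216126
0.197266,0.212405
0.201172,0.211772
0.205078,0.213447
0.208984,0.216837
0.212891,0.221494
0.216797,0.227087
0.220703,0.233374
0.224609,0.240182
0.228516,0.24739
0.232422,0.254913
0.236328,0.262692
0.240234,0.270687
0.244141,0.278871
0.248047,0.287225
0.251953,0.295737
0.255859,0.304396
0.259766,0.313198
0.263672,0.322135
0.267578,0.331203
0.271484,0.340398
0.275391,0.349716
0.279297,0.359152
0.283203,0.368703
0.287109,0.378363
0.291016,0.388128
0.294922,0.397994
0.298828,0.407954
0.302734,0.418005
0.306641,0.42814
0.310547,0.438353
0.314453,0.448639
0.318359,0.458991
0.322266,0.469402
0.326172,0.479867
0.330078,0.490378
0.333984,0.500928
0.337891,0.51151
0.341797,0.522116
0.345703,0.532739
0.349609,0.543371
0.353516,0.554003
0.357422,0.564628
0.361328,0.575238
0.365234,0.585823
0.369141,0.596376
0.373047,0.606887
0.376953,0.617347
0.380859,0.627749
0.384766,0.638082
0.388672,0.648338
0.392578,0.658508
0.396484,0.668582
0.400391,0.678551
0.404297,0.688406
0.408203,0.698139
0.412109,0.707738
0.416016,0.717196
0.419922,0.726503
0.423828,0.735651
0.427734,0.744629
0.431641,0.753429
0.435547,0.762043
0.439453,0.770461
0.443359,0.778675
0.447266,0.786677
0.451172,0.794457
0.455078,0.802009
0.458984,0.809324
0.462891,0.816393
0.466797,0.823211
0.470703,0.829769
0.474609,0.83606
0.478516,0.842077
0.482422,0.847815
0.486328,0.853265
0.490234,0.858424
0.494141,0.863284
0.498047,0.86784
0.501953,0.872088
0.505859,0.876023
0.509766,0.879639
0.513672,0.882934
0.517578,0.885903
0.521484,0.888543
0.525391,0.890851
0.529297,0.892824
0.533203,0.89446
0.537109,0.895758
0.541016,0.896715
0.544922,0.897331
0.548828,0.897605
0.552734,0.897536
0.556641,0.897125
0.560547,0.896373
0.564453,0.895279
0.568359,0.893846
0.572266,0.892075
0.576172,0.889967
0.580078,0.887526
0.583984,0.884755
0.587891,0.881655
0.591797,0.878231
0.595703,0.874487
0.599609,0.870427
0.603516,0.866055
0.607422,0.861376
0.611328,0.856396
0.615234,0.85112
0.619141,0.845554
0.623047,0.839704
0.626953,0.833576
0.630859,0.827177
0.634766,0.820515
0.638672,0.813595
0.642578,0.806427
0.646484,0.799016
0.650391,0.791372
0.654297,0.783502
0.658203,0.775415
0.662109,0.767118
0.666016,0.75862
0.669922,0.749931
0.673828,0.741058
0.677734,0.732011
0.681641,0.722799
0.685547,0.71343
0.689453,0.703915
0.693359,0.694261
0.697266,0.684479
0.701172,0.674577
0.705078,0.664564
0.708984,0.654451
0.712891,0.644246
0.716797,0.633958
0.720703,0.623596
0.724609,0.61317
0.728516,0.602688
0.732422,0.592159
0.736328,0.581592
0.740234,0.570996
0.744141,0.56038
0.748047,0.549751
0.751953,0.539118
0.755859,0.528488
0.759766,0.517871
0.763672,0.507274
0.767578,0.496704
0.771484,0.486169
0.775391,0.475675
0.779297,0.465231
0.783203,0.454842
0.787109,0.444516
0.791016,0.434259
0.794922,0.424076
0.798828,0.413974
0.802734,0.403959
0.806641,0.394036
0.810547,0.38421
0.814453,0.374486
0.818359,0.364869
0.822266,0.355363
0.826172,0.345973
0.830078,0.336703
0.833984,0.327556
0.837891,0.318536
0.841797,0.309646
0.845703,0.300889
0.849609,0.292269
0.853516,0.283787
0.857422,0.275447
0.861328,0.267249
0.865234,0.259197
0.869141,0.251291
0.873047,0.243534
0.876953,0.235926
0.880859,0.228468
0.884766,0.221162
0.888672,0.214008
0.892578,0.207006
0.896484,0.200157
0.900391,0.193461
0.904297,0.186918
0.908203,0.180527
0.912109,0.174288
0.916016,0.1682
0.919922,0.162263
0.923828,0.156476
0.927734,0.150838
0.931641,0.145347
0.935547,0.140003
0.939453,0.134804
0.943359,0.129749
0.947266,0.124836
0.951172,0.120062
0.955078,0.115428
0.958984,0.110929
0.962891,0.106566
0.966797,0.102335
0.970703,0.0982345
0.974609,0.0942625
0.978516,0.0904165
0.982422,0.0866943
0.986328,0.0830937
0.990234,0.0796123
0.994141,0.0762476
0.998047,0.0729973
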