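region,scanner_id,metric,slope,intercept,r2
abdomen_pelvis,CT1,sed,0.747,-2.236,0.675
abdomen_pelvis,CT2,sed,0.709,-1.005,0.874
chest,CT1,sed,0.548,-0.169,0.905
chest,CT2,sed,0.446,0.059,0.949
cap,CT1,sed,0.749,1.092,0.759
cap,CT2,sed,0.922,-0.580,0.913
abdomen,CT1,sed,0.389,-0.540,0.844
chest_abdomen,CT1,sed,0.717,-0.093,0.818
abdomen_pelvis,CT1,ed,1.123,-7.217,0.657
abdomen_pelvis,CT2,ed,0.921,-2.8,0.936
chest,CT1,ed,0.714,-1.031,0.850
chest,CT2,ed,0.454,0.0733,0.927
cap,CT1,ed,0.935,-0.248,0.452
cap,CT2,ed,1.182,-2.179,0.921
abdomen,CT1,ed,0.510,-2.116,0.827
chest_abdomen,CT1,ed,0.935,-2.098,0.673
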